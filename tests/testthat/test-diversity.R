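# exhaustive subset-mean oracle for rarefied richness: mean number of
# species over all size-t subsets of sampling units
subset_mean_richness <- function(m, t) {
  combs <- utils::combn(nrow(m), t)
  mean(apply(combs, 2, function(idx)
    sum(colSums(m[idx, , drop = FALSE]) > 0)))
}

test_that("sample coverage matches the hand-evaluated estimator", {
  # T=4, Y=(4,1,1): U=6, Q1=2, Q2=0 -> 1 - (2/6)*(6/6)
  inc <- incidence_freq(c(a = 4, b = 1, c = 1), T = 4)
  expect_equal(sample_coverage(inc, 4), 1 - 2 / 6, tolerance = 1e-12)
  # no uniques -> full coverage
  inc0 <- incidence_freq(c(a = 3, b = 2), T = 4)
  expect_equal(sample_coverage(inc0, 4), 1)
  expect_error(sample_coverage(incidence_freq(c(a = 2), T = 2), 0), ">= 1")
})

test_that("coverage is nondecreasing in t across random fixtures", {
  for (s in 1:25) {
    inc <- random_incidence(T = sample(3:8, 1), S = sample(2:10, 1),
                            seed = s)
    cov <- sample_coverage(inc, seq_len(3 * inc$T))
    expect_true(all(diff(cov) >= -1e-12), info = paste("seed", s))
    expect_true(all(cov >= 0 & cov <= 1))
  }
})

test_that("interpolated richness equals the exhaustive subset mean", {
  # hand case: T=3, Y=(3,1), t=2 -> 2 - C(2,2)/C(3,2) = 5/3
  inc <- incidence_freq(c(a = 3, b = 1), T = 3)
  expect_equal(interpolate_richness(inc, 2), 5 / 3, tolerance = 1e-12)
  expect_equal(interpolate_richness(inc, 3), 2)       # t = T -> S_obs
  expect_equal(interpolate_richness(inc, 1), inc$U / inc$T)  # linearity
  expect_error(interpolate_richness(inc, 4), "1..T")

  for (s in 1:30) {
    inc <- random_incidence(T = sample(3:8, 1), S = sample(2:10, 1),
                            seed = 100 + s)
    for (t in seq_len(inc$T)) {
      expect_equal(interpolate_richness(inc, t),
                   subset_mean_richness(inc$unit_matrix, t),
                   tolerance = 1e-10)
    }
  }
})

test_that("chao2 reproduces hand evaluations and dominates S_obs", {
  expect_equal(chao2(incidence_freq(c(a = 4, b = 4, c = 1, d = 1, e = 2),
                                    T = 4)), 6.5)  # 5 + (3/4)*(4/2)
  inc2 <- incidence_freq(stats::setNames(c(rep(5, 6), rep(1, 4)),
                                         paste0("s", 1:10)), T = 5)
  expect_equal(chao2(inc2), 14.8)  # bias-corrected branch, Q2 = 0
  inc0 <- incidence_freq(c(a = 3, b = 2), T = 4)
  expect_equal(chao2(inc0), inc0$S_obs)
  expect_error(chao2(incidence_freq(c(a = 1), T = 1)), "T >= 2")
  for (s in 1:20) {
    inc <- random_incidence(sample(3:8, 1), sample(2:10, 1), seed = 200 + s)
    expect_gte(chao2(inc), inc$S_obs)
  }
})

test_that("extrapolation starts at S_obs, approaches chao2, is continuous", {
  inc <- incidence_freq(c(a = 4, b = 4, c = 1, d = 1, e = 2), T = 4)
  expect_equal(extrapolate_richness(inc, 0), inc$S_obs)
  expect_equal(extrapolate_richness(inc, 1e6), 6.5, tolerance = 1e-6)
  inc0 <- incidence_freq(c(a = 3, b = 2), T = 4)
  expect_equal(extrapolate_richness(inc0, 50), inc0$S_obs)
  for (s in 1:10) {
    inc <- random_incidence(sample(4:8, 1), sample(3:10, 1), seed = 300 + s)
    # slope continuity is not required, value continuity is
    expect_equal(extrapolate_richness(inc, 0),
                 interpolate_richness(inc, inc$T))
    curve <- vapply(1:(2 * inc$T), function(t)
      if (t <= inc$T) interpolate_richness(inc, t)
      else extrapolate_richness(inc, t - inc$T), numeric(1))
    expect_true(all(diff(curve) >= -1e-10))
  }
})

test_that("hill q=1 behaves at the boundary cases", {
  # perfect evenness: equals the richness estimate at t = T
  even <- incidence_freq(c(a = 2, b = 2), T = 2)
  expect_equal(hill_shannon(even, 2), 2)
  # single species present in every unit -> 1 at all t
  one <- incidence_freq(c(a = 5), T = 5)
  expect_equal(hill_shannon(one, c(1, 3, 5, 8)), rep(1, 4))
  # plug-in oracle at the reference size
  for (s in 1:10) {
    inc <- random_incidence(sample(3:8, 1), sample(3:10, 1), seed = 400 + s)
    ai <- inc$Y / inc$U
    expect_equal(hill_shannon(inc, inc$T), exp(-sum(ai * log(ai))),
                 tolerance = 1e-10)
  }
})

test_that("hill estimates are ordered q1 <= q0 and q0 is nondecreasing", {
  for (s in 1:15) {
    inc <- random_incidence(sample(4:8, 1), sample(3:10, 1), seed = 500 + s)
    ts <- 1:(2 * inc$T)
    q0 <- vapply(ts, function(t)
      if (t <= inc$T) interpolate_richness(inc, t)
      else extrapolate_richness(inc, t - inc$T), numeric(1))
    q1 <- hill_shannon(inc, ts)
    expect_true(all(q1 <= q0 + 1e-8), info = paste("seed", s))
    expect_true(all(diff(q0) >= -1e-10))
  }
})

test_that("coverage standardisation finds the linear-scan t", {
  for (s in 1:10) {
    inc <- random_incidence(sample(4:8, 1), sample(3:10, 1), seed = 600 + s)
    target <- 0.97
    cov <- sample_coverage(inc, seq_len(3 * inc$T))
    hit <- which(cov >= target - 1e-12)
    est <- tryCatch(
      suppressWarnings(estimate_at_coverage(inc, 0, target, B = 50, seed = 1)),
      error = function(e) e)
    if (length(hit)) {
      expect_equal(suppressWarnings(
        estimate_at_coverage(inc, 0, target, B = 50, seed = 1)$t), hit[1])
    } else {
      expect_s3_class(est, "error")
      expect_match(conditionMessage(est), "cap")
    }
  }
  # Q1 = 0 assemblage: coverage 1 at T, any target satisfied by t <= T
  inc0 <- incidence_freq(c(a = 3, b = 2), T = 4)
  expect_lte(estimate_at_coverage(inc0, 0, 0.99, B = 50)$t, inc0$T)
  expect_error(estimate_at_coverage(inc0, 0, 1.5), "target_coverage")
})

test_that("unit bootstrap matches the exhaustive resample oracle at T=4", {
  inc <- random_incidence(T = 4, S = 6, seed = 42)
  t_eval <- 3
  # enumerate all 4^4 equally likely resamples of the 4 units
  grid <- expand.grid(rep(list(1:4), 4))
  stats_all <- apply(grid, 1, function(idx) {
    Y <- colSums(inc$unit_matrix[as.integer(idx), , drop = FALSE])
    Y <- Y[Y > 0]
    if (!length(Y)) return(0)
    interpolate_richness(incidence_freq(Y, 4), t_eval)
  })
  exact_se <- sqrt(mean((stats_all - mean(stats_all))^2))
  B <- 400
  bt <- bootstrap_ci(inc, 0, t_eval, B = B, seed = 7, type = "units")
  # 3 Monte-Carlo standard errors of a bootstrap sd estimate
  mc_tol <- 3 * exact_se / sqrt(2 * (B - 1))
  expect_lt(abs(bt$se - exact_se), mc_tol + 1e-8)
})

test_that("bootstrap determinism and degenerate cases", {
  inc <- random_incidence(T = 6, S = 8, seed = 3)
  b1 <- bootstrap_ci(inc, 0, 4, B = 100, seed = 11)
  b2 <- bootstrap_ci(inc, 0, 4, B = 100, seed = 11)
  expect_identical(b1, b2)
  # all units identical -> zero variance
  m <- matrix(TRUE, 5, 3)
  inc_const <- incidence_freq(unit_matrix = m)
  bt <- bootstrap_ci(inc_const, 0, 3, B = 60, seed = 1, type = "units")
  expect_equal(bt$se, 0)
  expect_equal(bt$ci84[1], bt$ci84[2])
  expect_error(bootstrap_ci(incidence_freq(c(a = 1), T = 1), 0, 1, B = 60),
               "single sampling unit")
  expect_error(bootstrap_ci(inc, 0, 4, B = 10), "B must be >= 50")
  # chao-style bootstrap also runs and is seeded
  c1 <- bootstrap_ci(inc, 1, 4, B = 80, seed = 5, type = "chao")
  c2 <- bootstrap_ci(inc, 1, 4, B = 80, seed = 5, type = "chao")
  expect_identical(c1, c2)
  expect_gte(c1$se, 0)
})

test_that("84% CI overlap comparison follows the boundary convention", {
  mk <- function(est, se, target = 0.97) {
    structure(list(q = 0, t = 5, T = 5, estimate = est, se = se,
                   ci84 = c(est - 1.4051 * se, est + 1.4051 * se),
                   ci95 = c(est - 1.96 * se, est + 1.96 * se),
                   coverage = target, target_coverage = target,
                   extrapolated = FALSE, label = "x"),
              class = "hill_estimate")
  }
  expect_false(compare_methods(mk(5, 1), mk(5, 1)))
  expect_true(compare_methods(mk(1, 0.3), mk(10, 0.3)))
  # touching endpoints: [1,2] vs [2,3] -> overlap -> not significant
  a <- mk(1.5, 0.5 / 1.4051); b <- mk(2.5, 0.5 / 1.4051)
  expect_false(compare_methods(a, b))
  bad <- mk(5, 1, target = 0.9)
  expect_error(compare_methods(mk(5, 1), bad), "coverage")
})
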