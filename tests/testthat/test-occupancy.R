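test_that("detection histories have the documented structure", {
  d <- small_dataset(seed = 1)
  h <- build_history(d, "famA")
  nocc <- rowSums(!is.na(h$y))
  # PC-only sites have 3 occasions; ARU+PC sites 3 + 2 days x 5 windows
  expect_setequal(unique(nocc), c(3, 13))
  # lag is zero on every PC occasion and every first-of-day ARU window
  pc_occ <- h$occ$method == 0 & !is.na(h$occ$method)
  expect_true(all(h$occ$lag[pc_occ] == 0))
  first_of_day <- is.na(h$lag_src) & !is.na(h$y)
  expect_true(all(h$occ$lag[first_of_day] == 0))
  # lag equals the previous window's detection elsewhere
  src_ok <- !is.na(h$lag_src)
  expect_equal(h$occ$lag[src_ok],
               h$y[cbind(row(h$lag_src)[src_ok], h$lag_src[src_ok])])
  # never-detected sites are retained (they inform psi)
  expect_true(any(rowSums(h$y, na.rm = TRUE) == 0))
  expect_error(build_history(d, "not-a-family"), "not present")
})

test_that("the candidate set enumerates exactly nine well-formed models", {
  ms <- model_set()
  expect_length(ms, 9)
  base <- ms$baseline$det_terms
  expect_setequal(base, c("wind", "hour", "hour2", "date", "date2",
                          "canopy", "canopy2", "lag"))
  for (m in ms) {
    # interactions only alongside the method main effect
    if (any(grepl("^m_", m$det_terms)))
      expect_true("method" %in% m$det_terms, info = m$name)
    expect_true(all(base %in% m$det_terms), info = m$name)
    expect_equal(m$psi_terms, c("elevation", "cres"))
  }
  expect_equal(sum(vapply(ms, function(m)
    length(m$det_terms) == length(base), logical(1))), 1)
  expect_error(occu_model_spec(c("m_date")), "main effect")
})

test_that("log-likelihood matches hand evaluations", {
  h <- toy_history(1, 2, seed = 1)
  h <- set_history_y(h, matrix(c(1, 1), 1, 2))
  spec0 <- occu_model_spec(name = "int")
  # psi = 1, p = 1 -> log L = 0
  expect_equal(occ_loglik(c(20, 20), h, spec0), 0, tolerance = 1e-6)
  # psi = 0.5, p = 0.5, y = (0,0) -> L = 0.5*0.25 + 0.5 = 0.625
  h0 <- set_history_y(h, matrix(c(0, 0), 1, 2))
  expect_equal(occ_loglik(c(0, 0), h0, spec0), log(0.625),
               tolerance = 1e-10)
  expect_error(occ_loglik(c(0, 0, 0), h0, spec0), "length")
})

test_that("log-likelihood equals the latent-state enumeration oracle", {
  spec <- occu_model_spec(
    det_terms = c("wind", "hour", "lag", "method"),
    psi_terms = c("elevation", "cres"))
  for (s in 1:30) {
    set.seed(s)
    n <- sample(2:6, 1); J <- sample(3:12, 1)
    h <- toy_history(n, J, seed = 1000 + s, n_pc = sample(0:2, 1))
    pars <- rnorm(3 + 5, 0, 1)
    # oracle: direct probability-space evaluation per site
    psi <- plogis(pars[1] + pars[2] * h$site_cov$elevation +
                    pars[3] * h$site_cov$cres)
    eta <- pars[4] + pars[5] * h$occ$wind + pars[6] * h$occ$hour +
      pars[7] * h$occ$lag + pars[8] * h$occ$method
    expect_equal(occ_loglik(pars, h, spec),
                 loglik_oracle(psi, plogis(eta), h$y),
                 tolerance = 1e-10, info = paste("seed", s))
  }
})

test_that("likelihood is invariant to site order", {
  h <- toy_history(8, 6, seed = 3, n_pc = 2)
  spec <- occu_model_spec(det_terms = c("wind", "lag"),
                          psi_terms = "elevation")
  pars <- c(0.3, -0.2, -0.5, 0.4, 0.8)
  perm <- sample(8)
  h2 <- h
  h2$y <- h$y[perm, , drop = FALSE]
  h2$lag_src <- h$lag_src[perm, , drop = FALSE]
  h2$occ <- lapply(h$occ, function(m) m[perm, , drop = FALSE])
  h2$site_cov <- h$site_cov[perm, , drop = FALSE]
  expect_equal(occ_loglik(pars, h2, spec), occ_loglik(pars, h, spec),
               tolerance = 1e-12)
})

test_that("with the lag coefficient at zero the model reduces to the
           standard single-season likelihood", {
  h <- toy_history(6, 8, seed = 4)
  with_lag <- occu_model_spec(det_terms = c("wind", "lag"),
                              psi_terms = "elevation")
  without <- occu_model_spec(det_terms = "wind", psi_terms = "elevation")
  pars <- c(0.2, -0.4, -0.3, 0.5)
  expect_equal(occ_loglik(append(pars, 0, after = 4), h, with_lag),
               occ_loglik(pars, h, without), tolerance = 1e-12)
})

test_that("QAIC follows its definition and floors chat at 1", {
  f <- list(logLik = -100, K = 5)
  expect_equal(qaic(f, 1), 212)
  expect_equal(qaic(f, 2), 112)
  expect_equal(qaic(f, 0.5), qaic(f, 1))
  expect_error(qaic(f, 0), "> 0")
})

test_that("fitting recovers parameters and rejects degenerate input", {
  spec0 <- occu_model_spec(name = "int")
  h <- toy_history(400, 5, seed = 9)
  truth <- c(qlogis(0.7), qlogis(0.4))
  ysim <- simulate_occu(h, spec0, truth, seed = 21)
  h <- set_history_y(h, ysim)
  f <- occ_fit(spec0, h, n_starts = 2)
  expect_lt(abs(plogis(f$coef[1]) - 0.7), 0.07)
  expect_lt(abs(plogis(f$coef[2]) - 0.4), 0.05)
  expect_false(f$singular_vcov)
  expect_equal(f$K, 2)
  # seeded refit is identical
  f2 <- occ_fit(spec0, h, n_starts = 2)
  expect_identical(f$coef, f2$coef)
  # single site with detections -> data-insufficient
  h1 <- toy_history(4, 4, seed = 10)
  y <- matrix(0, 4, 4); y[1, ] <- 1
  h1 <- set_history_y(h1, y)
  expect_error(occ_fit(spec0, h1), "data-insufficient")
})

test_that("chat estimation is seeded, positive and reduces QAIC to AIC at 1", {
  spec0 <- occu_model_spec(det_terms = "lag", name = "lag-only")
  h <- toy_history(60, 6, seed = 12)
  ysim <- simulate_occu(h, spec0, c(qlogis(0.6), qlogis(0.35), 0.8),
                        seed = 5)
  h <- set_history_y(h, ysim)
  f <- occ_fit(spec0, h, n_starts = 2)
  c1 <- estimate_chat(f, n_boot = 15, seed = 3)
  c2 <- estimate_chat(f, n_boot = 15, seed = 3)
  expect_identical(as.numeric(c1), as.numeric(c2))
  expect_gt(as.numeric(c1), 0)
  expect_equal(qaic(f, 1), -2 * f$logLik + 2 * (f$K + 1))
  # all-zero histories are rejected
  hz <- set_history_y(h, h$y * 0)
  fz <- f; fz$history <- hz
  expect_error(estimate_chat(fz, n_boot = 5), "zero")
})

test_that("model selection ranks, flags and tie-breaks", {
  d <- small_dataset(seed = 1)
  h <- build_history(d, "famA")
  sel <- select_model(h, chat = 1, n_starts = 1, seed = 2)
  expect_equal(nrow(sel$table), 9)
  expect_equal(sel$flag, "ok")
  expect_true(all(diff(sel$table$QAIC) >= 0))
  expect_equal(sel$table$dQAIC[1], 0)
  expect_equal(sel$best, sel$table$model[1])
  # flags driven purely by chat
  expect_equal(select_model(h, chat = 5, n_starts = 1)$flag, "lack_of_fit")
  expect_equal(select_model(h, chat = 0.2, n_starts = 1)$flag,
               "insufficient_data")
})

test_that("prediction curves stay in [0,1]; chat = 1 leaves bands alone", {
  d <- small_dataset(seed = 1)
  h <- build_history(d, "famA")
  f <- occ_fit(model_set()$method, h, n_starts = 1)
  p1 <- predict_detection(f, "hour", method = "ARU", chat = 1)
  p_half <- predict_detection(f, "hour", method = "ARU", chat = 0.5)
  expect_identical(p1, p_half)  # chat < 1 floors to 1
  p2 <- predict_detection(f, "hour", method = "ARU", chat = 2.5)
  expect_true(all(p2$lo95 >= 0 & p2$hi95 <= 1))
  expect_true(all(p2$lo95 <= p1$lo95 & p2$hi95 >= p1$hi95))
  expect_true(all(p2$lo84 >= p2$lo95 & p2$hi84 <= p2$hi95))
  expect_warning(predict_detection(f, "hour", values = c(-50, 50)),
                 "beyond")
})

test_that("delta-method prediction SE matches a Monte-Carlo oracle", {
  # two-parameter toy fit: p ~ intercept + hour
  h <- toy_history(200, 4, seed = 15)
  spec <- occu_model_spec(det_terms = "hour", name = "toy")
  ysim <- simulate_occu(h, spec, c(qlogis(0.8), -0.4, 0.6), seed = 2)
  h <- set_history_y(h, ysim)
  f <- occ_fit(spec, h, n_starts = 1)
  pd <- predict_detection(f, "hour", values = c(-1, 0, 1.5), method = "PC")
  set.seed(99)
  draws <- MASS_mvrnorm_free(1e5, f$coef[2:3], f$vcov[2:3, 2:3])
  for (i in seq_len(3)) {
    x <- c(1, pd$value[i])
    mc_se <- stats::sd(draws %*% x)
    expect_lt(abs(pd$se_logit[i] - mc_se) / mc_se, 0.05)
  }
})
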