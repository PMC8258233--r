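test_that("the full-scale designs reproduce the study tallies", {
  bc <- generate_scenario("BC", seed = 1)
  expect_equal(tally_site_surveys(bc, method = "ARU"), 700)
  expect_equal(tally_site_surveys(bc, method = "PC"), 387)
  expect_equal(tally_site_surveys(bc), 1087)
  expect_equal(nrow(bc$sites), 129)
  expect_equal(sum(bc$sites$has_aru), 52)

  cl <- generate_scenario("Chile", seed = 1)
  expect_equal(tally_site_surveys(cl, method = "ARU"), 450)
  expect_equal(tally_site_surveys(cl), 900)
  expect_equal(nrow(cl$sites), 150)
  expect_equal(sum(cl$sites$has_aru), 30)

  # assemblage sizes implied by the design
  expect_equal(build_incidence(cl, "montane", "pooled_morning")$T, 150)
  expect_equal(build_incidence(cl, "montane", "per_hour", hour = 2)$T, 30)
  expect_equal(build_incidence(bc, "alpine", "pc")$T, 48)
  expect_equal(build_incidence(bc, "montane", "pc")$T, 54)
  expect_equal(build_incidence(bc, "alpine", "pooled_morning")$T, 220)
  expect_equal(build_incidence(bc, "montane", "pooled_morning")$T, 240)
  expect_equal(build_incidence(bc, "alpine", "per_hour", hour = 0)$T, 44)
  expect_equal(build_incidence(bc, "subalpine", "per_hour", hour = 4)$T, 48)

  validate_survey_data(bc, check_habitat_rule = TRUE)
  validate_survey_data(cl, check_habitat_rule = TRUE)
  # generated occasion counts per modelling site span 3..23 in BC
  h <- build_history(bc, bc$families$family[1])
  expect_gte(min(rowSums(!is.na(h$y))), 3)
  expect_lte(max(rowSums(!is.na(h$y))), 23)
})

test_that("degenerate communities behave as specified", {
  design <- design_config("BC", n_mountains = 1, aru_mountains = 1,
                          aru_days = 2, drop_alpine_mountain = NA,
                          drop_subalpine_site = NA)
  never <- species_profiles("ghost", "famX", psi_montane = 0,
                            psi_subalpine = 0, psi_alpine = 0)
  d0 <- generate_dataset(design, never, seed = 1)
  expect_equal(nrow(d0$detections), 0)
  everywhere <- species_profiles("omni", "famY", psi_montane = 1,
                                 psi_subalpine = 1, psi_alpine = 1,
                                 b0_pc = 30, b0_aru = 30)
  d1 <- generate_dataset(design, everywhere, seed = 1)
  expect_equal(nrow(d1$detections), nrow(d1$surveys))
  expect_error(generate_dataset(design, everywhere[0, ], seed = 1),
               "empty community")
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_scenario("Chile", seed = 42)
  b <- generate_scenario("Chile", seed = 42)
  expect_identical(a, b)
  c <- generate_scenario("Chile", seed = 43)
  expect_false(identical(a$detections, c$detections))
})

test_that("empirical detection frequency converges to the configured p", {
  design <- design_config("BC", n_mountains = 4, aru_mountains = 1:4,
                          aru_days = rep(4, 4), aru_sites_per_habitat = 5,
                          drop_alpine_mountain = NA,
                          drop_subalpine_site = NA)
  p_true <- 0.3
  sp <- species_profiles("flat", "famF", psi_montane = 1,
                         psi_subalpine = 1, psi_alpine = 1,
                         b0_pc = qlogis(p_true), b0_aru = qlogis(p_true))
  hits <- 0; n <- 0
  for (s in 1:8) {
    d <- generate_dataset(design, sp, seed = 100 + s)
    hits <- hits + nrow(d$detections)
    n <- n + nrow(d$surveys)
  }
  expect_gte(n, 1e4)
  expect_lt(abs(hits / n - p_true), 0.02)
})

test_that("the Markov term induces positive within-day association", {
  design <- design_config("BC", n_mountains = 2, aru_mountains = 1:2,
                          aru_days = c(4, 4), drop_alpine_mountain = NA,
                          drop_subalpine_site = NA)
  sp <- species_profiles("sticky", "famS", psi_montane = 1,
                         psi_subalpine = 1, psi_alpine = 1,
                         b0_pc = qlogis(0.3), b0_aru = qlogis(0.2),
                         b_lag = 2)
  agree <- c(det = 0, ndet = 0); tot <- c(det = 0, ndet = 0)
  for (s in 1:6) {
    d <- generate_dataset(design, sp, seed = 200 + s)
    sv <- d$surveys[d$surveys$method == "ARU", ]
    sv <- sv[order(sv$site_id, sv$day_index, sv$hour_index), ]
    y <- sv$survey_id %in% d$detections$survey_id
    prev_ok <- c(FALSE, sv$site_id[-1] == sv$site_id[-nrow(sv)] &
                   sv$day_index[-1] == sv$day_index[-nrow(sv)])
    yprev <- c(FALSE, y[-length(y)])
    agree["det"] <- agree["det"] + sum(y[prev_ok & yprev])
    tot["det"] <- tot["det"] + sum(prev_ok & yprev)
    agree["ndet"] <- agree["ndet"] + sum(y[prev_ok & !yprev])
    tot["ndet"] <- tot["ndet"] + sum(prev_ok & !yprev)
  }
  expect_gt(agree["det"] / tot["det"], agree["ndet"] / tot["ndet"])
})

test_that("regional scenarios show the expected method biases", {
  cl <- generate_scenario("Chile", seed = 1)
  sm <- single_method_species(cl)
  expect_gt(nrow(sm$pc_only), 0)
  fam <- cl$families$family[match(sm$pc_only$species, cl$families$species)]
  silent_guilds <- c("Tyrannidae", "Accipitridae", "Falconidae",
                     "Cathartidae")
  expect_gte(mean(fam %in% silent_guilds), 0.5)
  # ARU asymptote stays below the PC asymptote in the silent-guild alpine
  expect_lt(chao2(build_incidence(cl, "alpine", "pooled_morning")),
            chao2(build_incidence(cl, "alpine", "pc")))

  bc <- generate_scenario("BC", seed = 1)
  expect_gte(chao2(build_incidence(bc, "montane", "pooled_morning")),
             chao2(build_incidence(bc, "montane", "pc")))
})
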