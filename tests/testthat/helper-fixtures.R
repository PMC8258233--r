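# Fixture builders shared across test files. Everything is generated in
# code; no fixture files.

# minimal one-site, one-survey, one-detection dataset
tiny_dataset <- function() {
  survey_dataset(
    sites = data.frame(
      site_id = "S1", region = "BC", mountain = "M01", habitat = "montane",
      elevation = 1200, canopy_cover = 70, understory_cover = 30,
      shrub_cover = 20, ground_cover = 50, has_aru = TRUE),
    surveys = data.frame(
      survey_id = "S1-PC1", site_id = "S1", method = "PC",
      date = as.Date("2019-06-01"), hours_after_sunrise = 1,
      wind_score = 0, day_index = 1, hour_index = NA_integer_,
      round_index = 1, canopy_at_survey = 70),
    detections = data.frame(survey_id = "S1-PC1", species = "sp1"),
    families = data.frame(species = "sp1", family = "fam1"),
    known = data.frame(habitat = "montane", species = "sp1"))
}

# a scaled-down two-mountain design with a handful of species; fast to
# generate, exercises every code path (PC + ARU, lag, leaf-out off)
small_dataset <- function(seed = 1, region = "BC") {
  design <- design_config(
    region, n_mountains = 2, aru_mountains = 1:2,
    aru_days = c(2, 2), drop_alpine_mountain = NA,
    drop_subalpine_site = NA)
  community <- species_profiles(
    species = paste0("sp", 1:6),
    family = c("famA", "famA", "famB", "famB", "famC", "famD"),
    psi_montane = c(0.9, 0.7, 0.3, 0.2, 0.6, 0),
    psi_subalpine = c(0.5, 0.6, 0.7, 0.5, 0.3, 0),
    psi_alpine = c(0.1, 0.2, 0.8, 0.7, 0.1, 0),
    b0_pc = c(-0.5, -1, -1, -1.5, -0.8, -1),
    b0_aru = c(-0.8, -0.7, -1.2, -Inf, -0.6, -1),
    b_hour = c(-0.3, 0, 0.2, 0, 0, 0),
    b_lag = c(1, 0, 0, 0, 0.5, 0))
  generate_dataset(design, community, seed = seed)
}

# random incidence fixture with unit-level matrix attached
random_incidence <- function(T, S, seed = 1, p = 0.4) {
  set.seed(seed)
  m <- matrix(stats::runif(T * S) < p, T, S,
              dimnames = list(NULL, paste0("sp", seq_len(S))))
  # ensure at least one detected species so U > 0
  if (all(colSums(m) == 0)) m[1, 1] <- TRUE
  incidence_freq(unit_matrix = m)
}

# hand-built detection history: n sites x J occasions, all valid, with
# random standardized covariates; ARU occasions form one day so the lag
# chain is exercised
toy_history <- function(n, J, seed = 1, n_pc = 0) {
  set.seed(seed)
  mk <- function(v) matrix(v, n, J)
  method <- mk(rep(c(rep(0, n_pc), rep(1, J - n_pc)), each = n))
  lag_src <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    if (j > n_pc + 1) lag_src[, j] <- j - 1L
  }
  y <- mk(rbinom(n * J, 1, 0.4))
  h <- structure(list(
    family = "toy", habitats = "montane",
    site_id = paste0("S", seq_len(n)),
    y = y,
    occ = list(method = method,
               wind = mk(rnorm(n * J)), hour = mk(rnorm(n * J)),
               date = mk(rnorm(n * J)), canopy = mk(rnorm(n * J)),
               lag = mk(0)),
    lag_src = lag_src,
    site_cov = data.frame(site_id = paste0("S", seq_len(n)),
                          elevation = rnorm(n), cres = rnorm(n)),
    scaling = list(wind = c(mean = 0, sd = 1), hour = c(mean = 0, sd = 1),
                   date = c(mean = 0, sd = 1),
                   canopy = c(mean = 0, sd = 1),
                   elevation = c(mean = 0, sd = 1),
                   cres = c(mean = 0, sd = 1))),
    class = "detection_history")
  set_history_y(h, y)
}

# multivariate normal draws via Cholesky (avoids a MASS dependency)
MASS_mvrnorm_free <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  sweep(matrix(stats::rnorm(n * length(mu)), n) %*% L, 2, mu, "+")
}

# direct-probability latent-state oracle for the occupancy likelihood
loglik_oracle <- function(psi, p, y) {
  # psi: length n; p, y: n x J matrices (NA = missing occasion)
  sum(vapply(seq_along(psi), function(i) {
    ok <- !is.na(y[i, ])
    cond <- prod(ifelse(y[i, ok] == 1, p[i, ok], 1 - p[i, ok]))
    log(psi[i] * cond + (1 - psi[i]) * as.numeric(all(y[i, ok] == 0)))
  }, numeric(1)))
}
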