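# Synthetic survey-data generator. Emulates a two-region mountain study
# design: per mountain, three habitats (montane/subalpine/alpine) with
# five point-count sites each surveyed in three rounds, ARUs at two sites
# per habitat on ARU-equipped mountains sampled in five hourly 6-min
# windows per day over 2-4 days. Species detections follow a logit model
# with method-specific intercepts (a zero-vocalisation species has ARU
# detection exactly 0), quadratic date/hour/canopy effects and a
# first-order Markov term linking consecutive same-day ARU windows.

#' Survey design configuration
#'
#' @param region `"BC"` or `"Chile"`.
#' @param n_mountains number of mountains (BC 9, Chile 10).
#' @param aru_mountains indices of mountains with ARUs (BC all, Chile
#'   first five).
#' @param aru_days sampled ARU days per mountain (length `n_mountains`;
#'   BC default: three 4-day mountains, six 2-day; Chile: 3 days each).
#' @param sites_per_habitat point-count sites per habitat per mountain.
#' @param aru_sites_per_habitat sites per habitat that receive an ARU.
#' @param pc_rounds point-count rounds over the season.
#' @param samples_per_day analysed ARU windows per day (hour 0..4).
#' @param season_start first survey date (ISO string).
#' @param season_days length of the field season in days.
#' @param drop_alpine_mountain index of a mountain whose alpine was
#'   inaccessible (all five alpine sites and both alpine ARUs missing);
#'   `NA` for none.
#' @param drop_subalpine_site mountain index losing one subalpine site
#'   (`NA` for none).
#' @return list of class `design_config`.
#' @export
design_config <- function(region = c("BC", "Chile"),
                          n_mountains = if (region == "BC") 9 else 10,
                          aru_mountains = if (region == "BC") 1:9 else 1:5,
                          aru_days = NULL,
                          sites_per_habitat = 5,
                          aru_sites_per_habitat = 2,
                          pc_rounds = 3,
                          samples_per_day = 5,
                          season_start = if (region == "BC") "2019-05-30"
                                         else "2018-11-07",
                          season_days = 45,
                          drop_alpine_mountain = if (region == "BC") 4 else NA,
                          drop_subalpine_site = if (region == "BC") 5 else NA) {
  region <- match.arg(region)
  if (is.null(aru_days)) {
    aru_days <- if (region == "BC") c(4, 4, 4, rep(2, n_mountains - 3))
                else rep(3, n_mountains)
  }
  stopifnot(length(aru_days) == n_mountains)
  structure(list(region = region, n_mountains = n_mountains,
                 aru_mountains = aru_mountains, aru_days = aru_days,
                 sites_per_habitat = sites_per_habitat,
                 aru_sites_per_habitat = aru_sites_per_habitat,
                 pc_rounds = pc_rounds, samples_per_day = samples_per_day,
                 season_start = as.Date(season_start),
                 season_days = season_days,
                 drop_alpine_mountain = drop_alpine_mountain,
                 drop_subalpine_site = drop_subalpine_site),
            class = "design_config")
}

#' Species profiles for the generator
#'
#' One row per species. Occupancy probabilities are per habitat;
#' detection intercepts are on the logit scale per method (`-Inf` encodes
#' a zero-vocalisation species that an ARU can never detect); slope
#' coefficients apply to covariates standardised within the generated
#' design.
#'
#' @param species,family character vectors.
#' @param psi_montane,psi_subalpine,psi_alpine occupancy probabilities.
#' @param b0_pc,b0_aru logit detection intercepts by method.
#' @param b_wind,b_hour,b_hour2,b_date,b_date2,b_canopy,b_canopy2,b_lag
#'   detection slopes (defaults 0; `b_lag` is the Markov term).
#' @return data.frame of class `species_community`.
#' @export
species_profiles <- function(species, family,
                             psi_montane = 0.5, psi_subalpine = 0.5,
                             psi_alpine = 0.5, b0_pc = -1, b0_aru = -1,
                             b_wind = 0, b_hour = 0, b_hour2 = 0,
                             b_date = 0, b_date2 = 0, b_canopy = 0,
                             b_canopy2 = 0, b_lag = 0) {
  out <- data.frame(species = species, family = family,
                    psi_montane = psi_montane,
                    psi_subalpine = psi_subalpine,
                    psi_alpine = psi_alpine,
                    b0_pc = b0_pc, b0_aru = b0_aru, b_wind = b_wind,
                    b_hour = b_hour, b_hour2 = b_hour2, b_date = b_date,
                    b_date2 = b_date2, b_canopy = b_canopy,
                    b_canopy2 = b_canopy2, b_lag = b_lag,
                    stringsAsFactors = FALSE)
  bad <- with(out, psi_montane < 0 | psi_montane > 1 |
                psi_subalpine < 0 | psi_subalpine > 1 |
                psi_alpine < 0 | psi_alpine > 1)
  if (any(bad)) stop("occupancy probabilities outside [0, 1]", call. = FALSE)
  class(out) <- c("species_community", "data.frame")
  out
}

hab_abbrev <- c(montane = "mon", subalpine = "sub", alpine = "alp")

build_sites <- function(design) {
  elev_rng <- list(montane = c(1000, 1450), subalpine = c(1200, 1650),
                   alpine = c(1350, 1800))
  canopy_rng <- list(montane = c(55, 95), subalpine = c(6, 45),
                     alpine = c(0, 4))
  rows <- list()
  for (m in seq_len(design$n_mountains)) {
    for (h in HABITATS) {
      ns <- design$sites_per_habitat
      drop <- integer(0)
      if (h == "alpine" && isTRUE(m == design$drop_alpine_mountain))
        next
      if (h == "subalpine" && isTRUE(m == design$drop_subalpine_site))
        drop <- ns  # the last subalpine site did not fit the terrain
      for (k in setdiff(seq_len(ns), drop)) {
        rows[[length(rows) + 1]] <- data.frame(
          site_id = sprintf("%s-M%02d-%s-S%d", design$region, m,
                            hab_abbrev[[h]], k),
          region = design$region, mountain = sprintf("M%02d", m),
          habitat = h,
          elevation = stats::runif(1, elev_rng[[h]][1], elev_rng[[h]][2]),
          canopy_cover = stats::runif(1, canopy_rng[[h]][1],
                                      canopy_rng[[h]][2]),
          understory_cover = stats::runif(1, 5, 60),
          shrub_cover = stats::runif(1, 5, 60),
          ground_cover = stats::runif(1, 20, 95),
          has_aru = m %in% design$aru_mountains &&
            k <= design$aru_sites_per_habitat,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

build_surveys <- function(design, sites) {
  rows <- list()
  hour_band <- list(montane = c(0, 2.5), subalpine = c(1.5, 4),
                    alpine = c(2.5, 5.5))
  wind_p <- c(0.45, 0.3, 0.17, 0.08)
  leafout <- function(site_hab, frac) {
    if (design$region == "Chile" && site_hab != "alpine")
      0.55 + 0.45 * frac else 1
  }
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    m <- as.integer(sub("M", "", st$mountain))
    # three point-count rounds ~2 weeks apart, upslope within a morning
    jit <- sample.int(6, 1) - 1
    for (r in seq_len(design$pc_rounds)) {
      date <- design$season_start + (r - 1) * 14 + jit +
        sample.int(3, 1) - 1
      frac <- min(as.numeric(date - design$season_start) /
                    design$season_days, 1)
      rows[[length(rows) + 1]] <- data.frame(
        survey_id = sprintf("%s-PC%d", st$site_id, r),
        site_id = st$site_id, method = "PC", date = date,
        hours_after_sunrise = stats::runif(1, hour_band[[st$habitat]][1],
                                           hour_band[[st$habitat]][2]),
        wind_score = sample(0:3, 1, prob = wind_p),
        day_index = r, hour_index = NA_integer_, round_index = r,
        canopy_at_survey = st$canopy_cover * leafout(st$habitat, frac),
        stringsAsFactors = FALSE)
    }
    if (st$has_aru) {
      nd <- design$aru_days[m]
      days <- sort(sample.int(design$season_days, nd))
      for (d in seq_len(nd)) {
        date <- design$season_start + days[d] - 1
        frac <- min(as.numeric(date - design$season_start) /
                      design$season_days, 1)
        for (hr in seq_len(design$samples_per_day) - 1) {
          rows[[length(rows) + 1]] <- data.frame(
            survey_id = sprintf("%s-ARU-D%d-H%d", st$site_id, d, hr),
            site_id = st$site_id, method = "ARU", date = date,
            hours_after_sunrise = hr + stats::runif(1, 0, 0.9),
            wind_score = sample(0:3, 1, prob = wind_p),
            day_index = d, hour_index = hr, round_index = NA_integer_,
            canopy_at_survey = st$canopy_cover * leafout(st$habitat, frac),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic survey dataset
#'
#' Draws latent occupancy per species and site from the habitat-specific
#' occupancy probabilities, then detections per site-survey from the
#' logit detection model. Consecutive same-day ARU windows are generated
#' sequentially so the Markov lag term acts on the realised detection of
#' the previous window. Covariates are standardised within the generated
#' design before species coefficients are applied.
#'
#' @param design a [design_config()].
#' @param community a [species_profiles()] data.frame.
#' @param seed integer seed; everything (sites, covariates, occupancy,
#'   detections) is reproducible.
#' @param known optional known-community data.frame (`habitat`,
#'   `species`); defaults to all species with occupancy > 0 per habitat.
#' @return a validated [survey_dataset()].
#' @export
generate_dataset <- function(design, community, seed = 1, known = NULL) {
  stopifnot(inherits(design, "design_config"))
  if (!nrow(community)) stop("empty community", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sites <- build_sites(design)
  surveys <- build_surveys(design, sites)

  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  wz <- z(surveys$wind_score)
  hz <- z(surveys$hours_after_sunrise)
  dz <- z(as.numeric(surveys$date - design$season_start))
  cz <- z(surveys$canopy_at_survey)
  is_aru <- surveys$method == "ARU"
  # generation order: PC rows arbitrary; ARU rows already site/day/hour
  aru_ord <- which(is_aru)
  site_hab <- sites$habitat[match(surveys$site_id, sites$site_id)]

  det <- vector("list", nrow(community))
  for (sp in seq_len(nrow(community))) {
    pr <- community[sp, ]
    psi <- c(montane = pr$psi_montane, subalpine = pr$psi_subalpine,
             alpine = pr$psi_alpine)[sites$habitat]
    zocc <- stats::rbinom(nrow(sites), 1, psi)
    occ_sites <- sites$site_id[zocc == 1]
    if (!length(occ_sites)) next
    at_occ <- surveys$site_id %in% occ_sites
    eta0 <- ifelse(is_aru, pr$b0_aru, pr$b0_pc) +
      pr$b_wind * wz + pr$b_hour * hz + pr$b_hour2 * hz^2 +
      pr$b_date * dz + pr$b_date2 * dz^2 +
      pr$b_canopy * cz + pr$b_canopy2 * cz^2
    y <- integer(nrow(surveys))
    pc_rows <- which(!is_aru & at_occ)
    y[pc_rows] <- stats::rbinom(length(pc_rows), 1,
                                stats::plogis(eta0[pc_rows]))
    prev_key <- ""
    prev_y <- 0L
    for (r in aru_ord) {
      if (!at_occ[r]) next
      key <- paste(surveys$site_id[r], surveys$day_index[r])
      lagval <- if (key == prev_key) prev_y else 0L
      p <- stats::plogis(eta0[r] + pr$b_lag * lagval)
      if (is.infinite(pr$b0_aru) && pr$b0_aru < 0) p <- 0
      yy <- stats::rbinom(1, 1, p)
      y[r] <- yy
      prev_key <- key
      prev_y <- yy
    }
    hits <- which(y == 1)
    if (length(hits))
      det[[sp]] <- data.frame(survey_id = surveys$survey_id[hits],
                              species = pr$species,
                              stringsAsFactors = FALSE)
  }
  detections <- do.call(rbind, det)
  if (is.null(detections))
    detections <- data.frame(survey_id = character(), species = character())

  if (is.null(known)) {
    known <- do.call(rbind, lapply(HABITATS, function(h) {
      col <- paste0("psi_", h)
      spp <- community$species[community[[col]] > 0]
      if (!length(spp)) return(NULL)
      data.frame(habitat = h, species = spp, stringsAsFactors = FALSE)
    }))
    if (is.null(known))
      known <- data.frame(habitat = character(), species = character())
  }
  survey_dataset(sites, surveys, detections,
                 community[c("species", "family")], known)
}
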