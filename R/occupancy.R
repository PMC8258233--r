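# Family-level single-season occupancy-detection models. Occupancy (psi)
# is modelled on site elevation and canopy-on-elevation residuals;
# detection (p) on survey conditions (wind, time of morning, date, canopy,
# all with quadratics where peaks are plausible), survey method (PC vs
# ARU) and a first-order Markov autocorrelation covariate: the observed
# detection at the immediately preceding same-day ARU window.

#' Build a family detection history
#'
#' One row per site in the retained habitats (all point-count sites, not
#' just paired ones). Occasions are ordered point-count rounds first, then
#' ARU windows by day and hour. Continuous covariates are centred and
#' scaled (mean 0, sd 1) before quadratics are formed; the scaling is
#' stored so predictions can be made on the natural scale. The Markov lag
#' covariate is the observed detection at the immediately preceding ARU
#' window within the same site-day, and 0 for first-of-day and all PC
#' occasions.
#'
#' @param x a [survey_dataset()].
#' @param family family name (must appear in the family lookup).
#' @param habitats habitats to include (e.g. from [filter_families()]);
#'   default all three.
#' @param region optional region filter.
#' @return object of class `detection_history`.
#' @export
build_history <- function(x, family, habitats = HABITATS, region = NULL) {
  stopifnot(inherits(x, "survey_dataset"))
  if (!family %in% x$families$family)
    stop("family not present in dataset: ", family, call. = FALSE)
  s <- x$sites
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  cres_all <- canopy_residuals(s)
  s <- s[s$habitat %in% habitats, , drop = FALSE]
  s <- s[order(s$site_id), , drop = FALSE]
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  fam_spp <- x$families$species[x$families$family == family]
  det <- x$detections[x$detections$species %in% fam_spp, , drop = FALSE]
  det_ids <- unique(det$survey_id)

  # occasion ordering: PC rounds 1..3, then ARU by (day, hour)
  sv$is_aru <- sv$method == "ARU"
  ord <- order(sv$site_id, sv$is_aru,
               ifelse(sv$is_aru, sv$day_index, sv$round_index),
               ifelse(sv$is_aru, sv$hour_index, 0L))
  sv <- sv[ord, , drop = FALSE]
  sv$y <- as.integer(sv$survey_id %in% det_ids)
  date0 <- min(sv$date)
  sv$date_num <- as.numeric(sv$date - date0)

  site_ids <- s$site_id
  idx <- split(seq_len(nrow(sv)), factor(sv$site_id, levels = site_ids))
  surveyed <- lengths(idx) > 0
  site_ids <- site_ids[surveyed]
  s <- s[surveyed, , drop = FALSE]
  idx <- idx[surveyed]
  if (!length(idx)) stop("no surveyed sites for the selected habitats",
                         call. = FALSE)
  J <- max(vapply(idx, length, 1L))
  if (J < 1) stop("no surveys for the selected sites", call. = FALSE)
  mk <- function() matrix(NA_real_, length(site_ids), J,
                          dimnames = list(site_ids, NULL))
  y <- mk(); method <- mk(); wind <- mk(); hour <- mk(); date <- mk()
  canopy <- mk(); lag <- mk()
  lag_src <- matrix(NA_integer_, length(site_ids), J,
                    dimnames = list(site_ids, NULL))
  for (i in seq_along(site_ids)) {
    rows <- idx[[i]]
    jj <- seq_along(rows)
    y[i, jj] <- sv$y[rows]
    method[i, jj] <- as.numeric(sv$is_aru[rows])
    wind[i, jj] <- sv$wind_score[rows]
    hour[i, jj] <- sv$hours_after_sunrise[rows]
    date[i, jj] <- sv$date_num[rows]
    canopy[i, jj] <- sv$canopy_at_survey[rows]
    lg <- numeric(length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      if (sv$is_aru[r] && k > 1) {
        pr <- rows[k - 1]
        same_day <- sv$is_aru[pr] && sv$day_index[pr] == sv$day_index[r]
        if (same_day) {
          lg[k] <- sv$y[pr]
          lag_src[i, k] <- k - 1L
        }
      }
    }
    lag[i, jj] <- lg
  }

  zstat <- function(m) {
    v <- m[!is.na(m)]
    c(mean = mean(v), sd = if (stats::sd(v) > 0) stats::sd(v) else 1)
  }
  scaling <- list(wind = zstat(wind), hour = zstat(hour),
                  date = zstat(date), canopy = zstat(canopy),
                  elevation = c(mean = mean(s$elevation),
                                sd = max(stats::sd(s$elevation), 1e-12)),
                  cres = c(mean = 0,
                           sd = max(stats::sd(cres_all[s$site_id]), 1e-12)),
                  date0 = date0)
  z <- function(m, sc) (m - sc["mean"]) / sc["sd"]

  structure(list(
    family = family, habitats = habitats, site_id = site_ids,
    y = y,
    occ = list(method = method,
               wind = z(wind, scaling$wind),
               hour = z(hour, scaling$hour),
               date = z(date, scaling$date),
               canopy = z(canopy, scaling$canopy),
               lag = lag),
    lag_src = lag_src,
    site_cov = data.frame(
      site_id = site_ids,
      elevation = as.numeric(z(s$elevation, scaling$elevation)),
      cres = as.numeric(z(cres_all[s$site_id], scaling$cres)),
      row.names = NULL),
    scaling = scaling),
    class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  nocc <- rowSums(!is.na(x$y))
  cat(sprintf("<detection_history> %s: %d sites, %d-%d occasions, naive occupancy %.2f\n",
              x$family, nrow(x$y), min(nocc), max(nocc),
              mean(rowSums(x$y, na.rm = TRUE) > 0)))
  invisible(x)
}

#' Construct a custom occupancy model specification
#'
#' Mostly useful for simulation studies (e.g. an intercept-only model);
#' the nine-model candidate set of the analysis comes from [model_set()].
#'
#' @param det_terms detection terms, a subset of `wind`, `hour`, `hour2`,
#'   `date`, `date2`, `canopy`, `canopy2`, `lag`, `method`, `m_canopy`,
#'   `m_canopy2`, `m_hour`, `m_hour2`, `m_date`, `m_date2`. The intercept
#'   is always included.
#' @param psi_terms occupancy terms, a subset of `elevation`, `cres`.
#' @param name model label.
#' @return an `occu_model_spec`.
#' @export
occu_model_spec <- function(det_terms = character(0),
                            psi_terms = character(0), name = "custom") {
  has_int <- grepl("^m_", det_terms)
  if (any(has_int) && !"method" %in% det_terms)
    stop("method interactions require the method main effect", call. = FALSE)
  structure(list(name = name, det_terms = det_terms,
                 psi_terms = psi_terms),
            class = "occu_model_spec")
}

#' The nine candidate detection models
#'
#' The baseline model (survey conditions plus the Markov lag term), the
#' baseline plus a method effect, and the seven models adding method
#' interactions with every combination of canopy, hour-of-morning and
#' date (each interaction carries both the linear and the quadratic term
#' of its covariate). Occupancy is always
#' `~ elevation + canopy residual`.
#'
#' @return named list of `occu_model_spec` objects, length 9.
#' @export
model_set <- function() {
  base <- c("wind", "hour", "hour2", "date", "date2",
            "canopy", "canopy2", "lag")
  ints <- list(canopy = c("m_canopy", "m_canopy2"),
               hour = c("m_hour", "m_hour2"),
               date = c("m_date", "m_date2"))
  spec <- function(name, extra) {
    structure(list(name = name, det_terms = c(base, extra),
                   psi_terms = c("elevation", "cres")),
              class = "occu_model_spec")
  }
  combos <- list(character(0), "canopy", "hour", "date",
                 c("canopy", "hour"), c("canopy", "date"),
                 c("hour", "date"), c("canopy", "hour", "date"))
  combo_name <- function(cb) {
    if (!length(cb)) "method"
    else if (length(cb) == 3) "global"
    else paste0("method_x_", paste(cb, collapse = "_"))
  }
  out <- c(list(baseline = spec("baseline", character(0))),
           stats::setNames(lapply(combos, function(cb)
             spec(combo_name(cb), c("method", unlist(ints[cb])))),
             vapply(combos, combo_name, character(1))))
  stopifnot(length(out) == 9)
  out
}

# detection design matrix over the flattened valid occasions
det_design <- function(occ, valid, terms) {
  v <- lapply(occ, function(m) m[valid])
  col <- function(term) {
    switch(term,
           wind = v$wind, hour = v$hour, hour2 = v$hour^2,
           date = v$date, date2 = v$date^2,
           canopy = v$canopy, canopy2 = v$canopy^2,
           lag = v$lag, method = v$method,
           m_canopy = v$method * v$canopy,
           m_canopy2 = v$method * v$canopy^2,
           m_hour = v$method * v$hour,
           m_hour2 = v$method * v$hour^2,
           m_date = v$method * v$date,
           m_date2 = v$method * v$date^2,
           stop("unknown detection term: ", term))
  }
  X <- cbind(`(Intercept)` = rep(1, sum(valid)))
  for (tm in terms) X <- cbind(X, stats::setNames(list(col(tm)), tm)[[1]])
  colnames(X) <- c("(Intercept)", terms)
  X
}

psi_design <- function(history, terms = c("elevation", "cres")) {
  X <- cbind(`(Intercept)` = rep(1, nrow(history$y)))
  for (tm in terms) X <- cbind(X, history$site_cov[[tm]])
  colnames(X) <- c("(Intercept)", terms)
  X
}

# internal: everything the likelihood needs, computed once per model
occu_frame <- function(history, model) {
  valid <- !is.na(history$y)
  list(valid = valid,
       y = history$y[valid],
       site = row(history$y)[valid],
       Xp = det_design(history$occ, valid, model$det_terms),
       Xpsi = psi_design(history, model$psi_terms),
       n_site = nrow(history$y))
}

occu_nll_factory <- function(frame) {
  kpsi <- ncol(frame$Xpsi)
  kp <- ncol(frame$Xp)
  no_det <- as.numeric(rowsum(frame$y, frame$site,
                              reorder = TRUE)[, 1] == 0)
  nll <- function(par) {
    psi <- stats::plogis(drop(frame$Xpsi %*% par[seq_len(kpsi)]))
    eta <- drop(frame$Xp %*% par[kpsi + seq_len(kp)])
    cond <- stats::dbinom(frame$y, 1, stats::plogis(eta), log = TRUE)
    cond_site <- as.numeric(rowsum(cond, frame$site, reorder = TRUE)[, 1])
    # log(psi * exp(cond) + (1 - psi) * I{all zero}), stably
    a <- log(psi) + cond_site
    ll <- ifelse(no_det == 1,
                 pmax(a, log1p(-psi)) +
                   log1p(exp(pmin(a, log1p(-psi)) -
                               pmax(a, log1p(-psi)))),
                 a)
    -sum(ll)
  }
  # analytic gradient: with site weight w = P(occupied | data)
  # (1 for sites with a detection), d l / d logit(psi) = w - psi and
  # d l / d beta = X' [ w (y - p) ]
  gr <- function(par) {
    psi <- stats::plogis(drop(frame$Xpsi %*% par[seq_len(kpsi)]))
    eta <- drop(frame$Xp %*% par[kpsi + seq_len(kp)])
    p <- stats::plogis(eta)
    cond <- stats::dbinom(frame$y, 1, p, log = TRUE)
    cond_site <- as.numeric(rowsum(cond, frame$site, reorder = TRUE)[, 1])
    C <- exp(cond_site)
    w <- ifelse(no_det == 1, psi * C / (psi * C + (1 - psi)), 1)
    g_psi <- drop(crossprod(frame$Xpsi, w - psi))
    g_p <- drop(crossprod(frame$Xp, w[frame$site] * (frame$y - p)))
    -c(g_psi, g_p)
  }
  list(nll = nll, gr = gr)
}

#' Occupancy-detection log-likelihood
#'
#' The zero-inflated Bernoulli likelihood of the single-season occupancy
#' model: for each site, `psi * prod_j p_j^y (1-p_j)^(1-y) + (1-psi) *
#' I(all y = 0)`, with missing occasions skipped. Detection covariates
#' (including the Markov lag term) enter `p` through a logit link;
#' occupancy covariates enter `psi` likewise.
#'
#' @param params coefficient vector: occupancy block (intercept,
#'   elevation, canopy residual) followed by the detection block
#'   (intercept plus `model$det_terms` in order).
#' @param history a [build_history()] object.
#' @param model an `occu_model_spec` from [model_set()].
#' @return log-likelihood (scalar).
#' @export
occ_loglik <- function(params, history, model = model_set()$baseline) {
  stopifnot(inherits(history, "detection_history"))
  frame <- occu_frame(history, model)
  need <- ncol(frame$Xpsi) + ncol(frame$Xp)
  if (length(params) != need)
    stop(sprintf("params must have length %d (%d psi + %d detection)",
                 need, ncol(frame$Xpsi), ncol(frame$Xp)), call. = FALSE)
  if (any(!is.finite(frame$Xp)) || any(!is.finite(frame$Xpsi)))
    stop("non-finite covariates in history", call. = FALSE)
  -occu_nll_factory(frame)$nll(params)
}

#' Fit an occupancy-detection model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimisation from multiple starting points; the
#' first start uses naive occupancy/detection rates for the intercepts and
#' zeros elsewhere, the rest are random perturbations. The covariance
#' matrix is the inverse of the observed information at the optimum.
#'
#' @param model an `occu_model_spec` from [model_set()].
#' @param history a [build_history()] object.
#' @param n_starts number of optimisation starts (default 5).
#' @param seed seed for the random starts.
#' @return object of class `occupancy_fit`: `coef`, `vcov`, `logLik`,
#'   `K`, `model`, `convergence`, `history` (the data it was fit to).
#' @export
occ_fit <- function(model, history, n_starts = 5, seed = 1) {
  stopifnot(inherits(history, "detection_history"),
            inherits(model, "occu_model_spec"))
  det_sites <- sum(rowSums(history$y, na.rm = TRUE) > 0)
  if (nrow(history$y) < 2 || det_sites < 2)
    stop("data-insufficient: need >= 2 sites with >= 1 detection",
         call. = FALSE)
  frame <- occu_frame(history, model)
  fns <- occu_nll_factory(frame)
  nll <- fns$nll
  kpsi <- ncol(frame$Xpsi); kp <- ncol(frame$Xp)
  naive_psi <- min(max(det_sites / frame$n_site, 0.05), 0.95)
  naive_p <- min(max(mean(frame$y), 0.05), 0.95)
  start0 <- c(stats::qlogis(naive_psi), rep(0, kpsi - 1),
              stats::qlogis(naive_p), rep(0, kp - 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start0 else start0 + stats::rnorm(kpsi + kp, 0, 0.5)
    opt <- tryCatch(
      stats::optim(st, nll, gr = fns$gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimisation failed from all starts", call. = FALSE)
  if (best$convergence != 0)
    warning("optimiser reported non-convergence (code ",
            best$convergence, "); returning best-found parameters")
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  singular <- is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)
  nm <- c(paste0("psi_", colnames(frame$Xpsi)),
          paste0("p_", colnames(frame$Xp)))
  coefs <- stats::setNames(best$par, nm)
  if (!singular) dimnames(V) <- list(nm, nm)
  structure(list(
    coef = coefs, vcov = if (singular) NULL else V,
    logLik = -best$value, K = length(coefs), model = model,
    convergence = best$convergence, singular_vcov = singular,
    n_sites = frame$n_site, n_obs = length(frame$y),
    history = history),
    class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> model %s: logLik %.2f, K = %d, %d sites\n",
              x$model$name, x$logLik, x$K, x$n_sites))
  print(round(x$coef, 3))
  invisible(x)
}

#' Quasi-AIC
#'
#' `QAIC = -2 logL / max(chat, 1) + 2 (K + 1)`; the `+1` accounts for
#' estimating the overdispersion parameter, and `chat < 1` is floored at 1
#' by standard convention.
#'
#' @param fit an [occ_fit()] result (or a list with `logLik` and `K`).
#' @param chat overdispersion factor (`> 0`).
#' @return QAIC value.
#' @export
qaic <- function(fit, chat = 1) {
  if (chat <= 0) stop("chat must be > 0", call. = FALSE)
  -2 * fit$logLik / max(chat, 1) + 2 * (fit$K + 1)
}
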