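# Overdispersion (c-hat) via a MacKenzie-Bailey-style parametric
# bootstrap, QAIC model selection over the nine-model set, and
# detection-probability prediction curves.

# linear predictors for psi and for p-with-lag-zeroed, plus the lag
# coefficient, for one fitted (or hypothetical) parameter vector
occu_linpred <- function(params, history, model) {
  valid <- !is.na(history$y)
  occ0 <- history$occ
  occ0$lag <- occ0$lag * 0
  Xp0 <- det_design(occ0, valid, model$det_terms)
  Xpsi <- psi_design(history, model$psi_terms)
  kpsi <- ncol(Xpsi)
  b_p <- params[kpsi + seq_len(ncol(Xp0))]
  eta0 <- matrix(NA_real_, nrow(history$y), ncol(history$y))
  eta0[valid] <- drop(Xp0 %*% b_p)
  lag_pos <- match("lag", model$det_terms)
  list(psi = stats::plogis(drop(Xpsi %*% params[seq_len(kpsi)])),
       eta0 = eta0,
       b_lag = if (is.na(lag_pos)) 0 else b_p[lag_pos + 1L],
       valid = valid)
}

#' Simulate detection histories from a fitted occupancy model
#'
#' Parametric simulation honouring the Markov structure: latent occupancy
#' is drawn per site, then detections are generated occasion by occasion
#' with the lag covariate taken from the *simulated* previous same-day ARU
#' window.
#'
#' @param fit an [occ_fit()] result.
#' @param seed integer seed.
#' @return a detection matrix shaped like `fit$history$y`.
#' @export
simulate_history <- function(fit, seed = 1) {
  simulate_occu(fit$history, fit$model, fit$coef, seed = seed)
}

#' Simulate detections under an arbitrary occupancy model
#'
#' Like [simulate_history()] but takes the model specification and the
#' parameter vector directly, so data can be generated from a chosen
#' model (e.g. with a true method-by-date interaction) using an existing
#' history as the design template.
#'
#' @param history a [build_history()] object supplying the design.
#' @param model an `occu_model_spec`.
#' @param params coefficient vector (psi block then detection block).
#' @param seed integer seed.
#' @return a detection matrix shaped like `history$y`.
#' @export
simulate_occu <- function(history, model, params, seed = 1) {
  lp <- occu_linpred(params, history, model)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(history$y); J <- ncol(history$y)
  z <- stats::rbinom(n, 1, lp$psi)
  y <- matrix(NA_real_, n, J, dimnames = dimnames(history$y))
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      if (!lp$valid[i, j]) next
      if (z[i] == 0) { y[i, j] <- 0; next }
      src <- history$lag_src[i, j]
      lagval <- if (is.na(src)) 0 else y[i, src]
      p <- stats::plogis(lp$eta0[i, j] + lp$b_lag * lagval)
      y[i, j] <- stats::rbinom(1, 1, p)
    }
  }
  y
}

#' Replace the detections of a history (updating the lag covariate)
#'
#' @param history a [build_history()] object.
#' @param y replacement detection matrix (same shape as `history$y`).
#' @return the history with `y` and the Markov lag covariate updated.
#' @export
set_history_y <- function(history, y) {
  stopifnot(identical(dim(y), dim(history$y)))
  history$y <- y
  lag <- history$occ$lag * 0
  src_ok <- !is.na(history$lag_src)
  lag[src_ok] <- y[cbind(row(history$lag_src)[src_ok],
                         history$lag_src[src_ok])]
  history$occ$lag <- lag
  history
}

# probability of an arbitrary detection history h (vector over the site's
# valid occasions) at site i, with the lag covariate implied by h itself
site_history_prob <- function(h, i, cols, lp, lag_src) {
  eta <- lp$eta0[i, cols]
  lagval <- numeric(length(cols))
  for (k in seq_along(cols)) {
    src <- lag_src[i, cols[k]]
    if (!is.na(src)) {
      pos <- match(src, cols)
      if (!is.na(pos)) lagval[k] <- h[pos]
    }
  }
  p <- stats::plogis(eta + lp$b_lag * lagval)
  cond <- prod(ifelse(h == 1, p, 1 - p))
  lp$psi[i] * cond + (1 - lp$psi[i]) * as.numeric(all(h == 0))
}

# MacKenzie-Bailey-style chi-square over detection-history frequencies,
# cohorted by missingness pattern; unobserved histories contribute their
# pooled expected count
mb_chisq <- function(params, history, model) {
  lp <- occu_linpred(params, history, model)
  pat <- apply(lp$valid, 1, function(v) paste(which(v), collapse = ","))
  chi2 <- 0
  for (pp in unique(pat)) {
    sites <- which(pat == pp)
    cols <- as.integer(strsplit(pp, ",")[[1]])
    hs <- apply(history$y[sites, cols, drop = FALSE], 1, paste,
                collapse = "")
    uh <- unique(hs)
    E_tot <- 0
    for (h in uh) {
      hv <- as.numeric(strsplit(h, "")[[1]])
      E <- sum(vapply(sites, function(i)
        site_history_prob(hv, i, cols, lp, history$lag_src), numeric(1)))
      O <- sum(hs == h)
      if (E > 0) chi2 <- chi2 + (O - E)^2 / E
      E_tot <- E_tot + E
    }
    chi2 <- chi2 + max(length(sites) - E_tot, 0)
  }
  chi2
}

#' Overdispersion factor via parametric bootstrap
#'
#' The observed detection-history chi-square statistic is divided by its
#' mean over datasets simulated from the fitted model (each refit before
#' the statistic is computed): `chat = chi2_obs / mean(chi2_sim)`. Values
#' near 1 indicate adequate fit; `chat > 4` suggests lack of fit and
#' `chat < 0.3` insufficient data.
#'
#' @param fit an [occ_fit()] result (normally the most complex model).
#' @param n_boot bootstrap replicates (default 1000; reduce for quick
#'   checks).
#' @param seed integer seed.
#' @param n_starts optimisation starts per refit (default 1, from the
#'   fitted parameters).
#' @return `chat` (scalar, `> 0`) with attributes `chi2_obs` and
#'   `chi2_boot`.
#' @export
estimate_chat <- function(fit, n_boot = 1000, seed = 1, n_starts = 1) {
  stopifnot(inherits(fit, "occupancy_fit"))
  history <- fit$history
  if (sum(history$y, na.rm = TRUE) == 0)
    stop("all detection histories are zero", call. = FALSE)
  obs <- mb_chisq(fit$coef, history, fit$model)
  sim_stats <- vapply(seq_len(n_boot), function(b) {
    ysim <- simulate_history(fit, seed = seed * 10000L + b)
    hsim <- set_history_y(history, ysim)
    fb <- tryCatch(
      occ_fit(fit$model, hsim, n_starts = n_starts, seed = b),
      error = function(e) NULL)
    if (is.null(fb)) return(NA_real_)
    mb_chisq(fb$coef, hsim, fit$model)
  }, numeric(1))
  sim_stats <- sim_stats[is.finite(sim_stats)]
  if (!length(sim_stats)) stop("all bootstrap refits failed", call. = FALSE)
  chat <- obs / mean(sim_stats)
  attr(chat, "chi2_obs") <- obs
  attr(chat, "chi2_boot") <- sim_stats
  chat
}

#' Fit and rank the nine-model detection set by QAIC
#'
#' Fits every candidate model, computes QAIC with a shared overdispersion
#' factor, and ranks them (ties broken by smaller `K`). Families whose
#' global-model `chat` exceeds 4 are flagged `lack_of_fit`; below 0.3,
#' `insufficient_data`; model output should not be interpreted for
#' flagged families.
#'
#' @param history a [build_history()] object.
#' @param chat overdispersion factor; if `NULL` it is estimated from the
#'   most complex (global) model via [estimate_chat()].
#' @param models candidate list (default [model_set()]).
#' @param n_starts optimisation starts per model.
#' @param chat_boot bootstrap replicates for `chat` when estimated here.
#' @param seed integer seed.
#' @return list with `table` (model, K, logLik, QAIC, dQAIC, converged),
#'   `best` (name), `fits`, `chat`, `flag` (`"ok"`, `"lack_of_fit"` or
#'   `"insufficient_data"`).
#' @export
select_model <- function(history, chat = NULL, models = model_set(),
                         n_starts = 3, chat_boot = 100, seed = 1) {
  stopifnot(inherits(history, "detection_history"))
  fits <- lapply(models, function(m)
    tryCatch(occ_fit(m, history, n_starts = n_starts, seed = seed),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("no model converged", call. = FALSE)
  if (is.null(chat)) {
    gl <- fits[["global"]]
    if (inherits(gl, "error"))
      stop("global model failed; supply chat explicitly", call. = FALSE)
    chat <- estimate_chat(gl, n_boot = chat_boot, seed = seed)
  }
  flag <- if (chat > 4) "lack_of_fit" else
    if (chat < 0.3) "insufficient_data" else "ok"
  tab <- do.call(rbind, lapply(names(fits)[ok], function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, K = f$K, logLik = f$logLik,
               QAIC = qaic(f, chat), converged = f$convergence == 0,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$QAIC, tab$K), , drop = FALSE]
  tab$dQAIC <- tab$QAIC - tab$QAIC[1]
  rownames(tab) <- NULL
  list(table = tab, best = tab$model[1], fits = fits[ok],
       chat = as.numeric(chat), flag = flag)
}

#' Predicted detection-probability curves with inflated intervals
#'
#' Detection probability across a grid of one survey covariate (others
#' held at their mean, lag at 0), for a given method, with delta-method
#' standard errors on the logit scale. When `chat > 1`, standard errors
#' are multiplied by `sqrt(chat)` before the 84% and 95% bands are formed,
#' so overdispersion widens the intervals.
#'
#' @param fit an [occ_fit()] result with a non-singular covariance.
#' @param var covariate to sweep: `"hour"`, `"date"`, `"canopy"` or
#'   `"wind"` (natural scale).
#' @param values grid values on the natural scale; defaults to 25 points
#'   across the observed range. A warning is issued outside that range.
#' @param method `"ARU"` or `"PC"`.
#' @param chat overdispersion factor (default 1).
#' @param lag value for the Markov lag covariate (default 0).
#' @return data.frame: `var`, `value`, `method`, `p`, `se_logit`, `lo84`,
#'   `hi84`, `lo95`, `hi95`; probabilities always within \[0, 1\].
#' @export
predict_detection <- function(fit, var = c("hour", "date", "canopy", "wind"),
                              values = NULL, method = c("ARU", "PC"),
                              chat = 1, lag = 0) {
  stopifnot(inherits(fit, "occupancy_fit"))
  var <- match.arg(var)
  method <- match.arg(method)
  if (is.null(fit$vcov))
    stop("singular covariance: cannot form prediction intervals",
         call. = FALSE)
  history <- fit$history
  sc <- history$scaling[[var]]
  obs_nat <- history$occ[[var]][!is.na(history$occ[[var]])] * sc["sd"] + sc["mean"]
  if (is.null(values))
    values <- seq(min(obs_nat), max(obs_nat), length.out = 25)
  if (any(values < min(obs_nat) - 1e-9 | values > max(obs_nat) + 1e-9))
    warning("prediction grid extends beyond the observed covariate range")
  zval <- (values - sc["mean"]) / sc["sd"]
  terms <- fit$model$det_terms
  meth <- as.numeric(method == "ARU")
  X <- vapply(terms, function(tm) {
    base <- switch(tm,
                   wind = if (var == "wind") zval else 0,
                   hour = if (var == "hour") zval else 0,
                   hour2 = if (var == "hour") zval^2 else 0,
                   date = if (var == "date") zval else 0,
                   date2 = if (var == "date") zval^2 else 0,
                   canopy = if (var == "canopy") zval else 0,
                   canopy2 = if (var == "canopy") zval^2 else 0,
                   lag = lag, method = meth,
                   m_canopy = meth * (if (var == "canopy") zval else 0),
                   m_canopy2 = meth * (if (var == "canopy") zval^2 else 0),
                   m_hour = meth * (if (var == "hour") zval else 0),
                   m_hour2 = meth * (if (var == "hour") zval^2 else 0),
                   m_date = meth * (if (var == "date") zval else 0),
                   m_date2 = meth * (if (var == "date") zval^2 else 0))
    rep_len(base, length(values))
  }, numeric(length(values)))
  X <- cbind(1, matrix(X, nrow = length(values)))
  kpsi <- length(fit$model$psi_terms) + 1L
  bp <- fit$coef[kpsi + seq_len(ncol(X))]
  Vp <- fit$vcov[kpsi + seq_len(ncol(X)), kpsi + seq_len(ncol(X))]
  eta <- drop(X %*% bp)
  se <- sqrt(pmax(rowSums((X %*% Vp) * X), 0)) * sqrt(max(chat, 1))
  data.frame(var = var, value = values, method = method,
             p = stats::plogis(eta), se_logit = se,
             lo84 = stats::plogis(eta - Z84 * se),
             hi84 = stats::plogis(eta + Z84 * se),
             lo95 = stats::plogis(eta - Z95 * se),
             hi95 = stats::plogis(eta + Z95 * se))
}
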