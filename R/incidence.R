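#' Incidence frequencies for one assemblage
#'
#' The sufficient statistics for incidence-based diversity estimation: the
#' number of sampling units `T` and, for each detected species, the number
#' of units `Y_i` in which it was detected at least once.
#'
#' @param Y named integer vector of incidence frequencies (one entry per
#'   detected species, each in `1..T`). Species never detected are simply
#'   absent.
#' @param T number of sampling units (site-surveys).
#' @param label assemblage label for printing and bookkeeping.
#' @param unit_matrix optional logical matrix (sampling units x species);
#'   when supplied, `Y` and `T` are derived from it and the matrix is kept
#'   so that bootstrap resampling over sampling units is possible.
#' @return object of class `incidence_freq` with elements `label`, `T`,
#'   `Y`, and derived `U` (total incidences), `Q1` (uniques), `Q2`
#'   (duplicates) and `S_obs`.
#' @export
incidence_freq <- function(Y = NULL, T = NULL, label = "",
                           unit_matrix = NULL) {
  if (!is.null(unit_matrix)) {
    unit_matrix <- unit_matrix > 0
    T <- nrow(unit_matrix)
    Y <- colSums(unit_matrix)
  }
  Y <- Y[Y > 0]
  if (any(Y > T)) stop("incidence frequency exceeds number of units T",
                       call. = FALSE)
  if (is.null(T) || T < 1) stop("T must be >= 1", call. = FALSE)
  structure(
    list(label = label, T = as.integer(T), Y = Y,
         U = sum(Y), Q1 = sum(Y == 1), Q2 = sum(Y == 2),
         S_obs = length(Y), unit_matrix = unit_matrix),
    class = "incidence_freq")
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat(sprintf("<incidence_freq> %s: T = %d units, S_obs = %d, U = %d, Q1 = %d, Q2 = %d\n",
              x$label, x$T, x$S_obs, x$U, x$Q1, x$Q2))
  invisible(x)
}

#' Build incidence frequencies for a habitat-by-method assemblage
#'
#' Restricts to paired PC/ARU sites (sites with `has_aru`) by default, so
#' that PC and ARU assemblages are directly comparable, then counts for
#' each species the number of site-surveys with at least one detection.
#'
#' @param x a [survey_dataset()].
#' @param habitat one of `"montane"`, `"subalpine"`, `"alpine"`.
#' @param pooling sampling-unit definition: `"pc"` (point-count surveys),
#'   `"pooled_morning"` (all ARU windows, hours 0--4 pooled) or
#'   `"per_hour"` (ARU windows at a single `hour`).
#' @param hour hour index 0--4, required for `pooling = "per_hour"`.
#' @param region optional region filter.
#' @param paired_only restrict to sites surveyed by both methods (default
#'   `TRUE`, as required for method comparisons).
#' @return an [incidence_freq()].
#' @export
build_incidence <- function(x, habitat,
                            pooling = c("pooled_morning", "per_hour", "pc"),
                            hour = NULL, region = NULL, paired_only = TRUE) {
  stopifnot(inherits(x, "survey_dataset"))
  habitat <- match.arg(habitat, HABITATS)
  pooling <- match.arg(pooling)
  s <- x$sites
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  s <- s[s$habitat == habitat, , drop = FALSE]
  if (paired_only) s <- s[s$has_aru, , drop = FALSE]
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  if (pooling == "pc") {
    sv <- sv[sv$method == "PC", , drop = FALSE]
  } else {
    sv <- sv[sv$method == "ARU", , drop = FALSE]
    if (pooling == "per_hour") {
      if (is.null(hour) || !hour %in% 0:4)
        stop("per_hour pooling requires hour in 0..4", call. = FALSE)
      sv <- sv[sv$hour_index == hour, , drop = FALSE]
    }
  }
  if (nrow(sv) == 0) stop("no sampling units in assemblage", call. = FALSE)
  d <- x$detections[x$detections$survey_id %in% sv$survey_id, , drop = FALSE]
  d <- unique(d[c("survey_id", "species")])
  spp <- sort(unique(d$species))
  m <- matrix(FALSE, nrow = nrow(sv), ncol = length(spp),
              dimnames = list(sv$survey_id, spp))
  if (nrow(d)) {
    m[cbind(match(d$survey_id, sv$survey_id), match(d$species, spp))] <- TRUE
  }
  lab <- sprintf("%s/%s%s", habitat,
                 if (pooling == "pc") "PC" else "ARU",
                 if (pooling == "per_hour") paste0("@h", hour) else
                   if (pooling == "pooled_morning") "(pooled)" else "")
  incidence_freq(label = lab, unit_matrix = m)
}

#' Select families and habitats for occupancy modelling
#'
#' A family is retained if its naive occupancy (fraction of sites with at
#' least one detection by either method) reaches `min_occupancy` in at
#' least one habitat. For each retained family, habitats are ranked by
#' their share of the family's occupied sites and included, largest share
#' first, until the cumulative share reaches `habitat_share`.
#'
#' @param x a [survey_dataset()].
#' @param region optional region filter.
#' @param min_occupancy naive-occupancy threshold (default 0.15).
#' @param habitat_share cumulative occupied-site share a family's modelled
#'   habitats must cover (default 0.90).
#' @return data.frame with one row per retained family: `family`,
#'   `habitats` (comma-separated), `max_occupancy`, `n_occupied_sites`.
#' @export
filter_families <- function(x, region = NULL, min_occupancy = 0.15,
                            habitat_share = 0.90) {
  stopifnot(inherits(x, "survey_dataset"))
  s <- x$sites
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  d <- x$detections[x$detections$survey_id %in% sv$survey_id, , drop = FALSE]
  unmapped <- setdiff(unique(d$species), x$families$species)
  if (length(unmapped))
    stop("species with no family mapping: ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  d$family <- x$families$family[match(d$species, x$families$species)]
  d$site_id <- sv$site_id[match(d$survey_id, sv$survey_id)]
  d$habitat <- s$habitat[match(d$site_id, s$site_id)]
  n_sites_hab <- table(factor(s$habitat, levels = HABITATS))
  occ <- unique(d[c("family", "site_id", "habitat")])
  out <- lapply(sort(unique(occ$family)), function(fam) {
    of <- occ[occ$family == fam, , drop = FALSE]
    n_occ_hab <- table(factor(of$habitat, levels = HABITATS))
    naive <- as.numeric(n_occ_hab) / pmax(as.numeric(n_sites_hab), 1L)
    if (max(naive) < min_occupancy) return(NULL)
    share <- as.numeric(n_occ_hab) / nrow(of)
    names(share) <- HABITATS
    # greedy descending-share accumulation; ties resolved by fixed
    # habitat order so output is independent of input row order
    ord <- order(-share, seq_along(share))
    cum <- cumsum(share[ord])
    k <- which(cum >= habitat_share - 1e-12)[1]
    habs <- HABITATS[ord][seq_len(k)]
    habs <- habs[share[habs] > 0]
    data.frame(family = fam,
               habitats = paste(habs, collapse = ","),
               max_occupancy = max(naive),
               n_occupied_sites = nrow(of),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(family = character(), habitats = character(),
                      max_occupancy = numeric(),
                      n_occupied_sites = integer())
  }
  rownames(out) <- NULL
  out
}
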