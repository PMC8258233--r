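# Species-level method-bias machinery: which species are detected by only
# one method, is that attributable to chance, and what share of the known
# community does each method reach.

#' Species detected by exactly one method
#'
#' Restricted to paired PC/ARU sites so both methods had the opportunity
#' to detect every species. A species that truly never vocalises can only
#' ever appear in the PC-only list.
#'
#' @param x a [survey_dataset()].
#' @param habitat optional habitat filter.
#' @param region optional region filter.
#' @return list with data.frames `pc_only` and `aru_only` (columns
#'   `species`, `incidence` = number of site-surveys with a detection),
#'   plus `both` (character vector of dual-method species).
#' @export
single_method_species <- function(x, habitat = NULL, region = NULL) {
  stopifnot(inherits(x, "survey_dataset"))
  s <- x$sites[x$sites$has_aru, , drop = FALSE]
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  if (!is.null(habitat)) s <- s[s$habitat == match.arg(habitat, HABITATS), ]
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  d <- x$detections[x$detections$survey_id %in% sv$survey_id, , drop = FALSE]
  d$method <- sv$method[match(d$survey_id, sv$survey_id)]
  d <- unique(d[c("survey_id", "species", "method")])
  inc <- function(meth) {
    di <- d[d$method == meth, , drop = FALSE]
    tab <- table(di$species)
    stats::setNames(as.integer(tab), names(tab))
  }
  pc <- inc("PC"); aru <- inc("ARU")
  pc_only <- setdiff(names(pc), names(aru))
  aru_only <- setdiff(names(aru), names(pc))
  list(
    pc_only = data.frame(species = pc_only,
                         incidence = as.integer(pc[pc_only]),
                         row.names = NULL),
    aru_only = data.frame(species = aru_only,
                          incidence = as.integer(aru[aru_only]),
                          row.names = NULL),
    both = sort(intersect(names(pc), names(aru))))
}

#' Fisher's exact test for a method-by-detection 2x2 table
#'
#' Two-sided exact p-value from the conditional hypergeometric
#' distribution: the sum of probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed table.
#'
#' @param x_a,n_a detections and total site-surveys for method A.
#' @param x_b,n_b detections and total site-surveys for method B.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(x_a, n_a, x_b, n_b) {
  if (any(c(x_a, n_a, x_b, n_b) < 0) || x_a > n_a || x_b > n_b)
    stop("need 0 <= x <= n for both methods", call. = FALSE)
  if (n_a == 0 && n_b == 0)
    stop("both methods have zero site-surveys", call. = FALSE)
  k <- x_a + x_b
  support <- max(0, k - n_b):min(k, n_a)
  probs <- stats::dhyper(support, n_a, n_b, k)
  p_obs <- stats::dhyper(x_a, n_a, n_b, k)
  # tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Method-bias table for single-method species
#'
#' For every species detected by only one method at paired sites, tests
#' whether the detection imbalance between methods is attributable to
#' chance, via [fisher_exact()] on detection frequencies across all
#' site-surveys.
#'
#' @param x a [survey_dataset()].
#' @param region optional region filter.
#' @param alpha significance level for the `significant` flag (default
#'   0.05; no multiple-testing correction is applied).
#' @return data.frame with one row per single-method species: `species`,
#'   `only_method`, `x_pc`, `n_pc`, `x_aru`, `n_aru`, `p_value`,
#'   `significant`.
#' @export
method_bias <- function(x, region = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "survey_dataset"))
  s <- x$sites[x$sites$has_aru, , drop = FALSE]
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  n_pc <- sum(sv$method == "PC")
  n_aru <- sum(sv$method == "ARU")
  d <- x$detections[x$detections$survey_id %in% sv$survey_id, , drop = FALSE]
  d$method <- sv$method[match(d$survey_id, sv$survey_id)]
  d <- unique(d[c("survey_id", "species", "method")])
  sm <- single_method_species(x, region = region)
  tally <- function(sp, meth) sum(d$species == sp & d$method == meth)
  rows <- lapply(c(sm$pc_only$species, sm$aru_only$species), function(sp) {
    x_pc <- tally(sp, "PC"); x_aru <- tally(sp, "ARU")
    p <- fisher_exact(x_pc, n_pc, x_aru, n_aru)
    data.frame(species = sp,
               only_method = if (x_aru == 0) "PC" else "ARU",
               x_pc = x_pc, n_pc = n_pc, x_aru = x_aru, n_aru = n_aru,
               p_value = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), only_method = character(),
                      x_pc = integer(), n_pc = integer(),
                      x_aru = integer(), n_aru = integer(),
                      p_value = numeric(), significant = logical())
  }
  rownames(out) <- NULL
  out
}

#' Percent of the known community captured
#'
#' Expresses an asymptotic richness estimate as a percentage of the known
#' (multiyear inventory) species richness, capped at 100 for reporting.
#'
#' @param estimate asymptotic richness estimate(s), e.g. from [chao2()].
#' @param known_richness known community richness (`>= 1`), recycled.
#' @return percentage(s) in `[0, 100]`.
#' @export
percent_of_known <- function(estimate, known_richness) {
  if (any(known_richness < 1)) stop("known_richness must be >= 1", call. = FALSE)
  pmin(100, 100 * estimate / known_richness)
}

#' Community capture summary per habitat for one method
#'
#' Chao2 asymptote of the method's accumulation curve in each habitat,
#' expressed as percent of the known community, with the across-habitat
#' mean and range.
#'
#' @param x a [survey_dataset()].
#' @param pooling `"pc"` or `"pooled_morning"` (ARU), per
#'   [build_incidence()].
#' @param region optional region filter.
#' @return list with `per_habitat` (data.frame: habitat, asymptote, known,
#'   pct), `mean_pct`, `range_pct`.
#' @export
capture_summary <- function(x, pooling = c("pooled_morning", "pc"),
                            region = NULL) {
  pooling <- match.arg(pooling)
  per <- lapply(HABITATS, function(h) {
    inc <- build_incidence(x, h, pooling = pooling, region = region)
    known <- length(unique(x$known$species[x$known$habitat == h]))
    asy <- chao2(inc)
    data.frame(habitat = h, asymptote = asy, known = known,
               pct = percent_of_known(asy, known))
  })
  per <- do.call(rbind, per)
  list(per_habitat = per, mean_pct = mean(per$pct),
       range_pct = range(per$pct))
}
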