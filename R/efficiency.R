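# Time-cost model and bootstrap protocol-efficiency analysis: how much of
# the known community does a candidate survey protocol (n point counts +
# n ARU windows per site) detect, per hour of combined field and
# laboratory effort.

#' Time-cost parameters for survey protocols
#'
#' Per-site visitation and per-sample processing costs, in minutes. The
#' ARU visitation cost covers both the deployment and the retrieval visit;
#' in mixed protocols up to `shared_visits_cover_pcs` point counts ride
#' along with those visits for free, and each further point count incurs
#' one extra PC visitation cost.
#'
#' @param aru_visit_min ARU visitation cost, min/site (default 40).
#' @param aru_sample_min ARU processing cost, min/sample (default 9).
#' @param pc_visit_min PC visitation cost, min/site (default 20).
#' @param pc_sample_min PC cost, min/count (default 7).
#' @param shared_visits_cover_pcs PCs covered by shared ARU visits
#'   (default 2).
#' @return list of class `cost_params`.
#' @export
cost_params <- function(aru_visit_min = 40, aru_sample_min = 9,
                        pc_visit_min = 20, pc_sample_min = 7,
                        shared_visits_cover_pcs = 2) {
  p <- list(aru_visit_min = aru_visit_min, aru_sample_min = aru_sample_min,
            pc_visit_min = pc_visit_min, pc_sample_min = pc_sample_min,
            shared_visits_cover_pcs = shared_visits_cover_pcs)
  if (any(unlist(p) < 0)) stop("cost parameters must be >= 0", call. = FALSE)
  structure(p, class = "cost_params")
}

#' Total effort hours for a survey protocol
#'
#' Minutes per site are: PC-only protocols
#' `n_pc * (pc_visit + pc_sample)`; ARU-only `aru_visit + aru_sample *
#' n_aru`; mixed `aru_visit + aru_sample * n_aru + pc_sample * n_pc +
#' pc_visit * max(0, n_pc - shared)` where `shared` point counts are
#' conducted during ARU deployment/retrieval visits.
#'
#' @param n_pc point counts per site (0--3).
#' @param n_aru ARU samples per site (0--15).
#' @param n_sites number of sites.
#' @param costs a [cost_params()].
#' @return effort in hours (`n_sites * minutes / 60`). Vectorised over
#'   `n_pc`/`n_aru`/`n_sites`.
#' @export
protocol_effort_hours <- function(n_pc, n_aru, n_sites,
                                  costs = cost_params()) {
  if (any(n_pc < 0) || any(n_aru < 0) || any(n_sites < 0))
    stop("negative protocol inputs", call. = FALSE)
  n <- max(length(n_pc), length(n_aru), length(n_sites))
  n_pc <- rep_len(n_pc, n); n_aru <- rep_len(n_aru, n)
  n_sites <- rep_len(n_sites, n)
  mins <- ifelse(
    n_aru == 0,
    n_pc * (costs$pc_visit_min + costs$pc_sample_min),
    costs$aru_visit_min + costs$aru_sample_min * n_aru +
      costs$pc_sample_min * n_pc +
      costs$pc_visit_min * pmax(0, n_pc - costs$shared_visits_cover_pcs))
  mins[n_aru == 0 & n_pc == 0] <- 0
  n_sites * mins / 60
}

#' Round effort hours for reporting
#'
#' Values of 10 hours or more are printed to the nearest hour, smaller
#' values to 0.1 hour (so 14.7 prints as 15 and 4.5 stays 4.5); raw hours
#' should be retained for computation.
#'
#' @param hours numeric effort hours.
#' @return rounded numeric vector.
#' @export
format_effort_hours <- function(hours) {
  ifelse(hours >= 10, round(hours), round(hours, 1))
}

# per-site survey-by-species detection structure for one habitat,
# restricted to paired PC/ARU sites
site_survey_species <- function(x, habitat, region = NULL) {
  s <- x$sites[x$sites$has_aru, , drop = FALSE]
  if (!is.null(region)) s <- s[s$region == match.arg(region, REGIONS), ]
  s <- s[s$habitat == match.arg(habitat, HABITATS), , drop = FALSE]
  if (!nrow(s)) stop("no paired sites in habitat", call. = FALSE)
  sv <- x$surveys[x$surveys$site_id %in% s$site_id, , drop = FALSE]
  d <- x$detections[x$detections$survey_id %in% sv$survey_id, , drop = FALSE]
  spp <- sort(unique(d$species))
  m <- matrix(FALSE, nrow(sv), length(spp),
              dimnames = list(sv$survey_id, spp))
  if (nrow(d)) {
    m[cbind(match(d$survey_id, sv$survey_id), match(d$species, spp))] <- TRUE
  }
  list(sites = s$site_id,
       pc_rows = lapply(s$site_id, function(id)
         which(sv$site_id == id & sv$method == "PC")),
       aru_rows = lapply(s$site_id, function(id)
         which(sv$site_id == id & sv$method == "ARU")),
       m = m)
}

#' Bootstrapped species richness of a survey protocol
#'
#' At each paired site, draws `n_aru` ARU samples and `n_pc` point counts
#' with replacement from that site's available surveys, pools the species
#' detected across all sites, and counts them; repeated `B` times to give
#' a bootstrap mean and SE (the SD of the replicate richness values). Also
#' reports the mean as a percentage of the habitat's known community.
#'
#' @param x a [survey_dataset()].
#' @param habitat habitat to analyse.
#' @param n_pc point counts per site per replicate.
#' @param n_aru ARU samples per site per replicate.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param region optional region filter.
#' @param pc_replace draw point counts with replacement (default `TRUE`);
#'   set `FALSE` to draw distinct rounds.
#' @return list of class `protocol_curve_point`: `n_pc`, `n_aru`,
#'   `n_sites`, `effort_hours`, `mean_richness`, `se`, `pct_known`, `B`.
#' @export
bootstrap_protocol_richness <- function(x, habitat, n_pc, n_aru, B = 10000,
                                        seed = 1, region = NULL,
                                        pc_replace = TRUE,
                                        costs = cost_params()) {
  stopifnot(inherits(x, "survey_dataset"))
  str <- site_survey_species(x, habitat, region)
  n_sites <- length(str$sites)
  known <- length(unique(x$known$species[x$known$habitat == habitat]))
  hours <- protocol_effort_hours(n_pc, n_aru, n_sites, costs)
  if (n_pc == 0 && n_aru == 0) {
    return(structure(list(n_pc = 0, n_aru = 0, n_sites = n_sites,
                          effort_hours = 0, mean_richness = 0, se = 0,
                          pct_known = 0, B = B),
                     class = "protocol_curve_point"))
  }
  if (n_pc > 0 && !pc_replace &&
      any(vapply(str$pc_rows, length, 1L) < n_pc))
    stop("n_pc exceeds available point counts at some site (pc_replace = FALSE)",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- str$m
  reps <- vapply(seq_len(B), function(b) {
    rows <- unlist(lapply(seq_len(n_sites), function(i) {
      c(if (n_pc > 0)
          str$pc_rows[[i]][sample.int(length(str$pc_rows[[i]]), n_pc,
                                      replace = pc_replace)],
        if (n_aru > 0)
          str$aru_rows[[i]][sample.int(length(str$aru_rows[[i]]), n_aru,
                                       replace = TRUE)])
    }))
    sum(colSums(m[rows, , drop = FALSE]) > 0)
  }, numeric(1))
  structure(list(n_pc = n_pc, n_aru = n_aru, n_sites = n_sites,
                 effort_hours = hours, mean_richness = mean(reps),
                 se = stats::sd(reps),
                 pct_known = percent_of_known(mean(reps), max(known, 1)),
                 B = B),
            class = "protocol_curve_point")
}

#' Protocol-efficiency curves for one habitat
#'
#' Evaluates ARU-only (1..`max_aru` samples/site), PC-only
#' (1..`max_pc` counts/site) and all mixed protocols, returning one row
#' per protocol.
#'
#' @param x a [survey_dataset()].
#' @param habitat habitat to analyse.
#' @param max_pc,max_aru protocol grid limits (defaults 3 and 15).
#' @param B bootstrap replicates per protocol.
#' @param seed integer seed (each protocol gets a deterministic sub-seed).
#' @param region optional region filter.
#' @return data.frame with `n_pc`, `n_aru`, `n_sites`, `effort_hours`,
#'   `mean_richness`, `se`, `pct_known`.
#' @export
protocol_curves <- function(x, habitat, max_pc = 3, max_aru = 15, B = 1000,
                            seed = 1, region = NULL,
                            costs = cost_params()) {
  grid <- expand.grid(n_pc = 0:max_pc, n_aru = 0:max_aru)
  grid <- grid[grid$n_pc + grid$n_aru > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pt <- bootstrap_protocol_richness(
      x, habitat, grid$n_pc[i], grid$n_aru[i], B = B,
      seed = seed * 1000L + i, region = region, costs = costs)
    as.data.frame(unclass(pt)[c("n_pc", "n_aru", "n_sites", "effort_hours",
                                "mean_richness", "se", "pct_known")])
  })
  out <- do.call(rbind, rows)
  out$habitat <- habitat
  rownames(out) <- NULL
  out
}

#' Pareto frontier of survey protocols
#'
#' The "best" protocols: those not dominated by any other protocol, i.e.
#' no other protocol detects at least as large a share of the community
#' for no more effort (with one of the two strictly better).
#'
#' @param curves data.frame with columns `effort_hours` and `pct_known`
#'   (e.g. from [protocol_curves()]).
#' @return the non-dominated rows, sorted by effort.
#' @export
efficiency_frontier <- function(curves) {
  stopifnot(all(c("effort_hours", "pct_known") %in% names(curves)))
  n <- nrow(curves)
  if (n < 1) return(curves)
  dominated <- vapply(seq_len(n), function(i) {
    any(curves$effort_hours <= curves$effort_hours[i] &
          curves$pct_known >= curves$pct_known[i] &
          (curves$effort_hours < curves$effort_hours[i] |
             curves$pct_known > curves$pct_known[i]))
  }, logical(1))
  out <- curves[!dominated, , drop = FALSE]
  out[order(out$effort_hours), , drop = FALSE]
}
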