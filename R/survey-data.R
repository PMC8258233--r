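#' @keywords internal
"_PACKAGE"

HABITATS <- c("montane", "subalpine", "alpine")
REGIONS <- c("BC", "Chile")
METHODS <- c("PC", "ARU")

#' Survey dataset container
#'
#' Bundles the five tables of a dual-method survey campaign: sites, survey
#' events, detections, a species-to-family lookup and the known community
#' inventory per habitat. The unit of observation throughout is the
#' *site-survey*: one 6-min point count (PC) or one analysed 6-min ARU
#' recording window.
#'
#' @param sites data.frame with columns `site_id`, `region`, `mountain`,
#'   `habitat`, `elevation`, `canopy_cover`, `understory_cover`,
#'   `shrub_cover`, `ground_cover`, `has_aru`.
#' @param surveys data.frame with columns `survey_id`, `site_id`, `method`
#'   (`"PC"` or `"ARU"`), `date` (`Date`), `hours_after_sunrise`,
#'   `wind_score` (0--3), `day_index`, `hour_index` (0--4, ARU only, else
#'   `NA`), `round_index` (1--3, PC only, else `NA`), `canopy_at_survey`.
#' @param detections data.frame with columns `survey_id`, `species`.
#'   Duplicate (survey, species) rows are collapsed: a species is either
#'   detected or not within one site-survey.
#' @param families data.frame with columns `species`, `family`.
#' @param known data.frame with columns `habitat`, `species`; the multiyear
#'   inventory of species known to occur in each habitat.
#' @param validate logical; run [validate_survey_data()] on construction.
#'
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(sites, surveys, detections, families, known,
                           validate = TRUE) {
  sites <- as.data.frame(sites)
  surveys <- as.data.frame(surveys)
  detections <- as.data.frame(detections)
  families <- as.data.frame(families)
  known <- as.data.frame(known)
  if (!inherits(surveys$date, "Date")) {
    surveys$date <- as.Date(surveys$date)
  }
  dup <- duplicated(detections[c("survey_id", "species")])
  if (any(dup)) detections <- detections[!dup, , drop = FALSE]
  rownames(sites) <- rownames(surveys) <- rownames(detections) <- NULL
  x <- structure(
    list(sites = sites, surveys = surveys, detections = detections,
         families = families, known = known),
    class = "survey_dataset")
  if (validate) validate_survey_data(x)
  x
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  sites:      %d (%s)\n", nrow(x$sites),
              paste(unique(x$sites$region), collapse = ", ")))
  cat(sprintf("  surveys:    %d site-surveys (PC %d, ARU %d)\n",
              nrow(x$surveys), sum(x$surveys$method == "PC"),
              sum(x$surveys$method == "ARU")))
  cat(sprintf("  detections: %d records, %d species, %d families\n",
              nrow(x$detections), length(unique(x$detections$species)),
              length(unique(x$families$family))))
  invisible(x)
}

req_cols <- list(
  sites = c("site_id", "region", "mountain", "habitat", "elevation",
            "canopy_cover", "understory_cover", "shrub_cover",
            "ground_cover", "has_aru"),
  surveys = c("survey_id", "site_id", "method", "date",
              "hours_after_sunrise", "wind_score", "day_index",
              "hour_index", "round_index", "canopy_at_survey"),
  detections = c("survey_id", "species"),
  families = c("species", "family"),
  known = c("habitat", "species"))

#' Validate a survey dataset
#'
#' Checks schema (required columns), referential integrity (every survey's
#' `site_id` exists; every detection's `survey_id` exists), value ranges
#' (covers in \[0, 100\], wind 0--3, ARU `hour_index` in 0--4, PC
#' `round_index` in 1--3) and, optionally, the habitat classification rule
#' used in the field (montane >= 50% canopy, subalpine 5--50%, alpine
#' 0--5%).
#'
#' @param x a [survey_dataset()].
#' @param check_habitat_rule logical; also enforce the canopy/habitat rule.
#' @return `x`, invisibly. Errors describe the first violated constraint.
#' @export
validate_survey_data <- function(x, check_habitat_rule = FALSE) {
  stopifnot(inherits(x, "survey_dataset"))
  for (tb in names(req_cols)) {
    missing <- setdiff(req_cols[[tb]], names(x[[tb]]))
    if (length(missing)) {
      stop(sprintf("schema error: table '%s' is missing column(s): %s",
                   tb, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  s <- x$sites; sv <- x$surveys; d <- x$detections
  if (anyDuplicated(s$site_id))
    stop("integrity error: duplicated site_id in sites", call. = FALSE)
  if (anyDuplicated(sv$survey_id))
    stop("integrity error: duplicated survey_id in surveys", call. = FALSE)
  bad <- setdiff(sv$site_id, s$site_id)
  if (length(bad))
    stop(sprintf("integrity error: surveys reference unknown site_id: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- setdiff(d$survey_id, sv$survey_id)
  if (length(bad))
    stop(sprintf("integrity error: detections reference unknown survey_id: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (!all(s$region %in% REGIONS))
    stop("sites$region must be one of: ", paste(REGIONS, collapse = ", "),
         call. = FALSE)
  if (!all(s$habitat %in% HABITATS))
    stop("sites$habitat must be one of: ", paste(HABITATS, collapse = ", "),
         call. = FALSE)
  if (any(s$elevation <= 0)) stop("elevation must be > 0", call. = FALSE)
  covers <- c("canopy_cover", "understory_cover", "shrub_cover", "ground_cover")
  for (cc in covers) {
    if (any(s[[cc]] < 0 | s[[cc]] > 100))
      stop(sprintf("%s outside [0, 100]", cc), call. = FALSE)
  }
  if (!all(sv$method %in% METHODS))
    stop("surveys$method must be PC or ARU", call. = FALSE)
  if (any(sv$wind_score < 0 | sv$wind_score > 3))
    stop("wind_score outside 0..3", call. = FALSE)
  if (any(sv$hours_after_sunrise < 0))
    stop("hours_after_sunrise must be >= 0", call. = FALSE)
  aru <- sv$method == "ARU"
  if (any(is.na(sv$hour_index[aru])) ||
      any(!sv$hour_index[aru] %in% 0:4))
    stop("ARU surveys require hour_index in 0..4", call. = FALSE)
  if (any(is.na(sv$round_index[!aru])) ||
      any(!sv$round_index[!aru] %in% 1:3))
    stop("PC surveys require round_index in 1..3", call. = FALSE)
  if (any(!nzchar(d$species)))
    stop("empty species name in detections", call. = FALSE)
  if (check_habitat_rule) {
    lo <- c(montane = 50, subalpine = 5, alpine = 0)[s$habitat]
    hi <- c(montane = 100, subalpine = 50, alpine = 5)[s$habitat]
    bad <- s$canopy_cover < lo | s$canopy_cover > hi
    if (any(bad))
      stop(sprintf("habitat/canopy rule violated at site(s): %s",
                   paste(utils::head(s$site_id[bad], 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' Reads the five-table CSV schema (`sites.csv`, `surveys.csv`,
#' `detections.csv`, `families.csv`, `known_community.csv`). Files are
#' comma-separated UTF-8 with a header row; dates are ISO-8601.
#'
#' @param dir directory containing the five CSV files, or a named list of
#'   paths with elements `sites`, `surveys`, `detections`, `families`,
#'   `known`.
#' @param validate logical; validate after reading.
#' @return a [survey_dataset()].
#' @export
read_survey_data <- function(dir, validate = TRUE) {
  if (is.character(dir) && length(dir) == 1) {
    paths <- list(sites = file.path(dir, "sites.csv"),
                  surveys = file.path(dir, "surveys.csv"),
                  detections = file.path(dir, "detections.csv"),
                  families = file.path(dir, "families.csv"),
                  known = file.path(dir, "known_community.csv"))
  } else {
    paths <- dir
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  sites <- rd(paths$sites)
  surveys <- rd(paths$surveys)
  surveys$date <- as.Date(surveys$date)
  sites$has_aru <- as.logical(sites$has_aru)
  survey_dataset(sites, surveys, rd(paths$detections), rd(paths$families),
                 rd(paths$known), validate = validate)
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey_data()]; round-trips all records and values.
#'
#' @param x a [survey_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_survey_data <- function(x, dir) {
  stopifnot(inherits(x, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  sv <- x$surveys
  sv$date <- format(sv$date, "%Y-%m-%d")
  wr(x$sites, "sites.csv")
  wr(sv, "surveys.csv")
  wr(x$detections, "detections.csv")
  wr(x$families, "families.csv")
  wr(x$known, "known_community.csv")
  invisible(dir)
}

#' Count site-surveys
#'
#' One site-survey is one 6-min observation unit: a single point count or a
#' single analysed ARU window. Counts are additive across disjoint regions
#' and methods.
#'
#' @param x a [survey_dataset()].
#' @param region optional region filter (`"BC"` or `"Chile"`).
#' @param method optional method filter (`"PC"` or `"ARU"`).
#' @return integer count of survey events.
#' @export
tally_site_surveys <- function(x, region = NULL, method = NULL) {
  stopifnot(inherits(x, "survey_dataset"))
  sv <- x$surveys
  if (!is.null(region)) {
    region <- match.arg(region, REGIONS)
    keep <- x$sites$site_id[x$sites$region == region]
    sv <- sv[sv$site_id %in% keep, , drop = FALSE]
  }
  if (!is.null(method)) {
    method <- match.arg(method, METHODS)
    sv <- sv[sv$method == method, , drop = FALSE]
  }
  nrow(sv)
}

#' Ordinary least-squares residuals of canopy cover on elevation
#'
#' Canopy cover declines with elevation, so raw canopy and elevation are
#' collinear as occupancy covariates. The occupancy model therefore uses
#' the residuals of an OLS fit of canopy cover on elevation in place of raw
#' canopy.
#'
#' @param sites the `sites` table of a [survey_dataset()], or any
#'   data.frame with `site_id`, `elevation` and `canopy_cover` columns.
#' @return named numeric vector of residuals (names are `site_id`); sums
#'   to zero up to floating point error.
#' @export
canopy_residuals <- function(sites) {
  if (inherits(sites, "survey_dataset")) sites <- sites$sites
  ok <- is.finite(sites$elevation) & is.finite(sites$canopy_cover)
  if (sum(ok) < 3) stop("need >= 3 sites with finite elevation and canopy",
                        call. = FALSE)
  s <- sites[ok, , drop = FALSE]
  if (stats::sd(s$elevation) == 0)
    stop("elevation is constant: canopy-on-elevation slope undefined",
         call. = FALSE)
  fit <- stats::lm(canopy_cover ~ elevation, data = s)
  r <- stats::residuals(fit)
  names(r) <- s$site_id
  r
}
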