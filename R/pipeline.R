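# One-command orchestration: simulate (or ingest) -> diversity ->
# occupancy -> method comparison -> protocol efficiency, with per-stage
# seeds, CSV outputs and a machine-readable JSON summary. CSV/JSON are
# the contract; plots are conveniences.

#' Pipeline run configuration
#'
#' @param scenario `"BC"` or `"Chile"` to simulate the default scenario,
#'   or `NULL` to read data from `input_dir`.
#' @param input_dir directory with the five CSV tables (used when
#'   `scenario` is `NULL`).
#' @param out_dir output directory.
#' @param stages stages to run, a subset of `"diversity"`, `"occupancy"`,
#'   `"compare"`, `"efficiency"`.
#' @param seeds named list of integer seeds per stochastic stage
#'   (`simulate`, `diversity`, `occupancy`, `efficiency`).
#' @param coverage coverage target for diversity standardisation.
#' @param boot_div bootstrap replicates for diversity CIs.
#' @param chat_boot goodness-of-fit bootstrap replicates.
#' @param max_families cap on families modelled (most-occupied first);
#'   keeps desk-scale runs quick.
#' @param efficiency_reps bootstrap replicates per protocol.
#' @param max_aru,max_pc protocol grid limits.
#' @param plots also write simple PDF plots (default `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = "BC", input_dir = NULL,
                       out_dir = "duosurvey-out",
                       stages = c("diversity", "occupancy", "compare",
                                  "efficiency"),
                       seeds = list(simulate = 1, diversity = 2,
                                    occupancy = 3, efficiency = 4),
                       coverage = 0.97, boot_div = 200, chat_boot = 50,
                       max_families = 3, efficiency_reps = 1000,
                       max_aru = 15, max_pc = 3, plots = FALSE) {
  known_stages <- c("diversity", "occupancy", "compare", "efficiency")
  bad <- setdiff(stages, known_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in c("simulate", "diversity", "occupancy", "efficiency")) {
    if (is.null(seeds[[nm]]))
      stop("missing seed for stage: ", nm, call. = FALSE)
  }
  structure(list(scenario = scenario, input_dir = input_dir,
                 out_dir = out_dir, stages = stages, seeds = seeds,
                 coverage = coverage, boot_div = boot_div,
                 chat_boot = chat_boot, max_families = max_families,
                 efficiency_reps = efficiency_reps, max_aru = max_aru,
                 max_pc = max_pc, plots = plots),
            class = "run_config")
}

wr_csv <- function(df, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes stage CSVs plus a
#' `summary.json` under `out_dir`. Identical configuration and seeds give
#' a byte-identical summary.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  dataset <- if (!is.null(config$scenario)) {
    generate_scenario(config$scenario, seed = config$seeds$simulate)
  } else {
    if (is.null(config$input_dir))
      stop("either scenario or input_dir must be given", call. = FALSE)
    read_survey_data(config$input_dir)
  }
  region <- unique(dataset$sites$region)[1]
  write_survey_data(dataset, file.path(out, "data"))

  summary <- list(
    package_version = as.character(utils::packageVersion("duosurvey")),
    region = region,
    seeds = config$seeds,
    tallies = list(
      site_surveys_total = tally_site_surveys(dataset),
      site_surveys_pc = tally_site_surveys(dataset, method = "PC"),
      site_surveys_aru = tally_site_surveys(dataset, method = "ARU")))

  if ("diversity" %in% config$stages) {
    rows <- list(); curves <- list()
    for (h in HABITATS) {
      for (pl in c("pc", "pooled_morning")) {
        inc <- tryCatch(build_incidence(dataset, h, pooling = pl),
                        error = function(e) NULL)
        if (is.null(inc)) next
        for (q in 0:1) {
          est <- tryCatch(
            suppressWarnings(estimate_at_coverage(
              inc, q, target_coverage = config$coverage,
              B = config$boot_div, seed = config$seeds$diversity)),
            error = function(e) e)
          rows[[length(rows) + 1]] <- if (inherits(est, "error")) {
            # coverage target unreachable for this assemblage: keep the
            # row, flagged, rather than aborting the whole stage
            data.frame(habitat = h,
                       method = if (pl == "pc") "PC" else "ARU-pooled",
                       q = q, t = NA_integer_, estimate = NA_real_,
                       se = NA_real_, lo84 = NA_real_, hi84 = NA_real_,
                       lo95 = NA_real_, hi95 = NA_real_,
                       coverage = NA_real_, extrapolated = NA)
          } else {
            data.frame(
              habitat = h, method = if (pl == "pc") "PC" else "ARU-pooled",
              q = q, t = est$t, estimate = est$estimate, se = est$se,
              lo84 = est$ci84[1], hi84 = est$ci84[2],
              lo95 = est$ci95[1], hi95 = est$ci95[2],
              coverage = est$coverage, extrapolated = est$extrapolated)
          }
        }
        curves[[length(curves) + 1]] <- accumulation_curve(inc, 0)
      }
    }
    div <- do.call(rbind, rows)
    wr_csv(div, file.path(out, "diversity"), "estimates.csv")
    wr_csv(do.call(rbind, curves), file.path(out, "diversity"),
           "accumulation_curves.csv")
    summary$diversity <- div
  }

  if ("occupancy" %in% config$stages) {
    tasks <- filter_families(dataset)
    tasks <- tasks[order(-tasks$max_occupancy), , drop = FALSE]
    tasks <- utils::head(tasks, config$max_families)
    sel_rows <- list(); coef_rows <- list()
    for (i in seq_len(nrow(tasks))) {
      fam <- tasks$family[i]
      habs <- strsplit(tasks$habitats[i], ",")[[1]]
      res <- tryCatch({
        hist <- build_history(dataset, fam, habitats = habs)
        select_model(hist, chat_boot = config$chat_boot,
                     seed = config$seeds$occupancy)
      }, error = function(e) e)
      if (inherits(res, "error")) next
      tb <- res$table
      tb$family <- fam; tb$chat <- res$chat; tb$flag <- res$flag
      sel_rows[[length(sel_rows) + 1]] <- tb
      if (res$flag == "ok") {
        bf <- res$fits[[res$best]]
        coef_rows[[length(coef_rows) + 1]] <- data.frame(
          family = fam, model = res$best, term = names(bf$coef),
          estimate = as.numeric(bf$coef),
          se = if (!is.null(bf$vcov)) sqrt(diag(bf$vcov)) else NA_real_)
      }
    }
    if (length(sel_rows))
      wr_csv(do.call(rbind, sel_rows), file.path(out, "occupancy"),
             "model_selection.csv")
    if (length(coef_rows))
      wr_csv(do.call(rbind, coef_rows), file.path(out, "occupancy"),
             "coefficients.csv")
    summary$occupancy_families <- tasks$family
  }

  if ("compare" %in% config$stages) {
    mb <- method_bias(dataset)
    wr_csv(mb, file.path(out, "compare"), "method_bias.csv")
    cap_aru <- capture_summary(dataset, "pooled_morning")
    cap_pc <- capture_summary(dataset, "pc")
    wr_csv(rbind(cbind(method = "ARU-pooled", cap_aru$per_habitat),
                 cbind(method = "PC", cap_pc$per_habitat)),
           file.path(out, "compare"), "community_capture.csv")
    summary$capture <- list(
      aru_mean_pct = cap_aru$mean_pct, aru_range_pct = cap_aru$range_pct,
      pc_mean_pct = cap_pc$mean_pct, pc_range_pct = cap_pc$range_pct,
      n_significant_bias = sum(mb$significant))
  }

  if ("efficiency" %in% config$stages) {
    curves <- list()
    for (h in HABITATS) {
      cv <- tryCatch(
        protocol_curves(dataset, h, max_pc = config$max_pc,
                        max_aru = config$max_aru,
                        B = config$efficiency_reps,
                        seed = config$seeds$efficiency),
        error = function(e) NULL)
      if (!is.null(cv)) curves[[h]] <- cv
    }
    allc <- do.call(rbind, curves)
    wr_csv(allc, file.path(out, "efficiency"), "protocol_curves.csv")
    front <- do.call(rbind, lapply(names(curves), function(h) {
      f <- efficiency_frontier(curves[[h]]); f$habitat <- h; f
    }))
    wr_csv(front, file.path(out, "efficiency"), "frontier.csv")
    one_aru <- allc[allc$n_pc == 0 & allc$n_aru == 1, , drop = FALSE]
    summary$effort_hours <- lapply(seq_len(nrow(one_aru)), function(i)
      list(habitat = one_aru$habitat[i], n_pc = 0, n_aru = 1,
           n_sites = one_aru$n_sites[i],
           effort_hours = one_aru$effort_hours[i],
           effort_hours_printed = format_effort_hours(one_aru$effort_hours[i])))
  }

  # summary.json must be byte-identical across reruns with equal seeds,
  # so wall-clock info goes to the run log instead
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(c(
    sprintf("duosurvey %s", utils::packageVersion("duosurvey")),
    sprintf("finished: %s", format(Sys.time())),
    sprintf("elapsed_s: %.1f",
            as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("seeds: %s", paste(names(config$seeds),
                               unlist(config$seeds), sep = "=",
                               collapse = " "))),
    file.path(out, "run_log.txt"))
  invisible(summary)
}
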