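# End-to-end orchestration: simulate / analyze / report. Thin, config-
# driven wrappers over the package's modules, with per-stage row counts
# and a reproducible run manifest. One seed in the config determines all
# stochastic behavior (simulation and permutation tests).

#' Default run configuration
#'
#' Every field defaults to the analysis chain's stated constants: 10-km
#' island buffer, 24-h regularization step (implicit in the daily
#' smoother), 1-km sargassum radius, magnetic declination 0.
#'
#' @param scenario "jan" or "jul" (simulate).
#' @param n_turtles cohort size (NULL = scenario default).
#' @param n_residential residential count (NULL = scenario default).
#' @param duration_days track duration.
#' @param seed master seed.
#' @param buffer_km island buffer radius.
#' @param declination_deg magnetic declination.
#' @param sarg_radius_km sargassum extraction radius.
#' @param watson_B Watson-test permutations.
#' @param gamm_k spatial basis dimension.
#' @param gamm_fixed candidate fixed effects.
#' @param arma_max ACF/PACF-seeded grid cap for ARMA orders.
#' @param res_deg simulated field resolution.
#' @param out_dir output directory.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(scenario = "jan", n_turtles = NULL,
                       n_residential = NULL, duration_days = 15,
                       seed = 1, buffer_km = 10, declination_deg = 0,
                       sarg_radius_km = 1, watson_B = 9999,
                       gamm_k = 30,
                       gamm_fixed = c("cur_speed_kmday", "sst",
                                      "sargassum", "weight_kg", "period"),
                       arma_max = 4, res_deg = 0.25,
                       out_dir = tempfile("run")) {
  structure(as.list(environment()), class = "run_config")
}

#' Simulate a scenario cohort to disk
#'
#' Writes the fix table, gridded field, island polygon, per-animal
#' covariates and the ground-truth daily tables (true positions and true
#' daily-mean swim vectors), plus a JSON manifest. Deterministic under
#' the config seed.
#'
#' @param config a [run_config()].
#' @return invisible list of written paths and the cohort object.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(config$scenario, n_turtles = config$n_turtles,
                        seed = config$seed,
                        n_residential = config$n_residential,
                        duration_days = config$duration_days,
                        res_deg = config$res_deg)
  od <- config$out_dir
  write_fixes(cohort$fixes, file.path(od, "fixes.csv"))
  write_field(cohort$field, file.path(od, "field.csv"))
  write_polygon(cohort$island, file.path(od, "island.csv"))
  utils::write.csv(cohort$covariates, file.path(od, "covariates.csv"),
                   row.names = FALSE)
  truth <- do.call(rbind, lapply(names(cohort$tracks), function(a) {
    d <- cohort$tracks[[a]]$daily
    cbind(id = a, d)
  }))
  utils::write.csv(truth, file.path(od, "truth_daily.csv"),
                   row.names = FALSE)
  manifest <- list(stage = "simulate", scenario = config$scenario,
                   seed = config$seed,
                   n_turtles = nrow(cohort$covariates),
                   n_residential = sum(cohort$covariates$residential),
                   n_fixes = nrow(cohort$fixes))
  jsonlite::write_json(manifest, file.path(od, "manifest_simulate.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("simulated ", manifest$n_turtles, " animals (",
          manifest$n_residential, " residential), ",
          manifest$n_fixes, " fixes -> ", od)
  invisible(list(dir = od, cohort = cohort))
}

## analyze one simulated scenario directory; returns per-period products
.analyze_period <- function(dir, config) {
  fixes <- read_fixes(file.path(dir, "fixes.csv"))
  field <- read_field(file.path(dir, "field.csv"))
  island <- read_polygon(file.path(dir, "island.csv"))
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"))
  labels <- classify_dispersal(fixes, island, config$buffer_km)
  disp_ids <- labels$id[labels$label == "dispersive"]
  reg <- regularize_cohort(fixes[fixes$id %in% disp_ids, , drop = FALSE],
                           island, config$buffer_km)
  decomps <- list(); annos <- list(); pers <- list()
  init_head <- numeric(0)
  for (a in names(reg$tracks)) {
    tr <- reg$tracks[[a]]
    if (nrow(tr) < 2) next
    decomps[[a]] <- decompose_track(tr, field)
    annos[[a]] <- annotate_track(tr, field,
                                 sarg_radius_km = config$sarg_radius_km)
    if (nrow(tr) >= 3)
      pers[[a]] <- persistence_series(decomps[[a]], annos[[a]])
    h <- initial_heading(fixes[fixes$id == a, ], config$declination_deg)
    if (is.finite(h)) init_head[a] <- h
  }
  daily_head <- unlist(lapply(decomps, function(d) {
    ok <- !is.na(d$ground_east) &
      !(d$ground_east == 0 & d$ground_north == 0)
    velocity_direction_deg(d$ground_east[ok], d$ground_north[ok])
  }))
  cur_dir <- unlist(lapply(decomps, function(d) {
    ok <- !is.na(d$cur_east) & !(d$cur_east == 0 & d$cur_north == 0)
    velocity_direction_deg(d$cur_east[ok], d$cur_north[ok])
  }))
  summary <- cohort_summary(reg$tracks, decomps, annos, covariates)
  pers_all <- if (length(pers)) do.call(rbind, pers) else NULL
  if (!is.null(pers_all))
    pers_all <- merge(pers_all,
                      covariates[, c("id", "period", "age_class",
                                     "weight_kg")],
                      by = "id", sort = FALSE)
  list(labels = labels, tracks = reg$tracks, decomps = decomps,
       annos = annos, persistence = pers_all, summary = summary,
       daily_headings = daily_head, current_directions = cur_dir,
       initial_headings = init_head, covariates = covariates,
       skipped = reg$skipped, removed_count = reg$removed_count)
}

#' Analyze one or more simulated (or ingested) scenario directories
#'
#' Chains classification, buffer filtering, state-space regularization,
#' current correction, environmental annotation, movement metrics,
#' circular tests across periods and the persistence GAMM; writes the
#' full product set (labels, daily products, summary, test table, model
#' coefficient table, elimination trace, manifest) under
#' `config$out_dir`.
#'
#' @param input_dirs character vector of directories written by
#'   [run_simulate()] (one per period).
#' @param config a [run_config()]; `out_dir` receives the products.
#' @return invisible list of the in-memory products.
#' @export
run_analyze <- function(input_dirs, config) {
  stopifnot(inherits(config, "run_config"))
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  per <- lapply(input_dirs, .analyze_period, config = config)
  names(per) <- vapply(per, function(p)
    as.character(p$covariates$period[1]), character(1))

  labels <- do.call(rbind, lapply(per, `[[`, "labels"))
  utils::write.csv(labels, file.path(od, "dispersal_labels.csv"),
                   row.names = FALSE)
  daily <- do.call(rbind, unlist(lapply(per, `[[`, "decomps"),
                                 recursive = FALSE))
  if (!is.null(daily) && nrow(daily))
    write_daily_products(daily, od, "daily")
  summary <- do.call(rbind, lapply(per, `[[`, "summary"))
  utils::write.csv(summary, file.path(od, "track_summary.csv"),
                   row.names = FALSE)

  # circular contrasts on pooled daily values per period
  tests <- NULL
  if (sum(vapply(per, function(p) length(p$daily_headings) > 0,
                 logical(1))) >= 1) {
    heads <- lapply(per, `[[`, "daily_headings")
    curs <- lapply(per, `[[`, "current_directions")
    tests <- heading_current_contrast(heads, curs, B = config$watson_B,
                                      seed = config$seed)
    utils::write.csv(tests, file.path(od, "circular_tests.csv"),
                     row.names = FALSE)
  }

  # persistence model across periods (dispersive animals only)
  pers <- do.call(rbind, lapply(per, `[[`, "persistence"))
  model <- NULL
  if (!is.null(pers) && nrow(pers) >= 30) {
    fixed <- config$gamm_fixed
    have <- vapply(setdiff(fixed, "period"), function(v)
      v %in% names(pers) && any(!is.na(pers[[v]])), logical(1))
    fixed <- c(names(have)[have],
               if ("period" %in% fixed) "period")
    spec <- gamm_spec(fixed = fixed, k = min(config$gamm_k, nrow(pers) - 10))
    sel <- backward_eliminate(pers, spec)
    # residual ARMA order from the selected model, then final refit
    runs_ix <- .residual_runs(seq_along(sel$fit$residuals),
                              sel$fit$dd$animal, sel$fit$dd$day)
    runs <- lapply(runs_ix, function(ix) sel$fit$residuals[ix])
    ao <- select_arma(runs, config$arma_max, config$arma_max)
    sp_final <- sel$spec; sp_final$arma_p <- ao$p; sp_final$arma_q <- ao$q
    final <- fit_pgamm(pers, sp_final)
    model <- list(selection = sel, arma_order = ao, final = final)
    utils::write.csv(sel$trace, file.path(od, "elimination_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(final$coefficients,
                     file.path(od, "model_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(edf = final$smoother$edf,
                                F = final$smoother$F,
                                p = final$smoother$p,
                                arma_p = final$arma$p,
                                arma_q = final$arma$q,
                                aic = final$aic),
                     file.path(od, "model_smoother.csv"),
                     row.names = FALSE)
    utils::write.csv(persistence_surface(final),
                     file.path(od, "persistence_surface.csv"),
                     row.names = FALSE)
    utils::write.csv(pers, file.path(od, "persistence_series.csv"),
                     row.names = FALSE)
  } else {
    message("persistence model skipped: too few dispersive daily rows")
  }

  manifest <- list(
    stage = "analyze", seed = config$seed,
    inputs = input_dirs,
    n_animals = nrow(labels),
    n_dispersive = sum(labels$label == "dispersive"),
    n_residential = sum(labels$label == "residential"),
    removed_in_buffer = sum(vapply(per, `[[`, numeric(1),
                                   "removed_count")),
    skipped_animals = unlist(lapply(per, `[[`, "skipped")),
    daily_rows = if (is.null(daily)) 0L else nrow(daily),
    persistence_rows = if (is.null(pers)) 0L else nrow(pers),
    model_fitted = !is.null(model))
  jsonlite::write_json(manifest, file.path(od, "manifest_analyze.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(periods = per, labels = labels, summary = summary,
                 tests = tests, persistence = pers, model = model,
                 manifest = manifest))
}

#' Human-readable run report
#'
#' Collates the product tables of a completed [run_analyze()] directory
#' into one markdown summary: cohort counts, circular means per group,
#' the test table, the final model coefficients and the elimination
#' trace. Missing stages are marked unavailable.
#'
#' @param dir products directory.
#' @param path optional output file (default `report.md` inside `dir`).
#' @return the report text, invisibly; also written to `path`.
#' @export
run_report <- function(dir, path = file.path(dir, "report.md")) {
  L <- character()
  add <- function(...) L <<- c(L, paste0(...))
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  add("# Dispersal analysis report\n")
  lab <- rd("dispersal_labels.csv")
  if (is.null(lab)) add("## Cohort\n\n(unavailable)\n") else {
    add("## Cohort\n")
    add("- animals: ", nrow(lab))
    add("- dispersive: ", sum(lab$label == "dispersive"))
    add("- residential: ", sum(lab$label == "residential"), "\n")
  }
  ts <- rd("track_summary.csv")
  if (!is.null(ts)) {
    add("## Track summaries (per-animal means)\n")
    add("- mean 24-h displacement (km): ",
        round(mean(ts$mean_disp_km, na.rm = TRUE), 1))
    add("- mean swimming speed (km/day): ",
        round(mean(ts$mean_swim_kmday, na.rm = TRUE), 1), "\n")
  }
  ct <- rd("circular_tests.csv")
  if (is.null(ct)) add("## Circular tests\n\n(unavailable)\n") else {
    add("## Circular tests (Watson U2, permutation p)\n")
    for (i in seq_len(nrow(ct)))
      add("- ", ct$contrast[i], ": U2 = ", signif(ct$u2[i], 3),
          ", p = ", signif(ct$p[i], 3))
    add("")
  }
  mc <- rd("model_coefficients.csv")
  if (is.null(mc)) add("## Persistence model\n\n(unavailable)\n") else {
    add("## Persistence model (final, after AIC backward elimination)\n")
    for (i in seq_len(nrow(mc)))
      add("- ", mc$term[i], ": ", signif(mc$estimate[i], 3),
          " +/- ", signif(mc$se[i], 3), " (p = ", signif(mc$p[i], 2), ")")
    sm <- rd("model_smoother.csv")
    if (!is.null(sm))
      add("- s(lat,lon): EDF = ", round(sm$edf, 2),
          ", F = ", signif(sm$F, 3), ", ARMA(", sm$arma_p, ",",
          sm$arma_q, ")")
    add("")
    tr <- rd("elimination_trace.csv")
    if (!is.null(tr)) {
      add("### Elimination trace\n")
      for (i in seq_len(nrow(tr)))
        add("- step ", tr$step[i], ": AIC = ", round(tr$aic[i], 2),
            " (", tr$action[i], ")")
      add("")
    }
  }
  txt <- paste(L, collapse = "\n")
  writeLines(txt, path)
  invisible(txt)
}
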