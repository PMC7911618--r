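#' Build a pipeline configuration
#'
#' Assembles (and validates) the declarative configuration driving
#' [run_pipeline()]. Either a synthetic scenario is generated
#' (`simulate = TRUE`, the default) or raster/occurrence paths are
#' read from disk.
#'
#' @param simulate Generate synthetic inputs from `scenario`?
#' @param scenario A [synthetic_scenario()] (simulated runs). The
#'   current stack, true suitability, occurrences and one future stack
#'   per entry of `future_scenarios` are generated from it.
#' @param future_scenarios Named list of future perturbations, each a
#'   list with `warming_offset` and `precip_factor`; defaults to a
#'   single `"future"` scenario using the scenario's own values.
#' @param current_rasters,future_rasters,occurrence_file File inputs
#'   (`simulate = FALSE`): named vectors/lists of `.asc` paths per
#'   variable, a named list of such sets per future scenario, and an
#'   occurrence CSV.
#' @param geodetector List of screening settings: `L`, `q_threshold`,
#'   `spacing_km`, `n_permutations`.
#' @param model List of model settings: `fc`, `rm`, `background_n`,
#'   `n_knots`, `max_iter`, `test_fraction`, `output`, `clamp`.
#' @param thresholds Suitability class thresholds (default
#'   `c(0.1, 0.3, 0.6)`).
#' @param min_class Binary reclassification cut for range change
#'   (default 1 = any suitable).
#' @param seed Mandatory integer seed controlling every stochastic
#'   stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            scenario = synthetic_scenario(),
                            future_scenarios = NULL,
                            current_rasters = NULL,
                            future_rasters = NULL,
                            occurrence_file = NULL,
                            geodetector = list(),
                            model = list(),
                            thresholds = c(0.1, 0.3, 0.6),
                            min_class = 1,
                            seed = 1L) {
  if (is.null(seed)) abort("`seed` is mandatory.")
  gd <- utils::modifyList(
    list(L = 5, q_threshold = 0.1, spacing_km = 10, n_permutations = 199),
    geodetector)
  md <- utils::modifyList(
    list(fc = "LQHPT", rm = 1, background_n = 10000, n_knots = 50,
         max_iter = 500, test_fraction = 0.25, output = "cloglog",
         clamp = TRUE),
    model)
  if (simulate && is.null(future_scenarios)) {
    future_scenarios <- list(
      future = list(warming_offset = scenario$warming_offset,
                    precip_factor = scenario$precip_factor))
  }
  if (!simulate) {
    for (p in c(unlist(current_rasters), unlist(future_rasters),
                occurrence_file)) {
      if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
    }
  }
  structure(
    list(simulate = simulate, scenario = scenario,
         future_scenarios = future_scenarios,
         current_rasters = current_rasters, future_rasters = future_rasters,
         occurrence_file = occurrence_file,
         geodetector = gd, model = md, thresholds = thresholds,
         min_class = min_class, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (scenario fields are passed to [synthetic_scenario()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- if (!is.null(y$scenario)) {
    sc <- y$scenario
    if (!is.null(sc$beta)) sc$beta <- unlist(sc$beta)
    if (!is.null(sc$gamma)) sc$gamma <- unlist(sc$gamma)
    do.call(synthetic_scenario, sc)
  } else synthetic_scenario()
  pipeline_config(
    simulate = y$simulate %||% TRUE,
    scenario = scenario,
    future_scenarios = y$future_scenarios,
    current_rasters = y$current_rasters,
    future_rasters = y$future_rasters,
    occurrence_file = y$occurrence_file,
    geodetector = y$geodetector %||% list(),
    model = y$model %||% list(),
    thresholds = unlist(y$thresholds %||% c(0.1, 0.3, 0.6)),
    min_class = y$min_class %||% 1,
    seed = y$seed %||% abort("Config must set `seed`.")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_stack_from_paths <- function(paths) {
  raster_stack(purrr::imap(as.list(paths), function(p, nm) {
    read_esri_ascii(p, name = if (nzchar(nm)) nm else NULL)
  }))
}

#' Run the full forecasting pipeline
#'
#' Executes every stage in order — simulate (or load) inputs, screen
#' variables with the geodetector, split presences, fit the
#' maximum-entropy model, evaluate it, project current and future
#' suitability, classify, summarize areas and percent changes, compute
#' binary range changes and centroid shifts, and run MESS diagnostics —
#' writing every artifact (rasters as `.asc`, tables as CSV, the model
#' as a plain-text lambdas file, plus a log) into `run_dir`.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param run_dir Output directory (created if needed).
#' @return A list of class `pipeline_run` with the run directory, the
#'   fitted model and the report tables; `make_report(run_dir)`
#'   reproduces the tables from the artifacts alone.
#' @export
run_pipeline <- function(config, run_dir = tempfile("rangecast_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
    say("stage %s done (%.2fs)", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  seed <- config$seed
  say("run start, seed %d, config hash %s", seed,
      substr(rlang::hash(unclass(config)), 1, 12))

  inputs <- stage("inputs", {
    if (config$simulate) {
      sc <- config$scenario
      sc$seed <- seed
      stack <- make_environment(sc)
      truth <- make_true_suitability(stack, sc)
      occ <- sample_occurrences(truth, sc$n_presences, seed = seed + 1L)
      futures <- purrr::imap(config$future_scenarios, function(fs, nm) {
        make_future_environment(stack, sc,
                                warming_offset = fs$warming_offset,
                                precip_factor = fs$precip_factor)
      })
      list(stack = stack, occurrences = occ, futures = futures)
    } else {
      list(stack = load_stack_from_paths(config$current_rasters),
           occurrences = read_occurrences(config$occurrence_file),
           futures = purrr::map(config$future_rasters,
                                load_stack_from_paths))
    }
  })
  write_occurrences(inputs$occurrences, file.path(run_dir, "occurrences.csv"))

  screening <- stage("geodetect", {
    gd <- config$geodetector
    screen_variables(inputs$stack, inputs$occurrences, L = gd$L,
                     q_threshold = gd$q_threshold,
                     spacing_km = gd$spacing_km,
                     n_permutations = gd$n_permutations, seed = seed + 2L)
  })
  write.csv(screening, file.path(run_dir, "q_table.csv"), row.names = FALSE)
  selected <- attr(screening, "selected")
  if (!length(selected)) {
    say("empty geodetector selection; keeping all variables")
    selected <- screening$variable
  }
  say("geodetector retained %d/%d variables: %s", length(selected),
      nrow(screening), paste(selected, collapse = ", "))
  sub_stack <- raster_stack(inputs$stack$layers[selected])

  md <- config$model
  split <- split_data(inputs$occurrences, test_fraction = md$test_fraction,
                      seed = seed + 3L)
  model <- stage("train", {
    bg <- sample_background(sub_stack, n = md$background_n, seed = seed + 4L)
    extr <- extract_values(sub_stack, split$train)
    dropped <- sum(!extr$valid)
    if (dropped) say("dropped %d training occurrence(s) on nodata cells",
                     dropped)
    # one record per cell
    extr <- extr[extr$valid, ]
    extr <- extr[!duplicated(extr[, c("row", "col")]), ]
    maxent_train(extr[, names(sub_stack), drop = FALSE],
                 bg[, names(sub_stack), drop = FALSE],
                 fc = md$fc, rm = md$rm, n_knots = md$n_knots,
                 max_iter = md$max_iter)
  })
  say("model: %d/%d nonzero features, gain %.4f, %s",
      sum(model$lambda != 0), length(model$lambda), model$gain,
      if (model$converged) "converged" else "not converged")
  write_maxent_model(model, file.path(run_dir, "model_lambdas.txt"))

  evaluation <- stage("evaluate", {
    test_extr <- extract_values(sub_stack, split$test)
    test_extr <- test_extr[test_extr$valid, ]
    evaluate_model(model,
                   test_presence = test_extr[, names(sub_stack),
                                             drop = FALSE],
                   jackknife = TRUE, seed = seed + 5L)
  })
  write.csv(tibble(metric = c("train_auc", "test_auc"),
                   value = c(evaluation$train_auc, evaluation$test_auc)),
            file.path(run_dir, "auc.csv"), row.names = FALSE)
  write.csv(evaluation$contribution,
            file.path(run_dir, "contribution.csv"), row.names = FALSE)
  write.csv(evaluation$importance,
            file.path(run_dir, "permutation_importance.csv"),
            row.names = FALSE)
  write.csv(evaluation$jackknife,
            file.path(run_dir, "jackknife.csv"), row.names = FALSE)

  project_one <- function(stk, label) {
    suit <- project(model, stk, clamp = md$clamp, output = md$output)
    write_esri_ascii(suit, file.path(run_dir,
                                     sprintf("suitability_%s.asc", label)))
    cls <- classify(suit, thresholds = config$thresholds)
    write_esri_ascii(cls, file.path(run_dir, sprintf("class_%s.asc", label)))
    list(suitability = suit, classified = cls,
         areas = area_summary(cls, period = label),
         binary = binarize(cls, min_class = config$min_class))
  }

  current <- stage("project_current", project_one(inputs$stack, "current"))
  futures <- stage("project_future", {
    purrr::imap(inputs$futures, function(stk, nm) project_one(stk, nm))
  })

  areas <- dplyr::bind_rows(current$areas,
                            purrr::map_dfr(futures, "areas"))
  write.csv(areas, file.path(run_dir, "areas.csv"), row.names = FALSE)

  changes <- stage("rangechange", {
    purrr::imap_dfr(futures, function(f, nm) {
      rc <- range_change(current$binary, f$binary, period = nm)
      write_esri_ascii(rc$gain, file.path(run_dir,
                                          sprintf("gain_%s.asc", nm)))
      write_esri_ascii(rc$loss, file.path(run_dir,
                                          sprintf("loss_%s.asc", nm)))
      write_esri_ascii(rc$unchanged,
                       file.path(run_dir, sprintf("unchanged_%s.asc", nm)))
      rc$summary
    })
  })
  write.csv(changes, file.path(run_dir, "range_changes.csv"),
            row.names = FALSE)

  centroids <- stage("centroids", {
    c0 <- centroid(current$binary)
    purrr::imap_dfr(futures, function(f, nm) {
      dplyr::bind_cols(tibble(period = nm),
                       centroid_shift(c0, centroid(f$binary)))
    })
  })
  write.csv(centroids, file.path(run_dir, "centroids.csv"),
            row.names = FALSE)

  mess_means <- stage("mess", {
    occ_vals <- extract_values(sub_stack, inputs$occurrences)
    occ_vals <- occ_vals[occ_vals$valid, names(sub_stack), drop = FALSE]
    purrr::imap_dfr(inputs$futures, function(stk, nm) {
      mm <- mess(occ_vals, stk)
      write_esri_ascii(mm$similarity,
                       file.path(run_dir, sprintf("mess_%s.asc", nm)))
      tibble(period = nm,
             mean_s_at_occurrences =
               mean_mess_at_points(mm, inputs$occurrences),
             extrapolation_fraction =
               mean(mm$similarity$values[
                 is.finite(mm$similarity$values)] < 0))
    })
  })
  write.csv(mess_means, file.path(run_dir, "mess_means.csv"),
            row.names = FALSE)

  say("run complete")
  writeLines(log_lines, log_path)
  structure(
    list(run_dir = run_dir, config = config, model = model,
         screening = screening, evaluation = evaluation, areas = areas,
         changes = changes, centroids = centroids,
         mess_means = mess_means),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s\n", x$run_dir))
  cat(sprintf("  train AUC %.3f, test AUC %.3f\n",
              x$evaluation$train_auc, x$evaluation$test_auc))
  print(x$areas)
  invisible(x)
}

#' Build the report tables of a completed run
#'
#' Reads the persisted artifacts of a [run_pipeline()] directory and
#' assembles the reporting analogue of the suitable-area, range-change,
#' centroid and MESS summaries. Percent changes are recomputed from the
#' area table itself, so every derived column is reproducible from the
#' persisted areas.
#'
#' @param run_dir A run directory (or a directory containing at least
#'   `areas.csv` with a `"current"` row).
#' @return A list of class `pipeline_report` with `areas`,
#'   `percent_changes`, and — when present in the run — `range_changes`,
#'   `centroids`, `mess_means`, `auc` and `q_table` tibbles.
#' @export
make_report <- function(run_dir) {
  areas_path <- file.path(run_dir, "areas.csv")
  if (!file.exists(areas_path)) {
    abort(sprintf("Incomplete run: %s not found.", areas_path))
  }
  areas <- as_tibble(read.csv(areas_path))
  cur <- areas[areas$period == "current", ]
  if (!nrow(cur)) abort("Area table has no `current` row.")
  pct <- purrr::map_dfr(which(areas$period != "current"), function(i) {
    dplyr::bind_cols(tibble(period = areas$period[i]),
                     percent_change(cur, areas[i, ]))
  })
  maybe <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) as_tibble(read.csv(p))
  }
  structure(
    list(areas = areas, percent_changes = pct,
         range_changes = maybe("range_changes.csv"),
         centroids = maybe("centroids.csv"),
         mess_means = maybe("mess_means.csv"),
         auc = maybe("auc.csv"),
         q_table = maybe("q_table.csv")),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\nAreas (10^4 km^2):\n")
  print(x$areas)
  cat("\nPercent changes vs current:\n")
  print(x$percent_changes)
  if (!is.null(x$range_changes)) {
    cat("\nRange changes (10^4 km^2):\n")
    print(x$range_changes)
  }
  if (!is.null(x$centroids)) {
    cat("\nCentroid shifts:\n")
    print(x$centroids)
  }
  if (!is.null(x$mess_means)) {
    cat("\nMESS means at occurrences:\n")
    print(x$mess_means)
  }
  invisible(x)
}
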