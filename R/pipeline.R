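#' Default pipeline configuration
#'
#' A nested list understood by [run_pipeline()]. Any element can be
#' overridden, or the whole configuration supplied as a YAML file with
#' the same keys. The default calibration grid is a compact
#' regularization-by-feature-class grid suited to desk-scale synthetic
#' runs; the full 40 x 31 grid of [tuning_grid()] can be requested
#' explicitly via `tuning$rm` / `tuning$fc`.
#'
#' @param seed Global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @return Configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    scenario = list(),                 # overrides for scenario_config()
    vars = NULL,                       # model variables (default: study stack)
    screening = list(c_min = 0.1, r_max = 0.8),
    initial_fit = list(classes = "LQ", rm = 1),
    tuning = list(rm = c(0.5, 1, 2, 4),
                  fc = c("L", "LQ", "LQH", "LQP", "LQPH"),
                  skip = FALSE),
    replicates = list(count = 10, test_percent = 25),
    classification = list(thresholds = c(0.05, 0.33, 0.66)),
    binarization = list(threshold = 0.05),
    background = list(n_max = 10000),
    n_knots = 30
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_config()].
#' @return Configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else user[[k]]
  }
  base
}

#' Average replicate predictions on a (projection) stack
#'
#' @param result A `replicate_result` from [replicate_fit()].
#' @param stack Layer stack providing the model variables (e.g. a future
#'   epoch).
#' @return Single-layer suitability `layer_stack` (cellwise mean cloglog).
#' @export
project_replicates <- function(result, stack) {
  maps <- lapply(result$models, function(m) predict(m, stack, transform = "cloglog"))
  vals <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$layers$suitability; v[is.na(v)] <- 0; v
  })) / length(maps)
  vals[!stack$mask] <- NA_real_
  layer_stack(list(suitability = vals), stack$xll, stack$yll, stack$cellsize)
}

#' Run the full synthetic-scenario analysis pipeline
#'
#' Executes, with logging and reproducible per-stage seeding: scenario
#' generation, occurrence sampling, grid thinning, background sampling,
#' the initial all-variable fit and percent contributions, two-stage
#' variable screening, AICc candidate scoring and selection (unless
#' `tuning$skip` with a fixed `rm`/`fc` is configured), the replicated
#' final model, per-epoch suitability classification and class areas,
#' and per-future-scenario change maps, centroids and migration vectors.
#' All intermediate tables and rasters plus a JSON run manifest are
#' written under `out_dir`.
#'
#' @param config Configuration list (see [default_config()]) or a path
#'   to a YAML file.
#' @param out_dir Output directory for artifacts (NULL to skip writing).
#' @param quiet Suppress stage messages.
#' @return A `pipeline_result` list with all stage outputs.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  seed <- config$seed
  t0 <- Sys.time()
  timings <- list()
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # --- scenario -------------------------------------------------------
  sc_args <- config$scenario
  sc_args$seed <- sc_args$seed %||% stage_seed(seed, "scenario")
  scenario <- generate_scenario(do.call(scenario_config, sc_args))
  future_epochs <- setdiff(scenario$epochs, "current")
  log_stage("scenario", sprintf("generated %d x %d grid, epochs: %s",
                                scenario$config$nrow, scenario$config$ncol,
                                paste(scenario$epochs, collapse = ", ")))

  # --- occurrences ----------------------------------------------------
  occ <- sample_occurrences(scenario, "current",
                            seed = stage_seed(seed, "occurrences"))
  vars <- config$vars %||% c(scenario$config$niche_vars, names(scenario$noise))
  stack <- scenario_stack(scenario, "current", vars = vars)
  occ_thin <- thin_to_grid(occ, stack)
  log_stage("thin", sprintf("%d records -> %d after grid thinning",
                            nrow(occ), nrow(occ_thin)))

  # --- background + presence values ----------------------------------
  bg <- background_sample(stack, n_max = config$background$n_max,
                          seed = stage_seed(seed, "background"))
  Xp <- presence_values(stack, occ_thin)
  log_stage("background", sprintf("%d background cells, %d presences",
                                  nrow(bg$X), nrow(Xp)))

  # --- initial fit + screening ----------------------------------------
  initial <- fit_maxent(Xp, bg$X, classes = config$initial_fit$classes,
                        rm = config$initial_fit$rm, n_knots = config$n_knots)
  contrib <- percent_contribution(initial)
  selection <- select_variables(stack, contrib,
                                c_min = config$screening$c_min,
                                r_max = config$screening$r_max)
  kept <- selection$kept
  log_stage("screen", sprintf("kept %d/%d variables: %s",
                              length(kept), length(vars),
                              paste(kept, collapse = ", ")))
  stack_kept <- select_layers(stack, kept)
  Xp_kept <- Xp[, kept, drop = FALSE]
  Xb_kept <- bg$X[, kept, drop = FALSE]

  # --- tuning ---------------------------------------------------------
  if (isTRUE(config$tuning$skip)) {
    if (is.null(config$tuning$rm) || is.null(config$tuning$fc) ||
        length(config$tuning$rm) != 1 || length(config$tuning$fc) != 1) {
      stop("tuning$skip requires a single fixed rm and fc")
    }
    scored <- NULL
    best <- data.frame(fc = config$tuning$fc, rm = config$tuning$rm,
                       stringsAsFactors = FALSE)
    log_stage("tune", sprintf("skipped; fixed fc=%s rm=%g", best$fc, best$rm))
  } else {
    grid <- tuning_grid(rm = config$tuning$rm, fc = config$tuning$fc)
    scored <- score_candidates(candidate_grid(grid), Xp_kept, Xb_kept,
                               n_knots = config$n_knots)
    best <- select_best(scored)
    log_stage("tune", sprintf("%d candidates; best fc=%s rm=%g (k=%d, AICc=%.2f)",
                              nrow(scored), best$fc, best$rm, best$k, best$AICc))
  }

  # --- replicated final model -----------------------------------------
  repl <- replicate_fit(stack_kept, Xp_kept, Xb_kept,
                        fc = best$fc, rm = best$rm,
                        reps = config$replicates$count,
                        test_percent = config$replicates$test_percent,
                        seed = stage_seed(seed, "replicates"),
                        n_knots = config$n_knots)
  log_stage("fit", sprintf("%d replicates; mean test AUC %.3f",
                           repl$reps, repl$summary$mean[repl$summary$metric == "test_auc"]))

  # --- per-epoch suitability + classification -------------------------
  suit <- list(current = repl$mean_map)
  for (ep in future_epochs) {
    suit[[ep]] <- project_replicates(repl, scenario_stack(scenario, ep, vars = kept))
  }
  classified <- lapply(suit, classify, thresholds = config$classification$thresholds)
  areas <- lapply(classified, class_areas)
  log_stage("classify", sprintf("current class areas (1e4 km2): %s",
                                paste(sprintf("%s=%.2f", names(areas$current),
                                              areas$current), collapse = " ")))

  # --- range dynamics --------------------------------------------------
  thr <- config$binarization$threshold
  changes <- list(); track <- list()
  cen0 <- centroid(suit$current, thr)
  track[["current"]] <- data.frame(epoch = "current", lat = cen0$lat,
                                   lon = cen0$lon, distance_km = 0,
                                   bearing_deg = NA_real_, label = "",
                                   stringsAsFactors = FALSE)
  for (ep in future_epochs) {
    changes[[ep]] <- change_map(suit$current, suit[[ep]], threshold = thr)
    cen <- centroid(suit[[ep]], thr)
    mig <- migration(cen0, cen)
    track[[ep]] <- data.frame(epoch = ep, lat = cen$lat, lon = cen$lon,
                              distance_km = mig$distance_km,
                              bearing_deg = mig$bearing_deg,
                              label = mig$label, stringsAsFactors = FALSE)
    log_stage("change", sprintf("%s: centroid moved %.1f km %s", ep,
                                mig$distance_km, mig$label))
  }
  track <- do.call(rbind, track)

  result <- structure(
    list(config = config, scenario = scenario, occurrences = occ_thin,
         background = bg, selection = selection, contributions = contrib,
         candidates = scored, best = best, replicates = repl,
         suitability = suit, classified = classified, areas = areas,
         changes = changes, centroid_track = track, timings = timings),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

# Write every pipeline artifact plus a machine-readable manifest.
write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  # manifest records paths relative to out_dir so runs are comparable
  add <- function(p) paths <<- c(paths, sub(paste0(out_dir, .Platform$file.sep),
                                            "", p, fixed = TRUE))

  add(write_occurrences(result$occurrences,
                        file.path(out_dir, "occurrences_thinned.csv")))
  add(write_selection(result$selection, out_dir))
  if (!is.null(result$candidates)) {
    p <- file.path(out_dir, "candidates.csv")
    utils::write.csv(as.data.frame(result$candidates), p, row.names = FALSE)
    add(p)
  }
  p <- file.path(out_dir, "evaluation_summary.csv")
  utils::write.csv(result$replicates$summary, p, row.names = FALSE)
  add(p)
  for (ep in names(result$suitability)) {
    sub <- file.path(out_dir, ep)
    s <- result$suitability[[ep]]
    names(s$layers) <- "suitability"
    add(write_asc(s, sub))
    add(write_classified(result$classified[[ep]], sub))
  }
  for (ep in names(result$changes)) {
    add(write_asc(result$changes[[ep]], file.path(out_dir, ep), vars = "change",
                  digits = 1))
  }
  add(write_centroid_track(result$centroid_track,
                           file.path(out_dir, "centroid_track.csv")))
  best_model <- result$replicates$models[[1]]
  add(write_maxent_model(best_model, file.path(out_dir, "model_replicate1.txt")))

  manifest <- list(
    package = "nichemax",
    version = as.character(utils::packageVersion("nichemax")),
    seed = result$config$seed,
    config = result$config,
    best = as.list(result$best),
    artifacts = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
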