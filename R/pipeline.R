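#' Default pipeline configuration
#'
#' Returns the fully populated default configuration: the bundled synthetic
#' scenario as input, 5 km thinning, 0.7 collinearity threshold, the
#' 1000-or-n pseudo-absence rule, five random 70/30 validation splits,
#' TSS >= 0.7 / AUC >= 0.8 gates, and null-model checking. Every field can
#' be overridden through `...` or by the structured YAML file read by
#' [validate_config()].
#'
#' @param ... named overrides of top-level fields (nested lists are merged
#'   shallowly).
#' @return a `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(mode = "simulate", n_occurrences = 500L, cell_size = 0.25,
                 occurrences = NULL, regions = NULL),
    populations = list(
      list(name = "native", region = "source_continent", role = "native"),
      list(name = "introduced", region = "target_continent",
           role = "introduced")),
    target_region = "target_continent",
    comparisons = list(list(introduced = "introduced", native = "native")),
    thinning = list(radius_km = 5, enabled = TRUE),
    selection = list(threshold = 0.7, replicates = 3L,
                     preliminary_algorithm = "rf"),
    model = list(algorithms = c("rf", "maxent", "gam"), train_frac = 0.7,
                 repeats = 5L, gates = c(tss_min = 0.7, auc_min = 0.8),
                 combination = "mean"),
    null_models = list(enabled = TRUE, replicates = 10L,
                       algorithm = "maxent", alpha = 0.05),
    seed = 1L,
    output_dir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (sub in names(dots[[nm]])) cfg[[nm]][[sub]] <- dots[[nm]][[sub]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a configuration list, merges it over the
#' defaults, and checks every constraint, collecting *all* violations into
#' one error rather than stopping at the first.
#'
#' @param config YAML path or list of overrides.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invrisk("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- do.call(default_config, config)
  errors <- character()
  add <- function(msg) errors <<- c(errors, msg)
  tf <- cfg$model$train_frac
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    add("model.train_frac must lie strictly between 0 and 1")
  }
  if (cfg$thinning$radius_km <= 0) add("thinning.radius_km must be positive")
  th <- cfg$selection$threshold
  if (!is.numeric(th) || th < 0 || th > 1) {
    add("selection.threshold must lie in [0, 1]")
  }
  g <- cfg$model$gates
  if (is.null(g[["tss_min"]]) || g[["tss_min"]] < -1 || g[["tss_min"]] > 1) {
    add("model.gates['tss_min'] must lie in [-1, 1]")
  }
  if (is.null(g[["auc_min"]]) || g[["auc_min"]] < 0 || g[["auc_min"]] > 1) {
    add("model.gates['auc_min'] must lie in [0, 1]")
  }
  if (length(cfg$model$algorithms) < 2) {
    add("model.algorithms must name at least two algorithm families")
  } else if (!all(cfg$model$algorithms %in% sdm_algorithms())) {
    add(paste0("unknown algorithm(s): ",
               paste(setdiff(cfg$model$algorithms, sdm_algorithms()),
                     collapse = ", ")))
  }
  if (cfg$model$repeats < 1) add("model.repeats must be >= 1")
  if (cfg$null_models$enabled && cfg$null_models$replicates < 2) {
    add("null_models.replicates must be >= 2")
  }
  if (!cfg$input$mode %in% c("simulate", "files")) {
    add("input.mode must be 'simulate' or 'files'")
  }
  if (identical(cfg$input$mode, "files")) {
    if (is.null(cfg$input$occurrences)) {
      add("input.occurrences (CSV path) required when input.mode = 'files'")
    } else if (!file.exists(cfg$input$occurrences)) {
      add(paste0("occurrence file not found: ", cfg$input$occurrences))
    }
    if (is.null(cfg$input$regions)) {
      add("input.regions required when input.mode = 'files'")
    } else {
      for (rn in names(cfg$input$regions)) {
        for (pn in names(cfg$input$regions[[rn]]$predictors)) {
          f <- cfg$input$regions[[rn]]$predictors[[pn]]$file
          if (!file.exists(f)) {
            add(sprintf("raster for %s/%s not found: %s", rn, pn, f))
          }
        }
      }
    }
  }
  pop_names <- vapply(cfg$populations, `[[`, character(1), "name")
  for (cmp in cfg$comparisons) {
    for (side in c("introduced", "native")) {
      if (!cmp[[side]] %in% pop_names) {
        add(sprintf("comparison names unknown population '%s'", cmp[[side]]))
      }
    }
  }
  if (length(errors)) {
    stop_invrisk("invalid pipeline configuration:\n  - ",
                 paste(errors, collapse = "\n  - "))
  }
  cfg
}

load_pipeline_inputs <- function(cfg) {
  if (identical(cfg$input$mode, "simulate")) {
    scen <- synthetic_scenario(seed = spawn_seed(cfg$seed, 11),
                               n_occurrences = cfg$input$n_occurrences,
                               cell_size = cfg$input$cell_size)
    list(stacks = scen$stacks, occurrences = scen$occurrences,
         scenario = scen)
  } else {
    occ <- read_occurrences(cfg$input$occurrences)
    stacks <- lapply(cfg$input$regions, function(rg) {
      grids <- lapply(rg$predictors, function(p) read_raster(p$file))
      predictor_stack(grids, vapply(rg$predictors, `[[`, character(1),
                                    "category"))
    })
    list(stacks = stacks, occurrences = occ, scenario = NULL)
  }
}

#' Run the full invasion-risk pipeline
#'
#' Orchestrates all stages for every configured population: spatial
#' thinning, pseudo-absence generation, predictor importance and
#' collinearity pruning, gated ensemble fitting, optional null-model
#' checking, projection of every model onto the target region's stack,
#' MSS binarization (each population using the threshold calibrated on its
#' own data), and expansion/stabilization/unfilling decomposition with RR
#' and IRS for every configured introduced-vs-native pair. All randomness
#' derives from the single master seed, so identical configurations yield
#' identical reports.
#'
#' @param config a `pipeline_config`, a list of overrides, or a YAML path
#'   (passed through [validate_config()]).
#' @return a `run_report` list: per-stage record counts and seeds, retained
#'   predictors, candidate-member metrics, null comparisons, thresholds,
#'   projected suitability grids, binary ranges, and one `range_shift`
#'   result per comparison.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  inputs <- load_pipeline_inputs(cfg)
  target_stack <- inputs$stacks[[cfg$target_region]]
  if (is.null(target_stack)) {
    stop_invrisk("target region '", cfg$target_region, "' has no stack")
  }
  report <- list(config = cfg, seed = cfg$seed, stages = list(),
                 populations = list(), comparisons = list(),
                 scenario = inputs$scenario,
                 version = as.character(utils::packageVersion("invrisk")))
  occ <- inputs$occurrences
  report$stages$load <- c(n_records = nrow(occ),
                          n_duplicates = attr(occ, "n_duplicates") %||% 0L)
  if (isTRUE(cfg$thinning$enabled)) {
    thin <- thin_occurrences(occ, radius_km = cfg$thinning$radius_km,
                             seed = spawn_seed(cfg$seed, 21))
    report$stages$thinning <- c(n_before = nrow(occ),
                                n_after = nrow(thin$kept),
                                n_removed = nrow(thin$report))
    occ <- thin$kept
  }
  pi <- 0L
  for (pop in cfg$populations) {
    pi <- pi + 1L
    pop_occ <- occ[occ$species == pop$name, , drop = FALSE]
    stack <- inputs$stacks[[pop$region]]
    if (is.null(stack)) {
      stop_invrisk("population '", pop$name, "': no stack for region '",
                   pop$region, "'")
    }
    pseed <- spawn_seed(cfg$seed, 30 + pi)
    ex <- extract_values(pop_occ, stack)
    pa <- generate_pseudo_absences(stack, ex$points,
                                   seed = spawn_seed(pseed, 1))
    Xa <- rbind(ex$X, extract_values(pa, stack)$X)
    ya <- c(rep(1L, nrow(ex$X)), rep(0L, nrow(Xa) - nrow(ex$X)))
    prelim <- fit_member(cfg$selection$preliminary_algorithm, Xa, ya,
                         seed = spawn_seed(pseed, 2))
    imp <- permutation_importance(prelim, Xa,
                                  replicates = cfg$selection$replicates,
                                  seed = spawn_seed(pseed, 3))
    sel <- select_predictors(Xa, imp, threshold = cfg$selection$threshold)
    Xr <- Xa[, sel$retained, drop = FALSE]
    ens <- ensemble_sdm(Xr, ya, algorithms = cfg$model$algorithms,
                        train_frac = cfg$model$train_frac,
                        repeats = cfg$model$repeats,
                        gates = cfg$model$gates,
                        combination = cfg$model$combination,
                        seed = spawn_seed(pseed, 4))
    nullcmp <- NULL
    if (isTRUE(cfg$null_models$enabled)) {
      nulls <- build_null_models(stack, ex$points,
                                 algorithm = cfg$null_models$algorithm,
                                 replicates = cfg$null_models$replicates,
                                 seed = spawn_seed(pseed, 5))
      nullcmp <- compare_real_vs_null(ens$evals[ens$evals$passed, ], nulls,
                                      alpha = cfg$null_models$alpha)
    }
    projection <- predict_raster(ens, target_stack)
    range_map <- binarize(projection, ens$ensemble_mss_threshold,
                          label = pop$name)
    report$populations[[pop$name]] <- list(
      role = pop$role, region = pop$region, seed = pseed,
      n_occurrences = nrow(ex$points),
      extraction = ex$report,
      n_pseudo_absences = nrow(Xa) - nrow(ex$X),
      importance = imp, selection = sel,
      retained_predictors = sel$retained,
      model = ens, evals = ens$evals,
      mss_threshold = ens$ensemble_mss_threshold,
      null_comparison = nullcmp,
      projection = projection, range_map = range_map)
  }
  for (cmp in cfg$comparisons) {
    res <- range_shift(report$populations[[cmp$introduced]]$range_map,
                       report$populations[[cmp$native]]$range_map)
    report$comparisons[[paste(cmp$introduced, "vs", cmp$native)]] <- res
  }
  class(report) <- "run_report"
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("invrisk pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$stages$thinning)) {
    cat(sprintf("  thinning: %d -> %d records\n",
                x$stages$thinning[["n_before"]],
                x$stages$thinning[["n_after"]]))
  }
  for (nm in names(x$populations)) {
    p <- x$populations[[nm]]
    cat(sprintf("  %s (%s, %s): %d occ, %d predictors retained, %d members, MSS %.3f\n",
                nm, p$role, p$region, p$n_occurrences,
                length(p$retained_predictors), length(p$model$members),
                p$mss_threshold))
  }
  for (nm in names(x$comparisons)) {
    cat(sprintf("  comparison %s: RR(NR/IR) %.3g, IRS %.3g (variant %.3g)\n",
                nm, x$comparisons[[nm]]$RR_native_over_introduced,
                x$comparisons[[nm]]$IRS,
                x$comparisons[[nm]]$IRS_reported_variant))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits the tabular parts of the report as CSV, the projected suitability
#' and binary range maps as ASCII grids, and a JSON summary of thresholds,
#' metrics, and range-shift indices.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = report$seed, version = report$version,
                  stages = report$stages, populations = list(),
                  comparisons = list())
  for (nm in names(report$populations)) {
    p <- report$populations[[nm]]
    utils::write.csv(p$evals, file.path(dir, paste0(nm, "_members.csv")),
                     row.names = FALSE)
    utils::write.csv(p$importance,
                     file.path(dir, paste0(nm, "_importance.csv")),
                     row.names = FALSE)
    write_raster(p$projection, file.path(dir, paste0(nm, "_suitability.asc")))
    rg <- p$range_map
    write_raster(raster_grid(ifelse(rg$nodata_mask, NA_real_,
                                    rg$presence * 1),
                             rg$template$origin_lon, rg$template$origin_lat,
                             rg$template$cell_size),
                 file.path(dir, paste0(nm, "_range.asc")))
    summary$populations[[nm]] <- list(
      n_occurrences = p$n_occurrences,
      retained_predictors = p$retained_predictors,
      mss_threshold = p$mss_threshold,
      seed = p$seed,
      null_p_auc = if (!is.null(p$null_comparison)) p$null_comparison$p_auc,
      null_p_tss = if (!is.null(p$null_comparison)) p$null_comparison$p_tss)
  }
  rows <- lapply(names(report$comparisons), function(nm) {
    r <- report$comparisons[[nm]]
    data.frame(comparison = nm, expansion_km2 = r$area_expansion,
               stabilization_km2 = r$area_stabilization,
               unfilling_km2 = r$area_unfilling, IR_km2 = r$IR,
               NR_km2 = r$NR, RR = r$RR,
               RR_native_over_introduced = r$RR_native_over_introduced,
               IRS = r$IRS, IRS_reported_variant = r$IRS_reported_variant,
               excluded_cells = r$excluded_cells,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) {
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(dir, "range_shift.csv"),
                     row.names = FALSE)
    summary$comparisons <- df
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
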