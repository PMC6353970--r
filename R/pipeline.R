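#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates simulate -> dpca -> decode -> distance -> compare-variance
#' over one or more task designs and writes every stage's outputs as plain
#' text (CSV/JSON) into an output directory, together with a machine-readable
#' `summary.json` and a run log recording seeds, dimensions and iteration
#' counts. The run is byte-reproducible for a fixed configuration.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{design}{either a [task_design()] object or a list of
#'       [task_design()] arguments.}
#'     \item{input}{optional path to a population CSV; when absent,
#'       `synthetic` must give [effect_spec()] arguments plus `n_neurons`.}
#'     \item{stages}{character subset of
#'       `c("simulate", "dpca", "decode", "distance", "compare_variance")`
#'       (default: all that are applicable).}
#'     \item{seed}{integer master seed (per-stage seeds derive from it).}
#'     \item{decode}{optional list of [decode_timecourse()] /
#'       [significance_intervals()] settings.}
#'     \item{distance}{optional list of [bootstrap_bands()] settings.}
#'     \item{parameter_levels}{optional pair for the symmetric 2 x 2
#'       distance analysis.}
#'   }
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary list (also written to
#'   `file.path(out_dir, "summary.json")`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  design <- if (inherits(config$design, "task_design")) config$design
            else do.call(task_design, config$design)
  all_stages <- c("simulate", "dpca", "decode", "distance",
                  "compare_variance")
  stages <- if (is.null(config$stages)) all_stages
            else match.arg(config$stages, all_stages, several.ok = TRUE)
  log_lines <- c(sprintf("run_pipeline seed=%d design=%s S=%d V=%d T=%d",
                         seed, design$name,
                         length(design$parameter_levels),
                         length(design$visual_levels), design$n_bins))
  summary <- list(design = design$name, seed = seed)

  stage_fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # --- input: simulate or load -------------------------------------------
  if ("simulate" %in% stages && is.null(config$input)) {
    rec <- tryCatch({
      syn <- config$synthetic
      n_neurons <- if (is.null(syn$n_neurons)) 100L else syn$n_neurons
      syn$n_neurons <- NULL
      if (!is.null(syn$target_fractions))
        syn$target_fractions <- unlist(syn$target_fractions)
      if (is.null(syn$seed)) syn$seed <- seed
      spec <- do.call(effect_spec, as.list(syn))
      simulate_population(design, n_neurons, spec)
    }, error = function(e) stage_fail("simulate", e))
    write_population_csv(rec, file.path(out_dir, "population.csv"))
    write_design_json(design, file.path(out_dir, "design.json"))
    planted <- attr(rec, "planted")
    jsonlite::write_json(
      list(seed = planted$spec$seed,
           n_neurons = rec$n_neurons,
           baseline_hz = planted$spec$baseline_hz,
           noise = planted$spec$noise,
           planted_fractions = as.list(planted$fractions)),
      file.path(out_dir, "simulate_sidecar.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$n_neurons <- rec$n_neurons
    summary$planted_fractions <- as.list(planted$fractions)
    log_lines <- c(log_lines, sprintf("simulate N=%d trials=%d-%d",
                                      rec$n_neurons, rec$trial_range[1],
                                      rec$trial_range[2]))
  } else {
    abort_if(is.null(config$input), "no input CSV and 'simulate' not staged")
    rec <- tryCatch(read_population_csv(config$input, design),
                    error = function(e) stage_fail("load", e))
  }

  # --- dpca ---------------------------------------------------------------
  fit <- NULL
  if ("dpca" %in% stages) {
    fit <- tryCatch(dpca(rec, q = if (is.null(config$q)) 10L else config$q),
                    error = function(e) stage_fail("dpca", e))
    split <- explained_variance_split(fit)
    comp <- fit$components
    utils::write.csv(
      data.frame(component = comp$component,
                 marginalization = comp$marginalization,
                 variance_pct = 100 * comp$variance_fraction),
      file.path(out_dir, "dpca_components.csv"), row.names = FALSE)
    d <- dim(fit$projections)
    proj_df <- data.frame(
      component = rep(seq_len(d[1]), times = d[2] * d[3] * d[4]),
      parameter_level = rep(rep(design$parameter_levels, each = d[1]),
                            times = d[3] * d[4]),
      visual_level = rep(rep(design$visual_levels, each = d[1] * d[2]),
                         times = d[4]),
      bin = rep(seq_len(d[4]) - 1L, each = d[1] * d[2] * d[3]),
      value = as.vector(fit$projections))
    utils::write.csv(proj_df, file.path(out_dir, "dpca_projections.csv"),
                     row.names = FALSE)
    summary$variance_split_pct <- as.list(round(as.numeric(split), 6) |>
                                            stats::setNames(names(split)))
    summary$cumvar_dpca_at_q <- fit$cumvar_dpca[length(fit$cumvar_dpca)]
    log_lines <- c(log_lines,
                   sprintf("dpca lambda=%.4g q=%s", fit$lambda,
                           paste(fit$q, collapse = ",")))
  }

  # --- decode -------------------------------------------------------------
  if ("decode" %in% stages) {
    dc <- config$decode
    res <- tryCatch({
      decode_timecourse(
        rec,
        target = if (is.null(dc$target)) "parameter" else dc$target,
        n_iterations = if (is.null(dc$n_iterations)) 100L else dc$n_iterations,
        q_axes = if (is.null(dc$q_axes)) 1L else dc$q_axes,
        seed = seed + 1L)
    }, error = function(e) stage_fail("decode", e))
    sig <- significance_intervals(
      res,
      n_shuffles = if (is.null(dc$n_shuffles)) 100L else dc$n_shuffles,
      alpha = if (is.null(dc$alpha)) 0.05 else dc$alpha,
      min_consecutive = if (is.null(dc$min_consecutive)) 10L
                        else dc$min_consecutive,
      seed = seed + 2L)
    utils::write.csv(
      data.frame(bin = seq_along(res$accuracy) - 1L,
                 accuracy = res$accuracy,
                 null_q95 = sig$null_quantile,
                 significant = sig$significant),
      file.path(out_dir, "decode_timecourse.csv"), row.names = FALSE)
    jsonlite::write_json(
      apply(sig$intervals, 1, function(r) list(start_bin = r[1] - 1L,
                                               end_bin = r[2] - 1L)),
      file.path(out_dir, "decode_intervals.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$decode <- list(
      mean_accuracy = mean(res$accuracy),
      max_accuracy = max(res$accuracy),
      chance = res$chance,
      n_significant_bins = sum(sig$significant),
      intervals = nrow(sig$intervals))
    log_lines <- c(log_lines,
                   sprintf("decode iters=%d shuffles=%d", res$n_iterations,
                           sig$n_shuffles))
  }

  # --- distance -----------------------------------------------------------
  if ("distance" %in% stages) {
    ds <- config$distance
    bands <- tryCatch({
      bootstrap_bands(
        rec,
        parameter_levels = config$parameter_levels,
        n_bootstrap = if (is.null(ds$n_bootstrap)) 100L else ds$n_bootstrap,
        q = if (is.null(ds$q)) 5L else ds$q,
        min_consecutive = if (is.null(ds$min_consecutive)) 10L
                          else ds$min_consecutive,
        seed = seed + 3L)
    }, error = function(e) stage_fail("distance", e))
    utils::write.csv(
      data.frame(
        bin = rep(seq_along(bands$parameter_curve) - 1L, 2),
        curve = rep(c("parameter", "visual"),
                    each = length(bands$parameter_curve)),
        value = c(bands$parameter_curve, bands$visual_curve),
        ci_lo = c(bands$ci_lower["parameter", ], bands$ci_lower["visual", ]),
        ci_hi = c(bands$ci_upper["parameter", ], bands$ci_upper["visual", ])),
      file.path(out_dir, "distance_curves.csv"), row.names = FALSE)
    summary$distance <- list(
      mean_parameter = mean(bands$parameter_curve),
      mean_visual = mean(bands$visual_curve),
      separation_intervals = nrow(bands$separation_intervals))
    log_lines <- c(log_lines, sprintf("distance bootstrap=%d",
                                      bands$n_bootstrap))
  }

  # --- compare-variance ---------------------------------------------------
  if ("compare_variance" %in% stages && !is.null(fit)) {
    split <- explained_variance_split(fit)
    cmp <- chi2_compare(c(unname(split["visual"]), unname(split["parameter"])),
                        labels = c("visual", "parameter"))
    utils::write.csv(
      data.frame(groups = paste(cmp$labels, collapse = " vs "),
                 chi2 = cmp$chi2, dof = cmp$dof, p_value = cmp$p_value,
                 significant = cmp$significant),
      file.path(out_dir, "variance_comparison.csv"), row.names = FALSE)
    summary$variance_comparison <- list(chi2 = cmp$chi2, dof = cmp$dof,
                                        p_value = cmp$p_value,
                                        significant = cmp$significant)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
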