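#' Restrict a time course to a subset of variables
#'
#' @param tc An [ss_timecourse()].
#' @param variables Character vector of variable names to keep.
#' @return An [ss_timecourse()] over the selected variables.
#' @export
subset_timecourse <- function(tc, variables) {
  stopifnot(inherits(tc, "ss_timecourse"), all(variables %in% tc$variables))
  idx <- match(variables, tc$variables)
  ss_timecourse(tc$values[idx, , , drop = FALSE], tc$times,
                variables, tc$conditions)
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end analysis run needs: the data, the
#' variable-selection rule, the structural masks, the optimizer settings, the
#' sensitivity perturbation, an output directory and the master seed recorded
#' in all outputs.
#'
#' @param data An [ss_timecourse()] or path to a long-format CSV.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-condition fits derive sub-seeds from it.
#' @param ranking Optional `"ssys_corr_ranking"` (or path to a `variable,r,p`
#'   CSV) used to select variables before fitting.
#' @param select_k Number of top-|r| variables to keep (requires `ranking`).
#' @param mask_g,mask_h Structural masks passed to [ssys_fit()] (or paths to
#'   model JSON files whose masks are reused).
#' @param control An [ssys_control()].
#' @param sensitivity_fraction Perturbation used by [sensitivity_analysis()].
#' @param x0 Initial-state policy for candidate integration.
#' @return A list of class `"ssys_pipeline_config"`.
#' @export
pipeline_config <- function(data, out_dir, seed = 1L, ranking = NULL,
                            select_k = NULL, mask_g = NULL, mask_h = NULL,
                            control = ssys_control(),
                            sensitivity_fraction = 0.05,
                            x0 = "first-observation") {
  structure(list(data = data, out_dir = out_dir, seed = as.integer(seed),
                 ranking = ranking, select_k = select_k,
                 mask_g = mask_g, mask_h = mask_h, control = control,
                 sensitivity_fraction = sensitivity_fraction, x0 = x0),
            class = "ssys_pipeline_config")
}

#' Run the end-to-end network-analysis pipeline
#'
#' Executes the full workflow: (optional) correlation-based variable
#' selection, an independent S-system fit per experimental condition,
#' perturbation sensitivity analysis of each fitted network, and — when two
#' or more conditions are present — an edge-by-edge comparison of the first
#' two fitted networks with sign-reversal flags. All numeric outputs are
#' written under `config$out_dir` together with a manifest (configuration,
#' seed, package and R versions) that fully determines them: rerunning with
#' the same manifest reproduces every number.
#'
#' Outputs: `model_<condition>.json`, `sensitivity_<condition>.csv`,
#' `network_<condition>.sif` / `.graphml`, `fit_report.csv`,
#' `comparison.csv` (when applicable), and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ssys_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tc <- config$data
  if (is.character(tc)) tc <- read_timecourse(tc)
  stopifnot(inherits(tc, "ss_timecourse"))

  # --- selection stage ---
  if (!is.null(config$select_k)) {
    if (is.null(config$ranking)) {
      stop("selection stage: 'select_k' requires a 'ranking'")
    }
    ranking <- config$ranking
    if (is.character(ranking)) {
      ranking <- corr_ranking(read.csv(ranking, stringsAsFactors = FALSE))
    }
    keep <- select_top(ranking, k = config$select_k)
    keep <- keep[keep %in% tc$variables]
    tc <- subset_timecourse(tc, keep)
  }

  mask_g <- resolve_mask(config$mask_g, "mask_g")
  mask_h <- resolve_mask(config$mask_h, "mask_h")

  set.seed(config$seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L,
                           length(tc$conditions))

  fits <- list()
  sens <- list()
  report <- data.frame(condition = character(0), error_percent = numeric(0),
                       seed = integer(0), stringsAsFactors = FALSE)
  for (d in seq_along(tc$conditions)) {
    cond <- tc$conditions[d]
    tag <- gsub("[^A-Za-z0-9]+", "_", cond)
    one <- ss_timecourse(tc$values[, , d, drop = FALSE], tc$times,
                         tc$variables, cond)
    fit <- ssys_fit(one, mask_g = mask_g, mask_h = mask_h,
                    control = config$control, seed = cond_seeds[d],
                    x0 = config$x0)
    fits[[cond]] <- fit
    write_ssys_model(fit$model,
                     file.path(config$out_dir, paste0("model_", tag, ".json")))
    sr <- sensitivity_analysis(fit$model, one$values[, 1, 1], one$times,
                               fraction = config$sensitivity_fraction)
    sens[[cond]] <- sr
    write_sensitivity(sr, file.path(config$out_dir,
                                    paste0("sensitivity_", tag, ".csv")))
    export_network(fit$model,
                   file.path(config$out_dir, paste0("network_", tag, ".sif")))
    export_network(fit$model,
                   file.path(config$out_dir, paste0("network_", tag, ".graphml")),
                   report = sr)
    report <- rbind(report,
                    data.frame(condition = cond,
                               error_percent = fit$score$total_error_percent,
                               seed = cond_seeds[d], stringsAsFactors = FALSE))
  }
  write.csv(report, file.path(config$out_dir, "fit_report.csv"),
            row.names = FALSE, quote = FALSE)

  comparison <- NULL
  if (length(fits) >= 2) {
    comparison <- compare_networks(fits[[1]]$model, fits[[2]]$model)
    write.csv(as.data.frame(comparison),
              file.path(config$out_dir, "comparison.csv"),
              row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    conditions = tc$conditions,
    condition_seeds = cond_seeds,
    variables = tc$variables,
    select_k = config$select_k,
    sensitivity_fraction = config$sensitivity_fraction,
    control = unclass(config$control),
    package_version = as.character(packageVersion("ssysnet")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits = fits, sensitivity = sens, comparison = comparison,
                 report = report, out_dir = config$out_dir))
}

resolve_mask <- function(mask, which) {
  if (is.null(mask)) return(NULL)
  if (is.character(mask)) {
    model <- read_ssys_model(mask)
    return(model[[which]])
  }
  mask
}
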