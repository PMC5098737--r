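# Umbrella pipeline: simulate -> fit-dwi -> fit-dce -> stats -> report.

.config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    protocol = list(),          # overrides for make_protocol()
    phantom = list(),           # overrides for make_phantom() compartments
    cohort = list(n_per_group = 5L, include_native = FALSE),
    fit = list(b_threshold = 200, reg = 1e-6, baseline_frames = 10L,
               dwi_noise_sd = 0, dce_noise_sd = 0),
    stats = list(alpha = 0.05, bonferroni_m = NULL, welch = FALSE),
    log_level = "info",
    render = FALSE
  )
}

#' Validate a pipeline run configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs. The
#' configuration may be a named list or the path to a YAML file with the
#' same structure (`seed`, `out_dir`, `protocol`, `phantom`, `cohort`,
#' `fit`, `stats`, `log_level`, `render`).
#'
#' @param config Named list or YAML path.
#' @return Validated config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_renalmr(sprintf("config file not found: '%s'", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_renalmr("config schema error: unknown keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in c("cohort", "fit", "stats")) {
    bad <- setdiff(names(config[[sec]] %||% list()), names(defaults[[sec]]))
    if (length(bad) > 0) {
      stop_renalmr(sprintf("config schema error: unknown keys in %s: %s",
                           sec, paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config)
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1,
              "config schema error: seed must be a single number")
  cfg
}

log_stage <- function(cfg, stage, t0, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  msg <- paste(..., collapse = " ")
  message(sprintf("[renalmr] %-9s %5.1fs %s", stage,
                  as.numeric(proc.time()[3] - t0), msg))
}

#' Run the full quantification pipeline on synthetic data
#'
#' Executes, in order: cohort + phantom simulation, diffusion fitting
#' (ADC and segmented IVIM, whole-kidney ROI excluding the pelvis), DCE
#' deconvolution (ROI mode), and the statistics stage (per-group summaries,
#' Bonferroni-corrected t-tests of each allograft group against the
#' syngeneic controls, and the MR-histology correlations). Writes a single
#' JSON report plus the cohort CSV (and optionally NIfTI series and PNG
#' maps) to `out_dir` when one is configured.
#'
#' @param config See [validate_config()].
#' @return The report as a named list (invisibly written to
#'   `out_dir/report.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  t0 <- proc.time()[3]
  protocol <- do.call(make_protocol, cfg$protocol)
  seed <- as.integer(cfg$seed)

  # --- simulate -----------------------------------------------------------
  cohort <- simulate_cohort(
    default_groups(n = cfg$cohort$n_per_group %||% 5L,
                   include_native = isTRUE(cfg$cohort$include_native)),
    seed = seed
  )
  phantom <- do.call(make_phantom, c(list(protocol = protocol), cfg$phantom))
  dwi <- simulate_dwi(phantom, noise_sd = cfg$fit$dwi_noise_sd, seed = seed + 1L)
  dce <- simulate_dce(phantom, noise_sd = cfg$fit$dce_noise_sd, seed = seed + 2L,
                      baseline_frames = cfg$fit$baseline_frames)
  log_stage(cfg, "simulate", t0, nrow(cohort), "animals;",
            sum(phantom$kidney_mask), "graft voxels")

  # --- fit-dwi ------------------------------------------------------------
  adc <- fit_adc(dwi, mask = phantom$kidney_mask)
  ivim <- fit_ivim_segmented(dwi, b_threshold = cfg$fit$b_threshold,
                             mask = phantom$kidney_mask)
  dwi_summary <- rbind(roi_summary(adc, phantom$kidney_mask, "graft"),
                       roi_summary(ivim, phantom$kidney_mask, "graft"))
  log_stage(cfg, "fit-dwi", t0, sprintf("graft ADC %.3f x10^-3 mm^2/s",
                                        dwi_summary$mean[dwi_summary$metric == "adc"]))

  # --- fit-dce ------------------------------------------------------------
  dce_fit <- fit_dce(dce, mask = phantom$kidney_mask,
                     aif_mask = phantom$artery_mask, reg = cfg$fit$reg,
                     roi_name = "graft")
  log_stage(cfg, "fit-dce", t0, sprintf("graft plasma flow %.2f ml/100ml/min",
                                        dce_fit$result$fp))

  # --- stats --------------------------------------------------------------
  groups <- unique(cohort$group)
  group_means <- do.call(rbind, lapply(groups, function(g) {
    sub <- cohort[cohort$group == g, ]
    data.frame(group = g,
               adc_mean = mean(sub$adc), adc_sd = sd0(sub$adc),
               plasma_flow_mean = mean(sub$plasma_flow),
               plasma_flow_sd = sd0(sub$plasma_flow),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  ref <- "syngeneic"
  others <- setdiff(groups, ref)
  comparisons <- c(
    lapply(others, function(g) ttest_groups(cohort, "adc", g, ref,
                                            welch = isTRUE(cfg$stats$welch),
                                            alpha = cfg$stats$alpha)),
    lapply(others, function(g) ttest_groups(cohort, "plasma_flow", g, ref,
                                            welch = isTRUE(cfg$stats$welch),
                                            alpha = cfg$stats$alpha))
  )
  comparisons <- bonferroni(comparisons, m = cfg$stats$bonferroni_m)
  normality <- lapply(setNames(c("adc", "plasma_flow"), c("adc", "plasma_flow")),
                      function(v) ks_normality(cohort[[v]])[c("statistic", "p", "normal")])
  correlations <- list(
    correlate(cohort, "adc", "f480_pct", method = "pearson"),
    correlate(cohort, "adc", "interstitial_inflammation"),
    correlate(cohort, "plasma_flow", "intimal_arteritis")
  )
  log_stage(cfg, "stats", t0, length(comparisons), "comparisons,",
            length(correlations), "correlations")

  report <- list(
    provenance = list(
      software = paste("renalmr", as.character(utils::packageVersion("renalmr"))),
      seed = seed,
      config_hash = unname(config_hash(cfg)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    units = list(adc = "mm^2/s x10^-3", plasma_flow = "ml/100ml/min",
                 ecv = "ml/100ml", mtt = "min"),
    imaging = list(dwi_roi = dwi_summary, dce_roi = dce_fit$summary),
    cohort_groups = group_means,
    comparisons = comparison_table(comparisons),
    correlations = lapply(correlations, function(x)
      x[c("var_x", "var_y", "method", "r", "p", "n")]),
    normality = normality
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(cfg$out_dir, "cohort.csv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    if (isTRUE(cfg$render)) {
      render_maps(list(adc = adc$adc), file.path(cfg$out_dir, "maps"),
                  units = c(adc = "mm^2/s"))
    }
    log_stage(cfg, "report", t0, "written to", cfg$out_dir)
  }
  invisible(report)
}

# order-independent hash of the scientific configuration (md5 of canonical
# JSON); output location does not change what was computed
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
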