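#' Configuration for a full divergence analysis run
#'
#' @param input either a CSV path (with `mapping`) or a
#'   [simulation_config()] to generate data.
#' @param mapping column mapping when `input` is a path.
#' @param contrast analysis contrast: `"vs_control"` or `"vs_adm"`.
#' @param r_grid imputed pre-post correlations (unique, strictly in (0, 1)).
#' @param sampling_rho assumed within-study sampling correlation (pooling
#'   and pre-aggregation); default 0.6.
#' @param models pooling models to run (see [pool_effects()]); `"all"`
#'   expands to every model.
#' @param cer control event rate for NNT conversion.
#' @param higher_is_better outcome-scale orientation.
#' @param moderators character vector of study-level covariates to screen in
#'   the moderator analysis (columns of the comparison table, or
#'   `"baseline_imbalance"` which is derived).
#' @param min_k_bivariate minimum paired studies required to fit a bivariate
#'   model (default 10).
#' @param out_dir optional output directory; when given, all result tables
#'   are written as CSV/JSON.
#' @return a `run_config` list.
#' @export
run_config <- function(input = simulation_config(),
                       mapping = metapsy_mapping(),
                       contrast = c("vs_control", "vs_adm"),
                       r_grid = c(0.2, 0.4, 0.6, 0.8),
                       sampling_rho = 0.6,
                       models = "che", cer = 0.2,
                       higher_is_better = FALSE,
                       moderators = c("attrition", "baseline_imbalance",
                                      "rob_low_count", "control_type",
                                      "treatment_type"),
                       min_k_bivariate = 10L,
                       out_dir = NULL) {
  contrast <- match.arg(contrast)
  if (anyDuplicated(r_grid) || any(r_grid <= 0 | r_grid >= 1)) {
    stop("r_grid values must be unique and strictly in (0, 1)")
  }
  if (identical(models, "all")) {
    models <- c("che", "aggregate", "best_case", "worst_case",
                "outlier_excluded")
  }
  structure(list(input = input, mapping = mapping, contrast = contrast,
                 r_grid = r_grid, sampling_rho = sampling_rho,
                 models = models, cer = cer,
                 higher_is_better = higher_is_better, moderators = moderators,
                 min_k_bivariate = as.integer(min_k_bivariate),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full SMD-divergence analysis
#'
#' Pipeline stages: load or simulate the comparison table; apply the
#' eligibility filter; compute the SMD-variant grid; pool every
#' (variant, r) cell under each configured model; fit the bivariate
#' divergence model (with slope test) for every change-score variant and
#' correlation; screen the configured study-level moderators of the
#' divergence; and assemble a run log. Any stage error aborts with the stage
#' name attached.
#'
#' @param cfg a [run_config()].
#' @return a `divergence_bundle` list: `data`, `dropped`, `effects`,
#'   `pooled`, `bivariate` (summary tibble), `bivariate_fits` (list of
#'   `bivariate_fit` objects), `moderation`, `log`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  data <- stage("load", {
    if (inherits(cfg$input, "simulation_config")) {
      simulate_aggregate_dataset(cfg$input)
    } else {
      read_trial_data(cfg$input, cfg$mapping, contrast = cfg$contrast)
    }
  })
  data <- data[data$contrast == cfg$contrast, , drop = FALSE]

  filt <- stage("filter", filter_eligible(data))
  kept <- filt$kept
  if (nrow(kept) < 2) stop("stage 'filter' left fewer than 2 comparisons")

  es <- stage("effect_sizes",
              smd_variant_grid(kept, r_grid = cfg$r_grid,
                               higher_is_better = cfg$higher_is_better))

  pooled <- stage("pooling",
                  pool_grid(es, models = cfg$models,
                            sampling_rho = cfg$sampling_rho, cer = cfg$cer))

  biv_fits <- list()
  biv_rows <- list()
  for (v in c("CS_BL", "CS_CS", "CS_EP")) {
    for (r in cfg$r_grid) {
      pairs <- make_pairs(es, v, r, cfg$sampling_rho)
      if (nrow(pairs) < cfg$min_k_bivariate) next
      fit <- stage(sprintf("bivariate %s r=%s", v, r),
                   fit_bivariate(pairs, variant = v, assumed_r = r))
      key <- sprintf("%s_r%s", v, r)
      biv_fits[[key]] <- fit
      biv_rows[[key]] <- tibble::tibble(
        variant = v, assumed_r = r, k = fit$k,
        mu_ep = fit$mu[1], mu_cs = fit$mu[2],
        tau2_ep = fit$T[1, 1], tau2_cs = fit$T[2, 2], tau_cov = fit$T[1, 2],
        slope = fit$slope, slope_se = fit$slope_se, p_vs_one = fit$p_vs_one,
        slope_reverse = fit$diagnostics$slope_reverse
      )
    }
  }
  bivariate <- dplyr::bind_rows(biv_rows)

  moderation <- NULL
  if (length(cfg$moderators) && length(biv_fits)) {
    mod_rows <- list()
    study_cov <- .study_covariates(kept)
    for (key in names(biv_fits)) {
      fit <- biv_fits[[key]]
      pairs <- make_pairs(es, fit$variant, fit$assumed_r, cfg$sampling_rho)
      for (mv in cfg$moderators) {
        x <- study_cov[[mv]][match(pairs$study_id, study_cov$study_id)]
        if (all(is.na(x))) next
        tab <- tryCatch(divergence_moderation(pairs, x),
                        error = function(e) NULL)
        if (is.null(tab)) next
        tab$variant <- fit$variant
        tab$assumed_r <- fit$assumed_r
        tab$moderator <- mv
        mod_rows[[length(mod_rows) + 1L]] <- tab
      }
    }
    moderation <- if (length(mod_rows)) dplyr::bind_rows(mod_rows) else NULL
  }

  log <- list(
    package = "smdvariants",
    version = as.character(utils::packageVersion("smdvariants")),
    contrast = cfg$contrast, r_grid = cfg$r_grid,
    sampling_rho = cfg$sampling_rho, models = cfg$models, cer = cfg$cer,
    higher_is_better = cfg$higher_is_better,
    n_comparisons_in = nrow(data), n_comparisons_kept = nrow(kept),
    n_studies_kept = length(unique(kept$study_id)),
    n_dropped = nrow(filt$dropped),
    synthetic = inherits(cfg$input, "simulation_config"),
    seed = if (inherits(cfg$input, "simulation_config")) cfg$input$seed else NA
  )

  bundle <- structure(list(data = kept, dropped = filt$dropped, effects = es,
                           pooled = pooled, bivariate = bivariate,
                           bivariate_fits = biv_fits, moderation = moderation,
                           log = log),
                      class = "divergence_bundle")
  if (!is.null(cfg$out_dir)) .write_bundle(bundle, cfg$out_dir)
  bundle
}

# one row per study with the moderator covariates (first comparison wins;
# baseline imbalance is averaged over a study's instruments)
.study_covariates <- function(kept) {
  bi <- baseline_imbalance(kept)
  df <- tibble::tibble(study_id = kept$study_id,
                       attrition = kept$attrition,
                       rob_low_count = kept$rob_low_count,
                       control_type = kept$control_type,
                       treatment_type = kept$treatment_type,
                       baseline_imbalance = bi)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$study_id),
    attrition = .data$attrition[1], rob_low_count = .data$rob_low_count[1],
    control_type = .data$control_type[1],
    treatment_type = .data$treatment_type[1],
    baseline_imbalance = mean(.data$baseline_imbalance), .groups = "drop")
  agg
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_effect_sizes(bundle$effects, file.path(out_dir, "effect_sizes.csv"))
  write.csv(as.data.frame(bundle$pooled), file.path(out_dir, "pooled.csv"),
            row.names = FALSE, na = "")
  if (nrow(bundle$bivariate)) {
    write.csv(as.data.frame(bundle$bivariate),
              file.path(out_dir, "bivariate.csv"), row.names = FALSE, na = "")
  }
  if (!is.null(bundle$moderation)) {
    write.csv(as.data.frame(bundle$moderation),
              file.path(out_dir, "moderation.csv"), row.names = FALSE, na = "")
  }
  write_drop_report(bundle$dropped, file.path(out_dir, "drop_report.json"))
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize how strongly the SMD variants diverge
#'
#' Reports, per pooling model: the range of pooled SMDs across variants and
#' correlations, each variant's difference to the endpoint estimate, and the
#' bivariate slopes flagged as significantly different from one. Every
#' number is taken from the bundle's machine-readable tables.
#'
#' @param bundle result of [run_full_analysis()].
#' @param alpha significance level for flagging slopes (default 0.05).
#' @return list with `range` (per-model min/max/width tibble), `delta_to_ep`
#'   (per variant x r x model), and `flagged_slopes`.
#' @export
summarize_divergence <- function(bundle, alpha = 0.05) {
  pooled <- bundle$pooled
  rng <- dplyr::summarise(
    dplyr::group_by(pooled, .data$model),
    min_smd = min(.data$smd), max_smd = max(.data$smd),
    width = max(.data$smd) - min(.data$smd), .groups = "drop")
  ep <- pooled[pooled$variant == "EP_EP", c("model", "smd")]
  names(ep)[2] <- "smd_ep"
  delta <- dplyr::left_join(pooled[pooled$variant != "EP_EP",
                                   c("model", "variant", "assumed_r", "smd")],
                            ep, by = "model")
  delta$delta_smd <- delta$smd - delta$smd_ep
  delta <- delta[order(delta$model, delta$variant, delta$assumed_r), ]
  flagged <- if (nrow(bundle$bivariate)) {
    bundle$bivariate[bundle$bivariate$p_vs_one < alpha,
                     c("variant", "assumed_r", "slope", "p_vs_one")]
  } else NULL
  list(range = rng, delta_to_ep = tibble::as_tibble(delta),
       flagged_slopes = flagged)
}

#' @export
print.divergence_bundle <- function(x, ...) {
  cat(sprintf("SMD-divergence bundle: %d studies, %d comparisons, %d effects\n",
              x$log$n_studies_kept, nrow(x$data), nrow(x$effects)))
  cat(sprintf("  pooled table: %d rows (%s)\n", nrow(x$pooled),
              paste(unique(x$pooled$model), collapse = ", ")))
  if (nrow(x$bivariate)) {
    cat(sprintf("  bivariate fits: %d; slopes %.3f..%.3f\n",
                nrow(x$bivariate), min(x$bivariate$slope),
                max(x$bivariate$slope)))
  }
  invisible(x)
}
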