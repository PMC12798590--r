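#' Hedges' small-sample correction factor J
#'
#' Exact gamma-function form `J(m) = Gamma(m/2) / (sqrt(m/2) Gamma((m-1)/2))`
#' evaluated in log-gamma space for numerical stability. Multiplying a raw
#' standardized mean difference by `J(m)` removes its positive small-sample
#' bias (Hedges' g).
#'
#' @param m degrees of freedom, `n_int + n_ctrl - 2`; must be >= 2.
#' @return correction factor in (0, 1).
#' @export
#' @examples
#' hedges_j(10)               # 0.9227
#' 1 - 3 / (4 * 10 - 1)       # common approximation
hedges_j <- function(m) {
  if (any(m < 2)) stop("domain error: degrees of freedom m must be >= 2")
  exp(lgamma(m / 2) - 0.5 * log(m / 2) - lgamma((m - 1) / 2))
}

#' Pooled standard deviation of two arms
#'
#' `sqrt(((n1 - 1) sd1^2 + (n2 - 1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param sd1,sd2 arm SDs (positive).
#' @param n1,n2 arm sample sizes (>= 2).
#' @return pooled SD.
#' @export
pooled_sd <- function(sd1, sd2, n1, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("domain error: arm sample sizes must be >= 2")
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

.variants <- c("EP_EP", "CS_BL", "CS_CS", "CS_EP")

# numerator (mean difference) and standardizing SD for one variant,
# vectorized over comparisons; sign flipped so positive favors the
# intervention on scales where lower scores are better
.smd_core <- function(data, variant, r, higher_is_better) {
  sign <- if (higher_is_better) 1 else -1
  if (variant == "EP_EP") {
    num <- data$mean_ep_int - data$mean_ep_ctrl
    den <- pooled_sd(data$sd_ep_int, data$sd_ep_ctrl, data$n_int, data$n_ctrl)
  } else {
    cs_int <- change_summaries(data$mean_bl_int, data$sd_bl_int,
                               data$mean_ep_int, data$sd_ep_int, data$n_int, r)
    cs_ctrl <- change_summaries(data$mean_bl_ctrl, data$sd_bl_ctrl,
                                data$mean_ep_ctrl, data$sd_ep_ctrl, data$n_ctrl, r)
    num <- cs_int$mean_cs - cs_ctrl$mean_cs
    den <- switch(variant,
      CS_BL = pooled_sd(data$sd_bl_int, data$sd_bl_ctrl, data$n_int, data$n_ctrl),
      CS_CS = pooled_sd(cs_int$sd_cs, cs_ctrl$sd_cs, data$n_int, data$n_ctrl),
      CS_EP = pooled_sd(data$sd_ep_int, data$sd_ep_ctrl, data$n_int, data$n_ctrl)
    )
  }
  if (any(den == 0, na.rm = TRUE)) {
    bad <- data$study_id[which(den == 0)]
    stop("degenerate-input error: zero standardizing SD in study ",
         paste(unique(bad), collapse = ", "))
  }
  list(num = sign * num, den = den)
}

#' Sampling variance of the endpoint SMD (Hedges' g)
#'
#' Unbiased estimator: `(n1 + n2) / (n1 n2) + (1 - (m - 2) / (m J(m)^2)) g^2`
#' with `m = n1 + n2 - 2`.
#'
#' @param smd bias-corrected endpoint SMD.
#' @param n1,n2 arm sample sizes.
#' @return sampling variance.
#' @export
var_smd_ep <- function(smd, n1, n2) {
  m <- n1 + n2 - 2
  (n1 + n2) / (n1 * n2) + (1 - (m - 2) / (m * hedges_j(m)^2)) * smd^2
}

#' Delta-method sampling variance for change-score SMDs (CS/CS, CS/EP)
#'
#' `J(m)^2 (2 (1 - r) (n1 + n2) / (n1 n2) + g^2 / (2 m))`. The same form is
#' applied to both the change-SD- and the endpoint-SD-standardized change
#' SMD; see the methods vignette for a discussion of what this form does and
#' does not estimate for the CS/CS variant.
#'
#' @param smd bias-corrected change-score SMD.
#' @param n1,n2 arm sample sizes.
#' @param r assumed pre-post correlation.
#' @return sampling variance.
#' @export
var_smd_cs_delta <- function(smd, n1, n2, r) {
  m <- n1 + n2 - 2
  hedges_j(m)^2 * (2 * (1 - r) * (n1 + n2) / (n1 * n2) + smd^2 / (2 * m))
}

#' Morris sampling variance for the baseline-SD-standardized change SMD
#'
#' Pre-post-control design variance for a difference in mean change
#' standardized by the pooled baseline SD:
#' `2 J(m)^2 (1 - r) A (m / (m - 2)) (1 + g^2 / (2 (1 - r) A)) - g^2`
#' with `A = (n1 + n2) / (n1 n2)` and `m = n1 + n2 - 2`. The coefficient of
#' `g^2` is `J(m)^2 m / (m - 2) - 1 > 0`, so the closed form is positive for
#' valid inputs; a defensive guard (hard error, or the opt-in `floor`)
#' protects against degenerate arguments all the same.
#'
#' @param smd bias-corrected CS/BL SMD.
#' @param n1,n2 arm sample sizes.
#' @param r assumed pre-post correlation.
#' @param floor optional positive lower bound applied instead of erroring
#'   when the closed form is non-positive; `NULL` (default) disables it.
#' @return sampling variance.
#' @export
var_smd_cs_bl <- function(smd, n1, n2, r, floor = NULL) {
  m <- n1 + n2 - 2
  if (any(m <= 2)) stop("domain error: Morris variance requires m > 2")
  A <- (n1 + n2) / (n1 * n2)
  v <- 2 * hedges_j(m)^2 * (1 - r) * A * (m / (m - 2)) *
    (1 + smd^2 / (2 * (1 - r) * A)) - smd^2
  bad <- v <= 0
  if (any(bad)) {
    if (is.null(floor)) {
      stop("degenerate-variance error: non-positive Morris variance (|smd| too ",
           "large for m); set a positive floor to override")
    }
    v[bad] <- floor
  }
  v
}

#' Compute one SMD variant for a comparison table
#'
#' @param data eligible comparison tibble.
#' @param variant one of `"EP_EP"`, `"CS_BL"`, `"CS_CS"`, `"CS_EP"`.
#' @param r assumed pre-post correlation (ignored for `EP_EP`).
#' @param higher_is_better set `TRUE` for outcome scales where higher scores
#'   are better; default `FALSE` (symptom scales), so positive SMDs favor
#'   the intervention.
#' @param var_floor passed to [var_smd_cs_bl()] for the CS/BL variant.
#' @return tibble with columns `study_id`, `instrument_id`, `contrast`,
#'   `variant`, `assumed_r`, `smd`, `variance`, `m`.
#' @export
smd_variant <- function(data, variant, r = NA_real_, higher_is_better = FALSE,
                        var_floor = NULL) {
  variant <- match.arg(variant, .variants)
  if (variant != "EP_EP" && (is.na(r) || r <= 0 || r >= 1)) {
    stop("domain error: change-score variants require r in (0, 1)")
  }
  core <- .smd_core(data, variant, r, higher_is_better)
  m <- data$n_int + data$n_ctrl - 2
  g <- core$num / core$den * hedges_j(m)
  v <- switch(variant,
    EP_EP = var_smd_ep(g, data$n_int, data$n_ctrl),
    CS_BL = var_smd_cs_bl(g, data$n_int, data$n_ctrl, r, floor = var_floor),
    CS_CS = var_smd_cs_delta(g, data$n_int, data$n_ctrl, r),
    CS_EP = var_smd_cs_delta(g, data$n_int, data$n_ctrl, r)
  )
  r_used <- if (variant == "EP_EP") NA_real_ else r
  tibble::tibble(
    study_id = data$study_id, instrument_id = data$instrument_id,
    contrast = data$contrast, variant = variant,
    assumed_r = r_used, smd = g, variance = v, m = as.integer(m)
  )
}

#' Effect-size grid: all SMD variants over a pre-post correlation grid
#'
#' Per comparison, one EP/EP estimate plus the three change-score variants at
#' every correlation in `r_grid` (13 estimates per comparison at the default
#' four-value grid).
#'
#' @inheritParams smd_variant
#' @param r_grid correlations to impute for change-score variants, values
#'   strictly in (0, 1); default `c(0.2, 0.4, 0.6, 0.8)`.
#' @return long effect-size tibble (see [smd_variant()] for columns), with a
#'   `config` attribute recording the grid and sign convention.
#' @export
#' @examples
#' cfg <- simulation_config(k_studies = 3, seed = 7)
#' d <- simulate_aggregate_dataset(cfg)
#' es <- smd_variant_grid(d)
#' nrow(es) / nrow(d)  # 13
smd_variant_grid <- function(data, r_grid = c(0.2, 0.4, 0.6, 0.8),
                             higher_is_better = FALSE, var_floor = NULL) {
  if (length(r_grid) == 0L) stop("r_grid must be non-empty")
  if (any(r_grid <= 0 | r_grid >= 1)) stop("r_grid values must lie in (0, 1)")
  if (nrow(data) == 0L) {
    out <- tibble::tibble(study_id = character(), instrument_id = character(),
                          contrast = character(), variant = character(),
                          assumed_r = numeric(), smd = numeric(),
                          variance = numeric(), m = integer())
  } else {
    pieces <- list(smd_variant(data, "EP_EP", higher_is_better = higher_is_better))
    for (r in r_grid) {
      for (v in c("CS_BL", "CS_CS", "CS_EP")) {
        pieces[[length(pieces) + 1L]] <-
          smd_variant(data, v, r = r, higher_is_better = higher_is_better,
                      var_floor = var_floor)
      }
    }
    out <- dplyr::bind_rows(pieces)
  }
  attr(out, "config") <- list(r_grid = r_grid, higher_is_better = higher_is_better)
  out
}

#' Write the long effect-size table with its configuration metadata
#'
#' @param es effect-size tibble from [smd_variant_grid()].
#' @param path output CSV path; a JSON sidecar `<path>.meta.json` records the
#'   correlation grid and sign convention.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(es, path) {
  write.csv(as.data.frame(es), path, row.names = FALSE, na = "")
  cfg <- attr(es, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}
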