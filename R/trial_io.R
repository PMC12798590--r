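#' @importFrom stats coef lm optimize nlminb pnorm qnorm qt pt pchisq qchisq
#'   rnorm sd setNames var complete.cases quantile median rWishart runif
#'   rlnorm rbinom
#' @importFrom utils read.csv write.csv head
#' @importFrom dplyr .data
NULL

# canonical per-comparison column layout used throughout the package;
# one row = one intervention-vs-comparator contrast on one instrument
.comparison_cols <- c(
  "study_id", "instrument_id", "contrast",
  "n_int", "n_rand_int", "mean_bl_int", "sd_bl_int", "mean_ep_int", "sd_ep_int",
  "n_ctrl", "n_rand_ctrl", "mean_bl_ctrl", "sd_bl_ctrl", "mean_ep_ctrl", "sd_ep_ctrl",
  "rob_low_count", "attrition", "control_type", "treatment_type",
  "monotherapy_int", "monotherapy_ctrl", "has_change_scores"
)

.missing_tokens <- c("", "NA", "NaN", "na", "n/a", "N/A")

#' Default column mapping for the Metapsy-style trial schema
#'
#' Maps the canonical comparison fields onto the column names used by the
#' 2023 Metapsy depression database deposits (one row per comparison, arm 1 =
#' psychotherapy, arm 2 = comparator). Override individual entries, or load a
#' mapping from YAML with [read_mapping_yaml()], when reading a dataset whose
#' columns are named differently.
#'
#' @param ... named character entries overriding individual defaults, e.g.
#'   `study = "trial_name"`.
#' @return named character vector mapping canonical fields to CSV columns.
#'   Entries mapped to `NA` are treated as absent from the file.
#' @export
#' @examples
#' metapsy_mapping(study = "trial")
metapsy_mapping <- function(...) {
  map <- c(
    study = "study", instrument = "instr", contrast = "condition_arm2",
    n_int = "n_arm1", n_rand_int = "rand_arm1",
    mean_bl_int = "mean_bl_arm1", sd_bl_int = "sd_bl_arm1",
    mean_ep_int = "mean_arm1", sd_ep_int = "sd_arm1",
    n_ctrl = "n_arm2", n_rand_ctrl = "rand_arm2",
    mean_bl_ctrl = "mean_bl_arm2", sd_bl_ctrl = "sd_bl_arm2",
    mean_ep_ctrl = "mean_arm2", sd_ep_ctrl = "sd_arm2",
    rob_low_count = "rob", attrition = NA, control_type = "condition_arm2",
    treatment_type = "multi_arm1",
    monotherapy_int = NA, monotherapy_ctrl = NA,
    mean_change_int = "mean_change_arm1", sd_change_int = "sd_change_arm1",
    mean_change_ctrl = "mean_change_arm2", sd_change_ctrl = "sd_change_arm2"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) stop("unknown mapping fields: ", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

#' Identity mapping for files written by [write_trial_data()]
#'
#' @return named character vector mapping every canonical field to itself.
#' @export
canonical_mapping <- function() {
  fields <- c(.comparison_cols[.comparison_cols != "has_change_scores"],
              "mean_change_int", "sd_change_int", "mean_change_ctrl", "sd_change_ctrl")
  fields[fields == "study_id"] <- "study"
  fields[fields == "instrument_id"] <- "instrument"
  setNames(fields, fields)
}

#' Load a column mapping from a YAML file
#'
#' @param path YAML file with a flat `field: column` mapping.
#' @return named character vector suitable for [read_trial_data()].
#' @export
read_mapping_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(metapsy_mapping, lapply(y, as.character))
}

.parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% .missing_tokens] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read an aggregate-trial dataset into the comparison table
#'
#' Reads a UTF-8, comma-separated trial file (header row required) and
#' returns one row per (study, instrument, contrast) comparison in the
#' canonical layout. Numeric cells that fail to parse are set to missing and
#' recorded in the load report attached as attribute `"load_report"`.
#' Missing-value tokens accepted in numeric columns: empty cell, `NA`, `NaN`.
#'
#' Pooled attrition is derived as `1 - (n_int + n_ctrl) /
#' (n_rand_int + n_rand_ctrl)` when randomized sample sizes are available and
#' no attrition column is mapped; otherwise it is missing.
#'
#' @param path CSV file path.
#' @param mapping named character vector from [metapsy_mapping()],
#'   [canonical_mapping()] or [read_mapping_yaml()].
#' @param contrast value recorded in the `contrast` column when the file does
#'   not encode it: `"vs_control"` or `"vs_adm"`.
#' @return tibble of comparisons; attribute `"load_report"` is a tibble with
#'   columns `row`, `column`, `value` listing unparseable numeric cells.
#' @export
read_trial_data <- function(path, mapping = metapsy_mapping(),
                            contrast = c("vs_control", "vs_adm")) {
  contrast <- match.arg(contrast)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("input error: empty file: ", path)

  need <- c("study", "n_int", "mean_bl_int", "sd_bl_int", "mean_ep_int",
            "sd_ep_int", "n_ctrl", "mean_bl_ctrl", "sd_bl_ctrl",
            "mean_ep_ctrl", "sd_ep_ctrl")
  miss <- need[!is.na(mapping[need]) & !(mapping[need] %in% names(raw))]
  if (length(miss)) {
    stop("configuration error: mapped columns absent from file: ",
         paste(sprintf("%s -> %s", miss, mapping[miss]), collapse = ", "))
  }

  col <- function(field, parse = TRUE) {
    nm <- mapping[[field]]
    if (is.null(nm) || is.na(nm) || !(nm %in% names(raw))) {
      return(rep(NA, nrow(raw)))
    }
    if (parse) .parse_num(raw[[nm]]) else as.character(raw[[nm]])
  }

  num_fields <- c("n_int", "n_rand_int", "mean_bl_int", "sd_bl_int",
                  "mean_ep_int", "sd_ep_int", "n_ctrl", "n_rand_ctrl",
                  "mean_bl_ctrl", "sd_bl_ctrl", "mean_ep_ctrl", "sd_ep_ctrl",
                  "rob_low_count", "attrition",
                  "mean_change_int", "sd_change_int",
                  "mean_change_ctrl", "sd_change_ctrl")
  vals <- lapply(num_fields, col)
  names(vals) <- num_fields

  # load report: cells that were non-missing text but did not parse
  report <- list()
  for (f in num_fields) {
    nm <- mapping[[f]]
    if (is.null(nm) || is.na(nm) || !(nm %in% names(raw))) next
    txt <- trimws(raw[[nm]])
    bad <- which(is.na(vals[[f]]) & !is.na(txt) & !(txt %in% .missing_tokens))
    if (length(bad)) {
      report[[f]] <- tibble::tibble(row = bad, column = nm, value = txt[bad])
    }
  }
  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(row = integer(), column = character(), value = character())

  instr <- col("instrument", parse = FALSE)
  if (all(is.na(instr))) instr <- rep("instr_1", nrow(raw))
  contr <- col("contrast", parse = FALSE)
  contr <- if (all(is.na(contr)) || !all(contr %in% c("vs_control", "vs_adm"), na.rm = TRUE)) {
    rep(contrast, nrow(raw))
  } else contr

  mono <- function(field) {
    x <- col(field, parse = FALSE)
    out <- rep(TRUE, nrow(raw))
    out[!is.na(x)] <- tolower(x[!is.na(x)]) %in% c("true", "t", "1", "yes", "mono", "monotherapy")
    out
  }

  out <- tibble::tibble(
    study_id = col("study", parse = FALSE),
    instrument_id = instr,
    contrast = contr,
    n_int = vals$n_int, n_rand_int = vals$n_rand_int,
    mean_bl_int = vals$mean_bl_int, sd_bl_int = vals$sd_bl_int,
    mean_ep_int = vals$mean_ep_int, sd_ep_int = vals$sd_ep_int,
    n_ctrl = vals$n_ctrl, n_rand_ctrl = vals$n_rand_ctrl,
    mean_bl_ctrl = vals$mean_bl_ctrl, sd_bl_ctrl = vals$sd_bl_ctrl,
    mean_ep_ctrl = vals$mean_ep_ctrl, sd_ep_ctrl = vals$sd_ep_ctrl,
    rob_low_count = vals$rob_low_count,
    attrition = vals$attrition,
    control_type = col("control_type", parse = FALSE),
    treatment_type = col("treatment_type", parse = FALSE),
    monotherapy_int = mono("monotherapy_int"),
    monotherapy_ctrl = mono("monotherapy_ctrl"),
    has_change_scores = (!is.na(vals$mean_change_int) & !is.na(vals$mean_change_ctrl))
  )
  no_attr <- is.na(out$attrition)
  out$attrition[no_attr] <- pooled_attrition(out[no_attr, , drop = FALSE])
  attr(out, "load_report") <- report
  out
}

#' Write a comparison table as CSV in the canonical layout
#'
#' The written file round-trips through [read_trial_data()] with
#' [canonical_mapping()].
#'
#' @param data comparison tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  cols <- intersect(c(.comparison_cols[.comparison_cols != "has_change_scores"],
                      "mean_change_int", "sd_change_int",
                      "mean_change_ctrl", "sd_change_ctrl"), names(data))
  out <- as.data.frame(data[cols])
  names(out)[names(out) == "study_id"] <- "study"
  names(out)[names(out) == "instrument_id"] <- "instrument"
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Pooled attrition across both trial arms
#'
#' Attrition is the proportion of randomized participants lost to follow-up,
#' pooled over arms: `1 - (n_int + n_ctrl) / (n_rand_int + n_rand_ctrl)`.
#' Missing when randomized sample sizes are unavailable.
#'
#' @param data comparison tibble.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @export
pooled_attrition <- function(data) {
  ok <- !is.na(data$n_rand_int) & !is.na(data$n_rand_ctrl)
  out <- rep(NA_real_, nrow(data))
  out[ok] <- pmax(0, 1 - (data$n_int[ok] + data$n_ctrl[ok]) /
                    (data$n_rand_int[ok] + data$n_rand_ctrl[ok]))
  out
}

#' Apply the eligibility filter to a comparison table
#'
#' Keeps comparisons where both arms report endpoint sample size and
#' baseline/endpoint mean and SD, with positive SDs. Comparisons reporting
#' only change scores are dropped with reason `"change_only"`; in
#' psychotherapy-vs-pharmacotherapy contrasts, rows whose arms are not
#' monotherapy are dropped with reason `"non_monotherapy_arm"`. The filter is
#' idempotent.
#'
#' @param data comparison tibble from [read_trial_data()] or
#'   [simulate_aggregate_dataset()].
#' @return list with elements `kept` (comparison tibble) and `dropped`
#'   (tibble with `study_id`, `instrument_id`, `reason`).
#' @export
filter_eligible <- function(data) {
  if (nrow(data) == 0L) {
    return(list(kept = data,
                dropped = tibble::tibble(study_id = character(),
                                         instrument_id = character(),
                                         reason = character())))
  }
  req <- list(
    missing_n = c("n_int", "n_ctrl"),
    missing_baseline_mean = c("mean_bl_int", "mean_bl_ctrl"),
    missing_baseline_sd = c("sd_bl_int", "sd_bl_ctrl"),
    missing_endpoint_mean = c("mean_ep_int", "mean_ep_ctrl"),
    missing_endpoint_sd = c("sd_ep_int", "sd_ep_ctrl")
  )
  reason <- rep(NA_character_, nrow(data))
  # reverse order so the first missing field (in the order above) wins
  for (r in rev(names(req))) {
    bad <- rowSums(is.na(data[req[[r]]])) > 0
    reason[bad] <- r
  }
  has_cs <- if ("has_change_scores" %in% names(data)) data$has_change_scores else FALSE
  reason[!is.na(reason) & has_cs] <- "change_only"

  sds <- c("sd_bl_int", "sd_bl_ctrl", "sd_ep_int", "sd_ep_ctrl")
  bad_sd <- is.na(reason) & rowSums(as.matrix(data[sds]) <= 0) > 0
  reason[bad_sd] <- "nonpositive_sd"
  small_n <- is.na(reason) & (data$n_int < 2 | data$n_ctrl < 2)
  reason[small_n] <- "insufficient_n"
  non_mono <- is.na(reason) & data$contrast == "vs_adm" &
    !(data$monotherapy_int & data$monotherapy_ctrl)
  reason[non_mono] <- "non_monotherapy_arm"

  drop <- !is.na(reason)
  list(
    kept = data[!drop, , drop = FALSE],
    dropped = tibble::tibble(study_id = data$study_id[drop],
                             instrument_id = data$instrument_id[drop],
                             reason = reason[drop])
  )
}

#' Write the eligibility drop report as JSON
#'
#' @param dropped `dropped` element from [filter_eligible()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_drop_report <- function(dropped, path) {
  jsonlite::write_json(dropped, path, dataframe = "rows", na = "null")
  invisible(path)
}

#' Change-score summaries from baseline and endpoint summaries
#'
#' Constructs the arm-level mean, SD and sample size of the pre-to-post
#' change from reported aggregate summaries and an imputed pre-post
#' correlation `r`:
#' `mean_cs = mean_ep - mean_bl`,
#' `sd_cs = sqrt(sd_ep^2 + sd_bl^2 - 2 r sd_ep sd_bl)`, `n_cs = n_ep`.
#'
#' @param mean_bl,sd_bl baseline mean and SD (vectors recycle).
#' @param mean_ep,sd_ep endpoint mean and SD.
#' @param n_ep analyzed sample size at endpoint.
#' @param r assumed pre-post correlation, strictly inside (-1, 1).
#' @return tibble with columns `mean_cs`, `sd_cs`, `n_cs`.
#' @export
#' @examples
#' change_summaries(24, 8, 15.5, 8, 50, r = 0.5)
change_summaries <- function(mean_bl, sd_bl, mean_ep, sd_ep, n_ep, r) {
  if (any(r <= -1 | r >= 1)) {
    stop("domain error: pre-post correlation r must lie strictly in (-1, 1)")
  }
  if (any(sd_bl <= 0, na.rm = TRUE) || any(sd_ep <= 0, na.rm = TRUE)) {
    stop("domain error: SDs must be positive")
  }
  sd_cs <- sqrt(sd_ep^2 + sd_bl^2 - 2 * r * sd_ep * sd_bl)
  if (any(sd_cs == 0, na.rm = TRUE)) {
    stop("degenerate-input error: change-score SD is zero")
  }
  tibble::tibble(mean_cs = mean_ep - mean_bl, sd_cs = sd_cs,
                 n_cs = as.integer(n_ep))
}

#' Baseline imbalance of a comparison
#'
#' Absolute standardized between-group difference at baseline: the absolute
#' baseline mean difference divided by the pooled baseline SD.
#'
#' @param data comparison tibble (baseline summaries present in both arms).
#' @return nonnegative numeric vector, one value per comparison.
#' @export
baseline_imbalance <- function(data) {
  ps <- pooled_sd(data$sd_bl_int, data$sd_bl_ctrl, data$n_int, data$n_ctrl)
  if (any(ps == 0, na.rm = TRUE)) {
    stop("degenerate-input error: pooled baseline SD is zero")
  }
  abs(data$mean_bl_int - data$mean_bl_ctrl) / ps
}
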