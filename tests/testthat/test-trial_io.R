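# A small Metapsy-style CSV written at test time, exercising the default
# column mapping, missing tokens and an unparseable cell.
write_fixture_csv <- function(path, n_studies = 3, instruments = 2,
                              tweak = identity) {
  rows <- list()
  for (i in seq_len(n_studies)) {
    for (j in seq_len(instruments)) {
      rows[[length(rows) + 1L]] <- data.frame(
        study = paste0("trial", i), instr = paste0("scale", j),
        condition_arm2 = "wl", multi_arm1 = "cbt",
        n_arm1 = 40, rand_arm1 = 44, mean_bl_arm1 = 24.2, sd_bl_arm1 = 7.9,
        mean_arm1 = 15.1, sd_arm1 = 8.3,
        n_arm2 = 38, rand_arm2 = 42, mean_bl_arm2 = 23.8, sd_bl_arm2 = 8.1,
        mean_arm2 = 19.7, sd_arm2 = 7.6,
        rob = 2, mean_change_arm1 = "", sd_change_arm1 = "",
        mean_change_arm2 = "", sd_change_arm2 = "",
        stringsAsFactors = FALSE
      )
    }
  }
  df <- tweak(do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("reading a trial CSV yields one comparison per study-instrument pair", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path, n_studies = 3, instruments = 2)
  d <- read_trial_data(path)
  expect_equal(nrow(d), 6L)
  expect_equal(length(unique(d$study_id)), 3L)
  expect_setequal(unique(d$instrument_id), c("scale1", "scale2"))
  # attrition derived from randomized vs analyzed counts
  expect_equal(d$attrition[1], 1 - (40 + 38) / (44 + 42), tolerance = 1e-12)
  expect_equal(nrow(attr(d, "load_report")), 0L)
})

test_that("missing tokens pass through as NA and bad numerics are reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path, tweak = function(df) {
    df$sd_arm1[1] <- "NA"
    df$sd_arm1[2] <- "NaN"
    df$mean_arm2[3] <- "oops"
    df
  })
  d <- read_trial_data(path)
  expect_equal(nrow(d), 6L)          # rows retained, fields missing
  expect_true(is.na(d$sd_ep_int[1]))
  expect_true(is.na(d$sd_ep_int[2]))
  expect_true(is.na(d$mean_ep_ctrl[3]))
  rep <- attr(d, "load_report")
  expect_equal(nrow(rep), 1L)        # only the unparseable cell is flagged
  expect_equal(rep$value, "oops")
})

test_that("read errors are specific: absent mapped column, empty file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path, tweak = function(df) {
    df$sd_bl_arm1 <- NULL
    df
  })
  expect_error(read_trial_data(path), "configuration error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("study,instr", empty)
  expect_error(read_trial_data(empty), "input error")
  expect_error(read_trial_data("no/such/file.csv"), "not found")
})

test_that("eligibility filter drops incomplete rows with machine-readable reasons", {
  d <- make_comparisons(10)
  d$sd_bl_int[c(2, 5, 8)] <- NA_real_
  out <- filter_eligible(d)
  expect_equal(nrow(out$kept), 7L)
  expect_equal(nrow(out$dropped), 3L)
  expect_true(all(out$dropped$reason == "missing_baseline_sd"))
  # complete rows pass unchanged
  expect_identical(out$kept$study_id, d$study_id[-c(2, 5, 8)])
  # idempotence
  again <- filter_eligible(out$kept)
  expect_identical(again$kept, out$kept)
  expect_equal(nrow(again$dropped), 0L)
})

test_that("change-score-only rows and non-monotherapy ADM arms are excluded", {
  d <- make_comparisons(6)
  d$has_change_scores[2] <- TRUE
  d[2, c("mean_bl_int", "sd_bl_int", "mean_ep_int", "sd_ep_int")] <- NA_real_
  d$contrast[4:6] <- "vs_adm"
  d$monotherapy_ctrl[5] <- FALSE
  out <- filter_eligible(d)
  expect_equal(sort(out$dropped$reason), c("change_only", "non_monotherapy_arm"))
  expect_equal(nrow(out$kept), 4L)
})

test_that("change summaries follow the imputed-correlation construction", {
  # equal SDs at half correlation: sd_cs equals the common SD
  cs <- change_summaries(24, 8, 15.5, 8, 50, r = 0.5)
  expect_equal(cs$sd_cs, 8)
  expect_equal(cs$mean_cs, -8.5)
  expect_equal(cs$n_cs, 50L)
  # direct arithmetic case
  cs2 <- change_summaries(20, 6, 18, 8, 30, r = 0.2)
  expect_equal(cs2$sd_cs, sqrt(36 + 64 - 2 * 0.2 * 48), tolerance = 1e-12)
  expect_equal(cs2$sd_cs, 8.98888, tolerance = 1e-5)
  # domain errors; inside the open interval the change SD stays positive
  # because sd_ep^2 + sd_bl^2 - 2 r sd_ep sd_bl = (sd_ep - sd_bl)^2
  # + 2 sd_ep sd_bl (1 - r) > 0 for r < 1
  expect_error(change_summaries(20, 6, 18, 8, 30, r = 1), "domain error")
  expect_error(change_summaries(20, 6, 18, 8, 30, r = -1.2), "domain error")
  expect_gt(change_summaries(20, 8, 18, 8, 30, r = 1 - 1e-8)$sd_cs, 0)
})

test_that("sd_cs decreases strictly in r for fixed SDs", {
  grid <- seq(-0.9, 0.9, by = 0.1)
  sds <- vapply(grid, function(r) change_summaries(0, 5, 0, 7, 20, r)$sd_cs, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("baseline imbalance is the absolute standardized baseline difference", {
  d <- make_comparisons(1)
  d$mean_bl_int <- 20; d$mean_bl_ctrl <- 22
  d$sd_bl_int <- d$sd_bl_ctrl <- 4
  d$n_int <- d$n_ctrl <- 50L
  expect_equal(baseline_imbalance(d), 0.5)
  # identical baselines
  d$mean_bl_ctrl <- 20
  expect_equal(baseline_imbalance(d), 0)
  # asymmetric n and SDs
  d2 <- make_comparisons(1)
  d2$mean_bl_int <- 21; d2$mean_bl_ctrl <- 20
  d2$sd_bl_int <- 3; d2$sd_bl_ctrl <- 5
  d2$n_int <- 10L; d2$n_ctrl <- 90L
  ps <- sqrt((9 * 9 + 89 * 25) / 98)
  expect_equal(ps, 4.85084, tolerance = 1e-5)
  expect_equal(baseline_imbalance(d2), 1 / ps, tolerance = 1e-12)
})

test_that("write/read round-trip preserves all comparison fields", {
  d <- make_comparisons(5, instruments = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_data(d, path)
  back <- read_trial_data(path, mapping = canonical_mapping())
  for (col in c("n_int", "mean_bl_int", "sd_bl_int", "mean_ep_int",
                "sd_ep_int", "n_ctrl", "mean_bl_ctrl", "sd_bl_ctrl",
                "mean_ep_ctrl", "sd_ep_ctrl", "rob_low_count", "attrition")) {
    expect_equal(back[[col]], d[[col]], tolerance = 1e-10, label = col)
  }
  expect_identical(back$study_id, d$study_id)
  expect_identical(back$instrument_id, d$instrument_id)
})

test_that("drop report serializes to JSON and mapping round-trips via YAML", {
  d <- make_comparisons(3)
  d$sd_ep_ctrl[1] <- NA_real_
  out <- filter_eligible(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_drop_report(out$dropped, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$reason, "missing_endpoint_sd")

  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(study = "trial_name", n_int = "N1"), ypath)
  map <- read_mapping_yaml(ypath)
  expect_equal(unname(map["study"]), "trial_name")
  expect_equal(unname(map["n_int"]), "N1")
  expect_equal(unname(map["sd_ep_int"]), "sd_arm1")  # untouched default
})
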