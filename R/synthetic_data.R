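# Synthetic randomized-trial generator with known ground truth. Individual
# participant data follow the ANCOVA-compatible data-generating process
#   X ~ N(mu_bl, sigma_bl^2),  Y = alpha + beta X + eps - theta_i sigma_ep T,
# with beta = rho sigma_ep / sigma_bl and Var(eps) = sigma_ep^2 (1 - rho^2),
# so that corr(X, Y) = rho, Var(Y) = sigma_ep^2, and the true endpoint SMD of
# study i is theta_i = theta + N(0, tau_between^2). Lower scores mean fewer
# symptoms unless `higher_is_better` is set. Multiple instruments per study
# are correlated re-measurements sharing a latent subject factor, so their
# effect estimates are correlated across instruments (approximately by
# `instrument_cor`), each carrying its own effect shift N(0, tau_within^2).

#' Configuration for the synthetic trial generator
#'
#' Defaults describe a plausible depression-psychotherapy trial corpus:
#' baseline severity 24 (SD 8) on a BDI-like scale, per-arm sample sizes
#' log-normal with median 40, control-group improvement of 4 points, true
#' endpoint SMD 0.5 with between-study SD 0.2 and within-study
#' (instrument-level) SD 0.1, pre-post correlation 0.5, and two instruments
#' per study correlated at 0.6 (matching the sampling correlation assumed in
#' pooling). See the methods vignette for the rationale of each value.
#'
#' @param k_studies number of trials.
#' @param theta true endpoint SMD (positive = intervention better).
#' @param tau_between between-study SD of true effects.
#' @param tau_within within-study (between-instrument) SD of true effects.
#' @param rho_prepost true pre-post correlation, in (-1, 1).
#' @param mu_bl,sigma_bl baseline mean and SD (scale units).
#' @param sigma_ep endpoint SD; `NULL` (default) uses `sigma_bl`.
#' @param ctrl_improvement mean pre-to-post improvement in the control arm
#'   (scale units).
#' @param n_median,n_sdlog per-arm sample sizes are drawn log-normal with
#'   this median and log-SD (minimum 10); set `n_sdlog = 0` for fixed n.
#' @param instruments_per_study instruments (effect sizes) per trial; a
#'   length-2 vector gives a uniform range.
#' @param instrument_cor correlation between instrument measurements of the
#'   same subject (drives the sampling correlation of within-study effects).
#' @param p_missing_sd_bl probability a comparison loses its baseline SDs
#'   (triggering the eligibility filter).
#' @param p_change_only probability a comparison reports only change scores.
#' @param higher_is_better orientation of the outcome scale.
#' @param seed integer master seed; every study uses a derived substream so
#'   changing `k_studies` does not reshuffle earlier studies.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(k_studies = 200, theta = 0.5, tau_between = 0.2,
                              tau_within = 0.1, rho_prepost = 0.5,
                              mu_bl = 24, sigma_bl = 8, sigma_ep = NULL,
                              ctrl_improvement = 4,
                              n_median = 40, n_sdlog = 0.35,
                              instruments_per_study = c(1, 3),
                              instrument_cor = 0.6,
                              p_missing_sd_bl = 0, p_change_only = 0,
                              higher_is_better = FALSE, seed = 42L) {
  if (rho_prepost <= -1 || rho_prepost >= 1) {
    stop("domain error: rho_prepost must lie in (-1, 1)")
  }
  if (p_missing_sd_bl < 0 || p_missing_sd_bl > 1 ||
      p_change_only < 0 || p_change_only > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (sigma_bl <= 0) stop("sigma_bl must be positive")
  if (is.null(sigma_ep)) sigma_ep <- sigma_bl
  structure(list(
    k_studies = k_studies, theta = theta, tau_between = tau_between,
    tau_within = tau_within, rho_prepost = rho_prepost,
    mu_bl = mu_bl, sigma_bl = sigma_bl, sigma_ep = sigma_ep,
    ctrl_improvement = ctrl_improvement, n_median = n_median,
    n_sdlog = n_sdlog, instruments_per_study = instruments_per_study,
    instrument_cor = instrument_cor, p_missing_sd_bl = p_missing_sd_bl,
    p_change_only = p_change_only, higher_is_better = higher_is_better,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# derived per-study seed; keeps substreams stable when k changes
.study_seed <- function(seed, study_index) {
  as.integer((as.numeric(seed) * 1000003 + study_index * 7919) %% 2147483629)
}

.draw_n <- function(cfg) {
  if (cfg$n_sdlog == 0) return(as.integer(cfg$n_median))
  max(10L, as.integer(round(rlnorm(1, log(cfg$n_median), cfg$n_sdlog))))
}

#' Simulate individual participant data for one trial
#'
#' Generates per-subject (arm, pre, post) scores for the primary instrument
#' of study `study_index` under the configured data-generating process.
#'
#' @param cfg a [simulation_config()].
#' @param study_index study number (drives the seed substream).
#' @param n_per_arm overrides the configured sample-size draw when given.
#' @return tibble with columns `arm` (`"int"`/`"ctrl"`), `x_pre`, `y_post`;
#'   attribute `"theta_i"` holds the study's true effect.
#' @export
simulate_ipd_trial <- function(cfg, study_index = 1L, n_per_arm = NULL) {
  set.seed(.study_seed(cfg$seed, study_index))
  theta_i <- cfg$theta + rnorm(1, 0, cfg$tau_between)
  n <- if (is.null(n_per_arm)) .draw_n(cfg) else as.integer(n_per_arm)
  if (n < 2) stop("need at least 2 subjects per arm")
  rho <- cfg$rho_prepost
  beta <- rho * cfg$sigma_ep / cfg$sigma_bl
  mu_ep_ctrl <- cfg$mu_bl - cfg$ctrl_improvement
  alpha <- mu_ep_ctrl - beta * cfg$mu_bl
  sd_eps <- cfg$sigma_ep * sqrt(1 - rho^2)
  sign <- if (cfg$higher_is_better) 1 else -1
  arm <- rep(c("int", "ctrl"), each = n)
  tmt <- as.numeric(arm == "int")
  x <- rnorm(2 * n, cfg$mu_bl, cfg$sigma_bl)
  y <- alpha + beta * x + rnorm(2 * n, 0, sd_eps) +
    sign * theta_i * cfg$sigma_ep * tmt
  out <- tibble::tibble(arm = arm, x_pre = x, y_post = y)
  attr(out, "theta_i") <- theta_i
  out
}

#' ANCOVA, change-score and endpoint estimators on trial IPD
#'
#' Computes the three classical treatment-effect estimators on individual
#' participant data: the ANCOVA estimate (treatment coefficient of
#' `y ~ treatment + x`), the crude change-score estimate (between-arm
#' difference in mean `y - x`), and the endpoint estimate (between-arm
#' difference in mean `y`). All are reported on the outcome scale, oriented
#' intervention minus control.
#'
#' @param ipd tibble from [simulate_ipd_trial()].
#' @return named numeric vector `c(theta_ancova, theta_cs, theta_ep)`.
#' @export
estimators_on_ipd <- function(ipd) {
  if (length(unique(ipd$arm)) < 2) stop("both arms must be present")
  tmt <- as.numeric(ipd$arm == "int")
  fit <- lm(y_post ~ tmt + x_pre, data = ipd)
  cs <- ipd$y_post - ipd$x_pre
  c(theta_ancova = unname(coef(fit)["tmt"]),
    theta_cs = mean(cs[tmt == 1]) - mean(cs[tmt == 0]),
    theta_ep = mean(ipd$y_post[tmt == 1]) - mean(ipd$y_post[tmt == 0]))
}

# per-study aggregate rows across instruments (internal)
.simulate_study_rows <- function(cfg, study_index) {
  set.seed(.study_seed(cfg$seed, study_index))
  theta_i <- cfg$theta + rnorm(1, 0, cfg$tau_between)
  n_int <- .draw_n(cfg); n_ctrl <- .draw_n(cfg)
  p_instr <- if (length(cfg$instruments_per_study) == 2) {
    sample(cfg$instruments_per_study[1]:cfg$instruments_per_study[2], 1)
  } else as.integer(cfg$instruments_per_study)
  rho <- cfg$rho_prepost
  lam <- sqrt(cfg$instrument_cor)          # loading on the latent subject factor
  sign <- if (cfg$higher_is_better) 1 else -1
  mu_ep_ctrl <- cfg$mu_bl - cfg$ctrl_improvement

  instruments <- paste0("instr_", seq_len(p_instr))
  n_tot <- n_int + n_ctrl
  tmt <- rep(c(1, 0), c(n_int, n_ctrl))
  # latent standardized (pre, post) pair, correlation rho
  zx <- rnorm(n_tot)
  zy <- rho * zx + sqrt(1 - rho^2) * rnorm(n_tot)

  # covariates shared across instruments of a study
  rob <- sample(0:4, 1)
  attr_true <- runif(1, 0, 0.3)
  n_rand_int <- round(n_int / (1 - attr_true))
  n_rand_ctrl <- round(n_ctrl / (1 - attr_true))
  ctrl_type <- sample(c("waitlist", "care_as_usual", "other_ctrl"), 1)
  trt_type <- sample(c("cbt", "bat", "ipt", "pst"), 1)

  rows <- lapply(seq_len(p_instr), function(j) {
    theta_ij <- theta_i + if (p_instr > 1) rnorm(1, 0, cfg$tau_within) else 0
    ux <- rnorm(n_tot); uy <- rho * ux + sqrt(1 - rho^2) * rnorm(n_tot)
    xj <- cfg$mu_bl + cfg$sigma_bl * (lam * zx + sqrt(1 - lam^2) * ux)
    yj <- mu_ep_ctrl + cfg$sigma_ep * (lam * zy + sqrt(1 - lam^2) * uy) +
      sign * theta_ij * cfg$sigma_ep * tmt
    int <- tmt == 1
    tibble::tibble(
      study_id = sprintf("study_%03d", study_index),
      instrument_id = instruments[j], contrast = "vs_control",
      n_int = n_int, n_rand_int = n_rand_int,
      mean_bl_int = mean(xj[int]), sd_bl_int = sd(xj[int]),
      mean_ep_int = mean(yj[int]), sd_ep_int = sd(yj[int]),
      n_ctrl = n_ctrl, n_rand_ctrl = n_rand_ctrl,
      mean_bl_ctrl = mean(xj[!int]), sd_bl_ctrl = sd(xj[!int]),
      mean_ep_ctrl = mean(yj[!int]), sd_ep_ctrl = sd(yj[!int]),
      rob_low_count = rob, attrition = NA_real_,
      control_type = ctrl_type, treatment_type = trt_type,
      monotherapy_int = TRUE, monotherapy_ctrl = TRUE,
      has_change_scores = FALSE,
      mean_change_int = NA_real_, sd_change_int = NA_real_,
      mean_change_ctrl = NA_real_, sd_change_ctrl = NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$attrition <- pooled_attrition(out)

  # missing-summary patterns injected at the study level
  if (runif(1) < cfg$p_change_only) {
    out$mean_change_int <- out$mean_ep_int - out$mean_bl_int
    out$mean_change_ctrl <- out$mean_ep_ctrl - out$mean_bl_ctrl
    out$sd_change_int <- out$sd_ep_int
    out$sd_change_ctrl <- out$sd_ep_ctrl
    out$mean_bl_int <- out$sd_bl_int <- out$mean_ep_int <- out$sd_ep_int <- NA_real_
    out$mean_bl_ctrl <- out$sd_bl_ctrl <- out$mean_ep_ctrl <- out$sd_ep_ctrl <- NA_real_
    out$has_change_scores <- TRUE
  } else if (runif(1) < cfg$p_missing_sd_bl) {
    out$sd_bl_int <- out$sd_bl_ctrl <- NA_real_
  }
  out
}

#' Simulate an aggregate-level trial dataset
#'
#' Generates `k_studies` trials, each contributing one comparison per
#' instrument in the canonical comparison layout, with missing-summary
#' patterns injected per the configuration. Deterministic given the seed.
#'
#' @param cfg a [simulation_config()].
#' @return comparison tibble accepted by [filter_eligible()] and
#'   [smd_variant_grid()].
#' @export
simulate_aggregate_dataset <- function(cfg) {
  dplyr::bind_rows(lapply(seq_len(cfg$k_studies),
                          function(i) .simulate_study_rows(cfg, i)))
}

#' Simulate, export as CSV, and snapshot the configuration
#'
#' Writes the dataset in the canonical trial CSV dialect (readable by
#' [read_trial_data()] with [canonical_mapping()]) and a YAML snapshot of the
#' generator configuration alongside it.
#'
#' @param cfg a [simulation_config()].
#' @param out_path output CSV path.
#' @return the dataset tibble, invisibly.
#' @export
aggregate_and_export <- function(cfg, out_path) {
  data <- simulate_aggregate_dataset(cfg)
  write_trial_data(data, out_path)
  yaml::write_yaml(unclass(cfg), paste0(out_path, ".config.yaml"))
  invisible(data)
}

#' Expected SMD-variant surface over a (theta, rho) grid
#'
#' For each grid point, simulates `reps` two-arm trials, computes all four
#' SMD variants with the true correlation imputed, and tabulates their mean
#' against the closed-form large-sample predictions (endpoint-variant value
#' `theta` for EP/EP, CS/BL and CS/EP, and `theta / sqrt(2 (1 - rho))` for
#' CS/CS under equal baseline/endpoint SDs).
#'
#' @param theta_grid true-effect values.
#' @param rho_grid pre-post correlation values.
#' @param cfg base configuration (heterogeneity is switched off internally so
#'   the surface reflects the estimators, not between-study spread).
#' @param reps simulated trials per grid point.
#' @param n_per_arm per-arm sample size for the surface trials.
#' @return tibble with columns `theta`, `rho`, `variant`, `mean_smd`,
#'   `predicted`.
#' @export
divergence_surface <- function(theta_grid, rho_grid, cfg = simulation_config(),
                               reps = 50, n_per_arm = 100) {
  if (!length(theta_grid) || !length(rho_grid)) stop("grids must be non-empty")
  rows <- list()
  cell <- 0L
  for (th in theta_grid) {
    for (rho in rho_grid) {
      cell <- cell + 1L
      sub <- cfg
      sub$theta <- th; sub$rho_prepost <- rho
      sub$tau_between <- 0; sub$tau_within <- 0
      sub$instruments_per_study <- 1L
      sub$n_median <- n_per_arm; sub$n_sdlog <- 0
      sub$k_studies <- reps
      sub$seed <- .study_seed(cfg$seed, 10000L + cell)
      data <- simulate_aggregate_dataset(sub)
      es <- smd_variant_grid(data, r_grid = rho,
                             higher_is_better = cfg$higher_is_better)
      means <- tapply(es$smd, es$variant, mean)
      pred <- c(EP_EP = th, CS_BL = th, CS_EP = th,
                CS_CS = th / sqrt(2 * (1 - rho)))
      rows[[cell]] <- tibble::tibble(
        theta = th, rho = rho, variant = names(means),
        mean_smd = as.numeric(means),
        predicted = as.numeric(pred[names(means)])
      )
    }
  }
  dplyr::bind_rows(rows)
}
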