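# Independent oracles and fixture builders used across the suite.

# grid-refinement maximizer of the restricted log-likelihood of the
# one-parameter random-effects model; independent of any fitting library
reml_grid_oracle <- function(y, v, lo = 0, hi = 2, steps = 400, iters = 6) {
  rll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  for (it in seq_len(iters)) {
    g <- seq(lo, hi, length.out = steps)
    val <- vapply(g, rll, 0)
    i <- which.max(val)
    lo <- g[max(1, i - 1)]
    hi <- g[min(steps, i + 1)]
  }
  t2 <- (lo + hi) / 2
  w <- 1 / (v + t2)
  c(tau2 = t2, mu = sum(w * y) / sum(w))
}

# hand-built effect-size table (one row per study unless p > 1)
make_es <- function(smd, variance, study = NULL, instrument = NULL,
                    variant = "EP_EP", r = NA_real_) {
  k <- length(smd)
  tibble::tibble(
    study_id = if (is.null(study)) sprintf("s%03d", seq_len(k)) else study,
    instrument_id = if (is.null(instrument)) rep("i1", k) else instrument,
    contrast = "vs_control", variant = variant, assumed_r = r,
    smd = smd, variance = variance, m = 100L
  )
}

# three-level effect data with known components and correlated sampling errors
gen_three_level <- function(k, theta = 0.4, tau_b = 0.3, tau_w = 0.15,
                            rho = 0.6, seed = 5) {
  set.seed(seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    p <- sample(1:4, 1)
    th_i <- theta + rnorm(1, 0, tau_b)
    v <- runif(p, 0.02, 0.08)
    R <- matrix(rho, p, p); diag(R) <- 1
    eps <- as.numeric(t(chol(sqrt(outer(v, v)) * R)) %*% rnorm(p))
    rows[[i]] <- make_es(th_i + rnorm(p, 0, tau_w) + eps, v,
                         study = rep(sprintf("s%03d", i), p),
                         instrument = paste0("i", seq_len(p)))
  }
  dplyr::bind_rows(rows)
}

# paired bivariate study effects with known between-study covariance T
gen_pairs <- function(k, mu = c(0.5, 0.55), Tm, v_range = c(0.02, 0.08),
                      seed = 1) {
  set.seed(seed)
  u <- t(t(chol(Tm)) %*% matrix(rnorm(2 * k), 2))
  v1 <- runif(k, v_range[1], v_range[2])
  v2 <- runif(k, v_range[1], v_range[2])
  tibble::tibble(
    study_id = sprintf("s%03d", seq_len(k)),
    y_ep = mu[1] + u[, 1] + rnorm(k, 0, sqrt(v1)), v_ep = v1,
    y_cs = mu[2] + u[, 2] + rnorm(k, 0, sqrt(v2)), v_cs = v2
  )
}

# small canonical comparison table built in code
make_comparisons <- function(k = 4, seed = 99, instruments = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(k), function(i) {
    tibble::tibble(
      study_id = sprintf("fix_%02d", i),
      instrument_id = paste0("instr_", seq_len(instruments)),
      contrast = "vs_control",
      n_int = 40L + 2L * i, n_rand_int = 45L + 2L * i,
      mean_bl_int = 24 + rnorm(instruments, 0, 0.5), sd_bl_int = 8,
      mean_ep_int = 15 + rnorm(instruments, 0, 0.5), sd_ep_int = 8,
      n_ctrl = 40L, n_rand_ctrl = 44L,
      mean_bl_ctrl = 24 + rnorm(instruments, 0, 0.5), sd_bl_ctrl = 8,
      mean_ep_ctrl = 20 + rnorm(instruments, 0, 0.5), sd_ep_ctrl = 8,
      rob_low_count = (i - 1L) %% 5L, attrition = 0.1,
      control_type = "waitlist", treatment_type = "cbt",
      monotherapy_int = TRUE, monotherapy_ctrl = TRUE,
      has_change_scores = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

# Monte-Carlo sampling variances of the four SMD variants from aggregate
# summaries, using Wishart-distributed sample covariances (exact under
# bivariate normality) instead of subject-level simulation
mc_variant_variances <- function(n, rho, delta, R = 200000, sd = 8,
                                 seed = 1234) {
  set.seed(seed)
  Sigma <- matrix(c(sd^2, rho * sd^2, rho * sd^2, sd^2), 2)
  draw_arm <- function(mu_ep) {
    mb <- rnorm(R, 24, sd / sqrt(n))
    me <- mu_ep + rho * (mb - 24) + rnorm(R, 0, sd * sqrt(1 - rho^2) / sqrt(n))
    W <- rWishart(R, n - 1, Sigma / (n - 1))
    list(mb = mb, me = me, sb = sqrt(W[1, 1, ]), se = sqrt(W[2, 2, ]))
  }
  int <- draw_arm(24 - delta * sd)   # intervention endpoint lower (better)
  ctl <- draw_arm(24)
  m <- 2 * n - 2
  J <- hedges_j(m)
  pool2 <- function(s1, s2) sqrt(((n - 1) * s1^2 + (n - 1) * s2^2) / m)
  num_cs <- -((int$me - int$mb) - (ctl$me - ctl$mb))  # positive favors int
  num_ep <- -(int$me - ctl$me)
  sdcs_i <- sqrt(int$se^2 + int$sb^2 - 2 * rho * int$se * int$sb)
  sdcs_c <- sqrt(ctl$se^2 + ctl$sb^2 - 2 * rho * ctl$se * ctl$sb)
  c(EP_EP = var(J * num_ep / pool2(int$se, ctl$se)),
    CS_BL = var(J * num_cs / pool2(int$sb, ctl$sb)),
    CS_CS = var(J * num_cs / pool2(sdcs_i, sdcs_c)),
    CS_EP = var(J * num_cs / pool2(int$se, ctl$se)))
}
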