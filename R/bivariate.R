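# Bivariate random-effects meta-analysis of paired (endpoint, change-score)
# study effects. Per study i the observed pair follows
#   (y_EP, y_CS)' ~ N(mu + u_i, diag(v_EP, v_CS)),  u_i ~ N(0, T),
# with T unstructured (3 free parameters) and the within-study sampling
# covariance fixed at zero (the two estimates are treated as conditionally
# independent within a trial). Estimation is REML with the fixed effects
# profiled out by GLS; T is parameterized as (log tau_EP, log tau_CS,
# atanh r_T) so positive semidefiniteness holds by construction.

.biv_T <- function(p) {
  t1 <- exp(p[1]); t2 <- exp(p[2]); r <- tanh(p[3])
  matrix(c(t1^2, r * t1 * t2, r * t1 * t2, t2^2), 2)
}

# restricted negative log-likelihood, vectorized over studies via
# closed-form 2x2 inverses
.biv_reml_nll <- function(p, y1, y2, v1, v2) {
  Tm <- .biv_T(p)
  a <- Tm[1, 1] + v1; b <- Tm[1, 2]; d <- Tm[2, 2] + v2
  det <- a * d - b^2
  if (any(det <= 0)) return(1e10)
  i11 <- d / det; i22 <- a / det; i12 <- -b / det
  S11 <- sum(i11); S22 <- sum(i22); S12 <- sum(i12)
  Sdet <- S11 * S22 - S12^2
  if (Sdet <= 0) return(1e10)
  # GLS mean: mu = S^-1 (sum of Sigma_i^-1 y_i)
  z1 <- sum(i11 * y1 + i12 * y2); z2 <- sum(i12 * y1 + i22 * y2)
  mu1 <- (S22 * z1 - S12 * z2) / Sdet
  mu2 <- (S11 * z2 - S12 * z1) / Sdet
  r1 <- y1 - mu1; r2 <- y2 - mu2
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  0.5 * (sum(log(det)) + log(Sdet) + quad)
}

.biv_mu <- function(p, y1, y2, v1, v2) {
  Tm <- .biv_T(p)
  a <- Tm[1, 1] + v1; b <- Tm[1, 2]; d <- Tm[2, 2] + v2
  det <- a * d - b^2
  i11 <- d / det; i22 <- a / det; i12 <- -b / det
  S <- matrix(c(sum(i11), sum(i12), sum(i12), sum(i22)), 2)
  z <- c(sum(i11 * y1 + i12 * y2), sum(i12 * y1 + i22 * y2))
  mu <- solve(S, z)
  list(mu = mu, S = S)
}

# central-difference Hessian of a scalar function of a parameter vector
.fd_hessian <- function(f, p, h = 1e-4) {
  n <- length(p)
  H <- matrix(NA_real_, n, n)
  hv <- h * (1 + abs(p))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- rep(0, n); ei[i] <- hv[i]; ej[j] <- hv[j]
      H[i, j] <- H[j, i] <-
        (f(p + ei + ej) - f(p + ei - ej) - f(p - ei + ej) + f(p - ei - ej)) /
        (4 * hv[i] * hv[j])
    }
  }
  H
}

#' Pair endpoint and change-score effect estimates study by study
#'
#' Pre-aggregates the effect-size grid within studies (via
#' [aggregate_within_study()] with the given sampling correlation) separately
#' for the endpoint variant and one change-score variant, then joins studies
#' contributing both.
#'
#' @param es long effect-size tibble from [smd_variant_grid()].
#' @param variant change-score variant: `"CS_BL"`, `"CS_CS"` or `"CS_EP"`.
#' @param r assumed pre-post correlation selecting the change-score cell.
#' @param sampling_rho within-study sampling correlation for pre-aggregation.
#' @return tibble with columns `study_id`, `y_ep`, `v_ep`, `y_cs`, `v_cs`.
#' @export
make_pairs <- function(es, variant, r, sampling_rho = 0.6) {
  variant <- match.arg(variant, c("CS_BL", "CS_CS", "CS_EP"))
  ep <- aggregate_within_study(es[es$variant == "EP_EP", , drop = FALSE],
                               sampling_rho)
  cs <- aggregate_within_study(
    es[es$variant == variant & !is.na(es$assumed_r) & es$assumed_r == r, ,
       drop = FALSE], sampling_rho)
  common <- intersect(ep$study_id, cs$study_id)
  ep <- ep[match(common, ep$study_id), ]
  cs <- cs[match(common, cs$study_id), ]
  tibble::tibble(study_id = common, y_ep = ep$smd, v_ep = ep$variance,
                 y_cs = cs$smd, v_cs = cs$variance)
}

#' Bivariate random-effects fit of paired endpoint / change-score effects
#'
#' Fits the bivariate model by REML and derives the divergence slope
#' `slope = T[EP,CS] / T[EP,EP]` -- the regression coefficient of the true
#' change-score effect on the true endpoint effect implied by the fitted
#' between-study covariance `T`. Its standard error comes from the delta
#' method applied to the observed information of T's parameters. If the
#' information matrix is singular at the optimum (boundary fits), the slope
#' test falls back to a seeded parametric bootstrap.
#'
#' @param pairs tibble from [make_pairs()] (columns `y_ep`, `v_ep`, `y_cs`,
#'   `v_cs`); at least 10 studies.
#' @param variant,assumed_r optional labels stored in the fit.
#' @param boot_reps parametric-bootstrap replicates for the fallback p-value.
#' @param boot_seed seed for the bootstrap fallback.
#' @return object of class `bivariate_fit`: pooled means `mu`, covariance
#'   `T`, `slope`, `slope_se`, `p_vs_one`, the reverse slope
#'   `T[EP,CS]/T[CS,CS]` in `diagnostics`, and convergence info.
#' @export
fit_bivariate <- function(pairs, variant = NA_character_, assumed_r = NA_real_,
                          boot_reps = 2000, boot_seed = 1L) {
  k <- nrow(pairs)
  if (k < 10) stop("insufficient-data error: need >= 10 paired studies")
  y1 <- pairs$y_ep; y2 <- pairs$y_cs; v1 <- pairs$v_ep; v2 <- pairs$v_cs
  nll <- function(p) .biv_reml_nll(p, y1, y2, v1, v2)

  # moment-based start: sample covariance of the pairs minus mean sampling var
  C <- stats::cov(cbind(y1, y2))
  t1 <- sqrt(max(C[1, 1] - mean(v1), 1e-3))
  t2 <- sqrt(max(C[2, 2] - mean(v2), 1e-3))
  r0 <- max(min(C[1, 2] / (t1 * t2), 0.95), -0.95)
  lower <- c(log(1e-4), log(1e-4), atanh(-0.9999))
  upper <- c(log(50), log(50), atanh(0.9999))
  starts <- list(c(log(t1), log(t2), atanh(r0)),
                 c(log(0.3), log(0.3), atanh(0.5)),
                 c(log(0.1), log(0.1), 0))
  best <- NULL
  for (s in starts) {
    opt <- nlminb(s, nll, lower = lower, upper = upper,
                  control = list(iter.max = 500, rel.tol = 1e-12))
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  if (!is.finite(best$objective) || best$objective >= 1e10) {
    stop("numerical error: bivariate REML did not converge")
  }
  p <- best$par
  Tm <- .biv_T(p)
  mu <- .biv_mu(p, y1, y2, v1, v2)
  slope <- Tm[1, 2] / Tm[1, 1]
  slope_rev <- Tm[1, 2] / Tm[2, 2]

  # delta-method SE: slope = tanh(p3) * exp(p2 - p1)
  H <- .fd_hessian(nll, p)
  grad <- c(-slope, slope, (1 - tanh(p[3])^2) * exp(p[2] - p[1]))
  Vp <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(Vp) || any(!is.finite(Vp)) || any(diag(Vp) <= 0)
  if (!singular) {
    slope_se <- sqrt(max(as.numeric(t(grad) %*% Vp %*% grad), 0))
    singular <- !is.finite(slope_se) || slope_se == 0
  }
  boot_p <- NA_real_
  if (singular) {
    warning("singular information at optimum; using seeded parametric ",
            "bootstrap for the slope test")
    slope_se <- NA_real_
    boot_p <- .biv_boot_p(p, mu$mu, v1, v2, slope, boot_reps, boot_seed)
  }
  stat <- if (!singular) (slope - 1) / slope_se else NA_real_
  p_one <- if (!singular) 2 * pnorm(-abs(stat)) else boot_p

  structure(list(
    variant = variant, assumed_r = assumed_r,
    mu = setNames(mu$mu, c("ep", "cs")), T = Tm,
    slope = slope, slope_se = slope_se, statistic = stat, p_vs_one = p_one,
    k = k, params = p, vcov_params = if (!singular) Vp else NULL,
    diagnostics = list(slope_reverse = slope_rev,
                       tau_ep = sqrt(Tm[1, 1]), tau_cs = sqrt(Tm[2, 2]),
                       cor_T = Tm[1, 2] / sqrt(Tm[1, 1] * Tm[2, 2]),
                       convergence = best$convergence,
                       bootstrap = singular)
  ), class = "bivariate_fit")
}

# parametric bootstrap under H0: slope = 1, holding tau_CS and the fitted
# correlation structure's scale; refits each replicate and compares slopes
.biv_boot_p <- function(p, mu, v1, v2, slope_obs, B, seed) {
  Tm <- .biv_T(p)
  T0 <- Tm
  T0[1, 2] <- T0[2, 1] <- T0[1, 1]        # null: T12 = T11 -> slope 1
  cT <- T0[1, 2] / sqrt(T0[1, 1] * T0[2, 2])
  if (abs(cT) >= 1) {                      # keep the null matrix PSD
    T0[2, 2] <- T0[1, 1] * 1.0001
  }
  L <- chol(T0 + diag(1e-10, 2))
  k <- length(v1)
  set.seed(seed)
  slopes <- numeric(B)
  for (b in seq_len(B)) {
    u <- matrix(rnorm(2 * k), k, 2) %*% L
    yb1 <- mu[1] + u[, 1] + rnorm(k, 0, sqrt(v1))
    yb2 <- mu[2] + u[, 2] + rnorm(k, 0, sqrt(v2))
    opt <- nlminb(p, .biv_reml_nll, y1 = yb1, y2 = yb2, v1 = v1, v2 = v2,
                  lower = c(log(1e-4), log(1e-4), atanh(-0.9999)),
                  upper = c(log(50), log(50), atanh(0.9999)))
    Tb <- .biv_T(opt$par)
    slopes[b] <- Tb[1, 2] / Tb[1, 1]
  }
  mean(abs(slopes - 1) >= abs(slope_obs - 1))
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate fit (%s, r = %s), k = %d studies\n",
              ifelse(is.na(x$variant), "?", x$variant),
              ifelse(is.na(x$assumed_r), "-", format(x$assumed_r)), x$k))
  cat(sprintf("  mu_EP = %.3f, mu_CS = %.3f\n", x$mu[1], x$mu[2]))
  cat(sprintf("  T: tau2_EP = %.3f, tau2_CS = %.3f, cov = %.3f (cor %.3f)\n",
              x$T[1, 1], x$T[2, 2], x$T[1, 2], x$diagnostics$cor_T))
  cat(sprintf("  slope = %.3f (SE %s), p vs 1 = %.4g\n", x$slope,
              ifelse(is.na(x$slope_se), "boot", sprintf("%.3f", x$slope_se)),
              x$p_vs_one))
  invisible(x)
}

#' Wald test of the divergence slope against unity
#'
#' @param fit a `bivariate_fit`.
#' @return list with `statistic` and `p_vs_one` (two-sided Wald p; bootstrap
#'   p if the fit's information matrix was singular).
#' @export
slope_test <- function(fit) {
  list(statistic = fit$statistic, p_vs_one = fit$p_vs_one)
}

#' Moderator analysis of endpoint / change-score divergence
#'
#' Forms the within-study divergence `delta_i = y_cs - y_ep` with sampling
#' variance `v_ep + v_cs` (conditional independence) and meta-regresses it on
#' a study-level covariate with REML and the Knapp-Hartung adjustment.
#' Categorical covariates additionally get per-level pooled divergences with
#' 95% CIs and an omnibus moderation test.
#'
#' @param pairs tibble from [make_pairs()].
#' @param covariate numeric or character/factor vector aligned with `pairs`
#'   rows (one value per study).
#' @param kind `"continuous"` or `"categorical"`; guessed from the covariate
#'   type when omitted.
#' @param min_coverage minimum fraction of studies with a non-missing
#'   covariate (default 0.8); below this the analysis errors.
#' @return tibble of moderation results with attribute `"n_dropped"` (studies
#'   dropped for a missing covariate).
#' @export
divergence_moderation <- function(pairs, covariate,
                                  kind = c("auto", "continuous", "categorical"),
                                  min_coverage = 0.8) {
  kind <- match.arg(kind)
  if (length(covariate) != nrow(pairs)) {
    stop("covariate must have one value per study in `pairs`")
  }
  ok <- !is.na(covariate)
  if (mean(ok) < min_coverage) {
    stop(sprintf("covariate present for %.0f%% of studies (< %.0f%% required)",
                 100 * mean(ok), 100 * min_coverage))
  }
  n_dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  x <- covariate[ok]
  if (kind == "auto") {
    kind <- if (is.numeric(x)) "continuous" else "categorical"
  }
  delta <- pairs$y_cs - pairs$y_ep
  v <- pairs$v_ep + pairs$v_cs
  if (kind == "continuous") {
    if (var(x) == 0) stop("no-variation error: covariate is constant")
    fit <- rma(yi = delta, vi = v, mods = ~ x, method = "REML", test = "knha")
    out <- tibble::tibble(
      term = c("intercept", "slope"),
      estimate = as.numeric(fit$beta), se = fit$se,
      ci_low = fit$ci.lb, ci_high = fit$ci.ub, p = fit$pval,
      omnibus_p = fit$QMp, k = fit$k
    )
  } else {
    x <- factor(x)
    if (nlevels(x) < 2) stop("no-variation error: covariate is constant")
    omni <- rma(yi = delta, vi = v, mods = ~ x, method = "REML", test = "knha")
    rows <- lapply(levels(x), function(l) {
      idx <- x == l
      if (sum(idx) < 2) {
        return(tibble::tibble(term = l, estimate = NA_real_, se = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, omnibus_p = omni$QMp,
                              k = sum(idx)))
      }
      f <- rma(yi = delta[idx], vi = v[idx], method = "REML", test = "knha")
      tibble::tibble(term = l, estimate = as.numeric(f$beta), se = f$se,
                     ci_low = f$ci.lb, ci_high = f$ci.ub, p = f$pval,
                     omnibus_p = omni$QMp, k = sum(idx))
    })
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "kind") <- kind
  out
}

#' Scatter plot of paired effects with the fitted divergence line
#'
#' @param fit a `bivariate_fit`.
#' @param pairs the pairs the fit was computed from.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_divergence <- function(fit, pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  intercept <- fit$mu[2] - fit$slope * fit$mu[1]
  ggplot2::ggplot(pairs, ggplot2::aes(x = y_ep, y = y_cs)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = fit$slope, intercept = intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "Endpoint SMD (EP/EP)",
                  y = sprintf("Change-score SMD (%s, r = %s)", fit$variant,
                              format(fit$assumed_r)),
                  subtitle = sprintf("slope = %.3f, p vs 1 = %.3g",
                                     fit$slope, fit$p_vs_one)) +
    ggplot2::theme_minimal()
}
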