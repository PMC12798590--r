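#' @importFrom metafor rma rma.mv
NULL

.new_meta_result <- function(pooled, se, ci, i2, tau2_b, tau2_w, pi, nnt,
                             k, n_eff, model, df = NA_real_, extra = list()) {
  structure(list(
    pooled_smd = pooled, se = se, ci95 = ci, i2 = i2,
    tau2_between = tau2_b, tau2_within = tau2_w,
    tau2_total = sum(c(tau2_b, tau2_w), na.rm = TRUE),
    pi95 = pi, nnt = nnt, k_studies = k, n_effects = n_eff,
    model = model, df = df, diagnostics = extra
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Pooled SMD (%s model): %.3f (SE %.4f), 95%% CI [%.3f; %.3f]\n",
              x$model, x$pooled_smd, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  I2 = %.1f%%, tau2 between/within/total = %.3f / %s / %.3f\n",
              x$i2, x$tau2_between,
              ifelse(is.na(x$tau2_within), "-", sprintf("%.3f", x$tau2_within)),
              x$tau2_total))
  cat(sprintf("  95%% PI [%.3f; %.3f], NNT = %.2f, k = %d studies, %d effects\n",
              x$pi95[1], x$pi95[2], x$nnt, x$k_studies, x$n_effects))
  invisible(x)
}

#' @export
as.data.frame.meta_result <- function(x, ...) {
  data.frame(model = x$model, smd = x$pooled_smd, se = x$se,
             ci_low = x$ci95[1], ci_high = x$ci95[2], i2 = x$i2,
             tau2_between = x$tau2_between, tau2_within = x$tau2_within,
             tau2_total = x$tau2_total, pi_low = x$pi95[1], pi_high = x$pi95[2],
             nnt = x$nnt, k = x$k_studies, n_effects = x$n_effects)
}

# Higgins-Thompson "typical" within-study sampling variance
.typical_v <- function(v) {
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

.prediction_interval <- function(pooled, se, tau2, k) {
  if (k > 2) {
    crit <- qt(0.975, k - 2)
    pooled + c(-1, 1) * crit * sqrt(tau2 + se^2)
  } else {
    c(NA_real_, NA_real_)
  }
}

#' Convert an SMD to a number needed to treat
#'
#' Furukawa-Leucht conversion `NNT = 1 / (pnorm(d + qnorm(cer)) - cer)`,
#' where `cer` is the assumed control-group event (response) rate. For
#' `d = 0` the NNT is infinite; negative SMDs yield a negative value
#' (number needed to harm convention) unless `negative = "error"`.
#'
#' @param smd standardized mean difference (positive favors treatment).
#' @param cer control event rate in (0, 1); default 0.2.
#' @param negative `"signed"` (default) or `"error"` for `smd < 0`.
#' @return numeric NNT.
#' @export
#' @examples
#' smd_to_nnt(0.78)  # about 3.6
smd_to_nnt <- function(smd, cer = 0.2, negative = c("signed", "error")) {
  negative <- match.arg(negative)
  if (any(cer <= 0 | cer >= 1)) stop("cer must lie in (0, 1)")
  if (negative == "error" && any(smd < 0)) {
    stop("smd < 0: treatment is harmful under this sign convention")
  }
  out <- 1 / (pnorm(smd + qnorm(cer)) - cer)
  out[smd == 0] <- Inf
  out
}

#' Inverse-variance random-effects pooling (REML + Knapp-Hartung)
#'
#' Pools one estimate per study with a REML heterogeneity estimate and the
#' Knapp-Hartung adjustment for the pooled effect's standard error and CI
#' (t reference with k - 1 df). The 95% prediction interval uses a t
#' distribution with k - 2 df.
#'
#' @param es effect-size tibble with one row per study (columns `study_id`,
#'   `smd`, `variance`).
#' @param cer control event rate for the NNT conversion.
#' @param knha apply the Knapp-Hartung adjustment (default `TRUE`).
#' @param label model label stored in the result.
#' @return a `meta_result`.
#' @export
pool_random_effects <- function(es, cer = 0.2, knha = TRUE,
                                label = "aggregate") {
  if (nrow(es) < 2) stop("insufficient-data error: need at least 2 estimates")
  if (anyDuplicated(es$study_id)) {
    stop("expected one estimate per study; pre-aggregate first")
  }
  fit <- rma(yi = es$smd, vi = es$variance, method = "REML",
             test = if (knha) "knha" else "z", control = list(maxiter = 500))
  k <- fit$k
  pooled <- as.numeric(fit$beta)
  se <- fit$se
  ci <- c(fit$ci.lb, fit$ci.ub)
  tau2 <- fit$tau2
  i2 <- 100 * tau2 / (tau2 + .typical_v(es$variance))
  pi <- .prediction_interval(pooled, se, tau2, k)
  .new_meta_result(pooled, se, ci, i2, tau2_b = tau2, tau2_w = NA_real_,
                   pi = pi, nnt = smd_to_nnt(pooled, cer), k = k, n_eff = k,
                   model = label, df = k - 1,
                   extra = list(fit = fit))
}

# block-diagonal within-study sampling covariance with constant correlation
.sampling_blocks <- function(v, study, rho) {
  V <- matrix(0, length(v), length(v))
  for (s in unique(study)) {
    idx <- which(study == s)
    b <- rho * sqrt(outer(v[idx], v[idx]))
    diag(b) <- v[idx]
    ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      stop("input error: sampling covariance block not positive definite ",
           "for study ", s)
    }
    V[idx, idx] <- b
  }
  V
}

# symmetric inverse square root with PSD guard
.inv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < tol * max(e$values, tol))) return(NULL)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
}
.mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

# CR2 cluster-robust variance of the GLS intercept with Satterthwaite df.
# Phi: working (= model-implied) covariance blocks; y, study aligned.
.cr2_intercept <- function(y, study, Phi_blocks) {
  ids <- names(Phi_blocks)
  W <- lapply(Phi_blocks, solve)
  XtWX <- sum(vapply(W, sum, 0))     # X = column of ones
  B <- 1 / XtWX
  beta <- B * sum(vapply(ids, function(s) sum(W[[s]] %*% y[study == s]), 0))

  cr1_fallback <- FALSE
  u <- list()    # u_j = W_j A_j x_j B (k_j-vector), for c'B X'W A e pieces
  meat <- 0
  for (s in ids) {
    idx <- which(study == s)
    e_j <- y[idx] - beta
    Phi <- Phi_blocks[[s]]
    ones <- rep(1, length(idx))
    S_j <- Phi - B * tcrossprod(ones)       # Var(e_j) under working model
    Phih <- .mat_sqrt(Phi)
    inner <- .inv_sqrt(Phih %*% S_j %*% Phih)
    if (is.null(inner)) {
      cr1_fallback <- TRUE
      A_j <- diag(length(idx))
    } else {
      A_j <- Phih %*% inner %*% Phih
    }
    Wj <- W[[s]]
    u[[s]] <- as.numeric(Wj %*% A_j %*% ones) * B
    meat <- meat + sum(u[[s]] * e_j)^2
  }
  q <- length(ids)
  if (cr1_fallback) {
    warning("CR2 adjustment ill-conditioned for some clusters; ",
            "falling back to CR1 scaling")
    meat <- meat * q / (q - 1)
  }
  se <- sqrt(meat)

  # Satterthwaite df from the quadratic-form eigenstructure
  N <- length(y)
  Wfull <- matrix(0, N, N); Phifull <- matrix(0, N, N)
  for (s in ids) {
    idx <- which(study == s)
    Wfull[idx, idx] <- W[[s]]
    Phifull[idx, idx] <- Phi_blocks[[s]]
  }
  H <- B * matrix(rep(colSums(Wfull), N), nrow = N, byrow = TRUE)
  ImHt <- t(diag(N) - H)
  G <- matrix(0, N, q)
  for (j in seq_along(ids)) {
    idx <- which(study == ids[j])
    G[, j] <- ImHt[, idx, drop = FALSE] %*% u[[ids[j]]]
  }
  O <- t(G) %*% Phifull %*% G
  df <- sum(diag(O))^2 / sum(O^2)
  list(beta = beta, se = se, df = df)
}

#' Three-level correlated-and-hierarchical-effects (CHE) pooling
#'
#' Fits a three-level random-effects model to effect sizes clustered within
#' studies, assuming a constant sampling correlation `sampling_rho` between
#' effect sizes of the same study. Between- and within-study heterogeneity
#' components are estimated by REML (via [metafor::rma.mv()]); the pooled
#' effect's standard error uses the CR2 small-sample cluster-robust estimator
#' with Satterthwaite degrees of freedom, computed in-package.
#'
#' @param es effect-size tibble (columns `study_id`, `smd`, `variance`),
#'   possibly several rows per study.
#' @param sampling_rho assumed sampling correlation within studies, in
#'   `[0, 1)`; default 0.6.
#' @param cer control event rate for the NNT conversion.
#' @return a `meta_result` with both heterogeneity components; `i2` is the
#'   multilevel total I2 (total heterogeneity over total variance, with the
#'   Higgins-Thompson typical sampling variance).
#' @export
pool_che <- function(es, sampling_rho = 0.6, cer = 0.2) {
  if (nrow(es) < 2) stop("insufficient-data error: need at least 2 estimates")
  if (sampling_rho < 0 || sampling_rho >= 1) stop("sampling_rho must be in [0, 1)")
  dat <- data.frame(yi = es$smd, vi = es$variance,
                    study = es$study_id, esid = seq_len(nrow(es)))
  V <- .sampling_blocks(dat$vi, dat$study, sampling_rho)
  fit <- rma.mv(yi, V, random = ~ 1 | study / esid, data = dat,
                method = "REML", sparse = TRUE,
                control = list(iter.max = 1000, rel.tol = 1e-9))
  tau2_b <- fit$sigma2[1]
  tau2_w <- fit$sigma2[2]
  tau2 <- tau2_b + tau2_w

  blocks <- lapply(split(seq_len(nrow(dat)), dat$study), function(idx) {
    M <- V[idx, idx, drop = FALSE] + tau2_b + tau2_w * diag(length(idx))
    M
  })
  ord <- order(match(dat$study, names(blocks)))  # align y with block order
  rob <- .cr2_intercept(dat$yi[ord], dat$study[ord], blocks)
  pooled <- rob$beta
  se <- rob$se
  ci <- pooled + c(-1, 1) * qt(0.975, rob$df) * se
  k <- length(unique(dat$study))
  i2 <- 100 * tau2 / (tau2 + .typical_v(dat$vi))
  pi <- .prediction_interval(pooled, se, tau2, k)
  .new_meta_result(pooled, se, ci, i2, tau2_b, tau2_w, pi,
                   smd_to_nnt(pooled, cer), k = k, n_eff = nrow(es),
                   model = "che", df = rob$df,
                   extra = list(fit = fit, gls_beta = as.numeric(fit$beta)))
}

#' Pre-aggregate multiple effect sizes within studies
#'
#' Borenstein-type combination: per study the combined effect is the mean of
#' its `p` effects and the combined variance is
#' `(1/p^2) * sum_ij rho_ij sqrt(v_i v_j)` with `rho_ii = 1` and
#' `rho_ij = rho`.
#'
#' @param es effect-size tibble.
#' @param rho assumed sampling correlation within studies, in `[0, 1)`.
#' @return effect-size tibble with one row per study (the first row's
#'   metadata columns are retained; `instrument_id` becomes `"combined"` for
#'   studies that had several effects).
#' @export
aggregate_within_study <- function(es, rho = 0.6) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  split_idx <- split(seq_len(nrow(es)), es$study_id)
  rows <- lapply(split_idx, function(idx) {
    row <- es[idx[1], , drop = FALSE]
    p <- length(idx)
    if (p > 1L) {
      v <- es$variance[idx]
      R <- matrix(rho, p, p); diag(R) <- 1
      row$smd <- mean(es$smd[idx])
      row$variance <- sum(R * sqrt(outer(v, v))) / p^2
      row$instrument_id <- "combined"
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out[order(match(out$study_id, unique(es$study_id))), , drop = FALSE]
}

#' Keep only the highest or lowest effect size within each study
#'
#' Ties are broken deterministically by lexical order of `instrument_id`.
#'
#' @param es effect-size tibble.
#' @param which `"highest"` or `"lowest"`.
#' @return effect-size tibble with one row per study.
#' @export
select_extreme <- function(es, which = c("highest", "lowest")) {
  which <- match.arg(which)
  ord <- order(es$study_id,
               if (which == "highest") -es$smd else es$smd,
               es$instrument_id)
  sorted <- es[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$study_id), , drop = FALSE]
  out[order(match(out$study_id, unique(es$study_id))), , drop = FALSE]
}

#' Leave-one-out influence screening of a one-per-study effect table
#'
#' Computes leave-one-out diagnostics (studentized deleted residuals, DFFITS,
#' Cook's distance, hat values, covariance ratio, leave-one-out tau2 and Q)
#' for a REML random-effects fit and flags influential studies using the
#' usual rules of thumb: `|DFFITS| > 3 sqrt(1/(k-1))`, Cook's distance above
#' the median of a chi-square with 1 df, hat value `> 3/k`, or a studentized
#' deleted residual `|z| > 1.96` together with any of the former. Thresholds
#' are configurable.
#'
#' @param es effect-size tibble with one row per study; needs `k >= 5`.
#' @param dffits_crit,cook_crit,hat_crit,resid_crit rule-of-thumb thresholds;
#'   `NULL` selects the defaults above.
#' @return list with `kept`, `excluded` (both effect-size tibbles) and
#'   `diagnostics` (per-study tibble of all metrics and flags).
#' @export
influence_exclusion <- function(es, dffits_crit = NULL, cook_crit = NULL,
                                hat_crit = NULL, resid_crit = 1.96) {
  k <- nrow(es)
  if (k < 5) stop("insufficient-data error: need at least 5 studies")
  if (anyDuplicated(es$study_id)) {
    stop("expected one estimate per study; pre-aggregate first")
  }
  # deterministic base order so flags are invariant to input ordering
  ord <- order(es$study_id)
  eso <- es[ord, , drop = FALSE]
  fit <- rma(yi = eso$smd, vi = eso$variance, method = "REML",
             control = list(maxiter = 500))
  inf <- metafor::influence.rma.uni(fit)
  d <- inf$inf
  if (is.null(dffits_crit)) dffits_crit <- 3 * sqrt(1 / (k - 1))
  if (is.null(cook_crit)) cook_crit <- qchisq(0.5, 1)
  if (is.null(hat_crit)) hat_crit <- 3 / k
  a <- abs(d$dffits) > dffits_crit
  b <- d$cook.d > cook_crit
  cc <- d$hat > hat_crit
  dd <- abs(d$rstudent) > resid_crit & (a | b | cc)
  flag <- a | b | cc | dd
  diagnostics <- tibble::tibble(
    study_id = eso$study_id, rstudent = d$rstudent, dffits = d$dffits,
    cook_d = d$cook.d, hat = d$hat, cov_ratio = d$cov.r,
    tau2_del = d$tau2.del, q_del = d$QE.del,
    flag_dffits = a, flag_cook = b, flag_hat = cc, flag_resid = dd,
    influential = flag
  )
  list(kept = eso[!flag, , drop = FALSE],
       excluded = eso[flag, , drop = FALSE],
       diagnostics = diagnostics)
}

#' Pool an effect-size table under one of the study's pooling models
#'
#' Dispatches to the model variants examined in the analysis: `"che"`
#' (three-level model on all effects, CR2 errors), `"aggregate"`
#' (within-study pre-aggregation then REML + Knapp-Hartung), `"best_case"` /
#' `"worst_case"` (highest / lowest effect per study, then REML + KH), and
#' `"outlier_excluded"` (pre-aggregation, influence screening, then REML +
#' KH on the retained studies).
#'
#' @param es effect-size tibble for a single (variant, assumed_r) cell.
#' @param model pooling model.
#' @param sampling_rho assumed within-study sampling correlation.
#' @param cer control event rate for NNT.
#' @return a `meta_result`.
#' @export
pool_effects <- function(es, model = c("che", "aggregate", "best_case",
                                       "worst_case", "outlier_excluded"),
                         sampling_rho = 0.6, cer = 0.2) {
  model <- match.arg(model)
  if (model == "che") return(pool_che(es, sampling_rho, cer))
  sel <- switch(model,
    aggregate = aggregate_within_study(es, sampling_rho),
    best_case = select_extreme(es, "highest"),
    worst_case = select_extreme(es, "lowest"),
    outlier_excluded = aggregate_within_study(es, sampling_rho)
  )
  n_eff <- nrow(es)
  excluded <- NULL
  if (model == "outlier_excluded") {
    scr <- influence_exclusion(sel)
    sel <- scr$kept
    excluded <- scr$excluded$study_id
  }
  out <- pool_random_effects(sel, cer = cer, label = model)
  out$n_effects <- n_eff
  if (!is.null(excluded)) out$diagnostics$excluded_studies <- excluded
  out
}

#' Pool every (variant, assumed_r) cell of an effect-size grid
#'
#' @param es long effect-size tibble from [smd_variant_grid()].
#' @param models pooling models to run (see [pool_effects()]).
#' @param sampling_rho,cer passed to [pool_effects()].
#' @return tibble shaped like the study's main results table: one row per
#'   variant x assumed_r x model with pooled SMD, SE, CI, I2, heterogeneity
#'   components, prediction interval, NNT and counts.
#' @export
pool_grid <- function(es, models = "che", sampling_rho = 0.6, cer = 0.2) {
  cells <- unique(es[c("variant", "assumed_r")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- es[es$variant == cells$variant[i] &
                (is.na(es$assumed_r) == is.na(cells$assumed_r[i])) &
                (is.na(es$assumed_r) | es$assumed_r %in% cells$assumed_r[i]), ,
              drop = FALSE]
    for (mod in models) {
      res <- pool_effects(sub, mod, sampling_rho = sampling_rho, cer = cer)
      row <- as.data.frame(res)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variant = cells$variant[i], assumed_r = cells$assumed_r[i]),
        row)
    }
  }
  tibble::as_tibble(dplyr::bind_rows(rows))
}
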