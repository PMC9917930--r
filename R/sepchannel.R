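#' Estimate the consensus intra-spot correlation
#'
#' The red and green log-intensities of one spot share hybridization and
#' spot-size effects and are therefore correlated after the design effects
#' are removed. A single consensus value is used for all probes: per-probe
#' residual correlations across spots are variance-stabilized by `atanh`,
#' robustly averaged with a trimmed mean, and transformed back.
#'
#' @param channel probes x channels matrix of normalized log2 intensities
#'   (typically the offset-50 branch of [preprocess_experiment()]).
#' @param design per-channel design data frame with columns `group` and
#'   `timepoint` (one row per channel column).
#' @param trim trimming fraction of the trimmed mean.
#' @return consensus correlation in (-1, 1).
#' @export
estimate_intraspot_rho <- function(channel, design, trim = 0.1) {
  narr <- ncol(channel) / 2
  if (narr < 3) stop("need at least 3 arrays")
  if (nrow(channel) < 50) stop("need at least 50 probes")
  r <- .perprobe_spot_cor(channel, design)
  r <- r[is.finite(r)]
  tanh(mean(atanh(r), trim = trim))
}

## Per-probe within-spot residual correlations (same centering as the
## consensus estimator), untransformed and clamped away from +-1.
.perprobe_spot_cor <- function(channel, design) {
  gi <- seq(1, ncol(channel), by = 2)
  ri <- gi + 1
  G <- channel[, gi, drop = FALSE]
  R <- channel[, ri, drop = FALSE]
  cellG <- paste(design$group[gi], design$timepoint[gi])
  cellR <- paste(design$group[ri], design$timepoint[ri])
  for (cl in unique(cellG)) {
    j <- cellG == cl
    G[, j] <- G[, j, drop = FALSE] - rowMeans(G[, j, drop = FALSE])
  }
  for (cl in unique(cellR)) {
    j <- cellR == cl
    R[, j] <- R[, j, drop = FALSE] - rowMeans(R[, j, drop = FALSE])
  }
  r <- rowSums(G * R) / sqrt(rowSums(G^2) * rowSums(R^2))
  pmin(pmax(r, -0.9999), 0.9999)
}

#' Intensity-dependent consensus intra-spot correlation
#'
#' The within-spot correlation of real (and realistically simulated)
#' two-color data falls with spot intensity: additive scanner background
#' noise, which is independent between channels, dominates dim spots and
#' dilutes the shared spot effects. A single consensus value is therefore
#' anti-conservative for dim probes. This estimator smooths the
#' variance-stabilized per-probe spot correlations against average log2
#' intensity (loess on the atanh scale) and returns one consensus value
#' per probe.
#'
#' @inheritParams estimate_intraspot_rho
#' @param A per-probe average log2 intensity (e.g. `rowMeans` of the A
#'   matrix).
#' @param span loess span of the smooth.
#' @return numeric vector, one correlation in (-1, 1) per probe.
#' @export
intraspot_rho_curve <- function(channel, design, A, span = 0.4) {
  if (ncol(channel) / 2 < 3) stop("need at least 3 arrays")
  if (nrow(channel) < 50) stop("need at least 50 probes")
  r <- .perprobe_spot_cor(channel, design)
  ## probes with zero residual variance (e.g. fully tied after quantile
  ## normalization) carry no correlation information
  r[!is.finite(r)] <- 0
  fitted <- limma::loessFit(atanh(r), A, span = span)$fitted
  fitted[!is.finite(fitted)] <- 0
  tanh(pmin(pmax(fitted, -5), 5))
}

## 2x2 within-spot whitening: channels ordered (G, R) per array.
## Returns the function applied to a 2n-vector or (2n x k) matrix laid out
## with consecutive (G, R) pairs in rows.
.whiten_pairs <- function(x, rho) {
  s <- sqrt(1 - rho^2)
  gi <- seq(1, nrow(x), by = 2)
  ri <- gi + 1
  out <- x
  out[ri, ] <- (x[ri, , drop = FALSE] - rho * x[gi, , drop = FALSE]) / s
  out
}

#' Generalized least squares for one probe's channel observations
#'
#' Fits the channel observations of a single probe by GLS with a
#' block-diagonal correlation structure: the two channels of one spot have
#' correlation `rho`, distinct spots are independent. Implemented by
#' whitening each 2x2 block and solving ordinary least squares on the
#' transformed system.
#'
#' @param y numeric vector of length `2 * n_arrays`, ordered as
#'   consecutive (green, red) pairs per array.
#' @param X design matrix with `length(y)` rows (e.g. group-cell
#'   indicators).
#' @param rho intra-spot correlation in (-1, 1).
#' @return list with `coefficients`, `s2` (residual variance), `df`
#'   (residual degrees of freedom) and `cov_unscaled`
#'   (`(X' Sigma^-1 X)^-1`, to be scaled by the variance).
#' @export
fit_probe_gls <- function(y, X, rho) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X are incompatible")
  if (length(y) %% 2 != 0) stop("observations must come in channel pairs")
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)")
  ys <- .whiten_pairs(cbind(y), rho)
  Xs <- .whiten_pairs(X, rho)
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) {
    bad <- colnames(Xs)[setdiff(seq_len(ncol(Xs)), qx$pivot[seq_len(qx$rank)])]
    stop("design is rank deficient; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, ys)
  res <- ys - Xs %*% beta
  df <- length(y) - ncol(Xs)
  s2 <- sum(res^2) / df
  xtx_inv <- solve(crossprod(Xs))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       s2 = s2, df = df, cov_unscaled = xtx_inv)
}

## Vectorized GLS over all probes: same whitened design, multivariate lm.
## Returns coefficients (p x probes), s2, df, cov_unscaled.
.fit_all_gls <- function(channel, X, rho) {
  Xs <- .whiten_pairs(as.matrix(X), rho)
  Ys <- .whiten_pairs(t(channel), rho)
  fit <- stats::lm.fit(Xs, Ys)
  df <- nrow(Xs) - fit$rank
  s2 <- colSums(fit$residuals^2) / df
  xtx_inv <- solve(crossprod(Xs))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coefficients = fit$coefficients, s2 = s2, df = df,
       cov_unscaled = xtx_inv)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates a scaled inverse-chi-square prior (prior degrees of freedom
#' `d0`, prior variance `s0^2`) by matching moments of `log s^2` and
#' shrinks each probe's variance towards the prior:
#' `s2_tilde = (d0 s0^2 + df s^2) / (d0 + df)`. Moderated t-statistics
#' gain `d0` degrees of freedom. If the variances are essentially
#' constant, `d0 = Inf` and `s2_tilde` equals the common value.
#'
#' @param s2 per-probe residual variances (>= 100 values for a stable
#'   prior).
#' @param df residual degrees of freedom (scalar or per-probe).
#' @param covariate optional per-probe covariate (average log2 intensity);
#'   when supplied the prior variance follows a smooth trend in it,
#'   restoring exchangeability when residual variance depends on
#'   intensity. The prior degrees of freedom stay scalar.
#' @return list with `d0`, `s0_2` (scalar, or per-probe under a trend),
#'   `s2_tilde` and `df_total = df + d0`.
#' @export
moderate_variances <- function(s2, df, covariate = NULL) {
  if (length(s2) < 100) stop("need at least 100 probes for prior estimation")
  sq <- limma::squeezeVar(s2, df, covariate = covariate)
  d0 <- sq$df.prior
  list(d0 = d0, s0_2 = sq$var.prior, s2_tilde = sq$var.post,
       df_total = df + d0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; ties and input
#' order are preserved.
#'
#' @param p raw p-values in [0, 1].
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Build the group-cell design matrix for channel observations.
.cell_design <- function(design) {
  cells <- paste(design$group, design$timepoint, sep = ".")
  lev <- unique(cells)
  X <- outer(cells, lev, "==") * 1
  colnames(X) <- lev
  X
}

#' Differential-expression contrasts by separate-channel analysis
#'
#' Fits a group-cell means model (group x timepoint) to the channel
#' observations of every probe by GLS with intra-spot correlation, then
#' tests six contrasts: treated vs control at each time point, and the
#' within-control time contrasts (later minus earlier). Per the two-branch
#' normalization, log2 fold changes are taken from the offset-0 data while
#' the moderated test statistics and p-values come from the offset-50
#' data. BH adjustment is applied within each contrast.
#'
#' @param prep a `cd_prep` object from [preprocess_experiment()] holding
#'   both `offset0` and `offset50` branches.
#' @param rho intra-spot correlation. `NULL` (the default) uses the
#'   intensity-stratified consensus: per-probe correlations are smoothed
#'   against average log2 intensity ([intraspot_rho_curve()]) and probes
#'   are fitted in intensity strata, each with its stratum consensus; a
#'   scalar forces one common correlation for all probes.
#' @param alpha adjusted-p significance threshold.
#' @param n_strata number of intensity strata for the stratified fit.
#' @param trend use an intensity-dependent prior variance in the
#'   empirical-Bayes moderation (residual variance of two-color data
#'   falls with intensity even after the offset).
#' @return object of class `cd_detest`: list with `results` (long data
#'   frame: `probe_id, contrast, logFC, mean_ctrl, mean_trt, s2, s2_tilde,
#'   t, df, p, p_adj, sig`), `rho` (consensus scalar), `rho_probe`
#'   (per-probe values used), `moderation` (prior parameters) and
#'   `design`.
#' @export
run_contrasts <- function(prep, rho = NULL, alpha = 0.05, n_strata = 10,
                          trend = TRUE) {
  if (is.null(prep$offset0) || is.null(prep$offset50))
    stop("both offset-0 and offset-50 normalized data are required")
  design <- prep$design
  tps <- unique(design$timepoint)
  if (length(tps) != 3) stop("expected three time points in the design")
  X <- .cell_design(design)
  np <- length(prep$probe_id)
  A <- rowMeans(prep$offset50$A)

  rho_consensus <- estimate_intraspot_rho(prep$offset50$channel, design)
  if (is.null(rho)) {
    rho_probe <- intraspot_rho_curve(prep$offset50$channel, design, A)
    qs <- unique(stats::quantile(A, seq(0, 1, length.out = n_strata + 1)))
    strata <- cut(A, qs, include.lowest = TRUE)
  } else {
    rho_probe <- rep(rho, np)
    rho_consensus <- rho
    strata <- factor(rep(1, np))
  }

  ## contrasts: treated-vs-control per time point; control later-vs-earlier
  cmat <- list()
  for (t in tps)
    cmat[[paste0("cort_vs_ctrl_", t)]] <-
      c(paste0("cort.", t), paste0("control.", t))
  time_pairs <- list(c("h5", "h1"), c("h9", "h1"), c("h9", "h5"))
  for (pr in time_pairs)
    cmat[[paste0("ctrl_", pr[1], "_vs_", pr[2])]] <-
      c(paste0("control.", pr[1]), paste0("control.", pr[2]))

  ## stratified GLS: one whitened fit per intensity stratum, with the
  ## stratum's consensus correlation
  est0 <- est50 <- matrix(NA_real_, np, length(cmat),
                          dimnames = list(prep$probe_id, names(cmat)))
  vfac <- est50
  s2 <- numeric(np)
  df <- NA_integer_
  rho_used <- numeric(np)
  for (b in levels(strata)) {
    idx <- which(strata == b)
    rb <- tanh(mean(atanh(rho_probe[idx])))
    if (!is.finite(rb)) rb <- rho_consensus
    rho_used[idx] <- rb
    f0 <- .fit_all_gls(prep$offset0$channel[idx, , drop = FALSE], X, rb)
    f5 <- .fit_all_gls(prep$offset50$channel[idx, , drop = FALSE], X, rb)
    s2[idx] <- f5$s2
    df <- f5$df
    for (nm in names(cmat)) {
      plus <- cmat[[nm]][1]; minus <- cmat[[nm]][2]
      est0[idx, nm] <- f0$coefficients[plus, ] - f0$coefficients[minus, ]
      est50[idx, nm] <- f5$coefficients[plus, ] - f5$coefficients[minus, ]
      vfac[idx, nm] <- f5$cov_unscaled[plus, plus] +
        f5$cov_unscaled[minus, minus] - 2 * f5$cov_unscaled[plus, minus]
    }
  }
  mod <- moderate_variances(s2, df, covariate = if (trend) A else NULL)

  ## raw-scale group mean intensities (offset-0 channels) per design cell
  cells <- paste(design$group, design$timepoint, sep = ".")
  raw <- 2^prep$offset0$channel
  cellmean <- sapply(unique(cells), function(cl)
    rowMeans(raw[, cells == cl, drop = FALSE]))

  res <- list()
  for (nm in names(cmat)) {
    plus <- cmat[[nm]][1]; minus <- cmat[[nm]][2]
    tstat <- est50[, nm] / sqrt(mod$s2_tilde * vfac[, nm])
    dft <- mod$df_total
    p <- 2 * stats::pt(-abs(tstat), df = dft)
    p_adj <- bh_adjust(p)
    res[[nm]] <- data.frame(
      probe_id = prep$probe_id, contrast = nm,
      logFC = est0[, nm],
      mean_ctrl = cellmean[, minus],
      mean_trt = cellmean[, plus],
      s2 = s2, s2_tilde = mod$s2_tilde,
      t = tstat, df = if (length(dft) == 1) rep(dft, np) else dft,
      p = p, p_adj = p_adj, sig = p_adj < alpha,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, res), rho = rho_consensus,
                 rho_probe = rho_used,
                 moderation = list(d0 = mod$d0,
                                   s0_2 = if (length(mod$s0_2) == 1)
                                     mod$s0_2 else mean(mod$s0_2)),
                 design = design, alpha = alpha),
            class = "cd_detest")
}

#' @export
print.cd_detest <- function(x, ...) {
  cat("Separate-channel differential expression\n")
  cat(sprintf("  probes: %d   contrasts: %d   rho: %.3f\n",
              length(unique(x$results$probe_id)),
              length(unique(x$results$contrast)), x$rho))
  cat(sprintf("  moderation: d0 = %.2f, s0^2 = %.4g\n",
              x$moderation$d0, x$moderation$s0_2))
  tab <- tapply(x$results$sig, x$results$contrast, sum)
  cat("  significant probes (adj p <", x$alpha, "):\n")
  for (nm in names(tab)) cat(sprintf("    %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}
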