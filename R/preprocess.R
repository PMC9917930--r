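#' Normexp background correction
#'
#' Models the background-subtracted intensity of each spot as the sum of a
#' normal background component `N(mu, sigma^2)` and an exponential true
#' signal with mean `alpha`, fits (mu, sigma, alpha) by maximum likelihood
#' and returns the posterior expected signal `E[S | X = x]`, which is
#' strictly positive for every spot.
#'
#' @param fg,bg foreground and background intensity vectors (same length,
#'   finite, >= 0).
#' @param tol convergence tolerance passed to the likelihood optimizer.
#' @return numeric vector of corrected intensities, all > 0.
#' @seealso [normexp_signal()] for the conditional expectation at fixed
#'   parameters.
#' @export
normexp_correct <- function(fg, bg, tol = 1e-8) {
  if (length(fg) != length(bg)) stop("fg and bg must have equal length")
  if (length(fg) < 10) stop("need at least 10 spots to estimate parameters")
  if (!all(is.finite(fg)) || !all(is.finite(bg)))
    stop("intensities must be finite")
  x <- fg - bg
  if (stats::sd(x) < .Machine$double.eps^0.5)
    stop("degenerate (constant) intensities: cannot fit the normexp model")
  fit <- limma::normexp.fit(x, method = "mle")
  out <- limma::normexp.signal(fit$par, x)
  pmax(out, .Machine$double.xmin)
}

#' Normexp posterior expected signal at fixed parameters
#'
#' `E[S | X = x]` for `X = S + B`, `S ~ Exp(mean alpha)`,
#' `B ~ N(mu, sigma^2)`.
#'
#' @param mu,sigma,alpha model parameters (`sigma`, `alpha` > 0).
#' @param x observed (background-subtracted) intensities.
#' @export
normexp_signal <- function(mu, sigma, alpha, x) {
  stopifnot(sigma > 0, alpha > 0)
  limma::normexp.signal(c(mu, log(sigma), log(alpha)), x)
}

#' M/A values from corrected channel intensities
#'
#' `M = log2((R + offset) / (G + offset))`,
#' `A = (log2(R + offset) + log2(G + offset)) / 2`. The offset (50 by
#' default in the testing branch of the pipeline) damps the variance of
#' log-ratios of dim spots; fold changes are computed at offset 0.
#'
#' @param R,G corrected red/green intensities (> 0, or > -offset).
#' @param offset non-negative intensity offset.
#' @return data frame with columns `M`, `A`.
#' @export
compute_ma <- function(R, G, offset = 0) {
  if (offset < 0) stop("offset must be >= 0")
  if (any(R + offset <= 0) || any(G + offset <= 0))
    stop("offset intensities must be positive")
  lr <- log2(R + offset)
  lg <- log2(G + offset)
  data.frame(M = lr - lg, A = (lr + lg) / 2)
}

#' Recover single-channel intensities from M and A
#'
#' Exact inverse of [compute_ma()] at offset 0:
#' `R = 2^(A + M/2)`, `G = 2^(A - M/2)` (equivalently `G = R / 2^M`).
#'
#' @param M,A finite M/A vectors.
#' @return data frame with columns `R`, `G` (raw scale, > 0).
#' @export
decompose_channels <- function(M, A) {
  if (!all(is.finite(M)) || !all(is.finite(A))) stop("M and A must be finite")
  data.frame(R = 2^(A + M / 2), G = 2^(A - M / 2))
}

#' Within-array loess normalization of M on A
#'
#' Replaces M by the residual of a robustified local regression of M on A,
#' removing intensity-dependent dye bias. A is unchanged.
#'
#' @param M,A per-spot M/A values of one array (>= 30 spots).
#' @param span loess span in (0, 1].
#' @param iterations robustifying iterations.
#' @return numeric vector of normalized M values.
#' @export
loess_normalize <- function(M, A, span = 0.3, iterations = 4) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(M) < 30) stop("need at least 30 spots for loess normalization")
  fit <- limma::loessFit(M, A, span = span, iterations = iterations)
  M - fit$fitted
}

#' Between-array quantile normalization
#'
#' Forces every column (array/channel) to the same distribution: the mean
#' of the sorted columns. Rank order within each column is preserved.
#'
#' @param x numeric matrix, probes in rows, arrays (or channels) in
#'   columns; at least 2 columns, no missing values.
#' @return matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 arrays")
  if (anyNA(x)) stop("missing values are not supported")
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Full preprocessing of a simulated (or read-in) experiment
#'
#' Per array: normexp background correction of each channel, M/A
#' computation at the requested offset, within-array loess normalization.
#' Across arrays: decomposition into single-channel log2 intensities and
#' between-array quantile normalization of the pooled channel matrix (both
#' channels of every array stacked as columns). Technical copies of
#' multi-copy probes are averaged into one value per array before the
#' channel matrix is formed.
#'
#' Two parallel normalized datasets are typically produced: offset 0 (fold
#' changes and reported intensities) and offset 50 (test statistics); see
#' `offsets`.
#'
#' @param x list with `arrays` and `design` as produced by
#'   [simulate_experiment()] or [read_experiment()].
#' @param offsets numeric vector of offsets to process.
#' @param span,iterations loess settings, see [loess_normalize()].
#' @return object of class `cd_prep`: list with `design` (per-channel
#'   design: `array, dye, group, timepoint`), `probe_id`, and one element
#'   per offset named `offset<k>`, each a list with `channel` (probes x
#'   channels matrix of normalized log2 single-channel intensities), `M`
#'   and `A` matrices (probes x arrays).
#' @export
preprocess_experiment <- function(x, offsets = c(0, 50), span = 0.3,
                                  iterations = 4) {
  arrays <- x$arrays
  adesign <- x$design
  narr <- length(arrays)
  probe_ids <- sort(unique(arrays[[1]]$probe_id))
  np <- length(probe_ids)

  ## background-correct once per array, reuse for all offsets
  corrected <- lapply(arrays, function(tab) {
    list(R = normexp_correct(tab$r_fg, tab$r_bg),
         G = normexp_correct(tab$g_fg, tab$g_bg),
         probe_id = tab$probe_id)
  })

  chan_design <- data.frame(
    array = rep(adesign$array, each = 2),
    dye = rep(c("G", "R"), narr),
    group = rep(c("control", "cort"), narr),
    timepoint = rep(adesign$timepoint, each = 2),
    stringsAsFactors = FALSE)
  chan_design$channel <- paste(chan_design$array, chan_design$dye, sep = ".")

  out <- list(design = chan_design, probe_id = probe_ids)
  for (off in offsets) {
    Mmat <- matrix(NA_real_, np, narr,
                   dimnames = list(probe_ids, adesign$array))
    Amat <- Mmat
    for (a in seq_len(narr)) {
      ca <- corrected[[a]]
      ma <- compute_ma(ca$R, ca$G, offset = off)
      m_norm <- loess_normalize(ma$M, ma$A, span = span,
                                iterations = iterations)
      ## average technical copies on the M/A scale
      Mmat[, a] <- rowsum(m_norm, ca$probe_id)[probe_ids, 1] /
        tabulate(factor(ca$probe_id, levels = probe_ids))
      Amat[, a] <- rowsum(ma$A, ca$probe_id)[probe_ids, 1] /
        tabulate(factor(ca$probe_id, levels = probe_ids))
    }
    chan <- matrix(NA_real_, np, 2 * narr,
                   dimnames = list(probe_ids, chan_design$channel))
    for (a in seq_len(narr)) {
      dc <- decompose_channels(Mmat[, a], Amat[, a])
      chan[, 2 * a - 1] <- log2(dc$G)
      chan[, 2 * a]     <- log2(dc$R)
    }
    chan <- quantile_normalize(chan)
    out[[paste0("offset", off)]] <- list(channel = chan, M = Mmat, A = Amat)
  }
  class(out) <- "cd_prep"
  out
}
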