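# Independent oracles, deliberately naive: each recomputes the quantity
# from first principles through a different route than the implementation.

# GLS by explicit matrix algebra: beta = (X' S^-1 X)^-1 X' S^-1 y with the
# full block-diagonal correlation matrix built out.
gls_oracle <- function(y, X, rho) {
  n <- length(y)
  S <- diag(n)
  for (i in seq(1, n, by = 2)) {
    S[i, i + 1] <- rho
    S[i + 1, i] <- rho
  }
  Si <- solve(S)
  V <- solve(t(X) %*% Si %*% X)
  beta <- V %*% t(X) %*% Si %*% y
  res <- y - X %*% beta
  df <- n - ncol(X)
  s2 <- drop(t(res) %*% Si %*% res) / df
  list(coefficients = drop(beta), s2 = s2, df = df, cov_unscaled = V)
}

# E[S | X = x] for X = S + B, S ~ Exp(mean alpha), B ~ N(mu, sigma^2),
# by numerical quadrature over the joint density.
normexp_quad_oracle <- function(mu, sigma, alpha, x) {
  vapply(x, function(xi) {
    f <- function(s) exp(-s / alpha) * dnorm(xi - s, mu, sigma)
    ## posterior mass sits near s = x - mu; integrate a wide finite
    ## window around it (quadrature over [0, Inf) misses narrow peaks)
    lo <- max(0, xi - mu - 15 * sigma)
    hi <- max(xi - mu + 15 * sigma, 15 * sigma)
    num <- integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-10)$value
    den <- integrate(f, lo, hi, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

# Benjamini-Hochberg step-up by hand.
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Directly simulated channel matrices (probes x 2*narr, G/R interleaved)
# with a known within-spot correlation, bypassing the intensity model.
simulate_channels <- function(n_probes, narr, rho, timepoints = 3,
                              probe_sd = 1, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  base <- rnorm(n_probes, 8, probe_sd)
  chan <- matrix(NA_real_, n_probes, 2 * narr)
  for (a in seq_len(narr)) {
    zg <- rnorm(n_probes)
    zr <- rho * zg + sqrt(1 - rho^2) * rnorm(n_probes)
    chan[, 2 * a - 1] <- base + noise_sd * zg
    chan[, 2 * a]     <- base + noise_sd * zr
  }
  tp <- sort(rep_len(paste0("t", seq_len(timepoints)), narr))
  design <- data.frame(
    array = rep(sprintf("a%02d", seq_len(narr)), each = 2),
    dye = rep(c("G", "R"), narr),
    group = rep(c("control", "cort"), narr),
    timepoint = rep(tp, each = 2),
    stringsAsFactors = FALSE)
  colnames(chan) <- paste(design$array, design$dye, sep = ".")
  list(channel = chan, design = design)
}

# A small fully-processed experiment reused across tests.
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_probes = 1200, effect_size_log2 = 2,
                        pattern_fractions = c(LONG_LASTING = 0.02,
                                              INTERMEDIATE = 0.02,
                                              SHORT = 0.02,
                                              REVERSAL = 0.01,
                                              SECONDARY = 0.02,
                                              "NULL" = 0.91),
                        seed = 42)
      sim <- simulate_experiment(cfg)
      prep <- preprocess_experiment(sim)
      de <- run_contrasts(prep)
      cache <<- list(cfg = cfg, sim = sim, prep = prep, de = de)
    }
    cache
  }
})
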