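test_that("GLS reduces to ordinary group means and pooled SE at rho = 0", {
  set.seed(5)
  n <- 6
  y <- rnorm(2 * n, 8)
  X <- cbind(ctrl = rep(c(1, 0), n), trt = rep(c(0, 1), n))
  fit <- fit_probe_gls(y, X, rho = 0)
  g <- y[seq(1, 2 * n, 2)]; r <- y[seq(2, 2 * n, 2)]
  expect_equal(unname(fit$coefficients), c(mean(g), mean(r)),
               tolerance = 1e-12)
  pooled <- ((n - 1) * var(g) + (n - 1) * var(r)) / (2 * n - 2)
  se_gls <- sqrt(fit$s2 * (fit$cov_unscaled["ctrl", "ctrl"] +
                             fit$cov_unscaled["trt", "trt"]))
  expect_equal(se_gls, sqrt(pooled * 2 / n), tolerance = 1e-12)
})

test_that("GLS matches the explicit matrix-algebra oracle", {
  set.seed(8)
  for (rho in c(0.5, -0.3, 0.85)) {
    y <- rnorm(4, 10)
    X <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1))
    got <- fit_probe_gls(y, X, rho)
    want <- gls_oracle(y, X, rho)
    expect_equal(got$coefficients, want$coefficients, tolerance = 1e-10)
    expect_equal(got$s2, want$s2, tolerance = 1e-10)
    expect_equal(got$cov_unscaled, want$cov_unscaled, tolerance = 1e-10)
    # and a larger balanced case
    y2 <- rnorm(12)
    X2 <- cbind(g1 = rep(c(1, 0), 6),
                g2 = rep(c(0, 1), 6))
    got2 <- fit_probe_gls(y2, X2, rho)
    want2 <- gls_oracle(y2, X2, rho)
    expect_equal(got2$coefficients, want2$coefficients, tolerance = 1e-10)
    expect_equal(got2$s2, want2$s2, tolerance = 1e-10)
  }
})

test_that("GLS group difference is translation invariant and rank checked", {
  set.seed(9)
  y <- rnorm(8)
  X <- cbind(a = rep(c(1, 0), 4), b = rep(c(0, 1), 4))
  f1 <- fit_probe_gls(y, X, 0.6)
  f2 <- fit_probe_gls(y + 5, X, 0.6)
  d1 <- f1$coefficients["a"] - f1$coefficients["b"]
  d2 <- f2$coefficients["a"] - f2$coefficients["b"]
  expect_equal(d1, d2, tolerance = 1e-12)
  Xbad <- cbind(X, both = X[, 1] + X[, 2])
  expect_error(fit_probe_gls(y, Xbad, 0.5), "rank deficient")
})

test_that("consensus intra-spot correlation is recovered from channel data", {
  # duplicated channels: correlation saturates
  sim <- simulate_channels(300, 9, 0)
  dup <- sim$channel
  dup[, seq(2, ncol(dup), 2)] <- dup[, seq(1, ncol(dup), 2)]
  expect_gte(estimate_intraspot_rho(dup, sim$design), 0.99)
  # independent channels: near zero at many probes
  sim0 <- simulate_channels(5000, 9, 0, seed = 3)
  expect_lt(abs(estimate_intraspot_rho(sim0$channel, sim0$design)), 0.05)
  # known correlation recovered
  for (rho in c(0.5, 0.7, 0.9)) {
    s <- simulate_channels(2000, 9, rho, seed = 4)
    expect_lt(abs(estimate_intraspot_rho(s$channel, s$design) - rho), 0.1)
  }
  expect_error(estimate_intraspot_rho(sim$channel[, 1:4], sim$design[1:4, ]),
               "3 arrays")
})

test_that("consensus correlation agrees with the established two-color toolchain", {
  s <- simulate_channels(1000, 9, 0.7, seed = 6)
  gi <- seq(1, ncol(s$channel), 2)
  ma <- list(M = s$channel[, gi + 1] - s$channel[, gi],
             A = (s$channel[, gi + 1] + s$channel[, gi]) / 2)
  # channel-level cell-means design, rows ordered (G, R) per array
  dsn <- cortidecay:::.cell_design(s$design)
  ref <- suppressWarnings(
    limma::intraspotCorrelation(ma, dsn))$consensus.correlation
  got <- estimate_intraspot_rho(s$channel, s$design)
  expect_lt(abs(got - ref), 0.05)
})

test_that("variance moderation shrinks towards a recoverable prior", {
  set.seed(10)
  d0 <- 4; s0 <- 1; df <- 10
  s2 <- s0 * d0 / rchisq(10000, d0) * rchisq(10000, df) / df
  mod <- moderate_variances(s2, df)
  expect_gt(mod$d0, 2.5); expect_lt(mod$d0, 6)
  expect_lt(abs(mod$s0_2 - s0) / s0, 0.1)
  # shrinkage identity
  expect_equal(mod$s2_tilde,
               (mod$d0 * mod$s0_2 + df * s2) / (mod$d0 + df),
               tolerance = 1e-8)
  # moderated value lies between the observed variance and the prior
  expect_true(all(mod$s2_tilde >= pmin(s2, mod$s0_2) - 1e-12))
  expect_true(all(mod$s2_tilde <= pmax(s2, mod$s0_2) + 1e-12))
  # identical variances: infinite prior df, no change
  modc <- moderate_variances(rep(2, 200), df)
  expect_equal(unname(modc$s2_tilde), rep(2, 200))
  expect_error(moderate_variances(s2[1:50], df), "100 probes")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, bh_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # order invariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), adj[o])
    # monotone in raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  sr <- small_run()
  prep <- sr$prep
  swapped <- prep
  swapped$design$group <- ifelse(prep$design$group == "cort",
                                 "control", "cort")
  a <- run_contrasts(prep, rho = 0.6)
  b <- run_contrasts(swapped, rho = 0.6)
  ra <- a$results[a$results$contrast == "cort_vs_ctrl_h1", ]
  rb <- b$results[b$results$contrast == "cort_vs_ctrl_h1", ]
  expect_equal(rb$logFC, -ra$logFC, tolerance = 1e-10)
  expect_equal(rb$p, ra$p, tolerance = 1e-10)
})

test_that("separate-channel fit agrees with the established implementation", {
  # independent cross-check of the whole moderated pipeline on one branch
  sr <- small_run()
  prep <- sr$prep
  gi <- seq(1, ncol(prep$offset50$channel), 2)
  M <- prep$offset50$channel[, gi + 1] - prep$offset50$channel[, gi]
  A <- (prep$offset50$channel[, gi + 1] + prep$offset50$channel[, gi]) / 2
  ma <- list(M = M, A = A)
  X <- cortidecay:::.cell_design(prep$design)
  rho <- sr$de$rho
  fit <- limma::lmscFit(ma, X, correlation = rho)
  est_ref <- fit$coefficients[, "cort.h1"] -
    fit$coefficients[, "control.h1"]
  s2_ref <- fit$sigma^2
  f50 <- cortidecay:::.fit_all_gls(prep$offset50$channel, X, rho)
  est_ours <- f50$coefficients["cort.h1", ] -
    f50$coefficients["control.h1", ]
  expect_equal(unname(est_ours), unname(est_ref), tolerance = 1e-8)
  expect_equal(unname(f50$s2), unname(s2_ref), tolerance = 1e-8)
})

test_that("the global null keeps the realized false-positive proportion at bay", {
  # null experiments at the default generator conditions; per-contrast
  # false-discovery proportion V / max(R, 1)
  nrep <- 12
  fdp <- c()
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_probes = 1000, pattern_fractions = c("NULL" = 1),
                      seed = 1000 + i)
    sim <- simulate_experiment(cfg)
    prep <- preprocess_experiment(sim)
    de <- run_contrasts(prep)
    r <- de$results[grepl("cort_vs_ctrl", de$results$contrast), ]
    byc <- split(r$sig, r$contrast)
    fdp <- c(fdp, vapply(byc, function(s) sum(s) / max(sum(s), 1),
                         numeric(1)))
  }
  mcse <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * max(mcse, 0.02))
  # and most null contrasts produce no discovery at all
  expect_gte(mean(fdp == 0), 0.85)
})

test_that("a strong persistent effect is detected at every time point", {
  sr <- small_run()
  truth <- sr$sim$truth
  hi_ll <- truth$pattern == "LONG_LASTING" & truth$intensity_class == "high"
  r <- sr$de$results
  ok <- rep(TRUE, sum(hi_ll))
  for (tp in c("h1", "h5", "h9")) {
    d <- r[r$contrast == paste0("cort_vs_ctrl_", tp), ]
    d <- d[match(truth$probe_id[hi_ll], d$probe_id), ]
    ok <- ok & d$sig & (sign(d$logFC) == truth$direction[hi_ll])
  }
  expect_gte(mean(ok), 0.95)
})
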