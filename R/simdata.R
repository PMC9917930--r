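## Temporal expression patterns recognised throughout the package.
## NULL probes carry no planted effect; COMPLEX arises only as a call,
## never as a planted truth.
PATTERNS <- c("LONG_LASTING", "INTERMEDIATE", "SHORT", "REVERSAL",
              "SECONDARY", "NULL")
CATEGORIES <- c(PATTERNS[1:5], "COMPLEX", "NULL")

#' Simulation configuration for a synthetic two-color time-course experiment
#'
#' Describes a corticosterone time-course: three sampling times of the light
#' phase (`h1`, `h5`, `h9`), control and treated samples co-hybridized on
#' each array (control on the green/Cy3 channel, treated on red/Cy5), eight
#' biological replicates per time point. Probe-level effects are planted as
#' log2 fold changes following one of the temporal decay patterns.
#'
#' The raw-intensity model for each spot channel is
#' `fg = N(background_mu, background_sigma^2) + S`, with true signal
#' `S = S0 * 2^(effect/channel + biological noise + array scale + dye bias)`
#' where per-probe baselines `S0` are drawn so that their marginal is a
#' mixture of exponentials (mean `signal_alpha` for the high-intensity
#' component), the structure that normexp background correction assumes.
#' Biological noise of the two channels of one spot is bivariate normal
#' with correlation `intraspot_rho`. Dye bias is a smooth cubic function of
#' average log-intensity added to M (removable by loess); array scale
#' offsets are shared by both channels of an array.
#'
#' @param n_probes number of gene-detecting probes.
#' @param pattern_fractions named proportions over
#'   `LONG_LASTING, INTERMEDIATE, SHORT, REVERSAL, SECONDARY, NULL`;
#'   must sum to 1.
#' @param effect_size_log2 planted |log2 fold change|, a single value or a
#'   named vector per non-NULL pattern.
#' @param arrays_per_timepoint biological replicates per time point (>= 2).
#' @param timepoints ordered time-point labels.
#' @param intraspot_rho residual correlation of the two channels of a spot,
#'   in [0, 1).
#' @param background_mu,background_sigma mean and sd of the additive normal
#'   background (raw fluorescence units).
#' @param signal_alpha mean of the exponential high-intensity baseline
#'   signal component (raw scale).
#' @param dye_bias_amplitude amplitude of the smooth A-dependent M offset.
#' @param array_scale_sd sd of per-array log2 scale offsets.
#' @param low_intensity_fraction fraction of probes with true baseline
#'   signal below 50 (the reporting filter cutoff).
#' @param bio_sd biological log2 sd within a group.
#' @param seed integer seed; the experiment is fully reproducible from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_probes = 2000,
                       pattern_fractions = c(LONG_LASTING = 0.065,
                                             INTERMEDIATE = 0.041,
                                             SHORT        = 0.069,
                                             REVERSAL     = 0.002,
                                             SECONDARY    = 0.114,
                                             "NULL"       = 0.709),
                       effect_size_log2 = 0.5,
                       arrays_per_timepoint = 8,
                       timepoints = c("h1", "h5", "h9"),
                       intraspot_rho = 0.7,
                       background_mu = 50,
                       background_sigma = 10,
                       signal_alpha = 1000,
                       dye_bias_amplitude = 0.2,
                       array_scale_sd = 0.1,
                       low_intensity_fraction = 0.3,
                       bio_sd = 0.25,
                       seed = 1L) {
  pf <- pattern_fractions
  if (is.null(names(pf)) || !all(names(pf) %in% PATTERNS))
    stop("pattern_fractions must be named with the known patterns")
  pf <- pf[match(PATTERNS, names(pf))]
  pf[is.na(pf)] <- 0
  names(pf) <- PATTERNS
  if (abs(sum(pf) - 1) > 1e-9)
    stop("pattern_fractions must sum to 1")
  if (any(pf < 0)) stop("pattern_fractions must be non-negative")
  if (arrays_per_timepoint < 2) stop("arrays_per_timepoint must be >= 2")
  if (intraspot_rho < 0 || intraspot_rho >= 1)
    stop("intraspot_rho must be in [0, 1)")
  if (background_sigma < 0 || array_scale_sd < 0 || bio_sd < 0)
    stop("all standard deviations must be >= 0")
  if (signal_alpha <= 0) stop("signal_alpha must be positive")
  eff <- effect_size_log2
  if (length(eff) == 1L && is.null(names(eff)))
    eff <- stats::setNames(rep(eff, 5), PATTERNS[1:5])
  if (!all(PATTERNS[1:5] %in% names(eff)))
    stop("effect_size_log2 must cover every non-NULL pattern")
  if (any(eff <= 0)) stop("effect sizes must be positive")
  structure(list(n_probes = as.integer(n_probes),
                 pattern_fractions = pf,
                 effect_size_log2 = eff[PATTERNS[1:5]],
                 arrays_per_timepoint = as.integer(arrays_per_timepoint),
                 timepoints = timepoints,
                 intraspot_rho = intraspot_rho,
                 background_mu = background_mu,
                 background_sigma = background_sigma,
                 signal_alpha = signal_alpha,
                 dye_bias_amplitude = dye_bias_amplitude,
                 array_scale_sd = array_scale_sd,
                 low_intensity_fraction = low_intensity_fraction,
                 bio_sd = bio_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## per-pattern true log2FC at the three time points, given direction d
.pattern_profile <- function(pattern, d, eff) {
  e <- if (pattern == "NULL") 0 else d * eff[[pattern]]
  switch(pattern,
         LONG_LASTING = c(e, e, e),
         INTERMEDIATE = c(e, e, 0),
         SHORT        = c(e, 0, 0),
         REVERSAL     = c(e, 0, -e),
         SECONDARY    = c(0, e, e),
         "NULL"       = c(0, 0, 0))
}

#' Probe manifest for the array platform
#'
#' Builds the printed-probe composition of the platform: gene-detecting
#' probes printed once and gene-detecting probes printed in multiple
#' technical copies.
#'
#' @param n_single probes printed in one copy.
#' @param n_multi probes printed in `copies` copies.
#' @param copies number of printed copies for the multi-copy probes.
#' @return data frame with columns `probe_id`, `n_copies`,
#'   `is_control_probe`, `detects_gene`; attribute `total_spots` gives the
#'   number of printed spots.
#' @examples
#' m <- make_manifest(56305, 300, 10)
#' nrow(m)                  # 56605 unique gene-detecting probes
#' attr(m, "total_spots")   # 59305 printed spots
#' @export
make_manifest <- function(n_single, n_multi, copies = 10) {
  if (n_single < 0 || n_multi < 0 || copies < 1)
    stop("counts must be non-negative and copies >= 1")
  n <- n_single + n_multi
  man <- data.frame(
    probe_id = if (n > 0) sprintf("P%06d", seq_len(n)) else character(0),
    n_copies = c(rep(1L, n_single), rep(as.integer(copies), n_multi)),
    is_control_probe = logical(n),
    detects_gene = rep(TRUE, n),
    stringsAsFactors = FALSE)
  attr(man, "total_spots") <- n_single + n_multi * as.integer(copies)
  man
}

#' Simulate a two-color corticosterone time-course experiment
#'
#' Generates one spot table per array (control sample on the green channel,
#' treated on red) together with the ground truth of planted effects. See
#' [sim_config()] for the generative model.
#'
#' @param cfg a [sim_config()] object.
#' @param manifest optional [make_manifest()] data frame; multi-copy probes
#'   are printed as independent spots sharing the probe's truth. By default
#'   every probe is printed once.
#' @return list with elements `arrays` (named list of per-array data frames
#'   with columns `probe_id, row, col, r_fg, g_fg, r_bg, g_bg`), `design`
#'   (data frame `array, timepoint, replicate`) and `truth` (data frame
#'   `probe_id, pattern, direction, lfc_h1, lfc_h5, lfc_h9,
#'   intensity_class`).
#' @export
simulate_experiment <- function(cfg, manifest = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  np <- cfg$n_probes
  tps <- cfg$timepoints
  narr <- cfg$arrays_per_timepoint * length(tps)

  ## ground truth -----------------------------------------------------
  counts <- round(cfg$pattern_fractions * np)
  counts["NULL"] <- np - sum(counts[PATTERNS[1:5]])
  if (counts["NULL"] < 0) stop("pattern fractions leave no room for NULL probes")
  pattern <- sample(rep(PATTERNS, times = counts))
  direction <- ifelse(pattern == "NULL", 0L, sample(c(-1L, 1L), np, TRUE))
  prof <- t(vapply(seq_len(np), function(i)
    .pattern_profile(pattern[i], direction[i], cfg$effect_size_log2),
    numeric(3)))
  low <- stats::runif(np) < cfg$low_intensity_fraction
  ## baseline raw signal: mixture of exponentials; the low component sits
  ## below the intensity cutoff of 50, the high component above it
  ## low component calibrated so that post-correction mean normalized
  ## intensity stays below 50 (normexp shifts dim spots upward)
  s0 <- ifelse(low,
               stats::rexp(np, rate = 1 / 10),
               50 + stats::rexp(np, rate = 1 / cfg$signal_alpha))
  s0 <- pmax(s0, 0.5)
  base_log2 <- log2(s0)

  truth <- data.frame(probe_id = sprintf("P%06d", seq_len(np)),
                      pattern = pattern, direction = direction,
                      lfc_h1 = prof[, 1], lfc_h5 = prof[, 2],
                      lfc_h9 = prof[, 3],
                      intensity_class = ifelse(low, "low", "high"),
                      stringsAsFactors = FALSE)

  if (is.null(manifest)) {
    manifest <- data.frame(probe_id = truth$probe_id, n_copies = 1L,
                           is_control_probe = FALSE, detects_gene = TRUE,
                           stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(manifest$probe_id))
      stop("manifest probe_id values must be unique")
    if (nrow(manifest) != np)
      stop("manifest must contain one row per simulated probe")
    truth$probe_id <- manifest$probe_id
  }
  spot_probe <- rep(seq_len(np), times = manifest$n_copies)
  nspots <- length(spot_probe)

  design <- data.frame(
    array = sprintf("a%02d", seq_len(narr)),
    timepoint = rep(tps, each = cfg$arrays_per_timepoint),
    replicate = rep(seq_len(cfg$arrays_per_timepoint), length(tps)),
    stringsAsFactors = FALSE)

  rho <- cfg$intraspot_rho
  arr_scale <- stats::rnorm(narr, 0, cfg$array_scale_sd)
  ## fixed smooth cubic shape for the dye bias, scaled by the amplitude
  dye_curve <- function(A) {
    z <- (A - stats::median(A)) / max(stats::mad(A), 1e-6)
    z <- pmin(pmax(z, -3), 3)
    cfg$dye_bias_amplitude * (0.4 * z - 0.15 * z^2 + 0.05 * z^3)
  }

  grid <- ceiling(sqrt(nspots))
  arrays <- vector("list", narr)
  names(arrays) <- design$array
  for (a in seq_len(narr)) {
    ti <- match(design$timepoint[a], tps)
    delta <- prof[spot_probe, ti]
    ## correlated biological/spot noise for the two channels
    zg <- stats::rnorm(nspots)
    zr <- rho * zg + sqrt(1 - rho^2) * stats::rnorm(nspots)
    ## control animal expression is the baseline; the treated (red)
    ## channel carries the full planted effect
    lg <- base_log2[spot_probe] + cfg$bio_sd * zg + arr_scale[a]
    lr <- base_log2[spot_probe] + delta + cfg$bio_sd * zr + arr_scale[a]
    A <- (lg + lr) / 2
    bias <- dye_curve(A)
    sr <- 2^(lr + bias / 2)
    sg <- 2^(lg - bias / 2)
    r_fg <- stats::rnorm(nspots, cfg$background_mu, cfg$background_sigma) + sr
    g_fg <- stats::rnorm(nspots, cfg$background_mu, cfg$background_sigma) + sg
    r_bg <- pmax(stats::rnorm(nspots, cfg$background_mu,
                              cfg$background_sigma / 2), 0)
    g_bg <- pmax(stats::rnorm(nspots, cfg$background_mu,
                              cfg$background_sigma / 2), 0)
    arrays[[a]] <- data.frame(
      probe_id = manifest$probe_id[spot_probe],
      row = ((seq_len(nspots) - 1L) %/% grid) + 1L,
      col = ((seq_len(nspots) - 1L) %% grid) + 1L,
      r_fg = r_fg, g_fg = g_fg, r_bg = r_bg, g_bg = g_bg,
      stringsAsFactors = FALSE)
  }
  list(arrays = arrays, design = design, truth = truth)
}

#' Simulate qPCR plates with a five-fold dilution series
#'
#' Ct values follow `Ct = intercept - log_E(concentration * expression) +
#' noise`, so with efficiency base `E = 2` one two-fold concentration step
#' changes Ct by exactly one cycle. Each gene's plate carries a dilution
#' series of five five-fold steps (relative concentrations `5^0 .. 5^-4`)
#' and `reps` technical replicates of each biological sample.
#'
#' @param efficiencies named vector of amplification bases per gene, each
#'   in (1, 2.2].
#' @param true_ratios named list (per gene) of relative expression per
#'   sample (control mean = 1), or a named numeric of length-one ratios; a
#'   single unnamed sample called "s1" is generated for plain numerics.
#' @param reps technical replicates per sample.
#' @param noise_sd sd of Ct measurement noise (cycles).
#' @param intercept Ct of the undiluted calibrator.
#' @param seed integer seed.
#' @return long data frame `gene, sample_id, replicate, dilution, ct`;
#'   dilution-series rows have `sample_id == "dilution"` and `dilution`
#'   giving the relative concentration.
#' @export
simulate_qpcr <- function(efficiencies, true_ratios = NULL, reps = 3,
                          noise_sd = 0.1, intercept = 22, seed = 1L) {
  if (any(efficiencies <= 1) || any(efficiencies > 2.2))
    stop("efficiencies must be amplification bases in (1, 2.2]")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(as.integer(seed))
  out <- list()
  for (g in names(efficiencies)) {
    E <- efficiencies[[g]]
    ratios <- if (is.null(true_ratios)) c(s1 = 1)
              else if (is.list(true_ratios)) true_ratios[[g]]
              else true_ratios
    if (is.null(names(ratios)))
      names(ratios) <- sprintf("s%d", seq_along(ratios))
    conc <- 5^(0:-4)
    dil <- expand.grid(replicate = seq_len(reps), dilution = conc)
    dil_ct <- intercept - log(dil$dilution) / log(E) +
      stats::rnorm(nrow(dil), 0, noise_sd)
    out[[length(out) + 1L]] <- data.frame(
      gene = g, sample_id = "dilution", replicate = dil$replicate,
      dilution = dil$dilution, ct = dil_ct, stringsAsFactors = FALSE)
    smp <- expand.grid(replicate = seq_len(reps),
                       sample_id = names(ratios),
                       stringsAsFactors = FALSE)
    smp_ct <- intercept - log(ratios[smp$sample_id]) / log(E) +
      stats::rnorm(nrow(smp), 0, noise_sd)
    out[[length(out) + 1L]] <- data.frame(
      gene = g, sample_id = smp$sample_id, replicate = smp$replicate,
      dilution = 1, ct = as.numeric(smp_ct), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated experiment to tab-separated files
#'
#' One spot table per array plus `design.tsv`, `truth.tsv`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written file paths.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (a in names(sim$arrays)) {
    p <- file.path(dir, paste0(a, ".tsv"))
    utils::write.table(sim$arrays[[a]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("design", "truth")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(sim[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a simulated experiment back from a directory of TSV files
#' @param dir directory written by [write_experiment()].
#' @return list with `arrays`, `design` and (if present) `truth`.
#' @export
read_experiment <- function(dir) {
  design <- utils::read.table(file.path(dir, "design.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  arrays <- lapply(design$array, function(a)
    utils::read.table(file.path(dir, paste0(a, ".tsv")), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE))
  names(arrays) <- design$array
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.table(truth_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  list(arrays = arrays, design = design, truth = truth)
}
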