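#' Amplification efficiency from a dilution series
#'
#' Least-squares slope of mean Ct against log10 relative concentration;
#' the amplification base is `E = 10^(-1/slope)` and the efficiency
#' percentage is `(E - 1) * 100`. A perfectly doubling reaction has slope
#' -3.3219 and efficiency 100%.
#'
#' @param series data frame with columns `dilution` (relative
#'   concentration, e.g. `5^(0:-4)` for a five-fold series) and `ct`;
#'   technical replicates are averaged on the Ct scale per dilution
#'   point. At least 3 distinct dilutions spanning >= 2 log10 units.
#' @return list with `slope`, `E` (amplification base) and
#'   `efficiency_percent`.
#' @export
efficiency_from_dilution <- function(series) {
  pts <- stats::aggregate(ct ~ dilution, data = series, FUN = mean)
  if (nrow(pts) < 3) stop("need at least 3 dilution points")
  lx <- log10(pts$dilution)
  if (diff(range(lx)) < 2)
    stop("dilution series must span at least 2 log10 units")
  slope <- unname(stats::coef(stats::lm(pts$ct ~ lx))[2])
  if (slope >= 0)
    stop("non-negative slope: Ct must decrease with concentration")
  E <- 10^(-1 / slope)
  list(slope = slope, E = E, efficiency_percent = (E - 1) * 100)
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = mean control Ct - sample Ct` so that upregulated targets give
#' ratios above 1. With both bases equal to 2 this reduces to the
#' delta-delta-Ct value `2^(dCt_target - dCt_ref)`.
#'
#' @param E_target,E_ref amplification bases (> 1).
#' @param dCt_target,dCt_ref Ct differences (control mean minus sample).
#' @export
pfaffl_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (E_target <= 1 || E_ref <= 1)
    stop("amplification bases must be > 1")
  E_target^dCt_target / E_ref^dCt_ref
}

#' Correlation of qPCR ratios with decomposed microarray intensities
#'
#' Matches samples by ID across the two platforms and computes the
#' Pearson correlation for one (gene, probe) pair.
#'
#' @param pcr data frame `sample_id, value` (relative expression ratios).
#' @param microarray data frame `sample_id, value` (normalized
#'   single-channel intensities of one probe).
#' @return list with `r` and `n` (matched samples).
#' @export
correlate_pcr_microarray <- function(pcr, microarray) {
  m <- merge(pcr, microarray, by = "sample_id",
             suffixes = c("_pcr", "_array"))
  if (nrow(m) < 3) stop("fewer than 3 matched samples")
  list(r = pearson_r(m$value_pcr, m$value_array), n = nrow(m))
}

#' Pfaffl ratios for every sample of a qPCR plate table
#'
#' Averages technical replicates on the Ct scale, computes per-gene
#' amplification bases from each gene's dilution series, and returns the
#' efficiency-corrected expression of every sample relative to the mean
#' of the control samples, normalized to the reference gene.
#'
#' @param plate long data frame `gene, sample_id, replicate, dilution,
#'   ct` as produced by [simulate_qpcr()]; dilution-series rows have
#'   `sample_id == "dilution"`.
#' @param ref_gene reference (housekeeping) gene name.
#' @param control_samples sample IDs of the control group; defaults to
#'   all samples (ratios then relative to the grand mean).
#' @return list with `efficiencies` (per gene) and `ratios` (data frame
#'   `gene, sample_id, ratio`).
#' @export
pfaffl_table <- function(plate, ref_gene, control_samples = NULL) {
  if (!ref_gene %in% plate$gene)
    stop("reference gene not present on the plate")
  genes <- unique(plate$gene)
  eff <- lapply(stats::setNames(genes, genes), function(g)
    efficiency_from_dilution(plate[plate$gene == g &
                                     plate$sample_id == "dilution", ]))
  smp <- plate[plate$sample_id != "dilution", ]
  ct <- stats::aggregate(ct ~ gene + sample_id, data = smp, FUN = mean)
  samples <- unique(ct$sample_id)
  if (is.null(control_samples)) control_samples <- samples
  dct <- function(g) {
    cg <- ct[ct$gene == g, ]
    ctrl <- mean(cg$ct[cg$sample_id %in% control_samples])
    stats::setNames(ctrl - cg$ct, cg$sample_id)
  }
  dct_ref <- dct(ref_gene)
  out <- list()
  for (g in setdiff(genes, ref_gene)) {
    d <- dct(g)
    common <- intersect(names(d), names(dct_ref))
    out[[g]] <- data.frame(
      gene = g, sample_id = common,
      ratio = pfaffl_ratio(eff[[g]]$E, d[common],
                           eff[[ref_gene]]$E, dct_ref[common]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(efficiencies = eff, ratios = do.call(rbind, out))
}
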