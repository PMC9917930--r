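#' Classifier configuration
#'
#' Thresholds of the temporal taxonomy: the adjusted-p significance cutoff,
#' the low-intensity reporting cutoff (mean normalized single-channel
#' intensity below 50), and the fold-change magnitude bin edges on the
#' |log2FC| scale. The default edges 0.32, 0.58 and 1 correspond to 25%,
#' 50% and 100% expression differences (log2 1.25 = 0.32, log2 1.5 = 0.58,
#' log2 2 = 1).
#'
#' @param alpha adjusted-p threshold.
#' @param intensity_cutoff low-intensity flag cutoff (raw intensity units).
#' @param bin_edges_log2 strictly increasing positive bin edges.
#' @export
classifier_config <- function(alpha = 0.05, intensity_cutoff = 50,
                              bin_edges_log2 = c(0.32, 0.58, 1.0)) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (any(diff(bin_edges_log2) <= 0) || any(bin_edges_log2 <= 0))
    stop("bin edges must be strictly increasing and positive")
  structure(list(alpha = alpha, intensity_cutoff = intensity_cutoff,
                 bin_edges_log2 = bin_edges_log2),
            class = "classifier_config")
}

MAGNITUDE_BINS <- c("<=25%", "25-50%", "50-100%", ">100%")

#' Fold-change magnitude bin
#'
#' Bins `|log2FC|` into `(0, e1]`, `(e1, e2]`, `(e2, e3]`, `(e3, Inf)`;
#' the lower edges are exclusive and upper edges inclusive, so a value
#' exactly at 0.32 falls in the smallest bin.
#'
#' @param lfc log2 fold change (sign is ignored).
#' @param cfg a [classifier_config()].
#' @return factor with levels `<=25%`, `25-50%`, `50-100%`, `>100%`.
#' @export
assign_magnitude_bin <- function(lfc, cfg = classifier_config()) {
  if (any(!is.finite(lfc))) stop("log2FC must be finite")
  cut(abs(lfc), breaks = c(-Inf, cfg$bin_edges_log2, Inf),
      labels = MAGNITUDE_BINS, right = TRUE)
}

#' Low-intensity flag
#'
#' A probe is flagged when the mean of the normalized single-channel
#' intensities across all arrays of the compared groups falls below the
#' cutoff.
#'
#' @param intensities non-negative group mean intensities (or all
#'   per-channel intensities) to average.
#' @param cutoff intensity cutoff.
#' @export
apply_intensity_filter <- function(intensities, cutoff = 50) {
  if (any(intensities < 0)) stop("intensities must be >= 0")
  mean(intensities) < cutoff
}

## decision table; s* logical significance, d* sign of logFC
.classify_one <- function(s1, s5, s9, d1, d5, d9) {
  if (!s1) {
    if (s5 || s9) return("SECONDARY")
    return("NULL")
  }
  if ((s5 && d5 != d1) || (s9 && d9 != d1)) return("REVERSAL")
  if (s5 && s9) return("LONG_LASTING")
  if (s5) return("INTERMEDIATE")
  if (s9) return("COMPLEX")
  "SHORT"
}

## reference timepoint whose logFC feeds the magnitude bin
.bin_timepoint <- function(category, s5, s9) {
  switch(category,
         LONG_LASTING = "h9",
         INTERMEDIATE = "h5",
         SHORT        = "h1",
         REVERSAL     = "h1",
         SECONDARY    = if (s9) "h9" else "h5",
         COMPLEX      = if (s9) "h9" else if (s5) "h5" else "h1",
         "NULL"       = NA_character_)
}

#' Classify one probe's three-timepoint result triple
#'
#' Applies the temporal decay taxonomy to the treated-vs-control results
#' at hours 1, 5 and 9 of the resting period:
#' * `LONG_LASTING` - significant at all three time points, same sign;
#' * `INTERMEDIATE` - significant at h1 and h5 (same sign), back to
#'   baseline at h9;
#' * `SHORT` - significant only at h1;
#' * `REVERSAL` - significant at h1 and at a later time point with the
#'   opposite sign;
#' * `SECONDARY` - not significant at h1 but significant later;
#' * `COMPLEX` - significant at h1 and h9 only, same sign (no named
#'   pattern);
#' * `NULL` - no significant time point.
#'
#' The magnitude bin is taken at the category's reference time point: the
#' latest significant time point for persistent categories (h9 for
#' long-lasting, h5 for intermediate), h1 for short and reversal.
#'
#' @param h1,h5,h9 lists or one-row data frames with elements `logFC`,
#'   `p_adj`, and mean group intensities `mean_ctrl`, `mean_trt`.
#' @param cfg a [classifier_config()].
#' @return one-row data frame: `category, dir_h1, dir_h5, dir_h9,
#'   magnitude_bin, bin_timepoint, low_intensity`.
#' @export
classify_probe <- function(h1, h5, h9, cfg = classifier_config()) {
  for (h in list(h1, h5, h9))
    if (is.null(h$logFC) || is.null(h$p_adj))
      stop("each timepoint needs logFC and p_adj")
  s <- c(h1$p_adj < cfg$alpha, h5$p_adj < cfg$alpha, h9$p_adj < cfg$alpha)
  d <- sign(c(h1$logFC, h5$logFC, h9$logFC))
  category <- .classify_one(s[1], s[2], s[3], d[1], d[2], d[3])
  bt <- .bin_timepoint(category, s[2], s[3])
  lfc <- switch(if (is.na(bt)) "none" else bt,
                h1 = h1$logFC, h5 = h5$logFC, h9 = h9$logFC, none = NA_real_)
  ints <- unlist(lapply(list(h1, h5, h9),
                        function(h) c(h$mean_ctrl, h$mean_trt)))
  data.frame(category = category,
             dir_h1 = if (s[1]) d[1] else 0L,
             dir_h5 = if (s[2]) d[2] else 0L,
             dir_h9 = if (s[3]) d[3] else 0L,
             magnitude_bin = if (is.na(bt)) NA_character_ else
               as.character(assign_magnitude_bin(lfc, cfg)),
             bin_timepoint = bt,
             low_intensity = if (length(ints))
               apply_intensity_filter(ints, cfg$intensity_cutoff) else NA,
             stringsAsFactors = FALSE)
}

#' Classify all probes of a differential-expression run
#'
#' Vectorized application of [classify_probe()] to the three
#' treated-vs-control contrasts of a [run_contrasts()] result.
#'
#' @param detest a `cd_detest` object (or its `results` data frame).
#' @param cfg a [classifier_config()]; its `alpha` overrides the one used
#'   at test time.
#' @return data frame of temporal calls, one row per probe:
#'   `probe_id, category, dir_h1, dir_h5, dir_h9, lfc_h1, lfc_h5, lfc_h9,
#'   magnitude_bin, bin_timepoint, low_intensity`.
#' @export
classify_probes <- function(detest, cfg = classifier_config()) {
  res <- if (inherits(detest, "cd_detest")) detest$results else detest
  need <- paste0("cort_vs_ctrl_", c("h1", "h5", "h9"))
  if (!all(need %in% res$contrast))
    stop("missing treated-vs-control contrast(s): ",
         paste(setdiff(need, res$contrast), collapse = ", "))
  wide <- lapply(need, function(nm) {
    d <- res[res$contrast == nm, ]
    d[order(d$probe_id), ]
  })
  ids <- wide[[1]]$probe_id
  if (!identical(ids, wide[[2]]$probe_id) ||
      !identical(ids, wide[[3]]$probe_id))
    stop("contrasts cover different probe sets")
  n <- length(ids)
  s <- matrix(unlist(lapply(wide, function(d) d$p_adj < cfg$alpha)), n, 3)
  d <- matrix(unlist(lapply(wide, function(d) sign(d$logFC))), n, 3)
  lfc <- matrix(unlist(lapply(wide, function(d) d$logFC)), n, 3)
  category <- vapply(seq_len(n), function(i)
    .classify_one(s[i, 1], s[i, 2], s[i, 3], d[i, 1], d[i, 2], d[i, 3]),
    character(1))
  bt <- vapply(seq_len(n), function(i)
    .bin_timepoint(category[i], s[i, 2], s[i, 3]), character(1))
  bin_lfc <- lfc[cbind(seq_len(n), match(bt, c("h1", "h5", "h9")))]
  bins <- rep(NA_character_, n)
  ok <- !is.na(bt)
  bins[ok] <- as.character(assign_magnitude_bin(bin_lfc[ok], cfg))
  ## mean normalized intensity over both groups and all three time points
  meanint <- rowMeans(matrix(unlist(lapply(wide, function(dd)
    (dd$mean_ctrl + dd$mean_trt) / 2)), n, 3))
  data.frame(probe_id = ids, category = category,
             dir_h1 = ifelse(s[, 1], d[, 1], 0L),
             dir_h5 = ifelse(s[, 2], d[, 2], 0L),
             dir_h9 = ifelse(s[, 3], d[, 3], 0L),
             lfc_h1 = lfc[, 1], lfc_h5 = lfc[, 2], lfc_h9 = lfc[, 3],
             magnitude_bin = bins, bin_timepoint = bt,
             low_intensity = meanint < cfg$intensity_cutoff,
             stringsAsFactors = FALSE)
}

#' Consolidate probe-level temporal calls to gene level
#'
#' Excludes probes whose annotation is multi-gene, inconsistent or absent,
#' then groups the remaining probes by consensus gene symbol. Probes of
#' one gene may legitimately disagree (different transcript variants), so
#' the per-gene row retains the full set of categories.
#'
#' @param calls data frame from [classify_probes()].
#' @param annotation data frame from [consensus_annotate()] (columns
#'   `probe_id`, `status`, `consensus_symbol`).
#' @return list with `genes` (data frame `gene, n_probes, categories`),
#'   `excluded` (counts by reason) and `probes` (the retained calls with
#'   gene symbols attached).
#' @export
consolidate_genes <- function(calls, annotation) {
  m <- merge(calls, annotation[, c("probe_id", "status", "consensus_symbol")],
             by = "probe_id", all.x = TRUE)
  m$status[is.na(m$status)] <- "unannotated"
  drop_reason <- ifelse(m$status == "multi_gene", "multi-gene",
                 ifelse(m$status == "inconsistent", "inconsistent",
                 ifelse(m$status == "unannotated", "unannotated", NA)))
  excluded <- table(drop_reason[!is.na(drop_reason)])
  keep <- m[is.na(drop_reason), ]
  genes <- if (nrow(keep)) {
    agg <- lapply(split(keep, keep$consensus_symbol), function(d)
      data.frame(gene = d$consensus_symbol[1], n_probes = nrow(d),
                 categories = paste(sort(unique(d$category)),
                                    collapse = ";"),
                 stringsAsFactors = FALSE))
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(gene = character(0), n_probes = integer(0),
               categories = character(0))
  }
  list(genes = genes,
       excluded = stats::setNames(as.integer(excluded), names(excluded)),
       probes = keep)
}

#' Score recovery of planted temporal patterns
#'
#' Confusion matrix of planted pattern vs called category, with recall and
#' precision per planted pattern.
#'
#' @param calls data frame from [classify_probes()].
#' @param truth ground-truth data frame from [simulate_experiment()].
#' @return list with `confusion` (patterns x categories table), `recall`
#'   and `precision` (named vectors over planted patterns).
#' @export
score_recovery <- function(calls, truth) {
  if (!setequal(calls$probe_id, truth$probe_id))
    stop("probe IDs of calls and truth do not match")
  truth <- truth[match(calls$probe_id, truth$probe_id), ]
  conf <- table(factor(truth$pattern, levels = PATTERNS),
                factor(calls$category, levels = CATEGORIES))
  names(dimnames(conf)) <- c("planted", "called")
  shared <- intersect(rownames(conf), colnames(conf))
  recall <- vapply(shared, function(k) {
    n <- sum(conf[k, ])
    if (n == 0) NA_real_ else conf[k, k] / n
  }, numeric(1))
  precision <- vapply(shared, function(k) {
    n <- sum(conf[, k])
    if (n == 0) NA_real_ else conf[k, k] / n
  }, numeric(1))
  list(confusion = conf, recall = recall, precision = precision)
}
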