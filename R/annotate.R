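#' Build a synonym map for gene-symbol canonicalization
#'
#' Symbols are matched case-insensitively after whitespace stripping. The
#' map is closed symmetrically at construction: every synonym resolves to
#' its canonical symbol, and a canonical symbol resolves to itself. A
#' symbol may not map to two different canonical symbols.
#'
#' @param canonical character vector of canonical symbols.
#' @param synonyms list of character vectors, one per canonical symbol.
#' @return object of class `synonym_map`.
#' @export
synonym_map <- function(canonical = character(0), synonyms = list()) {
  if (length(canonical) != length(synonyms))
    stop("canonical and synonyms must have equal length")
  key <- tolower(trimws(canonical))
  lookup <- stats::setNames(canonical, key)
  for (i in seq_along(canonical)) {
    for (s in synonyms[[i]]) {
      k <- tolower(trimws(s))
      existing <- unname(lookup[k])
      if (!is.na(existing) && existing != canonical[i])
        stop("symbol '", s, "' maps to two canonical symbols")
      lookup[k] <- canonical[i]
    }
  }
  structure(list(lookup = lookup), class = "synonym_map")
}

#' Canonicalize gene symbols through a synonym map
#'
#' Unknown symbols pass through with whitespace stripped (their own
#' spelling is treated as canonical). Idempotent.
#'
#' @param symbols character vector.
#' @param map a [synonym_map()] (or NULL for plain normalization).
#' @export
canonicalize_symbols <- function(symbols, map = NULL) {
  s <- trimws(symbols)
  if (is.null(map)) return(s)
  k <- tolower(s)
  hit <- k %in% names(map$lookup)
  s[hit] <- unname(map$lookup[k[hit]])
  s
}

#' Consensus annotation of probes from two sources
#'
#' Compares per-probe gene-symbol sets from two independent annotation
#' sources after synonym canonicalization (case-insensitive). Status:
#' * `unannotated` - both sources empty;
#' * `consistent` - equal single-gene sets with identical raw symbols;
#' * `consistent_via_synonym` - equal after synonym resolution only;
#' * `multi_gene` - sources agree but on more than one gene;
#' * `inconsistent` - anything else (including partial agreement).
#'
#' @param source1,source2 data frames with columns `probe_id` and
#'   `symbols` (pipe-separated symbol lists; empty string or NA for no
#'   annotation). Probe IDs must be unique within a source.
#' @param map optional [synonym_map()].
#' @return data frame: `probe_id, symbols_source1, symbols_source2,
#'   consensus_symbol, status`.
#' @export
consensus_annotate <- function(source1, source2, map = NULL) {
  for (src in list(source1, source2))
    if (anyDuplicated(src$probe_id))
      stop("duplicate probe rows within an annotation source")
  ids <- union(source1$probe_id, source2$probe_id)
  g1 <- source1$symbols[match(ids, source1$probe_id)]
  g2 <- source2$symbols[match(ids, source2$probe_id)]
  split_syms <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  }
  out <- data.frame(probe_id = ids,
                    symbols_source1 = ifelse(is.na(g1), "", g1),
                    symbols_source2 = ifelse(is.na(g2), "", g2),
                    consensus_symbol = NA_character_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s1 <- split_syms(g1[i])
    s2 <- split_syms(g2[i])
    if (!length(s1) && !length(s2)) {
      out$status[i] <- "unannotated"
      next
    }
    c1 <- unique(canonicalize_symbols(s1, map))
    c2 <- unique(canonicalize_symbols(s2, map))
    if (setequal(tolower(c1), tolower(c2)) && length(c1) && length(c2)) {
      if (length(c1) > 1) {
        out$status[i] <- "multi_gene"
      } else {
        raw_equal <- setequal(tolower(s1), tolower(s2))
        out$status[i] <- if (raw_equal) "consistent"
                         else "consistent_via_synonym"
        out$consensus_symbol[i] <- c1[1]
      }
    } else {
      out$status[i] <- "inconsistent"
    }
  }
  out
}

## transcript biotypes the reporting understands; anything else -> other
KNOWN_BIOTYPES <- c("protein_coding", "lncRNA", "lincRNA", "miRNA", "snRNA",
                    "rRNA", "retained_intron", "processed_transcript",
                    "nonsense_mediated_decay", "processed_pseudogene",
                    "pseudogene", "antisense", "TEC",
                    "protein_coding_LoF")

#' Probe-level canonical-transcript flag and biotype summary
#'
#' A probe is flagged canonical when any of its transcript hits is the
#' gene's Ensembl-style canonical transcript (the representative variant
#' with the highest conserved-exon coverage). Unknown biotypes are
#' reported as `other` with a warning.
#'
#' @param hits data frame with columns `transcript_id`, `biotype`,
#'   `canonical` (logical or 0/1); zero rows allowed.
#' @return list with `canonical` (flag) and `biotypes` (character vector
#'   of the hit biotypes, normalized).
#' @export
flag_canonical <- function(hits) {
  if (!nrow(hits)) return(list(canonical = FALSE, biotypes = character(0)))
  bt <- hits$biotype
  unknown <- !(bt %in% KNOWN_BIOTYPES)
  if (any(unknown)) {
    warning("unknown biotype(s): ",
            paste(unique(bt[unknown]), collapse = ", "),
            "; reported as 'other'")
    bt[unknown] <- "other"
  }
  list(canonical = any(as.logical(hits$canonical)), biotypes = bt)
}
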