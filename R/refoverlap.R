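#' Referential gene list
#'
#' A named set of gene symbols against which result lists are compared,
#' e.g. core or extended glucocorticoid-responsive genes or
#' stress-responsive genes from meta-analyses. Symbols are deduplicated
#' after canonicalization.
#'
#' @param name list name.
#' @param symbols character vector of gene symbols (nonempty).
#' @param tier one of `core`, `extended`, `stress`.
#' @param map optional [synonym_map()] used to canonicalize.
#' @export
reference_list <- function(name, symbols, tier = c("core", "extended",
                                                   "stress"),
                           map = NULL) {
  tier <- match.arg(tier)
  symbols <- unique(canonicalize_symbols(symbols, map))
  symbols <- symbols[nzchar(symbols)]
  if (!length(symbols)) stop("reference list must contain symbols")
  structure(list(name = name, symbols = symbols, tier = tier),
            class = "reference_list")
}

#' Overlap of a result gene list with a reference list
#'
#' Synonym-aware, case-insensitive matching. Two percentages are
#' reported, since the relevant denominator depends on the question:
#' `pct_of_reference = |matched| / |reference| * 100` (coverage of the
#' reference) and `pct_of_results = |matched| / |results| * 100` (share
#' of the results already known).
#'
#' @param result_genes character vector of result gene symbols.
#' @param reference a [reference_list()].
#' @param map optional [synonym_map()].
#' @param digits rounding of the percentages.
#' @return list with `matched` (character), `n_matched`, `n_reference`,
#'   `n_results`, `pct_of_reference`, `pct_of_results`.
#' @export
overlap_report <- function(result_genes, reference, map = NULL,
                           digits = 0) {
  if (!length(reference$symbols)) stop("empty reference list")
  res <- unique(tolower(canonicalize_symbols(result_genes, map)))
  ref <- canonicalize_symbols(reference$symbols, map)
  matched <- ref[tolower(ref) %in% res]
  list(matched = matched,
       n_matched = length(matched),
       n_reference = length(ref),
       n_results = length(res),
       pct_of_reference = round(100 * length(matched) / length(ref),
                                digits),
       pct_of_results = if (length(res))
         round(100 * length(matched) / length(res), digits) else NA_real_)
}
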