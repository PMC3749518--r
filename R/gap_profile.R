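# Fig.-style gap-frequency bins: ordered upper bounds (exclusive) with a
# final closed top bin so the bins partition [0, 1]; a frequency of exactly
# 0.75 falls in the top bin.
GAP_BIN_BREAKS <- c(0.001, 0.05, 0.2, 0.35, 0.5, 0.75)
GAP_BIN_LABELS <- c("grey", "violet", "blue", "green", "yellow", "orange", "red")

#' Bin a gap frequency
#'
#' Assigns a frequency in `[0, 1]` to one of seven half-open bins
#' `[0, 0.001), [0.001, 0.05), [0.05, 0.2), [0.2, 0.35), [0.35, 0.5),
#' [0.5, 0.75), [0.75, 1]`, labelled grey, violet, blue, green, yellow,
#' orange, red. The bins partition `[0, 1]`.
#'
#' @param freq Numeric vector of frequencies in `[0, 1]`.
#' @return Character vector of bin labels.
#' @export
bin_gap_frequency <- function(freq) {
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  GAP_BIN_LABELS[findInterval(freq, GAP_BIN_BREAKS) + 1L]
}

#' Map alignment columns to ungapped reference positions
#'
#' Each column where the reference taxon has a residue maps to its 1-based
#' position in the ungapped reference sequence; columns where the reference
#' is gapped (insertions relative to the reference) map to `NA`.
#'
#' @param x An [msa].
#' @param reference Taxon id of the reference sequence.
#' @return Integer vector of length `ncol(x)`; strictly increasing over the
#'   mapped columns.
#' @export
map_columns_to_reference <- function(x, reference) {
  if (!reference %in% x$taxa) stop("reference taxon '", reference, "' absent")
  refgap <- gap_mask(x)[reference, ]
  if (all(refgap)) stop("reference row is all gaps")
  pos <- rep(NA_integer_, length(refgap))
  pos[!refgap] <- seq_len(sum(!refgap))
  pos
}

#' Gap-frequency profile of a taxon group in reference coordinates
#'
#' For every position of the ungapped reference sequence, the fraction of
#' the group's rows that are gapped in the corresponding alignment column,
#' together with its frequency bin. Columns where the reference itself is
#' gapped are excluded.
#'
#' @param x An [msa].
#' @param grouping A [taxon_grouping].
#' @param group Group label to profile.
#' @param reference Reference taxon id (need not belong to the group).
#' @return Data frame of class `gap_profile` with columns `position`,
#'   `column`, `frequency`, `bin`; attribute `group_size`.
#' @export
gap_frequencies <- function(x, grouping, group, reference) {
  taxa <- intersect(group_taxa(grouping, group), x$taxa)
  if (length(taxa) == 0L) stop("group '", group, "' has no taxa in the alignment")
  pos <- map_columns_to_reference(x, reference)
  cols <- which(!is.na(pos))
  gaps <- gap_mask(x)[taxa, cols, drop = FALSE]
  freq <- colMeans(gaps)
  out <- data.frame(position = pos[cols], column = cols,
                    frequency = unname(freq),
                    bin = bin_gap_frequency(unname(freq)))
  attr(out, "group_size") <- length(taxa)
  class(out) <- c("gap_profile", "data.frame")
  out
}

#' Test whether taxa lack a reference region
#'
#' A taxon "lacks" the region when all of its characters across the
#' alignment columns mapping to the reference interval are gaps; a
#' `tolerance` fraction of residue-bearing positions can be allowed for
#' curation noise (default 0: complete absence required).
#'
#' @param x An [msa].
#' @param reference Reference taxon id.
#' @param start,end 1-based closed interval in ungapped reference
#'   coordinates.
#' @param taxa Taxa to test (default: all rows of the alignment).
#' @param tolerance Maximum fraction of interval positions that may carry a
#'   residue while still calling the region absent (default 0).
#' @return List with `absent` (named logical per taxon), `lacking` (taxon
#'   ids called absent) and `n_lacking`.
#' @export
region_absent <- function(x, reference, start, end, taxa = NULL,
                          tolerance = 0) {
  pos <- map_columns_to_reference(x, reference)
  ref_len <- max(pos, na.rm = TRUE)
  if (start < 1L || end > ref_len || start > end) {
    stop("interval ", start, "-", end, " outside reference length ", ref_len)
  }
  cols <- which(!is.na(pos) & pos >= start & pos <= end)
  if (is.null(taxa)) taxa <- x$taxa
  gaps <- gap_mask(msa_subset(x, taxa = taxa))[, cols, drop = FALSE]
  residue_frac <- 1 - rowMeans(gaps)
  absent <- residue_frac <= tolerance
  list(absent = absent, lacking = names(absent)[absent],
       n_lacking = sum(absent))
}
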