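#' Per-column conservation profile
#'
#' For every alignment column, the fraction of non-gap rows sharing the
#' single most frequent residue, and the non-gap count. Gaps (and ambiguity
#' codes) are excluded from both numerator and denominator; an all-gap
#' column has undefined conservation (`NA`) and non-gap count 0.
#'
#' @param x An [msa].
#' @return Data frame with columns `column`, `conservation`, `non_gap`.
#' @export
conservation_profile <- function(x) {
  letters_ <- alignment_alphabet(x$alphabet)
  nc <- ncol(x$mat)
  cons <- numeric(nc)
  ng <- integer(nc)
  for (j in seq_len(nc)) {
    counts <- composition_vector(x$mat[, j], letters_)
    ng[j] <- as.integer(sum(counts))
    cons[j] <- if (ng[j] == 0L) NA_real_ else max(counts) / ng[j]
  }
  data.frame(column = seq_len(nc), conservation = cons, non_gap = ng)
}

#' Trim an alignment to its conserved core
#'
#' Removes leading and trailing columns up to the first/last column whose
#' conservation strictly exceeds `threshold` (both ends are trimmed inward;
#' all-gap columns never qualify). Interior columns are untouched and row
#' and column order is preserved.
#'
#' @param x An [msa].
#' @param threshold Conservation that must be exceeded, in (0, 1); default
#'   0.33.
#' @return List with `alignment` (trimmed [msa]) and `annotation` (data
#'   frame `column`, `status` of `"kept"`/`"trimmed"`, in original
#'   coordinates).
#' @export
trim_to_conserved <- function(x, threshold = 0.33) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1 (it must be exceedable)")
  }
  prof <- conservation_profile(x)
  ok <- !is.na(prof$conservation) & prof$conservation > threshold
  if (!any(ok)) stop("nothing conserved: no column exceeds conservation ", threshold)
  first <- which(ok)[1L]
  last <- which(ok)[length(which(ok))]
  status <- rep("trimmed", ncol(x$mat))
  status[first:last] <- "kept"
  list(alignment = msa_subset(x, columns = first:last),
       annotation = data.frame(column = seq_len(ncol(x$mat)), status = status))
}

#' Find variable regions of an alignment
#'
#' Maximal runs of at least `min_run` consecutive columns whose conservation
#' is below `threshold` (columns with undefined conservation count as
#' unconserved). Intervals are 1-based and closed.
#'
#' @param profile A conservation profile from [conservation_profile] (or an
#'   [msa], which is profiled first).
#' @param threshold Conservation bound (default 0.33); a column is variable
#'   when its conservation is strictly less.
#' @param min_run Minimum run length (default 10).
#' @return Data frame with columns `start`, `end`, `width` (possibly 0 rows).
#' @export
find_variable_regions <- function(profile, threshold = 0.33, min_run = 10L) {
  if (inherits(profile, "msa")) profile <- conservation_profile(profile)
  low <- is.na(profile$conservation) | profile$conservation < threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             width = r$lengths[keep])
}

#' Mask single-sequence insertions
#'
#' Columns in which exactly one row has a residue (all others gapped) are
#' insertions private to one sequence; they are replaced by gaps in every
#' row. Alignment length is unchanged and the operation is idempotent.
#'
#' @param x An [msa].
#' @return List with `alignment` (masked [msa]) and `annotation` (data frame
#'   `column`, `masked`).
#' @export
mask_single_sequence_insertions <- function(x) {
  prof <- conservation_profile(x)
  mask <- prof$non_gap == 1L
  out <- x
  if (any(mask)) out$mat[, mask] <- "-"
  list(alignment = out,
       annotation = data.frame(column = prof$column, masked = mask))
}
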