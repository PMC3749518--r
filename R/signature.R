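# Column composition: counts of each standard residue among one group's
# rows of one column. Gaps and ambiguity codes are excluded.
composition_vector <- function(chars, alphabet_letters) {
  tab <- table(factor(chars, levels = alphabet_letters))
  as.numeric(tab)
}

#' Base column-signature statistic
#'
#' Measures how different two groups' residue compositions are in one
#' alignment column. The counts of each standard residue form one vector
#' per group; the statistic is the squared Euclidean distance between the
#' unit-normalised vectors, `2 * (1 - cos(theta))`. It is 0 when the two
#' compositions are proportional (identical usage), 2 when the groups use
#' entirely disjoint residues (orthogonal vectors), and does not depend on
#' within-group conservation.
#'
#' @param vec_a,vec_b Non-negative count vectors of equal length (4
#'   components for nucleotides, 20 for amino acids).
#' @return The signature value in `[0, 2]`; 0 if exactly one vector is all
#'   zero (no comparison possible); `NA` if both are all zero.
#' @export
kovbasa_base <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) stop("composition vectors differ in length")
  if (any(vec_a < 0) || any(vec_b < 0)) stop("counts must be non-negative")
  ta <- sum(vec_a); tb <- sum(vec_b)
  if (ta == 0 && tb == 0) return(NA_real_)
  if (ta == 0 || tb == 0) return(0)
  s <- 2 * (1 - sum(vec_a * vec_b) / sqrt(sum(vec_a^2) * sum(vec_b^2)))
  min(max(s, 0), 2)
}

#' Conservation difference between two groups in a column
#'
#' The largest within-group relative residue frequency found in either
#' group, minus that same residue's frequency in the other group. Among
#' (residue, group) pairs tied for the maximum frequency, the pair giving
#' the largest difference is chosen (ties broken by alphabet order, then
#' group A before group B), making the result deterministic.
#'
#' @param vec_a,vec_b Non-negative count vectors, each with positive total.
#' @return The difference, in `[0, 1]`.
#' @export
conservation_difference <- function(vec_a, vec_b) {
  ta <- sum(vec_a); tb <- sum(vec_b)
  if (ta == 0 || tb == 0) stop("both groups must have residues in the column")
  fa <- vec_a / ta
  fb <- vec_b / tb
  fmax <- max(fa, fb)
  d <- -Inf
  for (i in seq_along(fa)) {
    if (fa[i] == fmax) d <- max(d, fa[i] - fb[i])
    if (fb[i] == fmax) d <- max(d, fb[i] - fa[i])
  }
  d
}

#' Modified column-signature score
#'
#' The full conservation-weighted score for one alignment column over a set
#' of sampled rows: `M = S * g * d / 2`, where `S` is [kovbasa_base], `g`
#' the fraction of sampled characters that are non-gap, and `d` the
#' [conservation_difference]. `M` lies in `[0, 1]`: 0 for equal residue
#' usage, 1 for disjoint usage with full conservation in at least one group
#' and no gaps. A column where either group has no residues is flagged
#' skipped and scores 0.
#'
#' @param chars Character vector: the column's characters for the sampled
#'   rows.
#' @param groups Group label per sampled row (exactly two distinct labels
#'   across the sample).
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return List with `S`, `g`, `d`, `M`, `skipped`.
#' @export
modified_column_score <- function(chars, groups,
                                  alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  letters_ <- alignment_alphabet(alphabet)
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) != 2L) {
    stop("need exactly two groups among sampled rows, got: ",
         paste(labs, collapse = ", "))
  }
  a <- composition_vector(chars[groups == labs[1L]], letters_)
  b <- composition_vector(chars[groups == labs[2L]], letters_)
  g <- (sum(a) + sum(b)) / length(chars)
  if (sum(a) == 0 || sum(b) == 0) {
    return(list(S = NA_real_, g = g, d = NA_real_, M = 0, skipped = TRUE))
  }
  S <- kovbasa_base(a, b)
  d <- conservation_difference(a, b)
  list(S = S, g = g, d = d, M = S * g * d / 2, skipped = FALSE)
}

#' Per-column signature scores for an alignment
#'
#' @param x An [msa].
#' @param taxa_a,taxa_b Taxon ids of the two sampled groups (must be rows of
#'   `x`).
#' @return Data frame with one row per column: `column`, `S`, `g`, `d`, `M`,
#'   `skipped`.
#' @export
alignment_signature <- function(x, taxa_a, taxa_b) {
  sub <- msa_subset(x, taxa = c(taxa_a, taxa_b))
  letters_ <- alignment_alphabet(x$alphabet)
  mat <- sub$mat
  ia <- seq_along(taxa_a)
  ib <- length(taxa_a) + seq_along(taxa_b)
  nc <- ncol(mat)
  S <- g <- d <- M <- numeric(nc)
  skipped <- logical(nc)
  for (j in seq_len(nc)) {
    a <- composition_vector(mat[ia, j], letters_)
    b <- composition_vector(mat[ib, j], letters_)
    g[j] <- (sum(a) + sum(b)) / nrow(mat)
    if (sum(a) == 0 || sum(b) == 0) {
      S[j] <- NA_real_; d[j] <- NA_real_; M[j] <- 0; skipped[j] <- TRUE
    } else {
      S[j] <- kovbasa_base(a, b)
      d[j] <- conservation_difference(a, b)
      M[j] <- S[j] * g[j] * d[j] / 2
    }
  }
  data.frame(column = seq_len(nc), S = S, g = g, d = d, M = M,
             skipped = skipped)
}

#' Mean signature score over alignment columns
#'
#' Arithmetic mean of the modified score over usable (non-skipped) columns.
#'
#' @inheritParams alignment_signature
#' @return List with `mean` and `n_skipped`.
#' @export
alignment_mean_score <- function(x, taxa_a, taxa_b) {
  sig <- alignment_signature(x, taxa_a, taxa_b)
  usable <- !sig$skipped
  if (!any(usable)) stop("no usable columns: every column lacks residues in one group")
  list(mean = mean(sig$M[usable]), n_skipped = sum(!usable))
}

#' Resampled signature comparison of two taxon groups
#'
#' The resampling protocol for comparing two groups (e.g. phyla) across an
#' alignment: repeatedly draw `n` taxa from each group uniformly without
#' replacement, compute the column-averaged modified signature score for the
#' sample, and summarise the replicate scores as mean and standard
#' deviation (denominator `R - 1`). When the grouping carries species ids,
#' one strain per species is kept before sampling (the lexicographically
#' smallest taxon id). Deterministic given `seed`.
#'
#' @param x An [msa].
#' @param grouping A [taxon_grouping].
#' @param group_x,group_y Labels of the two groups to compare.
#' @param n Taxa sampled per group per replicate (default 10).
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed for the sampling stream.
#' @return Object of class `signature_comparison`: `groups`, `n`, `reps`,
#'   `seed`, `scores` (length `reps`), `mean`, `sd`.
#' @export
compare_phyla <- function(x, grouping, group_x, group_y, n = 10L,
                          reps = 1000L, seed = 1L) {
  pool_x <- intersect(group_taxa(grouping, group_x, one_per_species = TRUE),
                      x$taxa)
  pool_y <- intersect(group_taxa(grouping, group_y, one_per_species = TRUE),
                      x$taxa)
  if (length(pool_x) < n) {
    stop("group '", group_x, "' has only ", length(pool_x),
         " eligible taxa, need ", n)
  }
  if (length(pool_y) < n) {
    stop("group '", group_y, "' has only ", length(pool_y),
         " eligible taxa, need ", n)
  }
  set.seed(seed)
  scores <- vapply(seq_len(reps), function(r) {
    ta <- sample(pool_x, n)
    tb <- sample(pool_y, n)
    alignment_mean_score(x, ta, tb)$mean
  }, numeric(1L))
  structure(list(groups = c(group_x, group_y), n = n, reps = reps,
                 seed = seed, scores = scores,
                 mean = mean(scores),
                 sd = if (reps > 1L) stats::sd(scores) else NA_real_),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("Signature comparison %s vs %s: %.3f+/-%.3f (n=%d, %d replicates)\n",
              x$groups[1L], x$groups[2L], x$mean, x$sd, x$n, x$reps))
  invisible(x)
}

#' Closest group and two-standard-deviation set
#'
#' Given signature comparisons of one focal group against several candidate
#' groups, reports the candidate with the lowest mean score (most similar)
#' and the set of candidates whose mean lies within two combined standard
#' deviations of it: candidate i is in the set iff
#' `|mean_i - mean_min| <= 2 * sqrt(sd_i^2 + sd_min^2)`.
#'
#' @param comparisons Named list of `signature_comparison` objects (names
#'   label the candidate groups).
#' @return List with `closest` (name), `within_two_sd` (character vector,
#'   always containing `closest`) and a summary data frame `table`.
#' @export
closest_group_call <- function(comparisons) {
  if (length(comparisons) == 0L) stop("no comparisons given")
  if (is.null(names(comparisons))) {
    names(comparisons) <- vapply(comparisons, function(cc) cc$groups[2L],
                                 character(1L))
  }
  means <- vapply(comparisons, `[[`, numeric(1L), "mean")
  sds <- vapply(comparisons, `[[`, numeric(1L), "sd")
  imin <- which.min(means)
  thr <- 2 * sqrt(sds^2 + sds[imin]^2)
  within <- abs(means - means[imin]) <= thr
  list(closest = names(comparisons)[imin],
       within_two_sd = names(comparisons)[within],
       table = data.frame(group = names(comparisons), mean = unname(means),
                          sd = unname(sds), within = unname(within)))
}
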