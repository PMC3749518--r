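#' Clade-cover table across gene trees
#'
#' Fills a trees-by-groups table with minimum clade-cover sizes: for each
#' gene tree and each taxonomic group, the number of disjoint clades (with
#' an intruder allowance) needed to encompass the group's leaves present in
#' that tree. Groups represented in a tree by fewer than `min_taxa` leaves
#' get a missing cell.
#'
#' @param trees Named list of rooted [ape::phylo] trees (names label rows).
#' @param grouping A [taxon_grouping] mapping leaves to taxonomic groups.
#' @param focal Focal group label (first column; defines the
#'   monophyletic/polyphyletic partition).
#' @param reference_groups Character vector of reference group labels whose
#'   cover sizes are summed per tree.
#' @param budget Intruder allowance passed to [min_clade_cover].
#' @param mode Budget mode, see [min_clade_cover].
#' @param min_taxa Minimum leaves of a group required in a tree for its cell
#'   to be computed (default 2; an underrepresented group is reported as NA).
#' @return Object of class `coherence_table`: integer matrix `cells`
#'   (rows = trees; columns = focal then reference groups) plus the summary
#'   of [coherence_summary].
#' @export
coherence_table <- function(trees, grouping, focal, reference_groups,
                            budget = 5L, mode = "per-clade", min_taxa = 2L) {
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  groups <- c(focal, reference_groups)
  cells <- matrix(NA_integer_, nrow = length(trees), ncol = length(groups),
                  dimnames = list(names(trees), groups))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    for (g in groups) {
      leaves <- intersect(group_taxa(grouping, g), tr$tip.label)
      if (length(leaves) < min_taxa) next
      cells[i, g] <- min_clade_cover(tr, leaves, budget = budget, mode = mode)$k
    }
  }
  out <- coherence_summary(cells, focal = focal)
  out$budget <- budget
  out$mode <- mode
  out
}

#' Summarise a clade-cover table
#'
#' Computes, from a trees-by-groups matrix of cover sizes, the per-tree sum
#' over the reference groups (missing cells excluded), the partition of
#' trees into those where the focal group is monophyletic (focal cell = 1)
#' versus polyphyletic (> 1), each partition's mean sum and standard error
#' of the mean, and a one-sided Welch two-sample t-test of whether the
#' polyphyletic trees need more clades overall.
#'
#' @param cells Integer matrix, rows = trees, columns = groups; the focal
#'   group's column is excluded from the row sums.
#' @param focal Column name of the focal group (default: first column).
#' @return Object of class `coherence_table` with elements `cells`, `sums`,
#'   `monophyletic` (logical per tree), `mono_sums`, `poly_sums`,
#'   `mono_mean`, `mono_sem`, `poly_mean`, `poly_sem`, `test` (an `htest`
#'   from [partition_test], or NULL if either partition has < 2 trees).
#' @export
coherence_summary <- function(cells, focal = colnames(cells)[1L]) {
  if (!focal %in% colnames(cells)) stop("focal column '", focal, "' not in table")
  ref <- setdiff(colnames(cells), focal)
  sums <- rowSums(cells[, ref, drop = FALSE], na.rm = TRUE)
  mono <- !is.na(cells[, focal]) & cells[, focal] == 1L
  mono_sums <- sums[mono]
  poly_sums <- sums[!mono]
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  test <- if (length(mono_sums) > 1L && length(poly_sums) > 1L) {
    partition_test(mono_sums, poly_sums)
  } else NULL
  structure(list(cells = cells, focal = focal, sums = sums,
                 monophyletic = mono,
                 mono_sums = mono_sums, poly_sums = poly_sums,
                 mono_mean = mean(mono_sums), mono_sem = sem(mono_sums),
                 poly_mean = mean(poly_sums), poly_sem = sem(poly_sums),
                 test = test),
            class = "coherence_table")
}

#' @export
print.coherence_table <- function(x, ...) {
  cat("Clade-cover coherence table: ", nrow(x$cells), " trees, focal group '",
      x$focal, "'\n", sep = "")
  cat(sprintf("  monophyletic trees (n=%d): mean sum %.1f +/- %.1f (sem)\n",
              length(x$mono_sums), x$mono_mean, x$mono_sem))
  cat(sprintf("  polyphyletic trees (n=%d): mean sum %.1f +/- %.1f (sem)\n",
              length(x$poly_sums), x$poly_mean, x$poly_sem))
  if (!is.null(x$test)) {
    cat(sprintf("  one-sided Welch t-test (poly > mono): t = %.2f, P = %.4f\n",
                unname(x$test$statistic), x$test$p.value))
  }
  invisible(x)
}

#' Test whether polyphyletic trees are less coherent overall
#'
#' One-sided Welch two-sample t-test of the per-tree sums of clade-cover
#' sizes, alternative: the polyphyletic partition has the larger mean.
#'
#' @param mono_sums Sums for trees with a monophyletic focal group.
#' @param poly_sums Sums for trees with a polyphyletic focal group.
#' @return An object of class `htest`.
#' @export
partition_test <- function(mono_sums, poly_sums) {
  stats::t.test(poly_sums, mono_sums, alternative = "greater",
                var.equal = FALSE)
}

#' Bundled subtree counts for aminoacyl-tRNA synthetase gene trees
#'
#' Loads the reference dataset shipped with the package: for each of 18
#' aminoacyl-tRNA synthetase protein trees, the number of monophyletic
#' subtrees needed to encompass the focal group (classes Mollicutes +
#' Erysipelotrichia) and seven reference taxonomic groups, with NA where a
#' group was underrepresented in a tree, plus the published per-tree sum.
#'
#' @return List with `cells` (matrix suitable for [coherence_summary]) and
#'   `published_sum` (named numeric vector).
#' @export
aars_subtree_counts <- function() {
  path <- system.file("extdata", "aars_subtree_counts.tsv", package = "cladesig")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cells <- as.matrix(df[, setdiff(names(df), c("tree", "published_sum"))])
  rownames(cells) <- df$tree
  list(cells = cells, published_sum = stats::setNames(df$published_sum, df$tree))
}
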