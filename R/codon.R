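# Synonymous-codon families under the standard genetic code: amino acid ->
# codons. Stop codons are excluded; Met and Trp are singleton families.
codon_families <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      fams <- split(names(gc), unname(gc))
      cache <<- fams[names(fams) != "*"]
    }
    cache
  }
})

#' The 61 sense codons of the standard genetic code
#' @return Character vector, alphabetical order.
#' @export
sense_codons <- function() {
  sort(unlist(codon_families(), use.names = FALSE))
}

#' Count codons in a coding sequence
#'
#' @param cds A nucleotide coding sequence (string; `U` accepted).
#' @param id Optional gene id attached to the result.
#' @return Named integer vector over the 61 sense codons, with attributes
#'   `length` (sense codons counted), `internal_stop` (logical) and `id`.
#'   Stop codons and codons containing non-ACGT characters are excluded
#'   from the counts; an internal stop raises a warning and sets the flag.
#' @export
count_codons <- function(cds, id = NULL) {
  cds <- toupper(gsub("U", "T", cds, fixed = TRUE))
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length ", n, " is not a positive multiple of 3",
         if (!is.null(id)) paste0(" (gene '", id, "')") else "")
  }
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  stops <- which(!is.na(aa) & aa == "*")
  internal_stop <- any(stops < length(codons))
  if (internal_stop) {
    warning("internal stop codon in ",
            if (is.null(id)) "CDS" else paste0("gene '", id, "'"))
  }
  keep <- codons[!is.na(aa) & aa != "*"]
  counts <- table(factor(keep, levels = sense_codons()))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "length") <- length(keep)
  attr(out, "internal_stop") <- internal_stop
  attr(out, "id") <- id
  out
}

#' Count codons for a set of coding sequences
#'
#' @param seqs Named character vector of CDS strings, or a path to a FASTA
#'   file of coding sequences.
#' @return Integer matrix, rows = genes, columns = the 61 sense codons.
#' @export
count_cds_set <- function(seqs) {
  if (length(seqs) == 1L && file.exists(seqs)) {
    set <- Biostrings::readBStringSet(seqs)
    seqs <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("gene", seq_along(seqs))
  m <- t(vapply(names(seqs), function(id) count_codons(seqs[[id]], id = id),
                integer(61L)))
  colnames(m) <- sense_codons()
  m
}

#' Codon-usage profile from pooled codon counts
#'
#' Relative synonymous frequencies: each codon's frequency within its
#' amino-acid family. Families with no observations get uniform
#' frequencies, so every family sums to 1.
#'
#' @param counts Named numeric vector (or single-row slice) over the 61
#'   sense codons.
#' @return Named numeric vector over the 61 sense codons, class
#'   `codon_profile`.
#' @export
codon_profile_from_counts <- function(counts) {
  counts <- counts[sense_codons()]
  prof <- stats::setNames(numeric(61L), sense_codons())
  for (fam in codon_families()) {
    tot <- sum(counts[fam])
    prof[fam] <- if (tot > 0) counts[fam] / tot else 1 / length(fam)
  }
  class(prof) <- c("codon_profile", "numeric")
  prof
}

#' Reference codon-usage profiles for simulation
#'
#' Convenience profiles with a named synonymous-preference structure:
#' `"uniform"` (equal use of synonyms), `"at_rich"`/`"gc_rich"` (3:1
#' preference for codons ending in A/T, resp. G/C — the weak-ending bias
#' typical of low-G+C genomes), and `"at_only"`/`"gc_only"` (all synonymous
#' mass on A/T-ending, resp. G/C-ending codons, a fully disjoint
#' preference pair; families whose codons all share an ending keep uniform
#' use).
#'
#' @param bias One of `"uniform"`, `"at_rich"`, `"gc_rich"`, `"at_only"`,
#'   `"gc_only"`.
#' @return A `codon_profile`.
#' @export
codon_profile <- function(bias = c("uniform", "at_rich", "gc_rich",
                                   "at_only", "gc_only")) {
  bias <- match.arg(bias)
  codons <- sense_codons()
  third <- substr(codons, 3L, 3L)
  w <- stats::setNames(rep(1, 61L), codons)
  if (bias == "at_rich") w[third %in% c("A", "T")] <- 3
  if (bias == "gc_rich") w[third %in% c("G", "C")] <- 3
  if (bias == "at_only") w[third %in% c("G", "C")] <- 0
  if (bias == "gc_only") w[third %in% c("A", "T")] <- 0
  prof <- stats::setNames(numeric(61L), codons)
  for (fam in codon_families()) {
    tot <- sum(w[fam])
    prof[fam] <- if (tot > 0) w[fam] / tot else 1 / length(fam)
  }
  class(prof) <- c("codon_profile", "numeric")
  prof
}

#' Chi-squared codon-usage match of a gene against a reference profile
#'
#' Compares a gene's codon counts to a reference usage, conditioning on the
#' gene's amino-acid composition: within each synonymous family the
#' expected count of a codon is the family's observed total times the
#' reference frequency. Families with fewer than 2 synonyms or fewer than
#' 2 observed codons contribute nothing. The statistic sums
#' `(obs - exp)^2 / exp` over codons with positive expectation; degrees of
#' freedom add `(number of synonyms with exp > 0) - 1` per contributing
#' family. The gene matches when the upper-tail p-value is at least
#' `threshold`.
#'
#' @param counts Named numeric vector over the 61 sense codons.
#' @param profile A `codon_profile`.
#' @param threshold Match threshold on the p-value (default 0.1).
#' @return List with `statistic`, `df`, `p_value`, `match`, `testable`. An
#'   untestable gene (no contributing family) has `match = NA`.
#' @export
chisq_match <- function(counts, profile, threshold = 0.1) {
  counts <- counts[sense_codons()]
  if (sum(counts) < 1) stop("gene has no codon counts")
  stat <- 0
  df <- 0L
  for (fam in codon_families()) {
    if (length(fam) < 2L) next
    tot <- sum(counts[fam])
    if (tot < 2) next
    ex <- tot * profile[fam]
    use <- ex > 0
    if (sum(use) < 1L) next
    stat <- stat + sum((counts[fam][use] - ex[use])^2 / ex[use])
    df <- df + sum(use) - 1L
  }
  if (df == 0L) {
    return(list(statistic = NA_real_, df = 0L, p_value = NA_real_,
                match = NA, testable = FALSE))
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, match = p >= threshold,
       testable = TRUE)
}

#' Match every gene of a genome against a reference profile
#'
#' @param genes Integer matrix of codon counts (rows = genes, columns = the
#'   61 sense codons), as from [count_cds_set] or [simulate_genes].
#' @param profile A `codon_profile`.
#' @param threshold Match threshold (default 0.1).
#' @return Data frame with one row per gene: `gene`, `statistic`, `df`,
#'   `p_value`, `match`, `testable`.
#' @export
match_profile <- function(genes, profile, threshold = 0.1) {
  res <- lapply(rownames(genes), function(g) {
    r <- chisq_match(genes[g, ], profile, threshold = threshold)
    data.frame(gene = g, statistic = r$statistic, df = r$df,
               p_value = r$p_value, match = r$match, testable = r$testable)
  })
  do.call(rbind, res)
}

#' Modal codon usage of a genome
#'
#' Estimates the codon-usage profile matched by the largest number of the
#' genome's genes: starting from the genome-total usage, alternate between
#' (i) testing every gene against the current profile with [chisq_match]
#' and (ii) recomputing the profile from the pooled counts of the matching
#' genes, until the matched set stabilises (or `max_iter` iterations).
#'
#' When a genome is a strong mixture (e.g. a large horizontally acquired
#' fraction with very different usage), the genome-total profile can be
#' matched by no gene at all; the iteration then reseeds the profile from
#' the pooled counts of the best-agreeing tenth of the genes (highest
#' p-values) and continues, so the mode is climbed from the densest region
#' instead of the mixture average. If even the reseeded profile is matched
#' by no gene, the genome-total profile is returned with an empty matched
#' set and a warning.
#'
#' @param genes Integer matrix of codon counts (>= 10 genes).
#' @param threshold Match threshold (default 0.1).
#' @param max_iter Iteration cap (default 100).
#' @return List with `profile` (a `codon_profile`), `matched` (gene ids),
#'   `iterations`, `matched_history` (matched-set size per iteration).
#' @export
modal_usage <- function(genes, threshold = 0.1, max_iter = 100L) {
  if (nrow(genes) < 10L) stop("modal usage needs at least 10 genes")
  initial <- codon_profile_from_counts(colSums(genes))
  prof <- initial
  matched_prev <- NULL
  history <- integer(0L)
  reseeded <- FALSE
  for (it in seq_len(max_iter)) {
    res <- match_profile(genes, prof, threshold = threshold)
    matched <- res$gene[res$testable & res$match]
    history <- c(history, length(matched))
    if (length(matched) == 0L) {
      if (reseeded) {
        warning("no gene matches the genome-wide or reseeded usage")
        return(list(profile = initial, matched = character(0L),
                    iterations = it, matched_history = history))
      }
      reseeded <- TRUE
      ord <- order(-res$p_value, res$statistic)
      matched <- res$gene[ord][seq_len(max(10L, ceiling(0.1 * nrow(genes))))]
    }
    if (!is.null(matched_prev) && setequal(matched, matched_prev)) break
    matched_prev <- matched
    prof <- codon_profile_from_counts(colSums(genes[matched, , drop = FALSE]))
  }
  list(profile = prof, matched = matched, iterations = it,
       matched_history = history)
}

#' Percentage of genes matching any of several reference usages
#'
#' A gene matches when its p-value reaches the threshold against at least
#' one profile; the percentage is over testable genes (genes untestable
#' against every profile are excluded from the denominator).
#'
#' @param genes Integer matrix of codon counts.
#' @param profiles List of `codon_profile`s.
#' @param threshold Match threshold (default 0.1).
#' @return List with `percent`, `report` (data frame: `gene`, `match`,
#'   `best_profile`, `best_p`, `testable`) and `n_testable`.
#' @export
percent_matching_any <- function(genes, profiles, threshold = 0.1) {
  ids <- rownames(genes)
  if (length(profiles) == 0L) {
    return(list(percent = 0,
                report = data.frame(gene = ids, match = FALSE,
                                    best_profile = NA_character_,
                                    best_p = NA_real_, testable = NA),
                n_testable = NA_integer_))
  }
  if (is.null(names(profiles))) names(profiles) <- paste0("profile", seq_along(profiles))
  pmat <- vapply(profiles, function(pr) match_profile(genes, pr, threshold)$p_value,
                 numeric(length(ids)))
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = length(ids))
  testable <- apply(pmat, 1L, function(p) any(!is.na(p)))
  if (!any(testable)) stop("no testable genes")
  best_p <- apply(pmat, 1L, function(p) if (all(is.na(p))) NA_real_ else max(p, na.rm = TRUE))
  best_profile <- names(profiles)[apply(pmat, 1L, function(p) {
    if (all(is.na(p))) NA_integer_ else which.max(p)
  })]
  match <- !is.na(best_p) & best_p >= threshold
  list(percent = 100 * sum(match) / sum(testable),
       report = data.frame(gene = ids, match = match,
                           best_profile = best_profile, best_p = best_p,
                           testable = testable),
       n_testable = sum(testable))
}

#' Partition a genome into native and non-native genes
#'
#' Native genes match the genome's own modal codon usage (candidates for
#' vertical inheritance); non-native genes do not (candidates for
#' horizontal acquisition). Untestable genes are reported separately.
#'
#' @param genes Integer matrix of codon counts.
#' @param threshold Match threshold (default 0.1).
#' @return List with `native`, `non_native`, `untestable` (gene id
#'   vectors) and `modal` (the [modal_usage] fit).
#' @export
native_partition <- function(genes, threshold = 0.1) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty genome")
  fit <- modal_usage(genes, threshold = threshold)
  res <- match_profile(genes, fit$profile, threshold = threshold)
  list(native = res$gene[res$testable & res$match],
       non_native = res$gene[res$testable & !res$match],
       untestable = res$gene[!res$testable],
       modal = fit)
}

#' Mean G+C content of a set of coding sequences
#'
#' Unweighted mean over genes of the per-gene percentage of G and C
#' residues.
#'
#' @param seqs Named character vector of CDS strings, or a FASTA path.
#' @return Percent G+C (scalar) with attribute `per_gene`.
#' @export
mean_gc <- function(seqs) {
  if (length(seqs) == 1L && file.exists(seqs)) {
    set <- Biostrings::readBStringSet(seqs)
    seqs <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  per_gene <- vapply(seqs, function(s) {
    s <- toupper(gsub("U", "T", s, fixed = TRUE))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars <- chars[chars %in% c("A", "C", "G", "T")]
    if (length(chars) == 0L) stop("sequence with no unambiguous nucleotides")
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1L))
  out <- mean(per_gene)
  attr(out, "per_gene") <- per_gene
  out
}

#' Total-variation distance between two codon-usage profiles
#'
#' Averaged over synonymous families: half the L1 distance between the
#' within-family frequency vectors, averaged across the multi-codon
#' families.
#'
#' @param p,q `codon_profile`s.
#' @return Scalar in `[0, 1]`.
#' @export
profile_tv_distance <- function(p, q) {
  fams <- Filter(function(f) length(f) > 1L, codon_families())
  tv <- vapply(fams, function(fam) 0.5 * sum(abs(p[fam] - q[fam])), numeric(1L))
  mean(tv)
}
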