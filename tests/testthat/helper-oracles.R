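# Independent brute-force oracles, kept deliberately naive: they enumerate
# rather than exploit the laminar structure the implementations rely on.

# All ways to cover the group leaves of a subtree with disjoint clades:
# recursively, either take the whole clade at this node or combine covers of
# the children (cross product). Returns a list of integer node-id vectors.
enumerate_covers <- function(tree, n_grp, children, v) {
  if (n_grp[v] == 0L) return(list(integer(0L)))
  kids <- children[[as.character(v)]]
  out <- list(v)
  if (!is.null(kids)) {
    combos <- list(integer(0L))
    for (ch in kids) {
      sub <- enumerate_covers(tree, n_grp, children, ch)
      combos <- unlist(lapply(combos, function(a) {
        lapply(sub, function(b) c(a, b))
      }), recursive = FALSE)
    }
    out <- c(out, combos)
  }
  out
}

# Exhaustive minimum clade cover (both budget modes) for small trees.
brute_force_cover <- function(tree, group, budget, mode = "per-clade") {
  sets <- enumerate_clades(tree)
  n_grp <- vapply(sets, function(s) sum(s %in% group), integer(1L))
  n_for <- lengths(sets) - n_grp
  root <- ape::Ntip(tree) + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  covers <- enumerate_covers(tree, n_grp, children, root)
  ok <- vapply(covers, function(cv) {
    if (length(cv) == 0L) return(FALSE)
    if (mode == "per-clade") all(n_for[cv] <= budget) else sum(n_for[cv]) <= budget
  }, logical(1L))
  if (!any(ok)) return(Inf)
  min(lengths(covers[ok]))
}

# Exhaustive single-gain parsimony: smallest set of all-absent clades whose
# union is exactly the absent tip set.
brute_force_dollo <- function(tree, states) {
  tips <- tree$tip.label
  absent_tips <- tips[!states[tips]]
  if (length(absent_tips) == 0L) return(0L)
  sets <- enumerate_clades(tree)
  cand <- which(vapply(sets, function(s) all(s %in% absent_tips), logical(1L)))
  best <- Inf
  for (k in seq_along(cand)) {
    for (combo in utils::combn(cand, k, simplify = FALSE)) {
      if (setequal(unlist(sets[combo]), absent_tips)) {
        best <- k
        break
      }
    }
    if (is.finite(best)) break
  }
  best
}

# A planted loss set is recoverable from the tip pattern iff no loss branch
# is nested below another AND every loss branch's parent clade still has a
# present tip (otherwise sibling losses merge into one ancestral loss).
losses_recoverable <- function(tree, planted, states) {
  sets <- enumerate_clades(tree)
  for (v in planted) {
    for (w in setdiff(planted, v)) {
      if (all(sets[[v]] %in% sets[[w]])) return(FALSE)
    }
  }
  parent <- integer(length(sets))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (v in planted) {
    par_tips <- sets[[parent[v]]]
    if (!any(states[par_tips])) return(FALSE)
  }
  TRUE
}

# Random grouping over a tree's tips
random_group <- function(tree, frac = 0.4) {
  n <- ape::Ntip(tree)
  k <- max(1L, round(frac * n))
  sample(tree$tip.label, k)
}

# Build an msa from bare strings with automatic ids
quick_msa <- function(..., alphabet = "nucleotide", ids = NULL) {
  seqs <- c(...)
  if (is.null(ids)) ids <- sprintf("t%02d", seq_along(seqs))
  msa(stats::setNames(seqs, ids), alphabet = alphabet)
}

# Composition vector over the standard alphabet from residue characters
comp_vec <- function(chars, alphabet = "nucleotide") {
  as.numeric(table(factor(chars, levels = alignment_alphabet(alphabet))))
}
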