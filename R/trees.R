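#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree] that enforces unique leaf labels.
#' Polytomies are allowed.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  } else {
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse error: no tree read")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a tree to Newick
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree on an outgroup leaf
#'
#' Places the root on the edge subtending the named leaf, preserving all
#' other structure. Rooting an already correctly rooted tree is a no-op.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Leaf label to root on.
#' @return A rooted [ape::phylo] tree.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' not in tree; available leaves: ",
         paste(utils::head(sort(tree$tip.label), 10L), collapse = ", "),
         if (length(tree$tip.label) > 10L) ", ..." else "")
  }
  if (ape::is.rooted(tree)) {
    kids <- tree$edge[tree$edge[, 1L] == ape::Ntip(tree) + 1L, 2L]
    og <- which(tree$tip.label == outgroup)
    if (og %in% kids) return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# Leaf-label sets below every node (tips and internal nodes), indexed by
# node number. Computed in one postorder pass; polytomies supported.
node_leaf_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; chd <- ord$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  sets
}

#' Enumerate all clades of a rooted tree
#'
#' A clade is the set of leaves below one node; every leaf is itself a
#' (trivial) clade, and the root clade is the full leaf set. The number of
#' clades equals the number of nodes.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @return List of character vectors of leaf labels, one per node.
#' @export
enumerate_clades <- function(tree) {
  node_leaf_sets(tree)
}

#' Minimum clade cover of a taxon group
#'
#' Finds the minimum number of pairwise-disjoint clades whose union contains
#' every leaf of a taxonomic group, tolerating up to `budget` foreign
#' ("intruder") leaves. With `mode = "per-clade"` the budget applies to each
#' chosen clade independently; with `mode = "total"` it bounds the summed
#' foreign count over the whole cover. A group coverable by a single clade
#' is called monophyletic (within the allowance); a group needing more is
#' polyphyletic.
#'
#' For `mode = "per-clade"` the optimum is the number of maximal
#' budget-eligible clades containing at least one group leaf: clades form a
#' laminar family, so the maximal eligible clades are pairwise disjoint, no
#' single eligible clade can contain two of them, and every group leaf lies
#' in one (a leaf is a clade with zero foreign leaves). `mode = "total"`
#' uses an exact dynamic program over the tree with the foreign budget as
#' knapsack state.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param group Character vector of group leaf labels.
#' @param budget Maximum number of foreign leaves tolerated (default 5).
#' @param mode `"per-clade"` (default) or `"total"`.
#' @return List of class `clade_cover`: `k` (cover size), `clades` (list of
#'   leaf sets, largest first, ties by smallest leaf label), `foreign`
#'   (foreign-leaf count per chosen clade), `monophyletic` (`k == 1`),
#'   `budget`, `mode`, `group`.
#' @export
min_clade_cover <- function(tree, group, budget = 5L, mode = c("per-clade", "total")) {
  mode <- match.arg(mode)
  if (length(group) == 0L) stop("group is empty")
  missing <- setdiff(group, tree$tip.label)
  if (length(missing) > 0L) {
    stop("group leaves absent from tree: ", paste(missing, collapse = ", "))
  }
  sets <- node_leaf_sets(tree)
  n_grp <- vapply(sets, function(s) sum(s %in% group), integer(1L))
  n_for <- lengths(sets) - n_grp
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])

  chosen <- integer(0L)
  if (mode == "per-clade") {
    eligible <- n_for <= budget
    # preorder walk: take a node if eligible and containing group leaves,
    # otherwise descend
    stack <- root
    while (length(stack) > 0L) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (n_grp[v] == 0L) next
      if (eligible[v]) {
        chosen <- c(chosen, v)
      } else {
        stack <- c(children[[as.character(v)]], stack)
      }
    }
  } else {
    chosen <- cover_dp_total(tree, sets, n_grp, n_for, budget, root, children)
  }
  ord_sz <- order(-lengths(sets[chosen]),
                  vapply(sets[chosen], min, character(1L)))
  chosen <- chosen[ord_sz]
  structure(list(group = group, k = length(chosen),
                 clades = sets[chosen], foreign = unname(n_for[chosen]),
                 monophyletic = length(chosen) == 1L,
                 budget = budget, mode = mode),
            class = "clade_cover")
}

#' @export
print.clade_cover <- function(x, ...) {
  cat("Minimum clade cover: k = ", x$k, " (",
      if (x$monophyletic) "monophyletic" else "polyphyletic",
      "), budget ", x$budget, " [", x$mode, "]\n", sep = "")
  for (i in seq_len(x$k)) {
    cat("  clade ", i, ": ", length(x$clades[[i]]), " leaves, ",
        x$foreign[i], " foreign\n", sep = "")
  }
  invisible(x)
}

# Exact DP for the total-budget mode. best[[v]][j+1] = minimum number of
# clades inside the subtree of v covering all its group leaves with at most
# j foreign leaves in total (Inf when infeasible, 0 when no group leaves).
# Children are combined by min-plus convolution over the budget; the
# per-child prefix arrays are kept for reconstruction.
cover_dp_total <- function(tree, sets, n_grp, n_for, budget, root, children) {
  nnode <- length(sets)
  nb <- budget + 1L
  best <- vector("list", nnode)
  pref <- vector("list", nnode)   # list of prefix arrays over children
  post <- ape::reorder.phylo(tree, "postorder")
  order_nodes <- c(post$edge[, 2L], root)
  for (v in order_nodes) {
    if (n_grp[v] == 0L) {
      best[[v]] <- rep(0, nb)
      next
    }
    kids <- children[[as.character(v)]]
    if (is.null(kids)) {           # a group leaf: must be taken itself
      comb <- rep(Inf, nb)
    } else {
      p <- vector("list", length(kids) + 1L)
      p[[1L]] <- rep(0, nb)
      for (i in seq_along(kids)) {
        cur <- p[[i]]; chb <- best[[kids[i]]]
        newc <- rep(Inf, nb)
        for (j in seq_len(nb)) {
          if (!is.finite(cur[j])) next
          for (l in seq_len(nb - j + 1L)) {
            cand <- cur[j] + chb[l]
            if (cand < newc[j + l - 1L]) newc[j + l - 1L] <- cand
          }
        }
        p[[i + 1L]] <- newc
      }
      pref[[v]] <- p
      comb <- p[[length(kids) + 1L]]
    }
    take <- rep(Inf, nb)
    if (n_for[v] <= budget) take[(n_for[v] + 1L):nb] <- 1
    best[[v]] <- pmin(comb, take)
  }
  if (!is.finite(best[[root]][nb])) {
    stop("no cover of the group within total foreign budget ", budget)
  }
  chosen <- integer(0L)
  rec <- function(v, j) {          # j = foreign budget allotted to v's subtree
    if (n_grp[v] == 0L) return(invisible(NULL))
    kids <- children[[as.character(v)]]
    take_cost <- if (n_for[v] <= j) 1 else Inf
    comb_cost <- if (is.null(kids)) Inf else pref[[v]][[length(kids) + 1L]][j + 1L]
    if (take_cost <= comb_cost) {
      chosen <<- c(chosen, v)
      return(invisible(NULL))
    }
    # undo the child convolution: walk children backwards finding a split
    rem <- j
    for (i in rev(seq_along(kids))) {
      target <- pref[[v]][[i + 1L]][rem + 1L]
      for (l in 0:rem) {
        if (is.finite(pref[[v]][[i]][rem - l + 1L]) &&
            is.finite(best[[kids[i]]][l + 1L]) &&
            pref[[v]][[i]][rem - l + 1L] + best[[kids[i]]][l + 1L] == target) {
          rec(kids[i], l)
          rem <- rem - l
          break
        }
      }
    }
    invisible(NULL)
  }
  rec(root, budget)
  chosen
}
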