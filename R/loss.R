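#' Single-origin (Dollo) loss map for one binary trait
#'
#' Assumes the trait was present in the root ancestor and can only be lost;
#' the minimum-loss reconstruction then places one loss event on the edge
#' subtending each maximal all-absent clade. The loss count is minimal
#' among all assignments with a single gain, absent tips fall below exactly
#' one loss branch, and present tips below none. Polytomies are supported
#' (a polytomy with several all-absent children yields one loss per such
#' child).
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param states Named logical vector over all tip labels, `TRUE` =
#'   present.
#' @return List of class `loss_map`: `count`, `loss_nodes` (child-node ids
#'   of the loss branches), `loss_clades` (leaf sets below each loss
#'   branch), `presence` (implied state per node, tips first).
#' @export
dollo_losses <- function(tree, states) {
  tips <- tree$tip.label
  if (!all(tips %in% names(states))) {
    stop("missing states for tips: ",
         paste(setdiff(tips, names(states)), collapse = ", "))
  }
  states <- as.logical(states[tips])
  if (anyNA(states)) stop("tip states must be TRUE/FALSE")
  if (!any(states)) stop("all tips absent: a single origin cannot be inferred")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  # absent(v): every tip below v is absent (postorder conjunction)
  absent <- c(!states, rep(TRUE, tree$Nnode))
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chd <- post$edge[k, 2L]
    absent[par] <- absent[par] && absent[chd]
  }
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  loss_nodes <- which(absent & seq_len(nnode) != root &
                      !absent[pmax(parent, 1L)])
  sets <- node_leaf_sets(tree)
  structure(list(count = length(loss_nodes),
                 loss_nodes = loss_nodes,
                 loss_clades = sets[loss_nodes],
                 presence = !absent),
            class = "loss_map")
}

#' @export
print.loss_map <- function(x, ...) {
  cat("Dollo loss map: ", x$count, " loss event(s)\n", sep = "")
  for (i in seq_along(x$loss_clades)) {
    cat("  loss ", i, ": clade {",
        paste(x$loss_clades[[i]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Loss maps for every trait of a presence matrix
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param presence Logical matrix, rows = taxa, columns = traits.
#' @return List with `maps` (named list of [dollo_losses] results),
#'   `counts` (named integer vector) and `range` (`c(min, max)` of loss
#'   counts across traits).
#' @export
loss_table <- function(tree, presence) {
  traits <- colnames(presence)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(presence)))
  maps <- lapply(seq_along(traits), function(j) {
    dollo_losses(tree, stats::setNames(presence[, j], rownames(presence)))
  })
  names(maps) <- traits
  counts <- vapply(maps, `[[`, integer(1L), "count")
  list(maps = maps, counts = counts, range = range(counts))
}
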