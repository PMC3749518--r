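# Random binary topology over a set of leaf labels, built by coalescent-style
# random pairwise joins. Nested-list form: a leaf is a label string, an
# internal node a list of two children.
random_topology_nested <- function(labels) {
  nodes <- as.list(sample(labels))
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    nodes <- c(nodes[-i], list(list(nodes[[i[1L]]], nodes[[i[2L]]])))
  }
  nodes[[1L]]
}

# Graft a leaf strictly inside a subtree: a random proper descendant D is
# replaced by (D, leaf), so the subtree's root clade always contains the
# grafted leaf (a single-leaf subtree is wrapped instead).
graft_inside <- function(tree, leaf) {
  paths <- list()
  walk <- function(node, path) {
    if (length(path) > 0L) paths[[length(paths) + 1L]] <<- path
    if (is.list(node)) for (i in seq_along(node)) walk(node[[i]], c(path, i))
  }
  walk(tree, integer(0L))
  if (length(paths) == 0L) return(list(tree, leaf))
  p <- paths[[sample.int(length(paths), 1L)]]
  tree[[p]] <- list(tree[[p]], leaf)
  tree
}

as_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, as_newick, character(1L)), collapse = ","), ")")
}

random_topology_newick <- function(labels) {
  as_newick(random_topology_nested(labels))
}

#' Simulate a two-group alignment with planted signature columns
#'
#' Generates an alignment of two equal-size taxon groups whose columns fall
#' into three categories: `signature` columns use disjoint character sets
#' between the groups (each group conserved to a consensus character of its
#' own half of the alphabet at level `conservation`), `conserved` columns
#' share a single character across all rows, and `random` columns draw every
#' cell uniformly from the alphabet. Each cell is independently gapped with
#' probability `gap_prob`. Ground-truth column categories are returned, so
#' downstream statistics can be checked against the planted structure.
#'
#' @param n_per_group Taxa per group (default 10).
#' @param n_columns Alignment columns (>= 1).
#' @param categories Named proportions for `signature`, `conserved`,
#'   `random` (normalised to sum to 1).
#' @param conservation Within-group consensus conservation of signature
#'   columns, in `[1/alphabet size, 1]` (default 1).
#' @param gap_prob Per-cell gap probability (default 0).
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return List with `alignment` (an [msa]), `grouping` (a
#'   [taxon_grouping] with groups `"A"` and `"B"`), `columns` (data frame
#'   `column`, `category`).
#' @export
simulate_alignment <- function(n_per_group = 10L, n_columns = 200L,
                               categories = c(signature = 0.1,
                                              conserved = 0.6,
                                              random = 0.3),
                               conservation = 1, gap_prob = 0,
                               alphabet = c("nucleotide", "amino-acid"),
                               seed = 1L) {
  alphabet <- match.arg(alphabet)
  letters_ <- alignment_alphabet(alphabet)
  if (n_columns < 1L) stop("need at least one column")
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be in [0, 1]")
  if (conservation > 1 || conservation < 1 / length(letters_)) {
    stop("conservation ", conservation, " not achievable (must be in [",
         signif(1 / length(letters_), 3), ", 1])")
  }
  categories <- categories[c("signature", "conserved", "random")]
  categories[is.na(categories)] <- 0
  if (any(categories < 0) || sum(categories) <= 0) stop("invalid category proportions")
  categories <- categories / sum(categories)
  set.seed(seed)
  n_sig <- round(categories[["signature"]] * n_columns)
  n_con <- round(categories[["conserved"]] * n_columns)
  n_con <- min(n_con, n_columns - n_sig)
  cat_vec <- sample(rep(c("signature", "conserved", "random"),
                        c(n_sig, n_con, n_columns - n_sig - n_con)))
  half <- length(letters_) / 2
  half_a <- letters_[seq_len(half)]
  half_b <- letters_[seq_len(half) + half]
  n <- 2L * n_per_group
  mat <- matrix("", nrow = n, ncol = n_columns)
  draw_conserved <- function(pool, m) {
    cons <- sample(pool, 1L)
    out <- rep(cons, m)
    noise <- stats::runif(m) > conservation
    if (any(noise) && length(pool) > 1L) {
      out[noise] <- sample(setdiff(pool, cons), sum(noise), replace = TRUE)
    }
    out
  }
  for (j in seq_len(n_columns)) {
    mat[, j] <- switch(cat_vec[j],
      signature = c(draw_conserved(half_a, n_per_group),
                    draw_conserved(half_b, n_per_group)),
      conserved = rep(sample(letters_, 1L), n),
      random = sample(letters_, n, replace = TRUE))
  }
  if (gap_prob > 0) mat[stats::runif(length(mat)) < gap_prob] <- "-"
  width <- max(2L, nchar(as.character(n_per_group)))
  ids <- c(sprintf(paste0("A%0", width, "d"), seq_len(n_per_group)),
           sprintf(paste0("B%0", width, "d"), seq_len(n_per_group)))
  seqs <- stats::setNames(apply(mat, 1L, paste, collapse = ""), ids)
  list(alignment = msa(seqs, alphabet = alphabet),
       grouping = taxon_grouping(ids, rep(c("A", "B"), each = n_per_group)),
       columns = data.frame(column = seq_len(n_columns), category = cat_vec))
}

#' Simulate a tree with a fragmented focal group and intruder leaves
#'
#' Builds a rooted tree in which the focal group's leaves occur in exactly
#' `fragments` maximal clades, each salted with `intruders` foreign leaves
#' (mimicking horizontal transfer into the group), with an outgroup leaf
#' attached at the root. Intruders are grafted strictly inside their
#' fragment, so when a fragment has at least two focal leaves the smallest
#' clade spanning them contains all of that fragment's intruders. The
#' backbone is a ladder alternating background blocks and focal fragments,
#' so any clade containing two fragments also contains at least one full
#' background block; fragments and blocks are themselves random binary
#' topologies, and all branch lengths are 1.
#'
#' @param n_focal Number of focal-group leaves (>= `fragments`).
#' @param n_background Number of background leaves (>= `fragments` when the
#'   group is fragmented).
#' @param fragments Number of maximal clades the focal group is split into
#'   (>= 1).
#' @param intruders Foreign leaves inserted inside each focal clade (>= 0).
#' @param outgroup Outgroup leaf label (default `"OUT"`).
#' @param seed Integer seed.
#' @return List with `tree` (rooted [ape::phylo]), `grouping` (groups
#'   `"focal"`, `"background"`, `"outgroup"`), `fragments` (list of focal
#'   leaf sets per planted clade), `n_fragments`.
#' @export
simulate_tree <- function(n_focal = 10L, n_background = 30L, fragments = 1L,
                          intruders = 0L, outgroup = "OUT", seed = 1L) {
  if (fragments < 1L) stop("fragments must be >= 1")
  if (intruders < 0L) stop("intruders must be >= 0")
  if (n_focal < fragments) stop("need at least one focal leaf per fragment")
  if (intruders > 0L && n_background == 0L) {
    stop("intruders requested but there are no background leaves")
  }
  if (fragments > 1L && n_background < fragments) {
    stop("need at least ", fragments, " background leaves to separate ",
         fragments, " fragments")
  }
  set.seed(seed)
  focal <- sprintf("F%03d", seq_len(n_focal))
  background <- if (n_background > 0L) sprintf("B%03d", seq_len(n_background)) else character(0L)
  frag_assign <- sort(rep_len(seq_len(fragments), n_focal))
  frag_leaves <- split(focal, frag_assign)
  intruder_leaves <- vector("list", fragments)
  frag_nwk <- character(fragments)
  for (f in seq_len(fragments)) {
    intruder_leaves[[f]] <- if (intruders > 0L) {
      sprintf("I%d_%02d", f, seq_len(intruders))
    } else character(0L)
    frag <- random_topology_nested(frag_leaves[[f]])
    for (intr in intruder_leaves[[f]]) frag <- graft_inside(frag, intr)
    frag_nwk[f] <- as_newick(frag)
  }
  n_blocks <- if (n_background >= fragments + 1L) fragments + 1L else
    min(fragments, n_background)
  if (n_blocks > 0L) {
    block_assign <- sort(rep_len(seq_len(n_blocks), n_background))
    blocks <- vapply(split(sample(background), block_assign),
                     random_topology_newick, character(1L))
  } else {
    blocks <- character(0L)
  }
  spine <- if (n_blocks > 0L) blocks[1L] else frag_nwk[1L]
  start_f <- if (n_blocks > 0L) 1L else 2L
  for (f in seq(start_f, length.out = fragments - start_f + 1L)) {
    spine <- paste0("(", spine, ",", frag_nwk[f], ")")
    if (f + 1L <= n_blocks) spine <- paste0("(", spine, ",", blocks[f + 1L], ")")
  }
  nwk <- paste0("(", outgroup, ",", spine, ");")
  tree <- read_tree(text = nwk)
  tree$edge.length <- rep(1, nrow(tree$edge))
  intr <- unlist(intruder_leaves)
  grouping <- taxon_grouping(
    c(focal, background, intr, outgroup),
    c(rep("focal", n_focal), rep("background", n_background + length(intr)),
      "outgroup"))
  list(tree = tree, grouping = grouping, fragments = unname(frag_leaves),
       n_fragments = fragments)
}

#' Simulate per-gene codon counts from reference usages
#'
#' Draws genes whose amino-acid composition is uniform over the 20
#' families and whose synonymous codons are multinomial within each family
#' according to the assigned profile. A specified fraction of genes is
#' drawn from a second ("foreign") profile, emulating horizontally acquired
#' genes of atypical codon usage.
#'
#' @param profile Native `codon_profile` (see [codon_profile]).
#' @param n_genes Number of genes.
#' @param len_range Two integers: inclusive range of gene lengths in codons
#'   (minimum >= 1).
#' @param foreign_fraction Fraction of genes drawn from `foreign_profile`
#'   (default 0).
#' @param foreign_profile `codon_profile` for the foreign genes (required
#'   when `foreign_fraction > 0`).
#' @param seed Integer seed.
#' @return List with `genes` (integer matrix, rows = genes, columns = the
#'   61 sense codons) and `labels` (character vector, `"native"` or
#'   `"foreign"` per gene).
#' @export
simulate_genes <- function(profile, n_genes = 100L, len_range = c(200L, 400L),
                           foreign_fraction = 0, foreign_profile = NULL,
                           seed = 1L) {
  if (any(len_range < 1L)) stop("gene length must be at least 1 codon")
  if (foreign_fraction < 0 || foreign_fraction > 1) {
    stop("foreign_fraction must be in [0, 1]")
  }
  if (foreign_fraction > 0 && is.null(foreign_profile)) {
    stop("foreign_fraction > 0 needs a foreign_profile")
  }
  set.seed(seed)
  n_foreign <- round(foreign_fraction * n_genes)
  labels <- sample(rep(c("foreign", "native"), c(n_foreign, n_genes - n_foreign)))
  fams <- codon_families()
  codons <- sense_codons()
  genes <- matrix(0L, nrow = n_genes, ncol = 61L,
                  dimnames = list(sprintf("g%04d", seq_len(n_genes)), codons))
  for (i in seq_len(n_genes)) {
    pr <- if (labels[i] == "foreign") foreign_profile else profile
    lens <- seq(len_range[1L], len_range[2L])
    len <- lens[sample.int(length(lens), 1L)]
    aa <- sample(names(fams), len, replace = TRUE)
    for (a in unique(aa)) {
      fam <- fams[[a]]
      cnt <- stats::rmultinom(1L, sum(aa == a), pr[fam])[, 1L]
      genes[i, fam] <- genes[i, fam] + as.integer(cnt)
    }
  }
  list(genes = genes, labels = labels)
}

#' Simulate independent trait losses on a tree
#'
#' Each trait starts present at the root and is lost independently on every
#' branch with probability `loss_prob`; all tips below a loss are absent.
#' The planted loss branches are returned per trait (including losses
#' nested below an earlier loss, which leave no separate trace in the tip
#' pattern).
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param n_traits Number of traits.
#' @param loss_prob Per-branch loss probability.
#' @param seed Integer seed.
#' @return List with `presence` (logical matrix tips x traits), `losses`
#'   (list per trait of planted child-node ids) and `effective_losses`
#'   (list per trait of the non-nested subset actually shaping the tip
#'   pattern).
#' @export
simulate_losses <- function(tree, n_traits = 6L, loss_prob = 0.05, seed = 1L) {
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must be in [0, 1]")
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  sets <- node_leaf_sets(tree)
  traits <- sprintf("trait%02d", seq_len(n_traits))
  presence <- matrix(TRUE, nrow = ntip, ncol = n_traits,
                     dimnames = list(tree$tip.label, traits))
  losses <- effective <- vector("list", n_traits)
  names(losses) <- names(effective) <- traits
  for (j in seq_len(n_traits)) {
    hit <- which(stats::runif(nedge) < loss_prob)
    loss_nodes <- tree$edge[hit, 2L]
    lost_tips <- unique(unlist(sets[loss_nodes]))
    presence[lost_tips, j] <- FALSE
    losses[[j]] <- loss_nodes
    # a loss is effective unless an ancestor branch also lost the trait
    eff <- loss_nodes[vapply(loss_nodes, function(v) {
      !any(vapply(setdiff(loss_nodes, v), function(w) {
        all(sets[[v]] %in% sets[[w]])
      }, logical(1L)))
    }, logical(1L))]
    effective[[j]] <- eff
  }
  list(presence = presence, losses = losses, effective_losses = effective)
}
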