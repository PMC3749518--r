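test_that("rooting on an outgroup places it as sister to everything else", {
  tr <- read_tree(text = "((a,b),(c,out));")
  rooted <- root_on_outgroup(tr, "out")
  sets <- enumerate_clades(rooted)
  expect_true(any(vapply(sets, setequal, logical(1L), c("a", "b", "c"))))
  # idempotent on the same outgroup
  again <- root_on_outgroup(rooted, "out")
  expect_true(ape::all.equal.phylo(rooted, again, use.edge.length = FALSE))
  expect_error(root_on_outgroup(tr, "zz"), "available leaves")
})

test_that("clade enumeration matches the node count", {
  expect_length(enumerate_clades(read_tree(text = "((a,b),(c,d));")), 7L)
  # caterpillar of n leaves has 2n - 1 clades
  for (n in c(4L, 7L)) {
    nwk <- Reduce(function(acc, x) paste0("(", acc, ",", x, ")"),
                  paste0("t", 2:n), paste0("t", 1L))
    expect_length(enumerate_clades(read_tree(text = paste0(nwk, ";"))),
                  2L * n - 1L)
  }
  # clades form a laminar family: pairwise nested or disjoint
  set.seed(12)
  tr <- ape::rtree(10L)
  sets <- enumerate_clades(tr)
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      expect_true(ov == 0L || ov == min(length(sets[[i]]), length(sets[[j]])))
    }
  }
})

test_that("minimum clade cover handles exact clades, splits and budgets", {
  tr <- read_tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  cc <- min_clade_cover(tr, c("a", "b"), budget = 0L)
  expect_equal(cc$k, 1L)
  expect_true(cc$monophyletic)
  expect_equal(cc$foreign, 0L)
  # group split across the root needs two clades
  cc2 <- min_clade_cover(tr, c("a", "b", "e", "f"), budget = 0L)
  expect_equal(cc2$k, 2L)
  expect_false(cc2$monophyletic)
  # a budget lets intruders ride along
  expect_equal(min_clade_cover(tr, c("a", "c"), budget = 2L)$k, 1L)
  expect_equal(min_clade_cover(tr, c("a", "c"), budget = 1L)$k, 2L)
  # budget 0 counts maximal pure-group clades
  expect_equal(min_clade_cover(tr, c("a", "b", "c"), budget = 0L)$k, 2L)
  expect_error(min_clade_cover(tr, c("a", "zz")), "zz")
  expect_error(min_clade_cover(tr, character(0L)), "empty")
})

test_that("cover size shrinks as the intruder budget grows", {
  set.seed(77)
  for (i in 1:25) {
    tr <- ape::rtree(sample(6:12, 1L))
    grp <- random_group(tr)
    ks <- vapply(0:6, function(b) min_clade_cover(tr, grp, budget = b)$k,
                 integer(1L))
    expect_true(all(diff(ks) <= 0L))
    # budget 0 and cover 1 means the group is a strict clade
    strict <- any(vapply(enumerate_clades(tr), setequal, logical(1L), grp))
    expect_equal(ks[1L] == 1L, strict)
  }
})

test_that("both budget modes equal the exhaustive optimum on random trees", {
  set.seed(31)
  for (i in 1:40) {
    tr <- ape::rtree(sample(5:10, 1L))
    grp <- random_group(tr)
    for (b in c(0L, 2L, 4L)) {
      expect_equal(min_clade_cover(tr, grp, budget = b, mode = "per-clade")$k,
                   brute_force_cover(tr, grp, b, "per-clade"))
      expect_equal(min_clade_cover(tr, grp, budget = b, mode = "total")$k,
                   brute_force_cover(tr, grp, b, "total"))
    }
  }
})

test_that("chosen clades are disjoint, cover the group and respect the budget", {
  set.seed(55)
  for (i in 1:20) {
    tr <- ape::rtree(12L)
    grp <- random_group(tr)
    cc <- min_clade_cover(tr, grp, budget = 3L)
    all_leaves <- unlist(cc$clades)
    expect_false(anyDuplicated(all_leaves) > 0L)
    expect_true(all(grp %in% all_leaves))
    expect_true(all(cc$foreign <= 3L))
  }
})

test_that("the coherence table recovers planted fragment counts", {
  grouping <- NULL
  trees <- list()
  for (f in 1:3) {
    sim <- simulate_tree(n_focal = 9L, n_background = 24L, fragments = f,
                         intruders = 2L, seed = 100L + f)
    trees[[paste0("tree", f)]] <- sim$tree
    grouping <- sim$grouping     # identical taxa labels across sims
  }
  tab <- coherence_table(trees, grouping, focal = "focal",
                         reference_groups = "background", budget = 5L)
  expect_equal(unname(tab$cells[, "focal"]), 1:3)
  # the background column is a cover size too, so sums are defined
  expect_true(all(is.finite(tab$sums)))
})

test_that("underrepresented groups get missing cells excluded from sums", {
  cells <- matrix(c(1L, 2L, 3L, NA, 4L, 1L), nrow = 2L,
                  dimnames = list(c("t1", "t2"), c("focal", "g1", "g2")))
  s <- coherence_summary(cells, focal = "focal")
  expect_equal(unname(s$sums), c(7L, 1L))
  expect_equal(unname(s$monophyletic), c(TRUE, FALSE))
})

test_that("the partition test is a one-sided Welch t-test", {
  mono <- c(10, 12, 14)
  poly <- c(20, 25, 30)
  res <- partition_test(mono, poly)
  # closed-form Welch statistic for the 3-vs-3 toy
  t_hand <- (mean(poly) - mean(mono)) /
    sqrt(var(poly) / 3 + var(mono) / 3)
  expect_equal(unname(res$statistic), t_hand)
  expect_lt(res$p.value, 0.05)
  # identical samples: no evidence of a difference
  same <- partition_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p.value, 0.5)
})
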