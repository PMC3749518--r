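test_that("base signature value hits its anchors", {
  # fully conserved disjoint residues, and alternating disjoint pairs
  expect_identical(kovbasa_base(comp_vec(c("A", "A", "A", "A")),
                                comp_vec(c("G", "G", "G", "G"))), 2)
  expect_identical(kovbasa_base(comp_vec(c("A", "T", "A", "T")),
                                comp_vec(c("G", "C", "G", "C"))), 2)
  # proportional compositions score 0
  expect_equal(kovbasa_base(comp_vec(c("A", "A")),
                            comp_vec(c("A", "A", "A", "A"))), 0)
  # partial overlap: unit vectors (1,0,0,0) vs (1,0,1,0)/sqrt(2)
  expect_equal(kovbasa_base(comp_vec(c("A", "A", "A", "A")),
                            comp_vec(c("A", "A", "G", "G"))),
               2 * (1 - 2 / sqrt(8)))
  # degenerate vectors
  expect_equal(kovbasa_base(c(0, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_true(is.na(kovbasa_base(c(0, 0, 0, 0), c(0, 0, 0, 0))))
})

test_that("conservation difference follows the largest-frequency rule", {
  aa <- "amino-acid"
  expect_equal(conservation_difference(comp_vec(c("W", "W", "W", "Y"), aa),
                                       comp_vec(c("A", "L", "V", "W"), aa)),
               0.5)
  expect_equal(conservation_difference(comp_vec(c("A", "A")),
                                       comp_vec(c("A", "A"))), 0)
  expect_equal(conservation_difference(comp_vec(c("A", "A", "A", "A")),
                                       comp_vec(c("G", "G", "G", "G"))), 1)
  # tie between groups: the pair maximising the difference wins
  expect_equal(conservation_difference(comp_vec(c("A", "A", "G", "G")),
                                       comp_vec(c("A", "A", "C", "C"))), 0.5)
})

test_that("modified column score combines base value, gaps and conservation", {
  grp <- rep(c("x", "y"), each = 4L)
  full <- modified_column_score(c("A", "A", "A", "A", "G", "G", "G", "G"), grp)
  expect_identical(full$M, 1)
  # S = 2 but only half-conserved: M = 2 * 1 * (0.5 / 2)
  alt <- modified_column_score(c("A", "T", "A", "T", "G", "C", "G", "C"), grp)
  expect_equal(alt$M, 0.5)
  # half the rows gapped: M = 2 * 0.5 * (1 / 2)
  gapped <- modified_column_score(c("A", "A", "-", "-", "G", "G", "-", "-"), grp)
  expect_equal(gapped$M, 0.5)
  expect_equal(gapped$g, 0.5)
  # one group entirely gapped: skipped, scores 0
  onesided <- modified_column_score(c("A", "A", "A", "A", "-", "-", "-", "-"), grp)
  expect_true(onesided$skipped)
  expect_identical(onesided$M, 0)
  expect_error(modified_column_score(c("A", "G"), c("x", "x")), "two groups")
})

test_that("column scores are bounded, symmetric and relabel-invariant", {
  set.seed(202)
  nuc <- alignment_alphabet("nucleotide")
  grp <- rep(c("x", "y"), each = 5L)
  for (i in 1:300) {
    chars <- sample(c(nuc, "-"), 10L, replace = TRUE)
    r <- modified_column_score(chars, grp)
    expect_gte(r$M, 0)
    expect_lte(r$M, 1)
    swapped <- modified_column_score(chars, rev(grp))
    expect_equal(swapped$M, r$M)
    if (!r$skipped) {
      expect_equal(swapped$S, r$S)
      expect_equal(swapped$d, r$d)
    }
    # relabeling residues by a permutation leaves the score unchanged
    perm <- stats::setNames(sample(nuc), nuc)
    relabeled <- ifelse(chars %in% nuc, perm[chars], chars)
    expect_equal(modified_column_score(relabeled, grp)$M, r$M)
  }
})

test_that("mean score over planted alignments equals the planted fraction", {
  sim <- simulate_alignment(n_per_group = 6L, n_columns = 100L,
                            categories = c(signature = 0.25, conserved = 0.75,
                                           random = 0),
                            conservation = 1, seed = 11L)
  sc <- alignment_mean_score(sim$alignment,
                             group_taxa(sim$grouping, "A"),
                             group_taxa(sim$grouping, "B"))
  expect_equal(sc$mean, 0.25)
  expect_equal(sc$n_skipped, 0L)
})

test_that("mean score errors when no column is usable", {
  aln <- msa(c(a = "AA", b = "--"), "nucleotide")
  expect_error(alignment_mean_score(aln, "a", "b"), "no usable columns")
})

test_that("resampled comparison is reproducible and degenerates correctly", {
  sim <- simulate_alignment(n_per_group = 8L, n_columns = 60L,
                            categories = c(signature = 0.5, conserved = 0.5,
                                           random = 0),
                            conservation = 0.9, seed = 21L)
  a <- compare_phyla(sim$alignment, sim$grouping, "A", "B", n = 5L,
                     reps = 20L, seed = 7L)
  b <- compare_phyla(sim$alignment, sim$grouping, "A", "B", n = 5L,
                     reps = 20L, seed = 7L)
  expect_identical(a$scores, b$scores)
  # R = 1 with n = full group size equals the plain alignment mean
  d <- compare_phyla(sim$alignment, sim$grouping, "A", "B", n = 8L,
                     reps = 1L, seed = 1L)
  full <- alignment_mean_score(sim$alignment,
                               group_taxa(sim$grouping, "A"),
                               group_taxa(sim$grouping, "B"))
  expect_equal(d$mean, full$mean)
  expect_error(compare_phyla(sim$alignment, sim$grouping, "A", "B", n = 9L),
               "'A' has only 8")
})

test_that("one strain per species is enforced before sampling", {
  sim <- simulate_alignment(n_per_group = 4L, n_columns = 10L, seed = 3L)
  g <- sim$grouping
  g$species <- c("s1", "s1", "s2", "s3", "u1", "u2", "u3", "u4")
  expect_error(compare_phyla(sim$alignment, g, "A", "B", n = 4L, reps = 2L),
               "'A' has only 3")
})

test_that("null mean signature falls toward 0 as shared conservation rises", {
  means <- vapply(c(0, 0.5, 0.8), function(p_cons) {
    sim <- simulate_alignment(n_per_group = 10L, n_columns = 150L,
                              categories = c(signature = 0,
                                             conserved = p_cons,
                                             random = 1 - p_cons),
                              seed = 31L)
    # both "groups" drawn from one pool: relabel the split arbitrarily
    alignment_mean_score(sim$alignment,
                         sim$alignment$taxa[c(1:5, 11:15)],
                         sim$alignment$taxa[c(6:10, 16:20)])$mean
  }, numeric(1L))
  expect_true(all(diff(means) < 0))
  expect_lt(means[3L], 0.05)
})

test_that("closest group call applies the two-standard-deviation rule", {
  mk <- function(m, s, g) structure(list(groups = c("focal", g), mean = m,
                                         sd = s), class = "signature_comparison")
  single <- closest_group_call(list(only = mk(0.05, 0.01, "only")))
  expect_equal(single$closest, "only")
  expect_equal(single$within_two_sd, "only")
  # gap 0.018 vs 2 * sqrt(2 * 0.005^2) = 0.0141: excluded
  two <- closest_group_call(list(firm = mk(0.040, 0.005, "firm"),
                                 prot = mk(0.058, 0.005, "prot")))
  expect_equal(two$closest, "firm")
  expect_equal(two$within_two_sd, "firm")
  # equal means: both inside
  tie <- closest_group_call(list(g1 = mk(0.05, 0.004, "g1"),
                                 g2 = mk(0.05, 0.009, "g2")))
  expect_setequal(tie$within_two_sd, c("g1", "g2"))
})
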