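test_that("codon counting excludes stops and validates frame", {
  counts <- count_codons("ATGAAATAA")
  expect_equal(unname(counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(counts), 2L)
  expect_equal(attr(counts, "length"), 2L)
  expect_error(count_codons("ATGAA"), "multiple of 3")
  expect_warning(count_codons("ATGTAAAAA"), "internal stop")
})

test_that("codon counts recount correctly on random sequences", {
  set.seed(61)
  for (i in 1:10) {
    len <- 3L * sample(50:150, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    codons <- substring(s, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
    n_stop <- sum(codons %in% c("TAA", "TAG", "TGA"))
    counts <- suppressWarnings(count_codons(s))
    expect_equal(sum(counts), len %/% 3L - n_stop)
  }
})

test_that("chi-squared match reproduces the two-family toy exactly", {
  counts <- stats::setNames(integer(61L), sense_codons())
  counts[c("AAA", "AAG")] <- c(10L, 0L)   # Lys family, ref 0.5/0.5
  counts[c("TTT", "TTC")] <- c(5L, 5L)    # Phe family, ref 0.5/0.5
  res <- chisq_match(counts, codon_profile("uniform"))
  expect_equal(res$statistic, 10)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, stats::pchisq(10, 2L, lower.tail = FALSE))
  expect_false(res$match)
})

test_that("proportional usage matches with p = 1; disjoint usage never does", {
  prof <- codon_profile("uniform")
  counts <- stats::setNames(integer(61L), sense_codons())
  counts[c("AAA", "AAG")] <- 6L
  counts[c("GGA", "GGC", "GGG", "GGT")] <- 8L
  res <- chisq_match(counts, prof)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$match)

  only_gc <- simulate_genes(codon_profile("gc_only"), n_genes = 20L,
                            len_range = c(300L, 300L), seed = 5L)
  res2 <- match_profile(only_gc$genes, codon_profile("at_only"))
  expect_true(all(res2$p_value < 1e-10))
})

test_that("genes without multi-synonym observations are untestable", {
  counts <- stats::setNames(integer(61L), sense_codons())
  counts[c("ATG", "TGG")] <- c(3L, 2L)    # Met and Trp only
  res <- chisq_match(counts, codon_profile("uniform"))
  expect_false(res$testable)
  expect_true(is.na(res$match))
})

test_that("the statistic grows and p shrinks as usage departs from the reference", {
  prof <- codon_profile("uniform")
  base <- stats::setNames(integer(61L), sense_codons())
  stats_seq <- vapply(0:5, function(shift) {
    counts <- base
    counts[c("AAA", "AAG")] <- c(6L + shift, 6L - shift)
    chisq_match(counts, prof)$statistic
  }, numeric(1L))
  expect_true(all(diff(stats_seq) > 0))
  p_seq <- stats::pchisq(stats_seq, 1L, lower.tail = FALSE)
  expect_true(all(diff(p_seq) < 0))
})

test_that("modal usage recovers a homogeneous genome's profile and is a fixed point", {
  sim <- simulate_genes(codon_profile("at_rich"), n_genes = 120L,
                        len_range = c(250L, 350L), seed = 41L)
  fit <- modal_usage(sim$genes)
  expect_lt(profile_tv_distance(fit$profile, codon_profile("at_rich")), 0.05)
  # the iteration settles: the last two matched-set sizes agree and the
  # final set holds the bulk of the genes
  h <- fit$matched_history
  expect_equal(h[length(h)], h[length(h) - 1L])
  expect_gte(h[length(h)], 0.8 * nrow(sim$genes))
  refit <- modal_usage(sim$genes[fit$matched, , drop = FALSE])
  expect_setequal(refit$matched, fit$matched)
  expect_error(modal_usage(sim$genes[1:5, ]), "at least 10")
})

test_that("percent matching any profile is order-invariant with sane edge cases", {
  sim <- simulate_genes(codon_profile("at_rich"), n_genes = 60L,
                        len_range = c(300L, 300L), seed = 17L)
  profs <- list(a = codon_profile("gc_rich"), b = codon_profile("at_rich"))
  p1 <- percent_matching_any(sim$genes, profs)
  p2 <- percent_matching_any(sim$genes, rev(profs))
  expect_equal(p1$percent, p2$percent)
  expect_equal(percent_matching_any(sim$genes, list())$percent, 0)
  untestable <- matrix(0L, nrow = 2L, ncol = 61L,
                       dimnames = list(c("g1", "g2"), sense_codons()))
  untestable[, "ATG"] <- 5L
  expect_error(percent_matching_any(untestable, profs), "no testable")
})

test_that("planted foreign genes land in the non-native partition", {
  sim <- simulate_genes(codon_profile("at_only"), n_genes = 150L,
                        len_range = c(250L, 350L),
                        foreign_fraction = 0.2,
                        foreign_profile = codon_profile("gc_only"),
                        seed = 23L)
  np <- native_partition(sim$genes)
  foreign_ids <- rownames(sim$genes)[sim$labels == "foreign"]
  expect_gte(mean(foreign_ids %in% np$non_native), 0.9)
  native_ids <- rownames(sim$genes)[sim$labels == "native"]
  expect_gte(mean(native_ids %in% np$native), 0.8)
  expect_error(native_partition(sim$genes[0L, , drop = FALSE]), "empty")
})

test_that("mean G+C averages per-gene percentages unweighted", {
  expect_equal(as.numeric(mean_gc(c(g1 = "GGCC", g2 = "GGGG"))), 100)
  expect_equal(as.numeric(mean_gc(c(g1 = "ATAT"))), 0)
  # unweighted: a short all-GC gene and a long all-AT gene average to 50
  expect_equal(as.numeric(mean_gc(c(g1 = "GC", g2 = "ATATATATAT"))), 50)
  set.seed(3)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE), collapse = "")
  }, character(1L))
  names(seqs) <- paste0("g", 1:5)
  hand <- mean(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    100 * mean(ch %in% c("G", "C"))
  }, numeric(1L)))
  expect_equal(as.numeric(mean_gc(seqs)), hand)
})
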