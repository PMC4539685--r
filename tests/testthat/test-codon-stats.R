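test_that("codon counting credits starts to methionine and skips N codons", {
  expect_equal(sum(count_codons(character())), 0L)
  cnt <- count_codons("GTGAAATAA")
  expect_equal(unname(cnt["ATG"]), 1L)  # GTG start counted as Met-group start
  expect_equal(unname(cnt["GTG"]), 0L)
  expect_equal(unname(cnt["AAA"]), 1L)
  expect_equal(unname(cnt["TAA"]), 1L)
  cntN <- count_codons("ATGANATAA")
  expect_equal(sum(cntN), 2L)  # the N-containing codon is skipped
  expect_error(count_codons("ATGXXXTAA"), class = "trnaflux_invalid_sequence")
  expect_error(count_codons("ATGAA"), class = "trnaflux_frame_error")
})

test_that("codon counting equals an independent per-triplet tally", {
  set.seed(11)
  cds <- vapply(1:5, function(i) random_cds(sample(20:60, 1)), "")
  # brute-force oracle: chop every CDS into triplets and table them,
  # rewriting the leading triplet as ATG
  triplets <- unlist(lapply(cds, function(s) {
    tr <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    tr[1] <- "ATG"
    tr
  }))
  oracle <- table(factor(triplets, levels = sort(names(Biostrings::GENETIC_CODE))))
  expect_equal(unname(count_codons(cds)), as.integer(oracle))
})

test_that("relative usage normalizes per amino acid", {
  counts <- setNames(integer(64), sort(names(Biostrings::GENETIC_CODE)))
  counts[c("GCG", "GCC", "GCA", "GCT")] <- c(36L, 27L, 21L, 16L)
  u <- relative_usage(counts)
  expect_equal(unname(u$rel[c("GCG", "GCC", "GCA", "GCT")]),
               c(0.36, 0.27, 0.21, 0.16))
  # single nonzero codon in a family
  counts["AAA"] <- 5L
  u <- relative_usage(counts)
  expect_equal(unname(u$rel["AAA"]), 1)
  # empty families are flagged NA; observed families sum to 1
  expect_true(is.na(u$rel["TTT"]))
  aa <- Biostrings::GENETIC_CODE[names(u$rel)]
  sums <- tapply(u$rel, aa, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
})

test_that("every usage table from simulated genomes satisfies the group-sum invariant", {
  sim <- tiny_sim()
  for (st in c("S1", "REF")) {
    u <- genome_usage(sim$genomes[[st]])
    aa <- Biostrings::GENETIC_CODE[names(u$rel)]
    sums <- tapply(ifelse(is.na(u$rel), 0, u$rel), aa, sum)
    expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))
  }
})

test_that("fold enrichment follows the ratio rules", {
  counts <- setNames(rep(3L, 64), sort(names(Biostrings::GENETIC_CODE)))
  u <- relative_usage(counts)
  expect_equal(unname(fold_enrichment(u, u)), rep(1, 64))
  # genome-zero/subset-positive is infinite, both-zero is 1
  c2 <- counts; c2["AAA"] <- 0L
  u2 <- relative_usage(c2)
  # a "subset" with more codons than the genome table draws a warning
  expect_warning(f <- fold_enrichment(u, u2), "really a subset")
  expect_true(is.infinite(f["AAA"]))
  c3 <- counts; c3[c("GCG", "GCC", "GCA", "GCT")] <- 0L
  f2 <- fold_enrichment(relative_usage(c3), relative_usage(c3))
  expect_equal(unname(f2["GCG"]), 1)
})

test_that("cross-strain enrichment CIs match the t formula", {
  folds <- rbind(a = rep(2, 64), b = rep(2, 64), c = rep(2, 64))
  colnames(folds) <- sort(names(Biostrings::GENETIC_CODE))
  ci <- enrichment_ci(folds)
  expect_equal(ci$lo, ci$hi)  # identical folds give zero width
  m <- do.call(rbind, lapply(1:5, function(i) {
    r <- rep(1, 64); names(r) <- colnames(folds); r["AAA"] <- i; r
  }))
  ci99 <- enrichment_ci(m, level = 0.99)
  row <- ci99[ci99$codon == "AAA", ]
  expect_equal(row$mean, 3)
  expect_equal(row$lo, 3 - 4.604095 * sd(1:5) / sqrt(5), tolerance = 1e-6)
  ci95 <- enrichment_ci(m, level = 0.95)
  expect_true(ci95[ci95$codon == "AAA", "lo"] > row$lo)  # wider at 0.99
  expect_error(enrichment_ci(m[1, , drop = FALSE]), class = "trnaflux_ci_undefined")
})

test_that("codon ranking is a permutation with lexicographic tie-break", {
  codons <- sort(names(Biostrings::GENETIC_CODE))
  fold <- setNames(rep(1, 64), codons)
  r <- rank_codons(fold)
  expect_equal(unname(r), 1:64)  # all-tied folds rank in codon order
  fold[c("AGA", "GGA", "ACA")] <- c(4.1, 3.0, 2.5)
  r <- rank_codons(fold)
  expect_equal(unname(r[c("AGA", "GGA", "ACA")]), c(1L, 2L, 3L))
  # against an independent sort oracle on random folds
  set.seed(5)
  f2 <- setNames(round(runif(64), 2), codons)
  r2 <- rank_codons(f2)
  oracle <- codons[order(-f2, codons)]
  expect_equal(names(sort(r2)), oracle)
  expect_setequal(r2, 1:64)
})

test_that("rank sums behave at the extremes", {
  codons <- sort(names(Biostrings::GENETIC_CODE))
  rank <- setNames(1:64, codons)
  expect_equal(rank_sum(codons[c(2, 3, 4)], rank), 9)
  expect_equal(rank_sum(codons[1:3], rank), 6)
  expect_equal(rank_sum(codons[62:64], rank), 189)
  expect_error(rank_sum(character(), rank), class = "trnaflux_empty_targets")
  expect_error(rank_sum("XXX", rank), class = "trnaflux_unknown_target")
})

test_that("exact rank-sum p matches full enumeration in both modes", {
  # distinct mode: enumerate all C(64,3) subsets
  sums <- colSums(combn(64, 3))
  for (S in c(6, 9, 15, 40, 189)) {
    expect_equal(exact_rank_sum_p(S, 3, 64), mean(sums <= S))
  }
  expect_equal(exact_rank_sum_p(6, 3, 64), 1 / 41664)
  expect_equal(exact_rank_sum_p(9, 3, 64), 7 / 41664)
  expect_equal(exact_rank_sum_p(189, 3, 64), 1)
  # with-replacement mode: enumerate ordered triples over a smaller n
  grid <- expand.grid(1:10, 1:10, 1:10)
  tups <- rowSums(grid)
  for (S in c(3, 9, 17, 30)) {
    expect_equal(exact_rank_sum_p(S, 3, 10, mode = "with_replacement"),
                 mean(tups <= S))
  }
  # monotone non-decreasing in S
  ps <- vapply(6:189, exact_rank_sum_p, 0, k = 3, n = 64)
  expect_true(all(diff(ps) >= 0))
})

test_that("Monte-Carlo rank test converges to the exact value and is reproducible", {
  rt1 <- permutation_rank_test(9, 3, 64, reps = 10000L, seed = 7)
  rt2 <- permutation_rank_test(9, 3, 64, reps = 10000L, seed = 7)
  expect_identical(rt1$p_mc, rt2$p_mc)
  rt <- permutation_rank_test(9, 3, 64, reps = 200000L, seed = 1)
  se <- sqrt(rt$p_exact * (1 - rt$p_exact) / rt$reps)
  expect_lt(abs(rt$p_mc - rt$p_exact), 3 * se + 1 / rt$reps)
  # maximum sum gives p = 1 under the add-one convention
  expect_equal(permutation_rank_test(189, 3, 64, reps = 1000L, seed = 1)$p_mc, 1)
})

test_that("absolute codon influx counts the codons carried by SGE copies", {
  sim <- tiny_sim()
  seqs <- reference_gene_seqs(sim, "sge")
  cl <- build_clusters(seqs)
  cl <- count_copies(cl, seqs, sim$genomes["S1"])
  influx <- absolute_codon_influx(cl, sim$genomes["S1"])
  expect_equal(unname(influx$mean),
               as.numeric(sim$truth$sge_codon_counts$S1))
  # empty cluster set gives zero counts
  none <- absolute_codon_influx(list(), sim$genomes["S1"])
  expect_true(all(none$mean == 0))
})
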