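mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) chars[p] <- chartr("ACGT", "GTAC", chars[p])
  paste(chars, collapse = "")
}

test_that("alignment statistics define identity and coverage over the query", {
  q <- random_cds(30, seed = 21)
  st <- align_stats(q, q)
  expect_equal(st$identity, 1)
  expect_equal(st$coverage, 1)
  # embedded in a longer subject: still a full-coverage perfect hit
  st2 <- align_stats(q, paste0(random_cds(20, seed = 1), q, random_cds(20, seed = 2)))
  expect_equal(st2$identity, 1)
  expect_equal(st2$coverage, 1)
  # subject missing the last half of the query
  st3 <- align_stats(q, substr(q, 1, nchar(q) / 2))
  expect_equal(st3$coverage, 0.5)
  # 77 bp with 3 planted substitutions: identity 74/77
  s77 <- paste(rep(c("A", "C", "G", "T"), length.out = 77), collapse = "")
  st4 <- align_stats(s77, mutate_at(s77, c(10, 40, 70)))
  expect_equal(st4$identity, 74 / 77)
  # identity is symmetric for equal-length inputs
  st5 <- align_stats(mutate_at(s77, c(10, 40, 70)), s77)
  expect_equal(st5$identity, st4$identity)
})

test_that("find_copies recovers planted copies at the strict 95/95 thresholds", {
  set.seed(31)
  gene <- random_cds(70)
  L <- nchar(gene)
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- paste0(spacer(500), gene, spacer(800), gene, spacer(600),
                   gene, spacer(500))
  h <- find_copies(gene, genome)
  expect_equal(nrow(h), 3L)
  expect_true(all(h$identity == 1 & h$coverage == 1 & h$strand == "+"))
  # a reverse-strand copy is found with strand '-'
  genome_rc <- paste0(spacer(500), gene, spacer(700), revcomp(gene), spacer(500))
  h2 <- find_copies(gene, genome_rc)
  expect_setequal(h2$strand, c("-", "+"))
  # a copy with >5% divergence is excluded (here 6%)
  div6 <- trnaflux:::mutate_seq(gene, 6)
  genome_d <- paste0(spacer(500), gene, spacer(700), div6, spacer(500))
  h3 <- find_copies(gene, genome_d)
  expect_equal(nrow(h3), 1L)
  # a copy with 4% divergence is kept
  div4 <- trnaflux:::mutate_seq(gene, 4)
  genome_k <- paste0(spacer(500), gene, spacer(700), div4, spacer(500))
  h4 <- find_copies(gene, genome_k)
  expect_equal(nrow(h4), 2L)
})

test_that("single-linkage clustering chains paralogs through pairwise links", {
  a <- random_cds(70, seed = 41)
  b <- mutate_at(a, seq(5, 35, by = 5))    # ~3% from a
  c_ <- mutate_at(b, seq(40, 70, by = 5))  # ~3% from b, ~6% from a
  far <- random_cds(70, seed = 42)
  cl <- build_clusters(c(A = a, B = b, C = c_, X = far))
  sizes <- sort(vapply(cl, function(x) length(x$members), 0L))
  expect_equal(unname(sizes), c(1L, 3L))
  expect_setequal(cl[["A"]]$members, c("A", "B", "C"))
  # four identical paralogs form one cluster
  cl2 <- build_clusters(c(t1 = a, t2 = a, t3 = a, t4 = a))
  expect_length(cl2, 1L)
  expect_length(cl2[[1]]$members, 4L)
})

test_that("redundant cluster culling is deterministic and idempotent", {
  sim <- tiny_sim()
  seqs <- reference_gene_seqs(sim, "sge")
  cl <- build_clusters(seqs)
  cl <- count_copies(cl, seqs, sim$genomes["S1"])
  expect_identical(names(cull_redundant_sets(cl)), names(cl))  # disjoint: unchanged
  # a slightly diverged duplicate query rediscovers the same loci;
  # the smaller cluster is culled
  dup <- trnaflux:::mutate_seq(seqs[["FAM1_REF_c01"]], 2)
  seqs2 <- c(seqs, ZDUP = dup)
  cl2 <- build_clusters(seqs2, min_identity = 0.99)  # force ZDUP into its own cluster
  expect_true("ZDUP" %in% names(cl2))
  cl2 <- count_copies(cl2, seqs2, sim$genomes["S1"])
  culled <- cull_redundant_sets(cl2)
  expect_false("ZDUP" %in% names(culled))
  expect_identical(names(cull_redundant_sets(culled)), names(culled))
})

test_that("tandem arrays are runs of nearby same-strand copies", {
  set.seed(51)
  gene <- random_cds(25)
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome_str <- paste0(spacer(400), gene, spacer(200), gene, spacer(200), gene,
                       spacer(9000), gene, spacer(400))
  cl <- list(cluster_id = "g", members = "g",
             hits = list(s = find_copies(gene, genome_str)))
  expect_equal(nrow(cl$hits$s), 4L)
  td <- detect_tandem(cl, "s", window = 5000)
  expect_equal(td, c(TRUE, TRUE, TRUE, FALSE))
  # far-apart copies are not tandem
  td2 <- detect_tandem(cl, "s", window = 100)
  expect_equal(td2, rep(FALSE, 4L))
})

test_that("context classification matches the generator truth", {
  sim <- tiny_sim()
  seqs <- reference_gene_seqs(sim, "trna")
  cl <- build_clusters(seqs)
  cl <- count_copies(cl, seqs, sim$genomes)
  map <- c(tandem = "tandem_array", phage_flanked = "phage_flanked",
           host_flanked = "host_flanked")
  truth <- sim$truth$trna_contexts
  n_checked <- 0L
  for (st in c("S1", "S2", "S3")) {
    f <- sim$genomes[[st]]$features
    for (ac in c("TCT", "TCC", "TGT")) {
      cc <- context_calls(cl[[paste0("tRNA_", ac, "_orig")]],
                          sim$genomes[[st]])
      tt <- truth[truth$strain == st & truth$anticodon == ac, ]
      for (i in seq_len(nrow(cc))) {
        fid <- f$gene_id[f$start < cc$end[i] & f$end > cc$start[i] &
                           f$category == "trna"]
        expect_equal(cc$call[i], unname(map[tt$context[match(fid, tt$gene_id)]]))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 24L)
  # the original copy is identified by synteny with the reference strain
  orig <- find_original(cl[["tRNA_TCT_orig"]], sim$genomes$S1,
                        sim$genomes$REF)
  h <- cl[["tRNA_TCT_orig"]]$hits$S1
  h <- h[order(h$start), ]
  expect_false(is.na(orig))
  expect_equal(h$identity[orig], 1)  # the original is the undiverged copy
})

test_that("copy counts on the small strain set equal the truth", {
  sim <- tiny_sim()
  seqs <- reference_gene_seqs(sim)
  cl <- build_clusters(seqs)
  cl <- count_copies(cl, seqs, sim$genomes)
  truth <- sim$truth
  for (fam in c("FAM1", "FAM2")) {
    cid <- grep(paste0("^", fam, "_REF"), names(cl), value = TRUE)[1]
    for (st in truth$strains) {
      tt <- truth$sge[truth$sge$strain == st & truth$sge$family_id == fam, ]
      expect_equal(unname(cl[[cid]]$copy_count[st]),
                   if (nrow(tt)) tt$detectable else 0L,
                   info = paste(fam, st))
    }
  }
  for (ac in c("TCT", "TCC", "TGT")) {
    det <- vapply(truth$strains, function(st)
      sum(truth$trna_contexts$strain == st &
            truth$trna_contexts$anticodon == ac &
            truth$trna_contexts$detectable), 0L)
    expect_equal(cl[[paste0("tRNA_", ac, "_orig")]]$copy_count[truth$strains],
                 det)
  }
})

test_that("the SGE load t-test handles degenerate and regular input", {
  expect_equal(sge_group_ttest(c(5, 5, 5), c(5, 5, 5))$p, 1)
  r <- sge_group_ttest(c(440, 441, 439), c(10, 11, 9))
  expect_lt(r$p, 1e-4)
  r2 <- sge_group_ttest(c(10, 11, 9), c(440, 441, 439))
  expect_equal(r2$p, r$p)       # label swap leaves p unchanged
  expect_equal(r2$t, -r$t)
})
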