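test_that("sampled genes are well-formed and reproducible", {
  u <- default_background_usage()
  set.seed(1)
  g <- sample_gene(2, u)
  expect_match(g, "^ATG(TAA|TAG|TGA)$")  # minimal gene: start + stop only
  set.seed(9); a <- sample_genes(rep(30L, 5), u)
  set.seed(9); b <- sample_genes(rep(30L, 5), u)
  expect_identical(a, b)
  expect_true(all(substr(a, 1, 3) == "ATG"))
  expect_true(all(substring(a, 88) %in% c("TAA", "TAG", "TGA")))
})

test_that("sampled codon usage converges to the profile", {
  u <- default_background_usage()
  set.seed(2)
  genes <- sample_genes(rep(200L, 3000), u)
  counts <- count_codons(genes)
  ala <- counts[c("GCG", "GCC", "GCA", "GCT")]
  expect_equal(unname(ala["GCG"] / sum(ala)), 0.36, tolerance = 0.01 / 0.36)
  expect_equal(unname(ala / sum(ala)), c(0.36, 0.27, 0.21, 0.16),
               tolerance = 0.05)
})

test_that("bias_usage renormalizes within the amino-acid family", {
  u <- default_background_usage()
  expect_equal(bias_usage(u, c(AAA = 1, GGA = 1))$rel, u$rel)
  b <- bias_usage(u, c(GCA = 4))
  # hand renormalization: (0.36, 0.27, 0.84, 0.16) / 1.63
  expect_equal(unname(b$rel[c("GCG", "GCC", "GCA", "GCT")]),
               c(0.36, 0.27, 0.84, 0.16) / 1.63, tolerance = 1e-9)
  expect_equal(sum(b$rel[c("GCG", "GCC", "GCA", "GCT")]), 1)
  # single-codon family is forced back to 1
  expect_equal(unname(bias_usage(u, c(ATG = 7))$rel["ATG"]), 1)
  expect_equal(unname(bias_usage(u, c(TGG = 0.1))$rel["TGG"]), 1)
})

test_that("mutate_seq applies an exact substitution count", {
  set.seed(3)
  s <- random_cds(40)
  for (pct in c(0, 2, 4, 6)) {
    m <- trnaflux:::mutate_seq(s, pct)
    diffs <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    expect_equal(diffs, round(pct / 100 * nchar(s)))
  }
})

test_that("plant_copies realizes the requested genomic contexts", {
  set.seed(4)
  cfg <- tiny_config()
  sim <- tiny_sim()
  g <- sim$genomes$REF
  elem <- random_cds(40)

  res <- plant_copies(g, elem, 3, context = "tandem", id_prefix = "tnd")
  pl <- res$placements
  expect_equal(nrow(pl), 3L)
  expect_lt(max(pl$end) - min(pl$start), 5000)
  expect_equal(unique(pl$strand), "+")
  seqs <- mapply(function(a, b) genome_slice(res$genome, a, b), pl$start, pl$end)
  expect_true(all(seqs == elem))  # tandem copies are identical

  res2 <- plant_copies(g, elem, 2, context = "host_flanked", id_prefix = "hf")
  f <- res2$genome$features
  for (i in seq_len(2)) {
    j <- match(res2$placements$gene_id[i], f$gene_id)
    expect_equal(f$category[j - 1L], "host")
    expect_equal(f$category[j + 1L], "host")
  }

  tr <- paste(sample(c("A", "C", "G", "T"), 77, replace = TRUE), collapse = "")
  res3 <- plant_copies(g, tr, 7, context = "phage_flanked", divergence_pct = 4,
                       id_prefix = "pf", category = "trna", anticodon = "TCT",
                       min_separation = 6000)
  f3 <- res3$genome$features
  idents <- numeric(7)
  for (i in seq_len(7)) {
    j <- match(res3$placements$gene_id[i], f3$gene_id)
    expect_equal(f3$category[j - 1L], "phage")
    expect_equal(f3$category[j + 1L], "phage")
    s <- genome_slice(res3$genome, f3$start[j], f3$end[j])
    idents[i] <- mean(strsplit(s, "")[[1]] == strsplit(tr, "")[[1]])
  }
  # 4% divergence on 77 bp is exactly 3 substitutions: identity 74/77
  expect_equal(idents, rep(74 / 77, 7))

  tiny <- annotated_genome("t", paste(rep("ACGT", 30), collapse = ""))
  expect_error(plant_copies(tiny, elem, 1, context = "host_flanked"),
               class = "trnaflux_no_space")
})

test_that("simulated LGT gains land in exactly the descendant tips", {
  sim <- tiny_sim()
  pres <- lgt_presence_from_genomes(sim$genomes)
  truth <- sim$truth$lgt
  for (i in seq_len(nrow(truth))) {
    clade <- strsplit(truth$clade[i], ",")[[1]]
    expect_setequal(colnames(pres)[pres[truth$gene_id[i], ]], clade)
  }
  # a gain at the root would appear in all tips
  cfg <- tiny_config(seed = 77, n_host_genes = 120L)
  cfg$lgt_gains <- list(list(label = "root", clade = cfg$tree$tip.label,
                             n_genes = 2L, length_codons = 60L,
                             bias = c(AGA = 2)))
  sim2 <- simulate_strains(cfg)
  pres2 <- lgt_presence_from_genomes(sim2$genomes)
  expect_true(all(pres2))
  # an unknown clade tip is rejected at configuration time
  expect_error({
    bad <- tiny_config()
    bad$lgt_gains[[1]]$clade <- c("S1", "NOPE")
    simulation_config(seed = 1, tree = bad$tree, n_host_genes = 10,
                      gene_length_codons = c(100, 10),
                      base_anticodons = "TCT", reference_strain = "REF",
                      lgt_gains = bad$lgt_gains)
  }, class = "trnaflux_unknown_node")
})

test_that("simulation is deterministic and self-consistent", {
  cfg <- tiny_config(seed = 123, n_host_genes = 120L)
  s1 <- simulate_strains(cfg)
  s2 <- simulate_strains(cfg)
  expect_identical(s1$genomes$S1$sequence, s2$genomes$S1$sequence)
  expect_identical(s1$truth, s2$truth)
  # the self-audit re-runs cleanly on the result
  expect_true(trnaflux:::audit_simulation(s1))
  # emitted files recount to the same truth
  out <- tempfile()
  write_simulation(s1, out)
  g <- read_genome(file.path(out, "S1.fasta"), file.path(out, "S1.gff3"))
  expect_equal(unname(anticodon_counts(g)["S1", ]),
               unname(s1$truth$trna_counts["S1", ]))
  expect_true(file.exists(file.path(out, "truth.json")))
  unlink(out, recursive = TRUE)
})

test_that("sampled usage under a biased profile converges to bias_usage", {
  bg <- default_background_usage()
  biased <- bias_usage(bg, c(AGA = 4, GGA = 4, ACA = 4))
  set.seed(14)
  long_fam <- sample_genes(rep(500L, 8), biased)
  u <- relative_usage(count_codons(long_fam))
  for (cd in c("AGA", "GGA", "ACA")) {
    expect_lt(abs(u$rel[cd] - biased$rel[cd]), 0.05)
  }
  # and the realized counts stored in the truth set reflect the same bias:
  # the planted codons dominate their synonymous families
  sim <- tiny_sim()
  su <- relative_usage(sim$truth$sge_codon_counts$S1)
  for (cd in c("AGA", "GGA", "ACA")) {
    aa <- Biostrings::GENETIC_CODE[cd]
    fam <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
    expect_equal(names(which.max(su$rel[fam])), cd)
  }
})
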