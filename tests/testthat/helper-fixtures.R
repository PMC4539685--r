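# Shared fixtures: a small strain-set configuration exercising every
# planted feature class, plus convenience builders. The full-size default
# configuration is reserved for the acceptance suite.

tiny_tree <- function() {
  ape::read.tree(text = paste0(
    "((S1:0.02,(S2:0.01,S3:0.01):0.01):0.05,",
    "(REF:0.02,E1:0.02):0.05);"))
}

tiny_config <- function(seed = 42L, n_host_genes = 150L) {
  shig <- c("S1", "S2", "S3")
  cps <- function(s, ref, e) setNames(c(rep(s, 3L), ref, e),
                                      c(shig, "REF", "E1"))
  bias3 <- c(AGA = 4, GGA = 4, ACA = 4)
  simulation_config(
    seed = seed, tree = tiny_tree(), n_host_genes = n_host_genes,
    gene_length_codons = c(120, 20),
    base_anticodons = c("TCT", "TCC", "TGT", "AAA", "CCC", "GGG", "TTT", "ACG"),
    reference_strain = "REF",
    sge_families = list(
      list(family_id = "FAM1", length_codons = 100L, bias = bias3,
           divergence_pct = 0, copies = cps(8L, 1L, 1L)),
      list(family_id = "FAM2", length_codons = 90L, bias = bias3,
           divergence_pct = 4, copies = cps(5L, 1L, 0L))),
    trna_plants = list(
      list(anticodon = "TCT", strains = shig, n_copies = 3L,
           context = "phage_flanked", divergence_pct = 4),
      list(anticodon = "TCC", strains = shig, n_copies = 3L,
           context = "tandem", divergence_pct = 0),
      list(anticodon = "TGT", strains = shig, n_copies = 2L,
           context = "host_flanked", divergence_pct = 0)),
    lgt_gains = list(
      list(label = "g1", clade = shig, n_genes = 4L,
           length_codons = 150L, bias = c(AGA = 3)),
      list(label = "g2", clade = c("S2", "S3"), n_genes = 4L,
           length_codons = 150L, bias = c(AGA = 6))),
    groups = list(shigella_like = shig, others = c("REF", "E1")))
}

# memoized tiny simulation shared across test files
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_strains(tiny_config())
    cache
  }
})

# reference gene sequences (sge + trna) of a simulated strain set
reference_gene_seqs <- function(sim, categories = c("sge", "trna")) {
  ref <- sim$truth$reference_strain
  rf <- sim$genomes[[ref]]$features
  keep <- rf$category %in% categories
  setNames(
    mapply(function(a, b, d) genome_slice(sim$genomes[[ref]], a, b, d),
           rf$start[keep], rf$end[keep], rf$strand[keep]),
    rf$gene_id[keep])
}

# random CDS built directly from codons (for brute-force tallies)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons <- setdiff(sort(names(Biostrings::GENETIC_CODE)),
                    c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
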