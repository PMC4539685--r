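# Strain-set simulation: a shared (vertically inherited) host genome per
# tree tip, plus per-strain planted SGE families, tRNA gene copies in
# controlled contexts, and LGT gene sets gained at chosen tree nodes.

#' Build and validate a simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param tree Strain phylogeny ([ape::phylo]); its tips are the strains.
#' @param n_host_genes Number of shared host genes.
#' @param gene_length_codons `c(mean, sd)` of host gene length in codons.
#' @param background `codon_usage_table` for host genes.
#' @param base_anticodons Anticodons present as single-copy tRNA genes in
#'   every strain (the ancestral tRNA complement).
#' @param reference_strain Strain whose gene copies are planted undiverged
#'   (the ancestral-like reference used for queries and fold changes).
#' @param sge_families List of families: each a list with `family_id`,
#'   `length_codons`, `bias` (codon multipliers), `divergence_pct`,
#'   `copies` (named integer per strain).
#' @param trna_plants List of plants: each a list with `anticodon`,
#'   `strains`, `n_copies`, `context` (`tandem`/`phage_flanked`/
#'   `host_flanked`), `divergence_pct`.
#' @param lgt_gains List of gains: each a list with `label`, `clade`
#'   (character vector of tips whose MRCA is the gain node), `n_genes`,
#'   `length_codons`, `bias`.
#' @param groups Named list of strain-id vectors (group definitions used
#'   by the downstream tests).
#' @param spacer_bp Intergenic spacer length.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed, tree, n_host_genes, gene_length_codons,
                              background = default_background_usage(),
                              base_anticodons, reference_strain,
                              sge_families = list(), trna_plants = list(),
                              lgt_gains = list(), groups = list(),
                              spacer_bp = 100L) {
  stopifnot(inherits(tree, "phylo"), !anyDuplicated(tree$tip.label),
            n_host_genes >= 1L, length(gene_length_codons) == 2L,
            reference_strain %in% tree$tip.label)
  tips <- tree$tip.label
  for (fam in sge_families) {
    stopifnot(!is.null(fam$family_id), all(fam$bias > 0),
              fam$divergence_pct >= 0, fam$divergence_pct <= 50,
              all(fam$copies >= 0), all(names(fam$copies) %in% tips))
  }
  for (pl in trna_plants) {
    stopifnot(pl$anticodon %in% codons_all(), all(pl$strains %in% tips),
              pl$n_copies >= 0,
              pl$context %in% c("tandem", "phage_flanked", "host_flanked"),
              pl$divergence_pct >= 0, pl$divergence_pct <= 50)
  }
  for (g in lgt_gains) {
    if (!all(g$clade %in% tips))
      stop_trnaflux("unknown_node",
                    paste("lgt gain clade tips not in tree:",
                          paste(setdiff(g$clade, tips), collapse = ", ")))
    stopifnot(!is.null(g$label), g$n_genes >= 1L, all(g$bias > 0))
  }
  structure(list(seed = as.integer(seed), tree = tree,
                 n_host_genes = as.integer(n_host_genes),
                 gene_length_codons = gene_length_codons,
                 background = background,
                 base_anticodons = base_anticodons,
                 reference_strain = reference_strain,
                 sge_families = sge_families, trna_plants = trna_plants,
                 lgt_gains = lgt_gains, groups = groups,
                 spacer_bp = as.integer(spacer_bp)),
            class = "simulation_config")
}

#' Default simulation configuration
#'
#' The package's reference study conditions: 12 strains on a two-clade
#' tree — five "Shigella-like" pathogenic strains (S1-S5) and seven others
#' (the ancestral-like reference REF plus E1-E6) — each with ~2,000 shared
#' host genes of mean length 300 codons. Three SGE families are planted at
#' insertion-sequence-like copy numbers (140/33/45 copies per pathogenic
#' strain versus 1-3 elsewhere, echoing IS1/IS2/IS600 loads) with family
#' divergence 0/2/4%, all codon-biased 4x toward AGA, GGA and ACA; a
#' fourth, 6%-diverged family probes the similarity threshold. Extra tRNA
#' gene copies for the anticodons decoding those codons (TCT, TCC, TGT)
#' are planted in the pathogenic clade: 7 phage-flanked copies at 4%
#' divergence (an argO-like profile), a 3-copy identical tandem array
#' (glyVXY-like) and 2 host-flanked copies. LGT gene sets with increasing
#' AGA bias are gained at successively nested nodes of the pathogenic
#' clade.
#'
#' @param seed RNG seed (default 1).
#' @param n_host_genes Number of shared host genes (default 2000).
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(seed = 1L, n_host_genes = 2000L) {
  tree <- ape::read.tree(text = paste0(
    "((S1:0.02,(S2:0.016,(S3:0.012,(S4:0.008,S5:0.008):0.004):0.004):0.004):0.08,",
    "(REF:0.02,(E1:0.016,(E2:0.013,(E3:0.01,(E4:0.008,(E5:0.006,E6:0.006)",
    ":0.002):0.002):0.003):0.003):0.004):0.08);"))
  shig <- paste0("S", 1:5)
  others <- c("REF", paste0("E", 1:6))
  cps <- function(s, ref, e) setNames(c(rep(s, 5L), ref, rep(e, 6L)),
                                      c(shig, others))
  bias3 <- c(AGA = 4, GGA = 4, ACA = 4)
  acs <- c("TCT", "TCC", "TGT")  # anticodons decoding AGA, GGA, ACA
  base_acs <- unique(c(acs, setdiff(codons_all(), acs)[1:27]))
  simulation_config(
    seed = seed, tree = tree, n_host_genes = n_host_genes,
    gene_length_codons = c(300, 60),
    base_anticodons = base_acs,
    reference_strain = "REF",
    sge_families = list(
      list(family_id = "IS1L", length_codons = 250L, bias = bias3,
           divergence_pct = 0, copies = cps(140L, 3L, 3L)),
      list(family_id = "IS2L", length_codons = 300L, bias = bias3,
           divergence_pct = 2, copies = cps(33L, 2L, 2L)),
      list(family_id = "IS600L", length_codons = 280L, bias = bias3,
           divergence_pct = 4, copies = cps(45L, 1L, 1L)),
      list(family_id = "ISDIV6", length_codons = 260L, bias = bias3,
           divergence_pct = 6, copies = cps(10L, 1L, 0L))),
    trna_plants = list(
      list(anticodon = "TCT", strains = shig, n_copies = 7L,
           context = "phage_flanked", divergence_pct = 4),
      list(anticodon = "TCC", strains = shig, n_copies = 3L,
           context = "tandem", divergence_pct = 0),
      list(anticodon = "TGT", strains = shig, n_copies = 2L,
           context = "host_flanked", divergence_pct = 0)),
    lgt_gains = list(
      list(label = "n1", clade = shig, n_genes = 12L,
           length_codons = 300L, bias = c(AGA = 2)),
      list(label = "n2", clade = shig[2:5], n_genes = 12L,
           length_codons = 300L, bias = c(AGA = 4)),
      list(label = "n3", clade = shig[3:5], n_genes = 12L,
           length_codons = 300L, bias = c(AGA = 6)),
      list(label = "n4", clade = shig[4:5], n_genes = 12L,
           length_codons = 300L, bias = c(AGA = 8)),
      list(label = "n5", clade = shig[5], n_genes = 12L,
           length_codons = 300L, bias = c(AGA = 10))),
    groups = list(shigella_like = shig, others = others))
}

# Insert distinct gene sequences at separate host-flanked loci.
plant_gene_set <- function(genome, seqs, ids, category) {
  gaps <- host_host_gaps(genome)
  if (nrow(gaps) < length(seqs))
    stop_trnaflux("no_space", "not enough host-flanked gaps for gene set")
  chosen <- sample.int(nrow(gaps), length(seqs))
  insertions <- lapply(seq_along(seqs), function(i) {
    list(pos = gaps$pos[chosen[i]], seq = seqs[i],
         feats = data.frame(gene_id = ids[i], start = 0L,
                            end = nchar(seqs[i]), strand = "+",
                            category = category, product = "",
                            anticodon = NA_character_, usable = TRUE,
                            stringsAsFactors = FALSE),
         n_sub = 0L)
  })
  apply_insertions(genome, insertions)
}

#' Simulate an annotated strain set with truth
#'
#' Builds a root genome (host genes plus single-copy tRNA genes for the
#' base anticodons) that every tip inherits verbatim, then plants the
#' configured SGE families, LGT gene sets (gained at tree nodes, present
#' in exactly the descending tips) and tRNA copies per strain. Sequences
#' of each SGE family and LGT gene are sampled once, so undiverged copies
#' are identical across strains. Copies in the reference strain are
#' planted undiverged (the ancestral originals); copies elsewhere receive
#' exactly `round(divergence_pct/100 * length)` substitutions each. A
#' self-audit recounts the emitted features against the truth set.
#'
#' @param config A `simulation_config` (see [simulation_config()],
#'   [default_simulation_config()]).
#' @return List with `genomes` (named list of [annotated_genome()]),
#'   `truth` (see Details), `tree` and `config`.
#' @details The truth set contains: `sge` (per strain/family planted and
#'   detectable-at-95/95 copy counts), `trna` (per strain/anticodon total
#'   copy counts), `trna_contexts` (per planted or original tRNA locus:
#'   context and substitution count), `lgt` (gene to gain-clade map),
#'   `sge_codon_counts` (realized codon counts over each strain's planted
#'   SGE copies) and `family_seqs` (the family consensus sequences).
#' @export
simulate_strains <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  tips <- tree$tip.label
  bg <- config$background
  ref <- config$reference_strain

  # --- root genome shared by all tips -------------------------------------
  lens <- pmax(50L, as.integer(round(rnorm(config$n_host_genes,
                                           config$gene_length_codons[1],
                                           config$gene_length_codons[2]))))
  host_seqs <- sample_genes(lens, bg)
  host_ids <- sprintf("HG%04d", seq_along(host_seqs))
  trna_seqs <- setNames(vapply(config$base_anticodons,
                               function(a) random_spacer(77L), ""),
                        config$base_anticodons)
  n_tr <- length(trna_seqs)
  slot <- pmax(1L, as.integer(round(seq_along(trna_seqs) *
                                      config$n_host_genes / (n_tr + 1L))))
  item_seq <- character(0); item_id <- character(0)
  item_cat <- character(0); item_ac <- character(0)
  ti <- 1L
  for (i in seq_along(host_seqs)) {
    item_seq <- c(item_seq, host_seqs[i]); item_id <- c(item_id, host_ids[i])
    item_cat <- c(item_cat, "host"); item_ac <- c(item_ac, NA_character_)
    while (ti <= n_tr && slot[ti] == i) {
      item_seq <- c(item_seq, trna_seqs[ti])
      item_id <- c(item_id, paste0("tRNA_", names(trna_seqs)[ti], "_orig"))
      item_cat <- c(item_cat, "trna")
      item_ac <- c(item_ac, names(trna_seqs)[ti])
      ti <- ti + 1L
    }
  }
  m <- length(item_seq)
  spacers <- vapply(seq_len(m + 1L), function(i) random_spacer(config$spacer_bp), "")
  pieces <- character(2L * m + 1L)
  pieces[seq(1L, 2L * m + 1L, by = 2L)] <- spacers
  pieces[seq(2L, 2L * m, by = 2L)] <- item_seq
  starts <- cumsum(nchar(pieces)) - nchar(pieces)
  feat_starts <- starts[seq(2L, 2L * m, by = 2L)]
  root <- annotated_genome("ROOT", paste(pieces, collapse = ""),
                           data.frame(gene_id = item_id, start = feat_starts,
                                      end = feat_starts + nchar(item_seq),
                                      strand = "+", category = item_cat,
                                      product = "", anticodon = item_ac,
                                      usable = TRUE, stringsAsFactors = FALSE))

  # --- shared element sequences -------------------------------------------
  fam_seqs <- lapply(config$sge_families, function(fam)
    sample_genes(fam$length_codons, bias_usage(bg, fam$bias)))
  names(fam_seqs) <- vapply(config$sge_families, `[[`, "", "family_id")
  lgt_sets <- lapply(config$lgt_gains, function(g) {
    seqs <- sample_genes(rep(g$length_codons, g$n_genes), bias_usage(bg, g$bias))
    setNames(seqs, sprintf("LGT_%s_g%02d", g$label, seq_len(g$n_genes)))
  })

  genomes <- list()
  sge_rows <- list(); trna_ctx_rows <- list(); sge_codon_counts <- list()
  for (st in tips) {
    g <- root; g$strain_id <- st
    strain_sge_seqs <- character(0)
    for (fi in seq_along(config$sge_families)) {
      fam <- config$sge_families[[fi]]
      n <- fam$copies[st] %||% 0L
      n <- if (is.na(n)) 0L else n
      if (n == 0L) next
      div <- if (st == ref) 0 else fam$divergence_pct
      res <- plant_copies(g, fam_seqs[[fam$family_id]], n,
                          context = "host_flanked", divergence_pct = div,
                          id_prefix = paste(fam$family_id, st, sep = "_"),
                          category = "sge")
      g <- res$genome
      L <- nchar(fam_seqs[[fam$family_id]])
      n_sub <- round(div / 100 * L)
      strain_sge_seqs <- c(strain_sge_seqs,
                           mapply(function(a, b, d) genome_slice(g, a, b, d),
                                  res$placements$start, res$placements$end,
                                  res$placements$strand))
      sge_rows[[length(sge_rows) + 1L]] <- data.frame(
        strain = st, family_id = fam$family_id, planted = n,
        divergence_pct = div,
        detectable = if (1 - n_sub / L > 0.95) n else 0L,
        stringsAsFactors = FALSE)
    }
    for (gi in seq_along(config$lgt_gains)) {
      gain <- config$lgt_gains[[gi]]
      if (!st %in% gain$clade) next
      res <- plant_gene_set(g, unname(lgt_sets[[gi]]), names(lgt_sets[[gi]]),
                            "lgt")
      g <- res$genome
    }
    for (pl in config$trna_plants) {
      if (!st %in% pl$strains || pl$n_copies == 0L) next
      same_ac <- g$features$category == "trna" &
        !is.na(g$features$anticodon) & g$features$anticodon == pl$anticodon
      res <- plant_copies(g, trna_seqs[[pl$anticodon]], pl$n_copies,
                          context = pl$context,
                          divergence_pct = pl$divergence_pct,
                          id_prefix = paste0("tRNA_", pl$anticodon, "_", st),
                          category = "trna", anticodon = pl$anticodon,
                          min_separation = 6000L,
                          avoid = as.integer(g$features$start[same_ac]))
      g <- res$genome
      L <- 77L
      trna_ctx_rows[[length(trna_ctx_rows) + 1L]] <- data.frame(
        strain = st, anticodon = pl$anticodon,
        gene_id = res$placements$gene_id,
        context = res$placements$context,
        n_sub = res$placements$n_sub,
        detectable = 1 - res$placements$n_sub / L > 0.95,
        stringsAsFactors = FALSE)
    }
    # every strain carries the original single-copy tRNA genes, host-flanked
    trna_ctx_rows[[length(trna_ctx_rows) + 1L]] <- data.frame(
      strain = st, anticodon = config$base_anticodons,
      gene_id = paste0("tRNA_", config$base_anticodons, "_orig"),
      context = "host_flanked", n_sub = 0L, detectable = TRUE,
      stringsAsFactors = FALSE)
    sge_codon_counts[[st]] <- if (length(strain_sge_seqs))
      count_codons(strain_sge_seqs) else setNames(integer(64), codons_all())
    genomes[[st]] <- g
  }

  trna_truth <- do.call(rbind, trna_ctx_rows)
  trna_counts <- do.call(rbind, lapply(tips, function(st) {
    tt <- trna_truth[trna_truth$strain == st, ]
    as.integer(table(factor(tt$anticodon, levels = codons_all())))
  }))
  dimnames(trna_counts) <- list(tips, codons_all())

  lgt_truth <- do.call(rbind, lapply(seq_along(config$lgt_gains), function(gi) {
    g <- config$lgt_gains[[gi]]
    data.frame(gene_id = names(lgt_sets[[gi]]), label = g$label,
               clade = paste(g$clade, collapse = ","),
               stringsAsFactors = FALSE)
  }))

  truth <- list(strains = tips, reference_strain = ref,
                sge = do.call(rbind, sge_rows),
                trna_counts = trna_counts,
                trna_contexts = trna_truth,
                lgt = lgt_truth,
                sge_codon_counts = sge_codon_counts,
                family_seqs = fam_seqs,
                lgt_seqs = lgt_sets)
  sim <- list(genomes = genomes, truth = truth, tree = tree, config = config)
  audit_simulation(sim)
  sim
}

# Generator self-audit: recounting the emitted features must reproduce the
# truth set exactly.
audit_simulation <- function(sim) {
  counted <- anticodon_counts(sim$genomes)
  stopifnot(identical(unname(counted[, colnames(sim$truth$trna_counts)] -
                               sim$truth$trna_counts),
                      unname(matrix(0L, nrow(counted), 64L))))
  for (st in sim$truth$strains) {
    f <- sim$genomes[[st]]$features
    tab <- sim$truth$sge[sim$truth$sge$strain == st, ]
    for (i in seq_len(nrow(tab))) {
      n_feat <- sum(startsWith(f$gene_id, paste(tab$family_id[i], st, sep = "_")) &
                      f$category == "sge")
      stopifnot(n_feat == tab$planted[i])
    }
    present <- sim$truth$lgt$gene_id %in% f$gene_id
    should <- vapply(strsplit(sim$truth$lgt$clade, ",", fixed = TRUE),
                     function(cl) st %in% cl, logical(1))
    stopifnot(identical(present, should))
  }
  invisible(TRUE)
}

#' LGT gene presence/absence matrix from simulated genomes
#'
#' @param genomes Named list of [annotated_genome()] objects.
#' @return Logical matrix gene x strain over all category-`lgt` features.
#' @export
lgt_presence_from_genomes <- function(genomes) {
  ids <- sort(unique(unlist(lapply(genomes, function(g)
    g$features$gene_id[g$features$category == "lgt"]))))
  m <- vapply(genomes, function(g) ids %in% g$features$gene_id,
              logical(length(ids)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(ids),
                                 dimnames = list(ids, names(genomes)))
  rownames(m) <- ids
  m
}

#' Write a simulated strain set to disk
#'
#' Emits per-strain FASTA + GFF3, the strain tree as Newick, and the truth
#' set as JSON under one output directory.
#'
#' @param sim Result of [simulate_strains()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(sim$genomes)) {
    write_genome(sim$genomes[[st]],
                 file.path(out_dir, paste0(st, ".fasta")),
                 file.path(out_dir, paste0(st, ".gff3")))
  }
  write_tree(sim$tree, file.path(out_dir, "tree.nwk"))
  truth <- sim$truth
  truth$trna_counts <- as.data.frame(truth$trna_counts)
  truth$sge_codon_counts <- lapply(truth$sge_codon_counts, as.list)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
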