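# End-to-end orchestration: simulate (or load) genomes, then codon usage,
# SGE enrichment + rank test, copy-number clusters and contexts, tRNA
# profile, LGT node assignment and PIC correlation, with TSV outputs, JSON
# parameter sidecars and a markdown summary report.

#' Assemble a pipeline configuration
#'
#' @param simulation A `simulation_config` driving the synthetic strain
#'   set (see [default_simulation_config()]). Alternatively `genome_dir`
#'   may point at an existing directory of `<strain>.fasta` +
#'   `<strain>.gff3` pairs plus `tree.nwk`.
#' @param genome_dir Optional directory of pre-existing genomes.
#' @param reference_strain Reference (ancestral-like) strain id.
#' @param groups Named list with strain-id vectors `focal` and `others`
#'   (the group comparison for tRNA enrichment and SGE load).
#' @param target_codons Codons whose tRNA genes are hypothesized to
#'   amplify; used for the rank-sum test.
#' @param min_identity,min_coverage Copy-number thresholds.
#' @param fold_threshold tRNA fold-change gate.
#' @param ci_level Confidence level for enrichment CIs.
#' @param rank_reps Monte-Carlo replicates for the rank test.
#' @param seed Root seed; every stage derives its stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = default_simulation_config(),
                            genome_dir = NULL,
                            reference_strain = simulation$reference_strain %||% "REF",
                            groups = simulation$groups %||% NULL,
                            target_codons = c("AGA", "GGA", "ACA"),
                            min_identity = 0.95, min_coverage = 0.95,
                            fold_threshold = 2, ci_level = 0.99,
                            rank_reps = 10000L, seed = 1L) {
  if (is.null(groups) || !all(c("shigella_like", "others") %in% names(groups) |
                              c("focal", "others") %in% names(groups)))
    stop_trnaflux("bad_config", "groups must define a focal set and an others set")
  if (!is.null(genome_dir) && !dir.exists(genome_dir))
    stop_trnaflux("bad_config", paste("genome_dir does not exist:", genome_dir))
  structure(list(simulation = simulation, genome_dir = genome_dir,
                 reference_strain = reference_strain, groups = groups,
                 target_codons = target_codons, min_identity = min_identity,
                 min_coverage = min_coverage, fold_threshold = fold_threshold,
                 ci_level = ci_level, rank_reps = as.integer(rank_reps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_genome_dir <- function(dir) {
  fas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  genomes <- lapply(fas, function(f) {
    read_genome(f, sub("\\.fasta$", ".gff3", f),
                strain_id = tools::file_path_sans_ext(basename(f)))
  })
  names(genomes) <- vapply(genomes, `[[`, "", "strain_id")
  tree <- read_tree(file.path(dir, "tree.nwk"))
  list(genomes = genomes, tree = tree)
}

stage_seed <- function(root, stage) {
  (root * 131L + stage * 7919L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: simulate/load genomes; per-strain codon
#' usage; SGE fold enrichment with CIs, ranking and the rank-sum
#' permutation test; copy-number clusters, culling and context calls for
#' the reference strain's SGE and tRNA genes; anticodon copy-number and
#' fold-change tables with group tests; LGT node assignment, per-node AGA
#' proportions and PIC correlation of codon use versus tRNA copy number.
#' Every stage writes a TSV plus a JSON sidecar of its parameters; a
#' markdown report aggregates the key tables. A fixed configuration and
#' seed give byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- function(stage, params) {
    jsonlite::write_json(params, file.path(out_dir, paste0(stage, ".params.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  focal <- config$groups$shigella_like %||% config$groups$focal
  others <- config$groups$others
  ref <- config$reference_strain

  # stage 1: genomes ------------------------------------------------------
  if (!is.null(config$genome_dir)) {
    loaded <- load_genome_dir(config$genome_dir)
    genomes <- loaded$genomes; tree <- loaded$tree; truth <- NULL
  } else {
    simcfg <- config$simulation
    simcfg$seed <- stage_seed(config$seed, 1L)
    sim <- simulate_strains(simcfg)
    genomes <- sim$genomes; tree <- sim$tree; truth <- sim$truth
  }
  sidecar("genomes", list(seed = config$seed, strains = names(genomes)))

  # stage 2: codon usage ---------------------------------------------------
  usage_all <- lapply(genomes, genome_usage)
  usage_df <- do.call(rbind, lapply(names(usage_all), function(st)
    data.frame(strain = st, codon = codons_all(),
               count = as.integer(usage_all[[st]]$counts),
               rel = as.numeric(usage_all[[st]]$rel),
               stringsAsFactors = FALSE)))
  write_table(usage_df, file.path(out_dir, "usage.tsv"))
  sidecar("usage", list(genetic_code = "bacterial-11"))

  # stage 3: SGE enrichment -------------------------------------------------
  folds <- lapply(focal, function(st) {
    sge_cds <- extract_cds(genomes[[st]])
    sge_ids <- genomes[[st]]$features$gene_id[genomes[[st]]$features$category == "sge"]
    sub <- relative_usage(count_codons(sge_cds[names(sge_cds) %in% sge_ids]))
    fold_enrichment(sub, usage_all[[st]])
  })
  names(folds) <- focal
  ci <- enrichment_ci(do.call(rbind, folds), level = config$ci_level)
  mean_fold <- colMeans(do.call(rbind, folds))
  ranks <- rank_codons(mean_fold)
  S <- rank_sum(config$target_codons, ranks)
  rt <- permutation_rank_test(S, length(config$target_codons), 64L,
                              reps = config$rank_reps,
                              seed = stage_seed(config$seed, 3L))
  enrich_df <- data.frame(codon = codons_all(), mean_fold = mean_fold,
                          ci_lo = ci$lo, ci_hi = ci$hi, rank = ranks,
                          stringsAsFactors = FALSE)
  write_table(enrich_df[order(enrich_df$rank), ], file.path(out_dir, "enrich.tsv"))
  sidecar("enrich", list(level = config$ci_level, targets = config$target_codons,
                         rank_sum = S, p_mc = rt$p_mc, p_exact = rt$p_exact,
                         reps = rt$reps, seed = rt$seed, mode = rt$mode))

  # stage 4: copy number ----------------------------------------------------
  ref_feat <- genomes[[ref]]$features
  ref_ids <- ref_feat$gene_id[ref_feat$category %in% c("sge", "trna")]
  ref_seqs <- setNames(
    mapply(function(a, b, d) genome_slice(genomes[[ref]], a, b, d),
           ref_feat$start[match(ref_ids, ref_feat$gene_id)],
           ref_feat$end[match(ref_ids, ref_feat$gene_id)],
           ref_feat$strand[match(ref_ids, ref_feat$gene_id)]),
    ref_ids)
  clusters <- build_clusters(ref_seqs, config$min_identity, config$min_coverage)
  clusters <- count_copies(clusters, ref_seqs, genomes,
                           config$min_identity, config$min_coverage)
  clusters <- cull_redundant_sets(clusters)
  copies_df <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id,
               n_members = length(cl$members),
               strain = names(cl$copy_count),
               copy_count = as.integer(cl$copy_count),
               stringsAsFactors = FALSE)))
  write_table(copies_df, file.path(out_dir, "clusters.tsv"))
  ctx_df <- do.call(rbind, lapply(clusters, function(cl)
    do.call(rbind, lapply(names(genomes), function(st) {
      cc <- context_calls(cl, genomes[[st]], strain = st)
      if (nrow(cc) == 0L) return(NULL)
      cbind(cluster_id = cl$cluster_id, strain = st, cc)
    }))))
  write_table(ctx_df, file.path(out_dir, "context.tsv"))
  sidecar("copies", list(min_identity = config$min_identity,
                         min_coverage = config$min_coverage,
                         reference = ref))

  # SGE load t-test
  sge_totals <- vapply(names(genomes), function(st)
    sum(genomes[[st]]$features$category == "sge"), 0L)
  tt <- sge_group_ttest(sge_totals[focal], sge_totals[others])
  sidecar("sge_load", list(totals = as.list(sge_totals), t = tt$t, p = tt$p))

  # stage 5: tRNA profile ----------------------------------------------------
  ac_tab <- anticodon_counts(genomes)
  fc <- fold_change(ac_tab, ref)
  gt <- group_enrichment_test(fc, focal, others,
                              threshold = config$fold_threshold)
  write_table(data.frame(strain = rownames(ac_tab), ac_tab,
                         check.names = FALSE), file.path(out_dir, "trna.tsv"))
  write_table(gt, file.path(out_dir, "trna_tests.tsv"))
  sidecar("trna", list(reference = ref, threshold = config$fold_threshold))

  # stage 6: LGT phylogenetics -----------------------------------------------
  presence <- lgt_presence_from_genomes(genomes)
  lgt_df <- NULL; pic <- NULL
  if (nrow(presence) > 0L) {
    asg <- assign_gain_nodes(presence, tree)
    sets <- cumulative_sets(asg)
    cds_by_strain <- lapply(genomes, extract_cds)
    aga <- vapply(names(genomes), function(st)
      aga_arg_proportion(sets[[st]], cds_by_strain[[st]]), numeric(1))
    aga[is.na(aga)] <- 0
    trna_aga <- ac_tab[names(genomes), revcomp("AGA")]
    lgt_df <- data.frame(strain = names(genomes),
                         n_lgt_genes = lengths(sets)[names(genomes)],
                         aga_proportion = aga, trna_aga = trna_aga,
                         stringsAsFactors = FALSE)
    write_table(lgt_df, file.path(out_dir, "lgt.tsv"))
    pic <- pic_correlation(tree, setNames(aga, names(genomes)),
                           setNames(as.numeric(trna_aga), names(genomes)))
    sidecar("lgt", list(r = pic$r, t = pic$t, df = pic$df, p = pic$p))
  }

  report <- c(
    "# Pipeline report", "",
    sprintf("Strains: %s", paste(names(genomes), collapse = ", ")),
    sprintf("Reference strain: %s", ref), "",
    "## tRNA anticodon fold change (group test)", "",
    df_to_md(gt[gt$passed_threshold, , drop = FALSE]),
    "", "## Codon enrichment in SGE genes (top 10 by rank)", "",
    df_to_md(utils::head(enrich_df[order(enrich_df$rank), ], 10L)),
    "", sprintf("Rank sum of target codons (%s): %d; p_mc = %.4g, p_exact = %.4g",
                paste(config$target_codons, collapse = ","), S, rt$p_mc, rt$p_exact),
    "", sprintf("SGE load Welch t-test (focal vs others): t = %.3f, p = %.4g",
                tt$t, tt$p),
    "", "## Copy clusters", "", df_to_md(utils::head(copies_df, 20L)))
  if (!is.null(pic)) {
    report <- c(report, "",
                sprintf("## PIC correlation AGA codon use vs tRNA-AGA copy number: r = %.3f, p = %.4g",
                        pic$r, pic$p))
  }
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(genomes = genomes, tree = tree, truth = truth,
                 usage = usage_all, folds = folds, enrichment = enrich_df,
                 rank_test = rt, clusters = clusters, contexts = ctx_df,
                 sge_ttest = tt, anticodon_table = ac_tab, fold_change = fc,
                 group_tests = gt, lgt = lgt_df, pic = pic))
}

df_to_md <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("(none)")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}
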