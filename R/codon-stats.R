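# Codon counting, per-amino-acid relative usage, subset-vs-genome fold
# enrichment with cross-strain confidence intervals, codon ranking, and the
# rank-sum permutation test.

#' Count in-frame codons over a set of coding sequences
#'
#' Tallies every in-frame triplet of every CDS into the 64-codon table.
#' Because bacterial start codons vary (ATG, GTG, TTG all initiate with
#' formyl-methionine), the leading triplet of each CDS is credited to the
#' methionine group (recorded under ATG) regardless of its identity.
#' Codons containing N are skipped; any other non-ACGTN character rejects
#' the sequence.
#'
#' @param cds_list Character vector of coding sequences, each with length
#'   divisible by 3.
#' @return Named integer vector of counts over the 64 codons.
#' @export
#' @examples
#' count_codons("GTGAAATAA")  # GTG start credited to Met (ATG)
count_codons <- function(cds_list) {
  codons <- codons_all()
  counts <- setNames(integer(64), codons)
  cds_list <- toupper(unlist(cds_list, use.names = FALSE))
  if (!length(cds_list)) return(counts)
  if (any(grepl("[^ACGTN]", cds_list)))
    stop_trnaflux("invalid_sequence", "CDS contains non-ACGTN characters")
  if (any(nchar(cds_list) %% 3L != 0L))
    stop_trnaflux("frame_error", "CDS length not divisible by 3")
  firsts <- substr(cds_list, 1L, 3L)
  counts["ATG"] <- counts["ATG"] + sum(!grepl("N", firsts, fixed = TRUE))
  rest <- substring(cds_list, 4L)
  rest <- rest[nzchar(rest)]
  if (length(rest)) {
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(rest), width = 3L, step = 3L)
    counts <- counts + as.integer(colSums(freq))[match(codons, colnames(freq))]
  }
  counts
}

#' Per-amino-acid relative codon usage
#'
#' Normalizes raw codon counts within each synonymous family so that the
#' codons coding the same amino acid sum to 1 (the three stop codons form
#' one group). Families with zero total count get `NA` frequencies and are
#' flagged.
#'
#' @param counts Named vector of counts over the 64 codons
#'   (as from [count_codons()]).
#' @param genetic_code Identifier stored with the table; the codon-to-amino
#'   acid map is the standard (bacterial) code.
#' @return A `codon_usage_table`: list with `counts`, `rel` (per-amino-acid
#'   frequencies, `NA` for empty groups) and `genetic_code`.
#' @export
relative_usage <- function(counts, genetic_code = "bacterial-11") {
  codons <- codons_all()
  stopifnot(all(codons %in% names(counts)))
  counts <- counts[codons]
  if (any(counts < 0)) stop_trnaflux("bad_counts", "negative codon counts")
  aa <- codon_to_aa()
  group_tot <- tapply(counts, aa, sum)[aa]
  rel <- ifelse(group_tot > 0, counts / group_tot, NA_real_)
  structure(list(counts = counts, rel = setNames(as.numeric(rel), codons),
                 genetic_code = genetic_code),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %s codons counted, %d/21 amino-acid groups observed\n",
              format(sum(x$counts), big.mark = ","),
              length(unique(codon_to_aa()[!is.na(x$rel)]))))
  invisible(x)
}

#' Codon usage of a genome or gene subset
#'
#' Convenience wrapper: extracts coding sequences and returns the
#' per-amino-acid relative usage table.
#'
#' @param genome An [annotated_genome()].
#' @param categories Feature categories to include (default: all
#'   protein-coding categories).
#' @return A `codon_usage_table`.
#' @export
genome_usage <- function(genome, categories = setdiff(FEATURE_CATEGORIES, "trna")) {
  cds <- extract_cds(genome)
  keep <- genome$features$gene_id[genome$features$category %in% categories]
  relative_usage(count_codons(cds[names(cds) %in% keep]))
}

#' Fold enrichment of codon usage in a gene subset versus the genome
#'
#' For each codon, the enrichment is the ratio of its per-amino-acid
#' relative frequency in the subset to its frequency over all genes. The
#' genome table should be computed over *all* genes including the subset,
#' which makes the measure conservative. A codon unused genome-wide but
#' used in the subset is flagged infinite; a codon absent from both is
#' assigned 1.
#'
#' @param subset,genome `codon_usage_table` objects.
#' @return Named numeric vector of per-codon fold enrichments.
#' @export
fold_enrichment <- function(subset, genome) {
  stopifnot(inherits(subset, "codon_usage_table"),
            inherits(genome, "codon_usage_table"))
  if (sum(subset$counts) > sum(genome$counts))
    warning("subset has more codons than the genome table; is the subset really a subset?")
  rs <- ifelse(is.na(subset$rel), 0, subset$rel)
  rg <- ifelse(is.na(genome$rel), 0, genome$rel)
  fold <- ifelse(rg > 0, rs / rg, ifelse(rs > 0, Inf, 1))
  setNames(fold, codons_all())
}

#' Cross-strain confidence intervals for per-codon fold enrichment
#'
#' Given one fold-enrichment vector per strain, returns the across-strain
#' mean and a t-based confidence interval for each codon:
#' mean +/- t_{(1+level)/2, n-1} * s / sqrt(n).
#'
#' @param per_strain_folds List (or strain-by-codon matrix) of fold vectors.
#' @param level Confidence level (default 0.99).
#' @return Data frame with columns `codon`, `mean`, `lo`, `hi`, `n`.
#' @export
enrichment_ci <- function(per_strain_folds, level = 0.99) {
  m <- if (is.matrix(per_strain_folds)) per_strain_folds
       else do.call(rbind, per_strain_folds)
  if (nrow(m) < 2L)
    stop_trnaflux("ci_undefined", "confidence intervals need at least 2 strains")
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  half <- qt((1 + level) / 2, df = nrow(m) - 1L) * s / sqrt(nrow(m))
  data.frame(codon = colnames(m) %||% codons_all(), mean = mu,
             lo = mu - half, hi = mu + half, n = nrow(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank codons from most to least enriched
#'
#' Rank 1 is the most enriched codon. Infinite enrichments sort first;
#' ties are broken by codon lexicographic order so the ranking is always a
#' permutation of 1..64.
#'
#' @param fold Named fold-enrichment vector (as from [fold_enrichment()]).
#' @return Named integer vector of ranks (1 = most enriched).
#' @export
rank_codons <- function(fold) {
  stopifnot(!is.null(names(fold)))
  ord <- order(-fold, names(fold))
  rank <- integer(length(fold))
  rank[ord] <- seq_along(fold)
  setNames(rank, names(fold))
}

#' Sum of ranks of a target codon set
#'
#' @param targets Character vector of codons.
#' @param rank Named rank vector (from [rank_codons()]).
#' @return Integer rank sum.
#' @export
rank_sum <- function(targets, rank) {
  if (!length(targets)) stop_trnaflux("empty_targets", "empty target codon set")
  if (!all(targets %in% names(rank)))
    stop_trnaflux("unknown_target",
                  paste("targets not in ranking:",
                        paste(setdiff(targets, names(rank)), collapse = ", ")))
  sum(rank[targets])
}

#' Exact lower-tail p-value for a rank sum
#'
#' Probability that a random set of `k` ranks drawn from 1..n has sum at
#' most `S`. In `distinct` mode the null draws k-subsets without
#' replacement (counted by dynamic programming over C(n, k) subsets); in
#' `with_replacement` mode it draws ordered k-tuples.
#'
#' @param S Observed rank sum.
#' @param k Number of target codons.
#' @param n Ranking size (64 by default usage; 61 for sense-codon-only
#'   rankings).
#' @param mode `"distinct"` (default) or `"with_replacement"`.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' exact_rank_sum_p(9, 3, 64)  # 7 / choose(64, 3)
exact_rank_sum_p <- function(S, k, n, mode = c("distinct", "with_replacement")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, k <= n, S >= k)
  if (mode == "distinct" && S < k * (k + 1) / 2)
    stop_trnaflux("bad_rank_sum", "S below the minimum distinct rank sum")
  S <- min(S, k * n)
  # ways[t+1, s+1] = number of size-t draws with sum s (sums capped at S)
  ways <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  ways[1L, 1L] <- 1
  if (mode == "distinct") {
    for (v in seq_len(min(n, S))) {
      for (t in k:1) {
        src <- seq_len(S + 1L - v)
        ways[t + 1L, src + v] <- ways[t + 1L, src + v] + ways[t, src]
      }
    }
    sum(ways[k + 1L, ]) / choose(n, k)
  } else {
    for (t in seq_len(k)) {
      acc <- numeric(S + 1L)
      for (v in seq_len(min(n, S))) {
        src <- seq_len(S + 1L - v)
        acc[src + v] <- acc[src + v] + ways[t, src]
      }
      ways[t + 1L, ] <- acc
    }
    sum(ways[k + 1L, ]) / n^k
  }
}

#' One-tailed Monte-Carlo rank-sum permutation test
#'
#' Tests whether `k` target codons rank higher (lower rank sum) than
#' expected by chance, by drawing random sets of `k` ranks from 1..n and
#' counting draws whose sum is at most the observed sum. The Monte-Carlo
#' estimate uses the add-one convention `(hits + 1) / (reps + 1)` so finite
#' sampling never reports 0; the exact enumerated p-value is reported
#' alongside.
#'
#' @param S Observed rank sum (see [rank_sum()]).
#' @param k Number of target codons.
#' @param n Ranking size.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed Optional RNG seed for reproducibility.
#' @param mode `"distinct"` (default) or `"with_replacement"`.
#' @return A `rank_test_result` list: `observed_sum`, `k`, `n`, `p_mc`,
#'   `p_exact`, `reps`, `seed`, `mode`.
#' @export
permutation_rank_test <- function(S, k, n, reps = 10000L, seed = NULL,
                                  mode = c("distinct", "with_replacement")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample.int(n, reps * k, replace = TRUE), nrow = k)
  if (mode == "distinct" && k > 1L) {
    repeat {
      dup <- rep(FALSE, ncol(m))
      for (i in seq_len(k - 1L))
        for (j in seq(i + 1L, k))
          dup <- dup | m[i, ] == m[j, ]
      if (!any(dup)) break
      m[, dup] <- sample.int(n, sum(dup) * k, replace = TRUE)
    }
  }
  hits <- sum(colSums(m) <= S)
  structure(list(observed_sum = S, k = k, n = n,
                 p_mc = (hits + 1) / (reps + 1),
                 p_exact = exact_rank_sum_p(S, k, n, mode),
                 reps = reps, seed = seed, mode = mode),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Rank-sum permutation test (one-tailed, low sums): S = %d, k = %d, n = %d\n",
              x$observed_sum, x$k, x$n))
  cat(sprintf("  p (Monte-Carlo, %d reps, %s) = %.4g; p (exact) = %.4g\n",
              x$reps, x$mode, x$p_mc, x$p_exact))
  invisible(x)
}

#' Absolute codon influx from selfish-element proliferation
#'
#' Counts the codons carried by every located copy of a set of
#' selfish-element gene clusters, per strain, and averages across strains.
#' This measures how many copies of each codon SGE proliferation has
#' introduced into each genome.
#'
#' @param clusters Copy clusters with located hits (see [count_copies()]).
#' @param genomes Named list of [annotated_genome()] objects.
#' @param strains Strains to average over (default: all in `genomes`).
#' @return List with `per_strain` (strain-by-codon count matrix) and
#'   `mean` (named numeric, averaged over `strains`).
#' @export
absolute_codon_influx <- function(clusters, genomes, strains = names(genomes)) {
  codons <- codons_all()
  per_strain <- matrix(0L, nrow = length(genomes), ncol = 64L,
                       dimnames = list(names(genomes), codons))
  for (st in names(genomes)) {
    seqs <- character()
    for (cl in clusters) {
      h <- cl$hits[[st]]
      if (is.null(h) || nrow(h) == 0L) next
      s <- mapply(function(a, b, d) genome_slice(genomes[[st]], a, b, d),
                  h$start, h$end, h$strand)
      seqs <- c(seqs, s)
    }
    ok <- nchar(seqs) %% 3L == 0L
    if (any(!ok))
      warning(sprintf("%s: dropping %d hit(s) with length not divisible by 3",
                      st, sum(!ok)))
    if (any(ok)) per_strain[st, ] <- count_codons(seqs[ok])
  }
  list(per_strain = per_strain,
       mean = colMeans(per_strain[strains, , drop = FALSE]))
}
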