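# Reference-driven gene copy-number detection: seed-and-extend similarity
# search with glocal verification at strict identity/coverage thresholds,
# single-linkage paralog clustering, redundant-set culling, tandem-array
# detection and flanking-context classification.

.sub_matrix <- local({
  cache <- NULL
  function(match = 1, mismatch = -1) {
    key <- paste(match, mismatch)
    if (is.null(cache) || attr(cache, "key") != key) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
      attr(m, "key") <- key
      cache <<- m
    }
    cache
  }
})

#' Glocal alignment statistics between two sequences
#'
#' Aligns the query globally against a locally selected region of the
#' subject (free end-gaps on the subject), with default scoring +1 match,
#' -1 mismatch, -2 per gap position. Identity is matches divided by aligned
#' query positions; coverage is aligned query positions divided by query
#' length, so a subject missing half the query yields coverage 0.5.
#'
#' @param query,subject DNA strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `identity`, `coverage`, `score`, `subject_start`,
#'   `subject_end` (1-based positions of the aligned region in the
#'   subject).
#' @export
align_stats <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(query), nzchar(subject))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap)
  alignment_to_stats(al, nchar(query))
}

alignment_to_stats <- function(al, query_len) {
  st <- alignment_stats_batch(al, query_len)
  list(identity = st$identity[1], coverage = st$coverage[1],
       score = st$score[1], subject_start = st$subject_start[1],
       subject_end = st$subject_end[1])
}

# Vectorized identity/coverage/score over a PairwiseAlignments object.
# Aligned query positions are exactly the matched plus mismatched pairs;
# query positions opposite subject gaps count toward neither.
alignment_stats_batch <- function(als, query_len) {
  nm <- Biostrings::nmatch(als)
  nmm <- Biostrings::nmismatch(als)
  aligned <- nm + nmm
  data.frame(identity = ifelse(aligned > 0, nm / aligned, 0),
             coverage = aligned / query_len,
             score = Biostrings::score(als),
             subject_start = Biostrings::start(Biostrings::subject(als)),
             subject_end = Biostrings::end(Biostrings::subject(als)))
}

# Candidate copy start positions (0-based) of `query` on the forward
# strand of `subject_dna`, from exact matches of non-overlapping k-mer
# seeds. With floor(L/k) seeds, a copy differing by fewer than that many
# substitutions is guaranteed to retain an intact seed (pigeonhole), so
# every copy near the similarity threshold surfaces as a candidate. Seed
# hits projecting to nearby gene starts collapse into one candidate.
seed_candidates <- function(query, subject_dna, k = 12L, tol = NULL) {
  L <- nchar(query)
  starts <- seq.int(1L, L - k + 1L, by = k)
  seeds <- substring(query, starts, starts + k - 1L)
  keep <- !grepl("N", seeds, fixed = TRUE)
  if (!any(keep)) return(integer())
  seeds <- seeds[keep]; offsets <- starts[keep]
  cand <- unlist(lapply(seq_along(seeds), function(i) {
    m <- Biostrings::matchPattern(seeds[i], subject_dna)
    if (length(m)) Biostrings::start(m) - offsets[i] else integer()
  }), use.names = FALSE)
  cand <- sort(unique(cand))
  if (!length(cand)) return(integer())
  tol <- tol %||% max(10L, as.integer(0.2 * L))
  grp <- cumsum(c(TRUE, diff(cand) > tol))
  as.integer(round(tapply(cand, grp, function(x) x[ceiling(length(x) / 2)])))
}

#' Find copies of a reference gene in a target genome
#'
#' Seed-and-extend similarity search: exact k-mer seed matches on both
#' strands nominate candidate windows, each verified by glocal alignment.
#' Hits must exceed both thresholds strictly (identity and query coverage
#' of exactly 0.95 fail at the defaults). Overlapping hits are merged
#' keeping the best-scoring one. For queries shorter than the seed length,
#' a full mismatch-tolerant scan replaces the seed stage.
#'
#' @param reference_gene DNA string of the query gene.
#' @param target_genome An [annotated_genome()] or plain DNA string.
#' @param min_identity,min_coverage Strict lower thresholds (default 0.95).
#' @param k Seed length (default 12).
#' @return Data frame with columns `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `coverage`, `score`.
#' @export
find_copies <- function(reference_gene, target_genome,
                        min_identity = 0.95, min_coverage = 0.95, k = 12L) {
  genome_seq <- if (inherits(target_genome, "annotated_genome"))
    target_genome$sequence else toupper(target_genome)
  subject_dna <- Biostrings::DNAString(genome_seq)
  G <- nchar(genome_seq)
  L <- nchar(reference_gene)
  queries <- c(`+` = toupper(reference_gene), `-` = revcomp(reference_gene))

  if (L < k) {
    hits <- lapply(names(queries), function(strand) {
      mm <- floor((1 - min_identity) * L)
      m <- Biostrings::matchPattern(queries[[strand]], subject_dna,
                                    max.mismatch = mm)
      if (!length(m)) return(NULL)
      qchars <- strsplit(queries[[strand]], "")[[1]]
      ident <- vapply(as.character(m), function(s)
        mean(strsplit(s, "")[[1]] == qchars), numeric(1))
      data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
                 strand = strand, identity = ident, coverage = 1,
                 score = ident * L - (1 - ident) * L,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, hits)
  } else {
    pad <- max(20L, as.integer(0.15 * L))
    hits <- lapply(names(queries), function(strand) {
      q <- queries[[strand]]
      cand <- seed_candidates(q, subject_dna, k = k)
      if (!length(cand)) return(NULL)
      w0 <- pmax(0L, cand - pad)
      w1 <- pmin(G, cand + L + pad)
      wins <- Biostrings::DNAStringSet(substring(genome_seq, w0 + 1L, w1))
      qs <- Biostrings::DNAStringSet(rep(q, length(cand)))
      als <- Biostrings::pairwiseAlignment(
        qs, wins, type = "global-local",
        substitutionMatrix = .sub_matrix(), gapOpening = 0, gapExtension = 2)
      st <- alignment_stats_batch(als, L)
      ok <- st$identity > min_identity & st$coverage > min_coverage
      if (!any(ok)) return(NULL)
      data.frame(start = w0[ok] + st$subject_start[ok] - 1L,
                 end = w0[ok] + st$subject_end[ok],
                 strand = strand, identity = st$identity[ok],
                 coverage = st$coverage[ok], score = st$score[ok],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, hits)
  }
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  merge_hits(out)
}

# Greedy best-score-first merge of hits overlapping by more than half the
# shorter hit; prevents double counting when several queries or windows
# rediscover the same locus.
merge_hits <- function(hits) {
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    if (any(kept)) {
      kj <- which(kept)
      inter <- pmin(hits$end[kj], hits$end[i]) - pmax(hits$start[kj], hits$start[i])
      shorter <- pmin(hits$end[kj] - hits$start[kj], hits$end[i] - hits$start[i])
      ov <- any(inter > 0.5 * shorter)
    }
    kept[i] <- !ov
  }
  hits <- hits[kept, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Cluster reference genes into paralog families
#'
#' Single-linkage clustering of reference genes over the strict
#' identity/coverage relation, so that chains of pairwise-similar paralogs
#' (e.g. a tRNA gene cluster like asnT/asnU/asnV/asnW, where every member
#' retrieves the others as hits) fall into one cluster. Candidate pairs
#' are prescreened by shared k-mers before alignment.
#'
#' @param reference_genes Named character vector `gene_id -> sequence`.
#' @param min_identity,min_coverage Strict thresholds (default 0.95).
#' @param k Seed length for the k-mer prescreen.
#' @param min_shared_kmers Minimum shared k-mers to nominate a pair.
#' @return List of clusters, each a list with `cluster_id` (lexicographic
#'   first member) and `members`.
#' @export
build_clusters <- function(reference_genes, min_identity = 0.95,
                           min_coverage = 0.95, k = 12L, min_shared_kmers = 2L) {
  ids <- names(reference_genes)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # identical sequences are trivially linked
  seq_grp <- split(seq_len(n), reference_genes)
  for (g in seq_grp) if (length(g) > 1L) for (i in g[-1]) union_(g[1], i)
  reps <- vapply(seq_grp, `[`, 0L, 1)

  if (length(reps) > 1L) {
    km <- lapply(reps, function(i) {
      s <- reference_genes[[i]]
      if (nchar(s) < k) return(character())
      unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    })
    idx <- data.frame(kmer = unlist(km, use.names = FALSE),
                      gene = rep(seq_along(reps), lengths(km)))
    by_kmer <- split(idx$gene, idx$kmer)
    by_kmer <- by_kmer[lengths(by_kmer) > 1L]
    pairs <- unlist(lapply(by_kmer, function(g) {
      cmb <- combn(sort(g), 2L)
      paste(cmb[1, ], cmb[2, ])
    }), use.names = FALSE)
    if (length(pairs)) {
      tab <- table(pairs)
      cand <- names(tab)[tab >= min_shared_kmers]
      for (pr in cand) {
        ij <- as.integer(strsplit(pr, " ", fixed = TRUE)[[1]])
        a <- reps[ij[1]]; b <- reps[ij[2]]
        if (find(a) == find(b)) next
        st1 <- align_stats(reference_genes[[a]], reference_genes[[b]])
        ok <- st1$identity > min_identity && st1$coverage > min_coverage
        if (!ok) {
          st2 <- align_stats(reference_genes[[b]], reference_genes[[a]])
          ok <- st2$identity > min_identity && st2$coverage > min_coverage
        }
        if (ok) union_(a, b)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  clusters <- lapply(split(seq_len(n), roots), function(members) {
    mem_ids <- sort(ids[members])
    list(cluster_id = mem_ids[1], members = mem_ids)
  })
  names(clusters) <- vapply(clusters, `[[`, "", "cluster_id")
  clusters[order(names(clusters))]
}

#' Count gene copies per strain for each paralog cluster
#'
#' Queries every (sequence-distinct) cluster member against every genome
#' with [find_copies()] and unions the hit loci, so a strain matching any
#' one member contributes all of its detectable copies. Overlapping hits
#' from different member queries are merged keeping the best score.
#'
#' @param clusters Clusters from [build_clusters()].
#' @param reference_genes Named character vector used to build the clusters.
#' @param genomes Named list of [annotated_genome()] objects.
#' @param min_identity,min_coverage,k Passed to [find_copies()].
#' @return The clusters, each augmented with `hits` (per-strain hit data
#'   frames) and `copy_count` (named integer per strain).
#' @export
count_copies <- function(clusters, reference_genes, genomes,
                         min_identity = 0.95, min_coverage = 0.95, k = 12L) {
  lapply(clusters, function(cl) {
    qseqs <- unique(unname(reference_genes[cl$members]))
    cl$hits <- lapply(genomes, function(g) {
      hs <- lapply(qseqs, find_copies, target_genome = g,
                   min_identity = min_identity, min_coverage = min_coverage,
                   k = k)
      merge_hits(do.call(rbind, hs))
    })
    cl$copy_count <- vapply(cl$hits, nrow, 0L)
    cl
  })
}

#' Cull redundant copy clusters
#'
#' When two clusters' hit-locus sets overlap reciprocally by more than half
#' of their members (the same family of loci discovered under two slightly
#' diverged queries), the cluster with fewer reference members is dropped;
#' ties drop the lexicographically later cluster id. The rule is
#' deterministic and idempotent.
#'
#' @param clusters Clusters with hits (from [count_copies()]).
#' @return Filtered cluster list.
#' @export
cull_redundant_sets <- function(clusters) {
  if (length(clusters) < 2L) return(clusters)
  loci <- lapply(clusters, function(cl) {
    do.call(rbind, lapply(names(cl$hits), function(st) {
      h <- cl$hits[[st]]
      if (nrow(h) == 0L) return(NULL)
      data.frame(strain = st, start = h$start, end = h$end,
                 stringsAsFactors = FALSE)
    }))
  })
  covered_frac <- function(a, b) {
    if (is.null(a) || nrow(a) == 0L) return(0)
    if (is.null(b)) return(0)
    cov <- vapply(seq_len(nrow(a)), function(i) {
      bb <- b[b$strain == a$strain[i], , drop = FALSE]
      if (nrow(bb) == 0L) return(FALSE)
      inter <- pmin(bb$end, a$end[i]) - pmax(bb$start, a$start[i])
      shorter <- pmin(bb$end - bb$start, a$end[i] - a$start[i])
      any(inter > 0.5 * shorter)
    }, logical(1))
    mean(cov)
  }
  ids <- names(clusters)
  drop <- setNames(logical(length(clusters)), ids)
  for (i in seq_along(clusters)) {
    for (j in seq_along(clusters)) {
      if (j <= i || drop[i] || drop[j]) next
      if (covered_frac(loci[[i]], loci[[j]]) > 0.5 &&
          covered_frac(loci[[j]], loci[[i]]) > 0.5) {
        ni <- length(clusters[[i]]$members)
        nj <- length(clusters[[j]]$members)
        victim <- if (ni < nj) i else if (nj < ni) j
                  else which(ids == max(ids[c(i, j)]))
        drop[victim] <- TRUE
      }
    }
  }
  clusters[!drop]
}

#' Detect tandem arrays among a cluster's hits in one strain
#'
#' Marks maximal runs of two or more same-strand cluster hits whose
#' successive gaps are at most `window` bp as tandem arrays (the signature
#' of within-genome duplication, e.g. the glyV-glyX-glyY tRNA cluster).
#'
#' @param cluster A cluster with hits (from [count_copies()]).
#' @param strain Strain id.
#' @param window Maximum gap between successive array members (bp).
#' @return Logical vector, one element per hit (in start order).
#' @export
detect_tandem <- function(cluster, strain, window = 5000L) {
  h <- cluster$hits[[strain]]
  if (is.null(h) || nrow(h) == 0L) return(logical())
  h <- h[order(h$start), , drop = FALSE]
  tandem <- logical(nrow(h))
  if (nrow(h) >= 2L) {
    gap_ok <- c(FALSE, h$start[-1] - h$end[-nrow(h)] <= window &
                         h$strand[-1] == h$strand[-nrow(h)])
    run <- cumsum(!gap_ok)
    run_sizes <- table(run)
    tandem <- run_sizes[as.character(run)] >= 2L
  }
  as.logical(tandem)
}

#' Classify the genomic context of each cluster hit in one strain
#'
#' For every hit locus, finds the nearest annotated feature on each side
#' (ignoring features that overlap the cluster's own hits) within
#' `flank_window` bp. Tandem-array members are labelled first; remaining
#' loci with a phage gene on either side are `phage_flanked` (the
#' signature of phage-mediated lateral transfer), loci with host genes on
#' both sides are `host_flanked`, and anything else is `ambiguous`.
#'
#' @param cluster A cluster with hits (from [count_copies()]).
#' @param genome The [annotated_genome()] of `strain`.
#' @param strain Strain id (default: the genome's strain id).
#' @param window Tandem gap window (bp), see [detect_tandem()].
#' @param flank_window Maximum distance to a flanking feature (bp).
#' @return Data frame with one row per hit: `start`, `end`, `strand`,
#'   `call`, `flank_left`, `flank_right`, `left_category`,
#'   `right_category`, `identity_to_original`.
#' @export
context_calls <- function(cluster, genome, strain = genome$strain_id,
                          window = 5000L, flank_window = 10000L) {
  h <- cluster$hits[[strain]]
  if (is.null(h) || nrow(h) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      call = character(), flank_left = character(),
                      flank_right = character(), left_category = character(),
                      right_category = character(),
                      identity_to_original = numeric(),
                      stringsAsFactors = FALSE))
  h <- h[order(h$start), , drop = FALSE]
  tandem <- detect_tandem(cluster, strain, window = window)
  f <- genome$features
  # features overlapping any cluster hit are the cluster's own annotations
  own <- rep(FALSE, nrow(f))
  for (i in seq_len(nrow(h)))
    own <- own | (f$start < h$end[i] & f$end > h$start[i])
  f <- f[!own, , drop = FALSE]
  res <- lapply(seq_len(nrow(h)), function(i) {
    left <- f[f$end <= h$start[i] & h$start[i] - f$end <= flank_window, , drop = FALSE]
    right <- f[f$start >= h$end[i] & f$start - h$end[i] <= flank_window, , drop = FALSE]
    lf <- if (nrow(left)) left[which.max(left$end), ] else NULL
    rf <- if (nrow(right)) right[which.min(right$start), ] else NULL
    lc <- if (is.null(lf)) NA_character_ else lf$category
    rc <- if (is.null(rf)) NA_character_ else rf$category
    call <- if (tandem[i]) "tandem_array"
      else if (isTRUE(lc == "phage") || isTRUE(rc == "phage")) "phage_flanked"
      else if (isTRUE(lc == "host") && isTRUE(rc == "host")) "host_flanked"
      else "ambiguous"
    data.frame(start = h$start[i], end = h$end[i], strand = h$strand[i],
               call = call,
               flank_left = if (is.null(lf)) NA_character_ else lf$gene_id,
               flank_right = if (is.null(rf)) NA_character_ else rf$gene_id,
               left_category = lc, right_category = rc,
               identity_to_original = h$identity[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Locate the original (syntenic) copy of a cluster in a strain
#'
#' The original host copy is the hit syntenic with the reference strain's
#' locus: the one whose nearest flanking host genes match the flanks of the
#' reference gene in the reference genome. Returns the row index into the
#' strain's hit table, or `NA` if no hit is syntenic.
#'
#' @param cluster A cluster with hits.
#' @param genome Target strain's [annotated_genome()].
#' @param reference_genome The reference strain's [annotated_genome()].
#' @param flank_window Maximum flank distance (bp).
#' @return Integer index (into the start-ordered hit table) or `NA`.
#' @export
find_original <- function(cluster, genome, reference_genome,
                          flank_window = 10000L) {
  ref_feat <- reference_genome$features
  idx <- match(cluster$cluster_id, ref_feat$gene_id)
  if (is.na(idx)) return(NA_integer_)
  nbr <- function(feats, start, end) {
    left <- feats[feats$end <= start & feats$category == "host", , drop = FALSE]
    right <- feats[feats$start >= end & feats$category == "host", , drop = FALSE]
    c(if (nrow(left)) left$gene_id[which.max(left$end)] else NA_character_,
      if (nrow(right)) right$gene_id[which.min(right$start)] else NA_character_)
  }
  ref_nbr <- nbr(ref_feat, ref_feat$start[idx], ref_feat$end[idx])
  h <- cluster$hits[[genome$strain_id]]
  if (is.null(h) || nrow(h) == 0L) return(NA_integer_)
  h <- h[order(h$start), , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    if (identical(nbr(genome$features, h$start[i], h$end[i]), ref_nbr))
      return(i)
  }
  NA_integer_
}

#' Welch t-test for selfish-element load between strain groups
#'
#' Two-sample Welch t-test (two-sided) comparing per-strain total SGE copy
#' numbers between two strain groups. Degenerate input with zero variance
#' in both groups returns p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param countsA,countsB Numeric vectors of per-strain SGE totals.
#' @return List with `t` and `p`.
#' @export
sge_group_ttest <- function(countsA, countsB) {
  stopifnot(length(countsA) >= 2L, length(countsB) >= 2L)
  if (var(countsA) == 0 && var(countsB) == 0) {
    if (mean(countsA) == mean(countsB)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(countsA) - mean(countsB)) * Inf, p = 0))
  }
  tt <- t.test(countsA, countsB)
  list(t = unname(tt$statistic), p = tt$p.value)
}
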