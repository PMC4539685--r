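# Anticodon-level tRNA copy-number tables, fold change against a reference
# strain, and Mann-Whitney group enrichment tests.

#' Anticodon copy-number table across strains
#'
#' Counts tRNA gene copies per anticodon per strain, either from GFF3
#' annotation (`anticodon=` attributes on tRNA features) or from an
#' external tRNA scan converted to feature tables (see [read_trnascan()]).
#' Anticodons are reported in the DNA alphabet; the decoded codon is the
#' reverse complement of the anticodon. tRNA features lacking an anticodon
#' are tallied in an extra `unknown` column with a warning.
#'
#' @param genomes Named list of [annotated_genome()] objects, or a single
#'   genome.
#' @return Integer matrix strain x anticodon (64 columns, plus `unknown`
#'   if needed), with attribute `source = "annotation"`.
#' @export
anticodon_counts <- function(genomes) {
  if (inherits(genomes, "annotated_genome")) {
    genomes <- setNames(list(genomes), genomes$strain_id)
  }
  codons <- codons_all()
  tab <- matrix(0L, nrow = length(genomes), ncol = 64L,
                dimnames = list(names(genomes), codons))
  unknown <- setNames(integer(length(genomes)), names(genomes))
  for (st in names(genomes)) {
    f <- genomes[[st]]$features
    ac <- toupper(f$anticodon[f$category == "trna"])
    bad <- is.na(ac) | !ac %in% codons
    if (any(bad)) {
      warning(sprintf("%s: %d tRNA feature(s) without a valid anticodon counted as 'unknown'",
                      st, sum(bad)))
      unknown[st] <- sum(bad)
    }
    cnt <- table(factor(ac[!bad], levels = codons))
    tab[st, ] <- as.integer(cnt)
  }
  if (any(unknown > 0L)) tab <- cbind(tab, unknown = unknown)
  attr(tab, "source") <- "annotation"
  tab
}

#' Parse tRNAscan-SE tabular output into a feature table
#'
#' Reads the standard tabular output of tRNAscan-SE (three header lines,
#' then whitespace-separated columns: sequence name, tRNA number, begin,
#' end, type, anticodon, intron bounds, score) and returns tRNA features in
#' the package's internal convention, usable with [annotated_genome()] or
#' directly tallied by [anticodon_counts_from_scan()].
#'
#' @param path Path to the tRNAscan-SE tabular file.
#' @return Data frame with columns `seqid`, `gene_id`, `start`, `end`
#'   (0-based half-open), `strand`, `category`, `anticodon`.
#' @export
read_trnascan <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(seqid = character(), gene_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      category = character(), anticodon = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  begin <- as.integer(m[, 3]); end <- as.integer(m[, 4])
  strand <- ifelse(begin <= end, "+", "-")
  data.frame(seqid = m[, 1],
             gene_id = paste0(m[, 1], "_trna", m[, 2]),
             start = pmin(begin, end) - 1L,
             end = pmax(begin, end),
             strand = strand,
             category = "trna",
             anticodon = toupper(m[, 6]),
             stringsAsFactors = FALSE)
}

#' Anticodon counts from external tRNA scan tables
#'
#' @param scans Named list (per strain) of data frames from
#'   [read_trnascan()].
#' @return Integer matrix strain x anticodon with
#'   attribute `source = "external_scan"`.
#' @export
anticodon_counts_from_scan <- function(scans) {
  codons <- codons_all()
  tab <- matrix(0L, nrow = length(scans), ncol = 64L,
                dimnames = list(names(scans), codons))
  for (st in names(scans)) {
    ac <- toupper(scans[[st]]$anticodon)
    tab[st, ] <- as.integer(table(factor(ac[ac %in% codons], levels = codons)))
  }
  attr(tab, "source") <- "external_scan"
  tab
}

#' Fold change of anticodon copy number versus a reference strain
#'
#' Elementwise ratio of each strain's anticodon counts to the reference
#' (ancestral-like) strain's. Anticodons absent from both are assigned
#' fold change 1; anticodons absent from the reference but present in a
#' strain are flagged `novel` and their fold change reported as the
#' absolute copy count (anticodon-level counting absorbs novel gene
#' variants, e.g. a phage-derived tRNA pooling with the native isoacceptor,
#' into the anticodon total).
#'
#' @param table Strain x anticodon count matrix from [anticodon_counts()].
#' @param reference_strain Row name of the reference strain.
#' @return List with `fc` (numeric matrix) and `novel` (logical matrix).
#' @export
fold_change <- function(table, reference_strain) {
  if (!reference_strain %in% rownames(table))
    stop_trnaflux("missing_reference",
                  paste("reference strain not in table:", reference_strain))
  ref <- table[reference_strain, ]
  fc <- sweep(table, 2L, ref, "/")
  both_zero <- sweep(table == 0L, 2L, ref == 0L, "&")
  fc[both_zero] <- 1
  novel <- sweep(table > 0L, 2L, ref == 0L, "&")
  fc[novel] <- table[novel]
  list(fc = fc, novel = novel)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location shift between two samples. When the total
#' number of group assignments is small (min sample size at most 8 and at
#' most 2e5 assignments) the p-value is exact, by full enumeration of the
#' ways the pooled observations can be split between the groups (ties
#' handled naturally through midranks); otherwise a normal approximation
#' with tie and continuity corrections is used. U counts pairs where x
#' exceeds y (plus half the ties).
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x shifted above y) or
#'   `"less"`.
#' @return List with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  mu <- n * m / 2
  if (min(n, m) <= 8L && choose(n + m, n) <= 2e5) {
    splits <- combn(n + m, n)
    Us <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      greater = mean(Us >= U),
      less = mean(Us <= U),
      two.sided = mean(abs(Us - mu) >= abs(U - mu)))
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  ties <- table(pooled)
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  cc <- 0.5
  z <- switch(alternative,
    greater = (U - mu - cc) / sqrt(sigma2),
    less = (U - mu + cc) / sqrt(sigma2),
    two.sided = (U - mu - sign(U - mu) * cc) / sqrt(sigma2))
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(U = U, p = min(1, p), method = "normal")
}

#' Group enrichment test for anticodon fold changes
#'
#' For each anticodon, computes the mean fold change within a strain group
#' (e.g. the Shigella set); anticodons whose mean exceeds `threshold`
#' (default 2-fold) are tested against the comparison group with the
#' Mann-Whitney U test. All anticodons are reported, with a flag for the
#' threshold gate.
#'
#' @param fold_table Result of [fold_change()] (or its `fc` matrix).
#' @param group_members,others Disjoint character vectors of strain ids,
#'   each of length at least 2.
#' @param threshold Fold-change gate (default 2).
#' @param alternative Test sidedness (default `"greater"`: enrichment).
#' @return Data frame: `anticodon`, `mean_fc_group`, `mean_fc_others`,
#'   `passed_threshold`, `U`, `p` (NA when the gate is not passed).
#' @export
group_enrichment_test <- function(fold_table, group_members, others,
                                  threshold = 2, alternative = "greater") {
  fc <- if (is.list(fold_table)) fold_table$fc else fold_table
  stopifnot(all(group_members %in% rownames(fc)),
            all(others %in% rownames(fc)),
            !length(intersect(group_members, others)),
            length(group_members) >= 2L, length(others) >= 2L)
  res <- lapply(colnames(fc), function(ac) {
    g <- fc[group_members, ac]
    o <- fc[others, ac]
    passed <- mean(g) > threshold
    if (passed) {
      mw <- mann_whitney_u(g, o, alternative = alternative)
      data.frame(anticodon = ac, mean_fc_group = mean(g),
                 mean_fc_others = mean(o), passed_threshold = TRUE,
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    } else {
      data.frame(anticodon = ac, mean_fc_group = mean(g),
                 mean_fc_others = mean(o), passed_threshold = FALSE,
                 U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
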