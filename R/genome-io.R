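# Genome/feature data model and readers-writers for FASTA, GFF3, Newick
# and TSV. Internal coordinates are 0-based half-open; GFF3's 1-based
# inclusive convention is converted at the file boundary only.

FEATURE_CATEGORIES <- c("host", "sge", "trna", "lgt", "phage", "other")

#' Construct an annotated genome
#'
#' An annotated genome couples a single replicon sequence with a typed
#' feature table. Feature categories distinguish ordinary host genes,
#' selfish genetic elements (`sge`), tRNA genes (`trna`), laterally
#' transferred genes (`lgt`), phage genes (`phage`) and anything else
#' (`other`). tRNA features carry their anticodon; protein-coding features
#' whose length is not a multiple of 3 are kept but flagged unusable and
#' excluded from codon counting.
#'
#' @param strain_id Strain identifier.
#' @param sequence Single DNA string (A/C/G/T/N, any case; stored upper).
#' @param features Data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `category`, `product`,
#'   `anticodon` (NA except for tRNA features).
#' @param circular Is the replicon circular?
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(strain_id, sequence, features = empty_features(),
                             circular = TRUE) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop_trnaflux("invalid_sequence",
                  sprintf("genome '%s' contains non-ACGTN characters", strain_id))
  features <- as_feature_frame(features)
  bad <- features$start < 0L | features$end > nchar(sequence) |
    features$end <= features$start
  if (any(bad))
    stop_trnaflux("coord_error",
                  sprintf("feature(s) %s outside [0, %d] or empty",
                          paste(features$gene_id[bad], collapse = ", "),
                          nchar(sequence)))
  len <- features$end - features$start
  coding <- features$category != "trna"
  unusable <- coding & (len %% 3L != 0L)
  if (any(unusable & features$usable)) {
    warning(sprintf("%d protein-coding feature(s) with length not divisible by 3 flagged unusable: %s",
                    sum(unusable & features$usable),
                    paste(utils::head(features$gene_id[unusable & features$usable], 5),
                          collapse = ", ")))
  }
  features$usable <- features$usable & !unusable
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(strain_id = strain_id, sequence = sequence,
                 features = features, circular = isTRUE(circular)),
            class = "annotated_genome")
}

empty_features <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), category = character(),
             product = character(), anticodon = character(),
             usable = logical(), stringsAsFactors = FALSE)
}

as_feature_frame <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_features())
  need <- c("gene_id", "start", "end", "strand", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_trnaflux("bad_features", paste("missing feature columns:",
                                        paste(miss, collapse = ", ")))
  if (is.null(df$product)) df$product <- ""
  if (is.null(df$anticodon)) df$anticodon <- NA_character_
  if (is.null(df$usable)) df$usable <- TRUE
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (!all(df$strand %in% c("+", "-")))
    stop_trnaflux("bad_features", "strand must be '+' or '-'")
  if (!all(df$category %in% FEATURE_CATEGORIES))
    stop_trnaflux("bad_features",
                  paste("unknown category:",
                        paste(setdiff(df$category, FEATURE_CATEGORIES), collapse = ", ")))
  is_trna <- df$category == "trna"
  if (any(is_trna & is.na(df$anticodon)))
    stop_trnaflux("bad_features", "tRNA features must carry an anticodon")
  df$anticodon[!is_trna] <- NA_character_
  df[c("gene_id", "start", "end", "strand", "category", "product",
       "anticodon", "usable")]
}

stop_trnaflux <- function(kind, msg) {
  stop(structure(class = c(paste0("trnaflux_", kind), "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d features (%s)\n",
              x$strain_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$features),
              paste(sprintf("%s=%d", names(table(x$features$category)),
                            as.integer(table(x$features$category))),
                    collapse = " ")))
  invisible(x)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' The FASTA file must contain one record per replicon (only the single
#' replicon named by the GFF3 seqid column is used). Feature categories are
#' taken from a `category=` attribute; GFF3 `tRNA` records become category
#' `trna` and carry their `anticodon=` attribute; feature types other than
#' CDS/gene/tRNA without a category map to `other`.
#'
#' @param fasta_path Path to the FASTA sequence.
#' @param gff3_path Path to the GFF3 annotation.
#' @param strain_id Optional strain id (default: FASTA record name).
#' @return An [annotated_genome()].
#' @export
read_genome <- function(fasta_path, gff3_path, strain_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  rec_id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  feats <- read_gff3(gff3_path)
  if (nrow(feats) > 0L) {
    feats <- feats[feats$seqid == rec_id | length(seqs) == 1L, , drop = FALSE]
    feats$seqid <- NULL
  } else {
    feats$seqid <- NULL
  }
  annotated_genome(strain_id %||% rec_id, sequence, feats)
}

# Minimal GFF3 feature reader. Returns the internal feature frame plus a
# seqid column; converts 1-based inclusive to 0-based half-open.
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    out <- empty_features(); out$seqid <- character(); return(out)
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) != 9L)
    stop_trnaflux("gff_parse", sprintf("%s: expected 9 tab-separated columns", path))
  attr_get <- function(attrs, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    r <- regmatches(attrs, regexec(pat, attrs))
    vapply(r, function(z) if (length(z) == 2L) utils::URLdecode(z[2]) else NA_character_, "")
  }
  type <- m[, 3]
  category <- attr_get(m[, 9], "category")
  category[type == "tRNA"] <- "trna"
  category[is.na(category)] <- "other"
  data.frame(
    gene_id = attr_get(m[, 9], "ID"),
    start = as.integer(m[, 4]) - 1L,
    end = as.integer(m[, 5]),
    strand = m[, 7],
    category = category,
    product = ifelse(is.na(attr_get(m[, 9], "product")), "", attr_get(m[, 9], "product")),
    anticodon = attr_get(m[, 9], "anticodon"),
    seqid = m[, 1],
    stringsAsFactors = FALSE
  )
}

#' Write an annotated genome to FASTA + GFF3
#'
#' @param genome An [annotated_genome()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- genome$strain_id
  Biostrings::writeXStringSet(seq, fasta_path)
  f <- genome$features
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(f) > 0L) {
    type <- ifelse(f$category == "trna", "tRNA", "CDS")
    attrs <- paste0("ID=", f$gene_id,
                    ifelse(f$category %in% c("trna", "other"), "",
                           paste0(";category=", f$category)),
                    ifelse(nzchar(f$product), paste0(";product=", f$product), ""),
                    ifelse(is.na(f$anticodon), "", paste0(";anticodon=", f$anticodon)))
    writeLines(paste(genome$strain_id, "trnaflux", type, f$start + 1L, f$end,
                     ".", f$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(genome)
}

#' Extract coding sequences from an annotated genome
#'
#' Returns the coding DNA of every usable protein-coding feature (all
#' categories except `trna`), reverse-complementing minus-strand features.
#' Sequences with more than `max_n_frac` ambiguous bases are dropped with a
#' warning; individual N-containing codons in the survivors are skipped
#' later, at counting time.
#'
#' @param genome An [annotated_genome()].
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.1).
#' @return Named character vector `gene_id -> coding sequence`.
#' @export
extract_cds <- function(genome, max_n_frac = 0.1) {
  f <- genome$features
  f <- f[f$category != "trna" & f$usable, , drop = FALSE]
  if (nrow(f) == 0L) return(setNames(character(), character()))
  seqs <- substring(genome$sequence, f$start + 1L, f$end)
  neg <- f$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  n_frac <- vapply(gregexpr("N", seqs, fixed = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), 0L) / nchar(seqs)
  if (any(n_frac > max_n_frac)) {
    warning(sprintf("excluding %d CDS with >%g%% N content",
                    sum(n_frac > max_n_frac), 100 * max_n_frac))
    seqs <- seqs[n_frac <= max_n_frac]
    f <- f[n_frac <= max_n_frac, , drop = FALSE]
  }
  setNames(seqs, f$gene_id)
}

#' Feature sequence at a genomic interval
#'
#' @param genome An [annotated_genome()].
#' @param start,end 0-based half-open interval.
#' @param strand `+` or `-` (minus returns the reverse complement).
#' @return DNA string.
#' @export
genome_slice <- function(genome, start, end, strand = "+") {
  s <- substring(genome$sequence, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read a strain phylogeny from Newick
#'
#' Wraps [ape::read.tree()] and rejects duplicate tip labels. Trees without
#' branch lengths are accepted (downstream contrasts then default to unit
#' lengths).
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_trnaflux("tree_parse", paste("cannot parse", path))
  if (anyDuplicated(tree$tip.label))
    stop_trnaflux("tree_dup_tips", "duplicate tip labels in tree")
  tree
}

#' Write a strain phylogeny to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return Invisibly, the tree.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Write a table as UTF-8 TSV with a header row
#'
#' @param rows Data frame.
#' @param tsv_path Output path.
#' @return Invisibly, `rows`.
#' @export
write_table <- function(rows, tsv_path) {
  write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(rows)
}
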