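# Synthetic annotated strain sets with planted selfish-element codon bias,
# multi-copy tRNA genes in controlled genomic contexts, and node-specific
# LGT gene sets, with a machine-readable truth set. The generator is
# first-class, tested code: every analysis stage is validated against its
# truth output without any external download.

#' Build a codon usage table directly from relative frequencies
#'
#' @param rel Named numeric vector over the 64 codons; each amino-acid
#'   group must sum to 1 (or be all-NA).
#' @return A `codon_usage_table` with zero counts.
#' @export
usage_from_rel <- function(rel) {
  codons <- codons_all()
  stopifnot(all(codons %in% names(rel)))
  rel <- rel[codons]
  aa <- codon_to_aa()
  sums <- tapply(ifelse(is.na(rel), 0, rel), aa, sum)
  if (any(abs(sums[sums > 0] - 1) > 1e-9))
    stop_trnaflux("bad_usage", "per-amino-acid frequencies must sum to 1")
  structure(list(counts = setNames(integer(64), codons), rel = rel,
                 genetic_code = "bacterial-11"),
            class = "codon_usage_table")
}

#' Default background codon usage
#'
#' The package's default host-genome codon profile: the alanine family is
#' set to the canonical *E. coli* values (GCG 0.36, GCC 0.27, GCA 0.21,
#' GCT 0.16) and every other synonymous family is uniform. Shipped as a
#' plain-text table in `extdata` so a genome-derived profile can be
#' dropped in via [read_usage_table()].
#'
#' @return A `codon_usage_table`.
#' @export
default_background_usage <- function() {
  path <- system.file("extdata", "background_usage.tsv", package = "trnaflux")
  if (nzchar(path)) return(read_usage_table(path))
  build_default_usage()
}

build_default_usage <- function() {
  aa <- codon_to_aa()
  rel <- 1 / table(aa)[aa]
  rel <- setNames(as.numeric(rel), names(aa))
  rel[c("GCG", "GCC", "GCA", "GCT")] <- c(0.36, 0.27, 0.21, 0.16)
  usage_from_rel(rel)
}

#' Read a codon usage profile from TSV
#'
#' @param path TSV with columns `codon` and `rel`.
#' @return A `codon_usage_table`.
#' @export
read_usage_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  usage_from_rel(setNames(df$rel, df$codon))
}

#' Bias a codon usage profile toward chosen codons
#'
#' Multiplies the per-amino-acid frequency of each named codon by its
#' multiplier and renormalizes within each synonymous family, so a
#' single-codon family is unchanged and a zero-frequency codon stays zero.
#'
#' @param base A `codon_usage_table`.
#' @param bias Named numeric vector `codon -> multiplier` (> 0).
#' @return A biased `codon_usage_table`.
#' @export
#' @examples
#' b <- default_background_usage()
#' bias_usage(b, c(GCA = 4))$rel[c("GCG", "GCC", "GCA", "GCT")]
bias_usage <- function(base, bias) {
  stopifnot(inherits(base, "codon_usage_table"), all(bias > 0),
            all(names(bias) %in% codons_all()))
  rel <- base$rel
  rel[names(bias)] <- rel[names(bias)] * bias
  aa <- codon_to_aa()
  sums <- tapply(ifelse(is.na(rel), 0, rel), aa, sum)[aa]
  rel <- ifelse(sums > 0, rel / sums, rel)
  usage_from_rel(setNames(as.numeric(rel), codons_all()))
}

#' Sample coding genes from a codon usage profile
#'
#' Each gene starts with ATG and ends with a stop codon drawn from the
#' stop-group frequencies; internal codons are drawn by first picking an
#' amino acid uniformly and then a codon with the family's relative
#' frequencies. Gene length is in codons (start and stop included), so the
#' minimum length 2 gives `ATG` + stop.
#'
#' @param lengths Integer vector of gene lengths in codons (each >= 2).
#' @param usage A `codon_usage_table` (per-amino-acid normalized).
#' @return Character vector of coding sequences.
#' @export
sample_genes <- function(lengths, usage) {
  stopifnot(all(lengths >= 2L), inherits(usage, "codon_usage_table"))
  aa <- codon_to_aa()
  aas <- setdiff(unique(aa), "*")
  rel <- ifelse(is.na(usage$rel), 0, usage$rel)
  n_int <- lengths - 2L
  total <- sum(n_int)
  internal <- character(total)
  if (total > 0L) {
    draw <- sample(aas, total, replace = TRUE)
    for (a in aas) {
      idx <- which(draw == a)
      if (!length(idx)) next
      grp <- names(aa)[aa == a]
      p <- rel[grp]
      if (sum(p) == 0) p <- rep(1, length(grp))
      internal[idx] <- if (length(grp) == 1L) grp
                       else sample(grp, length(idx), replace = TRUE, prob = p)
    }
  }
  stops <- names(aa)[aa == "*"]
  p_stop <- rel[stops]
  if (sum(p_stop) == 0) p_stop <- rep(1, length(stops))
  stop_draw <- sample(stops, length(lengths), replace = TRUE, prob = p_stop)
  gene_idx <- rep.int(seq_along(lengths), n_int)
  mids <- character(length(lengths))
  if (total > 0L) {
    mid_split <- split(internal, factor(gene_idx, levels = seq_along(lengths)))
    mids <- vapply(mid_split, paste, "", collapse = "")
  }
  paste0("ATG", mids, stop_draw)
}

#' @rdname sample_genes
#' @param length_codons Single gene length in codons.
#' @export
sample_gene <- function(length_codons, usage) {
  sample_genes(length_codons, usage)
}

# Apply exactly round(divergence_pct/100 * L) substitutions at distinct
# random sites (uniform substitution model, no indels). The deterministic
# substitution count gives similarity thresholds analytic expectations:
# 4% divergence on 77 bp is exactly 3 substitutions, identity 74/77.
mutate_seq <- function(seq, divergence_pct) {
  L <- nchar(seq)
  n_sub <- round(divergence_pct / 100 * L)
  if (n_sub == 0L) return(seq)
  pos <- sample.int(L, n_sub)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Gaps between consecutive features whose flanks are both host genes;
# returns a data frame of insertable midpoints. Planting into such a gap
# subdivides it, so a gap is never reused across planting calls.
host_host_gaps <- function(genome, min_width = 40L) {
  f <- genome$features
  if (nrow(f) < 2L) return(data.frame(pos = integer(), width = integer()))
  i <- seq_len(nrow(f) - 1L)
  ok <- f$category[i] == "host" & f$category[i + 1L] == "host" &
    f$start[i + 1L] - f$end[i] >= min_width
  data.frame(pos = as.integer(floor((f$end[i] + f$start[i + 1L]) / 2))[ok],
             width = (f$start[i + 1L] - f$end[i])[ok])
}

#' Plant copies of an element into a genome
#'
#' Inserts `n` copies of a DNA element with a controlled genomic context:
#' `tandem` places all copies consecutively on the same strand within a
#' few hundred bp (identical, as within-genome duplication would leave
#' them); `phage_flanked` places each copy at a separate locus with a
#' freshly sampled phage gene immediately on both sides (the signature of
#' phage-mediated transfer) and `divergence_pct` percent of sites
#' substituted per copy; `host_flanked` places each copy between two host
#' genes. Insertion sites are gaps flanked by host genes on both sides, so
#' successive planting calls never disturb each other's contexts.
#'
#' @param genome An [annotated_genome()].
#' @param element DNA string to plant.
#' @param n Number of copies (>= 1).
#' @param context `"tandem"`, `"phage_flanked"` or `"host_flanked"`.
#' @param divergence_pct Percent of sites substituted per copy (0-50;
#'   forced to 0 for tandem copies).
#' @param id_prefix Prefix for the new feature ids.
#' @param category Feature category of the copies (`"sge"`, `"trna"`,
#'   `"lgt"`).
#' @param anticodon Anticodon attribute (tRNA copies only).
#' @param strand Strand of the planted copies.
#' @param min_separation Minimum distance between insertion sites (bp);
#'   keeps independently inserted copies from resembling a tandem array.
#' @param avoid Genomic positions (e.g. of pre-existing copies of the same
#'   element) that every insertion site must stay `min_separation` bp away
#'   from.
#' @param phage_usage Usage table for sampling flanking phage genes
#'   (default: the package default background).
#' @return List with `genome` (the augmented genome) and `placements`
#'   (data frame: `gene_id`, `start`, `end`, `strand`, `context`,
#'   `n_sub`).
#' @export
plant_copies <- function(genome, element, n, context = c("tandem",
                         "phage_flanked", "host_flanked"),
                         divergence_pct = 0, id_prefix = "copy",
                         category = "sge", anticodon = NA_character_,
                         strand = "+", min_separation = 0L,
                         avoid = integer(), phage_usage = NULL) {
  context <- match.arg(context)
  stopifnot(n >= 1L, divergence_pct >= 0, divergence_pct <= 50)
  element <- toupper(element)
  gaps <- host_host_gaps(genome)
  if (length(avoid) && min_separation > 0L) {
    far <- vapply(gaps$pos, function(p) all(abs(p - avoid) > min_separation),
                  logical(1))
    gaps <- gaps[far, , drop = FALSE]
  }
  if (nrow(gaps) == 0L)
    stop_trnaflux("no_space", "no host-flanked gap available for planting")
  feat_row <- function(id, rel_start, len) {
    data.frame(gene_id = id, start = rel_start, end = rel_start + len,
               strand = strand, category = category, product = "",
               anticodon = if (category == "trna") anticodon else NA_character_,
               usable = TRUE, stringsAsFactors = FALSE)
  }
  oriented <- function(s) if (strand == "-") revcomp(s) else s

  insertions <- list()
  if (context == "tandem") {
    pos <- gaps$pos[sample.int(nrow(gaps), 1L)]
    spacer <- 60L
    seg <- character(0); feats <- NULL; off <- 0L
    for (i in seq_len(n)) {
      seg <- c(seg, oriented(element))
      feats <- rbind(feats, feat_row(sprintf("%s_t%02d", id_prefix, i),
                                     off, nchar(element)))
      off <- off + nchar(element)
      if (i < n) { seg <- c(seg, random_spacer(spacer)); off <- off + spacer }
    }
    insertions[[1L]] <- list(pos = pos, seq = paste(seg, collapse = ""),
                             feats = feats, n_sub = rep(0L, n))
  } else {
    ord <- sample.int(nrow(gaps))
    chosen <- integer(0)
    for (g in ord) {
      if (length(chosen) == n) break
      if (!length(chosen) ||
          all(abs(gaps$pos[g] - gaps$pos[chosen]) > min_separation))
        chosen <- c(chosen, g)
    }
    if (length(chosen) < n)
      stop_trnaflux("no_space",
                    sprintf("could not place %d copies with separation %d bp", n,
                            min_separation))
    if (context == "phage_flanked" && is.null(phage_usage))
      phage_usage <- build_default_usage()
    for (i in seq_len(n)) {
      copy <- mutate_seq(element, divergence_pct)
      n_sub <- round(divergence_pct / 100 * nchar(element))
      id <- sprintf("%s_c%02d", id_prefix, i)
      if (context == "phage_flanked") {
        ph <- sample_genes(c(150L, 150L), phage_usage)
        margin <- 20L
        seqs <- c(ph[1], random_spacer(margin), oriented(copy),
                  random_spacer(margin), ph[2])
        lens <- nchar(seqs)
        offs <- cumsum(c(0L, lens))[1:5]
        feats <- rbind(
          data.frame(gene_id = paste0(id, "_phL"), start = offs[1],
                     end = offs[1] + lens[1], strand = "+",
                     category = "phage", product = "phage protein",
                     anticodon = NA_character_, usable = TRUE,
                     stringsAsFactors = FALSE),
          feat_row(id, offs[3], nchar(copy)),
          data.frame(gene_id = paste0(id, "_phR"), start = offs[5],
                     end = offs[5] + lens[5], strand = "+",
                     category = "phage", product = "phage protein",
                     anticodon = NA_character_, usable = TRUE,
                     stringsAsFactors = FALSE))
        insertions[[length(insertions) + 1L]] <-
          list(pos = gaps$pos[chosen[i]], seq = paste(seqs, collapse = ""),
               feats = feats, n_sub = n_sub)
      } else {
        insertions[[length(insertions) + 1L]] <-
          list(pos = gaps$pos[chosen[i]], seq = oriented(copy),
               feats = feat_row(id, 0L, nchar(copy)), n_sub = n_sub)
      }
    }
  }
  res <- apply_insertions(genome, insertions)
  res$placements$context <- context
  res
}

# Apply a list of insertions (all positions in the current coordinate
# system, at distinct sites) in one sequence rebuild.
apply_insertions <- function(genome, insertions) {
  pos <- vapply(insertions, `[[`, 0L, "pos")
  ord <- order(pos)
  insertions <- insertions[ord]
  pos <- pos[ord]
  seqs <- vapply(insertions, `[[`, "", "seq")
  lens <- nchar(seqs)
  shift_before <- cumsum(c(0L, lens))[seq_along(lens)]
  pieces <- character(2L * length(pos) + 1L)
  prev <- 0L
  for (i in seq_along(pos)) {
    pieces[2L * i - 1L] <- substring(genome$sequence, prev + 1L, pos[i])
    pieces[2L * i] <- seqs[i]
    prev <- pos[i]
  }
  pieces[2L * length(pos) + 1L] <- substring(genome$sequence, prev + 1L,
                                             nchar(genome$sequence))
  new_seq <- paste(pieces, collapse = "")

  f <- genome$features
  shift <- c(0L, cumsum(lens))[findInterval(f$start, pos) + 1L]
  f$start <- f$start + shift
  f$end <- f$end + shift
  placed <- NULL
  for (i in seq_along(insertions)) {
    nf <- insertions[[i]]$feats
    nf$start <- nf$start + pos[i] + shift_before[i]
    nf$end <- nf$end + pos[i] + shift_before[i]
    nf$n_sub <- insertions[[i]]$n_sub
    placed <- rbind(placed, nf)
  }
  f <- rbind(f, placed[names(f)])
  g <- annotated_genome(genome$strain_id, new_seq, f, genome$circular)
  placements <- placed[placed$category != "phage",
                       c("gene_id", "start", "end", "strand", "n_sub")]
  rownames(placements) <- NULL
  list(genome = g, placements = placements)
}
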