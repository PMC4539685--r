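# LGT node assignment from presence/absence, cumulative per-tip gene sets,
# AGA-arginine proportions, and correlation via phylogenetically
# independent contrasts (Felsenstein pruning, re-implemented).

#' Read a gene presence/absence matrix from TSV
#'
#' Rows are genes (first column gene id), columns strains, values 0/1 or
#' TRUE/FALSE.
#'
#' @param path TSV path.
#' @return Logical matrix gene x strain.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df[[1]]
  if (any(rowSums(m) == 0L))
    stop_trnaflux("empty_presence", "presence matrix has all-absent gene rows")
  m
}

#' Assign a gene's gain point to a tree node
#'
#' Under a single-gain, no-loss model, a gene present in a set of tips was
#' gained on the branch above the most recent common ancestor of those
#' tips: a gene in one tip maps to that tip's terminal node, a gene in all
#' tips to the root. Node ids use the ape numbering (tips `1..N`, internal
#' nodes `N+1..`).
#'
#' @param presence_row Logical vector named by strain, or a character
#'   vector of tips possessing the gene.
#' @param tree An [ape::phylo] tree containing those tips.
#' @return Integer node id.
#' @export
assign_gain_node <- function(presence_row, tree) {
  tips <- if (is.logical(presence_row)) names(presence_row)[presence_row]
          else as.character(presence_row)
  if (!length(tips))
    stop_trnaflux("empty_presence", "gene present in no tip")
  if (!all(tips %in% tree$tip.label))
    stop_trnaflux("unknown_tip",
                  paste("tips not in tree:",
                        paste(setdiff(tips, tree$tip.label), collapse = ", ")))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Assign every gene of a presence matrix to its gain node
#'
#' @param presence Logical matrix gene x strain (see
#'   [read_presence_matrix()]).
#' @param tree An [ape::phylo] tree.
#' @return A `node_assignment` list: `gene_node` (named integer),
#'   `node_genes` (list node id -> gene ids), `tree`.
#' @export
assign_gain_nodes <- function(presence, tree) {
  gene_node <- vapply(rownames(presence), function(g)
    assign_gain_node(presence[g, ], tree), 0L)
  node_genes <- split(names(gene_node), gene_node)
  structure(list(gene_node = gene_node, node_genes = node_genes, tree = tree),
            class = "node_assignment")
}

#' Cumulative LGT gene sets per tip
#'
#' Each tip accumulates the genes assigned to every node on its
#' root-to-tip path (a gene gained at an ancestral node is carried by all
#' descendant tips).
#'
#' @param assignments A `node_assignment` from [assign_gain_nodes()].
#' @param tree Tree (default: the one stored in `assignments`).
#' @return Named list tip -> character vector of gene ids.
#' @export
cumulative_sets <- function(assignments, tree = assignments$tree) {
  root <- length(tree$tip.label) + 1L
  sets <- lapply(seq_along(tree$tip.label), function(i) {
    path <- if (i == root) i else ape::nodepath(tree, from = root, to = i)
    out <- unlist(assignments$node_genes[as.character(path)], use.names = FALSE)
    if (is.null(out)) character(0) else out
  })
  setNames(sets, tree$tip.label)
}

#' Proportion of arginine codons encoded by AGA in a gene set
#'
#' AGA codon count divided by the total count over the six arginine codons
#' (CGT, CGC, CGA, CGG, AGA, AGG), computed over the coding sequences of
#' the gene set. Returns `NA` when the set encodes no arginine.
#'
#' @param gene_set Character vector of gene ids (empty set gives `NA`).
#' @param cds_source Named character vector `gene_id -> CDS` (as from
#'   [extract_cds()]).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
aga_arg_proportion <- function(gene_set, cds_source) {
  if (!length(gene_set)) return(NA_real_)
  seqs <- cds_source[names(cds_source) %in% gene_set]
  if (!length(seqs)) return(NA_real_)
  counts <- count_codons(seqs)
  argn <- sum(counts[arg_codons()])
  if (argn == 0) return(NA_real_)
  unname(counts["AGA"] / argn)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node of a fully
#' resolved tree the contrast is the difference between the two daughter
#' values divided by the square root of the summed daughter branch
#' lengths; the ancestral value is the branch-length-weighted average and
#' the parent branch is lengthened by the product over the sum of the
#' daughter lengths. Trees without branch lengths get unit lengths.
#' Polytomies are rejected unless `resolve_polytomies = TRUE`, which
#' resolves them arbitrarily with zero-length internal branches.
#'
#' @param tree An [ape::phylo] tree.
#' @param trait Named numeric vector of tip values.
#' @param resolve_polytomies Resolve polytomies with zero-length branches?
#' @return Numeric vector of standardized contrasts, named by internal
#'   node id.
#' @export
pic_contrasts <- function(tree, trait, resolve_polytomies = FALSE) {
  stopifnot(all(tree$tip.label %in% names(trait)))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve_polytomies)
      stop_trnaflux("polytomy",
                    "tree has polytomies; resolve them (or set resolve_polytomies = TRUE for an arbitrary zero-length resolution)")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  if (any(tree$edge.length < 0))
    stop_trnaflux("bad_branch_lengths", "negative branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  x <- c(trait[tree$tip.label], rep(NA_real_, nnode))
  bl <- numeric(ntip + nnode)
  bl[tree$edge[, 2]] <- tree$edge.length
  contrasts <- setNames(rep(NA_real_, nnode), as.character(ntip + seq_len(nnode)))
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq(1L, nrow(tr$edge), by = 2L)) {
    node <- tr$edge[i, 1]
    kids <- tr$edge[c(i, i + 1L), 2]
    b <- bl[kids]
    if (sum(b) <= 0)
      stop_trnaflux("bad_branch_lengths",
                    sprintf("zero summed daughter branch lengths at node %d", node))
    contrasts[as.character(node)] <- (x[kids[1]] - x[kids[2]]) / sqrt(sum(b))
    x[node] <- sum(x[kids] / b) / sum(1 / b)
    bl[node] <- bl[node] + prod(b) / sum(b)
  }
  contrasts
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Computes standardized contrasts for both traits on the same tree and
#' correlates them through the origin: r = sum(u v) / sqrt(sum(u^2)
#' sum(v^2)), with t = r sqrt(df) / sqrt(1 - r^2) on df = (number of
#' contrasts - 1) and a two-sided p-value. With fewer than 3 contrasts the
#' correlation is reported but p is undefined.
#'
#' @param tree An [ape::phylo] tree.
#' @param x,y Named numeric tip trait vectors.
#' @param resolve_polytomies Passed to [pic_contrasts()].
#' @return A `pic_result` list: `contrasts_x`, `contrasts_y`, `r`, `t`,
#'   `df`, `p`, `n_contrasts`.
#' @export
pic_correlation <- function(tree, x, y, resolve_polytomies = FALSE) {
  u <- pic_contrasts(tree, x, resolve_polytomies = resolve_polytomies)
  v <- pic_contrasts(tree, y, resolve_polytomies = resolve_polytomies)
  r <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  df <- length(u) - 1L
  if (length(u) < 3L) {
    return(structure(list(contrasts_x = u, contrasts_y = v, r = r,
                          t = NA_real_, df = df, p = NA_real_,
                          n_contrasts = length(u)),
                     class = "pic_result"))
  }
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), df)
  structure(list(contrasts_x = u, contrasts_y = v, r = r, t = tstat,
                 df = df, p = p, n_contrasts = length(u)),
            class = "pic_result")
}

#' @export
print.pic_result <- function(x, ...) {
  cat(sprintf("PIC correlation (through origin): r = %.4f, t = %.3f, df = %d, p = %.4g (%d contrasts)\n",
              x$r, x$t, x$df, x$p, x$n_contrasts))
  invisible(x)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Simulates one or two traits under Brownian motion along the branches;
#' with two traits the per-branch increments are bivariate normal with the
#' given correlation. Used to validate the contrasts machinery (a pair
#' simulated at correlation rho should be recovered by
#' [pic_correlation()], and independent traits should show no
#' correlation).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param correlation Increment correlation between the two traits.
#' @param sd Increment standard deviation per unit branch length.
#' @return List with tip-value vectors `x` and `y`.
#' @export
sim_bm_traits <- function(tree, correlation = 0, sd = 1) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  x <- numeric(nn); y <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    s <- sd * sqrt(tr$edge.length[i])
    z1 <- rnorm(1); z2 <- rnorm(1)
    x[child] <- x[par] + s * z1
    y[child] <- y[par] + s * (correlation * z1 + sqrt(1 - correlation^2) * z2)
  }
  list(x = setNames(x[seq_len(ntip)], tree$tip.label),
       y = setNames(y[seq_len(ntip)], tree$tip.label))
}
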