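test_that("gain nodes are the MRCA of the possessing tips", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  ntip <- 5L
  expect_equal(assign_gain_node(c(A = TRUE, B = FALSE, C = FALSE,
                                  D = FALSE, E = FALSE), tr),
               match("A", tr$tip.label))
  all_tips <- setNames(rep(TRUE, 5), tr$tip.label)
  expect_equal(assign_gain_node(all_tips, tr), ntip + 1L)  # root
  expect_equal(assign_gain_node(c("A", "B"), tr), ape::getMRCA(tr, c("A", "B")))
  expect_error(assign_gain_node(c("A", "ZZ"), tr), class = "trnaflux_unknown_tip")
  expect_error(assign_gain_node(character(), tr), class = "trnaflux_empty_presence")
})

test_that("MRCA placement agrees with exhaustive single-gain parsimony", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  ntip <- length(tr$tip.label)
  # oracle: the gain node is the node with the fewest descendant tips whose
  # clade still covers every possessing tip
  desc_tips <- lapply(seq_len(ntip + tr$Nnode), function(nd) {
    if (nd <= ntip) tr$tip.label[nd]
    else tr$tip.label[ape::prop.part(tr)[[nd - ntip]]]
  })
  set.seed(71)
  for (rep in 1:40) {
    pres <- tr$tip.label[sample(ntip, sample(ntip, 1))]
    covering <- which(vapply(desc_tips, function(d) all(pres %in% d), TRUE))
    oracle <- covering[which.min(lengths(desc_tips)[covering])]
    expect_equal(assign_gain_node(pres, tr), oracle)
  }
})

test_that("cumulative sets union genes along the root-to-tip path", {
  tr <- ape::read.tree(text = "(A:1,(B:1,(C:1,D:1):1):1);")
  pres <- rbind(g_root = c(A = TRUE, B = TRUE, C = TRUE, D = TRUE),
                g_bcd = c(A = FALSE, B = TRUE, C = TRUE, D = TRUE),
                g_cd = c(A = FALSE, B = FALSE, C = TRUE, D = TRUE),
                g_d = c(A = FALSE, B = FALSE, C = FALSE, D = TRUE))
  asg <- assign_gain_nodes(pres, tr)
  sets <- cumulative_sets(asg)
  expect_setequal(sets$A, "g_root")
  expect_setequal(sets$B, c("g_root", "g_bcd"))
  expect_setequal(sets$C, c("g_root", "g_bcd", "g_cd"))
  expect_setequal(sets$D, c("g_root", "g_bcd", "g_cd", "g_d"))
  expect_equal(length(sets$D), sum(lengths(asg$node_genes)) -
                 length(sets$C) + 3L)  # nested accumulation
})

test_that("simulated gains are recovered exactly from presence/absence", {
  sim <- tiny_sim()
  pres <- lgt_presence_from_genomes(sim$genomes)
  asg <- assign_gain_nodes(pres, sim$tree)
  sets <- cumulative_sets(asg)
  truth <- sim$truth$lgt
  for (st in sim$tree$tip.label) {
    want <- truth$gene_id[vapply(strsplit(truth$clade, ","), function(cl)
      st %in% cl, TRUE)]
    expect_setequal(sets[[st]], want)
  }
})

test_that("AGA arginine proportions follow the definition", {
  # a set whose only arginines are AGA
  cds <- c(g1 = "ATGAGAAGATAA")
  expect_equal(aga_arg_proportion("g1", cds), 1)
  # 3 AGA among 100 arginine codons -> 0.03
  set.seed(81)
  arg <- c(rep("AGA", 3), sample(c("CGT", "CGC", "CGA", "CGG", "AGG"),
                                 97, replace = TRUE))
  cds2 <- c(big = paste0("ATG", paste(sample(arg), collapse = ""), "TAA"))
  expect_equal(aga_arg_proportion("big", cds2), 0.03)
  # no arginine at all is undefined
  expect_true(is.na(aga_arg_proportion("g1", c(g1 = "ATGAAATAA"))))
  expect_true(is.na(aga_arg_proportion(character(), cds)))
})

test_that("planted AGA bias yields monotone proportions along nested gains", {
  sim <- tiny_sim()
  cds <- extract_cds(sim$genomes$S3)
  truth <- sim$truth$lgt
  p1 <- aga_arg_proportion(truth$gene_id[truth$label == "g1"], cds)
  p2 <- aga_arg_proportion(truth$gene_id[truth$label == "g2"], cds)
  expect_lt(p1, p2)  # AGA bias 3x then 6x
})

test_that("independent contrasts match ape and hand-worked cases", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(abs(unname(pic_contrasts(tr2, c(A = 1, B = 3)))),
               2 / sqrt(2), tolerance = 1e-12)
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 1, B = 3, C = 2, D = 8)
  u <- pic_contrasts(tr4, x)
  # hand-worked pruning: cherries (1-3)/sqrt(2), (2-8)/sqrt(2); ancestors
  # at 2 and 5 on branches 1 + 1/2; root contrast (2-5)/sqrt(3)
  expect_equal(sort(abs(unname(u))),
               sort(abs(c(-2 / sqrt(2), -6 / sqrt(2), -3 / sqrt(3)))),
               tolerance = 1e-12)
  expect_equal(unname(pic_contrasts(tr4, c(A = 2, B = 2, C = 2, D = 2))),
               rep(0, 3))
  set.seed(91)
  for (n in c(8, 16, 32)) {
    tr <- ape::rtree(n)
    y <- setNames(rnorm(n), tr$tip.label)
    mine <- pic_contrasts(tr, y)
    theirs <- ape::pic(y[tr$tip.label], tr)
    expect_equal(abs(unname(mine[names(theirs)])), abs(unname(theirs)),
                 tolerance = 1e-9)
  }
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(pic_contrasts(star, c(A = 1, B = 2, C = 3)),
               class = "trnaflux_polytomy")
  expect_length(pic_contrasts(star, c(A = 1, B = 2, C = 3),
                              resolve_polytomies = TRUE), 2L)
})

test_that("PIC correlation is exact for linear traits and star trees", {
  set.seed(92)
  tr <- ape::rtree(16)
  x <- setNames(rnorm(16), tr$tip.label)
  res <- pic_correlation(tr, x, 2 * x)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, 14L)
  # a star tree with equal branch lengths reproduces Pearson correlation
  star <- ape::read.tree(text = paste0("(", paste(sprintf("t%d:1", 1:12),
                                                  collapse = ","), ");"))
  y1 <- setNames(rnorm(12), star$tip.label)
  y2 <- setNames(rnorm(12), star$tip.label)
  res2 <- pic_correlation(star, y1, y2, resolve_polytomies = TRUE)
  expect_equal(res2$r, cor(y1, y2), tolerance = 1e-9)
  # two tips: r reported, p undefined
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  res3 <- pic_correlation(tr2, c(A = 1, B = 2), c(A = 5, B = 1))
  expect_true(is.na(res3$p))
})

test_that("correlated Brownian traits are recovered without bias", {
  set.seed(93)
  tr <- ape::rtree(32)
  rs <- replicate(30, {
    tv <- sim_bm_traits(tr, correlation = 0.9)
    pic_correlation(tr, tv$x, tv$y)$r
  })
  expect_lt(abs(mean(rs) - 0.9), 0.1)
})
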