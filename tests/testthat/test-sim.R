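test_that("species tree models carry the study parameter values", {
  m <- build_species_tree(1, "high")
  expect_identical(canonical_newick(m$phy, lengths = FALSE), "(((A,B),C),D);")
  expect_setequal(m$tau[m$tau > 0], c(0.01, 0.02, 0.03))
  expect_true(all(m$theta == 0.02))

  m2 <- build_species_tree(2, "low")
  expect_identical(canonical_newick(m2$phy, lengths = FALSE), "((A,B),(C,D));")
  expect_equal(sort(m2$tau[m2$tau > 0]), c(0.001, 0.001, 0.003))
  expect_true(all(m2$theta == 0.002))

  m3 <- build_species_tree(1, "low")
  expect_gt(max(m3$tau), max(m3$tau[-which.max(m3$tau)]))  # root is oldest
  expect_error(build_species_tree(3, "low"), "unknown tree id")
})

test_that("locus rescaling applies the mito multipliers exactly once", {
  m <- build_species_tree(1, "low")
  expect_identical(scale_to_locus(m, locus_spec("nuclear"))$tau, m$tau)
  mt <- scale_to_locus(m, locus_spec("mitochondrial"))
  expect_equal(max(mt$tau), 0.06)    # 0.003 * 20
  expect_equal(mt$theta[1], 0.01)    # 0.002 * 5
  expect_error(scale_to_locus(mt, locus_spec("mitochondrial")),
               "already scaled")
  expect_equal(locus_spec("mitochondrial")$length, 1000L)
  expect_equal(locus_spec("nuclear")$length, 500L)
})

test_that("two-lineage TMRCA matches Exponential(2/theta) by moments and KS", {
  set.seed(11)
  theta <- 0.01
  single <- structure(list(
    phy = clock_tree(parse_newick("(A:1,B:1);"), c(0, 0, 100)),
    tau = c(0, 0, 100), theta = rep(theta, 3), scaled = FALSE),
    class = "species_tree_model")
  ## two sequences from population A only: their TMRCA is the first (and,
  ## below tau, only possible) coalescence
  draws <- replicate(10000, {
    gt <- sim_gene_tree(single, c(A = 2, B = 1))
    ages <- sort(node_ages(gt$phy))
    ages[ages > 0][1]
  })
  within <- draws[draws < 100]
  se <- (theta / 2) / sqrt(length(within))
  expect_lt(abs(mean(within) - theta / 2), 3 * se)
  ks <- suppressWarnings(stats::ks.test(within, stats::pexp,
                                        rate = 2 / theta))
  expect_gt(ks$p.value, 0.01)
})

test_that("cross-species coalescences never predate the divergence", {
  set.seed(12)
  m <- build_species_tree(1, "high")
  for (i in 1:50) {
    gt <- sim_gene_tree(m, c(A = 3, B = 3, C = 3, D = 3))
    ages <- node_ages(gt$phy)
    cl <- tree_clades_all(gt$phy)
    for (v in (ape::Ntip(gt$phy) + 1L):length(cl)) {
      pops <- unique(gt$pop[cl[[v]]])
      if (all(c("A", "B") %in% pops)) expect_gte(ages[v], 0.01)
      if (all(c("A", "D") %in% pops)) expect_gte(ages[v], 0.03)
    }
    ## and the full density is finite (compatibility invariant)
    expect_true(is.finite(msc_logdensity(gt, m)))
  }
})

test_that("vanishing ancestral theta removes incomplete lineage sorting", {
  set.seed(13)
  m <- build_species_tree(1, "high")
  ntips <- ape::Ntip(m$phy)
  m$theta[(ntips + 1):length(m$theta)] <- 1e-9  # ancestral branches only
  hits <- replicate(100, {
    gt <- sim_gene_tree(m, c(A = 1, B = 1, C = 1, D = 1))
    tr <- gt$phy
    tr$tip.label <- sub("_1$", "", tr$tip.label)
    identical(canonical_newick(tr, lengths = FALSE), "(((A,B),C),D);")
  })
  expect_equal(mean(hits), 1)
})

test_that("JC69 sequence simulation matches the divergence formula", {
  set.seed(14)
  ## near-zero branch lengths give (essentially) identical sequences
  flat <- sim_alignment(clock_tree(parse_newick("(A:1,B:1);"),
                                   c(0, 0, 1e-12)), 2000)
  expect_true(all(flat[1, ] == flat[2, ]))
  ## 2-tip clock tree at divergence d
  d <- 0.03  # per-branch, total separation 0.06
  gphy <- clock_tree(parse_newick("(x:1,y:1);"), c(0, 0, d))
  aln <- sim_alignment(gphy, 100000)
  p <- mean(aln[1, ] != aln[2, ])
  expected <- 0.75 * (1 - exp(-4 * (2 * d) / 3))
  se <- sqrt(expected * (1 - expected) / 100000)
  expect_lt(abs(p - expected), 3 * se)
  ## base composition near uniform
  comp <- table(aln) / length(aln)
  expect_true(all(abs(comp - 0.25) < 0.01))
})

test_that("expected A-B divergence reflects 2*tau_AB + theta", {
  set.seed(15)
  m <- build_species_tree(1, "high")  # tau_AB = 0.01, theta = 0.02
  diffs <- replicate(60, {
    gt <- sim_gene_tree(m, c(A = 1, B = 1, C = 1, D = 1))
    aln <- sim_alignment(gt, 500)
    p <- mean(aln["A_1", ] != aln["B_1", ])
    -0.75 * log(1 - 4 * p / 3)       # saturation-corrected distance
  })
  expect_lt(abs(mean(diffs) - 0.04), 3 * stats::sd(diffs) / sqrt(60))
})

test_that("replicate datasets have the study dimensions and are reproducible", {
  set.seed(16)
  r3 <- sim_replicate(replicate_config(1, "low", 3, 1))
  expect_equal(dim(r3$mito$aln), c(24, 1000))
  expect_equal(dim(r3$nuclear[[1]]$aln), c(24, 500))
  expect_equal(length(r3$nuclear), 1)
  expect_true(all(table(r3$popmap) == 3))
  expect_setequal(unique(r3$popmap),
                  c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"))

  r5 <- sim_replicate(replicate_config(2, "high", 5, 5))
  expect_equal(dim(r5$mito$aln), c(40, 1000))
  expect_equal(dim(r5$nuclear[[3]]$aln), c(40, 500))
  expect_equal(length(r5$nuclear), 5)

  set.seed(123); a <- sim_replicate(replicate_config(1, "low", 3, 1))
  set.seed(123); b <- sim_replicate(replicate_config(1, "low", 3, 1))
  expect_identical(a$mito$aln, b$mito$aln)
  expect_identical(write_newick(a$nuclear[[1]]$gtree$phy),
                   write_newick(b$nuclear[[1]]$gtree$phy))
  expect_identical(a$popmap, b$popmap)
})
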