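test_that("constrained ML guide trees keep populations monophyletic", {
  set.seed(23)
  rep <- sim_replicate(replicate_config(1, "high", 3, 1))
  g <- ml_guide_tree(rep$mito$aln, rep$popmap)
  expect_setequal(g$tip.label, unique(rep$popmap))
  expect_equal(ape::Ntip(g), 8)
  seqtree <- attr(g, "seq_tree")
  keys <- names(tree_clades(seqtree))
  for (p in unique(rep$popmap)) {
    tips <- names(rep$popmap)[rep$popmap == p]
    expect_true(paste(sort(tips), collapse = "|") %in% keys)
  }
  ## deterministic given the data
  g2 <- ml_guide_tree(rep$mito$aln, rep$popmap)
  expect_identical(write_newick(g), write_newick(g2))
})

test_that("two populations give the single possible rooted topology", {
  set.seed(24)
  m <- build_species_tree(1, "high")
  gt <- sim_gene_tree(m, c(A = 6, B = 1, C = 1, D = 1))
  aln <- sim_alignment(gt, 600)
  aln <- aln[grep("^A_", rownames(aln)), ]
  popmap <- setNames(rep(c("P1", "P2"), each = 3), rownames(aln))
  g <- ml_guide_tree(aln, popmap)
  expect_identical(canonical_newick(g, lengths = FALSE), "(P1,P2);")
  expect_error(ml_guide_tree(aln, setNames(rep("P1", 6), rownames(aln))),
               "2 populations")
})

test_that("ML search recovers deep divergences consistently", {
  set.seed(25)
  hits <- 0
  n <- 12
  for (i in seq_len(n)) {
    rep <- sim_replicate(replicate_config(1, "high", 3, 1))
    g <- ml_guide_tree(rep$mito$aln, rep$popmap)
    rec <- clade_recovery(true_guide_tree(1), list(g))
    hits <- hits + all(rec[c("A1|A2", "B1|B2", "C1|C2", "D1|D2",
                             "A1|A2|B1|B2")] == 1)
  }
  ## the well-separated clades are recovered essentially always
  expect_gte(hits / n, 0.9)
})

test_that("species-tree MCMC samples the Yule topology prior when data are off", {
  set.seed(26)
  m <- build_species_tree(1, "high")
  gt <- sim_gene_tree(m, c(A = 2, B = 2, C = 2, D = 2))
  aln <- sim_alignment(gt, 60)
  popmap <- setNames(sub("_[0-9]+$", "", rownames(aln)), rownames(aln))
  ## proper truncated priors (root age bounded) make the sampled prior a
  ## genuine distribution; without data the topology law is the Yule one
  fit <- species_tree_mcmc(list(aln), popmap, n_iter = 1e7,
                           sample_every = 200, likelihood_off = TRUE,
                           root_age_bound = 0.1)
  keys <- vapply(seq_len(fit$n_samples), function(i)
    coaldelim:::.canon_key_parents(fit$par[i, ], fit$populations), "")
  tab <- table(keys)
  expect_equal(length(tab), 15)  # all rooted 4-tip topologies visited
  freq <- as.numeric(tab) / sum(tab)
  ## uniform over labeled histories: balanced shapes 2/18, caterpillars 1/18
  balanced <- grepl("^\\(\\([A-D],[A-D]\\),\\([A-D],[A-D]\\)\\);$", names(tab))
  expect_equal(sum(balanced), 3)
  ## class means are tight; individual topologies get an autocorrelation-
  ## aware band (the chain visits topologies in correlated stretches)
  expect_lt(abs(mean(freq[balanced]) - 2 / 18), 0.012)
  expect_lt(abs(mean(freq[!balanced]) - 1 / 18), 0.008)
  expect_true(all(abs(freq[balanced] - 2 / 18) < 0.03))
  expect_true(all(abs(freq[!balanced] - 1 / 18) < 0.03))
})

test_that("species-tree MCMC is deterministic given the seed", {
  set.seed(27)
  rep <- sim_replicate(replicate_config(1, "high", 3, 1))
  alns <- lapply(rep$nuclear, `[[`, "aln")
  set.seed(1); f1 <- species_tree_mcmc(alns, rep$popmap, n_iter = 2e4)
  set.seed(1); f2 <- species_tree_mcmc(alns, rep$popmap, n_iter = 2e4)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$tau, f2$tau)
  m1 <- map_guide_tree(f1, keep_last = floor(f1$n_samples * 2200 / 3000))
  m2 <- map_guide_tree(f2, keep_last = floor(f2$n_samples * 2200 / 3000))
  expect_identical(write_newick(m1), write_newick(m2))
})

test_that("MAP extraction honours keep_last and sampled-state validity", {
  set.seed(28)
  rep <- sim_replicate(replicate_config(1, "high", 3, 1))
  fit <- species_tree_mcmc(lapply(rep$nuclear, `[[`, "aln"), rep$popmap,
                           n_iter = 1e5)
  expect_error(map_guide_tree(fit, keep_last = fit$n_samples + 1),
               "keep_last")
  map <- map_guide_tree(fit, keep_last = floor(fit$n_samples * 2200 / 3000))
  expect_setequal(map$tip.label, fit$populations)
  ages <- node_ages(map)
  expect_true(all(ages[map$edge[, 1]] > ages[map$edge[, 2]]))
  ## every sampled species tree is a valid clock tree over the populations
  for (i in seq(1, fit$n_samples, length.out = 25)) {
    tr <- sptree_samples(fit, round(i))[[1]]
    expect_setequal(tr$tip.label, fit$populations)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("recovery of the MAP topology improves with divergence depth", {
  set.seed(29)
  scales <- c(1, 4, 16)
  recs <- vapply(scales, function(sc) {
    hits <- 0
    for (i in 1:8) {
      m <- build_species_tree(1, "low")
      m$tau <- m$tau * sc
      m$phy <- clock_tree(m$phy, m$tau)
      gt <- sim_gene_tree(m, c(A = 2, B = 2, C = 2, D = 2))
      aln <- sim_alignment(gt, 500)
      popmap <- setNames(sub("_[0-9]+$", "", rownames(aln)), rownames(aln))
      fit <- species_tree_mcmc(list(aln), popmap, n_iter = 2e5)
      map <- map_guide_tree(fit, keep_last = floor(fit$n_samples * 2200 / 3000))
      hits <- hits + identical(canonical_newick(map, lengths = FALSE),
                               "(((A,B),C),D);")
    }
    hits / 8
  }, 0)
  expect_true(recs[3] >= recs[1])  # deeper divergence, easier recovery
})
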