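test_that("pair posteriors map to the MRCA split node, also on wrong guides", {
  guide <- parse_newick("((A1,A2),B1);")
  probs <- setNames(c(0.25, 0.95), names(tree_clades(guide)))
  ## sorted: clade keys are A1|A2|B1 (root) and A1|A2
  expect_equal(pair_split_posterior(probs, c("A1", "A2"), guide),
               unname(probs["A1|A2"]))
  ## pair spanning the root maps to the root node
  expect_equal(pair_split_posterior(probs, c("A1", "B1"), guide),
               unname(probs["A1|A2|B1"]))
  ## wrong guide where A1 and A2 are not sisters: the split separating them
  ## is a deeper node (the node-11 rule)
  wrong <- parse_newick("((A1,B1),(A2,B2));")
  wp <- setNames(c(0.7, 0.2, 0.4), names(tree_clades(wrong)))
  expect_equal(pair_split_posterior(wp, c("A1", "A2"), wrong),
               unname(wp["A1|A2|B1|B2"]))
  expect_error(pair_split_posterior(wp, c("A1", "ZZ"), wrong), "ZZ")
})

test_that("false-positive rates follow the 95% threshold rule", {
  expect_equal(false_positive_rate(c(0.96, 0.30)), 0.5)
  expect_equal(false_positive_rate(c(0.1, 0.5, 0.9)), 0)
  expect_equal(false_positive_rate(c(0.1, 0.5, 0.9), threshold = 0), 1)
  m <- cbind(A1A2 = c(0.99, 0.01), B1B2 = c(0.2, 0.96))
  expect_equal(unname(false_positive_rate(m)), c(0.5, 0.5))
  expect_error(false_positive_rate(numeric(0)), "no replicates")
})

test_that("histograms use 0.05 bins with a closed last bin", {
  h <- posterior_histogram(c(1.0, 0.975, 0.94, 0.0, 0.049))
  expect_equal(sum(h), 5)
  expect_equal(unname(h[20]), 2)   # 1.0 and 0.975 in [0.95, 1]
  expect_equal(unname(h[1]), 2)    # 0 and 0.049 in [0, 0.05)
  expect_equal(unname(h[19]), 1)
  set.seed(38)
  p <- runif(500)
  expect_equal(unname(posterior_histogram(p)[20]) / 500,
               false_positive_rate(p, 0.95))
})

test_that("study summaries use the documented quantile rule and round-trip", {
  recs <- lapply(1:4, function(i) list(
    pair_post = matrix(c(0.1, 0.2, 0.3, 0.4)[i], 1, 1,
                       dimnames = list(NULL, "A1A2")),
    clade_post = c("A1|A2|B1|B2" = c(0.9, 0.95, 1, 1)[i]),
    guide_correct = c("A1|A2|B1|B2" = TRUE)))
  s <- summarize_study(recs)
  expect_equal(unname(s$pair_quartiles["A1A2", "median"]), 0.25)
  expect_equal(unname(s$clade_quartiles[1, "median"]), 0.975)
  expect_equal(unname(s$false_positive["A1A2"]), 0)
  expect_equal(sum(s$histograms[, "A1A2"]), 4)

  ## persistence: records written to JSON and reloaded give the same summary
  f <- tempfile(fileext = ".json")
  flat <- lapply(recs, function(r) list(pair = unname(r$pair_post[1, 1]),
                                        clade = unname(r$clade_post),
                                        correct = unname(r$guide_correct)))
  jsonlite::write_json(flat, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = FALSE)
  recs2 <- lapply(back, function(r) list(
    pair_post = matrix(r$pair, 1, 1, dimnames = list(NULL, "A1A2")),
    clade_post = c("A1|A2|B1|B2" = r$clade),
    guide_correct = c("A1|A2|B1|B2" = r$correct)))
  s2 <- summarize_study(recs2)
  expect_equal(s2$pair_quartiles, s$pair_quartiles)
  expect_equal(s2$false_positive, s$false_positive)
})

test_that("study configurations enumerate and validate", {
  expect_error(study_config(n_replicates = 0), "at least one replicate")
  grid <- expand.grid(tree = 1:2, rate = c("low", "high"), n = c(3L, 5L))
  cfgs <- lapply(seq_len(nrow(grid)), function(i)
    study_config(grid$tree[i], as.character(grid$rate[i]), grid$n[i]))
  expect_equal(length(cfgs), 8)  # the study's eight parameter combinations
})

test_that("studies are reproducible and robust to replicate order", {
  cfg <- study_config(1, "high", 3, 1, guide_arm = "ml", n_replicates = 3,
                      delimit = FALSE)
  r1 <- run_study(cfg, master_seed = 5)
  r2 <- run_study(cfg, master_seed = 5)
  expect_identical(lapply(r1$records, `[[`, "guide"),
                   lapply(r2$records, `[[`, "guide"))
  ## per-replicate seeds are recorded so any replicate re-runs on its own
  rec <- r1$records[[2]]
  set.seed(rec$seed)
  rep <- sim_replicate(replicate_config(1, "high", 3, 1))
  g <- ml_guide_tree(rep$mito$aln, rep$popmap)
  expect_identical(write_newick(g), rec$guide)
  ## summaries are invariant under reordering of the records
  recs <- lapply(1:4, function(i) list(
    pair_post = matrix(runif(1), 1, 1, dimnames = list(NULL, "A1A2")),
    clade_post = c("A1|A2" = runif(1)),
    guide_correct = c("A1|A2" = i %% 2 == 0)))
  s1 <- summarize_study(recs)
  s2 <- summarize_study(rev(recs))
  expect_equal(s1$false_positive, s2$false_positive)
  expect_equal(s1$pair_quartiles, s2$pair_quartiles)
  expect_equal(s1$guide_recovery, s2$guide_recovery)
})
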