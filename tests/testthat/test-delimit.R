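test_that("model enumeration matches the recursion and brute force", {
  g2 <- parse_newick("(X,Y);")
  expect_equal(nrow(enumerate_models(g2)), 2)
  expect_equal(n_delim_models(g2), 2)

  g1 <- true_guide_tree(1)   # nested cherries, caterpillar backbone
  gb <- true_guide_tree(2)   # four cherries, balanced backbone
  expect_equal(n_delim_models(g1), 23)
  expect_equal(n_delim_models(gb), 26)
  expect_equal(nrow(enumerate_models(g1)), 23)
  expect_equal(nrow(enumerate_models(gb)), 26)
  expect_equal(brute_models(g1), 23)
  expect_equal(brute_models(gb), 26)

  set.seed(30)
  for (i in 1:5) {
    g <- ape::rtree(sample(3:6, 1))
    m <- enumerate_models(g)
    expect_equal(nrow(m), n_delim_models(g))
    expect_equal(nrow(m), brute_models(g))
    expect_equal(anyDuplicated(apply(m, 1, paste, collapse = "")), 0)
    ## ancestor closure of every enumerated model
    par <- coaldelim:::.guide_parent(g)
    ntip <- ape::Ntip(g)
    root <- ntip + 1L
    for (r in seq_len(nrow(m))) {
      for (j in which(m[r, ])) {
        v <- ntip + j
        if (v != root) expect_true(m[r, par[v] - ntip])
      }
    }
  }
})

test_that("split proposals respect bounds and reverse exactly", {
  set.seed(31)
  guide <- parse_newick("((X,Y),Z);")
  prior <- delim_prior("low")
  ## gene tree over one sequence per population, with a known cross age
  gphy <- clock_tree(parse_newick("((X_1:1,Y_1:1):1,Z_1:2);"),
                     c(0, 0, 0, 0.004, 0.002))
  gt <- structure(list(phy = gphy, age = c(0, 0, 0, 0.004, 0.002),
                       pop = c(X_1 = "X", Y_1 = "Y", Z_1 = "Z")),
                  class = "gene_tree")
  st <- delim_state(guide, split = c(TRUE, FALSE),
                    tau = c(0, 0, 0, 0.003, 0),
                    theta = c(NA, NA, 0.002, 0.002, 0.002),
                    gene_trees = list(gt))
  ## splitting the cherry node (5): U = min(parent tau 0.003, X-Y cross
  ## coalescence age 0.002)
  for (i in 1:20) {
    prop <- propose_split(st, 5, prior)
    expect_equal(prop$U, 0.002)
    expect_lt(prop$state$tau[5], st$tau[4])      # below the parent tau
    expect_gt(prop$state$tau[5], 0)
    ## merge restores the original state exactly
    back <- propose_merge(prop$state, 5)
    expect_identical(back$split, st$split)
    expect_identical(back$tau, st$tau)
    expect_identical(back$theta, st$theta)
  }
  ## immediate cross-coalescence: U = 0 forces rejection
  gt0 <- gt
  gt0$phy <- clock_tree(gphy, c(0, 0, 0, 0.004, 0))
  gt0$age <- c(0, 0, 0, 0.004, 0)
  st0 <- st; st0$gene_trees <- list(gt0)
  expect_true(isTRUE(propose_split(st0, 5, prior)$rejected))
  expect_error(propose_split(st, 4, prior), "already split")
})

test_that("split acceptance components reduce to hand computation when the
           likelihood is off (2-population guide)", {
  set.seed(32)
  guide <- parse_newick("(X,Y);")
  prior <- delim_prior("low")
  gphy <- clock_tree(parse_newick("(X_1:1,Y_1:1);"), c(0, 0, 0.005))
  gt <- structure(list(phy = gphy, age = c(0, 0, 0.005),
                       pop = c(X_1 = "X", Y_1 = "Y")), class = "gene_tree")
  st <- delim_state(guide, split = FALSE, tau = c(0, 0, 0),
                    theta = c(NA, NA, 0.002), gene_trees = list(gt))
  prop <- propose_split(st, 3, prior)
  expect_equal(prop$U, 0.005)
  ## prior component by hand: tau0 gamma density appears; theta priors of the
  ## two fresh draws cancel against the proposal; the model mass is uniform
  ## so its ratio vanishes
  tau0 <- prop$state$tau[3]
  expect_equal(unname(prop$log_components["prior"]),
               dgamma(tau0, prior$tau_shape, rate = prior$tau_rate,
                      log = TRUE))
  expect_equal(unname(prop$log_components["proposal"]), log(0.005))
})

test_that("likelihood-off delimitation recovers the uniform model prior", {
  set.seed(33)
  aln <- toy_alignment(c("X_1", "Y_1"), nsites = 50)
  popmap <- setNames(c("X", "Y"), rownames(aln))
  guide <- parse_newick("(X,Y);")
  fit <- delimit(list(aln), guide, popmap, prior = delim_prior("low"),
                 control = delim_control(burnin = 2000, nsamples = 15000,
                                         sample_every = 1, runs = 2),
                 likelihood_off = TRUE, check_states = TRUE)
  expect_lt(abs(fit$split_prob["X|Y"] - 0.5), 0.02)
})

test_that("runs pool by concatenation and split probabilities are averages", {
  set.seed(34)
  rep <- sim_replicate(replicate_config(1, "high", 3, 1))
  fit <- delimit(lapply(rep$nuclear, `[[`, "aln"), true_guide_tree(1),
                 rep$popmap, prior = delim_prior("high"),
                 control = delim_control(burnin = 300, nsamples = 500,
                                         sample_every = 1, runs = 2))
  pooled <- rowMeans(fit$per_run)
  expect_equal(unname(fit$split_prob), unname(pooled), tolerance = 1e-12)
  expect_equal(fit$n_samples, 1000)
  expect_true(all(fit$split_prob >= 0 & fit$split_prob <= 1))
  expect_equal(sum(fit$model_post), 1)
  ## determinism
  set.seed(7)
  f1 <- delimit(lapply(rep$nuclear, `[[`, "aln"), true_guide_tree(1),
                rep$popmap, control = delim_control(burnin = 100,
                                                    nsamples = 200,
                                                    sample_every = 1,
                                                    runs = 1))
  set.seed(7)
  f2 <- delimit(lapply(rep$nuclear, `[[`, "aln"), true_guide_tree(1),
                rep$popmap, control = delim_control(burnin = 100,
                                                    nsamples = 200,
                                                    sample_every = 1,
                                                    runs = 1))
  expect_identical(f1$split_prob, f2$split_prob)
  expect_identical(f1$tau0, f2$tau0)
})

test_that("sampled states pass the debug validity assertions", {
  set.seed(35)
  rep <- sim_replicate(replicate_config(1, "low", 3, 1))
  expect_no_error(
    delimit(lapply(rep$nuclear, `[[`, "aln"), true_guide_tree(1),
            rep$popmap, prior = delim_prior("low"),
            control = delim_control(burnin = 200, nsamples = 400,
                                    sample_every = 1, runs = 1),
            check_states = TRUE))
})

test_that("auto-tuned moves land in a sane acceptance window", {
  set.seed(36)
  rep <- sim_replicate(replicate_config(1, "low", 3, 1))
  fit <- delimit(lapply(rep$nuclear, `[[`, "aln"), true_guide_tree(1),
                 rep$popmap, prior = delim_prior("low"),
                 control = delim_control(burnin = 1500, nsamples = 2500,
                                         sample_every = 1, runs = 1))
  expect_gt(fit$acc$scale[1], 0.1)
  expect_lt(fit$acc$scale[1], 0.9)
  expect_gt(fit$acc$theta[1], 0.1)
  expect_lt(fit$acc$theta[1], 0.9)
})

test_that("the quadrature oracle behaves at its edges", {
  prior <- delim_prior("high")
  aln <- toy_alignment(c("X_1", "Y_1", "Z_1", "W_1", "V_1"), nsites = 10)
  popmap <- setNames(c("X", "Y", "Z", "W", "V"), rownames(aln))
  expect_error(oracle_model_posterior(aln, ape::rtree(5), popmap, prior),
               "too large")
  ## single population: the one-species model gets probability 1
  one <- oracle_model_posterior(toy_alignment("X_1", 10),
                                structure(list(edge = matrix(0, 0, 2),
                                               tip.label = "X",
                                               Nnode = 0L), class = "phylo"),
                                c(X_1 = "X"), prior)
  expect_equal(unname(one["(none)"]), 1)
})

test_that("strongly divergent populations are split with high probability", {
  set.seed(37)
  ## tau ten times theta and 500 sites: the within-population pair pins theta
  ## low, so the one-species model cannot explain the deep X-Y divergence
  sp <- structure(list(
    phy = clock_tree(parse_newick("(X:1,Y:1);"), c(0, 0, 0.05)),
    tau = c(0, 0, 0.05), theta = c(0.005, 0.005, 0.005), scaled = FALSE),
    class = "species_tree_model")
  gt <- sim_gene_tree(sp, c(X = 2, Y = 1))
  aln <- sim_alignment(gt, 500)
  popmap <- setNames(sub("_[0-9]+$", "", rownames(aln)), rownames(aln))
  ## prior means match the generating values, as in the study convention
  prior <- delim_prior(tau_rate = 20, theta_rate = 200)
  post <- oracle_model_posterior(aln, parse_newick("(X,Y);"), popmap, prior)
  expect_equal(sum(post), 1, tolerance = 1e-4)
  expect_gt(unname(post["X|Y"]), 0.95)
})
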