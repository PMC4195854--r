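test_that("JC69 transition probabilities follow the closed form", {
  expect_equal(jc69_prob(0), diag(4), ignore_attr = TRUE)
  expect_true(all(abs(jc69_prob(1e6) - 0.25) < 1e-12))
  P <- jc69_prob(0.1)
  ## independent evaluation of 1/4 + 3/4 exp(-4t/3) at t = 0.1
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-0.4 / 3), 4))
  expect_equal(unname(P[1, 2]), 0.25 - 0.25 * exp(-0.4 / 3))
  expect_true(all(abs(rowSums(P) - 1) < 1e-14))
  expect_error(jc69_prob(-0.1), "non-negative")
})

test_that("Chapman-Kolmogorov holds to 1e-12", {
  for (s in c(0.01, 0.3, 1.7)) for (t in c(0.05, 0.9)) {
    expect_true(all(abs(jc69_prob(s) %*% jc69_prob(t) -
                        jc69_prob(s + t)) < 1e-12))
  }
})

test_that("pruning equals the exhaustive-state oracle on small trees", {
  ## single site, two identical tips at t = 0
  aln1 <- matrix(c("A", "A"), 2, 1, dimnames = list(c("x", "y"), NULL))
  t0 <- parse_newick("(x:0,y:0);")
  expect_equal(jc69_loglik(t0, aln1), log(0.25))

  set.seed(17)
  for (ntip in 3:4) {
    for (rep in 1:4) {
      phy <- ape::rtree(ntip)
      phy$edge.length <- runif(nrow(phy$edge), 0, 0.5)
      aln <- toy_alignment(phy$tip.label, nsites = 10, seed = rep * 7)
      expect_equal(jc69_loglik(phy, aln), brute_jc69_loglik(phy, aln),
                   tolerance = 1e-10)
    }
  }
})

test_that("pruning likelihood is exchangeable over sites and sequences", {
  set.seed(18)
  phy <- ape::rtree(5)
  aln <- toy_alignment(phy$tip.label, nsites = 30)
  ll <- jc69_loglik(phy, aln)
  expect_equal(jc69_loglik(phy, aln[, sample(30)]), ll)
  perm <- sample(5)
  expect_equal(jc69_loglik(phy, aln[perm, ]), ll)
  expect_error(jc69_loglik(phy, aln[1:4, ]), "bijection")
})

test_that("branch-length optimisation recovers the JC distance", {
  set.seed(19)
  gphy <- clock_tree(parse_newick("(x:1,y:1);"), c(0, 0, 0.04))
  aln <- sim_alignment(gphy, 3000)
  p <- mean(aln[1, ] != aln[2, ])
  start <- parse_newick("(x:0.2,y:0.2);")
  opt <- optim_branch_lengths(start, aln)
  expect_equal(sum(opt$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-6)
  ## identical sequences: zero lengths
  aln_id <- rbind(x = aln[1, ], y = aln[1, ])
  opt0 <- optim_branch_lengths(start, aln_id)
  expect_true(all(opt0$edge.length < 1e-9))
})

test_that("optimisation never decreases the likelihood", {
  set.seed(20)
  m <- build_species_tree(1, "high")
  gt <- sim_gene_tree(m, c(A = 2, B = 2, C = 2, D = 2))
  aln <- sim_alignment(gt, 400)
  tr <- ape::unroot(gt$phy)
  tr$edge.length[] <- 0.05
  ll0 <- jc69_loglik(tr, aln)
  lls <- vapply(1:5, function(k) {
    attr(optim_branch_lengths(tr, aln, max_sweeps = k, tol = 0), "loglik")
  }, 0)
  expect_true(all(diff(c(ll0, lls)) > -1e-9))
  ## agreement with the independently implemented optimiser in phangorn
  dat <- phangorn::phyDat(tolower(aln), type = "DNA")
  ref <- phangorn::optim.pml(phangorn::pml(tr, dat), optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(attr(optim_branch_lengths(tr, aln), "loglik"), ref$logLik,
               tolerance = 1e-4)
})

test_that("MSC density matches closed forms and normalises", {
  theta <- 0.005
  single <- structure(list(
    phy = clock_tree(parse_newick("(A:1,B:1);"), c(0, 0, 10)),
    tau = c(0, 0, 10), theta = rep(theta, 3), scaled = FALSE),
    class = "species_tree_model")
  dens2 <- function(t) {
    gphy <- clock_tree(parse_newick("(A_1:1,A_2:1);"), c(0, 0, t))
    gt <- structure(list(phy = gphy, age = c(0, 0, t),
                         pop = c(A_1 = "A", A_2 = "A")),
                    class = "gene_tree")
    exp(msc_logdensity(gt, single))
  }
  expect_equal(dens2(1e-12), 2 / theta, tolerance = 1e-6)
  expect_equal(log(dens2(0.003)), log(2 / theta) - 2 * 0.003 / theta)
  ## density integrates to 1 over the coalescent time (quadrature)
  expect_equal(stats::integrate(Vectorize(dens2), 0, 1,
                                rel.tol = 1e-8)$value, 1, tolerance = 1e-6)

  ## three lineages, one population: ranked two-age density normalises after
  ## summing the three labeled topologies (symmetry: multiply by 3)
  dens3 <- function(t1, t2) {
    gphy <- clock_tree(parse_newick("((A_1:1,A_2:1):1,A_3:2);"),
                       c(0, 0, 0, t2, t1))
    gt <- structure(list(phy = gphy, age = c(0, 0, 0, t2, t1),
                         pop = setNames(rep("A", 3),
                                        c("A_1", "A_2", "A_3"))),
                    class = "gene_tree")
    exp(msc_logdensity(gt, single))
  }
  inner <- Vectorize(function(t1) {
    stats::integrate(Vectorize(function(t2) dens3(t1, t2)), t1, 0.2,
                     rel.tol = 1e-9)$value
  })
  total <- 3 * stats::integrate(inner, 0, 0.2, rel.tol = 1e-7)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("incompatible gene trees get the -Inf sentinel", {
  m <- build_species_tree(1, "high")
  gphy <- clock_tree(parse_newick("(A_1:1,B_1:1);"), c(0, 0, 0.001))
  gt <- structure(list(phy = gphy, age = c(0, 0, 0.001),
                       pop = c(A_1 = "A", B_1 = "B")), class = "gene_tree")
  expect_identical(msc_logdensity(gt, m), -Inf)  # 0.001 < tau_AB = 0.01
})

test_that("MSC density agrees with an independent event-sweep implementation", {
  set.seed(21)
  for (i in 1:60) {
    m <- build_species_tree(sample(1:2, 1), sample(c("low", "high"), 1))
    gt <- sim_gene_tree(m, setNames(sample(1:3, 4, TRUE), m$phy$tip.label))
    expect_equal(msc_logdensity(gt, m), indep_msc_logdensity(gt, m),
                 tolerance = 1e-10)
  }
})

test_that("simulator and density agree on the 3-lineage first-event rate", {
  set.seed(22)
  theta <- 0.01
  single <- structure(list(
    phy = clock_tree(parse_newick("(A:1,B:1);"), c(0, 0, 100)),
    tau = c(0, 0, 100), theta = rep(theta, 3), scaled = FALSE),
    class = "species_tree_model")
  first <- replicate(20000, {
    gt <- sim_gene_tree(single, c(A = 3, B = 1))
    a <- node_ages(gt$phy)
    min(a[a > 0])
  })
  first <- first[first < 100]
  se <- (theta / 6) / sqrt(length(first))
  expect_lt(abs(mean(first) - theta / 6), 3 * se)  # implied rate 6/theta
})

test_that("delimitation prior has the configured hyperparameters", {
  low <- delim_prior("low")
  expect_equal(low$tau_shape / low$tau_rate, 1 / 333)   # mean 0.003
  expect_equal(low$theta_rate, 500)
  high <- delim_prior("high")
  expect_equal(high$tau_rate, 33)
  expect_equal(high$theta_rate, 50)

  ## fully collapsed model: no tau terms, one theta term, uniform model mass
  guide <- parse_newick("(X,Y);")
  st <- delim_state(guide, split = FALSE, tau = c(0, 0, 0),
                    theta = c(NA, NA, 0.002))
  lp <- log_prior_delimitation(st, low)
  expect_equal(lp, dgamma(0.002, 1, rate = 500, log = TRUE) + log(1 / 2))

  ## split model adds the tau0 gamma and the daughter thetas
  st2 <- delim_state(guide, split = TRUE, tau = c(0, 0, 0.001),
                     theta = c(0.001, 0.003, 0.002))
  lp2 <- log_prior_delimitation(st2, low)
  expect_equal(lp2, sum(dgamma(c(0.001, 0.003, 0.002), 1, rate = 500,
                               log = TRUE)) +
                 dgamma(0.001, 1, rate = 333, log = TRUE) + log(1 / 2))
})

test_that("the order-polytope age prior uses the hook-length density", {
  ## caterpillar guide over 3 populations: full model has one non-root split
  ## node with h = 1, density 1/tau0 on (0, tau0)
  guide <- parse_newick("((X,Y),Z);")
  prior <- delim_prior("low")
  st <- delim_state(guide, split = c(TRUE, TRUE),
                    tau = c(0, 0, 0, 0.003, 0.001),
                    theta = c(0.002, 0.002, 0.002, 0.002, 0.002))
  lp <- log_prior_delimitation(st, prior)
  by_hand <- sum(dgamma(rep(0.002, 5), 1, rate = 500, log = TRUE)) +
    dgamma(0.003, 1, rate = 333, log = TRUE) - log(0.003) -
    log(n_delim_models(guide))
  expect_equal(lp, by_hand)
})
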