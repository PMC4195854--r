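test_that("Newick parsing builds the expected structure and rejects bad input", {
  t1 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(t1), 3)
  ages <- node_ages(t1)
  expect_equal(unname(ages[4]), 2)   # root age under the clock interpretation
  expect_equal(unname(ages[5]), 1)

  expect_error(parse_newick("(A:1);"), "at least 2 tips")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "position")
  expect_error(parse_newick("((A,B),(C,D),(E,F),(G,H));"), "non-binary")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
  ## a basal trifurcation (unrooted convention) is accepted
  expect_s3_class(parse_newick("(A:1,B:1,C:1);"), "phylo")
})

test_that("canonical Newick writing round-trips and is idempotent", {
  set.seed(71)
  for (i in 1:20) {
    phy <- ape::rtree(sample(4:12, 1))
    s1 <- write_newick(phy)
    s2 <- write_newick(parse_newick(s1))
    expect_identical(s1, s2)
    ## structure preserved
    expect_identical(sort(names(tree_clades(parse_newick(s1)))),
                     sort(names(tree_clades(phy))))
  }
})

test_that("clades match the expected sets, including the caterpillar induction", {
  expect_setequal(names(tree_clades(parse_newick("(((A,B),C),D);"))),
                  c("A|B", "A|B|C", "A|B|C|D"))
  expect_setequal(names(tree_clades(parse_newick("((A,B),(C,D));"))),
                  c("A|B", "C|D", "A|B|C|D"))
  for (n in 4:8) {
    s <- paste0(paste(rep("(", n - 1), collapse = ""), "t1",
                paste(vapply(2:n, function(i) paste0(",t", i, ")"), ""),
                      collapse = ""), ";")
    cl <- tree_clades(parse_newick(s))
    expect_length(cl, n - 1)          # one nested clade per internal node
  }
})

test_that("clade recovery counts strict clade presence", {
  true <- parse_newick("(((A,B),C),D);")
  expect_true(all(clade_recovery(true, rep(list(true), 10)) == 1))
  alt <- parse_newick("(((A,C),B),D);")  # lacks clade AB
  rec <- clade_recovery(true, c(rep(list(true), 5), rep(list(alt), 5)))
  expect_equal(unname(rec["A|B"]), 0.5)
  expect_equal(unname(rec["A|B|C"]), 1.0)
  expect_error(clade_recovery(true, list(parse_newick("((A,B),(C,E));"))),
               "tip sets")
})

test_that("clade recovery agrees with independent bipartition counting", {
  set.seed(31)
  for (rep in 1:10) {
    true <- ape::rtree(8)
    inferred <- lapply(1:10, function(i) ape::rtree(8))
    mine <- clade_recovery(true, inferred)
    ## independent oracle: per-clade set membership computed from scratch
    for (k in names(mine)) {
      tips <- strsplit(k, "|", fixed = TRUE)[[1]]
      hits <- vapply(inferred, function(tr) {
        any(vapply(tree_clades_all(tr)[-seq_len(8)], function(cl)
          setequal(cl, tips), TRUE))
      }, TRUE)
      expect_equal(unname(mine[k]), mean(hits))
    }
  }
})

test_that("clade recovery is invariant under consistent tip relabeling", {
  set.seed(5)
  true <- ape::rtree(6)
  inferred <- lapply(1:5, function(i) ape::rtree(6))
  r1 <- clade_recovery(true, inferred)
  perm <- setNames(paste0("z", 1:6), true$tip.label)
  relab <- function(tr) { tr$tip.label <- unname(perm[tr$tip.label]); tr }
  r2 <- clade_recovery(relab(true), lapply(inferred, relab))
  expect_equal(sort(unname(r1)), sort(unname(r2)))
})

test_that("midpoint rooting places the root on the longest path", {
  ## pendant lengths 1 (A), 3 (B), 1 (C): diameter path B-A (or B-C) length 4,
  ## midpoint 1 unit from the junction on B's edge
  mr <- midpoint_root(parse_newick("(A:1,B:3,C:1);"))
  ages <- node_ages(mr)
  expect_equal(max(ages), 2)
  d <- ape::dist.nodes(mr)
  root <- ape::Ntip(mr) + 1L
  expect_equal(unname(d[root, which(mr$tip.label == "B")]), 2)
  ## two tips: equidistant root
  mr2 <- midpoint_root(parse_newick("(A:1,B:1);"))
  d2 <- ape::dist.nodes(mr2)
  expect_equal(unname(d2[3, 1]), unname(d2[3, 2]))
})

test_that("midpoint rooting matches phangorn and preserves bipartitions", {
  set.seed(13)
  for (i in 1:15) {
    tr <- ape::unroot(ape::rtree(8))
    mine <- midpoint_root(tr)
    ref <- phangorn::midpoint(tr)
    expect_identical(canonical_newick(mine, lengths = FALSE),
                     canonical_newick(ref, lengths = FALSE))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), tr)), 0)
  }
})

test_that("midpoint rooting recovers the root split of clock trees", {
  set.seed(99)
  hits <- 0
  for (i in 1:50) {
    clock <- ape::rcoal(8)
    root_key <- sort(names(tree_clades(clock)))
    re <- midpoint_root(ape::unroot(clock))
    hits <- hits + identical(sort(names(tree_clades(re))), root_key)
  }
  expect_equal(hits, 50)
})

test_that("degenerate all-zero branch lengths root deterministically", {
  tr <- parse_newick("(A:0,B:0,C:0);")
  r1 <- midpoint_root(tr)
  r2 <- midpoint_root(tr)
  expect_identical(write_newick(r1), write_newick(r2))
})

test_that("modal topology picks the most frequent sample with documented ties", {
  a <- clock_tree(parse_newick("((A,B),C);"), c(0, 0, 0, 2, 1))
  b <- clock_tree(parse_newick("((A,C),B);"), c(0, 0, 0, 2, 1))
  expect_identical(canonical_newick(modal_topology(rep(list(a), 5)),
                                    lengths = FALSE),
                   canonical_newick(a, lengths = FALSE))
  ## exact tie: lexicographically smallest canonical string wins, which is
  ## ((A,B),C) over ((A,C),B)
  tie <- modal_topology(c(rep(list(a), 3), rep(list(b), 3)))
  expect_identical(canonical_newick(tie, lengths = FALSE), "((A,B),C);")
  expect_error(modal_topology(list()), "empty")
})

test_that("burn-in bookkeeping keeps the last 2200 of 3000 samples", {
  a <- clock_tree(parse_newick("((A,B),C);"), c(0, 0, 0, 2, 1))
  b <- clock_tree(parse_newick("((A,C),B);"), c(0, 0, 0, 2, 1))
  ## first 800 samples are topology b, last 2200 are a; with the protocol
  ## burn-in fraction the counts must be over exactly the last 2200 trees
  samples <- c(rep(list(b), 800), rep(list(a), 2200))
  m <- modal_topology(samples, burn_in_fraction = 800 / 3000)
  expect_identical(canonical_newick(m, lengths = FALSE), "((A,B),C);")
  ## sanity: with no burn-in the tie-break would still pick a (2200 > 800)
  m2 <- map_guide_tree(samples, keep_last = 2200)
  expect_identical(canonical_newick(m2, lengths = FALSE), "((A,B),C);")
})
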