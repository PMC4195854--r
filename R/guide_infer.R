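## Guide-tree construction: (i) constrained maximum-likelihood gene-tree
## estimation on the mitochondrial locus with midpoint rooting, and (ii)
## Bayesian multispecies-coalescent species-tree MCMC on the nuclear loci
## with modal-topology (MAP) extraction.

## is every population a clade of the unrooted tree (i.e. one side of some
## bipartition)?
.pops_monophyletic_unrooted <- function(phy, popmap) {
  keys <- names(tree_clades(phy))
  all_tips <- sort(phy$tip.label)
  for (p in unique(popmap[phy$tip.label])) {
    tips <- sort(phy$tip.label[popmap[phy$tip.label] == p])
    if (length(tips) == 1L) next
    comp <- setdiff(all_tips, tips)
    if (!(.clade_key(tips) %in% keys) && !(.clade_key(comp) %in% keys))
      return(FALSE)
  }
  TRUE
}

.pop_ladder <- function(seqs) {
  s <- paste0(seqs[1])
  for (i in seq_along(seqs)[-1]) s <- paste0("(", s, ",", seqs[i], ")")
  s
}

.start_tree_newick <- function(aln, popmap) {
  labs <- rownames(aln)
  pops <- sort(unique(popmap[labs]))
  D <- ape::dist.dna(.as_dnabin(aln), model = "JC69",
                     pairwise.deletion = FALSE, as.matrix = TRUE)
  D[!is.finite(D)] <- max(D[is.finite(D)], 0.75) * 1.5
  ## population-level mean distances
  P <- length(pops)
  Dp <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    gi <- labs[popmap[labs] == pops[i]]
    gj <- labs[popmap[labs] == pops[j]]
    Dp[i, j] <- Dp[j, i] <- mean(D[gi, gj])
  }
  pop_nwk <- if (P == 2) {
    paste0("(", pops[1], ",", pops[2], ");")
  } else {
    ptree <- ape::nj(as.dist(Dp))
    ptree$edge.length <- NULL
    ape::write.tree(ptree)
  }
  for (p in pops) {
    seqs <- labs[popmap[labs] == p]
    sub <- .pop_ladder(seqs)
    pop_nwk <- gsub(paste0("([(,])", p, "([,)])"),
                    paste0("\\1", sub, "\\2"), pop_nwk)
  }
  pop_nwk
}

#' Constrained ML guide tree from a mitochondrial alignment
#'
#' Infers the unrooted ML gene tree under JC69 with each population
#' constrained to be monophyletic (neighbor-joining start from JC distances,
#' then best-improvement NNI hill climbing with per-edge Newton branch-length
#' optimisation, skipping rearrangements that break a constraint), roots it
#' at the midpoint of the longest tip-to-tip path, and collapses each
#' population subtree to a single tip. Deterministic given the data.
#'
#' @param aln mitochondrial alignment matrix.
#' @param popmap named character vector mapping sequences to populations.
#' @param max_rounds cap on NNI improvement rounds.
#' @return rooted `phylo` over the populations, with attributes `loglik` and
#'   `seq_tree` (the full rooted sequence tree).
#' @export
ml_guide_tree <- function(aln, popmap, max_rounds = 30) {
  validate_alignment(aln)
  .check_popmap(rownames(aln), popmap)
  labs <- rownames(aln)
  pops <- sort(unique(popmap[labs]))
  if (length(pops) < 2) stop("need at least 2 populations")

  pat <- compress_patterns(aln)
  opt <- function(phy, sweeps = 12L, tol = 1e-7) {
    ord <- match(phy$tip.label, pat$labels)
    res <- .cd_optim_edges(phy$edge, ape::Ntip(phy),
                           pmax(phy$edge.length, 1e-8),
                           pat$states[ord, , drop = FALSE], pat$weights,
                           sweeps, tol)
    phy$edge.length <- res$el
    attr(phy, "loglik") <- res$loglik
    phy
  }

  cur <- parse_newick(.start_tree_newick(aln, popmap))
  cur$edge.length <- rep(0.02, nrow(cur$edge))
  cur <- opt(cur)

  raw_ll <- function(phy) {
    ord <- match(phy$tip.label, pat$labels)
    .cd_loglik(phy$edge, ape::Ntip(phy), pmax(phy$edge.length, 1e-8),
               pat$states[ord, , drop = FALSE], pat$weights)
  }
  if (length(labs) > 3) {
    for (round in seq_len(max_rounds)) {
      ## normalise node numbering of the rearranged trees (phangorn::nni
      ## returns trees whose root is not at the ape-conventional index)
      nbs <- lapply(phangorn::nni(cur), function(tr)
        ape::read.tree(text = ape::write.tree(tr)))
      keep <- vapply(nbs, .pops_monophyletic_unrooted, TRUE, popmap = popmap)
      nbs <- nbs[keep]
      if (!length(nbs)) break
      ## screen candidates at current branch lengths; re-optimise only the
      ## most promising few (branch lengths change little under one NNI)
      screen <- vapply(nbs, raw_ll, 0)
      top <- order(screen, decreasing = TRUE)[seq_len(min(5L, length(nbs)))]
      best <- NULL
      best_ll <- attr(cur, "loglik") + 1e-6
      for (i in top) {
        nb2 <- opt(nbs[[i]], sweeps = 4L, tol = 1e-5)
        ll <- attr(nb2, "loglik")
        if (ll > best_ll + 1e-9 ||
            (!is.null(best) && abs(ll - best_ll) <= 1e-9 &&
             canonical_newick(nb2, lengths = FALSE) <
             canonical_newick(best, lengths = FALSE))) {
          best <- nb2; best_ll <- ll
        }
      }
      if (is.null(best)) break
      cur <- opt(best)
      if (attr(cur, "loglik") <= best_ll - 1e-6) cur <- best  # paranoia
    }
  }

  rooted <- .midpoint_root_constrained(cur, popmap)
  guide <- .collapse_populations(rooted, popmap)
  attr(guide, "loglik") <- attr(cur, "loglik")
  attr(guide, "seq_tree") <- rooted
  guide
}

## midpoint rooting, falling back to the nearest rooting that keeps every
## population monophyletic as a rooted clade (the midpoint can in principle
## fall inside a population subtree)
.midpoint_root_constrained <- function(phy, popmap) {
  rooted <- midpoint_root(phy)
  ok <- function(tr) {
    keys <- names(tree_clades(tr))
    for (p in unique(popmap[tr$tip.label])) {
      tips <- tr$tip.label[popmap[tr$tip.label] == p]
      if (length(tips) > 1L && !(.clade_key(tips) %in% keys)) return(FALSE)
    }
    TRUE
  }
  if (ok(rooted)) return(rooted)
  ## try rooting on each edge (at its midpoint) in order of increasing
  ## distance from the global midpoint, keeping the first valid rooting
  cand <- list()
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    r <- tryCatch(ape::collapse.singles(
      phytools::reroot(phy, node.number = child,
                       position = phy$edge.length[e] / 2)),
      error = function(err) NULL)
    if (!is.null(r) && ok(r)) cand[[length(cand) + 1L]] <- r
  }
  if (!length(cand)) stop("no rooting keeps the populations monophyletic")
  cand[[1L]]
}

.collapse_populations <- function(rooted, popmap) {
  pops <- sort(unique(popmap[rooted$tip.label]))
  keep <- vapply(pops, function(p)
    rooted$tip.label[popmap[rooted$tip.label] == p][1], "")
  guide <- ape::keep.tip(rooted, unname(keep))
  guide$tip.label <- names(keep)[match(guide$tip.label, keep)]
  guide$node.label <- NULL
  guide
}

## ---- Bayesian species-tree MCMC (the multilocus nuclear arm) ----

#' Bayesian species-tree MCMC under the multispecies coalescent
#'
#' Samples population trees from the posterior `p(S, tau, theta, lambda,
#' {G_i} | X)` with a Yule prior on the species tree, `f(lambda) = 1/lambda`,
#' and `f(theta) = 1/theta` truncated to `theta_bounds` (the truncation makes
#' the posterior proper; see the package vignette). Gene trees per locus are
#' part of the state; correct population assignment of the sequences is
#' assumed, but sequences of a population are not constrained to be
#' monophyletic on the gene trees.
#'
#' The study protocol collects 3000 samples every 2000 iterations (6 million
#' elementary updates in total); scaled-down chains are used for the
#' replicated evaluations.
#'
#' @param loci list of nuclear alignment matrices.
#' @param popmap named character vector mapping sequences to populations.
#' @param n_iter total elementary MCMC updates.
#' @param sample_every sampling interval (default `n_iter / 3000`).
#' @param tune_frac fraction of the chain used for step-size auto-tuning.
#' @param theta_bounds truncation interval of the 1/theta prior.
#' @param root_age_bound upper truncation of the root divergence time
#'   (`Inf` by default; set a finite bound for prior-only validation runs so
#'   that the sampled prior is proper).
#' @param likelihood_off replace the sequence likelihood by 1 (prior
#'   validation runs).
#' @return object of class `sptree_mcmc`: list with `samples` (list of clock
#'   `phylo` over populations), `lambda`, `logpost`, `acc`.
#' @export
species_tree_mcmc <- function(loci, popmap, n_iter = 6e6,
                              sample_every = NULL, tune_frac = 0.1,
                              theta_bounds = c(1e-6, 1),
                              root_age_bound = Inf,
                              likelihood_off = FALSE) {
  if (inherits(loci, "matrix")) loci <- list(loci)
  for (aln in loci) .check_popmap(rownames(aln), popmap)
  labs <- rownames(loci[[1]])
  pops <- sort(unique(popmap[unlist(lapply(loci, rownames))]))
  P <- length(pops)
  if (P < 2) stop("need at least 2 populations")
  if (is.null(sample_every)) sample_every <- max(1L, floor(n_iter / 3000))

  ## UPGMA initialisation of the population tree from mean JC distances
  dists <- lapply(loci, function(aln) {
    D <- ape::dist.dna(.as_dnabin(aln), model = "JC69",
                       pairwise.deletion = FALSE, as.matrix = TRUE)
    D[!is.finite(D)] <- max(D[is.finite(D)], 0.5)
    D
  })
  Dp <- matrix(0, P, P, dimnames = list(pops, pops))
  for (D in dists) {
    l <- rownames(D)
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      gi <- l[popmap[l] == pops[i]]; gj <- l[popmap[l] == pops[j]]
      Dp[i, j] <- Dp[j, i] <- Dp[i, j] + mean(D[gi, gj]) / length(dists)
    }
  }
  hc <- stats::hclust(stats::as.dist(Dp), method = "average")
  sphy <- ape::as.phylo(hc)
  ages <- node_ages(sphy)
  ## enforce strictly decreasing ages root-to-tip and a positive floor
  ntip_s <- ape::Ntip(sphy)
  ages[-seq_len(ntip_s)] <- pmax(ages[-seq_len(ntip_s)], 1e-6)
  ord <- ape::reorder.phylo(sphy, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    if (ages[p] <= ages[c]) ages[p] <- ages[c] * 1.001 + 1e-7
  }
  sphy <- clock_tree(sphy, ages)

  within <- numeric(0)
  for (D in dists) {
    l <- rownames(D)
    for (p in pops) {
      g <- l[popmap[l] == p]
      if (length(g) > 1) within <- c(within, mean(D[g, g][upper.tri(D[g, g])]))
    }
  }
  theta0 <- min(max(mean(within), 1e-4, na.rm = TRUE), theta_bounds[2])
  if (!is.finite(theta0)) theta0 <- 1e-3

  init_model <- structure(list(phy = sphy, tau = ages,
                               theta = rep(theta0, P + sphy$Nnode),
                               scaled = FALSE), class = "species_tree_model")
  counts <- table(popmap)

  cloci <- lapply(loci, function(aln) {
    gt <- sim_gene_tree(init_model, counts[pops])
    lab <- gt$phy$tip.label
    new <- lab
    for (p in pops) {
      seqs <- names(popmap)[popmap == p]
      seqs <- seqs[seqs %in% rownames(aln)]
      new[grep(paste0("^", p, "_"), lab)] <- seqs
    }
    gt$phy$tip.label <- new
    gt$pop <- setNames(popmap[new], new)
    .locus_to_c(aln, popmap, pops, gt)
  })

  H <- sum(ages[ages > 0]) + max(ages)
  res <- .cd_sptree_mcmc(cloci, .phylo_parents0(sphy), ages,
                         rep(theta0, P + sphy$Nnode), (P - 1) / H,
                         theta_bounds[1], theta_bounds[2],
                         as.integer(n_iter),
                         as.integer(tune_frac * n_iter),
                         as.integer(sample_every), likelihood_off,
                         root_age_bound)

  structure(list(par = res$par, tau = res$tau, lambda = res$lambda,
                 logpost = res$logpost, acc = res$acc,
                 theta = res$theta, n_iter = n_iter,
                 sample_every = sample_every, populations = pops,
                 n_samples = nrow(res$par)),
            class = "sptree_mcmc")
}

#' Extract sampled species trees from a fit
#' @param fit a `sptree_mcmc` object.
#' @param which indices of samples to convert (default all).
#' @return list of clock `phylo` over the populations.
#' @export
sptree_samples <- function(fit, which = seq_len(fit$n_samples)) {
  lapply(which, function(i)
    .phylo_from_parents(fit$par[i, ], fit$tau[i, ], fit$populations))
}

#' @export
print.sptree_mcmc <- function(x, ...) {
  cat(sprintf(
    "Species-tree MCMC: %d samples (%d populations, every %d of %g updates)\n",
    x$n_samples, length(x$populations), x$sample_every, x$n_iter))
  invisible(x)
}

## canonical topology key straight from a 0-based parent vector (fast path
## used when summarising thousands of posterior samples)
.canon_key_parents <- function(par0, labels) {
  n <- length(par0)
  kids <- vector("list", n)
  root <- 0L
  for (v in seq_len(n)) {
    p <- par0[v] + 1L
    if (p <= 0L) root <- v else kids[[p]] <- c(kids[[p]], v)
  }
  rec <- function(v) {
    if (v <= length(labels)) return(c(labels[v], labels[v]))
    parts <- lapply(kids[[v]], rec)
    ord <- order(vapply(parts, `[`, "", 2L))
    parts <- parts[ord]
    c(paste0("(", paste(vapply(parts, `[`, "", 1L), collapse = ","), ")"),
      parts[[1L]][2L])
  }
  paste0(rec(root)[1L], ";")
}

#' MAP guide tree from species-tree MCMC samples
#'
#' The modal topology among the last `keep_last` sampled trees (the study
#' protocol keeps the last 2200 of 3000), with mean node ages; ties broken
#' toward the lexicographically smallest canonical Newick string.
#'
#' @param fit a `sptree_mcmc` fit (or a plain list of `phylo`).
#' @param keep_last number of most recent samples to use.
#' @return rooted clock `phylo`.
#' @export
map_guide_tree <- function(fit, keep_last = 2200) {
  if (!inherits(fit, "sptree_mcmc")) {
    n <- length(fit)
    if (n == 0L) stop("no samples")
    if (keep_last > n) stop("keep_last exceeds the number of samples")
    return(modal_topology(fit[(n - keep_last + 1L):n]))
  }
  n <- fit$n_samples
  if (n == 0L) stop("no samples")
  if (keep_last > n) stop("keep_last exceeds the number of samples")
  idx <- (n - keep_last + 1L):n
  raw <- apply(fit$par[idx, , drop = FALSE], 1L, paste, collapse = ",")
  uraw <- unique(raw)
  ukey <- vapply(uraw, function(r)
    .canon_key_parents(as.integer(strsplit(r, ",")[[1]]), fit$populations),
    "")
  keys <- ukey[match(raw, uraw)]
  tab <- table(keys)
  win <- sort(names(tab)[tab == max(tab)])[1L]
  sub <- idx[keys == win]
  ## mean age per node of the modal topology (node identity is stable within
  ## a topology because the guide populations are fixed)
  par0 <- fit$par[sub[1L], ]
  tau <- colMeans(fit$tau[sub, , drop = FALSE])
  ## identical topology strings can still have internal node ids permuted;
  ## average ages by clade key instead
  nnode <- length(par0)
  P <- length(fit$populations)
  clade_of <- function(par0) {
    keysv <- character(nnode)
    kids <- vector("list", nnode)
    root <- 0L
    for (v in seq_len(nnode)) {
      p <- par0[v] + 1L
      if (p <= 0L) root <- v else kids[[p]] <- c(kids[[p]], v)
    }
    rec <- function(v) {
      if (v <= P) {
        keysv[v] <<- fit$populations[v]
        return(fit$populations[v])
      }
      tips <- sort(unlist(lapply(kids[[v]], rec)))
      keysv[v] <<- paste(tips, collapse = "|")
      tips
    }
    rec(root)
    keysv
  }
  acc <- new.env(parent = emptyenv())
  ## samples with the same topology can still differ in node-id layout;
  ## group by raw parent vector so ages are averaged with one pass per layout
  sub_raw <- raw[match(sub, idx)]
  for (r in unique(sub_raw)) {
    rows <- sub[sub_raw == r]
    kv <- clade_of(fit$par[rows[1L], ])
    mtau <- colSums(fit$tau[rows, , drop = FALSE])
    for (v in (P + 1L):nnode) {
      prev <- if (is.null(acc[[kv[v]]])) c(0, 0) else acc[[kv[v]]]
      acc[[kv[v]]] <- prev + c(mtau[v], length(rows))
    }
  }
  kv <- clade_of(par0)
  tau_out <- numeric(nnode)
  for (v in (P + 1L):nnode) {
    a <- acc[[kv[v]]]
    tau_out[v] <- a[1] / a[2]
  }
  ## guard monotonicity against averaging artefacts
  for (v in order(vapply(seq_len(nnode), function(v) {
    d <- 0; x <- v
    while (par0[x + 0L] >= 0) { d <- d + 1; x <- par0[x] + 1L }
    -d
  }, 0))) {
    p <- par0[v] + 1L
    if (p > 0L && tau_out[p] <= tau_out[v])
      tau_out[p] <- tau_out[v] * (1 + 1e-9) + 1e-12
  }
  .phylo_from_parents(par0, tau_out, fit$populations)
}
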