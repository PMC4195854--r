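# Independent oracles used across the suite. These deliberately re-derive
# quantities with different algorithms/code paths than the package internals.

# exhaustive-state JC69 likelihood: sum over all internal-node state
# assignments (feasible for <= 4 tips)
brute_jc69_loglik <- function(phy, aln) {
  states <- match(aln, c("T", "C", "A", "G")) - 1L
  dim(states) <- dim(aln)
  rownames(states) <- rownames(aln)
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  par <- rep(NA_integer_, ntip + nint)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  elen <- rep(NA_real_, ntip + nint)
  elen[phy$edge[, 2]] <- phy$edge.length
  P <- lapply(elen, function(t) if (is.na(t)) NULL else jc69_prob(t))
  tipidx <- match(phy$tip.label, rownames(aln))
  ll <- 0
  for (site in seq_len(ncol(aln))) {
    tot <- 0
    grid <- as.matrix(expand.grid(rep(list(0:3), nint)))
    for (g in seq_len(nrow(grid))) {
      assign <- c(states[tipidx, site], grid[g, ])
      p <- 0.25  # root state frequency
      for (v in seq_len(ntip + nint)) {
        if (is.na(par[v])) next
        p <- p * P[[v]][assign[par[v]] + 1L, assign[v] + 1L]
      }
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

# independent MSC log density: event-sweep over all boundaries, locating the
# occupant species branch of every lineage at interval midpoints
indep_msc_logdensity <- function(gtree, model) {
  phy <- gtree$phy
  ages <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  sp <- model$phy
  stau <- model$tau
  sth <- model$theta
  spar <- rep(NA_integer_, ape::Ntip(sp) + sp$Nnode)
  spar[sp$edge[, 2]] <- sp$edge[, 1]
  sdesc <- lapply(tree_clades_all(sp), identity)
  gdesc <- tree_clades_all(phy)
  loc <- function(tipset, t) {
    pops <- unique(gtree$pop[tipset])
    v <- which(sp$tip.label == pops[1])
    while (!all(pops %in% sdesc[[v]])) v <- spar[v]
    while (!is.na(spar[v]) && stau[spar[v]] <= t) v <- spar[v]
    v
  }
  gpar <- rep(NA_integer_, ntip + phy$Nnode)
  gpar[phy$edge[, 2]] <- phy$edge[, 1]
  groot <- ntip + 1L
  events <- sort(unique(c(ages[ages > 0], stau[stau > 0])))
  lo <- 0; ld <- 0
  for (t1 in events) {
    tm <- (lo + t1) / 2
    act <- which(vapply(seq_len(ntip + phy$Nnode), function(v)
      ages[v] <= tm && (is.na(gpar[v]) || ages[gpar[v]] > tm), TRUE))
    act <- act[act != groot]
    cnt <- table(vapply(act, function(v) loc(gdesc[[v]], tm), 0L))
    for (b in names(cnt)) {
      j <- cnt[[b]]
      ld <- ld - j * (j - 1) * (t1 - lo) / sth[as.integer(b)]
    }
    for (v in which(abs(ages - t1) < 1e-18)) {
      if (v <= ntip) next
      b <- loc(gdesc[[v]], t1)
      if (t1 < stau[b]) return(-Inf)
      ld <- ld + log(2 / sth[b])
    }
    lo <- t1
  }
  ld
}

# tip descendants for every node (tips included), by node id
tree_clades_all <- function(phy) {
  ntip <- ape::Ntip(phy)
  out <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- phy$tip.label[i]
  ord <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

# brute-force ancestor-closed subset enumeration of delimitation models
brute_models <- function(guide) {
  ntip <- ape::Ntip(guide)
  nint <- guide$Nnode
  par <- rep(NA_integer_, ntip + nint)
  par[guide$edge[, 2]] <- guide$edge[, 1]
  root <- ntip + 1L
  ok <- 0L
  for (mask in 0:(2^nint - 1)) {
    split <- as.logical(bitwAnd(mask, 2^(seq_len(nint) - 1L)))
    closed <- TRUE
    for (j in seq_len(nint)) {
      v <- ntip + j
      if (split[j] && v != root && !split[par[v] - ntip]) closed <- FALSE
    }
    if (closed) ok <- ok + 1L
  }
  ok
}

# small deterministic alignment on given labels (arbitrary but fixed content)
toy_alignment <- function(labels, nsites = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(sample(c("T", "C", "A", "G"), length(labels) * nsites,
                     replace = TRUE),
              nrow = length(labels), dimnames = list(labels, NULL))
  m
}
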