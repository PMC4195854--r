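## Probability kernels: JC69 transition probabilities, pruning log-likelihood,
## multispecies-coalescent gene-tree density, and prior configuration.

#' JC69 transition probability matrix
#'
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 stochastic matrix over the states T, C, A, G; diagonal entries
#'   `1/4 + 3/4 exp(-4t/3)`, off-diagonal `1/4 - 1/4 exp(-4t/3)`.
#' @export
jc69_prob <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length must be a single non-negative number")
  E <- exp(-4 * t / 3)
  P <- matrix(0.25 * (1 - E), 4, 4,
              dimnames = list(.DNA_ALPHABET, .DNA_ALPHABET))
  diag(P) <- 0.25 + 0.75 * E
  P
}

#' Compress an alignment into site patterns
#'
#' @param aln character alignment matrix.
#' @return list with `states` (integer matrix, rows = sequences in input
#'   order, values 0..3 for T,C,A,G), `weights` (pattern multiplicities) and
#'   `labels`.
#' @export
compress_patterns <- function(aln) {
  validate_alignment(aln)
  idx <- matrix(match(aln, .DNA_ALPHABET) - 1L, nrow = nrow(aln))
  key <- apply(idx, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = idx[, first, drop = FALSE], weights = as.numeric(tab),
       labels = rownames(aln))
}

.edge_inputs <- function(phy, aln) {
  pat <- compress_patterns(aln)
  ord <- match(phy$tip.label, pat$labels)
  if (anyNA(ord)) stop("tree tips and alignment labels do not match")
  list(edge = phy$edge, ntip = ape::Ntip(phy),
       states = pat$states[ord, , drop = FALSE], weights = pat$weights)
}

#' Pruning log-likelihood under JC69
#'
#' Felsenstein pruning with uniform base frequencies and compressed site
#' patterns; accepts rooted binary trees or unrooted trees with a basal
#' trifurcation.
#'
#' @param phy `phylo` with branch lengths; tip labels must match `aln` rows.
#' @param aln character alignment matrix.
#' @return log-likelihood (a finite negative number).
#' @export
jc69_loglik <- function(phy, aln) {
  if (!setequal(phy$tip.label, rownames(aln)) ||
      ape::Ntip(phy) != nrow(aln))
    stop("tree tips and alignment labels must be in bijection")
  inp <- .edge_inputs(phy, aln)
  .cd_loglik(inp$edge, inp$ntip, phy$edge.length, inp$states, inp$weights)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Iterative per-edge Newton optimisation of the JC69 pruning likelihood
#' (each branch has a closed-form concave one-dimensional profile in
#' `exp(-4t/3)`); the likelihood is non-decreasing across sweeps.
#'
#' @param phy `phylo` (rooted or unrooted); initial lengths used as start.
#' @param aln character alignment matrix.
#' @param max_sweeps,tol convergence controls.
#' @return `phy` with optimised `edge.length` and attribute `loglik`.
#' @export
optim_branch_lengths <- function(phy, aln, max_sweeps = 20, tol = 1e-8) {
  inp <- .edge_inputs(phy, aln)
  el0 <- phy$edge.length
  if (is.null(el0)) el0 <- rep(0.05, nrow(phy$edge))
  res <- .cd_optim_edges(inp$edge, inp$ntip, el0, inp$states, inp$weights,
                         max_sweeps, tol)
  phy$edge.length <- res$el
  attr(phy, "loglik") <- res$loglik
  phy
}

## ---- conversions to the 0-based C structures ----

.phylo_parents0 <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- rep(-1L, n)
  par[phy$edge[, 2]] <- phy$edge[, 1] - 1L
  par
}

.gene_to_c <- function(gtree, label_order = NULL) {
  phy <- gtree$phy
  if (!is.null(label_order)) {
    ## permute tip indices so tip i matches label_order[i]
    perm <- match(label_order, phy$tip.label)
    if (anyNA(perm)) stop("gene tree tips do not match requested labels")
    phy_new <- phy
    inv <- order(perm)
    phy_new$tip.label <- phy$tip.label[perm]
    map <- seq_len(ape::Ntip(phy) + phy$Nnode)
    map[perm] <- seq_along(perm)
    phy_new$edge <- matrix(map[phy$edge], ncol = 2)
    phy <- phy_new
  }
  age <- node_ages(phy)
  list(par = .phylo_parents0(phy), age = age, labels = phy$tip.label)
}

.phylo_from_parents <- function(par0, age, tip_labels) {
  n <- length(par0)
  ntip <- length(tip_labels)
  ## re-index internals so that the root becomes ntip+1, by decreasing age
  ids <- integer(n)
  ids[seq_len(ntip)] <- seq_len(ntip)
  internal <- setdiff(seq_len(n), seq_len(ntip))
  internal <- internal[order(age[internal], decreasing = TRUE)]
  ids[internal] <- ntip + seq_along(internal)
  nonroot <- which(par0 >= 0)
  edge <- cbind(ids[par0[nonroot] + 1L], ids[nonroot])
  age2 <- numeric(n)
  age2[ids] <- age
  phy <- structure(list(edge = edge, tip.label = tip_labels,
                        Nnode = n - ntip),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  clock_tree(phy, age2)
}

#' Multispecies-coalescent log density of a gene tree
#'
#' Sum over species-tree branches of `log(2/theta)` per coalescence and
#' `-j(j-1) dt / theta` per interval with `j` lineages. Returns `-Inf` for
#' gene trees incompatible with the species tree (a coalescence younger than
#' the divergence time of the species it would have to join) — the sentinel
#' used by the MCMC engines to reject invalid proposals.
#'
#' @param gtree a `gene_tree`.
#' @param model a `species_tree_model` whose tip labels match the gene tree's
#'   population labels.
#' @return log density (or `-Inf`).
#' @export
msc_logdensity <- function(gtree, model) {
  validate_species_tree(model)
  gc <- .gene_to_c(gtree)
  tipmap <- match(gtree$pop[gc$labels], model$phy$tip.label) - 1L
  if (anyNA(tipmap)) stop("gene tree populations not found on species tree")
  .cd_msc_logdensity(gc$par, gc$age, tipmap, .phylo_parents0(model$phy),
                     model$tau, model$theta)
}

## ---- priors ----

#' Prior configuration for species delimitation
#'
#' Diffuse gamma priors `G(shape, rate)` on the root divergence time tau0 and
#' on every population size theta; divergence times of non-root split nodes
#' given tau0 follow the uniform (symmetric Dirichlet, alpha = 1) density on
#' the order polytope of the split nodes. The delimitation-model prior is
#' uniform over the models generated by the guide tree (or, optionally,
#' proportional to the number of ranked labeled histories of each model).
#'
#' The two study presets match the simulated truths: low rate `tau0 ~
#' G(1, 333)` (mean 0.003), `theta ~ G(1, 500)` (mean 0.002); high rate
#' `tau0 ~ G(1, 33)`, `theta ~ G(1, 50)`.
#'
#' @param rate `"low"` or `"high"` preset; ignored if the shapes/rates are
#'   given explicitly.
#' @param tau_shape,tau_rate gamma prior on tau0.
#' @param theta_shape,theta_rate gamma prior on each theta.
#' @param model_prior `"uniform"` or `"ranked"`.
#' @return a `prior_config` list.
#' @export
delim_prior <- function(rate = c("low", "high"), tau_shape = 1,
                        tau_rate = NULL, theta_shape = 1, theta_rate = NULL,
                        model_prior = c("uniform", "ranked")) {
  rate <- match.arg(rate)
  model_prior <- match.arg(model_prior)
  if (is.null(tau_rate)) tau_rate <- if (rate == "low") 333 else 33
  if (is.null(theta_rate)) theta_rate <- if (rate == "low") 500 else 50
  stopifnot(tau_shape > 0, tau_rate > 0, theta_shape > 0, theta_rate > 0)
  structure(list(tau_shape = tau_shape, tau_rate = tau_rate,
                 theta_shape = theta_shape, theta_rate = theta_rate,
                 model_prior = model_prior),
            class = "prior_config")
}

#' Delimitation state (reference representation)
#'
#' A plain-R representation of the reversible-jump state used for validation
#' and for the reference-level proposal bookkeeping in [propose_split()]. The MCMC
#' engine keeps its own equivalent internal state.
#'
#' @param guide rooted binary `phylo` over populations.
#' @param split logical vector over internal nodes (ape ids `Ntip+1 ..`),
#'   ancestor-closed: a node may be split only if its parent is split.
#' @param tau numeric per node id (0 at collapsed/tip nodes).
#' @param theta numeric per node id (`NA` at inactive nodes). Active nodes are
#'   the root and every node whose parent is split.
#' @param gene_trees optional list of `gene_tree` (needed by proposal ops).
#' @return a `delim_state` list.
#' @export
delim_state <- function(guide, split, tau, theta, gene_trees = list()) {
  ntip <- ape::Ntip(guide)
  n <- ntip + guide$Nnode
  stopifnot(length(split) == guide$Nnode, length(tau) == n,
            length(theta) == n)
  st <- structure(list(guide = guide, split = split, tau = tau,
                       theta = theta, gene_trees = gene_trees),
                  class = "delim_state")
  validate_delim_state(st)
  st
}

.guide_parent <- function(guide) {
  par <- rep(NA_integer_, ape::Ntip(guide) + guide$Nnode)
  par[guide$edge[, 2]] <- guide$edge[, 1]
  par
}

.is_split <- function(st, v) {
  ntip <- ape::Ntip(st$guide)
  v > ntip && isTRUE(st$split[v - ntip])
}

#' Validate a delimitation state
#' @param st a `delim_state`.
#' @return the state, invisibly; errors on violated invariants.
#' @export
validate_delim_state <- function(st) {
  guide <- st$guide
  ntip <- ape::Ntip(guide)
  par <- .guide_parent(guide)
  root <- .root_node(guide)
  for (v in (ntip + 1L):(ntip + guide$Nnode)) {
    if (.is_split(st, v) && v != root && !.is_split(st, par[v]))
      stop("split set is not ancestor-closed at node ", v)
    if (.is_split(st, v)) {
      if (st$tau[v] <= 0) stop("split node ", v, " must have tau > 0")
      if (v != root && st$tau[par[v]] <= st$tau[v])
        stop("tau must decrease from root to tips")
    } else if (st$tau[v] != 0) {
      stop("collapsed node ", v, " must have tau = 0")
    }
  }
  invisible(st)
}

#' Log prior density of a delimitation state
#'
#' Gamma log density on tau0 and on each active theta; the uniform
#' order-polytope density `prod(h_v) / tau0^k` on the `k` non-root split ages
#' (with `h_v` the number of split non-root nodes in the subtree of `v`); and
#' the log mass of the delimitation model itself.
#'
#' @param st a `delim_state`.
#' @param prior a [delim_prior()] configuration.
#' @return log prior density.
#' @export
log_prior_delimitation <- function(st, prior) {
  validate_delim_state(st)
  guide <- st$guide
  ntip <- ape::Ntip(guide)
  par <- .guide_parent(guide)
  root <- .root_node(guide)
  lp <- 0
  ## theta terms for active lineages
  for (v in seq_len(ntip + guide$Nnode)) {
    if (v == root || .is_split(st, par[v]))
      lp <- lp + dgamma(st$theta[v], prior$theta_shape,
                        rate = prior$theta_rate, log = TRUE)
  }
  ## tau terms
  if (.is_split(st, root)) {
    t0 <- st$tau[root]
    lp <- lp + dgamma(t0, prior$tau_shape, rate = prior$tau_rate, log = TRUE)
    h <- integer(ntip + guide$Nnode)
    ord <- ape::reorder.phylo(guide, "postorder")
    ch <- .children_list(guide)
    k <- 0
    for (v in unique(ord$edge[, 1])) {  # postorder internal nodes
      if (!.is_split(st, v)) next
      h[v] <- 1L + sum(h[ch[[v]]])
      if (v != root) {
        k <- k + 1
        lp <- lp + log(h[v])
      }
    }
    lp <- lp - k * log(t0)
  }
  ## model mass
  if (prior$model_prior == "uniform") {
    lp <- lp - log(n_delim_models(guide))
  } else {
    split_nodes <- which(st$split) + ntip
    lp <- lp + .log_ranked_histories(guide, split_nodes) -
      .log_total_ranked(guide)
  }
  lp
}

## number of ranked histories of the model tree defined by `split_nodes`
.log_ranked_histories <- function(guide, split_nodes) {
  ntip <- ape::Ntip(guide)
  ch <- .children_list(guide)
  r <- integer(ntip + guide$Nnode)
  ord <- unique(ape::reorder.phylo(guide, "postorder")$edge[, 1])
  lp <- 0
  s <- 0
  for (v in ord) {
    if (!(v %in% split_nodes)) next
    r[v] <- 1L + sum(r[ch[[v]]])
    s <- s + 1
    lp <- lp - log(r[v])
  }
  lp + lgamma(s + 1)
}

.log_total_ranked <- function(guide) {
  ntip <- ape::Ntip(guide)
  models <- enumerate_models(guide)
  w <- vapply(seq_len(nrow(models)), function(i) {
    .log_ranked_histories(guide, ntip + which(models[i, ]))
  }, 0)
  m <- max(w)
  m + log(sum(exp(w - m)))
}
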