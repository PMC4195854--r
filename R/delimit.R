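## Bayesian species delimitation on a fixed guide tree by reversible-jump
## MCMC over node collapse/split models, plus model enumeration and the
## spec-level split-proposal bookkeeping used in validation.

#' Enumerate delimitation models of a guide tree
#'
#' A delimitation model is an ancestor-closed set of split interior nodes
#' (a node may be split only if its parent is split; the root may always be
#' split). The number of models obeys `N(tip) = 1`,
#' `N(node) = 1 + N(left) * N(right)`.
#'
#' @param guide rooted binary `phylo`.
#' @return logical matrix, one row per model, one column per interior node
#'   (columns named by clade key); `TRUE` = split.
#' @export
enumerate_models <- function(guide) {
  ntip <- ape::Ntip(guide)
  ch <- .children_list(guide)
  nint <- guide$Nnode
  rec <- function(v) {
    ## returns list of integer vectors of split node ids within subtree(v)
    if (v <= ntip) return(list(integer(0)))
    l <- rec(ch[[v]][1]); r <- rec(ch[[v]][2])
    out <- list(integer(0))
    for (a in l) for (b in r) out[[length(out) + 1L]] <- c(v, a, b)
    out
  }
  models <- rec(.root_node(guide))
  m <- matrix(FALSE, length(models), nint)
  for (i in seq_along(models)) m[i, models[[i]] - ntip] <- TRUE
  cl <- tree_clades(guide)
  colnames(m) <- names(cl)
  m
}

#' Number of delimitation models of a guide tree
#' @param guide rooted binary `phylo`.
#' @return integer count.
#' @export
n_delim_models <- function(guide) {
  ntip <- ape::Ntip(guide)
  ch <- .children_list(guide)
  rec <- function(v) {
    if (v <= ntip) return(1)
    1 + rec(ch[[v]][1]) * rec(ch[[v]][2])
  }
  rec(.root_node(guide))
}

#' Signature string of a delimitation model
#'
#' Split clades sorted and joined with `";"`; the fully collapsed one-species
#' model is `"(none)"`. Used as a stable model key by [delimit()] and
#' [oracle_model_posterior()].
#'
#' @param guide rooted binary `phylo`.
#' @param split logical vector over interior nodes (ape order).
#' @return character scalar.
#' @export
model_signature <- function(guide, split) {
  if (!any(split)) return("(none)")
  keys <- names(tree_clades(guide))[which(split)]
  paste(sort(keys), collapse = ";")
}

## ---- spec-level split/merge proposal bookkeeping ----

.split_upper_bound_r <- function(st, v) {
  guide <- st$guide
  ntip <- ape::Ntip(guide)
  par <- .guide_parent(guide)
  desc <- .tip_descendants(guide)
  ch <- .children_list(guide)
  side1 <- desc[[ch[[v]][1]]]; side2 <- desc[[ch[[v]][2]]]
  sub <- desc[[v]]
  U <- if (!is.na(par[v]) && .is_split(st, par[v])) st$tau[par[v]] else Inf
  for (gt in st$gene_trees) {
    gdesc <- .tip_descendants(gt$phy)
    ages <- node_ages(gt$phy)
    gntip <- ape::Ntip(gt$phy)
    for (g in (gntip + 1L):(gntip + gt$phy$Nnode)) {
      pops <- unique(gt$pop[gdesc[[g]]])
      if (all(pops %in% sub) && any(pops %in% side1) && any(pops %in% side2))
        U <- min(U, ages[g])
    }
  }
  U
}

#' Propose splitting a collapsed guide-tree node
#'
#' The reversible-jump split proposal: a new divergence time `tau_v ~
#' U(0, U)`, where `U` is the smaller of the parent's tau and the youngest
#' gene-tree coalescence that joins lineages from the two daughter
#' populations groups, and new thetas for the two daughter lineages drawn
#' from their gamma prior (so their prior and proposal densities cancel).
#' Returns the proposed state together with the log Metropolis-Hastings-Green
#' components; the move is rejected outright when `U = 0` (a gene tree
#' coalesces across the daughters immediately).
#'
#' @param st a `delim_state` with gene trees.
#' @param node ape id of a collapsed interior node whose parent is split (or
#'   the root).
#' @param prior a [delim_prior()].
#' @return list with `state` (proposed `delim_state`), `U`, and
#'   `log_components` (named: `prior`, `msc_change_needed`, `proposal`); or
#'   a list with `rejected = TRUE` and a `reason`.
#' @export
propose_split <- function(st, node, prior) {
  validate_delim_state(st)
  guide <- st$guide
  ntip <- ape::Ntip(guide)
  par <- .guide_parent(guide)
  root <- .root_node(guide)
  ch <- .children_list(guide)
  if (node <= ntip) stop("cannot split a tip")
  if (.is_split(st, node)) stop("node is already split")
  if (node != root && !.is_split(st, par[node]))
    stop("parent must be split (ancestor closure)")
  U <- .split_upper_bound_r(st, node)
  if (U <= 0)
    return(list(rejected = TRUE, reason = "immediate cross-coalescence (U = 0)"))
  tau_new <- runif(1, 0, U)
  th <- rgamma(2, prior$theta_shape, rate = prior$theta_rate)
  new <- st
  new$split[node - ntip] <- TRUE
  new$tau[node] <- tau_new
  new$theta[ch[[node]]] <- th
  lp_new <- log_prior_delimitation(new, prior)
  lp_old <- log_prior_delimitation(st, prior)
  ## theta prior terms of the two fresh draws cancel against the proposal
  dprior <- lp_new - lp_old -
    sum(dgamma(th, prior$theta_shape, rate = prior$theta_rate, log = TRUE))
  list(state = new, U = U,
       log_components = c(prior = dprior, proposal = log(U)))
}

.active_nodes <- function(st) {
  guide <- st$guide
  ntip <- ape::Ntip(guide)
  par <- .guide_parent(guide)
  root <- .root_node(guide)
  which(vapply(seq_len(ntip + guide$Nnode), function(v)
    v == root || .is_split(st, par[v]), TRUE))
}

#' Merge a split guide-tree node (reverse of [propose_split()])
#' @param st a `delim_state`.
#' @param node ape id of a split node whose children are both collapsed.
#' @return the merged `delim_state`.
#' @export
propose_merge <- function(st, node) {
  validate_delim_state(st)
  ntip <- ape::Ntip(st$guide)
  ch <- .children_list(st$guide)
  if (!.is_split(st, node)) stop("node is not split")
  for (c in ch[[node]])
    if (.is_split(st, c)) stop("children must be collapsed before merging")
  new <- st
  new$split[node - ntip] <- FALSE
  new$tau[node] <- 0
  new$theta[ch[[node]]] <- NA_real_
  new
}

## ---- main rjMCMC driver ----

#' Control settings for the delimitation rjMCMC
#'
#' Defaults mirror the study protocol: burn-in 5000 sweeps, 20,000 samples
#' taken every 2 sweeps, two independent runs combined. `algorithm` is a
#' provenance tag only (the stationary distribution does not depend on the
#' proposal kernel; this implementation uses its own split proposal, see
#' [propose_split()]).
#'
#' @param burnin,nsamples,sample_every chain schedule (in sweeps).
#' @param runs number of independent runs to combine.
#' @param algorithm provenance tag.
#' @return a `delim_control` list.
#' @export
delim_control <- function(burnin = 5000, nsamples = 20000, sample_every = 2,
                          runs = 2, algorithm = "0;e=2") {
  stopifnot(burnin >= 0, nsamples > 0, sample_every >= 1, runs >= 1)
  structure(list(burnin = as.integer(burnin), nsamples = as.integer(nsamples),
                 sample_every = as.integer(sample_every),
                 runs = as.integer(runs), algorithm = algorithm),
            class = "delim_control")
}

.pop_distance_heights <- function(loci, popmap, guide) {
  ## mean JC distance between the population groups under each guide node
  pops <- guide$tip.label
  D <- NULL
  for (aln in loci) {
    d <- ape::dist.dna(.as_dnabin(aln), model = "JC69",
                       pairwise.deletion = FALSE, as.matrix = TRUE)
    d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
    if (is.null(D)) D <- d * 0
    D <- D + d / length(loci)
  }
  labs <- rownames(D)
  desc <- .tip_descendants(guide)
  ch <- .children_list(guide)
  ntip <- ape::Ntip(guide)
  tau <- numeric(ntip + guide$Nnode)
  ord <- unique(ape::reorder.phylo(guide, "postorder")$edge[, 1])
  for (v in ord) {
    g1 <- labs[popmap[labs] %in% desc[[ch[[v]][1]]]]
    g2 <- labs[popmap[labs] %in% desc[[ch[[v]][2]]]]
    tau[v] <- mean(D[g1, g2]) / 2
    tau[v] <- max(tau[v], 1e-6, 1.0001 * max(tau[ch[[v]]]))
  }
  within <- numeric(0)
  for (p in pops) {
    g <- labs[popmap[labs] == p]
    if (length(g) > 1) within <- c(within, mean(D[g, g][upper.tri(D[g, g])]))
  }
  theta0 <- max(mean(within), 1e-4)
  if (!is.finite(theta0)) theta0 <- 1e-3
  list(tau = tau, theta0 = theta0)
}

.locus_to_c <- function(aln, popmap, pops, gtree) {
  pat <- compress_patterns(aln)
  gc <- .gene_to_c(gtree, label_order = pat$labels)
  list(state = pat$states, w = pat$weights,
       pop = match(popmap[pat$labels], pops) - 1L,
       par = gc$par, age = gc$age)
}

#' Bayesian species delimitation by reversible-jump MCMC
#'
#' Samples delimitation models generated by collapsing/splitting nodes of a
#' fixed rooted guide tree, jointly with divergence times, population sizes
#' and per-locus gene trees, targeting the posterior under the multispecies
#' coalescent with JC69 likelihoods. Runs `control$runs` independent chains
#' (fresh starting gene trees each) and pools their samples.
#'
#' @param loci list of nuclear alignment matrices.
#' @param guide rooted binary `phylo` over the populations.
#' @param popmap named character vector mapping sequences to populations.
#' @param prior a [delim_prior()].
#' @param control a [delim_control()].
#' @param likelihood_off replace the sequence likelihood by 1 (prior
#'   validation runs).
#' @param check_states assert ancestor closure and gene-tree compatibility at
#'   every retained sample.
#' @return object of class `delim_fit`: per-node posterior split
#'   probabilities keyed by clade tip set, per-model posterior probabilities,
#'   per-run probabilities (consistency diagnostics), tau0/theta samples and
#'   acceptance rates.
#' @export
delimit <- function(loci, guide, popmap, prior = delim_prior("low"),
                    control = delim_control(), likelihood_off = FALSE,
                    check_states = FALSE) {
  if (inherits(loci, "matrix")) loci <- list(loci)
  stopifnot(length(loci) >= 1, inherits(guide, "phylo"))
  for (aln in loci) .check_popmap(rownames(aln), popmap)
  pops <- guide$tip.label
  if (!setequal(unique(popmap[unlist(lapply(loci, rownames))]), pops))
    stop("guide tree tips must match the populations in the population map")
  ntip <- ape::Ntip(guide)
  nnode <- ntip + guide$Nnode
  par0 <- .phylo_parents0(guide)

  init <- .pop_distance_heights(loci, popmap, guide)
  split0 <- c(rep(FALSE, ntip), rep(TRUE, guide$Nnode))  # per node; tips never split
  theta0 <- rep(init$theta0, nnode)

  init_model <- structure(list(phy = clock_tree(guide, init$tau),
                               tau = init$tau, theta = theta0,
                               scaled = FALSE), class = "species_tree_model")
  counts <- table(popmap)

  run_one <- function() {
    cl <- lapply(loci, function(aln) {
      gt <- sim_gene_tree(init_model, counts[pops])
      ## rename simulated tips (pop_i) to actual sequence labels, per pop
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
    .cd_rjmcmc(cl, par0, split0, init$tau * ifelse(seq_len(nnode) > ntip, 1, 0),
               theta0, prior$tau_shape, prior$tau_rate, prior$theta_shape,
               prior$theta_rate, ifelse(prior$model_prior == "uniform", 0L, 1L),
               control$burnin, control$nsamples, control$sample_every,
               likelihood_off, check_states)
  }

  runs <- lapply(seq_len(control$runs), function(i) run_one())

  clade_keys <- names(tree_clades(guide))
  int_cols <- (ntip + 1L):nnode
  per_run <- vapply(runs, function(r) colMeans(r$split[, int_cols, drop = FALSE]),
                    numeric(guide$Nnode))
  split_all <- do.call(rbind, lapply(runs, `[[`, "split"))
  split_prob <- setNames(colMeans(split_all[, int_cols, drop = FALSE]),
                         clade_keys)

  sigs <- apply(split_all[, int_cols, drop = FALSE] == 1L, 1L, function(s)
    model_signature(guide, s))
  model_post <- sort(table(sigs) / length(sigs), decreasing = TRUE)

  structure(list(
    guide = guide,
    split_prob = split_prob,
    per_run = matrix(per_run, nrow = guide$Nnode,
                     dimnames = list(clade_keys, NULL)),
    model_post = setNames(as.numeric(model_post), names(model_post)),
    tau0 = unlist(lapply(runs, `[[`, "tau_root")),
    theta_root = unlist(lapply(runs, `[[`, "theta_root")),
    acc = list(rj = vapply(runs, `[[`, 0, "acc_rj"),
               theta = vapply(runs, `[[`, 0, "acc_theta"),
               scale = vapply(runs, `[[`, 0, "acc_scale")),
    n_samples = nrow(split_all),
    prior = prior, control = control
  ), class = "delim_fit")
}

#' @export
print.delim_fit <- function(x, ...) {
  cat("Bayesian species delimitation (rjMCMC on a fixed guide tree)\n")
  cat(sprintf("  %d populations, %d pooled samples from %d run(s)\n",
              ape::Ntip(x$guide), x$n_samples, x$control$runs))
  cat("  posterior split probabilities:\n")
  for (k in names(x$split_prob))
    cat(sprintf("    %-30s %.4f\n", k, x$split_prob[k]))
  invisible(x)
}

#' @export
summary.delim_fit <- function(object, ...) {
  run_disagreement <- if (ncol(object$per_run) > 1)
    max(abs(object$per_run[, 1] - object$per_run[, 2])) else NA_real_
  out <- list(split_prob = object$split_prob,
              model_post = object$model_post,
              tau0_mean = mean(object$tau0[object$tau0 > 0]),
              run_disagreement = run_disagreement,
              acc = object$acc)
  class(out) <- "summary.delim_fit"
  out
}

#' @export
print.summary.delim_fit <- function(x, ...) {
  cat("Split probabilities:\n"); print(round(x$split_prob, 4))
  cat("Top models:\n"); print(round(head(x$model_post, 8), 4))
  cat(sprintf("Mean tau0 (root split samples): %.5f\n", x$tau0_mean))
  if (!is.na(x$run_disagreement))
    cat(sprintf("Max between-run split-probability gap: %.4f\n",
                x$run_disagreement))
  invisible(x)
}
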