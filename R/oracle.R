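## Exhaustive-enumeration posterior oracle for small delimitation problems.
##
## For each delimitation model the marginal likelihood is computed by an
## exhaustive sum over rooted labeled gene-tree topologies, branch
## assignments and within-branch event orders, with numerical (Gauss-
## Legendre) integration over coalescent times and divergence times.
## Population-size parameters are integrated analytically: a gamma prior
## G(a, b) against the per-branch coalescent kernel 2^c theta^-c exp(-A /
## theta) has the closed form 2^c * 2 b^a / Gamma(a) * (A/b)^((a-c)/2) *
## BesselK(2 sqrt(A b), a-c), which keeps the quadrature at most
## four-dimensional for the supported problem sizes.

.gauss_legendre01 <- function(n) {
  ## nodes/weights on (0,1) via the Golub-Welsch eigen decomposition
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- (e$vectors[1, ])^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

## all rooted labeled binary topologies on tip indices `tips`; each node is
## list(tips=..., left=..., right=...) or a leaf list(tips=i)
.rooted_topologies <- function(tips) {
  n <- length(tips)
  if (n == 1) return(list(list(tips = tips)))
  out <- list()
  ## subsets containing the first tip (avoids double counting)
  others <- tips[-1]
  for (k in 0:(length(others) - 1)) {
    for (sub in if (k == 0) list(integer(0)) else
         utils::combn(others, k, simplify = FALSE)) {
      left_tips <- c(tips[1], sub)
      right_tips <- setdiff(tips, left_tips)
      for (l in .rooted_topologies(left_tips))
        for (r in .rooted_topologies(right_tips))
          out[[length(out) + 1L]] <- list(tips = tips, left = l, right = r)
    }
  }
  out
}

## flatten a topology into parent/child arrays; tips 1..N first
.topo_arrays <- function(topo, N) {
  par <- integer(2 * N - 1); ch <- vector("list", 2 * N - 1)
  nid <- N
  build <- function(node) {
    if (length(node$tips) == 1) return(node$tips)
    nid <<- nid + 1L
    me <- nid
    l <- build(node$left); r <- build(node$right)
    par[l] <<- me; par[r] <<- me
    ch[[me]] <<- c(l, r)
    me
  }
  root <- build(topo)
  list(par = par, ch = ch, root = root, N = N)
}

.log_bessel_theta_integral <- function(c, A, a, b) {
  ## log integral over theta of G(theta; a, b) * 2^c theta^-c exp(-A/theta)
  out <- numeric(length(A))
  zero <- A <= 0
  out[zero] <- if (c == 0) 0 else -Inf
  if (any(!zero)) {
    A1 <- A[!zero]
    out[!zero] <- c * log(2) + a * log(b) - lgamma(a) + log(2) +
      ((a - c) / 2) * (log(A1) - log(b)) +
      log(besselK(2 * sqrt(A1 * b), nu = a - c, expon.scaled = TRUE)) -
      2 * sqrt(A1 * b)
  }
  out
}

.lse <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## linear extensions of a partial order given as a logical precedence matrix
.linear_extensions <- function(prec) {
  n <- nrow(prec)
  if (n == 0) return(list(integer(0)))
  out <- list()
  rec <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (x in remaining) {
      if (!any(prec[remaining, x] & remaining != x))
        rec(setdiff(remaining, x), c(acc, x))
    }
  }
  rec(seq_len(n), integer(0))
  out
}

#' Exact model posterior by enumeration and quadrature
#'
#' Exhaustive posterior over delimitation models for small problems (at most
#' 3 populations, at most 2 sequences per population, at most 4 sequences in
#' total, one locus); refuses anything larger. Used as the independent
#' verification oracle for [delimit()].
#'
#' @param aln single-locus alignment matrix.
#' @param guide rooted guide tree over the populations.
#' @param popmap named character vector.
#' @param prior a [delim_prior()] (uniform model prior).
#' @param n_tau,n_age Gauss-Legendre node counts for the divergence-time and
#'   coalescent-age dimensions.
#' @return named numeric vector of model posterior probabilities (names from
#'   [model_signature()]), summing to 1.
#' @export
oracle_model_posterior <- function(aln, guide, popmap, prior,
                                   n_tau = 16, n_age = 12) {
  validate_alignment(aln)
  P <- ape::Ntip(guide)
  if (P == 1L) return(c("(none)" = 1))  # one population: nothing to delimit
  N <- nrow(aln)
  counts <- table(popmap[rownames(aln)])
  if (P > 3 || N > 4 || any(counts > 2))
    stop("problem too large for the enumeration oracle ",
         "(max 3 populations, 2 sequences each, 4 sequences total)")
  if (prior$model_prior != "uniform")
    stop("the oracle assumes the uniform model prior")
  pat <- compress_patterns(aln)
  labs <- pat$labels
  tip_pop <- popmap[labs]
  pops <- guide$tip.label
  gl_t <- .gauss_legendre01(n_tau)
  gl_a <- .gauss_legendre01(n_age)
  models <- enumerate_models(guide)
  ntip_g <- ape::Ntip(guide)
  gpar <- .guide_parent(guide)
  groot <- .root_node(guide)
  gch <- .children_list(guide)
  gdesc <- .tip_descendants(guide)
  topos <- .rooted_topologies(seq_len(N))

  marg <- numeric(nrow(models))
  for (mi in seq_len(nrow(models))) {
    split <- rep(FALSE, ntip_g + guide$Nnode)
    split[ntip_g + which(models[mi, ])] <- TRUE
    ## contracted model tree over guide nodes
    active <- vapply(seq_len(ntip_g + guide$Nnode), function(v)
      v == groot || (!is.na(gpar[v]) && split[gpar[v]]), TRUE)
    anodes <- which(active)
    aidx <- match(seq_along(active), anodes)  # guide node -> model index
    mpar <- vapply(anodes, function(v)
      if (v == groot) NA_integer_ else aidx[gpar[v]], 0L)
    is_mtip <- !split[anodes]
    nmod <- length(anodes)
    ## lineage holding each population
    cur <- vapply(seq_len(P), function(p) {
      v <- p
      while (v != groot && !split[gpar[v]]) v <- gpar[v]
      aidx[v]
    }, 0L)
    tip_lin <- cur[match(tip_pop, pops)]        # per gene tip, model node
    nin_tip <- tabulate(tip_lin, nbins = nmod)  # samples entering each tip
    ## split nodes as model indices, ordered root-first (chain for P <= 3)
    split_m <- which(!is_mtip)
    depth_m <- integer(nmod)
    for (v in seq_len(nmod)) {
      d <- 0; x <- v
      while (!is.na(mpar[x])) { d <- d + 1; x <- mpar[x] }
      depth_m[v] <- d
    }
    split_m <- split_m[order(depth_m[split_m])]
    k_tau <- length(split_m)
    mroot <- which(is.na(mpar))

    ## tau grids (qgamma transform for the root, uniform fractions below;
    ## valid because the split nodes form a chain when P <= 3)
    if (k_tau == 0) {
      tau_grid <- matrix(0, 1, 0); tau_w <- 1
    } else {
      grids <- list(stats::qgamma(gl_t$x, prior$tau_shape,
                                  rate = prior$tau_rate))
      wlist <- list(gl_t$w)
      if (k_tau >= 2) {
        for (j in 2:k_tau) { grids[[j]] <- gl_t$x; wlist[[j]] <- gl_t$w }
      }
      eg <- expand.grid(grids)
      ew <- apply(expand.grid(wlist), 1, prod)
      tau_grid <- as.matrix(eg)
      if (k_tau >= 2) for (j in 2:k_tau)
        tau_grid[, j] <- tau_grid[, j] * tau_grid[, j - 1]
      ## Jacobian of tau_j = u_j * tau_{j-1} cancels against the polytope
      ## density 1/tau0 (h_v = 1 on a chain), so weights need no extra factor
      tau_w <- ew
    }

    logvals <- numeric(0)
    for (ti in seq_len(nrow(tau_grid))) {
      tau_m <- numeric(nmod)
      tau_m[split_m] <- tau_grid[ti, ]
      tval <- vapply(topos, function(topo) {
        ta <- .topo_arrays(topo, N)
        .log_topo_integral(ta, tau_m, mpar, mroot, tip_lin,
                           nin_tip, pat, prior, gl_a)
      }, 0)
      logvals <- c(logvals, log(tau_w[ti]) + .lse(tval))
    }
    marg[mi] <- .lse(logvals)
  }
  post <- exp(marg - .lse(marg))
  names(post) <- apply(models, 1, function(s) model_signature(guide, s))
  post
}

## log integral over coalescent ages for one gene topology, at fixed tau
.log_topo_integral <- function(ta, tau_m, mpar, mroot, tip_lin, nin_tip, pat,
                               prior, gl_a) {
  N <- ta$N
  events <- (N + 1):(2 * N - 1)
  nev <- length(events)
  nmod <- length(tau_m)
  ## model-node MRCA of each gene node
  mdepth <- integer(nmod)
  for (v in seq_len(nmod)) {
    d <- 0; x <- v
    while (!is.na(mpar[x])) { d <- d + 1; x <- mpar[x] }
    mdepth[v] <- d
  }
  mmrca <- function(a, b) {
    while (a != b) if (mdepth[a] < mdepth[b]) b <- mpar[b] else a <- mpar[a]
    a
  }
  node_m <- integer(2 * N - 1)
  node_m[seq_len(N)] <- tip_lin
  for (e in events[order(vapply(events, function(e)
    length(.gather_tips(ta, e)), 0))]) {
    cc <- ta$ch[[e]]
    node_m[e] <- mmrca(node_m[cc[1]], node_m[cc[2]])
  }
  ## path from mrca to root = allowed branches per event
  allowed <- lapply(events, function(e) {
    v <- node_m[e]; out <- v
    while (!is.na(mpar[v])) { v <- mpar[v]; out <- c(out, v) }
    out
  })
  logtotal <- numeric(0)
  ## enumerate assignments (events indexed 1..nev in `events` order)
  idx <- rep(1L, nev)
  repeat {
    alpha <- vapply(seq_len(nev), function(i) allowed[[i]][idx[i]], 0L)
    names(alpha) <- NULL
    if (.assignment_consistent(ta, events, alpha, mpar, mdepth))
      logtotal <- c(logtotal,
                    .log_assignment_integral(ta, events, alpha, tau_m, mpar,
                                             mroot, tip_lin, nin_tip, pat,
                                             prior, gl_a))
    ## advance mixed-radix counter
    j <- 1L
    while (j <= nev) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(allowed[[j]])) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > nev) break
  }
  .lse(logtotal)
}

.gather_tips <- function(ta, v) {
  if (v <= ta$N) return(v)
  unlist(lapply(ta$ch[[v]], .gather_tips, ta = ta))
}

.assignment_consistent <- function(ta, events, alpha, mpar, mdepth) {
  ## event's branch must be ancestral-or-equal to its children's branches
  anc_or_eq <- function(a, b) {  # is a ancestor-or-equal of b?
    while (!is.na(b) && mdepth[b] >= mdepth[a]) {
      if (a == b) return(TRUE)
      b <- mpar[b]
    }
    a == b && !is.na(b)
  }
  for (i in seq_along(events)) {
    e <- events[i]
    for (c in ta$ch[[e]]) {
      if (c <= ta$N) next
      j <- match(c, events)
      if (!anc_or_eq(alpha[i], alpha[j]) && alpha[i] != alpha[j])
        return(FALSE)
    }
  }
  TRUE
}

.log_assignment_integral <- function(ta, events, alpha, tau_m, mpar, mroot,
                                     tip_lin, nin_tip, pat, prior, gl_a) {
  nev <- length(events)
  ## within-branch precedence from the gene-tree ancestry, then enumerate
  ## the within-branch event orders (linear extensions)
  prec <- matrix(FALSE, nev, nev)  # prec[i, j]: event i before event j
  anc <- function(a, b) {  # gene node a strict ancestor of gene node b?
    v <- b
    repeat {
      v <- if (ta$par[v] == 0) NA else ta$par[v]
      if (is.na(v)) return(FALSE)
      if (v == a) return(TRUE)
    }
  }
  for (i in seq_len(nev)) for (j in seq_len(nev)) {
    if (i != j && alpha[i] == alpha[j] && anc(events[j], events[i]))
      prec[i, j] <- TRUE
  }
  ## candidate within-branch total orders = linear extensions of prec
  ## restricted branch-wise; equivalently: linear extensions of prec with
  ## the constraint applied only within branches. Enumerate global orders of
  ## all events consistent with gene ancestry, then dedupe by within-branch
  ## order.
  full_prec <- matrix(FALSE, nev, nev)
  for (i in seq_len(nev)) for (j in seq_len(nev))
    if (i != j && anc(events[j], events[i])) full_prec[i, j] <- TRUE
  exts <- .linear_extensions(full_prec)
  seen <- character(0)
  logtotal <- numeric(0)
  for (ext in exts) {
    key <- paste(vapply(sort(unique(alpha)), function(b)
      paste(ext[alpha[ext] == b], collapse = ","), ""), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    logtotal <- c(logtotal,
                  .log_region_integral(ta, events, alpha, ext, tau_m, mpar,
                                       mroot, tip_lin, nin_tip, pat, prior,
                                       gl_a))
  }
  .lse(logtotal)
}

.log_region_integral <- function(ta, events, alpha, ord, tau_m, mpar, mroot,
                                 tip_lin, nin_tip, pat, prior, gl_a) {
  nev <- length(events)
  npts <- length(gl_a$x)
  s_scale <- prior$theta_shape / prior$theta_rate + 1e-6  # root-branch decay
  ## sequentially build the age grid in the order `ord`
  ages <- vector("list", nev)     # per event, vector over grid
  weight <- 1                     # vector over grid
  gsize <- 1
  age_of <- function(v, grid_len) {
    if (v <= ta$N) return(rep(0, grid_len))
    a <- ages[[match(v, events)]]
    if (length(a) < grid_len) a <- rep(a, each = grid_len / length(a))
    a
  }
  for (i in ord) {
    e <- events[i]
    b <- alpha[i]
    new_gsize <- gsize * npts
    lo <- rep(tau_m[b], new_gsize)
    for (c in ta$ch[[e]]) lo <- pmax(lo, rep(age_of(c, gsize), each = npts))
    ## within-branch predecessor
    pos <- match(i, ord[alpha[ord] == b])
    if (!is.na(pos) && pos > 1) {
      predi <- ord[alpha[ord] == b][pos - 1]
      lo <- pmax(lo, rep(age_of(events[predi], gsize), each = npts))
    }
    u <- rep(gl_a$x, times = gsize)
    w <- rep(gl_a$w, times = gsize)
    weight <- rep(weight, each = npts)
    if (is.na(mpar[b])) {
      t_e <- lo - s_scale * log(1 - u)
      weight <- weight * w * s_scale / (1 - u)
    } else {
      hi <- tau_m[mpar[b]]
      len <- pmax(hi - lo, 0)
      t_e <- lo + u * len
      weight <- weight * w * len
    }
    ages[[i]] <- t_e
    gsize <- new_gsize
  }
  ## expand all event ages to the final grid size
  A <- matrix(0, gsize, nev)
  for (i in seq_len(nev)) A[, i] <- age_of(events[i], gsize)
  if (all(weight == 0)) return(-Inf)
  ## per-branch coalescent statistics on the model tree
  nmod <- length(tau_m)
  cb <- tabulate(alpha, nbins = nmod)
  nin <- nin_tip
  ## postorder accumulate entering lineages
  mord <- order(-vapply(seq_len(nmod), function(v) {
    d <- 0; x <- v
    while (!is.na(mpar[x])) { d <- d + 1; x <- mpar[x] }
    d
  }, 0))
  for (v in mord) {
    if (is.na(mpar[v])) next
    nin[mpar[v]] <- nin[mpar[v]] + nin[v] - cb[v]
  }
  logfactor <- rep(0, gsize)
  for (b in seq_len(nmod)) {
    if (nin[b] < 2 && cb[b] == 0) next
    ev_b <- ord[alpha[ord] == b]  # events in this branch, in time order
    j <- nin[b]
    t_prev <- rep(tau_m[b], gsize)
    Ab <- rep(0, gsize)
    for (i in ev_b) {
      Ab <- Ab + j * (j - 1) * (A[, i] - t_prev)
      t_prev <- A[, i]
      j <- j - 1
    }
    if (!is.na(mpar[b]))
      Ab <- Ab + j * (j - 1) * (tau_m[mpar[b]] - t_prev)
    logfactor <- logfactor + .log_bessel_theta_integral(
      cb[b], Ab, prior$theta_shape, prior$theta_rate)
  }
  ## JC69 log likelihood of the gene tree over the grid
  loglik <- .grid_log_seq_lik(ta, A, events, pat, gsize)
  .lse(log(pmax(weight, 0)) + logfactor + loglik)
}

.grid_log_seq_lik <- function(ta, A, events, pat, gsize) {
  npat <- length(pat$weights)
  age_vec <- function(v) if (v <= ta$N) rep(0, gsize) else A[, match(v, events)]
  partial <- function(v) {
    ## list of 4 (gsize x npat) matrices
    if (v <= ta$N) {
      st <- pat$states[v, ]
      return(lapply(0:3, function(x)
        matrix(as.numeric(st == x), gsize, npat, byrow = TRUE)))
    }
    out <- NULL
    for (c in ta$ch[[v]]) {
      Lc <- partial(c)
      E <- exp(-4 / 3 * (age_vec(v) - age_vec(c)))
      pdv <- 0.25 * (1 - E)
      S <- Lc[[1]] + Lc[[2]] + Lc[[3]] + Lc[[4]]
      contrib <- lapply(1:4, function(x) pdv * S + E * Lc[[x]])
      out <- if (is.null(out)) contrib else
        lapply(1:4, function(x) out[[x]] * contrib[[x]])
    }
    out
  }
  Lr <- partial(ta$root)
  site <- 0.25 * (Lr[[1]] + Lr[[2]] + Lr[[3]] + Lr[[4]])
  (log(site) %*% pat$weights)[, 1]
}
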