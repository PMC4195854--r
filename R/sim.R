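## Synthetic-data generator: species trees, gene trees under the multispecies
## coalescent, JC69 sequence simulation, and full replicate datasets.
##
## Time (both species divergence times tau and population sizes theta) is
## measured in expected substitutions per site throughout.

#' Species tree models of the simulation study
#'
#' Two four-species trees: tree 1 is the caterpillar `(((A,B),C),D)` with
#' divergence times `(tau_AB, tau_ABC, tau_ABCD)`, tree 2 the balanced
#' `((A,B),(C,D))` with `(tau_AB, tau_CD, tau_ABCD)`. At the low mutation rate
#' the times are `(0.001, 0.002, 0.003)` (tree 1) or `(0.001, 0.001, 0.003)`
#' (tree 2) with theta `0.002` on every branch; the high rate multiplies all
#' values by 10.
#'
#' @param tree_id 1 (caterpillar) or 2 (balanced).
#' @param rate `"low"` or `"high"` mutation rate.
#' @return an object of class `species_tree_model`: list with `phy` (clock
#'   `phylo`), `tau` (node ages), `theta` (per-node population sizes; the
#'   entry of a node is the theta of the branch above it, the root entry is
#'   the ancestral-most population).
#' @export
build_species_tree <- function(tree_id, rate = c("low", "high")) {
  rate <- match.arg(rate)
  if (!tree_id %in% c(1L, 2L)) stop("unknown tree id: ", tree_id)
  mult <- if (rate == "high") 10 else 1
  theta0 <- 0.002 * mult
  if (tree_id == 1L) {
    phy <- parse_newick("(((A,B),C),D);")
    ## ape ids: tips A=1,B=2,C=3,D=4; root=5, ABC=6, AB=7
    tau <- c(0, 0, 0, 0, 0.003, 0.002, 0.001) * mult
  } else {
    phy <- parse_newick("((A,B),(C,D));")
    ## tips A=1,B=2,C=3,D=4; root=5, AB=6, CD=7
    tau <- c(0, 0, 0, 0, 0.003, 0.001, 0.001) * mult
  }
  model <- structure(list(phy = clock_tree(phy, tau), tau = tau,
                          theta = rep(theta0, length(tau)),
                          scaled = FALSE),
                     class = "species_tree_model")
  validate_species_tree(model)
  model
}

#' Validate a species tree model
#' @param model a `species_tree_model`.
#' @return the model, invisibly.
#' @export
validate_species_tree <- function(model) {
  stopifnot(inherits(model, "species_tree_model"))
  phy <- model$phy
  ntip <- ape::Ntip(phy)
  if (any(model$tau[seq_len(ntip)] != 0)) stop("tip ages must be 0")
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    if (model$tau[p] <= model$tau[c])
      stop("parent age must exceed child age")
  }
  if (any(model$theta <= 0)) stop("all theta must be positive")
  invisible(model)
}

#' Locus specification
#'
#' Nuclear loci use the species-tree parameters as-is (500 sites); the
#' mitochondrial locus has a 20-fold higher mutation rate and one quarter the
#' effective population size, i.e. `tau_mt = 20 tau_nuc`, `theta_mt =
#' 5 theta_nuc` (1000 sites).
#'
#' @param kind `"nuclear"` or `"mitochondrial"`.
#' @param length sequence length in sites (defaults: 500 nuclear, 1000 mito).
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(kind = c("nuclear", "mitochondrial"), length = NULL) {
  kind <- match.arg(kind)
  if (is.null(length)) length <- if (kind == "nuclear") 500L else 1000L
  mult <- if (kind == "nuclear") c(tau = 1, theta = 1) else c(tau = 20, theta = 5)
  structure(list(kind = kind, length = as.integer(length),
                 tau_mult = unname(mult["tau"]),
                 theta_mult = unname(mult["theta"])),
            class = "locus_spec")
}

#' Rescale a species tree model for a locus
#'
#' Multiplies all divergence times by the locus tau multiplier and all theta by
#' its theta multiplier. Refuses to rescale a model that has already been
#' scaled for a mitochondrial locus (the operation is not idempotent).
#'
#' @param model a `species_tree_model` on the nuclear scale.
#' @param spec a [locus_spec()].
#' @return a rescaled `species_tree_model`.
#' @export
scale_to_locus <- function(model, spec) {
  validate_species_tree(model)
  stopifnot(inherits(spec, "locus_spec"))
  if (isTRUE(model$scaled) && spec$kind == "mitochondrial")
    stop("model is already scaled for a mitochondrial locus")
  model$tau <- model$tau * spec$tau_mult
  model$theta <- model$theta * spec$theta_mult
  model$phy <- clock_tree(model$phy, model$tau)
  model$scaled <- spec$kind == "mitochondrial"
  model
}

## ---- gene tree simulation under the MSC ----

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within a species-tree branch holding `k` lineages with population size
#' `theta`, the waiting time to the next coalescence is exponential with rate
#' `k(k-1)/theta`; the coalescing pair is uniform; lineages that fail to
#' coalesce before the branch's parent divergence time are passed upward. The
#' root population runs until a single lineage remains.
#'
#' @param model a `species_tree_model`.
#' @param n_per_species named integer vector of sample counts, names matching
#'   the species-tree tip labels.
#' @return object of class `gene_tree`: list with `phy` (clock `phylo` over
#'   sequence labels `<species>_<i>`), `age` (node ages), `pop` (named
#'   character vector, population of each tip).
#' @export
sim_gene_tree <- function(model, n_per_species) {
  validate_species_tree(model)
  phy <- model$phy
  ntip_sp <- ape::Ntip(phy)
  if (is.null(names(n_per_species)))
    names(n_per_species) <- phy$tip.label
  stopifnot(all(phy$tip.label %in% names(n_per_species)),
            all(n_per_species >= 1))
  ch <- .children_list(phy)
  ntot <- sum(n_per_species[phy$tip.label])

  ## gene tree node bookkeeping (grow arrays; ape ids assigned at the end)
  g_par <- integer(0); g_age <- numeric(0); g_lab <- character(0)
  new_node <- function(age, lab = NA_character_) {
    g_age[length(g_age) + 1L] <<- age
    g_par[length(g_par) + 1L] <<- NA_integer_
    g_lab[length(g_lab) + 1L] <<- lab
    length(g_age)
  }
  g_ch <- list()

  ## active lineages per species-tree node, processed tips-first
  lineages <- vector("list", ntip_sp + phy$Nnode)
  for (s in seq_len(ntip_sp)) {
    sp <- phy$tip.label[s]
    n <- n_per_species[[sp]]
    lineages[[s]] <- vapply(seq_len(n), function(i)
      new_node(0, paste0(sp, "_", i)), 0L)
  }

  coalesce_in <- function(lin, t0, t1, theta) {
    ## evolve lineage set from time t0 until t1 (Inf for the root branch)
    t <- t0
    while (length(lin) > 1L) {
      k <- length(lin)
      wait <- rexp(1L, rate = k * (k - 1) / theta)
      if (t + wait >= t1) return(list(lin = lin, t = t1))
      t <- t + wait
      pair <- sample.int(k, 2L)
      anc <- new_node(t)
      g_ch[[anc]] <<- lin[pair]
      g_par[lin[pair]] <<- anc
      lin <- c(lin[-pair], anc)
    }
    list(lin = lin, t = t1)
  }

  ord <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])
  root <- .root_node(phy)
  for (v in c(setdiff(seq_len(ntip_sp + phy$Nnode), c(ord)), ord)) {
    ## iterate species nodes in postorder (tips first, then `ord`)
    if (v %in% ord) {
      lin <- unlist(lapply(ch[[v]], function(c) lineages[[c]]))
    } else {
      lin <- lineages[[v]]
    }
    t0 <- model$tau[v]
    t1 <- if (v == root) Inf else {
      p <- which(vapply(ch, function(x) v %in% x, TRUE))
      model$tau[p]
    }
    res <- coalesce_in(lin, t0, t1, model$theta[v])
    lineages[[v]] <- res$lin
  }
  stopifnot(length(lineages[[root]]) == 1L)

  ## convert to phylo: tips are nodes with no children
  ntot_nodes <- length(g_age)
  is_tip <- !is.na(g_lab)
  stopifnot(sum(is_tip) == ntot)
  id <- integer(ntot_nodes)
  tip_order <- order(g_lab[is_tip])
  id[which(is_tip)[tip_order]] <- seq_len(ntot)
  internal <- which(!is_tip)
  internal <- internal[order(g_age[internal], decreasing = TRUE)]  # root first
  id[internal] <- ntot + seq_along(internal)
  edge <- matrix(0L, ntot_nodes - 1L, 2L)
  k <- 0L
  for (v in seq_len(ntot_nodes)) {
    if (!is.na(g_par[v])) {
      k <- k + 1L
      edge[k, ] <- c(id[g_par[v]], id[v])
    }
  }
  age <- numeric(ntot_nodes); age[id] <- g_age
  lab <- character(ntot); lab[id[is_tip]] <- g_lab[is_tip]
  gphy <- structure(list(edge = edge, tip.label = lab,
                         Nnode = ntot_nodes - ntot),
                    class = "phylo")
  gphy <- ape::reorder.phylo(gphy, "cladewise")
  gphy <- clock_tree(gphy, age)
  pop <- setNames(sub("_[0-9]+$", "", lab), lab)
  structure(list(phy = gphy, age = age, pop = pop), class = "gene_tree")
}

#' Simulate a JC69 alignment on a gene tree
#'
#' Root states are uniform on `{T,C,A,G}` per site; each branch applies the
#' JC69 transition probabilities for its length; sites are independent.
#'
#' @param gtree a `gene_tree` (or any clock `phylo` passed via `phy`).
#' @param length number of sites.
#' @param kind locus kind recorded on the alignment attribute.
#' @return character alignment matrix (rows = sequences).
#' @export
sim_alignment <- function(gtree, length,
                          kind = c("nuclear", "mitochondrial")) {
  kind <- match.arg(kind)
  phy <- if (inherits(gtree, "gene_tree")) gtree$phy else gtree
  dat <- phangorn::simSeq(phy, l = length, type = "DNA")
  m <- toupper(as.character(dat))
  m <- m[phy$tip.label, , drop = FALSE]
  validate_alignment(m)
  attr(m, "locus_kind") <- kind
  m
}

## ---- replicate datasets ----

#' Study configuration for one parameter combination
#'
#' @param tree_id species tree 1 or 2.
#' @param rate `"low"` or `"high"`.
#' @param n_per_pop sequences per population (3 or 5).
#' @param n_nuclear number of nuclear loci (1 or 5).
#' @return a `replicate_config` list.
#' @export
replicate_config <- function(tree_id = 1L, rate = "low", n_per_pop = 3L,
                             n_nuclear = 1L) {
  structure(list(tree_id = as.integer(tree_id), rate = rate,
                 n_per_pop = as.integer(n_per_pop),
                 n_nuclear = as.integer(n_nuclear)),
            class = "replicate_config")
}

.relabel_populations <- function(gtree, n_per_pop, assign_map) {
  ## assign_map: named character vector species-sequence label -> new label
  old <- gtree$phy$tip.label
  new <- unname(assign_map[old])
  gtree$phy$tip.label <- new
  gtree$pop <- setNames(sub("_[0-9]+$", "", new), new)
  gtree
}

#' Simulate one replicate dataset
#'
#' Each species is panmictic: `2 * n_per_pop` sequences are simulated per
#' species at every locus and then split at random into two populations
#' (`A1`/`A2`, ...), with the same split used at all loci of the replicate.
#' The mitochondrial locus (1000 sites) uses the 20x/5x rescaled model; each
#' nuclear locus has 500 sites.
#'
#' @param config a [replicate_config()].
#' @return list with elements `mito` (list of `aln`, `gtree`), `nuclear`
#'   (list of such lists), `popmap`, `model` (nuclear-scale model), `config`.
#' @export
sim_replicate <- function(config) {
  stopifnot(inherits(config, "replicate_config"))
  model <- build_species_tree(config$tree_id, config$rate)
  mito_model <- scale_to_locus(model, locus_spec("mitochondrial"))
  species <- model$phy$tip.label
  n <- config$n_per_pop

  ## one random panmictic split per replicate, shared across loci
  assign_map <- character(0)
  for (sp in species) {
    seqs <- paste0(sp, "_", seq_len(2L * n))
    perm <- sample(seqs)
    new <- c(paste0(sp, "1_", seq_len(n)), paste0(sp, "2_", seq_len(n)))
    assign_map[perm] <- new
  }
  counts <- setNames(rep(2L * n, length(species)), species)

  sim_locus <- function(m, len, kind) {
    gt <- sim_gene_tree(m, counts)
    gt <- .relabel_populations(gt, n, assign_map)
    aln <- sim_alignment(gt, len, kind)
    list(aln = aln, gtree = gt)
  }
  mito <- sim_locus(mito_model, 1000L, "mitochondrial")
  nuclear <- lapply(seq_len(config$n_nuclear), function(i)
    sim_locus(model, 500L, "nuclear"))

  labels <- rownames(mito$aln)
  popmap <- setNames(sub("_[0-9]+$", "", labels), labels)
  list(mito = mito, nuclear = nuclear, popmap = popmap,
       model = model, config = config)
}

#' Correct population (guide) tree implied by a species tree
#'
#' Each species tip `X` is replaced by the cherry `(X1, X2)`; node ages for the
#' population-pair nodes are 0 (populations of one species are panmictic).
#'
#' @param tree_id species tree 1 or 2.
#' @return rooted `phylo` over the eight populations (topology only).
#' @export
true_guide_tree <- function(tree_id) {
  if (tree_id == 1L)
    parse_newick("((((A1,A2),(B1,B2)),(C1,C2)),(D1,D2));")
  else if (tree_id == 2L)
    parse_newick("(((A1,A2),(B1,B2)),((C1,C2),(D1,D2)));")
  else stop("unknown tree id: ", tree_id)
}

#' Write a replicate dataset to disk
#'
#' Persists per-locus PHYLIP alignments, true gene trees (Newick with branch
#' lengths), the population map, and a JSON manifest.
#'
#' @param rep a replicate from [sim_replicate()].
#' @param dir output directory (created if missing).
#' @param seed optional seed recorded in the manifest.
#' @export
write_replicate <- function(rep, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylip(rep$mito$aln, file.path(dir, "mito.phy"))
  write_newick(rep$mito$gtree$phy, file.path(dir, "mito.tre"))
  for (i in seq_along(rep$nuclear)) {
    write_phylip(rep$nuclear[[i]]$aln, file.path(dir, sprintf("nuc%d.phy", i)))
    write_newick(rep$nuclear[[i]]$gtree$phy,
                 file.path(dir, sprintf("nuc%d.tre", i)))
  }
  write_popmap(rep$popmap, file.path(dir, "Imap.txt"))
  manifest <- c(rep$config, list(seed = seed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
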