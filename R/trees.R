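#' @useDynLib coaldelim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rexp rgamma dgamma setNames quantile median optimize
#' @importFrom utils head tail
NULL

## ---- basic tree helpers (ape `phylo` is the working container) ----

.children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2])
  }
  ch
}

.root_node <- function(phy) ape::Ntip(phy) + 1L

#' Node ages of a clock tree
#'
#' Ages are measured in expected substitutions per site above the tips
#' (tips have age 0). For trees that are not exactly ultrametric the age of a
#' node is defined as the longest path from the node to any descendant tip,
#' which reduces to the usual height for clock trees.
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(phy) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  n <- ape::Ntip(phy) + phy$Nnode
  age <- numeric(n)
  ## postorder: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    age[p] <- max(age[p], age[c] + ord$edge.length[i])
  }
  age[seq_len(ape::Ntip(phy))] <- 0
  age
}

#' Build a clock tree from a topology and node ages
#'
#' @param phy rooted binary `phylo` (edge lengths ignored).
#' @param ages numeric vector per ape node id; tip entries must be 0 and every
#'   parent must be strictly older than its children.
#' @return `phylo` with edge lengths `ages[parent] - ages[child]`.
#' @export
clock_tree <- function(phy, ages) {
  el <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(el < 0)) stop("ages must decrease from root to tips")
  phy$edge.length <- el
  phy
}

## ---- Newick I/O ----

.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at position ",
         length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing ';' terminator at position ", nchar(text))
  invisible(TRUE)
}

#' Parse a Newick string into a rooted tree
#'
#' Accepts strictly bifurcating rooted trees, or unrooted trees written with a
#' basal trifurcation (as produced by unrooted ML programs). Any other
#' multifurcation is rejected.
#'
#' @param text a single Newick string.
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick: unparsable string at position 1")
  if (ape::Ntip(phy) < 2L)
    stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels")
  ch <- .children_list(phy)
  nch <- lengths(ch)[(ape::Ntip(phy) + 1L):(ape::Ntip(phy) + phy$Nnode)]
  root_nch <- lengths(ch)[.root_node(phy)]
  if (any(nch > 3L) || any(nch[-1L] != 2L & nch[-1L] != 0L) ||
      (root_nch != 2L && root_nch != 3L))
    stop("non-binary internal node (only a basal trifurcation is allowed)")
  phy
}

#' Read a Newick file
#' @param file path to a Newick file (may hold several trees, one per line).
#' @return a `phylo`, or a list of `phylo` if the file holds several trees.
#' @export
read_newick <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1L]] else trees
}

.canon_str <- function(phy, node, ch, lengths, digits) {
  if (node <= ape::Ntip(phy)) {
    lab <- phy$tip.label[node]
    return(list(str = lab, min = lab))
  }
  parts <- lapply(ch[[node]], .canon_str, phy = phy, ch = ch,
                  lengths = lengths, digits = digits)
  ord <- order(vapply(parts, `[[`, "", "min"))
  parts <- parts[ord]
  kids <- ch[[node]][ord]
  inner <- vapply(seq_along(parts), function(i) {
    s <- parts[[i]]$str
    if (!is.null(lengths)) {
      ei <- which(phy$edge[, 2] == kids[i])
      s <- paste0(s, ":", sprintf(paste0("%.", digits, "g"),
                                  phy$edge.length[ei]))
    }
    s
  }, "")
  list(str = paste0("(", paste(inner, collapse = ","), ")"),
       min = parts[[1L]]$min)
}

#' Canonical Newick form
#'
#' Children are ordered by the lexicographically smallest descendant tip label,
#' which makes the string a deterministic key for a (rooted) topology and the
#' basis for all tie-breaking in the package.
#'
#' @param phy a `phylo`.
#' @param lengths include branch lengths?
#' @param digits significant digits used to format branch lengths.
#' @return a single Newick string.
#' @export
canonical_newick <- function(phy, lengths = !is.null(phy$edge.length),
                             digits = 12) {
  ch <- .children_list(phy)
  len <- if (lengths && !is.null(phy$edge.length)) TRUE else NULL
  paste0(.canon_str(phy, .root_node(phy), ch, len, digits)$str, ";")
}

#' Write a tree in canonical Newick form
#' @param phy a `phylo`.
#' @param file optional path; if `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(phy, file = NULL, digits = 12) {
  s <- canonical_newick(phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

## ---- clades and recovery ----

.clade_key <- function(labels) paste(sort(labels), collapse = "|")

.tip_descendants <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  desc <- vector("list", n)
  for (i in seq_len(ntip)) desc[[i]] <- phy$tip.label[i]
  ord <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

#' Clades of a rooted tree
#'
#' One tip-label set per internal node, including the root clade (all tips).
#' Scoring functions exclude the root clade themselves since it is trivially
#' present in every rooted tree.
#'
#' @param phy rooted `phylo`.
#' @return named list of sorted character vectors; names are canonical clade
#'   keys (sorted labels joined by `|`).
#' @export
tree_clades <- function(phy) {
  ntip <- ape::Ntip(phy)
  desc <- .tip_descendants(phy)
  cl <- lapply((ntip + 1L):(ntip + phy$Nnode), function(v) sort(desc[[v]]))
  names(cl) <- vapply(cl, .clade_key, "")
  cl
}

#' Clade recovery frequencies
#'
#' For each non-root clade of the reference tree, the fraction of trees in
#' `inferred` that contain that clade (strict rooted clade presence, as in
#' consensus-style clade counting).
#'
#' @param true_tree rooted reference `phylo`.
#' @param inferred list of rooted `phylo` on the same tip set.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
clade_recovery <- function(true_tree, inferred) {
  if (inherits(inferred, "phylo")) inferred <- list(inferred)
  tips <- sort(true_tree$tip.label)
  cl <- tree_clades(true_tree)
  root_key <- .clade_key(tips)
  cl <- cl[names(cl) != root_key]
  counts <- setNames(numeric(length(cl)), names(cl))
  for (tr in inferred) {
    if (!identical(sort(tr$tip.label), tips))
      stop("tip sets differ between true and inferred trees")
    keys <- names(tree_clades(tr))
    counts <- counts + (names(cl) %in% keys)
  }
  counts / length(inferred)
}

#' Modal (MAP) topology of a tree sample
#'
#' Returns the most frequently sampled rooted topology after discarding a
#' burn-in fraction; node ages of the returned tree are the mean ages of each
#' clade over the samples having the modal topology. Ties between equally
#' frequent topologies are broken toward the lexicographically smallest
#' canonical Newick string.
#'
#' @param samples list of rooted clock `phylo` trees.
#' @param burn_in_fraction fraction of initial samples to drop.
#' @return a `phylo` clock tree.
#' @export
modal_topology <- function(samples, burn_in_fraction = 0) {
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  n <- length(samples)
  if (n == 0L) stop("empty sample list")
  keep <- samples[(floor(burn_in_fraction * n) + 1L):n]
  keys <- vapply(keep, canonical_newick, "", lengths = FALSE)
  tab <- table(keys)
  winners <- names(tab)[tab == max(tab)]
  win <- sort(winners)[1L]
  sub <- keep[keys == win]
  ## mean age per clade over the modal-topology samples
  acc <- new.env(parent = emptyenv())
  for (tr in sub) {
    ages <- node_ages(tr)
    ntip <- ape::Ntip(tr)
    desc <- .tip_descendants(tr)
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      k <- .clade_key(desc[[v]])
      prev <- if (is.null(acc[[k]])) c(0, 0) else acc[[k]]
      acc[[k]] <- prev + c(ages[v], 1)
    }
  }
  out <- sub[[1L]]
  ntip <- ape::Ntip(out)
  desc <- .tip_descendants(out)
  ages <- numeric(ntip + out$Nnode)
  for (v in (ntip + 1L):(ntip + out$Nnode)) {
    a <- acc[[.clade_key(desc[[v]])]]
    ages[v] <- a[1] / a[2]
  }
  ## guard against mean ages that violate parent > child by tiny amounts
  ord <- ape::reorder.phylo(out, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    if (p > ntip && c > ntip && ages[p] <= ages[c])
      ages[p] <- ages[c] * (1 + 1e-9)
  }
  clock_tree(out, ages)
}

## ---- midpoint rooting ----

#' Midpoint rooting
#'
#' Roots an unrooted tree (basal trifurcation allowed) at the midpoint of the
#' longest tip-to-tip path. Ties — including the degenerate all-zero branch
#' length case — are broken toward the lexicographically smallest sorted tip
#' pair, so the operation is deterministic.
#'
#' @param phy `phylo` with non-negative branch lengths, at least 2 tips.
#' @return rooted binary `phylo`.
#' @export
midpoint_root <- function(phy) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length),
            all(phy$edge.length >= 0))
  ntip <- ape::Ntip(phy)
  if (ntip < 2L) stop("need at least 2 tips")
  D <- ape::dist.nodes(phy)
  Dt <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dmax <- max(Dt)
  ## candidate pairs within numerical tolerance of the diameter
  idx <- which(Dt >= dmax - 1e-12 & upper.tri(Dt), arr.ind = TRUE)
  pair_key <- apply(idx, 1L, function(r) {
    paste(sort(phy$tip.label[r]), collapse = "|")
  })
  best <- idx[order(pair_key)[1L], ]
  i <- best[1L]; j <- best[2L]
  path <- ape::nodepath(phy, i, j)
  half <- Dt[i, j] / 2
  ## walk from i along the path; find the edge straddling the midpoint
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    el <- D[a, b]
    if (cum + el >= half - 1e-15) {
      pos_from_b <- cum + el - half  # distance from node b back toward a
      rooted <- phytools::reroot(phy, node.number = .mr_child(phy, a, b),
                                 position = .mr_pos(phy, a, b, pos_from_b))
      rooted <- ape::collapse.singles(rooted)
      return(.mr_finish(rooted))
    }
    cum <- cum + el
  }
  stop("internal error: midpoint not located")  # nocov
}

## For the edge between path nodes a and b, phytools::reroot() needs the
## *child* endpoint of that edge and the distance above the child.
.mr_child <- function(phy, a, b) {
  if (any(phy$edge[, 1] == a & phy$edge[, 2] == b)) b else a
}
.mr_pos <- function(phy, a, b, pos_from_b) {
  ei <- which((phy$edge[, 1] == a & phy$edge[, 2] == b) |
              (phy$edge[, 1] == b & phy$edge[, 2] == a))
  el <- phy$edge.length[ei]
  child_is_b <- phy$edge[ei, 2] == b
  ## phytools::reroot measures position from the rootward end of the edge
  if (child_is_b) el - pos_from_b else pos_from_b
}
.mr_finish <- function(rooted) {
  rooted$node.label <- NULL
  rooted
}
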