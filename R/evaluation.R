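## Scoring of replicate studies: mapping population pairs to guide-tree
## nodes, false-positive rates at the 95% threshold, clade-recovery
## frequencies, and median/quartile/histogram summaries.

#' Posterior split probability attached to a pair of populations
#'
#' Returns the split posterior of the most recent common ancestor of the two
#' tips on the (possibly wrong) inferred guide tree: splitting that node is
#' what separates the pair into different species.
#'
#' @param fit a `delim_fit` (or a named split-probability vector keyed by
#'   clade, with `guide` supplied).
#' @param pair character vector of two tip labels.
#' @param guide guide tree (taken from `fit` if absent).
#' @return posterior probability.
#' @export
pair_split_posterior <- function(fit, pair, guide = NULL) {
  if (inherits(fit, "delim_fit")) {
    guide <- fit$guide
    probs <- fit$split_prob
  } else probs <- fit
  stopifnot(length(pair) == 2)
  if (!all(pair %in% guide$tip.label))
    stop("pair tips not found on the guide tree: ",
         paste(setdiff(pair, guide$tip.label), collapse = ", "))
  m <- ape::getMRCA(guide, pair)
  key <- .clade_key(.tip_descendants(guide)[[m]])
  unname(probs[key])
}

#' False-positive rate across replicates
#'
#' Fraction of replicates in which a pair's split posterior reaches the
#' threshold (default 0.95, the study's well-supported-split criterion).
#'
#' @param pair_posteriors numeric vector (one per replicate) or a matrix with
#'   one column per pair.
#' @param threshold posterior probability threshold in `(0, 1]` (a threshold
#'   of 0 counts every replicate).
#' @return per-pair rate(s) in `[0, 1]`.
#' @export
false_positive_rate <- function(pair_posteriors, threshold = 0.95) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.matrix(pair_posteriors)) {
    if (nrow(pair_posteriors) == 0) stop("no replicates")
    return(colMeans(pair_posteriors >= threshold))
  }
  if (!length(pair_posteriors)) stop("no replicates")
  mean(pair_posteriors >= threshold)
}

#' Histogram of posterior probabilities with 0.05 bins
#'
#' 20 bins of width 0.05 over `[0, 1]`; every bin is left-closed except the
#' last, which is `[0.95, 1]` (closed at 1) so that its relative frequency
#' equals the false-positive rate at the 0.95 threshold.
#'
#' @param p numeric vector of posterior probabilities.
#' @return named integer vector of counts (21 break points, 20 bins).
#' @export
posterior_histogram <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  idx <- pmin(floor(p / 0.05), 19) + 1L
  counts <- tabulate(idx, nbins = 20L)
  names(counts) <- sprintf("[%.2f,%.2f%s", seq(0, 0.95, 0.05),
                           seq(0.05, 1, 0.05),
                           c(rep(")", 19), "]"))
  counts
}

#' Summaries of a replicate study
#'
#' Medians and (lower, upper) quartiles (type-7 linear interpolation) of the
#' per-replicate posterior split probabilities for each scored clade, 0.05-bin
#' histograms, false-positive rates at 0.95, and clade-recovery frequencies
#' of the inferred guide trees, with binomial standard errors.
#'
#' @param records list of replicate records from [run_study()].
#' @return a `study_summary` list.
#' @export
summarize_study <- function(records) {
  if (!length(records)) stop("no replicate records")
  n <- length(records)
  pair_names <- colnames(records[[1]]$pair_post)
  pairs <- do.call(rbind, lapply(records, `[[`, "pair_post"))
  clade_names <- names(records[[1]]$clade_post)
  clades <- do.call(rbind, lapply(records, `[[`, "clade_post"))

  qtab <- function(m) {
    t(apply(m, 2, function(x) {
      x <- x[!is.na(x)]
      stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    }))
  }
  fp <- false_positive_rate(pairs, 0.95)
  recov <- colMeans(do.call(rbind, lapply(records, `[[`, "guide_correct")))
  se <- function(p) sqrt(p * (1 - p) / n)

  out <- list(
    n = n,
    pair_quartiles = structure(qtab(pairs),
                               dimnames = list(pair_names,
                                               c("median", "q25", "q75"))),
    clade_quartiles = structure(qtab(clades),
                                dimnames = list(clade_names,
                                                c("median", "q25", "q75"))),
    false_positive = fp,
    false_positive_se = se(fp),
    guide_recovery = recov,
    guide_recovery_se = se(recov),
    histograms = apply(pairs, 2, posterior_histogram)
  )
  class(out) <- "study_summary"
  out
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study summary over %d replicates\n", x$n))
  cat("Guide-tree clade recovery:\n")
  print(round(x$guide_recovery, 3))
  cat("False-positive rates (posterior >= 0.95):\n")
  print(round(x$false_positive, 4))
  cat("Within-species pair split probabilities (median [q25, q75]):\n")
  print(round(x$pair_quartiles, 3))
  invisible(x)
}

#' Study configuration
#'
#' @param tree_id,rate,n_per_pop,n_nuclear simulation settings
#'   (see [replicate_config()]).
#' @param guide_arm `"ml"` (constrained ML on the mitochondrial locus),
#'   `"sptree"` (species-tree MCMC on the nuclear loci) or `"true"` (the
#'   correct guide tree).
#' @param n_replicates number of replicate data sets.
#' @param sptree_iter,sptree_keep species-tree MCMC schedule (updates;
#'   samples kept for the MAP tree). The protocol values are 6e6 and 2200.
#' @param delim_control a [delim_control()] for the rjMCMC.
#' @param delimit run the delimitation stage (disable to score guide trees
#'   only)?
#' @return a `study_config` list.
#' @export
study_config <- function(tree_id = 1L, rate = "low", n_per_pop = 3L,
                         n_nuclear = 1L, guide_arm = c("ml", "sptree", "true"),
                         n_replicates = 100L, sptree_iter = 1e5,
                         sptree_keep = NULL,
                         delim_control = coaldelim::delim_control(
                           burnin = 2000, nsamples = 5000, sample_every = 1),
                         delimit = TRUE) {
  guide_arm <- match.arg(guide_arm)
  if (n_replicates < 1) stop("need at least one replicate")
  structure(list(tree_id = tree_id, rate = rate, n_per_pop = n_per_pop,
                 n_nuclear = n_nuclear, guide_arm = guide_arm,
                 n_replicates = as.integer(n_replicates),
                 sptree_iter = sptree_iter, sptree_keep = sptree_keep,
                 delim_control = delim_control, delimit = delimit),
            class = "study_config")
}

#' Run a replicate study
#'
#' For each replicate: simulate the dataset, infer the guide tree with the
#' configured arm, delimit species on it with the rjMCMC (combined runs), and
#' record guide-tree correctness flags, per-pair and per-true-clade split
#' posteriors. Per-replicate seeds are drawn once from the master seed so any
#' replicate can be re-run on its own.
#'
#' @param config a [study_config()].
#' @param master_seed integer seed controlling the whole study.
#' @param progress print a dot per replicate?
#' @return list with `records` (per-replicate), `summary` (a
#'   [summarize_study()] result when delimitation ran), `config`,
#'   `master_seed`.
#' @export
run_study <- function(config, master_seed = 1L, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(master_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  rc <- replicate_config(config$tree_id, config$rate, config$n_per_pop,
                         config$n_nuclear)
  true_guide <- true_guide_tree(config$tree_id)
  prior <- delim_prior(config$rate)
  true_clades <- tree_clades(true_guide)
  root_key <- .clade_key(sort(true_guide$tip.label))
  scored_keys <- setdiff(names(true_clades), root_key)
  pops <- sort(true_guide$tip.label)
  species <- sort(unique(sub("[12]$", "", pops)))
  pairs <- lapply(species, function(s) paste0(s, 1:2))
  names(pairs) <- vapply(species, function(s) paste0(s, "1", s, "2"), "")

  records <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[i])
    rec <- tryCatch({
      rep <- sim_replicate(rc)
      guide <- switch(config$guide_arm,
        ml = ml_guide_tree(rep$mito$aln, rep$popmap),
        sptree = {
          fit <- species_tree_mcmc(lapply(rep$nuclear, `[[`, "aln"),
                                   rep$popmap, n_iter = config$sptree_iter)
          keep <- config$sptree_keep
          if (is.null(keep))
            keep <- floor(fit$n_samples * 2200 / 3000)
          map_guide_tree(fit, keep_last = keep)
        },
        true = true_guide)
      guide_keys <- names(tree_clades(guide))
      guide_correct <- setNames(scored_keys %in% guide_keys, scored_keys)
      out <- list(replicate = i, seed = rep_seeds[i],
                  guide = write_newick(guide),
                  guide_correct = guide_correct)
      if (config$delimit) {
        fit <- delimit(lapply(rep$nuclear, `[[`, "aln"), guide, rep$popmap,
                       prior = prior, control = config$delim_control)
        pair_post <- vapply(pairs, function(pr)
          pair_split_posterior(fit, pr), 0)
        clade_post <- vapply(scored_keys, function(k) {
          if (k %in% names(fit$split_prob)) unname(fit$split_prob[k])
          else NA_real_
        }, 0)
        root_post <- unname(fit$split_prob[.clade_key(sort(guide$tip.label))])
        out$pair_post <- matrix(pair_post, nrow = 1,
                                dimnames = list(NULL, names(pairs)))
        out$clade_post <- clade_post
        out$root_post <- root_post
        out$split_prob <- fit$split_prob
        out$run_gap <- if (ncol(fit$per_run) > 1)
          max(abs(fit$per_run[, 1] - fit$per_run[, 2])) else NA_real_
      }
      out
    }, error = function(e) list(replicate = i, seed = rep_seeds[i],
                                error = conditionMessage(e)))
    records[[i]] <- rec
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  failed <- vapply(records, function(r) !is.null(r$error), TRUE)
  if (any(failed))
    warning(sum(failed), " replicate(s) failed; they are excluded from summaries")
  ok <- records[!failed]
  summary <- if (config$delimit && length(ok)) summarize_study(ok) else NULL
  list(records = records, summary = summary, config = config,
       master_seed = master_seed, n_failed = sum(failed))
}

#' Guide-tree recovery study (no delimitation stage)
#'
#' Convenience wrapper scoring only clade recovery of the inferred guide
#' trees against the correct population tree.
#'
#' @inheritParams run_study
#' @return list with `recovery` (named frequencies), `records`, `config`.
#' @export
run_guide_study <- function(config, master_seed = 1L, progress = FALSE) {
  config$delimit <- FALSE
  res <- run_study(config, master_seed, progress)
  ok <- res$records[vapply(res$records, function(r) is.null(r$error), TRUE)]
  rec <- colMeans(do.call(rbind, lapply(ok, `[[`, "guide_correct")))
  list(recovery = rec, n = length(ok), records = res$records,
       config = res$config)
}
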