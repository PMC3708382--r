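## Gene-tree inference and branch supports.
##
## Maximum likelihood: neighbor-joining start, branch-length + model
## optimization and NNI hill climbing (via phangorn's pml machinery),
## nonparametric bootstrap, and the aLRT statistic (twice the
## log-likelihood gap between the best and second-best arrangement
## around each internal branch). Maximum parsimony: Fitch score,
## heuristic (or exhaustive, small n) search, bootstrap, and the decay
## index. All supports are keyed by canonical bipartition strings so
## they can be mapped onto a reference topology.

#' Settings for gene-tree inference
#'
#' @param model_tag `"JTT"` (amino acid) or `"K2P"` (DNA; the
#'   transition/transversion ratio is estimated per gene).
#' @param n_gamma_categories discrete-gamma categories for inference.
#' @param estimate_gamma estimate the gamma shape by ML (on the fixed
#'   topology, during branch-length optimization)?
#' @param bootstrap_reps bootstrap replicates.
#' @param seed integer seed; every stochastic step derives child seeds
#'   from it by fixed arithmetic.
#' @param exhaustive_cutoff taxon count at or below which parsimony
#'   search and decay-index anti-constraint search enumerate all
#'   topologies (capped at 8 for tractability: 10395 trees).
#' @param nni_tol log-likelihood improvement below which an NNI move is
#'   considered neutral.
#' @return list of class `inference_settings`.
#' @export
inference_settings <- function(model_tag = c("JTT", "K2P"),
                               n_gamma_categories = 4, estimate_gamma = TRUE,
                               bootstrap_reps = 100, seed = 1,
                               exhaustive_cutoff = 8, nni_tol = 1e-4) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  stopifnot(n_gamma_categories >= 1, bootstrap_reps >= 0)
  structure(list(model_tag = model_tag,
                 n_gamma_categories = as.integer(n_gamma_categories),
                 estimate_gamma = isTRUE(estimate_gamma),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 exhaustive_cutoff = min(as.integer(exhaustive_cutoff), 8L),
                 nni_tol = nni_tol),
            class = "inference_settings")
}

as_phydat <- function(aln) {
  phangorn::phyDat(unclass(aln),
                   type = if (attr(aln, "alphabet") == "dna") "DNA" else "AA")
}

.pml_model <- function(settings) {
  if (settings$model_tag == "JTT") "JTT" else "K80"
}

.nj_start <- function(d) {
  dm <- phangorn::dist.hamming(d)
  if (all(dm == 0))
    warning("all sequences identical; starting tree is arbitrary")
  t0 <- ape::nj(dm)
  t0$edge.length[t0$edge.length < 1e-8] <- 1e-8
  ape::unroot(t0)
}

#' Discrete-gamma tree log-likelihood
#'
#' Independent implementation (Felsenstein pruning over a discrete-gamma
#' rate mixture) of the likelihood that the search in [ml_tree()]
#' optimizes; used for cross-checks and small exact computations.
#'
#' @param topology `phylo` with branch lengths in expected
#'   substitutions/site; leaves must match the alignment taxa.
#' @param alignment a [pi_alignment()].
#' @param settings an [inference_settings()].
#' @param gamma_shape gamma shape; `NULL` means no rate heterogeneity
#'   (single category), regardless of `n_gamma_categories`.
#' @param kappa transition/transversion ratio for K2P.
#' @return total log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(topology, alignment,
                                settings = inference_settings(),
                                gamma_shape = NULL, kappa = 2) {
  if (!setequal(topology$tip.label, rownames(alignment)))
    stop("topology leaves and alignment taxa differ")
  model <- substitution_model(settings$model_tag, kappa)
  cache <- prune_cache(topology, alignment_codes(alignment), model)
  if (is.null(gamma_shape) || settings$n_gamma_categories == 1L) {
    return(sum(prune_loglik_cached(cache, 1)))
  }
  k <- settings$n_gamma_categories
  cr <- discretize_gamma(gamma_shape, k)
  per_cat <- vapply(cr, function(r) prune_loglik_cached(cache, r),
                    numeric(cache$n_sites))
  if (cache$n_sites == 1L) per_cat <- matrix(per_cat, nrow = 1)
  m <- apply(per_cat, 1, max)
  sum(m + log(rowMeans(exp(per_cat - m))))
}

#' ML gene tree
#'
#' Neighbor-joining start from Hamming distances, then joint
#' branch-length/model optimization and NNI hill climbing to a local
#' optimum. For K2P the transition/transversion ratio is estimated; the
#' gamma shape is estimated when `estimate_gamma` is set and then held
#' fixed during the topology search.
#'
#' @param alignment a [pi_alignment()] with >= 4 taxa.
#' @param settings an [inference_settings()].
#' @return list of class `ml_fit`: `tree` (unrooted, branch lengths in
#'   subs/site), `logLik`, `shape`, and the underlying `pml` fit.
#' @export
ml_tree <- function(alignment, settings = inference_settings()) {
  stopifnot(nrow(alignment) >= 4)
  set.seed(settings$seed)
  d <- as_phydat(alignment)
  t0 <- .nj_start(d)
  fit <- phangorn::pml(t0, d, k = settings$n_gamma_categories, shape = 1)
  if (all(phangorn::dist.hamming(d) == 0)) {
    ## degenerate input: no signal to optimize; keep the arbitrary NJ
    ## resolution with (near) zero-length branches
    return(structure(list(tree = ape::unroot(fit$tree),
                          logLik = as.numeric(stats::logLik(fit)),
                          shape = fit$shape, fit = fit,
                          settings = settings),
                     class = "ml_fit"))
  }
  fit <- tryCatch(
    phangorn::optim.pml(
      fit, model = .pml_model(settings), optEdge = TRUE,
      optGamma = settings$estimate_gamma && settings$n_gamma_categories > 1,
      rearrangement = "NNI",
      control = phangorn::pml.control(trace = 0, epsilon = 1e-8)),
    error = function(e) tryCatch(
      phangorn::optim.pml(fit, model = .pml_model(settings), optEdge = TRUE,
                          control = phangorn::pml.control(trace = 0)),
      error = function(e2) fit))
  structure(list(tree = ape::unroot(fit$tree),
                 logLik = as.numeric(stats::logLik(fit)),
                 shape = fit$shape, fit = fit, settings = settings),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit> %d taxa, logLik %.3f, %s+G(%d) shape %.3g\n",
              length(x$tree$tip.label), x$logLik, x$settings$model_tag,
              x$settings$n_gamma_categories, x$shape))
  invisible(x)
}

## re-fit a fixed topology (branch lengths re-optimized) and return logLik
.refit_topology <- function(topo, fit0, settings) {
  if (is.null(topo$edge.length))
    topo$edge.length <- rep(0.05, nrow(topo$edge))
  topo$edge.length[is.na(topo$edge.length) | topo$edge.length < 1e-8] <- 1e-8
  f <- phangorn::pml(topo, fit0$data, k = fit0$k, shape = fit0$shape,
                     bf = fit0$bf, Q = fit0$Q)
  f <- phangorn::optim.pml(f, optEdge = TRUE,
                           control = phangorn::pml.control(trace = 0))
  f
}

#' ML nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement, re-runs the ML search
#' (started from the point-estimate tree, model parameters held fixed)
#' and reports, for each bipartition of the point-estimate tree, the
#' percentage of replicates containing it.
#'
#' @param alignment a [pi_alignment()].
#' @param settings an [inference_settings()] (`bootstrap_reps >= 1`).
#' @param fit optional precomputed [ml_tree()] result.
#' @return data frame with columns `split` and `ml_bp` (0-100).
#' @export
ml_bootstrap <- function(alignment, settings = inference_settings(),
                         fit = NULL) {
  stopifnot(settings$bootstrap_reps >= 1)
  if (is.null(fit)) fit <- ml_tree(alignment, settings)
  point_splits <- bipartitions(fit$tree)
  counts <- stats::setNames(numeric(length(point_splits)), point_splits)
  fit0 <- fit$fit
  for (b in seq_len(settings$bootstrap_reps)) {
    set.seed(child_seed(settings$seed, 1000 + b))
    idx <- sample.int(ncol(alignment), replace = TRUE)
    db <- as_phydat(alignment[, idx])
    fb <- phangorn::pml(fit0$tree, db, k = fit0$k, shape = fit0$shape,
                        bf = fit0$bf, Q = fit0$Q)
    ## degenerate replicates (e.g. all resampled sites invariant) keep the
    ## unoptimized start rather than aborting the gene
    fb <- tryCatch(
      phangorn::optim.pml(fb, optEdge = TRUE, rearrangement = "NNI",
                          control = phangorn::pml.control(trace = 0,
                                                          maxit = 5)),
      error = function(e) fb)
    sb <- bipartitions(fb$tree)
    hit <- point_splits %in% sb
    counts[hit] <- counts[hit] + 1
  }
  data.frame(split = point_splits,
             ml_bp = 100 * unname(counts) / settings$bootstrap_reps)
}

## all NNI neighbors of `tree`, grouped by the bipartition each destroys
.nni_by_split <- function(tree) {
  nbs <- phangorn::nni(tree)
  orig <- bipartitions(tree)
  out <- lapply(stats::setNames(orig, orig), function(s) list())
  for (i in seq_along(nbs)) {
    nb <- nbs[[i]]  # [[ restores compressed tip labels on multiPhylo
    missing <- setdiff(orig, bipartitions(nb))
    if (length(missing) == 1 && missing %in% names(out))
      out[[missing]] <- c(out[[missing]], list(nb))
  }
  out
}

#' aLRT branch support
#'
#' For each internal branch of the ML tree, evaluates the two NNI
#' rearrangements around the branch with branch lengths re-optimized and
#' returns twice the log-likelihood gap between the best and second-best
#' of the three arrangements, clamped at 0 when a rearrangement beats
#' the current tree.
#'
#' @param fit an [ml_tree()] result (NNI-locally optimal).
#' @param settings an [inference_settings()].
#' @return data frame with columns `split` and `alrt` (>= 0).
#' @export
alrt_statistic <- function(fit, settings = fit$settings) {
  tree <- fit$fit$tree
  groups <- .nni_by_split(ape::unroot(tree))
  lnl0 <- fit$logLik
  stat <- vapply(names(groups), function(s) {
    alts <- vapply(groups[[s]], function(nb)
      as.numeric(stats::logLik(.refit_topology(nb, fit$fit, settings))),
      numeric(1))
    all3 <- sort(c(lnl0, alts), decreasing = TRUE)
    max(0, 2 * (all3[1] - all3[2]) * (lnl0 >= max(alts) - settings$nni_tol))
  }, numeric(1))
  data.frame(split = names(groups), alrt = unname(stat), row.names = NULL)
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree, summed across sites;
#' gaps and ambiguities count as missing (any state).
#'
#' @param topology `phylo` whose leaves match the alignment taxa.
#' @param alignment a [pi_alignment()].
#' @return integer score.
#' @export
fitch_score <- function(topology, alignment) {
  if (!setequal(topology$tip.label, rownames(alignment)))
    stop("topology leaves and alignment taxa differ")
  as.integer(phangorn::fitch(topology, as_phydat(alignment)))
}

.all_topologies <- function(labels) {
  phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
}

#' Most-parsimonious tree
#'
#' Exhaustive enumeration for small problems (`<= exhaustive_cutoff`
#' taxa); otherwise a parsimony ratchet with SPR swapping from a
#' neighbor-joining start. Deterministic given the seed.
#'
#' @param alignment a [pi_alignment()] with >= 4 taxa.
#' @param settings an [inference_settings()].
#' @return list of class `mp_fit`: `tree`, `score`, `exhaustive` flag.
#' @export
mp_tree <- function(alignment, settings = inference_settings()) {
  stopifnot(nrow(alignment) >= 4)
  d <- as_phydat(alignment)
  n <- nrow(alignment)
  if (n <= settings$exhaustive_cutoff) {
    trees <- .all_topologies(rownames(alignment))
    sc <- phangorn::fitch(trees, d)
    best <- which.min(sc)
    res <- list(tree = trees[[best]], score = as.integer(sc[best]),
                exhaustive = TRUE)
  } else {
    set.seed(settings$seed)
    t0 <- .nj_start(d)
    tr <- phangorn::pratchet(d, start = t0, maxit = 20, minit = 5, k = 5,
                             trace = 0, rearrangements = "SPR", all = FALSE)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
    res <- list(tree = ape::unroot(tr),
                score = as.integer(phangorn::fitch(tr, d)),
                exhaustive = FALSE)
  }
  structure(res, class = "mp_fit")
}

#' MP nonparametric bootstrap supports
#'
#' As [ml_bootstrap()] with the parsimony estimator: each replicate is
#' re-searched by SPR hill climbing from a neighbor-joining start.
#'
#' @param alignment a [pi_alignment()].
#' @param settings an [inference_settings()].
#' @param fit optional precomputed [mp_tree()] result.
#' @return data frame with columns `split` and `mp_bp` (0-100).
#' @export
mp_bootstrap <- function(alignment, settings = inference_settings(),
                         fit = NULL) {
  stopifnot(settings$bootstrap_reps >= 1)
  if (is.null(fit)) fit <- mp_tree(alignment, settings)
  point_splits <- bipartitions(fit$tree)
  counts <- stats::setNames(numeric(length(point_splits)), point_splits)
  for (b in seq_len(settings$bootstrap_reps)) {
    set.seed(child_seed(settings$seed, 2000 + b))
    idx <- sample.int(ncol(alignment), replace = TRUE)
    alnb <- alignment[, idx]
    db <- as_phydat(alnb)
    start <- suppressWarnings(.nj_start(db))
    tb <- tryCatch(
      suppressWarnings(
        phangorn::optim.parsimony(start, db, method = "fitch",
                                  rearrangements = "SPR", trace = 0)),
      error = function(e) start)
    sb <- bipartitions(tb)
    hit <- point_splits %in% sb
    counts[hit] <- counts[hit] + 1
  }
  data.frame(split = point_splits,
             mp_bp = 100 * unname(counts) / settings$bootstrap_reps)
}

#' Decay index (Bremer support)
#'
#' For each internal branch of the MP tree: the parsimony score of the
#' best tree lacking that bipartition minus the best overall score. The
#' anti-constraint search is exhaustive at or below
#' `exhaustive_cutoff` taxa; above that, the two NNI rearrangements
#' around the branch (each refined by SPR hill climbing, refits that
#' reintroduce the bipartition discarded) give an upper bound on the
#' support, flagged in the `exact` column.
#'
#' @param fit an [mp_tree()] result.
#' @param alignment the alignment the tree was inferred from.
#' @param settings an [inference_settings()].
#' @return data frame with columns `split`, `di` (>= 0), `exact`.
#' @export
decay_index <- function(fit, alignment, settings = inference_settings()) {
  d <- as_phydat(alignment)
  n <- nrow(alignment)
  splits_mp <- bipartitions(fit$tree)
  if (n <= settings$exhaustive_cutoff) {
    trees <- .all_topologies(rownames(alignment))
    sc <- phangorn::fitch(trees, d)
    spl <- lapply(trees, bipartitions)
    di <- vapply(splits_mp, function(s) {
      lacking <- !vapply(spl, function(x) s %in% x, logical(1))
      min(sc[lacking]) - fit$score
    }, numeric(1))
    exact <- TRUE
  } else {
    groups <- .nni_by_split(fit$tree)
    di <- vapply(splits_mp, function(s) {
      cand <- vapply(groups[[s]], function(nb) {
        sc_nb <- phangorn::fitch(nb, d)
        ref <- suppressWarnings(
          phangorn::optim.parsimony(nb, d, method = "fitch",
                                    rearrangements = "SPR", trace = 0))
        if (!(s %in% bipartitions(ref)))
          sc_nb <- min(sc_nb, phangorn::fitch(ref, d))
        sc_nb
      }, numeric(1))
      min(cand) - fit$score
    }, numeric(1))
    exact <- FALSE
  }
  data.frame(split = splits_mp, di = as.integer(pmax(di, 0)), exact = exact,
             row.names = NULL)
}
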