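## Evaluation of DPI as a predictor of phylogenetic performance: tree
## distance to the reference topology, paired predicted-vs-empirical
## proportionate performance (PPP/EPP), per-gene proportionate support
## (PLRS/PIDS) and cumulative sampling paths, with Pearson correlations.

#' Pair genes best-with-worst by DPI rank
#'
#' Pairs (rank 1, rank n), (rank 2, rank n-1), ...; with an odd number of
#' genes the median-ranked gene is dropped.
#'
#' @param ranking a [rank_genes()] result (or data frame with `gene_id`
#'   and `rank`).
#' @return data frame with columns `gene_hi`, `gene_lo` (hi = higher
#'   DPI).
#' @export
pair_genes <- function(ranking) {
  n <- nrow(ranking)
  if (n < 2) stop("pairing requires >= 2 genes")
  ranking <- ranking[order(ranking$rank), ]
  k <- n %/% 2
  data.frame(gene_hi = ranking$gene_id[seq_len(k)],
             gene_lo = ranking$gene_id[n + 1 - seq_len(k)])
}

#' Predicted proportionate performance of a gene pair
#'
#' @param dpi_hi,dpi_lo DPI of the higher- and lower-ranked gene
#'   (`dpi_hi >= dpi_lo >= 0`, not both zero).
#' @return `dpi_hi / (dpi_hi + dpi_lo)`, in `[0.5, 1]`.
#' @export
ppp <- function(dpi_hi, dpi_lo) {
  if (dpi_lo > dpi_hi) stop("dpi_hi must be >= dpi_lo")
  if (dpi_hi <= 0 && dpi_lo <= 0)
    stop("both DPI values are zero; pair undefined")
  dpi_hi / (dpi_hi + dpi_lo)
}

#' Empirical proportionate performance of a gene pair
#'
#' Counts reference nodes where each gene's support strictly exceeds the
#' other's; ties count to neither gene under the default policy (or half
#' to each under `"half"`). `EPP = n_hi / (n_hi + n_lo)`, undefined (NA)
#' when every node ties.
#'
#' @param support_hi,support_lo numeric support values on the same
#'   reference-node set (equal length; names, if present, must match).
#' @param tie_policy `"none"` (strict wins only) or `"half"`.
#' @return list with `epp` (in `[0,1]` or `NA`), `n_hi`, `n_lo`.
#' @export
epp <- function(support_hi, support_lo, tie_policy = c("none", "half")) {
  tie_policy <- match.arg(tie_policy)
  if (length(support_hi) != length(support_lo))
    stop("support vectors must cover the same reference-node set")
  if (!is.null(names(support_hi)) && !is.null(names(support_lo))) {
    if (!setequal(names(support_hi), names(support_lo)))
      stop("support vectors must cover the same reference-node set")
    support_lo <- support_lo[names(support_hi)]
  }
  n_hi <- sum(support_hi > support_lo)
  n_lo <- sum(support_lo > support_hi)
  if (tie_policy == "half") {
    ties <- sum(support_hi == support_lo)
    n_hi <- n_hi + ties / 2
    n_lo <- n_lo + ties / 2
  }
  list(epp = if (n_hi + n_lo > 0) n_hi / (n_hi + n_lo) else NA_real_,
       n_hi = n_hi, n_lo = n_lo)
}

#' Map per-branch supports onto a reference topology
#'
#' A reference bipartition present in the gene tree receives that
#' branch's support; a reference bipartition the gene tree does not
#' contain receives 0 (a gene contradicting a node lends it no support).
#'
#' @param support data frame with columns `split` and one support column
#'   (as returned by [ml_bootstrap()], [alrt_statistic()], ...), keyed by
#'   canonical bipartition.
#' @param reference reference `phylo` topology (same leaf set as the
#'   gene tree the supports came from).
#' @param value name of the support column; default: the second column.
#' @return named numeric vector over the reference's bipartitions.
#' @export
map_supports_to_reference <- function(support, reference, value = NULL) {
  if (is.null(value)) value <- setdiff(names(support), "split")[1]
  ref_splits <- bipartitions(reference)
  out <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  hit <- support$split %in% ref_splits
  out[support$split[hit]] <- support[[value]][hit]
  out
}

#' Per-gene proportionate support (PLRS / PIDS)
#'
#' Given a genes x reference-nodes support matrix (zeros where the gene
#' does not recover the node), divides each entry by the number of genes
#' and averages across nodes, yielding each gene's relative contribution
#' to the global support of the reference phylogeny. The alternative
#' normalization divides each node's column by its sum across genes
#' instead.
#'
#' @param support_matrix numeric matrix, rows = genes, columns =
#'   reference nodes.
#' @param n_genes denominator for the literal normalization; defaults to
#'   `nrow(support_matrix)`.
#' @param normalization `"n_genes"` (default, divide by the gene count)
#'   or `"node_sum"` (divide by the per-node sum over genes).
#' @return named numeric vector, one value per gene.
#' @export
plrs <- function(support_matrix, n_genes = nrow(support_matrix),
                 normalization = c("n_genes", "node_sum")) {
  normalization <- match.arg(normalization)
  m <- as.matrix(support_matrix)
  if (normalization == "n_genes") {
    rowMeans(m / n_genes)
  } else {
    cs <- colSums(m)
    cs[cs == 0] <- 1  # all-zero node contributes 0 either way
    rowMeans(sweep(m, 2, cs, "/"))
  }
}

#' Cumulative support-sampling paths
#'
#' Cumulative sums of per-gene proportionate support when genes are
#' added in four orders: descending support (ideal design), ascending
#' (worst case), the analytic average path (k-th point = k x mean), and
#' DPI-rank order. All four curves end at the same total.
#'
#' @param gene_support named numeric vector of per-gene PLRS/PIDS.
#' @param ranking a [rank_genes()] result covering the same genes.
#' @return data frame with columns `k`, `ideal`, `worst`, `average`,
#'   `dpi_order`.
#' @export
cumulative_paths <- function(gene_support, ranking) {
  if (length(gene_support) < 2) stop("need >= 2 genes")
  stopifnot(setequal(names(gene_support), ranking$gene_id))
  by_rank <- gene_support[ranking$gene_id[order(ranking$rank)]]
  k <- seq_along(gene_support)
  data.frame(k = k,
             ideal = cumsum(sort(gene_support, decreasing = TRUE)),
             worst = cumsum(sort(gene_support)),
             average = k * mean(gene_support),
             dpi_order = cumsum(unname(by_rank)))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

## cheap deterministic content hash of an alignment (for child seeds)
.alignment_hash <- function(aln) {
  v <- match(unclass(aln), c(DNA_STATES, AA_STATES))
  v[is.na(v)] <- 0L
  sum(v * (seq_along(v) %% 97L + 1L)) %% 1000003
}

#' Settings for a study evaluation
#'
#' @param support branch-support metric used for EPP and the cumulative
#'   paths: `"ml_bp"`, `"mp_bp"`, `"alrt"` or `"di"`.
#' @param h1,h2 DPI epoch in Myr; `h2 = NULL` means the chronogram root.
#' @param rates a [rate_settings()].
#' @param inference an [inference_settings()].
#' @param tie_policy EPP tie policy, see [epp()].
#' @param plrs_normalization see [plrs()].
#' @param support_replicates compute the (expensive) support metric only
#'   for this many replicates per gene; DPI and RF still use all
#'   replicates. `Inf` (default) = all. A compute-scaling knob for large
#'   replicated studies.
#' @param seed master seed for the inference stages.
#' @return list of class `evaluation_settings`.
#' @export
evaluation_settings <- function(support = c("ml_bp", "mp_bp", "alrt", "di"),
                                h1 = 0, h2 = NULL,
                                rates = NULL, inference = NULL,
                                tie_policy = c("none", "half"),
                                plrs_normalization = c("n_genes", "node_sum"),
                                support_replicates = Inf,
                                seed = 1) {
  structure(list(support = match.arg(support), h1 = h1, h2 = h2,
                 rates = rates, inference = inference,
                 tie_policy = match.arg(tie_policy),
                 plrs_normalization = match.arg(plrs_normalization),
                 support_replicates = support_replicates,
                 seed = as.integer(seed)),
            class = "evaluation_settings")
}

.default_stage_settings <- function(settings, study) {
  model_tag <- study$genes[[1]]$design$model_tag
  if (is.null(settings$rates)) settings$rates <- rate_settings(model_tag)
  if (is.null(settings$inference))
    settings$inference <- inference_settings(model_tag, seed = settings$seed)
  settings
}

#' Run the full DPI-vs-performance evaluation on a study
#'
#' For every gene replicate: estimates per-site rates on the chronogram,
#' computes DPI over the epoch, infers the ML gene tree, measures the RF
#' distance to the reference topology, and (as required by the chosen
#' support metric) computes bootstrap/aLRT/parsimony supports mapped
#' onto the reference. Replicate values are averaged per gene; the gene
#' ranking uses replicate-mean DPI. Three analyses are reported: DPI
#' rank vs RF distance (Pearson), PPP vs EPP over best-worst pairs
#' (Pearson), and per-gene proportionate support with cumulative
#' sampling paths. Genes failing at any stage are excluded with a
#' logged reason rather than aborting the study.
#'
#' @param study a `pi_study` from [build_study()] (or the same shape
#'   assembled from empirical inputs).
#' @param settings an [evaluation_settings()].
#' @param reference reference topology; defaults to the study
#'   chronogram's topology.
#' @return list of class `study_evaluation`: `genes` (per-gene table),
#'   `pairs`, `correlations`, `paths`, `excluded`, `ranking`.
#' @export
evaluate_study <- function(study, settings = evaluation_settings(),
                           reference = NULL) {
  settings <- .default_stage_settings(settings, study)
  if (is.null(reference)) reference <- study$chronogram
  ref_splits <- bipartitions(reference)
  h2 <- if (is.null(settings$h2)) root_depth(study$chronogram) else settings$h2
  need_ml <- settings$support %in% c("ml_bp", "alrt")
  need_mp <- settings$support %in% c("mp_bp", "di")

  per_rep <- list()
  excluded <- list()
  for (i in seq_along(study$genes)) {
    g <- study$genes[[i]]
    res <- tryCatch({
      rates <- suppressWarnings(
        estimate_rates(g$alignment, study$chronogram, settings$rates))
      gene_dpi <- dpi(rates, settings$h1, h2)
      inf <- settings$inference
      ## content-derived child seed: identical alignments are processed
      ## identically (so true ties stay ties), independent of position
      inf$seed <- as.integer(child_seed(settings$seed,
                                        .alignment_hash(g$alignment)))
      fit <- ml_tree(g$alignment, inf)
      rf <- rf_distance(fit$tree, reference)
      node_support <- NULL
      if (g$replicate <= settings$support_replicates) {
        support <- switch(settings$support,
          ml_bp = ml_bootstrap(g$alignment, inf, fit),
          alrt  = alrt_statistic(fit, inf),
          mp_bp = mp_bootstrap(g$alignment, inf),
          di    = {
            mp <- mp_tree(g$alignment, inf)
            decay_index(mp, g$alignment, inf)
          })
        node_support <- map_supports_to_reference(support, reference,
                                                  value = settings$support)
      }
      list(gene_id = g$gene_id, replicate = g$replicate, dpi = gene_dpi,
           rf = rf, node_support = node_support)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1]] <-
        data.frame(gene_id = g$gene_id, replicate = g$replicate,
                   reason = conditionMessage(res))
    } else per_rep[[length(per_rep) + 1]] <- res
  }
  if (!length(per_rep)) stop("every gene failed evaluation")

  ## replicate means per gene
  ids <- vapply(per_rep, `[[`, character(1), "gene_id")
  genes <- sort(unique(ids))
  mean_dpi <- vapply(genes, function(g)
    mean(vapply(per_rep[ids == g], `[[`, numeric(1), "dpi")), numeric(1))
  mean_rf <- vapply(genes, function(g)
    mean(vapply(per_rep[ids == g], `[[`, numeric(1), "rf")), numeric(1))
  support_mat <- do.call(rbind, lapply(genes, function(g) {
    sup <- Filter(Negate(is.null),
                  lapply(per_rep[ids == g], `[[`, "node_support"))
    if (!length(sup)) return(rep(NA_real_, length(ref_splits)))
    rowMeans(matrix(unlist(sup), nrow = length(ref_splits)))
  }))
  rownames(support_mat) <- genes; colnames(support_mat) <- ref_splits

  ranking <- .rank_from_dpi(mean_dpi, settings$h1, h2)
  gene_table <- data.frame(gene_id = ranking$gene_id, dpi = ranking$dpi,
                           rank = ranking$rank,
                           rf = mean_rf[ranking$gene_id])
  gene_support <- plrs(support_mat,
                       normalization = settings$plrs_normalization)
  gene_table$plrs <- unname(gene_support[gene_table$gene_id])

  ## analysis 1: rank vs RF distance
  cor_rank_rf <- tryCatch(pearson(gene_table$rank, gene_table$rf),
                          error = function(e) list(r = NA, p = NA, n = nrow(gene_table)))
  ## analysis 2: PPP vs EPP over best-worst pairs
  pairs <- pair_genes(ranking)
  pairs$ppp <- NA_real_; pairs$epp <- NA_real_
  pairs$n_hi <- NA_real_; pairs$n_lo <- NA_real_
  for (j in seq_len(nrow(pairs))) {
    hi <- pairs$gene_hi[j]; lo <- pairs$gene_lo[j]
    if (mean_dpi[hi] <= 0 && mean_dpi[lo] <= 0) next  # pair excluded
    if (anyNA(support_mat[hi, ]) || anyNA(support_mat[lo, ])) next
    pairs$ppp[j] <- ppp(mean_dpi[hi], mean_dpi[lo])
    e <- epp(support_mat[hi, ], support_mat[lo, ], settings$tie_policy)
    pairs$epp[j] <- e$epp; pairs$n_hi[j] <- e$n_hi; pairs$n_lo[j] <- e$n_lo
  }
  ok <- is.finite(pairs$ppp) & is.finite(pairs$epp)
  cor_ppp_epp <- if (sum(ok) >= 3)
    tryCatch(pearson(pairs$ppp[ok], pairs$epp[ok]),
             error = function(e) list(r = NA_real_, p = NA_real_, n = sum(ok)))
  else list(r = NA_real_, p = NA_real_, n = sum(ok))
  ## analysis 3: cumulative paths + rank vs PLRS correlation
  paths <- cumulative_paths(gene_support, ranking)
  cor_rank_plrs <- tryCatch(pearson(gene_table$rank, gene_table$plrs),
                            error = function(e) list(r = NA, p = NA, n = nrow(gene_table)))

  correlations <- data.frame(
    analysis = c("rank_vs_rf", "ppp_vs_epp", "rank_vs_plrs"),
    n = c(cor_rank_rf$n, cor_ppp_epp$n, cor_rank_plrs$n),
    r = c(cor_rank_rf$r, cor_ppp_epp$r, cor_rank_plrs$r),
    p = c(cor_rank_rf$p, cor_ppp_epp$p, cor_rank_plrs$p))

  structure(list(genes = gene_table, pairs = pairs,
                 correlations = correlations, paths = paths,
                 support_matrix = support_mat, ranking = ranking,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                            else NULL,
                 settings = settings),
            class = "study_evaluation")
}

#' @export
print.study_evaluation <- function(x, ...) {
  cat(sprintf("<study_evaluation> %d genes, support = %s\n",
              nrow(x$genes), x$settings$support))
  print(x$correlations)
  invisible(x)
}
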