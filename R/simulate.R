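## Synthetic data: Yule chronograms and rate-heterogeneous alignments.
##
## The generator emulates a classic simulation design: alignments of 300
## sites evolved on a 28-taxon, 973-Myr-deep ultrametric tree, at one of
## 10 mean rates spanning 0.0001-0.001 subs/site/Myr, with among-site
## heterogeneity from a 10-category discrete gamma (shape in
## {none, 0.5, 1, 2, 3}) and 20% invariant sites. Under the fixed-counts
## scheme every replicate holds exactly 60 invariant sites and 24 sites
## per category, so replicates share the exact rate multiset but not the
## sequences.

#' Simulation design for one gene
#'
#' @param mean_rate mean rate of the non-invariant sites, subs/site/Myr.
#' @param gamma_alpha gamma shape for among-site heterogeneity, or `NA`
#'   for a single rate class.
#' @param n_categories discrete-gamma categories.
#' @param invariant_fraction proportion of zero-rate sites.
#' @param n_sites alignment length.
#' @param model_tag `"JTT"` (amino acid) or `"K2P"` (DNA).
#' @param kappa transition/transversion ratio for K2P.
#' @param replicate_scheme `"fixed_counts"` (exact per-category site
#'   counts) or `"stochastic"` (each site draws its class independently).
#' @param n_replicates replicate alignments per design.
#' @param rate_scaling `"noninvariant"` (default): category rates average
#'   `mean_rate` over the variable sites only, so the alignment-wide mean
#'   is `mean_rate * (1 - invariant_fraction)`. `"global"`: rescaled by
#'   `1/(1 - invariant_fraction)` so the alignment-wide mean equals
#'   `mean_rate`.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(mean_rate, gamma_alpha = NA, n_categories = 10,
                              invariant_fraction = 0.20, n_sites = 300,
                              model_tag = c("JTT", "K2P"), kappa = 2,
                              replicate_scheme = c("fixed_counts", "stochastic"),
                              n_replicates = 10,
                              rate_scaling = c("noninvariant", "global")) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  replicate_scheme <- match.arg(replicate_scheme)
  rate_scaling <- match.arg(rate_scaling)
  stopifnot(mean_rate > 0, is.na(gamma_alpha) || gamma_alpha > 0,
            n_categories >= 1, invariant_fraction >= 0, invariant_fraction < 1,
            n_sites >= 1, n_replicates >= 1)
  structure(list(mean_rate = mean_rate, gamma_alpha = gamma_alpha,
                 n_categories = as.integer(n_categories),
                 invariant_fraction = invariant_fraction,
                 n_sites = as.integer(n_sites), model_tag = model_tag,
                 kappa = kappa, replicate_scheme = replicate_scheme,
                 n_replicates = as.integer(n_replicates),
                 rate_scaling = rate_scaling),
            class = "simulation_design")
}

#' Simulate a pure-birth (Yule) chronogram
#'
#' Starts from a root split into two lineages; while k lineages are
#' extant the waiting time to the next split is Exp(k), and the splitting
#' lineage is chosen uniformly. After the n-th tip appears, a final
#' Exp(n) interval runs to the present. Node times are then rescaled so
#' the root depth equals `root_depth` exactly, giving an ultrametric tree
#' by construction.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param root_depth depth in Myr (> 0).
#' @param seed integer RNG seed.
#' @return a `chronogram` (ultrametric `phylo`) with tips `t1..tn`; the
#'   unscaled split times are attached as attribute `"event_times"`.
#' @export
generate_chronogram <- function(n_taxa, root_depth, seed = 1) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  stopifnot(root_depth > 0)
  set.seed(as.integer(seed))
  ## grow the tree: nodes identified by integer ids as they appear
  parent <- integer(0); birth <- numeric(0)
  new_node <- function() length(parent) + 1L
  root <- 1L; parent[1] <- 0L; birth[1] <- 0
  active <- c(2L, 3L); parent[2:3] <- root; birth[2:3] <- 0
  t <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k)
    j <- active[sample.int(k, 1)]
    c1 <- length(parent) + 1L; c2 <- c1 + 1L
    parent[c(c1, c2)] <- j; birth[c(c1, c2)] <- t
    active <- c(setdiff(active, j), c1, c2)
  }
  t_end <- t + stats::rexp(1, rate = n_taxa)
  ## assemble an ape phylo: tips are nodes with no children
  has_child <- unique(parent[parent > 0])
  ids <- seq_along(parent)
  tip_ids <- setdiff(ids[-root], has_child)
  int_ids <- c(root, setdiff(has_child, root))
  n <- length(tip_ids)
  stopifnot(n == n_taxa)
  renum <- integer(length(parent))
  renum[tip_ids] <- seq_len(n)
  renum[int_ids] <- n + seq_along(int_ids)
  end_time <- rep(t_end, length(parent))
  for (i in has_child) end_time[i] <- birth[parent == i][1]
  keep <- ids != root
  edge <- cbind(renum[parent[keep]], renum[ids[keep]])
  elen <- (end_time[keep] - birth[keep]) * (root_depth / t_end)
  phy <- list(edge = edge, edge.length = elen,
              tip.label = paste0("t", seq_len(n)), Nnode = length(int_ids))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy <- as_chronogram(phy)
  ## unscaled split times (root splits at 0), for checking Yule growth
  attr(phy, "event_times") <- sort(end_time[int_ids])
  phy
}

#' Draw per-site generating rates for a design
#'
#' Under `fixed_counts`, exactly `round(n_sites * invariant_fraction)`
#' sites get rate 0 and the remaining sites are split equally across the
#' gamma categories (an error if the counts do not divide evenly); site
#' positions are shuffled. Under `stochastic`, each site is independently
#' invariant with probability `invariant_fraction`, otherwise assigned a
#' uniformly drawn category.
#'
#' @param design a [simulation_design()].
#' @param seed integer RNG seed.
#' @return a [site_rate_vector()] with provenance `"generating"`.
#' @export
assign_site_rates <- function(design, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(as.integer(seed))
  K <- if (is.na(design$gamma_alpha)) 1L else design$n_categories
  cat_rates <- if (is.na(design$gamma_alpha)) 1
               else discretize_gamma(design$gamma_alpha, K)
  scale <- design$mean_rate *
    if (design$rate_scaling == "global") 1 / (1 - design$invariant_fraction) else 1
  cat_rates <- cat_rates * scale
  n <- design$n_sites
  if (design$replicate_scheme == "fixed_counts") {
    n_inv <- round(n * design$invariant_fraction)
    n_var <- n - n_inv
    if (n_var %% K != 0)
      stop("fixed_counts: ", n_var, " variable sites not divisible into ",
           K, " categories")
    rates <- c(rep(0, n_inv), rep(cat_rates, each = n_var %/% K))
    rates <- rates[sample.int(n)]
  } else {
    inv <- stats::runif(n) < design$invariant_fraction
    rates <- ifelse(inv, 0, cat_rates[sample.int(K, n, replace = TRUE)])
  }
  site_rate_vector(rates, provenance = "generating")
}

#' Simulate an alignment on a chronogram
#'
#' Root states are drawn from the model's stationary frequencies (JTT
#' empirical frequencies, or uniform 1/4 for K2P); along each branch each
#' site evolves by the transition matrix \eqn{\exp(Q \lambda_i t)}.
#' Zero-rate sites are identical across all taxa by construction.
#'
#' @param chronogram ultrametric tree, durations in Myr.
#' @param site_rates a [site_rate_vector()] (subs/site/Myr).
#' @param model_tag `"JTT"` or `"K2P"`.
#' @param kappa transition/transversion ratio (K2P).
#' @param seed integer RNG seed.
#' @return a [pi_alignment()].
#' @export
simulate_alignment <- function(chronogram, site_rates, model_tag = c("JTT", "K2P"),
                               kappa = 2, seed = 1) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  rates <- if (inherits(site_rates, "site_rate_vector")) site_rates$rates
           else as.numeric(site_rates)
  stopifnot(all(rates >= 0))
  model <- substitution_model(model_tag, kappa)
  set.seed(as.integer(seed))
  tree <- stats::reorder(chronogram, "cladewise")  # parents before children
  n_tip <- length(tree$tip.label)
  n_sites <- length(rates)
  ns <- model$n_states
  ## category compression: transition matrices only per (edge, unique rate)
  u <- sort(unique(rates))
  rate_id <- match(rates, u)
  root <- n_tip + 1L
  states <- matrix(NA_integer_, n_tip + tree$Nnode, n_sites)
  states[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = model$pi)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    child_states <- states[p, ]
    for (ci in seq_along(u)) {
      if (u[ci] == 0) next  # invariant sites copy the parent state
      sites <- which(rate_id == ci)
      if (!length(sites)) next
      P <- transition_matrix(model, u[ci] * tree$edge.length[k])
      for (s in unique(states[p, sites])) {
        idx <- sites[states[p, sites] == s]
        child_states[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
    states[ch, ] <- child_states
  }
  mat <- matrix(model$states[states[seq_len(n_tip), ]], n_tip, n_sites)
  rownames(mat) <- tree$tip.label
  pi_alignment(mat, if (model_tag == "K2P") "dna" else "aa")
}

#' The standard 10 x 5 simulation grid
#'
#' Ten mean rates evenly spaced from 0.0001 to 0.001 subs/site/Myr crossed
#' with five heterogeneity regimes (no heterogeneity plus gamma shapes
#' 0.5, 1, 2 and 3), giving 50 designs of 300 sites with 20% invariant
#' sites and 10-category discrete gamma under the fixed-counts scheme.
#'
#' @param model_tag `"JTT"` or `"K2P"`.
#' @param n_replicates replicates per design.
#' @param n_sites sites per alignment.
#' @return list of [simulation_design()] objects, named `g01..g50`.
#' @export
standard_design_grid <- function(model_tag = c("JTT", "K2P"), n_replicates = 10,
                                 n_sites = 300) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  rates <- seq(1e-4, 1e-3, length.out = 10)
  alphas <- c(NA, 0.5, 1, 2, 3)
  grid <- expand.grid(alpha = alphas, rate = rates,
                      KEEP.OUT.ATTRS = FALSE)  # rate varies slowest
  designs <- lapply(seq_len(nrow(grid)), function(i)
    simulation_design(mean_rate = grid$rate[i], gamma_alpha = grid$alpha[i],
                      model_tag = model_tag, n_replicates = n_replicates,
                      n_sites = n_sites))
  names(designs) <- sprintf("g%02d", seq_along(designs))
  designs
}

## deterministic child-seed derivation: independent of how many genes
## precede, bounded below 2^31
child_seed <- function(master_seed, index) {
  (as.numeric(master_seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647
}

#' Simulate a full study from a design grid
#'
#' For every design and replicate, draws generating site rates and
#' simulates an alignment on the shared chronogram. Seeds for each
#' (design, replicate) are derived from `seed` by fixed arithmetic, so
#' the study is byte-reproducible and individual genes can be regenerated
#' independently.
#'
#' @param designs list of [simulation_design()] (e.g.
#'   [standard_design_grid()]).
#' @param chronogram the shared chronogram; default is a seeded 28-taxon,
#'   973-Myr Yule tree.
#' @param seed master seed.
#' @return list of class `pi_study`: `chronogram`, `genes` (one entry per
#'   design x replicate with `gene_id`, `replicate`, `alignment`,
#'   `rates_true`, `seed`), and a `manifest` data frame.
#' @export
build_study <- function(designs, chronogram = NULL, seed = 1) {
  if (is.null(chronogram))
    chronogram <- generate_chronogram(28, 973, seed = child_seed(seed, 0))
  genes <- list()
  rows <- list()
  idx <- 0L
  for (g in seq_along(designs)) {
    d <- designs[[g]]
    gene_id <- names(designs)[g]
    if (is.null(gene_id) || !nzchar(gene_id)) gene_id <- sprintf("g%02d", g)
    for (r in seq_len(d$n_replicates)) {
      idx <- idx + 1L
      sd <- child_seed(seed, idx)
      rates <- assign_site_rates(d, seed = sd)
      aln <- simulate_alignment(chronogram, rates, d$model_tag, d$kappa,
                                seed = sd + 1)
      genes[[idx]] <- list(gene_id = gene_id, replicate = r, design = d,
                           alignment = aln, rates_true = rates, seed = sd)
      rows[[idx]] <- data.frame(gene_id = gene_id, replicate = r,
                                mean_rate = d$mean_rate,
                                gamma_alpha = d$gamma_alpha,
                                model_tag = d$model_tag, n_sites = d$n_sites,
                                seed = sd)
    }
  }
  structure(list(chronogram = chronogram, genes = genes,
                 manifest = do.call(rbind, rows)),
            class = "pi_study")
}

#' @export
print.pi_study <- function(x, ...) {
  cat(sprintf("<pi_study> %d gene alignments (%d designs) on a %d-taxon chronogram\n",
              length(x$genes), length(unique(x$manifest$gene_id)),
              length(x$chronogram$tip.label)))
  invisible(x)
}

#' Write a study to disk
#'
#' Emits one FASTA per gene replicate, the chronogram as Newick, the
#' generating rates as TSV, and a manifest TSV binding them.
#'
#' @param study a `pi_study` from [build_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$chronogram, file.path(dir, "chronogram.nwk"))
  paths <- character(length(study$genes))
  for (i in seq_along(study$genes)) {
    g <- study$genes[[i]]
    base <- sprintf("%s_rep%d", g$gene_id, g$replicate)
    paths[i] <- paste0(base, ".fasta")
    write_alignment(g$alignment, file.path(dir, paths[i]))
    utils::write.table(
      data.frame(site = seq_along(g$rates_true$rates), rate = g$rates_true$rates),
      file.path(dir, paste0(base, ".rates.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- cbind(study$manifest, path = paths)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
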