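## Felsenstein pruning engine, vectorized across sites with per-site rates.
##
## For a reversible model with spectral form Q = T1 diag(e) T2, the
## transition matrix along a branch of duration t at site rate r is
## P = T1 diag(exp(e * r * t)) T2. Propagating a partial-likelihood block
## L (n_states x n_sites) through a branch therefore costs two dense
## matrix products plus an elementwise exp, with per-site rates entering
## only through the factor exp(outer(e, r * t)). This is what makes
## per-site rate optimization cheap: one pruning pass evaluates every
## site at its own candidate rate.

## tip partial block: n_states x n_sites indicator columns, all-ones for
## missing (gap/ambiguity) characters
.tip_partial <- function(codes_row, n_states) {
  n <- length(codes_row)
  L <- matrix(0, n_states, n)
  miss <- is.na(codes_row)
  if (any(!miss)) L[cbind(codes_row[!miss], which(!miss))] <- 1
  L[, miss] <- 1
  L
}

## Precompute everything that does not depend on the candidate rates.
## codes: integer matrix taxa x sites (rownames = taxon labels, NA missing).
prune_cache <- function(tree, codes, model) {
  n_tip <- length(tree$tip.label)
  stopifnot(!is.null(rownames(codes)),
            all(tree$tip.label %in% rownames(codes)))
  codes <- codes[tree$tip.label, , drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  tips <- lapply(seq_len(n_tip), function(i) .tip_partial(codes[i, ], model$n_states))
  list(tree = tree, model = model, n_tip = n_tip, n_sites = ncol(codes),
       tips = tips,
       n_children = tabulate(tree$edge[, 1], nbins = n_tip + tree$Nnode))
}

## Per-site log-likelihoods at per-site rates; `rates` scalar or vector.
prune_loglik_cached <- function(cache, rates) {
  tree <- cache$tree; model <- cache$model
  n_tip <- cache$n_tip; n_sites <- cache$n_sites
  if (length(rates) == 1L) rates <- rep(rates, n_sites)
  stopifnot(length(rates) == n_sites, all(rates >= 0))
  ns <- model$n_states
  e <- model$eigenvalues; T1 <- model$T1; T2 <- model$T2
  partial <- vector("list", n_tip + tree$Nnode)
  logscale <- numeric(n_sites)
  edge <- tree$edge; elen <- tree$edge.length
  seen <- integer(length(partial))
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1]; child <- edge[k, 2]
    L <- if (child <= n_tip) cache$tips[[child]] else partial[[child]]
    v <- rates * elen[k]
    W <- T1 %*% (exp(outer(e, v)) * (T2 %*% L))
    W[W < 0] <- 0
    ## exact identity at v = 0: avoid spectral roundoff leaking probability
    if (any(v == 0)) W[, v == 0] <- L[, v == 0]
    if (is.null(partial[[parent]])) partial[[parent]] <- W
    else partial[[parent]] <- partial[[parent]] * W
    if (child > n_tip) partial[child] <- list(NULL)
    seen[parent] <- seen[parent] + 1L
    ## rescale the parent block once all its children are in
    if (seen[parent] == cache$n_children[parent]) {
      mx <- apply(partial[[parent]], 2, max)
      pos <- mx > 0
      if (any(pos)) {
        partial[[parent]][, pos] <- partial[[parent]][, pos] /
          rep(mx[pos], each = ns)
        logscale[pos] <- logscale[pos] + log(mx[pos])
      }
      if (any(!pos)) logscale[!pos] <- -Inf
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- colSums(model$pi * partial[[root]])
  ifelse(lik > 0 & is.finite(logscale), log(lik) + logscale, -Inf)
}

## Convenience wrapper: one-shot per-site log-likelihoods.
prune_loglik <- function(tree, codes, rates, model) {
  prune_loglik_cached(prune_cache(tree, codes, model), rates)
}
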