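## Independent oracles used across the suite. These deliberately avoid the
## package's own pruning/bipartition code paths: likelihoods by exhaustive
## enumeration over ancestral states, parsimony by enumeration over
## ancestral assignments, splits by literal edge removal.

## exhaustive-likelihood oracle: sum over all ancestral-state assignments
oracle_site_lik <- function(tree, codes_col, rate, model) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  ns <- model$n_states
  Plist <- lapply(tree$edge.length, function(t) transition_matrix(model, rate * t))
  internals <- (n + 1):(n + tree$Nnode)
  root <- tree$edge[nrow(tree$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internals))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(n + tree$Nnode)
    st[internals] <- grid[g, ]
    st[seq_len(n)] <- codes_col[tree$tip.label]
    p <- model$pi[st[root]]
    for (k in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      if (ch <= n && is.na(st[ch])) next  # missing tip: sums to 1
      p <- p * Plist[[k]][st[pa], st[ch]]
    }
    total <- total + p
  }
  total
}

## gamma-mixture version: average the oracle over discrete-gamma categories
oracle_tree_loglik <- function(tree, aln, model, shape = NULL, k = 1) {
  codes <- pirank:::alignment_codes(aln)
  cr <- if (is.null(shape)) 1 else discretize_gamma(shape, k)
  sum(apply(codes, 2, function(col) {
    names(col) <- rownames(codes)
    log(mean(vapply(cr, function(r) oracle_site_lik(tree, col, r, model),
                    numeric(1))))
  }))
}

## brute-force parsimony: minimize changes over all ancestral assignments
oracle_fitch <- function(tree, codes) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  ns <- max(codes, na.rm = TRUE)
  internals <- (n + 1):(n + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internals))))
  total <- 0
  for (s in seq_len(ncol(codes))) {
    col <- codes[tree$tip.label, s]
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- integer(n + tree$Nnode)
      st[internals] <- grid[g, ]
      st[seq_len(n)] <- col
      changes <- 0
      for (k in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
        if (ch <= n && is.na(st[ch])) next
        changes <- changes + (st[pa] != st[ch])
      }
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

## splits by literal edge removal: drop each internal edge, collect the
## two components' tip labels
oracle_splits <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  g <- igraph_free_components <- NULL  # no igraph: hand-rolled BFS
  out <- character(0)
  for (k in seq_len(nrow(phy$edge))) {
    if (phy$edge[k, 2] <= n) next  # trivial split
    ## component of the child after removing edge k
    adj <- rbind(phy$edge, phy$edge[, 2:1])
    adj <- adj[-c(k, k + nrow(phy$edge)), , drop = FALSE]
    seen <- phy$edge[k, 2]
    frontier <- seen
    while (length(frontier)) {
      nxt <- adj[adj[, 1] %in% frontier, 2]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    side <- phy$tip.label[seen[seen <= n]]
    if (length(side) >= 2 && length(side) <= n - 2)
      out <- c(out, pirank:::.split_key(side, phy$tip.label))
  }
  sort(unique(out))
}

## random unrooted binary topology with random branch lengths
random_topology <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, rooted = FALSE)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.05, 0.8)
  phy
}

## closed-form K2P probability that two sequences separated by v expected
## substitutions differ at a site (kappa = ts/tv ratio)
k2p_p_diff <- function(v, kappa = 2) {
  ## rates: alpha = kappa*beta (transition), beta; scaled so
  ## total rate alpha + 2 beta = 1 => beta = 1/(kappa + 2)
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * v) - 0.5 * exp(-2 * (alpha + beta) * v)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * v)
  p_ts + p_tv
}

## K2P distance from observed transition (P) and transversion (Q) fractions
k2p_distance <- function(P, Q) {
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
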