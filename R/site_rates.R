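## Maximum-likelihood estimation of an independent rate per alignment site
## on a fixed chronogram (branch durations in Myr; rates in
## substitutions/site/Myr). One rate parameter per site, no re-estimation
## of topology or branch durations: deliberately the simplest model that
## identifies the per-site rate, to avoid overparameterization.

#' Settings for per-site rate estimation
#'
#' @param model_tag `"JTT"` or `"K2P"`.
#' @param kappa transition/transversion ratio (K2P only).
#' @param rate_upper upper bound on the site rate, subs/site/Myr. The
#'   default, 20 expected substitutions root-to-tip, is set per call from
#'   the chronogram depth; saturated columns clamp here with a warning.
#'   Informativeness at such rates is essentially zero at all relevant
#'   depths, so the clamp cannot distort gene rankings.
#' @param rate_lower lower bound (>= 0).
#' @param tol relative tolerance of the scalar refinement.
#' @param n_grid points in the coarse geometric grid searched before
#'   refinement (guards against flat or multimodal site likelihoods).
#' @return a list of class `rate_settings`.
#' @export
rate_settings <- function(model_tag = c("JTT", "K2P"), kappa = 2,
                          rate_upper = NULL, rate_lower = 0,
                          tol = 1e-5, n_grid = 25) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  stopifnot(rate_lower >= 0, is.null(rate_upper) || rate_upper > rate_lower)
  structure(list(model_tag = model_tag, kappa = kappa,
                 rate_upper = rate_upper, rate_lower = rate_lower,
                 tol = tol, n_grid = as.integer(n_grid)),
            class = "rate_settings")
}

.settings_model <- function(settings) {
  substitution_model(settings$model_tag, settings$kappa)
}

.resolve_rate_upper <- function(settings, chronogram) {
  if (!is.null(settings$rate_upper)) settings$rate_upper
  else 20 / max(ape::node.depth.edgelength(chronogram))
}

#' Log-likelihood of one alignment column at a given site rate
#'
#' Felsenstein pruning on the fixed chronogram, with per-branch transition
#' matrices \eqn{\exp(Q \lambda t)}. Gaps and ambiguities contribute a
#' partial likelihood of 1 for every state (missing data). A rate of 0
#' gives \eqn{\log \pi_s} for a monomorphic column in state s and
#' \eqn{-\infty} for a polymorphic one.
#'
#' @param chronogram ultrametric tree, durations in Myr.
#' @param column character vector of states, named by taxon (or in
#'   `chronogram$tip.label` order).
#' @param rate site rate, subs/site/Myr (>= 0).
#' @param settings a [rate_settings()].
#' @return scalar log-likelihood.
#' @export
site_log_likelihood <- function(chronogram, column, rate,
                                settings = rate_settings()) {
  if (rate < 0) stop("rate must be >= 0")
  aln <- .column_alignment(column, chronogram, settings)
  prune_loglik(chronogram, alignment_codes(aln), rate, .settings_model(settings))[1]
}

.column_alignment <- function(column, chronogram, settings) {
  if (is.null(names(column))) names(column) <- chronogram$tip.label
  mat <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  pi_alignment(mat, if (settings$model_tag == "K2P") "dna" else "aa")
}

#' ML rate for one alignment column
#'
#' Coarse geometric-grid search followed by golden-section refinement of
#' the site log-likelihood over `[rate_lower, rate_upper]`. Monomorphic or
#' all-missing columns return exactly 0.
#'
#' @inheritParams site_log_likelihood
#' @return estimated rate (scalar).
#' @export
estimate_site_rate <- function(chronogram, column, settings = rate_settings()) {
  aln <- .column_alignment(column, chronogram, settings)
  as.numeric(.estimate_rates_impl(aln, chronogram, settings)$rates)
}

#' ML per-site rates for an alignment on a chronogram
#'
#' Applies the per-column rate estimator to every site. The chronogram is
#' pruned to the taxa present in the alignment (at least 4 shared taxa
#' required). Invariant columns return exactly 0; columns whose likelihood
#' is still increasing at `rate_upper` clamp there with a warning.
#'
#' @param alignment a [pi_alignment()].
#' @param chronogram ultrametric tree, durations in Myr.
#' @param settings a [rate_settings()].
#' @return a `site_rate_vector`: list with `rates` (subs/site/Myr),
#'   `loglik` (per-site log-likelihood at the optimum), and
#'   `provenance = "estimated"`.
#' @export
estimate_rates <- function(alignment, chronogram, settings = rate_settings()) {
  stopifnot(inherits(alignment, "pi_alignment"))
  shared <- intersect(rownames(alignment), chronogram$tip.label)
  if (length(shared) < 4) stop("fewer than 4 taxa shared between alignment and chronogram")
  .estimate_rates_impl(alignment, chronogram, settings)
}

.estimate_rates_impl <- function(alignment, chronogram, settings) {
  shared <- intersect(rownames(alignment), chronogram$tip.label)
  if (length(shared) < 2) stop("fewer than 2 taxa shared between alignment and chronogram")
  if (length(shared) < length(chronogram$tip.label))
    chronogram <- ape::keep.tip(chronogram, shared)
  alignment <- alignment[shared, ]
  model <- .settings_model(settings)
  codes <- alignment_codes(alignment)
  n_sites <- ncol(codes)
  rates <- numeric(n_sites)
  loglik <- numeric(n_sites)

  ## monomorphic (ignoring missing) or all-missing columns: rate exactly 0
  n_distinct <- apply(codes, 2, function(x) length(unique(x[!is.na(x)])))
  invariant <- n_distinct <= 1L
  if (any(invariant)) {
    mono_state <- apply(codes[, invariant, drop = FALSE], 2,
                        function(x) { u <- unique(x[!is.na(x)]); if (length(u)) u else NA })
    loglik[invariant] <- ifelse(is.na(mono_state), 0, log(model$pi[mono_state]))
  }
  if (all(invariant))
    return(site_rate_vector(rates, provenance = "estimated", loglik = loglik))

  upper <- .resolve_rate_upper(settings, chronogram)
  lower <- max(settings$rate_lower, 1e-6 * upper / 20)  # geometric grid needs > 0
  poly <- which(!invariant)
  cache <- prune_cache(chronogram, codes[, poly, drop = FALSE], model)
  np <- length(poly)

  grid <- exp(seq(log(lower), log(upper), length.out = settings$n_grid))
  gl <- vapply(grid, function(r) prune_loglik_cached(cache, r), numeric(np))
  if (np == 1L) gl <- matrix(gl, nrow = 1)
  best <- max.col(gl, ties.method = "first")

  ## golden-section refinement in log-rate space, all sites in lockstep
  lg <- log(grid)
  a <- lg[pmax(best - 1L, 1L)]
  b <- lg[pmin(best + 1L, settings$n_grid)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- prune_loglik_cached(cache, exp(x1))
  f2 <- prune_loglik_cached(cache, exp(x2))
  max_iter <- ceiling(log(settings$tol / max(b - a)) / log(gr)) + 2L
  for (it in seq_len(max(max_iter, 1L))) {
    take1 <- f1 >= f2          # maximum lies in [a, x2]; else in [x1, b]
    x1old <- x1; x2old <- x2; f1old <- f1; f2old <- f2
    b <- ifelse(take1, x2old, b)
    a <- ifelse(take1, a, x1old)
    x1 <- ifelse(take1, b - gr * (b - a), x2old)
    x2 <- ifelse(take1, x1old, a + gr * (b - a))
    fe <- prune_loglik_cached(cache, exp(ifelse(take1, x1, x2)))
    f1 <- ifelse(take1, fe, f2old)
    f2 <- ifelse(take1, f1old, fe)
    if (max(b - a) < settings$tol) break
  }
  mid <- exp((a + b) / 2)
  fmid <- prune_loglik_cached(cache, mid)
  ## saturated columns: likelihood still rising at the cap
  at_cap <- best == settings$n_grid & abs(mid - upper) < upper * 0.05
  if (any(at_cap)) {
    mid[at_cap] <- upper
    fmid[at_cap] <- prune_loglik_cached(cache, ifelse(at_cap, upper, mid))[at_cap]
    warning(sum(at_cap), " column(s) clamped at rate_upper = ", format(upper))
  }
  rates[poly] <- mid
  loglik[poly] <- fmid
  site_rate_vector(rates, provenance = "estimated", loglik = loglik)
}

#' Construct a site-rate vector
#'
#' @param rates numeric vector of non-negative, finite per-site rates in
#'   substitutions/site/Myr.
#' @param provenance `"generating"` (simulation truth) or `"estimated"`.
#' @param loglik optional per-site log-likelihood at the estimate.
#' @return list of class `site_rate_vector`.
#' @export
site_rate_vector <- function(rates, provenance = c("generating", "estimated"),
                             loglik = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(rates), all(is.finite(rates)), all(rates >= 0))
  structure(list(rates = as.numeric(rates), provenance = provenance,
                 loglik = loglik),
            class = "site_rate_vector")
}

#' @export
print.site_rate_vector <- function(x, ...) {
  cat(sprintf("<site_rate_vector> %d sites (%s); mean %.3g, %d invariant\n",
              length(x$rates), x$provenance, mean(x$rates), sum(x$rates == 0)))
  invisible(x)
}
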