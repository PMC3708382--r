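## Substitution models: state spaces, rate matrices, spectral form.
##
## Both models used here are time-reversible, so Q = S diag(pi) with a
## symmetric exchangeability matrix S. Q is scaled to one expected
## substitution per unit of rate*time, which makes branch length x rate
## directly interpretable as expected substitutions per site.

DNA_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## JTT (Jones, Taylor & Thornton 1992) exchangeabilities, lower triangle of
## the 20x20 matrix in column-major order over the state order above, and
## the accompanying stationary amino-acid frequencies. These are the
## standard published values used by all major phylogenetics programs.
JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  0.076747923252076758, 0.051690948309051694, 0.042644957355042652,
  0.051543948456051550, 0.019802980197019805, 0.040751959248040752,
  0.061829938170061841, 0.073151926848073159, 0.022943977056022944,
  0.053760946239053767, 0.091903908096091905, 0.058675941324058678,
  0.023825976174023829, 0.040125959874040135, 0.050900949099050907,
  0.068764931235068771, 0.058564941435058568, 0.014260985739014262,
  0.032101967898032102, 0.066004933995066004)

#' Build a scaled substitution model
#'
#' Constructs the rate matrix \eqn{Q} and its spectral decomposition for
#' one of the two models used throughout the package: the JTT empirical
#' amino-acid model or the Kimura two-parameter (K2P) nucleotide model.
#' \eqn{Q} is normalized so that the expected number of substitutions per
#' site per unit of (rate x time) equals 1.
#'
#' @param model_tag `"JTT"` (20-state amino acid) or `"K2P"` (4-state DNA).
#' @param kappa transition/transversion rate ratio, used only for K2P.
#' @return An object of class `pi_model`: a list with `states`, `pi`
#'   (stationary frequencies), `Q`, and the spectral factors needed for
#'   fast transition-probability evaluation.
#' @examples
#' m <- substitution_model("K2P", kappa = 2)
#' rowSums(m$Q)  # ~0
#' @export
substitution_model <- function(model_tag = c("JTT", "K2P"), kappa = 2) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  if (model_tag == "JTT") {
    states <- AA_STATES
    pi <- JTT_FREQS
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- JTT_EXCH
    S <- S + t(S)
  } else {
    stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
    states <- DNA_STATES
    pi <- rep(0.25, 4)
    S <- matrix(1, 4, 4, dimnames = list(states, states))
    diag(S) <- 0
    S["A", "G"] <- S["G", "A"] <- kappa
    S["C", "T"] <- S["T", "C"] <- kappa
  }
  dimnames(S) <- list(states, states)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  ## reversibility: B = D^{1/2} Q D^{-1/2} is symmetric; eigendecompose it.
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2  # kill roundoff asymmetry
  eg <- eigen(B, symmetric = TRUE)
  T1 <- eg$vectors / sp        # diag(1/sqrt(pi)) %*% V
  T2 <- t(eg$vectors) * rep(sp, each = length(pi))  # t(V) %*% diag(sqrt(pi))
  structure(list(tag = model_tag, kappa = if (model_tag == "K2P") kappa else NA_real_,
                 states = states, n_states = length(states),
                 pi = pi, Q = Q, eigenvalues = eg$values, T1 = T1, T2 = T2),
            class = "pi_model")
}

#' @export
print.pi_model <- function(x, ...) {
  cat(sprintf("<pi_model> %s, %d states%s\n", x$tag, x$n_states,
              if (!is.na(x$kappa)) sprintf(", kappa = %g", x$kappa) else ""))
  invisible(x)
}

#' Transition probability matrix P(v) = exp(Q v)
#'
#' @param model a `pi_model`.
#' @param v expected substitutions per site (rate x time), scalar >= 0.
#' @return the `n_states` x `n_states` stochastic matrix.
#' @export
transition_matrix <- function(model, v) {
  stopifnot(v >= 0)
  P <- model$T1 %*% (exp(model$eigenvalues * v) * model$T2)
  ## clip tiny negative roundoff
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Equal-probability discrete gamma rate categories
#'
#' Splits a gamma(shape = alpha, mean = 1) distribution into `n_categories`
#' equal-probability bins and represents each bin by its conditional mean,
#' then rescales so the category mean is exactly 1. This is the standard
#' mean-per-bin discretization used for among-site rate heterogeneity.
#'
#' @param alpha gamma shape parameter (> 0). Small alpha = strong
#'   heterogeneity; alpha -> Inf approaches a single rate.
#' @param n_categories number of categories (>= 1).
#' @return numeric vector of relative rates with mean exactly 1.
#' @examples
#' discretize_gamma(0.5, 4)
#' @export
discretize_gamma <- function(alpha, n_categories) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha))
  if (alpha <= 0) stop("gamma shape 'alpha' must be > 0")
  n_categories <- as.integer(n_categories)
  stopifnot(n_categories >= 1)
  if (n_categories == 1L) return(1)
  probs <- seq(0, 1, length.out = n_categories + 1)
  q <- stats::qgamma(probs, shape = alpha, rate = alpha)
  ## E[X; X in bin] for gamma(a, a) is pgamma(q, a + 1, a) differences
  ## (each bin has probability 1/K, so conditional mean = K * increment).
  inc <- diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
  r <- n_categories * inc
  r / mean(r)
}
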