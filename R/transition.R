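#' Build the state transition model of a POBDS
#'
#' The hidden state evolves as `X_k = f(X_{k-1}) XOR n_k`, where f is the
#' synchronous Boolean update and the noise vector `n_k` has i.i.d.
#' Bernoulli(`p`) components. Over the enumerated state space this is a
#' Markov chain with column-stochastic transition matrix
#' `M[j, i] = p^h (1-p)^(d-h)`, `h` the Hamming distance between state `s_j`
#' and `f(s_i)`. `p = 0` recovers the deterministic map; `p = 0.5` makes
#' every transition equally likely (a fully chaotic chain).
#'
#' @param net A `boolean_network` with at most 12 genes; larger networks are
#'   refused — exact filtering is intractable there, use [run_sir_bkf()].
#' @param p Process-noise intensity, a per-gene flip probability in
#'   \[0, 0.5\].
#' @return A `transition_model`: the network, `p`, the 2^d x 2^d matrix `M`,
#'   and the enumerated state matrix used by the exact filters.
#' @export
build_transition_matrix <- function(net, p) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(p) != 1L || is.na(p) || p < 0 || p > 0.5)
    stop("'p' must be a scalar in [0, 0.5]")
  d <- length(net$genes)
  if (d > 12)
    stop("exact transition matrix refused for d > 12 (2^d states); use run_sir_bkf()")
  S <- state_matrix(d)
  Snext <- network_step(net, S)
  # H[j, i] = Hamming(s_j, f(s_i)) via bit agreement counts
  H <- S %*% t(1L - Snext) + (1L - S) %*% t(Snext)
  M <- p^H * (1 - p)^(d - H)
  structure(list(net = net, p = p, d = d, M = M, states = S,
                 codec = state_codec(d)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("POBDS transition model: d = %d genes (%d states), p = %g\n",
              x$d, 2L^x$d, x$p))
  invisible(x)
}

#' Sample one noisy state transition
#'
#' Draws `f(x) XOR n` with `n` i.i.d. Bernoulli(`p`). `x` may be a matrix of
#' states (one per row) for vectorized draws, e.g. to propagate a particle
#' ensemble or to estimate transition frequencies by Monte Carlo.
#'
#' @param net A `boolean_network`.
#' @param p Flip probability in \[0, 0.5\].
#' @param x Boolean state vector or n x d matrix.
#' @return Successor state(s), shaped like `x`.
#' @export
sample_transition <- function(net, p, x) {
  if (length(p) != 1L || p < 0 || p > 0.5) stop("'p' must be a scalar in [0, 0.5]")
  fx <- network_step(net, x)
  n <- if (is.null(dim(fx))) length(fx) else length(fx)
  flips <- stats::runif(n) < p
  out <- (fx + flips) %% 2L
  storage.mode(out) <- "integer"
  out
}
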