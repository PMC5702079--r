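#' State/index codec for the enumerated Boolean state space
#'
#' Exact filtering enumerates all 2^d Boolean states. The codec fixes the
#' bijection between state vectors and the integers 0..2^d-1: gene 1 is the
#' most significant bit, so index = sum_j x_j * 2^(d-j) — lexicographic in
#' the printed gene order. Posterior distribution vectors (PDVs) are indexed
#' in this order everywhere in the package.
#'
#' @param d Number of genes (d >= 1).
#' @return A `state_codec` object.
#' @export
state_codec <- function(d) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L) stop("'d' must be a positive integer")
  structure(list(d = d, weights = 2^((d - 1L):0)), class = "state_codec")
}

#' @rdname state_codec
#' @param codec A `state_codec`.
#' @param x A Boolean state vector (length d) or an n x d matrix of states.
#' @return `encode_state`: integer index/indices in 0..2^d-1.
#' @export
encode_state <- function(codec, x) {
  stopifnot(inherits(codec, "state_codec"))
  xm <- as_state_matrix(x, codec$d)
  idx <- as.vector(xm %*% codec$weights)
  if (is.null(dim(x))) idx[1L] else idx
}

#' @rdname state_codec
#' @param i Integer index/indices in 0..2^d-1.
#' @return `decode_state`: Boolean vector (or matrix, one state per row).
#' @export
decode_state <- function(codec, i) {
  stopifnot(inherits(codec, "state_codec"))
  if (any(i < 0 | i > 2^codec$d - 1)) stop("state index out of range")
  d <- codec$d
  out <- matrix(0L, length(i), d)
  for (j in seq_len(d)) out[, j] <- bitwAnd(as.integer(i %/% codec$weights[j]), 1L)
  if (length(i) == 1L) out[1L, ] else out
}

# all 2^d states as a 2^d x d matrix, row i+1 = decode(i)
state_matrix <- function(d) {
  cod <- state_codec(d)
  decode_state(cod, 0:(2^d - 1))
}
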