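#' Companion matrix of a lagged bivariate coefficient set
#'
#' Stacks the per-lag 2x2 coefficient matrices of a bivariate autoregression
#' into the one-step (companion) form whose eigenvalues govern stability.
#'
#' @param coeffs List of 2x2 numeric matrices, one per lag.
#' @return A `2p x 2p` numeric matrix for `p` lags.
#' @export
companion_matrix <- function(coeffs) {
  stopifnot(is.list(coeffs), length(coeffs) >= 1)
  k <- 2L
  p <- length(coeffs)
  C <- matrix(0, k * p, k * p)
  for (i in seq_len(p)) {
    A <- coeffs[[i]]
    if (!is.matrix(A) || !all(dim(A) == c(2, 2))) {
      stop("each coefficient matrix must be 2x2")
    }
    C[1:k, ((i - 1L) * k + 1L):(i * k)] <- A
  }
  if (p > 1) {
    C[(k + 1L):(k * p), 1L:(k * (p - 1L))] <- diag(k * (p - 1L))
  }
  C
}

#' Spectral radius of the companion matrix
#'
#' The autoregression is stationary (stable) if and only if this radius is
#' strictly below 1.
#'
#' @inheritParams companion_matrix
#' @return Largest eigenvalue modulus of [companion_matrix()].
#' @export
spectral_radius <- function(coeffs) {
  max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
}

# Deterministic expansion of a root seed into per-unit seeds, kept inside
# the 32-bit signed integer range.
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) + as.numeric(index) * 7919) %% 2147483647)
}

# Stop unless `value` is one of the allowed labels.
match_vocab <- function(value, vocab, what) {
  if (length(value) != 1 || !value %in% vocab) {
    stop(sprintf("%s must be one of: %s (got '%s')",
                 what, paste(vocab, collapse = ", "), paste(value, collapse = ",")))
  }
  value
}
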