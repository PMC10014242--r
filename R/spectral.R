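#' Metropolis-Hastings consensus weights
#'
#' Builds the symmetric doubly stochastic weight matrix used by distributed
#' averaging: off-diagonal weight `1 / (1 + max(d_i, d_j))` on edges, zero on
#' non-edges, and diagonal entries completing each row to one. A connected
#' graph is required for averaging to reach the global mean.
#'
#' @param tp A connected [topology()].
#' @return An `n x n` doubly stochastic matrix.
#' @examples
#' W <- metropolis_hastings_weights(generate_ring(6, 2))
#' range(rowSums(W))
#' @export
metropolis_hastings_weights <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  if (!is_connected_topology(tp)) {
    stop("graph is disconnected: averaging consensus is not guaranteed")
  }
  d <- degrees(tp)
  n <- tp$n
  W <- matrix(0, n, n)
  if (nrow(tp$edges) > 0L) {
    w <- 1 / (1 + pmax(d[tp$edges[, 1L]], d[tp$edges[, 2L]]))
    W[tp$edges] <- w
    W[tp$edges[, c(2L, 1L), drop = FALSE]] <- w
  }
  diag(W) <- 1 - rowSums(W)
  W
}

#' Uniform safe averaging step size
#'
#' The scalar step `epsilon = 1 / (1 + max_i d_i)` makes `I - epsilon * L`
#' doubly stochastic with non-negative entries on any graph, so the scalar
#' Belief Consensus update converges to the mean on connected graphs.
#'
#' @param tp A [topology()].
#' @return The scalar step size.
#' @export
safe_epsilon <- function(tp) {
  stopifnot(inherits(tp, "topology"))
  1 / (1 + max(degrees(tp)))
}

#' Spectral radius and dominant eigenvector
#'
#' @param m A square numeric matrix.
#' @return The largest eigenvalue modulus, with the corresponding eigenvector
#'   attached as attribute `"eigenvector"` (real part, unit norm, first
#'   nonzero entry made positive).
#' @examples
#' spectral_radius(diag(2))
#' @export
spectral_radius <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be a square matrix")
  e <- eigen(m)
  i <- which.max(Mod(e$values))
  v <- Re(e$vectors[, i])
  nz <- which(abs(v) > 1e-12)
  if (length(nz) > 0L && v[nz[1L]] < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  structure(Mod(e$values[i]), eigenvector = v)
}
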