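#' Draw a spatially structured field from the intrinsic CAR prior
#'
#' Samples one realization of the intrinsic conditional-autoregressive (ICAR)
#' Gaussian Markov random field on a contiguity graph, under the sum-to-zero
#' constraint that identifies the improper prior. Each node's effect is
#' conditionally Normal around the mean of its neighbors with conditional
#' standard deviation `tau / sqrt(degree)`.
#'
#' The draw is taken in the eigenbasis of the graph Laplacian `L`: the joint
#' (constrained) covariance is `tau^2` times the Moore-Penrose pseudo-inverse
#' of `L`, so independent Normal deviates with variance `tau^2 / lambda_k` on
#' the non-null eigenvectors give an exact sample. Dense eigendecomposition is
#' cheap at the lattice sizes used for simulation (hundreds of nodes).
#'
#' @param graph a connected [nbhd_graph()].
#' @param tau conditional standard deviation of the CAR prior; `tau = 0`
#'   returns the all-zero field.
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG stream is left untouched.
#' @return numeric vector of node effects in `graph$node_ids` order, summing
#'   to zero.
#' @examples
#' g <- make_lattice(5, 5)
#' v <- sample_car_field(g, tau = 1, seed = 1)
#' sum(v)
#' @export
sample_car_field <- function(graph, tau, seed = NULL) {
  if (!inherits(graph, "nbhd_graph")) {
    abort_recwalk("`graph` must be a nbhd_graph.", "invalid_argument")
  }
  if (length(tau) != 1L || is.na(tau) || tau < 0) {
    abort_recwalk("`tau` must be a single nonnegative number.", "invalid_argument")
  }
  if (!graph_is_connected(graph)) {
    abort_recwalk("graph is disconnected; the intrinsic CAR field is undefined across islands.",
                  "island")
  }
  J <- n_nodes(graph)
  if (tau == 0) return(numeric(J))
  eig <- car_eigen(graph)
  with_seed(seed, {
    z <- rnorm(J - 1L) * tau / sqrt(eig$values)
    v <- drop(eig$vectors %*% z)
    v - mean(v) # remove numerical drift off the constraint
  })
}

# eigendecomposition of the Laplacian with the null (constant) mode dropped;
# cached on the graph environmentally is not needed at these sizes
car_eigen <- function(graph) {
  L <- graph_laplacian(graph)
  eig <- eigen(L, symmetric = TRUE)
  J <- nrow(L)
  keep <- seq_len(J - 1L) # eigenvalues sorted decreasing; last is the null mode
  list(values = eig$values[keep], vectors = eig$vectors[, keep, drop = FALSE])
}

# marginal (constrained) standard deviations of an ICAR field at tau = 1:
# sqrt of the diagonal of the Laplacian pseudo-inverse
car_marginal_sd <- function(graph) {
  eig <- car_eigen(graph)
  sqrt(colSums(t(eig$vectors^2) / eig$values))
}
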