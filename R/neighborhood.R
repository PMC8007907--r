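#' Select the K nearest neighbors of an entity
#'
#' Neighbors are ranked by the value of the base similarity matrix itself
#' (not by distances between its rows): `N(i)` holds the `k` positions
#' `j != i` with the largest `base[i, j]`, ties broken by ascending
#' position index. Self-neighborship is excluded.
#'
#' @param base Square similarity matrix.
#' @param i Entity position (1-based row of `base`).
#' @param k Number of neighbors, `1 <= k <= nrow(base) - 1`.
#' @return Integer vector of `k` neighbor positions, ordered by decreasing
#'   similarity (ties ascending by index).
#' @export
select_neighbors <- function(base, i, k) {
  assert_square(base, "base")
  n <- nrow(base)
  i <- assert_count(i, "i")
  if (i > n) abort("`i` exceeds the number of entities.")
  k <- assert_count(k, "k")
  if (k > n - 1L) abort(sprintf("`k` = %d exceeds the %d available neighbors.", k, n - 1L))
  cand <- setdiff(seq_len(n), i)
  ord <- cand[order(-base[i, cand], cand)]
  ord[seq_len(k)]
}

#' Linear-neighborhood reconstruction weights for one entity
#'
#' Solves the simplex-constrained, Tikhonov-regularised quadratic program
#' that reconstructs entity `i` as a convex combination of its neighbors:
#'
#' \deqn{\min_w \; w^\top (G_i + \alpha I)\, w \quad \text{s.t.}\;
#'       \textstyle\sum_j w_j = 1,\; w_j \ge 0}
#'
#' with the Gram matrix
#' `G_i[j, k] = (X_i - X_{i_j})' (X_i - X_{i_k})` built from the feature
#' rows `X` (here: rows of the base similarity matrix). The optimal weights
#' are the linear-neighborhood similarities of `i` to its neighbors.
#'
#' @param features Numeric matrix of row features (the base similarity
#'   matrix in the standard pipeline).
#' @param i Entity position.
#' @param neighbors Integer positions of the neighbor set (from
#'   [select_neighbors()]).
#' @param alpha Nonnegative regularisation weight (default 0.7); any
#'   `alpha > 0` makes the solution unique.
#' @param qp_tolerance Nonnegativity slack for the solver; returned weights
#'   below it are clipped to zero and the row renormalised.
#' @return Numeric weight vector over `neighbors`, summing to 1.
#'
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 2))
#' lns_weights(X, 1, c(2, 3), alpha = 0)    # (0.8, 0.2)
#' lns_weights(X, 1, c(2, 3), alpha = 0.7)  # (0.734375, 0.265625)
#' @export
lns_weights <- function(features, i, neighbors, alpha = 0.7,
                        qp_tolerance = 1e-8) {
  if (!is.matrix(features) || !is.numeric(features)) {
    abort("`features` must be a numeric matrix.")
  }
  assert_scalar_number(alpha, "alpha", lower = 0)
  assert_scalar_number(qp_tolerance, "qp_tolerance", lower = 0, strict_lower = TRUE)
  neighbors <- as.integer(neighbors)
  K <- length(neighbors)
  if (K < 1L) abort("need at least one neighbor.")
  if (K == 1L) return(1)
  diffs <- matrix(features[i, ], K, ncol(features), byrow = TRUE) -
    features[neighbors, , drop = FALSE]
  G <- tcrossprod(diffs) + alpha * diag(K)
  ## pracma::quadprog minimises 0.5 x' C x - d' x; C = 2G gives w' G w.
  sol <- tryCatch(
    pracma::quadprog(2 * G, rep(0, K),
                     Aeq = matrix(1, 1L, K), beq = 1, lb = rep(0, K)),
    error = function(e) abort(sprintf("QP solver failed for entity %d: %s",
                                      i, conditionMessage(e)))
  )
  w <- sol$xmin
  if (any(w < -qp_tolerance) || abs(sum(w) - 1) > 1e-6) {
    abort(sprintf("QP solution for entity %d violates the simplex (eflag %s).",
                  i, format(sol$eflag)))
  }
  w[w < qp_tolerance] <- 0
  w / sum(w)
}

#' Build a linear-neighborhood similarity (LNS) graph
#'
#' Applies [lns_weights()] to every entity of a base similarity matrix and
#' scatters the weights onto a square matrix `W`: `W[i, j]` is the
#' reconstruction weight of neighbor `j` for entity `i`, and 0 whenever
#' `j` is not among the K nearest neighbors of `i`. `W` is row-stochastic
#' and nonnegative with a zero diagonal, and is generally *asymmetric* —
#' it is the directed graph on which label propagation runs.
#'
#' @inheritParams lns_weights
#' @param base Square similarity matrix; its rows double as the feature
#'   vectors of the QP.
#' @param k_neighbors Explicit neighborhood size; overrides
#'   `neighbor_fraction` when given.
#' @param neighbor_fraction Neighborhood size as a fraction of the number
#'   of entities (default 0.3; `K = max(1, round(f * N))`, capped at
#'   `N - 1`).
#' @return `W`, a square numeric matrix with the dimnames of `base`.
#' @export
lns_graph <- function(base, k_neighbors = NULL, neighbor_fraction = 0.3,
                      alpha = 0.7, qp_tolerance = 1e-8) {
  assert_square(base, "base")
  n <- nrow(base)
  if (n < 2L) abort("need at least 2 entities to build a neighborhood graph.")
  if (is.null(k_neighbors)) {
    assert_scalar_number(neighbor_fraction, "neighbor_fraction",
                         lower = 0, upper = 1, strict_lower = TRUE)
    k <- max(1L, as.integer(round(neighbor_fraction * n)))
  } else {
    k <- assert_count(k_neighbors, "k_neighbors")
  }
  k <- min(k, n - 1L)
  W <- matrix(0, n, n, dimnames = dimnames(base))
  for (i in seq_len(n)) {
    nb <- select_neighbors(base, i, k)
    W[i, nb] <- lns_weights(base, i, nb, alpha = alpha,
                            qp_tolerance = qp_tolerance)
  }
  W
}
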