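#' Transition matrix of the heterogeneous microbe-disease network
#'
#' Stacks microbe similarity, disease similarity and the bipartite
#' association matrix into one network over `n + m` nodes (microbes first,
#' then diseases),
#' `A = [[S_M, Y], [Y', S_D]]` with the similarity diagonals zeroed, and
#' column-normalises it into the transition matrix of a random walk.
#' Columns of isolated nodes stay zero (with a warning): a walker never
#' moves *to* them.
#'
#' @param Y Association input (edge-list data frame, 0/1 matrix or
#'   [mda_associations()] object).
#' @param S_M,S_D Microbe- and disease-side similarity matrices (symmetric
#'   affinities; the GAP similarities in the standard pipeline).
#' @return Column-stochastic `(n+m) x (n+m)` matrix; node names are the
#'   microbe ids followed by the disease ids.
#' @export
heterogeneous_transition <- function(Y, S_M, S_D) {
  Y <- as_mda_assoc(Y, "Y")
  assert_square(S_M, "S_M")
  assert_square(S_D, "S_D")
  A <- as.matrix(Y)
  n <- nrow(A); m <- ncol(A)
  if (nrow(S_M) != n) abort("`S_M` must be n x n for n microbes.")
  if (nrow(S_D) != m) abort("`S_D` must be m x m for m diseases.")
  SM <- S_M; diag(SM) <- 0
  SD <- S_D; diag(SD) <- 0
  block <- rbind(cbind(SM, A), cbind(t(A), SD))
  dimnames(block) <- list(c(Y$microbes, Y$diseases), c(Y$microbes, Y$diseases))
  csum <- colSums(block)
  zero <- csum == 0
  if (any(zero)) {
    warn(sprintf("%d isolated node(s) in the heterogeneous network keep zero columns.",
                 sum(zero)))
  }
  sweep(block, 2L, ifelse(zero, 1, csum), `/`)
}

#' Random walk with restart (RWR)
#'
#' Stationary distribution of a walk on `transition` that, at every step,
#' teleports back to the seed set with probability `restart`:
#' `p = restart * e + (1 - restart) * T p`, with `e` uniform over `seeds`.
#' Solved by power iteration to an L1 change below `tol`.
#'
#' @param transition Column-stochastic matrix from
#'   [heterogeneous_transition()].
#' @param seeds Node positions (integers) or node names to restart to.
#' @param restart Restart probability in `(0, 1)` (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000); exceeding it is an error
#'   reporting the last residual.
#' @return Named numeric vector of stationary probabilities (sums to 1 when
#'   every reachable column is stochastic).
#'
#' @examples
#' T2 <- matrix(c(0, 1, 1, 0), 2, 2)
#' rwr_scores(T2, seeds = 1, restart = 0.5)  # (2/3, 1/3)
#' @export
rwr_scores <- function(transition, seeds, restart = 0.5, tol = 1e-10,
                       max_iter = 1000L) {
  assert_square(transition, "transition")
  assert_scalar_number(restart, "restart", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(tol, "tol", lower = 0, strict_lower = TRUE)
  max_iter <- assert_count(max_iter, "max_iter")
  n <- nrow(transition)
  if (is.character(seeds)) {
    seeds <- match(seeds, rownames(transition))
    if (anyNA(seeds)) abort("unknown seed node name(s).")
  }
  seeds <- unique(as.integer(seeds))
  if (length(seeds) < 1L || any(seeds < 1L | seeds > n)) {
    abort("`seeds` must name at least one valid node.")
  }
  e <- numeric(n)
  e[seeds] <- 1 / length(seeds)
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- restart * e + (1 - restart) * drop(transition %*% p)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- rownames(transition)
      return(p)
    }
  }
  abort(sprintf("RWR did not converge in %d iterations (last L1 change %.3g).",
                max_iter, delta))
}

#' Select reliable negative microbe-disease pairs
#'
#' Positive-unlabeled negative mining: for every disease, a random walk
#' with restart is seeded at the disease node together with its known
#' microbes, and each unlabeled pair `(i, j)` is scored by the stationary
#' mass the walk for disease `j` leaves on microbe node `i`. Pairs the
#' network keeps furthest from the positives — the lowest-scoring
#' unlabeled pairs overall — are returned as the reliable negative set.
#' Known positives can never be selected.
#'
#' @inheritParams heterogeneous_transition
#' @inheritParams rwr_scores
#' @param n_negatives Number of negatives to return, or
#'   `"match_positives"` (default) for one negative per known positive.
#'   Requests beyond the number of unlabeled pairs are clamped with a
#'   warning.
#' @return A tibble with columns `microbe`, `disease`, `score`, sorted by
#'   ascending RWR score (ties broken by microbe then disease index), of
#'   class `mda_negatives`.
#' @export
select_negatives <- function(Y, S_M, S_D, n_negatives = "match_positives",
                             restart = 0.5, tol = 1e-10, max_iter = 1000L) {
  Y <- as_mda_assoc(Y, "Y")
  A <- as.matrix(Y)
  if (sum(A) < 1) abort("need at least one known association.")
  n <- nrow(A); m <- ncol(A)
  if (identical(n_negatives, "match_positives")) {
    n_negatives <- sum(A)
  } else {
    n_negatives <- assert_count(n_negatives, "n_negatives")
  }
  n_unlabeled <- sum(A == 0)
  if (n_negatives > n_unlabeled) {
    warn(sprintf("requested %d negatives but only %d unlabeled pairs exist; clamping.",
                 n_negatives, n_unlabeled))
    n_negatives <- n_unlabeled
  }
  trans <- heterogeneous_transition(Y, S_M, S_D)
  score <- matrix(NA_real_, n, m, dimnames = dimnames(A))
  for (j in seq_len(m)) {
    seeds <- c(which(A[, j] == 1), n + j)
    p <- rwr_scores(trans, seeds, restart = restart, tol = tol,
                    max_iter = max_iter)
    score[, j] <- p[seq_len(n)]
  }
  unl <- which(A == 0, arr.ind = TRUE)
  s <- score[unl]
  ord <- order(s, unl[, 1L], unl[, 2L])
  keep <- ord[seq_len(n_negatives)]
  out <- tibble(
    microbe = Y$microbes[unl[keep, 1L]],
    disease = Y$diseases[unl[keep, 2L]],
    score = s[keep]
  )
  structure(out, class = c("mda_negatives", class(out)),
            rwr_scores = score)
}
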