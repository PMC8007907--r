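## Independent oracles and small generators shared across tests.

## GAP kernel by explicit double loop (no vectorised linear algebra).
gap_oracle <- function(profiles, gamma_prime = 1) {
  n <- nrow(profiles)
  norm <- mean(apply(profiles, 1L, function(r) sum(r^2)))
  g <- gamma_prime / norm
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-g * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  S
}

## AUC by brute-force pairwise comparison (ties count one half).
brute_auc <- function(pos, neg) {
  wins <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(wins)
}

## Uniform-ish random points on the probability simplex.
random_simplex <- function(n, k) {
  x <- matrix(-log(runif(n * k)), n, k)
  x / rowSums(x)
}

## LNS quadratic objective w' (G + alpha I) w for entity i and its neighbors.
lns_objective <- function(features, i, neighbors, w, alpha) {
  diffs <- matrix(features[i, ], length(neighbors), ncol(features),
                  byrow = TRUE) - features[neighbors, , drop = FALSE]
  G <- tcrossprod(diffs) + alpha * diag(length(neighbors))
  drop(t(w) %*% G %*% w)
}

## Random row-stochastic nonnegative matrix with zero diagonal.
random_row_stochastic <- function(n) {
  W <- matrix(runif(n * n), n, n)
  diag(W) <- 0
  W / rowSums(W)
}

## Small named binary association matrix.
random_assoc <- function(n, m, p = 0.3) {
  A <- matrix(rbinom(n * m, 1L, p), n, m,
              dimnames = list(sprintf("m%02d", seq_len(n)),
                              sprintf("d%02d", seq_len(m))))
  if (sum(A) == 0) A[1, 1] <- 1
  A
}

## Path to the installed command-line script.
cli_path <- function() {
  file.path(find.package("nllmda"), "exec", "nllmda")
}

## Run the CLI in a child Rscript; returns exit status (stdout/err captured).
run_cli <- function(args, log = NULL) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- log %||% nullfile()
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  system2(rscript, c(cli_path(), args), stdout = out, stderr = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
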