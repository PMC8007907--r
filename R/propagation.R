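#' Label propagation on a neighborhood graph
#'
#' Diffuses known association labels over an LNS graph. With diffusion
#' rate `beta`, each step mixes neighbor labels and re-injects the initial
#' labels: `F_{t+1} = beta * W F_t + (1 - beta) * F_0`, which converges to
#' the closed form
#'
#' \deqn{F = (1 - \beta)(I - \beta W)^{-1} F_0.}
#'
#' `side = "microbe"` diffuses along microbe-microbe edges (`W` is
#' `n x n`, each disease's label column is propagated); `side = "disease"`
#' diffuses along disease-disease edges (`W` is `m x m`, each microbe's
#' label row is propagated). The closed form is the production path; the
#' iterative mode exists as a numerical cross-check and both agree to
#' `1e-8` under the default tolerances.
#'
#' @param W Row-stochastic nonnegative graph from [lns_graph()].
#' @param Y0 Initial label matrix (`n x m`; the training association
#'   matrix, possibly real-valued).
#' @param beta Diffusion rate in `[0, 1)` (default 0.1); `beta = 0` returns
#'   `Y0` unchanged.
#' @param side Which entity graph `W` describes.
#' @param mode `"closed_form"` (default) or `"iterative"`.
#' @param iter_tolerance,max_iter Iterative-mode stopping rule: max-abs
#'   change below `iter_tolerance` (default 1e-10) within `max_iter`
#'   iterations.
#' @return Score matrix of the same shape as `Y0`.
#'
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' label_propagate(W, matrix(c(1, 0)), beta = 0.1)  # (0.9091, 0.0909)
#' @export
label_propagate <- function(W, Y0, beta = 0.1, side = c("microbe", "disease"),
                            mode = c("closed_form", "iterative"),
                            iter_tolerance = 1e-10, max_iter = 10000L) {
  assert_square(W, "W")
  side <- match.arg(side)
  mode <- match.arg(mode)
  assert_scalar_number(beta, "beta", lower = 0, upper = 1, strict_upper = TRUE)
  if (!is.matrix(Y0)) Y0 <- as.matrix(Y0)
  sz <- if (side == "microbe") nrow(Y0) else ncol(Y0)
  if (nrow(W) != sz) {
    abort(sprintf("`W` is %d x %d but the %s side of `Y0` has %d entities.",
                  nrow(W), ncol(W), side, sz))
  }
  if (beta == 0) return(Y0)
  if (mode == "closed_form") {
    M <- diag(nrow(W)) - beta * W
    out <- tryCatch(
      if (side == "microbe") (1 - beta) * solve(M, Y0)
      else (1 - beta) * t(solve(M, t(Y0))),
      error = function(e) abort(sprintf("(I - beta W) solve failed: %s",
                                        conditionMessage(e)))
    )
    dimnames(out) <- dimnames(Y0)
    return(out)
  }
  assert_scalar_number(iter_tolerance, "iter_tolerance", lower = 0,
                       strict_lower = TRUE)
  max_iter <- assert_count(max_iter, "max_iter")
  Ft <- Y0
  for (it in seq_len(max_iter)) {
    Fn <- if (side == "microbe") beta * (W %*% Ft) + (1 - beta) * Y0
          else beta * (Ft %*% t(W)) + (1 - beta) * Y0
    delta <- max(abs(Fn - Ft))
    Ft <- Fn
    if (delta < iter_tolerance) {
      dimnames(Ft) <- dimnames(Y0)
      return(Ft)
    }
  }
  abort(sprintf("label propagation did not converge in %d iterations (last change %.3g).",
                max_iter, delta))
}

#' Convex integration of per-model score matrices
#'
#' Final scores are the weighted sum `Z = sum_k omega_k * Y_k` over the
#' per-similarity label-propagation models, with `omega` on the
#' probability simplex.
#'
#' @param models List of score matrices of identical shape.
#' @param weights Numeric vector of simplex weights, one per model
#'   (nonnegative, summing to 1 within 1e-10).
#' @return The integrated score matrix.
#' @export
integrate_scores <- function(models, weights) {
  if (!is.list(models) || length(models) < 1L) abort("`models` must be a nonempty list.")
  if (length(weights) != length(models)) {
    abort(sprintf("%d weights supplied for %d models.", length(weights),
                  length(models)))
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10) {
    abort("`weights` must be nonnegative and sum to 1.")
  }
  dims <- lapply(models, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    abort("all model score matrices must share the same shape.")
  }
  Z <- matrix(0, dims[[1L]][1L], dims[[1L]][2L])
  for (k in seq_along(models)) Z <- Z + weights[k] * models[[k]]
  dimnames(Z) <- dimnames(models[[1L]])
  Z
}

## Enumerate the simplex grid {w >= 0, sum w = 1} with spacing `step`, in
## decreasing lexicographic order of (w_1, ..., w_S): ties in the grid
## search resolve toward weight on the earlier models.
simplex_grid <- function(S, step) {
  n_steps <- round(1 / step)
  if (abs(n_steps * step - 1) > 1e-9) abort("`grid_step` must divide 1.")
  combos <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    do.call(rbind, lapply(total:0, function(v) {
      cbind(v, combos(total - v, parts - 1L))
    }))
  }
  g <- combos(n_steps, S) * step
  dimnames(g) <- NULL
  g
}

#' Fit integration weights against selected negatives
#'
#' Searches the simplex grid with spacing `grid_step` for the weight
#' vector whose integrated scores best separate known positives from
#' reliable negatives (rank AUC). When every candidate ties (e.g. all
#' models identical) or no negatives are supplied, the uniform weights are
#' returned.
#'
#' @inheritParams integrate_scores
#' @param positives Two-column object (microbe, disease) of known positive
#'   pairs — ids or 1-based positions matching the score matrices.
#' @param negatives Same shape, the reliable negatives (e.g. from
#'   [select_negatives()]); must be disjoint from `positives`.
#' @param grid_step Grid spacing on the simplex (default 0.1).
#' @return Numeric weight vector of length `length(models)`.
#' @export
fit_integration_weights <- function(models, positives, negatives,
                                    grid_step = 0.1) {
  if (!is.list(models) || length(models) < 1L) abort("`models` must be a nonempty list.")
  S <- length(models)
  uniform <- rep(1 / S, S)
  pos <- as_pair_index(positives, models[[1L]], "positives")
  if (nrow(pos) < 1L) abort("`positives` must contain at least one pair.")
  if (is.null(negatives) || NROW(negatives) == 0L) return(uniform)
  neg <- as_pair_index(negatives, models[[1L]], "negatives")
  if (nrow(merge(as.data.frame(pos), as.data.frame(neg))) > 0L) {
    abort("`positives` and `negatives` must be disjoint.")
  }
  grid <- simplex_grid(S, grid_step)
  pos_scores <- vapply(models, function(M) M[pos], numeric(nrow(pos)))
  neg_scores <- vapply(models, function(M) M[neg], numeric(nrow(neg)))
  if (nrow(pos) == 1L) pos_scores <- matrix(pos_scores, 1L)
  if (nrow(neg) == 1L) neg_scores <- matrix(neg_scores, 1L)
  aucs <- apply(grid, 1L, function(w) {
    rank_auc(drop(pos_scores %*% w), drop(neg_scores %*% w))
  })
  if (diff(range(aucs)) < 1e-12) return(uniform)
  drop(grid[which.max(aucs), ])
}

## Normalise pair specifications (id or positional) to a 2-column integer
## matrix indexing into `M`.
as_pair_index <- function(pairs, M, arg) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (!is.matrix(pairs) || ncol(pairs) < 2L) {
    abort(sprintf("`%s` must be a two-column matrix or data frame.", arg))
  }
  if (is.character(pairs)) {
    i <- match(pairs[, 1L], rownames(M))
    j <- match(pairs[, 2L], colnames(M))
    if (anyNA(i) || anyNA(j)) abort(sprintf("`%s` contains unknown identifiers.", arg))
    pairs <- cbind(i, j)
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > nrow(M)) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > ncol(M))) {
    abort(sprintf("`%s` indexes outside the score matrix.", arg))
  }
  unname(pairs[, 1:2, drop = FALSE])
}

#' Fit the NLLMDA association prediction model
#'
#' End-to-end pipeline. From the binary association matrix it computes the
#' microbe GAP similarity, the disease GAP similarity and (when symptom
#' data are given) the symptom similarity; learns a linear-neighborhood
#' graph on each; runs closed-form label propagation per graph — model 1
#' diffuses along microbes on `LNS(S_M)`, models 2 and 3 along diseases on
#' `LNS(S_G)` and `LNS(S_s)` — and integrates the per-model score matrices
#' with simplex weights. Without symptom data the pipeline degrades to the
#' two GAP models (with a message). Reliable negatives are mined only when
#' they are needed, i.e. when `weights = "fit"`.
#'
#' @param associations Edge-list data frame, 0/1 matrix or
#'   [mda_associations()] object.
#' @param symptoms Optional disease-symptom weight table: matrix or data
#'   frame (first column disease ids), see [read_symptom_table()].
#' @param symptom_sim Optional precomputed disease symptom-similarity
#'   matrix (square, disease ids on dimnames); overrides `symptoms`.
#' @param gamma_m_prime,gamma_d_prime GAP bandwidth multipliers
#'   (default 1).
#' @param gamma Weight of the symptom channel in the combined disease
#'   similarity (default 0.7); only used when `third_model = "combined"`.
#' @param alpha LNS Tikhonov regulariser (default 0.7).
#' @param beta Label-propagation diffusion rate (default 0.1).
#' @param k_neighbors,neighbor_fraction Neighborhood size, see
#'   [lns_graph()].
#' @param weights `"uniform"` (default), `"fit"` (grid search against
#'   mined negatives), or an explicit simplex weight vector.
#' @param third_model `"symptom"` (default): model 3 propagates on the
#'   symptom similarity; `"combined"`: on `S_G + gamma * S_s`.
#' @param restart,n_negatives Negative-selection settings, see
#'   [select_negatives()]; used only when `weights = "fit"`.
#' @return An object of class `nllmda_fit` with elements `scores`
#'   (integrated matrix `Z`), `models` (per-model score matrices),
#'   `weights`, `similarities`, `graphs`, `negatives` (or `NULL`),
#'   `associations`, and `params`. See [tidy.nllmda_fit()],
#'   [glance.nllmda_fit()], [rank_scores()].
#'
#' @examples
#' sim <- simulate_mda(n_microbes = 30, m_diseases = 12, seed = 7)
#' fit <- nllmda(sim$associations, symptoms = sim$symptoms)
#' glance(fit)
#' tidy(fit)
#' @export
nllmda <- function(associations, symptoms = NULL, symptom_sim = NULL,
                   gamma_m_prime = 1, gamma_d_prime = 1, gamma = 0.7,
                   alpha = 0.7, beta = 0.1,
                   k_neighbors = NULL, neighbor_fraction = 0.3,
                   weights = "uniform",
                   third_model = c("symptom", "combined"),
                   restart = 0.5, n_negatives = "match_positives") {
  assoc <- as_mda_assoc(associations)
  third_model <- match.arg(third_model)
  Y <- as.matrix(assoc)
  if (sum(Y) < 1) abort("model fitting needs at least one known association.")

  S_M <- gap_similarity(Y, gamma_m_prime)
  S_G <- gap_similarity(t(Y), gamma_d_prime)
  S_s <- NULL
  if (!is.null(symptom_sim)) {
    assert_square(symptom_sim, "symptom_sim")
    S_s <- align_symptom_similarity(symptom_sim, assoc$diseases)
  } else if (!is.null(symptoms)) {
    S_s <- align_symptom_similarity(symptom_similarity(symptoms),
                                    assoc$diseases)
  }

  sims <- list(microbe_gap = S_M, disease_gap = S_G)
  if (!is.null(S_s)) {
    sims$disease_symptom <- if (third_model == "combined") {
      combine_disease_similarity(S_G, S_s, gamma)
    } else {
      S_s
    }
  } else {
    inform("no symptom data supplied; integrating the two GAP models only.")
  }

  graphs <- lapply(sims, lns_graph, k_neighbors = k_neighbors,
                   neighbor_fraction = neighbor_fraction, alpha = alpha)
  models <- list(
    microbe_gap = label_propagate(graphs$microbe_gap, Y, beta, side = "microbe"),
    disease_gap = label_propagate(graphs$disease_gap, Y, beta, side = "disease")
  )
  if (!is.null(S_s)) {
    models$disease_symptom <- label_propagate(graphs$disease_symptom, Y, beta,
                                              side = "disease")
  }

  negatives <- NULL
  if (identical(weights, "fit")) {
    negatives <- select_negatives(assoc, S_M, S_G, n_negatives = n_negatives,
                                  restart = restart)
    pos <- which(Y == 1, arr.ind = TRUE)
    omega <- fit_integration_weights(models, pos, negatives)
  } else if (identical(weights, "uniform")) {
    omega <- rep(1 / length(models), length(models))
  } else {
    if (!is.numeric(weights) || length(weights) != length(models)) {
      abort(sprintf("`weights` must be \"uniform\", \"fit\", or %d numbers.",
                    length(models)))
    }
    omega <- weights
  }
  names(omega) <- names(models)

  Z <- integrate_scores(models, omega)
  structure(
    list(
      scores = Z, models = models, weights = omega,
      similarities = sims, graphs = graphs, negatives = negatives,
      associations = assoc,
      params = list(gamma_m_prime = gamma_m_prime,
                    gamma_d_prime = gamma_d_prime, gamma = gamma,
                    alpha = alpha, beta = beta, k_neighbors = k_neighbors,
                    neighbor_fraction = neighbor_fraction,
                    third_model = third_model)
    ),
    class = "nllmda_fit"
  )
}

#' @export
print.nllmda_fit <- function(x, ...) {
  cat(sprintf(
    "<nllmda_fit> %d microbes x %d diseases | models: %s | beta = %g\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("%s (%.2f)", names(x$weights), x$weights), collapse = ", "),
    x$params$beta
  ))
  invisible(x)
}

#' Tidy methods for NLLMDA fits
#'
#' `tidy()` returns one row per microbe-disease pair with its integrated
#' score, ranked as in [rank_scores()]; `glance()` returns a one-row model
#' summary. With `new_only = TRUE` the known associations are dropped
#' *before* ranking, so `top_k` keeps the best novel candidates — the
#' case-study use ("top k candidate microbes per disease").
#'
#' @param x An [nllmda()] fit.
#' @param new_only Drop pairs that are already known associations.
#' @param top_k,per_disease See [rank_scores()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.nllmda_fit <- function(x, new_only = FALSE, top_k = NULL,
                            per_disease = FALSE, ...) {
  out <- rank_scores(x)
  if (new_only) {
    out <- out |>
      dplyr::filter(.data$known == 0L) |>
      dplyr::mutate(rank = dplyr::row_number())
  }
  if (per_disease) {
    out <- out |>
      dplyr::mutate(rank = dplyr::row_number(), .by = "disease_id") |>
      dplyr::arrange(match(.data$disease_id, colnames(x$scores)), .data$rank)
  }
  if (!is.null(top_k)) {
    top_k <- assert_count(top_k, "top_k")
    out <- dplyr::filter(out, .data$rank <= top_k)
  }
  out
}

#' @rdname tidy.nllmda_fit
#' @exportS3Method generics::glance
glance.nllmda_fit <- function(x, ...) {
  tibble(
    n_microbes = nrow(x$scores),
    n_diseases = ncol(x$scores),
    n_positives = sum(as.matrix(x$associations)),
    n_models = length(x$models),
    beta = x$params$beta,
    alpha = x$params$alpha,
    n_negatives = if (is.null(x$negatives)) 0L else nrow(x$negatives)
  )
}

#' Heatmap of predicted association scores
#'
#' Tile plot of the integrated score matrix with known associations
#' outlined, microbes on the y axis and diseases on the x axis.
#'
#' @param object An [nllmda()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nllmda_fit <- function(object, ...) {
  df <- tidy(object)
  df$microbe_id <- factor(df$microbe_id, levels = rev(rownames(object$scores)))
  df$disease_id <- factor(df$disease_id, levels = colnames(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease_id, y = .data$microbe_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$known == 1L),
                        shape = 21, size = 0.8, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "disease", y = "microbe", fill = "score",
                  title = "Integrated association scores",
                  subtitle = "dots mark known associations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
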