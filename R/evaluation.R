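## Rank-statistic AUC (Mann-Whitney with tied-rank averaging).
rank_auc <- function(pos, neg) {
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos < 1L || n_neg < 1L) abort("AUC needs at least one positive and one negative score.")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Ranking metrics for a scored test split
#'
#' Computes sensitivity `TP / (TP + FN)`, specificity `TN / (FP + TN)`,
#' accuracy `(TP + TN) / (TP + FP + TN + FN)` and the rank-statistic AUC
#' (probability a random test positive outscores a random test negative,
#' ties counting one half) for a set of test positives and test negatives.
#'
#' The confusion counts need a score threshold, which threshold-free AUC
#' does not; the default `threshold = "prevalence"` declares positive the
#' top-`q` scored test pairs where `q` is the number of test positives
#' (ties at the cut broken by microbe then disease index). A numeric
#' `threshold` declares positive every score strictly above it.
#'
#' @param scores Numeric score matrix (or an [nllmda()] fit).
#' @param positives,negatives Two-column objects (microbe, disease) of
#'   test pairs — ids or 1-based positions; must be disjoint.
#' @param threshold `"prevalence"` (default) or a numeric cut.
#' @return A one-row tibble of class `mda_metrics`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `auc`.
#'
#' @examples
#' Z <- matrix(c(0.9, 0.2, 0.4, 0.1, 0.6, 0.3), 2, 3,
#'             dimnames = list(c("m1", "m2"), c("d1", "d2", "d3")))
#' compute_metrics(Z, positives = cbind(c(1, 1), c(1, 2)),
#'                 negatives = cbind(c(2, 2), c(1, 3)))
#' @export
compute_metrics <- function(scores, positives, negatives,
                            threshold = "prevalence") {
  if (inherits(scores, "nllmda_fit")) scores <- scores$scores
  if (!is.matrix(scores) || !all(is.finite(scores))) {
    abort("`scores` must be a finite numeric matrix.")
  }
  pos <- as_pair_index(positives, scores, "positives")
  neg <- as_pair_index(negatives, scores, "negatives")
  if (nrow(pos) < 1L) abort("`positives` must be nonempty.")
  if (nrow(neg) < 1L) abort("AUC is undefined without test negatives.")
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (length(intersect(key(pos), key(neg)))) {
    abort("`positives` and `negatives` must be disjoint.")
  }
  s_pos <- scores[pos]; s_neg <- scores[neg]
  auc <- rank_auc(s_pos, s_neg)

  lab <- c(rep(TRUE, nrow(pos)), rep(FALSE, nrow(neg)))
  all_idx <- rbind(pos, neg)
  s_all <- c(s_pos, s_neg)
  if (identical(threshold, "prevalence")) {
    ord <- order(-s_all, all_idx[, 1L], all_idx[, 2L])
    called <- logical(length(s_all))
    called[ord[seq_len(nrow(pos))]] <- TRUE
  } else {
    assert_scalar_number(threshold, "threshold")
    called <- s_all > threshold
  }
  tp <- sum(called & lab); fp <- sum(called & !lab)
  fn <- sum(!called & lab); tn <- sum(!called & !lab)
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (fp + tn),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    auc = auc
  )
  class(out) <- c("mda_metrics", class(out))
  out
}

#' Cross-validation folds for association matrices
#'
#' Builds the train/test splits of the three masking protocols used to
#' benchmark association predictors:
#'
#' * **CV1** (new microbes) partitions the *rows*: test microbes have
#'   their whole association profile zeroed in the training matrix.
#' * **CV2** (new diseases) partitions the *columns* the same way.
#' * **CV3** (new pairs) partitions the *positive entries*: each fold
#'   zeroes one fifth (for 5 folds) of the known associations.
#'
#' Test positives are the masked known associations. Test negatives are
#' all unlabeled pairs inside the masked rows/columns (CV1/CV2) or all
#' unlabeled pairs of the matrix (CV3).
#'
#' @param Y Association input (edge list, matrix or [mda_associations()]).
#' @param scheme `"CV1"`, `"CV2"` or `"CV3"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed making the shuffle reproducible.
#' @return A list of folds, each a list with `train` (masked 0/1 matrix),
#'   `test_positives` and `test_negatives` (2-column position matrices).
#' @export
make_folds <- function(Y, scheme = c("CV3", "CV1", "CV2"), n_folds = 5L,
                       seed = NULL) {
  Y <- as_mda_assoc(Y, "Y")
  scheme <- match.arg(scheme)
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  A <- as.matrix(Y)
  local_seed(seed)
  if (scheme %in% c("CV1", "CV2")) {
    n_units <- if (scheme == "CV1") nrow(A) else ncol(A)
    if (n_units < n_folds) {
      abort(sprintf("%s needs at least %d %s.", scheme, n_folds,
                    if (scheme == "CV1") "microbes" else "diseases"))
    }
    units <- sample.int(n_units)
    groups <- split(units, cut(seq_along(units), n_folds, labels = FALSE))
    folds <- lapply(groups, function(g) {
      train <- A
      if (scheme == "CV1") train[g, ] <- 0 else train[, g] <- 0
      masked <- if (scheme == "CV1") {
        cbind(rep(g, each = ncol(A)), rep(seq_len(ncol(A)), length(g)))
      } else {
        cbind(rep(seq_len(nrow(A)), length(g)), rep(g, each = nrow(A)))
      }
      is_pos <- A[masked] == 1
      list(train = train,
           test_positives = masked[is_pos, , drop = FALSE],
           test_negatives = masked[!is_pos, , drop = FALSE])
    })
  } else {
    pos <- which(A == 1, arr.ind = TRUE)
    if (nrow(pos) < n_folds) {
      abort(sprintf("CV3 needs at least %d known associations.", n_folds))
    }
    neg <- which(A == 0, arr.ind = TRUE)
    shuffled <- sample.int(nrow(pos))
    groups <- split(shuffled, cut(seq_along(shuffled), n_folds, labels = FALSE))
    folds <- lapply(groups, function(g) {
      held <- pos[g, , drop = FALSE]
      train <- A
      train[held] <- 0
      list(train = train,
           test_positives = unname(held),
           test_negatives = unname(neg))
    })
  }
  names(folds) <- NULL
  for (f in folds) stopifnot(all(f$train[f$test_positives] == 0))
  folds
}

#' Repeated cross-validated evaluation of NLLMDA
#'
#' Runs [nllmda()] on every fold's training matrix over `n_trials`
#' independent shuffles of the chosen masking scheme and scores each
#' fold's test split with [compute_metrics()]. Trial `t` uses seed
#' `seed + t - 1`, so the full experiment is reproducible and trials are
#' independent.
#'
#' @inheritParams make_folds
#' @param associations Association input.
#' @param symptoms,symptom_sim Disease symptom data passed to [nllmda()]
#'   (computed once; symptom data describe diseases, not the train/test
#'   split, so they are never masked).
#' @param n_trials Number of repeated shuffles (default 10).
#' @param seed Base seed (default 1).
#' @param ... Further arguments to [nllmda()] (e.g. `alpha`, `beta`,
#'   `neighbor_fraction`).
#' @return A tibble of class `nllmda_cv` with one row per trial and fold
#'   (`trial`, `fold`, plus the [compute_metrics()] columns). The number
#'   of pipeline fits executed is recorded in attribute `n_fits`;
#'   [glance.nllmda_cv()] averages over rows.
#' @export
run_cv <- function(associations, symptoms = NULL, symptom_sim = NULL,
                   scheme = c("CV3", "CV1", "CV2"), n_folds = 5L,
                   n_trials = 10L, seed = 1L, ...) {
  assoc <- as_mda_assoc(associations)
  scheme <- match.arg(scheme)
  n_trials <- assert_count(n_trials, "n_trials")
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  S_s <- symptom_sim
  if (is.null(S_s) && !is.null(symptoms)) S_s <- symptom_similarity(symptoms)
  n_fits <- 0L
  rows <- purrr::map(seq_len(n_trials), function(t) {
    folds <- make_folds(assoc, scheme = scheme, n_folds = n_folds,
                        seed = seed + t - 1L)
    purrr::imap(folds, function(f, k) {
      train <- mda_associations(f$train)
      fit <- nllmda(train, symptom_sim = S_s, ...)
      n_fits <<- n_fits + 1L
      dplyr::bind_cols(
        tibble(trial = t, fold = k),
        compute_metrics(fit$scores, f$test_positives, f$test_negatives)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows, class = c("nllmda_cv", class(tibble())),
            scheme = scheme, n_fits = n_fits, seed = seed)
}

#' @rdname run_cv
#' @param x An `nllmda_cv` result.
#' @return `glance()` returns a one-row tibble with the scheme, the number
#'   of trials and folds, the mean of each metric across all fold
#'   evaluations, and the standard deviation and standard error of AUC.
#' @exportS3Method generics::glance
glance.nllmda_cv <- function(x, ...) {
  tibble(
    scheme = attr(x, "scheme"),
    n_trials = length(unique(x$trial)),
    n_folds = length(unique(x$fold)),
    sensitivity = mean(x$sensitivity),
    specificity = mean(x$specificity),
    accuracy = mean(x$accuracy),
    auc = mean(x$auc),
    auc_sd = stats::sd(x$auc),
    auc_se = stats::sd(x$auc) / sqrt(nrow(x))
  )
}

#' @rdname run_cv
#' @exportS3Method generics::tidy
tidy.nllmda_cv <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Distribution of cross-validated metrics
#'
#' Boxplots of per-fold sensitivity, specificity, accuracy and AUC across
#' trials.
#'
#' @param object An `nllmda_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nllmda_cv <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "accuracy", "auc"),
                        names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Cross-validated performance (%s)", attr(object, "scheme")),
      subtitle = sprintf("%d trial(s) x %d fold(s)",
                         length(unique(object$trial)),
                         length(unique(object$fold)))
    ) +
    ggplot2::theme_minimal()
}

#' Hyperparameter grid search by cross-validated AUC
#'
#' Exhaustively evaluates every combination of the supplied hyperparameter
#' values with [run_cv()] and ranks them by mean AUC. Ties keep the first
#' combination in iteration order (the order of `expand.grid` over the
#' supplied vectors).
#'
#' @inheritParams run_cv
#' @param grid Named list of parameter vectors; names must be [nllmda()]
#'   arguments (`gamma_m_prime`, `gamma_d_prime`, `gamma`, `alpha`,
#'   `beta`, `neighbor_fraction`, `k_neighbors`).
#' @param ... Fixed arguments passed to every [run_cv()] call.
#' @return A list with `best` (named list of the winning parameter values)
#'   and `table` (tibble of all combinations with their mean AUC and its
#'   standard deviation, in iteration order).
#' @export
grid_search_nllmda <- function(associations, grid, symptoms = NULL,
                               symptom_sim = NULL,
                               scheme = c("CV3", "CV1", "CV2"),
                               n_folds = 5L, n_trials = 2L, seed = 1L, ...) {
  if (!is.list(grid) || is.null(names(grid)) || any(names(grid) == "")) {
    abort("`grid` must be a named list of parameter value vectors.")
  }
  allowed <- c("gamma_m_prime", "gamma_d_prime", "gamma", "alpha", "beta",
               "neighbor_fraction", "k_neighbors")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    abort(sprintf("unknown grid parameter(s): %s", paste(bad, collapse = ", ")))
  }
  scheme <- match.arg(scheme)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  results <- purrr::map(seq_len(nrow(combos)), function(r) {
    args <- as.list(combos[r, , drop = FALSE])
    cv <- do.call(run_cv, c(
      list(associations = associations, symptoms = symptoms,
           symptom_sim = symptom_sim, scheme = scheme, n_folds = n_folds,
           n_trials = n_trials, seed = seed),
      args, list(...)
    ))
    tibble(mean_auc = mean(cv$auc), sd_auc = stats::sd(cv$auc))
  }) |> purrr::list_rbind()
  table <- dplyr::bind_cols(tibble::as_tibble(combos), results)
  best_row <- which.max(table$mean_auc)
  list(best = as.list(combos[best_row, , drop = FALSE]), table = table)
}
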