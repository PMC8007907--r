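test_that("metrics reproduce the hand contingency table", {
  ## positives (0.9, 0.8, 0.7, 0.2), negatives (0.75, 0.6, 0.3, 0.2, 0.1, 0.05)
  ## at threshold 0.5: TP=3, FN=1, FP=2, TN=4
  Z <- matrix(c(0.9, 0.8, 0.7, 0.2, 0.75, 0.6, 0.3, 0.2, 0.1, 0.05), 2, 5,
              dimnames = list(c("m1", "m2"), paste0("d", 1:5)))
  pos <- cbind(c(1, 2, 1, 2), c(1, 1, 2, 2))
  neg <- cbind(c(1, 2, 1, 2, 1, 2), c(3, 3, 4, 4, 5, 5))
  m <- compute_metrics(Z, pos, neg, threshold = 0.5)
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$fp, 2); expect_equal(m$tn, 4)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  ## counts partition the evaluated pairs and metrics match the counts
  expect_equal(m$tp + m$fp + m$tn + m$fn, 10)
  expect_equal(m$accuracy, (m$tp + m$tn) / 10, tolerance = 1e-12)
})

test_that("rank AUC matches hand cases and brute-force pairwise counting", {
  Z <- matrix(c(0.9, 0.4, 0.6, 0.1), 1, 4,
              dimnames = list("m1", paste0("d", 1:4)))
  m <- compute_metrics(Z, cbind(1, 1:2), cbind(1, 3:4))
  expect_equal(m$auc, 0.75)  # 3 of 4 positive-negative pairs won

  ## perfect ranking
  m2 <- compute_metrics(Z, cbind(1, c(1, 3)), cbind(1, c(2, 4)))
  expect_equal(m2$auc, 1)

  set.seed(71)
  for (rep in 1:10) {
    n_pos <- sample(1:25, 1); n_neg <- sample(1:25, 1)
    scores <- matrix(sample(seq(0, 1, 0.1), 50, TRUE), 5, 10,
                     dimnames = list(paste0("m", 1:5), paste0("d", 1:10)))
    all_pairs <- as.matrix(expand.grid(1:5, 1:10))[sample(50, n_pos + n_neg), ]
    pos <- all_pairs[seq_len(n_pos), , drop = FALSE]
    neg <- all_pairs[n_pos + seq_len(n_neg), , drop = FALSE]
    m <- compute_metrics(scores, pos, neg)
    expect_identical(m$auc, brute_auc(scores[pos], scores[neg]))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  scores <- matrix(runif(60), 6, 10,
                   dimnames = list(paste0("m", 1:6), paste0("d", 1:10)))
  pos <- cbind(sample(6, 12, TRUE), sample(10, 12, TRUE))
  pos <- unique(pos)
  neg <- as.matrix(expand.grid(1:6, 1:10))
  neg <- neg[!(paste(neg[, 1], neg[, 2]) %in% paste(pos[, 1], pos[, 2])), ]
  m <- compute_metrics(scores, pos, neg)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, nrow(pos)), rep(0, nrow(neg))),
    predictor = c(scores[pos], scores[neg]), quiet = TRUE, direction = "<"
  ))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the prevalence threshold calls exactly as many positives as observed", {
  set.seed(73)
  scores <- matrix(runif(40), 4, 10,
                   dimnames = list(paste0("m", 1:4), paste0("d", 1:10)))
  pos <- cbind(c(1, 2, 3), c(1, 2, 3))
  neg <- cbind(rep(1:4, 4), rep(4:7, each = 4))
  m <- compute_metrics(scores, pos, neg)
  expect_equal(m$tp + m$fp, 3)
  expect_equal(m$tp + m$fn, 3)
})

test_that("specificity and accuracy coincide when negatives dominate", {
  set.seed(74)
  scores <- matrix(runif(1010), 10, 101,
                   dimnames = list(paste0("m", 1:10), paste0("d", 1:101)))
  pos <- cbind(1:2, 1:2)
  neg <- as.matrix(expand.grid(1:10, 2:101))
  neg <- neg[!(paste(neg[, 1], neg[, 2]) %in% paste(pos[, 1], pos[, 2])), ]
  m <- compute_metrics(scores, pos, neg)
  expect_gt(nrow(neg) / nrow(pos), 100)
  expect_lt(abs(m$specificity - m$accuracy), 0.01)
})

test_that("metrics validate their inputs", {
  Z <- matrix(runif(4), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_error(compute_metrics(Z, cbind(1, 1), cbind(1, 1)), "disjoint")
  expect_error(compute_metrics(Z, cbind(1, 1), matrix(0L, 0, 2)), "negatives")
})

test_that("CV1 folds partition the rows; masking is seed-reproducible", {
  set.seed(75)
  A <- random_assoc(10, 6, p = 0.4)
  folds <- make_folds(A, scheme = "CV1", n_folds = 5, seed = 9)
  expect_length(folds, 5)
  ## each fold tests exactly 2 of the 10 rows, disjointly and exhaustively
  per_fold <- lapply(folds, function(f) {
    sort(unique(c(f$test_positives[, 1], f$test_negatives[, 1])))
  })
  expect_true(all(lengths(per_fold) == 2))
  expect_identical(sort(unlist(per_fold)), 1:10)
  ## leakage: masked entries are zero in the training matrix
  for (f in folds) {
    expect_true(all(f$train[f$test_positives] == 0))
    expect_true(all(f$train[f$test_negatives] == 0))
  }
  expect_identical(folds, make_folds(A, scheme = "CV1", n_folds = 5, seed = 9))
  expect_error(make_folds(A, scheme = "CV1", n_folds = 11), "at least")
})

test_that("CV3 folds partition the positives and test against all unlabeled pairs", {
  set.seed(76)
  A <- random_assoc(8, 8, p = 0.4)
  n_pos <- sum(A)
  folds <- make_folds(A, scheme = "CV3", n_folds = 4, seed = 3)
  test_counts <- vapply(folds, function(f) nrow(f$test_positives), 1L)
  expect_equal(sum(test_counts), n_pos)
  expect_true(max(test_counts) - min(test_counts) <= 1)
  for (f in folds) {
    expect_true(all(A[f$test_positives] == 1))
    expect_true(all(f$train[f$test_positives] == 0))
    expect_equal(nrow(f$test_negatives), sum(A == 0))
    ## non-held positives stay in training
    expect_equal(sum(f$train), n_pos - nrow(f$test_positives))
  }
})

test_that("CV2 test negatives live inside the masked columns only", {
  set.seed(77)
  A <- random_assoc(6, 10, p = 0.4)
  folds <- make_folds(A, scheme = "CV2", n_folds = 5, seed = 2)
  for (f in folds) {
    masked_cols <- unique(c(f$test_positives[, 2], f$test_negatives[, 2]))
    expect_length(masked_cols, 2)
    expect_true(all(f$train[, masked_cols] == 0))
    untouched <- setdiff(1:10, masked_cols)
    expect_identical(f$train[, untouched], A[, untouched] * 1)
  }
})

test_that("run_cv executes trials x folds pipeline fits and averages them", {
  sim <- simulate_mda(n_microbes = 30, m_diseases = 12, seed = 78)
  cv <- run_cv(sim$associations, symptoms = sim$symptoms, scheme = "CV3",
               n_folds = 5, n_trials = 2, seed = 4)
  expect_equal(nrow(cv), 10L)
  expect_identical(attr(cv, "n_fits"), 10L)
  expect_identical(unique(cv$trial), 1:2)
  g <- glance(cv)
  expect_equal(g$auc, mean(cv$auc))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  ## same seed, same report
  cv2 <- run_cv(sim$associations, symptoms = sim$symptoms, scheme = "CV3",
                n_folds = 5, n_trials = 2, seed = 4)
  expect_identical(tibble::as_tibble(cv), tibble::as_tibble(cv2))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("grid search evaluates every combination and returns the best by mean AUC", {
  sim <- simulate_mda(n_microbes = 25, m_diseases = 10, seed = 79)
  single <- grid_search_nllmda(sim$associations, list(beta = 0.1),
                               symptoms = sim$symptoms, n_trials = 1, seed = 5)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$best$beta, 0.1)

  gs <- grid_search_nllmda(
    sim$associations, list(beta = c(0.1, 0.9999), alpha = c(0.1, 0.7)),
    symptoms = sim$symptoms, n_trials = 1, seed = 5
  )
  expect_equal(nrow(gs$table), 4L)
  ## the near-singular beta stays finite-conditioned
  expect_true(all(is.finite(gs$table$mean_auc)))
  expect_equal(gs$table$mean_auc[which.max(gs$table$mean_auc)],
               max(gs$table$mean_auc))
  expect_error(grid_search_nllmda(sim$associations, list(bogus = 1)),
               "unknown grid parameter")
})
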