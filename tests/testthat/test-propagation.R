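test_that("label propagation matches the hand-solved 2x2 closed form", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  Y0 <- matrix(c(1, 0), 2, 1)
  got <- label_propagate(W, Y0, beta = 0.1)
  ## (1-b)(I-bW)^{-1}(1,0)' = (0.9/0.99)(1, 0.1)'
  expect_equal(drop(got), c(0.9 / 0.99, 0.09 / 0.99), tolerance = 1e-12)
  ## beta = 0 reduces to the initial labels
  expect_equal(label_propagate(W, Y0, beta = 0), Y0)
})

test_that("closed form, fixed-point iteration, and the Neumann series agree", {
  set.seed(51)
  W <- random_row_stochastic(12)
  Y0 <- matrix(runif(12 * 7), 12, 7)
  closed <- label_propagate(W, Y0, beta = 0.1, side = "microbe")
  iter <- label_propagate(W, Y0, beta = 0.1, side = "microbe",
                          mode = "iterative")
  expect_equal(closed, iter, tolerance = 1e-8)
  neumann <- matrix(0, 12, 7)
  Wp <- diag(12)
  for (t in 0:200) {
    neumann <- neumann + 0.9 * 0.1^t * (Wp %*% Y0)
    Wp <- Wp %*% W
  }
  expect_equal(closed, neumann, tolerance = 1e-8)
})

test_that("disease-side propagation mixes columns and transposes consistently", {
  set.seed(52)
  Wd <- random_row_stochastic(6)
  Y0 <- matrix(runif(4 * 6), 4, 6)
  d_side <- label_propagate(Wd, Y0, beta = 0.3, side = "disease")
  expect_equal(d_side,
               t(label_propagate(Wd, t(Y0), beta = 0.3, side = "microbe")),
               tolerance = 1e-12)
  expect_equal(label_propagate(Wd, Y0, beta = 0.3, side = "disease",
                               mode = "iterative"),
               d_side, tolerance = 1e-8)
  expect_error(label_propagate(Wd, Y0, beta = 0.3, side = "microbe"),
               "side")
})

test_that("propagation of nonnegative labels stays nonnegative", {
  set.seed(53)
  for (rep in 1:5) {
    W <- random_row_stochastic(9)
    Y0 <- matrix(rbinom(9 * 4, 1, 0.3), 9, 4)
    expect_true(all(label_propagate(W, Y0, beta = 0.4) >= -1e-12))
  }
})

test_that("score integration is the simplex-weighted sum with strict validation", {
  A <- matrix(1.0, 2, 2); B <- matrix(0.5, 2, 2); C <- matrix(0.0, 2, 2)
  Z <- integrate_scores(list(A, B, C), c(0.5, 0.3, 0.2))
  expect_equal(Z[1, 1], 0.65)
  expect_equal(integrate_scores(list(A, A, A), c(0.2, 0.3, 0.5)), A)
  expect_equal(integrate_scores(list(A, B, C), c(1, 0, 0)), A)
  expect_error(integrate_scores(list(A, B), c(1, 0, 0)), "weights")
  expect_error(integrate_scores(list(A, B), c(0.8, 0.1)), "sum to 1")
  expect_error(integrate_scores(list(A, matrix(0, 3, 3)), c(0.5, 0.5)),
               "same shape")
})

test_that("integration preserves a pair ordering all models agree on", {
  set.seed(54)
  base <- matrix(runif(20), 4, 5)
  models <- list(base, 2 * base + 1, 0.5 * base)
  Z <- integrate_scores(models, c(0.2, 0.5, 0.3))
  expect_identical(order(Z), order(base))
})

test_that("weight fitting recovers a perfectly separating model", {
  set.seed(55)
  pos <- cbind(sample(10, 20, TRUE), sample(8, 20, TRUE))
  pos <- unique(pos)
  all_pairs <- as.matrix(expand.grid(1:10, 1:8))
  key <- function(m) paste(m[, 1], m[, 2])
  neg <- all_pairs[!(key(all_pairs) %in% key(pos)), ][1:15, ]
  perfect <- matrix(0, 10, 8); perfect[pos] <- 1
  noise1 <- matrix(runif(80), 10, 8)
  noise2 <- matrix(runif(80), 10, 8)
  w <- fit_integration_weights(list(perfect, noise1, noise2), pos, neg)
  expect_equal(w, c(1, 0, 0))

  ## identical models: every grid point ties -> uniform weights
  w_tie <- fit_integration_weights(list(noise1, noise1, noise1), pos, neg)
  expect_equal(w_tie, rep(1 / 3, 3))

  ## no negatives -> uniform fallback
  expect_equal(fit_integration_weights(list(perfect, noise1), pos, NULL),
               c(0.5, 0.5))
})

test_that("the simplex grid enumerates compositions of 1/step", {
  g <- nllmda:::simplex_grid(3, 0.5)
  expect_equal(nrow(g), 6L)  # compositions of 2 into 3 parts
  expect_equal(rowSums(g), rep(1, 6))
  expect_true(all(g >= 0))
  g01 <- nllmda:::simplex_grid(3, 0.1)
  expect_equal(nrow(g01), choose(12, 2))
})

test_that("the end-to-end pipeline is deterministic and separates planted signal", {
  seps <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_mda(n_microbes = 40, m_diseases = 12, seed = 200 + s)
    fit <- nllmda(sim$associations, symptoms = sim$symptoms)
    A <- as.matrix(sim$associations)
    seps[s] <- mean(fit$scores[A == 1]) - mean(fit$scores[A == 0])
  }
  expect_true(all(seps > 0))

  sim <- simulate_mda(n_microbes = 40, m_diseases = 12, seed = 201)
  f1 <- nllmda(sim$associations, symptoms = sim$symptoms)
  f2 <- nllmda(sim$associations, symptoms = sim$symptoms)
  expect_identical(f1$scores, f2$scores)
  expect_equal(sum(f1$weights), 1)
  expect_equal(length(f1$models), 3L)
})

test_that("a zeroed disease recovers its true microbes better than random (new-disease check)", {
  ranks <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_mda(n_microbes = 40, m_diseases = 12, seed = 300 + s)
    A <- as.matrix(sim$associations)
    j <- which.max(colSums(A))
    truth <- which(A[, j] == 1)
    A_train <- A; A_train[, j] <- 0
    fit <- nllmda(mda_associations(A_train), symptoms = sim$symptoms)
    ranks[s] <- mean(rank(-fit$scores[, j])[truth]) / nrow(A)
  }
  ## mean normalised rank of the true microbes clearly better than 0.5
  expect_lt(mean(ranks), 0.4)
})

test_that("the pipeline without symptom data integrates the two GAP models", {
  sim <- simulate_mda(n_microbes = 30, m_diseases = 10, seed = 61)
  expect_message(fit <- nllmda(sim$associations), "two GAP models")
  expect_equal(length(fit$models), 2L)
  expect_equal(unname(fit$weights), c(0.5, 0.5))
})

test_that("weight fitting mode mines negatives and returns simplex weights", {
  sim <- simulate_mda(n_microbes = 30, m_diseases = 10, seed = 62)
  fit <- nllmda(sim$associations, symptoms = sim$symptoms, weights = "fit")
  expect_false(is.null(fit$negatives))
  expect_equal(nrow(fit$negatives), sum(as.matrix(sim$associations)))
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_mda(n_microbes = 20, m_diseases = 8, seed = 63)
  fit <- nllmda(sim$associations, symptoms = sim$symptoms)
  td <- tidy(fit)
  expect_equal(nrow(td), 20 * 8)
  expect_named(td, c("rank", "microbe_id", "disease_id", "score", "known"))
  expect_true(all(tidy(fit, new_only = TRUE)$known == 0))
  g <- glance(fit)
  expect_equal(g$n_models, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
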