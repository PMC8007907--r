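#' Simulate a microbe-disease benchmark with planted clusters
#'
#' Generates the kind of data the prediction pipeline assumes: microbes
#' and diseases fall into latent clusters, a microbe associates with a
#' same-cluster disease with probability `p_in` and with any other disease
#' with probability `p_out < p_in` ("similar microbes associate with
#' similar diseases"), and each disease carries a symptom weight vector
#' correlated with its cluster. Entities are assigned to clusters
#' round-robin (`m001` to cluster 1, `m002` to cluster 2, ...), so cluster
#' sizes are balanced by construction and runs differ only through the
#' Bernoulli draws and symptom noise.
#'
#' Disease symptom vectors mix a cluster prototype (a one-hot block over
#' the `symptom_dim` terms) with uniform noise:
#' `w = (1 - symptom_noise) * prototype + symptom_noise * U(0, 1)^dim`.
#'
#' The defaults (100 microbes, 30 diseases, 3 clusters, `p_in = 0.5`,
#' `p_out = 0.02`, `symptom_dim = 30`, `symptom_noise = 0.2`) form the
#' benchmark configuration used throughout the package's tests and
#' examples: a few hundred planted associations, sparse off-cluster
#' background, and informative but noisy symptom features.
#'
#' @param n_microbes,m_diseases Entity counts.
#' @param n_clusters Number of planted clusters (must not exceed either
#'   entity count).
#' @param p_in,p_out Within- and cross-cluster association probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param symptom_dim Number of symptom terms.
#' @param symptom_noise Noise mixing rate in `[0, 1]`; 0 gives pure
#'   prototypes, 1 pure noise.
#' @param seed Integer seed; the output is fully determined by it. If the
#'   draw comes out with no associations at all (possible for tiny, sparse
#'   configurations) the generator redraws once with a warning, then
#'   errors.
#' @return A list of class `mda_sim`: `associations`
#'   ([mda_associations()] object), `symptoms` (disease x symptom weight
#'   matrix), `microbe_clusters` and `disease_clusters` (tibbles with
#'   `id`, `cluster`), and `config`.
#'
#' @examples
#' sim <- simulate_mda(n_microbes = 40, m_diseases = 12, seed = 1)
#' sim$associations
#' table(sim$disease_clusters$cluster)
#' @export
simulate_mda <- function(n_microbes = 100L, m_diseases = 30L, n_clusters = 3L,
                         p_in = 0.5, p_out = 0.02, symptom_dim = 30L,
                         symptom_noise = 0.2, seed = NULL) {
  n_microbes <- assert_count(n_microbes, "n_microbes")
  m_diseases <- assert_count(m_diseases, "m_diseases")
  n_clusters <- assert_count(n_clusters, "n_clusters")
  if (n_clusters > min(n_microbes, m_diseases)) {
    abort("`n_clusters` must not exceed the smaller entity count.")
  }
  assert_scalar_number(p_in, "p_in", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(p_out, "p_out", lower = 0, upper = 1)
  if (p_out >= p_in) abort("need `p_out` < `p_in` for planted structure.")
  symptom_dim <- assert_count(symptom_dim, "symptom_dim")
  if (symptom_dim < n_clusters) abort("`symptom_dim` must be >= `n_clusters`.")
  assert_scalar_number(symptom_noise, "symptom_noise", lower = 0, upper = 1)
  local_seed(seed)

  microbes <- sprintf("m%03d", seq_len(n_microbes))
  diseases <- sprintf("d%03d", seq_len(m_diseases))
  cl_m <- ((seq_len(n_microbes) - 1L) %% n_clusters) + 1L
  cl_d <- ((seq_len(m_diseases) - 1L) %% n_clusters) + 1L

  draw <- function() {
    p <- ifelse(outer(cl_m, cl_d, `==`), p_in, p_out)
    matrix(rbinom(length(p), 1L, p), n_microbes, m_diseases,
           dimnames = list(microbes, diseases))
  }
  A <- draw()
  if (sum(A) == 0) {
    warn("simulated matrix had no associations; redrawing once.")
    A <- draw()
    if (sum(A) == 0) abort("configuration yields an empty association matrix.")
  }

  ## cluster prototypes: contiguous one-hot blocks over the symptom terms
  block <- cut(seq_len(symptom_dim), n_clusters, labels = FALSE)
  proto <- vapply(seq_len(n_clusters),
                  function(c) as.numeric(block == c), numeric(symptom_dim))
  symptoms <- (1 - symptom_noise) * t(proto[, cl_d, drop = FALSE]) +
    symptom_noise * matrix(runif(m_diseases * symptom_dim),
                           m_diseases, symptom_dim)
  dimnames(symptoms) <- list(diseases, sprintf("s%03d", seq_len(symptom_dim)))

  structure(
    list(
      associations = mda_associations(A),
      symptoms = symptoms,
      microbe_clusters = tibble(id = microbes, cluster = cl_m),
      disease_clusters = tibble(id = diseases, cluster = cl_d),
      config = list(n_microbes = n_microbes, m_diseases = m_diseases,
                    n_clusters = n_clusters, p_in = p_in, p_out = p_out,
                    symptom_dim = symptom_dim, symptom_noise = symptom_noise,
                    seed = seed)
    ),
    class = "mda_sim"
  )
}

#' @export
print.mda_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mda_sim> %d microbes x %d diseases, %d clusters, %d associations (p_in %.2f, p_out %.2f)\n",
    cfg$n_microbes, cfg$m_diseases, cfg$n_clusters,
    sum(as.matrix(x$associations)), cfg$p_in, cfg$p_out
  ))
  invisible(x)
}
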