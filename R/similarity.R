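#' Gaussian association-profile (GAP) similarity
#'
#' Radial-basis similarity between binary association profiles with a
#' data-normalised bandwidth. For profiles `A(i)` (the rows of `profiles`),
#'
#' \deqn{S(i, j) = \exp(-\gamma \, \|A(i) - A(j)\|^2), \qquad
#'       \gamma = \frac{\gamma'}{\frac{1}{n}\sum_k \|A(k)\|^2}}
#'
#' so the kernel width adapts to the overall density of the profile set and
#' the similarity is invariant to rescaling all profiles by a common
#' factor. Microbe similarity uses the rows of the association matrix as
#' profiles; disease similarity uses its columns (pass `t(Y)`).
#'
#' @param profiles Numeric matrix, one profile per row. Individual all-zero
#'   rows are fine (they occur for new microbes/diseases under
#'   cross-validation) as long as the profile set is not entirely zero.
#' @param gamma_prime Positive bandwidth multiplier \eqn{\gamma'}
#'   (default 1).
#' @return A square symmetric similarity matrix with unit diagonal and
#'   entries in `(0, 1]`, carrying the rownames of `profiles`.
#'
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
#' gap_similarity(Y)          # off-diagonal exp(-2)
#' gap_similarity(t(Y))       # disease-side similarity
#' @export
gap_similarity <- function(profiles, gamma_prime = 1) {
  if (!is.matrix(profiles) || !is.numeric(profiles)) {
    abort("`profiles` must be a numeric matrix (one profile per row).")
  }
  assert_scalar_number(gamma_prime, "gamma_prime", lower = 0, strict_lower = TRUE)
  sq <- rowSums(profiles^2)
  norm <- mean(sq)
  if (norm == 0) {
    abort("degenerate bandwidth: all profiles are zero, cannot normalise the kernel width.")
  }
  gamma <- gamma_prime / norm
  ## ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clipped against rounding
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  S <- exp(-gamma * d2)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Symptom-based disease similarity
#'
#' Cosine similarity between TF-IDF-weighted disease-symptom vectors, the
#' construction used by the human symptoms-disease network: the raw weight
#' of symptom `t` for disease `d` is multiplied by the smoothed inverse
#' document frequency `log(1 + n_diseases / n_diseases_with_t)` before
#' taking cosines, so ubiquitous symptoms are down-weighted (but never
#' erased, which keeps dense weight tables usable). Diseases with an
#' all-zero vector get similarity 0 to everything, including themselves.
#'
#' @param symptoms Nonnegative numeric matrix, diseases in rows and symptom
#'   terms in columns (see [read_symptom_table()]), or a data frame whose
#'   first column holds disease identifiers.
#' @param idf Apply inverse-document-frequency weighting (default `TRUE`).
#'   With `FALSE`, cosines are taken on the raw weights — useful when the
#'   table already carries calibrated weights.
#' @return Square symmetric matrix with entries in `[0, 1]`; diagonal 1 for
#'   diseases with a nonzero vector, 0 otherwise.
#'
#' @examples
#' w <- rbind(d1 = c(1, 1, 0), d2 = c(1, 0, 1), d3 = c(0, 1, 0), d4 = c(0, 0, 1))
#' symptom_similarity(w)["d1", "d2"]  # 0.5: every term occurs in 2 of 4 diseases
#' @export
symptom_similarity <- function(symptoms, idf = TRUE) {
  if (is.data.frame(symptoms)) {
    ids <- as.character(symptoms[[1L]])
    symptoms <- as.matrix(symptoms[-1L])
    rownames(symptoms) <- ids
  }
  if (!is.matrix(symptoms) || !is.numeric(symptoms) || any(symptoms < 0)) {
    abort("`symptoms` must be a nonnegative numeric matrix.")
  }
  W <- symptoms
  if (idf) {
    ## smoothed IDF: log(1 + N/df) never vanishes, so ubiquitous terms are
    ## down-weighted without being erased (real symptom tables are sparse,
    ## but dense nonnegative weight tables must stay usable)
    df <- colSums(W > 0)
    weight <- ifelse(df > 0, log1p(nrow(W) / df), 0)
    W <- sweep(W, 2L, weight, `*`)
  }
  nrm <- sqrt(rowSums(W^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  S <- tcrossprod(W * scale)
  diag(S) <- as.numeric(nrm > 0)
  S[S < 0] <- 0
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(symptoms), rownames(symptoms))
  S
}

#' Combine GAP and symptom disease similarity
#'
#' The final disease similarity adds the symptom channel to the GAP channel
#' with a relative weight `gamma`: `S_D = S_G + gamma * S_s`. No
#' renormalisation is applied, so entries may exceed 1; the downstream
#' linear-neighborhood step re-derives weights and is insensitive to the
#' overall scale.
#'
#' @param gap Disease GAP similarity matrix.
#' @param symptom Disease symptom similarity matrix on the identical
#'   disease index.
#' @param gamma Nonnegative weight of the symptom channel (default 0.7).
#' @return Combined square similarity matrix.
#' @export
combine_disease_similarity <- function(gap, symptom, gamma = 0.7) {
  assert_square(gap, "gap")
  assert_square(symptom, "symptom")
  assert_scalar_number(gamma, "gamma", lower = 0)
  if (!identical(dim(gap), dim(symptom)) ||
      !identical(rownames(gap), rownames(symptom))) {
    abort("`gap` and `symptom` must share the same disease index.")
  }
  S <- gap + gamma * symptom
  S
}

## Align a symptom-similarity matrix onto the association disease index.
## Diseases absent from the symptom data get zero similarity (warned), so
## the symptom channel simply carries no information for them.
align_symptom_similarity <- function(S_s, diseases) {
  out <- matrix(0, length(diseases), length(diseases),
                dimnames = list(diseases, diseases))
  have <- intersect(diseases, rownames(S_s))
  missing <- setdiff(diseases, have)
  if (length(missing)) {
    warn(sprintf("no symptom data for %d disease(s): %s",
                 length(missing), paste(missing, collapse = ", ")))
  }
  out[have, have] <- S_s[have, have]
  out
}
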