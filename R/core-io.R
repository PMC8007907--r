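#' Build a microbe-disease association matrix
#'
#' Constructs the binary incidence matrix `Y` at the core of microbe-disease
#' association (MDA) prediction: `Y[i, j] = 1` when microbe `i` has a curated
#' association with disease `j`, and 0 for an unlabeled pair. Rows are the
#' Gaussian association profiles (GAPs) of microbes, columns those of
#' diseases.
#'
#' @param x Either a data frame whose first two columns are microbe and
#'   disease identifiers (an edge list; duplicate pairs collapse to a single
#'   association), or a 0/1 matrix with microbe row names and disease column
#'   names.
#' @param microbes,diseases Optional character vectors fixing the identity
#'   and order of the row/column index. Defaults to first-appearance order
#'   for edge lists and dimname order for matrices. Identifiers listed here
#'   but absent from `x` become all-zero rows/columns (useful for
#'   cross-validation masks and for diseases known only through symptom
#'   data).
#'
#' @return An object of class `mda_assoc`: a list with elements `matrix`
#'   (binary numeric matrix with dimnames), `microbes` and `diseases`
#'   (character index vectors).
#'
#' @examples
#' edges <- tibble::tibble(
#'   microbe = c("m1", "m2", "m1"),
#'   disease = c("d1", "d2", "d1")
#' )
#' Y <- mda_associations(edges)
#' as.matrix(Y)
#' @export
mda_associations <- function(x, microbes = NULL, diseases = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("association matrices need microbe row names and disease column names.")
    }
    bad <- !(x %in% c(0, 1))
    if (any(bad)) {
      abort(sprintf("association matrix contains %d entries outside {0, 1}.",
                    sum(bad)))
    }
    microbes <- microbes %||% rownames(x)
    diseases <- diseases %||% colnames(x)
    Y <- matrix(0, length(microbes), length(diseases),
                dimnames = list(microbes, diseases))
    keep_m <- intersect(rownames(x), microbes)
    keep_d <- intersect(colnames(x), diseases)
    Y[keep_m, keep_d] <- x[keep_m, keep_d]
    return(new_mda_assoc(Y))
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2L) {
    abort("edge lists need at least two columns: microbe and disease identifiers.")
  }
  m_id <- as.character(x[[1L]])
  d_id <- as.character(x[[2L]])
  if (anyNA(m_id) || anyNA(d_id)) abort("edge list identifiers must not be NA.")
  microbes <- microbes %||% unique(m_id)
  diseases <- diseases %||% unique(d_id)
  if (!all(m_id %in% microbes)) abort("edge list names microbes missing from `microbes`.")
  if (!all(d_id %in% diseases)) abort("edge list names diseases missing from `diseases`.")
  Y <- matrix(0, length(microbes), length(diseases),
              dimnames = list(microbes, diseases))
  Y[cbind(match(m_id, microbes), match(d_id, diseases))] <- 1
  new_mda_assoc(Y)
}

new_mda_assoc <- function(Y) {
  if (anyDuplicated(rownames(Y))) abort("duplicate microbe identifiers.")
  if (anyDuplicated(colnames(Y))) abort("duplicate disease identifiers.")
  structure(
    list(matrix = Y, microbes = rownames(Y), diseases = colnames(Y)),
    class = "mda_assoc"
  )
}

#' @export
as.matrix.mda_assoc <- function(x, ...) x$matrix

#' @export
dim.mda_assoc <- function(x) dim(x$matrix)

#' @export
print.mda_assoc <- function(x, ...) {
  cat(sprintf(
    "<mda_assoc> %d microbes x %d diseases, %d associations (density %.3f)\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$matrix),
    mean(x$matrix)
  ))
  invisible(x)
}

#' @describeIn mda_associations Long tibble of the known associations
#'   (one row per `(microbe, disease)` pair with `y = 1`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mda_assoc <- function(x, ...) {
  idx <- which(x$matrix == 1, arr.ind = TRUE)
  tibble(
    microbe = x$microbes[idx[, 1L]],
    disease = x$diseases[idx[, 2L]]
  ) |>
    dplyr::arrange(match(.data$microbe, x$microbes),
                   match(.data$disease, x$diseases))
}

## Coerce the accepted association inputs (edge-list data frame, binary
## matrix, mda_assoc) to the internal container.
as_mda_assoc <- function(x, arg = "associations") {
  if (inherits(x, "mda_assoc")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(mda_associations(x))
  abort(sprintf("`%s` must be an edge-list data frame, a 0/1 matrix, or an `mda_assoc`.",
                arg))
}

#' Read and write association tables
#'
#' Associations travel as plain TSV in one of two layouts. An *edge list*
#' has no header and two tab-separated columns, `microbe_id` then
#' `disease_id`; lines starting with `#` are ignored and duplicate pairs
#' collapse to a single association. A *dense* table has disease
#' identifiers in the first row, microbe identifiers in the first column,
#' and 0/1 cells. Entity order is first-appearance order for edge lists and
#' header order for dense tables, so downstream matrices are reproducible
#' from the file alone.
#'
#' @param path Path to a TSV file.
#' @param format `"edge_list"`, `"dense"`, or `"auto"` (dense is recognised
#'   by its leading tab in the header row).
#' @return `read_associations()` returns an [mda_associations()] object.
#' @export
read_associations <- function(path, format = c("auto", "edge_list", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[!grepl("^\\s*(#|$)", lines)][1]
    if (is.na(first)) abort(sprintf("empty association file: %s", path))
    format <- if (startsWith(first, "\t")) "dense" else "edge_list"
  }
  if (format == "edge_list") read_edge_list(lines, path) else read_dense(lines, path)
}

read_edge_list <- function(lines, path) {
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(sprintf("empty association file: %s", path))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nums <- which(keep)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed edge list line %d in %s: need 2 tab-separated columns.",
                  nums[bad[1L]], path))
  }
  mda_associations(data.frame(
    microbe = vapply(fields, `[[`, "", 1L),
    disease = vapply(fields, `[[`, "", 2L)
  ))
}

read_dense <- function(lines, path) {
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) abort(sprintf("dense association file needs a header and >=1 row: %s", path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  diseases <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  microbes <- vapply(rows, `[[`, "", 1L)
  cells <- lapply(rows, `[`, -1L)
  n_bad <- which(lengths(cells) != length(diseases))
  if (length(n_bad)) {
    abort(sprintf("malformed dense line %d in %s: expected %d cells.",
                  n_bad[1L] + 1L, path, length(diseases)))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    abort(sprintf("dense association cells must be 0 or 1 in %s.", path))
  }
  Y <- matrix(vals, nrow = length(microbes), byrow = TRUE,
              dimnames = list(microbes, diseases))
  mda_associations(Y)
}

#' @rdname read_associations
#' @param x An [mda_associations()] object (or anything coercible).
#' @return `write_associations()` invisibly returns `path`. Edge lists are
#'   written sorted by (microbe index, disease index); isolated entities
#'   (all-zero rows/columns) are representable only in the dense layout.
#' @export
write_associations <- function(x, path, format = c("edge_list", "dense")) {
  x <- as_mda_assoc(x, "x")
  format <- match.arg(format)
  if (format == "edge_list") {
    idx <- which(x$matrix == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    writeLines(paste(x$microbes[idx[, 1L]], x$diseases[idx[, 2L]], sep = "\t"),
               path)
  } else {
    header <- paste(c("", x$diseases), collapse = "\t")
    body <- vapply(seq_along(x$microbes), function(i) {
      paste(c(x$microbes[i], format(x$matrix[i, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Rank predicted association scores
#'
#' Flattens a score matrix into a ranked table, the shape used for
#' case-study style reporting ("top k candidate microbes per disease").
#' Rows are sorted by descending score; exact ties break by
#' `(microbe_id, disease_id)` lexicographic order so output is
#' deterministic across runs.
#'
#' @param scores A numeric matrix of per-pair scores with microbe rownames
#'   and disease colnames, or an [nllmda()] fit.
#' @param known Optional 0/1 matrix of the same shape flagging known
#'   associations; for a fit, its training matrix is used.
#' @param top_k Keep only the `top_k` best-scored rows (globally, or per
#'   disease when `per_disease = TRUE`). Values larger than the number of
#'   pairs are clamped.
#' @param per_disease Rank within each disease instead of globally; output
#'   is then ordered by disease index, then rank.
#' @return A tibble with columns `rank`, `microbe_id`, `disease_id`,
#'   `score`, `known`.
#' @export
rank_scores <- function(scores, known = NULL, top_k = NULL, per_disease = FALSE) {
  if (inherits(scores, "nllmda_fit")) {
    known <- known %||% as.matrix(scores$associations)
    scores <- scores$scores
  }
  if (!is.matrix(scores) || is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort("`scores` must be a named numeric matrix or an nllmda fit.")
  }
  if (!all(is.finite(scores))) abort("scores must be finite.")
  if (!is.null(top_k)) top_k <- assert_count(top_k, "top_k")
  idx <- arrayInd(seq_along(scores), dim(scores))
  out <- tibble(
    microbe_id = rownames(scores)[idx[, 1L]],
    disease_id = colnames(scores)[idx[, 2L]],
    score = as.vector(scores),
    known = if (is.null(known)) 0L else as.integer(as.vector(known) > 0)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$microbe_id,
                        .data$disease_id)
  if (per_disease) {
    out <- out |>
      dplyr::mutate(rank = dplyr::row_number(), .by = "disease_id") |>
      dplyr::arrange(match(.data$disease_id, colnames(scores)), .data$rank)
  } else {
    out <- dplyr::mutate(out, rank = dplyr::row_number())
  }
  if (!is.null(top_k)) out <- dplyr::filter(out, .data$rank <= top_k)
  dplyr::select(out, "rank", "microbe_id", "disease_id", "score", "known")
}

#' @rdname rank_scores
#' @param path Output TSV path.
#' @param ... Passed on to `rank_scores()`.
#' @return `write_scores()` invisibly returns `path`; the file carries the
#'   header `rank  microbe_id  disease_id  score  known`.
#' @export
write_scores <- function(scores, path, ...) {
  tab <- rank_scores(scores, ...)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  writeLines(sprintf("%d\t%s\t%s\t%.10g\t%d", tab$rank, tab$microbe_id,
                     tab$disease_id, tab$score, tab$known), con)
  invisible(path)
}

#' Read a disease-symptom weight table
#'
#' A symptom table is a headered TSV: first column disease identifiers,
#' remaining columns nonnegative weights of symptom terms. It feeds
#' [symptom_similarity()].
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, diseases in rows, symptom terms in columns.
#' @export
read_symptom_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    abort("symptom weights must be finite and nonnegative.")
  }
  m
}

#' Read a precomputed square similarity matrix
#'
#' Bypass input for disease symptom similarity: a square TSV headered by
#' the same identifiers on rows and columns.
#'
#' @param path Path to the TSV.
#' @return A square numeric matrix with matching dimnames.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.delim(path, check.names = FALSE, row.names = 1L))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    abort("similarity file must be square with identical row/column identifiers.")
  }
  if (any(!is.finite(m)) || any(m < 0)) abort("similarities must be finite and nonnegative.")
  m
}
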