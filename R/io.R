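check_readable <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  invisible(path)
}

#' Read and write co-occurrence matrices
#'
#' Two on-disk formats are supported. The canonical format is a directed
#' triplet TSV, `term_i<TAB>term_j<TAB>count`, one nonzero cell per line
#' (human-diffable and natural for sparse literature-scale data). For
#' interoperability a MatrixMarket coordinate file can be written/read
#' instead, with a sidecar vocabulary file (one term per line, giving the
#' 1-based row/column order); the sidecar path is the matrix path plus
#' `".vocab"`.
#'
#' Reading validates as it parses: malformed lines, negative counts, and
#' duplicate `(i, j)` entries produce errors naming the offending line.
#' Writing then reading recovers the identical matrix (isolated
#' vocabulary terms survive only the MatrixMarket format, whose sidecar
#' lists the full vocabulary).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"mm"` (MatrixMarket + sidecar).
#' @param matrix A [cooc_matrix()].
#' @return `read_matrix()` returns a [cooc_matrix()]; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path, format = c("tsv", "mm")) {
  check_readable(path)
  format <- match.arg(format)
  if (format == "mm") return(read_matrix_mm(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(cooc_matrix(tibble::tibble(
      term1 = character(), term2 = character(), n = numeric()
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed triplet line %d in %s", bad[1], path))
  }
  term1 <- vapply(parts, `[[`, character(1), 1)
  term2 <- vapply(parts, `[[`, character(1), 2)
  n <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  bad <- which(is.na(n) | n < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid count on line %d in %s (must be a non-negative number)",
      bad[1], path
    ))
  }
  dup <- which(duplicated(paste0(term1, "\r", term2)))
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate (i, j) entry on line %d in %s", dup[1], path))
  }
  cooc_matrix(tibble::tibble(term1 = term1, term2 = term2, n = n))
}

#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "mm")) {
  check_cooc(matrix)
  format <- match.arg(format)
  if (format == "mm") {
    vocab <- attr(matrix, "vocabulary")
    i <- match(matrix$term1, vocab)
    j <- match(matrix$term2, vocab)
    m <- Matrix::sparseMatrix(
      i = i, j = j, x = matrix$n,
      dims = c(length(vocab), length(vocab))
    )
    Matrix::writeMM(m, path)
    writeLines(vocab, paste0(path, ".vocab"))
  } else {
    writeLines(
      sprintf("%s\t%s\t%g", matrix$term1, matrix$term2, matrix$n),
      path
    )
  }
  invisible(path)
}

read_matrix_mm <- function(path) {
  vocab_path <- paste0(path, ".vocab")
  if (!file.exists(vocab_path)) {
    rlang::abort(paste0("missing vocabulary sidecar file: ", vocab_path))
  }
  vocab <- readLines(vocab_path, encoding = "UTF-8")
  m <- methods::as(Matrix::readMM(path), "TsparseMatrix")
  if (nrow(m) != length(vocab) || ncol(m) != length(vocab)) {
    rlang::abort("MatrixMarket dimensions do not match the vocabulary sidecar")
  }
  if (any(m@x < 0)) rlang::abort("negative count in MatrixMarket file")
  cooc_matrix(
    tibble::tibble(
      term1 = vocab[m@i + 1L], term2 = vocab[m@j + 1L], n = m@x
    ),
    vocabulary = vocab
  )
}

#' Read a gold-standard relatedness file
#'
#' Expects a TSV with three columns, `term1<TAB>term2<TAB>score`, one
#' human-judged pair per line. Pairs are unordered; a pair appearing
#' twice (in either order) is an error.
#'
#' @param path File path.
#' @return A tibble with columns `term1`, `term2`, `score`.
#' @export
read_gold <- function(path) {
  check_readable(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed gold line %d in %s", bad[1], path))
  }
  out <- tibble::tibble(
    term1 = vapply(parts, `[[`, character(1), 1),
    term2 = vapply(parts, `[[`, character(1), 2),
    score = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  )
  if (any(is.na(out$score))) {
    rlang::abort(sprintf(
      "non-numeric score on line %d in %s",
      which(is.na(out$score))[1], path
    ))
  }
  dup <- which(duplicated(pair_key(out$term1, out$term2)))
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate gold pair on line %d in %s", dup[1], path))
  }
  out
}

#' Read word2vec text-format embeddings
#'
#' Parses the standard text dialect: a header line `<count> <dim>`
#' followed by one `term v1 ... v<dim>` line per term (space-separated).
#' Rows whose value count disagrees with the header dimensionality are an
#' error.
#'
#' @param path File path.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path) {
  check_readable(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) rlang::abort("empty embeddings file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) {
    rlang::abort("embeddings header must be `<count> <dim>`")
  }
  dim <- as.integer(header[2])
  body <- lines[-1]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != dim + 1L)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "embedding row %d has %d values, expected %d",
      bad[1], lengths(parts)[bad[1]] - 1L, dim
    ))
  }
  terms <- vapply(parts, `[[`, character(1), 1)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  rownames(vals) <- terms
  embedding_table(vals)
}

#' Read and write labelled pair files
#'
#' Silver-standard labels as TSV: `start<TAB>target<TAB>{0,1}`. A pair
#' carrying both labels is an error; a non-binary label is an error.
#'
#' @param path File path.
#' @param labels A data frame with columns `term1`, `term2`, `label`.
#' @return `read_labels()` returns a tibble with columns `term1`,
#'   `term2`, `label` (logical); `write_labels()` returns `path`
#'   invisibly.
#' @export
read_labels <- function(path) {
  check_readable(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed label line %d in %s", bad[1], path))
  }
  raw <- vapply(parts, `[[`, character(1), 3)
  if (!all(raw %in% c("0", "1"))) {
    rlang::abort(sprintf(
      "non-binary label on line %d in %s",
      which(!raw %in% c("0", "1"))[1], path
    ))
  }
  out <- tibble::tibble(
    term1 = vapply(parts, `[[`, character(1), 1),
    term2 = vapply(parts, `[[`, character(1), 2),
    label = raw == "1"
  )
  key <- paste0(out$term1, "\r", out$term2)
  conflict <- unique(key[duplicated(key)])
  for (k in conflict) {
    if (length(unique(out$label[key == k])) > 1) {
      rlang::abort(sprintf("pair labelled both true and false in %s", path))
    }
  }
  out[!duplicated(key), , drop = FALSE]
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  writeLines(
    sprintf("%s\t%s\t%d", labels$term1, labels$term2, as.integer(labels$label)),
    path
  )
  invisible(path)
}

#' Write a PR or ROC curve as TSV
#'
#' One point per rank: `rank<TAB>recall<TAB>precision` for PR curves, or
#' `rank<TAB>fpr<TAB>tpr` for ROC curves, preceded by a comment line with
#' the AUC.
#'
#' @param curve A `lbd_pr_curve` or `lbd_roc_curve`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  pts <- curve$points
  header <- sprintf("# auc\t%.10g", curve$auc)
  body <- sprintf("%d\t%.10g\t%.10g", pts$rank, pts[[2]], pts[[3]])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write scored pairs as TSV
#'
#' `term1<TAB>term2<TAB>score`, with `NA` for undefined scores.
#'
#' @param scored Output of [score_pairs()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scored, path) {
  score_txt <- ifelse(is.na(scored$score), "NA", sprintf("%.10g", scored$score))
  writeLines(sprintf("%s\t%s\t%s", scored$term1, scored$term2, score_txt), path)
  invisible(path)
}
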