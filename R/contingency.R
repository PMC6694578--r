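#' 2x2 contingency tables from four primitive cells
#'
#' Every association measure in the package reduces a term pair (or a
#' proxy-set pair) to four primitive numbers: the joint frequency `n11`,
#' the first-position marginal `n1p`, the second-position marginal `np1`,
#' and the grand total `npp`. All remaining cells follow by sums and
#' differences, and the expected cells `m_ij` follow from the marginals
#' under independence:
#'
#' \deqn{n_{12} = n_{1p} - n_{11},\quad n_{21} = n_{p1} - n_{11},\quad
#'       n_{22} = n_{pp} - n_{1p} - n_{p1} + n_{11}}
#' \deqn{m_{ij} = \mathrm{row}_i \cdot \mathrm{col}_j / n_{pp}}
#'
#' @param n11 Joint frequency (first term in first position, second term
#'   in second position).
#' @param n1p First-position marginal: total weight with the first term in
#'   first position.
#' @param np1 Second-position marginal.
#' @param npp Grand total of all pair counts.
#' @return An object of class `lbd_contingency`: a list with the four
#'   primitive cells, the derived cells `n12`, `n21`, `n22`, `n2p`, `np2`,
#'   and the expected cells `m11`, `m12`, `m21`, `m22`.
#' @examples
#' ct <- contingency_table(7, 14, 16, 30)
#' ct$n22
#' chi_squared(contingency_table(7, 14, 16, 100))
#' @export
contingency_table <- function(n11, n1p, np1, npp) {
  cells <- c(n11 = n11, n1p = n1p, np1 = np1, npp = npp)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    rlang::abort("contingency cells must be finite and non-negative")
  }
  if (n11 > n1p) rlang::abort("contingency constraint violated: n11 <= n1p")
  if (n11 > np1) rlang::abort("contingency constraint violated: n11 <= np1")
  if (n1p > npp) rlang::abort("contingency constraint violated: n1p <= npp")
  if (np1 > npp) rlang::abort("contingency constraint violated: np1 <= npp")
  n22 <- npp - n1p - np1 + n11
  if (n22 < 0) {
    rlang::abort("contingency constraint violated: n1p + np1 - n11 <= npp (n22 >= 0)")
  }
  n2p <- npp - n1p
  np2 <- npp - np1
  expected <- if (npp > 0) {
    c(
      m11 = n1p * np1 / npp, m12 = n1p * np2 / npp,
      m21 = np1 * n2p / npp, m22 = np2 * n2p / npp
    )
  } else {
    c(m11 = 0, m12 = 0, m21 = 0, m22 = 0)
  }
  structure(
    c(
      list(
        n11 = n11, n12 = n1p - n11, n21 = np1 - n11, n22 = n22,
        n1p = n1p, np1 = np1, n2p = n2p, np2 = np2, npp = npp
      ),
      as.list(expected)
    ),
    class = "lbd_contingency"
  )
}

#' @export
print.lbd_contingency <- function(x, ...) {
  cat("<lbd_contingency>\n")
  cat(sprintf("  observed: n11 %g  n12 %g | n1p %g\n", x$n11, x$n12, x$n1p))
  cat(sprintf("            n21 %g  n22 %g | n2p %g\n", x$n21, x$n22, x$n2p))
  cat(sprintf("  totals:   np1 %g  np2 %g | npp %g\n", x$np1, x$np2, x$npp))
  cat(sprintf(
    "  expected: m11 %.4g m12 %.4g m21 %.4g m22 %.4g\n",
    x$m11, x$m12, x$m21, x$m22
  ))
  invisible(x)
}

#' @rdname lbd_tidiers
#' @export
tidy.lbd_contingency <- function(x, ...) {
  tibble::tibble(
    cell = c("n11", "n12", "n21", "n22"),
    observed = c(x$n11, x$n12, x$n21, x$n22),
    expected = c(x$m11, x$m12, x$m21, x$m22)
  )
}

#' @rdname lbd_tidiers
#' @export
glance.lbd_contingency <- function(x, ...) {
  tibble::tibble(
    n11 = x$n11, n1p = x$n1p, np1 = x$np1, npp = x$npp,
    x2 = strip_reason(assoc_score(x, "x2")),
    dice = strip_reason(assoc_score(x, "dice")),
    ll = strip_reason(assoc_score(x, "ll"))
  )
}

strip_reason <- function(x) as.numeric(x)

# An undefined association score: NA with a machine-readable reason.
undefined_score <- function(reason) {
  structure(NA_real_, reason = reason, class = c("lbd_score", "numeric"))
}

defined_score <- function(value) {
  structure(as.numeric(value), reason = NA_character_, class = c("lbd_score", "numeric"))
}

#' Is an association score undefined?
#'
#' Degenerate inputs (an empty shared linking set, a zero marginal, a zero
#' expected cell) yield an undefined score rather than an error, so
#' ranking pipelines can drop or demote the pair. The reason travels with
#' the value.
#'
#' @param x A score returned by [assoc_score()] or [score_pairs()].
#' @return `TRUE` if the score is undefined.
#' @export
is_undefined <- function(x) {
  if (inherits(x, "lbd_undefined")) return(TRUE)
  is.na(as.numeric(x)[1])
}

#' @rdname is_undefined
#' @export
undefined_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

#' @export
print.lbd_score <- function(x, ...) {
  if (is.na(x)) {
    cat(sprintf("<undefined association score: %s>\n", attr(x, "reason")))
  } else {
    print(as.numeric(x))
  }
  invisible(x)
}

#' Pearson's chi-squared statistic of a contingency table
#'
#' \deqn{\chi^2 = \sum_{ij} (n_{ij} - m_{ij})^2 / m_{ij}}
#'
#' The statistic is returned unsigned (the standard Pearson form). With
#' `signed = TRUE` the value is negated when the observed joint cell falls
#' below its expectation (`n11 < m11`), which distinguishes positive from
#' negative association in rankings.
#'
#' If any expected cell `m_ij` is zero the statistic is undefined and an
#' NA score with a reason is returned (see [is_undefined()]); no
#' continuity correction is applied.
#'
#' @param table An [contingency_table()] object.
#' @param signed Negate when `n11 < m11`? Default `FALSE`.
#' @return A single numeric score (class `lbd_score`).
#' @export
chi_squared <- function(table, signed = FALSE) {
  stopifnot(inherits(table, "lbd_contingency"))
  m <- c(table$m11, table$m12, table$m21, table$m22)
  if (any(m <= 0)) {
    return(undefined_score("degenerate expected cell"))
  }
  n <- c(table$n11, table$n12, table$n21, table$n22)
  x2 <- sum((n - m)^2 / m)
  if (signed && table$n11 < table$m11) x2 <- -x2
  defined_score(x2)
}

# Registered association equations. Each takes an lbd_contingency and
# returns an lbd_score.
assoc_equations <- list(
  x2 = function(table) chi_squared(table),
  dice = function(table) {
    denom <- table$n1p + table$np1
    if (denom <= 0) return(undefined_score("zero marginal"))
    defined_score(2 * table$n11 / denom)
  },
  ll = function(table) {
    m <- c(table$m11, table$m12, table$m21, table$m22)
    if (any(m <= 0)) return(undefined_score("degenerate expected cell"))
    n <- c(table$n11, table$n12, table$n21, table$n22)
    terms <- ifelse(n == 0, 0, n * log(n / m))
    defined_score(2 * sum(terms))
  }
)

#' Evaluate an association equation on a contingency table
#'
#' Applies one of the registered association equations to a completed
#' table: `"x2"` (Pearson's chi-squared, the default used throughout the
#' package), `"dice"` (`2 n11 / (n1p + np1)`), or `"ll"` (log-likelihood
#' ratio, `2 sum n_ij log(n_ij / m_ij)` with `0 log 0` taken as 0).
#'
#' @inheritParams chi_squared
#' @param equation One of `"x2"`, `"dice"`, `"ll"`.
#' @return A single numeric score (class `lbd_score`); undefined on
#'   degenerate tables.
#' @examples
#' assoc_score(contingency_table(7, 14, 16, 100), "dice")
#' @export
assoc_score <- function(table, equation = "x2") {
  stopifnot(inherits(table, "lbd_contingency"))
  if (!is.character(equation) || length(equation) != 1 ||
      !equation %in% names(assoc_equations)) {
    rlang::abort(paste0(
      "unknown association equation; registered equations: ",
      paste(names(assoc_equations), collapse = ", ")
    ))
  }
  assoc_equations[[equation]](table)
}
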