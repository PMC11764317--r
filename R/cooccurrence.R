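# Exact 2x2 co-occurrence testing of two binary patient-level mutation
# statuses (e.g. APC DEL carriers vs PTCH1 ns-SNV carriers).

#' Build a 2x2 contingency table from two patient-status maps
#'
#' Fixed orientation: rows are status A (FALSE, TRUE), columns status B
#' (FALSE, TRUE), so `table[2, 2]` counts patients positive for both.
#'
#' @param status_a,status_b Named logical vectors over the same patient
#'   universe (names are patient ids).
#' @return 2x2 integer matrix with dimnames.
#' @export
build_2x2 <- function(status_a, status_b) {
  if (is.null(names(status_a)) || is.null(names(status_b)))
    stop("status vectors must be named by patient id")
  only <- c(setdiff(names(status_a), names(status_b)),
            setdiff(names(status_b), names(status_a)))
  if (length(only) > 0L)
    stop("patient(s) present in one status map only: ",
         paste(unique(only), collapse = ", "))
  b <- status_b[names(status_a)]
  tab <- matrix(c(sum(!status_a & !b), sum(!status_a & b),
                  sum(status_a & !b), sum(status_a & b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(a = c("FALSE", "TRUE"),
                                b = c("FALSE", "TRUE")))
  storage.mode(tab) <- "integer"
  tab
}

#' Exact (or chi-square) test of a 2x2 table
#'
#' Two-sided Fisher exact test with the probability-ordering definition: the
#' p-value sums the hypergeometric probabilities of every table with the
#' observed margins whose probability does not exceed the observed table's
#' (relative tolerance 1e-7 on the comparison).  Probabilities come from
#' [stats::dhyper()] evaluated in log space.  `method = "chisq"` instead
#' returns Pearson's chi-square p without continuity correction.
#' The odds ratio is the sample ratio `ad/bc` (`Inf` when `bc = 0` and
#' `ad > 0`; `NaN` when a whole margin is 0).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return List of class `cooccurrence_test`: `table`, `odds_ratio`,
#'   `p_two_sided`, `method`.
#' @export
fisher_exact_2x2 <- function(table, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (!is.matrix(table) || !all(dim(table) == 2L))
    stop("table must be a 2x2 matrix")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  n <- sum(table)
  if (n == 0L) stop("table total must be positive")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  or <- (a * d) / (b * c_)           # 0/0 -> NaN, x/0 -> Inf as documented

  p <- if (method == "chisq") {
    suppressWarnings(stats::chisq.test(table, correct = FALSE)$p.value)
  } else {
    r1 <- a + b; c1 <- a + c_
    support <- max(0L, r1 + c1 - n):min(r1, c1)
    logp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
    log_obs <- stats::dhyper(a, c1, n - c1, r1, log = TRUE)
    sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  }
  structure(list(table = table, odds_ratio = or,
                 p_two_sided = min(p, 1), method = method),
            class = "cooccurrence_test")
}

#' @export
print.cooccurrence_test <- function(x, ...) {
  cat("2x2 co-occurrence test (", x$method, ")\n", sep = "")
  print(x$table)
  cat(sprintf("odds ratio = %.3g, two-sided p = %.4g\n",
              x$odds_ratio, x$p_two_sided))
  invisible(x)
}

#' Co-occurrence of two gene-level mutation statuses
#'
#' Convenience wrapper: takes patient-status maps (or columns of a
#' `gene_del_matrix`), builds the 2x2 table and tests it.
#'
#' @param status_a,status_b Named logical vectors, or a `gene_del_matrix`
#'   plus gene name via `gene_a`/`gene_b`.
#' @param method Passed to [fisher_exact_2x2()].
#' @return `cooccurrence_test` object.
#' @export
cooccurrence_test <- function(status_a, status_b,
                              method = c("fisher", "chisq")) {
  fisher_exact_2x2(build_2x2(status_a, status_b), method = method)
}
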