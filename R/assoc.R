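#' Midranks of a numeric vector
#'
#' Ranks with tied values receiving the mean of the rank positions they span,
#' so that the ranks always sum to n(n+1)/2.
#'
#' @param values numeric vector, all finite.
#' @return numeric vector of midranks.
#' @export
midranks <- function(values) {
  if (length(values) == 0) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite input")
  rank(values, ties.method = "average")
}

#' Tie-corrected Spearman rank correlation
#'
#' Computes the Spearman coefficient r_s as the Pearson correlation of the
#' midranks of `x` and `y`, which handles ties exactly. The default p-value
#' uses the t approximation t = r_s * sqrt((n-2)/(1-r_s^2)) on n-2 degrees of
#' freedom, two-sided. If `permutations` is given, an additional permutation
#' p-value is computed by shuffling `y` against `x`:
#' p = (b + 1)/(m + 1) where b counts permutations with |r| at least the
#' observed |r| (the add-one rule keeps p positive).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param permutations optional number of random permutations.
#' @param seed optional integer seed for the permutation draw (recorded in
#'   the result).
#' @return an object of class `"spearman_result"`: list with `r_s`, `n`,
#'   `p_t`, and when requested `p_perm` and `seed`.
#' @export
#' @examples
#' spearman_cor(c(12, 12, 13, 13, 14, 14, 15, 17),
#'              c(13.8, 3.6, 10.3, 4.7, 12.1, 14.9, 14.8, 24.6))
spearman_cor <- function(x, y, permutations = NULL, seed = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  rx <- midranks(x)
  ry <- midranks(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance: r_s undefined")
  }
  r_s <- stats::cor(rx, ry)
  tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
  p_t <- if (abs(r_s) >= 1) {
    .Machine$double.xmin  # degenerate perfect correlation
  } else {
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- list(r_s = r_s, n = n, p_t = min(p_t, 1))
  if (!is.null(permutations)) {
    m <- as.integer(permutations)
    if (m < 1) stop("permutations must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    rxc <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    ryc <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    perm_r <- vapply(seq_len(m),
                     function(i) sum(rxc * ryc[sample.int(n)]),
                     numeric(1))
    b <- sum(abs(perm_r) >= abs(r_s) - 1e-12)
    out$p_perm <- (b + 1) / (m + 1)
    out$seed <- seed
  }
  class(out) <- "spearman_result"
  out
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r_s = %.4f (n = %d), p_t = %.4g\n",
              x$r_s, x$n, x$p_t))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  }
  invisible(x)
}

#' G-test of independence
#'
#' Log-likelihood-ratio test for an r x c contingency table of counts:
#' G = 2 * sum O * ln(O/E) over cells with O > 0, with expected counts E from
#' the independence model, compared to the chi-square distribution with
#' (r-1)(c-1) degrees of freedom. The optional Williams correction divides G
#' by q = 1 + (N * sum(1/rowsums) - 1) * (N * sum(1/colsums) - 1) / (6 N df).
#'
#' @param table matrix of nonnegative integer counts, at least 2 x 2, with
#'   all row and column margins positive.
#' @param williams apply the Williams small-sample correction (off by
#'   default).
#' @return an object of class `"g_test_result"`: list with `G`, `df`, `p`,
#'   `williams_corrected`.
#' @export
#' @examples
#' g_test(matrix(c(150, 25, 110, 76), 2, 2, byrow = TRUE))
g_test <- function(table, williams = FALSE) {
  O <- as.matrix(table)
  if (nrow(O) < 2 || ncol(O) < 2) stop("table must be at least 2 x 2")
  if (any(O < 0) || any(O != round(O))) stop("counts must be nonnegative integers")
  rs <- rowSums(O)
  cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  N <- sum(O)
  E <- outer(rs, cs) / N
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  G <- max(G, 0)  # guard tiny negative rounding on exact independence
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  if (williams) {
    q <- 1 + (N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1) / (6 * N * df)
    G <- G / q
  }
  structure(list(G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE),
                 williams_corrected = williams),
            class = "g_test_result")
}

#' @export
print.g_test_result <- function(x, ...) {
  cat(sprintf("G-test of independence: G = %.4g%s, df = %d, p = %.4g\n",
              x$G, if (x$williams_corrected) " (Williams-corrected)" else "",
              x$df, x$p))
  invisible(x)
}
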