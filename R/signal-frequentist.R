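# Frequentist disproportionality statistics on 2x2 contingency tables.
#
# Table convention: a = target reports with the event, b = target without,
# c = comparator with, d = comparator without; N = a + b + c + d.

.cells <- function(t) {
  if (is.data.frame(t) || is.list(t)) {
    lapply(t[c("a", "b", "c", "d")], as.numeric)
  } else if (is.numeric(t) && length(t) == 4) {
    as.list(stats::setNames(as.numeric(t), c("a", "b", "c", "d")))
  } else stop("expected a table with cells a, b, c, d")
}

# Haldane-Anscombe: add 0.5 to all four cells, only for tables with a zero
# cell (raw counts untouched otherwise so nonzero tables are unbiased)
.continuity <- function(a, b, c, d) {
  z <- (a == 0 | b == 0 | c == 0 | d == 0) * 0.5
  list(a = a + z, b = b + z, c = c + z, d = d + z)
}

#' Reporting odds ratio with log-normal 95% interval
#'
#' ROR = ad / (bc) with
#' CI95 = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' Tables with any zero cell are continuity-corrected by adding 0.5 to all
#' four cells. A table with an all-zero margin is undefined and returns NA
#' (reason in the \code{"reason"} attribute).
#'
#' @param t a 2x2 table: numeric (a, b, c, d), or a list/data.frame with
#'   columns a, b, c, d (vectorized).
#' @return data.frame(ror, ror_lo95, ror_hi95).
#' @examples
#' rorStat(c(25, 75, 100, 900))
#' @export
rorStat <- function(t) {
  cc <- .cells(t)
  bad <- (cc$a + cc$b == 0) | (cc$c + cc$d == 0) |
    (cc$a + cc$c == 0) | (cc$b + cc$d == 0)
  k <- .continuity(cc$a, cc$b, cc$c, cc$d)
  ror <- (k$a * k$d) / (k$b * k$c)
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  out <- data.frame(ror = ror,
                    ror_lo95 = exp(log(ror) - 1.96 * se),
                    ror_hi95 = exp(log(ror) + 1.96 * se))
  if (any(bad)) {
    out[bad, ] <- NA_real_
    attr(out, "reason") <- "all-zero margin: ROR undefined"
  }
  out
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' PRR = [a/(a+b)] / [c/(c+d)]; the chi-square statistic is Pearson's on
#' the 2x2 table with 1 df and no Yates correction, and \code{p_raw} is its
#' upper tail. Zero-cell tables are continuity-corrected as in [rorStat()].
#'
#' @inheritParams rorStat
#' @return data.frame(prr, chi2, p_raw).
#' @examples
#' prrStat(c(25, 75, 100, 900))
#' @export
prrStat <- function(t) {
  cc <- .cells(t)
  bad <- (cc$a + cc$b == 0) | (cc$c + cc$d == 0)
  k <- .continuity(cc$a, cc$b, cc$c, cc$d)
  prr <- (k$a / (k$a + k$b)) / (k$c / (k$c + k$d))
  N <- k$a + k$b + k$c + k$d
  chi2 <- N * (k$a * k$d - k$b * k$c)^2 /
    ((k$a + k$b) * (k$c + k$d) * (k$a + k$c) * (k$b + k$d))
  out <- data.frame(prr = prr, chi2 = chi2,
                    p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  if (any(bad)) {
    out[bad, ] <- NA_real_
    attr(out, "reason") <- "empty row margin: PRR undefined"
  }
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment with enforced monotonicity; the mapping back
#' to the input order is preserved (ties broken by stable input order have
#' no effect on the adjusted values). Adjusted values are elementwise >=
#' the raw ones and the procedure is idempotent.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
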