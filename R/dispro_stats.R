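# Disproportionality statistics on a 2x2 report-count table.
#
# Layout:                 event   no event
#        exposed            a        b
#        comparator         c        d
#
# PRR = (a/(a+b)) / (c/(c+d)), the ratio of event-reporting proportions.
# The 95% CI is the Wald interval on the log scale with
# SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)).

#' Construct a 2x2 contingency table of report counts
#'
#' @param a exposed reports containing the event.
#' @param b exposed reports without the event.
#' @param c comparator reports containing the event.
#' @param d comparator reports without the event.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("all cells must be non-negative integers")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "comparator"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Event-reporting rate per 1000 reports
#'
#' @param events number of reports containing the event.
#' @param total total reports in the group.
#' @return `1000 * events / total`.
#' @export
rate_per_1000 <- function(events, total) {
  if (any(total <= 0)) stop("total must be > 0")
  1000 * events / total
}

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, no continuity correction by default (enable the
#' Yates correction with `correct = TRUE`). All margins must be positive.
#'
#' @param t a [contingency_table()].
#' @param correct apply the Yates continuity correction.
#' @return list with elements `chi2` and `p_value`.
#' @export
chi_square <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: a table margin is zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Strict significance flag
#'
#' @param p p-value in \[0, 1\].
#' @param alpha significance level.
#' @return `TRUE` iff `p < alpha` (strict inequality).
#' @export
significance_flag <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  !is.na(p) & p < alpha
}

#' Proportional reporting ratio with confidence interval
#'
#' Computes the PRR, its Wald confidence interval on the log scale,
#' event-reporting rates per 1000 reports in each group, and the Pearson
#' chi-square test. When the event count is zero in either group the
#' Haldane–Anscombe correction (add 0.5 to all four cells) is applied to the
#' PRR and CI and flagged in the result; the chi-square test always uses the
#' raw counts.
#'
#' @param t a [contingency_table()].
#' @param z normal quantile for the interval (default `1.959964`, the 95%
#'   two-sided level).
#' @param alpha significance level for the `significant` flag.
#' @param correct Yates continuity correction for the chi-square component.
#' @return an object of class `dispro_result`: a list with `prr`, `ci_low`,
#'   `ci_high`, `rate_exposed_per_1000`, `rate_comparator_per_1000`, `chi2`,
#'   `p_value`, `significant`, `zero_cell_corrected`, and the input counts.
#' @examples
#' compute_prr(contingency_table(295, 61803, 5565, 636466))
#' @export
compute_prr <- function(t, z = 1.959964, alpha = 0.05, correct = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (a + b == 0 || cc + d == 0)
    stop("undefined cohort: a group has zero reports")
  corrected <- FALSE
  a2 <- a; b2 <- b; c2 <- cc; d2 <- d
  if (a == 0 || cc == 0) {
    a2 <- a + 0.5; b2 <- b + 0.5; c2 <- cc + 0.5; d2 <- d + 0.5
    corrected <- TRUE
  }
  prr <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  se  <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  ci_low  <- exp(log(prr) - z * se)
  ci_high <- exp(log(prr) + z * se)
  chi <- if (a + b > 0 && cc + d > 0 && a + cc > 0 && b + d > 0) {
    chi_square(t, correct = correct)
  } else {
    list(chi2 = NA_real_, p_value = NA_real_)
  }
  structure(
    list(prr = prr, ci_low = ci_low, ci_high = ci_high,
         rate_exposed_per_1000 = rate_per_1000(a, a + b),
         rate_comparator_per_1000 = rate_per_1000(cc, cc + d),
         chi2 = chi$chi2, p_value = chi$p_value,
         significant = if (is.na(chi$p_value)) NA else
           significance_flag(chi$p_value, alpha),
         zero_cell_corrected = corrected,
         a = a, b = b, c = cc, d = d),
    class = "dispro_result"
  )
}

#' @export
print.dispro_result <- function(x, ...) {
  cat(sprintf("PRR %.2f (95%% CI %.2f-%.2f)%s\n", x$prr, x$ci_low, x$ci_high,
              if (x$zero_cell_corrected) " [zero-cell corrected]" else ""))
  cat(sprintf("rates: %.1f vs %.1f per 1000 reports\n",
              x$rate_exposed_per_1000, x$rate_comparator_per_1000))
  if (!is.na(x$p_value)) {
    cat(sprintf("chi-square %.1f, p %s\n", x$chi2,
                if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  }
  invisible(x)
}

#' Flatten a dispro_result to a one-row data.frame
#' @param x a `dispro_result`.
#' @return one-row data.frame with the result fields as columns.
#' @export
as.data.frame.dispro_result <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, d = x$d,
             rate_exposed = x$rate_exposed_per_1000,
             rate_comparator = x$rate_comparator_per_1000,
             prr = x$prr, ci_low = x$ci_low, ci_high = x$ci_high,
             chi2 = x$chi2, p_value = x$p_value,
             significant = x$significant,
             zero_cell_corrected = x$zero_cell_corrected)
}
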