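## Significance tests for single projected time series: Mann-Kendall for
## continuous series (dormancy release, bloom, last spring freeze) and
## the Cox-Lewis test for event series (blossom frost occurrences).

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test.  `S` is the sum of the signs of all
#' pairwise forward differences; its variance uses the tie correction,
#' and the normal approximation is applied with a continuity correction.
#' Two-sided p-value.
#'
#' @param x numeric series in time order (`n >= 4`); ties allowed
#' @return object of class `trend_test`: list with `statistic` (S),
#'   `z`, `p_value`, `n`
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 values")
  S <- 0L
  for (i in seq_len(n - 1L))
    S <- S + sum(sign(x[(i + 1L):n] - x[i]))
  ## variance with tie correction
  ties <- table(x)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  p <- if (varS == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = S, z = z, p_value = min(p, 1), n = n,
                 test = "Mann-Kendall"), class = "trend_test")
}

#' Cox-Lewis test for a trend in event occurrence
#'
#' Tests whether events (e.g. blossom-frost years) concentrate early or
#' late within a fixed observation period.  Event times are measured at
#' the year midpoint relative to the period start; under the no-trend
#' null the centred, scaled mean event time
#' `U = (mean(t) - L/2) / (L / sqrt(12 n))` is standard normal.
#' Two-sided p-value.
#'
#' @param event_years integer years in which the event occurred
#' @param period integer `c(first, last)` years of the observation period
#' @return object of class `trend_test`: list with `statistic` (U),
#'   `p_value`, `n`
#' @export
cox_lewis <- function(event_years, period) {
  L <- period[2L] - period[1L] + 1L
  ev <- event_years[event_years >= period[1L] & event_years <= period[2L]]
  n <- length(ev)
  if (n == 0L) {
    warning("no events in the period; reporting no trend")
    return(structure(list(statistic = NA_real_, p_value = 1, n = 0L,
                          test = "Cox-Lewis"), class = "trend_test"))
  }
  tmid <- ev - period[1L] + 0.5
  U <- (mean(tmid) - L / 2) / (L / sqrt(12 * n))
  structure(list(statistic = U, p_value = 2 * stats::pnorm(-abs(U)),
                 n = n, test = "Cox-Lewis"), class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(x$test, "test: statistic =", signif(x$statistic, 4),
      " p =", signif(x$p_value, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Per-grid-point significance mask
#'
#' Applies a trend test to each grid point's series and returns the
#' significance mask used to blank non-significant fields in maps.
#'
#' @param x data frame with grouping column `grid_id`, a `year` column
#'   and a `value` column
#' @param test `"mk"` (Mann-Kendall, on `value`) or `"coxlewis"` (on
#'   event years where `value` is a 0/1 event flag)
#' @param alpha significance level
#' @return data frame `grid_id`, `statistic`, `p_value`, `significant`
#' @export
trend_mask <- function(x, test = c("mk", "coxlewis"), alpha = 0.05) {
  test <- match.arg(test)
  groups <- split(x, x$grid_id)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]][order(groups[[g]]$year), ]
    tt <- if (test == "mk") mann_kendall(d$value)
          else cox_lewis(d$year[d$value > 0], range(d$year))
    data.frame(grid_id = g, statistic = tt$statistic,
               p_value = tt$p_value,
               significant = tt$p_value < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
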