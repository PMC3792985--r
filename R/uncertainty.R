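## Partitioning of projection variance into internal variability, climate
## run and impact model components, weighted climate-impact signal,
## fractional uncertainty and time of emergence (Hawkins-Sutton-style
## decomposition applied to a single emission scenario).

#' Smooth an annual signal and separate internal variability
#'
#' Each (run, model) area-mean series is smoothed with a 10-year centred
#' moving average and then approximated by a 4th-order polynomial trend.
#' The residual variance about the trends, pooled over all members, is
#' the (time-constant) internal variability.
#'
#' @param x data frame `year`, `run`, `model`, `value` (annual area
#'   means, typically expressed as change from a reference mean)
#' @param ma_width moving-average width in years
#' @param degree polynomial degree of the trend fit
#' @return list with `fits` (data frame `year`, `run`, `model`, `fit`),
#'   `V` (pooled residual variance), `residuals`
#' @export
smooth_signal <- function(x, ma_width = 10L, degree = 4L) {
  stopifnot(all(c("year", "run", "model", "value") %in% names(x)))
  groups <- split(x, x[c("run", "model")], drop = TRUE)
  if (any(vapply(groups, nrow, integer(1L)) < 40L))
    stop("each (run, model) series needs at least 40 annual values")
  res <- lapply(groups, function(d) {
    d <- d[order(d$year), ]
    sm <- moving_average(d$value, ma_width)
    ok <- !is.na(sm)
    yc <- d$year - mean(d$year)
    fit <- stats::lm(sm[ok] ~ poly(yc[ok], degree, raw = TRUE))
    data.frame(year = d$year[ok], run = d$run[ok], model = d$model[ok],
               fit = unname(stats::fitted(fit)),
               resid = unname(stats::residuals(fit)))
  })
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  list(fits = all[c("year", "run", "model", "fit")],
       V = mean(all$resid^2),
       residuals = all$resid)
}

#' Partition projection variance
#'
#' Splits total projection variance at each year into internal
#' variability `V` (time-constant, from [smooth_signal()]), climate-run
#' variance `M(t)` (mean over impact models of the across-run variance of
#' the trend fits) and impact-model variance `I(t)` (weighted variance
#' across impact models of the run-mean fits).  Variances use population
#' (1/n) normalisation.  Fractions of the total sum to one at every year.
#'
#' @param fits data frame `year`, `run`, `model`, `fit` (from
#'   [smooth_signal()])
#' @param V internal variability
#' @param weights named numeric vector of impact-model weights (see
#'   [model_error_weights()]); equal weights when `NULL`
#' @return object of class `uncertainty_decomposition`: data frame
#'   `year`, `V`, `M`, `I`, `Ttot`, `fracV`, `fracM`, `fracI`
#' @export
partition_variance <- function(fits, V, weights = NULL) {
  models <- sort(unique(fits$model))
  runs <- sort(unique(fits$run))
  if (length(runs) < 2L && length(models) < 2L)
    warning("single run and single impact model: M = I = 0")
  if (is.null(weights))
    weights <- stats::setNames(rep(1 / length(models), length(models)),
                               models)
  weights <- weights[as.character(models)] / sum(weights[as.character(models)])
  years <- sort(unique(fits$year))
  ## fit array [year, run, model]
  arr <- array(NA_real_, c(length(years), length(runs), length(models)),
               dimnames = list(years, runs, models))
  idx <- cbind(match(fits$year, years), match(fits$run, runs),
               match(fits$model, models))
  arr[idx] <- fits$fit
  M <- I <- numeric(length(years))
  for (t in seq_along(years)) {
    by_model_var <- apply(arr[t, , , drop = FALSE], 3L,
                          function(v) pop_var(as.numeric(v)))
    M[t] <- sum(weights * by_model_var)
    run_means <- apply(arr[t, , , drop = FALSE], 3L,
                       function(v) mean(as.numeric(v)))
    I[t] <- pop_var_weighted(run_means, weights)
  }
  Ttot <- V + M + I
  out <- data.frame(year = years, V = V, M = M, I = I, Ttot = Ttot,
                    fracV = V / Ttot, fracM = M / Ttot, fracI = I / Ttot)
  class(out) <- c("uncertainty_decomposition", "data.frame")
  out
}

#' Impact-model weights from model errors
#'
#' Weights inversely proportional to each impact model's error (e.g. its
#' PRMSE), normalised to sum to one.  An error floor (default 0.1 d)
#' prevents an infinite weight for a zero error.
#'
#' @param errors named numeric vector of per-model errors
#' @param floor minimum error before inversion
#' @return named weights summing to one
#' @export
model_error_weights <- function(errors, floor = 0.1) {
  w <- 1 / pmax(errors, floor)
  w / sum(w)
}

#' Weighted mean climate-impact signal
#'
#' `G(t) = sum_i w_i * mean_s change_{i,s}(t)`: the across-run mean change
#' per impact model, combined with error-derived weights.
#'
#' @param fits data frame `year`, `run`, `model`, `fit` of changes
#'   relative to the reference epoch
#' @param weights named weights per model (see [model_error_weights()]);
#'   equal when `NULL`
#' @return data frame `year`, `G`
#' @export
weighted_mean_signal <- function(fits, weights = NULL) {
  models <- sort(unique(fits$model))
  if (is.null(weights))
    weights <- stats::setNames(rep(1 / length(models), length(models)),
                               models)
  weights <- weights[as.character(models)] / sum(weights[as.character(models)])
  years <- sort(unique(fits$year))
  G <- numeric(length(years))
  for (t in seq_along(years)) {
    d <- fits[fits$year == years[t], ]
    run_means <- tapply(d$fit, d$model, mean)
    G[t] <- sum(weights * run_means[as.character(models)])
  }
  data.frame(year = years, G = G)
}

#' Fractional uncertainty
#'
#' `F(t) = lambda * sqrt(Ttot(t)) / |G(t)|`, the inverse signal-to-noise
#' ratio at confidence multiplier `lambda` (0.674 for the 50% percentile,
#' 1 for 68.3%, 1.645 for 90%).  Years with a zero signal give `Inf`.
#'
#' @param G data frame `year`, `G` (see [weighted_mean_signal()])
#' @param Ttot data frame `year`, `Ttot` (see [partition_variance()]), or
#'   a numeric vector aligned with `G$year`
#' @param lambda confidence multiplier(s)
#' @return data frame `year`, one column `F_<lambda>` per lambda
#' @export
fractional_uncertainty <- function(G, Ttot, lambda = 1) {
  tt <- if (is.data.frame(Ttot)) Ttot$Ttot[match(G$year, Ttot$year)]
        else rep_len(Ttot, nrow(G))
  out <- data.frame(year = G$year)
  for (l in lambda) {
    f <- l * sqrt(tt) / abs(G$G)
    f[G$G == 0] <- Inf
    out[[paste0("F_", l)]] <- f
  }
  out
}

#' Time of emergence
#'
#' First year at which the fractional uncertainty drops to or below the
#' threshold and stays there for at least `persistence` consecutive
#' years, i.e. the projected change exceeds the projection noise.  Also
#' reports the year of minimum fractional uncertainty.
#'
#' @param F_df data frame `year` plus one fractional-uncertainty column
#'   (the first non-year column is used unless `col` is given)
#' @param threshold emergence threshold (default 1)
#' @param persistence consecutive years required at or below the
#'   threshold
#' @param col column name
#' @param after ignore years at or before this year (typically the end
#'   of the reference epoch, where the change is zero by construction)
#' @return list `emergence` (year or `NA`), `argmin` (year of minimum F)
#' @export
time_of_emergence <- function(F_df, threshold = 1, persistence = 5L,
                              col = NULL, after = NULL) {
  if (!is.null(after)) F_df <- F_df[F_df$year > after, , drop = FALSE]
  if (is.null(col)) col <- setdiff(names(F_df), "year")[1L]
  f <- F_df[[col]]
  yrs <- F_df$year
  below <- is.finite(f) & f <= threshold
  emergence <- NA_integer_
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= persistence)
  ## the run must persist to the end of the series or >= persistence years
  if (length(ok)) emergence <- yrs[starts[ok[1L]]]
  argmin <- yrs[which.min(ifelse(is.finite(f), f, Inf))]
  list(emergence = emergence, argmin = argmin)
}
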