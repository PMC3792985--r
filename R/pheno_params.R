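## Parameter sets for the seven phenological models.
##
## Model registry (integer ids):
##   1  thermal time                        (forcing from fixed t1 = Jan 1)
##   2  sequential chilling-forcing
##   3  parallel chilling-forcing
##   4  modified Utah chilling + fixed forcing threshold
##   5  thermal time with day-length factor (forcing from calibrated t1)
##   6  model 2 with day-length factor
##   7  model 3 with day-length factor
##
## Fields per model (presence follows the registry exactly):
##   Tbf   base temperature for forcing [deg C], all models
##   Tbc   base temperature for chilling [deg C], models 2-4, 6-7
##   Fcrit forcing threshold, models 1, 4, 5 (models 2/3/6/7 derive it
##         from the chilling state as a * exp(b * Sc))
##   Ccrit chilling threshold, models 2-4, 6-7
##   a, b  exponential chilling-forcing link, models 2, 3, 6, 7
##   c     day-length exponent (>= 0), models 5-7
##   t0    chilling start DOY, fixed at 213 (Aug 1)
##   t1    forcing start DOY, models 1 (fixed, Jan 1) and 5 (calibrated;
##         DOY >= 213 lies in the autumn of the season)

.model_fields <- list(
  `1` = c("Tbf", "Fcrit", "t1"),
  `2` = c("Tbf", "Tbc", "Ccrit", "a", "b"),
  `3` = c("Tbf", "Tbc", "Ccrit", "a", "b"),
  `4` = c("Tbf", "Tbc", "Ccrit", "Fcrit"),
  `5` = c("Tbf", "Fcrit", "c", "t1"),
  `6` = c("Tbf", "Tbc", "Ccrit", "a", "b", "c"),
  `7` = c("Tbf", "Tbc", "Ccrit", "a", "b", "c")
)

.model_types <- c("thermal time", "sequential chilling-forcing",
                  "parallel chilling-forcing", "modified Utah",
                  "thermal time + day length",
                  "sequential chilling-forcing + day length",
                  "parallel chilling-forcing + day length")

#' Which models use a chilling phase
#' @param model integer model id, 1-7
#' @return logical
#' @export
model_uses_chilling <- function(model) model %in% c(2L, 3L, 4L, 6L, 7L)

#' Construct a phenological parameter set
#'
#' Validates that exactly the fields the model admits are supplied and that
#' base temperatures lie inside the calibration bounds of 0-10 degrees C.
#'
#' @param model integer model id, 1-7 (see [model_uses_chilling()] and the
#'   registry in the package vignette)
#' @param ... named numeric parameters for the model
#' @return an object of class `pheno_params`
#' @examples
#' pheno_params(2, Tbf = 4, Tbc = 7, Ccrit = 90, a = 170, b = -0.01)
#' @export
pheno_params <- function(model, ...) {
  model <- as.integer(model)
  stopifnot(length(model) == 1L, model >= 1L, model <= 7L)
  p <- list(...)
  need <- .model_fields[[as.character(model)]]
  if (model == 1L && is.null(p$t1)) p$t1 <- 1  # fixed January 1 start
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("model ", model, " requires parameter(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(p), need)
  if (length(extra))
    stop("model ", model, " does not use parameter(s): ",
         paste(extra, collapse = ", "))
  if (model == 1L && p$t1 != 1)
    stop("model 1 uses a fixed forcing start of January 1 (t1 = 1)")
  if (p$Tbf < 0 || p$Tbf > 10)
    stop("Tbf must lie in [0, 10] degrees C")
  if (!is.null(p$Tbc) && (p$Tbc < 0 || p$Tbc > 10))
    stop("Tbc must lie in [0, 10] degrees C")
  if (!is.null(p$Fcrit) && p$Fcrit <= 0) stop("Fcrit must be positive")
  if (!is.null(p$Ccrit) && p$Ccrit <= 0) stop("Ccrit must be positive")
  if (!is.null(p$c) && p$c < 0) stop("day-length exponent c must be >= 0")
  structure(c(list(model = model), p[need]), class = "pheno_params")
}

#' @export
print.pheno_params <- function(x, ...) {
  cat("Phenological model ", x$model, " (", .model_types[x$model], ")\n",
      sep = "")
  flds <- setdiff(names(x), "model")
  cat(paste0("  ", flds, " = ", signif(unlist(x[flds]), 5)), sep = "\n")
  invisible(x)
}

#' Reference apple parameter sets
#'
#' Plausible parameterisations for apple bloom in a north-German maritime
#' climate (bloom around late April), one per model.  They serve as defaults
#' for the projection demos and as the generating truth of the synthetic
#' phenology fixtures; real applications should calibrate with [pheno_fit()].
#'
#' @param model integer model id, 1-7
#' @return a [pheno_params()] object
#' @export
default_pheno_params <- function(model) {
  model <- as.integer(model)
  switch(model,
    pheno_params(1, Tbf = 5, Fcrit = 145),
    pheno_params(2, Tbf = 4, Tbc = 7, Ccrit = 70, a = 400, b = -0.01),
    pheno_params(3, Tbf = 4, Tbc = 7, Ccrit = 70, a = 800, b = -0.01),
    pheno_params(4, Tbf = 4, Tbc = 7, Ccrit = 70, Fcrit = 210),
    pheno_params(5, Tbf = 4, Fcrit = 210, c = 2, t1 = 1),
    pheno_params(6, Tbf = 4, Tbc = 7, Ccrit = 70, a = 448, b = -0.01,
                 c = 0.8),
    pheno_params(7, Tbf = 4, Tbc = 7, Ccrit = 70, a = 896, b = -0.01,
                 c = 0.8),
    stop("model must be 1-7"))
}
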