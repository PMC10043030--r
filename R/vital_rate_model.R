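#' Vital-rate model container
#'
#' Bundles all fitted (or ground-truth) vital-rate parameter sets into the
#' object the kernel builders consume. All coefficient vectors follow the
#' layout `(intercept, z, z^2, c)` on the link scale and apply to
#' standardized size `z` and canopy `c`. Year effects are fixed intercept
#' offsets (first year 0); evaluators average predictions over years with
#' equal weight on the response scale, so the kernels describe a
#' time-invariant average year. Site random effects are marginalized at
#' zero (population-level prediction).
#'
#' @param survival list `coef` (logit scale), `year_offsets`.
#' @param growth list `coef` (mean of `z'`), `sd` (residual SD on the
#'   standardized scale), `year_offsets`.
#' @param breakage list `coef` (logit, intercept and size only).
#' @param resprout list `mean` and `logvar`, each `(intercept, z, z^2)`.
#' @param repro list `coef` (logit), `year_offsets`.
#' @param fruits list `coef` (log scale), `olre_sd` (SD of the lognormal
#'   observation-level effect; the marginal mean multiplies by
#'   `exp(olre_sd^2 / 2)`), `year_offsets`.
#' @param recruit scalar per-seed first-year seedling probability.
#' @param constants list: `f_seed` (mean seeds per fruit), `f_recfruit`
#'   (within-fruit germination multiplier for seeds not freed from the
#'   pulp by gut passage), `seedling` (truncated-normal seedling diameter
#'   distribution in cm: mean, sd, lower bound).
#' @return An object of class `vital_rate_model`.
#' @export
vital_rate_model <- function(survival, growth, breakage, resprout, repro,
                             fruits, recruit,
                             constants = list(
                               f_seed = 2, f_recfruit = 0.30,
                               seedling = c(mean = 0.767, sd = 0.269,
                                            lower = 0.380))) {
  pad4 <- function(x) c(x, rep(0, max(0, 4 - length(x))))[1:4]
  def_off <- function(l) if (is.null(l$year_offsets)) 0 else l$year_offsets
  vr <- list(
    survival = list(coef = pad4(survival$coef),
                    year_offsets = def_off(survival)),
    growth = list(coef = pad4(growth$coef), sd = growth$sd,
                  year_offsets = def_off(growth)),
    breakage = list(coef = pad4(breakage$coef)),
    resprout = list(mean = resprout$mean, logvar = resprout$logvar),
    repro = list(coef = pad4(repro$coef), year_offsets = def_off(repro)),
    fruits = list(coef = pad4(fruits$coef),
                  olre_sd = if (is.null(fruits$olre_sd)) 0 else fruits$olre_sd,
                  year_offsets = def_off(fruits)),
    recruit = recruit,
    constants = constants
  )
  stopifnot(vr$growth$sd > 0, recruit >= 0, recruit <= 1)
  class(vr) <- "vital_rate_model"
  vr
}

#' Build a vital-rate model directly from a ground truth
#'
#' Maps the generating parameters of a synthetic
#' [ground truth][default_ground_truth] onto a [vital_rate_model()], so
#' kernels can be built from known parameters without any fitting (useful
#' for oracle computations and for the frozen default parameter set).
#'
#' @param truth a `ground_truth` object.
#' @return A `vital_rate_model`.
#' @export
as_vital_rate_model <- function(truth) {
  validate_ground_truth(truth)
  vital_rate_model(
    survival = truth$survival,
    growth = truth$growth,
    breakage = truth$breakage,
    resprout = truth$resprout,
    repro = truth$repro,
    fruits = truth$fruits,
    recruit = truth$recruitment$p,
    constants = truth$constants
  )
}

# average an inverse-linked prediction over the study years
year_avg <- function(lp, offsets, invlink) {
  out <- 0
  for (o in offsets) out <- out + invlink(lp + o)
  out / length(offsets)
}

#' Evaluate vital-rate functions
#'
#' Population-level vital-rate predictions on the standardized state
#' scales, averaged over study years on the response scale.
#'
#' @param vr a [vital_rate_model()].
#' @param z,c standardized size and canopy (recycled).
#' @return Numeric vector of predictions.
#' @name vital-rate-evaluators
NULL

#' @rdname vital-rate-evaluators
#' @export
vr_survival <- function(vr, z, c = 0) {
  year_avg(link_lp(vr$survival$coef, z, c), vr$survival$year_offsets,
           stats::plogis)
}

#' @rdname vital-rate-evaluators
#' @export
vr_growth_mean <- function(vr, z, c = 0) {
  link_lp(vr$growth$coef, z, c) + mean(vr$growth$year_offsets)
}

#' @rdname vital-rate-evaluators
#' @export
vr_growth_sd <- function(vr) vr$growth$sd

#' @rdname vital-rate-evaluators
#' @export
vr_breakage <- function(vr, z) stats::plogis(link_lp(vr$breakage$coef, z))

#' @rdname vital-rate-evaluators
#' @export
vr_resprout_mean <- function(vr, z) {
  m <- vr$resprout$mean
  m[1] + m[2] * z + m[3] * z^2
}

#' @rdname vital-rate-evaluators
#' @export
vr_resprout_sd <- function(vr, z) {
  v <- vr$resprout$logvar
  exp(0.5 * (v[1] + v[2] * z + v[3] * z^2))
}

#' @rdname vital-rate-evaluators
#' @export
vr_repro <- function(vr, z, c = 0) {
  year_avg(link_lp(vr$repro$coef, z, c), vr$repro$year_offsets,
           stats::plogis)
}

#' @rdname vital-rate-evaluators
#' @export
vr_fruits <- function(vr, z, c = 0) {
  year_avg(link_lp(vr$fruits$coef, z, c), vr$fruits$year_offsets, exp) *
    exp(vr$fruits$olre_sd^2 / 2)
}

#' @export
print.vital_rate_model <- function(x, ...) {
  cat("Vital-rate model (standardized scales)\n")
  cat(sprintf("  survival logit: %s\n",
              paste(signif(x$survival$coef, 3), collapse = ", ")))
  cat(sprintf("  growth mean: %s (sd %.3f)\n",
              paste(signif(x$growth$coef, 3), collapse = ", "), x$growth$sd))
  cat(sprintf("  recruitment p = %.4f; seeds/fruit = %g; ",
              x$recruit, x$constants$f_seed))
  cat(sprintf("in-fruit multiplier = %.2f\n", x$constants$f_recfruit))
  invisible(x)
}
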