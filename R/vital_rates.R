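#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return The AICc value (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# attach standardized state columns to a census table
standardize_census <- function(records, grid) {
  records$z <- grid$std_size(records$diameter_t)
  records$z1 <- grid$std_size(records$diameter_t1)
  records$c <- grid$std_canopy(records$canopy)
  records$year <- factor(records$year)
  records$site <- factor(records$site)
  records
}

#' Flag abnormal growth transitions
#'
#' Fits the global growth model (size, size squared, canopy and year, on
#' the standardized log10-diameter scale) to all intact growth transitions
#' and flags records whose absolute studentized residual exceeds 2.24
#' times the standard deviation of the studentized residuals. Flagged
#' records are meant to be removed from all subsequent vital-rate fits;
#' in field data such transitions typically arise from tag loss and
#' misidentified individuals.
#'
#' @param records census table (see [generate_individuals()]).
#' @param grid an [ipm_grid][make_grid] supplying the standardization.
#' @return Integer vector of flagged record `id`s (possibly empty).
#' @export
detect_growth_outliers <- function(records, grid = make_grid()) {
  d <- standardize_census(records, grid)
  d <- d[d$survived == 1 & d$broke == 0 & !is.na(d$z1), ]
  if (nrow(d) < 10) stop("need at least 10 growth transitions")
  rhs <- "z + I(z^2) + c"
  if (nlevels(droplevels(d$year)) > 1) rhs <- paste(rhs, "+ year")
  fit <- stats::lm(stats::as.formula(paste("z1 ~", rhs)), data = d)
  if (nrow(d) <= length(stats::coef(fit)))
    stop("fewer growth records than growth-model parameters")
  if (stats::sd(stats::resid(fit)) < 1e-10) return(integer(0))
  rs <- stats::rstudent(fit)
  rs[!is.finite(rs)] <- 0
  s <- stats::sd(rs)
  if (!is.finite(s) || s == 0) return(integer(0))
  d$id[abs(rs) > 2.24 * s]
}

# the eight candidate model formulas: all subsets of the three
# main-effect blocks {year, size (z + z^2), canopy}
candidate_formulas <- function(response, random = "(1|site)",
                               include_year = TRUE) {
  blocks <- list(size = "z + I(z^2)", canopy = "c")
  if (include_year) blocks <- c(list(year = "year"), blocks)
  nb <- length(blocks)
  out <- character(0)
  for (m in 0:(2^nb - 1)) {
    terms <- unlist(blocks[bitwAnd(m, 2^(seq_len(nb) - 1)) > 0])
    rhs <- paste(c(if (length(terms)) terms else "1", random),
                 collapse = " + ")
    out <- c(out, paste(response, "~", rhs))
  }
  out
}

#' Fit a single vital-rate regression
#'
#' Thin wrapper around [glmmTMB::glmmTMB()] covering the four model
#' families used in the pipeline. Random intercepts (e.g. site) are
#' marginalized by Laplace approximation; the returned coefficients are
#' the population-level fixed effects. For `"poisson_olre"` an
#' observation-level random intercept captures extra-Poisson dispersion
#' (a Poisson-lognormal model); its SD is returned as `olre_sd`.
#'
#' @param records data frame with the model variables (use
#'   [standardize_census()]-style columns `z`, `c`, `year`, `site`).
#' @param formula model formula as a string or formula.
#' @param family one of `"binomial"`, `"gaussian"`, `"poisson_olre"`,
#'   `"betabinomial"`.
#' @return A list of class `vr_fit`: `coef` (named fixed effects),
#'   `loglik`, `k`, `n`, `aicc`, `sigma` (gaussian residual SD),
#'   `olre_sd`, `converged`, `formula`, `family`, and the fitted `model`.
#' @export
fit_vital_rate <- function(records,
                           formula,
                           family = c("binomial", "gaussian",
                                      "poisson_olre", "betabinomial")) {
  family <- match.arg(family)
  f <- if (is.character(formula)) stats::as.formula(formula) else formula
  fam <- switch(family,
                binomial = stats::binomial(),
                gaussian = stats::gaussian(),
                poisson_olre = stats::poisson(),
                betabinomial = glmmTMB::betabinomial())
  if (family == "poisson_olre") {
    records$.obs <- factor(seq_len(nrow(records)))
    f <- stats::update(f, . ~ . + (1 | .obs))
  }
  fit <- tryCatch(
    glmmTMB::glmmTMB(f, data = records, family = fam),
    error = function(e) e, warning = function(w) {
      suppressWarnings(glmmTMB::glmmTMB(f, data = records, family = fam))
    })
  if (inherits(fit, "error"))
    stop("vital-rate fit failed for '", deparse1(f), "': ",
         conditionMessage(fit))
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  conv <- isTRUE(fit$fit$convergence == 0) && !isTRUE(fit$sdr$pdHess == FALSE)
  if (!conv)
    warning("possible non-convergence for '", deparse1(f),
            "' (check separation or boundary estimates)")
  olre_sd <- NA_real_
  if (family == "poisson_olre") {
    vc <- glmmTMB::VarCorr(fit)$cond
    if (".obs" %in% names(vc)) olre_sd <- sqrt(as.numeric(vc[[".obs"]]))
  }
  vc <- tryCatch(stats::vcov(fit)$cond, error = function(e) NULL)
  structure(list(
    coef = glmmTMB::fixef(fit)$cond,
    se = if (!is.null(vc)) sqrt(diag(vc)) else NULL,
    loglik = as.numeric(ll), k = k, n = n,
    aicc = aicc(as.numeric(ll), k, n),
    sigma = if (family == "gaussian") stats::sigma(fit) else NA_real_,
    olre_sd = olre_sd,
    converged = conv, formula = deparse1(f), family = family,
    model = fit
  ), class = "vr_fit")
}

#' Select the most parsimonious model by AICc
#'
#' @param fits list of [vr_fit][fit_vital_rate] objects for one vital
#'   rate. The minimum-AICc model wins; exact ties are broken in favour of
#'   fewer parameters.
#' @return The winning `vr_fit`, with an `aicc_table` attribute ranking
#'   all candidates.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no candidate models supplied")
  tab <- data.frame(
    formula = vapply(fits, function(f) f$formula, ""),
    k = vapply(fits, function(f) f$k, 0),
    aicc = vapply(fits, function(f) f$aicc, 0)
  )
  ord <- order(tab$aicc, tab$k)
  best <- fits[[ord[1]]]
  attr(best, "aicc_table") <- tab[ord, ]
  best
}

#' Fit the re-sprout size model
#'
#' Gaussian model for the size of broken individuals after re-sprouting:
#' the mean is linear and quadratic in previous size and the log-variance
#' is likewise modelled as a function of size and size squared. With
#' fewer records than needed to estimate the variance function, the fit
#' falls back to a constant variance (with a warning).
#'
#' @param records data frame of re-sprout transitions with columns `z`
#'   (size before breakage) and `z1` (size after re-sprouting), both
#'   standardized.
#' @param min_records minimum number of transitions (default 8).
#' @return A list: `mean` (intercept, z, z^2), `logvar` (intercept, z,
#'   z^2 on the log-variance scale), `n`, and the fitted model.
#' @export
fit_resprout <- function(records, min_records = 8) {
  records <- records[!is.na(records$z1), ]
  if (nrow(records) < 3)
    stop("too few re-sprout transitions (", nrow(records),
         ") to fit any size model")
  if (stats::sd(records$z1) == 0)
    stop("degenerate re-sprout size distribution (all sizes identical)")
  small <- nrow(records) < min_records
  if (small)
    warning("only ", nrow(records), " re-sprout transitions (< ",
            min_records, "): falling back to constant variance")
  fit <- if (small) simpleError("sample too small") else tryCatch(
    glmmTMB::glmmTMB(z1 ~ z + I(z^2), dispformula = ~ z + I(z^2),
                     data = records),
    error = function(e) e)
  fallback <- inherits(fit, "error") ||
    !isTRUE(fit$fit$convergence == 0) || any(!is.finite(fit$fit$par))
  if (fallback) {
    if (!small)
      warning("size-dependent variance fit failed; ",
              "falling back to constant variance")
    fit <- glmmTMB::glmmTMB(z1 ~ z + I(z^2), data = records)
    logvar <- c(2 * log(stats::sigma(fit)), 0, 0)
  } else {
    # glmmTMB's gaussian dispersion predictor is on the log-SD scale
    logvar <- 2 * glmmTMB::fixef(fit)$disp
    logvar <- c(logvar, rep(0, 3 - length(logvar)))
  }
  mean_coef <- glmmTMB::fixef(fit)$cond
  mean_coef <- c(mean_coef, rep(0, 3 - length(mean_coef)))
  list(mean = unname(mean_coef), logvar = unname(logvar),
       n = nrow(records), model = fit)
}

#' Estimate per-seed first-year recruitment
#'
#' Fits a beta-binomial model (logit link) to sowing-experiment counts and
#' returns the marginal mean seedling probability. Canopy cover can be
#' included as a covariate but is off by default (recruitment was flat
#' along the canopy gradient in the system this package models).
#'
#' @param records recruitment table (see [generate_recruitment()]).
#' @param random random-effect term as a string, or `NULL`.
#' @param canopy include a canopy covariate?
#' @return List: `p` (mean per-seed seedling probability), `theta`
#'   (beta-binomial precision), `boundary` flag, and the model (or `NULL`
#'   at the boundary).
#' @export
estimate_recruitment <- function(records, random = "(1|site)",
                                 canopy = FALSE) {
  tot <- sum(records$seeds_sown)
  got <- sum(records$seedlings)
  if (got == 0) {
    warning("no seedlings recruited anywhere: recruitment at boundary 0")
    return(list(p = 0, theta = NA_real_, boundary = TRUE, model = NULL))
  }
  if (got == tot) {
    warning("every sown seed recruited: recruitment at boundary 1")
    return(list(p = 1, theta = NA_real_, boundary = TRUE, model = NULL))
  }
  rhs <- paste(c(if (canopy) "c" else "1", random), collapse = " + ")
  if (canopy) records$c <- as.numeric(scale(records$canopy))
  f <- paste("cbind(seedlings, seeds_sown - seedlings) ~", rhs)
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(stats::as.formula(f), data = records,
                                      family = glmmTMB::betabinomial())),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(glmmTMB::fixef(fit)$cond[[1]])) {
    warning("beta-binomial recruitment fit failed; using pooled proportion")
    return(list(p = got / tot, theta = NA_real_, boundary = FALSE,
                model = NULL))
  }
  list(p = unname(stats::plogis(glmmTMB::fixef(fit)$cond[[1]])),
       theta = glmmTMB::sigma(fit), boundary = FALSE, model = fit)
}

# map fitted fixed effects onto the (intercept, z, z2, c) layout plus
# per-year intercept offsets (treatment contrasts, first year = 0)
coef_layout <- function(cf) {
  pick <- function(nm) if (nm %in% names(cf)) unname(cf[[nm]]) else 0
  years <- grep("^year", names(cf), value = TRUE)
  list(coef = c(pick("(Intercept)"), pick("z"), pick("I(z^2)"), pick("c")),
       year_offsets = c(0, unname(cf[years])))
}

#' Fit all vital rates and package them for the IPM
#'
#' Runs the full statistical stage: standardizes the census table, removes
#' growth outliers ([detect_growth_outliers()]), fits each vital rate
#' (survival, growth, reproduction probability, fruit number) over the
#' eight-candidate model set and selects by AICc, fits breakage (size
#' only) and the re-sprout size model, and estimates recruitment from the
#' sowing experiment. Returns the population-level parameter set used to
#' build kernels.
#'
#' @param individuals census table.
#' @param recruitment sowing-experiment table.
#' @param grid an [ipm_grid][make_grid].
#' @param select if `FALSE`, fit only the global model for each rate
#'   (faster; used for bootstrap replicates and smoke runs).
#' @param random random-effect term for site, or `NULL` to drop it.
#' @param constants fixed constants: seeds per fruit, within-fruit
#'   germination multiplier, seedling size distribution (cm).
#' @return A [vital_rate_model()] with an attached `report` attribute
#'   (AICc tables, outlier ids, fit diagnostics).
#' @export
fit_vital_rates <- function(individuals, recruitment, grid = make_grid(),
                            select = TRUE, random = "(1|site)",
                            constants = list(
                              f_seed = 2, f_recfruit = 0.30,
                              seedling = c(mean = 0.767, sd = 0.269,
                                           lower = 0.380))) {
  d <- standardize_census(individuals, grid)
  outliers <- detect_growth_outliers(individuals, grid)
  d <- d[!(d$id %in% outliers), ]
  report <- list(outliers = outliers, aicc = list())

  fit_rate <- function(data, response, family) {
    forms <- candidate_formulas(response, random,
                                include_year = nlevels(droplevels(data$year)) > 1)
    if (!select) forms <- forms[length(forms)]  # global model only
    fits <- lapply(forms, function(f) fit_vital_rate(data, f, family))
    best <- select_model(fits)
    report$aicc[[response]] <<- attr(best, "aicc_table")
    best
  }

  surv <- fit_rate(d, "survived", "binomial")
  growth_d <- d[d$survived == 1 & d$broke == 0 & !is.na(d$z1), ]
  grow <- fit_rate(growth_d, "z1", "gaussian")
  alive <- d[d$survived == 1, ]
  brk <- fit_vital_rate(alive, paste("broke ~ z",
                                     if (!is.null(random)) paste("+", random)),
                        "binomial")
  resp_d <- d[d$survived == 1 & d$broke == 1 & !is.na(d$z1), ]
  resprout <- fit_resprout(resp_d)
  repro <- fit_rate(d, "reproductive", "binomial")
  fruit_d <- d[d$reproductive == 1, ]
  fruit_d$fruit_count <- as.integer(fruit_d$fruit_count)
  fruits <- fit_rate(fruit_d, "fruit_count", "poisson_olre")
  recruit <- estimate_recruitment(recruitment, random = random)

  sv <- coef_layout(surv$coef)
  gv <- coef_layout(grow$coef)
  rp <- coef_layout(repro$coef)
  fr <- coef_layout(fruits$coef)
  bk <- coef_layout(brk$coef)

  vr <- vital_rate_model(
    survival = list(coef = sv$coef, year_offsets = sv$year_offsets),
    growth = list(coef = gv$coef, sd = grow$sigma,
                  year_offsets = gv$year_offsets),
    breakage = list(coef = bk$coef[1:2]),
    resprout = list(mean = resprout$mean, logvar = resprout$logvar),
    repro = list(coef = rp$coef, year_offsets = rp$year_offsets),
    fruits = list(coef = fr$coef,
                  olre_sd = if (is.na(fruits$olre_sd)) 0 else fruits$olre_sd,
                  year_offsets = fr$year_offsets),
    recruit = recruit$p,
    constants = constants
  )
  report$fits <- list(survival = surv, growth = grow, breakage = brk,
                      resprout = resprout, repro = repro, fruits = fruits,
                      recruitment = recruit)
  attr(vr, "report") <- report
  vr
}
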