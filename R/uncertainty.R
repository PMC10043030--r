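#' Bootstrap specification
#'
#' @param B number of replicates (default 500).
#' @param level prediction-interval level in (0, 1) (default 0.95).
#' @param seed RNG seed.
#' @param components which data components are resampled: any of
#'   `"removals"`, `"scats"`, `"recruitment"` (dispersal uncertainty) and
#'   `"individuals"` (growth uncertainty; implies refitting the selected
#'   vital-rate models per replicate).
#' @return A list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(B = 500, level = 0.95, seed = 1L,
                           components = c("removals", "scats",
                                          "recruitment")) {
  stopifnot(B >= 2, level > 0, level <= 1)
  components <- match.arg(components,
                          c("removals", "scats", "recruitment",
                            "individuals"), several.ok = TRUE)
  structure(list(B = as.integer(B), level = level, seed = as.integer(seed),
                 components = components), class = "bootstrap_spec")
}

#' Empirical percentile interval
#'
#' Percentiles by linear interpolation between order statistics
#' (`stats::quantile()` type 7). The interval is not forced to bracket the
#' point estimate. `level = 1` returns the range.
#'
#' @param estimates numeric vector of bootstrap replicates.
#' @param level interval level in (0, 1\].
#' @return Named vector `c(lo, hi)`.
#' @export
percentile_interval <- function(estimates, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  q <- stats::quantile(estimates, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7, na.rm = TRUE)
  c(lo = q[1], hi = q[2])
}

# resample rows with replacement within strata, keeping per-stratum counts
# identical to the original data (guarantees every stratum stays present)
resample_within <- function(df, strata) {
  df[resample_index(split(seq_len(nrow(df)), strata)), , drop = FALSE]
}

resample_index <- function(split_idx) {
  unlist(lapply(split_idx, function(ix)
    ix[sample.int(length(ix), length(ix), replace = TRUE)]),
    use.names = FALSE)
}

#' Nonparametric bootstrap of the dispersal pipeline
#'
#' Resamples the input tables with replacement within strata — removal
#' observations and scats within species (so every disperser species is
#' present in each replicate, with replicate counts matching the original
#' per-stratum counts), recruitment records within site, and optionally
#' census individuals within site-by-year — recomputes the estimators on
#' each replicate, and evaluates a user statistic. Model *forms* are held
#' fixed: estimators are re-estimated per replicate but no model selection
#' is repeated.
#'
#' @param data list with elements `removals`, `scats`, `recruitment` (and
#'   `individuals` if resampled).
#' @param statistic function of a resampled `data` list returning a named
#'   numeric vector of the quantities of interest.
#' @param spec a [bootstrap_spec()].
#' @return Data frame of class `bootstrap_result`: `quantity`, `point`
#'   (statistic on the original data), `lo`, `hi`, `B`, `seed`; the
#'   replicate matrix is attached as attribute `replicates`.
#' @export
bootstrap_pipeline <- function(data, statistic, spec = bootstrap_spec()) {
  for (comp in spec$components) {
    if (is.null(data[[comp]]) || nrow(data[[comp]]) == 0)
      stop("component '", comp, "' has no records to resample")
  }
  strata_of <- function(comp, df) switch(
    comp,
    removals = df$species,
    scats = df$species,
    recruitment = df$site,
    individuals = interaction(df$site, df$year, drop = TRUE)
  )
  splits <- lapply(spec$components, function(comp) {
    s <- split(seq_len(nrow(data[[comp]])), strata_of(comp, data[[comp]]))
    if (any(lengths(s) == 0)) stop("empty stratum in component '", comp, "'")
    s
  })
  names(splits) <- spec$components
  point <- statistic(data)
  set.seed(spec$seed)
  reps <- matrix(NA_real_, spec$B, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(spec$B)) {
    rd <- data
    for (comp in spec$components) {
      rd[[comp]] <- data[[comp]][resample_index(splits[[comp]]), ,
                                 drop = FALSE]
    }
    reps[b, ] <- statistic(rd)
  }
  out <- do.call(rbind, lapply(seq_along(point), function(j) {
    ci <- percentile_interval(reps[, j], spec$level)
    data.frame(quantity = names(point)[j], point = unname(point[j]),
               lo = ci[["lo"]], hi = ci[["hi"]], B = spec$B,
               seed = spec$seed, stringsAsFactors = FALSE)
  }))
  attr(out, "replicates") <- reps
  class(out) <- c("bootstrap_result", class(out))
  out
}

#' Default statistic: growth rates and per-species deficits
#'
#' Builds the statistic used by the pipeline's uncertainty stage: from a
#' resampled data list it re-estimates disperser profiles and recruitment,
#' rebuilds the fecundity kernel on fixed vital rates, and returns the
#' gravity-weighted growth rate, the growth rate at full animal dispersal
#' for both scenarios, and each species' deficit `delta_lambda`.
#'
#' @param vitals a fixed [vital_rate_model()] (growth uncertainty off).
#' @param grid an [ipm_grid][make_grid].
#' @param weights availability weights.
#' @param scat_threshold pooling threshold passed to
#'   [estimate_disperser_profiles()].
#' @param species_deficits include per-species deficit effects?
#' @return A function suitable for [bootstrap_pipeline()].
#' @export
sde_statistic <- function(vitals, grid, weights, scat_threshold = 30,
                          species_deficits = TRUE) {
  P <- build_P(vitals, grid)
  loc <- local_lambdas(vitals, grid, P = P)
  force(weights)
  function(data) {
    vr <- vitals
    vr$recruit <- estimate_recruitment(data$recruitment)$p
    prof <- estimate_disperser_profiles(data$removals, data$scats, grid,
                                        scat_threshold = scat_threshold)
    loc_b <- if (vr$recruit == vitals$recruit) loc else
      local_lambdas(vr, grid, P = P)
    lam_grav <- gravity_weighted_lambda(loc_b, weights)
    K <- assemble(P, build_F(vr, prof, grid, 1))
    baseline <- if (species_deficits) kernel_baseline(K)
                else dominant_eigen(K)
    base <- baseline$lambda
    out <- c(lambda_gravity = lam_grav, lambda_full = base,
             delta_lambda = base - lam_grav)
    if (species_deficits) {
      d <- vapply(prof$profiles$species, function(s)
        sde_deficit(vr, prof, grid, s, baseline = baseline, P = P
        )$delta_lambda, 0)
      names(d) <- paste0("deficit_", prof$profiles$species)
      out <- c(out, d)
    }
    out
  }
}
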