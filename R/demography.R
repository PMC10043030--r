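#' Dominant eigenvalue and stable stage distribution
#'
#' Power iteration on a nonnegative projection kernel (a dense matrix or
#' an [ipm_kernel][assemble] with its structured matrix-vector product),
#' to a relative tolerance on the growth-rate estimate.
#'
#' @param K square matrix or `ipm_kernel`.
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1e5); non-convergence (e.g. for
#'   periodic kernels) is an error, not a silent result.
#' @param left iterate on the transpose, returning the left eigenvector
#'   (reproductive values) in `stable_dist`.
#' @return List: `lambda`, `stable_dist` (L1-normalized), `iterations`.
#' @export
dominant_eigen <- function(K, tol = 1e-10, max_iter = 1e5, left = FALSE) {
  if (inherits(K, "ipm_kernel")) {
    mv <- if (left) K$matvec_t else K$matvec
    n <- K$dim
  } else {
    K <- as.matrix(K)
    if (left) K <- t(K)
    mv <- function(v) as.vector(K %*% v)
    n <- nrow(K)
  }
  v <- rep(1 / n, n)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- mv(v)
    s <- sum(abs(w))
    if (s == 0) return(list(lambda = 0, stable_dist = v, iterations = it))
    lam_new <- sum(w) / sum(v)
    w <- w / s
    if (it > 1 &&
        abs(lam_new - lam) <= tol * max(abs(lam_new), .Machine$double.xmin) &&
        sum(abs(w - v)) <= sqrt(tol)) {
      return(list(lambda = lam_new, stable_dist = w, iterations = it))
    }
    lam <- lam_new
    v <- w
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (last lambda = ", signif(lam, 8),
       "); the kernel may be periodic or reducible with tied blocks")
}

#' Population growth rate
#'
#' @inheritParams dominant_eigen
#' @return The dominant eigenvalue (spectral radius) as a scalar.
#' @export
lambda <- function(K, tol = 1e-10, max_iter = 1e5) {
  dominant_eigen(K, tol, max_iter)$lambda
}

#' Growth rate of an edited kernel under baseline demographic weights
#'
#' The Rayleigh-quotient growth measure `u' K v / (u' v)`, with `v` the
#' stable stage distribution and `u` the reproductive values of a
#' *baseline* kernel. For the baseline itself this equals its dominant
#' eigenvalue exactly; for a scenario-edited kernel it is the standard
#' first-order (eigenvalue-perturbation) estimate of the new growth rate.
#' Species-loss scenarios are compared with this measure because the
#' asymptotic eigenvalue of a kernel with restored gravity retention is
#' taken over by whichever bright canopy segment can sustain itself in
#' isolation (a principal-submatrix bound), so asymptotic comparisons
#' reflect gap takeover by a vanishing sliver of habitat rather than the
#' dispersal service of the community; see the package vignette.
#'
#' @param K square matrix or [ipm_kernel][assemble] (the edited kernel).
#' @param v baseline stable stage distribution (nonnegative).
#' @param u baseline reproductive values; equal weights if `NULL`.
#' @return Scalar growth rate.
#' @export
weighted_growth <- function(K, v, u = NULL) {
  mv <- if (inherits(K, "ipm_kernel")) K$matvec else
    function(x) as.vector(as.matrix(K) %*% x)
  stopifnot(all(v >= 0), sum(v) > 0)
  if (is.null(u)) u <- rep(1, length(v))
  sum(u * mv(v)) / sum(u * v)
}

#' Baseline eigenstructure of a kernel
#'
#' Dominant eigenvalue with both the stable stage distribution (right
#' eigenvector) and the reproductive values (left eigenvector), as needed
#' to evaluate scenario edits via [weighted_growth()].
#'
#' @inheritParams dominant_eigen
#' @return List: `lambda`, `stable_dist`, `repro_value`.
#' @export
kernel_baseline <- function(K, tol = 1e-10, max_iter = 1e5) {
  r <- dominant_eigen(K, tol, max_iter)
  l <- dominant_eigen(K, tol, max_iter, left = TRUE)
  # report lambda through the same Rayleigh quotient used for scenario
  # kernels, so an unchanged kernel gives a change of exactly zero
  list(lambda = weighted_growth(K, r$stable_dist, l$stable_dist),
       stable_dist = r$stable_dist,
       repro_value = l$stable_dist)
}

#' Local population growth rates along the canopy gradient
#'
#' Per canopy segment, the growth rate of a population confined to that
#' environment with gravity dispersal only: the size-only kernel combining
#' the segment's survival/growth block with a gravity fecundity term whose
#' offspring stay under the parent's canopy.
#'
#' @param vitals a [vital_rate_model()].
#' @param grid an [ipm_grid][make_grid].
#' @param recfruit_on_gravity apply the within-fruit germination penalty
#'   to gravity-dispersed seeds (default `TRUE`).
#' @param P optional precomputed [build_P()] result.
#' @return Numeric vector of length `grid$n_c`.
#' @export
local_lambdas <- function(vitals, grid, recfruit_on_gravity = TRUE,
                          P = NULL) {
  if (is.null(P)) P <- build_P(vitals, grid)
  fdist <- fdist_probs(vitals, grid)
  phi <- fruit_production(vitals, grid)
  coef <- vitals$constants$f_seed * vitals$recruit *
    (if (recfruit_on_gravity) vitals$constants$f_recfruit else 1)
  vapply(seq_len(grid$n_c), function(k) {
    dominant_eigen(P$blocks[[k]] + coef * (fdist %*% t(phi[, k])))$lambda
  }, 0)
}

#' Availability-weighted population growth rate
#'
#' The gravity-dispersal summary: local growth rates weighted by the
#' relative abundance of the microhabitats and summed. (The dominant
#' eigenvalue of the block-diagonal gravity kernel is the maximum of the
#' local rates instead; both conventions are available, this function is
#' the weighted mean.)
#'
#' @param local_lams per-segment growth rates (see [local_lambdas()]).
#' @param weights availability weights (see [microhabitat_weights()]),
#'   nonnegative, summing to 1.
#' @return Scalar growth rate.
#' @export
gravity_weighted_lambda <- function(local_lams, weights) {
  stopifnot(length(local_lams) == length(weights), all(weights >= 0))
  sum(weights * local_lams) / sum(weights)
}

#' Animal-dispersal sweep
#'
#' Population growth rate as the proportion of fruits removed by animals
#' (`f_rel_anim_disp`) increases from 0 to 1, for the fully-established
#' scenario (plants occur along the whole canopy gradient) or the
#' gap-colonization scenario (plants rely on animals to reach the brighter
#' half of the gradient: the gravity pathway is confined to the darker
#' half and the availability weighting at `f = 0` is renormalized over the
#' darker segments). At `f = 0` the curve reports the availability-weighted
#' mean of the local growth rates — the convention matching a population
#' spread over the microhabitat distribution — rather than the dominant
#' eigenvalue of the uncoupled kernel (which is the maximum over
#' segments); for `f > 0` the dominant eigenvalue of the coupled kernel is
#' used. At `f = 1` the two scenarios coincide by construction.
#'
#' @inheritParams local_lambdas
#' @param profiles a `disperser_profiles` object.
#' @param weights microhabitat availability weights over segments.
#' @param scenario `"fully_established"` or `"gap_colonization"`.
#' @param n_points number of sweep values (default 11).
#' @return Data frame `f_rel_anim_disp`, `lambda`, `scenario`, with the
#'   animal-dispersal benefit `delta = lambda(1) - lambda(0)` as an
#'   attribute.
#' @export
dispersal_sweep <- function(vitals, profiles, grid, weights,
                            scenario = c("fully_established",
                                         "gap_colonization"),
                            n_points = 11, recfruit_on_gravity = TRUE,
                            P = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(P)) P <- build_P(vitals, grid)
  bright <- brighter_segments(grid)
  mask <- rep(1, grid$n_c)
  w <- weights
  if (scenario == "gap_colonization") {
    mask[bright] <- 0
    w[bright] <- 0
    if (sum(w) == 0) stop("no availability mass in the darker half")
    w <- w / sum(w)
  }
  loc <- local_lambdas(vitals, grid, recfruit_on_gravity, P = P)
  a_grid <- seq(0, 1, length.out = n_points)
  lam <- vapply(a_grid, function(a) {
    if (a == 0) return(gravity_weighted_lambda(loc, w))
    K <- assemble(P, build_F(vitals, profiles, grid, f_rel_anim_disp = a,
                             recfruit_on_gravity = recfruit_on_gravity,
                             gravity_mask = mask))
    dominant_eigen(K)$lambda
  }, 0)
  out <- data.frame(f_rel_anim_disp = a_grid, lambda = lam,
                    scenario = scenario)
  attr(out, "delta") <- lam[n_points] - lam[1]
  out
}

#' Gap-colonization sweep
#'
#' Convenience wrapper for [dispersal_sweep()] with
#' `scenario = "gap_colonization"`.
#'
#' @inheritParams dispersal_sweep
#' @return See [dispersal_sweep()].
#' @export
gap_colonization <- function(vitals, profiles, grid, weights,
                             n_points = 11, recfruit_on_gravity = TRUE,
                             P = NULL) {
  dispersal_sweep(vitals, profiles, grid, weights,
                  scenario = "gap_colonization", n_points = n_points,
                  recfruit_on_gravity = recfruit_on_gravity, P = P)
}

#' Interaction deficit after losing one disperser
#'
#' Rebuilds the fecundity kernel with the focal species' consumed and
#' dropped pathways removed and its interaction frequency rerouted to a
#' gravity-type pathway (seeds fall beneath the parent, keep the
#' within-fruit germination penalty, and are no longer exposed to the
#' species' seed predation). The change in growth rate
#' `delta_lambda = lambda(full) - lambda(deficit)` is the species' seed
#' dispersal effectiveness; it is negative for seed predators, whose loss
#' helps the plant.
#'
#' @inheritParams dispersal_sweep
#' @param species species id present in `profiles`.
#' @param baseline optional precomputed [kernel_baseline()] of the full
#'   kernel at `f_rel_anim_disp = 1`.
#' @param measure `"perturbation"` (default; the deficit kernel is
#'   evaluated by [weighted_growth()] against the baseline stable stage
#'   distribution and reproductive values) or `"asymptotic"` (dominant
#'   eigenvalue of the deficit kernel; see [weighted_growth()] for why
#'   the two diverge when a scenario restores gravity retention in
#'   self-sustaining bright gaps).
#' @return List: `lambda_base`, `lambda_deficit`, `delta_lambda` (under
#'   the selected measure), plus both raw scenario values
#'   (`lambda_deficit_perturbation`, `lambda_deficit_asymptotic`).
#' @export
sde_deficit <- function(vitals, profiles, grid, species,
                        baseline = NULL, P = NULL,
                        measure = c("perturbation", "asymptotic"),
                        recfruit_on_gravity = TRUE) {
  measure <- match.arg(measure)
  i <- match(species, profiles$profiles$species)
  if (is.na(i)) stop("unknown species: ", species)
  if (is.null(P)) P <- build_P(vitals, grid)
  if (is.null(baseline) || is.null(baseline$repro_value)) {
    baseline <- kernel_baseline(assemble(
      P, build_F(vitals, profiles, grid, 1,
                 recfruit_on_gravity = recfruit_on_gravity)))
  }
  mod <- profiles
  q_x <- mod$profiles$freq[i]
  mod$profiles$f_nocrush[i] <- 0   # silence consumed + dropped pathways
  K_def <- assemble(P, build_F(vitals, mod, grid, 1, extra_gravity = q_x,
                               recfruit_on_gravity = recfruit_on_gravity))
  lam_p <- weighted_growth(K_def, baseline$stable_dist,
                           baseline$repro_value)
  lam_a <- if (measure == "asymptotic") dominant_eigen(K_def)$lambda
           else NA_real_
  lam <- if (measure == "perturbation") lam_p else lam_a
  list(lambda_base = baseline$lambda,
       lambda_deficit = lam,
       delta_lambda = baseline$lambda - lam,
       lambda_deficit_perturbation = lam_p,
       lambda_deficit_asymptotic = lam_a)
}

#' Interaction compensation after losing one disperser
#'
#' Removes the focal species and rescales the remaining community's
#' interaction frequencies proportionally so fruit removal sums to one
#' again, then recomputes the growth rate at full animal dispersal.
#'
#' @inheritParams sde_deficit
#' @return List: `lambda_compensation` (under the selected measure),
#'   `lambda_base`, and the rescaled profiles.
#' @export
sde_compensation <- function(vitals, profiles, grid, species,
                             baseline = NULL, P = NULL,
                             measure = c("perturbation", "asymptotic"),
                             recfruit_on_gravity = TRUE) {
  measure <- match.arg(measure)
  i <- match(species, profiles$profiles$species)
  if (is.na(i)) stop("unknown species: ", species)
  if (is.null(P)) P <- build_P(vitals, grid)
  if (is.null(baseline) || is.null(baseline$repro_value)) {
    baseline <- kernel_baseline(assemble(
      P, build_F(vitals, profiles, grid, 1,
                 recfruit_on_gravity = recfruit_on_gravity)))
  }
  mod <- profiles
  mod$profiles <- mod$profiles[-i, , drop = FALSE]
  mod$deposition <- mod$deposition[-i, , drop = FALSE]
  tot <- sum(mod$profiles$freq)
  if (tot <= 0) stop("no remaining interaction frequency to rescale")
  mod$profiles$freq <- mod$profiles$freq / tot
  validate_profiles(mod)
  K <- assemble(P, build_F(vitals, mod, grid, 1,
                           recfruit_on_gravity = recfruit_on_gravity))
  lam <- if (measure == "perturbation")
    weighted_growth(K, baseline$stable_dist, baseline$repro_value)
  else dominant_eigen(K)$lambda
  list(lambda_compensation = lam,
       lambda_base = baseline$lambda,
       profiles = mod)
}

#' Probability of reaching reproduction (absorbing Markov chain)
#'
#' For every state `(size bin, canopy segment)`, the probability that an
#' individual eventually reproduces at least once before dying. Each step,
#' a survivor either reproduces (absorbing, probability `f_repr`) or
#' transitions through the `(1 - f_repr)`-weighted survival/growth
#' operator. Solved as the absorbing-chain linear system
#' `l = r + T' l` with `r = S * f_repr` and `T` the discounted `P`.
#'
#' @inheritParams local_lambdas
#' @return A matrix `n_z x n_c` of probabilities in \[0, 1\].
#' @export
reproduction_probability <- function(vitals, grid, P = NULL) {
  if (is.null(P)) P <- build_P(vitals, grid)
  n_z <- grid$n_z; n_c <- grid$n_c; n <- n_z * n_c
  repr <- outer(grid$z_mid, grid$c_mid, function(z, c) vr_repro(vitals, z, c))
  surv <- outer(grid$z_mid, grid$c_mid, function(z, c)
    vr_survival(vitals, z, c))
  Tm <- matrix(0, n, n)
  for (k in seq_len(n_c)) {
    idx <- ((k - 1) * n_z + 1):(k * n_z)
    Tm[idx, idx] <- P$blocks[[k]] * rep(1 - repr[, k], each = n_z)
  }
  r <- as.vector(surv * repr)
  l <- tryCatch(solve(diag(n) - t(Tm), r), error = function(e)
    stop("absorbing-chain solve failed (transient operator not ",
         "substochastic?): ", conditionMessage(e)))
  if (any(l < -1e-8 | l > 1 + 1e-8))
    stop("reproduction probabilities escaped [0, 1]; ",
         "check the transient operator's spectral radius")
  matrix(pmin(pmax(l, 0), 1), n_z, n_c)
}

#' Quality of seed dispersal (seed to reproductive adult)
#'
#' The probability that a seed handled by a given species produces a plant
#' that reproduces at least once: fruit-fate probabilities, deposition
#' along the canopy gradient, first-year recruitment (with the
#' within-fruit penalty for dropped fruits) and the
#' [reproduction_probability()] of the resulting seedling, averaged over
#' the seedling size distribution. Dropped fruits stay beneath the parent;
#' their canopy distribution is weighted by where fruits are produced
#' under the stable stage distribution of the full model (or by
#' availability, see `drop_weighting`).
#'
#' @inheritParams dispersal_sweep
#' @param species character vector of species ids (default: all).
#' @param drop_weighting `"stable"` (fruit production under the stable
#'   stage distribution at full animal dispersal) or `"availability"`.
#' @param weights availability weights (required for
#'   `drop_weighting = "availability"`).
#' @return Named numeric vector of per-seed probabilities.
#' @export
quality_to_adulthood <- function(vitals, profiles, grid,
                                 species = profiles$profiles$species,
                                 drop_weighting = c("stable",
                                                    "availability"),
                                 weights = NULL, P = NULL,
                                 recfruit_on_gravity = TRUE) {
  drop_weighting <- match.arg(drop_weighting)
  if (is.null(P)) P <- build_P(vitals, grid)
  fdist <- fdist_probs(vitals, grid)
  lmat <- reproduction_probability(vitals, grid, P = P)
  l_seg <- as.vector(fdist %*% lmat)   # per segment, averaged over f_dist

  if (drop_weighting == "stable") {
    K <- assemble(P, build_F(vitals, profiles, grid, 1,
                             recfruit_on_gravity = recfruit_on_gravity))
    v <- matrix(dominant_eigen(K)$stable_dist, grid$n_z, grid$n_c)
    g <- colSums(fruit_production(vitals, grid) * v)
    w_drop <- g / sum(g)
  } else {
    if (is.null(weights)) stop("availability weights required")
    w_drop <- weights / sum(weights)
  }

  p <- profiles$profiles
  f_rec <- vitals$recruit
  f_recf <- vitals$constants$f_recfruit
  out <- vapply(species, function(s) {
    i <- match(s, p$species)
    if (is.na(i)) stop("unknown species: ", s)
    consumed <- p$f_nocrush[i] * p$f_consumed[i] *
      sum(profiles$deposition[i, ] * f_rec * l_seg)
    dropped <- p$f_nocrush[i] * (1 - p$f_consumed[i]) *
      sum(w_drop * f_rec * f_recf * l_seg)
    consumed + dropped
  }, 0)
  names(out) <- species
  out
}

#' Per-species seed dispersal effectiveness table
#'
#' Combines quantity (relative interaction frequency), quality
#' ([quality_to_adulthood()]), the interaction-deficit effect on the
#' growth rate, the relative reduction expressed as percent of the total
#' animal-dispersal benefit, and (for selected species) the
#' interaction-compensation growth rate.
#'
#' @inheritParams dispersal_sweep
#' @param compensation_for species ids for which the compensation scenario
#'   is run (computationally heavier; default: the four most frequent).
#' @param lambda_gravity availability-weighted gravity growth rate used to
#'   normalize the relative reduction; computed if `NULL`.
#' @return A data frame of class `sde_result`, one row per species.
#' @export
sde_table <- function(vitals, profiles, grid, weights,
                      compensation_for = NULL, lambda_gravity = NULL,
                      measure = c("perturbation", "asymptotic"),
                      recfruit_on_gravity = TRUE) {
  measure <- match.arg(measure)
  P <- build_P(vitals, grid)
  baseline <- kernel_baseline(assemble(
    P, build_F(vitals, profiles, grid, 1,
               recfruit_on_gravity = recfruit_on_gravity)))
  base <- baseline$lambda
  if (is.null(lambda_gravity)) {
    lambda_gravity <- gravity_weighted_lambda(
      local_lambdas(vitals, grid, recfruit_on_gravity, P = P), weights)
  }
  sp <- profiles$profiles$species
  if (is.null(compensation_for))
    compensation_for <- sp[order(-profiles$profiles$freq)][
      seq_len(min(4, length(sp)))]
  qual <- quality_to_adulthood(vitals, profiles, grid, sp, P = P,
                               recfruit_on_gravity = recfruit_on_gravity)
  rows <- lapply(sp, function(s) {
    def <- sde_deficit(vitals, profiles, grid, s, baseline = baseline,
                       P = P, measure = measure,
                       recfruit_on_gravity = recfruit_on_gravity)
    comp <- if (s %in% compensation_for)
      sde_compensation(vitals, profiles, grid, s, baseline = baseline,
                       P = P, measure = measure,
                       recfruit_on_gravity = recfruit_on_gravity
      )$lambda_compensation else NA_real_
    data.frame(
      species = s,
      quantity = profiles$profiles$freq[match(s, sp)],
      quality = unname(qual[s]),
      delta_lambda_deficit = def$delta_lambda,
      relative_reduction_pct =
        100 * def$delta_lambda / (base - lambda_gravity),
      lambda_compensation = comp,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "lambda_base") <- base
  attr(out, "lambda_gravity") <- lambda_gravity
  attr(out, "measure") <- measure
  class(out) <- c("sde_result", class(out))
  out
}

#' Rank correlations of effectiveness with quantity and quality
#'
#' Spearman rank correlations of the per-species effectiveness (deficit
#' `delta_lambda`) against the quantity and the quality components. A
#' component with constant ranks across species has no defined rank
#' correlation; it is reported as such rather than propagated as `NaN`.
#'
#' @param sde an [sde_table()] result.
#' @return Data frame: `component`, `rho`, `p_value`, `n`, `note`.
#' @export
sde_correlations <- function(sde) {
  comp <- function(name, x) {
    y <- sde$delta_lambda_deficit
    if (length(unique(rank(x))) == 1 || length(unique(rank(y))) == 1) {
      return(data.frame(component = name, rho = NA_real_,
                        p_value = NA_real_, n = length(x),
                        note = "undefined (constant ranks)",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(y, x, method = "spearman", exact = FALSE))
    data.frame(component = name, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), note = "",
               stringsAsFactors = FALSE)
  }
  rbind(comp("quantity", sde$quantity), comp("quality", sde$quality))
}
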