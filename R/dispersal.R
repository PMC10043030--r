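#' Relative interaction frequency (the quantity of seed dispersal)
#'
#' Per species, the raw interaction frequency is
#' `visits * P(handled | handling observed) * mean(fruits handled | handled)`.
#' Exploratory pecking counts as a visit without successful handling;
#' visits where handling could not be observed still count toward the
#' visit total but are excluded from the handling-probability denominator.
#' Raw frequencies are normalized to sum to one.
#'
#' @param removals removal-observation table (see [generate_removals()]).
#' @return Data frame: `species`, `visits`, `p_handle`, `mean_fruits`,
#'   `raw`, `freq` (normalized, sums to 1).
#' @export
interaction_frequency <- function(removals) {
  if (nrow(removals) == 0) stop("no removal observations")
  species <- sort(unique(removals$species))
  grp <- removals$species
  agg <- function(x) {
    r <- rowsum(x, grp)
    out <- r[match(species, rownames(r)), 1]
    out[is.na(out)] <- 0
    out
  }
  visits <- agg(rep(1, nrow(removals)))
  n_obs <- agg(as.numeric(removals$handled != "unobserved"))
  n_yes <- agg(as.numeric(removals$handled == "yes"))
  fr_yes <- agg(removals$fruits_handled *
                  (removals$handled == "yes"))
  p_handle <- ifelse(n_obs > 0, n_yes / n_obs, 0)
  mean_fruits <- ifelse(n_yes > 0, fr_yes / n_yes, 0)
  raw <- visits * p_handle * mean_fruits
  total <- sum(raw)
  if (total <= 0) stop("no species handled any fruit")
  data.frame(species = species, visits = visits, p_handle = p_handle,
             mean_fruits = mean_fruits, raw = raw, freq = raw / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fruit-fate probabilities per species
#'
#' From handled fruits: `f_nocrush` is the probability that a handled
#' fruit is not crushed (seeds not destroyed), and `f_consumed` the
#' probability that an uncrushed fruit is swallowed or carried off rather
#' than dropped beneath the parent. Counts are weighted by the number of
#' fruits handled per observation.
#'
#' @inheritParams interaction_frequency
#' @return Data frame: `species`, `handled_fruits`, `f_nocrush`,
#'   `f_consumed`.
#' @export
fruit_fates <- function(removals) {
  species <- sort(unique(removals$species))
  h <- removals[removals$handled == "yes", ]
  agg <- function(x) {
    if (nrow(h) == 0) return(numeric(length(species)))
    r <- rowsum(x, h$species)
    out <- r[match(species, rownames(r)), 1]
    out[is.na(out)] <- 0
    out
  }
  tot <- agg(h$fruits_handled)
  crushed <- agg(h$fruits_handled * (h$fate == "crushed"))
  sw <- agg(h$fruits_handled * (h$fate == "swallowed_removed"))
  dr <- agg(h$fruits_handled * (h$fate == "dropped"))
  data.frame(
    species = species, handled_fruits = tot,
    f_nocrush = ifelse(tot > 0, 1 - crushed / tot, NA_real_),
    f_consumed = ifelse(sw + dr > 0, sw / (sw + dr), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Deposition distribution over canopy segments
#'
#' Gaussian kernel density estimate (Silverman's bandwidth) of the
#' standardized canopy positions of a species' scats, evaluated at the
#' segment midpoints and renormalized to sum to one. Records flagged as
#' coming from the excluded hotspot segment are dropped unless they
#' contain seeds of the focal species. With zero spread in the data, all
#' mass is assigned to the nearest segment.
#'
#' @param scats scat table (see [generate_scats()]).
#' @param species species id to estimate, or `NULL` to use all rows.
#' @param grid an [ipm_grid][make_grid].
#' @param min_scats hard floor on the usable sample size (default 30);
#'   species below it must be pooled first.
#' @param method `"kde"` (default) or `"hist"` (raw histogram).
#' @return Numeric vector of length `grid$n_c`, summing to 1.
#' @export
deposition_distribution <- function(scats, species = NULL,
                                    grid = make_grid(), min_scats = 30,
                                    method = c("kde", "hist")) {
  method <- match.arg(method)
  s <- scats
  if (!is.null(species)) s <- s[s$species == species, ]
  s <- s[!(s$excluded_hotspot == 1 & s$contains_focal == 0), ]
  if (nrow(s) < min_scats)
    stop("only ", nrow(s), " usable scats (< ", min_scats,
         "): pool this species before estimating deposition")
  x <- grid$std_canopy(s$canopy)
  if (method == "hist") {
    w <- graphics::hist(pmin(pmax(x, grid$c_range[1]), grid$c_range[2]),
                        breaks = grid$c_edges, plot = FALSE)$counts
  } else if (stats::sd(x) == 0) {
    w <- numeric(grid$n_c)
    w[which.min(abs(grid$c_mid - x[1]))] <- 1
  } else {
    bw <- stats::bw.nrd0(x)
    w <- vapply(grid$c_mid, function(m) mean(stats::dnorm(m, x, bw)), 0)
    if (!all(is.finite(w)) || sum(w) <= 0) {
      # bandwidth collapsed (near-identical positions): fall back to the
      # histogram, which always places the mass
      w <- graphics::hist(pmin(pmax(x, grid$c_range[1]), grid$c_range[2]),
                          breaks = grid$c_edges, plot = FALSE)$counts
    }
  }
  if (sum(w) <= 0) stop("degenerate deposition estimate")
  w / sum(w)
}

#' Microhabitat availability weights
#'
#' Histogram of canopy-cover measurements over the canopy segments,
#' normalized to sum to one.
#'
#' @param canopy_samples numeric vector of canopy cover percentages.
#' @param grid an [ipm_grid][make_grid].
#' @return Numeric vector of length `grid$n_c` summing to 1.
#' @export
microhabitat_weights <- function(canopy_samples, grid = make_grid()) {
  x <- grid$std_canopy(canopy_samples)
  x <- pmin(pmax(x, grid$c_range[1]), grid$c_range[2])
  w <- graphics::hist(x, breaks = grid$c_edges, plot = FALSE)$counts
  if (sum(w) == 0) stop("no canopy samples")
  w / sum(w)
}

#' Mass in the brighter half of the canopy range
#'
#' The threshold is the midpoint of the canopy range (brighter = lower
#' cover). Returns the availability mass and the deposition mass on the
#' brighter side; under random dispersal (deposition identical to
#' availability) the two fractions coincide.
#'
#' @param dist deposition distribution over segments (sums to 1).
#' @param availability availability weights over segments (sums to 1).
#' @param grid an [ipm_grid][make_grid].
#' @return Named vector `c(area_fraction, seed_fraction)`.
#' @export
brightest_fraction <- function(dist, availability, grid = make_grid()) {
  bright <- brighter_segments(grid)
  c(area_fraction = sum(availability[bright]),
    seed_fraction = sum(dist[bright]))
}

#' Pool rare species into an "other" profile
#'
#' Species with fewer usable scats than the threshold are merged into a
#' single pooled profile: interaction frequencies are summed, fruit fates
#' are recomputed from the pooled removal records, and the deposition
#' distribution is estimated from the pooled scats. Species observed only
#' in scats or camera records (no removal observations) inherit the pooled
#' profile's removal parameters, mirroring the assumption that such rare
#' dispersers are functionally similar to the other rare species.
#'
#' @param removals,scats input tables.
#' @param grid an [ipm_grid][make_grid].
#' @param scat_threshold minimum usable scats for a species-specific
#'   deposition estimate (default 30).
#' @param pooled_name label for the pooled profile.
#' @param method deposition estimator passed on to
#'   [deposition_distribution()].
#' @return A `disperser_profiles` object: data frame `profiles` (species,
#'   freq, f_nocrush, f_consumed, n_scats, pooled flag) and matrix
#'   `deposition` (species x segments, rows sum to 1).
#' @export
estimate_disperser_profiles <- function(removals, scats,
                                        grid = make_grid(),
                                        scat_threshold = 30,
                                        pooled_name = "other",
                                        method = "kde") {
  freq <- interaction_frequency(removals)
  fates <- fruit_fates(removals)
  usable <- scats[!(scats$excluded_hotspot == 1 & scats$contains_focal == 0), ]
  scat_counts <- table(usable$species)
  all_species <- sort(unique(c(freq$species, names(scat_counts))))
  n_scats <- as.integer(scat_counts[all_species])
  n_scats[is.na(n_scats)] <- 0L
  keep <- all_species[n_scats >= scat_threshold]
  pool <- setdiff(all_species, keep)
  if (length(pool) == 0 && length(keep) == 0) stop("no species in input")

  prof <- data.frame(species = keep, stringsAsFactors = FALSE)
  prof$freq <- freq$freq[match(keep, freq$species)]
  prof$freq[is.na(prof$freq)] <- 0
  prof$f_nocrush <- fates$f_nocrush[match(keep, fates$species)]
  prof$f_consumed <- fates$f_consumed[match(keep, fates$species)]
  prof$n_scats <- n_scats[match(keep, all_species)]
  prof$pooled <- FALSE

  dep <- matrix(NA_real_, nrow(prof) + (length(pool) > 0), grid$n_c,
                dimnames = list(c(prof$species,
                                  if (length(pool)) pooled_name), NULL))
  for (s in keep)
    dep[s, ] <- deposition_distribution(scats, s, grid,
                                        min_scats = scat_threshold,
                                        method = method)

  if (length(pool) > 0) {
    pr <- removals[removals$species %in% pool, ]
    pooled_freq <- sum(freq$freq[freq$species %in% pool])
    if (nrow(pr) > 0) {
      # recompute fates jointly over the pooled records
      pooled_fates <- fruit_fates(transform(pr, species = pooled_name))
      f_nc <- pooled_fates$f_nocrush
      f_co <- pooled_fates$f_consumed
    } else {
      f_nc <- f_co <- NA_real_
    }
    # the pooled group is the fallback: no floor re-applied beyond
    # requiring at least one usable scat
    pooled_scats <- scats[scats$species %in% pool, ]
    dep[pooled_name, ] <- deposition_distribution(
      transform(pooled_scats, species = pooled_name), pooled_name, grid,
      min_scats = 1, method = method)
    prof <- rbind(prof, data.frame(
      species = pooled_name, freq = pooled_freq, f_nocrush = f_nc,
      f_consumed = f_co, n_scats = sum(n_scats[match(pool, all_species)]),
      pooled = TRUE, stringsAsFactors = FALSE))
  }

  # species identified only by scats or cameras: inherit pooled fates
  if (any(is.na(prof$f_nocrush)) || any(is.na(prof$f_consumed))) {
    src <- which(prof$pooled)
    if (length(src) == 1 && !is.na(prof$f_nocrush[src])) {
      miss <- is.na(prof$f_nocrush)
      prof$f_nocrush[miss] <- prof$f_nocrush[src]
      prof$f_consumed[miss & is.na(prof$f_consumed)] <-
        prof$f_consumed[src]
    }
    # no uncrushed fruit observed: consumption given no crushing is
    # unobservable and the pathway weight is zero either way
    prof$f_consumed[is.na(prof$f_consumed) & !is.na(prof$f_nocrush) &
                      prof$f_nocrush == 0] <- 0
    # species never seen handling: zero frequency, inert fates
    inert <- is.na(prof$f_nocrush)
    prof$f_nocrush[inert] <- 0
    prof$f_consumed[is.na(prof$f_consumed)] <- 0
  }
  prof$freq <- prof$freq / sum(prof$freq)
  out <- list(profiles = prof, deposition = dep[prof$species, , drop = FALSE],
              grid_n_c = grid$n_c, scat_threshold = scat_threshold)
  class(out) <- "disperser_profiles"
  validate_profiles(out)
  out
}

#' Validate disperser profiles
#'
#' Asserts the conservation invariants: interaction frequencies sum to 1,
#' every deposition row sums to 1, and all probabilities lie in \[0, 1\].
#'
#' @param x a `disperser_profiles` object.
#' @return `x` invisibly, or an error.
#' @export
validate_profiles <- function(x) {
  p <- x$profiles
  if (abs(sum(p$freq) - 1) > 1e-12)
    stop("relative interaction frequencies must sum to 1")
  if (any(abs(rowSums(x$deposition) - 1) > 1e-12))
    stop("every deposition distribution must sum to 1")
  probs <- c(p$freq, p$f_nocrush, p$f_consumed, as.vector(x$deposition))
  if (any(probs < -1e-12 | probs > 1 + 1e-12, na.rm = TRUE))
    stop("profile probabilities must lie in [0, 1]")
  invisible(x)
}

#' @export
print.disperser_profiles <- function(x, ...) {
  cat("Disperser profiles (", nrow(x$profiles), " species, deposition over ",
      ncol(x$deposition), " canopy segments)\n", sep = "")
  print(x$profiles, row.names = FALSE)
  invisible(x)
}

#' Construct disperser profiles directly from a ground truth
#'
#' The oracle counterpart of [estimate_disperser_profiles()]: computes the
#' exact profiles implied by the generating parameters (true interaction
#' frequencies, fates and Beta deposition masses per segment), with the
#' same pooling rule applied using the expected scat counts.
#'
#' @param truth a [ground_truth][default_ground_truth] object.
#' @param grid an [ipm_grid][make_grid].
#' @param expected_scats total scat count used to decide pooling.
#' @param scat_threshold pooling threshold on expected scats.
#' @param pooled_name label for the pooled profile.
#' @return A `disperser_profiles` object.
#' @export
true_profiles <- function(truth, grid = make_grid(), expected_scats = 1729,
                          scat_threshold = 30, pooled_name = "other") {
  validate_ground_truth(truth)
  sp <- truth$species
  raw <- sp$visit_rate * sp$p_handle * sp$mean_fruits
  freq <- raw / sum(raw)
  exp_scats <- sp$scat_weight / sum(sp$scat_weight) * expected_scats
  pool <- exp_scats < scat_threshold
  seg_mass <- function(a, b) {
    u <- seq(0, 1, length.out = grid$n_c + 1)
    diff(stats::pbeta(u, a, b))
  }
  keep_idx <- which(!pool)
  prof <- data.frame(species = sp$species[keep_idx],
                     freq = freq[keep_idx],
                     f_nocrush = 1 - sp$p_crush[keep_idx],
                     f_consumed = sp$p_consume[keep_idx],
                     n_scats = round(exp_scats[keep_idx]),
                     pooled = FALSE, stringsAsFactors = FALSE)
  dep <- t(vapply(keep_idx, function(i)
    seg_mass(sp$dep_shape1[i], sp$dep_shape2[i]), numeric(grid$n_c)))
  rownames(dep) <- sp$species[keep_idx]
  if (any(pool)) {
    w <- sp$scat_weight[pool] / sum(sp$scat_weight[pool])
    handled <- sp$visit_rate[pool] * sp$p_handle[pool] * sp$mean_fruits[pool]
    hw <- handled / sum(handled)
    dep_pool <- colSums(
      w * t(vapply(which(pool), function(i)
        seg_mass(sp$dep_shape1[i], sp$dep_shape2[i]), numeric(grid$n_c))))
    nocrush_pool <- sum(hw * (1 - sp$p_crush[pool]))
    cons_pool <- sum(hw * (1 - sp$p_crush[pool]) * sp$p_consume[pool]) /
      nocrush_pool
    prof <- rbind(prof, data.frame(
      species = pooled_name, freq = sum(freq[pool]),
      f_nocrush = nocrush_pool, f_consumed = cons_pool,
      n_scats = round(sum(exp_scats[pool])), pooled = TRUE,
      stringsAsFactors = FALSE))
    dep <- rbind(dep, dep_pool)
    rownames(dep) <- prof$species
  }
  out <- list(profiles = prof, deposition = dep, grid_n_c = grid$n_c,
              scat_threshold = scat_threshold)
  class(out) <- "disperser_profiles"
  validate_profiles(out)
  out
}
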