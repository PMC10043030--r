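#' Generate individual census records
#'
#' Draws `n` individual-by-year vital-rate transitions from the generating
#' model of the ground truth: survival, breakage and reproduction are
#' Bernoulli on a logit-linear predictor in size, size squared and canopy
#' (plus fixed year offsets and Gaussian site intercepts); growth is
#' Gaussian on the standardized log10-diameter scale; fruit counts are
#' Poisson with a log link and lognormal observation-level noise.
#' Individuals that survive and break re-sprout with a strongly reduced
#' diameter drawn from the re-sprout size model. Output is deterministic
#' given `seed`.
#'
#' @param truth a [ground_truth][default_ground_truth] object.
#' @param n number of transitions (>= 1).
#' @param sites,years number of sites and study years.
#' @param seed RNG seed; defaults to `truth$seed + 1`.
#' @return A data frame with one row per transition: `id`, `site`, `year`,
#'   `diameter_t`, `diameter_t1` (cm, `NA` for deaths), `survived`,
#'   `broke`, `resprouted`, `reproductive`, `fruit_count`, `canopy`
#'   (percent cover).
#' @export
generate_individuals <- function(truth, n, sites = 14, years = 3,
                                 seed = truth$seed + 1L) {
  validate_ground_truth(truth)
  if (n < 1) stop("n must be >= 1")
  if (years > length(truth$survival$year_offsets))
    stop("more years requested than year offsets in the truth")
  set.seed(seed)
  grid <- make_grid()

  site <- sample.int(sites, n, replace = TRUE)
  site_eff <- stats::rnorm(sites, 0, truth$site_sd)
  year <- sample.int(years, n, replace = TRUE)

  sd0 <- truth$size_dist
  z <- stats::qnorm(stats::runif(
    n,
    stats::pnorm(sd0$range[1], sd0$mean, sd0$sd),
    stats::pnorm(sd0$range[2], sd0$mean, sd0$sd)
  ), sd0$mean, sd0$sd)
  canopy_unit <- stats::rbeta(n, truth$availability$shape1,
                              truth$availability$shape2)
  canopy <- truth$canopy_range[1] + canopy_unit * diff(truth$canopy_range)
  c_std <- grid$std_canopy(canopy)

  p_surv <- stats::plogis(link_lp(truth$survival$coef, z, c_std) +
                            truth$survival$year_offsets[year] +
                            site_eff[site])
  if (any(is.na(p_surv) | p_surv < 0 | p_surv > 1))
    stop("survival probabilities outside [0, 1] after linking")
  survived <- stats::rbinom(n, 1, p_surv)

  p_break <- stats::plogis(link_lp(truth$breakage$coef, z))
  broke <- survived * stats::rbinom(n, 1, p_break)

  mu_g <- link_lp(truth$growth$coef, z, c_std) +
    truth$growth$year_offsets[year] + site_eff[site] * 0.1
  z1 <- stats::rnorm(n, mu_g, truth$growth$sd)
  rs <- truth$resprout
  mu_r <- rs$mean[1] + rs$mean[2] * z + rs$mean[3] * z^2
  sd_r <- exp(0.5 * (rs$logvar[1] + rs$logvar[2] * z + rs$logvar[3] * z^2))
  z1[broke == 1] <- stats::rnorm(sum(broke), mu_r[broke == 1],
                                 sd_r[broke == 1])
  z1[survived == 0] <- NA_real_

  p_repr <- stats::plogis(link_lp(truth$repro$coef, z, c_std) +
                            truth$repro$year_offsets[year] + site_eff[site])
  reproductive <- stats::rbinom(n, 1, p_repr)
  lp_fr <- link_lp(truth$fruits$coef, z, c_std) +
    truth$fruits$year_offsets[year] + site_eff[site]
  fruit_count <- reproductive *
    stats::rpois(n, exp(lp_fr + stats::rnorm(n, 0, truth$fruits$olre_sd)))

  out <- data.frame(
    id = seq_len(n), site = site, year = year,
    diameter_t = grid$unstd_size(z),
    diameter_t1 = grid$unstd_size(z1),
    survived = survived, broke = broke,
    resprouted = broke,  # all surviving breakers re-sprout in the generator
    reproductive = reproductive, fruit_count = fruit_count,
    canopy = canopy
  )
  stopifnot(all(out$fruit_count[out$reproductive == 0] == 0))
  out
}

#' Generate fruit-removal observations
#'
#' Each visit is assigned a species by multinomial draw on the relative
#' visit rates; handling is Bernoulli per species; handled fruits receive
#' a fate (crushed, else swallowed/removed or dropped) by the per-species
#' fate probabilities; the number of fruits handled is 1 plus a Poisson
#' draw. A configurable fraction of visits is marked as
#' handling-unobserved and a further fraction of non-handling visits is
#' recorded as exploratory pecking.
#'
#' @inheritParams generate_individuals
#' @param total_visits number of visits to generate.
#' @return A data frame: `species`, `visit`, `tree`, `handled`
#'   (`"yes"`/`"no"`/`"unobserved"`), `fate` (`"swallowed_removed"`,
#'   `"dropped"`, `"crushed"`, `"pecked_only"`, `"none"`),
#'   `fruits_handled`.
#' @export
generate_removals <- function(truth, total_visits,
                              seed = truth$seed + 2L) {
  validate_ground_truth(truth)
  sp <- truth$species
  if (nrow(sp) == 0) stop("empty species list")
  set.seed(seed)
  n <- total_visits
  idx <- sample.int(nrow(sp), n, replace = TRUE,
                    prob = sp$visit_rate / sum(sp$visit_rate))
  handled_flag <- stats::rbinom(n, 1, sp$p_handle[idx])
  crushed <- stats::rbinom(n, 1, sp$p_crush[idx])
  consumed <- stats::rbinom(n, 1, sp$p_consume[idx])
  fate <- ifelse(handled_flag == 0, "none",
                 ifelse(crushed == 1, "crushed",
                        ifelse(consumed == 1, "swallowed_removed",
                               "dropped")))
  pecked <- handled_flag == 0 &
    stats::runif(n) < truth$pecking_fraction / max(1e-12, 1 - mean(sp$p_handle[idx]))
  fate[pecked] <- "pecked_only"
  fruits <- handled_flag * (1L + stats::rpois(n, pmax(sp$mean_fruits[idx] - 1, 0)))
  handled <- ifelse(handled_flag == 1, "yes", "no")
  unobs <- stats::runif(n) < truth$unobserved_fraction
  handled[unobs] <- "unobserved"
  fate[unobs] <- "none"
  fruits[unobs] <- 0L
  out <- data.frame(
    species = sp$species[idx], visit = seq_len(n),
    tree = sample.int(52, n, replace = TRUE),
    handled = handled, fate = fate, fruits_handled = fruits,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$fruits_handled[out$handled == "no"] == 0))
  out
}

#' Generate scat records
#'
#' Scat canopy positions are drawn from the depositing species' scaled
#' Beta distribution over the canopy range; whether a scat contains seeds
#' of the focal tree is Bernoulli per species; a configurable fraction of
#' scats is flagged as coming from the designated hotspot segment (the
#' rule that excludes a heavily visited fruiting neighbour tree unless the
#' scat contains focal seeds).
#'
#' @inheritParams generate_individuals
#' @param n_scats number of scats to generate.
#' @return A data frame: `species`, `segment`, `canopy` (percent),
#'   `contains_focal`, `seed_count`, `excluded_hotspot`.
#' @export
generate_scats <- function(truth, n_scats, seed = truth$seed + 3L) {
  validate_ground_truth(truth)
  sp <- truth$species
  set.seed(seed)
  n <- n_scats
  idx <- sample.int(nrow(sp), n, replace = TRUE,
                    prob = sp$scat_weight / sum(sp$scat_weight))
  u <- stats::rbeta(n, sp$dep_shape1[idx], sp$dep_shape2[idx])
  canopy <- truth$canopy_range[1] + u * diff(truth$canopy_range)
  out <- data.frame(
    species = sp$species[idx],
    segment = pmin(10L, 1L + as.integer(u * 10)),
    canopy = canopy,
    contains_focal = stats::rbinom(n, 1, sp$p_focal[idx]),
    seed_count = 1L + stats::rpois(n, 2),
    excluded_hotspot = as.integer(stats::runif(n) < truth$hotspot_fraction),
    stringsAsFactors = FALSE
  )
  out
}

#' Generate sowing-experiment recruitment records
#'
#' Seedling counts are beta-binomial: each plot draws a recruitment
#' probability from a Beta distribution with mean `p` and intra-class
#' correlation `phi` (the binomial limit as `phi -> 0`), then seedlings
#' binomial out of `seeds_per_plot` sown seeds.
#'
#' @inheritParams generate_individuals
#' @param plots number of subplot-years.
#' @param seeds_per_plot seeds sown per subplot (default 25).
#' @param sites number of experimental sites.
#' @return A data frame: `site`, `plot`, `year`, `seeds_sown`,
#'   `seedlings`, `canopy`.
#' @export
generate_recruitment <- function(truth, plots, seeds_per_plot = 25,
                                 sites = 4, seed = truth$seed + 4L) {
  validate_ground_truth(truth)
  set.seed(seed)
  p <- truth$recruitment$p
  phi <- truth$recruitment$phi
  if (phi > 0 && p > 0 && p < 1) {
    theta <- (1 - phi) / phi
    pr <- stats::rbeta(plots, p * theta, (1 - p) * theta)
  } else {
    pr <- rep(p, plots)
  }
  u <- stats::rbeta(plots, truth$availability$shape1,
                    truth$availability$shape2)
  out <- data.frame(
    site = rep_len(seq_len(sites), plots),
    plot = seq_len(plots),
    year = rep_len(1:3, plots),
    seeds_sown = seeds_per_plot,
    seedlings = stats::rbinom(plots, seeds_per_plot, pr),
    canopy = truth$canopy_range[1] + u * diff(truth$canopy_range)
  )
  stopifnot(all(out$seedlings >= 0 & out$seedlings <= out$seeds_sown))
  out
}

#' Generate microhabitat (canopy-cover) availability samples
#'
#' Draws canopy-cover measurements from the availability distribution of
#' the truth: a Beta on the unit canopy range, by default tuned so that
#' the brighter half of the range holds 7.3% of the mass.
#'
#' @inheritParams generate_individuals
#' @param n number of measurements.
#' @return A numeric vector of canopy cover percentages.
#' @export
generate_microhabitat <- function(truth, n, seed = truth$seed + 5L) {
  validate_ground_truth(truth)
  set.seed(seed)
  u <- stats::rbeta(n, truth$availability$shape1, truth$availability$shape2)
  truth$canopy_range[1] + u * diff(truth$canopy_range)
}

#' Simulate the full five-table input dataset
#'
#' Convenience wrapper producing all five record types at the default
#' study dimensions: 1002 vital-rate transitions at 14 sites over 3 years,
#' 1006 frugivore visits, 1729 scats, 100 sowing subplot-years with 25
#' seeds each, and 600 canopy-cover measurements.
#'
#' @inheritParams generate_individuals
#' @param n_individuals,n_visits,n_scats,n_plots,seeds_per_plot,n_microhabitat
#'   dataset dimensions.
#' @param sites,years census dimensions.
#' @return A named list of the five data frames plus the `truth` used.
#' @export
simulate_dataset <- function(truth = default_ground_truth(),
                             n_individuals = 1002, sites = 14, years = 3,
                             n_visits = 1006, n_scats = 1729,
                             n_plots = 100, seeds_per_plot = 25,
                             n_microhabitat = 600) {
  list(
    individuals = generate_individuals(truth, n_individuals, sites, years),
    removals = generate_removals(truth, n_visits),
    scats = generate_scats(truth, n_scats),
    recruitment = generate_recruitment(truth, n_plots, seeds_per_plot),
    microhabitat = data.frame(canopy = generate_microhabitat(truth, n_microhabitat)),
    truth = truth
  )
}

#' Write a simulated dataset as delimiter-separated tables
#'
#' Writes the five record tables as tab-separated text with a one-line
#' header, plus a YAML manifest recording the ground truth and seed.
#'
#' @param data a list as returned by [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("individuals", "removals", "scats", "recruitment",
               "microhabitat")) {
    utils::write.table(data[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- data$truth
  manifest <- list(
    seed = truth$seed,
    species = truth$species,
    parameters = truth[setdiff(names(truth), c("species", "seed"))]
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
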