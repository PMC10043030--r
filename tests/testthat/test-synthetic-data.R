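test_that("generators are deterministic given a seed", {
  a <- generate_individuals(fix_truth, 200)
  b <- generate_individuals(fix_truth, 200)
  expect_identical(a, b)
  expect_identical(generate_removals(fix_truth, 300),
                   generate_removals(fix_truth, 300))
  expect_identical(generate_scats(fix_truth, 300),
                   generate_scats(fix_truth, 300))
  expect_identical(generate_recruitment(fix_truth, 40),
                   generate_recruitment(fix_truth, 40))
  expect_false(identical(generate_individuals(fix_truth, 200, seed = 1),
                         generate_individuals(fix_truth, 200, seed = 2)))
})

test_that("census generator respects saturated links and type invariants", {
  sat <- fix_truth
  sat$survival$coef[1] <- Inf
  ind <- generate_individuals(sat, 500)
  expect_true(all(ind$survived == 1))

  ind <- generate_individuals(fix_truth, 500)
  expect_true(all(ind$fruit_count[ind$reproductive == 0] == 0))
  expect_true(all(ind$diameter_t > 0))
  expect_true(all(is.na(ind$diameter_t1[ind$survived == 0])))
  expect_true(all(ind$canopy >= fix_truth$canopy_range[1] &
                    ind$canopy <= fix_truth$canopy_range[2]))
  expect_error(generate_individuals(fix_truth, 0), "n must be")
})

test_that("census survival matches the analytic generating mean at n = 20000", {
  n <- 20000
  ind <- generate_individuals(fix_truth, n, seed = 7L)
  # recompute the exact generating probabilities from the draw
  # (site/year effects integrate out across the sample): compare the
  # empirical rate with the analytic population mean by Monte Carlo
  g <- make_grid()
  z <- g$std_size(ind$diameter_t)
  cc <- g$std_canopy(ind$canopy)
  p_pop <- mean(vapply(seq_len(n), function(i) {
    mean(plogis(link_lp_for_test(fix_truth$survival$coef, z[i], cc[i]) +
                  fix_truth$survival$year_offsets))
  }, 0))
  expect_lt(abs(mean(ind$survived) - p_pop), 0.01)
})

test_that("removal fates match the generating probabilities at 50000 visits", {
  one <- fix_truth
  one$species <- one$species[1, ]
  one$species$p_handle <- 1
  one$species$p_crush <- 1
  one$unobserved_fraction <- 0
  r <- generate_removals(one, 200)
  expect_true(all(r$fate == "crushed"))
  expect_true(all(r$handled == "yes"))

  r0 <- generate_removals(fix_truth, 500, seed = 3L)
  expect_true(any(r0$handled == "unobserved"))
  no_unobs <- fix_truth
  no_unobs$unobserved_fraction <- 0
  expect_false(any(generate_removals(no_unobs, 500)$handled == "unobserved"))

  big <- generate_removals(fix_truth, 50000, seed = 11L)
  sp <- fix_truth$species
  for (s in c("blackcap", "hawfinch")) {
    i <- match(s, sp$species)
    rs <- big[big$species == s & big$handled == "yes", ]
    se_cr <- sqrt(sp$p_crush[i] * (1 - sp$p_crush[i]) / nrow(rs))
    expect_lt(abs(mean(rs$fate == "crushed") - sp$p_crush[i]), 3 * se_cr)
    unc <- rs[rs$fate != "crushed", ]
    se_co <- sqrt(sp$p_consume[i] * (1 - sp$p_consume[i]) / nrow(unc))
    expect_lt(abs(mean(unc$fate == "swallowed_removed") - sp$p_consume[i]),
              3 * se_co)
  }
  # per-species visit shares
  shares <- table(big$species)[sp$species] / nrow(big)
  expect_true(all(abs(shares - sp$visit_rate / sum(sp$visit_rate)) < 0.01))
})

test_that("scat canopy positions follow the deposition distributions", {
  pt <- fix_truth
  pt$hotspot_fraction <- 0
  s0 <- generate_scats(pt, 400)
  expect_true(all(s0$excluded_hotspot == 0))

  big <- generate_scats(fix_truth, 60000, seed = 5L)
  sp <- fix_truth$species
  for (s in c("blackcap", "marten")) {
    i <- match(s, sp$species)
    u <- (big$canopy[big$species == s] - fix_truth$canopy_range[1]) /
      diff(fix_truth$canopy_range)
    ks <- max(abs(ecdf(u)(seq(0.01, 0.99, by = 0.01)) -
                    pbeta(seq(0.01, 0.99, by = 0.01),
                          sp$dep_shape1[i], sp$dep_shape2[i])))
    expect_lt(ks, 0.02)
  }
})

test_that("recruitment counts are beta-binomial with the stated moments", {
  p0 <- fix_truth
  p0$recruitment <- list(p = 0, phi = 0.2)
  expect_true(all(generate_recruitment(p0, 100)$seedlings == 0))
  p1 <- fix_truth
  p1$recruitment <- list(p = 1, phi = 0)
  r1 <- generate_recruitment(p1, 100)
  expect_true(all(r1$seedlings == r1$seeds_sown))

  # phi -> 0 limit: variance approaches the binomial variance
  pb <- fix_truth
  pb$recruitment <- list(p = 0.1, phi = 0)
  r <- generate_recruitment(pb, 10000, seeds_per_plot = 25, seed = 9L)
  v_bin <- 25 * 0.1 * 0.9
  expect_lt(abs(var(r$seedlings) - v_bin), 0.15 * v_bin)

  # with overdispersion the beta-binomial variance applies
  phi <- fix_truth$recruitment$phi
  p <- fix_truth$recruitment$p
  r2 <- generate_recruitment(fix_truth, 10000, seeds_per_plot = 25,
                             seed = 13L)
  v_bb <- 25 * p * (1 - p) * (1 + 24 * phi)
  expect_lt(abs(var(r2$seedlings) - v_bb), 0.1 * v_bb)
  expect_lt(abs(mean(r2$seedlings) - 25 * p), 3 * sqrt(v_bb / 10000) * 25 * 0.1)
})

test_that("microhabitat availability puts ~7.3% of mass in the brighter half", {
  x <- generate_microhabitat(fix_truth, 1e5, seed = 21L)
  mid <- mean(fix_truth$canopy_range)
  expect_lt(abs(mean(x < mid) - 0.073), 0.01)

  unif <- fix_truth
  unif$availability <- list(shape1 = 1, shape2 = 1)
  xu <- generate_microhabitat(unif, 2e4)
  expect_lt(abs(mean(xu < mid) - 0.5), 0.02)
})

test_that("invalid ground truths are rejected", {
  bad <- fix_truth
  bad$species$p_crush[1] <- 1.4
  expect_error(validate_ground_truth(bad), "probabilities")
  bad2 <- fix_truth
  bad2$species$visit_rate[] <- 0
  expect_error(validate_ground_truth(bad2), "positive")
  bad3 <- fix_truth
  bad3$growth$sd <- 0
  expect_error(validate_ground_truth(bad3), "growth SD")
})

test_that("written tables round-trip through the readers", {
  dat <- simulate_dataset(fix_truth, n_individuals = 120, n_visits = 150,
                          n_scats = 200, n_plots = 20, n_microhabitat = 80)
  dir <- withr::local_tempdir()
  write_dataset(dat, dir)
  expect_true(file.exists(file.path(dir, "manifest.yml")))
  back <- suppressWarnings(read_input_tables(list(
    individuals = file.path(dir, "individuals.tsv"),
    removals = file.path(dir, "removals.tsv"),
    scats = file.path(dir, "scats.tsv"),
    recruitment = file.path(dir, "recruitment.tsv"),
    microhabitat = file.path(dir, "microhabitat.tsv"))))
  expect_equal(nrow(back$individuals), 120)
  expect_equal(back$removals$fruits_handled, dat$removals$fruits_handled)
})
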