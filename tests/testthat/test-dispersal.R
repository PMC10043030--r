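test_that("interaction frequency composes visits, handling and fruits", {
  # one species: 10 visits, handled in 5, mean 4 fruits -> raw 20
  r <- make_removals(rep("a", 10),
                     c(rep("yes", 5), rep("no", 5)),
                     c(rep("swallowed_removed", 5), rep("none", 5)),
                     c(4, 4, 4, 4, 4, 0, 0, 0, 0, 0))
  f <- interaction_frequency(r)
  expect_equal(f$raw, 20)
  expect_equal(f$freq, 1)

  # two species with raw 20 and 5 -> 0.8 / 0.2
  r2 <- rbind(r, make_removals(rep("b", 10),
                               c(rep("yes", 5), rep("no", 5)),
                               c(rep("dropped", 5), rep("none", 5)),
                               c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)))
  f2 <- interaction_frequency(r2)
  expect_equal(f2$freq[f2$species == "a"], 0.8)
  expect_equal(f2$freq[f2$species == "b"], 0.2)
  expect_equal(sum(f2$freq), 1)

  # pecking counts as a visit but not a handling; unobserved visits count
  # toward visits but not the handling denominator
  r3 <- make_removals(c("a", "a", "a", "a"),
                      c("yes", "no", "unobserved", "no"),
                      c("swallowed_removed", "pecked_only", "none", "none"),
                      c(2, 0, 0, 0))
  f3 <- interaction_frequency(r3)
  expect_equal(f3$visits, 4)
  expect_equal(f3$p_handle, 1 / 3)
  expect_equal(f3$raw, 4 * (1 / 3) * 2)

  # record order never matters
  f4 <- interaction_frequency(r2[sample(nrow(r2)), ])
  expect_equal(f4[order(f4$species), ], f2[order(f2$species), ],
               ignore_attr = TRUE)
})

test_that("fruit fates give crush and consumption probabilities", {
  # a species crushing 80% of handled fruits -> f_nocrush = 0.20
  r <- make_removals(rep("hf", 10), rep("yes", 10),
                     c(rep("crushed", 8), "swallowed_removed", "dropped"),
                     rep(1, 10))
  ff <- fruit_fates(r)
  expect_equal(ff$f_nocrush, 0.2)
  expect_equal(ff$f_consumed, 0.5)

  # all swallowed
  r2 <- make_removals(rep("a", 5), rep("yes", 5),
                      rep("swallowed_removed", 5), rep(2, 5))
  ff2 <- fruit_fates(r2)
  expect_equal(ff2$f_nocrush, 1)
  expect_equal(ff2$f_consumed, 1)
})

test_that("estimators recover the generating dispersal parameters", {
  big <- generate_removals(fix_truth, 50000, seed = 17L)
  f <- interaction_frequency(big)
  sp <- fix_truth$species
  raw_true <- sp$visit_rate * sp$p_handle * sp$mean_fruits
  freq_true <- raw_true / sum(raw_true)
  expect_true(all(abs(f$freq[match(sp$species, f$species)] - freq_true)
                  < 0.01))
  ff <- fruit_fates(big)
  # per-species 3-SE bands (weighted proportions: conservative design
  # effect of 1.3 for the fruits-handled weighting)
  for (s in sp$species) {
    i <- match(s, sp$species)
    j <- match(s, ff$species)
    n_h <- sum(big$species == s & big$handled == "yes")
    se_cr <- 1.3 * sqrt(sp$p_crush[i] * (1 - sp$p_crush[i]) / n_h)
    expect_lt(abs(ff$f_nocrush[j] - (1 - sp$p_crush[i])), 3 * se_cr + 1e-3)
    n_u <- round(n_h * (1 - sp$p_crush[i]))
    se_co <- 1.3 * sqrt(sp$p_consume[i] * (1 - sp$p_consume[i]) / n_u)
    expect_lt(abs(ff$f_consumed[j] - sp$p_consume[i]), 3 * se_co + 1e-3)
  }
})

test_that("deposition estimates sum to one and track the data", {
  g <- fix_grid
  # uniform scats -> near-uniform segment distribution
  set.seed(33)
  u <- runif(10000)
  sc <- data.frame(species = "a",
                   canopy = 64.8 + u * 27.3,
                   contains_focal = 1, seed_count = 1,
                   excluded_hotspot = 0)
  d <- deposition_distribution(sc, "a", g)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_lt(max(abs(d - 0.1)), 0.02)

  # all scats in one segment -> > 0.95 of mass there
  sc2 <- sc[1:2000, ]
  sc2$canopy <- runif(2000, 71.0, 72.0)   # inside segment 3
  d2 <- deposition_distribution(sc2, "a", g)
  expect_gt(d2[3], 0.95)

  # hotspot-excluded records are dropped unless they contain focal seeds
  sc3 <- sc
  sc3$excluded_hotspot <- 1
  sc3$contains_focal <- 0
  expect_error(deposition_distribution(sc3, "a", g), "pool")

  # below the floor the species must be pooled first
  expect_error(deposition_distribution(sc[1:10, ], "a", g), "pool")
})

test_that("microhabitat weights are a normalized histogram", {
  g <- fix_grid
  w <- microhabitat_weights(rep(66, 50), g)
  expect_equal(w[1], 1)
  expect_equal(sum(w), 1)

  x <- generate_microhabitat(fix_truth, 1e5, seed = 23L)
  w2 <- microhabitat_weights(x, g)
  u <- seq(0, 1, length.out = g$n_c + 1)
  analytic <- diff(pbeta(u, fix_truth$availability$shape1,
                         fix_truth$availability$shape2))
  expect_lt(max(abs(w2 - analytic)), 0.01)
})

test_that("brighter-half fractions behave under the random-dispersal null", {
  g <- fix_grid
  unif <- rep(0.1, 10)
  bf <- brightest_fraction(unif, unif, g)
  expect_equal(unname(bf["area_fraction"]), 0.5)
  expect_equal(bf[["seed_fraction"]], bf[["area_fraction"]])

  avail <- fix_weights(g)
  bf2 <- brightest_fraction(avail, avail, g)
  expect_lt(abs(bf2[["area_fraction"]] - 0.073), 0.01)
  # the main birds deposit far less than availability in the bright half
  dep <- fix_profiles(g)$deposition["blackcap", ]
  bf3 <- brightest_fraction(dep, avail, g)
  expect_lt(bf3[["seed_fraction"]], bf3[["area_fraction"]])
  expect_lt(abs(bf3[["seed_fraction"]] - 0.035), 0.01)
})

test_that("pooling merges rare species and conserves totals", {
  set.seed(55)
  rem <- generate_removals(fix_truth, 2000, seed = 19L)
  sc <- generate_scats(fix_truth, 1729, seed = 25L)
  prof <- estimate_disperser_profiles(rem, sc, fix_grid)
  expect_s3_class(prof, "disperser_profiles")
  expect_equal(sum(prof$profiles$freq), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(prof$deposition) - 1) < 1e-12))
  expect_true("other" %in% prof$profiles$species)
  expect_true(all(prof$profiles$n_scats[!prof$profiles$pooled] >= 30))

  # threshold below every species' scat count: output has no pooled row
  prof_all <- estimate_disperser_profiles(rem, sc, fix_grid,
                                          scat_threshold = 5)
  expect_false(any(prof_all$profiles$pooled))
  expect_equal(sum(prof_all$profiles$freq), 1, tolerance = 1e-12)

  # species present only in scats inherit the pooled removal parameters
  sc_extra <- rbind(sc, transform(sc[1:40, ], species = "camera_only"))
  prof2 <- suppressWarnings(
    estimate_disperser_profiles(rem, sc_extra, fix_grid))
  row <- prof2$profiles[prof2$profiles$species == "camera_only", ]
  other <- prof2$profiles[prof2$profiles$species == "other", ]
  expect_equal(row$f_nocrush, other$f_nocrush)
  expect_equal(sum(prof2$profiles$freq), 1, tolerance = 1e-12)
})

test_that("oracle profiles agree with estimated profiles at large n", {
  rem <- generate_removals(fix_truth, 60000, seed = 27L)
  sc <- generate_scats(fix_truth, 40000, seed = 29L)
  est <- estimate_disperser_profiles(rem, sc, fix_grid_small,
                                     scat_threshold = 30 * 40000 / 1729)
  tru <- fix_profiles(fix_grid_small)
  shared <- intersect(est$profiles$species, tru$profiles$species)
  expect_gte(length(shared), 6)
  for (s in shared) {
    i <- match(s, est$profiles$species); j <- match(s, tru$profiles$species)
    expect_lt(abs(est$profiles$freq[i] - tru$profiles$freq[j]), 0.015)
    expect_lt(max(abs(est$deposition[s, ] - tru$deposition[s, ])), 0.03)
  }
})
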