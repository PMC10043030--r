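test_that("power iteration matches closed-form eigenvalues", {
  expect_equal(lambda(diag(5)), 1, tolerance = 1e-10)
  # 2x2 oracle: trace/determinant closed form
  A <- matrix(c(0.5, 0.1, 0.2, 0.4), 2, 2)
  lam_oracle <- (0.9 + sqrt(0.9^2 - 4 * (0.5 * 0.4 - 0.2 * 0.1))) / 2
  expect_equal(lambda(A), lam_oracle, tolerance = 1e-9)
  expect_equal(lam_oracle, (0.9 + sqrt(0.01 + 0.08)) / 2)
  # homogeneity
  expect_equal(lambda(2 * A), 2 * lambda(A), tolerance = 1e-9)
  # left eigenvector: reproductive values satisfy u'K = lambda u'
  eig <- dominant_eigen(A, left = TRUE)
  expect_equal(as.vector(eig$stable_dist %*% A),
               eig$lambda * eig$stable_dist, tolerance = 1e-8)
  # zero kernel
  expect_equal(lambda(matrix(0, 3, 3)), 0)
  # non-convergence on a periodic kernel is an error (the growth-rate
  # estimate oscillates and never settles)
  cyc <- matrix(c(0, 0.5, 2, 0), 2, 2)
  expect_error(lambda(cyc, max_iter = 200), "did not converge")
})

test_that("structured kernels give the same eigenvalue as their dense form", {
  vr <- fix_vitals()
  g <- fix_grid_small
  K <- assemble(build_P(vr, g), build_F(vr, fix_profiles(g), g, 0.8))
  e_struct <- dominant_eigen(K)
  e_dense <- dominant_eigen(as.matrix(K))
  expect_equal(e_struct$lambda, e_dense$lambda, tolerance = 1e-9)
  bl <- kernel_baseline(K)
  expect_equal(weighted_growth(K, bl$stable_dist, bl$repro_value),
               bl$lambda, tolerance = 1e-8)
})

test_that("local growth rates respond to the canopy gradient as generated", {
  vr <- fix_vitals()
  g <- fix_grid_small
  loc <- local_lambdas(vr, g)
  expect_length(loc, g$n_c)
  # negative canopy effects make lambda strictly decreasing across segments
  expect_true(all(diff(loc) < 0))

  # canopy-independent vitals give equal local rates
  vr_flat <- vr
  vr_flat$survival$coef[4] <- 0
  vr_flat$growth$coef[4] <- 0
  vr_flat$repro$coef[4] <- 0
  vr_flat$fruits$coef[4] <- 0
  loc_flat <- local_lambdas(vr_flat, g)
  expect_lt(diff(range(loc_flat)), 1e-9)

  # dead habitat: no survival, no reproduction -> lambda 0
  vr0 <- vr
  vr0$survival$coef <- c(-Inf, 0, 0, 0)
  vr0$survival$year_offsets <- 0
  vr0$repro$coef <- c(-Inf, 0, 0, 0)
  vr0$repro$year_offsets <- 0
  expect_equal(max(local_lambdas(vr0, g)), 0)
})

test_that("gravity-weighted growth rate is the availability-weighted mean", {
  expect_equal(gravity_weighted_lambda(c(0.95, 1.16), c(0.9, 0.1)), 0.971)
  expect_equal(gravity_weighted_lambda(c(1.16, 0.95), c(1, 0)), 1.16)
  expect_equal(gravity_weighted_lambda(rep(1.02, 4), c(0.1, 0.4, 0.4, 0.1)),
               1.02)
  expect_error(gravity_weighted_lambda(1:3, c(0.5, 0.5)))
})

test_that("dispersal sweeps behave at their endpoints and under no transport", {
  vr <- fix_vitals()
  g <- fix_grid_small
  prof <- fix_profiles(g)
  w <- fix_weights(g)
  est <- dispersal_sweep(vr, prof, g, w, "fully_established", n_points = 11)
  gap <- dispersal_sweep(vr, prof, g, w, "gap_colonization", n_points = 11)
  # at f = 0 the curve is the availability-weighted gravity summary
  expect_equal(est$lambda[1],
               gravity_weighted_lambda(local_lambdas(vr, g), w))
  # scenario endpoints at f = 1 are identical
  expect_equal(est$lambda[11], gap$lambda[11], tolerance = 1e-10)
  # the gap-colonization benefit is at least the fully-established one
  expect_gte(attr(gap, "delta"), attr(est, "delta"))
  # animal dispersal is beneficial overall in both scenarios, and the gap
  # curve rises monotonically over the animal-dominated half of the sweep
  # (the low-f region carries the documented eigenvalue/weighted-summary
  # discontinuity)
  expect_gt(attr(est, "delta"), 0)
  expect_gt(attr(gap, "delta"), 0)
  expect_true(all(diff(gap$lambda[6:11]) > -1e-9))

  # no-transport limit: a one-species community that swallows everything,
  # deposits into the parent's own segment, and pays no within-fruit
  # penalty reproduces the gravity kernel block exactly, so animal
  # dispersal changes nothing
  vr1 <- vr
  vr1$constants$f_recfruit <- 1
  prof_self <- prof
  prof_self$profiles <- prof_self$profiles[1, , drop = FALSE]
  prof_self$profiles$freq <- 1
  prof_self$profiles$f_nocrush <- 1
  prof_self$profiles$f_consumed <- 1
  k <- 4
  dep <- matrix(0, 1, g$n_c, dimnames = list("blackcap", NULL))
  dep[1, k] <- 1
  prof_self$deposition <- dep
  F_a <- build_F(vr1, prof_self, g, 0.6, recfruit_on_gravity = FALSE)
  F_g <- build_F(vr1, NULL, g, 0, recfruit_on_gravity = FALSE)
  blk <- function(M, k) {
    idx <- ((k - 1) * g$n_z + 1):(k * g$n_z)
    as.matrix(M)[idx, idx]
  }
  expect_equal(blk(F_a, k), blk(F_g, k), tolerance = 1e-12)
})

test_that("interaction deficit is zero for absent species and negative for predators", {
  vr <- fix_vitals()
  g <- fix_grid_small
  prof <- fix_profiles(g)
  P <- build_P(vr, g)
  bl <- kernel_baseline(assemble(P, build_F(vr, prof, g, 1)))

  ghost <- prof
  ghost$profiles <- rbind(ghost$profiles, data.frame(
    species = "ghost", freq = 0, f_nocrush = 0.9, f_consumed = 0.8,
    n_scats = 50, pooled = FALSE))
  ghost$deposition <- rbind(ghost$deposition,
                            ghost = ghost$deposition["blackcap", ])
  d0 <- sde_deficit(vr, ghost, g, "ghost", baseline = bl, P = P)
  expect_lt(abs(d0$delta_lambda), 1e-7)

  d_bc <- sde_deficit(vr, prof, g, "blackcap", baseline = bl, P = P)
  d_hf <- sde_deficit(vr, prof, g, "hawfinch", baseline = bl, P = P)
  expect_gt(d_bc$delta_lambda, 0)
  expect_lte(d_hf$delta_lambda, 0)
  # effectiveness ordered by interaction frequency among the dispersers
  d_rb <- sde_deficit(vr, prof, g, "robin", baseline = bl, P = P)
  expect_gt(d_bc$delta_lambda, d_rb$delta_lambda)

  # deficit of the whole community: the asymptotic gravity-only kernel has
  # the maximum local rate as its dominant eigenvalue
  all_gone <- prof
  all_gone$profiles$f_nocrush[] <- 0
  K_all <- assemble(P, build_F(vr, all_gone, g, 1, extra_gravity = 1))
  expect_equal(lambda(K_all),
               max(local_lambdas(vr, g)), tolerance = 1e-6)
})

test_that("compensation rescales the community and is exact under exchangeability", {
  vr <- fix_vitals()
  g <- fix_grid_small
  prof <- fix_profiles(g)
  P <- build_P(vr, g)
  bl <- kernel_baseline(assemble(P, build_F(vr, prof, g, 1)))

  comp <- sde_compensation(vr, prof, g, "blackcap", baseline = bl, P = P)
  expect_equal(sum(comp$profiles$profiles$freq), 1, tolerance = 1e-12)
  expect_false("blackcap" %in% comp$profiles$profiles$species)

  # exchangeable species: compensation equals the baseline exactly
  ex <- prof
  ex$profiles$f_nocrush[] <- 0.95
  ex$profiles$f_consumed[] <- 0.8
  for (i in seq_len(nrow(ex$deposition)))
    ex$deposition[i, ] <- ex$deposition[1, ]
  bl_ex <- kernel_baseline(assemble(P, build_F(vr, ex, g, 1)))
  comp_ex <- sde_compensation(vr, ex, g, ex$profiles$species[2],
                              baseline = bl_ex, P = P)
  expect_equal(comp_ex$lambda_compensation, bl_ex$lambda,
               tolerance = 1e-8)
})

test_that("Markov-chain quality matches closed forms and a Monte-Carlo oracle", {
  vr <- fix_vitals()
  g <- fix_grid_small
  prof <- fix_profiles(g)
  # closed form: immediate reproduction and certain survival
  vr1 <- vr
  vr1$repro$coef <- c(Inf, 0, 0, 0); vr1$repro$year_offsets <- 0
  vr1$survival$coef <- c(Inf, 0, 0, 0); vr1$survival$year_offsets <- 0
  q1 <- quality_to_adulthood(vr1, prof, g, "blackcap",
                             drop_weighting = "availability",
                             weights = fix_weights(g))
  p <- prof$profiles[prof$profiles$species == "blackcap", ]
  oracle <- p$f_nocrush * vr$recruit *
    (p$f_consumed + (1 - p$f_consumed) * vr$constants$f_recfruit)
  expect_equal(unname(q1), oracle, tolerance = 1e-10)

  # no survival anywhere: quality zero
  vr0 <- vr
  vr0$survival$coef <- c(-Inf, 0, 0, 0); vr0$survival$year_offsets <- 0
  q0 <- quality_to_adulthood(vr0, prof, g, "blackcap",
                             drop_weighting = "availability",
                             weights = fix_weights(g))
  expect_equal(unname(q0), 0)

  # small-chain linear solve vs simulation (3 sizes x 2 canopies)
  set.seed(77)
  n_z <- 3; n_c <- 2
  S <- matrix(runif(n_z * n_c, 0.4, 0.9), n_z, n_c)
  R <- matrix(runif(n_z * n_c, 0.05, 0.35), n_z, n_c)
  G <- lapply(1:n_c, function(k) {
    M <- matrix(runif(n_z * n_z), n_z, n_z)
    sweep(M, 2, colSums(M), "/")
  })
  # linear solve under the package's event order
  Tm <- matrix(0, n_z * n_c, n_z * n_c)
  for (k in 1:n_c) {
    idx <- ((k - 1) * n_z + 1):(k * n_z)
    Tm[idx, idx] <- G[[k]] * rep(S[, k] * (1 - R[, k]), each = n_z)
  }
  r <- as.vector(S * R)
  l_solve <- solve(diag(n_z * n_c) - t(Tm), r)
  # Monte-Carlo oracle: simulate seed fates
  sim_one <- function(state) {
    for (step in 1:500) {
      i <- (state - 1) %% n_z + 1; k <- (state - 1) %/% n_z + 1
      if (runif(1) > S[i, k]) return(0)
      if (runif(1) < R[i, k]) return(1)
      state <- (k - 1) * n_z + sample(n_z, 1, prob = G[[k]][, i])
    }
    0
  }
  n_sim <- 20000
  for (s0 in c(1, 4)) {
    hits <- mean(replicate(n_sim, sim_one(s0)))
    se <- sqrt(hits * (1 - hits) / n_sim)
    expect_lt(abs(hits - l_solve[s0]), 3 * se + 1e-9)
  }

  # full-model quality lies in [0, 1] and predators score lowest
  qa <- quality_to_adulthood(vr, prof, g)
  expect_true(all(qa >= 0 & qa <= 1))
  expect_equal(names(which.min(qa)), "hawfinch")
})

test_that("rank correlations flag degenerate components instead of NaN", {
  sde <- data.frame(
    species = letters[1:6],
    quantity = c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04),
    quality = rep(0.2, 6),
    delta_lambda_deficit = c(0.05, 0.03, 0.02, 0.012, 0.007, 0.004))
  ct <- sde_correlations(sde)
  expect_equal(ct$rho[ct$component == "quantity"], 1)
  expect_true(is.na(ct$rho[ct$component == "quality"]))
  expect_match(ct$note[ct$component == "quality"], "undefined")
})

test_that("effectiveness on the default fixture is quantity-dominated", {
  vr <- fix_vitals()
  g <- fix_grid_small
  prof <- fix_profiles(g)
  w <- fix_weights(g)
  sde <- sde_table(vr, prof, g, w)
  expect_equal(sum(sde$quantity), 1, tolerance = 1e-12)
  expect_true(all(sde$quality >= 0 & sde$quality <= 1))
  ct <- sde_correlations(sde)
  rho_qty <- ct$rho[ct$component == "quantity"]
  rho_qlt <- ct$rho[ct$component == "quality"]
  expect_gt(rho_qty, 0.8)
  expect_gt(rho_qty, abs(rho_qlt))
  # compensation buffers the loss of the top disperser: the functional
  # loss is far smaller than the deficit loss
  top <- sde$species[which.max(sde$quantity)]
  row <- sde[sde$species == top, ]
  base <- attr(sde, "lambda_base")
  expect_gt(row$lambda_compensation, base - row$delta_lambda_deficit)
})
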