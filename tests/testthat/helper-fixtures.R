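# shared fixtures: the frozen default truth, a small grid for fast kernel
# tests, and oracle profiles derived from the truth
fix_truth <- default_ground_truth(seed = 424242L)

fix_grid_small <- make_grid(n_z = 40)
fix_grid <- make_grid()

fix_vitals <- function() as_vital_rate_model(fix_truth)
fix_profiles <- function(grid = fix_grid_small) true_profiles(fix_truth, grid)

# availability weights implied by the truth's Beta availability, computed
# analytically (no sampling noise)
fix_weights <- function(grid = fix_grid_small) {
  u <- seq(0, 1, length.out = grid$n_c + 1)
  diff(pbeta(u, fix_truth$availability$shape1,
             fix_truth$availability$shape2))
}

candidate_formulas_for_test <- function(response) {
  disperseIPM:::candidate_formulas(response, random = NULL)
}

# linear predictor on the (intercept, z, z^2, c) layout, for oracles
link_lp_for_test <- function(coef, z, c = 0) {
  coef[1] + coef[2] * z + coef[3] * z^2 + coef[4] * c
}

# a minimal removal table builder for estimator unit tests
make_removals <- function(species, handled, fate, fruits) {
  data.frame(species = species, visit = seq_along(species),
             tree = 1L, handled = handled, fate = fate,
             fruits_handled = fruits, stringsAsFactors = FALSE)
}
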