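# bin-to-bin (cumulative kernel) discretization of a Gaussian transition:
# column j = probability of moving from source mean[j] into each
# destination bin, as CDF differences at the bin edges; probability mass
# outside the range is folded into the two outer bins (no eviction), so
# every column sums to one by construction.
bin_to_bin <- function(edges, mean, sd) {
  n <- length(edges) - 1L
  sd <- rep_len(sd, length(mean))
  vapply(seq_along(mean), function(j) {
    p <- stats::pnorm(edges, mean[j], sd[j])
    d <- diff(p)
    d[1] <- d[1] + p[1]
    d[n] <- d[n] + 1 - p[n + 1]
    d
  }, numeric(n))
}

#' Size-to-size growth operator for one canopy segment
#'
#' Builds the discretized growth kernel `G` at a fixed canopy segment
#' using cumulative-kernel (bin-to-bin) integration: source sizes are
#' evaluated at bin midpoints, destination probabilities are differences
#' of the growth CDF at the destination bin edges, and out-of-range mass
#' is folded into the outer bins. Every column sums to exactly one.
#'
#' @param vitals a [vital_rate_model()].
#' @param grid an [ipm_grid][make_grid].
#' @param segment canopy segment index (1-based).
#' @return An `n_z x n_z` matrix; column = source bin.
#' @export
growth_operator <- function(vitals, grid, segment = 1) {
  sd <- vr_growth_sd(vitals)
  if (!is.finite(sd) || sd <= 0) stop("growth SD must be positive")
  mu <- vr_growth_mean(vitals, grid$z_mid, grid$c_mid[segment])
  bin_to_bin(grid$z_edges, mu, sd)
}

# re-sprout size operator (size only; canopy-independent)
resprout_operator <- function(vitals, grid) {
  sd <- vr_resprout_sd(vitals, grid$z_mid)
  if (any(!is.finite(sd) | sd <= 0)) stop("re-sprout SD must be positive")
  bin_to_bin(grid$z_edges, vr_resprout_mean(vitals, grid$z_mid), sd)
}

#' Discretized seedling size distribution
#'
#' Probability, per size bin, of a new recruit starting in that bin: a
#' truncated normal on the diameter (cm) scale, renormalized above its
#' lower bound, mapped through the log10 standardization and discretized
#' by CDF differences at the bin edges (upper tail folded into the top
#' bin). Sums to one.
#'
#' @inheritParams growth_operator
#' @return Numeric vector of length `grid$n_z`.
#' @export
fdist_probs <- function(vitals, grid) {
  s <- vitals$constants$seedling
  d_edges <- grid$unstd_size(grid$z_edges)
  p_lb <- stats::pnorm(s[["lower"]], s[["mean"]], s[["sd"]])
  cdf <- (stats::pnorm(pmax(d_edges, s[["lower"]]), s[["mean"]], s[["sd"]]) -
            p_lb) / (1 - p_lb)
  pr <- diff(cdf)
  pr[grid$n_z] <- pr[grid$n_z] + 1 - cdf[grid$n_z + 1]
  pr
}

# expected fruit production f_repr * f_fruit at every grid point
fruit_production <- function(vitals, grid) {
  outer(grid$z_mid, grid$c_mid, function(z, c)
    vr_repro(vitals, z, c) * vr_fruits(vitals, z, c))
}

#' Survival/growth operator P
#'
#' `P = S(z,c) (1 - B(z)) G(z'|z,c) + S(z,c) B(z) R(z'|z)` applied per
#' canopy segment: survivors either grow in place or, after breakage,
#' re-sprout with a strongly reduced size. P never moves individuals
#' between canopy segments (block-diagonal in canopy).
#'
#' @inheritParams growth_operator
#' @return An object of class `ipm_P`: per-segment blocks plus the grid.
#' @export
build_P <- function(vitals, grid) {
  R <- resprout_operator(vitals, grid)
  B <- vr_breakage(vitals, grid$z_mid)
  blocks <- lapply(seq_len(grid$n_c), function(k) {
    S <- vr_survival(vitals, grid$z_mid, grid$c_mid[k])
    G <- growth_operator(vitals, grid, k)
    G * rep(S * (1 - B), each = grid$n_z) +
      R * rep(S * B, each = grid$n_z)
  })
  structure(list(blocks = blocks, grid = grid), class = "ipm_P")
}

#' @export
as.matrix.ipm_P <- function(x, ...) {
  n_z <- x$grid$n_z; n_c <- x$grid$n_c
  M <- matrix(0, n_z * n_c, n_z * n_c)
  for (k in seq_len(n_c)) {
    idx <- state_index(x$grid, seq_len(n_z), k)
    M[idx, idx] <- x$blocks[[k]]
  }
  M
}

#' Species-resolved fecundity operator F
#'
#' Builds the fecundity kernel as a parameterized object rather than a
#' dense matrix, so species-level scenario edits (interaction deficit,
#' compensation, dispersal sweeps) are parameter edits. Three pathways per
#' reproductive individual at `(z, c)`, all proportional to
#' `f_repr(z,c) f_fruit(z,c) f_seed f_recruit f_dist(z')`:
#'
#' * consumed by species `x` (weight `a q_x f_nocrush_x f_consumed_x`):
#'   offspring canopy drawn from the species' deposition distribution —
#'   the only pathway that moves seeds between canopy segments;
#' * dropped by species `x` (weight
#'   `a q_x f_nocrush_x (1 - f_consumed_x) f_recfruit`): offspring stay
#'   under the parent's canopy, seeds still inside the fruit pay the
#'   within-fruit germination penalty;
#' * gravity (weight `1 - a`): same canopy; pays the within-fruit penalty
#'   by default (`recfruit_on_gravity = FALSE` reproduces the variant
#'   without it).
#'
#' `a` is the proportion of fruits removed by the animal community
#' (`f_rel_anim_disp`).
#'
#' @param vitals a [vital_rate_model()].
#' @param profiles a `disperser_profiles` object (frequencies summing
#'   to 1) or `NULL` for a gravity-only kernel.
#' @param grid an [ipm_grid][make_grid].
#' @param f_rel_anim_disp proportion of fruits dispersed by animals, in
#'   \[0, 1\].
#' @param recfruit_on_gravity apply the within-fruit germination
#'   multiplier to gravity-dispersed seeds (default `TRUE`).
#' @param gravity_mask optional per-segment 0/1 multiplier on the
#'   gravity-type pathways (used by the gap-colonization scenario).
#' @param extra_gravity additional interaction-frequency mass rerouted to
#'   the gravity pathway (with the within-fruit penalty, scaled by
#'   `f_rel_anim_disp`); this is how the interaction-deficit scenario
#'   lets a lost disperser's seeds fall by gravity instead.
#' @return An object of class `ipm_F`.
#' @export
build_F <- function(vitals, profiles, grid, f_rel_anim_disp = 1,
                    recfruit_on_gravity = TRUE, gravity_mask = NULL,
                    extra_gravity = 0) {
  if (f_rel_anim_disp < 0 || f_rel_anim_disp > 1)
    stop("f_rel_anim_disp must lie in [0, 1]")
  if (!is.null(profiles)) validate_profiles(profiles)
  structure(list(
    fdist = fdist_probs(vitals, grid),
    phi = fruit_production(vitals, grid),
    profiles = profiles,
    a = f_rel_anim_disp,
    f_seed = vitals$constants$f_seed,
    f_recruit = vitals$recruit,
    f_recfruit = vitals$constants$f_recfruit,
    recfruit_on_gravity = recfruit_on_gravity,
    gravity_mask = if (is.null(gravity_mask)) rep(1, grid$n_c)
                   else rep_len(gravity_mask, grid$n_c),
    extra_gravity = rep_len(extra_gravity, grid$n_c),
    grid = grid
  ), class = "ipm_F")
}

# per-species pathway coefficients and the per-segment gravity-type
# coefficient of an ipm_F object
fecundity_coefs <- function(f) {
  base <- f$f_seed * f$f_recruit
  grav_pen <- if (f$recfruit_on_gravity) f$f_recfruit else 1
  if (is.null(f$profiles)) {
    A <- B <- numeric(0); D <- matrix(0, 0, f$grid$n_c)
  } else {
    p <- f$profiles$profiles
    A <- f$a * p$freq * p$f_nocrush * p$f_consumed * base
    B <- f$a * p$freq * p$f_nocrush * (1 - p$f_consumed) * base *
      f$f_recfruit
    D <- f$profiles$deposition
  }
  grav <- ((1 - f$a) * grav_pen + f$a * f$extra_gravity * f$f_recfruit) *
    base * f$gravity_mask
  list(
    transport = if (length(A)) as.vector(t(D) %*% A) else
      numeric(f$grid$n_c),                       # destination-segment weights
    local = sum(B) + grav                        # per source segment
  )
}

#' @export
as.matrix.ipm_F <- function(x, ...) {
  co <- fecundity_coefs(x)
  n_z <- x$grid$n_z; n_c <- x$grid$n_c
  u <- as.vector(outer(x$fdist, co$transport))   # destination profile
  M <- u %*% t(as.vector(x$phi))
  for (k in seq_len(n_c)) {
    idx <- state_index(x$grid, seq_len(n_z), k)
    M[idx, idx] <- M[idx, idx] + co$local[k] * (x$fdist %*% t(x$phi[, k]))
  }
  M
}

#' Assemble the full projection kernel
#'
#' `K = P + F` on the `(size x canopy)` state space. The result keeps the
#' block structure, exposing a fast matrix-vector product for the power
#' iteration; use [as.matrix()] for the dense kernel.
#'
#' @param P an `ipm_P` object (or `NULL` for fecundity only).
#' @param F_ an `ipm_F` object (or `NULL` for survival/growth only).
#' @return An object of class `ipm_kernel` with a `matvec` closure and
#'   `dim` (state dimension).
#' @export
assemble <- function(P, F_ = NULL) {
  grid <- if (!is.null(P)) P$grid else F_$grid
  n_z <- grid$n_z; n_c <- grid$n_c
  co <- if (!is.null(F_)) fecundity_coefs(F_) else NULL
  matvec <- function(v) {
    out <- numeric(n_z * n_c)
    vm <- matrix(v, n_z, n_c)
    if (!is.null(P)) {
      for (k in seq_len(n_c)) {
        idx <- ((k - 1) * n_z + 1):(k * n_z)
        out[idx] <- P$blocks[[k]] %*% vm[, k]
      }
    }
    if (!is.null(F_)) {
      g <- colSums(F_$phi * vm)       # fruit output per source segment
      local_part <- F_$fdist %*% t(co$local * g)
      transport <- sum(g) * outer(F_$fdist, co$transport)
      out <- out + as.vector(local_part + transport)
    }
    out
  }
  matvec_t <- function(u) {            # t(K) %*% u
    out <- numeric(n_z * n_c)
    um <- matrix(u, n_z, n_c)
    if (!is.null(P)) {
      for (k in seq_len(n_c)) {
        idx <- ((k - 1) * n_z + 1):(k * n_z)
        out[idx] <- crossprod(P$blocks[[k]], um[, k])
      }
    }
    if (!is.null(F_)) {
      uf <- colSums(um * F_$fdist)     # recruit value per segment
      per_source <- sum(co$transport * uf) + co$local * uf
      out <- out + as.vector(F_$phi * rep(per_source, each = n_z))
    }
    out
  }
  structure(list(P = P, F_ = F_, grid = grid, dim = n_z * n_c,
                 matvec = matvec, matvec_t = matvec_t),
            class = "ipm_kernel")
}

#' @export
as.matrix.ipm_kernel <- function(x, ...) {
  M <- if (!is.null(x$P)) as.matrix(x$P) else
    matrix(0, x$dim, x$dim)
  if (!is.null(x$F_)) M <- M + as.matrix(x$F_)
  M
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat("IPM kernel on", x$dim, "states (", x$grid$n_z, "size bins x",
      x$grid$n_c, "canopy segments )\n")
  if (!is.null(x$F_))
    cat("  f_rel_anim_disp =", x$F_$a, "\n")
  invisible(x)
}
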