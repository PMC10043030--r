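#' Default pipeline configuration
#'
#' @param seed master seed recorded in every output.
#' @return Nested list of all configuration defaults; any subset can be
#'   overridden through the `config` argument of [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = NULL,
    simulate = list(enabled = TRUE, n_individuals = 1002, sites = 14,
                    years = 3, n_visits = 1006, n_scats = 1729,
                    n_plots = 100, seeds_per_plot = 25,
                    n_microhabitat = 600),
    tables = NULL,
    grid = list(n_z = 100, n_c = 10),
    fit = list(select = TRUE, random = "(1|site)"),
    scenarios = list(recfruit_on_gravity = TRUE, sweep_points = 11,
                     scat_threshold = 30),
    bootstrap = list(B = 500, level = 0.95, enabled = FALSE)
  )
}

# deep merge of user config into defaults, logging defaulted keys
merge_config <- function(defaults, user, path = "", log = NULL) {
  if (is.null(log)) log <- new.env()
  if (is.null(log$defaulted)) log$defaulted <- character(0)
  out <- defaults
  for (nm in names(defaults)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!is.null(user[[nm]])) {
      if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
        out[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key, log)
      } else {
        out[[nm]] <- user[[nm]]
      }
    } else {
      log$defaulted <- c(log$defaulted, key)
    }
  }
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown configuration field(s): ",
         paste(if (nzchar(path)) paste0(path, ".", extra) else extra,
               collapse = ", "))
  attr(out, "defaulted") <- log$defaulted
  out
}

#' Run the full pipeline
#'
#' Executes every stage in order — simulate (or read) the five input
#' tables, fit the vital rates, estimate disperser profiles and
#' microhabitat weights, build the kernels, run the demographic analyses
#' (local growth rates, gravity-weighted rate, dispersal sweeps for both
#' scenarios, per-species effectiveness with deficit and compensation,
#' rank correlations), and optionally bootstrap prediction intervals —
#' and writes a machine-readable summary plus result tables.
#'
#' @param config a nested list (see [default_config()]) or the path to a
#'   YAML file with the same structure. `config$tables` (named file
#'   paths) replaces simulation by real input tables.
#' @param quiet suppress stage messages.
#' @return A list with all stage results (`data`, `vitals`, `profiles`,
#'   `weights`, `grid`, `local_lambdas`, `sweeps`, `sde`, `correlations`,
#'   `bootstrap`, `summary`, `config`). When `config$output_dir` is set,
#'   `summary.json`, `sde.tsv`, `sweep.tsv`, an optional `bootstrap.tsv`
#'   and a run log are written there.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  log_lines <- c(sprintf("run started %s", format(Sys.time())),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("defaulted config keys: %s",
                         paste(attr(cfg, "defaulted"), collapse = ", ")))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  grid <- stage("grid", make_grid(n_z = cfg$grid$n_z, n_c = cfg$grid$n_c))

  data <- stage("data", {
    if (!is.null(cfg$tables)) {
      say("reading input tables")
      read_input_tables(cfg$tables)
    } else if (isTRUE(cfg$simulate$enabled)) {
      say("simulating input tables (seed ", cfg$seed, ")")
      s <- cfg$simulate
      simulate_dataset(default_ground_truth(seed = cfg$seed),
                       n_individuals = s$n_individuals, sites = s$sites,
                       years = s$years, n_visits = s$n_visits,
                       n_scats = s$n_scats, n_plots = s$n_plots,
                       seeds_per_plot = s$seeds_per_plot,
                       n_microhabitat = s$n_microhabitat)
    } else {
      stop("no input tables configured and simulation disabled")
    }
  })
  stage("validate", validate_tables(data))

  say("fitting vital rates")
  vitals <- stage("vital_rates", fit_vital_rates(
    data$individuals, data$recruitment, grid,
    select = cfg$fit$select, random = cfg$fit$random))

  say("estimating disperser profiles")
  profiles <- stage("dispersal", estimate_disperser_profiles(
    data$removals, data$scats, grid,
    scat_threshold = cfg$scenarios$scat_threshold))
  weights <- stage("dispersal",
                   microhabitat_weights(data$microhabitat$canopy, grid))

  say("building kernels and running demographic analyses")
  res <- stage("demography", {
    P <- build_P(vitals, grid)
    loc <- local_lambdas(vitals, grid,
                         cfg$scenarios$recfruit_on_gravity, P = P)
    lam_grav <- gravity_weighted_lambda(loc, weights)
    sweeps <- rbind(
      dispersal_sweep(vitals, profiles, grid, weights,
                      "fully_established", cfg$scenarios$sweep_points,
                      cfg$scenarios$recfruit_on_gravity, P = P),
      dispersal_sweep(vitals, profiles, grid, weights,
                      "gap_colonization", cfg$scenarios$sweep_points,
                      cfg$scenarios$recfruit_on_gravity, P = P))
    sde <- sde_table(vitals, profiles, grid, weights,
                     lambda_gravity = lam_grav,
                     recfruit_on_gravity = cfg$scenarios$recfruit_on_gravity)
    list(P = P, local = loc, lambda_gravity = lam_grav, sweeps = sweeps,
         sde = sde, correlations = sde_correlations(sde))
  })

  boot <- NULL
  if (isTRUE(cfg$bootstrap$enabled) && cfg$bootstrap$B >= 2) {
    say("bootstrapping (", cfg$bootstrap$B, " replicates)")
    boot <- stage("bootstrap", bootstrap_pipeline(
      data, sde_statistic(vitals, grid, weights,
                          cfg$scenarios$scat_threshold),
      bootstrap_spec(B = cfg$bootstrap$B, level = cfg$bootstrap$level,
                     seed = cfg$seed)))
  }

  est <- res$sweeps[res$sweeps$scenario == "fully_established", ]
  gap <- res$sweeps[res$sweeps$scenario == "gap_colonization", ]
  summary <- list(
    seed = cfg$seed,
    grid = list(n_z = grid$n_z, n_c = grid$n_c),
    lambda_gravity_weighted = res$lambda_gravity,
    lambda_full_animal = est$lambda[nrow(est)],
    delta_lambda_fully_established = attr(est, "delta"),
    delta_lambda_gap_colonization = gap$lambda[nrow(gap)] - gap$lambda[1],
    local_lambdas = res$local,
    sweep = res$sweeps,
    sde = res$sde[, c("species", "quantity", "quality",
                      "delta_lambda_deficit", "relative_reduction_pct",
                      "lambda_compensation")],
    correlations = res$correlations,
    bootstrap = if (!is.null(boot))
      boot[, c("quantity", "point", "lo", "hi", "B", "seed")]
  )
  # fully-established and gap sweeps share attr names; recompute cleanly
  summary$delta_lambda_fully_established <-
    est$lambda[nrow(est)] - est$lambda[1]

  out <- list(data = data, grid = grid, vitals = vitals,
              profiles = profiles, weights = weights,
              local_lambdas = res$local,
              lambda_gravity = res$lambda_gravity, sweeps = res$sweeps,
              sde = res$sde, correlations = res$correlations,
              bootstrap = boot, summary = summary, config = cfg)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    utils::write.table(res$sde, file.path(cfg$output_dir, "sde.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$sweeps, file.path(cfg$output_dir, "sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(boot))
      utils::write.table(boot, file.path(cfg$output_dir, "bootstrap.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    files <- list.files(cfg$output_dir, full.names = TRUE,
                        pattern = "\\.(json|tsv)$")
    log_lines <- c(log_lines,
                   sprintf("%s  md5 %s", basename(files),
                           tools::md5sum(files)),
                   sprintf("run finished %s", format(Sys.time())))
    writeLines(log_lines, file.path(cfg$output_dir, "run_log.txt"))
  }
  invisible(out)
}
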