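# required columns per input table
table_schemas <- list(
  individuals = c("id", "site", "year", "diameter_t", "diameter_t1",
                  "survived", "broke", "resprouted", "reproductive",
                  "fruit_count", "canopy"),
  removals = c("species", "visit", "handled", "fate", "fruits_handled"),
  scats = c("species", "canopy", "contains_focal", "seed_count",
            "excluded_hotspot"),
  recruitment = c("site", "plot", "year", "seeds_sown", "seedlings",
                  "canopy"),
  microhabitat = c("canopy")
)

#' Read the five input tables
#'
#' Reads tab- or comma-separated tables with a one-line header, as written
#' by [write_dataset()] (the same schemas accepted for real field data),
#' and validates them.
#'
#' @param paths named list/vector of file paths (names as in
#'   [validate_tables()]).
#' @return Named list of data frames.
#' @export
read_input_tables <- function(paths) {
  tabs <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("input table '", nm, "' not found: ", p)
    if (file.size(p) == 0) stop("input table '", nm, "' is an empty file")
    utils::read.delim(p, sep = "", header = TRUE,
                      stringsAsFactors = FALSE)
  })
  names(tabs) <- names(paths)
  validate_tables(tabs)
  tabs
}

#' Validate input tables
#'
#' Checks headers, value ranges (canopy cover within \[0, 100\], positive
#' diameters, 0/1 flags, seedlings within sown seeds) with offending row
#' numbers, and referential integrity across tables: species appearing in
#' scats but never in removal observations are reported as a warning (they
#' are handled downstream by the rare-species pooling rule).
#'
#' @param tables named list of data frames; recognized names are
#'   `individuals`, `removals`, `scats`, `recruitment`, `microhabitat`.
#' @return The tables, invisibly; violations raise errors (or warnings
#'   where stated).
#' @export
validate_tables <- function(tables) {
  bad_rows <- function(cond) which(cond & !is.na(cond))
  fail <- function(tab, col, rows, msg) {
    stop(sprintf("table '%s', column '%s': %s (rows %s)", tab, col, msg,
                 paste(utils::head(rows, 5), collapse = ", ")))
  }
  for (nm in intersect(names(tables), names(table_schemas))) {
    df <- tables[[nm]]
    if (is.null(df) || nrow(df) == 0)
      stop("table '", nm, "' is empty")
    missing <- setdiff(table_schemas[[nm]], names(df))
    if (length(missing))
      stop("table '", nm, "' is missing required columns: ",
           paste(missing, collapse = ", "))
    if ("canopy" %in% names(df)) {
      r <- bad_rows(df$canopy < 0 | df$canopy > 100)
      if (length(r)) fail(nm, "canopy", r, "canopy cover outside [0, 100]")
    }
    for (col in intersect(c("diameter_t", "diameter_t1"), names(df))) {
      r <- bad_rows(df[[col]] <= 0)
      if (length(r)) fail(nm, col, r, "diameters must be positive")
    }
    for (col in intersect(c("survived", "broke", "resprouted",
                            "reproductive", "contains_focal",
                            "excluded_hotspot"), names(df))) {
      r <- bad_rows(!(df[[col]] %in% c(0, 1)))
      if (length(r)) fail(nm, col, r, "flag must be 0/1")
    }
    if (all(c("seedlings", "seeds_sown") %in% names(df))) {
      r <- bad_rows(df$seedlings < 0 | df$seedlings > df$seeds_sown)
      if (length(r)) fail(nm, "seedlings", r,
                          "seedling count outside [0, seeds_sown]")
    }
  }
  if (all(c("removals", "scats") %in% names(tables))) {
    only_scats <- setdiff(unique(tables$scats$species),
                          unique(tables$removals$species))
    if (length(only_scats))
      warning("species present in scats but absent from removals ",
              "(handled by the rare-species rule): ",
              paste(only_scats, collapse = ", "))
  }
  invisible(tables)
}
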