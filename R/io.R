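# Scoring-table CSV I/O with validation, and run-config reading.

SCORING_COLUMNS <- c("experiment", "vial", "sex", "dsred", "gfp", "body",
                     "eye", "count", "indel")

#' Read / write a scoring table
#'
#' CSV schema: header `experiment,vial,sex,dsred,gfp,body,eye,count,indel`.
#' `write_scoring_csv` then `read_scoring_csv` is lossless.  Unknown extra
#' columns are ignored with a warning; malformed rows (negative or
#' non-integer counts) are reported with their line numbers.  `col_map`
#' lets single-sheet exports of differently-headed scoring spreadsheets be
#' imported by naming which of their columns plays each schema role, e.g.
#' `c(vial = "Vial ID", dsred = "DsRed", count = "Flies")`.
#'
#' @param path CSV path.
#' @param col_map optional named character vector mapping schema column
#'   names to the file's column names.
#' @return `read_scoring_csv`: a validated scoring `data.frame`.
#' @export
read_scoring_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!is.null(col_map))
    names(df)[match(col_map, names(df))] <- names(col_map)
  missing <- setdiff(setdiff(SCORING_COLUMNS, "indel"), names(df))
  if (length(missing) > 0)
    stop("scoring file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), SCORING_COLUMNS)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if (!"indel" %in% names(df)) df$indel <- NA_character_
  bad <- which(is.na(df$count) | df$count < 0 |
                 df$count != as.integer(df$count))
  if (length(bad) > 0)
    stop("invalid count at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (counts must be non-negative integers)", call. = FALSE)
  df$count <- as.integer(df$count)
  df$indel <- as.character(df$indel)
  df$indel[df$indel %in% c("", "NA")] <- NA_character_
  df[, SCORING_COLUMNS]
}

#' @rdname read_scoring_csv
#' @param table a scoring `data.frame`.
#' @export
write_scoring_csv <- function(table, path) {
  stopifnot(all(setdiff(SCORING_COLUMNS, "indel") %in% names(table)))
  if (!"indel" %in% names(table)) table$indel <- NA_character_
  utils::write.csv(table[, SCORING_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a run configuration
#'
#' A single JSON document naming the architecture, drive parameters,
#' life-history parameters, release schedule and run plan; unknown keys are
#' rejected so typos fail loudly.  All defaults are filled in and the
#' resolved configuration is attached as an attribute for provenance.
#'
#' @param path JSON file.
#' @return a [scenario()].
#' @export
read_run_config <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path))
    stop("no such config file: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("architecture", "recomb_fraction", "q", "c", "d", "rho",
             "suppression", "fertility_locus", "life_history", "releases",
             "sim_mode", "replicates", "horizon_days", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  arch <- drive_architecture(cfg$architecture,
                             recomb_fraction = cfg$recomb_fraction)
  suppression <- isTRUE(cfg$suppression)
  params <- cube_params(
    arch,
    q = cfg$q %||% 1, c_conv = cfg$c %||% 1, d = cfg$d %||% 0,
    rho = cfg$rho %||% 1,
    fertility_rule = if (suppression)
      fertility_rule_functional(cfg$fertility_locus) else NULL)
  lh <- cfg$life_history %||% list()
  life <- do.call(life_history_params, lh)
  rel <- if (is.null(cfg$releases))
    release_schedule(genotype = drive_release_genotype(arch))
  else do.call(release_schedule, c(cfg$releases[setdiff(names(cfg$releases),
                                                        "genotype")],
    list(genotype = cfg$releases$genotype %||%
           drive_release_genotype(arch))))
  scn <- scenario(arch, params, life = life, releases = rel,
                  mode = if (suppression) "suppression" else "replacement",
                  sim_mode = cfg$sim_mode %||% "stochastic",
                  replicates = cfg$replicates %||% 1L,
                  horizon_days = cfg$horizon_days %||% 365L,
                  seed = cfg$seed %||% 1L)
  attr(scn, "resolved_config") <- cfg
  scn
}

#' Write ensemble trajectories as tidy CSV
#'
#' One row per (replicate, day, stage, sex, genotype); a sibling manifest
#' names the generator, package version and master seed.
#'
#' @param ensemble a [run_scenario()] result.
#' @param path output CSV.
#' @export
write_trajectory_csv <- function(ensemble, path) {
  dfs <- lapply(ensemble$runs, function(tr) {
    df <- as_trajectory_df(tr)
    df$replicate <- tr$replicate
    df[, c("replicate", "day", "stage", "sex", "genotype", "count")]
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(generator = "tgdrive::write_trajectory_csv",
         version = as.character(utils::packageVersion("tgdrive")),
         seed = ensemble$scenario$seed,
         architecture = ensemble$scenario$architecture$name,
         replicates = ensemble$scenario$replicates),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}
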