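# Synthetic fixture generators: scoring tables, sequencing-style indel
# records and miniature population scenarios with known ground truth.
# Every fixture is written together with a JSON manifest recording its
# generating parameters, so downstream estimates can be checked against
# the truth that produced the data.

#' Generate a synthetic scoring-table fixture
#'
#' Simulates a cross under known parameters and writes the resulting
#' per-vial phenotype scoring table as CSV (plus a `<path>.manifest.json`
#' with every generating parameter).  Regeneration with the same spec is
#' byte-identical.
#'
#' @param path output CSV path.
#' @param scheme a [cross_scheme()].
#' @param timing a [germline_timing()].
#' @param n_vials,n_offspring_per_vial table dimensions.
#' @param seed integer seed.
#' @param experiment experiment id recorded in the table.
#' @return the table (invisibly); files written at `path` and
#'   `<path>.manifest.json`.
#' @export
make_scoring_fixture <- function(path, scheme = cross_scheme(),
                                 timing = germline_timing(),
                                 n_vials = 11L, n_offspring_per_vial = 50L,
                                 seed = 1L, experiment = "fixture") {
  tab <- simulate_cross(scheme, timing, n_vials = n_vials,
                        n_offspring_per_vial = n_offspring_per_vial,
                        seed = seed, experiment = experiment)
  write_scoring_csv(tab, path)
  manifest <- list(
    generator = "tgdrive::make_scoring_fixture",
    version = as.character(utils::packageVersion("tgdrive")),
    seed = seed, n_vials = n_vials,
    n_offspring_per_vial = n_offspring_per_vial,
    scheme = scheme[setdiff(names(scheme), "architecture")],
    architecture = scheme$architecture$name,
    timing = list(z = timing$z, k = timing$k, q_late = timing$q_late,
                  c_late = timing$c_late, rho = timing$rho,
                  spectra = lapply(timing$spectra, unclass)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tab)
}

#' Generate a sequencing-style fixture of indel-labeled males
#'
#' Simulates the cross, then keeps only male records carrying resistant
#' alleles, optionally subsampling a fixed number of males per vial — the
#' structure of an experiment where resistant F2 males are sequenced to
#' identify their indel alleles.
#'
#' @inheritParams make_scoring_fixture
#' @param males_per_vial maximum sampled males per vial (`Inf` keeps all).
#' @return the filtered table (invisibly); files written as in
#'   [make_scoring_fixture()].
#' @export
make_sequencing_fixture <- function(path, scheme = cross_scheme(),
                                    timing = germline_timing(),
                                    n_vials = 20L,
                                    n_offspring_per_vial = 50L,
                                    males_per_vial = Inf, seed = 1L,
                                    experiment = "seqfix") {
  tab <- simulate_cross(scheme, timing, n_vials = n_vials,
                        n_offspring_per_vial = n_offspring_per_vial,
                        seed = seed, experiment = experiment)
  tab <- tab[tab$sex == "M" & !is.na(tab$indel), , drop = FALSE]
  if (is.finite(males_per_vial)) {
    keep <- lapply(split(seq_len(nrow(tab)), tab$vial), function(idx) {
      take <- idx
      csum <- cumsum(tab$count[idx])
      cut <- which(csum >= males_per_vial)
      if (length(cut) > 0) take <- idx[seq_len(cut[1])]
      take
    })
    tab <- tab[sort(unlist(keep)), , drop = FALSE]
  }
  write_scoring_csv(tab, path)
  jsonlite::write_json(
    list(generator = "tgdrive::make_sequencing_fixture", seed = seed,
         males_per_vial = males_per_vial,
         architecture = scheme$architecture$name,
         timing = list(z = timing$z, k = timing$k, q_late = timing$q_late,
                       c_late = timing$c_late, rho = timing$rho,
                       spectra = lapply(timing$spectra, unclass))),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(tab)
}

#' Miniature population scenario for fast tests
#'
#' A calibrated small-population scenario config whose deterministic
#' equilibrium equals the requested adult count — the standard dynamics at
#' desk scale.
#'
#' @param N equilibrium adult population size.
#' @param horizon_days simulated days.
#' @param architecture architecture name.
#' @param conversion allelic conversion efficiency.
#' @param replicates stochastic realizations.
#' @param seed master seed.
#' @param release_size released males per event (scaled to N by default).
#' @return a [scenario()] (replacement mode, stochastic).
#' @export
make_small_population_fixture <- function(N = 500, horizon_days = 200L,
                                          architecture = "full_GD",
                                          conversion = 1, replicates = 1L,
                                          seed = 1L,
                                          release_size = max(1L,
                                            round(N / 100))) {
  life <- life_history_params(N = N)
  arch <- drive_architecture(architecture)
  rel <- release_schedule(size = release_size,
                          genotype = drive_release_genotype(arch))
  scenario(arch, cube_params(arch, q = 1, c_conv = conversion, rho = 1),
           life = life, releases = rel, mode = "replacement",
           sim_mode = "stochastic", replicates = replicates,
           horizon_days = horizon_days, seed = seed)
}
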