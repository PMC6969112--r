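# Replacement and suppression experiment drivers: compose cubes and the
# population model over a grid of allelic conversion efficiencies and
# drive systems, and summarize the trajectory metrics.

drive_release_genotype <- function(architecture) {
  hap <- hap_code(rep("T", architecture$n_loci), architecture$n_loci)
  if (is_x_linked(architecture)) paste0(hap, "/Y|M")
  else genotype_code(hap, hap, "M", architecture$n_loci)
}

#' Population-replacement experiment
#'
#' For each drive system and allelic conversion efficiency, releases
#' drive-homozygous males into a wild-type equilibrium population and
#' summarizes spread: time for the carrier fraction to reach steady state,
#' the equilibrium carrier fraction, and final allele-class counts.
#' Exploratory drive parameters are used throughout: cleavage certain,
#' conversion on the grid, end-joining repairs all in-frame and cost-free,
#' no fitness costs.
#'
#' @param conversions allelic conversion efficiencies to scan.
#' @param systems architecture names.
#' @param replicates stochastic realizations per cell (ignored in
#'   deterministic mode).
#' @param life a [life_history_params()]; scale `N` down for quick runs.
#' @param horizon_days simulated days.
#' @param sim_mode `"deterministic"` or `"stochastic"`.
#' @param seed master seed.
#' @param releases optional common [release_schedule()] (the released
#'   genotype is substituted per system).
#' @return list with `summary` (data.frame keyed by system, efficiency,
#'   replicate) and `series` (carrier-fraction matrices per cell).
#' @export
replacement_experiment <- function(conversions = c(1, 0.9, 0.5),
                                   systems = c("full_GD", "tGDc"),
                                   replicates = 1L,
                                   life = life_history_params(),
                                   horizon_days = 730L,
                                   sim_mode = "deterministic",
                                   seed = 1L, releases = NULL) {
  rows <- list(); series <- list()
  for (sys in systems) {
    arch <- drive_architecture(sys)
    for (cv in conversions) {
      params <- cube_params(arch, q = 1, c_conv = cv, rho = 1)
      rel <- releases
      if (is.null(rel)) rel <- release_schedule(
        genotype = drive_release_genotype(arch))
      else rel$genotype <- drive_release_genotype(arch)
      scn <- scenario(arch, params, life = life, releases = rel,
                      mode = "replacement", sim_mode = sim_mode,
                      replicates = if (sim_mode == "stochastic")
                        replicates else 1L,
                      horizon_days = horizon_days, seed = seed)
      ens <- run_scenario(scn)
      for (tr in ens$runs) {
        cf <- carrier_fraction(tr)
        key <- paste(sys, cv, tr$replicate, sep = "|")
        series[[key]] <- cf
        ac <- allele_counts(tr)
        nd <- length(tr$day)
        rows[[key]] <- data.frame(
          system = sys, efficiency = cv, replicate = tr$replicate,
          time_to_steady = time_to_steady_state(cf),
          carrier_eq = mean(cf[max(1, nd - 29):nd]),
          T_final = sum(ac[nd, "T", ]), R_final = sum(ac[nd, "R", ]),
          W_final = sum(ac[nd, "W", ]))
      }
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       series = series)
}

#' Population-suppression experiment
#'
#' The drive disrupts a gene required in at least one copy for female
#' fertility (the gRNA locus of a split drive, the insertion locus of a
#' full drive): drive-homozygous females are sterile.  At complete
#' conversion the population crashes; when a small fraction of cleavages
#' end-join instead, in-frame resistant alleles restore fertility, are
#' immune to further cleavage, and rescue the population, which rebounds.
#'
#' @param conversions conversion efficiencies to scan (e.g. `c(1, 0.99)`).
#' @param systems architecture names.
#' @param replicates stochastic realizations per cell.
#' @param life a [life_history_params()].
#' @param horizon_days simulated days.
#' @param rho in-frame fraction of end-joining repairs.
#' @param seed master seed.
#' @param releases optional common release schedule.
#' @return data.frame keyed by (system, efficiency, replicate) with
#'   `crash_day` (days after first release, `NA` if none), `rebound`,
#'   `rebound_day`.
#' @export
suppression_experiment <- function(conversions = c(1, 0.99),
                                   systems = c("full_GD", "tGD_linked"),
                                   replicates = 10L,
                                   life = life_history_params(),
                                   horizon_days = 1095L, rho = 1,
                                   seed = 1L, releases = NULL) {
  rows <- list()
  for (sys in systems) {
    arch <- drive_architecture(sys)
    for (cv in conversions) {
      params <- cube_params(arch, q = 1, c_conv = cv, rho = rho,
                            fertility_rule = fertility_rule_functional())
      rel <- releases
      if (is.null(rel)) rel <- release_schedule(
        genotype = drive_release_genotype(arch))
      else rel$genotype <- drive_release_genotype(arch)
      scn <- scenario(arch, params, life = life, releases = rel,
                      mode = "suppression", sim_mode = "stochastic",
                      replicates = replicates,
                      horizon_days = horizon_days, seed = seed)
      ens <- run_scenario(scn)
      for (tr in ens$runs) {
        cr <- crash_and_rebound(tr)
        rows[[paste(sys, cv, tr$replicate)]] <- data.frame(
          system = sys, efficiency = cv, replicate = tr$replicate,
          crash_day = cr$crash_day, rebound = cr$rebound,
          rebound_day = cr$rebound_day)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
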