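# Single-patch, daily-time-step, genotype-resolved population model.
#
# State bookkeeping (end-of-day): juvenile cohorts are matrices with one
# row per in-stage age (row a has received a of that stage's daily survival
# draws) and one column per sex-tagged genotype; adult males are a vector
# over male genotypes; mated adult females a matrix (own genotype x stored
# mate genotype); never-mated females a vector.  The daily update applies,
# in order: oviposition, stage advancement, survival (density-dependent for
# larvae), emergence and once-only mating, then scheduled releases.

#' Release schedule
#'
#' @param first_day day of the first release (days are counted from the
#'   start of the simulation; the default burn-in leaves the population at
#'   equilibrium until then).
#' @param n_releases number of releases.
#' @param interval days between releases (default weekly).
#' @param size individuals per release.
#' @param genotype released genotype code (e.g. drive-homozygous males).
#' @param sex `"M"` or `"F"`.
#' @return data.frame of release events `(day, sex, genotype, count)`.
#' @export
release_schedule <- function(first_day = 50L, n_releases = 5L,
                             interval = 7L, size = 100L,
                             genotype, sex = "M") {
  stopifnot(size > 0, n_releases >= 0)
  if (n_releases == 0L)
    return(data.frame(day = integer(0), sex = character(0),
                      genotype = character(0), count = integer(0)))
  data.frame(day = first_day + interval * (seq_len(n_releases) - 1L),
             sex = sex, genotype = genotype, count = as.integer(size))
}

# precomputed quantities shared by every step of a run
cube_kernel <- function(cube, life) {
  nF <- length(cube$mothers); nM <- length(cube$fathers)
  nO <- length(cube$offspring)
  CU <- matrix(cube$tab, nrow = nF * nM, ncol = nO)  # rows: vec(AF) order
  fert <- rep(1, nF)
  if (!is.null(cube$params$fertility_rule))
    fert <- as.numeric(vapply(cube$mothers, cube$params$fertility_rule,
                              logical(1), architecture = cube$architecture))
  w_f <- omega_of(cube$params, cube$mothers) * fert   # fecundity weight
  w_m <- omega_of(cube$params, cube$fathers)          # mate-choice weight
  off_sex <- sub("^.*\\|", "", cube$offspring)
  off_to_female <- match(cube$offspring, cube$mothers)
  off_to_male <- match(cube$offspring, cube$fathers)
  list(CU = CU, w_f = w_f, w_m = w_m, off_sex = off_sex,
       off_to_female = off_to_female, off_to_male = off_to_male,
       nF = nF, nM = nM, nO = nO)
}

#' Wild-type equilibrium population state
#'
#' All individuals homozygous wild-type, stage cohorts at the deterministic
#' equilibrium, adult females pre-mated to wild-type males.  In stochastic
#' mode cohort sizes are integer-rounded by the largest-remainder method so
#' stage totals are preserved.
#'
#' @param cube the inheritance cube of the scenario's architecture.
#' @param life a [life_history_params()].
#' @param derived a [calibrate_life_history()] result.
#' @param stochastic round to integers for the stochastic model.
#' @return object of class `population_state`.
#' @export
equilibrium_state <- function(cube, life, derived, stochastic = TRUE) {
  n_loci <- cube$architecture$n_loci
  wt_hap <- hap_code(rep("W", n_loci), n_loci)
  wt_f <- genotype_code(wt_hap, wt_hap, "F", n_loci)
  wt_m <- if (is_x_linked(cube$architecture))
    paste0(wt_hap, "/Y|M") else genotype_code(wt_hap, wt_hap, "M", n_loci)
  nO <- length(cube$offspring)
  iF <- match(wt_f, cube$offspring); iM <- match(wt_m, cube$offspring)
  rnd <- function(x) if (stochastic) largest_remainder_round(x) else x
  mk <- function(sizes, T_stage) {
    m <- matrix(0, nrow = T_stage, ncol = nO)
    m[, iF] <- rnd(sizes / 2); m[, iM] <- rnd(sizes / 2)
    m
  }
  AM <- stats::setNames(numeric(length(cube$fathers)), cube$fathers)
  AM[wt_m] <- rnd(life$N / 2)
  AF <- matrix(0, length(cube$mothers), length(cube$fathers),
               dimnames = list(cube$mothers, cube$fathers))
  AF[wt_f, wt_m] <- rnd(life$N / 2)
  structure(list(
    day = 0L,
    E = mk(derived$eq$E, life$T_E),
    L = mk(derived$eq$L, life$T_L),
    P = mk(derived$eq$P, life$T_P),
    AM = AM, AF = AF,
    AU = stats::setNames(numeric(length(cube$mothers)), cube$mothers),
    offspring = cube$offspring, stochastic = stochastic),
    class = "population_state")
}

largest_remainder_round <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Adult counts of a population state
#'
#' @param state a `population_state`.
#' @return list with `males`, `females` (named vectors by genotype, females
#'   combining mated and unmated) and `total`.
#' @export
adult_counts <- function(state) {
  females <- rowSums(state$AF) + state$AU
  list(males = state$AM, females = females,
       total = sum(state$AM) + sum(females))
}

#' Advance the population by one day
#'
#' Applies, in order: (1) oviposition by mated females (mean clutch
#' `beta * omega * fertility` per female, offspring genotypes drawn from
#' the cube row of the stored pair); (2) stage advancement after
#' `T_E`/`T_L`/`T_P` in-stage days, with the oldest pupal cohort set aside
#' for emergence; (3) survival — density-independent `1 - mu_J` for
#' juveniles plus the daily larval density factor
#' `(alpha/(alpha + L_total))^(1/T_L)`, `1 - mu_M` for adults; (4)
#' emergence and mating: new females store one mate genotype sampled from
#' current adult males weighted by fitness (when no males exist, they stay
#' unmated and never lay); (5) releases scheduled for this day.  Stochastic
#' mode draws Poisson clutches, multinomial genotypes and binomial
#' survival; deterministic mode propagates expectations.
#'
#' @param state a `population_state`.
#' @param cube the scenario's inheritance cube.
#' @param life a [life_history_params()].
#' @param derived a [calibrate_life_history()] result.
#' @param releases optional release data.frame (only rows with
#'   `day == state$day + 1` are applied).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param kernel precomputed [cube] bookkeeping (internal; computed when
#'   missing).
#' @return the updated `population_state` (one day later).
#' @export
step_day <- function(state, cube, life, derived, releases = NULL,
                     mode = c("stochastic", "deterministic"),
                     kernel = NULL) {
  mode <- match.arg(mode)
  stoch <- mode == "stochastic"
  if (is.null(kernel)) kernel <- cube_kernel(cube, life)
  s_J <- 1 - derived$mu_J
  s_A <- 1 - life$mu_M
  day <- state$day + 1L

  # (1) oviposition
  lam <- life$beta * (kernel$w_f * state$AF)   # recycles w_f down columns
  new_eggs <- numeric(kernel$nO)
  if (sum(lam) > 0) {
    if (stoch) {
      clutch <- stats::rpois(length(lam), as.numeric(lam))
      nz <- which(clutch > 0)
      for (i in nz)
        new_eggs <- new_eggs +
          stats::rmultinom(1L, clutch[i], kernel$CU[i, ])[, 1]
    } else {
      new_eggs <- as.numeric(crossprod(kernel$CU, as.numeric(lam)))
    }
  }

  # (2) advancement (aging); oldest pupae emerge after survival
  emerge <- state$P[life$T_P, ]
  shift <- function(m, newrow) {
    if (nrow(m) > 1L) m[2:nrow(m), ] <- m[seq_len(nrow(m) - 1L), ]
    m[1L, ] <- newrow
    m
  }
  P <- shift(state$P, state$L[life$T_L, ])
  L <- shift(state$L, state$E[life$T_E, ])
  E <- shift(state$E, new_eggs)

  # (3) survival
  L_total <- sum(L)
  f_daily <- if (L_total > 0)
    (derived$alpha / (derived$alpha + L_total))^(1 / life$T_L) else 1
  surv <- function(x, p) {
    if (stoch) array(stats::rbinom(length(x), as.integer(round(x)), p),
                     dim = dim(x) %||% length(x))
    else x * p
  }
  E <- surv(E, s_J)
  L <- surv(L, s_J * f_daily)
  P <- surv(P, s_J)
  AM <- surv(state$AM, s_A); names(AM) <- names(state$AM)
  AF <- surv(state$AF, s_A); dimnames(AF) <- dimnames(state$AF)
  AU <- surv(state$AU, s_A); names(AU) <- names(state$AU)
  # `emerge` completed its last pupal survival draw yesterday; emergers are
  # not exposed to adult mortality on their emergence day.

  # (4) emergence + mating
  new_f <- numeric(kernel$nF); new_m <- numeric(kernel$nM)
  fem <- !is.na(kernel$off_to_female)
  new_f[kernel$off_to_female[fem]] <- emerge[fem]
  mal <- !is.na(kernel$off_to_male)
  new_m[kernel$off_to_male[mal]] <- emerge[mal]
  AM <- AM + new_m
  mate_w <- AM * kernel$w_m
  if (sum(mate_w) > 0) {
    if (stoch) {
      for (g in which(new_f > 0))
        AF[g, ] <- AF[g, ] +
          stats::rmultinom(1L, new_f[g], mate_w)[, 1]
    } else {
      AF <- AF + outer(new_f, mate_w / sum(mate_w))
    }
  } else if (sum(new_f) > 0) {
    AU <- AU + new_f   # no males around: females stay unmated, lay nothing
  }

  # (5) releases
  if (!is.null(releases) && nrow(releases) > 0) {
    today <- releases[releases$day == day, , drop = FALSE]
    for (i in seq_len(nrow(today))) {
      g <- canonical_genotype(today$genotype[i], cube$architecture)
      if (today$sex[i] == "M") {
        if (!g %in% names(AM)) stop("release genotype not in cube: ", g)
        AM[g] <- AM[g] + today$count[i]
      } else {
        if (!g %in% names(AU)) stop("release genotype not in cube: ", g)
        AU[g] <- AU[g] + today$count[i]
      }
    }
  }

  state$day <- day
  state$E <- E; state$L <- L; state$P <- P
  state$AM <- AM; state$AF <- AF; state$AU <- AU
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario definition
#'
#' Bundles everything needed for a reproducible simulation experiment.
#'
#' @param architecture a [drive_architecture()] (or its name).
#' @param cube_params a [cube_params()]; a fertility rule is required for
#'   suppression mode.
#' @param life a [life_history_params()].
#' @param releases a [release_schedule()]; defaults to 5 weekly releases of
#'   100 drive-homozygous adult males starting after a 50-day burn-in.
#' @param mode `"replacement"` or `"suppression"`.
#' @param sim_mode `"stochastic"` or `"deterministic"`.
#' @param replicates number of stochastic realizations.
#' @param horizon_days simulated days.
#' @param seed master seed; replicate seeds are derived from it.
#' @return object of class `drive_scenario`.
#' @export
scenario <- function(architecture, cube_params, life = life_history_params(),
                     releases = NULL, mode = c("replacement", "suppression"),
                     sim_mode = c("stochastic", "deterministic"),
                     replicates = 1L, horizon_days = 365L, seed = 1L) {
  mode <- match.arg(mode)
  sim_mode <- match.arg(sim_mode)
  if (is.character(architecture)) architecture <-
      drive_architecture(architecture)
  if (mode == "suppression" && is.null(cube_params$fertility_rule))
    stop("suppression mode requires a fertility_rule in cube_params",
         call. = FALSE)
  if (is.null(releases)) {
    hap <- hap_code(rep("T", architecture$n_loci), architecture$n_loci)
    g <- if (is_x_linked(architecture)) paste0(hap, "/Y|M")
         else genotype_code(hap, hap, "M", architecture$n_loci)
    releases <- release_schedule(genotype = g)
  }
  structure(list(architecture = architecture, cube_params = cube_params,
                 life = life, releases = releases, mode = mode,
                 sim_mode = sim_mode, replicates = as.integer(replicates),
                 horizon_days = as.integer(horizon_days),
                 seed = as.integer(seed)),
            class = "drive_scenario")
}

# documented sub-seeding: stream i of master seed s
derive_seed <- function(master, stream)
  as.integer((as.numeric(master) * 48271 + 1000003 * stream) %%
               2147483647)

#' Run a scenario
#'
#' Simulates `replicates` realizations (each with a seed derived from the
#' master seed by the documented sub-seeding rule), recording daily adult
#' counts per genotype and sex plus juvenile stage totals.
#'
#' @param scn a [scenario()].
#' @return object of class `ensemble`: list of `trajectory` objects (one
#'   per replicate), each with matrices `females`/`males` (day x genotype),
#'   juvenile stage totals, the release table and scenario metadata.
#' @export
run_scenario <- function(scn) {
  cube <- build_cube(scn$architecture, scn$cube_params)
  derived <- calibrate_life_history(scn$life)
  kernel <- cube_kernel(cube, scn$life)
  runs <- vector("list", scn$replicates)
  for (rep_i in seq_len(scn$replicates)) {
    set.seed(derive_seed(scn$seed, rep_i))
    st <- equilibrium_state(cube, scn$life, derived,
                            stochastic = scn$sim_mode == "stochastic")
    nd <- scn$horizon_days
    females <- matrix(0, nd + 1L, kernel$nF,
                      dimnames = list(NULL, cube$mothers))
    males <- matrix(0, nd + 1L, kernel$nM,
                    dimnames = list(NULL, cube$fathers))
    juveniles <- matrix(0, nd + 1L, 3L,
                        dimnames = list(NULL, c("egg", "larva", "pupa")))
    snap <- function(i, st) {
      females[i, ] <<- rowSums(st$AF) + st$AU
      males[i, ] <<- st$AM
      juveniles[i, ] <<- c(sum(st$E), sum(st$L), sum(st$P))
    }
    snap(1L, st)
    for (d in seq_len(nd)) {
      st <- step_day(st, cube, scn$life, derived, scn$releases,
                     mode = scn$sim_mode, kernel = kernel)
      snap(d + 1L, st)
    }
    runs[[rep_i]] <- structure(
      list(day = 0:nd, females = females, males = males,
           juveniles = juveniles, releases = scn$releases,
           architecture = scn$architecture, N = scn$life$N,
           replicate = rep_i, seed = derive_seed(scn$seed, rep_i)),
      class = "trajectory")
  }
  structure(list(runs = runs, scenario = scn), class = "ensemble")
}

#' Tidy per-day data frame of a trajectory
#'
#' @param traj a `trajectory` from [run_scenario()].
#' @return data.frame `(day, stage, sex, genotype, count)` for adults plus
#'   juvenile stage totals.
#' @export
as_trajectory_df <- function(traj) {
  nd <- length(traj$day)
  adult <- rbind(
    data.frame(day = rep(traj$day, ncol(traj$females)), stage = "adult",
               sex = "F",
               genotype = rep(colnames(traj$females), each = nd),
               count = as.numeric(traj$females)),
    data.frame(day = rep(traj$day, ncol(traj$males)), stage = "adult",
               sex = "M",
               genotype = rep(colnames(traj$males), each = nd),
               count = as.numeric(traj$males)))
  juv <- data.frame(day = rep(traj$day, 3L),
                    stage = rep(colnames(traj$juveniles), each = nd),
                    sex = NA_character_, genotype = NA_character_,
                    count = as.numeric(traj$juveniles))
  rbind(adult, juv)
}
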