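# Summary metrics over trajectories.  All metrics are pure functions of the
# recorded trajectory; recomputation is bit-identical.

# per-genotype indicator / count helpers -----------------------------------

genotype_has_transgene <- function(codes, architecture)
  vapply(codes, carries_allele, logical(1),
         architecture = architecture, state = "T")

#' Transgene carrier fraction
#'
#' Fraction of adults carrying at least one drive transgene copy (`T` at
#' any locus) — the payload-delivery metric for population replacement.
#'
#' @param traj a `trajectory` from [run_scenario()], or a
#'   `population_state` (then [adult_counts()] of that single state is
#'   used and a `cube` index must be supplied via `codes_f`/`codes_m`).
#' @return numeric vector per day (or scalar for a state); days with zero
#'   adults yield 0 with attribute `no_adults = TRUE` recorded per day.
#' @export
carrier_fraction <- function(traj) {
  carF <- genotype_has_transgene(colnames(traj$females), traj$architecture)
  carM <- genotype_has_transgene(colnames(traj$males), traj$architecture)
  tot <- rowSums(traj$females) + rowSums(traj$males)
  car <- as.numeric(traj$females %*% carF + traj$males %*% carM)
  out <- ifelse(tot > 0, car / pmax(tot, 1), 0)
  attr(out, "no_adults") <- tot == 0
  out
}

#' Adult allele-class counts over time
#'
#' Per-day copy counts of each allele class (`W`, `T`, `R`, `B`) at each
#' locus across adults.  Autosomal loci contribute two copies per adult;
#' X-linked loci contribute two per female and one per (hemizygous) male.
#'
#' @param traj a `trajectory`.
#' @return array `day x state x locus`.
#' @export
allele_counts <- function(traj) {
  arch <- traj$architecture
  n <- arch$n_loci
  cntF <- vapply(colnames(traj$females),
                 function(g) genotype_allele_counts(g, arch),
                 matrix(0L, 4L, n))                       # 4 x n x nGeno
  cntM <- vapply(colnames(traj$males),
                 function(g) genotype_allele_counts(g, arch),
                 matrix(0L, 4L, n))
  nd <- length(traj$day)
  out <- array(0, dim = c(nd, 4L, n),
               dimnames = list(NULL, STATE_CODES, LETTERS[seq_len(n)]))
  for (s in 1:4) for (i in seq_len(n)) {
    out[, s, i] <- as.numeric(
      traj$females %*% cntF[s, i, ] + traj$males %*% cntM[s, i, ])
  }
  out
}

#' First day a metric series reaches steady state
#'
#' The first day `t` such that the series' range over the window
#' `[t, t + window]` is below `epsilon`; `NA` if that never happens.
#'
#' @param series numeric per-day values (day 0 first).
#' @param epsilon range threshold (default 0.001).
#' @param window window length in days (default 30).
#' @return day index (0-based) or `NA`.
#' @export
time_to_steady_state <- function(series, epsilon = 0.001, window = 30L) {
  n <- length(series)
  if (n <= window) stop("series shorter than the window", call. = FALSE)
  for (t in seq_len(n - window)) {
    w <- series[t:(t + window)]
    if (max(w) - min(w) < epsilon) return(t - 1L)
  }
  NA_integer_
}

#' Crash and rebound classification of a suppression trajectory
#'
#' A *crash* is the loss of every adult female (extinction proxy); its day
#' is reported relative to the first release.  When no crash occurs, the
#' population *rebounds* if it suffered a genuine suppression dip — total
#' adults falling below `dip_fraction * N`, i.e. beyond ordinary stochastic
#' fluctuation around equilibrium — and later recovered to at least
#' `rebound_fraction * N` after the dip's minimum.  A flat trajectory
#' therefore neither crashes nor rebounds.
#'
#' @param traj a `trajectory` with release annotations.
#' @param crash_threshold adult females strictly below this count to crash
#'   (default 1, i.e. zero females in stochastic mode).
#' @param rebound_fraction fraction of the equilibrium size `N` defining
#'   recovery (default 0.5).
#' @param dip_fraction fraction of `N` below which the population must have
#'   dipped for a recovery to count as a rebound (default 0.9).
#' @return list `crash_day` (days since first release, or `NA`),
#'   `rebound` (logical), `rebound_day` (or `NA`).
#' @export
crash_and_rebound <- function(traj, crash_threshold = 1,
                              rebound_fraction = 0.5, dip_fraction = 0.9) {
  females <- rowSums(traj$females)
  adults <- females + rowSums(traj$males)
  first_release <- if (nrow(traj$releases) > 0) min(traj$releases$day)
                   else 0L
  after <- traj$day >= first_release
  crash_idx <- which(after & females < crash_threshold)
  if (length(crash_idx) > 0) {
    return(list(crash_day = traj$day[crash_idx[1]] - first_release,
                rebound = FALSE, rebound_day = NA_integer_))
  }
  a_after <- adults[after]; d_after <- traj$day[after]
  min_idx <- which.min(a_after)
  if (a_after[min_idx] >= dip_fraction * traj$N)
    return(list(crash_day = NA_integer_, rebound = FALSE,
                rebound_day = NA_integer_))
  rec <- which(a_after >= rebound_fraction * traj$N &
                 seq_along(a_after) > min_idx)
  if (length(rec) == 0)
    return(list(crash_day = NA_integer_, rebound = FALSE,
                rebound_day = NA_integer_))
  list(crash_day = NA_integer_, rebound = TRUE,
       rebound_day = d_after[rec[1]] - first_release)
}
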