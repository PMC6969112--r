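#' Mosquito life-history parameters
#'
#' Daily-time-step stage-structured parameters for an *Aedes aegypti*
#' population: egg production per female per day (`beta`), stage durations
#' in days (`T_E`, `T_L`, `T_P`), daily population growth rate (`r`, the
#' dominant growth factor of the density-independent linearization), adult
#' daily mortality (`mu_M`) and the equilibrium adult population size (`N`).
#'
#' @param beta egg production per female per day.
#' @param T_E,T_L,T_P egg / larval / pupal stage durations (days, positive
#'   integers).
#' @param r daily population growth rate, must exceed 1.
#' @param mu_M adult daily mortality in (0, 1).
#' @param N equilibrium total adult population size.
#' @return object of class `life_history_params`.
#' @export
life_history_params <- function(beta = 20, T_E = 5L, T_L = 6L, T_P = 4L,
                                r = 1.175, mu_M = 0.090, N = 10000) {
  stopifnot(T_E >= 1, T_L >= 1, T_P >= 1)
  if (mu_M <= 0 || mu_M >= 1) stop("mu_M must lie in (0,1)", call. = FALSE)
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (r <= 1)
    stop("daily growth rate r must exceed 1 for a viable population",
         call. = FALSE)
  structure(list(beta = beta, T_E = as.integer(T_E), T_L = as.integer(T_L),
                 T_P = as.integer(T_P), r = r, mu_M = mu_M, N = N),
            class = "life_history_params")
}

#' Calibrate derived life-history rates
#'
#' Two quantities are not printed in the parameter table and must be derived:
#'
#' 1. the common daily density-independent juvenile mortality `mu_J`,
#'    solved numerically so that the density-independent daily projection
#'    has dominant growth factor `r` (root of the characteristic equation
#'    `lambda^(T_J + 1) = (1 - mu_M) lambda^(T_J) + (beta/2)(1 - mu_J)^(T_J)`
#'    with `T_J = T_E + T_L + T_P`, evaluated at `lambda = r`);
#' 2. the larval density-dependence scale `alpha` of the daily larval
#'    survival multiplier `(alpha / (alpha + L_total))^(1/T_L)`, solved so
#'    the deterministic equilibrium holds exactly `N` adults.
#'
#' Equilibrium cohort sizes for every stage-age are returned; they form an
#' exact fixed point of the deterministic daily update.
#'
#' @param params a [life_history_params()].
#' @return object of class `derived_rates`: `mu_J`, `alpha`, `phi` (the
#'   equilibrium larval density survival factor over the whole stage),
#'   `eq` (list of equilibrium cohort sizes `E`, `L`, `P`, adults).
#' @examples
#' calibrate_life_history(life_history_params())$mu_J
#' @export
calibrate_life_history <- function(params) {
  p <- params
  T_J <- p$T_E + p$T_L + p$T_P
  s_A <- 1 - p$mu_M
  # density-independent growth factor as a function of mu_J
  growth <- function(mu_J)
    (p$beta / 2) * (1 - mu_J)^T_J / (p$r^T_J) + s_A - p$r
  if (growth(0) < 0)
    stop("no juvenile mortality in (0,1) achieves growth rate r; ",
         "r is infeasible for these parameters", call. = FALSE)
  mu_J <- stats::uniroot(growth, c(0, 1 - 1e-12), tol = 1e-10)$root
  s_J <- 1 - mu_J

  # equilibrium: recruitment balances adult mortality
  # phi = whole-stage larval density survival = alpha / (alpha + L_total)
  phi <- p$mu_M / ((p$beta / 2) * s_J^T_J)
  if (phi >= 1)
    stop("infeasible equilibrium: density-independent survival cannot ",
         "sustain N", call. = FALSE)
  f_daily <- phi^(1 / p$T_L)
  B <- p$beta * p$N / 2                       # daily egg input at equilibrium
  L_in <- B * s_J^p$T_E
  # larval totals as seen by the density term (cohorts holding 0..T_L-1
  # larval survival draws at the moment the term is applied)
  L_at_survival <- L_in * (s_J * f_daily)^(0:(p$T_L - 1))
  alpha <- phi * sum(L_at_survival) / (1 - phi)
  # end-of-day equilibrium cohorts: row a of a stage has received a of that
  # stage's survival draws
  E <- B * s_J^(seq_len(p$T_E))
  L <- L_in * (s_J * f_daily)^(seq_len(p$T_L))
  P <- L_in * (s_J * f_daily)^p$T_L * s_J^(seq_len(p$T_P))
  structure(list(mu_J = mu_J, alpha = alpha, phi = phi,
                 eq = list(E = E, L = L, P = P, adults = p$N,
                           L_at_survival = sum(L_at_survival)),
                 params = p),
            class = "derived_rates")
}
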