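# Randomization (permutation) tests, two-sided, with the add-one p-value
# convention p = (1 + #{|stat_perm| >= |stat_obs|}) / (n_perm + 1), which
# never reports an exact zero.

perm_pvalue <- function(extreme, total) (1 + extreme) / (total + 1)

#' Randomization test for a difference in means
#'
#' Permutes group labels uniformly over the pooled values and compares the
#' absolute difference in group means against the observed one.  With
#' `exact = TRUE` all label assignments are enumerated instead of sampled
#' (feasible for small groups); the same add-one p-value formula is applied
#' with the enumeration total in place of `n_perm`.
#'
#' @param group_a,group_b numeric vectors (e.g. per-vial inheritance
#'   fractions).
#' @param n_perm number of random permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all `choose(n, n_a)` assignments instead of
#'   sampling.
#' @return list with `p_value`, `observed` (mean(a) - mean(b)), `n_perm`.
#' @examples
#' randomization_test_means(c(.8, .9, .85), c(.5, .55, .6), seed = 1)
#' @export
randomization_test_means <- function(group_a, group_b, n_perm = 5000L,
                                     seed = 1L, exact = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  obs <- mean(group_a) - mean(group_b)
  stat <- function(idx) mean(pooled[idx]) - mean(pooled[-idx])
  if (exact) {
    combos <- utils::combn(na + nb, na)
    stats_all <- apply(combos, 2, stat)
    extreme <- sum(abs(stats_all) >= abs(obs) - 1e-12)
    return(list(p_value = perm_pvalue(extreme, ncol(combos)),
                observed = obs, n_perm = ncol(combos)))
  }
  set.seed(seed)
  extreme <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(na + nb, na)
    if (abs(stat(idx)) >= abs(obs) - 1e-12) extreme <- extreme + 1L
  }
  list(p_value = perm_pvalue(extreme, n_perm), observed = obs,
       n_perm = n_perm)
}

#' Randomization test for a difference in proportions
#'
#' Pools the Bernoulli outcomes of the two groups, permutes group labels,
#' and applies the same two-sided add-one p-value formula to the difference
#' in proportions.  `exact = TRUE` enumerates assignments by the
#' hypergeometric count of successes allotted to group A.
#'
#' @param successes_a,total_a,successes_b,total_b integer counts with
#'   `0 <= successes <= total`, totals positive.
#' @inheritParams randomization_test_means
#' @return list with `p_value`, `observed`, `n_perm`.
#' @export
randomization_test_proportions <- function(successes_a, total_a,
                                           successes_b, total_b,
                                           n_perm = 5000L, seed = 1L,
                                           exact = FALSE) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  if (successes_a < 0 || successes_a > total_a ||
      successes_b < 0 || successes_b > total_b)
    stop("successes must lie in [0, total]", call. = FALSE)
  obs <- successes_a / total_a - successes_b / total_b
  n <- total_a + total_b
  s <- successes_a + successes_b
  if (exact) {
    # number of label assignments giving x successes in group A
    xs <- max(0, s - total_b):min(s, total_a)
    counts <- choose(s, xs) * choose(n - s, total_a - xs)
    diffs <- xs / total_a - (s - xs) / total_b
    extreme <- sum(counts[abs(diffs) >= abs(obs) - 1e-12])
    return(list(p_value = perm_pvalue(extreme, choose(n, total_a)),
                observed = obs, n_perm = choose(n, total_a)))
  }
  set.seed(seed)
  pooled <- c(rep(1L, s), rep(0L, n - s))
  extreme <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, total_a)
    d <- mean(pooled[idx]) - mean(pooled[-idx])
    if (abs(d) >= abs(obs) - 1e-12) extreme <- extreme + 1L
  }
  list(p_value = perm_pvalue(extreme, n_perm), observed = obs,
       n_perm = n_perm)
}
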