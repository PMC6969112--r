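small_life <- life_history_params(N = 400)

test_that("replicates are reproducible from the master seed", {
  scn <- make_small_population_fixture(N = 300, horizon_days = 60,
                                       replicates = 2, seed = 42)
  e1 <- run_scenario(scn)
  e2 <- run_scenario(scn)
  expect_identical(e1$runs[[1]]$females, e2$runs[[1]]$females)
  expect_identical(e1$runs[[2]]$males, e2$runs[[2]]$males)
  # different replicate streams actually differ
  expect_false(identical(e1$runs[[1]]$females, e1$runs[[2]]$females))
})

test_that("stochastic counts stay non-negative integers", {
  der <- calibrate_life_history(small_life)
  a <- drive_architecture("full_GD")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 0.9, rho = 0.5))
  k <- tgdrive:::cube_kernel(cube, small_life)
  rel <- release_schedule(first_day = 10, size = 40,
                          genotype = "T/T|M")
  set.seed(7)
  st <- equilibrium_state(cube, small_life, der, stochastic = TRUE)
  for (d in 1:150) {
    st <- step_day(st, cube, small_life, der, releases = rel,
                   mode = "stochastic", kernel = k)
    for (x in list(st$E, st$L, st$P, st$AM, st$AF, st$AU)) {
      expect_true(all(x >= 0))
      expect_true(all(x == floor(x)))
    }
  }
})

test_that("deterministic step equals the stochastic one-step expectation", {
  life <- life_history_params(N = 2000)
  der <- calibrate_life_history(life)
  a <- drive_architecture("full_GD")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 0.8, rho = 1))
  k <- tgdrive:::cube_kernel(cube, life)
  st <- equilibrium_state(cube, life, der, stochastic = TRUE)
  # seed a drive cohort so genetics participates in the expectation
  st$AM["T/T|M"] <- 200
  st_det <- st; st_det$stochastic <- FALSE
  det <- step_day(st_det, cube, life, der, mode = "deterministic",
                  kernel = k)
  set.seed(123)
  n_draws <- 400
  egg_tot <- males_tot <- fem_tot <- 0
  eggs_geno <- numeric(ncol(st$E))
  for (i in seq_len(n_draws)) {
    s1 <- step_day(st, cube, life, der, mode = "stochastic", kernel = k)
    egg_tot <- egg_tot + sum(s1$E[1, ])
    eggs_geno <- eggs_geno + s1$E[1, ]
    males_tot <- males_tot + sum(s1$AM)
    fem_tot <- fem_tot + sum(s1$AF) + sum(s1$AU)
  }
  # means within 4 standard errors of the deterministic step
  expect_lt(abs(egg_tot / n_draws - sum(det$E[1, ])) /
              max(sum(det$E[1, ]), 1), 0.02)
  expect_lt(abs(males_tot / n_draws - sum(det$AM)) / sum(det$AM), 0.02)
  expect_lt(abs(fem_tot / n_draws - (sum(det$AF) + sum(det$AU))) /
              (sum(det$AF) + sum(det$AU)), 0.02)
  # genotype composition of new eggs matches in proportion
  p_det <- det$E[1, ] / sum(det$E[1, ])
  p_emp <- eggs_geno / sum(eggs_geno)
  expect_lt(max(abs(p_det - p_emp)), 0.02)
})

test_that("without males, emerging females stay unmated and lay nothing", {
  der <- calibrate_life_history(small_life)
  cube <- mendelian_cube(drive_architecture("full_GD"))
  k <- tgdrive:::cube_kernel(cube, small_life)
  set.seed(3)
  st <- equilibrium_state(cube, small_life, der, stochastic = TRUE)
  st$AM[] <- 0
  st$AF[] <- 0   # no mated females either: no eggs from day one
  # remove juvenile males too, so no male can ever emerge
  male_cols <- grepl("\\|M$", st$offspring)
  st$E[, male_cols] <- 0; st$L[, male_cols] <- 0; st$P[, male_cols] <- 0
  for (d in 1:30)
    st <- step_day(st, cube, small_life, der, mode = "stochastic",
                   kernel = k)
  expect_equal(sum(st$AF), 0)
  expect_gt(sum(st$AU), 0)    # females emerged but found no mates
  expect_equal(sum(st$E[1, ]), 0)
})

test_that("an empty population stays empty", {
  der <- calibrate_life_history(small_life)
  cube <- mendelian_cube(drive_architecture("full_GD"))
  k <- tgdrive:::cube_kernel(cube, small_life)
  st <- equilibrium_state(cube, small_life, der, stochastic = TRUE)
  for (nm in c("E", "L", "P", "AM", "AF", "AU")) st[[nm]][] <- 0
  set.seed(1)
  for (d in 1:10)
    st <- step_day(st, cube, small_life, der, mode = "stochastic",
                   kernel = k)
  expect_equal(adult_counts(st)$total, 0)
  expect_equal(sum(st$E) + sum(st$L) + sum(st$P), 0)
})

test_that("Mendelian cube with equal fitness leaves allele frequency driftless", {
  # expectation check in deterministic mode: a mixed population under a
  # Mendelian cube keeps its transgene allele frequency constant
  life <- life_history_params(N = 1000)
  der <- calibrate_life_history(life)
  cube <- mendelian_cube(drive_architecture("full_GD"))
  k <- tgdrive:::cube_kernel(cube, life)
  st <- equilibrium_state(cube, life, der, stochastic = FALSE)
  # adults only (empty juvenile pipeline), 20% of alleles in T/T adults
  st$E[] <- 0; st$L[] <- 0; st$P[] <- 0
  st$AM[] <- 0; st$AF[] <- 0
  st$AM["T/T|M"] <- 100; st$AM["W/W|M"] <- 400
  st$AF["T/T|F", "T/T|M"] <- 100
  st$AF["W/W|F", "W/W|M"] <- 400
  a <- drive_architecture("full_GD")
  t_per_geno <- function(codes)
    vapply(codes, function(g)
      tgdrive:::genotype_allele_counts(g, a)["T", 1], numeric(1))
  freq <- function(s) {
    # transgene copy frequency over the whole population, juveniles included
    tf <- t_per_geno(colnames(s$AF)); tm <- t_per_geno(names(s$AM))
    to <- t_per_geno(s$offspring)
    juv <- colSums(s$E) + colSums(s$L) + colSums(s$P)
    copies <- sum((rowSums(s$AF) + s$AU) * tf) + sum(s$AM * tm) +
      sum(juv * to)
    total <- 2 * (sum(s$AF) + sum(s$AU) + sum(s$AM) + sum(juv))
    copies / total
  }
  f0 <- freq(st)
  expect_equal(f0, 0.2)
  for (d in 1:200)
    st <- step_day(st, cube, life, der, mode = "deterministic", kernel = k)
  expect_equal(freq(st), f0, tolerance = 1e-9)
})

test_that("a perfect homing drive never loses ground after release", {
  life <- life_history_params(N = 500)
  der <- calibrate_life_history(life)
  a <- drive_architecture("full_GD")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 1))
  k <- tgdrive:::cube_kernel(cube, life)
  st <- equilibrium_state(cube, life, der, stochastic = FALSE)
  rel <- release_schedule(first_day = 5, n_releases = 3, size = 20,
                          genotype = "T/T|M")
  carriers <- vapply(colnames(st$AF), tgdrive:::carries_allele, logical(1),
                     architecture = a, state = "T")
  tfreq <- function(s) {
    cnt <- vapply(seq_along(s$AM), function(i) 0, numeric(1))
    males <- s$AM; fem <- rowSums(s$AF) + s$AU
    tc <- sum(vapply(names(males), function(g)
      tgdrive:::genotype_allele_counts(g, a)["T", 1] * males[[g]],
      numeric(1))) +
      sum(vapply(names(fem), function(g)
        tgdrive:::genotype_allele_counts(g, a)["T", 1] * fem[[g]],
        numeric(1)))
    tc / (2 * (sum(males) + sum(fem)))
  }
  fr <- numeric(0)
  for (d in 1:200) {
    st <- step_day(st, cube, life, der, releases = rel,
                   mode = "deterministic", kernel = k)
    fr <- c(fr, tfreq(st))
  }
  # adult drive-allele frequency rises monotonically once the release
  # pulses and the pre-release wild-type juvenile pipeline (last release
  # day 19 + 15 days egg-to-adult + mating turnover) have washed out
  expect_true(all(diff(fr[40:200]) >= -1e-12))
  expect_gt(fr[200], fr[40])
  expect_gt(fr[200], 0.5)
})
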