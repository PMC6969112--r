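# toy trajectory builder: hand-assembled matrices, no simulation
toy_traj <- function(females, males, arch = drive_architecture("full_GD"),
                     N = 100, release_day = 10L) {
  structure(list(
    day = 0:(nrow(females) - 1L), females = females, males = males,
    juveniles = matrix(0, nrow(females), 3,
                       dimnames = list(NULL, c("egg", "larva", "pupa"))),
    releases = data.frame(day = release_day, sex = "M",
                          genotype = "T/T|M", count = 1L),
    architecture = arch, N = N, replicate = 1L, seed = 1L),
    class = "trajectory")
}

test_that("carrier fraction counts adults with any transgene copy", {
  arch <- drive_architecture("full_GD")
  gf <- enumerate_genotypes(arch, "F"); gm <- enumerate_genotypes(arch, "M")
  females <- matrix(0, 3, length(gf), dimnames = list(NULL, gf))
  males <- matrix(0, 3, length(gm), dimnames = list(NULL, gm))
  females[, "W/W|F"] <- c(50, 35, 0)
  males[, "W/W|M"] <- c(50, 35, 0)
  females[2, "W/T|F"] <- 15; males[2, "T/T|M"] <- 15
  males[3, "T/T|M"] <- 10
  tr <- toy_traj(females, males)
  expect_equal(carrier_fraction(tr), c(0, 0.3, 1), ignore_attr = TRUE)
})

test_that("allele counts conserve total copies", {
  arch <- drive_architecture("full_GD")
  gf <- enumerate_genotypes(arch, "F"); gm <- enumerate_genotypes(arch, "M")
  set.seed(5)
  females <- matrix(rpois(3 * length(gf), 4), 3,
                    dimnames = list(NULL, gf))
  males <- matrix(rpois(3 * length(gm), 4), 3, dimnames = list(NULL, gm))
  tr <- toy_traj(females, males)
  ac <- allele_counts(tr)
  adults <- rowSums(females) + rowSums(males)
  expect_equal(as.numeric(rowSums(ac[, , 1])), 2 * adults)
})

test_that("X-linked allele counts give males one copy", {
  arch <- drive_architecture("full_GDX")
  gf <- enumerate_genotypes(arch, "F"); gm <- enumerate_genotypes(arch, "M")
  females <- matrix(0, 2, length(gf), dimnames = list(NULL, gf))
  males <- matrix(0, 2, length(gm), dimnames = list(NULL, gm))
  females[, "W/T|F"] <- 10   # 10 W + 10 T copies
  males[, "T/Y|M"] <- 5      # 5 T copies
  tr <- toy_traj(females, males, arch = arch)
  ac <- allele_counts(tr)
  expect_equal(as.numeric(ac[1, "T", 1]), 15)
  expect_equal(as.numeric(ac[1, "W", 1]), 10)
  expect_equal(as.numeric(rowSums(ac[, , 1])), c(25, 25))
})

test_that("time to steady state finds the first stable window", {
  expect_equal(time_to_steady_state(rep(0.5, 100), window = 30), 0)
  osc <- rep(c(0, 1), 60)
  expect_true(is.na(time_to_steady_state(osc, window = 30)))
  stepped <- c(seq(0, 1, length.out = 101), rep(1, 60))
  expect_equal(time_to_steady_state(stepped, epsilon = 0.001,
                                    window = 30), 100)
  expect_error(time_to_steady_state(1:10, window = 30), "shorter")
})

test_that("crash and rebound classification follows the definitions", {
  arch <- drive_architecture("full_GD")
  gf <- enumerate_genotypes(arch, "F"); gm <- enumerate_genotypes(arch, "M")
  base <- function(fem_series, male_series) {
    females <- matrix(0, length(fem_series), length(gf),
                      dimnames = list(NULL, gf))
    males <- matrix(0, length(male_series), length(gm),
                    dimnames = list(NULL, gm))
    females[, "W/W|F"] <- fem_series
    males[, "W/W|M"] <- male_series
    toy_traj(females, males, N = 100, release_day = 5L)
  }
  # monotone decline to zero females
  fem <- pmax(50 - (0:60), 0); mal <- rep(50, 61)
  cr <- crash_and_rebound(base(fem, mal))
  expect_equal(cr$crash_day, which(fem == 0)[1] - 1L - 5L)
  expect_false(cr$rebound)
  # dip to 0.2 N then recovery above 0.5 N
  fem2 <- c(rep(50, 10), seq(50, 10, length.out = 20),
            seq(10, 50, length.out = 31))
  cr2 <- crash_and_rebound(base(fem2, fem2))
  expect_true(is.na(cr2$crash_day))
  expect_true(cr2$rebound)
  expect_gt(cr2$rebound_day, 0)
  # constant population: neither crash nor rebound
  cr3 <- crash_and_rebound(base(rep(50, 61), rep(50, 61)))
  expect_true(is.na(cr3$crash_day))
  expect_false(cr3$rebound)
})

test_that("metrics are pure functions of the trajectory", {
  scn <- make_small_population_fixture(N = 250, horizon_days = 80, seed = 9)
  tr <- run_scenario(scn)$runs[[1]]
  expect_identical(carrier_fraction(tr), carrier_fraction(tr))
  expect_identical(allele_counts(tr), allele_counts(tr))
  expect_identical(crash_and_rebound(tr), crash_and_rebound(tr))
})
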