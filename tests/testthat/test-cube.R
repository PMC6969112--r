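archs <- c("full_GD", "full_GDX", "tGD_linked", "tGDc", "tGDX_linked",
           "tGDXc")

test_that("every cube row is a probability distribution", {
  for (nm in c("full_GD", "full_GDX", "tGDX_linked")) {
    a <- drive_architecture(nm)
    cube <- build_cube(a, cube_params(a, q = 0.8, c_conv = 0.7, d = 0.4,
                                      rho = 0.6))
    sums <- apply(cube$tab, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-12)
    expect_true(all(cube$tab >= 0))
  }
})

test_that("autosomal offspring sex marginal is half and half", {
  a <- drive_architecture("tGD_linked")
  cube <- build_cube(a, cube_params(a, q = 0.9, c_conv = 0.8, d = 0.5,
                                    rho = 0.3))
  sexes <- sub("^.*\\|", "", cube$offspring)
  fem <- apply(cube$tab[, , sexes == "F", drop = FALSE], c(1, 2), sum)
  expect_lt(max(abs(fem - 0.5)), 1e-12)
})

test_that("q = 0 and d = 0 reduces every architecture to Mendel", {
  for (nm in archs) {
    a <- drive_architecture(nm)
    drive_off <- build_cube(a, cube_params(a, q = 0, c_conv = 1, d = 0))
    expect_identical(drive_off$tab, mendelian_cube(a)$tab, info = nm)
    het <- if (a$n_loci == 1) "W/T|F" else "TA-WB/WA-WB|F"
    wt_f <- if (a$n_loci == 1) "W/W|M" else "WA-WB/WA-WB|M"
    if (is_x_linked(a)) wt_f <- if (a$n_loci == 1) "W/Y|M" else "WA-WB/Y|M"
    expect_identical(transmission_rate(drive_off, het, wt_f, "T"), 0.5,
                     info = nm)
  }
})

test_that("transmission from a het parent follows (1 + qc)/2", {
  a <- drive_architecture("full_GD")
  for (qc in list(c(1, 0.92), c(0.8, 0.5), c(0.6, 1))) {
    cube <- build_cube(a, cube_params(a, q = qc[1], c_conv = qc[2]))
    expect_equal(transmission_rate(cube, "T/W|F", "W/W|M", "T"),
                 (1 + qc[1] * qc[2]) / 2, tolerance = 1e-14)
  }
})

test_that("transmission is monotone in conversion efficiency", {
  a <- drive_architecture("tGD_linked")
  rates <- vapply(seq(0, 1, by = 0.1), function(cc) {
    cube <- build_cube(a, cube_params(a, q = 0.8, c_conv = cc))
    transmission_rate(cube, "TA-WB/WA-TB|F", "WA-WB/WA-WB|M", "T")
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-14))
})

test_that("X-linked males transmit the drive to all daughters only", {
  a <- drive_architecture("full_GDX")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 1))
  expect_equal(transmission_rate(cube, "W/W|F", "T/Y|M", "T"), 0.5)
  expect_equal(transmission_rate(cube, "W/W|F", "T/Y|M", "T",
                                 offspring_sex = "F"), 1)
  expect_equal(transmission_rate(cube, "W/W|F", "T/Y|M", "T",
                                 offspring_sex = "M"), 0)
})

test_that("a full-drive cross with certain homing leaves no drive-free offspring", {
  a <- drive_architecture("full_GD")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 1, d = 0))
  expect_equal(transmission_rate(cube, "W/T|F", "W/W|M", "T"), 1)
})

test_that("maternal deposition yields Mendelian drive transmission from the F1", {
  # a coupled-element mother with complete deposition turns every paternal
  # W into a resistant allele; the F1's own germline then has no W target
  # left, so the drive haplotype segregates at exactly 1/2
  a <- drive_architecture("tGDX_linked")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 1, d = 1, rho = 1))
  mother <- canonical_genotype("TA-TB/WA-WB|F", a)
  row <- cube$tab[mother, "WA-WB/Y|M", ]
  f1 <- names(row)[row > 0 & grepl("TA-TB", names(row)) &
                     grepl("\\|F$", names(row))]
  expect_identical(f1, "TA-TB/RA-RB|F")
  expect_equal(transmission_rate(cube, f1, "WA-WB/Y|M", "T"), 0.5)
})

test_that("cube equals the brute-force expansion on random parameters", {
  set.seed(101)
  a <- drive_architecture("full_GD")
  for (i in 1:5) {
    params <- cube_params(a, q = runif(1), c_conv = runif(1), d = runif(1),
                          rho = runif(1))
    cube <- build_cube(a, params)
    for (m in sample(cube$mothers, 3)) for (f in sample(cube$fathers, 3))
      expect_cube_matches_oracle(cube, m, f)
  }
  ac <- drive_architecture("tGDc")
  params <- cube_params(ac, q = runif(2), c_conv = runif(2), d = runif(2),
                        rho = runif(1))
  cube <- build_cube(ac, params)
  for (m in sample(cube$mothers, 4)) for (f in sample(cube$fathers, 2))
    expect_cube_matches_oracle(cube, m, f)
})

test_that("cube CSV round trip is bit-exact", {
  a <- drive_architecture("full_GDX")
  cube <- build_cube(a, cube_params(a, q = 0.77, c_conv = 0.31, d = 0.13,
                                    rho = 0.59))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cube_csv(cube, path)
  back <- read_cube_csv(path, a)
  expect_identical(back$tab, cube$tab)
})
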