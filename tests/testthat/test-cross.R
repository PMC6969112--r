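spec3 <- indel_spectrum(c("wA", "wB", "wC"), c(0.5, 0.3, 0.13),
                        tail_prob = 0.07)

coupled_maternal <- cross_scheme(f0_cas9_parent = "mother",
                                 f0_grna_parent = "mother", coupled = TRUE)

test_that("zygotic cleavage gives one clonal indel and Mendelian inheritance", {
  tab <- simulate_cross(coupled_maternal,
                        germline_timing(z = 1, rho = 1, spectra = spec3),
                        n_vials = 12, n_offspring_per_vial = 60, seed = 5)
  tally <- distinct_indel_tally(tab, "B")
  expect_true(all(tally$n_distinct == 1))
  s <- inheritance_summary(tab, "gfp")
  se <- s$sd / sqrt(s$n_vials)
  expect_lt(abs(s$mean - 0.5), 3 * se + 1e-9)
})

test_that("pure germline conversion gives full inheritance and no indels", {
  tab <- simulate_cross(cross_scheme(),
                        germline_timing(z = 0, q_late = 1, c_late = 1),
                        n_vials = 6, n_offspring_per_vial = 40, seed = 6)
  expect_equal(inheritance_summary(tab, "gfp")$mean, 1)
  expect_equal(inheritance_summary(tab, "dsred")$mean, 1)
  expect_true(all(is.na(tab$indel)))
})

test_that("late indel diversity is bounded by the precursor-cell count", {
  for (k in c(1L, 3L)) {
    tab <- simulate_cross(cross_scheme(),
                          germline_timing(z = 0, k = k, q_late = 1,
                                          c_late = 0.3, spectra =
                                            indel_spectrum(character(0),
                                                           numeric(0), 1)),
                          n_vials = 15, n_offspring_per_vial = 60,
                          seed = 7 + k)
    tally <- distinct_indel_tally(tab, "B")
    expect_true(all(tally$n_distinct <= k))
  }
})

test_that("expected marker inheritance is (1 + qc)/2 under late conversion", {
  qc <- 0.7
  tab <- simulate_cross(cross_scheme(),
                        germline_timing(z = 0, q_late = 1, c_late = qc),
                        n_vials = 40, n_offspring_per_vial = 250, seed = 8)
  s <- inheritance_summary(tab, "gfp")
  se <- s$sd / sqrt(s$n_vials)
  expect_lt(abs(s$mean - (1 + qc) / 2), 3 * se)
})

test_that("X-linked male F1 transmits the X marker to daughters only", {
  # male F1 carries Cas9 on his single X; daughters all inherit it, sons
  # never do, and overall transmission is Mendelian
  a <- drive_architecture("tGDX_linked")
  cube <- build_cube(a, cube_params(a, q = 1, c_conv = 1))
  expect_equal(transmission_rate(cube, "WA-WB/WA-WB|F", "TA-WB/Y|M", "T",
                                 offspring_sex = "F"), 1)
  expect_equal(transmission_rate(cube, "WA-WB/WA-WB|F", "TA-WB/Y|M", "T",
                                 offspring_sex = "M"), 0)
  expect_equal(transmission_rate(cube, "WA-WB/WA-WB|F", "TA-WB/Y|M", "T"),
               0.5)
})

test_that("male F1 germlines in autosomal schemes can convert", {
  sc <- cross_scheme(f1_sex_scored = "male",
                     architecture = drive_architecture("tGD_linked"))
  tab <- simulate_cross(sc, germline_timing(q_late = 1, c_late = 1),
                        n_vials = 5, n_offspring_per_vial = 40, seed = 9)
  expect_equal(inheritance_summary(tab, "gfp")$mean, 1)
  expect_error(cross_scheme(f1_sex_scored = "male",
                            architecture = drive_architecture("tGDX_linked")),
               "autosomal")
})

test_that("simulation is reproducible and scheme validation works", {
  t1 <- simulate_cross(coupled_maternal, germline_timing(z = 0.5,
                                                         spectra = spec3),
                       n_vials = 4, n_offspring_per_vial = 25, seed = 10)
  t2 <- simulate_cross(coupled_maternal, germline_timing(z = 0.5,
                                                         spectra = spec3),
                       n_vials = 4, n_offspring_per_vial = 25, seed = 10)
  expect_identical(t1, t2)
  expect_error(cross_scheme(coupled = TRUE, f0_cas9_parent = "mother",
                            f0_grna_parent = "father"), "single F0 parent")
})

test_that("inheritance summary averages vials, not flies", {
  tab <- data.frame(
    experiment = "e", vial = c(1L, 1L, 2L, 2L),
    sex = "F", dsred = c("+", "-", "+", "-"), gfp = c("+", "-", "+", "-"),
    body = "wild", eye = "wild", count = c(40L, 10L, 9L, 1L),
    indel = NA_character_)
  s <- inheritance_summary(tab, "gfp")
  expect_equal(s$per_vial$fraction, c(0.8, 0.9))
  expect_equal(s$mean, 0.85)   # unweighted over vials
  expect_equal(s$total_flies, 60)
  # empty vial excluded with a warning
  tab2 <- rbind(tab, data.frame(experiment = "e", vial = 3L, sex = "F",
                                dsred = "-", gfp = "-", body = "wild",
                                eye = "wild", count = 0L,
                                indel = NA_character_))
  expect_warning(s2 <- inheritance_summary(tab2, "gfp"), "empty")
  expect_equal(s2$n_vials, 2L)
})

test_that("distinct indel tally counts labels per locus", {
  tab <- data.frame(
    experiment = "e", vial = c(1L, 1L, 1L, 2L), sex = "M",
    dsred = "-", gfp = "-", body = "mutant", eye = "mutant",
    count = c(2L, 1L, 3L, 1L),
    indel = c("B=wA", "B=wA;A=yC", "B=wB", NA))
  tal <- distinct_indel_tally(tab, "B")
  expect_equal(tal$n_distinct, c(2L, 0L))
  expect_equal(tal$n_sampled, c(6L, 0L))
  expect_equal(distinct_indel_tally(tab, "A")$n_distinct, c(1L, 0L))
})
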