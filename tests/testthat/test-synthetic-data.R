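test_that("random PLCD sequences match their composition targets", {
  s <- make_random_plcd(100, seed = 5)
  p <- composition_profile(s)$category_fractions
  targets <- c(polar = 0.55, aromatic = 0.10, hydrophobic = 0.15,
               charged = 0.04, other = 0.16)
  expect_true(all(abs(p[names(targets)] - targets) <= 0.01 + 1e-12))
  # determinism
  expect_identical(make_random_plcd(100, seed = 5), s)
  expect_false(identical(make_random_plcd(100, seed = 6), s))
  # degenerate target: all charged
  sc <- make_random_plcd(40, targets = c(charged = 1), seed = 2)
  expect_true(all(strsplit(sc, "")[[1]] %in% c("D", "E", "K", "R")))
  expect_error(make_random_plcd(50, targets = c(polar = 0.7, charged = 0.2)),
               "sum to 1")
})

test_that("aromatic stickers are spread along the random sequences", {
  s <- strsplit(make_random_plcd(200, seed = 9), "")[[1]]
  pos <- which(classify_residue(s) == "aromatic")
  # near-uniform placement: largest sticker-free gap stays close to the
  # uniform spacing (200/20 = 10)
  expect_lt(max(diff(pos)), 2.5 * 200 / length(pos))
  expect_gt(length(pos), 15)
})

test_that("packaged sequences have the documented lengths and charge signs", {
  a1 <- study_fixture("A1_LCD")
  a12 <- study_fixture("A1_LCD_12D")
  fus <- study_fixture("FUS_LCD")
  expect_equal(a1$n_residues, 135)
  expect_equal(a12$n_residues, 135)
  expect_equal(fus$n_residues, 214)
  expect_gt(a1$ncpr, 0)
  expect_lt(a12$ncpr, 0)
  expect_lt(fus$ncpr, 0)
  expect_lt(a12$ncpr, a1$ncpr)
  # the +12D variant differs at exactly 12 positions, all Asp
  d <- which(a1$beads != a12$beads)
  expect_equal(length(d), 12)
  expect_true(all(a12$beads[d] == "D"))
  expect_true(all(a1$beads[d] %in% c("G", "S")))
})

test_that("homopolymer systems hit equal mass and the target volume fraction", {
  cfg <- scenario_config("fig9_lengths")
  lens <- vapply(cfg$species, function(s) s$n_residues, 0L)
  counts <- vapply(cfg$species, function(s) s$n_chains, 0L)
  expect_equal(lens, c(A = 150L, B = 300L))
  expect_equal(unname(lens * counts), rep(unname(lens[1] * counts[1]), 2))
  expect_equal(cfg$volume_fraction, 0.016, tolerance = 0.05)
  cfg3 <- scenario_config("fig9_three_lengths")
  lens3 <- vapply(cfg3$species, function(s) s$n_residues, 0L)
  counts3 <- vapply(cfg3$species, function(s) s$n_chains, 0L)
  expect_equal(unname(lens3), c(200L, 300L, 400L))
  expect_equal(length(unique(lens3 * counts3)), 1)
  expect_error(make_homopolymer_system(c(150, 301), two_type_model(),
                                       beads_per_species = 900),
               "divisible")
})

test_that("scenario ids produce valid configurations with scenario matrices", {
  e8 <- scenario_config("fig8_hetero", e_base = -1, delta = 0.5)
  ce <- e8$model$contact_energy
  expect_equal(ce["A", "B"], -1.5)
  expect_equal(ce["A", "A"], -1)
  expect_equal(length(e8$species), 2)
  em <- scenario_config("fig9_matched", scale_B = 0.8)
  cm <- em$model$contact_energy
  expect_equal(cm["B", "B"], -0.8)
  expect_equal(cm["A", "B"], -0.8)
  expect_equal(cm["A", "A"], -1)
  ep <- scenario_config("plcd_mixture")
  expect_equal(vapply(ep$species, function(s) s$n_residues, 0L),
               c(A1_LCD = 135L, FUS_LCD = 214L))
  expect_gt(ep$model$w_el, 0)
})

test_that("full-scale presets reproduce the production conditions", {
  f <- scenario_config("fig8_equal", scale = "full")
  expect_equal(unname(f$box), rep(150L, 3))
  expect_equal(f$total_steps, 3e10)
  expect_equal(f$n_replicates, 5L)
  expect_equal(f$init_box, 35L)
  expect_equal(vapply(f$species, function(s) s$n_residues, 0L),
               c(A = 150L, B = 150L))
})
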