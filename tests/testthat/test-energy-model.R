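test_that("pair energy combines the contact matrix with the charge penalty", {
  m <- two_type_model(eAA = -2, eAB = -1.5, eBB = -1, w_el = 1)
  # coupling off
  m0 <- two_type_model(eAA = -2, eAB = -1.5, eBB = -1, w_el = 0)
  expect_equal(pair_energy(m0, "A", "A", 0.7, -0.2), -2)
  # complementary charges cancel exactly
  expect_equal(pair_energy(m, "A", "B", 0.4, -0.4), -1.5)
  # direct arithmetic of the quadratic penalty
  expect_equal(pair_energy(m, "A", "A", 0.1, 0.1), -2 + 0.01)
  # symmetry under exchanging the two beads and their chains
  expect_equal(pair_energy(m, "A", "B", 0.3, -0.1),
               pair_energy(m, "B", "A", -0.1, 0.3))
  # like-charged replacement of a +/- pair weakens the attraction
  expect_gt(pair_energy(m, "A", "B", 0.2, 0.2),
            pair_energy(m, "A", "B", 0.2, -0.2))
  expect_error(pair_energy(m, "A", "Q"), class = "latmix_unknown_type_error")
})

test_that("interaction_model validates its inputs", {
  mm <- matrix(c(-1, -2, -1.99, -1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(interaction_model(mm), "symmetric")
  mm[1, 2] <- -2
  expect_error(interaction_model(mm, w_el = -1), "w_el")
  expect_error(interaction_model(mm, neighbor_shell = 6), "26")
  expect_s3_class(interaction_model(mm), "interaction_model")
})

test_that("scenario matrices realize the four interaction patterns", {
  eq <- scenario_matrix("equal", -1, 0.5)$contact_energy
  expect_equal(unname(eq), matrix(-1, 2, 2))
  he <- scenario_matrix("hetero_stronger", -1, 0.5)$contact_energy
  expect_equal(he["A", "B"], -1.5)
  expect_equal(he["B", "A"], -1.5)
  expect_equal(he["A", "A"], -1)
  expect_equal(he["B", "B"], -1)
  ho <- scenario_matrix("homo_stronger", -1, 0.5)$contact_energy
  expect_equal(ho["A", "A"], -1.5)
  expect_equal(ho["B", "B"], -1.5)
  expect_equal(ho["A", "B"], -1)
  as <- scenario_matrix("asymmetric_A_weak", -1, 0.5)$contact_energy
  expect_equal(as["A", "A"], -0.5)
  expect_equal(as["A", "B"], -1)
  expect_equal(as["B", "B"], -1)
  expect_error(scenario_matrix("equal", -1, -0.1), "delta")
  expect_error(scenario_matrix("equal", 1, 0.5), "negative")
})

test_that("interaction matrices round-trip through the text format", {
  m <- default_plcd_model(w_el = 2)
  f <- tempfile(fileext = ".tsv")
  write_interaction_matrix(m, f)
  back <- read_interaction_matrix(f, w_el = 2)
  expect_equal(back$contact_energy, m$contact_energy)
  expect_equal(back$w_el, 2)
})

test_that("system energy sums shell contacts, excluding bonded pairs", {
  sp <- list(A = homopolymer("A", 2, n_chains = 2))
  model <- two_type_model()  # all -1
  # two 2-bead chains in full face contact: 4 inter-chain shell pairs
  coords <- rbind(c(0, 0, 0), c(1, 0, 0),
                  c(0, 1, 0), c(1, 1, 0))
  fr <- manual_frame(coords, sp, model, box = 10)
  expect_equal(system_energy(fr), -4)
  # no two beads within the shell -> zero
  far <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(5, 5, 5), c(6, 5, 5))
  expect_equal(system_energy(manual_frame(far, sp, model, box = 12)), 0)
  # doubling every contact energy doubles the total (w_el = 0)
  model2 <- two_type_model(eAA = -2, eAB = -2, eBB = -2)
  expect_equal(system_energy(fr, model2), 2 * system_energy(fr))
  # overlapping beads are rejected
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(system_energy(manual_frame(bad, sp, model, box = 10)),
               "occupy")
})

test_that("the default PLCD matrix is symmetric with aromatic stickers", {
  m <- default_plcd_model()
  ce <- m$contact_energy
  expect_equal(ce, t(ce))
  expect_lt(ce["Y", "Y"], ce["G", "G"])   # stickers stronger than spacers
  expect_lt(ce["Y", "R"], ce["G", "S"])   # Arg is an auxiliary sticker
  expect_true(all(ce <= 0))
})
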