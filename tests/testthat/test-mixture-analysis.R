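test_that("additivity null interpolates the pure saturation concentrations", {
  expect_equal(additivity_null(2, 4, 1), 2)
  expect_equal(additivity_null(2, 4, 0), 4)
  expect_equal(additivity_null(2, 4, 0.5), 3)
  expect_equal(additivity_null(1, 3, c(0, 0.25, 1)), c(3, 2.5, 1))
  expect_error(additivity_null(2, 4, 1.2), "0, 1")
  expect_error(additivity_null(-1, 4, 0.5), "positive")
})

test_that("cooperativity classification follows the sign of the deviation", {
  arm0 <- data.frame(a = c(0, 0.5, 1), c_dilute_total = c(4, 3, 2))
  expect_equal(classify_cooperativity(arm0)$classification, "additive")
  armc <- data.frame(a = c(0, 0.25, 0.5, 0.75, 1),
                     c_dilute_total = c(4, 2.8, 2.2, 2.0, 2),
                     se = rep(0.05, 5))
  resc <- classify_cooperativity(armc)
  expect_equal(resc$classification, "positive")
  expect_true(all(resc$deviations$deviation < 0))
  armv <- data.frame(a = c(0, 0.5, 1), c_dilute_total = c(4, 3.8, 2),
                     se = rep(0.05, 3))
  expect_equal(classify_cooperativity(armv)$classification, "negative")
  expect_error(classify_cooperativity(
    data.frame(a = c(0.3, 0.5), c_dilute_total = c(1, 1))), "endpoint")
})

test_that("tie lines report both segment slopes and classify dominance", {
  # diagonal: both slopes 1, heterotypic-dominant
  tl <- tie_line(c(1, 1), c(2, 2), c(5, 5))
  expect_equal(tl$slope_dilute_to_total, 1)
  expect_equal(tl$slope_total_to_dense, 1)
  expect_equal(tl$collinearity_gap, 0)
  expect_equal(tl$classification, "heterotypic_dominant")
  # doubling line through the origin: slope 2, B-dominant
  tl2 <- tie_line(c(1, 2), c(2, 4), c(4, 8))
  expect_equal(tl2$slope_dilute_to_total, 2)
  expect_equal(tl2$slope_total_to_dense, 2)
  expect_equal(tl2$classification, "homotypic_B_dominant")
  # slope below one: A-dominant
  tl3 <- tie_line(c(2, 1), c(4, 2), c(8, 4))
  expect_equal(tl3$classification, "homotypic_A_dominant")
  # near-unity slopes within generous errors stay heterotypic
  tl4 <- tie_line(c(1, 1.05), c(2, 2), c(5, 5.1),
                  se_dilute = c(0.2, 0.2), se_dense = c(0.3, 0.3))
  expect_equal(tl4$classification, "heterotypic_dominant")
  # vertical segment flagged with infinite slope
  tlv <- tie_line(c(1, 1), c(1, 2), c(1, 5))
  expect_true(tlv$vertical)
  expect_true(is.infinite(tlv$slope_dilute_to_total))
})

test_that("crosslink parameter matches a hand-counted frame", {
  # 2 A-chains and 1 B-chain of 2 beads; A1-A2 touch (4 contacts),
  # A2-B touch (4 contacts), A1-B do not.
  # Ends: M_AA = 8, M_AB = 4, M_BA = 4, M_BB = 0; cluster beads: A 4, B 2.
  # Expectations: AA (4-2)/(6-2) = 1/2, AB 2/4 = 1/2, BA 4/4 = 1,
  # BB (2-2)/4 = 0 (undefined).
  # L_AA = (8/12)/(1/2) = 4/3, L_AB = (4/12)/(1/2) = 2/3, L_BA = 1, L_BB = NA.
  sp <- list(A = homopolymer("A", 2, n_chains = 2),
             B = homopolymer("B", 2, n_chains = 1))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0),
                  c(0, 1, 0), c(1, 1, 0),
                  c(0, 2, 0), c(1, 2, 0))
  tr <- manual_trajectory(list(coords), sp, two_type_model(), box = 12)
  cs <- crosslink_parameter(list(tr))
  expect_equal(cs$L["A", "A"], 4 / 3, tolerance = 1e-12)
  expect_equal(cs$L["A", "B"], 2 / 3, tolerance = 1e-12)
  expect_equal(cs$L["B", "A"], 1, tolerance = 1e-12)
  expect_true(is.na(cs$L["B", "B"]))
})

test_that("radius of gyration handles straight, compact and seam-crossing chains", {
  model <- two_type_model()
  # fully extended 4-bead chain: Rg = sqrt(5/4)
  sp <- list(A = homopolymer("A", 4, n_chains = 1))
  tr <- manual_trajectory(list(straight_chain(4, 3, 3, 3)), sp, model, box = 16)
  rg <- rg_profile(tr, binwidth = 2)
  got <- rg$rg_norm["A", which(rg$counts["A", ] > 0)]
  expect_equal(unname(got), sqrt(5 / 4) / sqrt(4), tolerance = 1e-9)
  # 2x2 plaquette: all beads 0.5*sqrt(2) from the center -> Rg = sqrt(1/2)
  plaq <- rbind(c(3, 3, 3), c(4, 3, 3), c(4, 4, 3), c(3, 4, 3))
  trp <- manual_trajectory(list(plaq), sp, model, box = 16)
  rgp <- rg_profile(trp, binwidth = 2)
  gotp <- rgp$rg_norm["A", which(rgp$counts["A", ] > 0)]
  expect_equal(unname(gotp), sqrt(0.5) / 2, tolerance = 1e-9)
  # chain wrapped across the periodic seam unwraps before measuring
  sp2 <- list(A = homopolymer("A", 4, n_chains = 1))
  wrapped <- rbind(c(14, 3, 3), c(15, 3, 3), c(0, 3, 3), c(1, 3, 3))
  trw <- manual_trajectory(list(wrapped), sp2, model, box = 16)
  rgw <- rg_profile(trw, binwidth = 2)
  gotw <- rgw$rg_norm["A", which(rgw$counts["A", ] > 0)]
  expect_equal(unname(gotw), sqrt(5 / 4) / sqrt(4), tolerance = 1e-9)
})

test_that("energy scaling touches one species' rows and columns once", {
  m <- two_type_model(eAA = -1, eAB = -2, eBB = -3)
  s <- scale_species_energies(m, "A", 0.5)
  expect_equal(s$contact_energy["A", "A"], -0.5)
  expect_equal(s$contact_energy["A", "B"], -1)
  expect_equal(s$contact_energy["B", "A"], -1)
  expect_equal(s$contact_energy["B", "B"], -3)
})

test_that("bisection matches a saturation concentration target", {
  # deterministic surrogate: c_sat decreases with interaction scale
  fn <- function(s) 2 / s
  res <- match_csat(fn, target = 1, lower = 0.5, upper = 8, tol = 1e-3,
                    max_iter = 40)
  expect_true(res$converged)
  expect_equal(res$scale, 2, tolerance = 1e-2)
  expect_error(match_csat(fn, target = 10, lower = 1, upper = 2), "bracket")
})
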