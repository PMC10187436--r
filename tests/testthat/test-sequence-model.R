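test_that("residues map to their coarse categories", {
  expect_equal(classify_residue("G"), "polar")
  expect_equal(classify_residue("Y"), "aromatic")
  expect_equal(classify_residue("P"), "other")
  expect_equal(classify_residue("H"), "aromatic")
  expect_equal(classify_residue(c("l", "d", "a")),
               c("hydrophobic", "charged", "other"))
  # every canonical residue lands in exactly one category
  all20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cats <- classify_residue(all20)
  expect_true(all(cats %in% c("polar", "aromatic", "hydrophobic",
                              "charged", "other")))
  expect_error(classify_residue("Z"), class = "latmix_unknown_residue_error")
  expect_error(classify_residue("GXS"), class = "latmix_unknown_residue_error")
})

test_that("composition profiles sum to one and match direct counts", {
  p <- composition_profile("GGSS")
  expect_equal(unname(p$category_fractions["polar"]), 1)
  expect_equal(sum(p$category_fractions), 1, tolerance = 1e-12)
  expect_equal(unname(composition_profile("DKDK")$category_fractions["charged"]), 1)
  p3 <- composition_profile("GYDP")
  expect_equal(unname(p3$category_fractions[c("polar", "aromatic",
                                              "charged", "other")]),
               rep(0.25, 4))
  expect_equal(sum(p3$residue_fractions), 1, tolerance = 1e-12)
  expect_error(composition_profile(""), class = "latmix_unknown_residue_error")
})

test_that("profile of a concatenation is the length-weighted mean of parts", {
  s1 <- "GGSSYYDD"
  s2 <- "PPPALIV"
  p1 <- composition_profile(s1)$category_fractions
  p2 <- composition_profile(s2)$category_fractions
  pc <- composition_profile(paste0(s1, s2))$category_fractions
  w <- nchar(s1) / (nchar(s1) + nchar(s2))
  expect_equal(pc, w * p1 + (1 - w) * p2, tolerance = 1e-12)
})

test_that("NCPR and FCR follow the charge counts, His neutral", {
  expect_equal(ncpr("EK"), 0)
  expect_equal(fcr("EK"), 1)
  expect_equal(ncpr("DDK"), -1 / 3)
  expect_equal(fcr("DDK"), 1)
  expect_equal(ncpr("GGGG"), 0)
  expect_equal(fcr("GGGG"), 0)
  expect_equal(ncpr("HHHH"), 0)  # His carries no charge
  expect_equal(fcr("HHHH"), 0)
})

test_that("NCPR flips sign under the D<->K, E<->R swap and |ncpr| <= fcr", {
  set.seed(42)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  swap <- c(D = "K", K = "D", E = "R", R = "E")
  for (i in 1:20) {
    s <- sample(aas, 30, replace = TRUE)
    s2 <- ifelse(s %in% names(swap), swap[s], s)
    expect_equal(ncpr(s2), -ncpr(s))
    expect_lte(abs(ncpr(s)), fcr(s))
    expect_equal(fcr(s2), fcr(s))
  }
})

test_that("polymer_species validates and derives its descriptors", {
  sp <- polymer_species("toy", "gysD", n_chains = 3)
  expect_s3_class(sp, "polymer_species")
  expect_equal(sp$n_residues, 4)
  expect_equal(sp$beads, c("G", "Y", "S", "D"))
  expect_equal(sp$ncpr, -0.25)
  expect_error(polymer_species("x", "G"), "at least 2")
  expect_error(polymer_species("x", "GG", n_chains = -1))
  # homopolymers have one distinct bead type and configurable charge
  h <- homopolymer("A", 10, n_chains = 2, ncpr = 0.3)
  expect_equal(length(unique(h$beads)), 1)
  expect_equal(h$ncpr, 0.3)
  expect_gte(h$fcr, abs(h$ncpr))
})

test_that("FASTA round trip preserves sequences, case-insensitively", {
  sp <- list(polymer_species("s1", "GYSSDKAP"),
             polymer_species("s2", "qqnngg"))
  f <- tempfile(fileext = ".fasta")
  write_species_fasta(sp, f)
  back <- read_species_fasta(f)
  expect_equal(names(back), c("s1", "s2"))
  expect_equal(back$s1$beads, sp[[1]]$beads)
  expect_equal(back$s2$beads, sp[[2]]$beads)
})
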