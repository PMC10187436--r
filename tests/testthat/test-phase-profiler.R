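test_that("largest cluster matches a brute-force adjacency closure", {
  sp <- list(A = homopolymer("A", 2, n_chains = 5))
  model <- two_type_model()
  # 5 chains: 1-2 touching, 2-3 touching, 4-5 touching, -> {1,2,3} largest
  coords <- rbind(c(0, 0, 0), c(1, 0, 0),
                  c(0, 1, 0), c(1, 1, 0),
                  c(0, 2, 0), c(1, 2, 0),
                  c(10, 10, 10), c(11, 10, 10),
                  c(10, 11, 10), c(11, 11, 10))
  fr <- manual_frame(coords, sp, model, box = 20)
  cl <- largest_cluster(fr)
  expect_setequal(cl$chains, 1:3)
  expect_false(cl$dispersed)
  # brute-force oracle: transitive closure over pairwise chain contacts
  chain_of <- rep(1:5, each = 2)
  adj <- matrix(FALSE, 5, 5)
  for (i in 1:9) for (j in (i + 1):10) {
    d <- pmin(abs(coords[i, ] - coords[j, ]), 20 - abs(coords[i, ] - coords[j, ]))
    if (max(d) <= 1 && chain_of[i] != chain_of[j])
      adj[chain_of[i], chain_of[j]] <- adj[chain_of[j], chain_of[i]] <- TRUE
  }
  reach <- adj | diag(5)
  for (k in 1:5) reach <- reach | (reach %*% reach > 0)
  comps <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  sizes <- lengths(strsplit(comps, ","))
  expect_equal(sort(cl$chains),
               as.integer(strsplit(comps[which.max(sizes)], ",")[[1]]))

  # fully dispersed frame: single flagged chain
  far <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(5, 5, 5), c(6, 5, 5),
               c(10, 10, 10), c(11, 10, 10),
               c(15, 15, 15), c(16, 15, 15),
               c(3, 12, 3), c(4, 12, 3))
  cl2 <- largest_cluster(manual_frame(far, sp, model, box = 20))
  expect_true(cl2$dispersed)
  expect_equal(length(cl2$chains), 1)
})

test_that("condensate center of mass respects periodic boundaries", {
  sp <- list(A = homopolymer("A", 2, n_chains = 1))
  model <- two_type_model()
  # compact pair away from the seam: equals the naive mean
  fr <- manual_frame(rbind(c(4, 5, 6), c(5, 5, 6)), sp, model, box = 20)
  expect_equal(condensate_com(fr, 1), c(4.5, 5, 6), tolerance = 1e-9)
  # straddling the seam symmetrically: COM at the seam, not the box center
  fr2 <- manual_frame(rbind(c(19, 0, 0), c(0, 0, 0)), sp, model, box = 20)
  com <- condensate_com(fr2, 1)
  expect_equal(min(com[1], 20 - com[1]), 0.5, tolerance = 1e-9)
  expect_error(condensate_com(fr2, integer(0)), "empty")
})

test_that("radial densities recover concentrated and uniform occupancies", {
  model <- two_type_model()
  sp <- list(A = homopolymer("A", 2, n_chains = 14))
  # compact blob: all beads within r < 3 of the center -> outer bins empty
  set.seed(3)
  base <- c(10, 10, 10)
  coords <- NULL
  occupied <- character(0)
  n <- 0
  while (n < 14) {
    p <- base + sample(-2:1, 3, replace = TRUE)
    key <- paste(p, collapse = ",")
    key2 <- paste(p + c(1, 0, 0), collapse = ",")
    if (key %in% occupied || key2 %in% occupied) next
    coords <- rbind(coords, p, p + c(1, 0, 0))
    occupied <- c(occupied, key, key2)
    n <- n + 1
  }
  tr <- manual_trajectory(list(unname(coords)), sp, model, box = 20)
  prof <- radial_profile(tr)
  expect_true(all(prof$density[, prof$bin_centers > 4] == 0))
  expect_gt(sum(prof$density[, prof$bin_centers < 4]), 0)

  # uniform random occupancy at fraction phi: flat profile ~ phi
  set.seed(7)
  L <- 24
  sites <- as.matrix(expand.grid(x = 0:(L - 1), y = 0:(L - 1), z = 0:(L - 1)))
  # dimer chains on x-adjacent site pairs at even x: sample without clashes
  pairs <- sites[sites[, 1] %% 2 == 0, ]
  pick <- pairs[sample(nrow(pairs), 500), ]
  coords2 <- matrix(NA_integer_, 1000, 3)
  coords2[seq(1, 999, 2), ] <- pick
  coords2[seq(2, 1000, 2), ] <- sweep(pick, 2, c(1, 0, 0), "+")
  sp2 <- list(A = homopolymer("A", 2, n_chains = 500))
  tr2 <- manual_trajectory(list(coords2), sp2, model, box = L)
  prof2 <- radial_profile(tr2)
  phi <- 1000 / L^3
  # innermost bins are excluded: with a near-uniform gas the center-of-mass
  # estimator correlates with density fluctuations, enriching tiny shells
  inner <- prof2$bin_centers >= 4 & prof2$bin_centers <= L / 2 - 1
  expect_equal(mean(prof2$density[1, inner]), phi, tolerance = 0.15)
  expect_true(all(abs(prof2$density[1, inner] / phi - 1) < 0.5))
})

test_that("logistic fits recover exact profiles and flag degenerate ones", {
  r <- seq(0.5, 24.5, by = 1)
  truth <- list(den = 0.62, dil = 0.004, rmid = 9.3, w = 1.4)
  rho <- truth$dil + (truth$den - truth$dil) /
    (1 + exp((r - truth$rmid) / truth$w))
  f <- fit_logistic(rho, r = r)
  expect_equal(f$rho_dense, truth$den, tolerance = 1e-6)
  expect_equal(f$rho_dilute, truth$dil, tolerance = 1e-6)
  expect_equal(f$r_mid, truth$rmid, tolerance = 1e-6)
  expect_equal(f$width, truth$w, tolerance = 1e-6)
  # interfacial interval brackets r_mid at the 90%/10% crossings
  expect_lt(f$r_lo, f$r_mid)
  expect_gt(f$r_hi, f$r_mid)
  expect_equal(f$r_hi - f$r_lo, 2 * f$width * log(9), tolerance = 1e-9)

  # step profile: small width, midpoint at the step
  step <- ifelse(r < 10, 0.6, 0.01)
  fs <- fit_logistic(step, r = r)
  expect_lt(fs$width, 0.6)
  expect_equal(fs$r_mid, 10, tolerance = 0.6)

  # flat profile: degenerate plateaus
  expect_error(fit_logistic(rep(0.3, 25), r = r),
               class = "latmix_single_phase_error")
})

test_that("coexisting concentrations read the fitted plateaus exactly", {
  r <- seq(0.5, 19.5, by = 1)
  mk <- function(den, dil) den / (1 + exp((r - 8) / 1.2)) +
    dil * (1 - 1 / (1 + exp((r - 8) / 1.2)))
  dens <- rbind(A = mk(0.5, 0.002), B = mk(0.25, 0.01))
  prof <- structure(list(
    bin_centers = r, density = dens, se = NULL,
    site_counts = rep(100, length(r)), replicate_density = NULL,
    cluster_fraction = 1, temperature = 5, binwidth = 1,
    species = c("A", "B"), cluster_threshold = 0.5), class = "radial_profile")
  pp <- coexisting_concentrations(prof)
  expect_false(pp$single_phase)
  expect_equal(pp$table$c_dense, c(0.5, 0.25), tolerance = 1e-6)
  expect_equal(pp$table$c_dilute, c(0.002, 0.01), tolerance = 1e-6)
})

test_that("binodals order by temperature and drop single-phase points", {
  # synthetic ensembles are expensive; use a fast two-temperature toy where
  # the high temperature is single-phase (dispersed chains)
  cfg <- scenario_config("fig8_equal", seed = 4, total_steps = 8e5,
                         n_replicates = 2, temperatures = c(10, 60))
  cfg$init_box <- 18L
  ens <- run_mc(cfg)
  expect_message(bino <- build_binodal(ens), "single-phase")
  if (nrow(bino) > 0) {
    expect_true(all(bino$temperature == 10))
    tot <- bino[bino$species == "total", ]
    sub <- bino[bino$species != "total", ]
    expect_equal(tot$c_dense, sum(sub$c_dense), tolerance = 1e-9)
    expect_true(all(sub$c_dilute <= sub$c_dense))
  }
})

test_that("two-component diagrams collect stoichiometries with pure endpoints", {
  mk <- function(na, nb, seed) {
    m <- two_type_model(eAA = -1, eAB = -1, eBB = -1)
    sp <- list()
    if (na > 0) sp$A <- homopolymer("A", 30, n_chains = na)
    if (nb > 0) sp$B <- homopolymer("B", 30, n_chains = nb)
    cfg <- run_config(sp, m, box = 30, temperatures = 5.5,
                      total_steps = 1e6, n_replicates = 2, seed = seed,
                      init_box = 12,
                      move_weights = latmix:::.PRESET_MOVE_WEIGHTS)
    run_mc(cfg)
  }
  ens <- list(mk(16, 0, 61), mk(8, 8, 62), mk(0, 16, 63))
  d <- two_component_diagram(ens)
  expect_s3_class(d, "two_component_diagram")
  expect_equal(d$a, c(0, 0.5, 1))
  # pure runs put their point on the corresponding axis
  expect_equal(d$c_dilute_B[d$a == 1], 0)
  expect_equal(d$c_dilute_A[d$a == 0], 0)
  expect_equal(d$c_tot_A[d$a == 1], 16 * 30 / 30^3)
  # bulk concentration brackets the coexisting phases (mass closure)
  tot <- d$c_tot_A + d$c_tot_B
  expect_true(all(d$c_dilute_A + d$c_dilute_B <= tot + 1e-9))
  expect_true(all(d$c_dense_A + d$c_dense_B >= tot - 1e-9))
  # a diagram plot renders from the assembled table
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  plot(d)
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
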