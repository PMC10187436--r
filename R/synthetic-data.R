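# Generators for every input the pipeline needs without downloads:
# homopolymer mixture scenarios, enumerable toy systems for the exact oracle,
# PLCD-like random sequences, and the packaged study-like sequences.

# move mix used by the scenario presets: local relaxation dominates, with
# occasional reptation, rigid-body and pivot moves; cluster translations are
# rare (they are expensive and mainly recentre the condensate).
.PRESET_MOVE_WEIGHTS <- c(local_bead = 70, slithering_snake = 4,
                          chain_translation = 8, pivot = 10,
                          double_pivot = 6, co_local = 1.9,
                          cluster_translation = 0.1)

# desk-scale study conditions per scenario (box sized to a total bead volume
# fraction of ~0.016, the condition all presets share; temperatures sit in
# the two-phase window of the e_base = -1 energy scale, see the vignette)
.DESK <- list(
  fig8 = list(length = 75L, n_per_species = 10L, box = 45L,
              temperatures = c(10, 12), steps = 3e6, replicates = 3L),
  fig9 = list(box = 48L, temperatures = 13, steps = 6e6, replicates = 3L),
  plcd = list(box = 47L, temperatures = 6, steps = 4e6, replicates = 3L)
)

# edge of a subbox holding the beads at ~0.3 volume fraction: a dense seed
# from which the condensate only needs surface equilibration
.dense_init_edge <- function(total_beads) {
  max(6L, as.integer(ceiling((total_beads / 0.3)^(1 / 3))))
}

#' Homopolymer mixture system
#'
#' Builds a run configuration for a mixture of generic-type homopolymers with
#' equal total bead counts per species (equal mass concentrations) at a
#' target total bead volume fraction.
#'
#' @param lengths integer vector of chain lengths, one per species.
#' @param model an `interaction_model` whose types cover "A", "B", ... as
#'   needed.
#' @param box lattice edge; if NULL, sized so that the realized volume
#'   fraction is close to `volume_fraction`.
#' @param beads_per_species total beads per species (chain counts are
#'   `beads_per_species / lengths`, which must divide evenly).
#' @param volume_fraction target total bead volume fraction (default 0.016).
#' @param ncpr per-species NCPR values (default 0: electrostatics inert).
#' @param ... passed to [run_config()].
#' @return a `run_config`.
#' @export
make_homopolymer_system <- function(lengths, model, box = NULL,
                                    beads_per_species = NULL,
                                    volume_fraction = 0.016, ncpr = NULL,
                                    ...) {
  k <- length(lengths)
  types <- LETTERS[seq_len(k)]
  if (is.null(beads_per_species)) {
    # smallest equal-mass bead count compatible with whole chains
    beads_per_species <- Reduce(function(a, b) a * b / .gcd(a, b),
                                as.numeric(lengths))
  }
  counts <- beads_per_species / lengths
  if (any(counts != round(counts)))
    stop("beads_per_species must be divisible by every chain length")
  if (is.null(ncpr)) ncpr <- rep(0, k)
  species <- lapply(seq_len(k), function(i) {
    homopolymer(types[i], lengths[i], n_chains = as.integer(counts[i]),
                ncpr = ncpr[i])
  })
  names(species) <- types
  total_beads <- beads_per_species * k
  if (is.null(box)) box <- max(8L, round((total_beads / volume_fraction)^(1/3)))
  run_config(species, model, box = box, ...)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Named scenario configurations
#'
#' Ready-made study conditions for the homopolymer-mixture scenario battery:
#' the four interaction scenarios of a 1:1 two-species mixture
#' (`fig8_equal`, `fig8_hetero`, `fig8_homo`, `fig8_asym`), the chain-length
#' scenarios (`fig9_lengths` = 150+300-mers, `fig9_matched` with one species'
#' energies rescaled, `fig9_three_lengths` = 200+300+400-mers), a tiny
#' enumerable toy (`toy_enumerable`), and a PLCD mixture built from the
#' packaged sequences (`plcd_mixture`). Desk scale keeps systems small enough
#' for a workstation; full scale reproduces the production conditions
#' (150-bead chains, 150^3 box, 3e10 steps, 5 replicates) and is meant for
#' cluster runs.
#'
#' @param scenario scenario id (see Details).
#' @param scale `"desk"` (default) or `"full"`.
#' @param seed base seed recorded in the configuration.
#' @param e_base,delta contact-energy scale and modulation of the scenario
#'   matrices.
#' @param temperatures optional override of the preset temperature list.
#' @param total_steps,n_replicates optional overrides.
#' @param scale_B scale factor on the longer species' energies for
#'   `fig9_matched` (default 0.93).
#' @param w_el electrostatic coupling for `plcd_mixture` (default 4).
#' @return a `run_config`.
#' @export
scenario_config <- function(scenario = c("fig8_equal", "fig8_hetero",
                                         "fig8_homo", "fig8_asym",
                                         "fig9_lengths", "fig9_matched",
                                         "fig9_three_lengths",
                                         "toy_enumerable", "plcd_mixture"),
                            scale = c("desk", "full"), seed = 1L,
                            e_base = -1, delta = 0.5,
                            temperatures = NULL, total_steps = NULL,
                            n_replicates = NULL, scale_B = 0.93, w_el = 4) {
  scenario <- match.arg(scenario)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  reps <- function(d) if (is.null(n_replicates)) (if (desk) d else 5L)
                      else n_replicates
  steps <- function(d) if (is.null(total_steps)) (if (desk) d else 3e10)
                       else total_steps

  if (startsWith(scenario, "fig8_")) {
    sc <- switch(scenario, fig8_equal = "equal",
                 fig8_hetero = "hetero_stronger",
                 fig8_homo = "homo_stronger",
                 fig8_asym = "asymmetric_A_weak")
    p <- .DESK$fig8
    len <- if (desk) p$length else 150L
    nper <- if (desk) p$n_per_species else 180L
    box <- if (desk) p$box else 150L
    model <- scenario_matrix(sc, e_base = e_base, delta = delta)
    return(make_homopolymer_system(
      rep(len, 2), model, box = box, beads_per_species = len * nper,
      temperatures = if (is.null(temperatures)) p$temperatures else temperatures,
      total_steps = steps(p$steps), n_replicates = reps(p$replicates),
      seed = seed, move_weights = .PRESET_MOVE_WEIGHTS,
      init_box = if (desk) .dense_init_edge(2 * len * nper) else 35L))
  }
  if (scenario %in% c("fig9_lengths", "fig9_matched")) {
    p <- .DESK$fig9
    model <- scenario_matrix("equal", e_base = e_base, delta = 0)
    if (scenario == "fig9_matched")
      model <- scale_species_energies(model, "B", scale_B)
    beads <- if (desk) 900L else 27000L
    return(make_homopolymer_system(
      c(150L, 300L), model, box = if (desk) p$box else 150L,
      beads_per_species = beads,
      temperatures = if (is.null(temperatures)) p$temperatures else temperatures,
      total_steps = steps(p$steps), n_replicates = reps(p$replicates),
      seed = seed, move_weights = .PRESET_MOVE_WEIGHTS,
      init_box = if (desk) .dense_init_edge(2 * beads) else 35L))
  }
  if (scenario == "fig9_three_lengths") {
    p <- .DESK$fig9
    model3 <- interaction_model(
      matrix(e_base, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3])))
    beads <- if (desk) 1200L else 18000L
    return(make_homopolymer_system(
      c(200L, 300L, 400L), model3, box = if (desk) 61L else 150L,
      beads_per_species = beads,
      temperatures = if (is.null(temperatures)) p$temperatures else temperatures,
      total_steps = steps(p$steps), n_replicates = reps(p$replicates),
      seed = seed, move_weights = .PRESET_MOVE_WEIGHTS,
      init_box = if (desk) .dense_init_edge(3 * beads) else 35L))
  }
  if (scenario == "toy_enumerable") {
    return(make_enumerable_toy(n_chains = 2, length = 3, box = 4,
                               energies = scenario_matrix("equal", -1, 0),
                               temperature = if (is.null(temperatures)) 1
                                             else temperatures,
                               seed = seed,
                               total_steps = if (is.null(total_steps)) 2e5
                                             else total_steps))
  }
  # plcd_mixture
  p <- .DESK$plcd
  a1 <- study_fixture("A1_LCD"); fus <- study_fixture("FUS_LCD")
  a1$n_chains <- if (desk) 6L else 100L
  fus$n_chains <- if (desk) 4L else 63L
  run_config(list(A1_LCD = a1, FUS_LCD = fus),
             default_plcd_model(w_el = w_el),
             box = if (desk) p$box else 120L,
             temperatures = if (is.null(temperatures)) p$temperatures
                            else temperatures,
             total_steps = steps(p$steps), n_replicates = reps(p$replicates),
             seed = seed, move_weights = .PRESET_MOVE_WEIGHTS,
             init_box = if (desk)
               .dense_init_edge(a1$n_chains * 135L + fus$n_chains * 214L)
             else 35L)
}

#' Tiny system for exact enumeration
#'
#' Builds a fully specified toy system small enough for
#' [enumerate_exact()], with homopolymer chains of alternating generic types
#' A, B, A, ...
#'
#' @param n_chains number of chains (<= 3).
#' @param length beads per chain (<= 4).
#' @param box lattice edge (<= 5).
#' @param energies an `interaction_model` over the generic types.
#' @param temperature reduced temperature(s).
#' @param seed,total_steps carried into the run configuration for the
#'   matching MC run.
#' @return a `run_config` (usable both with [enumerate_exact()] and
#'   [run_mc()]).
#' @export
make_enumerable_toy <- function(n_chains, length, box, energies,
                                temperature = 1, seed = 1L,
                                total_steps = 2e5) {
  if (n_chains > 3 || length > 4 || box > 5)
    stop(errorCondition("toy system exceeds the enumeration limits",
                        class = "latmix_enumeration_limit_error"))
  types <- rep(c("A", "B"), length.out = n_chains)
  species <- lapply(unique(types), function(tp) {
    homopolymer(tp, length, n_chains = sum(types == tp))
  })
  names(species) <- unique(types)
  run_config(species, energies, box = box, temperatures = temperature,
             total_steps = total_steps, n_replicates = 1L, seed = seed,
             init_box = box, n_frames = 200L,
             move_weights = c(local_bead = 60, slithering_snake = 10,
                              chain_translation = 20, pivot = 5,
                              double_pivot = 3, co_local = 2,
                              cluster_translation = 0))
}

# residue usage within categories for the random PLCD generator
.PLCD_RESIDUE_PROBS <- list(
  polar = c(G = 0.45, S = 0.35, T = 0.08, N = 0.06, Q = 0.05, C = 0.01),
  aromatic = c(Y = 0.50, F = 0.45, W = 0.03, H = 0.02),
  hydrophobic = c(L = 0.30, I = 0.20, V = 0.30, M = 0.20),
  charged = c(D = 0.30, E = 0.20, K = 0.25, R = 0.25),
  other = c(P = 0.80, A = 0.20)
)

#' Random PLCD-like sequence
#'
#' Draws a sequence whose category composition matches the targets to within
#' one residue, with the aromatic stickers placed near-uniformly along the
#' chain (the hallmark of natural PLCDs) and the remaining categories
#' shuffled over the other positions. Deterministic given the seed.
#'
#' @param length sequence length.
#' @param targets named category fractions summing to 1 (defaults follow the
#'   average PLCD composition: ~55% polar, ~10% aromatic, ~16% Pro/Ala,
#'   <5% charged, remainder aliphatic).
#' @param seed integer seed.
#' @return character string (the sequence).
#' @export
make_random_plcd <- function(length,
                             targets = c(polar = 0.55, aromatic = 0.10,
                                         hydrophobic = 0.15, charged = 0.04,
                                         other = 0.16),
                             seed = 1L) {
  if (abs(sum(targets) - 1) > 1e-9) stop("category targets must sum to 1")
  if (any(targets < 0)) stop("category targets must be non-negative")
  targets <- targets[.CATEGORIES]
  names(targets) <- .CATEGORIES
  targets[is.na(targets)] <- 0
  # largest-remainder rounding to exact counts
  raw <- targets * length
  counts <- floor(raw)
  left <- length - sum(counts)
  if (left > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  seq_out <- character(length)
  k <- counts[["aromatic"]]
  if (k > 0) {
    # evenly spaced sticker positions
    pos <- unique(round((seq_len(k) - 0.5) * length / k))
    while (length(pos) < k) pos <- sort(unique(c(pos, sample(setdiff(
      seq_len(length), pos), k - length(pos)))))
    pr <- .PLCD_RESIDUE_PROBS$aromatic
    seq_out[pos] <- sample(names(pr), k, replace = TRUE, prob = pr)
  } else pos <- integer(0)
  rest_cats <- rep(setdiff(.CATEGORIES, "aromatic"),
                   counts[setdiff(.CATEGORIES, "aromatic")])
  rest_cats <- sample(rest_cats)
  rest_pos <- setdiff(seq_len(length), pos)
  for (i in seq_along(rest_pos)) {
    pr <- .PLCD_RESIDUE_PROBS[[rest_cats[i]]]
    seq_out[rest_pos[i]] <- sample(names(pr), 1, prob = pr)
  }
  paste(seq_out, collapse = "")
}

# md5 checksums of the packaged (synthetic stand-in) sequence fixtures
.FIXTURE_MD5 <- "f35c65d06dbae8c0dbe531071c2505df"

#' Packaged PLCD sequences
#'
#' Returns one of the three packaged PLCD species: `A1_LCD` (135 residues,
#' net positive), `A1_LCD_12D` (the same sequence with 12 Gly/Ser positions
#' substituted to Asp, net negative) or `FUS_LCD` (214 residues, weakly net
#' negative). These are synthetic stand-in sequences generated to match the
#' documented lengths, charge signs and PLCD composition profile of the
#' study constructs; they are not transcriptions of the real proteins (see
#' the package vignette). The fixture file's checksum is verified on read.
#'
#' @param name fixture id.
#' @param n_chains chain count to attach (default 0).
#' @return a `polymer_species`.
#' @export
study_fixture <- function(name = c("A1_LCD", "A1_LCD_12D", "FUS_LCD"),
                          n_chains = 0L) {
  name <- match.arg(name)
  path <- system.file("extdata", "plcd_sequences_synthetic.fasta",
                      package = "latmix", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .FIXTURE_MD5)) {
    stop(errorCondition(
      sprintf("fixture checksum mismatch: %s (expected %s)", md5, .FIXTURE_MD5),
      class = "latmix_fixture_checksum_error"))
  }
  sp <- read_species_fasta(path)
  out <- sp[[name]]
  out$n_chains <- as.integer(n_chains)
  out
}
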