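# Interaction model: symmetric bead-type contact-energy matrix plus a
# mean-field electrostatic penalty based on the chain-pair-averaged NCPR.

#' Define an interaction model
#'
#' The energy of a contact between bead i (on chain a) and bead j (on chain b)
#' is `contact_energy[type_i, type_j] + w_el * mbar^2`, where
#' `mbar = (ncpr_a + ncpr_b) / 2` is the mean net charge per residue of the
#' two host chains. The electrostatic term is an even, repulsive penalty that
#' vanishes when the two chains' NCPRs cancel, so charge-complementary pairs
#' interact at the full strength of the contact matrix while like-charged
#' pairs are penalized. Contacts are defined on the 26-site neighbor shell of
#' the cubic lattice; chain-bonded pairs are excluded by default.
#'
#' @param contact_energy symmetric numeric matrix with bead-type row/column
#'   names; negative entries are attractive (reduced energy units).
#' @param w_el electrostatic coupling, >= 0 (reduced energy units).
#' @param neighbor_shell contact definition; only the 26-neighbor shell is
#'   supported by the sampling engine.
#' @param bonded_excluded exclude covalently bonded neighbors from contact
#'   energies (default TRUE).
#' @return an object of class `interaction_model`.
#' @examples
#' m <- scenario_matrix("hetero_stronger", e_base = -1, delta = 0.5)
#' pair_energy(m, "A", "B")
#' @export
interaction_model <- function(contact_energy, w_el = 0, neighbor_shell = 26L,
                              bonded_excluded = TRUE) {
  contact_energy <- as.matrix(contact_energy)
  if (is.null(rownames(contact_energy)) || is.null(colnames(contact_energy)))
    stop("contact_energy needs bead-type row and column names")
  if (!identical(rownames(contact_energy), colnames(contact_energy)))
    stop("contact_energy row and column names must match")
  if (max(abs(contact_energy - t(contact_energy))) > 1e-12)
    stop("contact_energy must be symmetric")
  if (w_el < 0) stop("w_el must be >= 0")
  if (neighbor_shell != 26L)
    stop("only the 26-neighbor contact shell is supported")
  structure(list(contact_energy = contact_energy, w_el = w_el,
                 neighbor_shell = 26L, bonded_excluded = bonded_excluded),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf("<interaction_model> %d bead types, w_el = %g, %d-neighbor shell\n",
              nrow(x$contact_energy), x$w_el, x$neighbor_shell))
  print(round(x$contact_energy, 3))
  invisible(x)
}

#' Pairwise contact energy
#'
#' @param model an `interaction_model`.
#' @param type_i,type_j bead-type codes (must exist in the contact matrix).
#' @param ncpr_a,ncpr_b net charge per residue of the two host chains.
#' @return contact energy in reduced units.
#' @export
pair_energy <- function(model, type_i, type_j, ncpr_a = 0, ncpr_b = 0) {
  stopifnot(inherits(model, "interaction_model"))
  types <- rownames(model$contact_energy)
  if (!(type_i %in% types) || !(type_j %in% types)) {
    stop(errorCondition(
      sprintf("unknown bead type(s): %s",
              paste(setdiff(c(type_i, type_j), types), collapse = ", ")),
      class = "latmix_unknown_type_error"))
  }
  if (abs(ncpr_a) > 1 || abs(ncpr_b) > 1) stop("NCPR values must lie in [-1, 1]")
  mbar <- (ncpr_a + ncpr_b) / 2
  model$contact_energy[type_i, type_j] + model$w_el * mbar^2
}

#' Two-species interaction scenarios
#'
#' Builds the 2x2 contact matrix (bead types "A" and "B") for the four
#' canonical homopolymer-mixture scenarios: all interactions equal;
#' heterotypic stronger than homotypic; homotypic stronger than heterotypic;
#' and an asymmetric case where A-A is weaker than B-B = A-B.
#'
#' @param scenario one of `"equal"`, `"hetero_stronger"`, `"homo_stronger"`,
#'   `"asymmetric_A_weak"`.
#' @param e_base base contact energy, must be negative (attractive).
#' @param delta modulation, >= 0.
#' @param w_el electrostatic coupling passed through to the model.
#' @return an `interaction_model` over bead types A and B.
#' @export
scenario_matrix <- function(scenario = c("equal", "hetero_stronger",
                                         "homo_stronger", "asymmetric_A_weak"),
                            e_base = -1, delta = 0.5, w_el = 0) {
  scenario <- match.arg(scenario)
  if (e_base >= 0) stop("e_base must be negative (attractive)")
  if (delta < 0) stop("delta must be >= 0")
  m <- matrix(e_base, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  if (scenario == "hetero_stronger") {
    m["A", "B"] <- m["B", "A"] <- e_base - delta
  } else if (scenario == "homo_stronger") {
    m["A", "A"] <- m["B", "B"] <- e_base - delta
  } else if (scenario == "asymmetric_A_weak") {
    m["A", "A"] <- e_base + delta
  }
  interaction_model(m, w_el = w_el)
}

#' Default PLCD contact matrix
#'
#' A stickers-and-spacers default over the 20 amino acids: aromatic-aromatic
#' contacts are strongly attractive (Tyr stronger than Phe), Arg acts as an
#' auxiliary sticker toward aromatics, and spacer-spacer contacts are weakly
#' attractive (Gly slightly more than Ser and other polar residues). These
#' are package defaults expressed in reduced units, not a fitted parameter
#' set; pass your own matrix to [interaction_model()] to override.
#'
#' @param w_el electrostatic coupling (default 4 reduced units).
#' @return an `interaction_model` over the 20 amino-acid bead types.
#' @export
default_plcd_model <- function(w_el = 4) {
  aa <- names(.AA_CATEGORY)
  m <- matrix(-0.25, length(aa), length(aa), dimnames = list(aa, aa))
  arom <- c("Y", "F", "W", "H")
  strength <- c(Y = -3.0, F = -2.4, W = -3.0, H = -1.2)
  for (a in arom) for (b in arom) m[a, b] <- (strength[[a]] + strength[[b]]) / 2
  for (a in arom) m["R", a] <- m[a, "R"] <- strength[[a]] / 2
  m["G", "G"] <- -0.45
  interaction_model(m, w_el = w_el)
}

# electrostatic penalty per species pair: w_el * ((ncpr_i + ncpr_j)/2)^2
.elec_matrix <- function(model, ncpr_by_species) {
  n <- length(ncpr_by_species)
  mbar <- outer(ncpr_by_species, ncpr_by_species, function(a, b) (a + b) / 2)
  mat <- model$w_el * mbar^2
  dimnames(mat) <- list(names(ncpr_by_species), names(ncpr_by_species))
  mat
}

#' Read or write an interaction matrix as a plain-text table
#'
#' The format is a whitespace-separated symmetric table with a header row and
#' first column of bead types.
#'
#' @param path file path.
#' @param model an `interaction_model` (for writing).
#' @param ... passed to [interaction_model()] when reading (e.g. `w_el`).
#' @return an `interaction_model` (read) or `path` invisibly (write).
#' @export
read_interaction_matrix <- function(path, ...) {
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                            check.names = FALSE))
  interaction_model(m, ...)
}

#' @rdname read_interaction_matrix
#' @export
write_interaction_matrix <- function(model, path) {
  stopifnot(inherits(model, "interaction_model"))
  write.table(model$contact_energy, path, quote = FALSE, sep = "\t",
              col.names = NA)
  invisible(path)
}

#' Total configurational energy of a frame
#'
#' Sums the pair energy over all unordered bead pairs within the 26-neighbor
#' shell, excluding chain-bonded pairs when the model says so.
#'
#' @param frame a `lattice_frame` (see [get_frame()]).
#' @param model an `interaction_model`; defaults to the model stored in the
#'   frame's system.
#' @return total energy in reduced units.
#' @export
system_energy <- function(frame, model = NULL) {
  stopifnot(inherits(frame, "lattice_frame"))
  sys <- frame$system
  if (is.null(model)) model <- sys$model
  tabs <- .system_tables(sys$species, model)
  cpp_total_energy(frame$coords, tabs$chain_of, tabs$type_of,
                   tabs$species_of_chain, frame$box,
                   tabs$contact_energy, tabs$elec, model$bonded_excluded)
}
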