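#' @useDynLib latmix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef sd setNames runif complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# residue category table: polar/aromatic/hydrophobic/charged; Ala and Pro
# fall into "other". His is aromatic and carries no charge in NCPR/FCR.
.AA_CATEGORY <- c(
  G = "polar", S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  F = "aromatic", Y = "aromatic", W = "aromatic", H = "aromatic",
  L = "hydrophobic", I = "hydrophobic", V = "hydrophobic", M = "hydrophobic",
  D = "charged", E = "charged", R = "charged", K = "charged",
  A = "other", P = "other"
)
.CATEGORIES <- c("polar", "aromatic", "hydrophobic", "charged", "other")
.POSITIVE <- c("K", "R")
.NEGATIVE <- c("D", "E")

.split_seq <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Classify amino-acid residues into coarse categories
#'
#' Residues are grouped as polar (Gly, Ser, Thr, Asn, Gln, Cys), aromatic
#' (Phe, Tyr, Trp, His), hydrophobic (Leu, Ile, Val, Met), charged (Asp, Glu,
#' Arg, Lys), with Ala and Pro in a remainder category ("other").
#'
#' @param aa character vector of one-letter residue codes (case-insensitive).
#' @return character vector of categories, one per residue.
#' @examples
#' classify_residue(c("G", "Y", "P"))
#' @export
classify_residue <- function(aa) {
  aa <- .split_seq(aa)
  bad <- !(aa %in% names(.AA_CATEGORY))
  if (any(bad)) {
    stop(errorCondition(
      sprintf("unknown residue code(s): %s", paste(unique(aa[bad]), collapse = ", ")),
      class = "latmix_unknown_residue_error"))
  }
  unname(.AA_CATEGORY[aa])
}

#' Define a polymer species
#'
#' A species is a named chain type: an ordered sequence of bead types (the 20
#' one-letter amino-acid codes, or generic types such as "A", "B" for
#' homopolymers) together with the number of chains of that species in the
#' system. For amino-acid sequences, the net charge per residue (NCPR) and
#' fraction of charged residues (FCR) are computed from the sequence; generic
#' bead types carry NCPR = FCR = 0 unless set explicitly.
#'
#' @param name species label.
#' @param beads bead-type sequence: a single string or a character vector.
#' @param n_chains number of chains of this species (default 0).
#' @param ncpr,fcr optional overrides of the sequence-derived values (needed
#'   for generic bead types that should carry charge).
#' @return an object of class `polymer_species`.
#' @examples
#' polymer_species("toy", "GYSSD", n_chains = 10)
#' homopolymer("A", 150, n_chains = 5)
#' @export
polymer_species <- function(name, beads, n_chains = 0L, ncpr = NULL, fcr = NULL) {
  beads <- .split_seq(beads)
  n <- length(beads)
  if (n < 2L) stop("a polymer species needs at least 2 beads")
  if (n_chains < 0L) stop("n_chains must be non-negative")
  is_aa <- all(beads %in% names(.AA_CATEGORY))
  ncpr_given <- !is.null(ncpr)
  if (is.null(ncpr)) {
    ncpr <- if (is_aa) (sum(beads %in% .POSITIVE) - sum(beads %in% .NEGATIVE)) / n else 0
  }
  if (is.null(fcr)) {
    fcr <- if (is_aa && !ncpr_given)
      sum(beads %in% c(.POSITIVE, .NEGATIVE)) / n else abs(ncpr)
  }
  if (abs(ncpr) > fcr + 1e-12 || fcr > 1 + 1e-12)
    stop("invalid charge descriptors: need |ncpr| <= fcr <= 1")
  structure(list(name = name, beads = beads, n_residues = n,
                 n_chains = as.integer(n_chains), ncpr = ncpr, fcr = fcr,
                 is_aa = is_aa),
            class = "polymer_species")
}

#' @rdname polymer_species
#' @param type bead-type code for the homopolymer (one distinct type).
#' @param n_residues chain length in beads.
#' @export
homopolymer <- function(name, n_residues, n_chains = 0L, type = name, ncpr = 0) {
  polymer_species(name, rep(type, n_residues), n_chains = n_chains, ncpr = ncpr)
}

#' @export
print.polymer_species <- function(x, ...) {
  cat(sprintf("<polymer_species> %s: %d beads x %d chains, NCPR %+.3f, FCR %.3f\n",
              x$name, x$n_residues, x$n_chains, x$ncpr, x$fcr))
  invisible(x)
}

#' Net charge per residue and fraction of charged residues
#'
#' NCPR is (count of Lys/Arg minus count of Asp/Glu) divided by chain length;
#' FCR is the total count of Lys/Arg/Asp/Glu divided by chain length. His is
#' treated as neutral.
#'
#' @param x a `polymer_species`, or a sequence (string / character vector).
#' @return a single number.
#' @examples
#' ncpr("DDK")  # -1/3
#' fcr("DDK")   # 1
#' @export
ncpr <- function(x) {
  if (inherits(x, "polymer_species")) return(x$ncpr)
  beads <- .split_seq(x)
  classify_residue(beads)  # validates codes
  (sum(beads %in% .POSITIVE) - sum(beads %in% .NEGATIVE)) / length(beads)
}

#' @rdname ncpr
#' @export
fcr <- function(x) {
  if (inherits(x, "polymer_species")) return(x$fcr)
  beads <- .split_seq(x)
  classify_residue(beads)
  sum(beads %in% c(.POSITIVE, .NEGATIVE)) / length(beads)
}

#' Composition profile of a species
#'
#' Fractions of residues per coarse category (polar, aromatic, hydrophobic,
#' charged, other) and per residue type.
#'
#' @param species a `polymer_species` or a sequence.
#' @return an object of class `composition_profile` with elements
#'   `category_fractions` and `residue_fractions`.
#' @export
composition_profile <- function(species) {
  beads <- if (inherits(species, "polymer_species")) species$beads else .split_seq(species)
  if (length(beads) < 1L) stop("empty sequence")
  cats <- classify_residue(beads)
  cf <- setNames(numeric(length(.CATEGORIES)), .CATEGORIES)
  tab <- table(cats) / length(beads)
  cf[names(tab)] <- as.numeric(tab)
  rf <- as.numeric(table(beads)) / length(beads)
  names(rf) <- names(table(beads))
  structure(list(category_fractions = cf, residue_fractions = rf,
                 n_residues = length(beads)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile>", x$n_residues, "residues\n")
  print(round(x$category_fractions, 3))
  invisible(x)
}

#' Read polymer species from a FASTA file
#'
#' Each record becomes one `polymer_species` (with `n_chains = 0`; set chain
#' counts when building a run configuration). Case-insensitive; accepts
#' single- or multi-record files.
#'
#' @param path FASTA file.
#' @return named list of `polymer_species`.
#' @export
read_species_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  out <- lapply(names(recs), function(nm) {
    polymer_species(nm, toupper(as.character(recs[[nm]])))
  })
  setNames(out, names(recs))
}

#' Write polymer species to a FASTA file
#'
#' @param species a `polymer_species` or list of them.
#' @param path output file.
#' @export
write_species_fasta <- function(species, path) {
  if (inherits(species, "polymer_species")) species <- list(species)
  seqinr::write.fasta(lapply(species, function(s) s$beads),
                      names = vapply(species, function(s) s$name, ""),
                      file.out = path)
  invisible(path)
}
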