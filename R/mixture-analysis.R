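# Mixture statistics: the additivity null and cooperativity classification,
# tie-line extraction and slope-based attribution, the L_{i-j} crosslinking
# parameter, and Rg/sqrt(N) interface profiles.

#' Additivity null for the dilute arm of a two-component phase diagram
#'
#' The expected total dilute-phase concentration when homotypic and
#' heterotypic interactions contribute additively:
#' `c_dilute = a * c_sat_A + (1 - a) * c_sat_B`, where `a` is the molecule
#' fraction of species A. Concave (below-null) dilute arms indicate positive
#' cooperativity via heterotypic interactions; convex (above-null) arms
#' indicate negative cooperativity.
#'
#' @param c_sat_A,c_sat_B intrinsic saturation concentrations of the pure
#'   species at the shared temperature, > 0.
#' @param a molecule fraction of species A, in `[0, 1]` (vectorized).
#' @return expected total dilute concentration.
#' @export
additivity_null <- function(c_sat_A, c_sat_B, a) {
  if (any(a < 0 | a > 1)) stop("mixing fraction a must lie in [0, 1]")
  if (c_sat_A <= 0 || c_sat_B <= 0) stop("c_sat values must be positive")
  a * c_sat_A + (1 - a) * c_sat_B
}

#' Classify cooperativity of a dilute arm
#'
#' Compares the total dilute-phase concentration of each interior
#' stoichiometry against the additivity null and classifies the arm by the
#' error-weighted sign of the mean deviation: below the null = positive
#' cooperativity (concave arm), above = negative (convex), indistinguishable
#' = additive.
#'
#' @param arm data frame with columns `a` (molecule fraction of species A)
#'   and `c_dilute_total`, optionally `se`; must contain both endpoints
#'   (`a = 0` and `a = 1`) unless the `c_sat` values are given.
#' @param c_sat_A,c_sat_B optional endpoint overrides.
#' @param z_threshold how many standard errors from zero the weighted mean
#'   deviation must be to leave the "additive" class (default 2).
#' @return list with `classification` (`"positive"`, `"additive"`,
#'   `"negative"`), per-point signed `deviations`, the weighted mean
#'   deviation and its standard error.
#' @export
classify_cooperativity <- function(arm, c_sat_A = NULL, c_sat_B = NULL,
                                   z_threshold = 2) {
  stopifnot(all(c("a", "c_dilute_total") %in% names(arm)))
  if (is.null(c_sat_A)) {
    if (!any(arm$a == 1)) stop("missing a = 1 endpoint (c_sat of species A)")
    c_sat_A <- arm$c_dilute_total[arm$a == 1][1]
  }
  if (is.null(c_sat_B)) {
    if (!any(arm$a == 0)) stop("missing a = 0 endpoint (c_sat of species B)")
    c_sat_B <- arm$c_dilute_total[arm$a == 0][1]
  }
  interior <- arm[arm$a > 0 & arm$a < 1, , drop = FALSE]
  if (nrow(interior) < 1) stop("need at least one interior stoichiometry")
  dev <- interior$c_dilute_total -
    additivity_null(c_sat_A, c_sat_B, interior$a)
  se <- if ("se" %in% names(interior) && all(is.finite(interior$se)) &&
            all(interior$se > 0)) interior$se else rep(NA_real_, nrow(interior))
  if (all(is.finite(se))) {
    w <- 1 / se^2
    wm <- sum(w * dev) / sum(w)
    wm_se <- sqrt(1 / sum(w))
  } else {
    wm <- mean(dev)
    wm_se <- if (length(dev) > 1) sd(dev) / sqrt(length(dev)) else NA_real_
  }
  cls <- if ((is.finite(wm_se) && abs(wm) <= z_threshold * wm_se) ||
             abs(wm) < 1e-12) "additive"
         else if (wm < 0) "positive" else "negative"
  list(classification = cls,
       deviations = data.frame(a = interior$a, deviation = dev, se = se),
       weighted_mean_deviation = wm, se = wm_se,
       c_sat_A = c_sat_A, c_sat_B = c_sat_B)
}

# slope of the segment p1 -> p2 in the (A, B) plane with propagated errors
.segment_slope <- function(p1, p2, se1 = c(0, 0), se2 = c(0, 0)) {
  dA <- p2[1] - p1[1]
  dB <- p2[2] - p1[2]
  if (abs(dA) < 1e-12) {
    return(list(slope = Inf, se = NA_real_, vertical = TRUE))
  }
  s <- dB / dA
  v <- (se1[2]^2 + se2[2]^2) / dA^2 + s^2 * (se1[1]^2 + se2[1]^2) / dA^2
  list(slope = s, se = sqrt(v), vertical = FALSE)
}

#' Extract a tie line from coexisting compositions
#'
#' Joins the three collinear-by-construction points `c_dilute`, `c_total`,
#' `c_dense` in the (c_A, c_B) plane, with species A on the abscissa. Two
#' slopes are reported (dilute-to-total and total-to-dense); their agreement
#' is the standard check that the system forms precisely two coexisting
#' phases. Classification: a slope of unity (within `z_threshold` standard
#' errors) means heterotypic interactions dominate; a slope below unity means
#' homotypic A-A interactions dominate; above unity, homotypic B-B.
#'
#' @param c_dilute,c_total,c_dense length-2 numeric vectors `(A, B)`.
#' @param se_dilute,se_dense optional length-2 standard errors (the total
#'   composition is set by the experimenter and carries no error).
#' @param z_threshold standard-error multiple around 1 for the heterotypic
#'   class (default 2).
#' @return an object of class `tie_line` with both slopes, the collinearity
#'   gap (absolute slope difference with propagated error) and the
#'   classification.
#' @export
tie_line <- function(c_dilute, c_total, c_dense,
                     se_dilute = c(0, 0), se_dense = c(0, 0),
                     z_threshold = 2) {
  s1 <- .segment_slope(c_dilute, c_total, se_dilute, c(0, 0))
  s2 <- .segment_slope(c_total, c_dense, c(0, 0), se_dense)
  gap <- abs(s1$slope - s2$slope)
  gap_se <- sqrt(sum(c(s1$se, s2$se)^2, na.rm = TRUE))
  slopes <- c(dilute_to_total = s1$slope, total_to_dense = s2$slope)
  ses <- c(s1$se, s2$se)
  fin <- is.finite(slopes)
  eff_se <- ifelse(is.na(ses) | ses == 0, 1e-8, ses)
  within <- abs(slopes - 1) <= z_threshold * eff_se
  if (any(fin)) {
    w <- 1 / eff_se[fin]^2
    mean_slope <- sum(slopes[fin] * w) / sum(w)
    mean_se <- sqrt(1 / sum(w))
  } else {
    mean_slope <- Inf; mean_se <- NA_real_
  }
  classification <-
    if (all(within[fin]) && any(fin)) "heterotypic_dominant"
    else if (mean_slope < 1) "homotypic_A_dominant"
    else "homotypic_B_dominant"
  structure(list(
    slope_dilute_to_total = s1$slope, se_dilute_to_total = s1$se,
    slope_total_to_dense = s2$slope, se_total_to_dense = s2$se,
    mean_slope = mean_slope, se_mean_slope = mean_se,
    intercept_dilute_to_total =
      if (is.finite(s1$slope)) c_total[2] - s1$slope * c_total[1] else NA_real_,
    collinearity_gap = gap, collinearity_gap_se = gap_se,
    vertical = s1$vertical || s2$vertical,
    classification = classification,
    points = rbind(c_dilute = c_dilute, c_total = c_total, c_dense = c_dense)
  ), class = "tie_line")
}

#' @export
print.tie_line <- function(x, ...) {
  cat(sprintf(
    "<tie_line> slopes %.3f (dilute-total), %.3f (total-dense); %s\n",
    x$slope_dilute_to_total, x$slope_total_to_dense, x$classification))
  invisible(x)
}

#' Tie line of a mixture ensemble
#'
#' Computes the phase point, takes the bulk composition from the
#' configuration, and extracts the tie line for a chosen species pair.
#'
#' @param ensemble an `mc_ensemble` of a two-species mixture.
#' @param species_a,species_b species spanning the plane (defaults: the
#'   configured species, in order).
#' @param ... passed to [phase_point()] and [tie_line()].
#' @return a `tie_line`.
#' @export
tie_line_mc <- function(ensemble, species_a = NULL, species_b = NULL, ...) {
  nm <- ensemble$config$tables$species_names
  if (is.null(species_a)) species_a <- nm[1]
  if (is.null(species_b)) species_b <- nm[2]
  dots <- list(...)
  pp_args <- dots[names(dots) %in% c("temperature", "binwidth",
                                     "cluster_threshold", "interface_q")]
  tl_args <- dots[names(dots) %in% "z_threshold"]
  pp <- do.call(phase_point, c(list(ensemble), pp_args))
  tb <- pp$table
  cfg <- ensemble$config
  V <- prod(cfg$box)
  bulk <- vapply(cfg$species, function(s) s$n_chains * s$n_residues / V, 0)
  names(bulk) <- nm
  g <- function(sp, col) tb[tb$species == sp, col]
  do.call(tie_line, c(list(
    c_dilute = c(g(species_a, "c_dilute"), g(species_b, "c_dilute")),
    c_total = c(bulk[[species_a]], bulk[[species_b]]),
    c_dense = c(g(species_a, "c_dense"), g(species_b, "c_dense")),
    se_dilute = c(g(species_a, "se_dilute"), g(species_b, "se_dilute")),
    se_dense = c(g(species_a, "se_dense"), g(species_b, "se_dense"))),
    tl_args))
}

# per-replicate L matrix for one trajectory
.crosslink_traj <- function(traj, cluster_threshold = 0.5) {
  tabs <- traj$tables
  ns <- length(tabs$species_names)
  M <- matrix(0, ns, ns)     # contact "ends": i-chains' contacts with j
  Bsum <- numeric(ns)        # cluster bead count per species, frame-summed
  Btot <- 0
  nfr <- 0L
  for (f in traj$frames) {
    cc <- cpp_chain_contacts(f, tabs$chain_of, traj$box)
    cl <- .largest_cluster_from_contacts(cc, tabs$n_chains)
    if (cl$dispersed) next
    incl <- cc[, 1] %in% cl$chains & cc[, 2] %in% cl$chains
    cc <- cc[incl, , drop = FALSE]
    si <- tabs$species_of_chain[cc[, 1]]
    sj <- tabs$species_of_chain[cc[, 2]]
    idx <- c((sj - 1) * ns + si, (si - 1) * ns + sj)
    s <- rowsum(c(cc[, 3], cc[, 3]), idx)
    acc <- numeric(ns * ns)
    acc[as.integer(rownames(s))] <- s[, 1]
    M <- M + matrix(acc, ns, ns)
    bead_sp <- tabs$species_of_chain[cl$chains]
    for (s in seq_len(ns))
      Bsum[s] <- Bsum[s] + sum(tabs$chain_lengths[cl$chains][bead_sp == s])
    Btot <- Btot + sum(tabs$chain_lengths[cl$chains])
    nfr <- nfr + 1L
  }
  if (nfr == 0L) return(NULL)
  Bbar <- Bsum / nfr
  Btotbar <- Btot / nfr
  # chain length per species (uniform within a species)
  Nsp <- vapply(seq_len(ns), function(s) {
    ls <- unique(tabs$chain_lengths[tabs$species_of_chain == s])
    ls[1]
  }, 0L)
  L <- matrix(NA_real_, ns, ns,
              dimnames = list(tabs$species_names, tabs$species_names))
  for (i in seq_len(ns)) {
    tot_i <- sum(M[i, ])
    if (tot_i == 0 || Bbar[i] == 0) next
    for (j in seq_len(ns)) {
      expect <- (Bbar[j] - (i == j) * Nsp[i]) / (Btotbar - Nsp[i])
      if (expect <= 0) next
      L[i, j] <- (M[i, j] / tot_i) / expect
    }
  }
  L
}

#' Crosslinking parameter L between species in the condensate
#'
#' `L[i, j]` is the observed fraction of species-i inter-chain bead contacts
#' made with species j inside the largest cluster, divided by the fraction
#' expected under random mixing given the cluster's composition (with the
#' querying chain's own beads removed from the expectation, so a
#' single-species system gives exactly 1). `L = 1` means random mixing;
#' `L > 1` an enrichment of i-j contacts; `L < 1` a depletion.
#'
#' @param x an `mc_ensemble` or a list of `mc_trajectory`.
#' @param temperature which temperature (for an ensemble with several).
#' @param cluster_threshold passed through to condensate identification.
#' @return object of class `crosslink_stats`: matrix `L`, standard errors
#'   across replicates, per-replicate values, and the temperature.
#' @export
crosslink_parameter <- function(x, temperature = NULL,
                                cluster_threshold = 0.5) {
  trs <- if (inherits(x, "mc_ensemble")) {
    if (is.null(temperature)) {
      temperature <- unique(vapply(x$trajectories, `[[`, 0, "temperature"))
      if (length(temperature) > 1)
        stop("ensemble has several temperatures; pick one")
    }
    trajectories(x, temperature = temperature)
  } else x
  mats <- Filter(Negate(is.null),
                 lapply(trs, .crosslink_traj, cluster_threshold))
  if (length(mats) == 0) stop("no condensate found in any replicate")
  ns <- nrow(mats[[1]])
  arr <- array(unlist(mats), c(ns, ns, length(mats)))
  Lm <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nse <- apply(!is.na(arr), c(1, 2), sum)
  Lse <- apply(arr, c(1, 2), sd, na.rm = TRUE) / sqrt(pmax(nse, 1))
  dimnames(Lm) <- dimnames(Lse) <- dimnames(mats[[1]])
  structure(list(L = Lm, se = Lse, n_replicates = length(mats),
                 per_replicate = arr,
                 temperature = if (is.null(temperature))
                   trs[[1]]$temperature else temperature),
            class = "crosslink_stats")
}

#' @export
print.crosslink_stats <- function(x, ...) {
  cat(sprintf("<crosslink_stats> T = %g, %d replicates\n", x$temperature,
              x$n_replicates))
  print(round(x$L, 3))
  invisible(x)
}

#' Crosslinking parameter across temperatures
#'
#' @param ensemble an `mc_ensemble` over several temperatures.
#' @param ... passed to [crosslink_parameter()].
#' @return data frame: temperature, species_i, species_j, L, se.
#' @export
crosslink_profile <- function(ensemble, ...) {
  temps <- sort(unique(vapply(ensemble$trajectories, `[[`, 0, "temperature")))
  rows <- lapply(temps, function(Tv) {
    cs <- crosslink_parameter(ensemble, temperature = Tv, ...)
    sp <- rownames(cs$L)
    expand <- expand.grid(species_i = sp, species_j = sp,
                          stringsAsFactors = FALSE)
    expand$L <- as.vector(cs$L)
    expand$se <- as.vector(cs$se)
    expand$temperature <- Tv
    expand
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crosslink_profile", "data.frame")
  out
}

# unwrap one frame's chains across the periodic seam (bond steps are always
# within the 26 shell, so each bond's minimal image is unambiguous)
.unwrap_chains <- function(coords, chain_of, box) {
  out <- matrix(NA_real_, nrow(coords), 3)
  for (ax in 1:3) {
    L <- box[ax]
    v <- coords[, ax]
    d <- diff(v)
    d <- d - L * round(d / L)
    same <- diff(chain_of) == 0
    d[!same] <- 0
    cum <- cumsum(c(v[1], d))
    # restart each chain at its own wrapped first bead
    starts <- which(c(TRUE, !same))
    offset <- rep(v[starts] - cum[starts], diff(c(starts, length(v) + 1)))
    out[, ax] <- cum + offset
  }
  out
}

#' Chain-dimension profile across the condensate
#'
#' For every chain in every analyzed frame, computes the radius of gyration
#' (about the chain's own center of mass, using seam-unwrapped coordinates),
#' normalizes by the square root of the chain length, and bins it by the
#' distance of the chain's center of mass from the condensate center of
#' mass. Averaged per replicate, with SEs across replicates.
#'
#' @param x an `mc_ensemble` or `mc_trajectory`.
#' @param temperature temperature filter for ensembles.
#' @param binwidth radial bin width (default 2 lattice units).
#' @return object of class `rg_profile`: bin centers, per-species mean
#'   `rg_norm` (Rg/sqrt(N)) matrix, SEs and per-bin chain counts.
#' @export
rg_profile <- function(x, temperature = NULL, binwidth = 2) {
  trs <- if (inherits(x, "mc_ensemble")) {
    if (is.null(temperature)) {
      temperature <- unique(vapply(x$trajectories, `[[`, 0, "temperature"))
      if (length(temperature) > 1)
        stop("ensemble has several temperatures; pick one")
    }
    trajectories(x, temperature = temperature)
  } else list(x)
  tabs <- trs[[1]]$tables
  ns <- length(tabs$species_names)
  box <- trs[[1]]$box
  nbins <- floor(min(box) / 2 / binwidth)
  chain_idx <- split(seq_len(tabs$n_beads), tabs$chain_of)
  per_rep <- lapply(trs, function(traj) {
    sums <- matrix(0, ns, nbins)
    cnts <- matrix(0, ns, nbins)
    for (f in traj$frames) {
      fr <- structure(list(coords = f, box = box, tables = tabs),
                      class = "lattice_frame")
      cl <- largest_cluster(fr)
      com <- condensate_com(fr, cl$chains)
      un <- .unwrap_chains(f, tabs$chain_of, box)
      for (c in seq_len(tabs$n_chains)) {
        idx <- chain_idx[[c]]
        xyz <- un[idx, , drop = FALSE]
        cm <- colMeans(xyz)
        rg <- sqrt(mean(rowSums(sweep(xyz, 2, cm)^2)))
        dcm <- abs((cm %% box) - com)
        dcm <- pmin(dcm, box - dcm)
        bin <- floor(sqrt(sum(dcm^2)) / binwidth) + 1
        if (bin > nbins) next
        s <- tabs$species_of_chain[c]
        sums[s, bin] <- sums[s, bin] + rg / sqrt(tabs$chain_lengths[c])
        cnts[s, bin] <- cnts[s, bin] + 1
      }
    }
    list(mean = ifelse(cnts > 0, sums / cnts, NA_real_), counts = cnts)
  })
  arr <- array(unlist(lapply(per_rep, `[[`, "mean")),
               c(ns, nbins, length(per_rep)))
  m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nrep_eff <- apply(!is.na(arr), c(1, 2), sum)
  se <- apply(arr, c(1, 2), sd, na.rm = TRUE) / sqrt(pmax(nrep_eff, 1))
  counts <- Reduce(`+`, lapply(per_rep, `[[`, "counts"))
  dimnames(m) <- dimnames(se) <- dimnames(counts) <-
    list(tabs$species_names, NULL)
  structure(list(bin_centers = (seq_len(nbins) - 0.5) * binwidth,
                 rg_norm = m, se = se, counts = counts,
                 temperature = if (is.null(temperature))
                   trs[[1]]$temperature else temperature,
                 species = tabs$species_names),
            class = "rg_profile")
}

#' @export
print.rg_profile <- function(x, ...) {
  cat(sprintf("<rg_profile> T = %g, %d species x %d bins\n",
              x$temperature, nrow(x$rg_norm), length(x$bin_centers)))
  invisible(x)
}

#' Scale one species' interaction energies
#'
#' Multiplies every contact-energy entry involving the given bead types
#' (homotypic and heterotypic alike) by a common factor. Used to tune one
#' species' driving force, e.g. to match saturation concentrations between
#' species of different lengths.
#'
#' @param model an `interaction_model`.
#' @param types bead type(s) belonging to the species being scaled.
#' @param factor multiplicative factor (> 0 keeps signs).
#' @return a new `interaction_model`.
#' @export
scale_species_energies <- function(model, types, factor) {
  m <- model$contact_energy
  sel <- rownames(m) %in% types
  touched <- outer(sel, sel, "|") # any entry involving the species, once
  m[touched] <- m[touched] * factor
  interaction_model(m, w_el = model$w_el,
                    bonded_excluded = model$bonded_excluded)
}

#' Match saturation concentrations by bisection
#'
#' Finds the uniform scale factor on one species' interaction energies at
#' which its saturation concentration equals a target, by bisection on a
#' user-supplied measurement function (typically wrapping a short simulation
#' campaign). The measurement may be stochastic; bisection only uses the
#' sign of the difference.
#'
#' @param csat_fn function(scale) returning the measured c_sat at that scale.
#' @param target the c_sat to match.
#' @param lower,upper bracketing scale factors; `csat_fn(lower) - target`
#'   and `csat_fn(upper) - target` must have opposite signs.
#' @param tol relative tolerance on the c_sat match (default 0.1).
#' @param max_iter maximum bisection steps (default 12).
#' @return list with `scale`, `c_sat`, `iterations`, `converged`.
#' @export
match_csat <- function(csat_fn, target, lower = 0.5, upper = 2,
                       tol = 0.1, max_iter = 12) {
  f_lo <- csat_fn(lower) - target
  f_hi <- csat_fn(upper) - target
  if (sign(f_lo) == sign(f_hi))
    stop("interval does not bracket the target c_sat")
  mid <- NA_real_; f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    c_mid <- csat_fn(mid)
    f_mid <- c_mid - target
    if (abs(f_mid) <= tol * target) {
      return(list(scale = mid, c_sat = c_mid, iterations = it,
                  converged = TRUE))
    }
    if (sign(f_mid) == sign(f_lo)) { lower <- mid; f_lo <- f_mid }
    else { upper <- mid; f_hi <- f_mid }
  }
  list(scale = mid, c_sat = f_mid + target, iterations = max_iter,
       converged = FALSE)
}
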