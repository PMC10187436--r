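# From trajectories to coexistence data: condensate identification, radial
# density profiles, logistic fits, per-species dilute/dense concentrations,
# binodals and fixed-temperature two-component phase diagrams.

#' Largest connected cluster of chains
#'
#' Two chains are linked when any inter-chain bead pair lies within the
#' 26-neighbor shell; the condensate is taken to be the largest connected
#' component of that chain-contact graph.
#'
#' @param frame a `lattice_frame`.
#' @return list with `chains` (chain indices), `fraction` (of all chains),
#'   and `dispersed` (TRUE when no two chains touch).
#' @export
largest_cluster <- function(frame) {
  tabs <- frame$tables
  cc <- cpp_chain_contacts(frame$coords, tabs$chain_of, frame$box)
  .largest_cluster_from_contacts(cc, tabs$n_chains)
}

.largest_cluster_from_contacts <- function(cc, n_chains) {
  if (nrow(cc) == 0) {
    return(list(chains = 1L, fraction = 1 / n_chains, dispersed = TRUE))
  }
  g <- igraph::graph_from_edgelist(cbind(cc[, 1], cc[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_chains - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  chains <- which(comp$membership == big)
  list(chains = chains, fraction = length(chains) / n_chains,
       dispersed = length(chains) == 1L)
}

#' Periodic-boundary-aware center of mass
#'
#' Computes the center of mass of the given chains' beads using the per-axis
#' circular mean, so that a condensate straddling the periodic seam is
#' centered correctly.
#'
#' @param frame a `lattice_frame`.
#' @param chains chain indices (default: all chains).
#' @return numeric length-3 coordinates in `[0, L)`.
#' @export
condensate_com <- function(frame, chains = NULL) {
  tabs <- frame$tables
  idx <- if (is.null(chains)) rep(TRUE, nrow(frame$coords))
         else tabs$chain_of %in% chains
  if (!any(idx)) stop("empty chain set")
  vapply(1:3, function(ax) {
    L <- frame$box[ax]
    th <- 2 * pi * frame$coords[idx, ax] / L
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang / (2 * pi) * L) %% L
  }, 0)
}

# per-frame accumulation of the radial histogram for one trajectory
.profile_traj <- function(traj, binwidth, nbins, cluster_threshold) {
  tabs <- traj$tables
  ns <- length(tabs$species_names)
  bead_species <- tabs$species_of_chain[tabs$chain_of]
  beads <- matrix(0, ns, nbins)
  sites <- numeric(nbins)
  frac <- numeric(length(traj$frames))
  for (i in seq_along(traj$frames)) {
    fr <- structure(list(coords = traj$frames[[i]], box = traj$box,
                         tables = tabs), class = "lattice_frame")
    cl <- largest_cluster(fr)
    frac[i] <- cl$fraction
    com <- condensate_com(fr, cl$chains)
    h <- cpp_radial_histogram(traj$frames[[i]], bead_species, com, traj$box,
                              binwidth, nbins, ns)
    beads <- beads + h$bead_counts
    sites <- sites + h$site_counts
  }
  list(beads = beads, sites = sites, cluster_fraction = mean(frac))
}

#' Radial density profile around the condensate center of mass
#'
#' Bins bead counts in spherical shells around the largest cluster's center
#' of mass, per frame, and divides by the number of lattice sites per shell,
#' giving a per-species volume-fraction profile. For an ensemble the profile
#' is computed per replicate and averaged, with standard errors across
#' replicates.
#'
#' @param x an `mc_trajectory` or `mc_ensemble`.
#' @param temperature for an ensemble: which temperature to profile
#'   (default: the only one present).
#' @param binwidth radial bin width in lattice units (default 1).
#' @param cluster_threshold minimum mean fraction of chains in the largest
#'   cluster below which the state point is considered single-phase
#'   (default 0.5); recorded, not enforced here.
#' @param ... unused.
#' @return an object of class `radial_profile`: `bin_centers`, `density`
#'   (species x bins), `se`, per-replicate densities, and the mean largest
#'   cluster fraction.
#' @export
radial_profile <- function(x, ...) UseMethod("radial_profile")

#' @rdname radial_profile
#' @export
radial_profile.mc_trajectory <- function(x, binwidth = 1,
                                         cluster_threshold = 0.5, ...) {
  nbins <- floor(min(x$box) / 2 / binwidth)
  acc <- .profile_traj(x, binwidth, nbins, cluster_threshold)
  dens <- sweep(acc$beads, 2, pmax(acc$sites, 1), "/")
  rownames(dens) <- x$tables$species_names
  structure(list(bin_centers = (seq_len(nbins) - 0.5) * binwidth,
                 density = dens, se = NULL, site_counts = acc$sites,
                 replicate_density = NULL,
                 cluster_fraction = acc$cluster_fraction,
                 temperature = x$temperature, binwidth = binwidth,
                 species = x$tables$species_names,
                 cluster_threshold = cluster_threshold),
            class = "radial_profile")
}

#' @rdname radial_profile
#' @export
radial_profile.mc_ensemble <- function(x, temperature = NULL, binwidth = 1,
                                       cluster_threshold = 0.5, ...) {
  if (is.null(temperature)) {
    temperature <- unique(vapply(x$trajectories, `[[`, 0, "temperature"))
    if (length(temperature) > 1)
      stop("ensemble has several temperatures; pick one")
  }
  trs <- trajectories(x, temperature = temperature)
  if (length(trs) == 0) stop("no trajectories at this temperature")
  profs <- lapply(trs, radial_profile, binwidth = binwidth,
                  cluster_threshold = cluster_threshold)
  ns <- length(profs[[1]]$species)
  nbins <- length(profs[[1]]$bin_centers)
  arr <- array(NA_real_, c(ns, nbins, length(profs)))
  for (r in seq_along(profs)) arr[, , r] <- profs[[r]]$density
  dens <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), sd) / sqrt(length(profs))
  dimnames(dens) <- dimnames(se) <- list(profs[[1]]$species, NULL)
  structure(list(bin_centers = profs[[1]]$bin_centers, density = dens,
                 se = se, site_counts = profs[[1]]$site_counts,
                 replicate_density = arr,
                 cluster_fraction = mean(vapply(profs, `[[`, 0,
                                                "cluster_fraction")),
                 temperature = temperature, binwidth = binwidth,
                 species = profs[[1]]$species,
                 cluster_threshold = cluster_threshold),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "<radial_profile> T = %g, %d species x %d bins, cluster fraction %.2f\n",
    x$temperature, nrow(x$density), length(x$bin_centers),
    x$cluster_fraction))
  invisible(x)
}

# four-parameter logistic fit of a decreasing radial density profile
.fit_logistic_core <- function(r, dens, weights = NULL, interface_q = 0.9) {
  ok <- is.finite(dens)
  r <- r[ok]; dens <- dens[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(r) < 8) stop("need at least 8 bins to fit")
  k <- max(2L, length(r) %/% 8L)
  den0 <- mean(head(dens, k))
  dil0 <- mean(tail(dens, k))
  if (!is.finite(den0) || !is.finite(dil0) ||
      den0 - dil0 < max(1e-4, 0.1 * den0)) {
    stop(errorCondition(
      "degenerate plateaus: no dense/dilute contrast (single-phase state point?)",
      class = "latmix_single_phase_error"))
  }
  half <- (den0 + dil0) / 2
  rmid0 <- r[which(dens <= half)[1]]
  if (is.na(rmid0)) rmid0 <- stats::median(r)
  sw <- sqrt(if (is.null(weights)) rep(1, length(r)) else weights)
  resid_fn <- function(p) {
    sw * (dens - (p[2] + (p[1] - p[2]) / (1 + exp((r - p[3]) / p[4]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(den0, max(dil0, 1e-8), rmid0, 1.5), fn = resid_fn,
      lower = c(0, 0, 0, 1e-6), upper = c(1, 1, max(r) * 2, max(r)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(errorCondition(paste("logistic fit failed:", conditionMessage(e)),
                          class = "latmix_single_phase_error"))
    })
  if (fit$info < 1 || fit$info > 4) {
    stop(errorCondition("logistic fit did not converge",
                        class = "latmix_single_phase_error"))
  }
  p <- list(den = fit$par[1], dil = fit$par[2], rmid = fit$par[3],
            w = fit$par[4])
  if (p$den <= p$dil) {
    stop(errorCondition("degenerate fit: dense plateau below dilute plateau",
                        class = "latmix_single_phase_error"))
  }
  # radii where the curve has covered (1 - q) and q of the drop
  span <- log(interface_q / (1 - interface_q))
  list(rho_dense = p$den, rho_dilute = p$dil, r_mid = p$rmid, width = p$w,
       r_lo = p$rmid - p$w * span, r_hi = p$rmid + p$w * span,
       interface_width = 2 * p$w * span)
}

#' Logistic fit of a radial density profile
#'
#' Fits `rho(r) = rho_dilute + (rho_dense - rho_dilute) / (1 + exp((r -
#' r_mid)/width))` by weighted least squares (weights: lattice sites per
#' shell). The interfacial interval `[r_lo, r_hi]` is where the fitted curve
#' passes 90% and 10% of the way from the dense to the dilute plateau (the
#' quantile is configurable). Degenerate profiles (no contrast between the
#' plateaus) raise an error of class `latmix_single_phase_error`, marking the
#' state point single-phase.
#'
#' @param profile a `radial_profile`, or a numeric vector of densities.
#' @param r bin centers (when `profile` is a plain vector).
#' @param species which species to fit (default: all in the profile).
#' @param weights optional fit weights.
#' @param interface_q quantile defining the interfacial interval
#'   (default 0.9, i.e. the 90%/10% crossings).
#' @return for a profile: named list (per species) of fit parameter lists
#'   (`rho_dense`, `rho_dilute`, `r_mid`, `width`, `r_lo`, `r_hi`); for a
#'   plain vector: a single such list.
#' @export
fit_logistic <- function(profile, r = NULL, species = NULL, weights = NULL,
                         interface_q = 0.9) {
  if (inherits(profile, "radial_profile")) {
    if (is.null(species)) species <- profile$species
    w <- if (is.null(weights)) profile$site_counts else weights
    out <- lapply(species, function(s) {
      .fit_logistic_core(profile$bin_centers, profile$density[s, ], w,
                         interface_q)
    })
    return(setNames(out, species))
  }
  .fit_logistic_core(r, profile, weights, interface_q)
}

#' Coexisting dilute- and dense-phase concentrations
#'
#' Reads the per-species dilute and dense volume fractions off the logistic
#' fits of the radial density profile: the far-field plateau is `c_dilute`
#' and the core plateau is `c_dense`. With per-replicate profiles available,
#' fits are done per replicate and standard errors about the replicate mean
#' are attached. A state point is declared single-phase when the fit
#' degenerates or the largest cluster holds less than the configured fraction
#' of chains.
#'
#' @param profile a `radial_profile` (ensemble version preferred).
#' @param interface_q passed to [fit_logistic()].
#' @return an object of class `phase_point`: data frame with one row per
#'   species (`c_dilute`, `se_dilute`, `c_dense`, `se_dense`), plus
#'   `temperature` and `single_phase` attributes.
#' @export
coexisting_concentrations <- function(profile, interface_q = 0.9) {
  stopifnot(inherits(profile, "radial_profile"))
  sp <- profile$species
  single <- profile$cluster_fraction < profile$cluster_threshold
  per_rep <- NULL
  if (!is.null(profile$replicate_density)) {
    nrep <- dim(profile$replicate_density)[3]
    per_rep <- array(NA_real_, c(length(sp), 2, nrep))
    for (r in seq_len(nrep)) {
      for (si in seq_along(sp)) {
        fit <- tryCatch(
          .fit_logistic_core(profile$bin_centers,
                             profile$replicate_density[si, , r],
                             profile$site_counts, interface_q),
          latmix_single_phase_error = function(e) NULL)
        if (!is.null(fit))
          per_rep[si, , r] <- c(fit$rho_dilute, fit$rho_dense)
      }
    }
  }
  mean_fit <- lapply(sp, function(s) {
    tryCatch(.fit_logistic_core(profile$bin_centers, profile$density[s, ],
                                profile$site_counts, interface_q),
             latmix_single_phase_error = function(e) NULL)
  })
  names(mean_fit) <- sp
  if (any(vapply(mean_fit, is.null, TRUE))) single <- TRUE
  df <- data.frame(
    species = sp,
    c_dilute = vapply(mean_fit, function(f) if (is.null(f)) NA_real_ else f$rho_dilute, 0),
    c_dense = vapply(mean_fit, function(f) if (is.null(f)) NA_real_ else f$rho_dense, 0),
    se_dilute = NA_real_, se_dense = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(per_rep)) {
    nrep_eff <- apply(!is.na(per_rep[, 1, , drop = FALSE]), 1, sum)
    df$se_dilute <- apply(per_rep[, 1, , drop = FALSE], 1, sd, na.rm = TRUE) /
      sqrt(pmax(nrep_eff, 1))
    df$se_dense <- apply(per_rep[, 2, , drop = FALSE], 1, sd, na.rm = TRUE) /
      sqrt(pmax(nrep_eff, 1))
  }
  structure(list(table = df, fits = mean_fit,
                 temperature = profile$temperature,
                 single_phase = single,
                 cluster_fraction = profile$cluster_fraction),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("<phase_point> T = %g%s\n", x$temperature,
              if (x$single_phase) " (single-phase)" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Phase point of an ensemble at one temperature
#'
#' Convenience wrapper: radial profile + logistic fits + replicate errors.
#'
#' @param ensemble an `mc_ensemble`.
#' @param temperature temperature to analyze.
#' @param ... passed to [radial_profile()] and [coexisting_concentrations()].
#' @return a `phase_point`.
#' @export
phase_point <- function(ensemble, temperature = NULL, ...) {
  dots <- list(...)
  prof_args <- dots[names(dots) %in% c("binwidth", "cluster_threshold")]
  cc_args <- dots[names(dots) %in% "interface_q"]
  prof <- do.call(radial_profile,
                  c(list(ensemble, temperature = temperature), prof_args))
  do.call(coexisting_concentrations, c(list(prof), cc_args))
}

#' Build a binodal from a multi-temperature ensemble
#'
#' Computes the phase point at every simulated temperature and assembles the
#' two-phase ones, ordered by temperature, into a coexistence table.
#' Single-phase temperatures are excluded with a note. Rows with species
#' "total" carry the summed volume fractions.
#'
#' @param ensemble an `mc_ensemble` covering >= 1 temperature.
#' @param ... passed to [phase_point()].
#' @return data frame of class `binodal`: temperature, species, c_dilute,
#'   se_dilute, c_dense, se_dense.
#' @export
build_binodal <- function(ensemble, ...) {
  temps <- sort(unique(vapply(ensemble$trajectories, `[[`, 0, "temperature")))
  rows <- list()
  for (Tv in temps) {
    pp <- phase_point(ensemble, temperature = Tv, ...)
    if (pp$single_phase) {
      message(sprintf("T = %g: single-phase; excluded from binodal", Tv))
      next
    }
    tb <- pp$table
    tb$temperature <- Tv
    tot <- data.frame(species = "total",
                      c_dilute = sum(tb$c_dilute),
                      c_dense = sum(tb$c_dense),
                      se_dilute = sqrt(sum(tb$se_dilute^2)),
                      se_dense = sqrt(sum(tb$se_dense^2)),
                      temperature = Tv, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- rbind(tb, tot)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), c_dilute = numeric(),
               c_dense = numeric(), se_dilute = numeric(),
               se_dense = numeric(), temperature = numeric())
  class(out) <- c("binodal", "data.frame")
  out
}

#' Two-component phase diagram at fixed temperature
#'
#' Assembles per-stoichiometry dilute-arm and dense-arm points in the
#' (c_A, c_B) plane from a list of ensembles that share the temperature and
#' the two species but differ in chain counts. Pure runs contribute the
#' intrinsic saturation-concentration endpoints.
#'
#' @param ensembles list of `mc_ensemble`, each at one temperature.
#' @param species_a,species_b the two species names spanning the plane
#'   (defaults: first two species seen across the ensembles).
#' @param ... passed to [phase_point()].
#' @return data frame of class `two_component_diagram`: one row per
#'   stoichiometry with the molecule fraction `a` of species A, bulk
#'   concentrations, and per-species dilute/dense concentrations with SEs.
#' @export
two_component_diagram <- function(ensembles, species_a = NULL,
                                  species_b = NULL, ...) {
  all_sp <- unique(unlist(lapply(ensembles, function(e)
    e$config$tables$species_names)))
  if (is.null(species_a)) species_a <- all_sp[1]
  if (is.null(species_b)) species_b <- setdiff(all_sp, species_a)[1]
  rows <- lapply(ensembles, function(e) {
    cfg <- e$config
    nm <- cfg$tables$species_names
    counts <- vapply(cfg$species, function(s) s$n_chains, 0L)
    lens <- vapply(cfg$species, function(s) s$n_residues, 0L)
    names(counts) <- names(lens) <- nm
    cA <- if (species_a %in% nm) counts[[species_a]] else 0L
    cB <- if (species_b %in% nm) counts[[species_b]] else 0L
    a <- cA / (cA + cB)
    V <- prod(cfg$box)
    bulk_A <- if (species_a %in% nm) cA * lens[[species_a]] / V else 0
    bulk_B <- if (species_b %in% nm) cB * lens[[species_b]] / V else 0
    pp <- phase_point(e, ...)
    g <- function(sp, col) {
      if (sp %in% pp$table$species) pp$table[pp$table$species == sp, col] else 0
    }
    data.frame(a = a, single_phase = pp$single_phase,
               temperature = pp$temperature,
               c_tot_A = bulk_A, c_tot_B = bulk_B,
               c_dilute_A = g(species_a, "c_dilute"),
               c_dilute_B = g(species_b, "c_dilute"),
               c_dense_A = g(species_a, "c_dense"),
               c_dense_B = g(species_b, "c_dense"),
               se_dilute_A = g(species_a, "se_dilute"),
               se_dilute_B = g(species_b, "se_dilute"),
               se_dense_A = g(species_a, "se_dense"),
               se_dense_B = g(species_b, "se_dense"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$a), ]
  rownames(out) <- NULL
  attr(out, "species") <- c(A = species_a, B = species_b)
  class(out) <- c("two_component_diagram", "data.frame")
  out
}
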