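# Canonical-ensemble Metropolis Monte Carlo of multichain self-avoiding
# polymers on a periodic cubic lattice.

# flatten a species list + interaction model into the integer tables the
# C++ engine consumes. Chains are laid out species by species; beads of a
# chain are contiguous and ordered along the chain.
.system_tables <- function(species, model = NULL) {
  stopifnot(length(species) >= 1)
  species <- lapply(species, function(s) {
    stopifnot(inherits(s, "polymer_species")); s
  })
  nms <- vapply(species, function(s) s$name, "")
  n_chains <- vapply(species, function(s) s$n_chains, 0L)
  if (sum(n_chains) < 1L) stop("system has no chains")
  lens <- vapply(species, function(s) s$n_residues, 0L)
  chain_lengths <- rep(unname(lens), unname(n_chains))
  species_of_chain <- rep(seq_along(species), n_chains)
  nchain <- length(chain_lengths)
  chain_of <- rep(seq_len(nchain), chain_lengths)
  tabs <- list(
    species_names = nms,
    chain_lengths = chain_lengths,
    species_of_chain = species_of_chain,
    chain_of = chain_of,
    n_beads = sum(chain_lengths),
    n_chains = nchain,
    ncpr = setNames(vapply(species, function(s) s$ncpr, 0), nms)
  )
  if (!is.null(model)) {
    type_names <- rownames(model$contact_energy)
    type_idx_per_species <- lapply(species, function(s) {
      idx <- match(s$beads, type_names)
      if (anyNA(idx)) {
        stop(errorCondition(
          sprintf("bead type(s) of species '%s' missing from contact matrix: %s",
                  s$name, paste(unique(s$beads[is.na(idx)]), collapse = ", ")),
          class = "latmix_unknown_type_error"))
      }
      idx
    })
    tabs$type_of <- unlist(rep(type_idx_per_species, n_chains))
    tabs$contact_energy <- unname(model$contact_energy)
    tabs$elec <- unname(.elec_matrix(model, tabs$ncpr))
  }
  tabs
}

.MOVE_KINDS <- c("local_bead", "slithering_snake", "chain_translation",
                 "pivot", "double_pivot", "co_local", "cluster_translation")

#' Build a run configuration
#'
#' Collects everything a simulation campaign needs: the species (with chain
#' counts), the interaction model, box size, temperatures, step counts, move
#' weights, replicate count and the base random seed. The realized total bead
#' volume fraction is recorded in the returned object.
#'
#' @param species named list of `polymer_species` with `n_chains` set.
#' @param model an `interaction_model`.
#' @param box lattice edge length (scalar, cubic) or length-3 integer vector.
#' @param temperatures reduced-unit temperatures (k_B = 1), all > 0.
#' @param total_steps Monte Carlo steps per run.
#' @param n_replicates independent replicates per temperature (default 5),
#'   each with a distinct derived seed.
#' @param seed base random seed; all per-replicate seeds derive from it.
#' @param init_box edge of the central dense-initialization subbox
#'   (default 35, clipped to the box).
#' @param move_weights named non-negative weights over the seven move kinds
#'   (local_bead, slithering_snake, chain_translation, pivot, double_pivot,
#'   co_local, cluster_translation); default equal.
#' @param dmax maximum per-axis displacement of translation moves.
#' @param analysis_fraction fraction of the run discarded as equilibration;
#'   frames are sampled from the remainder (default 0.5, i.e. the second half).
#' @param n_frames target number of sampled frames per run.
#' @param energy_stride steps between energy-trace records (default
#'   `total_steps / 500`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(species, model, box, temperatures, total_steps,
                       n_replicates = 5L, seed = 1L, init_box = 35L,
                       move_weights = NULL, dmax = 3L,
                       analysis_fraction = 0.5, n_frames = 40L,
                       energy_stride = NULL) {
  if (length(box) == 1L) box <- rep(as.integer(box), 3L)
  box <- as.integer(box)
  stopifnot(length(box) == 3L, all(box >= 3L))
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (total_steps < 0) stop("total_steps must be >= 0")
  if (is.null(move_weights)) {
    move_weights <- setNames(rep(1, 7L), .MOVE_KINDS)
  } else {
    stopifnot(all(names(move_weights) %in% .MOVE_KINDS),
              all(move_weights >= 0))
    w <- setNames(rep(0, 7L), .MOVE_KINDS)
    w[names(move_weights)] <- move_weights
    move_weights <- w
  }
  tabs <- .system_tables(species, model)
  V <- prod(box)
  if (tabs$n_beads > V) stop("bead count exceeds box volume")
  if (is.null(energy_stride)) energy_stride <- max(1, total_steps %/% 500)
  structure(list(
    species = species, model = model, box = box,
    temperatures = as.numeric(temperatures),
    total_steps = as.numeric(total_steps),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    init_box = as.integer(min(init_box, min(box))),
    move_weights = move_weights, dmax = as.integer(dmax),
    analysis_fraction = analysis_fraction, n_frames = as.integer(n_frames),
    energy_stride = as.numeric(energy_stride),
    volume_fraction = tabs$n_beads / V,
    tables = tabs
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_config> %d species, %d chains (%d beads), box %s\n",
    "  volume fraction %.4f, T = {%s}, %g steps x %d replicates, seed %d\n"),
    length(x$species), x$tables$n_chains, x$tables$n_beads,
    paste(x$box, collapse = "x"), x$volume_fraction,
    paste(x$temperatures, collapse = ", "), x$total_steps,
    x$n_replicates, x$seed))
  invisible(x)
}

# deterministic per-(temperature, replicate) seed, < 2^31
.derive_seed <- function(base, t_index, replicate) {
  (((base %% 65011) * 32003 + t_index * 1009 + replicate * 13) %% 2147483647) + 1
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move with probability `min(1, exp(-delta_E / T))`
#' (k_B = 1). Uses R's RNG; the compiled sampler has its own seeded stream.
#'
#' @param delta_E energy change of the proposed move.
#' @param temperature reduced temperature, > 0.
#' @return logical.
#' @export
metropolis_accept <- function(delta_E, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  delta_E <= 0 | runif(length(delta_E)) < exp(-delta_E / temperature)
}

#' Dense-seed initial frame
#'
#' Grows every chain as a self-avoiding walk inside the central
#' `init_box`^3 subregion of the full box, which mimics starting from a
#' pre-formed dense droplet and speeds up equilibration of the two-phase
#' system.
#'
#' @param config a `run_config`.
#' @param seed integer seed for the placement RNG.
#' @return a `lattice_frame`.
#' @export
init_dense <- function(config, seed = config$seed) {
  coords <- cpp_init_dense(config$tables$chain_lengths, config$box,
                           config$init_box, seed)
  new_frame(coords, config, step = 0)
}

# light frame object: coordinates + the tables needed to interpret them
new_frame <- function(coords, config, step = 0L) {
  structure(list(coords = coords, box = config$box, step = step,
                 system = list(species = config$species, model = config$model),
                 tables = config$tables),
            class = "lattice_frame")
}

#' Extract a sampled frame from a trajectory
#'
#' @param traj an `mc_trajectory`.
#' @param i frame index (1-based).
#' @return a `lattice_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "mc_trajectory"))
  structure(list(coords = traj$frames[[i]], box = traj$box,
                 step = traj$frame_steps[i], system = traj$system,
                 tables = traj$tables),
            class = "lattice_frame")
}

#' @export
print.lattice_frame <- function(x, ...) {
  cat(sprintf("<lattice_frame> %d beads in %d chains, box %s, step %g\n",
              nrow(x$coords), x$tables$n_chains,
              paste(x$box, collapse = "x"), x$step))
  invisible(x)
}

#' Run the Monte Carlo campaign
#'
#' Simulates every temperature x replicate combination of the configuration.
#' Each run starts from a fresh dense seed, evolves under the Metropolis
#' criterion with the configured move mix, and samples frames from the
#' analysis window (by default the second half of the run). Trajectories are
#' bit-for-bit reproducible from (config, seed).
#'
#' @param config a `run_config`.
#' @param validate if TRUE, recompute the total energy from scratch after
#'   every accepted move and check all frame invariants (slow; for testing).
#' @param verbose print per-run progress.
#' @return an object of class `mc_ensemble`: a list of `mc_trajectory`
#'   objects plus the configuration.
#' @export
run_mc <- function(config, validate = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tabs <- config$tables
  if (is.null(tabs$type_of)) stop("run_config lacks an interaction model")
  trajs <- list()
  k <- 0L
  for (ti in seq_along(config$temperatures)) {
    Tval <- config$temperatures[ti]
    for (r in seq_len(config$n_replicates)) {
      s <- .derive_seed(config$seed, ti, r)
      coords0 <- cpp_init_dense(tabs$chain_lengths, config$box,
                                config$init_box, s * 2 + 1)
      frame_start <- floor(config$total_steps * config$analysis_fraction)
      n_window <- max(config$total_steps - frame_start, 1)
      frame_stride <- max(1, floor(n_window / max(config$n_frames - 1, 1)))
      t0 <- proc.time()[["elapsed"]]
      res <- cpp_run_mc(coords0, tabs$chain_of, tabs$type_of,
                        tabs$species_of_chain, config$box,
                        tabs$contact_energy, tabs$elec,
                        config$model$bonded_excluded,
                        unname(config$move_weights), config$dmax,
                        config$total_steps, Tval, s,
                        config$energy_stride, frame_stride, frame_start,
                        validate)
      if (config$total_steps == 0 && length(res$frames) == 0) {
        res$frames <- list(coords0)
        res$frame_steps <- 0
      }
      k <- k + 1L
      trajs[[k]] <- structure(list(
        frames = res$frames, frame_steps = res$frame_steps,
        energy = data.frame(step = res$energy_steps, energy = res$energies),
        temperature = Tval, replicate = r, seed = s, box = config$box,
        system = list(species = config$species, model = config$model),
        tables = tabs,
        accepts = setNames(res$accepts, .MOVE_KINDS),
        proposals = setNames(res$proposals, .MOVE_KINDS),
        energy_final = res$energy_final,
        energy_recomputed = res$energy_recomputed,
        max_energy_drift = res$max_energy_drift,
        wallclock = proc.time()[["elapsed"]] - t0
      ), class = "mc_trajectory")
      if (verbose)
        message(sprintf("T = %g replicate %d: E = %.1f (%.1fs)",
                        Tval, r, res$energy_final, trajs[[k]]$wallclock))
    }
  }
  structure(list(trajectories = trajs, config = config), class = "mc_ensemble")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> T = %g, replicate %d, %d frames, final E = %.2f\n",
              x$temperature, x$replicate, length(x$frames), x$energy_final))
  invisible(x)
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("<mc_ensemble> %d trajectories (%d temperatures x %d replicates)\n",
              length(x$trajectories), length(x$config$temperatures),
              x$config$n_replicates))
  invisible(x)
}

#' Select trajectories from an ensemble
#'
#' @param ensemble an `mc_ensemble`.
#' @param temperature,replicate optional filters.
#' @return list of `mc_trajectory`.
#' @export
trajectories <- function(ensemble, temperature = NULL, replicate = NULL) {
  tr <- ensemble$trajectories
  if (!is.null(temperature))
    tr <- Filter(function(x) isTRUE(all.equal(x$temperature, temperature)), tr)
  if (!is.null(replicate))
    tr <- Filter(function(x) x$replicate == replicate, tr)
  tr
}

#' Exact Boltzmann averages for a tiny system by exhaustive enumeration
#'
#' Enumerates every configuration of a small multichain system (after
#' translational reduction: the first bead of the first chain is pinned) and
#' returns exact canonical averages of the energy and of the inter-chain
#' bead-contact counts per species pair. This is the independent oracle
#' against which the Monte Carlo sampler is validated.
#'
#' @param species named list of `polymer_species` with chain counts; keep the
#'   system tiny (a few chains of length <= 4 in a box of edge <= 5).
#' @param model an `interaction_model`.
#' @param box lattice edge (scalar or length 3).
#' @param temperatures temperatures at which to evaluate the averages.
#' @param max_states guard on the enumeration size (default 2e7).
#' @return list with `mean_energy` (per temperature), `mean_contacts`
#'   (list of per-species-pair matrices, one per temperature), and `n_states`.
#' @export
enumerate_exact <- function(species, model, box, temperatures,
                            max_states = 2e7) {
  if (length(box) == 1L) box <- rep(as.integer(box), 3L)
  tabs <- .system_tables(species, model)
  if (tabs$n_beads > 60 || prod(box) > 512)
    stop(errorCondition("state space too large for exact enumeration",
                        class = "latmix_enumeration_limit_error"))
  # per-chain bead-type index sequences
  type_seqs <- split(tabs$type_of, tabs$chain_of)
  res <- cpp_enumerate_exact(unname(type_seqs), tabs$species_of_chain, box,
                             tabs$contact_energy, tabs$elec,
                             model$bonded_excluded, temperatures, max_states)
  ns <- length(tabs$species_names)
  pair_mat <- function(row) {
    m <- matrix(0, ns, ns,
                dimnames = list(tabs$species_names, tabs$species_names))
    p <- 1L
    for (a in seq_len(ns)) for (b in a:ns) {
      m[a, b] <- m[b, a] <- row[p]; p <- p + 1L
    }
    m
  }
  list(mean_energy = setNames(res$mean_energy, temperatures),
       mean_contacts = lapply(seq_along(temperatures),
                              function(t) pair_mat(res$mean_contacts[t, ])),
       n_states = res$n_states)
}

#' Mean inter-chain contact counts of a trajectory
#'
#' Averages, over the sampled frames, the number of inter-chain bead-bead
#' contacts per unordered species pair (whole box). Comparable to the
#' `mean_contacts` of [enumerate_exact()].
#'
#' @param traj an `mc_trajectory`.
#' @return list with `mean_energy`, `contacts` (species-pair matrix) and
#'   `n_frames`.
#' @export
mean_contacts_mc <- function(traj) {
  tabs <- traj$tables
  ns <- length(tabs$species_names)
  acc <- matrix(0, ns, ns,
                dimnames = list(tabs$species_names, tabs$species_names))
  for (f in traj$frames) {
    cc <- cpp_chain_contacts(f, tabs$chain_of, traj$box)
    if (nrow(cc) > 0) {
      si <- tabs$species_of_chain[cc[, 1]]
      sj <- tabs$species_of_chain[cc[, 2]]
      a <- pmin(si, sj); b <- pmax(si, sj)
      s <- rowsum(cc[, 3], (b - 1) * ns + a)
      v <- numeric(ns * ns)
      v[as.integer(rownames(s))] <- s[, 1]
      acc <- acc + matrix(v, ns, ns)
    }
  }
  acc <- acc / length(traj$frames)
  acc[lower.tri(acc)] <- t(acc)[lower.tri(acc)]
  widx <- traj$energy$step >= min(traj$frame_steps)
  list(mean_energy = mean(traj$energy$energy[widx]),
       contacts = acc, n_frames = length(traj$frames))
}

# ---- trajectory text format -------------------------------------------------

#' Write / read a trajectory as plain text
#'
#' Line-oriented format: a header of `key: value` lines (box, temperature,
#' replicate, seed), one `chain <id> <species> <length>` line per chain, then
#' per sampled frame a `frame <step>` line followed by one `x y z` line per
#' bead, in bead order.
#'
#' @param traj an `mc_trajectory`.
#' @param path output file.
#' @return `path` (write) or an `mc_trajectory` (read; coordinates and
#'   species labels only, no energy model).
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# latmix trajectory v1", con)
  writeLines(sprintf("box: %s", paste(traj$box, collapse = " ")), con)
  writeLines(sprintf("temperature: %.10g", traj$temperature), con)
  writeLines(sprintf("replicate: %d", traj$replicate), con)
  writeLines(sprintf("seed: %d", traj$seed), con)
  tabs <- traj$tables
  for (c in seq_len(tabs$n_chains)) {
    writeLines(sprintf("chain %d %s %d", c,
                       tabs$species_names[tabs$species_of_chain[c]],
                       tabs$chain_lengths[c]), con)
  }
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("frame %g", traj$frame_steps[i]), con)
    f <- traj$frames[[i]]
    writeLines(paste(f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "# latmix trajectory"))
  kv <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", ln)
  }
  box <- as.integer(strsplit(kv("box"), " ")[[1]])
  ch_lines <- grep("^chain ", lines, value = TRUE)
  ch <- do.call(rbind, strsplit(ch_lines, " "))
  species_names <- unique(ch[, 3])
  species_of_chain <- match(ch[, 3], species_names)
  chain_lengths <- as.integer(ch[, 4])
  chain_of <- rep(seq_along(chain_lengths), chain_lengths)
  nb <- sum(chain_lengths)
  frame_at <- grep("^frame ", lines)
  frames <- lapply(frame_at, function(i) {
    block <- lines[(i + 1):(i + nb)]
    m <- matrix(as.integer(unlist(strsplit(block, " "))), ncol = 3,
                byrow = TRUE)
    m
  })
  frame_steps <- as.numeric(sub("^frame ", "", lines[frame_at]))
  tabs <- list(species_names = species_names, chain_lengths = chain_lengths,
               species_of_chain = species_of_chain, chain_of = chain_of,
               n_beads = nb, n_chains = length(chain_lengths))
  structure(list(frames = frames, frame_steps = frame_steps,
                 energy = data.frame(step = numeric(0), energy = numeric(0)),
                 temperature = as.numeric(kv("temperature")),
                 replicate = as.integer(kv("replicate")),
                 seed = as.integer(kv("seed")),
                 box = box, system = NULL, tables = tabs),
            class = "mc_trajectory")
}
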