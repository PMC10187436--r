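# Orchestration: structured-text run configs, the end-to-end pipeline
# (simulate -> profile -> phase points -> mixture statistics), manifests,
# TSV export and figure-style reporting.

#' Write / read a run configuration as a structured text file
#'
#' The on-disk format is YAML with top-level keys `box`, `temperatures`,
#' `total_steps`, `n_replicates`, `seed`, `species` (list of records with
#' `name`, `n_chains`, and either `sequence` or `type` + `length`, plus
#' optional `ncpr`), and `model` (`types`, `contact_energy` rows, `w_el`,
#' `bonded_excluded`). Optional keys mirror the [run_config()] arguments.
#' Schema violations are reported with their field paths.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sp <- lapply(config$species, function(s) {
    rec <- list(name = s$name, n_chains = s$n_chains)
    if (length(unique(s$beads)) == 1L) {
      rec$type <- s$beads[1]; rec$length <- s$n_residues
    } else rec$sequence <- paste(s$beads, collapse = "")
    rec$ncpr <- s$ncpr
    rec
  })
  m <- config$model
  obj <- list(
    box = as.integer(config$box),
    temperatures = config$temperatures,
    total_steps = config$total_steps,
    n_replicates = config$n_replicates,
    seed = config$seed,
    init_box = config$init_box,
    dmax = config$dmax,
    analysis_fraction = config$analysis_fraction,
    n_frames = config$n_frames,
    move_weights = as.list(config$move_weights),
    species = unname(sp),
    model = list(types = rownames(m$contact_energy),
                 contact_energy = unname(apply(m$contact_energy, 1, as.list)),
                 w_el = m$w_el, bonded_excluded = m$bonded_excluded)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

.require_field <- function(obj, field, path) {
  if (is.null(obj[[field]]))
    stop(sprintf("config schema violation: missing field '%s%s'",
                 path, field))
  obj[[field]]
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  for (f in c("box", "temperatures", "total_steps", "species", "model"))
    .require_field(obj, f, "")
  nrep <- if (is.null(obj$n_replicates)) 5L else as.integer(obj$n_replicates)
  if (nrep < 1) stop("config schema violation: 'n_replicates' must be >= 1")
  species <- lapply(seq_along(obj$species), function(i) {
    rec <- obj$species[[i]]
    pfx <- sprintf("species[%d].", i)
    nm <- .require_field(rec, "name", pfx)
    nc <- .require_field(rec, "n_chains", pfx)
    if (!is.null(rec$sequence)) {
      polymer_species(nm, rec$sequence, n_chains = nc, ncpr = rec$ncpr)
    } else {
      len <- .require_field(rec, "length", pfx)
      tp <- .require_field(rec, "type", pfx)
      homopolymer(nm, len, n_chains = nc, type = tp,
                  ncpr = if (is.null(rec$ncpr)) 0 else rec$ncpr)
    }
  })
  names(species) <- vapply(species, function(s) s$name, "")
  mrec <- obj$model
  types <- .require_field(mrec, "types", "model.")
  ce <- .require_field(mrec, "contact_energy", "model.")
  mat <- do.call(rbind, lapply(ce, unlist))
  dimnames(mat) <- list(types, types)
  model <- interaction_model(
    mat, w_el = if (is.null(mrec$w_el)) 0 else mrec$w_el,
    bonded_excluded = !isFALSE(mrec$bonded_excluded))
  args <- list(species = species, model = model, box = unlist(obj$box),
               temperatures = unlist(obj$temperatures),
               total_steps = obj$total_steps, n_replicates = nrep,
               seed = if (is.null(obj$seed)) 1L else obj$seed)
  for (f in c("init_box", "dmax", "analysis_fraction", "n_frames"))
    if (!is.null(obj[[f]])) args[[f]] <- obj[[f]]
  if (!is.null(obj$move_weights))
    args$move_weights <- unlist(obj$move_weights)
  do.call(run_config, args)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates every temperature x replicate of the configuration (resumable:
#' an existing trajectory file for a (T, replicate) pair is reused instead of
#' re-simulated), then computes radial profiles with logistic fits, phase
#' points, the binodal, crosslinking statistics, Rg profiles and — for
#' two-species systems — tie lines, writing every product as TSV next to a
#' JSON manifest that records the config snapshot, seeds, version and
#' output paths.
#'
#' @param config a `run_config` or the path to a config file.
#' @param outdir output directory (created if needed).
#' @param overwrite re-simulate even when trajectory files exist.
#' @param verbose print progress.
#' @return an object of class `latmix_manifest` (invisibly).
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  tabs <- config$tables
  trajs <- list(); seeds <- list(); paths <- list()
  k <- 0L
  for (ti in seq_along(config$temperatures)) {
    Tv <- config$temperatures[ti]
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      fn <- file.path(outdir, sprintf("traj_T%g_rep%d.txt", Tv, r))
      if (file.exists(fn) && !overwrite) {
        if (verbose) message("reusing ", fn)
        trajs[[k]] <- read_trajectory(fn)
        trajs[[k]]$tables <- tabs
        seeds[[k]] <- trajs[[k]]$seed
      } else {
        s <- .derive_seed(config$seed, ti, r)
        coords0 <- cpp_init_dense(tabs$chain_lengths, config$box,
                                  config$init_box, s * 2 + 1)
        frame_start <- floor(config$total_steps * config$analysis_fraction)
        frame_stride <- max(1, floor((config$total_steps - frame_start) /
                                       max(config$n_frames - 1, 1)))
        res <- cpp_run_mc(coords0, tabs$chain_of, tabs$type_of,
                          tabs$species_of_chain, config$box,
                          tabs$contact_energy, tabs$elec,
                          config$model$bonded_excluded,
                          unname(config$move_weights), config$dmax,
                          config$total_steps, Tv, s, config$energy_stride,
                          frame_stride, frame_start, FALSE)
        tr <- structure(list(
          frames = res$frames, frame_steps = res$frame_steps,
          energy = data.frame(step = res$energy_steps, energy = res$energies),
          temperature = Tv, replicate = r, seed = s, box = config$box,
          system = list(species = config$species, model = config$model),
          tables = tabs,
          accepts = setNames(res$accepts, .MOVE_KINDS),
          proposals = setNames(res$proposals, .MOVE_KINDS),
          energy_final = res$energy_final,
          energy_recomputed = res$energy_recomputed,
          max_energy_drift = res$max_energy_drift
        ), class = "mc_trajectory")
        if (verbose) message(sprintf("simulated T = %g replicate %d", Tv, r))
        trajs[[k]] <- tr
        seeds[[k]] <- s
        write_trajectory(tr, fn)
        en <- file.path(outdir, sprintf("energy_T%g_rep%d.tsv", Tv, r))
        .write_tsv(tr$energy, en)
        # advisory equilibration check on the analysis window
        if (.energy_slope_warn(tr))
          warning(sprintf(
            "T = %g replicate %d: energy not plateaued in analysis window", Tv, r),
            call. = FALSE)
      }
      paths[[sprintf("trajectory_T%g_rep%d", Tv, r)]] <- fn
    }
  }
  ens <- structure(list(trajectories = trajs, config = config),
                   class = "mc_ensemble")
  temps <- config$temperatures
  nm <- tabs$species_names

  # per-temperature products
  for (Tv in temps) {
    prof <- radial_profile(ens, temperature = Tv)
    fits <- lapply(nm, function(s)
      tryCatch(.fit_logistic_core(prof$bin_centers, prof$density[s, ],
                                  prof$site_counts),
               latmix_single_phase_error = function(e) NULL))
    names(fits) <- nm
    ptab <- data.frame(bin = prof$bin_centers)
    for (s in nm) {
      ptab[[paste0("density_", s)]] <- prof$density[s, ]
      f <- fits[[s]]
      ptab[[paste0("fit_", s)]] <- if (is.null(f)) NA_real_ else
        f$rho_dilute + (f$rho_dense - f$rho_dilute) /
          (1 + exp((prof$bin_centers - f$r_mid) / f$width))
    }
    fn <- file.path(outdir, sprintf("profile_T%g.tsv", Tv))
    .write_tsv(ptab, fn)
    paths[[sprintf("profile_T%g", Tv)]] <- fn

    cs <- tryCatch(crosslink_parameter(ens, temperature = Tv),
                   error = function(e) NULL)
    if (!is.null(cs)) {
      ltab <- expand.grid(species_i = nm, species_j = nm,
                          stringsAsFactors = FALSE)
      ltab$L <- as.vector(cs$L); ltab$se <- as.vector(cs$se)
      ltab$temperature <- Tv
      fn <- file.path(outdir, sprintf("crosslink_T%g.tsv", Tv))
      .write_tsv(ltab, fn)
      paths[[sprintf("crosslink_T%g", Tv)]] <- fn
    }

    rg <- rg_profile(ens, temperature = Tv)
    rtab <- data.frame(bin = rg$bin_centers)
    for (s in nm) {
      rtab[[paste0("rg_norm_", s)]] <- rg$rg_norm[s, ]
      rtab[[paste0("se_", s)]] <- rg$se[s, ]
    }
    fn <- file.path(outdir, sprintf("rg_T%g.tsv", Tv))
    .write_tsv(rtab, fn)
    paths[[sprintf("rg_T%g", Tv)]] <- fn

    if (length(nm) == 2) {
      tl <- tryCatch(tie_line_mc(ens, temperature = Tv),
                     error = function(e) NULL)
      if (!is.null(tl)) {
        ttab <- data.frame(
          temperature = Tv,
          slope_dilute_to_total = tl$slope_dilute_to_total,
          se_dilute_to_total = tl$se_dilute_to_total,
          slope_total_to_dense = tl$slope_total_to_dense,
          se_total_to_dense = tl$se_total_to_dense,
          collinearity_gap = tl$collinearity_gap,
          classification = tl$classification)
        fn <- file.path(outdir, sprintf("tieline_T%g.tsv", Tv))
        .write_tsv(ttab, fn)
        paths[[sprintf("tieline_T%g", Tv)]] <- fn
      }
    }
  }
  bin <- build_binodal(ens)
  fn <- file.path(outdir, "binodal.tsv")
  .write_tsv(as.data.frame(bin), fn)
  paths[["binodal"]] <- fn

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("latmix")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    wallclock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outdir = outdir,
    seeds = unlist(seeds),
    temperatures = temps,
    species = nm,
    volume_fraction = config$volume_fraction,
    config = yaml::yaml.load(yaml::as.yaml(.config_snapshot(config))),
    paths = paths
  ), class = "latmix_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.config_snapshot <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  yaml::read_yaml(tmp)
}

# advisory sliding-window slope test on the analysis-window energy trace
.energy_slope_warn <- function(traj, z = 4) {
  e <- traj$energy
  w <- e$step >= floor(max(e$step) / 2)
  if (sum(w) < 10) return(FALSE)
  fit <- stats::lm(energy ~ step, data = e[w, ])
  s <- summary(fit)$coefficients
  if (nrow(s) < 2) return(FALSE)
  abs(s[2, 1]) > z * s[2, 2] &&
    abs(s[2, 1]) * diff(range(e$step[w])) > 0.05 * abs(mean(e$energy[w]))
}

#' Read a pipeline manifest
#'
#' @param path manifest.json or its directory.
#' @return a `latmix_manifest`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$paths <- as.list(m$paths)
  structure(m, class = "latmix_manifest")
}

#' @export
print.latmix_manifest <- function(x, ...) {
  cat(sprintf("<latmix_manifest> %s: %d outputs, T = {%s}\n", x$outdir,
              length(x$paths), paste(x$temperatures, collapse = ", ")))
  invisible(x)
}

#' Render summary figures from a pipeline manifest
#'
#' Draws binodal, radial-profile (with logistic fits and interfacial
#' shading), crosslink-vs-temperature, Rg-profile and tie-line panels from
#' the manifest's TSV outputs only; nothing is recomputed. An incomplete
#' manifest raises an error listing the missing pieces.
#'
#' @param manifest a `latmix_manifest` (or path).
#' @param file optional PDF path; when NULL, draws on the current device.
#' @return invisibly, the vector of panels drawn.
#' @export
report <- function(manifest, file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  paths <- manifest$paths
  missing <- names(Filter(function(p) !file.exists(p), paths))
  if (length(paths) == 0)
    stop("empty manifest: no outputs recorded (missing: trajectories, profiles, binodal)")
  if (length(missing) > 0)
    stop("incomplete manifest; missing outputs: ",
         paste(missing, collapse = ", "))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  panels <- character(0)
  temps <- manifest$temperatures
  sp <- manifest$species
  cols <- grDevices::hcl.colors(max(3, length(sp)), "Dark 2")[seq_along(sp)]

  bino <- read.table(paths[["binodal"]], header = TRUE, sep = "\t")
  if (nrow(bino) > 0 && length(unique(bino$temperature)) >= 2) {
    plot(NA, xlim = range(c(bino$c_dilute, bino$c_dense)),
         ylim = range(bino$temperature),
         xlab = "volume fraction", ylab = "temperature (reduced)",
         main = "Binodal", log = "")
    for (i in seq_along(sp)) {
      b <- bino[bino$species == sp[i], ]
      points(b$c_dilute, b$temperature, col = cols[i], pch = 16)
      points(b$c_dense, b$temperature, col = cols[i], pch = 1)
    }
    legend("top", legend = sp, col = cols, pch = 16, bty = "n")
    panels <- c(panels, "binodal")
  } else if (length(temps) == 1) {
    message("binodal panel skipped: only one temperature in the manifest")
  }

  for (Tv in temps) {
    key <- sprintf("profile_T%g", Tv)
    if (is.null(paths[[key]])) next
    pr <- read.table(paths[[key]], header = TRUE, sep = "\t")
    dmax <- max(pr[, grep("^density_", names(pr))], na.rm = TRUE)
    plot(NA, xlim = range(pr$bin), ylim = c(0, dmax * 1.05),
         xlab = "r (lattice units)", ylab = "volume fraction",
         main = sprintf("Radial density, T = %g", Tv))
    for (i in seq_along(sp)) {
      points(pr$bin, pr[[paste0("density_", sp[i])]], col = cols[i], pch = 16,
             cex = 0.6)
      fc <- pr[[paste0("fit_", sp[i])]]
      if (!all(is.na(fc))) lines(pr$bin, fc, col = cols[i])
    }
    legend("topright", legend = sp, col = cols, pch = 16, bty = "n")
    panels <- c(panels, key)
  }

  ckeys <- sprintf("crosslink_T%g", temps)
  have <- ckeys %in% names(paths)
  if (any(have)) {
    cl <- do.call(rbind, lapply(ckeys[have], function(k)
      read.table(paths[[k]], header = TRUE, sep = "\t")))
    pairs <- unique(cl[, c("species_i", "species_j")])
    plot(NA, xlim = range(cl$temperature) + c(-0.5, 0.5),
         ylim = range(c(cl$L - cl$se, cl$L + cl$se), na.rm = TRUE),
         xlab = "temperature (reduced)", ylab = "L",
         main = "Crosslinking parameter")
    abline(h = 1, lty = 2, col = "grey")
    for (p in seq_len(nrow(pairs))) {
      d <- cl[cl$species_i == pairs$species_i[p] &
              cl$species_j == pairs$species_j[p], ]
      lines(d$temperature, d$L, col = p)
      points(d$temperature, d$L, col = p, pch = 16)
    }
    legend("topleft", legend = paste(pairs$species_i, "-", pairs$species_j),
           col = seq_len(nrow(pairs)), pch = 16, bty = "n", cex = 0.8)
    panels <- c(panels, "crosslink")
  }

  for (Tv in temps) {
    key <- sprintf("rg_T%g", Tv)
    if (is.null(paths[[key]])) next
    rg <- read.table(paths[[key]], header = TRUE, sep = "\t")
    ycols <- grep("^rg_norm_", names(rg))
    if (all(is.na(rg[, ycols]))) next
    plot(NA, xlim = range(rg$bin), ylim = range(rg[, ycols], na.rm = TRUE),
         xlab = "distance from condensate COM", ylab = "Rg / sqrt(N)",
         main = sprintf("Chain dimensions, T = %g", Tv))
    for (i in seq_along(sp)) {
      y <- rg[[paste0("rg_norm_", sp[i])]]
      lines(rg$bin[!is.na(y)], y[!is.na(y)], col = cols[i])
      points(rg$bin, y, col = cols[i], pch = 16, cex = 0.6)
    }
    legend("topleft", legend = sp, col = cols, pch = 16, bty = "n")
    panels <- c(panels, key)
  }
  invisible(panels)
}

#' @importFrom graphics plot points lines legend abline rect
NULL
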