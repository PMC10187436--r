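# base-graphics methods for the analysis products

.species_cols <- function(n) grDevices::hcl.colors(max(3, n), "Dark 2")[seq_len(n)]

#' @export
plot.radial_profile <- function(x, fits = NULL, ...) {
  ns <- nrow(x$density)
  cols <- .species_cols(ns)
  graphics::plot(NA, xlim = range(x$bin_centers),
                 ylim = c(0, max(x$density, na.rm = TRUE) * 1.05),
                 xlab = "r (lattice units)", ylab = "volume fraction",
                 main = sprintf("Radial density, T = %g", x$temperature), ...)
  if (is.null(fits))
    fits <- tryCatch(fit_logistic(x), error = function(e) NULL)
  for (i in seq_len(ns)) {
    s <- x$species[i]
    f <- fits[[s]]
    if (!is.null(f)) {
      graphics::rect(f$r_lo, 0, f$r_hi, max(x$density) * 1.05,
                     col = grDevices::adjustcolor(cols[i], 0.12), border = NA)
      curve_y <- f$rho_dilute + (f$rho_dense - f$rho_dilute) /
        (1 + exp((x$bin_centers - f$r_mid) / f$width))
      graphics::lines(x$bin_centers, curve_y, col = cols[i])
    }
    graphics::points(x$bin_centers, x$density[i, ], col = cols[i], pch = 16,
                     cex = 0.6)
    if (!is.null(x$se))
      graphics::arrows(x$bin_centers, x$density[i, ] - x$se[i, ],
                       x$bin_centers, x$density[i, ] + x$se[i, ],
                       length = 0.02, angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("topright", legend = x$species, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' @export
plot.binodal <- function(x, log_c = TRUE, ...) {
  if (nrow(x) == 0) stop("empty binodal")
  sp <- setdiff(unique(x$species), "total")
  cols <- .species_cols(length(sp))
  cx <- c(x$c_dilute, x$c_dense)
  cx <- cx[cx > 0]
  graphics::plot(NA, xlim = range(cx), ylim = range(x$temperature),
                 log = if (log_c) "x" else "",
                 xlab = "volume fraction", ylab = "temperature (reduced)",
                 main = "Binodal", ...)
  for (i in seq_along(sp)) {
    b <- x[x$species == sp[i], ]
    graphics::points(pmax(b$c_dilute, min(cx)), b$temperature, col = cols[i],
                     pch = 16)
    graphics::points(b$c_dense, b$temperature, col = cols[i], pch = 1)
  }
  graphics::legend("top", legend = sp, col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' @export
plot.crosslink_profile <- function(x, ...) {
  pairs <- unique(x[, c("species_i", "species_j")])
  graphics::plot(NA, xlim = range(x$temperature) + c(-0.5, 0.5),
                 ylim = range(c(x$L - x$se, x$L + x$se), na.rm = TRUE),
                 xlab = "temperature (reduced)", ylab = "L",
                 main = "Crosslinking parameter", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  for (p in seq_len(nrow(pairs))) {
    d <- x[x$species_i == pairs$species_i[p] &
           x$species_j == pairs$species_j[p], ]
    graphics::lines(d$temperature, d$L, col = p)
    graphics::points(d$temperature, d$L, col = p, pch = 16)
    graphics::arrows(d$temperature, d$L - d$se, d$temperature, d$L + d$se,
                     length = 0.02, angle = 90, code = 3, col = p)
  }
  graphics::legend("topleft",
                   legend = paste(pairs$species_i, "-", pairs$species_j),
                   col = seq_len(nrow(pairs)), pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.rg_profile <- function(x, ...) {
  ns <- nrow(x$rg_norm)
  cols <- .species_cols(ns)
  graphics::plot(NA, xlim = range(x$bin_centers),
                 ylim = range(x$rg_norm, na.rm = TRUE),
                 xlab = "distance from condensate COM (lattice units)",
                 ylab = expression(R[g] / sqrt(N)),
                 main = sprintf("Chain dimensions, T = %g", x$temperature),
                 ...)
  for (i in seq_len(ns)) {
    y <- x$rg_norm[i, ]
    ok <- !is.na(y)
    graphics::lines(x$bin_centers[ok], y[ok], col = cols[i])
    graphics::points(x$bin_centers, y, col = cols[i], pch = 16, cex = 0.6)
  }
  graphics::legend("topleft", legend = x$species, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' @export
plot.two_component_diagram <- function(x, arms = c("dilute", "dense"), ...) {
  arms <- match.arg(arms, several.ok = TRUE)
  sp <- attr(x, "species")
  xr <- range(c(if ("dilute" %in% arms) x$c_dilute_A,
                if ("dense" %in% arms) x$c_dense_A), na.rm = TRUE)
  yr <- range(c(if ("dilute" %in% arms) x$c_dilute_B,
                if ("dense" %in% arms) x$c_dense_B), na.rm = TRUE)
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = sprintf("c(%s)", sp[["A"]]),
                 ylab = sprintf("c(%s)", sp[["B"]]),
                 main = sprintf("Two-component diagram, T = %g",
                                x$temperature[1]), ...)
  if ("dilute" %in% arms) {
    graphics::points(x$c_dilute_A, x$c_dilute_B, pch = 16, col = "steelblue")
    # additivity reference: the straight line joining the pure endpoints
    ends <- x[x$a %in% c(0, 1), ]
    if (nrow(ends) == 2)
      graphics::lines(ends$c_dilute_A, ends$c_dilute_B, lty = 2,
                      col = "grey40")
  }
  if ("dense" %in% arms)
    graphics::points(x$c_dense_A, x$c_dense_B, pch = 1, col = "firebrick")
  invisible(x)
}

#' @export
plot.tie_line <- function(x, ...) {
  p <- x$points
  graphics::plot(p[, 1], p[, 2], pch = c(16, 15, 1),
                 xlab = "c(A)", ylab = "c(B)",
                 main = sprintf("Tie line (%s)", x$classification), ...)
  graphics::lines(p[, 1], p[, 2], col = "grey40")
  graphics::text(p[, 1], p[, 2], rownames(p), pos = 3, cex = 0.7)
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, ...) {
  acc <- object$accepts / pmax(object$proposals, 1)
  e <- object$energy$energy
  out <- list(temperature = object$temperature,
              replicate = object$replicate, seed = object$seed,
              n_frames = length(object$frames),
              acceptance_rates = round(acc, 4),
              energy_final = object$energy_final,
              energy_drift = abs(object$energy_final -
                                   object$energy_recomputed),
              energy_range = range(e))
  class(out) <- "summary.mc_trajectory"
  out
}

#' @export
print.summary.mc_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: T = %g, replicate %d, seed %d, %d frames\n",
              x$temperature, x$replicate, x$seed, x$n_frames))
  cat(sprintf("Final energy %.2f (bookkeeping drift %.2g)\n",
              x$energy_final, x$energy_drift))
  cat("Acceptance rates:\n")
  print(x$acceptance_rates)
  invisible(x)
}
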