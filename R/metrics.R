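#' Atom and molecule validity
#'
#' An atom is valid iff its bonded-neighbour count (from [perceive_bonds()],
#' hydrogens included) does not exceed the element's natural valence;
#' undersaturation is valid by definition. A molecule is valid iff all its
#' atoms are.
#'
#' @param config an [atomic_config()].
#' @param tolerance bond-perception tolerance (default 1.2).
#' @return Object of class `validity_report`: list with `atom_valid`
#'   (logical per atom), `fraction` (valid-atom fraction), `molecule_valid`,
#'   and `connected` (single bond-graph component).
#' @export
atom_validity <- function(config, tolerance = 1.2) {
  stopifnot_config(config)
  g <- perceive_bonds(config, tolerance)
  val <- if (n_atoms(config) > 0L) natural_valence(config$elements) else integer(0)
  ok <- g$neighbour_count <= val
  structure(
    list(atom_valid = ok,
         fraction = if (length(ok)) mean(ok) else 1,
         molecule_valid = all(ok),
         connected = graph_components(g) == 1L),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> valid atoms: ", round(100 * x$fraction, 1),
      "% | molecule ", if (x$molecule_valid) "valid" else "invalid",
      " | ", if (x$connected) "connected" else "fragmented", "\n", sep = "")
  invisible(x)
}

#' Fraction of connected structures
#'
#' @param configs list of [atomic_config()] objects (non-empty).
#' @param tolerance bond-perception tolerance.
#' @return Fraction in `[0, 1]` whose bond graph has exactly one component.
#' @export
connected_fraction <- function(configs, tolerance = 1.2) {
  if (length(configs) == 0L) stop("empty list", call. = FALSE)
  mean(vapply(configs, function(cfg) {
    graph_components(perceive_bonds(cfg, tolerance)) == 1L
  }, logical(1)))
}

#' Similarity-energy placement scan
#'
#' Probes the similarity-energy landscape: for every node of an xy grid, the
#' total similarity energy of the base configuration plus a probe atom at the
#' node (z = 0), including the perturbation the probe causes to the base
#' atoms' own environments. Reproduces the landscape in which specific
#' bonding-site minima emerge as the kernel width shrinks.
#'
#' @param base_config a (heavy-atom, xy-planar) configuration.
#' @param probe_element element of the probe (default "O").
#' @param refset a [reference_set()].
#' @param sigma kernel width.
#' @param spacing grid spacing in \enc{Å}{A} (default 0.1).
#' @param margin margin beyond the base-atom bounding box (default 3).
#' @param params [descriptor_params()].
#' @return Object of class `molforge_scan`: list with `x`, `y` (grid axes),
#'   `energy` (matrix, `energy[ix, iy]`), `sigma`, `base_config`.
#' @export
scan_placement_energy <- function(base_config, probe_element = "O", refset,
                                  sigma, spacing = 0.1, margin = 3,
                                  params = descriptor_params()) {
  stopifnot_config(base_config)
  pos <- base_config$positions
  xs <- seq(min(pos[, 1L]) - margin, max(pos[, 1L]) + margin, by = spacing)
  ys <- seq(min(pos[, 2L]) - margin, max(pos[, 2L]) + margin, by = spacing)
  els <- c(base_config$elements, probe_element)
  n <- n_atoms(base_config)
  energy <- matrix(NA_real_, length(xs), length(ys))
  R <- ref_matrix(refset)
  ch <- config_channels(atomic_config(els, rbind(pos, 0)), params)
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      p <- rbind(pos, c(xs[ix], ys[iy], 0))
      desc <- cpp_descriptors(p, ch, length(params$channels), params$r_cut,
                              params$r_min, params$n_radial, params$l_max,
                              params$ang_delta, FALSE)$desc
      d2 <- cross_dist2(desc, R) / (2 * sigma^2)
      energy[ix, iy] <- -sum(apply(-d2, 1L, logsumexp))
    }
  }
  structure(list(x = xs, y = ys, energy = energy, sigma = sigma,
                 base_config = base_config, probe = probe_element),
            class = "molforge_scan")
}

#' @export
print.molforge_scan <- function(x, ...) {
  cat("<molforge_scan> ", length(x$x), "x", length(x$y), " grid, sigma = ",
      signif(x$sigma, 3), ", E in [", signif(min(x$energy), 4), ", ",
      signif(max(x$energy), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.molforge_scan <- function(x, n_levels = 30, ...) {
  graphics::image(x$x, x$y, x$energy, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (A)", ylab = "y (A)", useRaster = TRUE, ...)
  graphics::contour(x$x, x$y, x$energy, nlevels = n_levels, add = TRUE,
                    drawlabels = FALSE, col = "grey30")
  graphics::points(x$base_config$positions[, 1:2], pch = 19, col = "white")
  invisible(x)
}

#' Count local minima of a placement scan
#'
#' Grid nodes within `region_radius` of `region_center` that are strictly
#' below all 8 neighbours and at least `depth_threshold` below the median
#' energy on the region's rim. The depth test suppresses shallow noise
#' minima.
#'
#' @param scan a `molforge_scan`.
#' @param region_center length-2 (x, y) centre in \enc{Å}{A}.
#' @param region_radius region radius in \enc{Å}{A}.
#' @param depth_threshold minimum depth below the rim median (default 0.1
#'   energy units).
#' @return Integer count; attribute `minima` holds the (x, y, energy) of
#'   each counted minimum.
#' @export
count_local_minima <- function(scan, region_center, region_radius,
                               depth_threshold = 0.1) {
  E <- scan$energy
  nx <- length(scan$x); ny <- length(scan$y)
  cx <- region_center[1L]; cy <- region_center[2L]
  if (cx < min(scan$x) || cx > max(scan$x) || cy < min(scan$y) ||
      cy > max(scan$y)) {
    stop("region outside grid", call. = FALSE)
  }
  dist2 <- outer((scan$x - cx)^2, (scan$y - cy)^2, `+`)
  inside <- dist2 <= region_radius^2
  spacing <- scan$x[2L] - scan$x[1L]
  rim <- inside & dist2 > (region_radius - 1.5 * spacing)^2
  if (!any(rim)) rim <- inside
  rim_median <- median(E[rim])
  found <- list()
  for (ix in 2:(nx - 1L)) {
    for (iy in 2:(ny - 1L)) {
      if (!inside[ix, iy]) next
      e <- E[ix, iy]
      nb <- E[(ix - 1L):(ix + 1L), (iy - 1L):(iy + 1L)]
      if (e < min(nb[-5L]) && e <= rim_median - depth_threshold) {
        found[[length(found) + 1L]] <- c(scan$x[ix], scan$y[iy], e)
      }
    }
  }
  structure(length(found),
            minima = if (length(found)) do.call(rbind, found) else
              matrix(numeric(0), 0L, 3L))
}
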