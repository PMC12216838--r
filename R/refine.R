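xh_bond_length <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

#' Count hydrogens needed to satisfy valences
#'
#' Per heavy atom, `max(0, natural_valence - round(sum of perceived bond
#' orders) - existing H neighbours)`. Heavy-heavy bond orders come from
#' [bond_order_estimate()]: distances below the pair's double-bond regime
#' count 2, aromatic/conjugated lengths count 1.5, and the summed valence is
#' rounded half-down so a benzene carbon (two aromatic bonds, sum 3) gains
#' exactly one hydrogen and a conjugated-but-single bond never suppresses one.
#'
#' @param config a configuration (heavy atoms, optionally with H already
#'   present -- existing H neighbours are subtracted).
#' @param tolerance bond-perception tolerance (default 1.2).
#' @return Integer vector: missing hydrogens per atom (0 for H atoms).
#' @export
count_missing_hydrogens <- function(config, tolerance = 1.2) {
  stopifnot_config(config)
  g <- perceive_bonds(config, tolerance)
  n <- n_atoms(config)
  counts <- integer(n)
  if (n == 0L) return(counts)
  val <- natural_valence(config$elements)
  for (i in seq_len(n)) {
    if (config$elements[i] == "H") next
    nb <- which(g$adjacency[i, ])
    ords <- 0
    n_h <- 0L
    for (j in nb) {
      if (config$elements[j] == "H") {
        n_h <- n_h + 1L
      } else {
        r <- sqrt(sum((config$positions[i, ] - config$positions[j, ])^2))
        ords <- ords + bond_order_estimate(config$elements[i],
                                           config$elements[j], r)
      }
    }
    heavy_val <- ceiling(ords - 0.5)  # round halves down: conjugation slack
    counts[i] <- max(0L, as.integer(val[i] - heavy_val) - n_h)
  }
  counts
}

#' Place hydrogens by rejection sampling
#'
#' Each hydrogen is proposed uniformly on a sphere of the element's X-H bond
#' length (C 1.09, N 1.01, O 0.96 \enc{Å}{A}) about its heavy atom and
#' rejected while closer than 0.9 \enc{Å}{A} to any other atom; after
#' `max_tries` failures the least-crowded proposal seen is kept, so placement
#' always succeeds.
#'
#' @param config heavy-atom configuration.
#' @param counts per-atom hydrogen counts, e.g. from
#'   [count_missing_hydrogens()].
#' @param max_tries rejection-sampling cap per hydrogen (default 64).
#' @return An [atomic_config()] with hydrogens appended (frozen mask FALSE
#'   for new atoms).
#' @export
place_hydrogens <- function(config, counts, max_tries = 64L) {
  stopifnot_config(config)
  counts <- rep_len(as.integer(counts), n_atoms(config))
  pos <- config$positions
  els <- config$elements
  frz <- config$frozen
  all_pos <- pos
  n0 <- n_atoms(config)
  for (i in seq_len(n0)) {
    if (counts[i] == 0L) next
    bl <- if (els[i] %in% names(xh_bond_length)) xh_bond_length[[els[i]]] else 1.09
    for (h in seq_len(counts[i])) {
      best <- NULL; best_d <- -Inf
      for (try in seq_len(max_tries)) {
        u <- rnorm(3)
        cand <- pos[i, ] + bl * u / sqrt(sum(u^2))
        dmin <- min(sqrt(rowSums(sweep(all_pos, 2L, cand)^2)))
        if (dmin > best_d) { best <- cand; best_d <- dmin }
        if (dmin >= 0.9) break
      }
      all_pos <- rbind(all_pos, best)
      els <- c(els, "H")
      frz <- c(frz, FALSE)
    }
  }
  rownames(all_pos) <- NULL
  atomic_config(els, all_pos, frz)
}

#' Relaxation configuration
#'
#' The composite relaxation potential: exponential short-range repulsion
#' between all atoms, harmonic bond terms (X-H bonds at their standard
#' lengths; heavy-heavy perceived bonds restrained to their entry lengths so
#' the generated skeleton is preserved), plus optionally the similarity
#' energy at the final annealed kernel width acting on the heavy atoms.
#'
#' @param max_iter L-BFGS iteration cap (default 200).
#' @param tol convergence threshold on the maximum force component (default
#'   1e-3).
#' @param k_bond harmonic bond stiffness (default 20, energy/\enc{Å}{A}\eqn{^2}).
#' @param alpha repulsion inverse range (default 4 /\enc{Å}{A}).
#' @param repulsion_strength repulsion amplitude (default 80, as in the
#'   generation loop); bonded (1-2) pairs are excluded from repulsion so bond
#'   lengths are set by the harmonic terms alone.
#' @param refset optional [reference_set()]; when given the similarity energy
#'   at `sigma_final` is added for heavy atoms.
#' @param sigma_final kernel width for the similarity term (default 0.1,
#'   about the end-of-anneal width).
#' @param w_sim weight of the similarity term (default 1).
#' @param params [descriptor_params()].
#' @return Object of class `relaxation_config`.
#' @export
relaxation_config <- function(max_iter = 200L, tol = 1e-3, k_bond = 20,
                              alpha = 4.0, repulsion_strength = 80,
                              refset = NULL, sigma_final = 0.1,
                              w_sim = 1, params = descriptor_params()) {
  if (tol <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(max_iter = as.integer(max_iter), tol = tol, k_bond = k_bond,
                 alpha = alpha, repulsion_strength = repulsion_strength,
                 refset = refset, sigma_final = sigma_final,
                 w_sim = w_sim, params = params),
            class = "relaxation_config")
}

# harmonic bond list for the relaxation potential: heavy-heavy perceived
# bonds restrained to their entry lengths; each H restrained to exactly one
# parent (its nearest heavy atom) at the standard X-H length; H-H never
# bonded
relax_bonds <- function(config) {
  els <- config$elements
  pos <- config$positions
  g <- perceive_bonds(config)
  keep <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  if (nrow(g$edges) > 0L) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
      if (els[i] == "H" || els[j] == "H") next
      r0 <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      keep <- rbind(keep, data.frame(i = i, j = j, r0 = r0))
    }
  }
  heavy_idx <- which(els != "H")
  for (h in which(els == "H")) {
    if (length(heavy_idx) == 0L) break
    d <- sqrt(rowSums(sweep(pos[heavy_idx, , drop = FALSE], 2L, pos[h, ])^2))
    parent <- heavy_idx[which.min(d)]
    keep <- rbind(keep, data.frame(i = parent, j = h,
                                   r0 = xh_bond_length[[els[parent]]] %||% 1.09))
  }
  keep
}

relax_energy_grad <- function(pos, config, bonds, control, movable) {
  cfg <- atomic_config(config$elements, pos, config$frozen)
  rep_ <- repulsive_energy_force(cfg, control$alpha, control$repulsion_strength)
  energy <- rep_$energy
  grad <- -rep_$force
  if (nrow(bonds) > 0L) {
    # 1-2 exclusion: bonded pairs interact through the harmonic term only
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      dvec <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(dvec^2))
      if (r < 1e-12) next
      e <- control$repulsion_strength * exp(-control$alpha * r)
      energy <- energy - e
      gk <- control$alpha * e * dvec / r
      grad[i, ] <- grad[i, ] - gk
      grad[j, ] <- grad[j, ] + gk
    }
  }
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      dvec <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(dvec^2))
      if (r < 1e-9) next
      energy <- energy + control$k_bond * (r - bonds$r0[k])^2
      gk <- 2 * control$k_bond * (r - bonds$r0[k]) * dvec / r
      grad[i, ] <- grad[i, ] - gk
      grad[j, ] <- grad[j, ] + gk
    }
  }
  if (!is.null(control$refset)) {
    heavy <- which(cfg$elements %in% control$params$channels)
    if (length(heavy) > 0L) {
      sub <- subset_config(cfg, heavy)
      sf <- similarity_force(sub, control$refset, control$sigma_final,
                             control$params)
      energy <- energy + control$w_sim * sf$energy
      grad[heavy, ] <- grad[heavy, ] - control$w_sim * sf$force
    }
  }
  list(energy = energy, grad = grad)
}

#' Relax a structure with the composite potential
#'
#' Quasi-Newton (L-BFGS-B) minimisation of the [relaxation_config()]
#' potential until the largest force component on a movable atom drops below
#' `tol` or the iteration cap is hit. Frozen atoms never move;
#' `only_hydrogens = TRUE` additionally pins all heavy atoms (used by the
#' valence re-check loop).
#'
#' @param config a full structure (with hydrogens).
#' @param control a [relaxation_config()].
#' @param only_hydrogens move only H atoms.
#' @return The relaxed [atomic_config()]; attributes `energy_initial`,
#'   `energy_final` and `converged` report the run.
#' @export
relax <- function(config, control = relaxation_config(),
                  only_hydrogens = FALSE) {
  stopifnot_config(config)
  n <- n_atoms(config)
  movable <- !config$frozen
  if (only_hydrogens) movable <- movable & config$elements == "H"
  if (!any(movable) || n == 0L) return(config)
  bonds <- relax_bonds(config)
  midx <- which(movable)
  pack <- function(pos) as.numeric(t(pos[midx, , drop = FALSE]))
  unpack <- function(x) {
    pos <- config$positions
    pos[midx, ] <- matrix(x, ncol = 3L, byrow = TRUE)
    pos
  }
  fn <- function(x) {
    eg <- relax_energy_grad(unpack(x), config, bonds, control, movable)
    if (!is.finite(eg$energy)) stop("non-finite relaxation energy", call. = FALSE)
    eg$energy
  }
  gr <- function(x) {
    eg <- relax_energy_grad(unpack(x), config, bonds, control, movable)
    as.numeric(t(eg$grad[midx, , drop = FALSE]))
  }
  e0 <- fn(pack(config$positions))
  opt <- optim(pack(config$positions), fn, gr, method = "L-BFGS-B",
               control = list(maxit = control$max_iter,
                              pgtol = control$tol, factr = 1e7))
  out <- atomic_config(config$elements, unpack(opt$par), config$frozen)
  attr(out, "energy_initial") <- e0
  attr(out, "energy_final") <- min(opt$value, e0)
  attr(out, "converged") <- opt$convergence == 0L
  if (opt$value > e0) {
    # L-BFGS-B never accepts an uphill final iterate in practice; guard anyway
    out <- config
    attr(out, "energy_initial") <- e0
    attr(out, "energy_final") <- e0
    attr(out, "converged") <- TRUE
  }
  out
}

#' Valence re-check loop
#'
#' After relaxation, bonding may have changed; this recomputes the missing
#' hydrogen counts, adds any newcomers, re-relaxes hydrogens only, and
#' repeats up to `max_rounds` times. Idempotent on valence-complete
#' structures.
#'
#' @param config a relaxed structure with hydrogens.
#' @param control a [relaxation_config()].
#' @param max_rounds maximum add/re-relax rounds (default 3).
#' @return The final [atomic_config()].
#' @export
valence_check_loop <- function(config, control = relaxation_config(),
                               max_rounds = 3L) {
  for (round in seq_len(max_rounds)) {
    counts <- count_missing_hydrogens(config)
    if (sum(counts) == 0L) break
    config <- place_hydrogens(config, counts)
    config <- relax(config, control, only_hydrogens = TRUE)
  }
  config
}

#' Full refinement: hydrogenate, relax, re-check valences
#'
#' @param config a generated heavy-atom structure (or any structure missing
#'   hydrogens).
#' @param control a [relaxation_config()].
#' @param skip_relax skip the geometry relaxation (hydrogen placement and
#'   valence arithmetic only).
#' @param max_rounds valence re-check rounds (default 3).
#' @return List with `config` (refined structure) and `added` (hydrogens
#'   added per original atom in the first round).
#' @export
refine <- function(config, control = relaxation_config(), skip_relax = FALSE,
                   max_rounds = 3L) {
  counts <- count_missing_hydrogens(config)
  out <- place_hydrogens(config, counts)
  if (!skip_relax) {
    out <- relax(out, control)
    out <- valence_check_loop(out, control, max_rounds)
  }
  list(config = out, added = counts)
}
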