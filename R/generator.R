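#' Sampler configuration
#'
#' @param n_steps sampler steps over the anneal (default 50).
#' @param noise_floor minimum per-step positional noise scale in \enc{Å}{A}
#'   (default 0.05); keeps a little exploration alive at the end of the
#'   anneal where the schedule-implied noise vanishes.
#' @param noise_scale multiplier tying the per-step noise to the annealed
#'   kernel width: noise sd is `max(noise_scale * sigma(t), noise_floor)`
#'   \enc{Å}{A} (default 1). Exploration shrinks as the kernel sharpens.
#' @param t_switch linear/geometric changeover of the time grid (default 1).
#' @param alpha repulsion inverse range in 1/\enc{Å}{A} (default 4).
#' @param repulsion_strength amplitude of the short-range repulsion in the
#'   combined force (default 80, calibrated to balance the similarity-force
#'   scale at contact distances; the bare pair term of
#'   [repulsive_energy_force()] keeps amplitude 1).
#' @param max_step per-atom displacement cap per sampler step in \enc{Å}{A}
#'   (default 0.3): keeps the integrator stable where the annealed force
#'   prefactor grows faster than the time step shrinks.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_steps = 50L, noise_floor = 0.05, noise_scale = 1,
                           t_switch = 1, alpha = 4.0, repulsion_strength = 80,
                           max_step = 0.3) {
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  if (noise_floor < 0) stop("noise_floor must be >= 0", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (max_step <= 0) stop("max_step must be > 0", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), noise_floor = noise_floor,
                 noise_scale = noise_scale, t_switch = t_switch, alpha = alpha,
                 repulsion_strength = repulsion_strength, max_step = max_step),
            class = "sampler_config")
}

#' Swarm (element-optimisation) configuration
#'
#' Settings for the mutation-augmented particle-swarm optimisation of the
#' element composition.
#'
#' @param n_particles swarm size (default 10), >= 2.
#' @param n_freq sampler steps between PSO rounds (default 2).
#' @param mutation_fraction fraction of (non-frozen) atoms mutated per
#'   non-elite particle (default 0.2); the count is `ceiling(f * n)`.
#' @param elements allowed swap elements (default C, N, O; group-1/17
#'   elements are forbidden because single-valence atoms saturate the
#'   similarity trivially).
#' @param beta0 prefactor of the inverse-temperature schedule
#'   `beta(t) = beta0 * exp(-t)` (default 5).
#' @param prob_sign `"text"` (default) mutates *low*-similarity atoms
#'   preferentially, `p ~ exp(beta * E_local)`; `"formula"` keeps the
#'   opposite (high-similarity-favouring) literal convention.
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 10L, n_freq = 2L,
                         mutation_fraction = 0.2,
                         elements = c("C", "N", "O"), beta0 = 5,
                         prob_sign = c("text", "formula")) {
  if (n_particles < 2L) stop("n_particles must be >= 2", call. = FALSE)
  if (!(mutation_fraction > 0 && mutation_fraction <= 1)) {
    stop("mutation_fraction must be in (0, 1]", call. = FALSE)
  }
  if (length(elements) == 0L) stop("empty allowed-element set", call. = FALSE)
  check_elements(elements)
  structure(list(n_particles = as.integer(n_particles),
                 n_freq = as.integer(n_freq),
                 mutation_fraction = mutation_fraction,
                 elements = elements, beta0 = beta0,
                 prob_sign = match.arg(prob_sign)),
            class = "swarm_config")
}

#' One annealed sampler step
#'
#' Injects Gaussian positional noise at scale
#' `max(noise_scale * sigma(t_k), noise_floor)` -- exploration tied to the
#' annealed kernel width -- then advances positions over `dt = t_k - t_{k+1}`
#' by an operator-split step (force as `dr/dt`): an explicit Heun
#' (predictor + trapezoidal corrector) step with per-atom displacement cap
#' for the stiff similarity + repulsion part, and an exact exponential step
#' for the linear prior part. Frozen atoms are untouched.
#'
#' @param config an [atomic_config()].
#' @param refset a [reference_set()].
#' @param prior a `prior_spec`.
#' @param schedule a [force_schedule()].
#' @param t_from,t_to consecutive grid times, `t_from > t_to`.
#' @param control a [sampler_config()].
#' @param params [descriptor_params()].
#' @return The updated `atomic_config`.
#' @export
sampler_step <- function(config, refset, prior, schedule, t_from, t_to,
                         control = sampler_config(),
                         params = descriptor_params()) {
  if (t_from <= t_to) stop("need t_from > t_to", call. = FALSE)
  n <- n_atoms(config)
  free <- !config$frozen
  dt <- t_from - t_to
  noise_sd <- max(control$noise_scale * schedule$sigma(t_from),
                  control$noise_floor)
  pos0 <- config$positions
  if (any(free) && noise_sd > 0) {
    pos0[free, ] <- pos0[free, , drop = FALSE] +
      matrix(rnorm(3L * sum(free), sd = noise_sd), sum(free), 3L)
  }
  clip <- function(step) {
    len <- sqrt(rowSums(step^2))
    over <- len > control$max_step
    if (any(over)) {
      step[over, ] <- step[over, , drop = FALSE] * (control$max_step / len[over])
    }
    step
  }
  # operator splitting: the similarity + repulsion part is stiff and
  # nonlinear -> explicit step with displacement cap; the prior part is
  # linear with known per-axis rate -> exact exponential step (stable and
  # full-strength at any dt)
  phi_at <- function(t) {
    rate <- (schedule$c_prior / n) * schedule$k_prior(t) / prior$covariance
    ifelse(rate > 1e-12, -expm1(-rate * dt) / rate, dt)
  }
  step_of <- function(f, t) {
    clip(dt * f$force_stiff) + sweep(f$force_prior, 2L, phi_at(t), `*`)
  }
  cfg <- atomic_config(config$elements, pos0, config$frozen)
  f0 <- combined_force(cfg, refset, prior, schedule, t_from, params,
                       control$alpha, control$repulsion_strength)
  pred <- atomic_config(cfg$elements, cfg$positions + step_of(f0, t_from),
                        cfg$frozen)
  f1 <- combined_force(pred, refset, prior, schedule, t_to, params,
                       control$alpha, control$repulsion_strength)
  pos <- cfg$positions + 0.5 * (step_of(f0, t_from) + step_of(f1, t_to))
  pos[!free, ] <- config$positions[!free, , drop = FALSE]
  if (any(!is.finite(pos))) stop("non-finite positions after step", call. = FALSE)
  atomic_config(config$elements, pos, config$frozen)
}

#' Create a mutated particle swarm
#'
#' Copies of the current configuration with element mutations: particle 1 is
#' the unchanged elite; every other particle mutates `ceiling(f * n_free)`
#' distinct non-frozen atoms, chosen with probability increasing in their
#' local similarity energy (low-similarity atoms mutate first), each to a
#' uniformly drawn different element of the allowed set.
#'
#' @param config an [atomic_config()] with at least one non-frozen atom.
#' @param refset a [reference_set()].
#' @param swarm a [swarm_config()].
#' @param t current time (sets `sigma` and `beta`).
#' @param schedule a [force_schedule()].
#' @param params [descriptor_params()].
#' @return List of `n_particles` configurations, the first identical to the
#'   input.
#' @export
mutate_swarm <- function(config, refset, swarm, t, schedule = force_schedule(),
                         params = descriptor_params()) {
  free_idx <- which(!config$frozen)
  if (length(free_idx) == 0L) stop("no mutable atoms", call. = FALSE)
  beta <- swarm$beta0 * exp(-t)
  sigma <- schedule$sigma(t)
  desc <- compute_descriptors(config, params)
  e_local <- vapply(seq_len(n_atoms(config)), function(i) {
    local_similarity_energy(desc[i, ], refset, sigma)
  }, numeric(1))
  # log f = -E_local; mutate lowest-similarity atoms preferentially
  lp <- if (swarm$prob_sign == "text") beta * e_local[free_idx] else
    -beta * e_local[free_idx]
  prob <- exp(lp - logsumexp(lp))
  n_mut <- min(length(free_idx), ceiling(swarm$mutation_fraction * length(free_idx)))
  particles <- vector("list", swarm$n_particles)
  particles[[1L]] <- config
  for (k in 2:swarm$n_particles) {
    els <- config$elements
    sites <- if (length(free_idx) == 1L) free_idx else
      sample(free_idx, n_mut, prob = prob)
    for (s in sites) {
      choices <- setdiff(swarm$elements, els[s])
      if (length(choices) == 0L) next
      els[s] <- if (length(choices) == 1L) choices else sample(choices, 1L)
    }
    particles[[k]] <- atomic_config(els, config$positions, config$frozen)
  }
  particles
}

#' Boltzmann particle selection
#'
#' Draws one particle with probability proportional to `exp(-beta * E)`,
#' computed via log-sum-exp.
#'
#' @param particles list of configurations.
#' @param energies numeric vector of their similarity energies (finite).
#' @param beta inverse temperature, >= 0.
#' @return One configuration from `particles`.
#' @export
select_particle <- function(particles, energies, beta) {
  if (length(particles) != length(energies)) {
    stop("particles and energies disagree in length", call. = FALSE)
  }
  if (any(!is.finite(energies))) stop("non-finite energies", call. = FALSE)
  if (length(particles) == 1L) return(particles[[1L]])
  lw <- -beta * energies
  p <- exp(lw - logsumexp(lw))
  particles[[sample.int(length(particles), 1L, prob = p)]]
}

#' Generate a heavy-atom molecular structure
#'
#' The main zero-shot generation loop: initial positions are sampled from the
#' spatial prior and elements drawn uniformly from the allowed set; the loop
#' then alternates rounds of element mutation (PSO) with annealed stochastic
#' position updates along the combined prior + similarity + repulsion force,
#' Boltzmann-selecting one particle after each round. Returns the final
#' heavy-atom structure (hydrogens are added separately by [refine()]).
#'
#' @param n_atoms number of atoms to generate (ignored if `config` given).
#' @param refset a [reference_set()] (default: the fixture bank).
#' @param prior a `prior_spec` (default [gaussian_prior()]).
#' @param schedule a [force_schedule()].
#' @param sampler a [sampler_config()].
#' @param swarm a [swarm_config()], or `NULL` to disable element
#'   optimisation.
#' @param config optional starting configuration (e.g. a frozen scaffold plus
#'   free atoms); frozen atoms never move or change element.
#' @param elements element pool for the initial uniform draw (default C, N,
#'   O). With `swarm = NULL` the composition stays fixed at this draw, which
#'   is the no-PSO ablation baseline.
#' @param seed integer seed; the whole run is reproducible given it.
#' @param params [descriptor_params()].
#' @param trajectory record the configuration at every knot (default FALSE).
#' @return An object of class `molforge_result`: list with `config` (final
#'   structure), `energies` (similarity energy at each knot), `times`
#'   (the grid), `trajectory` (optional list), `seed`, and the configs used.
#' @export
generate <- function(n_atoms = NULL, refset = default_reference_set(params),
                     prior = gaussian_prior(), schedule = force_schedule(),
                     sampler = sampler_config(), swarm = swarm_config(),
                     config = NULL, elements = c("C", "N", "O"), seed = 1L,
                     params = descriptor_params(), trajectory = FALSE) {
  set.seed(seed)
  if (is.null(config)) {
    if (is.null(n_atoms) || n_atoms < 1L) {
      stop("give n_atoms >= 1 or a starting config", call. = FALSE)
    }
    pool <- if (is.null(swarm)) elements else swarm$elements
    config <- atomic_config(sample(pool, n_atoms, replace = TRUE),
                            sample_prior(prior, n_atoms))
  } else {
    stopifnot_config(config)
    free <- which(!config$frozen)
    if (length(free) > 0L) {
      pos <- config$positions
      pos[free, ] <- sample_prior(prior, length(free))
      config <- atomic_config(config$elements, pos, config$frozen)
    }
  }
  grid <- time_grid(schedule, sampler$n_steps, sampler$t_switch)
  energy_at <- function(cfg, t) {
    similarity_energy(compute_descriptors(cfg, params), refset,
                      schedule$sigma(t))
  }
  energies <- numeric(length(grid))
  energies[1L] <- energy_at(config, grid[1L])
  traj <- if (trajectory) vector("list", length(grid)) else NULL
  if (trajectory) traj[[1L]] <- config

  pso_on <- !is.null(swarm) && any(!config$frozen)
  k <- 1L
  n_steps <- sampler$n_steps
  while (k <= n_steps) {
    if (pso_on) {
      span <- min(swarm$n_freq, n_steps - k + 1L)
      particles <- mutate_swarm(config, refset, swarm, grid[k], schedule, params)
      for (s in seq_len(span)) {
        particles <- lapply(particles, sampler_step, refset = refset,
                            prior = prior, schedule = schedule,
                            t_from = grid[k + s - 1L], t_to = grid[k + s],
                            control = sampler, params = params)
      }
      t_now <- grid[k + span]
      part_e <- vapply(particles, energy_at, numeric(1), t = t_now)
      beta <- swarm$beta0 * exp(-t_now)
      config <- select_particle(particles, part_e, beta)
      e_sel <- part_e[[which(vapply(particles, identical, logical(1), config))[1L]]]
      for (s in seq_len(span)) {
        energies[k + s] <- NA_real_
        if (trajectory) traj[[k + s]] <- NULL
      }
      energies[k + span] <- e_sel
      if (trajectory) traj[[k + span]] <- config
      k <- k + span
    } else {
      config <- sampler_step(config, refset, prior, schedule,
                             grid[k], grid[k + 1L], sampler, params)
      energies[k + 1L] <- energy_at(config, grid[k + 1L])
      if (trajectory) traj[[k + 1L]] <- config
      k <- k + 1L
    }
  }
  structure(
    list(config = config, energies = energies, times = grid,
         trajectory = traj, seed = seed, sampler = sampler, swarm = swarm,
         params = params),
    class = "molforge_result"
  )
}

#' @export
print.molforge_result <- function(x, ...) {
  cat("<molforge_result> seed", x$seed, "\n")
  print(x$config)
  e <- x$energies[!is.na(x$energies)]
  cat("E_sim:", round(e[1L], 3), "->", round(e[length(e)], 3), "over",
      length(x$times) - 1L, "steps\n")
  invisible(x)
}

#' @export
summary.molforge_result <- function(object, ...) {
  g <- perceive_bonds(object$config)
  v <- atom_validity(object$config)
  cat("Final structure:\n")
  print(object$config)
  cat("bonds:", nrow(g$edges), "| connected components:", graph_components(g),
      "| valid-atom fraction:", round(v$fraction, 3), "\n")
  invisible(object)
}

#' @export
plot.molforge_result <- function(x, ...) {
  ok <- !is.na(x$energies)
  graphics::plot(x$times[ok], x$energies[ok], type = "b", log = "x",
                 xlab = "t (anneal time)", ylab = expression(E[sim]),
                 main = "Similarity energy over the anneal", ...)
  invisible(x)
}
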