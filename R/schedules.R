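#' Force schedule for the annealed generation loop
#'
#' Holds the time range and the three scheduling functions that shift the
#' dynamics from prior-dominated exploration to similarity-dominated
#' settling:
#' \itemize{
#'   \item `k_prior(t) = tanh(20 t^2)` -- restorative-force weight, ~1 for
#'     most of the run and released only at the very end;
#'   \item `k_sim(t) = 1/sigma(t)^2 = 119 (1 - (t/10)^{1/4}) + 1` -- the
#'     similarity weight, growing from 1 at `t = 10` to 120 at `t = 0`;
#'   \item `sigma(t) = k_sim(t)^{-1/2}` -- the annealed kernel width
#'     (1 down to about 0.091).
#' }
#' The prior term is additionally scaled by `c_prior / n_atoms` during
#' generation so the restorative force matches the size of the molecule.
#' The default `c_prior = 90` balances the prior against the package's
#' similarity-force scale: at the 10-30-atom sizes the generator targets, an
#' atom one prior standard deviation off the density peak then feels a
#' restoring force comparable to the median mid-anneal similarity force, so
#' the early dynamics are genuinely prior-dominated.
#'
#' @param t_max,t_min time range of the anneal (defaults 10 and 0.01).
#' @param c_prior numerator of the 1/n prior multiplier (default 90).
#' @param k_gui constant guidance weight (default 1); used only by the
#'   guidance utilities.
#' @return An object of class `force_schedule` with callable members
#'   `k_prior`, `k_sim`, `sigma` and `k_gui`.
#' @export
force_schedule <- function(t_max = 10, t_min = 0.01, c_prior = 90, k_gui = 1) {
  if (!(t_max > t_min && t_min > 0)) stop("need t_max > t_min > 0", call. = FALSE)
  check_t <- function(t) {
    if (any(t < 0 | t > t_max + 1e-9)) {
      stop("t outside schedule range [0, t_max]", call. = FALSE)
    }
  }
  sched <- list(
    t_max = t_max, t_min = t_min, c_prior = c_prior,
    k_prior = function(t) { check_t(t); tanh(20 * t^2) },
    k_sim = function(t) { check_t(t); 119 * (1 - (t / 10)^(1 / 4)) + 1 },
    k_gui = function(t) rep_len(k_gui, length(t))
  )
  sched$sigma <- function(t) sched$k_sim(t)^(-1 / 2)
  class(sched) <- "force_schedule"
  sched
}

#' @export
print.force_schedule <- function(x, ...) {
  cat("<force_schedule> t in [", x$t_min, ", ", x$t_max, "], sigma: ",
      round(x$sigma(x$t_max), 4), " -> ", round(x$sigma(x$t_min), 4),
      ", c_prior = ", x$c_prior, "\n", sep = "")
  invisible(x)
}

#' Sampler time grid
#'
#' `n_steps + 1` strictly decreasing knots from `t_max` to `t_min`: the first
#' half of the intervals is linear in t (down to `t_switch`), the remainder
#' decays geometrically to `t_min`.
#'
#' @param schedule a [force_schedule()].
#' @param n_steps number of sampler steps, >= 2 (default 50).
#' @param t_switch changeover time between the linear and geometric phases
#'   (default 1).
#' @return Numeric vector of length `n_steps + 1`.
#' @export
time_grid <- function(schedule, n_steps = 50L, t_switch = 1) {
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  if (!(t_switch < schedule$t_max && t_switch > schedule$t_min)) {
    stop("t_switch must lie inside (t_min, t_max)", call. = FALSE)
  }
  n_lin <- ceiling(n_steps / 2)
  n_geo <- n_steps - n_lin
  lin <- seq(schedule$t_max, t_switch, length.out = n_lin + 1L)
  geo <- t_switch * (schedule$t_min / t_switch)^(seq_len(n_geo) / n_geo)
  c(lin, geo)
}

#' Combined generation force
#'
#' The per-atom force driving the position updates:
#' `(c_prior/n) k_prior(t) F_prior + k_sim(t) F~_sim + F_repulsive`, with the
#' QM term of the full formulation fixed at zero during the heavy-atom loop.
#' Rows of frozen atoms are zeroed.
#'
#' @param config an [atomic_config()].
#' @param refset a [reference_set()].
#' @param prior a `prior_spec`.
#' @param schedule a [force_schedule()].
#' @param t current time in `[t_min, t_max]`.
#' @param params [descriptor_params()].
#' @param alpha repulsion inverse range (default 4 /\enc{Å}{A}).
#' @param repulsion_strength repulsion amplitude (default 80; see
#'   [sampler_config()]).
#' @return List with `force` (n x 3), `energy` (similarity energy at
#'   `sigma(t)`) and `sigma`.
#' @export
combined_force <- function(config, refset, prior, schedule, t,
                           params = descriptor_params(), alpha = 4.0,
                           repulsion_strength = 80) {
  n <- n_atoms(config)
  sigma <- schedule$sigma(t)
  sim <- similarity_force(config, refset, sigma, params)
  rep_ <- repulsive_energy_force(config, alpha, repulsion_strength)
  pri <- (schedule$c_prior / n) * schedule$k_prior(t) *
    prior_force(config$positions, prior)
  stiff <- schedule$k_sim(t) * sim$force_tilde + rep_$force
  force <- pri + stiff
  force[config$frozen, ] <- 0
  if (any(!is.finite(force))) {
    stop("non-finite combined force: descriptor/parameter pathology",
         call. = FALSE)
  }
  # the similarity + repulsion part is stiff (curvature ~ k_sim) and needs
  # the sampler's displacement cap; the prior part is a linear restoring
  # force the Heun step integrates stably uncapped
  pri[config$frozen, ] <- 0
  stiff[config$frozen, ] <- 0
  list(force = force, force_prior = pri, force_stiff = stiff,
       energy = sim$energy, sigma = sigma)
}
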