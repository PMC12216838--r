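#' Guidance configuration
#'
#' @param energy `"standard"` (per-atom similarity energy) or `"inverse"`
#'   (inverse-sum energy, for fragment-biased guidance where every reference
#'   environment should find a match).
#' @param k_gui guidance-strength schedule: a constant or a function of t.
#' @param minibatch minibatch size m for importance resampling (default 8).
#' @param interval resampling interval N_IS in sampler steps (default 5).
#' @param temperature resampling temperature T > 0 (default 1).
#' @return Object of class `guidance_config`.
#' @export
guidance_config <- function(energy = c("standard", "inverse"), k_gui = 1,
                            minibatch = 8L, interval = 5L, temperature = 1) {
  if (minibatch < 1L || interval < 1L) stop("minibatch and interval must be >= 1",
                                            call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (!is.function(k_gui)) { k_const <- k_gui; k_gui <- function(t) k_const }
  structure(list(energy = match.arg(energy), k_gui = k_gui,
                 minibatch = as.integer(minibatch),
                 interval = as.integer(interval), temperature = temperature),
            class = "guidance_config")
}

#' Guide an external score model with the similarity force
#'
#' Additive score guidance: `s(x, t) + k_gui(t) * F_sim(x, t)` (or the
#' negative gradient of the inverse-sum energy when the guidance energy is
#' `"inverse"`). The base model is any callable `(config, t) -> n x 3`
#' matrix. Guidance on frozen atoms is zeroed.
#'
#' @param score_model callable `(config, t)` returning an n x 3 score.
#' @param config an [atomic_config()].
#' @param t model time.
#' @param refset a [reference_set()].
#' @param gconf a [guidance_config()].
#' @param sigma kernel width for the similarity term (default 0.2).
#' @param params [descriptor_params()].
#' @return n x 3 guided score matrix.
#' @export
guided_score <- function(score_model, config, t, refset,
                         gconf = guidance_config(), sigma = 0.2,
                         params = descriptor_params()) {
  s <- score_model(config, t)
  s <- matrix(as.numeric(s), n_atoms(config), 3L)
  if (any(!is.finite(s))) stop("non-finite base score", call. = FALSE)
  k <- gconf$k_gui(t)
  if (k == 0) return(s)
  f <- if (gconf$energy == "inverse") {
    inverse_similarity_force(config, refset, sigma, params)$force
  } else {
    similarity_force(config, refset, sigma, params)$force
  }
  f[config$frozen, ] <- 0
  s + k * f
}

#' Minibatch importance resampling
#'
#' Draws `m` members of the minibatch with replacement with weight
#' proportional to `exp(-E_i / T)` (log-sum-exp normalised), the
#' gradient-free alternative to score guidance.
#'
#' @param minibatch list of configurations (or any objects).
#' @param energies their guidance energies; finite, same length.
#' @param temperature T > 0.
#' @return A list of the same length, resampled.
#' @export
importance_resample <- function(minibatch, energies, temperature = 1) {
  m <- length(minibatch)
  if (length(energies) != m) stop("length mismatch", call. = FALSE)
  if (all(!is.finite(energies))) stop("all energies non-finite", call. = FALSE)
  lw <- -energies / temperature
  p <- exp(lw - logsumexp(lw))
  minibatch[sample.int(m, m, replace = TRUE, prob = p)]
}

#' Analytic Gaussian-mixture toy score model
#'
#' The exact score (gradient of the log-density) of an isotropic
#' Gaussian-mixture over per-atom positions at noise scale `sigma_t`:
#' a stand-in for a trained diffusion model in guidance tests.
#'
#' @param means N x 3 matrix of mixture means.
#' @param sigma_t noise scale; a number or a function of t.
#' @return A callable `(config, t) -> n x 3` score matrix.
#' @export
toy_gaussian_mixture_score <- function(means, sigma_t = function(t) t) {
  means <- as.matrix(means)
  if (length(means) == 3L && nrow(means) != 1L) means <- matrix(means, 1L, 3L)
  if (!is.function(sigma_t)) { s_const <- sigma_t; sigma_t <- function(t) s_const }
  function(config, t) {
    st <- sigma_t(t)
    pos <- config$positions
    out <- matrix(0, nrow(pos), 3L)
    for (i in seq_len(nrow(pos))) {
      dvec <- sweep(means, 2L, pos[i, ], `-`)        # mu - x
      lw <- -rowSums(dvec^2) / (2 * st^2)
      w <- exp(lw - logsumexp(lw))
      out[i, ] <- colSums(w * dvec) / st^2
    }
    out
  }
}
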