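#' Descriptor parameters
#'
#' Settings for the invariant local-environment descriptors: an
#' element-channelled Gaussian radial basis combined with a spherical-harmonic
#' power spectrum, evaluated on overlap-transformed distances inside a smooth
#' cutoff envelope, and normalised to unit length.
#'
#' @param r_cut locality cutoff in \enc{Å}{A} (default 5.0): atoms beyond it
#'   cannot influence a descriptor at all.
#' @param r_min overlap plateau in \enc{Å}{A} (default 0.75): below this
#'   separation the transformed distance is constant, so descriptors and
#'   gradients stay well-behaved for fully overlapping atoms.
#' @param n_radial number of radial Gaussian bumps (default 8).
#' @param l_max maximum angular momentum of the power spectrum (default 3,
#'   the supported maximum).
#' @param channels ordered element channel list. Defaults to C, N, O: group-1
#'   and group-17 elements are excluded from generation because single-valence
#'   elements trivially cap similarity optimisation; include `"H"`/`"S"`
#'   explicitly for reference extraction from protonated structures.
#' @param ang_delta width in \enc{Å}{A} of the smooth switch that turns the
#'   (direction-dependent) angular terms on above the overlap plateau
#'   (default 0.5).
#' @return An object of class `descriptor_params`.
#' @export
descriptor_params <- function(r_cut = 5.0, r_min = 0.75, n_radial = 8L,
                              l_max = 3L, channels = c("C", "N", "O"),
                              ang_delta = 0.5) {
  if (!(r_min > 0 && r_min < r_cut)) stop("need 0 < r_min < r_cut", call. = FALSE)
  if (n_radial < 1L) stop("n_radial must be >= 1", call. = FALSE)
  if (l_max < 0L || l_max > 3L) stop("l_max must be in 0..3", call. = FALSE)
  check_elements(channels)
  if (anyDuplicated(channels)) stop("duplicate channels", call. = FALSE)
  structure(
    list(r_cut = r_cut, r_min = r_min, n_radial = as.integer(n_radial),
         l_max = as.integer(l_max), channels = channels, ang_delta = ang_delta),
    class = "descriptor_params"
  )
}

#' @export
print.descriptor_params <- function(x, ...) {
  cat("<descriptor_params> d =", descriptor_dim(x),
      "| r_cut =", x$r_cut, "A, r_min =", x$r_min,
      "A | channels:", paste(x$channels, collapse = ","), "\n")
  invisible(x)
}

#' Descriptor vector dimension implied by a parameter set
#'
#' @param params a [descriptor_params()] object.
#' @return Integer dimension `d`.
#' @export
descriptor_dim <- function(params) {
  E <- length(params$channels)
  E + E * params$n_radial + E * (E + 1) / 2 * (params$l_max + 1)
}

#' Overlap-tolerant distance transform
#'
#' `r_min + max(0, r - r_min)`, i.e. distances are clamped from below at
#' `r_min` so the descriptor (and everything downstream) is constant on the
#' overlap plateau. Continuous, piecewise-linear, non-decreasing.
#'
#' @param r distance(s) in \enc{Å}{A}, non-negative.
#' @param r_min plateau radius in \enc{Å}{A} (default 0.75).
#' @return Transformed distance(s).
#' @examples
#' transform_distance(c(0, 0.75, 2), 0.75)
#' @export
transform_distance <- function(r, r_min = 0.75) {
  if (any(r < 0)) stop("distances must be non-negative", call. = FALSE)
  r_min + pmax(0, r - r_min)
}

config_channels <- function(config, params) {
  idx <- match(config$elements, params$channels)
  if (anyNA(idx)) {
    stop("element(s) outside descriptor channels: ",
         paste(unique(config$elements[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

#' Compute per-atom environment descriptors
#'
#' @param config an [atomic_config()] whose elements all appear in
#'   `params$channels`.
#' @param params a [descriptor_params()].
#' @return A numeric matrix (one unit-norm row per atom) of class
#'   `descriptor_set`, with the parameters attached as attribute `params`.
#' @export
compute_descriptors <- function(config, params = descriptor_params()) {
  stopifnot_config(config)
  ch <- config_channels(config, params)
  out <- cpp_descriptors(config$positions, ch, length(params$channels),
                         params$r_cut, params$r_min, params$n_radial,
                         params$l_max, params$ang_delta, FALSE)
  structure(out$desc, params = params, class = c("descriptor_set", "matrix", "array"))
}

#' Descriptors together with their position Jacobian
#'
#' Analytic derivatives of every descriptor component of every atom with
#' respect to every atomic coordinate (normalisation included).
#'
#' @inheritParams compute_descriptors
#' @return A list with `desc` (as [compute_descriptors()]) and `jac`, a
#'   4-d array with dimensions `(d, 3, n_atoms, n_atoms)`:
#'   `jac[f, a, k, i]` is the derivative of descriptor component `f` of atom
#'   `i` with respect to coordinate `a` of atom `k`.
#' @export
descriptor_jacobian <- function(config, params = descriptor_params()) {
  stopifnot_config(config)
  ch <- config_channels(config, params)
  out <- cpp_descriptors(config$positions, ch, length(params$channels),
                         params$r_cut, params$r_min, params$n_radial,
                         params$l_max, params$ang_delta, TRUE)
  n <- n_atoms(config)
  jac <- array(out$jac, dim = c(descriptor_dim(params), 3L, n, n))
  list(desc = structure(out$desc, params = params,
                        class = c("descriptor_set", "matrix", "array")),
       jac = jac)
}
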