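#' Supported chemical elements
#'
#' Elements the package knows covalent radii and natural valences for.
#' Generation itself is restricted to the heavy elements of the descriptor
#' channel list (C, N, O by default); hydrogen enters only at refinement.
#'
#' @format A named list with components `symbols`, `covalent_radius` (\enc{Å}{A},
#'   Cordero-style values) and `valence` (natural valence, integer).
#' @keywords internal
element_data <- local({
  symbols <- c("H", "C", "N", "O", "S")
  covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)
  valence <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L)
  list(symbols = symbols, covalent_radius = covalent_radius, valence = valence)
})

#' Natural valence lookup
#'
#' @param elements character vector of element symbols.
#' @return Integer vector of natural valences (H = 1, C = 4, N = 3, O = 2,
#'   S = 2). Unsupported symbols are an error.
#' @examples
#' natural_valence(c("C", "O"))
#' @export
natural_valence <- function(elements) {
  check_elements(elements)
  unname(element_data$valence[elements])
}

#' Covalent radius lookup
#'
#' @param elements character vector of element symbols.
#' @return Numeric vector of covalent radii in \enc{Å}{A}.
#' @export
covalent_radius <- function(elements) {
  check_elements(elements)
  unname(element_data$covalent_radius[elements])
}

check_elements <- function(elements) {
  bad <- setdiff(unique(elements), element_data$symbols)
  if (length(bad) > 0L) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Atomic configuration
#'
#' The object being generated: element symbols, Cartesian positions in
#' \enc{Å}{A}, and a per-atom frozen mask. Frozen atoms (a pre-placed scaffold)
#' keep their position and element throughout generation but still contribute
#' to every energy, so a scaffold shapes the similarity landscape around it.
#'
#' @param elements character vector of element symbols.
#' @param positions numeric matrix with one row per atom and 3 columns (\enc{Å}{A}).
#' @param frozen logical vector, `TRUE` marks an immutable atom. Recycled from
#'   a single value.
#' @return An object of class `atomic_config`.
#' @examples
#' atomic_config("O", matrix(0, 1, 3))
#' @export
atomic_config <- function(elements, positions, frozen = FALSE) {
  elements <- as.character(elements)
  if (length(elements) == 0L) {
    positions <- matrix(numeric(0), 0L, 3L)
  }
  positions <- as.matrix(positions)
  if (length(positions) == 3L && nrow(positions) != 1L) positions <- matrix(positions, 1L, 3L)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must have 3 columns", call. = FALSE)
  if (nrow(positions) != length(elements)) {
    stop("elements and positions disagree in length", call. = FALSE)
  }
  if (length(elements) > 0L && !all(is.finite(positions))) {
    stop("positions must be finite", call. = FALSE)
  }
  check_elements(elements)
  frozen <- rep_len(as.logical(frozen), length(elements))
  structure(
    list(elements = elements, positions = positions, frozen = frozen),
    class = "atomic_config"
  )
}

#' @export
print.atomic_config <- function(x, ...) {
  n <- length(x$elements)
  cat("<atomic_config> ", n, " atom", if (n != 1L) "s", sep = "")
  if (n > 0L) {
    tab <- table(x$elements)
    cat(" (", paste0(names(tab), tab, collapse = " "), ")", sep = "")
    if (any(x$frozen)) cat(", ", sum(x$frozen), " frozen", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.atomic_config <- function(x) length(x$elements)

n_atoms <- function(config) length(config$elements)

#' Extract a sub-configuration
#'
#' @param config an [atomic_config()].
#' @param idx integer or logical index of atoms to keep.
#' @return An `atomic_config` with the selected atoms.
#' @export
subset_config <- function(config, idx) {
  atomic_config(config$elements[idx], config$positions[idx, , drop = FALSE],
                config$frozen[idx])
}

#' Combine two configurations into one simulation box
#'
#' @param a,b [atomic_config()] objects.
#' @return An `atomic_config` holding the atoms of `a` followed by `b`.
#' @export
combine_configs <- function(a, b) {
  atomic_config(c(a$elements, b$elements),
                rbind(a$positions, b$positions),
                c(a$frozen, b$frozen))
}

stopifnot_config <- function(config) {
  if (!inherits(config, "atomic_config")) {
    stop("expected an 'atomic_config' object", call. = FALSE)
  }
  invisible(TRUE)
}
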