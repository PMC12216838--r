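#' Reference set of atomic environments
#'
#' A bank of per-atom descriptor vectors extracted from reference molecules;
#' it defines the chemical space the generator is steered towards. A params
#' fingerprint travels with the bank so descriptors computed with different
#' settings can never be mixed.
#'
#' @param desc matrix of reference descriptor rows.
#' @param labels optional data.frame with one row per reference
#'   (`molecule`, `atom`, `element`).
#' @param params the [descriptor_params()] used to build `desc`.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(desc, labels = NULL, params = descriptor_params()) {
  desc <- as.matrix(desc)
  if (nrow(desc) < 1L) stop("reference set needs at least one row", call. = FALSE)
  if (ncol(desc) != descriptor_dim(params)) {
    stop("descriptor dimension does not match params", call. = FALSE)
  }
  structure(list(desc = unclass(desc), labels = labels, params = params,
                 hash = params_hash(params)),
            class = "reference_set")
}

params_hash <- function(params) {
  paste(params$r_cut, params$r_min, params$n_radial, params$l_max,
        paste(params$channels, collapse = ""), params$ang_delta, sep = "|")
}

ref_matrix <- function(refset) {
  if (inherits(refset, "reference_set")) refset$desc else as.matrix(unclass(refset))
}

check_ref_params <- function(refset, params) {
  if (inherits(refset, "reference_set") &&
      !identical(refset$hash, params_hash(params))) {
    stop("reference set was built with different descriptor parameters",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", nrow(x$desc), " environments (d = ", ncol(x$desc),
      ")", sep = "")
  if (!is.null(x$labels)) {
    cat(" from ", length(unique(x$labels$molecule)), " molecules", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build a reference set from molecules
#'
#' Accepts fixture names, [atomic_config()] objects, or a directory of
#' XYZ files. Hydrogens (and any element outside the channel list) are
#' stripped before descriptor extraction: single-valence elements are
#' excluded from the reference data because they make similarity trivially
#' easy to saturate.
#'
#' @param molecules character vector of fixture names, a directory path
#'   containing `.xyz` files, or a list of [atomic_config()] objects.
#' @param params [descriptor_params()].
#' @return A [reference_set()].
#' @examples
#' build_reference_set(c("ethanol", "acetone"))
#' @export
build_reference_set <- function(molecules, params = descriptor_params()) {
  if (is.character(molecules) && length(molecules) == 1L &&
      dir.exists(molecules)) {
    files <- list.files(molecules, pattern = "\\.xyz$", full.names = TRUE)
    configs <- lapply(files, read_xyz)
    names(configs) <- basename(files)
  } else if (is.character(molecules)) {
    configs <- lapply(molecules, build_fixture, with_hydrogens = FALSE)
    names(configs) <- molecules
  } else {
    configs <- molecules
    if (is.null(names(configs))) names(configs) <- paste0("mol", seq_along(configs))
  }
  rows <- list(); labels <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    keep <- cfg$elements %in% params$channels
    cfg <- subset_config(cfg, keep)
    if (n_atoms(cfg) == 0L) next
    rows[[nm]] <- unclass(compute_descriptors(cfg, params))
    labels[[nm]] <- data.frame(molecule = nm, atom = seq_len(n_atoms(cfg)),
                               element = cfg$elements,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no reference environments found", call. = FALSE)
  reference_set(do.call(rbind, rows), do.call(rbind, labels), params)
}

#' Default fixture reference bank
#'
#' About a dozen small C/N/O molecules covering sp3 and sp2 carbon, aromatic
#' rings, ethers, alcohols, amines, carbonyls and carboxyls. Methane is
#' deliberately absent: its hydrogen-stripped skeleton is a bare atom, and an
#' isolated-atom reference environment rewards fragmentation (a lone atom
#' matches it exactly), the same degeneracy that motivates excluding
#' single-valence elements altogether.
#'
#' @param params [descriptor_params()].
#' @return A [reference_set()].
#' @export
default_reference_set <- function(params = descriptor_params()) {
  build_reference_set(c("ethanol", "methanol", "propane",
                        "isobutane", "dimethyl_ether", "benzene", "pyridine",
                        "furan", "acetone", "acetic_acid", "formic_acid",
                        "formaldehyde", "acetaldehyde", "methylamine"), params)
}

#' Persist / restore a reference set
#'
#' Plain TSV with the descriptor parameters as a JSON header comment;
#' [read_reference_set()] refuses nothing but recomputes the hash, so banks
#' built with different parameters stay incompatible.
#'
#' @param refset a [reference_set()].
#' @param path file path.
#' @return `write_reference_set` invisibly returns `path`;
#'   `read_reference_set` returns a [reference_set()].
#' @export
write_reference_set <- function(refset, path) {
  stopifnot(inherits(refset, "reference_set"))
  p <- refset$params
  hdr <- paste0("# params=", jsonlite::toJSON(
    p[c("r_cut", "r_min", "n_radial", "l_max", "channels", "ang_delta")],
    auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(refset$desc, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# params=")) stop("not a reference-set file", call. = FALSE)
  pl <- jsonlite::fromJSON(sub("^# params=", "", hdr))
  params <- descriptor_params(pl$r_cut, pl$r_min, pl$n_radial, pl$l_max,
                              pl$channels, pl$ang_delta)
  desc <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(desc) <- NULL
  reference_set(desc, params = params)
}
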