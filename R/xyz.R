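#' Read an XYZ or extended-XYZ file
#'
#' Plain XYZ (count line, comment line, `El x y z` rows) and the extended-XYZ
#' dialect are accepted. The frozen-atom mask is recovered either from a
#' per-atom `frozen` column declared in an extended-XYZ `Properties=` comment
#' line, or from a bare `frozen=...` key (comma/space separated 0/1 or T/F
#' flags) on the comment line. Absent both, the mask is all-`FALSE`.
#'
#' @param path path to the file.
#' @return An [atomic_config()].
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L) stop("malformed atom count in ", path, call. = FALSE)
  if (length(lines) < 2L + n) {
    stop("declared atom count (", n, ") exceeds available atom lines in ", path,
         call. = FALSE)
  }
  comment <- if (length(lines) >= 2L) lines[2L] else ""
  body <- lines[seq_len(n) + 2L]
  extra <- lines[-seq_len(2L + n)]
  if (any(nzchar(trimws(extra)))) {
    stop("declared atom count (", n, ") does not match number of atom lines in ",
         path, call. = FALSE)
  }
  if (n == 0L) return(atomic_config(character(0), matrix(numeric(0), 0, 3)))

  tok <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(tok)
  if (any(nfield < 4L)) stop("malformed atom line in ", path, call. = FALSE)
  elements <- vapply(tok, `[[`, "", 1L)
  pos <- t(vapply(tok, function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(!is.finite(pos))) stop("non-numeric coordinates in ", path, call. = FALSE)

  frozen <- rep(FALSE, n)
  props <- regmatches(comment, regexpr("Properties=\\S+", comment))
  if (length(props) == 1L) {
    # extended-XYZ: Properties=species:S:1:pos:R:3:frozen:L:1 style triplets
    fields <- strsplit(sub("^Properties=", "", props), ":")[[1L]]
    if (length(fields) %% 3L == 0L) {
      names_ <- fields[seq(1L, length(fields), by = 3L)]
      counts <- as.integer(fields[seq(3L, length(fields), by = 3L)])
      col <- 0L
      for (k in seq_along(names_)) {
        if (identical(names_[k], "frozen")) {
          vals <- vapply(tok, `[[`, "", col + 1L)
          frozen <- toupper(vals) %in% c("T", "TRUE", "1")
        }
        col <- col + counts[k]
      }
    }
  } else {
    m <- regmatches(comment, regexpr("frozen=\\S+", comment))
    if (length(m) == 1L) {
      flags <- strsplit(sub("^frozen=", "", m), ",")[[1L]]
      if (length(flags) == n) frozen <- toupper(flags) %in% c("T", "TRUE", "1")
    }
  }
  atomic_config(elements, pos, frozen)
}

#' Write an extended-XYZ file
#'
#' The frozen mask is serialized as a per-atom logical column declared in the
#' `Properties=` comment, so [read_xyz()] round-trips (elements, positions,
#' frozen mask) exactly.
#'
#' @param config an [atomic_config()].
#' @param path output path.
#' @param comment optional extra text appended to the comment line.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(config, path, comment = "") {
  stopifnot_config(config)
  n <- n_atoms(config)
  header <- sprintf("Properties=species:S:1:pos:R:3:frozen:L:1%s",
                    if (nzchar(comment)) paste0(" ", comment) else "")
  rows <- character(n)
  for (i in seq_len(n)) {
    rows[i] <- sprintf("%-2s %18.10f %18.10f %18.10f %s",
                       config$elements[i],
                       config$positions[i, 1L], config$positions[i, 2L],
                       config$positions[i, 3L],
                       if (config$frozen[i]) "T" else "F")
  }
  out <- c(as.character(n), header, rows)
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read molecules from an SDF file (optional)
#'
#' Thin wrapper over ChemmineR; only atom symbols and 3D coordinates are
#' used. Hydrogens are kept; strip them with [subset_config()] if needed.
#'
#' @param path path to an SDF file.
#' @return A list of [atomic_config()] objects.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_sdf() requires the ChemmineR package", call. = FALSE)
  }
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfs), function(i) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    symbols <- sub("_.*$", "", rownames(ab))
    atomic_config(symbols, ab[, 1:3, drop = FALSE])
  })
}
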