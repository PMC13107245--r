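#' Read an XYZ coordinate file
#'
#' Standard XYZ: an atom-count line, a free-text comment line, then one
#' `element x y z` record per atom. Topology is not part of the format and is
#' left empty; masses come from the built-in element table.
#'
#' @param path Path to an XYZ file.
#' @return A [toy_system()].
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "a lone manganese ion", "Mn 0 0 0"), f)
#' read_xyz(f)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("XYZ parse error at line 1: empty file")
  count <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(count) || count < 0)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  if (length(lines) < count + 2)
    stop("XYZ parse error: ", count, " atoms declared but only ",
         max(0L, length(lines) - 2L), " records present")
  if (count == 0)
    return(toy_system(character(0), matrix(numeric(0), ncol = 3)))
  elements <- character(count)
  pos <- matrix(NA_real_, count, 3)
  for (i in seq_len(count)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    elements[i] <- tok[1]
    pos[i, ] <- xyz
  }
  toy_system(elements, pos)
}

#' Write an XYZ coordinate file
#'
#' @param system A [toy_system()].
#' @param path Output path.
#' @param comment Comment line (line 2 of the file).
#' @param digits Decimal places for coordinates (>= 6 for lossless
#'   round-tripping at the package's tolerance).
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(system, path, comment = "generated by enzymn",
                      digits = 8) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  .write_xyz_frame(con, system$elements, system$positions, comment, digits)
  invisible(path)
}

.write_xyz_frame <- function(con, elements, positions, comment, digits = 8) {
  writeLines(as.character(length(elements)), con)
  writeLines(comment, con)
  if (length(elements) > 0) {
    writeLines(sprintf("%-3s %.*f %.*f %.*f", elements,
                       digits, positions[, 1], digits, positions[, 2],
                       digits, positions[, 3]), con)
  }
}

#' Write a trajectory as multi-frame XYZ
#'
#' Frames are concatenated XYZ blocks, the convention read by most molecular
#' viewers. The comment line carries the frame time in fs.
#'
#' @param traj An `md_trajectory` (see [run_md()]).
#' @param system The `toy_system` the trajectory belongs to (for element
#'   symbols).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz_frames <- function(traj, system, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    .write_xyz_frame(con, system$elements, traj$positions[f, , , drop = TRUE],
                     sprintf("t = %.3f fs", traj$times[f]))
  }
  invisible(path)
}

#' Read coordinates from a minimal PDB file
#'
#' Parses only ATOM/HETATM records using the PDB v3.3 fixed column widths;
#' every other record type is ignored. The element symbol is taken from
#' columns 77-78 when present, otherwise inferred from the atom-name field
#' (columns 13-16) by stripping digits and using the leading alphabetic part.
#'
#' @param path Path to a PDB file.
#' @return A [toy_system()] with atoms in record order. A file without any
#'   ATOM/HETATM records yields an empty system with a warning.
#' @export
read_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(keep) == 0) {
    warning("no ATOM/HETATM records in ", path, "; returning empty system")
    return(toy_system(character(0), matrix(numeric(0), ncol = 3)))
  }
  lines <- lines[keep]
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  if (anyNA(c(x, y, z)))
    stop("PDB parse error: non-numeric coordinate field in record ",
         which(is.na(x) | is.na(y) | is.na(z))[1])
  elem <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  infer <- elem == ""
  if (any(infer)) {
    guess <- sub("^([0-9]*)([A-Za-z]+).*$", "\\2", name[infer])
    # two-letter symbols arrive upper-cased in PDB names (e.g. "MN")
    elem[infer] <- guess
  }
  elem <- vapply(elem, .normalize_element, character(1))
  toy_system(elem, cbind(x, y, z), labels = name)
}

.normalize_element <- function(e) {
  if (nchar(e) == 0) stop("PDB parse error: cannot determine element symbol")
  e1 <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
  if (e1 %in% names(.ELEMENT_MASSES)) return(e1)
  # atom names like "HG21": try the first letter alone
  e2 <- toupper(substr(e, 1, 1))
  if (e2 %in% names(.ELEMENT_MASSES)) return(e2)
  e1
}
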