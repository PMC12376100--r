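# Readers and writers for the plain-text formats the tool touches.
#
# Files declare their units: PES CSVs via reader arguments (or '#' header
# comments for humans), parameter tables via explicit unit columns in the
# call.  All writes are atomic (write to a temp file in the destination
# directory, then rename).

#' Atomic CSV write
#'
#' @param x Data.frame.
#' @param path Destination.
#' @param ... Passed to [utils::write.csv()].
#' @return `path`, invisibly.
#' @export
write_csv_atomic <- function(x, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(x, tmp, row.names = FALSE, ...)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

#' Read a potential-energy grid from CSV
#'
#' Two-column files (`Q`, `V`) give a [potential_grid()]; files with
#' additional component columns (e.g. `Q`, `V_ISO`, `ELEC`, `PAULI`,
#' `DISP`, `POL`, `CT`) give a [decomposed_potential()] whose isolated
#' curve is the `V_ISO` column.  Lines starting with `#` are ignored.
#'
#' @param path CSV file.
#' @param reduced_mass Reduced mass, amu.
#' @param coordinate_unit Unit of the `Q` column.
#' @param energy_unit Unit of the energy columns (`"hartree"`,
#'   `"kjmol"`, `"kcalmol"` or `"cm-1"`).
#' @return A [potential_grid()] or [decomposed_potential()].
#' @export
read_pes_csv <- function(path, reduced_mass,
                         coordinate_unit = c("angstrom", "bohr"),
                         energy_unit = "hartree") {
  coordinate_unit <- match.arg(coordinate_unit)
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("PES file needs at least columns Q and V: ", path)
  qcol <- names(df)[1L]
  conv <- function(x) .energy_to_hartree(x, energy_unit)
  if (ncol(df) == 2L) {
    potential_grid(df[[qcol]], conv(df[[2L]]), reduced_mass,
                   coordinate_unit = coordinate_unit)
  } else {
    iso <- if ("V_ISO" %in% names(df)) "V_ISO" else names(df)[2L]
    grid <- potential_grid(df[[qcol]], conv(df[[iso]]), reduced_mass,
                           coordinate_unit = coordinate_unit)
    comp_cols <- setdiff(names(df), c(qcol, iso))
    decomposed_potential(grid, lapply(stats::setNames(comp_cols, comp_cols),
                                      function(nm) conv(df[[nm]])))
  }
}

#' Read a per-atom force-field parameter table
#'
#' CSV or JSON (by extension) with fields `name`, `charge`, `sigma`,
#' `epsilon`, `role`.  Every atom of a structure must match a row by
#' name.
#'
#' @param path CSV or JSON file.
#' @param sigma_unit,epsilon_unit Units of the stored parameters;
#'   converted to the internal angstrom / hartree convention.
#' @return Data.frame with columns `name`, `charge` (e), `sigma`
#'   (angstrom), `epsilon` (hartree), `role`.
#' @export
read_parameter_table <- function(path, sigma_unit = c("angstrom", "nm"),
                                 epsilon_unit = c("kjmol", "hartree",
                                                  "kcalmol")) {
  sigma_unit <- match.arg(sigma_unit)
  epsilon_unit <- match.arg(epsilon_unit)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, comment.char = "#")
  }
  need <- c("name", "charge", "sigma", "epsilon", "role")
  missing_ <- setdiff(need, names(tab))
  if (length(missing_) > 0L)
    stop("parameter table lacks column(s): ",
         paste(missing_, collapse = ", "))
  for (cl in c("charge", "sigma", "epsilon")) {
    bad <- which(!is.finite(as.numeric(tab[[cl]])))
    if (length(bad) > 0L)
      stop("missing or non-numeric ", cl, " for atom '",
           tab$name[bad[1L]], "'")
  }
  tab$sigma <- .length_to_angstrom(as.numeric(tab$sigma), sigma_unit)
  tab$epsilon <- .energy_to_hartree(as.numeric(tab$epsilon), epsilon_unit)
  tab$charge <- as.numeric(tab$charge)
  tab[need]
}

#' Read a multi-frame XYZ trajectory
#'
#' Plain XYZ: per frame an atom count line, a comment line, then
#' `name x y z` rows (angstrom).
#'
#' @param path XYZ file.
#' @return List of frames, each a list with `name` and `coordinates`.
#' @export
read_frames_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L)
      stop("malformed XYZ atom-count line ", i, " in ", path)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i, " in ", path)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    frames[[length(frames) + 1L]] <- list(
      name = vapply(rows, `[[`, character(1L), 1L),
      coordinates = matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))),
                           ncol = 3L, byrow = TRUE))
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

#' Write frames as multi-frame XYZ
#'
#' @param frames List of [snapshot_frame()]s.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_frames_xyz <- function(frames, path) {
  if (inherits(frames, "snapshot_frame")) frames <- list(frames)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "w")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(c(as.character(fr$n_atoms),
                 sprintf("frame %d box %s angstrom", k,
                         paste(format(fr$box), collapse = " "))), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", fr$name,
                       fr$coordinates[, 1L], fr$coordinates[, 2L],
                       fr$coordinates[, 3L]), con)
  }
  close(con)
  on.exit(NULL)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

#' Assemble snapshot frames from coordinates and a parameter table
#'
#' Each atom is matched to a parameter row by name; a missing row is an
#' error naming the atom.  Validates that the result has exactly one
#' terminal hydrogen and one of each triple-bond carbon.
#'
#' @param coords_frames List of frames from [read_frames_xyz()] (or any
#'   list of lists with `name` and `coordinates`).
#' @param params Parameter table from [read_parameter_table()].
#' @param box Box edge lengths, angstrom.
#' @return List of [snapshot_frame()]s.
#' @export
build_frames <- function(coords_frames, params, box) {
  lapply(coords_frames, function(fr) {
    idx <- match(fr$name, params$name)
    if (anyNA(idx))
      stop("no parameter row for atom '", fr$name[which(is.na(idx))[1L]], "'")
    snapshot_frame(fr$coordinates, params$charge[idx], params$sigma[idx],
                   params$epsilon[idx], params$role[idx], box,
                   name = fr$name)
  })
}

#' Read a PDB structure as a coordinate frame
#'
#' Thin wrapper over `bio3d::read.pdb()` returning the `name` +
#' `coordinates` layout of [read_frames_xyz()] (PDB serials are 1-based;
#' atoms are returned in file order).
#'
#' @param path PDB file.
#' @return One-element list of frames, as in [read_frames_xyz()].
#' @export
read_structure_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  list(list(name = pdb$atom$elety,
            coordinates = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)))
}
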