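#' Read a protein crystal structure
#'
#' Parses a PDB or mmCIF file into a `protein_structure`: a lightweight
#' container holding the resolution (from the `REMARK 2` record or the
#' mmCIF refinement category) and a tibble with one row per ATOM/HETATM
#' record. Nothing is dropped or merged at parse time: alternate locations,
#' waters and partial occupancies are all retained so that downstream
#' selection rules are explicit and testable.
#'
#' @param path path to the structure file.
#' @param dialect `"pdb"` (fixed-column) or `"mmcif"`.
#' @param structure_id identifier recorded in the object; defaults to the
#'   file name without extension.
#' @return A `protein_structure`: list with `structure_id`, `resolution`
#'   (Angstrom, `NA` when the file states none) and `atoms`, a tibble with
#'   columns `eleno`, `name`, `altloc`, `resname`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `occupancy`, `element`, `is_hetero`.
#' @examples
#' pdb <- build_hb_toy(hb_toy_geometries())
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, f)
#' read_structure(f)
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"),
                           structure_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.insert = FALSE,
                      rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = FALSE, rm.insert = FALSE,
                      rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", dialect, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("failed to parse ", dialect, " file '", path,
         "': no ATOM/HETATM records found", call. = FALSE)
  }
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back on the leading letter(s) of the atom name
    element[missing_el] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                               at$elety[missing_el])
  }
  atoms <- tibble::tibble(
    eleno = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = toupper(element),
    is_hetero = at$type == "HETATM"
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  resolution <- read_resolution(path, dialect)
  new_protein_structure(structure_id, resolution, atoms)
}

new_protein_structure <- function(structure_id, resolution, atoms) {
  structure(
    list(structure_id = structure_id, resolution = resolution, atoms = atoms),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$structure_id, "\n", sep = "")
  cat("  resolution: ",
      if (is.na(x$resolution)) "absent" else paste0(x$resolution, " A"),
      "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), " (",
      sum(x$atoms$is_hetero), " HETATM)\n", sep = "")
  invisible(x)
}

# Resolution lives in header records that coordinate parsers ignore;
# pull it out of the raw text.
read_resolution <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  if (dialect == "pdb") {
    rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rem) == 0L) return(NA_real_)
    tail_txt <- sub("^REMARK   2 RESOLUTION\\.", "", rem[1])
    m <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(m) == 0L) return(NA_real_)
    as.numeric(m)
  } else {
    for (key in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
      hit <- grep(key, lines, fixed = TRUE, value = TRUE)
      if (length(hit) > 0L) {
        m <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*$", trimws(hit[1])))
        if (length(m) > 0L) return(as.numeric(m))
      }
    }
    NA_real_
  }
}

#' Selection rules for atoms and structures
#'
#' Bundles the quality filters applied before hydrogen-bond feature
#' extraction: resolution cutoff (strictly better than, i.e. numerically
#' smaller), minimum occupancy, the allowed element set, solvent/hetero
#' exclusion and the requirement that hydrogens be present at all.
#'
#' @param max_resolution keep structures with resolution strictly below this
#'   value (Angstrom).
#' @param min_occupancy keep atoms with occupancy at or above this fraction.
#' @param require_hydrogens reject structures without any H atom.
#' @param exclude_solvent drop HETATM records and solvent residues.
#' @param elements allowed element symbols; `NULL` admits all.
#' @param solvent_residues residue names treated as solvent/small molecules.
#' @return A `selection_criteria` object.
#' @export
selection_criteria <- function(max_resolution = 1.2, min_occupancy = 0.95,
                               require_hydrogens = TRUE,
                               exclude_solvent = TRUE,
                               elements = c("N", "O", "H"),
                               solvent_residues = c("HOH", "DOD", "WAT")) {
  stopifnot(max_resolution > 0, min_occupancy >= 0, min_occupancy <= 1)
  structure(
    list(max_resolution = max_resolution, min_occupancy = min_occupancy,
         require_hydrogens = require_hydrogens,
         exclude_solvent = exclude_solvent,
         elements = if (is.null(elements)) NULL else toupper(elements),
         solvent_residues = toupper(solvent_residues)),
    class = "selection_criteria"
  )
}

#' Select atoms passing element, occupancy and solvent filters
#'
#' @param structure a `protein_structure` (or its `atoms` tibble).
#' @param criteria a [selection_criteria()] object.
#' @return Tibble of the passing atom records, in file order.
#' @export
select_atoms <- function(structure, criteria = selection_criteria()) {
  atoms <- if (inherits(structure, "protein_structure")) structure$atoms else structure
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(criteria$elements)) {
    keep <- keep & atoms$element %in% criteria$elements
  }
  keep <- keep & atoms$occupancy >= criteria$min_occupancy
  if (criteria$exclude_solvent) {
    keep <- keep & !atoms$is_hetero &
      !(toupper(atoms$resname) %in% criteria$solvent_residues)
  }
  atoms[keep, , drop = FALSE]
}

#' Filter structures on resolution and hydrogen content
#'
#' Keeps structures whose resolution is strictly better (numerically
#' smaller) than `criteria$max_resolution`. Structures with no stated
#' resolution are rejected, as are structures without hydrogens when
#' `require_hydrogens` is set. Rejections are reported via [message()].
#'
#' @param structures list of `protein_structure` objects.
#' @param criteria a [selection_criteria()] object.
#' @return The surviving structures (a list).
#' @export
filter_structures <- function(structures, criteria = selection_criteria()) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  keep <- vapply(structures, function(s) {
    if (is.na(s$resolution)) {
      message("rejecting ", s$structure_id, ": no stated resolution")
      return(FALSE)
    }
    if (s$resolution >= criteria$max_resolution) {
      message("rejecting ", s$structure_id, ": resolution ", s$resolution,
              " A not better than ", criteria$max_resolution, " A")
      return(FALSE)
    }
    if (criteria$require_hydrogens && !any(s$atoms$element == "H")) {
      message("rejecting ", s$structure_id, ": no hydrogen atoms")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  structures[keep]
}
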