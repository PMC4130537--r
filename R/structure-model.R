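#' Structure model: an ordered table of atoms
#'
#' The atom table carries `serial`, `name`, `element`, `residue_name`,
#' `residue_seq`, `chain`, Cartesian `x`, `y`, `z` (Angstrom) and, when
#' available, `charge` (e), `epsilon` (kcal/mol) and `rmin_half` (Angstrom)
#' nonbonded parameters.
#'
#' @param atoms A data.frame with at least the columns listed above
#'   (parameter columns optional).
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms) {
  need <- c("serial", "name", "element", "residue_name", "residue_seq",
            "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a model")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (any(atoms$element == "")) stop("empty element symbols")
  structure(list(atoms = as.data.frame(atoms)), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

coords_of <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

#' Trajectory: frames of coordinates over a fixed topology
#'
#' @param topology A [structure_model()] giving atom identities.
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   x1,y1,z1,x2,... order.
#' @return A `trajectory` object.
#' @export
trajectory <- function(topology, xyz) {
  stopifnot(inherits(topology, "structure_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("frame width (", ncol(xyz), ") does not match topology (",
         3L * nrow(topology$atoms), " coordinates)")
  structure(list(topology = topology, xyz = xyz), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$xyz), " frames x ",
      nrow(x$topology$atoms), " atoms\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

frame_coords <- function(traj, i)
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)

bio3d_to_model <- function(pdb) {
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(trimws(el) == ""))
    el <- substr(trimws(at$elety), 1, 1)
  el <- trimws(el)
  el[el == ""] <- substr(trimws(at$elety[el == ""]), 1, 1)
  structure_model(data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = el,
    residue_name = trimws(at$resid),
    residue_seq = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Read a structure or multi-MODEL trajectory from PDB
#'
#' Fixed-width ATOM/HETATM parsing is delegated to `bio3d::read.pdb`;
#' when alternate locations are present the highest-occupancy record is
#' kept. Partial charges and Lennard-Jones parameters are not part of PDB
#' and must be attached afterwards with [assign_nonbonded_params()].
#'
#' @param path Path to a PDB file.
#' @return `read_structure()` returns a [structure_model()];
#'   `read_trajectory()` a [trajectory()] whose topology is the first
#'   MODEL.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE, rm.alt = TRUE)
  bio3d_to_model(pdb)
}

#' @rdname read_structure
#' @export
read_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = TRUE)
  model <- bio3d_to_model(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(model, unclass(xyz))
}

#' Write a structure (or trajectory as multi-MODEL) to PDB
#'
#' @param model A [structure_model()] (or [trajectory()] for
#'   `write_trajectory`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords_of(model))),
                   resno = at$residue_seq, resid = at$residue_name,
                   eleno = at$serial, elety = at$name, chain = at$chain,
                   elesy = at$element)
  invisible(path)
}

#' @rdname write_structure
#' @param traj A [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    for (i in seq_len(nrow(at))) {
      nm <- at$name[i]
      nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        at$serial[i], nm, at$residue_name[i], at$chain[i], at$residue_seq[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, at$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms from a structure model
#'
#' Mini-language: `"chain"`, `"chain:res_lo-res_hi"` or
#' `"chain:res_lo-res_hi:NAME1,NAME2"`; an empty field matches everything,
#' so `"::CA"` selects all CA atoms. Alternatively pass explicit filters
#' via the named arguments.
#'
#' @param model A [structure_model()].
#' @param spec Selection string, or `NULL` to use the named filters.
#' @param chain,residues,atom_names Explicit filters (character / integer /
#'   character).
#' @return A [structure_model()] containing the matching atoms.
#' @examples
#' # select_atoms(model, "H:1-10:CA,N,C")
#' @export
select_atoms <- function(model, spec = NULL, chain = NULL, residues = NULL,
                         atom_names = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (!is.null(spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 1 && nzchar(parts[1])) chain <- parts[1]
    if (length(parts) >= 2 && nzchar(parts[2])) {
      rr <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      residues <- if (length(rr) == 2) seq(rr[1], rr[2]) else rr
    }
    if (length(parts) >= 3 && nzchar(parts[3]))
      atom_names <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
  }
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(residues)) keep <- keep & at$residue_seq %in% residues
  if (!is.null(atom_names)) keep <- keep & at$name %in% atom_names
  out <- model
  out$atoms <- at[keep, , drop = FALSE]
  out
}

#' Attach partial charges and Lennard-Jones parameters to a model
#'
#' Parameters are looked up by atom class in a TSV table with columns
#' `atom_class`, `epsilon` (kcal/mol), `rmin_half` (Angstrom) and
#' `default_charge` (e). The atom class is the element symbol by default.
#' A minimal element-keyed table ships with the package
#' (`system.file("extdata", "nonbonded_params.tsv", package = "somaticRS")`);
#' it is a generic, editable parameter set, not a reproduction of any
#' commercial force field.
#'
#' @param model A [structure_model()].
#' @param params Parameter data.frame or TSV path; default the bundled
#'   table.
#' @param keep_existing_charges Keep a `charge` column already present on
#'   the model instead of the table's default (default `TRUE`).
#' @return The model with `charge`, `epsilon`, `rmin_half` columns filled.
#' @export
assign_nonbonded_params <- function(model, params = NULL,
                                    keep_existing_charges = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(params))
    params <- system.file("extdata", "nonbonded_params.tsv",
                          package = "somaticRS")
  if (is.character(params))
    params <- utils::read.delim(params, stringsAsFactors = FALSE)
  at <- model$atoms
  idx <- match(at$element, params$atom_class)
  if (anyNA(idx))
    stop("no nonbonded parameters for atom class(es): ",
         paste(unique(at$element[is.na(idx)]), collapse = ", "))
  at$epsilon <- params$epsilon[idx]
  at$rmin_half <- params$rmin_half[idx]
  if (!("charge" %in% names(at)) || !keep_existing_charges)
    at$charge <- params$default_charge[idx]
  model$atoms <- at
  model
}
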