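cross_distances <- function(a_xyz, b_xyz) {
  # n_a x n_b Euclidean distance matrix
  a2 <- rowSums(a_xyz^2); b2 <- rowSums(b_xyz^2)
  d2 <- outer(a2, b2, "+") - 2 * a_xyz %*% t(b_xyz)
  sqrt(pmax(d2, 0))
}

#' Van der Waals contacts between two selections
#'
#' Lists all inter-selection atom pairs within the distance cutoff
#' (boundary inclusive). Hydrogens are excluded by default, so contacts are
#' heavy-atom contacts.
#'
#' @param sel_a,sel_b Disjoint [structure_model()] selections.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param include_hydrogens Count hydrogen atoms too (default `FALSE`).
#' @return Data.frame with one row per contact: serials, names, residues of
#'   both partners and `distance`, sorted by distance.
#' @export
vdw_contacts <- function(sel_a, sel_b, cutoff = 4.0,
                         include_hydrogens = FALSE) {
  stopifnot(inherits(sel_a, "structure_model"),
            inherits(sel_b, "structure_model"))
  a <- sel_a$atoms; b <- sel_b$atoms
  if (!include_hydrogens) {
    a <- a[a$element != "H", , drop = FALSE]
    b <- b[b$element != "H", , drop = FALSE]
  }
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty selection")
  d <- cross_distances(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  out <- data.frame(
    serial_a = a$serial[hit[, 1]], name_a = a$name[hit[, 1]],
    residue_a = paste0(a$residue_name[hit[, 1]], a$residue_seq[hit[, 1]]),
    chain_a = a$chain[hit[, 1]],
    serial_b = b$serial[hit[, 2]], name_b = b$name[hit[, 2]],
    residue_b = paste0(b$residue_name[hit[, 2]], b$residue_seq[hit[, 2]]),
    chain_b = b$chain[hit[, 2]],
    distance = d[hit],
    stringsAsFactors = FALSE)
  out[order(out$distance, out$serial_a, out$serial_b), , drop = FALSE]
}

# donor/acceptor typing by residue + atom name; N and O heavy atoms.
# Backbone N donates, backbone O accepts; side-chain and sugar oxygens
# frequently do both (hydroxyls), as do histidine/tryptophan ring nitrogens
# depending on protonation -- unknown names fall back to element-based
# typing (N: donor, O: donor+acceptor) with a log attribute.
hbond_type <- function(residue_name, atom_name, element) {
  donors <- c("N", "NE", "NH1", "NH2", "ND1", "NE2", "ND2", "NZ", "NE1",
              "OG", "OG1", "OH", "SG", "OW",
              "O2", "O3", "O4", "O5", "O6", "O2'", "O3'", "O4'", "O5'")
  acceptors <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                 "ND1", "NE2", "OW",
                 "O2", "O3", "O4", "O5", "O6", "O2'", "O3'", "O4'", "O5'")
  d <- atom_name %in% donors
  a <- atom_name %in% acceptors
  known <- d | a
  fallback <- !known & element %in% c("N", "O")
  d[fallback] <- TRUE
  a[fallback] <- a[fallback] | element[fallback] == "O"
  list(donor = d, acceptor = a, unknown = !known & !fallback)
}

vec_angle <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Intermolecular hydrogen bonds between two selections
#'
#' A bond is a donor/acceptor heavy-atom pair with D...A distance at most
#' `d_max`. When the donor has an explicit covalent hydrogen (an H atom
#' within 1.25 Angstrom in the same selection), the D-H...A angle must also
#' be at least `angle_min`; with no hydrogens present the criterion is
#' distance-only and the result carries attribute `mode =
#' "distance_only"`.
#'
#' @param sel_a,sel_b [structure_model()] selections (both directions of
#'   donation are examined).
#' @param d_max Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_min Minimum D-H...A angle in degrees.
#' @return Data.frame of bonds (`donor_serial`, `donor`, `acceptor_serial`,
#'   `acceptor`, `distance`, `angle` — `NA` in distance-only mode), with
#'   attribute `mode`.
#' @export
hydrogen_bonds <- function(sel_a, sel_b, d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(sel_a, "structure_model"),
            inherits(sel_b, "structure_model"))
  bonds <- list()
  mode <- "distance_only"
  for (dir in 1:2) {
    don_m <- if (dir == 1) sel_a else sel_b
    acc_m <- if (dir == 1) sel_b else sel_a
    dat <- don_m$atoms; aat <- acc_m$atoms
    dt <- hbond_type(dat$residue_name, dat$name, dat$element)
    at_ <- hbond_type(aat$residue_name, aat$name, aat$element)
    don <- dat[dt$donor, , drop = FALSE]
    acc <- aat[at_$acceptor, , drop = FALSE]
    if (nrow(don) == 0 || nrow(acc) == 0) next
    hyd <- dat[dat$element == "H", , drop = FALSE]
    d <- cross_distances(as.matrix(don[, c("x", "y", "z")]),
                         as.matrix(acc[, c("x", "y", "z")]))
    hit <- which(d <= d_max, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      i <- hit[k, 1]; j <- hit[k, 2]
      ang <- NA_real_
      if (nrow(hyd) > 0) {
        dh <- cross_distances(matrix(unlist(don[i, c("x", "y", "z")]), 1),
                              as.matrix(hyd[, c("x", "y", "z")]))
        hsel <- which(dh <= 1.25)
        if (length(hsel) > 0) {
          mode <- "angle_checked"
          angs <- vapply(hsel, function(h) {
            hv <- unlist(hyd[h, c("x", "y", "z")])
            vec_angle(unlist(don[i, c("x", "y", "z")]) - hv,
                      unlist(acc[j, c("x", "y", "z")]) - hv)
          }, numeric(1))
          ang <- max(angs)
          if (ang < angle_min) next
        }
      }
      bonds[[length(bonds) + 1L]] <- data.frame(
        donor_serial = don$serial[i],
        donor = paste0(don$residue_name[i], don$residue_seq[i], ":",
                       don$name[i]),
        acceptor_serial = acc$serial[j],
        acceptor = paste0(acc$residue_name[j], acc$residue_seq[j], ":",
                          acc$name[j]),
        distance = d[i, j], angle = ang, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(donor_serial = integer(), donor = character(),
               acceptor_serial = integer(), acceptor = character(),
               distance = numeric(), angle = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

COULOMB_K <- 332.0637  # kcal * Angstrom / (mol * e^2)

#' Nonbonded interaction energy between two selections
#'
#' Pairwise inter-selection sum within a spherical cutoff (hard
#' truncation, no switching): electrostatic `332.0637 q_i q_j / (eps r)`
#' and Lennard-Jones `eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
#' Lorentz-Berthelot-style combination `eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = rmin_half_i + rmin_half_j`. Units: kcal/mol, e, Angstrom.
#'
#' @param sel_a,sel_b [structure_model()] selections carrying `charge`,
#'   `epsilon`, `rmin_half` columns (see [assign_nonbonded_params()]).
#' @param cutoff Nonbonded cutoff in Angstrom (default 14.0).
#' @param dielectric Relative dielectric constant (default 1, in vacuo).
#' @param min_distance Pairs closer than this (Angstrom) raise an error to
#'   keep energies finite (default 0.1).
#' @return An `energy_decomposition` list: `total`, `vdw`,
#'   `electrostatic` (kcal/mol), with `total = vdw + electrostatic`.
#' @export
interaction_energy <- function(sel_a, sel_b, cutoff = 14.0, dielectric = 1.0,
                               min_distance = 0.1) {
  stopifnot(inherits(sel_a, "structure_model"),
            inherits(sel_b, "structure_model"))
  a <- sel_a$atoms; b <- sel_b$atoms
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty selection")
  for (col in c("charge", "epsilon", "rmin_half")) {
    for (nm in list(list(a, "sel_a"), list(b, "sel_b"))) {
      at <- nm[[1]]
      if (!(col %in% names(at)) || anyNA(at[[col]]))
        stop("missing '", col, "' for atoms in ", nm[[2]], ": ",
             paste(utils::head(at$serial[
               if (col %in% names(at)) is.na(at[[col]]) else TRUE], 10),
               collapse = ", "),
             " (run assign_nonbonded_params() first)")
    }
  }
  d <- cross_distances(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  if (any(d < min_distance))
    stop("atom pair(s) closer than ", min_distance, " Angstrom")
  within <- d <= cutoff
  qq <- outer(a$charge, b$charge)
  elec <- sum(COULOMB_K * qq[within] / (dielectric * d[within]))
  epsij <- sqrt(outer(a$epsilon, b$epsilon))
  rminij <- outer(a$rmin_half, b$rmin_half, "+")
  sr <- (rminij[within] / d[within])
  vdw <- sum(epsij[within] * (sr^12 - 2 * sr^6))
  structure(list(total = elec + vdw, vdw = vdw, electrostatic = elec),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf(
    "interaction energy (kcal/mol): total %.3f = vdw %.3f + elec %.3f\n",
    x$total, x$vdw, x$electrostatic))
  invisible(x)
}

#' Per-residue decomposition of the interaction energy
#'
#' Partitions [interaction_energy()] by residue of the first selection;
#' the per-residue terms sum to the whole-selection decomposition.
#'
#' @inheritParams interaction_energy
#' @return Data.frame with `chain`, `residue_seq`, `residue_name`, `total`,
#'   `vdw`, `electrostatic` (kcal/mol).
#' @export
per_residue_energy <- function(sel_a, sel_b, cutoff = 14.0, dielectric = 1.0,
                               min_distance = 0.1) {
  stopifnot(inherits(sel_a, "structure_model"))
  key <- paste(sel_a$atoms$chain, sel_a$atoms$residue_seq)
  rows <- lapply(unique(key), function(k) {
    sub <- sel_a
    sub$atoms <- sel_a$atoms[key == k, , drop = FALSE]
    e <- interaction_energy(sub, sel_b, cutoff, dielectric, min_distance)
    data.frame(chain = sub$atoms$chain[1],
               residue_seq = sub$atoms$residue_seq[1],
               residue_name = sub$atoms$residue_name[1],
               total = e$total, vdw = e$vdw, electrostatic = e$electrostatic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Kabsch: optimal rotation of x onto y (both n x 3, centred)
kabsch_rotation <- function(x, y) {
  s <- svd(t(x) %*% y)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

superpose_coords <- function(mobile, ref) {
  mc <- colMeans(mobile); rc <- colMeans(ref)
  xm <- sweep(mobile, 2, mc); xr <- sweep(ref, 2, rc)
  rot <- kabsch_rotation(xm, xr)
  sweep(xm %*% t(rot), 2, rc, "+")
}

#' Root-mean-square deviation between two congruent coordinate sets
#'
#' With `superpose = TRUE` (default) the mobile set is first fitted onto
#' the reference by least-squares (Kabsch) superposition, so rigid motions
#' give zero deviation.
#'
#' @param coords_ref,coords_alt Numeric `n x 3` matrices (or
#'   [structure_model()]s) with matched atom order.
#' @param superpose Optimally superpose before measuring (default `TRUE`;
#'   needs >= 3 atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_ref, coords_alt, superpose = TRUE) {
  if (inherits(coords_ref, "structure_model")) coords_ref <- coords_of(coords_ref)
  if (inherits(coords_alt, "structure_model")) coords_alt <- coords_of(coords_alt)
  coords_ref <- as.matrix(coords_ref); coords_alt <- as.matrix(coords_alt)
  if (!all(dim(coords_ref) == dim(coords_alt)) || ncol(coords_ref) != 3)
    stop("coordinate sets must be congruent n x 3 matrices")
  if (superpose) {
    if (nrow(coords_ref) < 3)
      stop("superposition needs at least 3 atoms")
    coords_alt <- superpose_coords(coords_alt, coords_ref)
  }
  sqrt(mean(rowSums((coords_ref - coords_alt)^2)))
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' Frames are superposed (on `fit_selection`, default all atoms) onto an
#' iteratively refined average structure; the RMSF of atom i is the RMS of
#' its displacement from its average position across frames.
#'
#' @param traj A [trajectory()].
#' @param selection Optional atom indices to report (default all).
#' @param fit_selection Optional atom indices used for the superposition
#'   (e.g. backbone); default all atoms.
#' @param n_iter Average-structure refinement passes (default 3).
#' @return Numeric vector of per-atom RMSF (Angstrom) for `selection`.
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL, n_iter = 3) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  na <- nrow(traj$topology$atoms)
  if (is.null(selection)) selection <- seq_len(na)
  if (is.null(fit_selection)) fit_selection <- seq_len(na)
  frames <- lapply(seq_len(nf), function(i) frame_coords(traj, i))
  if (nf < 2) {
    warning("single-frame trajectory: RMSF is identically zero")
    return(stats::setNames(numeric(length(selection)),
                           traj$topology$atoms$name[selection]))
  }
  avg <- frames[[1]]
  for (it in seq_len(n_iter)) {
    fitted <- lapply(frames, function(fr) {
      # fit on fit_selection, apply the rigid transform to all atoms
      mc <- colMeans(fr[fit_selection, , drop = FALSE])
      rc <- colMeans(avg[fit_selection, , drop = FALSE])
      rot <- kabsch_rotation(
        sweep(fr[fit_selection, , drop = FALSE], 2, mc),
        sweep(avg[fit_selection, , drop = FALSE], 2, rc))
      sweep(sweep(fr, 2, mc) %*% t(rot), 2, rc, "+")
    })
    avg <- Reduce("+", fitted) / nf
  }
  disp2 <- Reduce("+", lapply(fitted, function(fr) rowSums((fr - avg)^2))) / nf
  stats::setNames(sqrt(disp2[selection]),
                  traj$topology$atoms$name[selection])
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention (a clockwise far-bond rotation viewed along the
#' central bond is positive), degrees in (-180, 180]. The angle is
#' invariant under full reversal of the atom order and negates under
#' mirror reflection of the coordinates.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi angles of a chain
#'
#' Residues missing a neighbour (chain termini) have the undefined angle
#' reported as `NA`.
#'
#' @param model A [structure_model()] with backbone atoms N, CA, C.
#' @param chain Chain identifier.
#' @return Data.frame with `residue_seq`, `residue_name`, `phi`, `psi`
#'   (degrees) and `code` (see [ramachandran_code()]).
#' @export
phi_psi <- function(model, chain) {
  bb <- select_atoms(model, chain = chain, atom_names = c("N", "CA", "C"))$atoms
  res <- unique(bb$residue_seq)
  res <- res[order(res)]
  get <- function(r, nm) {
    row <- bb[bb$residue_seq == r & bb$name == nm, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    unlist(row[1, c("x", "y", "z")])
  }
  out <- lapply(res, function(r) {
    prevC <- get(r - 1, "C"); nextN <- get(r + 1, "N")
    N <- get(r, "N"); CA <- get(r, "CA"); C <- get(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) return(NULL)
    phi <- if (is.null(prevC)) NA_real_ else dihedral_angle(prevC, N, CA, C)
    psi <- if (is.null(nextN)) NA_real_ else dihedral_angle(N, CA, C, nextN)
    data.frame(residue_seq = r,
               residue_name = bb$residue_name[bb$residue_seq == r][1],
               phi = phi, psi = psi,
               code = ramachandran_code(phi, psi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ramachandran quadrant code of a phi/psi pair
#'
#' Coarse conformational coding used to describe CDR-H3 take-off geometry:
#' `a` = alpha region (phi <= 0, -120 < psi <= 50), `b` = beta region
#' (phi <= 0, psi > 50 or psi <= -120), `l` = left-handed alpha (phi > 0,
#' -120 < psi <= 50), `e` = extended positive-phi region (phi > 0
#' otherwise). Boundaries are configurable; residues with an undefined
#' angle code as `NA`.
#'
#' @param phi,psi Angles in degrees.
#' @param psi_lo,psi_hi The psi band separating the helical from the
#'   extended regions (defaults -120 and 50).
#' @return Character vector of codes `a`, `b`, `l`, `e` (or `NA`).
#' @examples
#' ramachandran_code(-57, -47)  # "a"
#' ramachandran_code(60, 40)    # "l"
#' @export
ramachandran_code <- function(phi, psi, psi_lo = -120, psi_hi = 50) {
  helical <- psi > psi_lo & psi <= psi_hi
  out <- ifelse(phi <= 0,
                ifelse(helical, "a", "b"),
                ifelse(helical, "l", "e"))
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

#' CDR-H3 take-off code over a residue window
#'
#' Concatenates the Ramachandran codes of the given residues (typically the
#' three base positions of the loop) and flags the kinked-plus-bulge
#' candidate pattern `bab`, the code combination characteristic of a K+
#' take-off geometry. This is a heuristic descriptor of the loop base, not
#' a full H3 classification.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @param residues Integer residue numbers of the take-off window.
#' @return List with `code` (string), `per_residue` (the [phi_psi()] rows)
#'   and `kinked_plus_candidate` (logical: code contains `"bab"`).
#' @export
takeoff_code <- function(model, chain, residues) {
  pp <- phi_psi(model, chain)
  pp <- pp[pp$residue_seq %in% residues, , drop = FALSE]
  code <- paste(pp$code, collapse = "")
  list(code = code, per_residue = pp,
       kinked_plus_candidate = grepl("bab", code, fixed = TRUE))
}
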