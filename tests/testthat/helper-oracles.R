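# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through seqinr, stratified
# statistics through stats::mantelhaen.test or hand-written formulas, and
# geometry through brute-force double loops.

# codon -> amino acid via seqinr (independent of Biostrings::GENETIC_CODE)
oracle_translate <- function(codon) {
  vapply(codon, function(cd)
    seqinr::translate(strsplit(tolower(cd), "")[[1]]), character(1),
    USE.NAMES = FALSE)
}

oracle_rs <- function(codon_from, codon_to) {
  ifelse(oracle_translate(codon_from) == oracle_translate(codon_to), "S", "R")
}

# exhaustive single-substitution R/S enumeration, naive double loop
oracle_inherent_rs <- function(nts) {
  cods <- substring(nts, seq(1, nchar(nts), 3), seq(3, nchar(nts), 3))
  r <- 0; s <- 0
  for (cod in cods) {
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cod, p, p)) next
        alt <- cod; substr(alt, p, p) <- b
        if (oracle_rs(cod, alt) == "R") r <- r + 1 else s <- s + 1
      }
    }
  }
  c(r = r, s = s)
}

# stratified table -> 2x2xK array for stats::mantelhaen.test
as_mh_array <- function(t) {
  arr <- array(0, c(2, 2, nrow(t)))
  for (i in seq_len(nrow(t)))
    arr[, , i] <- matrix(c(t$a[i], t$c[i], t$b[i], t$d[i]), 2)
  arr
}

# Breslow-Day by an independent numeric route: root-find the expected
# a-cell with uniroot instead of the quadratic formula
oracle_breslow_day <- function(t, psi) {
  stat <- 0
  for (i in seq_len(nrow(t))) {
    n <- t$a[i] + t$b[i] + t$c[i] + t$d[i]
    r1 <- t$a[i] + t$b[i]; c1 <- t$a[i] + t$c[i]
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    f <- function(x) x * (n - r1 - c1 + x) - psi * (r1 - x) * (c1 - x)
    a_exp <- stats::uniroot(f, c(lo + 1e-9, hi - 1e-9), tol = 1e-12)$root
    v <- 1 / (1 / a_exp + 1 / (r1 - a_exp) + 1 / (c1 - a_exp) +
                1 / (n - r1 - c1 + a_exp))
    stat <- stat + (t$a[i] - a_exp)^2 / v
  }
  stat
}

# random stratified table with all margins positive
random_stratified_table <- function(k = 4, lambda = 8) {
  repeat {
    a <- rpois(k, lambda) + 1; b <- rpois(k, lambda) + 1
    cc <- rpois(k, lambda) + 1; d <- rpois(k, lambda) + 1
    tt <- stratified_table(paste0("s", seq_len(k)), a, b, cc, d)
    if (all(tt$a + tt$b + tt$c + tt$d >= 2)) return(tt)
  }
}

# brute-force pairwise distances between two atom tables
oracle_pair_distances <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                          (a$z[i] - b$z[j])^2)
  out
}

# NeRF-style internal-to-cartesian placement: position D given A,B,C and
# bond length CD, angle BCD (deg), dihedral ABCD (deg)
place_atom <- function(A, B, C, length, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(ang), length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build an N-residue polypeptide backbone (N, CA, C per residue) with the
# given phi/psi angles (omega fixed at 180); returns a structure_model
build_backbone <- function(phi, psi, chain = "H") {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  coords <- list(c(0, 0, 0), c(1.46, 0, 0),
                 place_atom(c(-1, 1, 0), c(0, 0, 0), c(1.46, 0, 0),
                            1.52, 111, 45))  # seed triad: N1, CA1, C1
  names_out <- c("N", "CA", "C")
  res_out <- c(1L, 1L, 1L)
  for (r in 2:n_res) {
    k <- length(coords)
    # N(r): placed by psi(r-1) about CA(r-1)-C(r-1)
    coords[[k + 1]] <- place_atom(coords[[k - 2]], coords[[k - 1]],
                                  coords[[k]], 1.33, 116, psi[r - 1])
    # CA(r): omega = 180
    coords[[k + 2]] <- place_atom(coords[[k - 1]], coords[[k]],
                                  coords[[k + 1]], 1.46, 122, 180)
    # C(r): phi(r)
    coords[[k + 3]] <- place_atom(coords[[k]], coords[[k + 1]],
                                  coords[[k + 2]], 1.52, 111, phi[r])
    names_out <- c(names_out, "N", "CA", "C")
    res_out <- c(res_out, rep(r, 3L))
  }
  xyz <- do.call(rbind, coords)
  structure_model(data.frame(
    serial = seq_along(res_out), name = names_out,
    element = substr(names_out, 1, 1),
    residue_name = "ALA", residue_seq = res_out, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}
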