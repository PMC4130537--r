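#' Simulation configuration for clone generation
#'
#' @param seed Integer RNG seed for the run.
#' @param n_clones Number of clones to generate.
#' @param per_region_rate Named numeric vector: expected substitutions per
#'   codon for each region name (regions absent from the map are ignored;
#'   unnamed regions default to 0). Values >= 0.
#' @param titv_ratio Ratio of transition to transversion proposal weight
#'   (> 0). Each codon position has one transition and two transversion
#'   targets, so the realised transition fraction is
#'   `titv_ratio / (titv_ratio + 2)`.
#' @param allow_multi_hit_codons Allow more than one substitution in a codon
#'   (default `TRUE`).
#' @param stop_codon_policy `"allow"` (default; nonsense codons kept and
#'   labelled R) or `"forbid"` (substitutions producing a stop codon are
#'   redrawn).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_clones = 4L,
                       per_region_rate = c(FR1 = 0.01, CDR1 = 0.02,
                                           FR2 = 0.01, CDR2 = 0.06,
                                           FR3 = 0.02),
                       titv_ratio = 0.5,
                       allow_multi_hit_codons = TRUE,
                       stop_codon_policy = c("allow", "forbid")) {
  stop_codon_policy <- match.arg(stop_codon_policy)
  if (any(per_region_rate < 0)) stop("per_region_rate must be >= 0")
  if (titv_ratio <= 0) stop("titv_ratio must be > 0")
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 per_region_rate = per_region_rate,
                 titv_ratio = titv_ratio,
                 allow_multi_hit_codons = isTRUE(allow_multi_hit_codons),
                 stop_codon_policy = stop_codon_policy),
            class = "sim_config")
}

stop_codons <- c("TAA", "TAG", "TGA")

#' Generate a random germline V-gene sequence
#'
#' Draws codons uniformly from the 61 sense codons, so the sequence is an
#' open reading frame with no internal stops. Deterministic for a fixed
#' seed.
#'
#' @param seed Integer RNG seed.
#' @param n_codons Sequence length in codons; must cover the region map.
#' @param region_map A [region_map()] (default [default_vh_region_map()]).
#' @param id Sequence identifier.
#' @return An [annotated_sequence()].
#' @export
generate_germline <- function(seed, n_codons = 98L,
                              region_map = default_vh_region_map(),
                              id = "germline") {
  stopifnot(inherits(region_map, "region_map"))
  if (max(region_map$codon_end) > n_codons)
    stop("region map requires at least ", max(region_map$codon_end),
         " codons but n_codons = ", n_codons)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stop_codons)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  nts <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  annotated_sequence(id, nts, region_map)
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# substitution targets: the transition partner and the two transversions
transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

draw_target_base <- function(base, titv_ratio) {
  w <- c(titv_ratio, 1, 1)
  cand <- c(transition_of[[base]], transversions_of[[base]])
  sample(cand, 1L, prob = w / sum(w))
}

#' Mutate a germline sequence into a clone with labelled mutations
#'
#' Each nucleotide position mutates independently with probability
#' `per_region_rate[region]/3` (so a codon carries on average the configured
#' number of substitutions). Target bases follow the configured
#' transition/transversion proposal weights. The returned ground-truth list
#' is exhaustive: the clone differs from the germline exactly at the listed
#' positions, and every label is recomputed from the realised codon change.
#'
#' @param germline An [annotated_sequence()].
#' @param cfg A [sim_config()].
#' @param clone_id Identifier for the clone.
#' @return A list with `sequence` (clone DNA string) and `mutations`
#'   (data.frame: `clone_id`, `codon_index`, `within_codon_pos`,
#'   `nt_position`, `base_from`, `base_to`, `titv`, `rs`, `region`).
#' @export
mutate_clone <- function(germline, cfg, clone_id = "clone1") {
  stopifnot(inherits(germline, "annotated_sequence"),
            inherits(cfg, "sim_config"))
  g <- strsplit(germline$nucleotides, "")[[1]]
  n_codons <- length(g) %/% 3L
  reg <- region_of_codon(germline$regions, seq_len(n_codons))
  rate <- cfg$per_region_rate[reg]
  rate[is.na(rate)] <- 0
  p_nt <- pmin(rep(rate, each = 3L) / 3, 1)

  clone <- g
  hits <- which(stats::runif(length(g)) < p_nt)
  if (!cfg$allow_multi_hit_codons && length(hits) > 1) {
    cod <- (hits - 1L) %/% 3L + 1L
    hits <- hits[!duplicated(cod)]
  }
  for (i in hits) {
    ci <- (i - 1L) %/% 3L + 1L
    repeat {
      b <- draw_target_base(clone[i], cfg$titv_ratio)
      clone[i] <- b
      if (cfg$stop_codon_policy == "allow") break
      cod <- paste(clone[(3 * ci - 2):(3 * ci)], collapse = "")
      if (!cod %in% stop_codons) break
      clone[i] <- g[i]  # revert, then redraw a non-stop target
    }
  }
  clone_str <- paste(clone, collapse = "")
  recs <- compare_to_germline(germline, clone_str, clone_id = clone_id)
  mut <- data.frame(clone_id = recs$clone_id,
                    codon_index = recs$codon_index,
                    within_codon_pos = (recs$nt_position - 1L) %% 3L + 1L,
                    nt_position = recs$nt_position,
                    base_from = recs$base_from, base_to = recs$base_to,
                    titv = recs$titv, rs = recs$rs, region = recs$region,
                    stringsAsFactors = FALSE)
  list(sequence = clone_str, mutations = mut)
}

#' Simulate a germline plus a set of labelled clones
#'
#' Convenience driver: generates (or accepts) a germline and applies
#' [mutate_clone()] `cfg$n_clones` times under one seeded RNG stream.
#'
#' @param cfg A [sim_config()].
#' @param germline Optional [annotated_sequence()]; generated from
#'   `cfg$seed` when missing.
#' @param n_codons Codons for a generated germline.
#' @param region_map Region map for a generated germline.
#' @return List with `germline`, `clones` (named character vector) and
#'   `truth` (row-bound mutation data.frame).
#' @export
simulate_clone_set <- function(cfg, germline = NULL, n_codons = 98L,
                               region_map = default_vh_region_map()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(germline))
    germline <- generate_germline(cfg$seed, n_codons, region_map)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 10000L)
  clones <- character(); truth <- list()
  for (k in seq_len(cfg$n_clones)) {
    id <- sprintf("clone%02d", k)
    res <- mutate_clone(germline, cfg, clone_id = id)
    clones[id] <- res$sequence
    truth[[id]] <- res$mutations
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(clone_id = character(), codon_index = integer(),
               within_codon_pos = integer(), nt_position = integer(),
               base_from = character(), base_to = character(),
               titv = character(), rs = character(), region = character(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(germline = germline, clones = clones, truth = truth)
}

#' Generate a toy receptor/ligand atom pair with known geometry
#'
#' Builds two small structure models whose pairwise geometry is known by
#' construction, for validating contact, hydrogen-bond and energy operators.
#'
#' @param seed Integer RNG seed.
#' @param n_receptor_atoms,n_ligand_atoms Atom counts (>= 1).
#' @param geometry A list describing placement:
#'   `list(type = "cloud", box = 10)` scatters both selections in a shared
#'   cube of the given edge (Angstrom); `list(type = "separated", gap = 20)`
#'   offsets the ligand cloud so every inter-selection distance is >= `gap`;
#'   `list(type = "pair_distance", distance = 3.0)` additionally pins ligand
#'   atom 1 exactly `distance` from receptor atom 1.
#' @param charge Partial charge (e) given to every atom (receptor atoms get
#'   `+charge`, ligand atoms `-charge`); default 0.2.
#' @return List with `receptor` and `ligand` structure-model data.frames
#'   (see [structure_model()]).
#' @export
generate_toy_complex <- function(seed, n_receptor_atoms = 20L,
                                 n_ligand_atoms = 10L,
                                 geometry = list(type = "cloud", box = 10),
                                 charge = 0.2) {
  stopifnot(n_receptor_atoms >= 1L, n_ligand_atoms >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  box <- if (!is.null(geometry$box)) geometry$box else 10
  rxyz <- matrix(stats::runif(3 * n_receptor_atoms, 0, box), ncol = 3)
  lxyz <- matrix(stats::runif(3 * n_ligand_atoms, 0, box), ncol = 3)
  if (identical(geometry$type, "separated")) {
    gap <- if (!is.null(geometry$gap)) geometry$gap else 20
    lxyz[, 1] <- lxyz[, 1] + box + gap   # clouds span [0,box]; shift by box+gap
  }
  if (identical(geometry$type, "pair_distance")) {
    d <- geometry$distance
    rxyz[1, ] <- c(0, 0, 0)
    lxyz[1, ] <- c(d, 0, 0)
    if (n_ligand_atoms > 1)  # keep the rest of the ligand far away
      lxyz[-1, 1] <- lxyz[-1, 1, drop = FALSE] + box + 20
  }
  mk <- function(xyz, chain, resname, el, q0) {
    n <- nrow(xyz)
    structure_model(data.frame(
      serial = seq_len(n),
      name = paste0(el, seq_len(n)),
      element = el,
      residue_name = resname,
      residue_seq = ((seq_len(n) - 1L) %/% 4L) + 1L,
      chain = chain,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = q0,
      stringsAsFactors = FALSE))
  }
  list(receptor = mk(rxyz, "H", "ALA", "C", +charge),
       ligand = mk(lxyz, "Y", "FUC", "O", -charge))
}

#' Generate a toy trajectory by Gaussian perturbation of a model
#'
#' Frame 1 equals the input model's coordinates; each subsequent frame adds
#' independent isotropic Gaussian displacement of standard deviation
#' `noise_sd` (Angstrom, per coordinate) to the reference coordinates.
#'
#' @param model A [structure_model()].
#' @param n_frames Number of frames (>= 1).
#' @param noise_sd Per-coordinate displacement SD in Angstrom (>= 0).
#' @param seed Integer RNG seed.
#' @return A `trajectory` object (see [trajectory()]).
#' @export
generate_toy_trajectory <- function(model, n_frames, noise_sd, seed) {
  stopifnot(inherits(model, "structure_model"), n_frames >= 1, noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ref <- as.vector(t(as.matrix(model$atoms[, c("x", "y", "z")])))
  xyz <- matrix(rep(ref, each = n_frames), nrow = n_frames)
  if (n_frames > 1 && noise_sd > 0) {
    noise <- matrix(stats::rnorm((n_frames - 1L) * length(ref), 0, noise_sd),
                    nrow = n_frames - 1L)
    xyz[-1L, ] <- xyz[-1L, , drop = FALSE] + noise
  }
  trajectory(model, xyz)
}
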