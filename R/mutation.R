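#' Translate a codon under the standard genetic code
#'
#' Stops translate to `"*"`, which is treated as a distinct residue by
#' [classify_codon_effect()] (a nonsense change replaces the amino acid).
#'
#' @param codon Character vector of 3-mers over `A,C,G,T`.
#' @return Character vector of one-letter amino acids (`"*"` for stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon)))
    stop("codons must be 3-mers over A,C,G,T")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Purine<->purine (`A<->G`) and pyrimidine<->pyrimidine (`C<->T`) changes
#' are transitions; purine<->pyrimidine changes are transversions.
#'
#' @param base_from,base_to Single DNA bases; must differ elementwise.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("A", "C")  # transversion
#' @export
classify_substitution <- function(base_from, base_to) {
  base_from <- toupper(base_from); base_to <- toupper(base_to)
  ok <- c("A", "C", "G", "T")
  if (!all(base_from %in% ok) || !all(base_to %in% ok))
    stop("bases must be one of A, C, G, T")
  if (any(base_from == base_to))
    stop("base_from and base_to must differ (not a substitution)")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(base_from) == purine(base_to), "transition", "transversion")
}

#' Classify a codon change as replacement (R) or silent (S)
#'
#' R iff the standard-genetic-code translations differ; a stop codon counts
#' as a distinct residue, so nonsense changes are R.
#'
#' @param codon_from,codon_to Distinct in-frame codons over `A,C,G,T`.
#' @return `"R"` or `"S"` (vectorised).
#' @examples
#' classify_codon_effect("GAT", "GAC")  # S: both Asp
#' classify_codon_effect("TGG", "TGC")  # R: Trp -> Cys
#' @export
classify_codon_effect <- function(codon_from, codon_to) {
  if (any(toupper(codon_from) == toupper(codon_to)))
    stop("codon_from and codon_to must differ")
  ifelse(translate_codon(codon_from) == translate_codon(codon_to), "S", "R")
}

#' List and classify all substitutions of a clone against its germline
#'
#' The clone must be pre-aligned to germline coordinates (same length, no
#' indels). Each differing nucleotide yields one record; the R/S verdict is
#' codon-level, comparing the full germline codon with the full clone codon,
#' so two substitutions within one codon share a single verdict.
#'
#' @param germline An [annotated_sequence()].
#' @param clone Clone nucleotide string (same length as germline) or an
#'   `annotated_sequence`.
#' @param clone_id Identifier recorded in the output (defaults to the clone's
#'   own id, or `"clone"`).
#' @param mask_positions Optional integer vector of 1-based nucleotide
#'   positions to exclude from the output (indeterminate positions).
#' @return A data.frame of mutation records sorted by `nt_position`, with
#'   columns `clone_id`, `nt_position`, `codon_index`, `region`, `base_from`,
#'   `base_to`, `titv`, `rs`, `codon_from`, `codon_to`, `aa_from`, `aa_to`.
#' @export
compare_to_germline <- function(germline, clone, clone_id = NULL,
                                mask_positions = integer()) {
  stopifnot(inherits(germline, "annotated_sequence"))
  if (inherits(clone, "annotated_sequence")) {
    if (is.null(clone_id)) clone_id <- clone$id
    clone <- clone$nucleotides
  }
  if (is.null(clone_id)) clone_id <- "clone"
  clone <- toupper(as.character(clone))
  g <- germline$nucleotides
  if (nchar(clone) != nchar(g))
    stop("clone length (", nchar(clone), ") differs from germline (",
         nchar(g), "); sequences must be pre-aligned, indels unsupported")
  if (grepl("[^ACGT]", clone))
    stop("clone contains non-ACGT characters (ambiguity codes unsupported)")

  gb <- strsplit(g, "")[[1]]
  cb <- strsplit(clone, "")[[1]]
  pos <- which(gb != cb)
  pos <- setdiff(pos, as.integer(mask_positions))
  if (length(pos) == 0L) return(empty_mutation_records())

  codon_idx <- (pos - 1L) %/% 3L + 1L
  gcod <- codons_of(g)
  ccod <- codons_of(clone)
  rs <- classify_codon_effect(gcod[codon_idx], ccod[codon_idx])
  data.frame(
    clone_id = clone_id,
    nt_position = pos,
    codon_index = codon_idx,
    region = region_of_codon(germline$regions, codon_idx),
    base_from = gb[pos],
    base_to = cb[pos],
    titv = classify_substitution(gb[pos], cb[pos]),
    rs = rs,
    codon_from = gcod[codon_idx],
    codon_to = ccod[codon_idx],
    aa_from = translate_codon(gcod[codon_idx]),
    aa_to = translate_codon(ccod[codon_idx]),
    stringsAsFactors = FALSE
  )
}

empty_mutation_records <- function() {
  data.frame(clone_id = character(), nt_position = integer(),
             codon_index = integer(), region = character(),
             base_from = character(), base_to = character(),
             titv = character(), rs = character(),
             codon_from = character(), codon_to = character(),
             aa_from = character(), aa_to = character(),
             stringsAsFactors = FALSE)
}

#' Tabulate mutation records into a per-clone region x R/S table
#'
#' Produces one row per clone with R and S counts for each of FR1, CDR1,
#' FR2, CDR2, FR3, the marginal totals `TotalFR_*` and `TotalCDR_*`, and
#' transition/transversion totals. Junction records (beyond FR3) are dropped
#' by default because the junction's germline origin is not attributable.
#'
#' @param records Mutation-record data.frame from [compare_to_germline()]
#'   (rows from several clones may be concatenated).
#' @param region_map The [region_map()] the records were classified against.
#' @param exclude_beyond_fr3 Drop `JUNCTION` records before counting
#'   (default `TRUE`).
#' @param count_unit `"substitution"` (default) counts every nucleotide
#'   substitution; `"codon"` counts each mutated codon once, with its shared
#'   codon-level R/S verdict.
#' @return A data.frame with columns `clone`, `<region>_R`, `<region>_S`,
#'   `TotalFR_R`, `TotalFR_S`, `TotalCDR_R`, `TotalCDR_S`, `transitions`,
#'   `transversions`.
#' @export
tabulate_mutations <- function(records, region_map,
                               exclude_beyond_fr3 = TRUE,
                               count_unit = c("substitution", "codon")) {
  count_unit <- match.arg(count_unit)
  stopifnot(inherits(region_map, "region_map"))
  known <- c(region_map$region, "JUNCTION")
  if (nrow(records) > 0 && !all(records$region %in% known))
    stop("record region(s) absent from the region map: ",
         paste(setdiff(unique(records$region), known), collapse = ", "))

  regions <- intersect(c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
                       region_map$region)
  clones <- unique(records$clone_id)
  if (length(clones) == 0L) clones <- character()

  if (exclude_beyond_fr3 && nrow(records) > 0)
    records <- records[records$region != "JUNCTION", , drop = FALSE]

  one_row <- function(cl) {
    rec <- records[records$clone_id == cl, , drop = FALSE]
    counted <- rec
    if (count_unit == "codon" && nrow(rec) > 0)
      counted <- rec[!duplicated(rec$codon_index), , drop = FALSE]
    cnt <- function(reg, cls)
      sum(counted$region == reg & counted$rs == cls)
    vals <- unlist(lapply(regions, function(r) c(cnt(r, "R"), cnt(r, "S"))))
    names(vals) <- as.vector(rbind(paste0(regions, "_R"),
                                   paste0(regions, "_S")))
    fr <- grep("^FR", regions, value = TRUE)
    cdr <- grep("^CDR", regions, value = TRUE)
    out <- c(vals,
             TotalFR_R = sum(vals[paste0(fr, "_R")]),
             TotalFR_S = sum(vals[paste0(fr, "_S")]),
             TotalCDR_R = sum(vals[paste0(cdr, "_R")]),
             TotalCDR_S = sum(vals[paste0(cdr, "_S")]),
             transitions = sum(rec$titv == "transition"),
             transversions = sum(rec$titv == "transversion"))
    data.frame(clone = cl, as.list(out), stringsAsFactors = FALSE)
  }
  rows <- lapply(clones, one_row)
  if (length(rows) == 0L) {
    tmpl <- one_row("")[0, , drop = FALSE]
    return(tmpl)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inherent (expected) R/S ratio of a sequence region
#'
#' Enumerates all 9 possible single-nucleotide substitutions of every
#' selected codon, classifies each as replacement or silent under the
#' standard genetic code, and returns the ratio of counts. This is the
#' "inherent" R/S ratio of the sequence itself: the value expected under
#' mutation without selection (about 2.9 for a random coding sequence, the
#' reference value conventionally used to diagnose somatic hypermutation).
#'
#' @param sequence An [annotated_sequence()] or an in-frame DNA string.
#' @param codon_selection Integer vector of 1-based codon indices to
#'   enumerate (default: all codons). May also be a region name when
#'   `sequence` is annotated.
#' @return Numeric ratio `R/S` with attributes `r_count` and `s_count`;
#'   `+Inf` (with a warning) when no silent substitution exists.
#' @examples
#' inherent_rs_ratio("TCT")  # Ser: 6 R, 3 S -> 2.0
#' @export
inherent_rs_ratio <- function(sequence, codon_selection = NULL) {
  if (inherits(sequence, "annotated_sequence")) {
    nts <- sequence$nucleotides
    if (is.character(codon_selection) && length(codon_selection) >= 1 &&
        any(codon_selection %in% sequence$regions$region)) {
      all_idx <- seq_len(nchar(nts) %/% 3L)
      codon_selection <-
        all_idx[region_of_codon(sequence$regions, all_idx) %in% codon_selection]
    }
  } else {
    nts <- toupper(as.character(sequence))
    if (nchar(nts) %% 3L != 0L || grepl("[^ACGT]", nts))
      stop("sequence must be in-frame DNA over A,C,G,T")
  }
  cods <- codons_of(nts)
  if (is.null(codon_selection)) codon_selection <- seq_along(cods)
  codon_selection <- as.integer(codon_selection)
  if (length(codon_selection) == 0L)
    stop("empty codon selection")
  if (any(codon_selection < 1L | codon_selection > length(cods)))
    stop("codon selection out of range")

  bases <- c("A", "C", "G", "T")
  r <- 0L; s <- 0L
  for (cod in cods[codon_selection]) {
    cb <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, cb[p])) {
        alt <- cb; alt[p] <- b
        if (classify_codon_effect(cod, paste(alt, collapse = "")) == "R")
          r <- r + 1L else s <- s + 1L
      }
    }
  }
  if (s == 0L) {
    warning("no silent substitution possible in the selection; ratio is +Inf")
    ratio <- Inf
  } else ratio <- r / s
  structure(ratio, r_count = r, s_count = s)
}

#' Read / write clone sequences as FASTA
#'
#' Thin wrappers over Biostrings for the package's sequence I/O.
#'
#' @param path FASTA file path.
#' @return `read_fasta_sequences()` returns a named character vector of
#'   uppercase DNA strings.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta_sequences
#' @param sequences Named character vector of DNA strings.
#' @export
write_fasta_sequences <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
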