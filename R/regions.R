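#' Build a codon-indexed region map for an antibody V gene
#'
#' A region map assigns codon intervals (1-based, inclusive) to the Kabat
#' framework and CDR regions of a variable domain. Intervals must be
#' non-overlapping and ascending; they may leave gaps. Codons not covered by
#' any interval are treated as `JUNCTION` (beyond FR3), which downstream
#' tabulation excludes by default because the origin of junction nucleotides
#' cannot be attributed to the germline gene.
#'
#' @param region Character vector of region names. Allowed names:
#'   `FR1, CDR1, FR2, CDR2, FR3, JUNCTION`.
#' @param codon_start,codon_end Integer vectors of 1-based inclusive codon
#'   bounds, same length as `region`.
#' @return A `region_map` data.frame with columns `region`, `codon_start`,
#'   `codon_end`.
#' @examples
#' region_map(c("FR1", "CDR1"), c(1, 31), c(30, 35))
#' @export
region_map <- function(region, codon_start, codon_end) {
  region <- as.character(region)
  codon_start <- as.integer(codon_start)
  codon_end <- as.integer(codon_end)
  stopifnot(length(region) == length(codon_start),
            length(region) == length(codon_end))
  allowed <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "JUNCTION")
  bad <- setdiff(region, allowed)
  if (length(bad) > 0)
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  if (any(codon_start < 1L) || any(codon_end < codon_start))
    stop("codon intervals must satisfy 1 <= codon_start <= codon_end")
  ord <- order(codon_start)
  region <- region[ord]; codon_start <- codon_start[ord]; codon_end <- codon_end[ord]
  if (length(region) > 1 &&
      any(codon_start[-1] <= codon_end[-length(codon_end)]))
    stop("region intervals overlap")
  if (anyDuplicated(region))
    stop("duplicated region name in map")
  out <- data.frame(region = region, codon_start = codon_start,
                    codon_end = codon_end, stringsAsFactors = FALSE)
  class(out) <- c("region_map", "data.frame")
  out
}

#' Default Kabat-style VH region map (98 codons, FR1 through FR3)
#'
#' Codon intervals approximating the Kabat partition of a murine VH domain:
#' FR1 1-30, CDR1 31-35, FR2 36-49, CDR2 50-66, FR3 67-98. Codons beyond 98
#' fall in the junction and are excluded from mutation tallies.
#'
#' @return A [region_map()].
#' @export
default_vh_region_map <- function() {
  region_map(c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
             c(1L, 31L, 36L, 50L, 67L),
             c(30L, 35L, 49L, 66L, 98L))
}

#' Map codon indices to region names
#'
#' @param map A [region_map()].
#' @param codon_index Integer vector of 1-based codon indices.
#' @return Character vector of region names; `"JUNCTION"` for codons not
#'   covered by the map.
#' @export
region_of_codon <- function(map, codon_index) {
  stopifnot(inherits(map, "region_map"))
  codon_index <- as.integer(codon_index)
  out <- rep("JUNCTION", length(codon_index))
  for (i in seq_len(nrow(map))) {
    hit <- codon_index >= map$codon_start[i] & codon_index <= map$codon_end[i]
    out[hit] <- map$region[i]
  }
  out
}

#' Read / write a region map as TSV or YAML
#'
#' The TSV layout has columns `region`, `codon_start`, `codon_end`; the YAML
#' layout is a list of `{region, codon_start, codon_end}` records. Both use
#' 1-based inclusive codon intervals.
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` vs TSV).
#' @return `read_region_map()` returns a [region_map()];
#'   `write_region_map()` returns `path` invisibly.
#' @export
read_region_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(recs, as.data.frame))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  region_map(df$region, df$codon_start, df$codon_end)
}

#' @rdname read_region_map
#' @param map A [region_map()] to serialise.
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(map)), function(i)
      list(region = map$region[i],
           codon_start = map$codon_start[i],
           codon_end = map$codon_end[i]))
    yaml::write_yaml(recs, path)
  } else {
    utils::write.table(as.data.frame(map), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Annotated V-gene nucleotide sequence
#'
#' Couples an in-frame nucleotide sequence with its codon-indexed region map.
#'
#' @param id Sequence identifier.
#' @param nucleotides DNA string over `A,C,G,T`, length divisible by 3.
#' @param regions A [region_map()].
#' @return An `annotated_sequence` object (list with `id`, `nucleotides`,
#'   `regions`).
#' @export
annotated_sequence <- function(id, nucleotides, regions) {
  nucleotides <- toupper(as.character(nucleotides))
  if (nchar(nucleotides) %% 3L != 0L)
    stop("sequence length must be divisible by 3 (in-frame)")
  if (grepl("[^ACGT]", nucleotides))
    stop("sequence contains non-ACGT characters")
  stopifnot(inherits(regions, "region_map"))
  n_codons <- nchar(nucleotides) %/% 3L
  if (max(regions$codon_end) > n_codons)
    stop("region map extends beyond sequence (", max(regions$codon_end),
         " > ", n_codons, " codons)")
  structure(list(id = as.character(id), nucleotides = nucleotides,
                 regions = regions),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat("<annotated_sequence> ", x$id, ": ", nchar(x$nucleotides), " nt (",
      nchar(x$nucleotides) %/% 3L, " codons), ", nrow(x$regions),
      " annotated regions\n", sep = "")
  invisible(x)
}

# split an in-frame sequence into its codons
codons_of <- function(nucleotides) {
  n <- nchar(nucleotides) %/% 3L
  substring(nucleotides, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
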