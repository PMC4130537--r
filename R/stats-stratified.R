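#' Build a stratified 2x2 table of region x mutation-type counts
#'
#' Each stratum is one antibody's 2x2 table with rows CDR/FR and columns
#' R/S: `a` = CDR replacement, `b` = CDR silent, `c` = FR replacement,
#' `d` = FR silent. Stratifying by antibody (rather than pooling) guards
#' the association estimate against Simpson's paradox.
#'
#' @param label Character vector of unique stratum labels (antibody ids).
#' @param cdr_r,cdr_s,fr_r,fr_s Non-negative integer count vectors.
#' @return A `stratified_table` data.frame with columns `label`, `a`, `b`,
#'   `c`, `d`.
#' @export
stratified_table <- function(label, cdr_r, cdr_s, fr_r, fr_s) {
  counts <- cbind(cdr_r, cdr_s, fr_r, fr_s)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(label)) stop("stratum labels must be unique")
  if (any(rowSums(counts) == 0))
    stop("every stratum must contain at least one mutation")
  out <- data.frame(label = as.character(label),
                    a = as.integer(cdr_r), b = as.integer(cdr_s),
                    c = as.integer(fr_r), d = as.integer(fr_s),
                    stringsAsFactors = FALSE)
  class(out) <- c("stratified_table", "data.frame")
  out
}

#' Convert a per-clone mutation table to a stratified 2x2 table
#'
#' Uses the `TotalCDR_*` / `TotalFR_*` columns of a
#' [tabulate_mutations()] result, one stratum per clone.
#'
#' @param mutation_table Output of [tabulate_mutations()].
#' @return A [stratified_table()].
#' @export
as_stratified_table <- function(mutation_table) {
  stratified_table(mutation_table$clone,
                   mutation_table$TotalCDR_R, mutation_table$TotalCDR_S,
                   mutation_table$TotalFR_R, mutation_table$TotalFR_S)
}

#' Published VH mutation counts for the four anti-Lewis-Y antibodies
#'
#' The per-antibody replacement/silent totals in framework vs CDR regions
#' of the heavy-chain variable domain for BR55-2, B3, BR96 and mu3S193,
#' relative to the VH7183.a13.20 germline gene (junction region excluded).
#' These are the counts behind the reported common odds ratio of 6.26.
#'
#' @return A [stratified_table()] with four strata.
#' @export
ley_vh_mutation_counts <- function() {
  stratified_table(
    label = c("BR55-2", "B3", "BR96", "mu3S193"),
    cdr_r = c(4, 6, 4, 5),
    cdr_s = c(1, 1, 0, 0),
    fr_r  = c(2, 3, 3, 2),
    fr_s  = c(1, 3, 1, 1))
}

#' Per-stratum odds ratio
#'
#' @param s A [stratified_table()] (all rows used) or a single-row subset.
#' @param zero_policy `"raw"` returns the plain `(a*d)/(b*c)` (may be 0,
#'   `Inf`, or `NaN` for degenerate cells); `"haldane"` adds 0.5 to every
#'   cell first.
#' @return Numeric vector of odds ratios, named by stratum label.
#' @examples
#' stratum_odds_ratio(ley_vh_mutation_counts())
#' @export
stratum_odds_ratio <- function(s, zero_policy = c("raw", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(s, "stratified_table"))
  k <- if (zero_policy == "haldane") 0.5 else 0
  stats::setNames((s$a + k) * (s$d + k) / ((s$b + k) * (s$c + k)), s$label)
}

#' Mantel-Haenszel common odds ratio across strata
#'
#' The precision-weighted average association
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`. Zero cells need no
#' continuity adjustment: their terms simply vanish.
#'
#' @param t A [stratified_table()].
#' @return The common odds ratio (scalar); `Inf` with a warning when the
#'   denominator is zero.
#' @examples
#' mh_common_or(ley_vh_mutation_counts())  # 6.26
#' @export
mh_common_or <- function(t) {
  stopifnot(inherits(t, "stratified_table"))
  n <- t$a + t$b + t$c + t$d
  num <- sum(t$a * t$d / n)
  den <- sum(t$b * t$c / n)
  if (den == 0) {
    warning("all strata have a zero b*c product; common OR is infinite")
    return(Inf)
  }
  num / den
}

#' Cochran-Mantel-Haenszel chi-square test of association
#'
#' Tests whether mutation type (R vs S) is associated with region (CDR vs
#' FR) across strata, conditioning on the stratum margins. The statistic is
#' `(sum(a_i) - sum(E_i))^2 / sum(V_i)` with hypergeometric expectation
#' `E_i = r1_i c1_i / n_i` and variance
#' `V_i = r1_i r2_i c1_i c2_i / (n_i^2 (n_i - 1))`; df = 1.
#'
#' @param t A [stratified_table()].
#' @param continuity_correction Subtract 0.5 from the absolute deviation
#'   before squaring (default `FALSE`; the headline statistic is reported
#'   without it).
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value` and `estimate` (the MH common OR).
#' @examples
#' cmh_test(ley_vh_mutation_counts())  # X^2 = 3.92, p = 0.048
#' @export
cmh_test <- function(t, continuity_correction = FALSE) {
  stopifnot(inherits(t, "stratified_table"))
  n <- t$a + t$b + t$c + t$d
  if (any(n < 2)) stop("each stratum must have n >= 2")
  r1 <- t$a + t$b; r2 <- t$c + t$d
  c1 <- t$a + t$c; c2 <- t$b + t$d
  V <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  zero <- V == 0
  if (any(zero))
    warning("stratum(s) with a zero margin contribute no information: ",
            paste(t$label[zero], collapse = ", "))
  E <- r1 * c1 / n
  dev <- abs(sum(t$a[!zero]) - sum(E[!zero]))
  if (continuity_correction) dev <- max(0, dev - 0.5)
  stat <- dev^2 / sum(V[!zero])
  structure(list(
    statistic = c("Mantel-Haenszel X-squared" = stat),
    parameter = c(df = 1L),
    p.value = chi2_upper_tail(stat, 1L),
    estimate = c("common odds ratio" = mh_common_or(t)),
    method = paste0("Cochran-Mantel-Haenszel chi-squared test",
                    if (continuity_correction) " with continuity correction"
                    else " without continuity correction"),
    data.name = deparse(substitute(t))), class = "htest")
}

# expected a-cell consistent with odds ratio psi and the stratum margins:
# the admissible root of psi*(r1-a)(c1-a) = a*(n-r1-c1+a)
expected_a_given_or <- function(r1, c1, n, psi, label = "") {
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  if (abs(psi - 1) < 1e-12) return(r1 * c1 / n)
  A <- 1 - psi
  B <- (n - r1 - c1) + psi * (r1 + c1)
  C <- -psi * r1 * c1
  disc <- B^2 - 4 * A * C
  if (disc < 0)
    stop("no admissible expected cell for stratum ", label,
         " (negative discriminant)")
  roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  if (!any(ok))
    stop("no admissible expected cell for stratum ", label,
         " (roots outside margin range)")
  min(max(roots[ok][1], lo), hi)
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Tests whether a single common odds ratio describes every stratum, using
#' the Mantel-Haenszel estimate as the homogeneity null. For each stratum
#' the expected CDR-R cell consistent with the common OR and the stratum
#' margins is found (the admissible quadratic root), and the statistic sums
#' the squared standardized deviations; df = K - 1.
#'
#' @param t A [stratified_table()] with at least two strata.
#' @param tarone_adjustment Apply Tarone's correction, subtracting
#'   `(sum(a - a_exp))^2 / sum(Var)` (default `FALSE`).
#' @return An `htest` with `statistic`, `parameter` (df = K-1), `p.value`
#'   and `estimate` (the common OR used as the null).
#' @examples
#' breslow_day_test(ley_vh_mutation_counts())  # X^2 = 1.08, df = 3
#' @export
breslow_day_test <- function(t, tarone_adjustment = FALSE) {
  stopifnot(inherits(t, "stratified_table"))
  K <- nrow(t)
  if (K < 2) stop("Breslow-Day test needs at least two strata")
  psi <- mh_common_or(t)
  if (!is.finite(psi) || psi <= 0)
    stop("MH common odds ratio must be finite and positive")
  n <- t$a + t$b + t$c + t$d
  r1 <- t$a + t$b; c1 <- t$a + t$c
  a_exp <- vapply(seq_len(K), function(i)
    expected_a_given_or(r1[i], c1[i], n[i], psi, t$label[i]), numeric(1))
  b_exp <- r1 - a_exp
  c_exp <- c1 - a_exp
  d_exp <- n - r1 - c1 + a_exp
  v <- 1 / (1 / a_exp + 1 / b_exp + 1 / c_exp + 1 / d_exp)
  stat <- sum((t$a - a_exp)^2 / v)
  if (tarone_adjustment)
    stat <- stat - sum(t$a - a_exp)^2 / sum(v)
  df <- K - 1L
  structure(list(
    statistic = c("Breslow-Day X-squared" = stat),
    parameter = c(df = df),
    p.value = chi2_upper_tail(stat, df),
    estimate = c("common odds ratio (null)" = psi),
    method = paste0("Breslow-Day test of odds-ratio homogeneity",
                    if (tarone_adjustment) " (Tarone-adjusted)"),
    data.name = deparse(substitute(t))), class = "htest")
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `P(X >= x)` for a chi-square with `df` degrees of freedom.
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("statistic must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Full stratified report: per-stratum ORs, common OR, CMH and Breslow-Day
#'
#' @param t A [stratified_table()].
#' @param continuity_correction Passed to [cmh_test()].
#' @return A list with `per_stratum_or`, `common_or`, `cmh` and (when K >=
#'   2) `breslow_day`; class `stratified_report`.
#' @export
stratified_report <- function(t, continuity_correction = FALSE) {
  or <- mh_common_or(t)
  bd <- NULL
  bd_note <- NULL
  if (nrow(t) < 2) {
    bd_note <- "skipped: fewer than two strata"
  } else if (!is.finite(or) || or <= 0) {
    bd_note <- "skipped: MH common OR degenerate (zero or infinite)"
  } else {
    bd <- breslow_day_test(t)
  }
  out <- list(per_stratum_or = stratum_odds_ratio(t),
              common_or = or,
              cmh = cmh_test(t, continuity_correction),
              breslow_day = bd, breslow_day_note = bd_note)
  class(out) <- "stratified_report"
  out
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Per-stratum odds ratios:\n")
  print(round(x$per_stratum_or, 3))
  cat(sprintf("\nMH common OR: %.3f\n", x$common_or))
  cat(sprintf("CMH chi-square: %.3f (df %d), p = %.3f\n",
              x$cmh$statistic, x$cmh$parameter, x$cmh$p.value))
  if (!is.null(x$breslow_day))
    cat(sprintf("Breslow-Day chi-square: %.3f (df %d), p = %.3f\n",
                x$breslow_day$statistic, x$breslow_day$parameter,
                x$breslow_day$p.value))
  else cat("Breslow-Day:", x$breslow_day_note, "\n")
  invisible(x)
}
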