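#' Segregant genotype table for linkage analysis
#'
#' One row per segregant; each marker column holds the parental origin code
#' (`"A"` or `"B"`) of the allele observed in that segregant. Phase is fixed
#' by the cross's actual parents: a segregant is parental for a marker pair
#' iff its two origin codes are equal.
#'
#' @param df Data.frame containing a `segregant_id` column and one column
#'   per marker.
#' @param markers Character vector naming the marker columns.
#' @return A `genotype_table` data.frame with attribute `markers`.
#' @export
genotype_table <- function(df, markers) {
  if (!all(markers %in% names(df)))
    abort("marker columns missing from genotype table", "key_error")
  for (m in markers) {
    if (!all(df[[m]] %in% c("A", "B")))
      abort(sprintf("marker column %s contains codes other than A/B", m),
            "parse_error")
  }
  structure(as.data.frame(df), markers = markers,
            class = c("genotype_table", "data.frame"))
}

table_markers <- function(table) {
  attr(table, "markers") %||% setdiff(names(table), "segregant_id")
}

#' Per-marker allele distribution
#'
#' @param table A [genotype_table()].
#' @return Data.frame with columns `marker_id`, `count_A`, `count_B`
#'   (counts sum to the number of segregants for every marker).
#' @export
allele_distribution <- function(table) {
  if (nrow(table) == 0) abort("genotype table is empty", "validation_error")
  markers <- table_markers(table)
  data.frame(
    marker_id = markers,
    count_A = vapply(markers, function(m) sum(table[[m]] == "A"), integer(1)),
    count_B = vapply(markers, function(m) sum(table[[m]] == "B"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-point linkage between a marker pair
#'
#' Counts parental segregants (both origin codes equal) and nonparental
#' segregants (codes differ) and reports the recombination frequency
#' `r = NPS / N x 100%`. On a finite table `r` can exceed 50%; it is
#' reported as computed, with `phase_flag = TRUE` when above 50 (which
#' suggests a mis-specified phase).
#'
#' @param table A [genotype_table()].
#' @param marker_x,marker_y Marker column names.
#' @return One-row data.frame: `marker_x`, `marker_y`, `ps_count`,
#'   `nps_count`, `r_percent`, `phase_flag`.
#' @export
pairwise_linkage <- function(table, marker_x, marker_y) {
  markers <- table_markers(table)
  if (!marker_x %in% markers || !marker_y %in% markers)
    abort("marker absent from genotype table", "key_error")
  parental <- table[[marker_x]] == table[[marker_y]]
  n <- nrow(table)
  nps <- sum(!parental)
  r <- nps / n * 100
  data.frame(marker_x = marker_x, marker_y = marker_y,
             ps_count = sum(parental), nps_count = nps,
             r_percent = r, phase_flag = r > 50,
             stringsAsFactors = FALSE)
}

#' All-pairs two-point linkage matrix
#'
#' @param table A [genotype_table()] with at least two markers.
#' @return Data.frame with one row per unordered marker pair.
#' @export
linkage_matrix <- function(table) {
  markers <- table_markers(table)
  if (length(markers) < 2)
    abort("linkage matrix needs at least two markers", "validation_error")
  pairs <- utils::combn(markers, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
    pairwise_linkage(table, pairs[1, j], pairs[2, j])))
}

#' Exact binomial segregation-ratio test
#'
#' Two-sided exact binomial test of 1:1 segregation (H0: p = 1/2), summing
#' the probabilities of all outcomes no more likely than the observed one.
#'
#' @param k Count of parent-A alleles.
#' @param n Total segregants (>= 1).
#' @return List with `k`, `n`, `p_value`.
#' @export
segregation_ratio_test <- function(k, n) {
  if (n < 1) abort("segregation test undefined for n = 0", "undefined_test")
  if (k < 0 || k > n) abort("k must lie in [0, n]", "validation_error")
  structure(list(k = as.integer(k), n = as.integer(n),
                 p_value = binom.test(k, n, p = 0.5)$p.value),
            class = "segregation_test")
}
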