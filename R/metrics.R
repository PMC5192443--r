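# Peak-picking performance measures: counts, isotope coverage, and the
# Peak Picking Score (PPS).

#' Isotope coverage of a peak table
#'
#' The ratio between the number of detected isotope peaks (peaks that are a
#' member of any isotope cluster) and the number of detected peaks. Ranges
#' from 0 (no isotope clusters detected) to 1 (all peaks are part of isotope
#' clusters); higher coverage indicates higher peak-picking quality.
#'
#' @param peaks Peak tibble with an `id` column.
#' @param clusters `isotope_clusters` tibble referencing `peaks` by
#'   `peak_id`; referencing an unknown peak is an error.
#' @return Fraction in \[0, 1\]; 0 for an empty peak table.
#' @examples
#' pk <- table1_spectrum()
#' cl <- find_putative_clusters(pk)
#' isotope_coverage(pk, cl)
#' @export
isotope_coverage <- function(peaks, clusters) {
  stopifnot(is.data.frame(peaks), is.data.frame(clusters))
  if (nrow(peaks) == 0) return(0)
  ids <- unique(clusters$peak_id)
  if (length(setdiff(ids, peaks$id)) > 0) {
    stop("clusters reference peak id(s) not present in `peaks`",
         call. = FALSE)
  }
  length(ids) / nrow(peaks)
}

#' Peak Picking Score (PPS)
#'
#' The ratio between the squared number of reliable peaks and the number of
#' non-reliable peaks. Reliable peaks are cluster members. Non-reliable peaks
#' are non-cluster peaks that are *expected* to show a detectable isotope
#' peak: by default, peaks whose predicted first-isotope intensity (peak
#' intensity divided by the median mono/first-isotope ratio at the peak's
#' mass) exceeds the minimum detected intensity in the table. Without a
#' quantile table every non-cluster peak counts as non-reliable. When no
#' peak is non-reliable the squared reliable count is returned.
#'
#' @param peaks Peak tibble with `id` and `intensity`.
#' @param clusters `isotope_clusters` tibble.
#' @param quantile_table Optional `quantile_table` for the first isotope peak
#'   (ratio of monoisotopic to first isotope), used by the default
#'   expectation rule.
#' @param expectation_rule Optional function `f(non_cluster_peaks, peaks)`
#'   returning a logical vector flagging non-reliable peaks; overrides the
#'   default rule.
#' @return Non-negative score; 0 when there are no reliable peaks.
#' @examples
#' pk <- table1_spectrum()
#' cl <- find_putative_clusters(pk)
#' pps(pk, cl)
#' @export
pps <- function(peaks, clusters, quantile_table = NULL,
                expectation_rule = NULL) {
  stopifnot(is.data.frame(peaks), is.data.frame(clusters))
  reliable_ids <- intersect(unique(clusters$peak_id), peaks$id)
  n_rel <- length(reliable_ids)
  if (n_rel == 0) return(0)
  non <- peaks[!peaks$id %in% reliable_ids, ]
  flagged <- if (!is.null(expectation_rule)) {
    expectation_rule(non, peaks)
  } else if (!is.null(quantile_table) && nrow(non) > 0) {
    min_int <- min(peaks$intensity)
    vapply(seq_len(nrow(non)), function(k) {
      med <- suppressMessages(lookup_quantile(quantile_table, non$mz[k], 0.5))
      non$intensity[k] / med >= min_int
    }, logical(1))
  } else {
    rep(TRUE, nrow(non))
  }
  n_non <- sum(flagged)
  if (n_non == 0) n_rel^2 else n_rel^2 / n_non
}

#' Summarise peak picking and cluster detection performance
#'
#' One-row summary: number of peaks, isotope peaks, clusters, isotope
#' coverage and PPS.
#'
#' @inheritParams pps
#' @return One-row tibble (`n_peaks`, `n_isotope_peaks`, `n_clusters`,
#'   `isotope_coverage`, `pps`).
#' @export
evaluate_peaks <- function(peaks, clusters, quantile_table = NULL) {
  tibble::tibble(
    n_peaks = nrow(peaks),
    n_isotope_peaks = length(intersect(unique(clusters$peak_id), peaks$id)),
    n_clusters = length(unique(clusters$cluster_id)),
    isotope_coverage = isotope_coverage(peaks, clusters),
    pps = pps(peaks, clusters, quantile_table)
  )
}
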