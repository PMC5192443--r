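# Mass-specific validation of putative isotope clusters.
#
# For each cluster peak beyond the monoisotopic one, the observed ratio of
# monoisotopic to i-th peak abundance (bracketed by a noise interval derived
# from both peaks' signal-to-noise estimates) is compared with the mass-window
# confidence interval of that ratio over a compound database. On non-overlap
# the cluster is split: the suffix starting at the offending peak becomes a
# new putative cluster (validated recursively), handling overlapping isotope
# clusters, leading hydrogen-loss peaks and underestimated trailing peaks.

#' Noise-bracketed abundance ratio of two peaks
#'
#' With noise estimates `n_k = a_k / sn_k`, the ratio of peak 1 to peak 2 is
#' bracketed by `r_min = max(a1 - n1, 0) / (a2 + n2)` and
#' `r_max = (a1 + n1) / max(a2 - n2, eps)`. Infinite signal-to-noise collapses
#' the interval to the point ratio `a1/a2`.
#'
#' @param a1,a2 Peak abundances (counts), > 0.
#' @param sn1,sn2 Signal-to-noise ratios, > 0 (may be `Inf`).
#' @return Named numeric `c(low = r_min, high = r_max)`.
#' @examples
#' ratio_interval(100, Inf, 5, Inf)  # point ratio 20
#' ratio_interval(100, 10, 5, 10)
#' @export
ratio_interval <- function(a1, sn1, a2, sn2) {
  if (any(c(a1, a2, sn1, sn2) <= 0) || anyNA(c(a1, a2, sn1, sn2))) {
    stop("abundances and signal-to-noise ratios must be positive",
         call. = FALSE)
  }
  n1 <- a1 / sn1
  n2 <- a2 / sn2
  c(low = max(a1 - n1, 0) / (a2 + n2),
    high = (a1 + n1) / max(a2 - n2, .Machine$double.xmin))
}

.validate_one <- function(df, charge, tables, p_low, p_high) {
  kept <- list()
  rejected <- list()
  walk <- function(rows) {
    n <- nrow(rows)
    if (n < 2) {
      if (n > 0) rejected[[length(rejected) + 1]] <<- rows
      return(invisible())
    }
    mono <- rows[1, ]
    mono_mass <- mono$mz * charge
    for (j in 2:n) {
      iso_idx <- j - 1
      tab <- tables[[as.character(iso_idx)]]
      if (is.null(tab)) {
        stop("no quantile table for isotope index ", iso_idx, call. = FALSE)
      }
      ri <- ratio_interval(mono$intensity, mono$sn,
                           rows$intensity[j], rows$sn[j])
      qi <- lookup_interval(tab, mono_mass, p_low, p_high)
      overlap <- ri[["low"]] <= qi[["high"]] && qi[["low"]] <= ri[["high"]]
      if (!overlap) {
        prefix <- rows[seq_len(j - 1), ]
        if (nrow(prefix) >= 2) {
          kept[[length(kept) + 1]] <<- prefix
        } else {
          rejected[[length(rejected) + 1]] <<- prefix
        }
        walk(rows[j:n, ])
        return(invisible())
      }
    }
    kept[[length(kept) + 1]] <<- rows
    invisible()
  }
  walk(df)
  list(kept = kept, rejected = rejected)
}

#' Validate putative isotope clusters against database ratio intervals
#'
#' Walks each cluster's peaks from the first isotope peak onward and compares
#' the noise-bracketed ratio of the monoisotopic peak to the current peak
#' ([ratio_interval()]) with the database confidence interval for that
#' isotope index at the cluster's monoisotopic mass (m/z times charge,
#' [lookup_interval()]). When the intervals do not overlap the cluster is
#' split: the peaks before the offending one are kept if at least two remain,
#' and the suffix starting at the offending peak becomes a new putative
#' cluster with that peak as monoisotopic, validated recursively. Clusters
#' with fewer than two remaining peaks are dropped; their peaks are reported
#' as rejected.
#'
#' @param clusters An `isotope_clusters` tibble from
#'   [find_putative_clusters()]. A `sn` column is used when present.
#' @param peaks Optional peak tibble with `id` and `sn` to supply
#'   signal-to-noise estimates; peaks without an estimate get `sn = Inf`
#'   (point ratios, the strictest interpretation).
#' @param tables A `quantile_table_set` (or named list of `quantile_table`s,
#'   names `"1"`..`"5"`); default [default_quantile_tables()].
#' @param p_low,p_high Quantile pair defining the confidence interval
#'   (default 0.005/0.995: the 99% interval).
#' @return An `isotope_clusters` tibble of validated clusters (renumbered,
#'   `validated = TRUE`, `isotope_index` counted from each new monoisotopic
#'   peak), with attribute `rejected_peaks`: a tibble of peaks removed from
#'   clusters. Use [rejected_peaks()] to retrieve it.
#' @examples
#' cl <- find_putative_clusters(table1_spectrum())
#' \donttest{
#' validated <- validate_clusters(cl)
#' rejected_peaks(validated)
#' }
#' @export
validate_clusters <- function(clusters, peaks = NULL,
                              tables = default_quantile_tables(),
                              p_low = 0.005, p_high = 0.995) {
  stopifnot(is.data.frame(clusters))
  empty <- clusters[0, ]
  if (!"validated" %in% names(empty)) empty$validated <- logical()
  if (nrow(clusters) == 0) {
    attr(empty, "rejected_peaks") <- clusters[0, ]
    return(empty)
  }
  cl <- tibble::as_tibble(clusters)
  attr(cl, "rejected_peaks") <- NULL
  if (!"sn" %in% names(cl)) {
    if (!is.null(peaks) && all(c("id", "sn") %in% names(peaks))) {
      cl$sn <- peaks$sn[match(cl$peak_id, peaks$id)]
    } else {
      cl$sn <- NA_real_
    }
  }
  if (anyNA(cl$sn)) {
    message(sum(is.na(cl$sn)),
            " peak(s) without signal-to-noise estimate: assuming sn = Inf")
    cl$sn[is.na(cl$sn)] <- Inf
  }

  kept_all <- list()
  rejected_all <- list()
  for (cid in unique(cl$cluster_id)) {
    rows <- cl[cl$cluster_id == cid, ]
    rows <- rows[order(rows$isotope_index), ]
    res <- .validate_one(rows, rows$charge[1], tables, p_low, p_high)
    kept_all <- c(kept_all, res$kept)
    rejected_all <- c(rejected_all, res$rejected)
  }

  if (length(kept_all) == 0) {
    out <- cl[0, ]
  } else {
    kept_all <- kept_all[order(vapply(kept_all, function(x) x$mz[1],
                                      numeric(1)))]
    out <- purrr::imap_dfr(kept_all, function(x, k) {
      x$cluster_id <- as.integer(k)
      x$isotope_index <- seq_len(nrow(x)) - 1L
      x$validated <- TRUE
      x
    })
  }
  rej <- if (length(rejected_all)) {
    dplyr::bind_rows(rejected_all)
  } else {
    cl[0, ]
  }
  class(out) <- c("isotope_clusters", setdiff(class(out), "isotope_clusters"))
  attr(out, "rejected_peaks") <- tibble::as_tibble(rej)
  out
}

#' Peaks rejected during cluster validation
#'
#' @param validated Result of [validate_clusters()].
#' @return Tibble of rejected peaks (possibly empty).
#' @export
rejected_peaks <- function(validated) {
  rej <- attr(validated, "rejected_peaks")
  if (is.null(rej)) tibble::tibble() else rej
}
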