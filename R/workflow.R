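# End-to-end workflow: traditional peak table -> predicted isotope ROIs ->
# targeted picking at a relaxed threshold -> merged table -> coelution
# grouping -> putative cluster detection -> mass-specific validation ->
# performance metrics.

#' Run the isotope cluster detection and validation workflow
#'
#' Starting from a traditional peak table (supplied directly, or extracted
#' from a raw map via `examine_rois()` over user-supplied ROIs), the workflow
#' (1) predicts isotope ROIs from the detected peaks, (2) performs targeted
#' peak picking on the raw map at the relaxed signal-to-noise threshold
#' `snthr * r / 100`, (3) merges traditional and targeted peak tables
#' dropping redundant peaks, (4) groups coeluting peaks, (5) detects putative
#' isotope clusters per group, (6) validates them against mass-window
#' abundance-ratio intervals, and (7) computes performance metrics. Steps 1-3
#' are skipped when no raw map is given.
#'
#' @param peaks Traditional peak tibble (see [read_peaks_csv()] for the
#'   contract). May be `NULL` if `raw` and `user_rois` are given.
#' @param raw Optional raw-map tibble for targeted picking.
#' @param user_rois Optional ROI tibble examined at `snthr` to produce the
#'   traditional peaks when `peaks` is `NULL`.
#' @param tables `quantile_table_set` for validation
#'   (default [default_quantile_tables()]).
#' @param Z,I Maximum charge state and isotope number (defaults 3 and 5).
#' @param snthr Traditional signal-to-noise threshold (default 25).
#' @param r Relaxation factor in percent for targeted picking (default 25,
#'   i.e. snthr' = 6.25 at snthr = 25).
#' @param ppm_tol,abs_tol Pair tolerances for detection and merging
#'   (defaults 0 ppm, 0.01 Da).
#' @param rt_tol Retention-time tolerance for merging and coelution grouping
#'   (default 5 s).
#' @param p_low,p_high Validation interval probabilities (defaults
#'   0.005/0.995).
#' @param validate Set `FALSE` to skip mass-specific validation.
#' @param out_dir Optional directory; when given, every stage's output is
#'   written as CSV.
#' @param seed Seed for the noise-ROI control sampling.
#' @return List of class `isotope_workflow`: `peaks` (merged table),
#'   `iso_rois`, `targeted_peaks`, `clusters` (putative), `validated`,
#'   `rejected`, `summary` (one-row metrics tibble), `log` (per-stage
#'   counts).
#' @examples
#' wf <- run_workflow(peaks = table1_spectrum(), validate = FALSE)
#' wf$summary
#' @export
run_workflow <- function(peaks = NULL, raw = NULL, user_rois = NULL,
                         tables = default_quantile_tables(),
                         Z = 3, I = 5, snthr = 25, r = 25,
                         ppm_tol = 0, abs_tol = 0.01, rt_tol = 5,
                         p_low = 0.005, p_high = 0.995,
                         validate = TRUE, out_dir = NULL, seed = 1) {
  log <- list()
  if (is.null(peaks)) {
    if (is.null(raw) || is.null(user_rois)) {
      stop("supply `peaks`, or both `raw` and `user_rois`", call. = FALSE)
    }
    peaks <- examine_rois(raw, user_rois, snthr = snthr)
    peaks$provenance <- "traditional"
  }
  if (!"id" %in% names(peaks)) peaks$id <- paste0("p", seq_len(nrow(peaks)))
  log$traditional_peaks <- nrow(peaks)

  iso_rois <- NULL
  targeted <- NULL
  merged <- peaks
  if (!is.null(raw) && nrow(peaks) > 0) {
    iso_rois <- predict_isotope_rois(peaks, Z = Z, I = I)
    targeted <- examine_rois(raw, iso_rois,
                             snthr = relaxed_threshold(snthr, r))
    if (nrow(targeted) > 0) {
      targeted$id <- paste0("t", seq_len(nrow(targeted)))
    }
    merged <- merge_peak_tables(peaks, targeted, ppm_tol = ppm_tol,
                                abs_tol = abs_tol, rt_tol = rt_tol)
    log$isotope_rois <- nrow(iso_rois)
    log$targeted_peaks <- if (is.null(targeted)) 0L else nrow(targeted)
  }
  log$merged_peaks <- nrow(merged)

  grouped <- group_coeluting(merged, rt_tol = rt_tol)
  clusters <- dplyr::bind_rows(lapply(split(grouped, grouped$group),
    function(g) {
      find_putative_clusters(g, Z = Z, ppm_tol = ppm_tol, abs_tol = abs_tol)
    }))
  if (nrow(clusters) == 0) clusters <- empty_clusters()
  if (nrow(clusters) > 0) {
    # renumber cluster ids globally, ordered by monoisotopic m/z
    firsts <- tapply(seq_len(nrow(clusters)),
                     cumsum(clusters$isotope_index == 0), min)
    new_id <- integer(nrow(clusters))
    ord <- order(clusters$mz[firsts])
    for (k in seq_along(firsts)) {
      lo <- firsts[k]
      hi <- if (k < length(firsts)) firsts[k + 1] - 1 else nrow(clusters)
      new_id[lo:hi] <- match(k, ord)
    }
    clusters$cluster_id <- new_id
    clusters <- clusters[order(clusters$cluster_id, clusters$isotope_index), ]
  }
  class(clusters) <- c("isotope_clusters", setdiff(class(clusters),
                                                   "isotope_clusters"))
  log$putative_clusters <- length(unique(clusters$cluster_id))

  if (validate && nrow(clusters) > 0) {
    validated <- validate_clusters(clusters, peaks = merged, tables = tables,
                                   p_low = p_low, p_high = p_high)
  } else {
    validated <- clusters
  }
  log$validated_clusters <- length(unique(validated$cluster_id))

  qt1 <- if (!is.null(tables)) tables[["1"]] else NULL
  summary <- evaluate_peaks(merged, validated, quantile_table = qt1)

  out <- list(peaks = merged, iso_rois = iso_rois, targeted_peaks = targeted,
              clusters = clusters, validated = validated,
              rejected = rejected_peaks(validated), summary = summary,
              log = log)
  class(out) <- "isotope_workflow"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peaks_csv(merged, file.path(out_dir, "peaks.csv"))
    if (!is.null(iso_rois)) {
      write_rois_csv(iso_rois, file.path(out_dir, "isotope_rois.csv"))
    }
    write_clusters_csv(clusters, file.path(out_dir, "clusters_putative.csv"))
    write_clusters_csv(validated, file.path(out_dir, "clusters_validated.csv"))
    utils::write.csv(as.data.frame(summary),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.isotope_workflow <- function(x, ...) {
  cat("<isotope_workflow>\n")
  for (nm in names(x$log)) cat("  ", nm, ": ", x$log[[nm]], "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_workflow
#' @param x An `isotope_workflow`.
#' @param ... Unused.
#' @export
tidy.isotope_workflow <- function(x, ...) {
  tidy(x$validated)
}

#' @rdname run_workflow
#' @export
glance.isotope_workflow <- function(x, ...) {
  x$summary
}
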