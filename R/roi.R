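# Targeted peak picking support: predicted isotope ROIs, matched noise ROIs,
# the relaxed signal-to-noise threshold, a lightweight ROI examination, and
# merging of traditional and targeted peak tables.

#' Predict isotope regions of interest from a peak table
#'
#' For each detected peak, one ROI is predicted per charge state z in 1..Z
#' and isotope number i in 1..I: the peak's retention-time interval combined
#' with its m/z interval shifted by [isotope_mz_shift()]. The ROIs mark where
#' isotope peaks of the (putatively monoisotopic) source peak must appear.
#'
#' @param peaks Peak tibble with columns `mz`, `rt`, `mz_width`, `rt_width`
#'   (full widths) and optionally `id`.
#' @param Z Maximum charge state (default 3).
#' @param I Maximum isotope number (default 5).
#' @param merge_overlaps If `TRUE`, ROIs overlapping in both dimensions are
#'   merged into their bounding rectangle (default `FALSE`: exactly
#'   `nrow(peaks) * Z * I` ROIs are returned).
#' @return ROI tibble with columns `mz_min`, `mz_max`, `rt_min`, `rt_max`,
#'   `origin` (`"isotope"`), `z`, `i`, `source_peak`.
#' @examples
#' pk <- tibble::tibble(id = "p1", mz = 363.075, rt = 291,
#'                      mz_width = 0.02, rt_width = 10)
#' predict_isotope_rois(pk, Z = 3, I = 5)
#' @export
predict_isotope_rois <- function(peaks, Z = 3, I = 5, merge_overlaps = FALSE) {
  stopifnot(is.data.frame(peaks), Z >= 1, I >= 1)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(mz_min = numeric(), mz_max = numeric(),
                          rt_min = numeric(), rt_max = numeric(),
                          origin = character(), z = integer(), i = integer(),
                          source_peak = character()))
  }
  if (!"id" %in% names(peaks)) peaks$id <- paste0("p", seq_len(nrow(peaks)))
  grid <- tidyr::expand_grid(k = seq_len(nrow(peaks)),
                             z = seq_len(Z), i = seq_len(I))
  shift <- isotope_mz_shift(grid$z, grid$i)
  out <- tibble::tibble(
    mz_min = peaks$mz[grid$k] - peaks$mz_width[grid$k] / 2 + shift,
    mz_max = peaks$mz[grid$k] + peaks$mz_width[grid$k] / 2 + shift,
    rt_min = peaks$rt[grid$k] - peaks$rt_width[grid$k] / 2,
    rt_max = peaks$rt[grid$k] + peaks$rt_width[grid$k] / 2,
    origin = "isotope",
    z = as.integer(grid$z),
    i = as.integer(grid$i),
    source_peak = as.character(peaks$id)[grid$k]
  )
  if (merge_overlaps) out <- .merge_roi_overlaps(out)
  out
}

.merge_roi_overlaps <- function(rois) {
  n <- nrow(rois)
  if (n < 2) return(rois)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (rois$mz_min[a] <= rois$mz_max[b] && rois$mz_min[b] <= rois$mz_max[a] &&
          rois$rt_min[a] <= rois$rt_max[b] && rois$rt_min[b] <= rois$rt_max[a]) {
        parent[find(b)] <- find(a)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dplyr::summarise(
    dplyr::group_by(rois, root = root),
    mz_min = min(.data$mz_min), mz_max = max(.data$mz_max),
    rt_min = min(.data$rt_min), rt_max = max(.data$rt_max),
    origin = dplyr::first(.data$origin),
    z = dplyr::first(.data$z), i = dplyr::first(.data$i),
    source_peak = dplyr::first(.data$source_peak),
    .groups = "drop"
  )[-1]
}

# sample one value from the histogram of x: pick a bin by frequency, then
# uniform within the bin (50 equal-width bins)
.hist_sample <- function(x, n_out, bins = 50) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0) stop("no finite positive widths to sample from",
                           call. = FALSE)
  if (length(unique(x)) == 1) return(rep(x[1], n_out))
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  bin <- sample(seq_along(h$counts), n_out, replace = TRUE, prob = h$counts)
  stats::runif(n_out, h$breaks[bin], h$breaks[bin + 1])
}

#' Sample matched control (noise) ROIs
#'
#' For each predicted isotope ROI one noise ROI is sampled: its center m/z
#' and retention time are drawn uniformly within the min/max envelope of the
#' predicted ROIs' centers, its relative m/z width and rt width are drawn
#' from histograms of the detected peaks' widths. Noise ROIs quantify how
#' many peaks targeted picking would find at random locations.
#'
#' @param iso_rois ROI tibble from [predict_isotope_rois()] (non-empty).
#' @param peaks Detected peak tibble with `mz`, `mz_width`, `rt_width`.
#' @param seed Integer RNG seed (sampling is deterministic under it).
#' @return ROI tibble of the same size with `origin = "noise"`.
#' @export
sample_noise_rois <- function(iso_rois, peaks, seed = 1) {
  stopifnot(is.data.frame(iso_rois), is.data.frame(peaks))
  if (nrow(iso_rois) == 0) stop("`iso_rois` must be non-empty", call. = FALSE)
  n <- nrow(iso_rois)
  mz_c <- (iso_rois$mz_min + iso_rois$mz_max) / 2
  rt_c <- (iso_rois$rt_min + iso_rois$rt_max) / 2
  .with_seed(seed, {
    mz0 <- stats::runif(n, min(mz_c), max(mz_c))
    rt0 <- stats::runif(n, min(rt_c), max(rt_c))
    mzw <- .hist_sample(peaks$mz_width / peaks$mz, n) * mz0
    rtw <- .hist_sample(peaks$rt_width, n)
    tibble::tibble(
      mz_min = mz0 - mzw / 2, mz_max = mz0 + mzw / 2,
      rt_min = rt0 - rtw / 2, rt_max = rt0 + rtw / 2,
      origin = "noise", z = NA_integer_, i = NA_integer_,
      source_peak = NA_character_
    )
  })
}

#' Relaxed signal-to-noise threshold for targeted picking
#'
#' Targeted peak picking runs at `snthr * r / 100`, a fraction of the
#' traditional threshold; `r` is restricted to the grid 5, 10, ..., 100
#' percent. The recommended operating point is r = 25, i.e. snthr' = 6.25 for
#' snthr = 25.
#'
#' @param snthr Traditional signal-to-noise threshold (> 0).
#' @param r Relaxation factor in percent, one of 5, 10, ..., 100.
#' @return The relaxed threshold snthr'.
#' @examples
#' relaxed_threshold(25, 25)  # 6.25
#' @export
relaxed_threshold <- function(snthr, r = 25) {
  if (snthr <= 0) stop("`snthr` must be > 0", call. = FALSE)
  if (!r %in% seq(5, 100, by = 5)) {
    stop("`r` must be one of 5, 10, ..., 100", call. = FALSE)
  }
  snthr * r / 100
}

#' Examine ROIs in a raw map and extract chromatographic peaks
#'
#' A lightweight ROI examination: per ROI the extracted-ion trace (maximum
#' intensity per scan within the m/z interval) is built and its largest local
#' maximum is the peak apex. The local noise level is estimated as the median
#' intensity of centroids in the m/z regions flanking the ROI (between
#' `noise_gap` and `noise_pad` dalton beside it, over an extended
#' retention-time span);
#' when the flanks hold no centroids, the median of the trace outside the
#' apex's half-height span is used instead. The estimate is floored at 1
#' count and a peak is emitted when apex/noise reaches `snthr`. Peak
#' intensity is the trapezoidal area of the trace. The interface accepts
#' externally produced peak tables throughout the package, so a full
#' wavelet-based picker can be substituted.
#'
#' @param raw Raw map tibble (`scan`, `rt`, `mz`, `intensity`), centroided.
#' @param rois ROI tibble (`mz_min`, `mz_max`, `rt_min`, `rt_max`, optional
#'   `origin`). ROIs outside the raw map's range are skipped with a message.
#' @param snthr Signal-to-noise threshold applied to apex/noise.
#' @param noise_pad Width (dalton) of the flanking m/z regions used for the
#'   local noise estimate (default 0.2). The noise window extends the ROI's
#'   retention-time span twofold on either side.
#' @param noise_gap Guard band (dalton) between the ROI and its flanks,
#'   keeping jittered signal centroids out of the noise estimate
#'   (default 0.01).
#' @return Peak tibble (`id`, `mz`, `rt`, `intensity`, `sn`, `mz_width`,
#'   `rt_width`, `provenance`, `roi_index`).
#' @export
examine_rois <- function(raw, rois, snthr = 25, noise_pad = 0.2,
                         noise_gap = 0.01) {
  stopifnot(is.data.frame(raw), is.data.frame(rois))
  scan_rts <- sort(unique(raw$rt))
  out <- vector("list", nrow(rois))
  skipped <- 0L
  for (k in seq_len(nrow(rois))) {
    roi <- rois[k, ]
    if (roi$mz_max < min(raw$mz) || roi$mz_min > max(raw$mz) ||
        roi$rt_max < scan_rts[1] || roi$rt_min > scan_rts[length(scan_rts)]) {
      skipped <- skipped + 1L
      next
    }
    rts <- scan_rts[scan_rts >= roi$rt_min & scan_rts <= roi$rt_max]
    if (length(rts) < 3) next
    pts <- raw[raw$mz >= roi$mz_min & raw$mz <= roi$mz_max &
                 raw$rt >= roi$rt_min & raw$rt <= roi$rt_max, ]
    if (nrow(pts) == 0) next
    trace <- vapply(rts, function(t) {
      y <- pts$intensity[pts$rt == t]
      if (length(y)) max(y) else 0
    }, numeric(1))
    apex_i <- which.max(trace)
    apex <- trace[apex_i]
    if (apex <= 0) next
    # contiguous half-height span around the apex
    lo <- apex_i
    while (lo > 1 && trace[lo - 1] >= apex / 2) lo <- lo - 1
    hi <- apex_i
    while (hi < length(trace) && trace[hi + 1] >= apex / 2) hi <- hi + 1
    span_rt <- roi$rt_max - roi$rt_min
    flank <- raw$intensity[
      ((raw$mz >= roi$mz_min - noise_pad & raw$mz < roi$mz_min - noise_gap) |
         (raw$mz > roi$mz_max + noise_gap &
            raw$mz <= roi$mz_max + noise_pad)) &
        raw$rt >= roi$rt_min - 2 * span_rt &
        raw$rt <= roi$rt_max + 2 * span_rt]
    noise <- if (length(flank) > 0) {
      max(stats::median(flank), 1)
    } else {
      outside <- trace[-(lo:hi)]
      if (length(outside) == 0) 1 else max(stats::median(outside), 1)
    }
    sn <- apex / noise
    if (sn < snthr) next
    area <- sum(diff(rts) * (utils::head(trace, -1) + utils::tail(trace, -1)) / 2)
    span <- pts[pts$rt >= rts[lo] & pts$rt <= rts[hi], ]
    mz_est <- sum(span$mz * span$intensity) / sum(span$intensity)
    prov <- if (!"origin" %in% names(rois) || is.na(roi$origin)) {
      "traditional"
    } else {
      switch(roi$origin, isotope = "targeted-isotope",
             noise = "targeted-noise", "traditional")
    }
    out[[k]] <- tibble::tibble(
      mz = mz_est, rt = rts[apex_i], intensity = area, sn = sn,
      mz_width = max(max(span$mz) - min(span$mz), 1e-4),
      rt_width = max(rts[hi] - rts[lo], rts[2] - rts[1]),
      provenance = prov, roi_index = k
    )
  }
  if (skipped > 0) {
    message(skipped, " ROI(s) outside the raw map's range were skipped")
  }
  res <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(res) == 0) {
    return(tibble::tibble(id = character(), mz = numeric(), rt = numeric(),
                          intensity = numeric(), sn = numeric(),
                          mz_width = numeric(), rt_width = numeric(),
                          provenance = character(), roi_index = integer()))
  }
  dplyr::bind_cols(tibble::tibble(id = paste0("roi", res$roi_index)), res)
}

#' Merge a traditional and a targeted peak table
#'
#' Appends `added` to `base`, dropping added peaks that are redundant with a
#' base peak or with an added peak accepted before them: within
#' `max(mz * ppm_tol/1e6, abs_tol)` in m/z and within `rt_tol` in retention
#' time. Base peaks are always retained. The result is sorted by (rt, mz).
#'
#' @param base,added Peak tibbles with `mz` and `rt` columns.
#' @param ppm_tol Relative m/z tolerance in ppm (default 0).
#' @param abs_tol Absolute m/z tolerance in dalton (default 0.01).
#' @param rt_tol Retention-time tolerance in seconds (default 5).
#' @return Combined peak tibble.
#' @export
merge_peak_tables <- function(base, added, ppm_tol = 0, abs_tol = 0.01,
                              rt_tol = 5) {
  stopifnot(is.data.frame(base), is.data.frame(added),
            ppm_tol >= 0, abs_tol >= 0, rt_tol >= 0)
  if (nrow(added) > 0) {
    ref_mz <- base$mz
    ref_rt <- base$rt
    keep <- logical(nrow(added))
    for (k in seq_len(nrow(added))) {
      tol <- max(added$mz[k] * ppm_tol / 1e6, abs_tol)
      dup <- length(ref_mz) > 0 &&
        any(abs(ref_mz - added$mz[k]) <= tol &
              abs(ref_rt - added$rt[k]) <= rt_tol)
      if (!dup) {
        keep[k] <- TRUE
        ref_mz <- c(ref_mz, added$mz[k])
        ref_rt <- c(ref_rt, added$rt[k])
      }
    }
    added <- added[keep, ]
  }
  out <- dplyr::bind_rows(base, added)
  dplyr::arrange(out, .data$rt, .data$mz)
}
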