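# Readers and writers for the package's tabular interfaces (peak tables, ROI
# lists, cluster tables, formula lists) and the mzML raw-data interface.

#' Read and write peak tables as CSV
#'
#' Peak table CSV contract: columns `id`, `mz` (dalton), `rt` (seconds),
#' `intensity` (counts), `sn`, `mz_width`, `rt_width` (full widths),
#' `provenance`. Missing optional columns are tolerated on read.
#'
#' @param peaks Peak tibble.
#' @param path File path.
#' @return `read_peaks_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!"id" %in% names(df)) df$id <- paste0("p", seq_len(nrow(df)))
  df$id <- as.character(df$id)
  df
}

#' Read and write ROI lists as CSV
#'
#' ROI CSV contract: `mz_min`, `mz_max`, `rt_min`, `rt_max`, `origin`,
#' `z`, `i`, `source_peak`.
#'
#' @param rois ROI tibble.
#' @param path File path.
#' @return `read_rois_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_rois_csv <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Read and write cluster tables as CSV
#'
#' Cluster CSV contract: `cluster_id`, `charge`, `isotope_index`, `peak_id`,
#' `mz`, `intensity`, `validated`. `write_clusters_csv()` also writes a
#' `<path>_rejected.csv` sidecar when validation rejected peaks.
#'
#' @param clusters `isotope_clusters` tibble.
#' @param path File path.
#' @return `read_clusters_csv()` returns an `isotope_clusters` tibble; the
#'   writer returns `path` invisibly.
#' @export
write_clusters_csv <- function(clusters, path) {
  utils::write.csv(as.data.frame(clusters), path, row.names = FALSE)
  rej <- attr(clusters, "rejected_peaks")
  if (!is.null(rej) && nrow(rej) > 0) {
    utils::write.csv(as.data.frame(rej),
                     sub("\\.csv$", "_rejected.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_clusters_csv
#' @export
read_clusters_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  out$peak_id <- as.character(out$peak_id)
  class(out) <- c("isotope_clusters", class(out))
  out
}

#' Read a molecular-formula list
#'
#' Accepts either a plain text file with one formula per line (blank lines
#' and `#` comments ignored) or a CSV with a `formula` column.
#'
#' @param path File path.
#' @return Character vector of formula strings.
#' @export
read_formula_list <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- utils::read.csv(path)
    if (!"formula" %in% names(df)) {
      stop("CSV formula list must have a `formula` column", call. = FALSE)
    }
    return(as.character(df$formula))
  }
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read and write centroided raw maps as mzML
#'
#' Thin wrappers around the `mzR` package (Bioconductor). Reading returns the
#' tabular raw-map representation used throughout the package; writing emits
#' one centroid MS1 spectrum per scan.
#'
#' @param path mzML file path.
#' @param raw Raw-map tibble (`scan`, `rt`, `mz`, `intensity`).
#' @return `read_raw_mzml()` returns a raw-map tibble; `write_raw_mzml()`
#'   returns `path` invisibly.
#' @export
read_raw_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("package `mzR` is required to read mzML", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  keep <- which(hdr$msLevel == 1)
  out <- purrr::map_dfr(seq_along(keep), function(j) {
    sp <- mzR::peaks(h, keep[j])
    if (nrow(sp) == 0) return(NULL)
    tibble::tibble(scan = j, rt = hdr$retentionTime[keep[j]],
                   mz = sp[, 1], intensity = sp[, 2])
  })
  class(out) <- c("raw_map", class(out))
  out
}

#' @rdname read_raw_mzml
#' @export
write_raw_mzml <- function(raw, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("package `mzR` is required to write mzML", call. = FALSE)
  }
  scans <- sort(unique(raw$scan))
  pks <- lapply(scans, function(s) {
    x <- raw[raw$scan == s, ]
    x <- x[order(x$mz), ]
    cbind(mz = x$mz, intensity = x$intensity)
  })
  rts <- vapply(scans, function(s) raw$rt[raw$scan == s][1], numeric(1))
  hdr <- data.frame(
    seqNum = seq_along(scans), acquisitionNum = seq_along(scans),
    msLevel = 1L, polarity = 1L,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rts,
    basePeakMZ = vapply(pks, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(p) if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_along(scans)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}
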