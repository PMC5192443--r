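# Detection of putative isotope clusters in a coeluting peak group.
#
# Pairs of peaks are marked when the difference of their m/z spacing from the
# expected isotope spacing (1.003355/z) is within a mass tolerance; maximal
# gap-free chains of marked pairs form putative clusters, and clusters are
# retained greedily by size (largest first, peaks removed, repeat).

#' Pair tolerance for the isotope spacing test
#'
#' The allowed deviation of an observed peak spacing from the expected isotope
#' spacing: the maximum of a relative (ppm, referenced to the cluster's
#' monoisotopic mass) and an absolute (dalton) mass error.
#'
#' @param mono_mass Monoisotopic m/z of the (putative) cluster, dalton.
#' @param ppm_tol Relative mass error in ppm.
#' @param abs_tol Absolute mass error in dalton.
#' @return Tolerance in dalton.
#' @examples
#' pair_tolerance(121.019749, 73.9, 0)
#' pair_tolerance(300, 0, 0.01)
#' @export
pair_tolerance <- function(mono_mass, ppm_tol = 0, abs_tol = 0.01) {
  if (any(mono_mass <= 0)) stop("`mono_mass` must be > 0", call. = FALSE)
  if (any(ppm_tol < 0) || any(abs_tol < 0)) {
    stop("tolerances must be >= 0", call. = FALSE)
  }
  if (all(ppm_tol == 0) && all(abs_tol == 0)) {
    stop("at least one of `ppm_tol`, `abs_tol` must be positive", call. = FALSE)
  }
  pmax(mono_mass * ppm_tol / 1e6, abs_tol)
}

# Longest gap-free chain starting at every peak for a fixed spacing d and a
# fixed tolerance. mz must be sorted ascending. Returns list(len, nxt):
# len[k] = longest chain length starting at k, nxt[k] = successor index or NA.
# Among successors giving equal continuation length the one closest to the
# expected position wins; remaining ties go to the higher intensity.
.chain_dp <- function(mz, intensity, d, tol) {
  n <- length(mz)
  len <- rep(1L, n)
  nxt <- rep(NA_integer_, n)
  if (n < 2) return(list(len = len, nxt = nxt))
  for (k in (n - 1):1) {
    expected <- mz[k] + d
    cand <- which(abs(mz - expected) <= tol)
    cand <- cand[cand > k]
    if (length(cand) == 0) next
    best_len <- max(len[cand])
    cand <- cand[len[cand] == best_len]
    dev <- abs(mz[cand] - expected)
    cand <- cand[dev == min(dev)]
    if (length(cand) > 1) cand <- cand[which.max(intensity[cand])]
    len[k] <- 1L + best_len
    nxt[k] <- cand[1]
  }
  list(len = len, nxt = nxt)
}

.follow_chain <- function(nxt, start) {
  out <- start
  while (!is.na(nxt[out[length(out)]])) out <- c(out, nxt[out[length(out)]])
  out
}

# Best chain among all charge states and all start peaks.
# Returns list(idx, charge) or NULL. Preference: more peaks, then lower
# monoisotopic m/z, then smaller charge (widest spacing).
.best_chain <- function(mz, intensity, Z, ppm_tol, abs_tol) {
  best <- NULL
  for (z in seq_len(Z)) {
    d <- .delta_m / z
    if (ppm_tol == 0) {
      dp <- .chain_dp(mz, intensity, d, pair_tolerance(1, 0, abs_tol))
      starts <- which(dp$len >= 2)
      for (s in starts) {
        cand <- list(idx = .follow_chain(dp$nxt, s), charge = z)
        best <- .prefer_chain(best, cand, mz)
      }
    } else {
      for (s in seq_along(mz)) {
        tol <- pair_tolerance(mz[s], ppm_tol, abs_tol)
        dp <- .chain_dp(mz, intensity, d, tol)
        if (dp$len[s] < 2) next
        cand <- list(idx = .follow_chain(dp$nxt, s), charge = z)
        best <- .prefer_chain(best, cand, mz)
      }
    }
  }
  best
}

.prefer_chain <- function(best, cand, mz) {
  if (is.null(best)) return(cand)
  if (length(cand$idx) > length(best$idx)) return(cand)
  if (length(cand$idx) == length(best$idx)) {
    if (mz[cand$idx[1]] < mz[best$idx[1]]) return(cand)
    if (mz[cand$idx[1]] == mz[best$idx[1]] && cand$charge < best$charge) {
      return(cand)
    }
  }
  best
}

#' Detect putative isotope clusters in a coeluting peak group
#'
#' For each charge state z in 1..Z, peak pairs whose m/z spacing deviates from
#' the expected isotope spacing 1.003355/z by at most
#' [pair_tolerance()] are marked; maximal gap-free chains of marked successive
#' pairs are the putative isotope clusters. The largest cluster is retained,
#' its peaks removed, and the search repeated until no chain with at least two
#' peaks remains. Ties between equal-size chains go to the lower monoisotopic
#' m/z, then to the smaller charge.
#'
#' @param peaks Peak tibble with at least `mz` and `intensity`; an `id`
#'   column is carried through (created if absent). Peaks are assumed
#'   coeluting (group upstream with [group_coeluting()]).
#' @param Z Maximum charge state (default 3).
#' @param ppm_tol Relative mass error in ppm, referenced to each chain's
#'   monoisotopic m/z (default 0).
#' @param abs_tol Absolute mass error in dalton (default 0.01).
#' @return A tibble of class `isotope_clusters` with one row per cluster
#'   member: `cluster_id`, `charge`, `isotope_index` (0 = monoisotopic),
#'   `peak_id`, `mz`, `intensity`, `validated` (all `FALSE`), sorted by
#'   monoisotopic m/z. Zero-row tibble when no cluster is found.
#' @examples
#' find_putative_clusters(table1_spectrum(), abs_tol = 0.01)
#' @export
find_putative_clusters <- function(peaks, Z = 3, ppm_tol = 0, abs_tol = 0.01) {
  stopifnot(is.data.frame(peaks))
  empty <- empty_clusters()
  if (nrow(peaks) < 2) return(empty)
  if (!"id" %in% names(peaks)) peaks$id <- paste0("p", seq_len(nrow(peaks)))

  ord <- order(peaks$mz)
  mz <- peaks$mz[ord]
  intensity <- peaks$intensity[ord]
  ids <- as.character(peaks$id)[ord]

  avail <- rep(TRUE, length(mz))
  found <- list()
  repeat {
    sel <- which(avail)
    if (length(sel) < 2) break
    best <- .best_chain(mz[sel], intensity[sel], Z, ppm_tol, abs_tol)
    if (is.null(best)) break
    idx <- sel[best$idx]
    found[[length(found) + 1]] <- list(idx = idx, charge = best$charge)
    avail[idx] <- FALSE
  }
  if (length(found) == 0) return(empty)

  found <- found[order(vapply(found, function(cl) mz[cl$idx[1]], numeric(1)))]
  out <- purrr::imap_dfr(found, function(cl, k) {
    tibble::tibble(
      cluster_id = as.integer(k),
      charge = as.integer(cl$charge),
      isotope_index = seq_along(cl$idx) - 1L,
      peak_id = ids[cl$idx],
      mz = mz[cl$idx],
      intensity = intensity[cl$idx],
      validated = FALSE
    )
  })
  class(out) <- c("isotope_clusters", class(out))
  out
}

#' Minimal mass errors required for successful cluster detection
#'
#' Given the ordered peak masses of one singly charged isotope cluster,
#' returns the smallest absolute mass error (dalton) and the smallest
#' relative mass error (ppm, referenced to the monoisotopic mass) with which
#' every successive pair passes the isotope spacing test.
#'
#' @param cluster_masses Strictly increasing numeric vector of at least two
#'   peak masses (dalton), charge 1.
#' @return A one-row tibble with columns `abs_error` (dalton) and
#'   `ppm_error` (ppm).
#' @examples
#' asp <- reference_clusters()
#' minimal_detection_errors(asp$mass[asp$formula == "C4H7NO4"])
#' @export
minimal_detection_errors <- function(cluster_masses) {
  if (length(cluster_masses) < 2) {
    stop("need at least two masses", call. = FALSE)
  }
  if (any(diff(cluster_masses) <= 0)) {
    stop("`cluster_masses` must be strictly increasing", call. = FALSE)
  }
  abs_err <- max(abs(diff(cluster_masses) - .delta_m))
  tibble::tibble(abs_error = abs_err,
                 ppm_error = abs_err / cluster_masses[1] * 1e6)
}

#' An empty cluster table
#'
#' Zero-row `isotope_clusters` tibble with the full column contract; useful
#' as a neutral value when no clusters exist.
#'
#' @return Zero-row `isotope_clusters` tibble.
#' @export
empty_clusters <- function() {
  out <- tibble::tibble(
    cluster_id = integer(), charge = integer(), isotope_index = integer(),
    peak_id = character(), mz = numeric(), intensity = numeric(),
    validated = logical()
  )
  class(out) <- c("isotope_clusters", class(out))
  out
}

#' Group a peak table into coeluting pseudospectrum groups
#'
#' Simple retention-time grouping: peaks sorted by rt are split wherever the
#' gap to the previous peak exceeds `rt_tol`. This is workflow plumbing; any
#' external pseudospectrum assignment can be substituted by supplying a
#' `group` column directly.
#'
#' @param peaks Peak tibble with an `rt` column.
#' @param rt_tol Maximum retention-time gap (seconds) within one group.
#' @return `peaks` with an integer `group` column.
#' @export
group_coeluting <- function(peaks, rt_tol = 5) {
  stopifnot(is.data.frame(peaks), "rt" %in% names(peaks))
  if (nrow(peaks) == 0) return(dplyr::mutate(peaks, group = integer()))
  ord <- order(peaks$rt)
  grp <- cumsum(c(TRUE, diff(peaks$rt[ord]) > rt_tol))
  peaks$group <- NA_integer_
  peaks$group[ord] <- as.integer(grp)
  peaks
}

#' @export
print.isotope_clusters <- function(x, ...) {
  n_cl <- length(unique(x$cluster_id))
  cat("<isotope_clusters> ", n_cl, " cluster(s), ", nrow(x), " peak(s)",
      if (isTRUE(all(x$validated))) ", validated" else "", "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Summarise detected clusters
#'
#' `tidy()` returns one row per cluster (size, charge, monoisotopic m/z);
#' `glance()` returns a one-row overview.
#'
#' @param x An `isotope_clusters` tibble.
#' @param ... Unused.
#' @export
tidy.isotope_clusters <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$cluster_id),
    charge = dplyr::first(.data$charge),
    n_peaks = dplyr::n(),
    mono_mz = min(.data$mz),
    validated = all(.data$validated),
    .groups = "drop"
  )
}

#' @rdname tidy.isotope_clusters
#' @export
glance.isotope_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(unique(x$cluster_id)),
    n_peaks = nrow(x),
    max_size = if (nrow(x)) max(table(x$cluster_id)) else 0L,
    validated = nrow(x) > 0 && all(x$validated)
  )
}

#' Plot detected isotope clusters over a spectrum
#'
#' @param object An `isotope_clusters` tibble.
#' @param peaks Optional full peak table to draw unclustered peaks in grey.
#' @param ... Unused.
#' @export
autoplot.isotope_clusters <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_segment(
      data = peaks,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity),
      colour = "grey70"
    )
  }
  p +
    ggplot2::geom_segment(
      data = object,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                   yend = .data$intensity,
                   colour = factor(.data$cluster_id))
    ) +
    ggplot2::labs(x = "m/z [Da]", y = "intensity", colour = "cluster") +
    ggplot2::theme_minimal()
}
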