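# Theoretical isotope pattern computation.
#
# The isotopologue distribution of a formula is the convolution of the per-atom
# isotope distributions. We convolve sparse (mass, probability) lists, pruning
# negligible terms as we go, then merge centroids that are closer than the
# FWHM implied by the instrument resolution (FWHM = mass/resolution). At
# resolution 10,000 the isotopic fine structure is not resolved, so each
# reported peak is an abundance-weighted mixture of fine-structure peaks.

# Merge entries with (numerically) identical mass; a and b are lists with
# $mass and $prob.
.dist_normalise <- function(mass, prob, prune_rel, mass_cap) {
  keep <- prob >= prune_rel * max(prob)
  if (!is.null(mass_cap)) keep <- keep & (mass <= mass_cap)
  mass <- mass[keep]; prob <- prob[keep]
  ord <- order(mass)
  mass <- mass[ord]; prob <- prob[ord]
  # merge numerically identical masses (same isotopologue composition reached
  # by different convolution orders)
  grp <- cumsum(c(TRUE, diff(mass) > 1e-8))
  list(mass = as.numeric(tapply(mass * prob, grp, sum) / tapply(prob, grp, sum)),
       prob = as.numeric(tapply(prob, grp, sum)))
}

.dist_convolve <- function(a, b, prune_rel = 1e-9, mass_cap_width = NULL) {
  mass <- outer(a$mass, b$mass, `+`)
  prob <- outer(a$prob, b$prob, `*`)
  cap <- if (is.null(mass_cap_width)) NULL else min(mass) + mass_cap_width
  .dist_normalise(as.numeric(mass), as.numeric(prob), prune_rel, cap)
}

# n-fold self-convolution by binary exponentiation
.dist_power <- function(d, n, prune_rel = 1e-9, mass_cap_width = NULL) {
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else
        .dist_convolve(result, base, prune_rel, mass_cap_width)
    }
    n <- n %/% 2
    if (n > 0) base <- .dist_convolve(base, base, prune_rel, mass_cap_width)
  }
  result
}

#' Theoretical isotope pattern of a molecular formula
#'
#' Computes the centroided isotope cluster of a neutral molecular formula by
#' convolving the per-element isotope distributions, merging centroids that
#' fall within the mass resolution, and pruning low-abundance peaks. Peak
#' intensities are normalised so that the most intense peak is 100.
#'
#' @param formula Formula string or `molecular_formula` (non-empty).
#' @param resolution Instrument resolving power; centroids closer than
#'   `mass/resolution` (the implied FWHM) are merged into one peak by
#'   intensity-weighted averaging. Default 10000.
#' @param prune_threshold Minimum peak intensity retained, in percent of the
#'   *monoisotopic* peak's intensity (default 0.01). Use 0 to keep every
#'   computed peak.
#' @param max_isotopes Highest isotope number kept; the pattern comprises the
#'   monoisotopic peak and at most the first `max_isotopes` isotope peaks
#'   (default 5).
#' @param prune_rel Relative probability below which intermediate convolution
#'   terms are dropped (default 1e-9); bounds cost while keeping the fifth
#'   isotope peak accurate.
#' @param mass_weighted If `TRUE` (default), report centroid *areas* at
#'   constant resolving power: peak width scales with mass at fixed R, so the
#'   integrated area of a centroid whose height encodes abundance is
#'   proportional to abundance times mass. If `FALSE`, report plain
#'   isotopologue probabilities.
#' @return A tibble of class `isotope_pattern` with columns `mass` (dalton)
#'   and `rel_intensity` (percent of the base peak), plus attributes
#'   `formula`, `exact_mass`, `resolution`, `prune_threshold` and
#'   `total_prob` (summed isotopologue probability before merging/pruning;
#'   equals 1 up to convolution pruning loss).
#' @examples
#' theoretical_pattern("C4H7NO4")
#' @export
theoretical_pattern <- function(formula, resolution = 10000,
                                prune_threshold = 0.01, max_isotopes = 5,
                                prune_rel = 1e-9, mass_weighted = TRUE) {
  f <- .as_formula(formula)
  if (length(f) == 0) stop("cannot compute a pattern for an empty formula",
                           call. = FALSE)
  if (resolution <= 0) stop("`resolution` must be > 0", call. = FALSE)
  if (prune_threshold < 0) stop("`prune_threshold` must be >= 0", call. = FALSE)

  cap_width <- (max_isotopes + 2) * .delta_m
  dist <- NULL
  for (el in names(f)) {
    iso <- .isotope_data[[el]]
    d <- .dist_power(list(mass = iso$mass, prob = iso$abundance),
                     unclass(f)[[el]], prune_rel, cap_width)
    dist <- if (is.null(dist)) d else
      .dist_convolve(dist, d, prune_rel, cap_width)
  }

  mono_mass <- exact_mass(f)

  # centroid merging at the stated resolution: single-linkage grouping of
  # peaks whose gap to the previous peak is below the local FWHM
  fwhm <- dist$mass / resolution
  grp <- cumsum(c(TRUE, diff(dist$mass) >= fwhm[-1]))
  mass <- as.numeric(tapply(dist$mass * dist$prob, grp, sum) /
                       tapply(dist$prob, grp, sum))
  inten <- as.numeric(tapply(dist$prob, grp, sum))

  # isotope number relative to the monoisotopic (lightest) peak
  iso_n <- round((mass - mono_mass) / .delta_m)
  keep <- iso_n <= max_isotopes
  mass <- mass[keep]; inten <- inten[keep]; iso_n <- iso_n[keep]

  if (mass_weighted) inten <- inten * mass

  mono_idx <- which.min(abs(mass - mono_mass))
  rel <- 100 * inten / max(inten)
  keep <- rel >= prune_threshold * rel[mono_idx] / 100
  keep[mono_idx] <- TRUE
  mass <- mass[keep]; rel <- rel[keep]

  out <- tibble::tibble(mass = mass, rel_intensity = rel)
  attr(out, "formula") <- format(f)
  attr(out, "exact_mass") <- mono_mass
  attr(out, "resolution") <- resolution
  attr(out, "prune_threshold") <- prune_threshold
  attr(out, "total_prob") <- sum(dist$prob)
  class(out) <- c("isotope_pattern", class(out))
  out
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", attr(x, "formula"),
      " (exact mass ", sprintf("%.6f", attr(x, "exact_mass")),
      ", resolution ", attr(x, "resolution"), ")\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname theoretical_pattern
#' @param object An `isotope_pattern`.
#' @param ... Unused.
#' @export
autoplot.isotope_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mass,
                                       xend = .data$mass,
                                       y = 0,
                                       yend = .data$rel_intensity)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::labs(x = "mass [Da]", y = "relative intensity [%]",
                  title = attr(object, "formula")) +
    ggplot2::theme_minimal()
}

#' Write / read a theoretical pattern as CSV
#'
#' @param pattern An `isotope_pattern` tibble.
#' @param path File path.
#' @return `write_pattern_csv()` returns `path` invisibly; `read_pattern_csv()`
#'   returns a tibble with columns `mass` and `rel_intensity`.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern[c("mass", "rel_intensity")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
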