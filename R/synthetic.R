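# Synthetic data generators: molecular-formula databases emulating the
# composition of biological compound collections, and centroided LC-MS raw
# maps with planted isotope clusters and a known ground truth.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Composition classes of the synthetic database. Weights and elemental ratio
# ranges emulate the broad compound classes of biological databases:
# lipid-like (carbon-rich), sugar/organic-acid-like (oxygen-rich),
# nucleotide-like (phosphate- and nitrogen-rich, carbon-poor),
# peptide-like (nitrogen- and sulfur-bearing), and halogenated/aromatic
# natural products (Cl/Br-bearing). The halogen and phosphate classes matter:
# chlorinated and polyphosphorylated compounds define the extreme abundance
# ratios that mass-specific validation must tolerate.
.db_classes <- list(
  lipid      = list(weight = 0.25, hc = c(1.5, 2.1), oc = c(0.02, 0.30),
                    n_lambda = 0.3, s_p = 0.02, p_p = 0.05, cl_p = 0, br_p = 0),
  sugar_acid = list(weight = 0.30, hc = c(1.2, 1.9), oc = c(0.50, 1.30),
                    n_lambda = 0.4, s_p = 0.03, p_p = 0.08, cl_p = 0, br_p = 0),
  nucleotide = list(weight = 0.15, hc = c(1.0, 1.6), oc = c(0.80, 1.40),
                    n_range = c(3, 7), s_p = 0.02, p_counts = 0:3,
                    p_probs = c(0.25, 0.30, 0.25, 0.20), cl_p = 0, br_p = 0),
  peptide    = list(weight = 0.20, hc = c(1.4, 2.0), oc = c(0.25, 0.60),
                    nc = c(0.15, 0.35), s_p = 0.20, p_p = 0, cl_p = 0,
                    br_p = 0),
  halogen    = list(weight = 0.10, hc = c(0.7, 1.5), oc = c(0.05, 0.60),
                    n_lambda = 1.0, s_p = 0.05, p_p = 0, cl_p = 0.75,
                    br_p = 0.12)
)

.draw_class_formula <- function(cls, m_target, w) {
  hc <- stats::runif(1, cls$hc[1], cls$hc[2])
  oc <- stats::runif(1, cls$oc[1], cls$oc[2])
  n_S <- if (stats::runif(1) < cls$s_p * w[["S"]]) 1L + stats::rbinom(1, 1, 0.2) else 0L
  n_P <- if (!is.null(cls$p_counts)) {
    if (w[["P"]] > 0) sample(cls$p_counts, 1, prob = cls$p_probs) else 0L
  } else {
    if (stats::runif(1) < cls$p_p * w[["P"]]) sample(1:2, 1, prob = c(0.7, 0.3)) else 0L
  }
  n_Cl <- if (stats::runif(1) < cls$cl_p * w[["Cl"]]) {
    sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  } else 0L
  n_Br <- if (stats::runif(1) < cls$br_p * w[["Br"]]) {
    sample(1:2, 1, prob = c(0.8, 0.2))
  } else 0L

  per_c <- 12 + hc * 1.0078250319 + oc * 15.9949146221
  nc <- 0
  n_N_fixed <- NULL
  if (!is.null(cls$nc)) {
    nc <- stats::runif(1, cls$nc[1], cls$nc[2]) * w[["N"]]
    per_c <- per_c + nc * 14.0030740052
  } else if (!is.null(cls$n_range)) {
    n_N_fixed <- sample(cls$n_range[1]:cls$n_range[2], 1)
    n_N_fixed <- as.integer(round(n_N_fixed * w[["N"]]))
  } else {
    n_N_fixed <- stats::rpois(1, cls$n_lambda * w[["N"]])
  }

  extras <- n_S * 31.97207069 + n_P * 30.97376151 + n_Cl * 34.96885271 +
    n_Br * 78.9183376 +
    (if (!is.null(n_N_fixed)) n_N_fixed * 14.0030740052 else 0)
  n_C <- as.integer(round((m_target - extras) / per_c))
  if (is.na(n_C) || n_C < 1) return(NULL)
  n_H <- max(as.integer(round(hc * n_C)), 0L)
  n_O <- as.integer(round(oc * n_C))
  n_N <- if (!is.null(n_N_fixed)) n_N_fixed else as.integer(round(nc * n_C))

  counts <- c(C = n_C, H = n_H, N = n_N, O = n_O, S = n_S, P = n_P,
              Cl = n_Cl, Br = n_Br)
  counts <- counts[counts > 0]
  structure(as.integer(counts), names = names(counts),
            class = "molecular_formula")
}

#' Simulate a molecular-formula database
#'
#' Generates random, chemically plausible molecular formulas with exact masses
#' in a given range, drawn from a mixture of composition classes emulating a
#' biological compound database (lipid-like, sugar/acid-like,
#' nucleotide-like, peptide-like, halogenated). Deterministic under `seed`.
#'
#' @param n Number of formulas (>= 1).
#' @param mass_range Numeric length-2: admissible exact-mass interval, dalton.
#' @param element_weights Named multipliers for the heteroatom propensities
#'   (`N`, `S`, `P`, `Cl`, `Br`); e.g. `c(S = 0)` removes sulfur entirely.
#' @param seed Integer RNG seed.
#' @return Character vector of `n` formula strings (Hill notation).
#' @examples
#' simulate_formula_db(10, c(100, 500), seed = 1)
#' @export
simulate_formula_db <- function(n, mass_range = c(50, 1000),
                                element_weights = c(N = 1, S = 1, P = 1,
                                                    Cl = 1, Br = 1),
                                seed = 1) {
  stopifnot(n >= 1, length(mass_range) == 2, mass_range[1] < mass_range[2])
  if (mass_range[2] < 13) stop("mass range infeasible: below one carbon",
                               call. = FALSE)
  w <- c(N = 1, S = 1, P = 1, Cl = 1, Br = 1)
  w[names(element_weights)] <- element_weights
  cls_w <- vapply(.db_classes, `[[`, numeric(1), "weight")
  .with_seed(seed, {
    out <- character(n)
    for (k in seq_len(n)) {
      f <- NULL
      for (try in 1:200) {
        cls <- .db_classes[[sample(length(.db_classes), 1, prob = cls_w)]]
        m_target <- stats::runif(1, mass_range[1], mass_range[2])
        cand <- .draw_class_formula(cls, m_target, w)
        if (is.null(cand)) next
        m <- exact_mass(cand)
        if (m >= mass_range[1] && m < mass_range[2]) {
          f <- cand
          break
        }
      }
      if (is.null(f)) {
        stop("could not generate a formula in the requested mass range",
             call. = FALSE)
      }
      out[k] <- format(f)
    }
    out
  })
}

#' Simulate a centroided LC-MS raw map with planted isotope clusters
#'
#' Plants one isotope cluster per compound: Gaussian elution profiles per
#' isotopologue with apex intensities proportional to the theoretical
#' pattern, centroid m/z jitter, and a uniform noise floor of random centroid
#' peaks. Returns the raw map together with a ground-truth ledger listing
#' every planted isotopologue and its true signal-to-noise ratio
#' (apex intensity / noise level). Deterministic under `seed`.
#'
#' @param compounds Data frame with columns `formula`, `rt` (apex seconds),
#'   `intensity` (monoisotopic apex, counts) and optionally `rt_sigma`
#'   (Gaussian width, seconds, default 5).
#' @param rt_range Length-2 numeric, scan time range in seconds; default
#'   covers all compounds +/- 4 sigma.
#' @param scan_interval Seconds between scans (default 1).
#' @param mz_range m/z range for noise peaks; default spans the planted
#'   isotopologues +/- 5 Da.
#' @param noise_level Median intensity of noise peaks in counts (default 50);
#'   0 disables noise.
#' @param noise_per_scan Number of random noise centroids per scan
#'   (default 60).
#' @param mz_jitter Gaussian m/z jitter of signal centroids, dalton
#'   (default 3e-4).
#' @param resolution,prune_threshold,max_isotopes Passed to
#'   [theoretical_pattern()].
#' @param seed Integer RNG seed.
#' @return List with `raw` (tibble: `scan`, `rt`, `mz`, `intensity`, class
#'   `raw_map`) and `truth` (tibble: `formula`, `isotope`, `mz`, `rt`,
#'   `apex_intensity`, `true_sn`).
#' @examples
#' sim <- simulate_raw_map(
#'   data.frame(formula = "C20H30O5", rt = 120, intensity = 5000),
#'   seed = 7
#' )
#' head(sim$raw)
#' sim$truth
#' @export
simulate_raw_map <- function(compounds, rt_range = NULL, scan_interval = 1,
                             mz_range = NULL, noise_level = 50,
                             noise_per_scan = 60, mz_jitter = 3e-4,
                             resolution = 10000, prune_threshold = 0.01,
                             max_isotopes = 5, seed = 1) {
  stopifnot(is.data.frame(compounds),
            all(c("formula", "rt", "intensity") %in% names(compounds)),
            scan_interval > 0)
  if (!"rt_sigma" %in% names(compounds)) compounds$rt_sigma <- 5
  stopifnot(all(compounds$rt_sigma > 0), all(compounds$intensity > 0))

  patterns <- lapply(compounds$formula, theoretical_pattern,
                     resolution = resolution,
                     prune_threshold = prune_threshold,
                     max_isotopes = max_isotopes)

  truth <- purrr::imap_dfr(patterns, function(pat, k) {
    apex <- compounds$intensity[k] * pat$rel_intensity /
      pat$rel_intensity[which.min(abs(pat$mass - attr(pat, "exact_mass")))]
    tibble::tibble(
      formula = attr(pat, "formula"),
      isotope = round(pat$mass - attr(pat, "exact_mass")),
      mz = pat$mass,
      rt = compounds$rt[k],
      rt_sigma = compounds$rt_sigma[k],
      apex_intensity = apex,
      true_sn = if (noise_level > 0) apex / noise_level else Inf
    )
  })

  if (is.null(rt_range)) {
    rt_range <- c(max(min(compounds$rt - 4 * compounds$rt_sigma), 0),
                  max(compounds$rt + 4 * compounds$rt_sigma))
  }
  if (is.null(mz_range)) {
    mz_range <- c(min(truth$mz) - 5, max(truth$mz) + 5)
  }
  scans <- seq(rt_range[1], rt_range[2], by = scan_interval)

  .with_seed(seed, {
    signal <- purrr::map_dfr(seq_along(scans), function(si) {
      t <- scans[si]
      y <- truth$apex_intensity *
        exp(-(t - truth$rt)^2 / (2 * truth$rt_sigma^2))
      keep <- y >= 0.5
      if (!any(keep)) return(NULL)
      tibble::tibble(
        scan = si, rt = t,
        mz = truth$mz[keep] + stats::rnorm(sum(keep), 0, mz_jitter),
        intensity = y[keep]
      )
    })
    noise <- NULL
    if (noise_level > 0 && noise_per_scan > 0) {
      noise <- purrr::map_dfr(seq_along(scans), function(si) {
        tibble::tibble(
          scan = si, rt = scans[si],
          mz = stats::runif(noise_per_scan, mz_range[1], mz_range[2]),
          intensity = noise_level * stats::runif(noise_per_scan, 0.5, 1.5)
        )
      })
    }
    raw <- dplyr::arrange(dplyr::bind_rows(signal, noise), .data$scan, .data$mz)
    class(raw) <- c("raw_map", class(raw))
    list(raw = raw, truth = dplyr::select(truth, -"rt_sigma"))
  })
}
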