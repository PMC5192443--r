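# Bundled worked-example isotope clusters: six substances covering low/medium
# mass and the elements CHNO, S, Cl and B, with printed centroid masses
# (5 decimals) and relative intensities (percent of the base peak, 2 decimals)
# simulated at resolving power 10,000.

.table1 <- tibble::tribble(
  ~substance,                       ~formula,            ~mass,      ~rel_intensity,
  "aspartic acid",                  "C4H7NO4",           133.037508, 100.00,
  "aspartic acid",                  "C4H7NO4",           134.040468,   4.96,
  "aspartic acid",                  "C4H7NO4",           135.041918,   0.93,
  "aspartic acid",                  "C4H7NO4",           136.044728,   0.04,
  "cysteine",                       "C3H7NO2S",          121.019749, 100.00,
  "cysteine",                       "C3H7NO2S",          122.021976,   4.59,
  "cysteine",                       "C3H7NO2S",          123.016385,   5.05,
  "cysteine",                       "C3H7NO2S",          124.019165,   0.19,
  "cysteine",                       "C3H7NO2S",          125.018404,   0.03,
  "chloramphenicol",                "C11H12Cl2N2O5",     322.012327, 100.00,
  "chloramphenicol",                "C11H12Cl2N2O5",     323.015369,  13.00,
  "chloramphenicol",                "C11H12Cl2N2O5",     324.009595,  66.20,
  "chloramphenicol",                "C11H12Cl2N2O5",     325.012562,   8.53,
  "chloramphenicol",                "C11H12Cl2N2O5",     326.007250,  11.54,
  "chloramphenicol",                "C11H12Cl2N2O5",     327.010016,   1.45,
  "digoxigenin monodigitoxoside",   "C29H44O8",          520.303618, 100.00,
  "digoxigenin monodigitoxoside",   "C29H44O8",          521.307027,  32.24,
  "digoxigenin monodigitoxoside",   "C29H44O8",          522.309803,   6.70,
  "digoxigenin monodigitoxoside",   "C29H44O8",          523.312531,   1.04,
  "digoxigenin monodigitoxoside",   "C29H44O8",          524.315166,   0.13,
  "digoxigenin monodigitoxoside",   "C29H44O8",          525.317742,   0.01,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 524.961858, 100.00,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 525.964411,  13.30,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 526.959596,  35.41,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 527.962023,   4.63,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 528.963673,   1.11,
  "2-chloro-2'-deoxyadenosine-5'-triphosphate", "C10H15ClN5O12P3", 529.966017,   0.12,
  "autoinducer-2",                  "C5H10BO7",          192.055590,  24.37,
  "autoinducer-2",                  "C5H10BO7",          193.052059, 100.00,
  "autoinducer-2",                  "C5H10BO7",          194.055706,   6.13,
  "autoinducer-2",                  "C5H10BO7",          195.056530,   1.59,
  "autoinducer-2",                  "C5H10BO7",          196.059851,   0.09,
  "autoinducer-2",                  "C5H10BO7",          197.060963,   0.01
)

#' Worked-example isotope clusters as a coeluting peak table
#'
#' Returns the bundled reference spectra of six substances (aspartic acid,
#' cysteine, chloramphenicol, digoxigenin monodigitoxoside,
#' 2-chloro-2'-deoxyadenosine-5'-triphosphate, autoinducer-2) as a single
#' coeluting peak table. All six pooled give a synthetic spectrum of 33 peaks
#' whose isotope clusters exercise detection and validation across the
#' elements CHNO, S, Cl and B.
#'
#' @param substances Character vector of substance names (partial, case
#'   insensitive matching); default all six.
#' @param rt Shared retention time assigned to every peak (seconds).
#' @param sn Signal-to-noise ratio assigned to every peak; `Inf` (default)
#'   means noise-free abundances.
#' @return A peak tibble with columns `id`, `mz`, `rt`, `intensity`, `sn`,
#'   `mz_width`, `rt_width`, `provenance`, `substance`, `formula`.
#' @examples
#' table1_spectrum()                  # all 33 peaks
#' table1_spectrum("aspartic acid")   # one 4-peak cluster
#' @export
table1_spectrum <- function(substances = NULL, rt = 300, sn = Inf) {
  all_names <- unique(.table1$substance)
  if (is.null(substances)) {
    sel <- all_names
  } else {
    if (length(substances) == 0) {
      stop("`substances` must name at least one substance", call. = FALSE)
    }
    sel <- vapply(substances, function(s) {
      hit <- all_names[startsWith(tolower(all_names), tolower(s)) |
                         grepl(tolower(s), tolower(all_names), fixed = TRUE)]
      if (length(hit) != 1) {
        stop("unknown or ambiguous substance name: '", s, "'", call. = FALSE)
      }
      hit
    }, character(1), USE.NAMES = FALSE)
  }
  tbl <- .table1[.table1$substance %in% sel, ]
  tibble::tibble(
    id = paste0("t1_", seq_len(nrow(tbl))),
    mz = tbl$mass,
    rt = rt,
    intensity = tbl$rel_intensity,
    sn = sn,
    mz_width = 0.02,
    rt_width = 10,
    provenance = "traditional",
    substance = tbl$substance,
    formula = tbl$formula
  )
}

#' Printed reference values of the worked-example clusters
#'
#' The bundled per-substance reference rows: centroid mass and relative
#' intensity for the monoisotopic peak and up to five isotope peaks of six
#' substances, as used by [table1_spectrum()].
#'
#' @return Tibble with columns `substance`, `formula`, `mass`, `rel_intensity`.
#' @export
reference_clusters <- function() {
  .table1
}
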