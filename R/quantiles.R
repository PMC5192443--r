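# Mass-window quantile statistics of isotope abundance ratios over a compound
# database. For every compound the theoretical pattern gives the ratio of the
# monoisotopic peak to the 1st..5th isotope peak; compounds are grouped by
# exact mass into consecutive windows and per-window p-quantiles form the
# lookup tables used by cluster validation.

# p-grid used for quantile tables (23 values)
.default_p_grid <- sort(c(
  5.0e-6, 0.999995, 1.0e-5, 0.99999, 5.0e-5, 0.99995, 1.0e-4, 0.9999,
  5.0e-4, 0.9995, 0.001, 0.999, 0.005, 0.995, 0.01, 0.99, 0.025, 0.975,
  0.05, 0.95, 0.1, 0.9, 0.5
))

#' Isotope abundance ratios for a list of molecular formulas
#'
#' Computes, for each formula, the exact mass and the theoretical isotope
#' pattern, and records the relative intensity of the monoisotopic and first
#' five isotope peaks together with the ratio of the monoisotopic peak to each
#' isotope peak. Patterns are computed without an abundance prune threshold so
#' that weak high-ratio isotope peaks remain recordable; compounds whose
#' pattern lacks the i-th peak get `NA` for that ratio. Unparseable formulas
#' are skipped with a warning.
#'
#' @param formulas Character vector of formula strings (or list of
#'   `molecular_formula` objects).
#' @param resolution Resolving power for pattern computation (default 10000).
#' @param max_isotopes Highest isotope peak recorded (default 5).
#' @return A tibble with columns `formula`, `exact_mass`, `int_0` ..
#'   `int_<max_isotopes>` (relative intensities, monoisotopic = `int_0`) and
#'   `ratio_1` .. `ratio_<max_isotopes>` (monoisotopic/i-th intensity).
#' @examples
#' compound_ratios(c("C4H7NO4", "C5H10BO7"))
#' @export
compound_ratios <- function(formulas, resolution = 10000, max_isotopes = 5) {
  if (length(formulas) == 0) stop("`formulas` must be non-empty", call. = FALSE)
  rows <- purrr::map(formulas, function(f) {
    pat <- tryCatch(
      theoretical_pattern(f, resolution = resolution, prune_threshold = 0,
                          max_isotopes = max_isotopes),
      error = function(e) NULL
    )
    if (is.null(pat)) return(NULL)
    mono <- attr(pat, "exact_mass")
    iso_n <- round(pat$mass - mono)
    ints <- rep(NA_real_, max_isotopes + 1)
    ok <- iso_n >= 0 & iso_n <= max_isotopes
    ints[iso_n[ok] + 1] <- pat$rel_intensity[ok]
    row <- c(list(formula = attr(pat, "formula"), exact_mass = mono),
             stats::setNames(as.list(ints), paste0("int_", 0:max_isotopes)),
             stats::setNames(as.list(ints[1] / ints[-1]),
                             paste0("ratio_", seq_len(max_isotopes))))
    tibble::as_tibble(row)
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  if (failed > 0) {
    warning(failed, " formula(s) could not be parsed and were skipped",
            call. = FALSE)
  }
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stop("no formula could be parsed", call. = FALSE)
  dplyr::bind_rows(rows)
}

#' Build a mass-window quantile table of isotope abundance ratios
#'
#' Groups compound records by exact mass into consecutive half-open mass
#' windows `[k*w, (k+1)*w)` and computes, per window, the p-quantiles of the
#' ratio between two isotope peaks (by default monoisotopic over i-th).
#' Quantiles use the empirical order statistic with linear interpolation
#' (`stats::quantile()` type 7). Windows without compounds hold `NA`.
#'
#' @param records Tibble from [compound_ratios()].
#' @param window_size Mass window width in dalton, typically one of
#'   10, 25, 50, 100 or 250 (default 50).
#' @param isotope_index Isotope peak (1..5) whose intensity is the ratio
#'   denominator.
#' @param p_grid Probabilities at which quantiles are computed; default is
#'   the bundled 23-value grid.
#' @param ref_index Isotope peak used as the numerator (default 0, the
#'   monoisotopic peak); ordered pairs of isotope peaks are supported.
#' @param source_name Free-text label for the compound source.
#' @return An object of class `quantile_table`: a list with the quantile
#'   `matrix` (rows = p-quantiles, columns = mass windows), `p_grid`,
#'   `window_size`, `window_start`, `counts` (compounds per window),
#'   `isotope_index`, `ref_index` and `source_name`.
#' @examples
#' recs <- compound_ratios(c("C6H12O6", "C10H16N5O13P3", "C20H30O5"))
#' build_quantile_table(recs, window_size = 250, isotope_index = 1)
#' @export
build_quantile_table <- function(records, window_size = 50, isotope_index = 1,
                                 p_grid = NULL, ref_index = 0,
                                 source_name = "user") {
  stopifnot(is.data.frame(records), window_size > 0)
  if (!isotope_index %in% 1:5 && !paste0("int_", isotope_index) %in% names(records)) {
    stop("`isotope_index` must be one of the recorded isotope peaks",
         call. = FALSE)
  }
  if (is.null(p_grid)) p_grid <- .default_p_grid
  p_grid <- sort(unique(p_grid))

  num <- records[[paste0("int_", ref_index)]]
  den <- records[[paste0("int_", isotope_index)]]
  if (is.null(num) || is.null(den)) {
    stop("records lack intensities for the requested isotope peaks",
         call. = FALSE)
  }
  ratio <- num / den
  ok <- !is.na(ratio) & is.finite(ratio) & ratio > 0
  if (!any(ok)) {
    stop("no record has both isotope peaks ", ref_index, " and ",
         isotope_index, call. = FALSE)
  }
  mass <- records$exact_mass[ok]
  ratio <- ratio[ok]

  k <- floor(mass / window_size)
  k_max <- max(k)
  windows <- 0:k_max
  mat <- matrix(NA_real_, nrow = length(p_grid), ncol = length(windows),
                dimnames = list(format(p_grid, scientific = FALSE, trim = TRUE),
                                windows * window_size))
  counts <- integer(length(windows))
  for (j in seq_along(windows)) {
    x <- ratio[k == windows[j]]
    counts[j] <- length(x)
    if (length(x) > 0) {
      mat[, j] <- stats::quantile(x, probs = p_grid, type = 7, names = FALSE)
    }
  }
  structure(
    list(matrix = mat, p_grid = p_grid, window_size = window_size,
         window_start = windows * window_size, counts = counts,
         isotope_index = as.integer(isotope_index),
         ref_index = as.integer(ref_index), source_name = source_name),
    class = "quantile_table"
  )
}

#' Build the full set of validation quantile tables
#'
#' Convenience wrapper building one [build_quantile_table()] per isotope index
#' 1..`max_isotopes` from the same records.
#'
#' @inheritParams build_quantile_table
#' @param max_isotopes Highest isotope index (default 5).
#' @return Named list of `quantile_table` objects (`"1"` .. `"5"`), class
#'   `quantile_table_set`.
#' @export
build_quantile_tables <- function(records, window_size = 50, p_grid = NULL,
                                  max_isotopes = 5, source_name = "user") {
  tabs <- lapply(seq_len(max_isotopes), function(i) {
    build_quantile_table(records, window_size = window_size,
                         isotope_index = i, p_grid = p_grid,
                         source_name = source_name)
  })
  names(tabs) <- as.character(seq_len(max_isotopes))
  structure(tabs, class = "quantile_table_set")
}

#' Look up a ratio confidence interval for a mass
#'
#' Returns the `(p_low, p_high)` quantiles of the mass window containing
#' `mass`. Masses beyond the last populated window clamp to the last populated
#' window; an empty window falls back to the nearest populated one (with a
#' message).
#'
#' @param table A `quantile_table`.
#' @param mass Exact (monoisotopic) mass in dalton; must be > 0.
#' @param p_low,p_high Probabilities; must be members of the table's `p_grid`.
#'   Defaults 0.005 and 0.995, the 99% confidence interval.
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @examples
#' recs <- compound_ratios(c("C6H12O6", "C7H14O6", "C5H9NO4"))
#' qt <- build_quantile_table(recs, window_size = 50, isotope_index = 1)
#' lookup_interval(qt, 180)
#' @export
lookup_interval <- function(table, mass, p_low = 0.005, p_high = 0.995) {
  stopifnot(inherits(table, "quantile_table"))
  if (mass <= 0) stop("`mass` must be > 0", call. = FALSE)
  if (p_low >= p_high) stop("`p_low` must be < `p_high`", call. = FALSE)
  i_low <- match(p_low, table$p_grid)
  i_high <- match(p_high, table$p_grid)
  if (is.na(i_low) || is.na(i_high)) {
    stop("`p_low` and `p_high` must be members of the table's p_grid",
         call. = FALSE)
  }
  j <- .window_index(table, mass)
  c(low = table$matrix[i_low, j], high = table$matrix[i_high, j])
}

# column index of the populated window used for `mass` (clamping beyond the
# last populated window, nearest-populated fallback for empty windows)
.window_index <- function(table, mass) {
  populated <- which(table$counts > 0)
  j <- floor(mass / table$window_size) + 1
  if (j > max(populated)) {
    j <- max(populated)
  } else if (!(j %in% populated)) {
    j_new <- populated[which.min(abs(populated - j))]
    message("mass window [", (j - 1) * table$window_size, ",",
            j * table$window_size, ") is empty; using nearest populated ",
            "window starting at ", table$window_start[j_new])
    j <- j_new
  }
  j
}

#' Look up a single quantile for a mass
#'
#' @inheritParams lookup_interval
#' @param p A probability in the table's `p_grid` (default 0.5, the median).
#' @return The p-quantile of the ratio in the window containing `mass`.
#' @export
lookup_quantile <- function(table, mass, p = 0.5) {
  stopifnot(inherits(table, "quantile_table"))
  if (mass <= 0) stop("`mass` must be > 0", call. = FALSE)
  i <- match(p, table$p_grid)
  if (is.na(i)) stop("`p` must be a member of the table's p_grid",
                     call. = FALSE)
  table$matrix[i, .window_index(table, mass)]
}

#' @export
print.quantile_table <- function(x, ...) {
  cat("<quantile_table> ", x$source_name, ": ratio of isotope peak ",
      x$ref_index, " to ", x$isotope_index, ", window size ", x$window_size,
      " Da, ", length(x$window_start), " windows, ",
      sum(x$counts), " compounds\n", sep = "")
  invisible(x)
}

#' Tidy a quantile table into long format
#'
#' @param x A `quantile_table`.
#' @param ... Unused.
#' @return Tibble with columns `p`, `window_start`, `ratio`, `n_compounds`.
#' @export
tidy.quantile_table <- function(x, ...) {
  tibble::tibble(
    p = rep(x$p_grid, times = length(x$window_start)),
    window_start = rep(x$window_start, each = length(x$p_grid)),
    ratio = as.vector(x$matrix),
    n_compounds = rep(x$counts, each = length(x$p_grid))
  )
}

#' @rdname tidy.quantile_table
#' @export
glance.quantile_table <- function(x, ...) {
  tibble::tibble(
    source_name = x$source_name,
    isotope_index = x$isotope_index,
    window_size = x$window_size,
    n_windows = length(x$window_start),
    n_populated = sum(x$counts > 0),
    n_compounds = sum(x$counts)
  )
}

#' Plot mass-window quantile bands
#'
#' Draws selected quantile curves of the ratio of the monoisotopic to the
#' i-th isotope peak across mass windows, with the enclosed confidence band
#' shaded.
#'
#' @param object A `quantile_table`.
#' @param p_low,p_high Band bounds; must be members of the p-grid.
#' @param ... Unused.
#' @export
autoplot.quantile_table <- function(object, p_low = 0.025, p_high = 0.975,
                                    ...) {
  td <- tidy(object)
  band <- tidyr::pivot_wider(
    dplyr::filter(td, .data$p %in% c(p_low, 0.5, p_high)),
    id_cols = "window_start", names_from = "p", values_from = "ratio"
  )
  names(band) <- c("window_start", "low", "mid", "high")
  ggplot2::ggplot(band, ggplot2::aes(x = .data$window_start)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mid), colour = "darkgreen") +
    ggplot2::geom_line(ggplot2::aes(y = .data$low), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$high), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mass window start [Da]",
                  y = paste0("ratio mono / isotope ", object$isotope_index)) +
    ggplot2::theme_minimal()
}

# ---- serialization ----------------------------------------------------------

.qt_to_list <- function(x) {
  list(source_name = x$source_name, window_size = x$window_size,
       isotope_index = x$isotope_index, ref_index = x$ref_index,
       p_grid = x$p_grid, window_start = x$window_start, counts = x$counts,
       matrix = apply(x$matrix, 1, identity, simplify = FALSE))
}

.qt_from_list <- function(l) {
  num_row <- function(r) {
    vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }
  mat <- do.call(rbind, lapply(l$matrix, num_row))
  dimnames(mat) <- list(format(unlist(l$p_grid), scientific = FALSE,
                               trim = TRUE),
                        unlist(l$window_start))
  structure(
    list(matrix = mat, p_grid = unlist(l$p_grid),
         window_size = l$window_size,
         window_start = unlist(l$window_start),
         counts = as.integer(unlist(l$counts)),
         isotope_index = as.integer(l$isotope_index),
         ref_index = as.integer(l$ref_index),
         source_name = l$source_name),
    class = "quantile_table"
  )
}

#' Read and write quantile tables
#'
#' `write_quantile_table()`/`read_quantile_table()` serialize one
#' `quantile_table` (or a whole `quantile_table_set`) as JSON losslessly.
#' `write_quantile_table_csv()` writes the matrix of one table as CSV
#' (rows = p-quantiles, columns = window start masses).
#'
#' @param x A `quantile_table` or `quantile_table_set`.
#' @param path File path.
#' @return The read functions return the deserialized object; the write
#'   functions return `path` invisibly.
#' @export
write_quantile_table <- function(x, path) {
  payload <- if (inherits(x, "quantile_table_set")) {
    list(type = "quantile_table_set", tables = lapply(x, .qt_to_list))
  } else {
    stopifnot(inherits(x, "quantile_table"))
    list(type = "quantile_table", table = .qt_to_list(x))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_quantile_table
#' @export
read_quantile_table <- function(path) {
  l <- jsonlite::read_json(path)
  if (identical(l$type, "quantile_table_set")) {
    out <- lapply(l$tables, .qt_from_list)
    names(out) <- names(l$tables)
    return(structure(out, class = "quantile_table_set"))
  }
  .qt_from_list(l$table)
}

#' @rdname write_quantile_table
#' @export
write_quantile_table_csv <- function(x, path) {
  stopifnot(inherits(x, "quantile_table"))
  df <- data.frame(p = x$p_grid, x$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic quantile tables
#'
#' Loads the quantile tables shipped with the package, prebuilt from a
#' synthetic molecular-formula database of 20,000 compounds spanning 50-1000
#' Da generated by [simulate_formula_db()] (seed 1), window size 50 Da,
#' isotope peaks 1-5. These emulate the composition of a biological compound
#' database (including halogenated and phosphate-rich compound classes) and
#' make validation usable out of the box without external formula lists.
#'
#' @return A `quantile_table_set` (named list of five `quantile_table`s).
#' @export
default_quantile_tables <- function() {
  cache <- get0(".default_qt_cache", envir = .isoclustr_env)
  if (!is.null(cache)) return(cache)
  path <- system.file("extdata", "quantiles_synthetic_db_w50.json",
                      package = "isoclustr", mustWork = TRUE)
  out <- read_quantile_table(path)
  assign(".default_qt_cache", out, envir = .isoclustr_env)
  out
}

.isoclustr_env <- new.env(parent = emptyenv())
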