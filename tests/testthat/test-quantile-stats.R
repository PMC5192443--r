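test_that("compound ratios reproduce the worked-example intensities", {
  recs <- compound_ratios(c("C4H7NO4", "C5H10BO7"))
  expect_equal(recs$ratio_1[1], 100 / 4.96, tolerance = 0.5 / 20)
  expect_equal(recs$ratio_1[2], 24.37 / 100, tolerance = 0.01 / 0.24)
  expect_error(compound_ratios(character(0)), "non-empty")
  expect_warning(r <- compound_ratios(c("C6H12O6", "Xq9")), "skipped")
  expect_equal(nrow(r), 1)
  expect_error(suppressWarnings(compound_ratios("Xq9")), "no formula")
})

test_that("single-compound windows give constant quantiles", {
  recs <- compound_ratios("C6H12O6")
  qt <- build_quantile_table(recs, window_size = 50, isotope_index = 1)
  col <- qt$matrix[, qt$counts > 0]
  expect_true(all(abs(col - recs$ratio_1[1]) < 1e-12))
})

test_that("window count follows the half-open ceiling arithmetic", {
  recs <- tibble::tibble(
    formula = c("a", "b", "c"), exact_mass = c(10, 500, 990),
    int_0 = 100, int_1 = c(10, 20, 30), int_2 = NA_real_, int_3 = NA_real_,
    int_4 = NA_real_, int_5 = NA_real_,
    ratio_1 = c(10, 5, 10 / 3), ratio_2 = NA_real_, ratio_3 = NA_real_,
    ratio_4 = NA_real_, ratio_5 = NA_real_
  )
  qt <- build_quantile_table(recs, window_size = 50, isotope_index = 1)
  expect_equal(length(qt$window_start), 20)
  expect_error(build_quantile_table(recs, isotope_index = 2), "no record")
})

test_that("window quantiles match the sort-based oracle", {
  # pure-carbon chains: ratios known to vary smoothly with n
  recs <- compound_ratios(sprintf("C%d", 10:60))
  qt <- build_quantile_table(recs, window_size = 50, isotope_index = 1)
  j <- which(qt$window_start == 200)
  in_win <- recs$ratio_1[recs$exact_mass >= 200 & recs$exact_mass < 250]
  expect_equal(qt$matrix[match(0.5, qt$p_grid), j],
               oracle_quantile(in_win, 0.5))
  expect_equal(qt$matrix[, j],
               oracle_quantile(in_win, qt$p_grid), ignore_attr = TRUE)
})

test_that("quantiles are monotone in p and interval bounds are ordered", {
  recs <- small_db_records()
  qt <- build_quantile_table(recs, window_size = 100, isotope_index = 2)
  for (j in which(qt$counts > 0)) {
    expect_true(all(diff(qt$matrix[, j]) >= 0))
  }
  for (m in seq(60, 950, by = 37)) {
    iv <- suppressMessages(lookup_interval(qt, m))
    expect_lte(iv[["low"]], iv[["high"]])
  }
})

test_that("lookup uses half-open windows, clamps and falls back", {
  recs <- tibble::tibble(
    formula = c("a", "b"), exact_mass = c(125, 225),
    int_0 = 100, int_1 = c(10, 20),
    ratio_1 = c(10, 5)
  )
  qt <- build_quantile_table(recs, window_size = 50, isotope_index = 1)
  # mass on a boundary belongs to the upper window (half-open convention)
  expect_equal(lookup_interval(qt, 200)[["low"]], 5)
  expect_equal(lookup_interval(qt, 199.999)[["low"]], 10)
  # beyond the last populated window: clamp
  expect_equal(lookup_interval(qt, 5000)[["low"]], 5)
  # empty middle window: nearest populated fallback, logged
  expect_message(iv <- lookup_interval(qt, 160), "nearest populated")
  expect_equal(iv[["low"]], 10)
  expect_error(lookup_interval(qt, -5), "mass")
  expect_error(lookup_interval(qt, 125, 0.004, 0.995), "p_grid")
})

test_that("median mono/first ratio decreases across mass windows", {
  recs <- small_db_records()
  qt <- build_quantile_table(recs, window_size = 250, isotope_index = 1)
  med <- qt$matrix[match(0.5, qt$p_grid), qt$counts > 0]
  expect_true(all(diff(med) < 0))
})

test_that("ratio tables between arbitrary isotope peaks are supported", {
  recs <- small_db_records()
  qt <- build_quantile_table(recs, window_size = 250, isotope_index = 3,
                             ref_index = 1)
  expect_equal(qt$ref_index, 1L)
  j <- which(qt$counts > 0)[1]
  r <- recs$int_1 / recs$int_3
  in_win <- r[!is.na(r) & r > 0 &
                floor(recs$exact_mass / 250) == (qt$window_start[j] / 250)]
  expect_equal(qt$matrix[match(0.5, qt$p_grid), j],
               oracle_quantile(in_win, 0.5))
})

test_that("quantile table serialization round-trips losslessly", {
  recs <- small_db_records()
  qt <- build_quantile_tables(recs, window_size = 250, max_isotopes = 3,
                              source_name = "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  write_quantile_table(qt, path)
  back <- read_quantile_table(path)
  expect_s3_class(back, "quantile_table_set")
  for (i in as.character(1:3)) {
    expect_equal(back[[i]]$matrix, qt[[i]]$matrix)
    expect_equal(back[[i]]$p_grid, qt[[i]]$p_grid)
    expect_equal(back[[i]]$counts, qt[[i]]$counts)
    expect_equal(back[[i]]$window_start, qt[[i]]$window_start)
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  write_quantile_table_csv(qt[["1"]], csv)
  df <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(df$p, qt[["1"]]$p_grid)
})

test_that("bundled default tables load and look sane", {
  tabs <- default_quantile_tables()
  expect_s3_class(tabs, "quantile_table_set")
  expect_named(tabs, as.character(1:5))
  qt1 <- tabs[["1"]]
  expect_equal(qt1$window_size, 50)
  expect_gte(sum(qt1$counts), 19000)
  med <- qt1$matrix[match(0.5, qt1$p_grid), qt1$counts > 0]
  expect_true(all(diff(med) < 0))
})
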