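test_that("workflow on the worked example detects 6 and validates 6 with one
           rejected peak", {
  pk <- table1_spectrum(sn = 25)
  wf <- suppressMessages(run_workflow(peaks = pk))
  expect_equal(wf$log$putative_clusters, 6)
  expect_equal(wf$log$validated_clusters, 6)
  expect_equal(nrow(wf$rejected), 1)
  expect_equal(wf$summary$n_peaks, 33)
  expect_equal(wf$summary$n_isotope_peaks, 32)
  # fully deterministic: a second run is identical
  wf2 <- suppressMessages(run_workflow(peaks = pk))
  expect_equal(wf$summary, wf2$summary)
  expect_equal(tibble::as_tibble(wf$validated),
               tibble::as_tibble(wf2$validated))
})

test_that("workflow handles an empty peak table gracefully", {
  wf <- run_workflow(peaks = table1_spectrum()[0, ], validate = FALSE)
  expect_equal(wf$summary$n_peaks, 0)
  expect_equal(wf$summary$n_clusters, 0)
  expect_equal(wf$summary$isotope_coverage, 0)
})

test_that("workflow persists every stage as CSV when asked", {
  out <- withr::local_tempdir()
  pk <- table1_spectrum(sn = 25)
  suppressMessages(run_workflow(peaks = pk, out_dir = out))
  expect_true(file.exists(file.path(out, "peaks.csv")))
  expect_true(file.exists(file.path(out, "clusters_putative.csv")))
  expect_true(file.exists(file.path(out, "clusters_validated.csv")))
  expect_true(file.exists(file.path(out, "clusters_validated_rejected.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  back <- read_clusters_csv(file.path(out, "clusters_validated.csv"))
  expect_equal(length(unique(back$cluster_id)), 6)
})

test_that("peak, ROI and cluster CSVs round-trip", {
  pk <- table1_spectrum(sn = 25)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peaks_csv(pk, f)
  back <- read_peaks_csv(f)
  expect_equal(back$mz, pk$mz)
  expect_equal(back$id, pk$id)

  rois <- predict_isotope_rois(pk)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rois_csv(rois, f2)
  expect_equal(read_rois_csv(f2)$mz_min, rois$mz_min)

  cl <- find_putative_clusters(pk)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_clusters_csv(cl, f3)
  back3 <- read_clusters_csv(f3)
  expect_equal(back3$peak_id, cl$peak_id)
  expect_s3_class(back3, "isotope_clusters")
})

test_that("formula lists read from plain text and CSV", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "C6H12O6", "", "C4H7NO4"), f)
  expect_equal(read_formula_list(f), c("C6H12O6", "C4H7NO4"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(formula = c("C2H6", "CH4"), x = 1:2), f2,
                   row.names = FALSE)
  expect_equal(read_formula_list(f2), c("C2H6", "CH4"))
})

test_that("raw maps round-trip through mzML", {
  skip_if_not_installed("mzR")
  sim <- simulate_raw_map(
    data.frame(formula = "C6H12O6", rt = 50, intensity = 2000),
    noise_level = 20, noise_per_scan = 5, seed = 2
  )
  f <- withr::local_tempfile(fileext = ".mzML")
  write_raw_mzml(sim$raw, f)
  back <- read_raw_mzml(f)
  expect_equal(nrow(back), nrow(sim$raw))
  expect_equal(sort(back$mz), sort(sim$raw$mz), tolerance = 1e-6)
  expect_equal(sum(back$intensity), sum(sim$raw$intensity), tolerance = 1e-4)
})

test_that("tidy and glance methods summarise results", {
  pk <- table1_spectrum(sn = 25)
  cl <- find_putative_clusters(pk)
  td <- tidy(cl)
  expect_equal(nrow(td), 6)
  expect_named(td, c("cluster_id", "charge", "n_peaks", "mono_mz",
                     "validated"))
  gl <- glance(cl)
  expect_equal(gl$n_clusters, 6)
  wf <- suppressMessages(run_workflow(peaks = pk))
  expect_equal(glance(wf), wf$summary)
  expect_equal(nrow(tidy(wf)), 6)
})

test_that("autoplot methods return ggplot objects", {
  p1 <- autoplot(theoretical_pattern("C6H12O6"))
  expect_s3_class(p1, "ggplot")
  pk <- table1_spectrum()
  p2 <- autoplot(find_putative_clusters(pk), peaks = pk)
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(default_quantile_tables()[["1"]])
  expect_s3_class(p3, "ggplot")
})

test_that("the command-line interface runs on bundled data", {
  cli <- system.file("exec", "isoclustr", package = "isoclustr")
  if (!nzchar(cli)) cli <- file.path("..", "..", "exec", "isoclustr")
  skip_if(!file.exists(cli), "CLI script not found")
  td <- withr::local_tempdir()
  pk_csv <- file.path(td, "peaks.csv")
  write_peaks_csv(table1_spectrum(sn = 25), pk_csv)
  out_csv <- file.path(td, "clusters.csv")
  res <- system2("Rscript", c(cli, "detect", "--peaks", pk_csv,
                              "--out", out_csv),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_csv))
  cl <- read_clusters_csv(out_csv)
  expect_equal(length(unique(cl$cluster_id)), 6)
  out2 <- file.path(td, "rois.csv")
  system2("Rscript", c(cli, "predict-rois", "--peaks", pk_csv,
                       "--out", out2), stdout = TRUE, stderr = TRUE)
  expect_equal(nrow(read_rois_csv(out2)), 33 * 15)
})
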