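test_that("isotope m/z shifts follow i * delta_m / z", {
  expect_equal(isotope_mz_shift(1, 1), 1.003355)
  expect_equal(isotope_mz_shift(2, 2), 1.003355)
  expect_equal(isotope_mz_shift(3, 5), 5 * 1.003355 / 3, tolerance = 1e-9)
  expect_error(isotope_mz_shift(0, 1), ">= 1")
  expect_error(isotope_mz_shift(1, 0), ">= 1")
})

test_that("relaxed threshold follows snthr * r / 100 on the 5%-grid", {
  expect_equal(relaxed_threshold(25, 25), 6.25)
  expect_equal(relaxed_threshold(25, 100), 25)
  expect_equal(relaxed_threshold(10, 5), 0.5)
  expect_error(relaxed_threshold(25, 26), "must be one of")
  expect_error(relaxed_threshold(0, 25), "snthr")
})

test_that("ROI prediction emits Z*I ROIs per peak with shifted mz windows", {
  pk <- tibble::tibble(id = c("a", "b"), mz = c(363.075, 401.2),
                       rt = c(291, 340), mz_width = 0.02, rt_width = 10)
  rois <- predict_isotope_rois(pk, Z = 3, I = 5)
  expect_equal(nrow(rois), 2 * 3 * 5)
  expect_setequal(unique(rois$origin), "isotope")
  a <- rois[rois$source_peak == "a", ]
  expect_true(all(a$rt_min == 286 & a$rt_max == 296))
  z1 <- a[a$z == 1, ]
  expect_equal((z1$mz_min + z1$mz_max) / 2, 363.075 + 1.003355 * (1:5),
               tolerance = 1e-9)
  # single charge/isotope: plain +delta_m shift
  r11 <- predict_isotope_rois(pk, Z = 1, I = 1)
  expect_equal(nrow(r11), 2)
  expect_equal((r11$mz_min + r11$mz_max) / 2, pk$mz + 1.003355)
  expect_equal(nrow(predict_isotope_rois(pk[0, ])), 0)
})

test_that("ROI prediction is invariant to peak order", {
  pk <- tibble::tibble(id = letters[1:4], mz = c(200, 150, 400, 300),
                       rt = c(10, 20, 30, 40), mz_width = 0.02, rt_width = 8)
  a <- predict_isotope_rois(pk)
  b <- predict_isotope_rois(pk[4:1, ])
  key <- function(x) x[order(x$mz_min, x$rt_min, x$z, x$i), ]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("noise ROIs are one-per-input, inside the envelope, seeded", {
  pk <- tibble::tibble(id = letters[1:5], mz = seq(150, 550, by = 100),
                       rt = seq(50, 250, by = 50),
                       mz_width = runif(5, 0.01, 0.05),
                       rt_width = runif(5, 5, 15))
  iso <- predict_isotope_rois(pk)
  noise <- sample_noise_rois(iso, pk, seed = 42)
  expect_equal(nrow(noise), nrow(iso))
  mz_c <- (iso$mz_min + iso$mz_max) / 2
  rt_c <- (iso$rt_min + iso$rt_max) / 2
  n_mz_c <- (noise$mz_min + noise$mz_max) / 2
  n_rt_c <- (noise$rt_min + noise$rt_max) / 2
  expect_true(all(n_mz_c >= min(mz_c) & n_mz_c <= max(mz_c)))
  expect_true(all(n_rt_c >= min(rt_c) & n_rt_c <= max(rt_c)))
  expect_identical(noise, sample_noise_rois(iso, pk, seed = 42))
  expect_false(identical(noise, sample_noise_rois(iso, pk, seed = 43)))
  expect_error(sample_noise_rois(iso[0, ], pk), "non-empty")
})

test_that("ROI examination finds planted peaks at threshold", {
  sim <- simulate_raw_map(
    data.frame(formula = "C12H22O11", rt = 100, intensity = 5000),
    noise_level = 50, seed = 11
  )
  mono <- sim$truth[sim$truth$isotope == 0, ]
  roi <- tibble::tibble(mz_min = mono$mz - 0.01, mz_max = mono$mz + 0.01,
                        rt_min = mono$rt - 20, rt_max = mono$rt + 20,
                        origin = "isotope")
  hit <- examine_rois(sim$raw, roi, snthr = 25)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mz, mono$mz, tolerance = 0.001)
  expect_equal(hit$provenance, "targeted-isotope")
  # same ROI, prohibitive threshold: no peak
  expect_equal(nrow(examine_rois(sim$raw, roi, snthr = 1e5)), 0)
  # ROI outside the map: skipped with a message
  far <- tibble::tibble(mz_min = 5000, mz_max = 5001, rt_min = 0, rt_max = 50,
                        origin = "noise")
  expect_message(out <- examine_rois(sim$raw, far, snthr = 5), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("peak table merging dedups against base and is idempotent", {
  base <- tibble::tibble(id = paste0("b", 1:5),
                         mz = c(100, 200, 300, 400, 500),
                         rt = c(10, 20, 30, 40, 50), intensity = 1)
  expect_equal(nrow(merge_peak_tables(base, base)), nrow(base))
  far <- dplyr::mutate(base, id = paste0("a", 1:5), mz = mz + 5)
  expect_equal(nrow(merge_peak_tables(base, far)), 10)
  m1 <- merge_peak_tables(base, far)
  m2 <- merge_peak_tables(m1, far)
  expect_equal(m1, m2)
  # randomized quadratic-oracle comparison
  for (seed in 1:10) {
    set.seed(seed)
    b <- tibble::tibble(id = paste0("b", 1:50), mz = runif(50, 100, 110),
                        rt = runif(50, 0, 60), intensity = 1)
    a <- tibble::tibble(id = paste0("a", 1:50), mz = runif(50, 100, 110),
                        rt = runif(50, 0, 60), intensity = 1)
    expect_equal(nrow(merge_peak_tables(b, a, abs_tol = 0.5, rt_tol = 10)),
                 oracle_merge_size(b, a, abs_tol = 0.5, rt_tol = 10))
  }
})

test_that("optional ROI overlap merging reduces overlapping rectangles", {
  pk <- tibble::tibble(id = c("a", "b"), mz = c(300, 300.001),
                       rt = c(100, 100), mz_width = 0.05, rt_width = 10)
  all_rois <- predict_isotope_rois(pk, Z = 1, I = 2)
  merged <- predict_isotope_rois(pk, Z = 1, I = 2, merge_overlaps = TRUE)
  expect_lt(nrow(merged), nrow(all_rois))
  expect_true(all(merged$mz_max > merged$mz_min))
})
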