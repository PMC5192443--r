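test_that("ratio intervals bracket the point ratio and collapse at sn=Inf", {
  expect_equal(ratio_interval(100, Inf, 5, Inf),
               c(low = 20, high = 20))
  ri <- ratio_interval(100, 10, 5, 10)
  expect_equal(ri[["low"]], 90 / 5.5, tolerance = 1e-9)
  expect_equal(ri[["high"]], 110 / 4.5, tolerance = 1e-9)
  for (seed in 1:20) {
    set.seed(seed)
    a1 <- runif(1, 1, 1000); a2 <- runif(1, 1, 1000)
    s1 <- runif(1, 1.1, 100); s2 <- runif(1, 1.1, 100)
    ri <- ratio_interval(a1, s1, a2, s2)
    expect_lte(ri[["low"]], a1 / a2)
    expect_gte(ri[["high"]], a1 / a2)
  }
  expect_error(ratio_interval(-1, 10, 5, 10), "positive")
})

test_that("worked-example validation removes only the boron leading peak", {
  pk <- table1_spectrum(sn = 25)
  cl <- find_putative_clusters(pk, Z = 3, abs_tol = 0.01)
  v <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_true(all(v$validated))
  sizes <- sort(as.integer(table(v$cluster_id)))
  expect_equal(sizes, c(4L, 5L, 5L, 6L, 6L, 6L))
  rej <- rejected_peaks(v)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$mz, 192.055590)
  # the surviving boron cluster starts at the base peak
  auto <- v[abs(v$mz - 193.052059) < 1e-6, ]
  expect_equal(auto$isotope_index, 0L)
})

test_that("overlapping clusters linked by a spurious spacing are separated", {
  # concatenate two CHNO clusters so that the second's monoisotopic peak
  # continues the first chain with a valid spacing but an implausible ratio
  asp <- reference_clusters()
  a <- asp[asp$formula == "C4H7NO4", ]
  shift <- (a$mass[1] + 4 * 1.003355) - a$mass[1]
  b <- tibble::tibble(mass = a$mass + shift, rel_intensity = a$rel_intensity)
  pk <- tibble::tibble(
    id = paste0("p", 1:8),
    mz = c(a$mass, b$mass),
    rt = 100, intensity = c(a$rel_intensity, b$rel_intensity) * 100,
    sn = 50
  )
  cl <- find_putative_clusters(pk, Z = 1, abs_tol = 0.01)
  expect_equal(length(unique(cl$cluster_id)), 1)  # one merged chain
  v <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_equal(length(unique(v$cluster_id)), 2)
  m1 <- v$mz[v$cluster_id == 1 & v$isotope_index == 0]
  m2 <- v$mz[v$cluster_id == 2 & v$isotope_index == 0]
  expect_equal(sort(c(m1, m2)), c(a$mass[1], b$mass[1]))
  expect_equal(nrow(rejected_peaks(v)), 0)
})

test_that("an underestimated trailing peak is truncated", {
  asp <- reference_clusters()
  a <- asp[asp$formula == "C4H7NO4", ]
  pk <- tibble::tibble(
    id = paste0("p", 1:4), mz = a$mass, rt = 100,
    intensity = a$rel_intensity * c(1, 1, 1, 1 / 100) * 100, sn = 50
  )
  cl <- find_putative_clusters(pk, Z = 1, abs_tol = 0.01)
  expect_equal(nrow(cl), 4)
  v <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_equal(nrow(v), 3)
  expect_equal(rejected_peaks(v)$mz, a$mass[4])
})

test_that("a leading hydrogen-loss peak is released as unannotated", {
  asp <- reference_clusters()
  a <- asp[asp$formula == "C4H7NO4", ]
  pk <- tibble::tibble(
    id = paste0("p", 0:4),
    mz = c(a$mass[1] - 1.00783, a$mass), rt = 100,
    intensity = c(2, a$rel_intensity) * 100, sn = 50
  )
  cl <- find_putative_clusters(pk, Z = 1, abs_tol = 0.01)
  v <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_equal(length(unique(v$cluster_id)), 1)
  expect_equal(min(v$mz), a$mass[1])  # hydrogen-loss peak removed
})

test_that("validation is idempotent and output peaks are a subset", {
  pk <- table1_spectrum(sn = 25)
  cl <- find_putative_clusters(pk, abs_tol = 0.01)
  v1 <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_true(all(v1$peak_id %in% cl$peak_id))
  v2 <- suppressMessages(validate_clusters(v1, peaks = pk))
  expect_equal(strip_cl(v2), strip_cl(v1))
  expect_true(all(table(v1$cluster_id) >= 2))
})

test_that("lowering S/N (wider intervals) never increases splits", {
  pk0 <- table1_spectrum()
  cl_of <- function(sn) {
    pk <- table1_spectrum(sn = sn)
    cl <- find_putative_clusters(pk, abs_tol = 0.01)
    v <- suppressMessages(validate_clusters(cl, peaks = pk))
    length(unique(v$cluster_id)) + nrow(rejected_peaks(v))
  }
  frag <- vapply(c(Inf, 100, 25, 5, 2), cl_of, numeric(1))
  expect_true(all(diff(frag) <= 0))
})

test_that("clusters matching the database median pass unchanged", {
  tabs <- default_quantile_tables()
  mono_mass <- 350
  ints <- c(1e5, vapply(1:3, function(i) {
    1e5 / suppressMessages(lookup_quantile(tabs[[as.character(i)]],
                                           mono_mass, 0.5))
  }, numeric(1)))
  pk <- tibble::tibble(
    id = paste0("p", 1:4),
    mz = mono_mass + c(0:3) * 1.003355, rt = 50,
    intensity = ints, sn = Inf
  )
  cl <- find_putative_clusters(pk, Z = 1, abs_tol = 0.01)
  v <- suppressMessages(validate_clusters(cl, peaks = pk))
  expect_equal(nrow(v), 4)
  expect_equal(length(unique(v$cluster_id)), 1)
})

test_that("a missing quantile table for a needed index errors", {
  pk <- table1_spectrum("aspartic", sn = 25)
  cl <- find_putative_clusters(pk, abs_tol = 0.01)
  tabs <- default_quantile_tables()[c("1", "2")]
  class(tabs) <- "quantile_table_set"
  expect_error(
    suppressMessages(validate_clusters(cl, peaks = pk, tables = tabs)),
    "no quantile table"
  )
})
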