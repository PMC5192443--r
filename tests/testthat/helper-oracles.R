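# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive results by brute force (exhaustive enumeration, quadratic search,
# manual order statistics) rather than calling the production code paths.

delta_m_ref <- 1.003355

# --- exhaustive chain enumeration oracle for cluster detection --------------

# all maximal chains (index vectors into mz) for one charge, from one start
.oracle_chains_from <- function(mz, d, tol, start) {
  succ <- function(k) which(abs(mz - (mz[k] + d)) <= tol & mz > mz[k])
  out <- list()
  dfs <- function(chain) {
    s <- succ(chain[length(chain)])
    if (length(s) == 0) {
      out[[length(out) + 1]] <<- chain
      return(invisible())
    }
    for (nx in s) dfs(c(chain, nx))
  }
  dfs(start)
  out
}

# slot-wise chain preference: longer; lower monoisotopic mz; smaller charge;
# then per slot smaller deviation from the expected position, higher intensity
.oracle_better <- function(a, b, mz, intensity) {
  if (is.null(b)) return(TRUE)
  if (length(a$idx) != length(b$idx)) return(length(a$idx) > length(b$idx))
  if (mz[a$idx[1]] != mz[b$idx[1]]) return(mz[a$idx[1]] < mz[b$idx[1]])
  if (a$z != b$z) return(a$z < b$z)
  da <- abs(diff(mz[a$idx]) - delta_m_ref / a$z)
  db <- abs(diff(mz[b$idx]) - delta_m_ref / b$z)
  for (k in seq_along(da)) {
    if (da[k] != db[k]) return(da[k] < db[k])
    ia <- intensity[a$idx[k + 1]]; ib <- intensity[b$idx[k + 1]]
    if (ia != ib) return(ia > ib)
  }
  FALSE
}

# full detection oracle: exhaustive enumeration + greedy retention
oracle_find_clusters <- function(mz, intensity, Z = 3, ppm_tol = 0,
                                 abs_tol = 0.01) {
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  avail <- rep(TRUE, length(mz))
  clusters <- list()
  repeat {
    sel <- which(avail)
    if (length(sel) < 2) break
    best <- NULL
    for (z in seq_len(Z)) {
      d <- delta_m_ref / z
      for (s in seq_along(sel)) {
        tol <- max(mz[sel[s]] * ppm_tol / 1e6, abs_tol)
        for (ch in .oracle_chains_from(mz[sel], d, tol, s)) {
          if (length(ch) < 2) next
          cand <- list(idx = sel[ch], z = z)
          if (.oracle_better(cand, best, mz, intensity)) best <- cand
        }
      }
    }
    if (is.null(best)) break
    clusters[[length(clusters) + 1]] <- best
    avail[best$idx] <- FALSE
  }
  clusters <- clusters[order(vapply(clusters, function(cl) mz[cl$idx[1]],
                                    numeric(1)))]
  lapply(clusters, function(cl) list(mz = mz[cl$idx], charge = cl$z))
}

# random coeluting spectrum with planted chains plus unrelated peaks
random_spectrum <- function(seed, n_max = 12) {
  set.seed(seed)
  peaks <- NULL
  n_chains <- sample(1:2, 1)
  for (k in seq_len(n_chains)) {
    z <- sample(1:3, 1)
    len <- sample(2:5, 1)
    mono <- runif(1, 100, 600)
    jit <- runif(len - 1, -0.008, 0.008)
    mzs <- mono + cumsum(c(0, delta_m_ref / z + jit))
    peaks <- rbind(peaks, cbind(mzs, runif(len, 10, 100)))
  }
  n_noise <- sample(2:4, 1)
  peaks <- rbind(peaks, cbind(runif(n_noise, 100, 600),
                              runif(n_noise, 5, 50)))
  peaks <- peaks[seq_len(min(nrow(peaks), n_max)), , drop = FALSE]
  tibble::tibble(id = paste0("p", seq_len(nrow(peaks))),
                 mz = peaks[, 1], intensity = peaks[, 2])
}

# compare production clustering with the oracle on one spectrum
expect_matches_oracle <- function(spec, Z = 3, abs_tol = 0.01) {
  got <- find_putative_clusters(spec, Z = Z, abs_tol = abs_tol)
  want <- oracle_find_clusters(spec$mz, spec$intensity, Z = Z,
                               abs_tol = abs_tol)
  got_split <- if (nrow(got) == 0) list() else
    lapply(split(got, got$cluster_id), function(g) {
      list(mz = g$mz, charge = g$charge[1])
    })
  names(got_split) <- NULL
  expect_equal(got_split, want)
}

# --- quadratic merge oracle -------------------------------------------------

oracle_merge_size <- function(base, added, ppm_tol = 0, abs_tol = 0.01,
                              rt_tol = 5) {
  acc <- base[, c("mz", "rt")]
  for (k in seq_len(nrow(added))) {
    dup <- FALSE
    for (j in seq_len(nrow(acc))) {
      tol <- max(added$mz[k] * ppm_tol / 1e6, abs_tol)
      if (abs(acc$mz[j] - added$mz[k]) <= tol &&
          abs(acc$rt[j] - added$rt[k]) <= rt_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) acc <- rbind(acc, added[k, c("mz", "rt")])
  }
  nrow(acc)
}

# --- manual order-statistic quantile oracle ---------------------------------

oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# strip the rejected-peaks attribute for content comparisons
strip_cl <- function(x) {
  attr(x, "rejected_peaks") <- NULL
  tibble::as_tibble(x)
}

# --- shared fixtures (cached across tests in one session) -------------------

.fixture_env <- new.env()

small_db_records <- function() {
  if (is.null(.fixture_env$recs)) {
    db <- simulate_formula_db(400, c(50, 1000), seed = 101)
    .fixture_env$recs <- suppressWarnings(compound_ratios(db))
  }
  .fixture_env$recs
}
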