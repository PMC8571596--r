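test_that("make_windows tiles chromosomes on the step grid", {
  w <- make_windows(c(chr1 = 100000))
  expect_equal(w$start, c(0, 20000, 40000, 60000))
  expect_true(all(w$end - w$start == 40000))

  expect_equal(nrow(make_windows(c(chr1 = 40000))), 1)
  expect_equal(nrow(make_windows(c(chr1 = 39999))), 0)

  wp <- make_windows(c(chr1 = 90000), keep_partial = TRUE)
  expect_equal(wp[nrow(wp), "start"], 60000)
  expect_equal(wp[nrow(wp), "end"], 90000)

  expect_warning(make_windows(c(chr1 = 1e6), window_bp = 1000,
                              step_bp = 5000), "gaps")
  expect_error(make_windows(c(chr1 = 1e6), window_bp = 0), "positive")
  expect_error(make_windows(c(chr1 = -5)), "positive")
})

test_that("window_pi matches hand-derived per-site values", {
  # one SNP, 4 chromosomes (2 HG individuals), c = 2: pi_site = 8/12
  gm4 <- make_gm(matrix(c(1, 1, 0, 0), 1, 4), pos = 150)
  pops4 <- make_pops(2, 2)
  w <- list(chrom = "chr1", start = 0, end = 40000)
  expect_equal(window_pi(gm4, pops4, w, "HG"), (8 / 12) / 40000,
               tolerance = 1e-12)
  # monomorphic window
  gm_mono <- make_gm(matrix(0, 1, 4), pos = 150)
  expect_equal(window_pi(gm_mono, pops4, w, "HG"), 0)
  # n = 2 chromosomes (1 individual non-missing), c = 1 -> pi_site = 1
  gm2 <- make_gm(matrix(c(1, NA, 0, 0), 1, 4), pos = 150)
  expect_equal(window_pi(gm2, pops4, w, "HG"), 1 / 40000, tolerance = 1e-15)
  # per-site normalization mode
  expect_equal(window_pi(gm4, pops4, w, "HG", denominator = "sites"), 8 / 12,
               tolerance = 1e-12)
})

test_that("window_pi equals brute-force pairwise differences (oracle)", {
  set.seed(7)
  for (rep in 1:5) {
    n_ind <- 4  # 8 chromosomes per group at most
    dos <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 2 * n_ind, replace = TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), 30, 2 * n_ind)
    gm <- make_gm(dos, pos = sort(sample.int(5000, 30)))
    pops <- make_pops(n_ind, n_ind)
    for (w in list(list(chrom = "chr1", start = 0, end = 2500),
                   list(chrom = "chr1", start = 2500, end = 5000),
                   list(chrom = "chr1", start = 0, end = 5000))) {
      for (g in c("HG", "CG"))
        expect_equal(window_pi(gm, pops, w, g), brute_pi(gm, pops, w, g),
                     tolerance = 1e-12)
    }
  }
})

test_that("window_fst reproduces the Hudson estimator exactly", {
  w <- list(chrom = "chr1", start = 0, end = 1000)
  # fixed difference: p1 = 1, p2 = 0 -> F_ST = 1
  gm <- make_gm(matrix(c(2, 2, 0, 0), 1, 4), pos = 100)
  pops <- make_pops(2, 2)
  expect_equal(window_fst(gm, pops, w), 1)
  # p1 = 0.5 (n1 = 10), p2 = 0.25 (n2 = 8)
  d1 <- c(2, 2, 1, 0, 0)          # 5 ind = 10 chromosomes, 5 alt
  d2 <- c(1, 1, 0, 0)             # 4 ind = 8 chromosomes, 2 alt
  gm2 <- make_gm(matrix(c(d1, d2), 1, 9), pos = 100)
  pops2 <- make_pops(5, 4)
  expected <- (0.0625 - 0.25 / 9 - 0.1875 / 7) / 0.5
  expect_equal(window_fst(gm2, pops2, w), expected, tolerance = 1e-12)
  expect_equal(expected, 0.015873, tolerance = 1e-4)
  # monomorphic in both groups: no informative site -> NA
  gm3 <- make_gm(matrix(0, 1, 4), pos = 100)
  expect_true(is.na(window_fst(gm3, pops, w)))
})

test_that("ratio-of-averages windows match the per-site oracle", {
  set.seed(11)
  for (rep in 1:5) {
    dos <- matrix(sample(c(0L, 1L, 2L, NA), 40 * 10, replace = TRUE,
                         prob = c(0.45, 0.25, 0.25, 0.05)), 40, 10)
    gm <- make_gm(dos, pos = sort(sample.int(8000, 40)))
    pops <- make_pops(4, 6)
    w <- list(chrom = "chr1", start = 0, end = 8000)
    expect_equal(window_fst(gm, pops, w), brute_fst(gm, pops, w),
                 tolerance = 1e-12)
  }
})

test_that("F_ST <= 1 always; duplicated populations give near-zero windows", {
  set.seed(13)
  # property: fst <= 1 over random matrices
  for (rep in 1:20) {
    dos <- matrix(sample(0:2, 25 * 12, replace = TRUE), 25, 12)
    gm <- make_gm(dos, pos = sort(sample.int(4000, 25)))
    pops <- make_pops(6, 6)
    f <- window_fst(gm, pops, list(chrom = "chr1", start = 0, end = 4000))
    if (!is.na(f)) expect_lte(f, 1)
  }
  # identical groups: duplicated dosage columns, >= 50 segregating sites
  dos_half <- matrix(sample(0:2, 60 * 10, replace = TRUE), 60, 10)
  seg <- apply(dos_half, 1, function(x) length(unique(x)) > 1)
  dos_half <- dos_half[seg, ][1:50, ]
  gm <- make_gm(cbind(dos_half, dos_half), pos = (1:50) * 10)
  pops <- make_pops(10, 10)
  f <- window_fst(gm, pops, list(chrom = "chr1", start = 0, end = 1000))
  expect_lte(f, 0.05)
})

test_that("pi_ratio follows the limit conventions", {
  expect_equal(pi_ratio(0.002, 0.001), 2.0)
  expect_equal(pi_ratio(0.001, 0), Inf)
  expect_true(is.na(pi_ratio(0, 0)))
  expect_equal(pi_ratio(c(0.002, 0.001, 0), c(0.001, 0, 0)),
               c(2, Inf, NA))
  expect_error(pi_ratio(-1, 1))
})

test_that("select_top uses interpolated quantiles with strict selection", {
  rows <- data.frame(x = 1:100)
  up <- select_top(rows, "x", "upper", 0.01)
  expect_equal(up$cutoff, 99.01)
  expect_equal(up$selected$x, 100)
  lo <- select_top(rows, "x", "lower", 0.01)
  expect_equal(lo$selected$x, 1)
  # tie saturation: nothing strictly beyond the cutoff
  ties <- data.frame(x = rep(5, 50))
  expect_equal(nrow(select_top(ties, "x", "upper", 0.01)$selected), 0)
  # +Inf always selected in the upper tail; NA never ranked
  mixed <- data.frame(x = c(1:50, Inf, NA))
  sel <- select_top(mixed, "x", "upper", 0.02)
  expect_true(Inf %in% sel$selected$x)
  expect_false(any(is.na(sel$selected$x)))
  expect_error(select_top(data.frame(x = c(1, NA)), "x"), "at least 2")
  expect_error(select_top(rows, "nope"), "nope")
})

test_that("select_top returns ceiling(fraction * n) +/- 1 on distinct values", {
  set.seed(3)
  for (n in c(100, 500, 1000)) {
    rows <- data.frame(x = sample(seq_len(10 * n), n))
    for (fr in c(0.01, 0.025, 0.05)) {
      k <- nrow(select_top(rows, "x", "upper", fr)$selected)
      expect_lte(abs(k - ceiling(fr * n)), 1)
      k2 <- nrow(select_top(rows, "x", "lower", fr)$selected)
      expect_lte(abs(k2 - ceiling(fr * n)), 1)
    }
  }
})

test_that("intersect_windows is exact-coordinate set intersection", {
  A <- data.frame(chrom = "chr1", start = c(0, 20, 40) * 1000,
                  end = c(40, 60, 80) * 1000)
  B <- A[c(2, 3), ]; B <- rbind(B, data.frame(chrom = "chr1", start = 99000,
                                              end = 139000))
  C <- A[2, ]
  out <- intersect_windows(A, B, C)
  expect_equal(out$start, 20000)
  expect_equal(nrow(intersect_windows(A, B[0, ], C)), 0)
  expect_equal(intersect_windows(A, A, A), A[order(A$chrom, A$start), ])
})

test_that("window_scan agrees with the single-window operations", {
  set.seed(21)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 80 * 10, replace = TRUE,
                       prob = c(0.4, 0.3, 0.25, 0.05)), 80, 10)
  gm <- make_gm(dos, pos = sort(sample.int(100000, 80)))
  pops <- make_pops(5, 5)
  windows <- make_windows(c(chr1 = 100000))
  st <- window_scan(gm, pops, windows)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    expect_equal(st$pi_hg[i], window_pi(gm, pops, w, "HG"), tolerance = 1e-12)
    expect_equal(st$pi_cg[i], window_pi(gm, pops, w, "CG"), tolerance = 1e-12)
    expect_equal(st$fst[i], window_fst(gm, pops, w), tolerance = 1e-12)
  }
})
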