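pops_4_4 <- make_pops(4, 4)

test_that("cnv_maf counts variant-state carriers with folding", {
  vals <- c(rep(3, 5), rep(2, 67))
  expect_equal(cnv_maf(vals), 5 / 72)
  expect_equal(cnv_maf(rep(2, 10)), 0)
  expect_equal(cnv_maf(c(rep(2, 5), rep(0, 5))), 0.5)
  expect_error(cnv_maf(2), ">= 2")
})

test_that("cnv_silhouette scores cluster separation of CN classes", {
  expect_equal(cnv_silhouette(c(2, 2, 2, 4, 4)), 1)
  expect_equal(cnv_silhouette(rep(2.0, 6)), 0)
  s <- cnv_silhouette(c(2, 2.1, 3.9, 4))
  expect_gt(s, 0.9)
  # hand evaluation of the a/b formula for the same input
  manual <- mean(c((1.95 - 0.1) / 1.95, (1.85 - 0.1) / 1.85,
                   (1.85 - 0.1) / 1.85, (1.95 - 0.1) / 1.95))
  expect_equal(s, manual, tolerance = 1e-12)
})

test_that("cnv_silhouette matches cluster::silhouette when all clusters >= 2", {
  skip_if_not_installed("cluster")
  set.seed(5)
  for (rep in 1:10) {
    vals <- round(sample(c(rnorm(6, 1, 0.15), rnorm(6, 3, 0.15)),
                         12), 3)
    cl <- round(vals)
    if (min(table(cl)) < 2 || length(unique(cl)) < 2) next
    sil <- cluster::silhouette(as.integer(factor(cl)),
                               dist(vals, method = "manhattan"))
    expect_equal(cnv_silhouette(vals), mean(sil[, "sil_width"]),
                 tolerance = 1e-9)
  }
})

test_that("filter_reliable applies strict MAF and silhouette thresholds", {
  regions <- data.frame(chrom = "chr1", start = (0:3) * 1000,
                        end = (0:3) * 1000 + 500,
                        region_id = paste0("R", 1:4))
  vals <- rbind(
    c(rep(3, 2), rep(2, 48)),   # maf 0.04 -> removed
    c(rep(3, 5), rep(2, 45)),   # maf 0.10, clean clusters -> kept
    c(rep(4, 25), rep(2, 25)),  # maf 0.5 -> kept
    seq(1.5, 3.5, length.out = 50))  # continuum: maf 0.5 but blurred clusters
  cnm <- cn_matrix(regions, vals, paste0("S", 1:50))
  expect_lt(cnv_silhouette(vals[4, ]), 0.7)
  out <- suppressMessages(filter_reliable(cnm, silhouette_min = 0.7))
  expect_equal(out$regions$region_id, c("R2", "R3"))
  # maf exactly at the threshold is removed (strict inequality)
  vals2 <- matrix(c(rep(3, 1), rep(2, 19)), 1, 20)
  cnm2 <- cn_matrix(regions[1, ], vals2, paste0("S", 1:20))
  expect_equal(cnv_maf(vals2[1, ]), 0.05)
  expect_warning(suppressMessages(
    out2 <- filter_reliable(cnm2, maf_min = 0.05)), "no CNV region")
  expect_equal(nrow(out2$regions), 0)
})

test_that("cnv_vst follows the variance-decomposition formula", {
  pops <- pops_4_4
  expect_equal(cnv_vst(c(2, 2, 2, 2, 4, 4, 4, 4), pops), 1)
  expect_equal(cnv_vst(c(2, 2, 4, 4, 2, 2, 4, 4), pops), 0)
  # worked decomposition: V_pop1 = V_pop2 = 0.1875, V_total = 0.75
  expect_equal(cnv_vst(c(2, 2, 2, 3, 4, 4, 3, 4), pops), 0.75)
  expect_equal(cnv_vst(rep(2, 8), pops), 0)  # V_total = 0 convention
})

test_that("cnv_vst stays in [0,1] and is invariant to shifts and relabeling", {
  set.seed(17)
  pops <- make_pops(20, 52)
  for (rep in 1:1000) {
    vals <- sample(0:6, 72, replace = TRUE)
    v <- cnv_vst(vals, pops)
    expect_gte(v, 0)
    expect_lte(v, 1)
    if (rep <= 50) {
      expect_equal(cnv_vst(vals + 3.7, pops), v, tolerance = 1e-9)
      # permuting individuals within each group leaves V_ST unchanged
      perm <- c(sample(1:20), 20 + sample(1:52))
      expect_equal(cnv_vst(vals[perm], pops), v, tolerance = 1e-12)
    }
  }
  # vst = 1 iff both within-group variances are 0 and means differ
  expect_equal(cnv_vst(c(rep(1, 20), rep(5, 52)), pops), 1)
  expect_lt(cnv_vst(c(rep(1, 19), 1.2, rep(5, 52)), pops), 1)
})

test_that("cnv_fst dichotomizes carriers and applies the Hudson form", {
  pops <- pops_4_4
  expect_equal(cnv_fst(c(0, 0, 1, 1, 2, 2, 2, 2), pops), 1)  # q1=1, q2=0
  expect_true(is.na(cnv_fst(rep(2, 8), pops)))               # q1=q2=0
  # q1 = 0.5 (n1 = 10), q2 = 0.25 (n2 = 8)
  vals <- c(rep(3, 5), rep(2, 5), rep(4, 2), rep(2, 6))
  pops2 <- make_pops(10, 8)
  expect_equal(cnv_fst(vals, pops2),
               (0.0625 - 0.25 / 9 - 0.1875 / 7) / 0.5, tolerance = 1e-12)
})

test_that("cnv_ttest is a textbook Welch test with degenerate conventions", {
  pops <- pops_4_4
  tt <- cnv_ttest(c(2, 3, 2, 3, 4, 3, 4, 3), pops)
  expect_equal(tt$t_stat, -2.449, tolerance = 1e-3)
  expect_equal(tt$df, 6)
  expect_equal(tt$p_value, 0.0499, tolerance = 1e-2)
  # against stats::t.test on random inputs
  set.seed(23)
  for (rep in 1:20) {
    x <- rnorm(6, 2, 0.5); y <- rnorm(9, 2.5, 1.2)
    ref <- t.test(x, y)
    got <- cnv_ttest(c(x, y), make_pops(6, 9))
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  same <- cnv_ttest(c(2, 3, 2, 3, 2, 3, 2, 3), pops)
  expect_equal(unname(same$p_value), t.test(c(2,3,2,3), c(2,3,2,3))$p.value)
  const_eq <- cnv_ttest(rep(2, 8), pops)
  expect_equal(const_eq$p_value, 1)
  const_ne <- cnv_ttest(c(2, 2, 2, 2, 4, 4, 4, 4), pops)
  expect_equal(const_ne$p_value, 0)
  expect_true(const_ne$degenerate)
})

test_that("select_cnv_candidates intersects the two upper tails", {
  set.seed(29)
  n <- 100
  stats <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1000,
                      end = (0:(n - 1)) * 1000 + 500,
                      region_id = sprintf("R%03d", 1:n),
                      fst = sample(seq(0, 0.9, length.out = n)),
                      vst = sample(seq(0, 0.9, length.out = n)),
                      p_value = runif(n))
  # force one region into both tails
  stats$fst[7] <- 0.99; stats$vst[7] <- 0.99
  sel <- select_cnv_candidates(stats, fraction = 0.01)
  expect_equal(sel$candidates$region_id, "R007")
  expect_true("p_value" %in% names(sel$candidates))
  # disjoint tails -> empty set
  stats2 <- stats
  stats2$fst <- seq_len(n); stats2$vst <- rev(seq_len(n))
  expect_equal(nrow(select_cnv_candidates(stats2, 0.01)$candidates), 0)
})

test_that("injected differentiated regions land in the V_ST top fraction", {
  set.seed(31)
  pops <- make_pops(20, 52)
  n <- 200
  vals <- matrix(sample(c(1, 2, 3), n * 72, replace = TRUE,
                        prob = c(0.15, 0.7, 0.15)), n, 72)
  inj <- sample(n, 5)
  for (i in inj)
    vals[i, ] <- c(sample(0:1, 20, TRUE), sample(2:3, 52, TRUE, c(0.9, 0.1)))
  regions <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1000,
                        end = (0:(n - 1)) * 1000 + 500,
                        region_id = sprintf("R%03d", 1:n))
  cnm <- cn_matrix(regions, vals, names(pops))
  stats <- cnv_scan(cnm, pops)
  sel <- select_top(stats, "vst", "upper", 0.025)
  expect_true(all(regions$region_id[inj] %in% sel$selected$region_id))
})
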