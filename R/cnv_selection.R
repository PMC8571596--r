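# Copy-number state assignment: nearest integer, ties to even (base round).
cn_state <- function(values) round(values)

#' Copy-number variant-state frequency (MAF filter statistic)
#'
#' Fraction of individuals whose rounded copy number differs from the
#' diploid reference state, folded at 0.5.
#'
#' @param values numeric copy numbers, one per individual.
#' @param reference_cn reference copy number (diploid total, default 2).
#' @return \code{min(f, 1 - f)} with \code{f} the variant-carrier fraction.
#' @export
cnv_maf <- function(values, reference_cn = 2) {
  if (length(values) < 2) stop("need >= 2 individuals")
  f <- mean(cn_state(values) != reference_cn)
  min(f, 1 - f)
}

#' Mean silhouette score of copy-number genotype classes
#'
#' Individuals are clustered by rounded integer copy number; the silhouette
#' coefficient uses absolute-difference distance on the raw values. The mean
#' is taken over individuals in clusters of size >= 2 (a singleton class has
#' no within-cluster cohesion to measure); a single-cluster region scores 0
#' by convention.
#'
#' @param values numeric copy numbers, one per individual.
#' @return Mean silhouette in [-1, 1].
#' @export
cnv_silhouette <- function(values) {
  if (length(values) < 2) stop("need >= 2 individuals")
  cl <- cn_state(values)
  clusters <- unique(cl)
  if (length(clusters) < 2) return(0)
  sizes <- table(cl)
  s <- numeric(0)
  for (i in seq_along(values)) {
    if (sizes[as.character(cl[i])] < 2) next
    d <- abs(values[i] - values)
    a <- mean(d[cl == cl[i] & seq_along(values) != i])
    b <- min(vapply(clusters[clusters != cl[i]],
                    function(k) mean(d[cl == k]), numeric(1)))
    m <- max(a, b)
    s <- c(s, if (m == 0) 0 else (b - a) / m)
  }
  if (length(s) == 0) return(0)
  mean(s)
}

#' Filter a CN matrix down to reliable CNV regions
#'
#' Keeps regions whose variant-state frequency exceeds \code{maf_min}
#' (strict, matching "greater than 0.05") and whose mean silhouette is at
#' least \code{silhouette_min}; reports the counts removed per criterion.
#'
#' @param cnm a \code{\link{cn_matrix}}.
#' @param maf_min strict lower bound on \code{\link{cnv_maf}}.
#' @param silhouette_min inclusive lower bound on
#'   \code{\link{cnv_silhouette}}.
#' @param reference_cn reference copy number.
#' @return The filtered \code{\link{cn_matrix}} (possibly with 0 regions).
#' @export
filter_reliable <- function(cnm, maf_min = 0.05, silhouette_min = 0.7,
                            reference_cn = 2) {
  stopifnot(is(cnm, "cn_matrix"))
  maf <- apply(cnm$values, 1, cnv_maf, reference_cn = reference_cn)
  sil <- apply(cnm$values, 1, cnv_silhouette)
  keep <- maf > maf_min & sil >= silhouette_min
  message(sprintf(
    "filter_reliable: %d/%d kept (%d failed MAF > %g, %d failed silhouette >= %g)",
    sum(keep), length(keep), sum(maf <= maf_min), as.numeric(maf_min),
    sum(sil < silhouette_min), as.numeric(silhouette_min)))
  if (!any(keep)) {
    warning("no CNV region passed the reliability filters")
  }
  out <- cnm
  out$regions <- cnm$regions[keep, , drop = FALSE]
  rownames(out$regions) <- NULL
  out$values <- cnm$values[keep, , drop = FALSE]
  out
}

# population variance (denominator N): the choice that keeps V_ST in [0,1]
pop_var <- function(x) mean((x - mean(x))^2)

#' V_ST copy-number differentiation statistic
#'
#' Variance-decomposition analogue of F_ST for copy numbers:
#' \deqn{V_{ST} = \frac{V_{total} - (V_{pop1} N_{pop1} + V_{pop2} N_{pop2})/N_{total}}{V_{total}}}
#' where the variances are population variances (denominator \eqn{N}), so
#' the law of total variance bounds the statistic in [0, 1]. A region with
#' zero total variance scores 0.
#'
#' @param values numeric copy numbers, one per individual, named or ordered
#'   as \code{names(pops)}.
#' @param pops a \code{\link{population_map}} covering the individuals.
#' @return V_ST in [0, 1].
#' @export
cnv_vst <- function(values, pops) {
  v <- split_groups(values, pops)
  n1 <- length(v$hg); n2 <- length(v$cg)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  v_total <- pop_var(c(v$hg, v$cg))
  if (v_total == 0) return(0)
  within <- (pop_var(v$hg) * n1 + pop_var(v$cg) * n2) / (n1 + n2)
  (v_total - within) / v_total
}

# match CN values to groups, by name when available, else by pops order
split_groups <- function(values, pops) {
  if (!is.null(names(values))) {
    check_samples_mapped(names(values), pops)
    list(hg = values[group_ids(pops, "HG")],
         cg = values[group_ids(pops, "CG")])
  } else {
    if (length(values) != length(pops))
      stop("unnamed values must match the population map length")
    list(hg = values[unclass(pops) == "HG"],
         cg = values[unclass(pops) == "CG"])
  }
}

#' Hudson-form F_ST for one CNV region
#'
#' Copy numbers carry no allele phase, so the region is dichotomized into
#' variant carriers (rounded CN differing from \code{reference_cn}) versus
#' reference individuals; the Hudson estimator is then applied to the
#' carrier frequencies with individual-level sample sizes.
#'
#' @inheritParams cnv_vst
#' @param reference_cn reference copy number.
#' @return The F_ST estimate, or \code{NA} when both groups are monomorphic
#'   in the same state (zero denominator).
#' @export
cnv_fst <- function(values, pops, reference_cn = 2) {
  v <- split_groups(values, pops)
  n1 <- length(v$hg); n2 <- length(v$cg)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 individuals")
  q1 <- mean(cn_state(v$hg) != reference_cn)
  q2 <- mean(cn_state(v$cg) != reference_cn)
  den <- q1 * (1 - q2) + q2 * (1 - q1)
  if (den == 0) return(NA_real_)
  num <- (q1 - q2)^2 - q1 * (1 - q1) / (n1 - 1) - q2 * (1 - q2) / (n2 - 1)
  num / den
}

#' Welch two-sample t-test on raw copy numbers
#'
#' Two-sided Welch (unequal-variance) test of the group means. Degenerate
#' zero-variance-in-both-groups regions use the convention p = 1 for equal
#' means and p = 0 (flagged) for unequal means.
#'
#' @inheritParams cnv_vst
#' @return list with \code{t_stat}, \code{df}, \code{p_value} and
#'   \code{degenerate} (TRUE when both variances are 0 and means differ).
#' @export
cnv_ttest <- function(values, pops) {
  v <- split_groups(values, pops)
  x <- v$hg; y <- v$cg
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need >= 2 individuals")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t_stat = 0, df = NA_real_, p_value = 1, degenerate = FALSE))
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  se2 <- vx / length(x) + vy / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                 (vy / length(y))^2 / (length(y) - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df), degenerate = FALSE)
}

#' Per-region differentiation statistics for a CN matrix
#'
#' Computes MAF, silhouette, V_ST, Hudson F_ST and the Welch t-test for
#' every region of a (typically already reliability-filtered) CN matrix.
#'
#' @param cnm a \code{\link{cn_matrix}}.
#' @param pops a \code{\link{population_map}}.
#' @param reference_cn reference copy number.
#' @return data.frame of CNV stat rows (one per region) with region
#'   coordinates, \code{maf}, \code{silhouette}, \code{vst}, \code{fst},
#'   \code{t_stat}, \code{df}, \code{p_value}, group means/variances
#'   (population variances), \code{var_total} and group sizes.
#' @export
cnv_scan <- function(cnm, pops, reference_cn = 2) {
  stopifnot(is(cnm, "cn_matrix"))
  check_samples_mapped(cnm$individual_ids, pops)
  hg <- intersect(cnm$individual_ids, group_ids(pops, "HG"))
  cg <- intersect(cnm$individual_ids, group_ids(pops, "CG"))
  rows <- lapply(seq_len(nrow(cnm$regions)), function(i) {
    vals <- cnm$values[i, ]
    tt <- cnv_ttest(vals, pops)
    data.frame(
      chrom = cnm$regions$chrom[i], start = cnm$regions$start[i],
      end = cnm$regions$end[i], region_id = cnm$regions$region_id[i],
      maf = cnv_maf(vals, reference_cn),
      silhouette = cnv_silhouette(vals),
      vst = cnv_vst(vals, pops),
      fst = cnv_fst(vals, pops, reference_cn),
      t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
      mean_hg = mean(vals[hg]), mean_cg = mean(vals[cg]),
      var_hg = pop_var(vals[hg]), var_cg = pop_var(vals[cg]),
      var_total = pop_var(vals[c(hg, cg)]),
      n_hg = length(hg), n_cg = length(cg),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0))
  rownames(out) <- NULL
  out
}

#' Top-percentile intersection of V_ST and F_ST CNV outliers
#'
#' Applies \code{\link{select_top}} (upper tail) independently to the
#' \code{fst} and \code{vst} columns and intersects by region id; every
#' candidate keeps its Welch p-value.
#'
#' @param stats data.frame from \code{\link{cnv_scan}}.
#' @param fraction tail fraction (default top 1\%; the per-mille reading of
#'   the published cutoffs is available by passing 0.001).
#' @return list with \code{cutoffs} (named: fst, vst), \code{selected}
#'   (per-statistic tables) and \code{candidates} (intersection, sorted by
#'   chromosome then start).
#' @export
select_cnv_candidates <- function(stats, fraction = 0.01) {
  s_fst <- select_top(stats, "fst", "upper", fraction)
  s_vst <- select_top(stats, "vst", "upper", fraction)
  common <- intersect(s_fst$selected$region_id, s_vst$selected$region_id)
  cand <- stats[stats$region_id %in% common, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  list(cutoffs = c(fst = s_fst$cutoff, vst = s_vst$cutoff),
       selected = list(fst = s_fst$selected, vst = s_vst$selected),
       candidates = cand)
}
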