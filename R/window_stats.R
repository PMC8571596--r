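#' Tile chromosomes with sliding windows
#'
#' Builds the sliding-window tiling used by the selection scan: windows of
#' \code{window_bp} starting every \code{step_bp} (defaults 40 kb / 20 kb).
#' Only windows fully inside the chromosome are emitted unless
#' \code{keep_partial} asks for one truncated terminal window.
#'
#' @param chromosome_lengths named integer vector of chromosome lengths (bp).
#' @param window_bp window length in bp.
#' @param step_bp step between successive window starts in bp.
#' @param keep_partial emit a final truncated window when the step does not
#'   tile the chromosome exactly.
#' @return data.frame with columns \code{chrom}, \code{start} (0-based),
#'   \code{end} (exclusive).
#' @export
make_windows <- function(chromosome_lengths, window_bp = 40000,
                         step_bp = 20000, keep_partial = FALSE) {
  if (window_bp <= 0 || step_bp <= 0)
    stop("window_bp and step_bp must be positive")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (step_bp > window_bp)
    warning("step_bp > window_bp leaves gaps between windows")
  if (is.null(names(chromosome_lengths)))
    stop("chromosome_lengths must be named by chromosome")
  out <- lapply(names(chromosome_lengths), function(chr) {
    len <- chromosome_lengths[[chr]]
    starts <- seq(0, len, by = step_bp)
    starts <- starts[starts + window_bp <= len]
    ends <- starts + window_bp
    if (keep_partial) {
      last_end <- if (length(ends)) max(ends) else 0
      if (last_end < len) {
        s <- if (length(starts)) max(starts) + step_bp else 0
        if (s < len) {
          starts <- c(starts, s)
          ends <- c(ends, len)
        }
      }
    }
    if (length(starts) == 0) return(NULL)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(ends), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  rownames(out) <- NULL
  out
}

# Per-site allele summaries for one group: n = non-missing chromosomes,
# c = alt-allele count. Sites with n < 2 are uninformative.
site_group_counts <- function(gm, pops, group) {
  ids <- group_ids(pops, group)
  idx <- match(ids, gm$individual_ids)
  if (anyNA(idx))
    stop("individuals absent from the genotype matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  d <- gm$dosages[, idx, drop = FALSE]
  if (nrow(d) == 0)
    return(list(n = numeric(0), c = numeric(0)))
  list(n = 2 * rowSums(!is.na(d)), c = rowSums(d, na.rm = TRUE))
}

# Per-site unbiased pi: expected pairwise difference between two chromosomes
# drawn without replacement, 2c(n-c)/(n(n-1)); 0 where n < 2.
site_pi <- function(n, c) {
  p <- numeric(length(n))
  ok <- n >= 2
  p[ok] <- 2 * c[ok] * (n[ok] - c[ok]) / (n[ok] * (n[ok] - 1))
  p
}

# Per-site Hudson numerator/denominator; NA rows where either group has
# n < 2 or the site is monomorphic overall (D = 0 handled by caller).
site_hudson <- function(n1, c1, n2, c2) {
  p1 <- c1 / n1
  p2 <- c2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- n1 >= 2 & n2 >= 2
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  list(num = num, den = den)
}

# Sum per-site values over windows using cumulative sums per chromosome.
# values: matrix sites x k (rows aligned with gm$sites). Returns windows x k.
window_sums <- function(sites, windows, values) {
  values <- as.matrix(values)
  out <- matrix(0, nrow(windows), ncol(values))
  for (chr in unique(windows$chrom)) {
    w <- which(windows$chrom == chr)
    s <- which(sites$chrom == chr)
    if (length(s) == 0) next
    pos <- sites$pos[s]                    # sorted by construction
    cs <- rbind(0, apply(values[s, , drop = FALSE], 2, cumsum))
    lo <- findInterval(windows$start[w], pos)
    hi <- findInterval(windows$end[w], pos)
    out[w, ] <- cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]
  }
  out
}

#' Windowed nucleotide diversity for one group
#'
#' Per-site diversity is the unbiased pairwise-difference estimator
#' \eqn{2c(n-c)/(n(n-1))} with \eqn{n} the non-missing chromosome count and
#' \eqn{c} the alt-allele count in the group; sites with \eqn{n < 2}
#' contribute nothing. The window value is the per-site sum divided by the
#' window length in bp (default) or by the number of informative sites.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param pops a \code{\link{population_map}}.
#' @param window one-row data.frame (or list) with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param group \code{"HG"} or \code{"CG"}.
#' @param denominator \code{"window"} (bp) or \code{"sites"}.
#' @return Per-bp (or per-site) nucleotide diversity, a single number.
#' @export
window_pi <- function(gm, pops, window, group,
                      denominator = c("window", "sites")) {
  denominator <- match.arg(denominator)
  gc <- site_group_counts(gm, pops, group)
  in_w <- gm$sites$chrom == window$chrom &
    gm$sites$pos > window$start & gm$sites$pos <= window$end
  pis <- site_pi(gc$n, gc$c)[in_w]
  informative <- sum(gc$n[in_w] >= 2)
  if (denominator == "window")
    sum(pis) / (window$end - window$start)
  else if (informative > 0) sum(pis) / informative else 0
}

#' Windowed Hudson F_ST
#'
#' Ratio-of-averages Hudson estimator: per informative site (both groups
#' with at least two non-missing chromosomes), numerator
#' \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}; the window estimate is the
#' ratio of the two sums over sites with positive denominator. Windows with
#' no such site get \code{NA} (excluded from percentile ranking). The
#' per-site-average variant is available via \code{mode}.
#'
#' @inheritParams window_pi
#' @param mode \code{"ratio_of_averages"} (default, low-bias) or
#'   \code{"average_of_ratios"}.
#' @return The window F_ST estimate (may be negative), or \code{NA}.
#' @export
window_fst <- function(gm, pops, window,
                       mode = c("ratio_of_averages", "average_of_ratios")) {
  mode <- match.arg(mode)
  g1 <- site_group_counts(gm, pops, "HG")
  g2 <- site_group_counts(gm, pops, "CG")
  in_w <- gm$sites$chrom == window$chrom &
    gm$sites$pos > window$start & gm$sites$pos <= window$end
  h <- site_hudson(g1$n[in_w], g1$c[in_w], g2$n[in_w], g2$c[in_w])
  use <- !is.na(h$den) & h$den > 0
  if (!any(use)) return(NA_real_)
  if (mode == "ratio_of_averages")
    sum(h$num[use]) / sum(h$den[use])
  else
    mean(h$num[use] / h$den[use])
}

#' Diversity ratio pi(CG)/pi(HG)
#'
#' High values flag windows where the case group lost diversity relative to
#' the control group. \code{+Inf} when the case group is monomorphic but the
#' control group is not; \code{NA} (excluded from ranking) when both are 0.
#'
#' @param pi_cg,pi_hg non-negative per-bp diversities.
#' @return The ratio (vectorized).
#' @export
pi_ratio <- function(pi_cg, pi_hg) {
  stopifnot(all(pi_cg >= 0, na.rm = TRUE), all(pi_hg >= 0, na.rm = TRUE))
  r <- pi_cg / pi_hg
  r[pi_hg == 0 & pi_cg > 0] <- Inf
  r[pi_hg == 0 & pi_cg == 0] <- NA_real_
  r
}

#' Compute all window statistics for a two-population SNP scan
#'
#' Vectorized equivalent of calling \code{\link{window_pi}} (both groups),
#' \code{\link{pi_ratio}} and \code{\link{window_fst}} on every window.
#' \code{n_snps} counts sites informative in both groups.
#'
#' @inheritParams window_pi
#' @param windows data.frame from \code{\link{make_windows}}.
#' @inheritParams window_fst
#' @return data.frame of window stat rows: \code{chrom}, \code{start},
#'   \code{end}, \code{n_snps}, \code{pi_hg}, \code{pi_cg}, \code{pi_ratio},
#'   \code{fst}.
#' @export
window_scan <- function(gm, pops, windows,
                        denominator = c("window", "sites"),
                        mode = c("ratio_of_averages", "average_of_ratios")) {
  denominator <- match.arg(denominator)
  mode <- match.arg(mode)
  check_samples_mapped(gm$individual_ids, pops)
  g1 <- site_group_counts(gm, pops, "HG")
  g2 <- site_group_counts(gm, pops, "CG")
  pi1 <- site_pi(g1$n, g1$c)
  pi2 <- site_pi(g2$n, g2$c)
  h <- site_hudson(g1$n, g1$c, g2$n, g2$c)
  use <- !is.na(h$den) & h$den > 0
  num <- ifelse(use, h$num, 0)
  den <- ifelse(use, h$den, 0)
  ratio_site <- ifelse(use, h$num / h$den, 0)
  informative <- as.numeric(g1$n >= 2 & g2$n >= 2)
  sums <- window_sums(gm$sites, windows,
                      cbind(pi1, pi2, num, den, ratio_site, use, informative))
  len <- windows$end - windows$start
  n_inf1 <- sums[, 7]
  pi_hg <- if (denominator == "window") sums[, 1] / len else
    ifelse(n_inf1 > 0, sums[, 1] / n_inf1, 0)
  pi_cg <- if (denominator == "window") sums[, 2] / len else
    ifelse(n_inf1 > 0, sums[, 2] / n_inf1, 0)
  fst <- ifelse(sums[, 6] > 0,
                if (mode == "ratio_of_averages") sums[, 3] / sums[, 4]
                else sums[, 5] / sums[, 6],
                NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(sums[, 7]),
             pi_hg = pi_hg, pi_cg = pi_cg,
             pi_ratio = pi_ratio(pi_cg, pi_hg), fst = fst,
             stringsAsFactors = FALSE)
}

#' Select the extreme tail of a statistic
#'
#' Empirical-percentile outlier selection: the cutoff is the
#' linear-interpolation (type-7) quantile of the defined, finite values, and
#' the selection is strictly beyond the cutoff — mirroring how genome-wide
#' scans report e.g. "top 1\% (F_ST > cutoff)". \code{+Inf} values are
#' always selected in the upper tail; \code{NA}/\code{NaN} values never
#' enter the ranking.
#'
#' @param rows data.frame holding the statistic.
#' @param statistic column name to rank on.
#' @param tail \code{"upper"} or \code{"lower"}.
#' @param fraction tail mass, e.g. 0.01 for the top 1\%.
#' @return list with \code{cutoff} and \code{selected} (subset of
#'   \code{rows}, original order preserved).
#' @export
select_top <- function(rows, statistic, tail = c("upper", "lower"),
                       fraction = 0.01) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  vals <- rows[[statistic]]
  if (is.null(vals)) stop("no column '", statistic, "' in rows")
  defined <- !is.na(vals)
  if (sum(defined) < 2)
    stop("need at least 2 defined values of ", statistic, " to rank")
  finite <- defined & is.finite(vals)
  cutoff <- if (any(finite)) {
    quantile(vals[finite], if (tail == "upper") 1 - fraction else fraction,
             type = 7, names = FALSE)
  } else if (tail == "upper") Inf else -Inf
  sel <- if (tail == "upper")
    defined & (vals > cutoff | vals == Inf)
  else
    defined & vals < cutoff
  list(cutoff = cutoff, selected = rows[sel, , drop = FALSE])
}

#' Intersect window selections from several statistics
#'
#' Windows surviving all selections simultaneously (exact coordinate
#' identity over the shared tiling), sorted by chromosome then start.
#'
#' @param ... two or more data.frames with \code{chrom}, \code{start},
#'   \code{end} columns (e.g. the \code{selected} elements from
#'   \code{\link{select_top}}).
#' @return data.frame of the common windows (columns of the first input).
#' @export
intersect_windows <- function(...) {
  lists <- list(...)
  stopifnot(length(lists) >= 2)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  common <- Reduce(intersect, lapply(lists, key))
  first <- lists[[1]]
  out <- first[key(first) %in% common, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-statistic sweep-candidate selection
#'
#' The scan's decision rule: lower-tail top fraction of case-group diversity
#' \code{pi_hg}, upper-tail of the ratio \code{pi_ratio} and upper-tail of
#' \code{fst}, intersected. Windows with fewer than \code{min_snps}
#' informative SNPs are excluded from ranking (an empty window has pi = 0
#' for trivial reasons, not because of a sweep).
#'
#' @param stats window table from \code{\link{window_scan}}.
#' @param fraction tail fraction per statistic (default top 1\%).
#' @param min_snps minimum informative SNPs for a window to be ranked.
#' @return list with \code{cutoffs} (named: pi_hg, pi_ratio, fst),
#'   \code{selected} (per-statistic window tables) and \code{candidates}
#'   (the intersection).
#' @export
select_sweep_windows <- function(stats, fraction = 0.01, min_snps = 1) {
  ranked <- stats[stats$n_snps >= min_snps, , drop = FALSE]
  s_pi <- select_top(ranked, "pi_hg", "lower", fraction)
  s_ratio <- select_top(ranked, "pi_ratio", "upper", fraction)
  s_fst <- select_top(ranked, "fst", "upper", fraction)
  list(cutoffs = c(pi_hg = s_pi$cutoff, pi_ratio = s_ratio$cutoff,
                   fst = s_fst$cutoff),
       selected = list(pi_hg = s_pi$selected, pi_ratio = s_ratio$selected,
                       fst = s_fst$selected),
       candidates = intersect_windows(s_pi$selected, s_ratio$selected,
                                      s_fst$selected))
}
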