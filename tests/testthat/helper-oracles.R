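# Independent brute-force oracles used against the package's vectorized
# implementations, plus tiny fixture builders. Everything here is
# deliberately naive: enumeration, all-pairs loops, textbook formulas.

# build a genotype_matrix from a plain dosage matrix (sites x individuals)
make_gm <- function(dosages, chrom = "chr1",
                    pos = seq_len(nrow(as.matrix(dosages))) * 100,
                    ids = paste0("S", seq_len(ncol(as.matrix(dosages))))) {
  dosages <- as.matrix(dosages)
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
    dosages, ids)
}

make_pops <- function(n_hg, n_cg,
                      ids = c(paste0("S", seq_len(n_hg + n_cg)))) {
  population_map(ids, rep(c("HG", "CG"), c(n_hg, n_cg)))
}

# brute-force pi: expand dosages into chromosome alleles, average the
# per-bp difference count over all chromosome pairs
brute_pi <- function(gm, pops, window, group) {
  ids <- group_ids(pops, group)
  idx <- match(ids, gm$individual_ids)
  in_w <- gm$sites$chrom == window$chrom &
    gm$sites$pos > window$start & gm$sites$pos <= window$end
  total <- 0
  for (s in which(in_w)) {
    d <- gm$dosages[s, idx]
    d <- d[!is.na(d)]
    alleles <- unname(unlist(lapply(d, function(x)
      c(rep(1, x), rep(0, 2 - x)))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diffs <- diffs + (alleles[i] != alleles[j])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total / (window$end - window$start)
}

# per-site Hudson oracle, ratio of averages, written independently
brute_fst <- function(gm, pops, window) {
  i1 <- match(group_ids(pops, "HG"), gm$individual_ids)
  i2 <- match(group_ids(pops, "CG"), gm$individual_ids)
  in_w <- which(gm$sites$chrom == window$chrom &
                  gm$sites$pos > window$start & gm$sites$pos <= window$end)
  num <- den <- 0
  for (s in in_w) {
    d1 <- gm$dosages[s, i1]; d1 <- d1[!is.na(d1)]
    d2 <- gm$dosages[s, i2]; d2 <- d2[!is.na(d2)]
    n1 <- 2 * length(d1); n2 <- 2 * length(d2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(d1) / n1; p2 <- sum(d2) / n2
    D <- p1 * (1 - p2) + p2 * (1 - p1)
    if (D <= 0) next
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + D
  }
  if (den == 0) NA_real_ else num / den
}

# all-pairs interval overlap on 0-based half-open spans
brute_overlap <- function(intervals, genes) {
  hits <- list()
  for (i in seq_len(nrow(intervals))) for (j in seq_len(nrow(genes))) {
    if (intervals$chrom[i] == genes$chrom[j] &&
        intervals$start[i] < genes$end[j] &&
        genes$start[j] < intervals$end[i])
      hits[[length(hits) + 1]] <- c(i, j)
  }
  if (length(hits) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# exact hypergeometric upper tail by enumerating all C(N, n) draws
brute_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the successes
  mean(hits >= k)
}

# denominator-N variance, restated independently of the package internals
pop_var_oracle <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

# textbook BH step-up with cumulative-minimum monotonicity
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin((m / seq(m, 1)) * p[o][m:1])[m:1])
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
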