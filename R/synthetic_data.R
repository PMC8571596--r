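#' Configuration for the two-population cohort simulator
#'
#' The defaults state the simulated world once: a 20-vs-52 cohort (the
#' case/control shape of the motivating resequencing design) on one 10-Mb
#' chromosome at 1 SNP/kb, neutral background differentiation F = 0.02
#' under the Balding-Nichols model, five selective sweeps of one window
#' length (40 kb, aligned to the 20-kb step grid) at strength 0.95, and 200
#' CNV regions of which five are strongly differentiated between groups.
#'
#' @param seed integer seed; mandatory, every simulator output is a
#'   deterministic function of (config, seed).
#' @param n_hg,n_cg group sizes (case, control).
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param snp_density expected SNPs per bp.
#' @param f_bg background differentiation F in (0, 1).
#' @param sweep_windows data.frame(start, end), 0-based half-open spans in
#'   which the case group is swept.
#' @param sweep_strength in [0, 1]; 1 fixes the case group entirely.
#' @param n_cnv number of CNV regions.
#' @param n_diff_cnv number of differentiated CNV regions.
#' @param neutral_cn_states,neutral_cn_probs shared copy-number state
#'   distribution for neutral regions (both groups).
#' @param diff_hg_states,diff_hg_probs,diff_cg_states,diff_cg_probs
#'   per-group state distributions for differentiated regions (defaults:
#'   case mostly deleted at 0-1 copies, control at the reference 2-3).
#' @param cn_noise_sd Gaussian observation noise on copy numbers (read-depth
#'   estimation error); values are clamped at 0.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_hg = 20, n_cg = 52,
                       chrom = "chr1", chrom_length = 10e6,
                       snp_density = 1 / 1000,
                       f_bg = 0.02,
                       sweep_windows = data.frame(
                         start = c(1e6, 3e6, 5e6, 7e6, 9e6),
                         end = c(1e6, 3e6, 5e6, 7e6, 9e6) + 40000),
                       sweep_strength = 0.95,
                       n_cnv = 200, n_diff_cnv = 5,
                       neutral_cn_states = c(1, 2, 3),
                       neutral_cn_probs = c(0.15, 0.70, 0.15),
                       diff_hg_states = c(0, 1),
                       diff_hg_probs = c(0.6, 0.4),
                       diff_cg_states = c(2, 3),
                       diff_cg_probs = c(0.85, 0.15),
                       cn_noise_sd = 0.1) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_hg >= 2, n_cg >= 2, chrom_length > 0,
            f_bg > 0, f_bg < 1, sweep_strength >= 0, sweep_strength <= 1,
            n_diff_cnv <= n_cnv)
  if (nrow(sweep_windows) > 0 &&
      any(sweep_windows$start < 0 | sweep_windows$end > chrom_length))
    stop("sweep span outside the chromosome")
  structure(as.list(environment()), class = "sim_config")
}

sim_individual_ids <- function(config) {
  c(sprintf("HG_%02d", seq_len(config$n_hg)),
    sprintf("CG_%02d", seq_len(config$n_cg)))
}

#' Simulate two-population SNP genotypes with injected sweeps
#'
#' Neutral sites: ancestral frequency p ~ Uniform(0.05, 0.95); each group's
#' frequency is a Balding-Nichols draw, Beta with mean p and variance
#' p(1-p)F; dosages are Binomial(2, group frequency). Inside sweep spans
#' the case-group frequency is pulled toward the nearest fixation point:
#' p' = (1-s) p_draw + s round(p_draw), so strength 1 makes the case group
#' monomorphic there. Sites with no alt allele in the whole cohort are
#' dropped (a caller would not emit them).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{pops} (\code{\link{population_map}}) and \code{truth_windows}
#'   (data.frame of the swept spans).
#' @export
simulate_snp <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  n_sites <- round(config$chrom_length * config$snp_density)
  pos <- sort(sample.int(config$chrom_length, n_sites))
  p <- runif(n_sites, 0.05, 0.95)
  shape <- (1 - config$f_bg) / config$f_bg
  p_hg <- rbeta(n_sites, p * shape, (1 - p) * shape)
  p_cg <- rbeta(n_sites, p * shape, (1 - p) * shape)
  sw <- config$sweep_windows
  if (nrow(sw) > 0) {
    in_sweep <- Reduce(`|`, lapply(seq_len(nrow(sw)), function(i)
      pos > sw$start[i] & pos <= sw$end[i]))
    s <- config$sweep_strength
    p_hg[in_sweep] <- (1 - s) * p_hg[in_sweep] + s * round(p_hg[in_sweep])
  }
  d_hg <- matrix(rbinom(n_sites * config$n_hg, 2, rep(p_hg, config$n_hg)),
                 nrow = n_sites)
  d_cg <- matrix(rbinom(n_sites * config$n_cg, 2, rep(p_cg, config$n_cg)),
                 nrow = n_sites)
  dos <- cbind(d_hg, d_cg)
  seen <- rowSums(dos) > 0
  sites <- data.frame(chrom = config$chrom, pos = pos[seen],
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  ids <- sim_individual_ids(config)
  gm <- genotype_matrix(sites, dos[seen, , drop = FALSE], ids)
  pm <- population_map(ids, rep(c("HG", "CG"), c(config$n_hg, config$n_cg)))
  truth <- if (nrow(sw) > 0)
    data.frame(chrom = config$chrom, start = as.integer(sw$start),
               end = as.integer(sw$end))
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  list(genotypes = gm, pops = pm, truth_windows = truth)
}

#' Simulate a copy-number matrix with differentiated regions
#'
#' Neutral regions draw integer copy-number states from one shared
#' distribution for both groups; differentiated regions draw from strongly
#' shifted per-group distributions (default: case deleted, control at
#' reference). Gaussian observation noise is added and values clamped at 0.
#' The differentiated region ids are returned as ground truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cn} (\code{\link{cn_matrix}}), \code{pops} and
#'   \code{truth_regions} (character region ids).
#' @export
simulate_cn <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cnv
  n_ind <- config$n_hg + config$n_cg
  spacing <- floor(config$chrom_length / n)
  width <- sample(2000:min(10000, spacing - 1), n, replace = TRUE)
  starts <- (seq_len(n) - 1) * spacing
  regions <- data.frame(chrom = config$chrom, start = starts,
                        end = starts + width,
                        region_id = sprintf("CNVR_%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  diff_idx <- sort(sample.int(n, config$n_diff_cnv))
  draw <- function(states, k, probs)
    states[sample.int(length(states), k, replace = TRUE, prob = probs)]
  vals <- matrix(0, n, n_ind)
  hg_cols <- seq_len(config$n_hg)
  cg_cols <- config$n_hg + seq_len(config$n_cg)
  for (i in seq_len(n)) {
    if (i %in% diff_idx) {
      vals[i, hg_cols] <- draw(config$diff_hg_states, config$n_hg,
                               config$diff_hg_probs)
      vals[i, cg_cols] <- draw(config$diff_cg_states, config$n_cg,
                               config$diff_cg_probs)
    } else {
      vals[i, ] <- draw(config$neutral_cn_states, n_ind,
                        config$neutral_cn_probs)
    }
  }
  if (config$cn_noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(n * n_ind, 0, config$cn_noise_sd),
                          n, n_ind)
  vals <- pmax(vals, 0)
  ids <- sim_individual_ids(config)
  list(cn = cn_matrix(regions, vals, ids),
       pops = population_map(ids, rep(c("HG", "CG"),
                                      c(config$n_hg, config$n_cg))),
       truth_regions = regions$region_id[diff_idx])
}

#' Simulate the full cohort (SNPs + CNVs + ground truth)
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes}, \code{pops}, \code{cn},
#'   \code{truth} (list: \code{sweep_windows}, \code{diff_regions}) and the
#'   \code{config}.
#' @export
simulate_cohort <- function(config) {
  snp <- simulate_snp(config)
  cn <- simulate_cn(config)
  list(genotypes = snp$genotypes, pops = snp$pops, cn = cn$cn,
       truth = list(sweep_windows = snp$truth_windows,
                    diff_regions = cn$truth_regions),
       config = config)
}

# minimal fixed-column VCF 4.2 writer for simulated GT-only genotypes
write_sim_vcf <- function(gm, chrom_length, path) {
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$dosages), ncol(gm$dosages))
  ok <- !is.na(gm$dosages)
  gt[ok] <- codes[gm$dosages[ok] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", unique(gm$sites$chrom),
            as.integer(chrom_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t")), con)
  if (nrow(gm$sites) > 0) {
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

write_sim_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0)
    writeLines(sprintf(
      "%s\tsweepscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genes$chrom, genes$start + 1L, genes$end, genes$strand,
      genes$gene_id, genes$gene_name), con)
  invisible(path)
}

# toy gene models tiled over the simulated chromosome: one 20-kb gene every
# 100 kb, so some genes fall inside the default sweep spans
sim_genes <- function(config) {
  starts <- seq(10000, config$chrom_length - 30000, by = 100000)
  data.frame(chrom = config$chrom, start = as.integer(starts),
             end = as.integer(starts + 20000),
             strand = rep(c("+", "-"), length.out = length(starts)),
             gene_id = sprintf("GENE%03d", seq_along(starts)),
             gene_name = sprintf("GENE%03d", seq_along(starts)),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk as pipeline-ready fixture files
#'
#' Emits \code{snps.vcf}, \code{popmap.tsv}, \code{cn_matrix.tsv},
#' \code{genes.gff3} (toy gene models tiled over the chromosome) and
#' \code{truth.json} (the injected sweep spans and differentiated region
#' ids); optionally \code{gene_sets.gmt} with one term concentrated in the
#' swept-window genes plus background terms. All files are plain text and
#' byte-identical under the same (config, seed).
#'
#' @param bundle result of \code{\link{simulate_cohort}}.
#' @param directory output directory (created if needed).
#' @param force overwrite into a non-empty directory.
#' @param gmt also write a toy gene-set collection.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, directory, force = FALSE, gmt = FALSE) {
  if (dir.exists(directory) && length(dir(directory)) > 0 && !force)
    stop("directory ", directory, " is not empty (use force = TRUE)")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  config <- bundle$config
  paths <- file.path(directory,
                     c("snps.vcf", "popmap.tsv", "cn_matrix.tsv",
                       "genes.gff3", "truth.json"))
  write_sim_vcf(bundle$genotypes, config$chrom_length, paths[1])
  write.table(data.frame(id = names(bundle$pops),
                         group = unclass(bundle$pops)),
              paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_cn_matrix(bundle$cn, paths[3])
  genes <- sim_genes(config)
  write_sim_gff3(genes, paths[4])
  jsonlite::write_json(
    list(seed = config$seed,
         sweep_windows = bundle$truth$sweep_windows,
         diff_regions = bundle$truth$diff_regions),
    paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (gmt) {
    gmt_path <- file.path(directory, "gene_sets.gmt")
    ov <- overlap_genes(bundle$truth$sweep_windows, genes)
    sweep_set <- unique(ov$gene_id)
    others <- setdiff(genes$gene_id, sweep_set)
    lines <- c(
      paste(c("SWEEP_SET", "genes tiled into the swept spans", sweep_set),
            collapse = "\t"),
      paste(c("BACKGROUND_A", "first background genes",
              utils::head(others, 20)), collapse = "\t"),
      paste(c("BACKGROUND_B", "last background genes",
              utils::tail(others, 20)), collapse = "\t"))
    writeLines(lines, gmt_path)
    paths <- c(paths, gmt_path)
  }
  invisible(paths)
}
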