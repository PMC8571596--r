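#' Default run configuration
#'
#' Every default that the underlying scan defines follows the published
#' convention it mirrors: 40-kb windows with a 20-kb step, top 1\% tails for
#' both the SNP and CNV scans, CNV reliability MAF > 0.05, a ±2-Mb flank for
#' candidate-gene annotation and p < .05 / FDR <= 0.05 enrichment
#' thresholds.
#'
#' @param ... overrides of named defaults.
#' @return list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    vcf = NULL, popmap = NULL, cn = NULL, genes = NULL, gmt = NULL,
    out_dir = ".",
    window_bp = 40000, step_bp = 20000,
    top_fraction_snp = 0.01, top_fraction_cnv = 0.01,
    maf_min = 0.05, silhouette_min = 0.7, reference_cn = 2,
    min_snps = 1, flank_bp = 2e6,
    p_max = 0.05, q_max = 0.05,
    chrom_lengths = NULL, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (f in c("top_fraction_snp", "top_fraction_cnv"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 0.5)
      stop(f, " must lie in (0, 0.5]")
  structure(cfg, class = "run_config")
}

#' Read a JSON run-configuration file
#'
#' Keys mirror \code{\link{default_config}}; unknown keys are an error.
#' Precedence is CLI flags > file > defaults.
#'
#' @param path JSON file.
#' @param ... overrides applied on top of the file.
#' @return \code{run_config} list.
#' @export
read_run_config <- function(path, ...) {
  file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, utils::modifyList(file_cfg, list(...)))
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$out_dir
}

require_inputs <- function(cfg, keys, stage) {
  for (k in keys) {
    if (is.null(cfg[[k]]))
      stop(stage, ": config key '", k, "' is required")
    if (!file.exists(cfg[[k]]))
      stop(stage, ": input file not found: ", cfg[[k]])
  }
}

scan_chrom_lengths <- function(cfg, gm) {
  if (!is.null(cfg$chrom_lengths)) {
    cl <- unlist(cfg$chrom_lengths)
    return(cl)
  }
  # fall back to the span of observed SNPs, rounded up to the step grid
  pos_max <- tapply(gm$sites$pos, gm$sites$chrom, max)
  setNames(as.integer(ceiling(pos_max / cfg$step_bp) * cfg$step_bp),
           names(pos_max))
}

#' Run the sliding-window SNP selection scan
#'
#' VCF + population map + gene models in; window-statistic table, candidate
#' windows (TSV + BED) and candidate overlap genes out. The three
#' top-percentile cutoffs are logged in the same form scans report them
#' ("pi(HG) < c", "ratio > c", "F_ST > c").
#'
#' @param cfg a \code{run_config} (see \code{\link{default_config}}).
#' @return list with \code{stats}, \code{selection} (cutoffs + per-statistic
#'   selections + candidate windows) and \code{genes} (overlap table),
#'   invisibly.
#' @export
run_snp_scan <- function(cfg) {
  require_inputs(cfg, c("vcf", "popmap", "genes"), "snp-scan")
  out <- ensure_out_dir(cfg)
  gm <- read_vcf(cfg$vcf)
  pops <- read_population_map(cfg$popmap)
  genes <- read_genes(cfg$genes)
  if (nrow(gm$sites) == 0) {
    warning("snp-scan: VCF contains no biallelic SNPs; writing empty outputs")
    empty <- data.frame()
    write_results(empty, file.path(out, "window_stats.tsv"), "window_stats")
    write_results(empty, file.path(out, "snp_candidate_genes.tsv"),
                  "candidates")
    write_bed(data.frame(chrom = character(0), start = integer(0),
                         end = integer(0)),
              file.path(out, "snp_candidates.bed"))
    return(invisible(list(stats = empty, selection = NULL,
                          genes = empty)))
  }
  check_samples_mapped(gm$individual_ids, pops)
  windows <- make_windows(scan_chrom_lengths(cfg, gm),
                          window_bp = cfg$window_bp, step_bp = cfg$step_bp)
  message(sprintf("snp-scan: %d windows (%d kb / %d kb) over %d SNPs",
                  nrow(windows), cfg$window_bp %/% 1000,
                  cfg$step_bp %/% 1000, nrow(gm$sites)))
  stats <- window_scan(gm, pops, windows)
  sel <- select_sweep_windows(stats, fraction = cfg$top_fraction_snp,
                              min_snps = cfg$min_snps)
  message(sprintf(
    "snp-scan: top %.3g%% cutoffs: pi(HG) < %.6g; ratio > %.6g; F_ST > %.6g",
    100 * cfg$top_fraction_snp, sel$cutoffs["pi_hg"],
    sel$cutoffs["pi_ratio"], sel$cutoffs["fst"]))
  message(sprintf("snp-scan: %d candidate window(s) in the intersection",
                  nrow(sel$candidates)))
  gene_hits <- overlap_genes(sel$candidates, genes)
  write_results(stats, file.path(out, "window_stats.tsv"), "window_stats")
  write_results(gene_hits, file.path(out, "snp_candidate_genes.tsv"),
                "candidates")
  write_bed(sel$candidates, file.path(out, "snp_candidates.bed"))
  invisible(list(stats = stats, selection = sel, genes = gene_hits))
}

#' Run the CNV differentiation scan
#'
#' CN matrix + population map + gene models in; per-region V_ST / F_ST /
#' Welch statistics, top-percentile intersection candidates (TSV + BED) and
#' candidate genes (overlap plus ±flank) out.
#'
#' @inheritParams run_snp_scan
#' @return list with \code{stats}, \code{selection} and \code{genes},
#'   invisibly.
#' @export
run_cnv_scan <- function(cfg) {
  require_inputs(cfg, c("cn", "popmap", "genes"), "cnv-scan")
  out <- ensure_out_dir(cfg)
  cnm <- read_cn_matrix(cfg$cn)
  pops <- read_population_map(cfg$popmap)
  genes <- read_genes(cfg$genes)
  check_samples_mapped(cnm$individual_ids, pops)
  reliable <- filter_reliable(cnm, maf_min = cfg$maf_min,
                              silhouette_min = cfg$silhouette_min,
                              reference_cn = cfg$reference_cn)
  if (nrow(reliable$regions) < 2) {
    warning("cnv-scan: fewer than 2 reliable regions; writing empty outputs")
    empty <- data.frame()
    write_results(empty, file.path(out, "cnv_stats.tsv"), "cnv_stats")
    write_results(empty, file.path(out, "cnv_candidate_genes.tsv"),
                  "candidates")
    write_bed(data.frame(chrom = character(0), start = integer(0),
                         end = integer(0)),
              file.path(out, "cnv_candidates.bed"))
    return(invisible(list(stats = empty, selection = NULL, genes = empty)))
  }
  stats <- cnv_scan(reliable, pops, reference_cn = cfg$reference_cn)
  sel <- select_cnv_candidates(stats, fraction = cfg$top_fraction_cnv)
  message(sprintf(
    "cnv-scan: top %.3g%% cutoffs: F_ST > %.6g; V_ST > %.6g; %d candidate(s)",
    100 * cfg$top_fraction_cnv, sel$cutoffs["fst"], sel$cutoffs["vst"],
    nrow(sel$candidates)))
  ov <- overlap_genes(sel$candidates, genes)
  fl <- flank_genes(sel$candidates, genes, flank_bp = cfg$flank_bp)
  gene_hits <- rbind(ov, fl)
  write_results(stats, file.path(out, "cnv_stats.tsv"), "cnv_stats")
  write_results(gene_hits, file.path(out, "cnv_candidate_genes.tsv"),
                "candidates")
  write_bed(sel$candidates, file.path(out, "cnv_candidates.bed"))
  invisible(list(stats = stats, selection = sel, genes = gene_hits))
}

#' Run gene-set over-representation on candidate genes
#'
#' @inheritParams run_snp_scan
#' @param candidate_genes character vector of gene ids (typically the union
#'   of overlap and flank hits from the two scans).
#' @return The enrichment table, invisibly; \code{NULL} when no gene-set
#'   collection is configured (stage skipped with a notice).
#' @export
run_enrich <- function(cfg, candidate_genes) {
  if (is.null(cfg$gmt)) {
    message("enrich: no gene-set collection supplied; stage skipped")
    return(invisible(NULL))
  }
  require_inputs(cfg, c("gmt", "genes"), "enrich")
  out <- ensure_out_dir(cfg)
  sets <- read_gmt(cfg$gmt)
  universe <- gene_universe(read_genes(cfg$genes))
  tab <- if (length(candidate_genes) == 0) {
    message("enrich: empty candidate list; writing header-only output")
    enrich(character(0), universe, sets)[0, ]
  } else {
    enrich(candidate_genes, universe, sets,
           p_max = cfg$p_max, q_max = cfg$q_max)
  }
  write_results(tab, file.path(out, "enrichment.tsv"), "enrichment")
  invisible(tab)
}

#' Run the full pipeline (SNP scan, CNV scan, enrichment, manifest)
#'
#' @inheritParams run_snp_scan
#' @return list with the three stage results, invisibly. A
#'   \code{manifest.json} recording the configuration, input checksums,
#'   cutoffs and package version is written to the output directory.
#' @export
run_all <- function(cfg) {
  snp <- run_snp_scan(cfg)
  cnv <- run_cnv_scan(cfg)
  cand_genes <- unique(c(snp$genes$gene_id, cnv$genes$gene_id))
  enr <- run_enrich(cfg, cand_genes)
  out <- ensure_out_dir(cfg)
  inputs <- Filter(Negate(is.null),
                   cfg[c("vcf", "popmap", "cn", "genes", "gmt")])
  manifest <- list(
    package = "sweepscan",
    version = as.character(packageVersion("sweepscan")),
    config = cfg[setdiff(names(cfg), "chrom_lengths")],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    cutoffs = list(snp = as.list(snp$selection$cutoffs),
                   cnv = as.list(cnv$selection$cutoffs)),
    n_candidates = list(
      snp_windows = if (is.null(snp$selection)) 0L
                    else nrow(snp$selection$candidates),
      cnv_regions = if (is.null(cnv$selection)) 0L
                    else nrow(cnv$selection$candidates),
      genes = length(cand_genes)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(snp = snp, cnv = cnv, enrichment = enr))
}
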