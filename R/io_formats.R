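#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns the biallelic SNP
#' records as a \code{\link{genotype_matrix}} of alt-allele dosages.
#' Multi-allelic, indel and symbolic records are skipped (their count is
#' reported via \code{message()}). Genotype phase is ignored; missing and
#' half-missing genotypes become \code{NA}. Non-diploid genotypes are
#' rejected, not coerced.
#'
#' @param path path to a VCF file with a GT FORMAT field.
#' @param sample_subset optional character vector restricting the samples
#'   kept (order preserved as given); an unknown sample is an error.
#' @param pass_only if \code{TRUE}, keep only records whose FILTER column is
#'   \code{PASS} or \code{.}; by default FILTER is ignored, since site
#'   filtering belongs to the upstream calling pipeline.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, sample_subset = NULL, pass_only = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  hdr_samples <- colnames(vcf)
  if (!is.null(sample_subset)) {
    absent <- setdiff(sample_subset, hdr_samples)
    if (length(absent) > 0)
      stop("sample(s) requested but absent from VCF header: ",
           paste(absent, collapse = ", "))
    vcf <- vcf[, sample_subset]
  }
  n_total <- nrow(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  one_alt <- S4Vectors::elementNROWS(altl) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[one_alt] <- as.character(unlist(altl[one_alt]))
  is_snp <- one_alt & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  if (pass_only) {
    filt <- rr$FILTER
    is_snp <- is_snp & (filt %in% c("PASS", "."))
  }
  n_skipped <- n_total - sum(is_snp)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                    n_skipped))
  vcf <- vcf[is_snp, ]
  rr <- rr[is_snp]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  gt <- as.matrix(gt)
  dos <- gt_to_dosage(gt)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref[is_snp], alt = alt[is_snp],
    stringsAsFactors = FALSE)
  genotype_matrix(sites, dos, colnames(gt))
}

# GT strings -> dosage codes; phase ignored, ploidy != 2 rejected
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  norm <- gsub("|", "/", u, fixed = TRUE)
  ok <- grepl("^[01.]/[01.]$", norm)
  if (any(!ok))
    stop("unsupported genotype code(s) (non-diploid or allele > 1): ",
         paste(u[!ok], collapse = ", "))
  code <- rep(NA_integer_, length(u))
  called <- !grepl(".", norm, fixed = TRUE)
  code[called] <- vapply(strsplit(norm[called], "/", fixed = TRUE),
                         function(a) sum(as.integer(a)), integer(1))
  d <- code[match(as.vector(gt), u)]
  matrix(d, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
}

#' Read a two-column population assignment table
#'
#' Whitespace- or tab-delimited text, no header: individual id, then a group
#' label that normalizes (case-insensitively) to \code{HG} (case group) or
#' \code{CG} (control group).
#'
#' @param path path to the table.
#' @return A \code{\link{population_map}}.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("cannot read population map: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "group"),
                    colClasses = "character")
  population_map(tab$id, tab$group)
}

#' Read a copy-number matrix from TSV
#'
#' Expected layout: a header row carrying the individual ids, then one row
#' per CNV region: chromosome, 0-based start, exclusive end, region id,
#' followed by one copy-number value per individual. The header may or may
#' not name the four leading columns; only its last \eqn{n} fields are taken
#' as sample ids.
#'
#' @param path path to the TSV file.
#' @return A \code{\link{cn_matrix}}.
#' @export
read_cn_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read CN matrix: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2) stop("CN matrix must have a header row and >= 1 region")
  if (any(nf != nf[1]))
    stop("ragged CN matrix: row ", which(nf != nf[1])[1],
         " has ", nf[nf != nf[1]][1], " fields, expected ", nf[1])
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  tab <- read.table(path, header = FALSE, sep = "\t", skip = 1,
                    stringsAsFactors = FALSE, quote = "")
  n_ind <- ncol(tab) - 4L
  if (n_ind < 1) stop("CN matrix must have at least one sample column")
  ids <- utils::tail(header, n_ind)
  vals <- as.matrix(tab[, -(1:4), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric copy-number value in CN matrix")
  regions <- data.frame(chrom = as.character(tab[[1]]),
                        start = as.integer(tab[[2]]),
                        end = as.integer(tab[[3]]),
                        region_id = as.character(tab[[4]]),
                        stringsAsFactors = FALSE)
  cn_matrix(regions, vals, ids)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 \code{gene}-type features (1-based inclusive coordinates) are
#' converted to the package-internal 0-based half-open convention; BED
#' intervals are already half-open and pass through. Input need not be
#' sorted; output is sorted by chromosome then start.
#'
#' @param path path to the annotation file.
#' @param format \code{"gff3"} or \code{"bed"}; default guessed from the
#'   file extension.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{gene_id}, \code{gene_name}.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  if (!file.exists(path)) stop("cannot read gene file: ", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) {
      keep <- as.character(md$type) == "gene"
      gr <- gr[keep]
      md <- S4Vectors::mcols(gr)
    }
    gid <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
    gname <- if ("Name" %in% names(md)) as.character(md$Name) else gid
  } else {
    gid <- if ("name" %in% names(md)) as.character(md$name) else
      paste0("gene", seq_along(gr))
    gname <- gid
  }
  gid[is.na(gid)] <- paste0("gene", which(is.na(gid)))
  gname[is.na(gname)] <- gid[is.na(gname)]
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "*"
  # GRanges is 1-based closed on both formats after import; back to half-open
  genes <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand, gene_id = gid, gene_name = gname,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Read a GMT gene-set collection
#'
#' One set per line: term id, term name (or URL), then member gene ids, all
#' tab-separated. Empty member lists are an error.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors; \code{names()} are term ids and
#'   each element carries a \code{term_name} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need term id, name and >= 1 gene")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT term ", f[1], " has no member genes")
    sets[[f[1]]] <- structure(genes, term_name = f[2])
  }
  if (anyDuplicated(names(sets))) stop("duplicated term id in GMT file")
  sets
}

result_columns <- list(
  window_stats = c("chrom", "start", "end", "n_snps", "pi_hg", "pi_cg",
                   "pi_ratio", "fst"),
  cnv_stats = c("chrom", "start", "end", "region_id", "maf", "silhouette",
                "vst", "fst", "t_stat", "df", "p_value",
                "mean_hg", "mean_cg", "var_hg", "var_cg", "var_total",
                "n_hg", "n_cg"),
  candidates = c("chrom", "start", "end", "interval_id", "gene_id",
                 "relation", "distance_bp"),
  enrichment = c("term_id", "term_name", "k", "K", "n", "N", "p_value",
                 "q_value", "significant"))

#' Write a result table to TSV (and candidates to BED)
#'
#' Writes one of the pipeline's result tables with a fixed, documented
#' column order and floating-point values at 6 significant digits. For
#' \code{kind = "candidates"} a companion 3-column BED file (0-based
#' half-open) is written next to the TSV when \code{bed_path} is given.
#'
#' @param rows data.frame of the corresponding kind (possibly empty).
#' @param path output TSV path.
#' @param kind one of \code{"window_stats"}, \code{"cnv_stats"},
#'   \code{"candidates"}, \code{"enrichment"}.
#' @param bed_path optional BED output path (candidates only).
#' @return \code{path}, invisibly.
#' @export
write_results <- function(rows, path,
                          kind = c("window_stats", "cnv_stats",
                                   "candidates", "enrichment"),
                          bed_path = NULL) {
  kind <- match.arg(kind)
  cols <- result_columns[[kind]]
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0)
    rows <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0)
    stop("result table of kind '", kind, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  out <- rows[, cols, drop = FALSE]
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path)
  if (kind == "candidates" && !is.null(bed_path)) {
    bed <- unique(out[, c("chrom", "start", "end"), drop = FALSE])
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write intervals as BED3
#'
#' Candidate windows/regions in 0-based half-open BED, sorted and unique.
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- unique(intervals[, c("chrom", "start", "end"), drop = FALSE])
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  write.table(format(bed, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a copy-number matrix to TSV
#'
#' Inverse of \code{\link{read_cn_matrix}}; values at 6 significant digits.
#'
#' @param cnm a \code{\link{cn_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cn_matrix <- function(cnm, path) {
  stopifnot(is(cnm, "cn_matrix"))
  header <- c("chrom", "start", "end", "region_id", cnm$individual_ids)
  vals <- signif(cnm$values, 6)
  body <- cbind(cnm$regions[, c("chrom", "start", "end", "region_id")],
                as.data.frame(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
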