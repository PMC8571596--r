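# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(d) {
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end))
}

interval_ids <- function(intervals) {
  if (!is.null(intervals$region_id)) as.character(intervals$region_id)
  else paste(intervals$chrom, intervals$start, intervals$end, sep = ":")
}

#' Genes overlapping candidate intervals
#'
#' A gene is assigned to an interval when their half-open spans share at
#' least one base (strand is ignored). Backed by an interval-tree overlap
#' query, not an all-pairs scan.
#'
#' @param intervals data.frame of candidate windows or CNV regions
#'   (\code{chrom}, \code{start}, \code{end}, optionally \code{region_id}).
#' @param genes gene table from \code{\link{read_genes}}.
#' @return data.frame with one row per (interval, gene) overlap:
#'   \code{chrom}, \code{start}, \code{end}, \code{interval_id},
#'   \code{gene_id}, \code{relation = "overlap"}, \code{distance_bp = 0}.
#' @export
overlap_genes <- function(intervals, genes) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), interval_id = character(0),
                      gene_id = character(0), relation = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE)
  if (nrow(intervals) == 0 || nrow(genes) == 0) {
    if (nrow(intervals) > 0)
      warning("no genes available for overlap annotation")
    return(empty)
  }
  orphan <- setdiff(unique(intervals$chrom), unique(genes$chrom))
  if (length(orphan) > 0)
    warning("no genes on chromosome(s): ", paste(orphan, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(as_granges(intervals),
                                      as_granges(genes))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    chrom = intervals$chrom[qi], start = intervals$start[qi],
    end = intervals$end[qi], interval_id = interval_ids(intervals)[qi],
    gene_id = genes$gene_id[si], relation = rep("overlap", length(qi)),
    distance_bp = rep(0L, length(qi)),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes flanking candidate intervals within a distance
#'
#' Assigns gene G to interval I when the gap between their nearest edges is
#' at most \code{flank_bp} on either side and the two do not overlap
#' (overlapping genes are reported by \code{\link{overlap_genes}} only).
#' The default 2 Mb reflects the usual reach of long-range regulatory
#' effects quoted for CNV annotation.
#'
#' @inheritParams overlap_genes
#' @param flank_bp maximum edge-to-edge gap in bp (per side).
#' @return data.frame in the same layout as \code{\link{overlap_genes}} with
#'   \code{relation = "flank"} and the edge gap in \code{distance_bp}.
#' @export
flank_genes <- function(intervals, genes, flank_bp = 2e6) {
  stopifnot(flank_bp >= 0)
  if (nrow(intervals) == 0 || nrow(genes) == 0)
    return(overlap_genes(intervals[0, , drop = FALSE], genes[0, , drop = FALSE]))
  gi <- as_granges(intervals)
  gg <- as_granges(genes)
  # overlap query on intervals widened by flank_bp, then drop true overlaps
  widened <- GenomicRanges::resize(
    gi, GenomicRanges::width(gi) + 2 * (flank_bp + 1), fix = "center")
  hits <- GenomicRanges::findOverlaps(widened, gg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gi[qi], gg[si])
  keep <- !is.na(d) & d > 0 & d <= flank_bp
  # distance() is 0 both for true overlaps and for abutting ranges; keep
  # only the abutting case (no shared base in the half-open convention)
  abut <- !is.na(d) & d == 0 &
    (genes$end[si] <= intervals$start[qi] | genes$start[si] >= intervals$end[qi])
  keep <- keep | abut
  qi <- qi[keep]; si <- si[keep]; d <- d[keep]
  out <- data.frame(
    chrom = intervals$chrom[qi], start = intervals$start[qi],
    end = intervals$end[qi], interval_id = interval_ids(intervals)[qi],
    gene_id = genes$gene_id[si], relation = rep("flank", length(qi)),
    distance_bp = as.integer(d), stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$chrom, out$start, out$distance_bp, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicated gene universe
#'
#' Background gene list for enrichment: unique, sorted gene ids from an
#' annotation table (case-sensitive).
#'
#' @param genes gene table from \code{\link{read_genes}}.
#' @return Character vector of unique gene ids.
#' @export
gene_universe <- function(genes) {
  if (nrow(genes) == 0) return(character(0))
  sort(unique(as.character(genes$gene_id)))
}
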