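#' @importFrom stats quantile pt phyper p.adjust rbinom rbeta rnorm runif setNames var
#' @importFrom utils read.table write.table count.fields packageVersion
#' @importFrom methods is
NULL

GROUP_LEVELS <- c("HG", "CG")

#' Construct a biallelic SNP genotype matrix
#'
#' The central SNP container of the package: a set of biallelic SNP sites and,
#' for each diploid individual, the alt-allele dosage at every site (0, 1, 2,
#' or \code{NA} for a missing/half-missing genotype).
#'
#' @param sites data.frame with columns \code{chrom} (character), \code{pos}
#'   (1-based integer bp), \code{ref}, \code{alt} (single-base alleles).
#' @param dosages integer matrix, \code{nrow(sites)} rows by one column per
#'   individual; entries in \{0, 1, 2, NA\}.
#' @param individual_ids character vector of unique sample names, one per
#'   dosage column.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(sites, dosages, individual_ids) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  dosages <- as.matrix(dosages)
  if (nrow(sites) != nrow(dosages))
    stop("sites and dosages disagree on the number of SNP records")
  if (length(individual_ids) != ncol(dosages))
    stop("individual_ids and dosages disagree on the number of samples")
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad))
    stop("dosage codes must be 0, 1, 2 or NA")
  # positions strictly increasing within each chromosome
  if (nrow(sites) > 0) {
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    dosages <- dosages[o, , drop = FALSE]
    rownames(sites) <- NULL
    by_chr <- split(sites$pos, sites$chrom)
    if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))))
      stop("duplicate SNP positions within a chromosome")
  }
  dimnames(dosages) <- list(NULL, individual_ids)
  structure(
    list(sites = sites, dosages = dosages,
         individual_ids = as.character(individual_ids)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d individuals (%s)\n",
              nrow(x$sites), length(x$individual_ids),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Construct a two-group population map
#'
#' Assigns every individual to the case group \code{"HG"} or the control
#' group \code{"CG"}.
#'
#' @param ids character vector of individual ids.
#' @param groups character vector of labels, one of \code{"HG"}/\code{"CG"}
#'   per id (case-insensitive).
#' @return A named character vector of class \code{population_map}.
#' @export
population_map <- function(ids, groups) {
  ids <- as.character(ids)
  groups <- toupper(as.character(groups))
  if (length(ids) != length(groups))
    stop("ids and groups must have equal length")
  if (anyDuplicated(ids))
    stop("duplicated individual id in population map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !(groups %in% GROUP_LEVELS)
  if (any(bad))
    stop("population labels must be HG or CG; offending entries: ",
         paste(sprintf("%s=%s", ids[bad], groups[bad]), collapse = ", "))
  for (g in GROUP_LEVELS)
    if (!any(groups == g)) stop("population group ", g, " is empty")
  structure(setNames(groups, ids), class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("population_map: %d individuals (HG = %d, CG = %d)\n",
              length(x), sum(x == "HG"), sum(x == "CG")))
  invisible(x)
}

#' Ids of the individuals assigned to one group
#' @param pops a \code{population_map}.
#' @param group \code{"HG"} or \code{"CG"}.
#' @return Character vector of ids.
#' @export
group_ids <- function(pops, group) {
  group <- match.arg(toupper(group), GROUP_LEVELS)
  names(pops)[unclass(pops) == group]
}

#' Construct a copy-number matrix
#'
#' CNV regions by individuals, holding diploid-total copy numbers
#' (reference state 2). Values may be fractional: they are read-depth
#' estimates, not calls.
#'
#' @param regions data.frame with columns \code{chrom}, \code{start}
#'   (0-based), \code{end} (exclusive), \code{region_id} (unique).
#' @param values numeric matrix, regions x individuals, all values >= 0.
#' @param individual_ids character vector of sample names.
#' @return An object of class \code{cn_matrix}.
#' @export
cn_matrix <- function(regions, values, individual_ids) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("chrom", "start", "end", "region_id") %in% names(regions)))
  values <- as.matrix(values)
  if (nrow(regions) != nrow(values))
    stop("regions and values disagree on the number of regions")
  if (length(individual_ids) != ncol(values))
    stop("individual_ids and values disagree on the number of samples")
  if (anyDuplicated(regions$region_id))
    stop("region ids must be unique")
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  if (any(regions$end <= regions$start))
    stop("every region must satisfy end > start")
  if (any(values < 0, na.rm = TRUE) || anyNA(values))
    stop("copy-number values must be non-negative and non-missing")
  rownames(values) <- regions$region_id
  colnames(values) <- individual_ids
  rownames(regions) <- NULL
  structure(
    list(regions = regions, values = values,
         individual_ids = as.character(individual_ids)),
    class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d CNV regions x %d individuals\n",
              nrow(x$regions), length(x$individual_ids)))
  invisible(x)
}

# internal: check that every individual of a matrix-like object has a label
check_samples_mapped <- function(individual_ids, pops) {
  missing <- setdiff(individual_ids, names(pops))
  if (length(missing) > 0)
    stop("individuals absent from the population map: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
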