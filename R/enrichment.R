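#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability \eqn{P(X \ge k)} of drawing at least \code{k}
#' term members when \code{n} genes are drawn without replacement from a
#' universe of \code{N} genes containing \code{K} term members.
#'
#' @param k observed candidate genes in the term.
#' @param K term size within the universe.
#' @param n number of candidate genes in the universe.
#' @param N universe size.
#' @return The p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (k > K || K > N || k > n || n > N || min(k, K, n, N) < 0)
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment with monotonicity enforcement; the input order is
#' preserved in the output.
#'
#' @param p_values numeric vector in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every gene set with at least one candidate hit for
#' over-representation of the candidate genes against the annotation
#' universe, then applies Benjamini-Hochberg FDR control across the tested
#' terms. Candidates outside the universe are dropped with a warning (they
#' cannot be a draw from the background).
#'
#' @param candidates character vector of candidate gene ids.
#' @param universe character vector of background gene ids.
#' @param sets gene-set collection from \code{\link{read_gmt}} (or any named
#'   list of gene-id vectors, optionally carrying \code{term_name}
#'   attributes).
#' @param p_max nominal significance threshold (strict: p < p_max).
#' @param q_max FDR threshold (inclusive: q <= q_max).
#' @return data.frame sorted by p-value with columns \code{term_id},
#'   \code{term_name}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p_value}, \code{q_value}, \code{significant}.
#' @export
enrich <- function(candidates, universe, sets, p_max = 0.05, q_max = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty gene universe")
  candidates <- unique(as.character(candidates))
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside),
            " candidate gene(s) absent from the universe: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
    candidates <- intersect(candidates, universe)
  }
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(as.character(sets[[id]])), universe)
    K <- length(members)
    k <- length(intersect(members, candidates))
    if (k == 0) return(NULL)
    nm <- attr(sets[[id]], "term_name")
    data.frame(term_id = id,
               term_name = if (is.null(nm)) id else nm,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$p_value < p_max & out$q_value <= q_max
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
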