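#' Construct an AnnotationSet
#'
#' @param terms named list, term -> character vector of gene ids.
#' @param background character vector of population gene ids; defaults to
#'   the union of all annotated genes.
#' @param dropEmpty drop terms that end up empty (e.g. after intersecting
#'   with a restricted background).
#' @return an [AnnotationSet][AnnotationSet-class].
#' @export
annotationSet <- function(terms, background = NULL, dropEmpty = FALSE) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (dropEmpty) terms <- terms[lengths(terms) > 0L]
  if (is.null(background))
    background <- sort(unique(unlist(terms, use.names = FALSE)))
  new("AnnotationSet", terms = terms, background = unique(background))
}

#' Read a GMT annotation file into an AnnotationSet
#'
#' @param path GMT file path.
#' @param background optional explicit background population.
#' @return an [AnnotationSet][AnnotationSet-class].
#' @export
readAnnotationGMT <- function(path, background = NULL) {
  annotationSet(parseGeneSets(path, format = "gmt"), background = background)
}

#' Upper-tail hypergeometric p-value (standard or EASE)
#'
#' Standard mode is `P(X >= k)` for the overlap of a query of size `n` with
#' a term of size `K` in a background of size `N`. EASE mode (the DAVID
#' conservative variant) evaluates the same tail at `max(k - 1, 0)`, so it
#' is always at least as large as the standard p-value.
#'
#' @param k overlap count (vectorized).
#' @param n query size.
#' @param K term size.
#' @param N background size.
#' @param mode `"standard"` or `"ease"`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' hypergeomPValue(5, 5, 5, 20)            # 1 / choose(20, 5)
#' hypergeomPValue(5, 5, 5, 20, "ease")    # 76 / choose(20, 5)
#' @export
hypergeomPValue <- function(k, n, K, N, mode = c("standard", "ease")) {
  mode <- match.arg(mode)
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N))
    stop("hypergeomPValue: bounds violated (need 0 <= k <= min(n, K), ",
         "n <= N, K <= N)")
  kk <- if (mode == "ease") pmax(k - 1, 0) else k
  # P(X >= kk) with X ~ Hypergeom(N, K, n)
  phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, mapped back to the
#' input order (a validated wrapper around `p.adjust(method = "BH")`).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bhFDR <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("bhFDR: p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Overrepresentation of annotation terms in a gene query
#'
#' One row per term overlapping the query (k >= 1), hypergeometric p-value,
#' BH q-value across all tested terms, rows sorted by increasing p. Query
#' genes outside the background are dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param annotations an [AnnotationSet][AnnotationSet-class].
#' @param qThreshold FDR threshold for the significance flag.
#' @param mode hypergeometric mode (see [hypergeomPValue()]).
#' @return data.frame (term, k, n, K, N, p, q, flag).
#' @export
enrichTerms <- function(query, annotations, qThreshold = 0.05,
                        mode = c("standard", "ease")) {
  mode <- match.arg(mode)
  stopifnot(is(annotations, "AnnotationSet"))
  bg <- annotationBackground(annotations)
  query <- unique(as.character(query))
  outside <- setdiff(query, bg)
  if (length(outside)) {
    warning("enrichTerms: dropping ", length(outside),
            " query gene(s) outside the background")
    query <- intersect(query, bg)
  }
  if (!length(query)) stop("enrichTerms: empty query after background ",
                           "intersection")
  N <- length(bg)
  n <- length(query)
  terms <- annotationTerms(annotations)
  k <- vapply(terms, function(g) length(intersect(g, query)), integer(1))
  K <- lengths(terms)
  keep <- k >= 1L
  out <- data.frame(term = names(terms)[keep], k = k[keep], n = n,
                    K = unname(K[keep]), N = N,
                    p = hypergeomPValue(k[keep], n, K[keep], N, mode = mode),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bhFDR(out$p)
  out$flag <- out$q < qThreshold
  out[order(out$p, out$term), , drop = FALSE]
}
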