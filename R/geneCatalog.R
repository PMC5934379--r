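#' Parse gene feature sets from GMT or two-column TSV files
#'
#' GMT lines are `name<TAB>description<TAB>member1<TAB>member2...`; the
#' two-column TSV layout is `(set-name, gene_id)` rows. Within-set duplicate
#' gene ids are collapsed (first occurrence kept), preserving member order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return named list, set name -> character vector of gene ids.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdesc\tG1\tG2", tf)
#' parseGeneSets(tf)
#' @export
parseGeneSets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  if (format == "gmt") {
    for (i in seq_along(lines)) {
      if (!keep[i]) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      f <- f[nzchar(f)]
      if (length(f) < 3L)
        stop(sprintf("malformed GMT line %d in %s: need name, description, %s",
                     i, path, "and at least one member"))
      nm <- f[1]
      if (nm %in% names(sets))
        stop(sprintf("duplicate set name '%s' at line %d in %s", nm, i, path))
      sets[[nm]] <- unique(f[-(1:2)])
    }
  } else {
    for (i in seq_along(lines)) {
      if (!keep[i]) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L || !nzchar(f[1]) || !nzchar(f[2]))
        stop(sprintf("malformed TSV line %d in %s: need (set-name, gene_id)",
                     i, path))
      sets[[f[1]]] <- c(sets[[f[1]]], f[2])
    }
    sets <- lapply(sets, unique)
    if (any(lengths(sets) == 0L)) stop("empty member list in ", path)
  }
  if (!length(sets)) stop("no gene sets found in ", path)
  sets
}

#' Merge evidence-source gene sets into a FeatureCatalog
#'
#' Union by gene id across sources; each feature records every source set it
#' appears in. The catalog is canonically ordered by gene id, so merging is
#' idempotent and independent of input order.
#'
#' @param sets named list, source tag -> character vector of gene ids.
#' @param symbols optional named character vector mapping gene_id -> symbol;
#'   unmapped ids reuse the id as symbol.
#' @return a [FeatureCatalog][FeatureCatalog-class].
#' @examples
#' mergeFeatureSets(list(A = c("G1", "G2"), B = c("G2", "G3")))
#' @export
mergeFeatureSets <- function(sets, symbols = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a non-empty named list of gene id vectors")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  ids <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(ids))
    message("mergeFeatureSets: empty union of gene sets")
  src <- vapply(ids, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = ";")
  }, character(1))
  sym <- if (is.null(symbols)) ids else {
    out <- unname(symbols[ids])
    ifelse(is.na(out), ids, out)
  }
  new("FeatureCatalog",
      features = data.frame(gene_id = ids, symbol = sym,
                            sources = unname(src),
                            stringsAsFactors = FALSE, row.names = NULL),
      provenance = vapply(sets, length, integer(1)))
}

#' Screen features for correlation with an outcome
#'
#' Per-feature Pearson correlation with the outcome, two-sided p-value from
#' the exact t transform `t = R * sqrt((n - 2) / (1 - R^2))` on n - 2 degrees
#' of freedom, and FDR q-values (Benjamini-Hochberg). Zero-variance features
#' are flagged excluded rather than passed.
#'
#' @param expr numeric matrix (features x samples) or a
#'   `SummarizedExperiment`.
#' @param outcome numeric vector aligned with the samples.
#' @param qThreshold FDR threshold for the pass flag (default 0.05).
#' @return data.frame (gene_id, r, p, q, pass, excluded) with attribute
#'   `fdr_procedure = "BH"`.
#' @export
correlationScreen <- function(expr, outcome, qThreshold = 0.05) {
  m <- .asExprMatrix(expr)
  if (ncol(m) != length(outcome))
    stop("outcome length must match the number of samples")
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  if (anyNA(outcome)) stop("outcome must not contain missing values")
  n <- ncol(m)
  excl <- apply(m, 1L, function(x) anyNA(x) || sd(x) == 0) | sd(outcome) == 0
  r <- rep(NA_real_, nrow(m))
  if (any(!excl))
    r[!excl] <- as.vector(cor(t(m[!excl, , drop = FALSE]), outcome))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- rep(NA_real_, length(p))
  q[!excl] <- p.adjust(p[!excl], method = "BH")
  out <- data.frame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    r = r, p = p, q = q,
                    pass = !excl & !is.na(q) & q < qThreshold,
                    excluded = excl,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fdr_procedure") <- "BH"
  attr(out, "q_threshold") <- qThreshold
  out
}

#' Write a FeatureCatalog to TSV
#'
#' @param catalog a [FeatureCatalog][FeatureCatalog-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "FeatureCatalog"))
  write.table(featureTable(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asExprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  expr
}
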