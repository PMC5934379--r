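#' Wrap an expression matrix into a SummarizedExperiment
#'
#' Expression containers in this package are `SummarizedExperiment` objects
#' with a single `exprs` assay (features x samples, log2 intensities after
#' normalization) and a `level` flag (`"probe"` or `"gene"`) in the
#' metadata.
#'
#' @param values numeric matrix with feature row names and sample column
#'   names.
#' @param level `"probe"` or `"gene"`.
#' @return a `SummarizedExperiment`.
#' @export
expressionSE <- function(values, level = c("probe", "gene")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature row names and sample column names")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (level == "gene" && anyDuplicated(rownames(values)))
    stop("gene-level matrices must not contain duplicate feature ids")
  se <- SummarizedExperiment(assays = list(exprs = values))
  metadata(se)$level <- level
  se
}

#' @rdname expressionSE
#' @param x a `SummarizedExperiment` built by [expressionSE()].
#' @export
exprLevel <- function(x) metadata(x)$level %||% "probe"

#' Merge two probe-level platforms on shared probe identifiers
#'
#' Keeps the intersection of probe ids (in the first matrix's order) and
#' concatenates the sample columns; dropped probe counts are reported.
#'
#' @param m1,m2 probe-level expression matrices or `SummarizedExperiment`s.
#' @return a probe-level `SummarizedExperiment`.
#' @export
mergePlatforms <- function(m1, m2) {
  if (is(m1, "SummarizedExperiment") && exprLevel(m1) != "probe" ||
      is(m2, "SummarizedExperiment") && exprLevel(m2) != "probe")
    stop("mergePlatforms expects probe-level input")
  a <- .asExprMatrix(m1); b <- .asExprMatrix(m2)
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared)) stop("mergePlatforms: no shared probe identifiers")
  if (length(intersect(colnames(a), colnames(b))))
    stop("mergePlatforms: duplicated sample ids across platforms")
  message(sprintf("mergePlatforms: dropped %d + %d non-shared probes",
                  nrow(a) - length(shared), nrow(b) - length(shared)))
  expressionSE(cbind(a[shared, , drop = FALSE], b[shared, , drop = FALSE]),
               level = "probe")
}

#' Quantile normalization across samples
#'
#' Each sample's sorted values are replaced by the across-sample mean of
#' order statistics; tied values within a sample receive the mean of their
#' tied reference quantiles and per-sample rank order is preserved
#' (delegates to `limma::normalizeQuantiles(ties = TRUE)`). The operation
#' is idempotent and makes all sample columns identical after sorting.
#'
#' @param m expression matrix or `SummarizedExperiment`; no missing values.
#' @return object of the same kind as the input.
#' @export
quantileNormalize <- function(m) {
  x <- .asExprMatrix(m)
  if (anyNA(x))
    stop("quantileNormalize: missing values present; impute upstream")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (is(m, "SummarizedExperiment")) {
    assay(m) <- out
    m
  } else out
}

#' Summarize probe-level expression to gene level
#'
#' One output row per gene symbol, the per-sample median (or mean) over the
#' gene's probes. Unmapped probes are dropped and counted.
#'
#' @param m probe-level matrix or `SummarizedExperiment`.
#' @param probe2gene named character vector (probe -> gene) or a two-column
#'   data.frame (probe, gene).
#' @param stat `"median"` (robust default) or `"mean"`.
#' @return gene-level `SummarizedExperiment`.
#' @export
summarizeToGene <- function(m, probe2gene, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (is(m, "SummarizedExperiment") && exprLevel(m) != "probe")
    stop("summarizeToGene expects probe-level input")
  x <- .asExprMatrix(m)
  if (is.data.frame(probe2gene))
    probe2gene <- setNames(as.character(probe2gene[[2]]),
                           as.character(probe2gene[[1]]))
  genes <- probe2gene[rownames(x)]
  mapped <- !is.na(genes)
  if (!any(mapped)) stop("summarizeToGene: no probe maps to a gene")
  if (any(!mapped))
    message("summarizeToGene: dropped ", sum(!mapped), " unmapped probe(s)")
  x <- x[mapped, , drop = FALSE]
  genes <- genes[mapped]
  f <- if (stat == "median") median else mean
  idx <- split(seq_len(nrow(x)), genes)
  out <- t(vapply(idx, function(i) {
    apply(x[i, , drop = FALSE], 2L, f)
  }, numeric(ncol(x))))
  colnames(out) <- colnames(x)
  expressionSE(out[sort(rownames(out)), , drop = FALSE], level = "gene")
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' Computes pairwise Pearson correlations between samples; a sample is
#' flagged when its mean correlation to all other samples falls below
#' `cohort mean - thresholdSD * SD`. An average-linkage dendrogram on the
#' `1 - correlation` distance is returned for reporting (the deterministic
#' rule replaces visual dendrogram inspection). Constant samples are
#' flagged as degenerate.
#'
#' @param m expression matrix or `SummarizedExperiment` (>= 4 samples).
#' @param thresholdSD z-score cut (default 3).
#' @return list with `flagged` (sample ids), `meanCor`, `cutoff`,
#'   `dendrogram` (an `hclust`), `degenerate` (constant samples).
#' @export
flagOutlierSamples <- function(m, thresholdSD = 3) {
  x <- .asExprMatrix(m)
  if (ncol(x) < 4L) stop("flagOutlierSamples: need at least 4 samples")
  degenerate <- colnames(x)[apply(x, 2L, sd) == 0]
  ok <- setdiff(colnames(x), degenerate)
  cc <- suppressWarnings(cor(x))
  diag(cc) <- NA
  meanCor <- rowMeans(cc, na.rm = TRUE)
  mc <- meanCor[ok]
  cutoff <- mean(mc) - thresholdSD * sd(mc)
  flagged <- names(mc)[mc < cutoff]
  d <- as.dist(1 - ifelse(is.na(cc), 1, cc))
  list(flagged = sort(c(flagged, degenerate)),
       meanCor = meanCor, cutoff = cutoff,
       dendrogram = hclust(d, method = "average"),
       degenerate = degenerate)
}

#' Read / write expression matrices as TSV
#'
#' First column = feature id, header = sample ids.
#'
#' @param path file path.
#' @param level expression level flag.
#' @param log2Transform apply `log2` on read (for raw-scale input).
#' @return [readExpressionTSV()] returns a `SummarizedExperiment`;
#'   [writeExpressionTSV()] the path, invisibly.
#' @export
readExpressionTSV <- function(path, level = c("probe", "gene"),
                              log2Transform = FALSE) {
  level <- match.arg(level)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  if (log2Transform) m <- log2(m)
  expressionSE(m, level = level)
}

#' @rdname readExpressionTSV
#' @param m expression matrix or `SummarizedExperiment`.
#' @export
writeExpressionTSV <- function(m, path) {
  x <- .asExprMatrix(m)
  d <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
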