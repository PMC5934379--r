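#' MDRD estimated glomerular filtration rate
#'
#' IDMS-traceable 4-variable MDRD equation:
#' `175 * scr^-1.154 * age^-0.203 * 0.742^female * 1.212^black`
#' in ml/min/1.73 m^2.
#'
#' @param scr serum creatinine in mg/dl (> 0).
#' @param age age in years (> 0).
#' @param female,black logical flags (vectorized).
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' mdrdEGFR(1.0, 50)                      # ~79.1
#' mdrdEGFR(1.12, 54, female = TRUE)      # ~50.7
#' @export
mdrdEGFR <- function(scr, age, female = FALSE, black = FALSE) {
  if (any(scr <= 0) || any(age <= 0))
    stop("mdrdEGFR: creatinine and age must be positive")
  175 * scr^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Pre-transplant clinical candidate predictors
#'
#' The nine clinical parameters known at the time of transplantation used
#' for exhaustive clinical-model search and as part of the simulated
#' annealing candidate pool.
#'
#' @return character vector of cohort column names.
#' @export
clinicalCandidates <- function() {
  c("donor_age", "donor_gender", "last_donor_creatinine",
    "cold_ischemia_time", "recipient_age", "recipient_gender",
    "transplantation_number", "panel_reactive_antibodies", "hla_mismatches")
}

.alignMarkers <- function(cohort, markers) {
  if (is.null(markers)) return(NULL)
  m <- .asExprMatrix(markers)
  ids <- if ("sample_id" %in% names(cohort)) as.character(cohort$sample_id)
         else rownames(cohort)
  if (!is.null(colnames(m)) && !is.null(ids) && all(ids %in% colnames(m)))
    m <- m[, ids, drop = FALSE]
  else if (ncol(m) != nrow(cohort))
    stop("marker samples cannot be aligned with the cohort")
  m
}

.encodeClinical <- function(cohort, name, agePerDecade) {
  x <- cohort[[name]]
  switch(name,
    donor_age = if (agePerDecade) as.numeric(x) / 10 else as.numeric(x),
    donor_gender = ,
    recipient_gender = as.numeric(as.character(x) == "f"),
    transplantation_number = as.numeric(as.character(x) == "2nd"),
    panel_reactive_antibodies = {
      v <- as.character(x)
      out <- rep(NA_real_, length(v))
      out[v %in% "0%"] <- 0; out[v %in% "<20%"] <- 1; out[v %in% ">20%"] <- 2
      out
    },
    rejection = as.numeric(as.character(x) == "yes"),
    as.numeric(x))
}

#' Encode a design matrix from cohort columns and marker expression
#'
#' Encodings follow the reporting conventions of the outcome analysis:
#' gender coded m = 0, f = 1 (the coefficient is the m-to-f shift), donor
#' age per decade (configurable), transplantation number 0/1 (1st/2nd),
#' panel-reactive antibodies ordinal 0/1/2 with NA, HLA mismatches and
#' delayed graft function numeric, markers as log2 expression rows of the
#' gene-level matrix. Complete-case: rows with a missing value in any used
#' column or the response are dropped and counted. The response is
#' `egfr_12m`.
#'
#' @param cohort cohort data.frame (see [simulateCohort()] for the column
#'   dictionary).
#' @param predictors character vector of cohort columns and/or marker genes.
#' @param markers optional gene-level expression matrix or
#'   `SummarizedExperiment` (genes x samples).
#' @param agePerDecade scale `donor_age` to decades (default TRUE).
#' @param naAction `"omit"` (complete-case) or `"keep"` (leave NAs in the
#'   matrix, for downstream per-model filtering).
#' @return list with `design` (matrix with `(Intercept)` column), `response`,
#'   `rows` (retained row indices) and `dropped` (count).
#' @export
encodeDesign <- function(cohort, predictors, markers = NULL,
                         agePerDecade = TRUE, naAction = c("omit", "keep")) {
  naAction <- match.arg(naAction)
  mk <- .alignMarkers(cohort, markers)
  cols <- lapply(predictors, function(p) {
    if (p %in% names(cohort)) .encodeClinical(cohort, p, agePerDecade)
    else if (!is.null(mk) && p %in% rownames(mk)) as.numeric(mk[p, ])
    else stop("unresolvable predictor: ", p)
  })
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(cohort))), cols))
  colnames(X) <- c("(Intercept)", predictors)
  y <- as.numeric(cohort$egfr_12m)
  if (naAction == "keep")
    return(list(design = X, response = y, rows = seq_len(nrow(cohort)),
                dropped = 0L))
  ok <- stats::complete.cases(X) & !is.na(y)
  if (any(!ok))
    message("encodeDesign: dropped ", sum(!ok), " incomplete row(s)")
  list(design = X[ok, , drop = FALSE], response = y[ok],
       rows = which(ok), dropped = sum(!ok))
}

#' Ordinary least squares with LOOCV diagnostics
#'
#' Fits the linear model by QR decomposition, computes per-coefficient
#' t-tests, the overall F-test, R-squared, adjusted R-squared
#' (`1 - (1 - R^2)(n - 1)/(n - p - 1)` with p non-intercept predictors) and
#' the PRESS-based LOOCV RMSE / R-squared. Rank deficiency is an error
#' naming the collinear columns.
#'
#' @param design numeric model matrix including an intercept column.
#' @param response numeric outcome.
#' @param rows optional source-row indices carried for bookkeeping.
#' @return a [ModelFit][ModelFit-class].
#' @export
fitOLS <- function(design, response, rows = integer()) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fitOLS: need more observations than coefficients")
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("fitOLS: design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- qr.fitted(qrx, y)
  res <- y - fitted
  rss <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot),
                                drop = FALSE]
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_
  adj <- if (sst > 0) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  if (p > 1L && sst > 0) {
    fstat <- ((sst - rss) / (p - 1)) / sigma2
    fp <- pf(fstat, p - 1, n - p, lower.tail = FALSE)
  } else fstat <- fp <- NA_real_
  Q <- qr.Q(qrx)
  h <- rowSums(Q^2)
  if (any(h > 1 - 1e-10)) {
    lrmse <- lr2 <- NA_real_
  } else {
    pr <- res / (1 - h)
    press <- sum(pr^2)
    lrmse <- sqrt(press / n)
    lr2 <- if (sst > 0) 1 - press / sst else NA_real_
  }
  new("ModelFit",
      predictors = setdiff(colnames(X), "(Intercept)"),
      coefficients = cbind(estimate = beta, se = se, t = tval, p = pval),
      r2 = r2, adjR2 = adj, fStatistic = fstat, fPValue = fp,
      loocvRMSE = lrmse, loocvR2 = lr2, rss = rss,
      n = as.integer(n), df = as.integer(n - p),
      design = X, response = y, hat = h, residuals = res,
      rows = as.integer(rows))
}

#' Fit a model from cohort columns and markers
#'
#' Convenience wrapper: [encodeDesign()] (complete-case) then [fitOLS()].
#'
#' @inheritParams encodeDesign
#' @return a [ModelFit][ModelFit-class].
#' @export
fitModel <- function(cohort, predictors, markers = NULL,
                     agePerDecade = TRUE) {
  enc <- encodeDesign(cohort, predictors, markers = markers,
                      agePerDecade = agePerDecade)
  fitOLS(enc$design, enc$response, rows = enc$rows)
}

#' PRESS-based leave-one-out cross-validation statistics
#'
#' `PRESS = sum((e_i / (1 - h_ii))^2)` from the OLS residuals and hat-matrix
#' leverages; `loocv_rmse = sqrt(PRESS / n)`;
#' `loocv_r2 = 1 - PRESS / SST`. Identical to explicitly refitting the model
#' n times with one observation held out each time.
#'
#' @param design model matrix including intercept.
#' @param response numeric outcome.
#' @return list with `loocvRMSE` and `loocvR2`.
#' @export
pressLOOCV <- function(design, response) {
  X <- as.matrix(design); y <- as.numeric(response)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("pressLOOCV: rank-deficient design")
  Q <- qr.Q(qrx)
  h <- rowSums(Q^2)
  if (any(h > 1 - 1e-10))
    stop("pressLOOCV: a leverage equals 1 (observation determines its ",
         "own fit)")
  res <- y - qr.fitted(qrx, y)
  press <- sum((res / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  list(loocvRMSE = sqrt(press / length(y)),
       loocvR2 = if (sst > 0) 1 - press / sst else NA_real_)
}

# Fast LOOCV RMSE for subset-search objectives; Inf for invalid designs
# (rank deficiency, unit leverage, too few complete rows).
.loocvObjective <- function(Xfull, y, idx) {
  X <- Xfull[, idx, drop = FALSE]
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  if (nrow(X) <= ncol(X) + 1L) return(Inf)
  out <- cpp_ols_press(cbind(1, X), y[ok])
  if (is.na(out[["loocv_rmse"]])) Inf else out[["loocv_rmse"]]
}

#' Exhaustive clinical model search
#'
#' Enumerates every non-empty subset of the candidate clinical parameters,
#' ranks models by LOOCV RMSE (primary) and adjusted R-squared (secondary)
#' and returns the best fit together with the full ranking table. Models
#' containing parameters with missing values (e.g. panel-reactive
#' antibodies) are fit on their complete cases.
#'
#' @param cohort cohort data.frame.
#' @param candidates clinical parameter names (default
#'   [clinicalCandidates()]; at most 15).
#' @param agePerDecade passed to [encodeDesign()].
#' @return list with `fit` (a [ModelFit][ModelFit-class]) and `ranking`
#'   (data.frame: predictors, size, n, loocvRMSE, adjR2).
#' @export
bestClinicalModel <- function(cohort, candidates = clinicalCandidates(),
                              agePerDecade = TRUE) {
  if (length(candidates) > 15L)
    stop("bestClinicalModel: exhaustive search limited to 15 candidates")
  enc <- encodeDesign(cohort, candidates, agePerDecade = agePerDecade,
                      naAction = "keep")
  Xfull <- enc$design[, candidates, drop = FALSE]
  y <- enc$response
  subsets <- unlist(lapply(seq_along(candidates), function(k)
    combn(seq_along(candidates), k, simplify = FALSE)), recursive = FALSE)
  stats <- vapply(subsets, function(idx) {
    X <- Xfull[, idx, drop = FALSE]
    ok <- stats::complete.cases(X) & !is.na(y)
    X <- X[ok, , drop = FALSE]
    if (nrow(X) <= ncol(X) + 1L) return(c(Inf, -Inf, 0))
    out <- cpp_ols_press(cbind(1, X), y[ok])
    if (is.na(out[["loocv_rmse"]])) c(Inf, -Inf, nrow(X))
    else c(out[["loocv_rmse"]], out[["adj_r2"]], nrow(X))
  }, numeric(3))
  ranking <- data.frame(
    predictors = vapply(subsets, function(i) paste(candidates[i],
                                                   collapse = ","),
                        character(1)),
    size = lengths(subsets), n = as.integer(stats[3, ]),
    loocvRMSE = stats[1, ], adjR2 = stats[2, ],
    stringsAsFactors = FALSE)
  o <- order(ranking$loocvRMSE, -ranking$adjR2)
  ranking <- ranking[o, , drop = FALSE]
  rownames(ranking) <- NULL
  best <- candidates[subsets[[o[1]]]]
  list(fit = fitModel(cohort, best, agePerDecade = agePerDecade),
       ranking = ranking)
}

#' Simulated annealing configuration
#'
#' @param sizeMin,sizeMax bounds on the number of non-intercept predictors
#'   (defaults 6 and 8).
#' @param iterations Metropolis iterations per restart (default 5000).
#' @param restarts independent restarts (default 10).
#' @param t0 initial temperature in RMSE units (default 1).
#' @param cooling geometric cooling factor in (0, 1) (default 0.995).
#' @param seed RNG seed for full reproducibility.
#' @return list of class `"SAConfig"`.
#' @export
saConfig <- function(sizeMin = 6L, sizeMax = 8L, iterations = 5000L,
                     restarts = 10L, t0 = 1, cooling = 0.995, seed = 1L) {
  stopifnot(sizeMin >= 1, sizeMin <= sizeMax, iterations >= 0,
            restarts >= 1, cooling > 0, cooling < 1, t0 > 0)
  structure(list(sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts), t0 = t0,
                 cooling = cooling, seed = as.integer(seed)),
            class = "SAConfig")
}

#' Simulated annealing subset search minimizing LOOCV RMSE
#'
#' Searches predictor subsets whose size lies within the configured bounds
#' for the model minimizing the leave-one-out cross-validated RMSE. Moves
#' (swap one predictor in/out, add if below the maximum, drop if above the
#' minimum) are chosen uniformly; acceptance is Metropolis on the change in
#' LOOCV RMSE with geometric cooling `T_k = T0 * cooling^k`. Rank-deficient
#' or otherwise invalid proposals are rejected. The best state ever visited
#' across all restarts is returned; results are fully reproducible given
#' the seed.
#'
#' @param candidates character vector of candidate predictor names (cohort
#'   columns and/or marker genes); at least `sizeMin` of them.
#' @param cohort cohort data.frame.
#' @param markers optional gene-level expression (matrix or
#'   `SummarizedExperiment`).
#' @param config an [saConfig()] list.
#' @param agePerDecade passed to [encodeDesign()].
#' @return a [ModelFit][ModelFit-class] of the best subset found.
#' @export
saSubsetSearch <- function(candidates, cohort, markers = NULL,
                           config = saConfig(), agePerDecade = TRUE) {
  stopifnot(inherits(config, "SAConfig"))
  if (length(candidates) < config$sizeMin)
    stop("saSubsetSearch: fewer candidates than sizeMin")
  enc <- encodeDesign(cohort, candidates, markers = markers,
                      agePerDecade = agePerDecade, naAction = "keep")
  Xfull <- enc$design[, candidates, drop = FALSE]
  y <- enc$response
  nc <- length(candidates)
  sizeMax <- min(config$sizeMax, nc)
  set.seed(config$seed)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  obj <- function(idx) {
    key <- paste(idx, collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- .loocvObjective(Xfull, y, idx)
      cache[[key]] <- v
    }
    v
  }
  bestObj <- Inf
  bestState <- NULL
  for (r in seq_len(config$restarts)) {
    size <- sample(config$sizeMin:sizeMax, 1L)
    state <- sort(sample.int(nc, size))
    cur <- obj(state)
    if (cur < bestObj) { bestObj <- cur; bestState <- state }
    temp <- config$t0
    for (it in seq_len(config$iterations)) {
      out <- setdiff(seq_len(nc), state)
      moves <- c("swap"[length(out) > 0L],
                 "add"[length(state) < sizeMax && length(out) > 0L],
                 "drop"[length(state) > config$sizeMin])
      if (!length(moves)) break
      mv <- moves[sample.int(length(moves), 1L)]
      prop <- switch(mv,
        swap = sort(c(state[-sample.int(length(state), 1L)],
                      out[sample.int(length(out), 1L)])),
        add = sort(c(state, out[sample.int(length(out), 1L)])),
        drop = sort(state[-sample.int(length(state), 1L)]))
      po <- obj(prop)
      d <- po - cur
      if (is.finite(po) && (d <= 0 || runif(1) < exp(-d / temp))) {
        state <- prop
        cur <- po
        if (cur < bestObj) { bestObj <- cur; bestState <- state }
      }
      temp <- temp * config$cooling
    }
  }
  if (is.null(bestState) || !is.finite(bestObj))
    stop("saSubsetSearch: no valid model found")
  fitModel(cohort, candidates[bestState], markers = markers,
           agePerDecade = agePerDecade)
}

#' Iteratively remove non-significant predictors
#'
#' Repeatedly drops the single non-intercept predictor with the largest
#' p-value >= alpha and refits, until every remaining predictor is
#' significant. The intercept is never dropped; if everything is pruned the
#' intercept-only fit is returned with a warning.
#'
#' @param fit a [ModelFit][ModelFit-class].
#' @param alpha two-sided significance threshold (default 0.05).
#' @return a [ModelFit][ModelFit-class].
#' @export
pruneNonsignificant <- function(fit, alpha = 0.05) {
  stopifnot(is(fit, "ModelFit"))
  cur <- fit
  repeat {
    preds <- cur@predictors
    if (!length(preds)) {
      warning("pruneNonsignificant: all predictors pruned; returning ",
              "intercept-only fit")
      return(cur)
    }
    pv <- cur@coefficients[preds, "p"]
    if (max(pv) < alpha) return(cur)
    drop <- preds[which.max(pv)]
    keep <- c("(Intercept)", setdiff(preds, drop))
    cur <- fitOLS(cur@design[, keep, drop = FALSE], cur@response,
                  rows = cur@rows)
  }
}

#' Nested linear model comparison (extra-sum-of-squares F-test)
#'
#' `F = ((RSS_s - RSS_l) / (df_s - df_l)) / (RSS_l / df_l)` with the p-value
#' from the F distribution. By default the smaller model's predictors must
#' be a subset of the larger model's (strict nesting); `quasi = TRUE`
#' relaxes the subset check with a warning, mirroring comparisons in which
#' a predictor of the smaller model leaves the larger one.
#'
#' @param fitSmall,fitLarge [ModelFit][ModelFit-class] objects fit to the
#'   same response vector.
#' @param quasi allow non-nested predictor sets.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anovaNested <- function(fitSmall, fitLarge, quasi = FALSE) {
  stopifnot(is(fitSmall, "ModelFit"), is(fitLarge, "ModelFit"))
  if (fitSmall@n != fitLarge@n ||
      !isTRUE(all.equal(fitSmall@response, fitLarge@response)))
    stop("anovaNested: models must be fit to the same response vector")
  nested <- all(fitSmall@predictors %in% fitLarge@predictors)
  if (!nested) {
    if (!quasi)
      stop("anovaNested: models are not nested; use quasi = TRUE for a ",
           "quasi-nested comparison")
    warning("anovaNested: quasi-nested comparison of non-nested models")
  }
  df1 <- fitSmall@df - fitLarge@df
  if (df1 <= 0) stop("anovaNested: the larger model must use more ",
                     "degrees of freedom")
  Fstat <- ((fitSmall@rss - fitLarge@rss) / df1) /
    (fitLarge@rss / fitLarge@df)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = pf(Fstat, df1, fitLarge@df, lower.tail = FALSE),
       df1 = df1, df2 = fitLarge@df)
}

#' Pairwise Pearson correlations with Bonferroni flags
#'
#' Pearson R and two-sided p-value for every variable pair (pairwise
#' complete observations), flagged significant where `p < alpha / m` with
#' `m` the number of testable pairs. Constant variables yield undefined
#' (NA) entries.
#'
#' @param x numeric matrix or data.frame of variables (columns).
#' @param alpha family-wise error target (default 0.05).
#' @return list with symmetric matrices `r`, `p`, `significant`, plus `m`
#'   and `alpha`.
#' @export
correlationMatrixBonferroni <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  nv <- ncol(x)
  r <- p <- matrix(NA_real_, nv, nv, dimnames = list(colnames(x),
                                                     colnames(x)))
  diag(r) <- 1
  m <- 0L
  for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
    ok <- stats::complete.cases(x[, c(i, j)])
    if (sum(ok) < 3L || sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) next
    n <- sum(ok)
    rr <- cor(x[ok, i], x[ok, j])
    tt <- rr * sqrt((n - 2) / max(1 - rr^2, .Machine$double.eps))
    r[i, j] <- r[j, i] <- rr
    p[i, j] <- p[j, i] <- if (abs(rr) >= 1) 0 else 2 * pt(-abs(tt), n - 2)
    m <- m + 1L
  }
  sig <- !is.na(p) & p < alpha / max(m, 1L)
  list(r = r, p = p, significant = sig, m = m, alpha = alpha)
}

#' Post-operative add-on analysis
#'
#' Refits a base model with each post-transplant parameter added (delayed
#' graft function as a single numeric 0/1/2 predictor; rejection as a
#' binary flag), reporting the adjusted R-squared gain and the nested
#' ANOVA p-value on the branch's complete cases. Additionally tests each
#' marker predictor of the base model for association with delayed graft
#' function (Spearman rank trend across the three ordinal groups) and with
#' rejection (Wilcoxon rank-sum), Bonferroni-corrected over all marker
#' tests performed.
#'
#' @param fit base [ModelFit][ModelFit-class] produced by [fitModel()] /
#'   [saSubsetSearch()] (must carry source-row indices).
#' @param cohort cohort data.frame with `dgf` and `rejection` columns.
#' @param markers optional gene-level expression used for the marker
#'   association tests.
#' @param alpha significance threshold (default 0.05).
#' @return list with one element per branch (`dgf`, `rejection`): base and
#'   augmented adjusted R-squared, `deltaAdjR2`, `anova` (F, p), `n`; plus
#'   `markerTests` (data.frame) and `alpha`.
#' @export
postopAddonAnalysis <- function(fit, cohort, markers = NULL, alpha = 0.05) {
  stopifnot(is(fit, "ModelFit"))
  if (!length(fit@rows))
    stop("postopAddonAnalysis: fit does not carry source-row indices")
  if (!all(c("dgf", "rejection") %in% names(cohort)))
    stop("postopAddonAnalysis: cohort needs dgf and rejection columns")
  branches <- list(
    dgf = as.numeric(cohort$dgf)[fit@rows],
    rejection = .encodeClinical(cohort[fit@rows, , drop = FALSE],
                                "rejection", TRUE))
  out <- list(alpha = alpha)
  for (b in names(branches)) {
    v <- branches[[b]]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning("postopAddonAnalysis: ", b, " entirely missing; skipped")
      out[[b]] <- NULL
      next
    }
    base <- fitOLS(fit@design[ok, , drop = FALSE], fit@response[ok])
    XX <- cbind(fit@design[ok, , drop = FALSE], v[ok])
    colnames(XX) <- c(colnames(fit@design), b)
    aug <- fitOLS(XX, fit@response[ok])
    out[[b]] <- list(adjR2Base = adjR2(base), adjR2Augmented = adjR2(aug),
                     deltaAdjR2 = adjR2(aug) - adjR2(base),
                     anova = anovaNested(base, aug), n = sum(ok))
  }
  mk <- .alignMarkers(cohort, markers)
  tests <- NULL
  if (!is.null(mk)) {
    mkPreds <- intersect(fit@predictors, rownames(mk))
    rowsTests <- list()
    for (g in mkPreds) {
      gv <- as.numeric(mk[g, fit@rows])
      for (b in names(branches)) {
        v <- branches[[b]]
        ok <- !is.na(v)
        if (sum(ok) < 3L) next
        pv <- if (b == "dgf")
          suppressWarnings(cor.test(gv[ok], v[ok],
                                    method = "spearman"))$p.value
        else
          suppressWarnings(wilcox.test(gv[ok][v[ok] == 1],
                                       gv[ok][v[ok] == 0]))$p.value
        rowsTests[[length(rowsTests) + 1L]] <-
          data.frame(marker = g, branch = b, p = pv)
      }
    }
    if (length(rowsTests)) {
      tests <- do.call(rbind, rowsTests)
      tests$pBonferroni <- pmin(tests$p * nrow(tests), 1)
      tests$flag <- tests$pBonferroni < alpha
    }
  }
  out$markerTests <- tests
  out
}
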