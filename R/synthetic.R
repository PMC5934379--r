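#' Simulate an interaction network with planted dense clusters
#'
#' A sparse Erdos-Renyi background graph plus dense planted blocks, each
#' tied to the background by a fixed number of random bridge edges. Stands
#' in for the hybrid protein-interaction network underlying the molecular
#' model; ground-truth cluster memberships are returned for recovery
#' benchmarks.
#'
#' @param nBackground number of background nodes.
#' @param backgroundP background edge probability.
#' @param clusterSizes integer sizes of the planted clusters (each >= 3).
#' @param withinP within-cluster edge probability (> 0; recycled).
#' @param bridgeEdges bridge edges per cluster into the background.
#' @param seed RNG seed (bit-reproducible output).
#' @return list with `graph` (igraph) and `clusters` (list of node-id
#'   vectors).
#' @export
simulatePlantedGraph <- function(nBackground = 60, backgroundP = 0.03,
                                 clusterSizes = c(8, 8, 8), withinP = 0.9,
                                 bridgeEdges = 2, seed = 1) {
  stopifnot(backgroundP >= 0, backgroundP <= 1, nBackground >= 0)
  withinP <- rep_len(withinP, length(clusterSizes))
  if (any(clusterSizes < 3)) stop("planted cluster sizes must be >= 3")
  if (any(withinP <= 0) || any(withinP > 1))
    stop("withinP must lie in (0, 1]: a planted cluster with no possible ",
         "edges is an impossible spec")
  set.seed(seed)
  bg <- if (nBackground > 0) sprintf("BG%03d", seq_len(nBackground))
        else character()
  clusters <- lapply(seq_along(clusterSizes), function(i)
    sprintf("C%d_%02d", i, seq_len(clusterSizes[i])))
  pairUpper <- function(nodes, p) {
    n <- length(nodes)
    if (n < 2L || p <= 0) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- runif(nrow(idx)) < p
    if (!any(pick)) return(NULL)
    cbind(nodes[idx[pick, 1]], nodes[idx[pick, 2]])
  }
  edges <- list(pairUpper(bg, backgroundP))
  for (i in seq_along(clusters))
    edges[[length(edges) + 1L]] <- pairUpper(clusters[[i]], withinP[i])
  if (bridgeEdges > 0 && length(bg))
    for (i in seq_along(clusters))
      edges[[length(edges) + 1L]] <-
        cbind(sample(clusters[[i]], bridgeEdges, replace = TRUE),
              sample(bg, bridgeEdges, replace = TRUE))
  em <- do.call(rbind, edges)
  allNodes <- c(bg, unlist(clusters))
  ed <- if (is.null(em)) data.frame(from = character(), to = character())
        else data.frame(from = em[, 1], to = em[, 2])
  g <- graph_from_data_frame(ed, directed = FALSE, vertices = allNodes)
  list(graph = simplify(g), clusters = clusters)
}

#' Simulate GO-style annotations with planted enriched terms
#'
#' Planted terms are inserted verbatim; the remaining terms are drawn
#' uniformly from the gene population within the size range. The background
#' is the full gene population.
#'
#' @param genes character vector, the background population.
#' @param nTerms number of random (non-planted) terms.
#' @param planted named list, term -> gene set (must be subsets of `genes`).
#' @param termSizeRange integer range for random term sizes.
#' @param seed RNG seed.
#' @return an [AnnotationSet][AnnotationSet-class].
#' @export
simulateAnnotations <- function(genes, nTerms = 200, planted = list(),
                                termSizeRange = c(10, 50), seed = 1) {
  genes <- unique(as.character(genes))
  if (length(planted) &&
      !all(unlist(planted, use.names = FALSE) %in% genes))
    stop("planted term genes must be a subset of the gene population")
  set.seed(seed)
  terms <- lapply(planted, unique)
  lo <- min(termSizeRange); hi <- min(max(termSizeRange), length(genes))
  if (nTerms > 0) {
    for (i in seq_len(nTerms)) {
      sz <- sample(lo:hi, 1L)
      terms[[sprintf("TERM%04d", i)]] <- sample(genes, sz)
    }
  }
  annotationSet(terms, background = genes)
}

# Sample a vector of category labels with fixed total counts, shuffled.
.fixedCounts <- function(labels, counts, n) {
  counts <- round(counts / sum(counts) * n)
  while (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.max(counts)] <-
      counts[which.max(counts)] + 1L
  sample(rep(labels, times = counts))
}

#' Default planted regression coefficients
#'
#' The planted effect structure of the synthetic cohort: donor age (per
#' decade), donor gender (m to f) and five log2 marker expressions, plus a
#' delayed-graft-function effect that acts on the outcome but is not part
#' of the pre-transplant "true model".
#'
#' @return named numeric vector including `(Intercept)` and `dgf`.
#' @export
plantedBetaDefaults <- function() {
  c(`(Intercept)` = -171.83, donor_age = -2.69, donor_gender = 13.95,
    CD2BP2 = 35.41, SF3B1 = 67.29, EGF = 16.66, RALBP1 = -39.27,
    DDX19B = -32.18, dgf = -8.74)
}

# Joint-model t-statistic targets for the causal markers (back-transformed
# from the reported two-sided coefficient p-values at 68 residual df);
# together with the marker correlation structure they fix the relative
# log2 SDs of the causal markers.
.markerTTargets <- function() {
  c(CD2BP2 = 2.82, SF3B1 = 2.96, EGF = 3.47, RALBP1 = 3.51, DDX19B = 2.04)
}

.markerCorDefaults <- function() {
  data.frame(a = c("CD2BP2", "SF3B1", "RALBP1"),
             b = c("DDX19B", "RALBP1", "DDX19B"),
             r = c(0.48, 0.37, -0.5))
}

#' Simulate a transplant cohort with a planted linear eGFR signal
#'
#' Draws donor/recipient ages from a correlated bivariate normal, genders
#' and the categorical covariates with fixed category counts (shuffled),
#' donor creatinine from a lognormal, and >= `nMarkers` log2 marker
#' expressions from a multivariate normal in which five designated causal
#' markers carry the planted effects with the specified correlation
#' structure (repaired to the nearest positive-definite matrix if needed).
#' The outcome is
#' `egfr_12m = intercept + sum(beta * predictor) + beta_dgf * dgf + noise`,
#' truncated at 0. Unless `egfrNoiseSD` is given, the noise SD is solved in
#' closed form so that the population R-squared of the true pre-transplant
#' model (donor age, donor gender, five markers) equals `r2Target`; delayed
#' graft function contributes outcome variance but is not part of that true
#' model. Rejection is generated independent of the outcome.
#'
#' @param n cohort size (default 76).
#' @param seed RNG seed.
#' @param r2Target population R-squared of the true model (default 0.33).
#' @param clinicalR2Target population R-squared of the clinical-only part
#'   of the planted signal (default 0.17); together with `r2Target` this
#'   fixes the total marker-attributable outcome variance.
#' @param plantedBetas named coefficient vector (see
#'   [plantedBetaDefaults()]).
#' @param tTargets joint-model t-statistic targets of the causal markers;
#'   with the correlation structure (variance-inflation corrected) these
#'   set the relative causal-marker SDs, which are then scaled so the
#'   marker variance contribution meets the two R-squared targets.
#' @param markerSDs optional explicit named log2 SDs of the causal markers
#'   (overrides the t-target calibration).
#' @param markerCor data.frame (a, b, r) of causal-marker correlations.
#' @param nMarkers total number of marker genes (>= number of causal ones).
#' @param egfrNoiseSD optional explicit noise SD (overrides calibration).
#' @param donorAgeMean,donorAgeSD donor age distribution (years).
#' @param recipientAgeMean,recipientAgeSD recipient age distribution.
#' @param donorRecipientAgeR donor-recipient age correlation.
#' @param donorMF,recipientMF male/female counts (scaled to `n`).
#' @return list with `cohort` (data.frame), `markers` (gene-level
#'   `SummarizedExperiment`, log2 scale) and `truth` (planted parameters).
#' @export
simulateCohort <- function(n = 76, seed = 1, r2Target = 0.33,
                           clinicalR2Target = 0.17,
                           plantedBetas = plantedBetaDefaults(),
                           tTargets = .markerTTargets(),
                           markerSDs = NULL,
                           markerCor = .markerCorDefaults(),
                           nMarkers = 74, egfrNoiseSD = NULL,
                           donorAgeMean = 54.25, donorAgeSD = 17.35,
                           recipientAgeMean = 54.99, recipientAgeSD = 12.89,
                           donorRecipientAgeR = 0.47,
                           donorMF = c(46, 30), recipientMF = c(48, 28)) {
  stopifnot(n >= 10, abs(donorRecipientAgeR) < 1,
            donorAgeSD > 0, recipientAgeSD > 0)
  causal <- if (!is.null(markerSDs)) names(markerSDs) else names(tTargets)
  stopifnot(all(causal %in% names(plantedBetas)), nMarkers >= length(causal))
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))

  # correlated ages (years), floored at 18
  z <- matrix(rnorm(2 * n), ncol = 2)
  z[, 2] <- donorRecipientAgeR * z[, 1] +
    sqrt(1 - donorRecipientAgeR^2) * z[, 2]
  donorAge <- pmax(18, donorAgeMean + donorAgeSD * z[, 1])
  recipAge <- pmax(18, recipientAgeMean + recipientAgeSD * z[, 2])

  donorGender <- .fixedCounts(c("m", "f"), donorMF, n)
  recipGender <- .fixedCounts(c("m", "f"), recipientMF, n)
  # lognormal with mean 1.12, sd 0.64 on the natural scale
  sdlog <- sqrt(log(1 + (0.64 / 1.12)^2))
  crea <- rlnorm(n, meanlog = log(1.12) - sdlog^2 / 2, sdlog = sdlog)
  cit <- pmax(1, rnorm(n, 14.60, 4.88))
  txNum <- .fixedCounts(c("1st", "2nd"), c(63, 13), n)
  pra <- .fixedCounts(c("0%", "<20%", ">20%", NA), c(47, 8, 6, 15), n)
  hla <- .fixedCounts(0:6, c(16, 8, 15, 17, 9, 7, 4), n)
  rejection <- .fixedCounts(c("yes", "no", NA), c(9, 64, 3), n)
  dgf <- .fixedCounts(c(0, 1, 2), c(42, 21, 13), n)

  # causal marker covariance (log2 scale), PD-repaired if needed
  k <- length(causal)
  R <- diag(k); dimnames(R) <- list(causal, causal)
  for (i in seq_len(nrow(markerCor))) {
    R[markerCor$a[i], markerCor$b[i]] <- markerCor$r[i]
    R[markerCor$b[i], markerCor$a[i]] <- markerCor$r[i]
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("causal marker correlation matrix is not positive definite")

  # closed-form calibration: the clinical planted effects and the dgf
  # effect fix the clinical and post-operative variance shares; the two
  # R2 targets then determine both the noise SD and the total marker
  # variance contribution. Causal-marker SDs are proportioned to the
  # joint-model t targets (VIF-corrected for the marker correlations).
  bm <- plantedBetas[causal]
  pF <- sum(donorGender == "f") / n
  varClin <- plantedBetas[["donor_age"]]^2 * (donorAgeSD / 10)^2 +
    plantedBetas[["donor_gender"]]^2 * pF * (1 - pF)
  dgfProbs <- c(42, 21, 13) / 76
  eDgf <- sum(c(0, 1, 2) * dgfProbs)
  varDgf <- plantedBetas[["dgf"]]^2 *
    (sum(c(0, 1, 4) * dgfProbs) - eDgf^2)
  if (is.null(markerSDs)) {
    total <- varClin / clinicalR2Target
    varSignal <- r2Target * total
    varMark <- varSignal - varClin
    sigma2 <- total - varSignal - varDgf
    if (varMark <= 0 || sigma2 <= 0)
      stop("R2 targets are unattainable given the planted clinical and ",
           "dgf effects")
    vif <- diag(solve(R))
    u0 <- sign(bm) * tTargets[causal] * sqrt(vif)
    quad <- drop(t(u0) %*% R %*% u0)
    if (quad > 0) {
      kappa <- sqrt(varMark * n / (sigma2 * quad))
      markerSDs <- kappa * tTargets[causal] * sqrt(sigma2 * vif) /
        (abs(bm) * sqrt(n))
    } else markerSDs <- numeric(k)
    # markers planted with a zero effect get a plain default spread
    markerSDs[!is.finite(markerSDs) | markerSDs == 0] <- 0.15
    names(markerSDs) <- causal
  }
  D <- diag(markerSDs[causal], k)
  Sigma <- D %*% R %*% D
  dimnames(Sigma) <- list(causal, causal)
  varMark <- drop(t(bm) %*% Sigma %*% bm)
  varSignal <- varClin + varMark
  if (is.null(egfrNoiseSD)) {
    sigma2 <- varSignal * (1 - r2Target) / r2Target - varDgf
    if (sigma2 <= 0)
      stop("r2Target is unattainable given the planted dgf effect")
    egfrNoiseSD <- sqrt(sigma2)
  }

  # causal marker means chosen so the planted mean outcome is ~47.23
  target <- 47.23
  muMark <- if (abs(sum(bm)) < 1e-12) 5 else
    (target - plantedBetas[["(Intercept)"]] -
     plantedBetas[["donor_age"]] * donorAgeMean / 10 -
     plantedBetas[["donor_gender"]] * pF -
     plantedBetas[["dgf"]] * eDgf) / sum(bm)

  mk <- matrix(rnorm(n * k), ncol = k) %*% chol(Sigma)
  mk <- sweep(mk, 2L, rep(muMark, k), `+`)
  colnames(mk) <- causal
  nNoise <- nMarkers - k
  noiseNames <- sprintf("MK%03d", seq_len(nNoise))
  noiseMu <- runif(nNoise, 3, 10)
  noise <- sweep(matrix(rnorm(n * nNoise, sd = 0.15), ncol = nNoise),
                 2L, noiseMu, `+`)
  colnames(noise) <- noiseNames
  markers <- t(cbind(mk, noise))
  colnames(markers) <- ids

  signal <- plantedBetas[["(Intercept)"]] +
    plantedBetas[["donor_age"]] * donorAge / 10 +
    plantedBetas[["donor_gender"]] * (donorGender == "f") +
    drop(mk %*% bm) + plantedBetas[["dgf"]] * dgf
  egfr <- pmax(0, signal + rnorm(n, sd = egfrNoiseSD))

  cohort <- data.frame(
    sample_id = ids, donor_age = donorAge, donor_gender = donorGender,
    last_donor_creatinine = crea, cold_ischemia_time = cit,
    recipient_age = recipAge, recipient_gender = recipGender,
    transplantation_number = txNum, panel_reactive_antibodies = pra,
    hla_mismatches = hla, rejection = rejection, dgf = dgf,
    egfr_12m = egfr, stringsAsFactors = FALSE, row.names = ids)

  totalVar <- varSignal + varDgf + egfrNoiseSD^2
  list(cohort = cohort,
       markers = expressionSE(markers[sort(rownames(markers)), ,
                                      drop = FALSE], level = "gene"),
       truth = list(betas = plantedBetas, causal = causal,
                    sigma = egfrNoiseSD, r2Target = r2Target,
                    populationR2 = varSignal / totalVar,
                    clinicalR2 = varClin / totalVar,
                    markerMu = muMark, markerSigma = Sigma,
                    totalVar = totalVar))
}

#' Simulate probe-level expression from a gene-level matrix
#'
#' Expands each gene into a fixed number of probes (gene value plus a
#' probe-specific constant offset plus small measurement noise) and appends
#' planted outlier samples whose probe values are independently permuted;
#' used for exercising the preprocessing stage with known ground truth.
#'
#' @param markers gene-level matrix or `SummarizedExperiment`.
#' @param probesPerGene probes per gene (default 2).
#' @param nOutliers planted outlier samples appended (default 2).
#' @param offsetSD SD of the per-probe constant offset.
#' @param noiseSD SD of the probe measurement noise.
#' @param seed RNG seed.
#' @return list with `probes` (probe-level `SummarizedExperiment`),
#'   `probe2gene` (named character) and `outlierIds`.
#' @export
simulateProbeLevel <- function(markers, probesPerGene = 2, nOutliers = 2,
                               offsetSD = 0.3, noiseSD = 0.05, seed = 1) {
  x <- .asExprMatrix(markers)
  set.seed(seed)
  genes <- rep(rownames(x), each = probesPerGene)
  probeIds <- sprintf("P%05d", seq_along(genes))
  off <- rnorm(length(genes), sd = offsetSD)
  pm <- x[genes, , drop = FALSE] + off +
    matrix(rnorm(length(genes) * ncol(x), sd = noiseSD), nrow = length(genes))
  rownames(pm) <- probeIds
  outIds <- character()
  if (nOutliers > 0) {
    outIds <- sprintf("OUT%02d", seq_len(nOutliers))
    om <- vapply(seq_len(nOutliers), function(i) sample(pm[, 1 + (i %% ncol(pm))]),
                 numeric(nrow(pm)))
    colnames(om) <- outIds
    pm <- cbind(pm, om)
  }
  list(probes = expressionSE(pm, level = "probe"),
       probe2gene = setNames(genes, probeIds),
       outlierIds = outIds)
}

#' Distribute signature genes across evidence sources
#'
#' Emulates the multi-source gene signature: planted cluster genes,
#' background network genes and ids never present in the network are
#' distributed over named sources (with a fraction of genes shared between
#' two sources), and the expected size of the induced signature subgraph is
#' recorded when the network is supplied.
#'
#' @param clusters list of planted-cluster gene vectors.
#' @param backgroundGenes further network gene ids to include.
#' @param extraUnconnected count of ids absent from the network.
#' @param sourceSplit named fractions summing to 1 (primary source
#'   assignment probabilities).
#' @param overlapFraction fraction of genes also copied to a second source.
#' @param graph optional igraph network for the expected-retained count.
#' @param seed RNG seed.
#' @return list with `sets` (named list, source -> gene ids) and
#'   `expectedRetained` (NA without a graph).
#' @export
simulateSignatureSets <- function(clusters, backgroundGenes = character(),
                                  extraUnconnected = 0,
                                  sourceSplit = c(`LIT-CAN` = 0.05,
                                                  `TX-PERCO` = 0.45,
                                                  `TX-KAINZ` = 0.1,
                                                  `TX-SCIAN` = 0.4),
                                  overlapFraction = 0.05, graph = NULL,
                                  seed = 1) {
  if (abs(sum(sourceSplit) - 1) > 1e-8)
    stop("sourceSplit fractions must sum to 1")
  set.seed(seed)
  unc <- if (extraUnconnected > 0)
    sprintf("UNC%04d", seq_len(extraUnconnected)) else character()
  pool <- unique(c(unlist(clusters, use.names = FALSE),
                   backgroundGenes, unc))
  src <- names(sourceSplit)
  primary <- sample(src, length(pool), replace = TRUE, prob = sourceSplit)
  sets <- split(pool, factor(primary, levels = src))
  nOver <- floor(overlapFraction * length(pool))
  if (nOver > 0) {
    dup <- sample(pool, nOver)
    for (g in dup) {
      other <- setdiff(src, primary[match(g, pool)])
      tgt <- sample(other, 1L)
      sets[[tgt]] <- c(sets[[tgt]], g)
    }
  }
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0L]
  retained <- NA_integer_
  if (!is.null(graph)) {
    keep <- intersect(V(graph)$name, pool)
    sg <- induced_subgraph(graph, keep)
    retained <- sum(degree(sg) > 0)
  }
  list(sets = sets, expectedRetained = retained)
}
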