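# Identification of learning-index correlates: FDR-corrected Spearman
# screening, permutation-based voxelwise GLM, and partial-Spearman edge
# screening.

#' Spearman screening with Benjamini-Hochberg correction
#'
#' For every feature column: Spearman rank correlation with the learning
#' index (midranks for ties) and a two-sided p-value from the t
#' approximation; q-values by Benjamini-Hochberg over the whole feature
#' family; a feature is selected when q < alpha. Constant features are
#' excluded from the family with a warning.
#'
#' Exact null p-values (via the rank-statistic distribution, falling back to
#' the t approximation when ties make it unavailable) keep the BH procedure
#' calibrated at the small cohort sizes this screening is designed for.
#'
#' @param features participants-by-features numeric matrix with column names.
#' @param li learning-index vector.
#' @param alpha FDR level (default 0.05).
#' @return data.frame: feature, rho, p, q, selected, sign, excluded.
#' @export
spearmanScreen <- function(features, li, alpha = 0.05) {
  stopifnot(is.matrix(features), nrow(features) == length(li))
  n <- length(li)
  if (n < 4L) stop("need at least 4 participants")
  if (!all(is.finite(features))) stop("features must be finite")
  sds <- apply(features, 2L, stats::sd)
  excluded <- sds == 0
  if (any(excluded))
    warning("constant features excluded from the FDR family: ",
            paste(colnames(features)[excluded], collapse = ", "))
  rho <- rep(NA_real_, ncol(features))
  p <- rep(NA_real_, ncol(features))
  for (j in which(!excluded)) {
    ct <- suppressWarnings(stats::cor.test(features[, j], li,
                                           method = "spearman"))
    rho[j] <- unname(ct$estimate)
    p[j] <- min(ct$p.value, 1)
  }
  q <- rep(NA_real_, length(p))
  q[!excluded] <- stats::p.adjust(p[!excluded], method = "BH")
  data.frame(feature = colnames(features), rho = rho, p = p, q = q,
             selected = !is.na(q) & q < alpha,
             sign = sign(rho), excluded = excluded, row.names = NULL)
}

#' Benjamini-Hochberg step-up
#'
#' @param p vector of p-values.
#' @param alpha FDR level.
#' @return list: `q` (adjusted p-values, monotone in p), `selected` (logical,
#'   q < alpha).
#' @export
fdrBH <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, selected = !is.na(q) & q < alpha)
}

#' Permutation-based voxelwise GLM
#'
#' Per voxel, fits intensity ~ LI + covariates by ordinary least squares and
#' takes the t statistic of the LI coefficient (optionally a pseudo-t with
#' spatially smoothed residual variance). The null distribution is built by
#' Freedman-Lane permutation: residuals of the reduced (covariates-only)
#' model are permuted, added back to the reduced-model fit, and the full
#' model refitted. The voxel p-value is the rank of the observed |t| among
#' the permuted |t| values, p = (1 + #exceedances) / (nPerm + 1). Voxels with
#' p < voxelP are split by the sign of t, labelled into 26-connected
#' components, and clusters larger than `minCluster` voxels are kept.
#'
#' @param maps participants-by-voxels matrix (in-mask voxels, column order =
#'   `which(mask)`), or participants-long list of 3D maps.
#' @param li learning-index vector.
#' @param covariates data.frame of nuisance regressors (e.g. age, sex);
#'   factors are expanded via `model.matrix`.
#' @param mask logical 3D array giving the voxel geometry.
#' @param nPerm number of permutations (default 10000); if nPerm >= n! all
#'   n! permutations are enumerated instead.
#' @param voxelP voxel-level significance threshold (default 0.005).
#' @param minCluster cluster extent threshold; clusters of size strictly
#'   greater are kept (default 50).
#' @param pseudoTFwhmMm if positive, smooth the residual-variance map with
#'   this FWHM before forming t (pseudo-t); default 0 (plain t).
#' @param voxelSizeMm voxel size for the variance smoothing.
#' @return a \linkS4class{StatMap}.
#' @export
permutationGlmMap <- function(maps, li, covariates, mask, nPerm = 10000L,
                              voxelP = 0.005, minCluster = 50L,
                              pseudoTFwhmMm = 0, voxelSizeMm = 3) {
  if (is.list(maps) && !is.matrix(maps))
    maps <- do.call(rbind, lapply(maps, function(m) m[mask]))
  n <- nrow(maps)
  stopifnot(length(li) == n)
  Z <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  X <- cbind(Z[, 1, drop = FALSE], li = li, Z[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  if (n <= ncol(X)) stop("need more participants than regressors")
  tObs <- glmTStat(X, maps, mask, pseudoTFwhmMm, voxelSizeMm)
  # Freedman-Lane: permute reduced-model residuals
  Hfit <- Z %*% solve(crossprod(Z), crossprod(Z, maps))
  E <- maps - Hfit
  perms <- permutationSet(n, nPerm)
  exceed <- integer(ncol(maps))
  for (k in seq_len(ncol(perms))) {
    tStar <- glmTStat(X, Hfit + E[perms[, k], , drop = FALSE], mask,
                      pseudoTFwhmMm, voxelSizeMm)
    exceed <- exceed + (abs(tStar) >= abs(tObs))
  }
  pvox <- (1 + exceed) / (ncol(perms) + 1)
  dims <- dim(mask)
  tmap <- array(0, dims); tmap[mask] <- tObs
  pmap <- array(1, dims); pmap[mask] <- pvox
  sig <- array(FALSE, dims); sig[mask] <- pvox < voxelP
  labPos <- labelClusters(sig & tmap > 0)
  labNeg <- labelClusters(sig & tmap < 0)
  clusters <- array(0L, dims)
  rows <- list()
  keepClusters <- function(lab, sgn) {
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      vox <- which(lab == id)
      if (length(vox) > minCluster) {
        newLab <- (length(rows) + 1L) * sgn
        clusters[vox] <<- newLab
        peak <- vox[which.max(abs(tmap[vox]))]
        pk <- arrayInd(peak, dims)
        rows[[length(rows) + 1L]] <<- data.frame(
          label = newLab, sign = sgn, size = length(vox),
          peakX = pk[1], peakY = pk[2], peakZ = pk[3],
          peakT = tmap[peak])
      }
    }
  }
  keepClusters(labPos, 1L)
  keepClusters(labNeg, -1L)
  ct <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), sign = integer(), size = integer(),
               peakX = integer(), peakY = integer(), peakZ = integer(),
               peakT = numeric())
  new("StatMap", tmap = tmap, pmap = pmap, clusters = clusters,
      clusterTable = ct,
      settings = list(nPerm = ncol(perms), voxelP = voxelP,
                      minCluster = minCluster, connectivity = 26L,
                      pseudoTFwhmMm = pseudoTFwhmMm))
}

# t statistic of the second column (LI) of design X against each column of Y.
glmTStat <- function(X, Y, mask = NULL, pseudoTFwhmMm = 0, voxelSizeMm = 3) {
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  s2 <- colSums(res^2) / (nrow(X) - ncol(X))
  if (pseudoTFwhmMm > 0 && !is.null(mask)) {
    s2map <- array(0, dim(mask)); s2map[mask] <- s2
    s2map <- gaussianSmooth(s2map, pseudoTFwhmMm, voxelSizeMm)
    s2 <- s2map[mask]
  }
  beta[2L, ] / sqrt(pmax(s2, .Machine$double.eps) * XtXinv[2L, 2L])
}

# nPerm random permutations of 1..n (columns), or all n! when nPerm >= n!.
permutationSet <- function(n, nPerm) {
  if (n <= 7 && nPerm >= factorial(n)) {
    allp <- permuteAll(n)
    return(allp)
  }
  vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
}

permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permuteAll(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(rep(k, ncol(sub)), ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Label connected components of a 3D logical array
#'
#' 26-connectivity (faces, edges and corners) flood fill.
#'
#' @param x logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer 3D array of component labels (0 = background).
#' @export
labelClusters <- function(x, connectivity = 26L) {
  d <- dim(x)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nextLab <- 0L
  todo <- which(x)
  for (s in todo) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    stack <- s
    lab[s] <- nextLab
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      cv <- arrayInd(v, d)
      nb <- sweep(off, 2L, as.integer(cv), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[x[lin] & lab[lin] == 0L]
      lab[lin] <- nextLab
      stack <- c(stack, lin)
    }
  }
  lab
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and the covariates (midranks), residualises the x and
#' y ranks on the covariate ranks, and correlates the residuals. The p-value
#' uses the t approximation with df = n - 2 - k.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of nuisance variables.
#' @return list: rho, p, df.
#' @export
partialSpearman <- function(x, y, covariates) {
  n <- length(x)
  Z <- cbind(1, apply(as.matrix(covariates), 2L, rank))
  rx <- stats::lm.fit(Z, rank(x))$residuals
  ry <- stats::lm.fit(Z, rank(y))$residuals
  rho <- stats::cor(rx, ry)
  df <- n - 2L - (ncol(Z) - 1L)
  tt <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = df), df = df)
}

#' Edge-wise partial-Spearman screening of connectomes
#'
#' For every upper-triangle edge, the partial Spearman correlation between
#' edge strength and the learning index with the covariates as nuisance
#' variables; an edge is selected when its two-sided p falls below `pThresh`
#' (no FDR, matching the edge-screening convention used here). Constant edges
#' are excluded with a warning.
#'
#' @param edges participants-by-edges matrix (named columns, e.g. from
#'   [edgeVector()] per participant), or list of connectome matrices.
#' @param li learning-index vector.
#' @param covariates data.frame of nuisance regressors.
#' @param pThresh selection threshold on the raw p (default 0.005).
#' @return data.frame: edge, rho, p, selected, sign, excluded.
#' @export
edgeScreen <- function(edges, li, covariates, pThresh = 0.005) {
  if (is.list(edges) && !is.matrix(edges))
    edges <- do.call(rbind, lapply(edges, edgeVector))
  n <- nrow(edges)
  stopifnot(length(li) == n)
  sds <- apply(edges, 2L, stats::sd)
  excluded <- sds == 0
  if (any(excluded))
    warning("constant edges excluded: ",
            paste(colnames(edges)[excluded], collapse = ", "))
  Z <- cbind(1, apply(as.matrix(covariates), 2L, rank))
  ry <- stats::lm.fit(Z, rank(li))$residuals
  rx <- stats::lm.fit(Z, colRanks(edges[, !excluded, drop = FALSE]))$residuals
  rho <- rep(NA_real_, ncol(edges))
  rho[!excluded] <- drop(stats::cor(rx, ry))
  df <- n - 2L - (ncol(Z) - 1L)
  tt <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(edge = colnames(edges), rho = rho, p = p,
             selected = !is.na(p) & p < pThresh, sign = sign(rho),
             excluded = excluded, row.names = NULL)
}
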