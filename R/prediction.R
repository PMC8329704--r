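# Leave-one-out prediction of the learning index from screened single- and
# multimodal feature sets.

#' Assemble screened feature sets for prediction
#'
#' Builds the four single-modality feature sets (selected EEG cells,
#' significant morphometry cluster means, significant ALFF cluster means,
#' selected FC edges) plus their column-wise concatenation as the multimodal
#' set. Every column and the learning index are z-scored across participants.
#' A modality with no selected feature contributes a single flagged fallback
#' column (its best-ranked feature) and is marked degenerate.
#'
#' @param modalityFeatures named list (`eeg`, `smri`, `alff`, `fc`) of
#'   participants-by-features matrices of the already-screened columns; an
#'   entry may have 0 columns.
#' @param li learning-index vector.
#' @param fallback named list of single-column fallback matrices used for
#'   degenerate modalities (optional).
#' @return list: `sets` (list of \linkS4class{FeatureSet}, incl.
#'   `multimodal`), `li` (z-scored).
#' @export
assembleFeatures <- function(modalityFeatures, li, fallback = list()) {
  zscore <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2L, stats::sd)
    if (any(s == 0)) stop("constant feature column cannot be normalised")
    sweep(sweep(m, 2L, mu), 2L, s, `/`)
  }
  sets <- list()
  for (nm in names(modalityFeatures)) {
    m <- modalityFeatures[[nm]]
    degenerate <- is.null(m) || ncol(m) == 0L
    if (degenerate) {
      if (is.null(fallback[[nm]])) next
      m <- fallback[[nm]]
    }
    if (is.null(colnames(m))) colnames(m) <- paste0(nm, seq_len(ncol(m)))
    sets[[nm]] <- new("FeatureSet", name = nm, x = zscore(as.matrix(m)),
                      provenance = colnames(m), degenerate = degenerate)
  }
  if (length(sets) > 1L) {
    xs <- lapply(sets, function(s) s@x)
    multi <- do.call(cbind, xs)
    sets$multimodal <- new("FeatureSet", name = "multimodal", x = multi,
                           provenance = unlist(lapply(sets, function(s)
                             paste(s@name, s@provenance, sep = ":")),
                             use.names = FALSE),
                           degenerate = FALSE)
  }
  list(sets = sets, li = as.numeric(scale(li)))
}

# Bayesian linear regression with automatic relevance determination.
# Evidence maximisation with per-weight precision alpha_j and noise
# precision beta (MacKay fixed-point updates); features assumed centred.
ardFit <- function(x, y, maxIter = 300L, tol = 1e-4, alphaCap = 1e10) {
  x <- cbind(1, x)
  p <- ncol(x)
  alpha <- rep(1e-2, p)
  beta <- 1 / max(stats::var(y), 1e-12)
  xtx <- crossprod(x); xty <- crossprod(x, y)
  mOld <- rep(0, p)
  for (it in seq_len(maxIter)) {
    Sinv <- beta * xtx + diag(alpha, p)
    S <- solve(Sinv)
    m <- beta * S %*% xty
    gamma <- 1 - alpha * diag(S)
    alpha <- pmin(as.numeric(gamma / pmax(m^2, 1e-12)), alphaCap)
    res <- y - x %*% m
    beta <- max(length(y) - sum(gamma), 1e-6) / max(sum(res^2), 1e-12)
    if (max(abs(m - mOld)) < tol) break
    mOld <- m
  }
  list(coef = as.numeric(m))
}

ardPredict <- function(fit, x) as.numeric(cbind(1, x) %*% fit$coef)

#' Leave-one-out cross-validated prediction
#'
#' For each participant, a model is trained on the remaining n-1 and used to
#' predict the held-out learning index. Supported models: `svr_linear`
#' (linear epsilon-SVR, C = 1, epsilon = 0.1), `linear` (ordinary least
#' squares), `ardr` (Bayesian automatic relevance determination regression)
#' and `rfr` (random forest, 500 trees). Stochastic fits are re-seeded per
#' fold from `seed`, so repeat calls are identical.
#'
#' @param x participants-by-features matrix (normalised; see
#'   [assembleFeatures()]).
#' @param y learning-index vector (normalised).
#' @param model one of `"svr_linear"`, `"linear"`, `"ardr"`, `"rfr"`.
#' @param seed integer seed for stochastic models.
#' @param normalize `"global"` (default: inputs are taken as already
#'   normalised across the full cohort) or `"fold"` (z-scoring statistics
#'   refit on each training fold and applied to the held-out row).
#' @return numeric vector of held-out predictions.
#' @export
loocvPredict <- function(x, y, model = c("svr_linear", "linear", "ardr",
                                         "rfr"),
                         seed = 1L, normalize = c("global", "fold")) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (n < 3L) stop("need at least 3 participants for LOOCV")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    xte <- x[i, , drop = FALSE]
    if (normalize == "fold") {
      mu <- colMeans(xtr); s <- apply(xtr, 2L, stats::sd)
      s[s == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, s, `/`)
      xte <- sweep(sweep(xte, 2L, mu), 2L, s, `/`)
    }
    preds[i] <- switch(model,
      svr_linear = {
        fit <- e1071::svm(xtr, ytr, type = "eps-regression",
                          kernel = "linear", cost = 1, epsilon = 0.1,
                          scale = FALSE)
        as.numeric(stats::predict(fit, xte))
      },
      linear = {
        fit <- stats::lm.fit(cbind(1, xtr), ytr)
        cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        sum(cbind(1, xte) * cf)
      },
      ardr = ardPredict(ardFit(xtr, ytr), xte),
      rfr = {
        set.seed(childSeed(seed, i))
        fit <- randomForest::randomForest(xtr, ytr, ntree = 500L)
        as.numeric(stats::predict(fit, xte))
      })
  }
  preds
}

#' Prediction performance
#'
#' @param predictions,actual numeric vectors.
#' @return list: `mae` (mean absolute error) and `r` (Pearson correlation of
#'   predicted vs actual; NA if predictions are constant).
#' @export
evaluatePredictions <- function(predictions, actual) {
  stopifnot(length(predictions) == length(actual))
  r <- if (stats::sd(predictions) == 0 || stats::sd(actual) == 0) NA_real_
       else stats::cor(predictions, actual)
  list(mae = mean(abs(predictions - actual)), r = r)
}

#' Steiger's test for two dependent overlapping correlations
#'
#' Compares r(y, x1) against r(y, x2) when both correlations share the
#' variable y (here: the actual LI, correlated with two prediction vectors),
#' using Steiger's (1980) z for dependent correlations with r(x1, x2) as the
#' third correlation.
#'
#' @param r1 correlation of the first predictor with the shared variable.
#' @param r2 correlation of the second predictor with the shared variable.
#' @param r12 correlation between the two predictors.
#' @param n sample size.
#' @return list: z, p (two-sided).
#' @export
compareDependentCorrelations <- function(r1, r2, r12, n) {
  stopifnot(n > 3)
  if (isTRUE(all.equal(r1, r2))) return(list(z = 0, p = 1))
  rbar2 <- ((r1 + r2) / 2)^2
  f <- min((1 - r12) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fit and compare prediction models across feature sets
#'
#' Runs [loocvPredict()] for every feature set and model, evaluates MAE and
#' Pearson r, and tests each single-modality correlation against the
#' multimodal correlation of the same model with Steiger's z.
#'
#' @param assembled output of [assembleFeatures()].
#' @param models character vector of model names (see [loocvPredict()]).
#' @param seed integer seed.
#' @param linearForSingleColumn use ordinary linear regression in place of
#'   SVR whenever a feature set has exactly one column (default TRUE, the
#'   convention for a lone predictor).
#' @return a \linkS4class{PredictionReport}.
#' @export
predictLearning <- function(assembled, models = "svr_linear", seed = 1L,
                            linearForSingleColumn = TRUE) {
  sets <- assembled$sets
  li <- assembled$li
  rows <- list(); preds <- list()
  for (s in sets) for (mod in models) {
    effMod <- if (linearForSingleColumn && ncol(s@x) == 1L &&
                  mod == "svr_linear") "linear" else mod
    pr <- loocvPredict(s@x, li, model = effMod, seed = seed)
    ev <- evaluatePredictions(pr, li)
    preds[[paste(s@name, mod, sep = ".")]] <- pr
    rows[[length(rows) + 1L]] <- data.frame(
      featureSet = s@name, model = mod, modelUsed = effMod,
      mae = ev$mae, r = ev$r)
  }
  scores <- do.call(rbind, rows)
  comp <- list()
  if ("multimodal" %in% scores$featureSet) {
    for (mod in models) {
      pm <- preds[[paste("multimodal", mod, sep = ".")]]
      rMulti <- stats::cor(pm, li)
      for (s in sets) {
        if (s@name == "multimodal") next
        ps <- preds[[paste(s@name, mod, sep = ".")]]
        ct <- compareDependentCorrelations(rMulti, stats::cor(ps, li),
                                           stats::cor(pm, ps), length(li))
        comp[[length(comp) + 1L]] <- data.frame(
          featureSet = s@name, model = mod, rMulti = rMulti,
          rSingle = stats::cor(ps, li), z = ct$z, p = ct$p)
      }
    }
  }
  new("PredictionReport", scores = scores, predictions = preds,
      comparisons = if (length(comp)) do.call(rbind, comp) else data.frame(),
      li = li)
}
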