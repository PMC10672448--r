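# Aquaphotomics chemometric pipeline: water-band selection, MSC, centring,
# PCA, PLS-DA with cross-validated latent-variable selection, and per-class
# figures of merit.

#' Restrict spectra to the first-overtone water band
#'
#' Retains the wavelengths in the 1300-1600 nm band (first overtone of the
#' OH stretching vibrations), inclusive: 301 variables on a 1 nm grid.
#' Errors when the input grid does not cover the band.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param band inclusive wavelength limits in nm.
#' @return the band-restricted [SpectraMatrix-class].
#' @export
selectWaterBand <- function(spectra, band = c(1300, 1600)) {
  wl <- wavelengths(spectra)
  if (min(wl) > band[1] || max(wl) < band[2])
    .stopf("spectral grid [%d, %d] does not cover the %d-%d nm band",
           min(wl), max(wl), band[1], band[2])
  keep <- wl >= band[1] & wl <= band[2]
  spectra[keep, ]
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference spectrum over
#' wavelengths, `x = a + b * ref`, and corrected as `(x - a) / b`, removing
#' the per-sample additive offset and multiplicative scaling that light
#' scatter induces. The default reference is the column mean of the
#' (training) spectra supplied to `mscFitTransform`; test spectra must be
#' corrected with `mscApply` against the training reference to avoid
#' leakage.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param reference optional reference spectrum; defaults to `colMeans(X)`
#'   (requires >= 2 samples).
#' @return `mscFitTransform`: a list with `corrected` (matrix) and `state`
#'   (a [PreprocessState-class] carrying the reference).
#' @examples
#' X <- rbind(a = 1:5, b = 2 * (1:5) + 3)
#' msc <- mscFitTransform(X)
#' msc$corrected
#' @export
mscFitTransform <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) {
    if (nrow(X) < 2L)
      .stopf("at least 2 spectra are needed to fit an MSC reference")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X))
    .stopf("reference length (%d) does not match wavelengths (%d)",
           length(reference), ncol(X))
  state <- methods::new("PreprocessState", mscReference = as.numeric(reference))
  list(corrected = mscApply(X, state), state = state)
}

#' @rdname mscFitTransform
#' @param state a [PreprocessState-class] with a fitted `mscReference`.
#' @return `mscApply`: the corrected matrix.
#' @export
mscApply <- function(X, state) {
  X <- as.matrix(X)
  ref <- state@mscReference
  if (length(ref) != ncol(X))
    .stopf("reference length (%d) does not match wavelengths (%d)",
           length(ref), ncol(X))
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  if (denom < 1e-24) .stopf("MSC reference is constant")
  rm_ <- rowMeans(X)
  b <- as.vector((X - rm_) %*% refc) / denom
  small <- abs(b) < 1e-12
  if (any(small)) {
    ids <- rownames(X)[small]
    if (is.null(ids)) ids <- which(small)
    .stopf("MSC slope below 1e-12 for sample(s): %s",
           paste(ids, collapse = ", "))
  }
  a <- rm_ - b * mean(ref)
  (X - a) / b
}

#' Column mean-centring
#'
#' Centres by the supplied (training) column means; by default the means of
#' `X` itself, so training output has exact zero column means and test data
#' can be centred with the training means.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param columnMeans the centring vector; defaults to `colMeans(X)`.
#' @return the centred matrix, with the means used attached as attribute
#'   `"columnMeans"`.
#' @export
meanCenter <- function(X, columnMeans = NULL) {
  X <- as.matrix(X)
  if (is.null(columnMeans)) columnMeans <- colMeans(X)
  if (length(columnMeans) != ncol(X))
    .stopf("columnMeans length (%d) does not match columns (%d)",
           length(columnMeans), ncol(X))
  out <- sweep(X, 2L, columnMeans)
  attr(out, "columnMeans") <- columnMeans
  out
}

# Orient each component so its largest-|loading| entry is positive;
# reproducible score plots regardless of SVD sign indeterminacy.
.fixSigns <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of pretreated spectra
#'
#' Singular value decomposition of the pretreated (MSC-corrected, centred)
#' matrix: scores are the data projected on the loadings, explained-variance
#' fractions come from the squared singular values. Components are oriented
#' so the largest-magnitude loading is positive.
#'
#' @param X pretreated numeric matrix, samples x wavelengths.
#' @param k number of components, at most `min(nrow(X) - 1, ncol(X))`.
#' @return a list of class `PCAResult`: `scores` (samples x k), `loadings`
#'   (wavelengths x k, orthonormal columns), `explainedVarianceFraction`.
#' @export
pcaSpectra <- function(X, k = 3L) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax)
    .stopf("k = %d exceeds min(samples - 1, wavelengths) = %d", k, kmax)
  s <- svd(X, nu = k, nv = k)
  fixed <- .fixSigns(s$u %*% diag(s$d[seq_len(k)], k), s$v)
  structure(list(scores = fixed$scores, loadings = fixed$loadings,
                 explainedVarianceFraction = s$d[seq_len(k)]^2 / sum(s$d^2)),
            class = "PCAResult")
}

#' Random train/test split
#'
#' Uniform sampling of the test set without replacement, deterministic under
#' the seed. With `stratifyBy`, test samples are allocated across the label's
#' levels proportionally (largest remainders), keeping every class
#' represented in training.
#'
#' @param n total number of samples.
#' @param nTest test-set size, `0 < nTest < n` (58 at the reference n = 195).
#' @param seed integer seed.
#' @param stratifyBy optional label vector of length `n`.
#' @return a list of class `SplitPlan`: `train`, `test` (disjoint index sets
#'   whose union is `1:n`), `seed`.
#' @export
makeSplit <- function(n, nTest, seed = 1L, stratifyBy = NULL) {
  if (nTest <= 0L || nTest >= n)
    .stopf("nTest must satisfy 0 < nTest < n (got nTest = %d, n = %d)",
           nTest, n)
  test <- .withSeed(seed, function() {
    if (is.null(stratifyBy)) return(sort(sample.int(n, nTest)))
    stopifnot(length(stratifyBy) == n)
    f <- factor(stratifyBy)
    prop <- nTest * table(f) / n
    take <- floor(prop)
    rem <- nTest - sum(take)
    if (rem > 0) {
      o <- order(prop - take, decreasing = TRUE)
      take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1L
    }
    sort(unlist(lapply(levels(f), function(lv) {
      idx <- which(f == lv)
      sample(idx, min(take[[lv]], length(idx) - 1L))
    }), use.names = FALSE))
  })
  structure(list(train = setdiff(seq_len(n), test), test = test, seed = seed),
            class = "SplitPlan")
}

# ---- PLS-DA ----------------------------------------------------------------

# One-hot (0/1) class membership matrix with lexicographically ordered
# columns.
.oneHot <- function(labels) {
  f <- factor(labels)
  Y <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Fit a PLS-DA model
#'
#' Class membership is coded one-column-per-class 0/1; X and Y are centred
#' on their training means. Latent variables are extracted sequentially,
#' each weight vector being the dominant left singular vector of the
#' current X-Y cross-covariance (the fixed point of the NIPALS inner loop),
#' with X deflated by its rank-one score/loading approximation so successive
#' X-scores are mutually orthogonal. Regression coefficients
#' `B = W (P'W)^-1 Q'` reproduce the fitted class scores of the sequential
#' form.
#'
#' @param X pretreated numeric matrix, samples x wavelengths (centring is
#'   handled internally and recorded in the model).
#' @param labels class labels, >= 2 classes with >= 2 training samples each.
#' @param nLatent number of latent variables, in
#'   `[1, min(n - 1, wavelengths)]`.
#' @param mscReference optional reference recorded for provenance.
#' @return a [PLSDAModel-class].
#' @export
plsdaFit <- function(X, labels, nLatent, mscReference = numeric(0)) {
  X <- as.matrix(X)
  f <- factor(labels)
  if (nlevels(f) < 2L) .stopf("PLS-DA needs at least 2 classes")
  tab <- table(f)
  if (any(tab < 2L))
    .stopf("class(es) with fewer than 2 training samples: %s",
           paste(names(tab)[tab < 2L], collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  amax <- min(n - 1L, p)
  nLatent <- as.integer(nLatent)
  if (nLatent < 1L || nLatent > amax)
    .stopf("nLatent must be in [1, %d]", amax)
  Y <- .oneHot(f)
  xMean <- colMeans(X); yMean <- colMeans(Y)
  E <- sweep(X, 2L, xMean); Fc <- sweep(Y, 2L, yMean)
  q <- ncol(Y)
  W <- matrix(0, p, nLatent); P <- matrix(0, p, nLatent)
  Q <- matrix(0, q, nLatent); Tm <- matrix(0, n, nLatent)
  for (a in seq_len(nLatent)) {
    M <- crossprod(E, Fc)                       # p x q cross-covariance
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    i <- which.max(abs(w))
    if (w[i] < 0) w <- -w
    tt <- as.vector(E %*% w)
    ss <- sum(tt^2)
    if (ss < 1e-12)
      .stopf("X is exhausted after %d latent variable(s); nLatent too large",
             a - 1L)
    W[, a] <- w
    Tm[, a] <- tt
    P[, a] <- crossprod(E, tt) / ss
    Q[, a] <- crossprod(Fc, tt) / ss
    E <- E - tcrossprod(tt, P[, a])
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  fitted <- sweep(sweep(X, 2L, xMean) %*% B, 2L, yMean, "+")
  colnames(fitted) <- levels(f)
  methods::new("PLSDAModel", nLatent = nLatent, classLabels = levels(f),
               xMean = xMean, yMean = yMean, xWeights = W, xLoadings = P,
               yLoadings = Q, coefficients = B, fitted = fitted,
               mscReference = as.numeric(mscReference))
}

# Class assignment from continuous class scores; ties resolve to the
# lexicographically first label (labels are stored sorted).
.assignClass <- function(scores, classLabels)
  factor(classLabels[max.col(scores, ties.method = "first")],
         levels = classLabels)

#' Predict classes from a PLS-DA model
#'
#' Predicted class scores are `(X - xMean) B + yMean`; each sample is
#' assigned the class with the maximal score, ties resolving to the
#' lexicographically first class label.
#'
#' @param model a [PLSDAModel-class].
#' @param X pretreated numeric matrix on the model's wavelength grid.
#' @return a list with `class` (factor) and `scores` (samples x classes).
#' @export
plsdaPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@xMean))
    .stopf("wavelength grid mismatch: model has %d variables, data has %d",
           length(model@xMean), ncol(X))
  scores <- sweep(sweep(X, 2L, model@xMean) %*% model@coefficients, 2L,
                  model@yMean, "+")
  colnames(scores) <- model@classLabels
  list(class = .assignClass(scores, model@classLabels), scores = scores)
}

#' Per-class sensitivity, specificity and balanced error
#'
#' For the given class, `Sn = TP / (TP + FN)` and, treating all other
#' classes as negative, `Sp = TN / (TN + FP)`; the classification error is
#' the balanced `Er = 1 - (Sn + Sp) / 2`.
#'
#' @param true,predicted label vectors of equal length.
#' @param class the class evaluated (must occur among the true labels).
#' @param nLatent,phase metadata recorded in the result (`phase` is `"cv"`
#'   or `"prediction"`).
#' @return a one-row `data.frame`: `class`, `n_latent`, `phase`,
#'   `sensitivity`, `specificity`, `error`.
#' @examples
#' classMetrics(rep(c("a", "b"), c(10, 10)),
#'              rep(c("a", "b", "a", "b"), c(9, 1, 2, 8)), "a")
#' @export
classMetrics <- function(true, predicted, class, nLatent = NA_integer_,
                         phase = c("prediction", "cv")) {
  phase <- match.arg(phase)
  stopifnot(length(true) == length(predicted))
  true <- as.character(true); predicted <- as.character(predicted)
  if (!class %in% true)
    .stopf("class '%s' is absent from the true labels", class)
  pos <- true == class; hit <- predicted == class
  tp <- sum(pos & hit); fn <- sum(pos & !hit)
  tn <- sum(!pos & !hit); fp <- sum(!pos & hit)
  sn <- tp / (tp + fn)
  sp <- if ((tn + fp) > 0L) tn / (tn + fp) else NA_real_
  data.frame(class = class, n_latent = as.integer(nLatent), phase = phase,
             sensitivity = sn, specificity = sp,
             error = 1 - (sn + sp) / 2, stringsAsFactors = FALSE)
}

# Mean per-class balanced error over the classes present in `true`.
.balancedError <- function(true, predicted) {
  classes <- unique(as.character(true))
  mean(vapply(classes, function(cl)
    classMetrics(true, predicted, cl)$error, numeric(1)))
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin over folds. Venetian blinds: every k-th sample in order.
.makeFolds <- function(labels, k, scheme = c("stratified", "venetian")) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  fold <- integer(n)
  if (scheme == "venetian") {
    fold <- ((seq_len(n) - 1L) %% k) + 1L
  } else {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  }
  fold
}

# Coefficients from the first `a` components of stored weight/loading
# matrices.
.coefA <- function(W, P, Q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE], Wa),
               t(Q[, seq_len(a), drop = FALSE]))
}

.pickLV <- function(curve) which.min(curve)  # smallest count wins ties

#' Choose the number of latent variables by cross-validation
#'
#' k-fold cross-validation over candidate latent-variable counts
#' `1..maxLV`: per count, the mean (over folds and classes) balanced
#' classification error on held-out samples; the count minimizing it is
#' returned, the smallest count on ties. Folds are stratified by class
#' (venetian blinds selectable); a training fold losing a class entirely is
#' an error advising stratification.
#'
#' @param X pretreated training matrix, samples x wavelengths.
#' @param labels training class labels.
#' @param maxLV largest candidate count (capped by the fold training size).
#' @param kFolds number of folds.
#' @param seed integer seed for the fold assignment.
#' @param scheme `"stratified"` (default) or `"venetian"`.
#' @return a list: `nLatent` (chosen), `curve` (`data.frame` of `lv`,
#'   `cv_error`), `cvPredicted` (held-out predicted labels, samples x
#'   candidate counts).
#' @export
chooseLV <- function(X, labels, maxLV = 15L, kFolds = 10L, seed = 1L,
                     scheme = c("stratified", "venetian")) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  fold <- .withSeed(seed, function() .makeFolds(labels, kFolds, scheme))
  amax <- min(maxLV, n - max(table(fold)) - 1L, ncol(X))
  if (amax < 1L) .stopf("too few samples for cross-validation")
  classes <- sort(unique(labels))
  pred <- matrix(NA_character_, n, amax)
  for (kf in sort(unique(fold))) {
    tr <- fold != kf
    if (!all(classes %in% labels[tr]))
      .stopf("fold %d loses a class from training; use stratified folds", kf)
    fit <- plsdaFit(X[tr, , drop = FALSE], labels[tr], amax)
    Xv <- sweep(X[!tr, , drop = FALSE], 2L, fit@xMean)
    for (a in seq_len(amax)) {
      B <- .coefA(fit@xWeights, fit@xLoadings, fit@yLoadings, a)
      sc <- sweep(Xv %*% B, 2L, fit@yMean, "+")
      pred[!tr, a] <- as.character(.assignClass(sc, fit@classLabels))
    }
  }
  curve <- vapply(seq_len(amax), function(a)
    .balancedError(labels, pred[, a]), numeric(1))
  best <- .pickLV(curve)
  list(nLatent = as.integer(best),
       curve = data.frame(lv = seq_len(amax), cv_error = curve),
       cvPredicted = pred)
}

#' Run the full PLS-DA experiment for one label field
#'
#' The published pipeline, end to end: water-band selection, random
#' train/test split, MSC fitted on the training set, mean centring on
#' training means, cross-validated latent-variable selection, final fit, and
#' per-class sensitivity/specificity/balanced error in both the
#' cross-validation and the test-set prediction phase. Fully reproducible
#' under the seed.
#'
#' @param spectra a labelled [SpectraMatrix-class].
#' @param labelField one of the five categorical fields.
#' @param nTest test-set size (58 at n = 195).
#' @param kFolds cross-validation folds.
#' @param maxLV largest candidate latent-variable count.
#' @param seed integer seed driving the split and the folds.
#' @param band water-band limits in nm.
#' @param stratifySplit stratify the train/test split by the label.
#' @param absorbance analyse `log10(1/R)` instead of reflectance.
#' @return a list of class `plsdaExperiment`: `metrics` (one row per class
#'   per phase: class, n_latent, phase, sensitivity, specificity, error,
#'   all rounded to 3 decimals in `metricsTable()`), `nLatent`, `cvCurve`,
#'   `model`, `split`, `labelField`.
#' @export
runPLSDAExperiment <- function(spectra, labelField, nTest = 58L,
                               kFolds = 10L, maxLV = 15L, seed = 1L,
                               band = c(1300, 1600), stratifySplit = FALSE,
                               absorbance = FALSE) {
  labs <- spectraLabels(spectra)
  if (!labelField %in% names(labs))
    .stopf("label field '%s' is not present; have: %s", labelField,
           paste(names(labs), collapse = ", "))
  y <- as.character(labs[[labelField]])
  xb <- selectWaterBand(spectra, band)
  X <- spectraValues(xb)
  if (absorbance) {
    if (any(X <= 0)) .stopf("absorbance transform requires positive reflectance")
    X <- log10(1 / X)
  }
  n <- nrow(X)
  split <- makeSplit(n, nTest, seed,
                     stratifyBy = if (stratifySplit) y else NULL)
  msc <- mscFitTransform(X[split$train, , drop = FALSE])
  Xtr <- msc$corrected
  Xte <- mscApply(X[split$test, , drop = FALSE], msc$state)
  cv <- chooseLV(Xtr, y[split$train], maxLV = maxLV, kFolds = kFolds,
                 seed = seed)
  model <- plsdaFit(Xtr, y[split$train], cv$nLatent,
                    mscReference = msc$state@mscReference)
  predTest <- plsdaPredict(model, Xte)
  classes <- model@classLabels
  metrics <- do.call(rbind, c(
    lapply(classes, function(cl)
      classMetrics(y[split$train], cv$cvPredicted[, cv$nLatent], cl,
                   nLatent = cv$nLatent, phase = "cv")),
    lapply(classes, function(cl)
      classMetrics(y[split$test], as.character(predTest$class), cl,
                   nLatent = cv$nLatent, phase = "prediction"))))
  structure(list(metrics = metrics, nLatent = cv$nLatent,
                 cvCurve = cv$curve, model = model, split = split,
                 labelField = labelField, seed = seed),
            class = "plsdaExperiment")
}

#' @export
print.plsdaExperiment <- function(x, ...) {
  cat(sprintf("PLS-DA experiment on '%s': %d LV(s)\n", x$labelField,
              x$nLatent))
  print(metricsTable(x))
  invisible(x)
}

#' Figures-of-merit table for a PLS-DA experiment
#'
#' One row per class and phase with sensitivity, specificity and balanced
#' classification error, rounded to 3 decimals.
#'
#' @param experiment a result of [runPLSDAExperiment()].
#' @return a `data.frame`.
#' @export
metricsTable <- function(experiment) {
  m <- experiment$metrics
  m$sensitivity <- .roundReport(m$sensitivity)
  m$specificity <- .roundReport(m$specificity)
  m$error <- .roundReport(m$error)
  m
}
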