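#' @include AllClasses.R AllGenerics.R featureSet.R
NULL

#' Labeling schemes over the five emotional conditions
#'
#' The five conditions are quadrant combinations of the 2-D
#' valence-arousal affective space plus its neutral centre, so three
#' labelings exist: \code{arousal} (excited and distressed are high,
#' relaxed and depressed low, neutral neutral: 3 classes),
#' \code{valence} (excited and relaxed positive, distressed and
#' depressed negative, neutral neutral: 3 classes) and \code{emotion}
#' (identity: 5 classes).
#'
#' @param name scheme name.
#' @return list with \code{name}, \code{map} (named character:
#'   condition -> class) and \code{classOrder}.
#' @examples
#' labelScheme("arousal")$map[["excited"]]   # "high"
#' @export
labelScheme <- function(name = c("arousal", "valence", "emotion")) {
  name <- match.arg(name)
  emotionOrder <- c("distressed", "excited", "depressed", "relaxed",
                    "neutral")
  switch(name,
    arousal = list(
      name = "arousal",
      map = c(excited = "high", distressed = "high",
              relaxed = "low", depressed = "low", neutral = "neutral"),
      classOrder = c("high", "low", "neutral")),
    valence = list(
      name = "valence",
      map = c(excited = "positive", relaxed = "positive",
              distressed = "negative", depressed = "negative",
              neutral = "neutral"),
      classOrder = c("positive", "negative", "neutral")),
    emotion = list(
      name = "emotion",
      map = stats::setNames(emotionOrder, emotionOrder),
      classOrder = emotionOrder))
}

#' Map condition labels to scheme classes
#'
#' @param conditions character vector of condition labels.
#' @param scheme a scheme from \code{\link{labelScheme}} (or its name).
#' @return factor with levels in scheme class order.
#' @export
makeLabels <- function(conditions, scheme) {
  if (is.character(scheme)) scheme <- labelScheme(scheme)
  unknown <- setdiff(unique(conditions), names(scheme$map))
  if (length(unknown))
    stop("condition(s) unknown to scheme '", scheme$name, "': ",
         paste(unknown, collapse = ", "))
  factor(unname(scheme$map[conditions]), levels = scheme$classOrder)
}

#' k-fold one-vs-one RBF-SVM cross-validation
#'
#' Observations are shuffled with the given seed and split into k
#' contiguous equal-sized folds (the paper-style global shuffle that
#' mixes subjects; a stratified option exists for small or unbalanced
#' inputs).  Per fold, feature columns are standardized on the training
#' rows only, a one-against-one RBF-kernel SVM (libsvm via e1071; one
#' binary machine per class pair, majority vote with a deterministic
#' first-max tie-break in class order) is trained with cost C and
#' gamma = 1 / (n_features * var(training values)), and train and test
#' accuracies are recorded.  Identical seeds give identical folds,
#' accuracies and confusion matrices.
#'
#' @param features a \linkS4class{FeatureSet} (typically the reduced set
#'   from \code{\link{runSelection}}) or an observations x features
#'   matrix.
#' @param scheme label scheme name or object (see
#'   \code{\link{labelScheme}}); ignored when \code{labels} is given.
#' @param labels optional factor of class labels per observation.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param cost SVM cost parameter C (default 1).  A vector of
#'   candidates enables a small per-fold grid search: each candidate is
#'   scored by 3-fold cross-validation inside the training rows and the
#'   best (ties to the smallest cost) is used -- optional and off by
#'   default since the modelled protocol reports no tuning.
#' @param gamma RBF width; default the 1/(p * var) heuristic per fold.
#' @param stratify logical; split each class evenly over folds.
#' @param groupBy optional grouping vector (e.g. participant ids) for
#'   leave-one-group-out evaluation: folds become the groups and k is
#'   ignored.  The stricter alternative to the protocol's global
#'   shuffle, non-default.
#' @return a \linkS4class{CVReport}.
#' @export
crossValidate <- function(features, scheme = "emotion", labels = NULL,
                          k = 5L, seed = 42L, cost = 1, gamma = NULL,
                          stratify = FALSE, groupBy = NULL) {
  if (is(features, "FeatureSet")) {
    X <- t(featureValues(features))
    if (is.null(labels))
      labels <- makeLabels(observationLabels(features)$condition, scheme)
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("labels required for a plain matrix input")
  }
  schemeName <- if (is.character(scheme)) scheme else scheme$name
  labels <- droplevels(as.factor(labels))
  classOrder <- levels(labels)
  n <- nrow(X)
  if (!is.null(groupBy)) {
    groupBy <- as.factor(groupBy)
    if (length(groupBy) != n) stop("groupBy must have one entry per row")
    k <- nlevels(groupBy)
    if (k < 2L) stop("leave-one-group-out needs >= 2 groups")
  }
  k <- as.integer(k)
  if (k < 2L || n < k) stop("need k >= 2 and at least k observations")

  set.seed(seed)
  perm <- sample.int(n)
  foldOf <- integer(n)
  if (!is.null(groupBy)) {
    foldOf <- as.integer(groupBy)
  } else if (stratify) {
    for (cl in classOrder) {
      cls <- perm[labels[perm] == cl]
      foldOf[cls] <- rep_len(seq_len(k), length(cls))
    }
  } else {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    foldOf[perm] <- rep(seq_len(k), sizes)
  }

  foldTrain <- foldTest <- numeric(k)
  conf <- matrix(0L, length(classOrder), length(classOrder),
                 dimnames = list(classOrder, classOrder))
  nPairwise <- NA_integer_
  gammaUsed <- numeric(k)
  for (f in seq_len(k)) {
    tr <- foldOf != f; te <- !tr
    if (any(table(labels[tr]) == 0L))
      stop("a class is absent from the training fold; ",
           "consider stratify = TRUE")
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sd, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd, "/")
    g <- if (is.null(gamma)) {
      v <- stats::var(as.vector(Xtr))
      if (v <= 0) 1 / ncol(Xtr) else 1 / (ncol(Xtr) * v)
    } else gamma
    gammaUsed[f] <- g
    costF <- if (length(cost) > 1L)
      pickCost(Xtr, labels[tr], classOrder, cost, g, seed + f) else cost
    model <- e1071::svm(Xtr, factor(labels[tr], levels = classOrder),
                        kernel = "radial", cost = costF, gamma = g,
                        scale = FALSE)
    nPairwise <- length(model$rho)
    predTr <- stats::predict(model, Xtr)
    predTe <- stats::predict(model, Xte)
    foldTrain[f] <- 100 * mean(predTr == labels[tr])
    foldTest[f] <- 100 * mean(predTe == labels[te])
    conf <- conf + table(factor(labels[te], levels = classOrder),
                         factor(predTe, levels = classOrder))
  }

  new("CVReport",
      scheme = schemeName, classOrder = classOrder,
      foldTrain = foldTrain, foldTest = foldTest,
      confusionCounts = unclass(conf), seed = as.integer(seed), k = k,
      nPairwise = as.integer(nPairwise),
      hyperparams = list(cost = cost, gamma = gammaUsed,
                         gammaRule = if (is.null(gamma))
                           "1/(p*var)" else "fixed",
                         stratify = stratify))
}

## Inner 3-fold grid scoring of SVM cost candidates on training rows.
pickCost <- function(Xtr, ytr, classOrder, costs, gamma, seed) {
  set.seed(seed)
  ids <- sample(rep_len(1:3, nrow(Xtr)))
  score <- vapply(costs, function(cc) {
    acc <- 0
    for (f in 1:3) {
      tr <- ids != f
      if (any(table(ytr[tr]) == 0L)) return(-Inf)
      m <- e1071::svm(Xtr[tr, , drop = FALSE],
                      factor(ytr[tr], levels = classOrder),
                      kernel = "radial", cost = cc, gamma = gamma,
                      scale = FALSE)
      acc <- acc + mean(stats::predict(m, Xtr[!tr, , drop = FALSE]) ==
                          ytr[!tr])
    }
    acc
  }, numeric(1))
  costs[which.max(score)]
}

#' @describeIn crossValidate mean test accuracy in percent.
#' @param object a CVReport.
#' @export
setMethod("testAccuracy", "CVReport", function(object)
  mean(object@foldTest))

#' @describeIn crossValidate mean training accuracy in percent.
#' @export
setMethod("trainAccuracy", "CVReport", function(object)
  mean(object@foldTrain))

#' @describeIn crossValidate pooled confusion matrix; rows = actual
#'   class, columns = predicted, in scheme class order.  With
#'   \code{percent = TRUE} rows are normalized to sum to 100; an actual
#'   class with no pooled observations yields an all-zero row flagged in
#'   the \code{"emptyClasses"} attribute.
#' @param percent logical.
#' @export
setMethod("confusionMatrix", "CVReport", function(object, percent = TRUE) {
  m <- object@confusionCounts
  if (!percent) return(m)
  rs <- rowSums(m)
  out <- 100 * m / ifelse(rs == 0, 1, rs)
  attr(out, "emptyClasses") <- rownames(m)[rs == 0]
  out
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport (", object@scheme, ", ", object@k, "-fold, ",
      object@nPairwise, " pairwise SVMs)\n", sep = "")
  cat(sprintf("  train %.2f +/- %.2f %% | test %.2f +/- %.2f %%\n",
              mean(object@foldTrain), stats::sd(object@foldTrain),
              mean(object@foldTest), stats::sd(object@foldTest)))
})

#' Accuracy summary of several CV reports
#'
#' One row per report: scheme, mean and sd of train and test accuracy
#' (percent), matching the "a +/- b" reporting format.
#'
#' @param reports named list of \linkS4class{CVReport}.
#' @return data.frame.
#' @export
accuracyTable <- function(reports) {
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(run = nm, scheme = r@scheme,
               trainMean = mean(r@foldTrain),
               trainSd = stats::sd(r@foldTrain),
               testMean = mean(r@foldTest), testSd = stats::sd(r@foldTest),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Render a confusion matrix as a heatmap
#'
#' Base-graphics heatmap of the row-normalized confusion matrix
#' (rows = actual class), with the percentage printed in each cell.
#'
#' @param report a \linkS4class{CVReport}.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the percent matrix.
#' @export
plotConfusion <- function(report, file = NULL) {
  m <- confusionMatrix(report, percent = TRUE)
  k <- nrow(m)
  if (!is.null(file)) grDevices::png(file, width = 640, height = 560)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  zlim = c(0, 100), axes = FALSE, xlab = "", ylab = "",
                  main = paste0("Confusion (", report@scheme, "), %"))
  graphics::axis(1, seq_len(k), colnames(m), las = 2)
  graphics::axis(2, seq_len(k), rev(rownames(m)), las = 2)
  graphics::mtext("predicted", side = 1, line = 4.5)
  graphics::mtext("actual", side = 2, line = 4.5)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i, sprintf("%.1f", m[i, j]),
                   col = if (m[i, j] > 50) "white" else "black")
  invisible(m)
}
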