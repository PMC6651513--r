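#' Train the feed-forward ANN classifier
#'
#' A 16-12-9-2 fully connected network: sigmoid activations in the two
#' hidden layers (12 and 9 units) and a softmax output pair, trained by
#' full-batch gradient descent on the cross-entropy loss. Inputs are
#' expected to be standardized with training-split statistics.
#'
#' @param x numeric matrix (n x 16) of standardized feature vectors.
#' @param y labels (\code{"healthy"}/\code{"me"}), both classes present.
#' @param hidden hidden layer widths (default c(12, 9)).
#' @param epochs,lr gradient-descent schedule.
#' @param seed RNG seed for the weight initialisation.
#' @return An object of class \code{"retfuseANN"}.
#' @export
trainANN <- function(x, y, hidden = c(12L, 9L), epochs = 400L, lr = 0.5,
                     seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("both classes must be present")
  Y <- outer(y, classes, "==") * 1          # n x K
  withSeed(seed, {
    sizes <- c(ncol(x), hidden, ncol(Y))
    W <- lapply(seq_len(length(sizes) - 1L), function(i)
      matrix(rnorm(sizes[i] * sizes[i + 1L], sd = 1 / sqrt(sizes[i])),
             sizes[i], sizes[i + 1L]))
    b <- lapply(sizes[-1L], numeric)
    sigm <- function(z) 1 / (1 + exp(-z))
    n <- nrow(x)
    for (ep in seq_len(epochs)) {
      a1 <- sigm(sweep(x %*% W[[1]], 2L, b[[1]], "+"))
      a2 <- sigm(sweep(a1 %*% W[[2]], 2L, b[[2]], "+"))
      logits <- sweep(a2 %*% W[[3]], 2L, b[[3]], "+")
      P <- t(softmaxProb(t(logits)))
      d3 <- (P - Y) / n
      d2 <- (d3 %*% t(W[[3]])) * a2 * (1 - a2)
      d1 <- (d2 %*% t(W[[2]])) * a1 * (1 - a1)
      W[[3]] <- W[[3]] - lr * t(a2) %*% d3
      W[[2]] <- W[[2]] - lr * t(a1) %*% d2
      W[[1]] <- W[[1]] - lr * t(x) %*% d1
      b[[3]] <- b[[3]] - lr * colSums(d3)
      b[[2]] <- b[[2]] - lr * colSums(d2)
      b[[1]] <- b[[1]] - lr * colSums(d1)
    }
    structure(list(W = W, b = b, classes = classes, hidden = hidden),
              class = "retfuseANN")
  })
}

#' @export
predict.retfuseANN <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  sigm <- function(z) 1 / (1 + exp(-z))
  a1 <- sigm(sweep(x %*% object$W[[1]], 2L, object$b[[1]], "+"))
  a2 <- sigm(sweep(a1 %*% object$W[[2]], 2L, object$b[[2]], "+"))
  logits <- sweep(a2 %*% object$W[[3]], 2L, object$b[[3]], "+")
  P <- t(softmaxProb(t(logits)))
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[apply(P, 1L, which.max)]
}

#' Train the SVM classifier
#'
#' A binary support vector machine on the standardized 16-D features,
#' with either the Gaussian radial basis function kernel
#' (\code{exp(-gamma |u - v|^2)}) or the multilayer-perceptron
#' (hyperbolic tangent) kernel \code{tanh(scale <u, v> + offset)}.
#' Backed by \code{kernlab::ksvm}.
#'
#' @param x numeric matrix (n x p) of standardized features.
#' @param y labels, both classes present.
#' @param kernel \code{"rbf"} (default) or \code{"mlp"}.
#' @param C soft-margin cost (default 1).
#' @param gamma RBF width (default 1/16, i.e. 1/feature dimension).
#' @param mlpScale,mlpOffset tanh kernel parameters.
#' @return A fitted \code{kernlab::ksvm} model.
#' @export
trainSVM <- function(x, y, kernel = c("rbf", "mlp"), C = 1, gamma = 1 / 16,
                     mlpScale = 1 / 16, mlpOffset = 0) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("no training features supplied")
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("both classes must be present")
  kern <- switch(kernel,
                 rbf = kernlab::rbfdot(sigma = gamma),
                 mlp = kernlab::tanhdot(scale = mlpScale,
                                        offset = mlpOffset))
  kernlab::ksvm(x, y, type = "C-svc", kernel = kern, C = C, scaled = FALSE)
}

#' Train the Gaussian naive Bayes classifier
#'
#' Class priors are class frequencies; each feature gets a per-class
#' Gaussian likelihood (variance floored at 1e-9). Prediction applies
#' Bayes' rule \eqn{P(c_i | F_v) \propto P(F_v | c_i) P(c_i)} in log
#' space and returns the maximum a posteriori class.
#'
#' @param x numeric matrix (n x p) of features.
#' @param y labels, both classes present.
#' @return An object of class \code{"retfuseNB"}.
#' @export
trainNB <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("both classes must be present")
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  va <- do.call(rbind, lapply(classes, function(cl)
    pmax(apply(x[y == cl, , drop = FALSE], 2L, stats::var), 1e-9)))
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  structure(list(classes = classes, mean = mu, var = va, prior = prior),
            class = "retfuseNB")
}

#' @export
predict.retfuseNB <- function(object, newdata,
                              type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  lp <- vapply(seq_along(object$classes), function(ci) {
    m <- object$mean[ci, ]; v <- object$var[ci, ]
    rowSums(-0.5 * (sweep(x, 2L, m)^2) / matrix(v, nrow(x), ncol(x),
                                                byrow = TRUE) -
              0.5 * matrix(log(2 * pi * v), nrow(x), ncol(x),
                           byrow = TRUE)) + log(object$prior[ci])
  }, numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  if (type == "posterior") post
  else object$classes[apply(post, 1L, which.max)]
}

# Label with the most votes; with three binary voters a tie is impossible.
majorityVote <- function(votes) {
  tab <- table(votes)
  names(tab)[which.max(tab)]
}

#' Majority-vote ensemble prediction for one feature vector
#'
#' Each of the three classifiers votes; the final label is the one with
#' at least two votes (three binary voters cannot tie). The per-classifier
#' confidence for its voted class is recorded where available.
#'
#' @param ann a \code{"retfuseANN"}.
#' @param svm a \code{kernlab::ksvm} fit.
#' @param nb a \code{"retfuseNB"}.
#' @param fv a \linkS4class{FeatureVector} or numeric vector of length 16
#'   (already standardized, or supply \code{scaler}).
#' @param scaler optional list(center, scale) applied to the raw features.
#' @return A \linkS4class{RetinalDiagnosis}.
#' @export
predictEnsemble <- function(ann, svm, nb, fv, scaler = NULL) {
  v <- if (is(fv, "FeatureVector")) unname(features(fv)) else as.numeric(fv)
  if (length(v) != 16L) stop("feature vector must have length 16")
  if (!is.null(scaler)) v <- (v - scaler$center) / scaler$scale
  xm <- matrix(v, 1L)
  pAnn <- predict(ann, xm, type = "prob")
  vAnn <- colnames(pAnn)[which.max(pAnn)]
  vSvm <- as.character(kernlab::predict(svm, xm))
  pNb <- predict(nb, xm, type = "posterior")
  vNb <- colnames(pNb)[which.max(pNb)]
  votes <- c(ann = vAnn, svm = vSvm, nb = vNb)
  final <- majorityVote(votes)
  new("RetinalDiagnosis", votes = votes, final = final,
      posterior = c(ann = max(pAnn), nb = max(pNb)))
}

#' Train the full hybrid classifier bundle
#'
#' Standardizes the features with training statistics (z-scores), then
#' fits the ANN, the SVM and the naive Bayes model on the same matrix.
#'
#' @param x numeric matrix (n x 16) of raw fused features.
#' @param y labels.
#' @param config a \code{\link{retfuseConfig}}.
#' @param seed RNG seed (ANN initialisation).
#' @return A list of class \code{"retfuseEnsemble"} with elements ann,
#'   svm, nb and scaler.
#' @export
trainEnsemble <- function(x, y, config = retfuseConfig(), seed = 1L) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < 1e-8] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  ann <- trainANN(xs, y, hidden = config$ann$hidden,
                  epochs = config$ann$epochs, lr = config$ann$lr,
                  seed = seed)
  svm <- trainSVM(xs, y, kernel = config$svm$kernel, C = config$svm$C,
                  gamma = config$svm$gamma, mlpScale = config$svm$mlpScale,
                  mlpOffset = config$svm$mlpOffset)
  nb <- trainNB(xs, y)
  structure(list(ann = ann, svm = svm, nb = nb,
                 scaler = list(center = center, scale = scale)),
            class = "retfuseEnsemble")
}

#' @export
predict.retfuseEnsemble <- function(object, newdata, ...) {
  if (is(newdata, "FeatureVector")) newdata <- t(unname(features(newdata)))
  newdata <- as.matrix(newdata)
  apply(newdata, 1L, function(v)
    predictEnsemble(object$ann, object$svm, object$nb, v,
                    scaler = object$scaler)@final)
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), positive and
#' negative predictive values PPV = TP/(TP+FP), NPV = TN/(TN+FN), and
#' diagnostic accuracy A = (TP+TN)/(TP+TN+FP+FN). A metric whose
#' denominator is zero is reported as NA.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts; alternatively pass a
#'   single named list/vector as \code{TP}.
#' @return Named list with SE, SP, PPV, NPV, A.
#' @examples
#' classificationMetrics(TP = 2473, TN = 2338, FP = 212, FN = 77)$A
#' @export
classificationMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP) || length(TP) == 4L) {
    cc <- TP
    TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(SE = rat(TP, TP + FN), SP = rat(TN, TN + FP),
       PPV = rat(TP, TP + FP), NPV = rat(TN, TN + FN),
       A = (TP + TN) / total)
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; defined as 1 when both masks are
#' empty (agreement on absence).
#'
#' @param a,b binary matrices of one shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Stratified k-fold cross validation
#'
#' Folds are stratified by class and fully seeded. Per-fold accuracy and
#' the maximum achieved accuracy are reported.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param k number of folds (>= 2, <= n).
#' @param trainFun function(x, y) returning a model.
#' @param predictFun function(model, x) returning labels.
#' @param seed RNG seed for fold assignment.
#' @return list(accuracy = per-fold vector, max = max accuracy,
#'   folds = fold assignment).
#' @export
kfoldCV <- function(x, y, k, trainFun, predictFun, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of samples")
  folds <- integer(n)
  withSeed(seed, {
    # continuous round-robin across the class-blocked ordering keeps the
    # folds as equal as possible overall AND within each class
    ord <- unlist(lapply(unique(y), function(cl) sample(which(y == cl))))
    folds[ord] <- rep_len(seq_len(k), n)
  })
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- trainFun(x[tr, , drop = FALSE], y[tr])
    mean(predictFun(model, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  list(accuracy = acc, max = max(acc), folds = folds)
}
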