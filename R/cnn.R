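#' Numerically stable softmax
#'
#' \eqn{\sigma(x)_i = e^{x_i} / \sum_j e^{x_j}}, computed after
#' subtracting the maximum so that large inputs cannot overflow. The
#' output sums to 1 and is invariant to additive shifts of the input.
#'
#' @param x numeric vector (or matrix, applied column-wise).
#' @return Probability vector (or matrix) of the same shape.
#' @examples
#' softmaxProb(c(1, 2, 3))
#' @export
softmaxProb <- function(x) {
  if (length(x) == 0L) stop("softmax of an empty vector is undefined")
  if (!all(is.finite(x))) stop("softmax inputs must be finite")
  if (is.matrix(x)) {
    z <- exp(sweep(x, 2L, apply(x, 2L, max)))
    sweep(z, 2L, colSums(z), "/")
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

#' Feature CNN layer configuration
#'
#' The 14-layer structure-tensor-influenced feature extractor: input with
#' zero-center normalization; three 9x9 convolution blocks of 8, 16 and 32
#' filters (stride 1, 'same' padding), each followed by batch
#' normalization and ReLU; 2x2/stride-2 max pooling after the first two
#' blocks and a 50% dropout before the second pooling; and a final fully
#' connected layer emitting the eight significant features. The published
#' geometry uses 227x227x3 inputs; \code{inputSize} scales the raster
#' while preserving the layer sequence (the package trains at 48x48 by
#' default, see the methods vignette).
#'
#' @param inputSize input raster side in pixels (default 227).
#' @return A list of 14 layer descriptors.
#' @export
featureCNNConfig <- function(inputSize = 227L) {
  s <- as.integer(inputSize)
  if (s < 16L) stop("input size too small for three conv blocks")
  list(
    list(type = "input", h = s, w = s, c = 3L, zerocenter = TRUE),
    list(type = "conv", filters = 8L, k = 9L, stride = 1L, pad = "same"),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "maxpool", k = 2L, stride = 2L),
    list(type = "conv", filters = 16L, k = 9L, stride = 1L, pad = "same"),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "dropout", p = 0.5),
    list(type = "maxpool", k = 2L, stride = 2L),
    list(type = "conv", filters = 32L, k = 9L, stride = 1L, pad = "same"),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "fc", units = 8L)
  )
}

#' AlexNet-style modality recognizer geometry
#'
#' Returns the 25-layer architecture table of the classic AlexNet used for
#' transfer-learning modality recognition (input 227x227x3, five
#' convolution stages, three 4096/4096/2 fully connected layers, softmax
#' over the two modalities). The table documents the optional pretrained
#' backend; the package's default modality recognizer is the small
#' \code{\link{featureCNNConfig}} network trained from scratch.
#'
#' @return A data.frame with columns layer, function., description.
#' @export
alexnetLayerTable <- function() {
  data.frame(
    layer = 1:25,
    func = c("input", "conv", "relu", "norm", "maxpool", "conv", "relu",
             "norm", "maxpool", "conv", "relu", "conv", "relu", "conv",
             "relu", "maxpool", "fc", "relu", "dropout", "fc", "relu",
             "dropout", "fc", "softmax", "output"),
    description = c("227 x 227 x 3 images",
                    "96 11x11x3 convolutions", "ReLU",
                    "cross-channel normalization (5 channels)",
                    "3x3 max pooling", "256 5x5x48 convolutions", "ReLU",
                    "cross-channel normalization (5 channels)",
                    "3x3 max pooling", "384 3x3x256 convolutions", "ReLU",
                    "384 3x3x192 convolutions", "ReLU",
                    "256 3x3x192 convolutions", "ReLU", "3x3 max pooling",
                    "4096 fully connected", "ReLU", "50% dropout",
                    "4096 fully connected", "ReLU", "50% dropout",
                    "2 fully connected", "softmax",
                    "two classes (OCT, fundus)"),
    stringsAsFactors = FALSE)
}

# Broadcast a per-channel vector over an (H, W, C, N) array.
bcastC <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

channelReduce <- function(x, f) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  f(m)
}

#' Build a feature CNN
#'
#' Instantiates the network described by a \code{\link{featureCNNConfig}}
#' layer list with He-initialised weights, plus a detachable
#' softmax classification head used only during training; at inference
#' the head is dropped and the final fully connected activations are read
#' as the feature vector.
#'
#' @param config layer descriptor list.
#' @param nClasses classes of the training head (default 2).
#' @param classes class labels associated with head outputs.
#' @param seed RNG seed for weight initialisation.
#' @return An object of class \code{"retfuseCNN"}.
#' @examples
#' net <- buildFeatureCNN(featureCNNConfig(32), seed = 1)
#' cnnParameterCount(net, layer = 2)  # 9*9*3*8 + 8
#' @export
buildFeatureCNN <- function(config, nClasses = 2L,
                            classes = c("healthy", "me"), seed = 1L) {
  if (!length(config) || config[[1]]$type != "input")
    stop("config must start with an input layer")
  if (length(classes) != nClasses) stop("classes must match nClasses")
  withSeed(seed, {
    h <- config[[1]]$h; w <- config[[1]]$w; c <- config[[1]]$c
    params <- vector("list", length(config))
    for (i in seq_along(config)[-1]) {
      ly <- config[[i]]
      if (ly$type == "conv") {
        fanIn <- ly$k * ly$k * c
        params[[i]] <- list(
          W = array(rnorm(fanIn * ly$filters, sd = sqrt(2 / fanIn)),
                    c(ly$k, ly$k, c, ly$filters)),
          b = numeric(ly$filters))
        c <- ly$filters
      } else if (ly$type == "batchnorm") {
        params[[i]] <- list(gamma = rep(1, c), beta = numeric(c),
                            runMean = numeric(c), runVar = rep(1, c))
      } else if (ly$type == "maxpool") {
        h <- (h - ly$k) %/% ly$stride + 1L
        w <- (w - ly$k) %/% ly$stride + 1L
      } else if (ly$type == "fc") {
        fanIn <- h * w * c
        params[[i]] <- list(
          W = matrix(rnorm(fanIn * ly$units, sd = sqrt(2 / fanIn)),
                     fanIn, ly$units),
          b = numeric(ly$units))
        h <- 1L; w <- 1L; c <- ly$units
      } else if (!ly$type %in% c("relu", "dropout")) {
        stop("unknown layer type: ", ly$type)
      }
    }
    featDim <- h * w * c
    head <- list(W = matrix(rnorm(featDim * nClasses,
                                  sd = sqrt(2 / featDim)),
                            featDim, nClasses),
                 b = numeric(nClasses))
    structure(list(config = config, params = params, head = head,
                   classes = classes, inputMean = NULL, featDim = featDim,
                   trained = FALSE, log = NULL),
              class = "retfuseCNN")
  })
}

#' Parameter count of one CNN layer
#' @param model a \code{"retfuseCNN"}.
#' @param layer layer index in the config list.
#' @return Number of learnable parameters in that layer.
#' @export
cnnParameterCount <- function(model, layer) {
  p <- model$params[[layer]]
  if (is.null(p)) return(0L)
  sum(vapply(p[names(p) %in% c("W", "b", "gamma", "beta")], length,
             integer(1)))
}

# Forward pass. Returns list(out, caches) when backprop = TRUE; with
# stopBefore = i the (inference-mode) activations entering layer i are
# returned instead.
cnnForward <- function(model, x, training = FALSE, withHead = TRUE,
                       backprop = FALSE, stopBefore = NULL) {
  cfg <- model$config
  d0 <- c(cfg[[1]]$h, cfg[[1]]$w, cfg[[1]]$c)
  if (!identical(as.integer(dim(x)[1:3]), as.integer(d0)))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the network input ",
         paste(d0, collapse = "x"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (cfg[[1]]$zerocenter && !is.null(model$inputMean))
    x <- x - array(model$inputMean, dim(x))
  caches <- vector("list", length(cfg))
  for (i in seq_along(cfg)[-1]) {
    if (!is.null(stopBefore) && i == stopBefore) return(x)
    ly <- cfg[[i]]
    d <- dim(x)
    if (ly$type == "conv") {
      p <- model$params[[i]]
      k <- ly$k; pad <- (k - 1L) %/% 2L
      cols <- rf_im2col(as.vector(x), d[1], d[2], d[3], d[4], k, 1L, pad)
      Wm <- matrix(p$W, k * k * d[3], dim(p$W)[4])
      y <- cols %*% Wm
      y <- sweep(y, 2L, p$b, "+")
      dim(y) <- c(d[1], d[2], d[4], dim(p$W)[4])
      x2 <- aperm(y, c(1, 2, 4, 3))
      if (backprop) caches[[i]] <- list(cols = cols, inDim = d)
      x <- x2
    } else if (ly$type == "batchnorm") {
      p <- model$params[[i]]
      d <- dim(x)
      if (training) {
        mu <- channelReduce(x, colMeans)
        xc <- x - bcastC(mu, d)
        v <- channelReduce(xc^2, colMeans)
        invstd <- 1 / sqrt(v + 1e-5)
        xhat <- xc * bcastC(invstd, d)
        model$params[[i]]$runMean <- 0.9 * p$runMean + 0.1 * mu
        model$params[[i]]$runVar <- 0.9 * p$runVar + 0.1 * v
        if (backprop) caches[[i]] <- list(xhat = xhat, invstd = invstd)
        x <- bcastC(p$gamma, d) * xhat + bcastC(p$beta, d)
      } else {
        invstd <- 1 / sqrt(p$runVar + 1e-5)
        x <- bcastC(p$gamma * invstd, d) * (x - bcastC(p$runMean, d)) +
          bcastC(p$beta, d)
      }
    } else if (ly$type == "relu") {
      if (backprop) caches[[i]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (ly$type == "dropout") {
      if (training) {
        keep <- array(runif(length(x)) >= ly$p, dim(x)) / (1 - ly$p)
        if (backprop) caches[[i]] <- list(keep = keep)
        x <- x * keep
      }
    } else if (ly$type == "maxpool") {
      d <- dim(x)
      mp <- rf_maxpool(as.vector(x), d[1], d[2], d[3], d[4], ly$k,
                       ly$stride)
      oh <- (d[1] - ly$k) %/% ly$stride + 1L
      ow <- (d[2] - ly$k) %/% ly$stride + 1L
      x <- array(mp$out, c(oh, ow, d[3], d[4]))
      if (backprop) caches[[i]] <- list(argmax = mp$argmax,
                                        inDim = d)
    } else if (ly$type == "fc") {
      p <- model$params[[i]]
      d <- dim(x)
      n <- d[length(d)]
      xm <- matrix(x, ncol = n)            # featDim x N
      if (backprop) caches[[i]] <- list(xin = xm, inDim = d)
      x <- crossprod(p$W, xm) + p$b        # units x N
      dim(x) <- c(1L, 1L, ncol(p$W), n)
    }
  }
  feat <- matrix(x, ncol = dim(x)[length(dim(x))])  # featDim x N
  if (!withHead) return(if (backprop) list(out = feat, caches = caches)
                        else feat)
  logits <- crossprod(model$head$W, feat) + model$head$b
  if (backprop) list(out = logits, feat = feat, caches = caches,
                     model = model)
  else logits
}

#' Train a CNN by stochastic gradient descent
#'
#' Minimises the cross-entropy loss \eqn{CL = -\sum_w I_w \log P_w} with
#' momentum SGD over seeded mini-batches; dropout is active during
#' training only. The training log records per-iteration batch accuracy
#' and loss, with a validation pass every 100 iterations when a
#' validation set is supplied. Training is fully seeded: the same seed
#' reproduces the same weights and log.
#'
#' @param model a \code{"retfuseCNN"} from \code{\link{buildFeatureCNN}}.
#' @param x input array (H, W, 3, N) in the network's input size.
#' @param y factor or character labels of length N.
#' @param epochs,lr,momentum,batchSize SGD hyper-parameters.
#' @param seed RNG seed governing shuffling, dropout and initial state.
#' @param validation optional list(x =, y =) scored every 100 iterations.
#' @param verbose print progress.
#' @return The trained model; the log is in \code{model$log} (a
#'   data.frame: iteration, epoch, accuracy, loss, isValidation).
#' @export
trainCNN <- function(model, x, y, epochs = 30L, lr = 0.01, momentum = 0.9,
                     batchSize = 16L, seed = 1L, validation = NULL,
                     verbose = FALSE) {
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain at least two classes")
  if (!all(y %in% model$classes))
    stop("labels outside the model's class set")
  n <- dim(x)[4]
  if (length(y) != n) stop("labels must match the number of images")
  Y <- outer(model$classes, y, "==") * 1  # K x N indicator
  withSeed(seed, {
    if (is.null(model$inputMean) && model$config[[1]]$zerocenter)
      model$inputMean <- apply(x, 1:3, mean)
    vel <- list()
    logRows <- list()
    iter <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batchSize)) {
        idx <- ord[b0:min(b0 + batchSize - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- Y[, idx, drop = FALSE]
        fw <- cnnForward(model, xb, training = TRUE, withHead = TRUE,
                         backprop = TRUE)
        model <- fw$model  # batch-norm running stats updated in forward
        probs <- softmaxProb(fw$out)
        loss <- -mean(colSums(yb * log(pmax(probs, 1e-12))))
        acc <- mean(apply(fw$out, 2L, which.max) ==
                      apply(yb, 2L, which.max))
        grads <- cnnBackward(model, fw, (probs - yb) / ncol(yb))
        upd <- sgdUpdate(model, grads, vel, lr, momentum)
        model <- upd$model; vel <- upd$vel
        iter <- iter + 1L
        logRows[[length(logRows) + 1L]] <-
          data.frame(iteration = iter, epoch = ep, accuracy = acc,
                     loss = loss, isValidation = FALSE)
        if (!is.null(validation) && iter %% 100L == 0L) {
          vp <- predictCNN(model, validation$x, type = "prob")
          vy <- as.character(validation$y)
          vacc <- mean(model$classes[apply(vp, 2L, which.max)] == vy)
          vY <- outer(model$classes, vy, "==") * 1
          vloss <- -mean(colSums(vY * log(pmax(vp, 1e-12))))
          logRows[[length(logRows) + 1L]] <-
            data.frame(iteration = iter, epoch = ep, accuracy = vacc,
                       loss = vloss, isValidation = TRUE)
        }
      }
      if (verbose)
        message(sprintf("epoch %d: acc %.3f loss %.4f", ep, acc, loss))
    }
    model <- calibrateBatchNorm(model, x, chunk = batchSize)
    model$trained <- TRUE
    model$log <- do.call(rbind, logRows)
    model
  })
}

# Replace every batch-norm layer's running statistics with the exact
# population statistics of the training set at the final weights. SGD's
# exponentially averaged statistics lag the weights they normalized, so
# inference-mode accuracy would understate the fit without this pass.
# Layers are calibrated top-down (each pass uses the already-calibrated
# layers above it) and in chunks to bound memory.
calibrateBatchNorm <- function(model, x, chunk = 16L) {
  cfg <- model$config
  bnIdx <- which(vapply(cfg, function(l) l$type == "batchnorm",
                        logical(1)))
  n <- dim(x)[4]
  for (bi in bnIdx) {
    s1 <- s2 <- NULL
    cnt <- 0
    for (b0 in seq(1L, n, by = chunk)) {
      idx <- b0:min(b0 + chunk - 1L, n)
      a <- cnnForward(model, x[, , , idx, drop = FALSE],
                      training = FALSE, stopBefore = bi)
      d <- dim(a)
      m <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])
      s1 <- if (is.null(s1)) colSums(m) else s1 + colSums(m)
      s2 <- if (is.null(s2)) colSums(m^2) else s2 + colSums(m^2)
      cnt <- cnt + nrow(m)
    }
    mu <- s1 / cnt
    model$params[[bi]]$runMean <- mu
    model$params[[bi]]$runVar <- pmax(s2 / cnt - mu^2, 0)
  }
  model
}

# Backward pass given forward caches and head-logit gradient (K x N).
cnnBackward <- function(model, fw, dLogits) {
  cfg <- model$config
  grads <- vector("list", length(cfg))
  feat <- fw$feat
  gHead <- list(W = feat %*% t(dLogits), b = rowSums(dLogits))
  dx <- model$head$W %*% dLogits   # featDim x N
  for (i in rev(seq_along(cfg)[-1])) {
    ly <- cfg[[i]]
    ca <- fw$caches[[i]]
    if (ly$type == "fc") {
      p <- model$params[[i]]
      grads[[i]] <- list(W = ca$xin %*% t(dx), b = rowSums(dx))
      dx <- p$W %*% dx
      dim(dx) <- ca$inDim
    } else if (ly$type == "conv") {
      p <- model$params[[i]]
      d <- ca$inDim
      k <- ly$k; pad <- (k - 1L) %/% 2L
      f <- dim(p$W)[4]
      dYm <- matrix(aperm(dx, c(1, 2, 4, 3)), ncol = f)
      grads[[i]] <- list(
        W = array(crossprod(ca$cols, dYm), dim(p$W)),
        b = colSums(dYm))
      Wm <- matrix(p$W, k * k * d[3], f)
      dCols <- tcrossprod(dYm, Wm)
      dx <- array(rf_col2im(dCols, d[1], d[2], d[3], d[4], k, 1L, pad), d)
    } else if (ly$type == "batchnorm") {
      p <- model$params[[i]]
      d <- dim(dx)
      m <- d[1] * d[2] * d[4]
      dgamma <- channelReduce(dx * ca$xhat, colSums)
      dbeta <- channelReduce(dx, colSums)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dx <- bcastC(p$gamma * ca$invstd / m, d) *
        (m * dx - bcastC(dbeta, d) - ca$xhat * bcastC(dgamma, d))
    } else if (ly$type == "relu") {
      dx <- dx * ca$mask
    } else if (ly$type == "dropout") {
      if (!is.null(ca)) dx <- dx * ca$keep
    } else if (ly$type == "maxpool") {
      d <- ca$inDim
      dx <- array(rf_maxpool_bwd(as.vector(dx), ca$argmax,
                                 prod(d)), d)
    }
  }
  list(layers = grads, head = gHead)
}

sgdUpdate <- function(model, grads, vel, lr, momentum) {
  step <- function(p, g, v) {
    if (is.null(v)) v <- lapply(g, function(z) z * 0)
    for (nm in names(g)) {
      v[[nm]] <- momentum * v[[nm]] - lr * g[[nm]]
      p[[nm]] <- p[[nm]] + v[[nm]]
    }
    list(p = p, v = v)
  }
  if (is.null(vel$layers))
    vel$layers <- vector("list", length(grads$layers))
  for (i in seq_along(grads$layers)) {
    g <- grads$layers[[i]]
    if (is.null(g)) next
    s <- step(model$params[[i]], g, vel$layers[[i]])
    model$params[[i]][names(g)] <- s$p[names(g)]
    vel$layers[[i]] <- s$v
  }
  s <- step(model$head, grads$head, vel$head)
  model$head <- s$p; vel$head <- s$v
  list(model = model, vel = vel)
}

#' Predict with a trained CNN
#'
#' @param model a trained \code{"retfuseCNN"}.
#' @param x input array (H, W, 3, N) or (H, W, 3).
#' @param type \code{"class"}, \code{"prob"} (softmax columns) or
#'   \code{"features"} (the 8-D fully connected activations, head
#'   detached).
#' @return Predictions as requested; features are a featDim x N matrix.
#' @export
predictCNN <- function(model, x, type = c("class", "prob", "features")) {
  type <- match.arg(type)
  if (type == "features")
    return(cnnForward(model, x, training = FALSE, withHead = FALSE))
  logits <- cnnForward(model, x, training = FALSE, withHead = TRUE)
  probs <- softmaxProb(logits)
  if (type == "prob") probs
  else model$classes[apply(probs, 2L, which.max)]
}

#' @export
print.retfuseCNN <- function(x, ...) {
  cat("retfuseCNN:", length(x$config), "layers, input",
      paste(c(x$config[[1]]$h, x$config[[1]]$w, x$config[[1]]$c),
            collapse = "x"),
      "->", x$featDim, "features;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Resize scans into a CNN input batch
#'
#' Bilinear resize to the network raster; grayscale scans are replicated
#' to three channels.
#'
#' @param scans a \linkS4class{RetinalScan}, a pixel array, or a list of
#'   either.
#' @param size target side length in pixels.
#' @return Array (size, size, 3, N).
#' @export
prepareCNNInput <- function(scans, size) {
  if (!is.list(scans)) scans <- list(scans)
  n <- length(scans)
  out <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    p <- scans[[i]]
    if (is(p, "RetinalScan")) p <- p@pixels
    img <- if (length(dim(p)) == 3L)
      EBImage::Image(aperm(p, c(2, 1, 3)), colormode = "Color")
    else EBImage::Image(t(p))
    rz <- EBImage::resize(img, w = size, h = size)
    rd <- EBImage::imageData(rz)
    if (length(dim(rd)) == 3L) out[, , , i] <- aperm(rd, c(2, 1, 3))
    else out[, , , i] <- array(rep(t(rd), 3L), c(size, size, 3L))
  }
  clamp01(out)
}

#' Recognize the imaging modality of a scan
#'
#' The scan is resized to the recognizer's input raster (grayscale
#' replicated to three channels) and classified; the winning class and
#' its softmax probability are returned.
#'
#' @param model a trained modality \code{"retfuseCNN"} whose classes are
#'   \code{c("oct", "fundus")}.
#' @param scan a \linkS4class{RetinalScan}.
#' @return list(modality, probability, probabilities).
#' @export
recognizeModality <- function(model, scan) {
  if (!inherits(model, "retfuseCNN") || !model$trained)
    stop("a trained modality CNN is required")
  x <- prepareCNNInput(scan, model$config[[1]]$h)
  pr <- predictCNN(model, x, type = "prob")[, 1]
  best <- which.max(pr)
  list(modality = model$classes[best], probability = unname(pr[best]),
       probabilities = stats::setNames(pr, model$classes))
}
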