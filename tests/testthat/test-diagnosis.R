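separable16 <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 16), n, 16)
    y <- rep(c("healthy", "me"), length.out = n)
    x[y == "me", 1:4] <- x[y == "me", 1:4] + 4
    list(x = x, y = y)
  })
}

test_that("the ANN has the 16-12-9-2 architecture and fits separable data", {
  d <- separable16()
  ann <- trainANN(d$x, d$y, seed = 1)
  expect_equal(dim(ann$W[[1]]), c(16L, 12L))
  expect_equal(dim(ann$W[[2]]), c(12L, 9L))
  expect_equal(dim(ann$W[[3]]), c(9L, 2L))
  expect_equal(mean(predict(ann, d$x) == d$y), 1)
  # seeded determinism
  ann2 <- trainANN(d$x, d$y, seed = 1)
  expect_identical(ann$W, ann2$W)
  expect_error(trainANN(d$x, rep("me", nrow(d$x))), "both classes")
})

test_that("the RBF SVM solves non-linear problems a linear machine cannot", {
  # XOR pattern
  withr::local_seed(2)
  base <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  x <- base[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.05), 40, 2)
  y <- rep(c("healthy", "healthy", "me", "me"), each = 10)
  svm <- trainSVM(x, y, kernel = "rbf", gamma = 2)
  expect_equal(mean(as.character(kernlab::predict(svm, x)) == y), 1)

  # concentric classes: rbf beats a linear reference hyperplane
  r <- c(runif(30, 0, 0.8), runif(30, 1.6, 2.4))
  th <- runif(60, 0, 2 * pi)
  xc <- cbind(r * cos(th), r * sin(th))
  yc <- rep(c("healthy", "me"), each = 30)
  rbf <- trainSVM(xc, yc, kernel = "rbf", gamma = 1)
  lin <- kernlab::ksvm(xc, factor(yc), type = "C-svc",
                       kernel = kernlab::vanilladot(), C = 1,
                       scaled = FALSE)
  accR <- mean(as.character(kernlab::predict(rbf, xc)) == yc)
  accL <- mean(as.character(kernlab::predict(lin, xc)) == yc)
  expect_gte(accR, accL)
  expect_gte(accR, 0.95)

  # the MLP (tanh) kernel is available as the alternative hyperplane
  d <- separable16()
  mlp <- trainSVM(d$x, d$y, kernel = "mlp")
  expect_gte(mean(as.character(kernlab::predict(mlp, d$x)) == d$y), 0.9)

  expect_error(trainSVM(matrix(numeric(0), 0, 2), character(0)), "no training")
  expect_error(trainSVM(d$x, d$y, kernel = "poly"), "arg")
})

test_that("naive Bayes reproduces the closed-form Gaussian boundary", {
  # equal priors, N(0,1) vs N(4,1): the boundary is exactly at 2
  x0 <- (-4:4) / sqrt(7.5)               # mean 0, variance 1 exactly
  x1 <- 4 + c(-1, 1) / sqrt(2)           # mean 4, variance 1 exactly
  xall <- matrix(c(x0, x0 + 4), ncol = 1)
  yall <- rep(c("healthy", "me"), each = 9)
  nb <- trainNB(xall, yall)
  expect_equal(predict(nb, matrix(1.9)), "healthy")
  expect_equal(predict(nb, matrix(2.1)), "me")

  # unequal priors shift the boundary by log(p0/p1)/4 (closed form)
  nb2 <- trainNB(matrix(c(x0, x1), ncol = 1),
                 c(rep("healthy", 9), rep("me", 2)))
  shift <- log((9 / 11) / (2 / 11)) / 4
  expect_equal(predict(nb2, matrix(2 + shift - 0.02)), "healthy")
  expect_equal(predict(nb2, matrix(2 + shift + 0.02)), "me")

  expect_error(trainNB(xall, rep("me", 18)), "both classes")
})

test_that("naive Bayes posteriors match direct Bayes-rule evaluation", {
  withr::local_seed(5)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c("healthy", "me"), each = 20)
  nb <- trainNB(x, y)
  for (i in c(1, 7, 25, 40)) {
    got <- predict(nb, x[i, , drop = FALSE], type = "posterior")
    want <- oracleBayesPosterior(x[i, ], nb$mean, nb$var, nb$prior)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("the ensemble decision equals the majority on all 8 vote patterns", {
  pats <- expand.grid(ann = c("healthy", "me"), svm = c("healthy", "me"),
                      nb = c("healthy", "me"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    v <- unlist(pats[i, ])
    want <- if (sum(v == "me") >= 2) "me" else "healthy"
    expect_equal(retfuse:::majorityVote(v), want)
    # the RetinalDiagnosis class itself enforces the same rule
    dg <- new("RetinalDiagnosis", votes = v, final = want,
              posterior = numeric(0))
    expect_equal(dg@final, retfuse:::majorityVote(dg@votes))
    expect_error(new("RetinalDiagnosis", votes = v,
                     final = setdiff(c("healthy", "me"), want),
                     posterior = numeric(0)), "majority")
  }
})

test_that("predictEnsemble returns consistent votes on real models", {
  d <- separable16(60, seed = 3)
  ens <- trainEnsemble(d$x, d$y, seed = 1)
  dg <- predictEnsemble(ens$ann, ens$svm, ens$nb, d$x[1, ],
                        scaler = ens$scaler)
  expect_s4_class(dg, "RetinalDiagnosis")
  expect_equal(dg@final, retfuse:::majorityVote(dg@votes))
  # the bundle's predict method classifies separable data perfectly
  expect_equal(mean(predict(ens, d$x) == d$y), 1)
  expect_error(predictEnsemble(ens$ann, ens$svm, ens$nb, 1:5), "length 16")
})

test_that("classification metrics implement the confusion-count formulas", {
  m <- classificationMetrics(TP = 2473, TN = 2338, FP = 212, FN = 77)
  expect_equal(m$SE, 2473 / 2550)
  expect_equal(m$A, 4811 / 5100)
  # A is the SE/SP mixture weighted by class prevalence
  expect_equal(m$A, m$SE * 2550 / 5100 + m$SP * 2550 / 5100)
  # SE * (TP + FN) recovers TP exactly
  expect_equal(m$SE * 2550, 2473)

  sym <- classificationMetrics(TP = 1, TN = 1, FP = 1, FN = 1)
  expect_true(all(unlist(sym) == 0.5))

  # undefined denominators give NA, not errors
  nodeg <- classificationMetrics(TP = 0, TN = 5, FP = 0, FN = 0)
  expect_true(is.na(nodeg$SE))
  expect_true(is.na(nodeg$PPV))
  expect_equal(nodeg$A, 1)
  expect_error(classificationMetrics(0, 0, 0, 0), "zero")
  expect_error(classificationMetrics(-1, 2, 0, 0), "nonnegative")
})

test_that("dice handles identity, disjoint, partial and empty masks", {
  a <- matrix(0, 5, 5); a[1:2, 1] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 5, 5); b[4:5, 5] <- 1
  expect_equal(dice(a, b), 0)
  cc <- matrix(0, 5, 5); cc[2:3, 1] <- 1       # |a|=2, |b|=2, overlap 1
  expect_equal(dice(a, cc), 0.5)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice(a, matrix(0, 4, 4)), "shape")
})

test_that("stratified k-fold cross validation is balanced and seeded", {
  d <- separable16(10, seed = 6)
  trainFun <- function(x, y) trainNB(x, y)
  predictFun <- function(m, x) predict(m, x)
  cv <- kfoldCV(d$x, d$y, k = 2, trainFun, predictFun, seed = 1)
  expect_equal(as.vector(table(cv$folds)), c(5L, 5L))
  # 5 + 5 samples: each fold holds 2-3 of each class
  for (f in 1:2) {
    counts <- table(d$y[cv$folds == f])
    expect_length(counts, 2L)
    expect_true(all(counts >= 2))
  }
  # separable features: every fold reaches perfect accuracy
  d2 <- separable16(40, seed = 2)
  for (k in c(2, 4)) {
    cvk <- kfoldCV(d2$x, d2$y, k, trainFun, predictFun, seed = 3)
    expect_equal(cvk$max, 1)
  }
  cv2 <- kfoldCV(d$x, d$y, 2, trainFun, predictFun, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfoldCV(d$x, d$y, 11, trainFun, predictFun), "exceed")
})
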