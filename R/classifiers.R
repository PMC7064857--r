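# Classifier backends for the benchmarking harness. Each backend is a
# thin wrapper around an established implementation: k-nearest neighbours
# (class::knn), Gaussian naive Bayes (e1071), logistic regression
# (stats::glm), extremely randomized trees (ranger with the extratrees
# split rule), and gradient-boosted shallow trees (xgboost) as the boosted
# ensemble. Every backend returns hard 0/1 predictions plus a continuous
# positive-class score for the ROC curve.

classifier_codes <- c("knn", "gnb", "lr", "et", "ab")

classifier_labels <- c(
  knn = "k-nearest neighbours",
  gnb = "Gaussian naive Bayes",
  lr = "logistic regression",
  et = "extremely randomized trees",
  ab = "boosted trees"
)

fit_predict <- function(code, x_train, y_train, x_test, seed) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  switch(code,
    knn = {
      pred <- class::knn(x_train, x_test, cl = factor(y_train), k = 5L,
                         prob = TRUE)
      p_win <- attr(pred, "prob")
      cls <- as.integer(as.character(pred))
      list(class = cls, score = ifelse(cls == 1L, p_win, 1 - p_win))
    },
    gnb = {
      fit <- e1071::naiveBayes(x = as.data.frame(x_train),
                               y = factor(y_train, levels = c(0, 1)))
      pr <- stats::predict(fit, as.data.frame(x_test), type = "raw")[, "1"]
      list(class = as.integer(pr >= 0.5), score = pr)
    },
    lr = {
      df_train <- as.data.frame(x_train)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = y_train, df_train),
                   family = stats::binomial())
      )
      pr <- suppressWarnings(
        as.numeric(stats::predict(fit, as.data.frame(x_test), type = "response"))
      )
      list(class = as.integer(pr >= 0.5), score = pr)
    },
    et = {
      df_train <- as.data.frame(x_train)
      df_train$.y <- factor(y_train, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df_train,
        num.trees = 200L, splitrule = "extratrees", num.random.splits = 1L,
        replace = FALSE, sample.fraction = 1, probability = TRUE,
        seed = seed, num.threads = 1L
      )
      pr <- stats::predict(fit, as.data.frame(x_test),
                           num.threads = 1L)$predictions[, "1"]
      list(class = as.integer(pr >= 0.5), score = pr)
    },
    ab = {
      dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 2L,
                      eta = 0.3, nthread = 1L),
        data = dtrain, nrounds = 100L, verbose = 0
      )
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(x_test))
      list(class = as.integer(pr >= 0.5), score = pr)
    },
    stop("unknown classifier code: ", code, call. = FALSE)
  )
}
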