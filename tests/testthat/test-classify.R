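test_that("two-component PCA matches a brute-force eigendecomposition", {
  set.seed(51)
  X <- matrix(rnorm(50), 10, 5)
  res <- pca_first2(X)
  C <- cov(X)
  ei <- eigen(C, symmetric = TRUE)
  for (j in 1:2) {
    v <- ei$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])      # same sign convention
    expect_lt(max(abs(res$loadings[, j] - v)), 1e-10)
    sc <- scale(X, center = TRUE, scale = FALSE) %*% v
    expect_lt(max(abs(res$scores[, j] - sc)), 1e-10)
  }
  expect_gte(res$explained[1], res$explained[2])
  expect_equal(res$explained[1:2], ei$values[1:2] / sum(ei$values))
})

test_that("data confined to a plane is reconstructed exactly from 2 scores", {
  set.seed(52)
  basis <- qr.Q(qr(matrix(rnorm(15), 5, 3)))[, 1:2]
  X <- matrix(rnorm(40), 20, 2) %*% t(basis) + 1
  res <- pca_first2(X)
  recon <- res$scores %*% t(res$loadings)
  centered <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-10)
  expect_error(pca_first2(X[, 1, drop = FALSE] %*% t(c(1, 1, 1))),
               "non-degenerate")
})

test_that("QDA separates distant classes and normalizes posteriors", {
  set.seed(53)
  n <- 40
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 8), n, 2),
             matrix(rnorm(2 * n, mean = -8), n, 2))
  lab <- factor(rep(c("CN", "aMCI", "AD"), each = n),
                levels = c("CN", "aMCI", "AD"))
  mod <- qda_fit(X, lab)
  pr <- qda_predict(mod, X)
  expect_identical(as.character(pr$labels), as.character(lab))
  expect_true(all(abs(rowSums(pr$posterior) - 1) < 1e-12))
})

test_that("our QDA posteriors agree with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(54)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 1.5, 1.3), 30, 2),
             matrix(rnorm(40, -1, 0.7), 20, 2))
  lab <- factor(rep(c("a", "b", "c"), c(30, 30, 20)))
  ours <- qda_predict(qda_fit(X, lab), X)
  ref <- MASS::qda(X, lab)
  refp <- predict(ref, X)
  expect_gt(mean(as.character(ours$labels) ==
                   as.character(refp$class)), 0.99)
  expect_lt(max(abs(ours$posterior - refp$posterior)), 1e-6)
})

test_that("with equal class covariances QDA reduces to LDA", {
  skip_if_not_installed("MASS")
  set.seed(55)
  X <- rbind(matrix(rnorm(80), 40, 2) + 1.2,
             matrix(rnorm(80), 40, 2) - 1.2,
             cbind(rnorm(40, 3), rnorm(40, -3)))
  lab <- factor(rep(c("a", "b", "c"), each = 40))
  mod <- qda_fit(X, lab)
  pooled <- Reduce(`+`, lapply(levels(lab), function(cl)
    cov(X[lab == cl, ]) * (sum(lab == cl) - 1))) / (nrow(X) - 3)
  for (cl in names(mod$models)) {
    mod$models[[cl]]$cov <- pooled
    mod$models[[cl]]$inv <- solve(pooled)
    mod$models[[cl]]$logdet <- log(det(pooled))
  }
  grid <- as.matrix(expand.grid(seq(-5, 5, 0.25), seq(-5, 5, 0.25)))
  colnames(grid) <- NULL
  ld <- MASS::lda(X, lab)
  agree <- mean(as.character(qda_predict(mod, grid)$labels) ==
                  as.character(predict(ld, grid)$class))
  expect_gte(agree, 0.99)
})

test_that("singular class covariance raises a regularization hint", {
  X <- rbind(matrix(1, 5, 2),                        # zero variance class
             matrix(rnorm(20), 10, 2))
  lab <- factor(rep(c("flat", "ok"), c(5, 10)))
  expect_error(qda_fit(X, lab), "regularize")
  expect_silent(qda_fit(X, lab, regularize = 1e-3))
})

test_that("stratified 10-fold CV on 41 subjects: fold sizes, coverage,
           self-consistent error", {
  set.seed(56)
  lab <- factor(rep(c("CN", "aMCI", "AD"), c(15, 15, 11)),
                levels = c("CN", "aMCI", "AD"))
  X <- matrix(rnorm(41 * 6), 41, 6) +
    outer(as.integer(lab), 1:6, function(a, b) a * 0.8)
  cv <- crossval_10fold(X, lab, seed = 9)
  expect_identical(sort(unique(as.integer(table(cv$fold)))), c(4L, 5L))
  expect_identical(length(cv$predictions), 41L)
  expect_false(anyNA(cv$predictions))
  cm <- cv$confusion
  expect_identical(as.integer(colSums(cm)), c(15L, 15L, 11L))
  expect_equal(cv$cv_error, (sum(cm) - sum(diag(cm))) / 41)
  expect_equal(cv$standard_error,
               sqrt(cv$cv_error * (1 - cv$cv_error) / 41))
  # same seed, same folds; different seed, (almost surely) different folds
  cv2 <- crossval_10fold(X, lab, seed = 9)
  expect_identical(cv$fold, cv2$fold)
  cv3 <- crossval_10fold(X, lab, seed = 10)
  expect_false(identical(cv$fold, cv3$fold))
})

test_that("perfectly separated classes give zero cross-validated error", {
  set.seed(57)
  lab <- factor(rep(c("CN", "aMCI", "AD"), c(15, 15, 11)),
                levels = c("CN", "aMCI", "AD"))
  X <- matrix(rnorm(41 * 5, sd = 0.1), 41, 5) +
    outer(as.integer(lab), rep(1, 5)) * 10
  cv <- crossval_10fold(X, lab, seed = 3)
  expect_equal(cv$cv_error, 0)
})

test_that("confusion metrics match brute-force counting and handle NAs", {
  set.seed(58)
  truth <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
  pred <- factor(sample(c("a", "b", "c"), 60, replace = TRUE),
                 levels = levels(truth))
  cm <- confusion_matrix(pred, truth)
  met <- confusion_metrics(cm)
  for (g in levels(truth)) {
    tp <- sum(pred == g & truth == g)
    fp <- sum(pred == g & truth != g)
    fn <- sum(pred != g & truth == g)
    tn <- sum(pred != g & truth != g)
    row <- met$per_class[met$per_class$class == g, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
    expect_equal(row$ppv, tp / (tp + fp))
    expect_equal(row$npv, tn / (tn + fn))
  }
  expect_equal(met$accuracy, mean(pred == truth))
  # permuting subjects never changes the metrics
  o <- sample(60)
  met2 <- confusion_metrics(confusion_matrix(pred[o], truth[o]))
  expect_identical(met, met2)
  # identity-like matrix: every metric 1
  ident <- diag(c(5, 7, 9))
  mi <- confusion_metrics(ident)
  expect_true(all(unlist(mi$per_class[, -1]) == 1))
  # empty prediction row: PPV undefined, not zero
  cm0 <- matrix(c(0, 5, 0, 0, 7, 0, 0, 3, 4), 3, 3)
  m0 <- confusion_metrics(cm0)
  expect_true(is.na(m0$per_class$ppv[1]))
})

test_that("a strongly shifted synthetic cohort classifies well above
           chance", {
  hits <- 0L
  nrep <- 30L
  for (r in seq_len(nrep)) {
    sim <- simulate_cohort(cohort_design(seed = 6000 + r), spectra = FALSE)
    co <- sim$cohort
    mk <- paste0("^(", paste(pbem31p:::marker_names(), collapse = "|"),
                 ")_")
    feats <- as.matrix(co[, c(grep(mk, names(co), value = TRUE),
                              grep("^z_", names(co), value = TRUE))])
    cv <- crossval_10fold(feats, co$group, seed = r)
    if (1 - cv$cv_error >= 1 / 3 + 0.3) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})
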