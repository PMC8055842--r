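#' First two principal components
#'
#' Top-2 eigenpairs of the sample covariance of the (column-centered) feature
#' table, with a fixed sign convention: within each component the loading of
#' largest magnitude is made positive.
#'
#' @param features numeric matrix or data.frame (>= 3 rows and columns).
#' @return list with \code{scores} (n x 2), \code{loadings} (p x 2),
#'   \code{explained} (variance fractions of the two components),
#'   \code{center} (column means).
#' @export
pca_first2 <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 3L || ncol(X) < 3L)
    stop("pca_first2 needs at least 3 rows and 3 columns")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2L] < 1e-12 * pc$sdev[1L])
    stop("fewer than 2 non-degenerate dimensions")
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2L, flip, `*`)
  colnames(scores) <- colnames(rot) <- c("PC1", "PC2")
  list(scores = scores, loadings = rot,
       explained = pc$sdev[1:2]^2 / sum(pc$sdev^2),
       center = pc$center)
}

#' Fit a quadratic discriminant model
#'
#' Gaussian class-conditional model with class-specific covariance matrices
#' and empirical class priors.
#'
#' @param scores numeric matrix of features (typically n x 2 PCA scores).
#' @param labels factor of class labels; every class needs n >= 3.
#' @param regularize ridge added to each class covariance (default 0); set a
#'   small positive value if a class covariance is singular.
#' @return object of class \code{qda_model}.
#' @export
qda_fit <- function(scores, labels, regularize = 0) {
  X <- as.matrix(scores)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) < 3L))
    stop("qda_fit: every class needs at least 3 observations")
  classes <- levels(labels)
  mods <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    S <- stats::cov(Xi) + diag(regularize, ncol(X))
    dt <- det(S)
    if (!is.finite(dt) || dt <= 1e-300)
      stop(sprintf(
        "qda_fit: singular covariance for class %s; consider regularize > 0",
        cl))
    list(mean = colMeans(Xi), cov = S, inv = solve(S), logdet = log(dt),
         prior = mean(labels == cl))
  })
  names(mods) <- classes
  structure(list(classes = classes, models = mods, p = ncol(X)),
            class = "qda_model")
}

#' Predict classes and posteriors from a quadratic discriminant model
#'
#' Maximum-posterior rule; exact posterior ties are broken in favor of the
#' earlier class in the model's class order (CN before aMCI before AD when
#' fit on cohort labels).
#'
#' @param model a \code{qda_model}.
#' @param scores feature matrix with the same columns used in fitting.
#' @return list with \code{labels} (factor) and \code{posterior} (n x k
#'   matrix, rows summing to 1).
#' @export
qda_predict <- function(model, scores) {
  X <- as.matrix(scores)
  stopifnot(inherits(model, "qda_model"), ncol(X) == model$p)
  logd <- vapply(model$classes, function(cl) {
    m <- model$models[[cl]]
    d <- sweep(X, 2L, m$mean)
    -0.5 * rowSums((d %*% m$inv) * d) - 0.5 * m$logdet + log(m$prior)
  }, numeric(nrow(X)))
  logd <- matrix(logd, nrow = nrow(X),
                 dimnames = list(NULL, model$classes))
  post <- exp(logd - apply(logd, 1L, max))
  post <- post / rowSums(post)
  idx <- apply(post, 1L, which.max)   # which.max takes the first maximum
  list(labels = factor(model$classes[idx], levels = model$classes),
       posterior = post)
}

#' Stratified k-fold cross-validated PCA + QDA classification
#'
#' Partitions participants into stratified folds (each class spread evenly,
#' fold sizes differing by at most one), and for each fold standardizes the
#' features, fits the two-component PCA and the quadratic discriminant on the
#' training split only, then predicts the held-out split. Returns one
#' held-out prediction per subject.
#'
#' @param features numeric feature table (rows = subjects).
#' @param labels class labels (factor; order of levels fixes the class
#'   order).
#' @param seed integer seed for the fold assignment (required, logged in the
#'   output).
#' @param folds number of folds (default 10).
#' @return list with \code{predictions} (factor), \code{fold} (per-subject
#'   fold id), \code{confusion} (\code{\link{confusion_matrix}}),
#'   \code{cv_error}, \code{standard_error}, \code{seed}.
#' @export
crossval_10fold <- function(features, labels, seed, folds = 10L) {
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  if (n < folds) stop("need at least as many subjects as folds")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      # cyclic assignment with a rotating offset keeps fold sizes within 1
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- (offset + length(idx)) %% folds
    }
  })
  preds <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (nlevels(droplevels(labels[tr])) < nlevels(labels))
      stop(sprintf("class absent from the training split of fold %d", f))
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    pca <- pca_first2(Ztr)
    str <- pca$scores
    ste <- sweep(Zte, 2L, pca$center) %*% pca$loadings
    mod <- qda_fit(str, labels[tr])
    preds[!tr] <- qda_predict(mod, ste)$labels
  }
  cm <- confusion_matrix(preds, labels)
  err <- 1 - sum(diag(cm)) / n
  list(predictions = preds, fold = fold, confusion = cm,
       cv_error = err, standard_error = sqrt(err * (1 - err) / n),
       seed = seed, folds = folds)
}

#' Build a confusion matrix (rows = predicted, columns = true)
#'
#' @param predicted,true factors over the same class set.
#' @return k x k integer matrix of class \code{confusion_matrix}, rows
#'   predicted, columns true, in the class order of \code{true}.
#' @export
confusion_matrix <- function(predicted, true) {
  true <- as.factor(true)
  predicted <- factor(predicted, levels = levels(true))
  cm <- table(predicted = predicted, true = true)
  structure(unclass(cm), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Per-class sensitivity, specificity, positive and negative predictive
#' value, plus overall accuracy, misclassification count, cross-validation
#' error (1 - accuracy) and its binomial standard error. A metric with an
#' empty denominator (zero row or column sum) is reported as NA, not 0.
#'
#' @param cm square counts matrix, rows = predicted, columns = true.
#' @return list with \code{per_class} (data.frame) and scalars
#'   \code{accuracy}, \code{misclassified}, \code{cv_error},
#'   \code{standard_error}, \code{n}.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  classes <- colnames(cm) %||% paste0("class", seq_len(ncol(cm)))
  per <- do.call(rbind, lapply(seq_len(ncol(cm)), function(g) {
    tp <- cm[g, g]
    colsum <- sum(cm[, g])   # truly in class g
    rowsum <- sum(cm[g, ])   # predicted as class g
    fn <- colsum - tp
    fp <- rowsum - tp
    tn <- total - colsum - fp
    dv <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(class = classes[g],
               sensitivity = dv(tp, colsum),
               specificity = dv(tn, total - colsum),
               ppv = dv(tp, rowsum),
               npv = dv(tn, tn + fn),
               stringsAsFactors = FALSE)
  }))
  acc <- sum(diag(cm)) / total
  err <- 1 - acc
  list(per_class = per, accuracy = acc,
       misclassified = total - sum(diag(cm)),
       cv_error = err,
       standard_error = sqrt(err * (1 - err) / total),
       n = total)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = true)\n")
  print(unclass(x))
  invisible(x)
}
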