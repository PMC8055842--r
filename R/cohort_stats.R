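#' Adjust values for age, education and gender
#'
#' Ordinary least-squares adjustment: the covariate contribution is removed
#' and the grand mean added back. With \code{groups = NULL} (the default) the
#' values are regressed on the three covariates alone and the residuals
#' returned, so the adjusted values are exactly uncorrelated with each
#' covariate. When the group factor is supplied, the covariate coefficients
#' are instead estimated from the within-group variation (the covariance-
#' analysis convention): this matters when a covariate is confounded with
#' group membership — an older patient group, say — where the plain
#' residualization would absorb part of the group effect itself.
#'
#' @param values numeric vector, one per participant.
#' @param age,education numeric covariates.
#' @param gender binary indicator.
#' @param groups optional group factor; when given, covariate slopes come
#'   from the within-group regression.
#' @return adjusted values (same length).
#' @export
adjust_covariates <- function(values, age, education, gender,
                              groups = NULL) {
  n <- length(values)
  stopifnot(length(age) == n, length(education) == n, length(gender) == n)
  if (n < 5L) stop("adjustment needs at least 5 participants")
  C <- cbind(age = age, education = education, gender = gender)
  G <- if (is.null(groups)) matrix(1, n, 1L) else
    stats::model.matrix(~ as.factor(groups))
  X <- cbind(G, C)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    nm <- c(rep("group", ncol(G)), colnames(C))
    bad <- unique(nm[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]])
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qr_x, values)
  bc <- beta[(ncol(G) + 1L):ncol(X)]
  values - drop(scale(C, center = TRUE, scale = FALSE) %*% bc)
}

#' Shifted-log symmetrizing transform
#'
#' Symmetrizes a skewed sample: positive skew is transformed as
#' \code{log(x - a)} with \code{a < min(x)}; negative skew as
#' \code{-log(a - x)} with \code{a > max(x)}. The shift constant is chosen by
#' a one-dimensional search minimizing the absolute adjusted Fisher--Pearson
#' skewness of the transformed sample, subject to the domain constraint; if
#' the search cannot reduce the skewness the fallback
#' \code{a = min(x) - 0.1 range} (resp. \code{max(x) + 0.1 range}) is used.
#'
#' @param values numeric sample (n >= 3, non-constant).
#' @return list with \code{values} (transformed sample) and \code{spec}
#'   (one-row data.frame: direction, shift constant a, skewness before and
#'   after).
#' @export
shifted_log <- function(values) {
  if (length(values) < 3L) stop("shifted_log needs n >= 3")
  if (stats::sd(values) == 0) stop("shifted_log: constant input")
  sk0 <- sample_skewness(values)
  rng <- diff(range(values))
  positive <- sk0 >= 0
  trans <- function(a) if (positive) log(values - a) else -log(a - values)
  # parameterize the offset from the boundary on a log grid
  obj <- function(loff) abs(sample_skewness(trans(
    if (positive) min(values) - exp(loff) else max(values) + exp(loff))))
  o <- stats::optimize(obj, interval = log(rng) + c(-12, 4), tol = 1e-8)
  a <- if (positive) min(values) - exp(o$minimum) else
    max(values) + exp(o$minimum)
  out <- trans(a)
  if (!is.finite(o$objective) || o$objective > abs(sk0)) {
    a <- if (positive) min(values) - 0.1 * rng else max(values) + 0.1 * rng
    out <- trans(a)
  }
  list(values = out,
       spec = data.frame(direction = if (positive) "positive_skew" else
                           "negative_skew",
                         a = a, skew_before = sk0,
                         skew_after = sample_skewness(out),
                         stringsAsFactors = FALSE))
}

#' Scale columns to common (unit) variance
#'
#' @param table data.frame or matrix of non-constant numeric columns.
#' @return the table with every column divided by its sample SD (means are
#'   not shifted), so all column variances are 1.
#' @export
scale_common_variance <- function(table) {
  tab <- as.data.frame(table)
  for (j in seq_along(tab)) {
    s <- stats::sd(tab[[j]])
    if (!is.finite(s) || s == 0)
      stop(sprintf("scale_common_variance: constant column %s",
                   names(tab)[j]))
    tab[[j]] <- tab[[j]] / s
  }
  tab
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with df = (k - 1, N - k).
#'
#' @param values numeric outcomes.
#' @param groups factor (or coercible) of group labels.
#' @return list with F, p, df (length 2), and the sums of squares.
#' @export
anova_oneway <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df = c(tab[["Df"]][1L], tab[["Df"]][2L]),
       ss_between = tab[["Sum Sq"]][1L], ss_within = tab[["Sum Sq"]][2L])
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range-adjusted pairwise mean differences after a one-way
#' ANOVA, with familywise confidence intervals, plus the unadjusted pooled-SE
#' pairwise p value for reference (the adjusted p is never smaller).
#'
#' @param values numeric outcomes.
#' @param groups factor of group labels.
#' @param alpha familywise error rate for the confidence intervals.
#' @return data.frame: pair, diff (second minus first level), lwr, upr,
#'   p_adj, p_unadj.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  mse <- summary(fit)[[1L]][["Mean Sq"]][2L]
  dfw <- summary(fit)[[1L]][["Df"]][2L]
  ns <- table(groups)
  pairs <- rownames(tk)
  p_unadj <- vapply(pairs, function(pr) {
    gg <- strsplit(pr, "-", fixed = TRUE)[[1L]]
    se <- sqrt(mse * (1 / ns[[gg[1L]]] + 1 / ns[[gg[2L]]]))
    2 * stats::pt(-abs(tk[pr, "diff"] / se), dfw)
  }, numeric(1))
  data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             p_unadj = unname(p_unadj),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-by-marker interaction model for cognition
#'
#' Fixed-effects OLS of a cognitive outcome on group, a marker centered at
#' its grand mean, and their interaction:
#' \deqn{y = b_0 + b_1 I(aMCI) + b_2 I(AD) + b_3 x + b_4 x I(aMCI) +
#'       b_5 x I(AD) + e}
#' with CN as the reference level. Reports the six coefficients with t and p,
#' and the 2-df omnibus interaction F test.
#'
#' @param y cognitive outcome (z-scores).
#' @param x marker or co-factor values.
#' @param groups factor with levels CN, aMCI, AD (all present).
#' @return object of class \code{interaction_model}: coefficients table,
#'   interaction F and p, residuals, centered x.
#' @export
interaction_model <- function(y, x, groups) {
  groups <- as.factor(groups)
  want <- c("CN", "aMCI", "AD")
  if (all(want %in% levels(groups))) groups <- factor(groups, levels = want)
  groups <- droplevels(groups)
  if (nlevels(groups) != 3L)
    stop("interaction_model: all three groups must be present")
  xc <- x - mean(x)
  full <- stats::lm(y ~ groups * xc)
  reduced <- stats::lm(y ~ groups + xc)
  an <- stats::anova(reduced, full)
  ct <- summary(full)$coefficients
  coefs <- data.frame(term = c("b0", "b1", "b2", "b3", "b4", "b5"),
                      label = rownames(ct),
                      estimate = ct[, 1L], se = ct[, 2L],
                      t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 interaction_F = an$F[2L], interaction_p = an$`Pr(>F)`[2L],
                 interaction_df = c(an$Df[2L], an$Res.Df[2L]),
                 residuals = stats::residuals(full),
                 x_centered = xc, model = full),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("interaction F(%d,%d) = %.4f, p = %.4g\n",
              x$interaction_df[1L], x$interaction_df[2L],
              x$interaction_F, x$interaction_p))
  invisible(x)
}

#' Group-difference report for all markers and regions
#'
#' Runs the full statistical chain the pipeline uses on a cohort table:
#' covariate adjustment, shifted-log symmetrization, one-way ANOVA across the
#' three groups, Tukey HSD pairwise contrasts, and Benjamini--Hochberg FDR
#' across the marker-x-region F tests.
#'
#' @param cohort wide cohort data.frame (from \code{\link{simulate_cohort}}
#'   or assembled from fitted spectra).
#' @param markers marker names to test.
#' @param regions region names to test.
#' @param tukey_alpha familywise level for the Tukey intervals.
#' @return data.frame shaped like a group-comparison table: marker, region,
#'   F, df1, df2, p, p_fdr, and the three pairwise differences with adjusted
#'   p values.
#' @export
group_difference_report <- function(cohort, markers = marker_names(),
                                    regions = region_names(),
                                    tukey_alpha = 0.05) {
  rows <- NULL
  for (m in markers) {
    for (r in regions) {
      col <- paste0(m, "_", r)
      if (!col %in% names(cohort)) next
      adj <- adjust_covariates(cohort[[col]], cohort$age,
                               cohort$education, cohort$gender)
      tv <- shifted_log(adj)$values
      an <- anova_oneway(tv, cohort$group)
      tk <- tukey_hsd(tv, cohort$group, alpha = tukey_alpha)
      pick <- function(p) {
        i <- match(p, tk$pair)
        c(tk$diff[i], tk$p_adj[i])
      }
      mc <- pick("aMCI-CN"); ac <- pick("AD-CN"); am <- pick("AD-aMCI")
      rows <- rbind(rows, data.frame(
        marker = m, region = r, F = an$F, df1 = an$df[1L], df2 = an$df[2L],
        p = an$p,
        diff_amci_cn = mc[1L], p_amci_cn = mc[2L],
        diff_ad_cn = ac[1L], p_ad_cn = ac[2L],
        diff_ad_amci = am[1L], p_ad_amci = am[2L],
        stringsAsFactors = FALSE))
    }
  }
  rows$p_fdr <- stats::p.adjust(rows$p, method = "BH")
  rows[, c("marker", "region", "F", "df1", "df2", "p", "p_fdr",
           "diff_amci_cn", "p_amci_cn", "diff_ad_cn", "p_ad_cn",
           "diff_ad_amci", "p_ad_amci")]
}

#' Marker-cognition interaction report (temporal lobe)
#'
#' For each temporal-lobe marker and cognitive domain, adjusts both sides for
#' covariates, transforms and variance-scales the marker, and fits the
#' group-by-marker interaction model.
#'
#' @param cohort wide cohort data.frame.
#' @param markers marker names (temporal-lobe columns are used).
#' @param domains cognitive domain names (\code{z_<domain>} columns).
#' @return data.frame: marker, domain, interaction F/p, and the b3..b5
#'   estimates with p values.
#' @export
interaction_report <- function(cohort,
                               markers = c("energy_reserve",
                                           "energy_consumption",
                                           "metabolic_state", "mg"),
                               domains = c("memory", "executive_function",
                                           "attention", "language",
                                           "visuospatial")) {
  rows <- NULL
  for (m in markers) {
    col <- paste0(m, "_temporal")
    if (!col %in% names(cohort)) next
    x <- adjust_covariates(cohort[[col]], cohort$age, cohort$education,
                           cohort$gender)
    x <- shifted_log(x)$values
    x <- x / stats::sd(x)
    for (d in domains) {
      zc <- paste0("z_", d)
      if (!zc %in% names(cohort)) next
      y <- adjust_covariates(cohort[[zc]], cohort$age, cohort$education,
                             cohort$gender)
      im <- interaction_model(y, x, cohort$group)
      est <- function(term) {
        i <- match(term, im$coefficients$term)
        c(im$coefficients$estimate[i], im$coefficients$p[i])
      }
      b3 <- est("b3"); b4 <- est("b4"); b5 <- est("b5")
      rows <- rbind(rows, data.frame(
        marker = m, domain = d,
        F_interaction = im$interaction_F, p_interaction = im$interaction_p,
        b3 = b3[1L], p_b3 = b3[2L], b4 = b4[1L], p_b4 = b4[2L],
        b5 = b5[1L], p_b5 = b5[2L], stringsAsFactors = FALSE))
    }
  }
  rows
}
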