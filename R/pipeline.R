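#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' object: calibration constants, acquisition defaults, preprocessing and
#' fitting options, the significance levels (0.01 for cognitive measures,
#' 0.10 for the BEM markers, Tukey familywise 0.05), and the classifier's
#' seed and fold count. All study constants are defaults here, never
#' hard-coded in the stage logic.
#'
#' @param design a \code{\link{cohort_design}} (used when simulating).
#' @param calib an \code{\link{mrs_calibration}}.
#' @param acq an \code{\link{acq_params}}.
#' @param zero_fill_to zero-filling target before Fourier transform.
#' @param line_broadening quantification apodization in Hz (default 0; the
#'   8 Hz broadening used for display is not applied to quantified spectra).
#' @param fit_options options forwarded to \code{\link{fit_spectrum}}.
#' @param alpha_cognitive,alpha_bem,alpha_tukey significance levels.
#' @param classifier_seed,classifier_folds cross-validation controls.
#' @param fit_spectra quantify markers by fitting the generated spectra
#'   (slow, complete) instead of using the generator's marker table.
#' @param output_dir directory for report files (NULL = don't write).
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(design = cohort_design(),
                            calib = mrs_calibration(),
                            acq = acq_params(),
                            zero_fill_to = 4096L,
                            line_broadening = 0,
                            fit_options = list(),
                            alpha_cognitive = 0.01,
                            alpha_bem = 0.10,
                            alpha_tukey = 0.05,
                            classifier_seed = 1L,
                            classifier_folds = 10L,
                            fit_spectra = FALSE,
                            output_dir = NULL) {
  structure(list(design = design, calib = calib, acq = acq,
                 zero_fill_to = zero_fill_to,
                 line_broadening = line_broadening,
                 fit_options = fit_options,
                 alpha_cognitive = alpha_cognitive,
                 alpha_bem = alpha_bem,
                 alpha_tukey = alpha_tukey,
                 classifier_seed = classifier_seed,
                 classifier_folds = classifier_folds,
                 fit_spectra = fit_spectra,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Preprocess and quantify one FID
#'
#' The standard chain: zero-fill, apodize, Fourier transform, automatic
#' phase correction, Voigt fit, marker extraction.
#'
#' @param fid an \code{fid} object.
#' @param region region label for the marker row.
#' @param config a \code{\link{pipeline_config}}.
#' @return one-row \code{region_markers} data.frame.
#' @export
quantify_fid <- function(fid, region, config = pipeline_config()) {
  fid <- zero_fill(fid, max(config$zero_fill_to, length(fid$samples)))
  fid <- apodize(fid, config$line_broadening)
  spec <- to_spectrum(fid)
  spec <- auto_phase(spec)$spec
  fit <- fit_spectrum(spec, options = config$fit_options)
  bem_indices(fit, region, config$calib)
}

#' Run the full p-BEM analysis pipeline
#'
#' Executes simulate -> (preprocess -> fit -> markers) -> group statistics ->
#' interaction models -> PCA+QDA classification, and (optionally) writes the
#' marker table, the group-difference and interaction reports, the
#' classification report, and a provenance log to \code{config$output_dir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param input optional list with elements \code{cohort_table} and
#'   \code{spectra_dir} to analyze externally stored data (files named
#'   \code{<id>_<region>.csv} in the container format); default is to
#'   simulate from \code{config$design}.
#' @return object of class \code{pbem_report}: cohort, marker table, the two
#'   statistical reports, the classification result and metrics, and
#'   provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(input)) {
    sim <- stage("simulate",
                 simulate_cohort(config$design, spectra = config$fit_spectra,
                                 acq = config$acq, calib = config$calib))
    cohort <- sim$cohort
    spectra <- sim$spectra
  } else {
    cohort <- stage("load", read_cohort_table(input$cohort_table))
    spectra <- NULL
    if (!is.null(input$spectra_dir)) {
      spectra <- lapply(seq_len(nrow(cohort)), function(i) {
        out <- list()
        for (r in region_names()) {
          f <- file.path(input$spectra_dir,
                         sprintf("P%02d_%s.csv", cohort$id[i], r))
          if (!file.exists(f))
            stop(sprintf("missing spectra for participant P%02d (%s): %s",
                         cohort$id[i], r, f))
          out[[r]] <- read_fid(f)
        }
        out
      })
      names(spectra) <- sprintf("P%02d", cohort$id)
      config$fit_spectra <- TRUE
    }
  }

  if (config$fit_spectra) {
    if (is.null(spectra)) stop("fit_spectra = TRUE but no spectra available")
    markers_long <- stage("fit", {
      rows <- NULL
      for (i in seq_along(spectra)) {
        for (r in names(spectra[[i]])) {
          mk <- tryCatch(
            quantify_fid(spectra[[i]][[r]], r, config),
            error = function(e)
              stop(sprintf("participant %s, region %s: %s",
                           names(spectra)[i], r, conditionMessage(e))))
          mk$id <- i
          rows <- rbind(rows, mk)
        }
      }
      rows
    })
    wide <- markers_wide(markers_long)
    keep <- !grepl(paste0("^(", paste(marker_names(), collapse = "|"),
                          "|t_atp)_"), names(cohort))
    cohort <- cbind(cohort[, keep, drop = FALSE],
                    wide[match(cohort$id, wide$id), -1L, drop = FALSE])
  } else {
    markers_long <- if (is.null(input)) sim$markers else NULL
  }

  stats_report <- stage("stats",
    group_difference_report(cohort, tukey_alpha = config$alpha_tukey))
  inter_report <- stage("interaction", interaction_report(cohort))

  feat_cols <- c(grep(paste0("^(", paste(marker_names(), collapse = "|"),
                             ")_"), names(cohort), value = TRUE),
                 grep("^z_", names(cohort), value = TRUE))
  features <- stage("classify-features", {
    X <- as.matrix(cohort[, feat_cols])
    storage.mode(X) <- "double"
    X
  })
  cv <- stage("classify",
              crossval_10fold(features, cohort$group,
                              seed = config$classifier_seed,
                              folds = config$classifier_folds))
  metrics <- confusion_metrics(cv$confusion)

  report <- structure(list(cohort = cohort, markers = markers_long,
                           group_differences = stats_report,
                           interactions = inter_report,
                           classification = cv, metrics = metrics,
                           config = config,
                           provenance = list(
                             time = format(Sys.time()),
                             seed = config$design$seed,
                             classifier_seed = config$classifier_seed,
                             n = nrow(cohort),
                             fit_spectra = config$fit_spectra,
                             package_version = tryCatch(
                               as.character(utils::packageVersion("pbem31p")),
                               error = function(e) "dev"))),
                      class = "pbem_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_cohort_table(cohort, file.path(od, "cohort.tsv"))
    if (!is.null(markers_long))
      write_marker_table(markers_long, file.path(od, "markers.tsv"))
    utils::write.table(stats_report, file.path(od, "group_differences.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(inter_report, file.path(od, "interactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cls <- cbind(data.frame(predicted = rownames(cv$confusion)),
                 as.data.frame.matrix(unclass(cv$confusion)))
    utils::write.table(cls, file.path(od, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(metrics$per_class,
                       file.path(od, "classification_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report$provenance,
                         file.path(od, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pbem_report <- function(x, ...) {
  cat("p-BEM pipeline report\n")
  cat(sprintf("  %d participants, markers %s\n", nrow(x$cohort),
              if (isTRUE(x$config$fit_spectra)) "from spectral fits"
              else "from the generator"))
  sig <- x$group_differences[x$group_differences$p <= x$config$alpha_bem, ]
  cat(sprintf("  group differences at alpha = %.2f: %d of %d marker-region tests\n",
              x$config$alpha_bem, nrow(sig), nrow(x$group_differences)))
  cat(sprintf("  10-fold CV: error %.4f (SE %.4f), accuracy %.1f%%, %d misclassified of %d\n",
              x$classification$cv_error, x$classification$standard_error,
              100 * x$metrics$accuracy, x$metrics$misclassified,
              x$metrics$n))
  invisible(x)
}
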