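# End-to-end orchestration: phantoms/volumes -> centerline -> CSA ->
# cohort statistics -> normalization, with a config echo and flat-file
# outputs sufficient to re-run bit-identically under a fixed seed.

#' Read a pipeline run configuration
#'
#' YAML with the defaults filled in: `method` "both", `distance_mm` 64,
#' `extent_mm` 20, `smoothing_mm` 30, `alpha` 0.05, `seed` 1.
#'
#' @param path YAML file path.
#' @return a config list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("readRunConfig: file not found: ", path)
  .fillConfig(yaml::read_yaml(path))
}

.fillConfig <- function(config) {
  defaults <- list(method = "both", distance_mm = 64, extent_mm = 20,
                   smoothing_mm = 30, alpha = 0.05, seed = 1,
                   output_dir = "pmjcsa-run")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!config$method %in% c("pmj", "disc", "both"))
    stop("config: method must be 'pmj', 'disc' or 'both'")
  config
}

.phantomFromConfig <- function(ph) {
  spec <- ph$spec
  args <- list(curve = if (is.null(spec$curve)) "straight" else spec$curve)
  for (nm in c("radius_mm", "extent_si_mm", "voxel_size_mm", "tilt_deg",
               "pmj_offset_mm", "arc_radius_mm", "poly_x", "poly_y",
               "margin_vox"))
    if (!is.null(spec[[nm]])) args[[nm]] <- unlist(spec[[nm]])
  if (!is.null(spec$disc_arcs_mm))
    args$disc_arcs_mm <- unlist(spec$disc_arcs_mm)
  makeTubePhantom(do.call(phantomSpec, args))
}

.logLine <- function(con, stage, subject, msg) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", subject,
      ": ", msg, "\n", sep = "", file = con, append = TRUE)
}

#' Run the measurement + normalization pipeline
#'
#' Executes, in order and as configured: (1) per-subject imaging - load or
#' synthesize a cord mask + labels, measure PMJ-referenced and/or
#' vertebral CSA; (2) cohort statistics - correlations, sex t-test, age
#' fits; (3) normalization - apply a published model or refit on the
#' cohort (optionally after stepwise selection), with COV before/after
#' and z-scores. Writes `results.csv`, `cohort_normalized.csv`,
#' `models/*.json`, `report.md`, a config echo and a timestamped
#' `log.txt` into the output directory; failures are collected per
#' subject/stage in `failures.csv` while the run continues.
#'
#' @param config list (see [readRunConfig()]): fields `phantoms` (list of
#'   `list(name=, spec=)` or `list(name=, mask=, labels=)`), `cohort`
#'   (`list(csv=)` or `list(spec = list(...))`), `method`, `distance_mm`,
#'   `extent_mm`, `smoothing_mm`, `model` (published id) or `predictors`
#'   (refit; character vector), `stepwise` (logical; use
#'   [stepwiseSelect()] over `candidates`), `alpha`, `seed`, `output_dir`.
#' @return the run report, invisibly: list with `results` (per-subject
#'   data.frame or NULL), `comparison`, `statistics`, `model`,
#'   `normalized`, `cov`, `failures`.
#' @export
runPipeline <- function(config) {
  config <- .fillConfig(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  log <- file.path(out, "log.txt")
  cat("", file = log)
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  failures <- data.frame(stage = character(), subject = character(),
                         error = character())
  fail <- function(stage, subject, e) {
    failures <<- rbind(failures,
                       data.frame(stage = stage, subject = subject,
                                  error = conditionMessage(e)))
    .logLine(log, stage, subject, paste("FAILED:", conditionMessage(e)))
  }

  # ---- imaging stage ----
  results <- NULL
  comparison <- NULL
  if (!is.null(config$phantoms)) {
    rows <- list()
    for (ph in config$phantoms) {
      subject <- if (is.null(ph$name)) "subject" else ph$name
      row <- data.frame(subject = subject, csa_pmj = NA_real_,
                        n_slices_pmj = NA_integer_,
                        csa_vertebral = NA_real_,
                        n_slices_vertebral = NA_integer_)
      loaded <- tryCatch({
        if (!is.null(ph$mask)) {
          list(mask = readVolume(ph$mask),
               labels = readVolume(ph$labels))
        } else {
          phan <- .phantomFromConfig(ph)
          list(mask = phan$mask, labels = phan$labels)
        }
      }, error = function(e) { fail("load", subject, e); NULL })
      if (is.null(loaded)) { rows[[subject]] <- row; next }
      .logLine(log, "load", subject, "mask and labels ready")

      if (config$method %in% c("pmj", "both")) {
        r <- tryCatch(
          csaPMJ(loaded$mask, loaded$labels,
                 distance_mm = config$distance_mm,
                 extent_mm = config$extent_mm,
                 smoothing_mm = config$smoothing_mm),
          error = function(e) { fail("csa_pmj", subject, e); NULL })
        if (!is.null(r)) {
          row$csa_pmj <- csaValue(r); row$n_slices_pmj <- r@nSlices
          .logLine(log, "csa_pmj", subject,
                   sprintf("%.3f mm^2 over %d slices", r@value, r@nSlices))
        }
      }
      if (config$method %in% c("disc", "both")) {
        r <- tryCatch(
          csaVertebral(loaded$mask, loaded$labels,
                       smoothing_mm = config$smoothing_mm),
          error = function(e) { fail("csa_vertebral", subject, e); NULL })
        if (!is.null(r)) {
          row$csa_vertebral <- csaValue(r)
          row$n_slices_vertebral <- r@nSlices
          .logLine(log, "csa_vertebral", subject,
                   sprintf("%.3f mm^2 over %d slices", r@value, r@nSlices))
        }
      }
      rows[[subject]] <- row
    }
    results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.csv(results, file.path(out, "results.csv"),
                     row.names = FALSE)
    ok <- stats::complete.cases(results[, c("csa_pmj", "csa_vertebral")])
    if (config$method == "both" && sum(ok) >= 2)
      comparison <- compareMethods(results$csa_pmj[ok],
                                   results$csa_vertebral[ok])
  }

  # ---- cohort stage ----
  statistics <- NULL; model <- NULL; normalized <- NULL; covs <- NULL
  report <- NULL
  if (!is.null(config$cohort)) {
    cohort <- tryCatch({
      if (!is.null(config$cohort$csv))
        utils::read.csv(config$cohort$csv)
      else {
        args <- config$cohort$spec
        if (is.null(args$seed)) args$seed <- config$seed
        if (!is.null(args$true_coefficients))
          args$true_coefficients <- unlist(args$true_coefficients)
        makeCohort(do.call(cohortSpec, args))
      }
    }, error = function(e) { fail("cohort", "cohort", e); NULL })

    if (!is.null(cohort)) {
      .logLine(log, "cohort", "cohort", paste(nrow(cohort), "participants"))
      statistics <- cohortStatistics(cohort)

      predictors <- config$predictors
      if (isTRUE(config$stepwise)) {
        cand <- if (!is.null(config$candidates)) config$candidates else
          setdiff(names(cohort), "csa")
        sw <- stepwiseSelect(cohort, cand, alpha = config$alpha)
        predictors <- sw$selected
        .logLine(log, "stepwise", "cohort",
                 paste("selected:", paste(predictors, collapse = ", ")))
      }

      if (!is.null(config$model)) {
        model <- publishedModels(config$model)
      } else if (length(predictors)) {
        fitted <- tryCatch(
          fitResidualModel(cohort, predictors),
          error = function(e) { fail("fit", "cohort", e); NULL })
        if (!is.null(fitted)) { model <- fitted$model; report <- fitted$report }
      }

      if (!is.null(model)) {
        normed <- tryCatch(
          suppressWarnings(normalizeCSA(cohort$csa, cohort, model)),
          error = function(e) { fail("normalize", "cohort", e); NULL })
        if (!is.null(normed)) {
          normalized <- cbind(cohort,
                              csa_norm = normed,
                              z = csaZScore(normed, model))
          utils::write.csv(normalized,
                           file.path(out, "cohort_normalized.csv"),
                           row.names = FALSE)
          covs <- list(measured = covPercent(cohort$csa),
                       normalized = covPercent(normed))
          covs$reduction_pct <-
            100 * (covs$measured - covs$normalized) / covs$measured
          writeModelJSON(model,
                         file.path(out, "models",
                                   paste0(model@id, ".json")))
          .logLine(log, "normalize", "cohort",
                   sprintf("COV %.2f%% -> %.2f%%", covs$measured,
                           covs$normalized))
        }
      }
    }
  }

  if (nrow(failures))
    utils::write.csv(failures, file.path(out, "failures.csv"),
                     row.names = FALSE)
  reportObj <- list(results = results, comparison = comparison,
                    statistics = statistics, model = model,
                    regression = report, normalized = normalized,
                    cov = covs, failures = failures)
  .writeReportMd(reportObj, config, file.path(out, "report.md"))
  invisible(reportObj)
}

.writeReportMd <- function(r, config, path) {
  lines <- c("# pmjcsa run report", "")
  if (!is.null(r$results)) {
    lines <- c(lines, sprintf("## CSA (%d subject(s))", nrow(r$results)), "")
    for (i in seq_len(nrow(r$results)))
      lines <- c(lines, sprintf("- %s: PMJ %.3f mm^2, vertebral %.3f mm^2",
                                r$results$subject[i], r$results$csa_pmj[i],
                                r$results$csa_vertebral[i]))
    if (!is.null(r$comparison))
      lines <- c(lines, "",
                 sprintf(paste0("Paired comparison: mean difference %.4f ",
                                "mm^2, t = %.3f, p = %.3g"),
                         r$comparison$mean_difference, r$comparison$t,
                         r$comparison$p))
    lines <- c(lines, "")
  }
  if (!is.null(r$cov)) {
    lines <- c(lines, "## Normalization", "",
               sprintf("- model: %s", r$model@id),
               sprintf("- COV measured: %.2f%%", r$cov$measured),
               sprintf("- COV normalized: %.2f%%", r$cov$normalized),
               sprintf("- reduction: %.2f%%", r$cov$reduction_pct), "")
  }
  if (nrow(r$failures))
    lines <- c(lines, "## Failures", "",
               sprintf("- [%s] %s: %s", r$failures$stage,
                       r$failures$subject, r$failures$error))
  writeLines(lines, path)
  invisible(path)
}
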