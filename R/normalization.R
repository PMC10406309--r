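# Regression-residual normalization of CSA:
#   CSA_norm_i = CSA_meas_i + sum_j c_j (X_j,mean - X_j,meas_i)
# with the published coefficient registries, refitting on a cohort,
# stepwise predictor selection, z-scores and COV reporting.
#
# Predictor naming: plain column names of the cohort table, plus
# interaction terms "sex:<name>" meaning the raw product of sex (0 female,
# 1 male) and the predictor; interaction means are means of the product.

.SHARED_MEANS <- c(thalamus_volume = 15266, brain_volume = 1156171,
                   sex = 0.437, "sex:brain_volume" = 530335)

.mkModel <- function(id, coef, mu, sigma, reference, note = "") {
  means <- .SHARED_MEANS[names(coef)]
  new("NormalizationModel", id = id, predictors = names(coef),
      coefficients = coef, means = means, muNorm = mu, sigmaNorm = sigma,
      reference = reference, provenance = "published", note = note)
}

#' Published CSA normalization models
#'
#' The six published coefficient sets: three model families (M1: thalamus +
#' brain volume; M2: thalamus + brain volume + sex + sex x brain volume;
#' M3: brain volume + sex + sex x brain volume, for when thalamus volume is
#' unavailable or unreliable, e.g. thalamic atrophy) for each of the two
#' CSA references (PMJ distance, C2-C3 disc). Coefficients, predictor
#' means, mu_norm and sigma_norm are reproduced exactly as published.
#'
#' The M2-C2C3 sex coefficient is -1.235 as published, an order of
#' magnitude below its PMJ counterpart (-15) - most likely a typographical
#' loss of a digit. It is kept verbatim; using that model triggers a
#' warning, and refitting on your own cohort is the sanctioned fix.
#'
#' @param id optional model id ("M1-PMJ", "M1-C2C3", "M2-PMJ", "M2-C2C3",
#'   "M3-PMJ", "M3-C2C3"); NULL returns the whole registry.
#' @return a named list of [NormalizationModel-class], or a single model.
#' @examples
#' publishedModels("M1-PMJ")
#' @export
publishedModels <- function(id = NULL) {
  reg <- list(
    "M1-PMJ" = .mkModel("M1-PMJ",
      c(thalamus_volume = 1.986e-3, brain_volume = 7.56e-6),
      mu = 66.26, sigma = 5.72, reference = "pmj"),
    "M1-C2C3" = .mkModel("M1-C2C3",
      c(thalamus_volume = 0.002, brain_volume = 7.30e-6),
      mu = 66.40, sigma = 5.64, reference = "c2c3"),
    "M2-PMJ" = .mkModel("M2-PMJ",
      c(thalamus_volume = 1.98e-3, brain_volume = 2.45e-6, sex = -15,
        "sex:brain_volume" = 1.26e-5),
      mu = 66.26, sigma = 5.59, reference = "pmj"),
    "M2-C2C3" = .mkModel("M2-C2C3",
      c(thalamus_volume = 1.98e-3, brain_volume = 2.49e-6, sex = -1.235,
        "sex:brain_volume" = 1.26e-5),
      mu = 66.40, sigma = 5.61, reference = "c2c3",
      note = paste("sex coefficient -1.235 as published; inconsistent in",
                   "magnitude with the companion models (-15, -15.23),",
                   "likely a typographical loss of a digit")),
    "M3-PMJ" = .mkModel("M3-PMJ",
      c(brain_volume = 2.37e-5, sex = -15, "sex:brain_volume" = 1.24e-5),
      mu = 66.26, sigma = 5.94, reference = "pmj"),
    "M3-C2C3" = .mkModel("M3-C2C3",
      c(brain_volume = 2.38e-5, sex = -15.23, "sex:brain_volume" = 1.25e-5),
      mu = 66.40, sigma = 5.86, reference = "c2c3"))
  if (is.null(id)) return(reg)
  if (!id %in% names(reg))
    stop("unknown model id '", id, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[id]]
}

# resolve model predictor values (computing sex:x products) from a named
# list/vector or data.frame of base predictors
.predictorMatrix <- function(predictors, needed) {
  if (is.data.frame(predictors)) pl <- as.list(predictors)
  else pl <- as.list(predictors)
  n <- max(vapply(pl, length, 0L))
  out <- matrix(NA_real_, n, length(needed),
                dimnames = list(NULL, needed))
  for (nm in needed) {
    if (nm %in% names(pl)) {            # literal column (may be a product)
      out[, nm] <- pl[[nm]]
    } else if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      missing <- setdiff(parts, names(pl))
      if (length(missing))
        stop("missing predictor '", missing[1], "' (needed for interaction ",
             nm, ")")
      out[, nm] <- Reduce(`*`, pl[parts])
    } else {
      stop("missing predictor '", nm, "'")
    }
  }
  # 0 = female, 1 = male; a fractional value in [0, 1] is tolerated as a
  # cohort-mean plug-in, anything outside is a coding error
  if ("sex" %in% names(pl) && any(pl$sex < 0 | pl$sex > 1, na.rm = TRUE))
    stop("sex must be coded 0 (female) / 1 (male)")
  out
}

#' Normalize measured CSA with a normalization model
#'
#' Applies CSA_norm = CSA_meas + sum_j c_j (X_j,mean - X_j,meas).
#' Interaction predictors ("sex:brain_volume") are computed on the fly
#' from the base predictors. When every predictor sits at the model mean
#' the measured value is returned unchanged.
#'
#' @param csa_meas measured CSA values (mm^2), scalar or vector.
#' @param predictors named list/vector (scalar case) or data.frame
#'   (vectorized case) of predictor values; must cover every model
#'   predictor (interactions derived automatically). Sex is 0 = female,
#'   1 = male.
#' @param model a [NormalizationModel-class].
#' @return normalized CSA (mm^2), same length as `csa_meas`.
#' @examples
#' m <- publishedModels("M1-PMJ")
#' normalizeCSA(70, c(thalamus_volume = 14266, brain_volume = 1156171), m)
#' # 70 + 1.986e-3 * 1000 = 71.986
#' @export
normalizeCSA <- function(csa_meas, predictors, model) {
  stopifnot(is(model, "NormalizationModel"))
  if (nzchar(model@note))
    warning("model ", model@id, ": ", model@note)
  X <- .predictorMatrix(predictors, model@predictors)
  if (nrow(X) != length(csa_meas)) {
    if (length(csa_meas) == 1L) csa_meas <- rep(csa_meas, nrow(X))
    else if (nrow(X) == 1L) X <- X[rep(1L, length(csa_meas)), , drop = FALSE]
    else stop("csa_meas and predictors have incompatible lengths")
  }
  resid <- sweep(-X, 2, model@means, `+`)   # X_mean - X_meas
  as.numeric(csa_meas + resid %*% model@coefficients)
}

#' z-score of a normalized CSA
#'
#' (CSA_norm - mu_norm) / sigma_norm with the model's normalized-cohort
#' mean and STD.
#'
#' @param csa_norm normalized CSA values (mm^2).
#' @param model a [NormalizationModel-class].
#' @return dimensionless z-scores.
#' @export
csaZScore <- function(csa_norm, model) {
  stopifnot(is(model, "NormalizationModel"))
  (csa_norm - model@muNorm) / model@sigmaNorm
}

#' Coefficient of variation
#'
#' 100 x sample STD / mean (the n-1 denominator), in percent.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return COV in percent.
#' @export
covPercent <- function(values) {
  if (length(values) < 2L) stop("covPercent: need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("covPercent: mean is zero; COV undefined")
  100 * stats::sd(values) / m
}

# OLS through lm() with syntactic column names (model-term names like
# "sex:brain_volume" would otherwise be parsed as formula interactions)
.olsFit <- function(y, X) {
  df <- data.frame(.y = y, X)
  names(df) <- c(".y", paste0(".x", seq_len(ncol(X))))
  stats::lm(.y ~ ., data = df)
}

# design matrix for a predictor list over a cohort (listwise-complete
# enforced by the caller)
.designMatrix <- function(cohort, predictors, response = "csa") {
  X <- .predictorMatrix(cohort, predictors)
  y <- cohort[[response]]
  if (is.null(y)) stop("cohort has no '", response, "' column")
  list(X = X, y = y)
}

#' Fit a regression-residual normalization model on a cohort
#'
#' Ordinary least squares of measured CSA on the given predictors (plus
#' intercept). The fitted slopes become the residual coefficients c_j, the
#' cohort predictor means become X_j,mean, and mu_norm / sigma_norm are the
#' mean and sample STD of the normalized values on the fitting cohort.
#' By construction the normalization preserves the cohort mean
#' (mean(CSA_norm) = mean(CSA_meas)) and shrinks the STD by sqrt(1 - R^2).
#'
#' @param cohort data.frame with a `csa` column, a 0/1 `sex` column when
#'   used, and one column per base predictor; rows with missing values in
#'   the used columns are dropped (listwise deletion) with a message.
#' @param predictors predictor names; "sex:<name>" terms are raw products.
#' @param reference "pmj" or "c2c3" (metadata only).
#' @param response name of the measured CSA column.
#' @return list with `model` ([NormalizationModel-class]) and `report`
#'   (coefficient table with t and p per term, R2, adjusted R2, F, overall
#'   p, AIC).
#' @export
fitResidualModel <- function(cohort, predictors, reference = c("pmj", "c2c3"),
                             response = "csa") {
  reference <- match.arg(reference)
  base <- unique(unlist(strsplit(predictors, ":", fixed = TRUE)))
  used <- c(base, response)
  missingCols <- setdiff(used, names(cohort))
  if (length(missingCols))
    stop("cohort lacks column(s): ", paste(missingCols, collapse = ", "))
  cc <- stats::complete.cases(cohort[, used, drop = FALSE])
  if (!all(cc)) {
    message("fitResidualModel: dropping ", sum(!cc),
            " participant(s) with missing values")
    cohort <- cohort[cc, , drop = FALSE]
  }
  dm <- .designMatrix(cohort, predictors, response)
  n <- length(dm$y); p <- length(predictors)
  if (n <= p + 2) stop("fitResidualModel: need n > number of terms + 2")

  qrX <- qr(cbind(1, dm$X))
  if (qrX$rank < p + 1) {
    dropped <- c("(Intercept)", predictors)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("fitResidualModel: rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- .olsFit(dm$y, dm$X)
  sm <- summary(fit)
  coefs <- stats::coef(fit)[-1]
  names(coefs) <- predictors
  means <- colMeans(dm$X)
  names(means) <- predictors

  norm <- dm$y + as.numeric(sweep(-dm$X, 2, means, `+`) %*% coefs)
  model <- new("NormalizationModel", id = paste0("refit-", reference),
               predictors = predictors, coefficients = coefs, means = means,
               muNorm = mean(norm), sigmaNorm = stats::sd(norm),
               reference = reference, provenance = "refit", note = "")
  fstat <- sm$fstatistic
  report <- list(
    coefficients = data.frame(
      term = c("(Intercept)", predictors),
      coef = unname(stats::coef(fit)),
      t = unname(sm$coefficients[, "t value"]),
      p = unname(sm$coefficients[, "Pr(>|t|)"])),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    F = unname(fstat[1]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    AIC = stats::AIC(fit),
    n = n)
  list(model = model, report = report)
}

#' Stepwise predictor selection by correlation rank
#'
#' Candidates are ordered by decreasing |Pearson r| with measured CSA
#' (ties broken lexicographically by name). In that order each candidate
#' is tentatively added to the model and kept only if its term p-value in
#' the joint OLS fit is below `alpha`; after every successful entry, terms
#' whose p-value has risen above `alpha` are removed (highest p first).
#' Entry and exit use the same significance level. The procedure stops
#' when a full pass adds nothing.
#'
#' @param cohort data.frame with a `csa` column and candidate columns.
#' @param candidates candidate predictor names ("sex:<name>" allowed).
#' @param alpha significance level for entry and exit (default 0.05).
#' @param response measured CSA column name.
#' @param max_steps safety limit; exceeding it reports an entry/exit cycle.
#' @return list with `selected` (names, in entry order) and `trace`
#'   (data.frame: step, action = enter/reject/exit, term, p).
#' @export
stepwiseSelect <- function(cohort, candidates, alpha = 0.05,
                           response = "csa", max_steps = 100) {
  stopifnot(length(candidates) >= 1L)
  base <- unique(unlist(strsplit(candidates, ":", fixed = TRUE)))
  cc <- stats::complete.cases(cohort[, c(base, response), drop = FALSE])
  cohort <- cohort[cc, , drop = FALSE]
  X <- .predictorMatrix(cohort, candidates)
  y <- cohort[[response]]

  r <- abs(apply(X, 2, function(col) stats::cor(col, y)))
  ord <- candidates[order(-r, candidates)]   # |r| desc, name asc on ties

  termP <- function(sel) {
    fit <- .olsFit(y, X[, sel, drop = FALSE])
    p <- summary(fit)$coefficients[-1, "Pr(>|t|)"]
    names(p) <- sel
    p
  }

  selected <- character()
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), p = numeric())
  step <- 0L
  repeat {
    changed <- FALSE
    for (candTerm in setdiff(ord, selected)) {
      step <- step + 1L
      if (step > max_steps)
        stop("stepwiseSelect: entry/exit oscillation; no stable model after ",
             max_steps, " steps (last cycle around '", candTerm, "')")
      p <- termP(c(selected, candTerm))
      if (p[[candTerm]] < alpha) {
        selected <- c(selected, candTerm)
        trace <- rbind(trace, data.frame(step = step, action = "enter",
                                         term = candTerm, p = p[[candTerm]]))
        # exit phase: drop worst offender until all terms significant
        repeat {
          p <- termP(selected)
          worst <- which.max(p)
          if (p[worst] <= alpha) break
          trace <- rbind(trace, data.frame(step = step, action = "exit",
                                           term = names(p)[worst],
                                           p = p[worst]))
          selected <- setdiff(selected, names(p)[worst])
        }
        changed <- TRUE
        break
      } else {
        trace <- rbind(trace, data.frame(step = step, action = "reject",
                                         term = candTerm, p = p[[candTerm]]))
      }
    }
    if (!changed) break
  }
  rownames(trace) <- NULL
  list(selected = selected, trace = trace)
}

#' Cohort-level descriptive statistics
#'
#' The exploratory statistics computed on a cohort: the full Pearson
#' correlation matrix with per-pair p-values (uncorrected for multiple
#' comparisons, by design - it is exploratory), a two-sample t-test of CSA
#' by sex (equal variances assumed), and degree-1 and degree-2
#' least-squares fits of CSA on age with R^2.
#'
#' @param cohort data.frame; numeric columns enter the correlation matrix.
#'   `sex` (0/1) and `age` are used for the group test and age fits when
#'   present.
#' @param response measured CSA column name.
#' @return list with `correlations` (list of r and p matrices), `sex_ttest`
#'   (or NULL), `age_fits` (or NULL).
#' @export
cohortStatistics <- function(cohort, response = "csa") {
  num <- cohort[vapply(cohort, is.numeric, TRUE)]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  nm <- names(num)
  k <- length(nm)
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pv <- r
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    if (stats::sd(num[[i]]) == 0 || stats::sd(num[[j]]) == 0) next
    ct <- stats::cor.test(num[[i]], num[[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }

  sexTest <- NULL
  if ("sex" %in% nm && stats::sd(num$sex) > 0) {
    tt <- stats::t.test(num[[response]][num$sex == 1],
                        num[[response]][num$sex == 0], var.equal = TRUE)
    sexTest <- list(t = unname(tt$statistic), p = tt$p.value,
                    mean_male = mean(num[[response]][num$sex == 1]),
                    mean_female = mean(num[[response]][num$sex == 0]))
  }

  ageFits <- NULL
  if ("age" %in% nm) {
    d <- data.frame(y = num[[response]], x = num$age)
    f1 <- stats::lm(y ~ x, data = d)
    f2 <- stats::lm(y ~ x + I(x^2), data = d)
    ageFits <- list(
      linear = list(coefficients = unname(stats::coef(f1)),
                    r_squared = summary(f1)$r.squared),
      quadratic = list(coefficients = unname(stats::coef(f2)),
                       r_squared = summary(f2)$r.squared))
  }
  list(correlations = list(r = r, p = pv), sex_ttest = sexTest,
       age_fits = ageFits)
}

#' Serialize / deserialize a NormalizationModel as JSON
#'
#' @param model a [NormalizationModel-class].
#' @param path output (input) file path.
#' @return `path` invisibly (`readModelJSON`: the model).
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "NormalizationModel"))
  obj <- list(id = model@id, predictors = model@predictors,
              coefficients = as.list(model@coefficients),
              means = as.list(model@means),
              mu_norm = model@muNorm, sigma_norm = model@sigmaNorm,
              reference = model@reference, provenance = model@provenance,
              note = model@note)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$coefficients)
  means <- unlist(obj$means)[names(coefs)]
  new("NormalizationModel", id = obj$id, predictors = obj$predictors,
      coefficients = coefs, means = means, muNorm = obj$mu_norm,
      sigmaNorm = obj$sigma_norm, reference = obj$reference,
      provenance = obj$provenance,
      note = if (is.null(obj$note)) "" else obj$note)
}
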