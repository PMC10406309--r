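# Cohort simulator: per-participant predictor tables with a known
# generative linear model for CSA. Emulates the predictor structure the
# normalization assumes - dichotomous sex, correlated brain/thalamus
# volumes (Gaussian copula), additive Gaussian noise - so parameter
# recovery, stepwise selection and COV-reduction behavior can be tested
# against construction.

#' Specify a synthetic cohort
#'
#' Continuous predictors are sampled from a Gaussian copula over the
#' stated marginals; sex is Bernoulli, and its correlation with each
#' continuous predictor is induced by a sex-dependent mean shift (the
#' latent Gaussian correlations are solved so the TOTAL correlations match
#' the targets). Measured CSA is the generative linear predictor plus
#' Gaussian noise.
#'
#' Defaults echo the published cohort: n = 804, 43.7% male, brain volume
#' mean 1,156,171 mm^3, thalamus volume mean 15,266 mm^3, thalamus-brain
#' correlation 0.79, sex-brain 0.49, sex-thalamus 0.36, generative slopes
#' from the two-predictor CSA(PMJ) fit (intercept 27.18, thalamus 1.99e-3,
#' brain 7.56e-6), and noise calibrated so the predictors explain
#' `target_r2` = 0.267 of the CSA variance. SDs are not published; 110,000
#' and 1,500 mm^3 (roughly 10% coefficients of variation) are used as
#' realistic volumetric spreads.
#'
#' @param n participant count.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param sex_fraction proportion coded 1 (male).
#' @param predictor_means,predictor_sds named numeric vectors over the
#'   continuous predictors.
#' @param predictor_correlations correlation matrix (dimnames = predictor
#'   names) among the continuous predictors' TOTAL distributions.
#' @param sex_correlations named vector: target correlation of sex with
#'   each continuous predictor (0 for omitted names).
#' @param true_coefficients named generative weights; may include
#'   "intercept", "sex", any continuous predictor, and "sex:<name>" raw
#'   products.
#' @param noise_sd residual STD in mm^2, or NULL to derive it from
#'   `target_r2`.
#' @param target_r2 fraction of CSA variance explained by the linear
#'   predictor (used when `noise_sd` is NULL).
#' @return a list of class `"cohortSpec"`.
#' @seealso [makeCohort()]
#' @export
cohortSpec <- function(n = 804,
                       seed = 1,
                       sex_fraction = 0.437,
                       predictor_means = c(thalamus_volume = 15266,
                                           brain_volume = 1156171),
                       predictor_sds = c(thalamus_volume = 1500,
                                         brain_volume = 110000),
                       predictor_correlations = NULL,
                       sex_correlations = c(thalamus_volume = 0.36,
                                            brain_volume = 0.49),
                       true_coefficients = c(intercept = 27.18,
                                             thalamus_volume = 1.99e-3,
                                             brain_volume = 7.56e-6),
                       noise_sd = NULL,
                       target_r2 = 0.267) {
  nm <- names(predictor_means)
  stopifnot(n >= 4, length(nm) >= 1L, !is.null(nm),
            identical(sort(nm), sort(names(predictor_sds))),
            sex_fraction > 0, sex_fraction < 1,
            all(predictor_sds > 0))
  if (is.null(predictor_correlations)) {
    predictor_correlations <- diag(length(nm))
    dimnames(predictor_correlations) <- list(nm, nm)
    if (all(c("thalamus_volume", "brain_volume") %in% nm)) {
      predictor_correlations["thalamus_volume", "brain_volume"] <-
        predictor_correlations["brain_volume", "thalamus_volume"] <- 0.79
    }
  }
  sc <- rep(0, length(nm)); names(sc) <- nm
  sc[names(sex_correlations)[names(sex_correlations) %in% nm]] <-
    sex_correlations[names(sex_correlations) %in% nm]
  structure(list(n = as.integer(n), seed = seed,
                 sex_fraction = sex_fraction,
                 means = predictor_means[nm], sds = predictor_sds[nm],
                 corr = predictor_correlations[nm, nm, drop = FALSE],
                 sex_corr = sc,
                 beta = true_coefficients,
                 noise_sd = noise_sd, target_r2 = target_r2),
            class = "cohortSpec")
}

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic cohort table
#'
#' Samples the cohort defined by a [cohortSpec()]: a data.frame with
#' columns `sex` (0/1), one column per continuous predictor, and `csa`
#' (mm^2) = generative linear predictor + Gaussian noise. The generative
#' coefficients, the realized noise SD and the spec are retained in the
#' `"generative"` attribute.
#'
#' @param spec a [cohortSpec()].
#' @return data.frame of n rows; attribute `generative` documents the
#'   construction (beta, noise_sd, spec).
#' @examples
#' co <- makeCohort(cohortSpec(n = 100, seed = 7))
#' colMeans(co[c("sex", "csa")])
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  nm <- names(spec$means)
  k <- length(nm)
  p <- spec$sex_fraction
  rho <- spec$sex_corr

  # latent Gaussian correlation that yields the target TOTAL correlations
  # once the sex shift delta_j * (sex - p) is added
  corrZ <- diag(k); dimnames(corrZ) <- list(nm, nm)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    den <- sqrt((1 - rho[i]^2) * (1 - rho[j]^2))
    corrZ[i, j] <- (spec$corr[i, j] - rho[i] * rho[j]) / den
  }
  ev <- eigen(corrZ, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("makeCohort: implied latent correlation matrix is not positive ",
         "semi-definite (min eigenvalue ", format(min(ev)),
         "); relax predictor/sex correlations")

  .withSeed(spec$seed, {
    sex <- stats::rbinom(spec$n, 1, p)
    Z <- if (k == 1L) matrix(stats::rnorm(spec$n), ncol = 1) else
      MASS::mvrnorm(spec$n, mu = rep(0, k), Sigma = corrZ)
    X <- matrix(NA_real_, spec$n, k, dimnames = list(NULL, nm))
    for (j in seq_len(k)) {
      delta <- rho[j] * spec$sds[j] / sqrt(p * (1 - p))
      X[, j] <- spec$means[j] +
        spec$sds[j] * sqrt(1 - rho[j]^2) * Z[, j] +
        delta * (sex - p)
    }

    tab <- data.frame(sex = sex, X, check.names = FALSE)
    beta <- spec$beta
    eta <- rep(if ("intercept" %in% names(beta)) beta[["intercept"]] else 0,
               spec$n)
    for (b in setdiff(names(beta), "intercept")) {
      parts <- strsplit(b, ":", fixed = TRUE)[[1]]
      bad <- setdiff(parts, names(tab))
      if (length(bad))
        stop("makeCohort: true_coefficients names unknown predictor '",
             bad[1], "'")
      eta <- eta + beta[[b]] * Reduce(`*`, tab[parts])
    }
    noise_sd <- spec$noise_sd
    if (is.null(noise_sd)) {
      r2 <- spec$target_r2
      stopifnot(r2 > 0, r2 < 1)
      vs <- stats::var(eta)
      if (vs == 0)
        stop("makeCohort: target_r2 given but the linear predictor is ",
             "constant; provide noise_sd instead")
      noise_sd <- sqrt(vs * (1 - r2) / r2)
    }
    tab$csa <- eta + stats::rnorm(spec$n, 0, noise_sd)
    attr(tab, "generative") <- list(beta = beta, noise_sd = noise_sd,
                                    spec = spec)
    tab
  })
}
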