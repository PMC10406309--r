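test_that("the published registry is complete and exact", {
  reg <- publishedModels()
  expect_length(reg, 6)
  expect_identical(modelCoefficients(reg[["M1-PMJ"]])[["thalamus_volume"]],
                   1.986e-3)
  expect_identical(modelCoefficients(reg[["M1-C2C3"]])[["brain_volume"]],
                   7.30e-6)
  expect_identical(modelCoefficients(reg[["M3-C2C3"]])[["sex"]], -15.23)
  expect_identical(modelCoefficients(reg[["M2-C2C3"]])[["sex"]], -1.235)
  for (m in reg) {
    expect_identical(modelMeans(m)[["brain_volume"]], 1156171)
    expect_identical(m@provenance, "published")
  }
  expect_identical(modelMu(reg[["M1-PMJ"]]), 66.26)
  expect_identical(modelSigma(reg[["M3-C2C3"]]), 5.86)
  expect_error(publishedModels("M9-PMJ"), "unknown model id")
})

test_that("normalization at the predictor means is the identity", {
  # predictor values pinned at the registry means make the residual term
  # vanish term-by-term (sex and the interaction are supplied directly at
  # their means here, bypassing the 0/1 coding check on purpose)
  atMeans <- c(thalamus_volume = 15266, brain_volume = 1156171,
               sex = 0.437, "sex:brain_volume" = 530335)
  for (m in publishedModels()) {
    x <- suppressWarnings(
      normalizeCSA(70, atMeans[modelPredictors(m)], m))
    expect_identical(x, 70)
  }
})

test_that("normalizeCSA reproduces hand-computed values", {
  m1 <- publishedModels("M1-PMJ")
  expect_equal(normalizeCSA(70, c(thalamus_volume = 14266,
                                  brain_volume = 1156171), m1),
               70 + 1.986e-3 * 1000, tolerance = 1e-12)

  m3 <- publishedModels("M3-PMJ")
  got <- normalizeCSA(65, c(sex = 0, brain_volume = 1200000), m3)
  want <- 65 + 2.37e-5 * (1156171 - 1200000) - 15 * 0.437 +
    1.24e-5 * 530335
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("normalizeCSA is affine in the measured value with unit slope", {
  m <- publishedModels("M1-PMJ")
  preds <- c(thalamus_volume = 14000, brain_volume = 1100000)
  expect_identical(normalizeCSA(70 + 2.5, preds, m) -
                     normalizeCSA(70, preds, m), 2.5)
})

test_that("normalizeCSA validates its inputs", {
  m2 <- publishedModels("M2-PMJ")
  expect_error(normalizeCSA(70, c(thalamus_volume = 15000, sex = 1), m2),
               "missing predictor 'brain_volume'")
  expect_error(normalizeCSA(70, c(thalamus_volume = 15000,
                                  brain_volume = 1e6, sex = 2), m2),
               "sex must be coded")
})

test_that("the suspect published C2-C3 sex coefficient warns on use", {
  m <- publishedModels("M2-C2C3")
  expect_warning(
    normalizeCSA(70, c(thalamus_volume = 15266, brain_volume = 1156171,
                       sex = 1), m),
    "as published")
})

test_that("z-scores follow the printed mu and sigma", {
  m1 <- publishedModels("M1-PMJ")
  expect_identical(csaZScore(66.26, m1), 0)
  expect_equal(csaZScore(72, m1), (72 - 66.26) / 5.72, tolerance = 1e-12)
  mC <- publishedModels("M1-C2C3")
  expect_equal(csaZScore(66.40 - 5.64, mC), -1, tolerance = 1e-12)
})

test_that("covPercent matches hand arithmetic", {
  expect_identical(covPercent(rep(7, 10)), 0)
  expect_equal(covPercent(c(60, 70)), 100 * sd(c(60, 70)) / 65,
               tolerance = 1e-12)
  expect_equal(covPercent(c(60, 70)), 10.8786, tolerance = 1e-4)
  # the published cohort scale: mean 66.2, STD 6.69 -> ~ 10.1%
  expect_equal(100 * 6.69 / 66.2, 10.105, tolerance = 1e-3)
  expect_error(covPercent(c(-1, 1)), "mean is zero")
  expect_error(covPercent(5), "at least 2")
})

test_that("refitting on a noiseless cohort recovers the slopes exactly", {
  co <- makeCohort(cohortSpec(n = 60, seed = 8, noise_sd = 0,
                              true_coefficients = c(intercept = 27.18,
                                                    thalamus_volume = 1.99e-3,
                                                    brain_volume = 7.56e-6)))
  fit <- suppressWarnings(   # lm flags the perfect fit
    fitResidualModel(co, c("thalamus_volume", "brain_volume")))
  expect_equal(modelCoefficients(fit$model)[["thalamus_volume"]], 1.99e-3,
               tolerance = 1e-10)
  expect_equal(modelCoefficients(fit$model)[["brain_volume"]], 7.56e-6,
               tolerance = 1e-10)
  expect_equal(fit$report$r_squared, 1, tolerance = 1e-10)
})

test_that("residualization identities hold on a refit cohort", {
  co <- makeCohort(cohortSpec(n = 804, seed = 31))
  fit <- fitResidualModel(co, c("thalamus_volume", "brain_volume"))
  normed <- normalizeCSA(co$csa, co, fit$model)

  expect_lt(abs(mean(normed) - mean(co$csa)), 1e-6)
  expect_lt(abs(sd(normed) / sd(co$csa) - sqrt(1 - fit$report$r_squared)),
            1e-3)
  z <- csaZScore(normed, fit$model)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  # COV reduction ratio equals sqrt(1 - R^2): means are preserved
  expect_lt(abs(covPercent(normed) / covPercent(co$csa) -
                sqrt(1 - fit$report$r_squared)), 1e-3)
})

test_that("refit slopes sit within 2 SE of the generative truth", {
  co <- makeCohort(cohortSpec(n = 804, seed = 77))
  fit <- fitResidualModel(co, c("thalamus_volume", "brain_volume"))
  gen <- attr(co, "generative")
  se <- fit$report$coefficients
  for (term in c("thalamus_volume", "brain_volume")) {
    row <- which(se$term == term)
    est <- se$coef[row]
    sehat <- abs(est / se$t[row])
    expect_lt(abs(est - gen$beta[[term]]) / sehat, 2.5)
  }
})

test_that("rank-deficient designs are reported with the collinear term", {
  co <- makeCohort(cohortSpec(n = 100, seed = 2))
  co$dup <- co$brain_volume
  expect_error(fitResidualModel(co, c("brain_volume", "dup")),
               "collinear")
})

test_that("fitResidualModel applies listwise deletion", {
  co <- makeCohort(cohortSpec(n = 120, seed = 13))
  co$brain_volume[c(5, 50)] <- NA
  expect_message(fit <- fitResidualModel(co, c("thalamus_volume",
                                               "brain_volume")),
                 "dropping 2")
  expect_identical(fit$report$n, 118L)
})

test_that("stepwise selection behaves as constructed", {
  # only thalamus truly predicts; brain/height are independent noise
  coA <- makeCohort(cohortSpec(
    n = 400, seed = 6,
    predictor_means = c(thalamus_volume = 15266, brain_volume = 1156171,
                        height = 170),
    predictor_sds = c(thalamus_volume = 1500, brain_volume = 110000,
                      height = 9),
    predictor_correlations = diag(3) |>
      (\(m) { dimnames(m) <- rep(list(c("thalamus_volume", "brain_volume",
                                        "height")), 2); m })(),
    sex_correlations = c(thalamus_volume = 0, brain_volume = 0, height = 0),
    true_coefficients = c(intercept = 35, thalamus_volume = 2e-3),
    noise_sd = 3))
  swA <- stepwiseSelect(coA, c("thalamus_volume", "brain_volume", "height"))
  expect_identical(swA$selected, "thalamus_volume")

  # pure noise: nothing enters
  coB <- coA
  set.seed(17)
  coB$csa <- rnorm(nrow(coB), 66, 6)
  swB <- stepwiseSelect(coB, c("thalamus_volume", "brain_volume", "height"))
  expect_identical(swB$selected, character(0))
  expect_true(all(swB$trace$action == "reject"))

  # collinear thalamus + brain with real effects: both retained
  coC <- makeCohort(cohortSpec(n = 804, seed = 41))
  swC <- stepwiseSelect(coC, c("thalamus_volume", "brain_volume", "sex"))
  expect_true(all(c("thalamus_volume", "brain_volume") %in% swC$selected))
})

test_that("stepwise selection ignores candidate column order", {
  co <- makeCohort(cohortSpec(n = 804, seed = 51))
  cand <- c("thalamus_volume", "brain_volume", "sex")
  a <- stepwiseSelect(co, cand)
  b <- stepwiseSelect(co, rev(cand))
  expect_setequal(a$selected, b$selected)
})

test_that("cohort statistics report correlations, sex test and age fits", {
  co <- makeCohort(cohortSpec(n = 804, seed = 5))
  co$dup <- co$csa
  st <- cohortStatistics(co)
  expect_equal(st$correlations$r["csa", "dup"], 1)
  expect_lt(abs(st$correlations$r["sex", "brain_volume"] - 0.49), 0.09)
  expect_false(is.null(st$sex_ttest))

  # quadratic fit recovery on the printed age equation, noiseless
  age <- seq(48, 80, length.out = 200)
  coAge <- data.frame(age = age,
                      csa = 72.93 - 0.0469 * age - 0.000907 * age^2)
  stA <- suppressWarnings(cohortStatistics(coAge))  # perfect-fit warning
  expect_equal(stA$age_fits$quadratic$coefficients,
               c(72.93, -0.0469, -0.000907), tolerance = 1e-8)
  expect_equal(stA$age_fits$quadratic$r_squared, 1, tolerance = 1e-10)
})

test_that("model JSON round-trips", {
  fit <- fitResidualModel(makeCohort(cohortSpec(n = 200, seed = 9)),
                          c("thalamus_volume", "brain_volume", "sex",
                            "sex:brain_volume"))
  f <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(fit$model, f)
  back <- readModelJSON(f)
  expect_equal(modelCoefficients(back), modelCoefficients(fit$model))
  expect_equal(modelMeans(back), modelMeans(fit$model))
  expect_identical(back@reference, fit$model@reference)
})
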