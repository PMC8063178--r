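test_that("control folding averages complementary eye conditions", {
  lv <- c(0, 6, 24)
  m <- matrix(1:9, 3, 3, dimnames = list(lv, lv))
  crf <- assembleCrf(m, lv, mode = "control-fold")
  expect_equal(crf@values, unname((m + t(m)) / 2))
  expect_identical(targetEye(crf), "either")
  # a symmetric matrix is unchanged by folding
  sym <- (m + t(m)) / 2
  expect_equal(assembleCrf(sym, lv, mode = "control-fold")@values, unname(sym))
  mNA <- m; mNA[2, 2] <- NA
  expect_error(assembleCrf(mNA, lv), "missing cells")
})

test_that("patient role views hold identical numbers, re-ordered", {
  lv <- c(0, 6, 24)
  m <- matrix(rnorm(9), 3, 3, dimnames = list(lv, lv))
  fel <- assembleCrf(m, lv, mode = "patient-roles", amblyopicEye = "left",
                     targetRole = "fellow")
  amb <- assembleCrf(m, lv, mode = "patient-roles", amblyopicEye = "left",
                     targetRole = "amblyopic")
  expect_equal(sort(as.numeric(fel@values)), sort(as.numeric(amb@values)))
  expect_equal(fel@values, t(amb@values))
  # amblyopic eye = left means the amblyopic-target view is the raw grid
  expect_equal(amb@values, unname(m))
  # role swap is involutive
  expect_equal(swapRoles(swapRoles(fel))@values, fel@values)
  expect_identical(swapRoles(fel)@targetEye, "amblyopic")
})

test_that("a tonic left-eye cohort shows the attenuated monocular column", {
  p <- applyVariant(modelParams(), "tonic", 0.6, "left")
  cohort <- modelCohort(p, nSubj = 6, sigma = 0.05, seed = 3)
  # rows = left (amblyopic) target: its monocular CRF sits below the
  # fellow-target column at every nonzero contrast
  mn <- Reduce(`+`, lapply(cohort, function(x) x@values)) / length(cohort)
  ambCol <- mn[-1, 1]   # left eye targets, right eye blank
  felCol <- mn[1, -1]   # right eye targets, left eye blank
  expect_true(all(ambCol < felCol))
})

test_that("suppression contrast handles identities and degenerate input", {
  lv <- c(0, 6, 24, 48, 96)
  mk <- function(v) new("CRFMatrix", values = v, levels = lv,
                        targetEye = "left", modality = "model",
                        dispersion = matrix(numeric(0), 0, 0))
  flat <- lapply(1:5, function(i) mk(matrix(1, 5, 5)))
  s <- suppressionContrast(flat)
  expect_equal(s$t, 0); expect_equal(s$d, 0); expect_false(s$degenerate)
  # constant positive delta with zero variance is flagged
  v <- matrix(1, 5, 5); v[1, 5] <- 2
  expect_warning(sc <- suppressionContrast(lapply(1:4, function(i) mk(v))),
                 "zero-variance")
  expect_true(sc$degenerate)
  expect_equal(sc$mean_delta, 1)
})

test_that("suppression statistics match a paired t-test oracle", {
  p <- applyVariant(modelParams(), "dynamic", 3, "left")
  cohort <- modelCohort(p, nSubj = 9, sigma = 0.1, seed = 5)
  s <- suppressionContrast(cohort, lowLevel = 6)
  tt <- t.test(s$delta)   # independent route to the same statistic
  expect_equal(s$t, unname(tt$statistic))
  expect_equal(s$p, tt$p.value)
  expect_equal(s$d, mean(s$delta) / sd(s$delta))
})

test_that("asymmetric dynamic suppression is larger for the fellow-eye mask", {
  # weaker (left) eye suppresses the dominant eye more strongly; the dip
  # measured with the mask in the weaker eye (fellow-eye targets) exceeds
  # the reverse arrangement
  p <- applyVariant(modelParams(), "dynamic", 3, "left")
  cohort <- modelCohort(p, nSubj = 8, sigma = 0.05, seed = 7)
  # rows = left (weaker) targets, so the 96% mask sits in the fellow eye
  # and is suppressed strongly by the weaker-eye target
  dFellowMask <- suppressionContrast(cohort)$mean_delta
  # swapped view: mask in the weaker eye, suppressed only weakly
  dAmbMask <- suppressionContrast(lapply(cohort, swapRoles))$mean_delta
  expect_gt(dFellowMask, dAmbMask)
})

test_that("repeated-measures ANOVA matches a hand-computed oracle", {
  # 3 participants x 2 x 2 grid, computed by explicit sum-of-squares
  # decomposition (independent of aov)
  lv <- c(0, 96)
  set.seed(21)
  arr <- array(rnorm(12, mean = rep(c(1, 2, 1.5, 3), each = 3)), c(3, 2, 2))
  crfs <- lapply(1:3, function(s) new("CRFMatrix", values = arr[s, , ],
    levels = lv, targetEye = "left", modality = "model",
    dispersion = matrix(numeric(0), 0, 0)))
  res <- crfAnova(crfs)

  gm <- mean(arr)
  ssTot <- sum((arr - gm)^2)
  mSubj <- apply(arr, 1, mean); mT <- apply(arr, 2, mean); mM <- apply(arr, 3, mean)
  ssT <- 6 * sum((mT - gm)^2)          # 3 subj x 2 mask levels per target
  ssM <- 6 * sum((mM - gm)^2)
  mTM <- apply(arr, c(2, 3), mean)
  ssTM <- 3 * sum((mTM - outer(mT - gm, mM - gm, "+") - gm)^2)
  mST <- apply(arr, c(1, 2), mean)
  ssST <- 2 * sum((mST - outer(mSubj - gm, mT - gm, "+") - gm)^2)
  mSM <- apply(arr, c(1, 3), mean)
  ssSM <- 2 * sum((mSM - outer(mSubj - gm, mM - gm, "+") - gm)^2)
  ssS <- 4 * sum((mSubj - gm)^2)
  ssSTM <- ssTot - ssS - ssT - ssM - ssTM - ssST - ssSM

  FT <- (ssT / 1) / (ssST / 2)
  FM <- (ssM / 1) / (ssSM / 2)
  FI <- (ssTM / 1) / (ssSTM / 2)
  expect_equal(res$F, c(FT, FM, FI), tolerance = 1e-9)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(2, 2, 2))
  omega <- function(ssE, dfE, msErr) (ssE - dfE * msErr) / (ssTot + msErr)
  expect_equal(res$omega_sq,
               c(omega(ssT, 1, ssST / 2), omega(ssM, 1, ssSM / 2),
                 omega(ssTM, 1, ssSTM / 2)), tolerance = 1e-9)
})

test_that("ANOVA nulls land where they are constructed to land", {
  lv <- c(0, 6, 24, 48, 96)
  # response depends only on the target level: mask effect ~ null
  set.seed(31)
  crfs <- lapply(1:8, function(s) {
    v <- matrix(rep(c(0, 1, 2, 3, 4), 5), 5, 5) + rnorm(25, sd = 0.3)
    new("CRFMatrix", values = v, levels = lv, targetEye = "left",
        modality = "model", dispersion = matrix(numeric(0), 0, 0))
  })
  res <- crfAnova(crfs)
  expect_gt(res$F[1], 50)
  expect_lt(res$F[2], 3)
  expect_lt(res$omega_sq[2], 0.05)
  # pure-noise cohorts: omega^2 near zero on average
  om <- replicate(10, {
    crfsN <- lapply(1:6, function(s) new("CRFMatrix",
      values = matrix(rnorm(25), 5, 5), levels = lv, targetEye = "left",
      modality = "model", dispersion = matrix(numeric(0), 0, 0)))
    mean(crfAnova(crfsN)$omega_sq)
  })
  expect_lt(abs(mean(om)), 0.03)
})

test_that("ANOVA degrees of freedom follow the 5-level within design", {
  p <- modelParams()
  cohort <- modelCohort(p, nSubj = 12, sigma = 0.2, seed = 11)
  res <- crfAnova(cohort)
  expect_equal(res$df1, c(4, 4, 16))
  expect_equal(res$df2, c(44, 44, 176))
  expect_true(all(res$p[1:2] < 0.001))
})

test_that("model fitting is invariant to global data rescaling", {
  p <- modelParams()
  m <- crfValues(predictCrfMatrix(p))
  set.seed(2)
  m <- m + matrix(rnorm(25, sd = 0.02), 5, 5)
  rownames(m) <- colnames(m) <- crfLevelsDefault
  f1 <- fitModelToCrf(m, variants = "baseline", seed = 1)
  f2 <- fitModelToCrf(m * 100, variants = "baseline", seed = 1)
  expect_equal(attr(f1, "ranking"), attr(f2, "ranking"))
  expect_equal(f2$baseline$params@responseGain /
               f1$baseline$params@responseGain, 100, tolerance = 0.05)
  expect_equal(f2$baseline$rss / f1$baseline$rss, 1e4, tolerance = 0.05)
})

test_that("the generating variant wins model selection at low noise", {
  p0 <- modelParams()
  regimes <- list(
    baseline = p0,
    tonic = applyVariant(p0, "tonic", 0.6, "left"),
    dynamic = applyVariant(p0, "dynamic", 3, "left"))
  for (regime in names(regimes)) {
    wins <- 0
    for (s in 1:5) {
      m <- crfValues(predictCrfMatrix(regimes[[regime]]))
      set.seed(s * 7)
      m <- m + matrix(rnorm(25, sd = 0.05), 5, 5)
      rownames(m) <- crfLevelsDefault
      f <- fitModelToCrf(m, seed = s)
      if (attr(f, "ranking")[1] == regime) wins <- wins + 1
    }
    expect_gt(wins, 2.5)  # majority of seeds
  }
})

test_that("CRF matrices and parameter sets round-trip through text files", {
  p <- applyVariant(modelParams(), "tonic", 0.73, "right")
  fp <- tempfile(fileext = ".yaml")
  writeModelParams(p, fp)
  back <- readModelParams(fp)
  for (sl in slotNames(p)) expect_equal(slot(back, sl), slot(p, sl))
  unlink(fp)

  crf <- predictCrfMatrix(modelParams(), crfLevelsDefault)
  fc <- tempfile(fileext = ".tsv")
  writeCrfMatrix(crf, fc)
  crf2 <- readCrfMatrix(fc)
  expect_equal(crf2@values, crf@values, tolerance = 1e-12)
  expect_equal(crfLevels(crf2), crfLevels(crf))
  expect_identical(targetEye(crf2), targetEye(crf))
  unlink(fc)
})
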