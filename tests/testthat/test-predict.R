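test_that("stratified splits are disjoint, exhaustive and reproducible", {
  lab <- setNames(rep(c("GA", "control"), c(156, 402)), sprintf("S%03d", 1:558))
  sp <- splitCohort(lab, counts = c(GA = 91, control = 244), seed = 1)
  expect_equal(length(sp$discovery), 335)
  expect_equal(sum(lab[sp$discovery] == "GA"), 91)
  expect_equal(sum(lab[sp$validation] == "GA"), 65)
  expect_length(intersect(sp$discovery, sp$validation), 0)
  expect_setequal(c(sp$discovery, sp$validation), names(lab))
  sp2 <- splitCohort(lab, counts = c(GA = 91, control = 244), seed = 1)
  expect_identical(sp, sp2)

  spf <- splitCohort(lab, fraction = 91 / 156, seed = 2)
  expect_equal(sum(lab[spf$discovery] == "GA"), 91)
  expect_error(splitCohort(setNames(rep("GA", 5), letters[1:5])), "classes")
})

test_that("ridge logistic scorer separates, nulls out, and splits duplicate weights", {
  withr::with_seed(91, {
    x <- matrix(c(runif(40, -3, -1), runif(40, 1, 3)), ncol = 1)
    colnames(x) <- "f1"
    y <- rep(c("control", "GA"), each = 40)
  })
  fit <- fitClassifier(x, y, lambda = 1, caseLevel = "GA")
  expect_equal(aucValue(rocAuc(predict(fit, x), y, caseLevel = "GA")), 1)

  # permuted labels give chance-level validation AUC in most seeds
  withr::with_seed(93, {
    ok <- 0
    for (s in 1:50) {
      xtr <- matrix(rnorm(60 * 3), 60, 3,
                    dimnames = list(NULL, paste0("f", 1:3)))
      ytr <- sample(rep(c("control", "GA"), 30))
      xte <- matrix(rnorm(60 * 3), 60, 3,
                    dimnames = list(NULL, paste0("f", 1:3)))
      yte <- sample(rep(c("control", "GA"), 30))
      fitN <- fitClassifier(xtr, ytr, caseLevel = "GA")
      a <- aucValue(rocAuc(predict(fitN, xte), yte, caseLevel = "GA"))
      ok <- ok + (a >= 0.35 && a <= 0.65)
    }
    expect_gte(ok, 45)
  })

  # duplicated feature: ridge symmetry splits the weight evenly
  withr::with_seed(95, {
    x1 <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "f"))
    y <- rep(c("control", "GA"), 25)
  })
  xd <- cbind(f = x1[, 1], f2 = x1[, 1])
  fitD <- fitClassifier(xd, y, lambda = 2, caseLevel = "GA")
  expect_equal(fitD$coefficients[["f"]], fitD$coefficients[["f2"]],
               tolerance = 1e-8)

  expect_warning(
    fitC <- fitClassifier(cbind(flat = rep(1, 50), x1), y, caseLevel = "GA"),
    "constant")
  expect_equal(fitC$features, "f")
})

test_that("ridge logistic coefficients agree with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  withr::with_seed(97, {
    n <- 200
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  })
  lam <- 3
  mine <- fitClassifier(X, ifelse(y == 1, "GA", "control"), lambda = lam,
                        caseLevel = "GA")
  # glmnet objective: -(1/n) loglik + lambda_g/2 ||beta||^2
  gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = c(5, 1, lam / n) , standardize = FALSE,
                         thresh = 1e-12)
  ref <- as.numeric(glmnet::coef.glmnet(gfit, s = lam / n, exact = TRUE,
                                        x = X, y = y))
  expect_equal(unname(mine$coefficients), ref, tolerance = 1e-3)
})

test_that("AUC equals exhaustive pairwise counting and its invariances hold", {
  r <- rocAuc(c(0.9, 0.4, 0.5, 0.3), c("GA", "GA", "control", "control"),
              caseLevel = "GA")
  expect_equal(aucValue(r), 0.75)  # 3 of 4 pairs concordant
  expect_equal(aucValue(rocAuc(c(1, 2, 3, 4), rep(c("a", "b"), 2),
                               caseLevel = "b")), 0.75)
  expect_equal(aucValue(rocAuc(rep(1, 10), rep(c("a", "b"), 5),
                               caseLevel = "b")), 0.5)

  withr::with_seed(99, {
    for (rep in 1:30) {
      n <- sample(6:30, 1)
      sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
      lab <- sample(c("case", "ctrl"), n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      mine <- aucValue(rocAuc(sc, lab, caseLevel = "case"))
      expect_equal(mine, auc_bruteforce(sc, lab, "case"), tolerance = 1e-12)
      # monotone transform invariance
      expect_equal(aucValue(rocAuc(exp(3 * sc), lab, caseLevel = "case")),
                   mine, tolerance = 1e-12)
      # label swap
      expect_equal(aucValue(rocAuc(sc, lab, caseLevel = "ctrl")), 1 - mine,
                   tolerance = 1e-12)
    }
  })
  # the ROC curve is monotone
  cv <- rocCurve(r)
  expect_true(all(diff(cv$sensitivity) >= 0))
  expect_true(all(diff(cv$specificity) <= 0))
  expect_error(rocAuc(1:3, rep("a", 3)), "classes")
})

test_that("DeLong interval brackets the AUC and matches pROC and the bootstrap", {
  withr::with_seed(101, {
    sc <- c(rnorm(100), rnorm(100, 1))
    lab <- rep(c("control", "GA"), each = 100)
  })
  res <- delongCi(sc, lab, caseLevel = "GA")
  expect_true(res@ciLower <= res@auc && res@auc <= res@ciUpper)

  skip_if_not_installed("pROC")
  ref <- pROC::ci.auc(pROC::roc(lab, sc, levels = c("control", "GA"),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(res@ciLower, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(res@auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(res@ciUpper, as.numeric(ref[3]), tolerance = 1e-10)

  # variance close to a bootstrap estimate on one fixed dataset
  delongVar <- ((res@ciUpper - res@auc) / qnorm(0.975))^2
  boot <- withr::with_seed(103, {
    vapply(1:2000, function(i) {
      idx1 <- sample(which(lab == "GA"), replace = TRUE)
      idx0 <- sample(which(lab == "control"), replace = TRUE)
      aucValue(rocAuc(c(sc[idx1], sc[idx0]),
                      rep(c("GA", "control"), c(100, 100)), caseLevel = "GA"))
    }, numeric(1))
  })
  expect_lt(abs(delongVar - var(boot)) / var(boot), 0.15)
})

test_that("feature-set evaluation ranks a planted CAG signal above noise clinics", {
  cfg <- synthConfig(nCase = 60, nControl = 140, nTaxa = 40, nBlocks = 4,
                     depthMean = 3000, seed = 5,
                     outcomeCoefficients = c("1" = 1.2),
                     clinicalSpec = transform(defaultClinicalSpec(), shift = 0),
                     differentialTaxa = data.frame(taxon = integer(0),
                                                   log2fc = numeric(0)))
  sim <- generateCommunity(cfg, timepoints = "T2")
  ev <- suppressWarnings(
    evaluateFeatureSets(sim$experiment, sets = c("clinical", "cag"), seed = 7,
                        topN = 40, kRange = 2:6, nPerm = 99))
  cagVal <- ev$auc[ev$set == "cag" & ev$split == "validation"]
  clinVal <- ev$auc[ev$set == "clinical" & ev$split == "validation"]
  expect_gt(cagVal, clinVal)
  expect_gt(cagVal, 0.6)
  expect_true(all(ev$ciLower <= ev$auc & ev$auc <= ev$ciUpper))

  # cag_plus_clinical contains the cag features by construction
  ev2 <- suppressWarnings(
    evaluateFeatureSets(sim$experiment,
                        sets = c("cag", "cag_plus_clinical"), seed = 7,
                        topN = 40, kRange = 2:6, nPerm = 99))
  expect_gte(ev2$nFeatures[ev2$set == "cag_plus_clinical"][1],
             ev2$nFeatures[ev2$set == "cag"][1])
})
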