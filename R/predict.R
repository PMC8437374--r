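# Discovery/validation splitting, ridge-logistic scoring and ROC/AUC
# with DeLong confidence intervals.

#' Stratified discovery/validation split
#'
#' Disjoint, exhaustive, class-stratified random split. Either a single
#' `fraction` (rounded per class) or exact per-class discovery counts
#' may be given; the study design used per-class counts (91/244 of
#' 156/402).
#'
#' @param labels Per-sample class labels (named vector, or unnamed with
#'   `ids` supplied).
#' @param fraction Discovery fraction (default 0.6).
#' @param counts Optional named vector of exact discovery counts per
#'   class (overrides `fraction`).
#' @param seed Integer seed.
#' @param ids Sample identifiers (default `names(labels)`).
#' @return List with `discovery` and `validation` id vectors.
#' @examples
#' lab <- setNames(rep(c("GA", "control"), c(156, 402)), sprintf("S%03d", 1:558))
#' sp <- splitCohort(lab, counts = c(GA = 91, control = 244), seed = 1)
#' lengths(sp)
#' @export
splitCohort <- function(labels, fraction = 0.6, counts = NULL, seed = NULL,
                        ids = names(labels)) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) < 2L) stop("both classes must be present")
  if (is.null(ids)) ids <- as.character(seq_along(f))
  sizes <- table(f)
  if (any(sizes < 2L)) stop("class too small to stratify")
  disc <- with_seed(seed, {
    unlist(lapply(levels(f), function(l) {
      pool <- ids[f == l]
      k <- if (!is.null(counts)) {
        if (!l %in% names(counts)) stop("no discovery count for class ", l)
        counts[[l]]
      } else {
        round(fraction * length(pool))
      }
      if (k < 1 || k >= length(pool)) {
        stop("discovery count for class ", l, " must leave both splits nonempty")
      }
      sample(pool, k)
    }), use.names = FALSE)
  })
  list(discovery = disc, validation = setdiff(ids, disc))
}

#' Fit a ridge-penalized logistic scoring model
#'
#' Logistic regression with an L2 penalty on the (non-intercept)
#' coefficients, fitted by iteratively reweighted least squares. The
#' penalty keeps correlated feature panels (e.g. CAG abundances) stable
#' and guarantees convergence under complete separation. Features are
#' expected standardized; constant features are dropped with a warning.
#'
#' @param x Samples x features numeric matrix.
#' @param y Two-level factor or 0/1 vector.
#' @param caseLevel The level scored as the positive (case) class;
#'   default: the second factor level. Always state it explicitly for
#'   character labels — factor level order is locale-dependent.
#' @param lambda Ridge penalty on the objective
#'   \eqn{-\ell(\beta) + \lambda \|\beta\|^2 / 2} (default 1).
#' @param maxit,tol IRLS controls.
#' @return Object of class `ridgeLogistic` with `coefficients`,
#'   `features`, `lambda`; score new samples with `predict()` (returns
#'   the linear predictor).
#' @export
fitClassifier <- function(x, y, lambda = 1, caseLevel = NULL, maxit = 200,
                          tol = 1e-10) {
  x <- as.matrix(x)
  f <- .as_two_groups(y)
  if (!is.null(caseLevel)) {
    if (!caseLevel %in% levels(f)) stop("caseLevel not found in labels")
    f <- factor(f, levels = c(setdiff(levels(f), caseLevel), caseLevel))
  }
  yb <- as.numeric(f) - 1
  if (min(table(yb)) < 2L) stop("need >= 2 samples per class")
  constant <- apply(x, 2L, function(v) sd(v) == 0)
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  if (!ncol(x)) stop("no usable features")
  X <- cbind(`(Intercept)` = 1, x)
  pn <- ncol(X)
  R <- diag(c(0, rep(lambda, pn - 1L)))  # intercept unpenalized
  beta <- rep(0, pn)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, yb - mu) - R %*% beta
    H <- crossprod(X * w, X) + R
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol * max(1, max(abs(beta)))) break
  }
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 features = colnames(x), lambda = lambda),
            class = "ridgeLogistic")
}

#' @rdname fitClassifier
#' @param object A fitted `ridgeLogistic` model.
#' @param newdata Samples x features matrix containing `object$features`.
#' @param ... Unused.
#' @export
predict.ridgeLogistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  X <- cbind(1, newdata[, object$features, drop = FALSE])
  drop(X %*% object$coefficients)
}

#' @export
print.ridgeLogistic <- function(x, ...) {
  cat("ridgeLogistic:", length(x$features), "features, lambda =", x$lambda, "\n")
  invisible(x)
}

.split_scores <- function(scores, labels, caseLevel) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop("both classes must be present")
  if (is.null(caseLevel)) caseLevel <- levels(f)[2L]
  if (!caseLevel %in% levels(f)) stop("caseLevel not found in labels")
  list(cases = scores[f == caseLevel], controls = scores[f != caseLevel])
}

#' ROC curve and AUC (pairwise definition)
#'
#' AUC by the Mann-Whitney pairwise definition,
#' \eqn{(\#\{s_{case} > s_{control}\} + \frac{1}{2}\#ties) /
#' (n_{case} n_{control})}, computed via midranks; the curve enumerates
#' the sorted unique thresholds.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Two-level labels.
#' @param caseLevel Which level is the case class (default: the second
#'   factor level).
#' @return A [RocResult-class] without a confidence interval.
#' @examples
#' aucValue(rocAuc(c(0.9, 0.4, 0.5, 0.3), c("GA", "GA", "control", "control"),
#'                 caseLevel = "GA"))  # 0.75
#' @export
rocAuc <- function(scores, labels, caseLevel = NULL) {
  sp <- .split_scores(scores, labels, caseLevel)
  n1 <- length(sp$cases); n0 <- length(sp$controls)
  r <- rank(c(sp$cases, sp$controls))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(sp$cases >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(sp$controls < t), numeric(1)))
  new("RocResult", auc = auc, ciLower = NA_real_, ciUpper = NA_real_,
      curve = curve, nCases = n1, nControls = n0, method = "none")
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance from DeLong's placement values,
#' \eqn{V = var(V_{10})/n_1 + var(V_{01})/n_0}, with a normal
#' approximation CI truncated to `[0, 1]`. A degenerate variance (AUC
#' exactly 0 or 1) collapses the interval with a warning.
#'
#' @inheritParams rocAuc
#' @param level Confidence level (default 0.95).
#' @return A [RocResult-class] with CI.
#' @export
delongCi <- function(scores, labels, level = 0.95, caseLevel = NULL) {
  roc <- rocAuc(scores, labels, caseLevel)
  sp <- .split_scores(scores, labels, caseLevel)
  n1 <- length(sp$cases); n0 <- length(sp$controls)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 per class for a DeLong CI")
  v10 <- vapply(sp$cases, function(s) {
    (sum(sp$controls < s) + 0.5 * sum(sp$controls == s)) / n0
  }, numeric(1))
  v01 <- vapply(sp$controls, function(s) {
    (sum(sp$cases > s) + 0.5 * sum(sp$cases == s)) / n1
  }, numeric(1))
  v <- var(v10) / n1 + var(v01) / n0
  if (v <= 0) {
    warning("degenerate DeLong variance; interval collapses to the point AUC")
    v <- 0
  }
  z <- qnorm(1 - (1 - level) / 2)
  lo <- max(0, roc@auc - z * sqrt(v))
  hi <- min(1, roc@auc + z * sqrt(v))
  methods::initialize(roc, ciLower = lo, ciUpper = hi, method = "DeLong")
}

# standardize columns by discovery parameters
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, "/"))
}

#' Evaluate the five feature sets on a discovery/validation split
#'
#' Assembles the study's candidate feature panels — clinical indices,
#' covariate-adjusted significant genera, LEfSe-retained genera, CAG
#' abundances, and CAG plus clinical — from the discovery samples only
#' (feature selection, CAG clustering and standardization parameters
#' never see validation data), fits the ridge-logistic scorer on
#' discovery and reports ROC/AUC with DeLong CIs on both splits.
#'
#' @param x A [GuildExperiment-class] whose `colData` carries `group`,
#'   the covariates and the clinical indices; typically the T2 columns
#'   of a cohort (prediction uses pre-outcome profiles).
#' @param sets Which feature sets to evaluate.
#' @param seed Integer seed (split + any permutation streams).
#' @param discoveryFraction,discoveryCounts Passed to [splitCohort].
#' @param clinicalVars Clinical index columns (default
#'   [defaultClinicalSpec]'s names present in `colData`).
#' @param covariateVars Covariate columns for the adjusted models
#'   (default: the [defaultCovariateSpec] names present in `colData`).
#' @param topN,kRange,nPerm CAG clustering controls (see [clusterCags]).
#' @param fdr,ldaThreshold Differential-abundance thresholds.
#' @param lambda Ridge penalty for [fitClassifier].
#' @return `data.frame`: one row per (set, split) with `auc`, `ciLower`,
#'   `ciUpper`, `nFeatures`. Feature sets that come up empty are skipped
#'   with a warning.
#' @export
evaluateFeatureSets <- function(x,
    sets = c("clinical", "maaslin_genera", "lefse_genera", "cag",
             "cag_plus_clinical"),
    seed = 1L, discoveryFraction = 0.6, discoveryCounts = NULL,
    clinicalVars = NULL, covariateVars = NULL, topN = 99, kRange = 2:12,
    nPerm = 999, fdr = 0.05, ldaThreshold = 2, lambda = 1) {
  stopifnot(is(x, "GuildExperiment"))
  sets <- match.arg(sets, several.ok = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!"group" %in% colnames(cd)) stop("colData must have a 'group' column")
  labels <- setNames(as.character(cd$group), colnames(x))
  rel <- relAbundance(x)
  if (is.null(clinicalVars)) {
    clinicalVars <- intersect(defaultClinicalSpec()$name, colnames(cd))
  }
  if (is.null(covariateVars)) {
    covNames <- vapply(defaultCovariateSpec(), `[[`, character(1), "name")
    covariateVars <- intersect(covNames, colnames(cd))
  }
  sp <- splitCohort(labels, fraction = discoveryFraction,
                    counts = discoveryCounts,
                    seed = childSeed(seed, "split"))
  disc <- sp$discovery; val <- sp$validation

  featureMatrix <- function(set) {
    switch(set,
      clinical = {
        m <- as.matrix(cd[, clinicalVars, drop = FALSE])
        storage.mode(m) <- "double"
        m
      },
      maaslin_genera = {
        res <- adjustedLinearModels(rel[, disc, drop = FALSE], labels[disc],
                                    covariates = cd[disc, covariateVars,
                                                    drop = FALSE])
        hits <- res$taxon[res$q < fdr]
        if (!length(hits)) return(NULL)
        t(rel[hits, , drop = FALSE])
      },
      lefse_genera = {
        res <- lefseLite(rel[, disc, drop = FALSE], labels[disc], fdr = fdr,
                         ldaThreshold = ldaThreshold)
        hits <- res$taxon[res$retained]
        if (!length(hits)) return(NULL)
        t(rel[hits, , drop = FALSE])
      },
      cag = {
        discRel <- rel[, disc, drop = FALSE]
        keep <- selectTopTaxa(discRel, min(topN, nrow(discRel)))
        asg <- clusterCags(discRel[keep, , drop = FALSE], kRange = kRange,
                           nPerm = nPerm, seed = childSeed(seed, "permute"))
        t(cagAbundance(rel, asg))
      },
      cag_plus_clinical = {
        cagM <- if ("cag" %in% names(cache)) cache[["cag"]] else
          featureMatrix("cag")
        clinM <- featureMatrix("clinical")
        if (is.null(cagM)) NULL else cbind(cagM, clinM)
      })
  }

  rows <- list()
  cache <- list()
  for (set in sets) {
    m <- tryCatch(
      if (set %in% names(cache)) cache[[set]] else featureMatrix(set),
      error = function(e) { warning("feature set ", set, " failed: ",
                                    conditionMessage(e)); NULL })
    cache[[set]] <- m
    if (is.null(m) || !ncol(m)) {
      warning("feature set ", set, " is empty; skipped")
      next
    }
    rownames(m) <- colnames(x)
    std <- .standardize(m[disc, , drop = FALSE], m[val, , drop = FALSE])
    model <- fitClassifier(std$train, labels[disc], lambda = lambda,
                           caseLevel = "GA")
    for (split in c("discovery", "validation")) {
      idx <- if (split == "discovery") disc else val
      scr <- predict(model, if (split == "discovery") std$train else std$test)
      roc <- delongCi(scr, labels[idx], caseLevel = "GA")
      rows[[length(rows) + 1L]] <- data.frame(
        set = set, split = split, auc = roc@auc, ciLower = roc@ciLower,
        ciUpper = roc@ciUpper, nFeatures = length(model$features),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
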