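# Differential abundance: nonparametric screening with FDR control and a
# deterministic LDA effect size (LEfSe-style), plus covariate-adjusted
# linear-model confirmation (MaAsLin-style).

#' Kruskal-Wallis screening p-value per taxon
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation,
#' applied row-wise. Constant taxa get p = 1 with a warning (no rank
#' information).
#'
#' @param x Abundance matrix, taxa x samples.
#' @param labels Group labels (>= 2 groups).
#' @return Named numeric vector of raw p-values.
#' @export
kruskalPerTaxon <- function(x, labels) {
  .check_matrix(x, "table")
  f <- droplevels(as.factor(labels))
  if (nlevels(f) < 2L) stop("need at least 2 groups")
  constant <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant taxa assigned p = 1")
  }
  p <- rep(1, nrow(x))
  names(p) <- rownames(x)
  for (i in which(!constant)) {
    p[i] <- kruskal.test(x[i, ], f)$p.value
  }
  p
}

#' Benjamini-Hochberg step-up q-values
#'
#' Validated wrapper over `p.adjust(method = "BH")`; enforces input in
#' `[0, 1]` and preserves names and order.
#'
#' @param p Raw p-values.
#' @return Adjusted q-values.
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Deterministic LDA effect size per taxon
#'
#' A reproducible single-feature variant of the LEfSe effect size: each
#' taxon's relative abundance is rescaled to the conventional
#' per-million scale, projected on the (trivially one-dimensional,
#' unit-norm) linear discriminant between the two groups, and the score
#' is `log10` of the projected between-class mean difference, floored at
#' magnitude 1 so scores land on the familiar ~[0, 6] scale. The sign
#' marks the enriched group: positive when enriched in the first factor
#' level. No bootstrap subsampling is performed, so results are exactly
#' reproducible; within-class variances are floored at `varFloor` when
#' standardizing the discriminant direction (logged via warning).
#'
#' @param x Relative-abundance matrix, taxa x samples.
#' @param labels Two-group factor.
#' @param taxa Taxa to score (default: all rows; typically the
#'   KW+FDR-screened set).
#' @param scale Abundance rescaling factor (LEfSe convention: 1e6).
#' @param varFloor Variance floor for degenerate within-class variance.
#' @return Named numeric vector of signed LDA scores (0 for no
#'   difference).
#' @export
ldaEffectSize <- function(x, labels, taxa = rownames(x), scale = 1e6,
                          varFloor = 1e-10) {
  .check_matrix(x, "table")
  f <- .as_two_groups(labels)
  g1 <- f == levels(f)[1L]
  missing <- setdiff(taxa, rownames(x))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  floored <- FALSE
  scores <- vapply(taxa, function(t) {
    v <- x[t, ] * scale
    m1 <- mean(v[g1]); m2 <- mean(v[!g1])
    s2 <- (var(v[g1]) * (sum(g1) - 1) + var(v[!g1]) * (sum(!g1) - 1)) /
      (length(v) - 2)
    if (s2 < varFloor) floored <<- TRUE
    delta <- m1 - m2
    if (delta == 0) return(0)
    sign(delta) * log10(max(abs(delta), 1))
  }, numeric(1))
  if (floored) warning("degenerate within-class variance floored for some taxa")
  scores
}

#' LEfSe-style differential abundance pipeline
#'
#' Kruskal-Wallis screening, Benjamini-Hochberg FDR across taxa (the
#' study applies FDR control at the screening stage), then the
#' deterministic LDA effect size; a taxon is retained iff
#' `q < fdr` and `|LDA| > ldaThreshold`.
#'
#' @param x Relative-abundance matrix (taxa x samples) or
#'   [GuildExperiment-class].
#' @param labels Two-group factor (for a `GuildExperiment`, taken from
#'   `colData(x)$group` when omitted).
#' @param fdr FDR threshold (default 0.05).
#' @param ldaThreshold Absolute LDA score threshold (default 2).
#' @param ... Unused.
#' @return `data.frame` with columns `taxon`, `p`, `q`, `lda`,
#'   `direction` (the enriched group, defined only for retained taxa),
#'   `retained`.
#' @name lefseLite
NULL

#' @rdname lefseLite
#' @export
setMethod("lefseLite", "matrix", function(x, labels, fdr = 0.05,
                                          ldaThreshold = 2, ...) {
  f <- .as_two_groups(labels)
  p <- kruskalPerTaxon(x, f)
  q <- benjaminiHochberg(p)
  screened <- names(p)[q < fdr]
  lda <- rep(0, length(p))
  names(lda) <- names(p)
  if (length(screened)) {
    lda[screened] <- ldaEffectSize(x, f, taxa = screened)
  }
  retained <- q < fdr & abs(lda) > ldaThreshold
  direction <- ifelse(retained, ifelse(lda > 0, levels(f)[1L], levels(f)[2L]),
                      NA_character_)
  data.frame(taxon = names(p), p = unname(p), q = unname(q),
             lda = unname(lda), direction = direction, retained = retained,
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname lefseLite
#' @export
setMethod("lefseLite", "GuildExperiment", function(x, labels, fdr = 0.05,
                                                   ldaThreshold = 2, ...) {
  if (missing(labels)) labels <- SummarizedExperiment::colData(x)$group
  lefseLite(relAbundance(x), labels, fdr = fdr, ldaThreshold = ldaThreshold)
})

# transform proportions for linear modelling
.transform_abundance <- function(x, transform) {
  switch(transform,
    "arcsine-sqrt" = asin(sqrt(pmin(pmax(x, 0), 1))),
    "log10" = {
      half_min <- min(x[x > 0]) / 2
      log10(x + half_min)
    },
    stop("unknown transform: ", transform))
}

#' Covariate-adjusted per-taxon linear models (MaAsLin-style)
#'
#' Per taxon, ordinary least squares of the transformed relative
#' abundance on group plus covariates; the group coefficient's t-test
#' p-value is BH-adjusted across taxa. The arcsine-square-root transform
#' is the classic default for proportions; `log10` with a half-minimum
#' pseudocount is available. Categorical covariates are dummy-encoded
#' against their first level.
#'
#' @param x Relative-abundance matrix (taxa x samples) or
#'   [GuildExperiment-class].
#' @param labels Two-group factor; the coefficient is for the second
#'   level vs the first.
#' @param covariates `data.frame` of per-sample covariates (rows aligned
#'   to samples).
#' @param transform `"arcsine-sqrt"` (default) or `"log10"`.
#' @param ... Unused.
#' @return `data.frame` with `taxon`, `effect` (group coefficient on the
#'   transformed scale), `p`, `q`, `direction`.
#' @name adjustedLinearModels
NULL

#' @rdname adjustedLinearModels
#' @export
setMethod("adjustedLinearModels", "matrix",
function(x, labels, covariates = NULL, transform = "arcsine-sqrt", ...) {
  .check_matrix(x, "table")
  f <- .as_two_groups(labels)
  n <- ncol(x)
  if (length(f) != n) stop("labels must match samples")
  df <- data.frame(.group = f)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per sample")
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
    df <- cbind(df, covariates)
  }
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(.transform_abundance(x, transform))
  fit <- lm.fit(X, Y)
  coefs <- fit$coefficients
  res <- Y - X %*% coefs
  dfRes <- n - ncol(X)
  if (dfRes < 1) stop("not enough samples for the covariate model")
  sigma2 <- colSums(res^2) / dfRes
  xtxInv <- solve(crossprod(X))
  gi <- 2L  # group coefficient: first column is the intercept
  se <- sqrt(sigma2 * xtxInv[gi, gi])
  tt <- coefs[gi, ] / se
  p <- 2 * pt(abs(tt), dfRes, lower.tail = FALSE)
  p[se == 0] <- 1
  q <- benjaminiHochberg(p)
  data.frame(taxon = rownames(x), effect = unname(coefs[gi, ]),
             p = unname(p), q = unname(q),
             direction = ifelse(coefs[gi, ] > 0, levels(f)[2L], levels(f)[1L]),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname adjustedLinearModels
#' @export
setMethod("adjustedLinearModels", "GuildExperiment",
function(x, labels, covariates = NULL, transform = "arcsine-sqrt", ...) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (missing(labels)) labels <- cd$group
  adjustedLinearModels(relAbundance(x), labels, covariates, transform)
})
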