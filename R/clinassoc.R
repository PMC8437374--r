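# Covariate-adjusted clinical-index comparisons and taxon-clinical
# correlation structure.

#' Covariate-adjusted group differences in clinical indices
#'
#' Per index, a least-squares fit of the index on group plus covariates
#' over complete cases; the group coefficient's t-test p-value is
#' BH-adjusted across indices. Constant covariate columns are dropped
#' with a warning.
#'
#' @param clinical `data.frame` or matrix of continuous indices, one row
#'   per sample.
#' @param group Two-level factor.
#' @param covariates Optional per-sample covariate `data.frame`.
#' @return `data.frame` with `index`, `coefficient` (second group level
#'   vs first), `p`, `q`, `nUsed`.
#' @export
adjustedIndexDifference <- function(clinical, group, covariates = NULL) {
  clinical <- as.data.frame(clinical)
  f <- .as_two_groups(group)
  n <- nrow(clinical)
  if (length(f) != n) stop("group must match clinical rows")
  df <- data.frame(.group = f)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
    constant <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                       logical(1))
    if (any(constant)) {
      warning("dropping constant covariate(s): ",
              paste(colnames(covariates)[constant], collapse = ", "))
      covariates <- covariates[, !constant, drop = FALSE]
    }
    df <- cbind(df, covariates)
  }
  rows <- lapply(colnames(clinical), function(ix) {
    d <- cbind(.y = clinical[[ix]], df)
    cc <- complete.cases(d)
    d <- d[cc, , drop = FALSE]
    if (nrow(d) < ncol(df) + 2L) stop("too few complete cases for index ", ix)
    X <- model.matrix(~ ., data = d[-1L])
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient covariate matrix for index ", ix)
    }
    fit <- lm(d$.y ~ X - 1)
    sm <- summary(fit)$coefficients
    gi <- grep("^X\\.group", rownames(sm))
    data.frame(index = ix, coefficient = sm[gi, 1], p = sm[gi, 4],
               nUsed = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjaminiHochberg(out$p)
  rownames(out) <- NULL
  out[, c("index", "coefficient", "p", "q", "nUsed")]
}

# rank-residualize: ranks regressed on covariate model matrix
.rank_residuals <- function(v, X) {
  r <- rank(v)
  if (is.null(X)) return(r - mean(r))
  lm.fit(X, r)$residuals
}

#' Partial Spearman correlation between taxa and clinical indices
#'
#' Every variable — taxa, indices and numeric covariates alike — is
#' rank-transformed; the taxon and index ranks are residualized on the
#' covariate ranks (factors dummy-encoded) by least squares, and the
#' Pearson correlation of the residuals is the partial Spearman
#' coefficient. P-values use the t
#' approximation with `n - 2 - #covariate-columns` degrees of freedom;
#' BH adjustment is applied jointly across the whole taxa x indices
#' grid. With no covariates this reduces exactly to ordinary Spearman
#' correlation.
#'
#' @param taxa Taxa x samples abundance matrix.
#' @param clinical `data.frame`/matrix of indices, one row per sample.
#' @param covariates Optional per-sample covariate `data.frame`.
#' @return List of taxa x indices matrices: `rho`, `p`, `q`.
#' @export
partialSpearman <- function(taxa, clinical, covariates = NULL) {
  .check_matrix(taxa, "taxa table")
  clinical <- as.data.frame(clinical)
  n <- ncol(taxa)
  if (nrow(clinical) != n) stop("clinical rows must match samples")
  nCov <- 0L
  X <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
    num <- vapply(covariates, is.numeric, logical(1))
    covariates[num] <- lapply(covariates[num], rank)
    X <- model.matrix(~ ., data = covariates)
    nCov <- ncol(X) - 1L
  }
  dfT <- n - 2L - nCov
  if (dfT < 1L) stop("too few samples for ", nCov, " covariate columns")
  RT <- t(vapply(seq_len(nrow(taxa)),
                 function(i) .rank_residuals(taxa[i, ], X), numeric(n)))
  RC <- vapply(seq_along(clinical),
               function(j) .rank_residuals(clinical[[j]], X), numeric(n))
  rho <- cor(t(RT), RC)
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt(dfT / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), dfT, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  q <- matrix(benjaminiHochberg(as.vector(p)), nrow(p), ncol(p))
  dimnames(rho) <- dimnames(p) <- dimnames(q) <-
    list(rownames(taxa), colnames(clinical))
  list(rho = rho, p = p, q = q)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a binary variable (0/1 encoded) and a
#' continuous variable, with the usual t-transform p-value.
#'
#' @param labels Two-level factor or 0/1 vector; both classes must be
#'   present.
#' @param values Continuous vector.
#' @return List with `r` and `p`.
#' @examples
#' pointBiserial(c(0, 0, 1, 1), c(1, 2, 3, 4))  # r = 2/sqrt(5)
#' @export
pointBiserial <- function(labels, values) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop("both classes must be present")
  y <- as.numeric(f) - 1
  if (sd(values) == 0) return(list(r = 0, p = 1))
  r <- cor(y, values)
  n <- length(y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- if (abs(r) >= 1) 0 else 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

#' Two-layer significant-edge export (Sankey-ready)
#'
#' Builds the taxon -> index -> outcome edge list, keeping only edges
#' with `q < fdr` on each layer and preserving signs.
#'
#' @param taxonResults `data.frame` of differential-abundance results
#'   with columns `taxon` and `q` (and optionally `lda`/`effect` for the
#'   sign) — the taxa eligible for the first layer.
#' @param taxonIndex Result of [partialSpearman] (list with `rho`, `q`).
#' @param indexOutcome `data.frame` with columns `index`, `r` (or
#'   `coefficient`) and `q` for the index-outcome layer (e.g. from
#'   [pointBiserial] per index, BH-adjusted).
#' @param fdr FDR threshold applied to every layer.
#' @return `data.frame` with `source`, `target`, `value`, `q`, `sign`,
#'   `layer`.
#' @export
sankeyEdges <- function(taxonResults, taxonIndex, indexOutcome, fdr = 0.05) {
  stopifnot(all(c("taxon", "q") %in% colnames(taxonResults)),
            all(c("rho", "q") %in% names(taxonIndex)),
            all(c("index", "q") %in% colnames(indexOutcome)))
  vcol <- intersect(c("r", "coefficient"), colnames(indexOutcome))[1]
  keepTaxa <- taxonResults$taxon[taxonResults$q < fdr]
  keepTaxa <- intersect(keepTaxa, rownames(taxonIndex$rho))
  edges <- list()
  for (tx in keepTaxa) {
    sig <- which(taxonIndex$q[tx, ] < fdr)
    for (ix in names(sig)) {
      v <- taxonIndex$rho[tx, ix]
      edges[[length(edges) + 1L]] <- data.frame(
        source = tx, target = ix, value = v, q = taxonIndex$q[tx, ix],
        sign = ifelse(v > 0, "+", "-"), layer = "taxon-index",
        stringsAsFactors = FALSE)
    }
  }
  sigIdx <- indexOutcome[indexOutcome$q < fdr, , drop = FALSE]
  usedIdx <- unique(vapply(edges, function(e) e$target, character(1)))
  for (ri in seq_len(nrow(sigIdx))) {
    if (!sigIdx$index[ri] %in% usedIdx) next
    v <- sigIdx[[vcol]][ri]
    edges[[length(edges) + 1L]] <- data.frame(
      source = sigIdx$index[ri], target = "outcome", value = v,
      q = sigIdx$q[ri], sign = ifelse(v > 0, "+", "-"),
      layer = "index-outcome", stringsAsFactors = FALSE)
  }
  if (!length(edges)) {
    return(data.frame(source = character(0), target = character(0),
                      value = numeric(0), q = numeric(0), sign = character(0),
                      layer = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
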