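#' @include AllGenerics.R
NULL

#' GuildExperiment: genus-level counts with sample metadata
#'
#' The central data container of the package: a
#' [SummarizedExperiment::SummarizedExperiment] whose `"counts"` assay
#' holds a non-negative taxa x samples matrix, whose `colData` carries the
#' sample metadata (group, timepoint, covariates, clinical indices), and
#' whose `metadata()` list may carry a phylogenetic tree (`$tree`, an
#' [ape::phylo]) and, for synthetic cohorts, the generative ground truth
#' (`$truth`).
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @export
setClass("GuildExperiment", contains = "SummarizedExperiment")

setValidity("GuildExperiment", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("counts" %in% a)) return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (!is.numeric(m)) return("'counts' must be numeric")
  if (anyNA(m)) return("'counts' must not contain NA")
  if (any(m < 0)) return("'counts' must be non-negative")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("taxon rownames and sample colnames are required")
  if (anyDuplicated(rownames(object))) return("duplicated taxon identifiers")
  if (anyDuplicated(colnames(object))) return("duplicated sample identifiers")
  TRUE
})

#' Construct a GuildExperiment
#'
#' @param counts Non-negative numeric matrix, taxa in rows, samples in
#'   columns, with unique dimnames.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata,
#'   one row per column of `counts` (matched by rownames when present).
#' @param tree Optional rooted [ape::phylo] whose tip labels cover the
#'   taxa (used by [uniFrac]).
#' @param truth Optional list of generative ground truth (see
#'   [generateCommunity]).
#' @return A [GuildExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ge <- GuildExperiment(m, data.frame(group = c("GA", "control"), row.names = colnames(m)))
#' ge
#' @export
GuildExperiment <- function(counts, sampleData = NULL, tree = NULL, truth = NULL) {
  .check_matrix(counts, "counts")
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if (!is.null(rownames(sampleData))) {
      miss <- setdiff(colnames(counts), rownames(sampleData))
      if (length(miss)) stop("samples missing from sampleData: ",
                             paste(miss, collapse = ", "))
      sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
  }
  md <- list()
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
    md$tree <- tree
  }
  if (!is.null(truth)) md$truth <- truth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData, metadata = md
  )
  new("GuildExperiment", se)
}

setMethod("show", "GuildExperiment", function(object) {
  cat("GuildExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd)) {
    cat("  groups:", paste(sprintf("%s=%d", names(table(cd$group)),
                                   as.integer(table(cd$group))),
                           collapse = ", "), "\n")
  }
  if (!is.null(S4Vectors::metadata(object)$tree)) cat("  with phylogenetic tree\n")
  if (!is.null(S4Vectors::metadata(object)$truth)) cat("  with synthetic ground truth\n")
  invisible(NULL)
})

#' Co-abundance group assignment
#'
#' Result of [clusterCags]: a taxon-to-guild map together with the chosen
#' number of clusters and the per-`k` selection diagnostics.
#'
#' @slot assignment Named integer vector mapping each taxon to a CAG in
#'   `1..k`.
#' @slot k Integer, the selected number of co-abundance groups.
#' @slot diagnostics `data.frame` with one row per candidate `k`
#'   (columns `k`, `nPairs`, `maxP`, `allSignificant`, `meanR2`).
#' @slot method Character description of distance and linkage.
#' @slot fallback Logical; `TRUE` when no candidate `k` satisfied the
#'   all-pairs significance rule and the maximal mean R-squared fallback
#'   was used.
#' @export
setClass("CagAssignment",
  representation(assignment = "integer", k = "integer",
                 diagnostics = "data.frame", method = "character",
                 fallback = "logical"))

setValidity("CagAssignment", function(object) {
  a <- object@assignment
  if (is.null(names(a))) return("assignment must be named by taxon")
  if (anyDuplicated(names(a))) return("each taxon assigned exactly once")
  k <- object@k
  if (length(k) != 1L || k < 1L) return("k must be a single positive integer")
  if (!all(sort(unique(a)) == seq_len(k))) return("labels 1..k must all be nonempty")
  TRUE
})

setMethod("show", "CagAssignment", function(object) {
  cat("CagAssignment:", length(object@assignment), "taxa in", object@k, "CAGs",
      if (object@fallback) "(fallback k selection)" else "", "\n")
  print(table(CAG = object@assignment))
  invisible(NULL)
})

#' @rdname result-accessors
#' @export
setMethod("cagLabels", "CagAssignment", function(x) x@assignment)

#' @rdname result-accessors
#' @export
setMethod("cagK", "CagAssignment", function(x) x@k)

#' Sparse partial-correlation network
#'
#' Result of [sparsePartialNetwork]: a graphical-lasso precision estimate
#' expressed as partial correlations, with the EBIC-selected
#' regularization strength and the whole selection path.
#'
#' @slot nodes Character vector of variable (taxon or CAG) names.
#' @slot partialCor Symmetric matrix of partial correlations (unit
#'   diagonal ignored; entries in (-1, 1)).
#' @slot edges `data.frame` of the nonzero off-diagonal entries
#'   (`from`, `to`, `weight`, `sign`).
#' @slot lambda Selected regularization parameter.
#' @slot gamma EBIC gamma used.
#' @slot ebic EBIC value at the selected lambda.
#' @slot path `data.frame` with one row per candidate lambda
#'   (`lambda`, `nEdges`, `ebic`).
#' @export
setClass("PartialCorrelationNetwork",
  representation(nodes = "character", partialCor = "matrix",
                 edges = "data.frame", lambda = "numeric", gamma = "numeric",
                 ebic = "numeric", path = "data.frame"))

setValidity("PartialCorrelationNetwork", function(object) {
  pc <- object@partialCor
  if (!isSymmetric(unname(pc), tol = 1e-8)) return("partialCor must be symmetric")
  off <- pc[upper.tri(pc)]
  if (any(abs(off) >= 1)) return("partial correlations must lie in (-1, 1)")
  e <- object@edges
  if (nrow(e) && any(e$from == e$to)) return("no self-edges allowed")
  TRUE
})

setMethod("show", "PartialCorrelationNetwork", function(object) {
  cat("PartialCorrelationNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  cat(sprintf("  lambda = %.4g (EBIC gamma = %.2f, EBIC = %.2f)\n",
              object@lambda, object@gamma, object@ebic))
  invisible(NULL)
})

#' @rdname result-accessors
#' @export
setMethod("networkEdges", "PartialCorrelationNetwork", function(x) x@edges)

#' ROC curve with AUC and DeLong confidence interval
#'
#' @slot auc Area under the ROC curve (Mann-Whitney pairwise definition).
#' @slot ciLower,ciUpper 95 percent (by default) DeLong confidence bounds,
#'   `NA` when the CI was not requested.
#' @slot curve `data.frame` with `threshold`, `sensitivity`,
#'   `specificity` rows ordered from the most permissive threshold.
#' @slot nCases,nControls Class sizes.
#' @slot method Character, CI method ("DeLong").
#' @export
setClass("RocResult",
  representation(auc = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 curve = "data.frame", nCases = "integer",
                 nControls = "integer", method = "character"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0, 1]")
  if (!is.na(object@ciLower) && !is.na(object@ciUpper)) {
    if (object@ciLower > object@auc + 1e-12 ||
        object@ciUpper < object@auc - 1e-12)
      return("CI must contain the point AUC")
  }
  TRUE
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f", object@auc))
  if (!is.na(object@ciLower))
    cat(sprintf(" (95%%CI: %.4f, %.4f; %s)", object@ciLower, object@ciUpper,
                object@method))
  cat(sprintf("  [cases: %d, controls: %d]\n", object@nCases, object@nControls))
  invisible(NULL)
})

#' @rdname result-accessors
#' @export
setMethod("aucValue", "RocResult", function(x) x@auc)

#' @rdname result-accessors
#' @export
setMethod("aucCI", "RocResult", function(x) c(x@ciLower, x@ciUpper))

#' @rdname result-accessors
#' @export
setMethod("rocCurve", "RocResult", function(x) x@curve)

#' PERMANOVA result
#'
#' @slot statistic Pseudo-F statistic (Anderson's formulation).
#' @slot r2 Proportion of the total sum of squared distances explained by
#'   the grouping.
#' @slot pValue Permutation p-value with the +1 convention (never 0).
#' @slot nPerm Number of permutations used.
#' @slot seed Seed used for the permutation stream (`NA` if none given).
#' @export
setClass("PermanovaResult",
  representation(statistic = "numeric", r2 = "numeric", pValue = "numeric",
                 nPerm = "integer", seed = "integer"))

setValidity("PermanovaResult", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) return("R2 must lie in [0, 1]")
  lo <- 1 / (object@nPerm + 1)
  if (object@pValue < lo - 1e-12 || object@pValue > 1 + 1e-12)
    return("p must lie in [1/(nPerm+1), 1]")
  TRUE
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              object@statistic, object@r2, object@pValue, object@nPerm))
  invisible(NULL)
})

#' Participant-flow report
#'
#' Result of [applyExclusions]: the ordered exclusion cascade with the
#' number of subjects removed under each criterion (each subject counted
#' once, under the first criterion that flags it).
#'
#' @slot criteria Character vector, exclusion criteria in application order.
#' @slot excluded Integer vector, subjects excluded under each criterion.
#' @slot nEnrolled Integer, subjects entering the cascade.
#' @slot nFinal Integer, subjects retained.
#' @slot retained Character vector of retained subject identifiers.
#' @export
setClass("FlowReport",
  representation(criteria = "character", excluded = "integer",
                 nEnrolled = "integer", nFinal = "integer",
                 retained = "character"))

setValidity("FlowReport", function(object) {
  if (length(object@criteria) != length(object@excluded))
    return("criteria and excluded must have equal length")
  if (object@nFinal != object@nEnrolled - sum(object@excluded))
    return("nFinal must equal nEnrolled minus total excluded")
  if (length(object@retained) != object@nFinal)
    return("retained set size must equal nFinal")
  TRUE
})

setMethod("show", "FlowReport", function(object) {
  cat("FlowReport:", object@nEnrolled, "enrolled ->", object@nFinal, "retained\n")
  for (i in seq_along(object@criteria)) {
    cat(sprintf("  - %s: n = %d excluded\n", object@criteria[i], object@excluded[i]))
  }
  invisible(NULL)
})
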