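#' @importFrom methods new validObject is slot
#' @importFrom stats cor cutree hclust as.dist cmdscale pchisq pnorm pt qnorm
#'   rnorm runif rlnorm rbinom rmultinom sd var lm lm.fit model.matrix
#'   p.adjust complete.cases uniroot setNames kruskal.test wilcox.test t.test
#'   chisq.test quantile binomial
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# If `seed` is NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a per-stage child seed from a global seed
#'
#' One global seed is expanded into independent per-stage seeds by a fixed
#' affine rule modulo the Mersenne prime 2^31 - 1, so that adding a stage
#' never perturbs the draws of earlier stages.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 1) or a registered stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' childSeed(1, 1)
#' childSeed(1, "labels")
#' @export
childSeed <- function(seed, stage) {
  stages <- c(
    labels = 1L, covariates = 2L, factors = 3L, depths = 4L,
    counts = 5L, clinical = 6L, registry = 7L, split = 8L, permute = 9L
  )
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  stopifnot(length(seed) == 1L, length(stage) == 1L, stage >= 1)
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(stage) * 69621
  as.integer(x %% (m - 1) + 1)
}

# stderr logging with a stage tag, suppressible via suppressMessages()
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# shared argument checks -------------------------------------------------

.check_matrix <- function(x, what = "table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicated taxon identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicated sample identifiers")
  invisible(x)
}

.as_two_groups <- function(labels) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop("exactly two groups are required")
  f
}
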