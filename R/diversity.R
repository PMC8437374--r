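# Alpha diversity, rarefaction, beta-diversity distances, ordination and
# PERMANOVA.

#' Shannon diversity index
#'
#' \eqn{-\sum_i p_i \log_b p_i} over nonzero proportions after
#' normalizing. Log base 2 by default (the common amplicon-pipeline
#' convention); the base is a parameter.
#'
#' @param x Non-negative vector (one sample) or taxa x samples matrix
#'   (computed per column).
#' @param base Logarithm base.
#' @return Numeric value, or named vector for a matrix.
#' @examples
#' shannonIndex(c(0.25, 0.25, 0.25, 0.25))  # 2 bits
#' @export
shannonIndex <- function(x, base = 2) {
  if (is.matrix(x)) return(apply(x, 2L, shannonIndex, base = base))
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("all-zero sample")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Observed features (richness)
#'
#' @param x Non-negative count vector or taxa x samples matrix.
#' @return Number of taxa with count > 0 (per column for a matrix).
#' @export
observedFeatures <- function(x) {
  if (is.matrix(x)) return(colSums(x > 0))
  sum(x > 0)
}

#' Rarefy a count table to a common depth
#'
#' Samples with fewer total reads than `depth` are dropped (listed via a
#' message); every retained column is subsampled without replacement to
#' exactly `depth` reads.
#'
#' @param x Integer count matrix (taxa x samples) or
#'   [GuildExperiment-class].
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Rarefied count matrix over the retained samples.
#' @name rarefyCounts
NULL

#' @rdname rarefyCounts
#' @export
setMethod("rarefyCounts", "matrix", function(x, depth, seed = NULL, ...) {
  .check_matrix(x, "counts")
  if (depth < 1) stop("depth must be >= 1")
  tot <- colSums(x)
  keep <- tot >= depth
  if (!any(keep)) stop("rarefaction depth ", depth, " drops all samples")
  if (any(!keep)) {
    log_msg("rarefy", "dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(colnames(x)[!keep], collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  with_seed(seed, {
    out <- vapply(seq_len(ncol(x)), function(j) {
      reads <- rep.int(seq_len(nrow(x)), x[, j])
      tabulate(reads[sample.int(length(reads), depth)], nbins = nrow(x))
    }, integer(nrow(x)))
    out <- matrix(out, nrow = nrow(x))
    dimnames(out) <- dimnames(x)
    out
  })
})

#' @rdname rarefyCounts
#' @export
setMethod("rarefyCounts", "GuildExperiment", function(x, depth, seed = NULL, ...) {
  m <- rarefyCounts(SummarizedExperiment::assay(x, "counts"), depth, seed)
  GuildExperiment(m, SummarizedExperiment::colData(x)[colnames(m), , drop = FALSE],
                  tree = S4Vectors::metadata(x)$tree,
                  truth = S4Vectors::metadata(x)$truth)
})

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(i,j) = \sum_t |x_{ti} - x_{tj}| / \sum_t (x_{ti} + x_{tj})},
#' computed by [vegan::vegdist] on the sample profiles.
#'
#' @param x Abundance matrix (taxa x samples) or [GuildExperiment-class]
#'   (counts are converted to relative abundances first).
#' @param ... Unused.
#' @return A `dist` over samples.
#' @name brayCurtis
NULL

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "matrix", function(x, ...) {
  .check_matrix(x, "table")
  if (ncol(x) < 2L) stop("need at least 2 samples")
  vegan::vegdist(t(x), method = "bray")
})

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "GuildExperiment", function(x, ...) {
  brayCurtis(relAbundance(x))
})

# edge x tip incidence of a rooted tree, rows aligned to tree$edge
.edge_tip_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  M <- matrix(FALSE, nrow(tree$edge), nt,
              dimnames = list(NULL, tree$tip.label))
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(post$edge[, 1], post$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  tipsUnder <- vector("list", max(tree$edge))
  for (i in seq_len(nt)) tipsUnder[[i]] <- i
  for (r in seq_len(nrow(post$edge))) {
    child <- post$edge[r, 2]
    parent <- post$edge[r, 1]
    M[ord[r], tipsUnder[[child]]] <- TRUE
    tipsUnder[[parent]] <- c(tipsUnder[[parent]], tipsUnder[[child]])
  }
  M
}

#' UniFrac phylogenetic beta diversity
#'
#' Unweighted UniFrac is the branch length unique to one sample's clade
#' set divided by the total branch length covered by either sample.
#' Weighted UniFrac is the branch-length-weighted absolute difference of
#' subtree proportions, normalized by the branch-length-weighted sum of
#' the two profiles so values lie in `[0, 1]` (the classical normalized
#' variant; recorded in the result's `"variant"` attribute).
#'
#' @param x Count matrix (taxa x samples) or [GuildExperiment-class]
#'   carrying its tree in `metadata(x)$tree`.
#' @param tree Rooted [ape::phylo]; tips must cover all taxa (extra tips
#'   are pruned with a warning).
#' @param weighted Logical.
#' @param ... Unused.
#' @return A `dist` over samples with attribute `variant`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 0L, 3L, 0L), 4,
#'             dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
#' uniFrac(m, tr)  # disjoint clades: distance 1
#' @name uniFrac
NULL

#' @rdname uniFrac
#' @export
setMethod("uniFrac", "matrix", function(x, tree, weighted = FALSE, ...) {
  .check_matrix(x, "table")
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, rownames(x))
  if (length(extra)) {
    warning("pruning ", length(extra), " tree tip(s) absent from the table")
    tree <- ape::drop.tip(tree, extra)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  b <- tree$edge.length
  M <- .edge_tip_matrix(tree)
  P <- relAbundance(x)[colnames(M), , drop = FALSE]
  n <- ncol(P)
  A <- M %*% P                       # edge x sample subtree proportions
  pres <- (M %*% (P > 0)) > 0        # edge covered by sample
  d <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (weighted) {
        num <- sum(b * abs(A[, i] - A[, j]))
        den <- sum(b * (A[, i] + A[, j]))
      } else {
        num <- sum(b * xor(pres[, i], pres[, j]))
        den <- sum(b * (pres[, i] | pres[, j]))
      }
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  out <- as.dist(d)
  attr(out, "variant") <- if (weighted) "weighted-normalized" else "unweighted"
  out
})

#' @rdname uniFrac
#' @export
setMethod("uniFrac", "GuildExperiment", function(x, tree, weighted = FALSE, ...) {
  if (missing(tree)) tree <- S4Vectors::metadata(x)$tree
  if (is.null(tree)) stop("no tree supplied and none stored in the experiment")
  uniFrac(SummarizedExperiment::assay(x, "counts"), tree, weighted)
})

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \eqn{-d^2/2} and eigendecomposes it. Negative
#' eigenvalues are reported but excluded from the explained-variance
#' proportions.
#'
#' @param d A `dist` or symmetric distance matrix over >= 3 samples.
#' @param k Number of axes to keep (default: all with positive
#'   eigenvalue).
#' @return List with `coordinates` (samples x axes), `eigenvalues`,
#'   `proportionExplained`.
#' @export
pcoaOrdination <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 samples")
  cs <- cmdscale(as.dist(m), k = n - 1, eig = TRUE)
  eig <- cs$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  prop <- ifelse(pos, eig / sum(eig[pos]), 0)
  coords <- cs$points
  if (is.null(k)) k <- max(1L, sum(pos))
  k <- min(k, ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       proportionExplained = prop[seq_len(k)])
}

# squared-distance within-group sum of squares for a label vector
.ss_within <- function(D2, idx) {
  s <- 0
  for (ix in idx) s <- s + sum(D2[ix, ix]) / (2 * length(ix))
  s
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Anderson's one-factor pseudo-F from total and within-group sums of
#' squared distances, with a seeded label-permutation p-value using the
#' +1 convention, \eqn{p = (1 + \#\{F^* \ge F\}) / (nPerm + 1)}, so p is
#' never 0.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param labels Group labels (>= 2 groups, each with >= 2 samples).
#' @param nPerm Number of permutations (study convention: 9999).
#' @param seed Integer seed for the permutation stream.
#' @return A [PermanovaResult-class].
#' @export
permanova <- function(d, labels, nPerm = 9999, seed = NULL) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  f <- droplevels(as.factor(labels))
  if (length(f) != n) stop("labels must match the distance matrix")
  if (nlevels(f) < 2L) stop("need at least 2 groups")
  sizes <- table(f)
  if (any(sizes < 2L)) stop("every group needs at least 2 samples")
  a <- nlevels(f)
  sst <- sum(D2) / (2 * n)
  idx <- split(seq_len(n), f)
  ssw <- .ss_within(D2, idx)
  ssa <- sst - ssw
  fstat <- (ssa / (a - 1)) / (ssw / (n - a))
  r2 <- ssa / sst
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      sswP <- .ss_within(D2, lapply(idx, function(ix) perm[ix]))
      fP <- ((sst - sswP) / (a - 1)) / (sswP / (n - a))
      if (fP >= fstat - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  new("PermanovaResult", statistic = fstat, r2 = r2,
      pValue = (1 + exceed) / (nPerm + 1), nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration when both groups have n <= 20 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction, as used for alpha-diversity comparisons.
#'
#' @param a,b Numeric vectors.
#' @return List with `statistic` (W) and `p`.
#' @export
wilcoxonRankSum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 20 && length(b) <= 20
  res <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}
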