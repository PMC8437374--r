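# Co-abundance group (guild) discovery and sparse partial-correlation
# networks.

#' Select the most abundant taxa
#'
#' Top `n` taxa by mean relative abundance across samples; ties are
#' broken lexicographically by taxon id (logged).
#'
#' @param x Relative-abundance matrix, taxa x samples.
#' @param n Number of taxa to keep (study convention: 99). If fewer taxa
#'   are available, all are used with a warning.
#' @return Character vector of taxon ids, in abundance order.
#' @export
selectTopTaxa <- function(x, n = 99) {
  .check_matrix(x, "table")
  if (nrow(x) < n) {
    warning("only ", nrow(x), " taxa available; using all")
    n <- nrow(x)
  }
  means <- rowMeans(x)
  if (anyDuplicated(means[order(-means)][seq_len(min(n + 1L, length(means)))])) {
    log_msg("topTaxa", "abundance ties broken lexicographically by taxon id")
  }
  ord <- order(-means, rownames(x))
  rownames(x)[ord[seq_len(n)]]
}

#' Kendall tau-b correlation matrix between taxa
#'
#' Pairwise tie-corrected Kendall tau-b between taxon abundance vectors
#' (zero-inflated genus profiles have massive ties, so the tie-corrected
#' variant is essential). Constant taxa have undefined tau and are set
#' to 0 with a warning.
#'
#' @param x Abundance matrix, taxa x samples (>= 3 samples).
#' @return Symmetric taxa x taxa matrix with unit diagonal.
#' @export
kendallMatrix <- function(x) {
  .check_matrix(x, "table")
  if (ncol(x) < 3L) stop("need at least 3 samples")
  constant <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  K <- suppressWarnings(cor(t(x), method = "kendall"))
  if (any(constant)) {
    warning(sum(constant), " constant taxa: tau undefined, set to 0")
    K[constant, ] <- 0
    K[, constant] <- 0
  }
  diag(K) <- 1
  K
}

#' Cluster taxa into co-abundance groups with permutation-selected k
#'
#' Taxa are clustered hierarchically (Ward linkage by default) on the
#' distance `1 - Spearman rho` between their abundance profiles. For
#' each candidate `k` the tree is cut and every pair of clusters is
#' tested by [permanova] on the Kendall-correlation distance
#' `1 - tau` restricted to the pair's taxa, with cluster membership as
#' labels. The chosen `k` is the largest candidate for which all
#' pairwise tests have `p < alpha`; if none qualifies, the `k` with
#' maximal mean between-cluster R-squared is used and flagged
#' prominently.
#'
#' @param x Relative-abundance matrix (taxa x samples, taxa already
#'   restricted e.g. via [selectTopTaxa]) or [GuildExperiment-class].
#' @param kRange Candidate cluster numbers (default 2:12).
#' @param nPerm Permutations per pairwise test (study convention: 9999).
#' @param seed Integer seed for the permutation streams.
#' @param linkage `hclust` linkage (default `"ward.D2"`).
#' @param alpha Pairwise significance level for the k-selection rule.
#' @param profile Cluster taxa on their abundance vectors (default) or
#'   on the rows of the Kendall correlation matrix.
#' @param ... Unused.
#' @return A [CagAssignment-class].
#' @name clusterCags
NULL

#' @rdname clusterCags
#' @export
setMethod("clusterCags", "matrix",
function(x, kRange = 2:12, nPerm = 9999, seed = NULL, linkage = "ward.D2",
         alpha = 0.05, profile = c("abundance", "kendall"), ...) {
  .check_matrix(x, "table")
  profile <- match.arg(profile)
  p <- nrow(x)
  if (p < max(kRange) + 1L) stop("need more taxa than max(kRange)")
  K <- kendallMatrix(x)
  clusterInput <- if (profile == "abundance") x else K
  rho <- suppressWarnings(cor(t(clusterInput), method = "spearman"))
  rho[is.na(rho)] <- 0
  hc <- hclust(as.dist(1 - rho), method = linkage)
  Dtau <- 1 - K
  diag(Dtau) <- 0

  diag_rows <- list()
  cuts <- list()
  for (k in sort(kRange)) {
    lab <- cutree(hc, k)
    cuts[[as.character(k)]] <- lab
    pairs <- utils::combn(seq_len(k), 2L)
    ps <- numeric(ncol(pairs)); r2s <- numeric(ncol(pairs))
    for (ci in seq_len(ncol(pairs))) {
      members <- lab %in% pairs[, ci]
      sub <- Dtau[members, members, drop = FALSE]
      sublab <- lab[members]
      if (min(table(sublab)) < 2L) {  # singleton cluster: untestable pair
        ps[ci] <- 1; r2s[ci] <- 0
        next
      }
      pr <- permanova(sub, sublab, nPerm = nPerm,
                      seed = if (is.null(seed)) NULL
                             else childSeed(seed, "permute") + k * 1000L + ci)
      ps[ci] <- pr@pValue; r2s[ci] <- pr@r2
    }
    diag_rows[[as.character(k)]] <- data.frame(
      k = k, nPairs = ncol(pairs), maxP = max(ps),
      allSignificant = all(ps < alpha), meanR2 = mean(r2s))
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  ok <- diagnostics$k[diagnostics$allSignificant]
  fallback <- length(ok) == 0L
  if (fallback) {
    kSel <- diagnostics$k[which.max(diagnostics$meanR2)]
    log_msg("cag", "NO k in range has all pairwise PERMANOVA p < ", alpha,
            "; falling back to k = ", kSel, " (maximal mean between-cluster R2)")
  } else {
    kSel <- max(ok)
  }
  assignment <- cuts[[as.character(kSel)]]
  new("CagAssignment", assignment = assignment, k = as.integer(kSel),
      diagnostics = diagnostics,
      method = paste0("hclust(", linkage, ") on 1 - Spearman(", profile,
                      "); k by pairwise PERMANOVA on 1 - Kendall tau"),
      fallback = fallback)
})

#' @rdname clusterCags
#' @param topN For the `GuildExperiment` method: restrict to the top
#'   `topN` most abundant taxa first.
#' @export
setMethod("clusterCags", "GuildExperiment", function(x, topN = 99, ...) {
  rel <- relAbundance(x)
  keep <- selectTopTaxa(rel, topN)
  clusterCags(rel[keep, , drop = FALSE], ...)
})

#' Summed relative abundance per co-abundance group
#'
#' Per sample, the abundance of a CAG is the sum of the relative
#' abundances of its member taxa; taxa not covered by the assignment are
#' reported as an `unassigned` remainder row so columns still sum to 1.
#'
#' @param x Relative-abundance matrix (taxa x samples) or
#'   [GuildExperiment-class].
#' @param assignment A [CagAssignment-class] or named vector mapping
#'   taxa to cluster labels.
#' @param ... Unused.
#' @return Matrix, CAGs (+ `unassigned`) x samples.
#' @name cagAbundance
NULL

#' @rdname cagAbundance
#' @export
setMethod("cagAbundance", c("matrix", "ANY"), function(x, assignment, ...) {
  .check_matrix(x, "table")
  if (is(assignment, "CagAssignment")) assignment <- cagLabels(assignment)
  if (is.null(names(assignment))) stop("assignment must be named by taxon")
  missing <- setdiff(names(assignment), rownames(x))
  if (length(missing)) {
    stop("assignment references missing taxa: ", paste(missing, collapse = ", "))
  }
  labs <- sort(unique(assignment))
  out <- t(vapply(labs, function(l) {
    colSums(x[names(assignment)[assignment == l], , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(out) <- paste0("CAG", labs)
  rest <- setdiff(rownames(x), names(assignment))
  remainder <- colSums(x[rest, , drop = FALSE])
  if (any(remainder > 0)) out <- rbind(out, unassigned = remainder)
  colnames(out) <- colnames(x)
  out
})

#' @rdname cagAbundance
#' @export
setMethod("cagAbundance", c("GuildExperiment", "ANY"),
function(x, assignment, ...) {
  cagAbundance(relAbundance(x), assignment)
})

# ---- graphical lasso ---------------------------------------------------

# Friedman block coordinate descent for the L1-penalized Gaussian
# precision estimate. S: covariance/correlation; rho: scalar penalty or
# p x p penalty matrix (elementwise; used with 0/BIG entries to compute
# support-constrained MLEs). Warm starts via W (current covariance
# estimate) and B (p x p matrix of column lasso coefficients). An
# all-zero penalty is the unpenalized MLE: direct inversion.
.glasso_fit <- function(S, rho, W = NULL, B = NULL, maxit = 500, tol = 1e-7) {
  p <- ncol(S)
  if (length(rho) == 1L) rho <- matrix(rho, p, p)
  if (all(rho == 0)) {
    Theta <- solve(S)
    return(list(Theta = Theta, W = S, B = matrix(0, p, p)))
  }
  rhoBar <- mean(c(rho[row(rho) != col(rho) & rho < 1e5], 0))
  if (is.null(W)) W <- S
  if (is.null(B)) B <- matrix(0, p, p)
  diag(W) <- diag(S) + diag(rho)
  for (it in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      r12 <- rho[idx, j]
      beta <- B[idx, j]
      # inner lasso by coordinate descent
      for (inner in seq_len(maxit)) {
        bOld <- beta
        for (k in seq_along(idx)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          beta[k] <- sign(r) * max(abs(r) - r12[k], 0) / W11[k, k]
        }
        if (max(abs(beta - bOld)) < tol * max(1, max(abs(beta)))) break
      }
      B[idx, j] <- beta
      W[idx, j] <- W[j, idx] <- W11 %*% beta
    }
    if (mean(abs(W - Wold)) < tol * (mean(abs(S[row(S) != col(S)])) + rhoBar)) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta22 <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- theta22
    Theta[idx, j] <- -B[idx, j] * theta22
  }
  Theta <- (Theta + t(Theta)) / 2
  list(Theta = Theta, W = W, B = B)
}

# support-constrained Gaussian MLE: free entries unpenalized, banned
# off-diagonal entries forced to zero via a prohibitive penalty
.support_mle <- function(S, support) {
  p <- ncol(S)
  if (!any(support & row(support) != col(support))) {
    return(diag(1 / diag(S), p))
  }
  rho <- matrix(1000, p, p)
  rho[support] <- 0
  diag(rho) <- 0
  .glasso_fit(S, rho, maxit = 1000, tol = 1e-9)$Theta
}

#' Lasso-regularized partial correlation network selected by EBIC
#'
#' Estimates a sparse Gaussian graphical model over the variables (taxa
#' or CAGs) by the graphical lasso along a log-spaced path of 100
#' penalties from `lambda_max` (the smallest penalty giving an empty
#' graph) down to `ratio * lambda_max`. Each candidate edge set on the
#' path is scored by the extended BIC,
#' \eqn{-2 \ell + E \log n + 4 E \gamma \log p} with `E` the edge
#' count, evaluated at the support-constrained maximum-likelihood
#' precision (the original EBIC formulation for Gaussian graphical
#' models, rather than the penalized-likelihood shortcut, which
#' over-selects dense graphs at small `p`). Partial correlations
#' \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} are reported from
#' the selected support's constrained MLE.
#'
#' @param x Variables x samples matrix (taxa or CAG abundances) or
#'   [GuildExperiment-class] (uses relative abundances).
#' @param gamma EBIC gamma (default 0.5).
#' @param nLambda Number of penalties on the path (default 100).
#' @param ratio Smallest-to-largest penalty ratio (default 0.01).
#' @param corMethod Correlation used as input (`"pearson"` default,
#'   `"spearman"` available for heavy-tailed abundances).
#' @param ... Unused.
#' @return A [PartialCorrelationNetwork-class].
#' @examples
#' set.seed(1)
#' xv <- rnorm(300); yv <- xv + rnorm(300); zv <- yv + rnorm(300)
#' m <- rbind(X = xv, Y = yv, Z = zv)
#' colnames(m) <- paste0("s", 1:300)
#' net <- sparsePartialNetwork(m)
#' networkEdges(net)  # X-Y and Y-Z, no X-Z
#' @name sparsePartialNetwork
NULL

#' @rdname sparsePartialNetwork
#' @export
setMethod("sparsePartialNetwork", "matrix",
function(x, gamma = 0.5, nLambda = 100, ratio = 0.01,
         corMethod = c("pearson", "spearman"), ...) {
  .check_matrix(x, "variables")
  corMethod <- match.arg(corMethod)
  p <- nrow(x); n <- ncol(x)
  if (n < p + 1L) {
    warning("fewer samples (", n, ") than variables + 1 (", p + 1L,
            "); estimates may be unstable")
  }
  S <- cor(t(x), method = corMethod)
  if (anyNA(S)) stop("correlation undefined (constant variable?)")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    log_msg("glasso", "correlation matrix not positive definite; ",
            "regularizing the diagonal")
    S <- S + diag(1e-4 - min(ev, 0), p)
    S <- stats::cov2cor(S)
  }
  lmax <- max(abs(S[row(S) != col(S)]))
  lambdas <- exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda))
  W <- NULL; B <- NULL
  path <- data.frame(lambda = lambdas, nEdges = NA_integer_, ebic = NA_real_)
  refits <- list()  # one constrained-MLE refit per distinct support
  best <- NULL
  for (li in seq_along(lambdas)) {
    fit <- .glasso_fit(S, lambdas[li], W = W, B = B)
    W <- fit$W; B <- fit$B
    support <- abs(fit$Theta) > 1e-10
    diag(support) <- TRUE
    support <- support | t(support)
    key <- paste0("s:", paste(which(support[upper.tri(support)]), collapse = ","))
    if (is.null(refits[[key]])) {
      Theta <- .support_mle(S, support)
      E <- sum(support[upper.tri(support)])
      ll <- as.numeric(determinant(Theta, logarithm = TRUE)$modulus) -
        sum(S * Theta)
      refits[[key]] <- list(Theta = Theta, E = E, ll = ll)
    }
    rf <- refits[[key]]
    ebic <- -n * rf$ll + rf$E * log(n) + 4 * rf$E * gamma * log(p)
    path$nEdges[li] <- rf$E
    path$ebic[li] <- ebic
    if (is.null(best) || ebic < best$ebic - 1e-9) {
      best <- list(Theta = rf$Theta, lambda = lambdas[li], ebic = ebic)
    }
  }
  Theta <- best$Theta
  d <- sqrt(diag(Theta))
  pc <- -Theta / outer(d, d)
  diag(pc) <- 0
  pc[abs(pc) < 1e-10] <- 0
  dimnames(pc) <- list(rownames(x), rownames(x))
  ut <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(x)[ut[, 1]], to = rownames(x)[ut[, 2]],
    weight = pc[ut], sign = ifelse(pc[ut] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  new("PartialCorrelationNetwork", nodes = rownames(x), partialCor = pc,
      edges = edges, lambda = best$lambda, gamma = gamma, ebic = best$ebic,
      path = path)
})

#' @rdname sparsePartialNetwork
#' @export
setMethod("sparsePartialNetwork", "GuildExperiment", function(x, ...) {
  sparsePartialNetwork(relAbundance(x), ...)
})

#' Write a network as a weighted edge-list TSV
#'
#' @param network A [PartialCorrelationNetwork-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "PartialCorrelationNetwork"))
  utils::write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
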