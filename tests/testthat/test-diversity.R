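test_that("Shannon index matches the entropy formula", {
  expect_equal(shannonIndex(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(shannonIndex(c(1, 0, 0)), 0)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25), base = exp(1)),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  # unnormalized input is normalized first
  expect_equal(shannonIndex(c(2, 1, 1)), 1.5)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  m <- random_table(6, 4, seed = 2)
  expect_equal(unname(shannonIndex(m))[1], shannonIndex(m[, 1]))
})

test_that("observed features counts nonzero taxa", {
  expect_equal(observedFeatures(c(5, 0, 3)), 2)
  expect_equal(observedFeatures(c(0, 0)), 0)
  m <- random_table(6, 4, seed = 3)
  expect_equal(observedFeatures(m), colSums(m > 0))
})

test_that("rarefaction subsamples to exact depth without replacement", {
  m <- random_table(10, 6, seed = 5, zero_frac = 0.2)
  r <- rarefyCounts(m, depth = 30, seed = 1)
  expect_true(all(colSums(r) == 30))
  expect_true(all(r <= m[, colnames(r)]))  # without replacement

  # depth equal to the sample total returns the column unchanged
  tot1 <- sum(m[, 1])
  r1 <- suppressMessages(rarefyCounts(m[, 1, drop = FALSE], depth = tot1, seed = 1))
  expect_equal(r1[, 1], m[, 1])

  single <- matrix(100L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(rarefyCounts(single, 40, seed = 1)[1, 1], 40L)

  expect_message(rarefyCounts(m, depth = max(colSums(m)), seed = 1), "dropping")
  expect_error(rarefyCounts(m, depth = sum(m) + 1, seed = 1), "drops all")

  # rarefaction is unbiased for relative abundance: mean of 200 draws
  # within 2 SE of the true proportions
  x <- matrix(c(500L, 300L, 200L), 3, 1, dimnames = list(letters[1:3], "s"))
  draws <- vapply(1:200, function(s) rarefyCounts(x, 100, seed = s)[, 1] / 100,
                  numeric(3))
  pTrue <- c(0.5, 0.3, 0.2)
  se <- sqrt(pTrue * (1 - pTrue) / 100) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - pTrue) < 2.5 * se))
})

test_that("Bray-Curtis matches the hand formula at the extremes", {
  m <- cbind(s1 = c(0.5, 0.5, 0), s2 = c(0.25, 0.25, 0.5),
             s3 = c(0.5, 0.5, 0), s4 = c(0, 0, 1))
  rownames(m) <- paste0("g", 1:3)
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)
})

test_that("unweighted UniFrac does branch accounting correctly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(5L, 0L, 0L, 0L,  0L, 0L, 3L, 0L, 5L, 5L, 0L, 0L), 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  d <- as.matrix(uniFrac(m, tr, weighted = FALSE))
  expect_equal(d["s1", "s2"], 1)    # shared length 0 of covered 4
  # s1={A}, s3={A,B}: shared A branch(1)+internal(1); unique B branch 1
  expect_equal(d["s1", "s3"], 1 / 3)
  expect_equal(d["s1", "s1"], 0)

  # star tree with unit branches equals Jaccard on presence sets
  withr::with_seed(8, {
    nt <- 12
    star <- ape::stree(nt, "star")
    star$edge.length <- rep(1, nrow(star$edge))
    cnt <- matrix(rbinom(nt * 6, 1, 0.5) * rpois(nt * 6, 5), nt, 6,
                  dimnames = list(star$tip.label, paste0("s", 1:6)))
    cnt[, 1] <- pmax(cnt[, 1], 1)  # avoid empty samples
    cnt[1, ] <- pmax(cnt[1, ], 1)
    storage.mode(cnt) <- "integer"
    du <- as.matrix(uniFrac(cnt, star))
    pres <- cnt > 0
    for (i in 1:5) for (j in (i + 1):6) {
      jac <- 1 - sum(pres[, i] & pres[, j]) / sum(pres[, i] | pres[, j])
      expect_equal(du[i, j], jac, tolerance = 1e-12)
    }
  })

  expect_error(uniFrac(rbind(m, X = 1L), tr), "missing from tree")
  expect_warning(uniFrac(m[1:3, ], tr), "pruning")
})

test_that("weighted UniFrac agrees with the phyloseq reference on a random toy", {
  skip_if_not_installed("phyloseq")
  withr::with_seed(21, {
    tr <- ape::rtree(8)
    cnt <- matrix(rpois(8 * 5, 10), 8, 5,
                  dimnames = list(tr$tip.label, paste0("s", 1:5)))
    storage.mode(cnt) <- "integer"
  })
  mine <- as.matrix(uniFrac(cnt, tr, weighted = TRUE))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(cnt, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
  mineU <- as.matrix(uniFrac(cnt, tr, weighted = FALSE))
  refU <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(mineU, refU[rownames(mineU), colnames(mineU)], tolerance = 1e-10)
})

test_that("PCoA recovers Euclidean configurations and flags asymmetry", {
  pts <- c(0, 1, 2, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- pcoaOrdination(d)
  rec <- as.matrix(dist(res$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  res3 <- pcoaOrdination(d3)
  pos <- res3$eigenvalues[res3$eigenvalues > 1e-9]
  expect_equal(pos[1], pos[2], tolerance = 1e-9)  # all-equal distances

  ddup <- as.matrix(dist(c(0, 1, 1, 5)))
  dimnames(ddup) <- list(paste0("s", 1:4), paste0("s", 1:4))
  resd <- pcoaOrdination(ddup)
  expect_lt(max(abs(resd$coordinates["s2", ] - resd$coordinates["s3", ])), 1e-9)

  bad <- d; bad[1, 2] <- 9
  expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("PERMANOVA p agrees with exhaustive enumeration and vegan", {
  withr::with_seed(13, {
    pts <- matrix(rnorm(12), 6, 2)
    pts[4:6, ] <- pts[4:6, ] + 1.2
  })
  d <- dist(pts)
  lab <- rep(c("a", "b"), each = 3)
  pExact <- permanova_exhaustive_p(d, lab)
  res <- permanova(d, lab, nPerm = 9999, seed = 4)
  expect_lt(abs(res@pValue - pExact), 0.02)
  expect_equal(res@statistic, pseudo_f(d, lab), tolerance = 1e-12)

  # cross-check statistic and R2 against vegan's implementation
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = lab), permutations = 99)
  expect_equal(res@statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(res@r2, ad$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA degenerate inputs behave as specified", {
  dEq <- matrix(1, 6, 6) - diag(6)
  dimnames(dEq) <- list(paste0("s", 1:6), paste0("s", 1:6))
  res <- permanova(dEq, rep(c("a", "b"), 3), nPerm = 199, seed = 1)
  expect_equal(res@pValue, 1)  # F identical for every relabeling
  expect_error(permanova(dEq, rep("a", 6), nPerm = 99), "2 groups")
  expect_error(permanova(dEq, c("a", rep("b", 5)), nPerm = 99), "at least 2 samples")
})

test_that("rank-sum test is exact when possible, approximate otherwise", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # all 20 balanced splits: most extreme ordering has one-sided tail 1/20
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  withr::with_seed(6, {
    a <- rnorm(50); b <- rnorm(50, 2)
  })
  expect_lt(wilcoxonRankSum(a, b)$p, 0.001)
  expect_error(wilcoxonRankSum(numeric(0), 1), "nonempty")
})
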