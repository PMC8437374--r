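# Synthetic cohort generator.
#
# Latent log-normal factor model: each sample draws one Gaussian factor
# per taxon block; taxon log-abundances load on their block factor with
# weight sqrt(rho) plus independent noise with weight sqrt(1-rho), so the
# within-block latent correlation equals rho. Exponentiation and
# column normalization give compositions; sequencing reads are drawn
# multinomially at a per-sample log-normal depth. This produces the
# compositional, overdispersed, block-correlated structure the analysis
# stages assume, with known ground truth.

#' Synthetic cohort configuration
#'
#' @slot nCase,nControl Group sizes (default 156 anemic / 402 control).
#' @slot nTaxa Number of genera (default 99).
#' @slot nBlocks Number of planted co-abundance blocks (default 8).
#' @slot withinBlockCorr Latent within-block correlation in `[0, 1)`.
#' @slot depthMean Mean sequencing depth per sample (reads).
#' @slot depthDispersion Log-scale SD of the per-sample depth.
#' @slot differentialTaxa `data.frame(taxon, log2fc)`: planted
#'   case-vs-control fold changes (taxon index or name).
#' @slot outcomeCoefficients Per-block log-odds weights (named by block
#'   index) for a logistic outcome model on standardized true block
#'   abundances; empty for fixed group labels.
#' @slot covariateSpec List describing the 13 enrollment covariates.
#' @slot clinicalSpec `data.frame(name, mean, sd, shift)` for the
#'   clinical indices; `shift` is the case-minus-control group difference.
#' @slot seed Integer master seed, expanded per stage via [childSeed].
#' @export
setClass("SynthConfig",
  representation(nCase = "integer", nControl = "integer", nTaxa = "integer",
                 nBlocks = "integer", withinBlockCorr = "numeric",
                 depthMean = "numeric", depthDispersion = "numeric",
                 differentialTaxa = "data.frame",
                 outcomeCoefficients = "numeric",
                 covariateSpec = "list", clinicalSpec = "data.frame",
                 seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nCase < 1L || object@nControl < 1L) return("group sizes must be positive")
  if (object@nTaxa < 1L) return("nTaxa must be positive")
  if (object@nBlocks > object@nTaxa) return("nBlocks must not exceed nTaxa")
  rho <- object@withinBlockCorr
  if (rho < 0 || rho >= 1) return("withinBlockCorr must lie in [0, 1)")
  if (object@depthMean <= 0) return("depthMean must be positive")
  if (object@depthDispersion < 0) return("depthDispersion must be non-negative")
  TRUE
})

#' @describeIn SynthConfig Constructor with study-calibrated defaults:
#'   156 cases vs 402 controls, 99 genera in 8 blocks at within-block
#'   correlation 0.7, mean depth 40000 reads (log-SD 0.3), five planted
#'   2-fold differential genera, 13 enrollment covariates and 8 clinical
#'   indices with case-decreased Hb/RBC/ALB/DB/TB/FT4.
#' @param nCase,nControl,nTaxa,nBlocks,withinBlockCorr,depthMean,depthDispersion
#'   See slots.
#' @param differentialTaxa,outcomeCoefficients,covariateSpec,clinicalSpec,seed
#'   See slots; `NULL` selects the defaults above.
#' @export
synthConfig <- function(nCase = 156, nControl = 402, nTaxa = 99, nBlocks = 8,
                        withinBlockCorr = 0.7, depthMean = 40000,
                        depthDispersion = 0.3, differentialTaxa = NULL,
                        outcomeCoefficients = numeric(0),
                        covariateSpec = NULL, clinicalSpec = NULL, seed = 1L) {
  if (is.null(differentialTaxa)) {
    differentialTaxa <- data.frame(taxon = c(5L, 15L, 25L, 35L, 45L),
                                   log2fc = rep(1, 5))
    differentialTaxa <- differentialTaxa[differentialTaxa$taxon <= nTaxa, ]
  }
  if (is.null(covariateSpec)) covariateSpec <- defaultCovariateSpec()
  if (is.null(clinicalSpec)) clinicalSpec <- defaultClinicalSpec()
  new("SynthConfig",
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      nTaxa = as.integer(nTaxa), nBlocks = as.integer(nBlocks),
      withinBlockCorr = withinBlockCorr, depthMean = depthMean,
      depthDispersion = depthDispersion,
      differentialTaxa = as.data.frame(differentialTaxa),
      outcomeCoefficients = outcomeCoefficients,
      covariateSpec = covariateSpec, clinicalSpec = clinicalSpec,
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %d cases / %d controls, %d taxa in %d blocks (rho = %.2f)\n",
              object@nCase, object@nControl, object@nTaxa, object@nBlocks,
              object@withinBlockCorr))
  cat(sprintf("  depth ~ lognormal(mean %.0f, sdlog %.2f); %d differential taxa; %s outcome\n",
              object@depthMean, object@depthDispersion,
              nrow(object@differentialTaxa),
              if (length(object@outcomeCoefficients)) "logistic" else "fixed-label"))
  invisible(NULL)
})

#' Default covariate specification
#'
#' The 13 enrollment covariates of the cohort design (age, pre-pregnancy
#' BMI, parity, gravidity, income, education, passive smoking, antibiotic
#' use, supplement use, pre-pregnancy and in-pregnancy alcohol/caffeine),
#' with marginal distributions calibrated to the descriptive cohort table.
#'
#' @return A list of per-covariate specs (`name`, `type`, parameters).
#' @export
defaultCovariateSpec <- function() {
  list(
    list(name = "maternal_age", type = "continuous", mean = 29.0, sd = 3.2),
    list(name = "pre_bmi", type = "continuous", mean = 22.3, sd = 5.6),
    list(name = "parity", type = "binary", p = 0.24),
    list(name = "gravidity", type = "binary", p = 0.41),
    list(name = "family_income", type = "categorical",
         levels = c("low", "middle", "high"), p = c(0.13, 0.72, 0.15)),
    list(name = "education", type = "categorical",
         levels = c("college_or_below", "university", "graduate"),
         p = c(0.30, 0.54, 0.16)),
    list(name = "passive_smoking", type = "categorical",
         levels = c("never", "seldom", "always"), p = c(0.40, 0.50, 0.10)),
    list(name = "antibiotic_use", type = "binary", p = 0.57),
    list(name = "supplement_use", type = "binary", p = 0.94),
    list(name = "alcohol_pre", type = "binary", p = 0.07),
    list(name = "caffeine_pre", type = "binary", p = 0.43),
    list(name = "alcohol_pregnancy", type = "binary", p = 0.02),
    list(name = "caffeine_pregnancy", type = "binary", p = 0.16)
  )
}

#' Default clinical-index specification
#'
#' Gaussian means/SDs in conventional units for mid-pregnancy, with the
#' case-minus-control shifts reproducing the direction of the reported
#' group differences (ALB, DB, FT4, Hb, RBC, TB decreased in anemia;
#' serum iron unshifted).
#'
#' @return `data.frame(name, mean, sd, shift)`.
#' @export
defaultClinicalSpec <- function() {
  data.frame(
    name = c("Hb", "RBC", "ALB", "DB", "TB", "FT4", "serum_iron", "serum_ferritin"),
    mean = c(118, 4.0, 38, 2.5, 9.0, 15, 18, 45),
    sd = c(8, 0.35, 3, 0.8, 3.0, 2.0, 5, 20),
    shift = c(-10, -0.25, -1.5, -0.35, -1.2, -1.0, 0, -8)
  )
}

.draw_covariates <- function(spec, n) {
  out <- lapply(spec, function(s) {
    switch(s$type,
      continuous = rnorm(n, s$mean, s$sd),
      binary = factor(ifelse(runif(n) < s$p, "yes", "no"), levels = c("no", "yes")),
      categorical = factor(sample(s$levels, n, replace = TRUE, prob = s$p),
                           levels = s$levels),
      stop("unknown covariate type: ", s$type))
  })
  names(out) <- vapply(spec, `[[`, character(1), "name")
  as.data.frame(out, stringsAsFactors = FALSE)
}

# latent log-abundance draw for one timepoint; returns proportions taxa x n
.draw_composition <- function(mu, block, rho, n, groupShift) {
  p <- length(mu)
  b <- max(block)
  f <- matrix(rnorm(b * n), b, n)
  eps <- matrix(rnorm(p * n), p, n)
  x <- mu + sqrt(rho) * f[block, , drop = FALSE] + sqrt(1 - rho) * eps
  x <- x + groupShift
  e <- exp(x)
  sweep(e, 2L, colSums(e), "/")
}

#' Generate a synthetic two-timepoint cohort with known ground truth
#'
#' Draws a genus-level count table, sample metadata (group, timepoint,
#' covariates, clinical indices) and the planted truth from a
#' [SynthConfig-class]. Group labels are either fixed at the configured
#' sizes or, when `outcomeCoefficients` is non-empty, drawn from a
#' logistic model on the standardized true block (CAG) relative
#' abundances at the first timepoint, with the intercept solved so the
#' expected prevalence matches `nCase / (nCase + nControl)`. In the
#' logistic mode any planted `differentialTaxa` are ignored (with a
#' warning): group shifts cannot precede labels that are drawn from the
#' realized abundances.
#'
#' @param config A [SynthConfig-class].
#' @param timepoints Character subset of `c("T2", "T3")`; each timepoint
#'   is an independent abundance draw for the same subjects.
#' @param clinical Logical; also draw clinical indices into the metadata
#'   via [generateClinical].
#' @return A list with `experiment` (a [GuildExperiment-class] with the
#'   truth in its metadata) and `truth` (list: `blockAssignment`,
#'   `differentialTaxa`, `outcomeModel`, `labels`).
#' @examples
#' cfg <- synthConfig(nCase = 20, nControl = 40, nTaxa = 30, nBlocks = 4,
#'                    depthMean = 2000, seed = 7)
#' sim <- generateCommunity(cfg, timepoints = "T2")
#' sim$experiment
#' @export
generateCommunity <- function(config, timepoints = c("T2", "T3"),
                              clinical = TRUE) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  timepoints <- match.arg(timepoints, c("T2", "T3"), several.ok = TRUE)
  nCase <- config@nCase; nControl <- config@nControl
  n <- nCase + nControl
  p <- config@nTaxa
  taxa <- sprintf("genus_%03d", seq_len(p))
  subjects <- sprintf("S%04d", seq_len(n))
  block <- rep_len(seq_len(config@nBlocks), p)
  names(block) <- taxa
  mu <- seq(2.5, -2.5, length.out = p)

  coefs <- config@outcomeCoefficients
  logistic <- length(coefs) > 0L
  if (logistic) {
    bi <- if (is.null(names(coefs))) seq_along(coefs) else
      suppressWarnings(as.integer(names(coefs)))
    if (anyNA(bi) || any(bi < 1L) || any(bi > config@nBlocks)) {
      stop("outcomeCoefficients reference nonexistent block(s)")
    }
    if (nrow(config@differentialTaxa)) {
      warning("differentialTaxa ignored when outcomeCoefficients are given")
    }
  }

  dtx <- config@differentialTaxa
  if (nrow(dtx)) {
    idx <- if (is.numeric(dtx$taxon)) as.integer(dtx$taxon) else match(dtx$taxon, taxa)
    if (anyNA(idx) || any(idx < 1L) || any(idx > p)) {
      stop("differentialTaxa reference unknown taxa")
    }
    dtx$taxon <- taxa[idx]
    dtx$index <- idx
  }

  labels <- NULL
  if (!logistic) {
    labels <- with_seed(childSeed(config@seed, "labels"),
                        sample(rep(c("GA", "control"), c(nCase, nControl))))
  }

  covariates <- with_seed(childSeed(config@seed, "covariates"),
                          .draw_covariates(config@covariateSpec, n))

  countsList <- list(); metaList <- list()
  outcomeModel <- NULL
  for (ti in seq_along(timepoints)) {
    tp <- timepoints[ti]
    tpOff <- if (tp == "T2") 0L else 100L
    shift <- matrix(0, p, n)
    if (!logistic && nrow(dtx)) {
      shift[dtx$index, labels == "GA"] <- rep(log(2) * dtx$log2fc,
                                              sum(labels == "GA"))
    }
    prop <- with_seed(childSeed(config@seed, "factors") + tpOff,
                      .draw_composition(mu, block, config@withinBlockCorr, n, shift))
    if (logistic && is.null(labels)) {
      blockAb <- rowsum(prop, block)  # true block relative abundances
      z <- t(scale(t(blockAb)))
      eta0 <- drop(crossprod(z[bi, , drop = FALSE], coefs))
      target <- nCase / n
      alpha <- uniroot(function(a) mean(stats::plogis(a + eta0)) - target,
                       c(-20, 20))$root
      pr <- stats::plogis(alpha + eta0)
      y <- with_seed(childSeed(config@seed, "labels"), rbinom(n, 1L, pr))
      labels <- ifelse(y == 1L, "GA", "control")
      outcomeModel <- list(coefficients = coefs, blocks = bi, intercept = alpha)
    }
    depth <- with_seed(childSeed(config@seed, "depths") + tpOff, {
      d <- rlnorm(n, log(config@depthMean) - config@depthDispersion^2 / 2,
                  config@depthDispersion)
      pmax(1L, as.integer(round(d)))
    })
    counts <- with_seed(childSeed(config@seed, "counts") + tpOff, {
      m <- vapply(seq_len(n), function(j) rmultinom(1L, depth[j], prop[, j])[, 1L],
                  integer(p))
      matrix(m, nrow = p)
    })
    dimnames(counts) <- list(taxa, paste0(subjects, "_", tp))
    countsList[[tp]] <- counts
    metaList[[tp]] <- data.frame(
      sample_id = colnames(counts), subject_id = subjects, timepoint = tp,
      group = labels, covariates, stringsAsFactors = FALSE,
      row.names = colnames(counts))
  }

  counts <- do.call(cbind, unname(countsList))
  meta <- do.call(rbind, unname(metaList))
  rownames(meta) <- meta$sample_id
  truth <- list(blockAssignment = block,
                differentialTaxa = if (logistic) dtx[0, ] else dtx,
                outcomeModel = outcomeModel, labels = labels)
  if (clinical) {
    clin <- generateClinical(meta, config@clinicalSpec,
                             seed = childSeed(config@seed, "clinical"))
    meta <- cbind(meta, clin[rownames(meta), setdiff(colnames(clin), "sample_id"),
                             drop = FALSE])
  }
  ge <- GuildExperiment(counts, meta, truth = truth)
  list(experiment = ge, truth = truth)
}

# truncated normal draws via inverse-CDF, preserving the seeded stream
.rnorm_below <- function(n, mean, sd, upper) {
  qnorm(runif(n) * pnorm(upper, mean, sd), mean, sd)
}
.rnorm_above <- function(n, mean, sd, lower) {
  qnorm(pnorm(lower, mean, sd) + runif(n) * (1 - pnorm(lower, mean, sd)), mean, sd)
}

#' Generate clinical indices for a sample metadata table
#'
#' Gaussian indices with the configured case-minus-control shifts. The
#' hemoglobin column respects the cohort design: every sample at T2 is
#' non-anemic (Hb at or above `threshold`), and at the outcome timepoint
#' (T3) cases are forced below `threshold` and controls at or above it,
#' via seeded truncated-normal draws.
#'
#' @param metadata `data.frame` with `sample_id`, `group` and
#'   `timepoint` columns.
#' @param spec `data.frame(name, mean, sd, shift)`; see
#'   [defaultClinicalSpec].
#' @param seed Integer seed.
#' @param samples Sample ids to generate for (default: all in
#'   `metadata`); unknown ids raise an error.
#' @param threshold Anemia threshold for Hb in g/L.
#' @return `data.frame` of indices, rownames = sample ids.
#' @export
generateClinical <- function(metadata, spec = defaultClinicalSpec(), seed = 1L,
                             samples = NULL, threshold = 100) {
  stopifnot(all(c("sample_id", "group", "timepoint") %in% colnames(metadata)))
  if (is.null(samples)) samples <- metadata$sample_id
  miss <- setdiff(samples, metadata$sample_id)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  md <- metadata[match(samples, metadata$sample_id), ]
  n <- nrow(md)
  isCase <- md$group == "GA"
  with_seed(seed, {
    out <- lapply(seq_len(nrow(spec)), function(i) {
      m <- spec$mean[i] + spec$shift[i] * isCase
      s <- spec$sd[i]
      if (spec$name[i] == "Hb") {
        v <- numeric(n)
        t3case <- isCase & md$timepoint == "T3"
        v[t3case] <- .rnorm_below(sum(t3case), m[t3case], s, threshold - 1e-9)
        v[!t3case] <- .rnorm_above(sum(!t3case), m[!t3case], s, threshold)
        v
      } else {
        pmax(rnorm(n, m, s), 0)  # concentrations are non-negative
      }
    })
    names(out) <- spec$name
    df <- as.data.frame(out)
    rownames(df) <- md$sample_id
    cbind(sample_id = md$sample_id, df)
  })
}

#' Generate a cohort registry with mutually exclusive exclusion flags
#'
#' One row per enrolled subject with a boolean column per exclusion
#' criterion; the requested counts are met exactly and the flags are
#' mutually exclusive by construction (the participant-flow arithmetic
#' subtracts counts sequentially without overlaps).
#'
#' @param nEnrolled Number of subjects entering the cascade.
#' @param exclusionCounts Named integer vector: criterion -> count.
#' @param seed Integer seed (which subjects carry each flag is random).
#' @return `data.frame` with `subject_id` and one logical column per
#'   criterion.
#' @examples
#' reg <- generateCohortRegistry(781,
#'   c(assisted_conception = 19, twin_pregnancy = 8,
#'     pregnancy_complications = 142, anemia_T2 = 54), seed = 1)
#' colSums(reg[-1])
#' @export
generateCohortRegistry <- function(nEnrolled, exclusionCounts, seed = 1L) {
  stopifnot(is.numeric(exclusionCounts), !is.null(names(exclusionCounts)))
  nm <- names(exclusionCounts)
  exclusionCounts <- as.integer(exclusionCounts)
  names(exclusionCounts) <- nm
  if (any(exclusionCounts < 0)) stop("exclusion counts must be non-negative")
  if (sum(exclusionCounts) > nEnrolled) {
    stop("exclusion counts (", sum(exclusionCounts), ") exceed nEnrolled (",
         nEnrolled, ")")
  }
  ids <- sprintf("P%04d", seq_len(nEnrolled))
  ord <- with_seed(seed, sample.int(nEnrolled))
  reg <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  start <- 0L
  for (crit in names(exclusionCounts)) {
    k <- exclusionCounts[[crit]]
    flag <- logical(nEnrolled)
    if (k > 0) flag[ord[(start + 1L):(start + k)]] <- TRUE
    reg[[crit]] <- flag
    start <- start + k
  }
  reg
}
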