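# Participant-flow cascade and descriptive cohort statistics.

#' Apply an ordered exclusion cascade to a cohort registry
#'
#' Subjects flagged for several criteria are counted once, under the
#' first criterion in `criteria` order, mirroring how participant-flow
#' diagrams subtract counts sequentially.
#'
#' @param registry `data.frame` with a `subject_id` column and one
#'   logical column per criterion (see [generateCohortRegistry]).
#' @param criteria Character vector of criterion column names, in
#'   application order; empty vector retains everyone.
#' @return A [FlowReport-class].
#' @examples
#' reg <- generateCohortRegistry(10, c(a = 2, b = 1), seed = 1)
#' applyExclusions(reg, c("a", "b"))
#' @export
applyExclusions <- function(registry, criteria) {
  stopifnot("subject_id" %in% colnames(registry))
  unknown <- setdiff(criteria, colnames(registry))
  if (length(unknown)) stop("unknown criterion(s): ", paste(unknown, collapse = ", "))
  n <- nrow(registry)
  excludedUnder <- rep(NA_character_, n)
  for (crit in criteria) {
    flag <- registry[[crit]]
    if (!is.logical(flag)) stop("criterion column must be logical: ", crit)
    hit <- flag & is.na(excludedUnder)
    excludedUnder[hit] <- crit
  }
  counts <- vapply(criteria, function(cr) sum(excludedUnder == cr, na.rm = TRUE),
                   integer(1))
  retained <- registry$subject_id[is.na(excludedUnder)]
  new("FlowReport", criteria = as.character(criteria),
      excluded = as.integer(counts), nEnrolled = as.integer(n),
      nFinal = length(retained), retained = as.character(retained))
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' Uncorrected Pearson chi-square on an r x c contingency table; the
#' uncorrected statistic is the variant that reproduces the printed
#' descriptive-table p-values for the 2x2 characteristics.
#'
#' @param counts Non-negative integer matrix with at least 2 rows and
#'   2 columns.
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' chiSquareIndependence(matrix(c(204, 198, 79, 77), 2))
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) stop("need at least a 2x2 table")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal")
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom. Two
#' degenerate cases are resolved explicitly: both groups constant with
#' equal means gives statistic 0 and p 1; both constant with unequal
#' means is undefined and raises an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p`.
#' @export
welchT <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, df = Inf, p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  res <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Descriptive cohort table (mean +/- SD or n (%) with tests)
#'
#' Continuous characteristics are summarized as mean +/- SD per group and
#' compared by Welch's t-test; categorical characteristics as n (%) of
#' the full group size, compared by uncorrected Pearson chi-square across
#' non-missing levels. Missing values are excluded listwise per
#' characteristic and their counts reported. Percentages are always
#' recomputed from counts; the formatted strings are presentation only.
#'
#' @param metadata `data.frame` of per-subject characteristics.
#' @param group Name of the two-level grouping column.
#' @param variables Character vector of characteristic columns (default:
#'   all except `group` and identifier columns).
#' @return `data.frame` with one row per characteristic level:
#'   `characteristic`, `level`, one summary column per group, `test`,
#'   `p`, `nMissing`.
#' @export
summarizeTable1 <- function(metadata, group = "group", variables = NULL) {
  stopifnot(group %in% colnames(metadata))
  g <- .as_two_groups(metadata[[group]])
  if (is.null(variables)) {
    variables <- setdiff(colnames(metadata),
                         c(group, "sample_id", "subject_id", "timepoint"))
  }
  gl <- levels(g)
  nG <- table(g)
  rows <- list()
  for (v in variables) {
    if (!v %in% colnames(metadata)) {
      warning("characteristic absent, skipped: ", v)
      next
    }
    x <- metadata[[v]]
    nMiss <- sum(is.na(x))
    if (all(is.na(x))) {
      warning("characteristic all-missing, omitted: ", v)
      next
    }
    if (is.numeric(x)) {
      sm <- vapply(gl, function(l) {
        xi <- x[g == l & !is.na(x)]
        sprintf("%.2f ± %.2f", mean(xi), sd(xi))
      }, character(1))
      p <- tryCatch(welchT(x[g == gl[1]], x[g == gl[2]])$p,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = v, level = "", t(sm), test = "welch_t", p = p,
        nMissing = nMiss, stringsAsFactors = FALSE)
    } else {
      f <- factor(x)
      tab <- table(f, g)  # non-missing only
      p <- tryCatch(chiSquareIndependence(unclass(tab))$p,
                    error = function(e) NA_real_)
      for (li in seq_len(nrow(tab))) {
        sm <- vapply(gl, function(l) {
          sprintf("%d (%.2f)", tab[li, l], 100 * tab[li, l] / nG[[l]])
        }, character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = v, level = rownames(tab)[li], t(sm),
          test = "chi_square", p = if (li == 1L) p else NA_real_,
          nMissing = nMiss, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  colnames(out)[3:4] <- gl
  rownames(out) <- NULL
  out
}

#' Classify anemia from hemoglobin
#'
#' Strict threshold: anemic iff Hb is strictly below `threshold` g/L.
#' The cohort uses 100 g/L (stricter than the WHO 110 g/L definition, to
#' allow for the physiological plasma-volume increase of pregnancy).
#'
#' @param hb Hemoglobin in g/L (positive; vectorized).
#' @param threshold Diagnostic threshold in g/L.
#' @return Factor with levels `GA`, `normal`.
#' @examples
#' classifyAnemia(c(99.9, 100, 110))
#' @export
classifyAnemia <- function(hb, threshold = 100) {
  if (any(is.na(hb)) || any(hb <= 0)) stop("hb must be positive")
  factor(ifelse(hb < threshold, "GA", "normal"), levels = c("GA", "normal"))
}
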