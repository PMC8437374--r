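# Readers/writers for count tables, metadata and trees.
#
# Orientation is fixed everywhere: taxa in rows, samples in columns; the
# first TSV column holds taxon identifiers (lineage strings allowed), the
# header row holds sample identifiers. Readers reject malformed input
# rather than coercing it.

#' Read a taxa x samples count table from TSV
#'
#' @param path Path to a tab-separated file; first column taxon id,
#'   header row of sample ids.
#' @return Integer matrix, taxa x samples.
#' @details Duplicate taxon or sample identifiers, ragged rows, negative
#'   or non-integer entries raise an error naming the offending row.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon\ts1\ts2", "g1\t5\t0", "g2\t3\t7"), f)
#' readCountTable(f)
#' @export
readCountTable <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("count table needs a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- cells[[1L]]
  samples <- hdr[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicated sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  ncols <- length(hdr)
  body <- cells[-1L]
  taxa <- vapply(body, `[`, character(1), 1L)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != ncols) {
      stop("ragged row for taxon '", taxa[i], "' (row ", i + 1L, "): ",
           length(body[[i]]), " fields, expected ", ncols)
    }
  }
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon identifier(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(length(samples)))
  )
  vals <- matrix(vals, nrow = length(samples))  # guards length(samples)==1
  m <- t(vals)
  dimnames(m) <- list(taxa, samples)
  bad <- which(apply(m, 1L, function(r) anyNA(r) || any(r < 0) || any(r != floor(r))))
  if (length(bad)) {
    stop("non-integer, negative or unparseable entries in row(s): ",
         paste(taxa[bad], collapse = ", "))
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count or abundance table as TSV
#'
#' @param x Taxa x samples matrix with dimnames.
#' @param path Output path.
#' @param idColumn Name of the first (taxon id) column.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(x, path, idColumn = "taxon") {
  .check_matrix(x, "table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, scientific = FALSE,
                                   digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read/write sample metadata or clinical tables (TSV)
#'
#' Plain TSV with a `sample_id` first column; strings are kept as
#' characters, never coerced to factors.
#'
#' @param path File path.
#' @return `readSampleTable`: a data.frame with rownames set to
#'   `sample_id`.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("metadata TSV must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id values")
  rownames(df) <- df$sample_id
  df
}

#' @rdname readSampleTable
#' @param df Data frame with rownames or a `sample_id` column.
#' @export
writeSampleTable <- function(df, path) {
  df <- as.data.frame(df)
  if (!"sample_id" %in% colnames(df)) {
    df <- cbind(sample_id = rownames(df), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Column-normalizes a taxa x samples table so every sample sums to 1;
#' taxon and sample order are preserved. Idempotent on tables that are
#' already compositional.
#'
#' @param x Count matrix (taxa x samples) or [GuildExperiment-class].
#' @param ... Unused.
#' @return For a matrix, the column-normalized matrix; for a
#'   `GuildExperiment`, the normalized matrix of its `"counts"` assay.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
#' relAbundance(m)
#' @name relAbundance
NULL

#' @rdname relAbundance
#' @export
setMethod("relAbundance", "matrix", function(x, ...) {
  .check_matrix(x, "table")
  tot <- colSums(x)
  zero <- colnames(x)[tot <= 0]
  if (length(zero)) stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  sweep(x, 2L, tot, "/")
})

#' @rdname relAbundance
#' @export
setMethod("relAbundance", "GuildExperiment", function(x, ...) {
  relAbundance(SummarizedExperiment::assay(x, "counts"))
})

.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

#' Collapse lineage-labelled rows to a taxonomic rank
#'
#' Rows whose `;`-delimited lineage strings (with `k__/p__/.../g__`
#' prefixes) agree up to `rank` are summed. Rows with no assignment at
#' `rank` are pooled into one `unclassified-<parent>` row per deepest
#' assigned ancestor. Bare row names without lineage prefixes are treated
#' as already collapsed and pass through unchanged.
#'
#' @param x Count matrix, taxa x samples.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Count matrix with one row per collapsed taxon.
#' @examples
#' m <- rbind("k__B;p__F;g__Blautia" = c(3L, 1L),
#'            "k__B;p__F;g__Blautia " = c(4L, 0L))
#' rownames(m) <- c("k__B;p__F;g__Blautia", "k__B;p__F;g__Roseburia")
#' colnames(m) <- c("s1", "s2")
#' collapseToRank(m, "genus")
#' @export
collapseToRank <- function(x, rank = "genus") {
  .check_matrix(x, "table")
  rank <- match.arg(rank, names(.rank_prefixes))
  ri <- match(rank, names(.rank_prefixes))
  keys <- vapply(rownames(x), function(id) {
    if (!grepl("__", id, fixed = TRUE)) return(id)  # already collapsed
    parts <- trimws(strsplit(id, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    pref <- sub("__.*$", "", parts)
    name <- sub("^[a-z]__", "", parts)
    if (any(!pref %in% .rank_prefixes) || anyDuplicated(pref)) {
      stop("malformed lineage: '", id, "'")
    }
    lev <- match(pref, .rank_prefixes)
    if (is.unsorted(lev, strictly = TRUE)) stop("malformed lineage: '", id, "'")
    keep <- lev <= ri
    if (any(lev == ri) && nzchar(name[lev == ri])) {
      paste(parts[keep], collapse = ";")
    } else {
      anc <- which(keep & nzchar(name))
      parent <- if (length(anc)) name[max(anc)] else "root"
      paste0("unclassified-", parent)
    }
  }, character(1))
  groups <- split(seq_len(nrow(x)), factor(keys, levels = unique(keys)))
  out <- t(vapply(groups, function(ix) colSums(x[ix, , drop = FALSE]),
                  numeric(ncol(x))))
  dimnames(out) <- list(names(groups), colnames(x))
  storage.mode(out) <- storage.mode(x)
  out
}

#' Read a rooted phylogenetic tree from newick
#'
#' Thin wrapper over [ape::read.tree] that replaces missing branch
#' lengths with 0 (with a warning) and rejects negative lengths.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
readTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels")
  tree
}

#' @rdname readTree
#' @param tree An [ape::phylo] object.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write/read a flat key-value sidecar file
#'
#' Plain-text `key = value` lines used to persist simulation ground truth
#' and run parameter manifests; vectors are comma-joined.
#'
#' @param x Named list of atomic vectors.
#' @param path File path.
#' @return `readKeyValue`: named list of character vectors.
#' @export
writeKeyValue <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(k) {
    paste0(k, " = ", paste(format(x[[k]], trim = TRUE, scientific = FALSE),
                           collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeKeyValue
#' @export
readKeyValue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(" = ", lines), invert = TRUE)
  out <- lapply(kv, function(p) strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}
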