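#' Read an OTU count table
#'
#' Reads a tab-separated OTU count table and returns it in samples x OTUs
#' orientation. QIIME2-style exports that start with a `#OTU ID` header line
#' (OTUs as rows) are recognised automatically; the orientation can also be
#' forced with `otus_as_rows`.
#'
#' @param path Path to a TSV file. The first column holds row identifiers and
#'   the first row holds column identifiers.
#' @param otus_as_rows `NULL` (auto-detect from the `#OTU ID` header, default
#'   samples-as-rows otherwise), or a logical forcing the file orientation.
#' @return Integer matrix with samples as rows and OTUs as columns; dimnames
#'   carry sample and OTU identifiers.
#' @seealso [write_otu_table()], [filter_rare_otus()], [rarefy()]
#' @export
read_otu_table <- function(path, otus_as_rows = NULL) {
  first <- readLines(path, n = 1L)
  qiime_header <- startsWith(first, "#OTU ID")
  if (qiime_header) {
    # "#" would otherwise be eaten as a comment char
    raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                             comment.char = "", check.names = FALSE,
                             stringsAsFactors = FALSE)
    names(raw)[1] <- "#OTU ID"
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE)
  }
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate row identifiers in ", path, ": ", paste(dup, collapse = ", "))
  dupc <- unique(names(raw)[-1][duplicated(names(raw)[-1])])
  if (length(dupc) > 0)
    stop("duplicate column identifiers in ", path, ": ", paste(dupc, collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(is.na(suppressWarnings(as.numeric(m[, j]))))
    if (length(bad) > 0)
      stop("non-numeric count at row '", ids[bad[1]], "', column '",
           colnames(m)[j], "' in ", path)
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (is.null(otus_as_rows)) otus_as_rows <- qiime_header
  if (otus_as_rows) m <- t(m)
  m
}

#' Write an OTU count table as TSV
#'
#' @param x Samples x OTUs integer matrix.
#' @param path Output path.
#' @param otus_as_rows Write OTUs as rows with a `#OTU ID` header (QIIME2
#'   style) instead of samples as rows.
#' @export
write_otu_table <- function(x, path, otus_as_rows = FALSE) {
  if (otus_as_rows) {
    df <- data.frame(`#OTU ID` = colnames(x), t(x), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two-column TSV of OTU id and a Silva-style lineage string with
#' `;`-separated, rank-prefixed fields (`d__`, `p__`, `c__`, `o__`, `f__`,
#' `g__`). Lookups are total: OTUs absent from the table, or lineages without
#' a usable rank field, resolve to `"unassigned"`.
#'
#' @param path Path to a TSV file with columns `otu_id` and `lineage`.
#' @return A `taxonomy_table`: data frame with columns `otu_id` and `lineage`.
#' @seealso [tax_rank()]
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs columns otu_id and lineage")
  taxonomy_table(df[[1]], df[[2]])
}

#' Construct a taxonomy table
#'
#' @param otu_id Character vector of OTU identifiers (unique).
#' @param lineage Character vector of `;`-separated rank-prefixed lineages.
#' @return A `taxonomy_table` data frame.
#' @export
taxonomy_table <- function(otu_id, lineage) {
  otu_id <- as.character(otu_id)
  lineage <- as.character(lineage)
  if (anyDuplicated(otu_id)) stop("duplicate OTU ids in taxonomy")
  n_ranks <- lengths(strsplit(lineage, ";", fixed = TRUE))
  if (any(n_ranks > 7)) stop("lineages must have at most 7 ranks")
  out <- data.frame(otu_id = otu_id, lineage = lineage,
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Write a taxonomy table as TSV
#' @param tax A `taxonomy_table`.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a taxonomic rank for OTU ids
#'
#' @param tax A `taxonomy_table`.
#' @param otu_ids Character vector of OTU ids to resolve.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param warn Warn when a listed OTU has a malformed/empty rank field.
#' @return Character vector of taxon names, `"unassigned"` where unknown.
#' @export
tax_rank <- function(tax, otu_ids, rank = "phylum", warn = FALSE) {
  prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  rank <- match.arg(rank, names(prefixes))
  pre <- prefixes[[rank]]
  idx <- match(otu_ids, tax$otu_id)
  out <- rep("unassigned", length(otu_ids))
  hit <- !is.na(idx)
  if (any(hit)) {
    fields <- strsplit(tax$lineage[idx[hit]], ";", fixed = TRUE)
    val <- vapply(fields, function(f) {
      f <- trimws(f)
      m <- f[startsWith(f, pre)]
      if (length(m) == 0) return(NA_character_)
      sub(pre, "", m[1], fixed = TRUE)
    }, character(1))
    bad <- is.na(val) | val == ""
    if (warn && any(bad))
      warning(sum(bad), " lineage(s) without a usable '", pre, "' field; ",
              "assigned 'unassigned'")
    val[bad] <- "unassigned"
    out[hit] <- val
  }
  out
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `status`, `age`, `gender`, `bcs`. Empty
#' cells are missing values. `status` must be one of `control`,
#' `survey_ibd`, `acute_ibd` and may never be missing, since group membership
#' drives every analysis.
#'
#' @param path Path to a TSV file.
#' @return Data frame with `status` and `gender` as factors.
#' @seealso [impute_metadata()]
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "status", "age", "gender", "bcs")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  validate_metadata(df[need])
}

validate_metadata <- function(df) {
  status_levels <- c("control", "survey_ibd", "acute_ibd")
  gender_levels <- c("mare", "gelding_stallion")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  if (any(is.na(df$status)))
    stop("status may not be missing (allowed: ",
         paste(status_levels, collapse = ", "), ")")
  bad <- setdiff(unique(as.character(df$status)), status_levels)
  if (length(bad) > 0)
    stop("unrecognised status token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(status_levels, collapse = ", "))
  badg <- setdiff(unique(as.character(df$gender[!is.na(df$gender)])), gender_levels)
  if (length(badg) > 0)
    stop("unrecognised gender token(s): ", paste(badg, collapse = ", "),
         "; allowed: ", paste(gender_levels, collapse = ", "))
  df$status <- factor(df$status, levels = status_levels)
  df$gender <- factor(as.character(df$gender), levels = gender_levels)
  df$age <- as.numeric(df$age)
  df$bcs <- as.numeric(df$bcs)
  if (any(df$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (any(df$bcs < 1 | df$bcs > 5, na.rm = TRUE))
    stop("body condition score must lie in [1, 5]")
  df
}

#' Write sample metadata as TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Remove rare OTUs
#'
#' Keeps an OTU only if at least `min_samples` samples each contain at least
#' `min_reads` reads of it (per-sample threshold). The sample set is
#' unchanged. The operation is idempotent.
#'
#' @param counts Samples x OTUs count matrix.
#' @param min_reads Per-sample read threshold (default 10).
#' @param min_samples Number of samples that must reach the threshold
#'   (default 2).
#' @return The filtered count matrix.
#' @export
filter_rare_otus <- function(counts, min_reads = 10, min_samples = 2) {
  if (min_samples > nrow(counts))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         nrow(counts), ")")
  keep <- colSums(counts >= min_reads) >= min_samples
  counts[, keep, drop = FALSE]
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth` reads. Rows
#' already at the target depth pass through unchanged.
#'
#' @param counts Samples x OTUs count matrix.
#' @param depth Target depth; `NULL` uses the minimum row sum.
#' @param seed Integer seed; required for reproducibility.
#' @return Rarefied integer count matrix.
#' @export
rarefy <- function(counts, depth = NULL, seed) {
  if (missing(seed)) stop("rarefy() requires an explicit seed")
  rs <- rowSums(counts)
  if (is.null(depth)) depth <- min(rs)
  low <- rs < depth
  if (any(low))
    stop("sample(s) below the rarefaction depth ", depth, ": ",
         paste(rownames(counts)[low], collapse = ", "))
  set.seed(seed)
  # preconditions (integer counts, depth <= row sums) are checked above, so
  # the only remaining rrarefy warnings are advisory
  out <- suppressWarnings(vegan::rrarefy(counts, sample = depth))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Convert counts to relative abundances
#'
#' @param counts Samples x OTUs count matrix with positive row sums.
#' @return Matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(counts) {
  rs <- rowSums(counts)
  zero <- rs <= 0
  if (any(zero))
    stop("zero-sum sample(s): ", paste(rownames(counts)[zero], collapse = ", "))
  sweep(counts, 1, rs, "/")
}

#' Impute missing metadata covariates
#'
#' Missing `age` and `bcs` are replaced by the median of the observed values;
#' missing `gender` by the most frequent observed category (a median is
#' undefined for a two-level factor). `status` must already be complete.
#'
#' @param meta Metadata data frame as returned by [read_metadata()].
#' @return Metadata with no missing `age`, `gender` or `bcs`.
#' @export
impute_metadata <- function(meta) {
  for (col in c("age", "bcs")) {
    v <- meta[[col]]
    if (all(is.na(v))) stop("column '", col, "' is entirely missing")
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    meta[[col]] <- v
  }
  g <- meta$gender
  if (anyNA(g)) {
    if (all(is.na(g))) stop("column 'gender' is entirely missing")
    tab <- table(g)
    g[is.na(g)] <- names(tab)[which.max(tab)]
    meta$gender <- g
  }
  meta
}
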