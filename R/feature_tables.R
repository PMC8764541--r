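# Data model and I/O for ASV/OTU count tables, taxonomy maps and cohort
# metadata, plus table-level transforms (relative abundance, OTU collapse,
# control-ASV removal, rarefaction, alpha diversity).
#
# Orientation is fixed throughout the package: features are rows, samples are
# columns. Counts are non-negative integers.

#' Construct a validated feature table
#'
#' A feature table is a non-negative integer matrix of read counts with
#' features (ASVs or OTUs) as rows and samples as columns. The constructor
#' enforces the invariants every downstream operation relies on: unique
#' feature and sample identifiers, integral non-negative counts, and (by
#' default) a positive read total in every sample.
#'
#' @param counts Numeric matrix of counts, features x samples. Must carry
#'   row and column names unless `feature_ids`/`sample_ids` are supplied.
#' @param feature_ids Character vector of feature identifiers (defaults to
#'   `rownames(counts)`).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   `colnames(counts)`).
#' @param require_positive_samples Reject samples whose read total is zero.
#'   Loading always enforces this; internal transforms may relax it.
#' @return A numeric matrix of class `feature_table` with dimnames set.
#' @export
feature_table <- function(counts, feature_ids = rownames(counts),
                          sample_ids = colnames(counts),
                          require_positive_samples = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature_table needs feature and sample identifiers")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(counts)) {
    stop("length of feature_ids (", length(feature_ids),
         ") does not match number of rows (", nrow(counts), ")")
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of columns (", ncol(counts), ")")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature id: ",
         feature_ids[duplicated(feature_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and non-missing")
  }
  bad <- which(counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop("invalid count at feature '", feature_ids[i[1L]], "', sample '",
         sample_ids[i[2L]], "': counts must be non-negative integers")
  }
  if (require_positive_samples && ncol(counts) > 0) {
    tot <- colSums(counts)
    if (any(tot == 0)) {
      stop("sample with zero total count: ", sample_ids[which(tot == 0)[1L]])
    }
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  class(counts) <- c("feature_table", class(matrix()))
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x), " features x ", ncol(x), " samples, ",
      format(sum(x), big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

# strip the class so arithmetic helpers see a plain matrix
unclass_ft <- function(x) {
  x <- unclass(x)
  class(x) <- NULL
  as.matrix(x)
}

#' Read a feature table from a tab-separated file
#'
#' Expected layout: a header row whose first cell is `feature_id` followed by
#' sample identifiers, then one row per feature. Parsing is strict: ragged
#' rows, non-numeric, negative or fractional counts, and duplicated
#' identifiers all fail with a message naming the offending row or column.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("feature table file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  if (width < 2L) stop("feature table header has no sample columns: ", path)
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop("ragged row ", ragged[1L], ": expected ", width, " fields, got ",
         lengths(fields)[ragged[1L]])
  }
  sample_ids <- fields[[1L]][-1L]
  body <- fields[-1L]
  feature_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(width - 1L))
  )
  # vapply gives samples x features (or a vector when one sample)
  vals <- matrix(vals, nrow = width - 1L)
  if (anyNA(vals)) {
    i <- arrayInd(which(is.na(vals))[1L], dim(vals))
    stop("non-numeric count in row '", feature_ids[i[2L]], "', column '",
         sample_ids[i[1L]], "'")
  }
  feature_table(t(vals), feature_ids = feature_ids, sample_ids = sample_ids)
}

#' Write a feature table to a tab-separated file
#'
#' Inverse of [read_feature_table()]; round-trips losslessly.
#'
#' @param table A feature table.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  m <- unclass_ft(table)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ASV taxonomy map
#'
#' The map carries, per ASV, the nearest reference sequence, the percent
#' identity of the hit and a coarser taxon label used as a fallback when the
#' identity is below the OTU-membership threshold. Columns: `asv_id`,
#' `reference_id`, `identity_pct`, `taxon_label`.
#'
#' @param path TSV path.
#' @return data.frame with one row per ASV.
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  validate_taxonomy_map(transform_taxonomy(df))
}

transform_taxonomy <- function(df) {
  df$identity_pct <- as.numeric(df$identity_pct)
  df
}

validate_taxonomy_map <- function(tax) {
  need <- c("asv_id", "reference_id", "identity_pct", "taxon_label")
  miss <- setdiff(need, names(tax))
  if (length(miss)) stop("taxonomy map missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tax$asv_id)) {
    stop("ASV mapped more than once: ", tax$asv_id[duplicated(tax$asv_id)][1L])
  }
  if (anyNA(tax$identity_pct) || any(tax$identity_pct < 0) ||
      any(tax$identity_pct > 100)) {
    stop("identity_pct must lie in [0, 100]")
  }
  tax
}

#' Write a taxonomy map to TSV
#' @param tax Taxonomy map data.frame.
#' @param path Output path.
#' @export
write_taxonomy_map <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read cohort metadata
#'
#' One row per sample. Required columns: `sample_id`, `subject_id`, `role`
#' (`mother` or `infant`) and `pair_id` (for infant samples, the sample id of
#' the biological mother; empty for mothers). Any further columns are treated
#' as clinical covariates; empty strings are read as missing.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA"))
  validate_cohort_metadata(df)
}

validate_cohort_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "role", "pair_id")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  }
  if (!all(md$role %in% c("mother", "infant"))) {
    stop("role must be 'mother' or 'infant'")
  }
  mothers <- md$sample_id[md$role == "mother"]
  infants <- md[md$role == "infant", , drop = FALSE]
  if (anyNA(infants$pair_id)) {
    stop("infant sample without pair link: ",
         infants$sample_id[is.na(infants$pair_id)][1L])
  }
  unknown <- setdiff(infants$pair_id, mothers)
  if (length(unknown)) {
    stop("pair_id does not name a mother sample: ", unknown[1L])
  }
  if (any(!is.na(md$pair_id[md$role == "mother"]))) {
    stop("mother samples must not carry a pair_id")
  }
  md
}

#' Write cohort metadata to TSV
#' @param md Metadata data.frame.
#' @param path Output path.
#' @export
write_cohort_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove negative-control ASVs from a table
#'
#' Drops features flagged as contaminants (e.g. everything observed in a
#' sequencing negative control). Identifiers absent from the table are
#' ignored with a message; sample set and retained counts are unchanged.
#'
#' @param table Feature table.
#' @param control_asvs Character vector of feature ids to remove (may be
#'   empty).
#' @return Feature table without the control features.
#' @export
drop_control_asvs <- function(table, control_asvs) {
  m <- unclass_ft(table)
  control_asvs <- as.character(control_asvs)
  absent <- setdiff(control_asvs, rownames(m))
  if (length(absent)) {
    message("ignoring ", length(absent),
            " control id(s) absent from table: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  }
  keep <- setdiff(rownames(m), control_asvs)
  if (!length(keep)) stop("empty table: all features are control ASVs")
  feature_table(m[keep, , drop = FALSE], require_positive_samples = FALSE)
}

#' Per-sample relative abundance
#'
#' @param table Feature table (or count matrix) with positive sample totals.
#' @return Numeric matrix of the same shape; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass_ft(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample with zero total count: ", colnames(m)[which(tot == 0)[1L]])
  }
  sweep(m, 2L, tot, "/")
}

#' Collapse ASVs into OTUs by shared reference assignment
#'
#' ASVs whose nearest reference hit reaches `min_identity` percent identity
#' are grouped under their reference id; ASVs below the threshold fall back
#' to their coarser taxon label (prefixed `unassigned:`), mirroring a
#' classifier-based genus assignment. OTU counts are column-wise sums of the
#' member ASVs, so the grand read total is conserved.
#'
#' @param table ASV-level feature table.
#' @param tax Taxonomy map covering every feature in `table`.
#' @param min_identity Percent identity required for reference-based OTU
#'   membership (default 98.5).
#' @return list with `table` (OTU-level feature table) and `mapping` (named
#'   character vector, asv_id -> otu_id).
#' @export
collapse_to_otus <- function(table, tax, min_identity = 98.5) {
  m <- unclass_ft(table)
  tax <- validate_taxonomy_map(tax)
  idx <- match(rownames(m), tax$asv_id)
  if (anyNA(idx)) {
    stop("feature missing from taxonomy map: ",
         rownames(m)[is.na(idx)][1L])
  }
  otu <- ifelse(tax$identity_pct[idx] >= min_identity,
                tax$reference_id[idx],
                paste0("unassigned:", tax$taxon_label[idx]))
  names(otu) <- rownames(m)
  collapsed <- rowsum(m, group = otu, reorder = FALSE)
  list(
    table = feature_table(collapsed, require_positive_samples = FALSE),
    mapping = otu
  )
}

#' Expected rarefaction curve for one sample
#'
#' Expected number of distinct features observed in a uniform subsample of
#' size `d` drawn without replacement from a sample with feature counts
#' `sample_counts` and total `N`:
#' \deqn{E[S_d] = \sum_a \left[1 - \binom{N - n_a}{d} / \binom{N}{d}\right]}
#' Computed on the log scale for numerical stability. The curve is
#' non-decreasing in depth and reaches the observed richness at `d = N`.
#'
#' @param sample_counts Integer vector of per-feature counts for one sample.
#' @param depths Increasing integer subsample sizes, all `<= sum(sample_counts)`.
#' @return Numeric vector of expected richness, one value per depth.
#' @export
rarefaction_curve <- function(sample_counts, depths) {
  n <- as.numeric(sample_counts)
  if (any(n < 0 | n != round(n))) stop("counts must be non-negative integers")
  d <- as.numeric(depths)
  if (any(d < 0 | d != round(d))) stop("depths must be non-negative integers")
  if (is.unsorted(d, strictly = FALSE)) stop("depths must be increasing")
  N <- sum(n)
  if (any(d > N)) stop("depth exceeds sample total (", N, ")")
  n <- n[n > 0]
  vapply(d, function(dd) {
    # P(feature a unobserved) = C(N - n_a, dd) / C(N, dd)
    p_miss <- exp(lchoose(N - n, dd) - lchoose(N, dd))
    sum(1 - p_miss)
  }, numeric(1L))
}

#' Observed richness per sample
#'
#' Number of features detected (count >= 1) in each sample.
#'
#' @param table Feature table.
#' @return Named integer vector, one entry per sample.
#' @export
observed_richness <- function(table) {
  m <- unclass_ft(table)
  colSums(m >= 1L)
}

# detection (presence/absence) matrix used across modules
detection_matrix <- function(table) {
  unclass_ft(table) >= 1L
}
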