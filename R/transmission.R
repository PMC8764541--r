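# Shared-ASV identification and summary statistics for mother-infant pairs,
# the unrelated-pair null, and the per-OTU sharing index.
#
# Sharing is binary on detection: an ASV is shared by a pair when it has
# count >= 1 in both samples. Abundance concordance is not required.

infants_of <- function(metadata) {
  metadata[metadata$role == "infant", , drop = FALSE]
}

mothers_of <- function(metadata) {
  metadata$sample_id[metadata$role == "mother"]
}

check_samples_in_table <- function(table, ids) {
  missing <- setdiff(ids, colnames(table))
  if (length(missing)) stop("unknown sample id: ", missing[1L])
}

#' ASVs detected in both members of a pair
#'
#' @param table Feature table containing both samples.
#' @param infant_sample,mother_sample Sample ids.
#' @return Character vector of shared feature ids.
#' @export
find_shared_asvs <- function(table, infant_sample, mother_sample) {
  check_samples_in_table(table, c(infant_sample, mother_sample))
  d <- detection_matrix(table)
  rownames(d)[d[, infant_sample] & d[, mother_sample]]
}

#' Shared-ASV profile of one mother-infant pair
#'
#' Three summary statistics of the infant's shared ASVs with a designated
#' mother (biological or, for the null, unrelated): the number of shared
#' ASVs, their percentage of the infant's observed ASVs, and their cumulative
#' relative abundance in the infant.
#'
#' @param table Feature table.
#' @param infant_sample,mother_sample Sample ids.
#' @return list with `infant_sample_id`, `mother_sample_id`, `shared_asvs`,
#'   `n_shared`, `pct_shared` (fraction in [0,1]) and `shared_abundance`.
#' @export
shared_profile <- function(table, infant_sample, mother_sample) {
  check_samples_in_table(table, c(infant_sample, mother_sample))
  m <- unclass_ft(table)
  infant_counts <- m[, infant_sample]
  richness <- sum(infant_counts >= 1)
  if (richness == 0) stop("empty infant sample: ", infant_sample)
  shared <- find_shared_asvs(table, infant_sample, mother_sample)
  list(
    infant_sample_id = infant_sample,
    mother_sample_id = mother_sample,
    shared_asvs = shared,
    n_shared = length(shared),
    pct_shared = length(shared) / richness,
    shared_abundance = sum(infant_counts[shared]) / sum(infant_counts)
  )
}

# shared-statistic matrices for a set of infants against a set of mothers,
# computed with matrix products over the detection matrix
shared_stat_matrices <- function(table, infant_ids, mother_ids) {
  m <- unclass_ft(table)
  check_samples_in_table(table, c(infant_ids, mother_ids))
  d <- m >= 1L
  di <- d[, infant_ids, drop = FALSE]
  dm <- d[, mother_ids, drop = FALSE]
  rel_i <- sweep(m[, infant_ids, drop = FALSE], 2L,
                 colSums(m[, infant_ids, drop = FALSE]), "/")
  n_shared <- crossprod(di * 1, dm * 1)          # infants x mothers
  richness <- colSums(di)
  if (any(richness == 0)) {
    stop("empty infant sample: ", infant_ids[which(richness == 0)[1L]])
  }
  list(n_shared = n_shared,
       pct_shared = n_shared / richness,
       shared_abundance = crossprod(rel_i, dm * 1))
}

#' Shared-ASV profiles of all biological pairs
#'
#' One row per infant, computed against its own mother as linked by
#' `pair_id` in the metadata.
#'
#' @param table Feature table.
#' @param metadata Cohort metadata (see [read_cohort_metadata()]).
#' @return data.frame with columns `infant_sample_id`, `mother_sample_id`,
#'   `n_shared`, `pct_shared`, `shared_abundance`.
#' @export
related_profiles <- function(table, metadata) {
  metadata <- validate_cohort_metadata(metadata)
  inf <- infants_of(metadata)
  mothers <- unique(inf$pair_id)
  st <- shared_stat_matrices(table, inf$sample_id, mothers)
  idx <- cbind(seq_len(nrow(inf)), match(inf$pair_id, mothers))
  data.frame(infant_sample_id = inf$sample_id,
             mother_sample_id = inf$pair_id,
             n_shared = st$n_shared[idx],
             pct_shared = st$pct_shared[idx],
             shared_abundance = st$shared_abundance[idx],
             stringsAsFactors = FALSE)
}

#' Shared-ASV profiles of every unrelated mother-infant combination
#'
#' The null distribution of sharing statistics: every infant is profiled
#' against every mother in the cohort except its own, giving exactly
#' `n_infants * n_mothers - n_related_links` rows (twin infants each exclude
#' the same single mother). Rows are ordered infant-major with mother ids
#' ascending.
#'
#' @param table Feature table.
#' @param metadata Cohort metadata with at least two distinct mothers.
#' @return data.frame with the same columns as [related_profiles()].
#' @export
unrelated_pair_profiles <- function(table, metadata) {
  metadata <- validate_cohort_metadata(metadata)
  inf <- infants_of(metadata)
  mothers <- sort(mothers_of(metadata))
  if (length(mothers) < 2L) {
    stop("null undefined: cohort has fewer than two mothers")
  }
  st <- shared_stat_matrices(table, inf$sample_id, mothers)
  n_i <- nrow(inf)
  n_m <- length(mothers)
  infant_rep <- rep(inf$sample_id, each = n_m)
  mother_rep <- rep(mothers, times = n_i)
  own <- rep(inf$pair_id, each = n_m) == mother_rep
  idx <- cbind(rep(seq_len(n_i), each = n_m), rep(seq_len(n_m), times = n_i))
  out <- data.frame(infant_sample_id = infant_rep,
                    mother_sample_id = mother_rep,
                    n_shared = st$n_shared[idx],
                    pct_shared = st$pct_shared[idx],
                    shared_abundance = st$shared_abundance[idx],
                    stringsAsFactors = FALSE)
  out <- out[!own, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a sharing statistic between related and unrelated pairs
#'
#' Two-sided Mann-Whitney U comparison of one of the three sharing
#' statistics between biological pairs and the unrelated-pair null, with
#' group medians and ranges. On the ~1e5-element null the normal
#' approximation with tie correction is used; fully tied input yields p = 1
#' with a warning.
#'
#' @param related,unrelated Profile data.frames from [related_profiles()] and
#'   [unrelated_pair_profiles()].
#' @param statistic One of `"n_shared"`, `"pct_shared"`,
#'   `"shared_abundance"`.
#' @return list with `statistic`, per-group `median` and `range`, `U` and
#'   `p_value`.
#' @export
compare_related_vs_unrelated <- function(related, unrelated,
                                         statistic = c("shared_abundance",
                                                       "n_shared",
                                                       "pct_shared")) {
  statistic <- match.arg(statistic)
  x <- related[[statistic]]
  y <- unrelated[[statistic]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  mw <- mann_whitney(x, y, exact = "never")
  list(statistic = statistic,
       related_median = stats::median(x),
       related_range = range(x),
       unrelated_median = stats::median(y),
       unrelated_range = range(y),
       U = mw$U,
       p_value = mw$p_value)
}

#' Per-OTU sharing index across biological pairs
#'
#' For each OTU the index is the number of mother-infant pairs in which
#' mother and infant share at least one member ASV, divided by the number of
#' pairs in which either the mother or the infant carries the OTU. Counting
#' is at pair level, so a mother of twins enters once per pair (dual entry).
#' The index lies in [0,1]; when no pair carries the OTU it is undefined and
#' reported as `NA`.
#'
#' @param table ASV-level feature table.
#' @param metadata Cohort metadata.
#' @param mapping Named character vector, asv_id -> otu_id (e.g. from
#'   [collapse_to_otus()]); must cover every feature of `table`.
#' @param otu_ids OTUs to report (default: all OTUs in `mapping`, in order of
#'   first appearance). Unknown ids are an error.
#' @return data.frame with `otu_id`, `n_pairs_shared`, `n_union`, `index`.
#' @export
sharing_index <- function(table, metadata, mapping, otu_ids = NULL) {
  metadata <- validate_cohort_metadata(metadata)
  m <- unclass_ft(table)
  if (!all(rownames(m) %in% names(mapping))) {
    stop("mapping does not cover feature: ",
         setdiff(rownames(m), names(mapping))[1L])
  }
  all_otus <- unique(unname(mapping))
  if (is.null(otu_ids)) {
    otu_ids <- all_otus
  } else {
    unknown <- setdiff(otu_ids, all_otus)
    if (length(unknown)) stop("unknown OTU: ", unknown[1L])
  }
  inf <- infants_of(metadata)
  check_samples_in_table(table, c(inf$sample_id, inf$pair_id))
  d <- m >= 1L
  di <- d[, inf$sample_id, drop = FALSE] * 1
  dm <- d[, inf$pair_id, drop = FALSE] * 1   # one column per pair
  grp <- mapping[rownames(m)]
  carrier_i <- rowsum(di, grp) > 0           # otus x pairs
  carrier_m <- rowsum(dm, grp) > 0
  share <- rowsum(di * dm, grp) > 0
  n_shared <- rowSums(share)
  n_union <- rowSums(carrier_i | carrier_m)
  res <- data.frame(otu_id = rownames(carrier_i),
                    n_pairs_shared = unname(n_shared),
                    n_union = unname(n_union),
                    stringsAsFactors = FALSE)
  # OTUs in the mapping but absent from every sample
  absent <- setdiff(otu_ids, res$otu_id)
  if (length(absent)) {
    res <- rbind(res, data.frame(otu_id = absent, n_pairs_shared = 0L,
                                 n_union = 0L, stringsAsFactors = FALSE))
  }
  res$index <- ifelse(res$n_union > 0, res$n_pairs_shared / res$n_union, NA)
  res[match(otu_ids, res$otu_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
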