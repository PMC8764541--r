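# Community-level analyses: square-root Bray-Curtis distances, principal
# coordinate analysis, the origin-aware (shared vs nonshared) OTU table, and
# hierarchical clustering of infant microbiota.

#' Bray-Curtis distance matrix
#'
#' \deqn{BC(x, y) = \sum_a |x_a - y_a| / \sum_a (x_a + y_a)}
#' computed on per-sample profiles, optionally after an element-wise square
#' root of each profile (the transform used for all ordination and
#' clustering in this package). Identical profiles give 0, disjoint supports
#' give 1.
#'
#' @param abundances Numeric matrix, features x samples (relative abundances
#'   or counts; no renormalization is applied here).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return Object of class `dist_matrix`: a symmetric numeric matrix with a
#'   zero diagonal and sample ids as dimnames.
#' @export
bray_curtis <- function(abundances, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  m <- unclass_ft(abundances)
  if (is.null(colnames(m))) stop("abundance matrix must carry sample ids")
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("empty profile: ", colnames(m)[which(tot <= 0)[1L]])
  }
  if (transform == "sqrt") m <- sqrt(m)
  num <- as.matrix(stats::dist(t(m), method = "manhattan"))
  cs <- colSums(m)
  d <- num / outer(cs, cs, "+")
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(matrix()))
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \eqn{-\frac{1}{2} D^2} and eigendecomposes it. Coordinates
#' are returned for positive eigenvalues only; negative eigenvalues (which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' unaltered, with no Lingoes or Cailliez correction. On distances that are
#' Euclidean the embedding reproduces them exactly.
#'
#' @param dm Symmetric distance matrix (a `dist_matrix`, plain matrix or
#'   `dist`).
#' @return list of class `pcoa_result` with `points` (samples x positive
#'   axes), `eigenvalues` (all, descending, signed) and
#'   `proportion_explained` (per positive axis, relative to the positive
#'   eigenvalue mass).
#' @export
pcoa <- function(dm) {
  d <- as.matrix(dm)
  if (nrow(d) < 3L) stop("pcoa needs at least three samples")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  a <- -0.5 * d^2
  h <- diag(n) - matrix(1 / n, n, n)
  b <- h %*% a %*% h
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lambda <- e$values
  pos <- lambda > max(lambda, 0) * 1e-12 & lambda > 0
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lambda[pos]), sum(pos), sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = lambda,
                 proportion_explained = lambda[pos] / sum(lambda[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result: ", nrow(x$points), " samples, ", ncol(x$points),
      " positive axes; first axes explain ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 3L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Origin-aware (shared vs nonshared) OTU table for infants
#'
#' For each infant, each OTU's relative abundance is split into the part
#' carried by ASVs shared with the biological mother and the part that is
#' not, giving two features per OTU (`<otu>|shared`, `<otu>|nonshared`).
#' Shared + nonshared reproduces the plain OTU relative abundance exactly.
#'
#' @param table ASV-level feature table.
#' @param metadata Cohort metadata.
#' @param mapping Named character vector asv_id -> otu_id.
#' @return Numeric matrix (2 * n_otus) x n_infants of relative abundances,
#'   with attribute `otu_ids`.
#' @export
build_modified_otu_table <- function(table, metadata, mapping) {
  metadata <- validate_cohort_metadata(metadata)
  m <- unclass_ft(table)
  if (!all(rownames(m) %in% names(mapping))) {
    stop("mapping does not cover feature: ",
         setdiff(rownames(m), names(mapping))[1L])
  }
  inf <- infants_of(metadata)
  check_samples_in_table(table, c(inf$sample_id, inf$pair_id))
  d <- m >= 1L
  rel_i <- sweep(m[, inf$sample_id, drop = FALSE], 2L,
                 colSums(m[, inf$sample_id, drop = FALSE]), "/")
  shared_mask <- d[, inf$sample_id, drop = FALSE] &
    d[, inf$pair_id, drop = FALSE]
  grp <- mapping[rownames(m)]
  shared_part <- rowsum(rel_i * shared_mask, grp)
  nonshared_part <- rowsum(rel_i * !shared_mask, grp)
  otus <- rownames(shared_part)
  out <- rbind(shared_part, nonshared_part)
  rownames(out) <- c(paste0(otus, "|shared"), paste0(otus, "|nonshared"))
  colnames(out) <- inf$sample_id
  ord <- as.vector(rbind(seq_along(otus), seq_along(otus) + length(otus)))
  out <- out[ord, , drop = FALSE]
  attr(out, "otu_ids") <- otus
  out
}

#' Hierarchical clustering of infant microbiota
#'
#' Agglomerative clustering (UPGMA/average linkage by default) on
#' square-root Bray-Curtis distances of the origin-aware table, with the
#' dendrogram cut to exactly `k` groups.
#'
#' @param mot Modified OTU table from [build_modified_otu_table()] (or any
#'   features x infants abundance matrix).
#' @param k Number of clusters (default 8).
#' @param linkage `stats::hclust` method (default `"average"`).
#' @return list of class `infant_clusters`: `assignment` (named integer
#'   vector sample -> cluster), `k`, `tree` (the `hclust` object).
#' @export
cluster_infants <- function(mot, k = 8L, linkage = "average") {
  k <- as.integer(k)
  n <- ncol(mot)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k (", k, ") exceeds number of infants (", n, ")")
  d <- bray_curtis(mot, transform = "sqrt")
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, k = k, tree = tree),
            class = "infant_clusters")
}

#' Compare shared-ASV abundance between infant clusters
#'
#' Per-cluster medians and interquartile ranges of the total shared-ASV
#' abundance, with all-pairs Steel-Dwass p-values computed over clusters
#' holding at least two members.
#'
#' @param clusters An `infant_clusters` object (or a named cluster vector).
#' @param profiles Related-pair profiles ([related_profiles()]).
#' @return list with `summary` (data.frame: cluster, n, median, q1, q3) and
#'   `pairwise` (Steel-Dwass results, see [steel_dwass()]).
#' @export
cluster_shared_abundance_test <- function(clusters, profiles) {
  assignment <- if (inherits(clusters, "infant_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  idx <- match(names(assignment), profiles$infant_sample_id)
  if (anyNA(idx)) {
    stop("cluster member missing from profiles: ",
         names(assignment)[is.na(idx)][1L])
  }
  x <- profiles$shared_abundance[idx]
  groups <- split(x, assignment)
  sizes <- lengths(groups)
  if (sum(sizes >= 2L) < 2L) {
    stop("need at least two clusters with two or more members")
  }
  summary <- data.frame(
    cluster = names(groups),
    n = as.integer(sizes),
    median = vapply(groups, stats::median, numeric(1L)),
    q1 = vapply(groups, stats::quantile, numeric(1L), probs = 0.25,
                names = FALSE),
    q3 = vapply(groups, stats::quantile, numeric(1L), probs = 0.75,
                names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(summary = summary, pairwise = steel_dwass(groups[sizes >= 2L]))
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on whose co-membership the two partitions agree;
#' used to score recovery of planted cluster structure.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Rand index in [0,1].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least two elements")
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}
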