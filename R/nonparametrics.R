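# Hand-implemented nonparametric battery: Mann-Whitney U, Kruskal-Wallis
# with eta-squared effect size, Benjamini-Hochberg step-up FDR, Steel-Dwass
# all-pairs comparisons, and the clinical-factor screen that combines them.
#
# All tests are two-sided. Tie corrections follow the standard midrank
# formulas; see the methods vignette for the exact expressions.

# sum of (t^3 - t) over tie groups of the pooled midranked data
tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic is computed for the first sample,
#' `U = R_x - n_x (n_x + 1) / 2`. The p-value uses the normal approximation
#' with tie correction and (optionally) a 0.5 continuity correction; when
#' both samples have at most 8 observations and the pooled data are
#' tie-free, the exact null distribution of U is enumerated instead.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact `"auto"` (default: exact when feasible), `"never"`, or
#'   `"always"` (error if infeasible).
#' @param continuity Apply the continuity correction on the normal path.
#' @return list with `U`, `p_value`, `method` (`"exact"` or `"normal"`) and
#'   `z` (normal path only).
#' @export
mann_whitney <- function(x, y, exact = c("auto", "never", "always"),
                         continuity = TRUE) {
  exact <- match.arg(exact)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(c(x, y))) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- tie_term(r) > 0
  use_exact <- switch(exact,
    auto = n1 <= 8 && n2 <= 8 && !ties,
    never = FALSE,
    always = {
      if (ties) stop("exact Mann-Whitney requires tie-free data")
      TRUE
    })
  if (use_exact) {
    # enumerate all C(n, n1) placements of x's ranks among 1..n
    combos <- utils::combn(n, n1)
    u_all <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    return(list(U = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
  if (sig2 <= 0) {
    warning("all observations tied; p set to 1")
    return(list(U = u, p_value = 1, method = "normal", z = 0))
  }
  cc <- if (continuity) sign(u - mu) * 0.5 else 0
  z <- (u - mu - cc) / sqrt(sig2)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal", z = z)
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected H statistic over k groups with chi-squared p-value on
#' k - 1 degrees of freedom, and the rank-based effect size
#' \deqn{\eta^2_H = (H - k + 1) / (n - k),}
#' reported both raw and clipped to [0,1].
#'
#' @param groups List of numeric vectors, each non-empty, at least two
#'   groups, total n > k.
#' @return list with `H`, `df`, `p_value`, `eta_squared` (clipped),
#'   `eta_squared_raw`, `group_sizes`.
#' @export
kruskal_wallis_eta2 <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("group of size zero")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stop("groups must not contain NA")
  n <- length(pooled)
  k <- length(groups)
  if (n <= k) stop("total sample size must exceed the number of groups")
  r <- rank(pooled)
  idx <- rep(seq_len(k), sizes)
  rank_sums <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  corr <- 1 - tie_term(r) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  eta_raw <- (h - k + 1) / (n - k)
  list(H = h, df = k - 1L,
       p_value = stats::pchisq(h, k - 1L, lower.tail = FALSE),
       eta_squared = min(1, max(0, eta_raw)),
       eta_squared_raw = eta_raw,
       group_sizes = unname(sizes))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `p_(i) * n / i`, cumulative-minimized from the largest p downwards and
#' capped at 1; values are returned in the original order. Applying the
#' adjustment twice is idempotent.
#'
#' @param pvals Numeric vector of p-values in [0,1].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  p <- as.numeric(pvals)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(1, adj)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Steel-Dwass all-pairs rank comparisons
#'
#' For every pair of groups, ranks are computed within that pair only; the
#' absolute standardized rank sum (with tie correction) is referred to the
#' studentized-range distribution with `k` groups and infinite degrees of
#' freedom via `q = t * sqrt(2)`, giving familywise-error-controlled
#' p-values. With k = 2 this reduces exactly to the two-sided Mann-Whitney
#' normal approximation without continuity correction.
#'
#' @param groups Named list of numeric vectors, at least two groups, each of
#'   size >= 2.
#' @return data.frame with `group1`, `group2`, `statistic` (|t|) and
#'   `p_value`; symmetric in pair order.
#' @export
steel_dwass <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups")
  }
  if (any(lengths(groups) < 2L)) stop("each group needs at least two values")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(pr) {
    gi <- as.numeric(groups[[pr[1L]]])
    gj <- as.numeric(groups[[pr[2L]]])
    ni <- length(gi); nj <- length(gj); nn <- ni + nj
    r <- rank(c(gi, gj))
    ri <- sum(r[seq_len(ni)])
    e <- ni * (nn + 1) / 2
    v <- ni * nj / (nn * (nn - 1)) * (sum(r^2) - nn * (nn + 1)^2 / 4)
    if (v <= 0) {
      warning("fully tied pair; p set to 1")
      return(c(0, 1))
    }
    t_stat <- abs(ri - e) / sqrt(v)
    p <- stats::ptukey(t_stat * sqrt(2), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    c(t_stat, p)
  })
  data.frame(group1 = nm[pairs[1L, ]],
             group2 = nm[pairs[2L, ]],
             statistic = res[1L, ],
             p_value = res[2L, ],
             stringsAsFactors = FALSE)
}

#' Screen clinical factors against shared-ASV abundance
#'
#' For each factor: drop infants with a missing value, run Kruskal-Wallis
#' with eta-squared across the remaining levels, then adjust the raw
#' p-values across all screened factors with Benjamini-Hochberg. Follow-up
#' pairwise comparisons use Mann-Whitney for two-level factors and
#' Steel-Dwass for three or more levels (when every level has >= 2
#' observations). Factors left with fewer than two levels are skipped with a
#' warning.
#'
#' @param profiles Related-pair profiles with `infant_sample_id` and
#'   `shared_abundance` (see [related_profiles()]).
#' @param metadata Cohort metadata.
#' @param factors Character vector of metadata column names to screen.
#' @return list with `screen` (data.frame: factor, k, n, H, eta_squared,
#'   p_raw, p_fdr) and `pairwise` (named list of follow-up results).
#' @export
factor_screen <- function(profiles, metadata, factors) {
  metadata <- validate_cohort_metadata(metadata)
  inf <- infants_of(metadata)
  idx <- match(profiles$infant_sample_id, inf$sample_id)
  if (anyNA(idx)) {
    stop("profile infant missing from metadata: ",
         profiles$infant_sample_id[is.na(idx)][1L])
  }
  missing_cols <- setdiff(factors, names(inf))
  if (length(missing_cols)) {
    stop("unknown factor column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- list()
  pairwise <- list()
  for (f in factors) {
    val <- inf[[f]][idx]
    ok <- !is.na(val)
    groups <- split(profiles$shared_abundance[ok], val[ok])
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) {
      warning("factor '", f, "' has fewer than two non-missing levels; skipped")
      next
    }
    kw <- kruskal_wallis_eta2(groups)
    rows[[f]] <- data.frame(factor = f, k = length(groups),
                            n = sum(lengths(groups)), H = kw$H,
                            eta_squared = kw$eta_squared,
                            p_raw = kw$p_value, stringsAsFactors = FALSE)
    pairwise[[f]] <- if (length(groups) == 2L) {
      mw <- mann_whitney(groups[[1L]], groups[[2L]], exact = "never")
      data.frame(group1 = names(groups)[1L], group2 = names(groups)[2L],
                 statistic = mw$U, p_value = mw$p_value,
                 stringsAsFactors = FALSE)
    } else if (all(lengths(groups) >= 2L)) {
      steel_dwass(groups)
    } else {
      warning("factor '", f, "' has a singleton level; follow-up skipped")
      NULL
    }
  }
  if (!length(rows)) stop("no screenable factors")
  screen <- do.call(rbind, rows)
  rownames(screen) <- NULL
  screen$p_fdr <- benjamini_hochberg(screen$p_raw)
  list(screen = screen, pairwise = pairwise)
}
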