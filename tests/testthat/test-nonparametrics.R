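test_that("exact Mann-Whitney agrees with full enumeration", {
  # x = {1,2}, y = {3,4}: U = 0 and the exact two-sided p is 2/6
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$method, "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 2 / choose(4, 2))
  # tie-free configurations up to n = 6 against wilcox.test's exact path
  set.seed(1)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    pooled <- sample(100, n1 + n2)   # distinct values -> no ties
    x <- pooled[seq_len(n1)]; y <- pooled[-seq_len(n1)]
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$method, "exact")
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation Mann-Whitney matches wilcox.test with ties", {
  set.seed(2)
  for (rep in 1:20) {
    x <- sample(5, 15, replace = TRUE)
    y <- sample(6, 20, replace = TRUE)
    ours <- mann_whitney(x, y)   # ties force the normal path
    expect_equal(ours$method, "normal")
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # identical multisets -> p ~ 1; fully tied data warn and give p = 1
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3), exact = "never")$p_value,
            0.99)
  expect_warning(res <- mann_whitney(rep(1, 5), rep(1, 7)), "tied")
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(3)
  x <- rnorm(7); y <- rnorm(6, 1)
  base <- mann_whitney(x, y)
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) atan(v) * 5)) {
    tr <- mann_whitney(f(x), f(y))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("Kruskal-Wallis H, eta-squared and p match references", {
  # hand computation: ranks 1,2 | 3,4 -> H = 0.6 * 29 - 15 = 2.4
  res <- kruskal_wallis_eta2(list(c(1, 2), c(3, 4)))
  expect_equal(res$H, 2.4)
  expect_equal(res$eta_squared, 0.7)   # (2.4 - 2 + 1) / (4 - 2)
  expect_equal(res$p_value, pchisq(2.4, 1, lower.tail = FALSE))
  # degenerate all-tied input
  res0 <- kruskal_wallis_eta2(list(rep(2, 3), rep(2, 4)))
  expect_equal(res0$H, 0)
  expect_equal(res0$eta_squared, 0)
  expect_lt(res0$eta_squared_raw, 0)
  # tie-corrected H against kruskal.test on random data
  set.seed(4)
  for (rep in 1:10) {
    groups <- lapply(sample(3:5, 3, TRUE), function(n) sample(6, n, TRUE))
    ours <- kruskal_wallis_eta2(groups)
    ref <- kruskal.test(groups)
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # k = 2 identity: H equals the squared uncorrected Mann-Whitney z
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9)
  h <- kruskal_wallis_eta2(list(x, y))$H
  z <- mann_whitney(x, y, exact = "never", continuity = FALSE)$z
  expect_equal(h, z^2, tolerance = 1e-10)
  expect_error(kruskal_wallis_eta2(list(1:3)), "two groups")
  expect_error(kruskal_wallis_eta2(list(1:3, numeric(0))), "size zero")
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(1:20, 1))
    ours <- benjamini_hochberg(p)
    expect_equal(ours, p.adjust(p, "BH"), tolerance = 1e-12)
    # step-up properties: dominates raw p, order-preserving, capped at 1
    expect_true(all(ours >= p - 1e-15))
    expect_true(all(ours <= 1))
    expect_equal(order(ours[order(p)]), seq_along(p))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Steel-Dwass reduces to Mann-Whitney at k = 2 and is symmetric", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    sd_p <- steel_dwass(list(a = x, b = y))$p_value
    mw_p <- mann_whitney(x, y, exact = "never", continuity = FALSE)$p_value
    expect_lt(abs(sd_p - mw_p), 1e-6)
  }
  # label-order invariance
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  fwd <- steel_dwass(g)
  rev <- steel_dwass(g[c(3, 1, 2)])
  key <- function(d) {
    pair <- apply(cbind(d$group1, d$group2), 1,
                  function(r) paste(sort(r), collapse = "-"))
    d$p_value[order(pair)]
  }
  expect_equal(key(fwd), key(rev), tolerance = 1e-12)
  # identical groups -> all p ~ 1
  same <- steel_dwass(list(a = 1:5, b = 1:5, c = 1:5))
  expect_true(all(same$p_value > 0.99))
  expect_error(steel_dwass(list(a = 1:5)), "two groups")
  expect_error(steel_dwass(list(a = 1:5, b = 3)), "at least two values")
})

test_that("Steel-Dwass p decreases with the location shift of a pair", {
  set.seed(8)
  x <- rnorm(20)
  y0 <- rnorm(20)
  shifts <- c(0.2, 0.6, 1.0, 1.6)
  p <- vapply(shifts, function(s) {
    steel_dwass(list(a = x, b = y0 + s, c = rnorm(20)))$p_value[1]
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("Steel-Dwass controls familywise error on null pairs", {
  set.seed(9)
  hits <- replicate(1000, {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
    res <- steel_dwass(g)
    null_pair <- res$group1 == "a" & res$group2 == "b"
    any(res$p_value[null_pair] < 0.05)
  })
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("factor_screen flags the planted feeding effect", {
  sim <- quick_sim(n_pairs = 400, seed = 51)
  prof <- related_profiles(sim$table, sim$metadata)
  res <- factor_screen(prof, sim$metadata,
                       c("feeding", "sex", "delivery", "antibiotics",
                         "smoking", "age_category"))
  screen <- res$screen
  expect_equal(screen$factor[which.max(screen$eta_squared)], "feeding")
  expect_lt(screen$p_fdr[screen$factor == "feeding"], 0.05)
  expect_s3_class(res$pairwise$feeding, "data.frame")   # 3 levels -> Steel-Dwass
  expect_equal(nrow(res$pairwise$feeding), 3)
})

test_that("factor_screen handles missing covariates per factor", {
  sim <- quick_sim(n_pairs = 30, seed = 52)
  md <- sim$metadata
  md$partial <- ifelse(md$role == "infant",
                       c("u", "v")[1 + (seq_len(nrow(md)) %% 2)], NA)
  md$partial[md$role == "infant"][1:10] <- NA
  md$all_missing <- NA_character_
  prof <- related_profiles(sim$table, md)
  expect_warning(
    res <- factor_screen(prof, md, c("feeding", "partial", "all_missing")),
    "fewer than two"
  )
  expect_setequal(res$screen$factor, c("feeding", "partial"))
  expect_equal(res$screen$n[res$screen$factor == "partial"], 20)
})

test_that("factor_screen null rejection rate stays nominal", {
  # no planted effects: tau shifts all zero; 200 simulated screens
  set.seed(53)
  seeds <- sample.int(1e6, 200)
  frac_sig <- vapply(seeds, function(s) {
    sim <- quick_sim(n_pairs = 60, tau0 = 0.1,
                     covariate_effects = c(breast = 0, mixed = 0,
                                           formula = 0),
                     seed = s)
    prof <- related_profiles(sim$table, sim$metadata)
    res <- factor_screen(prof, sim$metadata,
                         c("feeding", "sex", "delivery", "smoking"))
    mean(res$screen$p_fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.05)
})
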