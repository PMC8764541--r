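test_that("bray_curtis matches hand calculation and brute force", {
  m <- cbind(s1 = c(0.8, 0.2), s2 = c(0.2, 0.8))
  rownames(m) <- c("a", "b")
  # sqrt transform: (|0.894-0.447| * 2) / (2 * (0.894 + 0.447)) = 1/3
  d <- bray_curtis(m, transform = "sqrt")
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-9)
  expect_equal(bray_curtis(m, "none")["s1", "s2"], bc_brute(m[, 1], m[, 2]))
  # identical profiles -> 0; disjoint supports -> 1
  m2 <- cbind(s1 = c(0.5, 0.5, 0, 0), s2 = c(0.5, 0.5, 0, 0),
              s3 = c(0, 0, 0.3, 0.7))
  rownames(m2) <- paste0("f", 1:4)
  d2 <- bray_curtis(m2, "sqrt")
  expect_equal(d2["s1", "s2"], 0)
  expect_equal(d2["s1", "s3"], 1)
  # brute-force equality on random 5x5 tables, both transforms
  for (i in 1:10) {
    set.seed(i)
    ra <- relative_abundance(random_table(5, 5))
    for (tr in c("sqrt", "none")) {
      x <- if (tr == "sqrt") sqrt(ra) else ra
      d <- bray_curtis(ra, tr)
      for (a in 1:4) for (b in (a + 1):5) {
        expect_equal(d[a, b], bc_brute(x[, a], x[, b]), tolerance = 1e-12)
      }
    }
  }
  expect_error(bray_curtis(cbind(s1 = c(0, 0), s2 = c(1, 0))),
               "empty profile")
})

test_that("bray_curtis agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(4)
  ra <- relative_abundance(random_table(8, 6))
  expect_equal(unname(bray_curtis(ra, "none")),
               unname(as.matrix(vegan::vegdist(t(ra), "bray"))),
               tolerance = 1e-12)
})

test_that("pcoa recovers Euclidean configurations exactly", {
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2,
                dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  expect_true(all(ord$eigenvalues > -1e-9))
  recon <- as.matrix(dist(ord$points))
  expect_equal(unname(recon), unname(d), tolerance = 1e-9)
  # equilateral triplet: two equal positive eigenvalues
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ot <- pcoa(tri)
  pos <- ot$eigenvalues[ot$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  # duplicated samples coincide
  d2 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  o2 <- pcoa(d2)
  expect_equal(o2$points[1, ], o2$points[2, ], tolerance = 1e-9)
  # validation
  bad <- d; bad[1, 2] <- 9
  expect_error(pcoa(bad), "symmetric")
})

test_that("pcoa agrees with ape on a Bray-Curtis matrix", {
  skip_if_not_installed("ape")
  set.seed(6)
  ra <- relative_abundance(random_table(10, 7))
  d <- bray_curtis(ra, "sqrt")
  ours <- pcoa(d)
  ref <- ape::pcoa(as.dist(d))
  npos <- sum(ours$eigenvalues > 1e-9)
  expect_equal(ours$eigenvalues[seq_len(npos)],
               ref$values$Eigenvalues[seq_len(npos)], tolerance = 1e-8)
  for (ax in 1:2) {  # coordinates up to sign
    expect_equal(abs(ours$points[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("modified OTU table splits abundance and conserves totals", {
  ft <- feature_table(matrix(
    c(5, 30,    # a: shared (in both), OTU R
      0, 10,    # b: infant only, OTU R
      3, 60),   # c: shared, OTU Q
    nrow = 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("M", "I"))))
  md <- data.frame(sample_id = c("M", "I"), subject_id = c("m", "i"),
                   role = c("mother", "infant"), pair_id = c(NA, "M"),
                   stringsAsFactors = FALSE)
  mapping <- c(a = "R", b = "R", c = "Q")
  mot <- build_modified_otu_table(ft, md, mapping)
  expect_equal(mot["R|shared", "I"], 0.3)
  expect_equal(mot["R|nonshared", "I"], 0.1)
  expect_equal(mot["Q|shared", "I"], 0.6)
  expect_equal(mot["Q|nonshared", "I"], 0)
  # conservation against the plain OTU table on a simulated cohort
  sim <- quick_sim(n_pairs = 12, seed = 41)
  mapping <- with(sim$taxonomy, setNames(reference_id, asv_id))
  mot <- build_modified_otu_table(sim$table, sim$metadata, mapping)
  otu <- collapse_to_otus(sim$table, sim$taxonomy)$table
  infants <- colnames(mot)
  rel_otu <- relative_abundance(otu)[, infants]
  for (o in attr(mot, "otu_ids")) {
    expect_equal(mot[paste0(o, "|shared"), ] + mot[paste0(o, "|nonshared"), ],
                 rel_otu[o, ], tolerance = 1e-9)
  }
  expect_true(all(mot >= 0))
  # infants with no shared ASVs have an all-zero shared block
  sim0 <- quick_sim(n_pairs = 6, tau0 = 0, background_rate = 0,
                    covariate_effects = c(breast = 0, mixed = 0, formula = 0),
                    seed = 42)
  mapping0 <- with(sim0$taxonomy, setNames(reference_id, asv_id))
  mot0 <- build_modified_otu_table(sim0$table, sim0$metadata, mapping0)
  expect_true(all(mot0[grepl("\\|shared$", rownames(mot0)), ] == 0))
})

test_that("cluster_infants recovers planted block structure", {
  # k identical-profile blocks are recovered exactly
  block <- function(v, n) matrix(rep(v, n), length(v),
                                 dimnames = list(paste0("f", seq_along(v)),
                                                 NULL))
  m <- cbind(block(c(0.9, 0.1, 0, 0), 4), block(c(0, 0, 0.2, 0.8), 4),
             block(c(0.25, 0.25, 0.25, 0.25), 4))
  colnames(m) <- paste0("i", 1:12)
  cl <- cluster_infants(m, k = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(rand_index(unname(cl$assignment), truth), 1)
  expect_equal(length(unique(cluster_infants(m, k = 1)$assignment)), 1)
  expect_error(cluster_infants(m, k = 13), "exceeds")
  # planted high-tau vs zero-tau regimes separate at k = 2
  sim <- quick_sim(n_pairs = 60, tau0 = 0,
                   covariate_effects = c(breast = 0, mixed = 0,
                                         formula = 0.75),
                   feeding_probs = c(breast = 0.5, mixed = 0, formula = 0.5),
                   background_rate = 0.02, seed = 43)
  mapping <- with(sim$taxonomy, setNames(reference_id, asv_id))
  mot <- build_modified_otu_table(sim$table, sim$metadata, mapping)
  cl <- cluster_infants(mot, k = 2)
  regime <- sim$truth$feeding[match(names(cl$assignment),
                                    sim$truth$infant_sample_id)]
  expect_gt(rand_index(unname(cl$assignment), as.integer(factor(regime))),
            0.9)
})

test_that("cluster_shared_abundance_test summarizes and compares clusters", {
  sim <- quick_sim(n_pairs = 40, seed = 44)
  prof <- related_profiles(sim$table, sim$metadata)
  cl <- structure(list(assignment = setNames(rep(1:2, each = 20),
                                             prof$infant_sample_id),
                       k = 2L), class = "infant_clusters")
  res <- cluster_shared_abundance_test(cl, prof)
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$summary$n, c(20, 20))
  expect_equal(nrow(res$pairwise), 1)
  # two identical clusters -> p ~ 1
  prof2 <- prof
  prof2$shared_abundance <- rep(prof$shared_abundance[1:20], 2)
  res2 <- cluster_shared_abundance_test(cl, prof2)
  expect_gt(res2$pairwise$p_value, 0.9)
  # singleton-only clusters are rejected
  cl_bad <- setNames(seq_len(nrow(prof)), prof$infant_sample_id)
  expect_error(cluster_shared_abundance_test(cl_bad, prof), "two or more")
})

test_that("cluster comparison controls the null and sees a planted shift", {
  set.seed(45)
  rejections <- replicate(200, {
    groups <- split(rnorm(60), rep(1:3, each = 20))
    min(steel_dwass(groups)$p_value) < 0.05
  })
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # one cluster shifted by +0.4 at n = 30/cluster: all its pairwise p < 0.01
  set.seed(46)
  groups <- list(a = rnorm(30, 0, 0.15), b = rnorm(30, 0, 0.15),
                 c = rnorm(30, 0.4, 0.15))
  sd_res <- steel_dwass(groups)
  with_c <- sd_res[sd_res$group1 == "c" | sd_res$group2 == "c", ]
  expect_true(all(with_c$p_value < 0.01))
})
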