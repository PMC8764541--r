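# Synthetic mother-infant paired cohorts with planted, covariate-dependent
# strain transmission. Every downstream stage (shared-ASV statistics, the
# unrelated-pair null, factor screens, clustering) can be validated against
# the ground truth this generator records.
#
# Generative model, in brief:
#   * Adult strain pool: n_adult_otus OTUs, each with strains_per_otu ASVs;
#     strain pools are disjoint across OTUs. Each mother carries exactly one
#     strain per adult OTU (chosen uniformly) with lognormal OTU weights.
#   * Infant OTUs form a second, adult-disjoint pool; each infant carries one
#     strain per infant OTU with its own lognormal weights.
#   * Acquisition is per strain: for each adult OTU the infant acquires its
#     own mother's strain with probability tau_i (tau0 plus a feeding-method
#     shift, clipped to [0,1]) and every other strain of that OTU with
#     probability beta (the environmental background). Acquired strains of an
#     OTU split the mother's OTU weight equally, so the infant's adult-derived
#     abundances mirror the maternal oral environment; at tau0 == beta the
#     process is exchangeable across mothers and related vs unrelated sharing
#     coincide in distribution.
#   * Reads are multinomial at depth ~ Normal(depth_mean, depth_sd) truncated
#     below at depth_min.

#' Configuration for a synthetic mother-infant cohort
#'
#' Defaults describe a desk-scale cohort patterned on a 4-month-checkup
#' tongue-swab study: ~5,500 reads per sample, feeding-method frequencies of
#' 57.2/29.4/13.5 percent (breast/mixed/formula), cesarean rate 19.6 percent,
#' and a baseline transmitted fraction of about 10 percent of the infant
#' community with formula-fed infants shifted upwards.
#'
#' @param n_pairs Number of mother-infant pairs (= infants).
#' @param twin_fraction Fraction of infants that are members of a twin pair
#'   sharing one mother (default 8/448).
#' @param n_adult_otus,strains_per_otu,n_infant_otus Pool sizes.
#' @param adult_lognormal_mu,adult_lognormal_sigma Lognormal parameters for
#'   adult OTU weights.
#' @param infant_lognormal_sigma Lognormal sigma for infant-specific OTU
#'   weights (mu fixed at 0; weights are normalized).
#' @param tau0 Baseline transmitted community fraction, in [0,1].
#' @param covariate_effects Named numeric vector of additive shifts on tau by
#'   feeding level (`breast`, `mixed`, `formula`).
#' @param background_rate Probability beta that an infant acquires any given
#'   non-maternal adult strain.
#' @param feeding_probs Sampling probabilities for the three feeding levels.
#' @param depth_mean,depth_sd,depth_min Read-depth model (normal, truncated
#'   below at `depth_min`).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 200L,
                       twin_fraction = 8 / 448,
                       n_adult_otus = 60L,
                       strains_per_otu = 12L,
                       n_infant_otus = 15L,
                       adult_lognormal_mu = 0,
                       adult_lognormal_sigma = 1.2,
                       infant_lognormal_sigma = 1.2,
                       tau0 = 0.10,
                       covariate_effects = c(breast = 0, mixed = 0.05,
                                             formula = 0.15),
                       background_rate = 0.02,
                       feeding_probs = c(breast = 255, mixed = 131,
                                         formula = 60) / 446,
                       depth_mean = 5493.4,
                       depth_sd = 1730.2,
                       depth_min = 500L,
                       seed = NULL) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              twin_fraction = twin_fraction,
              n_adult_otus = as.integer(n_adult_otus),
              strains_per_otu = as.integer(strains_per_otu),
              n_infant_otus = as.integer(n_infant_otus),
              adult_lognormal_mu = adult_lognormal_mu,
              adult_lognormal_sigma = adult_lognormal_sigma,
              infant_lognormal_sigma = infant_lognormal_sigma,
              tau0 = tau0,
              covariate_effects = covariate_effects,
              background_rate = background_rate,
              feeding_probs = feeding_probs,
              depth_mean = depth_mean,
              depth_sd = depth_sd,
              depth_min = as.integer(depth_min),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  frac <- c(twin_fraction = cfg$twin_fraction, tau0 = cfg$tau0,
            background_rate = cfg$background_rate)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad)) stop("fractions must lie in [0,1]: ",
                        paste(bad, collapse = ", "))
  if (cfg$n_pairs < 1L) stop("n_pairs must be positive")
  if (cfg$tau0 + max(c(0, cfg$covariate_effects)) > 1 + 1e-12) {
    stop("tau0 + max covariate shift exceeds 1")
  }
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (!setequal(names(cfg$feeding_probs), c("breast", "mixed", "formula"))) {
    stop("feeding_probs must be named breast/mixed/formula")
  }
  class(cfg) <- "sim_config"
  cfg
}

clip01 <- function(x) pmin(1, pmax(0, x))

# one lognormal weight profile per column, columns normalized to sum 1
lognormal_profiles <- function(n_feat, n_samp, mu, sigma) {
  w <- matrix(stats::rlnorm(n_feat * n_samp, mu, sigma), n_feat, n_samp)
  sweep(w, 2L, colSums(w), "/")
}

#' Simulate a mother-infant paired cohort with planted transmission
#'
#' See the package source header and the methods vignette for the generative
#' model. Returns the count table, metadata, taxonomy map and a truth ledger
#' recording, per infant, the target transmitted fraction and the identities
#' of the ASVs planted from the biological mother.
#'
#' @param config A [sim_config()].
#' @return list with elements `table` ([feature_table()]), `metadata`
#'   (cohort metadata data.frame), `taxonomy` (taxonomy map) and `truth`
#'   (data.frame with `infant_sample_id`, `tau_target`, `feeding` and a
#'   list-column `transmitted_asvs`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)

  n_inf <- config$n_pairs
  n_twin_pairs <- round(config$twin_fraction * n_inf / 2)
  if (2 * n_twin_pairs > n_inf) stop("twin_fraction too large for n_pairs")
  n_mo <- n_inf - n_twin_pairs
  if (n_mo < 1L) stop("cohort must contain at least one mother")

  K <- config$n_adult_otus      # adult OTUs
  S <- config$strains_per_otu   # strains per adult OTU
  J <- config$n_infant_otus     # infant-specific OTUs

  mother_ids <- sprintf("M%04d", seq_len(n_mo))
  infant_ids <- sprintf("I%04d", seq_len(n_inf))
  # twin infants occupy the first 2 * n_twin_pairs slots, two per mother
  mother_of <- c(rep(seq_len(n_twin_pairs), each = 2L),
                 seq_len(n_inf - 2L * n_twin_pairs) + n_twin_pairs)

  adult_asvs <- if (K > 0) {
    as.vector(t(outer(seq_len(K), seq_len(S),
                      function(o, s) sprintf("ASVa%03d.%02d", o, s))))
  } else character()
  infant_asvs <- if (J > 0) {
    as.vector(t(outer(seq_len(J), seq_len(S),
                      function(o, s) sprintf("ASVi%03d.%02d", o, s))))
  } else character()
  all_asvs <- c(adult_asvs, infant_asvs)
  if (!length(all_asvs)) stop("infeasible config: no feature pools defined")
  adult_asv_index <- function(otu, strain) (otu - 1L) * S + strain

  # ---- mothers -------------------------------------------------------------
  # strain choice (K x n_mo) and OTU weight profile (K x n_mo)
  strain_of <- matrix(sample.int(S, K * n_mo, replace = TRUE), K, n_mo)
  w_mother <- lognormal_profiles(K, n_mo, config$adult_lognormal_mu,
                                 config$adult_lognormal_sigma)

  profiles <- matrix(0, length(all_asvs), n_mo + n_inf,
                     dimnames = list(all_asvs, c(mother_ids, infant_ids)))
  if (K > 0) {
    rows <- adult_asv_index(rep(seq_len(K), n_mo), as.vector(strain_of))
    cols <- rep(seq_len(n_mo), each = K)
    profiles[cbind(rows, cols)] <- as.vector(w_mother)
  }

  # ---- infants -------------------------------------------------------------
  feeding <- sample(names(config$feeding_probs), n_inf, replace = TRUE,
                    prob = config$feeding_probs)
  shift <- config$covariate_effects[feeding]
  shift[is.na(shift)] <- 0
  tau <- clip01(config$tau0 + as.numeric(shift))
  beta <- config$background_rate

  transmitted <- vector("list", n_inf)
  for (i in seq_len(n_inf)) {
    m <- mother_of[i]
    raw <- numeric(length(all_asvs))
    acquired_own <- integer(0)
    if (K > 0) {
      own <- strain_of[, m]
      # acceptance probability per strain: tau for the maternal strain,
      # beta for every other strain of the OTU
      u <- matrix(stats::runif(S * K), S, K)
      thresh <- matrix(beta, S, K)
      thresh[cbind(own, seq_len(K))] <- tau[i]
      acq <- u < thresh                       # S x K
      n_acq <- colSums(acq)
      got <- n_acq > 0
      if (any(got)) {
        share <- w_mother[, m] / pmax(n_acq, 1L)
        rows <- adult_asv_index(rep(seq_len(K), each = S)[acq],
                                rep(seq_len(S), K)[acq])
        raw[rows] <- share[rep(seq_len(K), each = S)[acq]]
      }
      own_rows <- adult_asv_index(seq_len(K), own)
      acquired_own <- own_rows[acq[cbind(own, seq_len(K))]]
    }
    m_spec <- max(0, 1 - tau[i] - beta)
    if (J > 0 && m_spec > 0) {
      wi <- stats::rlnorm(J, 0, config$infant_lognormal_sigma)
      wi <- wi / sum(wi) * m_spec
      strain_i <- sample.int(S, J, replace = TRUE)
      rows <- length(adult_asvs) + (seq_len(J) - 1L) * S + strain_i
      raw[rows] <- wi
    }
    if (sum(raw) <= 0) {
      stop("infeasible config: infant ", infant_ids[i],
           " has an empty community (tau=", signif(tau[i], 3),
           ", beta=", beta, ", no acquirable pool)")
    }
    profiles[, n_mo + i] <- raw / sum(raw)
    transmitted[[i]] <- all_asvs[acquired_own]
  }

  # ---- read sampling -------------------------------------------------------
  n_samp <- n_mo + n_inf
  depth <- pmax(config$depth_min,
                round(stats::rnorm(n_samp, config$depth_mean, config$depth_sd)))
  counts <- matrix(0L, length(all_asvs), n_samp,
                   dimnames = dimnames(profiles))
  for (j in seq_len(n_samp)) {
    counts[, j] <- stats::rmultinom(1L, depth[j], profiles[, j])[, 1L]
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  table <- feature_table(counts)

  # planted transmissions restricted to ASVs actually detected in the mother
  det <- detection_matrix(table)
  transmitted <- lapply(seq_len(n_inf), function(i) {
    tr <- intersect(transmitted[[i]], rownames(counts))
    tr[det[tr, mother_ids[mother_of[i]]]]
  })

  # ---- metadata ------------------------------------------------------------
  sex <- sample(c("female", "male"), n_inf, TRUE, prob = c(231, 217) / 448)
  age_category <- sample(c("3mo", "4mo", "5mo+"), n_inf, TRUE,
                         prob = c(113, 312, 20) / 445)
  delivery <- sample(c("vaginal", "cesarean"), n_inf, TRUE,
                     prob = c(360, 88) / 448)
  antibiotics <- sample(c("none", "within_1mo"), n_inf, TRUE,
                        prob = c(428, 20) / 448)
  smoking <- sample(c("no", "yes"), n_inf, TRUE, prob = c(288, 160) / 448)
  gestational_wk <- round(stats::rnorm(n_inf, 39, 1.25), 1)
  birth_weight_g <- round(stats::rnorm(n_inf, 3000, 360))
  current_weight_g <- round(stats::rnorm(n_inf, 6734.7, 814.4))
  height_cm <- round(stats::rnorm(n_inf, 64, 2.2), 1)

  metadata <- rbind(
    data.frame(sample_id = mother_ids,
               subject_id = paste0("mother_", seq_len(n_mo)),
               role = "mother", pair_id = NA_character_,
               sex = NA_character_, age_category = NA_character_,
               feeding = NA_character_, delivery = NA_character_,
               antibiotics = NA_character_, smoking = NA_character_,
               gestational_wk = NA_real_, birth_weight_g = NA_real_,
               current_weight_g = NA_real_, height_cm = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(sample_id = infant_ids,
               subject_id = paste0("infant_", seq_len(n_inf)),
               role = "infant", pair_id = mother_ids[mother_of],
               sex = sex, age_category = age_category, feeding = feeding,
               delivery = delivery, antibiotics = antibiotics,
               smoking = smoking, gestational_wk = gestational_wk,
               birth_weight_g = birth_weight_g,
               current_weight_g = current_weight_g, height_cm = height_cm,
               stringsAsFactors = FALSE)
  )
  metadata <- validate_cohort_metadata(metadata)

  # ---- taxonomy ------------------------------------------------------------
  genera <- c("Streptococcus", "Neisseria", "Prevotella", "Veillonella",
              "Granulicatella", "Haemophilus", "Rothia", "Actinomyces")
  # "ASVa007.03" -> "OTUA007"; strain pools are disjoint across OTUs, so the
  # reference id is recoverable from the ASV id itself
  reference_id <- toupper(sub("^ASV", "OTU", sub("\\.\\d+$", "", all_asvs)))
  taxonomy <- data.frame(
    asv_id = all_asvs,
    reference_id = reference_id,
    identity_pct = 99.2,
    taxon_label = genera[(as.integer(factor(reference_id)) - 1L) %%
                           length(genera) + 1L],
    stringsAsFactors = FALSE
  )
  taxonomy <- taxonomy[taxonomy$asv_id %in% rownames(counts), , drop = FALSE]
  rownames(taxonomy) <- NULL

  truth <- data.frame(infant_sample_id = infant_ids,
                      mother_sample_id = mother_ids[mother_of],
                      tau_target = tau, feeding = feeding,
                      stringsAsFactors = FALSE)
  truth$transmitted_asvs <- transmitted

  list(table = table, metadata = metadata, taxonomy = taxonomy, truth = truth)
}

#' Realized relative abundance of the planted transmitted ASVs
#'
#' For each infant, the cumulative relative abundance (in the infant's
#' realized reads) of the ASVs the truth ledger marks as transmitted from the
#' biological mother. This is the recovery target for the shared-ASV
#' estimator.
#'
#' @param truth Truth ledger from [simulate_cohort()].
#' @param table Feature table from the same simulation.
#' @return Named numeric vector, one fraction per infant sample.
#' @export
planted_shared_fraction <- function(truth, table) {
  m <- unclass_ft(table)
  if (!all(truth$infant_sample_id %in% colnames(m))) {
    stop("truth ledger and table disagree: unknown infant sample")
  }
  if (!all(unlist(truth$transmitted_asvs) %in% rownames(m))) {
    stop("truth ledger and table disagree: unknown transmitted ASV")
  }
  rel <- relative_abundance(m)
  out <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth$transmitted_asvs[[i]]
    if (!length(tr)) return(0)
    sum(rel[tr, truth$infant_sample_id[i]])
  }, numeric(1L))
  names(out) <- truth$infant_sample_id
  out
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits `table.tsv`, `metadata.tsv`, `taxonomy.tsv` and `truth.tsv`
#' (transmitted ASVs comma-joined).
#'
#' @param sim Result of [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(sim$table, file.path(outdir, "table.tsv"))
  write_cohort_metadata(sim$metadata, file.path(outdir, "metadata.tsv"))
  write_taxonomy_map(sim$taxonomy, file.path(outdir, "taxonomy.tsv"))
  truth <- sim$truth
  truth$transmitted_asvs <- vapply(truth$transmitted_asvs, paste,
                                   character(1L), collapse = ",")
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(outdir)
}
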