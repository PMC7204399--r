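test_that("rank-statistic AUC equals brute force and pROC on tied data", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- round(runif(12), 1)          # rounding forces ties
    neg <- round(runif(30), 1)
    expect_equal(auc_rank(pos, neg), oracle_auc(pos, neg))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(12, 30)), predictor = c(pos, neg),
      quiet = TRUE, direction = "<"
    )))
    expect_equal(auc_rank(pos, neg), ref)
  }
})

test_that("ROC curves are monotone, anchored, and integrate to the AUC", {
  set.seed(7)
  pos <- round(rnorm(20), 1)
  neg <- round(rnorm(50, -0.5), 1)
  roc <- roc_points(pos, neg)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(area, auc_rank(pos, neg), tolerance = 1e-12)
})

test_that("LOOCV with perfect separation gives AUC 1", {
  # planted noiseless world: every held-out positive still projects high
  sim <- generate_synthetic(synthetic_spec(
    n_mirna = 12, n_disease = 8, n_groups = 2, p_in = 1, p_out = 0,
    kernel_signal = 1, noise_sd = 0, seed = 5
  ))
  cfg <- model_config(fusion = fusion_config(k_neighbors = 4, iterations = 3))
  ev <- loocv(sim$association, sim$kernels, cfg)
  expect_equal(ev$auc, 1)
  expect_true(all(ev$fold_records$n_outranking == 0))
})

test_that("a single known association yields the closed-form step ROC", {
  MD <- matrix(0, 4, 3, dimnames = list(rnd_names("m", 4), rnd_names("d", 3)))
  MD[2, 2] <- 1
  ad <- association_data(MD)
  kl <- random_kernels(ad, seed = 14)
  cfg <- tiny_config(k = 3)
  ev <- loocv(ad, kl, cfg)
  expect_equal(length(ev$pos_scores), 1L)
  # AUC = 1 - (rank - 1)/|candidates| under the tie-aware rule
  cand <- ev$neg_scores
  p <- ev$pos_scores
  expect_equal(ev$auc, (sum(p > cand) + 0.5 * sum(p == cand)) / length(cand))
  expect_gte(nrow(ev$roc_points), 2L)   # degenerate all-tied fold is legal
})

test_that("uniform-noise scores give AUC inside the permutation null band", {
  set.seed(31)
  pos <- runif(40)
  neg <- runif(400)
  a <- auc_rank(pos, neg)
  nb <- auc_permutation_null(pos, neg, n_reps = 200, seed = 99)
  expect_gt(a, nb$quantiles[[1]])
  expect_lt(a, nb$quantiles[[2]])
  expect_true(all(nb$draws >= 0 & nb$draws <= 1))
  expect_lt(abs(mean(nb$draws) - 0.5), 0.05)
})

test_that("evaluation protocols leave the input data unmodified", {
  ad <- random_ad(8, 6, p = 0.35, seed = 18)
  before <- ad$MD
  kl <- random_kernels(ad, seed = 18)
  cfg <- tiny_config(k = 4)
  invisible(loocv(ad, kl, cfg))
  expect_identical(ad$MD, before)
  invisible(loocv_entity(ad, kl, cfg, "new_mirna"))
  invisible(loocv_entity(ad, kl, cfg, "isolated_disease"))
  expect_identical(ad$MD, before)
})

test_that("per-fold recomputation is engaged: masking changes the Hamming kernel", {
  ad <- random_ad(8, 6, p = 0.35, seed = 18)
  known <- which(ad$MD == 1, arr.ind = TRUE)
  masked <- ad
  masked$MD[known[1, 1], known[1, 2]] <- 0
  expect_false(isTRUE(all.equal(
    as.matrix(hamming_similarity(masked, "disease")),
    as.matrix(hamming_similarity(ad, "disease"))
  )))
  # and consequently fast (frozen-similarity) and full LOOCV differ
  kl <- random_kernels(ad, seed = 18)
  cfg <- tiny_config(k = 4)
  full <- loocv(ad, kl, cfg)
  fast <- loocv(ad, kl, cfg, fast_loocv = TRUE)
  expect_false(isTRUE(all.equal(full$pos_scores, fast$pos_scores)))
})

test_that("fast and full LOOCV agree exactly under constant Hamming kernels", {
  ad <- random_ad(7, 5, p = 0.4, seed = 25)
  kl <- random_kernels(ad, seed = 25)
  cfg <- tiny_config(k = 4)
  override <- list(mirna = random_kernel(7, 91, ad$mirna_names, "hamming"),
                   disease = random_kernel(5, 92, ad$disease_names, "hamming"))
  full <- loocv(ad, kl, cfg, fast_loocv = FALSE, hamming_override = override)
  fast <- loocv(ad, kl, cfg, fast_loocv = TRUE, hamming_override = override)
  expect_equal(full$pos_scores, fast$pos_scores)
  expect_equal(full$auc, fast$auc)
})

test_that("entity masking zeroes the whole profile before recomputation", {
  MD <- matrix(0, 5, 4, dimnames = list(rnd_names("m", 5), rnd_names("d", 4)))
  MD[, 2] <- 1                        # one all-positive disease column
  MD[1, 1] <- 1
  ad <- association_data(MD)
  kl <- random_kernels(ad, seed = 8)
  cfg <- tiny_config(k = 4, gamma = 1)  # disease projection only
  ev <- loocv_entity(ad, kl, cfg, "isolated_disease")
  expect_true(all(is.finite(ev$pos_scores)))
  rec <- ev$fold_records[ev$fold_records$entity_id == "d02", ]
  expect_equal(rec$n_positives, 5L)   # whole column was held out and scored
  evm <- loocv_entity(ad, kl, cfg, "new_mirna")
  expect_true(all(is.finite(evm$pos_scores)))
})

test_that("entity protocols beat the permutation null on planted data", {
  sim <- generate_synthetic(synthetic_spec(n_mirna = 24, n_disease = 16,
                                           n_groups = 2, seed = 9))
  cfg <- model_config(fusion = fusion_config(k_neighbors = 8, iterations = 5))
  ev <- loocv_entity(sim$association, sim$kernels, cfg, "new_mirna")
  nb <- auc_permutation_null(ev, n_reps = 200, seed = 17)
  expect_gt(ev$auc, nb$quantiles[[2]])
})

test_that("parameter sweep reproduces direct calls and flags the argmax", {
  ad <- random_ad(8, 6, p = 0.35, seed = 40)
  kl <- random_kernels(ad, seed = 40)
  cfg <- tiny_config(k = 4)
  one <- parameter_sweep(ad, kl, alpha = 0.02, gamma = 0.27, config = cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$auc, loocv(ad, kl, cfg)$auc)
  expect_equal(one$beta, one$alpha)   # tied by default

  tb <- parameter_sweep(ad, kl, alpha = c(0, 0.1), gamma = 0.5, config = cfg)
  tb2 <- parameter_sweep(ad, kl, alpha = c(0, 0.1), gamma = 0.5, config = cfg)
  expect_identical(tb$auc, tb2$auc)   # deterministic
  best <- attr(tb, "best")
  expect_true(all(best$auc >= tb$auc))
})

test_that("candidate ranking excludes known pairs and breaks ties by name", {
  ad <- random_ad(8, 5, p = 0.4, seed = 55)
  kl <- random_kernels(ad, seed = 55)
  sc <- predict_associations(ad, kl, tiny_config(k = 4))
  d <- ad$disease_names[2]
  tb <- rank_candidates(sc, d, top_n = 100)
  expect_equal(nrow(tb), sum(ad$MD[, 2] == 0))   # capped at candidate count
  expect_false(any(tb$mirna_id %in% ad$mirna_names[ad$MD[, 2] == 1]))
  expect_identical(tb$score, sort(tb$score, decreasing = TRUE))

  sc$Fpf[] <- 0.5                                # force total ties
  tb2 <- rank_candidates(sc, d, top_n = 3)
  expect_identical(tb2$mirna_id, sort(tb2$mirna_id)[1:3])
  expect_error(rank_candidates(sc, "nope"), "unknown disease")
})

test_that("planted-block miRNAs are enriched among a disease's top candidates", {
  sim <- generate_synthetic(synthetic_spec(n_mirna = 40, n_disease = 20,
                                           n_groups = 2, p_in = 0.5,
                                           p_out = 0.02, seed = 11))
  cfg <- model_config(fusion = fusion_config(k_neighbors = 10, iterations = 5))
  sc <- predict_associations(sim$association, sim$kernels, cfg)
  d <- sim$association$disease_names[1]
  grp <- sim$disease_groups[[d]]
  top <- rank_candidates(sc, d, top_n = 10)
  same_block <- mean(sim$mirna_groups[top$mirna_id] == grp)
  # hypergeometric expectation: block share of eligible candidates
  eligible <- sim$association$MD[, d] == 0
  base_rate <- mean(sim$mirna_groups[eligible] == grp)
  expect_gt(same_block, base_rate)
})

test_that("tidiers and plots expose the evaluation results", {
  ad <- random_ad(6, 5, p = 0.4, seed = 60)
  kl <- random_kernels(ad, seed = 60)
  ev <- loocv(ad, kl, tiny_config(k = 3))
  expect_identical(tidy(ev), ev$roc_points)
  g <- glance(ev)
  expect_equal(g$auc, ev$auc)
  expect_s3_class(autoplot(ev), "ggplot")
  sc <- predict_associations(ad, kl, tiny_config(k = 3))
  expect_s3_class(autoplot(sc), "ggplot")
  f <- withr::local_tempfile()
  paths <- write_eval_report(ev, f)
  expect_true(all(file.exists(paths)))
  summ <- yaml::read_yaml(paths[["summary"]])
  expect_equal(summ$auc, ev$auc, tolerance = 1e-9)
})
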