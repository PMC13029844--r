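test_that("topk accuracy counts ranked hits and scores None as wrong", {
  classes <- c("A", "B", "C")
  # 10 samples: 7 hits at top-1, 2 more within the deeper list
  mat <- rbind(matrix(rep(c(1L, 2L, 3L), 7), ncol = 3, byrow = TRUE),
               c(2L, 1L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L))
  r <- make_rankings(mat, classes)
  labels <- rep("A", 10)
  expect_equal(topk_accuracy(r, labels, 1), 0.7)
  expect_equal(topk_accuracy(r, labels, 3), 1.0)
  expect_equal(topp_accuracy(r, labels, 2), 0.8)
  # complete ranking at k = C is always 1
  expect_equal(topk_accuracy(r, rep("C", 10), 3), 1)

  dec <- structure(data.frame(pred = c("A", "B", NA), tie = c(FALSE, FALSE, TRUE)),
                   class = c("ensemble_decision", "data.frame"))
  expect_equal(topk_accuracy(dec, c("A", "B", "C")), 2 / 3)
  expect_equal(topk_accuracy(dec, c("A", "A", "A")), 1 / 3)
  expect_error(topk_accuracy(dec[0, ], character(0)), "empty")
})

test_that("scenario A cross-validates at trial level within subjects", {
  cfg <- noiseless_config(n_subjects = 3, trials = 10, seed = 51)
  study <- build_study(cfg)
  rep_a <- run_scenario("A", study$unloaded, study$loaded,
                        configs = list(nc = list(architecture = "nearest_centroid")),
                        seed = 2, T = 3, folds = 5,
                        lambda_grid = seq(0.5, 2, by = 0.5))
  # noiseless, perfectly separable: every fold classifies perfectly
  expect_equal(rep_a$base$top1, 1)
  expect_equal(rep_a$base$top1_sd, 0)
  expect_equal(rep_a$ensemble$accuracy, c(1, 1))
  expect_equal(rep_a$folds, 5)
  # a subject with fewer trials than folds is refused
  expect_error(run_scenario("A", study$unloaded, study$loaded,
                            configs = list(nc = list(architecture = "nearest_centroid")),
                            seed = 2, folds = 11),
               "fewer cycles than folds")
})

test_that("scenarios B and C train on unloaded data only", {
  cfg <- small_config(n_subjects = 3, trials = 5, seed = 52)
  study <- build_study(cfg)
  configs <- list(nc = list(architecture = "nearest_centroid"),
                  nc_v = list(architecture = "nearest_centroid",
                              config = list(channels = c(2, 5))))
  rep_b <- run_scenario("B", study$unloaded, study$loaded, configs,
                        seed = 3, T = 3, lambda_grid = seq(0.5, 2, by = 0.5))
  expect_equal(rep_b$train_size, 15)
  expect_equal(rep_b$test_size, 15)
  rep_c <- run_scenario("C", study$unloaded, study$loaded, configs,
                        seed = 3, T = 3, lambda_grid = seq(0.5, 2, by = 0.5))
  # the augmented training set is nine times scenario B's
  expect_equal(rep_c$train_size, 9 * rep_b$train_size)
  expect_equal(rep_c$test_size, rep_b$test_size)
  expect_s3_class(rep_b$decisions$topT, "ensemble_decision")
  expect_equal(nrow(rep_b$decisions$topT), 15)
})

test_that("leave-one-out ablation recomputes ranks for each K - 1 subset", {
  classes <- c("A", "B", "C")
  set.seed(61)
  M <- 40
  labels_val <- sample(classes, M, replace = TRUE)
  labels_test <- sample(classes, M, replace = TRUE)
  noisy_post <- function(labels, good) {
    P <- matrix(runif(length(labels) * 3), ncol = 3)
    hit <- runif(length(labels)) < good
    P[cbind(seq_along(labels), match(labels, classes))] <-
      ifelse(hit, 2, P[cbind(seq_along(labels), match(labels, classes))])
    P <- P / rowSums(P)
    colnames(P) <- classes
    P
  }
  val <- list(noisy_post(labels_val, 0.9), noisy_post(labels_val, 0.7),
              noisy_post(labels_val, 0.5))
  tst <- list(noisy_post(labels_test, 0.9), noisy_post(labels_test, 0.7),
              noisy_post(labels_test, 0.5))
  for (j in 1:3) attr(val[[j]], "classifier_id") <-
    attr(tst[[j]], "classifier_id") <- paste0("m", j)

  ab <- ablate_leave_one_out(val, labels_val, tst, labels_test,
                             strategy = "topT", lambda = "sweep", T = 2,
                             lambda_grid = seq(0.5, 2, by = 0.5))
  expect_equal(ab$removed, c("none", "m1", "m2", "m3"))
  expect_equal(ab$delta[1], 0)
  expect_equal(ab$delta[-1], ab$accuracy[-1] - ab$accuracy[1])
  expect_true(all(ab$ties >= 0))

  # identical classifiers: removing any one changes nothing
  same <- list(val[[1]], val[[1]], val[[1]])
  same_t <- list(tst[[1]], tst[[1]], tst[[1]])
  ab2 <- ablate_leave_one_out(same, labels_val, same_t, labels_test,
                              strategy = "rank_order")
  expect_equal(ab2$delta, rep(0, 4))

  expect_error(ablate_leave_one_out(val[1], labels_val, tst[1], labels_test),
               "at least 2")
})

test_that("removing the sole correct voter lowers accuracy, per brute force", {
  classes <- c("A", "B")
  # validation accuracies 1.0 / 0.75 / 0.5 give weights 1, 2/3, 1/3
  labels_val <- c("A", "A", "B", "B")
  v_good <- post_matrix(list(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8),
                             c(0.1, 0.9)), classes, id = "good")
  v_med <- post_matrix(list(c(0.6, 0.4), c(0.8, 0.2), c(0.3, 0.7),
                            c(0.6, 0.4)), classes, id = "med")
  v_weak <- post_matrix(list(c(0.6, 0.4), c(0.3, 0.7), c(0.2, 0.8),
                             c(0.7, 0.3)), classes, id = "weak")
  # test: only "good" votes A on the true-A samples; its vote (weight 1)
  # ties the med+weak coalition (2/3 + 1/3) and the tie resolves to the
  # best classifier's Top-1
  labels_test <- c("A", "A")
  t_good <- post_matrix(list(c(0.9, 0.1), c(0.9, 0.1)), classes, id = "good")
  t_med <- post_matrix(list(c(0.3, 0.7), c(0.3, 0.7)), classes, id = "med")
  t_weak <- post_matrix(list(c(0.3, 0.7), c(0.3, 0.7)), classes, id = "weak")
  val <- list(v_good, v_med, v_weak)
  tst <- list(t_good, t_med, t_weak)
  ab <- ablate_leave_one_out(val, labels_val, tst, labels_test,
                             strategy = "rank_order", T = 1)
  full_acc <- ab$accuracy[ab$removed == "none"]
  drop_good <- ab$accuracy[ab$removed == "good"]
  expect_lt(drop_good, full_acc)
  # brute-force check of the full-ensemble decision
  rf <- rank_fusion(val, labels_val, T = 1)
  rankings <- lapply(tst, top_rankings, T = 1)
  sc <- brute_scores(rankings, rf, strategy = "rank_order")
  bd <- brute_decide(rankings, rf, sc)
  expect_equal(mean(!is.na(bd$pred) & bd$pred == labels_test), full_acc)
})

test_that("mass-gap analysis pairs errors with body-mass differences", {
  roster <- data.frame(subject_id = c("A", "B", "C"),
                       body_mass_kg = c(60, 62, 71))
  # two errors: A predicted as B (gap 2) and C predicted as B (gap 9)
  dec <- c("B", "B", "B")
  labels <- c("A", "B", "C")
  mg <- mass_confusion_analysis(dec, labels, roster)
  expect_equal(mg$n_errors, 2)
  expect_equal(sort(mg$gaps_kg), c(2, 9))
  expect_equal(mg$ecdf$fraction[mg$ecdf$threshold_kg == 4.6], 0.5)
  expect_equal(sum(mg$hist$count), 2)
  # histogram bins at 1 kg: gap 2 falls in (1,2], gap 9 in (8,9]
  expect_equal(mg$hist$count[mg$hist$bin_lo == 1], 1)
  expect_equal(mg$hist$count[mg$hist$bin_lo == 8], 1)

  # zero errors: empty histogram, ECDF reported as undefined
  mg0 <- mass_confusion_analysis(labels, labels, roster)
  expect_equal(mg0$n_errors, 0)
  expect_equal(nrow(mg0$hist), 0)
  expect_true(all(is.na(mg0$ecdf$fraction)))

  # None decisions count as errors but contribute no pair
  mgn <- mass_confusion_analysis(c(NA, "B", "C"), labels, roster)
  expect_equal(mgn$n_errors, 1)
  expect_equal(mgn$n_none, 1)
  expect_length(mgn$gaps_kg, 0)

  expect_error(mass_confusion_analysis(c("D", "B", "C"), labels, roster),
               "roster")
})

test_that("reports serialize to JSON and round-trip", {
  cfg <- small_config(n_subjects = 3, trials = 5, seed = 53)
  study <- build_study(cfg)
  rep_b <- run_scenario("B", study$unloaded, study$loaded,
                        configs = list(nc = list(architecture = "nearest_centroid")),
                        seed = 3, T = 2, lambda_grid = c(0.5, 1))
  payload <- list(scenario = rep_b$scenario, base = rep_b$base,
                  ensemble = rep_b$ensemble, curve = rep_b$lambda_curve)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$base$top1, rep_b$base$top1)
  expect_equal(back$ensemble$accuracy, rep_b$ensemble$accuracy)
  expect_equal(back$curve$accuracy, rep_b$lambda_curve$accuracy)
})
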