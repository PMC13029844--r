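test_that("top_rankings sorts by posterior with class-id tie breaking", {
  P <- post_matrix(list(c(0.5, 0.3, 0.2)), c("A", "B", "C"))
  expect_equal(unclass(top_rankings(P, 2))[1, ], c(1, 2), ignore_attr = TRUE)
  # exact tie: lower class index first
  P2 <- post_matrix(list(c(0.4, 0.4, 0.2)), c("A", "B", "C"))
  expect_equal(unclass(top_rankings(P2, 2))[1, ], c(1, 2), ignore_attr = TRUE)
  P3 <- post_matrix(list(c(0.2, 0.4, 0.4)), c("A", "B", "C"))
  expect_equal(unclass(top_rankings(P3, 2))[1, ], c(2, 3), ignore_attr = TRUE)
  # T = C gives a permutation of all classes
  r <- top_rankings(P, 3)
  expect_setequal(r[1, ], 1:3)
  expect_error(top_rankings(P, 4), "T must be")
  expect_error(top_rankings(P, 0), "T must be")
})

test_that("topp_accuracy counts hits within the first p positions", {
  classes <- c("A", "B", "C")
  # true classes at positions 1, 2, 2, and absent
  r <- make_rankings(rbind(c(1, 2), c(3, 1), c(2, 3), c(2, 3)), classes)
  labels <- c("A", "A", "C", "A")
  expect_equal(topp_accuracy(r, labels, 1), 0.25)
  expect_equal(topp_accuracy(r, labels, 2), 0.75)
  # perfect classifier: 1 at every p
  rp <- make_rankings(rbind(c(1, 2), c(2, 1)), classes)
  expect_equal(topp_accuracy(rp, c("A", "B"), 1), 1)
  expect_equal(topp_accuracy(rp, c("A", "B"), 2), 1)
  # true class never listed
  expect_equal(topp_accuracy(rp, c("C", "C"), 2), 0)
  expect_error(topp_accuracy(make_rankings(matrix(0L, 0, 2), classes),
                             character(0), 1), "empty")
})

test_that("ranks follow strict-majority counting with both tie clauses", {
  # plain case: distinct accuracies
  t1 <- rank_weight_table(cbind(c(0.9, 0.8, 0.7)))
  expect_equal(t1$R[, 1], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(t1$w[, 1], c(1, 2 / 3, 1 / 3), ignore_attr = TRUE)

  # tie at p = 2 reordered by Top-1 accuracy
  acc <- cbind(c(0.8, 0.9, 0.6), c(0.9, 0.9, 0.7))
  t2 <- rank_weight_table(acc)
  expect_equal(t2$R[, 2], c(2L, 1L, 3L), ignore_attr = TRUE)

  # persistent tie: identical everywhere, all share rank 1, all w = 1
  t3 <- rank_weight_table(matrix(0.85, 3, 2))
  expect_true(all(t3$R == 1L))
  expect_true(all(t3$w == 1))

  # position weights f_p = (T + 1 - p) / T
  t4 <- rank_weight_table(matrix(runif(10), 2, 5))
  expect_equal(t4$f, c(1, 0.8, 0.6, 0.4, 0.2))
  expect_true(all(t4$w >= 1 / t4$K & t4$w <= 1))
  expect_error(rank_weight_table(cbind(c(0.5, NA))), "non-finite")
})

test_that("weighted rank-order vote sums Top-1 weights per class", {
  classes <- c("A", "B", "C")
  # 5 classifiers with w_{j,1} = 1.0, 0.8, 0.6, 0.4, 0.2 (ranks 1..5)
  acc <- cbind(c(0.95, 0.9, 0.85, 0.8, 0.75))
  tab <- rank_weight_table(acc)
  expect_equal(tab$w[, 1], c(1, 0.8, 0.6, 0.4, 0.2), ignore_attr = TRUE)
  votes <- list(1L, 1L, 2L, 2L, 2L)  # A, A, B, B, B
  rankings <- lapply(votes, function(v) make_rankings(cbind(v), classes))
  dec <- vote_rank_order(rankings, tab, classes = classes)
  expect_equal(dec$pred, "A")  # 1.8 beats 1.2
  expect_false(dec$tie)
  expect_equal(attr(dec, "scores")[1, ], c(1.8, 1.2, 0), ignore_attr = TRUE)

  # unanimity
  rankings_u <- lapply(1:5, function(j) make_rankings(cbind(3L), classes))
  dec_u <- vote_rank_order(rankings_u, tab, classes = classes)
  expect_equal(dec_u$pred, "C")
  expect_false(dec_u$tie)
})

test_that("score ties go to the best classifier's Top-1, else None", {
  classes <- c("A", "B")
  # two equally-weighted classifiers disagree -> tie path
  tab <- rank_weight_table(cbind(c(0.9, 0.9)))
  r1 <- make_rankings(cbind(1L), classes)
  r2 <- make_rankings(cbind(2L), classes)
  dec <- vote_rank_order(list(r1, r2), tab, classes = classes)
  expect_true(dec$tie)
  # both classifiers are maximal and disagree -> None
  expect_true(is.na(dec$pred))

  # distinct Top-1 accuracy: the better classifier's vote decides
  tab2 <- rank_weight_table(cbind(c(0.9, 0.8)))
  # force a score tie by construction: w = (1, 0.5); give classifier 2 the
  # double vote via equal weights instead
  tab_eq <- rank_weight_table(cbind(c(0.9, 0.8), c(0.95, 0.95)))
  # directly exercise the resolver
  expect_equal(resolve_tie(c(1L, 2L), best_top1 = 1L), 1L)
  expect_equal(resolve_tie(c(1L, 2L), best_top1 = c(1L, 2L)), NA_integer_)
  # best classifier indicates a class outside the tied set -> None
  expect_equal(resolve_tie(c(1L, 2L), best_top1 = 3L), NA_integer_)
})

test_that("additive Top-T vote follows the lambda trade-off literally", {
  classes <- c("A", "B")
  # K identical classifiers: decision is their shared Top-1 for any lambda
  tab <- rank_weight_table(matrix(0.9, 3, 2))
  r <- make_rankings(rbind(c(1L, 2L)), classes)
  for (lam in c(0.2, 1, 2.5, 5)) {
    dec <- vote_topT_additive(list(r, r, r), tab, lambda = lam,
                              classes = classes)
    expect_equal(dec$pred, "A")
    expect_false(dec$tie)
  }

  # K = 2, T = 2, lambda = 1: coefficients reduce to f = (1, 0.5); opposed
  # rankings produce 1.5 vs 1.5 -> tie, resolved by... equal-best Top-1s
  # that disagree -> None
  tab2 <- rank_weight_table(matrix(0.8, 2, 2))
  rA <- make_rankings(rbind(c(1L, 2L)), classes)
  rB <- make_rankings(rbind(c(2L, 1L)), classes)
  dec2 <- vote_topT_additive(list(rA, rB), tab2, lambda = 1,
                             classes = classes)
  expect_true(dec2$tie)
  expect_true(is.na(dec2$pred))
  expect_equal(attr(dec2, "scores")[1, ], c(1.5, 1.5), ignore_attr = TRUE)

  expect_error(vote_topT_additive(list(rA, rB), tab2, lambda = -0.1),
               "lambda")
})

test_that("with T = 1 and lambda = 0 the Top-T vote reduces to rank order", {
  set.seed(42)
  classes <- paste0("c", 1:6)
  for (trial in 1:1000) {
    K <- sample(2:5, 1)
    C <- sample(2:6, 1)
    M <- sample(1:4, 1)
    acc <- matrix(round(runif(K), 2), K, 1)  # rounded to force occasional ties
    tab <- rank_weight_table(acc)
    rankings <- lapply(seq_len(K), function(j) {
      make_rankings(cbind(sample.int(C, M, replace = TRUE)), classes[1:C])
    })
    a <- vote_topT_additive(rankings, tab, lambda = 0, classes = classes[1:C])
    b <- vote_rank_order(rankings, tab, classes = classes[1:C])
    expect_identical(a$pred, b$pred)
    expect_identical(a$tie, b$tie)
  }
})

test_that("permuting class ids permutes decisions identically", {
  set.seed(7)
  classes <- c("A", "B", "C", "D")
  for (trial in 1:50) {
    K <- 3; M <- 5; Tdepth <- 2; C <- 4
    tab <- rank_weight_table(matrix(runif(K * Tdepth), K, Tdepth))
    rankings <- lapply(1:K, function(j) {
      make_rankings(t(replicate(M, sample.int(C, Tdepth))), classes)
    })
    perm <- sample.int(C)  # new index of class i is perm[i]
    permuted <- lapply(rankings, function(r) {
      make_rankings(matrix(perm[r], nrow(r), ncol(r)), classes[order(perm)])
    })
    for (lam in c(0.3, 1.7)) {
      d1 <- vote_topT_additive(rankings, tab, lambda = lam, classes = classes)
      d2 <- vote_topT_additive(permuted, tab, lambda = lam,
                               classes = classes[order(perm)])
      # class names travel with their relabelled indices, so predictions
      # must agree by name
      expect_identical(d2$pred, d1$pred)
      expect_identical(d2$tie, d1$tie)
    }
  }
})

test_that("duplicating every classifier leaves decisions unchanged", {
  set.seed(19)
  classes <- c("A", "B", "C")
  for (trial in 1:50) {
    K <- 3; M <- 6; Tdepth <- 2
    acc <- matrix(runif(K * Tdepth), K, Tdepth)
    rankings <- lapply(1:K, function(j) {
      make_rankings(t(replicate(M, sample.int(3, Tdepth))), classes)
    })
    tab <- rank_weight_table(acc)
    tab2 <- rank_weight_table(rbind(acc, acc))
    d1 <- vote_rank_order(rankings, tab, classes = classes)
    d2 <- vote_rank_order(c(rankings, rankings), tab2, classes = classes)
    expect_identical(d1$pred, d2$pred)
    lam <- runif(1, 0, 3)
    t1 <- vote_topT_additive(rankings, tab, lam, classes = classes)
    t2 <- vote_topT_additive(c(rankings, rankings), tab2, lam,
                             classes = classes)
    expect_identical(t1$pred, t2$pred)
  }
})

test_that("rank_fusion builds the full table from posteriors and labels", {
  classes <- c("A", "B", "C")
  P1 <- post_matrix(list(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1),
                         c(0.30, 0.35, 0.35), c(0.6, 0.3, 0.1)),
                    classes, id = "good")
  P2 <- post_matrix(list(c(0.1, 0.6, 0.3), c(0.2, 0.5, 0.3),
                         c(0.5, 0.2, 0.3), c(0.2, 0.2, 0.6)),
                    classes, id = "weak")
  labels <- c("A", "B", "C", "A")
  rf <- rank_fusion(list(P1, P2), labels, T = 2)
  expect_s3_class(rf, "rank_fusion")
  expect_equal(rf$classifier_ids, c("good", "weak"))
  # hand-checked: good finds A, B, A at top-1 and C at top-2 of row 3
  # (0.35 tie, B first by class id); weak finds B at top-1, C and A at top-2
  expect_equal(rf$acc["good", ], c(0.75, 1.0), ignore_attr = TRUE)
  expect_equal(rf$acc["weak", ], c(0.25, 0.75), ignore_attr = TRUE)
  expect_equal(rf$R["good", ], c(1L, 1L), ignore_attr = TRUE)
  # Acc is nondecreasing in p
  expect_true(all(diff(t(rf$acc)) >= -1e-12))

  dec <- predict(rf, list(P1, P2), strategy = "rank_order")
  expect_equal(nrow(dec), 4)
  expect_error(rank_fusion(list(P1, P2)), "labels")
})

test_that("lambda sweep covers the grid and finds constructed optima", {
  classes <- c("A", "B", "C")
  grid <- seq(0.1, 5, by = 0.1)
  expect_length(grid, 50)

  # single classifier: flat curve (decisions independent of lambda)
  P <- post_matrix(list(c(0.6, 0.3, 0.1), c(0.2, 0.7, 0.1)), classes)
  labels <- c("A", "B")
  rf1 <- rank_fusion(list(P), labels, T = 2)
  sw1 <- sweep_lambda(rf1, list(P), labels)
  expect_equal(length(unique(sw1$curve$accuracy)), 1)
  expect_equal(sw1$lambda_star, 0.1)  # smallest grid value on a flat curve

  # constructed trade-off: position information favours the truth, quality
  # weights favour the wrong class, so the optimum needs lambda > 1.
  # c1 (better Top-1) ranks (B, A); c2 (better Top-2) ranks (A, B); the
  # f-contributions of A and B cancel, so the decision is governed by the
  # sign of (1 - lambda): B for lambda < 1, A for lambda > 1.
  rankings <- list(make_rankings(rbind(c(2L, 1L)), classes),
                   make_rankings(rbind(c(1L, 2L)), classes))
  acc <- rbind(c(0.9, 0.92), c(0.5, 0.95))
  tabc <- rank_weight_table(acc)
  rf3 <- structure(c(unclass(tabc), list(classes = classes,
                                         classifier_ids = paste0("c", 1:2))),
                   class = c("rank_fusion", "rank_weight_table"))
  sw3 <- sweep_lambda(rf3, rankings, "A")
  # brute-force recomputation over the same grid agrees
  brute_acc <- vapply(grid, function(lam) {
    sc <- brute_scores(rankings, tabc, lam, "topT")
    d <- brute_decide(rankings, tabc, sc)
    mean(!is.na(d$pred) & d$pred == "A")
  }, numeric(1))
  expect_equal(sw3$curve$accuracy, brute_acc)
  expect_gte(sw3$lambda_star, 1)
  expect_equal(sw3$accuracy, 1)
  expect_error(sweep_lambda(rf3, rankings, "A", grid = numeric(0)), "empty")
})
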