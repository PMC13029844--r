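# Independent brute-force scorer for the two fusion strategies: loops
# literally over the indicator definition (classifier j ranked class i at
# position p) without any of the package's vectorized score accumulation.

brute_scores <- function(rankings, table, lambda = NULL, strategy = "topT") {
  K <- length(rankings)
  M <- nrow(rankings[[1]])
  C <- length(attr(rankings[[1]], "classes"))
  Tdepth <- if (strategy == "rank_order") 1L else table$T
  scores <- matrix(0, M, C)
  for (m in seq_len(M)) {
    for (i in seq_len(C)) {
      s <- 0
      for (j in seq_len(K)) {
        for (p in seq_len(Tdepth)) {
          d <- as.numeric(rankings[[j]][m, p] == i)
          if (d == 0) next
          coef <- if (strategy == "rank_order") table$w[j, 1]
                  else lambda * table$f[p] + (1 - lambda) * table$w[j, p]
          s <- s + coef * d
        }
      }
      scores[m, i] <- s
    }
  }
  scores
}

# brute-force decision with the same tie rule, written independently
brute_decide <- function(rankings, table, scores) {
  classes <- attr(rankings[[1]], "classes")
  top1_acc <- table$acc[, 1]
  best <- which(abs(top1_acc - max(top1_acc)) == 0)
  M <- nrow(scores)
  pred <- character(M)
  tie <- logical(M)
  for (m in seq_len(M)) {
    s <- scores[m, ]
    mx <- max(s)
    cand <- which(s >= mx - 1e-12 * max(1, abs(mx)))
    if (length(cand) == 1) {
      pred[m] <- classes[cand]
    } else {
      tie[m] <- TRUE
      tops <- unique(vapply(best, function(j) rankings[[j]][m, 1], integer(1)))
      if (length(tops) == 1 && tops %in% cand) pred[m] <- classes[tops]
      else pred[m] <- NA_character_
    }
  }
  list(pred = pred, tie = tie)
}

# all ordered T-tuples of distinct classes from 1..C
all_rank_lists <- function(C, Tdepth) {
  grids <- do.call(expand.grid, rep(list(seq_len(C)), Tdepth))
  keep <- apply(grids, 1, function(r) !anyDuplicated(r))
  as.matrix(grids[keep, , drop = FALSE])
}
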