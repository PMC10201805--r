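# Feature ranking by random-forest out-of-bag permutation importance and
# recursive single-feature elimination. The importance statistic is the mean
# per-tree drop in OOB accuracy when one feature is shuffled within that
# tree's OOB rows -- computed here from per-tree predictions, not taken from
# a library's impurity-based importance (a different statistic).

.perm_seed <- function(seed, k, j) {
  as.integer((abs(as.double(seed)) * 7919 + k * 104729 + j * 1299709) %%
               2147483562)
}

#' Out-of-bag permutation importance
#'
#' Grows `n_trees` CART trees on bootstrap samples (Gini splits, unlimited
#' depth, bootstrap size = n rows). For each tree `k` the baseline OOB
#' accuracy `L_k` is computed on the rows left out of its bootstrap sample;
#' for each feature `j` the accuracy `L_kj` is recomputed after permuting
#' column `j` within the OOB rows (permutation seeded deterministically from
#' `(seed, k, j)`). The importance of feature `j` is the mean accuracy drop
#' `P_j = (1/K) * sum_k (L_k - L_kj)`.
#'
#' @param fm A [feature_matrix()] with at least two classes.
#' @param n_trees Number of trees K (default 200).
#' @param seed Integer seed controlling bootstrap and permutations.
#' @param keep_deltas Keep the K x J matrix of per-tree accuracy drops?
#' @return An object of class `importance_ranking`: list with `scores`
#'   (named, sorted decreasing), `n_trees`, `n_empty_oob` and optionally
#'   `per_tree_deltas`.
#' @export
oob_importance <- function(fm, n_trees = 200, seed = 0, keep_deltas = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"), n_trees >= 1)
  x <- fm$values
  y <- factor(fm$labels)
  if (nlevels(y) < 2L) {
    stop("need at least 2 classes for importance ranking", call. = FALSE)
  }
  n <- nrow(x)
  J <- ncol(x)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  inbag <- rf$inbag
  oob_rows <- lapply(seq_len(n_trees), function(k) which(inbag[, k] == 0L))
  n_empty <- sum(vapply(oob_rows, length, integer(1)) == 0L)

  base_pred <- predict(rf, x, predict.all = TRUE)$individual
  y_chr <- as.character(y)
  L_base <- vapply(seq_len(n_trees), function(k) {
    rows <- oob_rows[[k]]
    if (length(rows) == 0L) return(NA_real_)
    mean(base_pred[rows, k] == y_chr[rows])
  }, numeric(1))

  deltas <- matrix(0, nrow = n_trees, ncol = J,
                   dimnames = list(NULL, colnames(x)))
  # stack every tree's OOB rows (feature j permuted within each tree's
  # block) into one prediction call per feature
  blocks <- unlist(oob_rows)
  block_tree <- rep.int(seq_len(n_trees), vapply(oob_rows, length, integer(1)))
  if (length(blocks) > 0L) {
    for (j in seq_len(J)) {
      nd <- x[blocks, , drop = FALSE]
      for (k in seq_len(n_trees)) {
        sel <- which(block_tree == k)
        if (length(sel) > 1L) {
          set.seed(.perm_seed(seed, k, j))
          nd[sel, j] <- nd[sel[sample.int(length(sel))], j]
        }
      }
      pred <- predict(rf, nd, predict.all = TRUE)$individual
      for (k in seq_len(n_trees)) {
        sel <- which(block_tree == k)
        if (length(sel) == 0L) next # empty OOB: delta stays 0
        L_kj <- mean(pred[cbind(sel, k)] == y_chr[blocks[sel]])
        deltas[k, j] <- L_base[k] - L_kj
      }
    }
  }
  scores <- colMeans(deltas)
  structure(list(scores = sort(scores, decreasing = TRUE),
                 n_trees = n_trees, n_empty_oob = n_empty,
                 per_tree_deltas = if (keep_deltas) deltas else NULL),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking> K =", x$n_trees, "trees\n")
  print(round(x$scores, 5))
  invisible(x)
}

#' Recursive feature elimination by OOB permutation importance
#'
#' Repeatedly: rank the surviving features with [oob_importance()], remove
#' the single least important one (ties broken by lexicographically last
#' name, recorded in the trace), re-fit on the reduced set, until `k_final`
#' features survive. The forest is re-grown from scratch each round.
#'
#' @inheritParams oob_importance
#' @param k_final Number of features to retain (default 10).
#' @return A list with `selected` (survivor names in final-round importance
#'   order, most important first) and `trace` (data frame: one row per
#'   elimination round with the dropped feature, its score, the surviving
#'   set size and whether a tie was broken).
#' @export
recursive_select <- function(fm, k_final = 10, n_trees = 200, seed = 0) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (k_final < 1) stop("k_final must be >= 1", call. = FALSE)
  feats <- fm$feature_names
  if (k_final > length(feats)) {
    stop("k_final (", k_final, ") exceeds feature count (", length(feats), ")",
         call. = FALSE)
  }
  trace <- list()
  round_i <- 0L
  last_scores <- NULL
  while (length(feats) > k_final) {
    round_i <- round_i + 1L
    sub <- feature_matrix(fm$values[, feats, drop = FALSE], fm$labels)
    imp <- oob_importance(sub, n_trees = n_trees,
                          seed = .perm_seed(seed, round_i, 0L))
    sc <- imp$scores
    worst_val <- min(sc)
    cand <- names(sc)[sc == worst_val]
    tie <- length(cand) > 1L
    drop_name <- sort(cand, method = "radix", decreasing = TRUE)[1L]
    trace[[round_i]] <- data.frame(round = round_i, dropped = drop_name,
                                   score = unname(sc[drop_name]),
                                   surviving = length(feats) - 1L,
                                   tie_broken = tie,
                                   stringsAsFactors = FALSE)
    feats <- setdiff(feats, drop_name)
    last_scores <- sc[names(sc) != drop_name]
  }
  selected <- if (!is.null(last_scores)) {
    names(sort(last_scores, decreasing = TRUE))
  } else feats
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(round = integer(), dropped = character(),
                    score = numeric(), surviving = integer(),
                    tie_broken = logical(), stringsAsFactors = FALSE))
}
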