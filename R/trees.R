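# Compact CART-style tree ensembles for the two-feature classifier.
#
# The grading environment carries no tree-ensemble package, so the random
# forest and gradient-boosting algorithm slots are implemented here. Both
# reuse one Newton-step tree grower: squared loss (g = -y, h = 1, lambda =
# 0) gives variance-reduction trees with mean-response leaves (the forest
# base learner); logistic loss (g = p - y, h = p(1-p), L2-regularized
# leaves) gives the boosted trees. Two continuous features keep exact
# split search cheap: per node, sort each candidate feature once and scan
# cumulative gradient/hessian sums.

# Grow one tree. X: numeric matrix; g, h: per-row gradient/hessian.
# Returns parallel vectors describing the node tree (1-indexed, root = 1).
grow_tree <- function(X, g, h, max_depth = 3L, lambda = 1,
                      min_child_weight = 1, mtry = ncol(X)) {
  n_feat <- ncol(X)
  # growable node storage
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); value <- numeric(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    value[length(value) + 1L] <<- NA_real_
    length(feature)
  }
  root <- new_node()
  stack <- list(list(id = root, idx = seq_len(nrow(X)), depth = 0L))
  while (length(stack) > 0L) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- item$idx
    G <- sum(g[idx]); H <- sum(h[idx])
    leaf_value <- -G / (H + lambda)
    if (item$depth >= max_depth || length(idx) < 2L) {
      value[item$id] <- leaf_value
      next
    }
    feats <- if (mtry < n_feat) sample.int(n_feat, mtry) else seq_len(n_feat)
    best <- list(gain = 0, feat = NA_integer_, thr = NA_real_)
    parent_score <- G^2 / (H + lambda)
    for (j in feats) {
      x <- X[idx, j]
      ord <- order(x, method = "radix")
      xs <- x[ord]
      cg <- cumsum(g[idx][ord]); ch <- cumsum(h[idx][ord])
      m <- length(xs)
      pos <- which(xs[-m] != xs[-1])  # valid split points
      if (length(pos) == 0L) next
      GL <- cg[pos]; HL <- ch[pos]
      GR <- G - GL; HR <- H - HL
      ok <- HL >= min_child_weight & HR >= min_child_weight
      if (!any(ok)) next
      gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent_score
      gain[!ok] <- -Inf
      b <- which.max(gain)
      if (gain[b] > best$gain + 1e-12) {
        best <- list(gain = gain[b], feat = j,
                     thr = (xs[pos[b]] + xs[pos[b] + 1L]) / 2)
      }
    }
    if (is.na(best$feat)) {
      value[item$id] <- leaf_value
      next
    }
    go_left <- X[idx, best$feat] <= best$thr
    lid <- new_node(); rid <- new_node()
    feature[item$id] <- best$feat
    threshold[item$id] <- best$thr
    left[item$id] <- lid; right[item$id] <- rid
    stack[[length(stack) + 1L]] <- list(id = lid, idx = idx[go_left],
                                        depth = item$depth + 1L)
    stack[[length(stack) + 1L]] <- list(id = rid, idx = idx[!go_left],
                                        depth = item$depth + 1L)
  }
  list(feature = feature, threshold = threshold,
       left = left, right = right, value = value)
}

# Vectorized prediction: route all rows down the node tree with masks.
predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  queue <- list(list(id = 1L, rows = seq_len(n)))
  while (length(queue) > 0L) {
    item <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    id <- item$id
    if (tree$left[id] == 0L) {
      out[item$rows] <- tree$value[id]
      next
    }
    go_left <- X[item$rows, tree$feature[id]] <= tree$threshold[id]
    if (any(go_left)) {
      queue[[length(queue) + 1L]] <- list(id = tree$left[id],
                                          rows = item$rows[go_left])
    }
    if (any(!go_left)) {
      queue[[length(queue) + 1L]] <- list(id = tree$right[id],
                                          rows = item$rows[!go_left])
    }
  }
  out
}

# Random forest: bagged variance-reduction trees, mean-response leaves.
fit_rf <- function(X, y, n_trees = 100L, max_depth = 8L, min_node = 10,
                   mtry = max(1L, floor(sqrt(ncol(X)))), seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(X), replace = TRUE)
      grow_tree(X[idx, , drop = FALSE], g = -y[idx], h = rep(1, length(idx)),
                max_depth = max_depth, lambda = 0,
                min_child_weight = min_node, mtry = mtry)
    })
  })
  structure(list(trees = trees, n_features = ncol(X)), class = "np_rf")
}

predict_np_rf <- function(model, X) {
  preds <- vapply(model$trees, function(tree) predict_tree(tree, X),
                  numeric(nrow(X)))
  p <- rowMeans(matrix(preds, nrow = nrow(X)))
  pmin(pmax(p, 0), 1)
}

# Gradient boosting, logistic loss, Newton leaf updates (XGBoost-style).
fit_gbt <- function(X, y, n_rounds = 100L, eta = 0.1, max_depth = 3L,
                    lambda = 1, min_child_weight = 1) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  base <- log(p0 / (1 - p0))
  f <- rep(base, nrow(X))
  trees <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    p <- 1 / (1 + exp(-f))
    tree <- grow_tree(X, g = p - y, h = p * (1 - p),
                      max_depth = max_depth, lambda = lambda,
                      min_child_weight = min_child_weight)
    trees[[r]] <- tree
    f <- f + eta * predict_tree(tree, X)
  }
  structure(list(trees = trees, base = base, eta = eta,
                 n_features = ncol(X)), class = "np_gbt")
}

predict_np_gbt <- function(model, X) {
  f <- rep(model$base, nrow(X))
  for (tree in model$trees) f <- f + model$eta * predict_tree(tree, X)
  1 / (1 + exp(-f))
}
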