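# Compact 1-D CNN for short feature vectors, implemented from first
# principles in base R (forward, backprop, Adam). With the default spec the
# layer lengths walk 10 -> conv(9) -> pool(8) -> conv(7) -> pool(6) ->
# flatten(6 x 32 = 192) -> fc(32) -> fc(2): stride-1 size-2 windows, no
# padding, batch norm + ReLU after each convolution, softmax output.

#' Sliding-window pooling
#'
#' `max_pool()` is the sliding-window maximum, `avg_pool()` the
#' sliding-window mean; at stride `s` the output length is
#' `floor((length(x) - size)/s) + 1`.
#'
#' @param x Numeric sequence, at least `size` long.
#' @param size Window size (default 2).
#' @param stride Step between windows (default 1).
#' @return Numeric vector of pooled values.
#' @examples
#' max_pool(c(1, 3, 2, 5)) # 3 3 5
#' avg_pool(c(1, 3, 2, 5)) # 2 2.5 3.5
#' @export
max_pool <- function(x, size = 2, stride = 1) {
  .pool(x, size, stride, max)
}

#' @rdname max_pool
#' @export
avg_pool <- function(x, size = 2, stride = 1) {
  .pool(x, size, stride, mean)
}

.pool <- function(x, size, stride, f) {
  n <- length(x)
  if (size > n) stop("pooling window (", size, ") larger than input (", n, ")",
                     call. = FALSE)
  starts <- seq(1L, n - size + 1L, by = stride)
  vapply(starts, function(i) f(x[i:(i + size - 1L)]), numeric(1))
}

#' CNN architecture specification
#'
#' Two convolutional blocks (conv -> batch norm -> ReLU -> max pool, all
#' kernels/windows 2 x 1 at stride 1, no padding) followed by two fully
#' connected layers ending in softmax. The constructor walks the layer
#' shapes and refuses any spec whose pooling would collapse a length
#' below 1.
#'
#' @param input_len Input feature count (default 10).
#' @param filters Filter counts of the two convolutional layers
#'   (default `c(16, 32)`).
#' @param kernel Convolution kernel length (default 2).
#' @param pool Pooling window length (default 2, stride 1).
#' @param fc_hidden Width of the first fully connected layer (default 32).
#' @param n_classes Number of output classes (default 2).
#' @return A list of class `cnn_spec`, including the computed `shape_walk`.
#' @export
cnn_spec <- function(input_len = 10, filters = c(16, 32), kernel = 2,
                     pool = 2, fc_hidden = 32, n_classes = 2) {
  stopifnot(length(filters) == 2, kernel >= 1, pool >= 1, fc_hidden >= 1,
            n_classes >= 2)
  l1 <- input_len - kernel + 1L
  l2 <- l1 - pool + 1L
  l3 <- l2 - kernel + 1L
  l4 <- l3 - pool + 1L
  walk <- c(input = input_len, conv1 = l1, pool1 = l2, conv2 = l3, pool2 = l4,
            flatten = l4 * filters[2L])
  if (any(walk < 1L)) {
    stop("inconsistent spec: layer lengths collapse below 1 (",
         paste(names(walk), walk, sep = "=", collapse = " -> "), ")",
         call. = FALSE)
  }
  structure(list(input_len = as.integer(input_len),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes),
                 shape_walk = walk),
            class = "cnn_spec")
}

#' Build an untrained CNN
#'
#' Parameters are initialised with seeded He-scaled Gaussians (batch-norm
#' scales at 1, biases and shifts at 0), so two builds from the same seed
#' produce identical forward passes.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the initialisation.
#' @return An object of class `cnn_model` (untrained).
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 0) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  K <- spec$kernel
  F1 <- spec$filters[1L]; F2 <- spec$filters[2L]
  flat <- spec$shape_walk[["flatten"]]
  he <- function(fan_in, dims) array(stats::rnorm(prod(dims), 0,
                                                  sqrt(2 / fan_in)), dims)
  params <- list(
    W1 = he(K, c(K, F1)), b1 = numeric(F1),
    g1 = rep(1, F1), be1 = numeric(F1),
    W2 = he(K * F1, c(K, F1, F2)), b2 = numeric(F2),
    g2 = rep(1, F2), be2 = numeric(F2),
    Wf1 = he(flat, c(flat, spec$fc_hidden)), bf1 = numeric(spec$fc_hidden),
    Wf2 = he(spec$fc_hidden, c(spec$fc_hidden, spec$n_classes)),
    bf2 = numeric(spec$n_classes))
  structure(list(spec = spec, params = params,
                 bn = list(rm1 = numeric(F1), rv1 = rep(1, F1),
                           rm2 = numeric(F2), rv2 = rep(1, F2)),
                 scale = NULL, classes = NULL, history = NULL,
                 trained = FALSE, seed = seed),
            class = "cnn_model")
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# channelwise batch norm over an array (B, L, C); returns normalized array
# plus the per-channel statistics needed for backprop
.bn_forward <- function(Z, gamma, beta, running_mean, running_var, training) {
  dims <- dim(Z)
  C <- dims[3L]
  Zm <- matrix(Z, ncol = C) # (B*L) x C, channel stats are column stats
  if (training) {
    mu <- colMeans(Zm)
    va <- colMeans(sweep(Zm, 2L, mu)^2)
  } else {
    mu <- running_mean
    va <- running_var
  }
  sd_inv <- 1 / sqrt(va + .bn_eps)
  Zn <- sweep(sweep(Zm, 2L, mu), 2L, sd_inv, `*`)
  H <- sweep(sweep(Zn, 2L, gamma, `*`), 2L, beta, `+`)
  list(H = array(H, dims), Zn = Zn, mu = mu, va = va, sd_inv = sd_inv)
}

.bn_backward <- function(dH, cache, gamma) {
  dims <- dim(dH)
  C <- dims[3L]
  dHm <- matrix(dH, ncol = C)
  N <- nrow(dHm)
  dgamma <- colSums(dHm * cache$Zn)
  dbeta <- colSums(dHm)
  dZn <- sweep(dHm, 2L, gamma, `*`)
  # dZ = (sd_inv/N) * (N*dZn - sum(dZn) - Zn * sum(dZn*Zn))
  s1 <- colSums(dZn)
  s2 <- colSums(dZn * cache$Zn)
  dZ <- sweep(N * dZn, 2L, s1) - sweep(cache$Zn, 2L, s2, `*`)
  dZ <- sweep(dZ, 2L, cache$sd_inv / N, `*`)
  list(dZ = array(dZ, dims), dgamma = dgamma, dbeta = dbeta)
}

# conv layer 1: X (B x L0) -> Z (B, L1, F1)
.conv1_forward <- function(X, W1, b1, spec) {
  B <- nrow(X)
  L1 <- spec$shape_walk[["conv1"]]
  F1 <- spec$filters[1L]
  Z <- array(0, c(B, L1, F1))
  for (d in seq_len(spec$kernel)) {
    Z <- Z + outer(X[, d:(d + L1 - 1L), drop = FALSE], W1[d, ])
  }
  sweep(Z, 3L, b1, `+`)
}

# conv layer 2: P (B, L2, F1) -> Z (B, L3, F2)
.conv2_forward <- function(P, W2, b2, spec) {
  B <- dim(P)[1L]
  L3 <- spec$shape_walk[["conv2"]]
  F1 <- spec$filters[1L]; F2 <- spec$filters[2L]
  Z <- array(0, c(B, L3, F2))
  for (d in seq_len(spec$kernel)) {
    slice <- matrix(P[, d:(d + L3 - 1L), , drop = FALSE], ncol = F1)
    Z <- Z + array(slice %*% matrix(W2[d, , ], F1, F2), c(B, L3, F2))
  }
  sweep(Z, 3L, b2, `+`)
}

# stride-1 size-2 max pool along dim 2, with argmax mask for backprop
# (ties route to the earlier position)
.pool_forward <- function(A) {
  L <- dim(A)[2L]
  left <- A[, 1:(L - 1L), , drop = FALSE]
  right <- A[, 2:L, , drop = FALSE]
  list(P = pmax(left, right), left_wins = left >= right)
}

.pool_backward <- function(dP, left_wins, L) {
  dims <- dim(dP)
  dA <- array(0, c(dims[1L], L, dims[3L]))
  dA[, 1:(L - 1L), ] <- dA[, 1:(L - 1L), , drop = FALSE] + dP * left_wins
  dA[, 2:L, ] <- dA[, 2:L, , drop = FALSE] + dP * !left_wins
  dA
}

# full forward pass; caches every intermediate needed for backprop
.cnn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  p <- model$params
  B <- nrow(X)
  Z1 <- .conv1_forward(X, p$W1, p$b1, spec)
  bn1 <- .bn_forward(Z1, p$g1, p$be1, model$bn$rm1, model$bn$rv1, training)
  A1 <- pmax(bn1$H, 0)
  pl1 <- .pool_forward(A1)
  Z2 <- .conv2_forward(pl1$P, p$W2, p$b2, spec)
  bn2 <- .bn_forward(Z2, p$g2, p$be2, model$bn$rm2, model$bn$rv2, training)
  A2 <- pmax(bn2$H, 0)
  pl2 <- .pool_forward(A2)
  flat <- matrix(pl2$P, nrow = B)
  Hpre <- sweep(flat %*% p$Wf1, 2L, p$bf1, `+`)
  H <- pmax(Hpre, 0)
  logits <- sweep(H %*% p$Wf2, 2L, p$bf2, `+`)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, X = X, Z1 = Z1, bn1 = bn1, A1 = A1,
       pl1 = pl1, Z2 = Z2, bn2 = bn2, A2 = A2, pl2 = pl2, flat = flat,
       Hpre = Hpre, H = H)
}

# cross-entropy loss and full gradient for one batch; y in 0..C-1
.cnn_loss_grads <- function(model, X, y, training = TRUE) {
  spec <- model$spec
  p <- model$params
  fw <- .cnn_forward(model, X, training = training)
  B <- nrow(X)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(fw$probs[idx], 1e-12)))
  dlogits <- fw$probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  g <- list()
  g$Wf2 <- t(fw$H) %*% dlogits
  g$bf2 <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wf2)
  dH[fw$Hpre <= 0] <- 0
  g$Wf1 <- t(fw$flat) %*% dH
  g$bf1 <- colSums(dH)
  dflat <- dH %*% t(p$Wf1)
  L4 <- spec$shape_walk[["pool2"]]
  F2 <- spec$filters[2L]
  dP2 <- array(dflat, c(B, L4, F2))
  L3 <- spec$shape_walk[["conv2"]]
  dA2 <- .pool_backward(dP2, fw$pl2$left_wins, L3)
  dA2[fw$bn2$H <= 0] <- 0
  bb2 <- .bn_backward(dA2, fw$bn2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  dZ2 <- bb2$dZ
  g$b2 <- apply(dZ2, 3L, sum)
  F1 <- spec$filters[1L]
  g$W2 <- array(0, dim(p$W2))
  dP1 <- array(0, dim(fw$pl1$P))
  dZ2m <- matrix(dZ2, ncol = F2)
  for (d in seq_len(spec$kernel)) {
    slice <- matrix(fw$pl1$P[, d:(d + L3 - 1L), , drop = FALSE], ncol = F1)
    g$W2[d, , ] <- t(slice) %*% dZ2m
    dP1[, d:(d + L3 - 1L), ] <- dP1[, d:(d + L3 - 1L), , drop = FALSE] +
      array(dZ2m %*% t(matrix(p$W2[d, , ], F1, F2)), c(B, L3, F1))
  }
  L1 <- spec$shape_walk[["conv1"]]
  dA1 <- .pool_backward(dP1, fw$pl1$left_wins, L1)
  dA1[fw$bn1$H <= 0] <- 0
  bb1 <- .bn_backward(dA1, fw$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  dZ1 <- bb1$dZ
  g$b1 <- apply(dZ1, 3L, sum)
  g$W1 <- matrix(0, spec$kernel, F1)
  dZ1m <- matrix(dZ1, ncol = F1)
  for (d in seq_len(spec$kernel)) {
    xs <- as.vector(fw$X[, d:(d + L1 - 1L), drop = FALSE])
    g$W1[d, ] <- drop(xs %*% dZ1m)
  }
  list(loss = loss, grads = g, fw = fw,
       batch_stats = list(mu1 = fw$bn1$mu, va1 = fw$bn1$va,
                          mu2 = fw$bn2$mu, va2 = fw$bn2$va))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Optimiser and split settings for classifier training: Adam with
#' cross-entropy loss, seeded stratified 3:1 train/test split.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (>= 1; default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed for the split, shuffling and any initialisation.
#' @param standardize Z-score features using training-fold statistics
#'   before the network (default TRUE)?
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100, batch_size = 32,
                         seed = 0, standardize = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

# fit on explicitly given rows only (leak-proof path used by run_case)
.cnn_fit <- function(model, x, y_raw, cfg) {
  if (cfg$epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  classes <- sort(unique(y_raw))
  if (length(classes) < 2L) {
    stop("training fold contains a single class", call. = FALSE)
  }
  if (length(classes) != model$spec$n_classes) {
    stop("spec expects ", model$spec$n_classes, " classes, data has ",
         length(classes), call. = FALSE)
  }
  y <- match(y_raw, classes) - 1L
  if (cfg$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    model$scale <- list(center = ctr, scale = scl)
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  } else {
    model$scale <- NULL
  }
  model$classes <- classes
  set.seed(cfg$seed)
  n <- nrow(x)
  adam <- .adam_init(model$params)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    bstarts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (bs in bstarts) {
      rows <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
      lg <- .cnn_loss_grads(model, x[rows, , drop = FALSE], y[rows],
                            training = TRUE)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      }
      st <- lg$batch_stats
      mom <- .bn_momentum
      model$bn$rm1 <- (1 - mom) * model$bn$rm1 + mom * st$mu1
      model$bn$rv1 <- (1 - mom) * model$bn$rv1 + mom * st$va1
      model$bn$rm2 <- (1 - mom) * model$bn$rm2 + mom * st$mu2
      model$bn$rv2 <- (1 - mom) * model$bn$rv2 + mom * st$va2
      upd <- .adam_step(model$params, lg$grads, adam, cfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state
      ep_loss <- ep_loss + lg$loss * length(rows)
    }
    losses[ep] <- ep_loss / n
  }
  model$history <- losses
  model$trained <- TRUE
  model
}

#' Stratified train/test split
#'
#' Seeded stratified partition preserving class proportions; the default
#' ratio is the 3:1 (75/25) protocol.
#'
#' @param labels Class label per row.
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, ratio = 0.75, seed = 0) {
  stopifnot(ratio > 0, ratio < 1)
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < 2L) {
      stop("class '", cl, "' has fewer than 2 rows; cannot split",
           call. = FALSE)
    }
    n_tr <- max(1L, min(length(rows) - 1L, round(ratio * length(rows))))
    train <- c(train, sample(rows, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train a classifier on a feature matrix
#'
#' Performs the seeded stratified 3:1 split, fits the model on the training
#' fold with Adam + cross-entropy (CNN) or the adapter's native fit (SVM),
#' and returns the trained model together with the held-out fold indices.
#'
#' @param model An untrained [build_cnn()] model or [build_svm()] adapter.
#' @param fm A [feature_matrix()] whose column count matches the model
#'   input length.
#' @param cfg A [train_config()].
#' @return A list with `model` (trained), `train_idx`, `test_idx`.
#' @export
train_model <- function(model, fm, cfg = train_config()) {
  UseMethod("train_model")
}

#' @export
train_model.cnn_model <- function(model, fm, cfg = train_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != model$spec$input_len) {
    stop("feature count (", ncol(fm$values), ") != spec input_len (",
         model$spec$input_len, ")", call. = FALSE)
  }
  sp <- stratified_split(fm$labels, 0.75, cfg$seed)
  fitted <- .cnn_fit(model, fm$values[sp$train, , drop = FALSE],
                     fm$labels[sp$train], cfg)
  list(model = fitted, train_idx = sp$train, test_idx = sp$test)
}

#' Predict class probabilities and labels
#'
#' Deterministic given the trained model: batch norm uses the stored
#' running statistics, and the label is the softmax argmax.
#'
#' @param object A trained `cnn_model`.
#' @param newdata Numeric matrix (rows x features) or [feature_matrix()].
#' @param ... Unused.
#' @return List with `probs` (rows x classes) and `labels`.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$input_len) {
    stop("feature count (", ncol(newdata), ") != spec input_len (",
         object$spec$input_len, ")", call. = FALSE)
  }
  if (!is.null(object$scale)) {
    newdata <- sweep(sweep(newdata, 2L, object$scale$center), 2L,
                     object$scale$scale, `/`)
  }
  fw <- .cnn_forward(object, newdata, training = FALSE)
  labs <- if (is.null(object$classes)) {
    max.col(fw$probs, ties.method = "first") - 1L
  } else {
    object$classes[max.col(fw$probs, ties.method = "first")]
  }
  list(probs = fw$probs, labels = labs)
}

#' @export
print.cnn_model <- function(x, ...) {
  w <- x$spec$shape_walk
  cat("<cnn_model> ", if (x$trained) "trained" else "untrained",
      "; shape ", paste(names(w), w, sep = "=", collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' SVM comparison baseline
#'
#' A thin adapter putting a radial-kernel support vector machine behind the
#' same `train_model()`/`predict()` contract as the CNN, for comparative
#' reporting only.
#'
#' @return An object of class `svm_model` (untrained).
#' @export
build_svm <- function() {
  structure(list(fit = NULL, trained = FALSE), class = "svm_model")
}

#' @export
train_model.svm_model <- function(model, fm, cfg = train_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  sp <- stratified_split(fm$labels, 0.75, cfg$seed)
  model <- .svm_fit(model, fm$values[sp$train, , drop = FALSE],
                    fm$labels[sp$train], cfg)
  list(model = model, train_idx = sp$train, test_idx = sp$test)
}

.svm_fit <- function(model, x, y_raw, cfg) {
  set.seed(cfg$seed)
  model$fit <- e1071::svm(x = x, y = factor(y_raw), kernel = "radial")
  model$classes <- sort(unique(y_raw))
  model$trained <- TRUE
  model
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  labs <- as.character(predict(object$fit, as.matrix(newdata)))
  labs <- if (is.numeric(object$classes)) as.numeric(labs) else labs
  list(probs = NULL, labels = labs)
}
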