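#' CNN architecture configuration
#'
#' The classifier is a small convolutional network with thirteen layers
#' carrying learnable weights, arranged as a four-layer pattern repeated
#' three times: a 3x3, stride-1, zero-padded ("same") convolution with 8,
#' 16 and 32 filters respectively, batch normalisation, a rectified linear
#' unit, and a 2x2 stride-2 max pool — except that the third repetition
#' replaces the pool with a fully connected layer of width `n_classes`
#' feeding a softmax. Spatial sizes run 50 -> 25 -> 12 (floor division by
#' the pools). The learnable-weight accounting counts each convolution's
#' kernel and bias, each batch normalisation's scale and shift pair, and
#' the fully connected layer.
#'
#' @param n_classes number of output classes (>= 2).
#' @param input_size input side length in pixels (default 50).
#' @param n_channels input channels (default 3, 16-bit RGB).
#' @param filters convolution filter counts (fixed at 8, 16, 32).
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(n_classes, input_size = 50L, n_channels = 3L,
                       filters = c(8L, 16L, 32L)) {
  stopifnot(n_classes >= 2L, length(filters) == 3L)
  if (!identical(as.integer(filters), c(8L, 16L, 32L)))
    stop("the architecture fixes the filter counts at 8, 16, 32")
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 n_channels = as.integer(n_channels),
                 filters = as.integer(filters)),
            class = "cnn_config")
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum; defaults follow the
#' conventional solver settings (momentum 0.9, minibatch 128) with the
#' initial learning rate 0.01, at most 20 epochs and validation every 30
#' iterations.
#'
#' @param learning_rate initial learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param max_epochs maximum epochs (default 20).
#' @param batch_size minibatch size (default 128).
#' @param l2 L2 regularization (weight decay) applied to convolution and
#'   fully connected weights, the conventional solver default 1e-4;
#'   biases and batch-norm parameters are not decayed.
#' @param validation_frequency iterations between validation checks
#'   (default 30).
#' @param seed seed for shuffling (weight init is seeded in
#'   [build_cnn()]).
#' @param verbose print progress lines (default `FALSE`).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         max_epochs = 20L, batch_size = 128L, l2 = 1e-4,
                         validation_frequency = 30L, seed = 1L,
                         verbose = FALSE) {
  stopifnot_scalar_num(learning_rate, "learning_rate", min = 0, strict = TRUE)
  stopifnot_scalar_num(max_epochs, "max_epochs", min = 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), l2 = l2,
                 validation_frequency = as.integer(validation_frequency),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build (initialise) the CNN
#'
#' He-normal initialisation for convolution and fully connected weights,
#' unit scale / zero shift for batch normalisation; reproducible from
#' `seed`.
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `kinet_cnn` holding the parameters, running
#'   batch-norm statistics and the configuration.
#' @export
build_cnn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  f <- config$filters
  cin <- c(config$n_channels, f[1L], f[2L])
  s1 <- config$input_size            # 50
  s2 <- s1 %/% 2L                    # 25
  s3 <- s2 %/% 2L                    # 12
  d_fc <- s3 * s3 * f[3L]
  withr::with_seed(as.integer(seed), {
    pars <- list()
    for (l in 1:3) {
      fan_in <- 9L * cin[l]
      pars[[paste0("W", l)]] <- matrix(rnorm(fan_in * f[l],
                                             sd = sqrt(2 / fan_in)),
                                       fan_in, f[l])
      pars[[paste0("b", l)]] <- numeric(f[l])
      pars[[paste0("g", l)]] <- rep(1, f[l])
      pars[[paste0("be", l)]] <- numeric(f[l])
    }
    pars$Wf <- matrix(rnorm(d_fc * config$n_classes, sd = sqrt(2 / d_fc)),
                      d_fc, config$n_classes)
    pars$bf <- numeric(config$n_classes)
  })
  running <- list(rm1 = numeric(f[1L]), rv1 = rep(1, f[1L]),
                  rm2 = numeric(f[2L]), rv2 = rep(1, f[2L]),
                  rm3 = numeric(f[3L]), rv3 = rep(1, f[3L]))
  structure(list(config = config, params = pars, running = running,
                 sizes = c(s1, s2, s3), init_seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "kinet_cnn")
}

#' @export
print.kinet_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1L)))
  cat(sprintf(
    "<kinet_cnn: 3x[conv3x3(%s)-BN-ReLU(-pool)] + FC(%d), %d parameters, %s>\n",
    paste(x$config$filters, collapse = ","), x$config$n_classes, np,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# images: [H, W, C, N] array (raw 16-bit counts) -> activation matrix
# (HWN x C) scaled to [0, 1].
images_to_input <- function(images) {
  d <- dim(images)
  ap <- aperm(images, c(1L, 2L, 4L, 3L))
  matrix(as.numeric(ap), d[1L] * d[2L] * d[4L], d[3L]) / 65535
}

# Full forward pass. Returns logits and (if training) layer caches.
cnn_forward <- function(model, x, N, training = FALSE) {
  p <- model$params; rn <- model$running
  s <- model$sizes
  cache <- list()
  a <- x
  H <- s[1L]; W <- s[1L]
  for (l in 1:3) {
    cv <- conv_fwd_cpp(a, p[[paste0("W", l)]], p[[paste0("b", l)]],
                       H, W, N, training)
    br <- bnrelu_fwd_cpp(cv$out, p[[paste0("g", l)]], p[[paste0("be", l)]],
                         rn[[paste0("rm", l)]], rn[[paste0("rv", l)]],
                         training, .bn_momentum, .bn_eps)
    if (training) {
      rn[[paste0("rm", l)]] <- as.numeric(br$rmean)
      rn[[paste0("rv", l)]] <- as.numeric(br$rvar)
      cache[[l]] <- list(c_in = ncol(a), cols = cv$cols, xhat = br$xhat,
                         isd = as.numeric(br$isd), y = br$out,
                         H = H, W = W)
    }
    r <- br$out
    if (l < 3L) {
      pl <- pool_fwd_cpp(r, H, W, N)
      if (training) cache[[l]]$pool_arg <- pl$argmax
      a <- pl$out
      H <- H %/% 2L; W <- W %/% 2L
    } else {
      a <- r
    }
  }
  X <- flatten_forward(a, H, W, N)
  logits <- add_cols(X %*% p$Wf, p$bf)
  list(logits = logits, X = X, cache = cache, running = rn,
       H3 = H, W3 = W)
}

# Forward + backward: loss and parameter gradients for one minibatch.
cnn_grads <- function(model, x, y_int, N) {
  p <- model$params
  fw <- cnn_forward(model, x, N, training = TRUE)
  ce <- softmax_ce(fw$logits, y_int, model$config$n_classes)
  g <- list()
  g$Wf <- crossprod(fw$X, ce$dlogits)
  g$bf <- colSums(ce$dlogits)
  da <- flatten_backward(ce$dlogits %*% t(p$Wf),
                         fw$H3, fw$W3, N, model$config$filters[3L])
  for (l in 3:1) {
    cch <- fw$cache[[l]]
    if (l < 3L)
      da <- pool_bwd_cpp(da, cch$pool_arg, cch$H * cch$W * N)
    bb <- bnrelu_bwd_cpp(da, cch$y, cch$xhat, cch$isd,
                         p[[paste0("g", l)]])
    g[[paste0("g", l)]] <- as.numeric(bb$dgamma)
    g[[paste0("be", l)]] <- as.numeric(bb$dbeta)
    cb <- conv_bwd_cpp(bb$dx, cch$cols, p[[paste0("W", l)]],
                       cch$H, cch$W, cch$c_in, N, l > 1L)
    g[[paste0("W", l)]] <- cb$dW
    g[[paste0("b", l)]] <- as.numeric(cb$db)
    if (l > 1L) da <- cb$dx
  }
  list(loss = ce$loss, grads = g, running = fw$running)
}

#' Class probabilities for a batch of images
#'
#' @param model a trained `kinet_cnn`.
#' @param images `[H, W, 3, N]` array of 16-bit images.
#' @param batch internal evaluation batch size.
#' @return `N x n_classes` matrix of softmax probabilities.
#' @export
predict_proba <- function(model, images, batch = 256L) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (d[1L] != model$config$input_size || d[3L] != model$config$n_channels)
    stop(sprintf("images must be %dx%dx%d",
                 model$config$input_size, model$config$input_size,
                 model$config$n_channels))
  N <- d[4L]
  out <- matrix(0, N, model$config$n_classes)
  for (start in seq(1L, N, by = batch)) {
    ix <- start:min(start + batch - 1L, N)
    x <- images_to_input(images[, , , ix, drop = FALSE])
    fw <- cnn_forward(model, x, length(ix), training = FALSE)
    out[ix, ] <- softmax_rows(fw$logits)
  }
  colnames(out) <- model$classes
  out
}

#' Predict class labels
#'
#' @inheritParams predict_proba
#' @param object a trained `kinet_cnn`.
#' @param ... unused.
#' @return factor of predicted class labels (argmax of the softmax).
#' @export
predict.kinet_cnn <- function(object, images, ...) {
  p <- predict_proba(object, images)
  cls <- if (!is.null(object$classes)) object$classes else
    as.character(seq_len(ncol(p)))
  factor(cls[max.col(p, ties.method = "first")], levels = cls)
}

#' Stratified train/validation/test split
#'
#' Randomised, stratified, disjoint and exhaustive split at the given
#' fractions (default 56/24/20), with largest-remainder rounding per
#' class.
#'
#' @param labels class label per item.
#' @param fractions length-3 numeric summing to 1
#'   (default `c(0.56, 0.24, 0.20)`).
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, fractions = c(0.56, 0.24, 0.20),
                          seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  out <- list(train = integer(), validation = integer(), test = integer())
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      n <- length(ix)
      raw <- fractions * n
      cnt <- floor(raw)
      rem <- n - sum(cnt)
      if (rem > 0) {
        extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1L
      }
      if (any(cnt == 0L))
        stop("class too small to populate every partition: ", cl)
      out$train <- c(out$train, ix[seq_len(cnt[1L])])
      out$validation <- c(out$validation,
                          ix[cnt[1L] + seq_len(cnt[2L])])
      out$test <- c(out$test, ix[cnt[1L] + cnt[2L] + seq_len(cnt[3L])])
    }
  })
  lapply(out, sort)
}

#' Downsample classes to a balanced dataset
#'
#' Randomly selects, without replacement, `min(class sizes)` items from
#' each class.
#'
#' @param labels class label per item.
#' @param seed integer seed.
#' @return sorted integer vector of retained indices.
#' @export
balance_classes <- function(labels, seed = 1L) {
  sizes <- table(labels)
  target <- min(sizes)
  withr::with_seed(as.integer(seed), {
    keep <- unlist(lapply(split(seq_along(labels), labels), function(ix)
      if (length(ix) == target) ix else sample(ix, target)),
      use.names = FALSE)
  })
  sort(keep)
}

#' Train the CNN
#'
#' Minibatch stochastic gradient descent with momentum on the softmax
#' cross-entropy, evaluating the validation set every
#' `validation_frequency` iterations and recording a history.
#'
#' @param model a `kinet_cnn` from [build_cnn()].
#' @param images `[50, 50, 3, N]` array of 16-bit images.
#' @param labels class label per image.
#' @param split list with `train` and `validation` index vectors (e.g.
#'   from [split_dataset()]).
#' @param tconfig a [train_config()].
#' @return the trained `kinet_cnn`, with `history` (data frame of
#'   iteration, training loss, validation loss/accuracy) and
#'   `final_validation_accuracy`.
#' @export
train_cnn <- function(model, images, labels, split, tconfig = train_config()) {
  stopifnot(inherits(model, "kinet_cnn"), inherits(tconfig, "train_config"))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != model$config$n_classes)
    stop(sprintf("%d classes in labels but model has %d outputs",
                 length(classes), model$config$n_classes))
  model$classes <- classes
  y_int <- match(as.character(labels), classes)
  tr <- split$train
  va <- split$validation
  if (!length(tr) || !length(va)) stop("empty training or validation set")
  p <- model$params
  vel <- lapply(p, function(w) w * 0)
  hist_it <- integer(); hist_loss <- numeric()
  hist_vloss <- numeric(); hist_vacc <- numeric()
  iter <- 0L
  s1 <- model$sizes[1L]
  validate <- function() {
    probs <- predict_proba(model, images[, , , va, drop = FALSE])
    vpred <- max.col(probs, ties.method = "first")
    vloss <- -mean(log(pmax(probs[cbind(seq_along(va), y_int[va])], 1e-12)))
    c(vloss, mean(vpred == y_int[va]))
  }
  epoch_seeds <- derive_seeds(tconfig$seed, tconfig$max_epochs)
  for (epoch in seq_len(tconfig$max_epochs)) {
    ord <- withr::with_seed(epoch_seeds[epoch], sample(tr))
    for (start in seq(1L, length(ord), by = tconfig$batch_size)) {
      ix <- ord[start:min(start + tconfig$batch_size - 1L, length(ord))]
      N <- length(ix)
      x <- images_to_input(images[, , , ix, drop = FALSE])
      gr <- cnn_grads(model, x, y_int[ix], N)
      model$running <- gr$running
      if (!is.finite(gr$loss))
        stop("training diverged (non-finite loss); reduce learning_rate")
      if (tconfig$l2 > 0)
        for (nm in c("W1", "W2", "W3", "Wf"))
          gr$grads[[nm]] <- gr$grads[[nm]] + tconfig$l2 * p[[nm]]
      for (nm in names(p)) {
        vel[[nm]] <- tconfig$momentum * vel[[nm]] -
          tconfig$learning_rate * gr$grads[[nm]]
        p[[nm]] <- p[[nm]] + vel[[nm]]
      }
      model$params <- p
      iter <- iter + 1L
      if (iter %% tconfig$validation_frequency == 0L) {
        v <- validate()
        hist_it <- c(hist_it, iter)
        hist_loss <- c(hist_loss, gr$loss)
        hist_vloss <- c(hist_vloss, v[1L])
        hist_vacc <- c(hist_vacc, v[2L])
        if (tconfig$verbose)
          message(sprintf(
            "epoch %d iter %d: train loss %.4f, val loss %.4f, val acc %.4f",
            epoch, iter, gr$loss, v[1L], v[2L]))
      }
    }
  }
  v <- validate()
  model$history <- data.frame(iteration = hist_it, train_loss = hist_loss,
                              val_loss = hist_vloss, val_accuracy = hist_vacc)
  model$final_validation_accuracy <- v[2L]
  model$trained <- TRUE
  model
}

#' Evaluate a model on a labelled test set
#'
#' @param model a trained `kinet_cnn`.
#' @param images `[50, 50, 3, N]` array.
#' @param labels true class labels.
#' @return an object of class `confusion_matrix`: counts with rows = true
#'   class, columns = predicted class, and an `accuracy` attribute
#'   (trace / total).
#' @export
evaluate_cnn <- function(model, images, labels) {
  pred <- predict.kinet_cnn(model, images)
  cls <- model$classes
  truth <- factor(as.character(labels), levels = cls)
  cm <- table(true = truth, predicted = pred)
  cm <- unclass(cm)
  structure(cm, class = "confusion_matrix",
            accuracy = sum(diag(cm)) / sum(cm))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (accuracy %.4f):\n", attr(x, "accuracy")))
  print(matrix(x, nrow(x), dimnames = dimnames(x)))
  invisible(x)
}
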