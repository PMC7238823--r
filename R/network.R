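# The 8-layer slice classifier: six convolution layers with leaky-ReLU
# activations interleaved with five 3x3 max-poolings, then two fully
# connected layers ending in a 2-way softmax. All convolutions and poolings
# use "same" padding with spatial size out = ceil(in / stride) -- the only
# policy under which the stated 4096-dimensional flattened input of FC1 is
# reachable from a 145 x 145 slice (1024 channels x 2 x 2). Forward and
# backward passes run through im2col/col2im kernels (src/kernels.cpp) and
# BLAS matrix products; weights are updated with Adam.

#' Architecture specification of the slice classifier
#'
#' The convolution chain is fixed: kernels 3,3,3,1,1,1; strides 3,3,3,1,1,1;
#' channels 1-32-64-128-256-512-1024; a 3x3 max-pool follows conv2..conv6
#' with strides 1,1,1,1,3. FC1 maps the flattened features to 100 units and
#' FC2 to the 2 class logits.
#'
#' @param lrelu_slope negative slope of the leaky rectifier (default 0.01).
#' @return an object of class `cnnel_network_spec` (list of layer
#'   descriptors).
#' @export
network_spec <- function(lrelu_slope = 0.01) {
  layers <- list(
    list(type = "conv", name = "conv1", k = 3L, stride = 3L, in_c = 1L,   out_c = 32L),
    list(type = "conv", name = "conv2", k = 3L, stride = 3L, in_c = 32L,  out_c = 64L),
    list(type = "pool", name = "pooling1", k = 3L, stride = 1L),
    list(type = "conv", name = "conv3", k = 3L, stride = 3L, in_c = 64L,  out_c = 128L),
    list(type = "pool", name = "pooling2", k = 3L, stride = 1L),
    list(type = "conv", name = "conv4", k = 1L, stride = 1L, in_c = 128L, out_c = 256L),
    list(type = "pool", name = "pooling3", k = 3L, stride = 1L),
    list(type = "conv", name = "conv5", k = 1L, stride = 1L, in_c = 256L, out_c = 512L),
    list(type = "pool", name = "pooling4", k = 3L, stride = 1L),
    list(type = "conv", name = "conv6", k = 1L, stride = 1L, in_c = 512L, out_c = 1024L),
    list(type = "pool", name = "pooling5", k = 3L, stride = 3L),
    list(type = "fc", name = "FC1", out = 100L),
    list(type = "fc", name = "FC2", out = 2L))
  structure(list(layers = layers, lrelu_slope = lrelu_slope),
            class = "cnnel_network_spec")
}

# "same" padding geometry: out = ceil(in / stride),
# pad_total = max((out - 1) * stride + k - in, 0), split low/high.
same_pad <- function(n, k, stride) {
  out <- ceiling(n / stride)
  pad <- max((out - 1) * stride + k - n, 0)
  list(out = as.integer(out), lo = as.integer(pad %/% 2),
       hi = as.integer(pad - pad %/% 2))
}

#' Per-layer spatial sizes of the convolution stack
#'
#' Applies the same-padding size recurrence `out = ceil(in / stride)` layer
#' by layer for a square input of side `input_side`, and reports the
#' flattened feature count entering FC1.
#'
#' @param spec a [network_spec()].
#' @param input_side square input side S.
#' @return tibble: layer, type, kernel, stride, in_side, out_side, channels.
#'   The flattened FC1 input dimension is attached as attribute
#'   `flat_dim` (`out_side^2 * 1024` after the last pooling).
#' @export
network_dims <- function(spec, input_side) {
  s <- as.integer(input_side)
  rows <- list()
  channels <- 1L
  for (ly in spec$layers) {
    if (ly$type == "fc") break
    p <- same_pad(s, ly$k, ly$stride)
    if (ly$type == "conv") channels <- ly$out_c
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = ly$name, type = ly$type, kernel = ly$k, stride = ly$stride,
      in_side = s, out_side = p$out, channels = channels)
    s <- p$out
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "flat_dim") <- as.integer(s^2 * 1024L)
  out
}

#' Initialize the slice-classifier network
#'
#' Allocates He-style fan-in-scaled random weights for every layer given the
#' input side. Errors if the input is too small for the stride chain.
#'
#' @param spec a [network_spec()].
#' @param input_side square input side S (>= 27).
#' @param seed integer seed for the weight draw.
#' @return an object of class `cnnel_network`: layer list with weights,
#'   geometry and the flattened dimension `flat_dim`.
#' @export
build_network <- function(spec = network_spec(), input_side, seed = 1) {
  s <- as.integer(input_side)
  if (s < 27) {
    # name the first layer whose input side falls below its kernel
    side <- s
    offender <- "conv1"
    for (ly in spec$layers) {
      if (ly$type == "fc") break
      if (side < ly$k) { offender <- ly$name; break }
      side <- same_pad(side, ly$k, ly$stride)$out
    }
    rlang::abort(sprintf(
      "input side %d too small for the stride chain (first collapsing layer: %s); need side >= 27",
      s, offender))
  }
  dims <- network_dims(spec, s)
  flat <- attr(dims, "flat_dim")
  layers <- list()
  side <- s
  with_seed(derive_seed(seed, 11L), {
    for (ly in spec$layers) {
      if (ly$type == "conv") {
        p <- same_pad(side, ly$k, ly$stride)
        fan_in <- ly$k^2 * ly$in_c
        W <- matrix(rnorm(fan_in * ly$out_c, sd = sqrt(2 / fan_in)),
                    fan_in, ly$out_c)
        layers[[ly$name]] <- c(ly, list(W = W, b = numeric(ly$out_c),
                                        in_side = side, out_side = p$out,
                                        pad = p))
        side <- p$out
      } else if (ly$type == "pool") {
        p <- same_pad(side, ly$k, ly$stride)
        layers[[ly$name]] <- c(ly, list(in_side = side, out_side = p$out,
                                        pad = p))
        side <- p$out
      } else {
        n_in <- if (ly$name == "FC1") flat else 100L
        W <- matrix(rnorm(n_in * ly$out, sd = sqrt(2 / n_in)), n_in, ly$out)
        layers[[ly$name]] <- c(ly, list(W = W, b = numeric(ly$out)))
      }
    }
  })
  structure(list(layers = layers, input_side = s, flat_dim = flat,
                 lrelu_slope = spec$lrelu_slope),
            class = "cnnel_network")
}

#' @export
print.cnnel_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (is.null(l$W)) 0 else length(l$W) + length(l$b), 0))
  cat(sprintf("<cnnel_network> input %d x %d, flattened dim %d, %s parameters\n",
              x$input_side, x$input_side, x$flat_dim, format(np, big.mark = ",")))
  invisible(x)
}

lrelu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# x: [S, S, 1, N] array. Returns list(probs, caches) -- caches only when
# `training`.
net_forward <- function(net, x, training = FALSE) {
  n <- dim(x)[4]
  caches <- if (training) list() else NULL
  cur <- x
  ch <- 1L
  for (ly in net$layers) {
    if (ly$type == "conv") {
      side <- ly$in_side; os <- ly$out_side
      cols <- im2col_cpp(as.numeric(cur), side, side, ly$in_c, n,
                         ly$k, ly$stride, ly$pad$lo, ly$pad$lo, os, os)
      z <- crossprod(cols, ly$W)
      z <- sweep(z, 2, ly$b, `+`)
      a <- lrelu(z, net$lrelu_slope)
      if (training) caches[[ly$name]] <- list(cols = cols, z = z, n = n)
      # rows of z are (oy, ox, n); rearrange to [os, os, out_c, n]
      cur <- aperm(array(a, c(os, os, n, ly$out_c)), c(1, 2, 4, 3))
      ch <- ly$out_c
    } else if (ly$type == "pool") {
      side <- ly$in_side; os <- ly$out_side
      mp <- maxpool_fwd_cpp(as.numeric(cur), side, side, ch, n,
                            ly$k, ly$stride, ly$pad$lo, ly$pad$lo, os, os)
      if (training) caches[[ly$name]] <-
          list(argmax = mp$argmax, in_len = length(cur), n = n)
      cur <- array(mp$out, c(os, os, ch, n))
    } else if (ly$name == "FC1") {
      flat <- matrix(as.numeric(cur), ncol = n)   # flat_dim x n
      z <- crossprod(flat, ly$W)                  # n x 100
      z <- sweep(z, 2, ly$b, `+`)
      a <- lrelu(z, net$lrelu_slope)
      if (training) caches$FC1 <- list(flat = flat, z = z)
      cur <- a
    } else {
      z <- cur %*% ly$W                            # n x 2
      z <- sweep(z, 2, ly$b, `+`)
      if (training) caches$FC2 <- list(a_in = cur)
      zs <- z - apply(z, 1, max)
      e <- exp(zs)
      cur <- e / rowSums(e)
    }
  }
  list(probs = cur, caches = caches)
}

# Cross-entropy gradient pass; returns list of gradients parallel to the
# weighted layers plus the loss value.
net_backward <- function(net, x, y, fwd) {
  n <- dim(x)[4]
  probs <- fwd$probs
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-12)))
  onehot <- matrix(0, n, 2); onehot[cbind(seq_len(n), y + 1L)] <- 1
  dz <- (probs - onehot) / n                      # n x 2
  grads <- list()
  caches <- fwd$caches
  # FC2
  grads$FC2 <- list(W = crossprod(caches$FC2$a_in, dz), b = colSums(dz))
  da <- tcrossprod(dz, net$layers$FC2$W)          # n x 100
  # FC1
  dz1 <- da * lrelu_grad(caches$FC1$z, net$lrelu_slope)
  grads$FC1 <- list(W = caches$FC1$flat %*% dz1, b = colSums(dz1))
  dflat <- net$layers$FC1$W %*% t(dz1)            # flat_dim x n
  # back through conv/pool stack
  last_pool <- net$layers$pooling5
  dcur <- array(as.numeric(dflat),
                c(last_pool$out_side, last_pool$out_side, 1024L, n))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "fc") next
    if (ly$type == "pool") {
      cache <- caches[[ly$name]]
      dx <- maxpool_bwd_cpp(as.numeric(dcur), cache$argmax, cache$in_len)
      ch <- length(dx) / (ly$in_side^2 * n)
      dcur <- array(dx, c(ly$in_side, ly$in_side, ch, n))
    } else {
      cache <- caches[[ly$name]]
      os <- ly$out_side
      # dcur: [os, os, out_c, n] -> rows (oy, ox, n) x out_c
      da_mat <- matrix(aperm(dcur, c(1, 2, 4, 3)), ncol = ly$out_c)
      dz_mat <- da_mat * lrelu_grad(cache$z, net$lrelu_slope)
      grads[[ly$name]] <- list(W = cache$cols %*% dz_mat, b = colSums(dz_mat))
      if (ly$name != "conv1") {
        dcols <- ly$W %*% t(dz_mat)
        dx <- col2im_cpp(dcols, ly$in_side, ly$in_side, ly$in_c, n,
                         ly$k, ly$stride, ly$pad$lo, ly$pad$lo, os, os)
        dcur <- array(dx, c(ly$in_side, ly$in_side, ly$in_c, n))
      }
    }
  }
  list(grads = grads, loss = loss)
}

#' Training configuration
#'
#' Defaults follow the reference regime (30 epochs, Adam with learning rate
#' 1e-4, batch size 200). Scaled-down desk runs take far fewer optimizer
#' steps, so they typically pass a larger learning rate and fewer epochs.
#' The effective batch size is `min(batch_size, dataset size)`.
#'
#' @param epochs training epochs (integer >= 0).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param beta1,beta2,eps Adam moment parameters (canonical defaults).
#' @param seed integer seed controlling weight init and batch shuffling.
#' @return an object of class `cnnel_train_config`.
#' @export
train_config <- function(epochs = 30, learning_rate = 1e-4, batch_size = 200,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1) {
  assert_that(epochs >= 0 && epochs == round(epochs), "epochs must be a non-negative integer")
  assert_that(learning_rate > 0 && batch_size >= 1, "learning_rate and batch_size must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = as.integer(seed)),
            class = "cnnel_train_config")
}

slices_to_array <- function(images) {
  s <- nrow(images[[1]])
  array(unlist(images, use.names = FALSE), c(s, s, 1L, length(images)))
}

#' Train a base classifier on one slice dataset
#'
#' @param slices rows of a slice dataset for a single (axis, coordinate):
#'   tibble with `image`, `label`, `provenance`, `subject_id` columns.
#'   Both classes must be present.
#' @param config a [train_config()].
#' @param spec a [network_spec()].
#' @return an object of class `cnnel_classifier`: axis, mm, network,
#'   per-epoch history (loss, accuracy), `converged` flag (100% accuracy on
#'   the original, non-augmented training slices), and the training subject
#'   ids (used by downstream leakage guards).
#' @export
train_classifier <- function(slices, config = train_config(), spec = network_spec()) {
  assert_that(length(unique(paste(slices$axis, slices$mm))) == 1,
              "train_classifier expects a single (axis, coordinate) dataset")
  y <- as.integer(slices$label)
  if (length(unique(y)) < 2) rlang::abort("training data contain a single class")
  x <- slices_to_array(slices$image)
  side <- dim(x)[1]
  net <- build_network(spec, side, seed = config$seed)
  n <- dim(x)[4]
  bs <- min(config$batch_size, n)
  state <- list(m = list(), v = list(), t = 0)
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            accuracy = numeric())
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      ord <- with_seed(derive_seed(config$seed, 13L, ep), sample.int(n))
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = bs)) {
        take <- ord[start:min(start + bs - 1, n)]
        xb <- x[, , , take, drop = FALSE]
        yb <- y[take]
        fwd <- net_forward(net, xb, training = TRUE)
        bwd <- net_backward(net, xb, yb, fwd)
        upd <- adam_update(net, bwd$grads, state, config)
        net <- upd$net; state <- upd$state
        ep_loss <- ep_loss + bwd$loss * length(take)
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs) - 1L == yb)
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n))
    }
  }
  clf <- structure(list(axis = as.character(slices$axis[1]), mm = slices$mm[1],
                        net = net, history = history, converged = FALSE,
                        val_accuracy = NA_real_,
                        train_subjects = unique(slices$subject_id)),
                   class = "cnnel_classifier")
  originals <- slices[slices$provenance == "original", ]
  if (config$epochs > 0 && nrow(originals) > 0) {
    clf$converged <- check_convergence(clf, originals)
  }
  clf
}

#' Convergence check on the original training slices
#'
#' A classifier counts as converged when it classifies every original
#' (non-augmented) training slice correctly.
#'
#' @param classifier a trained `cnnel_classifier`.
#' @param originals the original (provenance `"original"`) training rows.
#' @return logical flag.
#' @export
check_convergence <- function(classifier, originals) {
  originals <- originals[originals$provenance == "original", ]
  if (nrow(originals) == 0) {
    rlang::abort("degenerate input: no original training slices to check")
  }
  p <- predict_proba(classifier, originals$image)
  all(max.col(p) - 1L == as.integer(originals$label))
}

#' Class probabilities for a set of slices
#'
#' @param classifier a `cnnel_classifier` (or bare `cnnel_network`).
#' @param images list of square matrices matching the trained input side.
#' @return n x 2 matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(classifier, images) {
  net <- if (inherits(classifier, "cnnel_network")) classifier else classifier$net
  x <- slices_to_array(images)
  if (dim(x)[1] != net$input_side || dim(x)[2] != net$input_side) {
    rlang::abort(sprintf("images are %d x %d but the network expects %d x %d",
                         dim(x)[1], dim(x)[2], net$input_side, net$input_side))
  }
  net_forward(net, x, training = FALSE)$probs
}

#' @export
print.cnnel_classifier <- function(x, ...) {
  cat(sprintf("<cnnel_classifier> %s slice at %.6g mm, %d epochs, converged: %s%s\n",
              x$axis, x$mm, nrow(x$history), x$converged,
              if (is.na(x$val_accuracy)) "" else
                sprintf(", validation accuracy %.3f", x$val_accuracy)))
  invisible(x)
}

adam_update <- function(net, grads, state, config) {
  state$t <- state$t + 1
  corr1 <- 1 - config$beta1^state$t
  corr2 <- 1 - config$beta2^state$t
  for (nm in names(grads)) {
    for (p in c("W", "b")) {
      g <- grads[[nm]][[p]]
      key <- paste0(nm, ".", p)
      m <- state$m[[key]] %||% (g * 0)
      v <- state$v[[key]] %||% (g * 0)
      m <- config$beta1 * m + (1 - config$beta1) * g
      v <- config$beta2 * v + (1 - config$beta2) * g^2
      state$m[[key]] <- m
      state$v[[key]] <- v
      net$layers[[nm]][[p]] <- net$layers[[nm]][[p]] -
        config$learning_rate * (m / corr1) / (sqrt(v / corr2) + config$eps)
    }
  }
  list(net = net, state = state)
}
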