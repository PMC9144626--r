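# ---- compact SegNet-style encoder-decoder ---------------------------------
# Pixel-wise 3-class segmentation. Encoder: conv3x3+ReLU+maxpool(2) stages;
# decoder: unpool with the encoder's pooling indices (the SegNet hallmark)
# followed by conv3x3+ReLU; final 1x1 conv + softmax. Feature maps are
# (H*W) x C matrices so convolutions reduce to one BLAS matmul over the
# im2col patch matrix (C++ kernels in src/convnet.cpp).

#' Network configuration
#'
#' @param input_channels Input channels fed to the network (SHG + AF = 2).
#' @param n_classes Number of output classes.
#' @param encoder_depth Number of pooling stages; the input side must be
#'   divisible by `2^encoder_depth`.
#' @param base_filters Filters in the first encoder stage; stage `i` uses
#'   `base_filters * 2^(i-1)`.
#' @param use_pooling_indices Decoder upsampling by the encoder's max-pooling
#'   indices (`TRUE`, the SegNet scheme) or by nearest-neighbour (`FALSE`).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_channels = 2L, n_classes = 3L,
                           encoder_depth = 3L, base_filters = 8L,
                           use_pooling_indices = TRUE) {
  stopifnot(input_channels >= 1L, n_classes >= 2L, encoder_depth >= 1L,
            base_filters >= 1L)
  structure(list(input_channels = as.integer(input_channels),
                 n_classes = as.integer(n_classes),
                 encoder_depth = as.integer(encoder_depth),
                 base_filters = as.integer(base_filters),
                 use_pooling_indices = isTRUE(use_pooling_indices)),
            class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the reference optimisation recipe: stochastic gradient
#' descent with momentum 0.9, initial learning rate 0.01, L2 regularization
#' 0.0005, mini-batch size 4, 5000 epochs, augmentation by random flips and
#' translations of up to 20 px. Override `epochs` for desk-scale runs.
#'
#' @param momentum SGD momentum.
#' @param learning_rate Initial learning rate.
#' @param l2_regularization Weight-decay coefficient on conv weights.
#' @param epochs Training epochs.
#' @param mini_batch Images per SGD step.
#' @param max_translation_px Maximum augmentation shift in either axis.
#' @param flip_augment Random horizontal/vertical flips.
#' @param seed Integer seed for init, shuffling and augmentation.
#' @return An object of class `training_config`.
#' @export
training_config <- function(momentum = 0.9, learning_rate = 0.01,
                            l2_regularization = 0.0005, epochs = 5000L,
                            mini_batch = 4L, max_translation_px = 20L,
                            flip_augment = TRUE, seed = 1L) {
  stopifnot(momentum >= 0, momentum < 1, learning_rate > 0,
            l2_regularization >= 0, epochs >= 1L, mini_batch >= 1L,
            max_translation_px >= 0L)
  structure(list(momentum = momentum, learning_rate = learning_rate,
                 l2_regularization = l2_regularization,
                 epochs = as.integer(epochs), mini_batch = as.integer(mini_batch),
                 max_translation_px = as.integer(max_translation_px),
                 flip_augment = isTRUE(flip_augment), seed = as.integer(seed)),
            class = "training_config")
}

#' Paired flip/translation augmentation
#'
#' Applies one random horizontal and/or vertical flip and an integer
#' translation with `|dx|, |dy| <= max_translation_px`, identically to the
#' image channels and the mask. Vacated pixels are filled with intensity 0
#' and the Outer label.
#'
#' @param image An [mpm_image()].
#' @param mask Matching label mask.
#' @param cfg A [training_config()].
#' @param seed Integer seed (`NULL` uses current RNG state).
#' @return `list(image = , mask = )` after the common transform.
#' @export
augment_pair <- function(image, mask, cfg = training_config(), seed = NULL) {
  stopifnot(inherits(image, "mpm_image"))
  mask <- check_mask(mask)
  if (!identical(dim(image$shg), dim(mask))) stop("image/mask shape mismatch")
  gen <- function() {
    t_max <- cfg$max_translation_px
    dx <- if (t_max > 0) sample(-t_max:t_max, 1L) else 0L
    dy <- if (t_max > 0) sample(-t_max:t_max, 1L) else 0L
    fh <- cfg$flip_augment && runif(1) < 0.5
    fv <- cfg$flip_augment && runif(1) < 0.5
    tr <- function(m, fill) {
      if (fh) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
      if (fv) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      shift_fill(m, dy, dx, fill)
    }
    list(image = mpm_image(tr(image$shg, 0), tr(image$af, 0),
                           bit_depth = image$bit_depth,
                           pixel_size = image$pixel_size),
         mask = tr(mask, LBL_OUTER))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen)
}

# translate matrix by (dr, dc); out[r, c] = m[r - dr, c - dc], `fill` elsewhere
shift_fill <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  storage.mode(out) <- storage.mode(m)
  r0 <- max(1, 1 + dr); r1 <- min(H, H + dr)
  c0 <- max(1, 1 + dc); c1 <- min(W, W + dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  out
}

# ---- internal network plumbing --------------------------------------------

# He-initialised weights for the layer plan implied by the config
segnet_init <- function(net) {
  d <- net$encoder_depth
  filt <- net$base_filters * 2^(seq_len(d) - 1L)
  enc_in <- c(net$input_channels, filt[-d])
  dec_out <- c(rev(filt[-d]), net$base_filters)  # mirror, last stage -> base
  layers <- list()
  for (i in seq_len(d))
    layers[[paste0("enc", i)]] <- list(cin = enc_in[i], cout = filt[i])
  dec_in <- filt[d]
  for (i in seq_len(d)) {
    layers[[paste0("dec", i)]] <- list(cin = dec_in, cout = dec_out[i])
    dec_in <- dec_out[i]
  }
  layers[["out"]] <- list(cin = net$base_filters, cout = net$n_classes, k1 = TRUE)
  W <- lapply(layers, function(l) {
    fan <- if (isTRUE(l$k1)) l$cin else 9L * l$cin
    matrix(rnorm(fan * l$cout, 0, sqrt(2 / fan)), fan, l$cout)
  })
  b <- lapply(layers, function(l) numeric(l$cout))
  list(W = W, b = b, plan = layers)
}

# forward pass; x: (H*W) x Cin matrix. Returns logits and, if `cache`, the
# intermediates needed for backprop.
segnet_forward <- function(par, net, x, H, W, cache = FALSE) {
  d <- net$encoder_depth
  acts <- list(); cols <- list(); idxs <- list(); dims <- list()
  h <- H; w <- W
  a <- x
  for (i in seq_len(d)) {
    nm <- paste0("enc", i)
    cc <- cn_im2col3(a, h, w)
    z <- cc %*% par$W[[nm]]
    z <- z + rep(par$b[[nm]], each = nrow(z))
    r <- z * (z > 0)
    pl <- cn_maxpool2(r, h, w)
    if (cache) { cols[[nm]] <- cc; acts[[nm]] <- r; dims[[nm]] <- c(h, w) }
    idxs[[nm]] <- pl$idx
    a <- pl$out
    h <- h %/% 2L; w <- w %/% 2L
  }
  for (i in seq_len(d)) {
    nm <- paste0("dec", i)
    src <- paste0("enc", d - i + 1L)
    up_h <- h * 2L; up_w <- w * 2L
    a <- if (net$use_pooling_indices) cn_scatter(a, idxs[[src]], up_h, up_w)
         else nn_upsample(a, h, w)
    h <- up_h; w <- up_w
    cc <- cn_im2col3(a, h, w)
    z <- cc %*% par$W[[nm]]
    z <- z + rep(par$b[[nm]], each = nrow(z))
    if (cache) { cols[[nm]] <- cc; acts[[nm]] <- z }
    a <- z * (z > 0)
  }
  logits <- a %*% par$W[["out"]]
  logits <- logits + rep(par$b[["out"]], each = nrow(logits))
  if (!cache) return(logits)
  list(logits = logits, pre_out = a, cols = cols, acts = acts, idxs = idxs,
       dims = dims, H = H, W = W)
}

# nearest-neighbour 2x upsample (non-SegNet decoder option)
nn_upsample <- function(a, h, w) {
  H2 <- 2L * h
  out <- matrix(0, H2 * 2L * w, ncol(a))
  r <- ((seq_len(h * w) - 1L) %% h) + 1L
  c <- ((seq_len(h * w) - 1L) %/% h) + 1L
  for (dr in 0:1) for (dc in 0:1) {
    p <- (2L * r - 1L + dr) + (2L * c - 2L + dc) * H2
    out[p, ] <- a
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# one forward+backward pass for one image; y: integer vector (H*W) in 1..K
segnet_backward <- function(par, net, x, y, H, W) {
  fw <- segnet_forward(par, net, x, H, W, cache = TRUE)
  n <- nrow(fw$logits)
  P <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  acc <- mean(max.col(P, ties.method = "first") == y)
  G <- P
  G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
  G <- G / n
  d <- net$encoder_depth
  gW <- list(); gb <- list()
  gW[["out"]] <- crossprod(fw$pre_out, G)
  gb[["out"]] <- colSums(G)
  g <- G %*% t(par$W[["out"]])
  h <- H; w <- W
  for (i in rev(seq_len(d))) {
    nm <- paste0("dec", i)
    src <- paste0("enc", d - i + 1L)
    g <- g * (fw$acts[[nm]] > 0)
    gW[[nm]] <- crossprod(fw$cols[[nm]], g)
    gb[[nm]] <- colSums(g)
    g <- cn_col2im3(g %*% t(par$W[[nm]]), h, w, ncol(fw$cols[[nm]]) %/% 9L)
    g <- cn_gather(g, fw$idxs[[src]])  # undo unpooling
    h <- h %/% 2L; w <- w %/% 2L
  }
  # walk back up the encoder
  for (i in rev(seq_len(d))) {
    nm <- paste0("enc", i)
    hw <- fw$dims[[nm]]
    g <- cn_scatter(g, fw$idxs[[nm]], hw[1], hw[2])  # undo pooling
    g <- g * (fw$acts[[nm]] > 0)
    gW[[nm]] <- crossprod(fw$cols[[nm]], g)
    gb[[nm]] <- colSums(g)
    if (i > 1L)
      g <- cn_col2im3(g %*% t(par$W[[nm]]), hw[1], hw[2],
                      ncol(fw$cols[[nm]]) %/% 9L)
  }
  list(gW = gW, gb = gb, loss = loss, acc = acc)
}

# load a manifest entry as normalized input matrix + label vector
load_training_arrays <- function(manifest, rows) {
  lapply(rows, function(i) {
    img <- convert_to_8bit(read_mpm_image(
      manifest_path(manifest, "image_path", i),
      bit_depth = if ("bit_depth" %in% names(manifest)) manifest$bit_depth[i] else 12L))
    mask <- read_mask(manifest_path(manifest, "mask_path", i))
    list(img = img, mask = mask)
  })
}

#' Train the segmentation network
#'
#' Fits the compact SegNet-style encoder--decoder on the `train` rows of a
#' split manifest by SGD with momentum, minimising mean pixel-wise
#' cross-entropy plus an L2 penalty on convolution weights. Channels are
#' normalised by mean/sd computed on the training split only; the constants
#' are stored in the model. Augmentation (random flip + translation) is
#' applied per epoch.
#'
#' @param manifest Manifest data frame with a `split` column (see
#'   [split_dataset()]).
#' @param net A [network_config()].
#' @param cfg A [training_config()].
#' @param verbose Print a progress line every 10 epochs.
#' @return An object of class `segnet`, with `print`, `summary`, `plot`
#'   (training history) and `predict` methods.
#' @export
segnet <- function(manifest, net = network_config(), cfg = training_config(),
                   verbose = FALSE) {
  if (!"split" %in% names(manifest)) stop("manifest has no train/test split")
  tr_rows <- which(manifest$split == "train")
  if (!length(tr_rows)) stop("empty training split")
  if (cfg$mini_batch > length(tr_rows))
    stop("mini_batch larger than training-set size")
  data <- load_training_arrays(manifest, tr_rows)
  H <- nrow(data[[1]]$img$shg); W <- ncol(data[[1]]$img$shg)
  if (H %% 2^net$encoder_depth != 0L || W %% 2^net$encoder_depth != 0L)
    stop("input side must be divisible by 2^encoder_depth")
  ch_stack <- vapply(data, function(d) c(mean(d$img$shg), mean(d$img$af)),
                     numeric(2))
  mu <- rowMeans(ch_stack)
  sd_stack <- vapply(data, function(d)
    c(sd(as.vector(d$img$shg)), sd(as.vector(d$img$af))), numeric(2))
  sigma <- pmax(rowMeans(sd_stack), 1e-6)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  par <- NULL
  run <- function() {
    par <- segnet_init(net)
    vel <- list(W = lapply(par$W, function(w) w * 0),
                b = lapply(par$b, function(b) b * 0))
    n_tr <- length(data)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_acc <- 0; n_seen <- 0L
      for (start in seq(1L, n_tr, by = cfg$mini_batch)) {
        batch <- ord[start:min(start + cfg$mini_batch - 1L, n_tr)]
        acc_gW <- NULL; acc_gb <- NULL; bl <- 0; ba <- 0
        for (i in batch) {
          au <- augment_pair(data[[i]]$img, data[[i]]$mask, cfg)
          x <- cbind((as.vector(au$image$shg) - mu[1]) / sigma[1],
                     (as.vector(au$image$af) - mu[2]) / sigma[2])
          y <- as.vector(au$mask) + 1L
          g <- segnet_backward(par, net, x, y, H, W)
          if (is.null(acc_gW)) { acc_gW <- g$gW; acc_gb <- g$gb }
          else for (nm in names(acc_gW)) {
            acc_gW[[nm]] <- acc_gW[[nm]] + g$gW[[nm]]
            acc_gb[[nm]] <- acc_gb[[nm]] + g$gb[[nm]]
          }
          bl <- bl + g$loss; ba <- ba + g$acc
        }
        nb <- length(batch)
        if (!is.finite(bl)) stop("NaN loss at epoch ", ep, "; aborting")
        for (nm in names(par$W)) {
          gw <- acc_gW[[nm]] / nb + cfg$l2_regularization * par$W[[nm]]
          vel$W[[nm]] <- cfg$momentum * vel$W[[nm]] - cfg$learning_rate * gw
          par$W[[nm]] <- par$W[[nm]] + vel$W[[nm]]
          vel$b[[nm]] <- cfg$momentum * vel$b[[nm]] -
            cfg$learning_rate * (acc_gb[[nm]] / nb)
          par$b[[nm]] <- par$b[[nm]] + vel$b[[nm]]
        }
        ep_loss <- ep_loss + bl; ep_acc <- ep_acc + ba; n_seen <- n_seen + nb
      }
      history[nrow(history) + 1L, ] <<- list(ep, ep_loss / n_seen,
                                             ep_acc / n_seen)
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %d  loss %.4f  train acc %.3f",
                        ep, ep_loss / n_seen, ep_acc / n_seen))
    }
    par
  }
  par <- with_seed(cfg$seed, run)
  structure(list(par = par, net = net, cfg = cfg,
                 norm = list(mean = mu, sd = sigma),
                 input_dim = c(H, W), history = history),
            class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  cat("SegNet-style encoder-decoder (", x$net$encoder_depth, " pooling stages, ",
      x$net$base_filters, " base filters, ",
      sum(vapply(x$par$W, length, 0L)) + sum(vapply(x$par$b, length, 0L)),
      " parameters)\n", sep = "")
  n <- nrow(x$history)
  if (n) cat(sprintf("trained %d epochs; final loss %.4f, train accuracy %.3f\n",
                     n, x$history$loss[n], x$history$accuracy[n]))
  invisible(x)
}

#' @export
summary.segnet <- function(object, ...) {
  print(object)
  cat("channel normalization: mean", round(object$norm$mean, 2),
      " sd", round(object$norm$sd, 2), "\n")
  cat("layers:\n")
  for (nm in names(object$par$W))
    cat(sprintf("  %-5s %d -> %d\n", nm,
                object$par$plan[[nm]]$cin, object$par$plan[[nm]]$cout))
  invisible(object)
}

#' @export
plot.segnet <- function(x, ...) {
  par(mar = c(4, 4, 2, 4))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", main = "training history", ...)
  par(new = TRUE)
  plot(x$history$epoch, x$history$accuracy, type = "l", col = "red3",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  axis(4, col.axis = "red3")
  mtext_right("training pixel accuracy")
  invisible(x)
}

mtext_right <- function(lab) graphics::mtext(lab, side = 4, line = 2.5,
                                             col = "red3")

#' Predict a label mask for one image
#'
#' Deterministic pixel-wise argmax over the class scores.
#'
#' @param object A fitted [segnet()] model.
#' @param image An [mpm_image()]; converted to 8-bit if needed.
#' @param type `"mask"` for the label matrix, `"prob"` for the per-pixel
#'   class probability array (H x W x K).
#' @param ... Unused.
#' @return Label matrix over \{0, 1, 2\} or probability array.
#' @export
predict.segnet <- function(object, image, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(image, "mpm_image"))
  image <- convert_to_8bit(image)
  H <- nrow(image$shg); W <- ncol(image$shg)
  if (H %% 2^object$net$encoder_depth != 0L ||
      W %% 2^object$net$encoder_depth != 0L)
    stop("input side must be divisible by 2^encoder_depth")
  x <- cbind((as.vector(image$shg) - object$norm$mean[1]) / object$norm$sd[1],
             (as.vector(image$af) - object$norm$mean[2]) / object$norm$sd[2])
  logits <- segnet_forward(object$par, object$net, x, H, W)
  if (type == "prob") {
    P <- softmax_rows(logits)
    return(array(P, dim = c(H, W, object$net$n_classes)))
  }
  matrix(as.integer(max.col(logits, ties.method = "first") - 1L), H, W)
}

#' Save / load a segnet checkpoint
#'
#' The checkpoint is a plain JSON archive holding weights, both configs and
#' the normalization constants.
#'
#' @param model A fitted [segnet()] model.
#' @param path Checkpoint file path.
#' @return `load_segnet` returns the restored model.
#' @export
save_segnet <- function(model, path) {
  stopifnot(inherits(model, "segnet"))
  obj <- list(W = lapply(model$par$W, unclass),
              b = model$par$b,
              plan = model$par$plan,
              net = unclass(model$net), cfg = unclass(model$cfg),
              norm = model$norm, input_dim = model$input_dim,
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- do.call(network_config, obj$net)
  cfg <- do.call(training_config, obj$cfg)
  plan <- segnet_init(net)$plan
  W <- lapply(names(plan), function(nm) {
    w <- obj$W[[nm]]
    matrix(as.numeric(w), nrow = nrow(w))
  })
  names(W) <- names(plan)
  b <- lapply(names(plan), function(nm) as.numeric(obj$b[[nm]]))
  names(b) <- names(plan)
  structure(list(par = list(W = W, b = b, plan = plan), net = net, cfg = cfg,
                 norm = list(mean = as.numeric(obj$norm$mean),
                             sd = as.numeric(obj$norm$sd)),
                 input_dim = as.integer(obj$input_dim),
                 history = as.data.frame(obj$history)),
            class = "segnet")
}
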