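# Encoder-decoder segmentation models: U-Net, U-Net++ (nested dense skips),
# Attention U-Net (additive attention gates on skips), Residual U-Net
# (residual conv blocks). All run on the package's autodiff tape; every
# architecture maps a 1-channel H x W image to 2-channel per-pixel class
# scores at the same resolution.

#' Segmentation model configuration
#'
#' @param architecture One of `"unet"`, `"unetpp"`, `"attention_unet"`,
#'   `"residual_unet"`.
#' @param depth Number of 2x down-sampling stages (>= 2). Input height and
#'   width must be divisible by `2^depth`.
#' @param base_channels Channel width of the first stage; stage `i` uses
#'   `base_channels * 2^i` channels.
#' @param norm Per-block normalization: `"instance"` (per-image, per-channel)
#'   or `"none"`.
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("unet", "unetpp", "attention_unet",
                                          "residual_unet"),
                         depth = 4L, base_channels = 32L,
                         norm = c("instance", "none")) {
  architecture <- match.arg(architecture)
  norm <- match.arg(norm)
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  structure(list(architecture = architecture, depth = depth,
                 base_channels = as.integer(base_channels),
                 in_channels = 1L, out_classes = 2L, norm = norm),
            class = "model_config")
}

#' Desk-scale model preset
#'
#' A small configuration (depth 2, 8 base channels) sized for CPU runs on
#' 32-64 px phantom images; the full-scale default mirrors common practice
#' for 512 px scans (depth 4, 32 base channels).
#'
#' @param architecture Architecture name, as in [model_config()].
#' @return A `model_config`.
#' @export
desk_model_config <- function(architecture = "unet") {
  model_config(architecture, depth = 2L, base_channels = 8L)
}

## ---- parameter creation ------------------------------------------------

# Fetch-or-create a parameter; creation order is the forward-pass order, so
# initialization is deterministic under the build seed.
get_param <- function(tp, ps, name, init) {
  if (is.null(ps$W[[name]])) ps$W[[name]] <- init()
  ad_param(tp, ps, name)
}

he3 <- function(cin, cout) {
  function() matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9 * cin, cout)
}
he1 <- function(cin, cout) {
  function() matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}
heT <- function(cin, cout) {
  function() matrix(stats::rnorm(cin * 4 * cout, 0, sqrt(2 / cin)),
                    cin, 4 * cout)
}
zeros <- function(n) function() numeric(n)
ones <- function(n) function() rep(1, n)

conv3_layer <- function(tp, ps, x, prefix, cin, cout) {
  w <- get_param(tp, ps, paste0(prefix, ".w"), he3(cin, cout))
  b <- get_param(tp, ps, paste0(prefix, ".b"), zeros(cout))
  ad_conv3(tp, x, w, b)
}

conv1_layer <- function(tp, ps, x, prefix, cin, cout) {
  w <- get_param(tp, ps, paste0(prefix, ".w"), he1(cin, cout))
  b <- get_param(tp, ps, paste0(prefix, ".b"), zeros(cout))
  ad_conv1(tp, x, w, b)
}

norm_layer <- function(tp, ps, x, prefix, ch, norm) {
  if (norm == "none") return(x)
  g <- get_param(tp, ps, paste0(prefix, ".g"), ones(ch))
  b <- get_param(tp, ps, paste0(prefix, ".be"), zeros(ch))
  ad_instnorm(tp, x, g, b)
}

up_layer <- function(tp, ps, x, prefix, cin, cout) {
  w <- get_param(tp, ps, paste0(prefix, ".w"), heT(cin, cout))
  b <- get_param(tp, ps, paste0(prefix, ".b"), zeros(cout))
  ad_convT2(tp, x, w, b)
}

# two 3x3 convs, each followed by normalization and ReLU
conv_block <- function(tp, ps, x, prefix, cin, cout, norm) {
  h <- conv3_layer(tp, ps, x, paste0(prefix, ".c1"), cin, cout)
  h <- ad_relu(tp, norm_layer(tp, ps, h, paste0(prefix, ".n1"), cout, norm))
  h <- conv3_layer(tp, ps, h, paste0(prefix, ".c2"), cout, cout)
  ad_relu(tp, norm_layer(tp, ps, h, paste0(prefix, ".n2"), cout, norm))
}

# residual block: shortcut bypasses the two convolutions
res_block <- function(tp, ps, x, prefix, cin, cout, norm) {
  h <- conv3_layer(tp, ps, x, paste0(prefix, ".c1"), cin, cout)
  h <- ad_relu(tp, norm_layer(tp, ps, h, paste0(prefix, ".n1"), cout, norm))
  h <- conv3_layer(tp, ps, h, paste0(prefix, ".c2"), cout, cout)
  h <- norm_layer(tp, ps, h, paste0(prefix, ".n2"), cout, norm)
  s <- if (cin == cout) x else conv1_layer(tp, ps, x, paste0(prefix, ".sc"),
                                           cin, cout)
  ad_relu(tp, ad_add(tp, h, s))
}

# additive attention gate: skip features x gated by decoder signal g
attention_gate <- function(tp, ps, x, g, prefix, ch) {
  ci <- max(ch %/% 2L, 1L)
  qx <- conv1_layer(tp, ps, x, paste0(prefix, ".wx"), ch, ci)
  qg <- conv1_layer(tp, ps, g, paste0(prefix, ".wg"), ch, ci)
  q <- ad_relu(tp, ad_add(tp, qx, qg))
  a <- ad_sigmoid(tp, conv1_layer(tp, ps, q, paste0(prefix, ".psi"), ci, 1L))
  ad_mul_att(tp, x, a)
}

## ---- architecture forward passes ---------------------------------------

forward_unet <- function(cfg, block) function(tp, ps, x) {
  d <- cfg$depth; ch <- cfg$base_channels * 2L^(0:d)
  enc <- vector("list", d)
  h <- x; cin <- cfg$in_channels
  for (i in seq_len(d)) {
    enc[[i]] <- block(tp, ps, h, paste0("enc", i), cin, ch[i], cfg$norm)
    h <- ad_maxpool2(tp, enc[[i]])
    cin <- ch[i]
  }
  h <- block(tp, ps, h, "bottom", cin, ch[d + 1L], cfg$norm)
  for (i in rev(seq_len(d))) {
    u <- up_layer(tp, ps, h, paste0("up", i), ch[i + 1L], ch[i])
    skip <- enc[[i]]
    if (cfg$architecture == "attention_unet") {
      skip <- attention_gate(tp, ps, skip, u, paste0("ag", i), ch[i])
    }
    h <- block(tp, ps, ad_concat_c(tp, u, skip), paste0("dec", i),
               2L * ch[i], ch[i], cfg$norm)
  }
  conv1_layer(tp, ps, h, "head", ch[1L], cfg$out_classes)
}

forward_unetpp <- function(cfg) function(tp, ps, x) {
  d <- cfg$depth; ch <- cfg$base_channels * 2L^(0:d)
  # X[[i+1]][[j+1]] is node (level i, column j), channels ch[i+1]
  X <- lapply(0:d, function(i) vector("list", d - i + 1L))
  h <- x; cin <- cfg$in_channels
  for (i in 0:d) {  # backbone column j = 0
    if (i > 0L) {
      h <- ad_maxpool2(tp, X[[i]][[1L]])
      cin <- ch[i]
    }
    X[[i + 1L]][[1L]] <- conv_block(tp, ps, h, sprintf("x%d_0", i),
                                    cin, ch[i + 1L], cfg$norm)
  }
  for (j in 1:d) {
    for (i in 0:(d - j)) {
      u <- up_layer(tp, ps, X[[i + 2L]][[j]], sprintf("up%d_%d", i, j),
                    ch[i + 2L], ch[i + 1L])
      cat_id <- u
      for (jj in seq_len(j)) cat_id <- ad_concat_c(tp, cat_id, X[[i + 1L]][[jj]])
      X[[i + 1L]][[j + 1L]] <- conv_block(tp, ps, cat_id, sprintf("x%d_%d", i, j),
                                          (j + 1L) * ch[i + 1L], ch[i + 1L],
                                          cfg$norm)
    }
  }
  conv1_layer(tp, ps, X[[1L]][[d + 1L]], "head", ch[1L], cfg$out_classes)
}

#' Build a segmentation model
#'
#' Instantiates the architecture's parameters deterministically from `seed`
#' (He-style normal initialization). The model is fully convolutional, so the
#' same parameters serve any input whose sides are divisible by `2^depth`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `seg_model` object.
#' @export
build_seg_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  ps <- new.env(parent = emptyenv())
  ps$W <- list()
  fwd <- switch(config$architecture,
    unet = forward_unet(config, conv_block),
    attention_unet = forward_unet(config, conv_block),
    residual_unet = forward_unet(config, res_block),
    unetpp = forward_unetpp(config)
  )
  model <- structure(list(config = config, ps = ps, fwd = fwd, seed = seed),
                     class = "seg_model")
  # materialize parameters with a dummy forward pass under the seed,
  # preserving the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- 2L^config$depth
  tp <- ad_tape()
  x <- ad_const(tp, array(0, c(s, s, 1L)))
  fwd(tp, ps, x)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  model
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s depth=%d base=%d params=%d>\n",
              x$config$architecture, x$config$depth, x$config$base_channels,
              count_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A `seg_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$ps$W, length, integer(1)))
}

check_image_dims <- function(model, image) {
  d <- dim(image)
  s <- 2L^model$config$depth
  if (length(d) != 2L || d[1] %% s != 0L || d[2] %% s != 0L) {
    stop(sprintf("image dims must be H x W with both divisible by %d", s),
         call. = FALSE)
  }
}

# Forward pass to class scores; image is an H x W matrix in [0, 1].
model_scores <- function(model, image, tp = ad_tape()) {
  check_image_dims(model, image)
  x <- ad_const(tp, array(image, c(dim(image), 1L)))
  list(tp = tp, scores = model$fwd(tp, model$ps, x))
}

#' Predict per-pixel class probabilities and a binary mask
#'
#' @param model A `seg_model` from [build_seg_model()].
#' @param image Numeric H x W matrix with intensities in \[0, 1\].
#' @return A list with `probs` (H x W x 2 array; channel 1 background,
#'   channel 2 foreground; sums to 1 per pixel) and `mask` (H x W binary
#'   matrix, the per-pixel argmax).
#' @export
predict_mask <- function(model, image) {
  fw <- model_scores(model, image)
  s <- ad_val(fw$tp, fw$scores)
  m <- pmax(s[, , 1], s[, , 2])
  e1 <- exp(s[, , 1] - m); e2 <- exp(s[, , 2] - m)
  z <- e1 + e2
  probs <- array(c(e1 / z, e2 / z), dim(s))
  list(probs = probs, mask = (probs[, , 2] > probs[, , 1]) * 1)
}

## ---- training steps ----------------------------------------------------

# Loss and parameter gradients for one (image, one-hot target) sample.
model_loss_grads <- function(model, image, target_onehot, gr, alpha = 1) {
  fw <- model_scores(model, image)
  loss_id <- ad_hybrid_loss_node(fw$tp, fw$scores, target_onehot, alpha)
  ad_backward(fw$tp, loss_id, gr)
  as.numeric(ad_val(fw$tp, loss_id))
}

# One optimizer step on a mini-batch (list of list(image, target) with image
# in [0,1] and target one-hot H x W x 2). Returns the mean loss.
train_batch_step <- function(model, batch, opt, alpha = 1) {
  gr <- grad_store()
  losses <- vapply(batch, function(s) {
    model_loss_grads(model, s$image, s$target, gr, alpha)
  }, numeric(1))
  n <- length(batch)
  for (nm in names(gr$G)) gr$G[[nm]] <- gr$G[[nm]] / n
  adam_step(opt, model$ps, gr)
  mean(losses)
}

# Mean hybrid loss of the model over a list of samples (no gradients).
evaluate_loss <- function(model, samples, alpha = 1) {
  mean(vapply(samples, function(s) {
    pr <- predict_mask(model, s$image)
    hybrid_loss(pr$probs, s$target, alpha = alpha)$total
  }, numeric(1)))
}
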