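# Image transformation search space: 16 operations with discretized
# magnitude (10 levels) and application probability (11 levels), grouped
# into sub-strategies (pairs of ops) and strategies (lists of sub-strategies).

N_MAG_LEVELS <- 10L   # magnitude levels 0..9
N_PROB_LEVELS <- 11L  # probability levels 0..10 -> phi in {0, 0.1, ..., 1}

#' Table of the 16 augmentation operations
#'
#' Returns the operation table that defines the augmentation search space:
#' operation name, whether it carries a magnitude, the magnitude range in the
#' operation's native units, and whether the operation is geometric (moves
#' pixels, so the mask must be transformed identically) or photometric
#' (changes intensities only, mask untouched).
#'
#' Magnitude ranges (native units): ShearX/Y shear factor in [-0.3, 0.3];
#' TranslateX/Y offset in pixels in [-150, 150] (at the native 512 px scan
#' width; scaled proportionally for resized images); Rotate degrees in
#' [-30, 30]; Color/Contrast/Sharpness/Brightness enhancement factor
#' (0 = fully degenerate, 1 = identity) in [0, 0.9] (Color in [0.1, 0.9]);
#' Posterize bits kept in [4, 8]; Solarize inversion threshold in [0, 256].
#'
#' @return A data frame with one row per operation and columns `name`,
#'   `has_magnitude`, `mag_min`, `mag_max`, `category`.
#' @export
#' @examples
#' op_table()
op_table <- function() {
  df <- data.frame(
    name = c("ShearX", "ShearY", "TranslateX", "TranslateY", "Rotate",
             "Color", "Posterize", "Solarize", "Contrast", "Sharpness",
             "Brightness", "AutoContrast", "Equalize", "Invert",
             "HorizontalFlip", "VerticalFlip"),
    has_magnitude = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                      TRUE, TRUE, TRUE, TRUE, TRUE,
                      TRUE, FALSE, FALSE, FALSE,
                      FALSE, FALSE),
    mag_min = c(-0.3, -0.3, -150, -150, -30,
                0.1, 4, 0, 0, 0,
                0, NA, NA, NA, NA, NA),
    mag_max = c(0.3, 0.3, 150, 150, 30,
                0.9, 8, 256, 0.9, 0.9,
                0.9, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  geometric <- c("ShearX", "ShearY", "TranslateX", "TranslateY", "Rotate",
                 "HorizontalFlip", "VerticalFlip")
  df$category <- ifelse(df$name %in% geometric, "geometric", "photometric")
  df
}

# Normalize user-facing spellings ("Horizontal Flip") to canonical names.
normalize_op_name <- function(name) {
  key <- tolower(gsub("[ _-]", "", name))
  tab <- op_table()$name
  hit <- match(key, tolower(tab))
  if (any(is.na(hit))) {
    stop("unknown operation name(s): ",
         paste(name[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  tab[hit]
}

op_spec <- function(name) {
  tab <- op_table()
  tab[tab$name == normalize_op_name(name), , drop = FALSE]
}

#' Construct one operation instance
#'
#' An operation instance is one of the 16 operations together with a discrete
#' magnitude level in 0..9 (indexing ten equally spaced values across the
#' operation's magnitude range) and a discrete probability level in 0..10
#' (probability of application is `probability_level / 10`).
#'
#' Operations without a magnitude (AutoContrast, Equalize, Invert, the two
#' flips) carry but ignore their magnitude level; `NA` is accepted for any
#' operation and resolves to the midpoint of the magnitude range if the
#' operation needs one.
#'
#' @param op Operation name (see [op_table()]).
#' @param magnitude_level Integer in 0..9, or `NA`.
#' @param probability_level Integer in 0..10.
#' @return An object of class `op_instance`.
#' @export
#' @examples
#' op_instance("Rotate", 0, 10)   # rotate by -30 degrees, always applied
op_instance <- function(op, magnitude_level = NA, probability_level) {
  op <- normalize_op_name(op)
  if (!is.na(magnitude_level)) {
    magnitude_level <- as.integer(magnitude_level)
    if (magnitude_level < 0L || magnitude_level >= N_MAG_LEVELS) {
      stop("magnitude_level must be in 0..", N_MAG_LEVELS - 1L, call. = FALSE)
    }
  } else {
    magnitude_level <- NA_integer_
  }
  if (length(probability_level) != 1L || is.na(probability_level) ||
      probability_level != as.integer(probability_level)) {
    stop("probability_level must be a single integer in 0..10", call. = FALSE)
  }
  probability_level <- as.integer(probability_level)
  if (probability_level < 0L || probability_level >= N_PROB_LEVELS) {
    stop("probability_level must be in 0..", N_PROB_LEVELS - 1L, call. = FALSE)
  }
  structure(list(op = op, magnitude_level = magnitude_level,
                 probability_level = probability_level),
            class = "op_instance")
}

#' Resolve the native-unit magnitude of an operation instance
#'
#' Level `l` maps linearly across the operation's magnitude range:
#' `min + l * (max - min) / 9`. Posterize is rounded to the nearest integer
#' bit count. Operations without a magnitude return `NA`.
#'
#' @param inst An [op_instance()].
#' @return Magnitude in the operation's native units, or `NA`.
#' @export
#' @examples
#' magnitude_value(op_instance("Rotate", 0, 10))    # -30
#' magnitude_value(op_instance("Contrast", 9, 10))  # 0.9
magnitude_value <- function(inst) {
  stopifnot(inherits(inst, "op_instance"))
  spec <- op_spec(inst$op)
  if (!spec$has_magnitude) return(NA_real_)
  lvl <- inst$magnitude_level
  if (is.na(lvl)) {
    val <- (spec$mag_min + spec$mag_max) / 2   # null magnitude on a magnitude op
  } else {
    val <- spec$mag_min + lvl * (spec$mag_max - spec$mag_min) / (N_MAG_LEVELS - 1)
  }
  if (inst$op == "Posterize") val <- round(val)
  val
}

#' @export
print.op_instance <- function(x, ...) {
  mag <- if (is.na(x$magnitude_level)) "-" else x$magnitude_level
  cat(sprintf("<%s level=%s phi=%.1f>\n", x$op, mag, x$probability_level / 10))
  invisible(x)
}

#' Construct a sub-strategy (an ordered pair of operations)
#'
#' @param first,second [op_instance()] objects, applied in order.
#' @return An object of class `sub_strategy`.
#' @export
sub_strategy <- function(first, second) {
  stopifnot(inherits(first, "op_instance"), inherits(second, "op_instance"))
  structure(list(first = first, second = second), class = "sub_strategy")
}

#' Construct an augmentation strategy
#'
#' A strategy is an ordered list of sub-strategies. The search samples
#' 5-sub-strategy strategies; consolidating the top five searched strategies
#' yields a 25-sub-strategy strategy. Arbitrary lengths are accepted here
#' (e.g. when deserializing).
#'
#' @param substrategies List of [sub_strategy()] objects.
#' @return An object of class `aug_strategy`.
#' @export
aug_strategy <- function(substrategies) {
  if (!length(substrategies) ||
      !all(vapply(substrategies, inherits, logical(1), "sub_strategy"))) {
    stop("substrategies must be a non-empty list of sub_strategy objects",
         call. = FALSE)
  }
  structure(list(substrategies = substrategies), class = "aug_strategy")
}

#' @export
length.aug_strategy <- function(x) length(x$substrategies)

#' @export
print.aug_strategy <- function(x, ...) {
  cat(sprintf("Augmentation strategy with %d sub-strategies\n", length(x)))
  for (i in seq_along(x$substrategies)) {
    s <- x$substrategies[[i]]
    f <- s$first; g <- s$second
    fm <- if (is.na(f$magnitude_level)) "-" else f$magnitude_level
    gm <- if (is.na(g$magnitude_level)) "-" else g$magnitude_level
    cat(sprintf("  %2d: %s(%s, %.1f) -> %s(%s, %.1f)\n", i,
                f$op, fm, f$probability_level / 10,
                g$op, gm, g$probability_level / 10))
  }
  invisible(x)
}

#' The identity strategy
#'
#' A strategy of `n` sub-strategies whose operations all have application
#' probability 0, so applying it returns every input unchanged. Used as the
#' no-augmentation baseline.
#'
#' @param n Number of sub-strategies.
#' @return An `aug_strategy`.
#' @export
identity_strategy <- function(n = 5L) {
  noop <- op_instance("Invert", NA, 0L)
  aug_strategy(replicate(n, sub_strategy(noop, noop), simplify = FALSE))
}

#' Construct and validate an image/mask pair
#'
#' @param image Numeric matrix (H x W), intensities in \[0, 255\].
#' @param mask Matrix of the same dimensions with values in \{0, 1\}.
#' @return A list with elements `image` and `mask`, class `img_mask_pair`.
#' @export
img_mask_pair <- function(image, mask) {
  if (!is.matrix(image) || !is.matrix(mask)) {
    stop("image and mask must be matrices", call. = FALSE)
  }
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("mask must be strictly binary (values 0/1)", call. = FALSE)
  }
  structure(list(image = image, mask = mask * 1), class = "img_mask_pair")
}

## ---- geometric kernel -------------------------------------------------

# Sample img at 0-based coordinates (xs, ys) (matrices, x = column, y = row).
# Bilinear interpolation; out-of-bounds -> fill.
sample_bilinear <- function(img, xs, ys, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    out <- matrix(fill, nrow(xs), ncol(xs))
    idx <- (pmin(pmax(xi, 0), w - 1)) * h + pmin(pmax(yi, 0), h - 1) + 1
    out[ok] <- img[idx[ok]]
    out
  }
  v00 <- gather(x0, y0);     v10 <- gather(x0 + 1, y0)
  v01 <- gather(x0, y0 + 1); v11 <- gather(x0 + 1, y0 + 1)
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

sample_nearest <- function(img, xs, ys, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(xs); yi <- round(ys)
  ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
  out <- matrix(fill, nrow(xs), ncol(xs))
  idx <- (pmin(pmax(xi, 0), w - 1)) * h + pmin(pmax(yi, 0), h - 1) + 1
  out[ok] <- img[idx[ok]]
  out
}

# Apply the affine map dest -> src: (xs, ys) = M %*% (xd, yd) + t, 0-based
# pixel coordinates, to image (bilinear) and mask (nearest, re-binarized).
# Vacated regions are filled with 0 (dark OCT background).
warp_affine_pair <- function(pair, M, t) {
  h <- nrow(pair$image); w <- ncol(pair$image)
  xd <- matrix(rep(0:(w - 1), each = h), h, w)
  yd <- matrix(rep(0:(h - 1), times = w), h, w)
  xs <- M[1, 1] * xd + M[1, 2] * yd + t[1]
  ys <- M[2, 1] * xd + M[2, 2] * yd + t[2]
  img <- sample_bilinear(pair$image, xs, ys, fill = 0)
  msk <- sample_nearest(pair$mask, xs, ys, fill = 0)
  img_mask_pair(pmin(pmax(img, 0), 255), (msk >= 0.5) * 1)
}

apply_geometric <- function(pair, op, mag) {
  h <- nrow(pair$image); w <- ncol(pair$image)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  switch(op,
    HorizontalFlip = img_mask_pair(pair$image[, w:1, drop = FALSE],
                                   pair$mask[, w:1, drop = FALSE]),
    VerticalFlip = img_mask_pair(pair$image[h:1, , drop = FALSE],
                                 pair$mask[h:1, , drop = FALSE]),
    TranslateX = warp_affine_pair(pair, diag(2), c(-mag, 0)),
    TranslateY = warp_affine_pair(pair, diag(2), c(0, -mag)),
    ShearX = {
      # forward: x' = x + mag * (y - cy); inverse shear about the center
      M <- matrix(c(1, 0, -mag, 1), 2, 2)
      warp_affine_pair(pair, M, c(mag * cy, 0))
    },
    ShearY = {
      M <- matrix(c(1, -mag, 0, 1), 2, 2)
      warp_affine_pair(pair, M, c(0, mag * cx))
    },
    Rotate = {
      th <- mag * pi / 180  # counterclockwise positive, about the center
      M <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      t <- c(cx - M[1, 1] * cx - M[1, 2] * cy,
             cy - M[2, 1] * cx - M[2, 2] * cy)
      warp_affine_pair(pair, M, t)
    },
    stop("not a geometric op: ", op)
  )
}

## ---- photometric kernel -----------------------------------------------

# 3x3 smoothing kernel used by Sharpness (PIL SMOOTH), replicate-padded.
smooth3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1, 1:h, h), c(1, 1:w, w)]
  k <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1), 3, 3) / 13
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + k[di + 1, dj + 1] * p[(1:h) + di, (1:w) + dj]
  }
  out
}

apply_photometric <- function(img, op, mag) {
  out <- switch(op,
    Invert = 255 - img,
    Solarize = ifelse(img >= mag, 255 - img, img),
    Posterize = {
      bits <- as.integer(mag)
      keep <- bitwAnd(255L, bitwShiftL(255L, 8L - bits))
      matrix(bitwAnd(as.integer(round(img)), keep), nrow(img), ncol(img))
    },
    AutoContrast = {
      lo <- min(img); hi <- max(img)
      if (hi > lo) (img - lo) * (255 / (hi - lo)) else img
    },
    Equalize = {
      v <- as.integer(round(img))
      h <- tabulate(v + 1L, nbins = 256L)
      cdf <- cumsum(h)
      cdf_min <- min(cdf[cdf > 0])
      n <- length(v)
      if (n == cdf_min) {
        img  # constant image
      } else {
        lut <- round(255 * (cdf - cdf_min) / (n - cdf_min))
        matrix(lut[v + 1L], nrow(img), ncol(img))
      }
    },
    Brightness = img * mag,
    Contrast = {
      m <- mean(round(img))
      m + mag * (img - m)
    },
    Sharpness = {
      b <- smooth3(img)
      b + mag * (img - b)
    },
    Color = img,  # saturation blend is the identity on a single gray channel
    stop("not a photometric op: ", op)
  )
  pmin(pmax(out, 0), 255)
}

## ---- application ------------------------------------------------------

#' Apply one operation instance to an image/mask pair
#'
#' With probability `probability_level / 10` the transformation is applied;
#' otherwise the pair is returned unchanged. Geometric operations transform
#' image and mask with identical parameters (mask via nearest-neighbour
#' sampling, then re-binarized); photometric operations transform the image
#' only. Output dimensions always equal input dimensions and intensities are
#' clipped to \[0, 255\]. The probability draw consumes the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param pair An [img_mask_pair()].
#' @param inst An [op_instance()].
#' @return The transformed (or untouched) `img_mask_pair`.
#' @export
apply_op <- function(pair, inst) {
  if (!inherits(pair, "img_mask_pair")) pair <- img_mask_pair(pair$image, pair$mask)
  stopifnot(inherits(inst, "op_instance"))
  phi <- inst$probability_level / 10
  if (phi <= 0 || stats::runif(1) > phi) return(pair)
  spec <- op_spec(inst$op)
  mag <- magnitude_value(inst)
  if (spec$category == "geometric") {
    if (inst$op %in% c("TranslateX", "TranslateY")) {
      # translate magnitudes are in pixels at the native 512 px scan size;
      # scale proportionally for resized images
      mag <- mag * ncol(pair$image) / 512
    }
    apply_geometric(pair, inst$op, mag)
  } else {
    img_mask_pair(apply_photometric(pair$image, inst$op, mag), pair$mask)
  }
}

#' Apply a sub-strategy (two successive operations)
#'
#' Equivalent to `apply_op(apply_op(pair, sub$first), sub$second)` with two
#' independent probability draws.
#'
#' @param pair An [img_mask_pair()].
#' @param sub A [sub_strategy()].
#' @return The transformed `img_mask_pair`.
#' @export
apply_substrategy <- function(pair, sub) {
  stopifnot(inherits(sub, "sub_strategy"))
  apply_op(apply_op(pair, sub$first), sub$second)
}

#' Apply a strategy (uniformly chosen sub-strategy)
#'
#' One sub-strategy is selected uniformly at random and applied; this mirrors
#' how a strategy augments each mini-batch during training.
#'
#' @param pair An [img_mask_pair()].
#' @param strategy An [aug_strategy()].
#' @return The transformed `img_mask_pair`.
#' @export
apply_strategy <- function(pair, strategy) {
  stopifnot(inherits(strategy, "aug_strategy"))
  if (!length(strategy)) stop("empty strategy", call. = FALSE)
  k <- sample.int(length(strategy), 1L)
  apply_substrategy(pair, strategy$substrategies[[k]])
}

## ---- (de)serialization ------------------------------------------------

#' Serialize a strategy to a JSON policy document
#'
#' The document is a JSON array of sub-strategies; each sub-strategy is an
#' array of two `[op_name, magnitude_level | null, probability_level]`
#' triplets.
#'
#' @param strategy An [aug_strategy()].
#' @param path Optional file path; if given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
serialize_strategy <- function(strategy, path = NULL) {
  stopifnot(inherits(strategy, "aug_strategy"))
  enc <- lapply(strategy$substrategies, function(s) {
    lapply(list(s$first, s$second), function(o) {
      list(o$op,
           if (is.na(o$magnitude_level)) NULL else o$magnitude_level,
           o$probability_level)
    })
  })
  js <- jsonlite::toJSON(enc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a JSON policy document into a strategy
#'
#' @param doc JSON string, or a file path to one.
#' @return An [aug_strategy()].
#' @export
parse_strategy <- function(doc) {
  if (length(doc) == 1L && !grepl("\\[", doc) && file.exists(doc)) {
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  }
  raw <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (!length(raw)) stop("policy document contains no sub-strategies", call. = FALSE)
  subs <- lapply(seq_along(raw), function(i) {
    s <- raw[[i]]
    if (length(s) != 2L) {
      stop(sprintf("sub-strategy %d: expected exactly 2 operations, got %d",
                   i, length(s)), call. = FALSE)
    }
    ops <- lapply(seq_len(2L), function(j) {
      o <- s[[j]]
      if (length(o) != 3L) {
        stop(sprintf("sub-strategy %d, op %d: expected [name, level, prob]",
                     i, j), call. = FALSE)
      }
      lvl <- o[[2]]
      if (!is.null(lvl) && (!is.numeric(lvl) || lvl != as.integer(lvl))) {
        stop(sprintf("sub-strategy %d, op %d: magnitude level must be an integer or null",
                     i, j), call. = FALSE)
      }
      pr <- o[[3]]
      if (!is.numeric(pr) || length(pr) != 1L || pr != as.integer(pr) ||
          pr < 0 || pr >= N_PROB_LEVELS) {
        stop(sprintf("sub-strategy %d, op %d: probability level must be an integer in 0..10",
                     i, j), call. = FALSE)
      }
      tryCatch(
        op_instance(o[[1]], if (is.null(lvl)) NA else lvl, pr),
        error = function(e) {
          stop(sprintf("sub-strategy %d, op %d: %s", i, j, conditionMessage(e)),
               call. = FALSE)
        }
      )
    })
    sub_strategy(ops[[1]], ops[[2]])
  })
  aug_strategy(subs)
}

#' The searched policy shipped with the package
#'
#' Loads the bundled 25-sub-strategy consolidated policy (the outcome of a
#' full-scale search with a U-Net++ child model) from `inst/policies/`.
#'
#' @return An [aug_strategy()] of 25 sub-strategies.
#' @export
bundled_policy <- function() {
  parse_strategy(system.file("policies", "table2_unetpp.json",
                             package = "autoaugseg", mustWork = TRUE))
}
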