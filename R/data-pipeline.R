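# Synthetic OCT phantom cohort, dataset manifest I/O, patient-level nested
# splitting, and preprocessing of scan records into model tensors.
#
# The phantom emulates the structure of a retinal B-scan study: patients x
# eyes x consecutive scans of layered tissue (bright band stack on a dark
# background) containing hypo-reflective cavities whose size and position
# evolve smoothly across the scan index, plus multiplicative speckle noise,
# occasional vertical vessel shadows, and per-acquisition brightness and
# contrast offsets.

#' Phantom cohort configuration
#'
#' Defaults emulate the study cohort: 30 patients, both eyes, 25 consecutive
#' B-scans per eye (1500 scans in total). The remaining knobs control the
#' phantom's appearance; the methods vignette discusses what they emulate.
#'
#' @param n_patients,eyes_per_patient,scans_per_eye Cohort shape.
#' @param size Image side in pixels (square scans).
#' @param n_bands Number of tissue bands in the retinal stack.
#' @param cavity_range Integer range (min, max) of cavities per eye.
#' @param cavity_darkness Multiplicative intensity factor inside a cavity
#'   (hypo-reflective, so < 1).
#' @param speckle Speckle strength: standard deviation of the multiplicative
#'   noise (mean 1).
#' @param vessel_rate Probability that a scan carries a vessel shadow.
#' @param brightness_jitter,contrast_jitter Ranges (min, max) of the per-eye
#'   multiplicative brightness and contrast factors.
#' @param coherence In (0, 1): how slowly cavity geometry drifts across the
#'   scan index (higher = more similar adjacent scans).
#' @param geometry_jitter In \[0, 1\]: how much the layer-band geometry
#'   (retina position, thickness, curvature, band widths) varies across
#'   eyes. 1 = full variability (default); 0 = all eyes share the same band
#'   geometry, isolating photometric variability (used by the
#'   domain-shift experiments). Cavities are always drawn per eye.
#' @param seed Base seed; every scan derives its own stream from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 30L, eyes_per_patient = 2L,
                           scans_per_eye = 25L, size = 128L, n_bands = 5L,
                           cavity_range = c(1L, 4L), cavity_darkness = 0.25,
                           speckle = 0.2, vessel_rate = 0.3,
                           brightness_jitter = c(0.8, 1.2),
                           contrast_jitter = c(0.75, 1.25),
                           coherence = 0.9, geometry_jitter = 1,
                           seed = 1L) {
  stopifnot(n_patients >= 1, eyes_per_patient >= 1, scans_per_eye >= 1,
            size >= 16, cavity_range[1] >= 1,
            cavity_range[2] >= cavity_range[1],
            brightness_jitter[1] <= brightness_jitter[2],
            contrast_jitter[1] <= contrast_jitter[2],
            coherence > 0, coherence < 1,
            geometry_jitter >= 0, geometry_jitter <= 1)
  structure(as.list(environment()), class = "phantom_config")
}

# Per-eye latent geometry: band boundaries and cavity trajectories.
phantom_eye_latents <- function(cfg) {
  s <- cfg$size
  gj <- cfg$geometry_jitter
  jit <- function(lo, hi) {  # shrink the draw toward the range midpoint
    mid <- (lo + hi) / 2
    mid + gj * (stats::runif(1, lo, hi) - mid)
  }
  top0 <- jit(0.18, 0.30) * s
  thick <- jit(0.38, 0.50) * s
  amp <- jit(0.02, 0.06) * s
  phase <- gj * stats::runif(1, 0, 2 * pi)
  freq <- jit(0.6, 1.4)
  # band fractional widths and intensities (bright stack on dark background)
  wfrac <- 1 + gj * (stats::runif(cfg$n_bands, 0.6, 1.4) - 1)
  wfrac <- wfrac / sum(wfrac)
  inten <- rep(c(200, 120), length.out = cfg$n_bands) +
    gj * stats::rnorm(cfg$n_bands, 0, 10)
  cavity_band <- sample(seq_len(max(cfg$n_bands - 2L, 1L)) + 1L, 1L)
  n_cav <- sample(seq(cfg$cavity_range[1], cfg$cavity_range[2]), 1L)
  drift_sd <- (1 - cfg$coherence) * 0.05 * s
  cav <- lapply(seq_len(n_cav), function(i) {
    list(x0 = stats::runif(1, 0.2, 0.8) * s,
         s0 = stats::runif(1, 0.2, 0.8) * cfg$scans_per_eye,
         sig_s = stats::runif(1, 0.6, 1.0) * cfg$scans_per_eye,
         rx = stats::runif(1, 0.09, 0.16) * s,
         ry = stats::runif(1, 0.05, 0.08) * s,
         xdrift = stats::rnorm(1, 0, drift_sd),
         bright = stats::runif(1, cfg$brightness_jitter[1],
                               cfg$brightness_jitter[2]),
         contr = stats::runif(1, cfg$contrast_jitter[1],
                              cfg$contrast_jitter[2]))
  })
  list(top0 = top0, thick = thick, amp = amp, phase = phase, freq = freq,
       wfrac = wfrac, inten = inten, cavity_band = cavity_band, cav = cav,
       bright = stats::runif(1, cfg$brightness_jitter[1],
                             cfg$brightness_jitter[2]),
       contr = stats::runif(1, cfg$contrast_jitter[1],
                            cfg$contrast_jitter[2]))
}

# Render one scan (image + mask) from an eye's latents.
phantom_scan <- function(cfg, lat, scan_index) {
  s <- cfg$size
  xs <- 0:(s - 1)
  top <- lat$top0 + lat$amp * sin(2 * pi * lat$freq * xs / s + lat$phase)
  bounds <- rbind(top, top + outer(cumsum(lat$wfrac), rep(1, s)) * lat$thick)
  img <- matrix(30, s, s)  # dark vitreous/background floor
  rows <- matrix(rep(0:(s - 1), times = s), s, s)
  for (b in seq_len(cfg$n_bands)) {
    lo <- matrix(rep(bounds[b, ], each = s), s, s)
    hi <- matrix(rep(bounds[b + 1L, ], each = s), s, s)
    img[rows >= lo & rows < hi] <- lat$inten[b]
  }
  # cavities inside the designated band, smooth across scan_index
  mask <- matrix(0, s, s)
  cb <- lat$cavity_band
  for (cv in lat$cav) {
    scale <- exp(-(scan_index - cv$s0)^2 / (2 * cv$sig_s^2))
    if (scale < 0.35) next
    cx <- cv$x0 + cv$xdrift * (scan_index - cv$s0)
    ci <- round(cx)
    if (ci < 1 || ci > s) next
    cy <- (bounds[cb, ci] + bounds[cb + 1L, ci]) / 2
    rx <- cv$rx * scale; ry <- cv$ry * scale
    if (rx < 1.5 || ry < 1.5) next
    cols <- matrix(rep(xs, each = s), s, s)
    ell <- ((cols - cx) / rx)^2 + ((rows - cy) / ry)^2 <= 1
    mask[ell] <- 1
  }
  img[mask == 1] <- img[mask == 1] * cfg$cavity_darkness
  # vessel shadows: dark vertical streaks through and below the tissue
  if (stats::runif(1) < cfg$vessel_rate) {
    n_v <- sample(1:2, 1L)
    for (v in seq_len(n_v)) {
      x0 <- sample.int(s, 1L)
      w <- sample(2:5, 1L)
      cols_idx <- intersect(x0:(x0 + w), seq_len(s))
      shade <- rows[, cols_idx, drop = FALSE] >=
        matrix(rep(top[cols_idx], each = s), s, length(cols_idx))
      block <- img[, cols_idx, drop = FALSE]
      block[shade] <- block[shade] * 0.45
      img[, cols_idx] <- block
    }
  }
  # multiplicative speckle (gamma, mean 1, sd = cfg$speckle)
  if (cfg$speckle > 0) {
    shp <- 1 / cfg$speckle^2
    img <- img * matrix(stats::rgamma(s * s, shape = shp, rate = shp), s, s)
  }
  # per-acquisition brightness/contrast offset
  m <- mean(img)
  img <- (m + lat$contr * (img - m)) * lat$bright
  img_mask_pair(round(pmin(pmax(img, 0), 255)), mask)
}

#' Generate a synthetic phantom cohort on disk
#'
#' Writes 8-bit grayscale PNG images and binary PNG masks under `out_dir`
#' (one subdirectory per patient/eye) plus a `manifest.csv`, and returns the
#' manifest. With default settings this produces
#' 30 patients x 2 eyes x 25 scans = 1500 records.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame (columns `patient_id`, `eye`,
#'   `scan_index`, `image_path`, `mask_path`), invisibly carrying the config
#'   as an attribute.
#' @export
generate_phantom <- function(config = phantom_config(), out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  rows <- list()
  set.seed(config$seed)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (e in seq_len(config$eyes_per_patient)) {
      eye <- c("OD", "OS")[(e - 1L) %% 2L + 1L]
      lat <- phantom_eye_latents(config)
      sub <- file.path(out_dir, pid, eye)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      for (sc in seq_len(config$scans_per_eye) - 1L) {
        pair <- phantom_scan(config, lat, sc)
        ip <- file.path(sub, sprintf("scan_%02d.png", sc))
        mp <- file.path(sub, sprintf("mask_%02d.png", sc))
        png::writePNG(pair$image / 255, ip)
        png::writePNG(pair$mask, mp)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, eye = eye, scan_index = sc,
          image_path = ip, mask_path = mp, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "config") <- config
  invisible(manifest)
}

#' Write a dataset manifest to CSV
#'
#' Paths are stored relative to the manifest's directory.
#'
#' @param manifest Manifest data frame.
#' @param path CSV destination.
#' @export
write_manifest <- function(manifest, path) {
  base <- normalizePath(dirname(path), mustWork = FALSE)
  rel <- function(p) {
    ap <- normalizePath(p, mustWork = FALSE)
    sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", base), "/?"),
        "", ap)
  }
  out <- manifest
  out$image_path <- vapply(manifest$image_path, rel, character(1))
  out$mask_path <- vapply(manifest$mask_path, rel, character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV path; relative file paths are resolved against
#'   the manifest's directory.
#' @param check Verify that all referenced files exist.
#' @return Manifest data frame with absolute paths.
#' @export
read_manifest <- function(path, check = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "scan_index", "image_path", "mask_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  abs <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  m$image_path <- abs(m$image_path)
  m$mask_path <- abs(m$mask_path)
  if (anyDuplicated(m[c("patient_id", "eye", "scan_index")])) {
    stop("duplicate (patient_id, eye, scan_index) in manifest", call. = FALSE)
  }
  if (check) {
    missing <- !file.exists(m$image_path) | !file.exists(m$mask_path)
    if (any(missing)) {
      stop("manifest references missing files, e.g. ",
           m$image_path[which(missing)[1]], call. = FALSE)
    }
  }
  m
}

# Read one image file as an H x W intensity matrix in [0, 255].
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3L) {
    # luminance conversion for RGB(A) input
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a * 255
}

#' Read one scan record as an image/mask pair
#'
#' @param record One manifest row (list or single-row data frame).
#' @return An [img_mask_pair()] at native resolution, intensities \[0, 255\].
#' @export
read_scan_pair <- function(record) {
  img <- read_gray(record$image_path)
  msk <- read_gray(record$mask_path)
  msk <- (msk >= 127.5) * 1
  img_mask_pair(img, msk)
}

# Aspect-preserving resize to a square target with zero padding
# (bottom/right); returns the pair plus the pad/scale info.
resize_pair <- function(pair, target) {
  h <- nrow(pair$image); w <- ncol(pair$image)
  if (h == target && w == target) {
    return(list(pair = pair, scale = 1, pad_h = 0L, pad_w = 0L))
  }
  sc <- target / max(h, w)
  nh <- max(1L, round(h * sc)); nw <- max(1L, round(w * sc))
  xs <- matrix(rep((0:(nw - 1)) / sc, each = nh), nh, nw)
  ys <- matrix(rep((0:(nh - 1)) / sc, times = nw), nh, nw)
  img <- sample_bilinear(pair$image, xs, ys)
  msk <- (sample_nearest(pair$mask, xs, ys) >= 0.5) * 1
  out_i <- matrix(0, target, target)
  out_m <- matrix(0, target, target)
  out_i[1:nh, 1:nw] <- img
  out_m[1:nh, 1:nw] <- msk
  list(pair = img_mask_pair(out_i, out_m), scale = sc,
       pad_h = target - nh, pad_w = target - nw)
}

# [0,255] pair -> model sample: image in [0,1], one-hot target (H, W, 2).
pair_to_sample <- function(pair) {
  h <- nrow(pair$image); w <- ncol(pair$image)
  target <- array(0, c(h, w, 2L))
  target[, , 1] <- 1 - pair$mask
  target[, , 2] <- pair$mask
  list(image = pair$image / 255, target = target)
}

#' Convert a scan record to model input tensors
#'
#' Reads the record, resizes with aspect preserved plus zero padding to
#' `target_size`, scales intensities to \[0, 1\] and one-hot encodes the mask
#' (channel 1 background, channel 2 cavity).
#'
#' @param record One manifest row.
#' @param target_size Square output side; must suit the model depth.
#' @return List with `image` (H x W in \[0,1\]), `target` (H x W x 2
#'   one-hot), and `resize` (scale/pad bookkeeping for inverse mapping).
#' @export
to_model_input <- function(record, target_size) {
  rs <- resize_pair(read_scan_pair(record), target_size)
  out <- pair_to_sample(rs$pair)
  out$resize <- rs[c("scale", "pad_h", "pad_w")]
  out
}

#' Load a manifest into memory as augmentation-ready pairs
#'
#' @param manifest Manifest data frame.
#' @param target_size Optional square side to resize every pair to.
#' @return List of records, each with `pair` (an [img_mask_pair()], \[0,255\]
#'   intensities), `patient_id`, `eye`, `scan_index`.
#' @export
load_dataset <- function(manifest, target_size = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    pair <- read_scan_pair(rec)
    if (!is.null(target_size)) pair <- resize_pair(pair, target_size)$pair
    list(pair = pair, patient_id = rec$patient_id, eye = rec$eye,
         scan_index = rec$scan_index)
  })
}

#' Patient-level nested cross-validation split
#'
#' Patients are shuffled under `seed` into `k` folds. For each fold the held
#' out fold is the test set (20% of patients for k = 5); a
#' `valid_fraction` share of the remaining training portion (rounded to the
#' nearest patient) becomes the augmentation-search validation set, and the
#' rest is the training set. With 30 patients and the defaults this yields
#' 21 / 3 / 6 patients (70% / 10% / 20%). All assignments are at patient
#' granularity, so both eyes and all scans of a patient stay on one side of
#' every split.
#'
#' @param manifest Manifest data frame (or any data frame with a
#'   `patient_id` column).
#' @param k Number of folds.
#' @param valid_fraction Fraction of each fold's training portion used for
#'   validation.
#' @param seed Shuffle seed.
#' @return A `split_plan`: list of `k` folds, each with `test`, `valid`,
#'   `train` patient id vectors.
#' @export
make_splits <- function(manifest, k = 5L, valid_fraction = 0.125, seed = 1L) {
  patients <- sort(unique(manifest$patient_id))
  if (length(patients) < k) stop("fewer patients than folds", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[fold_of == f]
    rest <- shuffled[fold_of != f]
    n_valid <- max(1L, round(valid_fraction * length(rest)))
    valid <- sample(rest, n_valid)
    list(test = sort(test), valid = sort(valid),
         train = sort(setdiff(rest, valid)))
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(k = k, valid_fraction = valid_fraction, seed = seed,
                 folds = folds), class = "split_plan")
}

#' Write / read a split plan as JSON
#'
#' @param plan A `split_plan` from [make_splits()].
#' @param path JSON file path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p$folds <- lapply(seq_len(p$k), function(i) {
    f <- if (is.data.frame(p$folds)) as.list(p$folds[i, ]) else p$folds[[i]]
    lapply(f[c("test", "valid", "train")], function(v) sort(unlist(v)))
  })
  structure(p, class = "split_plan")
}
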