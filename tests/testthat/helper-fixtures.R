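# Shared fixtures: tiny phantom datasets and brute-force oracles.

# Small phantom cohort on disk (cached per-session by parameter key).
tiny_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(n_patients = 2, eyes = 1, scans = 4, size = 32, seed = 7, ...) {
    key <- paste(n_patients, eyes, scans, size, seed,
                 paste(unlist(list(...)), collapse = "_"), sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- phantom_config(n_patients = n_patients, eyes_per_patient = eyes,
                            scans_per_eye = scans, size = size, seed = seed,
                            ...)
      dir <- file.path(tempdir(), paste0("phantom_", key))
      cache[[key]] <- generate_phantom(cfg, dir)
    }
    cache[[key]]
  }
})

# In-memory records for model training.
tiny_records <- function(...) load_dataset(tiny_phantom(...))

# Training samples ([0,1] image + one-hot target) from records.
as_samples <- function(records) {
  lapply(records, function(r) autoaugseg:::pair_to_sample(r$pair))
}

# Train/validation record sets with a purely photometric domain shift:
# identical generative settings except the validation eyes are darker and
# lower-contrast (different patients in both sets).
shift_datasets <- function(seed, size = 64, n_train_pat = 4, n_valid_pat = 3,
                           scans = 4) {
  tr <- generate_phantom(
    phantom_config(n_patients = n_train_pat, eyes_per_patient = 1,
                   scans_per_eye = scans, size = size,
                   brightness_jitter = c(1, 1), contrast_jitter = c(1, 1),
                   geometry_jitter = 0.2, seed = seed),
    file.path(tempdir(), sprintf("shift_tr_%d_%d", seed, size)))
  va <- generate_phantom(
    phantom_config(n_patients = n_valid_pat, eyes_per_patient = 1,
                   scans_per_eye = scans, size = size,
                   brightness_jitter = c(0.35, 0.45),
                   contrast_jitter = c(0.45, 0.55),
                   geometry_jitter = 0.2, seed = seed + 500),
    file.path(tempdir(), sprintf("shift_va_%d_%d", seed, size)))
  valid <- lapply(load_dataset(va), function(r) {
    r$patient_id <- paste0("V", r$patient_id)
    r
  })
  list(train = load_dataset(tr), valid = valid)
}

# Brute-force pixel-count metrics oracle: explicit double loop.
oracle_metrics <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
      else if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}

# Dice coefficient of two binary masks (independent of compute_metrics).
mask_dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a * b) / s
}

train_until_dice <- function(model, samples, lr = 3e-3, max_steps = 200,
                             target = 0.95) {
  opt <- autoaugseg:::adam_new(lr = lr)
  dice <- 0
  for (step in seq_len(max_steps)) {
    autoaugseg:::train_batch_step(model, samples, opt)
    if (step %% 10 == 0 || step == max_steps) {
      dice <- mean(vapply(samples, function(s) {
        mask_dice(predict_mask(model, s$image)$mask, s$target[, , 2])
      }, numeric(1)))
      if (dice >= target) break
    }
  }
  dice
}
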