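test_that("phantom generation produces a coherent, well-formed cohort", {
  man <- tiny_phantom(n_patients = 2, eyes = 2, scans = 6, size = 48,
                      seed = 13)
  expect_equal(nrow(man), 2 * 2 * 6)
  expect_false(any(duplicated(man[c("patient_id", "eye", "scan_index")])))
  expect_true(all(file.exists(man$image_path)))
  recs <- load_dataset(man)
  # masks strictly binary, images 8-bit range
  for (r in recs) {
    expect_true(all(r$pair$mask %in% c(0, 1)))
    expect_true(all(r$pair$image >= 0 & r$pair$image <= 255))
  }
  # cavities are hypo-reflective: cavity mean below the surrounding band's
  # mean (6 px dilated bounding box, cavity excluded) in every image
  for (r in recs) {
    m <- r$pair$mask
    if (sum(m) < 10) next
    idx <- which(m == 1, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 6); r1 <- min(nrow(m), max(idx[, 1]) + 6)
    c0 <- max(1, min(idx[, 2]) - 6); c1 <- min(ncol(m), max(idx[, 2]) + 6)
    box <- r$pair$image[r0:r1, c0:c1]
    boxm <- m[r0:r1, c0:c1]
    expect_lt(mean(box[boxm == 1]), mean(box[boxm == 0]))
  }
  # cross-scan coherence: adjacent scans of one eye overlap in their masks
  eye <- recs[vapply(recs, function(r) r$eye == "OD" &&
                       r$patient_id == "P01", logical(1))]
  eye <- eye[order(vapply(eye, `[[`, numeric(1), "scan_index"))]
  dices <- c()
  for (i in seq_len(length(eye) - 1)) {
    a <- eye[[i]]$pair$mask; b <- eye[[i + 1]]$pair$mask
    if (sum(a) + sum(b) > 0) dices <- c(dices, mask_dice(a, b))
  }
  expect_gte(mean(dices), 0.5)
})

test_that("manifest round-trips through CSV", {
  man <- tiny_phantom(n_patients = 2, eyes = 1, scans = 3, size = 32,
                      seed = 17)
  path <- file.path(tempdir(), "roundtrip_manifest.csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$patient_id, man$patient_id)
  expect_equal(back$eye, man$eye)
  expect_equal(back$scan_index, man$scan_index)
  expect_equal(normalizePath(back$image_path),
               normalizePath(man$image_path))
})

test_that("patient-level nested splits give the 70/10/20 arithmetic", {
  man <- data.frame(patient_id = rep(sprintf("P%02d", 1:30), each = 2))
  plan <- make_splits(man, k = 5, valid_fraction = 0.125, seed = 3)
  for (f in plan$folds) {
    expect_length(f$test, 6L)
    expect_length(f$valid, 3L)
    expect_length(f$train, 21L)
    expect_length(intersect(f$test, f$valid), 0L)
    expect_length(intersect(f$test, f$train), 0L)
    expect_length(intersect(f$valid, f$train), 0L)
    expect_setequal(c(f$test, f$valid, f$train), unique(man$patient_id))
  }
  # every patient is in exactly one test fold
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(all_test, unique(man$patient_id))
  expect_equal(anyDuplicated(all_test), 0L)
  # determinism
  plan2 <- make_splits(man, k = 5, valid_fraction = 0.125, seed = 3)
  expect_equal(plan, plan2)
  expect_error(make_splits(data.frame(patient_id = c("a", "b")), k = 5),
               "fewer patients")
})

test_that("split exclusivity holds across many seeds", {
  man <- data.frame(patient_id = sprintf("P%02d", 1:23))
  for (seed in 1:200) {
    plan <- make_splits(man, k = 5, seed = seed)
    for (f in plan$folds) {
      expect_length(intersect(f$test, c(f$valid, f$train)), 0L)
      expect_length(intersect(f$valid, f$train), 0L)
      expect_setequal(c(f$test, f$valid, f$train), man$patient_id)
    }
  }
})

test_that("split plans round-trip through JSON", {
  man <- data.frame(patient_id = sprintf("P%02d", 1:12))
  plan <- make_splits(man, k = 3, seed = 5)
  path <- file.path(tempdir(), "plan.json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  for (i in 1:3) {
    expect_equal(back$folds[[i]]$test, plan$folds[[i]]$test)
    expect_equal(back$folds[[i]]$valid, plan$folds[[i]]$valid)
    expect_equal(back$folds[[i]]$train, plan$folds[[i]]$train)
  }
})

test_that("scan records convert to normalized model tensors", {
  man <- tiny_phantom(n_patients = 1, eyes = 1, scans = 2, size = 32,
                      seed = 19)
  rec <- man[1, ]
  out <- to_model_input(rec, 512)
  expect_identical(dim(out$image), c(512L, 512L))
  expect_identical(dim(out$target), c(512L, 512L, 2L))
  expect_true(all(out$image >= 0 & out$image <= 1))
  expect_equal(max(abs(out$target[, , 1] + out$target[, , 2] - 1)), 0)
  # at native size the one-hot argmax reproduces the stored mask exactly
  nat <- to_model_input(rec, 32)
  stored <- read_scan_pair(rec)$mask
  expect_identical((nat$target[, , 2] > nat$target[, , 1]) * 1, stored)
})

test_that("stronger speckle degrades a trained model's test performance", {
  run_dice <- function(speckle, seed) {
    man <- tiny_phantom(n_patients = 2, eyes = 1, scans = 6, size = 32,
                        seed = 100 + seed, speckle = speckle)
    recs <- load_dataset(man)
    train <- as_samples(recs[1:6])
    test <- as_samples(recs[7:12])
    set.seed(seed)
    m <- build_seg_model(model_config("unet", depth = 2, base_channels = 8),
                         seed = seed)
    opt <- autoaugseg:::adam_new(lr = 3e-3)
    for (i in 1:40) autoaugseg:::train_batch_step(m, train, opt)
    mean(vapply(test, function(s) {
      mask_dice(predict_mask(m, s$image)$mask, s$target[, , 2])
    }, numeric(1)))
  }
  wins <- 0L
  for (seed in 1:5) {
    if (run_dice(0.05, seed) > run_dice(0.6, seed)) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
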