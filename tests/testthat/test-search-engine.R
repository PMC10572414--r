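small_search_cfg <- function(time_horizon = 2L, epochs = 1L) {
  search_config(time_horizon = time_horizon, child_epochs = epochs,
                batch_size = 4L,
                model = model_config("unet", depth = 2L, base_channels = 4L,
                                     norm = "none"),
                learning_rate = 3e-3)
}

test_that("identity-strategy training equals augmentation-free training", {
  recs <- tiny_records(n_patients = 1, eyes = 1, scans = 4, size = 32,
                       seed = 23)
  cfg <- small_search_cfg(epochs = 3L)
  set.seed(7)
  m1 <- build_seg_model(cfg$model, seed = 7)
  train_child(m1, recs, identity_strategy(), cfg)
  # reference loop: same batching and RNG draws, no augmentation calls
  set.seed(7)
  m2 <- build_seg_model(cfg$model, seed = 7)
  opt <- autoaugseg:::adam_new(lr = cfg$learning_rate)
  n <- length(recs)
  for (ep in 1:3) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      sample.int(5L, 1L)  # the sub-strategy selection draw
      batch <- lapply(recs[idx], function(r) {
        autoaugseg:::pair_to_sample(r$pair)
      })
      autoaugseg:::train_batch_step(m2, batch, opt, alpha = cfg$alpha)
    }
  }
  expect_equal(m1$ps$W, m2$ps$W, tolerance = 1e-12)
})

test_that("training reaches high Dice on a small phantom set", {
  recs <- tiny_records(n_patients = 2, eyes = 1, scans = 4, size = 48,
                       seed = 24)
  cfg <- search_config(time_horizon = 1L, child_epochs = 40L, batch_size = 4L,
                       model = model_config("unet", depth = 2L,
                                            base_channels = 8L),
                       learning_rate = 3e-3)
  set.seed(9)
  m <- build_seg_model(cfg$model, seed = 9)
  out <- train_child(m, recs, identity_strategy(), cfg)
  expect_lt(utils::tail(out$history$loss, 1), out$history$loss[1])
  dice <- mean(vapply(as_samples(recs), function(s) {
    mask_dice(predict_mask(m, s$image)$mask, s$target[, , 2])
  }, numeric(1)))
  expect_gte(dice, 0.9)
})

test_that("sub-strategy draws during training are uniform", {
  recs <- tiny_records(n_patients = 1, eyes = 1, scans = 4, size = 16,
                       seed = 25)
  cfg <- search_config(time_horizon = 1L, child_epochs = 600L,
                       batch_size = 4L,
                       model = model_config("unet", depth = 2L,
                                            base_channels = 2L, norm = "none"),
                       learning_rate = 1e-4)
  set.seed(10)
  m <- build_seg_model(cfg$model, seed = 10)
  out <- train_child(m, recs, identity_strategy(), cfg)
  draws <- out$substrategy_draws
  expect_gte(length(draws), 500L)
  freq <- tabulate(draws, 5) / length(draws)
  se <- sqrt(0.2 * 0.8 / length(draws))
  expect_true(all(abs(freq - 0.2) <= 3 * se))
})

test_that("a single-iteration search keeps exact reward books", {
  d <- shift_datasets(301, size = 16, n_train_pat = 1, n_valid_pat = 1)
  cfg <- small_search_cfg(time_horizon = 1L)
  res <- run_search(d$train, d$valid, cfg, desk_controller_config(),
                    seed = 5)
  expect_equal(nrow(res$trace), 1L)
  expect_true(is.finite(res$trace$valid_loss))
  expect_equal(res$trace$reward, -res$trace$valid_loss, tolerance = 1e-9)
  # the logged strategy parses back to 5 sub-strategies
  expect_length(parse_strategy(res$trace$strategy[1]), 5L)
})

test_that("identical seeds give identical traces", {
  d <- shift_datasets(302, size = 16, n_train_pat = 1, n_valid_pat = 1)
  cfg <- small_search_cfg(time_horizon = 2L)
  r1 <- run_search(d$train, d$valid, cfg, desk_controller_config(), seed = 8)
  r2 <- run_search(d$train, d$valid, cfg, desk_controller_config(), seed = 8)
  expect_equal(r1$trace$reward, r2$trace$reward)
  expect_equal(r1$trace$strategy, r2$trace$strategy)
})

test_that("the search refuses patient overlap between train and validation", {
  recs <- tiny_records(n_patients = 2, eyes = 1, scans = 2, size = 16,
                       seed = 26)
  expect_error(run_search(recs, recs[1], small_search_cfg()),
               "patient overlap")
})

test_that("consolidation selects top rewards with earlier-iteration ties", {
  mk_strat <- function(tag) {
    aug_strategy(replicate(5, sub_strategy(
      op_instance("Brightness", tag, 5), op_instance("Invert", NA, tag)),
      simplify = FALSE))
  }
  rewards <- c(0.2, 0.9, 0.5, 0.9, 0.1, 0.7, 0.3)
  trace <- list(
    trace = data.frame(iteration = 1:7, reward = rewards),
    strategies = lapply(1:7, function(i) mk_strat((i - 1) %% 10))
  )
  out <- consolidate_top_strategies(trace, k = 5)
  expect_length(out, 25L)
  # brute-force oracle: stable sort by descending reward, then slice
  ord <- order(-rewards, 1:7)[1:5]
  expect_equal(ord, c(2, 4, 6, 3, 7))
  got_tags <- vapply(seq(1, 25, by = 5), function(i) {
    out$substrategies[[i]]$first$magnitude_level
  }, integer(1))
  expect_equal(got_tags, (ord - 1L) %% 10L)
  expect_error(consolidate_top_strategies(trace, k = 8), "fewer than k")
})

test_that("final cross-validated training emits per-fold metric records", {
  man <- tiny_phantom(n_patients = 4, eyes = 1, scans = 3, size = 16,
                      seed = 27)
  recs <- load_dataset(man)
  plan <- make_splits(man, k = 2, valid_fraction = 0.25, seed = 1)
  cfg <- small_search_cfg(epochs = 2L)
  out <- final_train_and_eval(recs, plan, identity_strategy(), cfg, seed = 3)
  expect_length(out, 2L)
  for (r in out) {
    for (m in c("accuracy", "dice", "precision", "recall", "specificity",
                "jaccard")) {
      expect_true(r[[m]] >= 0 && r[[m]] <= 1, info = m)
    }
    expect_equal(r$jaccard, r$dice / (2 - r$dice))
  }
})

test_that("run configuration YAML resolves and round-trips", {
  path <- file.path(tempdir(), "run.yaml")
  writeLines(c(
    "model:", "  architecture: unetpp", "  depth: 2", "  base_channels: 4",
    "search:", "  time_horizon: 3", "  child_epochs: 2",
    "controller:", "  learning_rate: 0.01",
    "data:", "  n_patients: 4", "  size: 32",
    "seed: 11"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$model$architecture, "unetpp")
  expect_equal(cfg$search$time_horizon, 3L)
  expect_equal(cfg$search$child_epochs, 2L)
  expect_equal(cfg$controller$learning_rate, 0.01)
  expect_equal(cfg$phantom$n_patients, 4)
  expect_equal(cfg$seed, 11)
  out <- file.path(tempdir(), "resolved.yaml")
  write_run_config(cfg, out)
  expect_true(file.exists(out))
  back <- yaml::read_yaml(out)
  expect_equal(back$model$architecture, "unetpp")
  expect_equal(back$seed, 11)
  writeLines(c("search:", "  bogus_knob: 1"), path)
  expect_error(read_run_config(path), "unknown config keys")
})
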