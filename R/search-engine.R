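# The augmentation-policy search: an outer RL loop samples a strategy,
# trains a freshly initialized child segmentation model with it, scores the
# child's hybrid loss on held-out validation patients, and feeds the
# negative loss back to the controller as reward. After the search, the
# sub-strategies of the top five strategies are consolidated into one
# 25-sub-strategy policy used for final training.

#' Search configuration
#'
#' Full-scale defaults mirror the study protocol (time horizon 1000, child
#' epochs 200, Adam learning rate 1e-4 with plateau reduction factor 0.5 and
#' patience 10); [desk_search_config()] provides a CPU-sized preset.
#'
#' @param time_horizon Number of RL iterations T.
#' @param child_epochs Training epochs E per child model.
#' @param batch_size Mini-batch size for child training.
#' @param model A [model_config()] for the child.
#' @param learning_rate Child Adam learning rate.
#' @param plateau_factor,plateau_patience ReduceLROnPlateau settings on the
#'   child's epoch training loss.
#' @param alpha Dice smoothing constant of the hybrid loss.
#' @param ppo_batch Number of most recent (strategy, reward) samples kept in
#'   the PPO update buffer.
#' @return A `search_config` list.
#' @export
search_config <- function(time_horizon = 1000L, child_epochs = 200L,
                          batch_size = 8L, model = model_config("unet"),
                          learning_rate = 1e-4, plateau_factor = 0.5,
                          plateau_patience = 10L, alpha = 1,
                          ppo_batch = 10L) {
  stopifnot(time_horizon >= 1L, child_epochs >= 1L, batch_size >= 1L,
            inherits(model, "model_config"))
  structure(list(time_horizon = as.integer(time_horizon),
                 child_epochs = as.integer(child_epochs),
                 batch_size = as.integer(batch_size), model = model,
                 learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 alpha = alpha, ppo_batch = as.integer(ppo_batch)),
            class = "search_config")
}

#' Desk-scale search preset
#'
#' A CPU-sized search: 30 iterations, a depth-2, 8-channel child trained for
#' 10 epochs with batch size 4 and Adam 3e-3 on 64 px phantoms. The child
#' uses no normalization layers so that, like the full-scale batch-norm
#' models evaluated with training-set statistics, it stays sensitive to
#' global intensity shifts between domains. Paired with a controller
#' learning rate of 0.05 (the study's 4e-4 is tied to its 1000-iteration
#' horizon; a 30-iteration search needs a step large enough to exploit
#' within the horizon).
#'
#' @param architecture Child architecture.
#' @return A `search_config`.
#' @export
desk_search_config <- function(architecture = "unet") {
  search_config(time_horizon = 30L, child_epochs = 10L, batch_size = 4L,
                model = model_config(architecture, depth = 2L,
                                     base_channels = 8L, norm = "none"),
                learning_rate = 3e-3)
}

#' Controller preset for desk-scale searches
#'
#' @return A [controller_config()] with learning rate 0.05.
#' @export
desk_controller_config <- function() {
  controller_config(learning_rate = 0.05)
}

## ---- child training -----------------------------------------------------

#' Train a child segmentation model under an augmentation strategy
#'
#' For every epoch and mini-batch, one sub-strategy is drawn uniformly from
#' the strategy and applied to the whole mini-batch (independent probability
#' draws per image) before the gradient step on the hybrid loss. The child's
#' Adam learning rate is reduced on plateau of the epoch training loss.
#' Deterministic for a fixed RNG state (`set.seed()` before calling).
#'
#' @param model A [build_seg_model()] child (updated in place).
#' @param train_set List of records with a `pair` element
#'   (see [load_dataset()]).
#' @param strategy An [aug_strategy()].
#' @param config A [search_config()].
#' @return List with the trained `model`, a `history` data frame (epoch,
#'   mean loss, learning rate) and `substrategy_draws` (the uniform
#'   sub-strategy indices drawn per batch).
#' @export
train_child <- function(model, train_set, strategy, config) {
  stopifnot(inherits(model, "seg_model"), inherits(strategy, "aug_strategy"),
            inherits(config, "search_config"))
  if (!length(train_set)) stop("empty training set", call. = FALSE)
  opt <- adam_new(lr = config$learning_rate)
  n <- length(train_set)
  bs <- min(config$batch_size, n)
  draws <- integer(0)
  hist <- vector("list", config$child_epochs)
  best <- Inf; stale <- 0L
  for (ep in seq_len(config$child_epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      k <- sample.int(length(strategy), 1L)
      draws <- c(draws, k)
      sub <- strategy$substrategies[[k]]
      batch <- lapply(train_set[idx], function(r) {
        pair_to_sample(apply_substrategy(r$pair, sub))
      })
      l <- train_batch_step(model, batch, opt, alpha = config$alpha)
      if (!is.finite(l)) {
        stop(sprintf("non-finite training loss at epoch %d", ep),
             call. = FALSE)
      }
      losses <- c(losses, l)
    }
    epl <- mean(losses)
    hist[[ep]] <- data.frame(epoch = ep, loss = epl, lr = opt$lr)
    if (epl < best - 1e-8) {
      best <- epl; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$plateau_patience) {
        opt$lr <- opt$lr * config$plateau_factor
        stale <- 0L
      }
    }
  }
  list(model = model, history = do.call(rbind, hist),
       substrategy_draws = draws)
}

## ---- the outer search loop ----------------------------------------------

#' Run the augmentation-policy search
#'
#' For each of `T` iterations: sample a strategy from the controller, train
#' a freshly initialized child model with it, evaluate the child's hybrid
#' loss on the validation patients, use the negative loss as reward, and
#' update the controller by PPO over a buffer of the most recent samples.
#' Training and validation records must be disjoint at the patient level.
#'
#' @param train_set,valid_set Record lists from [load_dataset()]; each
#'   record carries its `patient_id`.
#' @param config A [search_config()].
#' @param controller_cfg A [controller_config()].
#' @param seed Master seed: controls controller initialization, sampling,
#'   child initialization (per-iteration derived seeds) and training order.
#' @param trace_path Optional CSV path; the trace is appended to it
#'   incrementally, one row per iteration.
#' @return A `reward_trace`: list with `trace` (data frame: iteration,
#'   reward, valid_loss, strategy JSON), `strategies`, the final
#'   `controller`, and the patient ids the search touched.
#' @export
run_search <- function(train_set, valid_set, config = desk_search_config(),
                       controller_cfg = desk_controller_config(),
                       seed = 1L, trace_path = NULL) {
  stopifnot(inherits(config, "search_config"))
  tr_pat <- unique(vapply(train_set, `[[`, character(1), "patient_id"))
  va_pat <- unique(vapply(valid_set, `[[`, character(1), "patient_id"))
  overlap <- intersect(tr_pat, va_pat)
  if (length(overlap)) {
    stop("train/validation patient overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  controller <- build_controller(controller_cfg, seed = seed)
  valid_samples <- lapply(valid_set, function(r) pair_to_sample(r$pair))
  set.seed(seed)
  buf_samples <- list(); buf_rewards <- numeric(0)
  strategies <- vector("list", config$time_horizon)
  rows <- vector("list", config$time_horizon)
  child_seed <- seed + 131071L
  for (t in seq_len(config$time_horizon)) {
    s <- sample_strategy(controller)
    strategies[[t]] <- s$strategy
    # common random numbers: every iteration re-initializes and trains the
    # child under the same derived stream, so reward differences across
    # iterations reflect the strategy, not initialization luck
    ctrl_rng <- get(".Random.seed", globalenv())
    set.seed(child_seed)
    child <- build_seg_model(config$model, seed = child_seed)
    train_child(child, train_set, s$strategy, config)
    vloss <- evaluate_loss(child, valid_samples, alpha = config$alpha)
    assign(".Random.seed", ctrl_rng, globalenv())
    reward <- reward_from_validation(vloss)
    buf_samples <- c(buf_samples, list(s))
    buf_rewards <- c(buf_rewards, reward)
    keep <- max(1L, length(buf_samples) - config$ppo_batch + 1L)
    buf_samples <- buf_samples[keep:length(buf_samples)]
    buf_rewards <- buf_rewards[keep:length(buf_rewards)]
    update_policy(controller, buf_samples, buf_rewards, mode = "ppo")
    rows[[t]] <- data.frame(
      iteration = t, reward = reward, valid_loss = vloss,
      strategy = as.character(serialize_strategy(s$strategy)),
      stringsAsFactors = FALSE)
    if (!is.null(trace_path)) {
      utils::write.table(rows[[t]], trace_path, sep = ",",
                         row.names = FALSE, col.names = t == 1L,
                         append = t > 1L, qmethod = "double")
    }
  }
  structure(list(trace = do.call(rbind, rows), strategies = strategies,
                 controller = controller,
                 patients_touched = sort(c(tr_pat, va_pat))),
            class = "reward_trace")
}

#' Consolidate the top-k searched strategies into one policy
#'
#' Selects the `k` trace records with the highest reward (ties broken in
#' favour of the earlier iteration) and concatenates their sub-strategies in
#' descending reward order. With the standard 5-sub-strategy samples and
#' `k = 5` the result has 25 sub-strategies.
#'
#' @param trace A `reward_trace` from [run_search()], or a list with
#'   elements `trace` (data frame with `iteration` and `reward`) and
#'   `strategies`.
#' @param k Number of top strategies to merge.
#' @return An [aug_strategy()].
#' @export
consolidate_top_strategies <- function(trace, k = 5L) {
  df <- trace$trace
  if (nrow(df) < k) stop("trace has fewer than k records", call. = FALSE)
  ord <- order(-df$reward, df$iteration)[seq_len(k)]
  subs <- unlist(lapply(ord, function(i) {
    trace$strategies[[df$iteration[i]]]$substrategies
  }), recursive = FALSE)
  aug_strategy(subs)
}

## ---- final cross-validated training --------------------------------------

metrics_from_counts <- function(tp, fp, fn, tn) {
  pred <- matrix(0, 1, 1)  # dummy; rebuild a record from pooled counts
  rec <- compute_metrics(pred, pred)
  safe <- function(num, den, err) if (den == 0) (if (err == 0) 1 else 0) else num / den
  rec$accuracy <- (tp + tn) / (tp + tn + fp + fn)
  rec$accuracy_class_avg <- 0.5 * (safe(tp, tp + fn, fn) + safe(tn, tn + fp, fp))
  rec$dice <- safe(2 * tp, 2 * tp + fp + fn, fp + fn)
  rec$precision <- safe(tp, tp + fp, fp)
  rec$recall <- safe(tp, tp + fn, fn)
  rec$specificity <- safe(tn, tn + fp, fp)
  rec$jaccard <- safe(tp, tp + fp + fn, fp + fn)
  rec$TP <- tp; rec$FP <- fp; rec$FN <- fn; rec$TN <- tn
  rec$degenerate <- (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0)
  rec
}

#' Train final models across folds and evaluate the six metrics
#'
#' For each fold of the split plan: trains a fresh child on the fold's
#' training patients under `strategy`, then evaluates on the held-out test
#' patients. Per-fold metrics pool the pixel counts over all test images.
#'
#' @param dataset Record list from [load_dataset()].
#' @param plan A [make_splits()] plan.
#' @param strategy The (consolidated) [aug_strategy()] used for training.
#' @param config A [search_config()] (its model/epoch/batch settings are the
#'   training budget).
#' @param seed Seed; fold `f` trains from `seed + f`.
#' @param folds Which folds to run (default all).
#' @return List of per-fold `metrics_record` objects.
#' @export
final_train_and_eval <- function(dataset, plan, strategy, config, seed = 1L,
                                 folds = seq_len(plan$k)) {
  stopifnot(inherits(plan, "split_plan"))
  pid <- vapply(dataset, `[[`, character(1), "patient_id")
  lapply(folds, function(f) {
    fold <- plan$folds[[f]]
    train_recs <- dataset[pid %in% fold$train]
    test_recs <- dataset[pid %in% fold$test]
    set.seed(seed + f)
    child <- build_seg_model(config$model, seed = seed + f)
    train_child(child, train_recs, strategy, config)
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (r in test_recs) {
      s <- pair_to_sample(r$pair)
      pr <- predict_mask(child, s$image)
      m <- compute_metrics(pr$mask, r$pair$mask)
      counts <- counts + c(m$TP, m$FP, m$FN, m$TN)
    }
    metrics_from_counts(counts[1], counts[2], counts[3], counts[4])
  })
}

## ---- run configuration (YAML) ---------------------------------------------

#' Read a run configuration YAML file
#'
#' The file may carry `data`, `model`, `search` and `controller` sections;
#' missing entries fall back to the package defaults. Returns resolved
#' configuration objects.
#'
#' @param path YAML file path.
#' @return List with `phantom`, `model`, `search`, `controller`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(defaults, over) {
    if (is.null(over)) return(defaults)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    utils::modifyList(defaults, over)
  }
  model_args <- take(list(architecture = "unet", depth = 4L,
                          base_channels = 32L, norm = "instance"),
                     y$model)
  model <- do.call(model_config, model_args)
  search_args <- take(list(time_horizon = 1000L, child_epochs = 200L,
                           batch_size = 8L, learning_rate = 1e-4,
                           plateau_factor = 0.5, plateau_patience = 10L,
                           alpha = 1, ppo_batch = 10L),
                      y$search)
  search <- do.call(search_config, c(search_args, list(model = model)))
  ctrl_args <- take(list(hidden_units = 100L, learning_rate = 4e-4,
                         entropy_weight = 1e-5, init_range = 0.1,
                         ppo_clip = 0.2, ppo_epochs = 3L,
                         baseline_decay = 0.95),
                    y$controller)
  ctrl <- do.call(controller_config, ctrl_args)
  phantom <- do.call(phantom_config, y$data %||% list())
  list(phantom = phantom, model = model, search = search, controller = ctrl,
       seed = y$seed %||% 1L)
}

#' Write the resolved configuration of a run
#'
#' @param config List as returned by [read_run_config()].
#' @param path Output YAML path.
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    data = unclass(config$phantom),
    model = unclass(config$model),
    search = unclass(config$search)[setdiff(names(config$search), "model")],
    controller = unclass(config$controller),
    seed = config$seed
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}
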