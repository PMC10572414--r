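# Recurrent augmentation-policy controller: a single-layer LSTM that
# autoregressively emits 30 categorical decisions (operation type, magnitude
# level, probability level for each of the 10 operation slots), trained from
# scalar rewards with a PPO clipped-surrogate objective (REINFORCE available
# as a reference mode for gradient checks).

#' Controller configuration
#'
#' Defaults follow the study conditions: 100 LSTM hidden units, learning
#' rate 4e-4, entropy bonus weight 1e-5, parameters uniformly initialized in
#' (-0.1, 0.1). PPO settings (clip 0.2, 3 epochs per update, exponential
#' moving-average reward baseline with decay 0.95) are package defaults, not
#' study-reported values.
#'
#' @param hidden_units LSTM hidden state size.
#' @param num_substrategies,ops_per_substrategy Strategy shape; the number of
#'   decisions per sampled strategy is
#'   `num_substrategies * ops_per_substrategy * 3`.
#' @param learning_rate Adam learning rate for controller updates.
#' @param entropy_weight Weight of the entropy bonus.
#' @param init_range Parameters start uniform in `(-init_range, init_range)`.
#' @param ppo_clip PPO ratio clip; `Inf` disables clipping.
#' @param ppo_epochs Optimization epochs per update batch.
#' @param baseline_decay EMA decay of the reward baseline.
#' @param normalize_advantage Standardize advantages within each update
#'   batch (standard PPO practice; makes the update scale-free in the
#'   reward units).
#' @param embed_dim Token embedding size.
#' @param decision_vocabs Optional integer vector of per-step vocabulary
#'   sizes, overriding the standard `(16, 10, 11)` cycle (used for small
#'   bandit-style test problems).
#' @return A `controller_config` list.
#' @export
controller_config <- function(hidden_units = 100L, num_substrategies = 5L,
                              ops_per_substrategy = 2L,
                              learning_rate = 4e-4, entropy_weight = 1e-5,
                              init_range = 0.1, ppo_clip = 0.2,
                              ppo_epochs = 3L, baseline_decay = 0.95,
                              normalize_advantage = TRUE,
                              embed_dim = 16L, decision_vocabs = NULL) {
  n_ops <- nrow(op_table())
  if (is.null(decision_vocabs)) {
    decision_vocabs <- rep(c(n_ops, N_MAG_LEVELS, N_PROB_LEVELS),
                           num_substrategies * ops_per_substrategy)
  }
  structure(list(
    hidden_units = as.integer(hidden_units),
    num_substrategies = as.integer(num_substrategies),
    ops_per_substrategy = as.integer(ops_per_substrategy),
    learning_rate = learning_rate, entropy_weight = entropy_weight,
    init_range = init_range, ppo_clip = ppo_clip,
    ppo_epochs = as.integer(ppo_epochs), baseline_decay = baseline_decay,
    normalize_advantage = isTRUE(normalize_advantage),
    embed_dim = as.integer(embed_dim),
    decision_vocabs = as.integer(decision_vocabs)
  ), class = "controller_config")
}

# step -> vocabulary "type" index (one embedding/head per distinct vocab)
ctrl_types <- function(cfg) {
  vocabs <- cfg$decision_vocabs
  uv <- unique(vocabs)
  list(uniq = uv, of_step = match(vocabs, uv))
}

#' Build an augmentation-policy controller
#'
#' @param config A [controller_config()].
#' @param seed Seed for parameter initialization.
#' @return A `policy_controller` object.
#' @export
build_controller <- function(config = controller_config(), seed = 1L) {
  stopifnot(inherits(config, "controller_config"))
  ps <- new.env(parent = emptyenv())
  ps$W <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  H <- config$hidden_units; E <- config$embed_dim
  r <- config$init_range
  U <- function(...) {
    d <- c(...)
    array(stats::runif(prod(d), -r, r), d)
  }
  ty <- ctrl_types(config)
  ps$W$x0 <- U(1, E)
  ps$W$Etype <- U(length(ty$uniq), E)
  for (k in seq_along(ty$uniq)) {
    ps$W[[paste0("Etok", k)]] <- U(ty$uniq[k], E)
    ps$W[[paste0("head2w", k)]] <- U(H, ty$uniq[k])
    ps$W[[paste0("head2b", k)]] <- as.numeric(U(ty$uniq[k]))
  }
  ps$W$Wx <- U(E, 4 * H)
  ps$W$Wh <- U(H, 4 * H)
  ps$W$b <- as.numeric(U(4 * H))
  ps$W$head1w <- U(H, H)
  ps$W$head1b <- as.numeric(U(H))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(config = config, ps = ps,
                 opt = adam_new(lr = config$learning_rate),
                 state = local({
                   e <- new.env(parent = emptyenv())
                   e$baseline <- NA_real_
                   e
                 })),
            class = "policy_controller")
}

#' @export
print.policy_controller <- function(x, ...) {
  cat(sprintf("<policy_controller %d decisions, %d hidden units, baseline=%s>\n",
              length(x$config$decision_vocabs), x$config$hidden_units,
              format(x$state$baseline, digits = 4)))
  invisible(x)
}

# One unrolled pass. decisions = NULL -> sample each step from its softmax
# (consuming the R RNG); otherwise condition on the given decisions.
# on_tape = TRUE builds the differentiable graph and returns node ids.
ctrl_unroll <- function(ctrl, decisions = NULL, on_tape = FALSE) {
  cfg <- ctrl$config
  ps <- ctrl$ps
  ty <- ctrl_types(cfg)
  nstep <- length(cfg$decision_vocabs)
  H <- cfg$hidden_units
  sampling <- is.null(decisions)
  if (sampling) decisions <- integer(nstep)
  tp <- if (on_tape) ad_tape() else NULL
  probs <- vector("list", nstep)
  logp_ids <- integer(0); ent_ids <- integer(0)
  logp <- 0; entropy <- 0
  if (on_tape) {
    h <- ad_const(tp, matrix(0, 1, H)); cc <- ad_const(tp, matrix(0, 1, H))
    x <- ad_param(tp, ps, "x0")
    Wx <- ad_param(tp, ps, "Wx"); Wh <- ad_param(tp, ps, "Wh")
    b <- ad_param(tp, ps, "b")
    h1w <- ad_param(tp, ps, "head1w"); h1b <- ad_param(tp, ps, "head1b")
  } else {
    h <- matrix(0, 1, H); cc <- matrix(0, 1, H)
    x <- ps$W$x0
  }
  for (t in seq_len(nstep)) {
    k <- ty$of_step[t]
    V <- ty$uniq[k]
    if (on_tape) {
      z <- ad_bias_row(tp, ad_add(tp, ad_matmul(tp, x, Wx),
                                  ad_matmul(tp, h, Wh)), b)
      ig <- ad_sigmoid(tp, ad_slice_cols(tp, z, 1:H))
      fg <- ad_sigmoid(tp, ad_slice_cols(tp, z, H + 1:H))
      gg <- ad_tanh(tp, ad_slice_cols(tp, z, 2 * H + 1:H))
      og <- ad_sigmoid(tp, ad_slice_cols(tp, z, 3 * H + 1:H))
      cc <- ad_add(tp, ad_mul(tp, fg, cc), ad_mul(tp, ig, gg))
      h <- ad_mul(tp, og, ad_tanh(tp, cc))
      trunk <- ad_relu(tp, ad_bias_row(tp, ad_matmul(tp, h, h1w), h1b))
      logits <- ad_bias_row(tp,
        ad_matmul(tp, trunk, ad_param(tp, ps, paste0("head2w", k))),
        ad_param(tp, ps, paste0("head2b", k)))
      d <- decisions[t]
      logp_ids <- c(logp_ids, ad_logsoftmax_pick(tp, logits, d))
      ent_ids <- c(ent_ids, ad_entropy(tp, logits))
      x <- ad_add(tp, ad_row(tp, ad_param(tp, ps, paste0("Etok", k)), d),
                  ad_row(tp, ad_param(tp, ps, "Etype"), k))
    } else {
      z <- as.vector(x %*% ps$W$Wx) + as.vector(h %*% ps$W$Wh) + ps$W$b
      ig <- 1 / (1 + exp(-z[1:H]))
      fg <- 1 / (1 + exp(-z[H + 1:H]))
      gg <- tanh(z[2 * H + 1:H])
      og <- 1 / (1 + exp(-z[3 * H + 1:H]))
      cc <- fg * cc + ig * gg
      h <- og * tanh(cc)
      trunk <- pmax(as.vector(h %*% ps$W$head1w) + ps$W$head1b, 0)
      logits <- as.vector(trunk %*% ps$W[[paste0("head2w", k)]]) +
        ps$W[[paste0("head2b", k)]]
      zl <- logits - max(logits)
      q <- exp(zl) / sum(exp(zl))
      probs[[t]] <- q
      if (sampling) decisions[t] <- sample.int(V, 1L, prob = q)
      d <- decisions[t]
      logp <- logp + log(q[d])
      entropy <- entropy - sum(q * log(pmax(q, 1e-12)))
      x <- ps$W[[paste0("Etok", k)]][d, ] + ps$W$Etype[k, ]
    }
  }
  if (on_tape) {
    logp_id <- Reduce(function(a, b) ad_add(tp, a, b), logp_ids)
    ent_id <- Reduce(function(a, b) ad_add(tp, a, b), ent_ids)
    list(tp = tp, logp_id = logp_id, ent_id = ent_id)
  } else {
    list(decisions = decisions, log_prob = logp, entropy = entropy,
         probs = probs)
  }
}

# Decode a 30-decision vector into a 5-sub-strategy augmentation strategy.
decode_decisions <- function(cfg, decisions) {
  ops <- op_table()$name
  n_per <- 3L * cfg$ops_per_substrategy
  subs <- lapply(seq_len(cfg$num_substrategies), function(i) {
    base <- (i - 1L) * n_per
    insts <- lapply(seq_len(cfg$ops_per_substrategy), function(j) {
      o <- base + (j - 1L) * 3L
      op_instance(ops[decisions[o + 1L]], decisions[o + 2L] - 1L,
                  decisions[o + 3L] - 1L)
    })
    sub_strategy(insts[[1L]], insts[[2L]])
  })
  aug_strategy(subs)
}

#' Sample an augmentation strategy from the controller
#'
#' Autoregressively samples the controller's categorical decisions (30 for
#' the standard configuration) and decodes them into a strategy. Consumes the
#' R RNG stream, so sampling is reproducible under `set.seed()`.
#'
#' @param controller A [build_controller()] object.
#' @return A `strategy_sample` list: `strategy` (when the configuration is
#'   the standard 3-decision cycle), `decisions` (1-based token indices),
#'   `log_prob`, `entropy`, and the per-step `probs`.
#' @export
sample_strategy <- function(controller) {
  stopifnot(inherits(controller, "policy_controller"))
  cfg <- controller$config
  out <- ctrl_unroll(controller)
  standard <- identical(
    cfg$decision_vocabs,
    rep(c(nrow(op_table()), N_MAG_LEVELS, N_PROB_LEVELS),
        cfg$num_substrategies * cfg$ops_per_substrategy))
  out$strategy <- if (standard) decode_decisions(cfg, out$decisions) else NULL
  class(out) <- "strategy_sample"
  out
}

#' Turn a validation loss into the controller's reward
#'
#' @param loss Finite validation loss.
#' @return `-loss`.
#' @export
reward_from_validation <- function(loss) {
  if (!is.finite(loss)) stop("validation loss must be finite", call. = FALSE)
  -loss
}

#' Update the controller from sampled strategies and rewards
#'
#' Advantage is the reward minus an exponential moving-average baseline.
#' In `"ppo"` mode the clipped-surrogate objective (ratio on the joint
#' log-probability of the whole decision sequence) is optimized for
#' `ppo_epochs` passes over the batch; `"reinforce"` is the plain
#' score-function estimator used as the reference mode in gradient checks.
#' Both add an entropy bonus weighted by `entropy_weight`.
#'
#' @param controller A `policy_controller` (modified in place).
#' @param samples List of `strategy_sample` objects from [sample_strategy()].
#' @param rewards Numeric vector of rewards, one per sample.
#' @param mode `"ppo"` or `"reinforce"`.
#' @return A list with the updated `controller` and `diagnostics` (mean
#'   advantage, clip fraction, mean entropy, baseline).
#' @export
update_policy <- function(controller, samples, rewards,
                          mode = c("ppo", "reinforce")) {
  stopifnot(inherits(controller, "policy_controller"))
  mode <- match.arg(mode)
  if (!length(samples) || length(samples) != length(rewards)) {
    stop("samples and rewards must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(rewards))) {
    stop("rewards must be finite; update rejected", call. = FALSE)
  }
  cfg <- controller$config
  st <- controller$state
  if (is.na(st$baseline)) st$baseline <- mean(rewards)
  adv <- rewards - st$baseline
  if (cfg$normalize_advantage) {
    sd_a <- stats::sd(adv)
    if (length(adv) >= 2L && is.finite(sd_a) && sd_a > 1e-8) {
      adv <- (adv - mean(adv)) / sd_a
    } else {
      adv <- adv - mean(adv)
    }
  }
  epochs <- if (mode == "ppo") cfg$ppo_epochs else 1L
  clip <- cfg$ppo_clip
  n_clipped <- 0L; n_seen <- 0L
  ent_mean <- NA_real_
  for (ep in seq_len(epochs)) {
    gr <- grad_store()
    ents <- numeric(length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      u <- ctrl_unroll(controller, decisions = s$decisions, on_tape = TRUE)
      tp <- u$tp
      ents[i] <- ad_val(tp, u$ent_id)
      bonus <- ad_scale(tp, u$ent_id, cfg$entropy_weight)
      if (mode == "reinforce") {
        surr <- ad_scale(tp, u$logp_id, adv[i])
        obj <- ad_add(tp, surr, bonus)
      } else {
        ratio_id <- ad_exp(tp, ad_add(tp, u$logp_id,
                                      ad_const(tp, -s$log_prob)))
        ratio <- ad_val(tp, ratio_id)
        n_seen <- n_seen + 1L
        clipped <- is.finite(clip) &&
          ((adv[i] >= 0 && ratio > 1 + clip) ||
           (adv[i] < 0 && ratio < 1 - clip))
        if (clipped) {
          n_clipped <- n_clipped + 1L
          obj <- bonus  # surrogate is flat inside the clipped region
        } else {
          obj <- ad_add(tp, ad_scale(tp, ratio_id, adv[i]), bonus)
        }
      }
      loss_id <- ad_scale(tp, obj, -1)
      ad_backward(tp, loss_id, gr)
    }
    for (nm in names(gr$G)) gr$G[[nm]] <- gr$G[[nm]] / length(samples)
    adam_step(controller$opt, controller$ps, gr)
    if (ep == 1L) ent_mean <- mean(ents)
  }
  st$baseline <- cfg$baseline_decay * st$baseline +
    (1 - cfg$baseline_decay) * mean(rewards)
  diag <- list(mean_advantage = mean(adv),
               clip_fraction = if (n_seen) n_clipped / n_seen else 0,
               mean_entropy = ent_mean,
               baseline = st$baseline)
  list(controller = controller, diagnostics = diag)
}
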