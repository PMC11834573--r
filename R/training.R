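# Pretraining and fine-tuning loops: Adam with linear warmup/decay,
# per-sample gradient accumulation into batches, global-norm clipping,
# deterministic under a single seed, checkpoint/resume support.

#' Training configuration
#'
#' @param batch_size Samples per optimizer step (gradient accumulation).
#' @param epochs Number of passes over the data.
#' @param lr Peak learning rate (1e-4 for pretraining, 3e-4 for
#'   fine-tuning at full scale).
#' @param warmup_steps Warmup length; `NULL` = 5 percent of total steps.
#' @param weight_decay L2 coefficient.
#' @param beta1,beta2 Adam moment decays.
#' @param clip Global gradient-norm clip (0 disables).
#' @param seed RNG seed governing shuffling, corruption and init noise.
#' @param loss_weights Pretraining three-task weights.
#' @param eta_range,xi_std,mask_ratio_range Corruption parameters.
#' @return List of class `pairbind_train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 20L, lr = 1e-4,
                         warmup_steps = NULL, weight_decay = 1e-4,
                         beta1 = 0.9, beta2 = 0.99, clip = 1.0, seed = 1L,
                         loss_weights = c(type = 1, dist = 1, coord = 1),
                         eta_range = c(0.1, 0.5), xi_std = 0.05,
                         mask_ratio_range = c(0.1, 0.5)) {
  if (lr < 0) stop("lr must be >= 0")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 warmup_steps = warmup_steps,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 clip = clip, seed = as.integer(seed),
                 loss_weights = loss_weights, eta_range = eta_range,
                 xi_std = xi_std, mask_ratio_range = mask_ratio_range),
            class = "pairbind_train_config")
}

.resolve_warmup <- function(tc, total_steps) {
  if (!is.null(tc$warmup_steps)) return(tc$warmup_steps)
  max(1L, round(0.05 * total_steps))
}

#' Pretrain the ligand encoder with the three self-supervised tasks
#'
#' Per step: each molecule in the batch is corrupted (type masking +
#' LJ-gradient-directed coordinate noise), featurized on the noisy
#' coordinates, passed through encoder and heads, and the weighted
#' three-task loss is backpropagated; gradients are averaged over the
#' batch, clipped, and applied with Adam under a linear warmup/decay
#' schedule.
#'
#' @param molecules List of [molecule()] (a conformer is one sample; if a
#'   molecule has several conformers supply them as separate entries and
#'   one is picked per epoch upstream).
#' @param cfg [encoder_config()].
#' @param tc [train_config()].
#' @param lj LJ parameter table.
#' @param structure_mode Structural ablation flag.
#' @param resume Optional checkpoint from a previous [pretrain()] call; the
#'   loop continues from its recorded epoch with its optimizer and RNG
#'   state.
#' @param stop_after Stop after this epoch while keeping the LR schedule of
#'   the full `tc$epochs` run (supports checkpoint/resume).
#' @return Checkpoint list of class `pairbind_checkpoint`: `params`, `cfg`,
#'   `tc`, `opt`, `epoch`, `loss_history` (per-epoch data frame),
#'   `rng_state`, `vocab`.
#' @export
pretrain <- function(molecules, cfg = encoder_config(), tc = train_config(),
                     lj = load_lj_params(), structure_mode = "full",
                     resume = NULL, stop_after = tc$epochs) {
  if (length(molecules) == 0) stop("empty molecule dataset")
  n <- length(molecules)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  total_steps <- tc$epochs * steps_per_epoch
  warmup <- .resolve_warmup(tc, total_steps)
  if (is.null(resume)) {
    params <- c(init_encoder_params(cfg, atom_vocabulary(), "enc",
                                    seed = tc$seed + 101L),
                init_pretrain_heads(cfg, atom_vocabulary(), "heads",
                                    seed = tc$seed + 202L))
    opt <- adam_init(params, tc$beta1, tc$beta2,
                     weight_decay = tc$weight_decay)
    start_epoch <- 1L
    history <- NULL
    rng <- NULL
  } else {
    params <- resume$params; opt <- resume$opt
    start_epoch <- resume$epoch + 1L
    history <- resume$loss_history
    rng <- resume$rng_state
  }
  run <- function() {
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
    step <- (start_epoch - 1L) * steps_per_epoch
    for (epoch in seq(start_epoch, min(stop_after, tc$epochs))) {
      ord <- sample.int(n)
      ep_loss <- c(total = 0, type = 0, dist = 0, coord = 0)
      for (b in seq_len(steps_per_epoch)) {
        take <- ord[((b - 1) * tc$batch_size + 1):min(b * tc$batch_size, n)]
        acc <- NULL; bl <- 0
        for (i in take) {
          cr <- corrupt_molecule(molecules[[i]], lj,
                                 eta_range = tc$eta_range,
                                 xi_std = tc$xi_std,
                                 mask_ratio_range = tc$mask_ratio_range)
          pl <- pretrain_loss(params, cr, cfg,
                              loss_weights = tc$loss_weights,
                              structure_mode = structure_mode)
          acc <- grads_accumulate(acc, pl$grads)
          bl <- bl + pl$loss
          ep_loss <- ep_loss + c(pl$loss, pl$components)
        }
        cpp_scale_inplace(acc, 1 / length(take))
        if (tc$clip > 0) acc <- clip_global_norm(acc, tc$clip)
        step <- step + 1L
        lr <- lr_schedule(step, tc$lr, warmup, total_steps)
        upd <- adam_step(params, acc, opt, lr)
        params <- upd$params; opt <- upd$state
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  total = ep_loss[["total"]] / n,
                                  type = ep_loss[["type"]] / n,
                                  dist = ep_loss[["dist"]] / n,
                                  coord = ep_loss[["coord"]] / n))
    }
    structure(list(params = params, cfg = cfg, tc = tc, opt = opt,
                   epoch = min(stop_after, tc$epochs),
                   loss_history = history,
                   rng_state = get(".Random.seed", envir = globalenv()),
                   vocab = atom_vocabulary(),
                   structure_mode = structure_mode),
              class = "pairbind_checkpoint")
  }
  if (is.null(resume)) with_seed_(tc$seed, run()) else with_seed_(0L, run())
}

#' Evaluate a complex model on labelled samples
#'
#' @param model `pairbind_affinity_model`.
#' @param samples List of complex samples.
#' @return List with `yhat`, `y`, `site_probs`, `site_labels`, `metrics`
#'   ([metrics_report()]).
#' @export
evaluate_complexes <- function(model, samples) {
  samples <- precompute_features(samples)
  yhat <- numeric(length(samples))
  probs <- vector("list", length(samples))
  st <- model$label_stats
  if (is.null(st)) st <- c(mu = 0, sd = 1)
  for (i in seq_along(samples)) {
    fw <- .complex_forward(model$params, model$cfg, samples[[i]],
                           want_cache = FALSE)
    yhat[i] <- st[["mu"]] + st[["sd"]] * fw$yhat
    probs[[i]] <- fw$site_probs
  }
  y <- vapply(samples, `[[`, numeric(1), "pK")
  site_labels <- lapply(samples, `[[`, "site_labels")
  list(yhat = yhat, y = y, site_probs = probs, site_labels = site_labels,
       metrics = metrics_report(y, yhat,
                                unlist(site_labels), unlist(probs)))
}

#' Fine-tune the complex model for affinity and/or binding-site prediction
#'
#' Trains trunk + heads (and, unless frozen, both encoders) on labelled
#' complexes, evaluating on a validation set each epoch and keeping the
#' parameters of the best epoch (lowest validation RMSE for tasks
#' including affinity, otherwise highest site ROC-AUC). `pretrained`
#' ("with ligand pretraining") vs `NULL` ("from scratch") realises the
#' pretraining ablation.
#'
#' @param train_samples,val_samples Lists of complex samples (`ligand`,
#'   `protein`, `pK`, `site_labels`).
#' @param cfg [complex_config()].
#' @param tc [train_config()] (fine-tuning defaults: lr 3e-4, batch 8).
#' @param pretrained Optional [pretrain()] checkpoint (its encoder seeds
#'   the ligand branch).
#' @param init_model Optional `pairbind_affinity_model` to continue
#'   training from (curriculum fine-tuning); overrides `pretrained`.
#' @param tasks `"affinity"`, `"site"`, or `"both"`.
#' @param augment_jitter Coordinate-jitter augmentation: per epoch each
#'   training structure is re-featurized after adding isotropic Gaussian
#'   noise of this standard deviation (Angstrom) to all coordinates
#'   (0 disables). Mimics thermal fluctuation and discourages
#'   memorisation of exact bin patterns.
#' @param standardize_labels Standardize pK targets on the training set
#'   (predictions are mapped back).
#' @return List of class `pairbind_finetuned`: `model`, `history`
#'   (per-epoch metrics data frame), `best_epoch`.
#' @export
finetune <- function(train_samples, val_samples, cfg = complex_config(),
                     tc = train_config(batch_size = 8L, lr = 3e-4),
                     pretrained = NULL, init_model = NULL, tasks = "both",
                     standardize_labels = TRUE, augment_jitter = 0) {
  if (length(train_samples) == 0) stop("empty training set")
  if (tasks %in% c("affinity", "both") &&
      any(!vapply(train_samples, function(s) !is.null(s$pK), logical(1))))
    stop("affinity task enabled but pK labels missing")
  if (tasks %in% c("site", "both") &&
      any(!vapply(train_samples, function(s) !is.null(s$site_labels),
                  logical(1))))
    stop("site task enabled but site labels missing")
  train_samples <- precompute_features(train_samples)
  # standardize affinity targets on the training set; predictions are
  # mapped back to pK via the stored statistics
  label_stats <- c(mu = 0, sd = 1)
  if (standardize_labels && tasks %in% c("affinity", "both")) {
    ys <- vapply(train_samples, `[[`, numeric(1), "pK")
    label_stats <- c(mu = mean(ys), sd = max(stats::sd(ys), 1e-8))
    train_samples <- lapply(train_samples, function(s) {
      s$pK <- (s$pK - label_stats[["mu"]]) / label_stats[["sd"]]
      s
    })
  }
  n <- length(train_samples)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  total_steps <- tc$epochs * steps_per_epoch
  warmup <- .resolve_warmup(tc, total_steps)
  with_seed_(tc$seed, {
    model <- if (!is.null(init_model)) {
      m <- init_model
      m$cfg <- cfg
      m
    } else {
      init_complex_model(cfg,
                         pretrained = if (!is.null(pretrained))
                           pretrained$params else NULL)
    }
    if (standardize_labels && tasks %in% c("affinity", "both"))
      model$label_stats <- label_stats
    else if (is.null(model$label_stats))
      model$label_stats <- c(mu = 0, sd = 1)
    params <- model$params
    opt <- adam_init(params, tc$beta1, tc$beta2,
                     weight_decay = tc$weight_decay)
    history <- NULL
    best <- list(score = Inf, params = params, epoch = 0L)
    step <- 0L
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      epoch_samples <- train_samples
      if (augment_jitter > 0) {
        epoch_samples <- lapply(train_samples, function(s) {
          s$ligand$coords <- s$ligand$coords +
            matrix(stats::rnorm(length(s$ligand$coords), 0, augment_jitter),
                   ncol = 3)
          s$protein$ca_coords <- s$protein$ca_coords +
            matrix(stats::rnorm(length(s$protein$ca_coords), 0,
                                augment_jitter), ncol = 3)
          s$pf_lig <- NULL; s$pf_prot <- NULL
          s
        })
        epoch_samples <- precompute_features(epoch_samples)
      }
      ep_loss <- 0
      for (b in seq_len(steps_per_epoch)) {
        take <- ord[((b - 1) * tc$batch_size + 1):min(b * tc$batch_size, n)]
        acc <- NULL
        for (i in take) {
          fg <- finetune_sample_grads(params, cfg, epoch_samples[[i]], tasks)
          acc <- grads_accumulate(acc, fg$grads)
          ep_loss <- ep_loss + fg$loss
        }
        cpp_scale_inplace(acc, 1 / length(take))
        if (tc$clip > 0) acc <- clip_global_norm(acc, tc$clip)
        step <- step + 1L
        lr <- lr_schedule(step, tc$lr, warmup, total_steps)
        upd <- adam_step(params, acc, opt, lr)
        params <- upd$params; opt <- upd$state
      }
      row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                        val_rmse = NA_real_, val_pearson = NA_real_,
                        val_auc = NA_real_)
      score <- NA_real_
      if (length(val_samples) > 0) {
        model$params <- params
        ev <- evaluate_complexes(model, val_samples)
        row$val_rmse <- ev$metrics$rmse
        row$val_pearson <- ev$metrics$pearson
        row$val_auc <- ev$metrics$roc_auc
        score <- if (tasks %in% c("affinity", "both")) ev$metrics$rmse
                 else -ev$metrics$roc_auc
      } else {
        score <- ep_loss / n
      }
      history <- rbind(history, row)
      if (is.finite(score) && score < best$score)
        best <- list(score = score, params = params, epoch = epoch)
    }
    model$params <- best$params
    structure(list(model = model, history = history,
                   best_epoch = best$epoch, final_params = params, tc = tc,
                   tasks = tasks),
              class = "pairbind_finetuned")
  })
}

#' Run a k-fold cross-validation experiment
#'
#' Applies [finetune()] across the rounds of [make_cv_folds()] and collects
#' per-round test metrics.
#'
#' @param samples Named list of complex samples (names = IDs).
#' @param k Folds.
#' @param cfg,tc,pretrained,tasks Passed to [finetune()].
#' @param seed Fold-assignment seed.
#' @param rounds Optionally run only the first `rounds` rounds.
#' @return Data frame of per-round test metrics.
#' @export
crossvalidate <- function(samples, k = 10L, cfg = complex_config(),
                          tc = train_config(batch_size = 8L, lr = 3e-4),
                          pretrained = NULL, tasks = "both", seed = 1L,
                          rounds = k) {
  ids <- names(samples)
  if (is.null(ids)) stop("samples must be a named list (names = IDs)")
  sp <- make_cv_folds(ids, k, seed)
  out <- NULL
  for (r in seq_len(rounds)) {
    rd <- sp$rounds[[r]]
    ft <- finetune(samples[rd$train], samples[rd$val], cfg, tc,
                   pretrained = pretrained, tasks = tasks)
    ev <- evaluate_complexes(ft$model, samples[rd$test])
    out <- rbind(out, data.frame(round = r, n_test = length(rd$test),
                                 rmse = ev$metrics$rmse,
                                 pearson = ev$metrics$pearson,
                                 spearman = ev$metrics$spearman,
                                 roc_auc = ev$metrics$roc_auc,
                                 f1 = ev$metrics$f1))
  }
  out
}

#' Save / load checkpoints
#'
#' Checkpoints are single-file serialised parameter trees with their
#' configs, vocabulary and optimizer state (RDS, versioned by the package
#' version string).
#'
#' @param ckpt Checkpoint or model object.
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  ckpt$pairbind_version <- as.character(utils::packageVersion("pairbind"))
  saveRDS(ckpt, path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
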