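## Training loop: Adam on the categorical cross-entropy, seeded per-epoch
## shuffling, per-epoch train/validation metrics, best-validation-accuracy
## checkpointing. No augmentation, no scheduling, no early stopping.

#' Training configuration
#'
#' Full-scale defaults: Adam at learning rate 1e-4, batch size 16, 100
#' epochs, 70/15/15 fractional splitting (or 15% of a pre-split training set
#' carved for validation).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs (>= 1).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param seed seed for shuffling, dropout, and any split derived from this
#'   config.
#' @param split train/validation/test fractions (fractional mode).
#' @param val_fraction validation fraction of the training set (presplit
#'   mode).
#' @param checkpoint `"best"` restores the weights of the epoch with highest
#'   validation accuracy; `"last"` keeps the final weights.
#' @return a list of class `scmix_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L, epochs = 100L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7, seed = 1L,
                         split = c(0.70, 0.15, 0.15), val_fraction = 0.15,
                         checkpoint = c("best", "last")) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), split = split,
                 val_fraction = val_fraction,
                 checkpoint = match.arg(checkpoint)),
            class = "scmix_train_config")
}

## Adam update over all layers, in place
adam_step <- function(model, cfg, t) {
  lr <- cfg$learning_rate
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  for (ly in model$layers) {
    if (is.null(ly$opt)) {
      ly$opt <- lapply(ly$params, function(p) {
        z <- p; z[] <- 0
        list(m = z, v = z)
      })
    }
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      st <- ly$opt[[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      ly$opt[[nm]] <- st
      ly$params[[nm]] <- ly$params[[nm]] - corr * st$m / (sqrt(st$v) + cfg$eps)
    }
  }
  invisible(NULL)
}

snapshot_params <- function(model) {
  lapply(model$layers, function(ly)
    list(params = ly$params,
         run = if (inherits(ly, "ly_batchnorm"))
           list(mean = ly$run_mean, var = ly$run_var)))
}

restore_params <- function(model, snap) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run)) {
      model$layers[[i]]$run_mean <- snap[[i]]$run$mean
      model$layers[[i]]$run_var <- snap[[i]]$run$var
    }
  }
  invisible(model)
}

eval_split <- function(model, x, y, batch_size) {
  probs <- predict(model, x, batch_size = batch_size)
  yv <- max.col(y, ties.method = "first")
  pred <- max.col(probs, ties.method = "first")
  c(loss = cross_entropy(y, probs), acc = mean(pred == yv))
}

#' Train a model on a dataset split
#'
#' Minimizes the categorical cross-entropy with Adam; shuffles the training
#' data each epoch (seeded); records per-epoch train/validation loss and
#' accuracy; restores the checkpoint with the highest validation accuracy
#' when `cfg$checkpoint == "best"`.
#'
#' @param model a `scmix_model` (updated in place).
#' @param train training `scmix_dataset`.
#' @param val optional validation `scmix_dataset`.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @param target_val_acc optional fraction in `(0, 1]`: stop once validation
#'   accuracy reaches this target (a capability check convenience; the
#'   default `NULL` trains for the full epoch budget with no early stopping).
#' @return an object of class `scmix_run`: `history` tibble (epoch,
#'   train_loss, train_acc, val_loss, val_acc), `best_epoch`, `best_val_acc`,
#'   the trained `model`, and the configs.
#' @export
train_model <- function(model, train, val = NULL, cfg = train_config(),
                        verbose = FALSE, target_val_acc = NULL) {
  stopifnot(inherits(model, "scmix_model"), inherits(train, "scmix_dataset"))
  c_n <- model$cfg$num_classes
  xtr <- dataset_tensor(train)
  ytr <- one_hot(train$labels, c_n)
  xva <- if (!is.null(val)) dataset_tensor(val)
  yva <- if (!is.null(val)) one_hot(val$labels, c_n)
  n <- dim(xtr)[1]
  set.seed(cfg$seed)
  hist <- vector("list", cfg$epochs)
  best <- list(epoch = 0L, acc = -Inf, snap = NULL)
  t_step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (at in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[at:min(at + cfg$batch_size - 1L, n)]
      xb <- xtr[idx, , , , drop = FALSE]
      yb <- ytr[idx, , drop = FALSE]
      zero_grads(model$layers)
      probs <- model_forward(model, xb, training = TRUE)
      loss <- cross_entropy(yb, probs)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; aborting", epoch), call. = FALSE)
      model_backward(model, (probs - yb) / nrow(yb))
      t_step <- t_step + 1L
      adam_step(model, cfg, t_step)
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(probs, ties.method = "first") ==
                                 max.col(yb, ties.method = "first"))
    }
    row <- tibble::tibble(epoch = epoch,
                          train_loss = ep_loss / n, train_acc = ep_hits / n,
                          val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      vm <- eval_split(model, xva, yva, cfg$batch_size)
      row$val_loss <- vm["loss"]; row$val_acc <- vm["acc"]
      if (vm["acc"] > best$acc) {
        best <- list(epoch = epoch, acc = vm["acc"], snap = snapshot_params(model))
      }
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", epoch,
                      row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
    if (!is.null(target_val_acc) && !is.na(row$val_acc) &&
        row$val_acc >= target_val_acc) break
  }
  hist <- hist[!vapply(hist, is.null, TRUE)]
  if (cfg$checkpoint == "best" && !is.null(best$snap)) restore_params(model, best$snap)
  structure(list(history = dplyr::bind_rows(hist),
                 best_epoch = if (best$epoch > 0) best$epoch else cfg$epochs,
                 best_val_acc = if (is.finite(best$acc)) best$acc else NA_real_,
                 model = model, model_cfg = model$cfg, train_cfg = cfg),
            class = "scmix_run")
}

#' @export
print.scmix_run <- function(x, ...) {
  cat(sprintf("<scmix_run> %d epochs, best val acc %.3f (epoch %d)\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Serializes the architecture config and all parameters (including batch-
#' normalization running moments) with R's native serialization.
#'
#' @param model a `scmix_model`. @param path checkpoint file path.
#' @return `save_checkpoint`: invisibly, the path. `load_checkpoint`: a
#'   rebuilt `scmix_model`.
#' @export
save_checkpoint <- function(model, path) {
  state <- lapply(model$layers, function(ly)
    list(params = ly$params,
         run = if (inherits(ly, "ly_batchnorm"))
           list(mean = ly$run_mean, var = ly$run_var)))
  saveRDS(list(cfg = model$cfg, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  if (length(model$layers) != length(ck$state))
    stop("checkpoint does not match the architecture", call. = FALSE)
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$params <- ck$state[[i]]$params
    if (!is.null(ck$state[[i]]$run)) {
      model$layers[[i]]$run_mean <- ck$state[[i]]$run$mean
      model$layers[[i]]$run_var <- ck$state[[i]]$run$var
      model$layers[[i]]$seen <- TRUE
    }
  }
  model
}

#' Architecture summary as JSON
#'
#' Writes layer classes and parameter counts plus the architecture config.
#'
#' @param model a `scmix_model`. @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_architecture_json <- function(model, path) {
  layers <- lapply(model$layers, function(ly)
    list(type = class(ly)[1],
         params = lapply(ly$params, function(p) dim(p) %||% length(p))))
  jsonlite::write_json(
    list(variant = model$cfg$variant,
         num_parameters = count_parameters(model),
         config = model$cfg[setdiff(names(model$cfg), "swin")],
         layers = layers),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Evaluate a trained model on a test set
#'
#' Deterministic inference (dropout off, batch normalization in inference
#' mode); produces the confusion matrix, per-class + macro report, and
#' per-image predictions.
#'
#' @param model a `scmix_model` or `scmix_run`.
#' @param test a `scmix_dataset` with matching classes.
#' @param batch_size forward batch size (results are batch-size invariant).
#' @return an object of class `scmix_eval`: `confusion`, `report` (tibble),
#'   `predictions` (tibble: truth, pred, prob), `pooled_acc`.
#' @export
evaluate_model <- function(model, test, batch_size = 16L) {
  if (inherits(model, "scmix_run")) model <- model$model
  if (length(test$class_names) != model$cfg$num_classes)
    stop(sprintf("model has %d classes but the dataset has %d",
                 model$cfg$num_classes, length(test$class_names)), call. = FALSE)
  probs <- predict(model, test, batch_size = batch_size)
  pred <- max.col(probs, ties.method = "first")
  top_prob <- probs[cbind(seq_len(nrow(probs)), pred)]
  cm <- confusion_matrix(test$labels, pred, test$class_names)
  structure(list(confusion = cm,
                 report = metrics_report(cm),
                 predictions = tibble::tibble(
                   truth = test$class_names[test$labels],
                   pred = test$class_names[pred],
                   prob = top_prob),
                 pooled_acc = pooled_accuracy(cm)),
            class = "scmix_eval")
}

#' @export
print.scmix_eval <- function(x, ...) {
  macro <- x$report[x$report$class == "MACRO", ]
  cat(sprintf("<scmix_eval> pooled acc %.2f%%; macro acc %.2f, pr %.2f, re %.2f, f1 %.2f\n",
              x$pooled_acc, macro$acc, macro$pr, macro$re, macro$f1))
  invisible(x)
}

#' Train and evaluate every ablation variant
#'
#' Builds, trains, and evaluates all seven architecture variants under one
#' seed and collects their macro metrics into a comparison table. One
#' variant's failure does not abort the others.
#'
#' @param splits list with `train`, `val`, `test` datasets (see
#'   [split_dataset()]).
#' @param model_cfg a [model_config()]; its `variant` field is overridden.
#' @param train_cfg a [train_config()].
#' @param variants variant names to run (default: all seven).
#' @param verbose print progress.
#' @return an object of class `scmix_ablation`: `table` (tibble: variant,
#'   acc, pr, re, f1, n_params, error) and `evals` (per-variant
#'   `scmix_eval`s).
#' @export
run_ablation <- function(splits, model_cfg, train_cfg = train_config(),
                         variants = MODEL_VARIANTS, verbose = FALSE) {
  rows <- vector("list", length(variants))
  evals <- stats::setNames(vector("list", length(variants)), variants)
  for (i in seq_along(variants)) {
    v <- variants[i]
    rows[[i]] <- tryCatch({
      cfg_v <- model_cfg
      cfg_v$variant <- v
      validate_variant_shapes(cfg_v)
      model <- build_model(cfg_v, seed = train_cfg$seed)
      run <- train_model(model, splits$train, splits$val, train_cfg)
      ev <- evaluate_model(run, splits$test, train_cfg$batch_size)
      evals[[v]] <- ev
      macro <- ev$report[ev$report$class == "MACRO", ]
      if (verbose) message(sprintf("%s: macro acc %.2f", v, macro$acc))
      tibble::tibble(variant = v, acc = macro$acc, pr = macro$pr,
                     re = macro$re, f1 = macro$f1,
                     n_params = count_parameters(model), error = NA_character_)
    }, error = function(e) {
      tibble::tibble(variant = v, acc = NA_real_, pr = NA_real_, re = NA_real_,
                     f1 = NA_real_, n_params = NA_real_,
                     error = conditionMessage(e))
    })
  }
  structure(list(table = dplyr::bind_rows(rows), evals = evals),
            class = "scmix_ablation")
}

#' Desk-scale preset
#'
#' A reduced configuration for CPU-scale experimentation and testing:
#' 112-pixel inputs, 32 filters, depth 2, token grids 14/7 with 64-wide
#' tokens, window 7, 30 epochs at learning rate 1e-3. The full-scale
#' configuration is [paper_preset()].
#'
#' @param num_classes number of classes.
#' @return list with elements `model` ([model_config()]) and `train`
#'   ([train_config()]).
#' @export
desk_preset <- function(num_classes = 3L) {
  list(model = model_config(num_classes, input_size = 112L,
                            mpcm_patches = c(2L, 4L, 8L), filters = 32L,
                            depth = 2L, mpst_grids = c(14L, 7L),
                            token_dim = 64L,
                            swin = swin_config(window = 7L, heads = 4L,
                                               mlp_dim = 64L, dropout_rate = 0.1)),
       train = train_config(learning_rate = 1e-3, epochs = 30L))
}

#' Full-scale preset
#'
#' The architecture and optimizer at full scale: 224-pixel inputs, patch
#' sizes 2/4/8 with 128 filters and depth 4, token grids 28/14 with 256-wide
#' tokens, Adam at 1e-4, batch 16, 100 epochs.
#'
#' @param num_classes number of classes.
#' @return list with elements `model` and `train`.
#' @export
paper_preset <- function(num_classes) {
  list(model = model_config(num_classes), train = train_config())
}
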