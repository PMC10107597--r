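#' Train a model with Adam
#'
#' Mini-batch training with the Adam optimiser (default learning rate
#' 1e-4, the reference training setting). Batch order is reshuffled
#' every epoch from a seed derived deterministically from `seed` and the
#' epoch index, so two runs with identical inputs produce identical
#' loss curves.
#'
#' @param model a `tsd_model` from [build_model()].
#' @param train list with `x` `(N,S,S,C)` and `y` labels in
#'   `1..n_classes`.
#' @param val optional validation list of the same shape.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed shuffling seed (defaults to the model's config seed).
#' @param select which parameter state to return: `"final"` (the last
#'   epoch's, the default — no early stopping, matching the reference
#'   setup) or `"best_val"` (the epoch with the highest validation OA,
#'   the usual checkpoint-selection practice when a validation split
#'   exists; training still runs all `epochs`).
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, loss, train OA of the running epoch, val OA).
#' @export
train_model <- function(model, train, val = NULL, epochs = 30L,
                        batch_size = 16L, lr = 1e-4,
                        seed = model$cfg$seed,
                        select = c("final", "best_val"), verbose = FALSE) {
  stopifnot(epochs >= 1L, lr > 0, batch_size >= 1L)
  select <- match.arg(select)
  if (select == "best_val" && (is.null(val) || length(val$y) == 0L)) {
    stop("select = 'best_val' needs a validation split")
  }
  best <- list(oa = -Inf, params = NULL)
  n <- dim(train$x)[1L]
  stopifnot(n == length(train$y))
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_oa = numeric(), val_oa = numeric())
  for (ep in seq_len(epochs)) {
    set.seed(as.integer(seed) * 131L + ep)
    ord <- sample.int(n)
    ep_loss <- 0
    n_correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      gsum <- NULL
      for (i in idx) {
        fw <- forward_sample(model, batch_slice(train$x, i), keep_cache = TRUE)
        bw <- backward_sample(model, fw$cache, train$y[i])
        ep_loss <- ep_loss + bw$loss
        if (which.max(fw$probs) == train$y[i]) n_correct <- n_correct + 1L
        gsum <- if (is.null(gsum)) bw$grads else param_map2(gsum, bw$grads, `+`)
      }
      gavg <- param_map(gsum, function(x) x / length(idx))
      st <- adam_step(model$params, gavg, state, lr = lr)
      model$params <- st$params
      state <- st$state
    }
    val_oa <- NA_real_
    if (!is.null(val) && length(val$y) > 0L) {
      val_oa <- mean(predict_classes(model, val$x) == val$y)
      if (select == "best_val" && val_oa > best$oa) {
        best <- list(oa = val_oa, params = model$params)
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, train_oa = n_correct / n, val_oa = val_oa
    ))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  train OA %.3f  val OA %s",
                      ep, ep_loss / n, n_correct / n,
                      ifelse(is.na(val_oa), "-", sprintf("%.3f", val_oa))))
    }
  }
  if (select == "best_val" && !is.null(best$params)) model$params <- best$params
  list(model = model, history = history)
}

#' Evaluate a model on labelled data
#'
#' @param model a `tsd_model`.
#' @param x image batch `(N,S,S,C)`.
#' @param y true labels in `1..n_classes`.
#' @return list with the confusion matrix (`cm`) and the
#'   [metrics_report()] (`metrics`).
#' @export
evaluate_model <- function(model, x, y) {
  pred <- predict_classes(model, x)
  cm <- confusion_matrix(y, pred, n_classes = model$cfg$n_classes)
  list(cm = cm, metrics = metrics_report(cm))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialised model plus a plain-text
#' config snapshot (`config.dcf`) for inspection.
#'
#' @param model a `tsd_model`.
#' @param dir run directory (created if missing).
#' @return path of the checkpoint file, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "model.rds")
  saveRDS(model, path)
  cfg <- model$cfg
  snap <- data.frame(
    image_size = cfg$image_size, widths = paste(cfg$widths, collapse = ","),
    d_fuse = cfg$d_fuse, n_classes = cfg$n_classes,
    T1 = cfg$thresholds$T1, T2 = cfg$thresholds$T2, T3 = cfg$thresholds$T3,
    mean_rule = cfg$mean_rule, sgdm_shallow = cfg$sgdm_shallow,
    knockout = paste(cfg$knockout, collapse = ","), seed = cfg$seed
  )
  write.dcf(snap, file.path(dir, "config.dcf"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path)
  readRDS(path)
}

#' Threshold grid of the reference ablation study
#'
#' The six gate-threshold triples of the published comparison grid; the
#' first row is the best-performing (default) configuration.
#'
#' @return data.frame with columns `T1`, `T2`, `T3`.
#' @export
ablation_threshold_grid <- function() {
  data.frame(
    T1 = c(0.5, 0.6, 0.6, 0.6, 0.6, 0.7),
    T2 = c(0.3, 0.2, 0.2, 0.3, 0.4, 0.5),
    T3 = c(0.5, 0.5, 0.4, 0.6, 0.5, 0.5)
  )
}

ablate_one <- function(cfg, data, epochs, batch_size, lr) {
  model <- build_model(cfg)
  fit <- train_model(model, data$train, data$val, epochs = epochs,
                     batch_size = batch_size, lr = lr)
  ev <- evaluate_model(fit$model, data$test$x, data$test$y)
  ev$metrics
}

#' Threshold ablation
#'
#' Trains and evaluates one model per gate-threshold triple and reports
#' OA/AA/Kappa per row, in the schema of the published threshold table.
#'
#' @param grid data.frame with columns `T1`, `T2`, `T3` (default: the
#'   six reference triples).
#' @param base_cfg a [tsd_config()] supplying everything but the
#'   thresholds.
#' @param data list of `train`/`val`/`test` splits (as from
#'   [synth_tensors()]).
#' @param epochs,batch_size,lr training settings per variant.
#' @return data.frame: T1, T2, T3, OA, AA, Kappa (printed mode),
#'   Kappa_standard.
#' @export
ablate_thresholds <- function(grid = ablation_threshold_grid(), base_cfg, data,
                              epochs = 5L, batch_size = 16L, lr = 1e-4) {
  stopifnot(all(c("T1", "T2", "T3") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- base_cfg
    cfg$thresholds <- threshold_config(grid$T1[r], grid$T2[r], grid$T3[r])
    m <- ablate_one(cfg, data, epochs, batch_size, lr)
    data.frame(T1 = grid$T1[r], T2 = grid$T2[r], T3 = grid$T3[r],
               OA = m$OA, AA = m$AA, Kappa = m$kappa_printed,
               Kappa_standard = m$kappa_standard)
  })
  do.call(rbind, rows)
}

#' Feature-knockout ablation
#'
#' Trains one model per knocked-out pathway (its branch replaced by
#' exact zeros), in the schema of the published feature table
#' (`Model_nof_cg`, `Model_nof_1`, ...), plus the full model.
#'
#' @param knockouts character vector of pathways to knock out one at a
#'   time; subset of `c("f_cg", "f1", "f2", "f3")`.
#' @inheritParams ablate_thresholds
#' @return data.frame: model, OA, AA, Kappa, Kappa_standard.
#' @export
ablate_features <- function(knockouts = c("f_cg", "f1", "f2", "f3"),
                            base_cfg, data, epochs = 5L, batch_size = 16L,
                            lr = 1e-4) {
  variants <- c(as.list(knockouts), list(character(0)))
  labels <- c(paste0("Model_no", sub("^f_?", "f_", knockouts)), "full")
  rows <- lapply(seq_along(variants), function(i) {
    cfg <- base_cfg
    cfg$knockout <- variants[[i]]
    m <- ablate_one(cfg, data, epochs, batch_size, lr)
    data.frame(model = labels[i], OA = m$OA, AA = m$AA,
               Kappa = m$kappa_printed, Kappa_standard = m$kappa_standard)
  })
  do.call(rbind, rows)
}
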