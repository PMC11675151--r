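#' Combined BCE + hinge loss
#'
#' `L = w * BCE(sigmoid(p), y) + (1 - w) * mean(max(0, 1 - y' p))` with
#' `y' = 2y - 1`, averaged over edges. Logits are raw (pre-sigmoid).
#'
#' @param logits Raw model outputs.
#' @param labels Labels in `{0, 1}`.
#' @param w BCE weight in `[0, 1]` (default 0.5).
#' @return Scalar loss.
#' @export
combined_loss <- function(logits, labels, w = 0.5) {
  if (length(logits) == 0) stop("empty batch")
  stopifnot(length(logits) == length(labels), w >= 0, w <= 1,
            all(labels %in% c(0, 1)))
  bce <- -mean(labels * log_sigmoid(logits) +
                 (1 - labels) * log_sigmoid(-logits))
  yp <- 2 * labels - 1
  hinge <- mean(pmax(0, 1 - yp * logits))
  w * bce + (1 - w) * hinge
}

# d loss / d logits
combined_loss_grad <- function(logits, labels, w = 0.5) {
  n <- length(logits)
  yp <- 2 * labels - 1
  (w * (sigmoid(logits) - labels) +
      (1 - w) * (-yp) * as.numeric(1 - yp * logits > 0)) / n
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over all score thresholds (equivalent to the
#' Mann-Whitney statistic with half-credit for ties).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Labels in `{0, 1}`.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class
#'   is present.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(y)[keep] / n1)
  fpr <- c(0, cumsum(1 - y)[keep] / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Area under the precision-recall curve
#'
#' Step integration: `sum_k (R_k - R_{k-1}) P_k` over decreasing score
#' thresholds (ties grouped).
#'
#' @inheritParams roc_auc
#' @return AUPR, or `NA` if no positive labels.
#' @export
pr_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) {
    warning("AUPR undefined: no positive labels")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion counts at a threshold
#'
#' @param scores Scores on the probability scale (or any scale matching
#'   `threshold`).
#' @param labels Labels in `{0, 1}`.
#' @param threshold Decision threshold (score > threshold is positive).
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores > threshold)
  list(TP = sum(pred == 1 & labels == 1),
       FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs Number of epochs.
#' @param lr Adam learning rate.
#' @param loss_w BCE weight of the combined loss.
#' @param patience Early-stopping patience (epochs without validation
#'   AUC improvement); `Inf` disables early stopping.
#' @param seed Seed for training-time randomness (dropout).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, lr = 1e-3, loss_w = 0.5,
                         patience = 20, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, loss_w >= 0, loss_w <= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, loss_w = loss_w,
                 patience = patience, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the EPI edge classifier
#'
#' One shared model is trained across all chromosome subgraphs: each
#' epoch iterates the chromosomes, runs a full-subgraph forward pass,
#' computes the combined loss on training edges only, backpropagates and
#' applies one Adam update per subgraph. Validation AUC is computed
#' after every epoch; the returned parameters are those of the best
#' validation epoch (early stopping with the configured patience).
#'
#' @param graphs Named list of `epi_graph`s with splits assigned and
#'   edge types masked (see [assign_split()], [mask_edge_type()]).
#' @param config A [model_config()].
#' @param tconf A [train_config()].
#' @return An `epi_checkpoint`: `params`, `config`, `tconf`, `history`
#'   (per-epoch train loss and val AUC), `best_epoch`.
#' @export
train_epi_model <- function(graphs, config = model_config(),
                            tconf = train_config()) {
  batches <- lapply(graphs, make_model_batch, config = config)
  n_train <- sum(vapply(batches, function(b) sum(b$split == "train"), 0))
  if (n_train == 0) stop("no training edges")
  params <- init_model(config)
  state <- adam_init(params)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_auc = numeric(0))
  wait <- 0
  with_seed(tconf$seed, {
    for (ep in seq_len(tconf$epochs)) {
      tot_loss <- 0; tot_n <- 0
      for (b in batches) {
        tr <- b$split == "train"
        if (!any(tr)) next
        mask <- if (config$dropout > 0)
          matrix(stats::rbinom(b$n_nodes * config$embed_dim, 1,
                               1 - config$dropout) / (1 - config$dropout),
                 b$n_nodes, config$embed_dim)
        fw <- model_forward(params, b, config, dropout_mask = mask)
        loss <- combined_loss(fw$logits[tr], b$label[tr], tconf$loss_w)
        dl <- numeric(length(fw$logits))
        dl[tr] <- combined_loss_grad(fw$logits[tr], b$label[tr],
                                     tconf$loss_w)
        grads <- model_backward(params, b, config, fw$cache, dl)
        upd <- adam_step(params, grads, state, lr = tconf$lr)
        params <- upd$params; state <- upd$state
        tot_loss <- tot_loss + loss * sum(tr); tot_n <- tot_n + sum(tr)
      }
      val <- predict_edges(params, batches, config, split = "val")
      val_auc <- if (length(val$logits) > 0 &&
                     length(unique(val$labels)) == 2)
        roc_auc(val$logits, val$labels) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = tot_loss / tot_n,
                                     val_auc = val_auc))
      if (!is.na(val_auc) && val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= tconf$patience) break
      }
    }
  })
  final <- if (best$epoch > 0) best$params else params
  structure(list(params = final, config = config, tconf = tconf,
                 history = hist,
                 best_epoch = if (best$epoch > 0) best$epoch else
                   nrow(hist)),
            class = "epi_checkpoint")
}

# Forward over all batches, collecting logits/labels of one split.
predict_edges <- function(params, batches, config, split = "test") {
  logits <- numeric(0); labels <- integer(0)
  for (b in batches) {
    sel <- if (identical(split, "all")) rep(TRUE, length(b$label)) else
      b$split %in% split
    if (!any(sel)) next
    fw <- model_forward(params, b, config)
    logits <- c(logits, fw$logits[sel])
    labels <- c(labels, b$label[sel])
  }
  list(logits = logits, labels = labels)
}

#' Evaluate a trained model on a split
#'
#' Runs the forward pass on every chromosome subgraph and reports AUC
#' (trapezoidal ROC), AUPR (precision-recall step integration) and the
#' threshold metrics TPR, FPR (`FP / (FP + TN)`) and precision at 0.5 on
#' the sigmoid of the logits.
#'
#' @param checkpoint An `epi_checkpoint` from [train_epi_model()].
#' @param graphs Graphs as passed to training (splits assigned, types
#'   masked).
#' @param split `"train"`, `"val"`, `"test"`, a vector of those (e.g.
#'   `c("val", "test")` for all held-out edges) or `"all"`.
#' @param threshold Decision threshold on the probability scale.
#' @return List of metrics: `auc`, `aupr`, `tpr`, `fpr`, `precision`,
#'   `n_pos`, `n_neg`, `threshold`.
#' @export
evaluate_epi_model <- function(checkpoint, graphs, split = "test",
                               threshold = 0.5) {
  batches <- lapply(graphs, make_model_batch, config = checkpoint$config)
  pr <- predict_edges(checkpoint$params, batches, checkpoint$config, split)
  if (length(pr$logits) == 0)
    stop(sprintf("no edges in split '%s'", paste(split, collapse = "+")))
  prob <- sigmoid(pr$logits)
  cc <- confusion_counts(prob, pr$labels, threshold)
  list(auc = roc_auc(prob, pr$labels),
       aupr = pr_auc(prob, pr$labels),
       tpr = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_,
       fpr = if (cc$FP + cc$TN > 0) cc$FP / (cc$FP + cc$TN) else NA_real_,
       precision = if (cc$TP + cc$FP > 0) cc$TP / (cc$TP + cc$FP) else
         NA_real_,
       n_pos = sum(pr$labels == 1), n_neg = sum(pr$labels == 0),
       threshold = threshold)
}

# ---- checkpoint (de)serialization -----------------------------------------

#' Save a checkpoint as JSON text
#'
#' Parameters are stored with full numeric precision together with the
#' model and training configurations and the training history.
#'
#' @param checkpoint An `epi_checkpoint`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  ser <- lapply(checkpoint$params, function(x)
    list(dim = if (is.matrix(x)) dim(x) else length(x),
         data = as.vector(x)))
  obj <- list(schema = "epigat-checkpoint-1",
              params = ser,
              config = unclass(checkpoint$config),
              tconf = unclass(checkpoint$tconf),
              history = checkpoint$history,
              best_epoch = checkpoint$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint saved with [save_checkpoint()]
#'
#' @param path JSON checkpoint path.
#' @return An `epi_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "epigat-checkpoint-1"))
    stop("unrecognized checkpoint schema")
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else
      as.numeric(p$data)
  })
  cfg <- obj$config
  cfg$aggregation <- as.character(cfg$aggregation)
  class(cfg) <- "model_config"
  tc <- obj$tconf
  class(tc) <- "train_config"
  structure(list(params = params, config = cfg, tconf = tc,
                 history = obj$history, best_epoch = obj$best_epoch),
            class = "epi_checkpoint")
}

#' Fit train-split normalization and apply it to all graph features
#'
#' Normalization statistics are fitted on the feature matrices of
#' training-split nodes only (across all chromosomes) and then applied
#' to every node, so held-out data never influences the scaling.
#'
#' @param graphs Split-assigned graphs (nodes carry a `split` column).
#' @return List with `graphs` (features normalized) and `stats`.
#' @export
normalize_graph_features <- function(graphs) {
  train_mats <- list()
  for (g in graphs) {
    ids <- g$nodes$id[g$nodes$split == "train"]
    train_mats <- c(train_mats, g$features[ids])
  }
  if (length(train_mats) == 0) stop("no training nodes to fit on")
  stats <- fit_normalization(train_mats)
  for (chr in names(graphs))
    graphs[[chr]]$features <- lapply(graphs[[chr]]$features,
                                     apply_normalization, stats = stats)
  list(graphs = graphs, stats = stats)
}
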