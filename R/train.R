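#' Training recipe specification
#'
#' The default recipe trains from scratch with sigmoid binary cross-entropy,
#' the Adam optimiser at learning rate 1e-4 (default moment parameters),
#' batch size 64, up to 100 epochs, no schedule, no weight decay, no early
#' stopping.
#'
#' @param batch_size optimiser batch size (default 64)
#' @param epochs training epochs (default 100)
#' @param learning_rate Adam step size (default 1e-4)
#' @param beta1,beta2,eps Adam moment parameters
#' @param seed RNG seed controlling shuffling
#' @param micro_batch images processed per forward/backward slice; gradients
#'   are accumulated so the optimiser step is identical to a full-batch
#'   step (memory knob only)
#' @return an object of class `train_spec`
#' @export
train_spec <- function(batch_size = 64L, epochs = 100L,
                       learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, seed = 1L, micro_batch = 16L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0,
            micro_batch >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed),
                 micro_batch = as.integer(micro_batch)),
            class = "train_spec")
}

#' Sigmoid binary cross-entropy loss on logits
#'
#' Mean over batch and classes of
#' `-(y log sigmoid(z) + (1 - y) log(1 - sigmoid(z)))`, evaluated in the
#' numerically stable logit form `max(z, 0) - z y + log(1 + exp(-|z|))`, so
#' the value is finite for any finite logits.
#'
#' @param logits numeric matrix `n x L`
#' @param labels binary matrix `n x L`
#' @return scalar loss (>= 0)
#' @export
bce_loss <- function(logits, labels) {
  logits <- as.matrix(logits); labels <- as.matrix(labels)
  if (!all(dim(logits) == dim(labels))) {
    stop("logits and labels must be conformable", call. = FALSE)
  }
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# d loss / d logits for the mean-reduced BCE above, scaled so accumulating
# micro-batch gradients reproduces the full-batch gradient.
bce_grad <- function(logits, labels, denom) {
  (1 / (1 + exp(-logits)) - labels) / denom
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, spec) {
  state$t <- state$t + 1L
  bc1 <- 1 - spec$beta1^state$t
  bc2 <- 1 - spec$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- spec$beta1 * state$m[[nm]] + (1 - spec$beta1) * g
    state$v[[nm]] <- spec$beta2 * state$v[[nm]] + (1 - spec$beta2) * g * g
    params[[nm]] <- params[[nm]] - spec$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + spec$eps)
  }
  list(params = params, state = state)
}

#' Train a SqueezeViT model
#'
#' Runs the standard recipe: shuffled mini-batches, sigmoid BCE on logits,
#' Adam updates. Seed-reproducible on one machine. If evaluation data is
#' supplied, average AUROC and macro F1 on it are recorded every epoch.
#'
#' @param model a `squeezevit_model`
#' @param images training images, array `(H, W, n)`
#' @param labels binary label matrix `n x L`
#' @param spec a [train_spec()]
#' @param eval_images,eval_labels optional held-out data evaluated per epoch
#' @param checkpoint_path optional path; the final model is saved there
#' @param verbose print a line per epoch
#' @return list with `model` (trained) and `history` (tibble: epoch, loss,
#'   and when evaluation data is given, auroc + f1)
#' @export
train <- function(model, images, labels, spec = train_spec(),
                  eval_images = NULL, eval_labels = NULL,
                  checkpoint_path = NULL, verbose = FALSE) {
  labels <- as.matrix(labels)
  n <- dim(images)[3L]
  if (n == 0L || nrow(labels) == 0L) {
    stop("refusing to train on an empty dataset", call. = FALSE)
  }
  if (nrow(labels) != n) {
    stop("label rows (", nrow(labels), ") != image count (", n, ")",
         call. = FALSE)
  }
  if (ncol(labels) != model$config$num_labels) {
    stop("label columns (", ncol(labels), ") != model head width (",
         model$config$num_labels, ")", call. = FALSE)
  }
  if (all(labels == labels[1L])) {
    stop("refusing to train: labels are constant across the dataset, ",
         "nothing to learn", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  params <- model$params
  state <- adam_init(params)
  L <- ncol(labels)
  hist_rows <- vector("list", spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, n)]
      nb <- length(idx)
      acc <- NULL
      batch_loss <- 0
      for (ms in seq(1L, nb, by = spec$micro_batch)) {
        mi <- idx[ms:min(ms + spec$micro_batch - 1L, nb)]
        xb <- images[, , mi, drop = FALSE]
        yb <- labels[mi, , drop = FALSE]
        model$params <- params
        fw <- squeezevit_fwd(model, xb, cache = TRUE)
        batch_loss <- batch_loss +
          bce_loss(fw$out, yb) * length(mi) / nb
        dlog <- bce_grad(fw$out, yb, denom = nb * L)
        g <- squeezevit_bwd(model, dlog, fw$cache)
        acc <- if (is.null(acc)) g else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
          acc
        }
      }
      upd <- adam_step(params, acc, state, spec)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, batch_loss)
    }
    row <- list(epoch = ep, loss = mean(losses))
    if (!is.null(eval_images)) {
      model$params <- params
      probs <- predict(model, eval_images, type = "prob")
      ev <- classwise_auroc(probs, eval_labels)
      row$auroc <- ev$average
      row$f1 <- f1_average(probs, eval_labels)
    }
    hist_rows[[ep]] <- tibble::as_tibble(row)
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f%s\n", ep, row$loss,
                  if (!is.null(row$auroc))
                    sprintf("  auroc %.4f  f1 %.4f", row$auroc, row$f1)
                  else ""))
    }
  }
  model$params <- params
  history <- do.call(rbind, hist_rows)
  class(history) <- c("squeezevit_history", class(history))
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, history = history)
}

#' Evaluate a model on labelled images
#'
#' @param model a trained `squeezevit_model`
#' @param images array `(H, W, n)`
#' @param labels binary matrix `n x L`
#' @param ci compute a bootstrap 95% CI per class (slower)
#' @param ci_B bootstrap replicates for the CIs
#' @param seed seed for the CI bootstrap
#' @return a `squeezevit_eval` report (per-class AUROC, average AUROC,
#'   macro F1 at 0.5; CI columns when `ci = TRUE`)
#' @export
evaluate <- function(model, images, labels, ci = FALSE, ci_B = 2000L,
                     seed = 1L) {
  probs <- predict(model, images, type = "prob")
  report <- classwise_auroc(probs, as.matrix(labels))
  report$f1 <- f1_average(probs, as.matrix(labels))
  if (ci) {
    lo <- hi <- rep(NA_real_, ncol(probs))
    for (k in seq_len(ncol(probs))) {
      if (!is.na(report$per_class$auroc[k])) {
        iv <- bootstrap_ci(probs[, k], labels[, k], B = ci_B,
                           seed = seed + k)
        lo[k] <- iv[1L]; hi[k] <- iv[2L]
      }
    }
    report$per_class$ci_low <- lo
    report$per_class$ci_high <- hi
  }
  report
}

#' Max-over-classes abnormality score from a multi-label model
#'
#' Utility scoring for the binary normal/abnormal task using an already
#' trained multi-label model: the abnormality score of an image is the
#' maximum per-class sigmoid probability. Note the reference protocol
#' retrains a dedicated single-logit model for the binary task; this
#' shortcut is provided for exploration only.
#'
#' @param model a multi-label `squeezevit_model`
#' @param images array `(H, W, n)`
#' @return numeric abnormality score per image
#' @export
abnormality_score <- function(model, images) {
  apply(predict(model, images, type = "prob"), 1L, max)
}
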