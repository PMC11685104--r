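# Losses, optimizer and the seeded training loop.
#
# The sequence loss is the cross-entropy between each refinement iteration's
# predicted distribution and the native sequence, summed over iterations and
# positions; the secondary-structure loss is the cross-entropy of the
# auxiliary head against the ground-truth dot-bracket; the total objective is
# their (unit-weight by default) linear combination.

seq_to_idx <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], NUCLEOTIDES)
  idx  # N and other policy tokens come back NA and are excluded from losses
}

ss_to_idx <- function(ss) {
  symbols <- if (inherits(ss, "rna_ss")) ss$symbols else ss
  match(strsplit(symbols, "")[[1]], SS_SYMBOLS)
}

#' Iterative sequence cross-entropy loss
#'
#' `L_sup = - sum_k sum_i log p^k[i, target_i]` over all K refinement
#' iterations (sum reduction; `"mean"` divides by the number of summed
#' terms). Probabilities are clamped at `1e-9` before the log. Positions
#' whose target is NA (padding, or the policy token N) are excluded.
#'
#' @param per_iteration List of N x 4 distributions, one per iteration.
#' @param target Target sequence string over A/U/C/G (or integer indices).
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return Nonnegative scalar.
#' @export
sequence_loss <- function(per_iteration, target, reduction = "sum") {
  if (length(per_iteration) == 0L) stop("need at least one iteration")
  idx <- if (is.character(target)) seq_to_idx(target) else as.integer(target)
  total <- 0; terms <- 0L
  for (P in per_iteration) {
    if (nrow(P) != length(idx)) stop("distribution/target length mismatch")
    valid <- which(!is.na(idx))
    total <- total - sum(log(pmax(P[cbind(valid, idx[valid])], 1e-9)))
    terms <- terms + length(valid)
  }
  if (identical(reduction, "mean")) total / max(terms, 1L) else total
}

#' Secondary-structure cross-entropy loss
#'
#' `L_sec = - sum_i log a[i, truth_i]` with one-hot ground truth over the
#' dot-bracket alphabet; same clamp and reduction conventions as
#' [sequence_loss()].
#'
#' @param pred N x 3 distribution over (".", "(", ")").
#' @param truth An `rna_ss`, dot-bracket string, or integer indices.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return Nonnegative scalar.
#' @export
secondary_loss <- function(pred, truth, reduction = "sum") {
  idx <- if (is.character(truth) || inherits(truth, "rna_ss")) {
    ss_to_idx(truth)
  } else {
    as.integer(truth)
  }
  if (nrow(pred) != length(idx)) stop("prediction/truth length mismatch")
  valid <- which(!is.na(idx))
  total <- -sum(log(pmax(pred[cbind(valid, idx[valid])], 1e-9)))
  if (identical(reduction, "mean")) total / max(length(valid), 1L) else total
}

#' Total training loss
#'
#' Linear combination `w_sup * L_sup + w_sec * L_sec`, unit weights by
#' default.
#'
#' @param l_sup,l_sec Nonnegative loss components.
#' @param weights Length-2 vector `c(w_sup, w_sec)`.
#' @return Scalar.
#' @export
total_loss <- function(l_sup, l_sec, weights = c(1, 1)) {
  weights[1L] * l_sup + weights[2L] * l_sec
}

#' Training configuration
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Structures per optimizer step (default 1).
#' @param learning_rate Adam learning rate (> 0, default 1e-3).
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Integer seed covering shuffling and dropout.
#' @param loss_reduction `"sum"` (the form of the written objective) or
#'   `"mean"` (per-term average, sometimes steadier for optimization).
#' @param loss_weights Length-2 vector `c(w_sup, w_sec)`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 1L,
                         learning_rate = 1e-3, optimizer = "adam",
                         seed = 1L, loss_reduction = "sum",
                         loss_weights = c(1, 1)) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            identical(optimizer, "adam"),
            loss_reduction %in% c("sum", "mean"), length(loss_weights) == 2L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), loss_reduction = loss_reduction,
                 loss_weights = loss_weights),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

make_drop_masks <- function(cfg, n) {
  if (cfg$dropout <= 0) return(NULL)
  keep <- 1 - cfg$dropout
  lapply(seq_len(cfg$refinement_iterations), function(k) {
    lapply(seq_len(cfg$encoder_layers), function(l) {
      matrix(stats::rbinom(n * cfg$hidden_dim, 1L, keep) / keep,
             n, cfg$hidden_dim)
    })
  })
}

prepare_item <- function(item, graph_config) {
  structure <- item$structure
  graph <- build_graph(structure, graph_config)
  sequence <- item$sequence %||% structure$native_sequence
  if (is.null(sequence)) stop("item has no sequence")
  if (nchar(sequence) != graph$n) stop("sequence/structure length mismatch")
  ss <- item$secondary
  ss_idx <- if (is.null(ss)) NULL else ss_to_idx(ss)
  if (!is.null(ss_idx) && length(ss_idx) != graph$n) {
    stop("secondary structure/structure length mismatch")
  }
  list(graph = graph, target_idx = seq_to_idx(sequence), ss_idx = ss_idx,
       n = graph$n)
}

#' Train a design model
#'
#' Seeded training with Adam on the combined iterative-sequence and
#' secondary-structure cross-entropy objective. Items are length-bucketed:
#' batches are formed over structures sorted by length and padded to the
#' batch maximum, with padded positions excluded from message passing and
#' from every loss. Items that cannot be featurized are skipped with a
#' warning. The per-epoch record reports the loss components (in the
#' configured reduction) and the training-set sequence recovery of the final
#' iteration's argmax.
#'
#' @param dataset List of items `list(structure, sequence, secondary)`;
#'   `sequence` defaults to the structure's native sequence and `secondary`
#'   (dot-bracket truth for the auxiliary head) may be NULL.
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param graph_config A [graph_config()].
#' @param validation Optional list of items; when given, the returned model
#'   is the checkpoint with the best validation recovery.
#' @return Object of class `rna_design_fit`: list with `model`, `record`
#'   (data.frame: epoch, loss, l_sup, l_sec, recovery_pct, and
#'   val_recovery_pct when validation is given) and `best_epoch`.
#' @export
train <- function(dataset, model_config = rnadesign::model_config(),
                  train_config = rnadesign::train_config(),
                  graph_config = rnadesign::graph_config(),
                  validation = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  prepped <- list()
  for (i in seq_along(dataset)) {
    pr <- tryCatch(prepare_item(dataset[[i]], graph_config),
                   error = function(e) {
                     warning(sprintf("skipping item %d: %s", i,
                                     conditionMessage(e)))
                     NULL
                   })
    if (!is.null(pr)) prepped[[length(prepped) + 1L]] <- pr
  }
  if (length(prepped) == 0L) stop("no featurizable items in dataset")
  val_prepped <- if (!is.null(validation)) {
    lapply(validation, prepare_item, graph_config = graph_config)
  }

  model <- init_model(model_config, graph_config)
  cfg <- model$config
  state <- adam_init(model$params)
  lens <- vapply(prepped, `[[`, 0L, "n")
  order_len <- order(lens)
  batches <- split(order_len,
                   ceiling(seq_along(order_len) / train_config$batch_size))
  weights <- train_config$loss_weights
  mean_red <- identical(train_config$loss_reduction, "mean")

  record <- vector("list", train_config$epochs)
  best <- list(score = -Inf, params = model$params, epoch = NA_integer_)
  with_seed(train_config$seed, {
    for (epoch in seq_len(train_config$epochs)) {
      batch_order <- sample(length(batches))
      e_sup <- 0; e_sec <- 0; n_correct <- 0L; n_pos <- 0L; n_terms <- 0L
      for (bi in batch_order) {
        idxs <- batches[[bi]]
        max_n <- max(vapply(prepped[idxs], `[[`, 0L, "n"))
        gsum <- zero_like(model$params)
        for (ii in idxs) {
          it <- prepped[[ii]]
          g <- pad_graph(it$graph, max_n)
          pad <- max_n - it$n
          tgt <- c(it$target_idx, rep(NA_integer_, pad))
          ssx <- if (is.null(it$ss_idx)) NULL else
            c(it$ss_idx, rep(NA_integer_, pad))
          dm <- make_drop_masks(cfg, max_n)
          res <- model_grad(model, g, tgt, ssx, weights, dm)
          n_valid <- sum(!is.na(tgt))
          scale <- if (mean_red) {
            1 / max(cfg$refinement_iterations * n_valid, 1L)
          } else 1
          e_sup <- e_sup + res$l_sup * scale
          e_sec <- e_sec + res$l_sec * scale
          n_terms <- n_terms + 1L
          for (nm in names(gsum)) {
            gsum[[nm]] <- gsum[[nm]] + res$grads[[nm]] * scale
          }
          pred <- apply(res$P_final, 1L, which.max)
          real <- which(!is.na(tgt))
          n_correct <- n_correct + sum(pred[real] == tgt[real])
          n_pos <- n_pos + length(real)
        }
        st <- adam_step(state, model$params, gsum,
                        train_config$learning_rate)
        state <- st$state
        model$params <- st$params
      }
      rec_pct <- 100 * n_correct / max(n_pos, 1L)
      row <- data.frame(epoch = epoch, loss = e_sup * weights[1L] +
                          e_sec * weights[2L],
                        l_sup = e_sup, l_sec = e_sec,
                        recovery_pct = rec_pct)
      if (!is.null(val_prepped)) {
        vr <- eval_recovery(model, val_prepped)
        row$val_recovery_pct <- vr
        if (vr > best$score) {
          best <- list(score = vr, params = model$params, epoch = epoch)
        }
      }
      record[[epoch]] <- row
    }
  })
  record <- do.call(rbind, record)
  if (!is.null(val_prepped)) model$params <- best$params
  structure(list(model = model, record = record,
                 best_epoch = if (is.null(val_prepped)) NA_integer_ else
                   best$epoch),
            class = "rna_design_fit")
}

# Greedy recovery of a model on prepared items (no dropout).
eval_recovery <- function(model, prepped) {
  correct <- 0L; total <- 0L
  for (it in prepped) {
    prior <- matrix(0.25, it$n, 4L)
    H <- NULL
    for (k in seq_len(model$config$refinement_iterations)) {
      H <- encode(model, it$graph, prior)
      prior <- decode_sequence(model, H, prior)
    }
    pred <- apply(prior, 1L, which.max)
    real <- which(!is.na(it$target_idx))
    correct <- correct + sum(pred[real] == it$target_idx[real])
    total <- total + length(real)
  }
  100 * correct / max(total, 1L)
}

#' @export
print.rna_design_fit <- function(x, ...) {
  last <- x$record[nrow(x$record), ]
  cat(sprintf(paste0("RNA design fit: %d epochs, final loss %.3f, ",
                     "final training recovery %.1f%%\n"),
              nrow(x$record), last$loss, last$recovery_pct))
  invisible(x)
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single file holding the parameter set, the model and
#' graph configurations, and the feature-dictionary hash; loading refuses a
#' checkpoint whose hash does not match the featurization it declares.
#'
#' @param model An `rna_design_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rna_design_model"))
  saveRDS(list(params = model$params, config = model$config,
               graph_config = model$graph_config,
               feature_hash = model$feature_hash,
               format_version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  expected <- feature_dictionary_hash(raw$graph_config)
  if (!identical(raw$feature_hash, expected)) {
    stop("checkpoint feature-dictionary hash mismatch: refusing to load")
  }
  structure(list(params = raw$params, config = raw$config,
                 graph_config = raw$graph_config,
                 feature_hash = raw$feature_hash),
            class = "rna_design_model")
}
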