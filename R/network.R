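# The learnable structure->sequence mapping: a graph message-passing encoder
# over the attributed k-NN graph, a linear sequence decoder conditioned on the
# previous iteration's nucleotide distribution, a self-attention secondary
# structure head, and the iterative refinement loop that starts from the
# uniform distribution over A/U/C/G.
#
# No autodiff framework is used: forward passes cache the intermediates that
# the analytic reverse-mode gradients in gradients.R consume.

#' Model configuration
#'
#' @param encoder_layers Number of message-passing layers (>= 1, default 3).
#' @param hidden_dim Latent width (default 128).
#' @param ss_head_heads Attention heads in the secondary-structure head
#'   (must divide `hidden_dim`; default 4).
#' @param refinement_iterations Number of refinement iterations K (>= 1,
#'   default 3).
#' @param dropout Dropout fraction applied to node states between encoder
#'   layers during training (default 0.1).
#' @param prior_embed_dim Width of the embedded previous-iteration
#'   distribution fed to the decoder (default 16).
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(encoder_layers = 3L, hidden_dim = 128L,
                         ss_head_heads = 4L, refinement_iterations = 3L,
                         dropout = 0.1, prior_embed_dim = 16L, seed = 1L) {
  stopifnot(encoder_layers >= 1L, hidden_dim > 0L,
            refinement_iterations >= 1L, ss_head_heads >= 1L,
            hidden_dim %% ss_head_heads == 0L,
            dropout >= 0, dropout < 1)
  structure(list(encoder_layers = as.integer(encoder_layers),
                 hidden_dim = as.integer(hidden_dim),
                 ss_head_heads = as.integer(ss_head_heads),
                 refinement_iterations = as.integer(refinement_iterations),
                 dropout = dropout,
                 prior_embed_dim = as.integer(prior_embed_dim),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize a design model
#'
#' Seeded Glorot-uniform initialization of all weights (biases and layer-norm
#' shifts zero, layer-norm gains one).
#'
#' @param config A [model_config()].
#' @param graph_config A [graph_config()] fixing the featurization the model
#'   expects.
#' @return Object of class `rna_design_model`: list with `params` (flat named
#'   list of arrays), `config`, `graph_config` and `feature_hash`.
#' @export
init_model <- function(config = model_config(),
                       graph_config = rnadesign::graph_config()) {
  dict <- feature_dictionary(graph_config)
  d <- config$hidden_dim
  dp <- config$prior_embed_dim
  f_n <- dict$f_n; f_m <- dict$f_m
  params <- with_seed(config$seed, {
    p <- list(
      W_in = glorot(f_n, d), b_in = numeric(d), W_prior = glorot(4L, d))
    for (l in seq_len(config$encoder_layers)) {
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "W1")]] <- glorot(2L * d + f_m, d)
      p[[paste0(pre, "b1")]] <- numeric(d)
      p[[paste0(pre, "W2")]] <- glorot(d, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "w_att")]] <- drop(glorot(d, 1L))
      p[[paste0(pre, "b_att")]] <- 0
      p[[paste0(pre, "ln_g")]] <- rep(1, d)
      p[[paste0(pre, "ln_b")]] <- numeric(d)
    }
    p$dec.W_pemb <- glorot(4L, dp)
    p$dec.b_pemb <- numeric(dp)
    p$dec.W_dec <- glorot(d + dp, 4L)
    p$dec.b_dec <- numeric(4L)
    p$ss.Wq <- glorot(d, d); p$ss.Wk <- glorot(d, d); p$ss.Wv <- glorot(d, d)
    p$ss.Wo <- glorot(d, d); p$ss.bo <- numeric(d)
    p$ss.ln_g <- rep(1, d); p$ss.ln_b <- numeric(d)
    p$ss.W_ss <- glorot(d, 3L); p$ss.b_ss <- numeric(3L)
    p
  })
  structure(list(params = params, config = config,
                 graph_config = graph_config,
                 feature_hash = feature_dictionary_hash(graph_config)),
            class = "rna_design_model")
}

#' @export
print.rna_design_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("RNA design model: %d encoder layer(s), hidden_dim %d, ",
                     "%d refinement iteration(s), %d parameters\n"),
              x$config$encoder_layers, x$config$hidden_dim,
              x$config$refinement_iterations, npar))
  invisible(x)
}

ln_eps <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

# Flat edge-order helpers: edges are laid out node-major, i.e. node 1's K
# neighbour slots first.
edge_layout <- function(graph) {
  n <- graph$n; K <- graph$config$K
  list(i_idx = rep(seq_len(n), each = K),
       j_idx = as.vector(t(graph$index)),
       mask_flat = as.vector(t(graph$mask)),
       E2 = matrix(aperm(graph$edge, c(2L, 1L, 3L)), n * K,
                   dim(graph$edge)[3]))
}

#' Encode a structure graph into latent node states
#'
#' Runs the stack of message-passing layers: per edge an MLP message from
#' (sender state, receiver state, edge features), attention-style gating over
#' each node's neighbours, residual connection and layer normalization.
#' Padded positions (FALSE in `graph$node_mask`) produce zero vectors.
#' Deterministic given parameters and input (dropout masks, if any, are
#' supplied explicitly by the training loop).
#'
#' @param model An `rna_design_model`.
#' @param graph An `rna_graph` built with the model's `graph_config`.
#' @param prior N x 4 nucleotide distribution injected into the node states
#'   (default uniform).
#' @param drop_masks Optional list of per-layer dropout mask matrices.
#' @param want_cache Keep intermediates for the backward pass.
#' @return N x hidden_dim latent matrix (with attribute `"cache"` when
#'   requested).
#' @export
encode <- function(model, graph, prior = NULL, drop_masks = NULL,
                   want_cache = FALSE) {
  stopifnot(inherits(model, "rna_design_model"), inherits(graph, "rna_graph"))
  p <- model$params
  cfg <- model$config
  n <- graph$n; K <- graph$config$K; d <- cfg$hidden_dim
  if (ncol(graph$node) != nrow(p$W_in)) {
    stop("graph/node feature width does not match model configuration")
  }
  prior <- prior %||% matrix(0.25, n, 4L)
  stopifnot(nrow(prior) == n, ncol(prior) == 4L)
  lay <- edge_layout(graph)
  nm <- graph$node_mask

  H <- graph$node %*% p$W_in + rep(p$b_in, each = n) + prior %*% p$W_prior
  H[!nm, ] <- 0
  cache <- list(H0 = H, layers = vector("list", cfg$encoder_layers),
                lay = lay, prior = prior)
  for (l in seq_len(cfg$encoder_layers)) {
    pre <- sprintf("L%d.", l)
    H_in <- H
    Z <- cbind(H[lay$i_idx, , drop = FALSE], H[lay$j_idx, , drop = FALSE],
               lay$E2)
    A1 <- Z %*% p[[paste0(pre, "W1")]] + rep(p[[paste0(pre, "b1")]],
                                             each = nrow(Z))
    pos <- A1 > 0
    R1 <- A1 * pos
    M <- R1 %*% p[[paste0(pre, "W2")]] + rep(p[[paste0(pre, "b2")]],
                                             each = nrow(Z))
    s <- drop(R1 %*% p[[paste0(pre, "w_att")]]) + p[[paste0(pre, "b_att")]]
    S <- matrix(s, n, K, byrow = TRUE)
    W <- softmax_rows(S, graph$mask)
    wflat <- as.vector(t(W))
    AGG <- rowsum(wflat * M, lay$i_idx)
    rownames(AGG) <- NULL
    pre_ln <- H + AGG
    pre_ln[!nm, ] <- 0
    ln <- layernorm_forward(pre_ln, p[[paste0(pre, "ln_g")]],
                            p[[paste0(pre, "ln_b")]])
    H <- ln$y
    H[!nm, ] <- 0
    dmask <- if (!is.null(drop_masks)) drop_masks[[l]] else NULL
    if (!is.null(dmask)) H <- H * dmask
    if (want_cache) {
      cache$layers[[l]] <- list(H_in = H_in, pos = pos, R1 = R1, M = M,
                                W = W, xhat = ln$xhat, inv = ln$inv,
                                dmask = dmask)
    }
  }
  if (want_cache) attr(H, "cache") <- cache
  H
}

#' Decode a nucleotide distribution from latent states
#'
#' A single affine map from the concatenation of each position's latent
#' vector and its linearly embedded previous-iteration distribution to four
#' logits, softmax-normalized. Strictly per-position: one position's output
#' depends only on its own latent and prior.
#'
#' @param model An `rna_design_model`.
#' @param latent N x hidden_dim matrix from [encode()].
#' @param prior N x 4 previous-iteration distribution (default uniform).
#' @param want_cache Keep intermediates for the backward pass.
#' @return N x 4 probability matrix over (A, U, C, G), rows summing to 1.
#' @export
decode_sequence <- function(model, latent, prior = NULL, want_cache = FALSE) {
  p <- model$params
  n <- nrow(latent)
  prior <- prior %||% matrix(0.25, n, 4L)
  if (nrow(prior) != n) stop("latent and prior lengths differ")
  Pe <- prior %*% p$dec.W_pemb + rep(p$dec.b_pemb, each = n)
  Zd <- cbind(latent, Pe)
  logits <- Zd %*% p$dec.W_dec + rep(p$dec.b_dec, each = n)
  P <- softmax_rows(logits)
  colnames(P) <- NUCLEOTIDES
  if (want_cache) attr(P, "cache") <- list(Zd = Zd, P = P)
  P
}

#' Predict the secondary-structure distribution
#'
#' One multi-head self-attention layer over positions (padding masked out of
#' the attention), residual + layer normalization, then a per-position
#' 3-way classification over the dot-bracket alphabet.
#'
#' @param model An `rna_design_model`.
#' @param latent N x hidden_dim matrix from [encode()].
#' @param node_mask Logical length-N vector; FALSE positions are padding.
#' @param want_cache Keep intermediates for the backward pass.
#' @return N x 3 probability matrix over (".", "(", ")").
#' @export
predict_secondary <- function(model, latent, node_mask = NULL,
                              want_cache = FALSE) {
  p <- model$params
  n <- nrow(latent)
  if (n == 0L) stop("empty latent")
  node_mask <- node_mask %||% rep(TRUE, n)
  d <- ncol(latent)
  heads <- model$config$ss_head_heads
  dh <- d %/% heads
  Q <- latent %*% p$ss.Wq
  Km <- latent %*% p$ss.Wk
  V <- latent %*% p$ss.Wv
  Cc <- matrix(0, n, d)
  A_list <- vector("list", heads)
  col_mask <- matrix(rep(node_mask, each = n), n, n)
  for (h in seq_len(heads)) {
    ch <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, ch, drop = FALSE], Km[, ch, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(S, col_mask)
    Cc[, ch] <- A %*% V[, ch, drop = FALSE]
    A_list[[h]] <- A
  }
  O <- Cc %*% p$ss.Wo + rep(p$ss.bo, each = n)
  pre2 <- latent + O
  pre2[!node_mask, ] <- 0
  ln <- layernorm_forward(pre2, p$ss.ln_g, p$ss.ln_b)
  S2 <- ln$y
  S2[!node_mask, ] <- 0
  logits <- S2 %*% p$ss.W_ss + rep(p$ss.b_ss, each = n)
  P3 <- softmax_rows(logits)
  colnames(P3) <- SS_SYMBOLS
  if (want_cache) {
    attr(P3, "cache") <- list(Q = Q, Km = Km, V = V, Cc = Cc, A = A_list,
                              xhat = ln$xhat, inv = ln$inv, S2 = S2, P3 = P3,
                              node_mask = node_mask, dh = dh, heads = heads)
  }
  P3
}

# Argmax sequence with ties resolved alphabetically (A < C < G < U).
argmax_sequence <- function(P) {
  alpha_rank <- c(A = 1L, U = 4L, C = 2L, G = 3L)[colnames(P)]
  letters <- apply(P, 1L, function(row) {
    colnames(P)[order(-row, alpha_rank)[1L]]
  })
  paste(letters, collapse = "")
}

#' Repair an unbalanced dot-bracket string
#'
#' Converts unmatched brackets (a ')' with no earlier open '(' and leftover
#' '(') to '.' so the result is always balanced.
#'
#' @param symbols Dot-bracket string.
#' @return Balanced dot-bracket string.
#' @export
repair_dot_bracket <- function(symbols) {
  chars <- strsplit(symbols, "")[[1]]
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) chars[i] <- "." else
        stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) chars[stack] <- "."
  paste(chars, collapse = "")
}

#' Design a sequence for a backbone structure
#'
#' The iterative refinement loop: the per-position nucleotide distribution
#' starts uniform (0.25 each), and each of the K refinement iterations
#' re-encodes the graph with the previous distribution injected into the
#' node states, then decodes a new distribution. The designed sequence is
#' the argmax of the final distribution (ties alphabetical, A < C < G < U);
#' a sampling mode is available. The secondary-structure head reads the
#' final latent; its argmax dot-bracket is repaired to balanced form.
#'
#' @param structure An `rna_backbone` (N >= 3) or a prebuilt `rna_graph`.
#' @param model An `rna_design_model`.
#' @param iterations Override the configured number of refinement
#'   iterations.
#' @param mode `"argmax"` (default) or `"sample"`.
#' @param seed Seed used in sampling mode.
#' @return Object of class `design_result`: list with `sequence`,
#'   `per_iteration` (list of N x 4 distributions, length K),
#'   `secondary` (N x 3), `predicted_dotbracket` (`rna_ss`, repaired),
#'   `raw_dotbracket` (unrepaired argmax string) and `n`.
#' @export
design <- function(structure, model, iterations = NULL, mode = "argmax",
                   seed = 1L) {
  stopifnot(inherits(model, "rna_design_model"))
  graph <- if (inherits(structure, "rna_graph")) structure else
    build_graph(structure, model$graph_config)
  k_iter <- as.integer(iterations %||% model$config$refinement_iterations)
  stopifnot(k_iter >= 1L)
  n <- graph$n
  prior <- matrix(0.25, n, 4L)
  per_iteration <- vector("list", k_iter)
  H <- NULL
  for (k in seq_len(k_iter)) {
    H <- encode(model, graph, prior)
    Pk <- decode_sequence(model, H, prior)
    per_iteration[[k]] <- Pk
    prior <- Pk
  }
  P_final <- per_iteration[[k_iter]]
  sequence <- if (identical(mode, "sample")) {
    with_seed(seed, paste(apply(P_final, 1L, function(row) {
      sample(colnames(P_final), 1L, prob = row)
    }), collapse = ""))
  } else {
    argmax_sequence(P_final)
  }
  P3 <- predict_secondary(model, H, graph$node_mask)
  raw <- paste(SS_SYMBOLS[apply(P3, 1L, which.max)], collapse = "")
  structure(list(sequence = sequence, per_iteration = per_iteration,
                 secondary = P3,
                 predicted_dotbracket = new_rna_ss(repair_dot_bracket(raw)),
                 raw_dotbracket = raw, n = n),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Design result (%d nt, %d refinement iterations)\n", x$n,
              length(x$per_iteration)))
  cat("sequence:   ", x$sequence, "\n")
  cat("dot-bracket:", x$predicted_dotbracket$symbols, "\n")
  invisible(x)
}
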