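test_that("encode produces finite latents of the configured shape, deterministically", {
  st <- random_backbone(12, seed = 1)
  m <- tiny_model()
  g <- build_graph(st, m$graph_config)
  H1 <- encode(m, g)
  H2 <- encode(m, g)
  expect_equal(dim(H1), c(12L, 16L))
  expect_true(all(is.finite(H1)))
  expect_identical(H1, H2)
  # same seed, fresh model: identical parameters and output
  m2 <- tiny_model()
  expect_identical(m$params, m2$params)
  expect_identical(encode(m2, g), H1)
  # different seed: different parameters
  m3 <- tiny_model(seed = 2)
  expect_false(identical(m3$params$W_in, m$params$W_in))
})

test_that("encode zeroes padded positions and rejects mismatched features", {
  st <- random_backbone(10, seed = 2)
  m <- tiny_model()
  g <- pad_graph(build_graph(st, m$graph_config), 20)
  H <- encode(m, g)
  expect_true(all(H[11:20, ] == 0))
  expect_false(any(apply(H[1:10, ], 1, function(r) all(r == 0))))
  g_bad <- build_graph(st, graph_config(K = 5, rbf_count = 8))
  expect_error(encode(m, g_bad), "does not match")
})

test_that("decode_sequence is a row-normalized per-position map", {
  st <- random_backbone(9, seed = 3)
  m <- tiny_model()
  g <- build_graph(st, m$graph_config)
  H <- encode(m, g)
  P <- decode_sequence(m, H)
  expect_equal(dim(P), c(9L, 4L))
  expect_equal(rowSums(P), rep(1, 9), tolerance = 1e-6)
  expect_equal(colnames(P), c("A", "U", "C", "G"))
  # zeroed output weights give exactly uniform rows
  m0 <- m
  m0$params$dec.W_dec[] <- 0
  m0$params$dec.b_dec[] <- 0
  expect_equal(decode_sequence(m0, H),
               matrix(0.25, 9, 4, dimnames = list(NULL, c("A", "U", "C", "G"))))
  # per-position locality: perturbing one latent row leaves others unchanged
  H2 <- H
  H2[4, ] <- H2[4, ] + 1
  P2 <- decode_sequence(m, H2)
  expect_identical(P2[-4, ], P[-4, ])
  expect_false(identical(P2[4, ], P[4, ]))
  expect_error(decode_sequence(m, H, prior = matrix(0.25, 5, 4)),
               "lengths differ")
})

test_that("predict_secondary normalizes, attends across positions, and masks padding", {
  st <- random_backbone(14, seed = 4)
  m <- tiny_model()
  g <- build_graph(st, m$graph_config)
  H <- encode(m, g)
  P3 <- predict_secondary(m, H)
  expect_equal(dim(P3), c(14L, 3L))
  expect_equal(rowSums(P3), rep(1, 14), tolerance = 1e-6)
  # zeroed classifier gives uniform 1/3 rows
  m0 <- m
  m0$params$ss.W_ss[] <- 0
  m0$params$ss.b_ss[] <- 0
  expect_equal(unname(predict_secondary(m0, H)), matrix(1 / 3, 14, 3),
               tolerance = 1e-12)
  # self-attention is permutation-equivariant: swapping two latent rows
  # swaps their outputs and leaves the rest unchanged ...
  H2 <- H
  H2[c(5, 9), ] <- H2[c(9, 5), ]
  P3b <- predict_secondary(m, H2)
  expect_equal(P3b[5, ], P3[9, ], tolerance = 1e-9)
  expect_equal(P3b[-c(5, 9), ], P3[-c(5, 9), ], tolerance = 1e-9)
  # ... while perturbing one position's latent changes other positions
  # (the head genuinely attends across the chain)
  H3 <- H
  H3[5, ] <- H3[5, ] + 1
  P3c <- predict_secondary(m, H3)
  expect_gt(max(abs(P3c[-5, ] - P3[-5, ])), 1e-9)
  expect_error(predict_secondary(m, H[0, , drop = FALSE]), "empty")
})

test_that("design honors the refinement iteration contract", {
  st <- random_backbone(10, seed = 5)
  # default configuration: exactly 3 refinement iterations
  m_default <- init_model(model_config(hidden_dim = 16, ss_head_heads = 2,
                                       encoder_layers = 1, seed = 1),
                          tiny_graph_config())
  res <- design(st, m_default)
  expect_length(res$per_iteration, 3L)
  m <- tiny_model()
  for (k in c(1L, 5L)) {
    res_k <- design(st, m, iterations = k)
    expect_length(res_k$per_iteration, k)
    for (P in res_k$per_iteration) {
      expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
    }
  }
  expect_equal(nchar(res$sequence), 10L)
  expect_s3_class(res$predicted_dotbracket, "rna_ss")
  expect_true(oracle_balanced(res$predicted_dotbracket$symbols))
})

test_that("an untrained model with zeroed heads designs all-A under the tie rule", {
  st <- random_backbone(8, seed = 6)
  m <- tiny_model()
  m$params$dec.W_dec[] <- 0
  m$params$dec.b_dec[] <- 0
  res <- design(st, m)
  expect_equal(res$sequence, strrep("A", 8))
  for (P in res$per_iteration) {
    expect_equal(unname(P), matrix(0.25, 8, 4))
  }
})

test_that("design is invariant to rigid motion of the input end to end", {
  m <- tiny_model()
  for (seed in 1:3) {
    st <- random_backbone(15, seed = seed)
    res <- design(st, m)
    res2 <- design(apply_rigid(st, random_rigid_transform()), m)
    for (k in seq_along(res$per_iteration)) {
      expect_lt(max(abs(res$per_iteration[[k]] - res2$per_iteration[[k]])),
                1e-5)
    }
    expect_equal(res$sequence, res2$sequence)
    expect_lt(max(abs(res$secondary - res2$secondary)), 1e-5)
  }
})

test_that("sampling mode is seeded and draws from the final distribution", {
  st <- random_backbone(12, seed = 8)
  m <- tiny_model()
  s1 <- design(st, m, mode = "sample", seed = 3)$sequence
  s2 <- design(st, m, mode = "sample", seed = 3)$sequence
  expect_identical(s1, s2)
  expect_equal(nchar(s1), 12L)
})

test_that("repair_dot_bracket converts unmatched brackets to dots", {
  expect_equal(repair_dot_bracket("(((...)))"), "(((...)))")
  expect_equal(repair_dot_bracket("((...)"), ".(...)")
  expect_equal(repair_dot_bracket(")(..))"), ".(..).")
  expect_equal(repair_dot_bracket(")))"), "...")
  set.seed(77)
  for (rep in 1:30) {
    s <- paste(sample(c(".", "(", ")"), sample(3:20, 1), TRUE), collapse = "")
    expect_true(oracle_balanced(repair_dot_bracket(s)))
  }
})

test_that("analytic gradients match central finite differences", {
  gc_ <- graph_config(K = 4, rbf_count = 4)
  mc <- model_config(encoder_layers = 2, hidden_dim = 8, ss_head_heads = 2,
                     refinement_iterations = 2, dropout = 0,
                     prior_embed_dim = 3, seed = 5)
  st <- random_backbone(7, seed = 3, sigma = 0.2)
  g <- pad_graph(build_graph(st, gc_), 9)  # padding exercised too
  m <- init_model(mc, gc_)
  tgt <- c(withr::with_seed(7, sample(1:4, 7, TRUE)), NA, NA)
  ssx <- c(rnadesign:::ss_to_idx("((...))"), NA, NA)
  res <- rnadesign:::model_grad(m, g, tgt, ssx, weights = c(1, 0.7))
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    rnadesign:::model_grad(m2, g, tgt, ssx, weights = c(1, 0.7))$loss
  }
  eps <- 1e-6
  withr::with_seed(11, {
    for (nm in names(m$params)) {
      sz <- length(m$params[[nm]])
      for (i in if (sz <= 2) seq_len(sz) else sample(sz, 2)) {
        p_hi <- m$params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
        p_lo <- m$params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
        num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
        # scaled comparison: tiny gradients drown in finite-difference noise
        expect_lt(abs(res$grads[[nm]][i] - num) /
                    max(1, abs(num), abs(res$grads[[nm]][i])), 1e-4)
      }
    }
  })
})
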