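# A tiny one-marker CNN configuration where everything is hand-checkable.
mini_cnn_config <- function() {
  model_config(conv_channels = 1L, kernel_size = 2L, pool = 2L,
               embed_dim = 1L, heads = 1L, d_head = 2L,
               n_markers = 1L, n_windows = 3L, seed = 1L)
}

test_that("the CNN encoder matches a hand computation", {
  cfg <- mini_cnn_config()
  params <- init_model(cfg)
  params$cnn_e_Wconv <- matrix(c(1, 1), 1, 2)   # moving sum
  params$cnn_e_bconv <- 0
  params$cnn_e_Wfc <- matrix(2, 1, 1)
  params$cnn_e_bfc <- 1
  x <- matrix(c(1, 2, 3), 1, 3)
  # conv -> (3, 5); lrelu id; maxpool(2) -> 5; dense: 2 * 5 + 1 = 11
  expect_equal(cnn_encode(x, params, "enhancer", cfg), 11)
  # negative convolution output goes through the leaky slope
  params$cnn_e_Wconv <- matrix(c(-1, 0), 1, 2)
  # conv -> (-1, -2); lrelu(0.2) -> (-0.2, -0.4); pool -> -0.2; 2*-0.2+1
  expect_equal(cnn_encode(x, params, "enhancer", cfg), 0.6)

  # zero input with zero biases gives a zero embedding
  cfg7 <- model_config(seed = 3L)
  p7 <- init_model(cfg7)
  p7$cnn_p_bconv[] <- 0; p7$cnn_p_bfc[] <- 0
  expect_equal(cnn_encode(matrix(0, 7, 21), p7, "promoter", cfg7),
               rep(0, 32))
  # enhancer and promoter modules are independent
  x7 <- matrix(stats::runif(7 * 21), 7, 21)
  expect_false(isTRUE(all.equal(cnn_encode(x7, p7, "enhancer", cfg7),
                                cnn_encode(x7, p7, "promoter", cfg7))))
  expect_error(cnn_encode(matrix(0, 3, 5), p7, "enhancer", cfg7), "7 x 21")
})

test_that("node input concatenates embedding, degree and type in order", {
  v <- node_input(1:8, 3, c(0, 1))
  expect_length(v, 11)
  expect_equal(v, c(1:8, 3, 0, 1))
  expect_equal(utils::tail(node_input(numeric(32), 1, c(1, 0)), 2), c(1, 0))
})

test_that("attention weights are a neighborhood softmax, checked by hand", {
  cfg <- model_config(seed = 5L)
  p <- init_model(cfg)
  W <- p$W_h1; a <- p$a_h1
  nd <- cfg$node_dim
  set.seed(5)
  xi <- stats::runif(nd); xj <- matrix(stats::runif(3 * nd), 3)
  ef <- matrix(stats::runif(3 * 2), 3)

  expect_equal(attention_scores(xi, xj[1, , drop = FALSE],
                                ef[1, , drop = FALSE], W, a), 1)
  same <- attention_scores(xi, xj[c(1, 1, 1), ], ef[c(1, 1, 1), ], W, a)
  expect_equal(same, rep(1 / 3, 3))

  al <- attention_scores(xi, xj, ef, W, a)
  expect_equal(sum(al), 1, tolerance = 1e-6)
  expect_true(all(al > 0))
  # brute-force evaluation of score -> softmax
  sc <- vapply(1:3, function(q) {
    u <- as.vector(W %*% c(xi, xj[q, ], ef[q, ]))
    sum(a * ifelse(u > 0, u, 0.2 * u))
  }, 0)
  expect_equal(al, exp(sc) / sum(exp(sc)), tolerance = 1e-10)
})

test_that("attention is dynamic: rankings depend on the query node", {
  cfg <- model_config(seed = 8L)
  p <- init_model(cfg)
  nd <- cfg$node_dim
  set.seed(8)
  found <- FALSE
  for (try in 1:20) {
    xa <- stats::runif(nd); xb <- stats::runif(nd)
    xj <- matrix(stats::runif(2 * nd), 2)
    ef <- matrix(0.5, 2, 2)
    ra <- order(attention_scores(xa, xj, ef, p$W_h1, p$a_h1))
    rb <- order(attention_scores(xb, xj, ef, p$W_h1, p$a_h1))
    if (!identical(ra, rb)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("node update and edge classifier have the contracted shapes", {
  cfg <- model_config(seed = 2L)
  p <- init_model(cfg)
  set.seed(2)
  H0 <- matrix(stats::runif(4 * cfg$node_dim), 4)
  # single directed edge: weight 1, update = ELU(W x')
  up <- gat_node_update(H0, dst = 1, src = 2,
                        EF = matrix(0.5, 1, 2), p, cfg)
  expect_equal(dim(up), c(4, 32))           # 4 heads x 8 concat
  u <- as.vector(p$W_h1 %*% c(H0[1, ], H0[2, ], 0.5, 0.5))
  expect_equal(up[1, 1:8], ifelse(u > 0, u, exp(u) - 1))
  expect_equal(up[3, ], rep(0, 32))          # isolated node: no update

  cfgm <- model_config(aggregation = "mean", seed = 2L)
  upm <- gat_node_update(H0, 1, 2, matrix(0.5, 1, 2), init_model(cfgm), cfgm)
  expect_equal(dim(upm), c(4, 8))

  # zero classifier parameters give the bias for every edge
  pz <- p; pz$ae[] <- 0; pz$Wclas[] <- 0; pz$bclas <- 0.7
  expect_equal(classify_edges(up, c(1, 1), c(2, 3), matrix(0.5, 2, 2), pz),
               c(0.7, 0.7))
})

test_that("the vectorized forward pass matches the straight-line oracle", {
  for (seed in 1:5) {
    graphs <- random_model_graphs(seed, n_components = 3)
    cfg <- model_config(seed = seed)
    params <- init_model(cfg)
    for (g in graphs) {
      b <- make_model_batch(g, cfg)
      fw <- model_forward(params, b, cfg)
      expect_equal(fw$logits, oracle_forward(params, b, cfg),
                   tolerance = 1e-10)
      expect_true(all(is.finite(fw$logits)))
      # attention rows sum to one for every head and destination
      for (h in seq_len(cfg$heads)) {
        sums <- tapply(fw$cache$heads[[h]]$alpha, b$dst, sum)
        expect_true(all(abs(sums - 1) < 1e-6))
      }
    }
  }
  # mean aggregation follows the same contract
  graphs <- random_model_graphs(11, n_components = 3)
  cfgm <- model_config(aggregation = "mean", seed = 11)
  pm <- init_model(cfgm)
  b <- make_model_batch(graphs[[1]], cfgm)
  expect_equal(model_forward(pm, b, cfgm)$logits, oracle_forward(pm, b, cfgm),
               tolerance = 1e-10)
})

test_that("analytic gradients agree with central finite differences", {
  graphs <- random_model_graphs(4, n_components = 3)
  cfg <- model_config(conv_channels = 2L, embed_dim = 4L, heads = 2L,
                      d_head = 3L, seed = 4L)
  params <- init_model(cfg)
  b <- make_model_batch(graphs[[1]], cfg)
  tr <- b$split == "train"
  loss_at <- function(p) {
    fw <- model_forward(p, b, cfg)
    combined_loss(fw$logits[tr], b$label[tr], w = 0.5)
  }
  fw <- model_forward(params, b, cfg)
  dl <- numeric(length(fw$logits))
  dl[tr] <- epigat:::combined_loss_grad(fw$logits[tr], b$label[tr], 0.5)
  grads <- epigat:::model_backward(params, b, cfg, fw$cache, dl)
  h <- 1e-5
  set.seed(4)
  for (nm in names(params)) {
    n_entries <- length(params[[nm]])
    for (idx in sample(n_entries, min(3, n_entries))) {
      pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + h
      pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(unname(grads[[nm]][idx]), num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, idx))
    }
  }
})

test_that("logits are local, deterministic and permutation-equivariant", {
  graphs <- random_model_graphs(6, n_components = 4)
  cfg <- model_config(seed = 6L)
  params <- init_model(cfg)
  g <- graphs[[1]]
  b <- make_model_batch(g, cfg)
  base <- model_forward(params, b, cfg)$logits
  expect_identical(base, model_forward(params, b, cfg)$logits)

  # permuting the edge list permutes logits identically
  set.seed(6)
  perm <- sample(nrow(g$edges))
  gp <- g; gp$edges <- g$edges[perm, ]
  bp <- make_model_batch(gp, cfg)
  expect_equal(model_forward(params, bp, cfg)$logits, base[perm],
               tolerance = 1e-12)

  # permuting node order leaves each edge's logit unchanged
  pn <- sample(nrow(g$nodes))
  gn <- g; gn$nodes <- g$nodes[pn, ]; gn$features <- g$features[g$nodes$id[pn]]
  bn <- make_model_batch(gn, cfg)
  expect_equal(model_forward(params, bn, cfg)$logits, base,
               tolerance = 1e-10)
})
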