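#' Model hyperparameter configuration
#'
#' Architecture sizes for the hybrid CNN + dynamic-graph-attention edge
#' classifier. The per-element CNN convolves each marker row of the
#' 7 x 21 feature matrix independently (kernel `(1, kernel_size)`),
#' applies a leaky rectifier, max-pools along the window axis, and maps
#' the flattened result to an `embed_dim` embedding through a dense
#' layer. Enhancers and promoters have independent CNNs. The attention
#' layer follows the GATv2 ordering (shared linear map, leaky rectifier,
#' then the attention projection), so scores depend dynamically on the
#' query node.
#'
#' @param conv_channels Number of convolution output channels.
#' @param kernel_size Convolution kernel width along the window axis.
#' @param pool Max-pool width (and stride) along the window axis.
#' @param embed_dim CNN output embedding size.
#' @param heads Number of attention heads (H >= 1).
#' @param d_head Per-head output dimension.
#' @param aggregation `"concat"` or `"mean"` multi-head aggregation.
#' @param negative_slope Leaky rectifier slope.
#' @param dropout Dropout rate on the CNN embedding during training
#'   (0 disables).
#' @param n_markers,n_windows Feature matrix shape (7 x 21 by default).
#' @param edge_dim Number of edge features (distance + type = 2).
#' @param seed Seed used by [init_model()] for weight initialization.
#' @return A `model_config` list with derived dimensions attached.
#' @export
model_config <- function(conv_channels = 8L, kernel_size = 3L, pool = 2L,
                         embed_dim = 32L, heads = 4L, d_head = 8L,
                         aggregation = c("concat", "mean"),
                         negative_slope = 0.2, dropout = 0,
                         n_markers = 7L, n_windows = 21L, edge_dim = 2L,
                         seed = 1L) {
  aggregation <- match.arg(aggregation)
  stopifnot(heads >= 1, kernel_size >= 1, kernel_size <= n_windows,
            pool >= 1, dropout >= 0, dropout < 1)
  conv_out <- n_windows - kernel_size + 1L
  pool_out <- conv_out %/% pool
  stopifnot(pool_out >= 1)
  node_dim <- embed_dim + 3L            # embedding + degree + one-hot type
  upd_dim <- if (aggregation == "concat") heads * d_head else d_head
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 pool = as.integer(pool),
                 embed_dim = as.integer(embed_dim),
                 heads = as.integer(heads), d_head = as.integer(d_head),
                 aggregation = aggregation,
                 negative_slope = negative_slope, dropout = dropout,
                 n_markers = as.integer(n_markers),
                 n_windows = as.integer(n_windows),
                 edge_dim = as.integer(edge_dim),
                 conv_out = conv_out, pool_out = pool_out,
                 flat_dim = as.integer(n_markers * pool_out * conv_channels),
                 node_dim = as.integer(node_dim),
                 att_in = as.integer(2L * node_dim + edge_dim),
                 upd_dim = as.integer(upd_dim),
                 clas_in = as.integer(2L * upd_dim + edge_dim),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases; deterministic under
#' `config$seed`. Parameters are a flat named list of numeric arrays:
#' two CNNs (`cnn_e_*`, `cnn_p_*`), one `(W, a)` pair per attention head,
#' and the edge classifier (`ae`, `Wclas`, `bclas`).
#'
#' @param config A [model_config()].
#' @return Named list of parameter arrays.
#' @export
init_model <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    p <- list()
    for (t in c("e", "p")) {
      p[[paste0("cnn_", t, "_Wconv")]] <- glorot(cfg$conv_channels,
                                                 cfg$kernel_size)
      p[[paste0("cnn_", t, "_bconv")]] <- numeric(cfg$conv_channels)
      p[[paste0("cnn_", t, "_Wfc")]] <- glorot(cfg$flat_dim, cfg$embed_dim)
      p[[paste0("cnn_", t, "_bfc")]] <- numeric(cfg$embed_dim)
    }
    for (h in seq_len(cfg$heads)) {
      p[[paste0("W_h", h)]] <- glorot(cfg$d_head, cfg$att_in)
      p[[paste0("a_h", h)]] <- as.vector(glorot(cfg$d_head, 1))
    }
    p$ae <- as.vector(glorot(cfg$clas_in, 1))
    p$Wclas <- as.vector(glorot(cfg$clas_in, 1))
    p$bclas <- 0
    p
  })
}

# ---- CNN encoder ----------------------------------------------------------

cnn_forward <- function(X, Wconv, bconv, Wfc, bfc, cfg) {
  N <- dim(X)[1]
  if (N == 0)
    return(list(E = matrix(0, 0, cfg$embed_dim), cache = NULL))
  k <- cfg$kernel_size; To <- cfg$conv_out; C <- cfg$conv_channels
  Tp <- cfg$pool_out; pool <- cfg$pool
  M <- matrix(X, nrow = N * cfg$n_markers)   # rows: (marker, element)
  Z <- array(0, c(nrow(M), To, C))
  for (c in seq_len(C)) {
    Zc <- matrix(bconv[c], nrow(M), To)
    for (j in seq_len(k))
      Zc <- Zc + M[, j:(j + To - 1), drop = FALSE] * Wconv[c, j]
    Z[, , c] <- Zc
  }
  A <- leaky_relu(Z, cfg$negative_slope)
  P <- array(0, c(nrow(M), Tp, C))
  amax <- array(0L, c(nrow(M), Tp, C))
  for (c in seq_len(C)) for (u in seq_len(Tp)) {
    cols <- ((u - 1L) * pool + 1L):(u * pool)
    blk <- A[, cols, c, drop = FALSE]
    dim(blk) <- c(nrow(M), pool)
    amax[, u, c] <- max.col(blk, ties.method = "first")
    P[, u, c] <- blk[cbind(seq_len(nrow(M)), amax[, u, c])]
  }
  F_ <- matrix(array(P, c(N, cfg$n_markers, Tp, C)), nrow = N)
  E <- F_ %*% Wfc + rep(bfc, each = N)
  list(E = E, cache = list(M = M, Z = Z, F_ = F_, amax = amax, N = N))
}

cnn_backward <- function(dE, cache, Wconv, Wfc, cfg) {
  N <- cache$N
  k <- cfg$kernel_size; To <- cfg$conv_out; C <- cfg$conv_channels
  Tp <- cfg$pool_out; pool <- cfg$pool
  NM <- nrow(cache$M)
  dWfc <- crossprod(cache$F_, dE)
  dbfc <- colSums(dE)
  dF <- dE %*% t(Wfc)
  dP <- array(dF, c(NM, Tp, C))
  dA <- array(0, c(NM, To, C))
  for (c in seq_len(C)) for (u in seq_len(Tp)) {
    tsel <- (u - 1L) * pool + cache$amax[, u, c]
    idx <- seq_len(NM) + (tsel - 1L) * NM + (c - 1L) * NM * To
    dA[idx] <- dA[idx] + dP[, u, c]
  }
  dZ <- dA * leaky_relu_grad(cache$Z, cfg$negative_slope)
  dWconv <- matrix(0, C, k)
  dbconv <- numeric(C)
  for (c in seq_len(C)) {
    dZc <- dZ[, , c, drop = FALSE]
    dim(dZc) <- c(NM, To)
    dbconv[c] <- sum(dZc)
    for (j in seq_len(k))
      dWconv[c, j] <- sum(cache$M[, j:(j + To - 1), drop = FALSE] * dZc)
  }
  list(Wconv = dWconv, bconv = dbconv, Wfc = dWfc, bfc = dbfc)
}

#' Encode one feature matrix with the CNN
#'
#' Runs a single 7 x 21 matrix through the enhancer or promoter CNN
#' (independent modules): convolution along the window axis only, leaky
#' rectifier, max-pool, flatten, dense.
#'
#' @param feature_matrix A `n_markers x n_windows` matrix.
#' @param params Parameters from [init_model()].
#' @param etype `"enhancer"` or `"promoter"` (selects the CNN).
#' @param config The [model_config()].
#' @return Numeric embedding of length `config$embed_dim`.
#' @export
cnn_encode <- function(feature_matrix, params, etype, config) {
  if (!all(dim(feature_matrix) == c(config$n_markers, config$n_windows)))
    stop(sprintf("feature matrix must be %d x %d",
                 config$n_markers, config$n_windows))
  t <- if (match.arg(etype, c("enhancer", "promoter")) == "enhancer")
    "e" else "p"
  X <- array(0, c(1, config$n_markers, config$n_windows))
  X[1, , ] <- feature_matrix
  as.vector(cnn_forward(X, params[[paste0("cnn_", t, "_Wconv")]],
                        params[[paste0("cnn_", t, "_bconv")]],
                        params[[paste0("cnn_", t, "_Wfc")]],
                        params[[paste0("cnn_", t, "_bfc")]], config)$E)
}

#' Assemble the full node input vector
#'
#' Concatenation of the CNN embedding, the raw node degree and the
#' one-hot type, in that fixed order (promoter `(1,0)`, enhancer
#' `(0,1)`).
#'
#' @param embedding CNN embedding vector.
#' @param degree Node degree (raw count).
#' @param type_onehot Length-2 one-hot type vector.
#' @return Numeric vector of length `|embedding| + 3`.
#' @export
node_input <- function(embedding, degree, type_onehot) {
  stopifnot(length(type_onehot) == 2)
  c(embedding, degree, type_onehot)
}

# ---- batch construction ---------------------------------------------------

#' Build a model batch from an EPI graph
#'
#' Packs node feature matrices, structural features, and (directed) edge
#' indices into the array form the forward/backward passes consume. Edge
#' features must already be present (run [mask_edge_type()] first).
#'
#' @param graph An `epi_graph` with `dist_feat`/`type_feat` edge columns.
#' @param config A [model_config()].
#' @return A `model_batch` list.
#' @export
make_model_batch <- function(graph, config) {
  stopifnot_cols(graph$edges, c("dist_feat", "type_feat"), "edge table")
  nodes <- graph$nodes
  n <- nrow(nodes)
  is_enh <- nodes$etype == "enhancer"
  pack <- function(ids) {
    X <- array(0, c(length(ids), config$n_markers, config$n_windows))
    for (k in seq_along(ids)) X[k, , ] <- graph$features[[ids[k]]]
    X
  }
  cnn_row <- integer(n)
  cnn_row[is_enh] <- seq_len(sum(is_enh))
  cnn_row[!is_enh] <- seq_len(sum(!is_enh))
  node_idx <- stats::setNames(seq_len(n), nodes$id)
  e <- graph$edges
  i <- unname(node_idx[e$enhancer_id])
  j <- unname(node_idx[e$gene_id])
  EF <- cbind(dist = e$dist_feat, type = e$type_feat)
  list(n_nodes = n, node_ids = nodes$id, is_enh = is_enh,
       cnn_row = cnn_row,
       Xe = pack(nodes$id[is_enh]), Xp = pack(nodes$id[!is_enh]),
       deg = nodes$degree,
       type_oh = cbind(type_p = as.numeric(!is_enh),
                       type_e = as.numeric(is_enh)),
       i = i, j = j, EF = EF,
       label = e$label,
       split = if ("split" %in% names(e)) e$split else
         rep("train", nrow(e)),
       dst = c(i, j), src = c(j, i), EF2 = rbind(EF, EF))
}

group_sum <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- full forward pass ----------------------------------------------------

#' Forward pass of the EPI edge classifier
#'
#' CNN-encodes every node, assembles node inputs, runs one multi-head
#' GATv2 layer over the sample graph, and scores every edge with the
#' edge attention classifier. Returns raw logits (pre-sigmoid).
#'
#' @param params Parameters from [init_model()].
#' @param batch A [make_model_batch()].
#' @param config The [model_config()].
#' @param dropout_mask Optional 0/1-scaled mask (nodes x embed_dim)
#'   applied to the CNN embedding (training-time dropout).
#' @return List with `logits` (one per edge, in batch edge order) and
#'   `cache` for the backward pass.
#' @export
model_forward <- function(params, batch, config, dropout_mask = NULL) {
  cfg <- config
  fe <- cnn_forward(batch$Xe, params$cnn_e_Wconv, params$cnn_e_bconv,
                    params$cnn_e_Wfc, params$cnn_e_bfc, cfg)
  fp <- cnn_forward(batch$Xp, params$cnn_p_Wconv, params$cnn_p_bconv,
                    params$cnn_p_Wfc, params$cnn_p_bfc, cfg)
  E <- matrix(0, batch$n_nodes, cfg$embed_dim)
  E[batch$is_enh, ] <- fe$E[batch$cnn_row[batch$is_enh], , drop = FALSE]
  E[!batch$is_enh, ] <- fp$E[batch$cnn_row[!batch$is_enh], , drop = FALSE]
  if (!is.null(dropout_mask)) E <- E * dropout_mask
  H0 <- cbind(E, batch$deg, batch$type_oh)
  # GATv2 layer: directed edges dst <- src, features [x_dst, x_src, e]
  Q <- cbind(H0[batch$dst, , drop = FALSE], H0[batch$src, , drop = FALSE],
             batch$EF2)
  heads <- vector("list", cfg$heads)
  Hparts <- vector("list", cfg$heads)
  for (h in seq_len(cfg$heads)) {
    W <- params[[paste0("W_h", h)]]
    a <- params[[paste0("a_h", h)]]
    U <- Q %*% t(W)
    G <- leaky_relu(U, cfg$negative_slope)
    s <- as.vector(G %*% a)
    mx <- stats::ave(s, batch$dst, FUN = max)
    ex <- exp(s - mx)
    alpha <- ex / stats::ave(ex, batch$dst, FUN = sum)
    Xpre <- group_sum(alpha * U, batch$dst, batch$n_nodes)
    heads[[h]] <- list(U = U, G = G, alpha = alpha, Xpre = Xpre)
    Hparts[[h]] <- elu(Xpre)
  }
  H1 <- if (cfg$aggregation == "concat") do.call(cbind, Hparts) else
    Reduce(`+`, Hparts) / cfg$heads
  # edge classifier, enhancer embedding first
  Eprime <- cbind(H1[batch$i, , drop = FALSE], H1[batch$j, , drop = FALSE],
                  batch$EF)
  Zg <- sweep(Eprime, 2, params$ae, `*`)
  G2 <- elu(Zg)
  logits <- as.vector(G2 %*% params$Wclas) + params$bclas
  list(logits = logits,
       cache = list(fe = fe, fp = fp, H0 = H0, Q = Q, heads = heads,
                    H1 = H1, Eprime = Eprime, Zg = Zg, G2 = G2,
                    dropout_mask = dropout_mask))
}

# Backward pass: dlogits -> gradients for every parameter.
model_backward <- function(params, batch, config, cache, dlogits) {
  cfg <- config
  g <- list()
  g$Wclas <- colSums(cache$G2 * dlogits)
  g$bclas <- sum(dlogits)
  dG2 <- tcrossprod(dlogits, params$Wclas)
  dZg <- dG2 * elu_grad(cache$Zg)
  g$ae <- colSums(dZg * cache$Eprime)
  dEprime <- sweep(dZg, 2, params$ae, `*`)
  upd <- cfg$upd_dim
  dH1 <- group_sum(dEprime[, 1:upd, drop = FALSE], batch$i, batch$n_nodes) +
    group_sum(dEprime[, (upd + 1):(2 * upd), drop = FALSE], batch$j,
              batch$n_nodes)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  for (h in seq_len(cfg$heads)) {
    hc <- cache$heads[[h]]
    W <- params[[paste0("W_h", h)]]
    a <- params[[paste0("a_h", h)]]
    dXh <- if (cfg$aggregation == "concat")
      dH1[, ((h - 1) * cfg$d_head + 1):(h * cfg$d_head), drop = FALSE]
      else dH1 / cfg$heads
    dXpre <- dXh * elu_grad(hc$Xpre)
    dMsg <- dXpre[batch$dst, , drop = FALSE]
    dalpha <- rowSums(dMsg * hc$U)
    dU <- hc$alpha * dMsg
    sdot <- hc$alpha * dalpha
    ds <- sdot - hc$alpha * stats::ave(sdot, batch$dst, FUN = sum)
    g[[paste0("a_h", h)]] <- colSums(hc$G * ds)
    dG <- tcrossprod(ds, a)
    dU <- dU + dG * leaky_relu_grad(hc$U, cfg$negative_slope)
    g[[paste0("W_h", h)]] <- crossprod(dU, cache$Q)
    dQ <- dQ + dU %*% W
  }
  nd <- cfg$node_dim
  dH0 <- group_sum(dQ[, 1:nd, drop = FALSE], batch$dst, batch$n_nodes) +
    group_sum(dQ[, (nd + 1):(2 * nd), drop = FALSE], batch$src,
              batch$n_nodes)
  dE <- dH0[, 1:cfg$embed_dim, drop = FALSE]
  if (!is.null(cache$dropout_mask)) dE <- dE * cache$dropout_mask
  dEe <- matrix(0, dim(batch$Xe)[1], cfg$embed_dim)
  dEp <- matrix(0, dim(batch$Xp)[1], cfg$embed_dim)
  dEe[batch$cnn_row[batch$is_enh], ] <- dE[batch$is_enh, , drop = FALSE]
  dEp[batch$cnn_row[!batch$is_enh], ] <- dE[!batch$is_enh, , drop = FALSE]
  if (!is.null(cache$fe$cache)) {
    gb <- cnn_backward(dEe, cache$fe$cache, params$cnn_e_Wconv,
                       params$cnn_e_Wfc, cfg)
    g$cnn_e_Wconv <- gb$Wconv; g$cnn_e_bconv <- gb$bconv
    g$cnn_e_Wfc <- gb$Wfc; g$cnn_e_bfc <- gb$bfc
  }
  if (!is.null(cache$fp$cache)) {
    gb <- cnn_backward(dEp, cache$fp$cache, params$cnn_p_Wconv,
                       params$cnn_p_Wfc, cfg)
    g$cnn_p_Wconv <- gb$Wconv; g$cnn_p_bconv <- gb$bconv
    g$cnn_p_Wfc <- gb$Wfc; g$cnn_p_bfc <- gb$bfc
  }
  for (nm in names(params)) if (is.null(g[[nm]])) g[[nm]] <- params[[nm]] * 0
  g[names(params)]
}

# ---- small exported building blocks ---------------------------------------

#' GATv2 attention weights of a query node over its neighbors
#'
#' For query node features `x_i` and each neighbor `x_j` with edge
#' features `e_ij`, scores are `a' LeakyReLU(W [x_i; x_j; e_ij])`,
#' normalized with a softmax over the neighborhood. Because the leaky
#' rectifier is applied before the attention projection, the ranking of
#' neighbors depends on the query node (dynamic attention).
#'
#' @param x_i Query node feature vector.
#' @param X_j Matrix of neighbor feature vectors (one row each).
#' @param EF Matrix of edge feature vectors (one row per neighbor).
#' @param W,a Head parameters.
#' @param negative_slope Leaky rectifier slope.
#' @return Positive weights summing to 1 (one per neighbor); length 0
#'   for an empty neighborhood.
#' @export
attention_scores <- function(x_i, X_j, EF, W, a, negative_slope = 0.2) {
  if (NROW(X_j) == 0) return(numeric(0))
  Q <- cbind(matrix(x_i, NROW(X_j), length(x_i), byrow = TRUE), X_j, EF)
  s <- as.vector(leaky_relu(Q %*% t(W), negative_slope) %*% a)
  ex <- exp(s - max(s))
  ex / sum(ex)
}

#' Multi-head GATv2 node update
#'
#' Updates every node as `ELU(sum_j alpha_ij W [x_i; x_j; e_ij])` per
#' head, then aggregates heads by concatenation or averaging.
#'
#' @param H0 Node feature matrix (nodes x node_dim).
#' @param dst,src Directed edge endpoint indices (messages flow
#'   `src -> dst`; attention is normalized per `dst`).
#' @param EF Edge feature matrix (one row per directed edge).
#' @param params Parameters from [init_model()].
#' @param config The [model_config()].
#' @return Updated node matrix (nodes x upd_dim).
#' @export
gat_node_update <- function(H0, dst, src, EF, params, config) {
  cfg <- config
  Q <- cbind(H0[dst, , drop = FALSE], H0[src, , drop = FALSE], EF)
  parts <- vector("list", cfg$heads)
  for (h in seq_len(cfg$heads)) {
    W <- params[[paste0("W_h", h)]]
    a <- params[[paste0("a_h", h)]]
    U <- Q %*% t(W)
    s <- as.vector(leaky_relu(U, cfg$negative_slope) %*% a)
    mx <- stats::ave(s, dst, FUN = max)
    ex <- exp(s - mx)
    alpha <- ex / stats::ave(ex, dst, FUN = sum)
    parts[[h]] <- elu(group_sum(alpha * U, dst, nrow(H0)))
  }
  if (cfg$aggregation == "concat") do.call(cbind, parts) else
    Reduce(`+`, parts) / cfg$heads
}

#' Edge attention classifier
#'
#' Concatenates the updated endpoint features (enhancer first, promoter
#' second) with the edge features, applies elementwise edge attention
#' weights followed by an ELU, and maps through the output linear layer
#' to one logit per edge.
#'
#' @param H1 Updated node matrix.
#' @param i,j Edge endpoint indices (enhancer, promoter).
#' @param EF Edge feature matrix.
#' @param params Parameters from [init_model()].
#' @return Numeric logits, one per edge.
#' @export
classify_edges <- function(H1, i, j, EF, params) {
  Eprime <- cbind(H1[i, , drop = FALSE], H1[j, , drop = FALSE], EF)
  Zg <- sweep(Eprime, 2, params$ae, `*`)
  as.vector(elu(Zg) %*% params$Wclas) + params$bclas
}
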