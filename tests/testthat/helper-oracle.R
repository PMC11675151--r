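# Independent straight-line oracles, written as naive loops so they share
# no code path with the vectorized implementations they check.

lrelu_o <- function(x, s = 0.2) ifelse(x > 0, x, s * x)
elu_o <- function(x) ifelse(x > 0, x, exp(x) - 1)

# CNN for one element matrix, all loops explicit.
oracle_cnn <- function(X, Wconv, bconv, Wfc, bfc, cfg) {
  C <- cfg$conv_channels; k <- cfg$kernel_size
  To <- cfg$n_windows - k + 1; Tp <- To %/% cfg$pool
  flat <- numeric(cfg$n_markers * Tp * C)
  for (c in seq_len(C)) for (m in seq_len(cfg$n_markers)) {
    conv <- numeric(To)
    for (t in seq_len(To)) {
      z <- bconv[c]
      for (j in seq_len(k)) z <- z + X[m, t + j - 1] * Wconv[c, j]
      conv[t] <- lrelu_o(z, cfg$negative_slope)
    }
    for (u in seq_len(Tp)) {
      v <- max(conv[((u - 1) * cfg$pool + 1):(u * cfg$pool)])
      # flatten order: marker fastest, then pooled position, then channel
      flat[m + cfg$n_markers * (u - 1) + cfg$n_markers * Tp * (c - 1)] <- v
    }
  }
  out <- numeric(cfg$embed_dim)
  for (d in seq_len(cfg$embed_dim)) {
    v <- bfc[d]
    for (f in seq_along(flat)) v <- v + flat[f] * Wfc[f, d]
    out[d] <- v
  }
  out
}

# Full forward pass over a model batch, one node / edge / head at a time.
oracle_forward <- function(params, batch, cfg) {
  n <- batch$n_nodes
  H0 <- matrix(0, n, cfg$node_dim)
  for (v in seq_len(n)) {
    t <- if (batch$is_enh[v]) "e" else "p"
    X <- if (batch$is_enh[v]) batch$Xe[batch$cnn_row[v], , ] else
      batch$Xp[batch$cnn_row[v], , ]
    emb <- oracle_cnn(matrix(X, cfg$n_markers, cfg$n_windows),
                      params[[paste0("cnn_", t, "_Wconv")]],
                      params[[paste0("cnn_", t, "_bconv")]],
                      params[[paste0("cnn_", t, "_Wfc")]],
                      params[[paste0("cnn_", t, "_bfc")]], cfg)
    H0[v, ] <- c(emb, batch$deg[v], batch$type_oh[v, ])
  }
  nde <- length(batch$dst)
  parts <- vector("list", cfg$heads)
  for (h in seq_len(cfg$heads)) {
    W <- params[[paste0("W_h", h)]]
    a <- params[[paste0("a_h", h)]]
    upd <- matrix(0, n, cfg$d_head)
    for (v in seq_len(n)) {
      es <- which(batch$dst == v)
      if (length(es) == 0) next
      scores <- numeric(length(es))
      msgs <- matrix(0, length(es), cfg$d_head)
      for (q in seq_along(es)) {
        e <- es[q]
        x <- c(H0[v, ], H0[batch$src[e], ], batch$EF2[e, ])
        u <- as.vector(W %*% x)
        scores[q] <- sum(a * lrelu_o(u, cfg$negative_slope))
        msgs[q, ] <- u
      }
      al <- exp(scores - max(scores))
      al <- al / sum(al)
      acc <- numeric(cfg$d_head)
      for (q in seq_along(es)) acc <- acc + al[q] * msgs[q, ]
      upd[v, ] <- elu_o(acc)
    }
    parts[[h]] <- upd
  }
  H1 <- if (cfg$aggregation == "concat") do.call(cbind, parts) else
    Reduce(`+`, parts) / cfg$heads
  logits <- numeric(length(batch$i))
  for (e in seq_along(batch$i)) {
    ep <- c(H1[batch$i[e], ], H1[batch$j[e], ], batch$EF[e, ])
    logits[e] <- sum(params$Wclas * elu_o(params$ae * ep)) + params$bclas
  }
  logits
}

# Connected components by hand-rolled BFS over an edge list of node names.
oracle_bfs <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# Per-base mean signal over 0-based half-open intervals (tiny inputs only).
oracle_aggregate <- function(track, intervals) {
  bases <- unlist(lapply(seq_len(nrow(intervals)), function(r)
    if (intervals$end[r] > intervals$start[r])
      seq(intervals$start[r], intervals$end[r] - 1) else numeric(0)))
  if (length(bases) == 0) return(0)
  vals <- vapply(bases, function(b) {
    hit <- which(track$start <= b & track$end > b)
    if (length(hit) == 0) 0 else sum(track$signalValue[hit])
  }, 0)
  mean(vals)
}

# Two partitions of the same items are the same up to relabeling.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
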