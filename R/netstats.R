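#' Degree distributions of the positive EPI network
#'
#' Degrees are computed on positive (regulatory) edges only: how many
#' promoters each enhancer regulates, and how many enhancers regulate
#' each promoter.
#'
#' @param pairs Positive pair table (`enhancer_id`, `gene_id`; a `label`
#'   column, if present, is used to subset to positives).
#' @return List with `enhancer` and `promoter` degree data.frames
#'   (`id`, `degree`) and `quantiles` (0/25/50/75/100% per type).
#' @export
degree_distributions <- function(pairs) {
  pairs <- positive_pairs(pairs)
  ed <- table(pairs$enhancer_id)
  pd <- table(pairs$gene_id)
  qs <- function(x) stats::quantile(as.integer(x),
                                    probs = c(0, 0.25, 0.5, 0.75, 1))
  list(enhancer = data.frame(id = names(ed), degree = as.integer(ed),
                             stringsAsFactors = FALSE),
       promoter = data.frame(id = names(pd), degree = as.integer(pd),
                             stringsAsFactors = FALSE),
       quantiles = rbind(enhancer = qs(ed), promoter = qs(pd)))
}

positive_pairs <- function(pairs) {
  stopifnot_cols(pairs, c("enhancer_id", "gene_id"), "pair table")
  if ("label" %in% names(pairs))
    pairs <- pairs[pairs$label == 1, , drop = FALSE]
  pairs[!duplicated(pairs[, c("enhancer_id", "gene_id")]), , drop = FALSE]
}

#' Bipartite clustering coefficient per node
#'
#' Pairwise bipartite clustering (Latapy et al.): for nodes `u`, `v` of
#' the same type at distance 2, `cc(u, v) = |N(u) inter N(v)| /
#' |N(u) union N(v)|`; a node's coefficient is the mean of `cc(u, v)`
#' over its distance-2 neighbors `v`. A node in an isolated interaction
#' pair has no distance-2 neighbors and gets 0; nodes of a complete
#' bipartite cluster get 1.
#'
#' @param pairs Positive pair table.
#' @return Data.frame with `id`, `etype`, `bcc` (all values in
#'   `[0, 1]`).
#' @export
bipartite_clustering <- function(pairs) {
  pairs <- positive_pairs(pairs)
  nb_e <- split(pairs$gene_id, pairs$enhancer_id)
  nb_p <- split(pairs$enhancer_id, pairs$gene_id)
  bcc_side <- function(nb, other_nb) {
    vapply(names(nb), function(u) {
      nu <- nb[[u]]
      v2 <- setdiff(unique(unlist(other_nb[nu], use.names = FALSE)), u)
      if (length(v2) == 0) return(0)
      mean(vapply(v2, function(v) {
        nv <- nb[[v]]
        length(intersect(nu, nv)) / length(union(nu, nv))
      }, 0))
    }, 0)
  }
  be <- bcc_side(nb_e, nb_p)
  bp <- bcc_side(nb_p, nb_e)
  data.frame(id = c(names(be), names(bp)),
             etype = rep(c("enhancer", "promoter"),
                         c(length(be), length(bp))),
             bcc = c(unname(be), unname(bp)), stringsAsFactors = FALSE)
}

#' Connected-subgraph statistics of the positive EPI network
#'
#' One row per connected component: node count, edge count and average
#' node degree (`2E / V`), sorted by node count descending.
#'
#' @param pairs Positive pair table.
#' @return Data.frame with `component`, `node_count`, `edge_count`,
#'   `average_degree`.
#' @export
component_stats <- function(pairs) {
  pairs <- positive_pairs(pairs)
  g <- igraph::graph_from_data_frame(
    pairs[, c("enhancer_id", "gene_id")], directed = FALSE)
  memb <- igraph::components(g)$membership
  stats_ <- lapply(sort(unique(memb)), function(cid) {
    nodes <- names(memb)[memb == cid]
    ec <- sum(pairs$enhancer_id %in% nodes)
    data.frame(component = cid, node_count = length(nodes),
               edge_count = ec,
               average_degree = 2 * ec / length(nodes))
  })
  out <- do.call(rbind, stats_)
  out <- out[order(-out$node_count, out$component), ]
  rownames(out) <- NULL
  out
}

#' Intersection of EPI sets across datasets
#'
#' Pairs are keyed by (enhancer_id, gene_id). Reports, per dataset, the
#' unique count and proportion; shared counts for every dataset pair;
#' and the interactions common to all datasets.
#'
#' @param pair_sets Named list of positive pair tables.
#' @return List with `per_dataset` (total / unique counts and
#'   proportions), `pairwise` (shared counts per dataset pair) and
#'   `shared_all` (data.frame of pairs present in every dataset).
#' @export
epi_intersection <- function(pair_sets) {
  stopifnot(length(pair_sets) >= 1, !is.null(names(pair_sets)))
  keys <- lapply(pair_sets, function(p) {
    p <- positive_pairs(p)
    unique(paste(p$enhancer_id, p$gene_id, sep = "\r"))
  })
  nm <- names(keys)
  per <- do.call(rbind, lapply(nm, function(d) {
    others <- unique(unlist(keys[setdiff(nm, d)], use.names = FALSE))
    uniq <- sum(!(keys[[d]] %in% others))
    data.frame(dataset = d, total = length(keys[[d]]), unique = uniq,
               prop_unique = uniq / length(keys[[d]]),
               stringsAsFactors = FALSE)
  }))
  pw <- NULL
  if (length(nm) >= 2) {
    cmb <- utils::combn(nm, 2)
    pw <- data.frame(a = cmb[1, ], b = cmb[2, ],
                     shared = apply(cmb, 2, function(ab)
                       length(intersect(keys[[ab[1]]], keys[[ab[2]]]))),
                     stringsAsFactors = FALSE)
  }
  all_shared <- Reduce(intersect, keys)
  shared_df <- if (length(all_shared) > 0) {
    parts <- strsplit(all_shared, "\r", fixed = TRUE)
    data.frame(enhancer_id = vapply(parts, `[`, "", 1),
               gene_id = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(enhancer_id = character(0), gene_id = character(0))
  list(per_dataset = per, pairwise = pw, shared_all = shared_df)
}

#' Random-forest feature importance over windowed marker signals
#'
#' Flattens each element's 7 x 21 feature matrix to 147 predictors and
#' fits a random forest classifying whether the element participates in
#' a positive interaction; impurity (mean decrease in Gini) importances
#' are reshaped back to marker x window and normalized to sum to 1.
#'
#' @param matrices Named list of feature matrices (names = element ids).
#' @param labels Named 0/1 vector (or logical): participates in a
#'   positive EPI. Names must cover `names(matrices)`.
#' @param seed Random forest seed.
#' @param ntree Number of trees.
#' @return A 7 x 21 importance matrix (rows = markers, columns = window
#'   offsets) summing to 1.
#' @export
feature_importance <- function(matrices, labels, seed = 1L, ntree = 500L) {
  ids <- names(matrices)
  y <- labels[ids]
  if (anyNA(y)) stop("labels missing for some elements")
  y <- factor(as.integer(y), levels = c(0, 1))
  if (length(unique(y)) < 2)
    stop("feature importance needs both classes present")
  X <- t(vapply(matrices, as.vector,
                numeric(length(as.vector(matrices[[1]])))))
  nm <- rownames(matrices[[1]])
  nw <- ncol(matrices[[1]])
  offs <- colnames(matrices[[1]])
  colnames(X) <- paste0(rep(nm, nw), "_w", rep(offs, each = length(nm)))
  rf <- with_seed(seed,
                  randomForest::randomForest(X, y, ntree = ntree,
                                             importance = FALSE))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  m <- matrix(imp, nrow = length(nm), ncol = nw,
              dimnames = list(nm, offs))
  m / sum(m)
}
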