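#' Build per-chromosome EPI graphs
#'
#' Turns a labelled sample table into one undirected bipartite graph per
#' chromosome: enhancers and promoters are nodes, every sample (positive
#' or negative) is an edge carrying its distance and label. Node degree
#' is the incident sample-edge count.
#'
#' @param samples Prepared sample table (see [prepare_samples()]):
#'   `enhancer_id`, `gene_id`, `label`, `chrom`, `distance`.
#' @param features Named list of feature matrices covering every node id
#'   (see [featurize_all()]).
#' @return Named list of `epi_graph` objects (one per chromosome), each
#'   with `chrom`, `nodes` (id, etype, degree), `edges` (enhancer_id,
#'   gene_id, label, distance) and `features`.
#' @export
build_epi_graph <- function(samples, features) {
  stopifnot_cols(samples, c("enhancer_id", "gene_id", "label", "chrom",
                            "distance"), "sample table")
  ids <- unique(c(samples$enhancer_id, samples$gene_id))
  missing <- setdiff(ids, names(features))
  if (length(missing) > 0)
    stop(sprintf("missing feature matrices for node(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  graphs <- lapply(split(samples, samples$chrom), function(s) {
    node_id <- unique(c(s$enhancer_id, s$gene_id))
    etype <- ifelse(node_id %in% s$enhancer_id, "enhancer", "promoter")
    deg <- table(c(s$enhancer_id, s$gene_id))
    nodes <- data.frame(id = node_id, etype = etype,
                        degree = as.integer(deg[node_id]),
                        stringsAsFactors = FALSE)
    edges <- s[, c("enhancer_id", "gene_id", "label", "distance")]
    rownames(edges) <- NULL
    structure(list(chrom = s$chrom[1], nodes = nodes, edges = edges,
                   features = features[node_id]),
              class = "epi_graph")
  })
  graphs
}

#' Structural node features: degree and one-hot type
#'
#' Each node gets its raw degree plus a one-hot type encoding: promoters
#' are `(1, 0)`, enhancers `(0, 1)`.
#'
#' @param graph An `epi_graph`.
#' @return Numeric matrix (nodes x 3) with columns `degree`, `type_p`,
#'   `type_e`, rownames = node ids.
#' @export
structural_node_features <- function(graph) {
  n <- graph$nodes
  m <- cbind(degree = n$degree,
             type_p = as.numeric(n$etype == "promoter"),
             type_e = as.numeric(n$etype == "enhancer"))
  rownames(m) <- n$id
  m
}

#' Connected components of an EPI graph
#'
#' Components are computed over the union of positive and negative
#' sample edges. Labels are canonical: the component containing the
#' lexicographically smallest node id is 1, and so on, making the
#' labelling invariant to node order.
#'
#' @param graph An `epi_graph`.
#' @return Integer vector of component labels, named by node id.
#' @export
graph_components <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("enhancer_id", "gene_id")], directed = FALSE,
    vertices = graph$nodes$id)
  memb <- igraph::components(g)$membership
  # canonicalize by smallest member id
  reps <- tapply(names(memb), memb, min)
  rank <- stats::setNames(match(reps, sort(reps)), names(reps))
  out <- as.integer(rank[as.character(memb)])
  names(out) <- names(memb)
  out[graph$nodes$id]
}

#' Connectivity-based train/validation/test split
#'
#' Assigns whole connected components to splits so no node or edge is
#' ever shared between splits, while keeping each chromosome's edge
#' counts close to the target ratios. Components are taken largest
#' (by edge count) first, equal sizes in seed-shuffled order, and each
#' goes to the split with the largest remaining deficit. A chromosome
#' with fewer than 3 components is placed entirely in the training split
#' (with a warning), since a 3-way split cannot be formed.
#'
#' @param graphs Named list of `epi_graph`s from [build_epi_graph()].
#' @param ratios Target proportions for train/val/test (default 3:1:1).
#' @param seed Integer seed for shuffling equal-size components.
#' @return A `split_plan`: data.frame with `chrom`, `component`, `split`,
#'   `n_edges`, plus attribute `ratios` with achieved per-chromosome edge
#'   shares.
#' @export
split_by_connectivity <- function(graphs, ratios = c(3, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  target <- ratios / sum(ratios)
  splits <- c("train", "val", "test")
  plan <- list()
  with_seed(seed, {
    for (chr in names(graphs)) {
      g <- graphs[[chr]]
      comp <- graph_components(g)
      edge_comp <- comp[g$edges$enhancer_id]
      sizes <- table(edge_comp)
      cid <- as.integer(names(sizes))
      n_edges <- as.integer(sizes)
      if (length(cid) < 3) {
        warning(sprintf("chromosome %s has %d component(s); all assigned to train",
                        chr, length(cid)))
        plan[[chr]] <- data.frame(chrom = chr, component = cid,
                                  split = "train", n_edges = n_edges,
                                  stringsAsFactors = FALSE)
        next
      }
      ord <- sample(length(cid))             # shuffle, then stable sort by
      ord <- ord[order(-n_edges[ord])]       # size keeps shuffled tie order
      assigned <- stats::setNames(numeric(3), splits)
      total <- sum(n_edges)
      sp <- character(length(cid))
      for (k in ord) {
        deficit <- target * total - assigned
        pick <- splits[which.max(deficit)]
        sp[k] <- pick
        assigned[pick] <- assigned[pick] + n_edges[k]
      }
      plan[[chr]] <- data.frame(chrom = chr, component = cid, split = sp,
                                n_edges = n_edges, stringsAsFactors = FALSE)
    }
  })
  plan <- do.call(rbind, plan)
  rownames(plan) <- NULL
  ach <- do.call(rbind, lapply(split(plan, plan$chrom), function(p) {
    tot <- sum(p$n_edges)
    vapply(splits, function(s) sum(p$n_edges[p$split == s]) / tot, 0)
  }))
  attr(plan, "ratios") <- ach
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Apply a split plan to graphs
#'
#' Annotates every edge and node with its split. Nodes inherit the split
#' of their component, edges likewise; by construction the three node
#' (and edge) sets are disjoint.
#'
#' @param graphs Named list of `epi_graph`s.
#' @param plan A [split_by_connectivity()] plan.
#' @return The graphs with a `split` column on `nodes` and `edges`.
#' @export
assign_split <- function(graphs, plan) {
  for (chr in names(graphs)) {
    g <- graphs[[chr]]
    comp <- graph_components(g)
    p <- plan[plan$chrom == chr, ]
    map <- stats::setNames(p$split, p$component)
    g$nodes$split <- unname(map[as.character(comp)])
    g$edges$split <- unname(map[as.character(comp[g$edges$enhancer_id])])
    graphs[[chr]] <- g
  }
  graphs
}

#' Mask edge-type features outside the training split
#'
#' Builds the two edge features the model consumes: the pair distance
#' rescaled to `[0, 1]` over the 42 kb-500 kb filter range, and the edge
#' type. On training edges the type feature equals the label; on
#' validation and test edges it is replaced by an uninformative sentinel
#' so held-out labels never reach the model input. Idempotent.
#'
#' @param graph An `epi_graph` with `split` assigned on edges.
#' @param sentinel Neutral value for masked edges (default 0.5, the
#'   midpoint of the train encodings 0 and 1).
#' @param dist_range Distance range used for rescaling (bp).
#' @return The graph with `dist_feat` and `type_feat` edge columns.
#' @export
mask_edge_type <- function(graph, sentinel = 0.5,
                           dist_range = c(42000, 500000)) {
  stopifnot_cols(graph$edges, "split", "edge table")
  e <- graph$edges
  e$dist_feat <- pmin(pmax((e$distance - dist_range[1]) /
                             (dist_range[2] - dist_range[1]), 0), 1)
  e$type_feat <- ifelse(e$split == "train", as.numeric(e$label), sentinel)
  graph$edges <- e
  graph
}
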