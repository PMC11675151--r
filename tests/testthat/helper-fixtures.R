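# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 1L, chrom_length = 6e6,
                   n_enhancers = 12L, n_promoters = 20L, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Element/TSS tables in the shapes prepare_samples() expects.
enhancer_table <- function(elements) {
  e <- elements[elements$etype == "enhancer", ]
  data.frame(id = e$id, chrom = e$chrom, start = e$start, end = e$end,
             stringsAsFactors = FALSE)
}

tss_table <- function(elements) {
  p <- elements[elements$etype == "promoter", ]
  data.frame(gene_id = p$id, chrom = p$chrom, tss = p$tss,
             strand = p$strand, stringsAsFactors = FALSE)
}

# Zero or random feature matrices for a set of node ids.
dummy_features <- function(ids, seed = NULL) {
  out <- lapply(ids, function(id) {
    m <- matrix(0, 7, 21, dimnames = list(epi_markers(), -10:10))
    if (!is.null(seed)) {
      set.seed(seed + sum(utf8ToInt(id)))
      m[] <- stats::runif(7 * 21)
    }
    m
  })
  stats::setNames(out, ids)
}

# A random per-chromosome sample table made of small bipartite components
# joined by positive and negative edges; distances are valid by
# construction. Used for graph/split tests where signal is irrelevant.
random_sample_table <- function(seed, n_components = 8, chroms = "chr1") {
  set.seed(seed)
  rows <- list()
  for (chr in chroms) {
    for (k in seq_len(n_components)) {
      ne <- sample(1:3, 1); np <- sample(1:3, 1)
      eids <- sprintf("E_%s_%d_%d", chr, k, seq_len(ne))
      pids <- sprintf("P_%s_%d_%d", chr, k, seq_len(np))
      # double star through (e1, p1) keeps the component connected
      pairs <- unique(rbind(
        cbind(eids[1], pids),
        cbind(eids, pids[1]),
        if (stats::runif(1) < 0.5)
          cbind(sample(eids, 1), sample(pids, 1))))
      rows[[length(rows) + 1]] <- data.frame(
        enhancer_id = pairs[, 1], gene_id = pairs[, 2],
        label = stats::rbinom(nrow(pairs), 1, 0.5), chrom = chr,
        distance = stats::runif(nrow(pairs), 42000, 500000),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Graphs with dummy features and splits/masks applied, ready for the model.
random_model_graphs <- function(seed, n_components = 8, chroms = "chr1",
                                split_seed = seed) {
  s <- random_sample_table(seed, n_components, chroms)
  feats <- dummy_features(unique(c(s$enhancer_id, s$gene_id)), seed = seed)
  graphs <- build_epi_graph(s, feats)
  suppressWarnings({
    plan <- split_by_connectivity(graphs, seed = split_seed)
    graphs <- assign_split(graphs, plan)
  })
  lapply(graphs, mask_edge_type)
}

# The full prepared pipeline on a small planted fixture.
small_pipeline <- function(seed = 1L, prep_seed = 2L, split_seed = 3L, ...) {
  cfg <- tiny_config(seed = seed, n_chromosomes = 2L, chrom_length = 1e7,
                     n_enhancers = 24L, n_promoters = 48L, ...)
  fix <- suppressMessages(generate_fixture(cfg))
  prep <- suppressWarnings(prepare_samples(fix$pairs,
                                           enhancer_table(fix$elements),
                                           tss_table(fix$elements),
                                           seed = prep_seed))
  el <- elements_from_samples(prep$samples)
  feats <- featurize_all(el, fix$tracks, chrom_length = cfg$chrom_length)
  graphs <- build_epi_graph(prep$samples, feats)
  suppressWarnings({
    plan <- split_by_connectivity(graphs, seed = split_seed)
    graphs <- assign_split(graphs, plan)
    graphs <- normalize_graph_features(graphs)$graphs
  })
  list(config = cfg, fixture = fix, prep = prep,
       graphs = lapply(graphs, mask_edge_type))
}
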