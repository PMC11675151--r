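#' Configuration for the synthetic EPI fixture generator
#'
#' Describes a toy genome with planted enhancer-promoter regulatory
#' structure. Elements are laid out in well-separated loci along each
#' chromosome; positive interactions are planted as connected components
#' drawn from a mix of one-to-one, one-to-many and many-to-many
#' topologies; marker signal tracks carry Gaussian noise everywhere and an
#' additional enrichment (of size `signal_effect`, decaying linearly over
#' windows -2..+2) at elements that participate in a positive pair.
#'
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chrom_length Length of each chromosome in bp. Must be large
#'   enough to place all elements with full 21-window flanks and without
#'   signal-peak overlap between neighbouring elements.
#' @param n_enhancers,n_promoters Element counts across the whole genome.
#' @param component_topology Named mix weights (summing to 1) for
#'   `one_to_one`, `one_to_many` and `many_to_many` planted components.
#' @param distance_range Closed interval (bp) that every planted positive
#'   pair's enhancer-midpoint-to-TSS distance must fall in.
#' @param signal_effect Mean signal elevation at interacting elements, in
#'   the same units as the baseline signal (baseline mean is 1.0).
#' @param noise_sd Standard deviation of the Gaussian signal noise.
#' @param enriched_markers Markers that receive the planted enrichment;
#'   the remaining markers are pure noise (mimicking repressive marks that
#'   carry no positive signal at active elements).
#' @param enhancer_length Range (bp) of generated enhancer lengths.
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of the configuration including this seed.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_chromosomes = 2L,
                             chrom_length = 1e7,
                             n_enhancers = 40L,
                             n_promoters = 60L,
                             component_topology = c(one_to_one = 0.5,
                                                    one_to_many = 0.3,
                                                    many_to_many = 0.2),
                             distance_range = c(42000, 500000),
                             signal_effect = 3,
                             noise_sd = 0.5,
                             enriched_markers = c("H3K4me1", "H3K4me3",
                                                  "CTCF", "DNase"),
                             enhancer_length = c(200, 2000),
                             seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0,
            n_enhancers >= 0, n_promoters >= 0,
            length(distance_range) == 2, distance_range[1] < distance_range[2],
            signal_effect >= 0, noise_sd > 0,
            all(enriched_markers %in% epi_markers()),
            length(enhancer_length) == 2,
            enhancer_length[1] > 0, enhancer_length[1] <= enhancer_length[2])
  need <- c("one_to_one", "one_to_many", "many_to_many")
  if (!all(need %in% names(component_topology)))
    stop("component_topology must name one_to_one, one_to_many, many_to_many")
  component_topology <- component_topology[need]
  if (abs(sum(component_topology) - 1) > 1e-8)
    stop("component_topology mix weights must sum to 1")
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_enhancers = as.integer(n_enhancers),
              n_promoters = as.integer(n_promoters),
              component_topology = component_topology,
              distance_range = as.numeric(distance_range),
              signal_effect = as.numeric(signal_effect),
              noise_sd = as.numeric(noise_sd),
              enriched_markers = enriched_markers,
              enhancer_length = as.numeric(enhancer_length),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  # Placement feasibility: elements are laid out in loci of 6-10 elements
  # (45-80 kb apart within a locus) separated by > 520 kb gaps, so the
  # expected footprint is ~150 kb per element. Require headroom over the
  # expectation so placement cannot overrun the chromosome in practice.
  n_per_chr <- ceiling((cfg$n_enhancers + cfg$n_promoters) / cfg$n_chromosomes)
  if (n_per_chr > 0) {
    margin <- 42000
    need <- 2 * margin + n_per_chr * 165000
    if (cfg$chrom_length < need)
      stop(sprintf(paste("chrom_length too small: %d elements per chromosome",
                         "need about %.0f bp (got %.0f)"),
                   n_per_chr, need, cfg$chrom_length))
  }
  cfg
}

#' Place regulatory elements on the toy genome
#'
#' Elements are grouped into loci of 6-10 elements spaced 45-80 kb apart,
#' with gaps of more than 520 kb between loci — wider than the maximum
#' pairing distance, so regulatory neighbourhoods are confined within a
#' locus and the resulting EPI network forms many discrete connected
#' subgraphs (the archipelago structure typical of real EPI data).
#' Enhancer/promoter identity is assigned by shuffling within each
#' chromosome. A 42 kb margin at each chromosome end keeps every
#' element's 21 feature windows inside the chromosome. Deterministic
#' under the configured seed.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame of elements with columns `id`, `etype`
#'   (enhancer/promoter), `chrom`, `start`, `end` (0-based half-open),
#'   `strand` and `tss` (0-based TSS coordinate, `NA` for enhancers).
#'   Promoter intervals are the TSS -1500/+500 mapping.
#' @export
generate_elements <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    margin <- 42000
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    # round-robin the two element types over chromosomes
    enh_chr <- if (config$n_enhancers > 0)
      chroms[(seq_len(config$n_enhancers) - 1L) %% config$n_chromosomes + 1L]
      else character(0)
    pro_chr <- if (config$n_promoters > 0)
      chroms[(seq_len(config$n_promoters) - 1L) %% config$n_chromosomes + 1L]
      else character(0)
    rows <- list()
    for (chr in chroms) {
      ne <- sum(enh_chr == chr); np <- sum(pro_chr == chr)
      n <- ne + np
      if (n == 0) next
      types <- sample(c(rep("enhancer", ne), rep("promoter", np)))
      # loci of 6-10 elements, 45-80 kb apart, separated by > 520 kb gaps
      pos <- margin + stats::runif(1, 0, 50000)
      centers <- numeric(n)
      placed <- 0L
      while (placed < n) {
        k <- min(sample(6:10, 1), n - placed)
        for (t in seq_len(k)) {
          if (t > 1) pos <- pos + stats::runif(1, 45000, 80000)
          placed <- placed + 1L
          centers[placed] <- round(pos)
        }
        pos <- pos + 520000 + stats::runif(1, 0, 100000)
      }
      if (centers[n] > config$chrom_length - margin)
        stop("element placement failed: chrom_length too small")
      strand <- sample(c("+", "-"), n, replace = TRUE)
      len <- round(stats::runif(n, config$enhancer_length[1],
                                config$enhancer_length[2]))
      is_enh <- types == "enhancer"
      start <- end <- tss <- numeric(n)
      start[is_enh] <- centers[is_enh] - floor(len[is_enh] / 2)
      end[is_enh] <- start[is_enh] + len[is_enh]
      tss[is_enh] <- NA_real_
      strand[is_enh] <- "."
      if (any(!is_enh)) {
        tss[!is_enh] <- centers[!is_enh]
        pr <- promoter_from_tss(centers[!is_enh], strand[!is_enh],
                                config$chrom_length)
        start[!is_enh] <- pr$start
        end[!is_enh] <- pr$end
      }
      rows[[chr]] <- data.frame(
        id = ifelse(is_enh,
                    sprintf("ENH_%s_%03d", chr, cumsum(is_enh)),
                    sprintf("GENE_%s_%03d", chr, cumsum(!is_enh))),
        etype = types, chrom = chr, start = start, end = end,
        strand = strand, tss = tss, stringsAsFactors = FALSE)
    }
    el <- do.call(rbind, rows)
    if (is.null(el))
      el <- data.frame(id = character(0), etype = character(0),
                       chrom = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0),
                       tss = numeric(0), stringsAsFactors = FALSE)
    rownames(el) <- NULL
    # bounded sanity pass: the grid construction guarantees disjointness,
    # but a configuration slipping past the feasibility check must fail
    # loudly rather than emit overlapping elements
    for (chr in unique(el$chrom)) {
      sub <- el[el$chrom == chr, ]
      o <- order(sub$start)
      if (any(sub$start[o][-1] < sub$end[o][-nrow(sub)]))
        stop("element placement failed: chrom_length too small")
    }
    el
  })
}

#' Plant a positive EPI network over generated elements
#'
#' Walks the enhancers in random order and grows one component per seed
#' enhancer, with the component pattern (one-to-one, one-to-many,
#' many-to-many) drawn from the configured mix weights. A second pass
#' attaches most remaining enhancers to already-regulated promoters in
#' range, creating the promoter hubs (promoters regulated by several
#' enhancers) seen in real EPI networks. Every planted pair's
#' enhancer-midpoint-to-TSS distance lies inside
#' `config$distance_range`; each pair records its ground-truth connected
#' component id. Enhancers with no promoter in range are left isolated
#' (with a message).
#'
#' @param elements Output of [generate_elements()].
#' @param config The same [synthetic_config()].
#' @return Data.frame of positive pairs: `enhancer_id`, `gene_id`,
#'   `label` (all 1), `chrom`, `distance`, `component_id`.
#' @export
generate_epi_network <- function(elements, config) {
  stopifnot(inherits(config, "synthetic_config"))
  enh <- elements[elements$etype == "enhancer", , drop = FALSE]
  pro <- elements[elements$etype == "promoter", , drop = FALSE]
  empty <- data.frame(enhancer_id = character(0), gene_id = character(0),
                      label = integer(0), chrom = character(0),
                      distance = numeric(0), component_id = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(enh) == 0 || nrow(pro) == 0) return(empty)
  lo <- config$distance_range[1]; hi <- config$distance_range[2]
  emid <- (enh$start + enh$end) / 2
  # candidate promoters per enhancer (same chromosome, distance in range)
  cand <- lapply(seq_len(nrow(enh)), function(i) {
    j <- which(pro$chrom == enh$chrom[i])
    d <- abs(emid[i] - pro$tss[j])
    j[d >= lo & d <= hi]
  })
  with_seed(config$seed + 1L, {
    used_p <- rep(FALSE, nrow(pro))
    used_e <- rep(FALSE, nrow(enh))
    all_edges <- NULL
    n_isolated <- 0L
    pat_names <- names(config$component_topology)
    for (i in sample(seq_len(nrow(enh)))) {
      if (used_e[i]) next
      js <- cand[[i]][!used_p[cand[[i]]]]
      if (length(js) == 0) next
      pattern <- sample(pat_names, 1, prob = config$component_topology)
      edges <- NULL
      if (pattern == "one_to_one" || length(js) == 1) {
        p <- js[sample.int(length(js), 1)]
        edges <- cbind(i, p)
      } else if (pattern == "one_to_many") {
        # hub on either side: one enhancer regulating several promoters,
        # or several enhancers converging on one promoter
        if (stats::runif(1) < 0.5) {
          k <- min(sample(2:3, 1), length(js))
          ps <- js[sample.int(length(js), k)]
          edges <- cbind(i, ps)
        } else {
          p <- js[sample.int(length(js), 1)]
          partners <- which(!used_e & seq_len(nrow(enh)) != i &
                              vapply(cand, function(cs) p %in% cs,
                                     logical(1)))
          es <- c(i, partners[sample.int(length(partners),
                                         min(sample(1:2, 1),
                                             length(partners)))])
          edges <- cbind(es, p)
          used_e[es] <- TRUE
        }
      } else { # many_to_many: recruit a partner enhancer sharing candidates
        ps <- js[sample.int(length(js), min(sample(2:3, 1), length(js)))]
        edges <- cbind(i, ps)
        partners <- which(!used_e & seq_len(nrow(enh)) != i &
                            vapply(cand, function(cs) any(ps %in% cs),
                                   logical(1)))
        if (length(partners) > 0) {
          e2 <- partners[sample.int(length(partners), 1)]
          shared <- intersect(cand[[e2]], ps)
          edges <- rbind(edges, cbind(e2, shared))
          used_e[e2] <- TRUE
        }
      }
      used_e[i] <- TRUE
      used_p[edges[, 2]] <- TRUE
      all_edges <- rbind(all_edges, edges)
    }
    # hub pass: leftover enhancers drawing a shared-promoter pattern from
    # the mix attach to promoters that already regulate, so promoters
    # accumulate higher degrees than enhancers (a pure one-to-one mix
    # plants no hubs and leaves these enhancers isolated)
    for (i in which(!used_e)) {
      js <- cand[[i]][used_p[cand[[i]]]]
      pattern <- sample(pat_names, 1, prob = config$component_topology)
      if (length(js) == 0 || pattern == "one_to_one" ||
          stats::runif(1) > 0.7) {
        n_isolated <- n_isolated + 1L
        next
      }
      k <- if (pattern == "many_to_many") 2L else 1L
      ps <- js[sample.int(length(js), min(k, length(js)))]
      all_edges <- rbind(all_edges, cbind(i, ps))
      used_e[i] <- TRUE
    }
    if (n_isolated > 0)
      message(sprintf("%d enhancer(s) left isolated (no available promoter in distance range)",
                      n_isolated))
    if (is.null(all_edges)) return(empty)
    # ground-truth components by union-find over the final edge list
    parent <- seq_len(nrow(enh) + nrow(pro))
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(all_edges))) {
      a <- find(all_edges[r, 1]); b <- find(nrow(enh) + all_edges[r, 2])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(all_edges[, 1], find, 1L)
    comp_id <- match(roots, unique(roots))
    res <- data.frame(
      enhancer_id = enh$id[all_edges[, 1]],
      gene_id = pro$id[all_edges[, 2]],
      label = 1L,
      chrom = enh$chrom[all_edges[, 1]],
      distance = abs(emid[all_edges[, 1]] - pro$tss[all_edges[, 2]]),
      component_id = comp_id, stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

#' Simulate marker signal tracks with planted enrichment
#'
#' Emits one narrowPeak-style track per marker. Peaks tile the 21 feature
#' windows of every element; their signal is baseline 1.0 plus Gaussian
#' noise, and elements participating in a positive pair additionally gain
#' `signal_effect` (decaying linearly to zero over window offsets 0, 1, 2)
#' on the configured enriched markers. Signals are floored at 0.01 so
#' every peak has positive signal. Deterministic under the configured seed.
#'
#' @param elements Output of [generate_elements()].
#' @param pairs Positive pair table from [generate_epi_network()].
#' @param config The same [synthetic_config()].
#' @return Named list of 7 data.frames (one per marker, in [epi_markers()]
#'   order) with narrowPeak columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signalValue`, `pValue`, `qValue`, `peak`.
#' @export
generate_signal_tracks <- function(elements, pairs, config) {
  stopifnot(inherits(config, "synthetic_config"))
  scheme <- window_scheme()
  pos_ids <- unique(c(pairs$enhancer_id, pairs$gene_id))
  # windows for every element, in genomic order per chromosome
  win <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
    w <- build_windows(elements[i, ], scheme, config$chrom_length)
    w$element_id <- elements$id[i]
    w$chrom <- elements$chrom[i]
    w$enriched <- elements$id[i] %in% pos_ids
    w
  }))
  tracks <- stats::setNames(vector("list", 7), epi_markers())
  with_seed(config$seed + 2L, {
    for (m in epi_markers()) {
      eff <- if (m %in% config$enriched_markers)
        ifelse(win$enriched & abs(win$offset) <= 2,
               config$signal_effect * (1 - abs(win$offset) / 3), 0)
        else 0
      val <- pmax(0.01, 1.0 + eff + stats::rnorm(nrow(win), 0, config$noise_sd))
      keep <- win$end > win$start  # drop clamped zero-width windows
      tr <- data.frame(chrom = win$chrom[keep],
                       start = win$start[keep],
                       end = win$end[keep],
                       name = sprintf("%s_%s_w%d", m, win$element_id[keep],
                                      win$offset[keep]),
                       score = 0L, strand = ".",
                       signalValue = round(val[keep], 6),
                       pValue = -1, qValue = -1, peak = -1,
                       stringsAsFactors = FALSE)
      tr <- tr[order(tr$chrom, tr$start), ]
      rownames(tr) <- NULL
      tracks[[m]] <- tr
    }
  })
  tracks
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper chaining [generate_elements()],
#' [generate_epi_network()] and [generate_signal_tracks()].
#'
#' @param config A [synthetic_config()].
#' @return An `epi_fixture` list with `elements`, `pairs`, `tracks`,
#'   `config`.
#' @export
generate_fixture <- function(config) {
  elements <- generate_elements(config)
  pairs <- generate_epi_network(elements, config)
  tracks <- generate_signal_tracks(elements, pairs, config)
  structure(list(elements = elements, pairs = pairs, tracks = tracks,
                 config = config), class = "epi_fixture")
}

#' Write a fixture to disk in standard formats
#'
#' Writes `enhancers.bed` (BED6, 0-based half-open), `tss.tsv` (1-based
#' TSS positions), `pairs.tsv`, one `<marker>.bed` narrowPeak file per
#' marker, and `manifest.json` echoing the configuration. Files
#' round-trip bit-identically through [read_fixture()].
#'
#' @param fixture An `epi_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "epi_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- fixture$elements
  enh <- el[el$etype == "enhancer", , drop = FALSE]
  bed <- data.frame(chrom = enh$chrom, start = format_bp(enh$start),
                    end = format_bp(enh$end), name = enh$id,
                    score = 0L, strand = ".")
  utils::write.table(bed, file.path(dir, "enhancers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pro <- el[el$etype == "promoter", , drop = FALSE]
  tss <- data.frame(gene_id = pro$id, chrom = pro$chrom,
                    pos = format_bp(pro$tss + 1), strand = pro$strand)
  utils::write.table(tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  utils::write.table(fixture$pairs[, c("enhancer_id", "gene_id", "label",
                                       "component_id")],
                     file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  for (m in names(fixture$tracks)) {
    tr <- fixture$tracks[[m]]
    tr$start <- format_bp(tr$start); tr$end <- format_bp(tr$end)
    utils::write.table(tr, file.path(dir, paste0(m, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(generator = "epigat synthetic fixture",
                   config = unclass(fixture$config),
                   n_elements = nrow(el), n_pairs = nrow(fixture$pairs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `enhancers` (BED intervals), `tss` (0-based TSS
#'   table), `pairs`, and `tracks` (named list per marker).
#' @export
read_fixture <- function(dir) {
  tracks <- stats::setNames(lapply(epi_markers(), function(m)
    read_track_bed(file.path(dir, paste0(m, ".bed")))), epi_markers())
  list(enhancers = read_enhancers_bed(file.path(dir, "enhancers.bed")),
       tss = read_tss_tsv(file.path(dir, "tss.tsv")),
       pairs = read_pairs_tsv(file.path(dir, "pairs.tsv")),
       tracks = tracks)
}

#' Read enhancer intervals from a BED file
#'
#' @param path BED file with at least chrom/start/end/name columns,
#'   0-based half-open.
#' @return Data.frame with `id`, `chrom`, `start`, `end`.
#' @export
read_enhancers_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 4) stop("enhancer BED needs at least 4 columns (incl. name)")
  data.frame(id = b[[4]], chrom = b[[1]], start = as.numeric(b[[2]]),
             end = as.numeric(b[[3]]), stringsAsFactors = FALSE)
}

#' Read a TSS annotation TSV
#'
#' Expects a header with columns `gene_id`, `chrom`, `pos` (1-based TSS
#' position, converted to 0-based on read) and `strand`.
#'
#' @param path TSV path.
#' @return Data.frame with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_tss_tsv <- function(path) {
  t <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot_cols(t, c("gene_id", "chrom", "pos", "strand"), "TSS table")
  data.frame(gene_id = t$gene_id, chrom = t$chrom,
             tss = as.numeric(t$pos) - 1, strand = t$strand,
             stringsAsFactors = FALSE)
}

#' Read a BENGI-style enhancer-gene pair TSV
#'
#' @param path TSV with header columns `enhancer_id`, `gene_id`, `label`
#'   (1 positive / 0 negative) and optionally more.
#' @return The pair data.frame.
#' @export
read_pairs_tsv <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot_cols(p, c("enhancer_id", "gene_id", "label"), "pair table")
  p
}

#' Read a narrowPeak-style signal track
#'
#' @param path BED file with >= 7 columns; column 7 is signalValue.
#' @return Data.frame with `chrom`, `start`, `end`, `signalValue`, sorted
#'   by chrom then start.
#' @export
read_track_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 7)
    stop("signal track needs >= 7 columns with signalValue in column 7")
  tr <- data.frame(chrom = b[[1]], start = as.numeric(b[[2]]),
                   end = as.numeric(b[[3]]),
                   signalValue = as.numeric(b[[7]]),
                   stringsAsFactors = FALSE)
  tr[order(tr$chrom, tr$start), , drop = FALSE]
}
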