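#' Select positive pairs from a BENGI-style table
#'
#' Keeps rows with `label == 1` and collapses duplicate
#' (enhancer_id, gene_id) rows, which arise when several evidence lines
#' support the same interaction.
#'
#' @param raw_pairs Data.frame with at least `enhancer_id`, `gene_id`,
#'   `label`.
#' @return The deduplicated positive subset.
#' @export
select_positives <- function(raw_pairs) {
  stopifnot_cols(raw_pairs, c("enhancer_id", "gene_id", "label"),
                 "raw pair table")
  pos <- raw_pairs[raw_pairs$label == 1, , drop = FALSE]
  pos <- pos[!duplicated(pos[, c("enhancer_id", "gene_id")]), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Map a TSS to its promoter interval
#'
#' The promoter is the 1500 bp upstream / 500 bp downstream window around
#' the transcription start site, read in the gene's direction: on the +
#' strand `[tss - 1500, tss + 500)`, on the - strand `[tss - 500,
#' tss + 1500)` (0-based half-open). Intervals are clamped to
#' `[0, chrom_length)`.
#'
#' @param tss 0-based TSS coordinate(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @param chrom_length Chromosome length for clamping (default `Inf`, no
#'   upper clamp).
#' @return Data.frame with `start`, `end`.
#' @export
promoter_from_tss <- function(tss, strand, chrom_length = Inf) {
  stopifnot(all(strand %in% c("+", "-")))
  up <- ifelse(strand == "+", 1500, 500)
  dn <- 2000 - up
  start <- pmax(0, tss - up)
  end <- pmin(chrom_length, tss + dn)
  data.frame(start = start, end = end)
}

#' Map genes to promoters for a pair table
#'
#' Joins a positive/candidate enhancer-gene table against a TSS
#' annotation, producing enhancer-promoter records. When a gene has
#' several annotated TSSs the first one in the annotation is used
#' (one canonical promoter per gene).
#'
#' @param pairs Data.frame with `gene_id`.
#' @param tss Data.frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (see [read_tss_tsv()]).
#' @param chrom_length Optional clamp bound.
#' @return `pairs` with added `chrom`, `tss`, `strand`, `prom_start`,
#'   `prom_end` columns.
#' @export
map_gene_to_promoter <- function(pairs, tss, chrom_length = Inf) {
  stopifnot_cols(tss, c("gene_id", "chrom", "tss", "strand"), "TSS table")
  tss <- tss[!duplicated(tss$gene_id), , drop = FALSE]
  idx <- match(pairs$gene_id, tss$gene_id)
  if (anyNA(idx))
    stop(sprintf("gene(s) missing from TSS annotation: %s",
                 paste(utils::head(unique(pairs$gene_id[is.na(idx)]), 5),
                       collapse = ", ")))
  pr <- promoter_from_tss(tss$tss[idx], tss$strand[idx], chrom_length)
  cbind(pairs,
        data.frame(chrom = tss$chrom[idx], tss = tss$tss[idx],
                   strand = tss$strand[idx],
                   prom_start = pr$start, prom_end = pr$end,
                   stringsAsFactors = FALSE))
}

#' Enhancer-promoter distance
#'
#' Distance from the enhancer interval midpoint to the TSS, in bp. Both
#' elements must be on the same chromosome; trans pairs are not
#' supported.
#'
#' @param enh_start,enh_end Enhancer interval (0-based half-open).
#' @param tss 0-based TSS coordinate.
#' @param enh_chrom,prom_chrom Optional chromosome names; if both given
#'   they are checked for equality.
#' @return Non-negative distance(s) in bp.
#' @export
ep_distance <- function(enh_start, enh_end, tss,
                        enh_chrom = NULL, prom_chrom = NULL) {
  if (!is.null(enh_chrom) && !is.null(prom_chrom) &&
      any(enh_chrom != prom_chrom))
    stop("enhancer and promoter on different chromosomes (trans pairs unsupported)")
  abs((enh_start + enh_end) / 2 - tss)
}

#' Filter pairs by enhancer-promoter distance
#'
#' Retains pairs whose distance lies in the closed interval `[lo, hi]`
#' (both bounds inclusive).
#'
#' @param pairs Data.frame with a `distance` column.
#' @param lo,hi Bounds in bp; defaults 42 kb and 500 kb.
#' @return Filtered pairs.
#' @export
filter_by_distance <- function(pairs, lo = 42000, hi = 500000) {
  stopifnot_cols(pairs, "distance", "pair table")
  out <- pairs[pairs$distance >= lo & pairs$distance <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample balanced negative pairs
#'
#' For each enhancer appearing in the positive set, candidate negatives
#' are promoters on the same chromosome within `[lo, hi]` of it that show
#' no known interaction (promoters absent from the positive set, so a
#' sampled pair joins an active enhancer to an interaction-free
#' promoter). Each enhancer receives a
#' quota equal to its positive count, sampled without replacement; if an
#' enhancer has fewer candidates than quota, the shortfall is
#' redistributed at random over enhancers with spare candidates. When
#' candidates run out globally the negative set ends up smaller than the
#' positive set (a warning is emitted).
#'
#' @param positives Positive pair table with `enhancer_id`, `gene_id` and
#'   enhancer coordinates `enh_start`, `enh_end`, `chrom`.
#' @param promoters Promoter universe: data.frame with `gene_id`,
#'   `chrom`, `tss`.
#' @param lo,hi Distance bounds (bp).
#' @param seed Integer seed; sampling is deterministic given it.
#' @return Data.frame of negatives with `enhancer_id`, `gene_id`,
#'   `label = 0`, `chrom`, `distance`.
#' @export
sample_negatives <- function(positives, promoters, lo = 42000, hi = 500000,
                             seed = 1L) {
  stopifnot_cols(positives, c("enhancer_id", "gene_id", "enh_start",
                              "enh_end", "chrom"), "positive table")
  stopifnot_cols(promoters, c("gene_id", "chrom", "tss"), "promoter universe")
  promoters <- promoters[!duplicated(promoters$gene_id), , drop = FALSE]
  enh <- positives[!duplicated(positives$enhancer_id),
                   c("enhancer_id", "enh_start", "enh_end", "chrom")]
  interacting <- unique(positives$gene_id)
  quota <- table(positives$enhancer_id)
  # candidate gene lists per enhancer: interaction-free promoters in range
  cand <- lapply(seq_len(nrow(enh)), function(i) {
    j <- which(promoters$chrom == enh$chrom[i] &
                 !(promoters$gene_id %in% interacting))
    d <- abs((enh$enh_start[i] + enh$enh_end[i]) / 2 - promoters$tss[j])
    j[d >= lo & d <= hi]
  })
  with_seed(seed, {
    take <- pmin(as.integer(quota[enh$enhancer_id]), lengths(cand))
    short <- sum(quota) - sum(take)
    # redistribute shortfall over enhancers with spare candidates
    while (short > 0) {
      spare <- which(lengths(cand) > take)
      if (length(spare) == 0) break
      pick <- spare[sample.int(length(spare), min(short, length(spare)))]
      take[pick] <- take[pick] + 1L
      short <- short - length(pick)
    }
    if (short > 0)
      warning(sprintf("candidate promoters exhausted: %d fewer negatives than positives",
                      short))
    out <- lapply(seq_len(nrow(enh)), function(i) {
      if (take[i] == 0) return(NULL)
      js <- cand[[i]][sample.int(length(cand[[i]]), take[i])]
      data.frame(enhancer_id = enh$enhancer_id[i],
                 gene_id = promoters$gene_id[js],
                 label = 0L, chrom = enh$chrom[i],
                 distance = abs((enh$enh_start[i] + enh$enh_end[i]) / 2 -
                                  promoters$tss[js]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(enhancer_id = character(0), gene_id = character(0),
                        label = integer(0), chrom = character(0),
                        distance = numeric(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Run the full sample-preparation pipeline
#'
#' Positive selection, gene-to-promoter mapping, distance computation and
#' filtering, and balanced negative sampling, producing the labelled
#' sample table the downstream graph is built from.
#'
#' @param raw_pairs BENGI-style pair table (`enhancer_id`, `gene_id`,
#'   `label`).
#' @param enhancers Enhancer intervals (`id`, `chrom`, `start`, `end`).
#' @param tss TSS annotation (`gene_id`, `chrom`, `tss`, `strand`).
#' @param lo,hi Distance bounds in bp.
#' @param seed Seed for negative sampling.
#' @return List with `samples` (labelled EP pairs with coordinates and
#'   distances) and `report` (row counts after each step).
#' @export
prepare_samples <- function(raw_pairs, enhancers, tss,
                            lo = 42000, hi = 500000, seed = 1L) {
  stopifnot_cols(enhancers, c("id", "chrom", "start", "end"),
                 "enhancer table")
  pos <- select_positives(raw_pairs)
  n_pos_raw <- nrow(pos)
  idx <- match(pos$enhancer_id, enhancers$id)
  if (anyNA(idx))
    stop(sprintf("enhancer id(s) missing from annotation: %s",
                 paste(utils::head(unique(pos$enhancer_id[is.na(idx)]), 5),
                       collapse = ", ")))
  pos$enh_start <- enhancers$start[idx]
  pos$enh_end <- enhancers$end[idx]
  pos$enh_chrom <- enhancers$chrom[idx]
  pos <- map_gene_to_promoter(pos, tss)
  if (any(pos$enh_chrom != pos$chrom))
    stop("trans (cross-chromosome) pairs are unsupported")
  pos$distance <- ep_distance(pos$enh_start, pos$enh_end, pos$tss)
  pos <- filter_by_distance(pos, lo, hi)
  neg <- sample_negatives(pos, tss, lo, hi, seed)
  if (nrow(neg) > 0) {
    neg <- map_gene_to_promoter(neg[, c("enhancer_id", "gene_id", "label",
                                        "chrom", "distance")], tss)
    jdx <- match(neg$enhancer_id, enhancers$id)
    neg$enh_start <- enhancers$start[jdx]
    neg$enh_end <- enhancers$end[jdx]
  }
  keep <- c("enhancer_id", "gene_id", "label", "chrom", "distance",
            "enh_start", "enh_end", "tss", "strand",
            "prom_start", "prom_end")
  samples <- rbind(pos[, keep],
                   if (nrow(neg) > 0) neg[, keep])
  rownames(samples) <- NULL
  list(samples = samples,
       report = list(n_raw = nrow(raw_pairs), n_positive_raw = n_pos_raw,
                     n_positive = sum(samples$label == 1),
                     n_negative = sum(samples$label == 0)))
}
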