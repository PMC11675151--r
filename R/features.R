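#' Window scheme for feature extraction
#'
#' @param window_size Flank window width in bp (default 2000, the
#'   promoter length).
#' @param n_flank Number of flank windows per side (default 10), giving
#'   `2 * n_flank + 1` windows in total (21 at defaults: the element
#'   itself plus 10 windows outward on each side).
#' @return A `window_scheme` list.
#' @export
window_scheme <- function(window_size = 2000, n_flank = 10L) {
  stopifnot(window_size > 0, n_flank >= 0)
  structure(list(window_size = as.numeric(window_size),
                 n_flank = as.integer(n_flank)),
            class = "window_scheme")
}

#' Build the ordered windows around an element
#'
#' Window offset 0 is the element interval itself (variable length);
#' offsets -n..-1 and +1..+n are abutting fixed-width windows marching
#' outward from the element boundaries. Windows are clamped to
#' `[0, chrom_length)`; fully clamped windows become zero-width but are
#' still returned, so the count is always `2 * n_flank + 1`.
#'
#' @param element One-row data.frame (or list) with `start`, `end`.
#' @param scheme A [window_scheme()].
#' @param chrom_length Chromosome length in bp.
#' @return Data.frame with `offset`, `start`, `end`, ordered by offset.
#' @export
build_windows <- function(element, scheme = window_scheme(),
                          chrom_length = Inf) {
  w <- scheme$window_size
  n <- scheme$n_flank
  off <- seq.int(-n, n)
  start <- ifelse(off < 0, element$start + off * w,
           ifelse(off == 0, element$start, element$end + (off - 1) * w))
  end <- ifelse(off < 0, element$start + (off + 1) * w,
         ifelse(off == 0, element$end, element$end + off * w))
  start <- pmin(pmax(start, 0), chrom_length)
  end <- pmin(pmax(end, 0), chrom_length)
  data.frame(offset = off, start = start, end = end)
}

# 0-based half-open intervals -> IRanges (1-based closed); zero-width
# intervals are dropped.
to_iranges <- function(start, end) {
  keep <- end > start
  IRanges::IRanges(start = start[keep] + 1, end = end[keep])
}

from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Mask other regulatory elements out of windows
#'
#' Returns the sub-intervals of each window not covered by any other
#' annotated element, so that signal aggregation never reads signal
#' belonging to a neighbouring enhancer or promoter.
#'
#' @param windows Data.frame of windows (`start`, `end`, 0-based
#'   half-open); typically from [build_windows()].
#' @param other_elements Data.frame of intervals (`start`, `end`) to
#'   exclude; must not contain the focal element.
#' @return Data.frame with `window` (row index into `windows`), `start`,
#'   `end` of each unmasked piece. Fully masked or zero-width windows
#'   contribute no rows.
#' @export
mask_elements <- function(windows, other_elements) {
  others <- IRanges::reduce(to_iranges(other_elements$start,
                                       other_elements$end))
  win <- to_iranges(windows$start, windows$end)
  win_idx <- which(windows$end > windows$start)
  if (length(win) == 0)
    return(data.frame(window = integer(0), start = numeric(0),
                      end = numeric(0)))
  hits <- IRanges::findOverlaps(win, others)
  touched <- unique(S4Vectors::queryHits(hits))
  pieces <- lapply(seq_along(win), function(k) {
    if (!(k %in% touched)) return(cbind(k, from_iranges(win[k])))
    sd <- IRanges::setdiff(win[k], others)
    if (length(sd) == 0) return(NULL)
    cbind(k, from_iranges(sd))
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces))
    return(data.frame(window = integer(0), start = numeric(0),
                      end = numeric(0)))
  data.frame(window = win_idx[pieces[, 1]], start = pieces$start,
             end = pieces$end)
}

#' Aggregate track signal over an interval set
#'
#' Per-base mean of peak `signalValue` over the interval set: each base
#' covered by a peak contributes that peak's signal, uncovered bases
#' contribute 0, and the sum is divided by the total width of the set.
#' Returns 0 for an empty set or when no peak overlaps. Peaks within one
#' track are assumed non-overlapping.
#'
#' @param track Data.frame with `start`, `end`, `signalValue` (one
#'   chromosome's worth).
#' @param intervals Data.frame with `start`, `end` (0-based half-open).
#' @return A single numeric value.
#' @export
aggregate_signal <- function(track, intervals) {
  iv <- to_iranges(intervals$start, intervals$end)
  denom <- sum(IRanges::width(iv))
  if (denom == 0) return(0)
  tr <- to_iranges(track$start, track$end)
  sig <- track$signalValue[track$end > track$start]
  hits <- IRanges::findOverlaps(iv, tr)
  if (length(hits) == 0) return(0)
  ov <- IRanges::width(IRanges::pintersect(
    iv[S4Vectors::queryHits(hits)], tr[S4Vectors::subjectHits(hits)]))
  sum(ov * sig[S4Vectors::subjectHits(hits)]) / denom
}

#' Build feature matrices for a set of elements
#'
#' For every element: build its 21 windows, mask all other elements out
#' of them, and aggregate each marker track over the unmasked pieces,
#' yielding one `7 x 21` matrix per element (markers in [epi_markers()]
#' order as rows, window offsets -10..+10 as columns).
#'
#' @param elements Data.frame with `id`, `chrom`, `start`, `end` for
#'   every element to featurise (enhancer intervals and promoter
#'   intervals together, so masking sees all annotated elements).
#' @param tracks Named list of marker tracks (see [read_track_bed()]);
#'   must contain every marker in [epi_markers()].
#' @param scheme A [window_scheme()].
#' @param chrom_length Chromosome length (scalar or named vector by
#'   chromosome) used for window clamping.
#' @param stats Optional [fit_normalization()] output; if given, matrices
#'   are normalized before being returned.
#' @return Named list of matrices, one per element id.
#' @export
featurize_all <- function(elements, tracks, scheme = window_scheme(),
                          chrom_length = Inf, stats = NULL) {
  stopifnot_cols(elements, c("id", "chrom", "start", "end"),
                 "element table")
  missing <- setdiff(epi_markers(), names(tracks))
  if (length(missing) > 0)
    stop(sprintf("missing marker track(s): %s",
                 paste(missing, collapse = ", ")))
  markers <- epi_markers()
  n_win <- 2L * scheme$n_flank + 1L
  out <- stats::setNames(vector("list", nrow(elements)), elements$id)
  chrom_len <- function(chr) {
    if (length(chrom_length) == 1 && is.null(names(chrom_length)))
      chrom_length else chrom_length[[chr]]
  }
  for (chr in unique(elements$chrom)) {
    idx <- which(elements$chrom == chr)
    el_chr <- elements[idx, , drop = FALSE]
    trk_chr <- lapply(tracks[markers], function(t)
      t[t$chrom == chr, , drop = FALSE])
    # unmasked window pieces for every element on this chromosome
    pieces <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      wins <- build_windows(el_chr[k, ], scheme, chrom_len(chr))
      pcs <- mask_elements(wins, el_chr[-k, c("start", "end"), drop = FALSE])
      if (nrow(pcs) > 0) pcs$elem <- k
      pieces[[k]] <- pcs
    }
    pieces <- do.call(rbind, pieces[lengths(pieces) > 0 &
                                      vapply(pieces, nrow, 1L) > 0])
    mats <- lapply(seq_along(idx), function(k)
      matrix(0, length(markers), n_win,
             dimnames = list(markers, seq.int(-scheme$n_flank,
                                              scheme$n_flank))))
    if (!is.null(pieces) && nrow(pieces) > 0) {
      piv <- to_iranges(pieces$start, pieces$end)
      pw <- IRanges::width(piv)
      key <- (pieces$elem - 1L) * n_win + pieces$window
      denom <- rowsum(pw, key)
      for (m in markers) {
        t <- trk_chr[[m]]
        tir <- to_iranges(t$start, t$end)
        sig <- t$signalValue[t$end > t$start]
        hits <- IRanges::findOverlaps(piv, tir)
        if (length(hits) == 0) next
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        ov <- IRanges::width(IRanges::pintersect(piv[q], tir[s]))
        num <- rowsum(ov * sig[s], key[q])
        kk <- as.integer(rownames(num))
        vals <- as.vector(num) / as.vector(denom[match(kk, as.integer(rownames(denom))), ])
        ek <- (kk - 1L) %/% n_win + 1L
        wk <- (kk - 1L) %% n_win + 1L
        for (r in seq_along(kk)) mats[[ek[r]]][m, wk[r]] <- vals[r]
      }
    }
    for (k in seq_along(idx)) out[[idx[k]]] <- mats[[k]]
  }
  if (!is.null(stats)) out <- lapply(out, apply_normalization, stats = stats)
  out
}

#' Feature matrix for a single element
#'
#' Convenience wrapper around [featurize_all()].
#'
#' @param element One-row element data.frame (`id`, `chrom`, `start`,
#'   `end`).
#' @param tracks,scheme,chrom_length,stats See [featurize_all()].
#' @param other_elements Data.frame of other element intervals used for
#'   masking (may be empty).
#' @return A `7 x 21` matrix.
#' @export
featurize <- function(element, tracks, other_elements = NULL,
                      scheme = window_scheme(), chrom_length = Inf,
                      stats = NULL) {
  el <- element[, c("id", "chrom", "start", "end"), drop = FALSE]
  if (!is.null(other_elements) && nrow(other_elements) > 0) {
    oth <- data.frame(id = sprintf(".other_%d", seq_len(nrow(other_elements))),
                      chrom = element$chrom,
                      start = other_elements$start,
                      end = other_elements$end)
    el <- rbind(el, oth)
  }
  featurize_all(el, tracks, scheme, chrom_length, stats)[[element$id]]
}

#' Fit feature normalization statistics on training matrices
#'
#' Two-stage normalization fitted per marker (row) over every entry of
#' every training matrix: first a z-score (training mean and sd), then a
#' min-max rescale of the z-scores to `[0, 1]` (training extremes).
#' Markers constant on the training set (sd = 0) map to 0.
#'
#' @param matrices List of `7 x 21` feature matrices from the training
#'   split only.
#' @param fitted_on Tag recording which split the stats come from.
#' @return A `norm_stats` object with per-marker `mean`, `sd`, `min`,
#'   `max`.
#' @export
fit_normalization <- function(matrices, fitted_on = "train") {
  if (length(matrices) == 0) stop("empty training set")
  markers <- rownames(matrices[[1]])
  vals <- do.call(cbind, matrices)  # markers x (21 * n)
  mu <- rowMeans(vals)
  sd <- apply(vals, 1, stats::sd)
  z <- (vals - mu) / ifelse(sd > 0, sd, 1)
  structure(list(mean = mu, sd = sd,
                 min = apply(z, 1, min), max = apply(z, 1, max),
                 fitted_on = fitted_on, markers = markers),
            class = "norm_stats")
}

#' Apply fitted normalization to a feature matrix
#'
#' @param matrix_ A `7 x 21` feature matrix.
#' @param stats A [fit_normalization()] result.
#' @return Matrix of the same shape with all entries in `[0, 1]` (values
#'   outside the training range are clipped).
#' @export
apply_normalization <- function(matrix_, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  z <- (matrix_ - stats$mean) / ifelse(stats$sd > 0, stats$sd, 1)
  rng <- stats$max - stats$min
  out <- (z - stats$min) / ifelse(rng > 0, rng, 1)
  out[stats$sd == 0 | rng == 0, ] <- 0
  pmin(pmax(out, 0), 1)
}

#' Derive the element table of a sample set
#'
#' Collects the unique enhancers and promoters referenced by a prepared
#' sample table into one element table suitable for [featurize_all()].
#'
#' @param samples Output `samples` of [prepare_samples()].
#' @return Data.frame with `id`, `etype`, `chrom`, `start`, `end`.
#' @export
elements_from_samples <- function(samples) {
  enh <- samples[!duplicated(samples$enhancer_id), ]
  pro <- samples[!duplicated(samples$gene_id), ]
  rbind(data.frame(id = enh$enhancer_id, etype = "enhancer",
                   chrom = enh$chrom, start = enh$enh_start,
                   end = enh$enh_end, stringsAsFactors = FALSE),
        data.frame(id = pro$gene_id, etype = "promoter",
                   chrom = pro$chrom, start = pro$prom_start,
                   end = pro$prom_end, stringsAsFactors = FALSE))
}
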