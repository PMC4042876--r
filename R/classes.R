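#' Order genes by the position of their dominant peak
#'
#' For each row of an anchored TSS matrix (columns = oriented offsets, see
#' [anchored_matrix()]), finds the offset of the maximum signal (tie-break:
#' the 5'-most column) and ranks genes by increasing offset, i.e. from the
#' most 5' (upstream) accumulation to the most 3'. All-zero (or constant)
#' rows have no defined maximum and are dropped with a message.
#'
#' @param matrix Anchored profile matrix over TSS +/- flank, oriented.
#' @return Data frame `gene_id`, `offset` (bp, left edge of the maximal
#'   column; negative = upstream), `rank`, sorted by offset then gene id.
#' @export
order_by_max_offset <- function(matrix) {
  offs <- as.integer(colnames(matrix))
  flat <- apply(matrix, 1L, function(r) max(r) == min(r))
  if (any(flat)) {
    message(sum(flat), " gene(s) dropped: no defined maximum")
    matrix <- matrix[!flat, , drop = FALSE]
  }
  offset <- offs[apply(matrix, 1L, which.max)]
  ord <- order(offset, rownames(matrix))
  data.frame(gene_id = rownames(matrix)[ord],
             offset = offset[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Assign promoter classes from peak offsets
#'
#' Three classes by the oriented offset of the dominant peak: class I
#' (`offset < cut1`, most 5'), class II (`cut1 <= offset <= cut2`,
#' TSS-proximal) and class III (`offset > cut2`, most 3').
#'
#' @param assignments Data frame with an `offset` column (from
#'   [order_by_max_offset()]).
#' @param cut1,cut2 Class boundaries in bp (defaults -100 and +100).
#' @return `assignments` with a `class` column (`"I"`, `"II"`, `"III"`).
#' @export
assign_classes <- function(assignments, cut1 = -100, cut2 = 100) {
  stopifnot(cut1 < cut2)
  cls <- ifelse(assignments$offset < cut1, "I",
                ifelse(assignments$offset > cut2, "III", "II"))
  assignments$class <- cls
  assignments
}

#' Back-solve class cuts from target proportions
#'
#' Utility for matching observed class-size proportions: returns cuts
#' `(cut1, cut2)` placed halfway between the order statistics that split the
#' offsets into the requested proportions.
#'
#' @param offsets Numeric vector of peak offsets.
#' @param proportions Length-3 vector summing to 1 (class I, II, III).
#' @return Numeric `c(cut1, cut2)`.
#' @export
cuts_for_proportions <- function(offsets, proportions) {
  stopifnot(length(proportions) == 3L,
            abs(sum(proportions) - 1) < 1e-8)
  s <- sort(offsets)
  n <- length(s)
  n1 <- max(1L, min(n - 2L, round(proportions[1] * n)))
  n2 <- max(n1 + 1L, min(n - 1L, round((proportions[1] + proportions[2]) * n)))
  c((s[n1] + s[n1 + 1L]) / 2, (s[n2] + s[n2 + 1L]) / 2)
}

#' Select genes with dominant antisense transcription
#'
#' Two gates applied to class I genes around their detected dominant-peak
#' positions: (1) the antisense short-ssRNA mean over the oriented window
#' `[peak - 50, peak + 100)` must be significant under the usual
#' two-Gaussian mixture threshold across genes; (2) antisense must exceed
#' sense, tested per gene by a one-sided Mann-Whitney-Wilcoxon test on the
#' per-bin values of the window (antisense-strand bins vs sense-strand
#' bins), kept at `p < alpha`. Antisense means the ssRNA strand opposite to
#' the gene.
#'
#' @param genes Gene table (typically the class I subset).
#' @param peak_pos Named numeric vector: genomic position (bp) of each
#'   gene's dominant peak (names = gene ids).
#' @param ssrna_plus,ssrna_minus Stranded short-ssRNA [genome_track()]s
#'   (fine bins, e.g. 10 bp).
#' @param as_threshold Optional explicit antisense-mean threshold; when
#'   `NULL` it is fitted with [fit_two_gaussian_threshold()].
#' @param alpha MWW significance level (default 0.05).
#' @return List: `selected` (gene ids), `as_means`, `mww_p` (named vectors),
#'   `threshold`, `fit` (NULL if an explicit threshold was supplied).
#' @export
select_as_dominant <- function(genes, peak_pos, ssrna_plus, ssrna_minus,
                               as_threshold = NULL, alpha = 0.05) {
  pos <- peak_pos[genes$gene_id]
  if (anyNA(pos)) stop("peak_pos missing for some genes")
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, pos - 50, pos - 100)
  win_end <- ifelse(plus, pos + 100, pos + 50)
  B <- ssrna_plus$bin_size
  lens <- track_chrom_lengths(ssrna_plus)
  inb <- win_start >= 0 & win_end <= lens[genes$chrom]
  if (any(!inb)) {
    message(sum(!inb), " gene(s) dropped: peak window out of bounds")
  }
  genes <- genes[inb, , drop = FALSE]
  plus <- plus[inb]
  win <- data.frame(chrom = genes$chrom,
                    start = win_start[inb], end = win_end[inb])
  as_track_of <- function(i) if (plus[i]) ssrna_minus else ssrna_plus
  s_track_of <- function(i) if (plus[i]) ssrna_plus else ssrna_minus

  as_means <- vapply(seq_len(nrow(genes)), function(i) {
    region_means(as_track_of(i), win[i, , drop = FALSE])
  }, numeric(1))
  names(as_means) <- genes$gene_id

  fit <- NULL
  if (is.null(as_threshold)) {
    fit <- fit_two_gaussian_threshold(as_means)
    as_threshold <- fit$tau
  }
  sig <- as_means >= as_threshold

  mww_p <- rep(NA_real_, nrow(genes))
  names(mww_p) <- genes$gene_id
  for (i in which(sig)) {
    a_bins <- track_values_bp(as_track_of(i), win$chrom[i],
                              win$start[i], win$end[i])
    a_bins <- a_bins[seq(1L, length(a_bins), by = B)]
    s_bins <- track_values_bp(s_track_of(i), win$chrom[i],
                              win$start[i], win$end[i])
    s_bins <- s_bins[seq(1L, length(s_bins), by = B)]
    mww_p[i] <- suppressWarnings(
      stats::wilcox.test(a_bins, s_bins, alternative = "greater")$p.value)
  }
  selected <- genes$gene_id[sig & !is.na(mww_p) & mww_p < alpha]
  list(selected = selected, as_means = as_means, mww_p = mww_p,
       threshold = as_threshold, fit = fit)
}

#' Genomic position of an oriented TSS offset
#'
#' Maps oriented peak offsets (as reported by [order_by_max_offset()],
#' i.e. the 5'-most edge of the summit bin) to genomic coordinates: for a
#' plus-strand gene `tss + offset`, for a minus-strand gene
#' `tss - offset - bin` (the left edge of the bin whose oriented label is
#' `offset`). Peak positions in this convention are directly comparable to
#' [isoform_peak_distances()] output.
#'
#' @param genes Gene table.
#' @param offsets Oriented offsets in bp (aligned with `genes`).
#' @param bin Bin size of the underlying track.
#' @return Named numeric vector of genomic positions (names = gene ids).
#' @export
offset_to_genomic <- function(genes, offsets, bin) {
  tss <- tss_position(genes)
  pos <- ifelse(genes$strand == "+", tss + offsets, tss - offsets - bin)
  stats::setNames(pos, genes$gene_id)
}

# left edge (bp) of the maximal bin of `track` within [start, end);
# tie-break toward the 5' side of the given strand
max_bin_position <- function(track, chrom, start, end, strand = "+") {
  B <- track$bin_size
  v <- track_values_bp(track, chrom, start, end)
  v <- v[seq(1L, length(v), by = B)]
  if (strand == "-") {
    i <- length(v) - which.max(rev(v)) + 1L  # 5'-most for minus = rightmost
  } else {
    i <- which.max(v)
  }
  start + (i - 1L) * B
}

#' Distances of isoform maxima to the Pol II maximum
#'
#' For each gene and each mark track, the maximum is searched in the
#' oriented window `[tyr1p_pos - search, tyr1p_pos + search]` and its signed
#' distance to the gene's Pol II maximum computed. Positive distances mean
#' the mark's maximum lies beyond Pol II in the antisense direction (further
#' from the TSS on the upstream side); negative, between Pol II and the
#' TSS. A mark is colocalized when `|distance| <= coloc_tol`.
#'
#' @param mark_tracks Named list of [genome_track()]s (fine bins, e.g. 10 bp).
#' @param genes Gene table.
#' @param tyr1p_pos,polii_pos Named numeric vectors of genomic peak
#'   positions per gene id.
#' @param search Half-width of the search window, bp (default 100).
#' @param coloc_tol Colocalization tolerance, bp (default = one bin).
#' @return List: `records` (data frame gene_id, mark, mark_pos,
#'   distance_to_polii, distance_to_tyr1p, category) and `counts`
#'   (mark x {before, colocalized, after} table).
#' @export
isoform_peak_distances <- function(mark_tracks, genes, tyr1p_pos, polii_pos,
                                   search = 100, coloc_tol = NULL) {
  if (is.null(coloc_tol)) coloc_tol <- mark_tracks[[1L]]$bin_size
  recs <- list()
  for (mark in names(mark_tracks)) {
    track <- mark_tracks[[mark]]
    lens <- track_chrom_lengths(track)
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      tp <- tyr1p_pos[[gid]]
      pp <- polii_pos[[gid]]
      if (is.null(tp) || is.null(pp) || is.na(tp) || is.na(pp)) next
      ws <- tp - search; we <- tp + search
      if (ws < 0 || we > lens[genes$chrom[i]]) next
      mp <- max_bin_position(track, genes$chrom[i], ws, we, genes$strand[i])
      sign <- if (genes$strand[i] == "+") 1 else -1
      d_pol <- sign * (pp - mp)
      d_tyr <- sign * (tp - mp)
      category <- if (abs(d_pol) <= coloc_tol) "colocalized"
                  else if (d_pol > 0) "after" else "before"
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = gid, mark = mark, mark_pos = mp,
        distance_to_polii = d_pol, distance_to_tyr1p = d_tyr,
        category = category, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  counts <- table(factor(records$mark, levels = names(mark_tracks)),
                  factor(records$category,
                         levels = c("before", "colocalized", "after")))
  list(records = records, counts = counts)
}

#' Kolmogorov-Smirnov test of a distance distribution against background
#'
#' Two-sample KS on the raw (unbinned) distances; the returned histograms
#' (fixed-width bins, default 10 bp) are for display/emission only and play
#' no part in the test.
#'
#' @param distances Numeric vector (n >= 10).
#' @param background Numeric vector (n >= 10), e.g. distances recomputed on
#'   windows far from any annotation.
#' @param bin Histogram bin width in bp.
#' @return List: `D`, `p`, `hist` (data frame mid, count_signal,
#'   count_background).
#' @export
distance_background_test <- function(distances, background, bin = 10) {
  if (length(background) == 0L) stop("empty background sample")
  stopifnot(length(distances) >= 10L, length(background) >= 10L)
  ks <- suppressWarnings(stats::ks.test(distances, background))
  rng <- range(c(distances, background))
  breaks <- seq(floor(rng[1] / bin) * bin, ceiling(rng[2] / bin) * bin + bin,
                by = bin)
  h1 <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(background, breaks = breaks, plot = FALSE)
  list(D = unname(ks$statistic), p = ks$p.value,
       hist = data.frame(mid = h1$mids, count_signal = h1$counts,
                         count_background = h2$counts))
}
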