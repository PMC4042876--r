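#' Anchored signal matrix around oriented positions
#'
#' One row per anchor, columns covering `[anchor - flank, anchor + flank)`
#' resampled onto the track's bin grid in the anchor's 5'->3' orientation:
#' for minus-strand anchors the row is reversed so column 1 is always the
#' 5'-most (upstream) position. Unstranded anchors (e.g. enhancer centres)
#' keep genomic orientation. Column `j` holds the per-bp mean of the signal
#' over the j-th `bin_size`-wide slice of the window, so row means equal
#' [region_means()] on the same windows.
#'
#' @param track A [genome_track()].
#' @param anchors Data frame with columns `chrom`, `pos` (0-based bp),
#'   optional `strand` (`"+"`, `"-"`; missing or `"*"` = unstranded) and
#'   optional `id` for row names.
#' @param flank Half-window in bp; must be a multiple of the bin size.
#' @return Numeric matrix with `2 * flank / bin_size` columns; the column
#'   names are the oriented offsets (bp, left edge of each slice).
#' @export
anchored_matrix <- function(track, anchors, flank) {
  B <- track$bin_size
  if (flank %% B != 0L) stop("flank must be a multiple of the bin size")
  ncol <- 2L * flank %/% B
  n <- nrow(anchors)
  out <- matrix(0, nrow = n, ncol = ncol)
  stranded <- "strand" %in% names(anchors)
  for (i in seq_len(n)) {
    bp <- track_values_bp(track, anchors$chrom[i],
                          anchors$pos[i] - flank, anchors$pos[i] + flank)
    row <- .colMeans(matrix(bp, nrow = B), B, ncol)
    if (stranded && !is.na(anchors$strand[i]) && anchors$strand[i] == "-") {
      row <- rev(row)
    }
    out[i, ] <- row
  }
  colnames(out) <- seq.int(-flank, flank - B, by = B)
  if ("id" %in% names(anchors)) rownames(out) <- anchors$id
  out
}

#' Gene anchors for [anchored_matrix()]
#'
#' @param genes Gene table.
#' @param anchor `"tss"` or `"tes"`.
#' @return Anchor data frame (`chrom`, `pos`, `strand`, `id`).
#' @export
gene_anchors <- function(genes, anchor = c("tss", "tes")) {
  anchor <- match.arg(anchor)
  pos <- if (anchor == "tss") tss_position(genes) else tes_position(genes)
  data.frame(chrom = genes$chrom, pos = pos, strand = genes$strand,
             id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Composite length-normalised gene profile
#'
#' Per gene, the body signal (bin values between TSS and TES, 5'->3') is
#' linearly interpolated onto `body_points` equally spaced points; the
#' upstream half of the TSS flank window (`[TSS - flank, TSS)`) is prepended
#' and the downstream half of the TES window (`[TES, TES + flank)`)
#' appended, both at bin resolution. Rows are averaged column-wise into one
#' curve.
#'
#' @param track A [genome_track()].
#' @param genes Gene table (non-empty; genes longer than one bin).
#' @param flank Flank in bp (multiple of the bin size).
#' @param body_points Number of interpolated body points (default 1000).
#' @return List with `curve` (numeric vector of length
#'   `flank/bin + body_points + flank/bin`), `matrix` (per-gene rows) and
#'   `offsets` (axis labels: negative bp upstream, 1..body_points body,
#'   positive bp downstream).
#' @export
composite_gene_profile <- function(track, genes, flank = 1000,
                                   body_points = 1000L) {
  if (nrow(genes) == 0L) stop("empty gene list")
  B <- track$bin_size
  if (flank %% B != 0L) stop("flank must be a multiple of the bin size")
  fb <- flank %/% B
  n <- nrow(genes)
  out <- matrix(0, nrow = n, ncol = 2L * fb + body_points)
  for (i in seq_len(n)) {
    plus <- genes$strand[i] == "+"
    s <- genes$start[i]; e <- genes$end[i]
    body_bp <- track_values_bp(track, genes$chrom[i], s, e)
    up_bp <- if (plus) track_values_bp(track, genes$chrom[i], s - flank, s)
             else track_values_bp(track, genes$chrom[i], e, e + flank)
    dn_bp <- if (plus) track_values_bp(track, genes$chrom[i], e, e + flank)
             else track_values_bp(track, genes$chrom[i], s - flank, s)
    if (!plus) {
      body_bp <- rev(body_bp); up_bp <- rev(up_bp); dn_bp <- rev(dn_bp)
    }
    up <- .colMeans(matrix(up_bp, nrow = B), B, fb)
    dn <- .colMeans(matrix(dn_bp, nrow = B), B, fb)
    # body at bin resolution (last partial bin contributes its mean)
    nb <- ceiling(length(body_bp) / B)
    pad <- c(body_bp, rep(NA_real_, nb * B - length(body_bp)))
    bm <- matrix(pad, nrow = B)
    body <- .colMeans(bm, B, nb, na.rm = TRUE)
    if (nb == 1L) {
      interp <- rep(body, body_points)
    } else {
      centers <- (seq_len(nb) - 0.5) / nb
      xout <- seq(0, 1, length.out = body_points)
      interp <- stats::approx(centers, body, xout = xout, rule = 2)$y
    }
    out[i, ] <- c(up, interp, dn)
  }
  rownames(out) <- genes$gene_id
  offsets <- c(seq.int(-flank, -B, by = B), seq_len(body_points),
               seq.int(B, flank, by = B))
  list(curve = colMeans(out), matrix = out, offsets = offsets)
}

#' Rank-stratified average profiles
#'
#' Splits rows into the top 5\%, the 5-20\% band and the bottom 5\% by a
#' ranking value (descending; ties keep the stable input row order) and
#' returns the column-wise mean curve of each slice.
#'
#' @param matrix Profile matrix (rows = genes/regions).
#' @param ranking Numeric vector aligned with the rows.
#' @return List of curves `top5`, `mid5_20`, `bottom5` and the slice row
#'   indices.
#' @export
rank_strata_profiles <- function(matrix, ranking) {
  n <- nrow(matrix)
  stopifnot(length(ranking) == n)
  if (n < 20L) stop("need at least 20 rows for 5% strata")
  ord <- order(-ranking)  # stable for ties
  n5 <- max(1L, floor(n * 0.05))
  n20 <- floor(n * 0.20)
  top5 <- ord[seq_len(n5)]
  mid <- ord[seq.int(n5 + 1L, n20)]
  bottom5 <- ord[seq.int(n - n5 + 1L, n)]
  list(top5 = colMeans(matrix[top5, , drop = FALSE]),
       mid5_20 = colMeans(matrix[mid, , drop = FALSE]),
       bottom5 = colMeans(matrix[bottom5, , drop = FALSE]),
       idx = list(top5 = top5, mid5_20 = mid, bottom5 = bottom5))
}

#' Binary AT/GC content matrix
#'
#' Converts equal-length oriented sequences into a binary matrix for a
#' motif class: `W` scores weak bases (A or T), `S` strong bases (G or C).
#' `N` is 0 in both classes; any other character is an error. Input is
#' case-insensitive.
#'
#' @param sequences Character vector of equal-length sequences (already
#'   oriented 5'->3'), optionally named.
#' @param motif_class `"W"` or `"S"`.
#' @return Binary integer matrix, one row per sequence.
#' @export
sequence_content_matrix <- function(sequences, motif_class = c("W", "S")) {
  motif_class <- match.arg(motif_class)
  lens <- nchar(sequences)
  stopifnot(length(unique(lens)) == 1L)
  chars <- toupper(do.call(rbind, strsplit(sequences, "", fixed = TRUE)))
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequences may only contain A, C, G, T or N")
  }
  hit <- if (motif_class == "W") chars %in% c("A", "T")
         else chars %in% c("G", "C")
  out <- matrix(as.integer(hit), nrow = length(sequences))
  rownames(out) <- names(sequences)
  out
}

#' Spearman correlation of per-region mean signals
#'
#' Computes each track's mean signal per region and returns the matrix of
#' pairwise Spearman rank correlations. Used both for replicate
#' reproducibility (whole-gene windows) and for cross-correlation of marks
#' at promoter sections or enhancer centres.
#'
#' @param tracks Named list of [genome_track()] objects.
#' @param regions Region data frame (`chrom`, `start`, `end`), e.g. from
#'   [standard_window()] or enhancer centres +/- 2000 bp.
#' @return List with `rho` (correlation matrix) and `means` (region x track
#'   matrix). Tracks that are constant across regions give `NA` correlations
#'   with a warning.
#' @export
region_spearman <- function(tracks, regions) {
  stopifnot(length(tracks) >= 2L, nrow(regions) >= 3L)
  means <- vapply(tracks, region_means, numeric(nrow(regions)),
                  regions = regions)
  const <- apply(means, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant mean vector(s): ",
            paste(names(tracks)[const], collapse = ", "),
            "; Spearman rho undefined")
  }
  rho <- suppressWarnings(stats::cor(means, method = "spearman"))
  list(rho = rho, means = means)
}
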