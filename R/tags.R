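#' Aligned tags and paired fragments
#'
#' Single-end tags are data frames with columns `chrom`, `start`, `strand`
#' where `start` is the 0-based genomic coordinate of the read's 5' base
#' (for a minus-strand read this is its rightmost base). Paired fragments
#' are data frames with `chrom`, `start`, `end` (0-based half-open spans).
#' @name tagset
NULL

#' Remove artefactual tag piles
#'
#' PCR duplicates and collapsed repeats produce towers of tags sharing one
#' (chromosome, position, strand) coordinate. At most `max_per_position`
#' tags are retained per coordinate. With `"auto"`, the cap is the smallest
#' k whose Poisson upper-tail probability falls below `p_cut` given the
#' genome-wide per-position tag density `lambda = n_tags / (2 *
#' genome_size)` (two strands): piles deeper than expected by chance at that
#' density are truncated.
#'
#' @param tags Single-end tag table (see [tagset]).
#' @param max_per_position Positive integer cap, or `"auto"`.
#' @param genome_size Total genome length in bp (required for `"auto"`).
#' @param p_cut Poisson tail probability cutoff for `"auto"` (default 1e-6).
#' @return Filtered tag table (order of retained tags preserved).
#' @export
filter_tag_piles <- function(tags, max_per_position = "auto",
                             genome_size = NULL, p_cut = 1e-6) {
  if (nrow(tags) == 0L) {
    warning("empty tag set")
    return(tags)
  }
  if (identical(max_per_position, "auto")) {
    if (is.null(genome_size)) stop("genome_size required for auto threshold")
    lambda <- nrow(tags) / (2 * genome_size)
    k <- pile_threshold(lambda, p_cut)
  } else {
    k <- as.integer(max_per_position)
    stopifnot(k >= 1L)
  }
  key <- paste(tags$chrom, tags$start, tags$strand)
  occ <- stats::ave(seq_len(nrow(tags)), key, FUN = seq_along)
  tags[occ <= k, , drop = FALSE]
}

#' Poisson pile cap
#'
#' Smallest k with `P(Poisson(lambda) >= k) < p_cut`.
#' @param lambda Expected tags per (position, strand).
#' @param p_cut Tail probability cutoff.
#' @return Integer cap (at least 1).
#' @export
pile_threshold <- function(lambda, p_cut = 1e-6) {
  k <- 1L
  while (stats::ppois(k - 1L, lambda, lower.tail = FALSE) >= p_cut) {
    k <- k + 1L
  }
  k
}

#' Estimate the fragment length in silico
#'
#' Scans shifts from `read_length` to `max_shift` and returns the one
#' maximising the correlation between the binned density of forward-read 5'
#' ends and the binned density of reverse-read 5' ends shifted back by that
#' amount (strand cross-correlation). Ties break to the smallest shift, so
#' degenerate inputs return the `read_length` lower bound.
#'
#' @param tags Single-end tag table with both strands present.
#' @param max_shift Largest shift scanned, bp.
#' @param read_length Read length, bp (lower bound of the scan).
#' @param grid Scan resolution, bp (default 10).
#' @return Estimated fragment length in bp.
#' @export
estimate_elongation <- function(tags, max_shift, read_length, grid = 10L) {
  if (max_shift < read_length) stop("max_shift must be >= read_length")
  strands <- unique(tags$strand)
  if (!all(c("+", "-") %in% strands)) {
    stop("both strands are required to estimate the fragment length")
  }
  from <- ceiling(read_length / grid) * grid
  shifts <- c(read_length, if (from <= max_shift) seq.int(from, max_shift,
                                                          by = grid))
  shifts <- unique(shifts[shifts <= max_shift])
  best <- shifts[1L]; best_cor <- -Inf
  chroms <- unique(tags$chrom)
  binned <- lapply(chroms, function(chrom) {
    sel <- tags$chrom == chrom
    n <- max(tags$start[sel]) %/% grid + 1L
    f <- tabulate(tags$start[sel & tags$strand == "+"] %/% grid + 1L, n)
    r <- tabulate(tags$start[sel & tags$strand == "-"] %/% grid + 1L, n)
    list(f = f, r = r)
  })
  for (s in shifts) {
    b <- s %/% grid
    fs <- numeric(0); rs <- numeric(0)
    for (bd in binned) {
      n <- length(bd$f)
      if (n - b < 2L) next
      fs <- c(fs, bd$f[seq_len(n - b)])
      rs <- c(rs, bd$r[seq.int(b + 1L, n)])
    }
    if (length(fs) < 3L || stats::sd(fs) == 0 || stats::sd(rs) == 0) next
    cc <- stats::cor(fs, rs)
    if (cc > best_cor + 1e-12) {
      best_cor <- cc
      best <- s
    }
  }
  best
}

# fragments: data.frame(chrom, start, end); per-bp coverage averaged per bin
fragment_coverage_track <- function(frags, bin, chrom_sizes,
                                    per_bp_mean = TRUE) {
  values <- empty_track_values(chrom_sizes, bin)
  truncated <- 0L
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    sel <- frags$chrom == chrom
    if (!any(sel)) next
    s <- pmax(frags$start[sel], 0L)
    e <- pmin(frags$end[sel], L)
    truncated <- truncated + sum(frags$start[sel] < 0L | frags$end[sel] > L)
    ok <- e > s
    s <- s[ok]; e <- e[ok]
    diffarr <- numeric(L + 1L)
    add <- tabulate(s + 1L, L + 1L)
    rem <- tabulate(e + 1L, L + 1L)
    cov <- cumsum(add - rem)[seq_len(L)]
    nb <- length(values[[chrom]])
    padded <- c(cov, numeric(nb * bin - L))
    sums <- .colSums(matrix(padded, nrow = bin), bin, nb)
    values[[chrom]] <- if (per_bp_mean) sums / bin else sums
  }
  if (truncated > 0L) {
    message(truncated, " fragment(s) truncated at chromosome ends")
  }
  genome_track(values, bin)
}

tags_to_fragments <- function(tags, elongation) {
  plus <- tags$strand == "+"
  data.frame(chrom = tags$chrom,
             start = ifelse(plus, tags$start, tags$start - elongation + 1L),
             end = ifelse(plus, tags$start + elongation, tags$start + 1L),
             stringsAsFactors = FALSE)
}

#' Elongate tags and average coverage in bins
#'
#' Each single-end tag is extended to `elongation` bp in its 3' direction;
#' the per-bin value is the mean per-bp fragment coverage within the bin, so
#' the total signal mass `sum(bin values) * bin` equals the summed fragment
#' lengths (after truncation at chromosome ends, which is logged).
#'
#' @param tags Single-end tag table (see [tagset]).
#' @param elongation Fragment length in bp (>= `read_length`).
#' @param bin Bin width, bp.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param read_length Read length used for the precondition check.
#' @return A [genome_track()].
#' @export
elongate_and_bin <- function(tags, elongation, bin, chrom_sizes,
                             read_length = NULL) {
  if (!is.null(read_length) && elongation < read_length) {
    stop("elongation must be at least the read length")
  }
  fragment_coverage_track(tags_to_fragments(tags, elongation),
                          bin, chrom_sizes)
}

#' Input subtraction with equal-mass scaling
#'
#' The input track is scaled so its genome-wide mass matches the signal
#' track's (or both to one million with `scale = "per-million"`), then
#' subtracted bin-wise; negative bins are clipped to zero because downstream
#' profile means and mixture fits assume non-negative occupancy.
#'
#' @param track,input [genome_track()] objects on the same bin grid.
#' @param scale `"mass"` (default) or `"per-million"`.
#' @return Background-subtracted [genome_track()].
#' @export
subtract_input_and_scale <- function(track, input,
                                     scale = c("mass", "per-million")) {
  scale <- match.arg(scale)
  if (track$bin_size != input$bin_size ||
      !identical(names(track$values), names(input$values)) ||
      !identical(lengths(track$values), lengths(input$values))) {
    stop("track and input are not on the same bin grid")
  }
  mass_t <- sum(vapply(track$values, sum, numeric(1)))
  mass_i <- sum(vapply(input$values, sum, numeric(1)))
  out <- track$values
  if (scale == "mass") {
    k_t <- 1
    k_i <- if (mass_i > 0) mass_t / mass_i else 0
  } else {
    k_t <- if (mass_t > 0) 1e6 / mass_t else 0
    k_i <- if (mass_i > 0) 1e6 / mass_i else 0
  }
  for (chrom in names(out)) {
    out[[chrom]] <- pmax(k_t * track$values[[chrom]] -
                           k_i * input$values[[chrom]], 0)
  }
  genome_track(out, track$bin_size, strand_tag = track$strand_tag,
               assembly = track$assembly)
}

#' Nucleosome density and dyad-midpoint tracks from paired fragments
#'
#' Density mode scores the full MNase fragment spans (mean per-bp coverage
#' per bin; no input subtraction is applied to nucleosome data). Midpoint
#' mode places unit mass at `floor((start + end) / 2)` of each fragment, the
#' approximate dyad, scoring positioning rather than occupancy. Orphan
#' single-end tags can be connected into pseudo-fragments using a supplied
#' fragment-length estimate.
#'
#' @param pairs Paired fragment table (`chrom`, `start`, `end`) or `NULL`.
#' @param mode `"density"` or `"midpoint"`.
#' @param bin Bin width, bp.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param orphans Optional single-end tag table.
#' @param elongation Fragment length used to connect orphans (required if
#'   `orphans` given; also required if `pairs` is `NULL`).
#' @return A [genome_track()]; midpoint-mode values are dyad counts per bin.
#' @export
nucleosome_tracks <- function(pairs, mode = c("density", "midpoint"), bin,
                              chrom_sizes, orphans = NULL, elongation = NULL) {
  mode <- match.arg(mode)
  frags <- pairs
  if (!is.null(orphans) && nrow(orphans) > 0L) {
    if (is.null(elongation)) {
      stop("orphan tags need a fragment-length estimate to be connected")
    }
    frags <- rbind(frags[, c("chrom", "start", "end")],
                   tags_to_fragments(orphans, elongation))
  }
  if (is.null(frags) || nrow(frags) == 0L) {
    stop("no fragments: supply pairs or orphans with an elongation estimate")
  }
  if (mode == "density") {
    return(fragment_coverage_track(frags, bin, chrom_sizes))
  }
  mids <- (frags$start + frags$end) %/% 2L
  values <- empty_track_values(chrom_sizes, bin)
  for (chrom in names(chrom_sizes)) {
    sel <- frags$chrom == chrom & mids >= 0L & mids < chrom_sizes[[chrom]]
    if (!any(sel)) next
    values[[chrom]] <- tabulate(mids[sel] %/% bin + 1L,
                                length(values[[chrom]]))
  }
  genome_track(values, bin)
}
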