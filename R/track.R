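#' Fixed-bin genome coverage track
#'
#' A `genome_track` stores one numeric value per fixed-width genomic bin,
#' per chromosome. Bin `i` (0-based) covers the 0-based half-open interval
#' `[i * bin_size, (i + 1) * bin_size)`. All pipeline signal (ChIP-seq
#' occupancy, MNase density or dyad midpoints, strand-specific short-RNA
#' coverage) is carried in this container.
#'
#' @param values Named list of finite numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp (positive integer).
#' @param strand_tag One of `"none"`, `"plus"`, `"minus"`; used for
#'   strand-specific short-RNA tracks.
#' @param assembly Free-text assembly label.
#'
#' @return An object of class `genome_track`.
#' @export
genome_track <- function(values, bin_size, strand_tag = "none",
                         assembly = "custom") {
  stopifnot(is.list(values), length(values) > 0L, !is.null(names(values)),
            all(nzchar(names(values))))
  bin_size <- as.integer(bin_size)
  stopifnot(length(bin_size) == 1L, bin_size >= 1L)
  strand_tag <- match.arg(strand_tag, c("none", "plus", "minus"))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("track values must be numeric: ", chrom)
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-finite track values on ", chrom)
    }
    values[[chrom]] <- as.numeric(v)
  }
  structure(list(values = values[order(names(values))],
                 bin_size = bin_size,
                 strand_tag = strand_tag,
                 assembly = assembly),
            class = "genome_track")
}

#' @export
print.genome_track <- function(x, ...) {
  cat("genome_track:", length(x$values), "chromosome(s), bin",
      x$bin_size, "bp, strand", x$strand_tag, "\n")
  for (chrom in names(x$values)) {
    cat("  ", chrom, ": ", length(x$values[[chrom]]), " bins\n", sep = "")
  }
  invisible(x)
}

#' Chromosome lengths of a track, in bins and bp
#'
#' @param track A `genome_track`.
#' @return Named integer vector of chromosome lengths in bp (bin grid extent).
#' @export
track_chrom_lengths <- function(track) {
  vapply(track$values, length, integer(1)) * track$bin_size
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$size, df$chrom)
}

#' Write a chromosome sizes file
#' @param sizes Named integer vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(chrom = names(sizes), size = as.integer(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_track_values <- function(chrom_sizes, bin_size) {
  lapply(stats::setNames(as.list(chrom_sizes), names(chrom_sizes)),
         function(len) numeric(ceiling(len / bin_size)))
}

#' Read a coverage track from wiggle or bedGraph
#'
#' Parsing of the wiggle (fixedStep/variableStep) and bedGraph dialects is
#' delegated to \pkg{rtracklayer}; the resulting intervals are laid onto the
#' fixed bin grid. Every interval must start and end on a multiple of
#' `bin_size` (1-based wiggle starts are converted to 0-based first), so a
#' bedGraph line spanning several bins is split into constant bins and an
#' interval that straddles a bin boundary is a format error. Bins not covered
#' by the file are zero, and chromosomes present in `chrom_sizes` but absent
#' from the file come back as all-zero vectors.
#'
#' @param path Path to a `.wig` or `.bedGraph`/`.bg` file.
#' @param bin_size Declared bin width in bp.
#' @param chrom_sizes Named integer vector (see [read_chrom_sizes()]);
#'   defines the chromosomes and their extents.
#' @param format `"auto"` (by extension), `"wig"` or `"bedGraph"`.
#' @param strand_tag Strand tag to attach to the returned track.
#' @return A [genome_track()].
#' @export
read_track <- function(path, bin_size, chrom_sizes, format = "auto",
                       strand_tag = "none") {
  stopifnot(file.exists(path))
  bin_size <- as.integer(bin_size)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph" else "wig"
  }
  values <- empty_track_values(chrom_sizes, bin_size)
  has_content <- any(nzchar(trimws(readLines(path, warn = FALSE))))
  if (has_content) {
    gr <- rtracklayer::import(path, format = format)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chroms), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop("track file contains chromosomes absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    }
    s <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
    e <- GenomicRanges::end(gr)
    if (any(s %% bin_size != 0L) || any(e %% bin_size != 0L)) {
      stop("interval boundaries not on the ", bin_size,
           "-bp bin grid: irregular step")
    }
    score <- S4Vectors::mcols(gr)$score
    for (chrom in unique(chroms)) {
      idx <- which(chroms == chrom)
      nb <- length(values[[chrom]])
      bin_from <- s[idx] %/% bin_size
      bin_to <- e[idx] %/% bin_size  # exclusive
      touched <- integer(0)
      for (k in seq_along(idx)) {
        bins <- seq.int(bin_from[k], bin_to[k] - 1L)
        if (any(bins >= nb)) stop("interval beyond ", chrom, " extent")
        values[[chrom]][bins + 1L] <- score[idx[k]]
        touched <- c(touched, bins)
      }
      if (anyDuplicated(touched)) {
        stop("overlapping intervals on ", chrom)
      }
    }
  }
  genome_track(values, bin_size, strand_tag = strand_tag)
}

#' Write a track as fixedStep wiggle
#'
#' Emits one fixedStep declaration per chromosome with
#' `step = span = bin_size`, chromosomes in lexicographic order, values
#' printed with six decimals. Reading the file back with [read_track()]
#' recovers the values rounded to six decimals.
#'
#' @param track A [genome_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in sort(names(track$values))) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, track$bin_size, track$bin_size), con)
    writeLines(sprintf("%.6f", track$values[[chrom]]), con)
  }
  invisible(path)
}

#' Per-region mean of per-bp signal
#'
#' Bins partially overlapped by a region contribute in proportion to their
#' overlap, so the result equals the mean over every base pair of the region
#' of the (piecewise-constant) binned signal.
#'
#' @param track A [genome_track()].
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [gene_window()].
#' @param truncate If `TRUE` (default), regions running past a chromosome
#'   edge are clipped; if `FALSE` such regions are an error.
#' @return Numeric vector, one mean per region (NA for a region fully
#'   outside bounds when `truncate = TRUE`).
#' @export
region_means <- function(track, regions, truncate = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  B <- track$bin_size
  out <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    v <- track$values[[chrom]]
    if (is.null(v)) stop("unknown chromosome: ", chrom)
    s <- regions$start[i]; e <- regions$end[i]
    if (e <= s) stop("zero- or negative-length region at row ", i)
    if (truncate) {
      s <- max(s, 0); e <- min(e, length(v) * B)
      if (e <= s) { out[i] <- NA_real_; next }
    } else if (s < 0 || e > length(v) * B) {
      stop("region out of bounds at row ", i)
    }
    b0 <- s %/% B; b1 <- (e - 1L) %/% B
    if (b0 == b1) {
      out[i] <- v[b0 + 1L]
    } else {
      total <- v[b0 + 1L] * ((b0 + 1) * B - s) + v[b1 + 1L] * (e - b1 * B)
      if (b1 > b0 + 1L) {
        total <- total + sum(v[(b0 + 2L):b1]) * B
      }
      out[i] <- total / (e - s)
    }
  }
  out
}

#' Per-bp signal over a window
#'
#' Expands the binned signal to one value per base pair over
#' `[start, end)`. Positions outside the chromosome extent are zero.
#'
#' @inheritParams region_means
#' @param chrom,start,end Window coordinates (0-based half-open).
#' @return Numeric vector of length `end - start`.
#' @export
track_values_bp <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  B <- track$bin_size
  n <- end - start
  stopifnot(n > 0)
  out <- numeric(n)
  lo <- max(start, 0); hi <- min(end, length(v) * B)
  if (hi > lo) {
    pos <- seq.int(lo, hi - 1L)
    out[pos - start + 1L] <- v[pos %/% B + 1L]
  }
  out
}

#' Average several tracks bin-wise
#'
#' Replicate tracks are merged by the bin-wise mean (set `method = "sum"`
#' for summation).
#'
#' @param tracks List of [genome_track()] objects on the same grid.
#' @param method `"mean"` (default) or `"sum"`.
#' @return A [genome_track()].
#' @export
merge_tracks <- function(tracks, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(length(tracks) >= 1L)
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (t$bin_size != ref$bin_size ||
        !identical(names(t$values), names(ref$values)) ||
        !identical(lengths(t$values), lengths(ref$values))) {
      stop("tracks are not on the same bin grid")
    }
  }
  vals <- ref$values
  for (chrom in names(vals)) {
    m <- rowSums(vapply(tracks, function(t) t$values[[chrom]],
                        numeric(length(vals[[chrom]]))))
    vals[[chrom]] <- if (method == "mean") m / length(tracks) else m
  }
  genome_track(vals, ref$bin_size, strand_tag = ref$strand_tag,
               assembly = ref$assembly)
}
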