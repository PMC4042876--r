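# shared fixture builders: everything is generated in code, no stored data

# track with one chromosome from a plain numeric vector
vec_track <- function(v, bin = 50, chrom = "chr1", ...) {
  genome_track(stats::setNames(list(as.numeric(v)), chrom), bin, ...)
}

# a random seeded track over a few chromosomes
random_track <- function(seed, nbins = 200, bin = 50, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  vals <- lapply(stats::setNames(chroms, chroms),
                 function(ch) round(stats::rexp(nbins, 1), 4))
  genome_track(vals, bin)
}

# minimal gene table
gene_row <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     start = 10000, end = 16000, category = "coding") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end, category = category,
             stringsAsFactors = FALSE)
}

# a track with a single Gaussian summit (max exactly at the bin whose left
# edge is `center`), plus optional flat background
summit_track <- function(center, height, sd = 40, bin = 10, nbins = 4000,
                         chrom = "chr1", background = 0) {
  x <- (seq_len(nbins) - 1) * bin + bin / 2
  v <- background + height * exp(-(x - (center + bin / 2))^2 / (2 * sd^2))
  vec_track(v, bin = bin, chrom = chrom)
}

# small simulation config used across tests (fast to generate); caller
# arguments override the small-study defaults
small_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 60L, enhancer_count = 12L,
                   distractor_count = 5L, n_chromosomes = 2L,
                   chrom_length = 6.5e5, make_sequence = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, c(list(seed = seed), args))
}

# brute-force per-bp mean over a region (oracle for region_means)
bp_mean_oracle <- function(track, chrom, start, end) {
  mean(track_values_bp(track, chrom, start, end))
}

# brute-force run-scan + merge + summit oracle for the peak caller
peaks_oracle <- function(track, threshold, max_gap) {
  B <- track$bin_size
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    above <- which(v >= threshold)
    if (length(above) == 0L) next
    groups <- list()
    cur <- c(above[1L])
    for (b in above[-1L]) {
      gap_bp <- (b - cur[length(cur)] - 1L) * B
      if (b == cur[length(cur)] + 1L || gap_bp < max_gap) cur <- c(cur, b)
      else { groups[[length(groups) + 1L]] <- cur; cur <- c(b) }
    }
    groups[[length(groups) + 1L]] <- cur
    for (grp in groups) {
      span <- grp[1L]:grp[length(grp)]
      si <- span[which.max(v[span])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = (grp[1L] - 1L) * B, end = grp[length(grp)] * B,
        summit = (si - 1L) * B, height = v[si], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit = integer(), height = numeric())
}

# brute-force Mann-Whitney U by exhaustive pair counting
mww_u_oracle <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force two-sample KS statistic: sup |ECDF1 - ECDF2|
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}
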