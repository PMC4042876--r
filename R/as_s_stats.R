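#' Antisense and sense promoter mean signals
#'
#' For each gene, the antisense (AS) window is the oriented 500 bp
#' immediately upstream of the TSS and the sense (S) window the 500 bp
#' downstream; for a minus-strand gene the AS window therefore lies
#' genomically downstream of the TSS boundary. Genes whose windows run out
#' of bounds are dropped with a message.
#'
#' @param track A [genome_track()].
#' @param genes Gene table with strand.
#' @param polii_track Optional Pol II [genome_track()]; when given, per-gene
#'   Pol II means on the same two windows are attached as the normaliser.
#' @param width Window width in bp (default 500).
#' @return Data frame `gene_id`, `as_mean`, `s_mean` and (if requested)
#'   `as_polii`, `s_polii`.
#' @export
as_s_means <- function(track, genes, polii_track = NULL, width = 500) {
  asw <- gene_window(genes, "tss", -width, "tss", 0)
  sw <- gene_window(genes, "tss", 0, "tss", width)
  lens <- track_chrom_lengths(track)
  inb <- asw$start >= 0 & sw$start >= 0 &
    asw$end <= lens[asw$chrom] & sw$end <= lens[sw$chrom]
  if (any(!inb)) {
    message(sum(!inb), " gene(s) dropped: TSS window out of bounds")
  }
  out <- data.frame(gene_id = genes$gene_id[inb],
                    as_mean = region_means(track, asw[inb, , drop = FALSE]),
                    s_mean = region_means(track, sw[inb, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  if (!is.null(polii_track)) {
    out$as_polii <- region_means(polii_track, asw[inb, , drop = FALSE])
    out$s_polii <- region_means(polii_track, sw[inb, , drop = FALSE])
  }
  out
}

#' Paired antisense-vs-sense test
#'
#' The core divergent-transcription statistic: a parametric two-sided
#' paired t test of antisense against sense mean occupancy across genes,
#' after (i) one-sided IQR outlier filtering applied to each side
#' independently (a gene survives only if kept on both sides), (ii)
#' optional division of both sides by the per-gene Pol II mean (genes with
#' a zero normaliser are dropped and counted), and (iii) optional min-max
#' scaling of the surviving pooled AS and S values to [0, 1] (an affine map,
#' so it cannot change the t statistic or p value; it is retained because
#' boxplot-style displays use the scaled values).
#'
#' @param records Data frame from [as_s_means()].
#' @param scale01 Min-max scale the pooled surviving values (default TRUE).
#' @param normalizer Divide each side by its Pol II mean; requires the
#'   `as_polii`/`s_polii` columns.
#' @return List: `t`, `p` (two-sided), `n_used`, `mean_diff` (AS - S on the
#'   analysis scale), `filtered` (per-side outlier counts and zero-Pol II
#'   drops), `records` (surviving per-gene values), `zero_variance` flag,
#'   and `shapiro_p` (normality diagnostic on the differences, logged only,
#'   never used as a gate).
#' @export
as_s_test <- function(records, scale01 = TRUE, normalizer = FALSE) {
  a <- records$as_mean
  s <- records$s_mean
  dropped_zero <- 0L
  if (normalizer) {
    if (is.null(records$as_polii)) {
      stop("records carry no Pol II normaliser columns")
    }
    norm <- (records$as_polii + records$s_polii) / 2
    keep0 <- norm > 0
    dropped_zero <- sum(!keep0)
    a <- a[keep0] / norm[keep0]
    s <- s[keep0] / norm[keep0]
    records <- records[keep0, , drop = FALSE]
  }
  keep_a <- iqr_outlier_filter(a)
  keep_s <- iqr_outlier_filter(s)
  keep <- keep_a & keep_s
  a <- a[keep]; s <- s[keep]
  if (length(a) < 3L) stop("fewer than 3 gene records survive filtering")
  if (scale01) {
    pooled <- c(a, s)
    rng <- range(pooled)
    if (diff(rng) > 0) {
      a <- (a - rng[1]) / diff(rng)
      s <- (s - rng[1]) / diff(rng)
    }
  }
  d <- a - s
  zero_var <- stats::sd(d) == 0
  if (zero_var) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, s, paired = TRUE)
  }
  shapiro_p <- if (!zero_var && length(d) >= 3L && length(d) <= 5000L) {
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  } else NA_real_
  list(t = unname(tt$statistic), p = tt$p.value, n_used = length(a),
       mean_diff = mean(d),
       filtered = list(as_outliers = sum(!keep_a), s_outliers = sum(!keep_s),
                       both_kept = sum(keep), zero_polii = dropped_zero),
       records = data.frame(gene_id = records$gene_id[keep],
                            as_value = a, s_value = s,
                            stringsAsFactors = FALSE),
       zero_variance = zero_var, shapiro_p = shapiro_p)
}

#' Expression strata from replicate microarray data
#'
#' Merges replicates by the per-probe mean, probes mapping to one gene by
#' the median, orders genes by the merged expression and cuts the ordered
#' list at two quantile positions into low / medium / high strata.
#'
#' @param expr_replicates Numeric probe x replicate matrix (row names =
#'   probe ids).
#' @param probe_map Data frame `probe`, `gene_id` mapping probes to genes.
#' @param cuts Two increasing quantile positions in (0, 1); defaults
#'   `c(0.60, 0.82)`.
#' @param genes Optional gene table: when given, the standing gene filters
#'   ([filter_genes()] without the ssRNA rule) are applied before
#'   stratification.
#' @return List with `expression` (named per-gene merged values, ascending),
#'   and gene-id vectors `low`, `medium`, `high`.
#' @export
expression_strata <- function(expr_replicates, probe_map,
                              cuts = c(0.60, 0.82), genes = NULL) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2],
            all(cuts > 0), all(cuts < 1))
  probe_means <- rowMeans(expr_replicates)
  pm <- probe_map[probe_map$probe %in% names(probe_means), , drop = FALSE]
  merged <- tapply(probe_means[pm$probe], pm$gene_id, stats::median)
  merged <- merged[!is.na(merged)]
  if (!is.null(genes)) {
    kept <- filter_genes(genes)$retained$gene_id
    merged <- merged[names(merged) %in% kept]
  }
  if (length(unique(merged)) <= 1L) {
    stop("degenerate expression ordering: all merged values equal")
  }
  ord <- order(merged, names(merged))
  merged <- merged[ord]
  n <- length(merged)
  n_low <- floor(cuts[1] * n)
  n_lm <- floor(cuts[2] * n)
  if (n_low < 1L || n_lm <= n_low || n_lm >= n) {
    stop("cuts produce an empty stratum")
  }
  list(expression = merged,
       low = names(merged)[seq_len(n_low)],
       medium = names(merged)[seq.int(n_low + 1L, n_lm)],
       high = names(merged)[seq.int(n_lm + 1L, n)])
}
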