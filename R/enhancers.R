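#' Threshold/max-gap peak caller
#'
#' Enriched regions are maximal runs of bins at or above `threshold`; two
#' runs separated by a gap of less than `max_gap` bp are merged. The summit
#' is the highest bin of the merged region (tie-break: leftmost).
#'
#' @param track A [genome_track()].
#' @param threshold Signal threshold (> 0).
#' @param max_gap Merge gap in bp.
#' @return A `peak_set`: list with `peaks` (data frame `chrom`, `start`,
#'   `end`, `summit` (bp, left edge of the summit bin), `height`) and the
#'   calling parameters.
#' @export
call_peaks <- function(track, threshold, max_gap) {
  stopifnot(threshold > 0, max_gap >= 0)
  B <- track$bin_size
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    above <- v >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rs <- starts[r$values]; re <- ends[r$values]
    ms <- rs[1L]; me <- re[1L]
    flush <- function(s, e) {
      seg <- v[s:e]
      si <- s - 1L + which.max(seg)
      data.frame(chrom = chrom, start = (s - 1L) * B, end = e * B,
                 summit = (si - 1L) * B, height = v[si],
                 stringsAsFactors = FALSE)
    }
    if (length(rs) > 1L) {
      for (k in 2L:length(rs)) {
        if ((rs[k] - me - 1L) * B < max_gap) {
          me <- re[k]
        } else {
          out[[length(out) + 1L]] <- flush(ms, me)
          ms <- rs[k]; me <- re[k]
        }
      }
    }
    out[[length(out) + 1L]] <- flush(ms, me)
  }
  peaks <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit = integer(), height = numeric())
  }
  structure(list(peaks = peaks, threshold = threshold, max_gap = max_gap),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", nrow(x$peaks), "peak(s), threshold", x$threshold,
      ", max gap", x$max_gap, "bp\n")
  invisible(x)
}

peaks_granges <- function(ps) {
  p <- if (inherits(ps, "peak_set")) ps$peaks else ps
  if (nrow(p) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(p$chrom,
                         IRanges::IRanges(start = p$start + 1L, end = p$end))
}

regions_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# minimal gap in bp between each query region and its nearest subject
# interval (0 when overlapping); Inf when the subject set is empty
nearest_gap <- function(query_gr, subject_gr) {
  if (length(subject_gr) == 0L) return(rep(Inf, length(query_gr)))
  d <- rep(Inf, length(query_gr))
  hits <- GenomicRanges::distanceToNearest(query_gr, subject_gr)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' H3K4me3/H3K4me1 mean-signal ratios over regions
#'
#' @param me3_track,me1_track [genome_track()]s.
#' @param regions Region data frame (`chrom`, `start`, `end`).
#' @return Numeric ratios; regions with zero H3K4me1 mean are `NA` (logged).
#' @export
region_me_ratio <- function(me3_track, me1_track, regions) {
  num <- region_means(me3_track, regions)
  den <- region_means(me1_track, regions)
  zero <- den == 0
  if (any(zero, na.rm = TRUE)) {
    message(sum(zero, na.rm = TRUE),
            " region(s) with zero H3K4me1 mean dropped from ratio analysis")
  }
  out <- num / den
  out[zero] <- NA_real_
  out
}

#' Ratio threshold separating enhancers from promoter-like regions
#'
#' The default rule places the cutoff at a low quantile (5th percentile) of
#' the H3K4me3/me1 ratios of annotated promoters (TSS +/- 1000 windows): a
#' reproducible, conservative stand-in for the by-eye threshold between the
#' promoter-like and enhancer-like ratio populations. Intergenic candidates
#' keep enhancer status when their ratio falls below the threshold; promoter
#' candidates when at or above it.
#'
#' @param intergenic_ratios,promoter_ratios Candidate-group ratios (>= 10
#'   finite values each), used for validation/reporting.
#' @param annotated_ratios Ratios of annotated promoters.
#' @param mode `"quantile"` or `"constant"`.
#' @param quantile Quantile of the annotated-promoter ratios (default 0.05).
#' @param constant User threshold for `mode = "constant"`.
#' @return The threshold `tau_ratio`.
#' @export
ratio_threshold <- function(intergenic_ratios, promoter_ratios,
                            annotated_ratios, mode = c("quantile", "constant"),
                            quantile = 0.05, constant = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(constant)) stop("constant mode needs a threshold value")
    return(constant)
  }
  ann <- annotated_ratios[is.finite(annotated_ratios)]
  if (length(ann) == 0L) stop("no finite annotated-promoter ratios")
  if (sum(is.finite(intergenic_ratios)) < 10L ||
      sum(is.finite(promoter_ratios)) < 10L) {
    stop("need at least 10 finite ratios per candidate group")
  }
  stats::quantile(ann, quantile, names = FALSE, type = 7)
}

default_enhancer_params <- function() {
  list(promoter_up = 2000, promoter_down = 1000,
       min_gene_distance = 5000, k36_margin = 2000,
       ratio_mode = "quantile", ratio_quantile = 0.05,
       ratio_constant = NULL, center_flank = 2000)
}

# stage 1 of both workflows: candidate footprints where all peak sets in
# `required` overlap pairwise with the first one (>= 1 bp)
candidate_regions <- function(required) {
  base <- peaks_granges(required[[1L]])
  if (length(base) == 0L) return(GenomicRanges::GRanges())
  keep <- rep(TRUE, length(base))
  foot <- base
  for (ps in required[-1L]) {
    other <- peaks_granges(ps)
    ov <- GenomicRanges::findOverlaps(base, other)
    hit <- unique(S4Vectors::queryHits(ov))
    keep <- keep & seq_along(base) %in% hit
    # extend footprints by the overlapping partner peaks
    if (length(ov) > 0L) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      new_start <- pmin(GenomicRanges::start(foot)[qh],
                        GenomicRanges::start(other)[sh])
      new_end <- pmax(GenomicRanges::end(foot)[qh],
                      GenomicRanges::end(other)[sh])
      agg_s <- tapply(new_start, qh, min)
      agg_e <- tapply(new_end, qh, max)
      idx <- as.integer(names(agg_s))
      GenomicRanges::start(foot)[idx] <- pmin(
        GenomicRanges::start(foot)[idx], as.integer(agg_s))
      GenomicRanges::end(foot)[idx] <- pmax(
        GenomicRanges::end(foot)[idx], as.integer(agg_e))
    }
  }
  GenomicRanges::reduce(foot[keep])
}

classify_regions_core <- function(required_peaks, k36_peaks, tracks, genes,
                                  params, center_track, active_peaks = NULL,
                                  prefix = c("E", "P")) {
  p <- utils::modifyList(default_enhancer_params(), params)
  for (tr in c("h3k4me1", "h3k4me3", "ssrna")) {
    if (is.null(tracks[[tr]])) stop("missing track: ", tr)
  }
  cand <- candidate_regions(required_peaks)
  stages <- list()
  prom_win <- regions_granges(
    gene_window(genes, "tss", -p$promoter_up, "tss", p$promoter_down))
  is_prom <- IRanges::overlapsAny(cand, prom_win)
  E <- cand[!is_prom]
  P <- cand[is_prom]
  stages[[paste0(prefix[1], 1)]] <- length(E)
  stages[[paste0(prefix[2], 1)]] <- length(P)

  genes_gr <- regions_granges(genes)
  k36_gr <- peaks_granges(k36_peaks)
  rejected <- list()
  gap_gene <- nearest_gap(E, genes_gr)
  gap_k36 <- nearest_gap(E, k36_gr)
  drop_near <- gap_gene < p$min_gene_distance
  drop_k36 <- gap_k36 < p$k36_margin
  rejected$near_gene <- granges_regions(E[drop_near])
  rejected$k36 <- granges_regions(E[!drop_near & drop_k36])
  E <- E[!(drop_near | drop_k36)]
  stages[[paste0(prefix[1], 2)]] <- length(E)

  e_df <- granges_regions(E)
  p_df <- granges_regions(P)
  e_ratio <- region_me_ratio(tracks$h3k4me3, tracks$h3k4me1, e_df)
  p_ratio <- region_me_ratio(tracks$h3k4me3, tracks$h3k4me1, p_df)
  ann <- gene_window(genes, "tss", -1000, "tss", 1000)
  ann_ratio <- region_me_ratio(tracks$h3k4me3, tracks$h3k4me1, ann)
  tau <- ratio_threshold(e_ratio, p_ratio, ann_ratio,
                         mode = p$ratio_mode, quantile = p$ratio_quantile,
                         constant = p$ratio_constant)
  keep_e <- !is.na(e_ratio) & e_ratio < tau
  keep_p <- !is.na(p_ratio) & p_ratio >= tau
  e_df <- e_df[keep_e, , drop = FALSE]; e_ratio <- e_ratio[keep_e]
  p_df <- p_df[keep_p, , drop = FALSE]; p_ratio <- p_ratio[keep_p]
  stages[[paste0(prefix[1], 3)]] <- nrow(e_df)
  stages[[paste0(prefix[2], 2)]] <- nrow(p_df)

  centerize <- function(df) {
    if (nrow(df) == 0L) return(integer(0))
    vapply(seq_len(nrow(df)), function(i) {
      max_bin_position(center_track, df$chrom[i], df$start[i], df$end[i])
    }, numeric(1))
  }
  e_df$center <- centerize(e_df)
  p_df$center <- centerize(p_df)

  active_e <- rep(FALSE, nrow(e_df)); active_p <- rep(FALSE, nrow(p_df))
  if (!is.null(active_peaks)) {
    ac <- peaks_granges(active_peaks)
    active_e <- IRanges::overlapsAny(regions_granges(e_df), ac)
    active_p <- IRanges::overlapsAny(regions_granges(p_df), ac)
  }

  ssrna_mean <- function(df) {
    if (nrow(df) == 0L) return(numeric(0))
    region_means(tracks$ssrna,
                 data.frame(chrom = df$chrom,
                            start = df$center - p$center_flank,
                            end = df$center + p$center_flank))
  }
  keep_se <- if (nrow(e_df) >= 4L) iqr_outlier_filter(ssrna_mean(e_df))
             else rep(TRUE, nrow(e_df))
  keep_sp <- if (nrow(p_df) >= 4L) iqr_outlier_filter(ssrna_mean(p_df))
             else rep(TRUE, nrow(p_df))

  list(e_df = e_df, p_df = p_df, e_ratio = e_ratio, p_ratio = p_ratio,
       keep_se = keep_se, keep_sp = keep_sp,
       active_e = active_e, active_p = active_p,
       tau = tau, stages = stages, rejected = rejected)
}

#' Enhancer/promoter classification, Pol II workflow
#'
#' Stage 1: candidate footprints where a Pol II peak overlaps both an
#' H3K4me1 and an H3K4me3 peak (>= 1 bp; merged footprint). Stage 2: split
#' into promoter-region candidates (overlap with any oriented
#' `[TSS - 2000, TSS + 1000]` window) and intergenic candidates. Stage 3
#' (intergenic): reject regions closer than 5000 bp to any gene or with an
#' H3K36me3 peak within 2000 bp of their boundaries (lincRNA-like bodies).
#' Stage 4: H3K4me3/me1 ratio filter (see [ratio_threshold()]); intergenic
#' kept below the threshold, promoters at/above it. Stage 5: regions are
#' centred on their Pol II signal maximum, short-ssRNA means computed on
#' centre +/- 2000 bp and IQR outliers dropped from each class.
#'
#' @param peaks Named list of `peak_set`s: `polii`, `h3k4me1`, `h3k4me3`,
#'   `h3k36me3`.
#' @param tracks Named list of [genome_track()]s: `polii`, `h3k4me1`,
#'   `h3k4me3`, `ssrna` (strand-summed short-RNA signal).
#' @param genes Gene table.
#' @param params Named list overriding [default_enhancer_params()] entries.
#' @return List: `calls` (data frame `chrom`, `start`, `end`, `center`,
#'   `ratio`, `class` in {`enhancer`, `control_promoter`,
#'   `rejected:ssrna_outlier`}), `stages` (counts E1..E4, P1..P3),
#'   `tau_ratio`, `rejected` (stage-3 drop tables).
#' @export
classify_regions_polii <- function(peaks, tracks, genes, params = list()) {
  for (nm in c("polii", "h3k4me1", "h3k4me3", "h3k36me3")) {
    if (is.null(peaks[[nm]])) stop("missing peak set: ", nm)
  }
  if (is.null(tracks$polii)) stop("missing track: polii")
  core <- classify_regions_core(
    required_peaks = peaks[c("polii", "h3k4me1", "h3k4me3")],
    k36_peaks = peaks$h3k36me3, tracks = tracks, genes = genes,
    params = params, center_track = tracks$polii)
  core$stages$E4 <- sum(core$keep_se)
  core$stages$P3 <- sum(core$keep_sp)
  calls <- rbind(
    cbind(core$e_df, ratio = core$e_ratio,
          class = ifelse(core$keep_se, "enhancer",
                         "rejected:ssrna_outlier")),
    cbind(core$p_df, ratio = core$p_ratio,
          class = ifelse(core$keep_sp, "control_promoter",
                         "rejected:ssrna_outlier")))
  rownames(calls) <- NULL
  list(calls = calls,
       stages = core$stages[c("E1", "E2", "E3", "E4", "P1", "P2", "P3")],
       tau_ratio = core$tau, rejected = core$rejected)
}

#' Enhancer/promoter classification, H3K27ac workflow
#'
#' Same splitting logic as [classify_regions_polii()] but candidates only
#' require overlapping H3K4me1 and H3K4me3 peaks (no Pol II), regions are
#' centred on the H3K4me3 maximum, and overlap with an H3K27ac peak
#' additionally labels a region active. Both the whole enhancer/promoter
#' sets and their active subsets are reported.
#'
#' @param peaks Named list of `peak_set`s: `h3k4me1`, `h3k4me3`,
#'   `h3k36me3`, `h3k27ac`.
#' @param tracks Named list of [genome_track()]s: `h3k4me1`, `h3k4me3`,
#'   `ssrna`.
#' @param genes Gene table.
#' @param params As in [classify_regions_polii()].
#' @return List: `calls` (class in {`active_enhancer`, `enhancer`,
#'   `active_promoter`, `control_promoter`, `rejected:ssrna_outlier`};
#'   active classes are subsets of the whole sets), `stages` (E1'..E6',
#'   P1'..P6'), `tau_ratio`.
#' @export
classify_regions_k27ac <- function(peaks, tracks, genes, params = list()) {
  for (nm in c("h3k4me1", "h3k4me3", "h3k36me3", "h3k27ac")) {
    if (is.null(peaks[[nm]])) stop("missing peak set: ", nm)
  }
  core <- classify_regions_core(
    required_peaks = peaks[c("h3k4me1", "h3k4me3")],
    k36_peaks = peaks$h3k36me3, tracks = tracks, genes = genes,
    params = params, center_track = tracks$h3k4me3,
    active_peaks = peaks$h3k27ac)
  st <- core$stages
  stages <- list("E1'" = st$E1, "E2'" = st$E2, "E3'" = st$E3,
                 "E4'" = sum(core$active_e),
                 "E5'" = sum(core$active_e & core$keep_se),
                 "E6'" = sum(core$keep_se),
                 "P1'" = st$P1, "P2'" = st$P2,
                 "P3'" = sum(core$active_p),
                 "P5'" = sum(core$active_p & core$keep_sp),
                 "P6'" = sum(core$keep_sp))
  e_class <- ifelse(!core$keep_se, "rejected:ssrna_outlier",
                    ifelse(core$active_e, "active_enhancer", "enhancer"))
  p_class <- ifelse(!core$keep_sp, "rejected:ssrna_outlier",
                    ifelse(core$active_p, "active_promoter",
                           "control_promoter"))
  calls <- rbind(cbind(core$e_df, ratio = core$e_ratio, class = e_class),
                 cbind(core$p_df, ratio = core$p_ratio, class = p_class))
  rownames(calls) <- NULL
  list(calls = calls, stages = stages, tau_ratio = core$tau,
       rejected = core$rejected)
}

#' Pol II-normalised mark levels at enhancers vs promoters
#'
#' Per final region, the mark's mean over centre +/- `flank` divided by the
#' Pol II mean on the same window; regions with a zero Pol II mean are
#' dropped (and counted). Classes are compared with a two-sided
#' Mann-Whitney-Wilcoxon test.
#'
#' @param calls Call table from a classification workflow (needs `center`
#'   and `class`).
#' @param mark_track,polii_track [genome_track()]s.
#' @param flank Half-window in bp (default 2000).
#' @return List: `values` (per-region normalised values with class),
#'   `p` (MWW, enhancers vs promoters), `dropped_zero_polii`.
#' @export
enhancer_mark_stats <- function(calls, mark_track, polii_track,
                                flank = 2000) {
  enh <- calls$class %in% c("enhancer", "active_enhancer")
  prom <- calls$class %in% c("control_promoter", "active_promoter")
  sel <- calls[enh | prom, , drop = FALSE]
  if (!any(enh) || !any(prom)) stop("both classes must be non-empty")
  win <- data.frame(chrom = sel$chrom, start = sel$center - flank,
                    end = sel$center + flank)
  mk <- region_means(mark_track, win)
  pol <- region_means(polii_track, win)
  zero <- pol == 0
  if (any(zero)) {
    message(sum(zero), " region(s) with zero Pol II mean dropped")
  }
  vals <- data.frame(
    class = ifelse(sel$class %in% c("enhancer", "active_enhancer"),
                   "enhancer", "promoter"),
    value = mk / pol)[!zero, , drop = FALSE]
  p <- if (length(unique(vals$value)) == 1L) 1 else
    suppressWarnings(
      stats::wilcox.test(vals$value[vals$class == "enhancer"],
                         vals$value[vals$class == "promoter"])$p.value)
  list(values = vals, p = p, dropped_zero_polii = sum(zero))
}

#' Tissue specificity of enhancer-associated genes
#'
#' The associated gene set is the nearest gene on each side of each region
#' of the selected classes. Per tissue, a one-sided Mann-Whitney-Wilcoxon
#' test asks whether associated genes are expressed above the whole atlas;
#' tissues are ranked by ascending p value (ties: alphabetical).
#'
#' @param calls Call table from a classification workflow.
#' @param genes Gene table.
#' @param atlas Numeric gene x tissue expression matrix (row names = gene
#'   ids).
#' @param classes Call classes defining the region set (default: enhancer
#'   classes).
#' @return List: `table` (data frame `tissue`, `p`, ranked), `associated`
#'   (gene ids used), `coverage` (fraction of associated genes in atlas).
#' @export
tissue_specificity <- function(calls, genes, atlas,
                               classes = c("enhancer", "active_enhancer")) {
  sel <- calls[calls$class %in% classes, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no regions in the selected classes")
  assoc <- character(0)
  for (i in seq_len(nrow(sel))) {
    g <- genes[genes$chrom == sel$chrom[i], , drop = FALSE]
    left <- g[g$end <= sel$start[i], , drop = FALSE]
    right <- g[g$start >= sel$end[i], , drop = FALSE]
    sides <- 0L
    if (nrow(left) > 0L) {
      assoc <- c(assoc, left$gene_id[which.max(left$end)]); sides <- sides + 1L
    }
    if (nrow(right) > 0L) {
      assoc <- c(assoc, right$gene_id[which.min(right$start)])
      sides <- sides + 1L
    }
    if (sides < 2L) {
      message("region ", i, ": only ", sides,
              " flanking gene(s) found (chromosome end?)")
    }
  }
  assoc <- unique(assoc)
  in_atlas <- assoc[assoc %in% rownames(atlas)]
  if (length(in_atlas) == 0L) stop("no associated genes present in the atlas")
  coverage <- length(in_atlas) / length(assoc)
  p <- vapply(colnames(atlas), function(t) {
    suppressWarnings(stats::wilcox.test(atlas[in_atlas, t], atlas[, t],
                                        alternative = "greater")$p.value)
  }, numeric(1))
  ord <- order(p, names(p))
  list(table = data.frame(tissue = names(p)[ord], p = unname(p[ord]),
                          stringsAsFactors = FALSE),
       associated = in_atlas, coverage = coverage)
}
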