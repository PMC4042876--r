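#' Configuration for the synthetic regulatory genome
#'
#' Builds the parameter list the generators consume. Defaults describe a
#' compact two-chromosome genome carrying 120 genes (promoters), 40
#' intergenic enhancer islands, and 15 lincRNA-like distractors, with
#' strong planted separation between classes so recovery tests are stable
#' at small n. Proportions of the three promoter classes follow the
#' observed class sizes (57.5/31.2/11.3%), and the per-mark position
#' distributions relative to Pol II follow the observed
#' before/colocalized/after counts for Tyr1P, Ser5P and Ser7P.
#'
#' Key fields (all overridable): `n_chromosomes`, `chrom_length`,
#' `bin_size`; `n_genes`, `gene_length_meanlog`/`sdlog`/`range`;
#' `class_props` and `class_offset_ranges` (oriented bp around the TSS);
#' `peak_height` and `as_s_delta` (the planted antisense/sense Tyr1P summit
#' asymmetry, additive on the height scale); `peak_sd` (summit width);
#' `mark_distance_probs`/`magnitudes` (per-mark placement relative to
#' Pol II); `as_status_probs` and the ssRNA height fields;
#' enhancer/distractor counts, widths and mark heights;
#' `background_rate` (Poisson background per 50-bp bin, rescaled for other
#' bin sizes), `noise_smooth_bp` (fragment-scale smoothing of the
#' background), `noise_jitter_sd`; atlas fields (`n_tissues`,
#' `specific_tissue`, `expression_factor`); tag-stream fields
#' (`fragment_length`, `read_length`, ...); `seed`.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes = 2L, chrom_length = 1.2e6, bin_size = 50L,
    edge_margin = 10000, placement_gap = c(6000, 8000),
    n_genes = 120L,
    gene_length_meanlog = log(4500), gene_length_sdlog = 0.3,
    gene_length_range = c(2500, 12000),
    class_props = c(I = 0.575, II = 0.312, III = 0.113),
    class_offset_ranges = list(I = c(-800, -150), II = c(-80, 80),
                               III = c(150, 800)),
    peak_height = 8, as_s_delta = 2, peak_sd = 40, mirror_min = 150,
    polii_broad_height = 3, polii_broad_sd = 300,
    mark_distance_probs = list(
      tyr1p = c(before = 90, colocalized = 174, after = 265) / 529,
      ser5p = c(before = 99, colocalized = 278, after = 152) / 529,
      ser7p = c(before = 125, colocalized = 170, after = 234) / 529),
    mark_distance_magnitudes = c(20, 30, 40),
    as_status_probs = c(none = 0.5, weak = 0.15, dominant = 0.35),
    as_rna_height = 10, as_rna_sd = 0.3,
    weak_rna_height = 5.5, weak_rna_sd = 0.3,
    s_rna_height = 2, as_s_rna_ratio = 4,
    body_height = 3, promoter_me3_height = 8, promoter_me1_height = 2.5,
    promoter_me_sd = 300, promoter_k27ac_height = 6,
    active_promoter_fraction = 0.9, broad_sd = 200,
    enhancer_count = 40L, enhancer_width = 1500,
    enhancer_polii_height = 4, enhancer_tyr1p_height = 8,
    enhancer_ser5p_height = 4, enhancer_ser7p_height = 4,
    enhancer_me1_height = 8, enhancer_me3_height = 2.5,
    enhancer_k27ac_height = 6, active_enhancer_fraction = 0.5,
    enhancer_rna_height = 5,
    distractor_count = 15L, distractor_width = 3000,
    distractor_k36_height = 5,
    dyad_offsets = c(-650, -470, -290, 130),
    dyad_mid_height = 5, dyad_mid_sd = 20,
    dyad_den_height = 3, dyad_den_sd = 75,
    background_rate = 0.2, noise_smooth_bp = 150, noise_jitter_sd = 0,
    spacing_violators = 0L, excluded_category_genes = c(),
    make_sequence = TRUE, promoter_gc = 0.6, background_gc = 0.4,
    fragment_length = 180L, read_length = 36L,
    tags_per_peak = 200L, background_tags = 1000L,
    pairs_per_dyad = 40L, planted_duplicates = NULL,
    n_tissues = 84L, specific_tissue = "B_cell", expression_factor = 4,
    n_replicates = 3L, expr_meanlog = 6, expr_sdlog = 1,
    multi_probe_fraction = 0.3)
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$n_genes >= 0, cfg$enhancer_count >= 0,
            cfg$distractor_count >= 0, cfg$bin_size >= 1,
            abs(sum(cfg$class_props) - 1) < 1e-8,
            abs(sum(cfg$as_status_probs) - 1) < 1e-8,
            cfg$as_s_delta >= 0, cfg$as_s_delta < cfg$peak_height,
            cfg$n_tissues >= 2)
  class(cfg) <- "sim_config"
  cfg
}

snap_offset <- function(x, bin) floor(x / bin) * bin

# draw a planted oriented offset on the bin grid within a range; when the
# range spans the TSS the grid is restricted to offsets whose summit bin
# [o, o + bin) has its mirror bin [-o - bin, -o) inside the range too, so
# TSS-proximal summits are population-symmetric about the TSS
draw_offset <- function(range, bin) {
  grid <- seq.int(ceiling(range[1] / bin) * bin,
                  floor(range[2] / bin) * bin, by = bin)
  if (range[1] < 0 && range[2] > 0) {
    grid <- grid[(-grid - bin) %in% grid]
  }
  grid[sample.int(length(grid), 1L)]
}

#' Generate the synthetic genome: annotations, regions, truth, sequence
#'
#' Places genes, enhancer islands and lincRNA-like distractors sequentially
#' with inter-element gaps drawn from `placement_gap` (so genes are always
#' farther apart than the proximity filter's threshold unless
#' `spacing_violators` plants deliberate violations, and distal elements
#' are farther than 5 kb from genes). Every planted property downstream
#' analyses should recover is recorded in the truth tables.
#'
#' @param config A [sim_config()].
#' @return List: `genes` (annotation table), `regions` (distal elements),
#'   `truth` (list `genes`, `regions` of planted parameters),
#'   `chrom_sizes`, `sequences` (named character, or NULL).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  B <- config$bin_size
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(config$chrom_length,
                                     config$n_chromosomes), chroms)

  n_g <- config$n_genes
  n_e <- config$enhancer_count
  n_d <- config$distractor_count
  type <- sample(c(rep("gene", n_g), rep("enhancer", n_e),
                   rep("distractor", n_d)))
  # element coordinates live on a 50-bp grid (compatible with the 10- and
  # 50-bp bin sizes) so planted summits land exactly on bin centres
  glen <- round(pmin(pmax(
    stats::rlnorm(n_g, config$gene_length_meanlog, config$gene_length_sdlog),
    config$gene_length_range[1]), config$gene_length_range[2]) / 50) * 50
  lens <- integer(length(type))
  lens[type == "gene"] <- glen
  lens[type == "enhancer"] <- config$enhancer_width
  lens[type == "distractor"] <- config$distractor_width

  chrom_i <- 1L
  cursor <- config$edge_margin
  placement <- data.frame(type = type,
                          chrom = rep(NA_character_, length(type)),
                          start = rep(NA_integer_, length(type)),
                          end = rep(NA_integer_, length(type)),
                          stringsAsFactors = FALSE)
  for (i in seq_along(type)) {
    gap <- if (cursor == config$edge_margin) 0 else
      round(stats::runif(1, config$placement_gap[1],
                         config$placement_gap[2]) / 50) * 50
    while (cursor + gap + lens[i] > config$chrom_length - config$edge_margin) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > config$n_chromosomes) {
        stop("sizing error: elements do not fit the requested genome; ",
             "increase chrom_length or n_chromosomes")
      }
      cursor <- config$edge_margin
      gap <- 0
    }
    start <- cursor + gap
    placement$chrom[i] <- chroms[chrom_i]
    placement$start[i] <- start
    placement$end[i] <- start + lens[i]
    cursor <- start + lens[i]
  }

  gi <- which(placement$type == "gene")
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_along(gi)),
    chrom = placement$chrom[gi],
    strand = sample(c("+", "-"), length(gi), replace = TRUE),
    start = placement$start[gi],
    end = placement$end[gi],
    category = rep("coding", length(gi)),
    stringsAsFactors = FALSE)
  if (length(config$excluded_category_genes) > 0) {
    pool <- seq_len(nrow(genes))
    for (catname in names(config$excluded_category_genes)) {
      k <- config$excluded_category_genes[[catname]]
      pick <- sample(pool, k)
      genes$category[pick] <- catname
      pool <- setdiff(pool, pick)
    }
  }

  # planted spacing violations: short extra genes 500 bp behind a host gene
  if (config$spacing_violators > 0L) {
    hosts <- sample(seq_len(nrow(genes)), config$spacing_violators)
    extra <- genes[hosts, , drop = FALSE]
    extra$gene_id <- sprintf("viol%03d", seq_along(hosts))
    extra$start <- genes$end[hosts] + 500L
    extra$end <- extra$start + 2500L
    extra$category <- "coding"
    genes <- rbind(genes, extra)
  }

  n_genes_all <- nrow(genes)
  cls <- sample(names(config$class_props), n_genes_all, replace = TRUE,
                prob = config$class_props)
  tyr1p_off <- vapply(cls, function(cl) {
    draw_offset(config$class_offset_ranges[[cl]], B)
  }, numeric(1))
  draw_distance <- function(probs) {
    cat <- sample(names(probs), 1L, prob = probs)
    if (cat == "colocalized") return(0)
    mag <- config$mark_distance_magnitudes[
      sample.int(length(config$mark_distance_magnitudes), 1L)]
    if (cat == "before") -mag else mag
  }
  d_tyr1p <- vapply(seq_len(n_genes_all), function(i)
    draw_distance(config$mark_distance_probs$tyr1p), numeric(1))
  d_ser5p <- vapply(seq_len(n_genes_all), function(i)
    draw_distance(config$mark_distance_probs$ser5p), numeric(1))
  d_ser7p <- vapply(seq_len(n_genes_all), function(i)
    draw_distance(config$mark_distance_probs$ser7p), numeric(1))
  polii_off <- tyr1p_off + d_tyr1p
  as_status <- sample(names(config$as_status_probs), n_genes_all,
                      replace = TRUE, prob = config$as_status_probs)
  as_rna <- numeric(n_genes_all)
  as_rna[as_status == "weak"] <- stats::rnorm(sum(as_status == "weak"),
                                              config$weak_rna_height,
                                              config$weak_rna_sd)
  as_rna[as_status == "dominant"] <- stats::rnorm(
    sum(as_status == "dominant"), config$as_rna_height, config$as_rna_sd)
  s_rna <- rep(config$s_rna_height, n_genes_all)
  s_rna[as_status == "dominant"] <-
    as_rna[as_status == "dominant"] / config$as_s_rna_ratio
  active_prom <- rep(FALSE, n_genes_all)
  active_prom[sample(seq_len(n_genes_all),
                     round(config$active_promoter_fraction * n_genes_all))] <-
    TRUE

  truth_genes <- data.frame(
    gene_id = genes$gene_id, class = cls,
    tyr1p_offset = tyr1p_off, polii_offset = polii_off,
    ser5p_offset = polii_off - d_ser5p, ser7p_offset = polii_off - d_ser7p,
    d_tyr1p = d_tyr1p, d_ser5p = d_ser5p, d_ser7p = d_ser7p,
    as_status = as_status, as_rna = as_rna, s_rna = s_rna,
    active_promoter = active_prom,
    stringsAsFactors = FALSE)

  ri <- which(placement$type != "gene")
  regions <- data.frame(region_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        center = integer(0), status = character(0),
                        active = logical(0), stringsAsFactors = FALSE)
  if (length(ri) > 0L) {
    rdf <- placement[ri, , drop = FALSE]
    is_enh <- rdf$type == "enhancer"
    center <- ifelse(is_enh,
                     snap_offset(rdf$start + config$enhancer_width / 2, B),
                     snap_offset(rdf$start + 200, B))
    active <- rep(FALSE, nrow(rdf))
    ei <- which(is_enh)
    if (length(ei) > 0L) {
      active[ei[sample(seq_along(ei),
                       round(config$active_enhancer_fraction *
                               length(ei)))]] <- TRUE
    }
    regions <- data.frame(
      region_id = sprintf("r%03d", seq_len(nrow(rdf))),
      chrom = rdf$chrom, start = rdf$start, end = rdf$end,
      center = center,
      status = ifelse(is_enh, ifelse(active, "active_enhancer", "enhancer"),
                      "lincRNA_distractor"),
      active = active, stringsAsFactors = FALSE)
  }

  sequences <- NULL
  if (config$make_sequence) {
    base_p <- c(A = (1 - config$background_gc) / 2,
                C = config$background_gc / 2,
                G = config$background_gc / 2,
                T = (1 - config$background_gc) / 2)
    prom_p <- c(A = (1 - config$promoter_gc) / 2,
                C = config$promoter_gc / 2,
                G = config$promoter_gc / 2,
                T = (1 - config$promoter_gc) / 2)
    seq_chars <- lapply(chrom_sizes, function(L) {
      sample(names(base_p), L, replace = TRUE, prob = base_p)
    })
    tss <- tss_position(genes)
    for (i in which(cls == "I")) {  # CpG-island-like promoters in class I
      rng <- (tss[i] - 500):(tss[i] + 499) + 1L
      rng <- rng[rng >= 1L & rng <= chrom_sizes[[genes$chrom[i]]]]
      seq_chars[[genes$chrom[i]]][rng] <-
        sample(names(prom_p), length(rng), replace = TRUE, prob = prom_p)
    }
    sequences <- vapply(seq_chars, paste0, character(1), collapse = "")
  }

  list(genes = genes, regions = regions,
       truth = list(genes = truth_genes, regions = regions),
       chrom_sizes = chrom_sizes, sequences = sequences)
}

# deferred signal accumulator: summit/plateau contributions are collected
# as (bin index, value) chunks per (mark, chromosome) and summed once, so
# building tracks never copies whole chromosome vectors
make_accumulator <- function(chrom_sizes, bin, capacity = 2e5) {
  env <- new.env(parent = emptyenv())
  env$nbins <- vapply(chrom_sizes, function(L) as.integer(ceiling(L / bin)),
                      integer(1))
  env$bin <- bin
  env$keys <- character(capacity)
  env$idx <- vector("list", capacity)
  env$val <- vector("list", capacity)
  env$count <- 0L
  env
}

acc_push <- function(env, mark, chrom, idx, val) {
  k <- env$count + 1L
  if (k > length(env$keys)) stop("accumulator capacity exceeded")
  env$count <- k
  env$keys[k] <- paste0(mark, ".", chrom)
  env$idx[[k]] <- idx
  env$val[[k]] <- val
  invisible(NULL)
}

# Gaussian summit; its maximum sits exactly on the bin whose left edge is
# `center - bin/2` (callers centre on planted offsets + bin/2 so the summit
# bin is the planted one)
acc_bump <- function(env, mark, chrom, center, height, sd, bin) {
  n <- env$nbins[[chrom]]
  lo <- max(0L, floor((center - 4 * sd) / bin))
  hi <- min(n - 1L, ceiling((center + 4 * sd) / bin))
  if (hi < lo) return(invisible(NULL))
  idx <- lo:hi
  x <- idx * bin + bin / 2
  acc_push(env, mark, chrom, idx + 1L,
           height * exp(-(x - center)^2 / (2 * sd^2)))
}

acc_plateau <- function(env, mark, chrom, start, end, height, bin) {
  n <- env$nbins[[chrom]]
  s <- max(start, 0); e <- min(end, n * bin)
  if (e <= s) return(invisible(NULL))
  b0 <- s %/% bin; b1 <- (e - 1) %/% bin
  idx <- b0:b1
  ov <- pmin(e, (idx + 1) * bin) - pmax(s, idx * bin)
  acc_push(env, mark, chrom, idx + 1L, height * ov / bin)
}

acc_field <- function(env, mark, chrom) {
  v <- numeric(env$nbins[[chrom]])
  hit <- which(env$keys[seq_len(env$count)] == paste0(mark, ".", chrom))
  if (length(hit) > 0L) {
    idx <- unlist(env$idx[hit], use.names = FALSE)
    val <- unlist(env$val[hit], use.names = FALSE)
    agg <- rowsum(val, idx)
    v[as.integer(rownames(agg))] <- agg[, 1L]
  }
  v
}

smooth_mean <- function(v, w) {
  if (w <= 1L) return(v)
  cs <- cumsum(c(0, v))
  n <- length(v)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Generate coverage tracks embodying the planted truth
#'
#' Builds the full set of mark tracks from the genome's truth tables:
#' promoter-proximal summit pairs for Pol II and the phospho-isoforms (the
#' Tyr1P summit carries the planted antisense/sense height asymmetry
#' `as_s_delta`), gene-body signal for Ser2P and H3K36me3, promoter-flavour
#' H3K4me3 > H3K4me1, enhancer islands with the reverse flavour plus Pol II,
#' isoforms, optional H3K27ac and bidirectional short RNAs, lincRNA-like
#' distractors with H3K36me3 bodies, positioned nucleosome dyads, stranded
#' short-ssRNA tracks, and a pure-background input. Background is Poisson
#' noise per bin (rate `background_rate` per 50 bp, rescaled to the bin
#' size), smoothed over `noise_smooth_bp` to emulate fragment-scale
#' correlation, plus optional Gaussian jitter.
#'
#' @param genome Output of [generate_genome()].
#' @param config The [sim_config()] used.
#' @param bin_size Bin width of the emitted tracks (default
#'   `config$bin_size`).
#' @param marks Optional character vector restricting the output; unknown
#'   names are an error.
#' @return Named list of [genome_track()]s: `polii`, `tyr1p`, `ser5p`,
#'   `ser7p`, `ser2p`, `h3k4me1`, `h3k4me3`, `h3k36me3`, `h3k27ac`,
#'   `input`, `ssrna_plus`, `ssrna_minus`, `mnase_mid`, `mnase_den`.
#' @export
generate_tracks <- function(genome, config, bin_size = config$bin_size,
                            marks = NULL) {
  set.seed(config$seed + 1L)
  B <- as.integer(bin_size)
  all_marks <- c("polii", "tyr1p", "ser5p", "ser7p", "ser2p",
                 "h3k4me1", "h3k4me3", "h3k36me3", "h3k27ac", "input",
                 "ssrna_plus", "ssrna_minus", "mnase_mid", "mnase_den")
  if (!is.null(marks)) {
    bad <- setdiff(marks, all_marks)
    if (length(bad) > 0L) stop("unknown mark(s): ", paste(bad, collapse = ", "))
  }
  genes <- genome$genes
  tg <- genome$truth$genes
  regions <- genome$regions
  acc <- make_accumulator(genome$chrom_sizes, B,
                          capacity = 40L * (nrow(genes) + nrow(regions)) +
                            1000L)

  tss <- tss_position(genes)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  # oriented offset -> genomic bump centre landing the summit on the bin
  # whose oriented left edge is the planted offset
  gcenter <- function(i, off) tss[i] + sgn[i] * off + sgn[i] * B / 2
  h <- config$peak_height
  delta <- config$as_s_delta
  sd_pk <- config$peak_sd

  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    # Pol II / Ser5P / Ser7P: equal-height summit pairs mirrored about the
    # TSS (per-gene antisense/sense symmetry); the mirror is omitted for
    # TSS-proximal summits (would blend with the main one), and Pol II
    # additionally gets a broad central component
    for (m in c("polii", "ser5p", "ser7p")) {
      off <- switch(m, polii = tg$polii_offset[i],
                    ser5p = tg$ser5p_offset[i], ser7p = tg$ser7p_offset[i])
      acc_bump(acc, m, chrom, gcenter(i, off), h, sd_pk, B)
      # the mirror of summit bin [off, off + B) about the TSS is the bin
      # [-off - B, -off): exact per-gene antisense/sense symmetry. The
      # mirror is omitted for TSS-proximal summits (the two summits would
      # blend and displace the maximum); those genes draw their offsets
      # from a TSS-symmetric grid instead, so symmetry holds over genes.
      if (abs(off) >= config$mirror_min) {
        acc_bump(acc, m, chrom, gcenter(i, -off - B), h, sd_pk, B)
      }
    }
    acc_bump(acc, "polii", chrom, gcenter(i, 0),
             config$polii_broad_height, config$polii_broad_sd, B)
    # Tyr1P: dominant summit at the planted offset (height h + delta),
    # mirrored minor summit (h - delta) when far enough from the TSS
    oy <- tg$tyr1p_offset[i]
    acc_bump(acc, "tyr1p", chrom, gcenter(i, oy), h + delta, sd_pk, B)
    if (abs(oy) >= config$mirror_min) {
      acc_bump(acc, "tyr1p", chrom, gcenter(i, -oy - B), h - delta, sd_pk, B)
    }
    # gene bodies
    body <- if (genes$strand[i] == "+") c(genes$start[i] + 500, genes$end[i])
            else c(genes$start[i], genes$end[i] - 500)
    acc_plateau(acc, "ser2p", chrom, body[1], body[2], config$body_height, B)
    acc_plateau(acc, "h3k36me3", chrom, body[1], body[2],
                config$body_height, B)
    # promoter chromatin
    acc_bump(acc, "h3k4me3", chrom, gcenter(i, 0),
             config$promoter_me3_height, config$promoter_me_sd, B)
    acc_bump(acc, "h3k4me1", chrom, gcenter(i, 0),
             config$promoter_me1_height, config$promoter_me_sd, B)
    if (tg$active_promoter[i]) {
      acc_bump(acc, "h3k27ac", chrom, gcenter(i, 0),
               config$promoter_k27ac_height, config$broad_sd, B)
    }
    # stranded short ssRNAs: antisense at the Tyr1P summit, sense at +150
    as_track <- if (genes$strand[i] == "+") "ssrna_minus" else "ssrna_plus"
    s_track <- if (genes$strand[i] == "+") "ssrna_plus" else "ssrna_minus"
    if (tg$as_rna[i] > 0) {
      acc_bump(acc, as_track, chrom, gcenter(i, oy), tg$as_rna[i], sd_pk, B)
    }
    acc_bump(acc, s_track, chrom, gcenter(i, 150), tg$s_rna[i], sd_pk, B)
    # positioned nucleosomes (-3/-2/-1/+1 dyads, NDR in between)
    for (doff in config$dyad_offsets) {
      acc_bump(acc, "mnase_mid", chrom, gcenter(i, doff),
               config$dyad_mid_height, config$dyad_mid_sd, B)
      acc_bump(acc, "mnase_den", chrom, gcenter(i, doff),
               config$dyad_den_height, config$dyad_den_sd, B)
    }
  }

  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    c0 <- regions$center[i] + B / 2
    if (regions$status[i] == "lincRNA_distractor") {
      acc_bump(acc, "polii", chrom, c0, config$enhancer_polii_height,
               sd_pk, B)
      acc_bump(acc, "h3k4me1", chrom, c0, config$enhancer_me1_height,
               config$broad_sd, B)
      acc_bump(acc, "h3k4me3", chrom, c0, config$enhancer_me3_height,
               config$broad_sd, B)
      acc_plateau(acc, "h3k36me3", chrom, regions$start[i] + 700,
                  regions$end[i], config$distractor_k36_height, B)
      acc_bump(acc, "tyr1p", chrom, c0, 2, sd_pk, B)
      next
    }
    # enhancer island
    acc_bump(acc, "polii", chrom, c0, config$enhancer_polii_height, sd_pk, B)
    acc_bump(acc, "tyr1p", chrom, c0, config$enhancer_tyr1p_height, sd_pk, B)
    acc_bump(acc, "ser5p", chrom, c0, config$enhancer_ser5p_height, sd_pk, B)
    acc_bump(acc, "ser7p", chrom, c0, config$enhancer_ser7p_height, sd_pk, B)
    acc_bump(acc, "h3k4me1", chrom, c0, config$enhancer_me1_height,
             config$broad_sd, B)
    acc_bump(acc, "h3k4me3", chrom, c0, config$enhancer_me3_height,
             config$broad_sd, B)
    if (regions$active[i]) {
      acc_bump(acc, "h3k27ac", chrom, c0, config$enhancer_k27ac_height,
               config$broad_sd, B)
    }
    for (s in c(-150, 150)) {
      tr <- if (s < 0) "ssrna_minus" else "ssrna_plus"
      acc_bump(acc, tr, chrom, c0 + s, config$enhancer_rna_height, sd_pk, B)
    }
    for (doff in c(-430, -250, 250, 430)) {
      acc_bump(acc, "mnase_mid", chrom, c0 + doff, config$dyad_mid_height,
               config$dyad_mid_sd, B)
      acc_bump(acc, "mnase_den", chrom, c0 + doff, config$dyad_den_height,
               config$dyad_den_sd, B)
    }
  }

  rate <- config$background_rate * B / 50
  w <- max(1L, round(config$noise_smooth_bp / B))
  out <- list()
  for (m in all_marks) {
    vals <- list()
    for (chrom in sort(names(genome$chrom_sizes))) {
      v <- acc_field(acc, m, chrom)
      noise <- smooth_mean(stats::rpois(length(v), rate), w)
      if (config$noise_jitter_sd > 0) {
        noise <- noise + stats::rnorm(length(v), 0, config$noise_jitter_sd)
      }
      vals[[chrom]] <- pmax(v + noise, 0)
    }
    strand_tag <- switch(m, ssrna_plus = "plus", ssrna_minus = "minus",
                         "none")
    out[[m]] <- genome_track(vals, B, strand_tag = strand_tag)
  }
  if (!is.null(marks)) out <- out[marks]
  out
}

#' Generate a single-end tag stream and paired MNase fragments
#'
#' Single-end ChIP tags are drawn around every planted Pol II summit with
#' standard fragment geometry: fragment centres scatter around the summit,
#' forward-read 5' ends sit `fragment_length / 2` upstream of the centre and
#' reverse-read 5' ends the same distance downstream, so the strand
#' cross-correlation peaks at the fragment length. Uniform background tags
#' and optional planted duplicate piles are added. Paired fragments are
#' 147-bp spans around the planted nucleosome dyads.
#'
#' @param genome Output of [generate_genome()].
#' @param config The [sim_config()] used.
#' @return List: `tags` (`chrom`, `start`, `strand`), `pairs` (`chrom`,
#'   `start`, `end`).
#' @export
generate_tag_stream <- function(genome, config) {
  set.seed(config$seed + 2L)
  genes <- genome$genes
  tg <- genome$truth$genes
  f <- config$fragment_length
  centers <- data.frame(chrom = character(0), pos = numeric(0))
  if (nrow(genes) > 0L) {
    tss <- tss_position(genes)
    sgn <- ifelse(genes$strand == "+", 1, -1)
    centers <- rbind(centers,
                     data.frame(chrom = genes$chrom,
                                pos = tss + sgn * tg$polii_offset))
  }
  if (nrow(genome$regions) > 0L) {
    centers <- rbind(centers, data.frame(chrom = genome$regions$chrom,
                                         pos = genome$regions$center))
  }
  tags <- list()
  for (i in seq_len(nrow(centers))) {
    n <- config$tags_per_peak
    fc <- round(centers$pos[i] + stats::rnorm(n, 0, config$peak_sd))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", fc - f %/% 2, fc + f %/% 2)
    tags[[length(tags) + 1L]] <- data.frame(chrom = centers$chrom[i],
                                            start = start, strand = strand,
                                            stringsAsFactors = FALSE)
  }
  for (chrom in names(genome$chrom_sizes)) {
    n <- config$background_tags
    if (n > 0L) {
      tags[[length(tags) + 1L]] <- data.frame(
        chrom = chrom,
        start = sample.int(genome$chrom_sizes[[chrom]], n, replace = TRUE) - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$planted_duplicates)) {
    pd <- config$planted_duplicates
    tags[[length(tags) + 1L]] <- data.frame(
      chrom = rep(pd$chrom, pd$count),
      start = rep(pd$pos, pd$count),
      strand = rep(pd$strand, pd$count), stringsAsFactors = FALSE)
  }
  tags <- if (length(tags)) do.call(rbind, tags) else
    data.frame(chrom = character(0), start = integer(0),
               strand = character(0))
  if (nrow(tags) > 0L) {
    L <- genome$chrom_sizes[tags$chrom]
    tags$start <- pmin(pmax(tags$start, 0L), L - 1L)
  }

  pairs <- list()
  if (nrow(genes) > 0L) {
    tss <- tss_position(genes)
    sgn <- ifelse(genes$strand == "+", 1, -1)
    for (i in seq_len(nrow(genes))) {
      for (doff in config$dyad_offsets) {
        d <- tss[i] + sgn[i] * doff
        mid <- round(d + stats::rnorm(config$pairs_per_dyad, 0,
                                      config$dyad_mid_sd))
        pairs[[length(pairs) + 1L]] <- data.frame(
          chrom = genes$chrom[i], start = mid - 73L, end = mid + 74L,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  list(tags = tags, pairs = pairs)
}

#' Generate a tissue expression atlas and replicate matrix
#'
#' The atlas is a gene x tissue matrix of lognormal expression values with a
#' planted signal: genes flanking a true enhancer (nearest on each side)
#' have their expression multiplied by `expression_factor` in
#' `specific_tissue`. The replicate matrix is probe-level (some genes carry
#' several probes, exercising the probe-median merge rule) with
#' multiplicative replicate noise.
#'
#' @param genome Output of [generate_genome()].
#' @param config The [sim_config()] used.
#' @return List: `atlas` (gene x tissue matrix), `replicates` (probe x
#'   replicate matrix), `probe_map` (`probe`, `gene_id`),
#'   `adjacent_genes` (planted enhancer-flanking gene ids),
#'   `specific_tissue`.
#' @export
generate_expression_atlas <- function(genome, config) {
  set.seed(config$seed + 3L)
  genes <- genome$genes
  tissues <- c(config$specific_tissue,
               sprintf("tissue_%02d", seq_len(config$n_tissues - 1L)))
  n <- nrow(genes)
  atlas <- matrix(stats::rlnorm(n * length(tissues), config$expr_meanlog,
                                config$expr_sdlog),
                  nrow = n, dimnames = list(genes$gene_id, tissues))
  enh <- genome$regions[genome$regions$status %in%
                          c("enhancer", "active_enhancer"), , drop = FALSE]
  adjacent <- character(0)
  for (i in seq_len(nrow(enh))) {
    g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
    left <- g[g$end <= enh$start[i], , drop = FALSE]
    right <- g[g$start >= enh$end[i], , drop = FALSE]
    if (nrow(left) > 0L) adjacent <- c(adjacent,
                                       left$gene_id[which.max(left$end)])
    if (nrow(right) > 0L) adjacent <- c(adjacent,
                                        right$gene_id[which.min(right$start)])
  }
  adjacent <- unique(adjacent)
  atlas[adjacent, config$specific_tissue] <-
    atlas[adjacent, config$specific_tissue] * config$expression_factor

  n_probes <- 1L + stats::rbinom(n, 2L, config$multi_probe_fraction / 2)
  probe_map <- data.frame(
    probe = sprintf("p%05d", seq_len(sum(n_probes))),
    gene_id = rep(genes$gene_id, n_probes), stringsAsFactors = FALSE)
  base <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  probe_base <- rep(base, n_probes) *
    exp(stats::rnorm(sum(n_probes), 0, 0.2))
  replicates <- matrix(
    probe_base * exp(stats::rnorm(sum(n_probes) * config$n_replicates,
                                  0, 0.1)),
    nrow = sum(n_probes),
    dimnames = list(probe_map$probe,
                    sprintf("rep%d", seq_len(config$n_replicates))))
  list(atlas = atlas, replicates = replicates, probe_map = probe_map,
       adjacent_genes = adjacent, specific_tissue = config$specific_tissue)
}

#' Generate a complete synthetic study
#'
#' @param config A [sim_config()].
#' @param tracks,tags,atlas Logical switches for the heavier components.
#' @return List combining [generate_genome()] output with `tracks`,
#'   `tag_stream` and `expression` components (when requested).
#' @export
simulate_study <- function(config = sim_config(), tracks = TRUE,
                           tags = FALSE, atlas = TRUE) {
  genome <- generate_genome(config)
  out <- genome
  out$config <- config
  if (tracks) out$tracks <- generate_tracks(genome, config)
  if (tags) out$tag_stream <- generate_tag_stream(genome, config)
  if (atlas) out$expression <- generate_expression_atlas(genome, config)
  out
}

#' Write a synthetic study to disk in standard formats
#'
#' Emits fixedStep wiggle per track, BED6 annotation, the chromosome sizes
#' file, FASTA sequence (when generated) and TSV truth/atlas tables under
#' one directory.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(study$genes, file.path(dir, "genes.bed"),
                   keep_category = TRUE)
  write_chrom_sizes(study$chrom_sizes, file.path(dir, "chrom.sizes"))
  if (!is.null(study$tracks)) {
    for (m in names(study$tracks)) {
      write_track(study$tracks[[m]], file.path(dir, paste0(m, ".wig")))
    }
  }
  if (!is.null(study$sequences)) {
    writeLines(unlist(lapply(names(study$sequences), function(ch) {
      c(paste0(">", ch), study$sequences[[ch]])
    })), file.path(dir, "genome.fa"))
  }
  utils::write.table(study$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$regions, file.path(dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$expression)) {
    utils::write.table(study$expression$atlas, file.path(dir, "atlas.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(study$expression$replicates,
                       file.path(dir, "replicates.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(study$expression$probe_map,
                       file.path(dir, "probe_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
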