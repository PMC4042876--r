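test_that("peak calling merges runs across small gaps and finds summits", {
  tr <- vec_track(c(0, 0, 400, 500, 0, 0, 600, 0))
  ps <- call_peaks(tr, threshold = 350, max_gap = 150)
  expect_equal(nrow(ps$peaks), 1)
  expect_equal(ps$peaks$start, 100)   # bin 2 (0-based)
  expect_equal(ps$peaks$end, 350)     # through bin 6
  expect_equal(ps$peaks$summit, 300)  # bin 6
  expect_equal(ps$peaks$height, 600)

  ps2 <- call_peaks(tr, threshold = 350, max_gap = 50)
  expect_equal(nrow(ps2$peaks), 2)

  expect_equal(nrow(call_peaks(tr, threshold = 700, max_gap = 50)$peaks), 0)
})

test_that("peak caller equals the brute-force run-scan oracle", {
  for (s in 1:25) {
    set.seed(s)
    v <- rpois(500, 0.5) * runif(500, 0.5, 2)
    tr <- genome_track(list(chr1 = v, chr2 = rev(v)), 50)
    thr <- runif(1, 0.5, 2)
    gap <- sample(c(0, 50, 100, 200, 500), 1)
    got <- call_peaks(tr, thr, gap)$peaks
    want <- peaks_oracle(tr, thr, gap)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("me3/me1 ratios drop zero-denominator regions with a message", {
  me3 <- vec_track(rep(2, 20))
  me1 <- vec_track(c(rep(0, 10), rep(4, 10)))
  regions <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000))
  expect_message(r <- region_me_ratio(me3, me1, regions), "zero H3K4me1")
  expect_true(is.na(r[1]))
  expect_equal(r[2], 0.5)
})

test_that("ratio threshold uses the annotated-promoter quantile or a constant", {
  set.seed(41)
  intergenic <- runif(40, 0.1, 0.3)
  promoter <- runif(40, 3, 5)
  annotated <- rnorm(200, 3, 0.5)
  tau <- ratio_threshold(intergenic, promoter, annotated)
  expect_equal(tau, quantile(annotated, 0.05, names = FALSE))
  expect_true(all(intergenic < tau))
  expect_true(all(promoter > tau))
  expect_equal(ratio_threshold(intergenic, promoter, annotated,
                               mode = "constant", constant = 1.7), 1.7)
  expect_error(ratio_threshold(intergenic[1:5], promoter, annotated), "10")
})

# one compact constructed genome exercising the rejection rules
constructed_workflow_inputs <- function() {
  B <- 50
  nb <- 2000  # 100 kb
  bump <- function(center, h, sd = 100) {
    x <- (seq_len(nb) - 1) * B + B / 2
    h * exp(-(x - center)^2 / (2 * sd^2))
  }
  gene <- gene_row("g1", start = 10000, end = 20000)
  prom <- bump(10000, 8) # promoter signal at the gene TSS
  enh_far <- 60000       # > 5 kb from the gene: survives
  enh_near <- 24000      # 4 kb from the gene: rejected by the distance rule
  polii <- vec_track(prom + bump(enh_far, 6) + bump(enh_near, 6), B)
  me1 <- vec_track(0.5 * prom + bump(enh_far, 8) + bump(enh_near, 8) +
                     bump(10000, 2, 400), B)
  me3 <- vec_track(bump(10000, 8, 400) + bump(enh_far, 2.4) +
                     bump(enh_near, 2.4), B)
  k36 <- vec_track(bump(15000, 5, 800), B)
  ssrna <- vec_track(rep(1, nb), B)
  tracks <- list(polii = polii, h3k4me1 = me1, h3k4me3 = me3, ssrna = ssrna)
  peaks <- list(polii = call_peaks(polii, 2, 200),
                h3k4me1 = call_peaks(me1, 2, 200),
                h3k4me3 = call_peaks(me3, 2, 200),
                h3k36me3 = call_peaks(k36, 2, 200))
  list(peaks = peaks, tracks = tracks, genes = gene)
}

test_that("the Pol II workflow routes promoters, rejects near-gene regions", {
  inp <- constructed_workflow_inputs()
  res <- suppressMessages(
    classify_regions_polii(inp$peaks, inp$tracks, inp$genes,
                           params = list(ratio_mode = "constant",
                                         ratio_constant = 1)))
  # the promoter-window candidate went to the promoter branch
  expect_equal(res$stages$P1, 1)
  expect_equal(res$stages$P3, 1)
  # of the two intergenic candidates only the distal one survives
  expect_equal(res$stages$E1, 2)
  expect_equal(res$stages$E2, 1)
  expect_equal(nrow(res$rejected$near_gene), 1)
  expect_equal(sum(res$calls$class == "enhancer"), 1)
  enh <- res$calls[res$calls$class == "enhancer", ]
  expect_lt(abs(enh$center - 60000), 100)
  # stage counts are monotone along each branch
  expect_true(all(diff(unlist(res$stages[c("E1", "E2", "E3", "E4")])) <= 0))
  expect_true(all(diff(unlist(res$stages[c("P1", "P2", "P3")])) <= 0))
  expect_error(classify_regions_polii(inp$peaks[-1], inp$tracks, inp$genes),
               "polii")
})

test_that("H3K36me3 in the vicinity rejects lincRNA-like intergenic regions", {
  inp <- constructed_workflow_inputs()
  # plant a K36me3 body just over 1 kb from the distal candidate's boundary
  k36 <- vec_track({
    x <- (seq_len(2000) - 1) * 50 + 25
    5 * exp(-(x - 61800)^2 / (2 * 300^2))
  }, 50)
  inp$peaks$h3k36me3 <- call_peaks(k36, 2, 200)
  res <- suppressMessages(
    classify_regions_polii(inp$peaks, inp$tracks, inp$genes,
                           params = list(ratio_mode = "constant",
                                         ratio_constant = 1)))
  expect_equal(res$stages$E2, 0)
  expect_equal(sum(res$calls$class == "enhancer"), 0)
})

test_that("the H3K27ac workflow splits whole and active sets", {
  cfg <- small_config(seed = 31)
  genome <- generate_genome(cfg)
  tracks <- generate_tracks(genome, cfg)
  pk <- lapply(tracks[c("h3k4me1", "h3k4me3", "h3k36me3", "h3k27ac")],
               call_peaks, threshold = 2, max_gap = 350)
  ss <- merge_tracks(list(tracks$ssrna_plus, tracks$ssrna_minus), "sum")
  res <- suppressMessages(classify_regions_k27ac(
    pk, list(h3k4me1 = tracks$h3k4me1, h3k4me3 = tracks$h3k4me3, ssrna = ss),
    genome$genes))
  truth <- genome$regions
  n_active_truth <- sum(truth$status == "active_enhancer")
  n_enh_truth <- sum(truth$status %in% c("enhancer", "active_enhancer"))
  called_active <- sum(res$calls$class == "active_enhancer")
  called_whole <- sum(res$calls$class %in% c("enhancer", "active_enhancer"))
  expect_lte(abs(called_active - n_active_truth), 1)
  expect_lte(abs(called_whole - n_enh_truth), 1)
  # planted enhancers without H3K27ac stay in the whole set only
  expect_equal(called_whole - called_active,
               sum(truth$status == "enhancer"))
  # stage monotonicity within each branch
  expect_true(all(diff(unlist(res$stages[c("E1'", "E2'", "E3'")])) <= 0))
  expect_lte(res$stages[["E5'"]], res$stages[["E4'"]])
  expect_lte(res$stages[["E6'"]], res$stages[["E3'"]])
  expect_error(classify_regions_k27ac(pk[-4], list(), genome$genes),
               "h3k27ac")
})

test_that("normalised mark statistics compare classes with MWW", {
  calls <- data.frame(chrom = "chr1",
                      start = c(1000, 6000, 11000, 16000),
                      end = c(2000, 7000, 12000, 17000),
                      center = c(1500, 6500, 11500, 16500),
                      class = c("enhancer", "enhancer", "control_promoter",
                                "control_promoter"))
  polii <- vec_track(rep(2, 400))
  out <- suppressWarnings(enhancer_mark_stats(calls, polii, polii))
  expect_true(all(out$values$value == 1))
  expect_equal(out$p, 1)
  # planted 2x ratio at enhancers
  v <- rep(2, 400); v[1:180] <- 4
  mark <- vec_track(v)
  out2 <- suppressWarnings(enhancer_mark_stats(calls, mark, polii))
  expect_gt(min(out2$values$value[out2$values$class == "enhancer"]),
            max(out2$values$value[out2$values$class == "promoter"]))
  expect_error(enhancer_mark_stats(calls[1:2, ], mark, polii), "class")
})

test_that("MWW U and Spearman rho match brute-force oracles on small instances", {
  set.seed(81)
  for (i in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x <- sample(1:50, n1, replace = TRUE)  # ties included
    y <- sample(1:50, n2, replace = TRUE)
    w <- suppressWarnings(wilcox.test(x, y))
    expect_equal(unname(w$statistic), mww_u_oracle(x, y))
    m <- sample(4:30, 1)
    a <- rnorm(m); b <- rnorm(m)
    expect_equal(cor(a, b, method = "spearman"),
                 cor(rank(a), rank(b)), tolerance = 1e-12)
  }
})

test_that("tissue specificity ranks the planted tissue first", {
  cfg <- small_config(seed = 9)
  genome <- generate_genome(cfg)
  atlas <- generate_expression_atlas(genome, cfg)
  # region set taken from planted truth
  truth_enh <- genome$regions[genome$regions$status %in%
                                c("enhancer", "active_enhancer"), ]
  calls <- data.frame(chrom = truth_enh$chrom, start = truth_enh$start,
                      end = truth_enh$end, center = truth_enh$center,
                      class = "enhancer")
  res <- suppressMessages(tissue_specificity(calls, genome$genes,
                                             atlas$atlas))
  expect_equal(res$table$tissue[1], "B_cell")
  expect_setequal(res$associated, atlas$adjacent_genes)
})

test_that("an all-identical atlas yields equal p values in alphabetical order", {
  genes <- rbind(gene_row("a", start = 10000, end = 16000),
                 gene_row("b", start = 40000, end = 46000))
  atlas <- matrix(rep(c(1, 2), 3), nrow = 2,
                  dimnames = list(c("a", "b"), c("t_c", "t_a", "t_b")))
  calls <- data.frame(chrom = "chr1", start = 25000, end = 26000,
                      center = 25500, class = "enhancer")
  res <- suppressWarnings(tissue_specificity(calls, genes, atlas))
  expect_equal(length(unique(res$table$p)), 1)
  expect_equal(res$table$tissue, c("t_a", "t_b", "t_c"))
})

test_that("a region at a chromosome end logs a single flanking gene", {
  genes <- gene_row("a", start = 50000, end = 56000)
  atlas <- matrix(rnorm(2), 1, 2, dimnames = list("a", c("t1", "t2")))
  calls <- data.frame(chrom = "chr1", start = 10000, end = 11000,
                      center = 10500, class = "enhancer")
  expect_message(res <- suppressWarnings(
    tissue_specificity(calls, genes, atlas)), "flanking")
  expect_equal(res$associated, "a")
})
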