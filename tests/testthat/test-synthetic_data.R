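test_that("all generator outputs are reproducible under a fixed seed", {
  cfg <- small_config(seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  t1 <- generate_tracks(g1, cfg, marks = c("polii", "input"))
  t2 <- generate_tracks(g2, cfg, marks = c("polii", "input"))
  expect_identical(t1, t2)
  s1 <- generate_tag_stream(g1, cfg)
  s2 <- generate_tag_stream(g2, cfg)
  expect_identical(s1, s2)
  a1 <- generate_expression_atlas(g1, cfg)
  a2 <- generate_expression_atlas(g2, cfg)
  expect_identical(a1, a2)
})

test_that("class labels are drawn at the configured proportions", {
  cfg <- sim_config(seed = 77, n_genes = 1854L, n_chromosomes = 10L,
                    chrom_length = 2.4e6, enhancer_count = 0L,
                    distractor_count = 0L, make_sequence = FALSE,
                    class_props = c(I = 0.55, II = 0.32, III = 0.13))
  genome <- generate_genome(cfg)
  counts <- table(genome$truth$genes$class)[c("I", "II", "III")]
  expected <- c(1020, 593, 241)
  # oracle: multinomial sampling error around n * p
  se <- sqrt(1854 * c(0.55, 0.32, 0.13) * (1 - c(0.55, 0.32, 0.13)))
  expect_true(all(abs(as.numeric(counts) - expected) < 4 * se))
  # planted offsets respect their class ranges with margin beyond the cuts
  tg <- genome$truth$genes
  expect_true(all(tg$tyr1p_offset[tg$class == "I"] <= -150))
  expect_true(all(abs(tg$tyr1p_offset[tg$class == "II"]) <= 80))
  expect_true(all(tg$tyr1p_offset[tg$class == "III"] >= 150))
})

test_that("element placement respects spacing and sizing constraints", {
  cfg <- small_config(seed = 2)
  genome <- generate_genome(cfg)
  for (chrom in unique(genome$genes$chrom)) {
    els <- rbind(genome$genes[genome$genes$chrom == chrom,
                              c("chrom", "start", "end")],
                 genome$regions[genome$regions$chrom == chrom,
                                c("chrom", "start", "end")])
    els <- els[order(els$start), ]
    if (nrow(els) > 1) {
      gaps <- els$start[-1] - els$end[-nrow(els)]
      expect_true(all(gaps >= 5000))
    }
  }
  expect_error(generate_genome(sim_config(n_genes = 500L,
                                          chrom_length = 1e5,
                                          n_chromosomes = 1L)),
               "sizing")
})

test_that("a background-only track has mean close to the Poisson rate", {
  cfg <- small_config(seed = 12)
  genome <- generate_genome(cfg)
  input <- generate_tracks(genome, cfg, marks = "input")$input
  vals <- unlist(input$values)
  se <- sqrt(0.2 / length(vals))
  expect_lt(abs(mean(vals) - 0.2), 3 * se)
})

test_that("planted enhancer and promoter me3/me1 ratios are fully separated", {
  cfg <- small_config(seed = 13)
  genome <- generate_genome(cfg)
  tr <- generate_tracks(genome, cfg, marks = c("h3k4me1", "h3k4me3"))
  enh <- genome$regions[genome$regions$status != "lincRNA_distractor", ]
  enh_reg <- data.frame(chrom = enh$chrom, start = enh$center - 500,
                        end = enh$center + 500)
  prom <- standard_window(genome$genes, "tss")
  r_enh <- region_means(tr$h3k4me3, enh_reg) / region_means(tr$h3k4me1, enh_reg)
  r_prom <- region_means(tr$h3k4me3, prom) / region_means(tr$h3k4me1, prom)
  expect_lt(max(r_enh), min(r_prom))
})

test_that("a zero AS/S asymmetry gives a null Tyr1P antisense/sense contrast", {
  cfg <- small_config(seed = 16, as_s_delta = 0, n_genes = 150L,
                      chrom_length = 1.1e6)
  genome <- generate_genome(cfg)
  tyr <- generate_tracks(genome, cfg, marks = "tyr1p")$tyr1p
  rec <- as_s_means(tyr, genome$genes)
  # distal summits are mirrored per gene; TSS-proximal summit bins are
  # drawn symmetrically, so the population contrast is null
  out <- as_s_test(rec)
  expect_gt(out$p, 0.01)
  expect_lt(abs(mean(rec$as_mean - rec$s_mean)), 0.1)
})

test_that("a planted duplicate pile appears exactly at its configured depth", {
  cfg <- small_config(seed = 18, background_tags = 0L,
                      planted_duplicates = list(chrom = "chr2",
                                                pos = 123450L,
                                                strand = "+", count = 500L))
  genome <- generate_genome(cfg)
  stream <- generate_tag_stream(genome, cfg)
  hit <- stream$tags$chrom == "chr2" & stream$tags$start == 123450L &
    stream$tags$strand == "+"
  expect_equal(sum(hit), 500L)
  kept <- filter_tag_piles(stream$tags, 5)
  expect_equal(sum(kept$chrom == "chr2" & kept$start == 123450L &
                     kept$strand == "+"), 5L)
})

test_that("an empty truth yields an empty tag stream", {
  cfg <- sim_config(seed = 1, n_genes = 0L, enhancer_count = 0L,
                    distractor_count = 0L, background_tags = 0L,
                    make_sequence = FALSE)
  genome <- generate_genome(cfg)
  stream <- generate_tag_stream(genome, cfg)
  expect_equal(nrow(stream$tags), 0)
  expect_equal(nrow(stream$pairs), 0)
})

test_that("unknown requested marks are rejected", {
  cfg <- small_config(seed = 1)
  genome <- generate_genome(cfg)
  expect_error(generate_tracks(genome, cfg, marks = "h4k20me3"), "unknown")
})

test_that("a unit expression factor plants no tissue signal", {
  cfg <- small_config(seed = 23, expression_factor = 1)
  genome <- generate_genome(cfg)
  atlas <- generate_expression_atlas(genome, cfg)
  truth_enh <- genome$regions[genome$regions$status %in%
                                c("enhancer", "active_enhancer"), ]
  calls <- data.frame(chrom = truth_enh$chrom, start = truth_enh$start,
                      end = truth_enh$end, center = truth_enh$center,
                      class = "enhancer")
  res <- suppressMessages(tissue_specificity(calls, genome$genes,
                                             atlas$atlas))
  p_planted <- res$table$p[res$table$tissue == "B_cell"]
  expect_gt(p_planted, 1e-3)
})

test_that("study export writes the standard formats round-trippably", {
  cfg <- small_config(seed = 3, n_genes = 10L, enhancer_count = 2L,
                      distractor_count = 1L, make_sequence = TRUE)
  study <- simulate_study(cfg, tracks = FALSE, atlas = FALSE)
  study$tracks <- generate_tracks(study, cfg, marks = c("polii", "input"))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(sizes, study$chrom_sizes)
  back <- read_track(file.path(dir, "polii.wig"), cfg$bin_size, sizes)
  expect_equal(back$values, lapply(study$tracks$polii$values, round, 6))
  genes <- read_annotation(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), 10)
  fa <- readLines(file.path(dir, "genome.fa"))
  expect_equal(sum(startsWith(fa, ">")), cfg$n_chromosomes)
})
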