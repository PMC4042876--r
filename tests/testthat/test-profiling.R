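test_that("anchored rows are 5'-oriented and consistent with region means", {
  tr <- summit_track(center = 5000, height = 6, sd = 100, bin = 50,
                     nbins = 400)
  plus <- data.frame(chrom = "chr1", pos = 5025, strand = "+", id = "p")
  m <- anchored_matrix(tr, plus, flank = 1000)
  # symmetric planted summit -> symmetric row
  expect_equal(m[1, ], rev(m[1, ]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical summit seen from a minus-strand anchor gives the same row
  minus <- data.frame(chrom = "chr1", pos = 5025, strand = "-", id = "m")
  m2 <- anchored_matrix(tr, minus, flank = 1000)
  expect_equal(unname(m2[1, ]), unname(rev(m[1, ])))
  # row means equal region means over the same window
  rm <- region_means(tr, data.frame(chrom = "chr1", start = 4025, end = 6025))
  expect_equal(mean(m[1, ]), rm, tolerance = 1e-12)
})

test_that("flank must sit on the bin grid", {
  tr <- random_track(1)
  a <- data.frame(chrom = "chr1", pos = 3000, strand = "+")
  expect_error(anchored_matrix(tr, a, flank = 130), "multiple")
})

test_that("composite profile is flat for constant tracks and linear in signal", {
  tr <- vec_track(rep(2.5, 600))
  genes <- rbind(gene_row("a", start = 5000, end = 11000),
                 gene_row("b", strand = "-", start = 15000, end = 24000))
  prof <- composite_gene_profile(tr, genes, flank = 1000)
  expect_equal(length(prof$curve), 20 + 1000 + 20)
  expect_equal(prof$curve, rep(2.5, 1040), tolerance = 1e-9,
               ignore_attr = TRUE)
  # linearity
  tr2 <- vec_track(rep(5, 600))
  prof2 <- composite_gene_profile(tr2, genes, flank = 1000)
  expect_equal(prof2$curve, 2 * prof$curve, tolerance = 1e-12)
  expect_error(composite_gene_profile(tr, genes[0, ], flank = 1000), "empty")
})

test_that("a linear ramp across the body interpolates monotonically", {
  v <- numeric(600)
  v[101:220] <- seq(0, 1, length.out = 120)  # ramp over gene body bins
  tr <- vec_track(v)
  g <- gene_row(start = 5000, end = 11000)
  prof <- composite_gene_profile(tr, g, flank = 1000)
  body <- prof$curve[21:1020]
  expect_true(all(diff(body) >= -1e-12))
  expect_lt(body[1], 0.02)
  expect_gt(body[1000], 0.98)
})

test_that("composite equals a brute-force per-bp recomputation", {
  tr <- random_track(19, nbins = 600)
  set.seed(20)
  genes <- do.call(rbind, lapply(1:8, function(i) {
    gene_row(sprintf("g%d", i), chrom = sample(c("chr1", "chr2"), 1),
             strand = sample(c("+", "-"), 1), start = i * 3000,
             end = i * 3000 + sample(c(2100, 4550, 6000), 1))
  }))
  prof <- composite_gene_profile(tr, genes, flank = 1000)
  # independent recomputation from per-bp signal
  oracle <- matrix(0, nrow(genes), 1040)
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    plus <- gi$strand == "+"
    body <- track_values_bp(tr, gi$chrom, gi$start, gi$end)
    up <- track_values_bp(tr, gi$chrom,
                          if (plus) gi$start - 1000 else gi$end,
                          if (plus) gi$start else gi$end + 1000)
    dn <- track_values_bp(tr, gi$chrom,
                          if (plus) gi$end else gi$start - 1000,
                          if (plus) gi$end + 1000 else gi$start)
    if (!plus) { body <- rev(body); up <- rev(up); dn <- rev(dn) }
    nb <- ceiling(length(body) / 50)
    bins <- vapply(seq_len(nb), function(b) {
      mean(body[((b - 1) * 50 + 1):min(b * 50, length(body))])
    }, numeric(1))
    interp <- if (nb == 1) rep(bins, 1000) else
      approx((seq_len(nb) - 0.5) / nb, bins, xout = seq(0, 1, length.out = 1000),
             rule = 2)$y
    upb <- vapply(1:20, function(b) mean(up[((b - 1) * 50 + 1):(b * 50)]),
                  numeric(1))
    dnb <- vapply(1:20, function(b) mean(dn[((b - 1) * 50 + 1):(b * 50)]),
                  numeric(1))
    oracle[i, ] <- c(upb, interp, dnb)
  }
  expect_equal(unname(prof$matrix), oracle, tolerance = 1e-9)
  expect_equal(prof$curve, colMeans(oracle), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rank strata slice sizes and ordering are correct", {
  m <- matrix(rep(1:100, each = 10), nrow = 100, byrow = FALSE)
  m <- matrix(1, 100, 10)
  strata <- rank_strata_profiles(m, ranking = rep(1, 100))
  expect_equal(strata$top5, strata$bottom5)
  expect_equal(lengths(strata$idx), c(top5 = 5L, mid5_20 = 15L, bottom5 = 5L))
  # planted high-signal 5%
  m2 <- matrix(1, 100, 10)
  m2[1:5, ] <- 50
  s2 <- rank_strata_profiles(m2, ranking = rowMeans(m2))
  expect_true(all(s2$top5 > s2$bottom5))
  expect_error(rank_strata_profiles(m2[1:15, ], rowMeans(m2)[1:15]), "20")
})

test_that("curves are invariant to row permutation", {
  set.seed(33)
  m <- matrix(rnorm(600), 60, 10)
  r <- rnorm(60)
  perm <- sample(60)
  a <- rank_strata_profiles(m, r)
  b <- rank_strata_profiles(m[perm, ], r[perm])
  expect_equal(a$top5, b$top5)
  expect_equal(a$bottom5, b$bottom5)
})

test_that("binary sequence content matrices encode W/S classes", {
  expect_equal(sequence_content_matrix("ATGC", "W")[1, ], c(1, 1, 0, 0))
  expect_equal(sequence_content_matrix("aNgT", "S")[1, ], c(0, 0, 1, 0))
  set.seed(5)
  seqs <- vapply(1:20, function(i)
    paste0(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    character(1))
  w <- sequence_content_matrix(seqs, "W")
  s <- sequence_content_matrix(seqs, "S")
  expect_true(all(w + s == 1))
  expect_error(sequence_content_matrix("ACGX", "W"), "only contain")
})

test_that("class I promoters carry planted GC enrichment", {
  cfg <- small_config(seed = 14, make_sequence = TRUE)
  genome <- generate_genome(cfg)
  cls <- genome$truth$genes$class
  tssv <- ifelse(genome$genes$strand == "+", genome$genes$start,
                 genome$genes$end)
  gc_at <- function(i) {
    s <- substr(genome$sequences[[genome$genes$chrom[i]]],
                tssv[i] - 499, tssv[i] + 500)
    mean(sequence_content_matrix(s, "S"))
  }
  gc1 <- vapply(which(cls == "I"), gc_at, numeric(1))
  gc3 <- vapply(which(cls == "III"), gc_at, numeric(1))
  expect_gt(mean(gc1), mean(gc3) + 0.1)
})

test_that("Spearman correlations of region means hit hand-computed values", {
  v1 <- c(1, 2, 3, 4, 5)
  v2 <- c(2, 1, 4, 3, 5)
  t1 <- vec_track(rep(v1, each = 4))
  t2 <- vec_track(rep(v2, each = 4))
  regions <- data.frame(chrom = "chr1", start = (0:4) * 200,
                        end = (0:4) * 200 + 200)
  rs <- region_spearman(list(a = t1, b = t2), regions)
  # rank-displacement oracle: sum d^2 = 4 -> rho = 1 - 24/120 = 0.8
  expect_equal(rs$rho["a", "b"], 0.8)
  expect_equal(region_spearman(list(a = t1, b = t1), regions)$rho["a", "b"], 1)
  t3 <- vec_track(rep(rev(v1), each = 4))
  expect_equal(region_spearman(list(a = t1, b = t3), regions)$rho["a", "b"], -1)
  const <- vec_track(rep(1, 20))
  expect_warning(region_spearman(list(a = t1, b = const), regions),
                 "constant")
})

test_that("strand-mirrored genomes give identical anchored matrices", {
  set.seed(44)
  L <- 20000
  v <- rexp(L / 50)
  fwd <- vec_track(v)
  rev_ <- vec_track(rev(v))
  g_fwd <- gene_row("g", strand = "+", start = 6000, end = 12000)
  g_rev <- gene_row("g", strand = "-", start = L - 12000, end = L - 6000)
  m1 <- anchored_matrix(fwd, gene_anchors(g_fwd, "tss"), 1000)
  m2 <- anchored_matrix(rev_, gene_anchors(g_rev, "tss"), 1000)
  expect_equal(unname(m1), unname(m2))
  p1 <- composite_gene_profile(fwd, g_fwd, flank = 1000)
  p2 <- composite_gene_profile(rev_, g_rev, flank = 1000)
  expect_equal(p1$curve, p2$curve, tolerance = 1e-9)
})
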