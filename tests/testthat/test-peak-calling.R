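test_that("reads are binned by midpoint and counts are conserved", {
  ## 0-based read [150,250) has midpoint 200 -> third 100-bp bin
  rs <- read_set(GRanges("chr1", IRanges(151, 250)), "s", "input",
                 "TGFb_minus")
  tr <- bin_reads(rs, c(chr1 = 1000), bin_size = 100)
  expect_equal(tr$counts$chr1, c(0, 0, 1, rep(0, 7)))

  rs0 <- read_set(GRanges(), "s", "input", "TGFb_minus")
  tr0 <- bin_reads(rs0, c(chr1 = 550), bin_size = 100)
  expect_equal(sum(unlist(tr0$counts)), 0)
  expect_length(tr0$counts$chr1, 6)  # trailing partial bin included
  expect_equal(tr0$library_size, 0)

  set.seed(21)
  n <- 1e4
  start <- sample(1:9900, n, replace = TRUE)
  rs2 <- read_set(GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                          IRanges(start, width = 50)),
                  "s", "input", "TGFb_minus")
  tr2 <- bin_reads(rs2, c(chr1 = 10000, chr2 = 10000), bin_size = 73)
  expect_equal(sum(unlist(tr2$counts)), n)

  rs_bad <- read_set(GRanges("chrX", IRanges(1, 50)), "s", "input",
                     "TGFb_minus")
  expect_error(bin_reads(rs_bad, c(chr1 = 1000)), "chrX")
})

test_that("signal ratio reduces to identity and density limits", {
  chip <- make_track(list(chr1 = rep(5, 50)))
  ctrl <- make_track(list(chr1 = rep(5, 50)))
  rt <- ratio_track(chip, ctrl, pseudocount = 1)
  expect_equal(rt$ratio$chr1, rep(1, 50))

  ## no control, uniform chip -> self-normalized to ~1
  rt2 <- ratio_track(chip, pseudocount = 1)
  expect_equal(rt2$ratio$chr1, rep(6 / 5, 50))  # (5+1)/median(5)

  ## one bin at 10x control density, pseudocount -> 0 limit
  chip3 <- make_track(list(chr1 = c(rep(10, 49), 100)))
  ctrl3 <- make_track(list(chr1 = rep(10, 50)))
  r3 <- ratio_track(chip3, ctrl3, pseudocount = 1e-9)$ratio$chr1[50]
  lib_ratio <- sum(unlist(ctrl3$counts)) / sum(unlist(chip3$counts))
  expect_equal(r3, 10 * lib_ratio, tolerance = 1e-6)

  expect_error(ratio_track(chip, make_track(list(chr1 = rep(5, 50)),
                                            bin_size = 50)),
               "bin_size")
})

test_that("peak calling thresholds, merges and reports summits correctly", {
  flat <- make_ratio(list(chr1 = rep(1, 100)))
  expect_length(call_peaks(flat, threshold = 8), 0)

  ## two runs 150 bp apart with merge_gap 200 merge into one peak
  v <- rep(1, 40)
  v[11:14] <- 9       # [500,700) at bin 50
  v[18:21] <- 9       # gap of 3 bins = 150 bp
  rt <- make_ratio(list(chr1 = v), bin_size = 50)
  pk <- call_peaks(rt, 8, merge_gap = 200, min_width = 100)
  expect_length(pk, 1)
  expect_equal(start(pk), 501)
  expect_equal(end(pk), 1050)
  ## without merging they stay apart
  pk2 <- call_peaks(rt, 8, merge_gap = 0, min_width = 100)
  expect_length(pk2, 2)

  ## summit is the centre of the max-ratio bin, leftmost on ties
  v3 <- rep(1, 40); v3[11] <- 9; v3[12] <- 12; v3[13] <- 12
  pk3 <- call_peaks(make_ratio(list(chr1 = v3), bin_size = 50), 8,
                    merge_gap = 0, min_width = 100)
  expect_equal(mcols(pk3)$max_ratio, 12)
  expect_equal(mcols(pk3)$summit, 11 * 50 + 26)  # centre of bin 12
})

test_that("peak calling is monotone in threshold and idempotent", {
  set.seed(31)
  v <- 1 + rexp(500, 1 / 2)
  v[100:110] <- 12; v[300:303] <- 9
  rt <- make_ratio(list(chr1 = v))
  p_lo <- call_peaks(rt, 5)
  p_hi <- call_peaks(rt, 9)
  ## raising the threshold never adds a peak and never widens one
  expect_true(all(overlapsAny(p_hi, p_lo)))
  ov <- findOverlaps(p_hi, p_lo)
  expect_true(all(width(p_hi)[queryHits(ov)] <= width(p_lo)[subjectHits(ov)]))

  ## restricting the track to called regions and re-calling returns them
  v_masked <- rep(0, 500)
  for (i in seq_along(p_lo)) {
    b <- (start(p_lo)[i] - 1) %/% 100 + 1
    e <- (end(p_lo)[i] - 1) %/% 100 + 1
    v_masked[b:e] <- v[b:e]
  }
  p_again <- call_peaks(make_ratio(list(chr1 = v_masked)), 5)
  expect_equal(start(p_again), start(p_lo))
  expect_equal(end(p_again), end(p_lo))

  ## summit ratio equals a brute-force maximum scan over the region
  for (i in seq_along(p_lo)) {
    b <- ((start(p_lo)[i] - 1) %/% 100 + 1):((end(p_lo)[i] - 1) %/% 100 + 1)
    expect_equal(mcols(p_lo)$max_ratio[i], max(v[b]))
  }
})

test_that("a planted high-fold region is recovered as one matching peak", {
  cfg <- sim_config(seed = 17, n_genes = 5, n_chroms = 1, chrom_len = 1e6,
                    enrichment_fold = 10, peak_width = 1000,
                    class_fractions = c(nedd9_like = 0.2))
  sim <- simulate_annotation(cfg)
  rs <- simulate_reads(sim$annotation, sim$truth, "Smad2/3", "TGFb_plus", cfg)
  tr <- bin_reads(rs, sim$annotation$chrom_sizes)
  pk <- call_peaks(ratio_track(tr), 8)
  planted <- planted_peaks(sim$truth, "Smad2/3", "TGFb_plus")
  expect_length(pk, length(planted))
  ov <- findOverlaps(pk, planted)
  frac <- width(pintersect(pk[queryHits(ov)], planted[subjectHits(ov)])) /
    width(planted[subjectHits(ov)])
  expect_true(all(frac >= 0.8))
})

test_that("TSS metaprofiles are strand-symmetric, averaged and flat on noise", {
  ## one + strand gene with all signal in the TSS bin
  g1 <- GRanges("chr1", IRanges(5001, 6000), strand = "+",
                gene_id = "gp", tss = 5001)
  cnt <- rep(0, 100); cnt[51] <- 20  # bin [5000,5100) holds the TSS base
  tr <- make_track(list(chr1 = cnt), chrom_sizes = c(chr1 = 10000))
  mp <- tss_metaprofile(tr, g1, flank = 1000)
  expect_equal(mp$offset, seq(-950, 950, by = 100))
  expect_equal(mp$offset[which.max(mp$mean_signal)], 50)

  ## signal mirrored about the TSS base of a - strand gene gives the
  ## identical profile (exact at 1-bp bins)
  set.seed(7)
  tv <- rep(0, 2000); tv[901:1100] <- rpois(200, 3)
  mv <- rep(0, 2000); mv[seq_along(mv)] <- tv[pmax(pmin(2002 - seq_along(mv),
                                                        2000), 1)]
  gp <- GRanges("chr1", IRanges(1001, 1400), strand = "+",
                gene_id = "gp1", tss = 1001)
  gm <- GRanges("chr1", IRanges(601, 1001), strand = "-",
                gene_id = "gm1", tss = 1001)
  tp_ <- make_track(list(chr1 = tv), bin_size = 1,
                    chrom_sizes = c(chr1 = 2000))
  tm_ <- make_track(list(chr1 = mv), bin_size = 1,
                    chrom_sizes = c(chr1 = 2000))
  mp1 <- tss_metaprofile(tp_, gp, flank = 100)
  mp2 <- tss_metaprofile(tm_, gm, flank = 100)
  ## equal library sizes by construction of the mirror
  expect_equal(tm_$library_size, tp_$library_size)
  expect_equal(mp2$mean_signal, mp1$mean_signal)

  ## two genes with disjoint uniform signal average arithmetically
  gg <- c(g1, GRanges("chr1", IRanges(8001, 9000), strand = "+",
                      gene_id = "gq", tss = 8001))
  cnt3 <- rep(0, 100); cnt3[41:60] <- 10; cnt3[71:90] <- 30
  t3 <- make_track(list(chr1 = cnt3), chrom_sizes = c(chr1 = 10000))
  mp3 <- tss_metaprofile(t3, gg, flank = 1000)
  mp_a <- tss_metaprofile(t3, gg[1], flank = 1000)
  mp_b <- tss_metaprofile(t3, gg[2], flank = 1000)
  ## library-size scaling is shared, so the mean profile is the mean
  expect_equal(mp3$mean_signal, (mp_a$mean_signal + mp_b$mean_signal) / 2)

  ## uniform density -> flat profile
  t4 <- make_track(list(chr1 = rep(4, 100)), chrom_sizes = c(chr1 = 10000))
  mp4 <- tss_metaprofile(t4, g1, flank = 1000)
  expect_equal(diff(range(mp4$mean_signal)), 0)

  expect_error(tss_metaprofile(t4, g1[0], flank = 1000), "empty")
  expect_error(tss_metaprofile(t4, g1, flank = 1050), "multiple")
})
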