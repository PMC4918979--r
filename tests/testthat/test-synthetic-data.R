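test_that("simulation is deterministic and streams are independent", {
  cfg <- sim_config(seed = 11, n_genes = 30, chrom_len = 1e6)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(as.data.frame(a1$annotation$genes),
                   as.data.frame(a2$annotation$genes))
  expect_identical(a1$truth$genes, a2$truth$genes)
  expect_identical(a1$truth$peaks, a2$truth$peaks)

  r1 <- simulate_reads(a1$annotation, a1$truth, "Smad2/3", "TGFb_plus", cfg)
  r2 <- simulate_reads(a1$annotation, a1$truth, "Smad2/3", "TGFb_plus", cfg)
  expect_identical(start(r1$reads), start(r2$reads))
  expect_equal(r1$total_sequenced, round(r1$mapped / cfg$mapped_fraction))

  ## per-sample RNG streams: generating another sample in between does not
  ## perturb this one
  invisible(simulate_reads(a1$annotation, a1$truth, "H3K4me3", "TGFb_plus", cfg))
  r3 <- simulate_reads(a1$annotation, a1$truth, "Smad2/3", "TGFb_plus", cfg)
  expect_identical(start(r1$reads), start(r3$reads))
})

test_that("gene placement is disjoint, gapped, exonic and two-stranded", {
  cfg <- sim_config(seed = 3, n_genes = 50, n_chroms = 1, chrom_len = 1e6,
                    min_gene_gap = 2000)
  sim <- simulate_annotation(cfg)
  g <- sim$annotation$genes
  expect_length(g, 50)
  ## brute-force pairwise disjointness
  ov <- findOverlaps(g, g)
  expect_true(all(queryHits(ov) == subjectHits(ov)))
  gs <- sort(g, ignore.strand = TRUE)
  gaps <- start(gs)[-1] - end(gs)[-length(gs)] - 1
  expect_true(all(gaps >= cfg$min_gene_gap))
  expect_true(all(lengths(sim$annotation$exons) %in% 2:5))
  expect_setequal(unique(as.character(strand(g))), c("+", "-"))
  ## every Smad target has its planted peak midpoint inside its window
  tw <- bivalentSmad:::target_windows(sim$annotation, 10000)
  pk <- sim$truth$peaks[sim$truth$peaks$antibody == "Smad2/3", ]
  mids <- (pk$start + pk$end) %/% 2
  i <- match(pk$gene_id, g$gene_id)
  expect_true(all(mids >= start(tw)[i] & mids <= end(tw)[i]))
})

test_that("degenerate and infeasible configurations are handled", {
  empty <- simulate_annotation(sim_config(seed = 1, n_genes = 0))
  expect_length(empty$annotation$genes, 0)
  expect_equal(nrow(empty$truth$genes), 0)
  expect_equal(nrow(empty$truth$peaks), 0)
  expect_error(
    simulate_annotation(sim_config(seed = 1, n_genes = 500, n_chroms = 1,
                                   chrom_len = 1e6, min_gene_gap = 2000)),
    "cannot place")
})

test_that("read density is calibrated to the configured background", {
  cfg <- sim_config(seed = 5, n_genes = 10, n_chroms = 1, chrom_len = 2e6)
  sim <- simulate_annotation(cfg)
  ## a track with no planted enrichment: pure Poisson background
  rs <- suppressWarnings(
    simulate_reads(sim$annotation, list(peaks = sim$truth$peaks[0, ]),
                   "Smad2/3", "TGFb_minus", cfg))
  dens <- rs$mapped / 2e6
  expect_lt(abs(dens - cfg$background) / cfg$background, 0.01)

  ## planted 10-fold 1 kb peak: expected ~200 in-peak reads at 0.02 reads/bp
  cfg10 <- sim_config(seed = 5, n_genes = 10, n_chroms = 1, chrom_len = 2e6,
                      enrichment_fold = 10, peak_width = 1000)
  sim10 <- simulate_annotation(cfg10)
  pk <- planted_peaks(sim10$truth, "Smad2/3", "TGFb_plus")[1]
  rs10 <- simulate_reads(sim10$annotation, sim10$truth, "Smad2/3",
                         "TGFb_plus", cfg10)
  mids <- (start(rs10$reads) + end(rs10$reads) - 1) %/% 2  # 0-based midpoints
  n_in <- sum(mids >= start(pk) - 1 & mids < end(pk))
  expect_lt(abs(n_in - 200), 4 * sqrt(200))  # Poisson tail bound
})

test_that("expression effects, noise-free limits and the floor behave", {
  cfg0 <- sim_config(seed = 9, n_genes = 40, noise_sigma = 0,
                     frac_low_probes = 0)
  sim <- simulate_annotation(cfg0)
  tg <- simulate_expression(sim$annotation, sim$truth, cfg0, "TGFb")
  ratio <- tg$values[, "24"] / tg$values[, "0"]
  eff <- sim$truth$genes$tgfb_effect[match(unname(tg$probe_to_gene),
                                           sim$truth$genes$gene_id)]
  expect_equal(unname(ratio), eff, tolerance = 1e-12)

  rk <- simulate_expression(sim$annotation, sim$truth, cfg0, "RANKL")
  expect_equal(rk$timepoints, c(0, 3, 12, 24, 48, 72))
  flat_genes <- sim$truth$genes$gene_id[sim$truth$genes$rankl_72 == 1]
  flat_probes <- names(rk$probe_to_gene)[rk$probe_to_gene %in% flat_genes]
  fc <- fold_change(normalize_mean100(rk))
  expect_true(all(fc$categories[flat_probes, ] == "unchanged"))

  ## with noise, planted-up probes rank above neutral ones
  cfg <- sim_config(seed = 9, n_genes = 60)
  sim2 <- simulate_annotation(cfg)
  tg2 <- simulate_expression(sim2$annotation, sim2$truth, cfg, "TGFb")
  r2 <- tg2$values[, "24"] / tg2$values[, "0"]
  up <- sim2$truth$genes$gene_id[sim2$truth$genes$tgfb_effect > 1]
  is_up <- unname(tg2$probe_to_gene) %in% up
  expect_lt(wilcox.test(r2[is_up], r2[!is_up], alternative = "greater")$p.value,
            1e-6)
  ## some probes sit below the 70 floor (silent class + low secondaries)
  expect_gt(sum(apply(tg2$values, 1, max) <= 70), 0)
})

test_that("simulate_dataset writes a loadable, internally consistent bundle", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, n_genes = 20, chrom_len = 1e6)
  sim <- simulate_dataset(cfg, d)
  expect_true(all(file.exists(unlist(sim$paths))))
  anno <- read_annotation(sim$paths$annotation, "gff3")
  expect_equal(anno$genes$gene_id, sim$annotation$genes$gene_id)
  rsets <- load_readsets(sim$paths$samples)
  expect_length(rsets, 6)
  smad <- rsets[[which(vapply(rsets, function(r)
    r$antibody == "Smad2/3", logical(1)))[1]]]
  expect_equal(smad$mapped, sim$readsets[["Smad23_TGFb_plus"]]$mapped)
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$genes$gene_id, anno$genes$gene_id)
})
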