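test_that("BED12 blocks give the first intron by block arithmetic", {
  ## gene at 0-based offset 1000 with blocks [0,100) and [200,300):
  ## the intron is 0-based [1100,1200), i.e. 1-based closed [1101,1200]
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 1300, "gA", 0, "+", 1000, 1300, "0",
                   2, "100,100", "0,200", sep = "\t"), f)
  anno <- read_annotation(f, "bed12")
  g <- anno$genes
  expect_equal(g$gene_id, "gA")
  expect_equal(start(g), 1001)  # BED 0-based start -> 1-based internal
  expect_equal(mcols(g)$intron1_start, 1101)
  expect_equal(mcols(g)$intron1_end, 1200)
  expect_equal(mcols(g)$tss, 1001)
})

test_that("minus-strand first intron is the gap next to the highest exon", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 2000, 3000, "gB", 0, "-", 2000, 3000, "0",
                   3, "100,200,100", "0,400,900", sep = "\t"), f)
  anno <- read_annotation(f, "bed12")
  g <- anno$genes
  expect_equal(mcols(g)$tss, 3000)
  ## exons (1-based): [2001,2100],[2401,2600],[2901,3000]; transcription
  ## order on - strand starts at the highest exon
  expect_equal(mcols(g)$intron1_start, 2601)
  expect_equal(mcols(g)$intron1_end, 2900)
})

test_that("single-exon genes have no first intron and GFF3 round-trips", {
  anno <- tiny_annotation()
  expect_true(is.na(mcols(anno$genes["gSingle"])$intron1_start))
  expect_equal(mcols(anno$genes["gPlus"])$intron1_start, 100501)
  expect_equal(mcols(anno$genes["gPlus"])$intron1_end, 103000)
  expect_equal(mcols(anno$genes["gMinus"])$tss, 50000)
  ## - strand: first intron in transcription order is [42001, 47000]
  expect_equal(mcols(anno$genes["gMinus"])$intron1_start, 42001)
  expect_equal(mcols(anno$genes["gMinus"])$intron1_end, 47000)

  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(anno, f)
  back <- read_annotation(f, "gff3")
  expect_equal(back$genes$gene_id, anno$genes$gene_id)
  expect_equal(start(back$genes), start(anno$genes))
  expect_equal(end(back$genes), end(anno$genes))
  expect_equal(mcols(back$genes)$tss, mcols(anno$genes)$tss)
  expect_equal(mcols(back$genes)$intron1_start, mcols(anno$genes)$intron1_start)
  expect_equal(back$chrom_sizes, anno$chrom_sizes)
})

test_that("malformed GFF3 reports the offending line number", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsim\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsim\tgene\tbroken line"), f)
  expect_error(read_annotation(f, "gff3"), "line.*3")
})

test_that("gene validation rejects zero exons and unstranded genes", {
  g <- GRanges("chr1", IRanges(1, 100), strand = "*", gene_id = "gX")
  ex <- GRangesList(GRanges("chr1", IRanges(1, 100)))
  expect_error(annotation(g, ex, c(chr1 = 1000)), "strand")
  g2 <- GRanges("chr1", IRanges(1, 100), strand = "+", gene_id = "gX")
  expect_error(annotation(g2, GRangesList(GRanges()), c(chr1 = 1000)),
               "zero exons")
})

test_that("BED6 reads parse header metadata and validate intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("#sample_id=s1", "#antibody=Smad2/3", "#condition=TGFb_plus",
               "#total_sequenced=5",
               "chr1\t10\t60\tr1\t0\t+",
               "chr1\t100\t150\tr2\t0\t-",
               "chr1\t200\t250\tr3\t0\t."), f)
  rs <- read_reads_bed(f)
  expect_s3_class(rs, "ReadSet")
  expect_equal(rs$mapped, 3)
  expect_equal(rs$total_sequenced, 5)
  expect_equal(rs$antibody, "Smad2/3")
  expect_equal(start(rs$reads)[1], 11)  # 0-based BED -> 1-based internal

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines("#total_sequenced=7", empty)
  rs0 <- read_reads_bed(empty, antibody = "input", condition = "TGFb_minus")
  expect_equal(rs0$mapped, 0)
  expect_equal(rs0$total_sequenced, 7)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t40\tr1\t0\t+", bad)
  expect_error(read_reads_bed(bad), "invalid interval")
})

test_that("mapped-read percentage follows the rounding contract", {
  rs <- read_set(GRanges(), "s", "input", "TGFb_minus", total_sequenced = 3)
  rs$mapped <- 1
  expect_equal(mapping_summary(rs), 33.3)
  rs$mapped <- 3
  expect_equal(mapping_summary(rs), 100.0)
  rs$total_sequenced <- 0
  expect_error(mapping_summary(rs), "positive")
})

test_that("BED write/read round-trips interval sets", {
  set.seed(42)
  gr <- GRanges("chr1", IRanges(sample(1:10000, 10), width = sample(20:80, 10)),
                strand = sample(c("+", "-"), 10, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(start(sort(back)), start(sort(gr)))
  expect_equal(end(sort(back)), end(sort(gr)))
  expect_equal(as.character(strand(sort(back))), as.character(strand(sort(gr))))

  ## empty peak list -> valid empty file
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(GRanges(), f2)
  expect_true(file.exists(f2))
  expect_equal(length(read_bed(f2)), 0)

  ## reads written with header round-trip through read_reads_bed
  rs <- read_set(gr, "s1", "H3K4me3", "TGFb_plus", total_sequenced = 20)
  f3 <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(rs, f3)
  back_rs <- read_reads_bed(f3)
  expect_equal(back_rs$antibody, "H3K4me3")
  expect_equal(back_rs$total_sequenced, 20)
  expect_equal(sort(start(back_rs$reads)), sort(start(gr)))
})

test_that("bedGraph emits 0-based half-open runs and skips zero bins", {
  tr <- make_track(list(chr1 = c(5, 5, 0, 2)), bin_size = 100)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  expect_equal(readLines(f), c("chr1\t0\t200\t5", "chr1\t300\t400\t2"))
})

test_that("sample sheet metadata wins over BED headers", {
  d <- withr::local_tempdir()
  writeLines(c("#antibody=input", "#condition=TGFb_minus",
               "chr1\t0\t50\tr\t0\t+"),
             file.path(d, "a.bed"))
  yaml::write_yaml(list(samples = list(list(
    sample_id = "sheeted", path = "a.bed", antibody = "H3K27me3",
    condition = "TGFb_plus", total_sequenced = 9))),
    file.path(d, "samples.yaml"))
  rs <- load_readsets(file.path(d, "samples.yaml"))
  expect_named(rs, "sheeted")
  expect_equal(rs$sheeted$antibody, "H3K27me3")
  expect_equal(rs$sheeted$condition, "TGFb_plus")
  expect_equal(rs$sheeted$total_sequenced, 9)
})
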