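suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## three hand-built genes: + strand with intron, - strand with intron,
## single-exon + strand
tiny_annotation <- function() {
  genes <- GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges(c(100001, 40001, 5001), c(105000, 50000, 6000)),
    strand = c("+", "-", "+"),
    gene_id = c("gPlus", "gMinus", "gSingle"))
  exons <- GRangesList(
    GRanges("chr1", IRanges(c(100001, 103001), c(100500, 105000)), strand = "+"),
    GRanges("chr1", IRanges(c(40001, 47001), c(42000, 50000)), strand = "-"),
    GRanges("chr2", IRanges(5001, 6000), strand = "+"))
  annotation(genes, exons, c(chr1 = 200000, chr2 = 20000))
}

## a peak GRanges in the call_peaks output shape
make_peaks <- function(chrom, summit, max_ratio = 10, width = 200) {
  gr <- GRanges(chrom, IRanges(summit - width %/% 2, summit + width %/% 2),
                name = sprintf("peak_%05d", seq_along(summit)),
                summit = as.integer(summit), max_ratio = max_ratio)
  gr
}

## a SignalTrack built directly from per-chromosome bin-count vectors
make_track <- function(counts, bin_size = 100, chrom_sizes = NULL) {
  if (is.null(chrom_sizes))
    chrom_sizes <- setNames(lengths(counts) * bin_size, names(counts))
  structure(list(bin_size = as.integer(bin_size), counts = counts,
                 library_size = sum(unlist(counts)),
                 chrom_sizes = unlist(chrom_sizes)),
            class = "SignalTrack")
}

## a RatioTrack built directly from per-chromosome ratio vectors
make_ratio <- function(ratio, bin_size = 100, chrom_sizes = NULL) {
  if (is.null(chrom_sizes))
    chrom_sizes <- setNames(lengths(ratio) * bin_size, names(ratio))
  structure(list(bin_size = as.integer(bin_size), ratio = ratio,
                 chrom_sizes = unlist(chrom_sizes)),
            class = "RatioTrack")
}

## a small expression matrix from a plain matrix
make_expr <- function(values, timepoints, genes = NULL, normalized = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sub("^p", "g", rownames(values))
  expression_matrix(values, timepoints,
                    setNames(genes, rownames(values)), normalized = normalized)
}

## brute-force GSEA running sum and signed-extremum ES, O(N^2)-style
brute_gsea_es <- function(ids, scores, gene_set, p) {
  n <- length(ids)
  hit <- ids %in% gene_set
  w <- abs(scores)^p
  if (sum(w[hit]) == 0) { w <- rep(1, n) }
  run <- numeric(n)
  for (i in seq_len(n)) {  # recompute each prefix from scratch
    steps <- ifelse(hit[seq_len(i)],
                    w[seq_len(i)] / sum(w[hit]),
                    -1 / (n - sum(hit)))
    run[i] <- sum(steps)
  }
  mx <- max(run); mn <- min(run)
  if (mx > -mn) mx else mn
}

## one shared default-conditions simulation + pipeline run for the
## acceptance tests (computed lazily, reused across test files)
.shared <- new.env(parent = emptyenv())
default_run <- function() {
  if (!is.null(.shared$run)) return(.shared$run)
  dir <- file.path(tempdir(), "bivalentSmad-default-run")
  sim <- simulate_dataset(sim_config(seed = 7), dir)
  cfg <- pipeline_config(
    annotation = sim$paths$annotation,
    sample_sheet = sim$paths$samples,
    expression_tgfb = sim$paths$expression_tgfb,
    expression_rankl = sim$paths$expression_rankl,
    out_dir = file.path(dir, "out"),
    gsea_nperm = 199, seed = 7)
  report <- run_full(cfg, quiet = TRUE)
  .shared$run <- list(sim = sim, config = cfg, report = report)
  .shared$run
}
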