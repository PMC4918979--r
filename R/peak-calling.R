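## Binned coverage, signal-ratio tracks, ratio-threshold peak calling and
## TSS metaprofiles. Bins are [k*bin_size, (k+1)*bin_size) in 0-based
## genomic coordinates, i.e. bin k covers 1-based bases
## k*bin_size+1 .. (k+1)*bin_size; the trailing partial bin is kept.

#' Bin reads into a fixed-width coverage track
#'
#' Each read is assigned to the bin containing its midpoint.
#'
#' @param readset a [read_set()].
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 100).
#' @return A `SignalTrack`: list with `bin_size`, `counts` (named list of
#'   per-chromosome bin-count vectors), `library_size` (total reads
#'   assigned) and `chrom_sizes`.
#' @export
bin_reads <- function(readset, chrom_sizes, bin_size = 100) {
  stopifnot(bin_size >= 1)
  r <- readset$reads
  chroms <- as.character(seqnames(r))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown))
    stop("reads on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  n_bins <- as.integer(ceiling(unlist(chrom_sizes) / bin_size))
  names(n_bins) <- names(chrom_sizes)
  ## midpoint in 0-based coordinates: floor((start0 + end0)/2)
  mid0 <- (start(r) - 1L + end(r)) %/% 2L
  bin <- pmin(mid0 %/% as.integer(bin_size), n_bins[chroms] - 1L)
  counts <- lapply(names(chrom_sizes), function(chr) {
    tabulate(bin[chroms == chr] + 1L, nbins = n_bins[[chr]])
  })
  structure(list(bin_size = as.integer(bin_size),
                 counts = setNames(counts, names(chrom_sizes)),
                 library_size = length(r),
                 chrom_sizes = unlist(chrom_sizes)),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d reads in %d-bp bins over %d chromosome(s)\n",
              x$library_size, x$bin_size, length(x$counts)))
  invisible(x)
}

#' Per-bin signal ratio of ChIP over control
#'
#' The "peak signal ratio" underlying all peak calls. With a control track,
#' `ratio_b = ((chip_b + p) / chip_library) / ((ctrl_b + p) / ctrl_library)`
#' with pseudocount `p` guarding empty bins. With no control library the
#' denominator is a flat genome-wide background density estimated from the
#' ChIP track itself: by default the *median* bin count, which is robust to
#' inflation by the enriched regions being called (the mean is available via
#' `background = "mean"`).
#'
#' @param chip `SignalTrack` for the ChIP sample.
#' @param control optional `SignalTrack` for the input/control sample;
#'   must share `bin_size` and chromosomes.
#' @param pseudocount added read count per bin (default 1).
#' @param background background estimator used when `control` is `NULL`:
#'   `"median"` (default) or `"mean"`.
#' @return A `RatioTrack`: list with `bin_size`, `ratio` (named list of
#'   per-chromosome ratio vectors) and `chrom_sizes`.
#' @export
ratio_track <- function(chip, control = NULL, pseudocount = 1,
                        background = c("median", "mean")) {
  background <- match.arg(background)
  stopifnot(pseudocount > 0)
  if (!is.null(control)) {
    if (control$bin_size != chip$bin_size ||
        !setequal(names(control$counts), names(chip$counts)))
      stop("chip and control tracks must share bin_size and chromosomes")
    ratio <- lapply(names(chip$counts), function(chr) {
      num <- (chip$counts[[chr]] + pseudocount) / max(chip$library_size, 1)
      den <- (control$counts[[chr]] + pseudocount) / max(control$library_size, 1)
      num / den
    })
  } else {
    all_counts <- unlist(chip$counts, use.names = FALSE)
    bg <- switch(background, median = median(all_counts), mean = mean(all_counts))
    bg <- max(bg, pseudocount)  # degenerate near-empty tracks
    ratio <- lapply(names(chip$counts), function(chr) {
      (chip$counts[[chr]] + pseudocount) / bg
    })
  }
  structure(list(bin_size = chip$bin_size,
                 ratio = setNames(ratio, names(chip$counts)),
                 chrom_sizes = chip$chrom_sizes),
            class = "RatioTrack")
}

#' Call peaks on a signal-ratio track
#'
#' Maximal runs of bins with ratio >= `threshold`; runs separated by
#' <= `merge_gap` bp are merged; merged regions narrower than `min_width`
#' bp are dropped. The summit is the centre base of the maximum-ratio bin
#' (leftmost on ties).
#'
#' @param ratio a `RatioTrack` from [ratio_track()].
#' @param threshold calling threshold on the signal ratio (> 1); the
#'   Smad2/3 and H3K4me3 analyses use 8, H3K27me3 uses 5.
#' @param merge_gap maximum gap (bp) between runs that are merged
#'   (default 300).
#' @param min_width minimum peak width in bp (default 300).
#' @return `GRanges` of peaks, sorted and non-overlapping, with metadata
#'   columns `name`, `summit` (1-based base) and `max_ratio`.
#' @export
call_peaks <- function(ratio, threshold, merge_gap = 300, min_width = 300) {
  stopifnot(threshold > 1)
  bs <- ratio$bin_size
  gap_bins <- as.integer(merge_gap %/% bs)
  res <- lapply(names(ratio$ratio), function(chr) {
    v <- ratio$ratio[[chr]]
    above <- v >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    if (gap_bins > 0 && length(r$lengths) > 2) {
      fill <- r$values == FALSE & r$lengths <= gap_bins
      fill[c(1, length(fill))] <- FALSE  # never extend past outer runs
      r$values[fill] <- TRUE
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
    chr_len <- ratio$chrom_sizes[[chr]]
    reg_start1 <- (starts - 1L) * bs + 1L
    reg_end1 <- pmin(ends * bs, chr_len)
    wide <- (reg_end1 - reg_start1 + 1L) >= min_width
    if (!any(wide)) return(NULL)
    starts <- starts[wide]; ends <- ends[wide]
    reg_start1 <- reg_start1[wide]; reg_end1 <- reg_end1[wide]
    summit <- integer(length(starts)); mx <- numeric(length(starts))
    for (i in seq_along(starts)) {
      bins <- starts[i]:ends[i]
      b <- bins[which.max(v[bins])]  # leftmost tie
      mx[i] <- v[b]
      summit[i] <- min((b - 1L) * bs + bs %/% 2L + 1L, chr_len)
    }
    GRanges(factor(rep(chr, length(reg_start1)), levels = names(ratio$ratio)),
            IRanges(reg_start1, reg_end1), strand = "*",
            summit = summit, max_ratio = mx)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- GRanges()
    mcols(out) <- S4Vectors::DataFrame(name = character(0),
                                       summit = integer(0),
                                       max_ratio = numeric(0))
    return(out)
  }
  out <- sort(do.call(c, res))
  mcols(out)$name <- sprintf("peak_%05d", seq_along(out))
  out[, c("name", "summit", "max_ratio")]
}

#' Average signal profile around TSSs
#'
#' For each gene the per-bp read density in `[tss - flank, tss + flank)` is
#' extracted from the binned track, oriented so that negative offsets are
#' upstream (reversed on `-` strand genes), scaled to reads per million,
#' and averaged across genes in offset bins of the track's `bin_size`.
#' Genes whose window leaves the chromosome are skipped.
#'
#' @param track a `SignalTrack` from [bin_reads()].
#' @param genes `GRanges` of genes with `tss` metadata (e.g.
#'   `annotation$genes`), or an [annotation()] object.
#' @param flank half-window in bp; must be a multiple of the bin size.
#' @return A `Metaprofile` data.frame with columns `offset` (bin-centre
#'   position relative to the TSS, bp) and `mean_signal` (mean per-bp
#'   density per million mapped reads), with attribute `n_genes`.
#' @export
tss_metaprofile <- function(track, genes, flank = 2000) {
  if (inherits(genes, "Annotation")) genes <- genes$genes
  if (!length(genes)) stop("empty gene list")
  bs <- track$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of bin_size")
  scale <- 1e6 / (bs * max(track$library_size, 1))
  offs0 <- seq(-flank, flank - 1)  # per-base offsets, 0 = TSS base
  acc <- numeric(2 * flank); n_used <- 0L
  for (i in seq_along(genes)) {
    chr <- as.character(seqnames(genes)[i])
    cnt <- track$counts[[chr]]
    if (is.null(cnt)) next
    tss0 <- mcols(genes)$tss[i] - 1L
    pos0 <- if (as.character(strand(genes)[i]) == "-") tss0 - offs0 else tss0 + offs0
    if (min(pos0) < 0 || max(pos0) >= track$chrom_sizes[[chr]]) next
    acc <- acc + cnt[pos0 %/% bs + 1L] * scale
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no gene has a complete TSS window on the track")
  per_base <- acc / n_used
  k <- rep(seq_len(2 * flank / bs), each = bs)
  prof <- data.frame(
    offset = tapply(offs0, k, function(o) mean(o) + 0.5),
    mean_signal = as.numeric(tapply(per_base, k, mean)))
  rownames(prof) <- NULL
  attr(prof, "n_genes") <- n_used
  class(prof) <- c("Metaprofile", "data.frame")
  prof
}

#' Write a metaprofile as TSV
#' @param profile a [tss_metaprofile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metaprofile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
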