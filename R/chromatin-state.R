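## Peak-to-gene assignment (Smad2/3 target windows, promoter mark status)
## and chromatin-state transition classification. Membership is always
## tested on the peak SUMMIT; window bounds are inclusive at both ends.

#' Smad2/3 target genes from called binding regions
#'
#' A gene is a target iff some peak summit lies in the strand-oriented
#' window from `upstream` bp upstream of the TSS to the end of the first
#' intron (transcription order). Intronless genes use the gene end; the
#' window is clipped to the chromosome bounds.
#'
#' @param peaks peak `GRanges` from [call_peaks()].
#' @param anno an [annotation()] object.
#' @param upstream upstream extent in bp (default 10000).
#' @param window_end `"intron_end"` (default) or `"intron_start"`: whether
#'   the downstream bound is the end or the start of the first intron in
#'   transcription order.
#' @return sorted character vector of target gene ids.
#' @export
smad_target_genes <- function(peaks, anno, upstream = 10000,
                              window_end = c("intron_end", "intron_start")) {
  window_end <- match.arg(window_end)
  win <- target_windows(anno, upstream, window_end)
  g <- anno$genes
  if (!length(peaks)) return(character(0))
  summits <- GRanges(seqnames(peaks), IRanges(mcols(peaks)$summit, width = 1))
  hit <- overlapsAny(win, summits)
  sort(g$gene_id[hit])
}

## strand-oriented target windows as GRanges (1-based closed, clipped)
target_windows <- function(anno, upstream, window_end = "intron_end") {
  g <- anno$genes
  plus <- as.character(strand(g)) == "+"
  i1s <- mcols(g)$intron1_start
  i1e <- mcols(g)$intron1_end
  ## transcription-order end of the first intron, genomic coordinates:
  ## + strand: high bound is intron end (or start); - strand: low bound is
  ## intron start (transcription end) or intron end (transcription start)
  hi_intr <- if (window_end == "intron_end") i1e else i1s
  lo_intr <- if (window_end == "intron_end") i1s else i1e
  lo <- ifelse(plus, mcols(g)$tss - upstream,
               ifelse(is.na(lo_intr), start(g), lo_intr))
  hi <- ifelse(plus, ifelse(is.na(hi_intr), end(g), hi_intr),
               mcols(g)$tss + upstream)
  lo <- pmax(lo, 1)
  hi <- pmin(hi, anno$chrom_sizes[as.character(seqnames(g))])
  GRanges(seqnames(g), IRanges(lo, hi), strand = strand(g))
}

#' Promoter mark status per gene
#'
#' A gene carries the mark iff some peak summit lies within
#' `[tss - flank, tss + flank]` (both bounds inclusive). Used to call
#' K4(+) / K27(+) genes from H3K4me3 / H3K27me3 peak sets.
#'
#' @param peaks peak `GRanges` from [call_peaks()] for a single
#'   (antibody, condition) track.
#' @param anno an [annotation()] object.
#' @param flank promoter half-window in bp (default 1000).
#' @return named logical vector over all genes in `anno`.
#' @export
mark_status <- function(peaks, anno, flank = 1000) {
  g <- anno$genes
  status <- setNames(rep(FALSE, length(g)), g$gene_id)
  if (!length(peaks)) return(status)
  lo <- pmax(mcols(g)$tss - flank, 1)
  hi <- pmin(mcols(g)$tss + flank,
             anno$chrom_sizes[as.character(seqnames(g))])
  win <- GRanges(seqnames(g), IRanges(lo, hi))
  summits <- GRanges(seqnames(peaks), IRanges(mcols(peaks)$summit, width = 1))
  status[overlapsAny(win, summits)] <- TRUE
  status
}

## the four promoter states and the canonical transition of interest
STATES <- c("K4+K27+", "K4+K27-", "K4-K27+", "K4-K27-")

#' Canonical label of the bivalent-to-K4-only transition
#' @return the string `"K4+K27+ -> K4+K27-"`.
#' @export
bivalent_to_k4only <- function() "K4+K27+ -> K4+K27-"

state_label <- function(k4, k27) {
  paste0("K4", ifelse(k4, "+", "-"), "K27", ifelse(k27, "+", "-"))
}

#' Classify chromatin-state transitions per gene
#'
#' Combines K4/K27 status before (TGF-beta minus) and after (TGF-beta plus)
#' stimulation into one of the 16 (state_before, state_after) labels, e.g.
#' `"K4+K27+ -> K4+K27-"` for a resolving bivalent promoter.
#'
#' @param k4_before,k27_before,k4_after,k27_after named logical vectors
#'   over the same gene universe (from [mark_status()]).
#' @return A `GeneStateTable`: data.frame with columns `gene_id`,
#'   `k4_minus`, `k27_minus`, `k4_plus`, `k27_plus`, `state_before`,
#'   `state_after`, `transition`; attribute `counts` holds the 4x4
#'   before-by-after contingency table of label counts.
#' @export
classify_transitions <- function(k4_before, k27_before, k4_after, k27_after) {
  univ <- names(k4_before)
  for (m in list(k27_before, k4_after, k27_after)) {
    miss <- c(setdiff(univ, names(m)), setdiff(names(m), univ))
    if (length(miss))
      stop("gene universe mismatch across mark maps: ",
           paste(head(sort(unique(miss)), 5), collapse = ", "))
  }
  k27_before <- k27_before[univ]; k4_after <- k4_after[univ]
  k27_after <- k27_after[univ]
  before <- state_label(k4_before, k27_before)
  after <- state_label(k4_after, k27_after)
  df <- data.frame(gene_id = univ,
                   k4_minus = unname(k4_before), k27_minus = unname(k27_before),
                   k4_plus = unname(k4_after), k27_plus = unname(k27_after),
                   state_before = before, state_after = after,
                   transition = paste(before, "->", after),
                   stringsAsFactors = FALSE)
  attr(df, "counts") <- table(factor(before, STATES), factor(after, STATES),
                              dnn = c("before", "after"))
  class(df) <- c("GeneStateTable", "data.frame")
  df
}

#' Write gene-state and target tables as TSV
#' @param states a [classify_transitions()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_states <- function(states, path) {
  data.table::fwrite(as.data.frame(states), path, sep = "\t")
  invisible(path)
}
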