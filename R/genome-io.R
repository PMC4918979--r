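## Gene models, read sets and the readers/writers for GFF3/BED/bedGraph.
## Internal convention: GRanges / IRanges, i.e. 1-based closed coordinates.
## BED and bedGraph (0-based half-open) are converted at the boundary.

#' Construct a gene annotation
#'
#' An `Annotation` bundles one pre-collapsed gene model per gene (a single
#' interval with ordered exons), the derived TSS and first intron, and the
#' chromosome sizes. Multi-isoform resolution is out of scope: callers must
#' supply one model per gene.
#'
#' @param genes `GRanges` of gene spans, strand `+`/`-`, with a `gene_id`
#'   metadata column (unique, non-empty).
#' @param exons `GRangesList` parallel to `genes`: the exons of each gene,
#'   non-overlapping, within the gene span, on the same chrom/strand.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @return An object of class `Annotation` with elements `genes` (the input
#'   `GRanges` augmented with `tss`, `intron1_start`, `intron1_end` metadata
#'   columns; the intron columns are `NA` for single-exon genes), `exons`,
#'   and `chrom_sizes`.
#' @details The TSS is `start(gene)` on `+` and `end(gene)` on `-`. The
#'   first intron is the gap between exon 1 and exon 2 *in transcription
#'   order*, i.e. between the two highest-coordinate exons on `-` strand.
#' @export
annotation <- function(genes, exons, chrom_sizes) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"),
            length(genes) == length(exons))
  gid <- mcols(genes)$gene_id
  if (is.null(gid) || anyDuplicated(gid) || any(!nzchar(gid)))
    stop("genes must carry unique non-empty gene_id metadata")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("gene strand must be '+' or '-' (TSS windows need orientation)")
  chrom_sizes <- unlist(chrom_sizes)
  missing_chr <- setdiff(unique(as.character(seqnames(genes))), names(chrom_sizes))
  if (length(missing_chr))
    stop("chrom_sizes missing for: ", paste(missing_chr, collapse = ", "))
  too_big <- end(genes) > chrom_sizes[as.character(seqnames(genes))]
  if (any(too_big))
    stop("gene(s) extend past chromosome end: ",
         paste(gid[too_big], collapse = ", "))
  n_ex <- lengths(exons)
  if (any(n_ex == 0))
    stop("gene(s) with zero exons: ", paste(gid[n_ex == 0], collapse = ", "))
  intr <- t(vapply(seq_along(genes), function(i) {
    first_intron_bounds(exons[[i]], as.character(strand(genes))[i])
  }, integer(2)))
  mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "+",
                             start(genes), end(genes))
  mcols(genes)$intron1_start <- intr[, 1]
  mcols(genes)$intron1_end <- intr[, 2]
  names(genes) <- gid
  names(exons) <- gid
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "Annotation")
}

## genomic bounds [start, end] (1-based closed) of the first intron in
## transcription order, or c(NA, NA) for single-exon genes
first_intron_bounds <- function(ex, strand) {
  if (length(ex) < 2) return(c(NA_integer_, NA_integer_))
  o <- order(start(ex))
  ex <- ex[o]
  if (any(start(ex)[-1] <= end(ex)[-length(ex)]))
    stop("exons overlap or abut ambiguously")
  if (strand == "+") {
    c(end(ex)[1] + 1L, start(ex)[2] - 1L)
  } else {
    k <- length(ex)
    c(end(ex)[k - 1] + 1L, start(ex)[k] - 1L)
  }
}

#' @export
print.Annotation <- function(x, ...) {
  cat("Annotation:", length(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Read a gene annotation from GFF3 or BED12
#'
#' GFF3 files must contain `gene` features with unique `ID` attributes and
#' `exon` features whose `Parent` is the gene `ID` (one model per gene).
#' BED12 blocks are taken as exons. Chromosome sizes are taken from the
#' `chrom_sizes` argument, else from `##sequence-region` pragmas (GFF3),
#' else from the largest coordinate seen per chromosome.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed12"`.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return An [annotation()] object.
#' @export
read_annotation <- function(path, format = c("gff3", "bed12"), chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    check_gff3_lines(path)
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[tolower(gr$type) == "gene"]
    if (!length(genes)) stop("no gene features in ", path)
    ex <- gr[tolower(gr$type) == "exon"]
    parent <- as.character(ex$Parent)
    ex_by_gene <- split(ex, factor(parent, levels = genes$ID))
    n_ex <- lengths(ex_by_gene)
    if (any(n_ex == 0))
      stop("gene(s) with zero exons: ",
           paste(genes$ID[n_ex == 0], collapse = ", "))
    gg <- granges(genes)
    mcols(gg)$gene_id <- as.character(genes$ID)
    exl <- GRangesList(lapply(ex_by_gene, granges))
    if (is.null(chrom_sizes)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (!all(is.na(sl))) {
        chrom_sizes <- sl
      } else {
        ## fall back to the ##sequence-region pragmas
        pragmas <- grep("^##sequence-region", readLines(path, warn = FALSE),
                        value = TRUE)
        if (length(pragmas)) {
          f <- strsplit(trimws(pragmas), "\\s+")
          chrom_sizes <- setNames(vapply(f, function(x) as.numeric(x[4]),
                                         numeric(1)),
                                  vapply(f, `[`, character(1), 2))
        }
      }
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks)) stop("BED12 blocks required in ", path)
    gg <- granges(gr)
    mcols(gg)$gene_id <- as.character(gr$name)
    exl <- GRangesList(lapply(seq_along(gr), function(i) {
      GRanges(seqnames(gr)[i],
              IRanges::shift(gr$blocks[[i]], start(gr)[i] - 1L),
              strand = strand(gr)[i])
    }))
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(end(gg), as.character(seqnames(gg)), max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  annotation(gg, exl, chrom_sizes)
}

## cheap structural scan so malformed GFF3 reports its line number
check_gff3_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  body <- which(!startsWith(ln, "#") & nzchar(ln))
  nf <- lengths(strsplit(ln[body], "\t", fixed = TRUE))
  bad <- body[nf != 9]
  if (length(bad))
    stop("malformed GFF3 line(s) ", paste(head(bad, 5), collapse = ", "),
         " in ", path, " (expected 9 tab-separated fields)")
  invisible(TRUE)
}

#' Write a gene annotation as GFF3
#'
#' Emits `##sequence-region` pragmas, one `gene` feature per gene and its
#' `exon` children, so [read_annotation()] round-trips.
#'
#' @param anno an [annotation()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(anno, path) {
  g <- anno$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(anno$chrom_sizes), as.integer(anno$chrom_sizes)))
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              as.character(seqnames(g)[i]), start(g)[i],
                              end(g)[i], as.character(strand(g)[i]), gid))
    ex <- anno$exons[[i]]
    lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                              as.character(seqnames(ex)), start(ex), end(ex),
                              as.character(strand(ex)), gid, seq_along(ex), gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a ChIP-seq read set
#'
#' @param reads `GRanges` of aligned read intervals (strand may be `.`).
#' @param sample_id sample label.
#' @param antibody one of `"Smad2/3"`, `"H3K4me3"`, `"H3K27me3"`, `"input"`.
#' @param condition `"TGFb_plus"` or `"TGFb_minus"`.
#' @param total_sequenced total sequenced reads; defaults to the number of
#'   mapped reads supplied.
#' @return An object of class `ReadSet` with fields `sample_id`, `antibody`,
#'   `condition`, `reads`, `mapped` (= `length(reads)`) and `total_sequenced`.
#' @export
read_set <- function(reads, sample_id, antibody, condition,
                     total_sequenced = length(reads)) {
  antibody <- match.arg(antibody, c("Smad2/3", "H3K4me3", "H3K27me3", "input"))
  condition <- match.arg(condition, c("TGFb_plus", "TGFb_minus"))
  total_sequenced <- as.numeric(total_sequenced)
  if (total_sequenced < length(reads))
    stop("total_sequenced (", total_sequenced, ") < mapped reads (",
         length(reads), ")")
  structure(list(sample_id = sample_id, antibody = antibody,
                 condition = condition, reads = reads,
                 mapped = length(reads), total_sequenced = total_sequenced),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet %s [%s, %s]: %d mapped / %s sequenced\n",
              x$sample_id, x$antibody, x$condition, x$mapped,
              format(x$total_sequenced, big.mark = ",")))
  invisible(x)
}

#' Read aligned reads from a BED6 file
#'
#' Leading comment lines of the form `#key=value` may carry `sample_id`,
#' `antibody`, `condition` and `total_sequenced`; explicit arguments win
#' over the header.
#'
#' @param path BED6 file (0-based half-open; converted internally).
#' @param sample_id,antibody,condition,total_sequenced optional overrides.
#' @return A [read_set()].
#' @export
read_reads_bed <- function(path, sample_id = NULL, antibody = NULL,
                           condition = NULL, total_sequenced = NULL) {
  ln <- readLines(path, warn = FALSE)
  hdr_idx <- seq_len(match(FALSE, startsWith(ln, "#"), nomatch = length(ln) + 1L) - 1L)
  meta <- list()
  for (h in ln[hdr_idx]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- ln[setdiff(seq_along(ln), hdr_idx)]
  body <- body[nzchar(body)]
  if (length(body)) {
    dt <- data.table::fread(text = body, header = FALSE, sep = "\t")
    if (ncol(dt) < 3) stop("BED6 needs at least 3 columns in ", path)
    bad <- which(dt[[2]] >= dt[[3]] | dt[[2]] < 0)
    if (length(bad))
      stop("invalid interval(s) (start >= end) at record ",
           paste(head(bad, 5), collapse = ", "), " in ", path)
    reads <- GRanges(dt[[1]], IRanges(dt[[2]] + 1L, dt[[3]]),
                     strand = if (ncol(dt) >= 6) sub(".", "*", dt[[6]],
                                                     fixed = TRUE) else "*")
  } else {
    reads <- GRanges()
  }
  read_set(reads,
           sample_id = sample_id %||% meta$sample_id %||% basename(path),
           antibody = antibody %||% meta$antibody %||% "input",
           condition = condition %||% meta$condition %||% "TGFb_minus",
           total_sequenced = as.numeric(total_sequenced %||%
                                          meta$total_sequenced %||%
                                          length(reads)))
}

#' Write a read set as BED6 with a metadata header
#'
#' @param readset a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(readset, path) {
  hdr <- sprintf("#%s=%s",
                 c("sample_id", "antibody", "condition", "total_sequenced"),
                 c(readset$sample_id, readset$antibody, readset$condition,
                   format(readset$total_sequenced, scientific = FALSE)))
  writeLines(hdr, path)
  r <- readset$reads
  if (length(r)) {
    dt <- data.table::data.table(
      chrom = as.character(seqnames(r)), start = start(r) - 1L, end = end(r),
      name = sprintf("r%06d", seq_along(r)), score = 0L,
      strand = sub("\\*", ".", as.character(strand(r))))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Mapped-read percentage of a read set
#'
#' @param readset a [read_set()].
#' @return `100 * mapped / total_sequenced`, rounded to 1 decimal, e.g.
#'   `71.7` for 10,837,516 mapped of 15,108,905 sequenced.
#' @export
mapping_summary <- function(readset) {
  if (!is.numeric(readset$total_sequenced) || readset$total_sequenced <= 0)
    stop("total_sequenced must be positive to compute a mapped fraction")
  round(100 * readset$mapped / readset$total_sequenced, 1)
}

#' Write intervals or peaks as BED
#'
#' Plain `GRanges` become BED6; peak `GRanges` (with `summit` and
#' `max_ratio` metadata, see [call_peaks()]) become BED6+1 with
#' `score = round(10 * max_ratio)` and the 0-based summit in column 7.
#'
#' @param x `GRanges` (optionally peak-annotated) or a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "ReadSet")) return(write_reads_bed(x, path))
  stopifnot(is(x, "GRanges"))
  if (!length(x)) {
    file.create(path)
    return(invisible(path))
  }
  nm <- if (!is.null(mcols(x)$name)) as.character(mcols(x)$name)
        else if (!is.null(names(x))) names(x)
        else sprintf("iv%06d", seq_along(x))
  dt <- data.table::data.table(
    chrom = as.character(seqnames(x)), start = start(x) - 1L, end = end(x),
    name = nm,
    score = if (!is.null(mcols(x)$max_ratio)) round(10 * mcols(x)$max_ratio) else 0L,
    strand = sub("\\*", ".", as.character(strand(x))))
  if (!is.null(mcols(x)$summit)) dt$summit <- mcols(x)$summit - 1L
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read BED intervals (BED3/BED6) into a GRanges
#'
#' @param path BED file.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  gr <- GRanges(dt[[1]], IRanges(dt[[2]] + 1L, dt[[3]]),
                strand = if (ncol(dt) >= 6) sub("\\.", "*", dt[[6]]) else "*")
  if (ncol(dt) >= 4) names(gr) <- as.character(dt[[4]])
  gr
}

#' Write a binned signal track as bedGraph
#'
#' Consecutive bins with equal value are collapsed; zero-valued bins are
#' omitted (sparse bedGraph). Coordinates are 0-based half-open as the
#' format requires.
#'
#' @param track a [bin_reads()] track (or a ratio track from [ratio_track()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (!is.null(track$counts)) track$counts else track$ratio
  bs <- track$bin_size
  out <- lapply(names(vals), function(chr) {
    v <- vals[[chr]]
    r <- rle(v)
    ends0 <- cumsum(r$lengths) * bs
    starts0 <- ends0 - r$lengths * bs
    ends0[length(ends0)] <- min(ends0[length(ends0)], track$chrom_sizes[[chr]])
    keep <- r$values != 0
    data.table::data.table(chrom = chr, start = starts0[keep],
                           end = ends0[keep], value = r$values[keep])
  })
  data.table::fwrite(data.table::rbindlist(out), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a YAML sample sheet
#'
#' The sheet is a YAML list of records with fields `sample_id`, `path`,
#' `antibody`, `condition` and optionally `total_sequenced`. Relative paths
#' are resolved against the sheet's directory.
#'
#' @param path YAML file.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  y <- yaml::read_yaml(path)
  recs <- if (!is.null(y$samples)) y$samples else y
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(sample_id = r$sample_id, path = r$path, antibody = r$antibody,
               condition = r$condition,
               total_sequenced = as.numeric(r$total_sequenced %||% NA),
               stringsAsFactors = FALSE)
  }))
  abs <- file.path(dirname(path), df$path)
  df$path <- ifelse(file.exists(df$path), df$path, abs)
  df
}

#' Load all read sets named in a sample sheet
#'
#' Sheet metadata wins over BED header metadata on conflict.
#'
#' @param sheet data.frame from [read_sample_sheet()] or path to the YAML.
#' @return named list of [read_set()] objects, keyed by `sample_id`.
#' @export
load_readsets <- function(sheet) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    ts <- sheet$total_sequenced[i]
    read_reads_bed(sheet$path[i], sample_id = sheet$sample_id[i],
                   antibody = sheet$antibody[i], condition = sheet$condition[i],
                   total_sequenced = if (is.na(ts)) NULL else ts)
  })
  setNames(out, sheet$sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
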