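## Seeded synthetic data with planted truth: a toy genome, Smad2/3 and
## histone-mark read sets over Poisson background, and TGF-beta / RANKL
## expression time courses. Every output is a pure function of
## (config, seed); each (module, sample) gets its own RNG stream derived
## from the master seed by a stable hash, so adding samples never perturbs
## existing ones.

## RANKL time course (h) and the TGF-beta design (0 and 24 h)
RANKL_TIMEPOINTS <- c(0, 3, 12, 24, 48, 72)
TGFB_TIMEPOINTS <- c(0, 24)

#' Truth classes of the synthetic genome
#'
#' Each simulated gene belongs to one class fixing its Smad2/3 binding,
#' its K4/K27 promoter state before/after TGF-beta, its TGF-beta
#' expression fold and its RANKL time-course profile. The `nedd9_like`
#' class is the canonical planted positive: Smad2/3 target, bivalent
#' promoter resolving to K4-only, TGF-beta-induced (4-fold) and
#' RANKL-repressed (0.25 at 72 h).
#'
#' @return data.frame of class definitions (one row per class).
#' @export
truth_classes <- function() {
  rankl_flat <- c(1, 1, 1, 1, 1, 1)
  rankl_down <- c(1, 0.9, 0.6, 0.45, 0.35, 0.25)
  cls <- list(
    nedd9_like           = list(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, 4,   rankl_down),
    smad_k4only          = list(TRUE,  TRUE,  FALSE, TRUE,  FALSE, 3,   rankl_flat),
    smad_bivalent_stable = list(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  1,   rankl_flat),
    nontarget_resolving  = list(FALSE, TRUE,  TRUE,  TRUE,  FALSE, 1,   rankl_flat),
    nontarget_k4         = list(FALSE, TRUE,  FALSE, TRUE,  FALSE, 1,   rankl_flat),
    nontarget_silent     = list(FALSE, FALSE, FALSE, FALSE, FALSE, 1,   rankl_flat),
    nontarget_k27        = list(FALSE, FALSE, TRUE,  FALSE, TRUE,  1,   rankl_flat),
    nontarget_rankl_down = list(FALSE, TRUE,  FALSE, TRUE,  FALSE, 1,   c(1, 0.95, 0.8, 0.6, 0.45, 0.4)))
  df <- data.frame(
    class = names(cls),
    is_smad_target = vapply(cls, `[[`, logical(1), 1),
    k4_before = vapply(cls, `[[`, logical(1), 2),
    k27_before = vapply(cls, `[[`, logical(1), 3),
    k4_after = vapply(cls, `[[`, logical(1), 4),
    k27_after = vapply(cls, `[[`, logical(1), 5),
    tgfb_effect = vapply(cls, `[[`, numeric(1), 6),
    stringsAsFactors = FALSE, row.names = NULL)
  rp <- t(vapply(cls, `[[`, numeric(6), 7))
  colnames(rp) <- paste0("rankl_", RANKL_TIMEPOINTS)
  cbind(df, rp)
}

#' Simulation configuration
#'
#' Defaults define the standard study conditions: a 2 x 2 Mb toy genome
#' with 100 genes (10 of them `nedd9_like`, the rest spanning the other
#' truth classes), Poisson background of 0.02 reads/bp, 15-fold planted
#' enrichment, 0.717 mapped fraction, and lognormal expression noise of
#' sigma 0.15.
#'
#' @param seed master integer seed.
#' @param n_chroms,chrom_len genome shape.
#' @param n_genes number of genes (2-5 exons each, both strands).
#' @param min_gene_gap minimum intergenic distance (bp). The default 12 kb
#'   keeps every 10-kb promoter window inside its own intergenic space so
#'   planted peaks are attributable to exactly one gene.
#' @param background background read density (reads/bp).
#' @param enrichment_fold planted peak enrichment over background.
#' @param peak_width,mark_width widths (bp) of planted Smad2/3 and
#'   histone-mark regions (centred on the TSS).
#' @param read_length fixed read length (bp).
#' @param mapped_fraction mapped/sequenced fraction used to back-compute
#'   `total_sequenced`.
#' @param n_probes_per_gene array probes per gene.
#' @param noise_sigma lognormal expression noise (sd of log intensity).
#' @param frac_low_probes fraction of secondary probes with baseline below
#'   the 70 expression floor.
#' @param class_fractions named fractions over [truth_classes()] (must sum
#'   to <= 1; any remainder becomes `nontarget_k4`).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_len = 2e6,
                       n_genes = 100, min_gene_gap = 12000,
                       background = 0.02, enrichment_fold = 15,
                       peak_width = 1000, mark_width = 2000,
                       read_length = 50, mapped_fraction = 0.717,
                       n_probes_per_gene = 2, noise_sigma = 0.15,
                       frac_low_probes = 0.1,
                       class_fractions = c(nedd9_like = 0.10,
                                           smad_k4only = 0.15,
                                           smad_bivalent_stable = 0.10,
                                           nontarget_resolving = 0.10,
                                           nontarget_k4 = 0.15,
                                           nontarget_silent = 0.10,
                                           nontarget_k27 = 0.10,
                                           nontarget_rankl_down = 0.20)) {
  stopifnot(n_chroms >= 1, chrom_len > 0, n_genes >= 0, background > 0,
            enrichment_fold >= 1, read_length >= 1,
            n_probes_per_gene >= 1, noise_sigma >= 0,
            mapped_fraction > 0, mapped_fraction <= 1)
  if (sum(class_fractions) > 1 + 1e-9)
    stop("class_fractions must sum to <= 1")
  bad <- setdiff(names(class_fractions), truth_classes()$class)
  if (length(bad)) stop("unknown truth class(es): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_len = chrom_len, n_genes = n_genes,
                 min_gene_gap = min_gene_gap, background = background,
                 enrichment_fold = enrichment_fold, peak_width = peak_width,
                 mark_width = mark_width, read_length = read_length,
                 mapped_fraction = mapped_fraction,
                 n_probes_per_gene = n_probes_per_gene,
                 noise_sigma = noise_sigma,
                 frac_low_probes = frac_low_probes,
                 class_fractions = class_fractions),
            class = "SimConfig")
}

## stable (order-sensitive) hash of strings onto a 31-bit seed
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(paste(..., sep = "/")))
    h <- (h * 31 + b) %% 2147483647
  as.integer(max(h, 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' Simulate the toy genome and its planted truth
#'
#' Places `n_genes` non-overlapping genes (2-5 exons, both strands) with at
#' least `min_gene_gap` bp between them, assigns each a truth class by the
#' configured fractions, and derives the planted peaks: a `peak_width`
#' Smad2/3 region (TGF-beta plus) centred on the TSS of every target gene,
#' and `mark_width` H3K4me3/H3K27me3 regions centred on the TSS for every
#' "on" mark in each condition.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (an [annotation()]) and `truth` (a
#'   `TruthTable` list: `genes` data.frame of per-gene classes and
#'   expression effects; `peaks` data.frame of planted regions).
#' @export
simulate_annotation <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_len, config$n_chroms), chroms)
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  with_seed(derive_seed(config$seed, "annotation"), {
    gene_rows <- list(); exon_list <- list(); idx <- 0L
    for (ci in seq_len(config$n_chroms)) {
      k <- n_per[ci]
      if (k == 0) next
      n_ex <- sample(2:5, k, replace = TRUE)
      structs <- lapply(n_ex, function(ne) {
        el <- sample(200:500, ne, replace = TRUE)
        il <- if (ne > 1) sample(500:2000, ne - 1, replace = TRUE) else integer(0)
        list(exon_len = el, intron_len = il, span = sum(el) + sum(il))
      })
      spans <- vapply(structs, `[[`, numeric(1), "span")
      slack <- config$chrom_len - sum(spans) -
        (k + 1) * config$min_gene_gap
      if (slack < 0)
        stop("cannot place ", k, " genes on a ", config$chrom_len,
             "-bp chromosome with min_gene_gap ", config$min_gene_gap)
      extra <- { e <- rexp(k + 1); slack * e / sum(e) }
      pos <- config$min_gene_gap + floor(extra[1]) + 1
      for (gi in seq_len(k)) {
        idx <- idx + 1L
        st <- structs[[gi]]
        starts <- pos + cumsum(c(0, head(st$exon_len, -1) + st$intron_len))
        ends <- starts + st$exon_len - 1
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("g%03d", idx)
        gene_rows[[idx]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], start = pos,
          end = pos + st$span - 1, strand = strand)
        exon_list[[idx]] <- GRanges(chroms[ci], IRanges(starts, ends),
                                    strand = strand)
        pos <- pos + st$span + config$min_gene_gap + floor(extra[gi + 1])
      }
    }
    if (idx == 0L) {
      genes <- GRanges()
      mcols(genes)$gene_id <- character(0)
      anno <- annotation(genes, GRangesList(), chrom_sizes)
    } else {
      gdf <- do.call(rbind, gene_rows)
      genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                       strand = gdf$strand, gene_id = gdf$gene_id)
      anno <- annotation(genes, GRangesList(exon_list), chrom_sizes)
    }
    truth <- assign_truth(anno, config)
    list(annotation = anno, truth = truth)
  })
}

## class assignment and planted-peak derivation (called inside the
## annotation RNG stream so (annotation, truth) move together)
assign_truth <- function(anno, config) {
  defs <- truth_classes()
  n <- length(anno$genes)
  counts <- floor(config$class_fractions * n)
  rem <- n - sum(counts)
  if ("nontarget_k4" %in% names(counts)) {
    counts["nontarget_k4"] <- counts["nontarget_k4"] + rem
  } else {
    counts <- c(counts, nontarget_k4 = rem)
  }
  labels <- sample(rep(names(counts), counts))
  tt <- defs[match(labels, defs$class), ]
  tt$gene_id <- anno$genes$gene_id
  rownames(tt) <- NULL
  tt <- tt[, c("gene_id", setdiff(colnames(tt), "gene_id"))]

  g <- anno$genes
  mk_peak <- function(sel, antibody, condition, width) {
    if (!any(sel)) return(NULL)
    tss <- mcols(g)$tss[sel]
    chrom <- as.character(seqnames(g))[sel]
    data.frame(gene_id = g$gene_id[sel], antibody = antibody,
               condition = condition,
               chrom = chrom,
               start = pmax(tss - width %/% 2, 1),
               end = pmin(tss + width %/% 2,
                          anno$chrom_sizes[chrom]),
               fold = config$enrichment_fold, stringsAsFactors = FALSE)
  }
  peaks <- rbind(
    mk_peak(tt$is_smad_target, "Smad2/3", "TGFb_plus", config$peak_width),
    mk_peak(tt$k4_before, "H3K4me3", "TGFb_minus", config$mark_width),
    mk_peak(tt$k4_after, "H3K4me3", "TGFb_plus", config$mark_width),
    mk_peak(tt$k27_before, "H3K27me3", "TGFb_minus", config$mark_width),
    mk_peak(tt$k27_after, "H3K27me3", "TGFb_plus", config$mark_width))
  if (is.null(peaks))
    peaks <- data.frame(gene_id = character(0), antibody = character(0),
                        condition = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        fold = numeric(0))
  rownames(peaks) <- NULL
  structure(list(genes = tt, peaks = peaks), class = "TruthTable")
}

#' Planted peaks of one track as GRanges
#' @param truth a `TruthTable` from [simulate_annotation()].
#' @param antibody,condition track selector.
#' @return `GRanges` of planted regions with `gene_id` and `fold` metadata.
#' @export
planted_peaks <- function(truth, antibody, condition) {
  p <- truth$peaks[truth$peaks$antibody == antibody &
                     truth$peaks$condition == condition, , drop = FALSE]
  if (!nrow(p)) return(GRanges())
  GRanges(p$chrom, IRanges(p$start, p$end), gene_id = p$gene_id,
          fold = p$fold)
}

#' Simulate a ChIP-seq read set
#'
#' Uniform Poisson background at `config$background` reads/bp plus, inside
#' each planted region of the matching (antibody, condition), additional
#' reads at `(fold - 1) x background` density, so in-peak density is
#' `fold x background`. Reads are fixed-length intervals whose midpoints
#' are sampled; `total_sequenced` is back-computed from
#' `config$mapped_fraction`.
#'
#' @param anno an [annotation()].
#' @param truth a `TruthTable`.
#' @param antibody,condition track to simulate.
#' @param config a [sim_config()].
#' @return A [read_set()].
#' @export
simulate_reads <- function(anno, truth, antibody, condition, config) {
  pk <- truth$peaks[truth$peaks$antibody == antibody &
                      truth$peaks$condition == condition, , drop = FALSE]
  if (!nrow(pk) && antibody != "input")
    warning("no planted enrichment for ", antibody, " / ", condition,
            "; background-only read set")
  rl <- config$read_length
  with_seed(derive_seed(config$seed, "reads", antibody, condition), {
    parts <- lapply(names(anno$chrom_sizes), function(chr) {
      len <- anno$chrom_sizes[[chr]]
      n_bg <- rpois(1, config$background * len)
      mids <- floor(runif(n_bg, 0, len))  # 0-based midpoints
      pkc <- pk[pk$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(pkc))) {
        w <- pkc$end[i] - pkc$start[i] + 1
        n_extra <- rpois(1, (pkc$fold[i] - 1) * config$background * w)
        mids <- c(mids, floor(runif(n_extra, pkc$start[i] - 1, pkc$end[i])))
      }
      start1 <- pmin(pmax(mids - rl %/% 2 + 1, 1), len - rl + 1)
      GRanges(factor(rep(chr, length(start1)),
                     levels = names(anno$chrom_sizes)),
              IRanges(start1, width = rl), strand = "*")
    })
    reads <- do.call(c, parts)
    read_set(reads,
             sample_id = paste0(gsub("[^A-Za-z0-9]", "", antibody), "_",
                                condition),
             antibody = antibody, condition = condition,
             total_sequenced = round(length(reads) / config$mapped_fraction))
  })
}

#' Simulate an expression time course
#'
#' Per-probe lognormal baselines (secondary probes fall below the 70
#' expression floor with probability `frac_low_probes`; the
#' `nontarget_silent` class is low on all probes), multiplied by the
#' class's planted effect (`tgfb_effect` at 24 h for TGF-beta; the
#' per-timepoint `rankl_*` profile for RANKL) and by lognormal noise
#' `exp(N(0, noise_sigma))` on every measurement.
#'
#' @param anno an [annotation()].
#' @param truth a `TruthTable`.
#' @param config a [sim_config()].
#' @param stimulus `"TGFb"` (timepoints 0, 24 h) or `"RANKL"`
#'   (0, 3, 12, 24, 48, 72 h).
#' @return An un-normalized [expression_matrix()].
#' @export
simulate_expression <- function(anno, truth, config,
                                stimulus = c("TGFb", "RANKL")) {
  stimulus <- match.arg(stimulus)
  tp <- if (stimulus == "TGFb") TGFB_TIMEPOINTS else RANKL_TIMEPOINTS
  tt <- truth$genes
  npp <- config$n_probes_per_gene
  with_seed(derive_seed(config$seed, "expression", stimulus), {
    probe_gene <- rep(tt$gene_id, each = npp)
    probe_id <- paste0(probe_gene, "_p", rep(seq_len(npp), nrow(tt)))
    silent <- rep(tt$class == "nontarget_silent", each = npp)
    primary <- rep(c(TRUE, rep(FALSE, npp - 1)), nrow(tt))
    base <- exp(rnorm(length(probe_id), log(250), 0.4))
    low <- silent | (!primary & runif(length(probe_id)) < config$frac_low_probes)
    base[low] <- runif(sum(low), 10, 60)
    eff <- if (stimulus == "TGFb") {
      cbind(1, tt$tgfb_effect)[match(probe_gene, tt$gene_id), , drop = FALSE]
    } else {
      as.matrix(tt[match(probe_gene, tt$gene_id),
                   paste0("rankl_", RANKL_TIMEPOINTS)])
    }
    noise <- matrix(exp(rnorm(length(probe_id) * length(tp), 0,
                              config$noise_sigma)),
                    length(probe_id), length(tp))
    vals <- base * eff * noise
    rownames(vals) <- probe_id
    expression_matrix(vals, tp, setNames(probe_gene, probe_id))
  })
}

#' Simulate and write a complete dataset
#'
#' Writes `annotation.gff3`, one BED6 per ChIP sample (Smad2/3 TGF-beta
#' plus; H3K4me3 and H3K27me3 in both conditions; one input), expression
#' TSVs for both stimuli, `truth.json` and `samples.yaml` into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with `annotation`, `truth`, `readsets`,
#'   `expression` and the written `paths`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotation(config)
  anno <- sim$annotation; truth <- sim$truth
  tracks <- list(c("Smad2/3", "TGFb_plus"),
                 c("H3K4me3", "TGFb_minus"), c("H3K4me3", "TGFb_plus"),
                 c("H3K27me3", "TGFb_minus"), c("H3K27me3", "TGFb_plus"),
                 c("input", "TGFb_plus"))
  readsets <- lapply(tracks, function(tr)
    simulate_reads(anno, truth, tr[1], tr[2], config))
  names(readsets) <- vapply(readsets, `[[`, character(1), "sample_id")
  paths <- list(annotation = file.path(dir, "annotation.gff3"),
                expression_tgfb = file.path(dir, "expression_tgfb.tsv"),
                expression_rankl = file.path(dir, "expression_rankl.tsv"),
                truth = file.path(dir, "truth.json"),
                samples = file.path(dir, "samples.yaml"))
  write_annotation_gff3(anno, paths$annotation)
  bed_paths <- character(0)
  for (nm in names(readsets)) {
    bp <- file.path(dir, paste0(nm, ".bed"))
    write_reads_bed(readsets[[nm]], bp)
    bed_paths[nm] <- bp
  }
  expr <- list(TGFb = simulate_expression(anno, truth, config, "TGFb"),
               RANKL = simulate_expression(anno, truth, config, "RANKL"))
  write_expression_tsv(expr$TGFb, paths$expression_tgfb)
  write_expression_tsv(expr$RANKL, paths$expression_rankl)
  jsonlite::write_json(list(genes = truth$genes, peaks = truth$peaks,
                            seed = config$seed),
                       paths$truth, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(list(samples = lapply(names(readsets), function(nm) {
    rs <- readsets[[nm]]
    list(sample_id = nm, path = basename(bed_paths[[nm]]),
         antibody = rs$antibody, condition = rs$condition,
         total_sequenced = rs$total_sequenced)
  })), paths$samples)
  paths$beds <- bed_paths
  invisible(list(annotation = anno, truth = truth, readsets = readsets,
                 expression = expr, paths = paths))
}

#' Recovery and precision of called peaks against planted regions
#'
#' A planted region is recovered if some called peak overlaps it with at
#' least `min_reciprocal` of *both* widths; a called peak is a true
#' positive if it so matches some planted region.
#'
#' @param called peak `GRanges` from [call_peaks()].
#' @param planted `GRanges` of planted regions (see [planted_peaks()]).
#' @param min_reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return list with `recall`, `precision`, `n_called`, `n_planted`.
#' @export
evaluate_peak_recovery <- function(called, planted, min_reciprocal = 0.5) {
  if (!length(planted)) stop("no planted regions to evaluate against")
  hits <- findOverlaps(called, planted)
  ov <- width(pintersect(called[queryHits(hits)], planted[subjectHits(hits)]))
  good <- ov >= min_reciprocal * width(called[queryHits(hits)]) &
    ov >= min_reciprocal * width(planted[subjectHits(hits)])
  list(recall = length(unique(subjectHits(hits)[good])) / length(planted),
       precision = if (length(called))
         length(unique(queryHits(hits)[good])) / length(called) else NA_real_,
       n_called = length(called), n_planted = length(planted))
}
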