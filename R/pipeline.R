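## End-to-end orchestration: coverage -> ratio -> peaks per sample,
## target/mark assignment, state transitions, expression filtering and
## folds, enrichment statistics, candidate selection, and report output.

#' Pipeline configuration
#'
#' All thresholds default to the study's printed cutoffs, so `run_full()`
#' with defaults reproduces the published analysis on any input.
#'
#' @param annotation path to the gene annotation (GFF3 or BED12).
#' @param sample_sheet path to the YAML sample sheet.
#' @param expression_tgfb,expression_rankl paths to the expression TSVs.
#' @param out_dir output directory.
#' @param smad_ratio,k4_ratio,k27_ratio peak-calling ratio thresholds
#'   (8, 8, 5).
#' @param tss_flank promoter half-window for mark status (1000 bp).
#' @param upstream upstream extent of the target window (10000 bp).
#' @param expr_floor expression floor (70).
#' @param up_fold,down_fold fold-change cutoffs (2, 0.5).
#' @param tgfb_at,rankl_rank_at ranking timepoints: TGF-beta ratio at
#'   24 h, RANKL at 72 h.
#' @param rankl_down_times timepoints any/all of which must be down for
#'   the RANKL-down criterion (24, 48, 72 h).
#' @param rankl_down_mode `"any"` (default) or `"all"`.
#' @param require_tgfb_up,require_rankl_down add the expression criteria
#'   to candidate selection (both `FALSE` by default: candidates are
#'   Smad2/3 targets with a resolving bivalent promoter).
#' @param bin_size,merge_gap,min_width,pseudocount peak-calling geometry
#'   (see [call_peaks()] and [ratio_track()]).
#' @param use_control use the input sample as ratio denominator instead of
#'   the track's own background estimate (default `FALSE`).
#' @param annotation_format `"gff3"` or `"bed12"`.
#' @param gsea_nperm,seed GSEA permutation settings.
#' @param write_tracks also write per-sample bedGraph tracks.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(annotation, sample_sheet, expression_tgfb,
                            expression_rankl, out_dir,
                            smad_ratio = 8, k4_ratio = 8, k27_ratio = 5,
                            tss_flank = 1000, upstream = 10000,
                            expr_floor = 70, up_fold = 2, down_fold = 0.5,
                            tgfb_at = 24, rankl_rank_at = 72,
                            rankl_down_times = c(24, 48, 72),
                            rankl_down_mode = c("any", "all"),
                            require_tgfb_up = FALSE,
                            require_rankl_down = FALSE,
                            bin_size = 100, merge_gap = 300, min_width = 300,
                            pseudocount = 1, use_control = FALSE,
                            annotation_format = "gff3",
                            gsea_nperm = 1000, seed = 1,
                            write_tracks = FALSE) {
  thr <- c(smad_ratio, k4_ratio, k27_ratio, tss_flank, upstream, expr_floor,
           up_fold, down_fold, bin_size, pseudocount)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Select candidate genes by the intersection criteria
#'
#' Default criteria: Smad2/3 target AND bivalent promoter resolving to
#' K4-only (`K4+K27+ -> K4+K27-`). Optional criteria add TGF-beta-up
#' (ratio > `up_fold` at `tgfb_at`) and RANKL-down (ratio < `down_fold`
#' at any -- or all -- of `rankl_down_times`), both evaluated at gene
#' level (highest-mean-intensity probe). Genes absent from a required
#' fold-change table fail that criterion.
#'
#' @param states a [classify_transitions()] table.
#' @param smad_targets character vector from [smad_target_genes()].
#' @param tgfb_folds,rankl_folds [fold_change()] tables (only needed when
#'   the matching criterion is on).
#' @param require_tgfb_up,require_rankl_down logical criteria switches.
#' @param up_fold,down_fold cutoffs (2, 0.5).
#' @param tgfb_at TGF-beta evaluation timepoint (24 h).
#' @param rankl_down_times,rankl_down_mode RANKL-down aggregation.
#' @return A `CandidateReport` list: `candidates` (sorted gene ids),
#'   `evidence` (per-gene data.frame over the whole universe), `criteria`.
#' @export
select_candidates <- function(states, smad_targets, tgfb_folds = NULL,
                              rankl_folds = NULL,
                              require_tgfb_up = FALSE,
                              require_rankl_down = FALSE,
                              up_fold = 2, down_fold = 0.5, tgfb_at = 24,
                              rankl_down_times = c(24, 48, 72),
                              rankl_down_mode = c("any", "all")) {
  rankl_down_mode <- match.arg(rankl_down_mode)
  universe <- states$gene_id
  if (!length(universe)) stop("empty gene universe")
  ev <- data.frame(gene_id = universe,
                   is_smad_target = universe %in% smad_targets,
                   transition = states$transition,
                   resolving = states$transition == bivalent_to_k4only(),
                   stringsAsFactors = FALSE)
  sel <- ev$is_smad_target & ev$resolving
  gene_ratio <- function(fct, at) {
    rp <- representative_probes(fct)
    j <- match(at, fct$timepoints)
    if (is.na(j)) stop("unknown timepoint: ", at)
    setNames(fct$ratios[rp, j], unname(fct$probe_to_gene[rp]))
  }
  if (!is.null(tgfb_folds)) {
    r <- gene_ratio(tgfb_folds, tgfb_at)[universe]
    ev$tgfb_ratio <- unname(r)
    ev$tgfb_up <- !is.na(r) & r > up_fold
    if (require_tgfb_up) sel <- sel & ev$tgfb_up
  } else if (require_tgfb_up) {
    stop("require_tgfb_up needs tgfb_folds")
  }
  if (!is.null(rankl_folds)) {
    down <- vapply(rankl_down_times, function(t) {
      r <- gene_ratio(rankl_folds, t)[universe]
      !is.na(r) & r < down_fold
    }, logical(length(universe)))
    down <- matrix(down, nrow = length(universe))
    ev$rankl_down <- if (rankl_down_mode == "any") rowSums(down) > 0
                     else rowSums(down) == ncol(down)
    if (require_rankl_down) sel <- sel & ev$rankl_down
  } else if (require_rankl_down) {
    stop("require_rankl_down needs rankl_folds")
  }
  structure(list(candidates = sort(universe[sel]), evidence = ev,
                 criteria = list(require_tgfb_up = require_tgfb_up,
                                 require_rankl_down = require_rankl_down,
                                 up_fold = up_fold, down_fold = down_fold,
                                 tgfb_at = tgfb_at,
                                 rankl_down_times = rankl_down_times,
                                 rankl_down_mode = rankl_down_mode)),
            class = "CandidateReport")
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat("CandidateReport:", length(x$candidates), "candidate gene(s)\n")
  if (length(x$candidates))
    cat(" ", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

## simple stable hash of the analysis parameters for provenance
## (output location does not change what is computed)
config_hash <- function(config) {
  keep <- setdiff(names(config), c("out_dir", "write_tracks"))
  s <- jsonlite::toJSON(config[sort(keep)], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  sprintf("%08x", derive_seed(0, as.character(s)))
}

#' Run the full pipeline
#'
#' Stages: load annotation and samples; bin reads and build ratio tracks;
#' call Smad2/3 binding regions (ratio >= `smad_ratio`) and assign targets
#' through the TSS-to-first-intron window; call K4/K27 marks in both
#' conditions (+/- `tss_flank` of the TSS) and classify transitions;
#' normalize, filter and fold-change both expression matrices; compute
#' fold-enrichment/chi-square of targets in the transition and expression
#' categories and GSEA of targets in both ranked lists; select candidates.
#' Every stage is logged with its counts; the run is deterministic given
#' the config (including its `seed`).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress logging.
#' @return The `CandidateReport` from [select_candidates()], augmented
#'   with `stage_counts`, `enrichment`, `gsea`, `metaprofiles`,
#'   `provenance`, and `files` (everything also written under
#'   `config$out_dir`).
#' @export
run_full <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  anno <- read_annotation(config$annotation, config$annotation_format)
  say("annotation: %d genes", length(anno$genes))
  sheet <- read_sample_sheet(config$sample_sheet)
  readsets <- load_readsets(sheet)
  need <- list(smad = c("Smad2/3", "TGFb_plus"),
               k4_minus = c("H3K4me3", "TGFb_minus"),
               k4_plus = c("H3K4me3", "TGFb_plus"),
               k27_minus = c("H3K27me3", "TGFb_minus"),
               k27_plus = c("H3K27me3", "TGFb_plus"))
  pick <- function(ab, cond) {
    hit <- vapply(readsets, function(r)
      r$antibody == ab && r$condition == cond, logical(1))
    if (!any(hit))
      stop("missing required sample: ", ab, " / ", cond)
    readsets[[which(hit)[1]]]
  }
  rs <- lapply(need, function(x) pick(x[1], x[2]))
  for (r in rs) say("sample %s: %d reads mapped (%.1f%%)", r$sample_id,
                    r$mapped, mapping_summary(r))
  ctrl_track <- NULL
  if (isTRUE(config$use_control)) {
    hit <- vapply(readsets, function(r) r$antibody == "input", logical(1))
    if (!any(hit)) stop("use_control = TRUE but no input sample in sheet")
    ctrl_track <- bin_reads(readsets[[which(hit)[1]]], anno$chrom_sizes,
                            config$bin_size)
  }
  tracks <- lapply(rs, bin_reads, chrom_sizes = anno$chrom_sizes,
                   bin_size = config$bin_size)
  thresholds <- c(smad = config$smad_ratio, k4_minus = config$k4_ratio,
                  k4_plus = config$k4_ratio, k27_minus = config$k27_ratio,
                  k27_plus = config$k27_ratio)
  peaks <- lapply(names(tracks), function(nm) {
    rt <- ratio_track(tracks[[nm]], control = ctrl_track,
                      pseudocount = config$pseudocount)
    call_peaks(rt, thresholds[[nm]], config$merge_gap, config$min_width)
  })
  names(peaks) <- names(tracks)
  dir.create(file.path(config$out_dir, "peaks"), showWarnings = FALSE)
  for (nm in names(peaks)) {
    say("peaks %s: %d regions (ratio >= %g)", nm, length(peaks[[nm]]),
        thresholds[[nm]])
    write_bed(peaks[[nm]], file.path(config$out_dir, "peaks",
                                     paste0(nm, ".bed")))
  }
  if (isTRUE(config$write_tracks)) {
    dir.create(file.path(config$out_dir, "tracks"), showWarnings = FALSE)
    for (nm in names(tracks))
      write_bedgraph(tracks[[nm]], file.path(config$out_dir, "tracks",
                                             paste0(nm, ".bedGraph")))
  }

  targets <- smad_target_genes(peaks$smad, anno, config$upstream)
  say("Smad2/3 target genes: %d of %d", length(targets), length(anno$genes))
  marks <- lapply(c("k4_minus", "k4_plus", "k27_minus", "k27_plus"),
                  function(nm) mark_status(peaks[[nm]], anno, config$tss_flank))
  names(marks) <- c("k4_minus", "k4_plus", "k27_minus", "k27_plus")
  say("K4(+): %d / %d (TGFb-/+); K27(+): %d / %d", sum(marks$k4_minus),
      sum(marks$k4_plus), sum(marks$k27_minus), sum(marks$k27_plus))
  states <- classify_transitions(marks$k4_minus, marks$k27_minus,
                                 marks$k4_plus, marks$k27_plus)
  resolving <- states$gene_id[states$transition == bivalent_to_k4only()]
  say("bivalent -> K4-only genes: %d", length(resolving))

  expr <- lapply(list(tgfb = config$expression_tgfb,
                      rankl = config$expression_rankl), function(p) {
    filt <- filter_expressed(normalize_mean100(read_expression_tsv(p)),
                             config$expr_floor)
    filt$folds <- fold_change(filt$matrix, up_fold = config$up_fold,
                              down_fold = config$down_fold)
    filt
  })
  say("expressed: TGFb %d probes (%d genes); RANKL %d probes (%d genes)",
      expr$tgfb$n_probes, expr$tgfb$n_genes,
      expr$rankl$n_probes, expr$rankl$n_genes)

  universe <- anno$genes$gene_id
  enr <- list(
    transition = contingency(targets, resolving, universe),
    tgfb_up = contingency(intersect(targets, expr$tgfb$kept_genes),
                          category_members(expr$tgfb$folds, config$tgfb_at,
                                           "up", "gene"),
                          expr$tgfb$kept_genes),
    tgfb_down = contingency(intersect(targets, expr$tgfb$kept_genes),
                            category_members(expr$tgfb$folds, config$tgfb_at,
                                             "down", "gene"),
                            expr$tgfb$kept_genes),
    rankl_up = contingency(intersect(targets, expr$rankl$kept_genes),
                           category_members(expr$rankl$folds,
                                            config$rankl_rank_at, "up", "gene"),
                           expr$rankl$kept_genes),
    rankl_down = contingency(intersect(targets, expr$rankl$kept_genes),
                             category_members(expr$rankl$folds,
                                              config$rankl_rank_at, "down",
                                              "gene"),
                             expr$rankl$kept_genes))
  say("enrichment of targets in bivalent->K4-only: %.2f-fold (p = %.3g)",
      enr$transition$fold_enrichment, enr$transition$p)
  run_gsea <- function(ranked, set, label) {
    if (!length(set) || length(set) >= nrow(ranked)) {
      say("GSEA %s skipped (degenerate gene set of size %d)", label,
          length(set))
      return(NULL)
    }
    gsea_permutation_p(ranked, set, n_perm = config$gsea_nperm,
                       seed = derive_seed(config$seed, "gsea", label))
  }
  gsea <- list(
    tgfb = run_gsea(
      score_to_log2(ranked_list(expr$tgfb$folds, config$tgfb_at, "gene")),
      intersect(targets, expr$tgfb$kept_genes), "tgfb"),
    rankl = run_gsea(
      score_to_log2(ranked_list(expr$rankl$folds, config$rankl_rank_at,
                                "gene")),
      intersect(targets, expr$rankl$kept_genes), "rankl"))
  for (nm in names(gsea)) if (!is.null(gsea[[nm]]))
    say("GSEA %s: ES = %.3f (permutation p = %.3g)", nm, gsea[[nm]]$es,
        gsea[[nm]]$p_perm)

  dir.create(file.path(config$out_dir, "metaprofiles"), showWarnings = FALSE)
  metas <- lapply(names(tracks), function(nm) {
    mp <- tss_metaprofile(tracks[[nm]], anno$genes, flank = 20 * config$bin_size)
    write_metaprofile(mp, file.path(config$out_dir, "metaprofiles",
                                    paste0(nm, ".tsv")))
    mp
  })
  names(metas) <- names(tracks)

  report <- select_candidates(states, targets,
                              tgfb_folds = expr$tgfb$folds,
                              rankl_folds = expr$rankl$folds,
                              require_tgfb_up = config$require_tgfb_up,
                              require_rankl_down = config$require_rankl_down,
                              up_fold = config$up_fold,
                              down_fold = config$down_fold,
                              tgfb_at = config$tgfb_at,
                              rankl_down_times = config$rankl_down_times,
                              rankl_down_mode = config$rankl_down_mode)
  say("candidates: %d gene(s)", length(report$candidates))

  report$stage_counts <- list(
    n_genes = length(anno$genes),
    mapped_percent = mapping_summary(rs$smad),
    n_sbrs = length(peaks$smad),
    n_smad_targets = length(targets),
    n_k4_minus = sum(marks$k4_minus), n_k4_plus = sum(marks$k4_plus),
    n_k27_minus = sum(marks$k27_minus), n_k27_plus = sum(marks$k27_plus),
    n_resolving = length(resolving),
    tgfb_probes = expr$tgfb$n_probes, tgfb_genes = expr$tgfb$n_genes,
    rankl_probes = expr$rankl$n_probes, rankl_genes = expr$rankl$n_genes,
    n_candidates = length(report$candidates))
  report$enrichment <- enr
  report$gsea <- gsea
  report$metaprofiles <- metas
  report$provenance <- list(config_hash = config_hash(config),
                            seed = config$seed,
                            version = as.character(packageVersion("bivalentSmad")))

  files <- list(
    report = file.path(config$out_dir, "report.json"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    evidence = file.path(config$out_dir, "evidence.tsv"),
    smad_targets = file.path(config$out_dir, "smad_targets.tsv"),
    gene_states = file.path(config$out_dir, "gene_states.tsv"))
  data.table::fwrite(data.frame(gene_id = report$candidates),
                     files$candidates, sep = "\t")
  data.table::fwrite(report$evidence, files$evidence, sep = "\t")
  data.table::fwrite(data.frame(gene_id = targets), files$smad_targets,
                     sep = "\t")
  write_gene_states(states, files$gene_states)
  strip <- function(x) x[setdiff(names(x),
                                 c("running_sum", "es_perm", "leading_edge"))]
  jsonlite::write_json(
    list(candidates = report$candidates,
         stage_counts = report$stage_counts,
         enrichment = lapply(enr, unclass),
         gsea = lapply(gsea, function(g) strip(unclass(g))),
         criteria = report$criteria,
         provenance = report$provenance),
    files$report, auto_unbox = TRUE, digits = 10)
  report$files <- files
  report
}

## log2-transform ranked fold-change scores so GSEA hit weights treat
## x-fold up and 1/x down symmetrically
score_to_log2 <- function(ranked) {
  ranked$score <- log2(pmax(ranked$score, 1e-12))
  ranked
}
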