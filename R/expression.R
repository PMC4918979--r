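## Expression matrices (Affymetrix "average difference"-like intensities),
## per-array mean-100 normalization, the >70 expression floor, time-course
## fold changes with the 2-fold / 0.5-fold categories, and ranked lists.

#' Construct an expression matrix
#'
#' @param values numeric probe x timepoint matrix of intensities (>= 0),
#'   rownames = probe ids.
#' @param timepoints numeric vector of hours, strictly increasing from 0;
#'   one per column.
#' @param probe_to_gene named character vector mapping each probe to one
#'   gene id.
#' @param normalized logical; whether columns have been scaled to mean 100.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, timepoints, probe_to_gene,
                              normalized = FALSE) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), ncol(values) == length(timepoints))
  if (any(values < 0)) stop("intensities must be >= 0")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing and start at 0")
  if (is.null(rownames(values))) stop("values needs probe ids as rownames")
  miss <- setdiff(rownames(values), names(probe_to_gene))
  if (length(miss))
    stop("probes without gene mapping: ", paste(head(miss, 5), collapse = ", "))
  colnames(values) <- as.character(timepoints)
  structure(list(values = values, timepoints = as.numeric(timepoints),
                 probe_to_gene = probe_to_gene[rownames(values)],
                 normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes (%d genes) x %d timepoints (%s h)%s\n",
              nrow(x$values), length(unique(x$probe_to_gene)),
              length(x$timepoints), paste(x$timepoints, collapse = ","),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected columns: `probe_id`, `gene_id`, then one column per timepoint
#' named by hours.
#'
#' @param path TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  tp <- as.numeric(colnames(dt)[-(1:2)])
  vals <- as.matrix(dt[, -(1:2)])
  rownames(vals) <- dt[[1]]
  expression_matrix(vals, tp, setNames(dt[[2]], dt[[1]]))
}

#' Write an expression matrix as TSV
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  dt <- data.table::data.table(probe_id = rownames(mat$values),
                               gene_id = unname(mat$probe_to_gene))
  for (j in seq_along(mat$timepoints))
    dt[[as.character(mat$timepoints[j])]] <- mat$values[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Normalize each array (column) to mean intensity 100
#'
#' Mirrors the per-array scaling of average-difference values so that the
#' mean over all probes on each array is exactly 100. Idempotent.
#'
#' @param mat an [expression_matrix()].
#' @return the normalized [expression_matrix()].
#' @export
normalize_mean100 <- function(mat) {
  mu <- colMeans(mat$values)
  if (any(mu <= 0)) stop("cannot normalize a column with mean <= 0")
  mat$values <- sweep(mat$values, 2, 100 / mu, `*`)
  mat$normalized <- TRUE
  mat
}

#' Filter probes by the expression floor
#'
#' A probe is kept iff its intensity exceeds `floor` (strictly) at at least
#' one timepoint; kept genes are the genes of kept probes.
#'
#' @param mat a normalized [expression_matrix()].
#' @param floor intensity floor (default 70).
#' @return list with `matrix` (the filtered [expression_matrix()]),
#'   `kept_probes`, `kept_genes`, `n_probes`, `n_genes`.
#' @export
filter_expressed <- function(mat, floor = 70) {
  if (!mat$normalized) stop("normalize_mean100() must run before filtering")
  keep <- apply(mat$values, 1, max) > floor
  kept <- mat
  kept$values <- mat$values[keep, , drop = FALSE]
  kept$probe_to_gene <- mat$probe_to_gene[keep]
  genes <- sort(unique(unname(kept$probe_to_gene)))
  list(matrix = kept, kept_probes = rownames(kept$values),
       kept_genes = genes, n_probes = sum(keep), n_genes = length(genes))
}

#' Time-course fold changes and up/down categories
#'
#' `ratio(t) = max(value(t), epsilon) / max(value(0), epsilon)`; a probe is
#' `up` at t iff ratio > 2, `down` iff ratio < 0.5, else `unchanged`
#' (strict inequalities). The denominator floor `epsilon` guards
#' near-zero baselines of background-subtracted intensities.
#'
#' @param mat a normalized (and typically filtered) [expression_matrix()].
#' @param epsilon intensity floor for both ratio terms (default 1).
#' @param up_fold,down_fold category cutoffs (defaults 2 and 0.5).
#' @return A `FoldChangeTable`: list with `ratios` and `categories`
#'   (probe x timepoint matrices), `timepoints`, `probe_to_gene`, and
#'   `mean_intensity` (per-probe mean over timepoints, used for
#'   gene-level collapse).
#' @export
fold_change <- function(mat, epsilon = 1, up_fold = 2, down_fold = 0.5) {
  v <- pmax(mat$values, epsilon)
  ratios <- v / v[, 1]
  cats <- matrix("unchanged", nrow(ratios), ncol(ratios),
                 dimnames = dimnames(ratios))
  cats[ratios > up_fold] <- "up"
  cats[ratios < down_fold] <- "down"
  structure(list(ratios = ratios, categories = cats,
                 timepoints = mat$timepoints,
                 probe_to_gene = mat$probe_to_gene,
                 mean_intensity = rowMeans(mat$values)),
            class = "FoldChangeTable")
}

#' Probes or genes in a fold-change category at a timepoint
#'
#' @param fct a [fold_change()] table.
#' @param at timepoint in hours.
#' @param category `"up"`, `"down"` or `"unchanged"`.
#' @param level `"probe"` or `"gene"`; at gene level each gene is
#'   represented by its highest-mean-intensity probe.
#' @return character vector of probe or gene ids.
#' @export
category_members <- function(fct, at, category = c("up", "down", "unchanged"),
                             level = c("probe", "gene")) {
  category <- match.arg(category)
  level <- match.arg(level)
  j <- match(at, fct$timepoints)
  if (is.na(j)) stop("unknown timepoint: ", at)
  if (level == "probe") {
    rownames(fct$ratios)[fct$categories[, j] == category]
  } else {
    rep_probes <- representative_probes(fct)
    genes <- fct$probe_to_gene[rep_probes]
    sort(unname(genes[fct$categories[rep_probes, j] == category]))
  }
}

## one probe per gene: highest mean intensity, ties broken by probe id
representative_probes <- function(fct) {
  ord <- order(fct$probe_to_gene, -fct$mean_intensity, rownames(fct$ratios))
  probes <- rownames(fct$ratios)[ord]
  probes[!duplicated(fct$probe_to_gene[ord])]
}

#' Ranked list by fold change at a timepoint
#'
#' Entries are sorted by descending ratio at `at`; ties break by identifier
#' so the order is deterministic. At gene level each gene's score comes
#' from its highest-mean-intensity probe.
#'
#' @param fct a [fold_change()] table.
#' @param at timepoint in hours.
#' @param level `"probe"` or `"gene"`.
#' @return data.frame with columns `id` and `score` (the ratio at `at`),
#'   ordered.
#' @export
ranked_list <- function(fct, at, level = c("probe", "gene")) {
  level <- match.arg(level)
  j <- match(at, fct$timepoints)
  if (is.na(j)) stop("unknown timepoint: ", at)
  if (level == "probe") {
    id <- rownames(fct$ratios)
    score <- fct$ratios[, j]
  } else {
    rep_probes <- representative_probes(fct)
    id <- unname(fct$probe_to_gene[rep_probes])
    score <- fct$ratios[rep_probes, j]
  }
  o <- order(-score, id)
  data.frame(id = id[o], score = unname(score[o]), stringsAsFactors = FALSE)
}

#' Write fold changes as TSV
#' @param fct a [fold_change()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fct, path) {
  dt <- data.table::data.table(probe_id = rownames(fct$ratios),
                               gene_id = unname(fct$probe_to_gene))
  for (j in seq_along(fct$timepoints)) {
    dt[[paste0("ratio_", fct$timepoints[j])]] <- fct$ratios[, j]
    dt[[paste0("category_", fct$timepoints[j])]] <- fct$categories[, j]
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
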