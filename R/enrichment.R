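## Gene-set enrichment statistics: 2x2 fold enrichment with a Pearson
## chi-square test, and the GSEA running enrichment score with a
## gene-set-label permutation p-value.

#' 2x2 fold enrichment and chi-square test
#'
#' Cells: `a` = in set and in category, `b` = in set only, `c` = in
#' category only, `d` = neither. Fold enrichment is the set's frequency
#' inside the category over its frequency in the universe,
#' `(a/(a+c)) / ((a+b)/N)`. The chi-square statistic is Pearson's
#' `sum((O-E)^2/E)` on df = 1, by default without Yates continuity
#' correction (the counts in this analysis are large); `p` is the
#' upper-tail probability.
#'
#' @param set_members,category_members character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all ids.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return A `ContingencyResult` list: `a`, `b`, `c`, `d`,
#'   `fold_enrichment`, `chi2`, `p`, and `low_expected` flagging any
#'   expected cell count < 5.
#' @export
contingency <- function(set_members, category_members, universe,
                        correct = FALSE) {
  set_members <- unique(set_members)
  category_members <- unique(category_members)
  out <- c(setdiff(set_members, universe), setdiff(category_members, universe))
  if (length(out))
    stop("ids outside the universe: ", paste(head(out, 5), collapse = ", "))
  in_set <- universe %in% set_members
  in_cat <- universe %in% category_members
  a <- sum(in_set & in_cat); b <- sum(in_set & !in_cat)
  cc <- sum(!in_set & in_cat); d <- sum(!in_set & !in_cat)
  n <- a + b + cc + d
  fold <- if ((a + cc) > 0 && (a + b) > 0) (a / (a + cc)) / ((a + b) / n)
          else NA_real_
  margins_ok <- all(c(a + b, cc + d, a + cc, b + d) > 0)
  if (!margins_ok) {
    warning("zero margin: chi-square undefined")
    chi2 <- NA_real_; p <- NA_real_; low_expected <- NA
  } else {
    expected <- outer(c(a + b, cc + d), c(a + cc, b + d)) / n
    obs <- matrix(c(a, cc, b, d), 2)
    adj <- if (correct) pmin(abs(obs - expected), 0.5) else 0
    chi2 <- sum((abs(obs - expected) - adj)^2 / expected)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    low_expected <- any(expected < 5)
  }
  structure(list(a = a, b = b, c = cc, d = d, fold_enrichment = fold,
                 chi2 = chi2, p = p, low_expected = low_expected),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("2x2 [a=%d b=%d c=%d d=%d]: %.2f-fold enrichment, chi2 = %.3f, p = %.3g\n",
              x$a, x$b, x$c, x$d, x$fold_enrichment, x$chi2, x$p))
  invisible(x)
}

#' GSEA running enrichment score
#'
#' Walks the ranked list from the top; at gene-set hits the running sum
#' increases by `|score|^p / sum(|score|^p over hits)`, at misses it
#' decreases by `1/(N - Nh)`. The ES is the signed maximal deviation of
#' the running sum from zero. With `p = 0` this is the classic
#' Kolmogorov-Smirnov-like statistic; `p = 1` (the default elsewhere in
#' the package) weights hits by their scores.
#'
#' @param ranked data.frame with columns `id` and `score`, already ordered
#'   (e.g. from [ranked_list()]), or a character vector of ids (then
#'   `scores` may supply the scores).
#' @param gene_set character vector; must intersect the ranked ids and not
#'   cover them all.
#' @param p hit-weighting exponent, 0 or 1.
#' @param scores optional numeric vector parallel to `ranked` when
#'   `ranked` is a character vector.
#' @return A `GseaResult` list: `es`, `running_sum` (length N),
#'   `leading_edge` (set members at or before the extremum for positive
#'   ES, at or after it for negative ES), `n_hits`.
#' @export
gsea_es <- function(ranked, gene_set, p = 1, scores = NULL) {
  if (is.data.frame(ranked)) {
    ids <- as.character(ranked$id); sc <- as.numeric(ranked$score)
  } else {
    ids <- as.character(ranked)
    sc <- if (is.null(scores)) rep(1, length(ids)) else as.numeric(scores)
  }
  n <- length(ids)
  hit <- ids %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene_set does not intersect the ranked list")
  if (nh == n) stop("gene_set covers the whole ranked list")
  w <- abs(sc)^p
  wh <- sum(w[hit])
  if (wh == 0) { w <- rep(1, n); wh <- nh }  # all-zero hit scores: fall back to p = 0
  step <- ifelse(hit, w / wh, -1 / (n - nh))
  running <- cumsum(step)
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] > -running[i_min]) running[i_max] else running[i_min]
  leading <- if (es >= 0) ids[seq_len(i_max)][hit[seq_len(i_max)]]
             else ids[i_min:n][hit[i_min:n]]
  structure(list(es = es, running_sum = running, leading_edge = leading,
                 n_hits = nh),
            class = "GseaResult")
}

#' @export
print.GseaResult <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f (%d hits)%s\n", x$es, x$n_hits,
              if (!is.null(x$p_perm))
                sprintf(", permutation p = %.4g (%d permutations)",
                        x$p_perm, x$n_perm) else ""))
  invisible(x)
}

## ES for many permuted hit-position sets at once.
## hits: m x P matrix of column-sorted 1-based positions; w: rank weights.
es_from_hits_matrix <- function(hits, w, n) {
  m <- nrow(hits); p_cols <- ncol(hits)
  wh <- matrix(w[hits], m, p_cols)
  tot <- wh[m, , drop = TRUE]
  if (m > 1) {
    for (i in 2:m) wh[i, ] <- wh[i - 1, ] + wh[i, ]
    tot <- wh[m, ]
  }
  zero <- tot == 0
  if (any(zero)) {  # degenerate all-zero weights: unweighted fallback
    wh[, zero] <- matrix(seq_len(m), m, sum(zero))
    tot[zero] <- m
  }
  cw <- sweep(wh, 2, tot, `/`)
  drop_ <- sweep(hits, 1, seq_len(m), `-`) / (n - m)  # misses before each hit
  a <- cw - drop_                       # running sum at each hit
  b <- rbind(0, cw[-m, , drop = FALSE]) - drop_  # just before each hit
  max_a <- Reduce(pmax, asplit(a, 1))
  min_b <- Reduce(pmin, asplit(b, 1))
  ifelse(max_a > -min_b, max_a, min_b)
}

#' GSEA enrichment score with a permutation p-value
#'
#' Gene-set labels are permuted over the ranked universe (this design has
#' one array per timepoint, so sample-label permutation is unavailable);
#' the two-sided p-value is `(1 + #{|ES*| >= |ES|}) / (n_perm + 1)`.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A `GseaResult` as in [gsea_es()] plus `p_perm`, `n_perm`,
#'   `es_perm` (the permuted scores).
#' @export
gsea_permutation_p <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                               p = 1, scores = NULL) {
  stopifnot(n_perm >= 1)
  obs <- gsea_es(ranked, gene_set, p = p, scores = scores)
  if (is.data.frame(ranked)) {
    ids <- as.character(ranked$id); sc <- as.numeric(ranked$score)
  } else {
    ids <- as.character(ranked)
    sc <- if (is.null(scores)) rep(1, length(ids)) else as.numeric(scores)
  }
  n <- length(ids)
  m <- obs$n_hits
  w <- abs(sc)^p
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  hits <- vapply(seq_len(n_perm),
                 function(i) sort.int(sample.int(n, m)), integer(m))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  es_perm <- es_from_hits_matrix(matrix(hits, nrow = m), w, n)
  obs$p_perm <- (1 + sum(abs(es_perm) >= abs(obs$es))) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$es_perm <- es_perm
  obs
}
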