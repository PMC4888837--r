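#' Load a per-gene differential-expression table
#'
#' Knockdown-vs-control tables with one row per gene are the inputs to the
#' misregulation overlap and direction-concordance analyses; model fitting
#' itself (e.g. edgeR) happens upstream.
#'
#' @param path TSV with header columns `gene_id`, `log2fc`, `pvalue`,
#'   `padj`.
#' @return A validated `data.frame` of those columns.
#' @export
load_de_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_de_table(tab)
}

#' @rdname load_de_table
#' @param tab A `data.frame` to validate in place of a file.
#' @export
validate_de_table <- function(tab) {
  req <- c("gene_id", "log2fc", "pvalue", "padj")
  .stop_if(!all(req %in% names(tab)),
           paste("DE table missing column(s):",
                 paste(setdiff(req, names(tab)), collapse = ", ")))
  tab <- tab[, req]
  for (col in c("log2fc", "pvalue", "padj")) {
    bad <- which(!is.numeric(tab[[col]]) | is.na(tab[[col]]))
    .stop_if(length(bad) > 0L,
             sprintf("non-numeric %s at line %d", col, bad[1L] + 1L))
  }
  for (col in c("pvalue", "padj")) {
    bad <- which(tab[[col]] < 0 | tab[[col]] > 1)
    .stop_if(length(bad) > 0L,
             sprintf("%s outside [0,1] at line %d", col, bad[1L] + 1L))
  }
  dup <- which(duplicated(tab$gene_id))
  .stop_if(length(dup) > 0L,
           sprintf("duplicate gene_id '%s' at line %d",
                   tab$gene_id[dup[1L]], dup[1L] + 1L))
  tab
}

#' Significantly misregulated genes
#'
#' Genes whose `pvalue` (or `padj`) is strictly below `alpha`.
#'
#' @param tab A DE table (see [load_de_table()]).
#' @param alpha Significance threshold in (0, 1].
#' @param field `"pvalue"` (default) or `"padj"`.
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(tab, alpha = 0.01,
                              field = c("pvalue", "padj")) {
  field <- match.arg(field)
  stopifnot(alpha > 0, alpha <= 1)
  tab$gene_id[tab[[field]] < alpha]
}

#' Misregulated-gene overlap between two knockdowns
#'
#' Within the shared gene universe (intersection of gene ids), counts genes
#' misregulated in each table (`field < alpha`, strict) and their overlap,
#' and computes the exact upper-tail hypergeometric probability of an
#' overlap at least as large under independent draws from the universe. The
#' probability is descriptive; it is never used as a filter.
#'
#' @param table_a,table_b DE tables.
#' @param alpha Significance threshold. Default 0.01.
#' @param field Column tested. Default `"pvalue"`.
#' @param verbose Log universe accounting.
#' @return An object of class `concordance_result`: list with `n_sig_a`,
#'   `n_sig_b`, `n_overlap`, `overlap_genes`, `hypergeom_p`,
#'   `universe_size`.
#' @export
overlap_misregulated <- function(table_a, table_b, alpha = 0.01,
                                 field = c("pvalue", "padj"),
                                 verbose = FALSE) {
  field <- match.arg(field)
  universe <- intersect(table_a$gene_id, table_b$gene_id)
  .stop_if(length(universe) == 0L, "empty shared gene universe")
  .msg(verbose, sprintf(
    "overlap_misregulated: universe %d (tables %d / %d)",
    length(universe), nrow(table_a), nrow(table_b)))
  a <- table_a[table_a$gene_id %in% universe, ]
  b <- table_b[table_b$gene_id %in% universe, ]
  sig_a <- significant_genes(a, alpha, field)
  sig_b <- significant_genes(b, alpha, field)
  ov <- intersect(sig_a, sig_b)
  # P(X >= n_overlap), X ~ Hypergeom(universe; |sig_a| marked, |sig_b| drawn)
  p <- stats::phyper(length(ov) - 1L, length(sig_a),
                     length(universe) - length(sig_a), length(sig_b),
                     lower.tail = FALSE)
  structure(list(n_sig_a = length(sig_a), n_sig_b = length(sig_b),
                 n_overlap = length(ov), overlap_genes = ov,
                 hypergeom_p = p, universe_size = length(universe),
                 alpha = alpha, field = field),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Misregulated-gene overlap (%s < %g): %d and %d significant, %d shared (universe %d)\n",
    x$field, x$alpha, x$n_sig_a, x$n_sig_b, x$n_overlap, x$universe_size))
  cat(sprintf("  upper-tail hypergeometric P = %.3g\n", x$hypergeom_p))
  invisible(x)
}

#' Direction concordance between two knockdowns
#'
#' Selects genes significantly misregulated in `table_a` (`padj <
#' alpha_adj`, strict) that are also present in `table_b`, and reports the
#' fraction whose fold change has the same sign in both tables — the
#' quadrant analysis of a paired log2-fold-change scatter. Genes whose
#' `log2fc` in `table_b` is exactly 0 carry no direction and are excluded
#' from numerator and denominator.
#'
#' @param table_a,table_b DE tables; selection runs on `table_a`.
#' @param alpha_adj Adjusted-p threshold for selection. Default 0.05.
#' @param verbose Log exclusion accounting.
#' @return A list of class `direction_concordance` with
#'   `frac_same_direction`, `n_selected`, `n_compared`,
#'   `n_excluded_zero`, and `pairs` (gene_id, log2fc_a, log2fc_b,
#'   same_direction) for plotting.
#' @export
direction_concordance <- function(table_a, table_b, alpha_adj = 0.05,
                                  verbose = FALSE) {
  stopifnot(alpha_adj > 0, alpha_adj <= 1)
  sel <- table_a[table_a$padj < alpha_adj &
                   table_a$gene_id %in% table_b$gene_id, ]
  .stop_if(nrow(sel) == 0L, "no significant genes selected from table_a")
  m <- match(sel$gene_id, table_b$gene_id)
  pairs <- data.frame(gene_id = sel$gene_id,
                      log2fc_a = sel$log2fc,
                      log2fc_b = table_b$log2fc[m],
                      stringsAsFactors = FALSE)
  zero_b <- pairs$log2fc_b == 0
  .msg(verbose, sprintf(
    "direction_concordance: %d selected, %d excluded (log2fc_b == 0)",
    nrow(pairs), sum(zero_b)))
  cmp <- pairs[!zero_b, , drop = FALSE]
  cmp$same_direction <- sign(cmp$log2fc_a) == sign(cmp$log2fc_b)
  structure(list(
    frac_same_direction = if (nrow(cmp)) mean(cmp$same_direction) else NaN,
    n_selected = nrow(pairs),
    n_compared = nrow(cmp),
    n_excluded_zero = sum(zero_b),
    alpha_adj = alpha_adj,
    pairs = cmp
  ), class = "direction_concordance")
}

#' @export
print.direction_concordance <- function(x, ...) {
  cat(sprintf(
    "Direction concordance (padj < %g in first table): %.3f (%d of %d genes; %d zero-fold excluded)\n",
    x$alpha_adj, x$frac_same_direction, sum(x$pairs$same_direction),
    x$n_compared, x$n_excluded_zero))
  invisible(x)
}

#' @export
plot.direction_concordance <- function(x, ..., col = "firebrick") {
  lim <- range(c(x$pairs$log2fc_a, x$pairs$log2fc_b, 0))
  graphics::plot(x$pairs$log2fc_b, x$pairs$log2fc_a, pch = 16, cex = 0.6,
                 col = col, xlim = lim, ylim = lim,
                 xlab = "log2 fold change (second knockdown)",
                 ylab = "log2 fold change (selected knockdown)", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  invisible(x)
}

#' Write a DE table as TSV
#'
#' @param tab A DE table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_id\tlog2fc\tpvalue\tpadj", con)
  writeLines(sprintf("%s\t%.8g\t%.8g\t%.8g", tab$gene_id, tab$log2fc,
                     tab$pvalue, tab$padj), con)
  invisible(path)
}
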