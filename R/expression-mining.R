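#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count / (length_bp/1000) / (total/1e6)`.
#'
#' @param counts genes x samples matrix of nonnegative read counts.
#' @param gene_length_bp per-gene transcript length in bp (>= 1), recycled
#'   along rows.
#' @param totals per-sample total mapped reads (> 0).
#' @return genes x samples RPKM matrix.
#' @export
rpkm <- function(counts, gene_length_bp, totals) {
  counts <- as.matrix(counts)
  if (length(gene_length_bp) != nrow(counts))
    stop_arg("one gene length per row required")
  if (length(totals) != ncol(counts))
    stop_arg("one library total per column required")
  if (any(totals <= 0)) stop_arg("library totals must be > 0")
  if (any(gene_length_bp < 1)) stop_arg("gene lengths must be >= 1 bp")
  if (any(counts < 0)) stop_arg("counts must be nonnegative")
  sweep(counts / (gene_length_bp / 1000), 2, totals / 1e6, `/`)
}

#' log(RPKM + 1) transform
#'
#' @param x nonnegative matrix or vector of expression values.
#' @return elementwise natural `log(x + 1)`.
#' @export
log_rpkm <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop_arg("expression values must be nonnegative")
  log(x + 1)
}

#' Decile dispersion statistics for one gene
#'
#' The transcriptome-mining bimodality statistic: across the population, sort
#' a gene's expression values; the lowest decile is the `floor(n/10)` smallest
#' values (minimum 1) and the top decile the `floor(n/10)` largest. `p10` and
#' `p90` are their means and the percent standard deviation is
#' `pcsd = 100 * (p90 - p10) / (p90 + p10)` (defined as 0 when both decile
#' means are 0). A gene whose expression splits into a low and a high mode —
#' as under a strong eQTL — drives `p90` far from `p10` and pushes pcsd
#' toward 100. The alternative definition `method = "cv"` reports the percent
#' coefficient of variation over all samples instead.
#'
#' @param values one gene's expression across samples (missing values are
#'   dropped; at least 10 non-missing values required).
#' @param method `"decile"` (default, decile-contrast statistic) or `"cv"`
#'   (100 * SD/mean over all samples).
#' @return one-row data.frame with p10, p90, pcsd, n_samples.
#' @export
decile_stats <- function(values, method = c("decile", "cv")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 10) stop_arg("need >= 10 non-missing values, got ", n)
  s <- sort(values)
  k <- max(1L, n %/% 10L)
  p10 <- mean(s[seq_len(k)])
  p90 <- mean(s[seq.int(n - k + 1L, n)])
  pcsd <- if (method == "decile") {
    if (p90 + p10 == 0) 0 else 100 * (p90 - p10) / (p90 + p10)
  } else {
    m <- mean(values)
    if (m == 0) 0 else 100 * stats::sd(values) / m
  }
  data.frame(p10 = p10, p90 = p90, pcsd = pcsd, n_samples = n)
}

#' Decile dispersion table for an expression matrix
#'
#' Applies [decile_stats()] to every gene (row) of an expression matrix.
#'
#' @param expr genes x samples nonnegative expression matrix (RPKM), gene ids
#'   as rownames.
#' @param method passed to [decile_stats()].
#' @return data.frame of class `dispersion_table` with columns gene_id, p10,
#'   p90, pcsd, n_samples.
#' @export
dispersion_table <- function(expr, method = c("decile", "cv")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (any(expr < 0, na.rm = TRUE)) stop_arg("expression must be nonnegative")
  rows <- lapply(seq_len(nrow(expr)), function(i)
    decile_stats(expr[i, ], method = method))
  out <- do.call(rbind, rows)
  out <- data.frame(gene_id = rownames(expr) %||%
                      as.character(seq_len(nrow(expr))),
                    out, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("dispersion_table", "data.frame")
  out
}

#' Bimodality filter on a dispersion table
#'
#' Flags genes with high population dispersion (`pcsd > pcsd_min`) that are
#' also expressed in the tissue (`p90 > p90_min` RPKM). Both inequalities are
#' strict. Adds logical columns `passes_pcsd`, `passes_expression` and
#' `bimodal` (their conjunction).
#'
#' @param records a [dispersion_table()].
#' @param pcsd_min percent-SD threshold (default 45).
#' @param p90_min top-decile mean expression threshold in RPKM (default 3).
#' @return the table with the three flag columns filled in.
#' @seealso [bimodal_genes()]
#' @export
bimodal_filter <- function(records, pcsd_min = 45, p90_min = 3) {
  records$passes_pcsd <- records$pcsd > pcsd_min
  records$passes_expression <- records$p90 > p90_min
  records$bimodal <- records$passes_pcsd & records$passes_expression
  records
}

#' Genes passing the bimodality filter
#'
#' @inheritParams bimodal_filter
#' @return character vector of passing gene ids.
#' @export
bimodal_genes <- function(records, pcsd_min = 45, p90_min = 3) {
  flagged <- bimodal_filter(records, pcsd_min, p90_min)
  flagged$gene_id[flagged$bimodal]
}

#' Rank genes by dispersion
#'
#' Orders a dispersion table by descending pcsd, breaking ties by descending
#' p90 and then by gene id, so the ranking is a deterministic total order.
#'
#' @param records a [dispersion_table()].
#' @return the table reordered, with a `rank` column added.
#' @export
rank_by_pcsd <- function(records) {
  ord <- order(-records$pcsd, -records$p90, records$gene_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA for environment (planting-year) effects
#'
#' Tests whether a gene's expression differs between planting years, computed
#' directly from between- and within-group sums of squares: with k groups and
#' n values, `F = (SSB/(k-1)) / (SSW/(n-k))` and p from the F distribution.
#'
#' @param values numeric response (e.g. one gene's RPKM across RILs).
#' @param groups group labels (e.g. planting year), coerced to factor.
#' @return list of class `anova1` with ss_between, ss_within, df, F and p.
#' @export
year_effect_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) stop_arg("need >= 2 groups")
  n_g <- tabulate(groups)
  if (any(n_g < 2)) stop_arg("every group needs >= 2 values")
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(n_g * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(ss_between = ssb, ss_within = ssw, df = c(df1, df2),
                 F = f, p = p, group_means = means, n = n_g),
            class = "anova1")
}

#' @export
print.anova1 <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Read an expression TSV (genes in rows, samples in columns)
#'
#' @param path TSV with a leading `gene_id` column.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a dispersion table as TSV
#'
#' Columns gene_id, p10, p90, pcsd and, when present, the filter flags.
#'
#' @param records a [dispersion_table()].
#' @param path output path.
#' @export
write_dispersion_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dispersion TSV written by [write_dispersion_tsv()]
#' @param path input path.
#' @return a `dispersion_table`.
#' @export
read_dispersion_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("dispersion_table", "data.frame")
  out
}
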