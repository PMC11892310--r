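#' Stratify lines by genotype at two loci
#'
#' Builds the 2x2 homozygous design for the two-locus epistasis test: lines
#' heterozygous or missing at either locus are excluded (and counted), the
#' rest are keyed by (A, D) in {REF/REF, REF/ALT, ALT/REF, ALT/ALT} where REF
#' means homozygous reference (0/0) and ALT homozygous alternative (1/1).
#'
#' @param geno_a,geno_d named dosage vectors (0/1/2, NA missing) at the two
#'   loci; names are line ids.
#' @param phenotype data.frame with columns `ril_id` and `value` (or a named
#'   numeric vector).
#' @return data.frame of class `two_locus_design` with columns ril_id, A, D
#'   (factors REF/ALT), class, value; attributes `n_excluded_het` and
#'   `n_excluded_missing`.
#' @export
stratify <- function(geno_a, geno_d, phenotype) {
  if (is.data.frame(phenotype)) {
    ph <- stats::setNames(phenotype$value, phenotype$ril_id)
  } else ph <- phenotype
  ids <- intersect(intersect(names(geno_a), names(geno_d)), names(ph))
  if (!length(ids)) stop_arg("no line ids shared across inputs")
  a <- geno_a[ids]; d <- geno_d[ids]; y <- ph[ids]
  miss <- is.na(a) | is.na(d) | is.na(y)
  het <- !miss & (a == 1L | d == 1L)
  keep <- !miss & !het
  if (!any(keep)) stop_arg("no line is homozygous at both loci")
  lev <- c("REF", "ALT")
  out <- data.frame(ril_id = ids[keep],
                    A = factor(ifelse(a[keep] == 2L, "ALT", "REF"), lev),
                    D = factor(ifelse(d[keep] == 2L, "ALT", "REF"), lev),
                    value = as.numeric(y[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$class <- paste(out$A, out$D, sep = "/")
  attr(out, "n_excluded_het") <- sum(het)
  attr(out, "n_excluded_missing") <- sum(miss)
  class(out) <- c("two_locus_design", "data.frame")
  out
}

class_table <- function(design, value = design$value) {
  agg <- stats::aggregate(value, list(class = design$class),
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  out <- data.frame(class = agg$class, n = agg$x[, "n"],
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  ord <- c("REF/REF", "REF/ALT", "ALT/REF", "ALT/ALT")
  out[order(match(out$class, ord)), , drop = FALSE]
}

#' Two-way ANOVA for additive epistasis
#'
#' Fits `value ~ A * D` on the 2x2 homozygous design and reports the term
#' table with Type II sums of squares (robust to the unequal cell sizes of
#' RIL data), together with per-class phenotype summaries. Under pure
#' additivity the interaction sum of squares vanishes; a significant A x D
#' term would indicate non-additive epistasis.
#'
#' @param design a [stratify()] result.
#' @return object of class `epistasis_fit`: list with `lm` (the underlying
#'   fit), `anova` (term table: sum_sq, df, F, p), `groups` (per-class n,
#'   mean, sd), `coef` (effect estimates with standard errors:
#'   intercept = REF/REF mean, A and D main effects, A:D interaction).
#' @export
epistasis_anova <- function(design) {
  tab <- table(design$A, design$D)
  if (sum(tab >= 2) < 3)
    stop_arg("need >= 2 lines in at least 3 of the 4 genotype classes")
  interaction_ok <- all(tab > 0)
  fit <- if (interaction_ok) stats::lm(value ~ A * D, data = design)
         else stats::lm(value ~ A + D, data = design)
  an <- anova_type2_2x2(design)
  # a noiseless design fits perfectly; the SS table stays exact
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(lm = fit, anova = an, groups = class_table(design),
                 coef = cf, n = nrow(design),
                 n_excluded_het = attr(design, "n_excluded_het")),
            class = "epistasis_fit")
}

# Type II sums of squares on the 2x2 design by model comparison:
# SS(A | D) = RSS(~D) - RSS(~A+D), SS(D | A) likewise,
# SS(A:D | A,D) = RSS(~A+D) - RSS(~A*D); F against the full-model residual.
# With an empty cell the interaction is not estimable and its row is NA;
# with a zero residual (noiseless input) F and p are NA but the sums of
# squares remain exact.
anova_type2_2x2 <- function(design) {
  rss <- function(form) {
    f <- stats::lm(form, data = design)
    c(rss = sum(stats::residuals(f)^2), rank = f$rank)
  }
  m_a <- rss(value ~ A); m_d <- rss(value ~ D)
  m_ad <- rss(value ~ A + D); m_full <- rss(value ~ A * D)
  n <- nrow(design)
  ss <- c(A = max(0, m_d["rss"] - m_ad["rss"]),
          D = max(0, m_a["rss"] - m_ad["rss"]),
          `A:D` = max(0, m_ad["rss"] - m_full["rss"]))
  df <- c(A = 1, D = 1, `A:D` = m_full["rank"] - m_ad["rank"])
  df_res <- n - m_full["rank"]
  ms_res <- if (df_res > 0) m_full["rss"] / df_res else NA_real_
  f <- ifelse(df > 0, (ss / pmax(df, 1)) / ms_res, NA_real_)
  if (!is.na(ms_res) && ms_res == 0) f[] <- NA_real_
  p <- ifelse(is.na(f), NA_real_, stats::pf(f, df, df_res, lower.tail = FALSE))
  out <- data.frame(
    term = c("A", "D", "A:D", "Residuals"),
    sum_sq = c(unname(ss), unname(m_full["rss"])),
    df = c(unname(df), unname(df_res)),
    F = c(unname(f), NA), p = c(unname(p), NA),
    stringsAsFactors = FALSE)
  out$sum_sq[out$term == "A:D" & out$df == 0] <- NA
  out
}

#' @export
print.epistasis_fit <- function(x, ...) {
  cat("Two-locus additive epistasis ANOVA (n =", x$n, "homozygous lines)\n\n")
  print(transform(x$anova, sum_sq = signif(sum_sq, 5), F = signif(F, 5),
                  p = signif(p, 4)), row.names = FALSE)
  cat("\nGenotype classes (A/D):\n")
  print(transform(x$groups, mean = signif(mean, 5), sd = signif(sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.epistasis_fit <- function(object, ...) {
  cat("Effect estimates (dummy coding, REF/REF baseline):\n")
  print(signif(object$coef, 5))
  invisible(print(object))
}

#' @export
coef.epistasis_fit <- function(object, ...) stats::coef(object$lm)

#' Pairwise contrasts against the best genotype class
#'
#' Welch two-sample t-tests of every genotype class against the class with
#' the highest phenotype mean, reporting t, df, p and the finest of the
#' supplied alpha levels each comparison passes (the presentation used for
#' stating, e.g., that losing one ALT allele costs significance at p < 0.01
#' and losing the other at p < 0.001).
#'
#' @param design a [stratify()] result.
#' @param alpha_levels significance levels to annotate (finest reported).
#' @return data.frame with class, n, mean, t, df, p, `sig` (the smallest
#'   alpha passed as a character, or "ns"); attribute `best_class`.
#' @export
contrasts_vs_best <- function(design, alpha_levels = c(0.01, 0.001)) {
  gr <- class_table(design)
  gr_ok <- gr[gr$n >= 2, , drop = FALSE]
  if (!nrow(gr_ok)) stop_arg("no genotype class with n >= 2")
  best <- gr_ok$class[which.max(gr_ok$mean)]
  ybest <- design$value[design$class == best]
  others <- gr$class[gr$class != best]
  rows <- lapply(others, function(cl) {
    y <- design$value[design$class == cl]
    if (length(y) < 2) {
      warning("class ", cl, " has a single line; comparison skipped",
              call. = FALSE)
      return(data.frame(class = cl, n = length(y), mean = mean(y),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        sig = NA_character_, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(y, ybest)
    passed <- sort(alpha_levels[tt$p.value < alpha_levels])
    data.frame(class = cl, n = length(y), mean = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               sig = if (length(passed)) paste0("p<", passed[1]) else "ns",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_class") <- best
  out
}

#' Candidate-gene expression by genotype class
#'
#' For each candidate gene, summarizes expression per 2x2 genotype class and
#' runs a two-way (Type II) ANOVA of expression on the two loci — the check
#' that each gene's transcript abundance tracks its own locus without a
#' significant effect of the other locus or of the combination.
#'
#' @param design a [stratify()] result.
#' @param expr genes x samples expression matrix (RPKM) whose columns cover
#'   the design's line ids.
#' @param gene_ids genes (rows of `expr`) to summarize.
#' @return named list, one element per gene: list with `groups` (per-class n,
#'   mean, sd of expression) and `anova` (term table from `value ~ A * D` on
#'   expression).
#' @export
genotype_expression_summary <- function(design, expr, gene_ids) {
  missing_genes <- setdiff(gene_ids, rownames(expr))
  if (length(missing_genes))
    stop_arg("genes not in expression matrix: ",
             paste(missing_genes, collapse = ", "))
  ids <- intersect(design$ril_id, colnames(expr))
  if (!length(ids)) stop_arg("no design line has expression data")
  d <- design[design$ril_id %in% ids, , drop = FALSE]
  out <- lapply(gene_ids, function(g) {
    d$value <- as.numeric(expr[g, d$ril_id])
    list(groups = class_table(d), anova = anova_type2_2x2(d))
  })
  stats::setNames(out, gene_ids)
}
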