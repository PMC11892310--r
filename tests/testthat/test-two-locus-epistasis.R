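make_design <- function(n_per = 20, mu = 30, ba = 2, bd = 1, bi = 0,
                        sigma = 0, seed = 1) {
  set.seed(seed)
  cls <- expand.grid(A = c("REF", "ALT"), D = c("REF", "ALT"))
  d <- do.call(rbind, lapply(seq_len(nrow(cls)), function(i)
    data.frame(A = cls$A[i], D = cls$D[i],
               value = mu + ba * (cls$A[i] == "ALT") +
                 bd * (cls$D[i] == "ALT") +
                 bi * (cls$A[i] == "ALT" && cls$D[i] == "ALT") +
                 rnorm(n_per, 0, sigma))))
  d$A <- factor(d$A, c("REF", "ALT")); d$D <- factor(d$D, c("REF", "ALT"))
  d$ril_id <- sprintf("R%03d", seq_len(nrow(d)))
  d$class <- paste(d$A, d$D, sep = "/")
  class(d) <- c("two_locus_design", "data.frame")
  d
}

test_that("stratify excludes het/missing lines and keys the four classes", {
  ga <- c(r1 = 0L, r2 = 2L, r3 = 1L, r4 = 2L, r5 = NA_integer_, r6 = 0L)
  gd <- c(r1 = 0L, r2 = 2L, r3 = 0L, r4 = 0L, r5 = 2L, r6 = 2L)
  ph <- data.frame(ril_id = names(ga), trait = "STR", value = 1:6)
  d <- stratify(ga, gd, ph)
  expect_equal(nrow(d), 4)                   # r3 het, r5 missing
  expect_equal(attr(d, "n_excluded_het"), 1)
  expect_equal(attr(d, "n_excluded_missing"), 1)
  expect_setequal(d$class, c("REF/REF", "ALT/ALT", "ALT/REF", "REF/ALT"))
  expect_equal(sum(table(d$class)), nrow(d))
  expect_error(stratify(ga, gd, data.frame(ril_id = "zz", value = 1)),
               "shared")
  expect_error(stratify(c(x = 1L), c(x = 1L),
                        data.frame(ril_id = "x", value = 1)),
               "homozygous")
})

test_that("stratified class sizes match generator truth", {
  sim <- simulate_magic(small_config(seed = 71))
  g <- sim$genotypes
  dr <- sim$panel$drivers
  d <- stratify(setNames(g[, dr["A"]], rownames(g)),
                setNames(g[, dr["D"]], rownames(g)), sim$phenotype)
  a <- g[, dr["A"]]; dd <- g[, dr["D"]]
  keep <- a %in% c(0, 2) & dd %in% c(0, 2)
  expect_equal(nrow(d), sum(keep))
  expect_equal(sum(d$class == "ALT/ALT"), sum(a == 2 & dd == 2))
  expect_equal(attr(d, "n_excluded_het"), sum(!keep))
})

test_that("noiseless additive data gives zero interaction sum of squares", {
  d <- make_design(sigma = 0)
  fit <- epistasis_anova(d)
  expect_equal(fit$anova$sum_sq[fit$anova$term == "A:D"], 0,
               tolerance = 1e-20)
  expect_equal(fit$groups$mean, c(30, 31, 32, 33))
  # recovered effects are exact
  cf <- coef(fit)
  expect_equal(unname(cf["AALT"]), 2, tolerance = 1e-12)
  expect_equal(unname(cf["DALT"]), 1, tolerance = 1e-12)
})

test_that("Type I and Type II sums of squares coincide on balanced designs", {
  d <- make_design(sigma = 1, seed = 3)
  fit <- epistasis_anova(d)
  t1 <- anova(lm(value ~ A * D, data = d))
  for (tm in c("A", "D", "A:D"))
    expect_equal(fit$anova$sum_sq[fit$anova$term == tm],
                 t1[tm, "Sum Sq"], tolerance = 1e-10)
  # SS decomposition: terms + residual = total (balanced case)
  tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(fit$anova$sum_sq), tot, tolerance = 1e-8)
})

test_that("Type II sums of squares match car::Anova on unbalanced data", {
  d <- make_design(n_per = 30, sigma = 1, seed = 8)
  d <- d[-c(1:7, 40:44), ]                     # unbalance the cells
  fit <- epistasis_anova(d)
  ref <- car::Anova(lm(value ~ A * D, data = d), type = 2)
  for (tm in c("A", "D", "A:D")) {
    expect_equal(fit$anova$sum_sq[fit$anova$term == tm],
                 ref[tm, "Sum Sq"], tolerance = 1e-10)
    expect_equal(fit$anova$p[fit$anova$term == tm],
                 ref[tm, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("adding a constant to the phenotype changes no F or p", {
  d <- make_design(sigma = 1, seed = 4)
  d2 <- d; d2$value <- d2$value + 1000
  f1 <- epistasis_anova(d)$anova
  f2 <- epistasis_anova(d2)$anova
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
})

test_that("simulated effects are recovered within three standard errors", {
  cfg <- sim_config(n_rils = 550, loci_per_chromosome = 50, n_genes = 50,
                    beta_a = 2, beta_d = 1, beta_interact = 0,
                    pheno_sigma = 1, seed = 17)
  sim <- simulate_magic(cfg)
  g <- sim$genotypes; dr <- sim$panel$drivers
  d <- stratify(setNames(g[, dr["A"]], rownames(g)),
                setNames(g[, dr["D"]], rownames(g)), sim$phenotype)
  fit <- epistasis_anova(d)
  cf <- fit$coef
  expect_lt(abs(cf["AALT", "Estimate"] - 2), 3 * cf["AALT", "Std. Error"])
  expect_lt(abs(cf["DALT", "Estimate"] - 1), 3 * cf["DALT", "Std. Error"])
  expect_gt(fit$anova$p[fit$anova$term == "A:D"], 0.05)
})

test_that("contrasts against the best class flag the stated alpha levels", {
  # 3 sigma mean gaps at n = 50 per class: everything beyond p < 0.001
  d <- make_design(n_per = 50, ba = 3, bd = 3, sigma = 1, seed = 5)
  ct <- contrasts_vs_best(d)
  expect_equal(attr(ct, "best_class"), "ALT/ALT")
  expect_equal(nrow(ct), 3)                  # best class excluded
  expect_true(all(ct$sig == "p<0.001"))
  # identical distributions: not significant
  d0 <- make_design(n_per = 30, ba = 0, bd = 0, sigma = 1, seed = 6)
  ct0 <- contrasts_vs_best(d0)
  expect_true(all(ct0$p > 1e-4))
  # singleton class is skipped with a warning
  d1 <- make_design(n_per = 5, sigma = 1, seed = 7)
  d1 <- d1[-which(d1$class == "REF/ALT")[-1], ]
  expect_warning(ct1 <- contrasts_vs_best(d1), "single")
  expect_true(is.na(ct1$p[ct1$class == "REF/ALT"]))
})

test_that("per-gene expression ANOVA attributes each gene to its own locus", {
  cfg <- sim_config(n_rils = 550, loci_per_chromosome = 50, n_genes = 60,
                    eqtl_fold = 6, noise_cv = 0.2, seed = 23)
  sim <- simulate_magic(cfg)
  g <- sim$genotypes; dr <- sim$panel$drivers
  d <- stratify(setNames(g[, dr["A"]], rownames(g)),
                setNames(g[, dr["D"]], rownames(g)), sim$phenotype)
  dg <- sim$genes$driver_genes
  gs <- genotype_expression_summary(d, sim$expr$dpa16, unname(dg))
  # gene driven by locus A responds to A, not to D or the interaction
  anA <- gs[[dg[["A"]]]]$anova
  expect_lt(anA$p[anA$term == "A"], 1e-10)
  expect_gt(anA$p[anA$term == "D"], 0.001)
  anD <- gs[[dg[["D"]]]]$anova
  expect_lt(anD$p[anD$term == "D"], 1e-10)
  expect_gt(anD$p[anD$term == "A"], 0.001)
  # class means recover the generator's expected fold structure
  grA <- gs[[dg[["A"]]]]$groups
  base <- sim$genes$baseline[dg[["A"]]]
  hi <- grA$mean[grA$class %in% c("ALT/REF", "ALT/ALT")]
  lo <- grA$mean[grA$class %in% c("REF/REF", "REF/ALT")]
  expect_equal(mean(hi) / mean(lo), cfg$eqtl_fold, tolerance = 0.15)
  expect_equal(mean(lo), unname(base), tolerance = 0.15)
  expect_error(genotype_expression_summary(d, sim$expr$dpa16, "nope"),
               "not in expression")
})
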