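# Screen statistics: aggregation, normalization, testing, FDR, validation.

test_that("aggregation pools cells within condition and experiment", {
  per_cell <- data.frame(
    gene = rep(c("A", "Scrambled"), each = 6),
    sirna = rep(c("#1", "ctrl"), each = 6),
    experiment = rep(c(1, 1, 2, 2, 1, 2), 2),
    field = rep(c(1, 2, 1, 2, 3, 3), 2),
    circularity = c(0.2, 0.4, 0.6, 0.2, 0.6, 0.4, rep(0.5, 6)))
  agg <- aggregate_condition(per_cell)
  expect_equal(nrow(agg), 4)
  a1 <- agg[agg$gene == "A" & agg$experiment == 1, ]
  expect_equal(a1$mean_circularity, mean(c(0.2, 0.4, 0.6)))
  expect_equal(a1$n_cells, 3)
  # pre-aggregated input passes through
  expect_equal(aggregate_condition(agg)$mean_circularity,
               agg$mean_circularity)
  # missing control is an error naming the experiment
  expect_error(aggregate_condition(per_cell[per_cell$experiment == 1 |
                                              per_cell$gene == "A", ]),
               "experiment 2")
})

test_that("normalization maps controls to zero and removes batch factors", {
  tbl <- flat_screen_table(value = 0.5)
  tbl$mean_circularity[tbl$gene == "g01"] <- 1.0   # 2x control
  norm <- normalize_experiment(tbl)
  expect_true(all(norm$log2_norm[norm$gene == "Scrambled"] == 0))
  expect_true(all(norm$log2_norm[norm$gene == "g01"] == 1))
  expect_true(all(norm$log2_norm[!norm$gene %in% c("g01", "Scrambled")] == 0))
  # multiplicative batch factor per experiment cancels
  set.seed(1)
  tbl2 <- tbl
  for (e in unique(tbl2$experiment)) {
    b <- runif(1, 0.2, 5)
    sel <- tbl2$experiment == e
    tbl2$mean_circularity[sel] <- tbl2$mean_circularity[sel] * b
  }
  expect_equal(normalize_experiment(tbl2)$log2_norm, norm$log2_norm,
               tolerance = 1e-12)
  expect_error(normalize_experiment(transform(tbl, mean_circularity = 0)),
               "positive")
})

test_that("moderated t matches the literal-formula transcription", {
  set.seed(11)
  for (rep in 1:25) {
    n_cond <- sample(8:30, 1)
    mat <- matrix(rnorm(n_cond * 3, 0, exp(rnorm(1))), n_cond, 3)
    norm <- data.frame(gene = rep(sprintf("g%02d", 1:n_cond), each = 3),
                       sirna = "#1",
                       experiment = rep(1:3, n_cond),
                       log2_norm = c(t(mat)))
    # control rows are required by the interface; add exact zeros
    norm <- rbind(norm, data.frame(gene = "Scrambled", sirna = "ctrl",
                                   experiment = 1:3, log2_norm = 0))
    res <- differential_test(norm, stats_config())
    oracle <- naive_moderated_t(mat)
    r <- res[res$gene != "Scrambled", ]
    r <- r[order(as.integer(sub("g", "", r$gene))), ]
    expect_equal(attr(res, "prior")$d0, oracle$d0, tolerance = 1e-10)
    expect_equal(r$diff_circularity, oracle$diff, tolerance = 1e-12)
    expect_equal(r$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("prior df fixed at 0 reduces the moderated t to Student t", {
  set.seed(2)
  mat <- matrix(rnorm(60), 20, 3)
  norm <- data.frame(gene = rep(sprintf("g%02d", 1:20), each = 3),
                     sirna = "#1", experiment = rep(1:3, 20),
                     log2_norm = c(t(mat)))
  norm <- rbind(norm, data.frame(gene = "Scrambled", sirna = "ctrl",
                                 experiment = 1:3, log2_norm = 0))
  mod <- differential_test(norm, stats_config(prior_df = 0))
  stu <- differential_test(norm, stats_config(test = "student_t"))
  expect_equal(mod$p_value, stu$p_value, tolerance = 1e-12)
})

test_that("moderated-t prior agrees with limma's variance shrinkage", {
  set.seed(3)
  # genuinely heterogeneous variances drawn from the scaled-F model:
  # sigma_g^2 ~ s0*d0/chisq(d0), s_g^2 ~ sigma_g^2 * chisq(dg)/dg
  d0_true <- 5; dg <- 2
  sigma2 <- 0.2 * d0_true / rchisq(300, d0_true)
  s2 <- sigma2 * rchisq(300, dg) / dg
  fit <- microscreen:::fit_variance_prior(s2, rep(dg, 300))
  sq <- limma::squeezeVar(s2, df = dg)
  expect_false(fit$fallback)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, sq$var.prior, tolerance = 1e-6)

  # homogeneous variances: limma uses an infinite prior df, this package
  # documents a fixed fallback of 4
  s2_flat <- exp(rnorm(200, -2, 0.3))
  fit2 <- microscreen:::fit_variance_prior(s2_flat, rep(dg, 200))
  expect_true(fit2$fallback)
  expect_equal(fit2$d0, 4)
  expect_equal(limma::squeezeVar(s2_flat, df = dg)$df.prior, Inf)
})

test_that("degenerate variance cases behave as documented", {
  norm <- data.frame(gene = rep(c("A", "B"), each = 3), sirna = "#1",
                     experiment = rep(1:3, 2),
                     log2_norm = c(0, 0, 0, 0.1, 0.5, 0.9))
  norm <- rbind(norm, data.frame(gene = "Scrambled", sirna = "ctrl",
                                 experiment = 1:3, log2_norm = 0))
  expect_error(differential_test(norm, stats_config(test = "student_t")),
               "moderated_t")
  res <- differential_test(norm, stats_config())
  a <- res[res$gene == "A", ]
  expect_equal(a$diff_circularity, 0)
  expect_gt(a$p_value, 0.99)
  # fewer than 2 experiments is an error
  expect_error(differential_test(norm[norm$experiment == 1 |
                                        norm$gene == "Scrambled", ]),
               "at least 2")
})

test_that("BH adjustment matches hand computation and the naive oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_fdr(0.37), 0.37)
  set.seed(8)
  for (i in 1:5) {
    p <- runif(100)^sample(1:3, 1)
    expect_equal(adjust_fdr(p), naive_bh(p), tolerance = 1e-12)
    expect_equal(adjust_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(adjust_fdr(runif(20)) >= runif(0)))
})

test_that("hit classes follow the sign/FDR rule from the validation table", {
  res <- data.frame(gene = c("Tiam1", "MEK3", "JNK2"),
                    sirna = c("#1", "#2", "#1"),
                    diff_circularity = c(2.73, 0.58, -0.11),
                    p_value = c(1e-16, 0.05, 0.70),
                    fdr = c(1e-14, 0.07, 0.75))
  out <- classify_hits(res, stats_config())
  expect_equal(out$hit_class,
               c("positive", "not_significant", "not_significant"))
})

test_that("gene validation needs two concordant significant siRNAs", {
  mk <- function(gene, diffs, fdrs) data.frame(
    gene = gene, sirna = sprintf("#%d", seq_along(diffs)),
    diff_circularity = diffs, p_value = fdrs, fdr = fdrs)
  res <- rbind(mk("RhoE", c(1.93, 1.15, 0.73), c(1e-8, 0.004, 0.04)),
               mk("MEK3", c(0.58, -0.32, 0.16), c(0.07, 0.35, 0.64)),
               mk("JNK2", c(-0.11, -0.08, 1.08), c(0.75, 0.82, 0.004)),
               mk("Mixed", c(2.0, -2.0, 0.1), c(0.001, 0.001, 0.9)))
  out <- validate_gene(classify_hits(res, stats_config()), stats_config())
  expect_equal(out$status[out$gene == "RhoE"], "validated")
  expect_equal(out$status[out$gene == "MEK3"], "false_positive")
  expect_equal(out$status[out$gene == "JNK2"], "false_positive")
  # two significant but discordant siRNAs do not validate
  expect_equal(out$status[out$gene == "Mixed"], "false_positive")
  expect_error(validate_gene(classify_hits(mk("solo", 1, 0.01),
                                           stats_config()), stats_config()),
               "fewer than 2")
})
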