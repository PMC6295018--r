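# Synthetic-data generators: fields, screen tables, scratch pairs, Ct tables.

test_that("noiseless disk fields have exact ground truth", {
  specs <- lapply(1:3, function(i) shape_spec("disk", 10))
  fld <- generate_field(specs, c(120, 120), n_border = 0, noise_sd = 0,
                        seed = 1)
  expect_equal(max(fld$labels), 3)
  expect_equal(fld$truth$circularity, rep(1, 3))
  expect_equal(fld$n_border, 0)
  expect_setequal(unique(c(fld$image)), c(30, 200))
})

test_that("border placement yields the requested interior/border split", {
  specs <- lapply(1:5, function(i) shape_spec("disk", 10))
  fld <- generate_field(specs, c(150, 150), n_border = 2, noise_sd = 0,
                        seed = 4)
  expect_equal(fld$n_interior, 3)
  expect_equal(sum(fld$truth$border), 2)
  # border cells must actually touch an edge; interior ones must not
  for (k in seq_len(5)) {
    px <- which(fld$labels == k, arr.ind = TRUE)
    touches <- any(px[, 1] %in% c(1, 150) | px[, 2] %in% c(1, 150))
    expect_equal(touches, fld$truth$border[k])
  }
})

test_that("field generation is deterministic under a fixed seed", {
  specs <- lapply(1:10, function(i) shape_spec("ellipse", 8, aspect_ratio = 4))
  f1 <- generate_field(specs, c(200, 200), noise_sd = 5, seed = 7)
  f2 <- generate_field(specs, c(200, 200), noise_sd = 5, seed = 7)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$labels, f2$labels)
})

test_that("infeasible density fails loudly", {
  specs <- lapply(1:40, function(i) shape_spec("disk", 15))
  expect_error(generate_field(specs, c(100, 100), seed = 1, max_tries = 25),
               "could not place")
})

test_that("screen tables have the full design grid and exact null values", {
  des <- screen_design(n_genes = 157, noise_sd = 0, seed = 1)
  tbl <- generate_screen_tables(des)
  expect_equal(nrow(tbl), 157 * 3 * 3 + 3)
  expect_true(all(tbl$mean_circularity == des$control_mean))

  des2 <- screen_design(n_genes = 5, effect_map = c(gene001 = 1),
                        noise_sd = 0, seed = 1)
  tbl2 <- generate_screen_tables(des2)
  expect_true(all(tbl2$mean_circularity[tbl2$gene == "gene001"] ==
                    2 * des2$control_mean))
  expect_true(all(tbl2$mean_circularity[tbl2$gene != "gene001"] ==
                    des2$control_mean))
})

test_that("screen design rejects unknown genes and non-zero control effect", {
  expect_error(screen_design(n_genes = 3, effect_map = c(nope = 1)),
               "unknown genes")
  expect_error(screen_design(n_genes = 3,
                             effect_map = stats::setNames(1, "Scrambled")),
               "control")
})

test_that("scratch pairs encode the requested widths deterministically", {
  p <- generate_scratch_pair(400, 100, seed = 3)
  expect_equal(p$truth$closure_percent, 25)
  p2 <- generate_scratch_pair(400, 100, seed = 3)
  expect_identical(p$t1, p2$t1)
  expect_identical(p$t24, p2$t24)
  closed <- generate_scratch_pair(300, 0, seed = 5)
  # no band: the t24 image is pure lawn texture (no constant-ish stripe)
  expect_gt(min(apply(closed$t24, 2, stats::sd)), 10)
  expect_error(generate_scratch_pair(100, 200), "cannot widen")
  expect_error(generate_scratch_pair(-5, -10), "non-negative")
})

test_that("Ct tables encode folds on the cycle scale", {
  tb <- generate_ct_table(c(A = 0.25), base_ct = 24, noise_sd = 0, seed = 1)
  expect_true(all(tb$ct[tb$sample == "A" & tb$gene == "BDNF"] == 26))
  expect_true(all(tb$ct[tb$gene == "GAPDH"] == 18))
  expect_error(generate_ct_table(c(A = -1)), "positive")
  # fold 1 recovers exactly 1
  tb1 <- generate_ct_table(c(A = 1), noise_sd = 0)
  res <- delta_delta_ct(tb1)
  expect_equal(res$fold_change[res$sample == "A"], 1)
})

test_that("noisy Ct recovery is unbiased over many seeds", {
  folds <- vapply(1:200, function(s) {
    tb <- generate_ct_table(c(A = 0.5), noise_sd = 0.1, seed = 10000 + s)
    res <- delta_delta_ct(tb)
    res$fold_change[res$sample == "A"]
  }, numeric(1))
  expect_equal(mean(folds), 0.5, tolerance = 0.02)
})

test_that("all-null screens recover effects with mean near zero", {
  means <- vapply(1:20, function(s) {
    des <- screen_design(n_genes = 157, seed = 20000 + s)
    b <- run_screen(aggregated = generate_screen_tables(des))
    r <- b$results[b$results$gene != "Scrambled", ]
    mean(r$diff_circularity)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * 0.3 / sqrt(3 * 157))
})
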