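test_that("ground truth respects config degeneracies and determinism", {
  cfg0 <- sim_config(n_variants = 40, loop_lengths = 5, sigma_dna = 0,
                     prob_switch = 0, seed = 101)
  gt <- simulate_ground_truth(cfg0)
  lib <- gt[!gt$is_control, ]
  expect_true(all(lib$w == lib$w[1]))             # sigma_dna = 0
  expect_true(all(lib$s == 0))                    # prob_switch = 0
  expect_equal(lib$f1, lib$f0)
  expect_true(all(gt$true_ar == 1))
  expect_identical(anyDuplicated(gt$variant), 0L)
  expect_true(all(gt$f0 > 0 & gt$f0 <= 1 & gt$f1 >= gt$f0 & gt$f1 <= 1))

  gt2 <- simulate_ground_truth(cfg0)
  expect_identical(gt, gt2)                       # bit-identical under seed
  expect_error(sim_config(n_variants = 10), "seed")
})

test_that("switching strengths keep f0 <= f1 <= 1 and AR >= 1", {
  cfg <- sim_config(n_variants = 300, loop_lengths = 5, prob_switch = 0.5,
                    seed = 103)
  gt <- simulate_ground_truth(cfg)
  expect_true(all(gt$f1 >= gt$f0 - 1e-12))
  expect_true(all(gt$f1 <= 1 + 1e-12))
  expect_true(all(gt$true_ar >= 1 - 1e-12))
  expect_true(any(gt$s > 0))
})

test_that("expected counts reproduce RD = 100 f / f_ctl and AR = f1/f0 exactly", {
  cfg <- sim_config(n_variants = 60, loop_lengths = 5, prob_switch = 0.5,
                    depth_dna = 1e5, depth_rna = 1e5, seed = 105)
  gt <- simulate_ground_truth(cfg)
  ct <- simulate_counts(gt, cfg, expected = TRUE)
  act <- quantify_activity(ct)
  i <- match(act$variant, gt$variant)
  expect_equal(act$rd_minus, 100 * gt$f0[i] / 1, tolerance = 1e-9)
  expect_equal(act$rd_plus, 100 * gt$f1[i], tolerance = 1e-9)
  expect_equal(act$ar, gt$true_ar[i], tolerance = 1e-9)
})

test_that("sampled counts conserve configured depth and are seeded", {
  cfg <- sim_config(n_variants = 50, loop_lengths = 5, depth_dna = 2e4,
                    depth_rna = 3e4, seed = 107)
  gt <- simulate_ground_truth(cfg)
  ct <- simulate_counts(gt, cfg)
  dna_cols <- ct$coldata$assay == "DNA"
  expect_true(all(colSums(ct$counts[, dna_cols]) == 2e4))
  expect_true(all(colSums(ct$counts[, !dna_cols]) == 3e4))
  expect_identical(simulate_counts(gt, cfg)$counts, ct$counts)
})

test_that("read simulation round-trips counts exactly at zero error rate", {
  cfg <- sim_config(n_variants = 12, loop_lengths = 5, depth_dna = 400,
                    depth_rna = 400, replicates = 1, seed = 109)
  gt <- simulate_ground_truth(cfg)
  ct <- simulate_counts(gt, cfg)
  tpl <- tiny_template()
  labels <- colnames(ct$counts)
  bases <- c("AACCGG", "CCGGTT", "GGTTAA", "TTAACC")
  bc <- stats::setNames(labels, bases[seq_along(labels)])
  reads <- simulate_reads(ct, tpl, bc, error_rate = 0, seed = 1)
  back <- count_reads(reads, tpl, tiny_controls(), bc, min_dna = 0)
  common <- intersect(rownames(back$counts), rownames(ct$counts))
  expect_identical(back$counts[rownames(ct$counts), colnames(ct$counts)],
                   ct$counts)
})

test_that("read errors degrade architecture matching as (1-e)^len", {
  cfg <- sim_config(n_variants = 10, loop_lengths = 5, depth_dna = 1000,
                    depth_rna = 1000, replicates = 1,
                    controls = default_sim_controls()[1, ], seed = 111)
  gt <- simulate_ground_truth(cfg)
  ct <- simulate_counts(gt, cfg)
  tpl <- tiny_template()
  keep <- "RNA.minus.1"
  ct1 <- count_table(ct$counts[, keep, drop = FALSE],
                     ct$coldata[match(keep, colnames(ct$counts)), ],
                     ct$is_control)
  bc <- stats::setNames(keep, "AACCGG")

  reads <- simulate_reads(ct1, tpl, bc, error_rate = 0.01, seed = 2)
  back <- count_reads(reads, tpl, tiny_controls(), bc, min_dna = 0)
  matched_frac <- attr(back, "run_metrics")$n_counted / length(reads)
  # a library read survives iff barcode (6 nt) and the full rendered
  # architecture come through intact; loop errors still match (as another
  # variant), so the fraction sits slightly above (1-e)^read_length
  read_len <- 6L + nchar(render_variant(tpl, "AAAAA"))
  exp_frac <- (1 - 0.01)^read_len
  expect_gt(matched_frac, exp_frac - 0.03)
  expect_lt(matched_frac, exp_frac + 0.05)

  # error rate 1 destroys nearly every architecture match
  reads_bad <- simulate_reads(ct1, tpl, bc, error_rate = 1, seed = 3)
  back_bad <- count_reads(reads_bad, tpl, tiny_controls(), bc, min_dna = 0)
  expect_lt(attr(back_bad, "run_metrics")$n_counted / length(reads_bad), 0.01)
})

test_that("sort simulation: zero cell noise pins each variant to one bin", {
  cfg <- sim_config(n_variants = 20, loop_lengths = 5, sigma_cell = 0,
                    n_cells = 200, seed = 113)
  gt <- simulate_ground_truth(cfg)
  # fixed edges: auto-placed ones sit exactly on the extreme variant's and
  # the control's means (their mass straddles an edge by design)
  bsd <- simulate_facs(gt, cfg, edges = c(-Inf, -1, 0, 0.8, 1.4, 1.9, Inf))
  cells <- t(vapply(rownames(bsd$reads),
                    function(v) estimate_bin_cells(bsd, v),
                    numeric(ncol(bsd$reads))))
  expect_true(all(rowSums(cells > 0) == 1))
})

test_that("auto edges split the non-cleaving control over the top two bins", {
  cfg <- sim_config(n_variants = 100, loop_lengths = 5, n_cells = 4000,
                    seed = 115)
  gt <- simulate_ground_truth(cfg)
  bsd <- simulate_facs(gt, cfg)
  cells <- estimate_bin_cells(bsd, "sTRSVctl")
  B <- length(cells)
  top2 <- cells[c(B - 1, B)]
  expect_gt(sum(top2) / sum(cells), 0.95)
  expect_lt(abs(top2[1] - top2[2]) / sum(top2), 0.1)
})

test_that("end-to-end sort-seq recovery of rfu within 10 percent", {
  cfg <- sim_config(n_variants = 40, loop_lengths = 5, n_cells = 2000,
                    seed = 117)
  gt <- simulate_ground_truth(cfg)
  bsd <- simulate_facs(gt, cfg)
  fits <- fit_facs_bins(bsd)
  ctl <- cfg$controls
  known <- data.frame(name = ctl$name, log10_fluor = log10(100 * ctl$f))
  cal <- calibrate_and_normalize(fits, known)
  i <- match(cal$variant, gt$variant)
  truth_rfu <- 100 * gt$f0[i]
  ok <- cal$n_cells_est >= 2000 * 0.9 & cal$converged &
    !(cal$variant %in% ctl$name)
  rel_err <- abs(cal$rfu - truth_rfu) / truth_rfu
  expect_gt(mean(rel_err[ok] < 0.10), 0.9)
})

test_that("RNA-Seq and FACS-Seq activation ratios agree monotonically", {
  # all-switch library: a block of AR = 1 non-switches would tie-dilute the
  # rank correlation with independent assay noise
  cfg <- sim_config(n_variants = 120, loop_lengths = 5, prob_switch = 1,
                    depth_dna = 5e5, depth_rna = 5e5, n_cells = 2000,
                    seed = 119)
  gt <- simulate_ground_truth(cfg)
  act <- quantify_activity(simulate_counts(gt, cfg))
  minus <- simulate_facs(gt, cfg, "minus")
  plus <- simulate_facs(gt, cfg, "plus", edges = minus$edges)
  fm <- fit_facs_bins(minus); fp <- fit_facs_bins(plus)
  i <- match(fm$variant, fp$variant)
  facs_ar <- 10^(fp$mu[i] - fm$mu)
  j <- match(fm$variant, act$variant)
  ok <- !is.na(j) & !fm$variant %in% cfg$controls$name
  expect_gt(cor(facs_ar[ok], act$ar[j[ok]], method = "spearman"), 0.9)
})
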