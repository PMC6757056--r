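test_that("standardize centers and scales like the brute-force formula", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  set.seed(14)
  x <- rnorm(50, 3, 7)
  expect_equal(standardize(x), (x - mean(x)) / sd(x))
  expect_equal(standardize(standardize(x)), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "distinct")
})

test_that("one-hot encoding uses the A,C,U,G block order", {
  expect_equal(unname(one_hot("A")[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(one_hot("G")[1, ]), c(0, 0, 0, 1))
  expect_equal(unname(one_hot("U")[1, ]), c(0, 0, 1, 0))
  m <- one_hot(c("ACGTA", "TTTTT", "GGGGG"))
  expect_identical(dim(m), c(3L, 20L))
  expect_equal(unname(rowSums(m)), c(5, 5, 5))
  expect_error(one_hot("ANGTA"), "ambiguous")
  expect_error(one_hot("AXGTA"), "invalid")
})

test_that("14-bin assignment obeys the SD cutpoints and partitions", {
  b <- assign_activity_bins(c(-2.5, 1.5, -1.99, -1.75, -2, 1, 0.999))
  expect_identical(b$bin_index, c(1L, 14L, 2L, 3L, 1L, 14L, 13L))
  set.seed(15)
  z <- rnorm(500)
  bi <- assign_activity_bins(z)$bin_index
  expect_true(all(bi >= 1L & bi <= 14L))
  expect_identical(length(bi), 500L)         # every value in exactly one bin
  expect_identical(sum(table(bi)), 500L)
})

test_that("position entropy matches direct computation", {
  pe <- position_entropy(c("AA", "AC", "AG", "AT"))
  expect_equal(unname(pe$entropy), c(0, 2))
  expect_equal(unname(pe$freq[, 2]), rep(0.25, 4))
  # weighted frequencies shift the entropy
  pw <- position_entropy(c("AA", "AG"), weights = c(3, 1))
  expect_equal(unname(pw$entropy[2]),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("mutual information: independence, identity, brute-force oracle", {
  # all 16 ordered pairs once: columns independent and balanced -> MI = 0
  pairs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  expect_equal(mutual_information(pairs)$mi[1, 2], 0)
  # identical uniform columns -> MI = H = 2 bits
  ident <- paste0(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  expect_equal(mutual_information(ident)$mi[1, 2], 2)

  # brute-force double sum on a 6-sequence toy set
  seqs <- c("ACG", "ACG", "ATT", "GCG", "GTT", "GTA")
  res <- mutual_information(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  brute_mi <- function(ci, cj) {
    tot <- 0
    for (X in c("A", "C", "G", "T")) for (Y in c("A", "C", "G", "T")) {
      pij <- mean(ci == X & cj == Y)
      if (pij > 0) tot <- tot + pij * log2(pij / (mean(ci == X) * mean(cj == Y)))
    }
    tot
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(res$mi[i, j], brute_mi(m[, i], m[, j]))
  }
})

test_that("MI invariants: symmetry, entropy bound, independent column", {
  set.seed(16)
  seqs <- random_loops(1000, 4)
  # append an independently shuffled copy of column 1 as position 5
  extra <- sample(substr(seqs, 1, 1))
  seqs5 <- paste0(seqs, extra)
  res <- mutual_information(seqs5)
  expect_equal(res$mi, t(res$mi))
  H <- diag(res$mi)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lte(res$mi[i, j], min(H[i], H[j]) + 1e-9)
    expect_gte(res$mi[i, j], -1e-9)
  }
  expect_lt(res$mi[1, 5], 0.05)
})

test_that("weighted MI reduces to duplicating sequences", {
  seqs <- c("AC", "AG", "CC")
  w <- c(2, 1, 3)
  expanded <- rep(seqs, times = w)
  expect_equal(mutual_information(seqs, weights = w)$mi,
               mutual_information(expanded)$mi)
})

test_that("interpolated percentile matches the order-statistic definition", {
  expect_equal(percentile(1:20, 5), 1.95)
  expect_equal(percentile(1:20, 50), 10.5)
})

test_that("pairwise percentile contributions: constants, support, planting", {
  set.seed(17)
  seqs <- random_loops(120, 4)
  pc <- pairwise_percentile_contribution(seqs, rep(3.5, 120), q = 5,
                                         min_support = 5)
  expect_true(all(pc$value[pc$support >= 5] == 3.5))
  expect_true(all(is.na(pc$value[pc$support < 5])))

  # interpolated-percentile oracle on supported cells
  vals <- rnorm(120)
  pc2 <- pairwise_percentile_contribution(seqs, vals, q = 10, min_support = 5)
  m <- do.call(rbind, strsplit(seqs, ""))
  for (r in which(pc2$support >= 5)[1:20]) {
    base_i <- chartr("U", "T", pc2$base_i[r])
    base_j <- chartr("U", "T", pc2$base_j[r])
    sel <- m[, pc2$i[r]] == base_i & m[, pc2$j[r]] == base_j
    expect_equal(pc2$value[r], unname(quantile(vals[sel], 0.1, type = 7)))
  }

  # planted effect: G at position 1 co-occurs only with low values
  seqs3 <- c(paste0("G", random_loops(40, 3)), paste0("A", random_loops(40, 3)))
  vals3 <- c(rnorm(40, -3, 0.1), rnorm(40, 3, 0.1))
  pc3 <- pairwise_percentile_contribution(seqs3, vals3, q = 50, min_support = 3)
  g_cells <- pc3$value[pc3$i == 1 & pc3$base_i == "G" & !is.na(pc3$value)]
  expect_true(all(g_cells < median(vals3)))
})

test_that("median pairwise contribution is symmetric on symmetric data", {
  set.seed(18)
  seqs <- random_loops(300, 3)
  vals <- rnorm(300)
  pc <- pairwise_percentile_contribution(seqs, vals, q = 50, min_support = 2)
  tens <- attr(pc, "tensor")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(tens[i, j, , ], t(tens[j, i, , ]))
  }
})

test_that("IUPAC motif subsetting and fold-change summary", {
  seqs <- c("CATAA", "ARRAA" = "AAGAA", "AGGAG", "CCCCC", "GATAA")
  seqs <- unname(seqs)
  expect_identical(motif_subset(seqs, "NNNNN")$n_match, 5L)
  # CATAA fails NRRAR at position 3 (T not a purine)
  expect_false(motif_subset(seqs, "NRRAR")$mask[1])
  expect_true(motif_subset(seqs, "NRRAR")$mask[3])
  # literal motif matches only itself among literal sequences
  expect_identical(which(motif_subset(seqs, "ARRAA")$mask), 2L)
  expect_error(motif_subset(seqs, "NRRA!"), "IUPAC")
  expect_error(motif_subset(seqs, "NRRA"), "length")

  vals <- c(10, 2, 4, 50, 20)
  ms <- motif_subset(seqs, "NRRAR", values = vals)
  expect_equal(ms$mean_subset, mean(vals[ms$mask]))
  expect_equal(ms$fold_reduction, mean(vals) / mean(vals[ms$mask]))
})

test_that("per-bin logos round-trip frequencies to entropies", {
  set.seed(19)
  seqs <- random_loops(400, 5)
  lrd <- rnorm(400)
  sf <- seqfun_by_bin(seqs, lrd)
  expect_identical(sum(vapply(sf$per_bin, `[[`, 0, "n")), 400)
  for (b in sf$per_bin[1:3]) {
    recomputed <- apply(b$freq, 2, function(p) {
      p <- p[p > 0]; -sum(p * log2(p))
    })
    expect_equal(unname(b$entropy), unname(recomputed))
  }
})
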