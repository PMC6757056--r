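test_that("demultiplex assigns by exact barcode and reports discards", {
  bc <- c(ACGT = "RNA.minus.1", TGCA = "RNA.plus.1")
  reads <- c(paste0("ACGT", c("AAA", "CCC", "GGG")),
             paste0("TGCA", c("TTT", "AAA", "CCC")))
  s <- demultiplex(reads, bc)
  expect_identical(lengths(s), c(RNA.minus.1 = 3L, RNA.plus.1 = 3L))
  expect_identical(attr(s, "n_discarded"), 0L)
  expect_identical(s$RNA.minus.1, c("AAA", "CCC", "GGG"))

  # a single barcode mismatch discards the read
  s2 <- demultiplex(c("ACGAAAA", reads), bc)
  expect_identical(attr(s2, "n_discarded"), 1L)
  expect_error(demultiplex(reads, c(ACGT = "a", ACGT = "b")), "duplicate")
})

test_that("demultiplex conserves reads (property)", {
  set.seed(4)
  bc <- c(AAAA = "c1", CCCC = "c2", GGGG = "c3")
  for (rep in 1:5) {
    reads <- paste0(sample(c("AAAA", "CCCC", "GGGG", "TTTT"), 200, TRUE),
                    random_loops(200, 8))
    s <- demultiplex(reads, bc)
    expect_identical(sum(lengths(s)) + attr(s, "n_discarded"), length(reads))
    # per-condition counts match a brute-force tally of prefixes
    expect_identical(unname(lengths(s)),
                     unname(vapply(names(bc), function(b)
                       sum(startsWith(reads, b)), integer(1))))
  }
})

test_that("count_variants tallies and preserves zero rows", {
  empty <- count_variants(
    data.frame(assay = character(), condition = character(),
               replicate = integer(), variant = character()),
    variants = c("AAAAA", "CCCCC"), controls = "sTRSVctl")
  expect_true(all(empty$counts == 0))
  expect_true("sTRSVctl" %in% rownames(empty$counts))

  m <- data.frame(assay = "RNA", condition = "minus", replicate = 1L,
                  variant = rep("AAAAA", 5))
  expect_identical(unname(count_variants(m)$counts["AAAAA", 1]), 5)
})

test_that("count_variants equals a brute-force dictionary tally", {
  set.seed(9)
  vars <- random_loops(12)
  m <- data.frame(
    assay = sample(c("DNA", "RNA"), 300, TRUE),
    condition = sample(c("minus", "plus"), 300, TRUE),
    replicate = sample(1:2, 300, TRUE),
    variant = sample(c(vars, NA), 300, TRUE), stringsAsFactors = FALSE)
  ct <- count_variants(m)
  for (k in sample(nrow(m), 20)) {
    if (is.na(m$variant[k])) next
    lib <- paste(m$assay[k], m$condition[k], m$replicate[k], sep = ".")
    expect_identical(
      unname(ct$counts[m$variant[k], lib]),
      sum(m$variant == m$variant[k] & m$assay == m$assay[k] &
            m$condition == m$condition[k] & m$replicate == m$replicate[k],
          na.rm = TRUE) * 1)
  }
  expect_identical(sum(ct$counts), sum(!is.na(m$variant)) * 1)
})

test_that("filter_min_dna keeps variants covered in every DNA library", {
  ct <- make_count_table(
    dna_minus = c(v1 = 99, v2 = 100, v3 = 250, sTRSVctl = 5),
    rna_minus = c(v1 = 10, v2 = 10, v3 = 10, sTRSVctl = 10),
    controls = "sTRSVctl")
  out <- filter_min_dna(ct, 100)
  expect_setequal(rownames(out$counts), c("v2", "v3", "sTRSVctl"))
  expect_identical(attr(out, "filter_log")$removed, "v1")
  # threshold 0 is the identity
  expect_identical(filter_min_dna(ct, 0)$counts, ct$counts)
  # idempotent
  expect_identical(filter_min_dna(out, 100)$counts, out$counts)
})

test_that("the every-condition coverage rule matches brute force", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 40
    vars <- paste0("v", seq_len(n))
    libs <- list(
      DNA.minus.1 = stats::setNames(rpois(n, 100), vars),
      RNA.minus.1 = stats::setNames(rpois(n, 50), vars),
      DNA.minus.2 = stats::setNames(rpois(n, 100), vars),
      RNA.minus.2 = stats::setNames(rpois(n, 50), vars),
      DNA.plus.1 = stats::setNames(rpois(n, 100), vars),
      RNA.plus.1 = stats::setNames(rpois(n, 50), vars))
    ct <- make_count_table2(libs)
    out <- filter_min_dna(ct, 100)
    brute <- vars[libs$DNA.minus.1 >= 100 & libs$DNA.minus.2 >= 100 &
                    libs$DNA.plus.1 >= 100]
    expect_setequal(rownames(out$counts), brute)
  }
})

test_that("count table TSV round-trips", {
  ct <- make_count_table(
    dna_minus = c(AAAAA = 120, CCCCC = 80, sTRSVctl = 500),
    rna_minus = c(AAAAA = 60, CCCCC = 10, sTRSVctl = 900),
    controls = "sTRSVctl")
  fp <- tempfile(fileext = ".tsv")
  write_count_table(ct, fp)
  back <- read_count_table(fp)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$is_control, ct$is_control)
  expect_identical(back$coldata$assay, ct$coldata$assay)
})

test_that("count_reads runs reads to filtered counts with metrics", {
  tpl <- tiny_template()
  ctl <- tiny_controls()
  bc <- c(AAAACC = "RNA.minus.1", CCTTGG = "DNA.minus.1")
  loops <- c("CATAA", "GGTAC", "CATAA")
  reads <- c(paste0("AAAACC", render_variant(tpl, loops)),
             paste0("CCTTGG", render_variant(tpl, c("CATAA", "GGTAC"))),
             paste0("AAAACC", ctl$sequence[1]),
             "GGGGGGGGGG")
  ct <- count_reads(reads, tpl, ctl, bc, min_dna = 0)
  expect_identical(unname(ct$counts["CATAA", "RNA.minus.1"]), 2)
  expect_identical(unname(ct$counts["GGTAC", "DNA.minus.1"]), 1)
  expect_identical(unname(ct$counts["sTRSVctl", "RNA.minus.1"]), 1)
  met <- attr(ct, "run_metrics")
  expect_identical(met$n_discarded_barcode, 1L)
  expect_identical(met$n_counted, 6L)
})

test_that("FASTQ write/read round-trips (plain and gzipped)", {
  reads <- c("ACGTACGT", "TTTTCCCC")
  for (ext in c(".fastq", ".fastq.gz")) {
    fp <- tempfile(fileext = ext)
    write_fastq(reads, fp)
    expect_identical(read_fastq(fp), reads)
  }
})
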