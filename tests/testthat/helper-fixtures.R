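# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# a small switch template: 6-nt mock aptamer on loop I, degenerate loop II
tiny_template <- function(lengths = 5L) {
  build_switch_template("GGCAGC", "loopI", lengths)
}

tiny_controls <- function() {
  sim_control_sequences(default_sim_controls())
}

# count table built directly from a named matrix spec
make_count_table <- function(dna_minus, rna_minus, dna_plus = dna_minus,
                             rna_plus = rna_minus, controls = character()) {
  m <- cbind(`DNA.minus.1` = dna_minus, `RNA.minus.1` = rna_minus,
             `DNA.plus.1` = dna_plus, `RNA.plus.1` = rna_plus)
  cd <- data.frame(assay = c("DNA", "RNA", "DNA", "RNA"),
                   condition = c("minus", "minus", "plus", "plus"),
                   replicate = 1L)
  count_table(m, cd, is_control = rownames(m) %in% controls)
}

# replicate count table: same layout, two replicates
make_count_table2 <- function(counts_list, controls = character()) {
  # counts_list: named list lib -> named numeric vector
  m <- do.call(cbind, counts_list)
  f <- do.call(rbind, strsplit(names(counts_list), ".", fixed = TRUE))
  cd <- data.frame(assay = f[, 1], condition = f[, 2],
                   replicate = as.integer(f[, 3]))
  count_table(m, cd, is_control = rownames(m) %in% controls)
}

random_loops <- function(n, len = 5L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
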