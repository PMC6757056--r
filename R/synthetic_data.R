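# Seeded simulator for ribozyme-switch screens.
#
# Generative model: each variant has an uncleaved mRNA fraction f0 in (0,1]
# without ligand; ligand binding inhibits self-cleavage so the uncleaved
# fraction rises multiplicatively toward 1, f1 = f0 + (1 - f0) * s, with
# switching strength s in [0,1]. Steady-state mRNA is proportional to the
# uncleaved fraction. DNA copy number per variant carries log-normal
# dispersion w (the dominant noise source in oligo-pool libraries);
# sequencing is multinomial at fixed total depth. For sort-seq, per-cell
# log10 fluorescence is normal around log10(100 * f) with SD sigma_cell and
# cells are partitioned into bins.
#
# All functions draw their randomness from `set.seed(seed + fixed offset)`,
# so identical configs give bit-identical outputs.

#' Simulation configuration
#'
#' Defaults emulate the theophylline switch screen: an N4+N5 degenerate
#' loop II library (1280 variants) plus five spiked-in controls, two
#' biological replicates, sequencing depth 1e6 per library, and six sort
#' bins.
#'
#' @param n_variants number of library variants to draw (default `NULL`:
#'   the full enumerated library).
#' @param loop_lengths degenerate loop lengths (default `c(4, 5)`).
#' @param replicates biological replicates per condition (default 2).
#' @param depth_dna,depth_rna total sequencing reads per DNA / RNA library
#'   (default 1e6).
#' @param sigma_dna log-normal SD (natural log) of per-variant DNA copy
#'   weight (default 0.5; oligo-pool synthesis dispersion).
#' @param f0_logit_mean,f0_logit_sd logit-normal parameters of the basal
#'   uncleaved fraction f0 (defaults `qlogis(0.2)`, 1).
#' @param prob_switch probability a variant is a functional switch
#'   (default 0.2); non-switches have s = 0.
#' @param switch_shape1,switch_shape2 Beta parameters of the switching
#'   strength s for functional switches (default 2, 2).
#' @param sigma_cell per-cell SD of log10 fluorescence ratio (default 0.2).
#' @param n_cells cells per variant in the sort (default 2000).
#' @param n_bins number of sort bins (default 6).
#' @param reads_per_cell mean sort-seq sequencing reads per sorted cell
#'   (default 10).
#' @param error_rate per-base substitution error rate in simulated reads
#'   (default 0.001).
#' @param controls data.frame of spiked-in controls with columns `name` and
#'   `f` (fixed uncleaved fraction); default [default_sim_controls()].
#' @param seed integer seed; mandatory.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_variants = NULL, loop_lengths = c(4, 5),
                       replicates = 2L, depth_dna = 1e6, depth_rna = 1e6,
                       sigma_dna = 0.5,
                       f0_logit_mean = stats::qlogis(0.2), f0_logit_sd = 1,
                       prob_switch = 0.2, switch_shape1 = 2, switch_shape2 = 2,
                       sigma_cell = 0.2, n_cells = 2000, n_bins = 6L,
                       reads_per_cell = 10, error_rate = 0.001,
                       controls = default_sim_controls(), seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires an explicit seed")
  stopifnot(depth_dna > 0, depth_rna > 0, replicates >= 1L, n_bins >= 2L,
            sigma_dna >= 0, sigma_cell >= 0, error_rate >= 0, error_rate <= 1,
            prob_switch >= 0, prob_switch <= 1)
  structure(list(
    n_variants = n_variants, loop_lengths = sort(unique(as.integer(loop_lengths))),
    replicates = as.integer(replicates),
    depth_dna = depth_dna, depth_rna = depth_rna, sigma_dna = sigma_dna,
    f0_logit_mean = f0_logit_mean, f0_logit_sd = f0_logit_sd,
    prob_switch = prob_switch,
    switch_shape1 = switch_shape1, switch_shape2 = switch_shape2,
    sigma_cell = sigma_cell, n_cells = n_cells, n_bins = as.integer(n_bins),
    reads_per_cell = reads_per_cell, error_rate = error_rate,
    controls = controls, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default spiked-in control set for simulations
#'
#' Five synthetic plain ribozymes spanning the cleavage range, with the
#' non-cleaving sTRSVctl at f = 1. Names and f values are fixed; the
#' full-length sequences (for read simulation) use the plain-ribozyme
#' architecture with 8-nt loop II so they can never collide with an N4-6
#' library variant.
#'
#' @return data.frame with columns `name`, `f`, `loop1`, `loop2`.
#' @export
default_sim_controls <- function() {
  data.frame(
    name = c("sTRSVctl", "ctrl70", "ctrl35", "ctrl12", "ctrl04"),
    f = c(1, 0.70, 0.35, 0.12, 0.04),
    loop1 = c("TGTGCTT", "TGTGCTA", "TGTGCTC", "TGTGCTG", "TGTGCAT"),
    loop2 = c("ACGTACGT", "ACGTACGA", "ACGTACGC", "ACGTACGG", "ACGTACTT"),
    stringsAsFactors = FALSE
  )
}

#' Full-length sequences of the simulation controls
#'
#' @param controls control frame from [default_sim_controls()].
#' @return control set as from [control_ribozyme()], with
#'   `reference_rfu = 100 * f`.
#' @export
sim_control_sequences <- function(controls = default_sim_controls()) {
  do.call(rbind, lapply(seq_len(nrow(controls)), function(i) {
    tpl <- control_template(controls$loop1[i],
                            degenerate_lengths = nchar(controls$loop2[i]))
    control_ribozyme(controls$name[i],
                     render_variant(tpl, controls$loop2[i]),
                     reference_rfu = 100 * controls$f[i])
  }))
}

#' Draw a ground-truth library
#'
#' Samples distinct loop sequences, basal uncleaved fractions f0
#' (logit-normal), switching strengths s (spike-and-Beta mixture) and DNA
#' copy weights w (log-normal), and appends the spiked-in controls with
#' fixed f and s = 0.
#'
#' @param config a `sim_config`.
#' @return data.frame of class `ground_truth` with columns `variant`,
#'   `is_control`, `f0`, `s`, `f1`, `w`, `true_ar`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pool <- unlist(lapply(config$loop_lengths, function(L) {
    enumerate_library(build_switch_template("A", "loopI", L))
  }))
  n <- if (is.null(config$n_variants)) length(pool) else config$n_variants
  if (n > length(pool)) stop("n_variants exceeds library diversity")
  loops <- if (n == length(pool)) pool else sample(pool, n)
  f0 <- stats::plogis(stats::rnorm(n, config$f0_logit_mean, config$f0_logit_sd))
  is_switch <- stats::runif(n) < config$prob_switch
  s <- ifelse(is_switch,
              stats::rbeta(n, config$switch_shape1, config$switch_shape2), 0)
  w <- stats::rlnorm(n, 0, config$sigma_dna)
  ctl <- config$controls
  gt <- data.frame(
    variant = c(loops, ctl$name),
    is_control = c(rep(FALSE, n), rep(TRUE, nrow(ctl))),
    f0 = c(f0, ctl$f),
    s = c(s, rep(0, nrow(ctl))),
    w = c(w, rep(2, nrow(ctl))),  # controls spiked at twice per-variant representation
    stringsAsFactors = FALSE
  )
  gt$f1 <- gt$f0 + (1 - gt$f0) * gt$s
  gt$true_ar <- gt$f1 / gt$f0
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Simulate DNA and RNA read counts for both ligand conditions
#'
#' DNA reads are multinomial over variants with probabilities proportional
#' to w; RNA reads are proportional to w * f0 (without ligand) or w * f1
#' (with ligand). Replicates are independent draws. With
#' `expected = TRUE`, exact expected counts replace the draws (the
#' infinite-depth limit used for analytic checks).
#'
#' @param gt a `ground_truth`.
#' @param config the `sim_config` used to create it.
#' @param expected return expected rather than sampled counts.
#' @return a `count_table` with libraries DNA/RNA x minus/plus x replicate.
#' @export
simulate_counts <- function(gt, config, expected = FALSE) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p_dna <- gt$w / sum(gt$w)
  p_rna_minus <- gt$w * gt$f0 / sum(gt$w * gt$f0)
  p_rna_plus <- gt$w * gt$f1 / sum(gt$w * gt$f1)
  draw <- function(depth, p) {
    if (expected) depth * p else as.numeric(stats::rmultinom(1L, depth, p))
  }
  cols <- list(); cd <- list()
  for (r in seq_len(config$replicates)) {
    for (cond in c("minus", "plus")) {
      cols[[paste("DNA", cond, r, sep = ".")]] <- draw(config$depth_dna, p_dna)
      cd[[length(cd) + 1L]] <- data.frame(assay = "DNA", condition = cond,
                                          replicate = r)
      p_rna <- if (cond == "minus") p_rna_minus else p_rna_plus
      cols[[paste("RNA", cond, r, sep = ".")]] <- draw(config$depth_rna, p_rna)
      cd[[length(cd) + 1L]] <- data.frame(assay = "RNA", condition = cond,
                                          replicate = r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- gt$variant
  count_table(m, do.call(rbind, cd), is_control = gt$is_control)
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Render sequencing reads from a count table
#'
#' Each count emits one read: the library's condition barcode followed by
#' the full rendered architecture carrying the variant loop (controls emit
#' their own full-length sequence). Substitution errors are applied per
#' base at `error_rate`. At `error_rate = 0` a round trip through
#' [count_reads()] reproduces the counts exactly.
#'
#' @param counts a `count_table` (typically from [simulate_counts()], at
#'   modest depth; one read per count is materialized in memory).
#' @param template the `library_template` the variants belong to.
#' @param barcode_map named character vector `barcode -> assay.condition.replicate`
#'   covering every library in `counts`.
#' @param controls control sequence set ([sim_control_sequences()]).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed for error placement and read shuffling.
#' @return character vector of reads in shuffled order.
#' @export
simulate_reads <- function(counts, template, barcode_map,
                           controls = sim_control_sequences(),
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(counts, "count_table"))
  set.seed(seed + 2L)
  labels <- as.character(barcode_map)
  bcs <- names(barcode_map)
  lib_names <- colnames(counts$counts)
  if (!all(lib_names %in% labels)) {
    stop("barcode_map must cover every library: missing ",
         paste(setdiff(lib_names, labels), collapse = ", "))
  }
  variants <- rownames(counts$counts)
  full_seq <- character(length(variants))
  ctl_idx <- match(variants, controls$name)
  full_seq[!is.na(ctl_idx)] <- controls$sequence[ctl_idx[!is.na(ctl_idx)]]
  plain <- is.na(ctl_idx)
  if (any(plain)) full_seq[plain] <- render_variant(template, variants[plain])
  reads <- unlist(lapply(lib_names, function(lib) {
    bc <- bcs[match(lib, labels)]
    n <- counts$counts[, lib]
    paste0(bc, rep(full_seq, times = n))
  }), use.names = FALSE)
  reads <- mutate_reads(reads, error_rate)
  sample(reads)
}

#' Auto-placed sort-bin edges
#'
#' Interior edges are evenly spaced over the library's activity range in
#' log10 RFU, with the top boundary pinned to the non-cleaving control's
#' mean so the control's cell mass evenly spans the two highest bins; the
#' outermost edges are open.
#'
#' @param mu per-variant true log10 RFU values.
#' @param mu_ctl the reference control's mean.
#' @param n_bins number of bins.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
auto_bin_edges <- function(mu, mu_ctl, n_bins = 6L) {
  lo <- min(mu)
  interior <- seq(lo, mu_ctl, length.out = n_bins - 1L)
  c(-Inf, interior, Inf)
}

#' Simulate a sort-seq experiment
#'
#' Each variant contributes `n_cells` cells with per-cell log10 fluorescence
#' N(log10(100 * f), sigma_cell); cells fall into bins by the (auto-placed
#' or supplied) edges, and per-bin reads are multinomial over variants in
#' proportion to cell counts, with per-bin depth `reads_per_cell *
#' cells_sorted`.
#'
#' @param gt a `ground_truth`.
#' @param config the `sim_config`.
#' @param condition `"minus"` (uses f0) or `"plus"` (uses f1).
#' @param edges optional fixed bin edges (length `n_bins + 1`).
#' @return a `binned_sort_data`; attribute `"truth"` holds the per-variant
#'   true log10 RFU.
#' @export
simulate_facs <- function(gt, config, condition = c("minus", "plus"),
                          edges = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  condition <- match.arg(condition)
  set.seed(config$seed + if (condition == "minus") 3L else 4L)
  f <- if (condition == "minus") gt$f0 else gt$f1
  mu <- log10(100 * f)
  if (is.null(edges)) {
    ref <- which(gt$variant == "sTRSVctl")
    mu_ctl <- if (length(ref)) mu[ref[1L]] else max(mu)
    edges <- auto_bin_edges(mu, mu_ctl, config$n_bins)
  }
  B <- length(edges) - 1L
  cells <- t(vapply(mu, function(m) {
    x <- stats::rnorm(config$n_cells, m, max(config$sigma_cell, 1e-12))
    tabulate(findInterval(x, edges[-c(1L, B + 1L)], left.open = FALSE) + 1L,
             nbins = B)
  }, numeric(B)))
  rownames(cells) <- gt$variant
  cells_sorted <- colSums(cells)
  reads <- matrix(0, nrow = nrow(cells), ncol = B,
                  dimnames = list(gt$variant, NULL))
  for (b in seq_len(B)) {
    if (cells_sorted[b] == 0) next
    depth <- round(config$reads_per_cell * cells_sorted[b])
    reads[, b] <- as.numeric(
      stats::rmultinom(1L, depth, cells[, b] / cells_sorted[b]))
  }
  out <- binned_sort_data(reads, edges, cells_sorted,
                          total_reads = colSums(reads))
  attr(out, "truth") <- stats::setNames(mu, gt$variant)
  out
}
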