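# Sequence-function analysis of the randomized loop: standardization,
# 14-bin activity partitioning, entropy logos, mutual information,
# pairwise percentile contributions, one-hot encoding, IUPAC motifs.
#
# All operations assume equal-length loop sequences; mixed-length (N4-6)
# libraries are analyzed per length class unless an external alignment is
# supplied upstream.

# one-hot / frequency base ordering: A, C, U(T), G
SEQFUN_BASES <- c("A", "C", "T", "G")

seq_matrix <- function(seqs) {
  seqs <- as_dna(seqs, allow_n = TRUE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length (align upstream)")
  if (length(seqs) == 0L) stop("no sequences")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Standardize activity values to z-scores
#'
#' Translates to mean 0 and scales to standard deviation 1.
#'
#' @param values numeric vector (e.g. per-variant log10 RD).
#' @param sample_sd use the n-1 (sample) standard deviation (default) or the
#'   population (n) one.
#' @return standardized numeric vector.
#' @export
standardize <- function(values, sample_sd = TRUE) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) stop("standardize needs >= 2 distinct values")
  s <- stats::sd(v)
  if (!sample_sd) s <- s * sqrt((length(v) - 1) / length(v))
  (values - mean(v)) / s
}

#' One-hot encode equal-length loop sequences
#'
#' Each position expands to a 4-column block ordered A, C, U(T), G.
#'
#' @param seqs character vector of equal-length sequences over A,C,G,T/U.
#' @return m x 4n binary matrix; columns named `pos<j>.<base>` (U shown for
#'   display).
#' @export
one_hot <- function(seqs) {
  m <- seq_matrix(seqs)
  L <- ncol(m)
  out <- matrix(0L, nrow = nrow(m), ncol = 4L * L)
  for (j in seq_len(L)) {
    k <- match(m[, j], SEQFUN_BASES)
    if (anyNA(k)) stop("ambiguous bases cannot be one-hot encoded")
    out[cbind(seq_len(nrow(m)), 4L * (j - 1L) + k)] <- 1L
  }
  colnames(out) <- as.vector(outer(c("A", "C", "U", "G"),
                                   seq_len(L),
                                   function(b, j) paste0("pos", j, ".", b)))
  out
}

#' Assign standardized activities to 14 activity bins
#'
#' Bin 1 collects z <= -2 (two standard deviations below the mean), bin 14
#' collects z >= 1 (one standard deviation above), and bins 2-13 evenly
#' partition (-2, 1) into 12 left-closed intervals of width 0.25.
#'
#' @param z standardized log10 activity values.
#' @param lower_cut,upper_cut,n_mid_bins bin construction parameters
#'   (defaults -2, 1, 12).
#' @return list of class `activity_binning`: `bin_index` (integer 1..14 per
#'   value), `breaks` (interior cut points), and the parameters.
#' @export
assign_activity_bins <- function(z, lower_cut = -2, upper_cut = 1,
                                 n_mid_bins = 12L) {
  stopifnot(upper_cut > lower_cut, n_mid_bins >= 1L)
  width <- (upper_cut - lower_cut) / n_mid_bins
  bin <- ifelse(z <= lower_cut, 1L,
                ifelse(z >= upper_cut, n_mid_bins + 2L,
                       2L + floor((z - lower_cut) / width)))
  # guard float roundoff at the top interior boundary
  bin <- pmin(bin, n_mid_bins + 2L)
  structure(list(bin_index = as.integer(bin),
                 breaks = lower_cut + width * seq(0L, n_mid_bins),
                 lower_cut = lower_cut, upper_cut = upper_cut,
                 n_bins = n_mid_bins + 2L),
            class = "activity_binning")
}

weighted_base_freq <- function(col, weights) {
  w <- tapply(weights, factor(col, levels = SEQFUN_BASES), sum, default = 0)
  w / sum(w)
}

#' Per-position base frequencies and Shannon entropy
#'
#' @param seqs equal-length sequences.
#' @param weights optional non-negative per-sequence weights (default
#'   uniform).
#' @return list with `freq` (4 x L matrix, rows A,C,U,G) and `entropy`
#'   (bits per position, with 0 log 0 := 0).
#' @export
position_entropy <- function(seqs, weights = NULL) {
  m <- seq_matrix(seqs)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0), sum(weights) > 0)
  freq <- apply(m, 2L, weighted_base_freq, weights = weights)
  rownames(freq) <- c("A", "C", "U", "G")
  colnames(freq) <- paste0("pos", seq_len(ncol(freq)))
  H <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(freq = freq, entropy = H)
}

#' Mutual information between loop positions
#'
#' MI(i, j) = sum over base pairs of P_ij log2(P_ij / (P_i P_j)) with
#' (optionally weighted) observed frequencies; reported in bits. The
#' diagonal is set to the per-position entropy.
#'
#' @param seqs equal-length sequences.
#' @param weights optional non-negative per-sequence weights (e.g. read
#'   counts); default uniform.
#' @return list of class `mi_matrix`: `mi` (L x L symmetric, bits),
#'   `p_marg` (4 x L), `p_joint` (list of 4 x 4 tables keyed "i,j").
#' @export
mutual_information <- function(seqs, weights = NULL) {
  m <- seq_matrix(seqs)
  L <- ncol(m)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0), sum(weights) > 0)
  p_marg <- apply(m, 2L, weighted_base_freq, weights = weights)
  rownames(p_marg) <- SEQFUN_BASES
  mi <- matrix(0, L, L)
  p_joint <- list()
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  for (i in seq_len(L)) {
    mi[i, i] <- ent(p_marg[, i])
    for (j in if (i < L) (i + 1L):L else integer()) {
      tab <- tapply(weights,
                    list(factor(m[, i], levels = SEQFUN_BASES),
                         factor(m[, j], levels = SEQFUN_BASES)),
                    sum, default = 0)
      pj <- tab / sum(tab)
      outer_p <- p_marg[, i] %o% p_marg[, j]
      nz <- pj > 0
      mi[i, j] <- mi[j, i] <- sum(pj[nz] * log2(pj[nz] / outer_p[nz]))
      p_joint[[paste(i, j, sep = ",")]] <- pj
    }
  }
  structure(list(mi = mi, p_marg = p_marg, p_joint = p_joint),
            class = "mi_matrix")
}

#' Interpolated percentile (linear interpolation between order statistics)
#'
#' The percentile convention used throughout: `stats::quantile` type 7.
#'
#' @param x numeric vector.
#' @param q percentile in 0..100.
#' @export
percentile <- function(x, q) {
  unname(stats::quantile(x, q / 100, type = 7, names = FALSE, na.rm = TRUE))
}

#' Pairwise contribution of base pairs to low-activity percentiles
#'
#' For every position pair (i, j) and base pair (X, Y), the q-th percentile
#' of the activity values among sequences carrying X at i and Y at j.
#' Cells with fewer than `min_support` sequences are reported as `NA`.
#'
#' @param seqs equal-length sequences.
#' @param values activity values (log10 RD, possibly standardized) aligned
#'   to `seqs`.
#' @param q percentile (the screens use 5 or 10).
#' @param min_support minimum sequences per cell (default 5).
#' @return long-format data.frame with columns `i`, `j`, `base_i`, `base_j`
#'   (U shown for T), `support`, `value`; attribute `"tensor"` holds the
#'   same data as an L x L x 4 x 4 array.
#' @export
pairwise_percentile_contribution <- function(seqs, values, q = 5,
                                             min_support = 5L) {
  m <- seq_matrix(seqs)
  stopifnot(length(values) == nrow(m))
  L <- ncol(m)
  disp <- c(A = "A", C = "C", T = "U", G = "G")
  tensor <- array(NA_real_, dim = c(L, L, 4L, 4L),
                  dimnames = list(NULL, NULL, SEQFUN_BASES, SEQFUN_BASES))
  rows <- vector("list", L * L * 16L)
  r <- 0L
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    for (X in SEQFUN_BASES) for (Y in SEQFUN_BASES) {
      sel <- m[, i] == X & m[, j] == Y
      n <- sum(sel)
      val <- if (n >= min_support) percentile(values[sel], q) else NA_real_
      tensor[i, j, X, Y] <- val
      r <- r + 1L
      rows[[r]] <- data.frame(i = i, j = j, base_i = disp[[X]],
                              base_j = disp[[Y]], support = n, value = val)
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  rownames(out) <- NULL
  attr(out, "tensor") <- tensor
  attr(out, "q") <- q
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Subset a library by an IUPAC motif and summarize its activity
#'
#' @param seqs equal-length loop sequences.
#' @param motif IUPAC string of the same length (e.g. `"NRRAR"`).
#' @param values optional linear-scale activity values aligned to `seqs`;
#'   when given, the summary reports subset and library means and the fold
#'   reduction (library mean / subset mean).
#' @return list with `mask` (logical), `n_match`, and (with values)
#'   `mean_subset`, `mean_library`, `fold_reduction`.
#' @export
motif_subset <- function(seqs, motif, values = NULL) {
  m <- seq_matrix(seqs)
  motif <- toupper(motif)
  codes <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (length(codes) != ncol(m)) stop("motif length must equal loop length")
  if (!all(codes %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC codes: ",
         paste(setdiff(codes, names(IUPAC_SETS)), collapse = ", "))
  }
  mask <- rep(TRUE, nrow(m))
  for (j in seq_along(codes)) {
    mask <- mask & m[, j] %in% IUPAC_SETS[[codes[j]]]
  }
  out <- list(mask = mask, n_match = sum(mask))
  if (!is.null(values)) {
    stopifnot(length(values) == nrow(m))
    out$mean_subset <- mean(values[mask])
    out$mean_library <- mean(values)
    out$fold_reduction <- out$mean_library / out$mean_subset
  }
  out
}

#' Per-activity-bin sequence logos and covariation
#'
#' Convenience wrapper: bins standardized activities, then computes the
#' position-frequency matrix, entropies and MI matrix of each occupied bin.
#'
#' @param seqs equal-length loop sequences.
#' @param log10_rd per-variant log10 RD aligned to `seqs`.
#' @param weights optional per-sequence weights passed through.
#' @return list with `binning` and `per_bin` (one entry per occupied bin
#'   holding `n`, `freq`, `entropy`, `mi`).
#' @export
seqfun_by_bin <- function(seqs, log10_rd, weights = NULL) {
  z <- standardize(log10_rd)
  binning <- assign_activity_bins(z)
  per_bin <- lapply(sort(unique(binning$bin_index)), function(b) {
    sel <- binning$bin_index == b
    pe <- position_entropy(seqs[sel],
                           weights = if (is.null(weights)) NULL else weights[sel])
    list(bin = b, n = sum(sel), freq = pe$freq, entropy = pe$entropy,
         mi = mutual_information(seqs[sel],
                                 weights = if (is.null(weights)) NULL else weights[sel])$mi)
  })
  names(per_bin) <- paste0("bin", vapply(per_bin, `[[`, 0, "bin"))
  list(binning = binning, per_bin = per_bin)
}
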