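# Sort-seq (FACS-Seq) reconstruction of per-variant fluorescence.
#
# Cells carrying each variant are sorted into B fluorescence bins; per-bin
# sequencing read shares estimate per-bin cell counts, and an
# interval-censored normal MLE in log10(mCherry/BFP) space recovers the
# per-variant mean mu and spread sigma. Fitted mu values are calibrated to
# relative fluorescence units via spiked-in controls of known fluorescence
# and scaled so the non-cleaving control equals 100.

#' Construct binned sort data
#'
#' @param reads variants x bins matrix of read counts (rownames = variant).
#' @param edges numeric vector of B+1 increasing bin boundaries in
#'   log10(fluorescence ratio); the first may be `-Inf` and the last `+Inf`.
#' @param cells_sorted cells collected per bin (length B).
#' @param total_reads per-bin read totals; defaults to `colSums(reads)`
#'   (exhaustive tables).
#' @return object of class `binned_sort_data`.
#' @export
binned_sort_data <- function(reads, edges, cells_sorted, total_reads = NULL) {
  reads <- as.matrix(reads)
  B <- ncol(reads)
  stopifnot(B >= 2L, length(edges) == B + 1L, all(diff(edges) > 0),
            length(cells_sorted) == B, all(cells_sorted >= 0),
            !is.null(rownames(reads)))
  if (is.null(total_reads)) total_reads <- colSums(reads)
  stopifnot(length(total_reads) == B, all(colSums(reads) <= total_reads + 1e-9))
  colnames(reads) <- paste0("bin", seq_len(B))
  structure(list(reads = reads, edges = as.numeric(edges),
                 cells_sorted = as.numeric(cells_sorted),
                 total_reads = as.numeric(total_reads)),
            class = "binned_sort_data")
}

#' @export
print.binned_sort_data <- function(x, ...) {
  cat("binned_sort_data:", nrow(x$reads), "variants x", ncol(x$reads),
      "bins;", sum(x$cells_sorted), "cells sorted\n")
  invisible(x)
}

#' Estimate per-bin cell counts for a variant
#'
#' Allocates each bin's sorted cells to variants in proportion to read
#' share: cells(v, b) = reads(v, b) / total_reads(b) * cells_sorted(b).
#' Estimates are continuous expected counts, not integers.
#'
#' @param data a `binned_sort_data`.
#' @param variant variant name (row of `data$reads`).
#' @return numeric vector of per-bin cell-count estimates.
#' @export
estimate_bin_cells <- function(data, variant) {
  stopifnot(inherits(data, "binned_sort_data"))
  i <- match(variant, rownames(data$reads))
  if (is.na(i)) stop("variant '", variant, "' absent from sort data")
  r <- data$reads[i, ]
  tot <- data$total_reads
  if (any(r > 0 & tot == 0)) stop("reads present in a bin with zero total reads")
  frac <- ifelse(tot > 0, r / tot, 0)
  frac * data$cells_sorted
}

# censored-normal bin log-probabilities; end bins open to +/- Inf
bin_log_prob <- function(mu, sigma, edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  p <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  log(pmax(p, 1e-300))
}

#' Fit an interval-censored normal to binned cell counts
#'
#' Maximizes the multinomial log-likelihood of the per-bin counts under bin
#' probabilities Phi((hi - mu)/sigma) - Phi((lo - mu)/sigma), with the end
#' bins censored to +/- infinity. Initialization uses the weighted
#' mean/SD of bin midpoints, imputing end-bin midpoints one mean interior
#' bin-width beyond the edge. sigma is bounded below by 1e-3.
#'
#' @param cells per-bin (expected) cell counts, length B.
#' @param edges B+1 increasing edges. The outermost edges are always
#'   treated as open (+/- infinity) in the likelihood -- a sorter's end
#'   gates collect everything beyond them -- but finite values, when given,
#'   still inform the midpoint initialization.
#' @return list with `mu`, `sigma`, `loglik`, `n_cells_est` (total count
#'   used), `converged` (FALSE when all mass sits in a single end bin, where
#'   the MLE is at the boundary).
#' @export
fit_binned_normal <- function(cells, edges) {
  B <- length(cells)
  stopifnot(length(edges) == B + 1L, all(diff(edges) > 0), all(cells >= 0))
  n <- sum(cells)
  if (n <= 0) stop("no cells to fit")
  occupied <- which(cells > 0)

  widths <- diff(edges)
  interior_w <- widths[is.finite(widths)]
  w0 <- if (length(interior_w)) mean(interior_w) else 1
  mid <- (edges[-(B + 1L)] + edges[-1L]) / 2
  if (!is.finite(mid[1L])) mid[1L] <- edges[2L] - w0
  if (!is.finite(mid[B])) mid[B] <- edges[B] + w0
  lik_edges <- edges
  lik_edges[1L] <- -Inf
  lik_edges[B + 1L] <- Inf

  # degenerate case: every cell in one open end bin -> boundary MLE
  if (length(occupied) == 1L && occupied %in% c(1L, B)) {
    return(list(mu = mid[occupied], sigma = w0 / 2, loglik = 0,
                n_cells_est = n, converged = FALSE))
  }

  mu0 <- sum(cells * mid) / n
  s0 <- sqrt(max(sum(cells * (mid - mu0)^2) / n, 1e-6))
  nll <- function(par) {
    -sum(cells * bin_log_prob(par[1L], max(exp(par[2L]), 1e-3), lik_edges))
  }
  fit <- stats::optim(c(mu0, log(s0)), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  list(mu = fit$par[1L], sigma = max(exp(fit$par[2L]), 1e-3),
       loglik = -fit$value, n_cells_est = n,
       converged = fit$convergence == 0L)
}

#' Fit every variant in a binned sort dataset
#'
#' @param data a `binned_sort_data`.
#' @param min_cells skip variants whose estimated cell total is below this
#'   (default 1).
#' @return data.frame with columns `variant`, `mu`, `sigma`, `n_cells_est`,
#'   `converged`.
#' @export
fit_facs_bins <- function(data, min_cells = 1) {
  stopifnot(inherits(data, "binned_sort_data"))
  rows <- lapply(rownames(data$reads), function(v) {
    cells <- estimate_bin_cells(data, v)
    if (sum(cells) < min_cells) {
      return(data.frame(variant = v, mu = NA_real_, sigma = NA_real_,
                        n_cells_est = sum(cells), converged = FALSE))
    }
    f <- fit_binned_normal(cells, data$edges)
    data.frame(variant = v, mu = f$mu, sigma = f$sigma,
               n_cells_est = f$n_cells_est, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate fitted mu values to relative fluorescence units
#'
#' Least-squares linear map from fitted mu to the controls' known log10
#' fluorescence, applied to all variants; calibrated values are
#' exponentiated, divided by the mapped value of the reference control and
#' scaled by 100.
#'
#' @param fits data.frame from [fit_facs_bins()] (columns `variant`, `mu`).
#' @param controls data.frame with columns `name` and `log10_fluor` (known
#'   log10 fluorescence ratios from a flow analyzer); at least 2 controls
#'   with distinct fitted mu.
#' @param reference control name defining RFU = 100 (default `"sTRSVctl"`).
#' @return `fits` with added columns `log10_rfu_cal` and `rfu`; attribute
#'   `"calibration"` holds slope and intercept.
#' @export
calibrate_and_normalize <- function(fits, controls, reference = "sTRSVctl") {
  stopifnot(all(c("variant", "mu") %in% names(fits)),
            all(c("name", "log10_fluor") %in% names(controls)))
  idx <- match(controls$name, fits$variant)
  if (any(is.na(idx))) {
    stop("controls missing from fits: ",
         paste(controls$name[is.na(idx)], collapse = ", "))
  }
  mu_c <- fits$mu[idx]
  if (length(mu_c) < 2L) stop("need at least 2 fitted controls")
  if (stats::sd(mu_c) < 1e-12) stop("degenerate calibration: identical control mu")
  cal <- stats::lm.fit(cbind(1, mu_c), controls$log10_fluor)
  a <- cal$coefficients[1L]; b <- cal$coefficients[2L]
  mapped <- a + b * fits$mu
  ref_i <- match(reference, fits$variant)
  if (is.na(ref_i)) stop("reference control '", reference, "' not in fits")
  fits$log10_rfu_cal <- mapped
  fits$rfu <- 10^mapped / 10^mapped[ref_i] * 100
  attr(fits, "calibration") <- list(intercept = unname(a), slope = unname(b))
  fits
}

#' Activation ratio of calibrated fluorescence
#'
#' Identical contract to [activation_ratio()]; provided under the sort-seq
#' name for pipeline symmetry.
#'
#' @inheritParams activation_ratio
#' @export
facs_activation_ratio <- function(rd_minus, rd_plus) {
  activation_ratio(rd_minus, rd_plus)
}

#' Write / read binned sort data as TSV + JSON sidecar
#'
#' The TSV holds the variant x bin read counts; the JSON sidecar holds
#' `edges`, `cells_sorted` and `total_reads`.
#'
#' @param data a `binned_sort_data`.
#' @param path TSV path; the sidecar is `paste0(path, ".json")`.
#' @export
write_binned_sort_data <- function(data, path) {
  df <- data.frame(variant = rownames(data$reads), data$reads,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(edges = data$edges, cells_sorted = data$cells_sorted,
         total_reads = data$total_reads),
    paste0(path, ".json"), digits = NA
  )
  invisible(path)
}

#' @rdname write_binned_sort_data
#' @export
read_binned_sort_data <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$variant
  # jsonlite serializes open edges as the strings "-Inf"/"Inf"
  edges <- as.numeric(unlist(side$edges))
  binned_sort_data(m, edges, as.numeric(unlist(side$cells_sorted)),
                   as.numeric(unlist(side$total_reads)))
}
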