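# Normalized RNA/DNA activity, activation ratios, switching significance.
#
# The per-variant activity statistic is
#   RD_i = (RNA_i / DNA_i) / (RNA_ctl / DNA_ctl) * 100
# computed per condition and replicate, with the non-cleaving control
# (sTRSVctl) defining 100. If the control was not spiked in, the normalizer
# falls back to the mean RNA/DNA ratio of the 25 highest-ratio variants.

#' Normalize RNA read counts to DNA read counts
#'
#' For every (condition, replicate) pair with both an RNA and a DNA library,
#' computes per-variant RNA/DNA ratios and scales them so the control equals
#' 100. Variants with zero DNA in any library are dropped with a warning
#' (they are unquantifiable); RNA = 0 gives RD = 0.
#'
#' @param table a `count_table` containing paired DNA and RNA libraries.
#' @param control control variant name used as normalizer (default
#'   `"sTRSVctl"`).
#' @param fallback_top if the control row is absent, use the mean RNA/DNA
#'   ratio of this many top-ratio variants instead (default 25).
#' @param pseudocount added to RNA and DNA counts before ratios (default 0;
#'   the canonical analysis uses none).
#' @return object of class `rd_table`: list with `rd` (variants x
#'   "condition.replicate" matrix, linear scale), `is_control`,
#'   `control_used` (`"control"` or `"top25_fallback"`), `normalizer`
#'   (per-column RNA/DNA normalizing ratio).
#' @export
rd_normalize <- function(table, control = "sTRSVctl", fallback_top = 25,
                         pseudocount = 0) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table$counts) == 0L) stop("empty count table")
  cd <- table$coldata
  rna_idx <- which(cd$assay == "RNA")
  if (length(rna_idx) == 0L) stop("no RNA libraries in count table")
  cnt <- table$counts + pseudocount
  has_control <- control %in% rownames(cnt)

  pairs <- lapply(rna_idx, function(i) {
    j <- which(cd$assay == "DNA" & cd$condition == cd$condition[i] &
                 cd$replicate == cd$replicate[i])
    if (length(j) != 1L) {
      stop("RNA library ", colnames(table$counts)[i],
           " has no unique paired DNA library")
    }
    j
  })
  dna_idx <- unlist(pairs)

  # unquantifiable rows: DNA = 0 anywhere (after pseudocount)
  dna <- cnt[, dna_idx, drop = FALSE]
  bad <- apply(dna == 0, 1L, any)
  if (has_control && bad[match(control, rownames(cnt))]) {
    stop("control '", control, "' has zero DNA reads")
  }
  if (any(bad)) {
    warning(sum(bad), " variant(s) dropped: zero DNA reads")
    cnt <- cnt[!bad, , drop = FALSE]
    is_control <- table$is_control[!bad]
  } else {
    is_control <- table$is_control
  }

  ratio <- cnt[, rna_idx, drop = FALSE] / cnt[, dna_idx, drop = FALSE]
  colnames(ratio) <- paste(cd$condition[rna_idx], cd$replicate[rna_idx],
                           sep = ".")
  if (has_control) {
    norm <- ratio[match(control, rownames(cnt)), ]
    if (any(norm == 0)) stop("control '", control, "' has zero RNA reads")
    used <- "control"
  } else {
    if (nrow(ratio) < 1L) stop("no variants to derive fallback normalizer")
    k <- min(fallback_top, nrow(ratio))
    norm <- apply(ratio, 2L, function(r) mean(sort(r, decreasing = TRUE)[1:k]))
    used <- "top25_fallback"
  }
  rd <- sweep(ratio, 2L, norm, "/") * 100
  structure(list(rd = rd, is_control = is_control, control = control,
                 control_used = used, normalizer = norm),
            class = "rd_table")
}

#' @export
print.rd_table <- function(x, ...) {
  cat("rd_table:", nrow(x$rd), "variants x", ncol(x$rd),
      "condition.replicate columns; normalizer:", x$control_used, "\n")
  invisible(x)
}

#' Ligand activation ratio
#'
#' AR = RD(+ligand) / RD(-ligand). Vectorized; a zero denominator yields
#' `NA` (undefined, reported as missing).
#'
#' @param rd_minus,rd_plus normalized activity without / with ligand.
#' @return numeric activation ratios.
#' @export
activation_ratio <- function(rd_minus, rd_plus) {
  stopifnot(length(rd_minus) == length(rd_plus))
  ar <- rd_plus / rd_minus
  ar[rd_minus == 0] <- NA_real_
  ar
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Own step-up implementation (q(i) = min_{j >= i} p(j) * n / j on the
#' sorted p-values), kept independent of `stats::p.adjust` so the two can
#' cross-check each other.
#'
#' @param p numeric vector of p-values (NAs preserved).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0L) return(q)
  o <- order(p[ok], decreasing = TRUE)          # largest first
  ranked <- p[ok][o] * n / (n:1)                # p(j) * n / j, j = n..1
  q[ok][o] <- pmin(1, cummin(ranked))
  q
}

#' Per-variant significance of ligand-dependent switching
#'
#' Unpaired t-tests on replicate log10 RD values between the two ligand
#' conditions, with Benjamini-Hochberg correction across all tested
#' variants. Pooled-variance (classical) by default; Welch optional.
#'
#' @param log_rd_minus,log_rd_plus numeric matrices (variants x replicates)
#'   of log10 RD; rows with fewer than 2 finite values in either condition
#'   get `NA`.
#' @param sided `"two"` (default) or `"one"` (alternative: plus > minus, as
#'   used for flow-validation comparisons).
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return data.frame with columns `p` and `q` (BH-adjusted), one row per
#'   variant.
#' @export
switch_significance <- function(log_rd_minus, log_rd_plus,
                                sided = c("two", "one"), var_equal = TRUE) {
  sided <- match.arg(sided)
  log_rd_minus <- as.matrix(log_rd_minus)
  log_rd_plus <- as.matrix(log_rd_plus)
  stopifnot(nrow(log_rd_minus) == nrow(log_rd_plus))
  p <- vapply(seq_len(nrow(log_rd_minus)), function(i) {
    x <- log_rd_minus[i, ]; x <- x[is.finite(x)]
    y <- log_rd_plus[i, ];  y <- y[is.finite(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) return(NA_real_)
    v1 <- stats::var(x); v2 <- stats::var(y)
    d <- mean(y) - mean(x)
    if (v1 == 0 && v2 == 0) {
      if (d == 0) return(1)
      return(0)   # perfectly separated, zero-variance groups
    }
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tt <- d / se
    if (sided == "two") 2 * stats::pt(-abs(tt), df)
    else stats::pt(tt, df, lower.tail = FALSE)
  }, numeric(1))
  data.frame(p = p, q = bh_adjust(p))
}

#' Sets of top-ranked switches and their overlap
#'
#' Ranks each table by activation ratio and takes the top
#' `k = round((1 - percentile/100) * n)` variants per table (n is each
#' table's own size, so the two assays may contribute different k). Ties are
#' broken by lexicographic variant order for determinism.
#'
#' @param ar_a,ar_b named numeric vectors of activation ratios keyed by
#'   variant.
#' @param percentile percentile threshold, e.g. 95 keeps the top 5%.
#' @return list with `set_a`, `set_b` (character vectors), `intersection`,
#'   `n_intersect`, `k_a`, `k_b`.
#' @export
top_percentile_overlap <- function(ar_a, ar_b, percentile = 95) {
  stopifnot(length(ar_a) > 0L, length(ar_b) > 0L,
            !is.null(names(ar_a)), !is.null(names(ar_b)))
  top_k <- function(ar) {
    k <- round((1 - percentile / 100) * length(ar))
    ord <- order(-ar, names(ar))
    names(ar)[ord][seq_len(k)]
  }
  a <- top_k(ar_a); b <- top_k(ar_b)
  list(set_a = a, set_b = b, intersection = intersect(a, b),
       n_intersect = length(intersect(a, b)),
       k_a = length(a), k_b = length(b))
}

#' Full activity quantification of a count table
#'
#' Runs [rd_normalize()], averages replicates, and computes activation
#' ratios and switching significance on log10 RD.
#'
#' @param table a `count_table` with DNA and RNA libraries in conditions
#'   `"minus"` and `"plus"`.
#' @inheritParams rd_normalize
#' @inheritParams switch_significance
#' @return data.frame (class `activity_table`) with columns `variant`,
#'   `is_control`, `rd_minus`, `rd_plus` (replicate-mean linear RD),
#'   `log10_rd_minus`, `log10_rd_plus`, `ar`, `p`, `q`. Attribute
#'   `"normalization"` records the normalizer route.
#' @export
quantify_activity <- function(table, control = "sTRSVctl", fallback_top = 25,
                              pseudocount = 0, sided = c("two", "one"),
                              var_equal = TRUE) {
  sided <- match.arg(sided)
  rdt <- rd_normalize(table, control = control, fallback_top = fallback_top,
                      pseudocount = pseudocount)
  cols <- strsplit(colnames(rdt$rd), ".", fixed = TRUE)
  cond <- vapply(cols, `[`, "", 1L)
  minus <- rdt$rd[, cond == "minus", drop = FALSE]
  plus <- rdt$rd[, cond == "plus", drop = FALSE]
  if (ncol(minus) == 0L || ncol(plus) == 0L) {
    stop("need RNA libraries in both 'minus' and 'plus' conditions")
  }
  rd_minus <- rowMeans(minus)
  rd_plus <- rowMeans(plus)
  lg <- function(m) { out <- log10(m); out[m == 0] <- NA_real_; out }
  sig <- switch_significance(lg(minus), lg(plus), sided = sided,
                             var_equal = var_equal)
  out <- data.frame(
    variant = rownames(rdt$rd), is_control = rdt$is_control,
    rd_minus = rd_minus, rd_plus = rd_plus,
    log10_rd_minus = ifelse(rd_minus > 0, log10(rd_minus), NA_real_),
    log10_rd_plus = ifelse(rd_plus > 0, log10(rd_plus), NA_real_),
    ar = activation_ratio(rd_minus, rd_plus),
    p = sig$p, q = sig$q,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("activity_table", "data.frame")
  attr(out, "normalization") <- list(control = control,
                                     control_used = rdt$control_used,
                                     normalizer = rdt$normalizer)
  out
}

#' Write an activity table as TSV
#'
#' @param activity an `activity_table`.
#' @param path TSV path.
#' @export
write_activity_table <- function(activity, path) {
  utils::write.table(activity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
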