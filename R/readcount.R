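# Read demultiplexing, per-variant counting, DNA-coverage filtering.
#
# The count container is a DGEList-like S3 object: an integer matrix of
# variants x libraries plus a coldata frame describing each library as
# (assay, condition, replicate).

#' Construct a count table
#'
#' @param counts integer matrix, variants in rows (rownames = variant loop
#'   sequence or control name), libraries in columns.
#' @param coldata data.frame with one row per column of `counts` and columns
#'   `assay` ("DNA"/"RNA"), `condition` ("minus"/"plus"), `replicate` (int).
#' @param is_control logical vector parallel to rows.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, coldata, is_control = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in simulation
  stopifnot(!is.null(rownames(counts)), nrow(coldata) == ncol(counts),
            all(c("assay", "condition", "replicate") %in% names(coldata)))
  if (any(counts < 0)) stop("negative counts")
  if (is.null(is_control)) is_control <- rep(FALSE, nrow(counts))
  stopifnot(length(is_control) == nrow(counts))
  colnames(counts) <- with(coldata, paste(assay, condition, replicate, sep = "."))
  structure(list(counts = counts, coldata = coldata,
                 is_control = as.logical(is_control)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "variants (",
      sum(x$is_control), "controls ) x", ncol(x$counts), "libraries\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Demultiplex reads by exact condition barcode
#'
#' Each read is assigned to the condition whose barcode exactly matches the
#' read's prefix; the barcode is stripped. Non-matching reads are discarded
#' and counted.
#'
#' @param reads character vector of reads (barcode followed by insert).
#' @param barcode_map named character vector `barcode -> condition label`.
#'   Barcodes must be unique and of equal length.
#' @return list with one character vector of de-barcoded reads per condition
#'   label, plus attribute `"n_discarded"`.
#' @export
demultiplex <- function(reads, barcode_map) {
  bcs <- as_dna(names(barcode_map))
  if (anyDuplicated(bcs)) stop("duplicate barcodes")
  if (length(unique(nchar(bcs))) != 1L) stop("barcodes must have equal length")
  k <- nchar(bcs[1L])
  reads <- as_dna(reads, allow_n = TRUE)
  pre <- substr(reads, 1L, k)
  idx <- match(pre, bcs)
  out <- lapply(seq_along(bcs), function(i) {
    substring(reads[which(idx == i)], k + 1L)
  })
  names(out) <- as.character(barcode_map)
  attr(out, "n_discarded") <- sum(is.na(idx))
  out
}

#' Tally matched (library, variant) assignments into a count table
#'
#' @param matched data.frame with columns `assay`, `condition`, `replicate`,
#'   `variant` (NA variants, i.e. unmatched reads, are dropped) and optional
#'   `is_control`.
#' @param coldata library layout (as in [count_table()]); defaults to the
#'   distinct (assay, condition, replicate) triples observed.
#' @param variants optional character vector fixing the row universe (rows
#'   absent from `matched` get zero counts). Controls should be included so
#'   every control is present as a row even at zero depth.
#' @param controls optional character vector of control names.
#' @return a `count_table`.
#' @export
count_variants <- function(matched, coldata = NULL, variants = NULL,
                           controls = character()) {
  keep <- !is.na(matched$variant)
  matched <- matched[keep, , drop = FALSE]
  if (is.null(coldata)) {
    coldata <- unique(matched[, c("assay", "condition", "replicate")])
    if (nrow(coldata) == 0L) {
      coldata <- data.frame(assay = "RNA", condition = "minus", replicate = 1L)
    }
    rownames(coldata) <- NULL
  }
  lib_of <- function(a, cdn, r) paste(a, cdn, r, sep = ".")
  lib_levels <- lib_of(coldata$assay, coldata$condition, coldata$replicate)
  rows <- unique(c(variants, controls, matched$variant))
  if (length(rows) == 0L) rows <- controls
  m <- matrix(0, nrow = length(rows), ncol = length(lib_levels),
              dimnames = list(rows, lib_levels))
  if (nrow(matched)) {
    tab <- table(factor(matched$variant, levels = rows),
                 factor(lib_of(matched$assay, matched$condition,
                               matched$replicate), levels = lib_levels))
    m <- m + unclass(tab)
  }
  count_table(m, coldata, is_control = rows %in% controls)
}

#' Filter variants by minimum DNA read coverage
#'
#' Retains variants whose DNA read count is at least `threshold` in every
#' DNA library (all conditions and replicates). Spiked-in controls are always
#' retained so normalization never loses its anchor. The removed variants are
#' recorded in the `"filter_log"` attribute.
#'
#' @param table a `count_table`.
#' @param threshold minimum DNA reads per condition/replicate (default 100).
#' @return the filtered `count_table`.
#' @export
filter_min_dna <- function(table, threshold = 100) {
  stopifnot(inherits(table, "count_table"), threshold >= 0)
  dna <- table$counts[, table$coldata$assay == "DNA", drop = FALSE]
  keep <- if (ncol(dna) == 0L) rep(TRUE, nrow(table$counts)) else
    apply(dna >= threshold, 1L, all)
  keep <- keep | table$is_control
  out <- count_table(table$counts[keep, , drop = FALSE], table$coldata,
                     table$is_control[keep])
  attr(out, "filter_log") <- list(
    threshold = threshold,
    n_in = nrow(table$counts), n_out = sum(keep),
    removed = rownames(table$counts)[!keep]
  )
  out
}

#' Full read-to-counts stage
#'
#' Demultiplexes a read stream, matches each condition's reads against the
#' library architecture and controls, and tallies counts.
#'
#' @param reads character vector of barcoded reads.
#' @param template a `library_template`.
#' @param controls control set ([control_ribozyme()] rows) or `NULL`.
#' @param barcode_map named character vector `barcode -> "assay.condition.replicate"`.
#' @param min_dna DNA coverage threshold applied at the end (0 disables).
#' @return a `count_table`; attribute `"run_metrics"` holds discard and
#'   match totals.
#' @export
count_reads <- function(reads, template, controls, barcode_map, min_dna = 100) {
  streams <- demultiplex(reads, barcode_map)
  ctl_names <- if (is.null(controls)) character() else controls$name
  parts <- lapply(names(streams), function(lbl) {
    f <- strsplit(lbl, ".", fixed = TRUE)[[1L]]
    if (length(f) != 3L) stop("barcode_map labels must be assay.condition.replicate")
    v <- match_read(streams[[lbl]], template, controls)
    data.frame(assay = rep(f[1L], length(v)),
               condition = rep(f[2L], length(v)),
               replicate = rep(as.integer(f[3L]), length(v)),
               variant = as.character(v), stringsAsFactors = FALSE)
  })
  matched <- do.call(rbind, parts)
  cd <- do.call(rbind, lapply(names(streams), function(lbl) {
    f <- strsplit(lbl, ".", fixed = TRUE)[[1L]]
    data.frame(assay = f[1L], condition = f[2L], replicate = as.integer(f[3L]))
  }))
  ct <- count_variants(matched, coldata = cd, controls = ctl_names)
  if (min_dna > 0) ct <- filter_min_dna(ct, min_dna)
  attr(ct, "run_metrics") <- list(
    n_reads = length(reads),
    n_discarded_barcode = attr(streams, "n_discarded"),
    n_unmatched_architecture = sum(is.na(matched$variant)),
    n_counted = sum(!is.na(matched$variant))
  )
  ct
}

#' Write / read a count table as TSV
#'
#' Columns: `variant`, `is_control`, then one column per library named
#' `assay.condition.replicate`.
#'
#' @param table a `count_table`.
#' @param path TSV path.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(variant = rownames(table$counts),
                   is_control = table$is_control,
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  libs <- setdiff(names(df), c("variant", "is_control"))
  f <- do.call(rbind, strsplit(libs, ".", fixed = TRUE))
  cd <- data.frame(assay = f[, 1L], condition = f[, 2L],
                   replicate = as.integer(f[, 3L]))
  m <- as.matrix(df[, libs, drop = FALSE])
  rownames(m) <- df$variant
  count_table(m, cd, df$is_control)
}

#' Read merged reads from FASTQ (optionally gzipped)
#'
#' @param path FASTQ path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Write reads as FASTQ with uniform placeholder qualities
#'
#' @param reads character vector of sequences.
#' @param path output path (`.gz` suffix gzips).
#' @param ids read names; defaults to `read1..readN`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  x <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
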