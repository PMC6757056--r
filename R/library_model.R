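# Sequence architecture of hammerhead ribozyme switch libraries.
#
# A library member is rendered as
#   5'flank + stem-I slot + catalytic core + stem-II slot + 3'flank
# where exactly one slot carries the degenerate loop (N4-N6) and the other
# carries the aptamer (or a fixed loop for plain-ribozyme controls).

# Fixed architecture pieces shared by all constructs (DNA alphabet, sense
# strand). The head/tail carry the stem III closing sequence and poly-A/T
# context used for priming.
RZ_HEAD <- "AAACAAACAAAGCTGTCACCG"
RZ_CORE <- "CGGTCTGATGAGTC"
RZ_TAIL <- "GACGAAACAGCAAAAAGAAAAATAAAAA"

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and maps U to T. The internal alphabet is DNA because
#' sequencing reads are DNA-space; display layers may render U.
#'
#' @param x character vector of nucleotide strings (may contain U, lowercase).
#' @param allow_n allow ambiguous N characters (reads may carry them).
#' @return character vector over A,C,G,T (and N if allowed).
#' @export
as_dna <- function(x, allow_n = FALSE) {
  x <- chartr("u", "t", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(ok, x)
  if (any(bad)) {
    stop("invalid nucleotide characters in: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  x
}

#' Construct a ribozyme switch library template
#'
#' Builds the fixed-architecture template with the aptamer grafted onto one
#' stem loop and the opposing loop degenerate. Slot overlap bases (the
#' optimized fixed bases flanking each loop insertion point) default to the
#' empty string.
#'
#' @param aptamer nucleotide string placed in the `placement` slot. May be
#'   empty for plain-ribozyme templates (then the slot holds only its
#'   overlap bases).
#' @param placement `"loopI"` or `"loopII"`: the slot that receives the
#'   aptamer; the opposing slot is degenerate.
#' @param degenerate_lengths integer vector of allowed loop lengths
#'   (e.g. `c(4, 5)`); non-negative.
#' @param overlap_bases named list with optional entries `stem1_5p`,
#'   `stem1_3p`, `stem2_5p`, `stem2_3p` giving fixed bases flanking each
#'   slot's insert.
#' @param flank5,core,flank3 fixed architecture pieces; defaults are the
#'   shared hammerhead context.
#' @return an object of class `library_template`.
#' @examples
#' tpl <- build_switch_template("GGCGATACCAGCCGAAAGGCCCTTGGCAGC", "loopI", c(4, 5))
#' library_diversity(tpl)
#' @export
build_switch_template <- function(aptamer, placement = c("loopI", "loopII"),
                                  degenerate_lengths,
                                  overlap_bases = list(),
                                  flank5 = RZ_HEAD, core = RZ_CORE,
                                  flank3 = RZ_TAIL) {
  placement <- match.arg(placement)
  aptamer <- as_dna(aptamer)
  stopifnot(length(aptamer) == 1L)
  degenerate_lengths <- sort(unique(as.integer(degenerate_lengths)))
  if (length(degenerate_lengths) == 0L || any(degenerate_lengths < 0L)) {
    stop("degenerate lengths must be non-negative integers")
  }
  ob <- list(stem1_5p = "", stem1_3p = "", stem2_5p = "", stem2_3p = "")
  if (length(overlap_bases)) {
    bad <- setdiff(names(overlap_bases), names(ob))
    if (length(bad)) stop("unknown overlap slots: ", paste(bad, collapse = ", "))
    ob[names(overlap_bases)] <- lapply(overlap_bases, as_dna)
  }
  fixed_slot <- if (placement == "loopI") "stem1" else "stem2"
  degenerate_slot <- if (placement == "loopI") "stem2" else "stem1"
  slots <- list(
    stem1 = list(prefix = ob$stem1_5p, suffix = ob$stem1_3p),
    stem2 = list(prefix = ob$stem2_5p, suffix = ob$stem2_3p)
  )
  slots[[fixed_slot]]$insert <- aptamer
  structure(
    list(flank5 = as_dna(flank5), core = as_dna(core), flank3 = as_dna(flank3),
         slots = slots, degenerate_slot = degenerate_slot,
         degenerate_lengths = degenerate_lengths),
    class = "library_template"
  )
}

#' Plain-ribozyme template with fixed loop I and degenerate loop II
#'
#' Convenience constructor for the control architecture in which loop I is a
#' fixed sequence embedded between the GA/TC and C/G stem-closing bases.
#'
#' @param loop1 fixed loop I sequence.
#' @param degenerate_lengths allowed loop II lengths.
#' @return a `library_template`.
#' @export
control_template <- function(loop1, degenerate_lengths = 5L) {
  build_switch_template(
    aptamer = loop1, placement = "loopI",
    degenerate_lengths = degenerate_lengths,
    overlap_bases = list(stem1_5p = "GA", stem1_3p = "TC",
                         stem2_5p = "C", stem2_3p = "G")
  )
}

#' @export
print.library_template <- function(x, ...) {
  deg <- x$degenerate_slot
  cat("Ribozyme switch library template\n")
  cat("  degenerate slot:", deg, "; lengths:",
      paste(x$degenerate_lengths, collapse = ","), "\n")
  cat("  rendered layout: ", x$flank5, "-[stem I]-", x$core,
      "-[stem II]-", x$flank3, "\n", sep = "")
  cat("  diversity:", library_diversity(x), "variants\n")
  invisible(x)
}

slot_fixed_seq <- function(template, slot) {
  s <- template$slots[[slot]]
  paste0(s$prefix, s$insert, s$suffix)
}

#' Render the full-length sequence of one library variant
#'
#' @param template a `library_template`.
#' @param loop loop sequence(s) for the degenerate slot; vectorized.
#' @return character vector of rendered sequences.
#' @export
render_variant <- function(template, loop) {
  loop <- as_dna(loop)
  if (!all(nchar(loop) %in% template$degenerate_lengths)) {
    stop("loop length outside the template's degenerate lengths")
  }
  deg <- template$degenerate_slot
  s <- template$slots[[deg]]
  deg_seq <- paste0(s$prefix, loop, s$suffix)
  if (deg == "stem1") {
    paste0(template$flank5, deg_seq, template$core,
           slot_fixed_seq(template, "stem2"), template$flank3)
  } else {
    paste0(template$flank5, slot_fixed_seq(template, "stem1"),
           template$core, deg_seq, template$flank3)
  }
}

#' Number of unique variants a template encodes
#'
#' Sum over allowed loop lengths L of 4^L.
#'
#' @param template a `library_template`.
#' @return integer count.
#' @export
library_diversity <- function(template) {
  sum(4^template$degenerate_lengths)
}

#' Enumerate every loop sequence of a template
#'
#' @param template a `library_template` (total diversity must be modest;
#'   intended for N0-N6 designs).
#' @return character vector of loop sequences, ordered by length then
#'   lexicographically.
#' @export
enumerate_library <- function(template) {
  unlist(lapply(template$degenerate_lengths, function(L) {
    if (L == 0L) return("")
    g <- do.call(expand.grid,
                 c(rep(list(DNA_BASES), L), stringsAsFactors = FALSE))
    # expand.grid varies the first factor fastest; reverse for lexicographic
    sort(do.call(paste0, g[, rev(seq_len(L)), drop = FALSE]))
  }), use.names = FALSE)
}

#' Define a control ribozyme
#'
#' @param name identifier, e.g. `"sTRSVctl"`.
#' @param sequence full-length nucleotide sequence as sequenced.
#' @param reference_rfu known relative fluorescence (non-cleaving control
#'   sTRSVctl defines 100).
#' @return a one-row data.frame; `rbind` rows to build a control set.
#' @export
control_ribozyme <- function(name, sequence, reference_rfu = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(reference_rfu) && reference_rfu <= 0) {
    stop("reference_rfu must be positive")
  }
  data.frame(name = name, sequence = as_dna(sequence),
             reference_rfu = reference_rfu, stringsAsFactors = FALSE)
}

validate_controls <- function(controls) {
  if (is.null(controls) || nrow(controls) == 0L) {
    return(data.frame(name = character(), sequence = character(),
                      reference_rfu = numeric()))
  }
  stopifnot(all(c("name", "sequence") %in% names(controls)))
  if (anyDuplicated(controls$name)) stop("duplicate control names")
  controls$sequence <- as_dna(controls$sequence)
  controls
}

# Compiled matcher for a template: fixed prefix/suffix around the degenerate
# loop, used by match_read via a single regex with an anchored loop capture.
template_regex <- function(template) {
  deg <- template$degenerate_slot
  s <- template$slots[[deg]]
  if (deg == "stem1") {
    prefix <- paste0(template$flank5, s$prefix)
    suffix <- paste0(s$suffix, template$core,
                     slot_fixed_seq(template, "stem2"), template$flank3)
  } else {
    prefix <- paste0(template$flank5, slot_fixed_seq(template, "stem1"),
                     template$core, s$prefix)
    suffix <- paste0(s$suffix, template$flank3)
  }
  lens <- template$degenerate_lengths
  paste0(prefix, "([ACGT]{", min(lens), ",", max(lens), "})", suffix)
}

#' Match reads to library variants and spiked-in controls
#'
#' Controls are matched first by exact substring so a control can never parse
#' as a variant; otherwise the read must contain the exact fixed architecture
#' (zero mismatches by default) and the degenerate loop is extracted. Input is
#' case- and U/T-insensitive.
#'
#' @param reads character vector of merged reads (alphabet A,C,G,T,N,U).
#' @param template a `library_template`.
#' @param controls control set from [control_ribozyme()] (may be `NULL`).
#' @return character vector parallel to `reads`: the loop sequence for
#'   architecture matches, the control name for control matches, `NA` for
#'   no-match. Attribute `"is_control"` is a parallel logical vector.
#' @export
match_read <- function(reads, template, controls = NULL) {
  reads <- as_dna(reads, allow_n = TRUE)
  controls <- validate_controls(controls)
  out <- rep(NA_character_, length(reads))
  is_ctl <- rep(FALSE, length(reads))
  unmatched <- rep(TRUE, length(reads))
  for (k in seq_len(nrow(controls))) {
    hit <- unmatched & grepl(controls$sequence[k], reads, fixed = TRUE)
    out[hit] <- controls$name[k]
    is_ctl[hit] <- TRUE
    unmatched[hit] <- FALSE
  }
  if (any(unmatched)) {
    pat <- template_regex(template)
    m <- regexec(pat, reads[unmatched])
    loops <- vapply(regmatches(reads[unmatched], m), function(g) {
      if (length(g) >= 2L) g[2L] else NA_character_
    }, character(1))
    # alternation by length range can over/under-reach only if the loop
    # length is outside the allowed set
    loops[!is.na(loops) & !(nchar(loops) %in% template$degenerate_lengths)] <-
      NA_character_
    out[unmatched] <- loops
  }
  attr(out, "is_control") <- is_ctl
  out
}

#' Write template renderings or arbitrary sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Export an enumerated library as FASTA
#'
#' @param template a `library_template`.
#' @param path output FASTA path.
#' @export
export_library_fasta <- function(template, path) {
  loops <- enumerate_library(template)
  seqs <- render_variant(template, loops)
  write_fasta(stats::setNames(seqs, loops), path)
}
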