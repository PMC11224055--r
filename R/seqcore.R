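#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reference sequence record
#'
#' Lightweight container for one genomic locus: an identifier, an uppercase
#' DNA sequence restricted to the alphabet A/C/G/T/N, and a free-text
#' description. All coordinates used throughout the package are 0-based
#' half-open on the top strand of a `RefSeq`; user-facing reports render
#' 1-based inclusive coordinates. Topology is linear only.
#'
#' @param id Record identifier (single string).
#' @param seq DNA sequence (single string; case-insensitive, validated).
#' @param description Optional free-text description.
#' @return An object of class `RefSeq` with fields `id`, `seq`, `description`.
#' @examples
#' ref_seq("x", "acgt")
#' @export
ref_seq <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- validate_dna(seq, context = id)
  structure(list(id = id, seq = seq, description = description),
            class = "RefSeq")
}

#' @export
print.RefSeq <- function(x, ...) {
  cat(sprintf("RefSeq %s: %d bp", x$id, nchar(x$seq)))
  if (nzchar(x$description)) cat(" --", x$description)
  cat("\n  ", if (nchar(x$seq) > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq,
      "\n", sep = "")
  invisible(x)
}

# Uppercase and check alphabet; 'context' names the offending record in errors.
validate_dna <- function(seq, context = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop(sprintf("'%s': sequence must have length >= 1", context))
  if (grepl("U", seq, fixed = TRUE))
    stop(sprintf("'%s': RNA alphabet (U) not accepted; supply DNA", context))
  bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
  if (length(bad))
    stop(sprintf("'%s': invalid characters beyond A/C/G/T/N: %s",
                 context, paste(bad, collapse = ", ")))
  seq
}

#' Genomic interval (0-based, half-open)
#'
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); `end >= start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `Interval`.
#' @export
interval <- function(start, end, strand = ".") {
  stopifnot(length(start) == 1L, length(end) == 1L,
            start == floor(start), end == floor(end))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L) stop("interval start must be >= 0")
  if (end < start) stop("interval end must be >= start")
  if (!strand %in% c("+", "-", ".")) stop("strand must be '+', '-' or '.'")
  structure(list(start = start, end = end, strand = strand), class = "Interval")
}

#' @export
print.Interval <- function(x, ...) {
  cat(sprintf("Interval [%d, %d) %s (%d bp)\n", x$start, x$end, x$strand,
              x$end - x$start))
  invisible(x)
}

#' Length of an interval
#' @param iv An [interval()].
#' @return Integer width (`end - start`).
#' @export
interval_len <- function(iv) iv$end - iv$start

check_interval_within <- function(iv, ref, what = "interval") {
  n <- if (inherits(ref, "RefSeq")) nchar(ref$seq) else as.integer(ref)
  if (iv$end > n)
    stop(sprintf("%s [%d, %d) exceeds sequence length %d", what,
                 iv$start, iv$end, n))
  invisible(TRUE)
}

# substring by 0-based half-open interval
subseq0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

#' Load a FASTA file
#'
#' Reads all records, uppercases sequences, and validates the A/C/G/T/N
#' alphabet. RNA input (U) and other non-ACGTN characters are rejected with
#' an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [ref_seq()] records (names are record ids).
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop(sprintf("not a FASTA file: %s (%s)",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  out <- lapply(seq_along(set), function(i)
    ref_seq(ids[i], as.character(set[[i]]), desc[i]))
  names(out) <- ids
  out
}

#' Write RefSeq records to FASTA
#'
#' @param refs A `RefSeq` or list of `RefSeq` records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  if (inherits(refs, "RefSeq")) refs <- list(refs)
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "seq"))
  nm <- vapply(refs, `[[`, "", "id")
  dsc <- vapply(refs, `[[`, "", "description")
  names(seqs) <- ifelse(nzchar(dsc), paste(nm, dsc), nm)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq DNA string (A/C/G/T/N); `N` maps to `N`.
#' @return The reverse complement as a character string.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(seq) {
  seq <- validate_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# fast base-R reverse complement for hot inner loops (pre-validated input)
revcomp_chr <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons render as `"*"`; any codon containing
#' `N` translates to `"X"`.
#'
#' @param cds DNA string with length divisible by 3 (may be empty).
#' @return Protein string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) == 0L) return("")
  cds <- validate_dna(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

gc_percent <- function(seq) {
  if (nchar(seq) == 0L) return(NA_real_)
  b <- strsplit(seq, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

has_tttt <- function(seq) grepl("TTTT", seq, fixed = TRUE)

# render 0-based half-open as 1-based inclusive "start-end"
fmt1 <- function(start0, end0) sprintf("%d-%d", start0 + 1L, end0)
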