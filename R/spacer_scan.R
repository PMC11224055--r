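#' Enumerate SpCas9 protospacer/PAM sites near a window
#'
#' Scans both strands of a reference for 20-nt protospacers followed by an
#' NGG PAM (pattern configurable) and reports every site whose nick
#' coordinate falls inside `window`. The nick is the canonical SpCas9
#' blunt cut between protospacer positions 17 and 18 (3 nt 5' of the PAM),
#' expressed as the 0-based top-strand index of the first base 3' of the
#' broken bond. Spacers containing `N` are excluded (unsynthesizable).
#'
#' @param ref A [ref_seq()] record.
#' @param window An [interval()] the nick coordinate must fall in
#'   (`NULL` = whole sequence).
#' @param pam_pattern PAM on the protospacer strand, IUPAC (default `"NGG"`).
#' @param nick_offset Distance (nt) from the PAM-proximal protospacer end to
#'   the nick; 3 for SpCas9 nickases.
#' @param spacer_len Protospacer length (default 20).
#' @return A data.frame with one row per site: `ref_id`, `strand`, `spacer`
#'   (protospacer strand, 5'->3'), `pam`, `spacer_start`, `spacer_end`,
#'   `pam_start`, `pam_end` (all 0-based half-open, top strand) and `nick`.
#'   Sorted by `nick`, then strand (`+` first).
#' @export
find_spacers <- function(ref, window = NULL, pam_pattern = "NGG",
                         nick_offset = 3L, spacer_len = 20L) {
  stopifnot(inherits(ref, "RefSeq"))
  n <- nchar(ref$seq)
  if (is.null(window)) window <- interval(0L, n)
  check_interval_within(window, ref, "window")
  plen <- nchar(pam_pattern)
  subj <- Biostrings::DNAString(ref$seq)

  empty <- data.frame(ref_id = character(), strand = character(),
                      spacer = character(), pam = character(),
                      spacer_start = integer(), spacer_end = integer(),
                      pam_start = integer(), pam_end = integer(),
                      nick = integer(), stringsAsFactors = FALSE)

  scan_one <- function(strand) {
    pat <- if (strand == "+") pam_pattern else revcomp(pam_pattern)
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                     fixed = "subject")
    p <- BiocGenerics::start(hits) - 1L  # 0-based PAM start on top strand
    if (length(p) == 0L) return(empty)
    if (strand == "+") {
      keep <- p >= spacer_len
      p <- p[keep]
      ss <- p - spacer_len
      se <- p
      nick <- p - nick_offset
      spacer <- substring(ref$seq, ss + 1L, se)
      pam <- substring(ref$seq, p + 1L, p + plen)
    } else {
      keep <- p + plen + spacer_len <= n
      p <- p[keep]
      ss <- p + plen
      se <- ss + spacer_len
      nick <- ss + nick_offset
      spacer <- vapply(seq_along(p), function(i)
        revcomp(substring(ref$seq, ss[i] + 1L, se[i])), "")
      pam <- vapply(seq_along(p), function(i)
        revcomp(substring(ref$seq, p[i] + 1L, p[i] + plen)), "")
    }
    if (!length(p)) return(empty)
    df <- data.frame(ref_id = ref$id, strand = strand, spacer = spacer,
                     pam = pam, spacer_start = ss, spacer_end = se,
                     pam_start = p, pam_end = p + plen, nick = as.integer(nick),
                     stringsAsFactors = FALSE)
    df[!grepl("N", df$spacer, fixed = TRUE), , drop = FALSE]
  }

  out <- rbind(scan_one("+"), scan_one("-"))
  out <- out[out$nick >= window$start & out$nick < window$end, , drop = FALSE]
  out <- out[order(out$nick, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nick coordinate of a spacer site
#'
#' For a `+` site with spacer starting at `s` the nick is `s + 17`; for a
#' `-` site with top-strand PAM starting at `p` it is `p + 6` (3-nt PAM).
#' Both follow from the blunt cut 3 nt 5' of the PAM on the protospacer
#' strand.
#'
#' @param site One row of the data.frame returned by [find_spacers()]
#'   (or any list with `strand`, `spacer_start`, `pam_start`, `pam_end`).
#' @param nick_offset Distance from the PAM-proximal protospacer end.
#' @return Integer 0-based top-strand nick coordinate.
#' @export
nick_coordinate <- function(site, nick_offset = 3L) {
  site <- as.list(site)
  if (site$strand == "+") {
    as.integer(site$pam_start - nick_offset)
  } else {
    as.integer(site$pam_end + nick_offset)
  }
}

#' Write a spacer site report
#'
#' TSV with 1-based coordinates for bench use.
#'
#' @param sites data.frame from [find_spacers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spacer_report <- function(sites, path) {
  rep <- data.frame(ref_id = sites$ref_id, strand = sites$strand,
                    spacer = sites$spacer, pam = sites$pam,
                    spacer_start = sites$spacer_start + 1L,
                    nick = sites$nick + 1L, stringsAsFactors = FALSE)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
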