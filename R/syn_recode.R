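#' CDS annotation for a locus
#'
#' Describes the coding region(s) of a reference in top-strand coordinates.
#' `frame_offset` trims incomplete leading bases (in transcription order)
#' before codons are formed; the remaining concatenated CDS need not end on
#' a codon boundary (a trailing partial codon is ignored).
#'
#' @param starts,ends 0-based half-open top-strand interval bounds (vectors,
#'   same length, non-overlapping, given in ascending order).
#' @param strand `"+"` or `"-"` (transcription strand).
#' @param frame_offset 0, 1 or 2.
#' @return An object of class `CdsAnnotation`.
#' @export
cds_annotation <- function(starts, ends, strand = "+", frame_offset = 0L) {
  stopifnot(length(starts) == length(ends), all(ends > starts),
            strand %in% c("+", "-"), frame_offset %in% 0:2)
  ord <- order(starts)
  starts <- as.integer(starts[ord]); ends <- as.integer(ends[ord])
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)]))
    stop("CDS intervals overlap")
  structure(list(starts = starts, ends = ends, strand = strand,
                 frame_offset = as.integer(frame_offset)),
            class = "CdsAnnotation")
}

#' Read a CDS annotation from GFF3 or simple TSV
#'
#' GFF3: rows with type `CDS` are used; phase of the first CDS row (in
#' transcription order) supplies `frame_offset`. TSV: columns `start`,
#' `end` (1-based inclusive), `strand`, and optionally `frame_offset`.
#'
#' @param path Path to a `.gff`/`.gff3` or `.tsv` file.
#' @return A [cds_annotation()].
#' @export
read_cds <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gff <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    cds <- gff[gff[[3]] == "CDS", , drop = FALSE]
    if (nrow(cds) == 0L) stop("no CDS rows in GFF3 file")
    strand <- cds[[7]][1]
    ord <- if (strand == "+") order(cds[[4]]) else order(-cds[[4]])
    phase <- suppressWarnings(as.integer(cds[[8]][ord][1]))
    if (is.na(phase)) phase <- 0L
    cds_annotation(cds[[4]] - 1L, cds[[5]], strand, phase)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    fo <- if ("frame_offset" %in% names(tab)) tab$frame_offset[1] else 0L
    cds_annotation(tab$start - 1L, tab$end, tab$strand[1], fo)
  }
}

# Genomic positions of every codon in coding order. Columns: codon string
# (coding strand), aa, gmin/gmax (top-strand span), contiguous flag.
codon_map <- function(ref, cds) {
  pos <- unlist(mapply(function(s, e) s:(e - 1L), cds$starts, cds$ends,
                       SIMPLIFY = FALSE))
  if (cds$strand == "-") pos <- rev(pos)
  if (cds$frame_offset > 0L) pos <- pos[-seq_len(cds$frame_offset)]
  ncod <- length(pos) %/% 3L
  if (ncod == 0L)
    return(data.frame(codon = character(), aa = character(),
                      gmin = integer(), gmax = integer(),
                      contiguous = logical()))
  pos <- pos[seq_len(ncod * 3L)]
  idx <- matrix(pos, nrow = 3L)
  bases <- strsplit(ref$seq, "")[[1]]
  # idx columns are already in coding order; on the minus strand that means
  # descending top-strand positions, so the codon is the per-base complement
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  codons <- vapply(seq_len(ncod), function(i) {
    b <- bases[idx[, i] + 1L]
    if (cds$strand == "-") b <- comp[b]
    paste(b, collapse = "")
  }, "")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  data.frame(codon = codons,
             aa = aa,
             gmin = apply(idx, 2L, min), gmax = apply(idx, 2L, max),
             contiguous = apply(idx, 2L, function(x) max(x) - min(x) == 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Patch intervals of a pegRNA pair
#'
#' The retained sequence between each nick and its deletion boundary, which
#' the RT templates must re-encode.
#'
#' @param deletion The intended deletion [interval()].
#' @param pair A `PegRNAPair` (or any list with `n_f`, `n_r`).
#' @return `list(left = [n_f, d_start), right = [d_end, n_r))`; either may
#'   be empty.
#' @export
patch_intervals <- function(deletion, pair) {
  n_f <- pair$n_f; n_r <- pair$n_r
  if (n_f > deletion$start || n_r < deletion$end)
    stop("nick inside intended deletion")
  list(left = interval(n_f, deletion$start),
       right = interval(deletion$end, n_r))
}

#' Load a codon-usage table
#'
#' The bundled default is an Oryza sativa usage table (frequencies per 1000
#' codons) transcribed from public codon-usage compilations; any table with
#' columns `codon`, `aa`, `per1000` may be supplied. Only within-family
#' ranks are used (substitution tie-breaks).
#'
#' @param path Optional path to a TSV; `NULL` loads the bundled table.
#' @return data.frame with columns `codon`, `aa`, `per1000`.
#' @export
load_codon_usage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "osativa_codon_usage.tsv",
                        package = "pegdel")
  read.delim(path, stringsAsFactors = FALSE)
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Synonymously recode patch regions (PDel/Syn)
#'
#' For every complete codon lying inside a patch interval, substitutes the
#' synonymous codon with maximal Hamming distance to the wild-type codon;
#' ties are broken by higher codon-usage rank, then lexicographically.
#' Codons with no synonymous alternative (ATG, TGG) are left unchanged and
#' flagged. Substitutions that would create a TTTT/AAAA run or regenerate a
#' full protospacer+PAM match to a supplied spacer are skipped with a note.
#' Partial codons at patch edges are never substituted.
#'
#' @param ref A [ref_seq()] record.
#' @param patches List of [interval()]s (e.g. from [patch_intervals()]).
#' @param cds A [cds_annotation()].
#' @param policy `"strict"` errors if patch bases fall outside the CDS;
#'   `"lenient"` (default) leaves them unchanged with a warning.
#' @param avoid_spacers Character vector of protospacer+PAM sequences the
#'   recoded sequence must not regenerate.
#' @param usage_table Codon-usage data.frame (see [load_codon_usage()]).
#' @return An object of class `SynPlan`: `$substitutions` data.frame
#'   (`codon_start` 0-based top-strand, `wt_codon`, `new_codon`, `aa`,
#'   `note`; codons on the coding strand), `$patch_intervals`, `$strand`.
#' @export
recode <- function(ref, patches, cds, policy = c("lenient", "strict"),
                   avoid_spacers = NULL, usage_table = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(ref, "RefSeq"), inherits(cds, "CdsAnnotation"))
  if (is.null(usage_table)) usage_table <- load_codon_usage()
  patches <- Filter(function(p) interval_len(p) > 0L, patches)
  for (p in patches) check_interval_within(p, ref, "patch")

  cmap <- codon_map(ref, cds)
  in_cds <- rep(FALSE, nchar(ref$seq))
  for (i in seq_along(cds$starts))
    in_cds[(cds$starts[i] + 1L):cds$ends[i]] <- TRUE
  for (p in patches) {
    if (interval_len(p) == 0L) next
    covered <- in_cds[(p$start + 1L):p$end]
    if (!all(covered)) {
      msg <- sprintf("patch [%s] has %d base(s) outside the CDS",
                     fmt1(p$start, p$end), sum(!covered))
      if (policy == "strict") stop(msg)
      warning(paste0(msg, "; left unchanged (policy = lenient)"))
    }
  }

  code <- Biostrings::GENETIC_CODE
  fam <- split(names(code), code)
  work <- ref$seq
  subs <- list()
  add <- function(cs, wt, new, aa, note)
    subs[[length(subs) + 1L]] <<- data.frame(
      codon_start = cs, wt_codon = wt, new_codon = new, aa = aa, note = note,
      stringsAsFactors = FALSE)

  for (ci in seq_len(nrow(cmap))) {
    cod <- cmap[ci, ]
    inside <- any(vapply(patches, function(p)
      cod$gmin >= p$start && cod$gmax < p$end, FALSE))
    if (!inside || !cod$contiguous) next
    aa <- cod$aa
    family <- fam[[aa]]
    if (length(family) <= 1L) {
      add(cod$gmin, cod$codon, cod$codon, aa, "no_synonymous_alternative")
      next
    }
    cands <- setdiff(family, cod$codon)
    hd <- vapply(cands, hamming, 0, b = cod$codon)
    cands <- cands[hd == max(hd)]
    usage <- usage_table$per1000[match(cands, usage_table$codon)]
    usage[is.na(usage)] <- 0
    cands <- cands[order(-usage, cands, method = "radix")]
    chosen <- cands[1]
    top_new <- if (cds$strand == "-") revcomp(chosen) else chosen
    trial <- work
    substr(trial, cod$gmin + 1L, cod$gmin + 3L) <- top_new
    lo <- max(0L, cod$gmin - 25L); hi <- min(nchar(trial), cod$gmin + 28L)
    win_old <- substr(work, lo + 1L, hi); win_new <- substr(trial, lo + 1L, hi)
    count_runs <- function(s) length(gregexpr("TTTT|AAAA", s)[[1]][
      gregexpr("TTTT|AAAA", s)[[1]] > 0])
    if (count_runs(win_new) > count_runs(win_old)) {
      add(cod$gmin, cod$codon, cod$codon, aa, "skipped_tttt_run")
      next
    }
    regen <- FALSE
    for (sp in avoid_spacers) {
      hits <- function(s) lengths(regmatches(s, gregexpr(sp, s, fixed = TRUE))) +
        lengths(regmatches(s, gregexpr(revcomp(sp), s, fixed = TRUE)))
      if (hits(win_new) > hits(win_old)) { regen <- TRUE; break }
    }
    if (regen) {
      add(cod$gmin, cod$codon, cod$codon, aa, "skipped_regenerates_target")
      next
    }
    work <- trial
    add(cod$gmin, cod$codon, chosen, aa, "")
  }

  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(codon_start = integer(), wt_codon = character(),
               new_codon = character(), aa = character(), note = character(),
               stringsAsFactors = FALSE)
  structure(list(substitutions = subs, patch_intervals = patches,
                 strand = cds$strand), class = "SynPlan")
}

#' @export
print.SynPlan <- function(x, ...) {
  eff <- sum(x$substitutions$new_codon != x$substitutions$wt_codon)
  cat(sprintf("SynPlan: %d codon(s) examined, %d substituted (%s strand)\n",
              nrow(x$substitutions), eff, x$strand))
  invisible(x)
}

#' Apply a synonymous-substitution plan to a reference
#'
#' Length-preserving; errors if substitutions overlap or the wild-type
#' codons do not match the reference.
#'
#' @param ref A [ref_seq()] record.
#' @param plan A `SynPlan` from [recode()].
#' @return The substituted sequence as a character string.
#' @export
apply_syn <- function(ref, plan) {
  stopifnot(inherits(ref, "RefSeq"), inherits(plan, "SynPlan"))
  subs <- plan$substitutions
  subs <- subs[subs$new_codon != subs$wt_codon, , drop = FALSE]
  seq <- ref$seq
  if (nrow(subs) == 0L) return(seq)
  if (any(subs$codon_start + 3L > nchar(seq)) || any(subs$codon_start < 0L))
    stop("substitution coordinates outside the reference")
  ord <- order(subs$codon_start)
  subs <- subs[ord, , drop = FALSE]
  if (any(diff(subs$codon_start) < 3L)) stop("overlapping substitutions")
  minus <- identical(plan$strand, "-")
  for (i in seq_len(nrow(subs))) {
    cs <- subs$codon_start[i]
    wt_top <- if (minus) revcomp(subs$wt_codon[i]) else subs$wt_codon[i]
    new_top <- if (minus) revcomp(subs$new_codon[i]) else subs$new_codon[i]
    if (substr(seq, cs + 1L, cs + 3L) != wt_top)
      stop(sprintf("wild-type codon mismatch at %d", cs + 1L))
    substr(seq, cs + 1L, cs + 3L) <- new_top
  }
  seq
}

#' Write a SynPlan TSV report (1-based coordinates)
#'
#' @param plan A `SynPlan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_syn_report <- function(plan, path) {
  out <- plan$substitutions
  out$codon_start <- out$codon_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
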