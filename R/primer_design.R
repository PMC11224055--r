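# SantaLucia (1998) unified nearest-neighbor parameters (kcal/mol; cal/mol/K),
# keyed by top-strand dinucleotide. Complementary pairs share values.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Primer melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` for sequences shorter than 14 nt;
#' nearest-neighbor thermodynamics (SantaLucia 1998 unified parameters,
#' terminal A/T penalty, entropy salt correction
#' `dS + 0.368 (N-1) ln[Na+]`) for longer sequences. The method used is
#' recorded in the `"method"` attribute.
#'
#' @param seq Primer sequence (A/C/G/T, length >= 4).
#' @param na_mM Monovalent cation concentration (mM).
#' @param primer_nM,template_nM Strand concentrations (nM); the annealing
#'   duplex concentration is `primer_nM - template_nM / 2` (or `primer_nM`
#'   for a self-complementary primer).
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temp("AAAA")  # 8
#' @export
melting_temp <- function(seq, na_mM = 50, primer_nM = 25, template_nM = 25) {
  seq <- validate_dna(seq)
  if (grepl("N", seq, fixed = TRUE)) stop("Tm undefined for sequences with N")
  n <- nchar(seq)
  if (n < 4L) stop("sequence too short for a Tm estimate (length >= 4)")
  b <- strsplit(seq, "")[[1]]
  if (n < 14L) {
    tm <- 2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
    attr(tm, "method") <- "wallace"
    return(tm)
  }
  dinuc <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[dinuc])
  ds <- sum(NN_DS[dinuc])
  for (term in c(b[1], b[n])) {
    if (term %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  selfcomp <- identical(seq, revcomp_chr(seq))
  if (selfcomp) ds <- ds - 1.4
  k <- if (selfcomp) primer_nM * 1e-9 else (primer_nM - template_nM / 2) * 1e-9
  ds <- ds + 0.368 * (n - 1) * log(na_mM * 1e-3)
  tm <- (1000 * dh) / (ds + 1.9872 * log(k)) - 273.15
  attr(tm, "method") <- "nearest_neighbor"
  tm
}

#' Primer design parameters
#'
#' @param len_range Allowed primer lengths (nt).
#' @param tm_target Preferred Tm band (degrees C; scoring).
#' @param tm_accept Hard Tm acceptance band (degrees C).
#' @param tm_diff_max Maximum |Tm_fwd - Tm_rev|.
#' @param min_3prime_past Minimum nt of a junction primer 3' of the junction.
#' @param product_range Acceptable amplicon sizes for the junction scheme.
#' @param flank_scan How far (nt) beyond each deletion boundary to scan for
#'   flanking primers.
#' @param long_threshold Deletion length (bp) at which the flanking scheme
#'   applies (shorter deletions use the junction scheme).
#' @param min_product_edited Minimum edited-allele product for gel resolution.
#' @param resolvable_ratio,resolvable_diff Gel-resolvability proxy at 2.0%
#'   agarose: WT/edited size ratio or absolute difference threshold.
#' @return A list of class `primer_params`.
#' @export
primer_params <- function(len_range = c(18L, 30L), tm_target = c(58, 62),
                          tm_accept = c(52, 68), tm_diff_max = 3,
                          min_3prime_past = 5L, product_range = c(120L, 500L),
                          flank_scan = 300L, long_threshold = 100L,
                          min_product_edited = 100L, resolvable_ratio = 1.2,
                          resolvable_diff = 100L) {
  structure(list(len_range = as.integer(len_range), tm_target = tm_target,
                 tm_accept = tm_accept, tm_diff_max = tm_diff_max,
                 min_3prime_past = as.integer(min_3prime_past),
                 product_range = as.integer(product_range),
                 flank_scan = as.integer(flank_scan),
                 long_threshold = as.integer(long_threshold),
                 min_product_edited = as.integer(min_product_edited),
                 resolvable_ratio = resolvable_ratio,
                 resolvable_diff = as.integer(resolvable_diff)),
            class = "primer_params")
}

# perfect-match count of a primer against either strand of a template
# (pass template_rc to avoid recomputing the reverse complement per call)
match_count <- function(primer, template, template_rc = revcomp(template)) {
  cnt <- function(p, s) {
    m <- gregexpr(p, s, fixed = TRUE)[[1]]
    sum(m > 0)
  }
  cnt(primer, template) + cnt(primer, template_rc)
}

tm_ok <- function(tm, params) tm >= params$tm_accept[1] && tm <= params$tm_accept[2]

# scoring: distance from the preferred band, plus a light GC-clamp preference
primer_score <- function(seq, tm, params) {
  pen <- max(0, params$tm_target[1] - tm, tm - params$tm_target[2])
  clamp <- substr(seq, nchar(seq), nchar(seq)) %in% c("G", "C")
  pen + if (clamp) 0 else 0.5
}

new_primer_pair <- function(fwd, rev, tm_fwd, tm_rev, product_wt,
                            product_edited, scheme) {
  structure(list(fwd = fwd, rev = rev, tm_fwd = as.numeric(tm_fwd),
                 tm_rev = as.numeric(tm_rev), product_wt = product_wt,
                 product_edited = product_edited, scheme = scheme),
            class = "PrimerPair")
}

#' @export
print.PrimerPair <- function(x, ...) {
  cat(sprintf("PrimerPair [%s]\n  fwd %s (Tm %.1f)\n  rev %s (Tm %.1f)\n  product WT: %s bp, edited: %s bp\n",
              x$scheme, x$fwd, x$tm_fwd, x$rev, x$tm_rev,
              ifelse(is.na(x$product_wt), "none", x$product_wt),
              ifelse(is.na(x$product_edited), "none", x$product_edited)))
  invisible(x)
}

# find the best reverse primer in template[from..] giving a product (measured
# from fwd_start) within size limits; returns list(seq, tm, end) or NULL
scan_reverse <- function(template, fwd_start, fwd_tm, from, size_min, size_max,
                         params, unique_in = template) {
  best <- NULL; best_score <- Inf
  n <- nchar(template)
  unique_rc <- revcomp(unique_in)
  for (d in seq(fwd_start + size_min, min(fwd_start + size_max, n))) {
    for (len in seq(params$len_range[1], params$len_range[2])) {
      c0 <- d - len
      if (c0 < from) next
      win <- substr(template, c0 + 1L, d)
      if (grepl("N", win, fixed = TRUE)) next
      primer <- revcomp_chr(win)
      tm <- as.numeric(melting_temp(primer))
      if (!tm_ok(tm, params) || abs(tm - fwd_tm) > params$tm_diff_max) next
      if (match_count(primer, unique_in, unique_rc) != 1L) next
      sc <- primer_score(primer, tm, params)
      if (sc < best_score) {
        best <- list(seq = primer, tm = tm, end = d); best_score <- sc
      }
    }
    if (!is.null(best) && best_score == 0) break
  }
  best
}

#' Junction-specific detection primers (short deletions)
#'
#' One primer spans the deletion junction with at least
#' `params$min_3prime_past` nt on its 3' side past the junction and has no
#' perfect match in the wild-type allele (either strand), so only precise
#' deletion templates amplify; the mate sits in the retained flank.
#'
#' @param wt Wild-type allele sequence.
#' @param edited Edited (deleted) allele sequence.
#' @param junction 0-based deletion junction coordinate in `edited`.
#' @param params A [primer_params()] list.
#' @return A `PrimerPair` with `scheme = "junction"` and `product_wt = NA`.
#' @export
junction_primers <- function(wt, edited, junction, params = primer_params()) {
  wt <- validate_dna(wt); edited <- validate_dna(edited)
  if (identical(wt, edited))
    stop("no junction novelty: wild-type and edited alleles are identical")
  n <- nchar(edited)
  wt_rc <- revcomp(wt)
  best_f <- NULL; best_f_score <- Inf
  diag_best_tm <- NA_real_
  for (b in seq(junction + params$min_3prime_past,
                min(junction + params$len_range[2] - 1L, n))) {
    for (len in seq(params$len_range[1], params$len_range[2])) {
      a <- b - len
      if (a < 0L || a > junction - 1L) next
      primer <- substr(edited, a + 1L, b)
      if (grepl("N", primer, fixed = TRUE)) next
      tm <- as.numeric(melting_temp(primer))
      if (is.na(diag_best_tm) || abs(tm - 60) < abs(diag_best_tm - 60))
        diag_best_tm <- tm
      if (!tm_ok(tm, params)) next
      if (grepl(primer, wt, fixed = TRUE) || grepl(primer, wt_rc, fixed = TRUE))
        next
      sc <- primer_score(primer, tm, params)
      if (sc < best_f_score) {
        best_f <- list(seq = primer, tm = tm, start = a, end = b)
        best_f_score <- sc
      }
    }
  }
  if (is.null(best_f))
    stop(sprintf(
      "no junction-spanning primer satisfies uniqueness/Tm (nearest-miss Tm %.1f C; accept band %.0f-%.0f C)",
      diag_best_tm, params$tm_accept[1], params$tm_accept[2]))
  rev <- scan_reverse(edited, best_f$start, best_f$tm, best_f$end,
                      params$product_range[1], params$product_range[2], params)
  if (is.null(rev))
    stop("no mate primer in the retained flank satisfies Tm/uniqueness")
  product <- rev$end - best_f$start
  new_primer_pair(best_f$seq, rev$seq, best_f$tm, rev$tm,
                  product_wt = NA_integer_, product_edited = product,
                  scheme = "junction")
}

#' Flanking detection primers (long deletions)
#'
#' Both primers sit outside the deletion in the wild-type allele; WT and
#' edited products differ by exactly the deletion length and must be
#' resolvable on a 2.0% agarose gel (size ratio >= `resolvable_ratio` or
#' absolute difference >= `resolvable_diff`, with the edited product at
#' least `min_product_edited` bp).
#'
#' @param wt Wild-type allele sequence.
#' @param deletion The programmed deletion [interval()] in `wt` coordinates.
#' @param params A [primer_params()] list.
#' @return A `PrimerPair` with `scheme = "flanking"`.
#' @export
flanking_primers <- function(wt, deletion, params = primer_params()) {
  wt <- validate_dna(wt)
  dl <- interval_len(deletion)
  if (dl < params$long_threshold)
    stop(sprintf("deletion of %d bp is below the flanking-scheme threshold (%d bp); use the junction scheme",
                 dl, params$long_threshold))
  check_interval_within(deletion, nchar(wt), "deletion")
  ds <- deletion$start; de <- deletion$end
  wt_rc <- revcomp(wt)
  best_f <- NULL; best_score <- Inf
  for (a in seq(max(0L, ds - params$flank_scan), ds - params$len_range[1])) {
    for (len in seq(params$len_range[1], params$len_range[2])) {
      if (a + len > ds) next
      primer <- substr(wt, a + 1L, a + len)
      if (grepl("N", primer, fixed = TRUE)) next
      tm <- as.numeric(melting_temp(primer))
      if (!tm_ok(tm, params)) next
      if (match_count(primer, wt, wt_rc) != 1L) next
      sc <- primer_score(primer, tm, params) + (ds - a) / 1000
      if (sc < best_score) {
        best_f <- list(seq = primer, tm = tm, start = a, end = a + len)
        best_score <- sc
      }
    }
  }
  if (is.null(best_f))
    stop("flanks too short: no acceptable forward primer upstream of the deletion")
  left_arm <- ds - best_f$start
  size_min <- dl + max(params$min_product_edited, left_arm + params$len_range[1])
  rev <- scan_reverse(wt, best_f$start, best_f$tm,
                      from = de,
                      size_min = size_min,
                      size_max = dl + left_arm + params$flank_scan, params)
  if (is.null(rev))
    stop("flanks too short: no acceptable reverse primer downstream of the deletion")
  product_wt <- rev$end - best_f$start
  product_edited <- product_wt - dl
  if (product_edited < params$min_product_edited ||
      !(product_wt / product_edited >= params$resolvable_ratio ||
        product_wt - product_edited >= params$resolvable_diff))
    stop("no primer placement yields gel-resolvable WT/edited products")
  new_primer_pair(best_f$seq, rev$seq, best_f$tm, rev$tm,
                  product_wt = product_wt, product_edited = product_edited,
                  scheme = "flanking")
}

#' Zygosity-confirmation primers
#'
#' One primer anneals inside the deleted region (wild-type allele only) and
#' the mate in the retained downstream flank; a product therefore reports
#' the presence of an undeleted allele, distinguishing homozygous deletions
#' (no product) from heterozygous plants.
#'
#' @param wt Wild-type allele sequence.
#' @param deletion The programmed deletion [interval()].
#' @param params A [primer_params()] list.
#' @return A `PrimerPair` with `scheme = "zygosity"`; `product_edited` is
#'   `NA` (the edited allele yields no product).
#' @export
zygosity_primers <- function(wt, deletion, params = primer_params()) {
  wt <- validate_dna(wt)
  check_interval_within(deletion, nchar(wt), "deletion")
  ds <- deletion$start; de <- deletion$end
  edited <- paste0(subseq0(wt, 0L, ds), subseq0(wt, de, nchar(wt)))
  edited_rc <- revcomp(edited)
  wt_rc <- revcomp(wt)
  best_f <- NULL; best_score <- Inf
  for (a in seq(ds, de - params$len_range[1])) {
    for (len in seq(params$len_range[1], params$len_range[2])) {
      if (a + len > de) next
      primer <- substr(wt, a + 1L, a + len)
      if (grepl("N", primer, fixed = TRUE)) next
      tm <- as.numeric(melting_temp(primer))
      if (!tm_ok(tm, params)) next
      if (match_count(primer, wt, wt_rc) != 1L) next
      if (grepl(primer, edited, fixed = TRUE) ||
          grepl(primer, edited_rc, fixed = TRUE)) next
      sc <- primer_score(primer, tm, params)
      if (sc < best_score) {
        best_f <- list(seq = primer, tm = tm, start = a, end = a + len)
        best_score <- sc
      }
    }
  }
  if (is.null(best_f))
    stop("no unique primer available inside the deleted region")
  rev <- scan_reverse(wt, best_f$start, best_f$tm, from = de,
                      size_min = max(params$product_range[1],
                                     de - best_f$start + params$len_range[1]),
                      size_max = de - best_f$start + params$flank_scan, params)
  if (is.null(rev))
    stop("no mate primer in the undeleted region satisfies Tm/uniqueness")
  new_primer_pair(best_f$seq, rev$seq, best_f$tm, rev$tm,
                  product_wt = rev$end - best_f$start,
                  product_edited = NA_integer_, scheme = "zygosity")
}

#' Choose and run the detection scheme the deletion length calls for
#'
#' Deletions shorter than `params$long_threshold` use junction-specific
#' primers; longer ones use flanking primers.
#'
#' @param wt Wild-type allele sequence.
#' @param deletion The programmed deletion [interval()].
#' @param params A [primer_params()] list.
#' @return A `PrimerPair`.
#' @export
detection_primers <- function(wt, deletion, params = primer_params()) {
  dl <- interval_len(deletion)
  if (dl >= params$long_threshold) {
    flanking_primers(wt, deletion, params)
  } else {
    edited <- paste0(subseq0(wt, 0L, deletion$start),
                     subseq0(wt, deletion$end, nchar(wt)))
    junction_primers(wt, edited, deletion$start, params)
  }
}

#' Write a primer report TSV
#'
#' @param pairs A `PrimerPair` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_report <- function(pairs, path) {
  if (inherits(pairs, "PrimerPair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p)
    data.frame(scheme = p$scheme, fwd = p$fwd, rev = p$rev,
               tm_fwd = round(p$tm_fwd, 1), tm_rev = round(p$tm_rev, 1),
               product_wt = p$product_wt, product_edited = p$product_edited,
               stringsAsFactors = FALSE))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
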