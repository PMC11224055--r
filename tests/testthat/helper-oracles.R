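# Independent oracles and fixture builders (no package internals used).

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, TRUE, prob = p), collapse = "")
}

# brute-force reverse complement
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force NGG site scan on both strands; returns data.frame of
# strand, spacer_start, pam_start (0-based) and nick coordinate
oracle_scan_ngg <- function(seq) {
  n <- nchar(seq)
  out <- list()
  b <- strsplit(seq, "")[[1]]
  for (p in 0:(n - 3)) {
    if (p >= 20 && b[p + 2] == "G" && b[p + 3] == "G")  # top strand xGG
      out[[length(out) + 1L]] <- data.frame(strand = "+",
                                            spacer_start = p - 20L,
                                            pam_start = p, nick = p - 3L)
    if (p + 23 <= n && b[p + 1] == "C" && b[p + 2] == "C")  # bottom: CCx
      out[[length(out) + 1L]] <- data.frame(strand = "-",
                                            spacer_start = p + 3L,
                                            pam_start = p, nick = p + 6L)
  }
  if (!length(out))
    return(data.frame(strand = character(), spacer_start = integer(),
                      pam_start = integer(), nick = integer()))
  do.call(rbind, out)
}

# direct string surgery for a deletion
oracle_surgery <- function(seq, d_start, d_end) {
  paste0(substr(seq, 1, d_start), substr(seq, d_end + 1, nchar(seq)))
}

# naive longest common substring length (for homology-reduction checks)
oracle_lcs <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  for (i in seq_len(na)) {
    if (best + 1L > na - i + 1L) break
    for (len in seq(best + 1L, na - i + 1L)) {
      if (grepl(substr(a, i, i + len - 1L), b, fixed = TRUE)) best <- len
      else break
    }
    if (i + best > na) break
  }
  best
}

# background with no NGG/CCN PAM anywhere: an ACGT repeat has no GG or CC
acgt_background <- function(n) {
  substr(strrep("ACGT", ceiling(n / 4)), 1, n)
}

# plant specific bases (character vector) at 0-based position
plant_bases <- function(seq, pos0, bases) {
  substr(seq, pos0 + 1, pos0 + nchar(bases)) <- bases
  seq
}

# locus with a + strand protospacer whose nick falls at `nick`, on an
# ACGT-repeat background: PAM "NGG" needs GG at nick+4, nick+5 (0-based);
# flanking A's prevent satellite PAMs against background G's
plant_plus_site <- function(seq, nick) plant_bases(seq, nick + 3L, "AGGA")

# and a - strand site with nick at `nick`: CC at nick-6, nick-5
plant_minus_site <- function(seq, nick) plant_bases(seq, nick - 7L, "ACCA")

# random CDS locus: flank + ATG + random non-stop codons + stop + flank
random_cds_locus <- function(n_codons = 60, flank = 60) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  body <- paste(sample(codons, n_codons, TRUE), collapse = "")
  cds <- paste0("ATG", body, "TAA")
  seq <- paste0(random_seq(flank), cds, random_seq(flank))
  list(ref = ref_seq("cds_locus", seq),
       cds = cds_annotation(flank, flank + nchar(cds), "+", 0L),
       cds_start = flank, cds_end = flank + nchar(cds))
}

# python/biopython bridge for independent cross-checks
run_python <- function(code) {
  system2("python", args = "-", input = code, stdout = TRUE, stderr = FALSE)
}
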