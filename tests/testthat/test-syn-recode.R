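test_that("patch intervals are the nick-to-boundary remainders", {
  del <- interval(10, 20)
  p <- patch_intervals(del, list(n_f = 8L, n_r = 23L))
  expect_equal(c(p$left$start, p$left$end), c(8L, 10L))
  expect_equal(c(p$right$start, p$right$end), c(20L, 23L))
  p0 <- patch_intervals(del, list(n_f = 10L, n_r = 20L))
  expect_equal(interval_len(p0$left), 0L)
  expect_equal(interval_len(p0$right), 0L)
  expect_error(patch_intervals(del, list(n_f = 12L, n_r = 23L)),
               "nick inside")
})

test_that("recode picks the documented codons for known families", {
  # CDS = ATG AAA GGG ATG TAA starting at 6
  seq <- paste0("ACGTCA", "ATGAAAGGGATGTAA", "TGCACG")
  ref <- ref_seq("r", seq)
  cds <- cds_annotation(6L, 21L, "+", 0L)
  plan <- recode(ref, list(interval(9L, 18L)), cds)
  subs <- plan$substitutions
  # Lys AAA -> AAG (single synonymous alternative)
  expect_equal(subs$new_codon[subs$wt_codon == "AAA"], "AAG")
  # Met ATG flagged, unchanged
  atg <- subs[subs$wt_codon == "ATG", ]
  expect_equal(atg$new_codon, "ATG")
  expect_equal(atg$note, "no_synonymous_alternative")
  # Gly GGG -> max-Hamming tie broken by usage rank then lexicographic,
  # verified against exhaustive enumeration of the codon table
  usage <- load_codon_usage()
  code <- Biostrings::GENETIC_CODE
  cands <- setdiff(names(code)[code == "G"], "GGG")
  hd <- vapply(cands, function(c)
    sum(strsplit(c, "")[[1]] != strsplit("GGG", "")[[1]]), 0)
  cands <- cands[hd == max(hd)]
  per <- usage$per1000[match(cands, usage$codon)]
  expected <- cands[order(-per, cands)][1]
  expect_equal(subs$new_codon[subs$wt_codon == "GGG"], expected)
  # protein unchanged
  edited <- apply_syn(ref, plan)
  expect_equal(translate_cds(substr(edited, 7, 21)),
               translate_cds(substr(seq, 7, 21)))
})

test_that("apply_syn is local, length-preserving, and validated", {
  seq <- paste0("ACGTCA", "ATGAAAGGGTAA", "TGCACG")
  ref <- ref_seq("r", seq)
  cds <- cds_annotation(6L, 18L, "+", 0L)
  plan <- recode(ref, list(interval(9L, 12L)), cds)  # covers AAA only
  out <- apply_syn(ref, plan)
  expect_equal(nchar(out), nchar(seq))
  diffs <- which(strsplit(out, "")[[1]] != strsplit(seq, "")[[1]])
  expect_true(all(diffs >= 10 & diffs <= 12))
  # empty plan is identity
  empty <- recode(ref, list(interval(6L, 6L)), cds)
  expect_equal(apply_syn(ref, empty), seq)
  # corrupting coordinates errors
  bad <- plan
  bad$substitutions$codon_start <- 0L
  expect_error(apply_syn(ref, bad), "mismatch")
})

test_that("recoding preserves the protein and reduces patch homology", {
  set.seed(17)
  for (i in 1:15) {
    loc <- random_cds_locus(n_codons = 50)
    # patch: a window of complete codons inside the CDS
    c0 <- loc$cds_start + 3L * sample(2:20, 1)
    patch <- interval(c0, c0 + 3L * sample(3:8, 1))
    plan <- recode(loc$ref, list(patch), loc$cds)
    edited <- apply_syn(loc$ref, plan)
    cds_wt <- substr(loc$ref$seq, loc$cds_start + 1, loc$cds_end)
    cds_ed <- substr(edited, loc$cds_start + 1, loc$cds_end)
    expect_equal(translate_cds(cds_ed), translate_cds(cds_wt))
    expect_equal(nchar(edited), nchar(loc$ref$seq))
    n_sub <- sum(plan$substitutions$new_codon != plan$substitutions$wt_codon)
    patch_wt <- substr(loc$ref$seq, patch$start + 1, patch$end)
    patch_ed <- substr(edited, patch$start + 1, patch$end)
    if (n_sub > 0)
      expect_lt(oracle_lcs(patch_wt, patch_ed), interval_len(patch))
  }
})

test_that("minus-strand CDS codons are recoded synonymously", {
  set.seed(23)
  # protein-coding on the bottom strand: build as revcomp of a + CDS
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds_plus <- paste0("ATG", paste(sample(codons, 30, TRUE), collapse = ""), "TAA")
  seq <- paste0(random_seq(40), revcomp(cds_plus), random_seq(40))
  ref <- ref_seq("m", seq)
  cds <- cds_annotation(40L, 40L + nchar(cds_plus), "-", 0L)
  patch <- interval(52L, 76L)
  plan <- recode(ref, list(patch), cds)
  expect_equal(plan$strand, "-")
  edited <- apply_syn(ref, plan)
  tr <- function(s) translate_cds(revcomp(substr(s, 41, 40 + nchar(cds_plus))))
  expect_equal(tr(edited), tr(seq))
  expect_gt(sum(plan$substitutions$new_codon != plan$substitutions$wt_codon), 0)
})

test_that("patches outside the CDS follow the policy", {
  loc <- random_cds_locus(n_codons = 40, flank = 50)
  outside <- interval(10L, 30L)
  expect_error(recode(loc$ref, list(outside), loc$cds, policy = "strict"),
               "outside the CDS")
  expect_warning(plan <- recode(loc$ref, list(outside), loc$cds,
                                policy = "lenient"),
                 "outside the CDS")
  expect_equal(sum(plan$substitutions$new_codon !=
                     plan$substitutions$wt_codon), 0L)
})

test_that("substitutions never regenerate a supplied protospacer+PAM", {
  # patch codon GGG would normally become GGC; forbid the 23-mer that the
  # substitution would create and check it is skipped with a note
  seq <- paste0("ACGTCA", "ATGAAAGGGATGTAA", "TGCACG")
  ref <- ref_seq("r", seq)
  cds <- cds_annotation(6L, 21L, "+", 0L)
  free <- recode(ref, list(interval(12L, 15L)), cds)
  chosen <- free$substitutions$new_codon[free$substitutions$wt_codon == "GGG"]
  would_be <- apply_syn(ref, free)
  avoid <- substr(would_be, 4, 26)   # 23-mer covering the recoded codon
  plan <- recode(ref, list(interval(12L, 15L)), cds, avoid_spacers = avoid)
  row <- plan$substitutions[plan$substitutions$wt_codon == "GGG", ]
  expect_true(row$new_codon != chosen || row$note != "")
})
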