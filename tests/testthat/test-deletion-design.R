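test_that("edited_allele is exact string surgery", {
  ref <- ref_seq("r", "AAAACCCCGGGG")
  expect_equal(edited_allele(ref, interval(4, 8)), "AAAAGGGG")
  expect_equal(edited_allele(ref, interval(0, 0)), ref$seq)
  expect_error(edited_allele(ref, interval(4, 20)), "exceeds")
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(200)
    d <- sort(sample(0:200, 2))
    expect_equal(edited_allele(ref_seq("r", s), interval(d[1], d[2])),
                 oracle_surgery(s, d[1], d[2]))
  }
})

test_that("build_pegrna derives RTT and PBS from the worked geometry", {
  # 30-nt locus: 18 A, 8 C (deleted), GTCA; + site nicking at 18
  ref <- ref_seq("r", paste0(strrep("A", 18), strrep("C", 8), "GTCA"))
  edited <- paste0(strrep("A", 18), "GTCA")
  site <- list(strand = "+", spacer = strrep("A", 20), pam = "NGG",
               spacer_start = -2L, spacer_end = 18L, pam_start = 21L,
               pam_end = 24L, nick = 18L)
  peg <- build_pegrna(ref, site, edited, junction_in_edited = 18L,
                      pbs_len = 8L, rtt_len = 4L,
                      rtt_bounds = c(4L, 60L))
  expect_equal(substr(peg$rtt, 1, 4), "TGAC")
  expect_equal(peg$pbs, revcomp(strrep("A", 8)))
  # revcomp(rtt) is the edited window at the nick, definitionally
  expect_equal(revcomp(peg$rtt), substr(edited, 19, 22))
  # bounds are enforced
  expect_error(build_pegrna(ref, site, edited, 18L, pbs_len = 0L,
                            rtt_len = 4L, rtt_bounds = c(4L, 60L)),
               "pbs_len")
  expect_error(build_pegrna(ref, site, edited, 18L, pbs_len = 8L,
                            rtt_len = 10L),
               "too long")
})

test_that("boundary-exact PAMs give a top design with empty patches", {
  n <- 300L
  ds <- 120L; de <- 170L
  seq <- acgt_background(n)
  seq <- plant_plus_site(seq, ds)    # + nick exactly at d_start
  seq <- plant_minus_site(seq, de)   # - nick exactly at d_end
  ref <- ref_seq("exact", seq)
  designs <- design_pdel(ref, interval(ds, de))
  top <- designs[[1]]
  expect_equal(interval_len(top$patches$left), 0L)
  expect_equal(interval_len(top$patches$right), 0L)
  expect_equal(top$edited_allele, oracle_surgery(seq, ds, de))
  expect_true(all(validate_design(top, ref)$pass))
})

test_that("nearest + nick 4 nt left of the boundary yields a 4-nt patch", {
  n <- 300L
  ds <- 120L; de <- 170L
  seq <- acgt_background(n)
  seq <- plant_plus_site(seq, ds - 4L)
  seq <- plant_minus_site(seq, de)
  ref <- ref_seq("patched", seq)
  designs <- design_pdel(ref, interval(ds, de))
  top <- designs[[1]]
  expect_equal(top$pair$n_f, ds - 4L)
  expect_equal(interval_len(top$patches$left), 4L)
  expect_equal(top$edited_allele, oracle_surgery(seq, ds, de))
  expect_true(all(validate_design(top, ref)$pass))
})

test_that("degenerate deletions are rejected", {
  ref <- ref_seq("r", acgt_background(100))
  expect_error(design_pdel(ref, interval(10, 300)), "exceeds")
  expect_error(design_pdel(ref, interval(10, 20)),  # below min_del
               "outside configured range")
})

test_that("PDel enumeration equals the cross-product of boundary sites", {
  set.seed(21)
  seq <- random_seq(600)
  ref <- ref_seq("r", seq)
  ds <- 250L; de <- 350L
  params <- pdel_params(max_designs = 1000L)
  designs <- tryCatch(design_pdel(ref, interval(ds, de), params),
                      error = function(e) list())
  oracle <- oracle_scan_ngg(seq)
  left <- oracle[oracle$strand == "+" & oracle$nick <= ds &
                   oracle$nick >= ds - params$window, ]
  right <- oracle[oracle$strand == "-" & oracle$nick >= de &
                    oracle$nick <= de + params$window, ]
  # pairs the RT-template bound can serve (patch + junction span <= rtt max)
  usable <- 0L
  for (nf in left$nick) for (nr in right$nick) {
    if (ds - nf + params$min_flap_span <= params$rtt_bounds[2] &&
        nr - de + params$min_flap_span <= params$rtt_bounds[2] &&
        nf >= params$pbs_len && nr + params$pbs_len <= nchar(seq))
      usable <- usable + 1L
  }
  expect_equal(length(designs), usable)
})

test_that("emitted PDel designs reconstruct the surgery oracle across lengths", {
  set.seed(31)
  lens <- c(50L, 100L, 500L, 1000L, 2000L)
  for (dl in lens) {
    locus_len <- max(1200L, dl + 600L)
    seq <- random_seq(locus_len)
    ref <- ref_seq(paste0("L", dl), seq)
    ds <- as.integer((locus_len - dl) / 2)
    designs <- tryCatch(design_pdel(ref, interval(ds, ds + dl)),
                        error = function(e) list())
    for (d in designs) {
      oracle <- oracle_surgery(seq, ds, ds + dl)
      expect_equal(d$edited_allele, oracle)
      expect_equal(reconstruct_allele(d, ref), oracle)
      expect_true(all(validate_design(d, ref)$pass))
      # deletion-length conservation
      expect_equal(nchar(seq) - nchar(d$edited_allele), dl)
    }
  }
})

test_that("PE3 designs span the junction and respect the nick offset window", {
  set.seed(13)
  seq <- random_seq(800)
  ref <- ref_seq("r", seq)
  designs <- design_pe3(ref, interval(350, 410))
  expect_gt(length(designs), 0L)
  for (d in designs) {
    off <- abs(d$pe3$nick_offset)
    expect_gte(off, 40L); expect_lte(off, 100L)
    expect_true(d$pe3$nick_sgrna$strand != d$pe3$pegrna$strand)
    m <- d$pe3$nick_sgrna$nick
    expect_true(m <= 350L || m >= 410L)
    expect_true(all(validate_design(d, ref)$pass))
    expect_equal(reconstruct_allele(d, ref), oracle_surgery(seq, 350, 410))
  }
})

test_that("a locus engineered for one PE3 geometry yields exactly one design", {
  # one + pegRNA site close to the deletion start, one - nicking site 60 nt
  # to its left; the - site is too far from the deletion end to serve as a
  # pegRNA itself, so enumeration yields a single design
  n <- 400L; ds <- 200L; de <- 260L
  seq <- acgt_background(n)
  seq <- plant_plus_site(seq, ds)
  seq <- plant_minus_site(seq, ds - 60L)
  ref <- ref_seq("one", seq)
  oracle <- oracle_scan_ngg(seq)
  expect_equal(nrow(oracle), 2L)   # fixture sanity: only the planted sites
  designs <- design_pe3(ref, interval(ds, de))
  expect_length(designs, 1L)
  expect_equal(designs[[1]]$pe3$pegrna$strand, "+")
  expect_equal(designs[[1]]$pe3$nick_offset, -60L)
  expect_true(all(validate_design(designs[[1]], ref)$pass))
})

test_that("validate_design flags a corrupted RT template", {
  seq <- plant_minus_site(plant_plus_site(acgt_background(300), 120L), 170L)
  ref <- ref_seq("v", seq)
  d <- design_pdel(ref, interval(120, 170))[[1]]
  bad <- d
  rtt <- bad$pair$fwd$rtt
  flip <- if (substr(rtt, 3, 3) == "A") "C" else "A"
  substr(bad$pair$fwd$rtt, 3, 3) <- flip
  rep <- validate_design(bad, ref)
  expect_false(rep$pass[rep$check == "fwd_rtt_matches_edited"])
  expect_true(all(validate_design(d, ref)$pass))
})

test_that("ranking prefers shorter patches, penalizes TTTT, and is stable", {
  seq <- plant_minus_site(plant_plus_site(acgt_background(300), 120L), 170L)
  ref <- ref_seq("rk", seq)
  base <- design_pdel(ref, interval(120, 170))[[1]]
  shift <- design_pdel(ref_seq("rk2", plant_plus_site(seq, 116L)),
                       interval(120, 170))
  # candidate with patch 0 must outrank the patch-4 candidate from the
  # same locus (identical background, so other penalties are equal)
  patches <- vapply(shift, function(d) interval_len(d$patches$left), 0L)
  expect_equal(patches[1], min(patches))

  # stability: identical candidates keep input order
  ranked <- rank_designs(list(base, base))
  expect_identical(ranked[[1]]$pair$n_f, ranked[[2]]$pair$n_f)
  expect_equal(ranked[[1]]$score, ranked[[2]]$score)

  # TTTT run in the extension is penalized against an equal candidate
  tttt <- base
  tttt$pair$fwd$extension <- paste0("TTTT", tttt$pair$fwd$extension)
  ranked2 <- rank_designs(list(tttt, base))
  expect_gt(ranked2[[2]]$score, ranked2[[1]]$score)  # best first
  expect_equal(ranked2[[1]]$pair$fwd$extension, base$pair$fwd$extension)

  expect_error(rank_designs(list()), "no candidate")
})
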