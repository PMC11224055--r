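test_that("Wallace-rule temperatures for short oligos", {
  expect_equal(as.numeric(melting_temp("AAAA")), 8)
  expect_equal(as.numeric(melting_temp("GGGG")), 16)
  expect_equal(attr(melting_temp("ACGTACGT"), "method"), "wallace")
  expect_error(melting_temp("ACG"), "length >= 4")
  expect_error(melting_temp("ACGTN"), "N")
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  set.seed(41)
  seqs <- c(vapply(1:8, function(i) random_seq(20), ""),
            vapply(1:4, function(i) random_seq(26, gc = 0.6), ""))
  mine <- vapply(seqs, function(s) as.numeric(melting_temp(s)), 0)
  code <- c("from Bio.SeqUtils import MeltingTemp as mt",
            sprintf("print(mt.Tm_NN('%s'))", seqs))
  theirs <- as.numeric(run_python(code))
  expect_equal(length(theirs), length(mine))
  expect_true(all(abs(mine - theirs) < 0.5))
  expect_equal(attr(melting_temp(seqs[1]), "method"), "nearest_neighbor")
})

test_that("junction primers are edited-specific with sound arithmetic", {
  set.seed(43)
  wt <- random_seq(400)
  del <- interval(170, 230)
  ed <- oracle_surgery(wt, 170, 230)
  pair <- junction_primers(wt, ed, 170)
  expect_equal(pair$scheme, "junction")
  expect_true(is.na(pair$product_wt))
  # exhaustive substring oracle: primer occurs in edited, never in wt
  expect_true(grepl(pair$fwd, ed, fixed = TRUE))
  expect_false(grepl(pair$fwd, wt, fixed = TRUE))
  expect_false(grepl(pair$fwd, oracle_revcomp(wt), fixed = TRUE))
  # mate anneals in the retained flank of both alleles
  expect_true(grepl(oracle_revcomp(pair$rev), ed, fixed = TRUE))
  # product size = distance between 5' ends + reverse primer length
  a <- as.integer(regexpr(pair$fwd, ed, fixed = TRUE)) - 1L
  cpos <- as.integer(regexpr(oracle_revcomp(pair$rev), ed, fixed = TRUE)) - 1L
  expect_equal(pair$product_edited, (cpos + nchar(pair$rev)) - a)
  expect_lte(abs(pair$tm_fwd - pair$tm_rev), 3)
  # zero-length deletion has no junction novelty
  expect_error(junction_primers(wt, wt, 170), "novelty")
})

test_that("flanking primers differ by exactly the deletion length", {
  set.seed(47)
  wt <- random_seq(3000)
  del <- interval(500, 2500)
  pair <- flanking_primers(wt, del)
  expect_equal(pair$product_wt - pair$product_edited, 2000L)
  expect_gte(pair$product_edited, 100L)
  # primers outside the deletion, unique in the wild type
  a <- regexpr(pair$fwd, wt, fixed = TRUE) - 1L
  expect_lte(a + nchar(pair$fwd), 500L)
  rpos <- regexpr(oracle_revcomp(pair$rev), wt, fixed = TRUE) - 1L
  expect_gte(rpos, 2500L)
  count_hits <- function(p)
    lengths(regmatches(wt, gregexpr(p, wt, fixed = TRUE))) +
    lengths(regmatches(wt, gregexpr(p, oracle_revcomp(wt), fixed = TRUE)))
  expect_equal(count_hits(pair$fwd), 1L)
  expect_equal(count_hits(oracle_revcomp(pair$rev)), 1L)
  # short deletions are redirected to the junction scheme
  expect_error(flanking_primers(wt, interval(500, 550)), "junction scheme")
})

test_that("zygosity primers amplify the wild type only", {
  set.seed(53)
  wt <- random_seq(1200)
  del <- interval(400, 700)
  pair <- zygosity_primers(wt, del)
  expect_equal(pair$scheme, "zygosity")
  expect_true(is.na(pair$product_edited))
  ed <- oracle_surgery(wt, 400, 700)
  expect_true(grepl(pair$fwd, wt, fixed = TRUE))
  expect_false(grepl(pair$fwd, ed, fixed = TRUE))
  expect_false(grepl(pair$fwd, oracle_revcomp(ed), fixed = TRUE))
})

test_that("junction scheme is sound across many random designs", {
  set.seed(59)
  n_ok <- 0L
  for (i in 1:30) {
    wt <- random_seq(400)
    dl <- sample(40:80, 1)
    ds <- sample(120:200, 1)
    ed <- oracle_surgery(wt, ds, ds + dl)
    pair <- tryCatch(junction_primers(wt, ed, ds), error = function(e) NULL)
    if (is.null(pair)) next
    n_ok <- n_ok + 1L
    expect_false(grepl(pair$fwd, wt, fixed = TRUE))
    expect_false(grepl(pair$fwd, oracle_revcomp(wt), fixed = TRUE))
  }
  expect_gt(n_ok, 20L)  # the scheme succeeds on most random loci
})

test_that("detection_primers dispatches on the length threshold", {
  set.seed(61)
  wt <- random_seq(2000)
  expect_equal(detection_primers(wt, interval(900, 960))$scheme, "junction")
  expect_equal(detection_primers(wt, interval(700, 1200))$scheme, "flanking")
})
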