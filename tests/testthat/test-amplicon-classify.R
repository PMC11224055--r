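fix_alleles <- function(seed = 2, locus_len = 700, ds = 350, dl = 150) {
  set.seed(seed)
  wt <- random_seq(locus_len)
  list(wt = wt, ed = oracle_surgery(wt, ds, ds + dl), j = ds, dl = dl)
}

test_that("exact reads classify by their source allele", {
  fx <- fix_alleles()
  r_ed <- substr(fx$ed, fx$j - 70, fx$j + 70)   # spans the junction
  r_wt <- substr(fx$wt, fx$j - 70, fx$j + 70)
  calls <- classify_reads(c(r_ed, r_wt), fx$wt, fx$ed, fx$j)
  expect_equal(calls$category, c("precise_deletion", "wt"))
  expect_equal(calls$edit_distance_best, c(0L, 0L))
})

test_that("a junction insertion is called as an indel with its signature", {
  fx <- fix_alleles()
  ins <- paste0(substr(fx$ed, 1, fx$j), "G",
                substr(fx$ed, fx$j + 1, nchar(fx$ed)))
  rd <- substr(ins, fx$j - 70, fx$j + 72)
  call <- classify_read(rd, fx$wt, fx$ed, fx$j)
  expect_equal(call$category, "indel")
  expect_match(call$allele_key, "^indel:\\+1@")
  del2 <- paste0(substr(fx$ed, 1, fx$j), substr(fx$ed, fx$j + 3, nchar(fx$ed)))
  rd2 <- substr(del2, fx$j - 70, fx$j + 70)
  call2 <- classify_read(rd2, fx$wt, fx$ed, fx$j)
  expect_equal(call2$category, "indel")
  expect_match(call2$allele_key, "^indel:-2@")
})

test_that("classification is strand-symmetric", {
  fx <- fix_alleles()
  reads <- c(substr(fx$ed, fx$j - 70, fx$j + 70),
             substr(fx$wt, fx$j - 70, fx$j + 70),
             substr(paste0(substr(fx$ed, 1, fx$j), "GT",
                           substr(fx$ed, fx$j + 1, nchar(fx$ed))),
                    fx$j - 70, fx$j + 72))
  fwd <- classify_reads(reads, fx$wt, fx$ed, fx$j)
  rev <- classify_reads(vapply(reads, oracle_revcomp, ""), fx$wt, fx$ed, fx$j)
  expect_equal(rev$category, fwd$category)
  expect_equal(rev$allele_key, fwd$allele_key)
})

test_that("reads matching both alleles resolve to wild type", {
  fx <- fix_alleles()
  shared <- substr(fx$wt, 50, 200)   # upstream of the deletion
  call <- classify_read(shared, fx$wt, fx$ed, fx$j)
  expect_equal(call$category, "wt")
})

test_that("degraded and short reads are set aside as other", {
  fx <- fix_alleles()
  expect_equal(classify_read(strrep("ACGT", 30), fx$wt, fx$ed, fx$j)$category,
               "other")
  expect_equal(classify_read("ACGTACGTAC", fx$wt, fx$ed, fx$j)$allele_key,
               "short_read")
  expect_error(classify_reads("ACGU", fx$wt, fx$ed, fx$j))
})

test_that("the 5% allele filter renormalizes and is idempotent", {
  fr <- c(wt = 0.50, precise_deletion = 0.46, `indel:+1@0` = 0.04)
  once <- filter_alleles(fr)
  expect_equal(sum(once), 1)
  expect_equal(length(once), 2L)
  expect_equal(filter_alleles(once), once)
  set.seed(67)
  for (i in 1:20) {
    x <- runif(sample(2:6, 1)); x <- x / sum(x)
    names(x) <- paste0("a", seq_along(x))
    expect_equal(filter_alleles(filter_alleles(x)), filter_alleles(x))
  }
})

test_that("genotype rules follow the documented thresholds", {
  mk2 <- function(...) {
    kv <- c(...)
    data.frame(category = ifelse(startsWith(names(kv), "indel"), "indel",
                                 names(kv)),
               allele_key = names(kv), stringsAsFactors = FALSE)[
                 rep(seq_along(kv), kv), ]
  }
  expect_equal(call_plant(mk2(precise_deletion = 100))$genotype, "homozygous")
  expect_equal(call_plant(mk2(precise_deletion = 50, wt = 50))$genotype,
               "heterozygous")
  expect_equal(call_plant(mk2(precise_deletion = 40, `indel:+1@0` = 35,
                              wt = 25))$genotype, "chimeric")
  expect_equal(call_plant(mk2(wt = 100))$genotype, "wt")
  expect_equal(call_plant(mk2(wt = 97, precise_deletion = 3))$genotype, "wt")
  expect_equal(call_plant(mk2(precise_deletion = 75, wt = 25))$genotype,
               "chimeric")
  expect_equal(call_plant(mk2(wt = 20))$genotype, "low_depth")
})

test_that("cohort summary reproduces the worked 10-plant example", {
  plant <- function(id, geno, fr) {
    structure(list(plant_id = id, n_reads = 200L, allele_fractions = fr,
                   genotype = geno), class = "PlantCall")
  }
  plants <- c(
    lapply(1:3, function(i) plant(paste0("H", i), "homozygous",
                                  c(precise_deletion = 1))),
    list(plant("E1", "heterozygous", c(precise_deletion = 0.5, wt = 0.5))),
    list(plant("C1", "chimeric", c(precise_deletion = 0.4, `indel:+1@0` = 0.3,
                                   wt = 0.3))),
    lapply(1:2, function(i) plant(paste0("I", i), "homozygous",
                                  c(`indel:-2@0` = 1))),
    lapply(1:3, function(i) plant(paste0("W", i), "wt", c(wt = 1))))
  s <- summarize_cohort(plants, "toy")
  expect_equal(s$n_samples, 10L)
  expect_equal(s$pct_precise, 50)
  expect_gte(s$pct_indel, 20)
  expect_equal(s$pct_homo, 60)
  expect_equal(s$pct_het, 20)
  expect_equal(s$pct_chimeric, 20)
  expect_equal(s$pct_homo + s$pct_het + s$pct_chimeric, 100)
})

test_that("all-wild-type cohorts report zero with a flag", {
  plants <- lapply(1:4, function(i)
    structure(list(plant_id = paste0("w", i), n_reads = 200L,
                   allele_fractions = c(wt = 1), genotype = "wt"),
              class = "PlantCall"))
  s <- summarize_cohort(plants)
  expect_equal(s$pct_precise, 0)
  expect_true(s$no_precise_edits)
  expect_equal(s$pct_homo + s$pct_het + s$pct_chimeric, 0)
  expect_error(summarize_cohort(list()), "no plant calls")
})
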