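# deterministic largest-remainder apportionment of n into shares
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    ord <- order(-(raw - base), seq_along(raw), method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Simulate the amplicon reads of one plant
#'
#' Reads are windows of the sampled allele covering its junction, with
#' i.i.d. substitution errors. Per-allele read counts are apportioned
#' deterministically (largest remainder) by default, so that emitted read
#' proportions equal the truth fractions exactly whenever
#' `depth * fraction` is integral; `sampling = "multinomial"` draws them
#' instead. Fully reproducible for a fixed `seed`.
#'
#' @param alleles Character vector of allele sequences.
#' @param fractions Numeric vector summing to 1.
#' @param depth Number of reads.
#' @param error_rate Per-base substitution probability (0..0.1).
#' @param read_len Read length (nt).
#' @param junctions 0-based junction coordinate each read window must cover,
#'   one per allele (default: midpoint of each allele).
#' @param seed Optional integer seed (local RNG scope).
#' @param sampling `"exact"` (default) or `"multinomial"`.
#' @return data.frame with `read` (sequence) and `allele` (1-based index of
#'   the source allele).
#' @export
simulate_plant_reads <- function(alleles, fractions, depth = 200L,
                                 error_rate = 0, read_len = 150L,
                                 junctions = NULL, seed = NULL,
                                 sampling = c("exact", "multinomial")) {
  sampling <- match.arg(sampling)
  stopifnot(length(alleles) == length(fractions), depth >= 1L,
            error_rate >= 0, error_rate <= 0.1)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("allele fractions must sum to 1")
  if (is.null(junctions))
    junctions <- vapply(alleles, function(a) nchar(a) %/% 2L, 0L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  counts <- if (sampling == "exact") apportion(depth, fractions) else
    as.integer(stats::rmultinom(1L, depth, fractions))
  src <- rep(seq_along(alleles), counts)
  src <- src[sample.int(length(src))]
  bases <- c("A", "C", "G", "T")
  reads <- character(depth)
  for (i in seq_len(depth)) {
    a <- alleles[src[i]]
    n <- nchar(a)
    rl <- min(read_len, n)
    j <- junctions[src[i]]
    # window must cover the junction with a few bases on each side
    m <- min(5L, rl %/% 4L)
    lo <- max(0L, min(j + m, n) - rl)
    hi <- min(n - rl, max(0L, j - m))
    if (hi < lo) hi <- lo
    start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    read <- substr(a, start + 1L, start + rl)
    if (error_rate > 0) {
      nerr <- stats::rbinom(1L, rl, error_rate)
      if (nerr > 0L) {
        pos <- sample.int(rl, nerr)
        rb <- strsplit(read, "")[[1]]
        for (p in pos)
          rb[p] <- sample(setdiff(bases, rb[p]), 1L)
        read <- paste(rb, collapse = "")
      }
    }
    reads[i] <- read
  }
  data.frame(read = reads, allele = src, stringsAsFactors = FALSE)
}

#' Cohort simulation specification
#'
#' Study conditions default to the amplicon screen this package models:
#' ~200x depth per plant, heterozygous plants as a 50/50 edited/wild-type
#' mix, chimeric plants as a 3-way mix (edited, wild type, one indel
#' allele) with every component at least 10%.
#'
#' @param wt,edited Allele sequences.
#' @param junction_wt,junction_edited 0-based junction coordinates reads
#'   must cover (deletion start in `wt`, junction in `edited`).
#' @param n_plants Number of plants.
#' @param genotype_mix Named proportions over
#'   `homozygous`/`heterozygous`/`chimeric`/`wt`; must sum to 1.
#' @param indel_menu List of `c(offset, net)` indel signatures used to build
#'   imprecise alleles from the edited allele (net > 0 insertion, < 0
#'   deletion, at junction+offset).
#' @param depth Reads per plant.
#' @param error_rate Per-base substitution probability.
#' @param read_len Read length.
#' @param seed Integer seed.
#' @return A list of class `CohortSpec`.
#' @export
cohort_spec <- function(wt, edited, junction_wt, junction_edited,
                        n_plants = 20L,
                        genotype_mix = c(homozygous = 0.25,
                                         heterozygous = 0.25,
                                         chimeric = 0.25, wt = 0.25),
                        indel_menu = list(c(0L, 1L), c(0L, -2L)),
                        depth = 200L, error_rate = 0, read_len = 150L,
                        seed = 1L) {
  if (abs(sum(genotype_mix) - 1) > 1e-9)
    stop("genotype_mix proportions must sum to 1")
  stopifnot(depth >= 1L, error_rate >= 0, error_rate <= 0.1)
  structure(list(wt = wt, edited = edited, junction_wt = junction_wt,
                 junction_edited = junction_edited,
                 n_plants = as.integer(n_plants),
                 genotype_mix = genotype_mix, indel_menu = indel_menu,
                 depth = as.integer(depth), error_rate = error_rate,
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "CohortSpec")
}

# imprecise allele: net indel applied to the edited allele at junction+offset
indel_allele <- function(edited, junction, offset, net) {
  p <- junction + offset
  if (net > 0L) {
    ins <- paste(rep(c("T", "G", "A", "C"), length.out = net), collapse = "")
    paste0(subseq0(edited, 0L, p), ins, subseq0(edited, p, nchar(edited)))
  } else {
    paste0(subseq0(edited, 0L, p), subseq0(edited, p - net, nchar(edited)))
  }
}

#' Simulate a transgenic-plant cohort with known truth
#'
#' Writes one FASTQ per plant (constant Q30 qualities) plus a truth TSV.
#' Genotype realizations: homozygous = 100% edited; heterozygous = 50/50
#' edited/wild type; chimeric = random 3-way mix of edited, wild type and
#' one indel allele, each component >= 10%; wt = 100% wild type. Genotype
#' counts follow `genotype_mix` by largest-remainder apportionment and are
#' assigned to plants in a seeded random order.
#'
#' @param spec A [cohort_spec()].
#' @param outdir Output directory (created if needed).
#' @return list(truth = data.frame, fastq = character paths, alleles =
#'   named allele sequences), invisibly.
#' @export
simulate_cohort <- function(spec, outdir) {
  stopifnot(inherits(spec, "CohortSpec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create outdir: %s", outdir))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  genos <- rep(names(spec$genotype_mix),
               apportion(spec$n_plants, as.numeric(spec$genotype_mix)))
  genos <- genos[sample.int(length(genos))]

  indel_seqs <- vapply(spec$indel_menu, function(m)
    indel_allele(spec$edited, spec$junction_edited, m[1], m[2]), "")
  indel_junc <- vapply(spec$indel_menu, function(m)
    as.integer(spec$junction_edited + m[1] + max(0, m[2])), 0L)
  indel_names <- vapply(spec$indel_menu, function(m)
    sprintf("indel%+d@%+d", m[2], m[1]), "")

  truth <- list(); paths <- character(spec$n_plants)
  for (i in seq_len(spec$n_plants)) {
    pid <- sprintf("plant_%03d", i)
    g <- genos[i]
    if (g == "homozygous") {
      seqs <- spec$edited; fr <- 1; jn <- spec$junction_edited
      labels <- "precise_deletion"
    } else if (g == "heterozygous") {
      seqs <- c(spec$edited, spec$wt); fr <- c(0.5, 0.5)
      jn <- c(spec$junction_edited, spec$junction_wt)
      labels <- c("precise_deletion", "wt")
    } else if (g == "chimeric") {
      k <- sample.int(length(indel_seqs), 1L)
      u <- runif(3)
      fr <- 0.1 + 0.7 * u / sum(u)
      seqs <- c(spec$edited, spec$wt, indel_seqs[k])
      jn <- c(spec$junction_edited, spec$junction_wt, indel_junc[k])
      labels <- c("precise_deletion", "wt", indel_names[k])
    } else {
      seqs <- spec$wt; fr <- 1; jn <- spec$junction_wt
      labels <- "wt"
    }
    sim <- simulate_plant_reads(seqs, fr, spec$depth, spec$error_rate,
                                spec$read_len, jn)
    reads <- Biostrings::DNAStringSet(sim$read)
    names(reads) <- sprintf("%s_read%04d", pid, seq_along(sim$read))
    qual <- Biostrings::PhredQuality(
      Biostrings::BStringSet(strrep("?", nchar(sim$read))))
    path <- file.path(outdir, paste0(pid, ".fastq"))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(reads, qual), path)
    paths[i] <- path
    truth[[i]] <- data.frame(
      plant_id = pid, genotype = g,
      alleles = paste(labels, collapse = ";"),
      fractions = paste(sprintf("%.6g", fr), collapse = ";"),
      fastq = basename(path), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, fastq = paths,
                 alleles = c(wt = spec$wt, edited = spec$edited,
                             setNames(indel_seqs, indel_names))))
}

#' Genotype recovery of the classifier on a simulated cohort
#'
#' Convenience wrapper: simulates a cohort, classifies every plant, and
#' returns the fraction of plants whose called genotype equals the truth.
#'
#' @param spec A [cohort_spec()].
#' @param params A [classify_params()] list.
#' @param outdir Directory for the simulated FASTQs (default: tempdir).
#' @return list(recovery = fraction correct, plants = `PlantCall` list,
#'   truth = data.frame, summary = `CohortSummary`).
#' @export
genotype_recovery <- function(spec, params = classify_params(),
                              outdir = tempfile("cohort")) {
  sim <- simulate_cohort(spec, outdir)
  plants <- lapply(seq_len(nrow(sim$truth)), function(i)
    classify_fastq(file.path(outdir, sim$truth$fastq[i]), spec$wt,
                   spec$edited, spec$junction_edited,
                   sim$truth$plant_id[i], params))
  called <- vapply(plants, `[[`, "", "genotype")
  list(recovery = mean(called == sim$truth$genotype), plants = plants,
       truth = sim$truth, summary = summarize_cohort(plants))
}
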