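#' Classifier parameters
#'
#' Zygosity thresholds target diploid expectations at the ~200x amplicon
#' depth typical of plant editing screens; all are configurable.
#'
#' @param junction_window Half-width (nt) of the window around the deletion
#'   junction in which an alignment gap marks a read as an indel outcome.
#' @param max_mismatch_frac Maximum substitution fraction for a confident
#'   wt / precise-deletion call.
#' @param max_dist_frac Reads whose best edit distance exceeds this fraction
#'   of their length are set aside as `other`.
#' @param min_read_len Reads shorter than this are set aside as `other`.
#' @param allele_filter Alleles below this read fraction are filtered out
#'   (the 5% allele filter).
#' @param min_reads Plants with fewer reads are called `low_depth`.
#' @param wt_frac Minimum wild-type fraction for a `wt` call.
#' @param homo_frac Minimum single-allele fraction for a homozygous call.
#' @param het_band Fraction band both alleles must occupy for a
#'   heterozygous call.
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(junction_window = 10L, max_mismatch_frac = 0.1,
                            max_dist_frac = 0.2, min_read_len = 50L,
                            allele_filter = 0.05, min_reads = 50L,
                            wt_frac = 0.95, homo_frac = 0.90,
                            het_band = c(0.35, 0.65)) {
  structure(list(junction_window = as.integer(junction_window),
                 max_mismatch_frac = max_mismatch_frac,
                 max_dist_frac = max_dist_frac,
                 min_read_len = as.integer(min_read_len),
                 allele_filter = allele_filter,
                 min_reads = as.integer(min_reads), wt_frac = wt_frac,
                 homo_frac = homo_frac, het_band = het_band),
            class = "classify_params")
}

# Best ungapped placement of a read on a reference by seed-and-extend:
# exact 16-mer seeds anchor candidate offsets, mismatches are counted at
# each anchored offset, and the minimum within max_mm is returned (or NULL).
best_ungapped <- function(rd, subj_chr, max_mm) {
  rl <- nchar(rd)
  n <- nchar(subj_chr)
  rd_raw <- charToRaw(rd)
  best <- NULL
  seen <- integer(0)
  for (s0 in unique(pmax(1L, c(1L, 17L, 33L, rl - 15L)))) {
    if (s0 + 15L > rl) next
    hits <- gregexpr(substr(rd, s0, s0 + 15L), subj_chr, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      o <- h - s0 + 1L
      if (o < 1L || o + rl - 1L > n || o %in% seen) next
      seen <- c(seen, o)
      mm <- sum(charToRaw(substr(subj_chr, o, o + rl - 1L)) != rd_raw)
      if (mm <= max_mm && (is.null(best) || mm < best$mismatches))
        best <- list(mismatches = as.integer(mm), start0 = o - 1L)
    }
    if (!is.null(best) && best$mismatches <= 1L) break
  }
  best
}

# Batch gapped alignment of reads to one reference; returns per-read list
# of score, edit stats and indel ops with 0-based subject coordinates.
gapped_alignments <- function(pats, subj, submat) {
  a <- Biostrings::pairwiseAlignment(pats, subj, type = "global-local",
                                     substitutionMatrix = submat,
                                     gapOpening = 4, gapExtension = 1)
  ins_l <- Biostrings::insertion(a)     # pattern-frame ranges
  del_l <- Biostrings::deletion(a)
  sub0 <- BiocGenerics::start(Biostrings::subject(a)) - 1L
  sc <- BiocGenerics::score(a)
  mm <- Biostrings::nmismatch(a)
  lapply(seq_along(pats), function(i) {
    ins <- ins_l[[i]]; del <- del_l[[i]]
    ops <- list()
    if (length(ins) || length(del)) {
      tab <- rbind(
        if (length(ins)) data.frame(type = "ins",
                                    ps = BiocGenerics::start(ins),
                                    len = BiocGenerics::width(ins)),
        if (length(del)) data.frame(type = "del",
                                    ps = BiocGenerics::start(del),
                                    len = BiocGenerics::width(del)))
      tab <- tab[order(tab$ps), , drop = FALSE]
      shift <- sub0[i]
      for (k in seq_len(nrow(tab))) {
        ops[[length(ops) + 1L]] <- list(type = tab$type[k],
                                        pos = tab$ps[k] - 1L + shift,
                                        len = tab$len[k])
        shift <- shift + if (tab$type[k] == "ins") -tab$len[k] else tab$len[k]
      }
    }
    gap_cols <- sum(vapply(ops, `[[`, 0L, "len"))
    list(score = sc[i], mismatches = mm[i], gap_cols = gap_cols, ops = ops)
  })
}

#' Classify amplicon reads against wild-type and edited alleles
#'
#' Each read (and its reverse complement) is placed on both references;
#' the reference with the better placement wins, ties favoring wild type
#' (a read matching both carries no deletion evidence). Placement is
#' tiered for speed: exact substring match, then the best ungapped
#' placement within the mismatch budget, then semi-global gapped alignment
#' for reads neither admits (indel outcomes). A read is a
#' `precise_deletion` when the edited allele wins with a mismatch-only
#' junction window; an `indel` when the winning alignment has a gap inside
#' the target window (the junction window on the edited allele, the deleted
#' region on the wild type); `other` when the best edit distance is too
#' large or the read too short.
#'
#' @param reads Character vector (or `DNAStringSet`) of reads.
#' @param wt,edited Allele sequences.
#' @param junction 0-based deletion junction coordinate in `edited`
#'   (equals the deletion start in `wt`).
#' @param params A [classify_params()] list.
#' @return data.frame with one row per read: `category`, `allele_key`,
#'   `edit_distance_best`.
#' @export
classify_reads <- function(reads, wt, edited, junction,
                           params = classify_params()) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads))
  if (length(reads) == 0L)
    return(data.frame(category = character(), allele_key = character(),
                      edit_distance_best = integer()))
  reads <- toupper(reads)
  wt <- validate_dna(wt); edited <- validate_dna(edited)
  pats_all <- tryCatch(Biostrings::DNAStringSet(reads),
                       error = function(e) stop("non-DNA read: ",
                                                conditionMessage(e)))
  if (any(grepl("[^ACGTN]", reads)))
    stop("non-DNA read: only A/C/G/T/N accepted")
  rcs_all <- as.character(Biostrings::reverseComplement(pats_all))
  dl <- nchar(wt) - nchar(edited)
  w <- params$junction_window
  subj <- list(wt = Biostrings::DNAString(wt),
               edited = Biostrings::DNAString(edited))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)

  decide_ungapped <- function(ref, mismatches, rl) {
    if (mismatches > params$max_dist_frac * rl ||
        mismatches > params$max_mismatch_frac * rl)
      c("other", "other", mismatches)
    else if (ref == "edited")
      c("precise_deletion", "precise_deletion", mismatches)
    else c("wt", "wt", mismatches)
  }

  category <- character(length(reads))
  allele_key <- character(length(reads))
  dist_best <- rep(NA_integer_, length(reads))
  tier3 <- integer(0)
  rcs <- character(length(reads))

  for (i in seq_along(reads)) {
    rd <- reads[i]
    rl <- nchar(rd)
    if (rl < params$min_read_len) {
      category[i] <- "other"; allele_key[i] <- "short_read"
      next
    }
    rc <- rcs_all[i]; rcs[i] <- rc
    # tier 1: exact substring (wt checked first so that junction-blind
    # reads, which match both alleles, resolve to wt)
    res <- NULL
    for (ref in c("wt", "edited")) {
      if (grepl(rd, c(wt = wt, edited = edited)[[ref]], fixed = TRUE) ||
          grepl(rc, c(wt = wt, edited = edited)[[ref]], fixed = TRUE)) {
        res <- decide_ungapped(ref, 0L, rl)
        break
      }
    }
    # tier 2: best ungapped placement within the mismatch budget
    if (is.null(res)) {
      max_mm <- floor(params$max_mismatch_frac * rl)
      best <- NULL; best_ref <- NULL
      for (ref in c("wt", "edited")) {
        for (k in 1:2) {
          h <- best_ungapped(if (k == 1L) rd else rc,
                             c(wt = wt, edited = edited)[[ref]], max_mm)
          if (!is.null(h) &&
              (is.null(best) || h$mismatches < best$mismatches)) {
            best <- h; best_ref <- ref
          }
        }
      }
      if (!is.null(best))
        res <- decide_ungapped(best_ref, best$mismatches, rl)
    }
    if (is.null(res)) {
      tier3 <- c(tier3, i)
    } else {
      category[i] <- res[1]; allele_key[i] <- res[2]
      dist_best[i] <- as.integer(res[3])
    }
  }

  # tier 3: batched gapped alignment (indel outcomes and degraded reads)
  if (length(tier3)) {
    galn <- list(
      wt_f = gapped_alignments(Biostrings::DNAStringSet(reads[tier3]),
                               subj$wt, submat),
      wt_r = gapped_alignments(Biostrings::DNAStringSet(rcs[tier3]),
                               subj$wt, submat),
      ed_f = gapped_alignments(Biostrings::DNAStringSet(reads[tier3]),
                               subj$edited, submat),
      ed_r = gapped_alignments(Biostrings::DNAStringSet(rcs[tier3]),
                               subj$edited, submat))
    for (t in seq_along(tier3)) {
      i <- tier3[t]
      best <- NULL; best_ref <- NULL
      for (nm in names(galn)) {
        g <- galn[[nm]][[t]]
        if (is.null(best) || g$score > best$score) {
          best <- g
          best_ref <- if (startsWith(nm, "wt")) "wt" else "edited"
        }
      }
      dist <- best$mismatches + best$gap_cols
      win <- if (best_ref == "edited") c(junction - w, junction + w)
             else c(junction - w, junction + dl + w)
      in_win <- Filter(function(op)
        op$pos >= win[1] && op$pos <= win[2], best$ops)
      if (dist > params$max_dist_frac * nchar(reads[i])) {
        category[i] <- "other"; allele_key[i] <- "other"
      } else if (length(in_win) > 0L) {
        net <- sum(vapply(in_win, function(op)
          if (op$type == "ins") op$len else -op$len, 0L))
        category[i] <- "indel"
        allele_key[i] <- sprintf("indel:%+d@%d", net,
                                 in_win[[1]]$pos - junction)
      } else {
        # gap far from any junction, or mismatch-heavy: uninformative
        category[i] <- "other"; allele_key[i] <- "other"
      }
      dist_best[i] <- as.integer(dist)
    }
  }
  data.frame(category = category, allele_key = allele_key,
             edit_distance_best = dist_best, stringsAsFactors = FALSE)
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read A single read.
#' @return One-row data.frame (see [classify_reads()]).
#' @export
classify_read <- function(read, wt, edited, junction,
                          params = classify_params()) {
  classify_reads(read, wt, edited, junction, params)
}

#' Apply the 5% allele filter
#'
#' Drops alleles below `thresh` of reads and renormalizes; idempotent.
#'
#' @param fractions Named numeric vector of allele fractions.
#' @param thresh Filter threshold (default 0.05).
#' @return Renormalized named fractions.
#' @export
filter_alleles <- function(fractions, thresh = 0.05) {
  kept <- fractions[fractions >= thresh]
  if (length(kept) == 0L) return(kept)
  kept / sum(kept)
}

#' Call one plant's genotype from its read classifications
#'
#' Reads classified `other` are excluded from allele fractions; alleles
#' below the 5% filter are dropped and the remainder renormalized. Default
#' rules: `wt` when the wild-type fraction is at least `wt_frac`;
#' homozygous when one non-wild-type allele reaches `homo_frac`;
#' heterozygous when exactly one non-wild-type allele and both it and wild
#' type lie inside `het_band`; chimeric otherwise while a non-wild-type
#' allele survives; `low_depth` when fewer than `min_reads` reads.
#'
#' @param calls data.frame from [classify_reads()].
#' @param plant_id Plant identifier.
#' @param params A [classify_params()] list.
#' @return An object of class `PlantCall`: `plant_id`, `n_reads`,
#'   `allele_fractions` (named, post-filter), `genotype`.
#' @export
call_plant <- function(calls, plant_id = "plant",
                       params = classify_params()) {
  n_reads <- nrow(calls)
  informative <- calls[calls$category != "other", , drop = FALSE]
  fr <- numeric(0)
  if (nrow(informative) > 0L) {
    tab <- table(informative$allele_key)
    fr <- as.numeric(tab) / sum(tab)
    names(fr) <- names(tab)
    fr <- filter_alleles(fr, params$allele_filter)
  }
  genotype <- if (n_reads < params$min_reads || length(fr) == 0L) {
    "low_depth"
  } else {
    wt_frac <- if ("wt" %in% names(fr)) unname(fr[["wt"]]) else 0
    nonwt <- fr[setdiff(names(fr), "wt")]
    if (wt_frac >= params$wt_frac) "wt"
    else if (length(nonwt) >= 1L && max(nonwt) >= params$homo_frac) "homozygous"
    else if (length(nonwt) == 1L &&
             nonwt >= params$het_band[1] && nonwt <= params$het_band[2] &&
             wt_frac >= params$het_band[1] && wt_frac <= params$het_band[2])
      "heterozygous"
    else if (length(nonwt) >= 1L) "chimeric"
    else "wt"
  }
  structure(list(plant_id = plant_id, n_reads = n_reads,
                 allele_fractions = fr, genotype = genotype),
            class = "PlantCall")
}

#' @export
print.PlantCall <- function(x, ...) {
  cat(sprintf("Plant %s: %s (%d reads)\n", x$plant_id, x$genotype, x$n_reads))
  if (length(x$allele_fractions))
    cat(paste(sprintf("  %-24s %.3f", names(x$allele_fractions),
                      x$allele_fractions), collapse = "\n"), "\n")
  invisible(x)
}

#' Cohort editing statistics
#'
#' Percentage of total transgenic plants = plants with precise (or
#' imprecise) edits divided by the number of NGS samples; percentages of
#' correct-edit plants = homozygous / heterozygous / chimeric counts divided
#' by the number of plants carrying a precise edit.
#'
#' @param plant_calls List of `PlantCall` objects.
#' @param locus Locus label.
#' @return An object of class `CohortSummary`: `locus`, `n_samples`,
#'   `pct_precise`, `pct_indel`, `pct_homo`, `pct_het`, `pct_chimeric`,
#'   `n_precise_plants`, and `no_precise_edits` flag (percent scale,
#'   among-precise proportions reported as 0 when flagged).
#' @export
summarize_cohort <- function(plant_calls, locus = "locus") {
  if (length(plant_calls) == 0L) stop("no plant calls to summarize")
  n <- length(plant_calls)
  edited_geno <- c("homozygous", "heterozygous", "chimeric")
  has_precise <- vapply(plant_calls, function(p)
    p$genotype %in% edited_geno &&
      "precise_deletion" %in% names(p$allele_fractions), FALSE)
  has_indel <- vapply(plant_calls, function(p)
    p$genotype %in% edited_geno &&
      any(startsWith(names(p$allele_fractions), "indel:")), FALSE)
  np <- sum(has_precise)
  geno_precise <- vapply(plant_calls[has_precise], `[[`, "", "genotype")
  pct <- function(x) 100 * x
  structure(list(
    locus = locus, n_samples = n,
    pct_precise = pct(np / n), pct_indel = pct(sum(has_indel) / n),
    pct_homo = if (np) pct(sum(geno_precise == "homozygous") / np) else 0,
    pct_het = if (np) pct(sum(geno_precise == "heterozygous") / np) else 0,
    pct_chimeric = if (np) pct(sum(geno_precise == "chimeric") / np) else 0,
    n_precise_plants = np, no_precise_edits = np == 0L),
    class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort %s (n = %d samples)\n", x$locus, x$n_samples))
  cat(sprintf("  precise deletion: %.1f%%   indel: %.1f%%\n",
              x$pct_precise, x$pct_indel))
  if (!x$no_precise_edits)
    cat(sprintf("  among precise: homozygous %.1f%%, heterozygous %.1f%%, chimeric %.1f%%\n",
                x$pct_homo, x$pct_het, x$pct_chimeric))
  else cat("  no precise-edit plants\n")
  invisible(x)
}

#' Classify the FASTQ reads of one plant
#'
#' Paired files are processed as two read sets over the same amplicon.
#'
#' @param fastq Path(s) to FASTQ file(s) for one plant.
#' @param wt,edited Allele sequences.
#' @param junction 0-based junction coordinate in `edited`.
#' @param plant_id Plant identifier.
#' @param params A [classify_params()] list.
#' @return A `PlantCall`.
#' @export
classify_fastq <- function(fastq, wt, edited, junction, plant_id = "plant",
                           params = classify_params()) {
  reads <- unlist(lapply(fastq, function(f)
    as.character(Biostrings::readDNAStringSet(f, format = "fastq"))))
  calls <- classify_reads(reads, wt, edited, junction, params)
  call_plant(calls, plant_id, params)
}

#' Run the classifier over a cohort sample sheet
#'
#' The sample sheet is a TSV with columns `plant_id`, `fastq` (path;
#' optionally `fastq2` for pairs) and `locus`. Per-plant JSON reports and a
#' cohort TSV are written when `outdir` is given.
#'
#' @param sample_sheet Path to the sample-sheet TSV.
#' @param wt,edited Allele sequences for the locus.
#' @param junction 0-based junction coordinate in `edited`.
#' @param params A [classify_params()] list.
#' @param outdir Optional output directory for reports.
#' @return list(plants = list of `PlantCall`, summary = `CohortSummary`).
#' @export
run_cohort <- function(sample_sheet, wt, edited, junction,
                       params = classify_params(), outdir = NULL) {
  sheet <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  base <- dirname(sample_sheet)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  plants <- lapply(seq_len(nrow(sheet)), function(i) {
    files <- resolve(sheet$fastq[i])
    if ("fastq2" %in% names(sheet) && nzchar(sheet$fastq2[i]))
      files <- c(files, resolve(sheet$fastq2[i]))
    classify_fastq(files, wt, edited, junction, sheet$plant_id[i], params)
  })
  locus <- if ("locus" %in% names(sheet)) sheet$locus[1] else "locus"
  summ <- summarize_cohort(plants, locus)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (p in plants)
      jsonlite::write_json(
        list(plant_id = p$plant_id, n_reads = p$n_reads,
             genotype = p$genotype,
             allele_fractions = as.list(p$allele_fractions)),
        file.path(outdir, paste0(p$plant_id, ".json")), auto_unbox = TRUE,
        digits = NA)
    write.table(
      data.frame(locus = summ$locus, n_samples = summ$n_samples,
                 pct_precise = summ$pct_precise, pct_indel = summ$pct_indel,
                 pct_homo = summ$pct_homo, pct_het = summ$pct_het,
                 pct_chimeric = summ$pct_chimeric),
      file.path(outdir, "cohort_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  list(plants = plants, summary = summ)
}
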