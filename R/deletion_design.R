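#' Design parameters for deletion strategies
#'
#' Defaults follow common prime-editing practice (the choice is recorded in
#' all outputs): 13-nt PBS, 25-nt RT template per side, boundary search
#' window of 150 nt, PE3 nicking offset 40-100 nt. RT templates are extended
#' automatically (up to `rtt_max`) when a patch region must be re-encoded,
#' so that every flap still crosses the deletion junction by at least
#' `min_flap_span` nt.
#'
#' @param pbs_len Primer-binding-site length (nt).
#' @param rtt_len Default RT-template length per pegRNA (nt).
#' @param pbs_bounds,rtt_bounds Allowed `c(min, max)` for PBS / RTT lengths.
#' @param window Search window (nt) outward from each deletion boundary for
#'   candidate protospacers.
#' @param min_del,max_del Permitted deletion lengths (bp).
#' @param min_flap_span Minimum nt a flap must extend past the deletion
#'   junction.
#' @param pe3_offset Allowed `c(min, max)` distance (nt) between the pegRNA
#'   nick and the PE3 nicking-sgRNA nick.
#' @param weights Ranking penalty weights: per patch nt, per % PBS GC
#'   deviation from 50, per TTTT run in spacer+extension, per nt of
#'   nick-to-boundary distance, and per RTT whose first (scaffold-adjacent)
#'   base is C.
#' @param max_designs Maximum candidates returned after ranking.
#' @return A list of class `pdel_params`.
#' @export
pdel_params <- function(pbs_len = 13L, rtt_len = 25L,
                        pbs_bounds = c(8L, 17L), rtt_bounds = c(10L, 60L),
                        window = 150L, min_del = 25L, max_del = 5000L,
                        min_flap_span = 10L,
                        pe3_offset = c(40L, 100L),
                        weights = list(patch = 10, gc = 1, tttt = 50,
                                       dist = 1, rtt_first_c = 20),
                        max_designs = 20L) {
  stopifnot(pbs_len >= pbs_bounds[1], pbs_len <= pbs_bounds[2],
            rtt_len >= rtt_bounds[1], rtt_len <= rtt_bounds[2])
  structure(list(pbs_len = as.integer(pbs_len), rtt_len = as.integer(rtt_len),
                 pbs_bounds = as.integer(pbs_bounds),
                 rtt_bounds = as.integer(rtt_bounds),
                 window = as.integer(window), min_del = as.integer(min_del),
                 max_del = as.integer(max_del),
                 min_flap_span = as.integer(min_flap_span),
                 pe3_offset = as.integer(pe3_offset), weights = weights,
                 max_designs = as.integer(max_designs)),
            class = "pdel_params")
}

#' Load design parameters from a YAML config
#'
#' Any field of [pdel_params()] may be overridden; unnamed fields keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pdel_params` list.
#' @export
params_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pdel_params()
  for (nm in names(cfg)) {
    if (!nm %in% names(base)) stop(sprintf("unknown parameter '%s'", nm))
    if (nm == "weights") {
      base$weights[names(cfg$weights)] <- cfg$weights
    } else {
      base[[nm]] <- if (is.numeric(cfg[[nm]])) as.integer(cfg[[nm]]) else cfg[[nm]]
    }
  }
  class(base) <- "pdel_params"
  base
}

#' Intended edited allele after a programmed deletion
#'
#' Removes `deletion` from the reference; if a [recode()] plan is supplied
#' its synonymous substitutions are applied to the retained patch regions
#' first (they never overlap the deleted segment).
#'
#' @param ref A [ref_seq()] record.
#' @param deletion An [interval()] to delete.
#' @param syn_plan Optional `SynPlan` from [recode()].
#' @return The edited allele as a character string.
#' @export
edited_allele <- function(ref, deletion, syn_plan = NULL) {
  stopifnot(inherits(ref, "RefSeq"), inherits(deletion, "Interval"))
  check_interval_within(deletion, ref, "deletion")
  seq <- if (!is.null(syn_plan) && nrow(syn_plan$substitutions) > 0)
    apply_syn(ref, syn_plan) else ref$seq
  paste0(subseq0(seq, 0L, deletion$start), subseq0(seq, deletion$end, nchar(seq)))
}

#' Build one pegRNA against an intended edited allele
#'
#' The 3' extension is reported 5'->3' as synthesized (RTT then PBS). The
#' PBS is the reverse complement of the `pbs_len` nt immediately 5' of the
#' nick on the protospacer (nicked) strand of the *reference*; the RTT is
#' the reverse complement of the first `rtt_len` nt of the *edited allele*
#' downstream of the nick, read on the nicked strand.
#'
#' @param ref A [ref_seq()] record.
#' @param site One spacer site (row of [find_spacers()] output).
#' @param edited Edited allele string.
#' @param junction_in_edited 0-based coordinate the nick maps to in `edited`.
#' @param pbs_len,rtt_len Segment lengths (nt).
#' @param pbs_bounds,rtt_bounds Allowed length ranges.
#' @return An object of class `PegRNADesign`.
#' @export
build_pegrna <- function(ref, site, edited, junction_in_edited,
                         pbs_len = 13L, rtt_len = 25L,
                         pbs_bounds = c(8L, 17L), rtt_bounds = c(10L, 60L)) {
  site <- as.list(site)
  if (pbs_len < pbs_bounds[1] || pbs_len > pbs_bounds[2])
    stop(sprintf("pbs_len %d outside bounds [%d, %d]", pbs_len,
                 pbs_bounds[1], pbs_bounds[2]))
  if (rtt_len < rtt_bounds[1] || rtt_len > rtt_bounds[2])
    stop(sprintf("rtt_len %d outside bounds [%d, %d]", rtt_len,
                 rtt_bounds[1], rtt_bounds[2]))
  nick <- site$nick
  j <- as.integer(junction_in_edited)
  ne <- nchar(edited)
  if (site$strand == "+") {
    if (j + rtt_len > ne) stop("rtt_len too long: runs off the edited allele")
    if (nick - pbs_len < 0L) stop("pbs_len too long: runs off the reference")
    flap_top <- subseq0(edited, j, j + rtt_len)      # new 3' flap, top strand
    rtt <- revcomp(flap_top)
    pbs <- revcomp(subseq0(ref$seq, nick - pbs_len, nick))
  } else {
    if (j - rtt_len < 0L) stop("rtt_len too long: runs off the edited allele")
    if (nick + pbs_len > nchar(ref$seq))
      stop("pbs_len too long: runs off the reference")
    # flap is on the bottom strand; rtt = revcomp(flap) = top-strand window
    rtt <- subseq0(edited, j - rtt_len, j)
    pbs <- subseq0(ref$seq, nick, nick + pbs_len)
  }
  structure(list(site = site, strand = site$strand, nick = nick,
                 junction = j, spacer = site$spacer, pbs = pbs, rtt = rtt,
                 pbs_len = as.integer(pbs_len), rtt_len = as.integer(rtt_len),
                 extension = paste0(rtt, pbs)),
            class = "PegRNADesign")
}

#' @export
print.PegRNADesign <- function(x, ...) {
  cat(sprintf("PegRNA (%s strand) nick=%d\n  spacer %s\n  RTT    %s (%d nt)\n  PBS    %s (%d nt)\n",
              x$strand, x$nick + 1L, x$spacer, x$rtt, x$rtt_len, x$pbs,
              x$pbs_len))
  invisible(x)
}

# RTT length needed so the flap crosses its junction by >= min_flap_span,
# never shorter than the configured default. NA when it cannot fit rtt_max.
required_rtt <- function(patch_len, params) {
  need <- max(params$rtt_len, patch_len + params$min_flap_span)
  if (need > params$rtt_bounds[2]) return(NA_integer_)
  as.integer(need)
}

new_deletion_design <- function(strategy, deletion, edited, pair = NULL,
                                pe3 = NULL, syn_plan = NULL, patches = NULL) {
  structure(list(strategy = strategy, deletion = deletion,
                 pair = pair, pe3 = pe3, syn_plan = syn_plan,
                 edited_allele = edited, patches = patches, score = NA_real_),
            class = "DeletionDesign")
}

#' @export
print.DeletionDesign <- function(x, ...) {
  d <- x$deletion
  cat(sprintf("%s design: deletion [%s] (%d bp), score %.1f\n", x$strategy,
              fmt1(d$start, d$end), interval_len(d),
              if (is.na(x$score)) NA else x$score))
  if (!is.null(x$pair)) {
    cat(sprintf("  nicks: + %d / - %d; patches %d + %d nt\n",
                x$pair$n_f + 1L, x$pair$n_r + 1L,
                interval_len(x$patches$left), interval_len(x$patches$right)))
  }
  if (!is.null(x$pe3)) {
    cat(sprintf("  pegRNA nick %d (%s), nick-sgRNA nick %d (offset %+d)\n",
                x$pe3$pegrna$nick + 1L, x$pe3$pegrna$strand,
                x$pe3$nick_sgrna$nick + 1L, x$pe3$nick_offset))
  }
  if (!is.null(x$syn_plan) && nrow(x$syn_plan$substitutions) > 0)
    cat(sprintf("  %d synonymous substitutions in patches\n",
                nrow(x$syn_plan$substitutions)))
  invisible(x)
}

#' Design dual-pegRNA (PDel / PDel-Syn) deletions
#'
#' Enumerates `+`-strand protospacers whose nick lies at or left of the
#' deletion start and `-`-strand protospacers whose nick lies at or right of
#' the deletion end (within `params$window`), builds the forward/reverse
#' pegRNA pair against the intended edited allele for every combination, and
#' returns candidates ranked by [rank_designs()]. Sequence retained between
#' a nick and its deletion boundary (the "patch") is re-encoded by the RT
#' template; with `strategy = "PDelSyn"` the patch is synonymously recoded
#' first (requires `cds`).
#'
#' @param ref A [ref_seq()] record.
#' @param deletion An [interval()]; length must lie within
#'   `params$min_del`..`params$max_del`.
#' @param params A [pdel_params()] list.
#' @param strategy `"PDel"` or `"PDelSyn"`.
#' @param cds A [cds_annotation()] (required for `"PDelSyn"`).
#' @param syn_policy Passed to [recode()] (`"lenient"` or `"strict"`).
#' @return A list of `DeletionDesign` objects, best first.
#' @export
design_pdel <- function(ref, deletion, params = pdel_params(),
                        strategy = c("PDel", "PDelSyn"), cds = NULL,
                        syn_policy = "lenient") {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ref, "RefSeq"), inherits(deletion, "Interval"))
  check_interval_within(deletion, ref, "deletion")
  n <- nchar(ref$seq)
  dl <- interval_len(deletion)
  if (dl > n) stop("deletion longer than the locus")
  if (dl < params$min_del || dl > params$max_del)
    stop(sprintf("deletion length %d outside configured range [%d, %d]",
                 dl, params$min_del, params$max_del))
  if (strategy == "PDelSyn" && is.null(cds))
    stop("PDelSyn requires a cds annotation")
  ds <- deletion$start; de <- deletion$end

  lw <- interval(max(0L, ds - params$window), min(n, ds + 1L))
  rw <- interval(de, min(n, de + params$window + 1L))
  left <- find_spacers(ref, lw)
  left <- left[left$strand == "+" & left$nick <= ds, , drop = FALSE]
  right <- find_spacers(ref, rw)
  right <- right[right$strand == "-" & right$nick >= de, , drop = FALSE]
  if (nrow(left) == 0L)
    stop("no PAM available: no + strand nick at or left of the deletion start within the search window; consider a wider window or the PDel/Syn strategy")
  if (nrow(right) == 0L)
    stop("no PAM available: no - strand nick at or right of the deletion end within the search window; consider a wider window or the PDel/Syn strategy")

  designs <- list()
  for (i in seq_len(nrow(left))) {
    f <- as.list(left[i, ])
    rtt_f <- required_rtt(ds - f$nick, params)
    if (is.na(rtt_f) || f$nick - params$pbs_len < 0L) next
    for (k in seq_len(nrow(right))) {
      r <- as.list(right[k, ])
      rtt_r <- required_rtt(r$nick - de, params)
      if (is.na(rtt_r) || r$nick + params$pbs_len > n) next
      n_f <- f$nick; n_r <- r$nick
      patches <- list(left = interval(n_f, ds), right = interval(de, n_r))
      plan <- NULL
      if (strategy == "PDelSyn") {
        avoid <- c(paste0(f$spacer, f$pam), paste0(r$spacer, r$pam))
        plan <- recode(ref, patches, cds, policy = syn_policy,
                       avoid_spacers = avoid)
      }
      edited <- edited_allele(ref, deletion, plan)
      e_r <- n_r - dl
      fwd <- build_pegrna(ref, f, edited, n_f, params$pbs_len, rtt_f,
                          params$pbs_bounds, params$rtt_bounds)
      rev <- build_pegrna(ref, r, edited, e_r, params$pbs_len, rtt_r,
                          params$pbs_bounds, params$rtt_bounds)
      pair <- structure(list(fwd = fwd, rev = rev, n_f = n_f, n_r = n_r),
                        class = "PegRNAPair")
      designs[[length(designs) + 1L]] <-
        new_deletion_design(strategy, deletion, edited, pair = pair,
                            syn_plan = plan, patches = patches)
    }
  }
  if (length(designs) == 0L)
    stop("no PAM available: no spacer pair admits RT templates within bounds")
  designs <- rank_designs(designs, params)
  head(designs, params$max_designs)
}

#' Design PE3 deletions (single pegRNA + nicking sgRNA)
#'
#' One pegRNA whose RT template spans the deletion junction, plus a
#' complementary-strand nicking sgRNA whose nick lies outside the deleted
#' segment at a distance within `params$pe3_offset` of the pegRNA nick.
#' Both pegRNA orientations are enumerated.
#'
#' @inheritParams design_pdel
#' @return A list of `DeletionDesign` objects carrying `$pe3`, best first.
#' @export
design_pe3 <- function(ref, deletion, params = pdel_params()) {
  stopifnot(inherits(ref, "RefSeq"), inherits(deletion, "Interval"))
  check_interval_within(deletion, ref, "deletion")
  n <- nchar(ref$seq)
  dl <- interval_len(deletion)
  if (dl < params$min_del || dl > params$max_del)
    stop(sprintf("deletion length %d outside configured range [%d, %d]",
                 dl, params$min_del, params$max_del))
  ds <- deletion$start; de <- deletion$end
  edited <- edited_allele(ref, deletion)
  all_sites <- find_spacers(ref)
  off <- params$pe3_offset
  outside <- all_sites$nick <= ds | all_sites$nick >= de

  designs <- list()
  add_designs <- function(peg_sites, strand) {
    for (i in seq_len(nrow(peg_sites))) {
      s <- as.list(peg_sites[i, ])
      patch <- if (strand == "+") ds - s$nick else s$nick - de
      rtt_len <- required_rtt(patch, params)
      if (is.na(rtt_len)) next
      if (strand == "+" && s$nick - params$pbs_len < 0L) next
      if (strand == "-" && s$nick + params$pbs_len > n) next
      j <- if (strand == "+") s$nick else s$nick - dl
      # flap must run past the junction without leaving the edited allele
      if (strand == "+" && j + rtt_len > nchar(edited)) next
      if (strand == "-" && j - rtt_len < 0L) next
      peg <- build_pegrna(ref, s, edited, j, params$pbs_len, rtt_len,
                          params$pbs_bounds, params$rtt_bounds)
      nicks <- all_sites[outside & all_sites$strand != strand &
                           abs(all_sites$nick - s$nick) >= off[1] &
                           abs(all_sites$nick - s$nick) <= off[2], ,
                         drop = FALSE]
      for (k in seq_len(nrow(nicks))) {
        ns <- as.list(nicks[k, ])
        pe3 <- structure(list(pegrna = peg, nick_sgrna = ns,
                              nick_offset = ns$nick - s$nick),
                         class = "PE3Design")
        designs[[length(designs) + 1L]] <<-
          new_deletion_design("PE3", deletion, edited, pe3 = pe3,
                              patches = list(left = interval(min(s$nick, ds), ds),
                                             right = interval(de, max(s$nick, de))))
      }
    }
  }
  plus <- all_sites[all_sites$strand == "+" & all_sites$nick <= ds &
                      all_sites$nick >= ds - params$window, , drop = FALSE]
  minus <- all_sites[all_sites$strand == "-" & all_sites$nick >= de &
                       all_sites$nick <= de + params$window, , drop = FALSE]
  add_designs(plus, "+")
  add_designs(minus, "-")
  if (length(designs) == 0L)
    stop("no PE3 design: no pegRNA site with a complementary-strand nicking sgRNA in the offset window")
  designs <- rank_designs(designs, params)
  head(designs, params$max_designs)
}

design_pegrnas <- function(design) {
  if (!is.null(design$pair)) list(design$pair$fwd, design$pair$rev)
  else list(design$pe3$pegrna)
}

#' Reconstruct the edited allele from a design's pegRNA content
#'
#' Rebuilds the allele the design would install, using only the reference,
#' the nick coordinates, and the RT-template sequences (the programmed 3'
#' flaps) -- i.e. the information physically encoded in the pegRNAs. Used by
#' [validate_design()] to prove the design reproduces the intended allele.
#'
#' @param design A `DeletionDesign`.
#' @param ref The [ref_seq()] it was designed against.
#' @return The reconstructed allele string, or `NA` if the flaps do not
#'   overlap consistently.
#' @export
reconstruct_allele <- function(design, ref) {
  dl <- interval_len(design$deletion)
  n <- nchar(ref$seq)
  if (!is.null(design$pair)) {
    fwd <- design$pair$fwd; rev <- design$pair$rev
    n_f <- fwd$nick
    s1 <- revcomp(fwd$rtt)                  # covers edited [n_f, n_f+rtt_f)
    e_r <- rev$junction
    s2 <- rev$rtt                           # covers edited [a2, e_r)
    a2 <- e_r - rev$rtt_len
    b1 <- n_f + fwd$rtt_len
    # flap windows must tile the junction contiguously (overlap or abut)
    if (min(b1, e_r) < max(n_f, a2)) return(NA_character_)
    start_cov <- min(n_f, a2); end_cov <- max(b1, e_r)
    merged <- rep(NA_character_, end_cov - start_cov)
    merged[(n_f - start_cov + 1L):(b1 - start_cov)] <- strsplit(s1, "")[[1]]
    v2 <- strsplit(s2, "")[[1]]
    idx2 <- (a2 - start_cov + 1L):(e_r - start_cov)
    both <- !is.na(merged[idx2])
    if (any(merged[idx2][both] != v2[both])) return(NA_character_)
    merged[idx2] <- v2
    paste0(subseq0(ref$seq, 0L, start_cov), paste(merged, collapse = ""),
           subseq0(ref$seq, end_cov + dl, n))
  } else {
    peg <- design$pe3$pegrna
    if (peg$strand == "+") {
      s1 <- revcomp(peg$rtt)
      paste0(subseq0(ref$seq, 0L, peg$nick), s1,
             subseq0(ref$seq, peg$nick + peg$rtt_len + dl, n))
    } else {
      a <- peg$junction - peg$rtt_len
      paste0(subseq0(ref$seq, 0L, a), peg$rtt,
             subseq0(ref$seq, peg$junction + dl, n))
    }
  }
}

#' Validate a deletion design
#'
#' Checks the flap geometry of a design against its intended edited allele:
#' (a) the forward RT template writes the edited sequence downstream of its
#' nick; (b) likewise for the reverse flap; (c) the two flaps overlap and
#' tile the junction contiguously (PDel) or the single flap spans the
#' junction (PE3); (d) deletion-length arithmetic; (e) full reconstruction
#' from pegRNA content alone equals the intended allele.
#'
#' @param design A `DeletionDesign`.
#' @param ref The [ref_seq()] it was designed against.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_design <- function(design, ref) {
  edited <- design$edited_allele
  dl <- interval_len(design$deletion)
  j <- design$deletion$start
  res <- list()
  add <- function(check, pass, detail = "")
    res[[length(res) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  if (!is.null(design$pair)) {
    fwd <- design$pair$fwd; rev <- design$pair$rev
    n_f <- fwd$nick; e_r <- rev$junction
    add("fwd_rtt_matches_edited",
        revcomp(fwd$rtt) == subseq0(edited, n_f, n_f + fwd$rtt_len))
    add("rev_flap_matches_edited",
        rev$rtt == subseq0(edited, e_r - rev$rtt_len, e_r))
    o <- min(n_f + fwd$rtt_len, e_r) - max(n_f, e_r - rev$rtt_len)
    add("flaps_tile_junction",
        o >= 0L && n_f + fwd$rtt_len >= j && e_r - rev$rtt_len <= j,
        sprintf("window_overlap=%d", o))
  } else {
    peg <- design$pe3$pegrna
    if (peg$strand == "+") {
      add("rtt_matches_edited",
          revcomp(peg$rtt) == subseq0(edited, peg$junction,
                                      peg$junction + peg$rtt_len))
      add("rtt_spans_junction",
          peg$junction <= j && peg$junction + peg$rtt_len > j)
    } else {
      add("rtt_matches_edited",
          peg$rtt == subseq0(edited, peg$junction - peg$rtt_len,
                             peg$junction))
      add("rtt_spans_junction",
          peg$junction >= j && peg$junction - peg$rtt_len < j)
    }
    add("nick_sgrna_opposite_strand",
        design$pe3$nick_sgrna$strand != peg$strand)
  }
  add("deletion_length_arithmetic",
      nchar(edited) == nchar(ref$seq) - dl,
      sprintf("len(ref)=%d len(edited)=%d del=%d", nchar(ref$seq),
              nchar(edited), dl))
  rec <- reconstruct_allele(design, ref)
  add("reconstruction_equals_edited", identical(rec, edited))
  do.call(rbind, res)
}

#' Rank candidate deletion designs
#'
#' Stable sort by a weighted penalty: total patch length, PBS GC deviation
#' from 50%, TTTT runs in spacer+extension (internal Pol III terminator),
#' nick-to-boundary distances, and a C as the first (scaffold-adjacent) RTT
#' base. Ties are broken by ascending nick coordinates, then input order.
#'
#' @param candidates Nonempty list of `DeletionDesign` objects.
#' @param params A [pdel_params()] list (supplies `weights`).
#' @return The list reordered best-first, with `$score` filled in.
#' @export
rank_designs <- function(candidates, params = pdel_params()) {
  if (length(candidates) == 0L) stop("no candidate designs to rank")
  w <- params$weights
  score_one <- function(d) {
    pegs <- design_pegrnas(d)
    patch <- if (!is.null(d$patches))
      interval_len(d$patches$left) + interval_len(d$patches$right) else 0L
    gc_pen <- sum(vapply(pegs, function(p) abs(gc_percent(p$pbs) - 50), 0))
    tttt <- sum(vapply(pegs, function(p)
      has_tttt(paste0(p$spacer, p$extension)), FALSE))
    first_c <- sum(vapply(pegs, function(p)
      substr(p$rtt, 1L, 1L) == "C", FALSE))
    w$patch * patch + w$gc * gc_pen + w$tttt * tttt + w$dist * patch +
      w$rtt_first_c * first_c
  }
  scores <- vapply(candidates, score_one, 0)
  nf <- vapply(candidates, function(d)
    if (!is.null(d$pair)) d$pair$n_f else d$pe3$pegrna$nick, 0L)
  nr <- vapply(candidates, function(d)
    if (!is.null(d$pair)) d$pair$n_r else d$pe3$nick_sgrna$nick, 0L)
  ord <- order(scores, nf, nr, method = "radix")
  out <- candidates[ord]
  for (i in seq_along(out)) out[[i]]$score <- scores[ord][i]
  out
}

#' Write a design report TSV
#'
#' One row per candidate with 1-based coordinates, pegRNA sequences, patch
#' intervals and score.
#'
#' @param designs List of `DeletionDesign` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(designs, path) {
  rows <- lapply(designs, function(d) {
    pegs <- design_pegrnas(d)
    data.frame(
      strategy = d$strategy,
      deletion = fmt1(d$deletion$start, d$deletion$end),
      spacers = paste(vapply(pegs, `[[`, "", "spacer"), collapse = ";"),
      pams = paste(vapply(pegs, function(p) p$site$pam, ""), collapse = ";"),
      nicks = paste(vapply(pegs, function(p) p$nick + 1L, 0L), collapse = ";"),
      pbs = paste(vapply(pegs, `[[`, "", "pbs"), collapse = ";"),
      rtt = paste(vapply(pegs, `[[`, "", "rtt"), collapse = ";"),
      patch_left = if (!is.null(d$patches)) interval_len(d$patches$left) else 0L,
      patch_right = if (!is.null(d$patches)) interval_len(d$patches$right) else 0L,
      n_syn_subs = if (!is.null(d$syn_plan)) nrow(d$syn_plan$substitutions) else 0L,
      score = d$score, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
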