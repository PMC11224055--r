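#' Default epegRNA cassette parts
#'
#' Replaceable defaults for the fixed parts of an epegRNA expression
#' cassette. The scaffold, linker, tevopreQ1 and HDV sequences here are
#' canonical published parts supplied as placeholders -- substitute your
#' lab-validated sequences via the arguments or a YAML config. The optional
#' `promoter_tag` (e.g. an OsU6a handle) and `tRNA` parts default to empty
#' and are skipped in feature tables when empty.
#'
#' @param promoter_tag,trna,esgrna_scaffold,linker,tevopreq1,hdv Part
#'   sequences (DNA).
#' @return Named list of part sequences.
#' @export
default_parts <- function(
    promoter_tag = "",
    trna = "AACAAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCGATTCCCGGCTGGTGCA",
    esgrna_scaffold = "GTTTAAGAGCTATGCTGGAAACAGCATAGCAAGTTTAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC",
    linker = "GGCGGGA",
    tevopreq1 = "CGCGGTTCTATCTAGTTACGCGTTAAACCAACTAGAA",
    hdv = "GGCCGGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGGCAACATGCTTCGGCATGGCGAATGGGAC") {
  list(promoter_tag = promoter_tag, trna = trna,
       esgrna_scaffold = esgrna_scaffold, linker = linker,
       tevopreq1 = tevopreq1, hdv = hdv)
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Read cassette parts from a YAML config
#'
#' Keys override [default_parts()] entries.
#'
#' @param path Path to a YAML file.
#' @return Named list of part sequences.
#' @export
parts_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  parts <- default_parts()
  unknown <- setdiff(names(cfg), names(parts))
  if (length(unknown))
    stop(sprintf("unknown part(s) in config: %s", paste(unknown, collapse = ", ")))
  parts[names(cfg)] <- cfg
  parts
}

CASSETTE_ORDER <- c("promoter_tag", "tRNA", "spacer", "esgRNA_scaffold",
                    "rtt", "pbs", "linker", "tevopreQ1", "hdv")

#' Assemble an epegRNA expression cassette
#'
#' Parts are placed in the fixed order promoter_tag, tRNA, spacer, esgRNA
#' scaffold, RTT, PBS, linker, tevopreQ1, HDV (the 3' extension follows the
#' scaffold as RTT then PBS). A warning is raised when spacer+RTT+PBS
#' contains a TTTT run (internal Pol III terminator).
#'
#' @param design A `PegRNADesign` (from [build_pegrna()] or a
#'   `DeletionDesign`'s pair).
#' @param parts Part list from [default_parts()] / [parts_from_yaml()].
#' @return An object of class `EpegRNACassette` with `$parts` (named,
#'   ordered), `$full_seq`, and `$features` (0-based half-open tiling).
#' @export
assemble_epegrna <- function(design, parts = default_parts()) {
  stopifnot(inherits(design, "PegRNADesign"))
  required <- c("esgrna_scaffold", "linker", "tevopreq1", "hdv")
  for (p in required)
    if (is.null(parts[[p]]) || is.na(parts[[p]]))
      stop(sprintf("missing cassette part in config: %s", p))
  if (nchar(design$spacer) != 20L) stop("spacer must be 20 nt")
  seqs <- c(promoter_tag = toupper(parts$promoter_tag %||% ""),
            tRNA = toupper(parts$trna %||% ""),
            spacer = design$spacer,
            esgRNA_scaffold = toupper(parts$esgrna_scaffold),
            rtt = design$rtt, pbs = design$pbs,
            linker = toupper(parts$linker),
            tevopreQ1 = toupper(parts$tevopreq1),
            hdv = toupper(parts$hdv))
  seqs <- seqs[CASSETTE_ORDER]
  if (has_tttt(paste0(design$spacer, design$rtt, design$pbs)))
    warning("spacer+RTT+PBS contains a TTTT run (internal Pol III terminator)")
  keep <- nchar(seqs) > 0L
  lens <- nchar(seqs[keep])
  ends <- cumsum(lens)
  feats <- data.frame(name = names(seqs[keep]), start = ends - lens,
                      end = ends, stringsAsFactors = FALSE)
  structure(list(parts = as.list(seqs), full_seq = paste(seqs, collapse = ""),
                 features = feats), class = "EpegRNACassette")
}

#' @export
print.EpegRNACassette <- function(x, ...) {
  cat(sprintf("epegRNA cassette: %d bp, %d parts\n", nchar(x$full_seq),
              nrow(x$features)))
  print(x$features)
  invisible(x)
}

#' Assemble cassettes for a deletion design
#'
#' One cassette for a PE3 design, two for a PDel / PDel-Syn pair.
#'
#' @param design A `DeletionDesign`.
#' @param parts Part list.
#' @return List of `EpegRNACassette` objects.
#' @export
cassettes_for_design <- function(design, parts = default_parts()) {
  lapply(design_pegrnas(design), assemble_epegrna, parts = parts)
}

#' Emit a cassette as GenBank-format text
#'
#' One `misc_feature` per non-empty part, 1-based inclusive coordinates,
#' tiling the sequence without gaps or overlaps.
#'
#' @param cassette An `EpegRNACassette`.
#' @param id Record identifier.
#' @return GenBank record as a single string.
#' @export
emit_annotated <- function(cassette, id) {
  n <- nchar(cassette$full_seq)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     linear   SYN %s",
            substr(id, 1, 17), n, toupper(format(Sys.Date(), "%d-%b-%Y"))),
    sprintf("DEFINITION  epegRNA expression cassette %s.", id),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(cassette$features))) {
    f <- cassette$features[i, ]
    lines <- c(lines,
               sprintf("     misc_feature    %d..%d", f$start + 1L, f$end),
               sprintf("                     /label=%s", f$name))
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(cassette$full_seq)
  for (pos in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, pos, min(pos + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", pos, paste(blocks, collapse = " ")))
  }
  paste(c(lines, "//", ""), collapse = "\n")
}

#' Write GenBank records to a file
#'
#' @param cassettes List of `EpegRNACassette` objects (or a single one).
#' @param ids Record identifiers (recycled names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(cassettes, ids, path) {
  if (inherits(cassettes, "EpegRNACassette")) cassettes <- list(cassettes)
  txt <- mapply(emit_annotated, cassettes, ids)
  writeLines(paste(txt, collapse = ""), path, sep = "")
  invisible(path)
}

#' Parse features and sequence back out of a GenBank record
#'
#' Minimal reader for the records written by [emit_annotated()] (LOCUS,
#' labelled features, ORIGIN); used for round-trip verification.
#'
#' @param x GenBank text (single string) or a file path.
#' @return List of records, each `list(id, seq, features)` with 0-based
#'   half-open feature coordinates.
#' @export
read_genbank_features <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else
    strsplit(x, "\n")[[1]]
  recs <- list()
  starts <- grep("^LOCUS", lines)
  bounds <- c(starts, length(lines) + 1L)
  for (r in seq_along(starts)) {
    block <- lines[bounds[r]:(bounds[r + 1L] - 1L)]
    id <- strsplit(trimws(sub("^LOCUS\\s+", "", block[1])), "\\s+")[[1]][1]
    feats <- list()
    fi <- grep("^\\s{5}\\S+\\s+\\d+\\.\\.\\d+", block)
    for (i in fi) {
      loc <- regmatches(block[i], regexpr("\\d+\\.\\.\\d+", block[i]))[[1]]
      se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      lab <- sub("^\\s+/label=", "", block[i + 1L])
      feats[[length(feats) + 1L]] <-
        data.frame(name = lab, start = se[1] - 1L, end = se[2],
                   stringsAsFactors = FALSE)
    }
    oi <- grep("^ORIGIN", block)
    end <- grep("^//", block)
    seq <- ""
    if (length(oi) && length(end)) {
      body <- block[(oi + 1L):(end[1] - 1L)]
      seq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
    }
    recs[[length(recs) + 1L]] <-
      list(id = id, seq = seq,
           features = if (length(feats)) do.call(rbind, feats) else NULL)
  }
  recs
}
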