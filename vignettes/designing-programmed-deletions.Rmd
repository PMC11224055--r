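---
title: "Designing and analysing prime-editing programmed deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing prime-editing programmed deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegdel)
```

## The problem

Prime editors install precise sequence changes from a reverse-transcriptase
template (RTT) carried on the pegRNA, without a double-strand break. Two
configurations program deletions:

* **PE3** — one pegRNA whose RTT spans the intended deletion junction, plus
  a second sgRNA nicking the complementary strand to bias repair toward the
  edited strand.
* **PDel** (dual pegRNA) — two pegRNAs nicking opposite strands at the two
  deletion boundaries. Each RTT encodes the junction, so the two new 3'
  flaps jointly re-create the deleted locus minus the target segment.

A third variant, **PDel/Syn**, addresses loci where no PAM sits exactly at
a boundary. The retained sequence between the usable nick and the boundary
(the *patch*) must be re-encoded through the RTT; because an RTT that is
homologous to the genomic target reduces editing efficiency, the patch is
recoded with synonymous codon substitutions before the pegRNAs are built.
`pegdel` implements the design arithmetic of all three strategies, the
detection-primer schemes used to screen regenerated plants, and a
dual-reference classifier that turns per-plant amplicon reads into
precise-deletion / indel / wild-type outcomes, zygosity calls and cohort
statistics, for deletions of roughly 50–2000 bp in plant genomes (the
bundled codon-usage table is for rice).

## Coordinate and nick conventions

All internal coordinates are 0-based half-open on the top strand; reports
and the CLI render 1-based inclusive positions. SpCas9 nicks between
protospacer positions 17 and 18 (3 nt 5' of the NGG PAM). We record a nick
as the index of the first base 3' of the broken bond on the top strand, so
a nick value is simultaneously a string-cut boundary: for a `+` site with
spacer start $s$ the nick is $s+17$; for a `-` site with top-strand PAM
start $p$ it is $p+6$. The PAM pattern and the nick offset are
configurable for other nickases, and only linear loci are accepted.

## Design model

For a deletion $[d_s, d_e)$, `design_pdel()` enumerates `+` sites with
nick $n_f \le d_s$ and `-` sites with nick $n_r \ge d_e$ inside a search
window (default 150 nt outward from each boundary). Nicks *inside* the
intended deletion are rejected: sequence between an inward nick and the
boundary would be retained but never re-encoded, so such geometries cannot
produce the exact allele. Each pair yields

* patches $[n_f, d_s)$ and $[d_e, n_r)$,
* the intended edited allele (reference minus deletion, patches recoded
  first under PDel/Syn),
* a forward pegRNA whose RTT is the reverse complement of the edited
  window starting at its nick, and a reverse pegRNA mirrored on the bottom
  strand.

The PBS is always taken from the *reference* (it primes on genomic
sequence); the RTT from the *edited allele* (it writes the new sequence).
Defaults are a 13-nt PBS and a 25-nt RTT per side — common prime-editing
practice; the RTT is extended automatically up to 60 nt when a patch must
be re-encoded, keeping at least 10 nt of flap beyond the junction
(`min_flap_span`). The two flap windows must tile the junction
contiguously: with boundary-exact nicks they abut exactly at the junction;
with patches they overlap. `validate_design()` checks this geometry, and
`reconstruct_allele()` rebuilds the allele *only* from the reference, the
nicks and the RTT sequences — agreement with direct string surgery is the
package's core correctness property and an acceptance check.

For PE3, both pegRNA orientations are enumerated; the nicking sgRNA must
sit on the opposite strand, outside the deleted segment, with a nick
40–100 nt (configurable) from the pegRNA nick. The offset window is a
design choice — common PE3 practice — as the underlying study does not
state its offsets, nor its PBS/RTT lengths.

Candidates are ranked by a weighted penalty: 10 per patch nt, 1 per % of
PBS GC deviation from 50%, 50 per TTTT run in spacer+extension (an
internal Pol III terminator), 1 per nt of nick-to-boundary distance, and
20 when the first (scaffold-adjacent) RTT base is C — a known efficiency
heuristic; such candidates are penalized, not rejected. The weights are
documented defaults, not claimed optimal; ties break by ascending nick
coordinates, then input order (stable sort).

## Synonymous patch recoding

`recode()` substitutes every *complete* codon inside a patch with the
synonymous codon of maximal Hamming distance; ties break by higher rank in
the bundled *Oryza sativa* codon-usage table, then lexicographically.
Maximizing nucleotide divergence most directly serves the goal of removing
RTT/target homology; the recoding is verified to preserve the protein
exactly and to shorten the longest common substring between the original
and recoded patch. Codons without a synonymous alternative (ATG, TGG) are
flagged and left unchanged. A substitution is skipped, with a note, when
it would create a TTTT/AAAA run or regenerate a full protospacer+PAM match
to one of the chosen spacers. Partial codons at patch edges are never
touched (synonymy could not be guaranteed without editing outside the
patch), and patch bases outside the CDS are left unchanged with a warning
under the default lenient policy (`strict` errors instead): "synonymous"
is undefined off-frame, and silent substitution of non-coding DNA behind a
recoding function would be surprising behaviour.

## Cassettes

`assemble_epegrna()` lays out the expression cassette in the construction
order promoter tag, tRNA, 20-nt spacer, enhanced sgRNA scaffold, RTT, PBS,
linker, tevopreQ1, HDV; a PDel design yields two cassettes. The scaffold,
linker, tevopreQ1 and HDV defaults are canonical published parts shipped
as clearly replaceable placeholders (a YAML config overrides any of them),
and every output embeds the part sequences actually used. Features must
tile the sequence gap-free; `emit_annotated()` writes GenBank records that
round-trip through both the bundled reader and Biopython.

## Detection primers

Melting temperatures use the Wallace rule below 14 nt and SantaLucia
(1998) unified nearest-neighbor parameters with the entropy salt
correction above (50 mM Na+, 25 nM per strand); the testthat suite checks
the implementation against Biopython's independent one to within 0.5 °C.
Primer lengths are 18–30 nt with a preferred Tm band of 58–62 °C and a
hard acceptance band of 52–68 °C — at these thermodynamic conditions many
primers on ~50% GC templates sit below 58 °C, so the preferred band steers
scoring while the hard band keeps design feasible; pairs must agree within
3 °C and a 3' G/C clamp is preferred.

Deletions under 100 bp use **junction primers**: one primer spans the
deletion junction with at least 5 nt 3' of it and must have no perfect
match in the wild-type allele on either strand, so only precise-deletion
templates amplify. Longer deletions use **flanking primers** outside the
deletion; the WT and edited products then differ by exactly the deletion
length, with a gel-resolvability proxy (edited product ≥ 100 bp and size
ratio ≥ 1.2 or difference ≥ 100 bp at 2.0% agarose) standing in for the
gel itself. The **zygosity** scheme places one primer inside the deleted
segment and its mate in the retained flank: product presence reports an
undeleted allele, separating homozygous from heterozygous plants.

## Read classification and cohort statistics

`classify_reads()` places each read (and its reverse complement) on both
the wild-type and expected edited allele. Placement is tiered for speed —
exact substring, best ungapped placement anchored by exact 16-mer seeds,
then affine-gap semi-global alignment — with ties resolved toward wild
type, since a read that matches both alleles carries no deletion evidence.
A read is a *precise deletion* when the edited allele wins with a
mismatch-only junction window (±10 nt); an *indel* when the winning
alignment gaps inside the target window (the junction window on the edited
allele, the deleted region on the wild type), keyed by net length and
offset so distinct indel alleles stay distinct; and *other* when its best
edit distance exceeds 20% of its length (or it is shorter than 50 nt).

Per plant, alleles below 5% of informative reads are filtered out and the
rest renormalized — the filter is idempotent. The literature formulation
of this filter ("fewer than 5% of transgenic plants") is grammatically
garbled; it is read here as a per-plant read-fraction filter, and the
threshold is configurable. Genotype rules (all configurable): wild type
when the WT fraction is ≥ 0.95; homozygous when one non-WT allele reaches
0.90; heterozygous when exactly one non-WT allele and both it and WT lie
in [0.35, 0.65]; chimeric otherwise while a non-WT allele survives;
`low_depth` below 50 reads (a quarter of the ~200× depth the assay
targets). The thresholds are chosen to make diploid expectations robust
at that depth; "chimeric" has no numeric definition in the source study
and is defined operationally by these fraction patterns. Cohort
percentages follow the assay's formulas: edited plants over NGS samples,
and homozygous/heterozygous/chimeric proportions over plants carrying a
precise edit.

## The simulator

`simulate_cohort()` emulates a transgenic cohort: per-plant FASTQ files
(constant Q30 qualities) plus a truth table. Genotype realizations are
homozygous = 100% edited, heterozygous = 50/50 edited/WT, wild type =
100% WT, and chimeric = a random three-way mix of edited, WT and one
indel allele with every component ≥ 10% — a generative definition chosen
so the category is distinguishable from heterozygous by construction.
Reads are junction-covering windows with i.i.d. substitution errors.
Per-allele read counts are apportioned deterministically (largest
remainder) rather than drawn multinomially: emitted proportions then equal
truth fractions exactly whenever `depth × fraction` is integral, which is
what makes noise-free genotype recovery exactly 100% rather than
almost-always; `sampling = "multinomial"` restores sampled counts when
sampling noise itself is under study. The simulator does not model PCR
bias, chimeric PCR artifacts, quality-score variation or paired-end insert
sizes — so passing round-trips demonstrate the classifier's arithmetic on
the stated noise model, not robustness to those real-data artifacts, and
real amplicon data with heavy strand bias or contamination will need the
thresholds revisited.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise: 100 random 1–4 kb loci
across deletion lengths {50, 100, 500, 1000, 2000} for design-oracle
equivalence; 100 random CDS loci for protein preservation; 200-plant
cohorts at depth 200 (error 0 and 1%) for classifier round-trips; 200
random junction-primer designs plus 25 flanking designs; and the printed
per-locus efficiency table for the two strategy fold-ratios. Under the
default RTT bound (60 nt) a patch longer than 50 nt cannot be re-encoded,
so roughly one random locus in ten has no admissible pair and errors with
"no PAM available" — an honest outcome, not a failure, and the reason the
design-oracle rate is computed over emitted designs.

## Known limitations

No off-target scoring, chromatin or efficiency prediction; one deletion
per locus; no splice-site or regulatory-motif awareness in recoding beyond
the TTTT/PAM checks; primer design screens 3' complementarity only through
uniqueness, not full dimer thermodynamics; the classifier assumes the two
candidate alleles are known and will fold large unforeseen rearrangements
into `other`.
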