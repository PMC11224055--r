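# pegdel

Design and analysis toolkit for **prime-editing programmed genomic
deletions** (roughly 50–2000 bp) in plants.

Prime editors write new sequence from a reverse-transcriptase template
(RTT) carried on a pegRNA. `pegdel` implements the three deletion
strategies used in transgenic rice work and the downstream analysis that
goes with them:

* **PE3** — one pegRNA whose RTT spans the deletion junction plus a
  complementary-strand nicking sgRNA (`design_pe3()`);
* **PDel** — dual pegRNAs nicking opposite strands at the two deletion
  boundaries, each RTT encoding the junction so the two 3' flaps tile the
  edited allele (`design_pdel()`);
* **PDel/Syn** — PDel with the retained "patch" between a nick and its
  boundary synonymously recoded to remove RTT/target homology
  (`design_pdel(strategy = "PDelSyn")`, `recode()`, `apply_syn()`).

Around the designers it provides NGG protospacer scanning
(`find_spacers()`), annotated epegRNA expression cassettes in the order
spacer–scaffold–RTT–PBS–linker–tevopreQ1 with GenBank output
(`assemble_epegrna()`, `emit_annotated()`), the two detection-primer
schemes (junction-specific for deletions < 100 bp, flanking for ≥ 100 bp;
`junction_primers()`, `flanking_primers()`, `zygosity_primers()`), a
dual-reference amplicon read classifier with per-plant zygosity calls and
cohort statistics (`classify_reads()`, `call_plant()`,
`summarize_cohort()`), and a truth-tracked cohort simulator
(`simulate_cohort()`, `genotype_recovery()`).

The core invariant: every emitted design must rebuild the intended edited
allele from nothing but the reference, the nick coordinates and the RTT
sequences (`reconstruct_allele()`), in exact agreement with direct string
surgery. Per-plant genotypes follow allele-fraction rules after the 5%
allele filter (wt ≥ 0.95; homozygous ≥ 0.90 for one non-WT allele;
heterozygous with both alleles in [0.35, 0.65]; chimeric otherwise), and
cohort percentages are edited plants over NGS samples and
homozygous/heterozygous/chimeric proportions over precise-edit plants.

## Worked example

```r
library(pegdel)
set.seed(20)
locus <- ref_seq("OsToy1", paste(sample(c("A","C","G","T"), 1200, TRUE),
                                 collapse = ""))
del <- interval(500, 700)            # 200-bp deletion, 0-based half-open

top <- design_pdel(locus, del)[[1]]
top
#> PDel design: deletion [501-700] (200 bp), score 648.1
#>   nicks: + 452 / - 707; patches 49 + 6 nt
validate_design(top, locus)
#>                          check pass                                 detail
#> 1       fwd_rtt_matches_edited TRUE
#> 2      rev_flap_matches_edited TRUE
#> 3          flaps_tile_junction TRUE                      window_overlap=25
#> 4   deletion_length_arithmetic TRUE len(ref)=1200 len(edited)=1000 del=200
#> 5 reconstruction_equals_edited TRUE

detection_primers(locus$seq, del)    # >= 100 bp -> flanking scheme
#> PrimerPair [flanking]
#>   fwd GCCAACAATTGACCAGATCTTCTACCAC (Tm 58.1)
#>   rev CTGATTAGTCCGCAGAGGATCCATCC (Tm 58.4)
#>   product WT: 300 bp, edited: 100 bp
```

The best candidate nicks 49 nt left of the deletion start (no closer `+`
PAM exists), so its forward RTT is auto-extended to re-encode that 49-nt
patch and all five geometry checks pass; the flanking PCR products differ
by exactly the programmed 200 bp. Closing the loop through the simulator —
24 plants at 200× depth with 1% base error — the classifier recovers every
simulated genotype:

```r
spec <- cohort_spec(locus$seq, top$edited_allele, 500, 500,
                    n_plants = 24, depth = 200, error_rate = 0.01, seed = 99)
r <- genotype_recovery(spec)
r$recovery
#> [1] 1
r$summary
#> Cohort locus (n = 24 samples)
#>   precise deletion: 75.0%   indel: 25.0%
#>   among precise: homozygous 33.3%, heterozygous 33.3%, chimeric 33.3%
```

The 75% / 25% split and the equal thirds follow from the simulated
genotype mix (¼ each homozygous, heterozygous, chimeric, wild type:
chimeric plants carry the indel allele, wild-type plants carry no edit).

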