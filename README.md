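# isohybrid

Hybrid long- and short-read transcriptome characterization with
differential splicing calls, built as a tested, desk-scale R pipeline.

## The problem

Full-length cDNA sequencing (PacBio-style circular consensus reads)
reveals complete isoform structures — novel splice forms, lncRNAs,
fusion transcripts, alternative polyadenylation — while short reads
supply the depth needed to *quantify* splicing. Studies combining the
two (here modeled on a goat skin wound-healing design: control day-0
`CK` vs wounded day-5 `W`) chain together many small, well-defined
computations:

1. classify long reads into **full-length non-chimeric (FLNC)**,
   **full-length chimeric** and **non-full-length** by terminal primer
   and poly(A) detection;
2. **collapse** redundant spliced alignments into unique isoform models
   (exact junction chains, 50 bp end tolerance, absorption of
   5′-degraded fragments) and filter them with short-read junction
   support;
3. classify each isoform against the reference annotation into the
   eight structural categories **FSM / ISM / NIC / NNC / Antisense /
   Genic_Intron / Genic_Genomic / Intergenic**, assign known genes,
   cluster novel ones, and count extended locus boundaries;
4. predict **ORFs** with completeness classes (complete / 5′-partial /
   3′-partial / internal) and call known and novel **lncRNAs**
   (length > 200 nt, no ORF ≥ 100 aa, low intrinsic coding score);
5. detect **AS events** (exon skipping, intron retention, alt 5′/3′),
   cluster **poly(A) sites** (support > 0, single linkage at 15 bp) and
   find **fusion candidates** from split alignments;
6. quantify splicing with the exon inclusion level

   **ϕ = (I/LI) / (I/LI + S/LS)**,

   calling an event differentially spliced between groups when
   **Δϕ = |ϕ₁ − ϕ₂| > 0.05** and the Benjamini–Hochberg **FDR ≤ 0.01**
   of a two-sided exact test on [[I₁,S₁],[I₂,S₂]]; plus per-variant
   read assignment and 2^−ΔΔCt qPCR arithmetic.

Every stage is implemented in `R/` behind a small, documented API, and a
first-class **synthetic-data generator** plants every structure the
pipeline must find (known truth labels, true ϕ per condition, fusion
breakpoints, APA site clusters), so each stage is tested against ground
truth and against independent brute-force oracles.

## Worked example

The `analysis/` directory holds numbered drivers (`01_simulate.R` …
`07_report.R`) that run the whole study and write tables under
`results/`. In a session:

```r
library(isohybrid)
report <- run_pipeline(sim_config())
print(report)
#> <run_report>
#>   reads: 5000 (FLNC 4113, chimeric 501, non-FL 386)
#>   isoforms after collapse+filter: 45
#>   AS events: 8; APA genes: 12; fusions: 2
#>   differentially spliced events: 4 of 8 testable
```

Reading the numbers: of 5,000 simulated reads the classifier recovered
every planted label (10% chimeric, 8% non-full-length, 1% of full-length
reads missing poly(A)); 96 redundant aligned models collapsed to exactly
the 45 expressed isoforms; the eight planted AS events were all
re-detected, and exactly the four events planted with Δϕ = 0.3 between
CK and W were called significant (the four Δϕ = 0 events were not):

```r
report$diff_splicing[, c("event_id", "event_type", "phi1", "phi2", "delta_phi", "significant")]
#>   event_id       event_type  phi1  phi2 delta_phi significant
#> 1    EV001    exon_skipping 0.630 0.332     0.298        TRUE
#> 2    EV002 intron_retention 0.652 0.324     0.328        TRUE
#> 3    EV003       alt_5prime 0.670 0.356     0.314        TRUE
#> 4    EV004       alt_3prime 0.642 0.326     0.316        TRUE
#> 5    EV005    exon_skipping 0.632 0.664     0.032       FALSE
#> ...
```

`compute_phi(30, 10, 2, 1)` returns `0.6` — the closed form
(30/2)/(30/2 + 10/1) — and `ddct_relative_expression(10, 5, 9, 5)`
returns `0.5` (ΔΔCt = 1).

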