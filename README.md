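# bbsplice

Beta-binomial statistics for alternative splicing, with protein-level
effect prediction.

`bbsplice` analyzes local splice events — exon skips, intron retention,
alternative 3'/5' splice sites, mutually exclusive exons — quantified as
two isoform read counts per sample, the form in which splice-graph tools
export event counts from RNA-seq. It is aimed at two audiences: analysts
comparing splicing between sample groups (tumor vs normal, mutant vs
wild-type), and analysts hunting for splicing *outliers* — events in a
single patient that fall outside the range of a reference panel, as in
rare-disease diagnostics and tumor-specific isoform discovery. Each event
can then be translated into its predicted protein consequence and exported
as protein FASTA databases for proteogenomic validation by mass
spectrometry.

## The statistics

Counts for an event are modeled as beta-binomial. Sample *n* contributes
*I<sub>n</sub>* reads for isoform 1 out of *T<sub>n</sub>* total; the
latent percent spliced in (PSI) varies between samples following a beta
distribution reparameterized by its mean ψ and concentration
ω = α + β.

**Differential test.** A one-group fit (shared ψ, ω across all samples) is
compared with a two-group fit (per-group ψ, shared ω), both by maximum
likelihood under logistic constraints (2 < ω < ω<sub>M</sub> + 2 with
ω<sub>M</sub> = 200 by default, 0 < ψ < 1). The statistic

&nbsp;&nbsp;&nbsp;&nbsp;LR = ℓ<sub>two-group</sub> − ℓ<sub>one-group</sub> ≥ 0

ranks events; LR > 8 is the conventional operating threshold. Because the
depth enters through the binomial layer and biological spread through the
beta layer, high-coverage events with subtle PSI shifts and low-coverage
events with large shifts are both detectable.

**Outlier test.** Per event, the isoform with mean reference PSI < 0.5 is
the minor isoform. A beta distribution is fitted to the reference panel's
minor-isoform usage with 1/β<sub>M</sub> < α<sub>R</sub> ≤ 1 <
β<sub>R</sub> ≤ β<sub>M</sub> (β<sub>M</sub> = 80 by default), i.e. a
strictly decreasing density. A test sample scores

&nbsp;&nbsp;&nbsp;&nbsp;score = −log₁₀ P(X ≥ I<sub>s</sub>),&nbsp;
X ~ BetaBinomial(T<sub>s</sub>, α<sub>R</sub>, β<sub>R</sub>)

with threshold 10. If the panel has no minor-isoform reads, the fit is the
closed form α<sub>R</sub> = 1, β<sub>R</sub> = min(β<sub>M</sub>, ΣT).
Scores from two reference panels combine by the elementwise minimum.

Comparator baselines (Welch t-test on PSI, MAD and IQR outlier scores,
optionally masking depth < 10) are included for benchmarking, and a
synthetic-data module generates beta-binomial count tables plus a toy
genome/annotation whose protein-level annotation is known by construction.

## Worked example

```r
library(bbsplice)

tab <- simulate_counts(5,
  list(list(label = "ctrl", n_samples = 6, psi = 0.15),
       list(label = "case", n_samples = 6, psi = 0.55)),
  omega = 40, depth = 80, seed = 42)
groups <- setNames(ifelse(startsWith(tab$samples, "ctrl"), "CTRL", "CASE"),
                   tab$samples)
diff_test(tab, groups)[, c("event_jid", "lr", "psi_group1", "psi_group2",
                           "group_increased_alt", "pass")]
```

```
                         event_jid    lr psi_group1 psi_group2 group_increased_alt pass
1 1s+:g.3000j3200>3000j3230[splA3] 16.99      0.579      0.160                CTRL TRUE
2 1s+:g.3500j3700>3500j3730[splA3] 11.55      0.563      0.184                CTRL TRUE
3 1s+:g.2000j2200>2000j2230[splA3] 10.90      0.491      0.177                CTRL TRUE
4 1s+:g.2500j2700>2500j2730[splA3] 10.62      0.554      0.153                CTRL TRUE
5 1s+:g.1500j1700>1500j1730[splA3]  9.49      0.575      0.159                CTRL TRUE
```

All five simulated events separate the groups: the fitted PSI of isoform 1
is ≈ 0.55 in the cases (`psi_group1`; group labels sort alphabetically, so
group 1 is CASE) versus ≈ 0.17 in the controls, every LR clears the
threshold of 8 (`pass`), and the controls show increased usage of the
alternative isoform (isoform 2). Protein annotation of a generated
exon-skip fixture with a 103-nt cassette:

```r
toy <- make_toy_annotation()
annotate_events(toy$counts, toy$annotation)$effects[2,
  c("event_cat", "effect_cat", "aa_change_type", "refSeqPos", "altSeqPos", "altPept")]
```

```
  event_cat      effect_cat aa_change_type refSeqPos altSeqPos                         altPept
2  ExonSkip FrameDisruption          Novel     32-78     32-62 HILPRTVSQMDAELKDFGHILPRTVSQMDA*
```

Skipping a 103-nt exon shifts the reading frame: residues 32 onward are
replaced by a novel 31-residue run ending at a new stop, and the peptide is
absent from every annotated isoform of the gene (`Novel`) — the kind of
event that the exported novel-sequence FASTA database lets a mass
spectrometry search confirm.

A command-line wrapper with the same functionality is installed at
`inst/scripts/bbsplice` (subcommands `diff`, `outlier`, `baseline`,
`prot`, `filter`, `combine`, `simulate`).

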