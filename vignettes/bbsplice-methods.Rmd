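---
title: "Statistical models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbsplice)
```

# The data

A local splice event is a binary alternative in transcript structure —
exon skip (ES), intron retention (IR), alternative 3'/5' splice site
(A3/A5), or mutually exclusive exons (MX) — quantified per sample by two
read counts: reads supporting isoform 1 and reads supporting isoform 2.
The percent spliced in (PSI) of isoform 1 is `iso1 / (iso1 + iso2)`,
undefined at zero depth. "Isoform 1" is simply the isoform listed first in
the input; every statistic in the package is either reported for isoform 1
with the complement implied, or is invariant under relabeling, so the
choice carries no information.

Events are identified by a canonical string built from contig, strand and
both isoforms' junction coordinates, e.g.
`6s+:g.10723474j10724789>10723474j10724803[splA3]`. Junctions are stored as
(last exonic base of the upstream exon, first exonic base of the downstream
exon), 1-based, in genomic order regardless of strand; identifiers contain
no whitespace.

# The beta-binomial differential test

Counts are modeled as beta-binomial: sample `n` contributes `I_n` isoform-1
reads out of `T_n` total, with the latent per-sample PSI drawn from a beta
distribution. The beta is reparameterized by its mean `psi` and
concentration `omega = alpha + beta`; `psi` is the expected PSI and `omega`
captures how tightly biological replicates cluster around it. The binomial
layer models sampling depth, the beta layer biological variation — which is
why the test can use deep events with subtle PSI shifts and shallow events
with large shifts on the same footing.

The one-group model fits a single `(psi, omega)` to all samples by maximum
likelihood; the two-group model gives each group its own `psi` but shares
`omega` (different expected PSI, similar replicate-to-replicate spread).
The statistic is

```
lr = loglik(two-group) - loglik(one-group)
```

which is non-negative at the optimum because the models are nested. Events
are ranked by `lr`; the conventional operating threshold is `lr > 8`, and
no multiple-testing correction is applied — ranking plus a fixed threshold
is the intended operating mode. Degrees of freedom differ by one between
the models, so `lr` behaves like half a chi-square(1) deviance under the
null; the calibration property below checks the operating threshold
directly rather than relying on that asymptotic.

Constraints are imposed through logistic transforms of the optimizer
coordinates: `omega = omega_max / (1 + exp(a)) + 2` keeps
`2 < omega < omega_max + 2`, and `psi = 1 / (1 + exp(b))` keeps
`0 < psi < 1`. The default `omega_max = 200` bounds how spiky the beta may
become; the lower bound of 2 keeps both beta shapes above zero for any
mean.

Numerical choices:

* Optimization is Nelder-Mead with a BFGS fallback on failure, relative
  tolerance 1e-8, at most 500 iterations. `psi` is initialized at the
  pooled moment estimate `(sum(I) + 0.5) / (sum(T) + 1)` and `a` at 0
  (`omega = omega_max/2 + 2`); the moment start avoids stalls at the
  boundaries. If the optimizer ends below its starting value, the starting
  value is kept.
* Samples with `T_n = 0` contribute zero log density (a zero-trial
  beta-binomial is the unit mass) and are excluded from the used-sample
  counts; an event needs at least 2 covered samples per group to be
  scored — with fewer, a shared-versus-separate-PSI comparison is not
  meaningful. Events failing this are flagged, never dropped silently.
* Fits are computed in a canonical isoform orientation (the labeling with
  the smaller pooled count, decided in integer arithmetic) and mapped
  back. This makes the reported `lr` exactly invariant — to the last bit —
  under swapping the isoform columns, instead of merely up to optimizer
  noise.
* If the two-group optimum lands below the one-group optimum (optimizer
  noise in a nested pair), the two-group fit is replaced by the shared
  fit, so `lr >= 0` holds by construction as well as in expectation.

# The outlier score

Outlier detection asks a different question: is one sample's minor-isoform
usage extreme relative to a reference panel? Per event, the minor isoform
is the one with mean PSI below 0.5 across covered reference samples (an
exact tie goes to isoform 1; orientation is decided on the reference only
and applied unchanged to test samples). A beta distribution is fitted to
the reference panel's minor-isoform counts with shapes constrained to
`1/beta_max < alpha_R <= 1 < beta_R <= beta_max` (logistic transforms
again; default `beta_max = 80`), which forces the density to be strictly
decreasing: under the reference, more minor isoform is always less likely.
If the panel contains no minor-isoform reads at all, the fit has a closed
form: `alpha_R = 1`, `beta_R = min(beta_max, sum(T_n))`.

A test sample with `I_s` minor reads out of `T_s` is scored by the
upper-tail probability of its count under the fitted beta-binomial:

```
score = -log10 P(X >= I_s),  X ~ BetaBinomial(T_s, alpha_R, beta_R)
```

accumulated in log space so deep events with extreme counts still get
finite scores. Scores are non-negative, exactly 0 at `I_s = 0`,
non-decreasing in `I_s`, and conventionally thresholded at 10. The test is
one-sided by construction: a *deficit* of the minor isoform is never in
the tail of a strictly decreasing density, so only excess usage is
detectable.

Two conventions deserve emphasis because they were genuinely open:

* **Sign and base.** The score is the negative log10 of a tail
  probability, i.e. p-value-like: a score of 10 means an upper-tail
  probability of 1e-10. A raw log of a cumulative probability is
  non-positive and cannot be compared against a positive cutoff; the
  negative-log10 reading reconciles the decreasing-density construction,
  the positive threshold, and interpretability. Users comparing against
  other tools should check which convention those report.
* **Orientation on covered samples.** Mean reference PSI is computed over
  reference samples with nonzero depth; zero-depth samples carry no
  orientation information.

When two reference panels are available, the conservative combination is
the elementwise minimum of the two scores, with a missing score in either
run propagating as missing — an event counts as an outlier only if both
panels support it.

# Comparator statistics

Three deliberately simple baselines operate on PSI values directly, with
optional masking of observations below depth 10:

* Welch's two-sample t-test (unequal variances, Welch-Satterthwaite
  degrees of freedom) on per-group PSI. If both groups have zero variance
  the statistic is degenerate; the p-value is reported as 1 when the means
  agree and 0 otherwise, with a flag, so benchmark sweeps complete.
* MAD score: `(x_s - median(x_R)) / max(median(|x_R - median(x_R)|), 0.01)`,
  signed.
* IQR score: 0 inside the reference interquartile box, otherwise the
  distance to the nearer quartile over `max(Q75 - Q25, 0.01)`. Quartiles
  use linear interpolation between order statistics (`quantile` type 7),
  recorded here because the convention affects small panels.

The 0.01 floors prevent division blow-ups on nearly constant reference
panels; both floored branches are pinned by tests.

# Protein effect prediction

Each event isoform is matched against the protein-coding transcripts of
its gene (read from GTF plus genome FASTA, so no annotation service or
network is involved): a transcript matches an isoform when every junction
of that isoform coincides with one of the transcript's intron boundary
pairs — for two-junction isoforms the enclosed exon must be present
exactly, and for intron retention the retained interval must lie inside a
single exon. For each matching transcript the matched isoform's junctions
are swapped for the other isoform's and the exon chain is rebuilt from the
transcript span plus the edited intron set; the edit is an exact
involution, and inconsistent edits (overlapping or empty exons) downgrade
to an Unknown effect.

Both transcripts are translated from the annotated start codon with the
standard code, reading through in whatever frame the edit produces and
stopping at the first stop codon. The altered region is localized by
longest-common-prefix / longest-common-suffix trimming — exact here, since
by construction the two proteins differ in one contiguous edit, so no
alignment heuristic is needed. One wrinkle: a common suffix consisting
solely of the terminal `*` is *not* trimmed. When the residues before the
stop differ, the new stop belongs to the altered run, so a frameshifted
protein reports its novel tail through `*` (e.g. an altered peptide like
`SSFQF*`), rather than an off-by-one interval.

Effects are classified as:

* `Silent` — proteins identical;
* `FrameDisruption` — spliced CDS length change not a multiple of 3
  (measured as the change in exonic bases within the annotated CDS span);
* `Insertion` / `Deletion` — in-frame length gain/loss (an equal-length
  in-frame substitution, possible for MX, is reported as Insertion by
  documented tie-break);
* `Truncation` — in-frame edit introducing an early stop;
* `StopLoss` — the stop codon is lost (no stop reached, or the new stop
  lies beyond a lengthened protein);
* `NonCoding` — the edited region does not intersect the CDS;
* `Unknown` — no matching transcript, or the edit could not be applied.

The printed output categories of the reference implementation cover only a
subset (frame disruption, insertion, silent); the remainder of the
taxonomy is defined here and exercised by the generated fixtures. The
altered peptide is called `Novel` when it is not a substring of any
annotated protein isoform of the gene, `Known` otherwise (an empty altered
peptide — a clean deletion — is Known by definition). One sequence pair per
event is selected by: (1) pairs where the target isoform is also annotated,
(2) longest altered peptide, (3) longest starting protein, with a final
lexicographic tie-break on transcript id. Selenocysteine, readthrough and
non-standard codes are unsupported and yield Unknown.

Outputs are the effects table (identifier, categories, novelty, altered
intervals and peptides, and the group with increased alternative-isoform
usage copied from the differential fit) plus two protein FASTA databases:
known-isoform sequences and novel sequences, mirroring the two-database
search design used when matching tandem mass spectra.

# The synthetic-data generator

`simulate_counts()` draws data from exactly the generative model the tests
assume: per sample, PSI from `Beta(omega * psi, omega * (1 - psi))`, depth
from Poisson, the isoform-1 count binomial. Defaults used throughout the
checks are the separations the methods are designed around: `psi` 0.3
versus 0.7 with `omega = 50` and depth 100 for differential power and
recovery; `psi = 0.5` both sides at depth 50 for null calibration; a
low-minor-usage panel (`psi = 0.05`, `omega = 60`, depth 80) for outlier
self-calibration. Zero-depth draws are kept to exercise missing-data
paths. Problem sizes in the shipped checks — 200 events for power, 2000
for null calibration, 100 events by 20 held-out samples for outlier
calibration, 100-instance grid-oracle sweeps — were chosen as the smallest
sizes at which the Monte-Carlo error of each property is comfortably below
its acceptance margin.

Because the generator and the tests share the beta-binomial assumption,
passing calibration says the implementation is correct *under the model*;
it does not certify behavior on real RNA-seq, where depth is not Poisson,
PSI variation is not beta, counts can be overdispersed by mapping
artifacts, and events are not independent. The grid-search oracles,
closed-form identities and hand-computed values are model-free and carry
that part of the burden.

`make_toy_annotation()` builds a synthetic genome (one contig, under
100 kb) with one gene per supported (event type, effect category)
combination, alternating strands. Designs control codon phase so each
category is forced: a 102-nt cassette deletes 34 residues in frame while a
103-nt cassette shifts the frame; retained introns carry tryptophan runs
(absent from the filler codon pool) so inserted peptides are provably
novel; a mid-codon skip juxtaposes `TA|A` to force a truncation; a gene
whose stop codon sits inside the cassette and whose 3' UTR has no in-frame
stop forces stop loss. The expected annotation of every gene is derived
from the construction arithmetic, not from the pipeline, so the toy
catalog is an end-to-end oracle for the protein module. All-frame stop
runs in the 3' UTRs guarantee frameshifted reading terminates within the
transcript.

# Known limitations

* Only two-isoform local events are handled; alternative first/last exons
  and complex multi-alteration events are out of scope, as is detecting
  events from alignments (an upstream tool's job).
* The differential test offers two-group comparison only; no continuous
  covariates or batch terms.
* LR values are reported raw and ranked; no p-value calibration against a
  chi-square reference is attempted.
* Protein prediction trusts the annotated start codon and standard genetic
  code, and reports one prioritized sequence pair per event rather than
  all candidates.
* Events matching transcripts of several genes are annotated within the
  gene recorded on the event; cross-gene matches are not searched.
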