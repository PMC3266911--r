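---
title: "Methods: from focal amplicons to candidate oncogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from focal amplicons to candidate oncogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Osteosarcomas carry highly unstable genomes in which a handful of chromosomal
regions — 17p11.2–p12 prominently among them — are recurrently amplified.
Amplification-induced overexpression is a major route to oncogene activation,
so a gene that is (i) inside a recurrently amplified segment, (ii)
overexpressed in most tumours where it is amplified, and (iii) shows a
positive copy-number/expression correlation is a strong oncogene candidate.
`oncoamp` implements that chain of reasoning as a tested pipeline:

1. **Screen** tumours for regional amplification by qPCR gene dosage.
2. **Call** absolute integer copy number (CN) genome-wide from SNP-array
   LRR/BAF signals, correcting for aneuploidy.
3. **Scan** for significantly amplified regions with a GISTIC-style G-score
   and permutation FDR.
4. **Integrate** copy number with expression: rank genes by
   overexpression-given-amplification and filter on Pearson correlation.

A seeded synthetic-cohort generator with known ground truth replaces the
original arrays, so every stage is testable offline.

## qPCR relative quantification

Gene dosage uses the efficiency-corrected ratio

$$\mathrm{ratio} \;=\; \frac{E_t^{-(Ct_t - Ct_t^{cal})}}{E_r^{-(Ct_r - Ct_r^{cal})}},$$

which reduces to $2^{-\Delta\Delta Ct}$ at the ideal efficiency $E = 2$
(the default; instrument-fitted efficiencies can be supplied per assay, and
are validated to lie in $[1, 2.2]$). A ratio of 1 corresponds to two copies,
so CN $= 2 \cdot \mathrm{ratio}$. Two thresholds are deliberately asymmetric,
following the field's convention for this assay pair:

* **amplified**: CN $> 3.5$, *strict* inequality;
* **overexpressed**: fold change $\ge 2$, *inclusive*.

Triplicate Cts are averaged (arithmetic mean of cycles) before the ratio is
formed. A tumour enters the cohort when **at least one** of the eight marker
genes spanning 17p11.2–p12 (SCO1 … TOM1L2, 10.6–17.8 Mb) is amplified.

## Copy-number calling from LRR/BAF

For a pure tumour, LRR $\approx \log_2(\mathrm{CN}/2)$ and BAF clusters at
$b/\mathrm{CN}$ for B-allele count $b$. The caller proceeds per sample:

* **Segmentation.** Greedy binary segmentation on LRR per chromosome: the
  split maximising the within-segment SSE reduction is accepted iff the
  reduction exceeds a penalty, by default $2\hat\sigma^2\log n$ with
  $\hat\sigma$ from median absolute successive differences (robust to the
  very steps being sought). The penalty is floored at $10^{-8}$ so that
  noise-free input still splits only at exact steps. Ties go to the smallest
  index; the output is deterministic.
* **Integer fit.** Per segment, minimise over integers $c \in [0, c_{max}]$,
  $b \in [0, \lfloor c/2\rfloor]$:
  $w_L(\bar{L} - \log_2(\max(c,0.5)/2))^2 + w_B(\bar{m} - b/c)^2$, where
  $\bar{m}$ is the mean *mirrored* BAF $\min(B, 1-B)$ over probes with
  $\bar{m}\ge 0.05$ — effectively homozygous probes carry no allelic
  imbalance information and are excluded (standard allele-specific CN
  practice). Ties prefer smaller $c$, then smaller $b$. If a segment has no
  informative probe the BAF term is dropped. $c_{max} = 12$ by default,
  comfortably above the CN ~10 seen in real amplicon profiles.
* **Ploidy.** The probe-weighted modal segment CN genome-wide; ties to the
  smaller value. Labels are relative to ploidy (`gained`/`lost`/`normal`),
  so focal peaks on a triploid background are still gains — this is the
  aneuploidy correction, and it propagates into the amplitude definition
  below.

The published analyses used GLAD and the OverUnder plugin as black boxes;
neither algorithm is public in reproducible detail. The replacements above
are fully specified and recover simulated truth exactly at zero noise (an
end-to-end oracle exercised over multiple seeds in the test suite).

## Significance of recurrent amplification

Amplitude is linear CN above the sample's own ploidy,
$a(m,s) = \max(0, \mathrm{CN}(m,s) - \mathrm{ploidy}(s))$ — the zero point
sits exactly at ploidy, losses are ignored, and integer examples stay
integral. The per-marker G-score is the mean amplitude
$G(m) = \frac1N\sum_s a(m,s)$, jointly encoding frequency and amplitude of
aberration.

The null distribution: each permutation cyclically rotates every sample's
amplitude vector by an independent uniform offset within each chromosome,
preserving per-sample amplitude content and run lengths while destroying
cross-sample alignment. Permuted G values are pooled across markers and
permutations (a genome-wide null, giving p resolution finer than
$1/n_{perm}$), and

$$p(m) = \frac{1 + \#\{G^{perm} \ge G_{obs}(m)\}}{1 + n_{perm} M}.$$

Benjamini–Hochberg q-values follow; regions are maximal runs of markers with
$q < 0.25$, each reporting a single peak (arg-max G, leftmost on ties).
Iterative peel-off of secondary peaks is not implemented: two nearby
amplicons that never merge into one significant run are reported as two
regions, which is the geometry this analysis targets. The implementation
accumulates only non-zero amplitude runs, so permutation cost scales with
the amplified fraction of the genome; the construction is identical to the
dense one.

## Integration and ranking

Gene CN is the lower median of probes overlapping the gene's
`[start, end)` interval (lower median keeps integers integral), else the CN
of the nearest probe (ties to the lower coordinate). Fold change is the
tumour's linear expression over the osteoblast reference; multiple probes
per gene are averaged on the linear scale first. Per gene: `A` amplified
tumours, `O` overexpressed, `OA` both, and `pct` $= 100\,OA/A$ (undefined at
$A = 0$; reported to one decimal, compared at full precision). Genes with
`pct` $\ge 50$ (inclusive — a gene at exactly 50% makes the list) are ranked
by `pct`, ties by larger `OA`, then name.

The final filter computes Pearson's R between gene CN and expression with a
two-sided p from $t = R\sqrt{n-2}/\sqrt{1-R^2}$. The published cutoff
"positive R of approximately 0.5 or more and two-sided P ≤ 0.05" is
operationalised as $R > 0 \wedge P \le 0.05$: this reproduces the published
partition exactly (the marginal R = 0.49 gene passes; the two negative-R
genes fail), without inventing a hard 0.5 boundary the source itself
softened to "approximately". A strict `min_r` is available for users who
want it. Constant input vectors yield an undefined R and a non-passing,
flagged result rather than an error.

## The synthetic cohort: what it does and does not emulate

Defaults state the scaled-down world the property tests run in: three
chromosomes (~5,000 probes; chr17 at real length, two neutral autosomes),
20 tumours, ploidy drawn from {2: 0.6, 3: 0.3, 4: 0.1}, two chr17 amplicons
(CN 6, penetrance 0.5) centred at 13.5 and 17.2 Mb, LRR noise sd 0.15, BAF
noise sd 0.03. A full 370k-probe array is a `chrom_layout` away. Germline
genotypes are drawn per probe at population allele frequency 0.5;
heterozygous probes place all extra copies on one haplotype chosen uniformly
*per probe* (no linkage disequilibrium), so the B-count is 1 or CN−1 and the
mirrored BAF is exactly 1/CN either way — precisely the statistic the caller
consumes. CN-0 probes emit uniform BAF and LRR floored at −5.

Expression: $\log_2 x(g,s) = \beta_g + \gamma\,\log_2(\mathrm{CN}/2)\cdot
Z_{gs} + \varepsilon$ with dosage slope $\gamma = 1$, coupling indicator
$Z_{gs}\sim\mathrm{Bern}(0.65)$ by default (the published top genes show
50–76.5% overexpression-given-amplification), noise sd 0.25, and a single
osteoblast reference column. Per-sample child seeds are derived from one
root seed by fixed arithmetic, so cohorts are reproducible under
subsetting.

Not modelled, by design: tumour purity (the source cohort was >90% tumour
content; purity fixed at 1), subclonality, germline CNVs, sex chromosomes,
probe-level replicates, LD. A green test therefore establishes that the
*algorithms* recover a stated truth under calibrated noise — not that the
generator reproduces every failure mode of real arrays.

## Numerical choices

* All coordinates are 0-based half-open internally; BED on disk.
* Strict vs inclusive thresholds exactly as stated above; q-cutoff strict
  (`q < 0.25`).
* Deterministic tie-breaks everywhere (segmentation: smallest index; CN fit:
  smaller c then b; ploidy: smaller value; peaks: leftmost; ranking: larger
  OA then name), so equal seeds give byte-identical outputs — the pipeline
  manifest records md5 checksums to make this checkable.
* `p(m)` uses the add-one estimator, so no permutation p is ever 0 and
  `G = 0` implies `p = 1`.

## Known limitations

The permutation null conditions on the called amplitude matrix, not on raw
signal, so segmentation errors propagate into significance. The single-peak-
per-region rule can merge two amplicons bridged by a significant valley.
The ≥50% ranking treats every tumour with both data types equally; it does
not model per-tumour measurement quality.
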