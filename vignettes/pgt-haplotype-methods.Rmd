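---
title: "Haplotype-based PGT-M: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based PGT-M: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgthap)
```

## The clinical problem

A mother heterozygous for an autosomal-dominant pathogenic variant (the
motivating case is an *SPTB* splice variant at chr14:65,271,654 causing
hereditary spherocytosis) undergoes IVF with preimplantation genetic
testing. Each embryo contributes only a few trophectoderm cells, whose
whole-genome-amplified DNA suffers **allele dropout (ADO)**: a heterozygous
locus randomly loses one allele and types as homozygous. A direct genotype
of the variant site alone can therefore misdiagnose an embryo. The remedy
is linkage: type a dense panel of SNPs around the variant, phase the
mother's two haplotypes, label the variant-bearing one **M1**, and ask
which maternal haplotype each embryo inherited. A single dropout can
corrupt one SNP, but not a whole flank of them.

`pgthap` implements this workflow end to end, together with the companion
analyses a PGT cycle needs: mosaic-aneuploidy calling from low-pass
coverage, noninvasive fetal haplotype prediction from maternal plasma, and
splice-effect verification at the transcript level. A synthetic-family
generator reproduces the statistical structure of each input, so the whole
pipeline is testable without access to any subject data.

## Phasing through a reference embryo

Parental phase is obtained without population panels by using a
non-transferable ("waste") embryo of known carrier status as a proband.
At a **maternally informative** site — mother heterozygous, father
homozygous — the father's contribution to any child is forced, so
subtracting it from the reference embryo's genotype reveals the maternal
allele it received. The haplotype so assembled is labelled M1 if the
reference embryo carries the variant and M2 otherwise. Sites where both
parents are heterozygous are excluded outright (no statistical phasing is
attempted); sites whose reference genotype is impossible under Mendelian
inheritance are flagged and dropped. The same deduction with roles swapped
phases the father where requested; since the variant is maternal, P1 is
anchored arbitrarily to the haplotype transmitted to the reference embryo.

The phasing window defaults to 4 Mb total (±2 Mb around the variant),
a user-settable knob: published karyomapping-style workflows variously use
1–2 Mb per side, and the window is a trade-off between marker count and
recombination risk. At least one phased site is required on each flank;
fewer than five per flank triggers a warning, since flank-wise voting (next
section) needs headroom over its minimum support.

## Embryo diagnosis under allele dropout

Per site, the embryo's maternal allele is deduced exactly as in phasing.
Observed genotypes homozygous for the non-paternal allele lack the obligate
paternal allele; the only single-event explanation is dropout of the
paternal allele, so such sites are flagged `ADO_SUSPECT` and excluded from
voting rather than trusted.

The ordered M1/M2 calls are then explained by one of two models:

* **homogeneous** — one haplotype throughout, with a tolerated minority of
  discordant calls (dropout- or error-induced flips);
* **single changepoint** — haplotype A up to some inter-site gap, B after
  it (a meiotic recombination).

Each model's *misfit* is its number of discordant calls. A model is
admissible if its misfit fraction is at most `max_minority_fraction`
(default 0.15) and its support is sufficient: for the homogeneous model the
winning haplotype needs at least `min_support` calls (default 3) on **each
flank** of the variant and must win both flanks; for the changepoint model
each segment needs at least `min_support` calls. The admissible model with
the fewer discordant calls wins; ties go to the homogeneous model (no
recombination is the parsimonious explanation). Anything else is
`NO_CALL`. The defaults are chosen so that a single ADO or genotyping error
can never flip a call; both are configurable.

Two details deserve a note. First, the minority fraction of the
homogeneous model is assessed on the pooled calls, while support is
assessed per flank: with 11 informative markers per flank a per-flank
minority criterion would turn two stray flips in one flank (probability a
few percent per embryo at ADO 0.1) into forced no-calls, which is both
clinically wasteful and inconsistent with the accuracy this decision rule
otherwise achieves; the pooled criterion preserves single-flip robustness.
Second, the changepoint model is scored against the homogeneous model
rather than tried only when the flanks disagree: a recombinant whose short
segment sits at one end of the window would otherwise be absorbed as
"minority noise".

A recombinant call localizes the breakpoint to the gap between the last
discordant pair of informative sites. The haplotype at the variant is that
of the variant-proximal segment; if the breakpoint gap straddles the
variant itself, no linkage call is possible.

The final diagnosis requires concordance between linkage and the direct
variant genotype: M1 + variant present = carrier; M2 + variant absent =
non-carrier; any discordance (possible dropout at the variant site, or
unresolved recombination) forces `no_call` — the conservative clinical
posture, trusting neither source over the other. A missing direct test
yields a linkage-only call flagged as lower confidence. If the CNV stage
finds the chromosome carrying the variant non-euploid, the linkage result
is voided for that embryo, because diploid origin-calling assumptions no
longer hold.

## Mosaic aneuploidy from low-pass coverage

Binned read counts are modelled as Poisson with mean proportional to local
copy number. A whole-chromosome mosaic trisomy in a fraction `m` of biopsy
cells gives mean copy number `2 + m`, hence copy ratio `r = (2 + m)/2` and
the inversion `m = 2(r − 1)` for gains (`2(1 − r)` for losses), clipped to
[0, 1]. Only whole-chromosome aggregation is performed — the motivating
case involves whole-chromosome mosaic trisomies — and no GC correction is
applied (the simulator is GC-neutral; a per-bin covariate hook is the
natural extension).

Per-bin ratios use the genome-wide median of unmasked autosomal bin counts
(zero-count bins are masked). The **per-chromosome** ratio, however,
divides the chromosome's mean count by the median of the *other*
autosomes' bins: a leave-one-out reference. With the assayed chromosome
included, its own trisomic bins shift the reference median upward and bias
`m` low — by roughly 0.1 when a quarter of all bins are trisomic — so
excluding the tested chromosome from its own baseline is required for
unbiased dosage, at negligible cost when the genome is large.

Classification uses the common PGT-A reporting bands: `m < 0.2` euploid,
`0.2–0.8` mosaic, `> 0.8` full aneuploidy; an embryo has a normal
karyotype only if every called chromosome is euploid. A chromosome whose
`|r − 1|` is below the noise floor (default 0.05) is reported as direction
"none" with `m = 0`. When the simulated `m` equals a band boundary
(e.g. 0.8), measurement noise makes either adjacent class the expected
outcome; the validation suite treats both as correct at the boundary
value only.

## Noninvasive fetal haplotype prediction (NIPT-M)

Maternal plasma is a mixture: a fraction `ff` of cfDNA is fetal. At a
maternally informative site the expected alt-read fraction is

    p = (1 − ff) g_m / 2 + ff g_f / 2,

where the fetal genotype `g_f` is the hypothesized transmitted maternal
allele plus the father's obligate allele; sequencing error `e` attenuates
every expectation toward ½ as `p' = e + (1 − 2e) p`. At `ff = 0` both
hypotheses collapse to ½ — the dosage signal vanishes — so a positive
fetal fraction is a precondition for classification.

Three estimators precede classification. The error rate is the pooled alt
fraction over sites where both parents are homozygous reference (no true
alt allele can be present). The fetal fraction uses the
paternal-specific-allele estimator: where the mother is homozygous
reference and the father homozygous alternate, the fetus is an obligate
heterozygote and the expected alt fraction is `ff/2`; the estimate is
twice the mean alt fraction, error-corrected. Relative haplotype dosage
then accumulates, in site order, the binomial log-likelihood ratio of "M1
transmitted" against "M2 transmitted" and applies a sequential probability
ratio test with bounds `log((1−β)/α)` and `log(β/(1−α))`,
`α = β = 10⁻⁴` by default. Informative sites are processed in blocks of at
most 100; the fetal status is taken from the variant-containing block
(M1 = carrier, M2 = non-carrier, undecided = no call), with the flanking
blocks' agreement reported as a consistency check. Only the maternal
haplotype is tested by default — the variant is maternal — though the
dosage logic is symmetric.

## The synthetic-family generator

The generator emulates, with one shared seed, every input the pipeline
consumes; each operation draws from its own stream derived from
(seed, operation tag), so adding a stage never perturbs another stage's
output. Defaults are fixed once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| SNPs in window | 200 | chip-density markers in a 4 Mb window |
| window | 4 Mb total | ±2 Mb around chr14:65,271,654 |
| minor allele frequency | U(0.2, 0.5) | informative band of a genotyping array |
| ADO rate | 0.05 | typical single-cell WGA order of magnitude |
| genotyping error | 0.005 | chip-scale error |
| embryos | 5 | two euploid non-carriers, two mosaic non-carriers (one with multiple mosaic chromosomes), one mosaic carrier |
| coverage bins | 1100 (~45/autosome) | low-pass CNV-seq granularity |
| reads per bin | 100 | low-pass depth |
| fetal fraction | 0.10 | typical second-trimester value |
| plasma depth/site | 100 | targeted-panel depth |
| plasma error rate | 0.002 | NGS per-read error |

Founder haplotypes are drawn site-wise from the allele frequency
(Hardy–Weinberg founders, no linkage disequilibrium); recombination is
specified as explicit breakpoints per embryo rather than a rate, so a
switch can be placed deterministically; trisomy is whole-chromosome only.
These simplifications mean the generator validates the *decision logic*
under the assumed error models — it does not establish performance on real
chip intensities, LD structure, segmental aneuploidy, or GC-biased
coverage, and passing tests should be read accordingly.

## Validation experiments and problem sizes

The package's acceptance suite runs these experiments (sizes chosen to
make every Monte-Carlo bound sharp at interactive runtimes):

* **Splice worked example.** A synthetic 400-nt CDS carrying the known
  21-base segment `GGTGCTCTCTGGAGAGATGCT` at coding positions 279–299;
  deleting it must be called as an in-frame `c.279_299del`. The fixture
  pins the base after the interval so the placement is unambiguous; on
  references where the interval abuts a repeat, the reported interval is
  the HGVS 3'-most representative of the same edit, found by exhaustive
  interval enumeration in the test oracle.
* **Phasing.** 200 random trios of up to 10 sites, compared against
  exhaustive enumeration of all Mendelian-consistent phase assignments.
* **Embryo diagnosis.** 500 embryos, 22 informative SNPs (11 per flank),
  ADO 0.1, genotyping error 0.005: at least 99% of decided diagnoses
  correct and at most 5% no-calls; with no noise, 100% correct.
* **Recombination.** Noise-free single breakpoints across every interior
  inter-site gap (segments kept at or above the support minimum) must be
  localized to the true gap.
* **Mosaicism.** `m ∈ {0, 0.3, 0.5, 0.8, 1}` at 1000 bins × 100 reads on
  a compact four-chromosome genome (250 bins on the assayed chromosome;
  the diploid majority keeps the leave-one-out reference clean):
  `|m̂ − m| ≤ 0.05` in at least 95% of 200 replicates.
* **NIPT-M.** 200 pregnancies at ff = 0.10, depth 100, 200 informative
  sites: the transmitted haplotype correct in at least 99% of decided
  replicates, fetal fraction recovered within ±0.01, error rate within
  three binomial standard errors.
* **Determinism.** Re-running any workflow with the same seed reproduces
  byte-identical artifacts.

## Numerical and degenerate-input choices

Genotypes are stored as alt-allele dosages (0/1/2, `NA` missing);
coordinates are 1-based inclusive for variants (VCF convention) and
0-based half-open for coverage bins (BED convention). Transcript alignment
uses unit mismatch/gap costs; clean single-interval deletions are detected
exactly via the longest common prefix/suffix (which is the unit-cost
optimum for such pairs and directly yields the 3'-most placement), and the
general alignment path adds a one-unit gap-opening penalty solely to
prefer contiguous gaps among co-optimal paths. Zero informative sites, an
unanchored reference embryo (unknown carrier status), an empty flank,
all-zero coverage, and `ff = 0` are all hard errors or explicit no-calls
rather than silent degradation.

## Known limitations

No LD-aware simulation or population phasing; no X-linked or mitochondrial
logic; no segmental CNV or sex-chromosome ploidy; no HMM-style
probabilistic origin inference (flank voting is deliberately transparent);
transcript comparison covers CDS-level deletions, not genomic HGVS or
splice-strength prediction. These mirror the intended clinical scope: a
single autosomal-dominant maternal variant with a dense informative SNP
window.
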