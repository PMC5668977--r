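---
title: "heatmir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatmir: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`heatmir` reconstructs, as a tested pipeline, the analysis by which known and
novel plant miRNAs are identified from multi-library small RNA sequencing and
heat-responsive expression changes are called. This vignette documents the
models, every tunable parameter that matters, the synthetic study the package
validates itself against, and the design decisions taken where the method
left room.

## Preprocessing model

A raw read is assumed to be `insert + 3' adapter`, truncated to the read
length. The insert is the maximal prefix before the leftmost exact occurrence
of the adapter's first `seed_len = 8` bases; reads whose 3' terminus carries
only a shorter adapter prefix still count as matched down to
`min_terminal = 5` nt. Reads with no adapter evidence are discarded rather
than passed through: an untrimmed read cannot be distinguished from a longer
RNA, and a deterministic rule keeps the operation exactly testable. Inserts
shorter than 15 nt or longer than 40 nt, inserts containing `N`, and
poly(A)-dominated inserts (≥ 80% A, switchable via `polya_filter`) are
discarded, each with its own counted reason, so raw = kept + discarded holds
exactly at every stage.

Contaminant removal is exact-substring matching of each tag against the
user-supplied structural-RNA catalog (rRNA/tRNA/snoRNA/snRNA) and its reverse
complement. No mismatches are tolerated: the matching rule is then a
one-line oracle, and with a catalog of full-length structural RNAs an exact
15–40 nt match is already highly specific. TPM is
`count / clean_total × 10⁶`, where the clean total is the library's read
count after trimming, filtering and contaminant removal; per-library TPM over
the tag table therefore sums to 10⁶.

## Discovery model

Candidate tags need peak TPM ≥ 10 in at least one library, length 18–30 nt,
and 1–20 perfect-match genome hits. Mapping is a native k-mer-seeded exact
search (seed 12 nt, full verification of each seed hit, both strands):
with a zero-mismatch contract a seeded scan is complete, and it can be
checked verbatim against a naive full scan, which the test suite does on a
50-kb genome.

Each hit is expanded to a window of 200 bp on each side, reverse-complemented
for minus-strand hits, and folded. The built-in folding engine maximises a
stacking-aware pair score over all nested structures with a minimum hairpin
loop of 3 (GC = 3, AU = 2, GU = 1, +1 per stacked pair) by dynamic
programming, and reports `mfe = -score / 2` in pseudo-kcal/mol. The choice is
deliberate: the hairpin criteria below depend on the *topology* of the
mature/star duplex, not on calibrated energies, and a self-contained integer
DP is exactly reproducible and verifiable against exhaustive enumeration of
all structures at short lengths (the suite checks all of length ≤ 18). For
publication-grade energies every folding entry point accepts
`engine = "vienna"`, which shells out to the thermodynamic `RNAfold`
program; pseudo-energies and thermodynamic energies must not be compared
numerically across engines.

A folded candidate passes the stem-loop criteria when the mature lies
entirely on one arm outside the terminal loop, has at most `max_unpaired = 4`
unpaired bases, no asymmetric bulge larger than `max_bulge = 2` nt within the
duplex, and an opposite arm at least as long as the mature's paired extent.
These thresholds follow canonical plant-miRNA annotation practice (the
miRcheck tradition); all are arguments.

Classification precedence is strict: a candidate within 2 mismatches of any
reference mature (ungapped comparison; up to 2 nt length difference handled
by sliding, overhangs counted as mismatches) is **known** and never enters
the novel path. Remaining candidates are **novel** only if the trimmed
precursor is stable (`mfe_max = -16` kcal/mol, just above the least stable
precursors reported for plant miRNA catalogs of this kind) and a star is
structurally identifiable on the opposite arm with the canonical 2-nt 3'
overhang geometry. `discover_mirnas()` additionally requires, by default,
that the star sequence was actually sequenced (`require_star_read = TRUE`).
This was a genuinely open design point; we require star reads because (i)
star evidence is the accepted stringent criterion for novel plant miRNA
annotation, and (ii) at the TPM ≥ 10 threshold many 2-read tags become
candidates, and star evidence is the one criterion that scales with genome
size rather than with background depth. `validate_novel()` itself defaults
to flag-only so the lenient behaviour remains available.

Two scale-driven internals are worth knowing about. First, before the
cubic-time fold, each window is screened for an antisense region (Watson–
Crick or G:U) that could pair the mature within the criteria budget (≤ 4
mismatches, at most one bulge ≤ 2 nt, outside the mature itself). This is a
necessary condition for the criteria — a window without such a region cannot
pass them — and is slightly conservative only for duplexes with two or more
separate asymmetric bulges; `prescreen = FALSE` disables it. Second, one
catalog record is emitted per distinct mature sequence, keeping the first
genome coordinate when several loci qualify; highly expressed passenger
strands (miRNA*) that themselves clear the TPM filter are annotated as their
own arm records, as real catalogs do.

## Expression model

Replicates are pooled by summing counts per condition before testing; the
chi-square test compares a miRNA's pooled count in HS against CK relative to
the pooled clean totals (2×2 Pearson chi-square, df 1, no continuity
correction — the counts at which calls are made are large enough that the
uncorrected statistic matches its asymptotics, and it is the closed form
`N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` that the tests verify to 1e-9). Calls
require `|log₂FC| ≥ 1` and raw `p ≤ 0.05`; a Benjamini–Hochberg `q` column
is reported alongside but deliberately not used for calls, mirroring
standard practice for this test. The fold change uses pooled TPM with a
pseudo-count of one pooled read on each side
(`ε = 10⁶ / pooled_total`), which keeps log-fold-changes finite for
condition-absent miRNAs without distorting well-measured ones. A
conservative per-replicate mode (test each matched replicate pair, keep the
least significant p) is available via `replicate_policy = "per_rep"`.

Supporting statistics follow the field's conventions: replicate Pearson
correlations on `log₂(TPM+1)` over miRNAs expressed in at least one member
of the pair; tissue specificity (`specific` = TPM ≥ 10 in one tissue and 0
in the other at control temperature, `preferential` = the DE criteria met
between tissues at control); length distributions and positional base
frequencies over positions 1–24; qPCR fold changes by `2^−ΔΔCt` with the SE
propagated on ΔΔCt across replicate triplets; and the stigma-exsertion
D-value (stamen − pistil length, mm) with a Welch two-sided t-test.

## Targeting model

Target scoring reimplements the Allen-style plant expectation penalty as the
declared interpretation of a psRNATarget-like default configuration:
per-position penalties of 1.0 (mismatch), 0.5 (G:U), 2.0 (gap), doubled at
miRNA positions 2–13, a single 1-nt bulge allowed on either strand, and an
expectation cutoff of 3.0. Sites with a mismatch at miRNA positions 9–11 are
labelled translational; all others are cleavage sites. The cleavage
coordinate convention is fixed and documented: the cut falls between the
target bases pairing miRNA positions 11 and 10, and the reported coordinate
is the 0-based transcript index of the base opposite position 10 (for an
ungapped site spanning `[start0, end0)` this is `end0 − 10`). RACE clone
tables must use the same convention; `tally_race()` counts clones at the
predicted coordinate and reports any secondary peak supported by ≥ 2 clones.

## The synthetic study and what it does (not) show

`demo_dataset()` freezes the study conditions the pipeline is validated
under: a 100-kb random genome (GC 0.38), 30 planted hairpin loci — 20 whose
matures are taken verbatim from the synthetic reference catalog, 10 novel —
and the 16-library design (stamen/pistil × CK/HS × 2 d/12 d × 2 replicates)
at 200,000 reads per library. Planted hairpins are perfect stems (lower stem
8–14 nt, upper stem 4–8 nt, AU-rich loop 10–16 nt), giving precursors of
~61–110 nt, inside the 61–218 nt range observed for plant precursors of this
class; the generator folds and checks every hairpin before emitting it.
Baseline abundances are log-uniform on [50, 5000] TPM (the lower edge set by
the regime in which differential calls should still be powered); 10 loci are
down-regulated 4-fold in every HS library; star reads are simulated at 5% of
mature abundance; counts are Poisson around `TPM × depth / 10⁶` with a
negative-binomial option (`nb_size`) off by default, matching the count model
the chi-square test assumes. Matures carry the 5'-nucleotide bias of
AGO1-loaded plant sRNAs (~50% 5'-U, C-poor). Reads are insert + a common
small-RNA kit 3' adapter (a stand-in default, configurable per library
design), quality `"I"` throughout. Library composition is 45%
structural-RNA fragments and the remainder genomic degradation (15–40 nt),
consistent with sRNA libraries in which only ~25–30% of raw reads survive to
clean tags.

Two desk-scale artifacts deserve honesty. At 200k reads the clean totals are
~110k, so the TPM ≥ 10 rule admits every tag seen twice; random degradation
collisions then create thousands of genuine candidates, which is why the
prescreen exists. And because a 100-kb genome densely sampled by degradation
contains nearly every genomic 20-mer as a sequenced tag, a residual set of
random quasi-hairpins passes all novel criteria including star support —
on a chromosome-scale genome the same criteria are far more specific.
Passing the bundled tests therefore demonstrates correct mechanics,
calibrated error rates and full recovery of planted truth; it does not
certify the false-discovery rate of novel annotation on real genomes, nor
realism of sequencing error (not simulated), quality scores, or 5' adapter
remnants.

Problem sizes used by the test suite were chosen to keep a full run on one
CPU within a few minutes: the orchestration tests run a reduced study (8
loci, 16 × 20k reads, TPM threshold raised to 1000 to match the shallow
depth), while the acceptance tests and `scripts/acceptance.R` run the full
bundled study above, plus a 2,000-replicate Poisson null for the type-I
error of the DE test, a 50-kb mapping oracle comparison, 200 enumeration
cross-checks of the folding DP, and 1,000 random chi-square tables against
the closed form.

## Numerical and coding conventions

Coordinates are 0-based half-open internally and 1-based inclusive in GFF3
output. Sequences are handled as uppercase DNA (`T`) internally; RNA (`U`)
appears at the folding boundary and in alignments. Ties are broken
deterministically throughout (fold traceback prefers unpaired-then-stacked;
classification ties by reference name; overlapping target sites keep the
lowest expectation, then the leftmost coordinate), and every stochastic
entry point takes a seed, so identical inputs and seed give byte-identical
outputs. Degenerate inputs are defined rather than exceptional: a 2×2 table
with an empty margin tests as `chi2 = 0, p = 1`; zero-variance replicate
profiles flag `undefined` instead of erroring; a zero clean total is an
error naming the library.

## Known limitations

Pseudo-energies from the built-in engine are on their own scale and should
not be quoted as kcal/mol measurements; use the `vienna` engine for that.
Gapped alignment against the reference catalog, multi-loop precursors,
phased siRNA detection, degradome (PARE) analysis, GO/KEGG annotation and
dispersion-modelling DE (negative-binomial GLMs) are out of scope. The
chi-square DE test, like the practice it mirrors, treats pooled replicates
as one library and raw p-values as the call criterion; users wanting
shrinkage-based inference should export the count matrix to a dedicated DE
framework.
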