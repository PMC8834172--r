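---
title: "Methods: domain-resolved paralog conservation and knockout phenotype analysis"
author: "paralogPhen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-resolved paralog conservation and knockout phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogPhen)
```

## The problem

Teleost fish carry duplicated copies (ohnologs) of many genes that are
single-copy in mammals. For the voltage-gated sodium channel Nav1.1, the
zebrafish paralogs scn1laa and scn1lab are both candidate models for the
haploinsufficiency that underlies Dravet Syndrome in human *SCN1A*
patients — but the two paralogs need not be functionally equivalent.
`paralogPhen` implements the comparison at both ends:

* **genotype** — where, along the channel protein, have the paralogs
  diverged from the human reference, and what does a CRISPR knockout
  allele do to the coding sequence; and
* **phenotype** — do brain field-potential recordings show epileptiform
  and photosensitive events, and does locomotor behaviour show the
  hyperactivity / burst-movement signature.

All inputs can be supplied from real experiments (FASTA, domain tables,
trace and tracking CSV) or generated by the synthetic-data module with
known ground truth, so the entire analysis is testable offline.

## Alignment and per-domain conservation

Each paralog is aligned to the reference ortholog with a Gotoh
three-state global alignment under affine gap penalties: a gap of length
$L$ costs $g_o + (L-1)\,g_e$. Defaults are BLOSUM62 with $g_o = 10$,
$g_e = 1$ (familiar EMBOSS-style settings); the matrix and penalties are
arguments everywhere. Traceback ties are broken deterministically
(aligned pair, then gap-in-query, then gap-in-reference) so a given
input always produces the same alignment. The dynamic programme is
verified in the test suite against exhaustive enumeration of all global
alignments on short sequences.

Percent identity is computed **over reference residues**: the
denominator is the number of alignment columns in which the reference
holds a residue, so both substitutions and deletions in the paralog
count against conservation, while insertions do not add columns. This
matches the way conservation "versus the reference" is normally quoted;
`percent_identity()` also offers all-columns and shorter-sequence
denominators. `X` residues are scored by their matrix column but never
count as identical.

Reference-coordinate domain annotations (the UniProt convention:
transmembrane segments S1–S6 in channel domains I–IV, extracellular
loops, cytoplasmic linkers, pore loops, termini) are projected through
the alignment with `map_ref_position_to_column()` and scored per domain
for each paralog. The difference $\Delta = \mathrm{id}_B -
\mathrm{id}_A$ (percentage points; positive = paralog B better
conserved) is flagged when $|\Delta|$ **strictly exceeds** 20 points —
exactly 20.0 is not flagged. Domains whose reference span aligns
entirely to gaps get `NA` identity and are excluded from flagging rather
than being treated as 0. Spans shorter than 5 residues are marked
`short_peptide`: identity estimated from a handful of positions is
dominated by sampling noise, and such rows deserve an asterisk rather
than a confident call.

## The synthetic paralog family

`simulate_paralog_family()` draws a reference uniformly over the 20
canonical residues and derives each paralog site-wise: with the site's
divergence probability $d$ the residue is replaced by a uniformly chosen
*different* residue, so expected identity is exactly $1 - d$ and every
recovery test has a closed-form target. Small indels (1–3 residues) are
off by default; when enabled they are placed outside truth-flagged
domains so the flagging ground truth stays well defined.

`channel_family_spec()` packages the study conditions used throughout
the examples and the acceptance analysis: a 2216-residue reference with
58 features in the sodium-channel layout, paralog B diverging at 0.23
per site everywhere (expected protein-wide identity 77%), and paralog A
carrying an extra 0.45 divergence in 12 differentially conserved
features — among them the domain-II S4 voltage sensor and a domain-IV
cytoplasmic linker — plus a 0.02 background drift, giving an expected
protein-wide identity of 67%. These defaults mirror the published
identity pattern of the scn1laa/scn1lab pair versus SCN1A.

Two honest caveats about what the simulator does *not* model. First,
substitutions are site-independent, so an 18–30 residue feature's
realized identity has a binomial standard deviation of ~7–10 points;
with 46 near-equally-diverged features, several will cross the 20-point
flag threshold by chance in any one realization, and the *realized*
flagged count therefore sits above the 12 truth-flagged features. That
is a property of short windows, not a defect of the scorer — the
recovery guarantee (flagged set equals truth set in ≥ 95% of runs) is
stated and tested under conditions where the contrast is resolvable:
domains of ≥ 150 residues with rate differences of ≥ 0.35 against a
background of ≤ 0.05. Second, there is no phylogeny and no
position-specific substitution process; the generator answers "can the
pipeline recover a known divergence pattern", not "how did these genes
evolve".

## Knockout-allele consequence prediction

`apply_deletion()` removes a 1-based closed interval from the spliced
CDS; `translate_cds()` uses the standard nuclear code, translating to
the first stop (codons containing `N` become `X`, trailing partial
codons are ignored). `classify_edit()` reports:

* `frameshift` — deletion length not divisible by 3;
* `premature_stop_codon_index` — the edited frame's first stop when it
  falls strictly before the *stop-equivalent* position, defined as the
  wild-type stop codon index minus the number of whole codons removed
  ($\lfloor \mathrm{len}/3 \rfloor$). Without this correction every
  in-frame truncating deletion would be miscalled premature;
* `predicted_lof` — frameshift or premature stop.

Exon structure is deliberately not modelled: the pipeline edits the
spliced CDS, and exon numbers are metadata. The bundled fixture
(`synthetic_knockout_cds()`) is a fully synthetic 108-bp CDS that embeds
the real sgRNA protospacer and genotyping primer sites and reproduces
the allele's structure — a 7 bp deletion causing a frameshift into a
stop codon a few codons downstream — because the actual deleted bases
are only published as a chromatogram image.

## LFP preprocessing, spectra and spike detection

Recordings are expected at 1000 Hz. Preprocessing applies a band-stop at
50 Hz (width 2 Hz) and a band-pass at 2.5–100 Hz as **zero-phase
spectral masks**: the trace's FFT is multiplied by a real 0/1 mask and
inverted. We chose spectral masking over a zero-phase IIR (Butterworth)
chain deliberately: a projection is exactly idempotent — filtering twice
equals filtering once — whereas any IIR applied forward-backward keeps
re-attenuating its transition band (we measured 3–11% RMS change on
second application across orders 2–6), and for offline analysis there is
no causality constraint to justify that cost. The mask removes DC and
the mains line exactly and leaves pass-band amplitudes untouched; an
optional raised-cosine `transition_hz` softens the brick-wall edges if
ringing around large artefacts is a concern. The first minute of a bench
recording (electrode placement) can be trimmed with `trim_s = 60`;
synthetic traces default to no trim.

`power_spectrum()` takes one 40-s window (resolution 1/40 Hz), linearly
detrended and Hann-tapered by default, normalised so that the one-sided
power sums to the windowed signal's energy (Parseval; verified to
machine precision in the tests). `band_power()` integrates the 2.5–20 Hz
and 40–100 Hz bands used to characterise epileptiform enrichment.

`detect_spikes()` is a declared operationalization — the assay
literature reports events without defining a detector. It thresholds
$|x|$ at $k$ times a robust SD (1.4826 × MAD of the whole trace; if the
MAD is zero, as on a near-silent baseline carrying a few large events,
the plain SD is used before declaring the trace flat), merges crossings
within 100 ms, and reports onset, peak, amplitude in robust-SD units and
polarity. $k = 5$ by default; sensitivity is monotone non-increasing in
$k$. Events are locked to light stimuli by `stimulus_locked_responses()`:
an event belongs to the most recent stimulus if it follows it within
0.5 s ("directly after", made precise and configurable), and the
response fraction is the share of stimuli with at least one locked
event.

The LFP simulator injects a biphasic template — one positive then one
negative half-sine lobe, 30 ms each — on white or 1/f noise, with
Poisson spontaneous events, optional 50 Hz hum, and stimulus-locked
events placed within the response window at a set probability. The
noise statistics of real baselines are not published for this assay;
white noise at unit SD is a placeholder default, exposed in
`lfp_sim_spec()`.

## Locomotor analysis

Tracks are 90 min in 10-min bins by default; `trim_habituation()` drops
the first 30 min, leaving 6 bins. `activity_total()` sums per-bin
distance. `count_bursts()` counts contiguous runs of the
maximum-velocity series strictly above 50 mm/s, so one movement spanning
several samples counts once; it uses the fine-grained (1 s) velocity
series when the track carries one and the per-bin maxima otherwise. Two
caveats are worth stating: run-counting is monotone in the cutoff only
for excursions separated by sub-threshold samples (raising the cutoff
can split a long run in two), and burst recovery at the simulator's
Poisson rates requires the fine-grained series — at 10-min resolution
multiple bursts collide into one bin.

`mann_whitney_u()` computes U from midrank sums. For groups of up to 12
(the assay's cohort size) the two-sided p-value is **exact**: the full
permutation distribution of the rank sum over all $\binom{n_1+n_2}{n_1}$
labelings is obtained by a subset-sum dynamic programme over the doubled
(hence integer) midranks, which is valid under ties because the rank sum
depends only on which pooled positions are labelled. Two-sided p doubles
the smaller tail, capped at 1; significance is $p \le 0.01$, the
complement of the assay's "p > 0.01 is not significant" convention.
Larger groups use the normal approximation with tie and continuity
corrections; the suite checks exact and approximate p agree within 0.02
at $n_1 = n_2 = 12$ and that the exact p matches `stats::wilcox.test`'s
independent exact algorithm on tie-free data.

The cohort simulator draws per-bin distances from a zero-truncated
Gaussian (mean 1200 mm per 10-min bin, SD 300, clipped at zero — the
simplest positive activity model), multiplies group B's mean by
`group_effect`, and injects Poisson-distributed velocity excursions
above the cut-off at per-second resolution. A `group_effect` of 1 with
zero burst rates is the null; the mutant-like condition used in the
pipeline default is `group_effect = 2` with 20 bursts per recording.

## Problem sizes and numerical choices

The shipped tests and the acceptance analysis use: 200 random pairs for
the alignment oracle; 100 simulated families (four 160-residue domains,
rate contrast 0.45 vs ≤ 0.08 over a 0.05 background) for flag recovery;
50 paired 40-s traces for band enrichment; 200 seeds for the 0.6
response-probability mean; 500 null cohorts for type-I control; and
single fixed-seed cohorts for the qualitative phenotype contrast. These
sizes give sampling errors comfortably inside the stated tolerances
(e.g. 3 SE bands for binomial and Poisson means) while keeping the whole
analysis in the minutes range on one core. All randomness flows from
per-call integer seeds; the same spec and seed reproduce every artifact
byte-identically.

Degenerate inputs are handled explicitly rather than silently: empty
sequences, non-alphabet residues (reported with symbol and position),
overlapping or out-of-bounds domain spans (reported by label),
undefined identity (`NA`, never 0), flat traces (empty event list plus a
warning), trims that empty a track, and zero-length groups all raise
informative errors.

## Known limitations

* The published 67%/77% protein-wide identities and the 12-of-58
  flagged domains were obtained from specific Ensembl transcript
  translations and the UniProt feature set current at the time; both are
  version-sensitive, and the package treats reproducing them from real
  downloads as an external benchmark (see the README) rather than a unit
  test. The synthetic channel family encodes the same expected pattern
  with known truth.
* Pairwise reference-anchored alignment is the default; a three-sequence
  progressive mode is out of scope. Published identity scores were
  reported as robust to the aligner choice, but pairwise and MSA-derived
  identities are not guaranteed identical.
* No local alignment, no NMD or splice-site modelling, no seizure-stage
  classification, no channel biophysics: the scope is the
  sequence-to-statistics pipeline described above.
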