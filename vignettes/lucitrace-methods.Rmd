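---
title: "Methods: transgene insertion-site mapping and reporter calibration"
author: "lucitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transgene insertion-site mapping and reporter calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

Luciferase reporter cell lines are produced by lentiviral integration of a
promoter--luciferase cassette into a cancer cell genome. Two questions
about such a line are answerable from paired-end whole-genome sequencing:
*where* the cassette integrated (insertion sites), and *how many* cassette
copies a cell carries (per-genome abundance). Two more are answerable from
plate assays: whether bioluminescence is proportional to cell number
(calibration), and whether that proportionality survives a change of
culture condition such as stromal co-culture (stability). `lucitrace`
implements all four read-outs plus in-silico PCR validation of the
construct, and — because the corresponding raw study data are not publicly
deposited — a synthetic-data module that generates sequencing and plate
data with known ground truth, so every estimator is validated by parameter
recovery.

# Insertion-site detection

## Evidence model

A sequenced fragment that straddles an integration junction produces one of
two evidence classes against the dual reference (host genome + cassette):

* **Split (chimeric) reads** — a single read whose prefix aligns to one
  reference and suffix to the other. The *overhang* is the aligned length
  on each side. Junctions are retained only when both overhangs are at
  least `min_overhang_bp` (default 20); this is the primary retention rule
  and is deliberately the only read-level filter.
* **Discordant pairs** — one mate fully on the host, the other fully on
  the cassette. The pair does not cover the junction but implies a host
  interval that must contain it: from the host mate's inner edge,
  extending `insert_mean + 3·insert_sd − read_length` toward its mate.

## Alignment

Reads are aligned by exact k-mer seeding (k = 15, every read position
sampled) followed by ungapped extension under a per-segment substitution
budget (default 2); terminal mismatches are trimmed so segments always end
on matching bases. Ungapped extension is sufficient because the read
simulator emits substitutions only, and the retention rule is defined
purely by overhang length. Ties among equal-scoring placements break
deterministically (host contigs before cassette, then lowest coordinate,
then plus strand). Reads with more than `max_candidates_per_side` (4)
end-anchored placements are dropped as ambiguous — rare on non-repetitive
sequence, and a guard against repeat-driven false junctions. A full-length
single-reference placement suppresses split reporting for that read. The
inner loops are compiled (Rcpp), as is usual for sequence-level packages.

## Breakpoint resolution and microhomology

When the host and cassette share sequence at the junction
(*microhomology*), the cut point is ambiguous within that shared run, and
the mismatch budget can additionally drag an extension a few chance-matching
bases past the true junction. Both effects are handled in one step: within
the overlap zone of the two partner segments, every cut point is re-scored
base-by-base against the two references; the best-scoring cut is widened
to its *equivalence run* (adjacent cuts are interchangeable exactly when
host and cassette claim the same base, which is the definition of
microhomology) and reported at the **leftmost** compatible host
coordinate, with `microhomology_bp` equal to the run length. A fixed
convention is required for clustering; leftmost is used throughout.

Up to 2 bp of unaligned sequence between the partner segments is tolerated
(untemplated insertion at the junction) and flagged.

## Clustering and corroboration

One biological insertion produces two junction classes — the cassette's
head and its tail — which, for a clean insertion, share one host
coordinate in clean-genome space. Because of the leftmost convention, a
tail junction with microhomology *h* is reported *h* bases left of the
insertion point, so its site-level estimate is corrected to
`host_bp + microhomology` while head junctions contribute `host_bp`
directly. Estimates are clustered by single linkage within
`cluster_window_bp` (default 10) per contig; single linkage makes the site
count provably non-increasing in the window. The site position is the
median member estimate (lower of the two middles for even counts).

Discordant pairs corroborate the nearest site inside their implied
interval (padded by the cluster window on both ends, since budgeted
extension can overshoot a mate's edge by a few bases). Pairs that fit no
site may found discordant-only sites when at least `min_disc_support` of
them overlap. Sites below both support thresholds (defaults 2 and 2) are
dropped; thresholds of 2 suppress singleton error chimeras while costing
essentially nothing at 20--30× coverage, where a true junction typically
collects 15--25 split reads. A site is *corroborated* when both evidence
classes are present. Counts reported here are clustered insertion events,
not junction ends — one event contributes its head and tail junctions to
a single site.

# Per-genome abundance

Mean depth is aligned bases divided by reference length, with split reads
contributing their segment lengths to each side. The estimator is made
explicit so the aneuploidy standardization is testable:

* `raw_depth_ratio = mean_transgene_depth / mean_host_depth`
* `copies_per_cell = raw_depth_ratio × n_chrom / 23` — host mean depth is
  taken to represent the line's average chromosomal copy number relative
  to a haploid set;
* `copies_per_standard_genome = copies_per_cell × 46 / n_chrom` — the
  46-chromosome re-expression used for cross-line comparison.

Ratios between samples of the same line are therefore independent of the
karyotype constant, which the tests assert. The packaged karyotype table
carries C4-2B = 83, PC3 = 62, MDA-MB-231 = 67 (midpoint of the reported
65--69 range, CLI-overridable) and standard = 46.

# Reporter statistics

*Calibration* is ordinary least squares of RLU on seeded cell number with
an intercept (the regression form is not otherwise constrained, and the
slope is the comparison statistic either way); `slope_sd` is the standard
error of the slope. *Stability* compares a mono-culture and a co-culture
arm at a matched time point and cell number: fold changes are ratios of
arm means, the DNA-normalized fold divides the RLU fold by the DNA fold
(removing any genuine cell-number difference), and significance is a Welch
unequal-variance t-test on per-replicate `log(RLU/DNA)` — a single robust
two-arm test in place of a mix of t-tests and ANOVA; factorial ANOVA is
out of scope. The verdict is *unstable* only when the normalized fold is
outside `[1/threshold, threshold]` **and** p < alpha. The default
threshold of 2 sits between the ~1.2-fold drifts a stable reporter shows
and the ≥4-fold jumps of an unstable one; both threshold and alpha are
tunable. Relative expression uses the standard delta-delta-Ct form,
`2^(−ΔΔCt)`, against a housekeeping gene, with Ct accepted on (0, 45).
Because published designs normalize sometimes to the lowest seeding
density and sometimes to time zero, the reference condition is an explicit
argument (the caller chooses the control arm), not a fixed rule.

# In-silico PCR

Primer binding allows `max_mismatch` substitutions (default 0) but
requires the 3'-terminal `three_prime_exact` bases (default 3) to match
exactly, reflecting extension chemistry; N never matches. Amplicons are
enumerated for facing hits in either written orientation of the pair
within `max_len` (default 5,000 bp), so predictions are invariant under
reverse-complementing the template. No melting-temperature model is
computed; annealing temperatures and concentrations in the packaged
primer tables are metadata. The packaged template
(`extdata/transgene_synthetic.fa`) is a **synthetic** stand-in cassette:
random sequence carrying the published primer annealing sites at offsets
that reproduce the published amplicon sizes (198 bp and 102 bp for the
luciferase pairs, 124 bp for the promoter pair, 600 bp for the
promoter-forward → luciferase-reverse spanning product). Any user FASTA
can be substituted; predictions for the two luciferase pairs on the real
GenBank record will match the packaged sizes by construction of the
primer design, but positions are meaningful only on the real record.

# The simulators: what they emulate, and what they do not

`make_genome_with_insertions` draws host contigs i.i.d. uniform over ACGT
and splices the cassette (reverse-complemented for "−" events, copies
concatenated head-to-tail) at the planned 0-based positions. Insertions
are *clean*: no target-site duplication and no deletion at the locus,
since no integration microstructure is being modeled. Uniform sequence
contains no repeat families, so junction mapping is essentially
unambiguous — recovery results on this background demonstrate estimator
correctness, not robustness to segmental duplications, satellite repeats
or pseudogenes, which real genomes have and which would populate the
ambiguity guard.

`simulate_reads` draws `floor(coverage × genome_len / (2 × read_length))`
fragments uniformly with Gaussian insert sizes (resampled into
`[read_length, mean + 6 sd]`; defaults 350 ± 50, conventional for a
short-insert library), reports mate 2 as the reverse complement of the
fragment end, and applies i.i.d. substitution errors. No indels, PCR
duplicates, GC bias or quality model are simulated — the caller ignores
qualities (written as constant high) and tolerates substitutions by
budget.

`simulate_plate` writes mono-culture RLU as `slope × cells × noise` and
multiplies the co-culture arm by `cocult_fold`, while DNA tracks seeded
cells in *both* arms — the defining artefact structure in which signal
rises without a cell-number change. Noise is mean-one log-normal with the
given CV on each well independently; the defaults (titration 500--50,000
cells/well, 4 replicates, CV 10%) mirror a routine reporter titration.

All three simulators are deterministic given their seed, to the byte for
FASTQ output.

# Numerical and design choices

* All internal coordinates are 0-based half-open; BED is emitted natively
  and human-readable reports convert to 1-based. One convention end to
  end avoids off-by-one drift.
* Single linkage for clustering (monotone in the window); median-lower
  for positions (integer, deterministic).
* Degenerate inputs raise typed errors rather than returning NA: zero
  host depth, unknown karyotype, nonpositive denominator slopes, Ct
  outside (0, 45), fewer than 3 distinct calibration points.
* Problem sizes in the tests and the acceptance script are chosen to keep
  a full run in minutes on one core: recovery at 1 Mb/30× and 5 Mb/20×
  for the site caller (where both planted regimes — 4 and 84 insertions —
  are recovered exactly), 1 Mb pairs for the abundance ratio, and
  single-plate recovery for the stability statistics. Properties that are
  cheap (clustering, PCR, calibration) are exercised over many random
  cases per run.

# Known limitations

* The aligner is ungapped and substitution-only; reads containing indels
  near a junction would lose their split signal.
* Depth near junctions is slightly over-counted (partner segments may
  overlap by the microhomology) and under-counted at cassette overhangs
  shorter than the seed; both effects are per-junction and largely cancel
  in abundance *ratios*, where a residual bias of a few percent remains.
* Tandem multi-copy insertions are reported as one site (flagged via
  copy-aware truth in simulation); internal cassette-cassette junctions
  are not used as evidence.
* The stability test assumes matched seeding and a single time point per
  call; time-course modeling is left to the caller.
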