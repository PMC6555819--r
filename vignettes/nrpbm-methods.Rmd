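---
title: "SNV-PBM analysis of nuclear receptor heterodimers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNV-PBM analysis of nuclear receptor heterodimers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpbm)
```

# The measurement and the model

Nuclear receptors (NRs) that heterodimerize with RXR bind DNA direct repeats
(DRs): two 6-bp half-sites with consensus RGKTCA separated by a 0-5 bp spacer
(DR0-DR5). A single-nucleotide-variant (SNV) protein-binding microarray (PBM)
measures how every possible single-base substitution in and around a starting
("seed") direct repeat perturbs dimer binding. `nrpbm` implements the complete
analysis stack for such experiments:

1. **Probe design.** Each seed contributes its flanked context (5-bp flank +
   half-site + spacer + half-site + 5-bp flank, i.e. `22 + S` bp for spacer
   length `S`) and all `3 * (22 + S)` SNVs, centred in a 34-nt variable region
   next to a constant 24-nt primer region. Unique SNV sequences are printed as
   5 replicates per orientation (10 probes), everything else as 4 (8 probes);
   orientation o2 is the reverse complement of the o1 variable region. The
   default design -- 24 seeds at each spacer length 0-5 -- yields 10,728
   unique seed+SNV sequences (69 SNVs per DR1 seed). 500 random genomic
   34-mers (no Ns, no single-base run longer than 3) serve as the background
   set.
2. **Normalization.** Per unique sequence, replicate intensities from one
   orientation (o1 by default; NR dimers show an orientation bias on real
   arrays) are log-transformed and averaged, then standardized against the
   background probes: `z = (x - mu_bg) / sd_bg`. Background sequences thus
   have mean 0 / sd 1 by construction and z-scores are invariant to global
   rescaling, which is why a simple median-scaling stand-in suffices for
   between-array normalization.
3. **Energy matrices and motifs.** At every context position the four base
   variants are the seed plus its three SNVs; the delta-z entry is each
   variant's z minus the median of the four (so column medians are zero).
   Frequencies follow by a Boltzmann/softmax transform
   `f_i = exp(beta * z_i) / sum_k exp(beta * z_k)` with
   `beta = 15 / max z` over the seed and its SNVs. Log-odds PWMs use the
   pseudocount formalism `p_ij = (f_ij + s*b_i) / (sum_i f_ij + s)`,
   `S_ij = log2(p_ij / b_i)` with `s = 0.001` and background
   A 0.24, C 0.26, G 0.26, T 0.24 for genomic work (uniform elsewhere).
   PFMs are averaged element-wise and column-renormalized; half-site PFMs
   share the flank+half-site frame and so average across spacer lengths.
4. **Binding modes.** Seeds with maximum seed+SNV z below 3.0 are unbound
   ("none"). For bound seeds, each half-site's perturbation is the summed
   per-position delta-z range over its six positions; a half is *engaged*
   when its perturbation is at least `engage_abs` (default 2 z-units) and at
   least `engage_frac` (default 0.25) of the two halves' total. Both engaged
   = full-site mode, exactly one = 5'/3' half-site mode. The spacer-preference
   landscape collects, per spacer length, every bound seed's max SNV z and
   mode; mode-transition tables count seeds moving between modes across
   conditions (e.g. wild type versus a DNA-binding-domain mutant).
5. **Genomic enrichment.** True positives are reproducible bound regions (50%
   reciprocal overlap, boundary inclusive); negatives are size-matched random
   draws from accessible chromatin with all bound regions subtracted. Regions
   are scored by the maximum PWM window score over both strands (N scores 0);
   discrimination is AUC = U/(n_pos*n_neg) from the Wilcoxon rank-sum test
   with continuity correction, Bonferroni-corrected across models. The
   "active peak" filter keeps peaks in the strand-aware window upstream of
   differentially expressed genes' TSSs (plus strand `[t-w, t)`, minus strand
   `[p, p+w)`, default w = 10 kb).
6. **Affinity validation.** Competition-EMSA percent inhibition is
   `100 * (F0 - Fc) / F0`. Relative Kd comes from least-squares fitting of
   the exact ternary mass-action model -- free protein solved numerically
   from `Rt = Rf * (1 + Pt/(Kp+Rf) + Ct/(Kc+Rf))` -- rather than an IC50
   approximation, and is normalized so the highest-affinity sequence is 1.0.

# The synthetic generator

Because the pipeline must be testable without array downloads, the
`synthetic_pbm` layer generates fluorescence with the statistical structure
the analysis assumes. Occupancy of a probe is a Boltzmann-weighted sum over
all windows on both strands under up to three additive energy matrices --
full site (12+S positions) and 5'/3' half-site (5-bp flank + half-site, 11
positions) -- with nonnegative mode weights plus a constant nonspecific
baseline; it is symmetric under reverse complement by construction.
Fluorescence is occupancy times a constant gain, an o2 orientation-bias
factor, and multiplicative lognormal noise (intensities are positive and
right-skewed). `mode_truth()` builds matched seed/model pairs per mode: the
planted PFM puts frequency 0.85 on the consensus base at informative
positions, energies are `-log f` shifted so the consensus window scores zero,
and the planted mode weight is 500 against baseline 1. For half-site modes the
non-engaged half is fixed at CTCGAG (its own reverse complement, maximally
distant from AGGTCA) so the planted mode is identifiable; this matters because
occupancy sums over windows, and a seed whose other half also matches the
half-site model would genuinely be perturbed in both halves.

What the generator does *not* emulate: spatial array artifacts, scanner
saturation, sequence-composition biases of real genomic background probes,
ligand and cofactor effects, and cooperative or multi-dimer binding. Passing
recovery tests therefore demonstrates the inference is correct under the
model's own assumptions, not that real arrays are free of those artifacts.

A note on background probes: under a half-site-only truth model roughly 1-2%
of random background 34-mers contain a near-consensus half-site and light up.
This fattens the background tail and compresses z-scores (bound seeds sit
near z 4 rather than z 100 as under a full-site model) -- an emergent,
realistic property we kept, since random genomic sequence on real arrays
contains half-sites too.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `z_threshold` | 3.0 | z-units | affinity cutoff for bound seeds; functional sites validate down to z 1.5, so 3.0 is deliberately stringent |
| `beta_numerator` | 15 | -- | softmax sharpness, `beta = 15 / max z` per seed |
| `s` (pseudocount) | 0.001 | -- | keeps log-odds finite for zero frequencies |
| background `b` | 0.24/0.26/0.26/0.24 | freq | accessible-chromatin base composition (A/C/G/T); uniform elsewhere |
| `engage_frac` | 0.25 | -- | relative share of total perturbation a half must carry |
| `engage_abs` | 2.0 | z-units | absolute perturbation floor per half-site |
| `frac` (reciprocal overlap) | 0.5 | -- | reproducibility rule for bound regions, boundary inclusive |
| `window` | 10000 | bp | upstream window for the active-peak filter (50 kb and up-and-down variants supported) |
| `lognormal_sigma` | 0.1 | log units | replicate noise; matched by the parameter-recovery tests |

# Design choices where the design was open

- **z-scores on log intensities.** The intensity scale of the z transform is
  not fixed by the measurement itself; log stabilizes multiplicative noise
  and makes z invariant to global rescaling. A `scale = "linear"` switch is
  provided.
- **The z-to-frequency transform.** Only `beta = 15 / max z` is fixed
  externally; the softmax (Boltzmann) form is this package's choice, natural
  because delta-z behaves as a binding free-energy perturbation. Negative z
  enter as-is; no flooring.
- **`max z` per seed** is taken over the seed *and* its SNVs (the best SNV
  can outscore the seed).
- **Engagement rule.** No published criterion exists for clustering per-seed
  PFMs into full/half modes, so the range-based rule above is our
  operationalization; both knobs are config, and exact ties resolve to full
  (conservative toward the canonical model). Flanks inform logos but not mode
  calls. Published mutant mode-transition counts cannot be reproduced without
  the original raw data and criterion; the transition layer is validated
  qualitatively against simulations instead.
- **Half-site ablations are SNVs.** Ablating the top-contribution position of
  a half-site produces a sequence at Hamming distance 1 from the seed, i.e.
  always one of the seed's own SNV probes. To preserve the 10-vs-8 replicate
  multiplicity invariant the library records ablations as an annotation table
  pointing at the corresponding SNV sequence instead of duplicating probes.
- **Region score aggregation** is the max window score over both strands
  (occupancy-style ROC practice); `aggregate = "sum"` is available.
- **Between-array normalization** is median scaling, labelled as a simplified
  stand-in; the full regression-based normalization of the original array
  software is out of scope, and z-scoring absorbs global scale anyway.
- **Competition model.** The exact ternary mass-action equilibrium is solved
  by safeguarded bisection per competitor concentration (60 iterations,
  precision ~Rt/2^60); the fit optimizes log10(Kd) on [-12, -2]. The 95% CI
  is normal-theory on log(Kd) with the SE from 200 residual-resampling
  bootstrap refits -- on 9-point titrations this calibrates noticeably better
  than percentile intervals (about 0.90 observed coverage versus about 0.80
  in our coverage simulations at 5% multiplicative noise).
- **Seed generation.** The original 24 seeds per spacer are not published;
  `generate_seeds()` draws half-sites from RGKTCA with 0-2 substitutions,
  random spacers/flanks, and enforces pairwise context Hamming distance >= 3
  within a spacer stratum, which guarantees disjoint SNV neighbourhoods.
  User-supplied seed lists are accepted and checked the same way.
- **Coordinates** are 0-based half-open (BED convention) everywhere,
  including TSS positions; conversions to 1-based GenomicRanges happen only
  internally.

# Numerical notes and degenerate inputs

Softmax columns are max-shifted before exponentiation; PFM columns sum to 1
within 1e-9 and PWM round-trips (`2^S * b`) recover the pseudocounted
probabilities within 1e-12. `beta_param()` refuses non-positive maxima (beta
is undefined for unbound seeds; per-seed PFMs are only built for seeds above
the z threshold). Missing SNVs fail loudly with the absent variants listed;
missing replicates only warn and average what is available. Flat EMSA
titrations ("no transition observed"), fits pinned at the Kd search boundary,
empty score vectors, and interval sets with `start >= end` are all rejected
with specific errors.

# Problem sizes used in tests

Unit tests run the full enumeration design (24 seeds x DR0-DR5; counts are
exact and fast) and reduced simulations (4-10 seeds, 40-60 background
probes). The end-to-end recovery checks use the study-scale conditions per
scenario -- 24 seeds, 500 background probes, sigma 0.1, 5 replicates per
orientation -- and the enrichment benchmarks use 250-300 regions per class at
200 bp. These sizes give stable statistics (recovery fractions within a few
percent across seeds) while keeping the whole suite around a minute.

# Known limitations

- The engagement rule and the softmax transform are declared interpretations;
  alternative operationalizations plug in via config but are not swept.
- The synthetic benchmark's planted motifs are sampled from the PFM itself,
  so enrichment AUCs reflect in-model discrimination (about 0.88-0.92 at
  planted fraction 0.9), not performance on real ChIP data.
- Orientation bias is modelled as a single multiplicative factor; real arrays
  show sequence-dependent orientation effects.
- The EMSA layer fits one competitor at a time; global multi-curve fits and
  direct-titration models beyond one-site binding are out of scope.
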