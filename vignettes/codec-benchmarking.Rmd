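---
title: "Benchmarking DNA data-storage codecs: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking DNA data-storage codecs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oligobench)
```

This vignette is the package's own account of the science it
implements: the channel models and their assumptions, the reference
codecs, the threshold-estimation machinery, the parameters that matter
(with units and defaults), the numerical conventions, and the known
limitations. Nothing stated here as an empirical number goes beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## 1. The storage channel

### Basic iid scenario

The simplest benchmark treats every template position independently:
with probability `r` (errors nt⁻¹) an error occurs, and its type is
drawn from a fixed composition, by default 53% substitutions, 45%
deletions, 2% insertions — a mix resembling error patterns observed in
Illumina-sequenced oligo pools. Substitutions pick one of the three
other bases uniformly; insertions place one uniform base before the
position; deletions skip it. Sequence dropout is modelled separately:
a fraction `d` of references is removed (uniformly, without
replacement, `round((1-d)·N)` survivors with half-up rounding) *before*
copy generation, and each survivor then yields exactly `copies` reads
(default 30). Supported sweep ranges are `r ∈ [0.001, 0.40]` and
`d ∈ [0.005, 0.99]`.

This channel is deliberately idealized: no positional error profile,
no error runs, no coverage bias. It isolates codec behaviour from
workflow effects.

### Workflow scenario

`run_workflow()` approximates a full storage workflow with five
stages:

1. **Synthesis.** Each reference receives a log-normal relative
   abundance weight (`sigma_log`), is lost entirely with probability
   `p_fail`, and each physical molecule carries an iid error pattern
   from the synthesis error rates.
2. **PCR 1** (default 15 cycles, efficiency `eta = 0.95`): molecules
   amplify as a Galton–Watson process; new strands acquire
   substitutions at `e_pol` nt⁻¹ cycle⁻¹.
3. **Dilution** to a mean of `redundancy` (R) copies per reference:
   multinomial sampling of molecules; references drawn zero times drop
   out. With `sigma_log = 0` and `p_fail = 0` the zero class follows
   `e^{-R}` (tested).
4. **PCR 2** (default 25 cycles), as stage 2.
5. **Sequencing:** `depth · N` reads sampled multinomially from the
   final abundances, truncated to `read_length` (default 150 nt).

Numerically, amplification acts on aggregated abundances rather than
individual molecules: each post-dilution founder molecule receives a
Gamma(a, a) relative weight with `a = (1+eta)/(1-eta)`, the variance of
the normalized Galton–Watson limit, and founder molecules that receive
no sequencing read are never materialized. Substitutions accumulated
before dilution are shared by all reads of a founder; post-dilution
substitutions are drawn per read. This keeps runs at desk scale
(seconds for N = 100–200) while preserving the first two moments of
the copy-number process and the read-level error statistics.

Two presets are calibrated against reported end-to-end behaviour of
material-deposition and electrochemical workflows:

| preset | synthesis (sub/del/ins, nt⁻¹) | `sigma_log` | `p_fail` | `e_pol` | end-to-end target |
|---|---|---|---|---|---|
| `high_fidelity` | 5·10⁻⁴ / 4·10⁻⁴ / 1·10⁻⁴ | 0.30 | 0.001 | 10⁻⁶ | ≈0.1% nt⁻¹, dropout <1% |
| `low_fidelity`  | 9·10⁻³ / 4.4·10⁻³ / 1.0·10⁻³ | 0.85 | 0.03 | 3·10⁻⁵ | ≈1.5% nt⁻¹, dropout >2% |

The low-fidelity deletion and insertion rates follow reported amended
synthesis error rates for electrochemical pools; the substitution rate
is a calibration choice (reported values cover only the del/ins
amendments), flagged as such. `p_fail` — complete synthesis failure of
a sequence — is this package's design choice: log-normal abundance
dispersion alone cannot produce the >2% sequence loss observed for
electrochemical synthesis at high redundancy, because the zero class
of a log-normal-mixed Poisson at R = 1000 is negligible. All preset
fields are overridable.

The calibration invariants (error rate within [0.0005, 0.002] /
[0.010, 0.020] nt⁻¹; dropout <1% / >2% at R = 1000) are enforced by
the test suite via `analyze_error_rates()`, which recovers rates by
unit-cost alignment against the known origins.

## 2. Clustering and consensus

Decoders receive *consensus sequences*, padded or trimmed to the
design length L (several codec designs require fixed-length input; the
pad base is a fixed `A`, applied after consensus).

* `naive_cluster()` collapses reads to their distinct sequences,
  ordered by descending multiplicity (ties lexicographic). No
  alignment. This matches the common practice of feeding raw reads to
  a decoder.
* `lsh_cluster()` is a greedy single-pass MinHash clusterer: each
  read's signature (`h = 64` hash functions over its k-mer set) is
  compared against existing cluster representatives (the founding,
  heaviest read); the read joins the first cluster whose estimated
  Jaccard similarity reaches `tau`, else founds a new cluster.
  Deterministic given seed and input order (descending abundance).

**Why k = 6 and tau = 0.20.** An error at one position destroys up to
k template k-mers *and* creates up to k novel ones, so two reads at
per-nt error rate `r` share Jaccard similarity roughly
`q²/(2−q²)` with `q = (1−r)^k`. At `k = 12` this is ≈0.45 already at
`r = 0.02`, so a τ of 0.5 fragments clusters at error rates the
pipeline must handle. With `k = 6`, `J ≈ 0.62` at `r = 0.04` and
random cross-origin 150-mers still share essentially no 6-mers
(expected ≈5 of 4096, J ≈ 0.02, ten estimator standard deviations
below τ = 0.20). The test suite verifies both sides: cluster counts in
`[N, 1.2N]` with zero origin-mixing at `r = 0.02`, and perfect
specificity on error-free reads.

`call_consensus()` aligns members to the cluster's heaviest read with
an exact unit-cost edit-distance alignment (`utils::adist` transcript)
and takes an abundance-weighted plurality vote per column, including
insertion slots; gap-majority columns are deleted. Ties break by the
fixed base order A<C<G<T, and non-gap beats gap on a tie. A banded
alignment was considered and rejected: at L = 150 the exact DP is
C-fast and strictly more accurate, so no band parameter is exposed.

`evaluate_clustering()` implements the standard metrics: each
consensus is assigned to its nearest reference by Levenshtein distance
(ties → lowest reference index); **sensitivity** = fraction of
references with ≥1 assigned consensus; **specificity** = the same
numerator over the total consensus count; **accuracy** = mean over
references of the Levenshtein similarity `1 − d/max(|a|,|b|)` of each
reference's closest consensus. Two conventions are this package's
decisions and are recorded here because the printed definitions leave
them open: similarity is normalized by the longer sequence, and
accuracy averages over *all* references (an uncovered reference
contributes the similarity of whatever consensus is closest to it, not
zero-by-fiat, and 0 only for an empty consensus set).

## 3. Reference codecs

All codecs map bytes to DNA at 2 bit/nt (A=00, C=01, G=10, T=11, most
significant bits first) without GC or homopolymer constraints —
constraint coding is out of scope here. Every encoder records the
payload size and CRC-32 in its metadata; `codec_decode()` centrally
refuses to report success unless the recovered payload matches
byte-for-byte, so *no decoder can ever return a wrong success* (tested
with an adversarial decoder stub and corrupted end-to-end runs).

* **Baseline** — index prefix + payload chunk, no ECC. Tolerance comes
  entirely from clustering; one missing index or one surviving byte
  error fails the run.
* **Reed–Solomon inner/outer** (`rs_codec()`) — per sequence:
  `index | body | inner parity` over GF(256) (primitive polynomial
  0x11D); outer RS across the `outer_n` sequences of a block, applied
  per byte position, with `outer_k` data sequences. Inner decoding
  corrects up to `inner_parity/2` symbol errors, otherwise the
  sequence becomes an outer erasure; outer decoding is
  errors-and-erasures (`2e + f ≤ N−K`, Berlekamp–Massey on Forney
  syndromes, Chien search, Forney magnitudes, with a final syndrome
  re-check). Pools larger than one block are split round-robin by
  global index so clustered dropout spreads across blocks. The
  erasure bound `(N−K)/N` is verified exhaustively on a (7,4) instance
  and the inner radius on a (15,11) instance.
* **Fountain** (`fountain_codec()`) — LT droplets: 2-byte droplet
  seed, XOR of a degree-`d` segment subset (robust soliton,
  `c = 0.03`, `delta = 0.05`, expanded deterministically from the
  stored seed by a self-contained LCG), and a small RS parity used for
  *detection only* — a droplet failing verification is discarded,
  never corrected. Decoding peels degree-1 droplets and falls back to
  Gaussian elimination over GF(2) on the residual system (inactivation
  decoding); GE strictly enlarges the decodable set and makes
  moderate-overhead decoding (K = 100, ε = 0.10) reliable.
* **External adapter** (`external_codec_adapter()`) — wraps
  encode/decode shell commands exchanging binary payloads and FASTA;
  nonzero exit, missing output, or exceeding the time limit is a
  decode failure, mirroring the rule that any constraint violation
  counts as unsuccessful decoding.

Preset parameter sets targeting 0.50 / 1.00 / 1.50 bit nt⁻¹ at
L = 150 ship in `inst/extdata/codec_presets.yaml`; achieved rates are
within 5% of target (tested). The inner/outer split at each rate is a
free design choice, recorded in the preset file: lower rates spend
more on both inner parity and outer erasure capacity
(e.g. rate 0.50: inner parity 10, outer (100, 36) → erasure bound
64%; rate 1.50: inner parity 4, outer (100, 87) → 13%).

## 4. Threshold estimation and Pareto fronts

A *trial* is one full encode → channel → cluster → decode run at a
parameter value `x`, under per-stage wall-clock limits (benchmark
scale: 3600 s and 8 GiB per stage, one core; test scale: 60 s /
1 GiB). Stage timeouts and component crashes become failed trials,
never exceptions. In-process memory limits are advisory; they are
enforced for subprocess adapters.

`adaptive_scan()` spends exactly 30 trials: 10 log-spaced points over
the full range, then twice 10 more over `[t/2, 2t]` around the current
estimate (clipped to the range; if the interim fit is censored, the
refinement window is the hardest decade of the range). The final
logistic regression of success on `log x` reports the parameter value
at 95% success probability. Directions are explicit: error rate and
dropout are harder-is-larger; redundancy and depth are
harder-is-smaller.

**Separation.** When every success is strictly easier than every
failure the ML fit diverges. The fallback reports the 0.95-quantile of
the log-linear interpolant across the success/failure gap,
`t = s^0.95 · f^0.05`. The gap *midpoint* was considered and rejected:
it is the 50% point, and on a deterministic feasibility boundary it
overshoots the truth half the time — enough to push Pareto points
beyond an analytic boundary. The chosen quantile stays strictly inside
the gap, respects that a 95%-success threshold should hug the last
observed success, and keeps deterministic-boundary estimates
conservative. For noisy trial functions, runs that happen to end
completely separated carry genuinely limited information and their
estimates inherit the last lucky success; this inflates the upper tail
of the estimator (quantified by the estimator-recovery tests, which
bound the median error at 15%).

`pareto_scan()` runs ten 1-D scans per axis (the other axis fixed at
ten log-spaced values) and filters the threshold pairs to the
Pareto-efficient set under the declared directions; the filter is
tested against brute-force pairwise dominance.

`literature_protocol()` replicates serial dilution (10× per
iteration), serial amplification (extra PCR cycles per iteration) and
read down-sampling (decreasing depth grid), reporting the highest
iteration at which all `n_rep = 10` seeded repetitions decode.

## 5. Density arithmetic

`storage_density(rho, R, mw)` returns
`ρ·N_A / (R·M·8·10¹⁸)` EB g⁻¹ — decimal exabytes; the decimal
convention is what makes 2 bit/nt at R = 1 and M = 662 g mol⁻¹ bp⁻¹
round to 227 EB g⁻¹, the theoretical dsDNA maximum. The
`with_adapters` basis multiplies by the payload fraction of the total
sequence length (e.g. 126 of 170 nt when truncated adapters and a
suffix are attached). `redundancy_mass()` converts a DNA mass to
copies per sequence; note that published mass-to-redundancy
conversions do not always use M = 662 (some imply ≈616), so M is an
explicit parameter everywhere rather than a constant.

## 6. Reproducibility conventions

One root seed governs a run; every stage derives an independent stream
as FNV-1a(seed, stage name), so stages can be re-run in isolation and
identical configurations give bit-identical outputs (tested). The
fountain droplet expansion uses its own 32-bit LCG keyed by the
droplet seed, so decoding needs no shared RNG state. FASTQ qualities
are a constant placeholder — the pipeline is quality-blind by design —
and ground-truth origins travel in the read description
(`origin=<i>`), surviving round trips. "19 kB" payloads default to
19456 bytes.

## 7. Problem sizes used in the checks

The scaled-down benchmark conditions used by the end-to-end checks are
N = 100 sequences of L = 150 nt (one outer block per preset,
payloads of 936 / 1860 / 2784 bytes at rates 0.50 / 1.00 / 1.50),
30 reads per sequence, and 30-trial scans; exhaustive codec bounds use
(7,4) and (15,11) instances. These sizes keep every check at desk
scale while leaving the qualitative structure of the full-scale
problem intact: directional findings (clustering raises error
tolerance; lower rate tolerates more dropout; the high-fidelity
workflow needs less redundancy and depth than the low-fidelity one)
are preserved, while codec-specific headline numbers that depend on
third-party implementations are out of scope.

## 8. What the simulations do and do not show

The generators emulate iid errors at a fixed composition, log-normal
coverage bias, Poisson-like dropout, PCR substitution accumulation and
multinomial sequencing sampling. They do **not** emulate positional
error profiles, error bursts, quality scores, paired-end read
structure and merging artefacts, aging/decay lesions, nanopore error
models, or chimera formation. Passing tests therefore demonstrate
correctness of the pipeline and reproduction of the modelled
statistics — not that any codec would achieve the same thresholds on
real sequencing data. Known further limitations: in-process memory
limits are advisory; the MinHash clusterer compares against a single
founding representative (no centroid update); and the workflow channel
aggregates PCR noise into a Gamma approximation rather than simulating
per-molecule pedigrees.
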