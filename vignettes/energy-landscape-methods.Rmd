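---
title: "Energy-landscape analysis of TMS-evoked EEG: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of TMS-evoked EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmslandscape)
```

## The analysis in one paragraph

`tmslandscape` implements a complete pipeline for extracting group-difference
connectivity signatures from TMS-evoked EEG. Scalp epochs centred on a TMS
pulse are cleaned (±75 µV amplitude rejection), averaged to an event-related
potential (ERP), zero-phase FIR bandpass filtered (1–50 Hz), decimated by 2
and re-referenced to the common average. The clean ERP is source-localized
with a standardized minimum-norm (sLORETA) operator, reduced to alpha-band
(8–12 Hz) power per region of interest (ROI), and split into a pre-pulse
window (samples 1–500) and a post-pulse window (501–1000). For each
functional network, each window's ROI activity is binarized against its
window mean and modelled with a pairwise maximum-entropy (Ising) model whose
energy landscape defines stable network states (local minima under
single-region flips). Subject-wise energies of the group-selected stable
states are compared between groups and conditions with t-tests under a
per-network Bonferroni gate (α/n) and a stricter relevance gate (p ≤ 5×10⁻⁵),
yielding a signature table of network states that separate patients from
controls. Because no real recordings ship with the package, a synthetic-data
module generates complete cohorts with known ground truth, so every stage is
testable end to end.

## The pairwise maximum-entropy model

A network of $M$ regions has activity patterns
$\sigma \in \{-1,+1\}^M$. The model assigns each pattern the energy

$$E(\sigma) = -\sum_i h_i \sigma_i - \sum_{i<j} J_{ij}\,\sigma_i\sigma_j,$$

and the probability $P(\sigma) = e^{-E(\sigma)} / \sum_{\sigma'}
e^{-E(\sigma')}$. This is the maximum-entropy distribution consistent with
the empirical first and second moments $\langle\sigma_i\rangle$ and
$\langle\sigma_i\sigma_j\rangle$. `fit_maxent()` maximizes the
log-likelihood by gradient ascent; because the gradient is exactly the
mismatch between empirical and model moments, and model moments are computed
by exact enumeration of all $2^M$ states, convergence (`tol_moment`, default
$10^{-4}$ on the maximum absolute mismatch) certifies moment matching. The
landscape enumeration bounds the network size at $M \le 12$; the shipped
networks have $M \in \{5, 7\}$.

Numerical choices:

* learning rate 0.1, `max_iter` $10^5$; non-convergence is an error carrying
  the diagnostics rather than a silent bad fit;
* a region constant across all samples has empirical mean exactly ±1, for
  which no finite maximizer exists; its field is clipped to ±`h_max`
  (default 20) with a warning. A constant region also forces its pairwise
  moments to ±1, so the corresponding couplings are clipped in the same way
  — otherwise they diverge — and clipped parameters are excluded from the
  convergence check;
* `ising_boltzmann()` subtracts the maximum of $-E$ before exponentiating,
  so extreme parameters cannot overflow.

Stable states are patterns whose energy is less than or equal to that of all
$M$ single-flip neighbours, ranked by energy with ties broken by pattern
code. The disconnectivity structure is computed by threshold filtration:
states are activated in order of increasing energy and merged through
single-flip edges with a union–find structure; the energy level at which two
minima's basins first join is their barrier, which equals the minimax path
energy on the hypercube (the test suite verifies this against a
Floyd–Warshall oracle).

Binarization thresholds at the mean of each region's values **within the
window** (pre and post are thresholded separately, since each window's
average is computed for its own duration), and the inequality is strict:
values equal to the threshold are inactive. Group-level landscapes are
fitted per (group, condition) on all subjects' binarized windows
concatenated — concatenation order is irrelevant because only pattern counts
matter. The selected stable states are the union of the four group-condition
landscapes' minima (all local minima by default; `k_states` truncates).
Subject-wise energies re-fit the model per subject and window and evaluate
the selected patterns; this follows the reading that individual energies
come from individual models. The alternative — evaluating the group model —
produces identical values for every subject and therefore carries no
between-subject information; it is available behind `subject_fit = FALSE`
for diagnostics only.

## The inverse problem

The forward model is $\phi = KJ + c\mathbf{1}$: scalp potentials are
determined only up to an arbitrary constant $c$. With the average-reference
centering matrix $H = I - \mathbf{1}\mathbf{1}^\top/N_E$ and $K_c = HK$, the
minimum-norm inverse is $T = K_c^\top (K_c K_c^\top + \alpha H)^{+}$
(pseudo-inverse by eigendecomposition, relative cutoff $10^{-10}$), and the
sLORETA standardization divides each voxel's 3-vector estimate by its
$3\times3$ diagonal block of the resolution matrix $R = T K_c$:
$\mathrm{power}_v(t) = \hat{j}_v(t)^\top (R_{vv})^{-1} \hat{j}_v(t)$. Because
$R$ is positive semidefinite, the generalized-Cauchy–Schwarz (Schur
complement) inequality gives the standardized estimate its signature
property: a noiseless point source attains its power maximum at the true
voxel — zero localization error — which the acceptance suite verifies
exhaustively over every voxel of the toy model. Regularization `reg_alpha`
defaults to a trace-normalized heuristic ($10^{-3}\,\mathrm{tr}(K_cK_c^\top)
/ N_E$); the inverse is noiseless in principle, but any real run needs a
ridge, and the standardization makes the power maps fairly insensitive to
its exact value.

Alpha-band power is taken *after* source localization (the pipeline-order
reading of the processing graph): each current-density component is
zero-phase FIR filtered to 8–12 Hz and the quadratic form is re-evaluated
per sample, which keeps power nonnegative by construction. Filtering the
scalp signal to alpha before inversion instead is algebraically equivalent
for the linear part and available by filtering the ERP first.

Filters are Hamming-windowed linear-phase FIRs applied with reflection
padding and centred (zero-phase) alignment; the order scales with the
transition width (≈3.3 · fs/transition taps, ≥ 40 dB stopband). The taps are
re-centred to an exactly zero DC sum so constant offsets are removed even
though the 1 Hz lower edge is far narrower than any realizable transition at
these epoch lengths. The alpha filter uses a 6 Hz transition: a filter's
impulse-response duration is inversely proportional to its transition width,
and with a 2 Hz transition the response (~1.6 s) would smear activity across
the pre/post split; at 6 Hz the response is ~0.14 s while 20 Hz still falls
in the ≥ 40 dB stopband. Decimation low-passes at 0.8× the new Nyquist
before subsampling. The 2000-sample, 2 s epoch at 1000 Hz becomes a
1000-sample, 2 s segment at 500 Hz — the count of samples halves, not the
duration — which is the only reading consistent with pre/post windows of
exactly 500 samples each.

## What the synthetic cohorts emulate

The generator is a first-class module: it defines the study conditions under
which every downstream claim is tested.

* **Cohorts.** Three stimulation sites with the study's group sizes (left
  motor 22 patients/27 controls, left prefrontal 9/18, vermis 12/25), ~60
  trials per subject (configurable; per-subject trial-count variability is a
  parameter rather than a fixed distribution), 11 channels (F3, FZ, F4, T3,
  CZ, T4, P3, PZ, P4, O1, O2), 2 s epochs at 1000 Hz centred on the pulse.
  The raw rate is chosen so decimation by 2 yields the 1000-sample epoch
  whose halves are the 1–500 / 501–1000 analysis windows.
* **Ground truth.** One base Ising model per network, shared by both groups
  and conditions, so a cohort with `planted_delta_j = 0` is exchangeable by
  construction. Like the anatomy, the population model is a fixed study
  condition: by default every field is exactly $-0.1$ and every coupling
  exactly $+0.15$ — an operating point chosen from the exact Boltzmann
  distributions so that each network is weakly cooperative and its
  landscape is dominated by collective all-active/all-inactive states,
  precisely the kind of network state the signature analysis reports
  (nonzero dispersions around this point are available as parameters). The
  planted effect adds `planted_delta_j` (default 0.5) to every coupling of
  one network in the patients' post-TMS model only.
* **Dynamics.** Network states are drawn i.i.d. from the Boltzmann
  distribution (the model class being fitted has no temporal structure), one
  state per 200 ms frame. The frame length is set by channel physics: an
  8–12 Hz bandpass passes amplitude-envelope content only up to a few hertz,
  so envelope modulation faster than ~5 Hz cannot survive the chain. Within
  a subject the state sequence is fixed across trials — trial averaging
  retains only trial-locked signal, so any structure that must reach the ERP
  stage has to be deterministic per subject.
* **Carriers.** Each subject has one alpha frequency (9–11 Hz) shared by all
  regions; distinct per-region frequencies would beat against each other at
  < 2 Hz, exactly the band in which envelope information lives, corrupting
  every region's power series. Dipoles within a region share the envelope
  but each has its own carrier phase, which makes cross-region interference
  in the quadratic power phase-cancel instead of masquerading as envelope
  modulation.
* **Amplitudes and noise.** Active/inactive source amplitudes 8/0.8
  (arbitrary units against a lead field normalized to unit mean column
  norm) put the clean scalp signal at the few-to-tens of microvolts of
  resting alpha, with 5 µV Gaussian sensor noise; clean trials stay inside
  the ±75 µV gate. Artifacts are ±120 µV, 100 ms square pulses on one random
  channel in a configurable fraction of trials (default 0.1) —
  unambiguously across the gate.
* **Anatomy.** The toy head model is a deterministic schematic atlas:
  every network has a canonical centroid on a cortical shell under the
  electrode cap (sensorimotor central, visual occipital, auditory temporal,
  frontoparietal frontal with a parietal wing, salience fronto-medial,
  attention temporo-parietal), regions are lateralized by the Left/Right
  prefix of their name with a small within-network fan, and voxels sit at
  fixed scattered offsets around their region's centre. Anatomy is a study
  condition, identical in every run — just as real cohorts share one
  montage and one atlas — so no random geometry draw can make a region
  invisible. A region's voxels cycle through an orthonormal orientation
  triad, making each regional source unpolarized: no combination of phases
  can cancel its scalp visibility, and neighbouring regions never share a
  single topography. The lead field uses the infinite-homogeneous-medium
  dipole kernel. Each ROI owns at least one voxel (round-robin assignment).
  A region belonging to several networks is driven by the first network
  containing it; the default planted network (sensorimotor) shares no
  regions, so the planted contrast is not diluted by ownership.

What the generator does **not** emulate: realistic head geometry (BEM/FEM),
eyeblink or muscle artifact morphology, the TMS pulse artifact itself,
temporal autocorrelation of network states beyond the frame structure, and
1/f background EEG. Passing tests therefore demonstrate the correctness and
statistical behaviour of the pipeline under a controlled model of
alpha-band network dynamics — not performance on real recordings.

## What eleven channels can and cannot resolve

After average-referencing, 11 channels span a rank-10 signal space. No
inverse operator — sLORETA included — can linearly separate more than ~10
simultaneously active, same-band sources; with all six shipped networks (26
ROIs) active at once, the measured own-region share of each ROI estimate is
about 0.11 regardless of geometry, and per-region state recovery is
information-theoretically impossible. This mirrors the real constraint of a
sparse montage, which the original experimental design acknowledges. The
package handles this honestly:

* the statistical calibration of the selection procedure does not require
  source resolution and runs on the full configuration;
* the end-to-end planted-signature recovery study (`planted_recovery()`)
  uses a two-network cohort (sensorimotor + visual, 10 regions, 30 voxels,
  22/27 subjects) — a region count the montage can support — with the
  unplanted network as a within-run negative control. Detection means a
  Bonferroni-passing record for the planted network in a comparison the
  planted effect actually touches (patients pre vs post, or the post-TMS
  between-group contrast); the two untouched comparisons and the unplanted
  network stay quiet. The anatomy and the population model are fixed study
  conditions; replicates redraw cohorts (subjects, phases, noise).

## Statistical model

For every (site, network, stable pattern), four comparisons are run on
subject-wise energies: controls pre vs post and patients pre vs post
(paired t-tests — the same subjects are measured in both conditions), and
controls vs patients at pre and at post (Welch two-sample t-tests — the
groups are different people with unequal sizes, so pairing is impossible
and equal variances are not assumed). All tests are two-sided. Cohen's d
uses the pooled-SD convention for independent arms and mean(diff)/sd(diff)
for paired arms. Cells with fewer than two observations per arm are flagged
untestable rather than dropped; zero-variance paired differences yield
p = 1.

The Bonferroni gate divides α = 0.05 by n, the number of stable patterns
selected for that network's landscape, counted per network per stimulation
site (`pool_sites = TRUE` pools across sites instead). Because n counts
patterns — not the four comparison kinds — the gate controls the
family-wise error *within each comparison family per network*, and that is
the quantity `calibrate_null()` measures: the fraction of null cohorts in
which any pattern of a network passes the gate for a given comparison kind.
The relevance gate (p ≤ 5×10⁻⁵) is applied after, and in addition to, the
per-network gate.

## Problem sizes used by the tests and the acceptance script

All simulations are sized to run on one CPU in a few minutes each: the
maximum-entropy recovery check uses M = 5 and 10⁵ samples; landscape oracle
equivalence uses 100 random models at M ≤ 8; localization is verified over
every voxel of a ≤ 100-voxel model; the null calibration runs 1000 reduced
cohorts (M = 5, 10+10 subjects, 200 binarized samples per window) at the
Ising level, where the gate's behaviour is fully exercised without the
forward/inverse chain; and the planted-recovery study runs 50 full-pipeline
replicates of the two-network left-motor cohort at the study's 60 trials
per subject.

## Known limitations

* Exact enumeration bounds networks at 12 regions; larger networks would
  need MCMC fitting, which is out of scope.
* The default-mode network's constituent regions are not part of the
  shipped defaults (no canonical list was available); add an entry to the
  networks YAML to analyze it.
* Subject-level fits rest on ~5 independent network states per 1 s window —
  the information rate of an alpha-power channel — so subject-wise energies
  are noisy; group comparisons absorb this as between-subject variance.
* The binarization threshold (window mean) discards absolute power levels
  by design; effects expressed purely as overall power shifts are invisible
  to the landscape stage.
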