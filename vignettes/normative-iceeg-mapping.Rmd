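---
title: "Normative and abnormality mapping of intracranial EEG with normkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative and abnormality mapping of intracranial EEG with normkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normkit)
```

## The problem

Intracranial EEG (icEEG) is recorded from people with drug-resistant
epilepsy during presurgical evaluation. Because electrodes are only ever
implanted in patients, there is no healthy-control icEEG; a *normative map*
is instead built from the non-pathological tissue of many patients: for
each brain region (a parcel of a volumetric atlas) and each frequency band,
the distribution of a signal property across all subjects with coverage of
that region. A new subject's recording can then be compared against these
regional distributions, and regions whose activity deviates strongly
flagged as potentially pathological.

`normkit` implements that dataflow end to end:

1. **Temporal selection** — find clean interictal (between-seizure) periods
   in an annotated exam and extract fixed-length segments under explicit
   constraints.
2. **Spatial localisation** — assign each electrode contact to its nearest
   same-hemisphere grey-matter parcel and measure distances to a resection
   mask.
3. **Cohort database** — a validated, queryable document store for subject,
   exam and channel metadata (never raw signals; only file locations).
4. **Normative mapping** — per-channel log relative band power (log(RBP)),
   aggregated to regions, outlier-filtered, summarised as mean/SD/n per
   region and band.
5. **Abnormality mapping** — regional z-scores for held-out subjects,
   max-|z| regional abnormality, and the distinguishability statistic
   `D_RS` (AUROC of resected vs spared regions).

A seeded synthetic-cohort generator emulates every input, so the whole
pipeline is exercised against known ground truth without any clinical data.

## The metric

For a preprocessed segment, each channel's power spectral density is
estimated by Welch's method (2 s Hamming windows, 50% overlap, 0.5 Hz
resolution). Band power is the sum of PSD bins whose centre falls in the
half-open band; relative band power is

$$\mathrm{RBP}_b = \frac{P_b}{\sum_{b'} P_{b'}},$$

over the five default bands delta [1, 4), theta [4, 8), alpha [8, 13),
beta [13, 30) and gamma [30, 47.5) Hz. Because every in-range bin belongs to
exactly one band, the five RBP values sum to 1 *exactly*; the mapped
quantity is $\log_{10}(\mathrm{RBP})$. Channels sharing a region are
averaged in RBP space before the log (the mean of proportions is itself a
proportion; logging first would produce a geometric-mean hybrid).

The normative map stores, per (region, band): mean, SD and n of
$\log_{10}(\mathrm{RBP})$ across subjects, with regions below `min_n = 30`
subjects dropped — below that, the SD (the denominator of every z-score) is
too unstable to support abnormality mapping.

## Decision-point parameters

| parameter | default | why |
|---|---|---|
| state of consciousness | `W` (wake) | maps are state-specific; wake is the common baseline |
| seizure buffer | 2 h each side, per seizure type | keeps segments genuinely interictal; per-type overrides supported |
| minimum sampling rate | 200 Hz | resolves the gamma band with headroom |
| segment length | 70 s | ~69 Welch windows: stable PSD, short enough to stay stationary |
| segments per subject | 3, "where possible" | backups against later exclusions; shortfall is not an error |
| segment separation | 4 h start-to-start | temporal independence of backups |
| post-implant skip | 24 h | avoids implantation/anaesthesia effects |
| grey-matter distance | 5 mm | contacts further from grey matter are unassigned (`n/a`) |
| resection distance | 5 mm | contact counts as resected within 5 mm of the mask |
| resected region rule | strictly > 25% of contacts | regional resected/spared label |
| noisy-channel z | 3 (mapping), 5 (scoring) | scoring must not discard genuine spiking |
| leave-one-out z | 3, iterated to fixed point | removes regional outliers from the normative table |

Separation is measured start-to-start: segment length (70 s) is negligible
against the 4 h constraint and the edge convention is otherwise
unspecified; it is configurable. Clock-time windows (e.g. 8 am–10 pm) are
applied via the exam start datetime, timezone-naive.

## Preprocessing and numerical choices

Retained channels are common-average re-referenced (the reference is
computed *after* channel exclusion, so noisy channels cannot contaminate
it), band-passed to 0.5–47.5 Hz, notch-filtered at the mains base and
harmonics when they fall inside the analysis range, and resampled to a
common 200 Hz.

All filtering is performed by zero-phase FFT-domain masking with
raised-cosine (half-Hann) transition edges of 0.5 Hz, and resampling by the
Fourier method. An IIR (Butterworth) design applied forward–backward is the
more traditional choice; the FFT route was chosen deliberately: it is
exactly zero-phase, has unit passband gain to machine precision, needs no
filter-design dependency, and its behaviour is directly assertable (the
test suite checks ≥ 20 dB mains suppression with < 1 dB passband change).
On fixed-length segments the usual FFT-filtering caveat (circular
wrap-around at the edges) is immaterial at these transition widths.

Other numerical conventions:

* Distances are world-space millimetres from the query point to **voxel
  centres**; the paper-level convention (centres vs boundaries) is
  unspecified, centres are exact and simple. Nearest-voxel ties break by
  smallest label id, then lexicographic voxel index — determinism over
  geometric taste.
* Localisation is constrained to the channel's known hemisphere; a midline
  contact can be geometrically closer to contralateral grey matter.
* A flat (zero-power) channel yields `NA` relative band powers, never
  `-Inf`.
* Zero-SD cells: in the leave-one-out filter a value equal to a zero-spread
  rest has no finite z and is never flagged, while a deviant value against
  a zero-spread rest is unambiguously extreme and is removed; in z-scoring,
  a zero-SD normative cell is an error rather than an infinite score.
* The log base is 10 throughout (configurable in spirit; the choice only
  rescales z-scores by a constant and cancels in every downstream
  statistic).
* `D_RS` is computed by the closed-form Mann–Whitney rank statistic with
  exact tie handling (ties count one half), never by trapezoidal ROC
  integration. Orientation: 1 means resected regions are uniformly more
  abnormal; the convention is flippable. The maximum is taken over the
  *absolute* z-scores per region — pathology may push band power in either
  direction.

## The synthetic world

The generator's defaults are a stated world, not tuning knobs:

* **Signals.** Each clean channel is a Gaussian process with a prescribed
  spectrum: a $1/f^2$ background (85% oscillations / 12% background / 3%
  mains by variance), band-limited oscillation components whose variances
  follow the channel's regional profile, and a narrow mains peak (60 Hz
  default, RAM-style US data). Regional profiles are archetypes (hippocampus
  theta-rich, amygdala delta-heavy, temporal neocortex alpha-leaning,
  frontal beta-leaning), all delta-dominant as interictal icEEG is.
  Between-subject variation is lognormal with $\sigma = 0.1$ in
  $\log_{10}$ units (~25% power variation) at the region level, with 0.03
  channel-in-region jitter. Artifact channels get 30x-amplitude
  low-frequency non-physiological noise; spiking channels get ~70 ms
  biphasic transients at 0.5–2/min (the protocol only flags spikes, so only
  a plausible morphology is needed).
* **Timelines.** Circadian wake/sleep alternation (sleep 23:00–07:00 in
  N1/N2/N3/REM blocks, occasional afternoon naps), seizures from a Poisson
  process (2/day default) with a focal/subclinical/secondarily-generalised
  mix and type-dependent lognormal durations.
* **Recordings.** Written as scheduled fixed-length files (four 90 s chunks
  per day at 09:00, 12:30, 16:00, 19:30) rather than days of continuous
  samples: clinical systems also split exams into files, selection logic is
  exercised identically, and a literal multi-day cohort would be gigabytes
  of scratch data that tests nothing further. Candidate periods are
  intersected with recorded file spans.
* **Geometry.** A shared 1 mm toy volume with eight 10 mm grey cubes (four
  per hemisphere) inside white-matter slabs; one depth electrode per cube
  with contacts at jittered interior voxel centres, so each contact's true
  region is known by construction. Subcortical label ids match FreeSurfer
  (17/53 hippocampus, 18/54 amygdala); cortical ids follow the
  tutorial-style sequential numbering and are documented as synthetic.
* **Pathology.** Held-out subjects carry a +3 SD shift of gamma-band
  $\log_{10}$ power in designated regions, with the renormalisation of the
  other bands that necessarily follows, and a resection mask rasterised
  over those regions. Gamma was chosen as the shifted band because
  epileptogenic tissue expresses excess fast activity and the gamma band is
  least diluted by the $1/f$ background, so the realised log-RBP shift
  stays close to its nominal size.

What a green test does **not** establish: the synthetic world has no
volume-conduction structure, no real electrode trajectories, no
non-stationarity beyond block alternation, and its spectral statistics are
archetypes, not estimates of any clinical cohort. Green tests certify the
*dataflow* — constraint enforcement, localisation geometry, schema
integrity, spectral identities, estimator calibration and recovery of a
known ground truth — not clinical validity.

## Design choices where the design was open

* **Scoring pipeline asymmetries.** When scoring held-out subjects,
  pathological-channel exclusion and regional outlier removal are skipped
  *by construction* (the pathology is the signal being sought), and the
  noisy-channel threshold is raised to 5 so genuine spiking is never
  silently discarded. The run log's channel accounting makes these
  asymmetries auditable.
* **One segment per subject** enters the final map (the lowest surviving
  segment number); backups exist to survive exclusions, not to be pooled.
* **Database backend** is one JSON collection per class in a directory with
  content-hash ids: dependency-free, diffable, and byte-reproducible, which
  the determinism tests rely on. Uniqueness rules are enforced at insert at
  second precision for datetimes.
* **Automated QC stands in for visual inspection.** The protocol's visual
  segment/channel checks are desk-automated: flatline, robust-z of log
  total power across channels, and a non-negative log-log PSD slope
  (physiological spectra fall with frequency) flag unsuitable channels.
* **Greedy earliest-first placement** of segments is deterministic;
  reproducibility was preferred over placement optimality (a later feasible
  placement set is never searched once the greedy cursor passes it; the
  protocol only asks for segments "where possible").

## Limitations

* The scored subject must share the map's full metric configuration; this
  is enforced by a configuration hash, not re-derived from data.
* The leave-one-out filter assumes approximate normality of regional
  log(RBP); with very small cohorts (n per cell below ~10) it is
  aggressive, which the stated `min_n = 30` floor makes moot in practice.
* EDF import is not implemented; recordings enter via the package's own
  binary-plus-JSON containers.
* Only the relative-band-power metric is implemented; phase-amplitude
  coupling, absolute band power and centile (rather than z-score) mapping
  are out of scope.
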