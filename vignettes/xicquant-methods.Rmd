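---
title: "Methods: baseline correction, ion-trace extraction and quantification in xicquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline correction, ion-trace extraction and quantification in xicquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

xicquant is a headless toolkit for *targeted* analysis of hyphenated
mass-spectrometry data: the user declares which compound ions to trace, and
the package turns raw detector traces and MS1 scan sequences into integrated
responses and, when calibration standards are available, concentrations.
This vignette explains the algorithms, their assumptions, the tunable
parameters, and what the synthetic validation data does — and does not —
establish about behaviour on real data.

## Data model

Two kinds of raw input exist.

* A **chromatogram** is a pair of aligned vectors: strictly increasing
  retention times (minutes, by convention; the package never rescales file
  units) and detector responses, which may be negative (e.g. UV absorbance
  after vendor auto-zeroing). Delimited text is ingested by dialect
  sniffing: delimiter candidates are tried in the fixed order comma, tab,
  semicolon, whitespace-run, and the first candidate under which two
  consecutive rows expose at least two float columns wins; rows above that
  point are header, the first float column is time and the last is signal.
  This follows the widespread instrument-export convention of auxiliary
  columns between time and the primary signal. The decimal separator is the
  dot only — a comma-decimal locale is indistinguishable from comma-delimited
  data, so it is rejected rather than guessed.

* An **MS run** is an ordered collection of MS1 scans, each a centroided
  (or profile) spectrum: an ascending m/z array with aligned non-negative
  intensities plus a retention time. mzML files are read through `mzR`
  (ProteoWizard), which handles indexed and plain documents, 32/64-bit
  floats and zlib compression; xicquant filters to MS1, converts retention
  times to minutes, re-sorts any non-ascending m/z array (with a warning),
  treats a missing MS level as MS1 (logged), and imputes a missing retention
  time as the previous scan's time plus the run's median scan interval, so
  the trace axis never has silent gaps.

## SNIP baseline correction

Chromatographic baselines drift with gradient composition, column bleed and
detector temperature. xicquant estimates them with statistical non-linear
iterative peak clipping (SNIP) in a compressed space:

1. Shift the signal by its minimum so it is non-negative (this makes the
   algorithm exactly equivariant under additive offsets and well-defined for
   negative absorbances).
2. Compress with the log-log-square-root (LLS) operator
   $v = \ln(\ln(\sqrt{S + 1} + 1) + 1)$, flattening the dynamic range so tall
   peaks do not dominate the clipping arithmetic. The operator is strictly
   increasing and exactly invertible:
   $S = (e^{e^{v}-1}-1)^2 - 1$.
3. For iteration $i = 1, \dots, N$ replace each interior point by
   $\min\{w(t),\ \tfrac{1}{2}[w(t-i) + w(t+i)]\}$. The clipping half-width
   grows with the iteration index; points whose symmetric neighbours fall
   outside the array are left unchanged (no reflection padding, which can
   manufacture edge artefacts).
4. Decompress, unshift; the corrected signal is the input minus this
   baseline, so their sum reconstructs the input to within one floating-point
   ulp.

`iterations = 20` is the default for all chromatography data — enough for
routine LC/GC baselines at a fraction of the preprocessing cost of adaptive
schemes. Two consequences of the algorithm are worth knowing:

* The **effective clipping half-width is `iterations` samples**. A peak
  wider than roughly the clipping window is treated as baseline and eaten.
  At 5 samples/s, 20 iterations accommodate peaks with $\sigma$ up to about
  1 s; slower sampling or wider peaks need more iterations (the parameter is
  exposed everywhere, including the CLI's `--iterations`).
* On noisy data the min-clipping **baseline hugs noise valleys**, so the
  corrected trace carries a small positive offset of roughly twice the noise
  standard deviation. Whole-window sums of the corrected signal inherit this
  bias; the per-peak integrator below removes it with a local linear
  baseline. This is why area accuracy on noisy synthetic data is asserted on
  the anchored integrator, not on raw windowed sums.

There is also a systematic sag where the baseline is curved *in compressed
space* (even a linear ramp is curved there): the chord average under-cuts a
concave function. At routine acquisition densities (hundreds of samples per
minute) the sag is a fraction of a percent of the baseline range; it grows
with the per-sample step of the drift.

## Extracted ion chromatograms

Each declared ion m/z becomes a window. Tolerances are half-widths, either
relative (`mass_tol(ppm = 3)`, the default — at m/z 500 this spans
±0.0015 Th) or absolute (`mass_tol(da = 0.0003)` for narrow-window
high-resolution work). Identical ions declared by several compounds — after
rounding centres to 1e-6 Th, a floating-point-safe notion of "the same ion"
— share one window, so the run is scanned once per *unique* ion: with $U$
unique windows, $S$ scans and $M$ points per scan the cost is
$O(U \cdot S \cdot \log M)$, the $\log M$ coming from binary search for the
first in-window index in each sorted m/z array. Both window endpoints are
closed; everything inside is *summed* (not nearest-peak-picked), which is
the quantity the integrator needs and keeps additivity exact for disjoint
windows. The optimized path is validated against a naive full-scan reference
for exact equality — same summation order, bit-identical results.

An XIC's apex can be matched to chromatography: the nearest manual peak
label or expected retention time within `rt_tol` (default 0.5 min) annotates
the trace; farther labels leave it unmatched, which is a reported outcome,
not an error. Equidistant candidates resolve to the earlier retention time.

## Peak integration

Around a retention-time anchor (an expected RT, a matched label, or the apex
itself), the apex is the maximum within ±`rt_halfwindow` (default 0.5 min,
generous for LC peak widths). Bounds walk outward until the intensity rises
for two consecutive samples (robust to single-sample noise; the bound backs
off to the valley) or falls below 1% of the apex height. The peak area is
the trapezoidal integral above the straight line through the two bound
points — a local baseline suited to a narrow slice, where the long-context
SNIP estimator has nothing to work with — clipped at zero. If the anchored
region contains no signal at all, the fallback integrates the whole trace by
the trapezoidal rule with no baseline handling, so every (file, ion) pair
always yields a finite response.

## Calibration and quantification

One file is one calibrant point; a file's concentration comes either from an
explicit `filename, concentration` mapping or is imputed from the file name
(first token of the form number-immediately-followed-by-unit among pM, nM,
uM, µM, mM, M, ng/ml, ug/ml, mg/ml, case-insensitive; the number is reported
in the unit as written, never converted). Exactly one concentration per file
is allowed. Per compound, the calibrants' integrated responses (summed over
the compound's declared ions — co-measured species such as dimer ions then
contribute to the same response) are fitted by ordinary unweighted least
squares, either on raw scales (default) or log10–log10, the usual choice for
serial dilutions spanning decades. Unknowns are estimated by inverting the
line; estimates outside the calibrated range are returned but flagged as
extrapolated in the record's description. Calibrant records echo their known
concentration — user ground truth is never replaced by a re-estimate. A
compound whose calibration cannot be fitted is reported without
concentrations and does not disturb other compounds.

## Synthetic data and what it shows

The generator builds chromatograms as Gaussian peaks over a polynomial
baseline with additive white noise, and MS1 runs in which target ions elute
with Gaussian amplitude profiles among uniformly placed background ions with
exponentially distributed intensities (a crude but serviceable stand-in for
chemical noise across a realistic dynamic range). Calibration series embed
their concentration in the file name and realise a linear detector response
with multiplicative noise. Every generator is a pure function of its
arguments, including the seed, and returns ground truth alongside the data.
A minimal mzML 1.1.0 writer (uncompressed 64-bit floats) supports byte-exact
write–read validation against the full-featured reader.

Validation conditions are fixed once and mirror a routine acquisition:
15-minute runs at 5 samples/s (4,500 samples), three fast-LC peaks
($\sigma$ = 0.015–0.02 min, heights 800–1200) over a drifting polynomial
baseline with noise at 1% of the mean peak height; XIC equivalence on 100
randomized runs of up to 200 scans × 2,000 points × 50 windows; calibration
recovery on the five-decade ladder 1–10,000 with 1% multiplicative response
noise over 100 seeds, judged at the 100-unit point. These sizes keep the
whole validation suite to well under a minute while exercising every code
path at realistic densities.

What passing does **not** show: real chromatograms have asymmetric
(tailing) peaks, heteroscedastic and correlated noise, and co-eluting
interferences; real spectra have isotope patterns, adducts and
profile-mode peak shapes; real calibration curves saturate at high
concentration. The synthetic suite validates the *mechanics* — exactness of
the search, invertibility of the transforms, determinism of the pipeline,
unbiasedness under the stated noise model — not instrument-specific
performance. On noisy single realizations, individual peak areas can deviate
by up to ~8% (bound placement under noise); the per-run mean across peaks
stays within 5%, which is the accuracy claim the package makes and tests.

## Numerical choices and degenerate inputs

* Window dedup rounds to 1e-6 Th before equality; interval endpoints are
  closed on both sides.
* The optimized XIC sum uses the same index-order summation as the reference
  definition, so equality is exact, not approximate.
* `corrected + baseline == signal` holds to one ulp (the subtraction is
  performed once; IEEE addition does not exactly undo it).
* Short signals clamp SNIP iterations to `floor((n-1)/2)` with a warning;
  constant signals are their own baseline; empty scans contribute zero to
  every window and to the TIC.
* Unparseable rows after a header are skipped with a warning (instrument
  exports often append footer lines); a file with fewer than two parseable
  rows is a typed error, never a partially constructed chromatogram.
* Output records are sorted by (filename, ion name), making the exported
  CSV byte-deterministic regardless of input order or scheduling.

## Limitations

No untargeted feature finding, no peak-shape fitting or deconvolution of
co-eluting peaks, no retention-time alignment across runs, no
internal-standard or weighted calibration, no ion mobility or MS2/MRM
support, and mzML is the only MS format (write side: minimal uncompressed
subset only). These are deliberate scope boundaries, not roadmap accidents:
the package targets the declare-ions → integrate → calibrate workflow.
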