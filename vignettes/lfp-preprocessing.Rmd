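---
title: "Preprocessing chronically sensed deep-brain LFPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing chronically sensed deep-brain LFPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpclean)
```

Implanted deep-brain stimulation systems that sense local field potentials
(LFPs) deliver microvolt-scale bipolar recordings, typically streamed at
250 Hz. Three nuisance processes routinely corrupt the spectral quantities
clinicians and researchers care about (theta/alpha/beta/gamma band power):
a cardiac QRS artifact that is time-locked to the heartbeat and leaks into
the 4–30 Hz range, brief high-amplitude transients (movement artifacts,
stimulation on/off edges, interictal-like discharges) that contaminate the
whole power spectral density (PSD) despite lasting a fraction of a second,
and the broadband aperiodic 1/f background on which any periodic activity
rides. `lfpclean` implements a preprocessing chain for exactly these three
problems, in the order in which they are best removed: predictable
time-domain interference first, then frequency-domain window rejection, and
finally aperiodic detrending of the surviving background spectrum.

## Cardiac QRS template subtraction

The R wave is detected on a copy of the signal bandpassed to 5–30 Hz
(4th-order Butterworth applied forward–backward, so there is no group delay
and detected apexes stay aligned with the raw trace; the input is
odd-reflection padded so filter startup transients never touch the data).
Local maxima qualify as R peaks when their prominence exceeds 2.5 times the
standard deviation of the bandpassed signal and they are at least
`60 / max_heart_rate` seconds apart (0.5 s at the default 120 bpm ceiling,
i.e. 125 samples at 250 Hz). Because electrode geometry can invert the
complex, detection also runs on the negated signal; the polarity that finds
more peaks wins. Equal counts are common in the inverted case — zero-phase
bandpassing gives each inverted apex a positive ringing lobe — so ties are
broken by mean peak prominence (the true apex is always the more prominent),
and only then in favor of positive polarity.

The template is the pointwise mean of *raw-signal* windows of 36 samples on
either side of each apex. Averaging in the raw domain matters: the artifact
has energy outside 5–30 Hz, and subtracting a bandlimited template would
leave that energy behind. The averaged template is multiplied by an
equal-length symmetric Hanning window, which forces its endpoints to exactly
zero so subtraction cannot inject clicks; events whose window would cross a
record boundary are skipped rather than truncated for the same reason.
Cardiac contamination is time-locked across hemispheres, so
`remove_ecg_bilateral()` detects events on both channels, takes the channel
with the larger mean prominence as the reference, and reuses its event times
on the weaker channel (whose artifact may be too small to detect reliably).
Separate templates are averaged per channel and per stimulation state, since
stimulation can scale the artifact; a state with fewer than
`min_events = 10` usable events falls back to a pooled template. The floor
of 10 is the point below which averaging stops suppressing background
meaningfully (error shrinks as $1/\sqrt{n}$).

Two practical limits are worth knowing. First, the 2.5σ prominence rule
presumes a visible artifact: run on artifact-free data it will happily
"detect" the tallest noise peaks (prominence of an oscillatory noise maximum
is roughly twice its amplitude), and the resulting peak-aligned average is a
small but systematic wave packet. The method is therefore applied once, to
recordings in which a QRS complex is actually observed, not iterated.
Second, on perfectly periodic beat trains the ringing of adjacent filtered
complexes can superpose midway between beats and occasionally clear the
threshold; physiological heart-rate jitter removes this alignment.

## Spectral estimation

PSDs are estimated either by Welch's method (Hanning windows, 50% overlap,
symmetric zero-padding to `nfft`, one-sided density normalization in
µV²/Hz) or by the multitaper method (Slepian tapers, equal-weight average of
per-taper periodograms, additionally averaged over overlapped windows for
long records). The window arithmetic is exposed directly: the lowest
observable frequency of an `N`-sample window is `fs/N`; the DFT bin spacing
is `fs/nfft`; the effective smoothing of a Hanning window is its main-lobe
half-bandwidth `2 fs/nfft`; and a window of `T` seconds at half-bandwidth
`W` Hz supports `floor(2TW) − 1` tapers. At the package's standard
short-time setting — 2 s windows, 50% overlap, `W` = 1 Hz — that is 3 tapers
per window. When a long window's Hanning half-bandwidth would fall below
1 Hz, the multitaper default holds `W` at 1 Hz instead, converting
unneeded resolution into extra tapers and hence lower estimator variance.

Slepian tapers are computed in-package as eigenvectors of the standard
symmetric tridiagonal matrix, unit-energy normalized and cached per
parameter set (no installed R package provides them). Each analysis segment
is linearly detrended before tapering by default: steep 1/f backgrounds put
large slow excursions inside a 2 s window, and their sidelobe leakage
otherwise biases the whole estimate — with an exponent of 2 the broadband
log-log slope came out at −2.03 with detrending and visibly shallower
without. One honest caveat on nominal smoothing: the −3 dB width of the
*averaged* Slepian lobe is systematically a few tenths of a hertz inside
`2W` at small taper counts (measured 1.3/3.4/7.5 Hz against nominal 2/4/8 at
`W` = 1/2/4 with `T` = 2 s); the nominal figure is the concentration band,
not the half-power width.

## Rejection of nonstationary spectrogram windows

The background spectrum is estimated from a short-time multitaper
spectrogram (2 s, 50% overlap, 3 tapers) by discarding windows that do not
look like the rest and averaging the survivors *in linear power* (an average
of power estimates is itself a power estimate; averaging in dB would bias
low). Two single-pass Grubbs filters flag outliers, both computed on
dB-scale PSDs, z-scored across windows, and thresholded at

$$ z_{thr} = \frac{N-1}{\sqrt{N}} \sqrt{\frac{g}{N-2+g}}, \qquad
   g = t^2_{\alpha/2N,\,N-2}, $$

with α = 0.05 — the threshold adapts to the number of windows `N`. The first
filter's statistic is each window's mean Pearson correlation with all other
windows over the 4–75 Hz broadband range; it catches shape outliers but is
blind to pure level shifts (correlation is offset-invariant). The second
filter's statistic is mean dB power over 0–5.3 Hz, two-sided, catching the
low-frequency loading characteristic of movement and discharge transients.
The final rejection set is the union of the two.

Two operating characteristics follow from the mathematics and are
reproduced by the package's tests rather than hidden. (1) *Masking*: a
single-pass Grubbs test cannot reject `m` comparably contaminated windows
out of `N` once `m/N` reaches about 10% — the largest attainable z-score
with `m` equal outliers is $\sqrt{(N-m)(N-1)/(mN)}$, which for `m` = 3 of
`N` = 30 (2.95) essentially touches the threshold (2.91). One or two
contaminated windows are rejected with near certainty; three or more
comparable ones are not. (2) *Anticonservatism of the correlation filter*:
the mean-correlation statistic is bounded above by 1 and left-skewed, so a
two-sided |z| threshold derived from a normal model rejects clean windows
somewhat more often than its nominal α (all excess rejections are left-tail,
i.e. the least-correlated window of a clean set). The low-frequency power
filter, whose statistic is close to normal, holds its nominal level.

As an alternative estimate, `pca_background()` centers each window's dB PSD
by its own mean over 4–75 Hz and takes the first principal component across
windows — the spectral shape carrying the dominant shared variance — then
orients it to correlate positively with the mean PSD and least-squares
scales and shifts it onto the mean. On majority-clean spectrograms this
tracks the true background more closely than the raw mean, without any
threshold.

## Two-pass aperiodic (1/f) detrending

The aperiodic component is modeled in log10-power units as

$$ \log_{10} P(f) = b - \log_{10}(k + f^{x}), $$

with knee `k` (bend position), exponent `x` (decay) and offset `b`. The
model is fit by bounded Levenberg–Marquardt least squares
(`k ∈ [0, 10³]`, `x ∈ [0, 10]`; multiple starts, plus an exact log-linear
solution for the `k = 0` boundary where the knee and offset gradients turn
collinear). The fit is performed on log10 power; dB (10×) is used only for
display.

The first pass fits the 4–75 Hz broadband range. Periodic peaks inside that
band pull the fit upward, which both flattens detrended peaks and produces
negative residuals. The second pass therefore refits using only bins that
plausibly touch the aperiodic floor: a high band (default 55–75 Hz, above
the periodic bands but inside the broadband range) plus ±1-bin
neighborhoods of local minima of the first-pass residual (prominence at
least 0.05 log10 units). Two safeguards keep this refinement honest. If no
minima are found there were no peaks to correct, and the initial parameters
are kept — the high band alone cannot identify the knee, and refitting it
unconstrained sent `k` to its bound on peak-free spectra. And the refit is
adopted only if it at least halves the initial parameters' summed squared
error on the anchor set; a marginal gain means the anchors carry nothing
beyond estimator noise, and refitting them overfits. In all cases the
refined parameters never fit the anchor set worse than the initial ones.

Parameter recovery is verified on simulated backgrounds (300 s at 250 Hz)
with a multitaper estimator at 4 s windows and 0.5 Hz half-bandwidth —
finer smoothing than the short-time default, needed because 1 Hz smoothing
blurs knee curvature near the 4 Hz band edge (it biased `k` low by about
11% at `k` = 5). Knees at or below 1 Hz sit entirely outside the fit band
and are recovered only coarsely; the exponent and offset are robust
throughout.

## The synthetic LFP generator

Every test runs against `sim_spec()`/`assemble_recording()`, which emulate:
a 1/f-with-knee background synthesized by frequency-domain amplitude
shaping (uniform random phases, conjugate-symmetric spectrum, DC forced to
zero — giving direct control of `k`, `x`, `b` for recovery tests);
band-limited oscillations as Butterworth-filtered noise scaled to a target
RMS (filtered noise, not sinusoids, so spectral peaks have realistic
width); a quasi-periodic QRS train (three Gaussian deflections, Q and S
negative around a dominant R apex, ~55 samples wide at 250 Hz, shared event
times across channels, per-channel scale and polarity, optional
stimulation-state scaling); short transients (a sharp biphasic
interictal-like wave, and an exponentially settling stimulation-edge step);
and optional round-to-nearest digitization.

Defaults are chosen to be representative of chronically sensed thalamic
LFPs and stated once: background `k = 2`, `x = 1.5`, `b = 1` (≈5 µV RMS
trace), theta/beta oscillations of 1.5/1 µV RMS, heart rate 70 bpm with 3%
inter-beat jitter, QRS apex 40 µV (about 8× the background SD — cardiac
artifacts, where present at all, dominate the bandpassed trace), IED-like
transients 200 µV and stimulation edges 100 µV (visibly dominant
single-events, tens of times the background RMS). The generator emulates
the statistical structure the pipeline assumes — stationary background,
time-locked artifact, localized transients. It does not emulate
nonstationary neural dynamics, correlated bilateral backgrounds, P/T waves,
or genuine stimulation waveforms, so passing tests demonstrate correct
behavior under the pipeline's own assumptions, not performance on every
pathology a clinic will see.

Ground truth carries every component separately, and the contaminated trace
equals their sum exactly (before quantization), so tests can assert
conservation, detection recall/precision against true apex times, band-power
recovery against the clean trace, and rejection of exactly the
transient-bearing windows.

## Numerical and interface choices

* dB is `10·log10(power)` everywhere; fits run in log10 power.
* The DC bin is kept in PSD objects but excluded from all fits; one-sided
  density normalization satisfies Parseval within estimator tolerance.
* `nfft` defaults to the next power of two at or above the window length.
* Grubbs' `g` is the *squared* t quantile at upper-tail probability
  `α/(2N)`; with `N` = 10, α = 0.05 this gives the familiar critical value
  2.290. Degenerate inputs (zero statistic variance, zero-variance windows)
  reject nothing / are auto-rejected with a warning, respectively.
* Problem sizes in the test-suite simulations (60 s detection records,
  31 s / 30-window rejection replicates, 300 s recovery records, 5–20 seeds
  per stochastic claim) were chosen as the smallest at which the measured
  quantities are stable across seeds.
* All user-facing functions take the data object first and return tibbles,
  so pipelines compose with the pipe; `tidy()`/`glance()` methods summarize
  fits and rejection results, and `autoplot()` methods plot recordings,
  PSDs, spectrograms and detrended spectra.

## Known limitations

Rerunning QRS removal on already-clean data subtracts a small noise-peak
template (see above) — inspect before applying. The combined window filter
cannot reject three or more comparably contaminated windows of thirty
(Grubbs masking); recordings that contaminated should be segmented or
excised in the time domain first. The correlation filter over-rejects
slightly on clean stationary data (left-skewed statistic under a two-sided
test); the cost is small, since dropping the least-correlated clean window
barely moves a linear-power average. Percept-style session JSON ingestion
is best-effort against community-documented key names and does not promise
full dialect coverage.
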