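---
title: "Single-capture bright-field / holographic demultiplexing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-capture bright-field / holographic demultiplexing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfdhm)
```

## The measurement problem

A multimodal microscope can record, in one 8-bit camera exposure, the sum of
two images of the same scene: an incoherent bright-field (BF) intensity image
and an off-axis digital hologram formed by interfering a coherent object wave
$O$ with a tilted plane reference wave $R$. The recorded gray value is
proportional to

$$ I \;\propto\; \mathrm{BFI} \;+\; |O|^2 + |R|^2 \;+\; 2\,\mathrm{Re}(O R^{*}), $$

where BFI is the bright-field intensity. Because the reference is tilted by a
small angle $\theta$ relative to the object wave, the interference term rides
on a spatial carrier of frequency $\sin\theta/\lambda$ and separates from the
rest in the Fourier domain: the cross-correlation terms $OR^{*}$ and $O^{*}R$
sit at $\pm$ the carrier, while the BF spectrum and the holographic
autocorrelation $|O|^2+|R|^2$ stay centred on DC. One capture therefore holds
both a quantitative phase image (QPI) — the argument of the demodulated cross
band — and a BF image, at the cost of sharing the sensor's dynamic range and
spatial-frequency plane between the two modes. `bfdhm` implements both the
forward model (a simulator that renders such captures from known phantoms) and
the inverse pipeline (demultiplexing), so that every stage can be validated
against ground truth without any experimental capture.

## Geometry

The shipped instrument preset (`optics_preset("ts2r-20x")`) uses a 532 nm
laser, a 5.86 µm-pitch 1936 × 1216 px monochrome sensor, a 20× / NA 0.40
objective and a 1.9° object/reference tilt. Derived constants, all exposed as
closed forms:

```{r geometry}
cfg <- optics_preset("ts2r-20x")
field_of_view(cfg)        # um at the object plane
carrier_frequency(cfg)    # cycles/m at the sensor
fringe_period_px(cfg)     # 2.74 px: resolvable, above the 2 px Nyquist limit
pupil_cutoffs_px(cfg)     # coherent and incoherent cutoffs, cycles/px
```

Internally all frequencies are in cycles/pixel on a DC-centred grid; row-major
images with the origin at the top left; conversions to cycles/m happen only at
the interface. The paper-unstated carrier azimuth defaults to 45° so the
carrier sits on the spectral diagonal of a rectangular sensor, maximizing its
distance from the central band; it is configurable.

## The forward simulator

Phantoms live on the demagnified sensor grid (no resampling, so captures are
bit-reproducible): a medium refractive index, spherical inclusions with chord
thickness $t(\rho)=2\sqrt{r^2-\rho^2}$, and optional absorption. The object
wave is the coherent image of $a\,e^{i\varphi}$ with
$\varphi = 2\pi\,\Delta n\,t/\lambda$, low-passed by the circular coherent
pupil; the BF image is the incoherent image of $a^2$ under the autocorrelated
pupil (OTF). In this scalar model an in-focus pure-phase object is invisible
in BF, which is the practical motivation for pairing BF with QPI.

Gray-level mapping. The expected gray value is
`led_gain * p_led * BFI + laser_gain * p_laser * (|O|^2 + |R|^2 + 2 Re(O R*))`.
Two choices here are package design decisions, since emission powers at the
sample plane do not fix sensor gray levels:

* `led_gain` = 6 gray/mW maps the maximum LED power of the standard grid
  (30 mW) to a ≈180-gray background, leaving headroom for the fringes.
* `laser_gain` = 18 gray/mW keeps the noise-free image below full scale at the
  grid maximum (2.0 mW laser + 30 mW LED) while making the fringes clearly
  visible on top of the BF background, as they are in real multiplexed
  captures. A single shared gray/mW efficiency cannot do both, because the two
  sources reach the sensor along very different optical paths.
* `laser_ref_fraction` = 0.95: the object arm crosses the condenser, specimen
  and objective and is strongly attenuated, while the reference is injected
  just before the camera, so the effective sensor-plane power split is heavily
  reference-dominated. This ratio controls how strongly coherent disturbances
  appear in the central band relative to the cross band, and with a balanced
  split the optimal subtraction weight would be driven above 1 — incompatible
  with the observed optimum weights between 0.05 and 0.3.

Noise model (defaults chosen once, from the reported noise landmarks of the
instrument: a BF background STD of ≈2.6 gray levels and a laser-only intensity
STD roughly 9× higher):

* shot noise as Poisson photoelectrons with `gray_per_electron = 0.03`
  (Poisson directly on 8-bit gray values would give a ≈14-gray background STD,
  far off any real CMOS camera), plus Gaussian read noise of 1 gray;
  together ≈2.6 gray at the full-LED background;
* coherent artifacts: three fixed-frequency parasitic fringe systems plus
  band-limited speckle added to the object arm, total RMS 0.3 of the unit
  background amplitude. These reproduce the coherence-induced disturbances
  (dust, internal reflections) that make laser-only intensity images noisy and
  set a laser- and LED-power-independent QPI phase-noise floor of ≈0.2 rad;
* 8-bit quantization: round half up, clip; saturation above 1% of pixels
  warns, a noise-free mean above full scale errors.

The simulator does not model defocus, the LED's 28 nm spectral bandwidth or
partial spatial coherence, polarization, or fixed-pattern noise. Passing tests
therefore demonstrate correctness of the demultiplexing pipeline under an
idealized scalar model, not performance on real captures.

## QPI recovery

1. **Spectrum** — 2D FFT, DC-centred. No windowing by default (windows destroy
   the corner regions used for background statistics).
2. **Carrier location** — magnitude peak outside an exclusion disk of 1.5× the
   coherent cutoff (so the autocorrelation lobe cannot capture the search),
   restricted to the positive-$f_x$ half plane, refined by a 3×3 quadratic fit
   on the log magnitude. A peak must stand 3× above the 99.9th percentile of
   the searched spectrum; otherwise the capture has no usable hologram
   ("no carrier detected" — the expected failure mode at zero/low laser
   power). The quadratic fit is then polished by a phase-gradient refinement:
   demodulate, take the median wrapped phase increment along rows and columns,
   update the carrier, twice. This removes the residual tilt that a
   fraction-of-a-bin peak error would otherwise leave across the field.
3. **Cross-band extraction** — soft (Tukey-edged, 10% of radius) circular mask
   of radius `min(coherent cutoff, 0.5 |carrier|)` — the largest passband that
   cannot overlap the autocorrelation band — translated to DC by an
   integer-bin roll plus a residual-carrier phase ramp.
4. **Unwrapping** — reliability-sorting region growing (second-difference
   reliability, edges merged in decreasing reliability, whole regions shifted
   by multiples of $2\pi$). Total, deterministic, pixelwise congruent with the
   input modulo $2\pi$; residue counts are reported as a diagnostic.
5. **Aberration compensation** — least-squares fit of a total-degree-4
   bivariate polynomial (covers tilt plus $r^2$/$r^4$ spherical terms) over a
   sample-free background mask, subtracted everywhere. The default mask is
   four corner rectangles of 12% × 12% of the frame, inset 8 px from the
   border: FFT demodulation rings at the periodic frame boundary, so
   background statistics are taken slightly inside it; 12% per side keeps the
   mask above the 5%-of-frame support the fit requires. The method needs no
   knowledge of the specimen, only of sample-free regions. Compensation runs
   after unwrapping; the residual carrier is small enough after refinement
   that the order does not matter in practice.
6. **Background subtraction** — plane fit over the background ROIs plus a
   median offset, so the background sits at 0 rad; then optionally
   $t = \varphi \lambda / (2\pi \Delta n)$ to physical thickness.

Numerical accuracy: on a noise-free 10 µm sphere ($\Delta n$ = 0.05) the
recovered peak thickness is within ~1% of truth. Pointwise phase RMS inside
the dome is limited to ≈0.05 rad by the diffraction ringing of the hard-edged
coherent pupil itself (the band-limited optical image differs from the
geometric phase by that much), plus a comparable quantization contribution
when the fringe amplitude is only a few gray levels (laser at 0.4 mW); tests
therefore bound the end-to-end error at 0.08 rad against the band-limited
optical image and 0.1 rad against geometric truth, at full hologram contrast.
The outermost ~1 µm annulus of a 10 µm sphere carries phase gradients beyond
any passband at NA 0.40 and is excluded from pointwise comparisons.

## Bright-field recovery

The central band (default radius equal to the cross-band radius — symmetric
bands — shrunk if the carrier sits closer than two radii to DC) yields
$|A|$ with $A = O^2 + R^2 + \mathrm{BFI}$; the cross-band magnitude $B$ is on
the same gray scale because both come from the same spectrum, with no
renormalization. The recovered BF image is the weighted subtraction

$$ \mathrm{BFI} = |A| - w\,B, \qquad w \in [0, 1], $$

clipped at zero to guard against noise-induced negatives. The weight is chosen
by minimizing the population standard deviation over declared sample-free
background ROIs on a grid (default 0–1, step 0.05; ties break toward less
subtraction). The STD-versus-$w$ curve is concave-up with an interior minimum
whenever the coherent contribution is appreciable, and the optimal weight
grows with laser power — at the reference illumination (0.4 mW laser, 30 mW
LED) the simulated optimum lands at $w \approx 0.1$.

## Characterization sweeps

`sweep_laser()` (0.2–2.0 mW in 0.2 mW steps at fixed LED power) and
`sweep_led()` (3–30 mW in 3 mW steps at fixed laser power) synthesize one
capture per power × replicate (row seeds are `base seed + power index`, logged
in the table), demultiplex both modes, optimize $w$, and record background
metrics plus ordinary least-squares trend lines with Pearson r.

STD metrics for BF and for the laser-only intensity are *display-normalized*:
`STD × 180 / ROI mean`, i.e. noise after rescaling each image so its
background sits at the nominal full-LED level. Absolute gray-level STDs cannot
reproduce the reported illumination trends (the coherent disturbance is
LED-independent and shot noise grows with LED power), whereas images compared
at a common display brightness do: normalized BF noise falls monotonically
with LED power and rises with laser power, QPI background noise is flat in LED
power to within a few percent, and degrades sharply only at the lowest laser
power, where the hologram contrast is too weak for reliable unwrapping. The
raw STDs are kept in the table (`bf_std_raw`, `dhm_std_raw`) alongside.

Default study sizes: 512 × 512 frames, 10 power levels, 3 replicate seeds —
about half a minute per sweep on one CPU; the full 1936 × 1216 preset remains
available. The number of replicates per power is configurable (the sweep takes
a seed vector) since no canonical replicate count exists.

## Degenerate inputs and tie-breaks

* Carrier at DC (zero tilt) or below the detection ratio: hard error naming
  the cause; sweeps record the row as `carrier_ok = FALSE` and continue.
* `optimize_w` ties: smallest weight wins (least subtraction).
* Central-band radius is validated against `|carrier| − cross radius` (the
  default symmetric radii meet this bound with equality, accepted to
  tolerance).
* `phase_to_thickness` refuses $\Delta n = 0$.
* Unwrapping is total: any wrapped input yields a congruent surface; quality
  is reported via the residue count rather than failure.

## Known limitations

* The scalar incoherent BF model gives no edge contrast for pure-phase
  objects; mildly absorbing phantoms (transmittance 0.9) stand in for the
  visibility that real spheres gain through scattering outside the NA.
* Strongly absorbing scenes put bright-field spectral energy under the cross
  band (the incoherent support is twice the coherent one, while the carrier
  sits between), degrading QPI near high-contrast BF structure at low
  hologram contrast — a genuine limitation of single-capture multiplexing,
  not of the implementation.
* Absolute instrument numbers (fit coefficients of weight and noise trends,
  absolute gray-level STDs) are specific to one physical setup and are not
  reproduction targets; the package reproduces the geometry, the closed
  forms, and the qualitative power laws.
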