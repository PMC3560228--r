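---
title: "Automated functional capillary density from microcirculation video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated functional capillary density from microcirculation video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdens)
```

## The measurement problem

Sidestream dark field (SDF) and orthogonal polarization spectral imaging
illuminate mucosal tissue with green light near 550 nm. Hemoglobin absorbs
at that wavelength, so red blood cells appear dark on a bright tissue
background; a capillary is visible exactly where red cells are. Functional
capillary density (FCD) — the fraction of the observed tissue area (or the
skeleton length per area) occupied by capillaries that actually carry
flowing blood — is a standard readout of tissue perfusion, and falls under
hemorrhage and shock. `capdens` implements a fully automated analysis of
such recordings: stabilization, capillary segmentation, flow classification
and FCD, plus a phantom generator so every stage can be validated against a
known ground truth, and paired statistics for baseline-versus-condition
study tables.

## Pipeline

`analyze_video()` runs, in order:

1. **Stabilization** (`stabilize()`). Handheld probes shake; motion is
   modelled as per-frame integer translation. Control points are the
   per-tile maxima of a 3×3 Laplacian applied to the Gaussian-derivative
   gradient magnitude (`sigma` = 1.5 px): distinctive, typically
   vessel-branch-like structure. The frame is split into a 3×3 grid and the
   top 7 tiles provide one point each. Each point's 25×25 patch is matched
   by zero-mean normalized cross-correlation inside a 40×40 window in the
   next frame (integer offsets in ±7 px); the frame shift is the most
   frequent of the 7 displacements (ties to the smaller shift). Plurality
   is used rather than the median because control points that land on
   flowing cell columns track the flow: such points disagree with each
   other across vessels while points anchored on static tissue agree
   exactly, so the mode stays put even when several points straddle moving
   structure. Points are advected by the estimated shift and fully
   re-seeded when one drifts too close to a border or the estimate
   saturates the search radius. Frames are aligned by their cumulative
   shifts with edge replication; downstream analysis is restricted to the
   rectangle common to all aligned frames. A scene whose only
   high-contrast features move with the flow cannot be stabilized by any
   block matcher — there is nothing static to lock onto — so phantom
   validation of this stage uses scenes with static texture.

2. **Temporal averaging** (`weighted_mean()`). Each of the 20 analysed
   frame positions receives the weighted mean of the five surrounding
   frames, weights (1, 2, 3, 2, 1)/9, windows clamped at the sequence ends.
   Averaging improves vessel connectivity (cell columns fluctuate);
   averaging many more frames would smear moving cells into the plasma
   gaps and erase the very signal the flow classifier needs.

3. **Threshold schedule** (`build_schedule()`). Segmentation probes each
   averaged frame at 10 threshold levels. Level `k`'s threshold is the
   `q_k` quantile (defaults 0.10, 0.15, …, 0.55) of the pooled histogram of
   that level's own preprocessed training frames (up to 3 frames of the
   recording, evenly spaced). Computing the quantile after the level's
   CLAHE/median/stretch chain matters: CLAHE reshapes the histogram, so a
   quantile taken beforehand lands at an arbitrary fraction afterwards.
   With per-level quantiles the lowest level admits only the darkest ~10%
   of pixels — the wide, clear vessels — while the highest admits about
   half the image, vessels and background alike, exactly the regime the
   pixel verification is designed to prune. CLAHE tiles grow
   (8→64 px, clip limit 0.01) and median kernels shrink (7→3 px) with the
   level, so low levels are smoothed hard and high levels retain thin
   faint vessels.

4. **Per-level segmentation** (`segment_frame()`). For each level:
   contrast-limited adaptive histogram equalization, exact median
   smoothing, percentile stretch (1st/99th → 0/1), binarization (vessels
   are dark: foreground ⇔ intensity ≤ threshold), then pixel verification:

   - the exact Euclidean distance transform (`edt()`) gives every pixel its
     nearest background pixel (ties broken to the smaller row, then
     column);
   - for a candidate `p`, `b_p` is its nearest background pixel and
     `b_1..b_24` those of its 5×5 neighbours; the local diameter is
     `d = max_j ||b_p − b_j||` with argmax `b_max`; the angle at `p` in the
     triangle `(b_p, p, b_max)` is computed by the cosine rule with
     opposite side `d` (cosine clamped to [−1, 1] — evaluating the angle at
     non-extremal `b_j` can push the cosine outside the valid range, so
     only the `b_max` form is always well defined); the contrast ratio is
     `C = max_j GL(b_j)/GL(p)` on the CLAHE image;
   - `p` verifies iff `d < P_d` (13 px ≈ 20 µm: excludes venules and larger
     vessels), `theta > P_θ` (130°: enforces that the two background pixels
     lie on opposite sides of a thin band) and `C > P_C` (1.17: rejects
     low-contrast noise);
   - verified pixels with fewer than 2 verified 8-neighbours are dropped:
     vessel centerlines verify as contiguous chains, while noise produces
     isolated hits, and each isolated hit would otherwise stamp a disk far
     larger than what a radius-1 opening can later remove;
   - the vessel body is reconstructed as the union of disks of radius
     `floor((d − 1)/2)` centred at the midpoints of `(b_p, b_max)` — the
     local vessel-centre estimate the diameter actually spans. Centring at
     `p` itself would dilate every vessel by about half its width per side,
     because verified pixels cover the band interior, not only the
     centerline.

   The 10 per-level reconstructions are combined by a 2-of-10 vote
   (`min_level_votes`): levels probe with different CLAHE tile sizes and
   phases, so requiring agreement of two levels suppresses single-level
   noise and tile-offset width inflation; `1` gives the plain union.
   Isolated interior holes are filled and the mask is opened with a
   radius-1 disk.

5. **Frame combination** (`combine_frames()`). A pixel is vessel when
   segmented in more than a quarter of the per-frame masks
   (`floor(n/4)+1`; 6 of 20). The underlying rule — "segmented in more
   than one frame" — was formulated for temporally disjoint five-frame
   block means, where it equals more than a quarter of the masks; with
   sliding windows, adjacent masks share four of five frames and any
   one-off detection is echoed by its neighbours, so a literal vote of 2
   would be vacuous.

6. **Refinement** (`morph_postprocess()`, `region_grow()`). Bridge
   (connect neighbours not 8-connected within their 3×3 neighbourhood),
   fill isolated interior pixels, three passes of spur removal; then
   orientation-guided growth: in each 35×35 window the vessel orientation
   is the principal axis of the foreground second-order central moments
   (undefined below 10 vessel pixels or for isotropic moments), and
   endpoints grow along ±orientation one pixel at a time while the gray
   level stays within mean ± 0.5 SD of the window's vessel pixels, at most
   10 steps.

7. **Flow classification and FCD** (`activity_map()`, `classify_active()`,
   `fcd_area()`, `fcd_length()`). Transitions count per-pixel segmentation
   flips between consecutive masks. A pixel is flow-positive when it is
   vessel in the combined mask and flipped at least `t_flow = 2` times —
   it disappeared and reappeared, one full plasma-gap passage. Because
   perfusion is a property of a vessel, not a pixel, each 8-connected
   component of the combined mask is kept or dropped wholly by whether at
   least half its pixels are flow-positive (`component_vote`; disable for
   the literal per-pixel rule). Area FCD is the active percentage of the
   region of interest (the stabilized common rectangle minus the 2-px
   verification margin); length FCD skeletonizes the active mask
   (topology-preserving thinning) and counts 1 per axial step and √2 per
   diagonal step, scaled by the pixel pitch (default 20/13 ≈ 1.54 µm/px,
   from the 13-px diameter cap corresponding to ≈ 20 µm).

## The phantom generator

`phantom_spec()` / `render_sequence()` emulate what an SDF camera sees,
with per-vessel ground truth:

- **Geometry.** Curvilinear capillaries (piecewise-quadratic curves through
  random control points with curvature-limited turning), widths uniform in
  3–9 px, laid down by rejection sampling so distinct capillaries keep a
  2-px clearance — perfusion is a per-vessel label, so ground-truth tubes
  must not blend. The default vessel count scales with the field of view
  to hold the perfused area fraction near the healthy sublingual regime
  (~12–14%).
- **Optics.** Background tissue at 0.8; red cells at 0.35. Cells deform to
  fill the capillary lumen (single-file flow), so the rendered disks span
  the tube width and a dense column has exactly the static tube boundary
  as its silhouette. Plasma between cells does not absorb at 550 nm, so
  inter-cell gaps are rendered at the background level: a perfused vessel
  is visible only through its cell content. Non-perfused vessels hold a
  stagnant column at 0.55 — statically dark. A uniformly dark, unchanging
  lumen is indistinguishable from stagnant blood, and the temporal rule
  correctly calls it no-flow.
- **Flow.** Cell columns advect at 4 px/frame nominal (~150 µm/s at the
  default pixel pitch, a typical capillary red-cell speed), with per-vessel
  speeds at 0.9–1.2× (velocities are heterogeneous in vivo). Cells are
  spaced 7 px (below the effective cell length: the column is
  quasi-continuous) and the column carries 30-px plasma-gap windows every
  55 px of arc. These numbers satisfy two competing constraints that any
  flow phantom for this method must respect: a gap must outlast the ±2
  frame temporal averaging and the disk reconstruction's bridging
  (length ≥ 4·speed + width + 2), yet a full gap cycle must pass every
  pixel within the 20 analysed frames (period ≤ ~13·speed) so each
  perfused pixel flips at least twice.
- **Nuisances.** Additive Gaussian sensor noise (SD 0.02), optional global
  translational jitter (explicit per-frame shifts or a random-walk
  amplitude), optional static tissue texture and optional soft-edged
  venules (wider than `P_d`). Texture and venules default to off: a flat
  region whose intensity is crossed by a threshold level produces
  kernel-scale speckle that is geometrically indistinguishable from a
  capillary, and if the region is static it flickers under sensor noise
  and is then misread as flow. This is a genuine limitation of binary
  temporal differencing, not of the phantom: an in-vivo venule interior
  carries fast flow and is equally pathological for the rule; the
  published analyses relied on the diameter cap plus visual assessment.
  The geometric large-vessel exclusion itself is exercised directly by
  wide-band tests. Stabilization test scenes set `texture_sd > 0`
  explicitly to provide trackable static structure.

`true_fcd()` computes the reference values from the ground-truth perfused
tubes and analytic centerline lengths with the same formulas the pipeline
uses.

## What phantom validation does and does not show

On phantoms the pipeline recovers perfusion topology reliably: perfused
vessels are detected with pixel recall around 0.9, stagnant vessels are
classified inactive, and baseline versus half-perfusion phantom pairs
separate in the expected direction in 9 of 9 pairs at 240×320. The area
estimate, however, carries a positive boundary bias of roughly 1–2 px per
vessel side: the high threshold levels deliberately admit "almost all
vessels and background", the vessel-adjacent noise fringe merges into the
band and inflates the measured diameter, and the level and frame votes
retain near-widest evidence. On 3–9 px phantom vessels this is roughly +10% to +40% relative area
depending on the seed; at ~20 µm real vessels, and for
within-study contrasts (the baseline-versus-hemorrhage separation that is
the method's purpose), the bias is immaterial because it applies to both
arms. Length-based FCD is insensitive to it by construction. The phantom
also does not emulate depth blur, uneven illumination, pressure artifacts,
or capillary recruitment dynamics.

## Numerical and interface choices

- Frames are numeric matrices in [0, 1], `(row, col)` indexed, normalised
  by the container's representable maximum so thresholds are comparable
  across frames; RGB input reduces to the green channel (550 nm carries
  the contrast), with a luma override.
- The EDT is exact, with a distance cutoff option (`max_dist`) for
  pipeline use: verified capillaries have centre distances below
  `P_d/2 + 1`, so a cutoff of 32 px changes nothing while bounding work on
  background-heavy levels. Distances below the cutoff remain exact.
- The median filter is exact (a 16-bit-quantizing implementation would
  break the brute-force oracle tests); CLAHE is delegated to a standard
  tile-interpolated implementation, with the image padded by edge
  replication to a tile-divisible size and the conventional normalized
  clip-limit parameterization.
- Degenerate inputs are defined, not accidental: constant frames warn and
  pass through the stretch unchanged; a blank video yields FCD 0; an
  all-foreground mask is a no-background error unless a cutoff is given;
  `GL(p) = 0` makes the contrast ratio +∞ (the pixel passes that test);
  stabilization failure downgrades to an unstabilized analysis with a
  warning.
- Everything is deterministic for fixed inputs; the generator is
  bit-reproducible under a fixed seed with an isolated RNG stream.
- Problem sizes in the shipped tests and the analysis script are chosen to
  exercise every stage at meaningful scale: phantom validation runs at
  240×320 px with 24-frame videos and 20 analysed frame positions, the
  EDT oracle on 20×20 masks, stabilization on 160×220 textured scenes.

## Statistics module

`paired_t()` implements the paired t-test in closed form
(`t = mean(d)/(sd(d)/sqrt(n))`, two-sided p from the t distribution);
`summary_stats()` the mean and n−1 standard deviation; `bland_altman()`
the bias and 1.96·SD limits of agreement with per-pair points for
plotting. The package ships two per-subject FCD tables (nine swine,
healthy baseline versus 40% hemorrhage; area-based in percent and
length-based in mm/mm²) as CSV fixtures: `fcd_table_automated.csv` from
the fully automated analysis and `fcd_table_semiauto.csv` from the
manually edited commercial reference software. The automated table's
area-based columns give t(8) = 6.50, p ≈ 1.9×10⁻⁴; the semi-automated
table gives t(8) = 4.19. Two-sidedness is fixed by the printed
p-value/t-statistic pair.
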