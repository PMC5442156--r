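---
title: "mitoscreen: models and methods"
author: "mitoscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

# The assay being modelled

`mitoscreen` models a high-content time-lapse RNAi screen for cell-division
phenotypes. A custom siRNA library against 638 cancer-deregulated lncRNA
targets (up to five siRNAs each, more than 3,100 siRNAs in total) is
distributed over multi-well plates; each plate carries duplicated positive
viability controls (siRNAs against COPB2, KIF11 and PLK1), duplicated
non-targeting negative controls (NC A, B and D), empty wells and
mitotic-defect controls. Wells are seeded with 850 HeLa cells expressing
H2B-mCherry (chromatin, red) and GFP-alpha-tubulin (green) and imaged every
30 minutes from 4 to 72 hours post-transfection (137 frames).

The screen's readout is the **MitosisCount**: the number of mitotic events
per well over all time points, counted whenever one nuclear track splits
into two. Wells are normalized per plate with a robust z-score and hits are
called by fixed rules on z-scores and ordinal manual phenotype scores. A
validation round re-screens all hits on fresh plates, normalized to the
negative-control median (raw/mnc). Knockdown of mitosis-linked transcripts
produces a prometaphase arrest lasting up to ten hours, resolved by mitotic
death, mitotic exit (slippage) or cytokinesis failure, alongside early
direct apoptosis unrelated to arrest.

The package provides the full chain as testable code: a generative model of
wells and movies, segmentation, tracking and split detection, plate scoring
and hit calling, cell-fate classification, and scoring of RNA-pulldown
proteomics for the downstream interactome stage.

# The generative model

## Cell population dynamics

Each well is a branching process. Every interphase cell waits an
exponential time with hazard $r$ (events/cell/hour) to its next mitosis, in
competition with a small constant interphase-death hazard. A normal mitosis
dwells 0.6–1.4 h (about one hour, the normal mitosis duration) and ends in
a division that replaces the mother with two daughters. A knockdown
phenotype acts only after a penetration delay:

* **viability** class: the mitosis hazard is multiplied by $1 -
  \mathrm{effect}$ after the delay;
* **mitotic_arrest** class: a mitosis entered after the delay arrests with
  probability equal to the effect, dwells uniformly on $(2, 10]$ hours (the
  arrest can last up to ten hours), and resolves by mitotic death, mitotic
  exit or cytokinesis failure in the proportions of the arrest components
  of the fate mixture.

Defaults, chosen once and used everywhere:

| parameter | default | rationale |
|---|---|---|
| baseline mitosis hazard $r$ | 0.029 /cell/h | $\ln 2 / 24\,\mathrm{h}$, a typical HeLa doubling time |
| seeded cells per well | 850 | the assay's seeding density |
| penetration delay | 12 h | phenotypes penetrate late; they are strongest tens of hours after transfection |
| positive-control effect | 0.85 (multiplier 0.15) | a strong viability knockdown |
| interphase-death hazard | 5e-4 /cell/h | small background attrition |
| fate mixture | 42 / 28 / 5 / 25 % | mitotic death / mitotic exit / cytokinesis failure / direct apoptosis among phenotypic cells |
| arrest duration | Uniform(2, 10] h | only the 10 h cap is grounded; the law below the cap is our choice |
| direct-apoptosis time | Uniform(12, 24) h | direct apoptosis occurs early, between 12 and 24 hours |

Two simulators expose this model:

* `simulateWell()` is the event-level simulator: it produces a
  `CellEventLog` whose per-cell sequences obey the grammar
  `birth -> (mitosis_entry -> outcome)* -> optional interphase_death`,
  validated on construction, with division conservation (every division
  emits exactly two daughter births).
* `simulateWellCounts()` is the plate-scale fast path: it draws per-well
  division totals directly from the law of a linear-birth (Yule) process
  with a rate change at the penetration delay — births over an interval,
  given the population at its start, are negative binomial — vectorized
  over thousands of wells. Because the event-level simulator additionally
  occupies cells for about an hour per mitosis, its 68-hour totals run some
  20–25% below this idealized law; plate-level statistics only ever compare
  wells drawn from the same law, so this difference does not affect them,
  and the distinction is documented rather than hidden.

`assignFates()` generates phenotypic single-cell sequences directly from
the fate mixture (arrest entry uniform between 20 and 60 h), which is the
natural input for fate-classification studies where population dynamics are
irrelevant.

## Movie rendering

`renderMovie()` turns an event log into two-channel frames. Nuclei are
Gaussian blobs (sigma = half the nucleus radius, convolved with the PSF);
mitotic chromatin renders condensed (0.75x radius, brighter); newborn
daughters render compact for their first hour (re-forming telophase
nuclei); dying cells fragment into 3–5 small blobs for an hour and vanish;
a division replaces the mother with two daughters born two nucleus radii
apart. Motion is a per-frame Brownian walk with two physical constraints:
hard-core volume exclusion (nuclei repel below two radii — real nuclei
cannot interpenetrate) and reflecting walls 2.5 radii inside the frame
border, so nuclei neither render truncated at the edge nor pile up on the
boundary. The tubulin channel is decorative and is not segmented.

What the renderer does **not** emulate: photobleaching, illumination
gradients, focus drift, debris, three-dimensional motion, and
densities approaching confluence. Tests passing on these movies therefore
demonstrate the analysis pipeline's correctness on well-behaved input, not
robustness to every imaging pathology of a real screen.

# The analysis pipeline

## Segmentation

`segmentNuclei()` is the standard intensity pipeline for uniformly
illuminated frames: Gaussian smoothing (sigma 2 px), a global Otsu
threshold on the min–max normalized frame (making the mask invariant to
intensity rescaling), a distance-transform watershed to split touching
nuclei, and an area filter at 25% of the nominal nucleus area — small
enough to keep condensed mitotic chromatin, large enough to drop apoptotic
fragments, which are instead recovered as track terminations. Two
numerical choices matter:

* the watershed tolerance is 0.5 px: the distance-map saddle between two
  daughter nuclei sits less than 1 px below their maxima, so the
  conventional tolerance of 1 px would leave daughter pairs merged;
* a global threshold always "finds" structure in a signal-free frame, so a
  purely multiplicative contrast gate (above-threshold mean less than 1.5x
  the below-threshold mean) returns an empty mask for blank frames without
  breaking scale invariance.

Touching pairs are resolvable down to about 1.2 nucleus radii of center
separation for disc-like profiles; Gaussian-profile pairs merge below
roughly 1.6 radii because their union mask becomes a single convex lobe —
one reason the renderer enforces a two-radius exclusion.

## Tracking and MitosisCount

`linkTracks()` links objects frame to frame by greedy mutual nearest
neighbours within a gating radius (default 4 px: several sigma above the
per-frame Brownian displacement, yet below the separation at which
daughters appear, so a dividing mother's track *ends* instead of continuing
into one daughter). Tracks survive a single-frame dropout (`maxGap = 1`);
a gap-bridging link is rejected if the candidate object is more than 1.7x
the track's last area, because an object that doubles across a dropout is a
merge of touching nuclei, and bridging onto it would resurrect the track of
an already-divided mother. Global assignment is deliberately not used: at
the simulated densities mutual nearest neighbours are unambiguous and the
greedy linker is transparent.

`detectSplits()` emits a mitotic event when a track ends at frame $f$ and
at least two new tracks begin within the next two frames (1 h), inside a
radius of two nucleus radii of the parent's end. Each candidate daughter is
first attributed to its *nearest* eligible ending track, so simultaneous
nearby divisions cannot steal each other's daughters; ties break by
distance then track id, making daughter assignment deterministic.
`mitosisCount()` is the number of events — the well's MitosisCount.

On ten default small movies (256 px, 33 frames, 20 seeded cells, hazard
0.05/h) split detection reaches recall 0.98 and precision 0.97 against
the rendering ground truth, where recall is measured over divisions
occurring at least two frames before the movie ends (later ones cannot yet
show two daughters) and events are matched to divisions within a two-frame
window, with distance used only to break ties — rendered cells drift away
from their event-log anchor coordinates, so a tight positional gate would
reject legitimate detections.

## Plate scoring and hit calling

`robustZ()` implements the plate normalization
$$z = \frac{\mathrm{median}(\mathrm{samples}) - x}
           {1.4826 \cdot \mathrm{MAD}(\mathrm{samples})},$$
with the median and MAD taken over the plate's *sample* wells only
(controls excluded) and the MAD scaled for normal consistency. The sign is
deliberately oriented so that a *reduced* MitosisCount gives a *positive*
z: positive viability controls, which suppress mitosis, then score $z \ge
2$. A zero MAD is an explicit error, and at least five sample values are
required for the normalization to be meaningful. The validation screen
instead uses `rawOverMnc()` — the raw MitosisCount divided by the median of
the plate's negative controls — because a validation plate carries only
pre-selected hits and its sample median is biased by construction.

Hit rules, exactly as stated and with the z cutoff read inclusively
($z \ge 2$):

* bioinformatic hit: at least two siRNAs with $z \ge 2$;
* manual hit: at least three siRNAs with manual score $\ge 3$, or at least
  two with score $\ge 4$;
* validated: at least two of the *same* siRNAs that had an effect in the
  primary screen (counted toward either rule, i.e. $z \ge 2$ or score
  $\ge 3$) show raw/mnc $\le 0.8$ or a manual score $\ge 3$ in the
  validation screen. The validation sentence is ambiguous about whether the
  manual criterion needs its own two siRNAs; we read the OR per siRNA and
  require two qualifying siRNAs overall.

Both calling functions are verified against brute-force subset-enumeration
oracles over the exhaustive five-siRNA input space. Manual scores are
synthesized from the latent effect by the ordinal link
`clamp(round(1 + 4*effect + eps), 1, 5)` with Gaussian noise — the real
screen's scores are human judgements; this link is our model of them.

## Fate classification

`classifyFate()` scans each cell's sequence for its first mitosis whose
in-mitosis time exceeds the arrest threshold (default 2 h, twice the ~1 h
normal duration; no numeric arrest cutoff is part of the assay definition, so this is a
declared surrogate, exposed as a parameter). The resolving event names the
fate; an interphase death without prior arrest is direct apoptosis; short
mitoses ending in division are normal; unresolved arrests at the end of
observation are `other` and excluded, like normals, from the phenotypic
denominator of `fateProfile()`. On noiseless generator output the
classifier reproduces the generating label exactly (identity confusion
matrix), and the mixture is recovered at the binomial rate at n = 500,
2,000 and 10,000.

## Pulldown proteomics

`computeIbaq()` implements intensity-based absolute quantification: summed
peptide intensities divided by the number of theoretically observable
tryptic peptides. `enrichedProteins()` scores target versus the mean of
the control pulldowns by a pseudocount-stabilized log2 ratio
(pseudocount 1, cutoff 1 log2 unit, detection in the target required); no
canonical rule exists for calling an enriched set in this assay, so these
thresholds are our parameterized surrogate and are flagged as such. `termEnrichment()` is
a hypergeometric over-representation test with Benjamini–Hochberg
correction, verified against exhaustive enumeration of all draws for
universes up to 12.

# Pipeline driver and formats

`runScreen()` drives library -> plates -> phenotypes -> counts -> scores ->
calls -> summary, with stage-tagged errors and a manifest recording the
seed, the fully resolved configuration and its hash. Three execution paths
trade realism for speed: `fast` (count law; full screens in seconds),
`events` (per-well event logs) and `full` (render + segment + track; tiny
screens). The event-level and imaging paths agree on MitosisCount within
5% on default movies. All tables are tab-separated text with a
schema-version header line; movies are multi-frame 32-bit float TIFF
stacks, one per channel; configurations are flat key-value YAML documents
that reject unknown keys. All randomness derives from one user-visible
seed; per-well streams are derived by a stable hash of (plate, well).

The plate format is not fixed by the assay description; the default is
384-well (16 x 24) with one empty well per plate, configurable. The layout
of the mitotic-defect control wells is likewise unstated; we place three
duplicated `MITOTIC_CTRL` wells per plate without claiming fidelity.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script use deliberately moderate problem
sizes — 20 plates of 384 wells on the fast path, 2,000 phenotypic cells for
fate recovery, two 256-px/33-frame movies for tracking benchmarks — chosen
so the whole suite completes in a couple of minutes while keeping every
statistical tolerance at three binomial standard errors or better. Scaling
any of them up is a matter of changing one argument.

# Known limitations

* The fast path's count law idealizes mitosis as instantaneous; absolute
  division totals differ from the event-level simulator (documented above).
* The greedy linker is not a global assignment; at densities well above
  the defaults (or under motion much faster than the default Brownian
  step), identity switches would rise.
* Mitotic-phase *morphology* (prometaphase vs metaphase) is not classified
  from images; phase semantics live at the event-log level.
* The manual-score model is an ordinal link with Gaussian noise, not a
  model of human raters.
* The pulldown enrichment rule is a surrogate; no attempt is made to
  reproduce any specific published protein list.
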