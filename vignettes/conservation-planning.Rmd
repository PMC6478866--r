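---
title: "Methods: in situ conservation planning for crop wild relatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in situ conservation planning for crop wild relatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cwrinsitu` chains seven stages — synthetic-world generation, occurrence
quality control, presence–background distribution modelling, future-climate
ensembling, ecogeographic land characterization (ELC), protected-area gap
analysis, and reserve selection with site prioritization — into one
reproducible analysis for crop wild relative (CWR) conservation planning.
This vignette is the package's account of the science in each stage: the
models, their assumptions, the defaults and why they are what they are, and
what the synthetic ground truth can and cannot certify.

## The spatial abstraction

Everything lives on a flat Cartesian grid of square cells
(`grid_spec()`), indexed row-major by `cell_id`, with coordinates in km and
a default cell edge of 5 km — the resolution used in global CWR analyses.
Treating the grid as equal-area is deliberate: at this resolution the
analysis operates on cell counts (range sizes, coverage fractions, planning
units), and geodesic bookkeeping would add complexity without changing any
counted quantity. The package therefore performs no projection handling;
real-data users must supply layers already on an equal-area grid.

Rasters are tidy tibbles keyed by `cell_id` (`env_stack()` for multi-layer
environmental stacks, `range_map()` for binary species ranges, `pa_mask`
for protection). The on-disk contract is plain CSV — a long-format layer
table — rather than a binary raster format, which keeps every artifact
diffable and reproducible byte-for-byte.

## Synthetic worlds as ground truth

`simulate_world()` generates worlds with the statistical structure the
downstream analysis assumes, so each stage can be tested against known
truth:

* **Environmental layers.** 27 standardized variables split 9 edaphic /
  6 geophysical / 12 climatic (a plausible split of the variable inventory
  used at global scale; both the count and the split are configurable).
  Each layer is a Gaussian random field built by FFT convolution of white
  noise with a Gaussian kernel; the kernel sd is chosen so spatial
  correlation decays to 0.05 at the configured `autocorr_length_km`
  (default 50 km), which makes the practical variogram range equal the
  configured length — this is what the variogram-oracle test checks.
  `autocorr_length_km = 0` yields i.i.d. cells.
* **Niches.** True suitability is logistic in a few active variables
  (3 climatic, 1 edaphic, 1 geophysical by default, coefficients
  N(0, 1.5²)); the intercept is set so that ~15% of the species' native
  range lies at or above the s* = 0.5 suitability threshold. The true
  range is that cell set. Prevalence of 15% keeps ranges large enough to
  model yet leaves room for climate-driven contraction.
* **Occurrences.** Presences are multinomial draws over native-range cells
  with probability proportional to true suitability, jittered uniformly
  within the cell. Coordinate uncertainty is exponential with mean 3 km,
  capped at 10 km for clean records. Sample sizes follow a skewed mixture
  emulating real record availability (10% of species with 0 records, 20%
  with 1–9, 30% with 10–150, 40% with 300–600). Known-bad records are
  injected with truth flags — exact duplicates (10%), points outside the
  native range (5%), uncertainties in (10, 50] km (5%), missing coordinates
  (2%), non-target/cultivated flags (3%) — so the QC filters can be scored
  with exact precision and recall.
* **Protected areas.** A union of random compact blobs; a common radius
  multiplier is solved by a quantile so coverage matches the target
  fraction (default 15%) to within one cell.
* **Future climates.** Each of `n_future_realizations` (default 5;
  cluster-scale analyses have used 30 circulation models — the smaller
  default keeps desk-scale runs fast and is configurable) shifts every
  climatic layer by a realization-level mean draw
  (N(0.5, 0.2²) in layer-sd units) plus cellwise noise (sd 0.1), leaving
  edaphic and geophysical layers untouched. These magnitudes were fixed
  once to produce a realistic spread of true range losses, from none to
  near-total, across simulated species.

True range loss — `true_loss()` — compares the true current range with the
true range under the mean future stack. It is the recovery target for the
whole modelling chain.

What the generator does *not* emulate: observation bias (roadside or
herbarium-proximity sampling), taxonomic error beyond a boolean flag,
dispersal limits, interspecific interactions, and real covariance
structures between variable sets. Passing recovery tests therefore show
the chain is self-consistent — unbiased inputs in, truth out — not that it
is robust to the biases of real occurrence data.

## Occurrence quality control

`qc_clean()` applies filters in a fixed, audited order: non-target flag →
missing coordinates → outside native range → uncertainty strictly greater
than 10 km → exact-coordinate dedupe. Order matters for the per-species
removal accounting, which must reconcile exactly
(`raw = final + removals + duplicates`). Choices worth noting:

* The uncertainty rule is strict (`> 10 km`): a record at exactly 10 km is
  retained.
* Records with *missing* uncertainty are retained but counted separately
  (`n_missing_uncertainty`), making the choice auditable rather than
  silent.
* "Unique" means equal coordinates after rounding to the nearest metre —
  a reproducible dedupe that does not depend on grid snapping.
* A species with no native-range mask is flagged
  (`native_range_missing`) and its records dropped, never silently passed.

`assign_pathway()` routes species: ≥ 10 unique records → model; 1–9 →
50-km buffer fallback; 0 → excluded.

## Presence–background distribution models

The niche model is the maximum-entropy (Gibbs) distribution over background
cells subject to L1-penalized matching of presence feature means — the
convex program

$$\max_\eta\; \eta^\top \bar f_{pres} \;-\; \log \mathbb{E}_{bg}\,e^{\eta^\top f}\;-\;\beta\lVert\eta\rVert_1 .$$

* **Background** is a uniform sample without replacement of up to 10,000
  cells of the species' native range — the natural background extent, and
  the domain on which suitability is defined.
* **Features** are linear + quadratic terms of the VIF-screened variables,
  standardized against the background sample. Quadratics are the smallest
  feature class that lets the model express unimodal (niche-like)
  responses; hinge/product/threshold features are out of scope.
* **Screening**: `screen_vif()` iteratively removes the highest-VIF
  variable (recomputing jointly after each removal) until all
  VIF < 10. Ties (including infinite VIFs from exact collinearity) remove
  the variable latest in input order, keeping earlier variables — an
  arbitrary but deterministic rule. A single remaining variable has VIF
  defined as 1.
* **Optimization** is proximal gradient descent with backtracking; the
  stopping rule is the KKT residual of the penalized problem below 1e-6.
  The default penalty β = √(log p / n) scales like a lasso universal
  penalty with the presence count. When the presence feature mean lies
  outside the convex hull of background features the optimum is at
  infinity; the optimizer then stops at its iteration cap, warns, and the
  model is flagged — cross-validation treats any non-converged fold as
  inadequate.
* **Output scale**: suitability is the standard logistic transform
  `e^H q(x) / (1 + e^H q(x))` of the normalized Gibbs density `q`, where
  `H` is the entropy of `q` over the background. It is monotone in the
  linear predictor, so thresholds and AUC are unaffected by the choice.

**Adequacy.** `crossvalidate()` assigns presences to 5 seeded folds and
scores each fold's refit by AUC against the full background as
pseudo-absences. The adequacy rule — mean AUC ≥ 0.7 and fold-sd ≤ 0.15,
plus all folds converged — stands in for the standard adequacy criteria of
the modelling literature; the exact published cutoffs vary, so both numbers
are configurable. Inadequate models fall back to the buffer pathway exactly
as under-sampled species do. AUC against background is a relative measure
(background cells can be suitable), so it is used as a gate, not as a
performance claim.

**Thresholding.** `maxtrss_threshold()` scans every observed score
(training presences and background) as a candidate threshold and maximizes
sensitivity + specificity, with presences counted present at score ≥ t.
Candidates are observed values rather than a fixed grid, so the scan is
exact; ties go to the *smallest* threshold, i.e. the largest range — the
conservative direction for conservation planning. Training scores are used,
per the method's name.

**Futures.** Adequate models are projected onto each future realization;
the continuous projections are averaged cellwise, then binarized at the
current model's t* (mean-then-threshold, not threshold-then-vote). The
climate-stable range is the cellwise intersection of the current and
ensemble ranges. Buffer-pathway species have no future model: they are
carried into future-facing analyses unchanged (treated as
climate-invariant) and their loss fields are null — reported losses refer
to modelled species only.

## ELC maps and adaptive scenarios

`build_elc()` clusters each variable set (edaphic, geophysical, climatic)
independently with seeded k-means (10 restarts) on standardized
native-range cell values, then encodes the triple of cluster labels as one
composite integer category. A category is an "adaptive scenario": a
distinct environmental context within the species' range, used as the proxy
unit of potential genetic diversity. Defaults use k = 5 per set (at most
125 composite categories) in the building blocks and k = 3 per set in the
bundled pipeline, keeping desk-scale scenario counts interpretable; no
published k exists for this construction, so it is exposed as
configuration. Cells with missing data in any set get no category and are
excluded from every scenario count. Category labels are arbitrary;
downstream statistics only ever count categories, so relabeling changes
nothing.

ELC is built on baseline climate only. Future "genetic diversity loss" is
range-driven: scenarios present in the current range but absent from the
stable range.

## Gap analysis

Protected-area geometries are rasterized by the cell-centre rule (a cell is
protected iff its centre lies in a polygon; point geometries are dropped
with a logged count). Per species, `gap_analysis()` reports the
percentage of current range inside protected areas, projected 2070 range
loss, scenario coverage inside protected areas, and projected loss of
protected scenarios; a species is under-conserved when less than 50% of its
adaptive scenarios fall within protected areas, and flagged
"exclusively outside" at zero coverage. Because the share of species found
only outside protected areas has two plausible denominators (all listed
species vs assessed species), the pipeline report emits both. Crop-type
summaries average per-species values with genepool duplicates collapsed
within a type but kept across types; null losses (buffer species) are
excluded from loss means but the species still count. Headline percentages
round half-up to one decimal (or to integers where reports print integers)
— base R's banker's rounding would disagree with printed values at exact
halves.

## Reserve selection

`build_problem()` casts the minimum-set problem in Marxan's shape: planning
units are grid cells carrying any species×scenario combination; unit cost
is 10 inside and 50 outside protected areas (the cost differential is how
protected cells are prioritized — an optional hard lock-in was considered
and rejected as the stronger reading of an ambiguous prescription);
targets require ≥ 1 unit per combination at species penalty factor 1;
adjacency is rook-neighbour; the boundary length modifier (default 0.001)
multiplies the count of selected-unit edges facing unselected units or the
grid exterior (every unit has perimeter 4, in cell-edge units). Combinations
come from the climate-stable range when a valid future model exists, else
from the current range (full-loss and buffer species).

The penalty for an unmet combination is the cost of actually meeting it
with the cheapest single covering unit *including* that unit's full
boundary contribution (min cost + 4·BLM). A penalty of the bare unit cost
would make leaving a target unmet strictly cheaper than meeting it whenever
BLM > 0, which contradicts the design goal that penalties can always force
coverage; including the boundary term restores the guarantee that a
fully-covering optimum always exists.

`anneal()` runs independent chains of single-unit flip proposals under
geometric cooling (initial temperature adapted to the largest single-move
objective change), followed by a greedy repair pass that meets every
coverable target and a trim pass that removes units whose removal strictly
improves the objective without unmeeting targets. Runs are ranked by fewest
units, then lowest total unit cost, then lowest run index. The iteration
count is configurable; the bundled pipeline uses 100 runs of 10,000
iterations, ample for thousands of units at desk scale (production
configurations elsewhere have used 10⁸ iterations on clusters). The
annealer's incremental objective is verified in tests against
`reserve_objective()`, an independent from-scratch recomputation, and
against exhaustive 2ⁿ enumeration on small instances.

## Prioritization

`greedy_rank()` orders the chosen network's units by complementarity:
highest combination richness first, then whichever unit adds the most
uncovered combinations. Pragmatic mode restricts to protected-area units
until none adds coverage, then continues outside — so every productive
protected site precedes every outside site, and outside sites enter only
for combinations not represented inside protected areas. Ties break by most
new species added, then lowest unit id (a deterministic rule; the published
method does not specify one). Ranking stops when no unit adds coverage, so
final coverage equals the coverable universe in either mode — a property
the tests assert. Only units inside the top-ranked annealing solution are
ranked. `top_sites()` slices the first 100 protected and first 50 outside
sites by default; `headline_stats()` reports combined unique species and
combinations for any slice as set unions, with printed rounding.

## Numerical choices and degenerate inputs

* All generators and solvers are pure functions of (configuration, seed);
  stage seeds derive from one root seed via fixed substreams. Temporary
  seeding restores the caller's RNG state.
* MAXTRSS with identical scores everywhere returns that score with a
  warning; empty score sets are errors.
* Thresholds above every suitability give an empty range with a warning;
  an empty current range makes stability/loss undefined (error).
* k-means with k exceeding the number of distinct cell profiles is an
  error; k = 1 is a single category.
* An empty protected-area input yields an all-zero mask with a warning;
  coverage of an empty range is `NA`, never 0.
* Combinations occurring in no planning unit are reported and dropped with
  a warning, never silently.
* Removing the future-climate inputs degrades the pipeline to current-only
  mode: loss fields are null and selection runs on current ranges.

## Problem sizes

The test suite and acceptance script run entirely on synthetic worlds: unit
tests mostly on 2×2 to 60×60 grids; oracle comparisons on 100–200 random
instances per algorithm (annealing instances ≤ 15 units so 2ⁿ enumeration
is exact); ground-truth recovery on a 100×100-cell world with 20 species of
400 records each and 5 future realizations; and the bundled end-to-end
world at 60×60 cells with 20 species. These sizes were chosen as the
smallest at which every statistical property under test is comfortably
identifiable.

## Known limitations

* Environmental distinctiveness is a proxy for genetic diversity; the
  package inherits that assumption from the underlying methodology and
  cannot validate it — molecular data would be required.
* The MaxEnt feature set is linear + quadratic only; no hinge/threshold/
  product features or clamping.
* Buffer-pathway species are climate-invariant by construction, which
  understates risk for poorly-recorded species.
* The equal-area flat grid ignores geodesy; inputs must be pre-projected.
* Adequacy cutoffs (AUC ≥ 0.7, sd ≤ 0.15) and k per ELC set are
  conventions, not published constants; both are configuration, and
  conclusions can be sensitivity-checked across them.
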