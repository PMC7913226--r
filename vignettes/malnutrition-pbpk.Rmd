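---
title: "Translating whole-body PBPK models to malnourished pediatric populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating whole-body PBPK models to malnourished pediatric populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Severe acute malnutrition changes body composition — organ masses, fat and
muscle stores, blood volume, hematocrit, plasma proteins — and through them
the disposition of drugs. Controlled pharmacokinetic trials in malnourished
children are rare, so dosing guidance must usually be extrapolated.
`malnpbpk` implements a physiologically-based bridge: it starts from a
whole-body PBPK model of a healthy (reference) individual, applies pediatric
scaling through an age-resolved reference-physiology grid and enzyme
ontogeny, and then applies a set of *physiological scaling parameters*
(PSPs) — per-compartment multiplicative factors derived from adult
body-composition studies of malnutrition — to turn each non-malnourished
virtual individual into a mild, intermediate or severe malnutrition state.
Virtual trials on matched arms (the same individuals before and after
scaling) then isolate the pharmacokinetic consequence of malnutrition
itself, e.g. as the fold deviation (FD) of median AUC under flat versus
body-weight-adjusted dosing.

## The whole-body model

The disposition model is a standard perfusion-limited whole-body PBPK
structure: 14 organs/tissues (bone, brain, fat, gonads, intestines, lung,
stomach, heart, kidney, liver, muscle, pancreas, skin, spleen) connected by
arterial, venous and portal blood pools. The lung sits in series with the
circulation; the stomach, intestines, pancreas and spleen drain into the
portal vein and thence through the liver. Cardiac output is defined as the
sum of compartment blood flows excluding the lung, and each flow is
parameterized as specific perfusion (L/h per kg tissue) times compartment
mass — so any scaling of organ masses propagates linearly into organ blood
flows and cardiac output.

Each organ is a well-stirred compartment with a tissue:plasma partition
coefficient $K_p$ predicted from tissue composition by one of three
methods:

* **Rodgers–Rowland**: moderate-to-strong bases (basic p$K_a \ge 7$)
  partition into acidic phospholipids with an association constant anchored
  on blood-cell partitioning; acids, neutrals and weak bases get an
  extracellular albumin term driven by $1/f_{u,p} - 1$. Neutral lipid in
  adipose uses the vegetable-oil:water scale
  ($\log P_{vo:w} = 1.115 \log P - 1.35$), octanol elsewhere.
* **Tissue-composition standard** (`pksim`): lumped water/lipid/protein
  partitioning with lipid affinity $10^{\log P}$ and a protein affinity
  back-calculated so plasma reproduces the measured $f_{u,p}$.
* **Schmitt-type**: as the standard method with the membrane affinity of
  the ionized species attenuated to 5% of the neutral species.

Erythrocytes are handled through a constant whole-blood:plasma ratio
$B\!:\!P = (1-Hct) + Hct \cdot K_{ery}$, with $K_{ery}$ computed from
erythrocyte water, lipid and protein volume fractions (drug-specific for
pyrimethamine and sulfadoxine, whose reference concentrations are
whole-blood measurements). The four sub-compartments of platform-style
organ models are collapsed to one well-stirred space per organ: for the six
shipped drugs, cellular permeabilities were calculated rather than fitted
in the source parameterizations, indicating permeability is not
rate-limiting, so a permeability-limited variant is not part of this
package's surface.

Elimination terms follow the shipped drug files: glomerular filtration as a
drug-specific fraction of GFR acting on unbound plasma, tubular secretion
and hepatic/biliary "specific" clearances normalized to organ volume
(1/min), Michaelis–Menten hepatic metabolism with $V_{max}$ in pmol/min/mg
microsomal protein (scaled by 40 mg microsomal protein per g liver) and
$K_m$ in µM, and intrinsic clearances in µL/min/mg. All act on the unbound
concentration at organ outflow (well-stirred), which reproduces the
expected adult clearances, including the near-renal-plasma-flow-limited
secretion of cefoxitin and a roughly 30% renal contribution to
pyrimethamine elimination. Biliary clearance (ciprofloxacin) secretes into
the duodenal lumen, so the drug can be reabsorbed or leave fecally.

## Absorption

The gastrointestinal tract is divided into 12 segments (stomach, duodenum,
two jejunal, two ileal segments, caecum, four colonic segments, rectum),
each with a transit time, pH, fluid volume, geometric surface area and a
surface-area enhancement factor (SAEF; drug files may override it per
segment, e.g. ciprofloxacin's caecal 26.24 with zero elsewhere in the large
intestine). The lumen of each segment carries a dissolved and, for solid
formulations, a solid sub-compartment. Absorption flux is
$P_{int} \times \mathrm{SAEF} \times \mathrm{area} \times C_{lumen}$ into
the portal blood.

Dissolution follows either a Weibull law — parameterized by the time to
50% dissolved and a shape factor, with the scale chosen so that exactly
half the dose is dissolved at $t_{50}$ — or Noyes–Whitney dissolution of
monodisperse spherical particles (diffusion coefficient $5\times10^{-6}$
cm²/s, density 1.2 g/cm³, diffusion layer capped at 30 µm; the $m^{2/3}$
surface term is regularized near zero to keep the right-hand side
Lipschitz). Dissolution is capped by solubility: the measured
prandial-state solubility is applied uniformly across segments.
Extrapolating a single measured point across segment pH with
Henderson–Hasselbalch was considered and rejected: biorelevant-medium
solubilities already embed the luminal milieu, and pH extrapolation from
one point would unphysically collapse the absorption of a lipophilic base
such as lumefantrine. Under a fed state, gastric residence grows linearly
with the meal's caloric content — anchored to double at 300 kcal — the
drink volume adds to gastric fluid, and the fed solubility applies (for
lumefantrine the milk value, 0.05 mg/mL, stands in for the nutritional
drink, following the reported soy-milk food effect).

Gut anatomy is sized by the *age-specific reference* body (areas with the
0.75 power of reference weight, volumes linearly), not by the individual's
current weight: malnutrition scaling deliberately leaves gastrointestinal
functionality untouched, so a scaled individual keeps its gut.

## Virtual individuals and populations

`reference_individual(age, sex)` interpolates an embedded reference grid
(ages 0.25–80 y, compiled from ICRP-style reference anatomy, with
WHO-growth-consistent pediatric weights and heights) linearly in age.
Because interpolation is linear per compartment, organ masses sum exactly
to body weight at every age — mass closure is an invariant, and fat is the
closing term of the grid itself. The embedded perfusion fixture was
anchored, when it was compiled, so that applying the severe scaling set to
the reference man reduces cardiac output by roughly the reported quarter
(measured 24.7% with the shipped flow distribution).

Stochastic populations perturb each organ mass lognormally (default CV
15%) around its age-specific reference, jointly multiplied by a shared
body-size factor (SD 0.06 on the log scale) that also drives height
(coefficient 0.35 plus residual SD 0.025) — inducing the weight/height
correlation of real cohorts. Body weight is recomputed as the sampled
organ-mass sum, so closure survives sampling. Hematology, plasma proteins
and GFR receive a 5% CV. These variability constants are the package's own
calibration of an under-determined quantity; the one observable they were
chosen against is the outlier-discard fraction: removing individuals more
than 1 SD from the mean body-weight/height ratio (per sex when sexes are
mixed) discards 26–30% of a 46–48-month population, consistent with the
reported ≈26%.

Enzyme ontogeny uses Hill-type maturation curves normalized to reach 1 in
adults: CYP3A4 exceeds 90% of adult activity by 3 years; CYP1A2 has a
slower onset but is essentially mature before 2 years; unspecific hepatic
clearance matures early; tubular secretion tracks a half-maturation age of
0.4 y. GFR scales with the 0.75 power of reference weight and matures with
age. Only the qualitative anchors of these curves are externally
constrained; the constants live in `R/physiology.R`.

## The malnutrition scaling layer

Scaling factors derive from adult body-composition studies via the double
ratio
$$\mathrm{PSP} = \frac{X_{r,M}/X_{t,M}}{X_{r,N}/X_{t,N}},$$
reported malnourished over reported normal, each normalized by its
height-conditional typical value (`derive_psp()`). Directly derivable
factors: plasma proteins (serum albumin over the 4.25 g/100 mL reference;
the α1-acid-glycoprotein factor is set equal, as is the effective factor
for lumefantrine's lipoprotein binding, modeled with albumin as surrogate),
hematocrit (reference 0.47, back-derived consistently from all three
severity levels), and skin (Du Bois surface area at fixed height, i.e. the
weight ratio to the 0.425 power). Organ factors at mild and intermediate
levels interpolate linearly in the percent-of-standard weight/height
deficit (89.5 / 82.7 / 73.9% of standard) from the severe values. The
severe organ factors themselves, and the blood-compartment factors, are
shipped as a verbatim fixture: their height-adjusted typical values cannot
be reconstructed from the published record, and exact reproduction beats
unverifiable re-derivation. Fat and muscle are re-adjusted at each level by
one common multiplier so the scaled organ masses of the reference man sum
exactly to the target body weight (73.9% of 73.0 kg at severe, multiplier
1.014), preserving the fat:muscle ratio; if the multiplier would push a
factor above 1 it is capped with a warning.

`apply_psps()` multiplies compartment masses, plasma proteins and
hematocrit by their factors, recomputes body weight as the scaled sum,
scales GFR with kidney mass, and leaves height, age, ontogeny and specific
perfusion untouched — so absolute flows and cardiac output shrink with
mass. Unbound plasma fractions follow binding-protein proportionality,
$f_u' = 1/(1 + \frac{1-f_u}{f_u} r)$ with $r$ the plasma-protein factor.
Scaling is multiplicative and composable: applying two factor sets equals
applying their elementwise product.

Anthropometric evaluation uses weight-for-height and weight-for-age
z-scores, $(x - \mathrm{median})/\mathrm{SD}$, against an embedded
WHO-standards-like median/SD table (SD set to 8% of the median, matching
the dispersion of the standards; the LMS skewness machinery is
deliberately omitted because the z definition used here needs only median
and SD). Severe acute malnutrition is classified as WHZ strictly below −3.
Applying the severe set to a 46–48-month population drops WHZ by a nearly
constant ≈3 units, with individual values spanning roughly −1 to −4.5 —
individuals who started above the median remain above the −3 cutoff, which
is a property of fixed-state scaling, not a defect.

## Numerics

The ODE system (46 states) is compiled C solved with `deSolve::lsoda`,
default relative tolerance 1e-8 and absolute tolerance 1e-10 mg.
Concentrations entering elimination, absorption and saturation terms are
clipped at zero. Mass balance — administered = body burden + lumen +
cumulative elimination — is audited at every output time and stored on the
profile; the suite requires closure within 0.1%, and typical runs close to
1e-9 or better. Single doses enter at time zero (oral) or as a constant-
rate infusion with the integration split at the infusion boundary; a
zero-length infusion is a venous bolus. Oral solutions exceeding gastric
solubility precipitate the excess into a rapidly redissolving solid pool
(first-order, 6-minute half-time). Non-compartmental AUC uses
linear-up/log-down trapezoids; the terminal slope is the best
adjusted-$R^2$ log-linear fit over the last 3–10 post-peak points, with
points below $10^{-6}\,C_{max}$ excluded as solver noise.

## Virtual trials and problem sizes

`compare_dosing()` implements the matched-arm design: one non-malnourished
population (after outlier exclusion), a scaled copy of the *same*
individuals, both arms simulated under the same regimen, and the fold
deviation FD = median(AUC, malnourished)/median(AUC, reference). Exposure
is read in the matrix of the corresponding reference studies: plasma for
caffeine, cefoxitin, ciprofloxacin and lumefantrine; whole blood for
pyrimethamine and sulfadoxine. Quantitative ratio analyses use n = 200 per
arm and three seeds (median of per-seed FDs): with ~140 individuals
surviving exclusion per arm, the Monte-Carlo error of a median ratio is
comfortably inside a ±10% band, and the per-seed spread observed in
practice is under 1%. Direction-only checks (per-kg FD < 1 across all six
drugs) use n = 60 and one seed. These sizes are the package's choices for
routine verification; nothing prevents larger runs.

## What the generator does and does not emulate

The synthetic populations emulate age-dependent reference anatomy with
realistic biometric correlation and a fixed-state malnutrition transform.
They do not emulate: ethnicity-specific physiology (the reference grid is
a western-reference compilation), marasmus/kwashiorkor-specific phenotypes
(edema in particular), lethal starvation, malnutrition-induced changes in
gastrointestinal function or enzyme abundance (deliberately excluded),
disease comorbidity, or measurement noise in anthropometry. Passing tests
therefore demonstrate internal consistency of the translation strategy and
agreement with the published scaling anchors — not clinical validation,
which requires external concentration data that are out of scope here.

## Known limitations

* Specific perfusion is held age-constant; pediatric cardiac output is
  therefore driven entirely by organ-mass proportions.
* Tissue composition (and hence $K_p$) is not malnutrition-scaled, mirroring
  the source strategy; protein-binding changes enter only through
  $f_{u,p}$ and the albumin terms.
* Absorption of highly permeable drugs is gastric-emptying-limited and can
  be faster than observed; single-dose AUC of linear drugs is unaffected.
* The Weibull/particle dissolution laws share one solubility value across
  segments (see above).
* Multi-dose regimens are not implemented; the dose-strategy analyses are
  single-dose by design.
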