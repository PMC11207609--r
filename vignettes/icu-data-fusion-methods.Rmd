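---
title: "Models and methods behind icufusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icufusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icufusion)
```

`icufusion` is a desk-scale model of a critical-care data-fusion stack: it
takes raw medical-device messages in three dialects, lifts them into
FHIR-style observations, fuses them into per-patient states, computes
lung-protective ventilation indices and safety alerts, models the streaming
fabric that would carry the data in production (routing, failover, delay,
cluster reliability), and provides a staged feature-extraction plus
ensemble-classification scaffold for ARDS prediction. This vignette explains
the models, the tunable parameters, and the design decisions, in that order.

## Observation model and coding

The unit of exchange is a FHIR-style observation restricted to seven fields:
category code, subject (patient id), effective time, device type and
location, and an ordered list of components. Each component carries a LOINC
code, a display name, a typed value (decimal, integer, string, boolean, or a
`{low, high}` range) and a UCUM unit, which is mandatory for numeric values.
JSON is the single serialization dialect (one observation per NDJSON line);
we deliberately do not model the full FHIR resource graph, REST endpoints or
XML.

Two choices matter downstream:

* **Timestamps** must carry an explicit timezone designator and are
  normalized to UTC on parse. Multi-device fusion orders values by time;
  an ambiguous local time would silently corrupt last-write-wins fusion.
  Serialization is at whole-microsecond resolution; the shipped generators
  emit whole-second device clocks, for which the NDJSON round trip is exact.
* **The code registry** is a versioned JSON asset mapping canonical
  parameter names to LOINC/UCUM pairs. Only heart rate (8867-4,
  `{beats}/min`) and arterial oxygen saturation (2708-6) are anchored by the
  source system's own documentation; every other code is filled from the
  public LOINC table and marked `provenance: "external-standard"` in the
  asset. Lookups of unknown names fail loudly — a silent default unit on a
  clinical value is worse than a crash.

## Device-feature translation

Each datum a device can emit is registered as a *device feature* (DF):
category, canonical name, dialect, a dialect-specific locator, a value type
and an optional plausibility range. A parser is *compiled* from the DFs of
one (category, dialect) pair; compilation is pure, and the rules are stamped
with a content hash of their source rows rather than wall-clock time so that
recompiling an unchanged registry is byte-identical — important for
reproducible pipelines and for caching.

The three dialects are modeled minimally but faithfully:

* **HL7 v2 subset**: MSH + OBX segments, pipe-delimited, `^` component
  separator; OBX-3 carries the identifier, OBX-5 the value, OBX-6 the unit.
* **JSON**: locator is a `/`-separated key path.
* **Proprietary**: `LABEL<kv>VALUE` tokens joined by a field delimiter, both
  delimiters declared per category. This grammar is a repo convention: real
  vendor tables document code/value pairs without a formal grammar, and a
  declared-delimiter tokenizer is the smallest deterministic reading.

A production system generates such mappings with LLM assistance; here the
parser compiler is entirely table-driven, because a translation layer whose
behavior is not a pure function of its registry cannot be meaningfully
tested or audited.

Range policy is *flag-and-forward*: an out-of-range value is extracted,
flagged, and kept. In an ICU the extremes are exactly the values that
matter. Unmatched payload tokens are reported as residue, never silently
dropped, and the test suite asserts exact value conservation over generated
corpora: every emitted number reappears bit-identically as a component.
A message without a patient identifier translates with subject `UNKNOWN`
plus a warning, since device streams can outpace patient-registration
linkage. Device-reported time wins over gateway receive time when both are
present (a convention; the reconciliation is not specified by any standard
we model). FiO2 arriving as a percentage is normalized to the (0, 1]
fraction convention at translation time.

## Ventilation indices and alerts

Predicted body weight uses the ARDSNet/Devine form,
$PBW = 50 + 0.91(h - 152.4)$ kg for males and $45.5 + 0.91(h - 152.4)$ for
females with height $h$ in cm — the standard behind low-tidal-volume
practice. Below the 152.4 cm anchor the base weight is used as a floor.
Heights are validated to 120–230 cm.

Three indices are computed per fused state:

* **Ventilatory ratio** (dimensionless). The default computes
  $\mathrm{VR} = \dfrac{V_e \cdot P_{CO_2} \cdot V_t}{100 \cdot 37.5 \cdot PBW}$
  with $V_e$ in L/min and $V_t$ in mL, following the device-facing
  documentation this package models, whose typesetting is ambiguous about
  the numerator. The conventional bedside form,
  $\mathrm{VR} = \dfrac{V_e[\mathrm{mL/min}] \cdot P_{CO_2}}{100 \cdot PBW \cdot 37.5}$,
  is available as `method = "standard"`. Both are exposed because no worked
  value exists to disambiguate, and a package that silently picked one
  reading would hide a real uncertainty. The constants 100 and 37.5 (the
  reference PCO2 in mmHg) are named configuration constants in the source.
* **P/F ratio** $= P_{O_2}/F_iO_2$ in mmHg, FiO2 a fraction in (0, 1].
* **LTVV index** $= V_t/PBW$ in mL/kg.

Alerts fire on *strict* violation, matching the wording of the safety rules
they encode: LTVV > 8 mL/kg, P/F < 300 mmHg, FiO2 ≥ 0.4. A boundary LTVV of
exactly 8.0 is safe. Vital-sign normal ranges (HR 60–100, RR 12–20,
SpO2 ≥ 94 %, systolic BP 90–140) are configurable assets, not clinical
constants.

Data-level fusion is last-write-wins per parameter within a lookback window
(default 6 h) ending at the fusion time; each fused field retains the
provenance of its source observation. Missing required parameters raise an
incomplete-state error listing them, rather than producing indices from
stale or absent inputs. Fusion is idempotent.

The package ships a fixed, seedless worked-case trajectory: at the first
timestamp the indices are LTVV 10.0, P/F 164, FiO2 1.0 (three alerts), six
hours later LTVV 6.1, P/F 320, FiO2 0.35 (no alerts). The generator inputs
behind those derived values (Vt 600 → 366 mL, PBW 60 kg via a 163.4 cm male
profile, PO2 164 → 112 mmHg) are *constructed*: only the derived indices are
externally given, so the inputs were reverse-engineered to reproduce them
exactly, and are documented as such.

## Stream fabric

One topic per device category (`Topic_PM`, `Topic_VEN`, …), each sharded
into partitions (default 64). Initial partition placement is round-robin —
perfectly balanced and deterministic. On node failure only the failed
node's partitions move, re-placed by rendezvous (highest-random-weight)
hashing over the survivors; this is a consistent-hashing scheme chosen for
minimal reassignment churn. Message keys hash to partitions (xxHash via
`rlang::hash`), so a fixed key always routes to the same node while uniform
keys spread load; the suite asserts a max/min node-load ratio below 1.5
over 10⁴ random keys. Durability is an abstraction: queued messages survive
failures (replication factor ≥ 2 is assumed, not simulated byte-level), and
the fabric guarantees routing conservation — delivered count equals
enqueued count under any failure schedule leaving one live node.

Throughput accounting is an exact sum with decimal unit normalization
(1 Mbps = 1000 Kbps, 1 TB = 1000 GB — the only convention under which the
modeled per-category figures reconcile with their printed totals): the five
modeled categories aggregate to 65.66 Mbps and 21.7368 TB/year (22 TB at
nearest-TB rounding). One figure in the source inventory prints a garbled
unit ("7.2 Mbps Kbps" for hematology analyzers); the Mbps reading is
adopted because only it reconciles the net rate.

The delay simulator models Poisson arrivals over the topics, uniform
key-hash routing to `n` nodes, and exponential service per node — a fork of
M/M/1 queues evaluated by the Lindley recursion. Standard errors use batch
means (default 20 batches) because sojourn times are autocorrelated.
Absolute production delays are *not* reproduced — the underlying service
parameters are unpublished — only two checkable properties: agreement with
the M/M/1 closed form $1/(\mu - \lambda)$ at one node within 3 SE, and
monotone non-increase of expected delay in the node count.

## Cluster reliability

Node lifetimes are i.i.d. exponential with mean $1/\lambda$ and repairs
exponential with mean $1/\beta$; each node fails at most once per cycle.
With $\gamma$ = mean repair / mean lifetime, the probability that all $I$
nodes are simultaneously down at the instant of the last failure is

$$PF(2) = \frac{\gamma}{1+\gamma}, \qquad
  PF(3) = \frac{2\gamma^2}{(2\gamma+1)(\gamma+2)}, \qquad
  PF(I) = \prod_{k=1}^{I-1}\frac{(I-k)\gamma}{(I-k)\gamma+k}.$$

The general product follows from the independent exponential spacings of
the lifetime order statistics ($t_{(k+1)} - t_{(k)} \sim
\mathrm{Exp}((I-k)\lambda)$) and reduces exactly to the two printed forms;
the Monte-Carlo simulator, which draws raw lifetimes and sorts them rather
than using the spacings, confirms all three at $N = 10^6$ within 3 binomial
standard errors. A note on notation: the source material writes
$\gamma = \beta/\lambda$ while also defining $\beta$ through the *mean*
repair time; its numeric claims only reconcile when $\gamma$ is the
repair/lifetime *ratio of means*, which is the orientation adopted here.

Two derived quantities matter operationally, with one year = 8760 h:

* `max_repair_time(3, 8760, 1e-6)` inverts $PF(3)$ by monotone root-finding
  on $\log\gamma$ (bracket $[10^{-9}, 10^3]$, relative tolerance $10^{-9}$):
  a three-node cluster with one-year node lifetimes stays below a $10^{-6}$
  failure probability iff mean repair stays below ≈ 8.77 h, i.e. 9 h at
  whole-hour rounding. At exactly 9.00 h the closed form gives
  $PF(3) \approx 1.05\times10^{-6}$, marginally above the bound — the 9 h
  figure is a rounding of 8.77, and the package reports both rather than
  forcing the bound.
* `improvement(gamma)` $= (PF(2)-PF(3))/PF(2)$: at $\gamma = 10^{-3}$ a
  third node removes 99.90 % of the residual two-node risk.

The simulator also exposes a conservative `repair_deadline` event (any
earlier-failed node still down at the last failure), an upper bound on the
all-down probability, for comparison.

## Feature extraction and the ensemble

Feature extraction is a staged graph: Stage 0 is the raw table; later
stages hold derived features. Nodes are built-ins (PBW, ventilatory ratio —
which call the clinical-index functions directly, so graph outputs are
bit-identical to direct calls), bypasses (identity copies; a bypass may
shadow a Stage-0 name), or restricted arithmetic expressions. The
expression mini-language admits only `+ - * /`, parentheses, numeric
literals and known feature names — a sandboxed substitute for embedded
scripting that keeps extraction auditable. Stage ordering plus
same-stage-predecessor checking makes every valid graph acyclic with a
deterministic evaluation order; rows with missing inputs are dropped and
counted, never imputed silently. The default ARDS graph bypasses the six
sensor features (FiO2, PCO2, PO2, Ve, Vt, label), computes PBW at Stage 1
and the ventilatory ratio at Stage 2 — eight output features.

The ensemble fits an SVM (RBF kernel, `e1071`), gradient-boosted trees
(`xgboost`, 100 rounds, depth 4, learning rate 0.1, single thread for
determinism) and a multilayer perceptron (`nnet`, 8 hidden units, weight
decay 0.01, standardized inputs) on a train split (default 0.8) and scores
everything on the held-out remainder. Hyperparameters default to the
libraries' conventions and are recorded in the run manifest. Fusion is
majority voting by default: hard member votes decide the fused label, with
even-count ties broken toward the positive (disease) class — clinically
conservative — and logged. Because a vote fraction over three members takes
only four values, it is too coarse to rank cases, so the ensemble's AUC is
computed from the averaged member probabilities while its threshold metrics
(accuracy, precision, F1) come from the fused labels; probability averaging
is also available as the fusion rule itself. Other fusion rules (boosting,
bagging, stacking, blending) are declared extension points, not
implemented. `select_best()` is a deterministic argmax over the chosen
metric with declaration-order tie-breaks.

## Synthetic data: what it does and does not emulate

No real patient data ships with or is accessible to this package; every
input is generated.

* **Cohorts**: sex Bernoulli (default 0.5), heights normal per sex
  (male 170 ± 7 cm, female 158 ± 7 cm, resampled into 120–230 cm), ward
  zones drawn from a configurable mix. These are field-plausible
  conventions, not estimates from any real unit.
* **Streams**: per-category byte budgets proportional to the modeled data
  rates (29.7 : 26.1 : 2.32 : 0.344 : 7.2), scaled to a desk-size corpus
  (default ~400 kB) with the scale recorded in the manifest; dialects follow
  the device assignment. Payload values are uniform over plausible clinical
  ranges with short decimal representations, which makes value-conservation
  testing exact.
* **ARDS tables**: labels first (default prevalence 0.3), then latent P/F
  normal within class — ARDS mean 180 mmHg, non-ARDS mean 180 + effect
  (default effect 120 mmHg, within-class sd 40 mmHg). Equal-variance
  Gaussian classes make the label model *exactly* logistic in latent P/F
  with coefficient $-\mathrm{effect}/\mathrm{sd}^2$, and give a closed-form
  Bayes AUC $\Phi(\mathrm{effect}/(\mathrm{sd}\sqrt2))$ — about 0.983 at
  the defaults, a strong but imperfect planted signal. FiO2 is uniform on
  (0.30, 1.00) and PO2 is reconstructed as $P/F \times F_iO_2$, so
  classifiers must recover the ratio from the pair. PCO2 and Ve carry a
  mild secondary shift; Vt, height and sex are noise.

What passing tests on these data show: the pipeline loses nothing, the
extraction graph computes what the index functions compute, and the
ensemble can recover a planted, honestly-characterized signal (validation
AUC above 0.85 across seeds, above its weakest member). What they do not
show: performance on hospital data — real ARDS labels come from clinical
adjudication, features are missing not-at-random, and distributions drift;
none of that is emulated. The label here is a Berlin-like oxygenation
threshold stand-in, and published clinical AUCs are not comparable to
anything this package computes.

## Numerical choices and problem sizes

Root-finding uses bisection-style `uniroot` on $\log\gamma$ to $10^{-12}$
absolute tolerance in the log, giving $10^{-9}$ relative inversion accuracy.
Monte-Carlo reliability runs use $N = 10^6$ replications where closed-form
agreement is asserted (binomial SE ≈ $3\times10^{-4}$ at $p\approx0.09$)
and $N = 2\times10^5$ in routine tests. Delay simulations use 20,000
arrivals and 20 batch means. Ensemble checks use n = 2000 samples over five
seeds; parameter-recovery uses n = 20,000. These sizes give stable
assertions at comfortable desk-run times. All simulators take an explicit
seed, save and restore the caller's RNG state, and are reproducible
seed-for-seed.

## Known limitations

* The broker is in-memory and functional; no real Kafka/MongoDB
  connectivity, consumer groups, or exactly-once semantics.
* Reliability assumes exponential lifetimes/repairs and a single
  failure cycle per node; renewal processes are out of scope.
* The ventilatory-ratio default follows an ambiguously typeset formula;
  users wanting the conventional index must pass `method = "standard"`.
* LOINC codes beyond the two anchored ones are standards-derived
  conveniences; a deployment should review the registry asset.
* The delay simulator reproduces qualitative load-balancing behavior only.
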