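---
title: "Knockout damage and phenotype prediction in multi-omic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout damage and phenotype prediction in multi-omic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refnet)
```

# The network model

`refnet` represents a cell's molecular interaction network as typed
species — genes, transcripts, proteins, protein complexes, metabolites —
connected by typed interactions — transcriptions, translations,
metabolic reactions, complex assemblies, transport and exchange
processes. Interactions consume substrates and produce products with
positive stoichiometric coefficients; *control* is a separate edge kind
(a gene controls its transcription, a transcript its translation, an
enzyme its reaction), so stoichiometry stays physical and catalysts are
never consumed. Identifiers are namespaced (`g:`, `tr:`, `p:`, `cx:`,
`m:`, `ix:`) to keep the species and interaction id spaces disjoint by
construction, while source-database accessions are kept verbatim as
cross-references.

The reconstruction follows the reference-object approach: a gene,
transcript or protein *is* its primary sequence. Records from different
source databases whose normalized sequences (uppercased, whitespace
stripped — identity means exact string equality, no alignment) agree are
merged into one species carrying the union of cross-references.
Transcriptions and translations are not documented in source exports, so
one transcription is instantiated per (gene, transcript) link and one
translation per transcript; a transcript merged from *k* genes gets *k*
transcriptions. Enzymes attach to reactions through EC numbers, one
reaction copy per matching protein (isozymes become parallel copies); an
EC with trailing dashes matches any completion, because real exports
contain partial numbers. Complex records are deduplicated on the sorted
member set — the provenance of duplicated interaction records rarely
justifies two distinct complexes — and assemblies are irreversible (no
disassembly is instantiated). Finally every reversible reaction is split
into two irreversible directions, so downstream analyses never see a
reversible edge. Protein complexes never catalyze reactions here:
interaction databases do not annotate catalytic activity for complexes,
and inventing it would silently change damage propagation. Proteins
documented without any transcript are kept as orphan species with no
producing interaction.

# Boolean damage propagation

Each object has a Boolean feasibility. The rules are fixed by the
network structure: an interaction is feasible iff **all** species it
needs (substrates ∪ controllers) are feasible; a species is feasible iff
**at least one** producing interaction is feasible. A knockout clamps
the listed genes infeasible, starts everything else feasible, and
propagates *loss* of feasibility until nothing changes.

Two semantic choices matter:

* **Greatest fixed point.** Starting all-feasible and only removing
  feasibility yields the unique maximal assignment consistent with the
  rules and the clamp. This forbids a self-sustaining loop (e.g. a
  metabolic cycle) from being declared blocked merely because it is a
  loop — blockage must be *caused* by the knockout.
* **Roots stay feasible.** Species without producers (genes, medium-like
  metabolites, orphan proteins) have a vacuously false 'or' rule; they
  are treated as externally supplied and stay feasible unless
  explicitly knocked out.

The implementation is a worklist algorithm with producer counters (an
interaction blocks on the first infeasible requirement; a species blocks
when its last producer does), which visits each edge once; the contract
only fixes the result, which is evaluation-order independent, and the
test suite checks it against a brute-force oracle that re-evaluates all
rules in shuffled orders until fixation. Uncatalyzed reactions (no
controller) require only their substrates — the empty conjunct is
vacuously true — and their count is reported on the compiled model so
the assumption is never silent; whether to retain or drop uncatalyzed
reaction records entirely is a reconstruction option
(`uncatalyzed = "retain"`/`"drop"`), since source reaction tables do not
say whether uncatalyzed entries took part in the original analyses.

Ubiquitous currency metabolites (water, ATP, …) are **not** exempted
from requirement sets by default: nothing in the damage model justifies
a special case, and the layered structure already keeps damage local. An
explicit `exclude_species` list is available for networks where a highly
connected metabolite would otherwise funnel implausible blockage; any
use is recorded on the compiled model.

Structural consequences worth knowing (they anchor the tests): every
single-gene knockout blocks the gene and all its transcriptions
(probability 1, exactly one each in a one-transcript-per-gene network);
at most one protein can be blocked per single knockout (each translation
produces one protein); and the smallest possible damage in a network
with a redundant production route is 4 — gene, transcription,
transcript, translation — when the protein survives via its second
route. A duplicate-coding-sequence pair would produce damage of size 2
(gene + transcription, the merged transcript surviving); study sweeps
that assert the minimum of 4 therefore use a generator configuration
with `p_duplicate_cds = 0`.

# Constraint-based metabolic damage

For a stoichiometric model (metabolite × reaction matrix, flux bounds,
exchange flags, optional GPR rule per reaction) a knockout is analyzed
in three steps:

1. **GPR evaluation** — knocked genes false, all others true; standard
   Boolean evaluation (`AND` complexes, `OR` isozymes) decides enzyme
   availability; reactions whose rule is false are clamped to zero flux.
2. **Blocked reactions** — a reaction is blocked iff it cannot carry a
   steady-state flux: both its maximal and minimal flux over
   `{v : S v = 0, lb ≤ v ≤ ub}` are within tolerance `1e-9` of zero.
   Infinite bounds are replaced by magnitude `1000`. Each direction is
   decided by a strictly convex program
   (min ½‖v‖² − sign·v_j): because the flux region is convex and
   contains 0, its solution has a nonzero j-th coordinate exactly when
   some feasible flux does, and the Goldfarb–Idnani dual active-set
   method (quadprog) is immune to the degenerate vertices that make
   plain simplex implementations fail on these problems. Any flux
   vector observed during the sweep clears every reaction it uses, so
   most reactions never need their own solve.
3. **Blocked metabolites** — blocked iff all producing reactions
   (positive coefficient, non-exchange) are blocked and no uptake
   exchange for the metabolite is open in the medium; a metabolite with
   an open uptake is never blocked. A metabolite with no producers and
   no uptake is blocked vacuously.

*Unconditional* damage opens every exchange reaction in both directions
— the cell may take up and secrete everything exchangeable, which
subsumes aerobic, complex-medium conditions — so anything blocked there
is blocked under every medium (restricting a medium only removes flux
options; the tests verify this monotonicity on random models).
Exchange flux sign convention: uptake is negative flux (the exchange
column consumes the metabolite). Constitutively blocked reactions
(dead-end pathways present without any knockout) are computed as a
baseline and knockout damage is reported **net of baseline**, so only
additional blockage counts; callers who want the raw set get it too.

# Essentiality scoring

Variables with identical feasibility columns across all knockouts of a
study are statistically indistinguishable and are merged before scoring
(typically a gene with its transcription, transcript, translation and
protein); the partition is kept so results can be expanded back to
objects, and no phenotype information is used for the merge. The
essentiality score of a variable is the fraction of inviable strains
among the strains that block it — the empirical probability of death
given blockage. Score 1 defines unconditional essentiality *within the
studied context*; the fewer strains block a variable, the more biased
its score can be, so `unconditionally_essential()` exposes a
`min_support` filter (default 1, i.e. the bare definition). Variables
never blocked get `NA`, never 0 — zero would falsely assert evidence of
dispensability. Conflicting labels for a repeated strain id are resolved
by majority, with exact ties kept viable (the conservative direction)
under a warning.

# Phenotype classification

Feature selection keeps variables whose essentiality score *in the
training rows alone* is strictly greater than 0.5; undefined scores are
excluded, and an empty feature set falls back to majority-class
prediction with a warning. The classifier is a linear soft-margin SVM
with cost constant 1 — a maximum-margin separator in the binary
feasibility space; the soft margin is what lets noisy labels be absorbed
rather than destroying the fit, and the constant is exposed in the
configuration. The fitted machine is reduced to an explicit weight
vector and offset, oriented so positive decision values mean inviable; a
sample exactly on the hyperplane is predicted viable (conservative
toward the majority class). Hold-out evaluation draws fixed class counts
into training (class-count control, not proportion-preserving
stratification, matching designs that fix e.g. 1,400 inviable + 5,600
viable training strains), repeats the draw `n_repeats` times from a
seed, and reports per-repeat and mean/SD TPR and FPR. Feature selection
and training see only training rows; a test verifies the selected
features are a function of the training rows alone.

Layer-ablation experiments ("what does the protein-interaction network
contribute to prediction?") are pipeline configurations, not code paths:
rebuild the network without the layer (set `n_complex_records = 0`, or
`n_reactions = 0`, in the generator configuration — or assemble real
sources without those tables), recompute damage, and rerun the same
evaluation.

# The synthetic-data generator

The generator draws database-export-shaped records and assembles them
with the production reconstruction code, so the direct route and the
fixture-file route cannot drift apart. It emulates: one gene → one
transcript → one protein chains; occasional identical coding sequences
(`p_duplicate_cds`, default 0.01) that merge transcripts; proteins
redundantly listed across three pseudo-databases (always in the first,
with probability 0.5 / 0.3 in the others) to exercise sequence-identity
merging; orphan proteins (`p_orphan_protein`, default 0.02); redundant
production routes (`p_redundant_protein_route`, default 0.03) where two
transcripts share one protein; complex records with hub-skewed
membership (weights ∝ rank^−0.8) and sizes of median 2 with a geometric
heavy tail capped at 99; reactions with 1–3 substrates and products,
30% reversible, 90% enzyme-catalyzed through a pool of EC numbers with
1–2 enzymes each; and exchange processes for 10 of 60 metabolites.
Defaults were chosen once to echo the printed summary statistics of
curated yeast-scale reconstructions (median complex size 2, maximum 99,
hub proteins, a metabolic layer a few percent of the network) at desk
scale; they are not fitted to any dataset. Sequences are random strings
over the appropriate alphabet — no biological realism is claimed for
their content, only for the identity structure among them.

Knockout studies plant `n_essential` objects (genes by default;
`planted_types` widens the pool) and label a strain inviable iff its
Boolean damage intersects the planted set, then flip each label with
probability `label_noise`. This mechanism is a modelling choice standing
in for biology: it is exactly the inverse of the problem the
essentiality score solves, which is what makes noiseless recovery a
sharp correctness check — every reachable planted object must score
exactly 1, and the classifier must reach TPR 1 / FPR 0. Note the
converse does not hold at the full object level: a variable blocked
*only* by strains that also hit planted objects (say, a complex whose
members all come from planted-essential genes) legitimately scores 1
without being planted, so exact recovery is asserted at the gene level,
where genome-wide single knockouts pin every unplanted gene down with a
viable observation.

What passing these tests does **not** show about real data: real
knockout compendia are unevenly sampled, phenotypes are
condition-dependent, label noise is not independent per strain,
regulation is absent from the network, and the planted-truth mechanism
ignores dosage and compensation. The synthetic studies validate the
machinery, not the biology.

# Numerical and size choices

* Blocked-flux tolerance `1e-9`, open-bound magnitude `1000`; both
  exposed as arguments.
* The QP subroutine drops linearly dependent stoichiometry rows via a
  rank-revealing QR before solving.
* Damage matrices are stored sparsely (blocked entries only); merging
  hashes sparse column supports.
* Hold-out seeds derive deterministically from the configured seed per
  repeat; all generators restore the caller's RNG state.
* Test and validation problem sizes are the package's own choice of
  desk scale: networks of 30–200 genes (≈330–2,000 objects), studies of
  up to 5,000 strains, 30 random toy stoichiometric models of 8
  metabolites × 15 reactions, trend sweeps over 5 seeds × 4 settings.
  These run the whole suite in about a minute while leaving every
  structural property (probability-1 rows, minimum damage 4, recovery,
  monotone trends) exactly observable.

# Known limitations

* SBML import of foreign documents maps unannotated species to
  metabolites (with a warning count); five-layer typing round-trips only
  through this package's own controlled annotations.
* The metabolic analysis is structural: no biomass objective, no growth
  prediction under specific media, no thermodynamic constraints.
* Boolean damage has no notion of partial function, dosage, or
  regulation; recovery (gain-of-feasibility) dynamics are out of scope.
* EC matching is string-based with wildcard dashes; it does not consult
  reaction chemistry.
* The classifier is linear by design; no probability calibration is
  attempted.
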