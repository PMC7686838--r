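---
title: "Mining enriched scaffolds into structural queries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining enriched scaffolds into structural queries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffquery)
library(tibble)
```

## The procedure and its assumptions

scaffquery implements the ligand-based drug-repurposing recipe: compounds
known to act on the targets of a disease are pooled, the chemotypes they
share are distilled into substructure queries, and drug libraries are
filtered for those queries. The approach assumes (i) that activity is at
least partly encoded in a compound's framework rather than only in its
decorations — the justification for working with Bemis–Murcko scaffolds —
and (ii) that a substructure shared by many actives of one target is a
useful, if crude, pharmacophore proxy. Substructure search captures *local*
similarity: it tolerates large size differences between query and library
compound, which is exactly what repurposing across chemical series needs,
at the price of ignoring global shape and physicochemistry.

The pipeline is organized as six tabular stages (retrieval,
standardization, labeling, scaffolds, queries, screening); every stage
takes and returns a tibble keyed by UniProt accession and InChIKey, so a
run is an ordinary pipe chain and any stage can be re-run from its
predecessor's table.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `min_score` | 0.99 | association score (0–1) | keeps only targets with near-certain disease evidence; lowering it admits speculative targets and noise |
| `size` | 10,000 | targets/request | effectively "all targets" for one disease |
| page `limit` | 1000 | records/call | the bioactivity service's per-call ceiling; `plan_pagination()` derives `⌈total/1000⌉` offsets |
| `timeout` | 60 | s | service defaults of 2 s routinely truncate full pages |
| `cutoff` | 9 | pX | active ⇔ pX > 9, i.e. sub-nanomolar; membrane-transporter work uses 6 (< 1 µM) because potencies run lower for transporters. Strict inequality: exactly 1 nM is *not* active |
| `threshold` | 0.5 | MCS distance | scaffolds closer than 0.5 merge into one query; higher values give fewer, vaguer queries |
| `linkage` | average | – | compromise between single-linkage chaining and complete-linkage splitting; configurable |
| `min_query_size` | 3 | heavy atoms | suppresses vacuous one- or two-atom queries |
| `max_generic_rings` | 1 | rings | a lone ring (benzene, pyridine, piperidine) matches half of any drug library and carries no discriminative value |

## Matching semantics and numerical choices

**Aromaticity.** One perception model is fixed for the whole run: every
SMILES entering the graph layer is first canonicalized by OpenBabel, whose
aromatic form (lowercase atoms) the internal reader trusts; a bond written
without a glyph between two aromatic atoms is aromatic when it lies on a
ring and single otherwise (the biphenyl case). Standardization, scaffold
extraction, MCS and screening therefore agree bond-for-bond.

**Stereo removal** operates on the molecular graph — flags are cleared and
the structure re-canonicalized — rather than deleting characters from the
SMILES text, which would corrupt ring-bond slashes in aromatic systems.

**Salt stripping** uses a packaged fragment list (halides,
alkali/alkaline-earth ions, ammonium, sulfate, nitrate, water, common
solvents). When several non-salt fragments remain, the one with the most
heavy atoms is kept; ties break by molecular weight, then canonical SMILES
order, so the choice is deterministic. A structure whose fragments are all
salts is quarantined rather than guessed at.

**Charge neutralization** adds or removes protons only. Charges that
cannot be neutralized without changing bonds (quaternary N) are kept and
flagged `permanently_charged`; valence is re-checked afterwards and
violations quarantine the record. Beyond valence sanity no further
"structure quality" heuristics are applied — the package does not attempt
tautomer canonicalization, 3D clash detection, or pH-dependent protonation
(out of scope by design).

**Murcko frameworks** are rings plus linkers: terminal atoms are pruned
iteratively unless attached by a double/triple bond to a surviving atom
(so a carbonyl on a ring or linker stays, a carboxylic acid side chain
goes). Ring-free molecules have no framework and leave the pipeline at
this stage.

**MCS** is the maximum common *connected* substructure under element and
bond-aromaticity matching (aromatic matches only aromatic; rings need not
be complete), sized in heavy atoms. The search is branch-and-bound over
growing atom mappings with a canonical seed order, so it is deterministic;
a per-pair time budget (5 s default) degrades gracefully to best-found
with an `approximate` flag — at scaffold sizes (≤ ~20 atoms) the exact
search finishes in milliseconds and the flag never triggers in practice.
The distance is Tanimoto on atom counts, d = 1 − m/(|a|+|b|−m): 0 for
identical scaffolds, 1 only when no atom is shared; the alternative
1 − m/max(|a|,|b|) is available via `formula = "max"`. The exact metric of
the original workflow's similarity node is not documented, so the choice
is recorded here and surfaced in the function signature rather than hidden.

**Clustering** sorts scaffolds by canonical SMILES before the distance
matrix is built and assigns cluster ids in order of first member, making
the assignment invariant to input row order and to duplicated rows. A
single scaffold short-circuits to a singleton cluster with no matrix
computation. `stats::hclust`/`cutree` do the clustering itself.

**Multi-scaffold MCS** for a query folds pairwise in canonical-SMILES
order (MCS of the running pattern with the next member). Because a common
substructure of the running pattern is by construction a substructure of
every earlier member, the folded result provably matches all members; a
final verification pass asserts exactly that and aborts the run on any
violation rather than emitting an unsound query. Within a target,
identical patterns from different clusters are deduplicated with member
counts summed.

**Relation handling** for bioactivity bounds (the sources are silent on
this): "=" rows are always labeled; "< x" rows are kept only when the
bound itself forces activity (true pX strictly exceeds the bound's pX, so
"< 1 nM" is active at cutoff 9), and ">"-type rows symmetrically force
inactivity; anything else is unlabeled and excluded from aggregation. An
even active/inactive split gives median 0.5, which is *not* active — only
unanimous-majority evidence promotes a compound.

**Identity.** Deduplication is by InChIKey (not SMILES text), computed by
OpenBabel from the standardized structure; equal InChIKeys are checked to
imply equal canonical SMILES within a run.

## What the synthetic generator emulates — and what it does not

`generate_chemotype_library()` plants a known chemotype structure: five
default seed scaffolds (adamantane cage, biphenyl, 1,3-benzodioxole,
1-phenylpiperazine, and a purine–oxolane nucleoside analog), chosen once
because they are multi-ring (surviving the genericity filter), mutually at
MCS distance > 0.5 (so they cluster apart), inside the element whitelist,
and representative of the chemotype families enriched screens typically
surface. Analogs are the seed plus 1–3 substituents (methyl, ethyl,
hydroxyl, amino, fluoro, methoxy, carboxyl) at open ring positions, so
each analog's Murcko framework *is* its seed by construction and recovery
is decidable exactly. Decoys are ring-free chains and can never contain a
ring query. Requested fractions of records carry chiral side chains
(default 20 %), counter-ion fragments (20 %), and protonated amines (10 %)
to exercise standardization. Bioactivities are normal on the pX scale —
actives N(9.5, 0.3), inactives N(5, 0.5), three replicates — placing
actives comfortably above the cutoff and inactives ~8 sd below it.

Passing the planted-recovery test therefore shows the pipeline's machinery
is sound (standardization round-trips, scaffolds are extracted faithfully,
clusters and queries are generated and matched correctly). It does *not*
show that real screens achieve perfect recall: real actives are not exact
substituted copies of a handful of frameworks, real assay data mix
endpoints, units and quality, and real libraries contain chemotypes that
partially overlap the queries. Published hit counts at live-data scale
(hundreds of MCSs, tens of thousands of hits) depend on database state and
licensed libraries and are deliberately not reproduced here.

Study sizes (5 families × 8 analogs + 50 decoys per library; 2410-record
pagination; 3 replicates) are the package's validation conditions: large
enough that recall and decoy counts are meaningful, small enough that the
whole study runs in well under a minute on one core.

## Degenerate inputs and edge behaviour

* Empty pages, empty `data` arrays, entries without bound ligands, and
  chemcomp payloads without a descriptor are all legal inputs with defined
  results (empty tables, typed `no_structure` errors for skippable
  components); parsers ignore unknown keys.
* `total_count = 0` plans zero fetches; a one-scaffold target skips matrix
  construction; an empty cluster list yields an empty query table.
* Records failing any standardization stage are quarantined with the stage
  name as the reason; the clean/quarantine split is part of the public API.
* HTTP transport (live mode only) retries 3× with exponential backoff and
  drops the row on persistent failure, mirroring the filter-on-status-class
  practice; all tests run on fixtures.

## Known limitations

* The SMILES/SMARTS reader covers the dialects the pipeline emits and the
  fixtures use (organic subset, brackets, aromatic lowercase, ring-closure
  reuse, `[#n]` primitives, bond alternatives); it is not a full grammar —
  e.g. wildcard atoms, recursive SMARTS and atom maps are rejected.
* MCS is exact only within its time budget; the `approximate` flag is
  carried through to emitted queries.
* No fingerprint similarity, docking, tautomer handling or hit ranking
  beyond counts: the package stops where the substructure-screening recipe
  stops.
* 2D depictions use a force-directed layout of the molecular graph; they
  are schematic match illustrations, not publication-quality structure
  drawings.

## A minimal run

```{r example, eval = FALSE}
study <- run_synthetic_study(rng_seed = 1)
study$metrics[c("families_recovered", "analog_recall", "decoy_hits",
                "rediscovery_fraction_input")]
autoplot(study$clusters)
plot_px_distribution(study$activities, cutoff = 9)
```
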