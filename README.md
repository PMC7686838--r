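# scaffquery

Ligand-based in-silico drug repurposing in R: harvest target→ligand evidence
from public-data payloads, standardize the chemistry, label actives on the pX
scale, mine enriched Bemis–Murcko scaffolds into maximum-common-substructure
(MCS) SMARTS queries, and screen drug libraries by substructure to nominate
repurposing candidates.

## Who this is for

Computational chemists and data-mining practitioners who want a tested,
offline-runnable version of the classic ligand-based repurposing recipe:
collect every compound known to bind the targets of a disease, distill the
chemotypes those actives share, and ask which approved or investigational
drugs carry the same substructure. The package was built around two
motivating use cases — a rare membrane-transporter deficiency and the
COVID-19 target landscape — but every stage is generic.

## The method

For a disease *D* the pipeline proceeds:

1. **Retrieval.** Targets associated with *D* are fetched from a
   target-prioritization service (association score ≥ 0.99, up to 10,000
   targets), mapped to UniProt accessions, and cross-referenced to
   protein–ligand structures (bound nonpolymer components, minus
   co-crystallization agents) and to bioactivity databases. Paged activity
   retrieval plans `⌈total_count / 1000⌉` calls with offsets 0, 1000, 2000, …
   so every record is fetched exactly once. All parsers operate on the
   payload shapes of the live services and run identically on canned
   fixtures, so nothing here needs a network connection.
2. **Standardization.** Each compound is curated in six steps: stereo
   descriptors cleared on the molecular graph; salt/solvent fragments
   stripped (and reported); protonation-adjustable charges neutralized
   (quaternary nitrogens flagged as permanently charged); an element
   whitelist (H, C, N, O, F, Br, I, Cl, P, S) enforced; and canonical
   SMILES / InChI / InChIKey generated. InChIKey is the identity and
   deduplication key throughout. Failing records are quarantined with a
   reason, never silently dropped.
3. **Activity labeling.** Measurements (Ki, IC50, Km, …) are placed on one
   axis as pX = −log10(molar value); a compound is active when pX > cutoff
   (default 9, i.e. sub-nanomolar; a transporter case would use 6).
   Replicates are aggregated as the median of the binary labels per
   (target, InChIKey); only median = 1 survives. Active ligands are merged
   across sources and concatenated with structure-derived ligands.
4. **Scaffolds and queries.** Bemis–Murcko frameworks (ring systems plus
   connecting linkers; double-bonded attachments retained) are extracted
   and deduplicated per target; single-ring frameworks are discarded as too
   generic. Per target, scaffolds are clustered by MCS distance
   d(a,b) = 1 − m/(|a|+|b|−m), where m is the heavy-atom count of the
   maximum common connected substructure (element and bond-aromaticity
   matching), with average-linkage hierarchical clustering cut at distance
   0.5. Each cluster yields one SMARTS query — the MCS over all member
   scaffolds, written with `[#n]` atom primitives and explicit bonds — and
   every query is verified to match 100 % of its members.
5. **Screening.** Libraries (SDF or SMILES tables) are standardized with the
   same model and searched by subgraph matching. Hits carry matched atom
   indices (SVG highlights available), per-query and unique-compound counts,
   cross-library overlap by InChIKey, and a rediscovery flag for hits that
   were already in the active input set.

A synthetic-data module generates chemotype libraries with planted scaffold
families plus scaffold-free decoys, replicated bioactivities with controlled
pX distributions, and canned API payloads — so the full pipeline runs, and
its recall is measurable, with no downloads.

## Worked example

```r
library(scaffquery)
library(tibble)

compounds <- tibble(
  uniprot_id = "P11166",
  compound_id = c("CPD1", "CPD2", "CPD3", "CPD4"),
  smiles = c("CCc1ccc2ncccc2c1",      # ethylquinoline
             "Cc1ccc2ncccc2c1.Cl",    # methylquinoline hydrochloride
             "COc1ccc2ccccc2c1",      # methoxynaphthalene
             "CC(C)CCO"))             # ring-free

clean <- standardize_compounds(compounds) |> quarantined()
clean$clean[c("compound_id", "std_smiles", "inchikey")]
#> 1 CPD1  CCc1ccc2c(c1)cccn2  VDOYSQQOKJDYDR-UHFFFAOYSA-N
#> 2 CPD2  Cc1ccc2c(c1)cccn2   LUYISICIYVKBTA-UHFFFAOYSA-N   (Cl stripped)
#> 3 CPD3  COc1ccc2c(c1)cccc2  LUZDYPLAQQGJEA-UHFFFAOYSA-N
#> 4 CPD4  OCCC(C)C            PHTQWCKDNZKARW-UHFFFAOYSA-N

queries <- clean$clean |>
  extract_scaffolds() |>             # quinoline (x2 parents) + naphthalene
  filter_generic_scaffolds() |>
  cluster_scaffold_table(threshold = 0.5) |>
  generate_queries()
queries$smarts
#> [1] "[#6]:1:[#6]:[#6]:[#6](:[#6]:[#6]:1):[#6]:[#6]:[#6]"
```

The two fused frameworks sit at MCS distance 1 − 9/11 ≈ 0.18, co-cluster at
the 0.5 threshold, and fold into one 9-atom fused-ring query (the ring-free
compound contributes no scaffold). Screening a small library:

```r
lib <- tibble(library = "demo", compound_id = c("D1", "D2", "D3"),
              name = c("aminoquinoline", "naphthol", "butylamine"),
              smiles = c("Nc1ccc2ncccc2c1", "Oc1ccc2ccccc2c1", "CCCCN"))
lib_clean <- quarantined(standardize_compounds(lib))$clean
hits <- substructure_screen(lib_clean, queries)
hits$compound_id
#> [1] "D1" "D2"          # butylamine carries no fused-ring substructure
flag_rediscoveries(hits, clean$clean$inchikey)$rediscovery_fraction
#> [1] 0                  # no library hit was part of the active input set
```

The packaged 18-query enriched-MCS set
(`system.file("extdata", "table2.smarts", package = "scaffquery")`) works the
same way: its adamantane-cage query matches amantadine, its piperazine query
matches any piperazine-containing drug.

A command-line front end over the same functions ships at
`inst/scripts/scaffquery.R` (subcommands `synth`, `standardize`, `label`,
`scaffolds`, `queries`, `screen`, `run`).

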