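---
title: "Detecting, dating and classifying ubiquitylation-site gains in the human lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, dating and classifying ubiquitylation-site gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Lysine residues of human proteins are ubiquitylated (and modified by
ubiquitin-like proteins) at tens of thousands of positions, as catalogued
by diGly-remnant proteomics. Some of those lysines are not ancestral: they
arose by substitution somewhere on the human lineage during primate
evolution, and each such gain is a candidate for an evolutionarily novel
regulatory interaction. `ubigain` implements the comparative-genomic screen
that finds these gains: it maps observed modified lysines into orthologous
mammalian protein alignments, discards sites that cannot represent a
primate-lineage gain in a reliably aligned region, dates each surviving
gain to a branch of the human lineage, and asks whether the gained lysine
is a new target, an additional target next to a conserved one, or a
replacement for an ancestral target that was lost.

## Inputs and coordinate conventions

Three inputs drive a run:

* **Site tables** (TSV): one row per observed modified lysine, with the
  protein accession, the 1-based position of the lysine in that accession's
  coordinate system, and a 13-mer peptide with the modified lysine at the
  center. Positions are taken on the accession as given; the package never
  remaps accessions between databases. Rows whose center residue is not a
  lysine, or whose peptide is malformed, are rejected with per-row
  diagnostics. Sites repeated across experiments are collapsed to one row
  per `(protein, position, modification)` with the experiment labels
  unioned; conflicting peptides keep the longer one and are logged.
* **Per-gene protein alignments** (FASTA, one record per species). Rows
  use the multiz-derived dialect: `-` for gaps, `X` for unknown residues,
  `*` for stop codons. All three, and species absent from a file, are
  MISSING: they carry no evidence and can never support or veto a lysine
  call. Protein positions are 1-based; alignment columns are 0-based
  internally and 1-based in reports.
* **A species tree with a clade configuration** (newick + YAML). The
  packaged default covers 37 mammals: human, 10 other primates, 8 other
  Euarchontoglires, 10 Laurasiatheria, 3 Afrotheria, 2 Xenarthra, 2
  Metatheria and platypus. The configuration tags each species with its
  major clade (`pri`/`eua`/`lau`/`afr`/`xen`/`met`/`pro`) and defines the
  *clade ladder*: the nested clades human ⊂ human+chimp ⊂ African great
  apes ⊂ great apes ⊂ apes ⊂ catarrhines ⊂ simians ⊂ haplorhines ⊂
  primates. Nesting, monophyly and the primates/`pri` identity are
  verified at load time.

The screen operates on protein-level alignments. The source alignments of
this kind are distributed as CDS alignments; translating codon alignments
to protein rows is a documented extension point rather than a feature,
because every decision the pipeline makes is at the amino-acid level.

## Mapping and screening

A site is first located in its alignment: the reported position must hold
a lysine in the ungapped human row and the flanking context must equal the
reported peptide (truncation at protein termini and `X` wildcards
allowed). If the reported position does not hold a lysine — source
databases disagree on coordinates more often than on peptides — a unique
exact occurrence of the peptide elsewhere in the protein remaps the site
with a logged correction; zero or multiple occurrences reject it
(`PEPTIDE_MISMATCH`).

Four independent filters follow; all failing reasons are collected, and a
site is retained only if none fail:

* `MULTI_COPY` — the exact human sequence occurs in more than one gene
  set, so orthology is uncertain. Near-identical paralogs are out of reach
  without external annotation; the criterion is exact full-length identity.
* `EUARCHONTOGLIRES_K` — a non-primate Euarchontoglires species (the
  critical close outgroup: treeshrew, mouse, rat, kangaroo rat, guinea
  pig, squirrel, rabbit, pika) carries a lysine aligned with the site. Any
  such lysine implies the residue predates primates.
* `MANY_NONPRIMATE_K` — among non-primate species with an observed
  residue, the fraction carrying lysine exceeds
  `nonprimate_lysine_max_fraction` (default 0.2). This rejects ancestral
  or highly recurrent lysines that a single-outgroup check would miss.
* `LOW_CONSERVATION` — the mean identity to the human row, averaged over
  the `conservation_window` (default 10) residues on each side of the
  site (site column excluded, reference row excluded from the average,
  MISSING excluded), falls below `conservation_min_identity` (default
  0.6). Poorly conserved regions cannot support a per-column claim.

The two numeric thresholds deliberately reify what was a qualitative
manual-inspection judgment in the original screen, so both are exposed as
parameters with permissive defaults; reproducing any particular curated
set is explicitly not promised. An all-MISSING outgroup passes with a
`low_information` flag rather than being discarded — a screen over draft
genomes would otherwise throw away exactly the cases (like a missing
gibbon row) that the dating step is designed to handle. An explicit
curation table (`keep`/`drop` per site, with a reason) lets a user
reproduce by-hand decisions reproducibly.

## Dating gains

A retained gain is dated to the **smallest ladder clade containing every
primate observed with the lysine**. The implementation finds the MRCA of
the lysine-bearing primates on the topology and takes the first ladder
clade covering its descendant tips; because ladder clades are nested and
monophyletic this equals a direct minimal-superset scan, and the test
suite checks that equivalence against an independent brute-force oracle.
Consequences of the rule:

* Patchy presence (e.g. lysine in human and marmoset but not rhesus)
  dates to the minimal covering clade (simians); no loss-aware parsimony
  is attempted.
* When the species separating the chosen clade from larger ones are all
  MISSING, those larger clades cannot be excluded; the call is the
  smallest clade and every consistent clade is reported in an ambiguity
  list (the missing-gibbon situation).
* A lysine in a distant non-primate (say, dog) that survived the
  fraction filter is homoplasy: it is logged and never widens the clade,
  treating it as an independent event rather than shared ancestry.

## Window classification

Ubiquitylation sites can migrate: a nearby lysine may take over the
modification. For each retained gain the `window_radius` (default 5)
reference residues on each side are scanned — offsets count human
residues, skipping gap columns, matching how positions are described in
the literature. An offset is a *conserved alternative lysine* when the
fraction of non-MISSING non-primate species carrying K there is at least
`conserved_min_fraction` (default 0.75; no quantitative criterion exists
in the source literature, so the threshold is a parameter). The
classification is then:

* **new** — no conserved offset exists;
* **additional** — some conserved offset retains its lysine in the human
  row: old and new targets coexist;
* **shifted** — conserved offsets exist but none retains a human lysine:
  the ancestral target was lost as the novel one appeared.

One design choice deserves a note. A stricter definition of "shifted"
would demand the ancestral lysine be absent from *every* member of the
origin clade, but the canonical shifted example in this field (an ape-dated
gain whose ancestral neighbouring lysine survives in gibbon while all
great apes lost it) fails that test even though it is plainly a shift.
The classifier therefore keys "shifted" on the human row only, and records
whether the loss is clade-complete as a per-offset flag
(`lost_in_origin_clade`). This keeps the three classes a partition of the
retained set: every retained site gets exactly one class, and `new` is
exactly the absence of conserved offsets. Raising
`conserved_min_fraction` can only move sites into the `new` class, a
monotonicity the tests assert.

Gains are finally cross-referenced with an acetylation site table by
exact `(protein, position)` match, marking lysines under dual
modification (ubiquitylation/acetylation cross-talk candidates).

## The simulator

`sim_config()`/`simulate_dataset()` generate fully ground-truthed data so
the entire pipeline can be validated without external inputs. Sequences
evolve down the species tree under a uniform substitution model with
Poisson(rate × branch length × length) substitutions per edge (branch
lengths default to 1 when the newick carries none); the planted column is
then forced — an ancestral residue drawn from {Q, E, R}, the
substitutions actually observed at documented gain sites, replaced by K
in exactly the planted clade — and a confounder pattern is applied:
`euarchontoglires_K`, `nearby_conserved_K` (the additional-site pattern),
`ancestral_K_shift` (the shifted-site pattern), `many_nonprimate_K`, or
`low_conservation`. Chance lysines inside the ±5 window are scrubbed
(replaced by serine) before planting, so the expected window class is
exact by construction. Choices and their consequences:

* **Indel-free simulation.** Screening and dating are column-based; gaps
  are exercised by hand-written fixtures instead, which keeps the truth
  bookkeeping exact (planted column = position − 1).
* **Uniform substitution model**, not an empirical matrix: no pipeline
  stage depends on substitution-model realism, only on presence/absence
  of lysine and on identity fractions.
* The simulator does not imitate real divergence levels, alignment error,
  or assembly-quality artefacts. Passing on simulated data therefore
  demonstrates the logic (filters fire exactly when their pattern is
  present; dating and classification invert the generative process), not
  performance on real proteomes, where alignment quality and the two
  reified thresholds dominate.

Determinism: every output is reproducible byte-for-byte from the seed;
each gene uses an independent stream derived from `seed` and the gene
index.

## Numerical and degenerate-input choices

* Fractions compare with `>=`/`<=` at thresholds (a fraction exactly at
  the threshold passes the conservation filter and counts as conserved in
  the window).
* Windows clipped at protein termini proceed on the available offsets and
  are flagged.
* Peptide-conflict ties in deduplication break by length, then
  alphabetically, so output order is deterministic (sorted by accession
  and position).
* An empty site table yields empty, well-formed outputs and a zero
  funnel; funnel monotonicity (input ≥ non-redundant ≥ mapped ≥ retained)
  is asserted on every run.

## Validation scale

The shipped test suite and acceptance script validate on simulated data
at sizes chosen to exercise every branch of the ladder and every
confounder with comfortable margins: 500 zero-noise genes for
branch/class recovery, 100 genes per confounder rejection check, 10,000
random primate lysine-sets against the brute-force dating oracle, and a
noise ramp (rates 0–0.5 substitutions/site/branch-length) for the
monotone-degradation property. A full-scale run over the published
ubiquitylome tables and the 46-way alignment set is supported by the same
`run_pipeline()` entry point but requires those external downloads.

## Known limitations

* Orthology, alignment and realignment are out of scope: inputs are taken
  as aligned, and the paralogy filter sees only exact duplicate human
  sequences.
* No accession cross-mapping: a site reported on one database build of a
  protein will not be found in an alignment keyed to a different build
  unless a `gene_map` is supplied.
* Dating ignores lysine losses within the covering clade (no parsimony),
  and non-primate homoplasy is logged rather than modelled.
* The two screening thresholds and the window-conservation threshold are
  operational stand-ins for curatorial judgment; results at full scale
  depend on them.
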