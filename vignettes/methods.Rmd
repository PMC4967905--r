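---
title: "Deciding whether domain-architecture differences of orthologs are annotation errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether domain-architecture differences of orthologs are annotation errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofixr)
```

## The problem

When the predicted proteomes of two closely related species are compared,
orthologous proteins frequently differ in domain architecture — the ordered,
N-to-C sequence of conserved domain families. Taken at face value such
differences look like proteome innovation: new domain combinations arising
since the species diverged. But draft genomes annotated by automated
pipelines are riddled with structural gene-model errors — two genes merged
into one chimeric model, one gene split into fragments (sometimes across
scaffolds of a draft assembly), terminally truncated models, models extended
by a foreign domain, and genes missed entirely. Every one of these errors
masquerades as an architecture difference.

`orthofixr` implements a pipeline for deciding, pair by pair, whether an
architecture difference reflects a prediction error rather than biology, and
for correcting the erroneous model. Because real proteome pairs come with no
ground truth, the package also contains a first-class synthetic generator
that builds a proteome pair from a common ancestor, injects each error kind
with truth labels, and emits transcript (EST) evidence — so that every stage
of the pipeline is verifiable end to end.

## The pipeline

1. **Domain calling** (`call_domains()`): each catalog family's consensus is
   locally aligned against the protein, accepted hits are masked and the
   family re-scanned so tandem repeats are recovered. Architectures are
   compared as exact linear family-name strings (`compare_architectures()`),
   with repeat counts significant by default.
2. **Orthology** (`reciprocal_best_hits()`): two proteins are orthologs when
   each is the other's highest-scoring match and their identity over aligned
   columns reaches the cutoff (default 60%). Iterated mapping of unpaired
   proteins onto disjoint intervals of a partner protein
   (`map_partial_orthologs()`) reveals split-gene topologies.
3. **Error audit**: two misprediction rules flag suspect models — an
   extracellular-class and an intracellular-class domain co-occurring with no
   transmembrane segment between them (`check_localization_conflict()`), and
   drastic truncation of a globular domain relative to its family mean length
   (`check_truncation()`). Putative fusion junctions are tested against ESTs
   (`test_fusion_junction()`): reads spanning the junction support it; reads
   that stop (3' end) just before it, or start (5' end / signal peptide) just
   after it, with no spanning read, refute it.
4. **Correction** (`fix_prediction()`), in fixed tier order — the cheapest
   evidence first: (1) transcript evidence trims or splits a model at an
   EST-refuted junction; (2) translated six-frame search of the genomic locus
   merges split fragments or rebuilds a damaged model with the partner as
   template; (3) ortholog projection merges fragments whose combined
   architecture equals the intact partner's. Tier 3 is marked lower
   confidence in the output because convergent annotation errors in both
   species can fabricate exactly this kind of agreement.
5. **Missing genes** (`find_missing_gene()`): a sampled protein with no
   reciprocal best hit is searched against the partner genome in all six
   reading frames; a hit chain covering at least 80% of the query is turned
   into a gene model, translated, and its domains called.
6. **Survey** (`run_survey()`): samples multi-domain proteins, runs the whole
   chain, and tallies a concordance report — orthologs present/absent,
   architectures same/different before and after correction, and agreement
   of each member with a trusted reference proteome.

## The alignment substrate

All stages rest on one affine-gap Smith–Waterman aligner (Rcpp) with
BLOSUM62 scores, gap open 11 and gap extend 1 — blastp-like defaults; a gap
of length $k$ costs $11 + k$. We reproduce rankings and identities, not any
specific tool's scores. Two choices are deliberate:

* **Identity denominator.** Identity is matches over *all* aligned columns,
  gap columns included. This is the conservative reading; the quantity is
  not otherwise pinned down and the choice is stated so the 60% cutoff has
  one meaning everywhere.
* **Deterministic traces.** Among equal-scoring traces the trace prefers
  diagonal, then up, then left, and the traceback starts at the first
  maximal cell in row-major order, so reports reproduce bit for bit.

There is no E-value model: the synthetic universe is closed, so raw score
thresholds (configuration, default 30) suffice. Six-frame search
(`translated_search()`) reports forward-strand 0-based half-open DNA
coordinates regardless of hit strand, and extracts multiple loci per frame
by masking accepted hits.

## What the generator emulates — and what it does not

`simulate_proteome_pair()` builds a domain catalog (consensus sequences with
per-family localization class and mean length), an intronless ancestral
genome on scaffolds with at least 200 nt intergenic spacers, and two
daughter species.

* **Divergence.** Substitutions are drawn per residue with probability $p$,
  conditioned on BLOSUM62 target frequencies restricted to off-diagonal
  moves, so pairwise ortholog identity is approximately $1-p$. All
  substitution load is placed on one branch (species A is the ancestor copy)
  because that makes the calibration exact: $p = 0.188$ yields a mean
  pairwise identity of about 81.2%, the regime of interest for lancelet-like
  species pairs. Splitting the load across branches would require a
  back-substitution correction for the same pair identity while changing
  nothing the pipeline sees.
* **Membrane topology stand-ins.** A signal peptide is an initial methionine
  plus a 12-residue strongly hydrophobic run; a transmembrane segment is an
  internal 19-residue hydrophobic run. Both are detectable by a windowed
  Kyte–Doolittle rule (window 19, mean ≥ 2.5) without external predictors.
  Catalog consensi are hydropathy-capped (no 19-window mean ≥ 2.0) so a
  globular domain can never mimic the membrane motif; linkers are drawn from
  hydrophilic residues for the same reason.
* **Errors.** Fusion merges two adjacent plus-strand genes through a
  translated linker; fission cuts at an inter-domain linker (the only place
  the real splits occur in the motivating cases) into fragments at
  consecutive loci, optionally claimed on a different scaffold; truncation
  removes a terminal part of the last domain leaving under 60% of the
  family mean, so the truncation rule always has something to find;
  chimeric extension appends a foreign domain of opposite localization;
  omission drops the model but leaves the DNA. Per-kind rates are free
  parameters of the generator — the source material reports no per-kind
  frequencies — and default to a total error load of about 21% of genes,
  enough to exercise every correction path in a 100-protein sample.
* **ESTs.** Single-pass cDNA reads drawn from one gene's mRNA each; a read
  never spans two genes, which is precisely why no read can support an
  injected fusion junction. The library is end-biased, as real single-pass
  libraries are: at coverage ≥ 2 every gene gets one 5'-anchored and one
  3'-anchored (stop-containing) read, the remainder starting uniformly.
  This determinism is what makes "every error with transcript evidence is
  correctable" a theorem of the generator rather than a lottery.

Not emulated: introns and splice variants (correction is modeled as
translated search, not spliced alignment), nucleotide indels, EST sequencing
error, and codon-usage realism. Passing tests therefore demonstrate the
pipeline's logic — evidence handling, tie-breaking, bookkeeping — under the
stated noise model, not robustness to intron-aware gene structure or dirty
transcript data.

## Numerical choices

* **Domain-call acceptance: 0.45 × consensus self-score.** The audit must
  *see* a domain truncated to roughly half its family length (a perfect
  49%-length fragment scores about 0.49 × self-score), so the acceptance
  threshold sits below that with margin while still rejecting sub-half
  spurious hits. Overlapping hits keep the higher score (ties: longer hit,
  then earlier start); overlap above 20% of the shorter hit is a conflict.
* **Truncation threshold 0.6, strict.** Flags the ~0.49 worked case with
  margin; a hit at exactly 0.6 is not flagged.
* **Junction window 30 residues.** Spanning requires 30 aligned residues on
  both sides; boundary evidence (stop/start reads) counts within ±30 of the
  candidate junction. Candidate junctions are linker-gap midpoints, which
  sit within ~28 residues of the true junction for the generator's linker
  lengths, so the window is matched to the candidate uncertainty.
* **Partial-ortholog disjointness: < 20% mutual overlap** of intervals on
  the intact protein — tolerant of alignment-end wobble while preserving
  N-part/C-part semantics. The same 20% governs hit-overlap resolution and
  chain assembly.
* **Genome scans at 0.25 × query self-score** with ≥ 80% query coverage,
  where coverage counts residue-to-residue aligned columns (an early version
  counted interval extent and was fooled by a relative with one domain
  gapped out). Single covering hits are preferred; only failing that is a
  strictly collinear chain assembled (gaps ≤ 1 kb).
* **Percentages round half up** to integers, which is what reproduces the
  printed 43/53/45 from 40/49/42 of 93.
* **Problem sizes.** The default survey scenario uses a 160-gene ancestor,
  24 families, and a 100-protein sample; the divergence calibration uses
  500 genes. These sizes give every error kind multiple instances per run
  while keeping a full survey in the low minutes on one core.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_proteome_pair(seed = 1)
report <- run_survey(sim$predicted_a, sim$predicted_b, sim$reference,
                     sim$ests_a, sim$ests_b, sim$catalog,
                     survey_config(sample_size = 100, seed = 1))
report
glance(report)          # one-row concordance summary
tidy(report)            # per-pair provenance: flags, verdicts, tiers
autoplot(report)        # before/after correction bar chart
report_percentages(report)
```

On this seed the survey finds orthologs for 89 of 100 sampled proteins, 14
of the 89 pairs discordant in architecture; after tiered correction 0 remain
discordant, and all 11 absent orthologs are recovered from the partner
genome with their full architectures. A pair whose discordance is real
biology (injected at the truth level rather than as an annotation error)
stays discordant — correction can only restore what evidence supports.

## Design decisions taken where the design was open

* Species A is sampled and species B carries the default error load;
  profiles for both species are exposed, so asymmetry is a default, not a
  constraint.
* Only the single reciprocal best match is paired; co-orthologs from
  post-divergence duplication are deliberately not chased (a known
  limitation of the approach, accepted here).
* A repeat-count-only difference counts as non-identical (repeat counts are
  part of the linear architecture string); `collapse_repeats = TRUE`
  collapses runs for users who prefer the looser reading. Repeat-run
  differences classify as `repeat_count_change` ahead of the terminal
  extension categories, since an extra copy of the flanking family is more
  informatively a run-length change.
* The error-free ancestor stands in for the trusted reference proteome; the
  reference block of the report is computed by best hit with no identity
  cutoff, mirroring how a curated database is actually used.
* The CLI the pipeline might have grown is intentionally absent: the
  exported functions, `scripts/acceptance.R`, and this vignette are the
  interface.

## Known limitations

* Intronless gene models only; a spliced aligner would be needed before the
  correction tiers apply to real draft genomes.
* The localization rule inherits the catalog's localization classes; on
  real data those come from curation and are noisier.
* Junction refutation without any spanning-read requirement on the *intact*
  side can misfire near protein termini; in the survey it is only consulted
  for pairs that are already architecture-discordant.
* Divergence is substitution-only, so alignment identity is an unbiased
  estimate of sequence identity; indel-rich lineages would bias the 60%
  cutoff in ways the generator cannot show.
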