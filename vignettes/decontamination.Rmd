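---
title: "Taxonomy-aware contig decontamination: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy-aware contig decontamination: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxsieve)
```

## The screening model

`taxsieve` decides, contig by contig, whether the proteins an assembly encodes
are consistent with the genome they were deposited in. The model rests on two
observations. First, a protein's ranked homology hits against a
taxonomy-aware reference carry a taxonomic signal: when the top-scoring run of
hits agrees on a taxon that is not the host's, the protein likely did not come
from the host. Second, contamination arrives as whole contigs, whereas a
horizontally transferred (HGT) gene arrives embedded in a host chromosome.
Aggregating per-protein calls over contigs therefore both boosts accuracy
(ambiguous proteins inherit their contig's context) and separates
contamination from HGT.

The procedure is strictly two-step: per-protein calls
(`call_protein_taxon()`), then contig consensus (`contig_consensus()`). There
is no third mechanism; everything `decontaminate()` reports follows from these
two.

Assumptions worth stating explicitly:

* the reference is broad enough that genuine host proteins find same-taxon
  hits — hosts from undersampled lineages drift toward `UNCLASSIFIED`, which
  biases the tool toward *keeping* their contigs (a conservative failure);
* contigs are not chimeric: one contig, one source organism;
* annotation quality is good enough that proteins map to their contig
  (one membership entry per protein; a protein spanning two contigs is
  rejected as inconsistent input).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `rank` | `kingdom` | decision rank, one of the six fixed ranks |
| `threshold` | 0.5 | alien fraction *a/(a+h)* at or above which a contig is removed |
| `min_pident` | 20 | minimum percent identity of a usable hit (`-p`) |
| `cap` | 10 | window size for the confidence score |
| `excluded_taxids` | query taxid (CLI) | subject taxids ignored during calling |

A single rank is screened per run; screening several ranks is a loop over
runs. The 0.5 default makes removal a strict majority among *classified*
votes. Unclassified votes are excluded from the denominator deliberately:
counting them as host votes would conflate absence of evidence with host
evidence, and contigs with no evidence at all must be kept rather than
removed. The identity floor of 20 percent discards twilight-zone alignments
whose taxonomic labels are unreliable. The confidence window of 10 mirrors
the top-10 taxon support ratio, so the reported confidence and the
`taxon_support_ratio()` diagnostic are directly comparable; confidence is
reported per protein but does not weight the contig vote (one protein, one
vote), because the consensus is defined over discrete calls.

Excluding the query's own taxid matters whenever the reference contains the
query genome's own deposited proteins: those self-hits would otherwise confirm
the host label for every protein — contaminants included — and mask exactly
the contamination being screened for. The R-level functions leave
`excluded_taxids` empty by default (a reference may legitimately lack the
query), while the command-line `screen` run excludes the configured query
taxid unless told otherwise.

## Numerical and degenerate-case choices

* **Hit ordering.** Lists sort by decreasing bitscore; ties break by higher
  percent identity, then lexicographic subject id. The tie-break is arbitrary
  but fixed — identical inputs must yield byte-identical outputs, which the
  suite asserts via file checksums.
* **Absent ranks.** A lineage may be unlabeled at a rank (common in practice,
  e.g. no kingdom on many prokaryote paths). Absence is an explicit `NA`,
  never an empty string: a best hit unlabeled at the decision rank yields
  `UNCLASSIFIED`, and an unlabeled hit inside the list terminates the trimmed
  prefix. Silent coercion of gaps into labels would bias votes.
* **Dominant alien label ties** break lexicographically.
* **Empty inputs.** An empty hit list trims to empty and calls
  `UNCLASSIFIED` with confidence 0 (the label is `UNCLASSIFIED` exactly when
  confidence is 0); an all-unclassified contig has alien fraction 0 and is
  kept at every threshold.
* **AUC.** The rank-based (Mann–Whitney) formulation with midrank ties, which
  equals the brute-force count of wins plus half-ties over all spike×host
  pairs; the suite checks both that identity and agreement with an
  independent ROC package.
* **Support ratio with fewer than ten hits** uses the available hit count as
  denominator; a fixed denominator of ten would spuriously penalize proteins
  from sparse families. No hits at all gives `NA`, not 0 — "no evidence" and
  "contradicting evidence" must stay distinguishable.

## What the synthetic data emulates — and what it does not

The generator builds the study conditions the benchmark runs under. A
`mock_reference()` draws, per taxon, independent random amino-acid family
seeds (50 families per taxon in the standard setup; lengths 120–240) and four
variants per seed mutated at 5% per position — emulating a clustered,
taxonomy-labeled protein database with within-family divergence. Mock
proteomes are further mutated copies of one taxon's seeds, annotated onto
contigs; `generate_mix()` then transfers randomly selected donor proteins
onto virtual contigs of 1/2/5/10/20 proteins at spike levels from the
canonical grid (100–3200), keeping ground truth. Spiked virtual contigs are
pure-alien, matching the benchmark design; a mixed-contig HGT stress test is
expressible through `contig_consensus()` directly.

Because family seeds are independent random sequences, k-mer sharing across
families is negligible and the deterministic `toy_search()` (distinct shared
4-mers; bitscore = 2 × count, an arbitrary fixed scale since only ordering
matters; identity approximated by best-diagonal coverage) separates the taxa
essentially perfectly. That is the point — the benchmark validates the
*decision machinery* (trimming, calling, voting, removal, scoring) under
known ground truth, not the homology search. Real proteomes violate the
generator's simplifications in known ways: gene families are related across
taxa, identity distributions are continuous down into the twilight zone,
reference coverage is uneven, and real assemblies have heterogeneous contig
sizes. Perfect AUC on the mock conditions therefore does not promise perfect
AUC on real genome pairs; closely related host/contaminant pairs and
undersampled hosts are exactly where performance degrades.

## Problem sizes

The standard benchmark screens a 300-protein recipient (60 contigs of 5)
against a 450-protein donor across spike levels {100, 400} × contig sizes
{1, 5, 20} × 10 replicates — 60 full screening runs per sweep, which keeps a
sweep around a minute on one CPU while still exercising every removal path;
the exhaustive consensus oracle enumerates all vote configurations up to six
proteins per contig. Per-replicate seeds derive deterministically from one
master seed (`derive_seed()`), so sweeps rerun byte-identically.

## Known limitations

* Non-integrated extrachromosomal elements (plasmids) are removed when all
  their genes vote alien, even when they are genuine residents of the
  sequenced organism — an inherent consequence of contig-level voting.
* Highly fragmented assemblies (many 1–2 gene contigs) weaken the consensus;
  a single-protein contig stands or falls on one call.
* Hosts poorly covered by the reference are largely `UNCLASSIFIED` and their
  contamination escapes removal (contigs with no classified votes are kept).
* Chimeric contigs violate the one-contig-one-source assumption; the majority
  side of the chimera decides its fate.
* Screening operates on the annotated proteome; nucleotide-only contigs with
  no predicted proteins are invisible to it.
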