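---
title: "Total-evidence parsimony and the P5-swimming-crab morphotype: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-evidence parsimony and the P5-swimming-crab morphotype: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimpars)
```

## The problem

Portunoid crabs include the classic "swimming crabs", in which the fifth
pereiopod (P5) is remodelled into a paddle-like swimming leg. Whether this
P5-swimmer morphotype arose once or repeatedly can be addressed by scoring a
dependency-aware morphological character matrix across a broad taxon sample,
combining it with aligned gene partitions into a total-evidence supermatrix,
searching for maximum-parsimony (MP) trees, reconstructing ancestral states
under unordered parsimony, and asking whether reconstructed stem species
satisfy a fixed character-state definition of the morphotype.

`swimpars` implements that pipeline end to end, with simulators that let
every stage be exercised offline.

## The character catalog and inapplicability logic

The shipped catalog holds 59 discrete characters of the crab axial skeleton
(sternum, pleura, endophragmal infoldings such as the median plate, junction
plate and sella turcica), the extrinsic musculature of pereiopods 2–5, and
external features of P5 and the carapace. Hierarchical coding is explicit:
each character may carry *inapplicable-if* conditions naming a controlling
character and the controlling state(s). A taxon whose median plate is absent
(character 7, state 0) cannot be scored for median-plate shape characters;
those cells must be `-`.

Three deliberate conventions:

* **Verbatim retention of source inconsistencies.** Two conditions in the
  source list cite states their controller does not declare (character 12's
  `8(3)`; character 27's `9(2)`). They are kept verbatim, flagged at load
  time as `UNDECLARED_CONTROLLING_STATE` warnings, and can never match.
  This preserves the source text while surfacing the inconsistency.
* **Missing controllers are permissive.** A `?` on a controlling character
  cannot *prove* inapplicability, so the dependent is treated as applicable
  and no violation is raised. The consequence is that `is_applicable()` is
  monotone: resolving a `?` can only flip applicable → inapplicable.
* **Validation never errors.** `validate_matrix()` returns a report of
  every cell-level problem (state where inapplicable, `-` where applicable,
  undeclared code), ordered by taxon and character, so a matrix can be
  repaired in one pass.

## Scoring model

All characters are equally weighted and unordered: any state-to-state change
costs one step. Missing (`?`), inapplicable (`-`), and nucleotide ambiguity
symbols are scored as full ambiguity over the column's alphabet — gaps are
treated as missing data. Scoring `-` like `?` is a known simplification
relative to modern inapplicable-aware algorithms; it matches the behaviour
of the standard MP tools this pipeline emulates, and the catalog's
dependency logic is enforced at the data-validation layer instead.

Tree lengths use a bitmask Fitch pass (Hartigan counting, so multifurcating
trees are scored softly); MPR state sets — every state a node attains in at
least one minimum-length reconstruction — come from a uniform-cost Sankoff
down-pass/up-pass. Both are property-tested against exhaustive enumeration
of internal labelings on all trees up to 7 tips, and tree lengths are
additionally cross-checked against an independent implementation.

## Tree search

`mp_search()` uses random stepwise-addition starting trees followed by
first-improvement branch swapping, collecting all distinct equally optimal
topologies (with an equal-length plateau sweep around the optima, bounded
by `max_trees`). Two neighborhoods are provided: NNI and SPR. The SPR
neighborhood is generated from a rooted representation anchored at the
first taxon's pendant edge (prune any non-root subtree, regraft on any
remaining edge); requesting TBR falls back to this SPR set — a documented
design choice, adequate at the package's desk scale, where searches are
verified against exhaustive enumeration up to 7 taxa and against the known
generating topology of simulated 12-taxon studies.

**Collapsing rule.** After the search, `collapse_unsupported()` contracts
every internal branch whose minimum possible number of changes over all
most-parsimonious reconstructions is zero, all at once (the conservative
reading of "unsupported nodes were collapsed"). Note that headline tree
lengths always refer to binary trees: two branches can each admit a
change-free reconstruction although no single reconstruction frees both,
so rescoring a collapsed (polytomous) tree softly can exceed the binary
optimum. Consensus trees are never scored for headline lengths.

**Bootstrap.** `bootstrap_support()` resamples all columns with
replacement; each replicate runs a reduced search (one addition sequence,
NNI). When a replicate yields several optimal trees, each split receives
fractional credit, which avoids order dependence. Support is mapped onto a
tree's nodes by bipartition identity.

## Ancestral states and the morphotype rule

`reconstruct()` requires a fully resolved rooted tree: when the strict
consensus contains polytomies the user must supply one resolution — the
package flags the situation rather than resolving silently, because
reconstructions on an arbitrary resolution would carry false precision.
Inapplicable cells enter as full ambiguity; node–character pairs whose
controller is reconstructed entirely in a controlling state are annotated
`INAPPLICABLE_CONTEXT` (a reporting convention only).

The morphotype rule is a map from character id to allowed states; the
shipped fixture encodes the state combination shared by all P5-swimmers in
the study sample (twelve characters; the P5 anterior coxa muscle must
originate at the median plate, states `2` or `3` of character 34). Merus
length (character 44) only grades swimming effectiveness and is not part
of the rule. Verdicts are three-valued:

* terminals: `SWIMMER` if every rule character matches; `?` on a rule
  character gives `POSSIBLE`; a disallowed state — including `-`, since the
  required state then cannot hold — gives `NON_SWIMMER`;
* nodes: `SWIMMER` iff every MPR set is a subset of the allowed states,
  `POSSIBLE` iff all sets intersect them but at least one is not a subset,
  else `NON_SWIMMER`. The subset/intersection semantics is the conservative
  reading of rendering reconstruction ambiguity graphically.

One consequence worth noting: a strict reading of the rule classifies a
taxon that lacks the propodus lobe (character 46) as a non-swimmer even if
it shows the diagnostic muscle origin — which is exactly why the unusual
morphology-only taxon in the study sample (a swimmer by the authors'
judgement, with state `34(3)` but no propodus lobe) sits at the edge of
the definition. The classifier reports the failing characters so such
cases are visible rather than silently absorbed.

## Synthetic data: what it emulates and what it does not

* `simulate_tree()`: Yule (pure-birth) trees conditioned on the tip count.
  The source study has no generative model; pure birth is the simplest
  adequate choice.
* `simulate_morphology()`: symmetric k-state Markov characters simulated by
  uniformization (so true per-branch change counts are recorded, letting
  tests assert that parsimony never overcounts truth). Controllers are
  simulated first; dependents are masked to `-` wherever the controller
  takes a controlling state, and the hidden evolution of masked characters
  is discarded rather than re-seeded on regain — visible only in long
  simulations.
* `simulate_sequences()`: GTR+G+I with per-site rates (invariant with
  probability `p_inv`, otherwise gamma with mean 1). Default partition
  lengths are the study's printed ones — 671, 657, 426, 328 bp, 2082 sites
  in total. The study does not print its GTR parameters; the defaults are a
  fixed transition-biased, AT-rich parameterization typical of arthropod
  mitochondrial data (exchangeabilities 1,4,1,1,4,1; frequencies
  0.3/0.2/0.2/0.3; shape 0.5; invariant fraction 0.3), chosen once and not
  tuned.
* `make_fixture_study()`: a 12-taxon miniature with a designed swimmer
  clade, one within-clade loss branch, an outgroup lacking the median
  plate, 30 simulated filler characters and four short partitions carrying
  the signal of a known tree.

A green test on synthetic data establishes internal correctness of the
machinery (search recovers a known low-homoplasy topology; true ancestral
states fall inside MPR sets at low rates), not that any empirical claim is
reproduced: real alignments have correlated sites, heterogeneous taxon
sampling and alignment uncertainty that the generator does not emulate, and
the study's own alignment is unpublished, so its printed tree length cannot
be recomputed offline.

## Numerical choices and degenerate inputs

* Site patterns are compressed before scoring; all set arithmetic is exact
  integer bitmask work (alphabets are capped at 30 states).
* Wholly missing columns contribute length zero; a column's alphabet is
  the set of states observed in it (plus declared states when a catalog is
  available), which cannot change unordered lengths.
* Search tie-breaks (addition placement, neighbor order) are randomized
  but driven entirely by the configuration seed; fixed seed means
  bit-identical outputs, which the pipeline's checksummed manifest makes
  testable.
* Trees with fewer than 4 taxa are rejected; non-binary trees are rejected
  where the contract requires binarity (ASR, collapsing input) and scored
  softly where it does not (length of consensus-like trees).

## Known limitations

* Inapplicable-aware parsimony (treating `-` as its own grade of absence)
  is not implemented; `-` is missing data at scoring time.
* The TBR option is an SPR-neighborhood fallback; "new technology" search
  strategies (ratchet, drifting, sectorial) are out of scope.
* Bootstrap on matrices with many equally optimal replicate trees stores at
  most a bounded pool per replicate, so fractional credits for weakly
  supported splits are approximate; certainty (100%) and near-certainty
  behave exactly.
* The OTU fixture's gene-to-accession assignment is a best-effort
  transcription of a table whose flattened text is ambiguous in places;
  the bookkeeping counts it is used for are robust to this.
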