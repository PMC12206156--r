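---
title: "Alignment-graph assembly and polishing of viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-graph assembly and polishing of viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viralign)
```

## The method

`viralign` performs reference-guided assembly of small (viral-scale)
genomes. It needs two inputs: a *backbone* — any reasonably related
genome, typically another strain of the same virus or a de novo draft —
and the sequencing reads. One round of refinement has three steps.

**1. Alignment graph construction.** The backbone
$S = s_1 s_2 \ldots s_n$ seeds a graph with one node $v_i$ per base,
labeled $s_i$, chained by edges $(v_i, v_{i+1})$ of weight 0, plus two
virtual, unlabeled source/sink nodes flanking the chain. Each read is
aligned to the backbone and *threaded* through the graph by walking its
CIGAR: a read base that matches the backbone base maps onto the existing
node $v_j$ and increments the weight of the entering edge
$(v_{j-1}, v_j)$; a mismatched or inserted base creates a new node
labeled with the read base; a deletion contributes an edge that bypasses
the deleted backbone nodes. Every consecutive pair of visited nodes is
connected by an edge whose weight counts the supporting reads. After all
reads are threaded, nodes with the same label and a shared parent are
merged repeatedly (their entering-edge weights summed) and parallel
edges are collapsed, giving the simplified weighted DAG.

**2. Maximum total-weight path.** With $w(v, u)$ the weight of edge
$(v, u)$, the dynamic program

$$\mathrm{DP}[u] = \max_{v \in \mathrm{Pred}(u)} \{\mathrm{DP}[v] + w(v, u)\}$$

is evaluated in topological order (nodes without predecessors score 0),
the node with the global maximum is located, and the path ending there
is reconstructed by backtracking stored best predecessors — $O(|E|)$
overall. The concatenated node labels of that path are the refined
genome: the sequence supported by the most reads, with the weight-0
backbone spine available wherever read coverage is absent.

**3. Iteration to a fixpoint.** The refined genome becomes the backbone
of the next round; all reads are re-aligned and a fresh graph is built.
Iteration stops when the genome produced by an iteration is identical to
the previous one. Convergence is fast in practice — typically two to
four iterations — but the stopping rule alone does not guarantee
termination, so the driver adds an iteration cap (default 10) and an
oscillation check (a genome repeating a non-adjacent earlier iterate
stops the loop and returns the highest-weight iterate). *Polishing* a
draft assembly is the identical algorithm with the draft as the initial
backbone; short accurate reads pass through the same code path.

## Design choices in the graph

Several details are deliberate choices where the construction above
leaves room:

* **Backbone edges start at weight 0 and are never deleted.** Read
  support is then the only signal, and zero-coverage stretches fall back
  to the backbone instead of breaking the assembly.
* **Node ranks.** Every node carries a sortable rank: backbone nodes
  their position, a mismatch node slightly before the position it
  replaces, insertion nodes strictly between their flanking backbone
  positions (chained in read order). All threading edges therefore go
  strictly forward in rank, which makes the graph acyclic by
  construction and gives the tie-breaks below a stable, reproducible
  order.
* **Merge safety.** Merging two nodes that are connected by a directed
  path would collapse that path into a cycle, so such candidates are
  skipped — the usual partial-order-graph rule. The common case is a
  read inserting a base immediately before an identical backbone base.
  The check is a reachability probe inside a narrow rank window, backed
  by a global acyclicity re-validation after every merge round; merges
  are also restricted to nodes within one backbone position of each
  other, since remote same-parent pairs (reachable only through deletion
  bypass edges) are exactly the cycle-prone ones. Two backbone nodes
  never merge, which preserves backbone coordinates.
* **Integer weights everywhere.** The DP uses integer edge weights only,
  so ties are exact and runs are bit-reproducible. Equal-scoring
  predecessors are resolved by a parsimony rule first — prefer the path
  carrying fewer labeled nodes, so an equally supported single bypass
  edge beats the longer walk through a spurious repeat copy (the rule
  cannot collapse zero-coverage stretches, because a node with
  predecessors must extend one of them) — then by preferring backbone
  edges, the smaller-rank predecessor, and a non-`N` label; among equal
  DP maxima the largest-rank node wins, which extends the path through
  the zero-weight backbone tail rather than stopping early.
* **`N` handling.** `N` never matches any base during threading, so it
  spawns a new node; `N`-labeled nodes lose ties in the DP.

## The built-in aligner

The package carries its own seed-and-extend aligner so that the whole
pipeline runs without external binaries: exact k-mer seeds (13-mers,
falling back to 11/9-mers for highly divergent backbones) are collected
on both strands, the densest diagonal cluster selects the strand and a
target window, and a banded alignment with match $+1$, mismatch $-2$,
gap $-2$ (linear), free end-gaps on the backbone side, produces the
CIGAR. The band covers the seed window plus a drift margin of about
0.2 read lengths in total width. Indels in the resulting CIGAR are then
left-aligned against their local context — the canonical placement used
across read mappers. This matters more here than in variant calling:
reads sharing an indel must support the *same* bypass or insertion edge,
otherwise their weight scatters across the equivalent placements inside
a repeat and can let a spurious duplication survive (see *Limitations*).
External aligners are supported either through a SAM/BAM file (single
pass) or a command template such as
`"minimap2 -a {ref} {reads} > {sam}"` that is re-invoked each iteration;
only primary mapped records are threaded, so secondary or supplementary
placements cannot double-count read support.

## Evaluation metrics

`report()` computes the metric suite against a ground-truth genome, all
from exact unit-cost (Levenshtein) alignments computed in a diagonal
band that widens automatically until the optimum is provably inside it
(if the banded distance $d$ does not exceed the slack $w$ beyond the
diagonal corridor, no optimal path can leave the band):

* **edit distance** — minimum substitutions plus single-base
  insertions/deletions; exact.
* **mismatches / indels / indel length** — substituted columns, maximal
  gap runs (events), and total gap columns of one optimal global
  alignment; by unit-cost optimality,
  `mismatches + indel_length == edit_distance` for the reported
  alignment.
* **genome fraction** — percent of truth bases in matched columns of an
  alignment with free end gaps on the assembly side, so a truncated
  assembly loses fraction instead of accumulating giant indels.
* **similarity** — $100\,(1 - \text{edit distance}/\text{truth
  length})$, floored at 0.

These re-implement the familiar assembly-QC quantities directly from
their definitions rather than wrapping an external QC tool; a tool that
derives them from local alignment chains can differ by sub-percent
amounts on real data. `interior_breakdown()` restricts the counts to
columns more than a chosen trim (default 50 bp) from the truth ends,
separating residual end effects from interior accuracy.

## The read simulator

`simulate_reads()` emulates the distributional shape of long-read
simulators: per-read percent identity is drawn from a normal
distribution truncated above at `identity_max` and below at
`2 * identity_mean - identity_max` (so the configured mean is
preserved) and realised as `round((1 - identity) * length)` uniformly
placed errors; read lengths are normal, clipped to
`[200, genome length]`; half the reads are reverse-complemented. The
default error composition is 40% substitutions, 20% insertions, 40%
deletions, following published error decompositions of current
nanopore (R10.4-class) reads, where indels — deletions especially —
rival substitutions and insertions are the rarest class. Exactly
`round(divergence * n)` substitutions, logged with positions, derive a
backbone of known similarity from a truth genome.

Read *placement* deserves a note. The generator samples fragment
positions uniformly **with overhang past both genome ends**, truncating
at the boundary and rejecting visible spans under 200 bp — the terminal
fragments of a fragmented linear molecule. This keeps coverage
near-uniform up to the ends. The alternative (`placement =
"contained"`, reads fully inside the genome) leaves a coverage ramp of
roughly one read length at each end; a simple expectation calculation
shows that with 50× coverage of 2 kb reads on a 10 kb genome the ramp
leaves a base 50–150 bp from an end covered by only ~2–5 reads, so a
handful of uncorrectable backbone errors and single-read miscalls
persist near (and occasionally beyond) a 50 bp trim. Since the method
itself cannot correct what no read covers, the overhang model is the
default study condition, and the contained model remains available for
experiments on end behaviour.

What the simulator does **not** model: k-mer-dependent (systematic)
error patterns, junk/chimeric reads, adapters and base-quality scores.
Passing the synthetic suite therefore demonstrates the graph, DP,
iteration and evaluation machinery under realistic error *rates* and
read geometry, not robustness to systematic sequencer artefacts — for
real data, an external aligner tuned for the platform is recommended at
the alignment stage.

## Standard desk conditions

The package's reference scenarios, used throughout the tests, are a
10 kb random truth genome with (a) a backbone at 93% similarity, 50×
coverage, 2 kb mean read length, identity (95, 99, 2.5) — the typical
simulated-nanopore setting — and (b) a backbone-divergence ladder at
15/20/25/30% with 30× coverage and 4 kb reads, sharing one read set so
only the backbone varies. Under (a) the assembler reaches its fixpoint
in 2–3 iterations and the final genome interior (outside 50 bp at each
end) is exactly error-free; under (b) the interior stays error-free at
every rung. A full run takes on the order of a minute on one core.

## Numerical and degenerate-input behaviour

* Alignment bands always widen until provably exact for evaluation;
  the read aligner's band is fixed by its seed window (a read whose
  optimum leaves that envelope would be mis-scored, which the seed
  cluster makes unlikely).
* Empty backbones, empty read sets, zero aligned reads, malformed
  FASTA/FASTQ/CIGARs and cyclic graphs all raise immediate, specific
  errors; an unalignable subset of reads is dropped with a warning.
* With a fixed seed every stage is deterministic, including
  tie-breaking; two runs of the same command produce byte-identical
  output (manifests differ only in timestamps).

## Limitations

* **Length bias of the objective.** The maximum *total* weight path
  prefers, all else equal, paths with more edges. At a tandem repeat
  this can retain a duplicated copy when a few reads with coincidental
  insertion errors thread through it while the majority's deletion
  support sits on a single bypass edge. Indel left-alignment
  concentrates that support and makes the case rare, but an occasional
  single residual indel event near a repeat is possible at extreme
  backbone divergence.
* **Single haplotype.** A 50/50 mixed-strain sample has no unique
  maximum-weight path; the driver detects oscillation and returns the
  best iterate, but strain separation is out of scope.
* **Ends follow the backbone.** Where no read covers the genome ends,
  the output reproduces the backbone there (the weight-0 spine);
  `trim_unsupported_ends` optionally trims the output to the
  read-supported region.
* **Linear genomes.** No circular closure; a circular genome is
  assembled as a linear sequence with its ends left to the backbone.
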