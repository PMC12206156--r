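# viralign

Iterative alignment-graph assembly and polishing of viral genomes in R.

## The problem

Viral samples are routinely sequenced at high depth, but de novo
assemblers struggle with short genomes, uneven coverage and high-error
long reads, while naive reference mapping inherits every difference
between the sample and the chosen reference. `viralign` targets the
middle ground: it takes *any* related genome as a backbone — another
strain, or a rough de novo draft — and lets the reads vote it, base by
base, into the sampled genome. The same machinery polishes an existing
draft with long or short reads. It is aimed at researchers assembling
or polishing small (roughly 5–30 kb) genomes: HIV, SARS-CoV-2, measles
and the like.

## The method

One refinement round has three steps:

1. **Alignment graph.** The backbone `S = s1 s2 … sn` becomes a chain of
   single-base nodes `v1 → v2 → … → vn` with edge weight 0 (plus virtual
   source/sink ends). Each read is aligned to the backbone and threaded
   through the graph: a matching base re-uses the backbone node and
   increments the entering edge's weight, a mismatched or inserted base
   adds a new node labeled with the read base, a deletion adds an edge
   bypassing the deleted nodes. Nodes with the same label and a shared
   parent are merged with their entering-edge weights summed, and
   parallel edges are collapsed. Edge weights now count supporting
   reads.

2. **Maximum total-weight path.** In topological order,

   ```
   DP[u] = max over predecessors v of { DP[v] + w(v, u) }
   ```

   and the path ending at the global maximum, recovered by
   backtracking, is the refined genome — the sequence supported by the
   most reads, with the weight-0 backbone spine covering any
   zero-coverage gaps. Runs in O(|E|).

3. **Iterate.** The refined genome becomes the next backbone; reads are
   re-aligned and the graph rebuilt. Iteration stops when an iteration
   reproduces the previous genome exactly (typically after 2–4 rounds).

Everything runs self-contained: a built-in seed-and-extend banded
aligner handles read placement, or you can supply SAM/BAM from an
external aligner. A seeded simulator generates truth genomes, divergent
backbones and noisy long/short reads, and an evaluation module computes
genome fraction, mismatches, indel events/length, edit distance and
similarity against a ground truth — so the entire pipeline is testable
offline. See `vignette("alignment-graph-assembly")` for the model,
parameter choices and limitations.

## Worked example

Assemble a simulated 3 kb virus from a 93%-similar backbone and 30×
nanopore-like reads (mean length 600 bp, identity ~95%):

```r
library(viralign)

truth    <- random_genome(3000, seed = 5)
backbone <- mutate_genome(truth, 0.07, seed = 6)   # 93% similar strain
cfg <- sim_config(genome_length = 3000, coverage = 30,
                  mean_read_length = 600, seed = 7)
sim <- simulate_reads(truth, cfg)                  # 165 reads

res <- assemble(backbone, sim$reads, assembly_config())
res
#> <assembly_result> 3000 bp after 2 iteration(s); converged (fixpoint)
#>   iteration 1: 3000 bp, path weight 82300, edit to previous 210
#>   iteration 2: 3000 bp, path weight 83011, edit to previous 0

report(res$final_genome, truth)
#> <eval_report>
#>   genome fraction : 100.000%
#>   assembly length : 3000
#>   mismatches      : 0
#>   indels (events) : 0
#>   indel length    : 0
#>   edit distance   : 0
#>   similarity      : 100.00%
```

Iteration 1 already corrects the 210 backbone differences (edit
distance to the *previous* genome, i.e. the backbone, is 210); iteration
2 confirms the fixpoint. The path weight is the total read support along
the chosen path. The final genome here is exactly the truth: every
backbone substitution was outvoted by the reads.

The same functions drive the command line:

```sh
viralign simulate --length 3000 --divergence 0.07 --coverage 30 \
         --mean-len 600 --seed 7 --out-dir sim/
viralign assemble --reference sim/backbone.fasta --reads sim/reads.fastq \
         --out-dir asm/
viralign evaluate --assembly asm/final.fasta --truth sim/truth.fasta \
         --out report.tsv
```

(The launcher script is installed under `exec/viralign` in the package
library; polishing a draft is `viralign polish --draft draft.fasta …`.)

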