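---
title: "Training Boolean logic models with data-driven link integration"
author: "BoolSigNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training Boolean logic models with data-driven link integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolSigNet)
```

## The problem

Literature-derived prior knowledge networks (PKNs) of signal transduction
are signed, directed, and incomplete; purely data-driven networks (DDNs)
inferred from stimulus/inhibitor perturbation experiments are complete in
a different sense — they only ever connect the proteins the experiment
can see — and scale poorly. BoolSigNet combines the two: it infers a DDN
from the perturbation data, adds DDN links missing from the PKN as
*integrated* candidate links, scores each candidate by how well physical
protein–protein interaction (PIN) evidence supports it, and then trains
the combined logic superstructure against the data so that only links
the data and the penalties jointly justify survive.

## The model

A logic model is a signed hypergraph over species. Each hyperedge is one
candidate gate: its inputs are ANDed (an input with sign $-1$ enters as
$1-x$), and hyperedges sharing a target are ORed. A candidate model is a
bit string $P$ over the $M$ hyperedges. Simulation clamps stimulated
species to 1 and inhibited species to 0 (inhibition clamps the drugged
protein itself, and wins if a species is both), starts every other
species at 0 — no signal before stimulation — and iterates the
synchronous update to a fixed point. Species still changing after
$\lceil 1.2\,n \rceil$ synchronous steps (signal crosses each of $n$
species at most once in a feed-forward cascade; 20% slack for
near-cyclic structures) are declared unresolved and returned `NA`. An
`NA` prediction facing an observation contributes `naFac` (default 1,
the maximal squared deviation on $[0,1]$ data) to the error, so models
that fail to settle are penalized maximally.

Training minimizes

$$\theta(P) \;=\; \theta_f(P)
 \;+\; \alpha\,\frac{\sum_{e\,\in\,\mathrm{prior}} \nu_e P_e}
                    {\sum_{e\,\in\,\mathrm{prior}} \nu_e}
 \;+\; \beta\,\frac{\sum_{i\,\in\,\mathrm{int}} w_i \nu_i P_i}
                   {\sum_{i\,\in\,\mathrm{int}} w_i \nu_i},$$

where $\theta_f$ is the mean squared error between the normalized data
(continuous in $[0,1]$) and the Boolean prediction over all $N$ measured
points, $\nu_e$ is the gate arity (a 2-input AND counts exactly twice a
single edge), and $w_i \in (0,1]$ is the PIN-derived penalty weight of
an integrated link. Each size term is normalized by its own total
possible weighted size, so $\alpha$ and $\beta$ stay comparable across
superstructures of different size; an empty group contributes 0. Under
this normalization both terms are bounded by 1, which means $\beta$
values on the order of the achievable fit gains (roughly $10^{-2}$ to
$10^{-1}$) are the interesting regime for the synthetic benchmarks in
this package, while very large $\beta$ simply forbids integrated links.
With all $w_i = 1$ the PIN plays no role and, with $\beta = \alpha$,
prior and integrated links are penalized by the same coefficient — the
PIN-free single-penalty objective in spirit; the two size terms keep
their own denominators, a choice isolated in `objectiveScore()`.

## Pipeline stages and the choices behind them

**Inference.** FEED builds, per readout, a Boolean effect table: a
condition has an effect when it shifts the readout by more than
$k_\sigma\,\varepsilon$ relative to the reference ($\varepsilon$ is the
measurement uncertainty on the normalized scale, default 0.1, and
$k_\sigma = 2$). The reference is the fully unperturbed condition when
the design has one, otherwise 0 — normalized values are changes from
baseline, so an absent control row is equivalent to a zero reference.
The tables become links by three rules: a lone stimulus effect gives
$s \to m$; a lone inhibitor effect gives $i \to m$ with the opposite
sign (clamping $i$ to 0 and seeing $m$ drop means $i$ activates $m$);
and when inhibiting $i$ abolishes an $(s,m)$ response the path is
rerouted as $s \to i \to m$, dropping the direct edge, while an enabled
response gives $s \to i$ and $i \dashv m$. Only single-perturbation
contrasts are used; combinatorial rows stay in the tables for
diagnostics. ARACNe and CLR are native minimal implementations on a
plug-in mutual-information matrix (3 equal-width bins on $[0,1]$,
natural logs; cues enter as binary variables); their undirected edges
receive direction only during integration, cue → readout, and edges
orientable in neither direction are skipped with a warning. External
engines (e.g. Bayesian-network structure learning) plug in as adapter
functions `dataset -> SignedNetwork`.

**Compression.** Nodes with no measured node downstream
(non-observable) or no perturbed node upstream (non-controllable) are
deleted iteratively, deletions first, because deletions can create new
bypass candidates but not vice versa. Remaining unmeasured, unperturbed
nodes are bypassed with sign-product edges. Bypassing is restricted to
nodes with in-degree 1, or out-degree 1 *with a positive outgoing
edge*: collapsing a multi-input node through a negative edge would
replace $\lnot(x \lor y)$ by $\lnot x \lor \lnot y$ and change the
logic of the remaining nodes, which is precisely what compression must
not do. This is checked by a property test: on random acyclic PKNs the
compressed and uncompressed networks produce identical Boolean values
at every measured node under every cue combination. The test generates
networks whose roots are all stimuli; a non-controllable node feeding a
negative edge is a constant source whose removal genuinely changes the
logic downstream, so fully uncontrollable branches with inhibitory
edges are the one structure for which deletion-based compression is not
value-preserving — a limitation shared by any compression that removes
constant nodes without constant-folding them.

**Integration.** Every DDN link absent from the compressed network as a
direct edge of that sign is added with provenance `integrated`, even
when an indirect compressed path exists — training decides inclusion,
and $\beta$ controls the cost. Each added link is mapped back to the
*uncompressed* PKN: candidates are the cross product $U \times V$, with
$U$ the link source plus its downstream closure stopping at any other
cue and $V$ the target plus its ancestor closure stopping at any
measured node, minus pairs already adjacent in the PKN and self-pairs;
if everything is filtered the link itself is kept so the candidate set
is never empty. Links with an endpoint unknown to the PKN are flagged
novel. Unsigned links default to activation, a logged assumption.

**Weighting.** The reliability of an integrated link is the minimum
Dijkstra distance over its candidate pairs in the PIN, with edge
traversal weight $1/\text{evidence count}$ — well-supported
interactions are cheap, so a short, well-evidenced path makes a link
plausible. Weights are $w_i = d_i / d_{\mathrm{cap}}$ with
$d_{\mathrm{cap}}$ the largest finite reliability across records;
disconnected or unmappable links get the maximal weight 1 rather than
exclusion — missing PIN support should penalize, not forbid, since the
optimizer may still need the link to explain the data. The published
form of the reliability-to-penalty mapping is not fully specified, so
this convention is deliberately isolated in `penaltyWeights()`.

**Training.** The genetic algorithm uses linear-rank selection
(pressure 1.2), uniform crossover, per-bit mutation with probability
`mutationProb`$/M$ (half an expected flip per child by default),
elitism of 5, and stops after 500 generations or 100 without
improvement; `nRuns` independent runs (default 3) are pooled, every
evaluated bit string is recorded, and the family of models within
`relTol` (default 10%) of the best score is reported alongside the
best. Ties are resolved toward fewer selected hyperedges, then the
lexicographically smallest bit string, so results are reproducible
bit-for-bit given the seed. `exhaustiveSearch()` enumerates all $2^M$
models (guarded at $M \le 20$) and serves as the optimality oracle in
the test suite; on the benchmark instances used there (superstructures
with $M \le 12$) the GA attains the exhaustive optimum.

Under exhaustive optimization the selected weighted integrated size
$\sum w_i \nu_i P_i$ is provably non-increasing and the fit
non-decreasing in $\beta$. The *count* of selected integrated links
inherits that monotonicity exactly when integrated gates are
single-input with equal weights, which is how the sweep property is
exercised; with heterogeneous weights a cheaper-but-larger selection
can in principle replace an expensive small one, so the weighted size
is the quantity the package asserts in general.

## What the synthetic benchmarks emulate — and what they do not

`randomGoldStandard()` draws a random acyclic activation network
(12 nodes, 3 stimuli, 2 drug-inhibited nodes, 4 readouts, forward edge
density 0.25 by default) with every readout reachable from a stimulus,
and interprets it as an OR-only logic model. `simulateDataset()`
produces the single+pairs design typical of ligand/inhibitor screens —
an unperturbed control, each stimulus alone, each stimulus × inhibitor
pair — with additive Gaussian noise truncated to $[0,1]$ (default 0)
and a baseline time-0 layer of zeros, so datasets round-trip through
MIDAS files. `syntheticPIN()` wraps a network's undirected skeleton
with decoy interactions and evidence counts drawn from 1–5.

These fixtures reproduce the structure of perturbation screens, not
their biology: real data have correlated replicate noise, saturating
dose responses, incomplete designs, feedback loops, and readouts that
are imperfect proxies of activity. Passing the benchmarks therefore
shows the machinery is correct and internally consistent — zero
spurious FEED links on noise-free data, severed-dependency recovery at
5% noise — not that any particular biological network will be
recovered. The severed-link benchmark (`recoveryBenchmark()`) deletes a
gold edge only when the deletion demonstrably changes a readout
response *and* clean-data inference yields an integrable link, lying on
a gold path through the deleted edge, whose addition improves the fit;
without that precondition the replicate would test an unrestorable
scenario (for instance, a dependency whose direct edge still exists in
the compressed remainder), not the pipeline.

## Numerical choices and degenerate inputs

Fixed points are detected by exact state equality; after the iteration
cap, $n$ extra steps flag every still-changing species as `NA`.
Normalization uses a Hill transform $|r|^2/(|r|^2 + \mathrm{ec50}^2)$
of the relative change with a noise floor below which changes map to 0
and a saturation level above which they map to 1; it is a deliberately
simple thresholded stand-in, and pre-normalized MIDAS input bypasses
it. Constant variables get zero mutual-information rows; zero-variance
CLR rows get $z = 0$; the ARACNe data-processing inequality uses strict
inequality, so all-equal triangles lose no edge. Empty models are legal
(cues clamped, everything else 0); an empty candidate-model group
contributes 0 to the objective; datasets with no non-missing training
points are rejected. Problem sizes in the shipped tests (networks of
6–12 nodes, superstructures to $M = 12$ for exhaustive enumeration, 20
recovery replicates, 50 GA-oracle instances) were chosen so the whole
suite exercises every property at full strength while remaining quick
to run routinely.

## Known limitations

Synchronous Boolean semantics only — no fuzzy logic, ODEs,
asynchronous updates, or multi-value states; one training timepoint
(feedback-loop training over two timepoints is out of scope); FEED
exploits single-perturbation contrasts only; identifier namespaces of
PKN and PIN must already agree (no mapping layer); and the PIN is
consumed as given rather than rebuilt from source interaction
databases.
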