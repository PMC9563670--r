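---
title: "Single-chain subpathway impact analysis: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-chain subpathway impact analysis: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathimpact)
```

## The question the package answers

Given transcriptome profiles of the same tissue under two conditions —
canonically tumour samples before and after chemotherapy — which signalling
routes through known pathways have become more active? Whole-pathway
enrichment blurs this question: a pathway is a web of branching and crossing
chains, and activation is usually confined to particular routes. `pathimpact`
therefore decomposes each pathway into *single-chain subpathways* — maximal
directed chains from an entry gene (no parent) to an end gene (no child) —
and scores each chain's activation separately.

## From KGML to chains

Pathway topology is read from KGML (KEGG Markup Language). Only gene entries
become nodes; compound and map entries are dropped. Every typed relation is
collapsed to a sign: induction-like subtypes (activation, expression,
phosphorylation, and others) carry `+1`, inhibition-like subtypes
(inhibition, dissociation, dephosphorylation) carry `-1`. The full coding is
`kegg_relation_signs()` and can be overridden by passing a modified table to
`parse_kgml()`. Two rows deserve attention because they are easy to guess
wrong: *repression* and *missing interaction* both carry `+1` in this coding,
as does *ubiquitination*, while *dissociation* carries `-1`.

Two topological features prevent a pathway from being a plain DAG of genes,
and each gets its own normalization scheme:

* **Loops.** A directed cycle (feedback loop) is condensed into a single
  conjunctive node carrying all member genes; the node is considered active
  only when all members are active. After condensation the graph is acyclic.
  Strongly connected components are found with `igraph`; the package's tests
  check them against a brute-force mutual-reachability oracle.
* **Binding events.** A binding/association relation between genes B and C
  means the bound position of a chain may be occupied by B alone, by C
  alone, or by the complex B+C — the position is satisfied when at least one
  member is present. `expand_bindings()` generates one graph variant per
  choice; independent binding events combine multiplicatively (capped, with
  deterministic lexicographic truncation). KGML `group` entries (complexes)
  are translated into binding events among their components.

Chains are then enumerated by depth-first search over every binding variant,
deduplicated by their node-label sequence, and reported in lexicographic
order, so enumeration is deterministic regardless of input order. A node
that is both entry and end yields a chain of length 1.

The chain definition starts at entry nodes by default. The alternative
reading — chains may start anywhere, which subsumes all suffix chains and
produces much larger per-pathway counts — is available as
`enumeration_config(start_policy = "any_node")`; we default to `entry_only`
because the entry-to-end definition is the stricter one and the other is
recoverable from it.

## Differential expression from detection calls

The expression evidence is deliberately coarse: a gene is *present* in a
sample when at least one of its probes has an Affymetrix detection call of
`P`. Marginal (`M`) calls count as absent by default (conservative;
`marginal_present = TRUE` flips this). Presence shifts between conditions
are tested per gene:

* paired designs: McNemar's test on discordant pairs,
  $\chi^2 = (b - c)^2 / (b + c)$, where $b$ counts pairs present-before /
  absent-after and $c$ the reverse; $b = c = 0$ gives $\chi^2 = 0$, $p = 1$;
* unpaired designs: Pearson's chi-square on the 2×2 presence-by-condition
  table, without continuity correction (a correction is available via
  `correction = TRUE` in both tests).

Alongside, $\Delta E$ is the log2 fold change of summarized expression (post
over pre), with fold change $> 1$ meaning upregulation after treatment.
Means are floored at 1.0 before the ratio so that background-corrected
intensities near zero cannot produce infinite fold changes. Genes with
several probes are summarized by the per-sample maximum probe intensity
(consistent with the any-probe presence rule; `probe_summary = "mean"` is
available). A gene is flagged differentially expressed (DE) at `p < 0.05` by
default.

## The impact factor

Each chain is scored by propagating a *perturbation factor* from its entry:

$$PF(g) = \Delta E(g)\,\chi^2(g) + \beta_{ug}\,PF(u)$$

where $u$ is the unique upstream gene in the chain and $\beta_{ug}$ is the
step sign. For an all-induction chain the terminal factor telescopes to
$\sum_i \Delta E_i \chi^2_i$, which the tests assert, and negating all fold
changes negates every factor. Merged binding nodes are represented by the
member with the largest own perturbation $|\Delta E \cdot \chi^2|$
(`binding_agg = "mean"` averages instead); condensed loop nodes, being
conjunctive, always average their members. A chain gene absent from the
expression data contributes zero to its own term and only relays the
upstream signal.

The chain's *impact factor* combines the propagated perturbation with
pathway-level enrichment evidence:

$$IF = \log\frac{1}{P_{path}} +
      \frac{\sum_{g \in chain} |PF(g)|}{\overline{|\Delta E|}\; N_{de}}$$

with the natural log. $P_{path}$ is the upper-tail hypergeometric
probability of the pathway's DE-gene count given the universe (genes shared
between the expression platform and the loaded pathways, configurable);
$N_{de}$ is the number of DE genes among the chain's member genes and
$\overline{|\Delta E|}$ their mean absolute log fold change. Two readings of
the typeset formula are possible; we divide by
$\overline{|\Delta E|} \times N_{de}$ (rather than multiplying the ratio by
$N_{de}$) because the score should reward concentrated perturbation, not
raw DE-gene counts, and because this is the impact-factor form of the
signalling-perturbation literature the method builds on. When a chain holds
no DE gene the second term is defined as 0, so the score is always finite
and nonnegative.

The chain's direction is the sign of its terminal perturbation factor — the
chain's output node carries the propagated signal, so a positive terminal
factor is read as an upregulated (activated) subpathway.

## Significance

Condition labels are permuted — within patients for paired designs (each
pair swaps its pre/post labels independently with probability 1/2, the only
faithful within-patient scheme), across samples otherwise — and the entire
scoring pipeline is recomputed on each permuted dataset: fold changes,
presence tests, enrichment and impact factors alike. Only a full recompute
makes the null valid; freezing any ingredient would leak the observed
labels into the null.

Empirical p-values compare each observed impact factor against the pooled
null scores of chains of the *same length* (longer chains accumulate more
perturbation, so pooling across lengths would bias against short chains).
The estimator is the add-one tail proportion
$p = (1 + \#\{null \ge obs\}) / (1 + M)$, which cannot return zero and
remains valid at small permutation counts. The default is 10 permutations,
matching the workflow the method was described with; the package's own
calibration and benchmark tests use 100, and `n_permutations` should be
raised whenever the p-value resolution $1/(M+1)$ matters. Benjamini–Hochberg
adjustment yields q-values.

Two cohorts (e.g. a paired and an unpaired one) are combined by
`overlap_subpathways()` / `run_overlap()`: a chain is retained when its
empirical p-value is below the threshold in both cohorts *and* its terminal
perturbation factor is positive in both — significant in the same,
upregulated direction. The per-pathway summary reports significant-chain
counts per cohort, the overlap count, and the mean over retained chains of
`max(q_a, q_b)` as a conservative combined FDR.

## What the synthetic generator emulates — and what it does not

`generate_expression()` simulates a probe-level microarray dataset with
detection calls: log-normal expression (gene baseline sd 1, noise sd 0.5 on
the log2 scale), a shared per-patient intercept (sd 0.7) in paired designs,
two probes per gene, and Bernoulli presence calls at a baseline rate of 0.5.
A planted chain receives a log2 expression effect of 1.5 and a presence-rate
increase of 0.4 in post-treatment samples — a strong but realistic
activation signature over the default 40 patient pairs, mirroring a paired
pre/post design of that size.

One coupling is essential: detection calls derive from intensity on real
arrays, so the generator places absent samples at a background intensity
`call_gap = 2.5` log2 units below the gene's signal level. Without this
coupling a gene can show a chance presence shift (large $\chi^2$) with a
near-zero fold change, and the $1/\overline{|\Delta E|}$ normalization in
the impact factor then amplifies noise chains arbitrarily — an artifact of
decoupled simulation, not of real data.

The generator does not emulate MAS5/RMA summarization, probe-sequence
effects, batch structure, correlated co-expression beyond the patient
intercept, or realistic pathway topology; passing tests on it demonstrates
the statistical machinery (calibration, recovery, determinism), not
robustness to those real-data features.

Two fixed benchmark layouts are provided:

* `planted_benchmark()` — a target pathway of five parallel length-4 chains
  (the first planted) plus a decoy pathway of fifteen length-5 chains. The
  planted chain's length stratum therefore contains genuine competitors,
  and the decoy pathway supplies null enrichment; recovery is measured as
  the planted chain attaining the top impact factor in its stratum, and as
  two independently generated cohorts overlapping in exactly the planted
  chain.
* `calibration_benchmark()` — 20 pathways of parallel chains, lengths 16–19,
  five distinct chain counts (8–12) per length: 200 chains over 3500 genes.
  The layout is shaped by the discreteness of the score: chains without DE
  genes tie exactly within a pathway, pathways of identical size tie across
  pathways, and a pathway with zero DE genes puts all its chains on an
  exact floor of $IF = 0$. Distinct pathway sizes and large pathways (128
  genes and up) make these atoms rare, so testing the empirical p-values
  for uniformity under a null dataset is meaningful. On this layout the
  Kolmogorov–Smirnov distance to uniform at 100 permutations is expected
  below 0.1.

Problem sizes throughout the tests (1000 null genes for type-I error, 200
chains and 100 permutations for calibration, 20 replicates for recovery)
were chosen as the smallest sizes at which the assertions are statistically
meaningful.

## The cohort summarizer

`cohort_summary()` stratifies an unpaired cohort's metadata into 16 matching
strata: age (< 55 vs ≥ 55) × race (white vs non-white) × four receptor
groups. The receptor grouping is a partition: triple-positive
(ER+PR+HER2+); triple-negative (ER−PR−HER2−); all remaining combinations
split by HER2 status. The printed stratum labels of matched-cohort tables in
the literature are ambiguous about where ER+PR+HER2− belongs; we place it in
the HER2-negative mixed stratum so that every combination belongs to exactly
one stratum. Percentages are column percentages rounded half-up to two
decimals, matching how such tables are printed.

## Numerical and degenerate-case choices

* `b = c = 0` discordant pairs: $\chi^2 = 0$, $p = 1$; all-zero 2×2 tables
  are an error, zero-margin tables give $\chi^2 = 0$, $p = 1$.
* $P_{path}$ is constrained to $(0, 1]$; $k = 0$ gives $P_{path} = 1$
  exactly and a zero evidence term.
* $N_{de} = 0$ or $\overline{|\Delta E|} = 0$ zeroes the perturbation term
  instead of dividing by zero.
* Duplicate edges after condensation or merging keep the first row under a
  deterministic (from, to, subtype, sign) ordering; self-edges are dropped.
* Enumeration caps (`max_path_length = 30`, `max_paths_per_pathway =
  50000`, `binding_subset_cap = 81`) exist because all-simple-paths is
  exponential; truncation follows the lexicographic search order and warns.
* All randomness (generator, permutations) flows through explicit seeds via
  a private RNG stream that leaves the caller's `.Random.seed` untouched;
  identical config and seed reproduce byte-identical outputs.

## Known limitations

* Presence/absence testing discards quantitative information; genes that
  change magnitude while staying present contribute through $\Delta E$ only
  as a multiplier of a near-zero $\chi^2$.
* Chains that appear in several binding variants are deduplicated by node
  sequence; whether duplicated sub-chains across variants should be down-
  weighted instead is an open modelling question.
* The impact factor's $1/\overline{|\Delta E|}$ normalization makes chains
  carrying a single weakly-changed DE gene relatively volatile; the
  length-stratified permutation null absorbs this for significance, but
  raw impact-factor magnitudes should not be compared across datasets.
* With the default 10 permutations the smallest attainable p-value over a
  stratum of $S$ chains is $1/(10 S + 1)$; multiple-testing control is only
  as fine as this resolution.
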