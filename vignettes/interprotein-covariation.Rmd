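---
title: "Interprotein covariation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interprotein covariation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Residues that are in physical contact tend to co-evolve: a substitution at
one position shifts the selective pressure on its spatial neighbours. Within
a single protein family this signal, read from the columns of a multiple
sequence alignment (MSA), is the basis of contact prediction. Between two
interacting proteins the same logic applies, with one extra obstacle: each
row of the joint alignment must pair sequences that actually coexist in one
organism. `intercov` implements the full chain — pairing, scoring with three
method families, comparison, and structural evaluation — so that the methods
can be run on identical inputs and their disagreements inspected rather than
argued about.

# Pairing by taxonomic identifier

Given per-protein homolog sets (BLAST-style hit tables carrying an NCBI
taxID column), `build_paired_msa()` keeps a single homolog per organism and
protein. When a genome contributes several paralogs the hit with the lowest
E-value is taken as the presumed ortholog; ties fall back to the higher
bit-score, and a residual tie to the lexicographically smallest subject
identifier. That last rule is ours: some total order is needed for the
pipeline to be deterministic, and the subject id is the only stable key
left. Rows are ordered by ascending taxID with the concatenated reference
sequences first; row order carries no meaning downstream, it only needs to
be reproducible.

The concatenated alignment is then gap-trimmed to the reference (every
column where the reference has a gap is dropped from all rows) and rows
covering less than 50% of the remaining columns are removed. The boundary
is strict: a row at exactly 50% coverage stays. Practical guards — at most
six proteins, a warning beyond 2000 total reference columns — reflect where
dense linear algebra on the concatenated length stops being comfortable on
a workstation.

Redundancy is summarized by Hobohm-1 clustering (`hobohm1()`): a greedy
single pass in which each sequence joins the first cluster whose founder is
at least 62% identical, or founds its own. Two conventions are fixed here
because the underlying algorithm leaves them open: identity is counted over
columns where *both* sequences are non-gap (the unknown residue `X` counts
in the denominator but never matches), and the cluster representative is
its founder. Cluster weights `1/|cluster|` make the effective sequence
number Meff exactly the number of clusters.

# Corrected mutual information

`mi_zscores()` scores a column pair by the mutual information of the
weighted, pseudocounted pair frequencies,

$$\mathrm{MI}(i,j) = \sum_{a,b} f_{ij}(a,b)\,
  \log\frac{f_{ij}(a,b)}{f_i(a)\,f_j(b)},$$

in natural log units. Frequencies use a per-cell pseudocount
$\lambda = 0.05$ (the "low-count correction"; exposed as a parameter), are
weighted by the Hobohm cluster weights, and count a pair only when both
positions are non-gap. Because the single-site marginals are normalized per
column while pair counts are restricted to pair-complete rows, the
pseudocounted MI can dip microscopically below zero; it is clamped at 0.

Raw MI mixes direct covariation with phylogenetic and entropic background.
The average product correction subtracts the separable component:
$\mathrm{APC}(i,j) = \overline{\mathrm{MI}}_i\,\overline{\mathrm{MI}}_j /
\overline{\mathrm{MI}}$, with row and grand means taken off-diagonal, and
the corrected score is $\mathrm{MI} - \mathrm{APC}$.

The corrected scores are finally standardized against a randomization null:
each replicate permutes the residues of every column independently across
rows, which preserves column composition (hence conservation and the
entropic part of the background) while destroying all covariation. We pool
the corrected scores of all pairs over all replicates into a single null
mean and standard deviation rather than keeping per-pair nulls: per-pair
moments at 100 replicates are noisy, and after APC the pair-specific
background is largely gone, so the pooled null is both more stable and
cheaper. The replicate count (default 100) and the seed are parameters;
replicate $r$ draws under `seed + r`, so a single integer reproduces the
whole null.

The per-position conservation track is the Kullback–Leibler divergence of
the column composition from a background distribution (uniform by default),
ranging from 0 to $\log 20$.

# Direct-coupling analysis

Both DCA variants model the alignment rows as samples from a Potts
distribution $P(x) \propto \exp\!\big(\sum_i h_i(x_i) + \sum_{i<j}
e_{ij}(x_i, x_j)\big)$ over $q = 21$ states — the 20 amino acids plus the
gap as an explicit state (`X` maps to the gap state, carrying no
information). Treating the gap as a state is the convention of the
pseudo-likelihood tools this module mirrors; the gap row and column are
excluded again when coupling blocks are turned into scores. Sequences are
reweighted at the standard 80% identity threshold (`reweight_sequences()`),
using the same both-non-gap identity definition as everywhere else in the
package — one definition, stated once, rather than a second subtly
different one.

**Mean-field** (`mfdca_fit()`): frequencies are mixed with a pseudocount
fraction of 0.5 ($f \leftarrow 0.5 f_\mathrm{data} + 0.5/q$), the connected
correlation matrix $C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)$ is formed
over $q-1$ states per site (the last state gauged out), and the couplings
are $e = -C^{-1}$, read off in per-pair blocks and re-embedded in the
zero-sum gauge. The inversion is dense, which is exact and deterministic
but sizes the method: the matrix has $L(q-1)$ rows, so about 600
concatenated columns is a practical ceiling in 8 GB of memory.

Each pair is scored by its **direct information**: the mutual information
of the two-site distribution $P^{(dir)}_{ij}(a,b) \propto
e^{e_{ij}(a,b)}\,\mu_i(a)\,\mu_j(b)$ whose auxiliary fields $\mu$ are
iterated until the marginals match the empirical single-site frequencies
within $10^{-6}$ (a hard error, naming the pair, if 1000 iterations do not
get there — in practice a sign of a degenerate input).

**Pseudo-likelihood** (`plmdca_fit()`): minimizes the weighted negative
pseudo-log-likelihood with L2 penalties $\lambda_h = 0.01$ on fields and
$\lambda_e = 0.2(L-1)$ on couplings (the scaling keeps the per-pair penalty
commensurate as $L$ grows). The optimizer is L-BFGS-B from a zero
initialization, run to a projected-gradient tolerance of $10^{-4}$; both
choices are for determinism — the objective is convex enough that the
starting point does not matter statistically, but byte-reproducible output
requires fixing it. Non-convergence returns the best iterate with a
warning and a flag rather than failing, since a slightly premature stop
still ranks pairs usefully. Scores are Frobenius norms of the 20×20
non-gap coupling block after a per-block zero-sum gauge fix, followed by
the same APC as for MI. The gauge fix matters: the pseudo-likelihood is
invariant under per-pair shifts of rows and columns of $e_{ij}$
(compensated by the fields), so norms are only meaningful in a fixed gauge;
`zero_sum_gauge()` performs the transformation and the test suite checks
the pseudo-likelihood is unchanged by it.

Which mean-field output to rank by — direct information or corrected
norms — is genuinely open; both are computed, and direct information is the
default ranking for the mean-field method because it is that method's
traditional score.

# Comparison semantics

All methods are reduced to a `score_table` over the same positions, with
every pair classified `inter` or `intra:<protein>` by the segment map.
Rankings break ties by score, then smaller $i$, then smaller $j$.
`links_needed(ranked, class, n)` answers "how deep must I read the full
ranking to collect $n$ links of this class" — the quantity that tells a
user whether a method pushes interprotein signal to the top or buries it
under intraprotein pairs. `top_overlap()` intersects per-method top sets;
the default top set is a method's first $n$ pairs *of the target class*,
which matches the reading of "top-$n$ interprotein coincidence" we find
most useful, and a second mode (`mode = "overall"`) takes the top $n$
pairs overall and filters, for users who mean the other thing. Density
summaries report the inter / intra / pooled score distributions with
shared histogram breaks so methods can be overlaid.

# Structural evaluation

`contact_map()` calls a pair of mapped positions a contact when the
C$\alpha$–C$\alpha$ distance is strictly below 12 Å. Both choices — C$\alpha$
rather than heavy-atom minimum, and the strict inequality — follow the
convention the package standardizes on; a 12.0 Å pair is *not* a contact.
Reference positions are mapped onto PDB chains by global alignment
(match +1, mismatch 0, linear gap −1), taking every aligned residue pair,
matches and mismatches alike, as a mapping — a point mutation between the
alignment's reference and the deposited structure should not unmap a
position. A mapped fraction under 30% aborts with a "wrong chain?" error.
Positions without a mapping are excluded from all metrics rather than
scored as non-contacts: an unresolved loop says nothing about whether its
contacts exist. Metrics are precision among the top-$k$ class-filtered
pairs and the ROC AUC with contacts as positives (computed by cumulative
trapezoids; the test suite checks it against the Mann–Whitney rank-sum
identity).

# The synthetic generator

`sample_potts_msa()` draws alignments from a Potts model whose only
couplings are planted on chosen cross-segment pairs, with the Ising-like
diagonal form $e_{ij}(a,b) = s\,[a=b]$ so that signal strength is a single
scalar per pair and the $q=2$ case has a closed Boltzmann form to test
against. Sampling runs one independent Gibbs chain per sequence with 200
burn-in sweeps (independent chains cost more sweeps than one long chain
but remove any between-row autocorrelation from the fixture, which matters
because every scoring method assumes independent rows). All draws go
through R's RNG, so one seed fixes the alignment bit for bit.

The benchmark conditions used by the recovery tests and the acceptance
script are L = 40 columns split 20/20, q = 8 states, 2000 sequences, 10
planted pairs at strength 1.5 — strong enough that a sound implementation
recovers essentially all planted pairs, small enough that the full
benchmark (five seeds, all three methods) runs in minutes on one core.

What the generator deliberately does *not* emulate: phylogenetic
correlation between rows (real alignments are trees, not i.i.d. samples),
gaps, alignment errors, and single-site fields (real columns have skewed
compositions). Passing the planted-recovery tests therefore demonstrates
correctness of the estimators under their own model assumptions, not
field performance on real paired MSAs; the shuffle-null calibration
fixture makes the complementary point that no covariation is reported
when none exists.

# Numerical and degenerate-input choices

* Scores are computed and compared in double precision; MI values are
  clamped at 0; an APC over an all-zero matrix is defined as 0 so that
  degenerate inputs pass through rather than dividing by zero.
* A singular mean-field correlation matrix (possible at pseudocount 0 on
  degenerate data) is an error advising a pseudocount, not a silent
  regularization.
* Columns with no non-gap residue are a hard error naming the column —
  they indicate an upstream trimming mistake.
* External score files must cover every pair unless imported with
  `sparse = TRUE`, in which case missing pairs rank last; conflicting
  duplicate entries are an error, identical duplicates are tolerated.
* All user-facing coordinates are 1-based inclusive, matching how
  structural biologists number residues; the segment sidecar TSV states
  this in its column names.

# Limitations

The pairing rule is an orthology *proxy*: the best E-value hit per genome
can pick a paralog, and nothing in the package detects that. The DCA
module's dense linear algebra bounds mean-field fits at a few hundred
concatenated columns; the pseudo-likelihood fit scales further but is the
slowest step. The shuffle null calibrates the z-scores against an
independence hypothesis that ignores phylogeny, so z-scores on real
alignments are optimistic in absolute terms even where their ranking is
sound. PSICOV-style sparse inverse covariance is intentionally not
implemented; its outputs (or any external method's) enter through
`import_external_scores()` and are compared on equal terms.
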