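---
title: "Positional amino-acid gradients and the chronology of the genetic code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional amino-acid gradients and the chronology of the genetic code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aachron)
```

## The question and the statistic

The genetic code did not appear at once: a broad family of hypotheses
orders the 20 amino acids by when they were recruited into the code,
from structurally simple species such as glycine and alanine (early) to
complex ones such as tryptophan and methionine (late). `aachron` tests
whether that chronology left an imprint on modern protein sequences: do
recently recruited amino acids sit, on average, closer to the 5′
(N-terminal) end of genes, and early ones closer to the 3′ end?

The elementary statistic is deliberately simple. In a protein of length
$k$, every residue carries its 1-based position $1 \dots k$ (position 1
is the initiator residue; the stop signal is never a position). For each
amino-acid species $a$ present in the protein, the mean of its positions
is divided by $k$:

$$\bar{m}_a = \frac{1}{k\,n_a} \sum_{i\,:\,s_i = a} i,$$

the *size-standardised mean position*, lying in $(0, 1]$ and comparable
across proteins of different lengths. $\bar{m}_a < 0.5$ means the
species sits 5′-ward on average. Species absent from a protein are
recorded as missing, never as zero. Residues outside the 20 standard
codes (X, U, O, B, Z, …) occupy positions and count toward $k$ — so
that $\bar{m}_a$ keeps its meaning as a fraction of the coding length —
but are profiled in a separate bucket, never in the 20 species columns.

Two useful identities follow directly and are enforced as tests: the
count-weighted mean of all per-species mean positions is exactly
$(k+1)/2$ (rank mass is conserved), and reversing a sequence maps every
$\bar{m}_a$ to $(k+1)/k - \bar{m}_a$, so every correlation described
below flips sign under reversal.

## Inclusion-rank tables and the early/recent split

The built-in `consensus_ranks()` table is the consensus of 40 published
recruitment chronologies: G = 1, A = 2, D = 3, V = 4, P = 5, S = 6,
E = 7, T = L = 8, R = 10, Q = I = 11, N = 12, H = 14, K = 15, C = 16,
F = 17, Y = 18, M = 19, W = 20. Ties are legal (Q and I share rank 11).
Any other hypothesis can be loaded from a two-column TSV with
`load_rank_table()`; the package deliberately ships only the consensus,
since the individual hypothesis rank lists are not part of its inputs.

`epoch_of()` dichotomises a table at the consensus midpoint: *early*
means rank < 11, *recent* rank > 10. With the consensus table this is an
exact 10/10 split; the tied species Q and I fall on the recent side.

## Statistics kernel

All inference uses exact small-sample machinery, because the natural
sample sizes here (20 species, 19 contact pairs, a handful of protein
groups) are small:

* **Sign test** — exact binomial tails at success probability ½,
  `sign_test(s, n)`. The one-tailed value is the upper tail
  $P(X \ge s)$; the two-tailed value doubles the smaller tail and is
  capped at 1. No normal approximation is used anywhere. Published
  analyses of this design occasionally report a halved upper tail as
  the one-tailed value; this package does not emulate that convention —
  the exact tail convention is used consistently, which can make a
  reported significance look one doubling more conservative.
* **Fisher combination** — $-2\sum_i \ln P_i \sim \chi^2_{2k}$ for $k$
  independent P values (`fisher_combine()`).
* **Dependent-tests correction** — because the per-species tests are
  not independent (rank mass conservation couples them), nominal
  $\alpha$ is replaced by the mean false-discovery-rate critical value
  $\alpha(k+1)/(2k)$ (`fdr_critical()`): 0.0275 for $k = 10$, 0.02625
  for $k = 20$ at $\alpha = 0.05$.
* **Correlation** — Pearson r with P values from the exact
  $t$-transformation on $n - 2$ degrees of freedom
  (`pearson_test()`); Spearman is Pearson on mid-ranks
  (`spearman_test()`). The one-tailed direction defaults to negative,
  the direction the positional hypothesis predicts. Degenerate inputs —
  fewer than 3 pairs, or a constant vector — return a flagged missing
  result with a reason rather than an error or NaN, so that one
  pathological protein cannot abort a group analysis.

## Per-protein and group-level analyses

`protein_rank_correlation()` correlates, over the species present in
one protein, inclusion rank with $\bar{m}_a$ (the "ro" statistic; all
species with at least one residue participate — no minimum count is
imposed, since rare species carry legitimate information and their
noise is absorbed by the group level).

`summarize_group()` aggregates profiles over a named group of proteins.
Counting "below the midpoint" uses the strict inequality
$\bar{m}_a < 0.5$; a value of exactly 0.5 conforms to *neither*
direction, the conservative reading of a boundary case. Species absent
from a protein are excluded from that protein's tally, so the
denominators per species can be smaller than the group size. Two group
statistics summarise the gradient: `R_n`, the correlation of inclusion
rank with the fraction of proteins whose $\bar{m}_a < 0.5$ (predicted
positive), and `R_m`, the correlation of rank with the group-mean
$\bar{m}_a$ (predicted negative).

`cross_group_mean()` averages group means per species — unweighted by
default, so that a 10-protein group and a 100-protein group contribute
equally (weighting by per-species presence is available via
`weights = "size"`, and pooling all proteins can be had by treating
them as one group). A leave-species-out option (`exclude = "M"`)
probes the influence of extreme points such as methionine, whose
initiator role drags it 5′-ward mechanically.

`epoch_majority_test()` is the headline test: a species *conforms* if
it is early with grand mean above 0.5 or recent with grand mean below
0.5. The conforming count over the 20 species feeds the exact one-tailed
sign test; in parallel, per-species sign tests on the pooled protein
counts (one-tailed in each species' predicted direction) are
Fisher-combined separately within the early ten and the recent ten.

`covariate_correlation()` pairs each protein's ro value with an
external covariate — e.g. ranked time a mitochondrial gene spends
single-stranded, a mutation-rate proxy — matching strictly by protein
identifier, dropping and counting unmatched records.

## Contact-energy analyses

The folding-side companion analysis asks whether pairwise residue
contact energies relate to how far apart two species lie in the
recruitment chronology, $d(a,b) = |k_a - k_b|$ (`rank_diff_matrix()`;
invariant to shifting all ranks, zero for the tied pair Q–I).

Contact matrices are user-supplied labelled 20×20 TSVs
(`read_contact_matrix()`). Symmetry is enforced at load: asymmetries up
to $10^{-9}$ (formatting noise) are averaged away with a warning,
anything larger is rejected as a malformed matrix.
`focal_correlations()` computes, for each focal species, Pearson r over
its 19 pairs with the other species — the self pair is excluded because
$d(a,a) = 0$ by construction — reported with two-tailed P values, since
published matrix dialects differ in sign convention and direction is
part of the finding. The correlations are invariant to affine energy
transforms with positive scale and flip sign under negation, so the
dialect's units and offset never matter. `delta_matrix()` forms the
entrywise difference of two matrices (canonically: hydrophobic-core
energies minus polar-surface energies), and `matrix_correlation()`
correlates two whole matrices over the upper triangle plus diagonal
(210 entries) by default — the diagonal carries real self-contact
energies, so it is included, but `entries = "upper"` (190) and
`entries = "all"` (400) are available because published matrix-level
correlations do not always state their choice.

No published contact matrix is bundled: those tables carry their own
provenance and licensing, and the analyses here accept any matrix
dialect. `synthetic_contact_matrix()` builds fully determined fixtures
instead, $e = c \cdot d + \text{noise}$, for which every focal
correlation is known by construction.

## The synthetic-sequence generator

`generate_proteins()` draws the residue at relative position
$t = \mathrm{pos}/k$ from frequencies

$$\Pr(a \mid t) \propto f_a \exp\!\big(-\beta\, z_a\, (t - 0.5)\big),$$

where $f_a$ are baseline frequencies (uniform by default), and $z_a$ is
the species' inclusion rank centred and scaled to unit variance across
the 20 species. This log-linear position-by-rank interaction is the
simplest generative model that produces monotone shifts of $\bar{m}_a$
with rank: $\beta > 0$ enriches recent species toward the 5′ end.
Centring the ranks decouples $\beta$ from composition — at $t = 0.5$
the base frequencies are recovered exactly, so gradient strength and
amino-acid usage can be varied independently. An optional substitution
process then replaces each site independently with probability $\mu$ by
a residue drawn uniformly from the 20 species, attenuating the gradient
the way accumulated mutations would. Real mutation processes are
directional; uniform substitution is sufficient to study signal
attenuation, and a directional substitution matrix is a natural
extension point. Generation is byte-reproducible given the seed.

What the generator does *not* emulate: codon-level structure,
phylogenetic correlation between proteins (every sequence is
independent), realistic length and composition distributions, and
domain architecture. Passing the simulation-based tests therefore shows
that the pipeline detects and calibrates the positional signal it
defines — not that any particular real proteome carries that signal.
Re-deriving the biological result requires user-supplied proteome
FASTA, which the pipeline accepts but does not fetch.

```{r example}
rk <- consensus_ranks()
proteins <- generate_proteins(gradient_config(50, 200, beta = 1, seed = 1))
s <- summarize_group(position_profiles(proteins), rk, group = "demo")
s$R_m$r
```

## Numerical and calibration choices

Problem sizes for the simulation-based checks were chosen to make the
Monte-Carlo error a small fraction of the effects being measured while
keeping the default test run light: gradient-sign recovery uses 100
replicates of 100 proteins of length 300 at $\beta = 1$ (the sign of
`R_m` matches $-\operatorname{sign}(\beta)$ in at least 95 of 100), and
the size of `epoch_majority_test()` is checked at $\beta = 0$ over 200
replicates of two 30-protein groups. One subtlety in the latter: the
conforming-count sign test on $n = 20$ species is discrete, so its
achievable size at nominal $\alpha = 0.05$ is
$P(X \ge 15 \mid 20, \tfrac12) \approx 0.021$, not 0.05; the
calibration check therefore bounds the empirical rejection rate by the
nominal level plus binomial error and verifies the conforming count is
centred on 10, rather than expecting a literal 5% rejection rate.

Other fixed choices, all surfaced above: strict inequalities at the 0.5
midpoint; unweighted cross-group averaging; exact (not permutation,
not halved) tails everywhere; upper-triangle-plus-diagonal matrix
correlations; $10^{-9}$ symmetry tolerance; flagged-missing rather than
propagated NaN for degenerate correlations. Presentation rounding (the
×100 integer format used in report tables) is confined to the report
writers; every computed object and the JSON summary stay at full
precision.

## Limitations

The unit of analysis is the protein sequence; codon-level effects
(translation from nucleotides is out of scope beyond what the FASTA
reader accepts) and the mechanics of single-strandedness are not
computed here — covariates arrive pre-ranked from the user. Only the
consensus chronology ships; conclusions conditional on a specific
recruitment hypothesis require that hypothesis' rank table as input.
Group-level correlations over 20 species have limited power, and the
per-species sign tests share proteins, so the dependent-tests critical
value should be preferred over nominal $\alpha$ when scanning the
per-species results.
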