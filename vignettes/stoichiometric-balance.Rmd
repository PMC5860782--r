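---
title: "Stoichiometric balance in interface-resolved interaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric balance in interface-resolved interaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichbal)
```

This vignette documents the models implemented by `stoichbal`, the
assumptions behind them, the parameters that matter, and the numerical
choices that make results reproducible. It is the package's reference for
*why* the code does what it does; the README shows *how* to run it.

## The balance optimization

A protein-protein interaction network becomes an interface-interaction
network (IIN) when each binding interaction is assigned to the specific
interface the protein uses for it. Interfaces make copy-number balance
well-defined: an interface used competitively by several partners must
carry copies equal to the *sum* of the complexes it serves, whereas
noncompetitive interactions on distinct interfaces each demand their own
match.

Given a target vector of pairwise complexes $x$ (one entry per edge), the
interface copies they consume are $C = Ax$, where $A_{ij} = 1$ if interface
$i$ participates in interaction $j$ ($2$ for a self-interaction, so every
column of $A$ sums to 2). A copy vector is *balanced* when it equals $Ax$
for some $x \ge 0$ — exactly enough copies to realize some portfolio of
complexes with nothing left over.

Observed copies $C_0$ are generally not balanced, so the package solves

$$\min_{x \ge 0}\; \alpha\,(Ax - C_0)^T Z (Ax - C_0) + (Ax)^T H (Ax),$$

where $Z$ selects the constrained interfaces (all interfaces of every
protein with a measured copy number) and $H$ penalizes unequal copies among
the interfaces of one protein. The parameter $\alpha$ (dimensionless,
default 1; the useful range in our experience is roughly 0.01–2) trades
fidelity to $C_0$ against within-protein equality: small $\alpha$ forces a
protein's interfaces to a common value, large $\alpha$ lets them spread to
track $C_0$ more closely. The balanced protein copy number is the mean over
the protein's interfaces, and the spread is summarized per protein as the
interface *noise* $\sigma^2/\mu^2$ (population variance; zero for
single-interface proteins, infinite when a protein's interfaces average
zero but vary). Noise is non-decreasing in $\alpha$ on a fixed system,
which the test suite asserts.

**Choice of $H$.** Any positive semidefinite matrix whose kernel is exactly
the per-protein-equal vectors works; we use the canonical such matrix, one
complete-graph Laplacian block per protein (diagonal $k_p - 1$,
off-diagonals $-1$). A different PSD matrix with the same kernel would give
the same balanced solutions but different objective values, so objective
values are only comparable within this convention.

**Solving.** Both terms are squared seminorms, so the problem is recast
*exactly* as nonnegative least squares: stack $\sqrt{\alpha} Z^{1/2} A$
with $MA$, where $M$ holds one $(+1, -1)$ difference row per interface pair
within a protein (so $M^T M = H$), and solve with the deterministic
Lawson–Hanson active-set algorithm. When the stacked design matrix is rank
deficient the minimizer is not unique ("multiple locally optimized
solutions" in the glossary sense — the QP is convex, so these are all
global); we then add a ridge row block $\sqrt{\lambda} I$ with
$\lambda \approx 10^{-10}$ times the largest column norm squared, which
deterministically selects the (approximately) minimum-norm minimizer and
flags the result as degenerate. The forward map $C = A x_{\min}$ is applied
exactly, so `c_balanced_int` always satisfies the stoichiometry identically.

## Distance metrics and significance

How balanced the observed copies already are is measured by the distance
between $C_0$ and $C_\mathrm{balanced}$ at the protein level (the package
compares protein copies, after interface averaging, because over- and
under-expression is reported per protein):

* chi-square distance $\sum_i (X_i - Y_i)^2 / (X_i + Y_i)$ — absolute
  scale, dominated by large deviations, so one strongly overexpressed
  protein can swamp it;
* Jensen–Shannon divergence of the normalized vectors, in natural-log units
  (the base is a convention; nats are used throughout), bounded by
  $\ln 2$ — shape-sensitive, robust to single outliers.

Significance is empirical: draw `n_rand` random copy vectors from a null
abundance model (resampling a genome-wide pool, a log-normal fit, or a
permutation of the observed vector), balance each, and compare distances.
The p-value uses the add-one estimator $(1 + \#\{d_\mathrm{null} \le
d_\mathrm{obs}\}) / (n_\mathrm{rand} + 1)$, which is super-uniform under
the null and never zero at finite sample size — a perfectly balanced input
attains the minimum $1/(n_\mathrm{rand}+1)$.

## Random networks, motifs, rewiring

`generate_goh_iin()` implements the static-model generator: node $i$ gets
weight $i^{-\gamma}$ and edges are drawn between distinct nodes with
probability proportional to the weight product, rejected until the
requested number of unique edges exists. $\gamma = 0$ is Erdős–Rényi;
$\gamma \to 1$ approaches a scale-free degree distribution. The generator
parameterizes the *weight* exponent directly rather than the resulting
degree exponent. Each node is an interface on its own protein, matching
the competitive-binding setting in which these networks are analyzed.

Motif counts fix the following conventions (motif definitions in the
literature leave counting multiplicity open, so the package documents one
choice and the test suite pins it against a brute-force subgraph
enumerator): chains are
2-paths whose endpoints are not adjacent; triangles are vertex triples;
squares are 4-cycles (not necessarily induced); hubs are 3-stars,
$\binom{d}{3}$ per node; flags are (triangle, pendant edge) configurations.
Self-edges are ignored by motif counting.

Two rewiring modes: *interface rewiring* draws random child IINs for a
fixed parent protein network by swapping which interface of a protein
carries which interaction (preserving the protein edge set and every
interface's degree — this randomizes the competitive/noncompetitive
structure); *topology optimization* greedily accepts single-edge
replacements that lower
$w_1\,\mathrm{chains} + w_2\,\mathrm{triangles} - w_3\,\mathrm{squares} -
w_4\,\mathrm{hubs}$ (default weights all 1), preserving edge count and
connectivity. The direction of optimization mirrors the motif statistics
of curated biological IINs; the weights are a convention.

## Binary binding simulations

The misinteraction-cost analyses treat every node as a single competitive
interface. A binding model lists specific pairs (the network edges) and
nonspecific pairs (every remaining pair, self-pairs included) with
dissociation constants; the nonspecific/specific ratio corresponds to an
energy gap of $\ln(\mathrm{ratio})\,k_BT$. All bonds share a dissociation
rate $k_\mathrm{off} = 1\,\mathrm{s}^{-1}$ and
$k_\mathrm{on} = k_\mathrm{off}/K_D$ after converting $K_D$ to copy units
through an effective volume (default: 50 copies per µM). The absolute
volume only shifts the free fraction; cost trends are governed by the KD
ratio, which is why the default is a convenience scale rather than a cell
volume.

The engine is an exact Gillespie direct-method simulation over all
association/dissociation channels, with propensities in a Fenwick tree so
that networks with tens of thousands of nonspecific channels remain
tractable. Steady state is declared when the time-averaged totals of
specific complexes, nonspecific complexes, and free proteins drift less
than 1% between consecutive averaging windows of ten mean bond lifetimes
($10/k_\mathrm{off}$); reported counts are time averages over the final
window, averaged over replicate runs seeded from one master seed. Runs
that hit the window cap are counted and reported, not silently dropped.
Molecule conservation is asserted after every run.

Cost has two forms: complex-counting
$N_\mathrm{ns}/(N_\mathrm{s} + N_\mathrm{free})$, used for motif surfaces,
and protein-counting
$2N_\mathrm{ns}/(2N_\mathrm{s} + N_\mathrm{free})$, used for the large-IIN
study; a zero denominator yields 0 when the numerator is also zero and
infinity otherwise.

Cost surfaces vary two proteins over a copy grid with the rest fixed
(axes normalized by the fixed abundance). Sensitivity to imbalance is the
percent change in cost along the first principal component of the
lowest-cost decile of grid points, through the surface optimum; the
summary scalar is the mean absolute percent change per unit normalized
distance. Because a well-balanced motif drives its optimum cost toward
zero, percent changes are taken relative to the optimum cost floored at 2%
of the surface maximum, and if the principal axis has no extent inside the
grid (a corner optimum whose valley leaves the hull) the perpendicular
axis is used. The decile threshold is a convention for "the low-cost region";
for motifs whose global optimum is degenerate (a chain with one variable
protein at zero), the expansion point can be overridden to study a chosen
local minimum. Chain and flag motifs are asymmetric, so both
fixed/variable partitions are worth examining.

For single-interface networks, `balance_iin_copies()` produces balanced
copies directly: the equal-complex mode sets every edge's complex count
equal (copies proportional to degree); the balanced mode solves
$\min_{x\ge 0} \|Ax - C_0\|^2$ — the special case of the full program with
one interface per protein, where $H$ vanishes and no $\alpha$ or $Z$ is
needed.

## The network-free rule engine

Multi-site assembly makes the species space combinatorial, so the second
engine never enumerates species: molecules are typed site-graphs, and
complexes are connected components materialized as bonds form. Design
points that define the model class:

* **Bimolecular rules join distinct complexes.** Aggregates are therefore
  acyclic, and a dissociation always splits a complex — except where an
  explicit *ring-closure* rule is enabled, which may also fire within a
  complex (at a fixed high rate, default $10^3\,\mathrm{s}^{-1}$) when the
  two molecules already share a bonded neighbor. This implements
  cooperative closure of a correct trimer; it is enabled in the ARP2/3
  model and off in the clathrin module. Ring eligibility is evaluated for
  complexes up to 16 molecules — the closures it models concern
  near-native complexes, and the eligibility scan is quadratic in complex
  size.
* **Propensities come from global free-site pools** (per site class, split
  cytosol/membrane). A sampled pair landing in one molecule or complex is
  a null event — a self-loop of the Markov chain, statistically exact, at
  some cost in wasted draws (reported as `n_null`).
* **Two compartments.** A complex is membrane-associated exactly when it
  contains a lipid. Lipids are a pooled membrane population; a lipid is
  materialized when a protein binds it and dissolves back into the pool
  when released. Every rule has a solution-phase rate and an extra rate
  applied when both partners are membrane-associated, scaled by
  $V_\mathrm{cyt}/(A_\mathrm{mem}\cdot 2\sigma)$ — the standard
  $K_D^{2D} = K_D^{3D}/(2\sigma)$ reduction-of-dimensionality conversion
  with $\sigma$ a nanometer lengthscale. Doubling $\sigma$ halves the
  enhancement exactly.
* **Vesicle completion.** Any membrane complex holding at least the
  threshold number of *full* designated molecules (for clathrin: trimers
  whose three light-chain sites are bound through the specific light-chain
  rule — a site occupied by a misinteraction does not count) is deleted at
  $k_\mathrm{dump}$; its proteins re-enter the cytosol one at a time at
  $k_\mathrm{recyc}$ and its lipids return to the pool, so per-type totals
  are conserved through every dump/recycle cycle (asserted after each
  run). Recycling one molecule at a time matters: fast vesicle production
  can still transiently drain the adaptor pool.
* Steric hindrance is not modeled; aggregate compositions should be read
  with that in mind (see Limitations).

Splits locate the smaller fragment by bidirectional search and complexes
keep intrusive member lists, so event cost scales with the smaller
fragment rather than the aggregate — this is what makes full-scale
clathrin runs (tens of thousands of proteins, millions of lipids, millions
of events) run in seconds.

## The clathrin vesicle-forming module

`cme_parameters()` carries the module's parameter table: literature
dissociation constants for each binding interface pair, yeast copy
numbers, cytosol volume and membrane area, the 2D conversion lengthscale,
lipid density, the 100-triskelion vesicle threshold, and the dump/recycle
rates. Modeling conventions:

* Heavy chains are pre-assembled trimers with three polymerization legs,
  three light-chain sites, and three adaptor sites. ENT1/2 are merged into
  one type (identical partners). The two YAP paralogs follow the parameter
  table rows exactly as printed: YAP1801 carries the lipid-binding and
  heavy-chain sites, YAP1802 the heavy-chain and EDE1 sites.
* ENT and the YAPs compete for the same three adaptor sites on the trimer;
  the published interaction map does not resolve site sharing on the hub,
  so shared competition is the documented convention.
* Misinteractions: with multiplier $f$, every protein site-class pair
  lacking a specific rule receives a nonspecific rule at
  $f\sqrt{K_{D,\mathrm{mean},1} K_{D,\mathrm{mean},2}}$, where a site's
  $K_{D,\mathrm{mean}}$ is the geometric mean of its specific KDs (the
  geometric mean of KDs is the arithmetic mean of binding energies).
  $f = 10^4$ is an energy gap of $\ln 10^4 \approx 9.21\,k_BT$ (weak),
  $f = 10^3 \approx 6.91\,k_BT$ (strong). The lipid site itself takes no
  misinteractions — recruitment to the membrane stays specific — and
  misinteraction rules receive the same membrane enhancement as every
  other rule, since confinement does not know whether a contact is
  functional.
* Vesicle statistics report adaptor/scaffold proteins (ENT, SLA2, SYP1,
  EDE1, YAP1801/2) per full triskelion in each completed vesicle, and the
  fraction of triskelia whose *first* entry into a membrane-associated
  complex happened through a bond other than clathrin–clathrin
  polymerization (attributed once per trimer, at the joining bond).
* A `scale` switch multiplies all copies and co-scales volume and area
  (concentrations unchanged) for quick exploratory runs; analyses meant to
  mirror the full module run at scale 1, which the engine handles
  comfortably.

## The ARP2/3 assembly model

The seven-subunit model wires the core subunit ARC19 (ARPC4) to five
partners on distinct interfaces. Only the subunit contact topology — not a
quantitative interface map — is available for the assembled complex, so
the default periphery is a documented convention taken from the complex's
known subunit contacts: the ARP2–ARP3 pair, ARC40 (ARPC1) bridging ARP2
and ARC15 (ARPC5), ARC35 (ARPC2) contacting ARP3, and ARC18 (ARPC3) bound
to ARP3 (`arp23_edges()`; replaceable via the `edges` argument). This
density matters: misassembled chains such as ARC19–ARC40–ARP2–ARC19 — two
core subunits in one complex — require the bridging periphery, and they
are the dominant failure mode under core-subunit underexpression. Sparser
peripheries understate misassembly and inflate yields; denser ones
overstate cooperative closure.

Core-subunit bonds are 10-fold stronger than peripheral bonds (this
improves yield and is the documented default), and every edge that closes
a correct trimer carries the cooperative ring-closure rule. Copy modes:
balanced (all equal, default 5000 — yeast-scale abundances at about 1 µM
with the default effective volume) and observed-like (ARC19 at one fifth,
reflecting its measured underexpression). Yield is
$N_\mathrm{desired}/(N_\mathrm{desired} + N_\mathrm{undesired})$ over
proteins in complexes (free monomers ignored); a complex is complete when
it contains exactly one copy of each subunit and no misinteraction bonds.
`arp23_yield_sweep()` simulates each peripheral KD in a decade sweep to a
fixed time (default 50 mean bond lifetimes, by which the yield trajectory
has plateaued in our test conditions) and reports the maximum.

## What the synthetic generators do and do not emulate

The random-network generator, the abundance nulls, and the two kinetic
engines together emulate: interface-level competition, degree and motif
structure of curated IINs, lognormal-like abundance variation, mass-action
binding with a specific/nonspecific energy gap, membrane confinement, and
non-equilibrium vesicle turnover. They do not emulate: spatial structure
beyond two compartments, steric exclusion (aggregate compositions are
upper bounds — a vesicle carrying nineteen adaptors per triskelion would
exceed the surface area available on a 100 nm sphere, which is exactly the
geometric check `sphere_area_per_protein()` makes), cooperativity beyond
trimer closure, temporal gene regulation, and measurement noise in copy
numbers. Passing tests therefore validate the algorithms under the model's
own assumptions, not the biology of any particular cell.

## Numerical choices and problem sizes

* QP: Lawson–Hanson NNLS, deterministic; degeneracy resolved by the ridge
  described above; solver failures propagate as errors carrying the
  residual context, and significance resampling counts (rather than hides)
  failed null draws.
* Gillespie steady state: 1%-drift windows of $10/k_\mathrm{off}$; window
  cap 60; per-run seeds derived from the master seed so `n_runs` is
  embarrassingly reproducible.
* Rule engine: Fenwick-tree propensities refreshed incrementally and
  rebuilt every $10^6$ events to cancel floating-point drift; mt19937-64
  RNG seeded per run.
* Ties and degenerate inputs: zero-copy inputs give the zero solution;
  flat cost surfaces make sensitivity undefined (an error, not a guess);
  empty vesicle logs give `NA` summaries rather than errors.
* Test-suite problem sizes: networks of 5–150 nodes; 150–1500 Gillespie
  runs per estimate; clathrin at full parameter-table scale for short
  horizons and at 3% scale for dump/recycle cycling; ARP2/3 at 400–5000
  copies per subunit. The acceptance script runs the clathrin module at
  full scale and the ARP2/3 sweep at its default (yeast-scale) conditions.

## Known limitations

* The balance objective ignores binding affinities; strongly and weakly
  bound complexes count alike. Affinity-aware balance is a natural
  extension but out of scope.
* Integer copy numbers are not enforced; balanced copies are real-valued.
* The interface-rewiring move set preserves the parent protein graph and
  interface degrees, which is one faithful reading of
  competitive/noncompetitive randomization; other move sets with the same
  invariants exist.
* Aggregate compositions from the rule engine lack steric limits, and the
  clathrin module's vesicles form faster than endocytosis does in vivo —
  both are properties of the model class, shared with the analyses it
  reproduces, and are flagged where results depend on them.
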