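---
title: "Folding circular RNAs by helix-based landscape partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding circular RNAs by helix-based landscape partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circfold)
```

## The problem

Circular RNAs (circRNAs) are covalently closed: they have no 5' or 3'
end, every nucleotide has two backbone neighbors, and any consecutive
1..N numbering starting from an arbitrary origin is equivalent.
Predicting their secondary structure therefore differs from linear RNA
folding in two ways. First, the topology changes the loop bookkeeping:
the face of the chord diagram that no base pair encloses — the
*exterior face* — is a real loop and must be scored like one. Second,
a single minimum-free-energy (MFE) structure is often a poor summary of
a molecule whose landscape holds several deep basins; circRNAs in
particular are reported to function through alternative conformations.

`circfold` addresses both: it folds on the circle natively, and rather
than returning one structure it partitions the folding landscape into
discrete structural ensembles through the molecule's most stable
helices, reporting the MFE structure and stability of each ensemble.

## Model

### Structure universe

A secondary structure is a set of canonical base pairs (A-U, G-C, G-U)
drawn as chords of the circle, such that no position pairs twice, no
two chords cross (pseudoknots and kissing interactions are outside the
model), and every hairpin face keeps at least 3 unpaired nucleotides —
including the exterior face when only one helix borders it. Chords of a
circle cross exactly when their endpoints interleave in the cyclic
order; for points labelled 1..N this coincides with linear
interleaving, which is why predicted structures always render as
well-nested dot-bracket strings even when a helix runs across the
numbering origin.

### Energy model

The free energy of a structure is the sum over the faces of its chord
diagram (nearest-neighbor additivity):

* a face bordered by two pairs with no unpaired nucleotides is a
  **base stack**, scored as `dG(T) = dH - T * dS` from the tabulated
  Turner 2004 stack parameters;
* a one-branch face is a **hairpin loop**, a two-branch face with
  unpaired nucleotides an **internal or bulge loop**, both scored by
  size-keyed initiation tables; beyond the largest tabulated size
  (30 nt) the Jacobson-Stockmayer form
  `G(n) = G(30) + 1.75 kB T ln(n/30)` extrapolates;
* a face with three or more branches is a **multiloop**, scored by the
  affine form `a + b * branches + c * unpaired` with the Turner 2004
  coefficients `(9.3, -0.9, 0.0)` kcal/mol;
* the **exterior face** is re-classified by its branch degree (1 =
  hairpin-like, 2 = internal/bulge-like or a stack when both gaps are
  empty, 3+ = multiloop-like) and scored by the same rules; the bare
  circle defines the zero of energy.

Loop tables carry no enthalpy and are treated as purely entropic, so a
temperature change rescales them as `G(T) = (T/310.15) * G(37C)`;
stacks use their measured enthalpies. Dangling ends, terminal-AU
penalties, loop-sequence mismatch terms and coaxial stacking are
deliberately excluded: the model is minimal base-stacking plus loop
entropy, which keeps every reported number reproducible from the one
plain-text parameter file shipped with the package
(`system.file("extdata", "turner2004.par", package = "circfold")`).
The file grammar (sections `STACK`, `HAIRPIN`, `BULGE`, `INTERNAL`,
`MULTILOOP`, `MAXLOOP`) is documented in `?load_parameters`, so a
differently derived loop-entropy table can be dropped in without
touching code. Forbidden elements (hairpins under 3 nt) carry a large
finite sentinel (1e6 kcal/mol) whose Boltzmann weight underflows to
exactly zero, so no special cases reach the dynamic program.

### Helix-based landscape partitioning

A helix `(i, j, k)` is the run of `k` stacked pairs `(i+m, j-m)` mod N.
It is *saturated* when it cannot be extended: the next pair outward or
inward is noncanonical, would overlap the helix itself, or would pinch
a flanking loop below 3 nt. `enumerate_saturated_helices()` lists them
(modular arithmetic throughout, so origin-spanning helices are
first-class), `rank_helices()` orders them by their stacking free
energy and drops non-stable ones, and the pool grows from the most
stable downward until the number of landscape partitions reaches the
requested structure count (`grow_pool_until()`).

Each partition is an inclusion/exclusion *signature* over the pool:
`+h` forces every pair of helix `h`, `-h` forbids every one of its
pairs. Signatures whose included helices overlap or cross are deleted.
The resulting ensembles are pairwise disjoint — a structure containing
all pairs of each included helix and no pair of any excluded one
belongs to exactly one signature — which is what guarantees "at least
one helix difference" between any two reported structures. A structure
containing only part of an included helix belongs to no ensemble; this
forced-all/forbidden-all reading keeps ensembles disjoint at the price
of not being exhaustive, and we accept that trade-off deliberately.

### Conditional partition functions on the circle

Selecting any two paired positions i < j cuts the circle into the
internal fragment (i, j) and the external fragment (j, i). For the
ensemble conditioned on formation of the i-j pair,

    Q^(i-j) = Qfrag(i, j) * Qfrag(j, i)

where each factor is the conditional partition function of a *linear*
fragment with its terminal nucleotides paired with each other. Both
factors come from one standard O(N^3) McCaskill-style dynamic program
run over the doubled sequence (position p and p+N are the same
nucleotide), which yields every fragment of the circle in a single
pass. Energy ownership at the seam is exact: all energy lives in
stacks and loops, a fragment owns the loop closed by its terminal pair
and everything nested inside, and the closing pair itself carries no
standalone term — so the internal fragment owns the face inside (i, j),
the external fragment owns the face outside it, and every face of the
circular structure is counted exactly once.

The partition free energy is `G = -kB T ln Q^(i-j)` with
`kB = 0.0019872 kcal/(mol K)`. For each signature the engine scans
candidate closing pairs, selects the minimizer of `G`, and recovers the
MFE structure of both fragments by deterministic backtracking (ties
prefer the smaller 5' index, then the smaller 3' index). The reported
free energy of a structure is its direct loop-sum re-evaluation
(`evaluate_structure_energy()`), which the test-suite requires to agree
with the dynamic program to 1e-6 kcal/mol. When a signature includes no
helix, the open circle (no pairs, G = 0) competes as a candidate and
wins whenever no ensemble is more stable than the reference state.

Two design choices here were genuinely open and are worth recording:

* **Closing-pair selection.** The method defines selection by ensemble
  stability (`-kB T ln Q`), and that is the default. A pure-MFE switch
  (`fold_control(closing_rule = "mfe")`) selects by backtracked energy
  instead; it is the exact setting, used by the validation suite when
  comparing against exhaustive enumeration, because ensemble-guided
  selection can in principle land on a closing pair absent from the
  global MFE structure.
* **Candidate closing pairs.** By default candidates are restricted to
  pairs participating in a saturated helix (plus all forced pairs) —
  lone closing pairs make unstackable decompositions and never win.
  `fold_control(closing = "all")` scans every canonical pair; the
  validation suite uses it so that the engine's universe coincides
  exactly with the enumeration oracle's.

### Numerical choices

Partition-function tables are rescaled per nucleotide by
`exp(sigma/kT)` with `sigma = min(0, E_MFE)/N`, chosen after the MFE
pass; values are reported in the log domain, so conditional Q values at
N = 500 neither overflow nor lose the 1e-9 relative accuracy the tests
demand at small N. Interior loops inside the dynamic program are capped
at 30 unpaired nucleotides total (the standard cap; at oracle scales it
is unreachable, so engine and oracle universes coincide). Backtracking
re-derives each stored optimum with a 1e-7 kcal/mol matching tolerance
in a fixed scan order, which makes repeated runs byte-identical.
Degenerate inputs behave predictably: a homopolymer returns the open
circle at G = 0; contradictory constraints raise errors at validation,
while a signature whose ensemble is empty is silently dropped and the
run reports fewer structures than requested.

## Constraints

`HELIX i j k` forces the `k` pairs `(i+m, j-m)`; `LOOP i k` forces
positions `i..i+k-1` unpaired. Validation rejects noncanonical forced
pairs, out-of-range indices, nucleotides claimed twice, and crossing
forced helices — each with a distinct error, mirroring a hard "error"
status rather than a silent empty prediction. Inside the engine,
forced pairs become mandatory partners in every recursion case and
forced-loop positions lose their pairing ability, so every returned
structure satisfies the constraints by construction, not by filtering.

## What the synthetic data emulates — and what it does not

All testing runs on programmatically generated circles:
`hairpin_circle` (one GC stem, two loops), `two_helix` (two compatible
stems), and seeded `random` circles, optionally GC-biased so that
non-trivial minima exist at oracle scale. These fixtures exercise the
full machinery — modular indexing, origin-spanning helices, landscape
partitioning, constraint handling — but they are not real circRNAs:
natural sequences are longer, carry sequence-dependent loop effects and
ions this energy model ignores, and their reference structures come
from chemical probing. Passing the suite therefore certifies the
algorithm (exactness against enumeration, invariances, contracts), not
biological accuracy on any particular transcript. A note on fixture
sizing: a 4-bp GC stem on a 16-nt circle has *positive* total energy
(two hairpin penalties outweigh three GC stacks), so planted-stem
recovery is only a theorem for longer stems; the recovery tests use
N >= 22, where the planted stem is the unique stable helix and its
structure is safely below zero.

Problem sizes used by the validation suite were chosen to keep the
whole run inside a few minutes on one CPU while still being exhaustive
where it matters: 200 random circles (N 8-16) for MFE exactness, 50
(N <= 14) for partition-function equivalence over every canonical
closing pair, 50 for rotational invariance over all N shifts, 100
random constraint cases, and timing runs at N = 100/200/400/500.

## Known limitations

* No pseudoknots, kissing hairpins, or any cross-linked pairs: the
  energy parameters for the circular extensions of those motifs are
  coupled to loop sizes in ways the nearest-neighbor tables cannot
  express.
* Loop energies are size-only: sequence-dependent loop corrections,
  special small hairpins, asymmetry penalties and ionic-strength
  effects are not modeled.
* The stack parameters were measured in 1 M NaCl; helix stabilities in
  low-salt conditions will be overestimated.
* The landscape partition count grows as 2^pool; the pool is capped at
  12 helices (4096 signatures), far beyond any sensible requested
  structure count.
* Input length is capped at 500 nt by default — the dynamic program is
  O(N^3) time / O(N^2) memory, and a 500-nt prediction completes in
  well under a minute, but the cap keeps the 2N-doubled tables modest.

## A worked call

```{r example}
fit <- circfold(generate_fixture("hairpin_circle", 30), max_structures = 5)
fit
```

The five structures are the per-partition minima: the full planted stem
first, then the four ways the landscape looks when the stem or its
one-pair-shifted variants are excluded. Energies are loop-sum
re-evaluations in kcal/mol; `summary(fit)` additionally prints each
partition's ensemble stability `-kB T ln Q`.
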