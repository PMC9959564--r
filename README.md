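# circfold

Secondary-structure and folding-stability prediction for **circular
RNAs** — covalently closed transcripts with no 5'/3' ends — from
sequence alone, with alternative-structure ensembles generated by
helix-based partitioning of the folding landscape.

## Why circular RNAs need their own folder

On a circle every numbering origin is equivalent and the "outside" of
the structure is itself a loop, so linear folding tools mis-score the
exterior face and mishandle helices that run across the origin.
Moreover circRNAs are believed to act through *alternative*
conformations, which a single minimum-free-energy (MFE) structure
cannot capture. `circfold` folds natively on the circle and returns a
ranked set of structurally distinct alternatives.

## Method in brief

1. **Saturated helices.** Every maximal run of stacked canonical pairs
   `(i+m, j-m) mod N` is enumerated on the circle and ranked by its
   stacking free energy (Turner 2004 parameters, `dG = dH - T dS`).
2. **Landscape partitioning.** The most stable helices form a pool;
   each inclusion/exclusion signature over the pool (e.g.
   `+h1 -h2 +h3`) defines a disjoint structural ensemble: included
   helices are forced, excluded helices forbidden. The pool grows until
   the number of partitions reaches the requested structure count.
3. **Conditional partition functions.** A closing pair (i, j) cuts the
   circle into two linear fragments, and the ensemble conditioned on
   that pair has

        Q^(i-j) = Qfrag(i,j) x Qfrag(j,i),

   the product of the fragments' conditional partition functions with
   terminal nucleotides paired (one O(N^3) dynamic program over the
   doubled sequence yields them all).
4. **Per-partition MFE.** For each signature the closing pair
   minimizing `G = -kB T ln Q^(i-j)` is selected and the MFE structure
   is recovered by backtracking; structures are re-scored by an
   independent loop-sum evaluation and ranked by free energy
   (kcal/mol). Any two reported structures differ in at least one pool
   helix.

Constraints `HELIX i j k` (force k base pairs) and `LOOP i k` (force k
unpaired nucleotides) restrict the landscape; improper sets (crossing
or overlapping forced pairs) raise errors. Inputs up to 500 nt; an
exhaustive small-N enumeration oracle ships in the package as ground
truth for every engine contract.

## A worked example

```r
library(circfold)
fit <- circfold(generate_fixture("hairpin_circle", 30), max_structures = 5)
fit
```

```
Circular RNA folding: 'hairpin_circle_30', 30 nt at 37.0 C
  5 structure(s) from 5 landscape partition(s) over 4 pool helices

  GGGGGGGGGGGAAAACCCCCCCCCCCAAAA
 1 (((((((((((....)))))))))))....   -21.80 kcal/mol  +h1 -h2 -h3 -h4
 2 ((((((((((.....)))))))))).....   -18.30 kcal/mol  -h1 +h2 -h3 -h4
 3 .((((((((((.....))))))))))....   -18.30 kcal/mol  -h1 -h2 +h3 -h4
 4 ..(((((((((......)))))))))....   -15.60 kcal/mol  -h1 -h2 -h3 -h4
 5 (((((((((......)))))))))......   -15.60 kcal/mol  -h1 -h2 -h3 +h4
```

Structure 1 is the global MFE (the planted 11-bp stem: ten GC stacks at
-3.3 and one closing stack, plus two loop penalties); structures 2-5
are the best members of the ensembles that exclude that stem or force
its shifted variants — each differs from every other in at least one
pool helix. `summary(fit)` adds per-partition ensemble stabilities
`-kB T ln Q`, `plot(fit)` draws an arc diagram, and
`write_report(fit, "text" | "json" | "ct")` renders ranked dot-bracket
text, a machine-readable report, or connectivity tables whose backbone
closes from position N back to 1.

A thin command-line wrapper is installed with the package:

```sh
Rscript exec/circfold --seq GGGGGGAAAACCCCCCAAAA --max-structures 3 \
        --constraint "LOOP 7 4"
```

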