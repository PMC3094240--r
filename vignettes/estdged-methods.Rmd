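---
title: "Methods: corrected digital gene expression from EST library counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corrected digital gene expression from EST library counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Expressed sequence tags (ESTs) are single-pass reads from clones of a cDNA
library. The number of a library's sequences that map onto a gene cluster is
a digital measurement of that gene's expression in the sample the library was
made from. Comparing those counts between two pools of libraries — say,
normal versus cancerous tissue — is the classic "digital gene expression"
design, and its reliability depends on three things that are easy to get
wrong:

1. **Which libraries end up in each pool.** Libraries carry a free-form
   `keywords` annotation and a single controlled-vocabulary `unique tissue`
   annotation. A tissue search that substring-matches the keywords field,
   without respecting word boundaries, will return libraries for "ear" because
   their keywords contain "heart", "heart disease", "clear cell renal
   carcinoma" or "peripheral blood mononuclear cell" — every one of which
   contains the letters "ear". It will also include dependent tissues ("bone
   marrow" for "bone") and mixed-sample ("pooled tissue") libraries.
2. **How library size is counted.** The submitter-declared `SEQUENCES`
   annotation typically exceeds the number of sequences that actually map
   onto gene clusters, so a size cut-off applied to the declared value can
   keep libraries whose informative content is below the cut-off.
3. **Whether the statistics depend on display settings.** A significance
   value whose definition involves the display cut-off changes when the user
   changes what is displayed, which makes reported significance a function of
   presentation rather than of the data.

`estdged` implements the corrected workflow: exact unique-tissue selection,
mapped-count library sizes, union gene lists whose per-pool column sums equal
the pool totals by construction, and statistics computed on the full gene
list before any display filtering.

## Library selection

The **corrected selector** returns a library iff its case-folded,
whitespace-trimmed `unique tissue` annotation *equals* the query phrase. The
phrase being nested inside a longer annotation ("bone" inside "bone marrow")
is not a match, and "pooled tissue" libraries can only be selected by
querying "pooled tissue" itself. Keywords are ignored entirely, which is what
removes the metastasis traps: a bone-marrow library carrying a
"neuroblastoma" keyword can never be selected for "brain".

The **legacy emulator** reproduces the historical behaviour for comparison
studies: the query is accepted as a raw substring of any keywords phrase or
of the unique-tissue field, case-folded, with no word-boundary checks, and
mixed-sample libraries are not excluded. An optional per-query
`extra_phrases` list lets the emulator reproduce the hierarchy-descendant
behaviour (a "brain" query pulling in "neuroblastoma" and "Ewing's sarcoma"
keyword libraries); it is empty by default because that behaviour depended on
an external keyword ontology that this package deliberately does not model.

Both modes share the downstream filters: a histology class (`normal` /
`cancer` / `other`) assigned from a configurable whole-word cancer lexicon, a
protocol filter (`bulk`, not `normalized`), and the size cut-off — on mapped
counts in corrected mode, on declared counts in legacy mode. Because the
lexicon matches whole words, "neuroblastoma" does not match "blastoma"; a
fixture that needs a cancer classification carries an explicit cancer word in
its histology field.

Classification scoring counts a selected library as correct when its unique
tissue exactly matches the query; for "germ cell", "head and neck" and "stem
cell", which never occur as unique-tissue annotations, a whole-phrase
keywords match counts instead. Percentages are rounded half-up to two
decimals; an empty selection reports zeros flagged "not available" rather
than erroring on 0/0.

## Counting and the conservation property

`compute_mapped_counts()` sets each library's mapped count to the sum of its
expression-table entries. Pool totals (`A`, `B`) are sums of member mapped
counts, and the gene table is built from the same expression table restricted
to the pool members, so

* sum of the per-gene `a` column = pool A total, and likewise for `b`/B;
* the Boolean (presence/absence) and odds-ratio outputs enumerate the same
  union gene list — every cluster present in at least one pool;
* the known/unknown x unique/non-unique summary is tabulated from the gene
  list itself, so its four cells always total the list length.

The sequence odds ratio is `F = (a/A)/(b/B)`. Zero counts use explicit
conventions — `Inf` when the gene is present only in pool A, `0` only in
pool B, undefined (`NaN`) in neither (which cannot occur in a union list) —
with an optional pseudocount `c` giving `((a+c)/(A+c))/((b+c)/(B+c))` when a
finite ratio is preferred. Gene rows are ordered by descending `a+b` with
ties broken by cluster id, purely so reports are byte-reproducible.

"Known" genes are those with a non-empty symbol whose title does not match an
anonymous-transcript pattern (`Transcribed locus`, `cDNA clone`, `cDNA FLJ`,
whole-word `EST`, `hypothetical`, `open reading frame`; case-insensitive,
configurable). The rule is a documented heuristic: public databases contain
clusters with a real symbol but an anonymous clone title, and no published
specification of the historical rule exists.

## The fold-change posterior probability

The headline statistic is the posterior probability that a gene is at least
`k`-fold upregulated in pool A relative to pool B (default `k = 3`). Let
`p_A` and `p_B` be the per-sequence abundances of the gene in the two pools.
With uniform priors and binomial sampling, the posteriors given counts `a` of
`A` and `b` of `B` are independent:

```
p_A | data ~ Beta(a + 1, A - a + 1)
p_B | data ~ Beta(b + 1, B - b + 1)
P = Pr(p_A >= k * p_B)
```

Substituting `u = F_B(p_B)` (the Beta CDF) turns the defining double integral
into a one-dimensional integral of a smooth, monotone integrand on the unit
interval:

```
P = \int_0^1 [ 1 - F_A( min(1, k * Q_B(u)) ) ] du
```

where `Q_B` is the Beta quantile function. This is evaluated with a 32-point
Gauss–Legendre rule (nodes and weights computed once and cached; the count is
configurable). The substitution matters numerically: at pool totals in the
thousands the Beta densities are sharp spikes that a fixed rule on the raw
scale would sample badly, while in `u` the density is absorbed into the
quantile map — in the symmetric case (`a = b`, `k = 1`) the integrand is
exactly `1 - u` and the rule is exact, returning 0.5. The result is clamped
to `[0, 1]` against rounding at the extremes.

Two properties are enforced by construction and verified by tests:

* `P` depends only on `(a, A, b, B, k)` — never on a display cut-off;
* a Monte-Carlo oracle (`prob_fold_mc_oracle()`, direct sampling of the two
  posteriors under an explicit seed, leaving global RNG state untouched) is
  the internal ground truth; the quadrature agrees with a million-sample run
  within `max(0.01, 3 standard errors)` across a grid of counts at
  `A = B = 1000` and `k` in 1–10, where the worst observed deviation is
  about 0.002.

The quadrature kernel lives in a single function so an alternative integrand
(for example one conditioning on the combined total rather than using
independent posteriors) can be swapped in without touching any caller. `P` is
reported on a 0-to-1 scale with values near one significant, e.g. 0.95 for a
95% posterior probability of `k`-fold upregulation.

## Fisher exact test and q-values

As an alternative significance measure, `fisher_exact()` tests the 2x2 table
`[[a, A-a], [b, B-b]]`, summing hypergeometric probabilities of all tables no
more probable than the observed one (the minimum-likelihood two-sided
convention, with the customary `1 + 1e-7` relative tolerance; a one-sided
variant is available). p-values are converted to q-values by the
Benjamini–Hochberg step-up rule over the **complete** gene list. Because
filtering happens strictly after all statistics are computed, the q-value of
a gene — like its `P` — is bit-identical under every display cut-off
setting. This is the pipeline-level fix for significance values that change
with the display threshold: the fix is ordering, not arithmetic.

Display cut-offs themselves are pure filters: `F >= f_cutoff` (one-sided by
default, matching the "differs by a factor of x or more, upregulated"
reading; a two-sided flag also keeps `F <= 1/f_cutoff`), `P >= p_cutoff`
(significance near one), `q <= q_cutoff`. `F = Inf` rows pass any F cut-off;
rows with undefined statistics fail a set cut-off.

## Synthetic fixtures

The generator emits a library flat file, expression table and gene table plus
bookkeeping of every planted truth, as a pure function of scenario name, seed
and parameters. Named scenarios embed the documented pathologies:

* **ear-trap** — 6 true ear libraries plus 100 traps split
  70/10/8/5/3/2/2 across the documented categories ("heart" keywords,
  "heart disease" on brain/cerebellum/cerebrum/thymus/vascular libraries,
  "pericardium" with unique tissue "heart", "clear cell renal carcinoma",
  "clear cell ovarian tumor", "peripheral blood mononuclear cell", and
  pooled-tissue libraries with a "heart" keyword). Only the totals (6
  correct, 100 traps, hence 5.66% / 94.34% correct/incorrect under the
  legacy matcher) are anchored; the split across trap categories is a
  documented, configurable invention.
* **bone-vs-marrow**, **brain-metastasis**, **adipose-pools** — dependent
  tissue nesting, metastasis keyword traps, and declared-count inflation
  with two outside libraries for unique/non-unique flags, respectively.

The random generator draws tissues from a fixed vocabulary, guarantees each
library's keywords contain its unique-tissue phrase verbatim (so a corrected
selection is always nested inside the legacy one), gives each library at
least one gene with zero-truncated Poisson counts (mean 5 genes per library,
mean count 5 — small by design; nothing downstream depends on the count
distribution's shape), and sets
`declared = ceiling(mapped * (1 + inflation))`, rounded up so any positive
inflation is strictly visible.

What the fixtures do **not** emulate: realistic EST abundance distributions,
normalization-protocol effects on counts, the scale of real library
databases, or cluster rebuilding across database builds. Passing tests
demonstrate the correctness of the algorithms on data with known ground
truth, not biological conclusions about any real tissue.

## Numerical and design choices

* Problem sizes in the test suite: random databases of 12–50 libraries and
  10–30 gene clusters, 100 replicate fixtures for set-equality properties,
  a 5x5x4 count grid at `A = B = 1000` against a 10^6-sample oracle, and an
  exhaustive Fisher sweep over all 2x2 tables with row sums up to 30. These
  are the package's chosen verification scales; all ground truths are
  regenerated in code at test time.
* The Fisher enumeration cross-check in the tests uses independent
  log-factorial arithmetic compared at 1e-12 relative tolerance — the margins
  involved exceed exact integer range in doubles, and that tolerance is far
  below any printed precision.
* Percent rounding is half-up (not banker's), matching how the selection
  error rates are conventionally printed.
* All report numerics serialize at 6 significant digits (counts as
  integers), so byte-equality of reports is a meaningful determinism check;
  reports are written atomically (temp file + rename) so failures leave no
  partial output.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state.

## Limitations

* The fold-probability integrand is a reconstruction from the independent
  Beta-posterior model; historical published values computed on 2008–2011
  database snapshots are not reproducible without those snapshots and are
  not targets of this package's tests.
* No tissue ontology or synonym expansion: the corrected selector is
  deliberately exact, and the legacy emulator's descendant-phrase knob must
  be supplied by the user.
* The flat-file dialect is fixed by this package (required headings,
  semicolon-separated phrase lists, blank-line record separator); it mirrors
  the documented field inventory but is not a parser for any archive's
  actual dump format.
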