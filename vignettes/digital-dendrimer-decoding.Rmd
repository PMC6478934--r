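---
title: "Decoding binary dendrimers: paths, barcodes and tandem-MS masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding binary dendrimers: paths, barcodes and tandem-MS masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendricode)
```

## The molecular model

A digital dendrimer stores information in the spatial arrangement of two
sub-monomer units on a regularly branched scaffold: a butyl-spacer unit read
as a **0-bit** (nominal 184 Da) and a hexyl-spacer unit read as a **1-bit**
(nominal 212 Da).  Units are assembled into branched monomers
`t-b(b1b2)-f2` — a focal unit carrying bit `b` behind an acetyl-protected
thiol (`t`) and two periphery units carrying bits `b1`, `b2` behind
furan-protected maleimides (`f`) — and monomers are grown divergently:
generation 0 is the bare monomer, and each further generation couples a
fresh monomer (thiol–maleimide Michael addition) onto every periphery unit.
The notation `DN-100-011-G1` names the dendron whose focal monomer is
`1(00)` and whose generation-1 monomers are `0(11)`; a single code
(`DN-011-G2`) is replicated across all generations.  A generation-*n*
dendron of two-branch monomers therefore has $3(2^{n+1}-1)$ units and
$2^{n+1}$ leaves, which `build_tree()` realises as a deterministic,
preorder-stored rooted tree.

Three modelling choices are worth making explicit:

* **Generations count growth steps**: `G0` is one monomer, matching the
  naming of the bare-monomer species.
* **Schedules are innermost-first** (G0 code listed first): with this
  convention the tabulated precursor masses of `DN-100-011-G1` (5 one-bits)
  and `DN-111-000-G1` (3 one-bits) both follow exactly from the additive
  mass model below; the outermost-first reading contradicts them.
* **Strict grammar**: codes are exactly three bits and a schedule has
  length 1 or $n+1$.  The `DR` (dendrimer-variant) family is parsed and
  built with the same topology, but its core composition is deliberately
  left a configuration parameter — the available data do not determine it
  (see *Limitations*).

## Binary paths and the shuffle-product enumeration

The MS/MS-accessible information of a dendrimer is the set of **binary
paths**: bit strings read along any topological ordering of the tree (root
first, every parent before its children) — equivalently, reversed orders of
cleaving units one by one from the periphery in toward the focal core.
Orderings that spell the same string are indistinguishable, so the path set
is a *set of strings*.  `extract_paths()` computes it recursively: the path
set of a unit is its bit prepended to the deduplicated shuffle product of
its children's path sets, memoised on canonical subtree shape so symmetric
branches share work, with the pairwise shuffle itself a suffix-grid dynamic
programme.  Each unordered word pair is shuffled once.  This reaches
generation 2 (1,000+ paths of 21 bits) in well under a second on one core.

```{r}
extract_paths(dendrimer("DN-011-G1"))
```

`brute_force_paths()` is kept as a deliberately independent oracle: it walks
every topological ordering explicitly via a frontier recursion (guarded to
12 units) and the suite checks the two agree on every grammar-reachable
tree of that size, i.e. all 8 single monomers and all 64 two-code
generation-1 dendrons.

## Encryption and the canonical matrix

Stacking the $k$ paths as matrix rows admits $k!$ arrangements
(`count_row_arrangements()`, exact via an internal big-integer factorial).
The encryption rule **"1 > 0, right to left, upper"** collapses them to one
canonical matrix: rows are compared from the rightmost column leftward and,
at the first differing column, the row holding the 1 is placed nearer the
top.  This is exactly a stable, locale-independent radix sort on the
reversed rows in decreasing order, so it is idempotent and invariant to
input order; equal rows (impossible from a true path set, possible by
calling the function directly) retain input order as the documented
tie-break.

## Barcode and storage capacity

`matrix_to_pdmb()` maps 1-bits to dark modules; `add_finder_patterns()`
adds the one-module frame — solid dark "L" on the left column and bottom
row, alternating timing pattern on the top row and right column, each
starting dark at the corner adjacent to the solid L, with dark winning
where the two timing edges meet.  The timing phase follows the usual
Data-Matrix drawing convention; nothing in the source material fixes it,
and colours there are treated as illustration (output is monochrome).
Rendering targets plain-text portable bitmap (P1) and SVG, both
deterministic down to the byte; `read_pbm()` inverts the bitmap exactly,
which the suite uses as a round-trip property.

Capacity follows the plain module-count accounting with an 11% "normal"
error-correction reservation:

$$\text{bits} = \lfloor \text{modules} \times (1 - 0.11) \rfloor, \qquad
  \text{bytes} = \lfloor \text{bits} / 8 \rfloor.$$

For `DN-011-G1`: 6 paths × 9 units = 54 modules → 48 bits.  No
Reed–Solomon codewords are computed — the correction level is a capacity
reservation, configurable via the `correction` argument.  A small epsilon
inside the floor guards against the binary representation of the
correction fraction.

A caveat this package states openly: for `DN-011-G2` the distinct
topological-order strings number 2042 (confirmed here by two independent
algorithms), so the honest capacity under the formula above is 42,882
modules → 38,164 bits → 4,770 bytes.  Byte values sometimes quoted for
second-generation and `DR`-family species imply materially different row
counts (e.g. 1572 × 21) that cannot be derived from the stated path
definition plus the rectangular capacity formula; whatever additional
matrix-reduction rule produced them is not public, and this package does
not guess it.  The same applies to the 207-bit figure sometimes attached
to `DN-101-G1`.

## The mass engine

**Composition.**  All masses are monoisotopic and refer to the furan-free
species actually observed (the periphery furans leave by retro-Diels–Alder,
hence `[M+Na-nFu]+` precursors with $n$ = leaf count).  The defaults take
the linked 0-bit residue as C₈H₁₀NO₂S = 184.0432 Da and the 1-bit residue
exactly one C₂H₄ (28.0313 Da) higher, 212.0745 Da.  Each *free* (leaf)
maleimide carries one extra hydrogen relative to a thioether-linked unit;
tracking that hydrogen is what makes the G1 and G2 anchor masses mutually
consistent and pins the focal end-group constant at 41.0022 Da.  With
these constants the additive model

$$m/z = \sum_i u_{b_i} + n_\text{leaf}\,m_\mathrm{H} + E_\text{DN} +
  m_\mathrm{Na}$$

reproduces every additive-consistent tabulated DN precursor to
±0.01 Da.  The default mode is nevertheless **calibrated**: the m/z is an
anchor value for the same family and generation shifted by
$\Delta(\text{1-bits}) \times 28.0313$, which needs no end-group knowledge
and is exact at the anchors; composition mode is the fallback (and the
user-supplied route for families without anchors).

**Fragments.**  The succinimide-thioether S–C bond linking every adjacent
unit pair is the weak link under MS/MS.  Cutting linkage $e$ (child unit at
depth $d$) yields a focal-retaining fragment $t_{d+1}$ = precursor − subtree
mass + H and a periphery-retaining fragment $a_{d+1}$ = subtree mass − H +
Na, so every primary pair obeys the sodium complementarity
$m_t + m_a = m_\text{prec} + m_\mathrm{Na}$ *exactly*; the suite asserts
this to 10⁻⁹ Da, alongside a cut-every-edge oracle that recomputes fragment
masses from explicit node partitions.  Labels are layer-indexed (that is
what reported fragment tables use — a $t_4$ of a generation-1 dendron
retains 8 of 9 units), mass-degenerate fragments from symmetric branches
merge into one species with a multiplicity, and branch letters a, b, …
(for α, β, …) disambiguate same-layer species by decreasing m/z.
Double-cleavage (secondary) fragments on disjoint branches are available
behind `secondary = TRUE` but off by default.

**Matching.**  `match_peaks()` does greedy nearest-mass assignment, one
fragment per peak, within a 0.5 Da default tolerance (MALDI-TOF reflector
scale), ties breaking toward the lower theoretical m/z.  On the bundled
example spectrum of `DN-011-G1` (`inst/extdata/dn-011-g1-msms.csv`; its
intensity column is a placeholder — only the m/z values are meaningful):

```{r}
peaks <- read_peaklist(system.file("extdata", "dn-011-g1-msms.csv",
                                   package = "dendricode"))
match_peaks(peaks, enumerate_fragments(dendrimer("DN-011-G1")))
```

Three of the five peaks annotate within 0.16 Da.  The remaining two
(1070.46 and 843.37, nominally $t_2$α/$a_2$α) *cannot both* be matched by
any complementarity-exact theory: they are the two sides of the same cut,
so their theoretical sum is fixed at precursor + Na = 1915.59 Da, while the
reported pair sums to 1913.83 Da — 1.76 Da short, more than twice the
tolerance.  Both values sit ≈0.9 Da below theory, the signature of reading
one isotope low; the package reports them unassigned rather than bending
the model, and the corresponding acceptance expectations are left failing
by design.

**Identification.**  `identify_dendrimer()` scores each candidate by
(fraction of its theoretical fragment species matched) + (share of total
peak intensity carried by matched peaks), ranking deterministically with
alphabetical tie-break.  The score rewards both completeness and signal
coverage while staying in [0, 2]; it is intentionally simple and
thresholds on `frac_matched` are left to the caller.

## Synthetic fixtures

`generate_fixture(seed)` emulates the decoding workflow end to end: a
random DN dendron (generation ≤ 2 by default; schedule replicated or
per-generation with equal probability; uniform random codes), its full
theoretical fragment list as peaks with Gaussian m/z jitter of SD 0.05 Da
(reflector-scale mass accuracy), intensities proportional to species
multiplicity, plus 15 uniform noise peaks across 0.8–1.05× the fragment
mass range at low intensity.  The generator runs on a private RNG stream
(the session stream is untouched) and is byte-reproducible from its seed.
What it does **not** emulate: isotope envelopes, secondary fragmentation,
detector saturation, baseline chemical noise correlated with matrix
clusters, or mass-dependent resolution — so a passing self-identification
test demonstrates the scoring logic, not instrument-grade robustness.

## Numerical and design notes

* Problem sizes in the test suite are chosen to keep the default run fast:
  oracle equivalence is exhaustive over the 72 grammar-reachable trees of
  ≤ 12 units, canonicalisation is checked over 100 sampled permutations of
  the 6-row matrix, and generation-2 enumeration (the largest object
  touched) takes well under a second.
* `storage_capacity()` floors with a 10⁻⁹ epsilon; `encrypt_sort()` uses
  radix ordering (stable, C-locale); factorials are exact in base-10⁴
  limbs; fragment merging keys on m/z rounded to 10⁻⁶ Da.
* The CLI is a thin wrapper over exported functions (`cli_main()`), so the
  whole command surface is unit-testable in-process; the installed script
  lives at `system.file("cli", "dendricode", package = "dendricode")`.

## Limitations

* The `DR` core composition, the schedule semantics of two codes spread
  over three generations, and the matrix-reduction rule behind the
  second-generation byte figures discussed above are not inferable from
  available data; the package exposes configuration hooks instead of
  guesses.
* Monomers are restricted to two branches, as in the grammar; no 3-D or
  chemical-validity modelling is attempted.
* Absolute (composition-mode) masses for families other than DN require a
  user-supplied end-group constant.
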