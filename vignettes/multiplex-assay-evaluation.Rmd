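---
title: "Evaluating multiplex PCR and hybridization assays in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiplex PCR and hybridization assays in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexscreen)
```

## The problem

Highly multiplexed PCR and combined amplification/detection assays fail in
ways that single-primer design tools do not model. Primers from *different*
pairs can delimit unintended amplicons (by-products), degenerate oligos hit
loci that none of their designers intended, probes land inside the wrong
amplicons, and the oligo panel itself forms self-dimers, cross-dimers and
hairpins that deplete primers and depress amplification efficiency.
plexscreen evaluates a complete panel against arbitrary user references and
reports everything that *could* happen, leaving the judgement of what matters
to the assay designer: mismatch positions and thermodynamic values are
reported, never silently filtered.

The pipeline has three layers:

1. **Binding-site search** — every ungapped placement of every oligo on every
   contig, both strands, with up to k mismatches (k separately configurable
   for primers and probes, 0–3).
2. **Product prediction** — every combination of a rightward-extending primer
   hit and a downstream leftward-extending primer hit within the maximum
   product size becomes a predicted amplicon; probes fully contained in an
   amplicon are attached; everything else is classified as an unpaired hit.
3. **Thermodynamic screening** — nearest-neighbor ΔH/ΔS/ΔG/Tm for each
   primer/target duplex (mismatches included), plus exhaustive self-dimer,
   cross-dimer and hairpin scans of the panel at the user's experimental
   conditions.

## The search engine

The native backend is an exact Aho-Corasick multi-pattern automaton over the
alphabet {A,C,G,T,N}. Aho-Corasick matches exactly, so k-mismatch capability
is obtained by *Hamming-ball enumeration*: for each concrete pattern every
string at Hamming distance ≤ k is inserted into the automaton, annotated
with its distance. The ball of a pattern of length L has
`sum(choose(L, 0:k) * 3^(0:k))` members — 1,771 for a 20-mer at k = 2 — and
the union of all balls is bounded by a configurable cap (default 5×10⁶
patterns). Above the cap the engine falls back to the brute-force
sliding-window scanner, which produces identical results (this scanner is
also the independent oracle the test suite compares against). This design is
exact and non-heuristic: at a given k the native backend finds *every*
placement, which is what makes downstream "what could this panel amplify"
reasoning trustworthy.

Degenerate IUPAC codes are resolved before searching: each oligo expands to
the Cartesian product of its per-position codes (capped, default 1,024
variants), and after searching, hits are *deduplicated to one hit per
(parent oligo, contig, start, strand)*, keeping the variant with the fewest
mismatches (ties: lowest variant index). Without this rule a degenerate
oligo would appear to bind one site dozens of times.

Conventions worth stating precisely:

* Coordinates are 1-based, inclusive, and always reported on the plus
  strand; minus-strand hits are found by scanning for the reverse complement
  of the pattern.
* `mismatch_repr` entries are `offset:refBase>oligoBase` with offsets
  counted from the oligo's 5' end regardless of strand, and `refBase` read
  in the oligo's orientation. This makes the string directly interpretable
  against the oligo sequence — 3'-proximal mismatches, which practitioners
  weight heavily, are the high offsets.
* Reference characters outside A/C/G/T/N are normalized to N at load time,
  and N never matches any oligo base — a conservative stance toward dirty
  assemblies: an N can *cost* a hit (one of the k mismatches) but never
  fabricate one.

BLAST+ (`blastn -task blastn-short`) and bowtie adapters are provided for
compatibility; their tabular output is normalized to the same hit contract
(ungapped, full-query-coverage alignments only) and passed through the same
mismatch filter and deduplication. They are heuristic and may miss
placements the native backend finds; the native backend never requires them.

## Product prediction

A primer hit's *amplifying orientation* is determined by strand alone: a
plus-strand hit extends rightward, a minus-strand hit leftward. Role labels
(forward/reverse) are carried through for reporting but deliberately ignored
during pairing — a "forward" primer annealing on the minus strand is
exactly how unintended by-products arise, and surfacing those is the point
of the tool. Pairing likewise ignores set membership (the product records a
`cross_set` flag; its `set_id` is the rightward primer's). All combinations
within `max_product_size` are emitted; overlapping amplicons from nested
primer placements are legitimate output, not errors. No minimum product
length is enforced: two primers whose footprints overlap still define a
(short) product.

Probes are attached to every product that fully contains the probe's span,
on either strand — a hybridization probe can target either strand of a
double-stranded amplicon. A 3'-terminal primer mismatch does not veto a
product; it is reported (in `mismatch_repr` and in the weakened duplex ΔG)
and left to the user's interpretation, since published extension-blocking
rules disagree with one another.

The `size_match` annotation compares predicted length against the mapping
file's expected product size with exact equality by default; a bp tolerance
is exposed for gel-resolution use cases.

## Thermodynamics

Duplex enthalpies and entropies are summed over nearest-neighbor stacks
using the SantaLucia unified Watson-Crick parameter set with the
Allawi/SantaLucia/Peyret single-internal-mismatch extensions, plus terminal
initiation terms and the symmetry correction for self-complementary
duplexes. The tables ship as versioned TSV files under `inst/extdata/` (see
`nn_params()$versions`), so the parameter provenance is auditable and the
set is swappable. Tandem mismatches and terminal mismatches are outside the
parameter set and are rejected (product annotation trims terminal mismatch
columns and reports NA where a duplex cannot be scored).

Salt enters through the monovalent-equivalent conversion
`Na_eq = monovalent + 120*sqrt(max(0, divalent − dNTP))` (mM) and the
entropic correction `dS_corr = dS + 0.368*(N−1)*ln(Na_eq/1000)` per
phosphate step. Melting temperatures use
`Tm = 1000*dH/(dS_corr + R*ln(CT/x)) − 273.15` with x = 4 for
non-self-complementary and x = 1 for self-complementary bimolecular
structures, and the unimolecular form (no concentration term) for hairpins.
Products of ≥ 50 bp use the long-duplex empirical formula
`81.5 + 16.6*log10(Na_eq) + 0.41*%GC − 675/N`; shorter ones fall back to
the nearest-neighbor duplex Tm.

Dimers are scored by a windowed, ungapped, antiparallel scan: over every
offset of one sequence against the reverse of the other, every trimmed
window that starts and ends on Watson-Crick pairs and contains at most
isolated single mismatches is scored, and the window minimizing ΔG at the
step's annealing temperature is reported (ΔG ≥ 0 structures are reported as
0 with no structure string). This is a screening model, not a partition
function: it matches how practitioners triage panels, and it admits an
exact brute-force oracle — the test suite enumerates every offset and trim
on short oligos and verifies the scan returns the true minimum. Dangling
ends, coaxial stacking and terminal-mismatch stabilization are deliberately
out of scope.

Hairpins enumerate all stem/loop decompositions with stem ≥ 3 bp (strictly
Watson-Crick) and loop ≥ 3 nt; loop penalties are tabulated ΔG37 values
treated as purely entropic, with Jacobson-Stockmayer extrapolation between
and beyond tabulated sizes, and salt correction applied over the stem steps.

Degenerate oligos are screened through their thermodynamically most stable
expanded variant — the worst case for artefact formation — and the variant
used is recorded in the output.

### Flagging thresholds

Candidates are flagged with configurable thresholds defaulting to:
cross-dimers at ΔG ≤ −9 kcal/mol; self-dimers and hairpins at
ΔG ≤ −5 kcal/mol; hairpins additionally when Tm + 3 °C ≥ the step's
annealing temperature. The "step temperature" in the hairpin rule is read
as the step's annealing temperature. The complete matrix and all structures
are always written alongside the flagged list, so users applying different
cutoffs lose nothing.

## Conditions and defaults

`conditions()` captures one assay step: annealing temperature (°C),
monovalent cations (mM), divalent cations (mM), dNTP (mM) and oligo
concentration (nM). The package's worked examples use 55 °C, 50 mM
monovalent, 1.5 mM Mg²⁺, 0.8 mM dNTP and 111 nM per oligo for the
amplification step — a standard hot-start multiplex buffer — and 45 °C,
100 mM monovalent for hybridization. Divalent ions are handled by
monovalent-equivalence rather than a dedicated Mg²⁺ correction: it is a
single deterministic formula, and it reproduces the experimentally expected
direction (more Mg²⁺ → lower ΔG, higher Tm).

## The synthetic fixture and what the tests show

`demo_fixture()` builds a miniature assay whose ground truth is known by
construction: three random background contigs (2,000/1,800/1,500 bp, GC
0.45–0.55) with one multiplex set of six primers (one degenerate) and two
probes planted at fixed coordinates. Planting *overwrites* the background
(never inserts), so every truth coordinate is exact a priori. The planted
topologies cover: a clean amplicon with probe; a primer site carrying one
forced mismatch (present at k ≥ 1, absent at k = 0); two same-sense primer
placements sharing one reverse primer (two overlapping amplicons, each
carrying two probes); a degenerate-primer amplicon; lone forward and lone
reverse primers; and a probe with no product. The bundled copy under
`inst/extdata/demo/` is byte-identical to `demo_fixture(dir, seed = 42)`.

The generator emulates placement geometry and mismatch structure, which is
what the prediction layers consume. It does not emulate repeats, paralogs,
compositional bias or sequencing error, so passing tests demonstrate the
*bookkeeping* (search, pairing, attachment, classification) is exact — not
that real genomes are free of additional binding sites; on real data the
search layer will faithfully report whatever additional sites exist.

Problem sizes used by the automated checks were chosen to exercise the
engines well past the fixture scale while remaining quick on a laptop:
100 random search instances (contigs 1–5 kb, 5–20 patterns of 15–30 nt,
k ∈ 0–3) are compared hit-for-hit against the brute-force scanner, and the
dimer scan is verified against exhaustive enumeration on 8–12-mers, where
the enumeration is still exact.

## Numerical and design choices

* Variant expansion order is position-wise lexicographic, hit tables are
  canonically sorted, and CSV floats are fixed at two decimals, so two runs
  of one configuration are byte-identical.
* Dedup tie-breaks (lowest variant index) and pairing order are
  deterministic for the same reason.
* The two-decimal CSV formatting applies only to reports; all internal
  computation and the programmatic API are full double precision.
* The degeneracy cap (1,024 variants/oligo) and the pattern cap (5×10⁶)
  exist to keep pathological inputs (e.g. long N runs) from exhausting
  memory; both are configurable and both failure modes are explicit errors
  or documented fallbacks, never silent truncation.
* Probe-set association uses the `_probes` basename suffix and primer roles
  use the `_F`/`_R` name suffixes; both are conventions this package fixes
  (and exposes as arguments), since assay sheets in the wild vary.
* A single integer seed drives all fixture randomness through a private RNG
  stream that never disturbs the caller's `.Random.seed`.

## Known limitations

* Ungapped alignment only: insertions/deletions in the reference relative
  to an oligo are not found (consistent with the screening use case).
* The dimer/hairpin model is a windowed minimum, not a partition function;
  ΔG values are screening scores, and structures within ~0.5 kcal/mol of
  each other should be treated as equivalent.
* Mismatch thermodynamics cover single internal mismatches; duplexes with
  tandem or terminal mismatches are reported as unscorable (NA) rather than
  approximated.
* Amplification efficiency, polymerase kinetics and multiplex competition
  are out of scope: the tool reports what can hybridize and how stably,
  not band intensities.

## A complete run

```{r, eval = FALSE}
p <- demo_fixture_paths()
cfg <- run_config(
  references = p$references, primers = p$primers, probes = p$probes,
  mapping = p$mapping,
  search = search_config(max_mm_primer = 1, max_mm_probe = 1),
  max_product_size = 500,
  amplification = conditions("amplification", 55, monovalent = 50,
                             divalent = 1.5, dntp = 0.8, oligo_conc = 111),
  hybridization = conditions("hybridization", 45, monovalent = 100,
                             oligo_conc = 100),
  out_dir = "demo_out")
res <- run_pipeline(cfg)
res$products[, c("product_id", "contig_id", "start", "end", "length",
                 "fwd_name", "rev_name", "size_match")]
```

The same run is available from the shell via the installed `exec/plexscreen`
script, whose flags mirror `run_config()` one-to-one.
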