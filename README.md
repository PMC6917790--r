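# plexscreen

In silico evaluation of multiplex PCR and combined amplification/detection
(probe hybridization) assays against user-supplied reference sequences.

Multiplexed assays fail for reasons that singleplex design tools do not
model: primers from different pairs delimit unintended by-products,
degenerate oligos bind unplanned loci, probes fall inside the wrong
amplicons, and the panel itself forms primer dimers and hairpins that
deplete reagents. plexscreen takes a panel (primer sets plus internal
oligonucleotide probes), reference FASTA files, and the experimental
conditions, and reports everything the panel could plausibly do:

* **every binding site** of every oligo, both strands, up to k mismatches
  (k = 0–3, separately for primers and probes), via an exact (non-heuristic)
  Aho-Corasick multi-pattern search with Hamming-ball mismatch expansion;
  heuristic BLAST+/bowtie adapters are available and normalized to the same
  hit format;
* **every predicted amplicon**: all combinations of a rightward-extending
  and a downstream leftward-extending primer hit within the maximum product
  size — including cross-pair and same-primer by-products — with attached
  probes, per-primer mismatch descriptions, ΔG/Tm of each primer–target
  duplex, and the product Tm;
* **panel secondary structures**: self-dimers, cross-dimers and hairpins
  from nearest-neighbor thermodynamics (SantaLucia unified parameters with
  single internal mismatch extensions and salt correction), flagged at
  ΔG ≤ −9 kcal/mol (cross-dimers), ΔG ≤ −5 kcal/mol (self-dimers,
  hairpins), or hairpin Tm + 3 °C ≥ the step's annealing temperature.

Free energies follow the nearest-neighbor model
ΔG(T) = ΔH − T·ΔS_corr/1000 with
ΔS_corr = ΔS + 0.368·(N−1)·ln([Na⁺_eq]/1000) and
[Na⁺_eq] = [monovalent] + 120·√(max(0, [Mg²⁺] − [dNTP])) (mM);
bimolecular Tm = 1000·ΔH/(ΔS_corr + R·ln(C_T/x)) − 273.15. Mismatched
duplexes are scored with the published single-internal-mismatch stack
parameters — a G·G mismatch in its best context contributes −2.2 kcal/mol,
so "mismatched" is not "unstable". See the vignette
(`vignettes/multiplex-assay-evaluation.Rmd`) for the full model description
and design rationale.

## Worked example

The package bundles a miniature assay with known ground truth (three
contigs, one multiplex set of six primers — one degenerate — and two
probes; see `demo_fixture()`):

```r
library(plexscreen)
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
                 "fwd_name", "rev_name", "rev_mismatches", "size_match")]
#>   product_id contig_id start end length fwd_name rev_name rev_mismatches size_match
#> 1      P0001        c1   301 539    239   amrA_F   amrA_R              1       TRUE
#> 2      P0002        c2   401 719    319   blaT_F   blaT_R              0       TRUE
#> 3      P0003        c2   431 719    289   blaT_F   blaT_R              0      FALSE
#> 4      P0004        c3   250 469    220   vanX_F   vanX_R              0         NA
```

Four amplicons are predicted. P0001 forms despite one mismatch in its
reverse primer (reported, not vetoed — rerun with `max_mm_primer = 0` and
it disappears); P0002/P0003 are overlapping products of two placements of
the same forward primer sharing one reverse primer, each carrying both
probes; `size_match` compares the predicted length with the mapping file's
expected size (239 and 319 bp here; P0003's 289 bp does not match, and the
vanX pair has no expectation). Hits that pair with nothing are classified
rather than dropped:

```r
res$unpaired[, c("oligo_name", "contig_id", "start", "strand", "category")]
#>   oligo_name contig_id start strand                category
#> 1     blaT_F        c1  1200      + forward_without_reverse
#> 2     amrA_R        c3   800      - reverse_without_forward
#> 3     blaT_P        c3  1100      +   probe_without_product
```

Secondary structures print with their alignment; for example the strongest
cross-dimer of a primer against a near-complementary oligo:

```r
cond <- conditions("amplification", 55, monovalent = 50, divalent = 1.5,
                   dntp = 0.8, oligo_conc = 111)
cross_dimer("CAGTTGCGCCTAGGTTAAGC", "GCTTAACCTAGGCGCAACTG", cond)
#> dH = -158.90 kcal/mol, dS = -429.20 cal/(mol*K) (salt-corrected -442.45)
#> dG(step T) = -13.71 kcal/mol, dG37 = -21.68 kcal/mol, Tm = 59.96 degC
#> 5'-CAGTTGCGCCTAGGTTAAGC-3'
#>    ||||||||||||||||||||
#> 3'-GTCAACGCGGATCCAATTCG-5'
```

At −13.71 kcal/mol this pair would be flagged (≤ −9 kcal/mol) — a panel
containing both oligos would lose them to dimer formation at 55 °C.

With `out_dir` set, the run writes deterministic CSVs (`products.csv` in
long product-probe format, `unpaired.csv`, `degenerate_summary.csv`,
per-step dimer matrices, flagged structures, hairpins), a run log and a
config echo; identical configs reproduce the bundle byte for byte. The
installed `exec/plexscreen` script exposes the same pipeline from the
shell.

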