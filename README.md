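# mitoring

Structural genomics of circular plant mitochondrial genomes, in R.

Plant mtDNA is large, repeat-rich and structurally fluid: pairs of long
near-identical repeats recombine frequently, so one species' mitochondrial
genome exists as a set of interconvertible circular arrangements
("isoforms"), and the same repeats break assemblies.  `mitoring` is for
researchers finishing and comparing such genomes.  It provides:

* **Repeat discovery and naming** (`find_repeats`, `name_repeats`,
  `map_repeats_across_genomes`): k-mer seeded, x-drop extended pairs
  ≥ 50 bp, named `R01…Rn` by descending size, with homologous names
  transferred across genomes.
* **Assembly finishing** (`circularize_by_terminal_overlap`,
  `circularize_via_repeat`, `merge_circles_by_repeat`,
  `flag_repeat_contigs`): circularize contigs whose start duplicates their
  end (or whose ends sit inside a repeat), and merge circular chromosomes
  through recombination-like events at shared repeats — the product of
  merging circles of lengths `a` and `b` is a single circle of exactly
  `a + b` carrying two copies of the repeat.
* **Isoform testing** (`decompose_blocks`, `are_isoforms`,
  `structural_diff`): decompose two circles into shared blocks delimited by
  large repeats (≥ 500 bp by default) and decide by breadth-first search
  over recombination moves (inversion / fission / fusion, with subgenomic
  intermediates) whether they are perfect isoforms, returning a shortest
  move path or the irreducible differences.
* **Plastid insertions** (`find_insertions`, `classify_insertions`):
  detect MTPTs against a plastome reference, attribute plastid genes, and
  classify insertions across genomes as shared or variable (including
  mutually exclusive variants at one locus).
* **C-to-U RNA editing** (`call_editing_sites`, `annotate_effect`,
  `misincorporation_fraction`): a transparent threshold caller on per-site
  base counts restricted to coding regions, with codon-level effects
  (start gain, stop gain in overlapping frames, silent/missense) and the
  m1A misincorporation diagnostic.
* **Divergence** (`extract_concatenated_cds`, `align_pair`,
  `count_snps_gaps`, `distance_matrix`, `nj_tree`): concatenated-CDS
  SNP/gap tables and classic neighbor-joining trees (exact on additive
  matrices), with newick output.
* **Synthetic data** (`generate_mitogenome`, `shuffle_isoform`,
  `simulate_pileups`, …): seeded generators with machine-readable ground
  truth, so the whole stack is testable offline.

Internally all coordinates are 0-based half-open; 1-based coordinates
appear only in files (GFF3, pileup TSV) and reports.  Origin-spanning
features on circles are first-class.

## Worked example

```r
library(mitoring)

# a 30 kb circular genome with one inverted (800 bp) and one direct
# (600 bp) repeat pair planted at known positions
gen <- generate_mitogenome(genome_spec(30000,
  repeat_specs = list(
    list(length = 800, orientation = "inverted", copies = 2, family = "R02"),
    list(length = 600, orientation = "direct",   copies = 2, family = "R03")),
  seed = 11))
g <- gen$genome
g
#> CircularGenome 'synthetic_mt': circular, 30000 bp, 0 annotation(s)

rp <- name_repeats(find_repeats(g, min_len = 50), L = genome_length(g))
rp[, c("name", "a_start", "a_end", "b_start", "b_end",
       "orientation", "length", "identity")]
#>   name a_start a_end b_start b_end orientation length identity
#> 1  R01   26332 27132   29181 29981    inverted    800        1
#> 2  R02   19719 20319   27333 27933      direct    600        1

# apply one random recombination event, then prove the product is a
# perfect isoform of the original
sh <- shuffle_isoform(g, gen$truth, n_moves = 1, seed = 5)
are_isoforms(g, sh$genome, min_repeat = 500)
#> Isoform verdict: EQUIVALENT (perfect isoforms)
#> Moves: inversion@R01
```

The repeat table lists both planted pairs at their exact coordinates
(`identity = 1`), named by descending size.  The verdict says the shuffled
genome is reachable from the original by a single homologous-recombination
event — an inversion at the 800 bp inverted pair `R01` — i.e. the two
circles are alternative structural isoforms of the same genome, not
different genomes.

## Command line

Every module is exposed through one entry point (also installed at
`<library>/mitoring/scripts/mitoring`):

```sh
Rscript -e 'mitoring::mitoring_main(commandArgs(TRUE))' repeats genome.fasta -o repeats.bed
# subcommands: repeats circularize merge isoform cpinsert editing divergence tree simulate
```

Each run writes a JSON manifest (inputs, parameters, seed, version) next
to its outputs.

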