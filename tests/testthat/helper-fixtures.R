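# Shared fixture builders (all seeded, generated at test time).

rand_dna <- function(n, seed = NULL) {
  build <- function() paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# small genome with planted repeats, returns list(genome, truth)
fixture_repeat_genome <- function(length = 10000L, repeat_specs, seed = 1L) {
  generate_mitogenome(genome_spec(length, repeat_specs = repeat_specs,
                                  seed = seed))
}

# a reduced-scale plastome with the paper-sized gene set used in the
# insertion tests
fixture_plastome <- function(seed = 21L) {
  generate_plastome(30000L, genes = list(
    list(name = "ndhD", length = 1500, strand = "+"),
    list(name = "petG", length = 120, strand = "+"),
    list(name = "petL", length = 96, strand = "+"),
    list(name = "rbcL", length = 1434, strand = "+"),
    list(name = "rpoB", length = 3213, strand = "+"),
    list(name = "ycf3", length = 507, strand = "+"),
    list(name = "psaA", length = 2253, strand = "+"),
    list(name = "psaB", length = 2205, strand = "+"),
    list(name = "rpoC1", length = 2000, strand = "+")), seed = seed)
}

cp_gene_interval <- function(cp, gene, len, from_start = 0L) {
  r <- cp$annotations[cp$annotations$name == gene, , drop = FALSE]
  list(cp_start = r$start + from_start, cp_end = r$start + from_start + len)
}
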