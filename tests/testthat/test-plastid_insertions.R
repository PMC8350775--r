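test_that("six planted catalogue-sized insertions are recovered exactly", {
  cp <- fixture_plastome()
  specs <- list(cp_gene_interval(cp, "ndhD", 194),
                cp_gene_interval(cp, "petG", 116),
                cp_gene_interval(cp, "petL", 81),
                cp_gene_interval(cp, "rbcL", 198),
                cp_gene_interval(cp, "rpoB", 57),
                cp_gene_interval(cp, "ycf3", 72))
  gen <- generate_mitogenome(genome_spec(40000, insertion_specs = specs,
                                         seed = 401), cp = cp)
  calls <- find_insertions(gen$genome, cp)
  tr <- gen$truth$insertions
  expect_equal(nrow(calls), 6L)
  expect_setequal(calls$length, c(194L, 116L, 81L, 198L, 57L, 72L))
  expect_equal(calls$mt_start, sort(tr$mt_start))
  expect_true(all(calls$identity == 1))
  # gene attribution from cp annotation overlap
  genes <- sort(unlist(strsplit(calls$cp_genes, ",")))
  expect_setequal(genes, c("ndhD", "petG", "petL", "rbcL", "rpoB", "ycf3"))
  # mt-side and cp-side lengths both reported
  expect_equal(calls$length, calls$cp_length)
})

test_that("unrelated genomes give no calls; a large rpoC1-like piece is found", {
  cp <- fixture_plastome()
  bare <- generate_mitogenome(genome_spec(20000, seed = 402))$genome
  expect_equal(nrow(find_insertions(bare, cp)), 0L)

  gen <- generate_mitogenome(genome_spec(20000, insertion_specs = list(
    cp_gene_interval(cp, "rpoC1", 1239)), seed = 403), cp = cp)
  calls <- find_insertions(gen$genome, cp)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$length, 1239L)
  expect_true(grepl("rpoC1", calls$cp_genes))
})

test_that("strand covariance: rc of the cp reference flips strands only", {
  cp <- fixture_plastome()
  gen <- generate_mitogenome(genome_spec(20000, insertion_specs = list(
    cp_gene_interval(cp, "rbcL", 198),
    c(cp_gene_interval(cp, "ndhD", 194), list(strand = "-"))),
    seed = 404), cp = cp)
  fwd <- find_insertions(gen$genome, cp)
  rev <- find_insertions(gen$genome, reverse_complement(cp))
  o1 <- fwd[order(fwd$mt_start), ]; o2 <- rev[order(rev$mt_start), ]
  expect_equal(o1$length, o2$length)
  expect_equal(o1$mt_start, o2$mt_start)
  expect_true(all(o1$strand != o2$strand))
})

test_that("calls are disjoint on the mt side", {
  cp <- fixture_plastome()
  gen <- generate_mitogenome(genome_spec(30000, insertion_specs = list(
    cp_gene_interval(cp, "rpoC1", 1239),
    cp_gene_interval(cp, "rbcL", 198),
    cp_gene_interval(cp, "rpoB", 57)), seed = 405), cp = cp)
  calls <- find_insertions(gen$genome, cp)
  calls <- calls[order(calls$mt_start), ]
  if (nrow(calls) > 1L) {
    expect_true(all(calls$mt_start[-1] >= calls$mt_end[-nrow(calls)]))
  }
})

test_that("hits in the second plastid IR copy collapse onto the first", {
  genes <- list(list(name = "g1", length = 600, strand = "+"))
  cp <- generate_plastome(25000, genes = genes, ir = list(length = 3000),
                          seed = 406)
  ir <- mitoring:::.plastid_ir(cp)
  expect_false(is.null(ir))
  # plant an insertion copied from inside the SECOND IR copy
  src <- ir$b_start + 500L
  gen <- generate_mitogenome(genome_spec(15000, insertion_specs = list(
    list(cp_start = src, cp_end = src + 300L)), seed = 407), cp = cp)
  calls <- find_insertions(gen$genome, cp)
  expect_equal(nrow(calls), 1L)
  # reported cp interval lies in the first IR copy
  expect_true(mitoring:::.circ_overlap(calls$cp_start, calls$cp_length,
                                       ir$a_start, ir$length,
                                       cp$length) == calls$cp_length)
})

test_that("classification separates shared and variable clusters", {
  cp <- fixture_plastome()
  shared_specs <- list(cp_gene_interval(cp, "rbcL", 198),
                       cp_gene_interval(cp, "petG", 116))
  # two genomes carry an rpoC1-like insert, two carry psaA+psaB-like at the
  # same flanked locus (same genomic background, different insert)
  base <- generate_mitogenome(genome_spec(25000,
                                          insertion_specs = shared_specs,
                                          seed = 408), cp = cp)
  rA <- cp$annotations[cp$annotations$name == "rpoC1", ]
  pA <- cp$annotations[cp$annotations$name == "psaA", ]
  pB <- cp$annotations[cp$annotations$name == "psaB", ]
  ins_rpo <- mitoring:::.sub0(cp$seq, rA$start, rA$start + 1239L)
  ins_psa <- paste0(mitoring:::.sub0(cp$seq, rA$start, rA$start + 15L),
                    mitoring:::.sub0(cp$seq, pA$start, pA$start + 354L),
                    mitoring:::.sub0(cp$seq, pB$start, pB$start + 2253L))
  at <- 12000L
  mk <- function(id, insert) {
    s <- base$genome$seq
    circular_genome(id, paste0(substr(s, 1, at), insert,
                               substr(s, at + 1, nchar(s))), "circular")
  }
  genomes <- list(sat1 = mk("sat1", ins_rpo), sat2 = mk("sat2", ins_rpo),
                  sal1 = mk("sal1", ins_psa), sal2 = mk("sal2", ins_psa))
  calls <- lapply(genomes, find_insertions, cp = cp)
  tab <- classify_insertions(calls, genomes = genomes)
  shared <- tab[tab$status == "shared", ]
  variable <- tab[tab$status == "variable", ]
  expect_gte(length(unique(shared$cluster)), 2L)   # rbcL + petG
  expect_gte(length(unique(variable$cluster)), 2L) # rpoC1 vs psaA/psaB
  # the two variable clusters sit at one shared mt locus with a 2+2 split
  vclusters <- unique(variable$cluster)
  pres <- tapply(variable$present, variable$cluster, sum)
  expect_true(all(pres[as.character(vclusters)] == 2L))
  # the rpoC1-like and psaA-like variants occupy the same mt locus
  loc_rpo <- variable$locus[variable$present &
                              grepl("rpoC1", variable$cp_genes)]
  loc_psa <- variable$locus[variable$present &
                              grepl("psaA", variable$cp_genes)]
  expect_true(length(intersect(loc_rpo, loc_psa)) >= 1L)

  # all genomes identical -> everything shared
  same <- classify_insertions(list(a = calls$sat1, b = calls$sat1),
                              genomes = list(a = genomes$sat1,
                                             b = genomes$sat1))
  expect_true(all(same$status == "shared"))

  # absence in one genome -> variable cluster with absence recorded
  miss <- classify_insertions(list(a = calls$sat1, b = list(
    find_insertions(generate_mitogenome(genome_spec(25000,
      insertion_specs = shared_specs[1], seed = 409), cp = cp)$genome,
      cp))[[1]]))
  expect_true(any(miss$status == "variable" & !miss$present))
})
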