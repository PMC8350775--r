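editing_fixture <- function(seed = 501L) {
  generate_mitogenome(genome_spec(20000, gene_specs = list(
    list(name = "cox1", length = 900, strand = "+", start = "ACG"),
    list(name = "rps3", length = 600, strand = "-"),
    list(name = "nad1", length = 300, strand = "+")),
    editing_specs = list(
      list(gene = "cox1", offset = 1, extent = 0.89),
      list(gene = "rps3", offset = 200, extent = 0.5),
      list(gene = "nad1", offset = 50, extent = 0.95)),
    seed = seed))
}

test_that("strand-consistent C-to-U rule: only C/T (+) and G/A (-) are called", {
  gen <- editing_fixture()
  pl <- simulate_pileups(gen$genome, gen$truth$editing, depth = 100,
                         seed = 1, error_rate = 0)
  sites <- call_editing_sites(pl, gen$genome)
  expect_setequal(unique(sites$position), gen$truth$editing$position)
  ref <- substring(gen$genome$seq, sites$position + 1, sites$position + 1)
  expect_true(all((ref == "C" & sites$strand == "+") |
                    (ref == "G" & sites$strand == "-")))
  expect_true(all(sites$extent > 0 & sites$extent <= 1))
})

test_that("filter rules: depth, fraction, CDS restriction, variant class", {
  g <- circular_genome("g", paste0("ATG", "CCT", "TCA", "GGG", "TAA",
                                   rand_dna(85, seed = 502)),
                       annotations = annotation_table(
                         feature_type = "CDS", start = 0L, end = 15L,
                         strand = "+", name = "g1"))
  mk <- function(pos0, ref, A = 0, C = 0, G = 0, T = 0) {
    data.frame(seq_id = "g", pos = pos0 + 1L, ref_base = ref,
               count_A = A, count_C = C, count_G = G, count_T = T,
               position = pos0)
  }
  # ref C with 89% T -> called
  called <- call_editing_sites(mk(3L, "C", C = 11, T = 89), g)
  expect_equal(nrow(called), 1L)
  expect_equal(called$extent, 0.89)
  # below depth
  expect_equal(nrow(call_editing_sites(mk(3L, "C", C = 1, T = 8), g)), 0L)
  # below fraction
  expect_equal(nrow(call_editing_sites(mk(3L, "C", C = 95, T = 5), g)), 0L)
  # non-C-to-U (ref A with T majority, inside the CDS) discarded
  expect_equal(nrow(call_editing_sites(mk(0L, "A", A = 10, T = 90), g)), 0L)
  # outside CDS
  far <- mk(50L, substring(g$seq, 51, 51), C = 10, T = 90)
  expect_equal(nrow(call_editing_sites(far, g)), 0L)
  # ref mismatch errors with positions
  badpl <- mk(3L, "G", C = 11, T = 89)
  expect_error(call_editing_sites(badpl, g), "position")
  # monotonicity: lowering min_fraction never removes a call
  hi <- call_editing_sites(mk(3L, "C", C = 60, T = 40), g,
                           min_fraction = 0.3)
  lo <- call_editing_sites(mk(3L, "C", C = 60, T = 40), g,
                           min_fraction = 0.05)
  expect_true(all(hi$position %in% lo$position))
})

test_that("effects: start gain, silent, missense, stop gain in overlap", {
  # ACG|TCA|CCC|TAA: editing codon 1 pos 2 -> ATG start gain;
  # codon 2 (TCA) pos 2 -> TTA missense Ser->Leu; codon 3 pos 3 silent
  g <- circular_genome("g", paste0("ACGTCACCCTAA", rand_dna(88, seed = 503)),
                       annotations = annotation_table(
                         feature_type = "CDS", start = 0L, end = 12L,
                         strand = "+", name = "main"))
  eff <- annotate_effect(g, 1L)
  expect_equal(eff$effect, "start_gain")
  eff <- annotate_effect(g, 4L)
  expect_equal(eff$effect, "missense")
  expect_equal(eff$codon, "TCA")
  expect_equal(eff$codon_edited, "TTA")
  eff <- annotate_effect(g, 8L)
  expect_equal(eff$effect, "silent")
  expect_error(annotate_effect(g, 50L), "outside")

  # overlapping CDSs in different frames: one edit, two effect records
  # (missense in frame 1, stop gain in the +1-shifted frame, the
  # rps3/rpl16-style configuration): UCA -> UUA while xTC A -> ...TAG
  s <- paste0("ATG", "CTC", "ATT", "TCA", "GGT", "TAA", rand_dna(82, seed = 504))
  ann <- annotation_table(feature_type = c("CDS", "CDS"),
                          start = c(0L, 10L), end = c(18L, 16L),
                          strand = c("+", "+"), name = c("rps3", "rpl16"))
  g2 <- circular_genome("g2", s, annotations = ann)
  eff2 <- annotate_effect(g2, 10L)   # the C of TCA, first base of rpl16 frame
  expect_equal(nrow(eff2), 2L)
  expect_setequal(eff2$gene, c("rps3", "rpl16"))
  e_rps3 <- eff2[eff2$gene == "rps3", ]
  expect_equal(e_rps3$codon, "TCA")
  expect_equal(e_rps3$codon_edited, "TTA")
  expect_equal(e_rps3$effect, "missense")
  expect_equal(eff2$effect[eff2$gene == "rpl16"], "stop_gain")
})

test_that("minus-strand sites are edited in coding space", {
  gen <- editing_fixture()
  pl <- simulate_pileups(gen$genome, gen$truth$editing, depth = 200,
                         seed = 2, error_rate = 0)
  sites <- call_editing_sites(pl, gen$genome)
  rps3 <- sites[sites$gene == "rps3", ]
  expect_equal(nrow(rps3), 1L)
  expect_equal(rps3$strand, "-")
  # the codon is reported on the coding strand and carries a C at the
  # edited position
  expect_equal(substr(rps3$codon, rps3$codon_position, rps3$codon_position),
               "C")
  expect_equal(substr(rps3$codon_edited, rps3$codon_position,
                      rps3$codon_position), "T")
})

test_that("parameter recovery on simulated pileups at depth >= 50", {
  gen <- editing_fixture(505)
  tr <- gen$truth$editing
  depth <- 100L
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    pl <- simulate_pileups(gen$genome, tr, depth = depth, seed = seed,
                           error_rate = 0.002)
    sites <- call_editing_sites(pl, gen$genome)
    got <- sites[!duplicated(sites$position), ]
    # all planted sites recovered
    expect_setequal(got$position, tr$position)
    # extent error within 3 binomial SEs
    m <- match(tr$position, got$position)
    se <- sqrt(tr$extent * (1 - tr$extent) / depth)
    expect_true(all(abs(got$extent[m] - tr$extent) <= 3 * se + 1e-9),
                label = paste("seed", seed))
    # no false calls at non-planted positions (error rate stays below the
    # 10% fraction threshold at this depth)
    expect_equal(nrow(got), nrow(tr))
    hits <- hits + nrow(got); total <- total + nrow(tr)
  }
  expect_equal(hits, total)
})

test_that("m1A misincorporation diagnostic", {
  g <- circular_genome("g", rand_dna(5000, seed = 506))
  pos <- 4756L  # echoes a 1-based 4,757
  pl <- data.frame(seq_id = "g", pos = pos + 1L, ref_base = "A",
                   count_A = 103L, count_C = 0L, count_G = 0L,
                   count_T = 97L, position = pos)
  res <- misincorporation_fraction(pl, pos)
  expect_equal(res$fraction, 0.485)
  expect_true(res$flagged)

  pl2 <- data.frame(seq_id = "g", pos = 10L, ref_base = "A",
                    count_A = 200L, count_C = 0L, count_G = 0L,
                    count_T = 0L, position = 9L)
  res2 <- misincorporation_fraction(pl2, 9L)
  expect_equal(res2$fraction, 0)
  expect_false(res2$flagged)

  pl3 <- pl2; pl3[, c("count_A")] <- 0L
  expect_error(misincorporation_fraction(pl3, 9L), "zero depth")
  expect_error(misincorporation_fraction(pl2, 100L), "no pileup")
})
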