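iso_fixture <- function(seed, length = 25000L,
                        specs = list(
                          list(length = 700, orientation = "inverted",
                               copies = 2, family = "RI"),
                          list(length = 600, orientation = "direct",
                               copies = 2, family = "RD"))) {
  generate_mitogenome(genome_spec(length, repeat_specs = specs, seed = seed))
}

test_that("identical, rotated and reverse-complemented genomes are 0-move isoforms", {
  gen <- iso_fixture(301)
  g <- gen$genome
  for (other in list(g, rotate(g, 12345L), reverse_complement(g))) {
    v <- are_isoforms(g, other, min_repeat = 500)
    expect_true(isTRUE(v$equivalent))
    expect_length(v$moves, 0L)
  }
})

test_that("decompose_blocks: identical genomes give one block; an inversion splits them", {
  g0 <- generate_mitogenome(genome_spec(8000, seed = 302))$genome
  dec <- decompose_blocks(g0, g0, min_repeat = 500)
  expect_equal(nrow(dec$blocks), 1L)
  expect_identical(dec$arrangement_a, dec$arrangement_b)

  gen <- iso_fixture(303)
  sh <- shuffle_isoform(gen$genome, gen$truth, n_moves = 1, seed = 1)
  expect_equal(sh$log[[1]]$type, "inversion")
  dec <- decompose_blocks(gen$genome, sh$genome, min_repeat = 500)
  # same block ids on both sides, at least one sign/order change
  expect_setequal(gsub("^[+-]", "", dec$arrangement_a),
                  gsub("^[+-]", "", dec$arrangement_b))
  expect_false(identical(dec$arrangement_a, dec$arrangement_b))
  expect_equal(nrow(dec$private), 0L)
})

test_that("a six-block architecture is recovered from generator truth", {
  # three families >= 500 bp partition the circle into six block slots
  gen <- generate_mitogenome(genome_spec(30000, repeat_specs = list(
    list(length = 900, orientation = "inverted", copies = 2, family = "A"),
    list(length = 700, orientation = "direct", copies = 2, family = "B"),
    list(length = 500, orientation = "direct", copies = 2, family = "C")),
    seed = 304))
  dec <- decompose_blocks(gen$genome, gen$genome, min_repeat = 500)
  expect_equal(nrow(dec$blocks), 6L)
  expect_equal(nrow(dec$private), 0L)
})

test_that("recombination_moves enumerates the expected neighbor sets", {
  inv <- list(c("+R|F", "+B|A", "-R|F", "+B|B"))
  nb <- recombination_moves(inv)
  keys <- unique(vapply(nb, function(x) mitoring:::.state_key(x$state),
                        character(1)))
  expect_length(keys, 1L)                      # one inversion neighbor
  expect_true(all(vapply(nb, function(x) x$move$type, character(1)) ==
                    "inversion"))

  dir <- list(c("+R|F", "+B|A", "+R|F", "+B|B"))
  nbd <- recombination_moves(dir)
  expect_length(nbd, 1L)
  expect_equal(nbd[[1]]$move$type, "fission")
  expect_length(nbd[[1]]$state, 2L)            # two circles

  none <- list(c("+R|F", "+B|A", "+R|G", "+B|B"))
  expect_length(recombination_moves(none), 0L)

  # moves conserve the block multiset
  for (x in c(nb, nbd)) {
    syms <- gsub("^[+-]", "", unlist(x$state))
    expect_setequal(syms[startsWith(syms, "B|")], c("B|A", "B|B"))
  }
})

test_that("shuffle_isoform products are recognized within n moves", {
  gen <- iso_fixture(305)
  for (n in c(1L, 2L, 3L)) {
    sh <- shuffle_isoform(gen$genome, gen$truth, n_moves = n, seed = n + 10L)
    expect_lte(length(sh$log), n)
    v <- are_isoforms(gen$genome, sh$genome, min_repeat = 500,
                      max_moves = max(n, 2L))
    expect_true(isTRUE(v$equivalent), label = paste("n =", n))
    expect_lte(length(v$moves), n)
  }
  # n = 0 leaves the genome unchanged
  sh0 <- shuffle_isoform(gen$genome, gen$truth, n_moves = 0, seed = 1)
  expect_identical(sh0$genome$seq, gen$genome$seq)
  expect_length(sh0$log, 0L)
  # determinism of the move log
  sh_a <- shuffle_isoform(gen$genome, gen$truth, n_moves = 3, seed = 7)
  sh_b <- shuffle_isoform(gen$genome, gen$truth, n_moves = 3, seed = 7)
  expect_identical(sh_a$genome$seq, sh_b$genome$seq)
  expect_identical(sh_a$log, sh_b$log)
})

test_that("BFS verdict matches the sequence-level reachability oracle", {
  # small instance: 2 families, <= 8 blocks; enumerate reachable states on
  # raw DNA and check both directions of the equivalence
  gen <- generate_mitogenome(genome_spec(6000, repeat_specs = list(
    list(length = 400, orientation = "inverted", copies = 2, family = "RI"),
    list(length = 350, orientation = "direct", copies = 2, family = "RD")),
    seed = 306))
  g <- gen$genome
  tr <- gen$truth$repeats
  fam_seqs <- lapply(split(tr, tr$family), function(d) {
    d <- d[d$sign == "+", ][1, ]
    substr(g$seq, d$start + 1, d$end)
  })
  reach <- oracle_isoform_reachable(g$seq, fam_seqs, max_depth = 3L)
  expect_gt(nrow(reach), 1L)
  # positives: every reachable single-circle state is recognized, within
  # the oracle's move count
  picked <- reach[order(reach$moves), ]
  picked <- picked[!duplicated(picked$moves), ]   # one per depth
  for (r in seq_len(nrow(picked))) {
    other <- circular_genome("other", picked$canon[r], "circular")
    v <- are_isoforms(g, other, min_repeat = 300, max_moves = 4L)
    expect_true(isTRUE(v$equivalent), label = paste("depth", picked$moves[r]))
    expect_lte(length(v$moves), picked$moves[r])
  }
  # negative: a repeat-free segment swap is not reachable, and the BFS agrees
  s <- g$seq
  blockA <- substr(s, 1, 500); blockB <- substr(s, 501, 1000)
  swapped <- paste0(blockB, blockA, substr(s, 1001, nchar(s)))
  expect_false(oracle_canon_circle(swapped) %in% reach$canon)
  v <- are_isoforms(g, circular_genome("sw", swapped, "circular"),
                    min_repeat = 300, max_moves = 3L)
  expect_false(isTRUE(v$equivalent))
})

test_that("non-isoform differences are reported, never silently equivalent", {
  gen <- iso_fixture(307, length = 15000L)
  g <- gen$genome
  # 1 kb deletion -> private segment difference
  del <- circular_genome("del", paste0(substr(g$seq, 1, 2000),
                                       substr(g$seq, 3001, g$length)),
                         "circular")
  v <- are_isoforms(g, del, min_repeat = 500)
  expect_false(isTRUE(v$equivalent))
  expect_gte(nrow(v$differences), 1L)

  # duplication of a block fragment into another block, with no flanking
  # repeat: not explicable by repeat-mediated recombination
  ins <- circular_genome("ins", paste0(
    substr(g$seq, 1, 9000), substr(g$seq, 2001, 3000),
    substr(g$seq, 9001, g$length)), "circular")
  v2 <- are_isoforms(g, ins, min_repeat = 500)
  expect_false(isTRUE(v2$equivalent))
  expect_gte(nrow(v2$differences), 1L)

  # symmetric verdicts
  expect_false(isTRUE(are_isoforms(del, g, min_repeat = 500)$equivalent))
})

test_that("search caps yield an explicit undecided status", {
  gen <- iso_fixture(308)
  sh <- shuffle_isoform(gen$genome, gen$truth, n_moves = 1, seed = 3)
  v <- are_isoforms(gen$genome, sh$genome, min_repeat = 500, max_states = 2L)
  expect_true(is.na(v$equivalent))
  expect_equal(v$status, "undecided")
})

test_that("structural_diff reports mediating families and repeat expansions", {
  base <- fixture_repeat_genome(12000L, list(
    list(length = 900, orientation = "direct", copies = 2, family = "R02")),
    seed = 309)$genome
  rsal <- rand_dna(122, seed = 310)
  spacer <- rand_dna(500, seed = 311)
  A <- circular_genome("A", paste0(base$seq, rsal, spacer, rsal), "circular")
  B <- circular_genome("B", paste0(base$seq, rsal, spacer), "circular")
  sd <- structural_diff(A, B, min_repeat = 500)
  expect_gte(nrow(sd$copy_number_diffs), 1L)
  expect_true(any(sd$copy_number_diffs$copies_a == 2L &
                    sd$copy_number_diffs$copies_b == 1L))

  # repeat expansion (3.5 kb -> ~10 kb style) appears as a length diff row
  gen <- fixture_repeat_genome(12000L, list(
    list(length = 700, orientation = "direct", copies = 2, family = "R03")),
    seed = 312)
  tr <- gen$truth$repeats
  ext <- rand_dna(1500, seed = 313)
  s <- gen$genome$seq
  sB <- paste0(substr(s, 1, tr$end[1]), ext,
               substr(s, tr$end[1] + 1, tr$end[2]), ext,
               substr(s, tr$end[2] + 1, nchar(s)))
  B2 <- circular_genome("B2", sB, "circular")
  sd2 <- structural_diff(gen$genome, B2, min_repeat = 500)
  expect_equal(nrow(sd2$repeat_length_diffs), 1L)
  expect_equal(sd2$repeat_length_diffs$delta, 1500L)

  # identical genomes: empty diff
  sd0 <- structural_diff(base, base, min_repeat = 500)
  expect_equal(nrow(sd0$private), 0L)
  expect_equal(nrow(sd0$repeat_length_diffs), 0L)
  expect_equal(nrow(sd0$copy_number_diffs), 0L)
})
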