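test_that("a planted 60 bp direct pair is recovered with exact coordinates", {
  gen <- fixture_repeat_genome(10000L, list(
    list(length = 60, orientation = "direct", copies = 2, family = "F")),
    seed = 101)
  rp <- find_repeats(gen$genome, min_len = 50)
  tr <- gen$truth$repeats
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "direct")
  expect_equal(rp$length, 60L)
  expect_setequal(c(rp$a_start, rp$b_start), tr$start)
  expect_setequal(c(rp$a_end, rp$b_end), tr$end)
  expect_equal(rp$identity, 1)
})

test_that("a planted 186 bp inverted pair is recovered as inverted", {
  gen <- fixture_repeat_genome(10000L, list(
    list(length = 186, orientation = "inverted", copies = 2, family = "F")),
    seed = 102)
  rp <- find_repeats(gen$genome, min_len = 50)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "inverted")
  expect_equal(rp$length, 186L)
  expect_setequal(c(rp$a_start, rp$b_start), gen$truth$repeats$start)
})

test_that("a repeat-free genome yields an empty list (oracle-confirmed)", {
  gen <- fixture_repeat_genome(8000L, list(), seed = 103)
  expect_equal(nrow(oracle_exact_repeats(gen$genome$seq, 50)), 0L)
  expect_equal(nrow(find_repeats(gen$genome, min_len = 50)), 0L)
})

test_that("finder equals the exhaustive oracle on small genomes", {
  for (seed in c(111, 112, 113)) {
    gen <- fixture_repeat_genome(4000L, list(
      list(length = 120, orientation = "direct", copies = 2, family = "D"),
      list(length = 80, orientation = "inverted", copies = 2, family = "I")),
      seed = seed)
    got <- find_repeats(gen$genome, min_len = 50, min_identity = 1.0)
    want <- oracle_exact_repeats(gen$genome$seq, 50)
    key <- function(df) sort(paste(pmin(df$a_start, df$b_start),
                                   pmax(df$a_start, df$b_start),
                                   df$length, df$orientation))
    expect_identical(key(got), key(want), label = paste("seed", seed))
  }
})

test_that("origin-spanning repeat copies are found", {
  gen <- fixture_repeat_genome(6000L, list(
    list(length = 100, orientation = "direct", copies = 2, family = "F")),
    seed = 121)
  # rotate so that one copy straddles the origin
  mid <- gen$truth$repeats$start[2] + 50L
  g <- rotate(gen$genome, mid)
  rp <- find_repeats(g, min_len = 50)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$length, 100L)
  expect_true(any(c(rp$a_wraps, rp$b_wraps)))
})

test_that("repeat multiset is invariant under rotation", {
  gen <- fixture_repeat_genome(12000L, list(
    list(length = 300, orientation = "direct", copies = 2, family = "D"),
    list(length = 200, orientation = "inverted", copies = 2, family = "I")),
    seed = 131)
  ref <- find_repeats(gen$genome, min_len = 50)
  sig <- function(rp) rp[order(rp$length, rp$orientation),
                         c("length", "orientation", "identity")]
  for (off in c(777L, 5000L, 11999L)) {
    rot <- find_repeats(rotate(gen$genome, off), min_len = 50)
    expect_equal(sig(rot), sig(ref), ignore_attr = TRUE, label = off)
  }
  rc <- find_repeats(reverse_complement(gen$genome), min_len = 50)
  expect_equal(sig(rc), sig(ref), ignore_attr = TRUE)
})

test_that("name_repeats orders by size with positional tie-break", {
  gen <- fixture_repeat_genome(30000L, list(
    list(length = 3553, orientation = "direct", copies = 2, family = "c"),
    list(length = 10430, orientation = "direct", copies = 2, family = "b"),
    list(length = 347, orientation = "direct", copies = 2, family = "d")),
    seed = 141)
  rp <- name_repeats(find_repeats(gen$genome, min_len = 50),
                     L = gen$genome$length)
  expect_equal(rp$name, c("R01", "R02", "R03"))
  expect_equal(rp$length, c(10430L, 3553L, 347L))
  # ties broken by smaller a_start
  tie <- rp[c(1, 1), ]
  tie$length <- c(100L, 100L)
  tie$a_start <- c(500L, 100L)
  tie$name <- ""
  named <- name_repeats(tie, L = 30000L)
  expect_equal(named$a_start, c(100L, 500L))
  expect_equal(named$name, c("R01", "R02"))
  expect_equal(nrow(name_repeats(find_repeats(
    fixture_repeat_genome(3000L, list(), seed = 142)$genome))), 0L)
})

test_that("cross-genome mapping transfers names, handles expansion and novelty", {
  gen <- fixture_repeat_genome(20000L, list(
    list(length = 3553, orientation = "direct", copies = 2, family = "R03"),
    list(length = 900, orientation = "direct", copies = 2, family = "R05")),
    seed = 151)
  ra <- name_repeats(find_repeats(gen$genome, 50), gen$genome$length)
  # same genome -> identical naming
  mapped <- map_repeats_across_genomes(ra, gen$genome,
                                       find_repeats(gen$genome, 50))
  expect_setequal(mapped$name, ra$name)

  # expanded homolog (3,553 -> ~10 kb containing the smaller copy) keeps its
  # name; an unrelated new pair gets a fresh name
  tr <- gen$truth$repeats
  r03 <- tr[tr$family == "R03", ]
  ext <- rand_dna(6500, seed = 152)
  novel <- rand_dna(400, seed = 153)
  s <- gen$genome$seq
  parts <- c(substr(s, 1, r03$end[1]), ext,
             substr(s, r03$end[1] + 1, r03$end[2]), ext,
             substr(s, r03$end[2] + 1, nchar(s)),
             novel, rand_dna(200, seed = 154), novel)
  other <- circular_genome("other", paste(parts, collapse = ""), "circular")
  rb <- find_repeats(other, 50)
  mapped <- map_repeats_across_genomes(ra, other, rb)
  big <- mapped[which.max(mapped$length), ]
  expect_gt(big$length, 9000)
  expect_equal(big$name, ra$name[ra$length == 3553])
  expect_true(any(!mapped$name %in% ra$name))  # novel pair, fresh name
})

test_that("count_repeat_pairs counts families, not pairwise combinations", {
  gen <- fixture_repeat_genome(15000L, list(
    list(length = 400, orientation = "direct", copies = 3, family = "T"),
    list(length = 250, orientation = "direct", copies = 2, family = "D")),
    seed = 161)
  rp <- name_repeats(find_repeats(gen$genome, 50), gen$genome$length)
  expect_equal(sum(rp$length == 400), 3L)   # 3 pairwise combinations
  expect_equal(count_repeat_pairs(gen$genome), 2L)
  expect_equal(count_repeat_pairs(
    fixture_repeat_genome(3000L, list(), seed = 162)$genome), 0L)
})

test_that("nested copies (R04-in-R01 style) are reported with family grouping", {
  gen <- fixture_repeat_genome(30000L, list(
    list(length = 3000, orientation = "direct", copies = 2, family = "R01"),
    list(length = 400, orientation = "direct", copies = 1, family = "R04",
         within = "R01")), seed = 171)
  rp <- name_repeats(find_repeats(gen$genome, 50), gen$genome$length)
  # the standalone R04 copy pairs with the embedded copies inside both R01
  # copies: expect the 3000 bp pair plus >= 2 pairs of ~400 bp
  expect_equal(sum(rp$length == 3000), 1L)
  expect_gte(sum(rp$length == 400), 2L)
  small <- rp[rp$length == 400, ]
  expect_true(length(unique(small$family)) == 1L)
})

test_that("min_len below the supported seed size is rejected with advice", {
  g <- circular_genome("g", rand_dna(1000, seed = 181))
  expect_error(find_repeats(g, min_len = 10), "min_len")
})
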