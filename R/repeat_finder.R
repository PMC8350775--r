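#' Find repeated sequence pairs within a genome
#'
#' Discovers pairs of repeated segments (>= `min_len` bp, identity >=
#' `min_identity`) within one genome, respecting circular topology: copies
#' may span the origin.  Detection is exact k-mer seeding on the doubled
#' sequence followed by greedy gap-free x-drop extension, merging co-diagonal
#' seeds.  Both direct and inverted pairs are reported; tandem-like hits
#' whose two copies share more than half of their span are suppressed, as are
#' copies containing `N`.
#'
#' @param genome a [circular_genome()].
#' @param min_len minimum repeat length in bp (default 50).
#' @param min_identity identity floor in `[0, 1]` (default 0.99).
#' @param k seed k-mer size; automatically reduced to `min_len` when needed.
#' @return a `data.frame` of repeat pairs sorted by descending length with
#'   columns `name` (empty until [name_repeats()]), `family`, `a_start`,
#'   `a_end`, `a_wraps`, `b_start`, `b_end`, `b_wraps` (0-based half-open),
#'   `orientation` (`direct`/`inverted`), `length`, `identity` and `seq`
#'   (the copy-a sequence).
#' @seealso [name_repeats()], [map_repeats_across_genomes()],
#'   [count_repeat_pairs()]
#' @export
find_repeats <- function(genome, min_len = 50L, min_identity = 0.99,
                         k = 24L) {
  stopifnot(inherits(genome, "CircularGenome"))
  if (min_len < 20L) stop("min_len must be >= 20; lower values would need a ",
                          "smaller seed than supported (raise min_len)")
  k <- as.integer(min(k, min_len))
  L <- genome$length
  circular <- genome$topology == "circular"
  D <- if (circular) paste0(genome$seq, genome$seq) else genome$seq
  seeds <- .self_seed_pairs(D, L, k, circular)

  byt <- .seq_bytes(D)
  cbyt <- .seq_bytes(.complement_chr(D))
  nD <- length(byt)

  exact <- min_identity >= 0.999
  collect <- function(sd, orientation) {
    if (is.null(sd) || nrow(sd) == 0L) return(NULL)
    cl <- .cluster_seeds(sd$i, sd$j, k, orientation,
                         max_gap = if (exact) 1L else 4L * k)
    out <- vector("list", nrow(cl))
    for (r in seq_len(nrow(cl))) {
      cand <- .extend_candidate(cl[r, ], byt, byt, cbyt, orientation,
                                max_a = nD, max_b = nD, exact = exact)
      len_a <- cand$a2 - cand$a1 + 1L
      if (len_a < min_len) next
      if (len_a > L) next                      # cannot exceed the circle
      idn <- .candidate_identity(cand, byt, byt, cbyt, orientation)
      if (idn < min_identity) next
      out[[r]] <- cbind(cand, identity = idn)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(NULL)
    res <- do.call(rbind, out)
    res$orientation <- orientation
    res
  }

  cands <- rbind(collect(seeds$direct, "direct"),
                 collect(seeds$inverted, "inverted"))
  if (is.null(cands) || nrow(cands) == 0L) return(.empty_repeats())

  # normalize to genome coordinates and canonical unordered copy pairs
  na <- .norm_circ_interval(cands$a1, cands$a2 - cands$a1 + 1L, L, circular)
  nb <- .norm_circ_interval(cands$b1, cands$b2 - cands$b1 + 1L, L, circular)
  len <- cands$a2 - cands$a1 + 1L
  swap <- nb$start < na$start
  A <- na; A[swap, ] <- nb[swap, ]
  B <- nb; B[swap, ] <- na[swap, ]
  df <- data.frame(a_start = A$start, a_end = A$end, a_wraps = A$wraps,
                   b_start = B$start, b_end = B$end, b_wraps = B$wraps,
                   orientation = cands$orientation, length = len,
                   identity = cands$identity)
  df <- df[!duplicated(df[, c("a_start", "b_start", "orientation",
                              "length")]), , drop = FALSE]

  # drop pairs whose copies coincide or share > 50% of their span (tandem)
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    ov <- .circ_overlap(df$a_start[r], df$length[r],
                        df$b_start[r], df$length[r], L)
    keep[r] <- ov <= df$length[r] %/% 2L &&
      !(df$a_start[r] == df$b_start[r])
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(.empty_repeats())

  # drop candidates contained in a longer pair on the same diagonal
  # (split-wrap duplicates); containment = both copies inside the other's
  df <- df[order(-df$length, df$a_start, df$b_start), , drop = FALSE]
  contained <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    if (r == 1L) next
    for (q in seq_len(r - 1L)) {
      if (contained[q] || df$orientation[q] != df$orientation[r]) next
      inside <- function(sr, sq) {
        .circ_overlap(sr, df$length[r], sq, df$length[q], L) ==
          df$length[r]
      }
      if ((inside(df$a_start[r], df$a_start[q]) &&
           inside(df$b_start[r], df$b_start[q])) ||
          (inside(df$a_start[r], df$b_start[q]) &&
           inside(df$b_start[r], df$a_start[q]))) {
        contained[r] <- TRUE; break
      }
    }
  }
  df <- df[!contained, , drop = FALSE]
  rownames(df) <- NULL

  df$seq <- vapply(seq_len(nrow(df)), function(r) {
    .sub0_circ(genome$seq, df$a_start[r], df$a_end[r], df$a_wraps[r])
  }, character(1))
  df$name <- rep("", nrow(df))
  df$family <- rep("", nrow(df))
  df[, c("name", "family", "a_start", "a_end", "a_wraps", "b_start",
         "b_end", "b_wraps", "orientation", "length", "identity", "seq")]
}

.empty_repeats <- function() {
  data.frame(name = character(), family = character(), a_start = integer(),
             a_end = integer(), a_wraps = logical(), b_start = integer(),
             b_end = integer(), b_wraps = logical(),
             orientation = character(), length = integer(),
             identity = numeric(), seq = character())
}

#' Name repeat pairs R01...Rn by descending length
#'
#' Names are assigned strictly by descending length; ties are broken by the
#' smaller `a_start`.  Pairs that share a physical copy (multi-copy families
#' such as a triple-copy repeat reported as three pairwise combinations) are
#' grouped under a common `family` label, the name of the largest member.
#'
#' @param pairs repeat table from [find_repeats()] (one genome).
#' @param L genome length (needed for copy-overlap family grouping; taken
#'   from the data if an attribute is present, otherwise `max(end)` is used).
#' @return the table with `name` and `family` filled, sorted by name.
#' @export
name_repeats <- function(pairs, L = NULL) {
  if (nrow(pairs) == 0L) return(pairs)
  if (is.null(L)) L <- max(pairs$a_end, pairs$b_end)
  o <- order(-pairs$length, pairs$a_start, pairs$b_start)
  pairs <- pairs[o, , drop = FALSE]
  pairs$name <- sprintf("R%02d", seq_len(nrow(pairs)))

  # family grouping: union-find over pairs sharing >= 50% of a copy
  n <- nrow(pairs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  copies <- function(r) list(c(pairs$a_start[r], pairs$length[r]),
                             c(pairs$b_start[r], pairs$length[r]))
  if (n > 1L) {
    for (r in 2:n) for (q in 1:(r - 1L)) {
      shared <- FALSE
      for (cr in copies(r)) for (cq in copies(q)) {
        ov <- .circ_overlap(cr[1], cr[2], cq[1], cq[2], L)
        if (ov >= 0.5 * min(cr[2], cq[2])) shared <- TRUE
      }
      if (shared) parent[find(r)] <- find(q)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  pairs$family <- pairs$name[match(root, seq_len(n))]
  rownames(pairs) <- NULL
  pairs
}

# k-mer containment similarity of two repeat sequences (strand-agnostic):
# fraction of the shorter sequence's k-mers present in the longer one.
.repeat_similarity <- function(s1, s2, k = 24L) {
  if (nchar(s1) > nchar(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  if (nchar(s1) < k) k <- nchar(s1)
  k1 <- unique(.kmers(s1, k))
  k2 <- unique(c(.kmers(s2, k), .kmers(.revcomp(s2), k)))
  cov <- mean(k1 %in% k2)
  len_frac <- nchar(s1) / nchar(s1)  # shorter fully considered
  c(coverage = cov, len_frac = len_frac)
}

#' Transfer repeat names from a reference genome to another genome
#'
#' Each pair of `other_pairs` inherits the name of its reciprocal best
#' sequence match among the named reference pairs (k-mer containment >= 80%
#' of the shorter copy over >= 50% of its length, which also captures
#' containment such as an expanded homolog).  Unmatched pairs receive fresh
#' names continuing the reference series.
#'
#' @param reference_named named repeat table (see [name_repeats()]).
#' @param other_genome the genome `other_pairs` were found on.
#' @param other_pairs repeat table from [find_repeats()] on `other_genome`.
#' @return `other_pairs` with `name`/`family` filled.
#' @export
map_repeats_across_genomes <- function(reference_named, other_genome,
                                       other_pairs) {
  if (nrow(other_pairs) == 0L) return(other_pairs)
  if (nrow(reference_named) == 0L || !any(nzchar(reference_named$name))) {
    return(name_repeats(other_pairs, L = other_genome$length))
  }
  no <- nrow(other_pairs); nr <- nrow(reference_named)
  sim <- matrix(0, no, nr)
  for (i in seq_len(no)) for (j in seq_len(nr)) {
    sim[i, j] <- .repeat_similarity(other_pairs$seq[i],
                                    reference_named$seq[j])["coverage"]
  }
  # reciprocal best match at >= 0.8 shared-kmer coverage
  best_o <- apply(sim, 1, which.max)
  best_r <- apply(sim, 2, which.max)
  assigned <- rep(NA_character_, no)
  for (i in seq_len(no)) {
    j <- best_o[i]
    if (sim[i, j] >= 0.8 && best_r[j] == i) {
      assigned[i] <- reference_named$name[j]
    }
  }
  # fresh names continue after the highest reference number
  used_nums <- suppressWarnings(
    as.integer(sub("^R", "", grep("^R[0-9]+$",
                                  reference_named$name, value = TRUE))))
  nxt <- max(c(0L, used_nums), na.rm = TRUE)
  ord <- order(-other_pairs$length, other_pairs$a_start)
  for (i in ord) {
    if (is.na(assigned[i])) {
      nxt <- nxt + 1L
      assigned[i] <- sprintf("R%02d", nxt)
    }
  }
  other_pairs$name <- assigned
  other_pairs$family <- assigned
  other_pairs[order(-other_pairs$length, other_pairs$a_start), ,
              drop = FALSE]
}

#' Count repeat families >= `min_len` in a genome
#'
#' Convenience wrapper over [find_repeats()] + [name_repeats()]; counts named
#' families, so a triple-copy repeat (reported as several pairwise
#' combinations) contributes one.
#'
#' @inheritParams find_repeats
#' @return integer family count.
#' @export
count_repeat_pairs <- function(genome, min_len = 50L, min_identity = 0.99) {
  rp <- name_repeats(find_repeats(genome, min_len, min_identity),
                     L = genome$length)
  length(unique(rp$family))
}

#' Convert a repeat table to BED4 (one row per copy)
#' @param pairs repeat table.
#' @param genome the genome the repeats belong to.
#' @return BED data.frame (wrapping copies are clipped at the origin into
#'   their two arcs).
#' @export
repeats_to_bed <- function(pairs, genome) {
  rows <- list()
  L <- genome$length
  add <- function(chrom, s, e, w, nm) {
    if (!w) list(data.frame(chrom = chrom, start = s, end = e, name = nm))
    else list(data.frame(chrom = chrom, start = s, end = L, name = nm),
              data.frame(chrom = chrom, start = 0L, end = e, name = nm))
  }
  for (r in seq_len(nrow(pairs))) {
    nm <- if (nzchar(pairs$name[r])) pairs$name[r] else sprintf("rep%d", r)
    rows <- c(rows,
              add(genome$id, pairs$a_start[r], pairs$a_end[r],
                  pairs$a_wraps[r], nm),
              add(genome$id, pairs$b_start[r], pairs$b_end[r],
                  pairs$b_wraps[r], nm))
  }
  do.call(rbind, rows)
}
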