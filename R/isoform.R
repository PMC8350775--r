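# Structural-isoform analysis: decompose two circular genomes into shared
# blocks delimited by large repeats, and decide whether they are
# interconvertible by repeat-mediated homologous recombination.
#
# Arrangements are circular signed sequences over symbols "B|<id>" (blocks)
# and "R|<family>" (repeat copies), each prefixed with "+" or "-".  A state
# is a list of such circles.  Moves: inversion between two copies of a
# family in inverted relative orientation on one circle; fission of a circle
# at two direct copies; fusion of two circles at one copy each.  Every move
# conserves the block multiset and total length.

.sym_make <- function(kind, id, sign = "+") paste0(sign, kind, "|", id)
.sym_sign <- function(s) substr(s, 1L, 1L)
.sym_kind <- function(s) substr(s, 2L, 2L)
.sym_id <- function(s) substring(s, 4L)
.sym_flip <- function(s) {
  paste0(ifelse(substr(s, 1L, 1L) == "+", "-", "+"), substring(s, 2L))
}

.rotate_vec <- function(v, p) if (p == 1L) v else c(v[p:length(v)], v[seq_len(p - 1L)])
.reflect_vec <- function(v) .sym_flip(rev(v))

.canonical_circle <- function(v) {
  n <- length(v)
  best <- NULL; bestkey <- NULL
  for (w in list(v, .reflect_vec(v))) {
    for (p in seq_len(n)) {
      r <- .rotate_vec(w, p)
      key <- paste(r, collapse = ",")
      if (is.null(bestkey) || key < bestkey) { bestkey <- key; best <- r }
    }
  }
  best
}

.circle_key <- function(v) paste(.canonical_circle(v), collapse = ",")

.state_canonical <- function(state) {
  circ <- lapply(state, .canonical_circle)
  keys <- vapply(circ, paste, character(1), collapse = ",")
  circ[order(keys)]
}

.state_key <- function(state) {
  keys <- sort(vapply(state, .circle_key, character(1)))
  paste(keys, collapse = " || ")
}

#' Enumerate single-recombination neighbors of an arrangement state
#'
#' @param state list of circles, each a character vector of signed symbols
#'   (`"+B|A"`, `"-R|R02"`, ...); see [decompose_blocks()].
#' @param families optional character vector restricting the repeat families
#'   allowed to mediate moves (default: all `R|` symbols present).
#' @return list of neighbors, each `list(state, move = list(family, type))`;
#'   states are not canonicalized (callers canonicalize for deduplication).
#' @export
recombination_moves <- function(state, families = NULL) {
  occ <- list()  # family -> data.frame(circle, pos, sign)
  for (ci in seq_along(state)) {
    v <- state[[ci]]
    w <- which(.sym_kind(v) == "R")
    for (p in w) {
      fam <- .sym_id(v[p])
      occ[[fam]] <- rbind(occ[[fam]],
                          data.frame(circle = ci, pos = p,
                                     sign = .sym_sign(v[p])))
    }
  }
  if (!is.null(families)) occ <- occ[names(occ) %in% families]
  out <- list()
  add <- function(newstate, fam, type) {
    newstate <- newstate[lengths(newstate) > 0L]
    out[[length(out) + 1L]] <<- list(state = newstate,
                                     move = list(family = fam, type = type))
  }
  for (fam in names(occ)) {
    oc <- occ[[fam]]
    if (nrow(oc) < 2L) next
    for (u in seq_len(nrow(oc) - 1L)) for (w in (u + 1L):nrow(oc)) {
      c1 <- oc$circle[u]; c2 <- oc$circle[w]
      p <- oc$pos[u]; q <- oc$pos[w]
      s1 <- oc$sign[u]; s2 <- oc$sign[w]
      if (c1 == c2) {
        v <- state[[c1]]
        if (s1 != s2) {
          # inversion of the segment strictly between the two copies
          if (q > p + 1L) {
            nv <- c(v[seq_len(p)], .reflect_vec(v[(p + 1L):(q - 1L)]),
                    v[q:length(v)])
            ns <- state; ns[[c1]] <- nv
            add(ns, fam, "inversion")
          }
          # ... and of the complementary segment (reflection-equivalent but
          # generated for completeness; canonical dedup collapses them)
          outer_seg <- c(if (q < length(v)) v[(q + 1L):length(v)],
                         if (p > 1L) v[seq_len(p - 1L)])
          if (length(outer_seg) > 0L) {
            nv <- c(v[p:q], .reflect_vec(outer_seg))
            ns <- state; ns[[c1]] <- nv
            add(ns, fam, "inversion")
          }
        } else {
          # fission into two circles, one copy each
          part1 <- v[p:(q - 1L)]
          part2 <- c(v[q:length(v)], if (p > 1L) v[seq_len(p - 1L)])
          ns <- state
          ns[[c1]] <- part1
          ns[[length(ns) + 1L]] <- part2
          add(ns, fam, "fission")
        }
      } else {
        # fusion of two circles at one copy each
        v1 <- .rotate_vec(state[[c1]], p)
        v2 <- state[[c2]]
        if (s2 != s1) {
          v2 <- .reflect_vec(v2)
          q2 <- length(v2) - q + 1L
        } else q2 <- q
        v2 <- .rotate_vec(v2, q2)
        ns <- state
        ns[[c1]] <- c(v1, v2)
        ns[[c2]] <- character(0)
        add(ns, fam, "fusion")
      }
    }
  }
  out
}

# breadth-first search from state A to the canonical key of B
.bfs_isoform <- function(state_a, state_b, max_moves = 6L,
                         max_states = 100000L, families = NULL) {
  target <- .state_key(state_b)
  start_key <- .state_key(state_a)
  if (identical(start_key, target)) {
    return(list(found = TRUE, moves = list(), capped = FALSE, explored = 1L))
  }
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(start_key, TRUE, envir = visited)
  frontier <- list(list(state = state_a, path = list()))
  explored <- 1L
  capped <- FALSE
  for (depth in seq_len(max_moves)) {
    nxt <- list()
    for (node in frontier) {
      nbs <- recombination_moves(node$state, families = families)
      for (nb in nbs) {
        key <- .state_key(nb$state)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, TRUE, envir = visited)
        explored <- explored + 1L
        path <- c(node$path, list(nb$move))
        if (identical(key, target) && length(nb$state) == 1L) {
          return(list(found = TRUE, moves = path, capped = FALSE,
                      explored = explored))
        }
        if (explored >= max_states) {
          return(list(found = FALSE, moves = NULL, capped = TRUE,
                      explored = explored))
        }
        nxt[[length(nxt) + 1L]] <- list(state = nb$state, path = path)
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) {
      return(list(found = FALSE, moves = NULL, capped = FALSE,
                  explored = explored))
    }
  }
  # frontier still active when the move budget ran out
  list(found = FALSE, moves = NULL, capped = TRUE, explored = explored)
}

# --- block decomposition ---------------------------------------------------

# canonical strand-collapsed k-mer table of one genome: positions 1..L
.canon_kmer_table <- function(g, k) {
  L <- g$length
  D <- if (g$topology == "circular") paste0(g$seq, substr(g$seq, 1L, k)) else g$seq
  W <- nchar(D) - k + 1L
  km <- .kmers(D, k)[seq_len(min(L, W))]
  rc <- .kmers(.revcomp(D), k)
  rckm <- rc[W:1][seq_len(length(km))]
  canon <- ifelse(is.na(km) | km > rckm, rckm, km)
  fwd <- !is.na(km) & km <= rckm
  nn <- grepl("N", km, fixed = TRUE)
  canon[nn] <- NA_character_
  list(canon = canon, fwd = fwd)
}

# per-copy signed repeat-copy table for one genome, relative to reference
# family sequences (list family -> seq)
.repeat_copies <- function(pairs, genome, ref_seqs, min_repeat) {
  pairs <- pairs[pairs$length >= min_repeat, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(family = character(), start = integer(),
                      end = integer(), wraps = logical(), len = integer(),
                      sign = character()))
  }
  rows <- list()
  L <- genome$length
  for (r in seq_len(nrow(pairs))) {
    fam <- if (nzchar(pairs$family[r])) pairs$family[r] else pairs$name[r]
    for (side in c("a", "b")) {
      st <- pairs[[paste0(side, "_start")]][r]
      en <- pairs[[paste0(side, "_end")]][r]
      wr <- pairs[[paste0(side, "_wraps")]][r]
      ln <- .interval_len(st, en, wr, L)
      cs <- .sub0_circ(genome$seq, st, en, wr)
      ref <- ref_seqs[[fam]] %||% pairs$seq[r]
      sgn <- .copy_sign(cs, ref)
      rows[[length(rows) + 1L]] <- data.frame(family = fam, start = st,
                                              end = en, wraps = wr,
                                              len = ln, sign = sgn)
    }
  }
  df <- do.call(rbind, rows)
  # dedupe copies shared by several pairs of one family (>=50% overlap)
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    if (!keep[r]) next
    for (q in seq_len(nrow(df))) {
      if (q <= r || !keep[q] || df$family[q] != df$family[r]) next
      ov <- .circ_overlap(df$start[r], df$len[r], df$start[q], df$len[q], L)
      if (ov >= 0.5 * min(df$len[r], df$len[q])) keep[q] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# orientation of a repeat copy relative to the family reference sequence
.copy_sign <- function(copy_seq, ref_seq, k = 24L) {
  k <- min(k, nchar(copy_seq), nchar(ref_seq))
  kc <- unique(.kmers(copy_seq, k))
  f <- mean(kc %in% .kmers(ref_seq, k))
  r <- mean(kc %in% .kmers(.revcomp(ref_seq), k))
  if (f >= r) "+" else "-"
}

# coverage mask (logical of length L) of a set of (start, end, wraps) rows
.coverage_mask <- function(df, L, pad = 0L) {
  m <- logical(L)
  if (is.null(df) || nrow(df) == 0L) return(m)
  for (r in seq_len(nrow(df))) {
    ln <- .interval_len(df$start[r], df$end[r], df$wraps[r], L)
    idx <- ((df$start[r] - pad) + seq_len(ln + 2L * pad) - 1L) %% L
    m[idx + 1L] <- TRUE
  }
  m
}

#' Decompose two circular genomes into shared blocks delimited by repeats
#'
#' Blocks are maximal runs of co-linear anchors: 31-mers (strand-collapsed)
#' unique in both genomes and outside repeat copies of families >=
#' `min_repeat` bp.  Each genome's arrangement is its circular order of
#' signed block and repeat-copy symbols.  Unmatched stretches >=
#' `min_private` bp are reported as private segments.
#'
#' @param a,b circular [circular_genome()] objects.
#' @param repeats_a,repeats_b optional named repeat tables; computed (and
#'   names transferred from `a` to `b`) when `NULL`.
#' @param min_repeat repeat families >= this length delimit blocks and
#'   mediate recombination moves (default 500 bp, the size class involved in
#'   frequent reciprocal recombination).
#' @param k anchor k-mer size.
#' @param offset_tol tolerated indel drift (bp) between consecutive anchors.
#' @param max_jump anchor gap that forces a block boundary.
#' @param min_private minimum reported private-segment length.
#' @return list with `blocks` (placement table), `arrangement_a`,
#'   `arrangement_b` (signed symbol vectors), `private` (data.frame),
#'   `repeats_a`, `repeats_b`, `copies_a`, `copies_b`.
#' @export
decompose_blocks <- function(a, b, repeats_a = NULL, repeats_b = NULL,
                             min_repeat = 500L, k = 31L, offset_tol = 50L,
                             max_jump = 5000L, min_private = 100L) {
  stopifnot(a$topology == "circular", b$topology == "circular")
  if (is.null(repeats_a)) {
    repeats_a <- name_repeats(find_repeats(a, min_len = min_repeat),
                              L = a$length)
  }
  if (is.null(repeats_b)) {
    rb <- find_repeats(b, min_len = min_repeat)
    repeats_b <- map_repeats_across_genomes(repeats_a, b, rb)
  }
  ref_seqs <- stats::setNames(as.list(repeats_a$seq), repeats_a$family)
  copies_a <- .repeat_copies(repeats_a, a, ref_seqs, min_repeat)
  copies_b <- .repeat_copies(repeats_b, b, ref_seqs, min_repeat)

  ta <- .canon_kmer_table(a, k)
  tb <- .canon_kmer_table(b, k)
  ca <- table(ta$canon); cb <- table(tb$canon)
  ua <- names(ca)[ca == 1L]; ub <- names(cb)[cb == 1L]
  shared <- intersect(ua, ub)
  if (length(shared) == 0L) stop("unrelated genomes: no shared unique anchors")
  pa <- match(shared, ta$canon)   # 1-based position in a
  pb <- match(shared, tb$canon)
  sign <- ifelse(ta$fwd[pa] == tb$fwd[pb], "+", "-")

  # exclude anchors whose window touches a repeat copy in either genome
  mask_a <- .coverage_mask(copies_a, a$length)
  mask_b <- .coverage_mask(copies_b, b$length)
  win_hits <- function(p, L, mask) {
    vapply(p, function(pp) any(mask[((pp - 1L + 0:(k - 1L)) %% L) + 1L]),
           logical(1))
  }
  drop <- win_hits(pa, a$length, mask_a) | win_hits(pb, b$length, mask_b)
  pa <- pa[!drop]; pb <- pb[!drop]; sign <- sign[!drop]
  if (length(pa) == 0L) stop("unrelated genomes: no anchors outside repeats")

  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]; sign <- sign[o]
  n <- length(pa)
  Lb <- b$length

  # masked-position count along the forward arc [from, to] (1-based, mod L)
  cma <- c(0L, cumsum(mask_a)); cmb <- c(0L, cumsum(mask_b))
  arc_masked <- function(cm0, L, from, to) {
    f <- ((from - 1L) %% L) + 1L
    t <- ((to - 1L) %% L) + 1L
    if (f <= t) cm0[t + 1L] - cm0[f]
    else (cm0[L + 1L] - cm0[f]) + cm0[t + 1L]
  }

  chainable <- function(u, v, dpa) {
    if (sign[u] != sign[v]) return(FALSE)
    dpb <- if (sign[u] == "+") (pb[v] - pb[u]) %% Lb else (pb[u] - pb[v]) %% Lb
    if (dpa > max_jump || dpb > max_jump || abs(dpb - dpa) > offset_tol) {
      return(FALSE)
    }
    # a block may not straddle a repeat copy in either genome
    if (arc_masked(cma, a$length, pa[u], pa[u] + dpa + k - 1L) > 0L) {
      return(FALSE)
    }
    span_b <- if (sign[u] == "+") c(pb[u], pb[u] + dpb + k - 1L)
              else c(pb[v], pb[v] + dpb + k - 1L)
    if (arc_masked(cmb, Lb, span_b[1], span_b[2]) > 0L) return(FALSE)
    TRUE
  }
  newrun <- c(TRUE, !vapply(seq_len(n - 1L), function(u) {
    chainable(u, u + 1L, pa[u + 1L] - pa[u])
  }, logical(1)))
  run <- cumsum(newrun)
  nruns <- max(run)
  wrap_merged <- FALSE
  if (nruns > 1L) {
    # circular closure: does the last run chain into the first?
    u <- n; v <- 1L
    if (chainable(u, v, (pa[v] + a$length) - pa[u])) {
      run[run == nruns] <- 0L           # prepend to run 1 (wraps in a)
      run[run == 0L] <- 1L
      wrap_merged <- TRUE
      nruns <- max(run)
    }
  }

  blocks <- lapply(sort(unique(run)), function(rr) {
    idx <- which(run == rr)
    # for a wrap-merged first run, order anchors along the circle
    if (rr == 1L && wrap_merged) {
      # anchors are pa-sorted; circular order puts the high-pa tail first
      brk <- which(diff(pa[idx]) > max_jump)
      if (length(brk)) idx <- c(idx[(brk[1] + 1L):length(idx)],
                                idx[seq_len(brk[1])])
    }
    first <- idx[1]; last <- idx[length(idx)]
    a_start <- pa[first] - 1L
    a_len <- ((pa[last] - pa[first]) %% a$length) + k
    sgn <- sign[first]
    if (sgn == "+") {
      b_start <- pb[first] - 1L
      b_len <- ((pb[last] - pb[first]) %% Lb) + k
    } else {
      b_start <- pb[last] - 1L
      b_len <- ((pb[first] - pb[last]) %% Lb) + k
    }
    data.frame(a_start = a_start, a_len = a_len, b_start = b_start,
               b_len = b_len, sign = sgn)
  })
  bl <- do.call(rbind, blocks)
  bl$a_end <- (bl$a_start + bl$a_len) %% a$length
  bl$a_wraps <- bl$a_start + bl$a_len > a$length
  bl$a_end[!bl$a_wraps] <- bl$a_start[!bl$a_wraps] + bl$a_len[!bl$a_wraps]
  bl$b_end <- (bl$b_start + bl$b_len) %% Lb
  bl$b_wraps <- bl$b_start + bl$b_len > Lb
  bl$b_end[!bl$b_wraps] <- bl$b_start[!bl$b_wraps] + bl$b_len[!bl$b_wraps]
  ids <- .block_ids(nrow(bl))
  bl <- bl[order(-bl$a_len, bl$a_start), , drop = FALSE]
  bl$id <- ids
  bl <- bl[order(bl$a_start), , drop = FALSE]
  rownames(bl) <- NULL

  # arrangements: circular order of blocks and repeat copies
  arr <- function(block_col_start, sign_col, copies, genome_is_a) {
    elems <- rbind(
      data.frame(pos = bl[[block_col_start]],
                 sym = .sym_make("B", bl$id,
                                 if (genome_is_a) "+" else bl$sign)),
      if (nrow(copies) > 0L)
        data.frame(pos = copies$start,
                   sym = .sym_make("R", copies$family, copies$sign))
    )
    elems$sym[order(elems$pos)]
  }
  arrangement_a <- arr("a_start", NULL, copies_a, TRUE)
  arrangement_b <- arr("b_start", NULL, copies_b, FALSE)

  # private segments: uncovered runs >= min_private
  private <- rbind(
    .uncovered_runs(a, bl[, c("a_start", "a_end", "a_wraps")], copies_a,
                    min_private, "a"),
    .uncovered_runs(b, bl[, c("b_start", "b_end", "b_wraps")], copies_b,
                    min_private, "b"))

  list(blocks = bl, arrangement_a = arrangement_a,
       arrangement_b = arrangement_b, private = private,
       repeats_a = repeats_a, repeats_b = repeats_b,
       copies_a = copies_a, copies_b = copies_b)
}

.block_ids <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else c(LETTERS, paste0(rep(LETTERS, each = 26L),
                         rep(LETTERS, 26L)))[seq_len(n)]
}

.uncovered_runs <- function(g, block_df, copies, min_private, label) {
  names(block_df) <- c("start", "end", "wraps")
  m <- .coverage_mask(block_df, g$length) |
    .coverage_mask(copies, g$length, pad = 0L)
  r <- rle(!m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  w <- which(r$values & r$lengths >= min_private)
  if (!length(w)) {
    return(data.frame(genome = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  data.frame(genome = g$id, start = starts[w] - 1L, end = ends[w],
             length = r$lengths[w])
}

#' Decide whether two circular genomes are recombination isoforms
#'
#' Two genomes are "perfect isoforms" when one can be converted into the
#' other by homologous recombination events at shared large repeats
#' (inversions at inverted pairs; fission/fusion through subgenomic circles
#' at direct pairs), with no sequence gained or lost.  The decision is a
#' breadth-first search over arrangement states; intermediates may be
#' multi-circle but endpoints are single circles.
#'
#' @inheritParams decompose_blocks
#' @param max_moves search depth cap (recombination events).
#' @param max_states explored-state cap; exceeding it yields status
#'   `"undecided"`, never a silent "no".
#' @return list (class `IsoformVerdict`) with `equivalent` (TRUE/FALSE/NA),
#'   `moves` (list of `family`/`type` pairs for the shortest path found),
#'   `differences` (data.frame of private segments and block-set
#'   mismatches), `status` (`"decided"` or `"undecided"`), `n_states`.
#' @export
are_isoforms <- function(a, b, min_repeat = 500L, max_moves = 6L,
                         max_states = 100000L, repeats_a = NULL,
                         repeats_b = NULL, min_private = 100L) {
  dec <- decompose_blocks(a, b, repeats_a = repeats_a,
                          repeats_b = repeats_b, min_repeat = min_repeat,
                          min_private = min_private)
  verdict <- function(eq, moves, diffs, status, n) {
    structure(list(equivalent = eq, moves = moves, differences = diffs,
                   status = status, n_states = n, decomposition = dec),
              class = "IsoformVerdict")
  }
  if (nrow(dec$private) > 0L) {
    return(verdict(FALSE, NULL, dec$private, "decided", 0L))
  }
  # repeat family copy counts must agree
  fa <- table(dec$copies_a$family); fb <- table(dec$copies_b$family)
  fams <- union(names(fa), names(fb))
  mismatch <- fams[vapply(fams, function(f) {
    na <- if (f %in% names(fa)) fa[[f]] else 0L
    nb <- if (f %in% names(fb)) fb[[f]] else 0L
    na != nb
  }, logical(1))]
  if (length(mismatch)) {
    return(verdict(FALSE, NULL,
                   data.frame(genome = "both",
                              start = NA_integer_, end = NA_integer_,
                              length = NA_integer_,
                              note = paste("repeat copy-number mismatch:",
                                           paste(mismatch, collapse = ","))),
                   "decided", 0L))
  }
  res <- .bfs_isoform(list(dec$arrangement_a), list(dec$arrangement_b),
                      max_moves = max_moves, max_states = max_states)
  if (res$found) {
    verdict(TRUE, res$moves, NULL, "decided", res$explored)
  } else if (res$capped) {
    verdict(NA, NULL, NULL, "undecided", res$explored)
  } else {
    verdict(FALSE, NULL,
            data.frame(genome = "both", start = NA_integer_,
                       end = NA_integer_, length = NA_integer_,
                       note = "arrangements not connected by repeat-mediated moves"),
            "decided", res$explored)
  }
}

#' @export
print.IsoformVerdict <- function(x, ...) {
  eq <- if (isTRUE(x$equivalent)) "EQUIVALENT (perfect isoforms)"
        else if (isFALSE(x$equivalent)) "NOT equivalent" else "UNDECIDED"
  cat("Isoform verdict:", eq, "\n")
  if (length(x$moves)) {
    cat("Moves:", paste(vapply(x$moves, function(m)
      paste0(m$type, "@", m$family), character(1)), collapse = " -> "), "\n")
  }
  if (!is.null(x$differences) && nrow(x$differences)) {
    cat("Differences:\n"); print(x$differences)
  }
  invisible(x)
}

#' Structural comparison report between two circular genomes
#'
#' Produces a per-block placement table (order, sign, coordinates in each
#' genome), private segments, repeat-length differences between homologous
#' families, and families whose copy number differs (candidate mediators of
#' recombination events such as an intermediate-size repeat present twice in
#' one genome and once in the other).
#'
#' @inheritParams decompose_blocks
#' @param min_diff_repeat finer repeat threshold used only for the
#'   repeat-length and copy-number difference scans (default 100 bp), so
#'   intermediate-size events below the recombination threshold are still
#'   reported.
#' @return list with `placements`, `private`, `repeat_length_diffs`,
#'   `copy_number_diffs`.
#' @export
structural_diff <- function(a, b, min_repeat = 500L, repeats_a = NULL,
                            repeats_b = NULL, min_private = 100L,
                            min_diff_repeat = 100L) {
  dec <- decompose_blocks(a, b, repeats_a = repeats_a, repeats_b = repeats_b,
                          min_repeat = min_repeat, min_private = min_private)
  bl <- dec$blocks
  placements <- rbind(
    data.frame(block = bl$id, genome = a$id,
               order = rank(bl$a_start), start = bl$a_start, end = bl$a_end,
               wraps = bl$a_wraps, sign = "+", length = bl$a_len),
    data.frame(block = bl$id, genome = b$id,
               order = rank(bl$b_start), start = bl$b_start, end = bl$b_end,
               wraps = bl$b_wraps, sign = bl$sign, length = bl$b_len))

  # fine-grained repeat tables for the difference scans
  ra <- name_repeats(find_repeats(a, min_len = min_diff_repeat),
                     L = a$length)
  rb <- map_repeats_across_genomes(ra, b,
                                   find_repeats(b, min_len = min_diff_repeat))
  common <- intersect(ra$family, rb$family)
  rl <- do.call(rbind, lapply(common, function(f) {
    la <- max(ra$length[ra$family == f]); lb <- max(rb$length[rb$family == f])
    if (la != lb) data.frame(family = f, len_a = la, len_b = lb,
                             delta = lb - la) else NULL
  }))
  if (is.null(rl)) rl <- data.frame(family = character(), len_a = integer(),
                                    len_b = integer(), delta = integer())

  # copy-number differences: count occurrences of each family reference in
  # both genomes by direct sequence search (catches a family that exists as
  # a pair in one genome but single copy in the other)
  fams <- unique(c(ra$family, rb$family))
  cn <- do.call(rbind, lapply(fams, function(f) {
    ref <- c(ra$seq[ra$family == f], rb$seq[rb$family == f])[1]
    ca <- .count_occurrences(ref, a)
    cb <- .count_occurrences(ref, b)
    if (ca != cb) data.frame(family = f, copies_a = ca, copies_b = cb)
    else NULL
  }))
  if (is.null(cn)) cn <- data.frame(family = character(),
                                    copies_a = integer(),
                                    copies_b = integer())

  list(placements = placements, private = dec$private,
       repeat_length_diffs = rl, copy_number_diffs = cn)
}

# number of occurrences (both strands) of a sequence in a genome, counted as
# shared segments covering >= 90% of it
.count_occurrences <- function(seqstr, genome) {
  probe <- circular_genome("probe", seqstr, "linear")
  seg <- .shared_segments(probe, genome,
                          min_len = max(20L, floor(0.9 * nchar(seqstr))),
                          min_identity = 0.95)
  nrow(seg)
}
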