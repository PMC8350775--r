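# Internal k-mer seed / greedy x-drop extension engine.
#
# Circular sequences are handled on the doubled string; candidate intervals
# are normalized back to 0-based mod-L coordinates at the end.  The model is
# gap-free (plant-mtDNA repeats and recent plastid transfers are
# near-identical); mismatches are tolerated through the x-drop score.

.XDROP_MATCH <- 1L
.XDROP_MISMATCH <- -3L

# group positions of identical k-mers; returns list(gid = first-occurrence id
# per element, idx = element positions).  `km` may contain NA (masked).
.kmer_groups <- function(km) {
  valid <- !is.na(km)
  gid <- rep(NA_integer_, length(km))
  gid[valid] <- match(km[valid], km[valid])
  gid
}

# cluster seed pairs lying on one diagonal into runs with bounded gaps.
# seeds: data.frame(i, j); key = diagonal (j - i) for direct, i + j for
# inverted.  Returns data.frame(a1, a2, b1, b2) of 1-based inclusive windows.
.cluster_seeds <- function(i, j, k, orientation, max_gap) {
  if (length(i) == 0L) {
    return(data.frame(a1 = integer(), a2 = integer(),
                      b1 = integer(), b2 = integer()))
  }
  key <- if (orientation == "direct") j - i else i + j
  o <- order(key, i)
  key <- key[o]; i <- i[o]; j <- j[o]
  newrun <- c(TRUE, diff(key) != 0L | diff(i) > max_gap)
  run <- cumsum(newrun)
  a1 <- tapply(i, run, min); a2 <- tapply(i, run, max) + k - 1L
  if (orientation == "direct") {
    b1 <- tapply(j, run, min); b2 <- tapply(j, run, max) + k - 1L
  } else {
    b1 <- tapply(j, run, min); b2 <- tapply(j, run, max) + k - 1L
  }
  data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
             b1 = as.integer(b1), b2 = as.integer(b2))
}

# greedy x-drop extension of one gap-free candidate.
# byta/bytb: integer byte vectors of the two (possibly doubled) sequences;
# cbytb: complement bytes of sequence b (same orientation, not reversed).
# For "direct", a runs with b left-to-right.  For "inverted", copy_a pairs
# with the reverse complement of copy_b: extending a rightwards extends b
# leftwards and vice versa.
.extend_candidate <- function(cand, byta, bytb, cbytb, orientation,
                              max_a, max_b, xdrop = 15L, exact = FALSE) {
  a1 <- cand$a1; a2 <- cand$a2; b1 <- cand$b1; b2 <- cand$b2

  step <- function(av, bv) {
    # av, bv: byte vectors to compare elementwise; returns extension length
    n <- min(length(av), length(bv))
    if (n == 0L) return(0L)
    m <- av[seq_len(n)] == bv[seq_len(n)]
    if (exact) {
      # mismatch-free extension: leading run of matches
      bad <- which(!m)
      return(if (length(bad)) bad[1] - 1L else n)
    }
    sc <- cumsum(ifelse(m, .XDROP_MATCH, .XDROP_MISMATCH))
    peak <- cummax(sc)
    stop_at <- which(peak - sc >= xdrop)
    lim <- if (length(stop_at)) stop_at[1] - 1L else n
    if (lim == 0L) return(0L)
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] <= 0L) 0L else best
  }

  if (orientation == "direct") {
    # right
    ta <- seq.int(a2 + 1L, length.out = max(0L, min(max_a - a2, max_b - b2)))
    e <- step(byta[ta], bytb[b2 + seq_along(ta)])
    a2 <- a2 + e; b2 <- b2 + e
    # left
    n <- min(a1 - 1L, b1 - 1L)
    if (n > 0L) {
      e <- step(byta[a1 - seq_len(n)], bytb[b1 - seq_len(n)])
      a1 <- a1 - e; b1 <- b1 - e
    }
  } else {
    # right of a <-> left of b
    n <- min(max_a - a2, b1 - 1L)
    if (n > 0L) {
      e <- step(byta[a2 + seq_len(n)], cbytb[b1 - seq_len(n)])
      a2 <- a2 + e; b1 <- b1 - e
    }
    # left of a <-> right of b
    n <- min(a1 - 1L, max_b - b2)
    if (n > 0L) {
      e <- step(byta[a1 - seq_len(n)], cbytb[b2 + seq_len(n)])
      a1 <- a1 - e; b2 <- b2 + e
    }
  }
  data.frame(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
}

.candidate_identity <- function(cand, byta, bytb, cbytb, orientation) {
  av <- byta[cand$a1:cand$a2]
  bv <- if (orientation == "direct") bytb[cand$b1:cand$b2]
        else rev(cbytb[cand$b1:cand$b2])
  n <- min(length(av), length(bv))
  mean(av[seq_len(n)] == bv[seq_len(n)])
}

# mask k-mers containing N
.mask_n_kmers <- function(km) {
  km[grepl("N", km, fixed = TRUE)] <- NA_character_
  km
}

# Self-comparison seed pairs on a (possibly doubled) sequence.
# Returns list(direct = data.frame(i, j), inverted = data.frame(i, j)) with
# 1-based start positions; for circular input, i is restricted to 1..L.
.self_seed_pairs <- function(D, L, k, circular) {
  km <- .mask_n_kmers(.kmers(D, k))
  W <- length(km)
  if (W == 0L) return(list(direct = NULL, inverted = NULL))

  expand_group_pairs <- function(pos, restrict_first) {
    # all ordered pairs (p,q), p<q, p<=L (if restrict), 0 < q-p < L
    np <- length(pos)
    if (np < 2L) return(NULL)
    ii <- rep(pos, times = rev(seq_len(np)) - 1L)
    jj <- unlist(lapply(seq_len(np - 1L), function(u) pos[(u + 1L):np]),
                 use.names = FALSE)
    keep <- (jj - ii) %% L != 0L & (jj - ii) < L
    if (restrict_first) keep <- keep & ii <= L
    if (!any(keep)) return(NULL)
    cbind(ii[keep], jj[keep])
  }

  # --- direct: groups of identical forward k-mers.
  # With circular doubling every genome k-mer occurs twice ({i, i+L}); such
  # trivial groups are rejected vectorized before any per-group work.
  gid <- .kmer_groups(km)
  sel0 <- which(!is.na(gid))
  direct <- NULL
  if (length(sel0)) {
    o <- order(gid[sel0], sel0)
    gs <- gid[sel0][o]; ps <- sel0[o]
    last <- c(diff(gs) != 0L, TRUE)
    sz <- diff(c(0L, which(last)))
    firstpos <- ps[c(TRUE, utils::head(last, -1L))]
    lastpos <- ps[last]
    keep_grp <- (sz == 2L & ((lastpos - firstpos) %% L) != 0L) | sz > 2L
    if (any(keep_grp)) {
      elem_keep <- rep(keep_grp, sz)
      sp <- split(ps[elem_keep], rep(seq_along(sz)[keep_grp],
                                     sz[keep_grp]))
      prs <- lapply(sp, expand_group_pairs, restrict_first = circular)
      prs <- prs[!vapply(prs, is.null, logical(1))]
      if (length(prs)) {
        m <- do.call(rbind, prs)
        direct <- data.frame(i = m[, 1], j = m[, 2])
      }
    }
  }

  # --- inverted: forward k-mer at i equals rc of window at j
  Drc <- .revcomp(D)
  kmr <- .mask_n_kmers(.kmers(Drc, k))
  # rc of window starting at i is kmr[W - i + 1]
  rckm <- kmr[W:1]
  combined <- c(km, rckm)
  gidc <- .kmer_groups(combined)
  validc <- which(!is.na(gidc))
  tf <- tabulate(gidc[validc[validc <= W]], nbins = 2L * W)
  ti <- tabulate(gidc[validc[validc > W]] , nbins = 2L * W)
  mixed <- which(tf > 0L & ti > 0L)
  inverted <- NULL
  if (length(mixed)) {
    mflag <- logical(2L * W); mflag[mixed] <- TRUE
    selc <- validc[mflag[gidc[validc]]]
    sp <- split(selc, gidc[selc])
    prs <- lapply(sp, function(el) {
      fi <- el[el <= W]
      iv <- el[el > W] - W
      if (!length(fi) || !length(iv)) return(NULL)
      g <- expand.grid(i = fi, j = iv)
      keep <- g$i < g$j & (g$j - g$i) < L
      if (circular) keep <- keep & g$i <= L
      g <- g[keep, , drop = FALSE]
      if (nrow(g) == 0L) NULL else as.matrix(g)
    })
    prs <- prs[!vapply(prs, is.null, logical(1))]
    if (length(prs)) {
      m <- do.call(rbind, prs)
      inverted <- data.frame(i = m[, 1], j = m[, 2])
    }
  }
  list(direct = direct, inverted = inverted)
}

# Cross-comparison seed pairs between two (possibly doubled) sequences.
# i positions restricted to 1..La, j to 1..Lb (first copies).
.cross_seed_pairs <- function(Da, Db, La, Lb, k, both_strands = TRUE) {
  first_kmers <- function(D, L) {
    n <- min(L, nchar(D) - k + 1L)
    .mask_n_kmers(substring(D, 1:n, k:(n + k - 1L)))
  }
  kma <- first_kmers(Da, La)
  kmb <- first_kmers(Db, Lb)

  pair_up <- function(kb) {
    Wa <- length(kma); Wb <- length(kb)
    combined <- c(kma, kb)
    gid <- .kmer_groups(combined)
    valid <- which(!is.na(gid))
    ta <- tabulate(gid[valid[valid <= Wa]], nbins = Wa + Wb)
    tb <- tabulate(gid[valid[valid > Wa]], nbins = Wa + Wb)
    mixed <- which(ta > 0L & tb > 0L)
    if (!length(mixed)) return(NULL)
    mflag <- logical(Wa + Wb); mflag[mixed] <- TRUE
    sel <- valid[mflag[gid[valid]]]
    sp <- split(sel, gid[sel])
    prs <- lapply(sp, function(el) {
      ai <- el[el <= Wa]
      bj <- el[el > Wa] - Wa
      if (!length(ai) || !length(bj)) return(NULL)
      as.matrix(expand.grid(i = ai, j = bj))
    })
    prs <- prs[!vapply(prs, is.null, logical(1))]
    if (!length(prs)) return(NULL)
    m <- do.call(rbind, prs)
    data.frame(i = m[, 1], j = m[, 2])
  }

  direct <- pair_up(kmb)
  inverted <- NULL
  if (both_strands) {
    # rc of the window starting at j (1..Lb) lives at index Wb - j + 1 of
    # the reverse complement's window list
    Wb <- nchar(Db) - k + 1L
    revDb <- .revcomp(Db)
    n <- min(Lb, Wb)
    idx <- Wb - seq_len(n) + 1L
    rckmb <- .mask_n_kmers(substring(revDb, idx, idx + k - 1L))
    inverted <- pair_up(rckmb)
  }
  list(direct = direct, inverted = inverted)
}

# Normalize a candidate interval on a doubled circular sequence to genome
# coordinates.  Returns (start, end, wraps) 0-based half-open.
.norm_circ_interval <- function(start1, len, L, circular) {
  s0 <- if (circular) (start1 - 1L) %% L else start1 - 1L
  e <- s0 + len
  wraps <- circular & e > L
  data.frame(start = as.integer(s0),
             end = as.integer(ifelse(wraps, e - L, e)),
             wraps = wraps)
}

# circular overlap (bp) of two (start, len) spans on a circle of length L
.circ_overlap <- function(s1, l1, s2, l2, L) {
  p1 <- (s1 + seq_len(l1) - 1L) %% L
  p2 <- (s2 + seq_len(l2) - 1L) %% L
  length(intersect(p1, p2))
}
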