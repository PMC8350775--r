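# Independent brute-force oracles.  These deliberately share no code with
# the package's seed-and-extend or symbolic-arrangement engines: repeats are
# found by exhaustive diagonal/anti-diagonal byte comparison, and isoform
# reachability is enumerated on actual DNA strings.

# --- exhaustive maximal exact repeated-pair finder -------------------------
# Returns data.frame(a_start, b_start, length, orientation), 0-based starts,
# same reporting conventions as find_repeats (copies distinct, <= 50% span
# overlap, length <= L, pairs deduplicated modulo the circle).
oracle_exact_repeats <- function(seqstr, min_len, circular = TRUE) {
  L <- nchar(seqstr)
  D <- if (circular) paste0(seqstr, seqstr) else seqstr
  n <- nchar(D)
  b <- as.integer(charToRaw(D))
  cb <- as.integer(charToRaw(chartr("ACGTN", "TGCAN", D)))
  found <- new.env(parent = emptyenv())
  rows <- list()
  add <- function(i, j, len, orient) {
    # i, j 1-based starts in D
    s1 <- (i - 1L) %% L; s2 <- (j - 1L) %% L
    if (s1 == s2) return(invisible())
    if (len > L) return(invisible())
    p <- sort(c(s1, s2))
    # tandem filter: circular span overlap > 50%
    pos1 <- (p[1] + seq_len(len) - 1L) %% L
    pos2 <- (p[2] + seq_len(len) - 1L) %% L
    if (length(intersect(pos1, pos2)) > len %/% 2L) return(invisible())
    key <- paste(p[1], p[2], len, orient)
    if (!is.null(found[[key]])) return(invisible())
    found[[key]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      a_start = p[1], b_start = p[2], length = len, orientation = orient)
  }
  runs_of <- function(m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values & r$lengths >= min_len)
    cbind(starts[w], r$lengths[w])
  }
  # direct pairs: diagonal offset d
  for (d in seq_len(L - 1L)) {
    idx <- seq_len(n - d)
    rr <- runs_of(b[idx] == b[idx + d])
    if (nrow(rr)) for (w in seq_len(nrow(rr))) {
      i <- rr[w, 1]
      if (i <= L) add(i, i + d, rr[w, 2], "direct")
    }
  }
  # inverted pairs: window [i, i+len) equals rc of [j, j+len);
  # match condition b[u] == comp(b[s-u]) with s = i + j + len - 1 constant
  for (s in 3L:(2L * n)) {
    u <- max(1L, s - n):min(n, s - 1L)
    rr <- runs_of(b[u] == cb[s - u])
    if (nrow(rr)) for (w in seq_len(nrow(rr))) {
      i <- u[1] + rr[w, 1] - 1L
      len <- rr[w, 2]
      j <- s - (i + len - 1L)          # start of the partner copy
      if (i <= L || j <= L) add(min(i, j), max(i, j), len, "inverted")
    }
  }
  if (!length(rows)) {
    return(data.frame(a_start = integer(), b_start = integer(),
                      length = integer(), orientation = character()))
  }
  df <- do.call(rbind, rows)
  df[order(-df$length, df$a_start, df$b_start), , drop = FALSE]
}

# canonical form of a circular DNA string: lexicographically minimal among
# all rotations of itself and of its reverse complement
oracle_canon_circle <- function(s) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- nchar(s)
  best <- NULL
  for (w in c(s, rc)) {
    d <- paste0(w, w)
    rots <- substring(d, 1:L, L:(2L * L - 1L))
    m <- min(rots)
    if (is.null(best) || m < best) best <- m
  }
  best
}

oracle_canon_state <- function(circles) {
  paste(sort(vapply(circles, oracle_canon_circle, character(1))),
        collapse = "||")
}

# --- sequence-level isoform reachability ----------------------------------
# Enumerates every state reachable from `seqstr` by recombination at exact
# copies of the family sequences in `fam_seqs` (inversion at inverted pairs,
# fission at direct pairs, fusion across circles), up to `max_depth` moves.
# States are canonical multisets of circle strings.  Returns the set of
# single-circle canonical strings with their minimal move count.
oracle_isoform_reachable <- function(seqstr, fam_seqs, max_depth = 4L,
                                     max_states = 20000L) {
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  locate <- function(circle, fam) {
    # exact occurrences (0-based starts) of fam on both strands of a circle
    L <- nchar(circle)
    d <- paste0(circle, substr(circle, 1L, nchar(fam) - 1L))
    hits <- function(pat, sign) {
      g <- gregexpr(pat, d, fixed = TRUE)[[1]]
      if (g[1] == -1L) return(NULL)
      data.frame(start = as.integer(g) - 1L, sign = sign)
    }
    out <- rbind(hits(fam, "+"), hits(rc(fam), "-"))
    if (is.null(out)) out <- data.frame(start = integer(),
                                        sign = character())
    out[out$start < L, , drop = FALSE]
  }
  arc <- function(circle, from, to) {
    # 0-based half-open arc, wrap-aware
    L <- nchar(circle)
    from <- from %% L; to <- to %% L
    if (from < to) substr(circle, from + 1L, to)
    else paste0(substr(circle, from + 1L, L), substr(circle, 1L, to))
  }
  neighbors <- function(circles) {
    out <- list()
    for (fam in fam_seqs) {
      lf <- nchar(fam)
      occ <- do.call(rbind, lapply(seq_along(circles), function(ci) {
        lo <- locate(circles[[ci]], fam)
        if (nrow(lo)) cbind(lo, circle = ci) else NULL
      }))
      if (is.null(occ) || nrow(occ) < 2L) next
      for (u in seq_len(nrow(occ) - 1L)) for (v in (u + 1L):nrow(occ)) {
        c1 <- occ$circle[u]; c2 <- occ$circle[v]
        if (c1 == c2) {
          s <- circles[[c1]]
          p <- sort(c(occ$start[u], occ$start[v]))
          if (occ$sign[u] != occ$sign[v]) {
            mid <- arc(s, p[1] + lf, p[2])
            newc <- paste0(arc(s, 0L, p[1] + lf), rc(mid),
                           arc(s, p[2], 0L))
            # arc(s, p2, 0) is wrap-aware tail
            newc <- paste0(substr(s, 1L, p[1] + lf), rc(mid),
                           substr(s, p[2] + 1L, nchar(s)))
            out[[length(out) + 1L]] <- c(circles[-c1], list(newc))
          } else {
            A <- arc(s, p[1], p[2]); B <- arc(s, p[2], p[1])
            out[[length(out) + 1L]] <- c(circles[-c1], list(A, B))
          }
        } else {
          w1 <- arc(circles[[c1]], occ$start[u], occ$start[u])
          w1 <- paste0(substr(circles[[c1]], occ$start[u] + 1L,
                              nchar(circles[[c1]])),
                       substr(circles[[c1]], 1L, occ$start[u]))
          s2 <- circles[[c2]]
          if (occ$sign[v] != occ$sign[u]) {
            s2 <- rc(s2)
            st2 <- nchar(s2) - occ$start[v] - lf
          } else st2 <- occ$start[v]
          w2 <- paste0(substr(s2, st2 + 1L, nchar(s2)),
                       substr(s2, 1L, st2))
          fused <- paste0(w1, w2)
          out[[length(out) + 1L]] <- c(circles[-c(c1, c2)], list(fused))
        }
      }
    }
    out
  }
  start <- list(seqstr)
  seen <- new.env(parent = emptyenv())
  res <- new.env(parent = emptyenv())
  key0 <- oracle_canon_state(start)
  seen[[key0]] <- TRUE
  res[[oracle_canon_circle(seqstr)]] <- 0L
  frontier <- list(start)
  nstates <- 1L
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (nb in neighbors(st)) {
        key <- oracle_canon_state(nb)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        nstates <- nstates + 1L
        if (nstates > max_states) stop("oracle state cap exceeded")
        if (length(nb) == 1L) {
          ck <- oracle_canon_circle(nb[[1]])
          if (is.null(res[[ck]])) res[[ck]] <- depth
        }
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  out <- unlist(as.list(res))
  data.frame(canon = names(out), moves = unname(out),
             stringsAsFactors = FALSE)
}
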