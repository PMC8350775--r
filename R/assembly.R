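# Post-assembler structural logic: repeat-contig flagging, circularization,
# and recombination-like merging of circular chromosomes.

.err <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Shared similarity segments between two genomes (internal; also the engine
# behind plastid-insertion detection and auto repeat selection for merging).
# Returns a table like find_repeats() but with a_* on `ga` and b_* on `gb`.
.shared_segments <- function(ga, gb, min_len = 50L, min_identity = 0.99,
                             k = 24L, both_strands = TRUE, xdrop = 15L) {
  k <- as.integer(min(k, min_len))
  La <- ga$length; Lb <- gb$length
  circ_a <- ga$topology == "circular"; circ_b <- gb$topology == "circular"
  Da <- if (circ_a) paste0(ga$seq, ga$seq) else ga$seq
  Db <- if (circ_b) paste0(gb$seq, gb$seq) else gb$seq
  seeds <- .cross_seed_pairs(Da, Db, La, Lb, k, both_strands)

  byta <- .seq_bytes(Da); bytb <- .seq_bytes(Db)
  cbytb <- .seq_bytes(.complement_chr(Db))

  exact <- min_identity >= 0.999
  collect <- function(sd, orientation) {
    if (is.null(sd) || nrow(sd) == 0L) return(NULL)
    cl <- .cluster_seeds(sd$i, sd$j, k, orientation,
                         max_gap = if (exact) 1L else 4L * k)
    out <- vector("list", nrow(cl))
    for (r in seq_len(nrow(cl))) {
      cand <- .extend_candidate(cl[r, ], byta, bytb, cbytb, orientation,
                                max_a = length(byta), max_b = length(bytb),
                                xdrop = xdrop, exact = exact)
      len <- cand$a2 - cand$a1 + 1L
      if (len < min_len || len > La || len > Lb) next
      idn <- .candidate_identity(cand, byta, bytb, cbytb, orientation)
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
  if (is.null(cands) || nrow(cands) == 0L) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      a_wraps = logical(), b_start = integer(),
                      b_end = integer(), b_wraps = logical(),
                      orientation = character(), length = integer(),
                      identity = numeric()))
  }
  len <- cands$a2 - cands$a1 + 1L
  na <- .norm_circ_interval(cands$a1, len, La, circ_a)
  nb <- .norm_circ_interval(cands$b1, len, Lb, circ_b)
  df <- data.frame(a_start = na$start, a_end = na$end, a_wraps = na$wraps,
                   b_start = nb$start, b_end = nb$end, b_wraps = nb$wraps,
                   orientation = cands$orientation, length = len,
                   identity = cands$identity)
  df <- df[!duplicated(df[, c("a_start", "b_start", "orientation",
                              "length")]), , drop = FALSE]
  # drop segments contained in a longer one on both sides
  df <- df[order(-df$length, df$a_start), , drop = FALSE]
  contained <- logical(nrow(df))
  if (nrow(df) > 1L) {
    for (r in 2:nrow(df)) for (q in seq_len(r - 1L)) {
      if (contained[q] || df$orientation[q] != df$orientation[r]) next
      ov_a <- .circ_overlap(df$a_start[r], df$length[r],
                            df$a_start[q], df$length[q], La)
      ov_b <- .circ_overlap(df$b_start[r], df$length[r],
                            df$b_start[q], df$length[q], Lb)
      if (ov_a == df$length[r] && ov_b == df$length[r]) {
        contained[r] <- TRUE; break
      }
    }
  }
  df <- df[!contained, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a contig overlap graph edge table
#'
#' Edges connect contig extremities (`"L"` or `"R"`).
#' @param from,from_end,to,to_end,overlap equal-length vectors.
#' @return data.frame of edges.
#' @export
contig_overlap_graph <- function(from = character(), from_end = character(),
                                 to = character(), to_end = character(),
                                 overlap = integer()) {
  stopifnot(all(from_end %in% c("L", "R")), all(to_end %in% c("L", "R")))
  data.frame(from = from, from_end = from_end, to = to, to_end = to_end,
             overlap = as.integer(overlap), stringsAsFactors = FALSE)
}

#' Flag repeat contigs in an overlap graph
#'
#' A contig is flagged when it has at least two distinct neighbors on its
#' left end AND at least two on its right end -- the overlap-graph signature
#' of a repeated region connecting four different flanking contigs.
#'
#' @param graph edge table from [contig_overlap_graph()].
#' @return character vector of flagged contig ids.
#' @export
flag_repeat_contigs <- function(graph) {
  nodes <- unique(c(graph$from, graph$to))
  flagged <- character(0)
  for (nd in nodes) {
    nb <- function(end) {
      unique(c(graph$to[graph$from == nd & graph$from_end == end],
               graph$from[graph$to == nd & graph$to_end == end]))
    }
    if (length(nb("L")) >= 2L && length(nb("R")) >= 2L) {
      flagged <- c(flagged, nd)
    }
  }
  flagged
}

#' Circularize a linear contig by its terminal overlap
#'
#' Finds the longest prefix that matches the contig suffix at >=
#' `min_identity` (tolerating sequencing mismatches), removes one copy of
#' the duplicated end and returns a circle of `length(contig) - overlap` bp.
#' The junction keeps the prefix copy's bases.
#'
#' @param contig a linear [circular_genome()].
#' @param min_overlap minimum acceptable terminal overlap in bp.
#' @param min_identity identity floor for the overlap (default 0.99,
#'   tolerating about 1% long-read error).
#' @return a circular `CircularGenome`; errors with condition class
#'   `mitoring_no_terminal_overlap` when no qualifying overlap exists.
#' @export
circularize_by_terminal_overlap <- function(contig, min_overlap = 1000L,
                                            min_identity = 0.99) {
  if (contig$topology != "linear") stop("contig must be linear")
  s <- contig$seq
  Lc <- nchar(s)
  if (min_overlap >= Lc) .err("mitoring_no_terminal_overlap",
                              "min_overlap exceeds contig length")
  k <- min(31L, min_overlap)
  byt <- .seq_bytes(s)
  best <- 0L
  # seed with k-mers from several prefix offsets so a mismatch near the very
  # start cannot hide the overlap
  km_all <- .kmers(s, k)
  for (t in c(1L, 51L, 101L, 151L)) {
    if (t + k - 1L > Lc) break
    hits <- which(km_all == km_all[t])
    hits <- hits[hits > t]
    for (p in hits) {
      o <- Lc - (p - t)
      if (o < min_overlap || o >= Lc) next
      idn <- mean(byt[seq_len(o)] == byt[(Lc - o + 1L):Lc])
      if (idn >= min_identity && o > best) best <- o
    }
  }
  if (best == 0L) {
    .err("mitoring_no_terminal_overlap",
         sprintf("no terminal overlap >= %d bp at identity >= %.2f",
                 min_overlap, min_identity))
  }
  circular_genome(paste0(contig$id, "c"), .sub0(s, 0L, Lc - best),
                  "circular")
}

#' Circularize a contig whose extremities fall inside a repeat
#'
#' The contig is assumed to start with a suffix fragment of `repeat_sequence`
#' and to end with a prefix fragment of it (the assembler broke the circle
#' inside a repeat copy).  The two partial fragments are completed into one
#' full repeat copy; the resulting circle has length
#' `len(contig) - x - y + len(repeat)` where `x`/`y` are the anchored end
#' lengths.
#'
#' @param contig a linear [circular_genome()].
#' @param repeat_sequence the full repeat sequence (character).
#' @param min_anchor minimum length of each terminal anchor in bp.
#' @return a circular `CircularGenome`.
#' @export
circularize_via_repeat <- function(contig, repeat_sequence,
                                   min_anchor = 100L) {
  if (contig$topology != "linear") stop("contig must be linear")
  s <- contig$seq; Lc <- nchar(s)
  R <- toupper(repeat_sequence); lr <- nchar(R)
  k <- min(31L, min_anchor)
  kmR <- .kmers(R, k)

  # prefix of contig must match a suffix region of R
  p <- which(kmR == substr(s, 1L, k))
  x <- 0L
  for (pp in rev(p)) {
    xx <- lr - pp + 1L
    if (xx <= Lc && substr(s, 1L, xx) == substr(R, pp, lr)) { x <- xx; break }
  }
  # suffix of contig must match a prefix region of R
  q <- which(kmR == substr(s, Lc - k + 1L, Lc))
  y <- 0L
  for (qq in q) {
    yy <- qq + k - 1L
    if (yy <= Lc && substr(s, Lc - yy + 1L, Lc) == substr(R, 1L, yy)) {
      y <- yy; break
    }
  }
  if (x == 0L || y == 0L) {
    .err("mitoring_anchor_error",
         "contig extremities do not anchor the expected repeat flanks")
  }
  if (x < min_anchor || y < min_anchor) {
    .err("mitoring_anchor_error",
         sprintf("terminal anchors (%d, %d bp) below min_anchor = %d",
                 x, y, min_anchor))
  }
  if (Lc - x - y < 0L) {
    .err("mitoring_anchor_error", "terminal anchors overlap inconsistently")
  }
  u <- .sub0(s, x, Lc - y)
  circular_genome(paste0(contig$id, "c"), paste0(u, R), "circular")
}

#' Merge two circular chromosomes by recombination at a shared repeat
#'
#' Performs a recombination-like fusion: the product is one circle of length
#' `len(a) + len(b)` carrying two copies of the shared repeat, with the
#' crossover placed at the repeat midpoint.  In `family = "auto"` mode the
#' longest shared segment >= `min_shared` bp is used; alternatively pass
#' named repeat tables and a family name.
#'
#' @param a,b circular [circular_genome()] objects.
#' @param family `"auto"`, or a family name present in `shared` (a table of
#'   shared segments with a `name` column).
#' @param shared optional precomputed shared-segment table
#'   (columns as returned by the internal scanner; `a_*` on `a`, `b_*` on
#'   `b`).
#' @param min_shared minimum shared repeat length for auto mode.
#' @return merged circular `CircularGenome` named `<a>+<b>`; errors with
#'   condition class `mitoring_no_shared_repeat` when nothing qualifies.
#' @export
merge_circles_by_repeat <- function(a, b, family = "auto", shared = NULL,
                                    min_shared = 50L) {
  stopifnot(a$topology == "circular", b$topology == "circular")
  if (is.null(shared)) {
    shared <- .shared_segments(a, b, min_len = min_shared)
  }
  if (nrow(shared) == 0L) {
    .err("mitoring_no_shared_repeat",
         sprintf("no shared repeat >= %d bp between '%s' and '%s'",
                 min_shared, a$id, b$id))
  }
  if (identical(family, "auto")) {
    shared <- shared[order(-shared$length,
                           if (!is.null(shared$name)) shared$name else
                             shared$a_start), , drop = FALSE]
    seg <- shared[1, , drop = FALSE]
  } else {
    if (is.null(shared$name) || !family %in% shared$name) {
      .err("mitoring_no_shared_repeat",
           paste0("repeat family '", family, "' not shared by both circles"))
    }
    seg <- shared[shared$name == family, , drop = FALSE][1, , drop = FALSE]
  }

  # orient b so the shared copy reads forward on both circles
  bb <- b
  b_start <- seg$b_start
  if (seg$orientation == "inverted") {
    len <- seg$length
    b_start <- (b$length - seg$b_start - len) %% b$length
    bb <- reverse_complement(b)
  }
  ra <- rotate(a, seg$a_start)          # a = Ra + Sa
  rb <- rotate(bb, b_start)             # b = Rb + Sb
  l <- seg$length
  h <- l %/% 2L
  Ra <- .sub0(ra$seq, 0L, l);  Sa <- .sub0(ra$seq, l, ra$length)
  Rb <- .sub0(rb$seq, 0L, l);  Sb <- .sub0(rb$seq, l, rb$length)
  # crossover at the repeat midpoint: copy1 = Ra[1:h] + Rb[(h+1):l], then Sb;
  # copy2 = Rb[1:h] + Ra[(h+1):l], then Sa
  merged <- paste0(substr(Ra, 1L, h), substr(Rb, h + 1L, l), Sb,
                   substr(Rb, 1L, h), substr(Ra, h + 1L, l), Sa)
  circular_genome(paste0(a$id, "+", b$id), merged, "circular")
}
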