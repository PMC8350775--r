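# Detection and cross-genome classification of plastid-derived insertions
# (MTPTs) in mitochondrial genomes.

#' Detect plastid-derived insertions in a mitochondrial genome
#'
#' Scans the mitochondrial genome against the plastid reference by k-mer
#' seeding and gap-free x-drop extension on both strands, merges co-linear
#' segments separated by at most `merge_gap` bp, collapses hits falling in
#' the second copy of the plastid inverted repeat onto the first, and
#' attributes every plastid gene whose annotation overlaps the matched
#' plastid interval by at least 1 bp.
#'
#' @param mt mitochondrial [circular_genome()].
#' @param cp plastid [circular_genome()] carrying gene annotations (used for
#'   `cp_genes` attribution).
#' @param min_len minimum insertion length (default 50 bp).
#' @param min_identity identity floor (default 0.85, tolerant of older
#'   transfers; detection additionally requires at least one conserved
#'   `k`-mer seed).
#' @param k seed size (default 16 -- smaller than for repeat discovery, so
#'   diverged insertions still seed).
#' @param merge_gap co-linear segments closer than this are merged.
#' @param collapse_ir collapse hits in the second plastid inverted-repeat
#'   copy onto the first (default TRUE; the IR is auto-detected as the
#'   largest inverted repeat >= 1 kb of the plastid genome).
#' @return data.frame of calls sorted by mt position: `mt_start`, `mt_end`,
#'   `mt_wraps`, `cp_start`, `cp_end`, `cp_wraps`, `strand`, `length`
#'   (mt-side), `cp_length`, `identity`, `cp_genes` (comma-separated).
#' @export
find_insertions <- function(mt, cp, min_len = 50L, min_identity = 0.85,
                            k = 16L, merge_gap = 100L, collapse_ir = TRUE) {
  seg <- .shared_segments(mt, cp, min_len = min_len,
                          min_identity = min_identity, k = k,
                          both_strands = TRUE, xdrop = 20L)
  if (nrow(seg) == 0L) return(.empty_insertions())

  # merge co-linear segments within merge_gap on both genomes
  seg$diag <- ifelse(seg$orientation == "direct",
                     (seg$b_start - seg$a_start) %% cp$length,
                     (seg$b_start + seg$a_start) %% cp$length)
  seg <- seg[order(seg$orientation, seg$diag, seg$a_start), , drop = FALSE]
  merged <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) merged[[length(merged) + 1L]] <<- cur
  for (r in seq_len(nrow(seg))) {
    row <- seg[r, ]
    if (!is.null(cur) && row$orientation == cur$orientation &&
        abs(row$diag - cur$diag) <= merge_gap &&
        row$a_start - (cur$a_start + cur$length) <= merge_gap) {
      new_len <- (row$a_start + row$length) - cur$a_start
      cur$identity <- (cur$identity * cur$length +
                         row$identity * row$length) / (cur$length + row$length)
      cur$length <- new_len
      if (row$orientation == "direct") {
        cur$b_end <- row$b_end; cur$b_wraps <- cur$b_wraps || row$b_wraps
      } else {
        cur$b_start <- row$b_start; cur$b_wraps <- cur$b_wraps || row$b_wraps
      }
      cur$a_end <- row$a_end; cur$a_wraps <- cur$a_wraps || row$a_wraps
    } else {
      flush(); cur <- row
    }
  }
  flush()
  seg <- do.call(rbind, merged)

  # make calls disjoint on the mt side: keep longest; trim small overlaps
  # off shorter calls (both mt and cp side), drop a call only when kept
  # calls cover most of it
  seg <- seg[order(-seg$length), , drop = FALSE]
  La <- mt$length; Lb <- cp$length
  keep <- rep(TRUE, nrow(seg))
  if (nrow(seg) > 1L) {
    covered <- logical(La)
    mark <- function(st, ln) {
      covered[((st + seq_len(ln) - 1L) %% La) + 1L] <<- TRUE
    }
    mark(seg$a_start[1], seg$length[1])
    for (r in 2:nrow(seg)) {
      ln <- seg$length[r]
      pos <- ((seg$a_start[r] + seq_len(ln) - 1L) %% La) + 1L
      free <- !covered[pos]
      if (sum(free) < max(min_len, ln %/% 2L)) { keep[r] <- FALSE; next }
      runs <- rle(free)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      w <- which(runs$values)
      bestw <- w[which.max(runs$lengths[w])]
      ltrim <- starts[bestw] - 1L
      rtrim <- ln - ends[bestw]
      if (ltrim > 0L || rtrim > 0L) {
        newlen <- ln - ltrim - rtrim
        seg$a_start[r] <- (seg$a_start[r] + ltrim) %% La
        btrim <- if (seg$orientation[r] == "direct") ltrim else rtrim
        seg$b_start[r] <- (seg$b_start[r] + btrim) %% Lb
        seg$length[r] <- newlen
        ae <- seg$a_start[r] + newlen
        seg$a_wraps[r] <- ae > La
        seg$a_end[r] <- if (ae > La) ae - La else ae
        be <- seg$b_start[r] + newlen
        seg$b_wraps[r] <- be > Lb
        seg$b_end[r] <- if (be > Lb) be - Lb else be
      }
      mark(seg$a_start[r], seg$length[r])
    }
  }
  seg <- seg[keep, , drop = FALSE]

  # collapse hits inside the second IR copy of the plastome onto the first
  if (collapse_ir) {
    ir <- .plastid_ir(cp)
    if (!is.null(ir)) {
      for (r in seq_len(nrow(seg))) {
        ov <- .circ_overlap(seg$b_start[r],
                            .interval_len(seg$b_start[r], seg$b_end[r],
                                          seg$b_wraps[r], cp$length),
                            ir$b_start, ir$length, cp$length)
        ln <- .interval_len(seg$b_start[r], seg$b_end[r], seg$b_wraps[r],
                            cp$length)
        if (ov == ln) {
          # position within IR copy 2 -> mirrored position in copy 1
          off <- (seg$b_start[r] - ir$b_start) %% cp$length
          ns <- (ir$a_start + ir$length - off - ln) %% cp$length
          seg$b_start[r] <- ns
          ne <- ns + ln
          seg$b_wraps[r] <- ne > cp$length
          seg$b_end[r] <- if (ne > cp$length) ne - cp$length else ne
          seg$orientation[r] <- if (seg$orientation[r] == "direct")
            "inverted" else "direct"
        }
      }
    }
  }

  cp_len <- .interval_len(seg$b_start, seg$b_end, seg$b_wraps, cp$length)
  calls <- data.frame(mt_start = seg$a_start, mt_end = seg$a_end,
                      mt_wraps = seg$a_wraps, cp_start = seg$b_start,
                      cp_end = seg$b_end, cp_wraps = seg$b_wraps,
                      strand = ifelse(seg$orientation == "direct", "+", "-"),
                      length = seg$length, cp_length = cp_len,
                      identity = seg$identity)
  calls$cp_genes <- vapply(seq_len(nrow(calls)), function(r) {
    .overlapping_genes(cp, calls$cp_start[r], calls$cp_end[r],
                       calls$cp_wraps[r])
  }, character(1))
  calls <- calls[order(calls$mt_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

.empty_insertions <- function() {
  data.frame(mt_start = integer(), mt_end = integer(), mt_wraps = logical(),
             cp_start = integer(), cp_end = integer(), cp_wraps = logical(),
             strand = character(), length = integer(), cp_length = integer(),
             identity = numeric(), cp_genes = character())
}

# largest inverted repeat >= 1 kb of the plastid genome (the canonical IR),
# or NULL
.plastid_ir <- function(cp) {
  rp <- find_repeats(cp, min_len = 1000L, min_identity = 0.98)
  rp <- rp[rp$orientation == "inverted", , drop = FALSE]
  if (nrow(rp) == 0L) return(NULL)
  rp[which.max(rp$length), , drop = FALSE]
}

.overlapping_genes <- function(cp, start, end, wraps) {
  a <- cp$annotations
  if (is.null(a) || nrow(a) == 0L) return("")
  gene_rows <- a[a$feature_type %in% c("gene", "CDS", "rRNA", "tRNA"), ,
                 drop = FALSE]
  if (nrow(gene_rows) == 0L) return("")
  L <- cp$length
  ln <- .interval_len(start, end, wraps, L)
  hits <- vapply(seq_len(nrow(gene_rows)), function(r) {
    gl <- .interval_len(gene_rows$start[r], gene_rows$end[r],
                        gene_rows$wraps[r], L)
    .circ_overlap(start, ln, gene_rows$start[r], gl, L) >= 1L
  }, logical(1))
  paste(unique(gene_rows$name[hits]), collapse = ",")
}

#' Classify plastid insertions across genomes as shared or variable
#'
#' Clusters calls across genomes by reciprocal plastid-interval overlap
#' (>= 50%), labels each cluster `shared` (present in every genome) or
#' `variable`, and flags pairs of clusters occupying the same mitochondrial
#' locus in different genomes (mutually exclusive variants), detected by
#' matching the mitochondrial flanking sequence of the insertion sites.
#'
#' @param calls_per_genome named list: genome id -> call table from
#'   [find_insertions()].
#' @param genomes optional named list of the mt [circular_genome()] objects,
#'   required for mutually-exclusive-variant flagging (flank comparison).
#' @param flank bp of mitochondrial flank used to match loci.
#' @return data.frame with one row per (cluster, genome) pair: `cluster`,
#'   `genome`, `present`, `mt_start`, `mt_end`, `length`, `cp_genes`,
#'   `status` (shared/variable) and `locus` (same value = same mt locus).
#' @export
classify_insertions <- function(calls_per_genome, genomes = NULL,
                                flank = 200L) {
  if (length(calls_per_genome) < 2L) stop("need calls for >= 2 genomes")
  gids <- names(calls_per_genome)
  all_calls <- do.call(rbind, lapply(gids, function(g) {
    df <- calls_per_genome[[g]]
    if (nrow(df) == 0L) return(NULL)
    df$genome <- g
    df
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    return(data.frame(cluster = integer(), genome = character(),
                      present = logical(), mt_start = integer(),
                      mt_end = integer(), length = integer(),
                      cp_genes = character(), status = character(),
                      locus = integer()))
  }
  n <- nrow(all_calls)
  # single-linkage clustering by >= 50% reciprocal cp-interval overlap
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    li <- all_calls$cp_length[i]; lj <- all_calls$cp_length[j]
    ov <- .circ_overlap(all_calls$cp_start[i], li,
                        all_calls$cp_start[j], lj, .Machine$integer.max %/% 2L)
    if (ov >= 0.5 * li && ov >= 0.5 * lj) parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, integer(1))
  all_calls$cluster <- match(root, unique(root))

  # locus assignment via mt flank matching
  all_calls$locus <- all_calls$cluster
  if (!is.null(genomes)) {
    fl <- vapply(seq_len(n), function(i) {
      g <- genomes[[all_calls$genome[i]]]
      s <- (all_calls$mt_start[i] - flank) %% g$length
      .sub0_circ(g$seq, s, all_calls$mt_start[i],
                 s > all_calls$mt_start[i])
    }, character(1))
    # same locus when upstream flanks share most k-mers
    lparent <- seq_len(n)
    lfind <- function(x) { while (lparent[x] != x) x <- lparent[x]; x }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sim <- .repeat_similarity(fl[i], fl[j])["coverage"]
      if (!is.na(sim) && sim >= 0.8) lparent[lfind(j)] <- lfind(i)
    }
    lroot <- vapply(seq_len(n), lfind, integer(1))
    all_calls$locus <- match(lroot, unique(lroot))
  }

  # emit one row per cluster x genome (absences recorded)
  out <- list()
  for (cl in sort(unique(all_calls$cluster))) {
    rows <- all_calls[all_calls$cluster == cl, , drop = FALSE]
    status <- if (all(gids %in% rows$genome) &&
                  !any(duplicated(rows$genome))) "shared" else "variable"
    # a cluster sharing its mt locus with a different cluster is variable
    same_locus_other <- any(all_calls$locus %in% rows$locus &
                              all_calls$cluster != cl)
    if (same_locus_other) status <- "variable"
    for (g in gids) {
      gr <- rows[rows$genome == g, , drop = FALSE]
      if (nrow(gr) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, genome = g, present = TRUE,
          mt_start = gr$mt_start[1], mt_end = gr$mt_end[1],
          length = gr$length[1], cp_genes = gr$cp_genes[1],
          status = status, locus = gr$locus[1])
      } else {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, genome = g, present = FALSE,
          mt_start = NA_integer_, mt_end = NA_integer_,
          length = NA_integer_, cp_genes = "", status = status,
          locus = rows$locus[1])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert insertion calls to BED4 on the mitochondrial genome
#' @param calls call table from [find_insertions()].
#' @param mt the mitochondrial genome.
#' @export
insertions_to_bed <- function(calls, mt) {
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  nm <- ifelse(nzchar(calls$cp_genes),
               paste0("cp_insert:", calls$cp_genes), "cp_insert")
  data.frame(chrom = mt$id, start = calls$mt_start, end = calls$mt_end,
             name = nm)
}
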