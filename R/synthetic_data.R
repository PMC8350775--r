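# Seeded synthetic-genome generation with machine-readable ground truth.
# The generator plants repeats, genes, plastid-derived insertions and
# partial C-to-U editing sites into an i.i.d. background at a chosen GC,
# then breaks any emergent exact repeat >= min_len/2 by point substitution
# so the planted truth is the complete truth.

.MITO_GENE_TEMPLATE <- local({
  protein <- c(
    nad1 = 978, nad2 = 1467, nad3 = 357, nad4 = 1485, nad4L = 303,
    nad5 = 2013, nad6 = 618, nad7 = 1185, nad9 = 573, cox1 = 1584,
    cox2 = 783, cox3 = 798, cob = 1182, atp1 = 1527, atp4 = 594,
    atp6 = 723, atp8 = 480, atp9 = 225, ccmB = 621, ccmC = 753,
    ccmFc = 1329, ccmFn = 1734, matR = 1968, mttB = 777, rps1 = 552,
    rps3 = 1677, rps4 = 1053, rps7 = 447, rps12 = 378, rpl2 = 1035,
    rpl5 = 558, rpl10 = 483, rpl16 = 540)
  rrna <- c(rrn5 = 118, rrn18 = 1935, rrn26 = 3510)
  list(protein = protein, rrna = rrna)
})

#' Specification for a synthetic mitochondrial genome
#'
#' @param length genome length in bp (the assembled genomes this emulates
#'   are 350-380 kb; tests typically use reduced scale).
#' @param gc GC fraction of the background (default 0.45).
#' @param repeat_specs list of `list(length, orientation = "direct",
#'   copies = 2, family, within = NULL)`; `within` names a host family whose
#'   sequence will contain this one (nested copies).
#' @param gene_specs `"template"` for the built-in set (33 protein genes +
#'   3 rRNAs with generic names), `NULL` for none, or a list of
#'   `list(name, length, strand, start = "ATG")` (length divisible by 3).
#' @param insertion_specs list of `list(length)` (random plastid-like
#'   fragment) or `list(cp_start, cp_end)` referring to a supplied plastid
#'   genome.
#' @param editing_specs list of `list(gene, offset, extent)`; `offset` is
#'   0-based within the CDS and the generator forces a `C` there on the
#'   coding strand.
#' @param seed integer; same seed gives byte-identical output.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(length, gc = 0.45, repeat_specs = list(),
                        gene_specs = NULL, insertion_specs = list(),
                        editing_specs = list(), seed = 1L) {
  structure(list(length = as.integer(length), gc = gc,
                 repeat_specs = repeat_specs, gene_specs = gene_specs,
                 insertion_specs = insertion_specs,
                 editing_specs = editing_specs, seed = as.integer(seed)),
            class = "genome_spec")
}

.random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS: start codon, non-stop internal codons, one stop
.random_cds <- function(len, gc = 0.45, start = "ATG") {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ncod <- len %/% 3L - 2L
  codons <- character(ncod)
  for (i in seq_len(ncod)) {
    repeat {
      cd <- .random_dna(3L, gc)
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    codons[i] <- cd
  }
  paste0(start, paste(codons, collapse = ""), "TAA")
}

#' Generate a synthetic circular mitogenome with ground truth
#'
#' Features are placed without overlap (except requested nesting) with
#' random gaps; an error is raised when they cannot fit.  Same seed, same
#' bytes.
#'
#' @param spec a [genome_spec()].
#' @param cp optional plastid [circular_genome()] for interval-based
#'   insertion specs.
#' @param id genome identifier.
#' @return `list(genome, truth)`; `truth` has elements `repeats`, `genes`,
#'   `insertions`, `editing` (data.frames with exact coordinates) and
#'   `seed`.  Gene and insertion features are annotated on the genome.
#' @export
generate_mitogenome <- function(spec, cp = NULL, id = "synthetic_mt") {
  stopifnot(inherits(spec, "genome_spec"))
  .with_seed(spec$seed, {
    L <- spec$length

    # ---- materialize feature sequences
    feats <- list()   # each: list(kind, name, seq, strand, meta)
    fam_seqs <- list()
    for (rs in spec$repeat_specs) {
      fam <- rs$family %||% sprintf("F%02d", length(fam_seqs) + 1L)
      fam_seqs[[fam]] <- .random_dna(rs$length, spec$gc)
    }
    # nesting: embed nested family's sequence inside its host's
    for (rs in spec$repeat_specs) {
      if (!is.null(rs$within)) {
        host <- rs$within
        if (is.null(fam_seqs[[host]])) stop("unknown host family: ", host)
        if (rs$length >= nchar(fam_seqs[[host]])) {
          stop("nested repeat '", rs$family, "' does not fit inside '",
               host, "'")
        }
        off <- sample.int(nchar(fam_seqs[[host]]) - rs$length, 1L)
        fam_seqs[[rs$family]] <-
          substr(fam_seqs[[host]], off, off + rs$length - 1L)
      }
    }
    for (rs in spec$repeat_specs) {
      fam <- rs$family
      copies <- rs$copies %||% 2L
      orientation <- rs$orientation %||% "direct"
      for (ci in seq_len(copies)) {
        s <- fam_seqs[[fam]]
        sign <- "+"
        if (orientation == "inverted" && ci == 2L) { s <- .revcomp(s); sign <- "-" }
        feats[[length(feats) + 1L]] <- list(kind = "repeat", name = fam,
                                            seq = s, strand = "*",
                                            meta = list(copy = ci,
                                                        sign = sign,
                                                        orientation = orientation))
      }
    }

    gspecs <- spec$gene_specs
    if (identical(gspecs, "template")) {
      tpl <- .MITO_GENE_TEMPLATE
      gspecs <- c(
        lapply(names(tpl$protein), function(nm) {
          list(name = nm, length = unname(tpl$protein[nm]),
               strand = if (runif(1) < 0.5) "+" else "-", type = "CDS")
        }),
        lapply(names(tpl$rrna), function(nm) {
          list(name = nm, length = unname(tpl$rrna[nm]), strand = "+",
               type = "rRNA")
        }))
    }
    edit_by_gene <- split(spec$editing_specs,
                          vapply(spec$editing_specs, `[[`, character(1),
                                 "gene"))
    for (gs in gspecs %||% list()) {
      type <- gs$type %||% "CDS"
      if (type == "CDS") {
        s <- .random_cds(gs$length, spec$gc, start = gs$start %||% "ATG")
        # force a C at each planted editing offset (coding strand); C can
        # never create a stop codon
        for (es in edit_by_gene[[gs$name]] %||% list()) {
          off <- es$offset
          stopifnot(off >= 0L, off < gs$length)
          substr(s, off + 1L, off + 1L) <- "C"
        }
      } else {
        s <- .random_dna(gs$length, spec$gc)
      }
      feats[[length(feats) + 1L]] <- list(kind = type, name = gs$name,
                                          seq = s,
                                          strand = gs$strand %||% "+",
                                          meta = list())
    }

    ins_id <- 0L
    for (is_ in spec$insertion_specs) {
      ins_id <- ins_id + 1L
      if (!is.null(is_$cp_start)) {
        if (is.null(cp)) stop("insertion spec needs a plastid genome")
        s <- .sub0_circ(cp$seq, is_$cp_start, is_$cp_end,
                        is_$cp_start > is_$cp_end)
        meta <- list(cp_start = is_$cp_start, cp_end = is_$cp_end)
      } else {
        s <- .random_dna(is_$length, spec$gc)
        meta <- list(cp_start = NA_integer_, cp_end = NA_integer_)
      }
      if (!is.null(is_$strand) && is_$strand == "-") s <- .revcomp(s)
      feats[[length(feats) + 1L]] <- list(kind = "cp_insert",
                                          name = sprintf("ins%02d", ins_id),
                                          seq = s,
                                          strand = is_$strand %||% "+",
                                          meta = meta)
    }

    total <- sum(vapply(feats, function(f) nchar(f$seq), integer(1)))
    if (total > L) {
      stop("unsatisfiable spec: planted features (", total,
           " bp) exceed genome length (", L, " bp)")
    }

    # ---- placement: random order, random gaps (stick-breaking)
    if (length(feats)) feats <- feats[sample.int(length(feats))]
    free <- L - total
    nf <- length(feats)
    gaps <- if (nf > 0L) {
      cuts <- sort(sample.int(free + 1L, nf, replace = TRUE) - 1L)
      diff(c(0L, cuts))
    } else integer(0)
    pieces <- character(0)
    cursor <- 0L
    placed <- list()
    for (t in seq_len(nf)) {
      pieces <- c(pieces, .random_dna(gaps[t], spec$gc))
      cursor <- cursor + gaps[t]
      f <- feats[[t]]
      s <- if (f$kind %in% c("CDS", "rRNA", "gene") && f$strand == "-")
        .revcomp(f$seq) else f$seq
      pieces <- c(pieces, s)
      placed[[t]] <- c(f, list(start = cursor, end = cursor + nchar(s)))
      cursor <- cursor + nchar(s)
    }
    pieces <- c(pieces, .random_dna(L - cursor, spec$gc))
    seqstr <- paste(pieces, collapse = "")
    stopifnot(nchar(seqstr) == L)

    # ---- hygiene: break emergent exact duplicates >= 25 bp outside truth
    protected <- logical(L)
    for (p in placed) protected[(p$start + 1L):p$end] <- TRUE
    seqstr <- .break_emergent_repeats(seqstr, protected, k = 25L)
    # ... and make planted boundaries maximal: a background base flanking a
    # planted copy must not match its counterpart, or detectors would
    # (correctly) extend past the planted truth
    seqstr <- .break_matching_flanks(seqstr, placed, protected, L, cp)

    # ---- truth tables + annotations
    truth_repeats <- do.call(rbind, lapply(placed, function(p) {
      if (p$kind != "repeat") return(NULL)
      data.frame(family = p$name, copy = p$meta$copy, start = p$start,
                 end = p$end, wraps = FALSE, sign = p$meta$sign,
                 orientation = p$meta$orientation,
                 length = p$end - p$start)
    })) %||% data.frame()
    # nested families: copies inside each host copy
    for (rs in spec$repeat_specs) {
      if (is.null(rs$within)) next
      host_rows <- truth_repeats[truth_repeats$family == rs$within, ,
                                 drop = FALSE]
      nested <- fam_seqs[[rs$family]]
      for (hr in seq_len(nrow(host_rows))) {
        hseq <- fam_seqs[[rs$within]]
        if (host_rows$sign[hr] == "-") hseq <- .revcomp(hseq)
        offf <- regexpr(nested, hseq, fixed = TRUE)[1]
        offr <- regexpr(.revcomp(nested), hseq, fixed = TRUE)[1]
        use_f <- offf != -1L
        off <- if (use_f) offf else offr
        if (off == -1L) next
        truth_repeats <- rbind(truth_repeats, data.frame(
          family = rs$family, copy = max(truth_repeats$copy[
            truth_repeats$family == rs$family], 0L) + 1L,
          start = host_rows$start[hr] + off - 1L,
          end = host_rows$start[hr] + off - 1L + nchar(nested),
          wraps = FALSE, sign = if (use_f) host_rows$sign[hr] else
            if (host_rows$sign[hr] == "+") "-" else "+",
          orientation = "nested", length = nchar(nested)))
      }
    }

    truth_genes <- do.call(rbind, lapply(placed, function(p) {
      if (!p$kind %in% c("CDS", "rRNA", "gene")) return(NULL)
      data.frame(name = p$name, type = p$kind, start = p$start, end = p$end,
                 wraps = FALSE, strand = p$strand,
                 length = p$end - p$start)
    })) %||% data.frame()

    truth_ins <- do.call(rbind, lapply(placed, function(p) {
      if (p$kind != "cp_insert") return(NULL)
      data.frame(name = p$name, mt_start = p$start, mt_end = p$end,
                 cp_start = p$meta$cp_start, cp_end = p$meta$cp_end,
                 strand = p$strand, length = p$end - p$start)
    })) %||% data.frame()

    truth_edit <- NULL
    if (length(spec$editing_specs) && nrow(truth_genes) > 0L) {
      truth_edit <- do.call(rbind, lapply(spec$editing_specs, function(es) {
        gr <- truth_genes[truth_genes$name == es$gene, , drop = FALSE]
        if (nrow(gr) == 0L) stop("editing spec names unknown gene: ", es$gene)
        pos <- if (gr$strand == "+") gr$start + es$offset
               else gr$end - 1L - es$offset
        data.frame(gene = es$gene, offset = es$offset, position = pos,
                   strand = gr$strand, extent = es$extent)
      }))
    }
    truth_edit <- truth_edit %||% data.frame()

    ann <- annotation_table()
    if (nrow(truth_genes) > 0L) {
      ann <- rbind(ann, annotation_table(
        feature_type = truth_genes$type, start = truth_genes$start,
        end = truth_genes$end, strand = truth_genes$strand,
        name = truth_genes$name))
    }
    if (nrow(truth_ins) > 0L) {
      ann <- rbind(ann, annotation_table(
        feature_type = "cp_insert", start = truth_ins$mt_start,
        end = truth_ins$mt_end, strand = truth_ins$strand,
        name = truth_ins$name))
    }
    genome <- circular_genome(id, seqstr, "circular", ann)
    list(genome = genome,
         truth = list(genome_id = id, length = L, repeats = truth_repeats,
                      genes = truth_genes, insertions = truth_ins,
                      editing = truth_edit, seed = spec$seed))
  })
}

# force background bases flanking planted repeat copies / insertions to
# differ from their counterparts, so planted coordinates are maximal
.break_matching_flanks <- function(seqstr, placed, protected, L, cp,
                                   w = 3L) {
  # w flanking bases per side are forced to differ so that even a
  # mismatch-tolerant x-drop extension cannot cross the planted boundary
  base_at <- function(pos0) substr(seqstr, (pos0 %% L) + 1L, (pos0 %% L) + 1L)
  fix <- function(pos0, must_differ_from) {
    p1 <- (pos0 %% L) + 1L
    if (protected[p1]) return(invisible())
    cur <- substr(seqstr, p1, p1)
    if (!cur %in% must_differ_from) return(invisible())
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, must_differ_from))[1]
    substr(seqstr, p1, p1) <<- repl
    invisible()
  }
  offs <- seq_len(w) - 1L
  reps <- Filter(function(p) p$kind == "repeat", placed)
  if (length(reps) > 1L) {
    for (i in seq_len(length(reps) - 1L)) for (j in (i + 1L):length(reps)) {
      ri <- reps[[i]]; rj <- reps[[j]]
      if (ri$name != rj$name) next
      for (t in offs) {
        if (ri$meta$sign == rj$meta$sign) {
          fix(ri$start - 1L - t, base_at(rj$start - 1L - t))
          fix(ri$end + t, base_at(rj$end + t))
        } else {
          fix(ri$start - 1L - t, .complement_chr(base_at(rj$end + t)))
          fix(ri$end + t, .complement_chr(base_at(rj$start - 1L - t)))
        }
      }
    }
  }
  if (!is.null(cp)) {
    for (p in placed) {
      if (p$kind != "cp_insert" || is.na(p$meta$cp_start)) next
      Lcp <- cp$length
      cpb <- function(pos0) substr(cp$seq, (pos0 %% Lcp) + 1L,
                                   (pos0 %% Lcp) + 1L)
      for (t in offs) {
        if (p$strand == "-") {
          fix(p$start - 1L - t, .complement_chr(cpb(p$meta$cp_end + t)))
          fix(p$end + t, .complement_chr(cpb(p$meta$cp_start - 1L - t)))
        } else {
          fix(p$start - 1L - t, cpb(p$meta$cp_start - 1L - t))
          fix(p$end + t, cpb(p$meta$cp_end + t))
        }
      }
    }
  }
  seqstr
}

# point-mutate one occurrence of every emergent duplicated k-mer that is not
# fully inside planted features
.break_emergent_repeats <- function(seqstr, protected, k = 25L) {
  L <- nchar(seqstr)
  for (round in 1:5) {
    D <- paste0(seqstr, substr(seqstr, 1L, k))
    km <- .kmers(D, k)[seq_len(L)]
    rc <- .kmers(.revcomp(D), k)
    W <- nchar(D) - k + 1L
    rckm <- rc[W:1][seq_len(L)]
    canon <- pmin(km, rckm)
    dup <- duplicated(canon) | duplicated(canon, fromLast = TRUE)
    if (!any(dup)) return(seqstr)
    fixed_any <- FALSE
    for (pos in which(dup)) {
      win <- ((pos - 1L + 0:(k - 1L)) %% L) + 1L
      if (all(protected[win])) next       # planted duplication, keep
      tgt <- win[!protected[win]][ (sum(!protected[win]) + 1L) %/% 2L ]
      old <- substr(seqstr, tgt, tgt)
      new <- setdiff(c("A", "C", "G", "T"), old)[sample.int(3L, 1L)]
      substr(seqstr, tgt, tgt) <- new
      fixed_any <- TRUE
      break                               # recompute tables after each fix
    }
    if (!fixed_any) return(seqstr)
  }
  seqstr
}

#' Apply random repeat-mediated recombination moves to a genome
#'
#' Elementary events: an inversion at an inverted repeat pair, or a
#' fission+fusion through subgenomic circles at two interleaved direct
#' pairs (a translocation; counted as 2 events).  The product is always a
#' single circle and [are_isoforms()] must recognize it within `n_moves`.
#'
#' @param genome a circular [circular_genome()].
#' @param truth truth record from [generate_mitogenome()] (used for repeat
#'   family sequences).
#' @param n_moves number of elementary recombination events to apply.
#' @param seed RNG seed.
#' @return `list(genome, log)`; `log` is a list of
#'   `list(family, type)` entries, one per elementary event.
#' @export
shuffle_isoform <- function(genome, truth, n_moves, seed = 1L) {
  fam_tab <- truth$repeats
  if (is.null(fam_tab) || nrow(fam_tab) == 0L) {
    stop("no eligible repeat family in truth record")
  }
  fams <- unique(fam_tab$family[fam_tab$orientation != "nested"])
  fam_ref <- stats::setNames(lapply(fams, function(f) {
    r <- fam_tab[fam_tab$family == f & fam_tab$sign == "+", , drop = FALSE]
    .sub0_circ(genome$seq, r$start[1], r$end[1], r$wraps[1])
  }), fams)

  .with_seed(seed, {
    g <- genome
    log <- list()
    moves_left <- n_moves
    while (moves_left > 0L) {
      opts <- .eligible_moves(g, fam_ref, allow_transloc = moves_left >= 2L)
      if (length(opts) == 0L) {
        if (length(log) == 0L) stop("no eligible repeat family for moves")
        break
      }
      op <- opts[[sample.int(length(opts), 1L)]]
      if (op$type == "inversion") {
        g <- .seq_invert(g, op$c1, op$c2)
        log[[length(log) + 1L]] <- list(family = op$family,
                                        type = "inversion")
        moves_left <- moves_left - 1L
      } else {
        g <- .seq_translocate(g, op$f1_copies, op$f2_copies)
        log[[length(log) + 1L]] <- list(family = op$f1, type = "fission")
        log[[length(log) + 1L]] <- list(family = op$f2, type = "fusion")
        moves_left <- moves_left - 2L
      }
    }
    g$id <- paste0(genome$id, "_shuffled")
    list(genome = g, log = log)
  })
}

# locate copies of each family in the current genome; return eligible moves
.eligible_moves <- function(g, fam_ref, allow_transloc = TRUE) {
  copies <- lapply(fam_ref, function(ref) {
    probe <- circular_genome("probe", ref, "linear")
    seg <- .shared_segments(probe, g,
                            min_len = max(20L, floor(0.9 * nchar(ref))),
                            min_identity = 0.98)
    seg[order(seg$b_start), , drop = FALSE]
  })
  opts <- list()
  direct_fams <- list()
  for (f in names(copies)) {
    cc <- copies[[f]]
    if (nrow(cc) != 2L) next
    if (cc$orientation[1] != cc$orientation[2]) {
      # one forward, one reverse copy: inverted pair -> inversion
      opts[[length(opts) + 1L]] <- list(
        type = "inversion", family = f,
        c1 = c(cc$b_start[1], cc$b_end[1], cc$b_wraps[1]),
        c2 = c(cc$b_start[2], cc$b_end[2], cc$b_wraps[2]))
    } else {
      direct_fams[[f]] <- cc
    }
  }
  if (allow_transloc && length(direct_fams) >= 2L) {
    fs <- names(direct_fams)
    for (i in seq_len(length(fs) - 1L)) for (j in (i + 1L):length(fs)) {
      c1 <- direct_fams[[fs[i]]]; c2 <- direct_fams[[fs[j]]]
      # interleaved: f1 f2 f1 f2 around the circle
      pos <- rbind(data.frame(p = c1$b_start, f = fs[i]),
                   data.frame(p = c2$b_start, f = fs[j]))
      pos <- pos[order(pos$p), ]
      if (all(pos$f == c(fs[i], fs[j], fs[i], fs[j])) ||
          all(pos$f == c(fs[j], fs[i], fs[j], fs[i]))) {
        opts[[length(opts) + 1L]] <- list(
          type = "translocation", f1 = fs[i], f2 = fs[j],
          f1_copies = c1, f2_copies = c2)
      }
    }
  }
  opts
}

# invert the segment between two inverted repeat copies (crossover at the
# copy boundaries; copies preserved exactly)
.seq_invert <- function(g, c1, c2) {
  # order copies along the circle, non-wrapping assumed for planted repeats
  if (c1[1] > c2[1]) { tmp <- c1; c1 <- c2; c2 <- tmp }
  s <- g$seq
  mid <- .sub0(s, c1[2], c2[1])
  newseq <- paste0(.sub0(s, 0L, c1[2]), .revcomp(mid),
                   .sub0(s, c2[1], g$length))
  circular_genome(g$id, newseq, "circular")
}

# fission at direct family f1 then fusion at direct family f2 (interleaved):
# swaps the two segments between alternating copies
.seq_translocate <- function(g, c1, c2) {
  s <- g$seq; L <- g$length
  # circle: [f1#1) A [f2#1) B [f1#2) C [f2#2) D  (starts sorted)
  starts <- c(f1a = c1$b_start[1], f2a = c2$b_start[1],
              f1b = c1$b_start[2], f2b = c2$b_start[2])
  o <- order(starts)
  # rotate so that the first element is an f1 copy
  nm <- names(starts)[o]
  while (!startsWith(nm[1], "f1")) { o <- c(o[-1], o[1]); nm <- names(starts)[o] }
  p <- starts[o]
  seg <- function(from, to) .sub0_circ(s, from, to, from > to ||
                                         (from == to && FALSE))
  # pieces: P1=[p1,p2) P2=[p2,p3) P3=[p3,p4) P4=[p4,p1)
  P1 <- seg(p[1], p[2]); P2 <- seg(p[2], p[3])
  P3 <- seg(p[3], p[4]); P4 <- seg(p[4], p[1])
  # fission at f1 -> circles (P1 P2) and (P3 P4); fusion at f2 (starts of
  # P2 and P4) -> P1 P4' ... equivalently swap P2 and P4's downstream:
  newseq <- paste0(P1, P4, P3, P2)
  # rotate pieces so lengths conserved (they are: same multiset)
  g2 <- circular_genome(g$id, newseq, "circular")
  stopifnot(g2$length == L)
  g2
}

#' Linearize a circular genome with a duplicated terminal overlap
#'
#' Inverse of [circularize_by_terminal_overlap()]: cut at `cut` and append
#' the first `overlap` bp again, producing a contig of
#' `length + overlap` bp whose circularization recovers a rotation of the
#' genome.
#'
#' @param genome circular [circular_genome()].
#' @param cut 0-based cut position.
#' @param overlap bp duplicated at the end; must be `< length`.
#' @return linear `CircularGenome`.
#' @export
fragment_with_overlap <- function(genome, cut = 0L, overlap) {
  stopifnot(genome$topology == "circular")
  if (overlap >= genome$length) stop("overlap must be smaller than the genome")
  r <- rotate(genome, cut)
  circular_genome(paste0(genome$id, "_contig"),
                  paste0(r$seq, substr(r$seq, 1L, overlap)), "linear")
}

#' Split a circle into two subgenomic circles at a direct repeat pair
#'
#' Inverse of [merge_circles_by_repeat()]: recombination between two direct
#' copies of `family` splits the circle into two, each retaining one full
#' copy; lengths sum to the original.
#'
#' @param genome circular [circular_genome()].
#' @param truth truth record carrying the repeat table.
#' @param family family name with two direct copies.
#' @return list of two circular `CircularGenome`s.
#' @export
split_by_direct_repeat <- function(genome, truth, family) {
  rt <- truth$repeats
  rows <- rt[rt$family == family & rt$orientation != "nested", ,
             drop = FALSE]
  if (nrow(rows) != 2L) stop("family '", family, "' does not have 2 copies")
  if (any(rows$sign == "-")) {
    stop("family '", family, "' is inverted; fission needs direct copies")
  }
  rows <- rows[order(rows$start), ]
  s <- genome$seq
  c1 <- .sub0(s, rows$start[1], rows$start[2])
  c2 <- paste0(.sub0(s, rows$start[2], genome$length),
               .sub0(s, 0L, rows$start[1]))
  list(circular_genome(paste0(genome$id, "_sub1"), c1, "circular"),
       circular_genome(paste0(genome$id, "_sub2"), c2, "circular"))
}

#' Simulate per-site base-count pileups with planted editing
#'
#' Every CDS position gets a pileup column at the given depth; the edited
#' base count at planted sites is Binomial(depth, extent) (edited reads show
#' `T` at a `+`-strand site, `A` at a `-`-strand site, on the reference
#' forward strand); a uniform error rate scatters remaining reads.
#'
#' @param genome annotated [circular_genome()].
#' @param truth_editing editing truth table (`position`, `strand`,
#'   `extent`).
#' @param depth read depth per position.
#' @param seed RNG seed.
#' @param error_rate per-base error (default 0.002).
#' @param extra_positions additional 0-based positions to report (e.g. an
#'   rRNA m1A position).
#' @param extra_t_fraction optional named numeric: for an extra position
#'   (name = 0-based position), the fraction of reads reported as `T`
#'   (models m1A-driven misincorporation).
#' @return pileup data.frame as from [read_pileup_tsv()].
#' @export
simulate_pileups <- function(genome, truth_editing = NULL, depth = 100L,
                             seed = 1L, error_rate = 0.002,
                             extra_positions = integer(0),
                             extra_t_fraction = NULL) {
  cds <- genome$annotations
  cds <- cds[cds$feature_type == "CDS", , drop = FALSE]
  pos <- integer(0)
  L <- genome$length
  if (nrow(cds) > 0L) {
    for (r in seq_len(nrow(cds))) {
      ln <- .interval_len(cds$start[r], cds$end[r], cds$wraps[r], L)
      pos <- c(pos, (cds$start[r] + seq_len(ln) - 1L) %% L)
    }
  }
  pos <- sort(unique(c(pos, as.integer(extra_positions))))
  ref <- substring(genome$seq, pos + 1L, pos + 1L)
  n <- length(pos)
  ext <- numeric(n); edited_base <- rep(NA_character_, n)
  if (!is.null(truth_editing) && nrow(truth_editing) > 0L) {
    m <- match(truth_editing$position, pos)
    ok <- !is.na(m)
    ext[m[ok]] <- truth_editing$extent[ok]
    edited_base[m[ok]] <- ifelse(truth_editing$strand[ok] == "+", "T", "A")
  }
  if (!is.null(extra_t_fraction)) {
    m <- match(as.integer(names(extra_t_fraction)), pos)
    ok <- !is.na(m)
    ext[m[ok]] <- unname(extra_t_fraction)[ok]
    edited_base[m[ok]] <- "T"
  }
  .with_seed(seed, {
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    nedit <- ifelse(ext > 0, stats::rbinom(n, depth, ext), 0L)
    nref <- depth - nedit
    for (i in seq_len(n)) {
      counts[i, ref[i]] <- nref[i]
      if (nedit[i] > 0L) {
        counts[i, edited_base[i]] <- counts[i, edited_base[i]] + nedit[i]
      }
      if (error_rate > 0) {
        nerr <- stats::rbinom(1L, nref[i], error_rate)
        if (nerr > 0L) {
          others <- setdiff(c("A", "C", "G", "T"), ref[i])
          err <- stats::rmultinom(1L, nerr, rep(1 / 3, 3L))[, 1]
          counts[i, ref[i]] <- counts[i, ref[i]] - nerr
          counts[i, others] <- counts[i, others] + err
        }
      }
    }
    data.frame(seq_id = genome$id, pos = pos + 1L, ref_base = ref,
               count_A = counts[, "A"], count_C = counts[, "C"],
               count_G = counts[, "G"], count_T = counts[, "T"],
               position = pos,
               depth = depth)
  })
}

#' Generate a simple synthetic plastid genome with gene annotations
#'
#' @param length genome length (default 30 kb reduced-scale plastome).
#' @param genes list of `list(name, length, strand)`.
#' @param ir optional `list(length)`: plant a large inverted repeat pair.
#' @param gc background GC.
#' @param seed RNG seed.
#' @param id genome id.
#' @return annotated circular `CircularGenome`.
#' @export
generate_plastome <- function(length = 30000L, genes = list(), ir = NULL,
                              gc = 0.38, seed = 1L, id = "synthetic_cp") {
  spec <- genome_spec(length, gc = gc,
                      repeat_specs = if (!is.null(ir))
                        list(list(length = ir$length, orientation = "inverted",
                                  copies = 2L, family = "IR")) else list(),
                      gene_specs = lapply(genes, function(g) {
                        c(g, list(type = g$type %||% "gene"))
                      }),
                      seed = seed)
  gen <- generate_mitogenome(spec, id = id)
  g <- gen$genome
  tg <- gen$truth$genes
  if (!is.null(tg) && nrow(tg) > 0L) {
    g$annotations <- annotation_table(feature_type = tg$type,
                                      start = tg$start, end = tg$end,
                                      strand = tg$strand, name = tg$name)
  }
  g
}

#' Write a truth record as JSON
#' @param truth truth record from [generate_mitogenome()].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
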