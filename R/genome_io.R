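#' Circular genome data model and file formats
#'
#' A `CircularGenome` is a plain list with class `"CircularGenome"` holding a
#' DNA sequence (uppercase, alphabet `A`, `C`, `G`, `T`, `N`), a topology
#' (`"circular"` or `"linear"`), and an annotation table.  All coordinates are
#' 0-based half-open internally; 1-based coordinates appear only at file
#' boundaries (GFF3, pileup TSV) and in user-facing reports.  Features that
#' span the origin of a circular molecule are stored with `start > end` and
#' `wraps = TRUE`, and are resolved modulo the genome length.
#'
#' @param id character scalar identifier.
#' @param seq DNA sequence as a single uppercase string.
#' @param topology `"circular"` or `"linear"`.
#' @param annotations an annotation table as returned by [annotation_table()].
#' @return an object of class `CircularGenome` with fields `id`, `seq`,
#'   `topology`, `length` and `annotations`.
#' @examples
#' g <- circular_genome("g1", "ACGT")
#' genome_length(g)
#' @export
circular_genome <- function(id, seq, topology = c("circular", "linear"),
                            annotations = annotation_table()) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for genome '", id, "'")
  bad <- .first_bad_residue(seq)
  if (!is.null(bad)) {
    stop("invalid residue '", substr(seq, bad, bad), "' at position ", bad,
         " in genome '", id, "'")
  }
  g <- structure(list(id = id, seq = seq, topology = topology,
                      length = nchar(seq), annotations = annotations),
                 class = "CircularGenome")
  .validate_annotations(g)
  g
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome '%s': %s, %d bp, %d annotation(s)\n",
              x$id, x$topology, x$length, nrow(x$annotations)))
  invisible(x)
}

#' @rdname circular_genome
#' @param x a `CircularGenome`.
#' @export
genome_length <- function(x) x$length

#' Build an annotation table
#'
#' Columns: `feature_type` (gene, CDS, rRNA, tRNA, orf, cp_insert, repeat,
#' dpo, rpo), `start`/`end` (0-based half-open), `wraps` (origin-spanning
#' flag), `strand` (`+`, `-` or `*`), `name`, and a list column `qualifiers`.
#'
#' @param feature_type,start,end,strand,name vectors of equal length.
#' @param wraps logical; origin-spanning flag (default all `FALSE`).
#' @param qualifiers optional list of named lists, one per feature.
#' @return a `data.frame` with one row per feature.
#' @export
annotation_table <- function(feature_type = character(), start = integer(),
                             end = integer(), strand = character(),
                             name = character(), wraps = NULL,
                             qualifiers = NULL) {
  n <- length(feature_type)
  if (is.null(wraps)) wraps <- rep(FALSE, n)
  if (is.null(qualifiers)) qualifiers <- rep(list(list()), n)
  df <- data.frame(feature_type = as.character(feature_type),
                   start = as.integer(start), end = as.integer(end),
                   wraps = as.logical(wraps), strand = as.character(strand),
                   name = as.character(name), stringsAsFactors = FALSE)
  df$qualifiers <- qualifiers
  df
}

.validate_annotations <- function(g) {
  a <- g$annotations
  if (is.null(a) || nrow(a) == 0L) return(invisible(TRUE))
  L <- g$length
  bad <- a$start < 0L | a$start >= L | a$end < 0L | a$end > L
  if (any(bad)) {
    stop("annotation coordinates out of range [0, ", L, "] for '", g$id,
         "': rows ", paste(which(bad), collapse = ", "))
  }
  if (any(a$wraps) && g$topology != "circular") {
    stop("origin-spanning annotation on a linear genome '", g$id, "'")
  }
  invisible(TRUE)
}

#' Length of an annotation feature in bp
#' @param ann one row of an annotation table.
#' @param L genome length.
#' @export
feature_length <- function(ann, L) {
  .interval_len(ann$start, ann$end, ann$wraps, L)
}

#' Extract the sequence of a feature (strand-aware)
#'
#' @param genome a `CircularGenome`.
#' @param ann one row of the annotation table (or an index into it).
#' @return the feature sequence on its own strand.
#' @export
feature_seq <- function(genome, ann) {
  if (is.numeric(ann)) ann <- genome$annotations[ann, , drop = FALSE]
  s <- .sub0_circ(genome$seq, ann$start, ann$end, ann$wraps)
  if (identical(ann$strand, "-")) s <- .revcomp(s)
  s
}

# remap a 0-based half-open (possibly wrapping) interval after rotation
.rot_interval <- function(start, end, wraps, offset, L) {
  ln <- .interval_len(start, end, wraps, L)
  ns <- (start - offset) %% L
  ne <- ns + ln
  w <- ne > L
  data.frame(start = as.integer(ns),
             end = as.integer(ifelse(w, ne - L, ne)),
             wraps = w)
}

#' Rotate a circular genome to a new origin
#'
#' @param genome a circular `CircularGenome`.
#' @param offset new origin, 0-based; `rotate(g, genome_length(g))` is `g`.
#' @return the rotated genome with annotations remapped.
#' @export
rotate <- function(genome, offset) {
  if (genome$topology != "circular") stop("cannot rotate a linear genome")
  L <- genome$length
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(genome)
  s <- paste0(.sub0(genome$seq, offset, L), .sub0(genome$seq, 0L, offset))
  a <- genome$annotations
  if (nrow(a) > 0L) {
    r <- .rot_interval(a$start, a$end, a$wraps, offset, L)
    a$start <- r$start; a$end <- r$end; a$wraps <- r$wraps
  }
  circular_genome(genome$id, s, "circular", a)
}

#' Reverse-complement a genome, remapping annotations
#'
#' @param genome a `CircularGenome`.
#' @return the reverse-complemented genome; strands are flipped.
#' @export
reverse_complement <- function(genome) {
  L <- genome$length
  a <- genome$annotations
  if (nrow(a) > 0L) {
    ln <- .interval_len(a$start, a$end, a$wraps, L)
    ns <- (L - a$start - ln) %% L
    ne <- ns + ln
    w <- ne > L
    a$start <- as.integer(ns)
    a$end <- as.integer(ifelse(w, ne - L, ne))
    a$wraps <- w
    a$strand <- ifelse(a$strand == "+", "-", ifelse(a$strand == "-", "+", a$strand))
  }
  circular_genome(genome$id, .revcomp(genome$seq), genome$topology, a)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read genomes from a FASTA file
#'
#' Topology is taken from a `topology=circular` / `topology=linear` token in
#' the header, falling back to `default_topology`.
#'
#' @param path FASTA file.
#' @param default_topology used when the header carries no topology token.
#' @return a named list of `CircularGenome` objects.
#' @importFrom Biostrings readBStringSet
#' @export
read_fasta <- function(path, default_topology = "circular") {
  # read as raw strings so invalid residues are reported (with offsets)
  # rather than silently dropped
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  out <- lapply(seq_along(ss), function(i) {
    header <- names(ss)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    topo <- default_topology
    tt <- grep("^topology=", toks, value = TRUE)
    if (length(tt) > 0L) topo <- sub("^topology=", "", tt[1])
    seq <- toupper(as.character(ss[[i]]))
    if (nchar(seq) == 0L) stop("empty FASTA record '", id, "' in ", path)
    bad <- .first_bad_residue(seq)
    if (!is.null(bad)) {
      stop("record '", id, "': invalid residue at offset ", bad)
    }
    circular_genome(id, seq, topo)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write genomes to FASTA (topology recorded in the header)
#'
#' @param genomes a `CircularGenome` or list of them.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "CircularGenome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf(">%s topology=%s", g$id, g$topology), con)
    n <- nchar(g$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3 (1-based inclusive on disk; origin-spanning features are written as
# two parts sharing an ID and re-joined on read)

#' Read a GFF3 file into an annotation table
#'
#' @param path GFF3 file.
#' @param genome the `CircularGenome` the annotations belong to; coordinates
#'   are validated against its length and id.
#' @return annotation table (0-based half-open; origin-spanning two-part
#'   features are merged back into one wrapping row).
#' @export
read_gff3 <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(annotation_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9L)) stop("malformed GFF3 line(s): ", which(nf != 9L)[1])
  m <- do.call(rbind, f)
  seqid <- m[, 1]; type <- m[, 3]
  if (any(seqid != genome$id)) {
    stop("unknown seq_id '", setdiff(seqid, genome$id)[1], "' (expected '",
         genome$id, "')")
  }
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (any(is.na(start1)) || any(is.na(end1)) || any(start1 < 1L) ||
      any(end1 > genome$length) || any(end1 < start1)) {
    stop("GFF3 coordinates out of range for genome of length ", genome$length)
  }
  strand <- m[, 7]
  attrs <- m[, 9]
  getattr <- function(a, key) {
    mm <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(mm) >= 3) mm[3] else NA_character_
  }
  ids <- vapply(attrs, getattr, character(1), key = "ID")
  nm <- vapply(attrs, getattr, character(1), key = "Name")
  nm <- ifelse(is.na(nm), ifelse(is.na(ids), type, ids), nm)
  ann <- annotation_table(feature_type = type, start = start1 - 1L, end = end1,
                          strand = strand, name = nm,
                          qualifiers = lapply(ids, function(i) {
                            if (is.na(i)) list() else list(ID = i)
                          }))
  # re-join origin-spanning two-part features: same ID, one part ending at L,
  # the other starting at 0
  if (genome$topology == "circular" && any(!is.na(ids))) {
    keep <- rep(TRUE, nrow(ann))
    for (uid in unique(ids[!is.na(ids)])) {
      w <- which(!is.na(ids) & ids == uid)
      if (length(w) == 2L) {
        i1 <- w[ann$end[w] == genome$length]
        i2 <- w[ann$start[w] == 0L]
        if (length(i1) == 1L && length(i2) == 1L && i1 != i2) {
          ann$end[i1] <- ann$end[i2]
          ann$wraps[i1] <- TRUE
          keep[i2] <- FALSE
        }
      }
    }
    ann <- ann[keep, , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Write an annotation table as GFF3
#'
#' Origin-spanning rows are emitted as two parts sharing an `ID` attribute.
#'
#' @param genome a `CircularGenome` whose `annotations` are written.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @export
write_gff3 <- function(genome, path, source = "mitoring") {
  a <- genome$annotations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id, genome$length), con)
  if (nrow(a) > 0L) {
    for (i in seq_len(nrow(a))) {
      id <- a$qualifiers[[i]]$ID %||% sprintf("feat%04d", i)
      attr_str <- sprintf("ID=%s;Name=%s", id, a$name[i])
      if (a$wraps[i]) {
        parts <- rbind(c(a$start[i] + 1L, genome$length), c(1L, a$end[i]))
      } else {
        parts <- rbind(c(a$start[i] + 1L, a$end[i]))
      }
      for (p in seq_len(nrow(parts))) {
        writeLines(paste(genome$id, source, a$feature_type[i], parts[p, 1],
                         parts[p, 2], ".", a$strand[i], ".", attr_str,
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED4 (0-based half-open on disk, same as internal)

#' Read a BED4 file
#' @param path BED file.
#' @param genome optional `CircularGenome` for validation.
#' @return data.frame with chrom, start, end, name.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(f, function(x) x[1:4]))
  df <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]),
                   name = ifelse(is.na(m[, 4]), ".", m[, 4]),
                   stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    if (any(df$chrom != genome$id)) stop("unknown seq_id in BED: ", path)
    if (any(df$start < 0L | df$end > genome$length)) {
      stop("BED coordinates out of range for genome of length ", genome$length)
    }
  }
  df
}

#' Write a BED4 file
#' @param df data.frame with chrom, start, end, name.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  writeLines(paste(df$chrom, df$start, df$end, df$name, sep = "\t"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# per-site base-count pileup TSV
# columns: seq_id, pos (1-based), ref_base, count_A, count_C, count_G, count_T

#' Read a per-site base-count pileup TSV
#'
#' File columns are `seq_id`, `pos` (1-based), `ref_base`, `count_A`,
#' `count_C`, `count_G`, `count_T`; counts are read bases reported on the
#' reference forward strand.  The returned table carries an additional
#' 0-based `position` column used internally.
#'
#' @param path TSV file (with header).
#' @param genome optional `CircularGenome`; reference bases are validated.
#' @return data.frame of pileup columns.
#' @importFrom utils read.table write.table
#' @export
read_pileup_tsv <- function(path, genome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("seq_id", "pos", "ref_base", "count_A", "count_C", "count_G",
            "count_T")
  if (!all(need %in% names(df))) {
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$pos) - 1L
  df$depth <- df$count_A + df$count_C + df$count_G + df$count_T
  if (!is.null(genome)) {
    if (any(df$seq_id != genome$id)) stop("unknown seq_id in pileup: ", path)
    if (any(df$position < 0L | df$position >= genome$length)) {
      stop("pileup positions out of range")
    }
    ref <- substring(genome$seq, df$pos, df$pos)
    bad <- which(ref != df$ref_base)
    if (length(bad) > 0L) {
      stop("pileup ref_base mismatches genome at position(s) ",
           paste(utils::head(df$pos[bad], 10), collapse = ", "))
    }
  }
  df
}

#' Write a pileup table to TSV
#' @param df pileup data.frame (as from [read_pileup_tsv()] or
#'   [simulate_pileups()]).
#' @param path output file.
#' @export
write_pileup_tsv <- function(df, path) {
  out <- df[, c("seq_id", "pos", "ref_base", "count_A", "count_C",
                "count_G", "count_T")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in newick format
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
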