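# Coding-sequence divergence: concatenated CDS extraction, pairwise
# alignment (optimal affine-gap, with an anchored mode for long inputs),
# SNP/gap counting, p-distances and neighbor-joining trees.

#' Extract and concatenate coding sequences
#'
#' Genes are concatenated in alphabetical order of `gene_set` (fixed,
#' documented order so the result is deterministic across genomes).
#' Multi-part (trans-spliced) CDSs are joined in annotation order;
#' minus-strand parts are reverse-complemented.
#'
#' @param genome annotated [circular_genome()].
#' @param annotations annotation table; defaults to the genome's own.
#' @param gene_set character vector of gene names; every name must be
#'   annotated as CDS (missing genes are an error, never silently skipped).
#' @return concatenated DNA string.
#' @export
extract_concatenated_cds <- function(genome, annotations = NULL, gene_set) {
  if (is.null(annotations)) annotations <- genome$annotations
  cds <- annotations[annotations$feature_type == "CDS", , drop = FALSE]
  missing <- setdiff(gene_set, cds$name)
  if (length(missing)) {
    stop("gene(s) not annotated as CDS: ", paste(missing, collapse = ", "))
  }
  paste(vapply(sort(gene_set), function(g) {
    parts <- cds[cds$name == g, , drop = FALSE]
    paste(vapply(seq_len(nrow(parts)), function(p) {
      feature_seq(genome, parts[p, , drop = FALSE])
    }, character(1)), collapse = "")
  }, character(1)), collapse = "")
}

#' Optimal global pairwise alignment with affine gaps
#'
#' For inputs up to `anchored_above` bp this is a full dynamic-programming
#' global alignment (scores: `match`, `mismatch`, a gap run of length g
#' costing `gap_open + g * gap_extend`).  Longer inputs switch to anchored
#' mode: shared 31-mers unique in both sequences are chained co-linearly and
#' the segments between anchors are aligned optimally, with the identical
#' contract on each segment.
#'
#' @param a,b DNA strings (or `CircularGenome`s, whose sequence is used).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param anchored_above input length (bp) above which anchored mode is used.
#' @return list (class `PairwiseAlignment`) with `a`, `b` (aligned strings
#'   with `-` gaps), `score`, `params`, `mode`.
#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @export
align_pair <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                       gap_extend = -1, anchored_above = 50000L) {
  if (inherits(a, "CircularGenome")) a <- a$seq
  if (inherits(b, "CircularGenome")) b <- b$seq
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  params <- list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend)
  if (max(nchar(a), nchar(b)) <= anchored_above) {
    al <- .align_full(a, b, params)
    al$mode <- "full"
  } else {
    al <- .align_anchored(a, b, params)
    al$mode <- "anchored"
  }
  class(al) <- "PairwiseAlignment"
  al
}

.align_full <- function(a, b, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa), params = params)
}

.align_anchored <- function(a, b, params, k = 31L) {
  ka <- .kmers(a, k); kb <- .kmers(b, k)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  ia <- which(ua); m <- match(ka[ia], kb)
  keep <- !is.na(m) & ub[pmax(m, 1L)]
  pa <- ia[keep]; pb <- m[keep]
  if (length(pa) == 0L) return(.align_full(a, b, params))
  # chain: longest increasing subsequence of pb along pa order
  o <- order(pa); pa <- pa[o]; pb <- pb[o]
  lis <- .lis_indices(pb)
  pa <- pa[lis]; pb <- pb[lis]
  # drop overlapping anchors
  keep <- c(TRUE, diff(pa) >= k & diff(pb) >= k)
  pa <- pa[keep]; pb <- pb[keep]

  pieces_a <- character(0); pieces_b <- character(0); score <- 0
  prev_a <- 1L; prev_b <- 1L
  emit <- function(sa, sb) {
    if (nchar(sa) == 0L && nchar(sb) == 0L) return(invisible())
    if (nchar(sa) == 0L || nchar(sb) == 0L) {
      g <- max(nchar(sa), nchar(sb))
      pieces_a <<- c(pieces_a, if (nchar(sa)) sa else strrep("-", g))
      pieces_b <<- c(pieces_b, if (nchar(sb)) sb else strrep("-", g))
      score <<- score + params$gap_open + g * params$gap_extend
    } else {
      al <- .align_full(sa, sb, params)
      pieces_a <<- c(pieces_a, al$a); pieces_b <<- c(pieces_b, al$b)
      score <<- score + al$score
    }
  }
  for (t in seq_along(pa)) {
    emit(substr(a, prev_a, pa[t] - 1L), substr(b, prev_b, pb[t] - 1L))
    anchor <- substr(a, pa[t], pa[t] + k - 1L)
    pieces_a <- c(pieces_a, anchor); pieces_b <- c(pieces_b, anchor)
    score <- score + k * params$match
    prev_a <- pa[t] + k; prev_b <- pb[t] + k
  }
  emit(substr(a, prev_a, nchar(a)), substr(b, prev_b, nchar(b)))
  list(a = paste(pieces_a, collapse = ""), b = paste(pieces_b, collapse = ""),
       score = score, params = params)
}

# indices of one longest strictly increasing subsequence
.lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails_idx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    # binary search for first tail >= x[i]
    lo <- 1L; hi <- length(tails_idx)
    pos <- hi + 1L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails_idx[mid]] >= x[i]) { pos <- mid; hi <- mid - 1L }
      else lo <- mid + 1L
    }
    tails_idx[pos] <- i
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
  }
  out <- integer(0)
  cur <- tails_idx[length(tails_idx)]
  while (cur > 0L) { out <- c(cur, out); cur <- prev[cur] }
  out
}

#' Count SNPs and gap events in a pairwise alignment
#'
#' SNPs are columns with two distinct non-gap residues; gaps are maximal
#' runs of gap characters (indel events), each run counted once.  Gap
#' columns are additionally reported for transparency.
#'
#' @param alignment a `PairwiseAlignment` from [align_pair()] (or any list
#'   with aligned strings `a` and `b`).
#' @return list with `snps`, `gaps` (events), `gap_columns`, `length`.
#' @export
count_snps_gaps <- function(alignment) {
  va <- strsplit(alignment$a, "")[[1]]
  vb <- strsplit(alignment$b, "")[[1]]
  if (length(va) != length(vb)) stop("aligned rows differ in length")
  ga <- va == "-"; gb <- vb == "-"
  snps <- sum(!ga & !gb & va != vb)
  runs <- function(g) { r <- rle(g); sum(r$values) }
  list(snps = snps, gaps = runs(ga) + runs(gb),
       gap_columns = sum(ga | gb), length = length(va))
}

#' Count conserved positions in a multiple alignment
#'
#' @param msa character vector of equal-length aligned rows.
#' @return list with `length` (columns) and `conserved` (columns where all
#'   rows share one residue; any gap breaks conservation).
#' @export
conserved_positions <- function(msa) {
  if (length(msa) < 2L) stop("need >= 2 rows")
  ln <- unique(nchar(msa))
  if (length(ln) != 1L) stop("ragged alignment: row lengths ",
                             paste(ln, collapse = ", "))
  m <- do.call(rbind, strsplit(msa, ""))
  cons <- apply(m, 2L, function(col) length(unique(col)) == 1L &&
                  col[1] != "-")
  list(length = ln, conserved = sum(cons))
}

#' Pairwise p-distance matrix
#'
#' For rows of equal length the input is treated as a multiple alignment;
#' otherwise each pair is aligned with [align_pair()].  The p-distance
#' excludes every column containing a gap in either row (keeping SNP
#' semantics consistent with [count_snps_gaps()]).
#'
#' @param seqs named character vector of sequences.
#' @param ... passed to [align_pair()] when alignment is needed.
#' @return symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (n < 2L) stop("need >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_len(n))
  aligned <- length(unique(nchar(seqs))) == 1L
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  pdist <- function(sa, sb) {
    va <- strsplit(sa, "")[[1]]; vb <- strsplit(sb, "")[[1]]
    ok <- va != "-" & vb != "-"
    if (!any(ok)) return(0)
    mean(va[ok] != vb[ok])
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (aligned) {
      d[i, j] <- d[j, i] <- pdist(seqs[i], seqs[j])
    } else {
      al <- align_pair(seqs[[i]], seqs[[j]], ...)
      d[i, j] <- d[j, i] <- pdist(al$a, al$b)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (Q-criterion, standard branch-length formulas).
#' Ties in Q are broken by the smallest taxon-index pair.  Negative branch
#' lengths are clamped to zero with the remainder transferred to the sister
#' edge.  Exact on additive matrices.
#'
#' @param dm symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (is.null(n) || n < 3L) stop("need >= 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  nodes <- as.list(labels)            # newick fragment per active node
  d <- dm
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest-index tie-break: scan column-major over upper triangle
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (q[i, j] < bestq - 1e-12) { bestq <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], li, nodes[[j]], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
    d <- d2
  }
  dab <- d[1, 2]; dac <- d[1, 3]; dbc <- d[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[1]], la, nodes[[2]], lb, nodes[[3]], lc)
  ape::read.tree(text = nwk)
}

#' Pairwise divergence table over a set of genomes
#'
#' Extracts concatenated CDS with [extract_concatenated_cds()], aligns each
#' pair and reports SNPs and gap events.
#'
#' @param genomes named list of annotated [circular_genome()] objects.
#' @param gene_set gene names to concatenate (see
#'   [extract_concatenated_cds()]).
#' @param ... passed to [align_pair()].
#' @return data.frame with `genome_a`, `genome_b`, `snps`, `gaps`,
#'   `gap_columns`, `aln_length`.
#' @export
divergence_table <- function(genomes, gene_set, ...) {
  ids <- names(genomes)
  seqs <- vapply(genomes, extract_concatenated_cds, character(1),
                 gene_set = gene_set)
  out <- list()
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    al <- align_pair(seqs[[i]], seqs[[j]], ...)
    cnt <- count_snps_gaps(al)
    out[[length(out) + 1L]] <- data.frame(
      genome_a = ids[i], genome_b = ids[j], snps = cnt$snps,
      gaps = cnt$gaps, gap_columns = cnt$gap_columns,
      aln_length = cnt$length)
  }
  do.call(rbind, out)
}
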