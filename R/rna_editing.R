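# C-to-U RNA-editing calling from per-site base counts, functional-effect
# annotation, and the m1A misincorporation diagnostic.

#' Call C-to-U RNA editing sites from pileup base counts
#'
#' A site is called when depth >= `min_depth`, the position lies inside a
#' CDS, and the strand-consistent edited-base fraction reaches
#' `min_fraction`: reference `C` with `T` reads for a `+`-strand gene, or
#' reference `G` with `A` reads for a `-`-strand gene (counts are reported
#' on the reference forward strand).  All other variant classes are
#' discarded.  Effects are annotated per overlapping CDS via
#' [annotate_effect()].
#'
#' @param pileups pileup table (see [read_pileup_tsv()]); must carry
#'   `position` (0-based), `ref_base` and the four count columns.
#' @param genome the annotated [circular_genome()].
#' @param cds CDS annotation table (rows with `feature_type == "CDS"` are
#'   used); defaults to the genome's own annotations.
#' @param min_depth minimum read depth (default 10).
#' @param min_fraction minimum edited-read fraction (default 0.1).
#' @return data.frame of editing sites: `position` (0-based), `pos`
#'   (1-based, as reported externally), `gene`, `strand`, `depth`, `extent`,
#'   `codon_position`, `codon`, `codon_edited`, `effect` -- one row per
#'   (site, overlapping CDS) effect record.
#' @export
call_editing_sites <- function(pileups, genome, cds = NULL, min_depth = 10L,
                               min_fraction = 0.1) {
  if (is.null(cds)) cds <- genome$annotations
  cds <- cds[cds$feature_type == "CDS", , drop = FALSE]
  ref <- substring(genome$seq, pileups$position + 1L, pileups$position + 1L)
  bad <- which(ref != pileups$ref_base)
  if (length(bad)) {
    stop("pileup ref_base mismatches the genome at position(s) ",
         paste(utils::head(pileups$position[bad] + 1L, 10L), collapse = ", "))
  }
  depth <- pileups$count_A + pileups$count_C + pileups$count_G +
    pileups$count_T
  out <- list()
  for (i in seq_len(nrow(pileups))) {
    if (depth[i] < min_depth) next
    pos <- pileups$position[i]
    covering <- .cds_covering(cds, pos, genome$length)
    if (nrow(covering) == 0L) next
    for (ci in seq_len(nrow(covering))) {
      cdsrow <- covering[ci, , drop = FALSE]
      strand <- cdsrow$strand
      if (strand == "+" && pileups$ref_base[i] == "C") {
        extent <- pileups$count_T[i] / depth[i]
      } else if (strand == "-" && pileups$ref_base[i] == "G") {
        extent <- pileups$count_A[i] / depth[i]
      } else next
      if (extent < min_fraction) next
      eff <- annotate_effect_one(genome, cdsrow, pos)
      out[[length(out) + 1L]] <- data.frame(
        position = pos, pos = pos + 1L, gene = cdsrow$name,
        strand = strand, depth = depth[i], extent = extent,
        codon_position = eff$codon_position, codon = eff$codon,
        codon_edited = eff$codon_edited, effect = eff$effect)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), pos = integer(),
                      gene = character(), strand = character(),
                      depth = integer(), extent = numeric(),
                      codon_position = integer(), codon = character(),
                      codon_edited = character(), effect = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$gene), , drop = FALSE]
}

# CDS rows covering a 0-based position (wrap-aware)
.cds_covering <- function(cds, pos, L) {
  if (nrow(cds) == 0L) return(cds)
  hit <- vapply(seq_len(nrow(cds)), function(r) {
    s <- cds$start[r]; e <- cds$end[r]
    if (cds$wraps[r]) pos >= s || pos < e else pos >= s && pos < e
  }, logical(1))
  cds[hit, , drop = FALSE]
}

#' Annotate the functional effect of a C-to-U editing site
#'
#' The codon containing the site is edited in silico (C->T on the coding
#' strand) and translated with the standard genetic code.  `ACG -> ATG` in
#' the first codon is a `start_gain`; codons turning into stops are
#' `stop_gain`; stops turning into sense codons are `stop_loss`; synonymous
#' changes are `silent`, others `missense`.  A site inside several
#' overlapping CDSs yields one effect record per frame
#' (use [call_editing_sites()] for the multi-record form).
#'
#' @param genome annotated [circular_genome()].
#' @param cdsrow one CDS annotation row covering the site.
#' @param position 0-based genome position of the edited base.
#' @return list with `codon_position` (1|2|3), `codon`, `codon_edited`,
#'   `effect`.
#' @export
annotate_effect_one <- function(genome, cdsrow, position) {
  L <- genome$length
  s <- cdsrow$start
  # offset of the position within the CDS, along the coding strand
  off_fwd <- (position - s) %% L
  len <- .interval_len(cdsrow$start, cdsrow$end, cdsrow$wraps, L)
  if (off_fwd >= len) stop("position ", position + 1L,
                           " outside CDS '", cdsrow$name, "'")
  cds_seq <- feature_seq(genome, cdsrow)
  off <- if (cdsrow$strand == "-") len - 1L - off_fwd else off_fwd
  codon_idx <- off %/% 3L
  codon_pos <- off %% 3L + 1L
  codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  if (nchar(codon) < 3L) {
    return(list(codon_position = codon_pos, codon = codon,
                codon_edited = codon, effect = "other"))
  }
  edited <- codon
  substr(edited, codon_pos, codon_pos) <- "T"
  aa_ref <- .translate_codon(codon)
  aa_ed <- .translate_codon(edited)
  effect <-
    if (codon_idx == 0L && codon == "ACG" && edited == "ATG") "start_gain"
    else if (aa_ref != "*" && aa_ed == "*") "stop_gain"
    else if (aa_ref == "*" && aa_ed != "*") "stop_loss"
    else if (aa_ref == aa_ed) "silent"
    else if (is.na(aa_ref) || is.na(aa_ed)) "other"
    else "missense"
  list(codon_position = codon_pos, codon = codon, codon_edited = edited,
       effect = effect)
}

#' @importFrom Biostrings GENETIC_CODE
.translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate the effects of an editing site across all covering CDSs
#'
#' @param genome annotated [circular_genome()].
#' @param position 0-based genome position.
#' @param cds CDS annotation table; defaults to the genome's annotations.
#' @return data.frame with one row per covering CDS (gene, strand,
#'   codon_position, codon, codon_edited, effect); errors when the site is
#'   outside every CDS.
#' @export
annotate_effect <- function(genome, position, cds = NULL) {
  if (is.null(cds)) cds <- genome$annotations
  cds <- cds[cds$feature_type == "CDS", , drop = FALSE]
  covering <- .cds_covering(cds, position, genome$length)
  if (nrow(covering) == 0L) {
    stop("position ", position + 1L, " lies outside every CDS")
  }
  do.call(rbind, lapply(seq_len(nrow(covering)), function(ci) {
    eff <- annotate_effect_one(genome, covering[ci, , drop = FALSE], position)
    data.frame(gene = covering$name[ci], strand = covering$strand[ci],
               codon_position = eff$codon_position, codon = eff$codon,
               codon_edited = eff$codon_edited, effect = eff$effect)
  }))
}

#' T-misincorporation fraction at a position (m1A diagnostic)
#'
#' Reverse transcriptase misincorporates a T opposite 1-methyladenosine, so
#' a genomic A showing a T in an intermediate fraction of RNA-seq reads is
#' diagnostic of m1A.  Returns the T fraction and flags a candidate when the
#' reference base is A and the fraction falls in `[0.3, 0.7]`.
#'
#' @param pileups pileup table.
#' @param position 0-based genome position.
#' @return list with `fraction`, `flagged`, `depth`, `ref_base`.
#' @export
misincorporation_fraction <- function(pileups, position) {
  row <- pileups[pileups$position == position, , drop = FALSE]
  if (nrow(row) == 0L) stop("no pileup column at position ", position + 1L)
  row <- row[1, ]
  depth <- row$count_A + row$count_C + row$count_G + row$count_T
  if (depth == 0L) stop("zero depth at position ", position + 1L)
  frac <- row$count_T / depth
  list(fraction = frac,
       flagged = row$ref_base == "A" && frac >= 0.3 && frac <= 0.7,
       depth = depth, ref_base = row$ref_base)
}
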