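# Codon-aware effect annotation: reproduce the amino-acid chain of each
# variant from the genome sequences and the gene annotation.

#' Locate the feature containing a position
#'
#' @param position 1-based genomic position.
#' @param annotation Feature table (locus, start, end, strand, kind).
#' @return The feature row as a list, or `NULL` for non-genic positions.
#' @export
locate_feature <- function(position, annotation) {
  hit <- annotation[annotation$start <= position & position <= annotation$end, ,
                    drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  if (nrow(hit) > 1L) {
    .stop_sarg(sprintf("position %d lies in %d overlapping features",
                       position, nrow(hit)), "sargtype_ambiguity_error")
  }
  as.list(hit[1L, ])
}

# Extract, for one form, the codon containing `position` on the coding strand.
.codon_at <- function(seq, position, feature) {
  if (feature$strand == "+") {
    offset <- (position - feature$start) %% 3L
    iv <- c(position - offset, position - offset + 2L)
  } else {
    offset <- (feature$end - position) %% 3L
    iv <- c(position + offset - 2L, position + offset)
  }
  if (iv[1L] < feature$start || iv[2L] > feature$end) {
    .stop_sarg(sprintf("codon of position %d extends past the boundary of '%s'",
                       position, feature$locus), "sargtype_annotation_error")
  }
  codon <- substr(seq, iv[1L], iv[2L])
  if (feature$strand == "-") codon <- .revcomp(codon)
  list(codon = codon, offset = offset,
       index = if (feature$strand == "+") (iv[1L] - feature$start) %/% 3L + 1L
               else (feature$end - iv[2L]) %/% 3L + 1L)
}

#' Annotate variant effects
#'
#' For every variant position, determines its locus, codon context and
#' amino-acid chain across the three forms (fluitans III, natans I,
#' natans VIII; one chain entry per run of equal alleles), and classifies the
#' effect. Minus-strand genes are translated after complementation; rRNA,
#' tRNA and intergenic sites are reported with chain `"-"`.
#'
#' @param positions Vector of 1-based genomic positions.
#' @param genomes Named character vector with the three form sequences.
#' @param annotation Feature table.
#' @return Data frame with one row per position: `position`, `locus`, the
#'   three alleles, `codon_index`, `codon_offset`, per-form amino acids,
#'   `aa_chain`, `effect_class`.
#' @export
annotate_effects <- function(positions, genomes, annotation) {
  stopifnot(all(.FORMS %in% names(genomes)))
  rows <- lapply(positions, function(p) {
    alleles <- vapply(.FORMS, function(f) substr(genomes[[f]], p, p), character(1))
    feat <- locate_feature(p, annotation)
    if (is.null(feat) || feat$kind != "CDS") {
      cls <- if (is.null(feat)) "intergenic" else feat$kind
      return(data.frame(position = p,
                        locus = if (is.null(feat)) "Intergenic" else feat$locus,
                        nt_fluitans = alleles[[1L]], nt_natansI = alleles[[2L]],
                        nt_natansVIII = alleles[[3L]],
                        codon_index = NA_integer_, codon_offset = NA_integer_,
                        aa_fluitans_III = NA_character_,
                        aa_natans_I = NA_character_,
                        aa_natans_VIII = NA_character_,
                        aa_chain = "-", effect_class = cls,
                        stringsAsFactors = FALSE))
    }
    cods <- lapply(.FORMS, function(f) .codon_at(genomes[[f]], p, feat))
    aas <- vapply(cods, function(cd) .translate3(cd$codon), character(1))
    chain <- .chain_string(unname(alleles), aas)
    aa_set <- unique(aas)
    cls <- if (length(aa_set) == 1L) "synonymous"
           else if ("Stop" %in% aa_set) "nonsense"
           else "nonsynonymous"
    data.frame(position = p, locus = feat$locus,
               nt_fluitans = alleles[[1L]], nt_natansI = alleles[[2L]],
               nt_natansVIII = alleles[[3L]],
               codon_index = cods[[1L]]$index, codon_offset = cods[[1L]]$offset,
               aa_fluitans_III = aas[1L], aa_natans_I = aas[2L],
               aa_natans_VIII = aas[3L],
               aa_chain = chain, effect_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize amino-acid-level differences for a pair of forms
#'
#' @param annotations An [annotate_effects()] result.
#' @param pair Character vector of two form names.
#' @return List with `genes` (CDS loci whose amino acids differ between the
#'   pair), `n_genes`, and `rrna` (named counts of rRNA nucleotide
#'   differences for the pair).
#' @export
effect_summary <- function(annotations, pair) {
  .check_form(pair)
  stopifnot(length(pair) == 2L)
  aa_col <- c(fluitans_III = "aa_fluitans_III", natans_I = "aa_natans_I",
              natans_VIII = "aa_natans_VIII")
  nt_col <- c(fluitans_III = "nt_fluitans", natans_I = "nt_natansI",
              natans_VIII = "nt_natansVIII")
  a_aa <- annotations[[aa_col[[pair[1L]]]]]
  b_aa <- annotations[[aa_col[[pair[2L]]]]]
  cds <- !is.na(a_aa)
  diff_aa <- cds & a_aa != b_aa
  genes <- unique(annotations$locus[diff_aa])
  rrna <- annotations$effect_class == "rRNA" &
    annotations[[nt_col[[pair[1L]]]]] != annotations[[nt_col[[pair[2L]]]]]
  rrna_counts <- table(annotations$locus[rrna])
  list(genes = genes, n_genes = length(genes),
       rrna = stats::setNames(as.integer(rrna_counts), names(rrna_counts)))
}
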