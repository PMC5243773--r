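# Codon-constraint solving: find a strand, in-codon offset and codon context
# under which a variant site's per-form alleles translate to the amino-acid
# chain printed for that site.

# Expand an amino-acid chain ("Pro > Ser", "Gly > Asp > Gly", ...) to one
# amino acid per form. Chain entries correspond to runs of equal alleles in
# form order (fluitans III, natans I, natans VIII), so a synonymous change
# still prints two entries ("Ala > Ala") while a shared allele collapses
# ("Pro > Ser" for alleles C,C,T).
.expand_chain <- function(alleles, aa_chain) {
  runs <- rle(alleles)
  parts <- strsplit(aa_chain, " > ", fixed = TRUE)[[1]]
  if (length(parts) != length(runs$values)) {
    .stop_sarg(sprintf(
      "amino-acid chain '%s' has %d entries but alleles %s form %d runs",
      aa_chain, length(parts), paste(alleles, collapse = ","), length(runs$values)),
      "sargtype_validation_error")
  }
  rep(parts, runs$lengths)
}

# Collapse per-form amino acids back into the printed chain notation.
.chain_string <- function(alleles, aas) {
  runs <- rle(alleles)
  idx <- cumsum(runs$lengths) - runs$lengths + 1L
  paste(aas[idx], collapse = " > ")
}

.substituted_translations <- function(codon, offset, adj_alleles) {
  vapply(adj_alleles, function(a) {
    cf <- codon
    substr(cf, offset + 1L, offset + 1L) <- a
    .translate3(cf)
  }, character(1), USE.NAMES = FALSE)
}

#' Solve a single codon constraint
#'
#' Finds a coding strand, in-codon offset and base codon such that, reading
#' the coding strand, the codon containing the variant site translates to
#' each form's amino acid when that form's (strand-adjusted) allele is
#' substituted at the offset. The search is deterministic: plus strand first,
#' offsets ascending, codons in lexicographic order; the returned codon
#' carries the fluitans III allele at the offset.
#'
#' @param position Genomic position (1-based), used only for error reporting.
#' @param alleles Character vector of the three plus-strand alleles in form
#'   order (fluitans III, natans I, natans VIII).
#' @param aa_chain Amino-acid chain string, e.g. `"Pro > Ser"`.
#' @return A list with elements `strand` (`"+"` or `"-"`), `offset`
#'   (0, 1 or 2, on the coding strand) and `codon` (3-nt coding-strand codon).
#' @export
solve_codon_constraint <- function(position, alleles, aa_chain) {
  stopifnot(length(alleles) == 3L)
  aas <- .expand_chain(alleles, aa_chain)
  for (strand in c("+", "-")) {
    adj <- if (strand == "-") .complement(alleles) else alleles
    for (offset in 0:2) {
      for (codon in .CODONS) {
        if (substr(codon, offset + 1L, offset + 1L) != adj[1L]) next
        if (identical(.substituted_translations(codon, offset, adj), aas)) {
          return(list(strand = strand, offset = offset, codon = codon,
                      position = position))
        }
      }
    }
  }
  .stop_sarg(sprintf(
    "no (strand, offset, codon) realizes chain '%s' for alleles %s at position %d",
    aa_chain, paste(alleles, collapse = ","), position),
    "sargtype_infeasibility_error")
}

# Find the first codon satisfying one site at a *fixed* strand/offset, or NULL.
.solve_site_at <- function(adj_alleles, offset, aas) {
  for (codon in .CODONS) {
    if (substr(codon, offset + 1L, offset + 1L) != adj_alleles[1L]) next
    if (identical(.substituted_translations(codon, offset, adj_alleles), aas)) {
      return(codon)
    }
  }
  NULL
}

# Jointly solve all sites of one gene: a single strand and frame residue r
# must satisfy every site. On the plus strand r is the start position mod 3
# (offset_i = (pos_i - r) mod 3); on the minus strand r is the end position
# mod 3 (offset_i = (r - pos_i) mod 3). Search order: plus strand first,
# r ascending.
.solve_gene <- function(locus, positions, allele_mat, aa_chains) {
  aas <- lapply(seq_along(positions), function(i) {
    .expand_chain(allele_mat[i, ], aa_chains[i])
  })
  for (strand in c("+", "-")) {
    for (r in 0:2) {
      offsets <- if (strand == "+") (positions - r) %% 3L else (r - positions) %% 3L
      codons <- character(length(positions))
      ok <- TRUE
      for (i in seq_along(positions)) {
        adj <- if (strand == "-") .complement(allele_mat[i, ]) else allele_mat[i, ]
        codon <- .solve_site_at(adj, offsets[i], aas[[i]])
        if (is.null(codon)) { ok <- FALSE; break }
        codons[i] <- codon
      }
      if (ok) {
        return(list(locus = locus, strand = strand, r = r,
                    positions = positions, offsets = offsets, codons = codons,
                    aas = aas))
      }
    }
  }
  .stop_sarg(sprintf(
    "no single reading frame satisfies all %d variant site(s) of gene '%s'",
    length(positions), locus),
    "sargtype_infeasibility_error")
}
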