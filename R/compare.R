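# Whole-genome comparison of collinear sequences: variant scanning, pairwise
# difference counts, per-locus summaries, fixed-site verification and gene
# synteny.

.check_collinear <- function(lens) {
  if (length(unique(lens)) != 1L) {
    .stop_sarg("sequences have unequal lengths; inputs must be collinear (no implicit alignment)",
               "sargtype_collinearity_error")
  }
}

#' Scan collinear genomes for variant sites
#'
#' Reports every position at which at least two genomes carry distinct non-N
#' nucleotides. Alleles are reported on the plus strand; `N` never creates a
#' difference call.
#'
#' @param genomes Named character vector of two or more equal-length sequences.
#' @param annotation Optional feature table; when supplied, a `locus` column
#'   is added (`"Intergenic"` outside features).
#' @return Data frame with `position` and one allele column per genome,
#'   positions ascending.
#' @export
scan_variants <- function(genomes, annotation = NULL) {
  stopifnot(length(genomes) >= 2L, !is.null(names(genomes)))
  .check_collinear(nchar(genomes))
  mat <- vapply(genomes, .chars, character(nchar(genomes[[1L]])))
  is_var <- apply(mat, 1L, function(col) {
    a <- unique(col[col != "N"])
    length(a) >= 2L
  })
  pos <- which(is_var)
  out <- data.frame(position = pos, stringsAsFactors = FALSE)
  for (id in names(genomes)) out[[id]] <- mat[pos, id]
  if (!is.null(annotation)) {
    out$locus <- vapply(pos, function(p) {
      f <- locate_feature(p, annotation)
      if (is.null(f)) "Intergenic" else f$locus
    }, character(1))
  }
  out
}

#' Count nucleotide differences between two collinear sequences
#'
#' @param a,b Equal-length nucleotide strings. Columns where either sequence
#'   has `N` are never counted as differences.
#' @return Integer count of differing columns.
#' @export
count_differences <- function(a, b) {
  .check_collinear(c(nchar(a), nchar(b)))
  ca <- .chars(a); cb <- .chars(b)
  sum(ca != cb & ca != "N" & cb != "N")
}

#' Per-locus difference counts for a pair of forms
#'
#' @param variants Variant table (packaged schema or [scan_variants()] output
#'   over the three forms).
#' @param annotation Feature table used to assign loci when the variant table
#'   carries none.
#' @param pair Character vector of two form names.
#' @param loci Optional loci to report (zeros included); default: every locus
#'   with at least one difference for the pair.
#' @return Named integer vector mapping locus to difference count.
#' @export
locus_summary <- function(variants, annotation = NULL, pair, loci = NULL) {
  .check_form(pair)
  stopifnot(length(pair) == 2L)
  a <- .form_allele_col(variants, pair[1L])
  b <- .form_allele_col(variants, pair[2L])
  locus <- if ("locus" %in% names(variants)) {
    variants$locus
  } else if (!is.null(annotation)) {
    vapply(variants$position, function(p) {
      f <- locate_feature(p, annotation)
      if (is.null(f)) "Intergenic" else f$locus
    }, character(1))
  } else {
    .stop_sarg("variant table has no locus column and no annotation was given",
               "sargtype_validation_error")
  }
  diff <- a != b & a != "N" & b != "N"
  counts <- table(factor(locus[diff], levels = unique(locus)))
  counts <- counts[counts > 0L]
  out <- stats::setNames(as.integer(counts), names(counts))
  if (!is.null(loci)) {
    out <- stats::setNames(ifelse(loci %in% names(out), out[loci], 0L), loci)
    storage.mode(out) <- "integer"
  }
  out
}

#' Verify that diagnostic sites are fixed within forms
#'
#' Reads the observed allele of every specimen at each diagnostic position
#' (via its anchored amplicon), groups specimens by their supplied form
#' labels, and checks that each form carries a single non-N allele matching
#' the reference panel.
#'
#' @param cohort A [generate_cohort()] data frame (or one with the same
#'   columns).
#' @param profiles Diagnostic profiles from [derive_diagnostic_profiles()].
#' @return List with `table` (position x form allele summary with status),
#'   `pass` (all sites fixed and matching the panel), and `label_mismatches`
#'   (specimens whose molecular haplotype matches a different form than their
#'   label).
#' @export
verify_fixed_sites <- function(cohort, profiles) {
  if (nrow(cohort) == 0L) {
    .stop_sarg("cohort is empty", "sargtype_validation_error")
  }
  forms <- unique(cohort$true_form)
  if (any(table(cohort$true_form) == 0L)) {
    .stop_sarg("empty form group", "sargtype_validation_error")
  }
  obs <- lapply(seq_len(nrow(cohort)), function(i) {
    amps <- lapply(names(profiles), function(a) cohort[[a]][i])
    names(amps) <- names(profiles)
    .observed_alleles(amps, profiles)
  })
  rows <- list()
  pass <- TRUE
  for (assay in names(profiles)) {
    sites <- profiles[[assay]]$sites
    for (k in seq_len(nrow(sites))) {
      p <- sites$position[k]
      for (form in forms) {
        idx <- which(cohort$true_form == form)
        alleles <- vapply(obs[idx], function(o) o[[assay]][k], character(1))
        seen <- sort(unique(alleles[alleles != "N"]))
        fixed <- length(seen) == 1L
        expected <- sites[[form]][k]
        ok <- fixed && identical(seen, expected)
        if (!ok) pass <- FALSE
        rows[[length(rows) + 1L]] <- data.frame(
          assay = assay, position = p, form = form,
          alleles = paste(seen, collapse = "/"),
          expected = expected,
          status = if (fixed) "fixed" else "polymorphic",
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- type_cohort(cohort, profiles)
  structure(list(table = do.call(rbind, rows), pass = pass,
                 label_mismatches = calls$label_mismatches),
            class = "sarg_fixed_report")
}

#' Compare gene synteny between two annotations
#'
#' Breakpoints are counted over the shared gene set as orientation-aware
#' adjacencies of the first annotation absent from the second (an adjacency
#' `+a,+b` is also present as `-b,-a` on the reverse reading).
#'
#' @param annotA,annotB Feature tables (locus, start, end, strand).
#' @return List with `shared_genes`, `breakpoints`, `order_identical`.
#' @export
compare_synteny <- function(annotA, annotB) {
  if (nrow(annotA) == 0L || nrow(annotB) == 0L) {
    .stop_sarg("annotations must be non-empty", "sargtype_validation_error")
  }
  shared <- intersect(annotA$locus, annotB$locus)
  if (length(shared) == 0L) {
    return(list(shared_genes = 0L, breakpoints = 0L, order_identical = FALSE))
  }
  signed <- function(annot) {
    annot <- annot[annot$locus %in% shared, , drop = FALSE]
    annot <- annot[order(annot$start), , drop = FALSE]
    paste0(ifelse(annot$strand == "-", "-", "+"), annot$locus)
  }
  a <- signed(annotA); b <- signed(annotB)
  adj <- function(x) {
    if (length(x) < 2L) return(character(0))
    paste(x[-length(x)], x[-1L], sep = "|")
  }
  flip <- function(x) {
    sw <- ifelse(substr(x, 1L, 1L) == "+", "-", "+")
    paste0(sw, substring(x, 2L))
  }
  b_adj <- union(adj(b), adj(rev(flip(b))))
  breakpoints <- sum(!(adj(a) %in% b_adj))
  list(shared_genes = length(shared),
       breakpoints = breakpoints,
       order_identical = identical(a, b) && breakpoints == 0L)
}

#' AT content of a sequence
#'
#' @param genome Nucleotide string; `N` is excluded from the denominator.
#' @return Proportion (A+T)/(A+C+G+T).
#' @export
at_content <- function(genome) {
  ch <- .chars(genome)
  n <- sum(ch %in% .BASES)
  if (n == 0L) {
    .stop_sarg("sequence has no unambiguous nucleotides", "sargtype_validation_error")
  }
  sum(ch %in% c("A", "T")) / n
}
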