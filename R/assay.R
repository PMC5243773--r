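# In-silico PCR with the diagnostic primer panel, derivation of diagnostic
# site profiles, and typing of specimens from their amplicons.

#' Find primer binding sites
#'
#' Reports every ungapped match of the oligo on either strand with at most
#' `max_mismatch` mismatches and a perfect 3-base 3' clamp.
#'
#' @param genome Nucleotide string.
#' @param primer Oligo sequence (5'→3').
#' @param max_mismatch Maximum mismatches outside the 3' clamp.
#' @return Data frame `strand`, `start`, `end` (1-based inclusive plus-strand
#'   footprint), `mismatches`, ordered by position.
#' @export
find_primer_sites <- function(genome, primer, max_mismatch = 2L) {
  subject <- Biostrings::DNAString(genome)
  scan_one <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                     max.mismatch = max_mismatch)
    if (length(hits) == 0L) return(NULL)
    st <- BiocGenerics::start(hits); en <- BiocGenerics::end(hits)
    keep <- st >= 1L & en <= nchar(genome)
    st <- st[keep]; en <- en[keep]
    if (length(st) == 0L) return(NULL)
    mm <- vapply(seq_along(st), function(i) {
      w <- .chars(substr(genome, st[i], en[i]))
      sum(w != .chars(pattern))
    }, numeric(1))
    # 3' clamp: for a plus-strand site the primer 3' end is the window end;
    # for a minus-strand site (reverse-complemented pattern) it is the start.
    clamp_ok <- vapply(seq_along(st), function(i) {
      w <- substr(genome, st[i], en[i])
      if (strand == "+") {
        substr(w, nchar(w) - 2L, nchar(w)) == substr(pattern, nchar(pattern) - 2L, nchar(pattern))
      } else {
        substr(w, 1L, 3L) == substr(pattern, 1L, 3L)
      }
    }, logical(1))
    keep <- mm <= max_mismatch & clamp_ok
    if (!any(keep)) return(NULL)
    data.frame(strand = strand, start = st[keep], end = en[keep],
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(primer, "+"), scan_one(.revcomp(primer), "-"))
  if (is.null(out)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = numeric(0)))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico PCR for one primer pair
#'
#' A product is formed by a plus-strand forward site and a downstream
#' minus-strand reverse site within `max_product` bp; exactly one product
#' must form.
#'
#' @param genome Nucleotide string.
#' @param pair One row of a primer panel (`name`, `fwd_seq`, `rev_seq`).
#' @param max_mismatch Mismatch tolerance per primer.
#' @param max_product Maximum product length in bp.
#' @return List with `assay`, `start`, `end` (primer-inclusive product
#'   interval), `fwd_end`, `rev_start` (inner footprint boundaries) and `seq`.
#' @export
insilico_pcr <- function(genome, pair, max_mismatch = 2L, max_product = 2000L) {
  fwd <- find_primer_sites(genome, pair$fwd_seq, max_mismatch)
  rev <- find_primer_sites(genome, pair$rev_seq, max_mismatch)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- rev[rev$strand == "-", , drop = FALSE]
  products <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      if (rev$start[j] > fwd$end[i] &&
          rev$end[j] - fwd$start[i] + 1L <= max_product) {
        products[[length(products) + 1L]] <- c(fwd$start[i], rev$end[j],
                                               fwd$end[i], rev$start[j])
      }
    }
  }
  if (length(products) == 0L) {
    .stop_sarg(sprintf("assay '%s': no amplification", pair$name),
               "sargtype_no_amplification_error")
  }
  if (length(products) > 1L) {
    .stop_sarg(sprintf("assay '%s': %d products formed", pair$name,
                       length(products)), "sargtype_multiple_product_error")
  }
  p <- products[[1L]]
  list(assay = pair$name, start = p[1L], end = p[2L],
       fwd_end = p[3L], rev_start = p[4L],
       seq = substr(genome, p[1L], p[2L]))
}

#' Derive diagnostic site profiles from the three references
#'
#' Runs in-silico PCR per assay on each reference and collects the variant
#' positions falling strictly between the primer footprints, with each
#' form's expected allele.
#'
#' @param references A [build_references()] result (or a list with a
#'   `genomes` element naming the three forms).
#' @param primers Primer panel.
#' @param max_mismatch,max_product Passed to [insilico_pcr()].
#' @return Named list of class `sarg_profiles`, one element per assay:
#'   `assay`, product coordinates, per-form product sequences, and `sites`
#'   (data frame of positions and per-form alleles).
#' @export
derive_diagnostic_profiles <- function(references, primers = sarg_primers(),
                                       max_mismatch = 2L, max_product = 2000L) {
  genomes <- references$genomes
  stopifnot(all(.FORMS %in% names(genomes)))
  variants <- scan_variants(genomes)
  profiles <- list()
  for (j in seq_len(nrow(primers))) {
    pair <- primers[j, ]
    prods <- lapply(.FORMS, function(f) {
      insilico_pcr(genomes[[f]], pair, max_mismatch, max_product)
    })
    names(prods) <- .FORMS
    lens <- vapply(prods, function(p) nchar(p$seq), numeric(1))
    if (length(unique(lens)) != 1L) {
      .stop_sarg(sprintf("assay '%s': product lengths differ across forms",
                         pair$name), "sargtype_collinearity_error")
    }
    p0 <- prods[[1L]]
    inner <- variants$position > p0$fwd_end & variants$position < p0$rev_start
    sites <- variants[inner, c("position", .FORMS), drop = FALSE]
    rownames(sites) <- NULL
    profiles[[pair$name]] <- list(
      assay = pair$name, start = p0$start, end = p0$end,
      fwd_end = p0$fwd_end, rev_start = p0$rev_start,
      products = vapply(prods, function(p) p$seq, character(1)),
      sites = sites)
  }
  structure(profiles, class = "sarg_profiles")
}

# Anchor each amplicon to its assay's reference product and read the observed
# allele at every diagnostic position. Exact-length amplicons anchor
# directly; otherwise the ungapped offset maximizing identity to the closest
# reference product is used. Returns, per assay, a character vector of
# observed alleles (IUPAC ambiguity and out-of-range read as N).
.observed_alleles <- function(amplicons, profiles) {
  out <- list()
  for (assay in names(profiles)) {
    prof <- profiles[[assay]]
    sites <- prof$sites
    seq <- amplicons[[assay]]
    if (is.null(seq) || is.na(seq)) {
      out[[assay]] <- rep("N", nrow(sites))
      next
    }
    ref_len <- prof$end - prof$start + 1L
    fwd_len <- prof$fwd_end - prof$start + 1L
    rev_len <- prof$end - prof$rev_start + 1L
    if (nchar(seq) < max(fwd_len, rev_len)) {
      .stop_sarg(sprintf("assay '%s': amplicon shorter than its primer footprints", assay),
                 "sargtype_input_error")
    }
    if (nchar(seq) == ref_len) {
      d <- 0L
    } else {
      span <- abs(nchar(seq) - ref_len) + 5L
      score <- function(d) {
        max(vapply(prof$products, function(ref) {
          i <- seq_len(min(nchar(seq), nchar(ref) - d))
          i <- i[i + d >= 1L]
          sum(.chars(seq)[i] == .chars(ref)[i + d])
        }, numeric(1)))
      }
      cand <- seq.int(-span, span)
      d <- cand[which.max(vapply(cand, score, numeric(1)))]
    }
    ch <- .chars(seq)
    obs <- vapply(sites$position, function(p) {
      k <- p - prof$start - d + 1L
      if (k < 1L || k > length(ch)) return("N")
      b <- ch[k]
      if (b %in% .BASES) b else "N"
    }, character(1))
    out[[assay]] <- obs
  }
  out
}

#' Type one specimen from its amplicons
#'
#' The observed alleles at all diagnostic positions are compared with each
#' form's expected profile. A confident call requires a single form
#' consistent with every observed non-N site across all supplied assays; a
#' site pattern matching no form yields `unknown`, and assays individually
#' matching different forms yield `conflict`.
#'
#' @param amplicons Named list/vector mapping assay name to amplicon sequence.
#' @param profiles Diagnostic profiles.
#' @return List with `call`, `evidence` (per-site data frame), and the
#'   supporting/conflicting site counts for the called (or best) form.
#' @export
type_specimen <- function(amplicons, profiles) {
  if (length(amplicons) == 0L) {
    .stop_sarg("at least one amplicon is required", "sargtype_input_error")
  }
  obs <- .observed_alleles(as.list(amplicons), profiles)
  evidence <- list()
  per_assay <- list()
  for (assay in names(obs)) {
    sites <- profiles[[assay]]$sites
    o <- obs[[assay]]
    informative <- o != "N"
    matches <- vapply(.FORMS, function(f) {
      all(o[informative] == sites[[f]][informative])
    }, logical(1))
    if (any(informative)) per_assay[[assay]] <- .FORMS[matches]
    evidence[[assay]] <- data.frame(
      assay = assay, position = sites$position, observed = o,
      expected_fluitans_III = sites$fluitans_III,
      expected_natans_I = sites$natans_I,
      expected_natans_VIII = sites$natans_VIII,
      stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, evidence)
  rownames(evidence) <- NULL
  support <- vapply(.FORMS, function(f) {
    exp <- evidence[[paste0("expected_", f)]]
    sum(evidence$observed != "N" & evidence$observed == exp)
  }, integer(1))
  conflicts <- vapply(.FORMS, function(f) {
    exp <- evidence[[paste0("expected_", f)]]
    sum(evidence$observed != "N" & evidence$observed != exp)
  }, integer(1))
  if (length(per_assay) == 0L) {
    call <- "unknown"
  } else {
    joint <- Reduce(intersect, per_assay)
    if (length(joint) == 1L) {
      call <- joint
    } else if (length(joint) > 1L) {
      call <- "unknown"
    } else if (all(vapply(per_assay, length, integer(1)) > 0L)) {
      call <- "conflict"
    } else {
      call <- "unknown"
    }
  }
  best <- if (call %in% .FORMS) call else .FORMS[which.max(support)]
  list(call = call, evidence = evidence,
       n_supporting = unname(support[best]),
       n_conflicting = unname(conflicts[best]))
}

#' Type a cohort of specimens
#'
#' @param cohort A [generate_cohort()] data frame (or any data frame with
#'   `specimen_id`, `true_form` and one amplicon column per assay).
#' @param profiles Diagnostic profiles.
#' @return List of class `sarg_typing`: `calls` (per-specimen data frame),
#'   `summary` (counts per call), `label_mismatches` (confident calls
#'   contradicting the supplied morphological label).
#' @export
type_cohort <- function(cohort, profiles) {
  if (nrow(cohort) == 0L) {
    .stop_sarg("cohort is empty", "sargtype_validation_error")
  }
  calls <- lapply(seq_len(nrow(cohort)), function(i) {
    amps <- lapply(names(profiles), function(a) cohort[[a]][i])
    names(amps) <- names(profiles)
    tc <- type_specimen(amps, profiles)
    data.frame(specimen_id = cohort$specimen_id[i],
               label = cohort$true_form[i],
               call = tc$call,
               n_supporting = tc$n_supporting,
               n_conflicting = tc$n_conflicting,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  lv <- c(.FORMS, "unknown", "conflict")
  summary <- table(factor(calls$call, levels = lv))
  mism <- calls[calls$call %in% .FORMS & calls$call != calls$label, , drop = FALSE]
  rownames(mism) <- NULL
  structure(list(calls = calls,
                 summary = stats::setNames(as.integer(summary), lv),
                 label_mismatches = mism),
            class = "sarg_typing")
}
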