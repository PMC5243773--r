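# Synthetic reference construction: a gene layout satisfying every codon
# constraint of the variant panel, three reference mitogenomes realizing the
# panel exactly, labeled amplicon cohorts, and the toy nuclear/chloroplast
# marker panel.

.PAD_CDS <- 45L
.PAD_RRNA <- 30L
.TRN_HALF <- 35L
.MIN_CODONS <- 40L
.FILLER_SPACING <- 25L

# Nominal genomic windows for the diagnostic primer footprints; fixture
# constants chosen so both amplicons are variant-free in their footprints and
# carry their diagnostic sites strictly between the footprints.
.FP_NOMINAL <- list(
  cox2 = list(fwd_start = 21669L, rev_end = 22075L),
  cox3 = list(fwd_start = 14400L, rev_end = 14817L))

.FILLER_TRN <- paste0("trn", c(
  "A(ugc)", "C(gca)", "D(guc)", "E(uuc)", "F(gaa)", "G(ucc)", "H(gug)",
  "I(gau)", "K(uuu)", "L(uaa)", "M(cau)", "N(guu)", "P(ugg)", "R(ucu)",
  "S(uga)", "T(ugu)", "V(uac)", "Y(gua)"))
.FILLER_ORF <- paste0("orf", c(25, 31, 38, 42, 47, 51, 56, 60, 64, 68, 72,
                               77, 81, 86, 90, 95, 99, 104, 110, 115, 120, 124))

#' Generator configuration
#'
#' Holds the constants of the simulated study system: genome length and AT
#' content of the three collinear mitogenomes, the total gene count, the
#' per-base substitution noise applied to Sanger-style amplicons, and the
#' per-form cohort composition of the validation panel.
#'
#' @param seed Integer seed; every stochastic step derives from it.
#' @param genome_length Mitogenome length in bp.
#' @param at_fraction Target AT fraction of the references.
#' @param gene_count Total number of annotated genes.
#' @param noise_rate Per-base substitution probability for cohort amplicons
#'   (must be below 0.5).
#' @param cohort_sizes Named integer vector, specimens per form.
#' @return An object of class `sarg_config`.
#' @export
generator_config <- function(seed = 4727L,
                             genome_length = 34727L,
                             at_fraction = 0.638,
                             gene_count = 65L,
                             noise_rate = 0,
                             cohort_sizes = c(natans_VIII = 53L, natans_I = 13L,
                                              fluitans_III = 5L)) {
  if (!is.numeric(at_fraction) || at_fraction < 0 || at_fraction > 1) {
    .stop_sarg("at_fraction must lie in [0, 1]", "sargtype_validation_error")
  }
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 0.5) {
    .stop_sarg("noise_rate must lie in [0, 0.5)", "sargtype_validation_error")
  }
  if (any(cohort_sizes < 0) || is.null(names(cohort_sizes))) {
    .stop_sarg("cohort_sizes must be a named vector of non-negative counts",
               "sargtype_validation_error")
  }
  .check_form(names(cohort_sizes))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 at_fraction = at_fraction,
                 gene_count = as.integer(gene_count),
                 noise_rate = noise_rate,
                 cohort_sizes = cohort_sizes),
            class = "sarg_config")
}

# Genomic interval of the codon containing a site, given its coding offset.
.codon_interval <- function(position, offset, strand) {
  if (strand == "+") c(position - offset, position - offset + 2L)
  else c(position + offset - 2L, position + offset)
}

.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# Search for a primer footprint near its nominal window. Validity: inside the
# gene, clear of every variant codon, keeps the nominal inner diagnostic sites
# strictly between the footprints, and forces no stop codon into the gene
# frame through its fixed bases.
.place_footprint <- function(nominal_start, len, fixed_bases, gene,
                             vr_intervals, inner_sites, side) {
  shifts <- c(0L, as.vector(rbind(seq_len(12L), -seq_len(12L))))
  for (d in shifts) {
    s <- nominal_start + d
    e <- s + len - 1L
    if (s < gene$start + 3L || e > gene$end - 3L) next
    if (any(.overlaps(s, e, vr_intervals[, 1L], vr_intervals[, 2L]))) next
    if (length(inner_sites) > 0L) {
      if (side == "fwd" && e >= min(inner_sites)) next
      if (side == "rev" && s <= max(inner_sites)) next
    }
    # full codons of the gene frame lying entirely within the footprint
    if (gene$strand == "+") {
      first <- s + ((gene$start - s) %% 3L)
    } else {
      first <- s + ((gene$end - 2L - s) %% 3L)
    }
    cs <- seq.int(first, e, by = 3L)
    cs <- cs[cs + 2L <= e]
    ok <- TRUE
    for (p in cs) {
      tri <- paste(fixed_bases[(p - s + 1L):(p - s + 3L)], collapse = "")
      if (gene$strand == "-") tri <- .revcomp(tri)
      if (tri %in% .STOPS) { ok <- FALSE; break }
    }
    if (ok) return(c(start = s, end = e))
  }
  .stop_sarg(sprintf("no valid footprint placement near position %d", nominal_start),
             "sargtype_infeasibility_error")
}

#' Lay out gene features consistent with a variant table
#'
#' Derives one feature per distinct locus of the variant table (CDS for
#' protein genes and orfs, rRNA for the ribosomal genes, tRNA for trn loci),
#' solving for each CDS a single strand and reading frame under which every
#' variant site's amino-acid chain is realizable, then fills the remaining
#' space with placeholder trn/orf features up to `gene_count`. Sites whose
#' chain contains `Stop` are pinned to the terminal codon of their gene so no
#' reference carries an internal stop codon. Placement is fully deterministic.
#'
#' @param variants A variant table, see [load_variant_table()].
#' @param config A [generator_config()].
#' @param primers Primer panel whose footprints must be embeddable in their
#'   target genes; defaults to the packaged panel when those genes are present.
#' @return An object of class `sarg_layout` with elements `features`
#'   (data frame: locus, start, end, strand, kind), `genes` (per-CDS codon
#'   solutions), `primer_sites`, `config`.
#' @export
layout_genes <- function(variants, config = generator_config(), primers = NULL) {
  L <- config$genome_length
  if (L < max(variants$position)) {
    .stop_sarg("genome_length is smaller than the largest variant position",
               "sargtype_validation_error")
  }
  forbidden <- variants$position[.is_nongenic(variants$locus)]
  genic <- variants[!.is_nongenic(variants$locus), , drop = FALSE]
  loci <- unique(genic$locus)
  kind_of <- function(locus) {
    if (grepl("rRNA", locus, fixed = TRUE)) "rRNA"
    else if (grepl("^trn", locus)) "tRNA"
    else "CDS"
  }

  if (is.null(primers) && all(names(.FP_NOMINAL) %in% loci)) {
    primers <- sarg_primers()
  }

  # solve codon constraints per CDS gene
  genes <- list()
  for (locus in loci) {
    rows <- genic[genic$locus == locus, , drop = FALSE]
    if (kind_of(locus) != "CDS") next
    sol <- .solve_gene(locus, rows$position,
                       as.matrix(rows[, c("nt_fluitans", "nt_natansI", "nt_natansVIII")]),
                       rows$aa_chain)
    stops <- vapply(sol$aas, function(a) any(a == "Stop"), logical(1))
    if (sum(stops) > 1L) {
      .stop_sarg(sprintf("gene '%s' has more than one stop-bearing site", locus),
                 "sargtype_infeasibility_error")
    }
    sol$stop_site <- if (any(stops)) which(stops) else NA_integer_
    genes[[locus]] <- sol
  }

  # sequential interval placement in positional order
  ord <- order(vapply(loci, function(l) min(genic$position[genic$locus == l]), numeric(1)))
  loci <- loci[ord]
  feats <- list()
  prev_end <- 0L
  for (i in seq_along(loci)) {
    locus <- loci[i]
    kind <- kind_of(locus)
    sites <- genic$position[genic$locus == locus]
    m <- min(sites); M <- max(sites)
    lower <- prev_end + 2L
    before <- forbidden[forbidden < m]
    if (length(before) > 0L) lower <- max(lower, max(before) + 1L)
    upper <- L
    after <- forbidden[forbidden > M]
    if (length(after) > 0L) upper <- min(upper, min(after) - 1L)
    if (i < length(loci)) {
      next_m <- min(genic$position[genic$locus == loci[i + 1L]])
      upper <- min(upper, next_m - 3L)
    }
    if (kind == "tRNA") {
      start <- max(m - .TRN_HALF, lower)
      end <- min(M + .TRN_HALF, upper)
    } else if (kind == "rRNA") {
      start <- max(m - .PAD_RRNA, lower)
      end <- min(M + .PAD_RRNA, upper)
    } else {
      sol <- genes[[locus]]
      pin <- sol$stop_site
      ds <- m - .PAD_CDS
      if (locus %in% names(.FP_NOMINAL)) {
        ds <- min(ds, .FP_NOMINAL[[locus]]$fwd_start - 30L)
      }
      ds <- max(ds, lower)
      if (sol$strand == "+") {
        start <- ds + ((sol$r - ds) %% 3L)
        if (!is.na(pin)) {
          end <- sol$positions[pin] + (2L - sol$offsets[pin])
        } else {
          n <- max(ceiling((M + .PAD_CDS - start + 1L) / 3), .MIN_CODONS)
          end <- start + 3L * n - 1L
          while (end > upper) end <- end - 3L
        }
      } else {
        if (!is.na(pin)) {
          start <- sol$positions[pin] - (2L - sol$offsets[pin])
          if (start < lower) {
            .stop_sarg(sprintf("pinned start of gene '%s' collides with neighbours", locus),
                       "sargtype_infeasibility_error")
          }
        } else {
          t <- (sol$r + 1L) %% 3L
          start <- ds + ((t - ds) %% 3L)
        }
        n <- max(ceiling((M + .PAD_CDS - start + 1L) / 3), .MIN_CODONS)
        end <- start + 3L * n - 1L
        while (end > upper) end <- end - 3L
      }
      if ((end - start + 1L) %% 3L != 0L) {
        .stop_sarg(sprintf("gene '%s' length not divisible by 3", locus),
                   "sargtype_infeasibility_error")
      }
      genes[[locus]]$start <- start
      genes[[locus]]$end <- end
      # every site's codon must lie inside the gene, and a pinned stop codon
      # must be the terminal codon
      for (k in seq_along(sol$positions)) {
        ci <- .codon_interval(sol$positions[k], sol$offsets[k], sol$strand)
        if (ci[1L] < start || ci[2L] > end) {
          .stop_sarg(sprintf("variant codon at %d falls outside gene '%s'",
                             sol$positions[k], locus), "sargtype_infeasibility_error")
        }
      }
    }
    if (start < lower || end > upper || end < M || start > m) {
      .stop_sarg(sprintf("cannot place feature '%s' between its neighbours", locus),
                 "sargtype_infeasibility_error")
    }
    strand <- if (kind == "CDS") genes[[locus]]$strand else "+"
    feats[[locus]] <- data.frame(locus = locus, start = start, end = end,
                                 strand = strand, kind = kind,
                                 stringsAsFactors = FALSE)
    prev_end <- end
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  # primer footprints
  primer_sites <- NULL
  if (!is.null(primers)) {
    vr_intervals <- do.call(rbind, lapply(genes[!vapply(genes, is.null, logical(1))],
      function(sol) {
        t(vapply(seq_along(sol$positions), function(k) {
          .codon_interval(sol$positions[k], sol$offsets[k], sol$strand)
        }, numeric(2)))
      }))
    ps <- list()
    for (j in seq_len(nrow(primers))) {
      assay <- primers$name[j]
      gene_locus <- primers$gene[j]
      if (!gene_locus %in% names(genes) || !gene_locus %in% names(.FP_NOMINAL)) {
        .stop_sarg(sprintf("no layout anchor for assay '%s'", assay),
                   "sargtype_infeasibility_error")
      }
      gene <- genes[[gene_locus]]
      nom <- .FP_NOMINAL[[gene_locus]]
      fwd <- .chars(primers$fwd_seq[j])
      rev_plus <- .chars(.revcomp(primers$rev_seq[j]))
      inner <- genic$position[genic$locus == gene_locus &
                              genic$position > nom$fwd_start + length(fwd) - 1L &
                              genic$position < nom$rev_end - length(rev_plus) + 1L]
      f <- .place_footprint(nom$fwd_start, length(fwd), fwd, gene,
                            vr_intervals, inner, "fwd")
      r <- .place_footprint(nom$rev_end - length(rev_plus) + 1L, length(rev_plus),
                            rev_plus, gene, vr_intervals, inner, "rev")
      ps[[assay]] <- data.frame(
        assay = assay, role = c("fwd", "rev"),
        start = c(f[["start"]], r[["start"]]), end = c(f[["end"]], r[["end"]]),
        bases = c(primers$fwd_seq[j], .revcomp(primers$rev_seq[j])),
        stringsAsFactors = FALSE)
    }
    primer_sites <- do.call(rbind, ps)
    rownames(primer_sites) <- NULL
  }

  # placeholder features filling the gene complement
  n_fill <- config$gene_count - nrow(features)
  if (n_fill < 0L) {
    .stop_sarg("gene_count is smaller than the number of loci in the variant table",
               "sargtype_validation_error")
  }
  if (n_fill > 0L) {
    pool_names <- as.vector(rbind(c(.FILLER_TRN, rep(NA, length(.FILLER_ORF))),
                                  c(.FILLER_ORF, rep(NA, length(.FILLER_TRN)))))
    pool_names <- pool_names[!is.na(pool_names)][seq_len(min(n_fill,
      length(.FILLER_TRN) + length(.FILLER_ORF)))]
    if (length(pool_names) < n_fill) {
      .stop_sarg("not enough placeholder names to reach gene_count",
                 "sargtype_infeasibility_error")
    }
    bounds <- rbind(cbind(features$start, features$end),
                    cbind(forbidden, forbidden))
    bounds <- bounds[order(bounds[, 1L]), , drop = FALSE]
    gaps <- list()
    cur <- 1L
    for (k in seq_len(nrow(bounds))) {
      if (bounds[k, 1L] - 2L >= cur) gaps[[length(gaps) + 1L]] <- c(cur, bounds[k, 1L] - 2L)
      cur <- max(cur, bounds[k, 2L] + 2L)
    }
    if (cur <= L) gaps[[length(gaps) + 1L]] <- c(cur, L)
    fillers <- list()
    gi <- 1L
    at <- if (length(gaps) > 0L) gaps[[1L]][1L] else L + 1L
    for (nm in pool_names) {
      size <- if (grepl("^trn", nm)) 71L else 150L
      kind <- if (grepl("^trn", nm)) "tRNA" else "CDS"
      repeat {
        if (gi > length(gaps)) {
          .stop_sarg("not enough intergenic space for placeholder features",
                     "sargtype_infeasibility_error")
        }
        if (at + size - 1L <= gaps[[gi]][2L]) break
        gi <- gi + 1L
        if (gi <= length(gaps)) at <- gaps[[gi]][1L]
      }
      fillers[[nm]] <- data.frame(locus = nm, start = at, end = at + size - 1L,
                                  strand = "+", kind = kind,
                                  stringsAsFactors = FALSE)
      at <- at + size - 1L + .FILLER_SPACING
    }
    features <- rbind(features, do.call(rbind, fillers))
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  if (any(features$start[-1L] <= features$end[-nrow(features)])) {
    .stop_sarg("internal error: overlapping features in layout",
               "sargtype_infeasibility_error")
  }

  structure(list(features = features, genes = genes,
                 primer_sites = primer_sites, config = config,
                 variants = variants),
            class = "sarg_layout")
}

# Calibrate base probabilities so that codons drawn conditionally on being
# non-stop hit the target AT fraction in expectation.
.nonstop_codon_probs <- function(at_target) {
  comp <- t(vapply(.CODONS, function(c) {
    b <- .chars(c)
    c(at = sum(b %in% c("A", "T")), gc = sum(b %in% c("C", "G")))
  }, numeric(2)))
  nonstop <- !(.CODONS %in% .STOPS)
  cond_at <- function(atp) {
    w <- (atp / 2)^comp[, "at"] * ((1 - atp) / 2)^comp[, "gc"]
    w <- w[nonstop]
    sum(w * comp[nonstop, "at"]) / (3 * sum(w))
  }
  atp <- stats::uniroot(function(x) cond_at(x) - at_target,
                        lower = 0.02, upper = 0.98, tol = 1e-9)$root
  w <- (atp / 2)^comp[, "at"] * ((1 - atp) / 2)^comp[, "gc"]
  w[!nonstop] <- 0
  w / sum(w)
}

#' Build the three reference mitogenomes
#'
#' Constructs three collinear sequences of `genome_length` bp that are
#' identical everywhere except at the variant-table positions, where each
#' form carries its printed plus-strand allele. CDS regions are built codon
#' by codon (ATG start, stop-codon terminator, no internal stop codon in any
#' form), variant codons carry the layout's solved codon contexts, primer
#' footprints are embedded verbatim, and unconstrained positions are drawn to
#' approach the configured AT fraction.
#'
#' @param layout A [layout_genes()] result.
#' @param variants Variant table; defaults to the one in the layout.
#' @param config Generator configuration; defaults to the one in the layout.
#' @return An object of class `sarg_references`: list with `genomes` (named
#'   character vector: fluitans_III, natans_I, natans_VIII), `annotation`,
#'   `layout`, `variants`, `config`.
#' @export
build_references <- function(layout, variants = layout$variants,
                             config = layout$config) {
  L <- config$genome_length
  set.seed(config$seed)
  pbase <- c(config$at_fraction / 2, (1 - config$at_fraction) / 2,
             (1 - config$at_fraction) / 2, config$at_fraction / 2)
  base <- sample(.BASES, L, replace = TRUE, prob = pbase)
  codon_probs <- .nonstop_codon_probs(config$at_fraction)

  feats <- layout$features
  for (i in seq_len(nrow(feats))) {
    if (feats$kind[i] != "CDS") next
    locus <- feats$locus[i]
    start <- feats$start[i]; end <- feats$end[i]; strand <- feats$strand[i]
    n <- (end - start + 1L) %/% 3L
    codons <- sample(.CODONS, n, replace = TRUE, prob = codon_probs)
    codons[1L] <- "ATG"
    sol <- layout$genes[[locus]]
    pinned <- !is.null(sol) && !is.na(sol$stop_site)
    if (!pinned) codons[n] <- "TAA"
    if (!is.null(sol)) {
      for (k in seq_along(sol$positions)) {
        ci <- .codon_interval(sol$positions[k], sol$offsets[k], strand)
        idx <- if (strand == "+") (ci[1L] - start) %/% 3L + 1L
               else (end - ci[2L]) %/% 3L + 1L
        codons[idx] <- sol$codons[k]
      }
    }
    coding <- paste(codons, collapse = "")
    plus <- if (strand == "+") coding else .revcomp(coding)
    base[start:end] <- .chars(plus)
  }

  # embed primer footprints (plus-strand fixed bases)
  if (!is.null(layout$primer_sites)) {
    for (j in seq_len(nrow(layout$primer_sites))) {
      fp <- layout$primer_sites[j, ]
      base[fp$start:fp$end] <- .chars(fp$bases)
    }
  }

  # scrub any non-terminal stop codon introduced by footprint edges or
  # background draws adjacent to fixed bases; no stop codon contains C, so
  # setting one free coding base to C always works
  fixed <- logical(L)
  if (!is.null(layout$primer_sites)) {
    for (j in seq_len(nrow(layout$primer_sites))) {
      fp <- layout$primer_sites[j, ]
      fixed[fp$start:fp$end] <- TRUE
    }
  }
  fixed[variants$position] <- TRUE
  for (i in seq_len(nrow(feats))) {
    if (feats$kind[i] != "CDS") next
    start <- feats$start[i]; end <- feats$end[i]; strand <- feats$strand[i]
    n <- (end - start + 1L) %/% 3L
    reg <- base[start:end]
    coding <- if (strand == "+") reg else rev(.COMP[reg])
    for (k in seq_len(n - 1L)) {
      tri <- paste(coding[(3L * k - 2L):(3L * k)], collapse = "")
      if (!(tri %in% .STOPS)) next
      gpos <- if (strand == "+") start + 3L * (k - 1L) + 0:2 else end - 3L * (k - 1L) - (0:2)
      free <- gpos[!fixed[gpos]]
      if (length(free) == 0L) {
        .stop_sarg("internal stop codon with no free base", "sargtype_infeasibility_error")
      }
      base[free[1L]] <- if (strand == "+") "C" else "G"
    }
  }

  # realize the per-form alleles
  base[variants$position] <- variants$nt_fluitans
  genomes <- c(
    fluitans_III = paste(base, collapse = ""),
    natans_I = NA_character_,
    natans_VIII = NA_character_)
  b <- base; b[variants$position] <- variants$nt_natansI
  genomes["natans_I"] <- paste(b, collapse = "")
  b <- base; b[variants$position] <- variants$nt_natansVIII
  genomes["natans_VIII"] <- paste(b, collapse = "")

  structure(list(genomes = genomes, annotation = feats, layout = layout,
                 variants = variants, config = config),
            class = "sarg_references")
}

#' Generate a labeled amplicon cohort
#'
#' Amplifies the cox2/cox3 products in silico from each form's reference and
#' copies them into specimens with independent per-base substitution noise.
#'
#' @param references A [build_references()] result.
#' @param primers Primer panel; default the packaged panel.
#' @param config Generator configuration; default the one in `references`.
#' @return A data frame of class `sarg_cohort`: `specimen_id`, `true_form`,
#'   and one amplicon sequence column per assay.
#' @export
generate_cohort <- function(references, primers = sarg_primers(),
                            config = references$config) {
  sizes <- config$cohort_sizes
  if (any(sizes < 0)) {
    .stop_sarg("cohort sizes must be non-negative", "sargtype_validation_error")
  }
  if (config$noise_rate < 0 || config$noise_rate >= 0.5) {
    .stop_sarg("noise_rate must lie in [0, 0.5)", "sargtype_validation_error")
  }
  products <- lapply(names(references$genomes), function(id) {
    amps <- lapply(seq_len(nrow(primers)), function(j) {
      insilico_pcr(references$genomes[[id]], primers[j, ])$seq
    })
    names(amps) <- primers$name
    amps
  })
  names(products) <- names(references$genomes)

  set.seed(config$seed + 1L)
  rows <- list()
  for (form in names(sizes)) {
    for (k in seq_len(sizes[[form]])) {
      id <- sprintf("%s_%03d", form, k)
      row <- list(specimen_id = id, true_form = form)
      for (assay in primers$name) {
        seq <- products[[form]][[assay]]
        if (config$noise_rate > 0) {
          ch <- .chars(seq)
          hit <- which(stats::runif(length(ch)) < config$noise_rate)
          for (h in hit) ch[h] <- sample(setdiff(.BASES, ch[h]), 1L)
          seq <- paste(ch, collapse = "")
        }
        row[[assay]] <- seq
      }
      rows[[id]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  attr(cohort, "seed") <- config$seed
  attr(cohort, "noise_rate") <- config$noise_rate
  class(cohort) <- c("sarg_cohort", "data.frame")
  cohort
}

#' Generate the toy marker panel
#'
#' Builds aligned toy sequences for the nuclear and chloroplast barcoding
#' loci whose discriminating power the mitogenome comparison was evaluated
#' against: 18S and 5.8S identical across all three forms, ITS-2 with exactly
#' one site separating *S. natans VIII* from the two (identical) others, and
#' rbcL with exactly three sites separating *S. fluitans III* from both
#' *S. natans* forms.
#'
#' @param config A [generator_config()].
#' @return Named list of markers; each is a named character vector with one
#'   aligned sequence per form.
#' @export
generate_marker_panel <- function(config = generator_config()) {
  set.seed(config$seed + 2L)
  pbase <- c(config$at_fraction / 2, (1 - config$at_fraction) / 2,
             (1 - config$at_fraction) / 2, config$at_fraction / 2)
  draw <- function(n) paste(sample(.BASES, n, replace = TRUE, prob = pbase),
                            collapse = "")
  flip <- function(seq, pos) {
    ch <- .chars(seq)
    ch[pos] <- .BASES[(match(ch[pos], .BASES)) %% 4L + 1L]
    paste(ch, collapse = "")
  }
  identical3 <- function(seq) {
    stats::setNames(rep(seq, 3L), .FORMS)
  }
  its2 <- draw(300L)
  rbcl <- draw(800L)
  list(
    `18S` = identical3(draw(600L)),
    `5.8S` = identical3(draw(160L)),
    ITS2 = stats::setNames(c(its2, its2, flip(its2, 150L)), .FORMS),
    rbcL = stats::setNames(
      c(flip(flip(flip(rbcl, 200L), 400L), 600L), rbcl, rbcl), .FORMS))
}
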