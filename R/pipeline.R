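# End-to-end orchestration: simulate -> scan -> annotate -> assay -> type ->
# tree -> consolidated report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cls <- setdiff(class(e), c("condition", "error", "simpleError"))
    stop(errorCondition(sprintf("stage '%s': %s", name, conditionMessage(e)),
                        class = c(cls, "sargtype_stage_error", "sargtype_error",
                                  "error")))
  })
}

#' Run the full comparative pipeline
#'
#' Builds the three synthetic references realizing the packaged variant
#' panel, scans them for differences, annotates effects, derives the
#' diagnostic cox2/cox3 profiles, types a simulated cohort, and computes a
#' bootstrapped NJ tree. Every stage is deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @param bootstrap_replicates Bootstrap replicates for the tree stage.
#' @return Object of class `sarg_report`.
#' @export
run_pipeline <- function(config = generator_config(), bootstrap_replicates = 200L) {
  if (!inherits(config, "sarg_config")) {
    .stop_sarg("config must be a generator_config()", "sargtype_validation_error")
  }
  variants <- .stage("refpanel", sarg_variants())
  primers <- .stage("refpanel", sarg_primers())
  refs <- .stage("simulate", {
    build_references(layout_genes(variants, config, primers))
  })
  genomes <- refs$genomes
  dm <- .stage("scan", p_distance_matrix(genomes))
  scanned <- .stage("scan", scan_variants(genomes, refs$annotation))
  ann <- .stage("effects", annotate_effects(scanned$position, genomes, refs$annotation))
  eff_natans <- .stage("effects", effect_summary(ann, c("natans_I", "natans_VIII")))
  pairs <- list(
    natansI_vs_natansVIII = c("natans_I", "natans_VIII"),
    fluitans_vs_natansI = c("fluitans_III", "natans_I"),
    fluitans_vs_natansVIII = c("fluitans_III", "natans_VIII"))
  loc <- .stage("effects", lapply(pairs, function(p) {
    as.list(locus_summary(variants, pair = p))
  }))
  profiles <- .stage("assay", derive_diagnostic_profiles(refs, primers))
  cohort <- .stage("type", generate_cohort(refs, primers, config))
  typing <- .stage("type", type_cohort(cohort, profiles))
  if (sum(typing$summary) != nrow(cohort)) {
    .stop_sarg("typing counts do not sum to cohort size", "sargtype_validation_error")
  }
  boot <- .stage("tree", bootstrap_support(genomes, bootstrap_replicates,
                                           seed = config$seed + 3L))

  report <- list(
    config = unclass(config),
    n_variant_sites = nrow(scanned),
    genome_length = unname(nchar(genomes[[1L]])),
    pairwise_differences = lapply(pairs, function(p) {
      unname(dm$counts[p[1L], p[2L]])
    }),
    locus_summaries = loc,
    effects = list(
      natans_pair_genes = eff_natans$genes,
      natans_pair_n_genes = eff_natans$n_genes,
      natans_pair_rrna = as.list(eff_natans$rrna)),
    diagnostic_profiles = lapply(unclass(profiles), function(pr) {
      list(assay = pr$assay, product_start = pr$start, product_end = pr$end,
           sites = pr$sites)
    }),
    typing = list(summary = as.list(typing$summary),
                  n_label_mismatches = nrow(typing$label_mismatches)),
    tree = list(newick = ape::write.tree(boot$tree),
                supports = as.list(boot$supports)),
    bootstrap_replicates = bootstrap_replicates)
  structure(report, class = "sarg_report")
}

#' Write a pipeline report as JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sarg_report <- function(x, ...) {
  cat("Holopelagic Sargassum comparative mitogenomics report\n")
  cat(sprintf("  genome length: %d bp; variant sites: %d\n",
              x$genome_length, x$n_variant_sites))
  cat(sprintf("  pairwise differences: natans I/VIII %d, fluitans/natans I %d, fluitans/natans VIII %d\n",
              x$pairwise_differences$natansI_vs_natansVIII,
              x$pairwise_differences$fluitans_vs_natansI,
              x$pairwise_differences$fluitans_vs_natansVIII))
  cat(sprintf("  natans pair amino-acid differences in %d genes: %s\n",
              x$effects$natans_pair_n_genes,
              paste(x$effects$natans_pair_genes, collapse = ", ")))
  cat("  typing summary:",
      paste(sprintf("%s=%d", names(x$typing$summary), unlist(x$typing$summary)),
            collapse = ", "), "\n")
  cat(sprintf("  label mismatches: %d\n", x$typing$n_label_mismatches))
  cat(sprintf("  tree: %s\n", x$tree$newick))
  invisible(x)
}

#' @export
print.sarg_references <- function(x, ...) {
  cat(sprintf("sarg_references: %d genomes of %d bp, %d features\n",
              length(x$genomes), nchar(x$genomes[[1L]]), nrow(x$annotation)))
  invisible(x)
}

#' @export
print.sarg_typing <- function(x, ...) {
  cat("specimen typing:",
      paste(sprintf("%s=%d", names(x$summary), x$summary), collapse = ", "), "\n")
  if (nrow(x$label_mismatches) > 0L) {
    cat(sprintf("  %d specimen(s) whose molecular call contradicts the label\n",
                nrow(x$label_mismatches)))
  }
  invisible(x)
}
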