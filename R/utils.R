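# Internal constants and helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# All 64 codons in lexicographic order (A < C < G < T).
.CODONS <- as.vector(t(outer(
  as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0)))
.CODONS <- sort(.CODONS)

# One-letter to three-letter amino-acid names; "*" prints as "Stop" to match
# the published table.
.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop")

.FORMS <- c("fluitans_III", "natans_I", "natans_VIII")
.NONGENIC <- c("Intergenic Region", "Intergenic Spacer")

.translate3 <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  unname(.AA3[[aa]])
}

.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

.revcomp <- function(seq) {
  paste(rev(unname(.COMP[.chars(seq)])), collapse = "")
}

.complement <- function(bases) unname(.COMP[bases])

.stop_sarg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sargtype_error", "error")))
}

.check_form <- function(form) {
  bad <- setdiff(form, .FORMS)
  if (length(bad) > 0L) {
    .stop_sarg(sprintf("unknown form name(s): %s", paste(bad, collapse = ", ")),
               "sargtype_validation_error")
  }
  invisible(form)
}

.is_nongenic <- function(locus) locus %in% .NONGENIC

# Map the canonical form names onto the allele columns of a variant table
# (packaged schema nt_* or scan output named by genome id).
.form_allele_col <- function(variants, form) {
  cols <- c(fluitans_III = "nt_fluitans", natans_I = "nt_natansI",
            natans_VIII = "nt_natansVIII")
  if (cols[[form]] %in% names(variants)) return(variants[[cols[[form]]]])
  if (form %in% names(variants)) return(variants[[form]])
  .stop_sarg(sprintf("variant table carries no allele column for form '%s'", form),
             "sargtype_validation_error")
}
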