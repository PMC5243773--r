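# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

default_refs <- function() {
  if (is.null(.fixture_cache$refs)) {
    .fixture_cache$refs <- build_references(
      layout_genes(sarg_variants(), generator_config()))
  }
  .fixture_cache$refs
}

default_profiles <- function() {
  if (is.null(.fixture_cache$profiles)) {
    .fixture_cache$profiles <- derive_diagnostic_profiles(default_refs())
  }
  .fixture_cache$profiles
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Independent columnwise oracle for the variant scanner.
brute_force_scan <- function(genomes) {
  mat <- vapply(genomes, function(s) strsplit(s, "")[[1]],
                character(nchar(genomes[[1]])))
  pos <- integer(0)
  for (p in seq_len(nrow(mat))) {
    col <- mat[p, ]
    col <- col[col != "N"]
    if (length(unique(col)) >= 2) pos <- c(pos, p)
  }
  pos
}

# Independent oracle for the codon-constraint solver: exhaustive enumeration
# over 2 strands x 3 offsets x 64 codons using Biostrings translation.
brute_force_codon_solve <- function(alleles, aa_chain) {
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", `*` = "Stop")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  runs <- rle(alleles)
  aas <- rep(strsplit(aa_chain, " > ", fixed = TRUE)[[1]], runs$lengths)
  bases <- c("A", "C", "G", "T")
  codons <- sort(apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""))
  tr <- function(codon) {
    unname(aa3[as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(codon),
                            no.init.codon = TRUE)))])
  }
  for (strand in c("+", "-")) {
    adj <- if (strand == "-") unname(comp[alleles]) else alleles
    for (offset in 0:2) {
      for (codon in codons) {
        if (substr(codon, offset + 1, offset + 1) != adj[1]) next
        got <- vapply(adj, function(a) {
          cf <- codon
          substr(cf, offset + 1, offset + 1) <- a
          tr(cf)
        }, character(1), USE.NAMES = FALSE)
        if (identical(got, aas)) {
          return(list(strand = strand, offset = offset, codon = codon))
        }
      }
    }
  }
  NULL
}
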