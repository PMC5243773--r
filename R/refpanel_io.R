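# Reference-panel I/O: FASTA and GFF3 round-trips plus the packaged variant
# table and primer panel.

#' Read a multi-record nucleotide FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T` and IUPAC ambiguity codes
#' other than A/C/G/T are mapped to `N`. Records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record ids
#'   (header text up to the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    .stop_sarg(sprintf("file not found: %s", path), "sargtype_format_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    .stop_sarg(sprintf("not a readable FASTA file: %s", conditionMessage(e)),
                               "sargtype_format_error")
                  })
  if (length(set) == 0L) {
    .stop_sarg("FASTA file contains no records", "sargtype_format_error")
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    .stop_sarg("FASTA record with empty sequence", "sargtype_format_error")
  }
  seqs <- chartr("U", "T", seqs)
  # IUPAC ambiguity codes collapse to N; anything else is a format error.
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    .stop_sarg("FASTA contains non-nucleotide symbols", "sargtype_format_error")
  }
  seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Accepts features of type CDS, rRNA or tRNA with 1-based inclusive
#' coordinates; anything else is a format error.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `locus`, `start`, `end`, `strand`,
#'   `kind`, sorted by `start`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    .stop_sarg(sprintf("file not found: %s", path), "sargtype_format_error")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   .stop_sarg(sprintf("not a readable GFF3 file: %s", conditionMessage(e)),
                              "sargtype_format_error")
                 })
  kind <- as.character(gr$type)
  bad <- setdiff(unique(kind), c("CDS", "rRNA", "tRNA"))
  if (length(bad) > 0L) {
    .stop_sarg(sprintf("unsupported feature kind(s): %s", paste(bad, collapse = ", ")),
               "sargtype_format_error")
  }
  locus <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  feats <- data.frame(
    locus = locus,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    kind = kind,
    stringsAsFactors = FALSE)
  feats[feats$strand == "*", "strand"] <- "+"
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Write gene features to a GFF3 file
#'
#' @param features Data frame with columns `locus`, `start`, `end`, `strand`,
#'   `kind` (as returned by [read_gff3()] or [layout_genes()]).
#' @param path Output path.
#' @param seqname Sequence name used in column 1.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path, seqname = "mitogenome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  gr$type <- features$kind
  gr$ID <- features$locus
  gr$Name <- features$locus
  gr$phase <- ifelse(features$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load a variant table
#'
#' Reads a TSV transcription of the published whole-mitogenome difference
#' table: one row per variant site with its 1-based genomic position, locus,
#' the plus-strand allele of each form, and the amino-acid chain (one entry
#' per run of equal alleles in form order, `-` for non-coding sites).
#'
#' @param path Path to a TSV file with columns `position`, `locus`,
#'   `nt_fluitans`, `nt_natansI`, `nt_natansVIII`, `aa_chain`.
#' @return A validated data frame sorted by position.
#' @export
load_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("position", "locus", "nt_fluitans", "nt_natansI", "nt_natansVIII",
            "aa_chain")
  if (!all(need %in% names(tab))) {
    .stop_sarg(sprintf("variant table must have columns: %s", paste(need, collapse = ", ")),
               "sargtype_validation_error")
  }
  tab <- tab[order(tab$position), need, drop = FALSE]
  rownames(tab) <- NULL
  if (anyDuplicated(tab$position)) {
    .stop_sarg("duplicate genomic positions in variant table", "sargtype_validation_error")
  }
  alleles <- as.matrix(tab[, c("nt_fluitans", "nt_natansI", "nt_natansVIII")])
  if (!all(alleles %in% .BASES)) {
    .stop_sarg("variant alleles must be A, C, G or T", "sargtype_validation_error")
  }
  mono <- tab$nt_fluitans == tab$nt_natansI & tab$nt_natansI == tab$nt_natansVIII
  if (any(mono)) {
    .stop_sarg(sprintf("monomorphic row(s) at position(s) %s",
                       paste(tab$position[mono], collapse = ", ")),
               "sargtype_validation_error")
  }
  tab
}

#' Load a primer panel
#'
#' @param path Path to a TSV file with columns `name`, `fwd_seq`, `rev_seq`,
#'   `gene`.
#' @return A validated data frame, one row per primer pair.
#' @export
load_primer_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "fwd_seq", "rev_seq", "gene")
  if (!all(need %in% names(tab))) {
    .stop_sarg(sprintf("primer panel must have columns: %s", paste(need, collapse = ", ")),
               "sargtype_validation_error")
  }
  seqs <- c(tab$fwd_seq, tab$rev_seq)
  if (any(grepl("[^ACGT]", seqs))) {
    .stop_sarg("primer sequences must contain only A, C, G, T", "sargtype_validation_error")
  }
  if (any(nchar(seqs) < 15L)) {
    .stop_sarg("primers must be at least 15 nt long", "sargtype_validation_error")
  }
  tab
}

#' Packaged variant table (98 sites)
#'
#' @return The packaged transcription of the published whole-mitogenome
#'   difference table, see [load_variant_table()].
#' @export
sarg_variants <- function() {
  load_variant_table(system.file("extdata", "variant_table.tsv",
                                 package = "sargtype", mustWork = TRUE))
}

#' Packaged cox2/cox3 diagnostic primer panel
#'
#' @return The packaged primer panel, see [load_primer_panel()].
#' @export
sarg_primers <- function() {
  load_primer_panel(system.file("extdata", "primer_panel.tsv",
                                package = "sargtype", mustWork = TRUE))
}
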