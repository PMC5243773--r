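test_that("primer site search matches a sliding-window oracle", {
  set.seed(5)
  primer <- "CAAAGATGGATTCGACGGTTGG"
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  }
  genome <- paste0(random_seq(700), primer, random_seq(500),
                   revcomp(primer), random_seq(300))
  got <- find_primer_sites(genome, primer, max_mismatch = 2)

  # brute-force scan of both strands with the same clamp rule
  oracle <- list()
  k <- nchar(primer)
  for (s in seq_len(nchar(genome) - k + 1)) {
    w <- substr(genome, s, s + k - 1)
    mm_plus <- sum(strsplit(w, "")[[1]] != strsplit(primer, "")[[1]])
    if (mm_plus <= 2 && substr(w, k - 2, k) == substr(primer, k - 2, k)) {
      oracle[[length(oracle) + 1]] <- c(s, s + k - 1, mm_plus, 1)
    }
    rc <- revcomp(primer)
    mm_minus <- sum(strsplit(w, "")[[1]] != strsplit(rc, "")[[1]])
    if (mm_minus <= 2 && substr(w, 1, 3) == substr(rc, 1, 3)) {
      oracle[[length(oracle) + 1]] <- c(s, s + k - 1, mm_minus, -1)
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, sort(oracle[, 1]))
  expect_equal(sum(got$strand == "+"), sum(oracle[, 4] == 1))
  expect_true(all(got$mismatches == 0))

  # a primer absent everywhere yields no sites under the tolerance
  expect_equal(nrow(find_primer_sites(random_seq(500), primer, 2)), 0L)
})

test_that("in-silico PCR yields one product spanning the diagnostic sites", {
  refs <- default_refs()
  primers <- sarg_primers()
  cox3 <- primers[primers$name == "cox3", ]
  amp <- insilico_pcr(refs$genomes[["natans_I"]], cox3)
  expect_lte(amp$start, 14466)
  expect_gte(amp$end, 14516)
  expect_equal(nchar(amp$seq), amp$end - amp$start + 1)

  # reverse primer absent: no amplification
  half <- substr(refs$genomes[["natans_I"]], 1, amp$rev_start - 1)
  expect_error(insilico_pcr(half, cox3),
               class = "sargtype_no_amplification_error")

  # planted duplicate forward site: multiple products
  dup <- paste0(substr(refs$genomes[["natans_I"]], 1, amp$start - 1),
                cox3$fwd_seq,
                substr(refs$genomes[["natans_I"]], amp$start, nchar(refs$genomes[["natans_I"]])))
  expect_error(insilico_pcr(dup, cox3, max_product = 3000),
               class = "sargtype_multiple_product_error")
})

test_that("diagnostic profiles separate the three forms", {
  profiles <- default_profiles()
  cox3 <- profiles$cox3$sites
  row <- cox3[cox3$position == 14516, ]
  expect_equal(c(row$fluitans_III, row$natans_I, row$natans_VIII),
               c("G", "A", "G"))

  cox2 <- profiles$cox2$sites
  expect_gte(nrow(cox2), 3L)
  expect_true(all(cox2$natans_I == cox2$natans_VIII))
  expect_true(all(cox2$fluitans_III != cox2$natans_I))

  # joint expected haplotypes are pairwise distinct
  hap <- vapply(c("fluitans_III", "natans_I", "natans_VIII"), function(f) {
    paste(c(profiles$cox2$sites[[f]], profiles$cox3$sites[[f]]), collapse = "")
  }, character(1))
  expect_equal(length(unique(hap)), 3L)
})

test_that("specimens type to the expected form from their amplicons", {
  profiles <- default_profiles()
  amps_of <- function(form) {
    lapply(profiles, function(p) p$products[[form]])
  }
  expect_equal(type_specimen(amps_of("natans_VIII"), profiles)$call, "natans_VIII")
  expect_equal(type_specimen(amps_of("fluitans_III"), profiles)$call, "fluitans_III")
  expect_equal(type_specimen(amps_of("natans_I"), profiles)$call, "natans_I")

  # a confident call has zero conflicting sites
  tc <- type_specimen(amps_of("natans_I"), profiles)
  expect_equal(tc$n_conflicting, 0L)
  expect_gte(tc$n_supporting, 1L)

  # novel haplotype at a diagnostic site: unknown
  amps <- amps_of("natans_VIII")
  p <- profiles$cox3$sites$position[1] - profiles$cox3$start + 1
  bad <- setdiff(c("A", "C", "G", "T"),
                 unlist(profiles$cox3$sites[1, c("fluitans_III", "natans_I", "natans_VIII")]))[1]
  substr(amps$cox3, p, p) <- bad
  expect_equal(type_specimen(amps, profiles)$call, "unknown")

  # assays pointing to different forms: conflict
  mixed <- list(cox2 = profiles$cox2$products[["fluitans_III"]],
                cox3 = profiles$cox3$products[["natans_I"]])
  expect_equal(type_specimen(mixed, profiles)$call, "conflict")

  expect_error(type_specimen(list(cox2 = "ACGT"), profiles),
               class = "sargtype_input_error")
})

test_that("cohort typing recovers the study composition and flags label mismatches", {
  refs <- default_refs()
  profiles <- default_profiles()
  cohort <- generate_cohort(refs)
  typing <- type_cohort(cohort, profiles)
  expect_equal(typing$summary[["natans_VIII"]], 53L)
  expect_equal(typing$summary[["natans_I"]], 13L)
  expect_equal(typing$summary[["fluitans_III"]], 5L)
  expect_equal(typing$summary[["unknown"]], 0L)
  expect_equal(typing$summary[["conflict"]], 0L)

  # relabeling a specimen changes the reported mismatch, not the call
  relabeled <- cohort
  relabeled$true_form[1] <- "fluitans_III"  # actually a natans_VIII specimen
  t2 <- type_cohort(relabeled, profiles)
  expect_equal(t2$calls$call[1], "natans_VIII")
  expect_equal(nrow(t2$label_mismatches), 1L)
  expect_equal(t2$label_mismatches$specimen_id[1], cohort$specimen_id[1])

  expect_error(type_cohort(cohort[0, ], profiles),
               class = "sargtype_validation_error")
})

test_that("fixed-site verification passes on clean cohorts and flags planted variation", {
  refs <- default_refs()
  profiles <- default_profiles()
  cohort <- generate_cohort(refs)
  rep <- verify_fixed_sites(cohort, profiles)
  expect_true(rep$pass)
  expect_true(all(rep$table$status == "fixed"))
  expect_equal(nrow(rep$label_mismatches), 0L)

  # flip one specimen's allele at a cox3 diagnostic site
  dirty <- cohort
  i <- which(dirty$true_form == "natans_VIII")[1]
  p <- profiles$cox3$sites$position[2] - profiles$cox3$start + 1
  substr(dirty$cox3[i], p, p) <- "A"
  rep2 <- verify_fixed_sites(dirty, profiles)
  expect_false(rep2$pass)
  flagged <- rep2$table[rep2$table$status == "polymorphic", ]
  expect_equal(flagged$position, profiles$cox3$sites$position[2])
  expect_equal(flagged$form, "natans_VIII")
})
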