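test_that("layout covers every locus, fills to 65 genes and is deterministic", {
  v <- sarg_variants()
  cfg <- generator_config()
  lay <- layout_genes(v, cfg)
  feats <- lay$features
  expect_equal(nrow(feats), 65L)
  genic <- v[!v$locus %in% c("Intergenic Region", "Intergenic Spacer"), ]
  expect_true(all(unique(genic$locus) %in% feats$locus))

  # every genic site inside its own feature, every intergenic site outside all
  for (i in seq_len(nrow(genic))) {
    f <- locate_feature(genic$position[i], feats)
    expect_equal(f$locus, genic$locus[i])
  }
  inter <- v$position[v$locus %in% c("Intergenic Region", "Intergenic Spacer")]
  for (p in inter) expect_null(locate_feature(p, feats))

  # structural invariants
  expect_true(all(feats$start >= 1 & feats$end <= cfg$genome_length))
  expect_true(all(feats$start[-1] > feats$end[-nrow(feats)]))
  cds <- feats[feats$kind == "CDS", ]
  expect_true(all((cds$end - cds$start + 1) %% 3 == 0))

  expect_identical(lay$features, layout_genes(v, cfg)$features)
})

test_that("layout rejects genes whose sites admit no common reading frame", {
  # Leu>Leu with alleles C/A is only satisfiable at codon offset 2 on either
  # strand; two such sites 761 bp apart (761 mod 3 = 2) cannot share a frame
  toy <- data.frame(
    position = c(100L, 861L), locus = "toy",
    nt_fluitans = "C", nt_natansI = "A", nt_natansVIII = "A",
    aa_chain = "Leu > Leu", stringsAsFactors = FALSE)
  cfg <- generator_config(genome_length = 2000L, gene_count = 1L)
  expect_error(layout_genes(toy, cfg),
               class = "sargtype_infeasibility_error")
})

test_that("references realize the variant panel exactly", {
  refs <- default_refs()
  expect_equal(unname(nchar(refs$genomes)), rep(34727L, 3))

  v <- sarg_variants()
  # printed alleles at every site, e.g. 14516 (G, A, G)
  for (form_col in list(c("fluitans_III", "nt_fluitans"),
                        c("natans_I", "nt_natansI"),
                        c("natans_VIII", "nt_natansVIII"))) {
    got <- vapply(v$position, function(p) {
      substr(refs$genomes[[form_col[1]]], p, p)
    }, character(1))
    expect_identical(got, v[[form_col[2]]])
  }
  expect_equal(count_differences(refs$genomes[["fluitans_III"]],
                                 refs$genomes[["fluitans_III"]]), 0L)

  # identical everywhere else: the scan finds exactly the panel positions
  sv <- scan_variants(refs$genomes)
  expect_identical(sv$position, v$position)
})

test_that("no CDS of any reference contains an internal stop codon", {
  refs <- default_refs()
  feats <- refs$annotation
  stops <- c("TAA", "TAG", "TGA")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (form in names(refs$genomes)) {
    ch <- strsplit(refs$genomes[[form]], "")[[1]]
    for (i in which(feats$kind == "CDS")) {
      reg <- ch[feats$start[i]:feats$end[i]]
      if (feats$strand[i] == "-") reg <- rev(unname(comp[reg]))
      n <- length(reg) %/% 3
      cods <- vapply(seq_len(n), function(k) {
        paste(reg[(3 * k - 2):(3 * k)], collapse = "")
      }, character(1))
      expect_false(any(cods[-n] %in% stops),
                   info = paste(form, feats$locus[i]))
      expect_equal(cods[1], "ATG", info = paste(form, feats$locus[i]))
    }
  }
})

test_that("realized AT content approaches the configured fraction", {
  refs <- default_refs()
  for (form in names(refs$genomes)) {
    expect_gt(at_content(refs$genomes[[form]]), 0.628)
    expect_lt(at_content(refs$genomes[[form]]), 0.648)
  }
})

test_that("reference construction is reproducible from the seed", {
  v <- sarg_variants()
  cfg <- generator_config(seed = 99L)
  a <- build_references(layout_genes(v, cfg))
  b <- build_references(layout_genes(v, cfg))
  expect_identical(a$genomes, b$genomes)
  c <- build_references(layout_genes(v, generator_config(seed = 100L)))
  expect_false(identical(a$genomes, c$genomes))
  # but the variant panel is realized under any seed
  expect_equal(count_differences(c$genomes[["natans_I"]],
                                 c$genomes[["natans_VIII"]]), 7L)
})

test_that("generator config validates its bounds", {
  expect_error(generator_config(noise_rate = 0.5),
               class = "sargtype_validation_error")
  expect_error(generator_config(at_fraction = 1.2),
               class = "sargtype_validation_error")
  expect_error(generator_config(cohort_sizes = c(natans_I = -1L)),
               class = "sargtype_validation_error")
  expect_error(layout_genes(sarg_variants(), generator_config(genome_length = 30000L)),
               class = "sargtype_validation_error")
})

test_that("noiseless cohorts copy each form's reference amplicon verbatim", {
  refs <- default_refs()
  cohort <- generate_cohort(refs)
  expect_equal(nrow(cohort), 71L)
  expect_equal(as.vector(table(cohort$true_form)[c("natans_VIII", "natans_I", "fluitans_III")]),
               c(53L, 13L, 5L))
  profiles <- default_profiles()
  for (assay in names(profiles)) {
    for (form in unique(cohort$true_form)) {
      expect_true(all(cohort[[assay]][cohort$true_form == form] ==
                        profiles[[assay]]$products[[form]]))
    }
  }
  expect_identical(generate_cohort(refs), cohort)
})

test_that("marker panel reproduces the published negative results", {
  panel <- generate_marker_panel(generator_config())
  expect_equal(count_differences(panel$`18S`[["fluitans_III"]],
                                 panel$`18S`[["natans_I"]]), 0L)
  expect_equal(count_differences(panel$`18S`[["natans_I"]],
                                 panel$`18S`[["natans_VIII"]]), 0L)
  expect_equal(count_differences(panel$`5.8S`[["fluitans_III"]],
                                 panel$`5.8S`[["natans_VIII"]]), 0L)
  expect_equal(count_differences(panel$ITS2[["natans_VIII"]],
                                 panel$ITS2[["natans_I"]]), 1L)
  expect_equal(count_differences(panel$ITS2[["fluitans_III"]],
                                 panel$ITS2[["natans_I"]]), 0L)
  expect_equal(count_differences(panel$rbcL[["fluitans_III"]],
                                 panel$rbcL[["natans_I"]]), 3L)
  expect_equal(count_differences(panel$rbcL[["fluitans_III"]],
                                 panel$rbcL[["natans_VIII"]]), 3L)
  expect_equal(count_differences(panel$rbcL[["natans_I"]],
                                 panel$rbcL[["natans_VIII"]]), 0L)
})
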