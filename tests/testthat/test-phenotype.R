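# the epistatic phenotype engine

panel <- default_panel()

test_that("single-site loci classify by inheritance mode", {
  calls <- reference_calls(panel)
  # E-locus: one ginger allele is a carrier, two give the phene
  st <- classify_simple_locus(set_genotype(calls, "MC1R_ginger", "G", "A"),
                              "E_ginger", panel)
  expect_identical(st$state, "carrier")
  expect_false(st$provisional)
  st <- classify_simple_locus(set_genotype(calls, "MC1R_ginger", "A", "A"),
                              "E_ginger", panel)
  expect_identical(st$state, "ee_ginger")
  # K-locus deletion is dominant
  st <- classify_simple_locus(set_genotype(calls, "CBD103_K", "del", "del"),
                              "K", panel)
  expect_identical(st$state, "dominant_black")
  st <- classify_simple_locus(set_genotype(calls, "CBD103_K", "ins", "del"),
                              "K", panel)
  expect_identical(st$state, "dominant_black")
  # a missing call is imputed homozygous reference, provisionally
  st <- classify_simple_locus(set_missing(calls, "MC1R_ginger"),
                              "E_ginger", panel)
  expect_identical(st$state, "wildtype")
  expect_true(st$provisional)
  # mask allele is the reference C
  st <- classify_simple_locus(set_genotype(calls, "MC1R_mask", "C", "T"),
                              "E_mask", panel)
  expect_identical(st$state, "masked")
})

test_that("the D-locus needs a panel site and respects low coverage", {
  expect_error(classify_simple_locus(reference_calls(panel), "D", panel),
               "lacks")
  ext <- extend_panel(panel)
  calls <- reference_calls(ext)
  st <- classify_simple_locus(set_genotype(calls, "MLPH_dilution", "A", "A"),
                              "D", ext)
  expect_identical(st$state, "dilute")
  st <- classify_simple_locus(
    set_genotype(calls, "MLPH_dilution", "G", "A", status = "low_coverage"),
    "D", ext)
  expect_identical(st$state, "unknown")
  expect_true(st$provisional)
})

test_that("B-locus counts brown alleles across TYRP1 sites", {
  calls <- reference_calls(panel)
  st <- classify_b_locus(set_genotype(calls, "TYRP1_Q331X", "T", "T"), panel)
  expect_identical(st$state, "brown")
  st <- classify_b_locus(set_genotype(calls, "TYRP1_Q331X", "C", "T"), panel)
  expect_identical(st$state, "brown_carrier")
  expect_identical(classify_b_locus(calls, panel)$state, "black_capable")
  # compound heterozygote across two distinct sites: brown, phase unknown
  cc <- set_genotype(set_genotype(calls, "TYRP1_Q331X", "C", "T"),
                     "TYRP1_C41S", "T", "C")
  st <- classify_b_locus(cc, panel)
  expect_identical(st$state, "brown")
  expect_true(any(grepl("phase unknown", st$notes)))
})

test_that("A-locus haplotypes classify as at, Ay or recessive black", {
  calls <- reference_calls(panel)
  # Kelpie configuration: both indels homozygous insertion, wild-type exon
  kel <- set_genotype(calls, "RALY_dup", "ins", "ins")
  kel <- set_genotype(kel, "ASIP_ins239", "ins", "ins")
  kel <- set_genotype(kel, "ASIP_A82", "G", "G")
  kel <- set_genotype(kel, "ASIP_R83", "G", "G")
  expect_identical(classify_a_locus(kel, panel)$state, "tan_point_at")
  # the reference (and Dingo) haplotype is dominant yellow
  st <- classify_a_locus(calls, panel)
  expect_identical(st$state, "dominant_yellow_Ay")
  expect_true(any(grepl("saddle", st$notes)))
  # recessive black overrides
  expect_identical(
    classify_a_locus(set_genotype(calls, "ASIP_R92", "T", "T"), panel)$state,
    "recessive_black_a")
  # contradictory indel/exon combination degrades to unknown, with a note
  bad <- set_genotype(kel, "ASIP_A82", "T", "T")
  st <- classify_a_locus(bad, panel)
  expect_identical(st$state, "unknown")
  expect_true(any(grepl("conflict", st$notes)))
})

test_that("S-locus grades white by SINE and allele lengths", {
  calls <- reference_calls(panel)
  st <- classify_s_locus(set_genotype(calls, "MITF_SINE", "ins", "ins"),
                         panel)
  expect_identical(st$state, "white_extensive")
  no_sine <- set_genotype(calls, "MITF_SINE", "del", "del")
  st <- classify_s_locus(
    set_genotype(no_sine, "MITF_length", "10C9A2G12A", "10C9A2G12A"), panel)
  expect_identical(st$state, "white_none")  # 33/33, both below 35
  st <- classify_s_locus(
    set_genotype(no_sine, "MITF_length", "10C8A2G11A", "10C9A2G12A"), panel)
  expect_identical(st$state, "white_none")  # 31/33
  st <- classify_s_locus(no_sine, panel)    # 35/35 reference lengths
  expect_identical(st$state, "white_modest")
  st <- classify_s_locus(
    set_genotype(no_sine, "MITF_length", "10C9A2G12A", "12C9A2G12A"), panel)
  expect_identical(st$state, "white_modest")  # mixed 33/35 -> intermediate
  expect_true(any(grepl("intermediate", st$notes)))
})

test_that("coat predictions reproduce the published per-dog reasoning", {
  fx <- load_paper_fixture("tables")
  # solid brown conformation dog: dominant black epistatic over tan points
  p305 <- predict_coat(sample_calls(fx, "USCF305"), fx$panel)
  expect_identical(p305$base_color, "brown")
  expect_false(p305$tan_points)
  # black with tan points, carrying red/yellow; its coat shows no mask
  p6343 <- predict_coat(sample_calls(fx, "USCF6343"), fx$panel)
  expect_identical(p6343$base_color, "black")
  expect_true(p6343$tan_points)
  expect_true("carries red/yellow" %in% p6343$carrier_notes)
  # brown with tan points despite a missing ginger-site call (imputed)
  p6203 <- predict_coat(sample_calls(fx, "USCF6203"), fx$panel)
  expect_identical(p6203$base_color, "brown")
  expect_true(p6203$tan_points)
  expect_true(p6203$provisional)
  # black with tan points carrying brown
  p6348 <- predict_coat(sample_calls(fx, "USCF6348"), fx$panel)
  expect_identical(p6348$base_color, "black")
  expect_true("carries brown" %in% p6348$carrier_notes)
  # the all-reference genotype is a masked sable/fawn
  pref <- predict_coat(reference_calls(panel), panel)
  expect_identical(pref$base_color, "sable_fawn")
  expect_false(pref$tan_points)
  expect_true(pref$mask_visible)
  expect_true(length(pref$rationale) > 0)
})

test_that("exactly three of the five undeclared dogs predict brown with tan", {
  fx <- load_paper_fixture("tables")
  undeclared <- c("USCF6182", "USCF6203", "USCF6343", "USCF6348", "USCF6350")
  preds <- lapply(undeclared, function(id) {
    predict_coat(sample_calls(fx, id), fx$panel)
  })
  brown_tan <- vapply(preds, function(p) {
    identical(p$base_color, "brown") && isTRUE(p$tan_points)
  }, TRUE)
  expect_identical(undeclared[brown_tan],
                   c("USCF6182", "USCF6203", "USCF6350"))
})

test_that("all owner-declared coats and printed ear annotations reproduce", {
  fx <- load_paper_fixture("tables")
  for (i in seq_len(nrow(fx$samples))) {
    id <- fx$samples$sample_id[i]
    dc <- fx$samples$declared_coat[i]
    if (!is.na(dc)) {
      expect_true(coat_matches_declared(predict_coat(sample_calls(fx, id),
                                                     fx$panel), dc),
                  label = paste(id, "coat matches", dc))
    }
    de <- fx$samples$declared_ears[i]
    if (!is.na(de)) {
      ear <- predict_ears(sample_calls(fx, id), fx$panel)
      expect_identical(ear$consensus, tolower(de),
                       label = paste(id, "ear matches", de))
    }
  }
})

test_that("ear predictions follow the two-locus rule", {
  calls <- reference_calls(panel)
  prick <- set_genotype(set_genotype(calls, "MSRB3_HMGA2_SNP", "T", "T"),
                        "MSRB3_UTR_ins", "insTTTATTTTAT", "insTTTATTTTAT")
  expect_identical(predict_ears(prick, panel)$consensus, "prick")
  drop <- set_genotype(set_genotype(calls, "MSRB3_HMGA2_SNP", "C", "C"),
                       "MSRB3_UTR_ins", "del", "del")
  expect_identical(predict_ears(drop, panel)$consensus, "drop")
  # heterozygous SNP with a low-coverage insertion call
  semi <- set_genotype(set_genotype(calls, "MSRB3_HMGA2_SNP", "C", "T"),
                       "MSRB3_UTR_ins", "insTTTATTTTAT", "insTTTATTTTAT",
                       status = "low_coverage")
  e <- predict_ears(semi, panel)
  expect_identical(e$consensus, "semi_erect_possible")
  expect_identical(e$utr_call, "unknown")
  expect_true(e$provisional)
  # conflicting informative calls are discordant, not silently resolved
  disc <- set_genotype(set_genotype(calls, "MSRB3_HMGA2_SNP", "T", "T"),
                       "MSRB3_UTR_ins", "del", "del")
  expect_identical(predict_ears(disc, panel)$consensus, "discordant")
})

test_that("E-locus epistasis: e/e never yields a eumelanin base color", {
  set.seed(301)
  for (i in 1:40) {
    calls <- set_genotype(random_calls(panel), "MC1R_ginger", "A", "A")
    p <- predict_coat(calls, panel)
    expect_false(p$base_color %in% c("black", "brown"))
    expect_identical(p$base_color, "ginger_cream")
    expect_false(p$mask_visible)
  }
})

test_that("K-locus epistasis: dominant black suppresses tan points", {
  set.seed(302)
  for (i in 1:40) {
    calls <- set_genotype(random_calls(panel), "CBD103_K", "del", "del")
    # keep the E-locus away from e/e so the K rule is reachable
    calls <- set_genotype(calls, "MC1R_ginger",
                          sample(c("G", "A"), 1), "G")
    p <- predict_coat(calls, panel)
    expect_false(isTRUE(p$tan_points))
  }
})

test_that("predictions are deterministic and unphased", {
  set.seed(303)
  for (i in 1:20) {
    calls <- random_calls(panel)
    p1 <- predict_coat(calls, panel)
    p2 <- predict_coat(calls, panel)
    expect_identical(p1, p2)
    expect_identical(p1$rationale, p2$rationale)
    # swap heterozygote allele order everywhere
    swapped <- calls
    tmp <- swapped$allele1
    swapped$allele1 <- swapped$allele2
    swapped$allele2 <- tmp
    expect_identical(predict_coat(swapped, panel), p1)
    expect_identical(predict_ears(swapped, panel), predict_ears(calls, panel))
  }
})

test_that("predict_cohort summarises a cohort one row per sample", {
  fx <- load_paper_fixture("tables")
  out <- predict_cohort(fx, explain = TRUE)
  expect_identical(nrow(out), 14L)
  expect_true(all(c("base_color", "ear_consensus", "rationale") %in% names(out)))
  expect_true(all(nzchar(out$rationale)))
})
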