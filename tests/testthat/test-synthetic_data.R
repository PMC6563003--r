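# packaged fixtures and the cohort simulator

test_that("the tables cohort matches the printed matrix cell by cell", {
  fx <- load_paper_fixture("tables")
  expect_identical(nrow(fx$samples), 14L)
  expect_identical(length(unique(fx$calls$site_id)), 16L)
  g <- function(id, site) {
    cl <- get_call(fx, id, site)
    if (cl$status == "missing") "0 0" else paste(cl$allele1, cl$allele2, sep = "/")
  }
  # every heterozygous, missing or otherwise distinctive cell
  expect_identical(g("USCF305", "MC1R_ginger"), "G/A")
  expect_identical(g("USCF634", "MC1R_ginger"), "G/A")
  expect_identical(g("USCF6343", "MC1R_ginger"), "G/A")
  expect_identical(g("USCF6203", "MC1R_ginger"), "0 0")
  expect_identical(g("USCF636", "MC1R_ginger"), "0 0")
  expect_identical(g("USCF634", "MC1R_mask"), "C/T")
  expect_identical(g("USCF635", "MC1R_mask"), "C/C")
  expect_identical(g("USCF639", "MC1R_mask"), "C/C")
  expect_identical(g("USCF640", "MC1R_mask"), "C/C")
  expect_identical(g("USCF639", "TYRP1_Q331X"), "0 0")
  expect_identical(g("USCF635", "TYRP1_Q331X"), "C/T")
  expect_identical(g("USCF636", "TYRP1_Q331X"), "C/T")
  expect_identical(g("USCF6348", "TYRP1_Q331X"), "C/T")
  expect_identical(g("USCF305", "CBD103_K"), "del/del")
  # unphased: canonical order puts the declared-alternate order first
  expect_identical(g("USCF640", "MITF_length"), "10C9A2G12A/10C8A2G11A")
  expect_identical(g("Dingo_RKW13760", "MITF_length"),
                   "11C10A2G12A/11C10A2G12A")
  expect_identical(g("Dingo_RKW13760", "MITF_SINE"), "ins/ins")
  expect_identical(g("Dingo_RKW13760", "RALY_dup"), "del/del")
  expect_identical(g("Dingo_RKW13760", "ASIP_A82"), "T/T")
  expect_identical(g("Labrador_LA882", "MSRB3_UTR_ins"), "del/del")
  expect_identical(g("Labrador_LA882", "MSRB3_HMGA2_SNP"), "C/C")
  expect_identical(g("Dingo_RKW13760", "MSRB3_UTR_ins"), "insTTTAT/insTTTAT")
  expect_identical(g("USCF634", "MSRB3_HMGA2_SNP"), "C/T")
  # row-level structure: homozygous brown dogs; monomorphic rows
  for (id in c("USCF305", "USCF6182", "USCF6203", "USCF6350", "USCF6359")) {
    expect_identical(g(id, "TYRP1_Q331X"), "T/T")
  }
  kelpies <- fx$samples$sample_id[fx$samples$population %in% kelpie_populations()]
  for (id in kelpies) {
    expect_identical(g(id, "MITF_SINE"), "del/del")
    expect_identical(g(id, "RALY_dup"), "ins/ins")
    expect_identical(g(id, "ASIP_A82"), "G/G")
    expect_identical(g(id, "MSRB3_UTR_ins"),
                     "insTTTATTTTAT/insTTTATTTTAT")
  }
  # Labrador contributes only through the ear sites
  coat_sites <- setdiff(names(fx$panel$sites),
                        c("MSRB3_UTR_ins", "MSRB3_HMGA2_SNP"))
  for (s in coat_sites) expect_identical(g("Labrador_LA882", s), "0 0")
  # owner declarations
  expect_identical(fx$samples$declared_coat[fx$samples$sample_id == "USCF305"],
                   "Brown")
  expect_identical(sum(fx$samples$declared_coat == "Black and Tan", na.rm = TRUE), 5L)
  expect_identical(fx$samples$declared_ears[fx$samples$sample_id == "Labrador_LA882"],
                   "Drop")
})

test_that("the dingo_panel cohort encodes the reported tallies", {
  dg <- load_paper_fixture("dingo_panel")
  expect_identical(nrow(dg$samples), 26L)
  expect_true(all(dg$samples$population == "Dingo"))
  het <- sum(dg$calls$site_id == "MC1R_ginger" & dg$calls$allele2 == "A",
             na.rm = TRUE)
  expect_identical(het, 1L)
  # one equivocal CBD103 heterozygote, as a low-coverage call
  k <- dg$calls[dg$calls$site_id == "CBD103_K", ]
  expect_identical(sum(k$allele2 == "del", na.rm = TRUE), 1L)
  expect_identical(k$status[which(k$allele2 == "del")], "low_coverage")
  # itemized ASIP exon-4 genotype classes: 17 hom-Ay (incl. the
  # whole-genome animal), 6 het, 1 hom wild-type
  a82 <- dg$calls[dg$calls$site_id == "ASIP_A82" &
                  dg$calls$status != "missing", ]
  cls <- paste(a82$allele1, a82$allele2)
  expect_identical(sum(cls == "T T"), 17L)
  expect_identical(sum(cls == "T G"), 6L)
  expect_identical(sum(cls == "G G"), 1L)
  # the alternative reading drops one homozygote
  dg2 <- load_paper_fixture("dingo_panel", asip_reading = "stated_total")
  a82b <- dg2$calls[dg2$calls$site_id == "ASIP_A82" &
                    dg2$calls$status != "missing", ]
  expect_identical(sum(paste(a82b$allele1, a82b$allele2) == "T T"), 16L)
  # ratios robust to the discrepancy: Ay is the predominant allele either way
  for (d in list(dg, dg2)) {
    f <- allele_frequency(allele_counts(d, "Dingo", "ASIP_A82"))
    expect_gt(unname(f["T"]), 0.75)
  }
})

test_that("simulation respects degenerate configurations", {
  cfg <- sim_config(seed = 5, populations = c(Kelpie = 20L),
                    missing_rate = 0)
  cfg$site_freqs$Kelpie$MC1R_ginger <- c(G = 1, A = 0)
  sim <- simulate_cohort(cfg)
  mc <- sim$cohort$calls[sim$cohort$calls$site_id == "MC1R_ginger", ]
  expect_true(all(mc$allele1 == "G" & mc$allele2 == "G"))
  expect_identical(sum(sim$cohort$calls$status == "missing"), 0L)
})

test_that("identical seeds give byte-identical outputs", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(small_sim(99)$cohort, f1)
  write_genotype_table(small_sim(99)$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(cohorts_equal(small_sim(99)$cohort, small_sim(100)$cohort))
})

test_that("allele frequencies are recovered within binomial error", {
  # single-site configuration at freq 0.25, n = 1000 diploids
  cfg <- sim_config(seed = 41, populations = c(Kelpie = 1000L),
                    site_freqs = list(Kelpie = list(MC1R_ginger = c(G = 0.75, A = 0.25))),
                    ay_freq = c(Kelpie = 0),
                    missing_rate = 0,
                    panel = canidmorph:::new_panel(list(
                      get_site(default_panel(), "MC1R_ginger"))))
  sim <- simulate_cohort(cfg)
  f <- allele_frequency(allele_counts(sim$cohort, "Kelpie", "MC1R_ginger"))
  se3 <- 3 * sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(unname(f["A"]) - 0.25), se3)
})

test_that("mean absolute frequency error stays small over replicates", {
  # 100 seeded replicates at n = 500 across a frequency grid
  grid <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  panel1 <- canidmorph:::new_panel(list(get_site(default_panel(), "MC1R_ginger")))
  errs <- vapply(1:100, function(i) {
    p <- grid[(i - 1L) %% length(grid) + 1L]
    cfg <- sim_config(seed = 1000 + i, populations = c(Kelpie = 500L),
                      site_freqs = list(Kelpie = list(MC1R_ginger = c(G = 1 - p, A = p))),
                      ay_freq = c(Kelpie = 0), missing_rate = 0,
                      panel = panel1)
    sim <- simulate_cohort(cfg)
    f <- allele_frequency(allele_counts(sim$cohort, "Kelpie", "MC1R_ginger"))
    a <- if ("A" %in% names(f)) unname(f["A"]) else 0
    abs(a - p)
  }, 1)
  expect_lt(mean(errs), 0.02)
})

test_that("the simulator reproduces the study's data artifacts", {
  sim <- small_sim(7)
  # the MLPH dropout artifact: low-coverage calls concentrated at that site
  lc <- sim$cohort$calls[sim$cohort$calls$status == "low_coverage", ]
  expect_true(all(lc$site_id == "MLPH_dilution"))
  expect_gt(nrow(lc), 0)
  # truth table covers configured vs realized frequencies
  expect_true(all(c("configured_freq", "realized_freq") %in% names(sim$truth)))
  expect_true(all(abs(sim$truth$configured_freq - sim$truth$realized_freq) <= 1))
  # A-locus sampling is haplotype-consistent: samples with complete A-locus
  # calls never land in a contradictory state
  a_sites <- c("RALY_dup", "ASIP_ins239", "ASIP_A82", "ASIP_R83", "ASIP_R92")
  for (id in sim$cohort$samples$sample_id) {
    calls <- sample_calls(sim$cohort, id)
    complete <- all(calls$status[calls$site_id %in% a_sites] != "missing")
    if (complete) {
      st <- classify_a_locus(calls, sim$config$panel)
      expect_false(identical(st$state, "unknown"))
    }
  }
})

test_that("invalid simulation configurations are refused", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, populations = c(5L)), "named")
  expect_error(sim_config(seed = 1, missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(seed = 1, ay_freq = c(Kelpie = 2, Dingo = 0)),
               "ay_freq")
  cfg <- sim_config(seed = 1)
  cfg$site_freqs$Kelpie$MC1R_ginger <- c(G = 0.5, A = 0.2)
  expect_error(do.call(sim_config, list(
    seed = 1, site_freqs = cfg$site_freqs)), "invalid allele frequencies")
})
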