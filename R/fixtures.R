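#' Packaged study cohorts
#'
#' Two genotype cohorts ship with the package so that every pipeline stage
#' is testable without sequence data:
#'
#' * `"tables"` -- the published 14-sample x 16-site segregation matrix:
#'   twelve Kelpies (one conformation-type Australian Kelpie, eight
#'   Australian Working Kelpies, three Kelpies of undocumented type), one
#'   whole-genome-sequenced Dingo, and one Labrador retriever.  The
#'   Labrador enters only through the two ear sites; its coat-site calls
#'   are missing.  `"0 0"` cells and low-coverage daggers are preserved.
#' * `"dingo_panel"` -- the 26-Dingo comparison set: the whole-genome Dingo
#'   plus 25 locus-constrained records covering MC1R, CBD103 and ASIP
#'   exon 4 only (all other panel sites missing).  Exactly one of the 26
#'   carries the MC1R ginger variant, as a heterozygote; one
#'   locus-constrained record is an equivocal (low-coverage) CBD103
#'   heterozygote.  Published ASIP tallies are internally inconsistent
#'   (itemized genotype counts 16+6+1 sum to 23 against a stated total of
#'   22 sequences); both readings are available and the itemized counts are
#'   the default.
#'
#' @param variant `"tables"` or `"dingo_panel"`.
#' @param asip_reading For `"dingo_panel"`: `"itemized"` (16 homozygous
#'   dominant-yellow, 6 heterozygous, 1 homozygous wild-type among the
#'   locus-constrained records) or `"stated_total"` (one fewer homozygote,
#'   honouring the stated total of 22).
#' @return A `canid_cohort` over [default_panel()].
#' @export
load_paper_fixture <- function(variant = c("tables", "dingo_panel"),
                               asip_reading = c("itemized", "stated_total")) {
  variant <- match.arg(variant)
  if (variant == "tables") tables_fixture() else
    dingo_panel_fixture(match.arg(asip_reading))
}

# The 13 whole-genome columns in published order, then the Labrador.
.TABLES_SAMPLES <- data.frame(
  sample_id = c("Dingo_RKW13760", "USCF305", "USCF6182", "USCF6203",
                "USCF634", "USCF6343", "USCF635", "USCF636", "USCF639",
                "USCF640", "USCF6348", "USCF6350", "USCF6359",
                "Labrador_LA882"),
  population = c("Dingo", "AK", "Kelpie_unspecified", "Kelpie_unspecified",
                 "AWK", "Kelpie_unspecified", "AWK", "AWK", "AWK", "AWK",
                 "AWK", "AWK", "AWK", "Labrador"),
  declared_coat = c(NA, "Brown", NA, NA, "Black and Tan", NA,
                    "Black and Tan", "Black and Tan", "Black and Tan",
                    "Black and Tan", NA, NA, "Brown and Tan", NA),
  declared_ears = c("Prick", "Prick", NA, NA, NA, NA, NA, NA, NA, NA, NA,
                    NA, "Prick", "Drop"),
  stringsAsFactors = FALSE)

# Genotype cells per site, in .TABLES_SAMPLES order (14 cells per row).
# "0 0" = no call; a trailing dagger marks low sequencing coverage.
.TABLES_CELLS <- list(
  MC1R_ginger = c("G/G", "G/A", "G/G", "0 0", "G/A", "G/A", "G/G",
                  "0 0†", "G/G", "G/G", "G/G", "G/G", "G/G", "0 0"),
  MC1R_mask = c("T/T", "T/T", "T/T", "T/T", "C/T", "T/T", "C/C", "T/T",
                "C/C", "C/C", "T/T", "T/T", "T/T", "0 0"),
  TYRP1_C41S = c(rep("T/T", 13), "0 0"),
  TYRP1_Y185X = c(rep("T/T", 13), "0 0"),
  TYRP1_Q331X = c("C/C", "T/T", "T/T", "T/T", "C/C", "C/C", "C/T", "C/T",
                  "0 0", "C/C", "C/T", "T/T", "T/T", "0 0"),
  TYRP1_345delP = c(rep("ins/ins", 13), "0 0"),
  CBD103_K = c("ins/ins", "del/del", rep("ins/ins", 11), "0 0"),
  MITF_SINE = c("ins/ins", rep("del/del", 12), "0 0"),
  MITF_length = c("11C10A2G12A/11C10A2G12A",
                  rep("10C9A2G12A/10C9A2G12A", 8),
                  "10C8A2G11A/10C9A2G12A",
                  rep("10C9A2G12A/10C9A2G12A", 3), "0 0"),
  RALY_dup = c("del/del", rep("ins/ins", 12), "0 0"),
  ASIP_ins239 = c("del/del", rep("ins/ins", 12), "0 0"),
  ASIP_A82 = c("T/T", rep("G/G", 12), "0 0"),
  ASIP_R83 = c("A/A", rep("G/G", 12), "0 0"),
  ASIP_R92 = c(rep("C/C", 13), "0 0"),
  MSRB3_UTR_ins = c("insTTTAT/insTTTAT",
                    "insTTTATTTTAT/insTTTATTTTAT",
                    "insTTTATTTTAT/insTTTATTTTAT",
                    "insTTTATTTTAT/insTTTATTTTAT",
                    "insTTTATTTTAT/insTTTATTTTAT†",
                    rep("insTTTATTTTAT/insTTTATTTTAT", 8),
                    "del/del"),
  MSRB3_HMGA2_SNP = c("T/T", "T/T", "T/T", "T/T", "C/T", "T/T", "T/T",
                      "T/T", "T/T", "T/T", "T/T", "T/T", "T/T", "C/C"))

cells_to_calls <- function(sample_ids, cells_by_site) {
  do.call(rbind, lapply(names(cells_by_site), function(sid) {
    parsed <- lapply(cells_by_site[[sid]], parse_cell)
    data.frame(sample_id = sample_ids, site_id = sid,
               allele1 = vapply(parsed, `[[`, "", "allele1"),
               allele2 = vapply(parsed, `[[`, "", "allele2"),
               status = vapply(parsed, `[[`, "", "status"),
               note = vapply(parsed, `[[`, "", "note"),
               stringsAsFactors = FALSE)
  }))
}

tables_fixture <- function() {
  new_cohort(.TABLES_SAMPLES,
             cells_to_calls(.TABLES_SAMPLES$sample_id, .TABLES_CELLS),
             default_panel())
}

dingo_panel_fixture <- function(asip_reading = "itemized") {
  ids <- c("Dingo_RKW13760", sprintf("Dingo_LC%02d", 1:25))
  samples <- data.frame(sample_id = ids, population = "Dingo",
                        stringsAsFactors = FALSE)
  n_hom_ay <- if (asip_reading == "itemized") 16L else 15L
  lc_asip <- c(rep("hom_ay", n_hom_ay), rep("het", 6L), "hom_wt")
  calls <- NULL
  for (i in seq_along(ids)) {
    id <- ids[i]
    # MC1R coding region: exactly one heterozygote among the 26
    calls <- rbind(calls, make_call(id, "MC1R_ginger",
                                    "G", if (id == "Dingo_LC01") "A" else "G"))
    # CBD103 coding region: one equivocal possible heterozygote
    if (id == "Dingo_LC02") {
      calls <- rbind(calls, make_call(id, "CBD103_K", "ins", "del",
                                      "low_coverage", "equivocal"))
    } else {
      calls <- rbind(calls, make_call(id, "CBD103_K", "ins", "ins"))
    }
    # ASIP exon 4 (whole-genome Dingo homozygous dominant-yellow)
    state <- if (i == 1L) "hom_ay"
             else if (i - 1L <= length(lc_asip)) lc_asip[i - 1L]
             else NA
    if (!is.na(state)) {
      g <- switch(state,
                  hom_ay = list(c("T", "T"), c("A", "A")),
                  het = list(c("T", "G"), c("A", "G")),
                  hom_wt = list(c("G", "G"), c("G", "G")))
      calls <- rbind(calls,
                     make_call(id, "ASIP_A82", g[[1]][1], g[[1]][2]),
                     make_call(id, "ASIP_R83", g[[2]][1], g[[2]][2]),
                     make_call(id, "ASIP_R92", "C", "C"))
    }
  }
  new_cohort(samples, calls, default_panel())
}
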