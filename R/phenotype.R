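#' Epistatic prediction of coat color and ear carriage
#'
#' The engine reproduces, deterministically, the genotype-to-phenotype
#' reasoning applied by hand in canine coat-color genetics.  Locus states
#' are derived per classical locus (E, K, B, A, D, S) and combined under
#' the standard epistasis order:
#'
#' 1. E-locus `e/e` (MC1R p.R306*) blocks all eumelanin: the coat is
#'    ginger/cream regardless of every other locus, whose effects are
#'    reported only as carrier notes, and the melanistic mask cannot show.
#' 2. Otherwise K-locus dominant black (CBD103 deletion) forces a solid
#'    (self-colored) coat, suppressing A-locus patterning; the base hue
#'    (black vs brown) still follows the B-locus.
#' 3. Otherwise the A-locus decides patterning: tan points (`at/at`),
#'    dominant yellow/sable (`Ay`), or recessive black (`a/a`).
#' 4. B-locus (TYRP1, including compound heterozygotes across its variant
#'    sites) sets black vs brown eumelanin.
#' 5. Mask visibility follows the E-locus mask allele on non-ginger coats.
#' 6. D-locus (MLPH) dilution maps black to blue, brown to fawn and ginger
#'    to cream.
#' 7. S-locus (MITF) sets the expected extent of white markings.
#'
#' Missing genotype calls are imputed as homozygous reference and flag the
#' result `provisional`; low-coverage calls keep their alleles but also
#' flag `provisional`.  Contradictory genotypes degrade the affected field
#' to `"unknown"` with an explanatory rationale entry -- never an error.
#'
#' @name phenotype_engine
NULL

# ---- call plumbing ---------------------------------------------------------

#' Extract one sample's calls from a cohort
#'
#' @param cohort A `canid_cohort`.
#' @param sample_id Sample identifier.
#' @return A `data.frame` of that sample's calls (one row per panel site).
#' @export
sample_calls <- function(cohort, sample_id) {
  if (!sample_id %in% cohort$samples$sample_id) {
    stop("unknown sample ", sQuote(sample_id), call. = FALSE)
  }
  cohort$calls[cohort$calls$sample_id == sample_id, , drop = FALSE]
}

# genotype at a site with homozygous-reference imputation for missing calls;
# returns list(alleles = chr[2], provisional = lgl, imputed = lgl,
#              low_coverage = lgl)
site_genotype <- function(calls, site) {
  row <- calls[calls$site_id == site$site_id, , drop = FALSE]
  if (nrow(row) == 0L || row$status[1] == "missing") {
    return(list(alleles = rep(site$reference_allele, 2L),
                provisional = TRUE, imputed = TRUE, low_coverage = FALSE))
  }
  # calls may come from raw data frames: canonicalize allele order so that
  # predictions are invariant to heterozygote orientation
  list(alleles = order_call_alleles(row$allele1[1], row$allele2[1], site),
       provisional = row$status[1] == "low_coverage",
       imputed = FALSE, low_coverage = row$status[1] == "low_coverage")
}

n_allele <- function(g, allele) sum(g$alleles == allele)

locus_status <- function(locus_code, state, provisional = FALSE,
                         notes = character()) {
  structure(list(locus_code = locus_code, state = state,
                 provisional = provisional, notes = notes),
            class = "locus_status")
}

#' @export
print.locus_status <- function(x, ...) {
  cat("<locus_status> ", x$locus_code, ": ", x$state,
      if (x$provisional) " (provisional)" else "", "\n", sep = "")
  for (n in x$notes) cat("  - ", n, "\n", sep = "")
  invisible(x)
}

require_site <- function(panel, site_id, locus) {
  if (!site_id %in% panel_site_ids(panel)) {
    stop("panel lacks the ", site_id, " site required for the ", locus,
         " locus", call. = FALSE)
  }
  panel$sites[[site_id]]
}

# ---- single-site loci ------------------------------------------------------

#' Classify a single-site locus (E-ginger, E-mask, K or D)
#'
#' Recessive phenes require two copies of the phenotype allele, dominant
#' phenes one.  Missing calls are imputed as homozygous reference with
#' `provisional = TRUE`.  A low-coverage call at the D-locus yields state
#' `"unknown"`, since dilution cannot be asserted from thin coverage.
#'
#' @param calls A sample's calls, as from [sample_calls()].
#' @param locus One of `"E_ginger"`, `"E_mask"`, `"K"`, `"D"`.
#' @param panel The `canid_panel` (must contain the locus's site).
#' @return A `locus_status`.
#' @export
classify_simple_locus <- function(calls, locus = c("E_ginger", "E_mask", "K", "D"),
                                  panel) {
  locus <- match.arg(locus)
  spec <- switch(locus,
    E_ginger = list(site = "MC1R_ginger", code = "E",
                    hom = "ee_ginger", het = "carrier", none = "wildtype"),
    E_mask = list(site = "MC1R_mask", code = "E",
                  hom = "masked", het = "masked", none = "unmasked"),
    K = list(site = "CBD103_K", code = "K",
             hom = "dominant_black", het = "dominant_black", none = "non_black"),
    D = list(site = "MLPH_dilution", code = "D",
             hom = "dilute", het = "non_dilute", none = "non_dilute"))
  site <- require_site(panel, spec$site, locus)
  g <- site_genotype(calls, site)
  notes <- if (g$imputed)
    paste0(spec$site, " missing; imputed homozygous reference") else character()
  if (locus == "D" && g$low_coverage) {
    return(locus_status("D", "unknown", TRUE,
                        "low sequencing coverage at the dilution site"))
  }
  n <- n_allele(g, site$phenotype_allele)
  state <- if (n == 2L) spec$hom else if (n == 1L) spec$het else spec$none
  locus_status(spec$code, state, g$provisional, notes)
}

#' Classify the B-locus (TYRP1 brown) including compound heterozygotes
#'
#' Brown requires two brown-causing alleles counted across the four TYRP1
#' variant sites.  Two heterozygous sites are taken as a compound
#' heterozygote under an assumed-trans phasing and flagged `phase unknown`
#' (short-read data cannot distinguish cis configurations).
#'
#' @inheritParams classify_simple_locus
#' @return A `locus_status` with state `brown`, `brown_carrier` or
#'   `black_capable`.
#' @export
classify_b_locus <- function(calls, panel) {
  sites <- c("TYRP1_C41S", "TYRP1_Y185X", "TYRP1_Q331X", "TYRP1_345delP")
  total <- 0L
  n_het_sites <- 0L
  provisional <- FALSE
  notes <- character()
  for (sid in sites) {
    site <- require_site(panel, sid, "B")
    g <- site_genotype(calls, site)
    provisional <- provisional || g$provisional
    if (g$imputed) notes <- c(notes, paste0(sid, " missing; imputed homozygous reference"))
    n <- n_allele(g, site$phenotype_allele)
    total <- total + n
    if (n == 1L) n_het_sites <- n_het_sites + 1L
  }
  state <- if (total >= 2L) "brown" else if (total == 1L) "brown_carrier"
           else "black_capable"
  if (total >= 2L && n_het_sites >= 2L) {
    notes <- c(notes, "compound heterozygote across TYRP1 sites; trans phase assumed (phase unknown)")
  }
  locus_status("B", state, provisional, notes)
}

#' Classify the A-locus from the RALY/ASIP indels and ASIP exonic SNVs
#'
#' Tan-point (`at`) requires homozygous insertion at both the RALY 16-bp
#' duplication and the ASIP 239-base insertion, with exonic alleles
#' consistent with the wild-type codons; dominant yellow (`Ay`) requires a
#' deletion haplotype at those indels together with Ay-consistent exonic
#' alleles; homozygosity for the recessive-black exonic allele gives `a`.
#' A saddle (`as`) modifier note is recorded whenever the RALY deletion is
#' present on an Ay background.  Self-contradictory genotypes degrade to
#' `"unknown"` with an explanatory note.
#'
#' @inheritParams classify_simple_locus
#' @return A `locus_status`.
#' @export
classify_a_locus <- function(calls, panel) {
  raly <- site_genotype(calls, require_site(panel, "RALY_dup", "A"))
  ins239 <- site_genotype(calls, require_site(panel, "ASIP_ins239", "A"))
  a82 <- site_genotype(calls, require_site(panel, "ASIP_A82", "A"))
  r83 <- site_genotype(calls, require_site(panel, "ASIP_R83", "A"))
  r92 <- site_genotype(calls, require_site(panel, "ASIP_R92", "A"))
  provisional <- raly$provisional || ins239$provisional || a82$provisional ||
    r83$provisional || r92$provisional
  notes <- character()
  for (g in list(raly, ins239, a82, r83, r92)) {
    if (g$imputed) provisional <- TRUE
  }
  if (any(vapply(list(raly, ins239, a82, r83, r92), `[[`, TRUE, "imputed"))) {
    notes <- c(notes, "one or more A-locus calls missing; imputed homozygous reference")
  }

  if (n_allele(r92, "T") == 2L) {
    return(locus_status("A", "recessive_black_a", provisional,
                        c(notes, "homozygous recessive-black exonic allele (a/a)")))
  }
  at_hom <- n_allele(raly, "ins") == 2L && n_allele(ins239, "ins") == 2L
  ay_exonic <- n_allele(a82, "T") >= 1L || n_allele(r83, "A") >= 1L
  if (at_hom) {
    if (ay_exonic) {
      return(locus_status("A", "unknown", provisional,
                          c(notes, "tan-point indels conflict with dominant-yellow exonic alleles")))
    }
    return(locus_status("A", "tan_point_at", provisional,
                        c(notes, "homozygous insertion at RALY duplication and ASIP 239-base insertion")))
  }
  ay_indel <- n_allele(raly, "del") >= 1L && n_allele(ins239, "del") >= 1L
  if (ay_indel && ay_exonic) {
    if (n_allele(raly, "del") >= 1L) {
      notes <- c(notes, "RALY deletion present with Ay: saddle (as) patterning possible")
    }
    return(locus_status("A", "dominant_yellow_Ay", provisional,
                        c(notes, "deletion haplotype at A-locus indels with Ay-consistent exonic alleles")))
  }
  locus_status("A", "unknown", provisional,
               c(notes, "A-locus indel and exonic genotypes do not form a recognised haplotype"))
}

#' Classify the S-locus (MITF white spotting)
#'
#' Homozygosity for the SINE insertion predicts piebald/extreme white.
#' Otherwise white extent is graded by the two promoter length-polymorphism
#' alleles against the 35-base reference: both at least 35 bases predicts
#' modest white; both shorter predicts no more than minimal white; mixed
#' lengths are intermediate (reported as modest, with a note, since the
#' alleles act co-dominantly).
#'
#' @inheritParams classify_simple_locus
#' @param registry Allele-label registry used to resolve length alleles.
#' @return A `locus_status`.
#' @export
classify_s_locus <- function(calls, panel, registry = panel$registry) {
  sine <- site_genotype(calls, require_site(panel, "MITF_SINE", "S"))
  lp_site <- require_site(panel, "MITF_length", "S")
  lp <- site_genotype(calls, lp_site)
  provisional <- sine$provisional || lp$provisional ||
    sine$imputed || lp$imputed
  notes <- character()
  if (sine$imputed || lp$imputed) {
    notes <- c(notes, "S-locus call(s) missing; imputed homozygous reference")
  }
  if (n_allele(sine, "ins") == 2L) {
    return(locus_status("S", "white_extensive", provisional,
                        c(notes, "homozygous MITF SINE insertion: piebald/extreme white predicted")))
  }
  lens <- vapply(lp$alleles, function(a) {
    allele_length(resolve_allele_code(a, registry))
  }, 1L)
  ref_len <- allele_length(lp_site$reference_allele)
  state <- if (all(lens >= ref_len)) "white_modest"
           else if (all(lens < ref_len)) "white_none"
           else "white_modest"
  if (any(lens >= ref_len) && any(lens < ref_len)) {
    notes <- c(notes, "mixed promoter allele lengths: intermediate white extent (co-dominant), reported as modest")
  }
  locus_status("S", state, provisional, notes)
}

# ---- coat prediction -------------------------------------------------------

new_coat_prediction <- function(base_color, tan_points, mask_visible,
                                dilution, white_extent, carrier_notes,
                                provisional, rationale) {
  structure(list(base_color = base_color, tan_points = tan_points,
                 mask_visible = mask_visible, dilution = dilution,
                 white_extent = white_extent, carrier_notes = carrier_notes,
                 provisional = provisional, rationale = rationale),
            class = "coat_prediction")
}

#' Predict coat color from a sample's panel genotypes
#'
#' @param calls A sample's calls, as from [sample_calls()].
#' @param panel The `canid_panel`.
#' @return A `coat_prediction` with fields `base_color` (black, brown,
#'   sable_fawn, ginger_cream or unknown), `tan_points`, `mask_visible`,
#'   `dilution` (none, dilute, unknown), `white_extent` (none_or_minimal,
#'   modest, piebald_extreme, unknown), `carrier_notes`, `provisional`, and
#'   an ordered `rationale` of fired rules.
#' @export
predict_coat <- function(calls, panel) {
  e <- classify_simple_locus(calls, "E_ginger", panel)
  em <- classify_simple_locus(calls, "E_mask", panel)
  k <- classify_simple_locus(calls, "K", panel)
  b <- classify_b_locus(calls, panel)
  a <- classify_a_locus(calls, panel)
  s <- classify_s_locus(calls, panel)
  d <- if ("MLPH_dilution" %in% panel_site_ids(panel)) {
    classify_simple_locus(calls, "D", panel)
  } else NULL

  rationale <- character()
  carrier <- character()
  add <- function(r, msg) c(r, msg)

  eumelanin_base <- if (b$state == "brown") "brown" else "black"

  if (e$state == "ee_ginger") {
    base <- "ginger_cream"
    tan <- FALSE
    mask <- FALSE
    rationale <- add(rationale, "E-locus e/e: eumelanin blocked, coat is ginger/cream; mask cannot show on this background")
    if (k$state == "dominant_black") carrier <- c(carrier, "carries dominant black")
    if (b$state %in% c("brown", "brown_carrier")) carrier <- c(carrier, "carries brown")
    if (a$state == "tan_point_at") carrier <- c(carrier, "carries tan-point (at)")
  } else {
    if (k$state == "dominant_black") {
      base <- eumelanin_base
      tan <- FALSE
      rationale <- add(rationale, paste0(
        "K-locus dominant black: solid (self-colored) coat, A-locus patterning suppressed; base ",
        base, " from B-locus"))
    } else if (a$state == "tan_point_at") {
      base <- eumelanin_base
      tan <- TRUE
      rationale <- add(rationale, paste0(
        "A-locus at/at: tan-point patterning on a ", base, " base (B-locus)"))
    } else if (a$state == "dominant_yellow_Ay") {
      base <- "sable_fawn"
      tan <- FALSE
      rationale <- add(rationale, "A-locus Ay: dominant yellow (sable/fawn) coat")
    } else if (a$state == "recessive_black_a") {
      base <- eumelanin_base
      tan <- FALSE
      rationale <- add(rationale, paste0(
        "A-locus a/a: recessive solid ", base, " (B-locus hue)"))
    } else {
      base <- "unknown"
      tan <- NA
      rationale <- add(rationale, "A-locus state unresolved: base color and patterning unknown")
    }
    mask <- em$state == "masked" && !identical(base, "ginger_cream")
    if (em$state == "masked") {
      rationale <- add(rationale, if (mask)
        "E-locus mask allele present: melanistic mask visible" else
        "E-locus mask allele present but not visible on this coat")
    }
    if (e$state == "carrier") carrier <- c(carrier, "carries red/yellow")
    if (b$state == "brown_carrier") carrier <- c(carrier, "carries brown")
  }
  if (!identical(base, "brown") && b$state == "brown" && e$state == "ee_ginger") {
    # carrier note already recorded above
  }
  if (b$state == "brown" && !identical(base, "unknown") &&
      base %in% c("brown")) {
    rationale <- add(rationale, "B-locus brown (two TYRP1 brown alleles): eumelanin is brown")
  }

  dilution <- if (is.null(d)) {
    rationale <- add(rationale, "no D-locus site in panel: dilution not assessed")
    "unknown"
  } else if (d$state == "dilute") {
    rationale <- add(rationale, "D-locus d/d: color diluted (black->blue, brown->fawn, ginger->cream)")
    "dilute"
  } else if (d$state == "unknown") {
    rationale <- add(rationale, "D-locus unreadable (low coverage): dilution unknown")
    "unknown"
  } else "none"

  white <- switch(s$state,
                  white_extensive = "piebald_extreme",
                  white_modest = "modest",
                  white_none = "none_or_minimal",
                  "unknown")
  rationale <- add(rationale, paste0("S-locus: expected white extent ", white))
  rationale <- c(rationale, a$notes[grepl("conflict|unrecognised|recognised", a$notes)])

  provisional <- any(e$provisional, em$provisional, k$provisional,
                     b$provisional, a$provisional, s$provisional,
                     if (is.null(d)) FALSE else d$provisional)
  if (provisional) {
    rationale <- add(rationale, "one or more contributing genotypes missing or low-coverage: prediction provisional")
  }
  new_coat_prediction(base, tan, mask, dilution, white, unique(carrier),
                      provisional, rationale)
}

#' @export
print.coat_prediction <- function(x, ...) {
  cat("<coat_prediction> ", x$base_color,
      if (isTRUE(x$tan_points)) " with tan points" else "",
      if (isTRUE(x$mask_visible)) ", masked" else "",
      if (x$dilution == "dilute") ", dilute" else "",
      "; white: ", x$white_extent,
      if (x$provisional) " [provisional]" else "", "\n", sep = "")
  if (length(x$carrier_notes)) {
    cat("  carriers: ", paste(x$carrier_notes, collapse = "; "), "\n", sep = "")
  }
  cat("  rationale:\n")
  for (r in x$rationale) cat("   - ", r, "\n", sep = "")
  invisible(x)
}

# ---- ear prediction --------------------------------------------------------

#' Predict ear carriage from the two MSRB3-region sites
#'
#' The intergenic MSRB3--HMGA2 SNP calls prick (T/T), drop (C/C) or
#' possibly semi-erect (C/T); the MSRB3 3'UTR insertion calls prick
#' (insertion on both haplotypes) or drop (del/del).  The consensus is
#' `discordant` only when both per-locus calls are informative and
#' conflict; a low-coverage UTR call is treated as unknown and flags the
#' prediction provisional.
#'
#' @inheritParams classify_simple_locus
#' @return An `ear_prediction` with `snp_call`, `utr_call`, `consensus`,
#'   `provisional` and `rationale`.
#' @export
predict_ears <- function(calls, panel) {
  snp_site <- require_site(panel, "MSRB3_HMGA2_SNP", "EAR")
  utr_site <- require_site(panel, "MSRB3_UTR_ins", "EAR")
  rationale <- character()
  provisional <- FALSE

  g <- site_genotype(calls, snp_site)
  if (g$imputed) {
    snp <- "unknown"; provisional <- TRUE
    rationale <- c(rationale, "intergenic SNP call missing")
  } else {
    nt <- n_allele(g, "T")
    snp <- if (nt == 2L) "prick" else if (nt == 0L) "drop" else "semi_erect_possible"
    provisional <- provisional || g$low_coverage
    rationale <- c(rationale, paste0("intergenic SNP ", g$alleles[1], "/",
                                     g$alleles[2], ": ", snp))
  }

  g <- site_genotype(calls, utr_site)
  if (g$imputed) {
    utr <- "unknown"; provisional <- TRUE
    rationale <- c(rationale, "3'UTR insertion call missing")
  } else if (g$low_coverage) {
    utr <- "unknown"; provisional <- TRUE
    rationale <- c(rationale, "3'UTR call low-coverage: does not exclude heterozygosity, treated as unknown")
  } else {
    n_ins <- sum(grepl("^ins", g$alleles))
    utr <- if (n_ins == 2L) "prick" else if (n_ins == 0L) "drop" else "heterozygous"
    rationale <- c(rationale, paste0("3'UTR ", g$alleles[1], "/",
                                     g$alleles[2], ": ", utr))
  }

  consensus <- if (snp == "semi_erect_possible") {
    "semi_erect_possible"
  } else if (snp %in% c("prick", "drop") && utr %in% c("prick", "drop")) {
    if (snp == utr) snp else "discordant"
  } else if (snp %in% c("prick", "drop")) {
    snp
  } else if (utr %in% c("prick", "drop")) {
    utr
  } else {
    "unknown"
  }
  rationale <- c(rationale, paste0("consensus: ", consensus))
  structure(list(snp_call = snp, utr_call = utr, consensus = consensus,
                 provisional = provisional, rationale = rationale),
            class = "ear_prediction")
}

#' @export
print.ear_prediction <- function(x, ...) {
  cat("<ear_prediction> ", x$consensus,
      if (x$provisional) " [provisional]" else "",
      "  (SNP: ", x$snp_call, "; UTR: ", x$utr_call, ")\n", sep = "")
  invisible(x)
}

# ---- cohort-level wrapper --------------------------------------------------

#' Predict phenotypes for every sample in a cohort
#'
#' @param cohort A `canid_cohort`.
#' @param explain Append a semicolon-joined rationale column.
#' @return A `data.frame` with one row per sample: coat fields, ear fields
#'   and provisional flags.
#' @export
predict_cohort <- function(cohort, explain = FALSE) {
  out <- do.call(rbind, lapply(cohort$samples$sample_id, function(id) {
    calls <- sample_calls(cohort, id)
    coat <- predict_coat(calls, cohort$panel)
    ears <- predict_ears(calls, cohort$panel)
    df <- data.frame(sample_id = id,
                     base_color = coat$base_color,
                     tan_points = coat$tan_points,
                     mask_visible = coat$mask_visible,
                     dilution = coat$dilution,
                     white_extent = coat$white_extent,
                     carrier_notes = paste(coat$carrier_notes, collapse = "; "),
                     coat_provisional = coat$provisional,
                     ear_consensus = ears$consensus,
                     ear_provisional = ears$provisional,
                     stringsAsFactors = FALSE)
    if (explain) {
      df$rationale <- paste(c(coat$rationale, ears$rationale), collapse = " | ")
    }
    df
  }))
  rownames(out) <- NULL
  merge(cohort$samples, out, by = "sample_id", sort = FALSE)
}

#' Is a coat prediction consistent with an owner-declared color?
#'
#' Understands the declared strings used in working-dog registries:
#' `"Brown"`, `"Black"`, `"Black and Tan"`, `"Brown and Tan"`, `"Ginger"`,
#' `"Cream"`.  A declaration without "and Tan" requires tan points absent.
#'
#' @param prediction A `coat_prediction`.
#' @param declared Declared color string (`NA` returns `NA`).
#' @return Logical.
#' @export
coat_matches_declared <- function(prediction, declared) {
  if (is.na(declared)) return(NA)
  d <- tolower(declared)
  want_tan <- grepl("tan", d)
  want_base <- if (grepl("brown|red", d)) "brown"
               else if (grepl("black|blue", d)) "black"
               else if (grepl("ginger|cream|yellow", d)) "ginger_cream"
               else return(NA)
  identical(prediction$base_color, want_base) &&
    identical(isTRUE(prediction$tan_points), want_tan)
}
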