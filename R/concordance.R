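#' Cross-population allele concordance and divergence reporting
#'
#' These tools operationalize the allele-sharing argument used to assess
#' whether two canid populations share recent ancestry at the morphology
#' panel: per-site allele counts and frequencies, fixed-difference flags
#' (called allele sets disjoint), and a locus-level divergence verdict that
#' also recognises "same phene, different causal locus" -- e.g. a yellow
#' coat arising from MC1R e/e in one population but from ASIP dominant
#' yellow in the other.
#'
#' @name concordance
NULL

#' The population labels that constitute "Kelpie"
#'
#' Conformation (AK), working (AWK) and undocumented-type Kelpies.
#' @return Character vector of population labels.
#' @export
kelpie_populations <- function() c("AK", "AWK", "Kelpie_unspecified")

#' Allele counts for one site in one population
#'
#' Counts called alleles only (low-coverage calls are included: they carry
#' alleles); missing calls are excluded from the denominator and tallied
#' separately, so counts always sum to `2 * (n_samples - n_missing_calls)`.
#'
#' @param cohort A `canid_cohort`.
#' @param population One or more population labels (e.g.
#'   [kelpie_populations()] or `"Dingo"`).
#' @param site_id Panel site.
#' @return An `allele_counts` object.
#' @export
allele_counts <- function(cohort, population, site_id) {
  if (!site_id %in% panel_site_ids(cohort$panel)) {
    stop("unknown site ", sQuote(site_id), call. = FALSE)
  }
  ids <- cohort$samples$sample_id[cohort$samples$population %in% population]
  if (!length(ids)) {
    stop("no samples in population(s) ", paste(population, collapse = "/"),
         call. = FALSE)
  }
  cl <- cohort$calls[cohort$calls$site_id == site_id &
                     cohort$calls$sample_id %in% ids, , drop = FALSE]
  called <- cl$status != "missing"
  counts <- table(c(cl$allele1[called], cl$allele2[called]))
  structure(list(site_id = site_id,
                 population = paste(population, collapse = "/"),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_samples = length(ids),
                 n_missing_calls = sum(!called)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("<allele_counts> ", x$site_id, " in ", x$population, " (n=",
      x$n_samples, ", missing=", x$n_missing_calls, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Allele frequencies from allele counts
#'
#' @param counts An `allele_counts` object.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  total <- sum(counts$counts)
  if (total == 0L) {
    stop("no called alleles at ", counts$site_id, " in ", counts$population,
         ": frequency undefined", call. = FALSE)
  }
  counts$counts / total
}

#' Fixed difference between two populations at one site
#'
#' `TRUE` iff the called allele sets are disjoint.
#'
#' @param countsA,countsB `allele_counts` for the same site.
#' @return Logical.
#' @export
fixed_difference <- function(countsA, countsB) {
  stopifnot(inherits(countsA, "allele_counts"),
            inherits(countsB, "allele_counts"))
  if (!identical(countsA$site_id, countsB$site_id)) {
    stop("allele counts are for different sites: ", countsA$site_id, " vs ",
         countsB$site_id, call. = FALSE)
  }
  if (sum(countsA$counts) == 0L || sum(countsB$counts) == 0L) {
    stop("fixed_difference needs at least one called allele per population",
         call. = FALSE)
  }
  length(intersect(names(countsA$counts)[countsA$counts > 0L],
                   names(countsB$counts)[countsB$counts > 0L])) == 0L
}

# proportion of samples whose A-locus state is dominant_yellow_Ay, and the
# E-locus ginger allele frequency, for the yellow-mechanism comparison
yellow_mechanism <- function(cohort, population) {
  ids <- cohort$samples$sample_id[cohort$samples$population %in% population]
  e_freq <- tryCatch({
    ac <- allele_counts(cohort, population, "MC1R_ginger")
    f <- allele_frequency(ac)
    if ("A" %in% names(f)) unname(f["A"]) else 0
  }, error = function(e) NA_real_)
  states <- vapply(ids, function(id) {
    classify_a_locus(sample_calls(cohort, id), cohort$panel)$state
  }, "")
  ay_prop <- mean(states == "dominant_yellow_Ay")
  mech <- if (is.na(e_freq)) NA_character_
          else if (e_freq == 0 && ay_prop == 0) "none"
          else if (ay_prop >= e_freq) "ASIP_Ay" else "MC1R_e"
  list(e_freq = e_freq, ay_prop = ay_prop, mechanism = mech)
}

#' Locus-level divergence report between two populations
#'
#' Computes per-site allele counts, frequencies, shared-variant and
#' fixed-difference flags, then classifies each locus (gene) as
#' `concordant`, `segregating_shared` or `diverged`.  A locus is diverged
#' when any of its sites shows a fixed difference, or when the two
#' populations achieve the same phene through different causal loci (the
#' yellow-coat mechanism check, which compares the E-locus ginger allele
#' against the A-locus dominant-yellow state).
#'
#' @param cohort A `canid_cohort` containing both populations.
#' @param popA,popB Population label(s) for each side.
#' @return A `concordance_report`: `per_site` data.frame, `locus_class`
#'   data.frame, `verdict` list.
#' @export
divergence_report <- function(cohort, popA, popB) {
  panel <- cohort$panel
  labA <- paste(popA, collapse = "/")
  labB <- paste(popB, collapse = "/")
  if (!any(cohort$samples$population %in% popA)) {
    stop("no samples in population ", labA, call. = FALSE)
  }
  if (!any(cohort$samples$population %in% popB)) {
    stop("no samples in population ", labB, call. = FALSE)
  }
  rows <- lapply(panel$sites, function(site) {
    ca <- allele_counts(cohort, popA, site$site_id)
    cb <- allele_counts(cohort, popB, site$site_id)
    okA <- sum(ca$counts) > 0L
    okB <- sum(cb$counts) > 0L
    freq_str <- function(cc) {
      if (sum(cc$counts) == 0L) return(NA_character_)
      f <- allele_frequency(cc)
      paste(sprintf("%s=%.3g", names(f), f), collapse = ",")
    }
    data.frame(site_id = site$site_id, gene = site$gene,
               locus_code = site$locus_code,
               freq_A = freq_str(ca), freq_B = freq_str(cb),
               n_called_A = ca$n_samples - ca$n_missing_calls,
               n_called_B = cb$n_samples - cb$n_missing_calls,
               shared_variant = if (okA && okB) !fixed_difference(ca, cb) else NA,
               fixed_difference = if (okA && okB) fixed_difference(ca, cb) else NA,
               polymorphic = (length(ca$counts[ca$counts > 0]) > 1L) ||
                 (length(cb$counts[cb$counts > 0]) > 1L),
               stringsAsFactors = FALSE)
  })
  per_site <- do.call(rbind, rows)
  rownames(per_site) <- NULL

  mechA <- yellow_mechanism(cohort, popA)
  mechB <- yellow_mechanism(cohort, popB)
  mech_diverged <- !is.na(mechA$mechanism) && !is.na(mechB$mechanism) &&
    mechA$mechanism != "none" && mechB$mechanism != "none" &&
    mechA$mechanism != mechB$mechanism
  mech_genes <- if (mech_diverged) c("MC1R", "ASIP") else character()

  locus_class <- do.call(rbind, lapply(unique(per_site$gene), function(g) {
    sub <- per_site[per_site$gene == g, , drop = FALSE]
    informative <- !is.na(sub$fixed_difference)
    cls <- if (!any(informative)) {
      "uninformative"
    } else if (any(sub$fixed_difference[informative])) {
      "diverged"
    } else if (g %in% mech_genes) {
      "diverged"
    } else if (any(sub$polymorphic[informative])) {
      "segregating_shared"
    } else {
      "concordant"
    }
    reason <- if (identical(cls, "diverged")) {
      if (any(sub$fixed_difference[informative])) {
        paste0("fixed difference at ",
               paste(sub$site_id[informative & sub$fixed_difference], collapse = ", "))
      } else {
        paste0("same phene, different causal locus: yellow via ",
               mechA$mechanism, " in ", labA, " vs ", mechB$mechanism,
               " in ", labB)
      }
    } else ""
    data.frame(gene = g, classification = cls, reason = reason,
               stringsAsFactors = FALSE)
  }))
  rownames(locus_class) <- NULL

  diverged <- locus_class$gene[locus_class$classification == "diverged"]
  statement <- if (length(diverged)) {
    paste0("Populations ", labA, " and ", labB, " are diverged at ",
           length(diverged), " locus/loci (", paste(diverged, collapse = ", "),
           "): the data do not support a history of significant introgression ",
           "at the morphology panel.")
  } else {
    paste0("Populations ", labA, " and ", labB,
           " are concordant at the morphology panel (no fixed differences).")
  }
  structure(list(population_a = labA, population_b = labB,
                 per_site = per_site, locus_class = locus_class,
                 verdict = list(n_diverged = length(diverged),
                                diverged_loci = diverged,
                                statement = statement)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$population_a, " vs ", x$population_b, "\n",
      sep = "")
  print(x$locus_class, row.names = FALSE)
  cat("\n", x$verdict$statement, "\n", sep = "")
  invisible(x)
}
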