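#' Synthetic diploid cohorts at the morphology panel
#'
#' Genotypes are drawn per site under Hardy-Weinberg proportions at
#' configured allele frequencies, independently across sites -- except the
#' A-locus, where the RALY duplication, the ASIP 239-base insertion and the
#' two dominant-yellow exonic SNVs are sampled as two-allele haplotypes
#' (Ay vs at), because independent sampling would fabricate A-locus states
#' never seen in real dogs.  Missing calls and a localized low-coverage
#' dropout (emulating the GC-rich MLPH region) are injected at configured
#' rates.  Identical seeds give identical cohorts.
#'
#' @name synthetic_cohorts
NULL

.AY_HAP <- c(RALY_dup = "del", ASIP_ins239 = "del", ASIP_A82 = "T",
             ASIP_R83 = "A")
.AT_HAP <- c(RALY_dup = "ins", ASIP_ins239 = "ins", ASIP_A82 = "G",
             ASIP_R83 = "G")
.A_HAP_SITES <- names(.AY_HAP)

# Empirical per-population allele frequencies from the packaged cohorts;
# sites with no called alleles in a population fall back to monomorphic
# reference.  These defaults describe the study populations, not estimates
# for the breeds at large.
default_sim_freqs <- function(panel = default_panel()) {
  tables <- load_paper_fixture("tables")
  dingo <- load_paper_fixture("dingo_panel")
  lc_sites <- c("MC1R_ginger", "CBD103_K", "ASIP_A82", "ASIP_R83", "ASIP_R92")
  freq_or_null <- function(cohort, pops, sid) {
    tryCatch({
      if (sid %in% panel_site_ids(cohort$panel)) {
        allele_frequency(allele_counts(cohort, pops, sid))
      } else NULL
    }, error = function(e) NULL)
  }
  out <- list(Kelpie = list(), Dingo = list())
  for (sid in panel_site_ids(panel)) {
    ref_mono <- stats::setNames(1, panel$sites[[sid]]$reference_allele)
    fk <- freq_or_null(tables, kelpie_populations(), sid)
    out$Kelpie[[sid]] <- if (is.null(fk)) ref_mono else fk
    # the 26-Dingo set covers the locus-constrained sites; the remaining
    # sites come from the single whole-genome Dingo
    fd <- if (sid %in% lc_sites) freq_or_null(dingo, "Dingo", sid)
          else freq_or_null(tables, "Dingo", sid)
    out$Dingo[[sid]] <- if (is.null(fd)) ref_mono else fd
  }
  out
}

# Ay haplotype frequency per population, estimated from the packaged
# cohorts (exonic dominant-yellow allele frequency).
default_ay_freq <- function() {
  tables <- load_paper_fixture("tables")
  dingo <- load_paper_fixture("dingo_panel")
  kel <- allele_frequency(allele_counts(tables, kelpie_populations(), "ASIP_A82"))
  din <- allele_frequency(allele_counts(dingo, "Dingo", "ASIP_A82"))
  c(Kelpie = if ("T" %in% names(kel)) unname(kel["T"]) else 0,
    Dingo = if ("T" %in% names(din)) unname(din["T"]) else 0)
}

#' Build a simulation configuration
#'
#' @param seed Integer random seed (mandatory: simulated cohorts must be
#'   reproducible).
#' @param populations Named integer vector of sample sizes, e.g.
#'   `c(Kelpie = 50, Dingo = 26)`.
#' @param site_freqs Per-population allele-frequency lists:
#'   `site_freqs[[pop]][[site_id]]` is a named numeric vector over the
#'   site's alleles, summing to 1.  Defaults to the empirical frequencies
#'   of the packaged study cohorts.  A-locus haplotype sites are driven by
#'   `ay_freq` instead and ignored here.
#' @param ay_freq Named numeric: frequency of the dominant-yellow (Ay)
#'   haplotype per population (the complement is the tan-point haplotype).
#' @param missing_rate Per-site missing-call probability (scalar, or a
#'   named vector by site_id).
#' @param low_coverage_sites Site ids subject to localized coverage
#'   dropout; defaults to the MLPH dilution site when the panel carries it.
#' @param dropout_rate Probability that a call at a dropout site is flagged
#'   `low_coverage`.
#' @param panel Panel to simulate over; defaults to [default_panel()]
#'   extended with the MLPH dilution site so the dropout artifact has a
#'   target.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       populations = c(Kelpie = 50L, Dingo = 26L),
                       site_freqs = NULL,
                       ay_freq = NULL,
                       missing_rate = 0.02,
                       low_coverage_sites = NULL,
                       dropout_rate = 0.8,
                       panel = extend_panel(default_panel())) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config requires an explicit integer seed", call. = FALSE)
  }
  if (is.null(names(populations)) || any(populations < 0L)) {
    stop("populations must be a named vector of non-negative sizes",
         call. = FALSE)
  }
  if (is.null(site_freqs)) {
    site_freqs <- default_sim_freqs(panel)
    # MLPH is absent from the packaged cohorts; use an illustrative
    # low dilution-allele frequency for Kelpies (dilute dogs occur in the
    # working variety) and none for Dingoes
    if ("MLPH_dilution" %in% panel_site_ids(panel)) {
      if (!is.null(site_freqs$Kelpie)) {
        site_freqs$Kelpie$MLPH_dilution <- c(G = 0.9, A = 0.1)
      }
    }
  }
  if (is.null(ay_freq)) ay_freq <- default_ay_freq()
  for (pop in names(populations)) {
    if (is.null(site_freqs[[pop]])) {
      stop("no site frequencies configured for population ", sQuote(pop),
           call. = FALSE)
    }
    if (is.na(ay_freq[pop])) {
      stop("no Ay haplotype frequency for population ", sQuote(pop),
           call. = FALSE)
    }
    for (sid in setdiff(panel_site_ids(panel), .A_HAP_SITES)) {
      f <- site_freqs[[pop]][[sid]]
      if (is.null(f) || abs(sum(f) - 1) > 1e-8 || any(f < 0) || any(f > 1)) {
        stop("invalid allele frequencies for ", sid, " in ", pop, call. = FALSE)
      }
    }
  }
  if (any(ay_freq < 0) || any(ay_freq > 1)) {
    stop("ay_freq must lie in [0, 1]", call. = FALSE)
  }
  mr <- missing_rate
  if (any(mr < 0) || any(mr > 1)) stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must lie in [0, 1]", call. = FALSE)
  if (is.null(low_coverage_sites)) {
    low_coverage_sites <- intersect("MLPH_dilution", panel_site_ids(panel))
  }
  structure(list(seed = as.integer(seed), populations = populations,
                 site_freqs = site_freqs, ay_freq = ay_freq,
                 missing_rate = missing_rate,
                 low_coverage_sites = low_coverage_sites,
                 dropout_rate = dropout_rate, panel = panel),
            class = "sim_config")
}

site_missing_rate <- function(config, site_id) {
  mr <- config$missing_rate
  if (length(mr) == 1L && is.null(names(mr))) return(unname(mr))
  if (site_id %in% names(mr)) unname(mr[site_id]) else 0
}

#' Simulate a diploid cohort under a configuration
#'
#' @param config A [sim_config()].
#' @return A `canid_sim` list: `cohort` (a `canid_cohort`), `truth`
#'   (a data.frame of configured vs realized allele frequencies, computed
#'   before missingness masking) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  sids <- panel_site_ids(panel)
  samples <- NULL
  calls <- NULL
  truth_rows <- list()
  for (pop in names(config$populations)) {
    n <- config$populations[[pop]]
    if (n == 0L) next
    ids <- sprintf("%s_S%03d", pop, seq_len(n))
    samples <- rbind(samples, data.frame(sample_id = ids, population = pop,
                                         stringsAsFactors = FALSE))
    # A-locus haplotypes
    pAy <- unname(config$ay_freq[pop])
    hap1 <- stats::rbinom(n, 1L, pAy)  # 1 = Ay
    hap2 <- stats::rbinom(n, 1L, pAy)
    geno <- list()
    for (sid in .A_HAP_SITES) {
      a1 <- ifelse(hap1 == 1L, .AY_HAP[sid], .AT_HAP[sid])
      a2 <- ifelse(hap2 == 1L, .AY_HAP[sid], .AT_HAP[sid])
      geno[[sid]] <- cbind(a1, a2)
    }
    for (sid in setdiff(sids, .A_HAP_SITES)) {
      f <- config$site_freqs[[pop]][[sid]]
      al <- names(f)
      geno[[sid]] <- cbind(sample(al, n, replace = TRUE, prob = f),
                           sample(al, n, replace = TRUE, prob = f))
    }
    realized_ay <- mean(c(hap1, hap2))
    for (sid in sids) {
      gm <- geno[[sid]]
      drawn <- c(gm[, 1], gm[, 2])
      if (sid %in% .A_HAP_SITES) {
        conf <- stats::setNames(c(pAy, 1 - pAy),
                                c(.AY_HAP[sid], .AT_HAP[sid]))
      } else {
        conf <- config$site_freqs[[pop]][[sid]]
      }
      for (al in names(conf)) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          population = pop, site_id = sid, allele = al,
          configured_freq = unname(conf[al]),
          realized_freq = mean(drawn == al), stringsAsFactors = FALSE)
      }
      miss <- stats::runif(n) < site_missing_rate(config, sid)
      lowcov <- (sid %in% config$low_coverage_sites) &
        (stats::runif(n) < config$dropout_rate)
      status <- ifelse(miss, "missing",
                       ifelse(lowcov, "low_coverage", "called"))
      calls <- rbind(calls, data.frame(
        sample_id = ids, site_id = sid,
        allele1 = ifelse(miss, NA_character_, gm[, 1]),
        allele2 = ifelse(miss, NA_character_, gm[, 2]),
        status = status, note = NA_character_, stringsAsFactors = FALSE))
    }
  }
  if (is.null(samples)) stop("all population sizes are zero", call. = FALSE)
  cohort <- new_cohort(samples, calls, panel, check_alleles = FALSE)
  structure(list(cohort = cohort,
                 truth = do.call(rbind, truth_rows),
                 config = config),
            class = "canid_sim")
}

#' @export
print.canid_sim <- function(x, ...) {
  cat("<canid_sim> seed ", x$config$seed, "\n", sep = "")
  print(x$cohort)
  invisible(x)
}
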