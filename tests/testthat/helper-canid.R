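# shared test helpers: small random objects built in code

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a canonical run-length code with `k` runs
random_canonical_code <- function(k = 5L) {
  bases <- character(k)
  bases[1] <- sample(c("A", "C", "G", "T"), 1)
  for (i in seq_len(k - 1L)) {
    bases[i + 1L] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste0(sample(1:20, k, replace = TRUE), bases, collapse = "")
}

# a small simulated two-population cohort for round-trip properties
small_sim <- function(seed, n_kelpie = 8L, n_dingo = 4L,
                      missing_rate = 0.1) {
  simulate_cohort(sim_config(
    seed = seed,
    populations = c(Kelpie = n_kelpie, Dingo = n_dingo),
    missing_rate = missing_rate))
}

# one sample's calls as an editable long data.frame, starting from a
# homozygous-reference genotype at every default-panel site
reference_calls <- function(panel = default_panel(), sample_id = "S1") {
  do.call(rbind, lapply(panel$sites, function(s) {
    data.frame(sample_id = sample_id, site_id = s$site_id,
               allele1 = s$reference_allele, allele2 = s$reference_allele,
               status = "called", note = NA_character_,
               stringsAsFactors = FALSE)
  }))
}

set_genotype <- function(calls, site_id, a1, a2, status = "called") {
  i <- calls$site_id == site_id
  calls$allele1[i] <- a1
  calls$allele2[i] <- a2
  calls$status[i] <- status
  calls
}

set_missing <- function(calls, site_id) {
  i <- calls$site_id == site_id
  calls$allele1[i] <- NA_character_
  calls$allele2[i] <- NA_character_
  calls$status[i] <- "missing"
  calls
}

# a random single-sample genotype vector over the default panel (drawing
# alleles uniformly per site, A-locus from consistent haplotypes)
random_calls <- function(panel = default_panel()) {
  ay <- c(RALY_dup = "del", ASIP_ins239 = "del", ASIP_A82 = "T", ASIP_R83 = "A")
  at <- c(RALY_dup = "ins", ASIP_ins239 = "ins", ASIP_A82 = "G", ASIP_R83 = "G")
  h1 <- sample(c(TRUE, FALSE), 1)
  h2 <- sample(c(TRUE, FALSE), 1)
  calls <- reference_calls(panel)
  for (s in panel$sites) {
    sid <- s$site_id
    if (sid %in% names(ay)) {
      a1 <- if (h1) ay[[sid]] else at[[sid]]
      a2 <- if (h2) ay[[sid]] else at[[sid]]
    } else {
      al <- c(s$reference_allele, s$alternate_alleles)
      a1 <- sample(al, 1)
      a2 <- sample(al, 1)
    }
    calls <- set_genotype(calls, sid, a1, a2)
  }
  calls
}
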