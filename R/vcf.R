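#' VCF input and output at panel sites
#'
#' Cohorts can be exchanged as VCF (v4.2) restricted to panel coordinates.
#' SNVs are written at the site position; indel-class records use the
#' conventional anchored representation at position-1, with the anchor base
#' prepended to every allele.  Where the panel does not define the literal
#' inserted sequence (the CBD103 and TYRP1 3-base indels and the MITF SINE),
#' a synthetic placeholder sequence of the correct length is used and
#' documented as such; the reader matches alleles by sequence where known
#' and by inserted length otherwise, so placeholder content never changes a
#' genotype.
#'
#' Two input dialects are supported, differing only in what an absent
#' record means for a panel site: `"all-sites"` treats absence as
#' homozygous reference, `"sites-only"` as a missing call.  Within a
#' present record, `./.` is always a missing call.
#'
#' @name canid_vcf
NULL

.VCF_ANCHOR <- "A"
.KNOWN_INS <- c(RALY_dup = "CCCCAGGTCAGAGTTT",
                ASIP_ins239 = NA)  # length 239, sequence not in the panel

# Nucleotide content of one panel allele (insertion side only for indels).
allele_seq <- function(site, allele, registry = default_registry()) {
  if (site$variant_class == "SNV") return(allele)
  if (site$variant_class == "length_polymorphism") {
    return(decode_run_length(resolve_allele_code(allele, registry)))
  }
  if (allele == "del") return("")
  if (grepl("^ins[ACGT]+$", allele)) return(sub("^ins", "", allele))
  if (allele == "ins") {
    known <- .KNOWN_INS[site$site_id]
    if (!is.na(known)) return(unname(known))
    span <- if (site$site_id == "ASIP_ins239") 239L
            else if (!is.na(site$end_position)) site$end_position - site$position + 1L
            else 4L
    # synthetic placeholder: the genomic insert sequence is not part of the
    # panel definition; only its length is meaningful
    return(substr(strrep("ACGT", ceiling(span / 4)), 1L, span))
  }
  allele
}

is_indel_class <- function(site) {
  site$variant_class %in% c("indel", "SINE_insertion")
}

# VCF (REF, ALT...) strings for a site, plus the panel allele each maps to.
vcf_alleles_for_site <- function(site, registry = default_registry(),
                                 extra = character()) {
  panel_al <- unique(c(site_alleles(site), extra))
  seqs <- vapply(panel_al, allele_seq, "", site = site, registry = registry)
  if (is_indel_class(site)) {
    list(pos = site$position - 1L,
         vcf = paste0(.VCF_ANCHOR, seqs), panel = panel_al)
  } else {
    list(pos = site$position, vcf = unname(seqs), panel = panel_al)
  }
}

#' Write a cohort as a VCF file
#'
#' Sample population and declared phenotypes are preserved in
#' `##canidmorph_sample` header lines so that [read_vcf()] round-trips the
#' cohort.  Genotypes carry a `DP` field; low-coverage calls are written
#' with `DP` below the reader's default threshold of 4.
#'
#' @param cohort A `canid_cohort`.
#' @param path Output path (plain text `.vcf`).
#' @param dialect `"all-sites"` writes a record for every panel site;
#'   `"sites-only"` omits records at which every sample is missing.
#' @return `path`, invisibly.
#' @export
write_simulated_vcf <- function(cohort, path,
                                dialect = c("all-sites", "sites-only")) {
  stopifnot(inherits(cohort, "canid_cohort"))
  dialect <- match.arg(dialect)
  panel <- cohort$panel
  samples <- cohort$samples
  meta <- c("##fileformat=VCFv4.2",
            "##source=canidmorph",
            paste0("##canidmorph_dialect=", dialect),
            paste0("##contig=<ID=", unique(vapply(panel$sites, `[[`, "", "chromosome")), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            vapply(seq_len(nrow(samples)), function(i) {
              paste0("##canidmorph_sample=", samples$sample_id[i], "|",
                     samples$population[i], "|",
                     ifelse(is.na(samples$declared_coat[i]), ".", samples$declared_coat[i]), "|",
                     ifelse(is.na(samples$declared_ears[i]), ".", samples$declared_ears[i]))
            }, ""))
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples$sample_id), collapse = "\t")
  rows <- character(0)
  for (site in panel$sites) {
    cl <- cohort$calls[cohort$calls$site_id == site$site_id, , drop = FALSE]
    cl <- cl[match(samples$sample_id, cl$sample_id), , drop = FALSE]
    if (dialect == "sites-only" && all(cl$status == "missing")) next
    called <- cl$status != "missing"
    extra <- setdiff(unique(c(cl$allele1[called], cl$allele2[called])),
                     site_alleles(site))
    va <- vcf_alleles_for_site(site, panel$registry, extra)
    gts <- vapply(seq_len(nrow(cl)), function(i) {
      if (cl$status[i] == "missing") return("./.:.")
      i1 <- match(cl$allele1[i], va$panel) - 1L
      i2 <- match(cl$allele2[i], va$panel) - 1L
      dp <- if (cl$status[i] == "low_coverage") 2L else 20L
      paste0(min(i1, i2), "/", max(i1, i2), ":", dp)
    }, "")
    alt <- if (length(va$vcf) > 1L) paste(va$vcf[-1], collapse = ",") else "."
    rows <- c(rows, paste(c(site$chromosome, va$pos, site$site_id, va$vcf[1],
                            alt, ".", "PASS", ".", "GT:DP", gts),
                          collapse = "\t"))
  }
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

parse_sample_meta <- function(meta_lines) {
  lines <- grep("^##canidmorph_sample=", meta_lines, value = TRUE)
  if (!length(lines)) return(NULL)
  parts <- strsplit(sub("^##canidmorph_sample=", "", lines), "|", fixed = TRUE)
  data.frame(sample_id = vapply(parts, `[[`, "", 1),
             population = vapply(parts, `[[`, "", 2),
             declared_coat = ifelse(vapply(parts, `[[`, "", 3) == ".", NA,
                                    vapply(parts, `[[`, "", 3)),
             declared_ears = ifelse(vapply(parts, `[[`, "", 4) == ".", NA,
                                    vapply(parts, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

# Map one VCF allele string back onto a panel allele.
match_vcf_allele <- function(vcf_allele, site, va) {
  hit <- match(vcf_allele, va$vcf)
  if (!is.na(hit)) return(va$panel[hit])
  if (is_indel_class(site)) {
    ins <- sub(paste0("^", .VCF_ANCHOR), "", vcf_allele)
    if (!nzchar(ins)) return("del")
    # fall back to matching by inserted length (placeholder sequences)
    lens <- nchar(va$vcf) - 1L
    hit <- match(nchar(ins), lens[va$panel != "del"])
    if (!is.na(hit)) return(va$panel[va$panel != "del"][hit])
    return(paste0("ins", ins))  # novel insertion allele
  }
  if (site$variant_class == "length_polymorphism") {
    return(encode_run_length(vcf_allele))  # possibly novel; keep as code
  }
  vcf_allele  # novel SNV allele
}

#' Read genotypes at panel sites from a VCF file
#'
#' @param path VCF path (plain or bgzipped).
#' @param panel A `canid_panel`.
#' @param dialect How to interpret a panel site with no overlapping record:
#'   `"sites-only"` (default) emits a missing call, `"all-sites"` assumes
#'   homozygous reference.  If the file carries a `##canidmorph_dialect`
#'   line and no dialect is given explicitly, the file's declaration wins.
#' @param low_coverage_depth Calls with `DP` below this many reads are
#'   flagged `low_coverage` (default 4, the conventional minimum per-allele
#'   read support for a confident call).
#' @param sample_info Optional `data.frame` (`sample_id`, `population`, ...)
#'   supplying sample metadata absent from the VCF.
#' @return A `canid_cohort`.
#' @export
read_vcf <- function(path, panel, dialect = NULL, low_coverage_depth = 4L,
                     sample_info = NULL) {
  stopifnot(inherits(panel, "canid_panel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  sample_ids <- colnames(gt)[-1]
  if (is.null(sample_ids) || !length(sample_ids)) {
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)
  }
  if (is.null(dialect)) {
    decl <- grep("^##canidmorph_dialect=", vcf@meta, value = TRUE)
    dialect <- if (length(decl)) sub("^##canidmorph_dialect=", "", decl[1]) else "sites-only"
  }
  dialect <- match.arg(dialect, c("sites-only", "all-sites"))

  samples <- parse_sample_meta(vcf@meta)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    if (!is.null(sample_info)) {
      samples <- merge(samples, sample_info, by = "sample_id", all.x = TRUE,
                       sort = FALSE)
    }
  }
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  samples$sample_id <- sample_ids

  calls <- NULL
  for (site in panel$sites) {
    va <- vcf_alleles_for_site(site, panel$registry)
    want_pos <- if (is_indel_class(site)) c(site$position - 1L, site$position)
                else site$position
    idx <- which(fix[, "CHROM"] == site$chromosome &
                 as.integer(fix[, "POS"]) %in% want_pos)
    if (length(idx) > 1L) {
      stop("contradictory duplicate records for site ", site$site_id,
           " at ", site$chromosome, ":", site$position, call. = FALSE)
    }
    if (length(idx) == 0L) {
      calls <- rbind(calls, if (dialect == "all-sites") {
        make_call(sample_ids, site$site_id,
                  site$reference_allele, site$reference_allele,
                  "called", "assumed homozygous reference (all-sites dialect)")
      } else {
        missing_call(sample_ids, site$site_id)
      })
      next
    }
    alt_str <- fix[idx, "ALT"]
    file_alleles <- c(fix[idx, "REF"],
                      if (!is.na(alt_str) && alt_str != ".")
                        strsplit(alt_str, ",", fixed = TRUE)[[1]])
    mapped <- vapply(file_alleles, match_vcf_allele, "",
                     site = site, va = va, USE.NAMES = FALSE)
    fmt <- strsplit(gt[idx, 1], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    dpi <- match("DP", fmt)
    for (j in seq_along(sample_ids)) {
      fields <- strsplit(gt[idx, j + 1L], ":", fixed = TRUE)[[1]]
      g <- if (is.na(gti) || length(fields) < gti) "./." else fields[gti]
      ai <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (length(ai) != 2L || any(is.na(ai))) {
        calls <- rbind(calls, missing_call(sample_ids[j], site$site_id))
        next
      }
      dp <- if (!is.na(dpi) && length(fields) >= dpi)
        suppressWarnings(as.integer(fields[dpi])) else NA_integer_
      status <- if (!is.na(dp) && dp < low_coverage_depth) "low_coverage" else "called"
      calls <- rbind(calls, make_call(sample_ids[j], site$site_id,
                                      mapped[ai[1] + 1L], mapped[ai[2] + 1L],
                                      status))
    }
  }
  new_cohort(samples, calls, panel)
}
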