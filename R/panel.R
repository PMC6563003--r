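#' Morphology variant panel
#'
#' A `canid_panel` bundles an ordered set of [variant_site()] records with an
#' allele-label registry.  The packaged default covers the sixteen sites that
#' determine the externally visible coat-color loci (E, B, K, A, S by the
#' classical nomenclature) plus two ear-carriage sites near MSRB3, all on
#' CanFam3.1 coordinates.
#'
#' @name canid_panel
NULL

.LOCUS_CODES <- c("A", "B", "D", "E", "K", "S", "EAR")
.VARIANT_CLASSES <- c("SNV", "indel", "length_polymorphism", "SINE_insertion")
.INHERITANCE <- c("dominant", "recessive", "codominant")

#' Define one panel variant site
#'
#' @param site_id Short unique key, e.g. `"MC1R_ginger"`.
#' @param chromosome Canine chromosome label (character).
#' @param position 1-based CanFam3.1 coordinate.
#' @param end_position 1-based inclusive end for multi-base records; `NA`
#'   for SNVs.
#' @param gene Gene symbol (or region label for intergenic sites).
#' @param locus_code One of A, B, D, E, K, S, EAR.
#' @param variant_class One of SNV, indel, length_polymorphism,
#'   SINE_insertion.
#' @param reference_allele Reference allele string or run-length code.
#' @param alternate_alleles Character vector of alternate alleles/codes.
#' @param phenotype_allele The allele causing the phene.  May be the
#'   reference: at several sites (melanistic mask, the MITF SINE, the ASIP
#'   dominant-yellow codons) the CanFam reference carries the
#'   phenotype-causing allele, so "reference" must not be read as
#'   "wild-type".
#' @param inheritance dominant, recessive or codominant.
#' @param phene_label Free-text phene description.
#' @param omia_code OMIA phene identifier, if catalogued.
#' @return A `variant_site` object (a validated named list).
#' @export
variant_site <- function(site_id, chromosome, position, end_position = NA,
                         gene, locus_code, variant_class,
                         reference_allele, alternate_alleles,
                         phenotype_allele, inheritance,
                         phene_label = "", omia_code = NA_character_) {
  site <- structure(
    list(site_id = as.character(site_id),
         chromosome = as.character(chromosome),
         position = as.integer(position),
         end_position = if (is.na(end_position)) NA_integer_ else as.integer(end_position),
         gene = as.character(gene),
         locus_code = as.character(locus_code),
         variant_class = as.character(variant_class),
         reference_allele = as.character(reference_allele),
         alternate_alleles = as.character(alternate_alleles),
         phenotype_allele = as.character(phenotype_allele),
         inheritance = as.character(inheritance),
         phene_label = as.character(phene_label),
         omia_code = as.character(omia_code)),
    class = "variant_site")
  validate_variant_site(site)
}

validate_variant_site <- function(site) {
  id <- site$site_id
  if (!nzchar(id)) stop("variant site must have a non-empty site_id", call. = FALSE)
  if (is.na(site$position) || site$position < 1L) {
    stop("site ", sQuote(id), ": position must be a 1-based coordinate", call. = FALSE)
  }
  if (!is.na(site$end_position) && site$end_position < site$position) {
    stop("site ", sQuote(id), ": end_position precedes position", call. = FALSE)
  }
  if (!site$locus_code %in% .LOCUS_CODES) {
    stop("site ", sQuote(id), ": unknown locus_code ", sQuote(site$locus_code), call. = FALSE)
  }
  if (!site$variant_class %in% .VARIANT_CLASSES) {
    stop("site ", sQuote(id), ": unknown variant_class ", sQuote(site$variant_class), call. = FALSE)
  }
  if (!site$inheritance %in% .INHERITANCE) {
    stop("site ", sQuote(id), ": unknown inheritance ", sQuote(site$inheritance), call. = FALSE)
  }
  alleles <- c(site$reference_allele, site$alternate_alleles)
  if (anyDuplicated(alleles)) {
    stop("site ", sQuote(id), ": duplicated allele strings", call. = FALSE)
  }
  if (!site$phenotype_allele %in% alleles) {
    stop("site ", sQuote(id), ": phenotype_allele ", sQuote(site$phenotype_allele),
         " is not among the site's alleles", call. = FALSE)
  }
  site
}

site_alleles <- function(site) c(site$reference_allele, site$alternate_alleles)

new_panel <- function(sites, registry = default_registry(),
                      version = "canfam3.1-morphology-1") {
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) {
    stop("duplicate site_id in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  coords <- paste(vapply(sites, `[[`, "", "chromosome"),
                  vapply(sites, function(s) s$position, 1L))
  if (anyDuplicated(coords)) {
    stop("two panel records share one coordinate: ",
         paste(unique(coords[duplicated(coords)]), collapse = "; "), call. = FALSE)
  }
  validate_registry(registry)
  names(sites) <- ids
  structure(list(sites = sites, registry = registry, version = version),
            class = "canid_panel")
}

#' The default 16-site CanFam3.1 morphology panel
#'
#' Fourteen coat-color sites (2 MC1R, 4 TYRP1, 1 CBD103, 2 MITF, 1 RALY,
#' 3 ASIP SNVs and the 239-base ASIP insertion) and two ear sites (the
#' MSRB3 3'UTR insertion polymorphism and the MSRB3--HMGA2 intergenic SNP).
#'
#' Indel records keep their published orientation: at CBD103 the insertion
#' is the reference allele and the deletion the dominant-black alternate;
#' no left-alignment normalization is applied here.
#'
#' @return A `canid_panel` of 16 sites.
#' @export
default_panel <- function() {
  s <- list(
    variant_site("MC1R_ginger", "5", 63694334, NA, "MC1R", "E", "SNV",
                 "G", "A", "A", "recessive",
                 "Ginger (p.R306*)", "001199-9615"),
    variant_site("MC1R_mask", "5", 63694460, NA, "MC1R", "E", "SNV",
                 "C", "T", "C", "dominant",
                 "Melanistic mask (p.M264V); mask allele is the reference C",
                 "001590-9615"),
    variant_site("TYRP1_C41S", "11", 33317810, NA, "TYRP1", "B", "SNV",
                 "T", "C", "C", "recessive",
                 "Brown (p.C41S)", "001249-9615"),
    variant_site("TYRP1_Y185X", "11", 33319349, NA, "TYRP1", "B", "SNV",
                 "T", "G", "G", "recessive",
                 "Brown (p.Tyr185*)", "001249-9615"),
    variant_site("TYRP1_Q331X", "11", 33326685, NA, "TYRP1", "B", "SNV",
                 "C", "T", "T", "recessive",
                 "Brown (p.Q331X)", "001249-9615"),
    variant_site("TYRP1_345delP", "11", 33326727, 33326729, "TYRP1", "B", "indel",
                 "ins", "del", "del", "recessive",
                 "Brown (p.345delP)", "001249-9615"),
    variant_site("CBD103_K", "16", 58965449, 58965451, "CBD103", "K", "indel",
                 "ins", "del", "del", "dominant",
                 "Black (dominant); the insertion (reference) permits A-locus colors",
                 "001416-9613"),
    variant_site("MITF_SINE", "20", 21836232, 21836427, "MITF", "S", "SINE_insertion",
                 "ins", "del", "ins", "recessive",
                 "SINE insertion associated with piebald/extreme white",
                 "000214-9615"),
    variant_site("MITF_length", "20", 21839321, 21839366, "MITF", "S",
                 "length_polymorphism",
                 "12C9A2G12A",
                 c("11C10A2G12A", "10C9A2G12A", "10C8A2G11A"),
                 "12C9A2G12A", "codominant",
                 "Promoter length polymorphism; longer alleles give more white",
                 "000214-9615"),
    variant_site("RALY_dup", "24", 23252754, 23252770, "RALY", "A", "indel",
                 "del", "ins", "ins", "recessive",
                 "16-bp duplication (dupCCCCAGGTCAGAGTTT): at is ins/ins, saddle as is del-",
                 "001806-9615"),
    variant_site("ASIP_ins239", "24", 23365298, NA, "ASIP", "A", "indel",
                 "del", "ins", "ins", "recessive",
                 "239-base insertion: at is ins/ins, Ay is del-", "000201-9615"),
    variant_site("ASIP_A82", "24", 23393510, NA, "ASIP", "A", "SNV",
                 "T", "G", "T", "dominant",
                 "Sable/fawn: Ay carries the reference T", "000201-9615"),
    variant_site("ASIP_R83", "24", 23393514, NA, "ASIP", "A", "SNV",
                 "A", "G", "A", "dominant",
                 "Sable/fawn: Ay carries the reference A", "000201-9615"),
    variant_site("ASIP_R92", "24", 23393552, NA, "ASIP", "A", "SNV",
                 "C", "T", "T", "recessive",
                 "Recessive black (a is T/T)", "000201-9615"),
    variant_site("MSRB3_UTR_ins", "10", 8038433, NA, "MSRB3_UTR", "EAR", "indel",
                 "del", c("insTTTATTTTAT", "insTTTAT"), "del", "recessive",
                 "3'UTR insertion polymorphism; drop ears are del/del", NA),
    variant_site("MSRB3_HMGA2_SNP", "10", 8085469, NA, "MSRB3_HMGA2_intergenic",
                 "EAR", "SNV",
                 "C", "T", "C", "recessive",
                 "Intergenic ear SNP; drop ears are C/C", "000319-9615")
  )
  new_panel(s)
}

#' Optional D-locus (MLPH dilution) site
#'
#' The dilution splice variant in MLPH is not part of the default panel
#' (genotypes over the region are usually unreadable in short-read data
#' because of high local GC content), but cohorts that do carry D-locus
#' calls can use a panel extended with this record.  The coordinate follows
#' the OMIA 000031-9615 entry for the c.-22G>A variant.
#'
#' @return A `variant_site` for the MLPH dilution variant.
#' @export
mlph_site <- function() {
  variant_site("MLPH_dilution", "25", 48121642, NA, "MLPH", "D", "SNV",
               "G", "A", "A", "recessive",
               "Dilution (c.-22G>A): black->blue, brown->fawn, ginger->cream",
               "000031-9615")
}

#' Extend a panel with additional sites
#'
#' @param panel A `canid_panel`.
#' @param sites A list of `variant_site` objects (default: [mlph_site()]).
#' @return A new `canid_panel`.
#' @export
extend_panel <- function(panel, sites = list(mlph_site())) {
  stopifnot(inherits(panel, "canid_panel"))
  if (inherits(sites, "variant_site")) sites <- list(sites)
  new_panel(c(unname(panel$sites), sites), panel$registry,
            paste0(panel$version, "+ext"))
}

#' Load a variant panel
#'
#' With no argument returns the compiled-in [default_panel()].  Otherwise
#' reads a YAML panel description (one document: `version`, `registry`
#' mapping labels to run-length codes, and a `sites` list whose entries
#' carry the [variant_site()] fields) and validates it.
#'
#' @param config_source Path to a YAML panel file, or `NULL` for the
#'   default.
#' @return A validated `canid_panel`.
#' @export
load_panel <- function(config_source = NULL) {
  if (is.null(config_source)) return(default_panel())
  doc <- yaml::read_yaml(config_source)
  if (is.null(doc$sites) || !length(doc$sites)) {
    stop("panel config has no sites: ", config_source, call. = FALSE)
  }
  sites <- lapply(doc$sites, function(x) {
    variant_site(site_id = x$site_id, chromosome = x$chromosome,
                 position = x$position,
                 end_position = if (is.null(x$end_position)) NA else x$end_position,
                 gene = x$gene, locus_code = x$locus_code,
                 variant_class = x$variant_class,
                 reference_allele = x$reference_allele,
                 alternate_alleles = unlist(x$alternate_alleles),
                 phenotype_allele = x$phenotype_allele,
                 inheritance = x$inheritance,
                 phene_label = if (is.null(x$phene_label)) "" else x$phene_label,
                 omia_code = if (is.null(x$omia_code)) NA else x$omia_code)
  })
  registry <- if (is.null(doc$registry)) default_registry() else unlist(doc$registry)
  new_panel(sites, registry,
            if (is.null(doc$version)) "user" else doc$version)
}

#' Write a panel to a YAML file
#'
#' `load_panel(write_panel(p, f))` reproduces `p` exactly.
#'
#' @param panel A `canid_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "canid_panel"))
  doc <- list(
    version = panel$version,
    registry = as.list(panel$registry),
    sites = lapply(unname(panel$sites), function(s) {
      s <- unclass(s)
      s$alternate_alleles <- as.list(s$alternate_alleles)
      if (is.na(s$end_position)) s$end_position <- NULL
      if (is.na(s$omia_code)) s$omia_code <- NULL
      s
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Look up a panel site
#'
#' @param panel A `canid_panel`.
#' @param key Either a `site_id` string, or a length-2 vector/list of
#'   `(chromosome, position)`.
#' @return The matching `variant_site`.
#' @export
get_site <- function(panel, key) {
  stopifnot(inherits(panel, "canid_panel"))
  if (length(key) == 1L && is.character(key)) {
    site <- panel$sites[[key]]
    if (is.null(site)) stop("no panel site with id ", sQuote(key), call. = FALSE)
    return(site)
  }
  if (length(key) == 2L) {
    chrom <- as.character(key[[1]])
    pos <- as.integer(key[[2]])
    for (site in panel$sites) {
      if (site$chromosome == chrom && site$position == pos) return(site)
    }
    stop("no panel site at ", chrom, ":", pos, call. = FALSE)
  }
  stop("key must be a site_id or (chromosome, position)", call. = FALSE)
}

panel_site_ids <- function(panel) names(panel$sites)

#' @export
print.canid_panel <- function(x, ...) {
  cat("<canid_panel> ", x$version, ": ", length(x$sites), " sites\n", sep = "")
  df <- as.data.frame(x)
  print(df[, c("site_id", "chromosome", "position", "gene", "locus_code",
               "reference_allele", "phenotype_allele", "inheritance")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.canid_panel <- function(x, ...) {
  do.call(rbind, lapply(unname(x$sites), function(s) {
    data.frame(site_id = s$site_id, chromosome = s$chromosome,
               position = s$position, end_position = s$end_position,
               gene = s$gene, locus_code = s$locus_code,
               variant_class = s$variant_class,
               reference_allele = s$reference_allele,
               alternate_alleles = paste(s$alternate_alleles, collapse = ","),
               phenotype_allele = s$phenotype_allele,
               inheritance = s$inheritance, phene_label = s$phene_label,
               omia_code = s$omia_code, stringsAsFactors = FALSE)
  }))
}

#' @export
print.variant_site <- function(x, ...) {
  cat("<variant_site> ", x$site_id, "  ", x$gene, " (", x$locus_code,
      "-locus)\n  CFA", x$chromosome, ":", x$position,
      if (!is.na(x$end_position)) paste0("-", x$end_position) else "",
      "  ", x$reference_allele, ">",
      paste(x$alternate_alleles, collapse = "/"), "\n  phene: ",
      x$phene_label, " [", x$inheritance, ", causal allele ",
      x$phenotype_allele, "]\n", sep = "")
  invisible(x)
}
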