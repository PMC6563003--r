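#' Cohorts of diploid genotype calls at panel sites
#'
#' A `canid_cohort` holds a sample table (`sample_id`, `population`,
#' owner-declared phenotypes where known) and one diploid genotype call per
#' (sample, site) pair, in long form.  Calls are unphased; allele order
#' within a call carries no meaning and is canonicalized reference-first.
#'
#' Call `status` is one of:
#' * `"called"` -- both alleles observed;
#' * `"missing"` -- no genotype call (rendered `"0 0"` in tables);
#' * `"low_coverage"` -- a call is present but read support at the site was
#'   thin, so it does not exclude the other heterozygous state.
#'
#' Missing and low-coverage are deliberately distinct: a missing call has no
#' alleles at all, while a low-coverage call keeps its alleles and is merely
#' down-weighted to "provisional" by the phenotype engine.
#'
#' @name canid_cohort
NULL

.CALL_STATUS <- c("called", "missing", "low_coverage")
.POPULATIONS <- c("AK", "AWK", "Kelpie_unspecified", "Dingo", "Labrador", "Other")
.LOWCOV_MARK <- "†"  # dagger, the footnote marker used in genotype tables
.MISSING_CELL <- "0 0"

# Canonical allele order within an unphased call: reference first, then
# panel alternates in declared order, novel alleles last alphabetically.
order_call_alleles <- function(a1, a2, site) {
  alleles <- c(a1, a2)
  known <- site_alleles(site)
  rank <- match(alleles, known)
  rank[is.na(rank)] <- length(known) + 1L
  o <- order(rank, alleles)
  alleles[o]
}

make_call <- function(sample_id, site_id, allele1, allele2,
                      status = "called", note = NA_character_) {
  data.frame(sample_id = sample_id, site_id = site_id,
             allele1 = allele1, allele2 = allele2,
             status = status, note = note, stringsAsFactors = FALSE)
}

missing_call <- function(sample_id, site_id, note = NA_character_) {
  make_call(sample_id, site_id, NA_character_, NA_character_, "missing", note)
}

#' Construct a cohort
#'
#' @param samples `data.frame` with columns `sample_id`, `population` and
#'   optionally `declared_coat`, `declared_ears`.
#' @param calls Long-form `data.frame` with columns `sample_id`, `site_id`,
#'   `allele1`, `allele2`, `status` and optionally `note`.  Pairs absent
#'   from `calls` are completed as missing.
#' @param panel The `canid_panel` the calls refer to.
#' @param check_alleles Warn and flag calls whose alleles are not in the
#'   site's allele set (default `TRUE`).
#' @return A `canid_cohort`.
#' @export
new_cohort <- function(samples, calls, panel, check_alleles = TRUE) {
  stopifnot(inherits(panel, "canid_panel"))
  if (nrow(samples) == 0L) stop("no samples", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in cohort", call. = FALSE)
  }
  if (is.null(samples$population)) samples$population <- "Other"
  if (is.null(samples$declared_coat)) samples$declared_coat <- NA_character_
  if (is.null(samples$declared_ears)) samples$declared_ears <- NA_character_
  samples <- samples[, c("sample_id", "population", "declared_coat", "declared_ears")]

  unknown <- setdiff(unique(calls$site_id), panel_site_ids(panel))
  if (length(unknown)) {
    stop("calls refer to sites not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(calls$note)) calls$note <- NA_character_
  calls <- calls[, c("sample_id", "site_id", "allele1", "allele2", "status", "note")]
  key <- paste(calls$sample_id, calls$site_id)
  if (anyDuplicated(key)) {
    stop("more than one call for pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }

  # complete absent pairs as missing
  grid <- expand.grid(sample_id = samples$sample_id,
                      site_id = panel_site_ids(panel),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$sample_id, grid$site_id)
  absent <- grid[!gkey %in% key, , drop = FALSE]
  if (nrow(absent)) {
    calls <- rbind(calls, make_call(absent$sample_id, absent$site_id,
                                    NA_character_, NA_character_, "missing"))
  }

  for (i in seq_len(nrow(calls))) {
    st <- calls$status[i]
    if (!st %in% .CALL_STATUS) {
      stop("unknown call status ", sQuote(st), call. = FALSE)
    }
    both_na <- is.na(calls$allele1[i]) && is.na(calls$allele2[i])
    if (st == "missing" && !both_na) {
      stop("missing call with alleles present: ", calls$sample_id[i], " @ ",
           calls$site_id[i], call. = FALSE)
    }
    if (st != "missing" && both_na) {
      stop("called status without alleles: ", calls$sample_id[i], " @ ",
           calls$site_id[i], call. = FALSE)
    }
    if (!both_na) {
      site <- panel$sites[[calls$site_id[i]]]
      al <- order_call_alleles(calls$allele1[i], calls$allele2[i], site)
      calls$allele1[i] <- al[1]; calls$allele2[i] <- al[2]
      novel <- setdiff(al, site_alleles(site))
      if (length(novel)) {
        if (check_alleles) {
          warning("novel allele(s) ", paste(sQuote(novel), collapse = ", "),
                  " at ", calls$site_id[i], " for ", calls$sample_id[i],
                  call. = FALSE)
        }
        calls$note[i] <- if (is.na(calls$note[i])) "novel" else
          paste(calls$note[i], "novel", sep = ";")
      }
    }
  }
  o <- order(match(calls$sample_id, samples$sample_id),
             match(calls$site_id, panel_site_ids(panel)))
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  rownames(samples) <- NULL
  structure(list(samples = samples, calls = calls, panel = panel),
            class = "canid_cohort")
}

#' Retrieve one genotype call
#'
#' @param cohort A `canid_cohort`.
#' @param sample_id,site_id Keys of the call.
#' @return A one-row `data.frame` (sample_id, site_id, allele1, allele2,
#'   status, note).
#' @export
get_call <- function(cohort, sample_id, site_id) {
  hit <- cohort$calls$sample_id == sample_id & cohort$calls$site_id == site_id
  if (!any(hit)) {
    stop("no call for ", sample_id, " @ ", site_id, call. = FALSE)
  }
  cohort$calls[hit, , drop = FALSE]
}

#' @export
print.canid_cohort <- function(x, ...) {
  cat("<canid_cohort> ", nrow(x$samples), " samples x ",
      length(panel_site_ids(x$panel)), " sites (",
      sum(x$calls$status == "missing"), " missing, ",
      sum(x$calls$status == "low_coverage"), " low-coverage calls)\n", sep = "")
  print(table(x$samples$population))
  invisible(x)
}

format_cell <- function(allele1, allele2, status) {
  if (status == "missing") {
    cell <- .MISSING_CELL
  } else {
    cell <- paste(allele1, allele2, sep = "/")
  }
  if (status == "low_coverage") cell <- paste0(cell, .LOWCOV_MARK)
  cell
}

parse_cell <- function(cell, note_in = NA_character_) {
  cell <- trimws(cell)
  lowcov <- grepl(.LOWCOV_MARK, cell, fixed = TRUE) ||
    grepl("\\*$", cell)  # ASCII fallback marker
  cell <- trimws(gsub(paste0("[", .LOWCOV_MARK, "*]"), "", cell))
  if (cell %in% c("0 0", "0/0", "0|0", "", ".", "./.")) {
    note <- if (lowcov) {
      if (is.na(note_in)) "low coverage" else note_in
    } else note_in
    return(list(allele1 = NA_character_, allele2 = NA_character_,
                status = "missing", note = note))
  }
  parts <- strsplit(cell, "[/| ]+")[[1]]
  if (length(parts) != 2L) {
    stop("cannot parse genotype cell ", sQuote(cell), call. = FALSE)
  }
  list(allele1 = parts[1], allele2 = parts[2],
       status = if (lowcov) "low_coverage" else "called", note = note_in)
}

.META_COLS <- c("sample_id", "population", "declared_coat", "declared_ears")

#' Read a tab-separated genotype table
#'
#' Expected layout: one row per sample; columns `sample_id`, `population`,
#' `declared_coat`, `declared_ears` (the latter three optional) followed by
#' one column per panel `site_id`.  Cells are `allele1/allele2`; `"0 0"`
#' (or `"./."`) marks a missing call; a trailing dagger (or `*`) marks low
#' sequencing coverage.
#'
#' @param path File path.
#' @param panel A `canid_panel`.
#' @return A `canid_cohort`.
#' @export
read_genotype_table <- function(path, panel) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no samples in ", path, call. = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("genotype table lacks a sample_id column", call. = FALSE)
  }
  site_cols <- setdiff(names(df), .META_COLS)
  unknown <- setdiff(site_cols, panel_site_ids(panel))
  if (length(unknown)) {
    stop("unknown site column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  samples <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  for (mc in .META_COLS[-1]) {
    samples[[mc]] <- if (mc %in% names(df)) {
      ifelse(df[[mc]] %in% c("", "NA"), NA_character_, df[[mc]])
    } else NA_character_
  }
  calls <- do.call(rbind, lapply(site_cols, function(sc) {
    parsed <- lapply(df[[sc]], parse_cell)
    data.frame(sample_id = df$sample_id, site_id = sc,
               allele1 = vapply(parsed, `[[`, "", "allele1"),
               allele2 = vapply(parsed, `[[`, "", "allele2"),
               status = vapply(parsed, `[[`, "", "status"),
               note = vapply(parsed, `[[`, "", "note"),
               stringsAsFactors = FALSE)
  }))
  new_cohort(samples, calls, panel)
}

#' Write a cohort as a tab-separated genotype table
#'
#' Inverse of [read_genotype_table()]: reading the written file reproduces
#' the cohort, including missingness and low-coverage flags.
#'
#' @param cohort A `canid_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "canid_cohort"))
  if (nrow(cohort$samples) == 0L) stop("empty cohort", call. = FALSE)
  sids <- panel_site_ids(cohort$panel)
  out <- cohort$samples
  for (sc in sids) {
    cells <- vapply(out$sample_id, function(sm) {
      cl <- get_call(cohort, sm, sc)
      format_cell(cl$allele1, cl$allele2, cl$status)
    }, "")
    out[[sc]] <- cells
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Do two cohorts carry identical calls?
#'
#' Compares samples, status and (unphased) genotypes cell by cell.
#'
#' @param a,b `canid_cohort` objects over the same panel.
#' @return Logical.
#' @export
cohorts_equal <- function(a, b) {
  if (!identical(sort(a$samples$sample_id), sort(b$samples$sample_id))) {
    return(FALSE)
  }
  ka <- a$calls[order(a$calls$sample_id, a$calls$site_id), ]
  kb <- b$calls[order(b$calls$sample_id, b$calls$site_id), ]
  identical(ka$sample_id, kb$sample_id) &&
    identical(ka$site_id, kb$site_id) &&
    identical(ka$status, kb$status) &&
    all(is.na(ka$allele1) == is.na(kb$allele1)) &&
    all(ka$allele1 == kb$allele1, na.rm = TRUE) &&
    all(ka$allele2 == kb$allele2, na.rm = TRUE)
}
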