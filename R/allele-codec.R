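#' Run-length (CIGAR-style) codec for length-polymorphism alleles
#'
#' Length-polymorphism alleles at loci such as the MITF melanocyte-specific
#' promoter are conventionally written as a run-length code: `"12C9A2G12A"`
#' means 12 C's, 9 A's, 2 G's then 12 A's (35 bases in total).  Short labels
#' combine the decoded length with a letter reflecting order of discovery,
#' e.g. `"35A"` for the canine reference allele.
#'
#' @name allele_codec
#' @keywords internal
NULL

.RL_TOKEN <- "([0-9]+)([ACGT])"

# Parse a run-length code into a data.frame of (count, base) runs.
# Whitespace is stripped first: published expansions sometimes contain
# typesetting spaces.
parse_run_length <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("run-length code must be a single character string", call. = FALSE)
  }
  code <- gsub("[[:space:]]+", "", code)
  if (!nzchar(code)) {
    stop("empty run-length code", call. = FALSE)
  }
  if (!grepl(paste0("^(", .RL_TOKEN, ")+$"), code)) {
    stop("malformed run-length code (expected e.g. \"12C9A2G12A\"): ",
         sQuote(code), call. = FALSE)
  }
  m <- gregexpr(.RL_TOKEN, code)[[1]]
  toks <- regmatches(code, list(m))[[1]]
  counts <- as.integer(sub("[ACGT]$", "", toks))
  bases <- sub("^[0-9]+", "", toks)
  if (any(counts < 1L)) {
    stop("run-length counts must be >= 1 in ", sQuote(code), call. = FALSE)
  }
  data.frame(count = counts, base = bases, stringsAsFactors = FALSE)
}

# Merge adjacent runs with equal bases (canonical form).
canonicalize_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  keep <- integer(0)
  counts <- integer(0)
  for (i in seq_len(nrow(runs))) {
    if (length(keep) && runs$base[i] == runs$base[keep[length(keep)]]) {
      counts[length(counts)] <- counts[length(counts)] + runs$count[i]
    } else {
      keep <- c(keep, i)
      counts <- c(counts, runs$count[i])
    }
  }
  data.frame(count = counts, base = runs$base[keep], stringsAsFactors = FALSE)
}

runs_to_code <- function(runs) paste0(runs$count, runs$base, collapse = "")

#' Decode a run-length allele code into its nucleotide sequence
#'
#' @param code A run-length code such as `"12C9A2G12A"`.  Whitespace is
#'   ignored.  Non-canonical codes (adjacent runs of the same base, e.g.
#'   `"2A3A"`) are accepted with a warning and treated as their canonical
#'   equivalent.
#' @return A single nucleotide string whose length is the sum of the run
#'   counts.
#' @examples
#' decode_run_length("12C9A2G12A")  # the 35-base MITF reference allele
#' decode_run_length("1A")
#' @export
decode_run_length <- function(code) {
  runs <- parse_run_length(code)
  canon <- canonicalize_runs(runs)
  if (nrow(canon) != nrow(runs)) {
    warning("non-canonical run-length code ", sQuote(code),
            " (adjacent runs share a base); using canonical form ",
            sQuote(runs_to_code(canon)), call. = FALSE)
  }
  paste(strrep(canon$base, canon$count), collapse = "")
}

#' Encode a nucleotide sequence as a canonical run-length code
#'
#' Inverse of [decode_run_length()]: maximal runs, so
#' `encode_run_length(decode_run_length(x))` reproduces any canonical `x`.
#'
#' @param sequence A non-empty nucleotide string over A/C/G/T (whitespace
#'   tolerated and stripped).
#' @return The canonical run-length code.
#' @examples
#' encode_run_length(strrep(c("C", "A", "G", "A"), c(12, 9, 2, 12)))
#' @export
encode_run_length <- function(sequence) {
  if (!is.character(sequence) || is.na(sequence[1])) {
    stop("sequence must be a character string", call. = FALSE)
  }
  sequence <- gsub("[[:space:]]+", "", paste(sequence, collapse = ""))
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  r <- rle(chars)
  paste0(r$lengths, r$values, collapse = "")
}

#' Decoded length of a run-length allele
#'
#' Allele labels are conventionally prefixed with this length (a 33-base
#' allele may be labelled `"33C"`).
#'
#' @inheritParams decode_run_length
#' @return Integer number of bases.
#' @examples
#' allele_length("10C9A2G12A")  # 33
#' @export
allele_length <- function(code) {
  sum(parse_run_length(code)$count)
}

#' The packaged allele-label registry
#'
#' Maps short labels (length + discovery letter) to run-length codes for the
#' MITF promoter length polymorphism.  Ships exactly the attested alleles:
#' the canine reference `35A`, the wolf/Dingo `35B`, and the two alleles
#' observed in Kelpies, `33C` and `31A`.
#'
#' @return Named character vector: names are labels, values are canonical
#'   run-length codes.
#' @export
default_registry <- function() {
  c(`35A` = "12C9A2G12A",
    `35B` = "11C10A2G12A",
    `33C` = "10C9A2G12A",
    `31A` = "10C8A2G11A")
}

validate_registry <- function(registry) {
  if (is.null(registry) || length(registry) == 0L) return(invisible(registry))
  if (is.null(names(registry)) || anyDuplicated(names(registry))) {
    stop("registry labels must be unique and named", call. = FALSE)
  }
  if (anyDuplicated(registry)) {
    dup <- registry[duplicated(registry)][1]
    stop("registry maps two labels to one code: ", sQuote(dup), call. = FALSE)
  }
  invisible(registry)
}

#' Label a run-length allele
#'
#' Returns the registry label for a known code.  Unknown codes receive a new
#' label formed from the decoded length plus the next free letter for that
#' length (letters are awarded in order of discovery); the updated registry
#' is attached so callers can persist it.
#'
#' @param code Run-length code (canonicalized before lookup).
#' @param registry Label registry as from [default_registry()].
#' @return The short label, with the (possibly extended) registry in
#'   attribute `"registry"`.
#' @examples
#' label_allele("12C9A2G12A")  # "35A"
#' @export
label_allele <- function(code, registry = default_registry()) {
  validate_registry(registry)
  canon <- runs_to_code(canonicalize_runs(parse_run_length(code)))
  hit <- names(registry)[match(canon, registry)]
  if (!is.na(hit[1]) && nzchar(hit[1])) {
    return(structure(hit[1], registry = registry))
  }
  len <- allele_length(canon)
  same_len <- grepl(paste0("^", len, "[A-Z]$"), names(registry))
  used <- sub(paste0("^", len), "", names(registry)[same_len])
  # letters reflect order of discovery: continue after the highest letter
  # already awarded for this length rather than refilling gaps
  next_idx <- if (length(used)) max(match(used, LETTERS)) + 1L else 1L
  if (next_idx > length(LETTERS)) {
    stop("label letters exhausted for length ", len, call. = FALSE)
  }
  label <- paste0(len, LETTERS[next_idx])
  registry[label] <- canon
  structure(label, registry = validate_registry(registry))
}

# Resolve an allele written either as a short label ("33C") or a run-length
# code to its canonical code; plain allele strings pass through unchanged.
resolve_allele_code <- function(allele, registry = default_registry()) {
  if (allele %in% names(registry)) return(unname(registry[allele]))
  allele
}
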