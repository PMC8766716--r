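#' Parse a coding-DNA (c.) HGVS variant description
#'
#' Parses simple HGVS coding-DNA strings of the kind used to track
#' tumor-informed plasma markers: single-nucleotide substitutions such as
#' `"c.35G>A"` (whitespace around `>` tolerated, as in printed tables),
#' plus insertions (`"c.76_77insA"`), deletions (`"c.76del"`,
#' `"c.76_78del"`) and deletion-insertions (`"c.76_78delinsTT"`).
#' Non-substitution events are recognised and typed but not decomposed
#' beyond their start position.
#'
#' @param hgvs_c Character vector of HGVS c. strings.
#' @return A tibble with one row per input: `hgvs_c`, `position` (integer
#'   start position), `ref_base`, `alt_base` (single bases for
#'   substitutions, `NA` otherwise) and `kind` (one of `"substitution"`,
#'   `"insertion"`, `"deletion"`, `"delins"`).
#' @examples
#' parse_hgvs_c(c("c.35G > A", "c.34G > T", "c.76_78delinsTT"))
#' @export
parse_hgvs_c <- function(hgvs_c) {
  if (length(hgvs_c) == 0 || !is.character(hgvs_c)) {
    rlang::abort("`hgvs_c` must be a non-empty character vector.",
                 class = "mrdcall_format_error")
  }
  parse_one <- function(x) {
    raw <- x
    x <- gsub("\\s+", "", x)
    if (is.na(x) || !nzchar(x) || !startsWith(x, "c.")) {
      rlang::abort(
        sprintf("Not an HGVS c. description: '%s' (must begin with \"c.\").", raw),
        class = "mrdcall_format_error"
      )
    }
    body <- sub("^c\\.", "", x)
    # substitution: <pos><ref>><alt>
    m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1]]
    if (length(m) == 4) {
      return(tibble::tibble(hgvs_c = raw, position = as.integer(m[2]),
                            ref_base = m[3], alt_base = m[4],
                            kind = "substitution"))
    }
    m <- regmatches(body, regexec("^([0-9]+)(_[0-9]+)?delins[ACGT]+$", body))[[1]]
    if (length(m)) {
      return(tibble::tibble(hgvs_c = raw, position = as.integer(m[2]),
                            ref_base = NA_character_, alt_base = NA_character_,
                            kind = "delins"))
    }
    m <- regmatches(body, regexec("^([0-9]+)(_[0-9]+)?del([ACGT]+)?$", body))[[1]]
    if (length(m)) {
      return(tibble::tibble(hgvs_c = raw, position = as.integer(m[2]),
                            ref_base = NA_character_, alt_base = NA_character_,
                            kind = "deletion"))
    }
    m <- regmatches(body, regexec("^([0-9]+)(_[0-9]+)?(dup|ins)([ACGT]+)?$", body))[[1]]
    if (length(m)) {
      return(tibble::tibble(hgvs_c = raw, position = as.integer(m[2]),
                            ref_base = NA_character_, alt_base = NA_character_,
                            kind = "insertion"))
    }
    rlang::abort(
      sprintf("Cannot parse HGVS c. token '%s' in '%s'.", body, raw),
      class = "mrdcall_format_error"
    )
  }
  purrr::map_dfr(hgvs_c, parse_one)
}

#' Classify a single-nucleotide substitution as transition or transversion
#'
#' Transitions exchange purine for purine (A<->G) or pyrimidine for
#' pyrimidine (C<->T); transversions cross the two classes. The distinction
#' matters because amplicon sequencing background error is markedly higher
#' for transitions, so the class drives the expected false-positive rate of
#' a marker.
#'
#' @param ref_base,alt_base Character vectors of single bases in
#'   `A`, `C`, `G`, `T`. Recycled to a common length.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("G", "A")  # transition
#' classify_substitution("G", "T")  # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  n <- max(length(ref_base), length(alt_base))
  ref <- toupper(rep_len(ref_base, n))
  alt <- toupper(rep_len(alt_base, n))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    rlang::abort("ref_base and alt_base must be single bases in {A,C,G,T}.",
                 class = "mrdcall_domain_error")
  }
  if (any(ref == alt)) {
    rlang::abort("ref_base and alt_base must differ for a substitution.",
                 class = "mrdcall_domain_error")
  }
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Convert a cfDNA mass to haploid template copies
#'
#' One haploid human genome weighs about 3 pg, so an input mass of cfDNA
#' bounds the number of amplifiable template molecules per locus:
#' `floor(mass_ng * 1000 / pg_per_copy)`. Fractional copies are floored
#' because a partial template molecule cannot be amplified. This copy
#' number, not sequencing depth, is what ultimately limits sensitivity in
#' template-limited assays.
#'
#' @param mass_ng Numeric vector of input masses in nanograms (>= 0).
#' @param pg_per_copy Picograms of DNA per haploid genome copy (default 3).
#' @return Integer vector of template copy numbers.
#' @examples
#' mass_to_copies(25)   # 8333
#' mass_to_copies(300)  # 100000
#' @export
mass_to_copies <- function(mass_ng, pg_per_copy = 3) {
  if (any(mass_ng < 0) || any(is.na(mass_ng))) {
    rlang::abort("`mass_ng` must be non-negative.", class = "mrdcall_domain_error")
  }
  if (any(pg_per_copy <= 0)) {
    rlang::abort("`pg_per_copy` must be positive.", class = "mrdcall_domain_error")
  }
  # small epsilon guards floor() against 1/3-type floating error
  as.integer(floor(mass_ng * 1000 / pg_per_copy + 1e-9))
}

#' Theoretical VAF quantification limit for a template copy number
#'
#' The lowest variant allele frequency representable among `copies`
#' template molecules is the one where exactly one copy is mutant:
#' `100 / copies` percent. With 8,333 copies (25 ng at 3 pg/copy) this is
#' 0.012\% VAF; reaching 0.001\% requires 100,000 copies (300 ng).
#'
#' @param copies Integer vector of template copy numbers (>= 1).
#' @return Numeric vector, limit in percent VAF.
#' @export
theoretical_quantification_limit <- function(copies) {
  if (any(copies < 1)) {
    rlang::abort("`copies` must be >= 1.", class = "mrdcall_domain_error")
  }
  100 / copies
}

#' cfDNA mass required for a target quantification limit
#'
#' Inverts [theoretical_quantification_limit()] and [mass_to_copies()]:
#' the mass whose copy number makes a single mutant copy correspond to
#' `limit_pct` VAF, i.e. `(100 / limit_pct) * pg_per_copy / 1000` ng.
#'
#' @param limit_pct Target limit in percent VAF, in (0, 100].
#' @param pg_per_copy Picograms of DNA per haploid genome copy (default 3).
#' @return Numeric vector of masses in nanograms.
#' @examples
#' required_mass_for_limit(0.001)  # 300 ng
#' required_mass_for_limit(0.012)  # 25 ng
#' @export
required_mass_for_limit <- function(limit_pct, pg_per_copy = 3) {
  if (any(limit_pct <= 0) || any(limit_pct > 100)) {
    rlang::abort("`limit_pct` must lie in (0, 100].", class = "mrdcall_domain_error")
  }
  (100 / limit_pct) * pg_per_copy / 1000
}

#' Build a validated tumor-informed marker panel
#'
#' Assembles marker descriptions (gene symbol plus HGVS c. notation) into
#' the panel tibble the rest of the pipeline consumes. Substitution markers
#' get their ref/alt bases and transition/transversion class derived from
#' the HGVS string; insertion/deletion/delins markers carry their event
#' kind as the class.
#'
#' @param data A data frame with at least columns `marker_id`, `gene`,
#'   `hgvs_c`; optionally `hgvs_p`.
#' @return A tibble with columns `marker_id`, `gene`, `hgvs_c`, `hgvs_p`,
#'   `ref_base`, `alt_base`, `mutation_class`.
#' @examples
#' marker_panel(data.frame(marker_id = "KRAS_G12D", gene = "KRAS",
#'                         hgvs_c = "c.35G>A", hgvs_p = "p.Gly12Asp"))
#' @export
marker_panel <- function(data) {
  required <- c("marker_id", "gene", "hgvs_c")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(paste0("Marker table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrdcall_format_error")
  }
  if (anyDuplicated(data$marker_id)) {
    rlang::abort("marker_id values must be unique within a panel.",
                 class = "mrdcall_format_error")
  }
  parsed <- parse_hgvs_c(data$hgvs_c)
  class <- parsed$kind
  snv <- class == "substitution"
  class[snv] <- purrr::map2_chr(parsed$ref_base[snv], parsed$alt_base[snv],
                                classify_substitution)
  tibble::tibble(
    marker_id = as.character(data$marker_id),
    gene = as.character(data$gene),
    hgvs_c = as.character(data$hgvs_c),
    hgvs_p = if ("hgvs_p" %in% names(data)) as.character(data$hgvs_p) else NA_character_,
    ref_base = parsed$ref_base,
    alt_base = parsed$alt_base,
    mutation_class = class
  )
}

#' Read a marker panel from a tab-delimited file
#'
#' Expects a UTF-8 TSV with header columns `marker_id`, `gene`, `hgvs_c`
#' and optionally `hgvs_p`, `ref`, `alt`. Any `ref`/`alt` columns are
#' checked against the bases parsed from `hgvs_c`.
#'
#' @param path Path to the TSV file.
#' @return A marker panel tibble (see [marker_panel()]).
#' @export
read_marker_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  panel <- marker_panel(raw)
  if (all(c("ref", "alt") %in% names(raw))) {
    snv <- !is.na(panel$ref_base)
    bad <- snv & (panel$ref_base != raw$ref | panel$alt_base != raw$alt)
    if (any(bad)) {
      rlang::abort(paste0("ref/alt columns disagree with hgvs_c for marker(s): ",
                          paste(panel$marker_id[bad], collapse = ", ")),
                   class = "mrdcall_format_error")
    }
  }
  panel
}
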