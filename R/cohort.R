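#' Read a patient CNV table
#'
#' Reads a DECIPHER-style tab-separated CNV table with columns `patient_id`,
#' `chrom`, `start`, `end`, `variant_class`, `inheritance` (header required;
#' lines starting with `#` are skipped). Coordinates are normalised to
#' 0-based half-open internally; the input dialect defaults to the
#' 1-based inclusive convention used by clinical CNV tables.
#'
#' Variant classes are parsed case-insensitively: `del`/`deletion`/`loss`
#' map to `deletion`, `dup`/`duplication`/`gain` to `duplication`.
#' Inheritance tokens `de novo`/`de_novo`/`dn` map to `de_novo`;
#' `inherited`, `maternal`, `paternal` to `inherited`; anything else
#' (including blanks) to `unknown`. Leading `chr` prefixes on chromosome
#' names are stripped.
#'
#' @param file path to a TSV file, or a connection.
#' @param coordinate_dialect `"one_based_inclusive"` (default) or
#'   `"zero_based_half_open"`.
#' @return data.frame with columns `cnv_id`, `patient_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `variant_class`, `inheritance`.
#' @export
read_cnvs <- function(file,
                      coordinate_dialect = c("one_based_inclusive",
                                             "zero_based_half_open")) {
  coordinate_dialect <- match.arg(coordinate_dialect)
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("patient_id", "chrom", "start", "end",
                "variant_class", "inheritance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("CNV table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }

  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad_num <- which(is.na(start) | is.na(end) |
                   start != floor(start) | end != floor(end))
  if (length(bad_num)) {
    stop("non-integer coordinate in CNV table at row(s): ",
         paste(bad_num, collapse = ", "))
  }
  if (coordinate_dialect == "one_based_inclusive") start <- start - 1

  vc <- parse_variant_class(df$variant_class)
  bad_vc <- which(is.na(vc))
  if (length(bad_vc)) {
    stop("unknown variant_class token at row(s): ",
         paste(bad_vc, collapse = ", "), " (",
         paste(unique(df$variant_class[bad_vc]), collapse = ", "), ")")
  }

  bad_iv <- which(start >= end)
  if (length(bad_iv)) {
    stop("empty or inverted interval (start >= end) at row(s): ",
         paste(bad_iv, collapse = ", "))
  }

  data.frame(
    cnv_id = sprintf("cnv%05d", seq_len(nrow(df))),
    patient_id = df$patient_id,
    chrom = sub("^chr", "", df$chrom, ignore.case = TRUE),
    start = start,
    end = end,
    variant_class = vc,
    inheritance = parse_inheritance(df$inheritance),
    stringsAsFactors = FALSE)
}

parse_variant_class <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("del", "deletion", "loss")] <- "deletion"
  out[x %in% c("dup", "duplication", "gain")] <- "duplication"
  out
}

parse_inheritance <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("de novo", "de_novo", "denovo", "dn")] <- "de_novo"
  out[x %in% c("inherited", "maternal", "paternal")] <- "inherited"
  out
}

#' Write a CNV table
#'
#' Inverse of [read_cnvs()]: writes the normalised records back out in the
#' requested coordinate dialect.
#'
#' @param cnvs data.frame as returned by [read_cnvs()].
#' @param file output path.
#' @param coordinate_dialect dialect for the written coordinates.
#' @export
write_cnvs <- function(cnvs, file,
                       coordinate_dialect = c("one_based_inclusive",
                                              "zero_based_half_open")) {
  coordinate_dialect <- match.arg(coordinate_dialect)
  out <- cnvs[c("patient_id", "chrom", "start", "end",
                "variant_class", "inheritance")]
  if (coordinate_dialect == "one_based_inclusive") out$start <- out$start + 1
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Filter CNVs for one subnetwork
#'
#' Deletions and duplications form separate subnetworks, and by default only
#' de novo variants enter a network (inherited CNVs are also carried by an
#' unaffected parent and are less likely to drive the pathological
#' phenotype). Input order is preserved.
#'
#' @param cnvs data.frame of CNV records.
#' @param variant_class `"deletion"` or `"duplication"`.
#' @param de_novo_only keep only `inheritance == "de_novo"` records.
#' @return the retained rows (possibly zero).
#' @export
filter_for_network <- function(cnvs,
                               variant_class = c("deletion", "duplication"),
                               de_novo_only = TRUE) {
  variant_class <- match.arg(variant_class)
  keep <- cnvs$variant_class == variant_class
  if (de_novo_only) keep <- keep & cnvs$inheritance == "de_novo"
  out <- cnvs[keep, , drop = FALSE]
  if (!nrow(out)) {
    message("filter_for_network: no ", variant_class,
            if (de_novo_only) " de novo", " CNVs retained")
  }
  rownames(out) <- NULL
  out
}

#' Read patient HPO annotations
#'
#' Reads a tab-separated table with columns `patient_id`, `hpo_id` and
#' returns, per patient, the asserted terms together with their ancestor
#' closure (see [propagate()]). Ids not matching `HP:\\d{7}` are a row
#' error; well-formed ids absent from the ontology are dropped with a
#' warning so one retired term does not invalidate a patient record.
#'
#' @param file path to the annotation TSV.
#' @param onto an `hpo_ontology`.
#' @return named list of `term_set` objects, one per patient id.
#' @export
read_patient_hpo <- function(file, onto) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("patient_id", "hpo_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!grepl("^HP:[0-9]{7}$", df$hpo_id))
  if (length(bad)) {
    stop("malformed HPO id at row(s): ", paste(bad, collapse = ", "),
         " (", paste(unique(df$hpo_id[bad]), collapse = ", "), ")")
  }
  known <- df$hpo_id %in% c(onto$terms, names(onto$obsolete))
  if (any(!known)) {
    warning("dropping ", sum(!known), " annotation(s) with terms absent ",
            "from the ontology: ",
            paste(unique(df$hpo_id[!known]), collapse = ", "))
    df <- df[known, , drop = FALSE]
  }
  by_patient <- split(df$hpo_id, df$patient_id)
  lapply(by_patient, function(terms) propagate(onto, unique(terms)))
}

#' Write a patient annotation table
#'
#' @param annotations named list of `term_set` objects (direct terms are
#'   written, one row per patient-term pair).
#' @param file output path.
#' @export
write_patient_hpo <- function(annotations, file) {
  rows <- data.frame(
    patient_id = rep(names(annotations),
                     vapply(annotations, function(a) length(a$direct), 1L)),
    hpo_id = unlist(lapply(annotations, function(a) a$direct),
                    use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
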