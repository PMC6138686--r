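#' Serialize a tripartite network to a directory of text files
#'
#' Writes `patients.tsv`, `pheno_edges.tsv`, `locus_edges.tsv`, `loci.tsv`
#' (full locus table with supporting CNV ids), `loci.bed` and a
#' `manifest.json` recording the variant class, node/edge counts, file
#' digests and package version, so a scored network can be reloaded without
#' recomputation and a rerun can be verified byte for byte.
#'
#' @param net a `tripartite_network`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "tripartite_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  wt(data.frame(patient_id = net$patients), "patients.tsv")
  wt(data.frame(
    phenotype = rep(names(net$pheno_edges), lengths(net$pheno_edges)),
    phenotype_name = rep(unname(net$phenotype_names[names(net$pheno_edges)]),
                         lengths(net$pheno_edges)),
    patient_id = unlist(net$pheno_edges, use.names = FALSE)),
    "pheno_edges.tsv")
  wt(data.frame(
    locus_id = rep(names(net$locus_edges), lengths(net$locus_edges)),
    patient_id = unlist(net$locus_edges, use.names = FALSE)),
    "locus_edges.tsv")
  loci_flat <- net$loci
  loci_flat$cnv_ids <- vapply(loci_flat$cnv_ids, paste, "", collapse = ",")
  loci_flat$patient_ids <- vapply(loci_flat$patient_ids, paste, "",
                                  collapse = ",")
  wt(loci_flat, "loci.tsv")
  write_loci_bed(net$loci, file.path(dir, "loci.bed"))

  files <- c("patients.tsv", "pheno_edges.tsv", "locus_edges.tsv", "loci.tsv",
             "loci.bed")
  s <- network_stats(net)
  manifest <- list(
    variant_class = net$variant_class,
    stats = s[names(s) != "variant_class"],
    digests = as.list(tools::md5sum(file.path(dir, files))),
    package_version = as.character(utils::packageVersion("phenoloci")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Reload a serialized tripartite network
#'
#' @param dir directory written by [write_network()].
#' @return a `tripartite_network`.
#' @export
read_network <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE,
                                      colClasses = "character")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  patients <- rd("patients.tsv")$patient_id
  pe <- rd("pheno_edges.tsv")
  le <- rd("locus_edges.tsv")
  loci <- rd("loci.tsv")
  loci$start <- as.numeric(loci$start)
  loci$end <- as.numeric(loci$end)
  loci$n_cnvs <- as.integer(loci$n_cnvs)
  loci$n_patients <- as.integer(loci$n_patients)
  loci$cnv_ids <- strsplit(loci$cnv_ids, ",", fixed = TRUE)
  loci$patient_ids <- strsplit(loci$patient_ids, ",", fixed = TRUE)

  pheno_names <- stats::setNames(pe$phenotype_name, pe$phenotype)
  pheno_names <- pheno_names[!duplicated(names(pheno_names))]
  structure(
    list(variant_class = manifest$variant_class,
         patients = patients,
         pheno_edges = lapply(split(pe$patient_id, pe$phenotype), sort),
         locus_edges = stats::setNames(loci$patient_ids, loci$locus_id),
         loci = loci,
         phenotype_names = pheno_names),
    class = "tripartite_network")
}
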