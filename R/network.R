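#' Build a tripartite phenotype-patient-locus network
#'
#' Assembles one variant-class subnetwork: the patient layer is every patient
#' carrying at least one CNV of the class (after filtering), the locus layer
#' comes from [segment_sors()], and the phenotype layer links patients to
#' their propagated HPO terms. The population size N used by the
#' hypergeometric score is the size of this patient layer — annotated
#' patients without a CNV of the class are outside the subnetwork and do not
#' enter N.
#'
#' @param cnvs data.frame of CNV records already filtered to one variant
#'   class (see [filter_for_network()]).
#' @param annotations named list of `term_set` objects per patient id
#'   (patients missing from the list simply contribute no phenotype edges).
#' @param variant_class label recorded on the network.
#' @param phenotype_names optional named character vector of term labels.
#' @return object of class `tripartite_network`: list with `variant_class`,
#'   `patients`, `pheno_edges` (term -> patient ids), `locus_edges`
#'   (locus_id -> patient ids), `loci` (the [segment_sors()] table) and
#'   `phenotype_names`.
#' @export
build_network <- function(cnvs, annotations,
                          variant_class = c("deletion", "duplication"),
                          phenotype_names = NULL) {
  variant_class <- match.arg(variant_class)
  if (is.null(cnvs) || !nrow(cnvs)) {
    stop("cannot build a network without CNVs: no loci can be defined")
  }
  if (!all(cnvs$variant_class == variant_class)) {
    stop("CNV records of class other than ", variant_class,
         " present; run filter_for_network() first")
  }

  patients <- sort(unique(cnvs$patient_id))
  loci <- segment_sors(cnvs)

  pheno_edges <- list()
  for (pid in intersect(names(annotations), patients)) {
    for (term in annotations[[pid]]$propagated) {
      pheno_edges[[term]] <- c(pheno_edges[[term]], pid)
    }
  }
  pheno_edges <- lapply(pheno_edges, function(p) sort(unique(p)))
  if (length(pheno_edges)) pheno_edges <- pheno_edges[order(names(pheno_edges))]

  locus_edges <- stats::setNames(loci$patient_ids, loci$locus_id)

  if (is.null(phenotype_names)) {
    phenotype_names <- stats::setNames(names(pheno_edges), names(pheno_edges))
  }

  structure(
    list(variant_class = variant_class,
         patients = patients,
         pheno_edges = pheno_edges,
         locus_edges = locus_edges,
         loci = loci,
         phenotype_names = phenotype_names),
    class = "tripartite_network")
}

#' Summary counts of a tripartite network
#'
#' Patient, locus and phenotype node counts plus the unique
#' phenotype-patient and locus-patient edge counts (each pair counted once).
#'
#' @param net a `tripartite_network`.
#' @return named list of counts.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  list(variant_class = net$variant_class,
       n_patients = length(net$patients),
       n_loci = nrow(net$loci),
       n_phenotypes = length(net$pheno_edges),
       n_pheno_edges = sum(lengths(net$pheno_edges)),
       n_locus_edges = sum(lengths(net$locus_edges)))
}

#' @export
print.tripartite_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(paste0("Tripartite %s network: %d patients, %d loci, ",
                     "%d phenotypes\n  %d phenotype-patient edges, ",
                     "%d locus-patient edges\n"),
              s$variant_class, s$n_patients, s$n_loci, s$n_phenotypes,
              s$n_pheno_edges, s$n_locus_edges))
  invisible(x)
}
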