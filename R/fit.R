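#' Fit a phenotype-locus association network
#'
#' The main entry point. Takes a cohort of patient CNVs and HPO annotations,
#' builds the tripartite network for one variant class (phenotype layer -
#' patient layer - locus layer), and scores every connected phenotype-locus
#' pair with the Hypergeometric Index
#' \deqn{HyI = -\log_{10} P(X \ge k), \quad X \sim
#'   \mathrm{Hypergeom}(N, K, n)}
#' where, within the subnetwork, \eqn{N} is the number of patients, \eqn{K}
#' the patients annotated (directly or by propagation) with the phenotype,
#' \eqn{n} the patients whose CNVs cover the locus and \eqn{k} the patients
#' shared. Pairs with `hyi >= threshold` are flagged significant
#' (`threshold = 2` is `p <= 0.01`).
#'
#' The fitted object supports `print`, `summary`, `coef` (the association
#' table), `predict` (phenotype ranking for novel query CNVs) and `plot`
#' (HyI against phenotype frequency).
#'
#' @param cnvs data.frame of CNV records (see [read_cnvs()]); filtering to
#'   `variant_class` and, by default, de novo inheritance is applied here.
#' @param annotations named list of `term_set` objects per patient
#'   (see [read_patient_hpo()]), or a data.frame with columns `patient_id`,
#'   `hpo_id` to be propagated through `ontology`.
#' @param ontology an `hpo_ontology` from [parse_obo()]; kept on the object
#'   so reports can mark most-specific vs parental terms.
#' @param variant_class `"deletion"` or `"duplication"`.
#' @param de_novo_only restrict the network to de novo CNVs.
#' @param threshold HyI significance threshold.
#' @param hyi_ceiling cap on reported HyI values (absorbs p-value underflow).
#' @return object of class `phenoloci`.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1))
#' fit <- phenoloci(sim$cnvs, sim$annotations, sim$ontology)
#' summary(fit)
#' head(coef(fit))
#' @export
phenoloci <- function(cnvs, annotations, ontology,
                      variant_class = c("deletion", "duplication"),
                      de_novo_only = TRUE, threshold = 2,
                      hyi_ceiling = 300) {
  variant_class <- match.arg(variant_class)
  stopifnot(inherits(ontology, "hpo_ontology"))
  if (threshold <= 0) stop("threshold must be positive")

  if (is.data.frame(annotations)) {
    by_patient <- split(annotations$hpo_id, annotations$patient_id)
    annotations <- lapply(by_patient,
                          function(t) propagate(ontology, unique(t)))
  }

  kept <- filter_for_network(cnvs, variant_class, de_novo_only)
  if (!nrow(kept)) {
    stop("no ", variant_class, if (de_novo_only) " de novo",
         " CNVs in the cohort; cannot define loci")
  }

  net <- build_network(kept, annotations, variant_class,
                       phenotype_names = ontology$names)
  scores <- score_all(net, threshold = threshold, hyi_ceiling = hyi_ceiling)

  structure(
    list(network = net,
         scores = scores,
         ontology = ontology,
         threshold = threshold,
         hyi_ceiling = hyi_ceiling,
         variant_class = variant_class,
         call = match.call()),
    class = "phenoloci")
}

#' @export
print.phenoloci <- function(x, ...) {
  s <- network_stats(x$network)
  cat(sprintf("Phenotype-locus association network (%s subnetwork)\n",
              x$variant_class))
  cat(sprintf("  patients: %d   loci: %d   phenotypes: %d\n",
              s$n_patients, s$n_loci, s$n_phenotypes))
  cat(sprintf("  scored pairs (k >= 1): %d, of which %d significant (HyI >= %g)\n",
              nrow(x$scores), sum(x$scores$significant), x$threshold))
  invisible(x)
}

#' @export
summary.phenoloci <- function(object, ...) {
  s <- network_stats(object$network)
  sc <- object$scores
  out <- c(s, list(
    n_scored_pairs = nrow(sc),
    n_significant = sum(sc$significant),
    threshold = object$threshold,
    max_hyi = if (nrow(sc)) max(sc$hyi) else NA_real_,
    median_hyi = if (nrow(sc)) stats::median(sc$hyi) else NA_real_))
  class(out) <- "summary.phenoloci"
  out
}

#' @export
print.summary.phenoloci <- function(x, ...) {
  cat(sprintf("%s subnetwork\n", x$variant_class))
  cat(sprintf("  patients               %d\n", x$n_patients))
  cat(sprintf("  loci                   %d\n", x$n_loci))
  cat(sprintf("  phenotypes             %d\n", x$n_phenotypes))
  cat(sprintf("  phenotype-patient edges %d\n", x$n_pheno_edges))
  cat(sprintf("  locus-patient edges    %d\n", x$n_locus_edges))
  cat(sprintf("  scored pairs           %d\n", x$n_scored_pairs))
  cat(sprintf("  significant (HyI >= %g) %d\n", x$threshold, x$n_significant))
  cat(sprintf("  max / median HyI       %.4f / %.4f\n", x$max_hyi, x$median_hyi))
  invisible(x)
}

#' Association table of a fitted network
#'
#' @param object a `phenoloci` fit.
#' @param ... unused.
#' @return the phenotype-locus association data.frame (see [score_all()]).
#' @export
coef.phenoloci <- function(object, ...) {
  object$scores
}

#' Association table accessor
#'
#' Alias for [coef.phenoloci()] with an explicit name.
#'
#' @param object a `phenoloci` fit.
#' @param significant_only keep only pairs with `hyi >= threshold`.
#' @return data.frame of association scores.
#' @export
associations <- function(object, significant_only = FALSE) {
  stopifnot(inherits(object, "phenoloci"))
  sc <- object$scores
  if (significant_only) sc <- sc[sc$significant, , drop = FALSE]
  rownames(sc) <- NULL
  sc
}

#' Plot HyI against phenotype frequency
#'
#' Scatter of each scored pair's HyI against the phenotype's patient count
#' K. Widely spread phenotypes are shared with many loci by chance, so their
#' upper-tail probabilities stay large and their scores low; the plot makes
#' that negative relationship visible for a fitted network.
#'
#' @param x a `phenoloci` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phenoloci <- function(x, ...) {
  sc <- x$scores
  if (!nrow(sc)) stop("no scored pairs to plot")
  graphics::plot(sc$K, sc$hyi,
                 xlab = "phenotype frequency K (patients)",
                 ylab = "HyI", pch = 16,
                 col = ifelse(sc$significant, "firebrick", "grey40"), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
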