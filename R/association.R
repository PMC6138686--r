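#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts shared patients when `n` patients are drawn
#' without replacement from a population of `N` patients of which `K` carry
#' the phenotype. This is the probability of observing an equal or greater
#' patient overlap between a phenotype and a locus than the one seen, under
#' the null that locus carriers are an unbiased sample of the subnetwork.
#' The tail is inclusive and is evaluated in log space, so deep tails do not
#' underflow before the log transform.
#'
#' Arguments are vectorised.
#'
#' @param N population size (patients in the subnetwork).
#' @param K patients annotated with the phenotype.
#' @param n patients at the locus.
#' @param k patients shared between phenotype and locus.
#' @return `P(X >= k)`, in `(0, 1]`.
#' @seealso [hyi()] for the minus-log10 transform.
#' @examples
#' hypergeom_tail(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# shared domain checks; all args vectorised
check_hyper_args <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n))) {
    stop("hypergeometric arguments must satisfy 0 <= k <= min(K, n), ",
         "K <= N, n <= N")
  }
  invisible(TRUE)
}

# log10 upper-tail probability, computed fully in log space
log10_hypergeom_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Hypergeometric Index
#'
#' The association score between a phenotype and a locus:
#' `HyI = -log10(p)` where `p` is the upper-tail hypergeometric probability
#' of their observed patient overlap. `HyI >= 2` corresponds to
#' `p <= 0.01`, the default significance rule. Values are capped at
#' `ceiling` to absorb probabilities that underflow double precision.
#'
#' @param p probability in `(0, 1]` (vectorised).
#' @param ceiling maximum reported score.
#' @return `-log10(p)`, `>= 0`.
#' @examples
#' hyi(0.01)  # 2
#' @export
hyi <- function(p, ceiling = 300) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  pmin(-log10(p), ceiling)
}

#' Penetrance of a phenotype at a locus
#'
#' Percentage of patients carrying a variant at the locus who express the
#' phenotype: `100 * k / n`. A penetrance of 100 means every patient with
#' the locus affected shows the phenotype.
#'
#' @param k patients at the locus with the phenotype.
#' @param n patients at the locus.
#' @return percentage in `(0, 100]` for `k >= 1`.
#' @export
penetrance <- function(k, n) {
  if (any(n == 0)) stop("penetrance undefined for a locus with no patients")
  if (any(k < 0) || any(k > n)) stop("penetrance requires 0 <= k <= n")
  100 * k / n
}

#' Score as a percentage of the phenotype's best locus
#'
#' `100 * score / best`, where `best` is the maximum HyI that phenotype
#' reaches at any locus of the subnetwork. 100 marks the phenotype's
#' best-associated locus (all tied loci score 100).
#'
#' @param score HyI value of the pair.
#' @param best maximum HyI of the phenotype across loci.
#' @return percentage in `(0, 100]`.
#' @export
pct_max <- function(score, best) {
  if (any(best == 0)) stop("pct_max undefined when the phenotype's best HyI is 0")
  if (any(score < 0) || any(score > best)) {
    stop("pct_max requires 0 <= score <= best")
  }
  100 * score / best
}

#' Score all phenotype-locus pairs of a network
#'
#' Computes, for every phenotype-locus pair sharing at least one patient, the
#' counts (N, K, n, k), the upper-tail hypergeometric p-value, the HyI, the
#' penetrance and the percent-of-maximum, and flags significant pairs
#' (`hyi >= threshold`). Pairs with no shared patient carry no evidence of
#' association and are omitted by default.
#'
#' @param net a `tripartite_network` (see [build_network()]).
#' @param threshold HyI significance threshold; 2 corresponds to p <= 0.01.
#' @param include_disconnected also emit k = 0 pairs (never significant).
#' @param hyi_ceiling cap on reported HyI values.
#' @return data.frame with one row per scored pair, ordered by phenotype id
#'   then locus position: `phenotype`, `phenotype_name`, `locus_id`, `chrom`,
#'   `start`, `end`, `N`, `K`, `n`, `k`, `p_value`, `hyi`, `penetrance`,
#'   `pct_max`, `significant`, `p_adjust` (Benjamini-Hochberg, supplementary
#'   only — the significance flag uses the raw HyI rule).
#' @export
score_all <- function(net, threshold = 2, include_disconnected = FALSE,
                      hyi_ceiling = 300) {
  stopifnot(inherits(net, "tripartite_network"))
  N <- length(net$patients)
  phenos <- names(net$pheno_edges)
  loci <- net$loci

  if (!length(phenos) || !nrow(loci)) return(empty_scores())

  pairs <- lapply(phenos, function(ph) {
    ph_patients <- net$pheno_edges[[ph]]
    k <- vapply(loci$patient_ids, function(p) length(intersect(p, ph_patients)), 1L)
    keep <- if (include_disconnected) rep(TRUE, length(k)) else k >= 1L
    if (!any(keep)) return(NULL)
    data.frame(phenotype = ph,
               locus_idx = which(keep),
               K = length(ph_patients),
               n = loci$n_patients[keep],
               k = k[keep],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(empty_scores())

  log10p <- log10_hypergeom_tail(N, pairs$K, pairs$n, pairs$k)
  score <- pmin(-log10p, hyi_ceiling)
  best <- stats::ave(score, pairs$phenotype, FUN = max)

  out <- data.frame(
    phenotype = pairs$phenotype,
    phenotype_name = unname(net$phenotype_names[pairs$phenotype]),
    locus_id = loci$locus_id[pairs$locus_idx],
    chrom = loci$chrom[pairs$locus_idx],
    start = loci$start[pairs$locus_idx],
    end = loci$end[pairs$locus_idx],
    N = N, K = pairs$K, n = pairs$n, k = pairs$k,
    p_value = 10^log10p,
    hyi = score,
    penetrance = ifelse(pairs$k >= 1, 100 * pairs$k / pairs$n, 0),
    pct_max = ifelse(best > 0, 100 * score / best, NA_real_),
    significant = score >= threshold,
    stringsAsFactors = FALSE)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  ord <- order(out$phenotype, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "hyi_ceiling") <- hyi_ceiling
  out
}

empty_scores <- function() {
  data.frame(phenotype = character(), phenotype_name = character(),
             locus_id = character(), chrom = character(),
             start = numeric(), end = numeric(),
             N = integer(), K = integer(), n = integer(), k = integer(),
             p_value = numeric(), hyi = numeric(), penetrance = numeric(),
             pct_max = numeric(), significant = logical(),
             p_adjust = numeric(), stringsAsFactors = FALSE)
}
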