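#' Rank phenotypes for one query CNV
#'
#' Maps the query interval onto the reference loci and, for each overlapped
#' locus, lists the phenotypes whose association with that locus reaches the
#' HyI threshold, sorted by HyI descending (ties broken by term id). Each
#' row carries penetrance, percent-of-maximum and the percentage of the
#' locus covered by the query, and a marker: `"+"` for terms that are the
#' most specific among those reported at the locus, `"->"` for their
#' parental (less specific) terms.
#'
#' Phenotypes detected at an overlapped locus with at least one shared
#' patient but HyI below the threshold are returned separately in
#' `detected`; they are not reliable associations but are useful context
#' when reviewing a case.
#'
#' @param object a `phenoloci` fit.
#' @param chrom,start,end query interval, 0-based half-open.
#' @param threshold report threshold; defaults to the fit's.
#' @return list with elements `hits` (overlapped loci, see [map_query()]),
#'   `ranked` (data.frame of reported phenotype rows), `detected`
#'   (below-threshold rows) and `unmatched` (query regions outside all loci).
#' @export
rank_for_cnv <- function(object, chrom, start, end,
                         threshold = object$threshold) {
  stopifnot(inherits(object, "phenoloci"))
  hits <- map_query(object$network$loci, chrom, start, end)
  unmatched <- unmatched_region(hits, chrom, start, end)
  sc <- object$scores

  ranked <- NULL
  detected <- NULL
  for (i in seq_len(nrow(hits))) {
    at_locus <- sc[sc$locus_id == hits$locus_id[i], , drop = FALSE]
    if (!nrow(at_locus)) next
    at_locus$locus_overlap_pct <- hits$locus_overlap_pct[i]
    above <- at_locus[at_locus$hyi >= threshold, , drop = FALSE]
    below <- at_locus[at_locus$hyi < threshold, , drop = FALSE]
    if (nrow(above)) {
      above <- above[order(-above$hyi, above$phenotype), , drop = FALSE]
      parts <- most_specific(object$ontology, above$phenotype)
      above$marker <- ifelse(above$phenotype %in% parts$parental, "->", "+")
      ranked <- rbind(ranked, above)
    }
    detected <- rbind(detected, below)
  }
  cols <- c("locus_id", "locus_overlap_pct", "marker", "phenotype",
            "phenotype_name", "hyi", "penetrance", "pct_max", "K", "n", "k")
  ranked <- if (is.null(ranked)) {
    empty <- empty_scores()
    empty$locus_overlap_pct <- numeric()
    empty$marker <- character()
    empty[cols]
  } else {
    rownames(ranked) <- NULL
    ranked[cols]
  }
  list(hits = hits, ranked = ranked,
       detected = if (is.null(detected)) empty_scores() else detected,
       unmatched = unmatched)
}

#' Rank phenotypes for novel clinical cases
#'
#' Scores the query CNVs of one or more novel patients against the fitted
#' reference network. Query patients are never added to the network: the
#' reference associations stay fixed, exactly as when a new case is compared
#' against an existing cohort. Only query CNVs matching the fit's variant
#' class are used (others are skipped with a message).
#'
#' @param object a `phenoloci` fit.
#' @param newdata data.frame of query CNVs (columns as [read_cnvs()]).
#' @param observed optional named list (or data.frame with `patient_id`,
#'   `hpo_id`) of clinician-observed HPO terms per patient; when given, each
#'   case report carries the diagnosed-vs-identified comparison sets.
#' @param threshold report threshold; defaults to the fit's.
#' @param strict filter defining which non-diagnosed phenotypes are reported
#'   as putative novel findings: named list with `hyi` (exclusive lower
#'   bound), `penetrance` and `locus_overlap` (required exact percentages).
#' @param ... unused.
#' @return object of class `phenoloci_cases`: a list of case reports, one
#'   per query patient. Each report is a list with `patient_id`, `queries`
#'   (per-CNV ranking results), `identified`, `detected`, and — when
#'   `observed` was supplied — `observed`, `matched`, `novel`, `missed`.
#' @export
predict.phenoloci <- function(object, newdata, observed = NULL,
                              threshold = object$threshold,
                              strict = list(hyi = 2, penetrance = 100,
                                            locus_overlap = 100), ...) {
  stopifnot(is.data.frame(newdata))
  if (is.data.frame(observed)) {
    observed <- split(observed$hpo_id, observed$patient_id)
  }
  use <- newdata$variant_class == object$variant_class
  if (any(!use)) {
    message("skipping ", sum(!use), " query CNV(s) of a different variant class")
  }
  newdata <- newdata[use, , drop = FALSE]

  reports <- lapply(split(newdata, newdata$patient_id), function(qd) {
    queries <- lapply(seq_len(nrow(qd)), function(i) {
      res <- rank_for_cnv(object, qd$chrom[i], qd$start[i], qd$end[i],
                          threshold = threshold)
      res$cnv <- qd[i, , drop = FALSE]
      res
    })
    identified <- unique(unlist(lapply(queries, function(q) q$ranked$phenotype)))
    detected <- unique(unlist(lapply(queries, function(q) q$detected$phenotype)))
    strict_ids <- unique(unlist(lapply(queries, function(q) {
      r <- q$ranked
      r$phenotype[r$hyi > strict$hyi &
                  r$penetrance == strict$penetrance &
                  r$locus_overlap_pct == strict$locus_overlap]
    })))
    report <- list(patient_id = qd$patient_id[1],
                   queries = queries,
                   identified = sort(identified),
                   identified_strict = sort(strict_ids),
                   detected = sort(detected))
    if (!is.null(observed)) {
      obs <- observed[[report$patient_id]]
      obs <- if (is.null(obs)) character()
             else propagate(object$ontology, unique(obs))$propagated
      report <- c(report, compare_with_diagnosis(report, obs))
    }
    structure(report, class = "phenoloci_case")
  })
  structure(reports, class = "phenoloci_cases")
}

#' Compare system-identified phenotypes with the clinical diagnosis
#'
#' Splits the phenotypes of a case into the three comparison sets reported
#' for clinical cohorts: `matched` (diagnosed and identified by the system),
#' `novel` (identified under the strict filter but not diagnosed — putative
#' new clinical features that may warrant follow-up), and `missed`
#' (diagnosed but not identified). `observed` must already be propagated
#' through the ontology so parental terms compare like for like.
#'
#' @param report a case report from [predict.phenoloci()] (any list with
#'   `identified` and `identified_strict` character vectors).
#' @param observed propagated clinician-observed term ids.
#' @return list with `observed`, `matched`, `novel`, `missed`.
#' @export
compare_with_diagnosis <- function(report, observed) {
  observed <- unique(as.character(observed))
  list(observed = sort(observed),
       matched = sort(intersect(observed, report$identified)),
       novel = sort(setdiff(report$identified_strict, observed)),
       missed = sort(setdiff(observed, report$identified)))
}

#' @export
print.phenoloci_case <- function(x, digits = 2, ...) {
  cat("Case", x$patient_id, "-", length(x$queries), "query CNV(s)\n")
  for (q in x$queries) {
    cat(sprintf("  CNV %s:%s-%s  (%d locus hit(s))\n",
                q$cnv$chrom, format(q$cnv$start, scientific = FALSE),
                format(q$cnv$end, scientific = FALSE), nrow(q$hits)))
    if (nrow(q$ranked)) {
      r <- q$ranked
      for (i in seq_len(nrow(r))) {
        cat(sprintf("    %-2s %s (%s)  HyI %.2f  penetrance %.1f%%  %%max %.1f%%  overlap %.1f%%\n",
                    r$marker[i], r$phenotype_name[i], r$phenotype[i],
                    r$hyi[i], r$penetrance[i], r$pct_max[i],
                    r$locus_overlap_pct[i]))
      }
    }
    if (nrow(q$unmatched)) {
      for (i in seq_len(nrow(q$unmatched))) {
        cat(sprintf("    unmatched region %s:%s-%s\n", q$unmatched$chrom[i],
                    format(q$unmatched$start[i], scientific = FALSE),
                    format(q$unmatched$end[i], scientific = FALSE)))
      }
    }
  }
  if (!is.null(x$observed)) {
    cat(sprintf("  diagnosed & identified: %d | novel (strict): %d | not identified: %d\n",
                length(x$matched), length(x$novel), length(x$missed)))
  }
  invisible(x)
}

#' @export
print.phenoloci_cases <- function(x, ...) {
  cat(length(x), "case report(s)\n")
  for (case in x) print(case, ...)
  invisible(x)
}

#' Case reports as one flat table
#'
#' One row per ranked phenotype across all cases, mirroring the per-patient
#' report tables.
#'
#' @param x a `phenoloci_cases` object.
#' @param ... unused.
#' @return data.frame with columns `patient_id`, `chrom`, `start`, `end`,
#'   `locus_id`, `locus_overlap_pct`, `marker`, `phenotype`,
#'   `phenotype_name`, `hyi`, `penetrance`, `pct_max`.
#' @export
as.data.frame.phenoloci_cases <- function(x, ...) {
  rows <- lapply(unclass(x), function(case) {
    do.call(rbind, lapply(case$queries, function(q) {
      if (!nrow(q$ranked)) return(NULL)
      data.frame(patient_id = case$patient_id,
                 chrom = q$cnv$chrom, start = q$cnv$start, end = q$cnv$end,
                 q$ranked[c("locus_id", "locus_overlap_pct", "marker",
                            "phenotype", "phenotype_name", "hyi",
                            "penetrance", "pct_max")],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      locus_id = character(), locus_overlap_pct = numeric(),
                      marker = character(), phenotype = character(),
                      phenotype_name = character(), hyi = numeric(),
                      penetrance = numeric(), pct_max = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cohort summary counters
#'
#' Aggregates the diagnosed-vs-identified comparison over a set of cases.
#' Because a phenotype can recur across patients, both countings are
#' reported: unique HPO terms and patient-phenotype pairs.
#'
#' @param cases a `phenoloci_cases` object built with `observed` supplied.
#' @return data.frame with one row per counter (`counter`, `unique_terms`,
#'   `patient_term_pairs`).
#' @export
cohort_counters <- function(cases) {
  stopifnot(inherits(cases, "phenoloci_cases"))
  grab <- function(field) lapply(unclass(cases), `[[`, field)
  counters <- list(diagnosed = grab("observed"),
                   diagnosed_and_identified = grab("matched"),
                   identified_not_diagnosed_strict = grab("novel"),
                   diagnosed_not_identified = grab("missed"))
  data.frame(
    counter = names(counters),
    unique_terms = vapply(counters, function(l)
      length(unique(unlist(l))), 1L),
    patient_term_pairs = vapply(counters, function(l)
      length(unlist(l)), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort grid of diagnosis-vs-detection tiers
#'
#' For each (phenotype, patient) cell, classifies the relationship between
#' the clinical diagnosis and the network's detection, the way syndrome
#' cohorts are summarised in a shaded grid: significant detections of a
#' diagnosed phenotype in one tier, sub-threshold detections in a second,
#' diagnoses the system never saw in a third, and strict-filter predictions
#' without a diagnosis in a fourth.
#'
#' @param cases a `phenoloci_cases` object built with `observed` supplied.
#' @param phenotypes ordered character vector of term ids to report
#'   (defaults to every term diagnosed or predicted in the cohort).
#' @return list with `grid` (character matrix phenotypes x patients with
#'   values `diagnosed_and_significant`,
#'   `diagnosed_and_detected_below_threshold`, `diagnosed_only`,
#'   `predicted_only`, `absent`) and `per_phenotype` (data.frame with
#'   diagnosed and found counts per term).
#' @export
cohort_grid <- function(cases, phenotypes = NULL) {
  stopifnot(inherits(cases, "phenoloci_cases"))
  if (any(vapply(unclass(cases), function(c) is.null(c$observed), TRUE))) {
    stop("cohort_grid needs case reports built with observed terms")
  }
  if (is.null(phenotypes)) {
    phenotypes <- sort(unique(unlist(lapply(unclass(cases), function(c)
      c(c$observed, c$novel)))))
  }
  patients <- vapply(unclass(cases), `[[`, "", "patient_id")
  grid <- matrix("absent", nrow = length(phenotypes), ncol = length(patients),
                 dimnames = list(phenotypes, patients))
  for (case in unclass(cases)) {
    for (ph in phenotypes) {
      diagnosed <- ph %in% case$observed
      sig <- ph %in% case$identified
      below <- ph %in% case$detected
      tier <- if (diagnosed && sig) "diagnosed_and_significant"
        else if (diagnosed && below) "diagnosed_and_detected_below_threshold"
        else if (diagnosed) "diagnosed_only"
        else if (ph %in% case$novel) "predicted_only"
        else "absent"
      grid[ph, case$patient_id] <- tier
    }
  }
  diagnosed_tiers <- c("diagnosed_and_significant",
                       "diagnosed_and_detected_below_threshold",
                       "diagnosed_only")
  is_diag <- matrix(grid %in% diagnosed_tiers, nrow = length(phenotypes))
  per_phenotype <- data.frame(
    phenotype = phenotypes,
    n_diagnosed = rowSums(is_diag),
    n_found_significant = rowSums(grid == "diagnosed_and_significant"),
    n_predicted_only = rowSums(grid == "predicted_only"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(grid = grid, per_phenotype = per_phenotype)
}
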