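# fixture fit shared across the query tests
qfit <- NULL
get_qfit <- function() {
  if (is.null(qfit)) qfit <<- fixture_fit(seed = 1)
  qfit
}

test_that("rank_for_cnv reports planted phenotypes ranked by HyI", {
  fx <- get_qfit()
  planted <- fx$sim$truth$planted
  res <- rank_for_cnv(fx$fit, planted$chrom[1], planted$start[1],
                      planted$end[1])
  expect_gte(nrow(res$hits), 1)
  r <- res$ranked
  expect_equal(r$phenotype[1], planted$phenotype[1])
  expect_equal(r$marker[1], "+")
  expect_true(all(diff(r$hyi[r$locus_id == r$locus_id[1]]) <= 0))
  expect_true(all(r$hyi >= fx$fit$threshold))
  # below-threshold detections are kept apart from the ranking
  expect_true(all(res$detected$hyi < fx$fit$threshold))
})

test_that("queries overlapping no locus return an empty, flagged report", {
  fx <- get_qfit()
  # beyond every simulated CNV on chromosome 3
  res <- rank_for_cnv(fx$fit, "3", 4.99e6, 5e6)
  expect_equal(nrow(res$hits), 0)
  expect_equal(nrow(res$ranked), 0)
  expect_equal(res$unmatched$start, 4.99e6)
  expect_equal(res$unmatched$end, 5e6)
})

test_that("markers partition each locus's reported set per most_specific", {
  fx <- get_qfit()
  planted <- fx$sim$truth$planted
  for (i in seq_len(nrow(planted))) {
    r <- rank_for_cnv(fx$fit, planted$chrom[i], planted$start[i],
                      planted$end[i])$ranked
    for (loc in unique(r$locus_id)) {
      at <- r[r$locus_id == loc, ]
      parts <- most_specific(fx$fit$ontology, at$phenotype)
      expect_setequal(at$phenotype[at$marker == "+"], parts$specific)
      expect_setequal(at$phenotype[at$marker == "->"], parts$parental)
    }
  }
})

test_that("self-query of a network patient's CNV recovers all its loci", {
  fx <- get_qfit()
  cnvs <- fx$sim$cnvs
  withr::local_seed(42)
  for (idx in sample(nrow(cnvs), 10)) {
    q <- cnvs[idx, ]
    res <- rank_for_cnv(fx$fit, q$chrom, q$start, q$end)
    sup <- vapply(fx$fit$network$loci$cnv_ids,
                  function(s) q$cnv_id %in% s, TRUE)
    expect_setequal(res$hits$locus_id, fx$fit$network$loci$locus_id[sup])
    expect_equal(res$hits$locus_overlap_pct,
                 rep(100, nrow(res$hits)))
    expect_equal(nrow(res$unmatched), 0)
    # the ranking at each locus is exactly the above-threshold score rows
    sc <- coef(fx$fit)
    for (loc in res$hits$locus_id) {
      expected <- sc$phenotype[sc$locus_id == loc &
                               sc$hyi >= fx$fit$threshold]
      expect_setequal(res$ranked$phenotype[res$ranked$locus_id == loc],
                      expected)
    }
  }
})

test_that("predict builds case reports and the diagnosis comparison sets", {
  fx <- get_qfit()
  planted <- fx$sim$truth$planted
  carrier <- planted$carrier_ids[[1]][1]
  observed <- list(Q1 = c(planted$phenotype[1], "HP:9999999")[1])
  query <- data.frame(patient_id = "Q1", chrom = planted$chrom[1],
                      start = planted$start[1], end = planted$end[1],
                      variant_class = "deletion", stringsAsFactors = FALSE)
  cases <- predict(fx$fit, query, observed = observed)
  expect_s3_class(cases, "phenoloci_cases")
  case <- cases[[1]]
  expect_true(planted$phenotype[1] %in% case$identified)
  expect_true(planted$phenotype[1] %in% case$matched)
  # propagated ancestors of the observed term count as observed
  expect_true(all(case$matched %in% case$observed))
  # matched/missed partition the observed set; novel is disjoint from it
  expect_setequal(c(case$matched, case$missed), case$observed)
  expect_length(intersect(case$novel, case$observed), 0)
  flat <- as.data.frame(cases)
  expect_true(all(c("patient_id", "marker", "hyi") %in% names(flat)))
  expect_equal(unique(flat$patient_id), "Q1")
})

test_that("the strict novel filter requires full penetrance and overlap", {
  fx <- get_qfit()
  planted <- fx$sim$truth$planted
  query <- data.frame(patient_id = "Q1", chrom = planted$chrom[1],
                      start = planted$start[1], end = planted$end[1],
                      variant_class = "deletion", stringsAsFactors = FALSE)
  # nothing observed: novel = strict-filtered identified set
  cases <- predict(fx$fit, query, observed = list(Q1 = character()))
  case <- cases[[1]]
  r <- do.call(rbind, lapply(case$queries, `[[`, "ranked"))
  strict_ok <- unique(r$phenotype[r$hyi > 2 & r$penetrance == 100 &
                                  r$locus_overlap_pct == 100])
  expect_setequal(case$novel, strict_ok)
  # phenotypes failing any strict leg are identified but never novel
  failing <- setdiff(unique(r$phenotype), strict_ok)
  expect_true(all(failing %in% case$identified))
  expect_length(intersect(failing, case$novel), 0)
})

test_that("queries of the other variant class are skipped", {
  fx <- get_qfit()
  query <- data.frame(patient_id = "Q1", chrom = "1", start = 0, end = 1e6,
                      variant_class = "duplication", stringsAsFactors = FALSE)
  expect_message(cases <- predict(fx$fit, query), "different variant class")
  expect_length(cases, 0)
})

test_that("cohort grid tiers reconcile with the comparison sets", {
  fx <- get_qfit()
  planted <- fx$sim$truth$planted
  bg <- fx$sim$truth$background$phenotype[1]
  queries <- data.frame(
    patient_id = c("Q1", "Q2"),
    chrom = planted$chrom, start = planted$start, end = planted$end,
    variant_class = "deletion", stringsAsFactors = FALSE)
  observed <- list(Q1 = c(planted$phenotype[1], bg),  # one hit, one miss-ish
                   Q2 = "HP:0000001")                 # root only: propagates to nothing
  cases <- predict(fx$fit, queries, observed = observed)
  g <- cohort_grid(cases)
  expect_equal(dim(g$grid), c(nrow(g$per_phenotype), 2))
  expect_equal(g$grid[planted$phenotype[1], "Q1"],
               "diagnosed_and_significant")
  # every diagnosed cell maps back to observed; counts reconcile
  counters <- cohort_counters(cases)
  n_matched <- sum(g$grid == "diagnosed_and_significant")
  expect_equal(
    counters$patient_term_pairs[counters$counter == "diagnosed_and_identified"],
    n_matched)
  diag_tiers <- c("diagnosed_and_significant",
                  "diagnosed_and_detected_below_threshold", "diagnosed_only")
  expect_equal(sum(g$grid %in% diag_tiers),
               counters$patient_term_pairs[counters$counter == "diagnosed"])
  expect_equal(sum(g$grid == "predicted_only"),
               counters$patient_term_pairs[
                 counters$counter == "identified_not_diagnosed_strict"])
  # per-phenotype "x of y diagnosed" counters agree with the grid
  expect_equal(g$per_phenotype$n_found_significant,
               unname(rowSums(g$grid == "diagnosed_and_significant")))
})
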