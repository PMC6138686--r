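test_that("the generator is deterministic and honours planted structure", {
  cfg <- sim_config(seed = 1)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$cnvs, sim2$cnvs)
  expect_identical(lapply(sim1$annotations, `[[`, "direct"),
                   lapply(sim2$annotations, `[[`, "direct"))
  expect_identical(sim1$truth, sim2$truth)

  planted <- sim1$truth$planted
  # every carrier CNV contains the planted interval
  for (i in seq_len(nrow(planted))) {
    for (p in planted$carrier_ids[[i]]) {
      pc <- sim1$cnvs[sim1$cnvs$patient_id == p &
                      sim1$cnvs$chrom == planted$chrom[i], ]
      expect_true(any(pc$start <= planted$start[i] &
                      pc$end >= planted$end[i]))
    }
  }
  # a different seed gives a different cohort
  expect_false(identical(simulate_cohort(sim_config(seed = 2))$cnvs,
                         sim1$cnvs))
})

test_that("the planted locus is supported by exactly its carriers", {
  sim <- simulate_cohort(sim_config(seed = 1))
  loci <- segment_sors(sim$cnvs)
  planted <- sim$truth$planted
  for (i in seq_len(nrow(planted))) {
    hits <- map_query(loci, planted$chrom[i], planted$start[i],
                      planted$end[i])
    expect_equal(nrow(hits), 1)  # filler CNVs never overlap the interval
    expect_setequal(hits$patient_ids[[1]], planted$carrier_ids[[i]])
    # at full penetrance the planted pair has k = n = carriers
    with_pheno <- names(Filter(function(a)
      planted$phenotype[i] %in% a$direct, sim$annotations))
    expect_setequal(with_pheno, planted$carrier_ids[[i]])
  }
})

test_that("partial penetrance assigns the phenotype to round(p * carriers)", {
  cfg <- sim_config(seed = 7, planted = data.frame(
    chrom = "1", start = 4e6, end = 4.2e6, phenotype = NA_character_,
    penetrance = 0.5, carriers = 8L, stringsAsFactors = FALSE))
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$planted
  with_pheno <- names(Filter(function(a)
    planted$phenotype[1] %in% a$direct, sim$annotations))
  expect_length(with_pheno, 4)   # round(0.5 * 8)
  expect_true(all(with_pheno %in% planted$carrier_ids[[1]]))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_patients = 5,
                          planted = data.frame(chrom = "1", start = 0,
                                               end = 100,
                                               phenotype = NA_character_,
                                               penetrance = 1,
                                               carriers = 8L)),
               "exceeds n_patients")
  expect_error(sim_config(background_prevalence = 1), "prevalence")
  expect_error(sim_config(planted = data.frame(chrom = "9", start = 0,
                                               end = 100,
                                               phenotype = NA_character_,
                                               penetrance = 1,
                                               carriers = 2L)),
               "synthetic chromosomes")
})

test_that("recovery_report finds planted pairs and counts background hits", {
  fx <- fixture_fit(seed = 1)
  rec <- recovery_report(coef(fx$fit), fx$sim$truth)
  expect_equal(nrow(rec$planted), nrow(fx$sim$truth$planted))
  expect_true(all(rec$planted$significant))
  expect_true(all(rec$planted$rank == 1))
  expect_equal(rec$planted$k, rec$planted$n)   # full penetrance
  expect_lte(rec$background_fp_rate, 0.05)

  # empty truth: no recovery rows, background counters still present
  empty <- recovery_report(coef(fx$fit),
                           list(planted = fx$sim$truth$planted[0, ],
                                background = fx$sim$truth$background))
  expect_equal(nrow(empty$planted), 0)
  expect_gt(empty$n_background_pairs, 0)
})

test_that("raising a phenotype's prevalence lowers its association score", {
  # the specific-vs-prevalent contrast: same locus and overlap k, but the
  # phenotype spread over many extra patients; HyI must drop in every run
  for (seed in 1:20) {
    sim <- simulate_cohort(sim_config(seed = seed, n_patients = 80,
                                      planted = data.frame(
                                        chrom = "1", start = 4e6, end = 4.2e6,
                                        phenotype = NA_character_,
                                        penetrance = 1, carriers = 6L)))
    fit <- phenoloci(sim$cnvs, sim$annotations, sim$ontology)
    rec <- recovery_report(coef(fit), sim$truth)
    planted <- sim$truth$planted
    # spread the planted phenotype over 40% of the non-carriers
    extra <- setdiff(names(sim$annotations), planted$carrier_ids[[1]])
    withr::local_seed(seed)
    extra <- sample(extra, round(0.4 * length(extra)))
    ann2 <- sim$annotations
    for (p in extra) {
      ann2[[p]] <- propagate(sim$ontology,
                             c(ann2[[p]]$direct, planted$phenotype[1]))
    }
    fit2 <- phenoloci(sim$cnvs, ann2, sim$ontology)
    rec2 <- recovery_report(coef(fit2), sim$truth)
    expect_lt(rec2$planted$hyi[1], rec$planted$hyi[1])
  }
})
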