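#' Configuration for a synthetic cohort
#'
#' Describes a reproducible synthetic cohort with planted phenotype-locus
#' associations, used to validate the whole pipeline when real
#' access-controlled patient data is unavailable. Defaults emulate a small
#' rare-disease cohort: 200 patients, 1-3 de novo deletion CNVs each on
#' three small chromosomes, two planted loci each carried by 8 patients at
#' full penetrance, ten high-prevalence background phenotypes at 30%
#' prevalence, and two sporadic low-frequency terms per patient.
#'
#' @param seed integer seed; the cohort is a pure function of the config.
#' @param n_patients cohort size.
#' @param chrom_lengths named numeric vector of synthetic chromosome
#'   lengths (bp).
#' @param cnv_per_patient length-2 vector, min/max CNVs per patient.
#' @param cnv_length length-2 vector, min/max filler CNV length (bp).
#' @param planted data.frame with columns `chrom`, `start`, `end`,
#'   `phenotype` (NA = assign a leaf term at generation), `penetrance`
#'   (target in (0, 1]) and `carriers`.
#' @param n_background,background_prevalence number of background
#'   phenotypes and their per-patient prevalence.
#' @param sporadic_terms extra uniformly drawn leaf terms per patient.
#' @param ontology_depth,ontology_branching shape of the generated toy
#'   ontology tree (max children per internal node).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_patients = 200,
                       chrom_lengths = c("1" = 10e6, "2" = 8e6, "3" = 5e6),
                       cnv_per_patient = c(1, 3),
                       cnv_length = c(5e4, 1e6),
                       planted = data.frame(
                         chrom = c("1", "2"),
                         start = c(4.0e6, 2.0e6),
                         end = c(4.2e6, 2.15e6),
                         phenotype = NA_character_,
                         penetrance = 1.0,
                         carriers = 8L,
                         stringsAsFactors = FALSE),
                       n_background = 10,
                       background_prevalence = 0.3,
                       sporadic_terms = 2,
                       ontology_depth = 3,
                       ontology_branching = 4) {
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              chrom_lengths = chrom_lengths,
              cnv_per_patient = cnv_per_patient, cnv_length = cnv_length,
              planted = planted, n_background = n_background,
              background_prevalence = background_prevalence,
              sporadic_terms = sporadic_terms,
              ontology_depth = ontology_depth,
              ontology_branching = ontology_branching)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  p <- cfg$planted
  if (nrow(p)) {
    if (any(p$penetrance <= 0 | p$penetrance > 1)) {
      stop("planted penetrance targets must lie in (0, 1]")
    }
    if (any(p$carriers > cfg$n_patients)) {
      stop("planted carrier count exceeds n_patients")
    }
    if (any(!p$chrom %in% names(cfg$chrom_lengths)) ||
        any(p$end > cfg$chrom_lengths[p$chrom]) || any(p$start < 0) ||
        any(p$start >= p$end)) {
      stop("planted intervals must fit inside the synthetic chromosomes")
    }
  }
  if (cfg$background_prevalence <= 0 || cfg$background_prevalence >= 1) {
    stop("background prevalence must lie in (0, 1)")
  }
  invisible(cfg)
}

# random toy ontology: a tree of term ids below a single root, with
# 2..branching children per internal node; draws from the active RNG stream
make_toy_ontology <- function(depth, branching) {
  counter <- 1L
  new_id <- function() {
    id <- sprintf("HP:%07d", counter)
    counter <<- counter + 1L
    id
  }
  root <- new_id()
  parents <- stats::setNames(list(character()), root)
  level <- root
  for (d in seq_len(depth)) {
    nxt <- character()
    for (node in level) {
      for (i in seq_len(sample(2:max(2, branching), 1L))) {
        id <- new_id()
        parents[[id]] <- node
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  ids <- names(parents)
  structure(
    list(terms = ids,
         names = stats::setNames(
           c("All", paste0("term ", ids[-1L])), ids),
         parents = parents,
         roots = root,
         obsolete = character()),
    class = "hpo_ontology")
}

#' Generate a synthetic cohort with planted associations
#'
#' Produces, deterministically from the config seed, a toy ontology, a CNV
#' table and patient HPO annotations in which each planted locus is carried
#' by exactly its configured carriers (every carrier CNV contains the
#' planted interval; filler CNVs are placed uniformly but never overlap a
#' planted interval, so the planted locus's supporting set is exactly its
#' carriers) and each planted phenotype is asserted for exactly
#' `round(penetrance * carriers)` of them. Background phenotypes are
#' assigned to every patient independently at their prevalence, and each
#' patient also draws a few sporadic leaf terms, so propagated annotation
#' profiles have both shared and private structure.
#'
#' @param config a [sim_config()].
#' @return list with `cnvs` (CNV data.frame, all de novo deletions),
#'   `annotations` (named list of `term_set`), `ontology`
#'   (the toy `hpo_ontology`), `truth` (list with `planted` data.frame —
#'   including assigned phenotype ids and carrier ids — and `background`
#'   data.frame) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  onto <- make_toy_ontology(config$ontology_depth, config$ontology_branching)

  has_child <- unique(unlist(onto$parents, use.names = FALSE))
  leaves <- setdiff(onto$terms, c(has_child, onto$roots))
  planted <- config$planted
  need <- sum(is.na(planted$phenotype)) + config$n_background
  if (need > length(leaves)) {
    stop("toy ontology has too few leaves (", length(leaves),
         ") for the configured phenotypes (", need, ")")
  }
  pool <- sample(leaves)
  fill <- is.na(planted$phenotype)
  planted$phenotype[fill] <- pool[seq_len(sum(fill))]
  pool <- setdiff(pool, planted$phenotype)
  background <- data.frame(
    phenotype = pool[seq_len(config$n_background)],
    prevalence = config$background_prevalence,
    stringsAsFactors = FALSE)
  sporadic_pool <- setdiff(leaves, c(planted$phenotype, background$phenotype))

  patients <- sprintf("P%04d", seq_len(config$n_patients))

  # carrier CNVs: contain the planted interval, extended randomly
  cnv_rows <- list()
  planted$carrier_ids <- vector("list", nrow(planted))
  for (i in seq_len(nrow(planted))) {
    carriers <- sample(patients, planted$carriers[i])
    planted$carrier_ids[[i]] <- sort(carriers)
    chrom_len <- config$chrom_lengths[[planted$chrom[i]]]
    ext_left <- floor(stats::runif(length(carriers), 1, 2e5))
    ext_right <- floor(stats::runif(length(carriers), 1, 2e5))
    cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
      patient_id = carriers,
      chrom = planted$chrom[i],
      start = pmax(0, planted$start[i] - ext_left),
      end = pmin(chrom_len, planted$end[i] + ext_right),
      variant_class = "deletion", inheritance = "de_novo",
      stringsAsFactors = FALSE)
  }

  # filler CNVs placed uniformly, rejection-sampled off planted intervals
  n_carried <- table(factor(unlist(planted$carrier_ids), levels = patients))
  target <- sample(seq(config$cnv_per_patient[1], config$cnv_per_patient[2]),
                   length(patients), replace = TRUE)
  n_fill <- pmax(0L, target - as.integer(n_carried))
  chrom_names <- names(config$chrom_lengths)
  for (j in seq_along(patients)) {
    for (f in seq_len(n_fill[j])) {
      repeat {
        chrom <- sample(chrom_names, 1L,
                        prob = as.numeric(config$chrom_lengths))
        len <- floor(stats::runif(1, config$cnv_length[1],
                                  config$cnv_length[2]))
        start <- floor(stats::runif(1, 0, config$chrom_lengths[[chrom]] - len))
        end <- start + len
        clash <- planted$chrom == chrom & planted$start < end &
                 planted$end > start
        if (!any(clash)) break
      }
      cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
        patient_id = patients[j], chrom = chrom, start = start, end = end,
        variant_class = "deletion", inheritance = "de_novo",
        stringsAsFactors = FALSE)
    }
  }
  cnvs <- do.call(rbind, cnv_rows)
  cnvs <- cnvs[order(cnvs$patient_id, cnvs$chrom, cnvs$start), , drop = FALSE]
  cnvs <- data.frame(cnv_id = sprintf("cnv%05d", seq_len(nrow(cnvs))), cnvs,
                     stringsAsFactors = FALSE)
  rownames(cnvs) <- NULL

  # phenotype assignment
  direct <- stats::setNames(vector("list", length(patients)), patients)
  for (i in seq_len(nrow(planted))) {
    carriers <- planted$carrier_ids[[i]]
    n_expr <- round(planted$penetrance[i] * length(carriers))
    expressing <- sample(carriers, n_expr)
    for (p in expressing) direct[[p]] <- c(direct[[p]], planted$phenotype[i])
  }
  for (b in seq_len(nrow(background))) {
    hit <- patients[stats::runif(length(patients)) < background$prevalence[b]]
    for (p in hit) direct[[p]] <- c(direct[[p]], background$phenotype[b])
  }
  if (config$sporadic_terms > 0 && length(sporadic_pool)) {
    for (p in patients) {
      direct[[p]] <- c(direct[[p]],
                       sample(sporadic_pool,
                              min(config$sporadic_terms,
                                  length(sporadic_pool))))
    }
  }
  annotations <- lapply(direct, function(t) propagate(onto, unique(t)))

  list(cnvs = cnvs, annotations = annotations, ontology = onto,
       truth = list(planted = planted, background = background),
       config = config)
}

#' Recovery of planted associations from a score table
#'
#' For each planted (locus, phenotype) pair, locates the scored loci
#' overlapping the planted interval, takes the locus where the planted
#' phenotype scores best, and reports its HyI, significance and competition
#' rank there (1 + the number of phenotypes with strictly greater HyI at
#' that locus; a planted leaf tying with one of its own propagated ancestors
#' still ranks 1). Also counts, over all scored pairs whose phenotype is a
#' configured background phenotype, how many reach the significance
#' threshold — the empirical false-positive rate of the score under the
#' generator's null.
#'
#' @param scores association table from [score_all()] / [coef.phenoloci()].
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param threshold HyI significance threshold.
#' @return list with `planted` (data.frame: `phenotype`, `locus_id`, `hyi`,
#'   `rank`, `significant`, `k`, `n`) and scalars `n_background_pairs`,
#'   `n_background_significant`, `background_fp_rate`.
#' @export
recovery_report <- function(scores, truth, threshold = 2) {
  planted <- truth$planted
  rows <- lapply(seq_len(nrow(planted)), function(i) {
    over <- scores$chrom == planted$chrom[i] &
            scores$start < planted$end[i] & scores$end > planted$start[i]
    mine <- over & scores$phenotype == planted$phenotype[i]
    if (!any(mine)) {
      return(data.frame(phenotype = planted$phenotype[i],
                        locus_id = NA_character_, hyi = NA_real_,
                        rank = NA_integer_, significant = FALSE,
                        k = NA_integer_, n = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    best <- which(mine)[which.max(scores$hyi[mine])]
    at_locus <- scores$locus_id == scores$locus_id[best]
    data.frame(phenotype = planted$phenotype[i],
               locus_id = scores$locus_id[best],
               hyi = scores$hyi[best],
               rank = 1L + sum(scores$hyi[at_locus] > scores$hyi[best]),
               significant = scores$hyi[best] >= threshold,
               k = scores$k[best], n = scores$n[best],
               stringsAsFactors = FALSE)
  })
  planted_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phenotype = character(), locus_id = character(),
               hyi = numeric(), rank = integer(), significant = logical(),
               k = integer(), n = integer(), stringsAsFactors = FALSE)

  bg <- scores$phenotype %in% truth$background$phenotype
  n_bg <- sum(bg)
  n_sig <- sum(bg & scores$hyi >= threshold)
  list(planted = planted_df,
       n_background_pairs = n_bg,
       n_background_significant = n_sig,
       background_fp_rate = if (n_bg) n_sig / n_bg else NA_real_)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact formats the readers consume: `cnvs.tsv` (1-based
#' inclusive coordinates), `phenotypes.tsv`, `ontology.obo`,
#' `truth_planted.tsv` and `truth_background.tsv`.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cnvs(sim$cnvs, file.path(dir, "cnvs.tsv"))
  write_patient_hpo(sim$annotations, file.path(dir, "phenotypes.tsv"))
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  planted <- sim$truth$planted
  planted$carrier_ids <- vapply(planted$carrier_ids, paste, "", collapse = ",")
  utils::write.table(planted, file.path(dir, "truth_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$background,
                     file.path(dir, "truth_background.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an ontology as an OBO file
#'
#' Minimal OBO 1.2 emitter covering the fields [parse_obo()] reads.
#'
#' @param onto an `hpo_ontology`.
#' @param file output path.
#' @export
write_obo <- function(onto, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in onto$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", onto$names[[t]]),
                 paste0("is_a: ", onto$parents[[t]])), con)
  }
  for (t in names(onto$obsolete)) {
    writeLines(c("", "[Term]", paste0("id: ", t), "is_obsolete: true"), con)
    if (!is.na(onto$obsolete[[t]])) {
      writeLines(paste0("replaced_by: ", onto$obsolete[[t]]), con)
    }
  }
  invisible(file)
}
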