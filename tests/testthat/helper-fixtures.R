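# Shared fixtures and independent oracles, built in code at test time.

# -- tiny ontologies ---------------------------------------------------------

obo_lines <- function(...) paste(c(...), collapse = "\n")

obo_term <- function(id, name = id, is_a = character(), obsolete = FALSE,
                     replaced_by = NULL) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("is_a: ", is_a),
    if (obsolete) "is_obsolete: true",
    if (!is.null(replaced_by)) paste0("replaced_by: ", replaced_by))
}

# root -> A -> B -> D, root -> C, D also is_a C (diamond via A/C at level 1)
chain_onto <- function() {
  parse_obo(obo_lines(
    obo_term("HP:0000001", "All"),
    obo_term("HP:0000002", "A", "HP:0000001 ! All"),
    obo_term("HP:0000003", "B", "HP:0000002"),
    obo_term("HP:0000004", "C", "HP:0000001"),
    obo_term("HP:0000005", "D", c("HP:0000003", "HP:0000004"))))
}

# random DAG ontology for property tests: terms t2..tn each pick 1-2 parents
# among earlier terms (t1 is the root), so acyclicity holds by construction
random_onto <- function(n_terms, seed) {
  withr::local_seed(seed)
  ids <- sprintf("HP:%07d", seq_len(n_terms))
  stanzas <- lapply(seq_along(ids), function(i) {
    if (i == 1) return(obo_term(ids[1], "All"))
    parents <- sample(ids[seq_len(i - 1)], min(sample(1:2, 1), i - 1))
    obo_term(ids[i], paste0("term", i), parents)
  })
  parse_obo(obo_lines(unlist(stanzas)))
}

# -- tiny CNV cohorts --------------------------------------------------------

cnv_row <- function(patient_id, chrom, start, end,
                    variant_class = "deletion", inheritance = "de_novo",
                    cnv_id = NULL) {
  data.frame(cnv_id = if (is.null(cnv_id)) paste0("c_", patient_id, "_",
                                                  start) else cnv_id,
             patient_id = patient_id, chrom = as.character(chrom),
             start = start, end = end, variant_class = variant_class,
             inheritance = inheritance, stringsAsFactors = FALSE)
}

random_cnvs <- function(n, max_coord = 1000, chroms = c("1", "2")) {
  starts <- sample(0:(max_coord - 2), n, replace = TRUE)
  lens <- sample(1:(max_coord / 4), n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cnv_row(sprintf("P%02d", sample(ceiling(n / 2), 1)),
            sample(chroms, 1), starts[i],
            min(max_coord, starts[i] + lens[i]), cnv_id = sprintf("c%03d", i))
  }))
}

# -- per-base SOR oracle -----------------------------------------------------
# For every base, the set of covering CNVs; run-length encode the non-empty
# stretches. Independent of the breakpoint-sweep implementation.
oracle_sors <- function(cnvs) {
  out <- lapply(split(cnvs, cnvs$chrom), function(cc) {
    lo <- min(cc$start); hi <- max(cc$end)
    bases <- seq(lo, hi - 1)
    key <- vapply(bases, function(b)
      paste(sort(cc$cnv_id[cc$start <= b & cc$end > b]), collapse = ","), "")
    r <- rle(key)
    end_idx <- cumsum(r$lengths)
    start_idx <- c(1, utils::head(end_idx, -1) + 1)
    keep <- nzchar(r$values)
    data.frame(chrom = cc$chrom[1],
               start = bases[start_idx[keep]],
               end = bases[end_idx[keep]] + 1,
               key = r$values[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

# -- exact hypergeometric tail oracle ---------------------------------------
# Tail sum of binomial-coefficient products over a common denominator
# C(N, n); every intermediate integer is < 2^53 for N <= 30, so the
# arithmetic is exact.
oracle_tail <- function(N, K, n, k) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# small fitted model on a deterministic synthetic cohort
fixture_fit <- function(seed = 1, ...) {
  sim <- simulate_cohort(sim_config(seed = seed, ...))
  list(sim = sim,
       fit = phenoloci(sim$cnvs, sim$annotations, sim$ontology))
}
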