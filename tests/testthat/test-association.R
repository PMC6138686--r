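test_that("hypergeom_tail matches exact enumeration on the worked cases", {
  # frozen expected values computed with the rational oracle
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeom_tail(20, 3, 3, 3), 1 / 1140, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 4), oracle_tail(10, 5, 4, 4))
  expect_error(hypergeom_tail(10, 11, 4, 4), "hypergeometric")
  expect_error(hypergeom_tail(10, 5, 4, 5), "hypergeometric")
})

test_that("hypergeom_tail is symmetric in K and n", {
  grid <- expand.grid(N = c(8, 15, 25), K = 1:6, n = 1:6, k = 0:4)
  grid <- grid[grid$k <= pmin(grid$K, grid$n), ]
  expect_equal(hypergeom_tail(grid$N, grid$K, grid$n, grid$k),
               hypergeom_tail(grid$N, grid$n, grid$K, grid$k))
})

test_that("hyi transforms probabilities on the -log10 scale with a cap", {
  expect_identical(hyi(0.01), 2)
  expect_identical(hyi(1), 0)
  expect_equal(hyi(8.77193e-4), 3.0569, tolerance = 1e-4)
  expect_equal(hyi(1e-310), 300)   # underflow absorbed by the ceiling
  expect_equal(hyi(1e-310, ceiling = 50), 50)
  expect_error(hyi(0), "\\(0, 1\\]")
  expect_error(hyi(1.5), "\\(0, 1\\]")
})

test_that("penetrance and pct_max are plain percentages with guards", {
  expect_equal(penetrance(4, 4), 100)
  expect_equal(penetrance(3, 4), 75)
  expect_equal(penetrance(1, 2), 50)
  expect_error(penetrance(1, 0), "no patients")
  expect_equal(pct_max(3, 3), 100)
  expect_equal(pct_max(2, 4), 50)
  expect_equal(pct_max(0.5, 1), 50)
  expect_error(pct_max(1, 0), "best")
  expect_error(pct_max(5, 4), "score <= best")
})

test_that("tail is monotone: non-increasing in k, non-decreasing as K grows", {
  for (N in c(10, 20, 30)) {
    for (K in c(2, 5, N - 1)) {
      for (n in c(2, 5, N - 1)) {
        p_k <- hypergeom_tail(N, K, n, 0:min(K, n))
        expect_true(all(diff(p_k) <= 1e-15))
        # fixing k, a more frequent phenotype gives a larger tail -> lower HyI
        k <- min(2, K, n)
        p_K <- vapply(k:N, function(KK)
          hypergeom_tail(N, KK, n, min(k, KK, n)), 1)
        expect_true(all(diff(p_K) >= -1e-15))
      }
    }
  }
})

toy_net <- function() {
  # 20 patients; P1..P3 share a CNV (one locus); phenotype A in exactly those
  # three; phenotype B in everyone; phenotype C in P4 only (no locus patient)
  cnvs <- rbind(cnv_row("P01", "1", 10, 20, cnv_id = "c1"),
                cnv_row("P02", "1", 10, 20, cnv_id = "c2"),
                cnv_row("P03", "1", 10, 20, cnv_id = "c3"),
                do.call(rbind, lapply(4:20, function(i)
                  cnv_row(sprintf("P%02d", i), "2", 100 * i, 100 * i + 50,
                          cnv_id = sprintf("c%02d", i)))))
  onto <- parse_obo(obo_lines(
    obo_term("HP:0000001", "All"),
    obo_term("HP:0000002", "A", "HP:0000001"),
    obo_term("HP:0000003", "B", "HP:0000001"),
    obo_term("HP:0000004", "C", "HP:0000001")))
  ann <- c(
    lapply(sprintf("P%02d", 1:3), function(p)
      propagate(onto, c("HP:0000002", "HP:0000003"))),
    list(propagate(onto, c("HP:0000003", "HP:0000004"))),
    lapply(5:20, function(i) propagate(onto, "HP:0000003")))
  names(ann) <- sprintf("P%02d", 1:20)
  build_network(cnvs, ann, "deletion")
}

test_that("score_all reproduces the composed oracle on a toy network", {
  sc <- score_all(toy_net())
  a <- sc[sc$phenotype == "HP:0000002" & sc$locus_id == "1:10-20", ]
  expect_equal(nrow(a), 1)
  expect_equal(c(a$N, a$K, a$n, a$k), c(20, 3, 3, 3))
  expect_equal(a$p_value, 1 / 1140, tolerance = 1e-12)
  expect_equal(a$hyi, 3.0569, tolerance = 1e-4)
  expect_equal(a$penetrance, 100)
  expect_equal(a$pct_max, 100)
  expect_true(a$significant)

  # a phenotype carried by every patient is a certain event: HyI = 0
  b <- sc[sc$phenotype == "HP:0000003" & sc$locus_id == "1:10-20", ]
  expect_equal(c(b$K, b$k), c(20, 3))
  expect_equal(b$p_value, 1)
  expect_equal(b$hyi, 0)
  expect_false(b$significant)

  # pairs with no shared patient are not emitted
  expect_false(any(sc$phenotype == "HP:0000004" & sc$locus_id == "1:10-20"))
  expect_true(all(sc$k >= 1))

  # but can be requested for completeness
  full <- score_all(toy_net(), include_disconnected = TRUE)
  expect_true(any(full$k == 0))
  expect_false(any(full$significant[full$k == 0]))
})

test_that("significance flag flips exactly at p = 10^-threshold", {
  sc <- score_all(toy_net())
  expect_equal(sc$significant, sc$p_value <= 10^-2)
  relaxed <- score_all(toy_net(), threshold = 0.5)
  expect_equal(relaxed$significant, relaxed$p_value <= 10^-0.5)
  expect_equal(relaxed$hyi, sc$hyi)  # threshold only moves the flag
})

test_that("pct_max is 100 exactly for a phenotype's best loci, ties included", {
  # two identical loci on different chromosomes, same phenotype carriers
  cnvs <- rbind(cnv_row("P1", "1", 0, 10, cnv_id = "a1"),
                cnv_row("P2", "1", 0, 10, cnv_id = "a2"),
                cnv_row("P1", "2", 0, 10, cnv_id = "b1"),
                cnv_row("P2", "2", 0, 10, cnv_id = "b2"),
                cnv_row("P3", "3", 0, 10, cnv_id = "c1"))
  onto <- parse_obo(obo_lines(obo_term("HP:0000001", "All"),
                              obo_term("HP:0000002", "A", "HP:0000001")))
  ann <- list(P1 = propagate(onto, "HP:0000002"),
              P2 = propagate(onto, "HP:0000002"))
  sc <- score_all(build_network(cnvs, ann, "deletion"))
  ph <- sc[sc$phenotype == "HP:0000002", ]
  expect_equal(nrow(ph), 2)
  expect_equal(ph$pct_max, c(100, 100))
  expect_equal(ph$hyi[1], ph$hyi[2])
})
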