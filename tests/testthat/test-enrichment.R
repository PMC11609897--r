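test_that("E-values are pulldown/input frequency ratios", {
  d <- pool_design(toy_scaffold(), 1)  # 4 variants: A, C, G, U
  tin <- manual_counts("toy", c("A", "C", "G", "U"), c(50, 50, 50, 50))
  # identical tables give E = 1 everywhere; each degenerate scope warns
  # (the zero-sd warning itself is asserted in the z-score test below)
  e0 <- suppressWarnings(srbns_enrichment(tin, tin, d, pseudocount = 0))
  expect_true(all(abs(e0$E - 1) < 1e-12))
  # direct ratio arithmetic on a two-variant imbalance
  tpd <- manual_counts("toy", c("A", "C", "G", "U"), c(75, 25, 50, 50), "50")
  e1 <- srbns_enrichment(tin, tpd, d, pseudocount = 0)
  co <- summary(e1)
  expect_equal(co$E[co$loop == "A"], (75 / 200) / (50 / 200), tolerance = 1e-12)
  expect_equal(co$E[co$loop == "C"], 0.5, tolerance = 1e-12)
  expect_identical(unique(co$concentration), "50")
})

test_that("conservation: sum f_in * E = 1 without pseudocount (random tables)", {
  d <- cde_design(3)
  pool <- build_pool(d)
  set.seed(7)
  for (rep in 1:5) {
    ci <- rpois(nrow(pool), 40) + 1L   # full support
    cp <- rpois(nrow(pool), 40) + 1L
    tin <- manual_counts(pool$scaffold, pool$loop, ci)
    tpd <- manual_counts(pool$scaffold, pool$loop, cp, "50")
    enr <- srbns_enrichment(tin, tpd, d, pseudocount = 0)
    for (sc in unique(enr$scope)) {
      sub <- enr[enr$scope == sc, ]
      expect_lt(abs(sum(sub$f_in * sub$E) - 1), 1e-9)
    }
  }
})

test_that("dropout variants are flagged, never silently dropped", {
  d <- pool_design(toy_scaffold(), 1)
  tin <- manual_counts("toy", c("A", "C", "G"), c(50, 50, 50))  # U absent
  tpd <- manual_counts("toy", c("A", "C", "G", "U"), c(50, 50, 50, 5), "50")
  # the three defined E are identical here, so the degenerate-sd warning
  # fires once per scope
  enr <- suppressWarnings(srbns_enrichment(tin, tpd, d, pseudocount = 0))
  co <- summary(enr)
  expect_identical(nrow(co), 4L)          # all designed variants present
  expect_true(is.na(co$E[co$loop == "U"]))
  # with the default pseudocount E is defined for everything
  co2 <- summary(srbns_enrichment(tin, tpd, d))
  expect_false(anyNA(co2$E))
})

test_that("z-scores standardize E within scope and flag z > 3", {
  expect_equal(zscores(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(z <- zscores(c(2, 2, 2)), "identical")
  expect_identical(z, c(0, 0, 0))
  # direct-formula oracle on a vector with one large outlier; note a sample
  # z-score is bounded by (n-1)/sqrt(n), so the pool must be large enough
  # for any variant to clear z = 3 at all
  set.seed(1)
  E <- c(runif(19, 0.5, 1.5), 40)
  z <- zscores(E)
  z_direct <- (E - mean(E)) / sqrt(sum((E - mean(E))^2) / (length(E) - 1))
  expect_equal(z, z_direct, tolerance = 1e-12)
  expect_true(z[20] > 3 && all(z[1:19] < 3))
  # location-scale invariance of the significant set under positive scaling
  expect_equal(zscores(7 * E), z, tolerance = 1e-12)
})

test_that("stem enrichment is the pulldown/input share ratio vs a reference", {
  tin <- manual_counts(c("TNF", "UCP3"), c("UGU", "UAU"), c(500, 500))
  tpd <- manual_counts(c("TNF", "UCP3"), c("UGU", "UAU"), c(588, 412), "50")
  fe <- stem_enrichment(tin, tpd, reference = "UCP3")
  expect_equal(unname(fe["TNF"]), (0.588 / 0.5) / (0.412 / 0.5),
               tolerance = 1e-12)
  expect_identical(unname(fe["UCP3"]), 1)
  # identical shares give ratio 1 for all scaffolds
  fe0 <- stem_enrichment(tin, tin, reference = "UCP3")
  expect_true(all(abs(fe0 - 1) < 1e-12))
  expect_error(stem_enrichment(tin, tpd, reference = "HOMEZ"), "absent")
})

test_that("effective loop collapses outer Watson-Crick pairs into the stem", {
  expect_identical(effective_loop("CUGUG"),
                   list(collapsed = "UGU", extra_bp = 1L))
  expect_identical(effective_loop("GAAUC"),
                   list(collapsed = "AAU", extra_bp = 1L))
  expect_identical(effective_loop("AUGUC"),
                   list(collapsed = "AUGUC", extra_bp = 0L))
  # G-U wobble does not count for loop collapse
  expect_identical(effective_loop("GUGUU")$extra_bp, 0L)
  expect_error(effective_loop("AU"), "at least 3")
  # property: collapsed loop never shorter than 3 nt
  set.seed(3)
  for (i in 1:200) {
    l <- random_rna(sample(3:8, 1))
    res <- effective_loop(l)
    expect_gte(nchar(res$collapsed), 3L)
    expect_identical(nchar(res$collapsed) + 2L * res$extra_bp, nchar(l))
  }
})

test_that("enrichment logos are enrichment-weighted probability matrices", {
  loops <- enumerate_loop_variants(3)
  rec <- data.frame(loop = loops, E = rep(1, 64))
  m <- enrichment_logo(rec)
  expect_true(all(abs(m - 0.25) < 1e-12))
  # one-hot: all enrichment on a single variant
  rec$E <- as.numeric(loops == "UAU")
  m1 <- enrichment_logo(rec)
  expect_equal(unname(m1[1, ]), c(0, 0, 0, 1))  # U
  expect_equal(unname(m1[2, ]), c(1, 0, 0, 0))  # A
  expect_equal(unname(m1[3, ]), c(0, 0, 0, 1))  # U
  # random E against an independent brute-force summation
  set.seed(9)
  rec$E <- runif(64)
  m2 <- enrichment_logo(rec)
  for (p in 1:3) for (b in c("A", "C", "G", "U")) {
    direct <- sum(rec$E[substr(rec$loop, p, p) == b]) / sum(rec$E)
    expect_equal(unname(m2[p, b]), direct, tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(m2)), rep(1, 3), tolerance = 1e-9)
  expect_error(enrichment_logo(data.frame(loop = c("UAU", "UAUA"),
                                          E = c(1, 1))), "single loop length")
})

test_that("enrichment output writes and prints without error", {
  d <- pool_design(toy_scaffold(), 3)
  pool <- build_pool(d)
  set.seed(11)
  tin <- manual_counts(pool$scaffold, pool$loop, rpois(64, 50) + 1L)
  tpd <- manual_counts(pool$scaffold, pool$loop, rpois(64, 50) + 1L, "500")
  enr <- srbns_enrichment(tin, tpd, d)
  expect_output(print(enr), "sRBNS enrichment")
  tsv <- tempfile(fileext = ".tsv"); logo <- tempfile(fileext = ".tsv")
  write_enrichment(enr, tsv, logo_path = logo)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(enr))
  lm <- read.table(logo, header = TRUE, sep = "\t")
  expect_equal(rowSums(lm[, c("A", "C", "G", "U")]), rep(1, 3),
               tolerance = 1e-9)
})
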