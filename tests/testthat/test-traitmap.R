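test_that("Yates chi-square clamps at perfect fit and is swap-symmetric", {
  expect_equal(yates_chisq(c(30, 10), c(3, 1))$statistic, 0)
  a <- yates_chisq(c(231, 71), c(3, 1))
  b <- yates_chisq(c(71, 231), c(1, 3))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$df, 1L)
  expect_equal(a$verdict, "fits")
  expect_error(yates_chisq(c(0, 0), c(3, 1)), "zero total")
  expect_error(yates_chisq(c(10, 5), c(3, 0)), "ratio")
})

# 120 progeny, 29 determinate, perfectly co-segregating recessive marker
perfect_fixture <- function() {
  g <- c(rep("AA", 29), rep("H", 60), rep("BB", 31))
  y <- c(rep("determinate", 29), rep("indeterminate", 91))
  geno <- rbind(trait = g,
                unlinked = sample(c("AA", "H", "BB"), 120, TRUE,
                                  prob = c(1, 2, 1)))
  list(geno = geno, y = y,
       map = manual_map(c("trait", "unlinked"), c(0, 40)))
}

test_that("scan LOD at a perfect marker matches the closed form", {
  set.seed(99)
  fx <- perfect_fixture()
  sc <- locus_scan(fx$map, fx$geno, fx$y, positions = "bins")
  lod_closed <- 91 * log10(120 / 91) + 29 * log10(120 / 29)
  peak <- attr(sc, "peak")
  expect_equal(peak$bin_id, "trait")
  expect_equal(peak$lod, lod_closed, tolerance = 1e-9)
  expect_equal(round(peak$lod, 2), 28.82)
  expect_equal(attr(sc, "r2"), 1)
  # an unlinked marker carries little signal
  expect_lt(sc[sc$bin_id == "unlinked", ]$lod, 3)
  # constant phenotype: scan defined, all LOD zero
  sc0 <- locus_scan(fx$map, fx$geno, rep("indeterminate", 120),
                    positions = "bins")
  expect_true(all(sc0$lod == 0))
  # R2 is invariant to phenotype relabeling
  y_swapped <- ifelse(fx$y == "determinate", "indeterminate", "determinate")
  sc_sw <- locus_scan(fx$map, fx$geno, y_swapped, positions = "bins")
  expect_equal(attr(sc_sw, "r2"), attr(sc, "r2"), tolerance = 1e-9)
})

test_that("virtual positions interpolate between flanking markers", {
  set.seed(13)
  fx <- perfect_fixture()
  sc <- locus_scan(fx$map, fx$geno, fx$y, step = 2, positions = "all")
  expect_true(any(sc$type == "virtual"))
  # LOD at virtual positions decays away from the causal marker
  v <- sc[sc$type == "virtual", ]
  expect_true(all(v$lod <= attr(sc, "peak")$lod + 1e-9))
  # support interval covers the peak
  si <- attr(sc, "support_interval")
  expect_lte(si$lo, attr(sc, "peak")$pos_cM)
  expect_gte(si$hi, attr(sc, "peak")$pos_cM)
})

test_that("permutation threshold is deterministic and zero when degenerate", {
  set.seed(1)
  fx <- perfect_fixture()
  t1 <- permutation_threshold(fx$map, fx$geno, fx$y, n_perm = 150,
                              seed = 11, positions = "bins")
  t2 <- permutation_threshold(fx$map, fx$geno, fx$y, n_perm = 150,
                              seed = 11, positions = "bins")
  expect_identical(t1, t2)
  expect_gt(t1, 0)
  t0 <- permutation_threshold(fx$map, fx$geno,
                              rep("indeterminate", 120), n_perm = 50,
                              seed = 2, positions = "bins")
  expect_equal(as.numeric(t0), 0)
  # EM path (fractional weights via virtual positions) agrees with the
  # closed-form path at bin positions
  t3 <- permutation_threshold(fx$map, fx$geno, fx$y, n_perm = 30,
                              seed = 5, positions = "bins")
  fx_na <- fx
  fx_na$geno[2, 1] <- NA      # one missing entry forces the EM path
  t4 <- permutation_threshold(fx_na$map, fx_na$geno, fx$y, n_perm = 30,
                              seed = 5, positions = "bins")
  expect_lt(abs(t3 - t4), 0.75)
})

test_that("co-segregation coefficients pool populations", {
  g1 <- c(rep("AA", 100), rep("H", 200), rep("BB", 100))
  y1 <- c(rep(1, 100), rep(0, 300))
  full <- cosegregation(g1, y1)
  expect_equal(full$coefficient, 100)
  expect_true(full$fully_cosegregating)
  y2 <- y1
  y2[1:22] <- 0                      # 22 mismatches out of 400
  part <- cosegregation(g1, y2)
  expect_equal(part$coefficient, 94.5)
  expect_false(part$fully_cosegregating)
  pooled <- cosegregation(list(g1, g1), list(y1, y2))
  expect_equal(pooled$coefficient, 100 * (400 + 378) / 800)
  expect_error(cosegregation(rep(NA_character_, 5), rep(1, 5)),
               "zero scored")
})

test_that("a marker 1 cM from the trait locus breaks co-segregation", {
  # P(no recombinant among 2 x 400 gametes) is tiny at r = 0.01
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    r <- kosambi_inv(1)
    t1 <- sample(0:1, n, TRUE); t2 <- sample(0:1, n, TRUE)
    m1 <- ifelse(runif(n) < r, 1L - t1, t1)
    m2 <- ifelse(runif(n) < r, 1L - t2, t2)
    y <- as.integer(t1 + t2 == 0)
    g <- c("AA", "H", "BB")[m1 + m2 + 1L]
    cosegregation(g, y)$coefficient < 100
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("physical interval arithmetic and annotation overlap", {
  iv <- physical_interval(data.frame(scaffold = "Scaffold00170",
                                     pos = c(2464, 294813)))
  expect_equal(iv$span_kb, 292.35)
  expect_equal(iv$span_bp, 292349)
  expect_equal(physical_interval(data.frame(scaffold = "s", pos = c(5, 5)))$span_kb,
               0)
  expect_error(physical_interval(data.frame(scaffold = c("a", "b"),
                                            pos = c(1, 2))),
               "different scaffolds")
  ann <- data.frame(gene_id = sprintf("g%02d", 1:30),
                    scaffold = "Scaffold00170",
                    start = seq(3000, by = 10000, length.out = 30),
                    end = seq(4000, by = 10000, length.out = 30))
  iv2 <- physical_interval(data.frame(scaffold = "Scaffold00170",
                                      pos = c(2464, 294813)), ann)
  expect_equal(nrow(iv2$genes), sum(ann$start <= 294813 & ann$end >= 2464))
})
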