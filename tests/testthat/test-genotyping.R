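# build a genotype_matrix fixture directly: one scaffold, evenly spaced loci
fixture_gm <- function(sym, dp, spacing_bp = 1e4, threshold = 5L) {
  L <- nrow(sym)
  loci <- data.table::data.table(
    locus_id = sprintf("s1_%09d", seq_len(L) * spacing_bp),
    scaffold = "s1", pos = seq_len(L) * spacing_bp,
    ref = "A", alt = "G", is_indel = FALSE, origin = "P1")
  dimnames(sym) <- list(loci$locus_id, sprintf("F%03d", seq_len(ncol(sym))))
  dimnames(dp) <- dimnames(sym)
  structure(list(loci = loci, geno = sym, dp = dp,
                 depth_threshold = threshold,
                 progeny = colnames(sym)), class = "genotype_matrix")
}

test_that("six-symbol coding follows the depth criteria", {
  expect_equal(code_genotype("P1", "1/1", 5L), "AA")
  expect_equal(code_genotype("P1", "1/1", 4L), "D")
  expect_equal(code_genotype("P1", "0/0", 7L), "BB")
  expect_equal(code_genotype("P1", "0/0", 2L), "C")
  expect_equal(code_genotype("P2", "1/1", 9L), "BB")
  expect_equal(code_genotype("P2", "0/0", 1L), "D")
  expect_equal(code_genotype("P1", "0/1", 1L), "H")
  expect_equal(code_genotype("P1", "./.", 0L), "-")
  expect_error(code_genotype("P1", "1/2", 5L), "allele")
})

test_that("F2 transition kernel is stochastic with the right limits", {
  for (r in seq(0, 0.5, by = 0.05)) {
    tr <- f2_transition(r)
    expect_equal(rowSums(tr), c(AA = 1, H = 1, BB = 1))
  }
  expect_equal(f2_transition(0), diag(3), ignore_attr = TRUE)
  st <- f2_transition(0.5)
  for (i in 1:3) expect_equal(unname(st[i, ]), c(0.25, 0.5, 0.25))
})

test_that("posterior decoding equals exhaustive path enumeration", {
  params <- hmm_params()
  set.seed(42)
  for (case in 1:12) {
    L <- sample(2:8, 1L)
    sym <- sample(c("AA", "BB", "H", "C", "D", "-"), L, replace = TRUE)
    dp <- ifelse(sym %in% c("C", "D"), sample(1:4, L, replace = TRUE),
                 sample(5:12, L, replace = TRUE))
    dp[sym == "-"] <- 0L
    dp[sym == "H"] <- pmax(dp[sym == "H"], 2L)
    pos <- sort(sample.int(5e6, L))
    expect_equal(hmm_posterior(sym, dp, pos, params),
                 enum_posterior(sym, dp, pos, params),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("correction fixes low-confidence symbols and singleton errors", {
  # run of 20 AA with one central D at low depth, tight spacing
  sym <- matrix(rep("AA", 20), ncol = 1)
  sym[10, 1] <- "D"
  dp <- matrix(rep(10L, 20), ncol = 1)
  dp[10, 1] <- 2L
  gm <- fixture_gm(sym, dp, spacing_bp = 1e4)
  corr <- hmm_correct(gm)
  expect_equal(unname(corr[10, 1]), "AA")
  expect_equal(unname(corr[-10, 1]), rep("AA", 19))
  # isolated confident BB inside an AA run at tight spacing: a double
  # crossover is far less likely than a miscall, so the entry is flipped to
  # whatever the path-enumeration oracle says explains a wrong homozygote
  # best (state H at this depth, since (1/2)^k dwarfs eps^k)
  sym2 <- matrix(rep("AA", 21), ncol = 1)
  sym2[11, 1] <- "BB"
  dp2 <- matrix(rep(8L, 21), ncol = 1)
  gm2 <- fixture_gm(sym2, dp2, spacing_bp = 100)   # 100 bp = 0.0001 cM
  params2 <- hmm_params(epsilon = 0.005)
  corr2 <- hmm_correct(gm2, params2)
  po <- enum_posterior(sym2[7:15, 1], dp2[7:15, 1],
                       gm2$loci$pos[7:15], params2)
  oracle_state <- c("AA", "H", "BB")[which.max(po[5, ])]
  expect_equal(unname(corr2[11, 1]), oracle_state)
  expect_false(identical(unname(corr2[11, 1]), "BB"))
  # all-missing progeny stays missing
  sym3 <- matrix(rep("-", 6), ncol = 1)
  gm3 <- fixture_gm(sym3, matrix(rep(0L, 6), ncol = 1))
  expect_true(all(is.na(hmm_correct(gm3))))
  # output alphabet and shape are preserved
  expect_identical(dim(corr2), dim(sym2))
  expect_true(all(corr2 %in% c("AA", "H", "BB") | is.na(corr2)))
  # unsorted loci are rejected
  gm_bad <- gm
  gm_bad$loci$pos <- rev(gm_bad$loci$pos)
  expect_error(hmm_correct(gm_bad), "sorted")
})

test_that("raising epsilon never reduces singleton flips on a fixture", {
  set.seed(7)
  L <- 60
  sym <- matrix("AA", L, 5)
  planted <- matrix(FALSE, L, 5)
  for (j in 1:5) planted[sample.int(L, 4), j] <- TRUE
  sym[planted] <- "BB"                              # planted singletons
  dp <- matrix(6L, L, 5)
  gm <- fixture_gm(sym, dp, spacing_bp = 5e3)
  # a singleton counts as corrected when it no longer asserts the planted
  # symbol (flipped to another state or blanked to missing)
  flips <- vapply(c(0.001, 0.005, 0.02, 0.05), function(eps) {
    corr <- hmm_correct(gm, hmm_params(epsilon = eps))
    sum(corr[planted] != "BB" | is.na(corr[planted]))
  }, 1)
  expect_true(all(diff(flips) >= 0))
  expect_gt(flips[1], 0)
})

test_that("genotype accuracy contract", {
  x <- matrix(c("AA", "H", NA, "BB"), 2, 2)
  tr <- matrix(c("AA", "H", "AA", "BB"), 2, 2)
  expect_equal(genotype_accuracy(x, tr)$accuracy, 1)
  expect_equal(genotype_accuracy(x, tr)$n_scored, 3L)
  tr2 <- tr; tr2[1, 1] <- "BB"
  expect_equal(genotype_accuracy(x, tr2)$accuracy, 2 / 3)
  expect_error(genotype_accuracy(x, tr[1, , drop = FALSE]), "dimension")
  all_na <- matrix(NA_character_, 2, 2)
  expect_true(is.na(genotype_accuracy(all_na, tr)$accuracy))
  expect_equal(genotype_accuracy(all_na, tr)$n_scored, 0L)
})
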