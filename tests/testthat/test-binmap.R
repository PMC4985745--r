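test_that("Kosambi function matches closed forms and inverts exactly", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))
  expect_equal(round(kosambi(0.25), 2), 27.47)
  expect_equal(round(kosambi(0.49), 2), 114.88)   # 25 ln 99 = 114.878
  r <- seq(0, 0.499, by = 0.001)
  expect_equal(kosambi_inv(kosambi(r)), r, tolerance = 1e-10)
  expect_true(all(diff(kosambi(r)) > 0))
  expect_true(all(diff(diff(kosambi(r))) > 0))    # convex
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi(-0.01), "0.5")
  expect_error(kosambi_inv(-1), ">= 0")
})

mk_loci <- function(n, scaffold = "s1", spacing = 1e4) {
  data.table::data.table(locus_id = sprintf("%s_%09d", scaffold,
                                            seq_len(n) * spacing),
                         scaffold = scaffold, pos = seq_len(n) * spacing)
}

test_that("bin collapsing merges co-segregating runs only", {
  g <- rbind(c("AA", "H", "BB"),
             c("AA", "H", "BB"),
             c("AA", "AA", "BB"),    # differs in one progeny -> new bin
             c("AA", NA, "BB"))      # NA-compatible -> merges
  bs <- collapse_bins(g, mk_loci(4))
  expect_equal(nrow(bs$bins), 2L)
  expect_equal(bs$bins$n_loci, c(2L, 2L))
  expect_equal(unname(bs$geno[2L, ]), c("AA", "AA", "BB"))  # consensus fill
  expect_equal(sum(bs$bins$n_loci), 4L)                     # conservation
  # scaffold change always breaks a run
  loci2 <- rbind(mk_loci(2, "s1"), mk_loci(2, "s2"))
  loci2$locus_id <- sprintf("%s_%09d", loci2$scaffold, loci2$pos)
  g2 <- matrix("AA", 4, 3)
  expect_equal(nrow(collapse_bins(g2, loci2)$bins), 2L)
  expect_error(collapse_bins(g, mk_loci(4)[4:1]), "sorted")
})

test_that("1:2:1 chi-square and the segregation filter match direct formula", {
  expect_equal(chisq_121(30, 60, 30)$statistic, 0)
  expect_equal(chisq_121(60, 40, 20)$statistic, 40)  # sum (O-E)^2/E
  expect_equal(round(chisq_121(25, 70, 25)$statistic, 2), 3.33)
  expect_lt(chisq_121(25, 70, 25)$statistic, qchisq(0.95, 2))
  counts <- list(c(30, 60, 30), c(60, 40, 20), c(25, 70, 25))
  g <- do.call(rbind, lapply(counts, function(k)
    c(rep("AA", k[1]), rep("H", k[2]), rep("BB", k[3]))))
  loci <- mk_loci(3)
  # force distinct vectors so bins do not merge
  bs <- collapse_bins(g, loci)
  kept <- segregation_filter(bs, alpha = 0.05)
  expect_equal(nrow(kept$bins), 2L)
  expect_false("bin00002" %in% kept$bins$bin_id)
  rep <- attr(kept, "seg_report")
  expect_equal(rep[reason == "distorted", n], 1L)
})

test_that("two-point EM r estimate agrees with a grid-search ML oracle", {
  set.seed(21)
  states <- c("AA", "H", "BB")
  for (case in 1:15) {
    n <- sample(c(30, 60, 120), 1)
    r_true <- runif(1, 0, 0.5)
    # simulate a two-locus pair: gametes recombine with prob r_true
    g1a <- sample(0:1, n, replace = TRUE)
    g1b <- sample(0:1, n, replace = TRUE)
    g2a <- ifelse(runif(n) < r_true, 1L - g1a, g1a)
    g2b <- ifelse(runif(n) < r_true, 1L - g1b, g1b)
    v1 <- states[g1a + g1b + 1L]
    v2 <- states[g2a + g2b + 1L]
    est <- estimate_rf(v1, v2)
    oracle <- grid_rf(v1, v2)
    expect_lt(abs(est$r - oracle$r), 2e-4)
    expect_lt(abs(est$lod - oracle$lod), 1e-3)
  }
  # identical fully informative vectors: r = 0
  v <- rep(states, length.out = 50)
  expect_equal(estimate_rf(v, v)$r, 0)
  # degenerate: fewer than two co-observed progeny
  flagged <- estimate_rf(c("AA", NA, "H"), c(NA, "AA", "H"))
  expect_true(is.na(flagged$r))
  expect_equal(flagged$n, 1L)
})

test_that("independent bins estimate r near 0.5 with negligible LOD", {
  set.seed(31)
  states <- c("AA", "H", "BB")
  n <- 200
  v1 <- states[rbinom(n, 2, 0.5) + 1L]
  v2 <- states[rbinom(n, 2, 0.5) + 1L]
  est <- estimate_rf(v1, v2)
  expect_gt(est$r, 0.45)
  expect_lt(est$lod, 1)
  # pairwise matrix form agrees with the single-pair form
  pl <- pairwise_linkage(rbind(b1 = v1, b2 = v2))
  expect_equal(pl$r[1, 2], est$r, tolerance = 1e-8)
  expect_equal(pl$lod[1, 2], est$lod, tolerance = 1e-6)
  expect_equal(pl$r[1, 2], pl$r[2, 1])   # symmetry
})

test_that("grouping uses the AND of both thresholds", {
  ids <- paste0("b", 1:5)
  r <- matrix(0.5, 5, 5, dimnames = list(ids, ids))
  lod <- matrix(0, 5, 5, dimnames = list(ids, ids))
  link <- function(i, j, rv, lv) {
    r[i, j] <<- rv; r[j, i] <<- rv
    lod[i, j] <<- lv; lod[j, i] <<- lv
  }
  link(1, 2, 0.1, 20); link(2, 3, 0.1, 20)      # chain
  link(4, 5, 0.1, 20)
  link(3, 4, 0.1, 7.9)                           # below LOD threshold
  g <- group_bins(list(r = r, lod = lod), min_group_size = 1L)
  expect_equal(length(g), 2L)
  expect_setequal(g[[1]], c("b1", "b2", "b3"))
  # an edge with good LOD but r above 0.35 still fails
  link(3, 4, 0.40, 50)
  g2 <- group_bins(list(r = r, lod = lod), min_group_size = 1L)
  expect_equal(length(g2), 2L)
  # small groups are discarded and reported
  g3 <- group_bins(list(r = r, lod = lod), min_group_size = 2L)
  expect_equal(length(g3), 1L)
  expect_setequal(attr(g3, "discarded"), c("b4", "b5"))
})

test_that("bin ordering equals brute force on small known maps", {
  set.seed(55)
  states <- c("AA", "H", "BB")
  # six markers on a line, distances drawn from truth, n = 150
  n <- 150
  pos_cm <- c(0, 8, 15, 27, 36, 50)
  g1 <- matrix(sample(0:1, n, TRUE), 1)
  gam <- function() {
    al <- matrix(0L, 6, n)
    al[1, ] <- sample(0:1, n, TRUE)
    for (k in 2:6) {
      r <- kosambi_inv(pos_cm[k] - pos_cm[k - 1])
      flip <- runif(n) < r
      al[k, ] <- ifelse(flip, 1L - al[k - 1, ], al[k - 1, ])
    }
    al
  }
  geno <- matrix(states[gam() + gam() + 1L], 6, n)
  rownames(geno) <- paste0("m", 1:6)
  # scramble the rows so the input order is uninformative
  scr <- c(4, 1, 6, 3, 5, 2)
  geno_s <- geno[scr, ]
  pl <- pairwise_linkage(geno_s)
  res <- order_bins(rownames(geno_s), pl, order_lod = 3)
  # brute force over all 6! orders on the same criterion (oracle)
  ids <- sort(rownames(geno_s))
  bf <- brute_force_order(pl$r[ids, ids], pl$lod[ids, ids])
  s_pkg <- order_crit_oracle(match(res$bins, ids), pl$r[ids, ids],
                             pl$lod[ids, ids])
  expect_equal(s_pkg, bf$s, tolerance = 1e-9)
  # and the recovered order is the true line or its reverse
  true_order <- paste0("m", 1:6)
  expect_true(identical(res$bins, true_order) ||
              identical(res$bins, rev(true_order)))
  # two bins: single order, length = Kosambi(r)
  pl2 <- pairwise_linkage(geno_s[1:2, ])
  res2 <- order_bins(rownames(geno_s)[1:2], pl2)
  expect_equal(res2$pos[2], kosambi(min(pl2$r[1, 2], 0.49)))
})

test_that("map statistics reproduce the published interval arithmetic", {
  expect_equal(interval_means(152.35, 94, 1082),
               c(bin_interval = 1.62, marker_interval = 0.14))
  expect_equal(interval_means(245.85, 485, 4482)[["marker_interval"]], 0.05)
  map <- manual_map(paste0("b", 1:4), c(0, 2, 9, 12))
  map$bins <- data.table::data.table(bin_id = paste0("b", 1:4),
                                     n_loci = c(3L, 1L, 2L, 4L))
  map$lgs[[1]]$n_markers <- 10L
  st <- map_statistics(map, gap_cm = 5)
  expect_equal(st$n_gaps[1], 1L)                   # only the 7 cM gap
  expect_equal(st$length_cM[1], 12)
  expect_equal(st$bin_interval[1], 3)              # 12 / 4
  expect_equal(st[lg == "Total", n_markers], 10L)
  # reversing a linkage group changes neither length nor gap count
  map_rev <- map
  map_rev$lgs[[1]]$pos <- max(map$lgs[[1]]$pos) - rev(map$lgs[[1]]$pos)
  map_rev$lgs[[1]]$bins <- rev(map$lgs[[1]]$bins)
  st_rev <- map_statistics(map_rev, gap_cm = 5)
  expect_equal(st_rev$length_cM, st$length_cM)
  expect_equal(st_rev$n_gaps, st$n_gaps)
  # single-bin group has zero length and no gaps
  map1 <- manual_map("b1", 0)
  map1$bins <- data.table::data.table(bin_id = "b1", n_loci = 5L)
  st1 <- map_statistics(map1)
  expect_equal(st1$length_cM[1], 0)
  expect_equal(st1$n_gaps[1], 0L)
})
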