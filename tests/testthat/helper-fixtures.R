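# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: enumeration instead of forward-backward, grid
# search instead of EM, exhaustive permutations instead of local search.

small_cfg <- function(seed = 1, n = 40, len_bp = 2e6, len_cm = 50,
                      density = 1e-4, ...) {
  sim_config(n_progeny = n,
             scaffolds = data.frame(name = "s1", length_bp = len_bp,
                                    length_cM = len_cm),
             snp_density = density,
             trait_locus = list(scaffold = "s1", pos = round(len_bp / 2)),
             seed = seed, ...)
}

# read_obs -> locus_table without the VCF round trip (round trip has its
# own test); keeps simulation-heavy tests fast
obs_to_locus_table <- function(obs) {
  loci <- data.table::copy(obs$loci)
  loci[, is_indel := FALSE]
  structure(list(loci = loci, gt = obs$gt, dp = obs$dp,
                 samples = obs$samples, parents = c("P1", "P2")),
            class = "locus_table")
}

sim_to_corrected <- function(cfg, ...) {
  founders <- simulate_founders(cfg)
  truth <- simulate_f2(founders, cfg)
  obs <- observe(truth, cfg)
  tab <- obs_to_locus_table(obs)
  hq <- filter_high_quality(tab, min_calls = 20L)
  origins <- classify_parent_snps(hq)
  gm <- build_genotype_matrix(hq, origins)
  list(truth = truth, tab = tab, gm = gm,
       corrected = hmm_correct(gm, hmm_params(...)))
}

# exhaustive-path posterior: sum over all 3^L state paths
enum_posterior <- function(sym, depth, pos, params) {
  L <- length(sym)
  em <- f2binmap:::.emissions(sym, depth, params$epsilon)
  init <- c(0.25, 0.5, 0.25)
  rs <- pmin(kosambi_inv(params$cm_per_mb * diff(pos) / 1e6), 0.4999)
  tr <- lapply(rs, f2_transition)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  w <- apply(paths, 1L, function(s) {
    p <- init[s[1L]] * em[1L, s[1L]]
    if (L > 1L) for (i in 2:L) p <- p * tr[[i - 1L]][s[i - 1L], s[i]] * em[i, s[i]]
    p
  })
  po <- sapply(1:3, function(k)
    sapply(1:L, function(i) sum(w[paths[, i] == k])))
  po / rowSums(po)
}

# two-locus genotype-class log-likelihood and grid-search ML oracle
rf_loglik <- function(cnt, r) {
  p <- 1 - r
  pr <- matrix(c(p^2 / 4, p * r / 2, r^2 / 4,
                 p * r / 2, (p^2 + r^2) / 2, p * r / 2,
                 r^2 / 4, p * r / 2, p^2 / 4), 3L, 3L, byrow = TRUE)
  sum(ifelse(cnt > 0, cnt * log10(pmax(pr, 1e-300)), 0))
}

grid_rf <- function(g1, g2, grid = seq(0, 0.5, by = 1e-4)) {
  states <- c("AA", "H", "BB")
  co <- !is.na(match(g1, states)) & !is.na(match(g2, states))
  cnt <- table(factor(g1[co], states), factor(g2[co], states))
  ll <- vapply(grid, function(r) rf_loglik(cnt, r), 1)
  best <- which.max(ll)
  list(r = grid[best], lod = ll[best] - rf_loglik(cnt, 0.5))
}

# ordering criterion evaluated from scratch (independent of the package's
# incremental bookkeeping), and exhaustive minimisation over permutations
order_crit_oracle <- function(ord, r, lod, order_lod = 3) {
  m <- length(ord)
  d_adj <- kosambi(pmin(r[cbind(ord[-m], ord[-1L])], 0.49))
  posv <- numeric(m)
  posv[ord] <- c(0, cumsum(d_adj))
  s <- 0
  for (i in 1:(m - 1L)) for (j in (i + 1L):m)
    if (!is.na(lod[i, j]) && lod[i, j] >= order_lod)
      s <- s + lod[i, j] *
        (abs(posv[i] - posv[j]) - kosambi(min(r[i, j], 0.49)))^2
  s
}

brute_force_order <- function(r, lod, order_lod = 3) {
  m <- nrow(r)
  perms <- gtools_permutations(m)
  ss <- apply(perms, 1L, order_crit_oracle, r = r, lod = lod,
              order_lod = order_lod)
  list(order = perms[which.min(ss), ], s = min(ss))
}

# all permutations of 1..n without extra dependencies
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# truth-state genotype matrix for ad hoc trait-scan fixtures
manual_map <- function(bin_ids, pos) {
  structure(list(lgs = list(list(lg = 1L, bins = bin_ids, pos = pos,
                                 length = max(pos),
                                 n_markers = length(bin_ids))),
                 bins = data.table::data.table(bin_id = bin_ids)),
            class = "genetic_map")
}
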