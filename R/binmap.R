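#' Kosambi mapping function and its inverse
#'
#' `kosambi()` converts a recombination fraction to a map distance,
#' d = 25 ln((1+2r)/(1-2r)) cM; `kosambi_inv()` converts back,
#' r = tanh(d/50)/2. Each is the other's inverse to numerical precision.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @param d map distance(s) in cM, >= 0.
#' @return distance in cM / recombination fraction.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("d must be >= 0")
  0.5 * tanh(d / 50)
}

#' Collapse corrected genotypes into recombination bins
#'
#' Maximal runs of adjacent loci (within a scaffold) whose corrected
#' genotype vectors co-segregate become one bin; bins cover all loci
#' exactly once. Two adjacent loci co-segregate when their vectors agree in
#' every progeny where both are observed — a missing call carries no
#' information and never breaks a run; the bin's representative vector is
#' the run consensus (missing entries filled by the observed member value).
#' This keeps recombinant progeny with a no-call at a breakpoint-adjacent
#' locus countable in adjacent-bin linkage, which a literal
#' identical-vector rule would censor. Each bin gets its genotype counts
#' and a 1:2:1 segregation chi-square (df = 2, missing excluded).
#'
#' @param corrected loci x progeny matrix over AA/H/BB/NA.
#' @param loci data.table aligned with the rows (`locus_id`, `scaffold`,
#'   `pos`).
#' @return object of class `bin_set`: list with `bins` (data.table: bin_id,
#'   scaffold, start, end, n_loci, n_AA, n_H, n_BB, n_missing, chisq,
#'   p_value), `geno` (bins x progeny consensus matrix), `loci_map`
#'   (locus_id -> bin_id).
#' @export
collapse_bins <- function(corrected, loci) {
  stopifnot(nrow(corrected) == nrow(loci))
  o <- order(loci$scaffold, loci$pos)
  if (!identical(o, seq_len(nrow(loci))))
    stop("loci must be sorted by scaffold, position")
  L <- nrow(corrected)
  bid <- integer(L)
  cons <- list()
  cur <- corrected[1L, ]
  b <- 1L
  bid[1L] <- 1L
  if (L > 1L) for (i in 2:L) {
    v <- corrected[i, ]
    both <- !is.na(v) & !is.na(cur)
    if (loci$scaffold[i] == loci$scaffold[i - 1L] &&
        all(v[both] == cur[both])) {
      fill <- is.na(cur) & !is.na(v)
      cur[fill] <- v[fill]
    } else {
      cons[[b]] <- cur
      b <- b + 1L
      cur <- v
    }
    bid[i] <- b
  }
  cons[[b]] <- cur
  reps <- match(seq_len(b), bid)
  bins <- data.table(
    bin_id = sprintf("bin%05d", seq_len(b)),
    scaffold = loci$scaffold[reps],
    start = loci$pos[reps],
    end = loci$pos[c(reps[-1L] - 1L, L)],
    n_loci = as.integer(tabulate(bid)))
  geno <- do.call(rbind, cons)
  rownames(geno) <- bins$bin_id
  bins[, n_AA := rowSums(geno == "AA", na.rm = TRUE)]
  bins[, n_H := rowSums(geno == "H", na.rm = TRUE)]
  bins[, n_BB := rowSums(geno == "BB", na.rm = TRUE)]
  bins[, n_missing := rowSums(is.na(geno))]
  st <- chisq_121(bins$n_AA, bins$n_H, bins$n_BB)
  bins[, chisq := st$statistic]
  bins[, p_value := st$p_value]
  structure(list(bins = bins, geno = geno,
                 loci_map = data.table(locus_id = loci$locus_id,
                                       bin_id = bins$bin_id[bid])),
            class = "bin_set")
}

#' Chi-square test against a 1:2:1 ratio
#'
#' Plain (uncorrected) goodness-of-fit on the three genotype classes,
#' df = 2, missing calls excluded.
#'
#' @param n_aa,n_h,n_bb class counts (vectorized).
#' @return list of vectors `statistic`, `p_value` (`NA` for empty bins).
#' @export
chisq_121 <- function(n_aa, n_h, n_bb) {
  n <- n_aa + n_h + n_bb
  e_aa <- n / 4
  e_h <- n / 2
  stat <- ifelse(n > 0,
                 (n_aa - e_aa)^2 / e_aa + (n_h - e_h)^2 / e_h +
                 (n_bb - e_aa)^2 / e_aa,
                 NA_real_)
  list(statistic = stat, p_value = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Filter bins by Mendelian segregation
#'
#' Retains bins whose 1:2:1 chi-square p-value exceeds `alpha`
#' (i.e. no significant segregation distortion); all-missing bins are
#' discarded with their own reason.
#'
#' @param bs a [collapse_bins()] bin set.
#' @param alpha significance level (default 0.05).
#' @return filtered `bin_set` with a `seg_report` attribute.
#' @export
segregation_filter <- function(bs, alpha = 0.05) {
  stopifnot(inherits(bs, "bin_set"))
  empty <- is.na(bs$bins$p_value)
  keep <- !empty & bs$bins$p_value > alpha
  report <- data.table(
    reason = c("retained", "distorted", "all_missing"),
    n = c(sum(keep), sum(!keep & !empty), sum(empty)))
  out <- structure(list(bins = bs$bins[keep],
                        geno = bs$geno[keep, , drop = FALSE],
                        loci_map = bs$loci_map[bid_keep(bs, keep)]),
                   class = "bin_set")
  attr(out, "seg_report") <- report
  out
}

bid_keep <- function(bs, keep) bs$loci_map$bin_id %in% bs$bins$bin_id[keep]

# shared EM core: all arguments are same-shaped arrays of two-locus class
# counts N[dose1, dose2]; returns r and LOD arrays. The double-heterozygote
# class mixes phase; its expected recombinant-gamete count is 2r^2/(p^2+r^2).
.rf_em_core <- function(N00, N01, N02, N10, N11, N12, N20, N21, N22,
                        max_iter = 100L, tol = 1e-10) {
  n <- N00 + N01 + N02 + N10 + N11 + N12 + N20 + N21 + N22
  rec1 <- N01 + N10 + N12 + N21
  rec2 <- N02 + N20
  r <- array(0.25, dim = dim(as.array(n)))
  for (i in seq_len(max_iter)) {
    p <- 1 - r
    w11 <- 2 * r^2 / (p^2 + r^2)
    r_new <- (rec1 + 2 * rec2 + w11 * N11) / (2 * n)
    r_new[n == 0] <- NA_real_
    if (max(abs(r_new - r), na.rm = TRUE) < tol) { r <- r_new; break }
    r <- r_new
  }
  r <- pmin(pmax(r, 0), 0.5)
  xl <- function(cnt, pr) ifelse(cnt > 0, cnt * log10(pmax(pr, 1e-300)), 0)
  ll <- function(rr) {
    p <- 1 - rr
    xl(N00, p^2 / 4) + xl(N22, p^2 / 4) + xl(N02, rr^2 / 4) +
      xl(N20, rr^2 / 4) + xl(N01 + N10 + N12 + N21, rr * p / 2) +
      xl(N11, (p^2 + rr^2) / 2)
  }
  lod <- ll(r) - ll(array(0.5, dim = dim(as.array(r))))
  lod <- pmax(lod, 0)
  list(r = r, lod = lod, n = n)
}

#' Two-point recombination fraction between two bins
#'
#' Maximum-likelihood estimate for an F2 codominant pair via EM over the
#' nine two-locus genotype classes (the double-heterozygote phase ambiguity
#' is handled in expectation); LOD = log10 L(r) - log10 L(0.5).
#'
#' @param g1,g2 genotype vectors over AA/H/BB/NA for the two bins.
#' @return list with `r`, `lod`, `n` (co-observed progeny). With fewer than
#'   2 co-observed progeny the linkage is undefined: `r` and `lod` are `NA`.
#' @export
estimate_rf <- function(g1, g2) {
  states <- c("AA", "H", "BB")
  d1 <- match(g1, states) - 1L
  d2 <- match(g2, states) - 1L
  co <- !is.na(d1) & !is.na(d2)
  if (sum(co) < 2L)
    return(list(r = NA_real_, lod = NA_real_, n = sum(co)))
  cnt <- table(factor(d1[co], 0:2), factor(d2[co], 0:2))
  res <- .rf_em_core(cnt[1, 1], cnt[1, 2], cnt[1, 3],
                     cnt[2, 1], cnt[2, 2], cnt[2, 3],
                     cnt[3, 1], cnt[3, 2], cnt[3, 3])
  list(r = as.numeric(res$r), lod = as.numeric(res$lod), n = sum(co))
}

#' All pairwise two-point linkages
#'
#' Vectorized EM across every bin pair at once via indicator cross-products.
#'
#' @param geno bins x progeny matrix over AA/H/BB/NA.
#' @return list of bins x bins matrices `r`, `lod`, `n`.
#' @export
pairwise_linkage <- function(geno) {
  A <- (geno == "AA") * 1
  H <- (geno == "H") * 1
  B <- (geno == "BB") * 1
  A[is.na(A)] <- 0; H[is.na(H)] <- 0; B[is.na(B)] <- 0
  cp <- function(x, y) tcrossprod(x, y)
  res <- .rf_em_core(cp(A, A), cp(A, H), cp(A, B),
                     cp(H, A), cp(H, H), cp(H, B),
                     cp(B, A), cp(B, H), cp(B, B))
  dimnames(res$r) <- dimnames(res$lod) <- dimnames(res$n) <-
    list(rownames(geno), rownames(geno))
  res
}

#' Group bins into linkage groups
#'
#' Connected components of the graph whose edges join bin pairs with
#' LOD >= `min_lod` AND r <= `max_rf`; groups with at most `min_group_size`
#' bins are discarded and reported.
#'
#' @param linkage a [pairwise_linkage()] result.
#' @param min_lod minimum two-point LOD for an edge (default 8.0).
#' @param max_rf maximum recombination fraction for an edge (default 0.35,
#'   inclusive).
#' @param min_group_size groups of this many bins or fewer are dropped
#'   (default 10).
#' @return list of character vectors of bin ids, largest first, with a
#'   `discarded` attribute listing dropped bins.
#' @export
group_bins <- function(linkage, min_lod = 8, max_rf = 0.35,
                       min_group_size = 10L) {
  adj <- (linkage$lod >= min_lod & linkage$r <= max_rf)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(linkage$r)
  groups <- split(ids, comp$membership)
  keep <- vapply(groups, length, 1L) > min_group_size
  dropped <- unlist(groups[!keep], use.names = FALSE)
  groups <- groups[keep]
  groups <- groups[order(-vapply(groups, length, 1L))]
  names(groups) <- NULL
  attr(groups, "discarded") <- dropped
  groups
}

# weighted least-squares criterion of an order: sum over informative pairs
# of lod * (implied map distance - two-point Kosambi distance)^2
.order_criterion <- function(ord, pairs, adj_d_fun) {
  posv <- numeric(length(ord))
  posv[ord] <- c(0, cumsum(adj_d_fun(ord)))
  sum(pairs$w * (abs(posv[pairs$i] - posv[pairs$j]) - pairs$d)^2)
}

#' Order the bins of one linkage group
#'
#' Minimizes the weighted least-squares criterion
#' S = sum over pairs with LOD >= `order_lod` of LOD x (D_ij - d_ij)^2,
#' where D_ij is the map distance implied by the order (summed adjacent
#' Kosambi distances) and d_ij the two-point Kosambi distance. Built by
#' greedy best-position insertion, then window-3 ripple and 2-opt
#' improvement; ties break on bin id, and the returned orientation puts the
#' lexicographically smaller terminal bin first. Cumulative cM positions
#' come from adjacent two-point estimates.
#'
#' If the informative subgraph is disconnected the components are ordered
#' separately and concatenated with a warning.
#'
#' @param group character vector of bin ids (>= 2).
#' @param linkage a [pairwise_linkage()] result covering the group.
#' @param order_lod LOD floor for pairs entering the criterion (default 3).
#' @return list with `bins` (ordered ids) and `pos` (cumulative cM).
#' @export
order_bins <- function(group, linkage, order_lod = 3) {
  stopifnot(length(group) >= 2L)
  group <- sort(group)
  r <- linkage$r[group, group, drop = FALSE]
  lod <- linkage$lod[group, group, drop = FALSE]
  m <- length(group)
  inf <- which(upper.tri(lod) & !is.na(lod) & lod >= order_lod, arr.ind = TRUE)
  # connected components of the informative subgraph
  amat <- matrix(FALSE, m, m)
  amat[inf] <- TRUE
  gi <- igraph::graph_from_adjacency_matrix(amat | t(amat),
                                            mode = "undirected")
  comp <- igraph::components(gi)$membership
  if (max(comp) > 1L) {
    warning("informative subgraph disconnected; ordering per component")
    parts <- lapply(split(seq_len(m), comp), function(ix) {
      if (length(ix) == 1L) list(bins = group[ix], pos = 0)
      else order_bins(group[ix], linkage, order_lod)
    })
    bins <- unlist(lapply(parts, `[[`, "bins"), use.names = FALSE)
    gaps <- unlist(lapply(seq_along(parts), function(i) {
      g <- diff(parts[[i]]$pos)
      if (i == 1L) g else c(25, g)  # arbitrary 25 cM junction between parts
    }), use.names = FALSE)
    return(list(bins = bins, pos = c(0, cumsum(gaps))))
  }
  rc <- pmin(r, 0.49)
  dmat <- matrix(0, m, m)
  dmat[!is.na(rc)] <- kosambi(rc[!is.na(rc)])
  pairs <- list(i = inf[, 1L], j = inf[, 2L],
                w = lod[inf], d = dmat[inf])
  adj_d <- function(ord) {
    a <- ord[-length(ord)]
    b <- ord[-1L]
    dmat[cbind(a, b)]
  }
  crit <- function(ord) .order_criterion(ord, pairs, adj_d)
  # greedy best-position insertion over bins in id order
  ord <- c(1L, 2L)
  sub_crit <- function(ord) {
    if (length(ord) < 2L) return(0)
    sel <- pairs$i %in% ord & pairs$j %in% ord
    sp <- list(i = pairs$i[sel], j = pairs$j[sel],
               w = pairs$w[sel], d = pairs$d[sel])
    posv <- numeric(m)
    posv[ord] <- c(0, cumsum(adj_d(ord)))
    sum(sp$w * (abs(posv[sp$i] - posv[sp$j]) - sp$d)^2)
  }
  for (k in seq_len(m)[-(1:2)]) {
    best <- Inf; best_ord <- NULL
    for (at in 0:length(ord)) {
      cand <- append(ord, k, after = at)
      s <- sub_crit(cand)
      if (s < best - 1e-12) { best <- s; best_ord <- cand }
    }
    ord <- best_ord
  }
  # alternative start: LOD-weighted 1-D scaling of the two-point distances
  # (PCoA initialisation, Guttman-transform iterations) — robust to the
  # block-level misplacements a greedy start can make on dense groups; the
  # better-scoring start is the one refined
  if (m >= 4L) {
    wmat <- matrix(0, m, m)
    wmat[cbind(pairs$i, pairs$j)] <- pairs$w
    wmat <- wmat + t(wmat)
    dfull <- dmat
    unknown <- is.na(rc)
    diag(unknown) <- FALSE
    if (any(unknown)) dfull[unknown] <- 1.1 * max(dmat)
    x <- tryCatch(stats::cmdscale(stats::as.dist(dfull), k = 1L)[, 1L],
                  error = function(e) NULL)
    if (!is.null(x) && sum(wmat) > 0) {
      rs <- rowSums(wmat)
      rs[rs == 0] <- 1
      for (it in 1:100) {
        dx <- outer(x, x, "-")
        x_new <- (wmat %*% x + rowSums(wmat * dmat * sign(dx))) / rs
        if (max(abs(x_new - x)) < 1e-8) { x <- as.numeric(x_new); break }
        x <- as.numeric(x_new)
      }
      ord_sc <- order(x, seq_len(m))
      if (crit(ord_sc) < crit(ord)) ord <- ord_sc
    }
  }
  s_cur <- crit(ord)
  # local refinement: window-3 ripple, single-bin relocation (window 8),
  # and 2-opt segment reversal, cycled to convergence
  perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (round in 1:6) {
    improved_round <- FALSE
    if (m >= 3L) repeat {
      improved <- FALSE
      for (st in 1:(m - 2L)) {
        win <- ord[st:(st + 2L)]
        for (p in perms3[-1L]) {
          cand <- ord
          cand[st:(st + 2L)] <- win[p]
          s <- crit(cand)
          if (s < s_cur - 1e-12) {
            ord <- cand; s_cur <- s; improved <- TRUE
            improved_round <- TRUE
          }
        }
      }
      if (!improved) break
    }
    for (i in seq_len(m)) {                     # or-opt: relocate one bin
      base <- ord[-i]
      lo <- max(0L, i - 9L); hi <- min(m - 1L, i + 8L)
      for (at in lo:hi) {
        cand <- append(base, ord[i], after = at)
        s <- crit(cand)
        if (s < s_cur - 1e-12) {
          ord <- cand; s_cur <- s; improved_round <- TRUE
          break
        }
      }
    }
    improved <- TRUE
    while (improved) {                          # 2-opt
      improved <- FALSE
      for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        s <- crit(cand)
        if (s < s_cur - 1e-12) {
          ord <- cand; s_cur <- s; improved <- TRUE
          improved_round <- TRUE
        }
      }
    }
    if (!improved_round) break
  }
  if (group[ord[1L]] > group[ord[m]]) ord <- rev(ord)
  list(bins = group[ord], pos = c(0, cumsum(adj_d(ord))))
}

#' Assemble a genetic map from a bin set
#'
#' Runs pairwise linkage, grouping, and per-group ordering, then numbers the
#' linkage groups by descending marker count (the published numbering being
#' arbitrary). `ordering = "physical"` bypasses the ordering search and uses
#' the known scaffold order of the bins (valid for simulated or assembled
#' data); cM positions always come from adjacent two-point estimates.
#'
#' @param bs a [segregation_filter()]ed bin set.
#' @param min_lod,max_rf,min_group_size see [group_bins()].
#' @param order_lod see [order_bins()].
#' @param ordering `"search"` or `"physical"`.
#' @return object of class `genetic_map`: list with `lgs` (each: `lg`,
#'   `bins`, `pos`, `length`, `n_markers`) and `bins` (the bin table).
#' @export
build_map <- function(bs, min_lod = 8, max_rf = 0.35, min_group_size = 10L,
                      order_lod = 3, ordering = c("search", "physical")) {
  stopifnot(inherits(bs, "bin_set"))
  ordering <- match.arg(ordering)
  linkage <- pairwise_linkage(bs$geno)
  groups <- group_bins(linkage, min_lod, max_rf, min_group_size)
  lgs <- lapply(groups, function(g) {
    if (length(g) == 1L) return(list(bins = g, pos = 0))
    if (ordering == "physical") {
      bt <- bs$bins[match(g, bin_id)]
      g <- g[order(bt$scaffold, bt$start)]
      rr <- pmin(linkage$r[cbind(g[-length(g)], g[-1L])], 0.49)
      list(bins = g, pos = c(0, cumsum(kosambi(rr))))
    } else order_bins(g, linkage, order_lod)
  })
  nm <- vapply(lgs, function(x)
    sum(bs$bins$n_loci[match(x$bins, bs$bins$bin_id)]), 1)
  lgs <- lgs[order(-nm)]
  nm <- nm[order(-nm)]
  lgs <- lapply(seq_along(lgs), function(i)
    c(lgs[[i]], list(lg = i, length = max(lgs[[i]]$pos),
                     n_markers = as.integer(nm[i]))))
  structure(list(lgs = lgs, bins = bs$bins,
                 discarded = attr(groups, "discarded")),
            class = "genetic_map")
}

#' Table 2-style interval means
#'
#' Average bin and marker intervals divide total length by the count (not
#' count - 1), matching the published arithmetic; both to 2 decimals.
#'
#' @param length_cM linkage-group length.
#' @param n_bins,n_markers bin and marker counts.
#' @return named numeric: `bin_interval`, `marker_interval`.
#' @export
interval_means <- function(length_cM, n_bins, n_markers) {
  c(bin_interval = round(length_cM / n_bins, 2),
    marker_interval = round(length_cM / n_markers, 2))
}

#' Per-linkage-group map statistics
#'
#' Bin count, marker count, total length, average bin/marker interval
#' (length over count, 2 decimals) and the number of adjacent-bin gaps
#' strictly larger than `gap_cm`, plus a totals row.
#'
#' @param map a [build_map()] genetic map.
#' @param gap_cm gap threshold in cM (default 5).
#' @return data.table mirroring the published per-LG summary.
#' @export
map_statistics <- function(map, gap_cm = 5) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- rbindlist(lapply(map$lgs, function(x) {
    iv <- interval_means(x$length, length(x$bins), x$n_markers)
    data.table(lg = paste0("LG", x$lg), n_bins = length(x$bins),
               n_markers = x$n_markers, length_cM = round(x$length, 2),
               bin_interval = iv[["bin_interval"]],
               marker_interval = iv[["marker_interval"]],
               n_gaps = sum(diff(x$pos) > gap_cm))
  }))
  tot_len <- sum(vapply(map$lgs, `[[`, 1, "length"))
  iv <- interval_means(tot_len, sum(rows$n_bins), sum(rows$n_markers))
  rbind(rows, data.table(lg = "Total", n_bins = sum(rows$n_bins),
                         n_markers = sum(rows$n_markers),
                         length_cM = round(tot_len, 2),
                         bin_interval = iv[["bin_interval"]],
                         marker_interval = iv[["marker_interval"]],
                         n_gaps = sum(rows$n_gaps)))
}
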