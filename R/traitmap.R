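#' Yates-corrected chi-square test of a segregation ratio
#'
#' Goodness-of-fit with continuity correction for two phenotype classes
#' against an expected p:q ratio (df = 1):
#' chi2 = sum over classes of (max(|O - E| - 0.5, 0))^2 / E, reported to 2
#' decimals; the correction is clamped at zero deviation.
#'
#' @param observed counts of the two classes, e.g. c(indeterminate,
#'   determinate).
#' @param ratio expected ratio, e.g. c(3, 1) or c(1, 1).
#' @param alpha significance level for the verdict.
#' @return list: `statistic` (2 decimals), `p_value`, `df`, `expected`,
#'   `verdict` (`"fits"`/`"distorted"`).
#' @export
yates_chisq <- function(observed, ratio = c(3, 1), alpha = 0.05) {
  stopifnot(length(observed) == 2L, length(ratio) == 2L)
  if (sum(observed) <= 0) stop("zero total count")
  if (any(ratio <= 0)) stop("ratio terms must be > 0")
  e <- sum(observed) * ratio / sum(ratio)
  stat <- sum(pmax(abs(observed - e) - 0.5, 0)^2 / e)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = round(stat, 2), p_value = p, df = 1L, expected = e,
       verdict = if (p > alpha) "fits" else "distorted")
}

# phenotype vector -> 0/1 (1 = determinate); NA preserved
.as_y <- function(phenotype) {
  if (is.numeric(phenotype)) {
    stopifnot(all(phenotype %in% c(0, 1, NA)))
    return(as.integer(phenotype))
  }
  y <- rep(NA_integer_, length(phenotype))
  y[phenotype == "determinate"] <- 1L
  y[phenotype == "indeterminate"] <- 0L
  y
}

.class1_states <- function(model, recessive_geno) {
  switch(model,
         recessive = recessive_geno,
         dominant = c(recessive_geno, "H"),
         stop("unknown model"))
}

# per-individual membership weights of the affected genotype class at every
# scan position: observed genotypes give 0/1, missing/virtual positions give
# flanking-marker probabilities through the F2 transition kernel.
.scan_weights <- function(map, geno, model = "recessive",
                          recessive_geno = "AA", step = 2,
                          positions = c("all", "bins")) {
  positions <- match.arg(positions)
  cls <- .class1_states(model, recessive_geno)
  states <- c("AA", "H", "BB")
  prior <- c(0.25, 0.5, 0.25)
  n <- ncol(geno)
  meta <- list()
  W <- list()
  for (lgx in map$lgs) {
    bp <- lgx$pos
    grid <- if (positions == "all" && !is.null(step) && lgx$length > 0)
      seq(0, lgx$length, by = step) else numeric(0)
    grid <- grid[vapply(grid, function(p) min(abs(p - bp)) > 1e-9, TRUE)]
    allp <- sort(c(bp, grid))
    g <- geno[lgx$bins, , drop = FALSE]
    gidx <- matrix(match(g, states), nrow(g), n)
    for (p in allp) {
      bi <- which(abs(bp - p) <= 1e-9)
      w <- numeric(n)
      if (length(bi)) {              # at a bin: degenerate where observed
        s <- gidx[bi[1L], ]
        w <- ifelse(is.na(s), sum(prior[match(cls, states)]),
                    as.numeric(states[s] %in% cls))
        meta[[length(meta) + 1L]] <-
          data.table(lg = lgx$lg, pos_cM = p, type = "bin",
                     bin_id = lgx$bins[bi[1L]])
      } else {                       # virtual: flanking-marker probabilities
        kl <- if (any(bp < p)) max(which(bp < p)) else NA_integer_
        kr <- if (any(bp > p)) min(which(bp > p)) else NA_integer_
        Tl <- if (!is.na(kl))
          f2_transition(min(kosambi_inv(p - bp[kl]), 0.4999)) else NULL
        Tr <- if (!is.na(kr))
          f2_transition(min(kosambi_inv(bp[kr] - p), 0.4999)) else NULL
        sl <- if (!is.na(kl)) gidx[kl, ] else rep(NA_integer_, n)
        sr <- if (!is.na(kr)) gidx[kr, ] else rep(NA_integer_, n)
        for (i in seq_len(n)) {
          pr <- prior
          if (!is.na(sl[i])) pr <- Tl[sl[i], ]
          else pr <- prior
          if (!is.na(sr[i])) pr <- pr * Tr[, sr[i]]
          pr <- pr / sum(pr)
          w[i] <- sum(pr[match(cls, states)])
        }
        meta[[length(meta) + 1L]] <-
          data.table(lg = lgx$lg, pos_cM = p, type = "virtual",
                     bin_id = NA_character_)
      }
      W[[length(W) + 1L]] <- w
    }
  }
  list(W = do.call(cbind, W), meta = rbindlist(meta))
}

.xlx <- function(x) ifelse(x > 0, x * log(x), 0)

# closed-form binomial penetrance log-likelihoods for degenerate weights:
# a = affected-class cases, n1 = affected-class size, k = total cases, N = n
.ll_counts <- function(a, n1, k, N) {
  b <- k - a
  n0 <- N - n1
  ll1 <- .xlx(a) + .xlx(n1 - a) - .xlx(n1) +
         .xlx(b) + .xlx(n0 - b) - .xlx(n0)
  ll0 <- .xlx(k) + .xlx(N - k) - .xlx(N)
  pmax(ll1 - ll0, 0) / log(10)
}

# EM fit of the two-class mixture penetrance model for fractional weights
.fit_mixture <- function(w, y, max_iter = 200L, tol = 1e-9) {
  p1 <- sum(w * y) / max(sum(w), 1e-12)
  p0 <- sum((1 - w) * y) / max(sum(1 - w), 1e-12)
  bern <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    f1 <- w * ifelse(y == 1, bern(p1), 1 - bern(p1))
    f0 <- (1 - w) * ifelse(y == 1, bern(p0), 1 - bern(p0))
    li <- f1 + f0
    ll_new <- sum(log(pmax(li, 1e-300)))
    z <- f1 / pmax(li, 1e-300)
    p1 <- sum(z * y) / max(sum(z), 1e-12)
    p0 <- sum((1 - z) * y) / max(sum(1 - z), 1e-12)
    if (ll_new - ll < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(ll = ll, p1 = p1, p0 = p0, fitted = w * p1 + (1 - w) * p0)
}

.ll_null <- function(y) {
  k <- sum(y)
  N <- length(y)
  .xlx(k) + .xlx(N - k) - .xlx(N)
}

#' Single-locus penetrance-likelihood genome scan
#'
#' At every bin and (optionally) every `step`-cM virtual position, LOD is
#' the log10 ratio of the two-class penetrance model (phenotype probability
#' depends on the affected genotype class) to the single-frequency null.
#' Virtual positions and missing genotypes use flanking-marker class
#' probabilities through the F2 transition kernel, fitted by EM. R-squared
#' at the peak is 1 - RSS_model/RSS_null on the 0/1 phenotype; the support
#' interval collects positions within `drop` LOD of the peak on the peak's
#' linkage group.
#'
#' @param map a [build_map()] genetic map.
#' @param geno bin genotype matrix (bins x progeny, AA/H/BB/NA).
#' @param phenotype per-progeny phenotype: 0/1 or
#'   `"determinate"`/`"indeterminate"` (NA allowed).
#' @param model `"recessive"` (default) or `"dominant"`.
#' @param recessive_geno homozygous class carrying the recessive allele.
#' @param step virtual-position walk in cM (default 2).
#' @param positions `"all"` or `"bins"` (no virtual positions).
#' @param drop LOD drop defining the support interval (default 1).
#' @return data.table (`lg`, `pos_cM`, `type`, `bin_id`, `lod`) with
#'   attributes `peak` (one-row data.table), `r2`, `support_interval`
#'   (list: lg, lo, hi).
#' @export
locus_scan <- function(map, geno, phenotype, model = "recessive",
                       recessive_geno = "AA", step = 2,
                       positions = "all", drop = 1) {
  y <- .as_y(phenotype)
  stopifnot(length(y) == ncol(geno))
  keep <- !is.na(y)
  sw <- .scan_weights(map, geno, model, recessive_geno, step, positions)
  W <- sw$W[keep, , drop = FALSE]
  yk <- y[keep]
  res <- sw$meta
  lods <- numeric(ncol(W))
  degen <- apply(W, 2L, function(w) all(w %in% c(0, 1)))
  if (any(degen)) {
    a <- as.numeric(yk %*% W[, degen, drop = FALSE])
    lods[degen] <- .ll_counts(a, colSums(W[, degen, drop = FALSE]),
                              sum(yk), length(yk))
  }
  for (j in which(!degen))
    lods[j] <- max(0, (.fit_mixture(W[, j], yk)$ll - .ll_null(yk)) / log(10))
  res[, lod := lods]
  pk <- which.max(lods)
  fit <- .fit_mixture(W[, pk], yk)
  rss_null <- sum((yk - mean(yk))^2)
  r2 <- if (rss_null > 0) 1 - sum((yk - fit$fitted)^2) / rss_null else 0
  on_lg <- res$lg == res$lg[pk] & res$lod >= lods[pk] - drop
  attr(res, "peak") <- res[pk]
  attr(res, "r2") <- r2
  attr(res, "support_interval") <- list(lg = res$lg[pk],
                                        lo = min(res$pos_cM[on_lg]),
                                        hi = max(res$pos_cM[on_lg]))
  res
}

#' Permutation LOD threshold for the genome scan
#'
#' Permutes the phenotype among scored progeny and records the genome-wide
#' maximum LOD per permutation; the threshold is the (1 - alpha) quantile.
#' Deterministic given `seed`. When every scan position has degenerate
#' class weights (no missing genotypes, bins-only scan) the permutations are
#' evaluated in closed form via one matrix product; otherwise each
#' permutation refits the mixture by EM.
#'
#' @inheritParams locus_scan
#' @param n_perm number of permutations (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed RNG seed.
#' @return numeric threshold, with attribute `max_lods`.
#' @export
permutation_threshold <- function(map, geno, phenotype, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L,
                                  model = "recessive", recessive_geno = "AA",
                                  step = 2, positions = "all") {
  stopifnot(n_perm >= 1L)
  y <- .as_y(phenotype)
  keep <- !is.na(y)
  sw <- .scan_weights(map, geno, model, recessive_geno, step, positions)
  W <- sw$W[keep, , drop = FALSE]
  yk <- y[keep]
  N <- length(yk)
  set.seed(seed)
  if (all(W %in% c(0, 1))) {
    Yp <- t(vapply(seq_len(n_perm), function(i) sample(yk), yk))
    A <- Yp %*% W
    n1 <- matrix(colSums(W), n_perm, ncol(W), byrow = TRUE)
    lods <- .ll_counts(A, n1, sum(yk), N)
    mx <- apply(lods, 1L, max)
  } else {
    ll0 <- .ll_null(yk)
    mx <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(yk)
      max(vapply(seq_len(ncol(W)), function(j)
        max(0, (.fit_mixture(W[, j], yp)$ll - ll0) / log(10)), 1))
    }, 1)
  }
  structure(as.numeric(quantile(mx, 1 - alpha)), max_lods = mx)
}

#' Marker-phenotype co-segregation coefficient
#'
#' Percentage of scored progeny whose marker genotype predicts the phenotype
#' under the given inheritance model, pooled over one or more populations.
#'
#' @param genotypes genotype vector (AA/H/BB/NA) or list of vectors, one per
#'   population.
#' @param phenotype matching phenotype vector(s).
#' @param model,recessive_geno see [locus_scan()].
#' @return list: `coefficient` (percent), `fully_cosegregating`,
#'   `n_scored`, `n_match`.
#' @export
cosegregation <- function(genotypes, phenotype, model = "recessive",
                          recessive_geno = "AA") {
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  if (!is.list(phenotype)) phenotype <- list(phenotype)
  stopifnot(length(genotypes) == length(phenotype))
  cls <- .class1_states(model, recessive_geno)
  n_match <- 0L
  n_scored <- 0L
  for (i in seq_along(genotypes)) {
    g <- genotypes[[i]]
    y <- .as_y(phenotype[[i]])
    stopifnot(length(g) == length(y))
    ok <- !is.na(g) & !is.na(y)
    pred <- as.integer(g[ok] %in% cls)
    n_scored <- n_scored + sum(ok)
    n_match <- n_match + sum(pred == y[ok])
  }
  if (n_scored == 0L) stop("zero scored progeny")
  coef <- 100 * n_match / n_scored
  list(coefficient = coef, fully_cosegregating = coef == 100,
       n_scored = n_scored, n_match = n_match)
}

#' Physical span of a marker window
#'
#' Span = end - start in bp (the published convention for interval width),
#' reported in kb to 2 decimals; optionally lists annotated genes
#' overlapping the span.
#'
#' @param markers data.frame with `scaffold` and `pos` of the window
#'   markers (all on one scaffold).
#' @param annotation optional gene table (`gene_id`, `scaffold`, `start`,
#'   `end`).
#' @return list: `scaffold`, `start`, `end`, `span_bp`, `span_kb`, `genes`.
#' @export
physical_interval <- function(markers, annotation = NULL) {
  markers <- as.data.table(markers)
  if (length(unique(markers$scaffold)) != 1L)
    stop("markers lie on different scaffolds; interval undefined")
  lo <- min(markers$pos)
  hi <- max(markers$pos)
  genes <- NULL
  if (!is.null(annotation)) {
    ann <- as.data.table(annotation)
    genes <- ann[scaffold == markers$scaffold[1L] & end >= lo & start <= hi]
  }
  list(scaffold = markers$scaffold[1L], start = lo, end = hi,
       span_bp = hi - lo, span_kb = round((hi - lo) / 1000, 2),
       genes = genes)
}
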