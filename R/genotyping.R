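#' Depth-aware six-symbol genotype coding
#'
#' Codes a progeny call at a parent-unique locus: a homozygous call for the
#' P1 allele becomes `AA` at depth >= `threshold`, else `D`; a homozygous
#' call for the P2 allele becomes `BB` at depth >= `threshold`, else `C`;
#' a heterozygous call is `H` at any depth; no call is `-`.
#'
#' @param origin per-locus origin vector (`"P1"`/`"P2"`): which parent
#'   carries the ALT allele.
#' @param call VCF-style genotype strings (`0/0`, `0/1`, `1/1`, `./.`).
#' @param depth read depth per call.
#' @param threshold depth needed for a confident homozygous code.
#' @return character vector over `AA`, `BB`, `H`, `C`, `D`, `-`.
#' @export
code_genotype <- function(origin, call, depth, threshold = 5L) {
  stopifnot(all(origin %in% c("P1", "P2")))
  ok <- call %in% c("0/0", "0/1", "1/1", "./.")
  if (!all(ok))
    stop("call allele not among the locus alleles: ", call[!ok][1L])
  p1_hom <- ifelse(origin == "P1", "1/1", "0/0")
  out <- character(length(call))
  sel <- call == p1_hom
  out[sel] <- ifelse(depth[sel] >= threshold, "AA", "D")
  sel <- call == ifelse(origin == "P1", "0/0", "1/1")
  out[sel] <- ifelse(depth[sel] >= threshold, "BB", "C")
  out[call == "0/1"] <- "H"
  out[call == "./."] <- "-"
  out
}

#' Build the coded genotype matrix
#'
#' Applies [code_genotype()] to every progeny at every parent-unique locus.
#' InDels are excluded by default (the map is an SNP map; InDel loci feed
#' the PCR-marker association stage).
#'
#' @param tab a [merge_calls()] locus table (after filtering).
#' @param origins a [classify_parent_snps()] table.
#' @param depth_threshold confident-homozygote depth (default 5).
#' @param include_indels keep InDel loci in the matrix.
#' @return object of class `genotype_matrix`: list with `loci` (incl.
#'   `origin`), character matrix `geno` (loci x progeny), integer matrix
#'   `dp`, `depth_threshold`, `progeny`.
#' @export
build_genotype_matrix <- function(tab, origins, depth_threshold = 5L,
                                  include_indels = FALSE) {
  stopifnot(inherits(tab, "locus_table"))
  loci <- copy(tab$loci)
  loci[, origin := origins$origin[match(loci$locus_id, origins$locus_id)]]
  keep <- loci$origin %in% c("P1", "P2")
  if (!include_indels) keep <- keep & !loci$is_indel
  loci <- loci[keep]
  progeny <- setdiff(tab$samples, tab$parents)
  geno <- matrix("-", nrow(loci), length(progeny),
                 dimnames = list(loci$locus_id, progeny))
  dp <- tab$dp[loci$locus_id, progeny, drop = FALSE]
  for (s in progeny)
    geno[, s] <- code_genotype(loci$origin, tab$gt[loci$locus_id, s],
                               dp[, s], depth_threshold)
  structure(list(loci = loci, geno = geno, dp = dp,
                 depth_threshold = depth_threshold, progeny = progeny),
            class = "genotype_matrix")
}

#' HMM parameters for genotype correction
#'
#' @param epsilon per-read error probability (0 < epsilon < 0.5).
#' @param cm_per_mb rate converting physical to genetic distance when
#'   deriving inter-marker recombination fractions.
#' @param posterior_threshold posterior needed to impute or flip a symbol
#'   (in (0.5, 1]).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(epsilon = 0.005, cm_per_mb = 1,
                       posterior_threshold = 0.95) {
  stopifnot(epsilon > 0, epsilon < 0.5, cm_per_mb > 0,
            posterior_threshold > 0.5, posterior_threshold <= 1)
  structure(list(epsilon = epsilon, cm_per_mb = cm_per_mb,
                 posterior_threshold = posterior_threshold),
            class = "hmm_params")
}

#' F2 genotype transition matrix
#'
#' One-step transition probabilities between the states AA, H, BB across an
#' interval with recombination fraction `r`, from two independent meioses:
#' AA->AA (1-r)^2, AA->H 2r(1-r), AA->BB r^2, H->H (1-r)^2 + r^2, symmetric.
#'
#' @param r recombination fraction in [0, 0.5].
#' @return 3x3 row-stochastic matrix (rows/cols AA, H, BB).
#' @export
f2_transition <- function(r) {
  stopifnot(r >= 0, r <= 0.5)
  p <- 1 - r
  matrix(c(p^2,     2 * r * p,     r^2,
           r * p,   p^2 + r^2,     r * p,
           r^2,     2 * r * p,     p^2),
         3L, 3L, byrow = TRUE,
         dimnames = list(c("AA", "H", "BB"), c("AA", "H", "BB")))
}

# emission probabilities P(observed symbol, given its depth | state)
# under i.i.d. binomial read sampling with per-read error eps:
#   hom call from the right hom state: (1-eps)^k; from the wrong: eps^k;
#   from H: (1/2)^k (symmetric error keeps each read at 1/2);
#   het call: complement within each state; missing: uninformative.
.emissions <- function(sym, depth, eps) {
  L <- length(sym)
  em <- matrix(1, L, 3L)
  k <- depth
  hom1 <- sym %in% c("AA", "D")
  hom2 <- sym %in% c("BB", "C")
  het <- sym == "H"
  em[hom1, ] <- cbind((1 - eps)^k[hom1], 0.5^k[hom1], eps^k[hom1])
  em[hom2, ] <- cbind(eps^k[hom2], 0.5^k[hom2], (1 - eps)^k[hom2])
  hb <- 1 - (1 - eps)^k[het] - eps^k[het]
  em[het, ] <- cbind(hb, 1 - 2 * 0.5^k[het], hb)
  bad <- rowSums(em) <= 0            # inconsistent record (e.g. het, depth<2)
  em[bad, ] <- 1
  em
}

#' Posterior state probabilities along one marker chain
#'
#' Scaled forward-backward over the states AA, H, BB with the F2 transition
#' kernel; inter-marker recombination fractions come from the inverse
#' Kosambi transform of `cm_per_mb` x physical distance. Initial
#' distribution (1/4, 1/2, 1/4).
#'
#' @param sym coded symbols along one scaffold for one progeny.
#' @param depth depths matching `sym`.
#' @param pos physical positions (bp), strictly increasing.
#' @param params an [hmm_params()].
#' @return L x 3 matrix of posteriors (columns AA, H, BB).
#' @export
hmm_posterior <- function(sym, depth, pos, params) {
  stopifnot(inherits(params, "hmm_params"))
  if (is.unsorted(pos, strictly = TRUE)) stop("loci must be position-sorted")
  L <- length(sym)
  em <- .emissions(sym, depth, params$epsilon)
  init <- c(0.25, 0.5, 0.25)
  if (L == 1L) {
    po <- init * em[1L, ]
    return(matrix(po / sum(po), 1L, 3L,
                  dimnames = list(NULL, c("AA", "H", "BB"))))
  }
  d_cm <- params$cm_per_mb * diff(pos) / 1e6
  rs <- pmin(kosambi_inv(d_cm), 0.4999)
  tr <- lapply(rs, f2_transition)
  fwd <- matrix(0, L, 3L)
  sc <- numeric(L)
  a <- init * em[1L, ]
  sc[1L] <- sum(a)
  fwd[1L, ] <- a / sc[1L]
  for (i in 2:L) {
    a <- (fwd[i - 1L, ] %*% tr[[i - 1L]]) * em[i, ]
    sc[i] <- sum(a)
    fwd[i, ] <- a / sc[i]
  }
  bwd <- matrix(0, L, 3L)
  bwd[L, ] <- 1
  for (i in (L - 1L):1) {
    b <- tr[[i]] %*% (em[i + 1L, ] * bwd[i + 1L, ])
    bwd[i, ] <- b / sum(b)
  }
  po <- fwd * bwd
  po <- po / rowSums(po)
  colnames(po) <- c("AA", "H", "BB")
  po
}

#' Correct a coded genotype matrix with the HMM
#'
#' Per progeny per scaffold, posterior decoding over AA/H/BB. Low-confidence
#' entries (`C`, `D`, `-`) are replaced by the argmax state when its
#' posterior reaches `posterior_threshold`, else set missing. Confident
#' entries (`AA`, `BB`, `H`) are flipped only when the posterior support of
#' the observed state falls below `1 - posterior_threshold` (singleton-error
#' removal) and the argmax clears the threshold; otherwise kept.
#'
#' @param gm a [build_genotype_matrix()] result.
#' @param params an [hmm_params()].
#' @return character matrix (loci x progeny) over `AA`, `H`, `BB`, `NA`.
#' @export
hmm_correct <- function(gm, params = hmm_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- gm$loci
  for (sc in unique(loci$scaffold))
    if (is.unsorted(loci[scaffold == sc, pos], strictly = TRUE))
      stop("loci not position-sorted within scaffold ", sc)
  states <- c("AA", "H", "BB")
  out <- matrix(NA_character_, nrow(gm$geno), ncol(gm$geno),
                dimnames = dimnames(gm$geno))
  thr <- params$posterior_threshold
  for (sc in unique(loci$scaffold)) {
    idx <- which(loci$scaffold == sc)
    pos <- loci$pos[idx]
    for (j in seq_along(gm$progeny)) {
      sym <- gm$geno[idx, j]
      po <- hmm_posterior(sym, gm$dp[idx, j], pos, params)
      amax <- max.col(po, ties.method = "first")
      pmax_ <- po[cbind(seq_along(idx), amax)]
      res <- rep(NA_character_, length(idx))
      low <- sym %in% c("C", "D", "-")
      res[low & pmax_ >= thr] <- states[amax[low & pmax_ >= thr]]
      hi <- !low
      s_obs <- match(sym, states)
      p_obs <- po[cbind(seq_along(idx), ifelse(is.na(s_obs), 1L, s_obs))]
      keep <- hi & p_obs >= 1 - thr
      res[keep] <- sym[keep]
      flip <- hi & p_obs < 1 - thr & pmax_ >= thr
      res[flip] <- states[amax[flip]]
      out[idx, j] <- res
    }
  }
  out
}

#' Accuracy of corrected genotypes against simulated truth
#'
#' @param corrected matrix over AA/H/BB/NA from [hmm_correct()].
#' @param truth matching matrix of true symbols (see [state_symbols()]).
#' @return list with `accuracy` (fraction of non-missing entries equal to
#'   truth; `NA` when nothing is scored) and `n_scored`.
#' @export
genotype_accuracy <- function(corrected, truth) {
  if (!identical(dim(corrected), dim(truth)))
    stop("dimension mismatch between corrected matrix and truth")
  scored <- !is.na(corrected)
  n <- sum(scored)
  list(accuracy = if (n) mean(corrected[scored] == truth[scored]) else NA_real_,
       n_scored = n)
}
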