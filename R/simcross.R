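#' Simulation configuration for an F2 resequencing cross
#'
#' Describes the stated world the generator emulates: two fully homozygous
#' founders differing at parent-unique SNP loci laid on a small set of
#' scaffolds, an F2 of `n_progeny` individuals formed from two independently
#' recombined gametes, shotgun observation of every locus at a Poisson read
#' depth with per-read error and random call dropout, a fully penetrant
#' recessive locus controlling a binary growth-habit phenotype, and an
#' optional genomic deletion carried by a separately re-sequenced line.
#'
#' Defaults mirror the mapping study design at desk scale: 120 progeny,
#' 10x mean depth, and a recessive allele contributed by the determinate
#' parent P1 (so the homozygous-P1 class is the determinate class).
#'
#' @param n_progeny number of F2 individuals (>= 1).
#' @param scaffolds data.frame with columns `name`, `length_bp`, `length_cM`
#'   (genetic length used as the Poisson crossover rate per gamete).
#' @param snp_density expected parent-unique SNP loci per bp.
#' @param mean_depth Poisson mean reads per site per sample.
#' @param per_read_error probability a read reports the wrong allele.
#' @param missing_rate probability a site yields no call in a sample.
#' @param trait_locus list(scaffold=, pos=) of the causal locus; a marker is
#'   forced at this position by [simulate_founders()].
#' @param deletion optional list(scaffold=, start=, end=) interval deleted in
#'   the re-sequenced mutant line (see [simulate_coverage()]).
#' @param recessive_parent `"P1"` or `"P2"`: which founder carries the
#'   recessive determinate allele.
#' @param p1_fraction fraction of loci whose non-reference allele comes from
#'   P1 (P1-unique); default reflects a mutant line near-isogenic with the
#'   reference.
#' @param seed integer seed governing all randomness downstream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_progeny = 120,
                       scaffolds = data.frame(
                         name = c("scaffold01", "scaffold02"),
                         length_bp = c(10e6, 5e6),
                         length_cM = c(100, 50)),
                       snp_density = 1e-4,
                       mean_depth = 10,
                       per_read_error = 0.005,
                       missing_rate = 0.05,
                       trait_locus = list(scaffold = "scaffold01", pos = 5e6),
                       deletion = NULL,
                       recessive_parent = c("P1", "P2"),
                       p1_fraction = 46767 / 444731,
                       seed = 1L) {
  recessive_parent <- match.arg(recessive_parent)
  cfg <- structure(list(
    n_progeny = as.integer(n_progeny), scaffolds = as.data.table(scaffolds),
    snp_density = snp_density, mean_depth = mean_depth,
    per_read_error = per_read_error, missing_rate = missing_rate,
    trait_locus = trait_locus, deletion = deletion,
    recessive_parent = recessive_parent, p1_fraction = p1_fraction,
    seed = as.integer(seed)), class = "sim_config")
  err <- validate_sim_config(cfg)
  if (length(err)) stop("invalid sim_config: ", paste(err, collapse = "; "))
  cfg
}

validate_sim_config <- function(cfg) {
  err <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) err <<- c(err, msg)
  chk(nrow(cfg$scaffolds) >= 1L, "at least one scaffold required")
  chk(cfg$n_progeny >= 1L, "n_progeny must be >= 1")
  chk(all(cfg$scaffolds$length_bp > 0), "scaffold lengths must be > 0")
  chk(all(cfg$scaffolds$length_cM > 0), "genetic lengths must be > 0")
  chk(!anyDuplicated(cfg$scaffolds$name), "scaffold names must be unique")
  for (p in c("per_read_error", "missing_rate", "p1_fraction"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  chk(cfg$snp_density > 0, "snp_density must be > 0")
  chk(cfg$mean_depth >= 0, "mean_depth must be >= 0")
  if (!is.null(cfg$trait_locus))
    chk(cfg$trait_locus$scaffold %in% cfg$scaffolds$name,
        "trait_locus scaffold unknown")
  if (!is.null(cfg$deletion)) {
    i <- match(cfg$deletion$scaffold, cfg$scaffolds$name)
    chk(!is.na(i), "deletion scaffold unknown")
    if (!is.na(i))
      chk(cfg$deletion$start >= 1 &&
          cfg$deletion$end <= cfg$scaffolds$length_bp[i] &&
          cfg$deletion$start <= cfg$deletion$end,
          "deletion interval must lie within its scaffold")
  }
  err
}

#' Simulate two homozygous founders
#'
#' Lays parent-unique SNP loci on the configured scaffolds: locus count per
#' scaffold is Poisson(`snp_density` x length), positions are uniform without
#' replacement (strictly increasing), and each locus is homozygous REF in one
#' parent and homozygous ALT in the other. A marker locus is forced at the
#' configured trait-locus position.
#'
#' @param config a [sim_config()].
#' @return data.table with columns `locus_id`, `scaffold`, `pos`, `ref`,
#'   `alt`, `origin` (`"P1"`/`"P2"`: which parent carries ALT).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$scaffolds) == 0L) stop("zero scaffolds configured")
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(config$scaffolds)), function(i) {
    sc <- config$scaffolds[i]
    n <- rpois(1L, config$snp_density * sc$length_bp)
    p <- sort(sample.int(sc$length_bp, min(n, sc$length_bp)))
    if (!is.null(config$trait_locus) &&
        identical(config$trait_locus$scaffold, sc$name))
      p <- sort(unique(c(p, as.integer(config$trait_locus$pos))))
    data.table(scaffold = sc$name, pos = p)
  })
  f <- rbindlist(out)
  f[, ref := sample(bases, .N, replace = TRUE)]
  f[, alt := vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")]
  f[, origin := ifelse(runif(.N) < config$p1_fraction, "P1", "P2")]
  f[, locus_id := sprintf("%s_%09d", scaffold, pos)]
  setorder(f, scaffold, pos)
  f[]
}

# genetic position (cM) of loci under a uniform cM/bp rate per scaffold
.locus_cm <- function(pos, length_bp, length_cM) pos / length_bp * length_cM

#' Simulate F2 genotypes and phenotypes
#'
#' Each progeny is the union of two independent recombinant gametes; the
#' number of crossovers per gamete per scaffold is Poisson(genetic length in
#' Morgans) with breakpoints uniform on the genetic map (no interference).
#' Phenotype is assigned with complete penetrance at the trait locus: the
#' class homozygous for the recessive parent's alleles is determinate.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return object of class `truth_track`: list with `loci`, integer matrix
#'   `states` (loci x progeny, dosage 0/1/2 of the P2 allele, i.e.
#'   0=AA, 1=H, 2=BB), `crossovers` (data.table: progeny, gamete, scaffold,
#'   pos_bp), `phenotype` (character, named by progeny), `trait_idx`.
#' @export
simulate_f2 <- function(founders, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(founders) == 0L) stop("founder table is empty")
  trait_idx <- NA_integer_
  if (!is.null(config$trait_locus)) {
    trait_idx <- which(founders$scaffold == config$trait_locus$scaffold &
                       founders$pos == config$trait_locus$pos)
    if (length(trait_idx) != 1L)
      stop("trait locus not among simulated loci")
  }
  set.seed(config$seed + 1L)
  n <- config$n_progeny
  ids <- sprintf("F%03d", seq_len(n))
  L <- nrow(founders)
  states <- matrix(0L, L, n, dimnames = list(founders$locus_id, ids))
  xo <- vector("list", 2L * n * nrow(config$scaffolds))
  k <- 0L
  for (j in seq_len(n)) {
    dose <- integer(L)
    for (g in 1:2) {
      for (i in seq_len(nrow(config$scaffolds))) {
        sc <- config$scaffolds[i]
        idx <- which(founders$scaffold == sc$name)
        if (!length(idx)) next
        cm <- .locus_cm(founders$pos[idx], sc$length_bp, sc$length_cM)
        nx <- rpois(1L, sc$length_cM / 100)
        bx <- sort(runif(nx, 0, sc$length_cM))
        allele <- (sample(0:1, 1L) + findInterval(cm, bx)) %% 2L
        dose[idx] <- dose[idx] + allele
        if (nx > 0L) {
          k <- k + 1L
          xo[[k]] <- data.table(progeny = ids[j], gamete = g,
                                scaffold = sc$name,
                                pos_bp = bx / sc$length_cM * sc$length_bp)
        }
      }
    }
    states[, j] <- dose
  }
  crossovers <- if (k) rbindlist(xo[seq_len(k)]) else
    data.table(progeny = character(), gamete = integer(),
               scaffold = character(), pos_bp = numeric())
  phen <- rep("indeterminate", n)
  if (!is.na(trait_idx)) {
    rec_state <- if (config$recessive_parent == "P1") 0L else 2L
    phen[states[trait_idx, ] == rec_state] <- "determinate"
  }
  names(phen) <- ids
  structure(list(loci = founders, states = states, crossovers = crossovers,
                 phenotype = phen, trait_idx = trait_idx,
                 config = config), class = "truth_track")
}

#' Observe a truth track through the sequencing model
#'
#' Depth per site per sample is Poisson(`mean_depth`); each read from a
#' heterozygote carries either allele with probability 1/2 before error, and
#' per-read error flips the reported allele with probability
#' `per_read_error`. The called genotype is derived from allele counts (both
#' alleles seen = heterozygous call, one allele seen = homozygous call);
#' sites with depth 0, plus a `missing_rate` fraction of sites, yield no
#' call. Parents are observed through the same model.
#'
#' @param truth a [simulate_f2()] truth track.
#' @param config the same [sim_config()].
#' @return object of class `read_obs`: list with `loci`, `samples`
#'   (`"P1"`, `"P2"`, then progeny), character matrix `gt` (VCF-style
#'   `0/0`, `0/1`, `1/1`, `./.`), integer matrix `dp`.
#' @export
observe <- function(truth, config) {
  stopifnot(inherits(truth, "truth_track"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  loci <- truth$loci
  L <- nrow(loci)
  n <- ncol(truth$states)
  # parent truth: P1 carries two P1 alleles everywhere (dosage 0), P2 dosage 2
  st <- cbind(P1 = rep(0L, L), P2 = rep(2L, L), truth$states)
  m <- ncol(st)
  dp <- matrix(rpois(L * m, config$mean_depth), L, m)
  pr <- c(config$per_read_error, 0.5, 1 - config$per_read_error)
  p2_reads <- matrix(rbinom(L * m, dp, pr[st + 1L]), L, m)
  gt_p <- matrix("0/1", L, m)               # both alleles seen
  gt_p[p2_reads == 0L] <- "p1"              # only P1 allele
  gt_p[p2_reads == dp] <- "p2"              # only P2 allele
  gt_p[dp == 0L] <- "./."
  gt_p[matrix(runif(L * m) < config$missing_rate, L, m)] <- "./."
  # map P1/P2 alleles onto REF/ALT: ALT is the origin parent's allele
  p1_is_alt <- loci$origin == "P1"
  hom_p1 <- ifelse(p1_is_alt, "1/1", "0/0")
  hom_p2 <- ifelse(p1_is_alt, "0/0", "1/1")
  gt <- gt_p
  sel <- gt_p == "p1"
  gt[sel] <- hom_p1[row(gt_p)[sel]]
  sel <- gt_p == "p2"
  gt[sel] <- hom_p2[row(gt_p)[sel]]
  samples <- colnames(st)
  dimnames(gt) <- dimnames(dp) <- list(loci$locus_id, samples)
  structure(list(loci = loci, samples = samples, gt = gt, dp = dp),
            class = "read_obs")
}

#' Write one minimal VCF per sample
#'
#' Emits the dialect consumed by [read_sample_vcf()]: fixed columns plus a
#' single sample with `GT:DP`. Every founder locus is reported in every
#' sample (no-calls as `./.`), mirroring a merged-callset workflow.
#'
#' @param obs a [observe()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_sample_vcfs <- function(obs, dir) {
  stopifnot(inherits(obs, "read_obs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in obs$samples) {
    path <- file.path(dir, paste0(s, ".vcf"))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT:DP\t%s:%d",
                    obs$loci$scaffold, obs$loci$pos, obs$loci$locus_id,
                    obs$loci$ref, obs$loci$alt, obs$gt[, s], obs$dp[, s])
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=f2binmap"),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s, sep = "\t"), body), path)
    paths[s] <- path
  }
  paths
}

#' Simulate per-base coverage of a deletion-carrying line
#'
#' Stands in for re-sequencing an independent mutant line that is missing a
#' genomic segment: depth is Poisson(`mean_depth`) per base outside the
#' configured deletion and exactly 0 inside it. Only a window around the
#' deletion (plus flanks) is simulated; the result is run-length compressed.
#'
#' @param config a [sim_config()] with a non-NULL `deletion`.
#' @param flank bases simulated on each side of the deletion.
#' @return coverage profile data.table: `scaffold`, `start`, `end`
#'   (1-based inclusive), `depth`.
#' @export
simulate_coverage <- function(config, flank = 50e3) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$deletion)) stop("config has no deletion scenario")
  set.seed(config$seed + 3L)
  del <- config$deletion
  len <- config$scaffolds[name == del$scaffold, length_bp]
  lo <- max(1, del$start - flank)
  hi <- min(len, del$end + flank)
  d <- rpois(hi - lo + 1L, config$mean_depth)
  d[(del$start:del$end) - lo + 1L] <- 0L
  r <- rle(d)
  ends <- lo - 1L + cumsum(r$lengths)
  data.table(scaffold = del$scaffold,
             start = ends - r$lengths + 1L, end = ends,
             depth = r$values)
}

#' Symbols of the true state matrix
#'
#' @param states integer dosage matrix from [simulate_f2()].
#' @return character matrix over AA/H/BB.
#' @export
state_symbols <- function(states) {
  out <- matrix(c("AA", "H", "BB")[states + 1L], nrow(states), ncol(states))
  dimnames(out) <- dimnames(states)
  out
}
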