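#' Read one minimal-dialect VCF
#'
#' Parses the per-sample dialect written by [write_sample_vcfs()]: plain-text
#' VCF with one sample column and a FORMAT containing at least `GT` and `DP`.
#'
#' @param path file path.
#' @return data.table: `scaffold`, `pos`, `ref`, `alt`, `sample`, `gt`, `dp`.
#' @export
read_sample_vcf <- function(path) {
  hdr <- grep("^#CHROM", readLines(path, n = 200L))
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", readLines(path)[hdr[1L]]), "\t")[[1L]]
  dt <- fread(path, skip = hdr[1L], header = FALSE, sep = "\t",
              col.names = cols)
  dt[, CHROM := as.character(CHROM)]
  sample_id <- cols[10L]
  fmt <- strsplit(dt$FORMAT[1L], ":", fixed = TRUE)[[1L]]
  gt_i <- match("GT", fmt)
  dp_i <- match("DP", fmt)
  if (is.na(gt_i)) stop("FORMAT lacks GT in ", path)
  parts <- data.table::tstrsplit(dt[[sample_id]], ":", fixed = TRUE)
  gt <- parts[[gt_i]]
  gt[gt %in% c(".", "./.", ".|.")] <- "./."
  dp <- if (is.na(dp_i)) rep(NA_integer_, nrow(dt)) else
    suppressWarnings(as.integer(parts[[dp_i]]))
  data.table(scaffold = dt$CHROM, pos = dt$POS, ref = dt$REF, alt = dt$ALT,
             sample = sample_id, gt = gt, dp = dp)
}

#' Merge per-sample calls into a locus table
#'
#' Full outer join over (scaffold, pos): one row per locus with one genotype
#' and depth column per sample; absent sample-locus entries are missing.
#' Conflicting REF (or ALT) alleles at the same position are an error naming
#' the locus, mirroring merged-callset semantics.
#'
#' @param paths character vector of per-sample VCF paths, or a directory
#'   containing `*.vcf`.
#' @param parents the two sample names to treat as founders.
#' @return object of class `locus_table`: list with `loci` (data.table:
#'   scaffold, pos, ref, alt, is_indel), character matrix `gt`
#'   (loci x samples), integer matrix `dp`, `samples`, `parents`.
#' @export
merge_calls <- function(paths, parents = c("P1", "P2")) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.vcf$", full.names = TRUE)
  long <- rbindlist(lapply(paths, read_sample_vcf))
  key <- long[, .(scaffold, pos)]
  alleles <- unique(long[, .(scaffold, pos, ref, alt)])
  bad <- alleles[, .N, by = .(scaffold, pos)][N > 1L]
  if (nrow(bad))
    stop("conflicting alleles at locus ", bad$scaffold[1L], ":", bad$pos[1L])
  setorder(alleles, scaffold, pos)
  alleles[, locus_id := sprintf("%s_%09d", scaffold, pos)]
  alleles[, is_indel := nchar(ref) != 1L | nchar(alt) != 1L]
  samples <- unique(long$sample)
  L <- nrow(alleles)
  gt <- matrix("./.", L, length(samples),
               dimnames = list(alleles$locus_id, samples))
  dp <- matrix(0L, L, length(samples),
               dimnames = list(alleles$locus_id, samples))
  ridx <- match(sprintf("%s_%09d", long$scaffold, long$pos), alleles$locus_id)
  cidx <- match(long$sample, samples)
  gt[cbind(ridx, cidx)] <- long$gt
  dp[cbind(ridx, cidx)] <- ifelse(is.na(long$dp), 0L, long$dp)
  structure(list(loci = alleles, gt = gt, dp = dp, samples = samples,
                 parents = parents), class = "locus_table")
}

n_called <- function(tab) rowSums(tab$gt != "./.")

#' High-quality locus filter
#'
#' Retains loci whose non-missing call count across progeny and parents lies
#' in `[min_calls, max_calls]`. The study's literal presence window is
#' available via [hq_preset_literal()]; the default upper bound is the
#' sample count (no upper truncation).
#'
#' @param tab a [merge_calls()] locus table.
#' @param min_calls,max_calls inclusive call-count bounds; `max_calls = NULL`
#'   means the total sample count.
#' @return filtered `locus_table` with a `filter_report` attribute
#'   (data.table of discard counts by reason).
#' @export
filter_high_quality <- function(tab, min_calls = 20L, max_calls = NULL) {
  stopifnot(inherits(tab, "locus_table"))
  if (is.null(max_calls)) max_calls <- length(tab$samples)
  if (!(min_calls <= max_calls && max_calls <= length(tab$samples)))
    stop("need min_calls <= max_calls <= number of samples")
  nc <- n_called(tab)
  keep <- nc >= min_calls & nc <= max_calls
  report <- data.table(
    reason = c("retained", "too_few_calls", "too_many_calls"),
    n = c(sum(keep), sum(nc < min_calls), sum(nc > max_calls)))
  out <- subset_locus_table(tab, keep)
  attr(out, "filter_report") <- report
  out
}

#' The literal presence-window preset
#'
#' Reproduces the published rule of retaining loci present 20-100 times
#' across the 120 progeny plus two parents.
#' @param tab locus table.
#' @export
hq_preset_literal <- function(tab) filter_high_quality(tab, 20L, 100L)

subset_locus_table <- function(tab, keep) {
  structure(list(loci = tab$loci[keep], gt = tab$gt[keep, , drop = FALSE],
                 dp = tab$dp[keep, , drop = FALSE], samples = tab$samples,
                 parents = tab$parents), class = "locus_table")
}

#' Classify parent-unique homozygous SNPs
#'
#' Assigns every locus exactly one origin: `P1` (P1 homozygous for the
#' variant allele, P2 homozygous for the other), `P2` (the converse), or
#' `discarded` with a reason — heterozygous in a parent, the same homozygous
#' variant in both parents, or a parent call missing.
#'
#' @param tab locus table with both parent columns present.
#' @return data.table: `locus_id`, `origin` (`"P1"`, `"P2"`, `"discarded"`),
#'   `reason`; with a `class_counts` attribute.
#' @export
classify_parent_snps <- function(tab) {
  stopifnot(inherits(tab, "locus_table"))
  if (!all(tab$parents %in% tab$samples))
    stop("parent column missing: ",
         paste(setdiff(tab$parents, tab$samples), collapse = ", "))
  g1 <- tab$gt[, tab$parents[1L]]
  g2 <- tab$gt[, tab$parents[2L]]
  het <- function(g) g == "0/1"
  hom_alt <- function(g) g == "1/1"
  hom_ref <- function(g) g == "0/0"
  origin <- rep("discarded", nrow(tab$loci))
  reason <- rep(NA_character_, nrow(tab$loci))
  reason[g1 == "./." | g2 == "./."] <- "parent_missing"
  reason[het(g1) | het(g2)] <- "parent_heterozygous"
  reason[hom_alt(g1) & hom_alt(g2)] <- "shared_variant"
  reason[hom_ref(g1) & hom_ref(g2)] <- "no_variant"
  p1u <- hom_alt(g1) & hom_ref(g2)
  p2u <- hom_ref(g1) & hom_alt(g2)
  sel1 <- p1u & is.na(reason)
  sel2 <- p2u & is.na(reason)
  origin[sel1] <- "P1"
  origin[sel2] <- "P2"
  reason[sel1 | sel2] <- "unique"
  reason[is.na(reason)] <- "unclassifiable"
  out <- data.table(locus_id = tab$loci$locus_id, origin = origin,
                    reason = reason)
  attr(out, "class_counts") <- out[, .N, by = .(origin, reason)]
  out
}

#' Sequencing depth arithmetic
#'
#' depth = read_count x read_length / genome_size, to 2 decimals — the
#' convention used for whole-genome resequencing summaries against an
#' estimated genome size.
#'
#' @param read_count number of reads.
#' @param read_length read length in bp.
#' @param genome_size genome size in bp.
#' @return depth in x, rounded to 2 decimals.
#' @export
summarize_sequencing <- function(read_count, read_length, genome_size) {
  stopifnot(read_count > 0, read_length > 0, genome_size > 0)
  round(read_count * read_length / genome_size, 2)
}
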