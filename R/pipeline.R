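#' Pipeline configuration
#'
#' One structured object carrying every stage parameter; defaults mirror
#' the mapping study (depth threshold 5, presence filter from 20 calls,
#' segregation alpha 0.05, grouping at LOD 8.0 / r 0.35, groups of more
#' than 10 bins kept, ordering LOD floor 3.0, 2 cM scan walk, 1,000
#' permutations, 5 cM gap threshold).
#'
#' @param sim a [sim_config()] describing the simulated cross (also the
#'   seed source for the whole run).
#' @param depth_threshold confident-homozygote depth for coding.
#' @param min_calls,max_calls high-quality presence window.
#' @param epsilon,cm_per_mb,posterior_threshold HMM correction parameters.
#' @param seg_alpha segregation-distortion alpha.
#' @param min_lod,max_rf,min_group_size linkage grouping parameters.
#' @param order_lod,ordering bin ordering parameters.
#' @param scan_step walk interval in cM; `scan_positions` as in
#'   [locus_scan()].
#' @param n_perm,alpha permutation threshold parameters.
#' @param gap_cm map gap threshold.
#' @param out_dir artifact directory (NULL: no files written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            depth_threshold = 5L,
                            min_calls = 20L, max_calls = NULL,
                            epsilon = 0.005, cm_per_mb = 1,
                            posterior_threshold = 0.95,
                            seg_alpha = 0.05,
                            min_lod = 8, max_rf = 0.35,
                            min_group_size = 10L,
                            order_lod = 3, ordering = "search",
                            scan_step = 2, scan_positions = "all",
                            n_perm = 1000L, alpha = 0.05,
                            gap_cm = 5, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations naming each parameter; empty when
#'   the configuration is valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  err <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) err <<- c(err, msg)
  err <- c(err, validate_sim_config(config$sim))
  n_samples <- config$sim$n_progeny + 2L
  maxc <- if (is.null(config$max_calls)) n_samples else config$max_calls
  chk(config$min_calls <= maxc && maxc <= n_samples,
      "min_calls/max_calls outside [min_calls <= max_calls <= n_samples]")
  chk(config$depth_threshold >= 1, "depth_threshold must be >= 1")
  chk(config$epsilon > 0 && config$epsilon < 0.5,
      "epsilon must be in (0, 0.5)")
  chk(config$posterior_threshold > 0.5 && config$posterior_threshold <= 1,
      "posterior_threshold must be in (0.5, 1]")
  chk(config$seg_alpha > 0 && config$seg_alpha < 1,
      "seg_alpha must be in (0, 1)")
  chk(config$min_lod > 0, "min_lod must be > 0")
  chk(config$max_rf >= 0 && config$max_rf <= 0.5,
      "max_rf must be in [0, 0.5]")
  chk(config$min_group_size >= 0, "min_group_size must be >= 0")
  chk(config$order_lod > 0, "order_lod must be > 0")
  chk(config$ordering %in% c("search", "physical"),
      "ordering must be 'search' or 'physical'")
  chk(config$scan_step > 0, "scan_step must be > 0")
  chk(config$n_perm >= 1, "n_perm must be >= 1")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$gap_cm > 0, "gap_cm must be > 0")
  err
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a simulated cross
#'
#' simulate -> write/parse VCFs -> high-quality filter -> parent-unique
#' classification -> genotype coding -> HMM correction -> bin collapsing ->
#' segregation filter -> linkage map -> trait scan (+ permutation
#' threshold) -> peak-bin co-segregation -> optional deletion stage. All
#' randomness flows from `config$sim$seed`.
#'
#' @param config a valid [pipeline_config()].
#' @return list with `report` (stage counts and key results), `map`, `scan`,
#'   `stats`, `timings`; artifacts written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid configuration: ", paste(errs, collapse = "; "))
  t0 <- proc.time()[["elapsed"]]
  tick <- local({
    last <- t0
    function() {
      now <- proc.time()[["elapsed"]]
      d <- now - last
      last <<- now
      d
    }
  })
  timings <- list()
  vcf_dir <- file.path(if (is.null(config$out_dir)) tempfile("f2bm")
                       else config$out_dir, "vcf")
  founders <- .stage("simulate", simulate_founders(config$sim))
  truth <- .stage("simulate", simulate_f2(founders, config$sim))
  obs <- .stage("simulate", observe(truth, config$sim))
  paths <- .stage("simulate", write_sample_vcfs(obs, vcf_dir))
  timings$simulate <- tick()
  tab <- .stage("parse", merge_calls(vcf_dir))
  hq <- .stage("filter", filter_high_quality(tab, config$min_calls,
                                             config$max_calls))
  origins <- .stage("classify", classify_parent_snps(hq))
  timings$variants <- tick()
  gm <- .stage("code", build_genotype_matrix(hq, origins,
                                             config$depth_threshold))
  corrected <- .stage("correct", hmm_correct(gm, hmm_params(
    config$epsilon, config$cm_per_mb, config$posterior_threshold)))
  timings$genotyping <- tick()
  bs <- .stage("bin", collapse_bins(corrected, gm$loci))
  bs_kept <- .stage("bin", segregation_filter(bs, config$seg_alpha))
  map <- .stage("map", build_map(bs_kept, config$min_lod, config$max_rf,
                                 config$min_group_size, config$order_lod,
                                 config$ordering))
  stats <- map_statistics(map, config$gap_cm)
  timings$map <- tick()
  phen <- truth$phenotype
  scan <- .stage("scan", locus_scan(map, bs_kept$geno, phen,
                                    step = config$scan_step,
                                    positions = config$scan_positions))
  thr <- .stage("scan", permutation_threshold(
    map, bs_kept$geno, phen, n_perm = config$n_perm, alpha = config$alpha,
    seed = config$sim$seed + 4L, step = config$scan_step,
    positions = config$scan_positions))
  peak <- attr(scan, "peak")
  coseg <- if (!is.na(peak$bin_id))
    .stage("associate", cosegregation(bs_kept$geno[peak$bin_id, ], phen))
  else NULL
  timings$scan <- tick()
  deletions <- NULL
  if (!is.null(config$sim$deletion)) {
    cov <- .stage("sv", simulate_coverage(config$sim))
    deletions <- .stage("sv", find_zero_runs(cov))
  }
  timings$sv <- tick()
  report <- list(
    seed = config$sim$seed,
    n_progeny = config$sim$n_progeny,
    loci_parsed = nrow(tab$loci),
    loci_retained = nrow(hq$loci),
    parent_unique = list(P1 = sum(origins$origin == "P1"),
                         P2 = sum(origins$origin == "P2"),
                         discarded = sum(origins$origin == "discarded")),
    loci_coded = nrow(gm$loci),
    bins_formed = nrow(bs$bins),
    bins_retained = nrow(bs_kept$bins),
    n_lgs = length(map$lgs),
    map_length_cM = round(sum(vapply(map$lgs, `[[`, 1, "length")), 2),
    scan_peak = list(lg = peak$lg, pos_cM = peak$pos_cM,
                     lod = round(peak$lod, 3),
                     r2 = round(attr(scan, "r2"), 4)),
    lod_threshold = round(thr, 3),
    peak_cosegregation = if (!is.null(coseg))
      round(coseg$coefficient, 2) else NA_real_,
    deletions = if (!is.null(deletions))
      deletions[, .(scaffold, start, end, length)] else NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_map(map, file.path(config$out_dir, "map.tsv"))
    fwrite(stats, file.path(config$out_dir, "map_statistics.tsv"),
           sep = "\t")
    fwrite(scan, file.path(config$out_dir, "scan.tsv"), sep = "\t")
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(report = report, map = map, scan = scan, stats = stats,
       threshold = thr, timings = timings)
}

#' Export a genetic map as tab-separated text
#'
#' Columns: LG, bin id, cumulative position (cM), marker count, member
#' scaffold and physical bounds.
#'
#' @param map a [build_map()] genetic map.
#' @param path output file.
#' @return the exported data.table, invisibly.
#' @export
export_map <- function(map, path) {
  rows <- rbindlist(lapply(map$lgs, function(x)
    data.table(lg = x$lg, bin_id = x$bins, pos_cM = round(x$pos, 4))))
  rows <- merge(rows, map$bins[, .(bin_id, scaffold, start, end, n_loci)],
                by = "bin_id", sort = FALSE)
  setorder(rows, lg, pos_cM)
  fwrite(rows, path, sep = "\t")
  invisible(rows)
}

#' Write / read a flat pipeline configuration file
#'
#' Plain `key: value` text; scaffolds are encoded `name:bp:cM`
#' (semicolon-separated), the trait locus `scaffold:pos`, and a deletion
#' `scaffold:start:end`.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config()`: the path, invisibly;
#'   `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  s <- config$sim
  lines <- c(
    sprintf("n_progeny: %d", s$n_progeny),
    sprintf("scaffolds: %s", paste(sprintf("%s:%d:%g", s$scaffolds$name,
                                           as.integer(s$scaffolds$length_bp),
                                           s$scaffolds$length_cM),
                                   collapse = ";")),
    sprintf("snp_density: %g", s$snp_density),
    sprintf("mean_depth: %g", s$mean_depth),
    sprintf("per_read_error: %g", s$per_read_error),
    sprintf("missing_rate: %g", s$missing_rate),
    sprintf("trait_locus: %s:%d", s$trait_locus$scaffold,
            as.integer(s$trait_locus$pos)),
    if (!is.null(s$deletion))
      sprintf("deletion: %s:%d:%d", s$deletion$scaffold,
              as.integer(s$deletion$start), as.integer(s$deletion$end)),
    sprintf("recessive_parent: %s", s$recessive_parent),
    sprintf("seed: %d", s$seed),
    sprintf("depth_threshold: %d", config$depth_threshold),
    sprintf("min_calls: %d", config$min_calls),
    if (!is.null(config$max_calls))
      sprintf("max_calls: %d", config$max_calls),
    sprintf("epsilon: %g", config$epsilon),
    sprintf("cm_per_mb: %g", config$cm_per_mb),
    sprintf("posterior_threshold: %g", config$posterior_threshold),
    sprintf("seg_alpha: %g", config$seg_alpha),
    sprintf("min_lod: %g", config$min_lod),
    sprintf("max_rf: %g", config$max_rf),
    sprintf("min_group_size: %d", config$min_group_size),
    sprintf("order_lod: %g", config$order_lod),
    sprintf("ordering: %s", config$ordering),
    sprintf("scan_step: %g", config$scan_step),
    sprintf("scan_positions: %s", config$scan_positions),
    sprintf("n_perm: %d", config$n_perm),
    sprintf("alpha: %g", config$alpha),
    sprintf("gap_cm: %g", config$gap_cm))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- trimws(keys)
  num <- function(k, default = NULL)
    if (k %in% names(vals)) as.numeric(vals[[k]]) else default
  sc <- do.call(rbind, lapply(strsplit(strsplit(vals[["scaffolds"]],
                                                ";")[[1]], ":"),
                              function(p) data.frame(
                                name = p[1], length_bp = as.numeric(p[2]),
                                length_cM = as.numeric(p[3]))))
  tl <- strsplit(vals[["trait_locus"]], ":")[[1]]
  del <- if ("deletion" %in% names(vals)) {
    d <- strsplit(vals[["deletion"]], ":")[[1]]
    list(scaffold = d[1], start = as.numeric(d[2]), end = as.numeric(d[3]))
  } else NULL
  sim <- sim_config(
    n_progeny = num("n_progeny"), scaffolds = sc,
    snp_density = num("snp_density"), mean_depth = num("mean_depth"),
    per_read_error = num("per_read_error"),
    missing_rate = num("missing_rate"),
    trait_locus = list(scaffold = tl[1], pos = as.numeric(tl[2])),
    deletion = del, recessive_parent = vals[["recessive_parent"]],
    seed = num("seed"))
  pipeline_config(
    sim = sim, depth_threshold = as.integer(num("depth_threshold", 5)),
    min_calls = as.integer(num("min_calls", 20)),
    max_calls = if ("max_calls" %in% names(vals))
      as.integer(num("max_calls")) else NULL,
    epsilon = num("epsilon", 0.005), cm_per_mb = num("cm_per_mb", 1),
    posterior_threshold = num("posterior_threshold", 0.95),
    seg_alpha = num("seg_alpha", 0.05), min_lod = num("min_lod", 8),
    max_rf = num("max_rf", 0.35),
    min_group_size = as.integer(num("min_group_size", 10)),
    order_lod = num("order_lod", 3),
    ordering = if ("ordering" %in% names(vals))
      vals[["ordering"]] else "search",
    scan_step = num("scan_step", 2),
    scan_positions = if ("scan_positions" %in% names(vals))
      vals[["scan_positions"]] else "all",
    n_perm = as.integer(num("n_perm", 1000)), alpha = num("alpha", 0.05),
    gap_cm = num("gap_cm", 5))
}
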