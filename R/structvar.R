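#' Coverage profile from a per-base depth vector
#'
#' Run-length compresses per-base depths into the interval representation
#' (`scaffold`, `start`, `end`, `depth`, 1-based inclusive) used by
#' [find_zero_runs()].
#'
#' @param depths integer vector of per-base depths.
#' @param scaffold scaffold name.
#' @param offset position of the first element (default 1).
#' @return coverage profile data.table.
#' @export
coverage_profile <- function(depths, scaffold, offset = 1L) {
  stopifnot(all(depths >= 0))
  r <- rle(as.integer(depths))
  ends <- offset - 1L + cumsum(r$lengths)
  data.table(scaffold = scaffold, start = ends - r$lengths + 1L,
             end = ends, depth = r$values)
}

#' Detect deletions as maximal low-coverage runs
#'
#' Finds maximal runs of contiguous positions with depth <= `max_depth`
#' (default 0: true zero coverage) of length >= `min_length`. Calls are
#' disjoint and maximal by construction. If an annotation is supplied,
#' overlapped genes are reported as `full` (gene contained in the run) or
#' `partial`.
#'
#' @param profile coverage profile (`scaffold`, `start`, `end`, `depth`),
#'   contiguous within each scaffold.
#' @param min_length minimum run length in bp (default 1000).
#' @param max_depth maximum depth counted as absent (default 0).
#' @param annotation optional gene table (`gene_id`, `scaffold`, `start`,
#'   `end`).
#' @return data.table of calls: `scaffold`, `start`, `end`, `length`
#'   (inclusive, end - start + 1), `features` (comma-separated
#'   `gene(full|partial)` or "").
#' @export
find_zero_runs <- function(profile, min_length = 1000L, max_depth = 0L,
                           annotation = NULL) {
  profile <- as.data.table(profile)
  if (nrow(profile) == 0L) stop("empty coverage profile")
  setorder(profile, scaffold, start)
  calls <- profile[, {
    low <- depth <= max_depth
    if (!any(low)) NULL else {
      grp <- cumsum(c(TRUE, low[-1L] != low[-.N] |
                            start[-1L] != end[-.N] + 1L))
      dt <- data.table(start, end, low, grp)
      runs <- dt[low == TRUE, .(start = min(start), end = max(end)), by = grp]
      runs[, .(start, end)]
    }
  }, by = scaffold]
  if (nrow(calls) == 0L)
    return(data.table(scaffold = character(), start = integer(),
                      end = integer(), length = integer(),
                      features = character()))
  calls[, length := end - start + 1L]
  calls <- calls[length >= min_length]
  calls[, features := ""]
  if (!is.null(annotation) && nrow(calls)) {
    ann <- as.data.table(annotation)
    calls[, features := vapply(seq_len(.N), function(i) {
      ov <- ann[scaffold == calls$scaffold[i] &
                end >= calls$start[i] & start <= calls$end[i]]
      if (!nrow(ov)) return("")
      kind <- ifelse(ov$start >= calls$start[i] & ov$end <= calls$end[i],
                     "full", "partial")
      paste0(ov$gene_id, "(", kind, ")", collapse = ",")
    }, "")]
  }
  calls[]
}

#' Predict PCR amplicon presence across deletions
#'
#' A primer pair fails (`ABSENT`) when either primer annealing site
#' intersects a deletion; otherwise it is `PRESENT` with its reference
#' amplicon length (span of the pair, rev_end - fwd_start + 1).
#'
#' @param primers data.frame: `name`, `scaffold`, `fwd_start`, `fwd_end`,
#'   `rev_start`, `rev_end`.
#' @param deletions deletion calls (`scaffold`, `start`, `end`).
#' @return data.table: `name`, `status`, `amplicon_bp` (NA when absent).
#' @export
predict_amplicons <- function(primers, deletions) {
  primers <- as.data.table(primers)
  deletions <- as.data.table(deletions)
  stopifnot(all(primers$fwd_start < primers$rev_end))
  hit <- function(sc, s, e) {
    if (nrow(deletions) == 0L) return(FALSE)
    any(deletions$scaffold == sc & deletions$end >= s & deletions$start <= e)
  }
  status <- vapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i]
    if (hit(p$scaffold, p$fwd_start, p$fwd_end) ||
        hit(p$scaffold, p$rev_start, p$rev_end)) "ABSENT" else "PRESENT"
  }, "")
  data.table(name = primers$name, status = status,
             amplicon_bp = ifelse(status == "PRESENT",
                                  primers$rev_end - primers$fwd_start + 1L,
                                  NA_integer_))
}

#' Report genes lost or truncated by deletions
#'
#' Genes fully inside a deletion are `lost`; genes overlapping a deletion
#' boundary are `truncated`; genes merely abutting (adjacent,
#' non-overlapping) are unaffected and omitted.
#'
#' @param deletions deletion calls (`scaffold`, `start`, `end`).
#' @param annotation gene table (`gene_id`, `scaffold`, `start`, `end`).
#' @return data.table: `gene_id`, `status`.
#' @export
feature_loss_report <- function(deletions, annotation) {
  ann <- as.data.table(annotation)
  deletions <- as.data.table(deletions)
  if (nrow(ann) == 0L || nrow(deletions) == 0L)
    return(data.table(gene_id = character(), status = character()))
  out <- lapply(seq_len(nrow(deletions)), function(i) {
    d <- deletions[i]
    ov <- ann[scaffold == d$scaffold & end >= d$start & start <= d$end]
    if (!nrow(ov)) return(NULL)
    data.table(gene_id = ov$gene_id,
               status = ifelse(ov$start >= d$start & ov$end <= d$end,
                               "lost", "truncated"))
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table(gene_id = character(), status = character()))
  unique(res)
}
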