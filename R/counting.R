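# Variant x timepoint count tables for a single selection, with the
# timepoint schedule and normalization denominators used by the scoring
# module.

#' Timepoint schedule for a selection
#'
#' Timepoints may be variably spaced (e.g. hours of a growth selection) or
#' uniform (rounds of a phage selection). The first element is the input
#' timepoint. Regression is always performed on the normalized axis
#' `t / max(t)` so that scores are comparable between selections whose
#' timepoints differ in magnitude (rounds 0/1/2/3 versus hours 0/24/48/72).
#'
#' @param times Strictly increasing numeric vector; first element is the
#'   input timepoint and `max(times)` must be positive.
#' @return An object of class `timepoint_schedule` with elements `times` and
#'   `x` (normalized times).
#' @export
timepoint_schedule <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("a selection needs at least two timepoints")
  if (any(diff(times) <= 0)) stop("timepoints must be strictly increasing")
  if (max(times) <= 0) stop("max timepoint must be positive")
  structure(list(times = times, x = times / max(times)),
            class = "timepoint_schedule")
}

#' Variant count table for one selection
#'
#' Holds nonnegative integer counts per variant per timepoint together with
#' the per-timepoint read totals `N_t` and the timepoint schedule. `N_t`
#' defaults to the column sums (all accepted reads assigned to variants) but
#' may be supplied directly; it is the number of reads sequenced and may
#' exceed the assigned counts.
#'
#' @param counts Matrix or data frame of nonnegative integer counts; rows are
#'   variants (rownames or a `variant` column), columns timepoints.
#' @param times Numeric timepoints passed to [timepoint_schedule()], or a
#'   schedule object.
#' @param totals Optional numeric vector of per-timepoint read totals `N_t`.
#' @param wildtype Label of the wild-type row (default `"_wt"`); may be
#'   absent, in which case only library-size normalization is possible.
#' @return An object of class `variant_count_table`.
#' @export
variant_count_table <- function(counts, times, totals = NULL,
                                wildtype = "_wt") {
  if (is.data.frame(counts)) {
    if ("variant" %in% names(counts)) {
      rn <- counts$variant
      counts <- as.matrix(counts[setdiff(names(counts), "variant")])
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("counts must have variant rownames")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  schedule <- if (inherits(times, "timepoint_schedule")) times
              else timepoint_schedule(times)
  if (ncol(counts) != length(schedule$times)) {
    stop("number of count columns must match number of timepoints")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("t", schedule$times)
  }
  if (is.null(totals)) totals <- colSums(counts)
  totals <- as.numeric(totals)
  stopifnot(length(totals) == ncol(counts))
  structure(
    list(counts = counts, schedule = schedule, totals = totals,
         wildtype = wildtype),
    class = "variant_count_table"
  )
}

#' @export
print.variant_count_table <- function(x, ...) {
  cat("variant_count_table:", nrow(x$counts), "variants x",
      ncol(x$counts), "timepoints; wild-type",
      if (has_wildtype(x)) "present" else "absent", "\n")
  invisible(x)
}

has_wildtype <- function(table) {
  !is.null(table$wildtype) && table$wildtype %in% rownames(table$counts)
}

#' Variant frequencies
#'
#' `f_{v,t} = c_{v,t} / N_t`, the count of each variant divided by the number
#' of reads sequenced in that timepoint.
#'
#' @param table A [variant_count_table()].
#' @return Numeric matrix of frequencies with the same dimensions as the
#'   counts.
#' @export
frequencies <- function(table) {
  stopifnot(inherits(table, "variant_count_table"))
  bad <- which(table$totals == 0)
  if (length(bad)) {
    stop("read total N_t is zero at timepoint t = ",
         paste(table$schedule$times[bad], collapse = ", "))
  }
  sweep(table$counts, 2, table$totals, "/")
}

#' Filtered library size
#'
#' The per-timepoint sum of counts over variants that are present (count > 0)
#' at every timepoint. Used as the normalization denominator when the library
#' carries no wild-type sequence.
#'
#' @param table A [variant_count_table()].
#' @param t Optional timepoint value; if omitted, sizes for all timepoints are
#'   returned.
#' @return Numeric vector of filtered library sizes (named by timepoint), or a
#'   single value if `t` is given.
#' @export
filtered_library_size <- function(table, t = NULL) {
  stopifnot(inherits(table, "variant_count_table"))
  present <- rowSums(table$counts > 0) == ncol(table$counts)
  if (!any(present)) {
    warning("no variant is present at every timepoint; filtered library size is 0")
  }
  sizes <- colSums(table$counts[present, , drop = FALSE])
  names(sizes) <- table$schedule$times
  if (is.null(t)) return(sizes)
  idx <- match(t, table$schedule$times)
  if (is.na(idx)) stop("timepoint ", t, " not in schedule")
  unname(sizes[idx])
}

#' Align replicate count tables on a shared variant index
#'
#' Takes the union of variants across replicate tables (ordered by first
#' appearance) and expands each table to that index. Cells for variants never
#' observed in a replicate are filled with count 0 and flagged in a logical
#' `missing` matrix, so an observed zero remains distinguishable from an
#' absent variant.
#'
#' @param tables List of [variant_count_table()]s with identical schedules.
#' @return List of expanded tables, each with an added `missing` element.
#' @export
align_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "variant_count_table")))
  t0 <- tables[[1]]$schedule$times
  for (tb in tables[-1]) {
    if (!isTRUE(all.equal(tb$schedule$times, t0))) {
      stop("replicate tables have incompatible timepoint schedules")
    }
  }
  index <- unique(unlist(lapply(tables, function(tb) rownames(tb$counts))))
  lapply(tables, function(tb) {
    m <- matrix(0, nrow = length(index), ncol = ncol(tb$counts),
                dimnames = list(index, colnames(tb$counts)))
    found <- index %in% rownames(tb$counts)
    m[index[found], ] <- tb$counts[index[found], , drop = FALSE]
    tb$missing <- matrix(!found, nrow = length(index), ncol = ncol(tb$counts),
                         dimnames = dimnames(m))
    tb$counts <- m
    tb
  })
}

#' Write / read a count table as TSV
#'
#' The TSV has a `variant` column followed by one column per timepoint; a
#' sidecar JSON (same path with extension `.json`) records the schedule, the
#' read totals `N_t`, and the wild-type label so the table round-trips
#' exactly.
#'
#' @param table A [variant_count_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "variant_count_table"))
  df <- data.frame(variant = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(times = table$schedule$times, totals = table$totals,
               wildtype = table$wildtype)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("sidecar metadata file not found: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  variant_count_table(df, times = meta$times, totals = meta$totals,
                      wildtype = meta$wildtype)
}
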