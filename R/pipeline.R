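# Configuration-driven orchestration: experiment -> condition -> selection
# (replicate) -> sequencing library, with persistent TSV output, a config
# echo, a plain-text log, and sequence-function-map rendering.

cfg_stop <- function(path, msg) stop("config error at ", path, ": ", msg,
                                     call. = FALSE)

cfg_get <- function(x, field, path, required = TRUE, default = NULL) {
  if (is.null(x[[field]])) {
    if (required) cfg_stop(path, paste0("missing required field '", field, "'"))
    return(default)
  }
  x[[field]]
}

#' Validate an experiment configuration
#'
#' An experiment is a tree: experiment, conditions, selections (replicates),
#' and sequencing libraries. Each selection either names a pre-tabulated
#' count TSV (`counts_file`) or a list of `libraries`, one per timepoint, each
#' naming a FASTQ file (and optionally a barcode map). Replicate selections
#' within a condition must share a timepoint schedule. Violations are reported
#' with the offending config path.
#'
#' @param config A list (parsed JSON) or path to a JSON file.
#' @return The validated config list, invisibly annotated.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  cfg_get(config, "name", "$")
  conditions <- cfg_get(config, "conditions", "$")
  if (length(conditions) == 0L) cfg_stop("$.conditions", "empty")
  for (ci in seq_along(conditions)) {
    cpath <- sprintf("$.conditions[%d]", ci)
    cond <- conditions[[ci]]
    cfg_get(cond, "name", cpath)
    sels <- cfg_get(cond, "selections", cpath)
    if (length(sels) == 0L) cfg_stop(paste0(cpath, ".selections"), "empty")
    times0 <- NULL
    for (si in seq_along(sels)) {
      spath <- sprintf("%s.selections[%d]", cpath, si)
      sel <- sels[[si]]
      cfg_get(sel, "name", spath)
      times <- unlist(cfg_get(sel, "timepoints", spath))
      if (length(times) < 2L) {
        cfg_stop(paste0(spath, ".timepoints"),
                 "every selection needs at least two timepoints")
      }
      if (is.null(times0)) {
        times0 <- times
      } else if (!isTRUE(all.equal(times, times0))) {
        cfg_stop(paste0(spath, ".timepoints"),
                 "replicate selections within a condition must share a schedule")
      }
      has_counts <- !is.null(sel$counts_file)
      has_libs <- !is.null(sel$libraries)
      if (!has_counts && !has_libs) {
        cfg_stop(spath, "needs either 'counts_file' or 'libraries'")
      }
      if (has_libs) {
        if (length(sel$libraries) != length(times)) {
          cfg_stop(paste0(spath, ".libraries"),
                   "one library per timepoint required")
        }
        for (li in seq_along(sel$libraries)) {
          cfg_get(sel$libraries[[li]], "fastq",
                  sprintf("%s.libraries[%d]", spath, li))
        }
      }
    }
  }
  invisible(config)
}

load_selection_counts <- function(sel, config, log) {
  times <- unlist(sel$timepoints)
  if (!is.null(sel$counts_file)) {
    if (!file.exists(sel$counts_file)) {
      stop("input error: counts file not found: ", sel$counts_file)
    }
    if (file.exists(paste0(sel$counts_file, ".json"))) {
      return(read_counts_tsv(sel$counts_file))
    }
    df <- utils::read.table(sel$counts_file, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    return(variant_count_table(df, times = times))
  }
  ref_cfg <- config$reference
  ref <- if (!is.null(ref_cfg)) {
    reference_sequence(ref_cfg$sequence,
                       is_coding = isTRUE(ref_cfg$is_coding),
                       frame_offset = ref_cfg$frame_offset %||% 0L,
                       position_offset = ref_cfg$position_offset %||% 0L)
  }
  min_q <- config$min_quality %||% 20L
  count_list <- lapply(seq_along(sel$libraries), function(li) {
    lib <- sel$libraries[[li]]
    if (!file.exists(lib$fastq)) {
      stop("input error: FASTQ not found: ", lib$fastq)
    }
    reads <- read_fastq(lib$fastq)
    bc <- if (!is.null(lib$barcode_map)) read_barcode_map(lib$barcode_map)
    counts <- count_reads(reads, ref = ref, barcode_map = bc,
                          min_quality = min_q)
    log(sprintf("  t=%s: %d reads, %d counted, %d rejected",
                times[li], attr(counts, "tallies")["total"],
                attr(counts, "tallies")["counted"],
                attr(counts, "tallies")["total"] -
                  attr(counts, "tallies")["counted"]))
    counts
  })
  variants <- unique(unlist(lapply(count_list, `[[`, "variant")))
  m <- matrix(0, nrow = length(variants), ncol = length(times),
              dimnames = list(variants, paste0("t", times)))
  for (li in seq_along(count_list)) {
    m[count_list[[li]]$variant, li] <- count_list[[li]]$count
  }
  variant_count_table(m, times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment
#'
#' Executes the full pipeline for every condition: load or count reads into
#' per-replicate count tables, score each selection, combine replicates with
#' the random-effects model, attach BH-adjusted p-values, and (when a
#' retention fraction is configured) write the standard-error-filtered variant
#' set. All tables are persisted as TSV under `output_dir` together with a
#' config echo and a log; reruns on the same inputs are byte-identical.
#'
#' @param config A config list or path to a JSON file (see
#'   [validate_config()]).
#' @param output_dir Output directory (created if needed).
#' @return Named list (per condition) with elements `tables`, `scores`
#'   (per-replicate data frames), and `combined`.
#' @export
run_experiment <- function(config, output_dir) {
  config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(msg, log_con)
  log(paste("experiment:", config$name))
  normalization <- config$normalization %||% "wildtype"
  results <- list()
  for (cond in config$conditions) {
    log(paste("condition:", cond$name))
    cdir <- file.path(output_dir, cond$name)
    dir.create(cdir, showWarnings = FALSE)
    tables <- lapply(cond$selections, function(sel) {
      log(paste(" selection:", sel$name))
      load_selection_counts(sel, config, log)
    })
    names(tables) <- vapply(cond$selections, `[[`, "", "name")
    if (length(tables) >= 2L) {
      res <- score_replicates(tables, normalization = normalization)
      combined <- res$combined
    } else {
      res <- list(replicates = list(score_selection(tables[[1]],
                                                    normalization)))
      combined <- NULL
    }
    for (si in seq_along(res$replicates)) {
      sc <- res$replicates[[si]]
      write_scores_tsv(sc, file.path(cdir, sprintf(
        "scores_%s.tsv", names(tables)[si])))
      log(sprintf(" selection %s: %d variants scored, %d unscored",
                  names(tables)[si], sum(sc$method != "unscored"),
                  sum(sc$method == "unscored")))
    }
    if (!is.null(combined)) {
      combined$p_adj <- adjust_pvalues(combined$p)
      write_scores_tsv(combined, file.path(cdir, "combined.tsv"))
      log(sprintf(" combined: %d variants, %d unconverged",
                  sum(!is.na(combined$score)),
                  sum(!combined$converged, na.rm = TRUE)))
      retention <- config$retention_fraction
      if (!is.null(retention)) {
        scored <- combined[is.finite(combined$se), ]
        kept <- filter_variants(scored, "se", retention)
        writeLines(kept, file.path(cdir, "filtered_variants.txt"))
        log(sprintf(" retained %d of %d variants at fraction %.3g",
                    length(kept), nrow(scored), retention))
      }
    }
    results[[cond$name]] <- list(tables = tables, scores = res$replicates,
                                 combined = combined)
  }
  jsonlite::write_json(config, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results
}

# Translate the coding region of a reference into one amino acid per codon.
translate_reference <- function(ref) {
  coding <- substr(ref$sequence, ref$frame_offset + 1L, nchar(ref$sequence))
  codons <- substring(coding, seq(1, nchar(coding), 3), seq(3, nchar(coding), 3))
  vapply(codons, function(cd) Biostrings::GENETIC_CODE[[cd]], "")
}

# Extract single-amino-acid substitutions from combined score labels.
single_aa_changes <- function(scores) {
  lab <- scores$variant
  single <- !grepl(",", lab, fixed = TRUE)
  m <- regmatches(lab, regexec("\\(p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})\\)",
                               lab))
  hit <- single & lengths(m) == 4L
  if (!any(hit)) return(NULL)
  parts <- do.call(rbind, m[hit])
  data.frame(
    variant = lab[hit],
    position = as.integer(parts[, 3]),
    aa = names(AA_THREE)[match(parts[, 4], AA_THREE)],
    score = scores$score[hit],
    se = scores$se[hit],
    stringsAsFactors = FALSE
  )
}

#' Render a sequence-function map
#'
#' Draws the classic deep mutational scanning heatmap: one column per codon
#' position, one row per amino acid, with cell color diverging around 0
#' (score relative to wild-type). Cell diagonals encode the standard error,
#' scaled so the largest standard error spans the full diagonal; standard
#' errors below 2% of that maximum are not drawn. Wild-type cells are marked
#' with a circle and unmeasured cells are gray.
#'
#' When several nucleotide variants encode the same amino-acid change, the one
#' with the smallest standard error is shown.
#'
#' @param scores Combined score data frame with `variant`, `score`, `se`
#'   columns; variant labels must carry protein annotations (coding
#'   reference).
#' @param ref The coding [reference_sequence()].
#' @param file Optional output path (`.pdf` or `.svg`); written with
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if `file` is given.
#' @export
plot_sequence_function_map <- function(scores, ref, file = NULL) {
  stopifnot(inherits(ref, "reference_sequence"))
  if (!ref$is_coding) stop("sequence-function maps require a coding reference")
  changes <- single_aa_changes(scores)
  if (is.null(changes)) {
    stop("no single-amino-acid-substitution variants with protein labels found")
  }
  changes <- changes[is.finite(changes$score) & is.finite(changes$se), ]
  changes <- changes[order(changes$se), ]
  changes <- changes[!duplicated(changes[c("position", "aa")]), ]

  wt_aa <- translate_reference(ref)
  aa_levels <- rev(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*"))
  grid <- expand.grid(position = seq_along(wt_aa), aa = aa_levels,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, changes[c("position", "aa", "score", "se")],
                by = c("position", "aa"), all.x = TRUE)
  grid$aa <- factor(grid$aa, levels = aa_levels)
  grid$y <- as.integer(grid$aa)
  se_max <- max(grid$se, na.rm = TRUE)
  diag <- grid[!is.na(grid$se) & se_max > 0 & grid$se >= 0.02 * se_max, ]
  if (nrow(diag)) diag$len <- diag$se / se_max
  wt <- data.frame(position = seq_along(wt_aa),
                   y = match(wt_aa, aa_levels))

  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$position, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score), color = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey80", name = "score") +
    ggplot2::scale_y_continuous(breaks = seq_along(aa_levels),
                                labels = aa_levels, expand = c(0, 0)) +
    ggplot2::scale_x_continuous(breaks = seq_along(wt_aa), expand = c(0, 0)) +
    ggplot2::labs(x = "position", y = "amino acid") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (nrow(diag)) {
    p <- p + ggplot2::geom_segment(
      data = diag,
      ggplot2::aes(x = .data$position - .data$len / 2,
                   xend = .data$position + .data$len / 2,
                   y = .data$y - .data$len / 2,
                   yend = .data$y + .data$len / 2),
      linewidth = 0.3, color = "black"
    )
  }
  p <- p + ggplot2::geom_point(data = wt, shape = 1, size = 2)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = max(4, length(wt_aa) * 0.5), height = 6)
    return(invisible(p))
  }
  p
}
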