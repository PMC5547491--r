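# Shared fixture builders. Everything is generated in code; no data files.

# A small coding reference: ATG AAA GGC TAC (Met Lys Gly Tyr).
toy_ref <- function() reference_sequence("ATGAAAGGCTAC", is_coding = TRUE)

# Read with uniform quality.
toy_read <- function(bases, q = 30L) {
  read_record(bases, rep(q, nchar(bases)))
}

# Reverse read whose reverse complement equals `target` with per-position
# qualities `q` given in target orientation.
toy_rev_read <- function(target, q) {
  read_record(
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(target, "")[[1]]), collapse = "")),
    rev(q)
  )
}

# Count table from a plain matrix with default variant names v1, v2, ...
toy_table <- function(counts, times = seq_len(ncol(counts)) - 1,
                      wildtype = "_wt", rownames. = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- rownames. %||%
      c(wildtype, paste0("v", seq_len(nrow(counts) - 1)))
  }
  variant_count_table(counts, times = times, wildtype = wildtype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a FASTQ file (Sanger Phred+33) from bases + integer quality lists.
write_toy_fastq <- function(path, bases, quals, gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(bases)) {
    writeLines(c(paste0("@read", i), bases[i], "+",
                 intToUtf8(quals[[i]] + 33L)), con)
  }
  path
}

# Restricted (REML) negative log-likelihood of the one-random-effect model;
# independent of the package's Fisher-scoring implementation.
reml_nll <- function(s2, b, si2) {
  w <- 1 / (s2 + si2)
  bh <- sum(w * b) / sum(w)
  0.5 * (sum(log(s2 + si2)) + log(sum(w)) + sum(w * (b - bh)^2))
}

# Brute-force 1-D REML maximizer: log-spaced grid plus local refinement.
grid_reml <- function(b, si2) {
  hi <- max(stats::var(b) * 10, 1)
  grid <- c(0, exp(seq(log(1e-8), log(hi), length.out = 400)))
  nll <- vapply(grid, reml_nll, 0, b = b, si2 = si2)
  i <- which.min(nll)
  if (i == 1 && nll[1] <= nll[2]) return(0)
  stats::optimize(reml_nll, c(grid[max(i - 1, 1)], grid[min(i + 1, 400)]),
                  b = b, si2 = si2, tol = 1e-12)$minimum
}

# Small simulation config for fast unit tests (study-scale defaults are
# exercised in the acceptance tests).
small_config <- function(assay = "binding", ...) {
  simulation_config(assay, n_variants = 301L, population_size = 3e5,
                    wt_input_frequency = 0.01, reads_per_variant = 100L,
                    rounds = 3L, replicates = 3L, ...)
}
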