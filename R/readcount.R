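#' Assign a read to a scaffold by its constant arms
#'
#' A read is assigned to the scaffold whose 5' arm matches the read prefix and
#' whose 3' arm matches the read suffix, each with at most
#' `max_mismatch_per_arm` mismatches; the interior substring is the loop.
#' When several scaffolds qualify the one with fewest total arm mismatches
#' wins; a tie is ambiguous and the read stays unassigned.
#'
#' @param read nucleotide string (DNA or RNA; transliterated to RNA).
#' @param design a [pool_design()] object.
#' @param max_mismatch_per_arm mismatch tolerance per arm (default 1).
#' @return a list with `scaffold` (name or `NA`), `loop` (string or `NA`),
#'   `loop_length` and `arm_mismatches`.
#' @export
assign_read <- function(read, design, max_mismatch_per_arm = 1L) {
  tab <- count_read_batch(read, design, max_mismatch_per_arm)
  list(scaffold = tab$scaffold[1], loop = tab$loop[1],
       loop_length = tab$loop_length[1], arm_mismatches = tab$mismatches[1])
}

# Vectorized core: classify a character vector of reads against every
# scaffold. Returns a data.frame with one row per read.
count_read_batch <- function(reads, design, max_mismatch_per_arm = 1L) {
  reads <- chartr("t", "u", chartr("T", "U", toupper(reads)))
  n <- length(reads)
  rl <- nchar(reads)
  best_mm <- rep(Inf, n)
  second_mm <- rep(Inf, n)
  best_sc <- rep(NA_character_, n)
  best_loop <- rep(NA_character_, n)
  for (s in design$scaffolds) {
    n5 <- nchar(s$arm5); n3 <- nchar(s$arm3)
    ok_len <- rl >= n5 + n3
    mm <- rep(Inf, n)
    if (any(ok_len)) {
      pre <- substr(reads, 1L, n5)
      suf <- substring(reads, rl - n3 + 1L)
      mm5 <- arm_mismatches(pre[ok_len], s$arm5)
      mm3 <- arm_mismatches(suf[ok_len], s$arm3)
      pass <- mm5 <= max_mismatch_per_arm & mm3 <= max_mismatch_per_arm
      mm_ok <- ifelse(pass, mm5 + mm3, Inf)
      mm[ok_len] <- mm_ok
    }
    better <- mm < best_mm
    tied <- mm == best_mm & is.finite(mm)
    second_mm[tied] <- mm[tied]
    second_mm[better] <- best_mm[better]
    best_mm[better] <- mm[better]
    best_sc[better] <- s$name
    if (any(better)) {
      idx <- which(better)
      n5 <- nchar(s$arm5); n3 <- nchar(s$arm3)
      best_loop[idx] <- substr(reads[idx], n5 + 1L, rl[idx] - n3)
    }
  }
  ambiguous <- is.finite(best_mm) & second_mm == best_mm
  assigned <- is.finite(best_mm) & !ambiguous
  data.frame(
    scaffold = ifelse(assigned, best_sc, NA_character_),
    loop = ifelse(assigned, best_loop, NA_character_),
    loop_length = ifelse(assigned, nchar(best_loop), NA_integer_),
    mismatches = ifelse(assigned, best_mm, NA_real_),
    stringsAsFactors = FALSE)
}

# Hamming mismatches between equal-length strings and a fixed arm,
# vectorized position by position (arms are short).
arm_mismatches <- function(strings, arm) {
  k <- nchar(arm)
  mm <- integer(length(strings))
  for (i in seq_len(k)) {
    mm <- mm + (substr(strings, i, i) != substr(arm, i, i))
  }
  mm
}

#' Count reads per (scaffold, loop) from a FASTQ file
#'
#' Streams a FASTQ file (plain or gzipped), assigns every read via the
#' constant arms, length-classifies the loop against the design, and tallies
#' counts. Reads whose loop length is not in the design are recorded under
#' the `invalid_loop_length` QC total; unassignable reads under `unassigned`.
#' Counting is order-independent and each read contributes at most one count.
#'
#' @param fastq path to a FASTQ file, or a character vector of read sequences.
#' @param design a [pool_design()] object.
#' @param condition condition label, e.g. `"input"` or a protein
#'   concentration in nM such as `"500"`.
#' @param max_mismatch_per_arm mismatch tolerance per arm (default 1).
#' @return an object of class `count_table`: a data.frame with columns
#'   `condition`, `scaffold`, `loop`, `count`, carrying a `qc` attribute with
#'   totals `reads`, `assigned`, `unassigned`, `invalid_loop_length`.
#' @export
count_reads <- function(fastq, design, condition = "input",
                        max_mismatch_per_arm = 1L) {
  stopifnot(inherits(design, "pool_design"))
  if (length(fastq) == 1L && file.exists(fastq)) {
    reads <- read_fastq_sequences(fastq)
  } else {
    reads <- as.character(fastq)
  }
  n_total <- length(reads)
  if (n_total == 0L) {
    return(new_count_table(
      data.frame(condition = character(0), scaffold = character(0),
                 loop = character(0), count = integer(0),
                 stringsAsFactors = FALSE),
      qc = c(reads = 0L, assigned = 0L, unassigned = 0L,
             invalid_loop_length = 0L)))
  }
  tab <- count_read_batch(reads, design, max_mismatch_per_arm)
  valid_len <- !is.na(tab$loop_length) & tab$loop_length %in% design$loop_lengths
  assigned <- !is.na(tab$scaffold)
  keep <- assigned & valid_len
  if (any(keep)) {
    counts <- as.data.frame(
      table(scaffold = tab$scaffold[keep], loop = tab$loop[keep]),
      stringsAsFactors = FALSE)
    counts <- counts[counts$Freq > 0L, , drop = FALSE]
    counts <- counts[order(counts$scaffold, counts$loop), , drop = FALSE]
    out <- data.frame(condition = condition, scaffold = counts$scaffold,
                      loop = counts$loop, count = as.integer(counts$Freq),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(condition = character(0), scaffold = character(0),
                      loop = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  }
  new_count_table(out, qc = c(
    reads = n_total,
    assigned = sum(keep),
    unassigned = sum(!assigned),
    invalid_loop_length = sum(assigned & !valid_len)))
}

new_count_table <- function(df, qc) {
  rownames(df) <- NULL
  structure(df, qc = qc, class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("sRBNS count table [%s]: %d (scaffold, loop) entries\n",
              paste(unique(x$condition), collapse = ","), nrow(x)))
  cat(sprintf("  reads %d | assigned %d | unassigned %d | invalid loop length %d\n",
              qc[["reads"]], qc[["assigned"]], qc[["unassigned"]],
              qc[["invalid_loop_length"]]))
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  print(utils::head(df, 10L))
  if (nrow(df) > 10L) cat(sprintf("  ... %d more rows\n", nrow(df) - 10L))
  invisible(x)
}

# FASTQ sequences via Biostrings; on a parse failure, locate the offending
# record with a line-level structural scan so the error names its index.
read_fastq_sequences <- function(path) {
  res <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) e)
  if (!inherits(res, "error")) return(unname(res))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- ceiling(length(lines) / 4)
  for (r in seq_len(n_rec)) {
    chunk <- lines[(4 * (r - 1) + 1):min(4 * r, length(lines))]
    if (length(chunk) < 4 || !startsWith(chunk[1], "@") ||
        !startsWith(chunk[3], "+") || nchar(chunk[2]) != nchar(chunk[4])) {
      stop(sprintf("malformed FASTQ record %d in '%s'", r, path), call. = FALSE)
    }
  }
  stop(sprintf("failed to parse FASTQ '%s': %s", path, conditionMessage(res)),
       call. = FALSE)
}

#' Write a count table (and its QC totals) as TSV
#'
#' @param x a `count_table`.
#' @param path output TSV path.
#' @param qc_path optional path for the QC totals TSV.
#' @return invisibly, `x`.
#' @export
write_count_table <- function(x, path, qc_path = NULL) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(qc_path)) {
    qc <- attr(x, "qc")
    write.table(data.frame(metric = names(qc), value = as.integer(qc)),
                qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path with columns condition, scaffold, loop, count.
#' @return a `count_table` (QC totals reconstructed from the counts alone).
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "character",
                                  "integer"))
  n <- sum(df$count)
  new_count_table(df, qc = c(reads = n, assigned = n, unassigned = 0L,
                             invalid_loop_length = 0L))
}
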