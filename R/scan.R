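#' Default Roquin loop motif patterns
#'
#' The six enriched ADE-variant hexaloop consensus patterns plus the CDE
#' triloop consensus YRU, as IUPAC strings with labels.
#'
#' @return data.frame with columns `label`, `iupac`.
#' @export
#' @examples
#' roquin_motifs()
roquin_motifs <- function() {
  data.frame(
    label = c("ADE-GUURUA", "ADE-GUUYMA", "ADE-GUUYUG",
              "ADE-AUUYUA", "ADE-AUUYUC", "ADE-AUUYUG", "CDE"),
    iupac = c("GUURUA", "GUUYMA", "GUUYUG",
              "AUUYUA", "AUUYUC", "AUUYUG", "YRU"),
    stringsAsFactors = FALSE)
}

IUPAC_RNA <- local({
  m <- Biostrings::IUPAC_CODE_MAP          # DNA-keyed: translate both sides
  m <- setNames(chartr("T", "U", m), chartr("T", "U", names(m)))
  lapply(m, function(x) strsplit(x, "", fixed = TRUE)[[1]])
})

#' Expand an IUPAC pattern into concrete RNA strings
#'
#' Cartesian expansion over each degenerate position; e.g. `"GUURUA"` expands
#' to GUUAUA and GUUGUA, and the CDE consensus `"YRU"` to its four triloops.
#'
#' @param pattern IUPAC string over A,C,G,U,R,Y,M,K,S,W,B,D,H,V,N (T allowed,
#'   transliterated).
#' @return character vector of concrete RNA strings.
#' @export
#' @examples
#' expand_iupac("YRU")
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(chartr("T", "U", toupper(pattern)), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_RNA))
  if (length(bad)) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ""),
         call. = FALSE)
  }
  sets <- IUPAC_RNA[chars]
  g <- do.call(expand.grid,
               c(unname(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  sort(do.call(paste0, g))
}

#' Find motif-capped stem-loop candidates in one sequence
#'
#' Slides each pattern over the sequence; every position where the loop
#' window matches the pattern and the flanking contiguous stem
#' ([stem_length_at()]) reaches `min_stem` base pairs yields one candidate.
#' Overlapping matches of different patterns are all reported. Scanning is on
#' the given (sense) strand only.
#'
#' @param seq RNA (or DNA) string.
#' @param patterns data.frame with columns `label`, `iupac`
#'   (default [roquin_motifs()]).
#' @param min_stem minimum contiguous closing stem length (default 6).
#' @param allow_wobble count G-U pairs in the stem (default FALSE).
#' @param seq_id identifier recorded in the output.
#' @return data.frame with columns `seq_id`, `loop_start`, `loop_end`
#'   (0-based half-open), `pattern`, `loop`, `stem_len`.
#' @export
find_candidates <- function(seq, patterns = roquin_motifs(), min_stem = 6L,
                            allow_wobble = FALSE, seq_id = "seq") {
  stopifnot(min_stem >= 1L)
  seq <- as_rna(seq)
  n <- nchar(seq)
  out <- list()
  for (r in seq_len(nrow(patterns))) {
    pat <- patterns$iupac[r]
    k <- nchar(pat)
    if (n < k + 2L * min_stem) next
    concrete <- expand_iupac(pat)
    # candidate loop windows must leave room for min_stem on both sides
    starts <- seq.int(min_stem + 1L, n - k - min_stem + 1L)
    windows <- substring(seq, starts, starts + k - 1L)
    hit <- which(windows %in% concrete)
    for (h in hit) {
      s0 <- starts[h] - 1L                       # 0-based loop start
      sl <- stem_length_at(seq, s0, s0 + k, allow_wobble)
      if (sl >= min_stem) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = seq_id, loop_start = s0, loop_end = s0 + k,
          pattern = patterns$label[r], loop = windows[h], stem_len = sl,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), loop_start = integer(0),
                      loop_end = integer(0), pattern = character(0),
                      loop = character(0), stem_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$loop_start, res$pattern), , drop = FALSE]
}

#' Predict CDE/ADE-like stem-loop elements in 3'-UTR sequences
#'
#' Runs [find_candidates()] on every FASTA record, annotates each candidate
#' with its hairpin folding probability ([hairpin_probability()] within a
#' local window around the stem-loop), and classifies it: `excluded` when
#' p_fold < `exclude_below` (default 5%), `high_confidence` when p_fold >=
#' `high_conf` (default 19%), `reported` otherwise.
#'
#' @param fasta path to a FASTA file of UTR sequences, or a named character
#'   vector of sequences.
#' @param patterns data.frame of motif patterns (default [roquin_motifs()]).
#' @param min_stem minimum contiguous stem length (default 6).
#' @param exclude_below,high_conf folding-probability thresholds.
#' @param model an [energy_model()].
#' @param allow_wobble count G-U stem pairs (default FALSE).
#' @param fold_flank nucleotides of sequence context beyond the stem included
#'   in the folding window on each side (default 20).
#' @return an object of class `srbns_scan`: a data.frame with candidate
#'   coordinates, `stem_len`, `p_fold` and `status`, plus a `per_sequence`
#'   attribute with reported-element counts per record.
#' @export
predict_elements <- function(fasta, patterns = roquin_motifs(), min_stem = 6L,
                             exclude_below = 0.05, high_conf = 0.19,
                             model = energy_model(), allow_wobble = FALSE,
                             fold_flank = 20L) {
  seqs <- load_utrs(fasta)
  res <- list()
  for (id in names(seqs)) {
    cand <- tryCatch(
      find_candidates(seqs[[id]], patterns, min_stem, allow_wobble, seq_id = id),
      error = function(e) {
        warning(sprintf("skipping record '%s': %s", id, conditionMessage(e)))
        NULL
      })
    if (is.null(cand) || nrow(cand) == 0L) next
    cand$p_fold <- vapply(seq_len(nrow(cand)), function(i) {
      windowed_p_fold(seqs[[id]], cand$loop_start[i], cand$loop_end[i],
                      cand$stem_len[i], model, fold_flank)
    }, numeric(1))
    res[[id]] <- cand
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(seq_id = character(0), loop_start = integer(0),
               loop_end = integer(0), pattern = character(0),
               loop = character(0), stem_len = integer(0),
               p_fold = numeric(0), stringsAsFactors = FALSE)
  out$status <- ifelse(out$p_fold < exclude_below, "excluded",
                       ifelse(out$p_fold >= high_conf, "high_confidence",
                              "reported"))
  rownames(out) <- NULL
  kept <- out[out$status != "excluded", , drop = FALSE]
  per_seq <- if (nrow(kept)) table(kept$seq_id) else table(character(0))
  structure(out,
            per_sequence = as.data.frame(per_seq,
                                         stringsAsFactors = FALSE),
            thresholds = c(exclude_below = exclude_below,
                           high_conf = high_conf, min_stem = min_stem),
            class = c("srbns_scan", "data.frame"))
}

# Fold within a window of the candidate hairpin: full hairpin plus
# `fold_flank` nt of context on each side. Keeps the interval DP cheap on
# long UTRs while retaining local competing structure.
windowed_p_fold <- function(seq, loop_start, loop_end, stem_len, model,
                            fold_flank) {
  n <- nchar(seq)
  a <- max(0L, loop_start - stem_len - fold_flank)
  b <- min(n, loop_end + stem_len + fold_flank)
  hairpin_probability(substr(seq, a + 1L, b),
                      loop_start - a, loop_end - a, stem_len, model)
}

load_utrs <- function(fasta) {
  if (length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readBStringSet(fasta)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- setNames(as.character(fasta), names(fasta))
    if (is.null(names(seqs)) && length(seqs)) {
      names(seqs) <- paste0("seq", seq_along(seqs))
    }
  }
  ok <- !grepl("[^ACGTUacgtu]", seqs)
  for (bad_id in names(seqs)[!ok]) {
    warning(sprintf("record '%s' contains non-nucleotide characters; skipped",
                    bad_id))
  }
  lapply(seqs[ok], as_rna)
}

#' @export
print.srbns_scan <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "stem-loop scan: %d candidate(s); %d high-confidence (p_fold >= %g), %d reported, %d excluded (< %g)\n",
    nrow(x), sum(x$status == "high_confidence"), th[["high_conf"]],
    sum(x$status == "reported"), sum(x$status == "excluded"),
    th[["exclude_below"]]))
  print(as.data.frame(unclass(x), stringsAsFactors = FALSE))
  invisible(x)
}

#' Write scan results as TSV and BED6
#'
#' BED uses 0-based half-open loop coordinates, name `pattern|loop` and
#' score `round(1000 * p_fold)`.
#'
#' @param x an `srbns_scan` object.
#' @param tsv,bed output paths (either may be NULL).
#' @param include_excluded write excluded candidates too (default FALSE).
#' @return invisibly, `x`.
#' @export
write_scan <- function(x, tsv = NULL, bed = NULL, include_excluded = FALSE) {
  df <- as.data.frame(x)
  if (!include_excluded) df <- df[df$status != "excluded", , drop = FALSE]
  if (!is.null(tsv)) {
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = df$seq_id, start = df$loop_start,
                         end = df$loop_end,
                         name = paste(df$pattern, df$loop, sep = "|"),
                         score = round(1000 * df$p_fold), strand = "+")
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(x)
}
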