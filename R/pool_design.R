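RNA_BASES <- c("A", "C", "G", "U")

#' Convert a nucleotide string to RNA
#'
#' Uppercases and transliterates T to U. Library designs are often written as
#' DNA oligos; all internal representations are RNA.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over \{A,C,G,U\}.
#' @keywords internal
as_rna <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence: ",
         paste(unique(gsub("[ACGU]", "", x[bad])), collapse = ""),
         call. = FALSE)
  }
  x
}

#' Define a stem-loop scaffold
#'
#' A scaffold is the constant part of an sRBNS library member: a 5' arm
#' (ending in the 5' strand of the stem) and a 3' arm (starting with the 3'
#' strand of the stem). The randomized loop is inserted between them. The
#' closing base pair of the loop is the last base of `arm5` paired with the
#' first base of `arm3`; its orientation (purine-pyrimidine vs
#' pyrimidine-purine) is part of what stem-loop readers such as the Roquin
#' ROQ domain discriminate.
#'
#' @param name short scaffold identifier, e.g. `"UCP3"` or `"TNF"`.
#' @param arm5,arm3 constant arms as RNA (or DNA, transliterated) strings.
#' @param min_stem number of terminal arm positions required to be mutually
#'   complementary (Watson-Crick or wobble); the documented stem length.
#' @return an object of class `scaffold_spec`.
#' @export
#' @examples
#' scaffold_spec("toy", "GGCGGCG", "CGCCGCC")
scaffold_spec <- function(name, arm5, arm3, min_stem = 6L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  arm5 <- as_rna(arm5)
  arm3 <- as_rna(arm3)
  if (!nzchar(arm5) || !nzchar(arm3)) {
    stop("scaffold arms must be nonempty", call. = FALSE)
  }
  n_check <- min(min_stem, nchar(arm5), nchar(arm3))
  for (i in seq_len(n_check)) {
    b5 <- substr(arm5, nchar(arm5) - i + 1L, nchar(arm5) - i + 1L)
    b3 <- substr(arm3, i, i)
    if (!is_pair(b5, b3, allow_wobble = TRUE)) {
      stop(sprintf(
        "scaffold '%s': arm positions %d from the loop (%s/%s) do not pair; %s",
        name, i, b5, b3, "declared stem is not complementary"), call. = FALSE)
    }
  }
  structure(
    list(name = name, arm5 = arm5, arm3 = arm3,
         closing_pair = paste0(substr(arm5, nchar(arm5), nchar(arm5)),
                               substr(arm3, 1L, 1L))),
    class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("scaffold '%s': 5'-%s-[loop]-%s-3' (closing pair %s-%s)\n",
              x$name, x$arm5, x$arm3,
              substr(x$closing_pair, 1, 1), substr(x$closing_pair, 2, 2)))
  invisible(x)
}

#' Define a structured RNA pool
#'
#' Combines stem-loop scaffolds with a set of randomized loop lengths. The
#' pool contains every loop variant of every length on every scaffold; the
#' per-length pool size is 4^k, so the total number of distinct loop variants
#' is `sum(4^loop_lengths)` (e.g. 64 for a trinucleotide pool, 1344 for a
#' mixed N3/N4/N5 pool, 4096 for a hexanucleotide pool).
#'
#' @param scaffolds a list of [scaffold_spec()] objects (a single scaffold is
#'   also accepted).
#' @param loop_lengths integer vector of randomized window sizes (k >= 1).
#' @return an object of class `pool_design` with elements `scaffolds`,
#'   `loop_lengths` and `pool_size`.
#' @export
#' @examples
#' d <- pool_design(scaffold_spec("toy", "GGCGGCG", "CGCCGCC"), c(3, 4, 5))
#' d$pool_size  # 1344
pool_design <- function(scaffolds, loop_lengths) {
  if (inherits(scaffolds, "scaffold_spec")) scaffolds <- list(scaffolds)
  stopifnot(length(scaffolds) >= 1L,
            all(vapply(scaffolds, inherits, logical(1), "scaffold_spec")))
  nms <- vapply(scaffolds, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate scaffold names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  loop_lengths <- sort(unique(as.integer(loop_lengths)))
  if (length(loop_lengths) == 0L || anyNA(loop_lengths) || any(loop_lengths < 1L)) {
    stop("loop_lengths must be a nonempty set of integers >= 1", call. = FALSE)
  }
  names(scaffolds) <- nms
  structure(
    list(scaffolds = scaffolds, loop_lengths = loop_lengths,
         pool_size = sum(4^loop_lengths)),
    class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("sRBNS pool design: %d scaffold(s) x loop length(s) {%s}\n",
              length(x$scaffolds), paste(x$loop_lengths, collapse = ",")))
  cat(sprintf("  pool size n = %d loop variants (%d member sequences)\n",
              x$pool_size, x$pool_size * length(x$scaffolds)))
  for (s in x$scaffolds) print(s)
  invisible(x)
}

#' Enumerate all loop variants of a given length
#'
#' Returns the 4^k loop sequences of length `k` in lexicographic order over
#' A < C < G < U, so that output ordering is reproducible across runs.
#'
#' @param k loop length in nucleotides (k >= 0; k = 0 yields the empty loop).
#' @return character vector of 4^k distinct RNA strings.
#' @export
#' @examples
#' length(enumerate_loop_variants(3))  # 64
enumerate_loop_variants <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L) {
    stop("loop length k must be a single integer >= 0", call. = FALSE)
  }
  if (k == 0L) return("")
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  g <- do.call(expand.grid,
               c(rep(list(RNA_BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  do.call(paste0, rev(g))
}

#' Equal-abundance mixing ratios for multi-length pools
#'
#' When pools of different loop lengths are combined, the larger pools must be
#' mixed in with a corresponding excess so that every individual loop variant
#' has the same expected abundance: the mass fraction of length k is
#' proportional to its variant count 4^k.
#'
#' @param loop_lengths nonempty integer vector of loop lengths.
#' @return named numeric vector of mass fractions, summing to 1.
#' @export
#' @examples
#' mixing_ratios(c(3, 4, 5))  # 1/21, 4/21, 16/21
mixing_ratios <- function(loop_lengths) {
  loop_lengths <- sort(unique(as.integer(loop_lengths)))
  if (length(loop_lengths) == 0L || anyNA(loop_lengths)) {
    stop("loop_lengths must be a nonempty set of integers", call. = FALSE)
  }
  w <- 4^loop_lengths
  setNames(w / sum(w), loop_lengths)
}

#' Materialize a pool design as member sequences
#'
#' Enumerates every (scaffold, loop) combination of the design. Expected
#' fractions implement [mixing_ratios()] across loop lengths and uniform mass
#' across scaffolds, so every individual member has the same expected
#' abundance.
#'
#' @param design a [pool_design()] object.
#' @return a data.frame with columns `scaffold`, `loop`, `loop_length`,
#'   `sequence` (arm5 + loop + arm3) and `expected_fraction` (sums to 1).
#' @export
build_pool <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  n_sc <- length(design$scaffolds)
  frac_k <- mixing_ratios(design$loop_lengths)
  per_len <- lapply(design$loop_lengths, function(k) {
    loops <- enumerate_loop_variants(k)
    data.frame(loop = loops, loop_length = k,
               expected_fraction = frac_k[[as.character(k)]] / length(loops),
               stringsAsFactors = FALSE)
  })
  loops <- do.call(rbind, per_len)
  out <- do.call(rbind, lapply(design$scaffolds, function(s) {
    data.frame(scaffold = s$name, loop = loops$loop,
               loop_length = loops$loop_length,
               sequence = paste0(s$arm5, loops$loop, s$arm3),
               expected_fraction = loops$expected_fraction / n_sc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a pool design from a YAML configuration file
#'
#' The file holds a `loop_lengths` sequence and a `scaffolds` list of
#' `{name, arm5, arm3}` entries (DNA is accepted and transliterated). An
#' optional per-scaffold `min_stem` overrides the declared stem length checked
#' at construction.
#'
#' @param path path to the YAML file.
#' @return a [pool_design()] object.
#' @export
read_pool_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scaffolds) || is.null(cfg$loop_lengths)) {
    stop("design config must contain 'scaffolds' and 'loop_lengths'",
         call. = FALSE)
  }
  scaffolds <- lapply(cfg$scaffolds, function(s) {
    scaffold_spec(s$name, s$arm5, s$arm3,
                  min_stem = if (is.null(s$min_stem)) 6L else as.integer(s$min_stem))
  })
  pool_design(scaffolds, unlist(cfg$loop_lengths))
}

#' Write the enumerated pool as FASTA plus a TSV manifest
#'
#' FASTA record ids are `scaffold|loop`; the manifest lists scaffold, loop,
#' loop length and expected fraction for every member.
#'
#' @param design a [pool_design()] object.
#' @param fasta,manifest output paths (either may be `NULL` to skip).
#' @return (invisibly) the [build_pool()] data.frame that was written.
#' @export
write_pool <- function(design, fasta = NULL, manifest = NULL) {
  pool <- build_pool(design)
  if (!is.null(fasta)) {
    seqs <- Biostrings::RNAStringSet(pool$sequence)
    names(seqs) <- paste(pool$scaffold, pool$loop, sep = "|")
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(manifest)) {
    write.table(pool[, c("scaffold", "loop", "loop_length", "expected_fraction")],
                manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(pool)
}
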