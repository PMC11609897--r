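#' Equilibrium binding model for read simulation
#'
#' Per-variant dissociation constants plus experiment-level parameters. Loop
#' variants without an explicit K_D receive `default_kd` (a nonbinder, e.g.
#' 5000 nM). Capture of a pool member in the pulldown is modeled as specific
#' occupancy theta = [P]/([P] + K_D) (protein in excess over RNA, single
#' site) plus a uniform nonspecific background.
#'
#' @param kd named numeric vector of dissociation constants in nM; names are
#'   `"scaffold|loop"` keys or bare loop strings (applied to all scaffolds).
#' @param default_kd K_D assigned to unlisted variants (nM).
#' @param protein_concs protein concentrations in nM (defaults 10, 50, 500).
#' @param background nonspecific capture probability in [0, 1).
#' @param depth reads per simulated library.
#' @return an object of class `binding_model`.
#' @export
#' @examples
#' binding_model(c(UAU = 30, UGU = 40), default_kd = 5000)
binding_model <- function(kd = numeric(0), default_kd = 5000,
                          protein_concs = c(10, 50, 500),
                          background = 0.002, depth = 1e5) {
  stopifnot(all(kd > 0), default_kd > 0,
            background >= 0, background < 1, depth >= 1)
  structure(list(kd = kd, default_kd = default_kd,
                 protein_concs = protein_concs,
                 background = background, depth = as.integer(depth)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf(
    "binding model: %d explicit K_D value(s), default %g nM; [P] = {%s} nM\n",
    length(x$kd), x$default_kd, paste(x$protein_concs, collapse = ", ")))
  cat(sprintf("  background %.4g, depth %d reads/library\n",
              x$background, x$depth))
  invisible(x)
}

#' Single-site equilibrium occupancy
#'
#' Fraction of RNA bound at equilibrium with protein in excess:
#' theta = [P] / ([P] + K_D). Strictly increasing in protein concentration,
#' strictly decreasing in K_D; 0 without protein and approaching 1 at
#' saturation.
#'
#' @param kd dissociation constant in nM (> 0).
#' @param protein free protein concentration in nM (>= 0).
#' @return occupancy in [0, 1).
#' @export
#' @examples
#' fraction_bound(50, 50)  # 0.5 at [P] = K_D
fraction_bound <- function(kd, protein) {
  if (any(kd <= 0)) stop("kd must be positive", call. = FALSE)
  if (any(protein < 0)) stop("protein concentration must be >= 0", call. = FALSE)
  protein / (protein + kd)
}

# Resolve the K_D of every pool member against the model's kd map.
member_kd <- function(pool, model) {
  kd <- rep(model$default_kd, nrow(pool))
  keys <- paste(pool$scaffold, pool$loop, sep = "|")
  hit <- match(keys, names(model$kd))
  kd[!is.na(hit)] <- model$kd[hit[!is.na(hit)]]
  bare <- match(pool$loop, names(model$kd))
  use_bare <- is.na(hit) & !is.na(bare)
  kd[use_bare] <- model$kd[bare[use_bare]]
  kd
}

#' Simulate an sRBNS experiment
#'
#' Draws an input library multinomially from the design's expected member
#' abundances ([mixing_ratios()] across loop lengths, uniform across
#' scaffolds), and one pulldown library per protein concentration with
#' member capture probability proportional to
#' `abundance * (theta * (1 - background) + background)`, where theta is the
#' equilibrium occupancy [fraction_bound()]. Reads are the full member
#' sequence (arm5 + loop + arm3) written as DNA with a constant quality
#' string; an optional per-base substitution error exercises the mismatch
#' tolerance of the counting stage. Identical model + seed gives
#' byte-identical FASTQ output.
#'
#' @param design a [pool_design()] object.
#' @param model a [binding_model()].
#' @param dir output directory for FASTQ files (created if needed); when
#'   `NULL`, no files are written and read vectors are returned instead.
#' @param seed integer RNG seed.
#' @param error_rate per-base substitution probability (default 0).
#' @param gzip write gzipped FASTQ (default FALSE).
#' @return a list with `input` and one element per concentration (named by
#'   its nM value): file paths when `dir` is given, otherwise character
#'   vectors of read sequences. Also carries the per-member expected pulldown
#'   frequencies as attribute `expected`.
#' @export
simulate_srbns <- function(design, model, dir = NULL, seed = 1L,
                           error_rate = 0, gzip = FALSE) {
  stopifnot(inherits(design, "pool_design"), inherits(model, "binding_model"))
  if (model$depth < 1L) stop("depth must be >= 1", call. = FALSE)
  pool <- build_pool(design)
  kd <- member_kd(pool, model)
  set.seed(seed)
  abund <- pool$expected_fraction
  out <- list()
  expected <- list()
  draw <- function(prob) {
    counts <- as.integer(rmultinom(1, model$depth, prob))
    rep(seq_len(nrow(pool)), counts)
  }
  emit <- function(members, label) {
    seqs <- pool$sequence[members]
    if (error_rate > 0) seqs <- mutate_reads(seqs, error_rate)
    if (is.null(dir)) return(seqs)
    path <- file.path(dir, paste0(label, ".fastq", if (gzip) ".gz" else ""))
    write_fastq(seqs, path, prefix = label, gzip = gzip)
    path
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out$input <- emit(draw(abund), "input")
  expected$input <- abund
  for (p in model$protein_concs) {
    theta <- fraction_bound(kd, p)
    capture <- abund * (theta * (1 - model$background) + model$background)
    prob <- capture / sum(capture)
    lab <- paste0("pulldown_", p, "nM")
    out[[as.character(p)]] <- emit(draw(prob), lab)
    expected[[as.character(p)]] <- prob
  }
  attr(out, "expected") <- expected
  attr(out, "pool") <- pool
  out
}

mutate_reads <- function(seqs, error_rate) {
  chars <- strsplit(chartr("U", "T", seqs), "", fixed = TRUE)
  dna <- c("A", "C", "G", "T")
  mutated <- lapply(chars, function(v) {
    hit <- runif(length(v)) < error_rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(dna, b), 1L),
                       character(1))
    }
    paste(v, collapse = "")
  })
  unlist(mutated)
}

write_fastq <- function(seqs, path, prefix = "read", gzip = FALSE) {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  names(dna) <- paste0(prefix, "_", seq_along(dna))
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = gzip)
  invisible(path)
}

#' Read a K_D table from TSV
#'
#' Columns `scaffold` (optional; empty or `*` applies the K_D to every
#' scaffold), `loop`, `kd_nM`.
#'
#' @param path TSV path.
#' @return named numeric vector suitable for [binding_model()].
#' @export
read_kd_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("loop", "kd_nM") %in% names(df))) {
    stop("kd table needs columns 'loop' and 'kd_nM'", call. = FALSE)
  }
  loop <- as_rna(df$loop)
  keys <- if ("scaffold" %in% names(df)) {
    ifelse(is.na(df$scaffold) | df$scaffold %in% c("", "*"),
           loop, paste(df$scaffold, loop, sep = "|"))
  } else loop
  setNames(df$kd_nM, keys)
}
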