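#' sRBNS enrichment analysis: E-values, z-scores and significance
#'
#' For every designed loop variant, computes its frequency in the input and
#' pulldown libraries and the enrichment E = f_pulldown / f_input, then
#' standardizes the E-values within each scope (per scaffold, and pooled
#' across scaffolds as scope `COMBINED`) to z-scores. A variant is called
#' significantly enriched when its E-value lies more than three sample
#' standard deviations above the scope mean (z > 3). Pentanucleotide loops
#' whose outer bases can form a Watson-Crick pair are annotated with their
#' effective (collapsed) loop.
#'
#' A pseudocount (default 0.5) is added to every designed variant's count in
#' both conditions before normalization so that dropout variants have a
#' defined E; set `pseudocount = 0` for raw ratios, in which case variants
#' with zero input count get `E = NA` and are excluded from the z
#' computation (never silently dropped).
#'
#' @param input,pulldown `count_table` objects over the same design.
#' @param design the [pool_design()] the tables were counted against.
#' @param pseudocount nonnegative count added per variant and condition.
#' @param concentration label for the pulldown protein concentration (nM);
#'   taken from the pulldown table's condition when `NULL`.
#' @param z_threshold significance threshold on the z-score (default 3).
#' @return an object of class `srbns_enrichment`: a data.frame with columns
#'   `scope`, `concentration`, `loop`, `loop_length`, `n_in`, `n_pd`, `f_in`,
#'   `f_pd`, `E`, `z`, `significant`, `effective_loop`, `extra_bp`.
#' @export
#' @examples
#' d <- pool_design(scaffold_spec("toy", "GGCGGCG", "CGCCGCC"), 3)
#' reads_in <- build_pool(d)$sequence
#' reads_pd <- c(reads_in, rep(paste0("GGCGGCG", "UAU", "CGCCGCC"), 50))
#' enr <- srbns_enrichment(count_reads(reads_in, d), count_reads(reads_pd, d), d)
#' head(summary(enr))
srbns_enrichment <- function(input, pulldown, design, pseudocount = 0.5,
                             concentration = NULL, z_threshold = 3) {
  stopifnot(inherits(design, "pool_design"), pseudocount >= 0)
  if (is.null(concentration)) {
    concentration <- if (nrow(pulldown) > 0) pulldown$condition[1] else "pulldown"
  }
  pool <- build_pool(design)
  key <- function(df) paste(df$scaffold, df$loop, sep = "|")
  n_in <- count_vector(input, key(pool))
  n_pd <- count_vector(pulldown, key(pool))
  if (sum(n_in) == 0) stop("input table has no assigned reads", call. = FALSE)
  scopes <- c(names(design$scaffolds), "COMBINED")
  res <- lapply(scopes, function(sc) {
    if (sc == "COMBINED") {
      # pool counts across scaffolds per loop before normalizing
      ci <- tapply(n_in, pool$loop, sum)
      cp <- tapply(n_pd, pool$loop, sum)
      loops <- names(ci)
    } else {
      sel <- pool$scaffold == sc
      ci <- n_in[sel]; cp <- n_pd[sel]
      loops <- pool$loop[sel]
    }
    evalue_frame(sc, concentration, loops, as.numeric(ci), as.numeric(cp),
                 pseudocount, z_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            design = design, pseudocount = pseudocount,
            z_threshold = z_threshold,
            class = c("srbns_enrichment", "data.frame"))
}

count_vector <- function(tab, keys) {
  v <- setNames(numeric(length(keys)), keys)
  if (nrow(tab) > 0) {
    k <- paste(tab$scaffold, tab$loop, sep = "|")
    hit <- k %in% keys
    v[k[hit]] <- v[k[hit]] + tab$count[hit]
  }
  v
}

evalue_frame <- function(scope, concentration, loops, n_in, n_pd,
                         pseudocount, z_threshold) {
  ci <- n_in + pseudocount
  cp <- n_pd + pseudocount
  f_in <- if (sum(ci) > 0) ci / sum(ci) else rep(NA_real_, length(ci))
  f_pd <- if (sum(cp) > 0) cp / sum(cp) else rep(NA_real_, length(cp))
  E <- ifelse(f_in > 0, f_pd / f_in, NA_real_)
  z <- zscores(E)
  eff <- t(vapply(loops, function(l) {
    if (nchar(l) >= 3) {
      r <- effective_loop(l)
      c(r$collapsed, as.character(r$extra_bp))
    } else c(NA_character_, NA_character_)
  }, c(collapsed = "", extra_bp = "")))
  data.frame(
    scope = scope, concentration = as.character(concentration),
    loop = loops, loop_length = nchar(loops),
    n_in = n_in, n_pd = n_pd, f_in = f_in, f_pd = f_pd, E = E, z = z,
    significant = !is.na(z) & z > z_threshold,
    effective_loop = ifelse(eff[, 1] == loops, NA_character_, eff[, 1]),
    extra_bp = as.integer(eff[, 2]),
    stringsAsFactors = FALSE)
}

#' Standardize enrichment values to z-scores
#'
#' z = (E - mean(E)) / sd(E) over the defined (non-NA) E-values of one scope
#' and concentration, using the sample (n - 1) standard deviation. If the
#' standard deviation is zero all z are set to 0 (with a warning) so that no
#' variant is called significant in a degenerate scope.
#'
#' @param E numeric vector of enrichment values (NA allowed).
#' @return numeric vector of z-scores, NA where E is NA.
#' @export
#' @examples
#' zscores(c(1, 2, 3))  # -1 0 1
zscores <- function(E) {
  ok <- !is.na(E)
  z <- rep(NA_real_, length(E))
  if (sum(ok) < 2L) {
    z[ok] <- 0
    return(z)
  }
  s <- sd(E[ok])
  if (s == 0) {
    warning("all E-values identical in scope; z-scores set to 0")
    z[ok] <- 0
  } else {
    z[ok] <- (E[ok] - mean(E[ok])) / s
  }
  z
}

#' Collapse outer loop bases that can pair into the stem
#'
#' Larger loops whose outermost bases form a Watson-Crick pair (A-U or G-C)
#' are effectively shorter loops on a one-base-pair-longer stem: a
#' pentanucleotide loop CUGUG presents the triloop UGU on an extended stem.
#' Collapsing proceeds from the outside in while the outer bases pair and at
#' least 3 nt of loop remain.
#'
#' @param loop RNA loop string, length >= 3.
#' @return list with `collapsed` (innermost loop, >= 3 nt) and `extra_bp`
#'   (number of pairs absorbed into the stem; 0 means no collapse).
#' @export
#' @examples
#' effective_loop("CUGUG")  # UGU + 1 bp
#' effective_loop("AUGUC")  # no collapse: A-C does not pair
effective_loop <- function(loop) {
  loop <- as_rna(loop)
  n <- nchar(loop)
  if (n < 3L) stop("loop must be at least 3 nt", call. = FALSE)
  extra <- 0L
  while (n - 2L * (extra + 1L) >= 3L) {
    b5 <- substr(loop, extra + 1L, extra + 1L)
    b3 <- substr(loop, n - extra, n - extra)
    if (!is_pair(b5, b3, allow_wobble = FALSE)) break
    extra <- extra + 1L
  }
  list(collapsed = substr(loop, extra + 1L, n - extra), extra_bp = extra)
}

#' Per-scaffold stem enrichment
#'
#' Compares the read share of each scaffold (its stem) between pulldown and
#' input and reports it relative to a reference scaffold, e.g. "the TNF stem
#' is ~1.4-fold enriched against the UCP3 stem".
#'
#' @param input,pulldown `count_table` objects.
#' @param reference name of the reference scaffold.
#' @return named numeric vector: fold enrichment of every scaffold relative
#'   to `reference` (reference itself = 1).
#' @export
stem_enrichment <- function(input, pulldown, reference) {
  share <- function(tab) {
    s <- tapply(tab$count, tab$scaffold, sum)
    s / sum(s)
  }
  si <- share(input); sp <- share(pulldown)
  scaffolds <- union(names(si), names(sp))
  if (!reference %in% scaffolds) {
    stop(sprintf("reference scaffold '%s' absent from the tables", reference),
         call. = FALSE)
  }
  fe <- (sp[scaffolds] / si[scaffolds])
  names(fe) <- scaffolds
  out <- fe / fe[[reference]]
  out[!is.finite(out)] <- NA_real_
  out
}

#' Enrichment-weighted sequence logo matrix
#'
#' Position weight matrix in which each loop variant contributes its
#' enrichment: weight(p, b) = sum of E over variants with base b at position
#' p, divided by the total E. Rows (positions) are probability vectors.
#'
#' @param records an `srbns_enrichment` object or data.frame with columns
#'   `loop` and `E`.
#' @param scope scope to use when `records` spans several (default
#'   `"COMBINED"`).
#' @return a `logo_matrix`: positions x \{A,C,G,U\} numeric matrix whose rows
#'   sum to 1.
#' @export
enrichment_logo <- function(records, scope = "COMBINED") {
  df <- as.data.frame(records)
  if ("scope" %in% names(df)) df <- df[df$scope == scope, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records in scope", call. = FALSE)
  lens <- unique(nchar(df$loop))
  if (length(lens) != 1L) {
    stop("logo requires records of a single loop length; got lengths ",
         paste(lens, collapse = ","), call. = FALSE)
  }
  if (anyNA(df$E)) stop("all E-values must be defined for a logo", call. = FALSE)
  k <- lens
  m <- matrix(0, nrow = k, ncol = 4,
              dimnames = list(position = seq_len(k), base = RNA_BASES))
  tot <- sum(df$E)
  if (tot <= 0) stop("total enrichment is zero; logo undefined", call. = FALSE)
  for (p in seq_len(k)) {
    bp <- substr(df$loop, p, p)
    w <- tapply(df$E, bp, sum)
    m[p, names(w)] <- w / tot
  }
  structure(m, class = c("logo_matrix", "matrix"))
}

#' @export
print.logo_matrix <- function(x, digits = 3, ...) {
  cat("enrichment-weighted logo matrix (rows = loop positions):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.srbns_enrichment <- function(x, ...) {
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  cat(sprintf("sRBNS enrichment: %d records, scopes {%s}, concentration %s nM\n",
              nrow(df), paste(unique(df$scope), collapse = ", "),
              paste(unique(df$concentration), collapse = ", ")))
  nsig <- sum(df$significant[df$scope == "COMBINED"], na.rm = TRUE)
  cat(sprintf("  significant (z > %g, COMBINED scope): %d variant(s)\n",
              attr(x, "z_threshold"), nsig))
  top <- df[df$scope == "COMBINED", , drop = FALSE]
  top <- top[order(-top$E), , drop = FALSE][seq_len(min(5L, nrow(top))), ]
  cat("  top loops by E:\n")
  print(top[, c("loop", "E", "z", "significant", "effective_loop")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.srbns_enrichment <- function(object, scope = "COMBINED", ...) {
  df <- as.data.frame(unclass(object), stringsAsFactors = FALSE)
  df <- df[df$scope == scope, , drop = FALSE]
  df <- df[order(-df$E), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Plot an enrichment-weighted logo
#'
#' Stacked per-position base weights (letter heights proportional to the
#' enrichment-weighted base frequency), base graphics.
#'
#' @param x an `srbns_enrichment` object.
#' @param scope scope to plot (default `"COMBINED"`).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the [enrichment_logo()] matrix plotted.
#' @export
#' @importFrom graphics barplot legend
plot.srbns_enrichment <- function(x, scope = "COMBINED", ...) {
  m <- enrichment_logo(x, scope = scope)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", U = "#D62839")
  barplot(t(unclass(m)), col = cols, border = NA,
          xlab = "loop position", ylab = "enrichment-weighted frequency",
          names.arg = seq_len(nrow(m)), ...)
  legend("topright", legend = RNA_BASES, fill = cols, bty = "n", cex = 0.8)
  invisible(m)
}

#' Write an enrichment table (and optional logo matrix) as TSV
#'
#' @param x an `srbns_enrichment` object.
#' @param path output TSV path.
#' @param logo_path optional path for the COMBINED-scope logo matrix TSV
#'   (written only when all COMBINED E-values share one loop length).
#' @return invisibly, `x`.
#' @export
write_enrichment <- function(x, path, logo_path = NULL) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(logo_path)) {
    m <- enrichment_logo(x)
    write.table(cbind(position = seq_len(nrow(m)), as.data.frame(unclass(m))),
                logo_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
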