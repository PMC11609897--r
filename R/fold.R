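#' Pair-additive hairpin energy model
#'
#' A deliberately small thermodynamic model: each base pair contributes a
#' single stabilizing energy by pair type (AU, GC, GU wobble), structures are
#' pseudoknot-free, and every pair must enclose at least `min_hairpin_loop`
#' nucleotides. For this pair-additive model the blanket minimum-span rule is
#' exactly equivalent to requiring hairpin loops of at least
#' `min_hairpin_loop` unpaired bases, because a pair enclosing fewer
#' nucleotides cannot contain any inner pair. The model is simple enough that
#' the partition-function recursion can be validated against exhaustive
#' structure enumeration.
#'
#' @param e_au,e_gc,e_gu pair energies in kcal/mol (must be < 0, stabilizing).
#' @param rt thermal energy in kcal/mol.
#' @param min_hairpin_loop minimum unpaired nucleotides in a hairpin loop.
#' @param allow_wobble logical; admit G-U pairs.
#' @return an object of class `energy_model`.
#' @export
#' @examples
#' energy_model()
energy_model <- function(e_au = -1.1, e_gc = -2.4, e_gu = -1.0,
                         rt = 0.616, min_hairpin_loop = 3L,
                         allow_wobble = TRUE) {
  stopifnot(e_au < 0, e_gc < 0, e_gu < 0, rt > 0, min_hairpin_loop >= 3L)
  structure(list(e_au = e_au, e_gc = e_gc, e_gu = e_gu, rt = rt,
                 min_hairpin_loop = as.integer(min_hairpin_loop),
                 allow_wobble = isTRUE(allow_wobble)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "hairpin energy model: AU %.2f, GC %.2f, GU %s kcal/mol; RT %.3f; min loop %d\n",
    x$e_au, x$e_gc, if (x$allow_wobble) sprintf("%.2f", x$e_gu) else "(off)",
    x$rt, x$min_hairpin_loop))
  invisible(x)
}

#' Can two RNA bases pair?
#'
#' Watson-Crick pairs (A-U, G-C) always; G-U wobble only if `allow_wobble`.
#'
#' @param b1,b2 single RNA bases (vectorized).
#' @param allow_wobble logical.
#' @return logical vector.
#' @export
#' @examples
#' is_pair("A", "U")               # TRUE
#' is_pair("G", "U")               # TRUE (wobble)
#' is_pair("G", "U", FALSE)        # FALSE
is_pair <- function(b1, b2, allow_wobble = TRUE) {
  if (any(!c(b1, b2) %in% RNA_BASES)) {
    stop("bases must be single RNA characters A/C/G/U", call. = FALSE)
  }
  p <- paste0(b1, b2)
  wc <- p %in% c("AU", "UA", "GC", "CG")
  if (allow_wobble) wc | p %in% c("GU", "UG") else wc
}

# Per-pair Boltzmann weight exp(-E/RT); 0 if not pairable under the model.
pair_weight <- function(b1, b2, model) {
  p <- paste0(b1, b2)
  e <- rep(NA_real_, length(p))
  e[p %in% c("AU", "UA")] <- model$e_au
  e[p %in% c("GC", "CG")] <- model$e_gc
  if (model$allow_wobble) e[p %in% c("GU", "UG")] <- model$e_gu
  ifelse(is.na(e), 0, exp(-e / model$rt))
}

#' Contiguous stem length flanking a loop window
#'
#' Walks outward from the loop window `[loop_start, loop_end)` (0-based
#' half-open) and counts how many consecutive flanking positions form base
#' pairs, stopping at the first non-pair or the sequence boundary.
#'
#' @param seq RNA string (DNA transliterated).
#' @param loop_start,loop_end 0-based half-open loop coordinates.
#' @param allow_wobble logical; count G-U pairs as stem pairs.
#' @return integer stem length (0 if the closing positions do not pair).
#' @export
#' @examples
#' stem_length_at(paste0("GGGGGG", "UUU", "CCCCCC"), 6, 9)  # 6
stem_length_at <- function(seq, loop_start, loop_end, allow_wobble = FALSE) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (loop_start < 0L || loop_end > n || loop_start >= loop_end) {
    stop("loop window out of range", call. = FALSE)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- 0L
  repeat {
    i5 <- loop_start - len       # 1-based index of next 5' stem base
    i3 <- loop_end + len + 1L    # 1-based index of next 3' stem base
    if (i5 < 1L || i3 > n) break
    if (!is_pair(b[i5], b[i3], allow_wobble)) break
    len <- len + 1L
  }
  len
}

#' Exhaustively enumerate pseudoknot-free secondary structures
#'
#' The validation oracle for [hairpin_probability()]: lists every nested set
#' of base pairs in which each pair encloses at least `min_hairpin_loop`
#' nucleotides, including the empty structure. Guarded to short sequences
#' because the count grows super-exponentially.
#'
#' @param seq RNA string of length <= `max_len`.
#' @param model an [energy_model()].
#' @param max_len combinatorial guard (default 20).
#' @return a list of structures; each structure is an integer matrix with
#'   columns `i`, `j` (1-based paired positions), zero rows for the empty
#'   structure.
#' @export
enumerate_structures <- function(seq, model = energy_model(), max_len = 20L) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n > max_len) {
    stop(sprintf("sequence length %d exceeds enumeration guard (%d)", n, max_len),
         call. = FALSE)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  min_span <- model$min_hairpin_loop + 1L  # j - i must be > min_hairpin_loop
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n == 0L) return(list(empty))
  # enumerate over interval [i..j]: either i unpaired, or i pairs with some k
  rec <- function(i, j) {
    if (i > j) return(list(empty))
    out <- rec(i + 1L, j)                       # i unpaired
    if (i + min_span <= j) {
      for (k in seq.int(i + min_span, j)) {
        if (is_pair(b[i], b[k], model$allow_wobble)) {
          inner <- rec(i + 1L, k - 1L)
          outer <- rec(k + 1L, j)
          for (si in inner) for (so in outer) {
            out[[length(out) + 1L]] <- rbind(c(i = i, j = k), si, so)
          }
        }
      }
    }
    out
  }
  rec(1L, n)
}

# Boltzmann weight of one enumerated structure.
structure_weight <- function(pairs, b, model) {
  if (nrow(pairs) == 0L) return(1)
  prod(pair_weight(b[pairs[, 1]], b[pairs[, 2]], model))
}

# Partition function over [1..n] by interval DP.
#   Z[i,j] = Z[i,j-1] + sum_k blocked-aware w(k,j) * Z[i,k-1] * Z[k+1,j-1]
# `blocked` marks positions that must stay unpaired (used for the constrained
# ensemble, where the candidate stem occupies a masked block).
partition_fn <- function(b, model, blocked = NULL) {
  n <- length(b)
  if (n == 0L) return(1)
  if (is.null(blocked)) blocked <- rep(FALSE, n)
  min_span <- model$min_hairpin_loop + 1L
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- seq_len(n)[seq_len(n) - i > model$min_hairpin_loop]
    if (length(js)) w[i, js] <- pair_weight(b[i], b[js], model)
  }
  w[blocked, ] <- 0
  w[, blocked] <- 0
  # Z indexed with a +1 offset so empty intervals (j = i - 1) are reachable
  Z <- matrix(1, n + 1L, n + 1L)
  for (span in 1:n) {
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      # offset convention: Zo(i, j) stored at Z[i, j + 1]
      acc <- Z[i, j - 1L + 1L]       # j unpaired
      ks <- i:j
      ks <- ks[j - ks > model$min_hairpin_loop]
      if (length(ks)) {
        wk <- w[ks, j]
        nz <- wk > 0
        if (any(nz)) {
          ks <- ks[nz]; wk <- wk[nz]
          acc <- acc + sum(wk * Z[cbind(i, ks - 1L + 1L)] *
                             Z[cbind(ks + 1L, j - 1L + 1L)])
        }
      }
      Z[i, j + 1L] <- acc
    }
  }
  Z[1L, n + 1L]
}

#' Equilibrium probability that a candidate hairpin forms
#'
#' Computes p_fold = Z_constrained / Z, where Z sums Boltzmann weights over
#' all pseudoknot-free structures of `seq` under the pair-additive
#' [energy_model()], and Z_constrained sums over structures that contain all
#' `stem_len` closing base pairs of the candidate: pairs
#' (loop_start - m - 1, loop_end + m) for m = 0 .. stem_len - 1 (0-based).
#' The constrained sum factorizes into the stem weight times independent
#' partition functions over the loop interval and the exterior with the
#' stem-enclosed block masked.
#'
#' @param seq RNA string.
#' @param loop_start,loop_end 0-based half-open loop coordinates.
#' @param stem_len number of closing pairs required to form (>= 1).
#' @param model an [energy_model()].
#' @return probability in [0, 1]; 0 if any required pair is not pairable.
#' @export
#' @examples
#' # two-state toy: single G-C pair over a triloop
#' hairpin_probability("GAAAC", 1, 4, 1)
hairpin_probability <- function(seq, loop_start, loop_end, stem_len,
                                model = energy_model()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  stem_len <- as.integer(stem_len)
  if (stem_len < 1L) stop("stem_len must be >= 1", call. = FALSE)
  if (loop_start < 0L || loop_end > n || loop_start >= loop_end) {
    stop("loop window out of range", call. = FALSE)
  }
  if (loop_start - stem_len < 0L || loop_end + stem_len > n) {
    stop("candidate stem extends beyond the sequence", call. = FALSE)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  # constrained stem pairs, 1-based
  i5 <- loop_start - seq_len(stem_len) + 1L
  i3 <- loop_end + seq_len(stem_len)
  wst <- pair_weight(b[i5], b[i3], model)
  # innermost pair must satisfy the minimum loop span
  if (any(wst == 0) || (loop_end - loop_start) < model$min_hairpin_loop) return(0)
  z_all <- partition_fn(b, model)
  z_loop <- partition_fn(b[(loop_start + 1L):loop_end], model)
  blocked <- rep(FALSE, n)
  blocked[min(i5):max(i3)] <- TRUE
  z_ext <- partition_fn(b, model, blocked = blocked)
  prod(wst) * z_loop * z_ext / z_all
}

#' Brute-force folding probability (oracle)
#'
#' Same quantity as [hairpin_probability()], computed by exhaustive
#' enumeration of the structure ensemble. Intended for validation on short
#' sequences only.
#'
#' @inheritParams hairpin_probability
#' @param max_len enumeration guard passed to [enumerate_structures()].
#' @return probability in [0, 1].
#' @export
hairpin_probability_brute <- function(seq, loop_start, loop_end, stem_len,
                                      model = energy_model(), max_len = 20L) {
  seq <- as_rna(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  structs <- enumerate_structures(seq, model, max_len = max_len)
  need <- cbind(loop_start - seq_len(stem_len) + 1L,
                loop_end + seq_len(stem_len))
  ws <- vapply(structs, structure_weight, numeric(1), b = b, model = model)
  has_stem <- vapply(structs, function(p) {
    if (nrow(p) < nrow(need)) return(FALSE)
    key <- paste(p[, 1], p[, 2])
    all(paste(need[, 1], need[, 2]) %in% key)
  }, logical(1))
  sum(ws[has_stem]) / sum(ws)
}
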