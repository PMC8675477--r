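# Sequence-independent structural alignment and common-core extraction.
#
# The aligner alternates Kabsch superposition on the current residue
# correspondence with dynamic-programming re-alignment under the TM similarity
# 1/(1 + (d/d0)^2) (affine gaps, open -0.6, extend 0, ties toward the
# diagonal), seeded from gapless threadings at every offset plus length-20
# fragment pairings, and returns the highest-TM result. It is deterministic
# for fixed input.

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

alignment_seeds <- function(na, nb, fragment_len = 20L, fragment_stride = 20L) {
  seeds <- list()
  # gapless threading of the shorter onto the longer at all offsets
  if (na <= nb) {
    for (k in 0:(nb - na))
      seeds[[length(seeds) + 1L]] <- cbind(seq_len(na), seq_len(na) + k)
  } else {
    for (k in 0:(na - nb))
      seeds[[length(seeds) + 1L]] <- cbind(seq_len(nb) + k, seq_len(nb))
  }
  # fragment seeds
  fl <- min(fragment_len, na, nb)
  sa <- unique(c(seq(1L, na - fl + 1L, by = fragment_stride), na - fl + 1L))
  sb <- unique(c(seq(1L, nb - fl + 1L, by = fragment_stride), nb - fl + 1L))
  for (i in sa) for (j in sb)
    seeds[[length(seeds) + 1L]] <- cbind(i:(i + fl - 1L), j:(j + fl - 1L))
  seeds
}

# One refinement pass: superpose on the current pairs, rebuild the similarity
# matrix, re-align by DP. Returns the new pairs and their refit TM.
refine_pairs <- function(pairs, a, b, d0, l_norm, gap_open) {
  sup <- tryCatch(kabsch(a[pairs[, 1], , drop = FALSE],
                         b[pairs[, 2], , drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(sup)) return(NULL)
  ta <- apply_superposition(sup, a)
  s <- 1 / (1 + (cross_dist(ta, b) / d0)^2)
  new_pairs <- .nw_affine(s, gap_open, 0)
  if (nrow(new_pairs) < 3L) return(NULL)
  sup2 <- tryCatch(kabsch(a[new_pairs[, 1], , drop = FALSE],
                          b[new_pairs[, 2], , drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(sup2)) return(NULL)
  d <- sqrt(rowSums((apply_superposition(sup2, a[new_pairs[, 1], , drop = FALSE]) -
                       b[new_pairs[, 2], , drop = FALSE])^2))
  list(pairs = new_pairs, tm = sum(1 / (1 + (d / d0)^2)) / l_norm)
}

#' Align two traces without using their sequences
#'
#' Iterative TM-score structural alignment: correspondences are seeded by
#' gapless threading of the shorter trace onto the longer at every offset plus
#' length-20 fragment pairings; each seed alternates Kabsch superposition with
#' dynamic-programming re-alignment under the score `1/(1+(d/d0)^2)` until the
#' TM-score converges (delta < `tol` or `max_iter` iterations); the highest-TM
#' result is returned with a final TM-optimal superposition.
#'
#' @param a,b `"trace"` objects (both length >= 15).
#' @param params [tm_params()]; defaults to normalising by the shorter trace.
#' @param gap_open Affine gap-opening score on the TM similarity scale
#'   (default -0.6; extension is free).
#' @param max_iter,tol Convergence controls (defaults 50 and 1e-6).
#' @param keep_seeds After one refinement pass of every seed, only the
#'   `keep_seeds` best are iterated to convergence (default 8).
#' @return Object of class `"structaln"`: `pairs` (m x 2 index matrix, strictly
#'   increasing in both), `deviations`, `superposition`, `tm_score`, `params`,
#'   and the input traces `a`, `b`.
#' @export
align_traces <- function(a, b, params = NULL, gap_open = -0.6,
                         max_iter = 50L, tol = 1e-6, keep_seeds = 8L) {
  stopifnot(inherits(a, "trace"), inherits(b, "trace"))
  na <- length(a); nb <- length(b)
  if (na < 15L || nb < 15L) stop("traces must have at least 15 residues")
  if (is.null(params)) params <- tm_params(min(na, nb))
  d0 <- params$d0; l_norm <- params$l_norm
  ca <- a$coords; cb <- b$coords

  seeds <- alignment_seeds(na, nb)
  first <- lapply(seeds, refine_pairs, a = ca, b = cb, d0 = d0,
                  l_norm = l_norm, gap_open = gap_open)
  ok <- !vapply(first, is.null, logical(1))
  first <- first[ok]
  if (length(first) == 0L) stop("alignment failed: degenerate input geometry")
  ord <- order(vapply(first, `[[`, numeric(1), "tm"), decreasing = TRUE)
  first <- first[ord[seq_len(min(keep_seeds, length(first)))]]

  best <- NULL
  for (st in first) {
    pairs <- st$pairs; tm_prev <- st$tm
    state <- st
    for (it in seq_len(max_iter)) {
      nxt <- refine_pairs(state$pairs, ca, cb, d0, l_norm, gap_open)
      if (is.null(nxt)) break
      improved <- nxt$tm - tm_prev
      if (nxt$tm >= state$tm) state <- nxt
      if (abs(improved) < tol) break
      tm_prev <- nxt$tm
    }
    if (is.null(best) || state$tm > best$tm) best <- state
  }

  pa <- ca[best$pairs[, 1], , drop = FALSE]
  pb <- cb[best$pairs[, 2], , drop = FALSE]
  fin <- tm_superpose(pa, pb, params)
  structure(list(a = a, b = b, pairs = best$pairs,
                 deviations = fin$deviations,
                 superposition = fin$superposition,
                 tm_score = min(1, fin$tm), params = params),
            class = "structaln")
}

#' @export
print.structaln <- function(x, ...) {
  cat(sprintf(
    "<structaln> %d aligned pairs (of %d x %d), TM-score %.3f (L_norm %d, d0 %.2f A)\n",
    nrow(x$pairs), length(x$a), length(x$b), x$tm_score, x$params$l_norm,
    x$params$d0))
  invisible(x)
}

#' Extract the common core of a structural alignment
#'
#' Iteratively drops aligned pairs deviating by `cutoff` or more, re-superposes
#' on the survivors (Kabsch), and repeats until membership is stable. Pairs are
#' only ever dropped, never re-admitted. The reported RMSD is refit on the core
#' members.
#'
#' @param alignment A `"structaln"`.
#' @param cutoff Deviation cutoff in Angstrom (> 0; 4 is the conventional
#'   common-core threshold).
#' @return Object of class `"coreset"`: `cutoff`, `member_pairs`, `core_size`,
#'   `core_rmsd` (NA and `empty = TRUE` when nothing survives),
#'   `superposition`, `deviations`, and `tm_core` (TM-score over core pairs
#'   under the core superposition, normalised by the alignment's `l_norm`).
#' @export
common_core <- function(alignment, cutoff = 4) {
  stopifnot(inherits(alignment, "structaln"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (nrow(alignment$pairs) == 0L) stop("alignment has no pairs")
  ca <- alignment$a$coords; cb <- alignment$b$coords
  pairs <- alignment$pairs
  keep <- alignment$deviations < cutoff
  sup <- alignment$superposition
  dev <- alignment$deviations
  empty <- structure(list(cutoff = cutoff,
                          member_pairs = pairs[0, , drop = FALSE],
                          core_size = 0L, core_rmsd = NA_real_,
                          superposition = NULL, deviations = numeric(0),
                          tm_core = 0, empty = TRUE), class = "coreset")
  if (!any(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  dev <- dev[keep]
  repeat {
    if (nrow(pairs) < 3L) break  # too few members to refit; accept as-is
    sup2 <- tryCatch(kabsch(ca[pairs[, 1], , drop = FALSE],
                            cb[pairs[, 2], , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(sup2)) break
    sup <- sup2
    dev <- sqrt(rowSums((apply_superposition(sup, ca[pairs[, 1], , drop = FALSE]) -
                           cb[pairs[, 2], , drop = FALSE])^2))
    drop <- dev >= cutoff
    if (!any(drop)) break
    if (all(drop)) return(empty)
    pairs <- pairs[!drop, , drop = FALSE]
    dev <- dev[!drop]
  }
  structure(list(cutoff = cutoff, member_pairs = pairs,
                 core_size = nrow(pairs),
                 core_rmsd = sqrt(mean(dev^2)),
                 superposition = sup, deviations = dev,
                 tm_core = sum(1 / (1 + (dev / alignment$params$d0)^2)) /
                   alignment$params$l_norm,
                 empty = FALSE),
            class = "coreset")
}

#' @export
print.coreset <- function(x, ...) {
  if (x$empty) cat("<coreset> empty (no pair below", x$cutoff, "A)\n")
  else cat(sprintf("<coreset> %d pairs < %g A, core RMSD %.2f A\n",
                   x$core_size, x$cutoff, x$core_rmsd))
  invisible(x)
}

#' Tabulate a structural alignment
#'
#' @param alignment A `"structaln"`.
#' @return data.frame with `resid_a`, `aa_a`, `resid_b`, `aa_b`,
#'   `deviation` (Angstrom).
#' @export
alignment_table <- function(alignment) {
  p <- alignment$pairs
  data.frame(resid_a = alignment$a$residue_ids[p[, 1]],
             aa_a = alignment$a$sequence[p[, 1]],
             resid_b = alignment$b$residue_ids[p[, 2]],
             aa_b = alignment$b$sequence[p[, 2]],
             deviation = alignment$deviations)
}

#' Write an alignment as TSV
#' @param alignment A `"structaln"`.
#' @param path Output path.
#' @export
write_alignment_tsv <- function(alignment, path) {
  write.table(alignment_table(alignment), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write superposed traces as a two-model PDB
#'
#' Model 1 is trace `a` transformed by the alignment superposition; model 2 is
#' trace `b` in its original frame.
#'
#' @param alignment A `"structaln"`.
#' @param path Output path.
#' @export
write_superposed_pdb <- function(alignment, path) {
  a2 <- alignment$a
  a2$coords <- apply_superposition(alignment$superposition, a2$coords)
  write_trace_pdb(list(a2, alignment$b), path, models = TRUE)
}
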