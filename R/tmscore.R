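# TM-score: length-normalised structural similarity in (0, 1].

#' TM-score distance normalisation d0
#'
#' The standard normalisation `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, floored at
#' 0.5 Angstrom (so short lengths never produce a degenerate score).
#'
#' @param l_norm Residue count used for normalisation (>= 1).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm) {
  if (any(l_norm < 1)) stop("l_norm must be >= 1")
  x <- l_norm - 15
  max(0.5, 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8)
}

#' TM-score parameters
#'
#' @param l_norm Residue count used for normalisation. The package convention
#'   is to normalise pairwise alignments by the shorter trace's length.
#' @param d0 Distance scale in Angstrom; defaults to [tm_d0()] of `l_norm`,
#'   and is floored at 0.5.
#' @return List of class `"tm_params"` with `l_norm` and `d0`.
#' @export
tm_params <- function(l_norm, d0 = tm_d0(l_norm)) {
  l_norm <- as.integer(l_norm)
  if (l_norm < 1L) stop("l_norm must be >= 1")
  structure(list(l_norm = l_norm, d0 = max(0.5, d0)), class = "tm_params")
}

#' TM-score from per-pair deviations
#'
#' `TM = (1/L_norm) * sum_i 1 / (1 + (d_i / d0)^2)` over aligned pairs.
#'
#' @param deviations Per-pair deviations in Angstrom (>= 1 value).
#' @param params A [tm_params()].
#' @return TM-score.
#' @export
tm_score <- function(deviations, params) {
  if (length(deviations) < 1L) stop("at least one aligned pair is required")
  if (any(!is.finite(deviations) | deviations < 0))
    stop("deviations must be finite and non-negative")
  sum(1 / (1 + (deviations / params$d0)^2)) / params$l_norm
}

#' TM-optimal superposition of paired coordinates
#'
#' Finds the rigid superposition of `coords_a` onto `coords_b` maximising the
#' TM-score sum, by the usual iterative scheme: seed superpositions from
#' contiguous windows (full length, halves, quarters), then refine each on the
#' subset of pairs closer than a distance cut until membership stabilises.
#'
#' @param coords_a,coords_b Paired n x 3 coordinate matrices.
#' @param params A [tm_params()].
#' @return List: `superposition`, `tm` (the maximised TM-score), `deviations`
#'   (per pair, under the returned superposition).
#' @export
tm_superpose <- function(coords_a, coords_b, params) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  n <- nrow(a)
  if (n != nrow(b) || n < 1L) stop("paired coordinate sets required")
  if (n < 3L) return(tm_superpose_small(a, b, params))
  d0 <- params$d0
  best <- NULL
  seed_len <- unique(pmax(4L, floor(n / c(1L, 2L, 4L))))
  for (len in seed_len) {
    starts <- unique(c(seq(1L, n - len + 1L, by = max(1L, floor(len / 2))),
                       n - len + 1L))
    for (s in starts) {
      idx <- s:(s + len - 1L)
      sup <- tryCatch(kabsch(a[idx, , drop = FALSE], b[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sup)) next
      d_cut <- max(d0 + 1, 3.5)
      prev_sel <- integer(0)
      for (it in 1:20) {
        d <- sqrt(rowSums((apply_superposition(sup, a) - b)^2))
        tm <- sum(1 / (1 + (d / d0)^2)) / params$l_norm
        if (is.null(best) || tm > best$tm)
          best <- list(superposition = sup, tm = tm, deviations = d)
        sel <- which(d < d_cut)
        while (length(sel) < 3L) {
          d_cut <- d_cut + 0.5
          sel <- which(d < d_cut)
        }
        if (identical(sel, prev_sel)) break
        prev_sel <- sel
        sup2 <- tryCatch(kabsch(a[sel, , drop = FALSE], b[sel, , drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(sup2)) break
        sup <- sup2
      }
    }
  }
  if (is.null(best)) stop("degenerate geometry: no superposition could be fit")
  best
}

# 1 or 2 pairs can always be brought into exact coincidence up to bond-length
# mismatch; handled explicitly since Kabsch needs >= 3 points.
tm_superpose_small <- function(a, b, params) {
  n <- nrow(a)
  if (n == 1L) {
    sup <- structure(list(rotation = diag(3),
                          translation = as.numeric(b[1, ] - a[1, ]),
                          rmsd = 0), class = "superposition")
    return(list(superposition = sup, tm = 1 / params$l_norm, deviations = 0))
  }
  va <- a[2, ] - a[1, ]; vb <- b[2, ] - b[1, ]
  r <- if (sqrt(sum(va^2)) < 1e-12 || sqrt(sum(vb^2)) < 1e-12) diag(3)
       else rotation_between(va, vb)
  tv <- colMeans(b) - as.numeric(r %*% colMeans(a))
  sup <- structure(list(rotation = r, translation = tv, rmsd = NA_real_),
                   class = "superposition")
  d <- sqrt(rowSums((apply_superposition(sup, a) - b)^2))
  sup$rmsd <- sqrt(mean(d^2))
  list(superposition = sup, tm = sum(1 / (1 + (d / params$d0)^2)) / params$l_norm,
       deviations = d)
}
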