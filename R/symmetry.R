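# Internal C2 pseudosymmetry: split-point scanning, symmetry axis, helix
# tilts, and fold-connectivity combinatorics.
#
# A protein that arose by duplication-and-fusion of an antiparallel homodimer
# carries two structurally similar halves related by a two-fold rotation about
# an axis parallel to the membrane plane. The scan operationalises the choice
# of split point: every candidate split is tried, the halves are structurally
# aligned, and the split maximising the common-core TM-score is reported.

#' Split a trace into N- and C-terminal halves
#'
#' @param t A `"trace"`.
#' @param split_index Position (1-based, in trace order) of the last residue
#'   of the N-terminal half.
#' @param min_half_len Minimum residues per half (default 30).
#' @return List with elements `n` and `c` (both `"trace"`): contiguous halves
#'   whose union is the input and whose intersection is empty.
#' @export
split_trace <- function(t, split_index, min_half_len = 30L) {
  stopifnot(inherits(t, "trace"))
  n <- length(t)
  if (split_index < min_half_len || split_index > n - min_half_len)
    stop("split_index ", split_index, " outside legal bounds [", min_half_len,
         ", ", n - min_half_len, "]")
  idx_n <- seq_len(split_index)
  idx_c <- (split_index + 1L):n
  sub <- function(i) new_trace(t$chain_id, t$residue_ids[i], t$sequence[i],
                               t$coords[i, , drop = FALSE], t$insert[i])
  list(n = sub(idx_n), c = sub(idx_c))
}

#' Scan candidate split points for internal C2 pseudosymmetry
#'
#' For every candidate split in `window`, aligns the N- and C-terminal halves
#' with [align_traces()] and extracts the common core ([common_core()]); the
#' split maximising the core TM-score is returned. Candidate splits are scored
#' with the TM-score normalised by the *longer* half, which peaks at the
#' balanced split (an unbalanced split can only lose core coverage) and so
#' localises the duplication boundary; the verdict is `"symmetric"` when the
#' best core TM-score reaches `threshold`.
#'
#' @param t A `"trace"`.
#' @param window Integer vector (or `c(from, to)` range) of candidate split
#'   positions.
#' @param core_cutoff Common-core deviation cutoff in Angstrom (default 4).
#' @param threshold Symmetry verdict threshold on the core TM-score (default
#'   0.30: well below the 0.5 same-fold convention, appropriate for strongly
#'   diverged halves).
#' @param min_half_len Minimum residues per half (default 30).
#' @param frame Optional [membrane_frame()] for axis tilt reporting.
#' @param ... Passed to [align_traces()].
#' @return Object of class `"symreport"`: `split_index`, `n_half`, `c_half`,
#'   `alignment`, `core`, `axis` ([c2_axis()] of the core superposition, NULL
#'   if the core is empty), `verdict`, `threshold`, and `scan` (a data.frame of
#'   per-split scores).
#' @export
scan_splits <- function(t, window, core_cutoff = 4, threshold = 0.30,
                        min_half_len = 30L, frame = NULL, ...) {
  stopifnot(inherits(t, "trace"))
  n <- length(t)
  if (length(window) == 2L && window[2] > window[1] + 1L)
    window <- window[1]:window[2]
  window <- sort(unique(as.integer(window)))
  window <- window[window >= min_half_len & window <= n - min_half_len]
  if (length(window) == 0L) stop("empty candidate window after applying bounds")
  best <- NULL
  scan <- data.frame(split = window, core_size = NA_integer_,
                     core_rmsd = NA_real_, core_tm = NA_real_)
  for (i in seq_along(window)) {
    s <- window[i]
    halves <- split_trace(t, s, min_half_len)
    params <- tm_params(max(length(halves$n), length(halves$c)))
    aln <- align_traces(halves$n, halves$c, params = params, ...)
    core <- common_core(aln, core_cutoff)
    scan$core_size[i] <- core$core_size
    scan$core_rmsd[i] <- core$core_rmsd
    scan$core_tm[i] <- core$tm_core
    if (is.null(best) || core$tm_core > best$core$tm_core)
      best <- list(split = s, halves = halves, aln = aln, core = core)
  }
  axis <- if (!best$core$empty)
    tryCatch(c2_axis(best$core$superposition, frame), error = function(e) NULL)
  else NULL
  structure(list(split_index = best$split,
                 n_half = best$halves$n, c_half = best$halves$c,
                 alignment = best$aln, core = best$core, axis = axis,
                 verdict = if (best$core$tm_core >= threshold) "symmetric"
                           else "asymmetric",
                 threshold = threshold, scan = scan),
            class = "symreport")
}

#' @export
print.symreport <- function(x, ...) {
  cat(sprintf(
    "<symreport> verdict %s (core TM %.3f vs threshold %.2f)\n  best split %d: core %d pairs, RMSD %s A%s\n",
    x$verdict, x$core$tm_core, x$threshold, x$split_index, x$core$core_size,
    ifelse(is.na(x$core$core_rmsd), "NA", sprintf("%.2f", x$core$core_rmsd)),
    if (!is.null(x$axis)) sprintf(", rotation %.1f deg", x$axis$angle_deg)
    else ""))
  invisible(x)
}

#' Rotation axis and angle of a superposition
#'
#' The rotation angle is `acos((trace(R) - 1)/2)`; the axis is the rotation's
#' invariant direction, with its sign fixed so that rebuilding the rotation
#' from (axis, angle) reproduces `R`. With a membrane frame, the tilt of the
#' axis out of the membrane plane is reported (a duplication-derived channel
#' has its C2 axis parallel to the plane, i.e. tilt near 0).
#'
#' @param s A `"superposition"` (or any list with a proper `rotation` matrix).
#' @param frame Optional [membrane_frame()].
#' @return Object of class `"axisreport"`: `axis` (unit vector), `angle_deg`
#'   in `[0, 180]`, `c2_deviation_deg = |180 - angle_deg|`, and
#'   `membrane_parallel_tilt_deg` (NA without a frame).
#' @export
c2_axis <- function(s, frame = NULL) {
  r <- s$rotation
  if (abs(det(r) - 1) > 1e-6) stop("rotation must be proper (det +1)")
  angle <- rotation_angle_deg(r)
  if (angle < 1e-3)
    stop("undefined axis: rotation is (near) the identity")
  e <- eigen(r)
  k <- which.min(abs(e$values - 1))
  ax <- Re(e$vectors[, k])
  ax <- ax / sqrt(sum(ax^2))
  th <- angle * pi / 180
  # two sign candidates; keep the one that reconstructs R
  err <- function(u) max(abs(rotation_about_axis(u, th) - r))
  if (err(-ax) < err(ax)) ax <- -ax
  tilt <- NA_real_
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "membrane_frame"))
    tilt <- asin(min(1, abs(sum(ax * frame$normal)))) * 180 / pi
  }
  structure(list(axis = ax, angle_deg = angle,
                 c2_deviation_deg = abs(180 - angle),
                 membrane_parallel_tilt_deg = tilt),
            class = "axisreport")
}

#' @export
print.axisreport <- function(x, ...) {
  cat(sprintf("<axisreport> angle %.2f deg (C2 deviation %.2f), axis (%.3f, %.3f, %.3f)%s\n",
              x$angle_deg, x$c2_deviation_deg, x$axis[1], x$axis[2], x$axis[3],
              if (!is.na(x$membrane_parallel_tilt_deg))
                sprintf(", tilt out of membrane plane %.2f deg",
                        x$membrane_parallel_tilt_deg) else ""))
  invisible(x)
}

#' Axis of a helical segment
#'
#' First principal direction of the segment's C-alpha coordinates, oriented
#' N-terminus to C-terminus so tilt angles are signed-comparable.
#'
#' @param coords n x 3 coordinate matrix (n >= 6).
#' @return Unit 3-vector.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 6L) stop("helix segment must have at least 6 residues")
  cc <- sweep(coords, 2, colMeans(coords))
  ax <- svd(cc, nu = 0)$v[, 1]
  if (sum(ax * (coords[nrow(coords), ] - coords[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

angle_deg <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

#' Per-helix membrane tilts and symmetry-breaking differences
#'
#' Computes each labelled helix's tilt against the membrane normal and, for
#' helix labels present in both halves, the angle between the N-half helix
#' axis (mapped through the half-to-half superposition) and the corresponding
#' C-half axis. Large differences flag symmetry breaking of that helix.
#'
#' @param alignment A `"structaln"` of the N-half (`a`) against the C-half
#'   (`b`), e.g. from [scan_splits()].
#' @param segments data.frame with columns `label`, `half` (`"N"` or `"C"`),
#'   `from`, `to` (inclusive author residue ids within the respective half).
#'   Each segment must span >= 6 residues.
#' @param frame A [membrane_frame()].
#' @return data.frame with one row per label: `tilt_n_deg`, `tilt_c_deg`
#'   (tilt vs the membrane normal; NA if that half lacks the segment) and
#'   `n_to_c_angle_deg` (after mapping the N-half axis through the
#'   superposition).
#' @export
helix_tilts <- function(alignment, segments, frame) {
  stopifnot(inherits(alignment, "structaln"), inherits(frame, "membrane_frame"),
            all(c("label", "half", "from", "to") %in% names(segments)))
  seg_axis <- function(tr, from, to) {
    sel <- tr$residue_ids >= from & tr$residue_ids <= to
    if (sum(sel) < 6L)
      stop("segment ", from, "-", to, " has fewer than 6 residues")
    helix_axis(tr$coords[sel, , drop = FALSE])
  }
  labs <- unique(segments$label)
  out <- data.frame(label = labs, tilt_n_deg = NA_real_, tilt_c_deg = NA_real_,
                    n_to_c_angle_deg = NA_real_)
  r <- alignment$superposition$rotation
  for (i in seq_along(labs)) {
    sn <- segments[segments$label == labs[i] & toupper(segments$half) == "N", ]
    sc <- segments[segments$label == labs[i] & toupper(segments$half) == "C", ]
    ax_n <- ax_c <- NULL
    if (nrow(sn)) {
      ax_n <- seg_axis(alignment$a, sn$from[1], sn$to[1])
      out$tilt_n_deg[i] <- angle_deg(ax_n, frame$normal)
    }
    if (nrow(sc)) {
      ax_c <- seg_axis(alignment$b, sc$from[1], sc$to[1])
      out$tilt_c_deg[i] <- angle_deg(ax_c, frame$normal)
    }
    if (!is.null(ax_n) && !is.null(ax_c))
      out$n_to_c_angle_deg[i] <- angle_deg(as.numeric(r %*% ax_n), ax_c)
  }
  out
}

#' Count fold connectivities of a pseudosymmetric architecture
#'
#' Number of distinct ways TM helices could be connected given the
#' architecture: `n_in! * n_out! * n_prepend` — orderings of the helices
#' entering from the cytoplasmic side, times orderings of those on the other
#' side, times the number of helices to which a peripheral helix H0 could be
#' prepended.
#'
#' @param n_in,n_out,n_prepend Non-negative integer counts (`0! = 1`).
#' @return Integer count.
#' @seealso [enumerate_connectivities()] for the explicit enumeration.
#' @export
count_connectivities <- function(n_in, n_out, n_prepend) {
  for (v in c(n_in, n_out, n_prepend))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop("architecture counts must be non-negative integers")
  factorial(n_in) * factorial(n_out) * n_prepend
}

all_permutations <- function(n) {
  if (n <= 1L) return(list(seq_len(n)))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Enumerate fold connectivities explicitly
#'
#' Generates every (in-helix ordering, out-helix ordering, H0 prepend target)
#' triple and counts them; provided as the brute-force cross-check of
#' [count_connectivities()].
#'
#' @inheritParams count_connectivities
#' @param list_all Return the triples themselves instead of the count.
#' @return Integer count, or (with `list_all = TRUE`) a list of triples.
#' @export
enumerate_connectivities <- function(n_in, n_out, n_prepend, list_all = FALSE) {
  if (max(n_in, n_out) > 7L) stop("enumeration capped at 7 helices per side")
  pin <- all_permutations(n_in)
  pout <- all_permutations(n_out)
  count <- 0L
  out <- if (list_all) vector("list", 0) else NULL
  for (a in pin) for (b in pout) for (h in seq_len(n_prepend)) {
    count <- count + 1L
    if (list_all)
      out[[count]] <- list(in_order = a, out_order = b, prepend_to = h)
  }
  if (list_all) out else count
}
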