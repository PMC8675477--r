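# Percent-identity statistics, shuffled permutation null, excess identity.
#
# Identity definition used throughout: identical residues divided by columns
# where both rows carry a non-gap residue, x 100. 'X' (unknown residue) never
# counts as a match. In "pairwise_realign" mode each pair is globally
# re-aligned first (BLOSUM62, affine gaps 10/0.5, via Biostrings) before the
# same column rule is applied — the common behaviour of all-against-all
# identity matrices reported by alignment servers.

pair_identity_chars <- function(va, vb) {
  ok <- va != "-" & vb != "-"
  denom <- sum(ok)
  if (denom == 0L) return(NA_real_)
  100 * sum(ok & va == vb & va != "X") / denom
}

realign_pair <- function(sa, sb) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  va <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  vb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pair_identity_chars(va, vb)
}

#' All-against-all cross-group percent identity
#'
#' @param m An [msa()] with group labels.
#' @param group_a,group_b Group labels (cross-group pairs only; `a x b`
#'   comparisons).
#' @param mode `"from_msa"` (columns of the given alignment) or
#'   `"pairwise_realign"` (each pair globally re-aligned first).
#' @return Object of class `"identity_summary"`: `mean_pct`, `sd_pct`,
#'   `n_pairs`, `mode`, and the full `matrix` (rows = group a, cols = group
#'   b; NA for pairs with no co-occupied columns, which are skipped with a
#'   warning).
#' @export
pairwise_identity <- function(m, group_a, group_b,
                              mode = c("from_msa", "pairwise_realign")) {
  mode <- match.arg(mode)
  ia <- msa_group_rows(m, group_a)
  ib <- msa_group_rows(m, group_b)
  mat <- matrix(NA_real_, length(ia), length(ib),
                dimnames = list(m$ids[ia], m$ids[ib]))
  if (mode == "from_msa") {
    mm <- as.matrix(m)
    for (i in seq_along(ia)) {
      va <- mm[ia[i], ]
      for (j in seq_along(ib)) mat[i, j] <- pair_identity_chars(va, mm[ib[j], ])
    }
  } else {
    da <- degap(m$rows[ia]); db <- degap(m$rows[ib])
    for (i in seq_along(ia))
      for (j in seq_along(ib)) mat[i, j] <- realign_pair(da[i], db[j])
  }
  vals <- mat[!is.na(mat)]
  if (length(vals) == 0L) stop("no comparable pairs between the groups")
  if (anyNA(mat)) warning(sum(is.na(mat)),
                          " pair(s) had no co-occupied columns; skipped")
  structure(list(mean_pct = mean(vals),
                 sd_pct = if (length(vals) > 1L) sd(vals) else 0,
                 n_pairs = length(vals), mode = mode, matrix = mat),
            class = "identity_summary")
}

#' @export
print.identity_summary <- function(x, ...) {
  cat(sprintf("<identity_summary> %.1f +/- %.1f %% (s.d.) over %d pairs [%s]\n",
              x$mean_pct, x$sd_pct, x$n_pairs, x$mode))
  invisible(x)
}

#' Shuffled-sequence identity null
#'
#' Estimates the identity expected between unrelated sequences of the same
#' compositions: every sequence is residue-shuffled (uniform permutation;
#' composition preserved exactly), cross-group identities are recomputed, and
#' the results are pooled over `n_reps` shuffles. In `"pairwise_realign"` mode
#' the shuffled sequences are re-aligned pair by pair (as when the observed
#' identities come from an alignment server, where alignment itself inflates
#' the null above the raw composition expectation); in `"from_msa"` mode
#' residues are permuted within each row's non-gap positions.
#'
#' @inheritParams pairwise_identity
#' @param n_reps Shuffles per sequence (>= 1).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Object of class `"null_summary"`: `mean_pct`, `sd_pct`, `n_reps`,
#'   `seed`, `mode`.
#' @export
shuffled_identity_null <- function(m, group_a, group_b, n_reps = 10L,
                                   seed = 1L,
                                   mode = c("from_msa", "pairwise_realign")) {
  mode <- match.arg(mode)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  vals <- with_seed(seed, {
    out <- numeric(0)
    for (r in seq_len(n_reps)) {
      sh <- m
      sh$rows <- vapply(m$rows, shuffle_residues, character(1),
                        preserve_gaps = TRUE, USE.NAMES = FALSE)
      s <- suppressWarnings(pairwise_identity(sh, group_a, group_b, mode))
      out <- c(out, s$matrix[!is.na(s$matrix)])
    }
    out
  })
  structure(list(mean_pct = mean(vals),
                 sd_pct = if (length(vals) > 1L) sd(vals) else 0,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 mode = mode),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "<null_summary> %.1f +/- %.1f %% (s.d.), %d shuffle rep(s), seed %d [%s]\n",
    x$mean_pct, x$sd_pct, x$n_reps, x$seed, x$mode))
  invisible(x)
}

#' Excess identity over the shuffled null
#'
#' Converts the observed-minus-null mean identity into a residue count per
#' `per_length` residues, rounded to the nearest integer (halves down). A
#' negative excess is allowed and flagged.
#'
#' @param observed An `"identity_summary"` or a mean percent identity.
#' @param null A `"null_summary"` or a mean percent identity.
#' @param per_length Reference length in residues (>= 1).
#' @return Integer residue count, with attribute `excess_pct` (the raw
#'   difference in points) and, when negative, attribute `negative = TRUE`.
#' @export
excess_identity <- function(observed, null, per_length) {
  if (per_length < 1) stop("per_length must be >= 1")
  obs <- if (inherits(observed, "identity_summary")) observed$mean_pct
         else as.numeric(observed)
  nul <- if (inherits(null, "null_summary")) null$mean_pct else as.numeric(null)
  x <- (obs - nul) / 100 * per_length
  res <- ceiling(x - 0.5)   # round half-down
  attr(res, "excess_pct") <- obs - nul
  if (res < 0) attr(res, "negative") <- TRUE
  res
}
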