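# Column conservation, consensus sequences, and logo information content.
#
# Conservation here is an entropy-based score, NOT a phylogenetic rate model
# (no tree is used): it measures column variability only, and is labelled as
# such in all outputs.

column_freqs <- function(col) {
  res <- col[col != "-"]
  if (length(res) == 0L) return(NULL)
  tab <- table(factor(res, levels = c(AA20, "X")))
  tab / sum(tab)
}

#' Entropy-based per-column conservation
#'
#' For each column, the Shannon entropy of the non-gap residue frequencies is
#' rescaled to `conservation = 1 - H / log(20)` in `[0, 1]` (1 = invariant,
#' 0 = uniform over the 20 amino acids). Columns with more than 50% gaps are
#' flagged low-confidence; all-gap columns score NA.
#'
#' @param m An [msa()] (>= 2 rows).
#' @param grades Also bin the scores into 9 conservation grades (1 =
#'   variable ... 9 = conserved), the presentation convention of conservation
#'   servers.
#' @return data.frame: `column`, `conservation`, `gap_fraction`,
#'   `low_confidence`, and optionally `grade`. Attribute `method` records the
#'   entropy stand-in.
#' @export
column_conservation <- function(m, grades = FALSE) {
  mm <- as.matrix(m)
  if (nrow(mm) < 2L) stop("conservation needs at least 2 rows")
  ncol_ <- ncol(mm)
  cons <- gapf <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    col <- mm[, j]
    gapf[j] <- mean(col == "-")
    f <- column_freqs(col)
    if (is.null(f)) { cons[j] <- NA_real_; next }
    p <- f[f > 0]
    h <- -sum(p * log(p))
    cons[j] <- 1 - h / log(20)
  }
  out <- data.frame(column = seq_len(ncol_), conservation = cons,
                    gap_fraction = gapf,
                    low_confidence = gapf > 0.5 | is.na(cons))
  if (grades)
    out$grade <- ifelse(is.na(cons), NA_integer_,
                        pmin(9L, 1L + as.integer(floor(pmax(0, cons) * 9))))
  attr(out, "method") <- "shannon-entropy (not a phylogenetic model)"
  out
}

#' Consensus sequence of an MSA (or one group)
#'
#' Per column, the most frequent non-gap residue; ties are broken
#' lexicographically and flagged; a gap never wins; all-gap columns yield
#' `"-"`.
#'
#' @param m An [msa()].
#' @param group Group label, or `"all"` (default) for every row.
#' @return Consensus string with attributes `ties` (tied column indices) and
#'   `all_gap` (all-gap column indices).
#' @export
consensus <- function(m, group = "all") {
  mm <- as.matrix(m)[msa_group_rows(m, group), , drop = FALSE]
  cons <- character(ncol(mm))
  ties <- integer(0); allgap <- integer(0)
  for (j in seq_len(ncol(mm))) {
    col <- mm[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) { cons[j] <- "-"; allgap <- c(allgap, j); next }
    tab <- sort(table(res), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    if (length(top) > 1L) ties <- c(ties, j)
    cons[j] <- sort(top)[1]
  }
  structure(paste(cons, collapse = ""), ties = ties, all_gap = allgap)
}

#' Identity between two consensus sequences over selected sites
#'
#' @param cons_a,cons_b Consensus strings of equal length (as from
#'   [consensus()]).
#' @param sites Integer vector of column positions to score (non-empty,
#'   within length).
#' @return Percent identity over the masked sites where both consensuses are
#'   non-gap ('X' never matches).
#' @export
consensus_identity <- function(cons_a, cons_b, sites) {
  if (length(sites) == 0L) stop("empty site mask")
  va <- strsplit(as.character(cons_a), "")[[1]]
  vb <- strsplit(as.character(cons_b), "")[[1]]
  if (length(va) != length(vb)) stop("consensus sequences differ in length")
  if (any(sites < 1L | sites > length(va))) stop("site mask out of range")
  pair_identity_chars(va[sites], vb[sites])
}

#' Sequence-logo information content
#'
#' Per column: `IC = log2(20) - H` bits, with `H` the Shannon entropy (base 2)
#' of the non-gap residue frequencies; residue heights are frequency x IC.
#' All-gap columns have IC 0 and are flagged.
#'
#' @param m An [msa()] (>= 2 rows).
#' @return List of class `"logo"`: `ic` (bits per column), `heights` (residues
#'   x columns matrix), `all_gap` (flagged column indices).
#' @export
logo_information <- function(m) {
  mm <- as.matrix(m)
  if (nrow(mm) < 2L) stop("logo needs at least 2 rows")
  nc <- ncol(mm)
  ic <- numeric(nc)
  heights <- matrix(0, length(AA20) + 1L, nc,
                    dimnames = list(c(AA20, "X"), NULL))
  allgap <- integer(0)
  for (j in seq_len(nc)) {
    f <- column_freqs(mm[, j])
    if (is.null(f)) { allgap <- c(allgap, j); next }
    p <- f[f > 0]
    h2 <- -sum(p * log2(p))
    ic[j] <- log2(20) - h2
    heights[, j] <- as.numeric(f) * ic[j]
  }
  structure(list(ic = ic, heights = heights, all_gap = allgap),
            class = "logo")
}

#' @export
print.logo <- function(x, ...) {
  cat(sprintf("<logo> %d columns, IC range [%.2f, %.2f] bits\n",
              length(x$ic), min(x$ic), max(x$ic)))
  invisible(x)
}
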