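# Sequence-based membrane-topology profiling: hydropathy windows, charge
# tracks, hydrophobic-segment calling, and the length-vs-TMH-count histogram.

# Kyte-Doolittle hydropathy scale; 'X' (unknown) scores 0.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Moving-window hydropathy profile
#'
#' Centred moving average of per-residue Kyte-Doolittle values over an odd
#' window (default 9 residues). Positions without a full window are omitted,
#' matching a plotted moving average.
#'
#' @param seq Protein sequence (string or character vector).
#' @param window Odd window width, `<= nchar(seq)` (default 9).
#' @param scale Named per-residue scale (default the Kyte-Doolittle values;
#'   must cover the 20 amino acids, `X` scores 0 if absent).
#' @return Object of class `"hydropathy_profile"`: `positions` (centre
#'   residue indices), `values`, `window`, `scale_name`, `sequence`.
#' @export
hydropathy_profile <- function(seq, window = 9L, scale = KD_SCALE) {
  ch <- if (length(seq) > 1L) toupper(seq) else strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) stop("window exceeds sequence length")
  if (!"X" %in% names(scale)) scale <- c(scale, X = 0)
  bad <- setdiff(unique(ch), names(scale))
  if (length(bad)) stop("residues outside the scale alphabet: ",
                        paste(bad, collapse = ", "))
  v <- unname(scale[ch])
  vals <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  half <- (window - 1L) / 2L
  keep <- (half + 1L):(n - half)
  structure(list(positions = keep, values = vals[keep], window = window,
                 scale_name = if (identical(scale, c(KD_SCALE))) "Kyte-Doolittle"
                              else "custom",
                 sequence = paste(ch, collapse = "")),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %d positions (window %d, %s), range [%.2f, %.2f]\n",
              length(x$values), x$window, x$scale_name, min(x$values),
              max(x$values)))
  invisible(x)
}

#' Charged-residue track
#'
#' Positions of positively (K, R) and negatively (D, E) charged residues;
#' histidine is excluded (the minimal conventional charge set).
#'
#' @param seq Protein sequence.
#' @return List: `positive`, `negative` (1-based positions).
#' @export
charge_track <- function(seq) {
  ch <- if (length(seq) > 1L) toupper(seq) else strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(ch), MSA_ALPHABET)
  if (length(bad)) stop("illegal residues: ", paste(bad, collapse = ", "))
  list(positive = which(ch %in% c("K", "R")),
       negative = which(ch %in% c("D", "E")))
}

#' Call hydrophobic (putative transmembrane) segments
#'
#' Maximal runs of profile positions at or above `threshold` that span at
#' least `min_len` positions are reported as candidate TM helices. This is an
#' explicitly heuristic threshold caller — a stand-in for an HMM topology
#' predictor, useful for profiling and simulation, and its output makes no
#' claim to reproduce any particular predictor's.
#'
#' @param profile A [hydropathy_profile()].
#' @param threshold Hydropathy threshold (default 1.6).
#' @param min_len Minimum run length in profile positions (default 15).
#' @return data.frame of segments (`from`, `to` in residue positions of the
#'   window centres, `length`), with attribute `n_tmh` = number of segments.
#' @export
call_tm_segments <- function(profile, threshold = 1.6, min_len = 15L) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  above <- profile$values >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_len
  out <- data.frame(from = profile$positions[starts[ok]],
                    to = profile$positions[ends[ok]],
                    length = r$lengths[ok])
  attr(out, "n_tmh") <- nrow(out)
  out
}

#' Count heuristic TM segments in a sequence
#'
#' Convenience wrapper: [hydropathy_profile()] then [call_tm_segments()].
#'
#' @inheritParams hydropathy_profile
#' @inheritParams call_tm_segments
#' @return Integer segment count (0 when the sequence is shorter than the
#'   window).
#' @export
count_tmh <- function(seq, window = 9L, threshold = 1.6, min_len = 15L) {
  n <- if (length(seq) > 1L) length(seq) else nchar(seq)
  if (n < window) return(0L)
  nrow(call_tm_segments(hydropathy_profile(seq, window), threshold, min_len))
}

#' Length vs TMH-count 2-D histogram
#'
#' Bins integral-membrane-protein records by length (half-open bins of
#' `bin_width` residues, `[k*w, (k+1)*w)`) and TMH count. Contour levels at
#' multiples of `contour_step` proteins per bin are provided for rendering.
#'
#' @param records data.frame with columns `length` (>= 1) and `n_tmh` (>= 0),
#'   e.g. from [make_imp_set()].
#' @param bin_width Length bin width in residues (default 25).
#' @param contour_step Proteins per bin per contour (default 3).
#' @return Object of class `"tmh_hist"`: `counts` (length-bin x TMH matrix),
#'   `length_breaks`, `contour_levels`, `bin_width`, `contour_step`, `n`.
#' @export
length_tmh_histogram <- function(records, bin_width = 25L, contour_step = 3L) {
  if (NROW(records) == 0L) stop("records must be non-empty")
  stopifnot(all(c("length", "n_tmh") %in% names(records)),
            all(records$length >= 1), all(records$n_tmh >= 0))
  lb <- floor(records$length / bin_width)
  bins <- 0:max(lb)
  tmhs <- 0:max(records$n_tmh)
  counts <- table(factor(lb, levels = bins),
                  factor(records$n_tmh, levels = tmhs))
  counts <- matrix(as.integer(counts), nrow = length(bins),
                   dimnames = list(
                     length_bin = sprintf("[%d,%d)", bins * bin_width,
                                          (bins + 1L) * bin_width),
                     n_tmh = tmhs))
  mx <- max(counts)
  structure(list(counts = counts,
                 length_breaks = c(bins, max(bins) + 1L) * bin_width,
                 contour_levels = if (mx >= contour_step)
                   seq(contour_step, mx, by = contour_step) else numeric(0),
                 bin_width = bin_width, contour_step = contour_step,
                 n = NROW(records)),
            class = "tmh_hist")
}

#' @export
print.tmh_hist <- function(x, ...) {
  cat(sprintf("<tmh_hist> %d records, %d length bins x %d TMH counts (bin width %d aa, contours every %d)\n",
              x$n, nrow(x$counts), ncol(x$counts), x$bin_width, x$contour_step))
  invisible(x)
}

#' Write a hydropathy profile (and charge track) as TSV
#' @param profile A [hydropathy_profile()].
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  ct <- charge_track(profile$sequence)
  pos <- profile$positions
  df <- data.frame(position = pos,
                   aa = strsplit(profile$sequence, "")[[1]][pos],
                   hydropathy = profile$values,
                   charge = ifelse(pos %in% ct$positive, "+",
                                   ifelse(pos %in% ct$negative, "-", "")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
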