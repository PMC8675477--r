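# Seeded synthetic-data generators.
#
# Every generator is a pure function of its parameters plus seed
# (bit-reproducible) and returns the ground truth alongside the data, so
# downstream recovery tests consume only the data and compare to the truth.

# Membrane-protein-like amino-acid composition (documented default: enriched
# in L/I/V/A/F/G relative to soluble proteins). Sums to 1.
MEMBRANE_AA_FREQS <- c(A = 0.09, C = 0.01, D = 0.03, E = 0.04, F = 0.06,
                       G = 0.08, H = 0.02, I = 0.08, K = 0.04, L = 0.12,
                       M = 0.03, N = 0.03, P = 0.04, Q = 0.03, R = 0.04,
                       S = 0.06, T = 0.05, V = 0.09, W = 0.02, Y = 0.04)

sample_seq <- function(n, composition = MEMBRANE_AA_FREQS) {
  sample(names(composition), n, replace = TRUE, prob = composition)
}

# Idealised alpha-helix C-alpha coordinates: 100 deg turn and `rise` Angstrom
# per residue on a 2.3 Angstrom radius, axis along +/- z.
ideal_helix <- function(n, rise = 1.5, direction = 1, origin = c(0, 0, 0),
                        radius = 2.3) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  z <- if (direction > 0) rise * i else rise * (n - 1 - i)
  cbind(origin[1] + radius * cos(th), origin[2] + radius * sin(th),
        origin[3] + z)
}

#' Generate a synthetic C2-pseudosymmetric dimer trace
#'
#' Builds one half as an idealised antiparallel helical bundle
#' (alpha-helical geometry: 100 degrees turn and `rise` Angstrom per residue,
#' consecutive helices antiparallel at `helix_spacing`), generates the second
#' half by an exact 180-degree rotation about the planted axis (a line in the
#' membrane plane beside the bundle), joins the halves with a linker
#' interpolated between their termini, duplicates the half sequence, and adds
#' isotropic Gaussian coordinate noise. This emulates the fused antiparallel
#' homodimer from which an internally pseudosymmetric channel arises.
#'
#' The ground-truth split point is the midpoint of the linker: every split
#' inside the linker yields the same two-domain topology, and the midpoint is
#' the one a balanced-normalisation scan should recover.
#'
#' @param n_helices Helices per half (default 3).
#' @param helix_length Residues per helix (default 23, a membrane-spanning
#'   length at 1.5 Angstrom rise).
#' @param linker_length Residues joining the halves (default 10).
#' @param rise Rise per residue in Angstrom (default 1.5).
#' @param helix_spacing Distance between adjacent helix axes (default 10).
#' @param noise_sd Isotropic Gaussian noise per coordinate, Angstrom
#'   (default 0).
#' @param axis Planted C2 axis direction (default the y axis; must be a unit
#'   vector in the membrane plane for a membrane-parallel axis).
#' @param seed Integer seed.
#' @return List: `trace` (the full `"trace"`), and `truth` with `split`
#'   (ground-truth split position), `axis`, `axis_point`, `angle_deg` (180),
#'   `correspondence` (m x 2 matrix of half-to-half residue pairs), and
#'   `half_length`.
#' @export
make_c2_dimer <- function(n_helices = 3L, helix_length = 23L,
                          linker_length = 10L, rise = 1.5,
                          helix_spacing = 10, noise_sd = 0,
                          axis = c(0, 1, 0), seed = 1L) {
  stopifnot(n_helices >= 1L, helix_length >= 2L, linker_length >= 1L,
            rise > 0, helix_spacing > 0, noise_sd >= 0)
  u <- as.numeric(axis); u <- u / sqrt(sum(u^2))
  half <- do.call(rbind, lapply(seq_len(n_helices) - 1L, function(k)
    ideal_helix(helix_length, rise, direction = (-1)^k,
                origin = c(k * helix_spacing, 0, 0))))
  nh <- nrow(half)
  # 180-degree rotation about the planted axis through a point beside the
  # bundle (so the two halves do not overlap)
  perp <- crossprod_vec(u, c(0, 0, 1))
  if (sqrt(sum(perp^2)) < 1e-8) perp <- c(1, 0, 0)  # axis along z: any offset
  perp <- perp / sqrt(sum(perp^2))
  p0 <- colMeans(half) + perp * (n_helices * helix_spacing)
  r2 <- 2 * tcrossprod(u) - diag(3)
  half2 <- sweep(sweep(half, 2, p0) %*% t(r2), 2, p0, "+")
  lk <- sapply(seq_len(linker_length) / (linker_length + 1),
               function(f) half[nh, ] * (1 - f) + half2[1, ] * f)
  coords <- rbind(half, t(lk), half2)
  out <- with_seed(seed, {
    half_seq <- sample_seq(nh)
    linker_seq <- sample_seq(linker_length)
    co <- coords + rnorm(length(coords), 0, noise_sd)
    list(seq = c(half_seq, linker_seq, half_seq), coords = co)
  })
  n_total <- nh + linker_length + nh
  trace <- new_trace("A", seq_len(n_total), out$seq, out$coords)
  list(trace = trace,
       truth = list(split = nh + ceiling(linker_length / 2),
                    axis = u, axis_point = p0, angle_deg = 180,
                    correspondence = cbind(seq_len(nh),
                                           nh + linker_length + seq_len(nh)),
                    half_length = nh))
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a random-coil trace
#'
#' Fixed-step (3.8 Angstrom) random-walk C-alpha trace; a negative control
#' with no internal symmetry.
#'
#' @param n Residues.
#' @param seed Integer seed.
#' @param step Step length in Angstrom (default the C-alpha virtual bond 3.8).
#' @return A `"trace"`.
#' @export
make_random_coil <- function(n, seed = 1L, step = 3.8) {
  with_seed(seed, {
    dirs <- matrix(rnorm(3 * (n - 1)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * step
    coords <- rbind(0, apply(dirs, 2, cumsum))
    new_trace("A", seq_len(n), sample_seq(n), coords)
  })
}

#' Generate a two-group MSA with a planted cross-group identity
#'
#' Draws a group-A ancestor from `composition`; derives the group-B ancestor
#' by copying each site with a probability back-solved so that the *realised*
#' expected cross-group pairwise identity equals `cross_identity` (raw
#' copying would overshoot, because unrelated residues also coincide at rate
#' `q0 = sum(composition^2)`); rows within each group diverge from their
#' ancestor to `within_identity` expected identity by the same construction.
#' No gaps are introduced.
#'
#' @param n_rows_per_group Rows per group (default 6).
#' @param length Columns (default 200).
#' @param cross_identity Target expected cross-group pairwise identity as a
#'   fraction (default 0.125). Must be at least the composition coincidence
#'   rate `q0` and at most `within_identity^2 + (1 - within_identity^2) q0`;
#'   1 yields identical groups.
#' @param composition Named residue frequencies summing to 1 (default a
#'   membrane-protein-like mix).
#' @param within_identity Expected row-to-ancestor identity within a group
#'   (default 0.95).
#' @param seed Integer seed.
#' @return An [msa()] with groups `"A"` and `"B"` and attribute `truth`
#'   (planted parameters, the copy probabilities used, and the realised
#'   cross-group mean identity of the sample).
#' @export
make_msa_pair <- function(n_rows_per_group = 6L, length = 200L,
                          cross_identity = 0.125,
                          composition = MEMBRANE_AA_FREQS,
                          within_identity = 0.95, seed = 1L) {
  stopifnot(n_rows_per_group >= 1L, length >= 1L,
            cross_identity >= 0, cross_identity <= 1,
            abs(sum(composition) - 1) < 1e-6)
  q0 <- sum((composition / sum(composition))^2)
  if (cross_identity >= 1) {
    c_anc <- 1; c_row <- 1
  } else {
    c_row <- max(0, min(1, (within_identity - q0) / (1 - q0)))
    # realised cross identity = c_row^2 * q_anc + (1 - c_row^2) * q0,
    # with q_anc = c_anc + (1 - c_anc) * q0 the ancestor-ancestor identity
    q_anc <- (cross_identity - (1 - c_row^2) * q0) / max(c_row^2, 1e-12)
    c_anc <- max(0, min(1, (q_anc - q0) / (1 - q0)))
  }
  with_seed(seed, {
    anc_a <- sample_seq(length, composition)
    copy_from <- function(parent, p_copy) {
      keep <- runif(length) < p_copy
      out <- sample_seq(length, composition)
      out[keep] <- parent[keep]
      out
    }
    anc_b <- copy_from(anc_a, c_anc)
    rows_a <- replicate(n_rows_per_group,
                        paste(copy_from(anc_a, c_row), collapse = ""))
    rows_b <- replicate(n_rows_per_group,
                        paste(copy_from(anc_b, c_row), collapse = ""))
    m <- msa(ids = c(sprintf("A%03d", seq_len(n_rows_per_group)),
                     sprintf("B%03d", seq_len(n_rows_per_group))),
             rows = c(rows_a, rows_b),
             group = rep(c("A", "B"), each = n_rows_per_group))
    realized <- suppressWarnings(pairwise_identity(m, "A", "B"))$mean_pct / 100
    attr(m, "truth") <- list(cross_identity = cross_identity, q0 = q0,
                             copy_prob_ancestor = c_anc,
                             copy_prob_row = c_row,
                             realized_cross_identity = realized, seed = seed)
    m
  })
}

#' Sample structure-search Z-scores from the calibrated extreme-value law
#'
#' Inverse-CDF sampling from the Gumbel distribution whose upper tail
#' [z_to_p()] computes (scale `sqrt(6)/pi`, location `gamma * sqrt(6)/pi`):
#' the empirical exceedance frequency of the sample at any `z` converges to
#' `z_to_p(z)`. The sample has unit standard deviation and mean
#' `2 * gamma * sqrt(6)/pi` (about 0.90) — the location the score convention
#' implies.
#'
#' @param n Sample size (>= 1).
#' @param seed Integer seed.
#' @param cal Calibration constants (default [gumbel_calibration()]).
#' @return Numeric vector of Z-scores.
#' @export
make_gumbel_scores <- function(n, seed = 1L, cal = gumbel_calibration()) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    g <- -log(-log(runif(n)))
    cal$scale * (g + cal$offset)
  })
}

#' Sample a proteome-like set of membrane-protein records
#'
#' Lengths are log-normal; TMH counts are Poisson with rate proportional to
#' length (floored at 1), emulating the joint length/TMH-count distribution of
#' a bacterial multi-pass membrane proteome. Custom samplers override either
#' law (e.g. degenerate laws for testing).
#'
#' @param n Records (>= 1).
#' @param seed Integer seed.
#' @param length_sampler Optional `function(n)` returning lengths; default
#'   `round(rlnorm(n, log(350), 0.5))` floored at 50.
#' @param tmh_sampler Optional `function(lengths)` returning TMH counts;
#'   default `pmax(1, rpois(n, lengths / 95))`.
#' @return data.frame of class `"imp_records"`: `id`, `length`, `n_tmh`.
#' @export
make_imp_set <- function(n, seed = 1L, length_sampler = NULL,
                         tmh_sampler = NULL) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    len <- if (is.null(length_sampler)) pmax(50, round(rlnorm(n, log(350), 0.5)))
           else length_sampler(n)
    tmh <- if (is.null(tmh_sampler)) pmax(1L, rpois(n, len / 95))
           else tmh_sampler(len)
    out <- data.frame(id = sprintf("imp%05d", seq_len(n)),
                      length = as.integer(len), n_tmh = as.integer(tmh))
    class(out) <- c("imp_records", "data.frame")
    out
  })
}
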