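# C-alpha trace container and structure I/O.
#
# A trace is the atomic unit of every structural operation here: the ordered
# C-alpha coordinates of one chain segment together with its one-letter
# sequence and author residue numbering. Only C-alpha atoms are retained;
# all-atom detail is out of scope.

#' Construct a C-alpha trace
#'
#' @param chain_id Single chain identifier.
#' @param residue_ids Integer vector of author residue numbers, strictly
#'   increasing (ties allowed only via distinct insertion codes).
#' @param sequence One-letter amino-acid string (or character vector) of the
#'   same length; nonstandard residues are represented as `"X"`.
#' @param coords Numeric matrix (n x 3) of C-alpha positions in Angstrom.
#' @param insert Optional character vector of insertion codes (`""` if none);
#'   an insertion-coded residue orders after its base number.
#' @return An object of class `"trace"`.
#' @export
new_trace <- function(chain_id, residue_ids, sequence, coords, insert = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  residue_ids <- as.integer(residue_ids)
  if (is.null(insert)) insert <- rep("", length(residue_ids))
  insert[is.na(insert)] <- ""
  x <- structure(
    list(chain_id = as.character(chain_id)[1], residue_ids = residue_ids,
         insert = as.character(insert), sequence = toupper(sequence),
         coords = coords),
    class = "trace")
  validate_trace(x)
}

validate_trace <- function(x) {
  n <- length(x$residue_ids)
  if (length(x$sequence) != n || nrow(x$coords) != n)
    stop("trace fields must have equal length (residues, sequence, coords)")
  if (ncol(x$coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(x$coords))) stop("all trace coordinates must be finite")
  if (n > 1L) {
    d <- diff(x$residue_ids)
    same <- d == 0L
    if (any(d < 0L))
      stop("residue_ids must be increasing (author numbering order)")
    if (any(same)) {
      # equal numbers only legal through insertion codes, ordered after base
      ins_prev <- x$insert[-n][same]
      ins_next <- x$insert[-1L][same]
      if (any(ins_next <= ins_prev))
        stop("duplicate residue_ids without increasing insertion codes")
    }
  }
  x
}

#' @export
length.trace <- function(x) length(x$residue_ids)

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> chain %s, %d residues (%s..%s)\n", x$chain_id,
              length(x), x$residue_ids[1], x$residue_ids[length(x)]))
  invisible(x)
}

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% c(LETTERS)] <- "X"
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out[!out %in% valid] <- "X"
  out
}

#' Read a structure into C-alpha traces
#'
#' Parses a PDB or mmCIF file (via bio3d) and returns one [new_trace()] per
#' chain, keeping C-alpha atoms in author residue order. Residues without a
#' C-alpha are skipped; altloc duplicates are resolved to the highest
#' occupancy (first on tie); chains with zero C-alpha atoms are dropped with
#' a warning.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return Named list of `"trace"` objects, one per chain.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    # altloc duplicates are kept at parse time and resolved by occupancy below
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("parse error reading ", format, " file '", path,
                             "': ", conditionMessage(e)))
  atoms <- pdb$atom
  # C-alpha atoms of polymer residues; exclude calcium ions (element Ca)
  is_ca <- atoms$elety == "CA" &
    (is.na(atoms$elesy) | toupper(atoms$elesy) != "CA")
  atoms <- atoms[is_ca & is.finite(atoms$x), , drop = FALSE]
  traces <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    ins <- a$insert
    ins[is.na(ins)] <- ""
    key <- paste(a$resno, ins, sep = "_")
    # altloc resolution: highest occupancy per residue, first on tie
    occ <- a$o
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(a)), factor(key, unique(key))),
                          function(i) i[which.max(occ[i])]), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
    if (nrow(a) == 0L) {
      warning("chain ", ch, " has no C-alpha atoms; omitted")
      next
    }
    ins <- a$insert
    ins[is.na(ins)] <- ""
    traces[[as.character(ch)]] <- new_trace(
      chain_id = ch, residue_ids = a$resno,
      sequence = aa_three_to_one(a$resid),
      coords = cbind(a$x, a$y, a$z), insert = ins)
  }
  if (length(traces) == 0L) warning("no C-alpha atoms found in ", path)
  traces
}

#' Extract a (sub-)trace
#'
#' @param x A `"trace"` or a list of traces as returned by [read_structure()].
#' @param chain_id Chain to select when `x` is a list; ignored for a single
#'   trace.
#' @param residue_range `"all"`, or an inclusive `c(from, to)` pair of author
#'   residue numbers.
#' @return A `"trace"` restricted to the range, order preserved.
#' @export
get_trace <- function(x, chain_id = NULL, residue_range = "all") {
  if (inherits(x, "trace")) {
    tr <- x
    if (!is.null(chain_id) && !identical(chain_id, tr$chain_id))
      stop("lookup error: trace has chain '", tr$chain_id, "', not '",
           chain_id, "'")
  } else {
    if (is.null(chain_id)) stop("chain_id required for a multi-chain structure")
    tr <- x[[as.character(chain_id)]]
    if (is.null(tr)) stop("lookup error: unknown chain '", chain_id, "'")
  }
  if (identical(residue_range, "all")) return(tr)
  if (length(residue_range) != 2L || !is.numeric(residue_range))
    stop("residue_range must be \"all\" or c(from, to)")
  sel <- tr$residue_ids >= residue_range[1] & tr$residue_ids <= residue_range[2]
  if (!any(sel))
    stop("lookup error: empty residue range [", residue_range[1], ", ",
         residue_range[2], "] in chain ", tr$chain_id)
  new_trace(tr$chain_id, tr$residue_ids[sel], tr$sequence[sel],
            tr$coords[sel, , drop = FALSE], tr$insert[sel])
}

#' Write traces as a CA-only PDB file
#'
#' @param x A `"trace"` or list of traces; each list element is written as a
#'   separate MODEL when `models = TRUE`, otherwise concatenated.
#' @param path Output path.
#' @param models Write one MODEL record per trace (default when > 1 trace).
#' @export
write_trace_pdb <- function(x, path, models = NULL) {
  if (inherits(x, "trace")) x <- list(x)
  if (is.null(models)) models <- length(x) > 1L
  lines <- character(0)
  serial <- 0L
  for (m in seq_along(x)) {
    tr <- x[[m]]
    if (models) lines <- c(lines, sprintf("MODEL     %4d", m))
    res3 <- bio3d::aa123(tr$sequence)
    res3[tr$sequence == "X" | is.na(res3)] <- "UNK"
    for (i in seq_along(tr$residue_ids)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, res3[i], substr(tr$chain_id, 1, 1),
        tr$residue_ids[i], ifelse(tr$insert[i] == "", " ", tr$insert[i]),
        tr$coords[i, 1], tr$coords[i, 2], tr$coords[i, 3], 1, 0))
    }
    if (models) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trace as TSV (chain, resid, aa, x, y, z)
#' @param tr A `"trace"`.
#' @param path Output path.
#' @export
write_trace_tsv <- function(tr, path) {
  df <- data.frame(chain = tr$chain_id, resid = tr$residue_ids,
                   insert = tr$insert, aa = tr$sequence,
                   x = tr$coords[, 1], y = tr$coords[, 2], z = tr$coords[, 3])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a membrane reference frame
#'
#' The membrane is modelled as a hydrophobic slab of full width
#' `hydrophobic_width` centred at `midplane_z` along `normal`, flanked by two
#' interfacial layers each half the width of the hydrophobic layer. The
#' midplane can be shifted along the normal; a negative shift moves it toward
#' the cytoplasm (the convention used for the 1.8 Angstrom adjustment placing
#' a conserved arginine at the bilayer midplane).
#'
#' @param hydrophobic_width Full width of the hydrophobic layer (Angstrom, > 0).
#' @param midplane_shift Signed shift of the midplane along the normal
#'   (Angstrom; negative = toward the cytoplasm). Default 0.
#' @param normal Membrane normal vector (default z axis); normalised to unit
#'   length. Structures are assumed pre-oriented in this frame.
#' @return Object of class `"membrane_frame"` with fields `normal`,
#'   `midplane_z`, `hydrophobic_width`, `interfacial_width`.
#' @export
membrane_frame <- function(hydrophobic_width, midplane_shift = 0,
                           normal = c(0, 0, 1)) {
  if (!is.numeric(hydrophobic_width) || hydrophobic_width <= 0)
    stop("hydrophobic_width must be > 0")
  n <- as.numeric(normal)
  if (length(n) != 3L || !all(is.finite(n)) || sum(n^2) == 0)
    stop("normal must be a finite non-zero 3-vector")
  structure(list(normal = n / sqrt(sum(n^2)),
                 midplane_z = midplane_shift,
                 hydrophobic_width = hydrophobic_width,
                 interfacial_width = hydrophobic_width / 2),
            class = "membrane_frame")
}

#' Layer boundaries of a membrane frame
#'
#' @param frame A [membrane_frame()].
#' @return Named numeric vector of z positions along the normal:
#'   outer/inner edges of the interfacial layers and of the hydrophobic core.
#' @export
membrane_boundaries <- function(frame) {
  stopifnot(inherits(frame, "membrane_frame"))
  hw <- frame$hydrophobic_width / 2
  iw <- frame$interfacial_width
  z <- frame$midplane_z
  c(interfacial_lo = z - hw - iw, core_lo = z - hw,
    midplane = z, core_hi = z + hw, interfacial_hi = z + hw + iw)
}
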