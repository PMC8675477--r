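# Multiple-sequence-alignment container over the 20 amino acids, 'X' and '-'.

MSA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")
AA20 <- MSA_ALPHABET[1:20]

#' Construct an MSA
#'
#' @param ids Character vector of row labels.
#' @param rows Character vector of aligned sequences (equal length) over the
#'   20 amino acids, `"X"` and the gap `"-"`. Lowercase is uppercased and
#'   `"."` is read as a gap.
#' @param group Optional label per row (e.g. `"N"`/`"C"` half, or taxon
#'   group).
#' @return Object of class `"msa"`.
#' @export
msa <- function(ids, rows, group = NULL) {
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(ids) != length(rows)) stop("ids and rows must have equal length")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("all MSA rows must have equal length")
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                 MSA_ALPHABET)
  if (length(bad))
    stop("illegal characters in MSA: ", paste(bad, collapse = ", "))
  if (!is.null(group) && length(group) != length(rows))
    stop("group must have one label per row")
  structure(list(ids = as.character(ids), rows = rows,
                 group = if (is.null(group)) NULL else as.character(group)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns%s\n", length(x$rows),
              nchar(x$rows[1]),
              if (!is.null(x$group))
                paste0(" (groups: ", paste(unique(x$group), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @method as.matrix msa
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- x$ids
  m
}

#' Read an (aligned) FASTA file as an MSA
#'
#' @param path Path to a FASTA/aligned-FASTA file.
#' @param group_pattern Optional named character vector of regular
#'   expressions; a row's group is the name of the first pattern matching its
#'   id (NA if none).
#' @return An [msa()].
#' @export
read_msa <- function(path, group_pattern = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- names(ss)
  rows <- as.character(ss)
  group <- NULL
  if (!is.null(group_pattern)) {
    group <- rep(NA_character_, length(ids))
    for (g in names(group_pattern)) {
      hit <- is.na(group) & grepl(group_pattern[[g]], ids)
      group[hit] <- g
    }
  }
  msa(ids, rows, group)
}

#' Write an MSA as aligned FASTA
#' @param m An [msa()].
#' @param path Output path.
#' @export
write_msa <- function(m, path) {
  writeLines(as.vector(rbind(paste0(">", m$ids), m$rows)), path)
  invisible(path)
}

msa_group_rows <- function(m, group) {
  if (identical(group, "all") || is.null(group)) return(seq_along(m$rows))
  if (is.null(m$group)) stop("MSA has no group labels")
  idx <- which(m$group == group)
  if (length(idx) == 0L) stop("empty group: ", group)
  idx
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Shuffle the residues of a sequence
#'
#' Uniform random permutation of the residues; composition is preserved
#' exactly. With `preserve_gaps = TRUE` an aligned row keeps its gap
#' positions and only the residues are permuted among the non-gap positions.
#'
#' @param s A sequence string (possibly gapped).
#' @param preserve_gaps Keep gap positions fixed (default TRUE).
#' @return The shuffled string.
#' @export
shuffle_residues <- function(s, preserve_gaps = TRUE) {
  ch <- strsplit(s, "")[[1]]
  res <- which(ch != "-")
  if (length(res) > 1L) ch[res] <- ch[res][sample.int(length(res))]
  if (!preserve_gaps) ch <- ch[ch != "-"]
  paste(ch, collapse = "")
}
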