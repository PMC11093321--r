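#' Residue contact-probability maps
#'
#' A `contact_map` holds a symmetric n x n matrix `P` of contact
#' probabilities in `[0, 1]` for one protein chain, with a zero diagonal.
#' `P[i, j]` estimates whether residues `i` and `j` are spatially close in
#' the native fold, as produced by a coevolution-based contact predictor or
#' derived from 3-D coordinates. The map is the substrate for all network
#' scores: residues are nodes and pairs are edges weighted by `P[i, j]`.
#'
#' Construction symmetrizes the input as `(P + t(P)) / 2`, forces the
#' diagonal to zero, and clamps entries to `[0, 1]` with a warning; entries
#' beyond a 0.01 clamp tolerance are an error. Residue indices are 1-based:
#' matrix row `i` is sequence position `index_offset + i - 1`.
#'
#' @param P Square numeric matrix of contact probabilities.
#' @param protein_id Character identifier for the chain.
#' @param source_tag Short label for the provenance of the probabilities
#'   (e.g. `"dmp"`, `"raptorx"`, `"spot"`, `"structure"`, `"synthetic"`).
#' @param index_offset Sequence position of matrix row 1 (default 1).
#'
#' @return An object of class `contact_map` with elements `protein_id`,
#'   `P`, `n_residues`, `source_tag`, and `index_offset`.
#' @seealso [load_contact_map()], [contact_map_from_coordinates()],
#'   [prune_to_unweighted()], [score_protein()]
#' @export
#' @examples
#' P <- matrix(c(0, .5, 0, .5, 0, .2, 0, .2, 0), 3, 3)
#' cm <- contact_map(P, "toy")
#' cm$n_residues
contact_map <- function(P, protein_id, source_tag = "unknown", index_offset = 1L) {
  if (!is.matrix(P) || !is.numeric(P)) {
    stop_hotspotr("`P` must be a numeric matrix.", "hotspotr_validation_error")
  }
  if (nrow(P) != ncol(P)) {
    stop_hotspotr(
      sprintf("Contact matrix must be square, got %d x %d.", nrow(P), ncol(P)),
      "hotspotr_shape_error"
    )
  }
  if (anyNA(P) || any(!is.finite(P))) {
    stop_hotspotr("Contact matrix contains non-finite values.",
                  "hotspotr_validation_error")
  }
  if (any(P < -0.01) || any(P > 1.01)) {
    bad <- range(P)
    stop_hotspotr(
      sprintf("Contact probabilities outside [-0.01, 1.01] (range %.4g .. %.4g).",
              bad[1], bad[2]),
      "hotspotr_validation_error"
    )
  }
  P <- (P + t(P)) / 2
  diag(P) <- 0
  if (any(P < 0) || any(P > 1)) {
    warn("Contact probabilities clamped to [0, 1].")
    P[P < 0] <- 0
    P[P > 1] <- 1
  }
  dimnames(P) <- NULL
  structure(
    list(
      protein_id = as.character(protein_id),
      P = P,
      n_residues = nrow(P),
      source_tag = as.character(source_tag),
      index_offset = as.integer(index_offset)
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s [%s]: %d residues, mean P = %.3f\n",
              x$protein_id, x$source_tag, x$n_residues, mean(x$P)))
  invisible(x)
}

#' Read a contact-probability map from a predictor output file
#'
#' Supports two dialects: `"rr"`, the CASP-RR residue-pair record format
#' (`i j d_low d_high p` with 1-based `i < j`; optional `PFRMAT`/`TARGET`/
#' `MODEL`/`END` header lines and plain sequence lines are ignored), and
#' `"matrix"`, a dense whitespace-delimited n x n numeric grid. Pairs not
#' listed in an RR file default to probability 0. Asymmetric input is
#' averaged, and the diagonal forced to zero.
#'
#' @param path Path to the file.
#' @param format `"rr"` or `"matrix"`.
#' @param protein_id Identifier for the resulting map.
#' @param n_residues Chain length; for `"rr"` files it defaults to the
#'   length of an embedded sequence line if present, else the largest
#'   residue index seen. Ignored for `"matrix"`.
#' @param source_tag Provenance label stored on the map.
#'
#' @return A [contact_map()].
#' @export
load_contact_map <- function(path, format = c("rr", "matrix"), protein_id,
                             n_residues = NULL, source_tag = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_hotspotr(sprintf("File not found: %s", path), "hotspotr_io_error")
  }
  P <- switch(format,
    rr = parse_rr_file(path, n_residues),
    matrix = parse_matrix_file(path)
  )
  contact_map(P, protein_id = protein_id, source_tag = source_tag)
}

parse_rr_file <- function(path, n_residues = NULL) {
  lines <- readLines(path, warn = FALSE)
  seq_len_seen <- 0L
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)", line)) next
    if (grepl("^[A-Za-z]+$", line)) { # sequence line(s)
      seq_len_seen <- seq_len_seen + nchar(line)
      next
    }
    fields <- strsplit(line, "\\s+")[[1]]
    if (length(fields) < 5L || anyNA(suppressWarnings(as.numeric(fields[1:5])))) {
      stop_hotspotr(sprintf("Malformed RR record at line %d: '%s'", ln, line),
                    "hotspotr_parse_error")
    }
    recs[[length(recs) + 1L]] <- as.numeric(fields[1:5])
  }
  if (length(recs) == 0L && is.null(n_residues) && seq_len_seen == 0L) {
    stop_hotspotr("RR file contains no contact records and chain length is unknown.",
                  "hotspotr_parse_error")
  }
  recs <- do.call(rbind, recs)
  n <- n_residues %||% (if (seq_len_seen > 0L) seq_len_seen else max(recs[, 1:2]))
  n <- as.integer(n)
  P <- matrix(0, n, n)
  if (!is.null(recs)) {
    if (any(recs[, 1:2] < 1) || any(recs[, 1:2] > n)) {
      stop_hotspotr(sprintf("RR record indexes residue outside 1..%d.", n),
                    "hotspotr_parse_error")
    }
    i <- recs[, 1]; j <- recs[, 2]
    P[cbind(i, j)] <- recs[, 5]
    P[cbind(j, i)] <- recs[, 5]
  }
  P
}

parse_matrix_file <- function(path) {
  rows <- lapply(strsplit(trimws(readLines(path, warn = FALSE)), "\\s+"),
                 function(f) suppressWarnings(as.numeric(f)))
  rows <- rows[vapply(rows, length, 1L) > 0L]
  widths <- unique(vapply(rows, length, 1L))
  if (length(widths) != 1L || widths != length(rows)) {
    stop_hotspotr(
      sprintf("Matrix file is not square: %d rows, widths %s.",
              length(rows), paste(widths, collapse = ", ")),
      "hotspotr_shape_error"
    )
  }
  if (anyNA(unlist(rows))) {
    stop_hotspotr("Matrix file contains non-numeric entries.", "hotspotr_parse_error")
  }
  do.call(rbind, rows)
}

#' Derive a contact map from residue coordinates with a logistic soft cutoff
#'
#' Converts pairwise C-alpha distances `d_ij` (in Angstrom) to contact
#' probabilities via `P_ij = 1 / (1 + exp(d_ij - soft_cutoff))`, so a pair
#' at exactly the cutoff distance has probability 0.5 and probability decays
#' smoothly (rather than as a hard sphere) with distance.
#'
#' @param coords A data frame with columns `residue_index`, `x`, `y`, `z`
#'   (Angstrom), e.g. from [read_pdb_ca()] or [sample_chain_coordinates()].
#' @param soft_cutoff Soft cutoff distance in Angstrom (default 10).
#' @param protein_id Identifier; defaults to the `protein_id` attribute of
#'   `coords` if present.
#'
#' @return A [contact_map()] with `source_tag = "structure"`.
#' @export
contact_map_from_coordinates <- function(coords, soft_cutoff = 10,
                                         protein_id = NULL) {
  coords <- as_residue_coordinates(coords)
  assert_scalar_number(soft_cutoff, "soft_cutoff")
  if (nrow(coords) < 2L) {
    stop_hotspotr("At least 2 residues are required.", "hotspotr_validation_error")
  }
  if (anyDuplicated(coords$residue_index)) {
    stop_hotspotr("Duplicate residue_index in coordinates.",
                  "hotspotr_validation_error")
  }
  protein_id <- protein_id %||% attr(coords, "protein_id") %||% "structure"
  d <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  P <- 1 / (1 + exp(d - soft_cutoff))
  diag(P) <- 0
  contact_map(P, protein_id = protein_id, source_tag = "structure",
              index_offset = min(coords$residue_index))
}

as_residue_coordinates <- function(coords) {
  coords <- as_tibble(as.data.frame(coords))
  need <- c("residue_index", "x", "y", "z")
  if (!all(need %in% names(coords))) {
    stop_hotspotr(
      sprintf("Coordinates need columns %s.", paste(need, collapse = ", ")),
      "hotspotr_validation_error"
    )
  }
  if (anyNA(coords[need]) || any(!is.finite(as.matrix(coords[, c("x", "y", "z")])))) {
    stop_hotspotr("Coordinates contain non-finite values.", "hotspotr_validation_error")
  }
  if (is.unsorted(coords$residue_index, strictly = TRUE)) {
    stop_hotspotr("residue_index must be strictly increasing.",
                  "hotspotr_validation_error")
  }
  coords
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha atom per residue from the ATOM records of a
#' single-chain PDB file.
#'
#' @param path Path to a PDB file.
#' @param protein_id Identifier; defaults to the file name without extension.
#'
#' @return A tibble with columns `residue_index`, `x`, `y`, `z` and a
#'   `protein_id` attribute, suitable for [contact_map_from_coordinates()].
#' @export
read_pdb_ca <- function(path, protein_id = NULL) {
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[ca$atom, ]
  at <- at[!duplicated(at$resno), ]
  out <- tibble(
    residue_index = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z
  )
  out <- out[order(out$residue_index), ]
  attr(out, "protein_id") <- protein_id %||%
    sub("\\.[^.]*$", "", basename(path))
  out
}

#' Prune a weighted contact map to an unweighted network
#'
#' Edges with `P_ij < cutoff` are removed and the remaining edges get
#' weight 1. Backbone pairs `(i, i + 1)` are always kept so the resulting
#' graph is connected, which several path-based centralities require.
#'
#' @param map A [contact_map()].
#' @param cutoff Probability cutoff in `(0, 1]`; pairs at or above it are
#'   kept (default 0.1, i.e. the strict `P_ij < 0.1` removal rule).
#'
#' @return An object of class `binary_network` with a 0/1 `adjacency`
#'   matrix, `protein_id`, `n_residues`, and `pruning_cutoff`.
#' @export
prune_to_unweighted <- function(map, cutoff = 0.1) {
  stopifnot(inherits(map, "contact_map"))
  assert_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff > 1) {
    stop_hotspotr("`cutoff` must be in (0, 1].", "hotspotr_validation_error")
  }
  n <- map$n_residues
  A <- (map$P >= cutoff) * 1
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- 1
  A[cbind(idx + 1L, idx)] <- 1
  diag(A) <- 0
  structure(
    list(
      protein_id = map$protein_id,
      adjacency = A,
      n_residues = n,
      pruning_cutoff = cutoff
    ),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s: %d residues, %d edges (cutoff %.2f)\n",
              x$protein_id, x$n_residues, sum(x$adjacency) / 2, x$pruning_cutoff))
  invisible(x)
}

#' Write a contact map as a dense matrix or edge list
#'
#' `write_contact_matrix()` emits the full n x n grid with enough digits to
#' round-trip doubles exactly; `write_edge_list()` emits a TSV of 1-based
#' pairs `i`, `j`, `p` for the upper triangle with `p > 0`.
#'
#' @param map A [contact_map()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_contact_matrix <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  lines <- apply(map$P, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
write_edge_list <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  ut <- which(upper.tri(map$P) & map$P > 0, arr.ind = TRUE)
  df <- data.frame(
    i = ut[, 1], j = ut[, 2],
    p = sprintf("%.17g", map$P[ut])
  )
  df <- df[order(df$i, df$j), ]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Tidy a contact map into an edge tibble
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble with one row per unordered residue pair with nonzero
#'   probability: `protein_id`, `i`, `j`, `p`.
#' @export
tidy.contact_map <- function(x, ...) {
  ut <- which(upper.tri(x$P) & x$P > 0, arr.ind = TRUE)
  tibble(
    protein_id = x$protein_id,
    i = as.integer(ut[, 1]), j = as.integer(ut[, 2]),
    p = x$P[ut]
  ) |> dplyr::arrange(.data$i, .data$j)
}
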