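#' Assemble a per-site feature table from score tables and variant labels
#'
#' Joins long-format score tables (one or more sources per protein) with
#' per-site variant labels into a wide modelling table: one row per labelled
#' site, one column per `source:score` combination holding the
#' percentile-normalized value, plus optional external per-site score
#' columns (e.g. protein-language-model variant scores) carried through
#' as-is.
#'
#' @param scores A long score tibble ([score_protein()] output, possibly
#'   several proteins/sources bound with `dplyr::bind_rows()`).
#' @param labels A tibble with columns `protein_id`, `residue` (1-based) and
#'   `label` (1 = deleterious, 0 = neutral, or the strings
#'   `"deleterious"`/`"neutral"`).
#' @param score_set Optional character vector restricting the score names
#'   used (e.g. `c("W1","W2","W3","Winf","Ws","MSF","dlambda")` for the
#'   degree/GNM-only ablation).
#' @param sources Optional character vector restricting the sources used.
#' @param external Optional tibble of extra per-site feature columns keyed
#'   by `protein_id`, `residue`.
#'
#' @return A tibble with columns `protein_id`, `residue`, `label` and one
#'   numeric column per feature, named `"{source}:{score}"`.
#' @export
assemble_feature_table <- function(scores, labels, score_set = NULL,
                                   sources = NULL, external = NULL) {
  scores <- as_tibble(scores)
  labels <- normalize_labels(labels)
  if (!is.null(score_set)) {
    missing_scores <- setdiff(score_set, unique(scores$score))
    if (length(missing_scores) > 0) {
      stop_hotspotr(sprintf("Requested scores absent from score table: %s",
                            paste(missing_scores, collapse = ", ")),
                    "hotspotr_validation_error")
    }
    scores <- dplyr::filter(scores, .data$score %in% score_set)
  }
  if (!is.null(sources)) {
    missing_sources <- setdiff(sources, unique(scores$source))
    if (length(missing_sources) > 0) {
      stop_hotspotr(sprintf("Requested sources absent from score table: %s",
                            paste(missing_sources, collapse = ", ")),
                    "hotspotr_validation_error")
    }
    scores <- dplyr::filter(scores, .data$source %in% sources)
  }

  # every labelled site must index a residue present in every source
  ranges <- scores |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(lo = min(.data$residue), hi = max(.data$residue),
                     .groups = "drop")
  chk <- dplyr::left_join(labels, ranges, by = "protein_id")
  if (anyNA(chk$lo)) {
    stop_hotspotr(sprintf("Labelled proteins without score tables: %s",
                          paste(unique(chk$protein_id[is.na(chk$lo)]), collapse = ", ")),
                  "hotspotr_validation_error")
  }
  bad <- chk$residue < chk$lo | chk$residue > chk$hi
  if (any(bad)) {
    off <- chk[bad, c("protein_id", "residue")]
    stop_hotspotr(
      sprintf("Labelled residues outside protein length: %s",
              paste(sprintf("%s:%d", off$protein_id, off$residue), collapse = ", ")),
      "hotspotr_validation_error"
    )
  }

  wide <- scores |>
    dplyr::mutate(feature = paste0(.data$source, ":", .data$score)) |>
    dplyr::select("protein_id", "residue", "feature", "percentile") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "percentile")
  out <- dplyr::inner_join(labels, wide, by = c("protein_id", "residue"))

  if (!is.null(external)) {
    external <- as_tibble(external)
    out <- dplyr::left_join(out, external, by = c("protein_id", "residue"))
  }
  feats <- feature_names(out)
  fm <- as.matrix(out[feats])
  if (anyNA(fm) || any(!is.finite(fm))) {
    stop_hotspotr("Feature table contains missing or non-finite values.",
                  "hotspotr_validation_error")
  }
  if (anyDuplicated(out[c("protein_id", "residue")])) {
    stop_hotspotr("Duplicate (protein_id, residue) rows in feature table.",
                  "hotspotr_validation_error")
  }
  out
}

normalize_labels <- function(labels) {
  labels <- as_tibble(labels)
  need <- c("protein_id", "residue", "label")
  if (!all(need %in% names(labels))) {
    stop_hotspotr(sprintf("Labels need columns %s.", paste(need, collapse = ", ")),
                  "hotspotr_validation_error")
  }
  lab <- labels$label
  if (is.character(lab) || is.factor(lab)) {
    lab <- as.character(lab)
    if (!all(lab %in% c("deleterious", "neutral"))) {
      stop_hotspotr("Character labels must be 'deleterious' or 'neutral'.",
                    "hotspotr_validation_error")
    }
    lab <- as.integer(lab == "deleterious")
  }
  if (!all(lab %in% c(0L, 1L))) {
    stop_hotspotr("Labels must be binary (0/1 or deleterious/neutral).",
                  "hotspotr_validation_error")
  }
  tibble(protein_id = as.character(labels$protein_id),
         residue = as.integer(labels$residue),
         label = as.integer(lab))
}

#' Feature column names of a site feature table
#'
#' @param table A feature table from [assemble_feature_table()].
#' @return Character vector of feature column names (everything except the
#'   `protein_id`, `residue`, `label`, and `latent_prob` bookkeeping columns).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("protein_id", "residue", "label", "latent_prob"))
}

#' Split a site feature table into train/test partitions by protein
#'
#' Sites of one protein never straddle the boundary, preventing
#' protein-level information leakage between training and evaluation.
#' Either give an explicit list of training proteins (deterministic) or a
#' training fraction with a seed (seeded-shuffle deterministic).
#'
#' @param table A feature table from [assemble_feature_table()].
#' @param train_proteins Character vector of protein ids for training.
#' @param train_fraction Fraction of proteins assigned to training
#'   (used when `train_proteins` is `NULL`).
#' @param seed Integer seed for fraction mode.
#' @return A list with tibbles `train` and `test`.
#' @export
split_by_protein <- function(table, train_proteins = NULL,
                             train_fraction = NULL, seed = 1L) {
  table <- as_tibble(table)
  prot <- unique(table$protein_id)
  if (length(prot) < 2) {
    stop_hotspotr("Need at least 2 proteins to split.", "hotspotr_validation_error")
  }
  if (is.null(train_proteins)) {
    if (is.null(train_fraction)) {
      stop_hotspotr("Give either `train_proteins` or `train_fraction`.",
                    "hotspotr_validation_error")
    }
    k <- round(train_fraction * length(prot))
    train_proteins <- with_seed(seed, sample(prot, size = k))
  } else {
    absent <- setdiff(train_proteins, prot)
    if (length(absent) > 0) {
      stop_hotspotr(sprintf("Requested train proteins absent: %s",
                            paste(absent, collapse = ", ")),
                    "hotspotr_validation_error")
    }
  }
  test_proteins <- setdiff(prot, train_proteins)
  if (length(train_proteins) == 0 || length(test_proteins) == 0) {
    stop_hotspotr("Split leaves an empty partition.", "hotspotr_validation_error")
  }
  list(
    train = dplyr::filter(table, .data$protein_id %in% train_proteins),
    test = dplyr::filter(table, .data$protein_id %in% test_proteins)
  )
}

#' Write or read a variant site label TSV
#'
#' Columns: `protein_id`, `residue` (1-based), `label`
#' (`deleterious`/`neutral`), and optionally `latent_prob` for synthetic
#' cohorts.
#'
#' @param labels Label tibble.
#' @param path File path.
#' @return `write_labels()` returns the path invisibly; `read_labels()`
#'   the tibble with an integer `label`.
#' @export
write_labels <- function(labels, path) {
  out <- as_tibble(labels)
  out$label <- ifelse(out$label == 1, "deleterious", "neutral")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  normalize_labels_keep_extra(readr::read_tsv(path, show_col_types = FALSE))
}

normalize_labels_keep_extra <- function(labels) {
  out <- normalize_labels(labels)
  extra <- setdiff(names(labels), names(out))
  dplyr::bind_cols(out, as_tibble(labels)[extra])
}

#' Write a wide feature table TSV
#'
#' @param table Feature table.
#' @param path File path.
#' @return Path (write) / tibble (read).
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$protein_id <- as.character(out$protein_id)
  out$residue <- as.integer(out$residue)
  out$label <- as.integer(out$label)
  out
}
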