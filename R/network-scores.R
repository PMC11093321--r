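#' Weighted node degrees from matrix powers of the contact map
#'
#' `power_degree()` computes, for each residue `i`, the off-diagonal row sum
#' of the n-th power of the contact-probability matrix,
#' `W_n,i = sum_{k != i} (P^n)_ik`. For `n = 1` this is the weighted node
#' degree counting nearest-neighbour interactions; larger `n` folds in
#' indirect couplings through up to `n` intermediate contacts.
#'
#' @param map A [contact_map()].
#' @param n Power of the matrix, an integer `>= 1`.
#' @return A numeric vector of length `n_residues`.
#' @seealso [limit_degree()] for the `n -> Inf` limit, [similarity_degree()].
#' @export
#' @examples
#' P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
#' power_degree(contact_map(P, "chain"), 2) # c(1, 0, 1)
power_degree <- function(map, n) {
  stopifnot(inherits(map, "contact_map"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_hotspotr("`n` must be an integer >= 1.", "hotspotr_validation_error")
  }
  Pn <- map$P
  for (k in seq_len(n - 1L)) Pn <- Pn %*% map$P
  as.numeric(rowSums(Pn) - diag(Pn))
}

#' Principal-eigenvector node degree (the infinite-power limit)
#'
#' As `n` grows, the direction of [power_degree()] converges to the
#' eigenvector of `P` with the largest eigenvalue. Returned with unit
#' Euclidean norm and the sign fixed so the entry sum is positive; in the
#' connected nonnegative regime all entries are nonnegative
#' (Perron-Frobenius).
#'
#' @param map A [contact_map()].
#' @return A unit-norm numeric vector of length `n_residues`.
#' @export
limit_degree <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (all(map$P == 0)) {
    stop_hotspotr("All-zero contact map has no principal eigenvector.",
                  "hotspotr_validation_error")
  }
  es <- eigen(map$P, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v
}

#' Node degrees of the neighbourhood-similarity network
#'
#' Builds the similarity matrix `S_ij = sum_{k != i,j} P_ik * P_jk` (how
#' strongly residues `i` and `j` share contact neighbourhoods) and returns
#' its node degrees `W_s,i = sum_{k != i} S_ik`. For a zero-diagonal
#' symmetric map this is algebraically identical to `power_degree(map, 2)`.
#'
#' @param map A [contact_map()].
#' @return A numeric vector of length `n_residues`.
#' @export
similarity_degree <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  S <- map$P %*% map$P # (P^2)_ij = sum_k P_ik P_kj; k = i, j terms vanish (zero diag)
  as.numeric(rowSums(S) - diag(S))
}

#' Within-protein percentile normalization of a score vector
#'
#' Ranks the values (average ranks for ties) and linearly maps the ranks to
#' `[0, 1]`: `(rank - 1) / (n - 1)`. The minimum maps to 0, the maximum to
#' 1, and a constant vector maps to 0.5 everywhere. Percentiles make scores
#' comparable across proteins of different sizes and scales.
#'
#' @param raw Numeric vector of finite raw scores.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
#' @examples
#' percentile_normalize(c(3, 1, 2)) # 1.0 0.0 0.5
percentile_normalize <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw) || any(!is.finite(raw))) {
    stop_hotspotr("Scores must be finite and non-missing.",
                  "hotspotr_validation_error")
  }
  n <- length(raw)
  if (n == 1L) return(0.5)
  (rank(raw, ties.method = "average") - 1) / (n - 1)
}

#' Compute the full per-residue score table for one protein
#'
#' Runs the complete node-importance panel on a contact map: the five
#' weighted-degree scores (`W1`, `W2`, `W3`, `Winf`, `Ws`), the thirteen
#' classical centralities `C1`-`C13` (see [centrality_suite()]), and the two
#' sequence-GNM dynamics scores (`MSF`, `dlambda`; see [build_kirchhoff()]).
#' Each score is reported raw and percentile-normalized within the protein.
#'
#' @param map A [contact_map()].
#' @param include `"all"` for the full 20-score panel, or `"degree_gnm"` to
#'   restrict to the 7 degree/GNM scores (skipping `C1`-`C13`), which is much
#'   faster and loses little predictive signal.
#' @param pruning_cutoff Cutoff passed to [prune_to_unweighted()] for the
#'   centralities that need an unweighted graph.
#' @return A tibble in long format with columns `protein_id`, `source`,
#'   `residue` (1-based), `score`, `raw`, `percentile`.
#' @export
score_protein <- function(map, include = c("all", "degree_gnm"),
                          pruning_cutoff = 0.1) {
  stopifnot(inherits(map, "contact_map"))
  include <- match.arg(include)
  scores <- list(
    W1 = power_degree(map, 1),
    W2 = power_degree(map, 2),
    W3 = power_degree(map, 3),
    Winf = limit_degree(map),
    Ws = similarity_degree(map)
  )
  if (include == "all") {
    net <- prune_to_unweighted(map, pruning_cutoff)
    scores <- c(scores, centrality_suite(map, net))
  }
  km <- build_kirchhoff(map)
  scores$MSF <- msf_profile(km)
  scores$dlambda <- perturbation_sensitivity(km)

  purrr::imap(scores, function(v, nm) {
    tibble(
      protein_id = map$protein_id,
      source = map$source_tag,
      residue = seq_len(map$n_residues) + map$index_offset - 1L,
      score = nm,
      raw = as.numeric(v),
      percentile = percentile_normalize(v)
    )
  }) |> purrr::list_rbind()
}

#' Write or read a long-format score table TSV
#'
#' Columns: `protein_id`, `source`, `residue` (1-based), `score`, `raw`,
#' `percentile`.
#'
#' @param scores A score tibble from [score_protein()] (or several bound
#'   together).
#' @param path File path.
#' @return `write_score_table()` returns the path invisibly;
#'   `read_score_table()` returns the tibble.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      source = readr::col_character(),
      residue = readr::col_integer(),
      score = readr::col_character(),
      raw = readr::col_double(),
      percentile = readr::col_double()
    )
  )
}
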