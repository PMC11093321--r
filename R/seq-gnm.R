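#' Sequence-based Gaussian network model (Kirchhoff matrix)
#'
#' Builds the GNM connectivity (Kirchhoff) matrix for a contact map:
#' bonded pairs `(i, i + 1)` get `K_ij = -1` to enforce local chain
#' connectivity regardless of their predicted probability, non-bonded pairs
#' get `K_ij = -P_ij`, and the diagonal is set so every row and column sums
#' to zero. The eigen-decomposition is attached; for a chain-connected map
#' the spectrum has exactly one zero mode (the rigid-body mode).
#'
#' @param map A [contact_map()] with at least 3 residues.
#' @return An object of class `kirchhoff_model` with elements `protein_id`,
#'   `K`, `eigenvalues` (nondecreasing), `eigenvectors` (orthonormal
#'   columns, matching order), and `n_zero_modes`.
#' @seealso [msf_profile()], [perturbation_sensitivity()]
#' @export
build_kirchhoff <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  n <- map$n_residues
  if (n < 3) {
    stop_hotspotr("GNM needs at least 3 residues.", "hotspotr_validation_error")
  }
  K <- -map$P
  idx <- seq_len(n - 1L)
  K[cbind(idx, idx + 1L)] <- -1
  K[cbind(idx + 1L, idx)] <- -1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  es <- eigen(K, symmetric = TRUE)
  lambda <- rev(es$values)
  V <- es$vectors[, rev(seq_len(n)), drop = FALSE]
  zero_tol <- 1e-9 * max(lambda)
  structure(
    list(
      protein_id = map$protein_id,
      K = K,
      eigenvalues = lambda,
      eigenvectors = V,
      n_zero_modes = sum(lambda < zero_tol)
    ),
    class = "kirchhoff_model"
  )
}

#' @export
print.kirchhoff_model <- function(x, ...) {
  cat(sprintf("<kirchhoff_model> %s: %d residues, %d zero mode(s), lambda_max = %.3f\n",
              x$protein_id, nrow(x$K), x$n_zero_modes, max(x$eigenvalues)))
  invisible(x)
}

#' Per-residue mean-square fluctuations from the GNM
#'
#' `MSF_i = sum_{m > 0} V_mi^2 / lambda_m`, the diagonal of the
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix (in relative units;
#' MSF is proportional to the crystallographic B-factor). Rigid,
#' low-fluctuation residues mark structural cores and hinges that are
#' sensitive to mutation.
#'
#' @param model A [build_kirchhoff()] model with exactly one zero mode.
#' @return A strictly positive numeric vector of length `n_residues`.
#' @export
msf_profile <- function(model) {
  stopifnot(inherits(model, "kirchhoff_model"))
  if (model$n_zero_modes != 1L) {
    stop_hotspotr(
      sprintf(paste0("Kirchhoff matrix has %d zero modes; the contact graph must ",
                     "be connected (backbone edges guarantee this for maps built ",
                     "by this package)."), model$n_zero_modes),
      "hotspotr_validation_error"
    )
  }
  m <- seq_along(model$eigenvalues)[-1]
  as.numeric((model$eigenvectors[, m, drop = FALSE]^2) %*%
               (1 / model$eigenvalues[m]))
}

#' First-order eigenvalue sensitivity to weakening a residue's contacts
#'
#' Measures the dynamic importance of each residue by how much the GNM
#' spectrum shifts when all of that residue's couplings are uniformly
#' weakened. Scaling the off-diagonal couplings of residue `i` by
#' `(1 - eps)` (re-balancing the diagonal) shifts mode `m` by
#' `delta_lambda_m,i = -eps * sum_{j != i} w_ij (V_mi - V_mj)^2` to first
#' order, where `w_ij = |K_ij|`. The returned score is the eps-normalized
#' magnitude summed over the non-zero modes,
#' `s_i = sum_{m > 0} sum_{j != i} w_ij (V_mi - V_mj)^2`, which is
#' independent of the perturbation size. High values flag residues whose
#' local contacts carry the vibrational spectrum — perturbation-sensitive
#' sites that mimic mutational hotspots.
#'
#' @param model A [build_kirchhoff()] model with exactly one zero mode.
#' @param epsilon Nominal perturbation fraction; must be positive. The
#'   first-order score does not depend on it (kept for the finite-difference
#'   interpretation `s_i = -delta_lambda_i / epsilon`).
#' @return A nonnegative numeric vector of length `n_residues`.
#' @export
perturbation_sensitivity <- function(model, epsilon = 1e-4) {
  stopifnot(inherits(model, "kirchhoff_model"))
  assert_scalar_number(epsilon, "epsilon")
  if (epsilon <= 0) {
    stop_hotspotr("`epsilon` must be positive.", "hotspotr_validation_error")
  }
  if (model$n_zero_modes != 1L) {
    stop_hotspotr("Perturbation analysis requires exactly one zero mode.",
                  "hotspotr_validation_error")
  }
  W <- abs(model$K)
  diag(W) <- 0
  d <- rowSums(W)
  modes <- seq_along(model$eigenvalues)[-1]
  V <- model$eigenvectors[, modes, drop = FALSE]
  # sum_m sum_j w_ij (V_mi - V_mj)^2
  #   = sum_m [ V_mi^2 d_i - 2 V_mi (W V_m)_i + (W V_m^2)_i ]
  WV <- W %*% V
  WV2 <- W %*% (V^2)
  as.numeric(rowSums(V^2 * d - 2 * V * WV + WV2))
}
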