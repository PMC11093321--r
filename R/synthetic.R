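#' Sample collapsed protein-like chain coordinates
#'
#' Generates a self-avoiding random walk with the geometry of a C-alpha
#' trace: successive residues 3.8 Angstrom apart, no non-bonded pair closer
#' than 4.0 Angstrom, and the whole chain confined to a sphere of radius
#' `radius_coef * n^(1/3)` Angstrom. The confinement compacts the chain so
#' that interior residues accumulate many non-bonded contacts (a
#' contact-rich core) while surface residues stay sparsely connected — the
#' core-versus-periphery organisation that real globular proteins show.
#' Steps are rejection-resampled, with backtracking when the walk corners
#' itself; the result is deterministic given `seed`.
#'
#' @param n_residues Chain length, 10 to 500.
#' @param seed Integer seed.
#' @param bond_length Successive-residue distance (Angstrom).
#' @param min_separation Minimum non-bonded pair distance (Angstrom).
#' @param radius_coef Confinement radius coefficient (Angstrom per
#'   `n^(1/3)`).
#' @param max_restarts Whole-chain restarts before giving up.
#' @return A tibble with columns `residue_index`, `x`, `y`, `z` and a
#'   `protein_id` attribute.
#' @export
sample_chain_coordinates <- function(n_residues, seed,
                                     bond_length = 3.8,
                                     min_separation = 4.0,
                                     radius_coef = 3.0,
                                     max_restarts = 100L) {
  if (n_residues < 10 || n_residues > 500) {
    stop_hotspotr("`n_residues` must be between 10 and 500.",
                  "hotspotr_validation_error")
  }
  radius <- radius_coef * n_residues^(1 / 3)
  xyz <- with_seed(seed, {
    res <- NULL
    for (attempt in seq_len(max_restarts)) {
      res <- grow_chain(n_residues, bond_length, min_separation, radius)
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(xyz)) {
    stop_hotspotr(
      sprintf(paste0("Could not grow a confined self-avoiding chain of length %d ",
                     "after %d restarts; increase `radius_coef`."),
              n_residues, max_restarts),
      "hotspotr_generation_error"
    )
  }
  out <- tibble(residue_index = seq_len(n_residues),
                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "protein_id") <- sprintf("synthetic_n%d_s%d", n_residues, seed)
  out
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) return(v / nv)
  }
}

grow_chain <- function(n, bond, min_sep, radius,
                       step_tries = 60L, backtrack = 5L) {
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- random_unit_vector() * runif(1, 0, radius / 2)
  i <- 2L
  stuck <- 0L
  while (i <= n) {
    placed <- FALSE
    for (k in seq_len(step_tries)) {
      cand <- xyz[i - 1L, ] + bond * random_unit_vector()
      if (sum(cand^2) > radius^2) next
      if (i > 2L) {
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (any(d2 < min_sep^2)) next
      }
      xyz[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
      stuck <- 0L
    } else {
      stuck <- stuck + 1L
      if (stuck > 20L) return(NULL)
      i <- max(2L, i - backtrack) # unwind a few steps and try a new route
    }
  }
  xyz
}

#' Corrupt a contact map with predictor-style logit noise
#'
#' Emulates the fuzziness of coevolution contact predictors: each
#' probability is perturbed on the log-odds scale with symmetric Gaussian
#' noise (`eps_ij = eps_ji`), so values stay in `(0, 1)` and saturated
#' contacts stay saturated. `noise_sigma = 0` returns the input (up to the
#' clamp at 1e-6 / 1 - 1e-6 used to keep the logit finite).
#'
#' @param true_map A [contact_map()].
#' @param noise_sigma Standard deviation of the logit-scale noise (>= 0).
#' @param seed Integer seed.
#' @param source_tag Tag for the corrupted map (default `"noisy"`).
#' @return A [contact_map()] of the same size.
#' @export
corrupt_contact_map <- function(true_map, noise_sigma, seed,
                                source_tag = "noisy") {
  stopifnot(inherits(true_map, "contact_map"))
  if (noise_sigma < 0) {
    stop_hotspotr("`noise_sigma` must be >= 0.", "hotspotr_validation_error")
  }
  n <- true_map$n_residues
  P <- pmin(pmax(true_map$P, 1e-6), 1 - 1e-6)
  eps <- matrix(0, n, n)
  ut <- upper.tri(eps)
  eps[ut] <- with_seed(seed, rnorm(sum(ut), sd = noise_sigma))
  eps <- eps + t(eps)
  Pn <- plogis(qlogis(P) + eps)
  diag(Pn) <- 0
  contact_map(Pn, protein_id = true_map$protein_id, source_tag = source_tag,
              index_offset = true_map$index_offset)
}

#' Assign synthetic deleterious/neutral labels driven by core connectivity
#'
#' Samples `sites_per_protein` residues without replacement and labels each
#' deleterious with probability
#' `plogis(intercept + beta * W1-percentile)` computed on the *true* map, so
#' the label signal is the protein's genuine core connectivity and the
#' Bayes-optimal AUC of the cohort is known exactly from the stored latent
#' probabilities.
#'
#' @param true_map A [contact_map()].
#' @param beta Slope on the W1 percentile (>= 0); 0 removes the signal.
#' @param intercept Logit-scale intercept (baseline deleterious rate).
#' @param sites_per_protein Number of sites to sample.
#' @param seed Integer seed.
#' @return A tibble with `protein_id`, `residue`, `label` (0/1), and
#'   `latent_prob`.
#' @export
assign_variant_labels <- function(true_map, beta, intercept,
                                  sites_per_protein, seed) {
  stopifnot(inherits(true_map, "contact_map"))
  if (beta < 0) {
    stop_hotspotr("`beta` must be >= 0.", "hotspotr_validation_error")
  }
  n <- true_map$n_residues
  if (sites_per_protein > n) {
    stop_hotspotr("`sites_per_protein` exceeds the number of residues.",
                  "hotspotr_validation_error")
  }
  w1_pct <- percentile_normalize(power_degree(true_map, 1))
  with_seed(seed, {
    sites <- sort(sample.int(n, sites_per_protein))
    p <- plogis(intercept + beta * w1_pct[sites])
    tibble(
      protein_id = true_map$protein_id,
      residue = sites + true_map$index_offset - 1L,
      label = rbinom(length(sites), 1L, p),
      latent_prob = p
    )
  })
}

#' Generate a synthetic cohort for the full scoring and learning pipeline
#'
#' Composes [sample_chain_coordinates()], [contact_map_from_coordinates()],
#' [corrupt_contact_map()] and [assign_variant_labels()] per protein. Each
#' protein gets a true structure-derived contact map plus one corrupted map
#' per named noise source; labels are driven by the true map's core
#' connectivity. Per-protein sub-seeds are derived by a counter-based
#' scheme, so adding proteins never perturbs earlier ones. Defaults are the
#' package's reference study conditions.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param length_range Integer min/max chain length, inclusive.
#' @param sources Named numeric vector of logit-noise standard deviations,
#'   one corrupted map per entry.
#' @param beta,intercept Label-model parameters (see
#'   [assign_variant_labels()]).
#' @param sites_per_protein Labelled sites sampled per protein.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_cohort`: list with `proteins` (each
#'   holding `coords`, `true_map`, and the list `maps` of corrupted maps),
#'   `labels` (tibble including `latent_prob`), and `params`.
#' @export
generate_cohort <- function(n_proteins = 30L,
                            length_range = c(40L, 80L),
                            sources = c(coevo1 = 1.0, coevo2 = 1.0, coevo3 = 1.0),
                            beta = 6,
                            intercept = -1.5,
                            sites_per_protein = 20L,
                            seed = 1L) {
  if (n_proteins < 2) {
    stop_hotspotr("`n_proteins` must be >= 2.", "hotspotr_validation_error")
  }
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  proteins <- purrr::map(seq_len(n_proteins), function(i) {
    len <- length_range[1] +
      (derive_seed(seed, i, 1L) %% (length_range[2] - length_range[1] + 1L))
    pid <- sprintf("prot%03d", i)
    coords <- sample_chain_coordinates(len, seed = derive_seed(seed, i, 2L))
    attr(coords, "protein_id") <- pid
    true_map <- contact_map_from_coordinates(coords, protein_id = pid)
    true_map$source_tag <- "true"
    maps <- purrr::imap(as.list(sources), function(sigma, tag) {
      j <- match(tag, names(sources))
      corrupt_contact_map(true_map, sigma, seed = derive_seed(seed, i, 10L + j),
                          source_tag = tag)
    })
    list(protein_id = pid, coords = coords, true_map = true_map, maps = maps)
  })
  labels <- purrr::map(seq_len(n_proteins), function(i) {
    assign_variant_labels(proteins[[i]]$true_map, beta = beta,
                          intercept = intercept,
                          sites_per_protein = sites_per_protein,
                          seed = derive_seed(seed, i, 3L))
  }) |> purrr::list_rbind()
  structure(
    list(
      proteins = proteins,
      labels = labels,
      params = list(
        n_proteins = n_proteins, length_range = length_range,
        sources = sources, beta = beta, intercept = intercept,
        sites_per_protein = sites_per_protein, seed = as.integer(seed)
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_cohort> %d proteins (length %d-%d), %d source(s), %d sites, seed %d\n",
              p$n_proteins, p$length_range[1], p$length_range[2],
              length(p$sources), nrow(x$labels), p$seed))
  invisible(x)
}

#' Bayes-optimal AUC of a synthetic cohort's label model
#'
#' The AUC achieved by ranking sites by their true latent deleterious
#' probability — the recoverable ceiling for any classifier trained on
#' features derived from the maps.
#'
#' @param cohort A [generate_cohort()] object.
#' @return A single number in `[0, 1]`.
#' @export
bayes_auc <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  roc_auc(cohort$labels$latent_prob, cohort$labels$label)$auc
}

#' Score every map of a synthetic cohort
#'
#' Runs [score_protein()] on each corrupted map (and optionally the true
#' maps, tagged `"true"`) and binds the results.
#'
#' @param cohort A [generate_cohort()] object.
#' @param include Score panel passed to [score_protein()].
#' @param with_true_maps Also score the noise-free maps.
#' @return A long score tibble covering all proteins and sources.
#' @export
score_cohort <- function(cohort, include = c("all", "degree_gnm"),
                         with_true_maps = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  include <- match.arg(include)
  purrr::map(cohort$proteins, function(pr) {
    maps <- pr$maps
    if (with_true_maps) maps <- c(maps, list(true = pr$true_map))
    purrr::map(maps, score_protein, include = include) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Write a synthetic cohort to disk in the pipeline's exchange formats
#'
#' Per protein: a PDB file of the chain trace (`<id>.pdb`) and one dense
#' matrix file per source (`<id>_<source>.mat`); plus `labels.tsv` and a
#' JSON echo of the generator parameters. These are the same formats the
#' production loaders read.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pr in cohort$proteins) {
    n <- nrow(pr$coords)
    bio3d::write.pdb(
      file = file.path(dir, paste0(pr$protein_id, ".pdb")),
      xyz = as.numeric(t(as.matrix(pr$coords[, c("x", "y", "z")]))),
      resno = pr$coords$residue_index,
      resid = rep("GLY", n), elety = rep("CA", n), chain = rep("A", n)
    )
    write_contact_matrix(pr$true_map,
                         file.path(dir, paste0(pr$protein_id, "_true.mat")))
    for (tag in names(pr$maps)) {
      write_contact_matrix(pr$maps[[tag]],
                           file.path(dir, paste0(pr$protein_id, "_", tag, ".mat")))
    }
  }
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(cohort$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
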