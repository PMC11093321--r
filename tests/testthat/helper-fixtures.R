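# Shared fixtures and independent oracles.

# Random symmetric zero-diagonal contact map (all entries positive, so the
# implied graph is connected).
rand_map <- function(n, seed, lo = 0.01, hi = 0.9, id = "rand") {
  withr::with_seed(seed, {
    P <- matrix(runif(n * n, lo, hi), n, n)
  })
  P <- (P + t(P)) / 2
  diag(P) <- 0
  contact_map(P, id, source_tag = "synthetic")
}

# Three-residue chain with unit backbone couplings and no long-range contact.
chain3_map <- function() {
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 1
  P[2, 3] <- P[3, 2] <- 1
  contact_map(P, "chain3")
}

# 8-node unweighted fixture graph: backbone path 1..8 plus six chords.
fixture_adjacency <- function() {
  A <- matrix(0, 8, 8)
  edges <- rbind(cbind(1:7, 2:8), c(1, 4), c(2, 6), c(3, 5),
                 c(4, 7), c(5, 8), c(2, 8))
  A[edges] <- 1
  pmax(A, t(A))
}

# 6-node weighted fixture map.
fixture_weighted <- function() {
  W <- matrix(c(
    0,  .9, .1, 0,  .3, 0,
    .9, 0,  .8, .2, 0,  .4,
    .1, .8, 0,  .7, .5, 0,
    0,  .2, .7, 0,  .6, .1,
    .3, 0,  .5, .6, 0,  .8,
    0,  .4, 0,  .1, .8, 0), 6, 6, byrow = TRUE)
  contact_map(W, "wfix")
}

# Oracle: tie-corrected pairwise-comparison (Mann-Whitney) AUC by brute force.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Oracle: brute-force eigenvalue shift for weakening residue i's couplings by
# (1 - eps), re-diagonalizing the perturbed Kirchhoff matrix.
brute_delta_lambda <- function(K, i, eps) {
  Kp <- K
  Kp[i, ] <- Kp[i, ] * (1 - eps)
  Kp[, i] <- Kp[, i] * (1 - eps)
  diag(Kp) <- 0
  diag(Kp) <- -rowSums(Kp)
  sum(eigen(Kp, symmetric = TRUE, only.values = TRUE)$values) -
    sum(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
}

# Build a small labelled feature table with one perfectly separating feature.
separable_table <- function(n_per_protein = 10, n_proteins = 4) {
  rows <- expand.grid(protein_id = sprintf("p%d", seq_len(n_proteins)),
                      residue = seq_len(n_per_protein),
                      stringsAsFactors = FALSE)
  withr::with_seed(11, {
    rows$label <- as.integer(rows$residue %% 2L) # both classes in every protein
    rows$`src:good` <- rows$label + runif(nrow(rows), 0, 0.5)
    rows$`src:noise` <- runif(nrow(rows))
  })
  tibble::as_tibble(rows)
}

# Study-condition cohort shared by the end-to-end tests: computed once per
# session on first use, then cached.
.cohort_cache <- new.env(parent = emptyenv())

study_cohort_fixture <- function() {
  if (!is.null(.cohort_cache$fix)) {
    return(.cohort_cache$fix)
  }
  cohort <- generate_cohort(seed = 1L)
  scores <- score_cohort(cohort, include = "all")
  features <- assemble_feature_table(
    scores, cohort$labels[c("protein_id", "residue", "label")]
  )
  split <- split_by_protein(features, train_fraction = 0.75, seed = 101L)
  .cohort_cache$fix <- list(cohort = cohort, scores = scores,
                            features = features, split = split)
  .cohort_cache$fix
}
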