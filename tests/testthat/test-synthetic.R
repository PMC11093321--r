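test_that("chain sampling is deterministic in the seed", {
  a <- sample_chain_coordinates(25, seed = 42)
  b <- sample_chain_coordinates(25, seed = 42)
  expect_identical(a, b)
  c <- sample_chain_coordinates(25, seed = 43)
  expect_false(identical(a$x, c$x))
  expect_error(sample_chain_coordinates(5, seed = 1),
               class = "hotspotr_validation_error")
})

test_that("sampled chains honor bond length, self-avoidance, and confinement", {
  for (s in 1:5) {
    n <- c(20, 40, 60, 80, 100)[s]
    coords <- sample_chain_coordinates(n, seed = 700 + s)
    xyz <- as.matrix(coords[, c("x", "y", "z")])
    bonds <- sqrt(rowSums((xyz[-1, ] - xyz[-n, ])^2))
    expect_equal(bonds, rep(3.8, n - 1), tolerance = 1e-12)

    D <- as.matrix(dist(xyz))
    nonbonded <- abs(row(D) - col(D)) > 1
    expect_true(all(D[nonbonded] >= 4.0 - 1e-9))

    radius <- 3.0 * n^(1 / 3)
    expect_true(all(sqrt(rowSums(xyz^2)) <= radius + 1e-9))
  }
})

test_that("confined chains develop a contact-rich core", {
  coords <- sample_chain_coordinates(60, seed = 77)
  cm <- contact_map_from_coordinates(coords)
  # some residue pairs far apart in sequence must be in contact
  td <- tidy(cm)
  expect_gt(sum(td$p > 0.5 & (td$j - td$i) > 5), 5)
})

test_that("logit-noise corruption matches its closed form and sigma = 0 is identity", {
  cm <- rand_map(12, seed = 800, lo = 0.05, hi = 0.95)
  same <- corrupt_contact_map(cm, 0, seed = 1)
  expect_equal(same$P, cm$P, tolerance = 1e-9)

  sigma <- 1.3
  noisy <- corrupt_contact_map(cm, sigma, seed = 9)
  # reconstruct the noise draw and verify P' = plogis(qlogis(P) + eps)
  ut <- upper.tri(cm$P)
  eps <- withr::with_seed(9, rnorm(sum(ut), sd = sigma))
  expected <- qlogis(pmin(pmax(cm$P[ut], 1e-6), 1 - 1e-6)) + eps
  expect_equal(qlogis(noisy$P[ut]), expected, tolerance = 1e-9)
  # symmetry of the noise itself
  expect_identical(noisy$P, t(noisy$P))
  expect_true(all(noisy$P >= 0 & noisy$P <= 1))
  expect_equal(diag(noisy$P), rep(0, 12))

  expect_error(corrupt_contact_map(cm, -1, seed = 1),
               class = "hotspotr_validation_error")
})

test_that("a half-probability contact shifted by unit noise lands at plogis(1)", {
  P <- matrix(0.5, 4, 4)
  diag(P) <- 0
  cm <- contact_map(P, "half")
  noisy <- corrupt_contact_map(cm, 1, seed = 5)
  ut <- upper.tri(P)
  eps <- withr::with_seed(5, rnorm(sum(ut), sd = 1))
  expect_equal(noisy$P[ut], plogis(eps), tolerance = 1e-12)
  # spot-check the logistic itself
  expect_equal(plogis(1), 0.7310585786300049, tolerance = 1e-15)
})

test_that("label assignment follows the logistic model on true connectivity", {
  cm <- rand_map(30, seed = 900, id = "lp")
  lab <- assign_variant_labels(cm, beta = 6, intercept = -1.5,
                               sites_per_protein = 12, seed = 3)
  expect_equal(nrow(lab), 12)
  expect_false(any(duplicated(lab$residue)))
  expect_true(all(lab$label %in% c(0L, 1L)))
  pct <- percentile_normalize(power_degree(cm, 1))
  expect_equal(lab$latent_prob, plogis(-1.5 + 6 * pct[lab$residue]),
               tolerance = 1e-12)

  # beta = 0 removes the signal: all latent probabilities collapse
  lab0 <- assign_variant_labels(cm, beta = 0, intercept = -1.5,
                                sites_per_protein = 12, seed = 3)
  expect_equal(lab0$latent_prob, rep(plogis(-1.5), 12))

  expect_error(assign_variant_labels(cm, 6, -1.5, sites_per_protein = 31, seed = 1),
               class = "hotspotr_validation_error")
  expect_error(assign_variant_labels(cm, -2, -1.5, sites_per_protein = 5, seed = 1),
               class = "hotspotr_validation_error")
})

small_cohort <- function(seed, beta = 6, sigma = 1) {
  generate_cohort(n_proteins = 3L, length_range = c(25L, 35L),
                  sources = c(a = sigma), beta = beta, intercept = -1.5,
                  sites_per_protein = 12L, seed = seed)
}

test_that("cohort generation is deterministic and correctly shaped", {
  co <- small_cohort(seed = 21)
  co2 <- small_cohort(seed = 21)
  expect_identical(co$labels, co2$labels)
  expect_identical(co$proteins[[2]]$maps$a$P, co2$proteins[[2]]$maps$a$P)

  expect_length(co$proteins, 3)
  expect_equal(nrow(co$labels), 3 * 12)
  for (pr in co$proteins) {
    n <- pr$true_map$n_residues
    expect_true(n >= 25 && n <= 35)
    expect_equal(nrow(pr$coords), n)
    expect_named(pr$maps, "a")
    expect_equal(pr$maps$a$n_residues, n)
    expect_equal(pr$true_map$source_tag, "true")
    expect_equal(pr$maps$a$source_tag, "a")
  }
  expect_error(generate_cohort(n_proteins = 1), class = "hotspotr_validation_error")
})

test_that("adding proteins to a cohort never perturbs the earlier ones", {
  co3 <- generate_cohort(n_proteins = 3L, length_range = c(25L, 30L),
                         sources = c(a = 1), sites_per_protein = 10L, seed = 33)
  co5 <- generate_cohort(n_proteins = 5L, length_range = c(25L, 30L),
                         sources = c(a = 1), sites_per_protein = 10L, seed = 33)
  for (i in 1:3) {
    expect_identical(co5$proteins[[i]]$true_map$P, co3$proteins[[i]]$true_map$P)
    expect_identical(co5$proteins[[i]]$maps$a$P, co3$proteins[[i]]$maps$a$P)
  }
  expect_identical(
    dplyr::filter(co5$labels, .data$protein_id %in% sprintf("prot%03d", 1:3)),
    co3$labels
  )
})

test_that("the label signal strengthens with beta and the Bayes ceiling reflects it", {
  aucs <- sapply(c(0, 2, 6), function(beta) {
    mean(sapply(1:8, function(s) bayes_auc(small_cohort(seed = s, beta = beta))))
  })
  expect_lt(abs(aucs[1] - 0.5), 0.08) # no signal: chance
  expect_gt(aucs[2], aucs[1] + 0.05)
  expect_gt(aucs[3], aucs[2] + 0.05)
})

test_that("recoverable signal decays as map noise grows", {
  # AUC of the W1 percentile computed on the corrupted map, by noise level
  w1_auc <- function(co) {
    scored <- purrr::map(co$proteins, function(pr) {
      tibble::tibble(protein_id = pr$protein_id,
                     residue = seq_len(pr$maps[[1]]$n_residues),
                     w1 = percentile_normalize(power_degree(pr$maps[[1]], 1)))
    }) |> purrr::list_rbind()
    joined <- dplyr::inner_join(co$labels, scored, by = c("protein_id", "residue"))
    roc_auc(joined$w1, joined$label)$auc
  }
  seeds <- 1:20
  mean_auc <- sapply(c(0, 1, 3), function(sigma) {
    mean(sapply(seeds, function(s) w1_auc(small_cohort(seed = s, sigma = sigma))))
  })
  expect_gt(mean_auc[1], mean_auc[2])
  expect_gt(mean_auc[2], mean_auc[3])
  expect_gt(mean_auc[1], 0.6) # clean maps carry real signal
})

test_that("cohorts round-trip to disk in the pipeline exchange formats", {
  co <- small_cohort(seed = 55)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "prot001.pdb")))
  expect_true(file.exists(file.path(dir, "params.json")))

  back <- load_contact_map(file.path(dir, "prot002_a.mat"), "matrix", "prot002",
                           source_tag = "a")
  expect_identical(back$P, co$proteins[[2]]$maps$a$P)
  truth <- load_contact_map(file.path(dir, "prot002_true.mat"), "matrix", "prot002")
  expect_identical(truth$P, co$proteins[[2]]$true_map$P)

  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(labs$label, co$labels$label)
  expect_equal(labs$protein_id, co$labels$protein_id)

  params <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(params$seed, 55)
  expect_equal(params$beta, 6)
})
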