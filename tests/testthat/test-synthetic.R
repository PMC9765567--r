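# The synthetic ALE generator: determinism, design structure, planted
# identities, and dataset round-trips.

test_that("the design is deterministic and matches the campaign structure", {
  d1 <- generate_design(seed = 4)
  d2 <- generate_design(seed = 4)
  expect_identical(d1, d2)
  flasks <- unique(d1[, c("strain", "flask_index")])
  expect_equal(nrow(flasks), 22)
  expect_equal(length(unique(d1$strain)), 6)
  expect_equal(sum(table(d1$sample_id) != 1), 0)

  # growth rates rise monotonically to a plateau in [0.98, 1.11]
  for (s in unique(d1$strain)) {
    g <- unique(d1[d1$strain == s, c("flask_index", "growth_rate")])
    g <- g[order(g$flask_index), ]
    expect_true(all(diff(g$growth_rate) >= 0))
    expect_gte(tail(g$growth_rate, 1), 0.98)
    expect_lte(tail(g$growth_rate, 1), 1.11)
  }
  expect_error(generate_design(replicates = 1), "replicate")
  expect_error(generate_design(n_strains = 1), ">= 2")

  # a two-strain, two-flask design differences to two jumps
  d3 <- generate_design(n_strains = 2, flasks_per_strain = 2, seed = 1)
  X <- matrix(0, 1, nrow(d3), dimnames = list("f", d3$sample_id))
  expect_equal(nrow(compute_jumps(X, d3)$delta), 2)
})

test_that("the basis is sparse, full rank and category-labelled", {
  M <- generate_imodulon_model(300, 12, sparsity = 0.15, seed = 9)
  expect_equal(qr(M)$rank, 12)
  expect_equal(colSums(M != 0), rep(round(0.15 * 300), 12),
               ignore_attr = TRUE)
  expect_length(attr(M, "categories"), 12)

  M1 <- generate_imodulon_model(50, 1, sparsity = 0.1, seed = 1)
  expect_equal(ncol(M1), 1)
  Md <- generate_imodulon_model(40, 3, sparsity = 1, seed = 1)
  expect_true(all(Md != 0))
  expect_error(generate_imodulon_model(10, 10), "n_genes")
})

test_that("zero-noise activities reproduce the planted couplings exactly", {
  design <- generate_design(seed = 2)
  truth <- default_truth(toy_imodulons(), strains = unique(design$strain))
  A <- generate_activities(design, toy_imodulons(), truth,
                           replicate_noise = c(meanlog = -30, sdlog = 1e-3),
                           flask_noise_sd = 0, seed = 2)
  fl <- flask_level(A, design)
  # planted growth-correlated iModulons: per-strain Pearson |R| = 1
  for (im in names(truth$growth_correlated_imodulons)) {
    for (s in unique(design$strain)) {
      idx <- fl$info$strain == s
      r <- cor(fl$values[im, idx], fl$info$growth_rate[idx])
      expect_equal(abs(r), 1, tolerance = 1e-6)
      expect_equal(sign(r), unname(truth$growth_correlated_imodulons[im]))
    }
  }
  # planted trade-off with coupling c: flask-level r = -1
  pr <- truth$tradeoff_pairs
  for (k in seq_len(nrow(pr))) {
    r <- cor(fl$values[pr$imodulon_a[k], ], fl$values[pr$imodulon_b[k], ])
    expect_equal(r, -1, tolerance = 1e-6)
  }
  # a declared negative pair with c <= 0 is rejected
  bad <- truth
  bad$tradeoff_pairs$coupling[1] <- -2
  expect_error(generate_activities(design, toy_imodulons(), bad, seed = 1),
               "> 0")
})

test_that("replicate pairs differ by the planted symmetric log-normal noise", {
  design <- generate_design(seed = 6)
  truth <- default_truth(toy_imodulons(), strains = unique(design$strain))
  A <- generate_activities(design, toy_imodulons(), truth,
                           replicate_noise = c(meanlog = 0.3, sdlog = 0.4),
                           seed = 6)
  r1 <- design$sample_id[design$replicate_id == "r1"]
  r2 <- design$sample_id[design$replicate_id == "r2"]
  d <- abs(A[, r2] - A[, r1])
  lg <- log(as.numeric(d))
  expect_lt(abs(mean(lg) - 0.3), 0.1)
  expect_lt(abs(sd(lg) - 0.4), 0.1)
  # replicate means equal the flask value: the pair noise is symmetric
  fl <- flask_level(A, design)
  A2 <- generate_activities(design, toy_imodulons(), truth,
                            replicate_noise = c(meanlog = -30, sdlog = 1e-3),
                            flask_noise_sd = 0.5, seed = 6)
  fl2 <- flask_level(A2, design)
  expect_equal(dim(fl$values), dim(fl2$values))
})

test_that("expression is the exact factorization at zero noise", {
  M <- generate_imodulon_model(200, 8, sparsity = 0.2, seed = 3)
  A <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(colnames(M), paste0("s", 1:6)))
  X <- generate_expression(M, A, noise_sd = 0, nonneg = FALSE)
  expect_equal(unname(X), unname(M %*% A), ignore_attr = TRUE)
  expect_lt(max(abs(project_activities(M, X) - A)), 1e-8)

  # the non-negativity shift is global and recorded
  Xs <- generate_expression(M, A, noise_sd = 0, nonneg = TRUE)
  expect_gte(min(Xs), 0)
  expect_equal(unname(Xs), unname(M %*% A) + attr(Xs, "shift"),
               ignore_attr = TRUE)

  # per-gene baselines are recorded and absorbed as constant offsets
  Xb <- generate_expression(M, A, noise_sd = 0, baseline = c(5, 2), seed = 4)
  Ab <- project_activities(M, Xb)
  off <- Ab - A
  expect_lt(max(abs(off - rowMeans(off))), 1e-8)
})

test_that("convergent phenotypes cluster at the endpoint when noise-free", {
  design <- generate_design(seed = 8)
  truth <- default_truth(toy_imodulons(), strains = unique(design$strain))
  truth$growth_correlated_phenotypes <- character()  # pure clustering signal
  ph <- generate_phenotypes(design, truth, noise_sd = 0, spread_tight = 0,
                            seed = 8)
  for (pid in truth$convergent_phenotypes) {
    sub <- ph[ph$phenotype_id == pid, ]
    d_ep <- pairwise_distances(setNames(sub$value[sub$stage == "EP"],
                                        sub$strain[sub$stage == "EP"]))
    d_wt <- pairwise_distances(setNames(sub$value[sub$stage == "WT"],
                                        sub$strain[sub$stage == "WT"]))
    expect_lte(max(d_ep), min(d_wt))
  }
  expect_error(generate_phenotypes(design, default_truth(toy_imodulons(),
                                                         n_phenotypes = 11)),
               "smaller than")
})

test_that("causal mutations shift their jump-specific targets", {
  ds <- simulate_ale_dataset(seed = 12, n_genes = 300)
  jA <- suppressWarnings(compute_jumps(ds$A, ds$design, ds$mutations))
  jF <- suppressWarnings(compute_jumps(ds$flux_matrix, ds$design))
  feats <- suppressMessages(build_features(ds$mutations, jA$jumps))
  causal <- ds$truth$causal_mutations
  for (i in seq_len(nrow(causal))) {
    if (!causal$locus[i] %in% colnames(feats)) next
    hit <- feats[, causal$locus[i]] == 1
    tgt <- causal$target[i]
    deltas <- if (causal$target_kind[i] == "flux")
      jF$delta[rownames(feats), tgt] else jA$delta[rownames(feats), tgt]
    gap <- mean(deltas[hit]) - mean(deltas[!hit])
    expect_equal(sign(gap), sign(causal$effect[i]))
    expect_gt(abs(gap), abs(causal$effect[i]) / 2)
  }
})

test_that("flux records honour the net/exchange and precision identities", {
  ds <- simulate_ale_dataset(seed = 14, n_genes = 300)
  rec <- ds$fluxes
  expect_equal(rec$v_net, rec$v_forward - rec$v_backward)
  expect_equal(rec$v_exchange, pmin(rec$v_forward, rec$v_backward))
  expect_equal(rec$precision_stdev, (rec$ci_upper - rec$ci_lower) / 4)
  expect_true(all(rec$v_forward >= 0 & rec$v_backward >= 0))
})

test_that("datasets round-trip through disk and regenerate byte-identically", {
  ds <- simulate_ale_dataset(seed = 21, n_genes = 250)
  dir1 <- withr::local_tempdir()
  write_dataset(ds, dir1)
  back <- read_dataset(dir1)
  expect_equal(unname(back$X), unname(ds$X), ignore_attr = TRUE)
  expect_equal(back$design, ds$design)
  expect_equal(back$mutations, ds$mutations)
  expect_equal(back$phenotypes, ds$phenotypes)
  expect_equal(unname(back$M), unname(ds$M))
  expect_equal(back$flux_matrix[rownames(ds$flux_matrix),
                                colnames(ds$flux_matrix)],
               ds$flux_matrix)
  # truth file enumerates exactly the planted sets
  expect_setequal(back$truth$convergent_phenotypes,
                  ds$truth$convergent_phenotypes)
  expect_setequal(names(back$truth$growth_correlated_imodulons),
                  names(ds$truth$growth_correlated_imodulons))
  expect_equal(back$truth$causal_mutations$locus,
               ds$truth$causal_mutations$locus)

  # regeneration with the same seed is byte-identical on disk
  dir2 <- withr::local_tempdir()
  write_dataset(simulate_ale_dataset(seed = 21, n_genes = 250), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw",
                             file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw",
                             file.size(file.path(dir2, f))),
                     info = f)
  }
})
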