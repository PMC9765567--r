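# Projection onto the iModulon basis, explained variance, and DIMA.

test_that("projection solves the least-squares problem exactly", {
  # identity basis: activities are the expression values themselves
  M <- diag(4)
  dimnames(M) <- list(paste0("g", 1:4), paste0("IM", 1:4))
  X <- matrix(abs(rnorm(8)), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_equal(unname(project_activities(M, X)), unname(X))

  # exact factorization is recovered to machine precision
  set.seed(2)
  M2 <- generate_imodulon_model(200, 8, sparsity = 0.2, seed = 2)
  A0 <- matrix(rnorm(8 * 5), 8, 5,
               dimnames = list(colnames(M2), paste0("s", 1:5)))
  X2 <- M2 %*% A0
  expect_lt(max(abs(project_activities(M2, X2) - A0)), 1e-8)

  # noisy case equals the independent normal-equations solution
  Xn <- X2 + matrix(rnorm(length(X2), 0, 0.3), nrow(X2))
  A_hat <- project_activities(M2, Xn)
  A_oracle <- solve(t(M2) %*% M2, t(M2) %*% Xn)
  expect_equal(unname(A_hat), unname(A_oracle), tolerance = 1e-8)
})

test_that("projection guards gene matching and rank", {
  M <- generate_imodulon_model(100, 5, sparsity = 0.3, seed = 4)
  X <- matrix(rnorm(10), 10, 1,
              dimnames = list(rownames(M)[1:10], "s1"))
  expect_error(project_activities(M, X), "%")  # too few shared genes

  # duplicated column makes the basis rank-deficient
  M2 <- cbind(M, M[, 5, drop = FALSE])
  colnames(M2)[6] <- "IM06dup"
  Xf <- matrix(rnorm(100), 100, 1, dimnames = list(rownames(M), "s1"))
  expect_error(project_activities(M2, Xf), "rank-deficient")

  # per-gene centering against a reference set shifts activities only
  X3 <- abs(matrix(rnorm(300), 100, 3,
                   dimnames = list(rownames(M), paste0("s", 1:3))))
  a_raw <- project_activities(M, X3)
  a_cen <- project_activities(M, X3, center = c("s1", "s2"))
  shift <- a_raw - a_cen
  expect_lt(max(abs(shift - rowMeans(shift))), 1e-8)
})

test_that("explained variance is 1 iff the residual vanishes", {
  M <- generate_imodulon_model(150, 6, sparsity = 0.2, seed = 6)
  A <- matrix(rnorm(6 * 8), 6, 8,
              dimnames = list(colnames(M), paste0("s", 1:8)))
  X <- M %*% A
  expect_equal(explained_variance(M, A, X), 1)
  # zero activities against already-centered data explain nothing
  Xc <- X - rowMeans(X)
  expect_equal(explained_variance(M, A * 0, Xc), 0)
  # explained variance decreases as noise grows
  evs <- vapply(c(0.2, 1, 4), function(s) {
    set.seed(8)
    Xn <- X + matrix(rnorm(length(X), 0, s), nrow(X))
    explained_variance(M, project_activities(M, Xn), Xn)
  }, numeric(1))
  expect_true(all(diff(evs) < 0))
  expect_true(all(evs <= 1))
  expect_error(explained_variance(M, A, X * 0), "zero-variance")
})

test_that("the replicate null recovers known log-normal parameters", {
  set.seed(13)
  n <- 500
  d <- rlnorm(n, 0, 0.5)
  # two replicates per pseudo-flask differing by exactly +/- d/2 per iModulon
  A <- rbind(im = c(rbind(10 - d / 2, 10 + d / 2)))
  colnames(A) <- paste0("s", seq_len(2 * n))
  groups <- split(colnames(A), rep(seq_len(n), each = 2))
  null <- fit_replicate_null(A, groups)
  expect_lt(abs(null$mu - 0), 0.1)
  expect_lt(abs(null$sigma - 0.5), 0.1)
  expect_equal(null$n_fit, n)

  # scaling all activities by k shifts meanlog by log(k), sdlog unchanged
  null_k <- fit_replicate_null(A * 3, groups)
  expect_equal(null_k$mu, null$mu + log(3), tolerance = 1e-10)
  expect_equal(null_k$sigma, null$sigma, tolerance = 1e-10)

  # identical replicates leave nothing to fit
  A0 <- matrix(1, 1, 4, dimnames = list("im", paste0("s", 1:4)))
  expect_error(suppressMessages(
    fit_replicate_null(A0, list(colnames(A0)))), "zero")
})

test_that("dima requires both the q-value and the absolute-change threshold", {
  null <- structure(list(mu = 0, sigma = 0.5, n_fit = 100),
                    class = "lognormal_null")
  A <- rbind(IMa = c(0, 0, 0, 0), IMb = c(0, 0, 4.9, 4.9),
             IMc = c(0, 0, 10, 10))
  colnames(A) <- paste0("s", 1:4)
  res <- dima(A, c("s1", "s2"), c("s3", "s4"), null)
  expect_equal(res$p[res$imodulon == "IMa"], 1)       # no change
  expect_false(res$significant[res$imodulon == "IMa"])
  # |delta| = 4.9 clears the q threshold but misses the minimum change of 5
  expect_lt(res$q[res$imodulon == "IMb"], 0.05)
  expect_false(res$significant[res$imodulon == "IMb"])
  expect_true(res$significant[res$imodulon == "IMc"])
  expect_equal(res$direction[res$imodulon == "IMc"], "increased")

  # antisymmetry in the condition order
  rev <- dima(A, c("s3", "s4"), c("s1", "s2"), null)
  expect_equal(rev$delta_activity, -res$delta_activity)
  expect_equal(rev$p, res$p)

  expect_error(dima(A, "s9", "s1", null), "absent")
})

test_that("the DIMA screen counts significant calls consistently", {
  meta <- toy_meta(strains = c("A", "B"), flasks = c(0, 3, 6))
  null <- structure(list(mu = 0, sigma = 0.5, n_fit = 100),
                    class = "lognormal_null")
  A <- matrix(0, 2, nrow(meta), dimnames = list(c("IMa", "IMb"), meta$sample_id))
  # one planted WT -> EP shift per strain on IMa
  A["IMa", meta$stage == "EP"] <- 12
  cats <- c(IMa = "stress response", IMb = "translation")
  scr <- dima_screen(A, meta, null, categories = cats)
  sig <- scr$wt_ep[scr$wt_ep$significant, ]
  expect_equal(nrow(sig), 2)  # once per strain
  expect_equal(unique(sig$category), "stress response")
  # aggregated counts equal a brute-force recount of the table
  recount <- with(scr$wt_ep[scr$wt_ep$significant, ],
                  table(category, direction))
  expect_equal(sum(scr$category_counts$n), sum(recount))
  expect_equal(scr$category_counts$n[
    scr$category_counts$category == "stress response" &
      scr$category_counts$direction == "increased"], 2)
})

test_that("WT-discriminating iModulons are the planted offsets, exactly", {
  ds <- simulate_ale_dataset(seed = 3, n_genes = 400)
  planted <- sort(unique(unlist(lapply(ds$truth$wt_offset_imodulons, names))))
  wd <- wt_discriminating(ds$A, ds$design)
  expect_identical(sort(wd$imodulon[wd$selected]), planted)
  # a single strain cannot define strain discrimination
  one <- ds$design[ds$design$strain == "BL21", ]
  expect_error(wt_discriminating(ds$A[, one$sample_id], one), ">= 2 strains")
})

test_that("growth-correlated iModulons carry their planted signs", {
  ds <- simulate_ale_dataset(seed = 5, n_genes = 400)
  gci <- growth_correlated_imodulons(ds$A, ds$design)
  planted <- ds$truth$growth_correlated_imodulons
  sel <- gci[gci$selected, ]
  recovered <- intersect(sel$imodulon, names(planted))
  expect_gte(length(recovered), 5)
  expect_equal(sel$sign[match(recovered, sel$imodulon)],
               unname(planted[recovered]))

  # an exact affine coupling to growth is always selected, with its sign
  meta <- toy_meta(strains = c("A", "B"), flasks = c(0, 3, 7, 9))
  A <- rbind(IMup = rep(meta$growth_rate * 10, 1),
             IMnoise = rnorm(nrow(meta)))
  colnames(A) <- meta$sample_id
  res <- growth_correlated_imodulons(A, meta)
  expect_true(res$selected[res$imodulon == "IMup"])
  expect_equal(res$sign[res$imodulon == "IMup"], 1)
})
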