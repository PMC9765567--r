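# iModulon activity projection and differential activity analysis (DIMA).
#
# Expression decomposes as X = M %*% A for a fixed gene-weight basis M
# (genes x iModulons, from ICA of a reference compendium) and activities A
# (iModulons x samples). New samples are projected onto the fixed basis by
# least squares, A = pinv(M) %*% X.

#' Project expression onto a fixed iModulon basis
#'
#' Solves the least-squares problem X ~ M A per sample (Moore-Penrose
#' sense) on the intersection of gene ids. Refuses to run when fewer than
#' `min_match` of the basis genes are present, or when the restricted basis
#' loses column rank.
#'
#' @param M genes x iModulons weight matrix
#' @param X genes x samples expression matrix
#' @param center optional character vector of reference sample ids; when
#'   given, the per-gene mean over those samples is subtracted from X before
#'   projection
#' @param min_match minimum fraction of M's genes that must be present in X
#' @return iModulons x samples activity matrix
#' @export
project_activities <- function(M, X, center = NULL, min_match = 0.5) {
  common <- intersect(rownames(M), rownames(X))
  frac <- length(common) / nrow(M)
  if (frac < min_match) {
    stop(sprintf("only %.1f%% of basis genes present in expression (< %.0f%%)",
                 100 * frac, 100 * min_match), call. = FALSE)
  }
  dropped <- nrow(M) - length(common)
  if (dropped > 0) {
    message(dropped, " basis gene(s) absent from expression; projecting on ",
            length(common), " shared genes")
  }
  Mc <- M[common, , drop = FALSE]
  Xc <- X[common, , drop = FALSE]
  if (!is.null(center)) {
    miss <- setdiff(center, colnames(X))
    if (length(miss)) stop("reference sample(s) not in X: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    Xc <- Xc - rowMeans(Xc[, center, drop = FALSE])
  }
  qrM <- qr(Mc)
  if (qrM$rank < ncol(Mc)) {
    stop("restricted basis is rank-deficient: ", ncol(Mc) - qrM$rank,
         " unresolvable dimension(s)", call. = FALSE)
  }
  A <- qr.coef(qrM, Xc)
  rownames(A) <- colnames(M)
  colnames(A) <- colnames(X)
  A
}

#' Fraction of expression variance explained by the basis
#'
#' 1 - ||X_c - (M A)_c||_F^2 / ||X_c||_F^2 over the chosen samples, where
#' `_c` centers per gene over those samples; with `center = FALSE` both
#' terms are used uncentered. Centering makes the fraction measure shape
#' agreement rather than constant per-gene offsets. Computed on the gene
#' intersection of M and X.
#'
#' @param M genes x iModulons weight matrix
#' @param A iModulons x samples activity matrix
#' @param X genes x samples expression matrix
#' @param samples optional sample subset (default: all shared samples)
#' @param center center the denominator per gene over the subset
#' @return explained-variance fraction (at most 1; 1 iff the residual is 0)
#' @export
explained_variance <- function(M, A, X, samples = NULL, center = TRUE) {
  samples <- samples %||% intersect(colnames(X), colnames(A))
  genes <- intersect(rownames(M), rownames(X))
  Xs <- X[genes, samples, drop = FALSE]
  fit <- M[genes, , drop = FALSE] %*% A[, samples, drop = FALSE]
  if (center) {
    Xs <- Xs - rowMeans(Xs)
    fit <- fit - rowMeans(fit)
  }
  den <- sum(Xs^2)
  if (den == 0) stop("zero-variance sample subset", call. = FALSE)
  1 - sum((Xs - fit)^2) / den
}

#' Fit the log-normal replicate null for activity differences
#'
#' Absolute differences in iModulon activity between biological replicates
#' of the same flask are pooled across all iModulons and a log-normal
#' distribution is fitted by maximum likelihood. Zero differences are
#' dropped (with a message).
#'
#' @param A iModulons x samples activity matrix
#' @param replicate_groups list of character vectors of replicate sample ids
#' @return an object of class `lognormal_null`: list(mu, sigma, n_fit)
#' @export
fit_replicate_null <- function(A, replicate_groups) {
  diffs <- numeric()
  for (g in replicate_groups) {
    g <- intersect(g, colnames(A))
    if (length(g) < 2) next
    cb <- utils::combn(g, 2)
    for (k in seq_len(ncol(cb))) {
      diffs <- c(diffs, abs(A[, cb[1, k]] - A[, cb[2, k]]))
    }
  }
  if (!length(diffs)) stop("no replicate pair available", call. = FALSE)
  n_zero <- sum(diffs == 0)
  if (n_zero > 0) message(n_zero, " zero replicate difference(s) dropped")
  diffs <- diffs[diffs > 0]
  if (!length(diffs)) stop("all replicate differences are zero", call. = FALSE)
  if (length(diffs) < 10) {
    warning("only ", length(diffs), " replicate differences used to fit the null",
            call. = FALSE)
  }
  lg <- log(diffs)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  if (sigma == 0) stop("replicate differences are degenerate (sigma = 0)",
                       call. = FALSE)
  structure(list(mu = mu, sigma = sigma, n_fit = length(diffs)),
            class = "lognormal_null")
}

#' @export
print.lognormal_null <- function(x, ...) {
  cat(sprintf("log-normal replicate null: meanlog %.3f, sdlog %.3f (n = %d)\n",
              x$mu, x$sigma, x$n_fit))
  invisible(x)
}

#' Differential iModulon activity between two conditions
#'
#' Delta is the mean activity of `cond2` minus that of `cond1` per iModulon;
#' the p-value is the upper-tail probability of |Delta| under the log-normal
#' replicate null; BH across iModulons. Significance additionally requires
#' |Delta| above the absolute minimum-change threshold (default 5 activity
#' units).
#'
#' @param A iModulons x samples activity matrix
#' @param cond1,cond2 character vectors of sample ids for the two conditions
#' @param null a `lognormal_null` from [fit_replicate_null()]
#' @param min_change absolute activity change required for significance
#' @param alpha FDR level on the q-value
#' @param min_fc optional fold-change requirement on |mean2| / |mean1|
#'   (off by default; the absolute threshold is the primary rule)
#' @param categories optional named character map iModulon -> functional
#'   category
#' @return data.frame with one row per iModulon: delta_activity, p, q,
#'   significant, direction, category
#' @export
dima <- function(A, cond1, cond2, null, min_change = 5, alpha = 0.05,
                 min_fc = NULL, categories = NULL) {
  for (cc in list(cond1, cond2)) {
    miss <- setdiff(cc, colnames(A))
    if (length(miss)) stop("sample(s) absent from activity matrix: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (!length(cc)) stop("both conditions must be non-empty", call. = FALSE)
  }
  m1 <- rowMeans(A[, cond1, drop = FALSE])
  m2 <- rowMeans(A[, cond2, drop = FALSE])
  delta <- m2 - m1
  p <- stats::plnorm(abs(delta), meanlog = null$mu, sdlog = null$sigma,
                     lower.tail = FALSE)
  q <- bh_fdr(p)
  significant <- q <= alpha & abs(delta) > min_change
  if (!is.null(min_fc)) {
    ratio <- abs(m2) / pmax(abs(m1), .Machine$double.eps)
    significant <- significant & (ratio > min_fc | ratio < 1 / min_fc)
  }
  out <- data.frame(
    imodulon = rownames(A), delta_activity = unname(delta),
    p = unname(p), q = unname(q), significant = unname(significant),
    direction = ifelse(delta >= 0, "increased", "decreased"),
    stringsAsFactors = FALSE
  )
  out$category <- if (is.null(categories)) NA_character_ else
    unname(ifelse(is.na(categories[out$imodulon]), "unknown",
                  categories[out$imodulon]))
  out
}

#' DIMA screen over all jumps and WT-vs-EP contrasts
#'
#' Runs [dima()] for every consecutive assayed-flask pair (jump) and for the
#' WT-vs-EP contrast of each strain, and aggregates significant WT-vs-EP
#' calls into per-category, per-direction counts.
#'
#' @param A iModulons x samples activity matrix
#' @param meta sample metadata
#' @param null log-normal replicate null
#' @param categories optional iModulon category map
#' @param min_change,alpha thresholds passed to [dima()]
#' @return list with `wt_ep` and `jumps` result tables and a
#'   `category_counts` data.frame (category x direction counts over the
#'   significant WT-vs-EP calls, summed across strains)
#' @export
dima_screen <- function(A, meta, null, categories = NULL, min_change = 5,
                        alpha = 0.05) {
  meta <- meta[meta$sample_id %in% colnames(A), , drop = FALSE]
  wt_rows <- list(); jump_rows <- list()
  for (s in unique(meta$strain)) {
    ms <- meta[meta$strain == s, ]
    flasks <- sort(unique(ms$flask_index))
    samples_at <- function(f) ms$sample_id[ms$flask_index == f]
    wt <- samples_at(flasks[1]); ep <- samples_at(flasks[length(flasks)])
    d <- dima(A, wt, ep, null, min_change, alpha, categories = categories)
    d$strain <- s
    wt_rows[[s]] <- d
    if (length(flasks) >= 2) {
      for (k in seq_len(length(flasks) - 1)) {
        dj <- dima(A, samples_at(flasks[k]), samples_at(flasks[k + 1]), null,
                   min_change, alpha, categories = categories)
        dj$strain <- s
        dj$jump_id <- paste0(s, "_j", flasks[k], "_", flasks[k + 1])
        jump_rows[[dj$jump_id[1]]] <- dj
      }
    }
  }
  wt_ep <- do.call(rbind, wt_rows)
  jumps <- do.call(rbind, jump_rows)
  rownames(wt_ep) <- rownames(jumps) <- NULL
  sig <- wt_ep[wt_ep$significant, , drop = FALSE]
  if (nrow(sig)) {
    counts <- stats::aggregate(list(n = sig$significant),
                               by = list(category = ifelse(is.na(sig$category),
                                                           "unknown", sig$category),
                                         direction = sig$direction),
                               FUN = length)
  } else {
    counts <- data.frame(category = character(), direction = character(),
                         n = integer())
  }
  list(wt_ep = wt_ep, jumps = jumps, category_counts = counts)
}

#' iModulons discriminating wild-type expression states
#'
#' One-way ANOVA F-test across strains on the WT samples of each iModulon,
#' BH-adjusted; the default FDR threshold is deliberately strict (0.005).
#'
#' @param A iModulons x samples activity matrix
#' @param meta sample metadata
#' @param fdr FDR threshold
#' @return data.frame with F, p, q and a `selected` flag per iModulon
#' @export
wt_discriminating <- function(A, meta, fdr = 0.005) {
  wt <- meta[meta$stage == "WT" & meta$sample_id %in% colnames(A), ]
  sizes <- table(wt$strain)
  if (length(sizes) < 2) stop("need WT samples from >= 2 strains", call. = FALSE)
  if (any(sizes < 2)) stop("each strain needs >= 2 WT samples", call. = FALSE)
  Awt <- A[, wt$sample_id, drop = FALSE]
  res <- lapply(rownames(Awt), function(im) {
    ft <- anova_f_strain(Awt[im, ], wt$strain)
    data.frame(imodulon = im, F = ft$F, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$selected <- out$q < fdr
  out
}

#' Growth-correlated iModulons, conserved across strains
#'
#' Replicates are averaged per flask; within each strain the Pearson
#' correlation of activity with growth rate is computed across its flasks.
#' An iModulon is selected when its median |R| across strains exceeds
#' `r_min` and its median p-value is below `p_max`; the sign is that of the
#' median R.
#'
#' @param A iModulons x samples activity matrix
#' @param meta sample metadata (growth_rate required)
#' @param r_min minimum median absolute Pearson R
#' @param p_max maximum median p-value
#' @return data.frame with median_r, median_abs_r, median_p, sign and a
#'   `selected` flag per iModulon
#' @export
growth_correlated_imodulons <- function(A, meta, r_min = 0.75, p_max = 0.05) {
  fl <- flask_level(A[, meta$sample_id[meta$sample_id %in% colnames(A)],
                      drop = FALSE], meta)
  strains <- unique(fl$info$strain)
  rmat <- pmat <- matrix(NA_real_, nrow(A), length(strains),
                         dimnames = list(rownames(A), strains))
  for (s in strains) {
    j <- which(fl$info$strain == s)
    if (length(j) < 3) {
      warning("strain ", s, " has < 3 assayed flasks; excluded from the ",
              "growth-correlation medians", call. = FALSE)
      next
    }
    g <- fl$info$growth_rate[j]
    for (im in rownames(A)) {
      v <- fl$values[im, j]
      if (stats::sd(v) == 0 || stats::sd(g) == 0) {
        rmat[im, s] <- 0; pmat[im, s] <- 1
      } else {
        ct <- stats::cor.test(v, g)
        rmat[im, s] <- unname(ct$estimate); pmat[im, s] <- ct$p.value
      }
    }
  }
  if (all(is.na(rmat))) stop("no strain has >= 3 assayed flasks", call. = FALSE)
  med_r <- apply(rmat, 1, stats::median, na.rm = TRUE)
  med_abs <- apply(abs(rmat), 1, stats::median, na.rm = TRUE)
  med_p <- apply(pmat, 1, stats::median, na.rm = TRUE)
  data.frame(
    imodulon = rownames(A),
    median_r = unname(med_r), median_abs_r = unname(med_abs),
    median_p = unname(med_p), sign = sign(med_r),
    selected = unname(med_abs > r_min & med_p < p_max),
    stringsAsFactors = FALSE
  )
}
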