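# Mutation-systems correlate screening: encode which loci are gained in
# which fitness jumps and test for association with jump-specific changes
# in reaction flux and iModulon activity.

#' Binary mutation feature matrix over jumps
#'
#' One column per mutation feature (gene-level locus by default, or
#' locus:nucleotide at nucleotide level), one row per jump; a cell is 1 when
#' at least one event at that feature is gained in that jump. A feature is
#' gained in the jump ending at the first assayed flask at or after its
#' observed flask (events landing on unassayed flasks are reassigned with a
#' warning); events at or before a strain's first assayed flask are
#' wild-type alleles and never gained. Features present in fewer than
#' `min_jumps` jumps are untestable and dropped.
#'
#' @param mutations mutation event data.frame (see [read_mutations()])
#' @param jumps jump table as produced by [compute_jumps()] (`$jumps`)
#' @param level `"gene"` or `"nucleotide"`
#' @param min_jumps minimum number of jumps a feature must appear in
#' @return jumps x features binary matrix
#' @export
build_features <- function(mutations, jumps, level = c("gene", "nucleotide"),
                           min_jumps = 2) {
  level <- match.arg(level)
  mut <- mutations
  mut$feature <- if (level == "gene") mut$locus else
    paste(mut$locus, mut$nucleotide_id, sep = ":")
  # earliest observation per (strain, feature): presence is from then onward
  first <- stats::aggregate(observed_flask ~ strain + feature, mut, min)
  feats <- sort(unique(first$feature))
  mat <- matrix(0L, nrow(jumps), length(feats),
                dimnames = list(jumps$jump_id, feats))
  for (i in seq_len(nrow(first))) {
    s <- first$strain[i]
    assayed <- sort(unique(c(jumps$from_flask[jumps$strain == s],
                             jumps$to_flask[jumps$strain == s])))
    if (!length(assayed)) next
    obs <- first$observed_flask[i]
    cand <- assayed[assayed >= obs]
    if (!length(cand)) next
    eff <- cand[1]
    if (eff != obs) {
      warning("event at ", first$feature[i], " (", s, ") observed at unassayed ",
              "flask ", obs, "; assigned to flask ", eff, call. = FALSE)
    }
    if (eff == assayed[1]) next
    jid <- jumps$jump_id[jumps$strain == s & jumps$to_flask == eff]
    if (length(jid) == 1) mat[jid, first$feature[i]] <- 1L
  }
  n_jumps <- colSums(mat)
  drop <- n_jumps < min_jumps
  if (any(drop)) {
    message(sum(drop), " feature(s) present in < ", min_jumps,
            " jumps dropped as untestable")
  }
  mat[, !drop, drop = FALSE]
}

#' Association between a binary mutation feature and jump-specific changes
#'
#' Default: point-biserial correlation (equivalent to a two-sample t-test)
#' with a two-sided t-based p-value. The permutation option permutes the
#' feature labels; when the number of distinct placements is small enough
#' the permutation distribution is enumerated exactly, otherwise `n_perm`
#' seeded draws are used.
#'
#' @param feature binary vector over jumps (both classes present)
#' @param deltas numeric vector of jump-specific changes
#' @param method `"point_biserial"` or `"permutation"`
#' @param n_perm number of sampled permutations (when not enumerable)
#' @param seed seed for the sampled permutations
#' @return list(statistic, p, method)
#' @export
associate <- function(feature, deltas, method = c("point_biserial", "permutation"),
                      n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  feature <- as.numeric(feature)
  if (length(unique(feature)) < 2) {
    stop("feature must have both classes present", call. = FALSE)
  }
  if (length(feature) != length(deltas)) stop("length mismatch", call. = FALSE)
  r <- stats::cor(feature, deltas)
  if (method == "point_biserial") {
    p <- stats::cor.test(feature, deltas)$p.value
    return(list(statistic = r, p = p, method = method))
  }
  n <- length(feature)
  k <- sum(feature == 1)
  n_exact <- choose(n, k)
  if (n_exact <= n_perm) {
    pos <- utils::combn(n, k)
    stats_perm <- apply(pos, 2, function(ix) {
      f <- numeric(n); f[ix] <- 1
      stats::cor(f, deltas)
    })
    p <- mean(abs(stats_perm) >= abs(r) - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_perm <- replicate(n_perm, stats::cor(sample(feature), deltas))
    p <- (1 + sum(abs(stats_perm) >= abs(r) - 1e-12)) / (n_perm + 1)
  }
  list(statistic = r, p = p, method = "permutation")
}

#' Screen mutation features against jump-specific flux and activity changes
#'
#' Tests every feature against every target column; BH adjustment is applied
#' separately within the flux targets and within the iModulon targets,
#' mirroring their separate reporting.
#'
#' @param features jumps x features binary matrix (see [build_features()])
#' @param delta_flux optional jumps x reactions matrix of flux changes
#' @param delta_activity optional jumps x iModulons matrix of activity
#'   changes
#' @param fdr FDR threshold
#' @param method association method, see [associate()]
#' @param seed seed for permutation p-values
#' @return data.frame sorted by q with one row per (feature, target) test
#'   and a `significant` flag
#' @export
screen_correlates <- function(features, delta_flux = NULL, delta_activity = NULL,
                              fdr = 0.05, method = "point_biserial", seed = NULL) {
  targets <- list()
  if (!is.null(delta_flux)) targets$flux <- as.matrix(delta_flux)
  if (!is.null(delta_activity)) targets$imodulon <- as.matrix(delta_activity)
  if (!length(targets)) stop("no target table supplied", call. = FALSE)
  out <- list()
  for (kind in names(targets)) {
    tgt <- targets[[kind]]
    common <- intersect(rownames(features), rownames(tgt))
    if (length(common) < nrow(features)) {
      stop("jump rows of features and ", kind, " targets do not align", call. = FALSE)
    }
    tgt <- tgt[rownames(features), , drop = FALSE]
    rows <- list()
    for (f in colnames(features)) {
      for (tg in colnames(tgt)) {
        as_ <- associate(features[, f], tgt[, tg], method = method, seed = seed)
        rows[[paste(f, tg)]] <- data.frame(
          feature = f, target = tg, target_kind = kind,
          statistic = as_$statistic, p = as_$p,
          n_jumps_with_feature = sum(features[, f]),
          stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, rows)
    tab$q <- bh_fdr(tab$p)
    out[[kind]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- res$q <= fdr
  res[order(res$q, res$p), ]
}
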