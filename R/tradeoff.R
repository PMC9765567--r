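# Regulatory trade-off detection: PCA of jump-specific activity changes to
# shortlist candidate iModulons, then ANCOVA with strain intercepts on
# flask-level activities to call negatively coupled pairs.

#' PCA of jump-specific activity changes
#'
#' Columns are mean-centered (no variance scaling) and decomposed by the
#' covariance eigendecomposition. Explained-variance ratios sum to 1 over
#' all retained components. Known outliers (e.g. a single jump dominating a
#' motility iModulon) can be excluded cell-wise: excluded cells are replaced
#' by the mean of the remaining values in their column.
#'
#' @param delta jumps x iModulons matrix of activity differences
#' @param exclusions optional data.frame with columns `jump` and `imodulon`;
#'   a row with `jump = NA` drops the whole iModulon column
#' @return list with `loadings` (unit-norm columns), `ev_ratio` and `scores`
#' @export
jump_pca <- function(delta, exclusions = NULL) {
  delta <- as.matrix(delta)
  if (!is.null(exclusions) && nrow(exclusions)) {
    drop_cols <- unique(exclusions$imodulon[is.na(exclusions$jump)])
    if (length(drop_cols)) delta <- delta[, setdiff(colnames(delta), drop_cols),
                                          drop = FALSE]
    cellwise <- exclusions[!is.na(exclusions$jump), , drop = FALSE]
    for (i in seq_len(nrow(cellwise))) {
      jr <- cellwise$jump[i]; im <- cellwise$imodulon[i]
      if (!(jr %in% rownames(delta)) || !(im %in% colnames(delta))) next
      keep <- setdiff(rownames(delta), jr)
      delta[jr, im] <- mean(delta[keep, im])
    }
  }
  if (nrow(delta) < 2) stop("need >= 2 jumps", call. = FALSE)
  if (ncol(delta) < 2) stop("need >= 2 iModulons after exclusion", call. = FALSE)
  pc <- stats::prcomp(delta, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, ev_ratio = ev, scores = pc$x)
}

#' Candidate iModulons from PCA loadings
#'
#' Union, over components explaining at least `ev_min` of the variance, of
#' iModulons with absolute loading above `weight_min`.
#'
#' @param loadings iModulons x components loading matrix (unit-norm columns)
#' @param ev_ratios explained-variance ratio per component
#' @param weight_min absolute loading threshold
#' @param ev_min minimum explained-variance ratio for a component to qualify
#' @return character vector of candidate iModulons
#' @export
select_candidates <- function(loadings, ev_ratios, weight_min = 0.10,
                              ev_min = 0.05) {
  comps <- which(ev_ratios >= ev_min)
  if (!length(comps)) return(character())
  hits <- abs(loadings[, comps, drop = FALSE]) > weight_min
  rownames(loadings)[rowSums(hits) > 0]
}

#' ANCOVA with a common slope and strain-specific intercepts
#'
#' Fits y ~ x + strain and reports the coefficient of determination, the
#' common slope with its p-value, and the p-value of the added
#' slope-by-strain interaction F-test (homogeneity of the strain-specific
#' regression lines).
#'
#' @param y,x numeric activity vectors
#' @param strain strain label per observation
#' @return list(r2, slope, slope_p, homogeneity_p)
#' @export
ancova_fit <- function(y, x, strain) {
  strain <- as.factor(as.character(strain))
  sizes <- table(strain)
  if (length(sizes) < 2) stop("need >= 2 strains", call. = FALSE)
  if (any(sizes < 3)) stop("need >= 3 samples per strain", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate covariate (constant x)", call. = FALSE)
  fit0 <- stats::lm(y ~ x + strain)
  sm <- summary(fit0)
  fit1 <- stats::lm(y ~ x * strain)
  cmp <- stats::anova(fit0, fit1)
  list(
    r2 = sm$r.squared,
    slope = unname(stats::coef(fit0)["x"]),
    slope_p = sm$coefficients["x", "Pr(>|t|)"],
    homogeneity_p = cmp[2, "Pr(>F)"]
  )
}

#' Detect negatively coupled iModulon trade-off pairs
#'
#' Every unordered pair of candidate iModulons (canonical lexicographic
#' orientation, so results are order-invariant) is tested on flask-level
#' activities: Pearson correlation across all samples plus [ancova_fit()].
#' Pairs are kept when the correlation is negative, the BH-adjusted common
#' slope p-value passes `fdr`, and the ANCOVA R-squared exceeds `r2_min`.
#'
#' @param A iModulons x samples activity matrix
#' @param meta sample metadata
#' @param candidates candidate iModulon names (subset of rownames of A)
#' @param r2_min ANCOVA R-squared threshold
#' @param fdr BH threshold on the slope p-values
#' @param categories optional iModulon category map, used for the pair group
#'   label
#' @return data.frame of detected pairs (imodulon_a, imodulon_b, pearson_r,
#'   ancova_r2, slope, slope_p, homogeneity_p, q, group); the full tested
#'   table is attached as attribute `"tested"`
#' @export
detect_tradeoffs <- function(A, meta, candidates, r2_min = 0.95, fdr = 0.05,
                             categories = NULL) {
  bad <- setdiff(candidates, rownames(A))
  if (length(bad)) stop("candidate(s) absent from activity matrix: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  candidates <- sort(unique(candidates))
  if (length(candidates) < 2) {
    out <- data.frame(imodulon_a = character(), imodulon_b = character(),
                      pearson_r = numeric(), ancova_r2 = numeric(),
                      slope = numeric(), slope_p = numeric(),
                      homogeneity_p = numeric(), q = numeric(),
                      group = character())
    attr(out, "tested") <- out
    return(out)
  }
  meta <- meta[match(colnames(A), meta$sample_id), ]
  cb <- utils::combn(candidates, 2)
  rows <- list()
  for (k in seq_len(ncol(cb))) {
    a <- cb[1, k]; b <- cb[2, k]
    x <- A[a, ]; y <- A[b, ]
    anc <- tryCatch(ancova_fit(y, x, meta$strain), error = function(e) NULL)
    if (is.null(anc)) next
    rows[[k]] <- data.frame(
      imodulon_a = a, imodulon_b = b,
      pearson_r = stats::cor(x, y),
      ancova_r2 = anc$r2, slope = anc$slope, slope_p = anc$slope_p,
      homogeneity_p = anc$homogeneity_p,
      stringsAsFactors = FALSE
    )
  }
  tested <- do.call(rbind, rows)
  if (is.null(tested)) stop("no testable candidate pair", call. = FALSE)
  rownames(tested) <- NULL
  tested$q <- bh_fdr(tested$slope_p)
  keep <- tested$pearson_r < 0 & tested$q <= fdr & tested$ancova_r2 > r2_min
  out <- tested[keep, , drop = FALSE]
  out$group <- if (is.null(categories)) NA_character_ else {
    ca <- categories[out$imodulon_a]; cb2 <- categories[out$imodulon_b]
    ifelse(!is.na(ca) & !is.na(cb2) & ca == cb2, ca,
           paste(ifelse(is.na(ca), "unknown", ca),
                 ifelse(is.na(cb2), "unknown", cb2), sep = "/"))
  }
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}
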