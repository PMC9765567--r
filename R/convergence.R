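# Convergence/divergence testing of phenotype panels.
#
# Each phenotype's per-strain means at the wild-type (WT) and endpoint (EP)
# stages are transformed to vectors of pairwise distances; a one-sided
# Mann-Whitney U test (normal approximation) then asks whether the EP
# distances are smaller (convergence) or larger (divergence) than the WT
# distances, with Benjamini-Hochberg control across the panel.

#' Pairwise distances among per-strain means
#'
#' All unordered-pair absolute differences, in canonical order (pairs as
#' produced by `combn` on the input order). Six strains give 15 distances.
#'
#' @param values named numeric vector, one mean per strain
#' @return named non-negative numeric vector of length s(s-1)/2
#' @export
pairwise_distances <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 non-missing strain values", call. = FALSE)
  cb <- utils::combn(length(values), 2)
  d <- abs(values[cb[1, ]] - values[cb[2, ]])
  nm <- names(values) %||% as.character(seq_along(values))
  stats::setNames(as.numeric(d), paste(nm[cb[1, ]], nm[cb[2, ]], sep = "|"))
}

#' Mann-Whitney U statistic
#'
#' Counts pairs with x < y (ties count one half), x drawn from `xs` and y
#' from `ys`.
#'
#' @param xs,ys numeric samples (here: EP and WT distance vectors)
#' @return the U statistic
#' @export
mwu_u <- function(xs, ys) {
  if (!length(xs) || !length(ys)) stop("both samples must be non-empty", call. = FALSE)
  sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))
}

#' Normal-approximation p-value for the Mann-Whitney U statistic
#'
#' Gaussian tail of (U +/- 1/2 - n1 n2 / 2) / sigma with
#' sigma^2 = n1 n2 / 12 * ((n + 1) - T / (n (n - 1))), where T = sum(t^3 - t)
#' over tie groups. The exact-table alternative is unavailable for small U,
#' hence the approximation; the half-unit continuity correction is on by
#' default.
#'
#' @param U the U statistic (pairs with x < y)
#' @param n1,n2 sample sizes
#' @param alternative `"less"` (lower tail of U) or `"greater"` (upper tail)
#' @param continuity apply the 1/2 continuity correction
#' @param tie_sum tie-correction term sum(t^3 - t) over tied groups of the
#'   pooled sample (0 when no ties)
#' @return one-sided p-value
#' @export
mwu_normal_p <- function(U, n1, n2, alternative = c("greater", "less"),
                         continuity = TRUE, tie_sum = 0) {
  alternative <- match.arg(alternative)
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1", call. = FALSE)
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values tied: U variance is zero; p = 1", call. = FALSE)
    return(1)
  }
  cc <- if (continuity) 0.5 else 0
  if (alternative == "less") {
    stats::pnorm((U + cc - mu) / sqrt(sigma2))
  } else {
    stats::pnorm((U - cc - mu) / sqrt(sigma2), lower.tail = FALSE)
  }
}

# U and tie term from two samples.
mwu_test <- function(xs, ys, alternative, continuity = TRUE) {
  U <- mwu_u(xs, ys)
  tt <- table(c(xs, ys))
  tie_sum <- sum(tt^3 - tt)
  p <- mwu_normal_p(U, length(xs), length(ys), alternative = alternative,
                    continuity = continuity, tie_sum = tie_sum)
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]).
#'
#' @param pvalues p-values in `[0, 1]`
#' @return adjusted q-values
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify phenotypes as convergent, divergent or neither
#'
#' For each phenotype the per-strain WT and EP means are reduced to pairwise
#' distance vectors; U counts (EP < WT) pairs, so convergence is the upper
#' tail and divergence the lower tail. BH adjustment is applied within each
#' direction across the phenotype panel; a phenotype is labeled by whichever
#' direction passes `fdr` (at most one can).
#'
#' @param phenotypes phenotype panel data.frame (see [read_phenotypes()])
#' @param fdr false-discovery-rate threshold
#' @param continuity continuity correction for the normal approximation
#' @return data.frame with one row per tested phenotype: U, both one-sided
#'   p-values, their q-values and the label
#' @export
classify_convergence <- function(phenotypes, fdr = 0.05, continuity = TRUE) {
  ids <- unique(phenotypes$phenotype_id)
  rows <- list()
  for (pid in ids) {
    sub <- phenotypes[phenotypes$phenotype_id == pid, ]
    wt <- sub$value[sub$stage == "WT"]
    names(wt) <- sub$strain[sub$stage == "WT"]
    ep <- sub$value[sub$stage == "EP"]
    names(ep) <- sub$strain[sub$stage == "EP"]
    strains <- intersect(names(wt)[!is.na(wt)], names(ep)[!is.na(ep)])
    if (length(strains) < 2) {
      warning("phenotype ", pid, " lacks WT and EP means for >= 2 strains; skipped",
              call. = FALSE)
      next
    }
    d_wt <- pairwise_distances(wt[strains])
    d_ep <- pairwise_distances(ep[strains])
    conv <- mwu_test(d_ep, d_wt, "greater", continuity)
    div <- mwu_test(d_ep, d_wt, "less", continuity)
    rows[[pid]] <- data.frame(
      phenotype_id = pid, U = conv$U,
      p_convergent = conv$p, p_divergent = div$p,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no testable phenotypes", call. = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q_convergent <- bh_fdr(res$p_convergent)
  res$q_divergent <- bh_fdr(res$p_divergent)
  res$label <- ifelse(res$q_convergent <= fdr, "convergent",
                      ifelse(res$q_divergent <= fdr, "divergent", "neither"))
  res
}

#' Growth-correlation screen
#'
#' Pearson correlation of each target (phenotype, flux, iModulon activity,
#' ...) against growth rate across all flasks with strains pooled; two-sided
#' p-values; BH across targets.
#'
#' @param values targets x observations numeric matrix (row names are target
#'   ids)
#' @param growth growth rate per observation, 1/h
#' @param fdr significance threshold on the q-value
#' @return data.frame with r, p, q and a `significant` flag per target
#' @export
growth_correlation_screen <- function(values, growth, fdr = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) != length(growth)) {
    stop("growth must have one value per observation", call. = FALSE)
  }
  ok <- !is.na(growth)
  if (sum(ok) < 3) stop("need >= 3 paired observations", call. = FALSE)
  r <- p <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    v <- values[i, ok]
    if (stats::sd(v) == 0) {
      r[i] <- 0; p[i] <- 1
      next
    }
    ct <- stats::cor.test(v, growth[ok])
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  out <- data.frame(target = rownames(values) %||% as.character(seq_len(nrow(values))),
                    r = r, p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  out$significant <- out$q <= fdr & out$r != 0
  out
}

#' One-way fixed-effects ANOVA F-test for strain specificity
#'
#' @param values numeric observations
#' @param groups strain label per observation
#' @return list with the F statistic and upper-tail p-value
#' @export
anova_f_strain <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 strains", call. = FALSE)
  if (any(sizes < 2)) stop("each strain needs >= 2 observations", call. = FALSE)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    means <- tapply(values, groups, mean)
    if (stats::var(means) == 0) return(list(F = NaN, p = 1))
    warning("zero within-group variance everywhere; F = Inf", call. = FALSE)
    return(list(F = Inf, p = 0))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value)
}
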