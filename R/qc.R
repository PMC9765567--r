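# Compendium quality-control filters and small unit conversions.

#' Filter genes by length and per-sample expression support
#'
#' Keeps genes that are at least `min_length` nucleotides long and reach at
#' least `min_fpm` fragments per million mapped reads in every sample. FPM is
#' computed per sample against the total mapped fragments present in the
#' table.
#'
#' @param counts genes x samples matrix of non-negative fragment counts with
#'   gene row names
#' @param gene_lengths numeric vector of gene lengths (nt), aligned to rows
#' @param min_length minimum gene length in nucleotides
#' @param min_fpm minimum fragments per million mapped reads, required in
#'   every sample
#' @return character vector of kept gene ids
#' @export
filter_genes <- function(counts, gene_lengths, min_length = 100, min_fpm = 10) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must have one entry per gene", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero mapped fragments (FPM undefined): ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  fpm <- sweep(counts, 2, totals / 1e6, "/")
  keep <- (gene_lengths >= min_length) & apply(fpm >= min_fpm, 1, all)
  rownames(counts)[keep]
}

#' Replicate concordance filter on log-TPM profiles
#'
#' Flags biological replicate pairs whose squared Pearson correlation of
#' log-TPM falls below `r2_min`. In a group of two, a failing pair removes
#' both replicates; in larger groups the replicate with the lowest mean
#' pairwise R-squared is dropped repeatedly until every remaining pair
#' passes.
#'
#' @param X genes x samples log-TPM matrix
#' @param replicate_groups list of character vectors of sample ids, one per
#'   biological replicate group
#' @param r2_min minimum pairwise R-squared
#' @return list with `kept` and `removed` sample-id vectors and a `pairs`
#'   data.frame of all initial pairwise R-squared values
#' @export
replicate_qc <- function(X, replicate_groups, r2_min = 0.9) {
  kept <- character()
  removed <- character()
  pair_rows <- list()
  for (gi in seq_along(replicate_groups)) {
    g <- replicate_groups[[gi]]
    miss <- setdiff(g, colnames(X))
    if (length(miss)) stop("sample(s) not in matrix: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (length(g) < 2) stop("replicate group with fewer than 2 samples", call. = FALSE)
    sds <- apply(X[, g, drop = FALSE], 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant expression vector (correlation undefined): ",
           paste(g[sds == 0], collapse = ", "), call. = FALSE)
    }
    r2 <- stats::cor(X[, g, drop = FALSE])^2
    cb <- utils::combn(g, 2)
    pair_rows[[gi]] <- data.frame(
      group = gi,
      sample_a = cb[1, ], sample_b = cb[2, ],
      r2 = r2[cbind(cb[1, ], cb[2, ])],
      stringsAsFactors = FALSE
    )
    cur <- g
    repeat {
      rc <- r2[cur, cur, drop = FALSE]
      off <- rc[upper.tri(rc)]
      if (all(off >= r2_min)) break
      if (length(cur) == 2) {
        cur <- character()
        break
      }
      mean_r2 <- (rowSums(rc) - 1) / (length(cur) - 1)
      cur <- setdiff(cur, names(which.min(mean_r2)))
    }
    kept <- c(kept, cur)
    removed <- c(removed, setdiff(g, cur))
  }
  pairs <- do.call(rbind, pair_rows)
  pairs$pass <- pairs$r2 >= r2_min
  list(kept = kept, removed = removed, pairs = pairs)
}

#' log2(TPM + 1) transform
#'
#' @param tpm non-negative TPM values
#' @return log2(tpm + 1), same shape
#' @export
log_tpm_transform <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0", call. = FALSE)
  log2(tpm + 1)
}

#' Convert optical density to dry-weight concentration
#'
#' Uses the standard E. coli relationship 1.0 OD600 = 0.32 gDW/L.
#'
#' @param od600 optical density at 600 nm (>= 0)
#' @return biomass concentration in gDW/L
#' @export
od_to_gdw <- function(od600) {
  if (any(od600 < 0, na.rm = TRUE)) stop("OD600 must be >= 0", call. = FALSE)
  0.32 * od600
}
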