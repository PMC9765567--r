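# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of the simulator draw their own seed from the master
#' seed so that adding a stage never perturbs the draws of another.
#' Kept strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param k stage index (small non-negative integer)
#' @return an integer seed
#' @keywords internal
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 104729 * k) %% 2147483647L)
}

stop_if_not_numeric <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
}

# Write a data frame as CSV with numeric columns rendered at full double
# precision (%.17g), so that write -> read round-trips are bit-exact.
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Canonical unordered-pair labels, "a|b" with fixed input order.
pair_labels <- function(ids) {
  cb <- utils::combn(ids, 2)
  paste(cb[1, ], cb[2, ], sep = "|")
}
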