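# Independent oracles and small fixture builders. Everything here is
# deliberately brute-force and separate from the package's own code paths.

# Benjamini-Hochberg step-up, written out literally.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m / i * p[o[i]])
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Exact null distribution of U = #{x < y} for two tie-free samples of sizes
# n1, n2: enumerate every placement of the x-ranks among 1..(n1+n2).
mwu_exact_tail <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  # U = #{x < y} = sum over x of (number of y with larger rank)
  u_vals <- apply(combos, 2, function(xr) {
    sum(vapply(xr, function(r) sum(!(seq_len(n) %in% xr) & seq_len(n) > r),
               numeric(1)))
  })
  tab <- table(u_vals) / ncol(combos)
  u <- as.numeric(names(tab))
  list(u = u, prob = as.numeric(tab))
}

# OLS via explicit normal equations.
normal_eq_fit <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), r2 = r2)
}

# Pool-adjacent-violators for non-decreasing fit (uniform weights).
pava_oracle <- function(y) {
  blocks <- lapply(y, function(v) list(sum = v, n = 1))
  i <- 1
  while (i < length(blocks)) {
    a <- blocks[[i]]; b <- blocks[[i + 1]]
    if (a$sum / a$n > b$sum / b$n + 1e-15) {
      blocks[[i]] <- list(sum = a$sum + b$sum, n = a$n + b$n)
      blocks[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else {
      i <- i + 1
    }
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$n, b$n)))
}

# Minimal metadata for hand-built activity/expression fixtures.
toy_meta <- function(strains = c("A", "B"), flasks = c(0, 5, 9), reps = 2,
                     growth = NULL) {
  rows <- list()
  for (si in seq_along(strains)) {
    g <- growth %||% seq(0.6, 1.05, length.out = length(flasks))
    for (fi in seq_along(flasks)) {
      for (r in seq_len(reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_f%02d_r%d", strains[si], flasks[fi], r),
          strain = strains[si], flask_index = flasks[fi],
          replicate_id = paste0("r", r),
          stage = if (length(flasks) == 1) "WT" else
            c("WT", rep("intermediate", max(0, length(flasks) - 2)), "EP")[fi],
          growth_rate = g[fi], stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# iModulon names large enough for the default truth layout.
toy_imodulons <- function(n = 25) sprintf("IM%02d", seq_len(n))
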