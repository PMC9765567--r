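# Fitness-trajectory utilities and the jump-specific view of the data.
#
# A "jump" is the difference between two consecutively assayed flasks of one
# strain: in growth rate, in omics profiles, and in gained mutations.

#' Growth rate from OD measurements
#'
#' Ordinary least-squares slope of ln(OD600) against time.
#'
#' @param times sampling times in hours, strictly increasing
#' @param ods OD600 readings, all > 0
#' @return growth rate in 1/h
#' @export
growth_rate_from_od <- function(times, ods) {
  if (length(times) < 2 || length(ods) != length(times)) {
    stop("need >= 2 paired (time, OD) points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(ods <= 0)) stop("OD values must be > 0", call. = FALSE)
  y <- log(ods)
  tc <- times - mean(times)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Monotone smoothing of a fitness trajectory
#'
#' Node growth rates are first made monotone non-decreasing by isotonic
#' regression (pool adjacent violators), then joined by a shape-preserving
#' monotone cubic interpolant (PCHIP), which never overshoots between nodes.
#'
#' @param flask_indices strictly increasing flask indices (>= 2 nodes)
#' @param rates growth rates at those flasks, 1/h
#' @param n_grid number of points of the sampled smoothed curve
#' @return list with the sampled curve (`x`, `y`), the node positions
#'   (`node_x`) and the isotonic-adjusted node values (`node_values`)
#' @export
smooth_trajectory <- function(flask_indices, rates, n_grid = 201) {
  if (length(flask_indices) < 2) stop("need >= 2 nodes", call. = FALSE)
  if (any(diff(flask_indices) <= 0)) {
    stop("flask indices must be strictly increasing", call. = FALSE)
  }
  if (length(rates) != length(flask_indices)) {
    stop("rates must align with flask indices", call. = FALSE)
  }
  node <- stats::isoreg(flask_indices, rates)$yf
  xg <- seq(min(flask_indices), max(flask_indices), length.out = n_grid)
  yg <- pracma::pchip(flask_indices, node, xg)
  list(x = xg, y = yg, node_x = flask_indices, node_values = node)
}

#' Doubling time in minutes
#'
#' @param rate growth rate in 1/h, > 0
#' @return doubling time, 60 * ln(2) / rate, in minutes
#' @export
doubling_time_minutes <- function(rate) {
  if (any(rate <= 0)) stop("growth rate must be > 0", call. = FALSE)
  60 * log(2) / rate
}

# Average replicate columns of a features x samples matrix down to one
# column per (strain, flask). Column names become "<strain>_f<flask>".
# Matrices already at flask level (columns named "<strain>_f<flask>") are
# passed through.
flask_level <- function(X, meta) {
  flask_ids <- unique(paste0(meta$strain, "_f", meta$flask_index))
  if (all(colnames(X) %in% flask_ids)) {
    key <- colnames(X)
    fm <- unique(meta[, c("strain", "flask_index", "growth_rate")])
    fm$flask_id <- paste0(fm$strain, "_f", fm$flask_index)
    gr <- tapply(meta$growth_rate,
                 paste0(meta$strain, "_f", meta$flask_index), mean)
    info <- fm[match(key, fm$flask_id), c("strain", "flask_index")]
    info$growth_rate <- as.numeric(gr[key])
    info$flask_id <- key
    rownames(info) <- NULL
    return(list(values = X, info = info))
  }
  meta <- meta[match(colnames(X), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("samples missing from metadata", call. = FALSE)
  key <- paste0(meta$strain, "_f", meta$flask_index)
  groups <- split(seq_len(ncol(X)), key)[unique(key)]
  out <- vapply(groups, function(j) rowMeans(X[, j, drop = FALSE]),
                numeric(nrow(X)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = 1, dimnames = list(rownames(X), names(groups)))
  }
  info <- meta[!duplicated(key), c("strain", "flask_index", "growth_rate")]
  info$growth_rate <- vapply(groups, function(j) mean(meta$growth_rate[j]),
                             numeric(1))
  info$flask_id <- unique(key)
  rownames(info) <- NULL
  list(values = out, info = info)
}

#' Jump-specific differencing of a flask-level feature matrix
#'
#' Replicates are averaged per (strain, flask), then each strain's
#' consecutive assayed flask pairs are differenced (later minus earlier).
#' A 22-flask, 6-strain design yields 16 jumps. When mutation events are
#' supplied, each jump also records the loci gained at its destination
#' flask.
#'
#' @param X features x samples numeric matrix (e.g. activities or fluxes)
#' @param meta sample metadata (see [read_metadata()])
#' @param mutations optional mutation event data.frame (see
#'   [read_mutations()])
#' @return list with `delta` (jumps x features matrix), `jumps` (a
#'   data.frame with jump_id, strain, from_flask, to_flask, delta_growth)
#'   and `gained` (named list of gained loci per jump)
#' @export
compute_jumps <- function(X, meta, mutations = NULL) {
  fl <- flask_level(X, meta)
  info <- fl$info
  rows <- list()
  jump_meta <- list()
  for (s in unique(info$strain)) {
    idx <- which(info$strain == s)
    idx <- idx[order(info$flask_index[idx])]
    if (length(idx) < 2) {
      warning("strain ", s, " has a single assayed flask; no jumps", call. = FALSE)
      next
    }
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      jid <- paste0(s, "_j", info$flask_index[i], "_", info$flask_index[j])
      rows[[jid]] <- fl$values[, j] - fl$values[, i]
      jump_meta[[jid]] <- data.frame(
        jump_id = jid, strain = s,
        from_flask = info$flask_index[i], to_flask = info$flask_index[j],
        delta_growth = info$growth_rate[j] - info$growth_rate[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no strain has two assayed flasks", call. = FALSE)
  delta <- do.call(rbind, rows)
  colnames(delta) <- rownames(X)
  jumps <- do.call(rbind, jump_meta)
  rownames(jumps) <- NULL
  gained <- NULL
  if (!is.null(mutations)) {
    gained <- gained_mutations(mutations, jumps, info)
  }
  list(delta = delta, jumps = jumps, gained = gained)
}

# Map mutation events onto jumps. An event is present in its strain from its
# observed flask onward; it is "gained" in the jump ending at the first
# assayed flask >= observed_flask. Events observed at or before a strain's
# first assayed flask belong to the WT state and are never gained.
gained_mutations <- function(mutations, jumps, flask_info) {
  gained <- stats::setNames(vector("list", nrow(jumps)), jumps$jump_id)
  gained[] <- list(character())
  # a locus is present from its earliest event in a strain
  first <- stats::aggregate(observed_flask ~ strain + locus, mutations, min)
  for (i in seq_len(nrow(first))) {
    s <- first$strain[i]
    assayed <- sort(flask_info$flask_index[flask_info$strain == s])
    if (!length(assayed)) next
    obs <- first$observed_flask[i]
    cand <- assayed[assayed >= obs]
    if (!length(cand)) {
      warning("mutation at ", first$locus[i], " observed after the last ",
              "assayed flask of ", s, "; dropped", call. = FALSE)
      next
    }
    eff <- cand[1]
    if (eff != obs) {
      warning("mutation at ", first$locus[i], " (", s, ") observed at ",
              "unassayed flask ", obs, "; assigned to flask ", eff, call. = FALSE)
    }
    if (eff == assayed[1]) next  # WT allele
    jid <- jumps$jump_id[jumps$strain == s & jumps$to_flask == eff]
    if (length(jid) == 1) {
      gained[[jid]] <- unique(c(gained[[jid]], first$locus[i]))
    }
  }
  gained
}
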