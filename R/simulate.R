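# Synthetic six-strain ALE multi-omics generator.
#
# Emulates the assay structure of a multi-strain adaptive laboratory
# evolution campaign: 6 strains, 3-4 assayed flasks each (22 flasks, hence
# 16 jumps), biological duplicates, expression built as X = M %*% A plus
# Gaussian noise, replicate activity differences with log-normal magnitude,
# and planted signals for every downstream screen: growth-correlated
# iModulons, negatively coupled trade-off pairs, strain-specific WT
# offsets, convergent/divergent/neutral phenotypes, and causal mutations
# coupled to jump-specific flux or activity changes. Every planted signal
# is recorded in a truth object so recovery can be scored.

ALE_STRAINS <- c("MG1655", "W3110", "BL21", "C", "W", "Crooks")

IMODULON_CATEGORY_POOL <- c(
  "stress response", "translation", "motility", "carbon metabolism",
  "metal homeostasis", "amino acid biosynthesis", "nucleotide biosynthesis",
  "structural components", "cofactor metabolism", "regulatory", "unknown"
)

FLUX_REACTIONS <- c("G6PDH", "ME2", "SUCCOAS", "EDD", "PGI", "PFK", "PYK",
                    "CS", "ICDH", "THD2")

#' Generate the sampling design of a multi-strain ALE campaign
#'
#' Six strains with 3-4 assayed flasks each (22 flasks by default, which
#' difference to 16 jumps) and two biological replicates per flask. Growth
#' rates rise monotonically from a strain-specific wild-type value to a
#' plateau drawn from `plateau_range` (defaults span 0.98-1.11 1/h, i.e.
#' doubling times of roughly 38-42 min). Flask 0 is the preculture and the
#' WT stage; the last assayed flask is the evolved endpoint (EP).
#'
#' @param n_strains number of strains (>= 2)
#' @param flasks_per_strain integer vector (recycled) of assayed flasks per
#'   strain
#' @param replicates biological replicates per flask (>= 2; the replicate
#'   null is unfittable below 2)
#' @param seed integer seed
#' @param wt_rate_range range of wild-type growth rates, 1/h
#' @param plateau_range range of endpoint plateau growth rates, 1/h
#' @return sample metadata data.frame (one row per sample)
#' @export
generate_design <- function(n_strains = 6, flasks_per_strain = c(4, 4, 4, 4, 3, 3),
                            replicates = 2, seed = 1,
                            wt_rate_range = c(0.55, 0.85),
                            plateau_range = c(0.98, 1.11)) {
  if (n_strains < 2) stop("need >= 2 strains", call. = FALSE)
  if (replicates < 2) stop("need >= 2 replicates (replicate null unfittable)",
                           call. = FALSE)
  set.seed(seed)
  strains <- if (n_strains <= length(ALE_STRAINS)) ALE_STRAINS[seq_len(n_strains)]
             else c(ALE_STRAINS, sprintf("S%02d", seq_len(n_strains - length(ALE_STRAINS))))
  nf <- rep_len(flasks_per_strain, n_strains)
  rows <- list()
  for (i in seq_len(n_strains)) {
    s <- strains[i]
    flasks <- c(0, cumsum(sample(4:10, nf[i] - 1, replace = TRUE)))
    wt <- stats::runif(1, wt_rate_range[1], wt_rate_range[2])
    plateau <- stats::runif(1, plateau_range[1], plateau_range[2])
    frac <- seq(0, 1, length.out = nf[i])^0.7
    rates <- wt + (plateau - wt) * frac
    stage <- c("WT", rep("intermediate", nf[i] - 2), "EP")
    for (k in seq_len(nf[i])) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_f%02d_r%d", s, flasks[k], r),
          strain = s, flask_index = flasks[k],
          replicate_id = paste0("r", r), stage = stage[k],
          growth_rate = rates[k], stringsAsFactors = FALSE
        )
      }
    }
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  validate_metadata(meta)
  meta
}

#' Generate a sparse, near-orthogonal iModulon gene-weight basis
#'
#' Each column receives `round(sparsity * n_genes)` nonzero Gaussian
#' weights at random gene positions; the default weight scale (s.d. 0.5)
#' mirrors the small per-gene weights of ICA-derived regulatory bases. A rank-deficient draw is redrawn with
#' an incremented sub-seed (with a message). iModulons are assigned
#' functional-category labels (attached as the `"categories"` attribute).
#'
#' @param n_genes number of genes (> n_imodulons)
#' @param n_imodulons number of iModulons
#' @param sparsity fraction of nonzero weights per column
#' @param seed integer seed
#' @param weight_sd standard deviation of the nonzero weights
#' @param max_tries redraw budget for rank-deficient draws
#' @return genes x iModulons matrix with a `"categories"` attribute
#' @export
generate_imodulon_model <- function(n_genes = 1000, n_imodulons = 20,
                                    sparsity = 0.1, seed = 1, weight_sd = 0.5,
                                    max_tries = 10) {
  if (n_genes <= n_imodulons) stop("need n_genes > n_imodulons", call. = FALSE)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]", call. = FALSE)
  nz <- max(1L, round(sparsity * n_genes))
  for (try in seq_len(max_tries)) {
    set.seed(sub_seed(seed, try - 1))
    M <- matrix(0, n_genes, n_imodulons,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("IM%02d", seq_len(n_imodulons))))
    for (j in seq_len(n_imodulons)) {
      idx <- sample.int(n_genes, nz)
      M[idx, j] <- stats::rnorm(nz, 0, weight_sd)
    }
    if (qr(M)$rank == n_imodulons) {
      attr(M, "categories") <- stats::setNames(
        rep_len(IMODULON_CATEGORY_POOL, n_imodulons), colnames(M))
      return(M)
    }
    message("rank-deficient basis draw; redrawing with incremented sub-seed")
  }
  stop("could not draw a full-rank basis in ", max_tries, " tries", call. = FALSE)
}

#' Default planted-truth object
#'
#' Encodes, at a desk scale, the signal structure the screens are built to
#' recover: 6 growth-correlated iModulons (3 positive, 3 negative), 3
#' negatively coupled trade-off pairs, strain-specific WT activity offsets
#' on 5 iModulons, a 10 convergent / 2 divergent / 50 neutral phenotype
#' panel (8 of the 10 convergent phenotypes converging through growth
#' coupling), and 12 causal loci (4 coupled to reaction fluxes, 8 to iModulon
#' activities) with effect size 10 against the absolute DIMA threshold
#' of 5.
#'
#' @param imodulon_names iModulon names (>= 20 for the full default layout)
#' @param strains strain names
#' @param n_phenotypes total phenotype panel size
#' @param flux_reactions flux reaction ids
#' @return a list of planted signals (class `ale_truth`)
#' @export
default_truth <- function(imodulon_names, strains = ALE_STRAINS,
                          n_phenotypes = 62, flux_reactions = FLUX_REACTIONS) {
  im <- imodulon_names
  if (length(im) < 25) stop("default truth layout needs >= 25 iModulons",
                            call. = FALSE)
  pid <- sprintf("p%03d", seq_len(n_phenotypes))
  n_conv <- 10; n_div <- 2
  if (n_phenotypes < n_conv + n_div) {
    stop("n_phenotypes smaller than the planted label count", call. = FALSE)
  }
  causal <- data.frame(
    locus = c("zwf", "pykF", "lysC", "gnd",
              "rpoB", "rpoC", "spoT", "hns/tdk", "folM", "mrdA", "proQ",
              "pntA/ydgH"),
    target_kind = c(rep("flux", 4), rep("imodulon", 8)),
    target = c("G6PDH", "ME2", "SUCCOAS", "EDD", im[18:25]),
    effect = rep(c(10, -10), 6),
    stringsAsFactors = FALSE
  )
  stopifnot(all(causal$target[causal$target_kind == "flux"] %in% flux_reactions))
  structure(list(
    convergent_phenotypes = pid[seq_len(n_conv)],
    growth_correlated_phenotypes = pid[seq_len(8)],
    divergent_phenotypes = pid[n_conv + seq_len(n_div)],
    neutral_phenotypes = pid[(n_conv + n_div + 1):n_phenotypes],
    growth_correlated_imodulons = stats::setNames(c(1, 1, 1, -1, -1, -1), im[1:6]),
    tradeoff_pairs = data.frame(
      imodulon_a = im[c(7, 9, 11)], imodulon_b = im[c(8, 10, 12)],
      coupling = c(1, 0.8, 1.2), stringsAsFactors = FALSE
    ),
    wt_offset_imodulons = stats::setNames(
      lapply(seq_len(min(5, length(strains))), function(i)
        stats::setNames((-1)^i * 20, im[12 + i])),
      strains[seq_len(min(5, length(strains)))]
    ),
    causal_mutations = causal
  ), class = "ale_truth")
}

# effective assayed flask (first assayed >= observed) per causal event
causal_shift_table <- function(mutations, truth, meta) {
  causal <- truth$causal_mutations
  ev <- mutations[mutations$locus %in% causal$locus, , drop = FALSE]
  if (!nrow(ev)) return(NULL)
  first <- stats::aggregate(observed_flask ~ strain + locus, ev, min)
  out <- list()
  for (i in seq_len(nrow(first))) {
    s <- first$strain[i]
    assayed <- sort(unique(meta$flask_index[meta$strain == s]))
    cand <- assayed[assayed >= first$observed_flask[i]]
    if (!length(cand) || cand[1] == assayed[1]) next
    spec <- causal[causal$locus == first$locus[i], ]
    out[[i]] <- data.frame(strain = s, from_flask = cand[1],
                           target_kind = spec$target_kind, target = spec$target,
                           effect = spec$effect, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Generate planted mutation events
#'
#' Each causal locus of the truth is gained in `strains_per_locus` randomly
#' chosen strains, at one random jump each (observed at the jump's
#' destination flask). Background loci receive events at uniformly random
#' (strain, destination flask) positions at an expected `background_rate`
#' events per jump.
#'
#' @param design sample metadata from [generate_design()]
#' @param truth planted-truth object
#' @param background_rate expected background events per jump
#' @param n_background_loci size of the background locus pool
#' @param strains_per_locus strains in which each causal locus appears
#' @param seed integer seed
#' @return mutation event data.frame
#' @export
generate_mutations <- function(design, truth, background_rate = 1.5,
                               n_background_loci = 10, strains_per_locus = 2,
                               seed = 1) {
  set.seed(seed)
  strains <- unique(design$strain)
  flasks <- lapply(stats::setNames(strains, strains), function(s)
    sort(unique(design$flask_index[design$strain == s])))
  n_jumps <- sum(vapply(flasks, length, integer(1)) - 1)
  types <- c("SNP", "indel", "mobile_element", "large_deletion")
  rows <- list()
  add_event <- function(s, locus, flask) {
    rows[[length(rows) + 1]] <<- data.frame(
      strain = s, replicate_id = "r1", locus = locus,
      nucleotide_id = paste0(gsub("/", "_", locus, fixed = TRUE), ".",
                             sample.int(99999, 1)),
      mutation_type = sample(types, 1, prob = c(0.6, 0.2, 0.1, 0.1)),
      observed_flask = flask, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(truth$causal_mutations))) {
    locus <- truth$causal_mutations$locus[i]
    eligible <- strains[vapply(flasks[strains], length, integer(1)) >= 2]
    hit <- sample(eligible, min(strains_per_locus, length(eligible)))
    for (s in hit) {
      dest <- flasks[[s]][-1]
      add_event(s, locus, sample(dest, 1))
    }
  }
  bg_loci <- sprintf("y%s%s", sample(letters, n_background_loci, replace = TRUE),
                     sprintf("b%02d", seq_len(n_background_loci)))
  n_bg <- stats::rpois(1, background_rate * n_jumps)
  for (k in seq_len(n_bg)) {
    s <- sample(strains, 1)
    dest <- flasks[[s]][-1]
    add_event(s, sample(bg_loci, 1), sample(dest, 1))
  }
  mut <- do.call(rbind, rows)
  rownames(mut) <- NULL
  validate_mutations(mut)
  mut
}

#' Generate flask-level iModulon activities with planted signals
#'
#' Baseline activities are per-iModulon levels shared across strains (so
#' that wild-type states differ between strains only through the planted
#' offsets) plus flask-to-flask noise. Growth-correlated iModulons follow
#' an affine function of the within-strain growth-rate gain; trade-off
#' pairs obey B = -c * A + intercept + noise, with A a per-strain random
#' walk starting at the shared baseline; WT offsets apply at each strain's
#' first flask only; causal mutation shifts (when `mutations` is given)
#' apply from the gaining flask onward. Replicate pairs then differ by
#' symmetric noise +/- d/2 with |d| log-normal, which is exactly the form
#' the DIMA null assumes.
#'
#' The default growth-correlation slope places the within-strain signal at
#' about three noise standard deviations: strong enough for per-strain
#' Pearson |R| well above 0.75, while keeping the activity-vs-activity
#' coupling between opposite-sign growth-correlated iModulons far below
#' the trade-off ANCOVA R-squared threshold, so the only near-perfect
#' negative couplings are the planted pairs.
#'
#' @param design sample metadata
#' @param imodulon_names iModulon names
#' @param truth planted-truth object
#' @param replicate_noise c(meanlog, sdlog) of the replicate difference
#'   magnitude
#' @param flask_noise_sd baseline flask-to-flask activity noise (activity
#'   units)
#' @param gc_slope activity change per unit growth rate for planted
#'   growth-correlated iModulons
#' @param walk_sd step size of the trade-off driver random walk
#' @param seed integer seed
#' @param mutations optional mutation events for causal activity shifts
#' @return iModulons x samples activity matrix
#' @export
generate_activities <- function(design, imodulon_names, truth,
                                replicate_noise = c(meanlog = 0, sdlog = 0.5),
                                flask_noise_sd = 0.5, gc_slope = 18,
                                walk_sd = 14, seed = 1, mutations = NULL) {
  bad <- setdiff(c(names(truth$growth_correlated_imodulons),
                   truth$tradeoff_pairs$imodulon_a,
                   truth$tradeoff_pairs$imodulon_b,
                   unlist(lapply(truth$wt_offset_imodulons, names))),
                 imodulon_names)
  if (length(bad)) stop("truth references unknown iModulon(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(truth$tradeoff_pairs$coupling <= 0)) {
    stop("trade-off coupling coefficients must be > 0 (negative coupling ",
         "is applied as B = -c * A)", call. = FALSE)
  }
  set.seed(seed)
  flasks <- unique(design[, c("strain", "flask_index", "growth_rate")])
  flask_id <- paste0(flasks$strain, "_f", flasks$flask_index)
  n_im <- length(imodulon_names)
  V <- matrix(NA_real_, n_im, nrow(flasks),
              dimnames = list(imodulon_names, flask_id))
  gc <- truth$growth_correlated_imodulons
  pairs <- truth$tradeoff_pairs
  driver <- pairs$imodulon_a
  coupled <- pairs$imodulon_b
  base <- stats::setNames(stats::rnorm(n_im, 0, 2), imodulon_names)
  for (s in unique(flasks$strain)) {
    idx <- which(flasks$strain == s)
    idx <- idx[order(flasks$flask_index[idx])]
    nf <- length(idx)
    g <- flasks$growth_rate[idx]
    for (im in imodulon_names) {
      V[im, idx] <- base[[im]] + stats::rnorm(nf, 0, flask_noise_sd)
    }
    for (im in names(gc)) {
      V[im, idx] <- base[[im]] + gc[[im]] * gc_slope * (g - g[1]) +
        stats::rnorm(nf, 0, flask_noise_sd)
    }
    for (k in seq_along(driver)) {
      walk <- base[[driver[k]]] + c(0, cumsum(stats::rnorm(nf - 1, 0, walk_sd)))
      V[driver[k], idx] <- walk + stats::rnorm(nf, 0, flask_noise_sd)
      V[coupled[k], idx] <- -pairs$coupling[k] * walk +
        base[[coupled[k]]] + stats::rnorm(nf, 0, flask_noise_sd)
    }
    off <- truth$wt_offset_imodulons[[s]]
    if (!is.null(off)) {
      V[names(off), idx[1]] <- V[names(off), idx[1]] + off
    }
  }
  if (!is.null(mutations)) {
    shifts <- causal_shift_table(mutations, truth, design)
    shifts <- shifts[shifts$target_kind == "imodulon" &
                       shifts$target %in% imodulon_names, , drop = FALSE]
    for (i in seq_len(NROW(shifts))) {
      idx <- which(flasks$strain == shifts$strain[i] &
                     flasks$flask_index >= shifts$from_flask[i])
      V[shifts$target[i], idx] <- V[shifts$target[i], idx] + shifts$effect[i]
    }
  }
  # replicate layer: symmetric +/- d/2 within each pair, |d| log-normal
  A <- matrix(NA_real_, n_im, nrow(design),
              dimnames = list(imodulon_names, design$sample_id))
  for (j in seq_len(nrow(flasks))) {
    reps <- design$sample_id[design$strain == flasks$strain[j] &
                               design$flask_index == flasks$flask_index[j]]
    r <- 1
    while (r <= length(reps)) {
      d <- stats::rlnorm(n_im, replicate_noise[["meanlog"]],
                         replicate_noise[["sdlog"]])
      sgn <- sample(c(-1, 1), n_im, replace = TRUE)
      if (r + 1 <= length(reps)) {
        A[, reps[r]] <- V[, j] - sgn * d / 2
        A[, reps[r + 1]] <- V[, j] + sgn * d / 2
        r <- r + 2
      } else {
        A[, reps[r]] <- V[, j] + sgn * d / 2
        r <- r + 1
      }
    }
  }
  A
}

#' Generate expression from the basis and activities
#'
#' X = M %*% A plus iid Gaussian noise. An optional per-gene baseline
#' (constant across samples, like the large between-gene differences in
#' mean log-TPM of a real compendium) can be added; being constant per
#' gene, it is absorbed as a fixed per-iModulon offset by the projection
#' and cancels in every difference- or correlation-based screen. With
#' `nonneg = TRUE` (default) a global additive shift then makes all values
#' non-negative (log-TPM-like); shift and baseline are recorded as
#' attributes.
#'
#' @param M genes x iModulons weight matrix
#' @param A iModulons x samples activity matrix
#' @param noise_sd Gaussian noise standard deviation
#' @param seed integer seed
#' @param baseline optional c(mean, sd) of the per-gene baseline; NULL for
#'   none (then X = M A exactly at zero noise)
#' @param nonneg shift values to be >= 0
#' @return genes x samples expression matrix with `"shift"` and
#'   `"baseline"` attributes
#' @export
generate_expression <- function(M, A, noise_sd = 0.5, seed = 1,
                                baseline = NULL, nonneg = TRUE) {
  if (ncol(M) != nrow(A)) stop("M and A are not conformable", call. = FALSE)
  set.seed(seed)
  X <- M %*% A
  base_g <- NULL
  if (!is.null(baseline)) {
    base_g <- stats::rnorm(nrow(M), baseline[1], baseline[2])
    X <- X + base_g
  }
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(length(X), 0, noise_sd),
                                    nrow(X), ncol(X))
  shift <- 0
  if (nonneg && min(X) < 0) {
    shift <- -min(X)
    X <- X + shift
  }
  attr(X, "shift") <- shift
  attr(X, "baseline") <- base_g
  X
}

#' Generate a phenotype panel with planted convergence structure
#'
#' Convergent phenotypes have widely dispersed per-strain WT means and
#' tightly clustered EP means; divergent phenotypes the reverse; neutral
#' phenotypes equal dispersion at both stages. Most planted convergent
#' phenotypes converge through growth coupling: their stage means are
#' affine functions of the strain's stage growth rate, so wild-type means
#' disperse with the spread of wild-type growth rates while endpoint means
#' cluster with the narrow fitness plateau -- the mechanism behind the
#' observation that the large majority of convergent phenotypes are
#' growth-correlated. Units are assigned from the three conventions of the
#' panel (absolute flux, relative flux, physiology).
#'
#' @param design sample metadata
#' @param truth planted-truth object (defines the label sets, including
#'   which convergent phenotypes are growth-coupled)
#' @param noise_sd measurement noise added to every mean
#' @param spread_wide between-strain s.d. of the dispersed stage
#' @param spread_tight between-strain s.d. of the clustered stage
#' @param spread_neutral between-strain s.d. of both stages of neutral
#'   phenotypes
#' @param growth_slope magnitude of the growth coupling (phenotype units
#'   per 1/h; sign random per phenotype)
#' @param growth_scatter_wt extra wild-type scatter of growth-coupled
#'   phenotypes
#' @param seed integer seed
#' @return phenotype panel data.frame (see [read_phenotypes()])
#' @export
generate_phenotypes <- function(design, truth, noise_sd = 0.1, spread_wide = 4,
                                spread_tight = 0.3, spread_neutral = 1.5,
                                growth_slope = 32, growth_scatter_wt = 6,
                                seed = 1) {
  set.seed(seed)
  strains <- unique(design$strain)
  ids <- c(truth$convergent_phenotypes, truth$divergent_phenotypes,
           truth$neutral_phenotypes)
  labels <- rep(c("convergent", "divergent", "neutral"),
                c(length(truth$convergent_phenotypes),
                  length(truth$divergent_phenotypes),
                  length(truth$neutral_phenotypes)))
  growth_ids <- truth$growth_correlated_phenotypes %||% character()
  units <- rep_len(c("mmol/gDW/h", "mol/mol glucose", "1/h"), length(ids))
  # stage growth rate per strain (WT = first flask, EP = last)
  g_stage <- list()
  for (stage in c("WT", "EP")) {
    sub <- design[design$stage == stage, ]
    g_stage[[stage]] <- tapply(sub$growth_rate, sub$strain, mean)[strains]
  }
  rows <- list()
  for (i in seq_along(ids)) {
    center <- stats::rnorm(1, 10, 2)
    growth_coupled <- ids[i] %in% growth_ids
    slope <- if (growth_coupled) sample(c(-1, 1), 1) * growth_slope else 0
    sds <- switch(labels[i],
                  convergent = if (growth_coupled)
                    c(WT = growth_scatter_wt, EP = spread_tight)
                  else c(WT = spread_wide, EP = spread_tight),
                  divergent = c(WT = spread_tight, EP = spread_wide),
                  neutral = c(WT = spread_neutral, EP = spread_neutral))
    for (stage in c("WT", "EP")) {
      means <- center + slope * (g_stage[[stage]] - 0.9) +
        stats::rnorm(length(strains), 0, sds[[stage]]) +
        stats::rnorm(length(strains), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype_id = ids[i], unit = units[i], strain = strains,
        stage = stage, value = as.numeric(means), stdev = noise_sd,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate flask-level flux estimates with planted causal shifts
#'
#' Each reaction has a strain-specific baseline net flux plus flask noise;
#' causal mutation shifts apply from the gaining flask onward. Returns both
#' a reactions x flasks matrix (for jump differencing) and a flux record
#' table with forward/backward splits and 95% CIs obeying the net/exchange
#' and quarter-width precision identities.
#'
#' @param design sample metadata
#' @param truth planted-truth object
#' @param reactions reaction ids
#' @param noise_sd flask-to-flask flux noise
#' @param seed integer seed
#' @param mutations optional mutation events for causal shifts
#' @return list with `matrix` (reactions x flask ids) and `records`
#'   (data.frame in the flux CSV schema)
#' @export
generate_fluxes <- function(design, truth, reactions = FLUX_REACTIONS,
                            noise_sd = 0.5, seed = 1, mutations = NULL) {
  set.seed(seed)
  flasks <- unique(design[, c("strain", "flask_index")])
  flask_id <- paste0(flasks$strain, "_f", flasks$flask_index)
  Fm <- matrix(NA_real_, length(reactions), nrow(flasks),
               dimnames = list(reactions, flask_id))
  for (s in unique(flasks$strain)) {
    idx <- which(flasks$strain == s)
    for (rx in reactions) {
      Fm[rx, idx] <- stats::rnorm(1, 8, 2) +
        stats::rnorm(length(idx), 0, noise_sd)
    }
  }
  if (!is.null(mutations)) {
    shifts <- causal_shift_table(mutations, truth, design)
    shifts <- shifts[shifts$target_kind == "flux" &
                       shifts$target %in% reactions, , drop = FALSE]
    for (i in seq_len(NROW(shifts))) {
      idx <- which(flasks$strain == shifts$strain[i] &
                     flasks$flask_index >= shifts$from_flask[i])
      Fm[shifts$target[i], idx] <- Fm[shifts$target[i], idx] + shifts$effect[i]
    }
  }
  rec <- list()
  for (j in seq_len(nrow(flasks))) {
    v_net <- Fm[, j]
    v_b <- pmax(0.2, 0.2 - v_net)
    v_f <- v_net + v_b
    rec[[j]] <- data.frame(
      reaction_id = reactions, strain = flasks$strain[j],
      flask_index = flasks$flask_index[j],
      v_forward = v_f, v_backward = v_b,
      v_net = v_net, v_exchange = pmin(v_f, v_b),
      ci_lower = v_net - 0.6, ci_upper = v_net + 0.6,
      precision_stdev = 0.3,
      unit = "abs", stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(matrix = Fm, records = flux_records(records))
}

#' Simulate a complete six-strain ALE multi-omics dataset
#'
#' Orchestrates all generators under a single master seed (each stage draws
#' a derived sub-seed, so the output is fully deterministic) and returns
#' every table plus the planted truth.
#'
#' @param seed master integer seed
#' @param n_strains,flasks_per_strain,replicates design parameters (see
#'   [generate_design()])
#' @param n_genes,n_imodulons,sparsity basis parameters
#' @param n_phenotypes phenotype panel size
#' @param expr_noise_sd expression noise
#' @param expr_baseline per-gene baseline c(mean, sd) of mean log-TPM
#' @param replicate_noise replicate difference magnitude (meanlog, sdlog)
#' @param background_rate background mutation events per jump
#' @param truth optional custom planted truth (default [default_truth()])
#' @return an `ale_dataset` list: design, M (with categories), A, X,
#'   phenotypes, mutations, fluxes (records), flux_matrix, truth
#' @export
simulate_ale_dataset <- function(seed = 1, n_strains = 6,
                                 flasks_per_strain = c(4, 4, 4, 4, 3, 3),
                                 replicates = 2, n_genes = 1000,
                                 n_imodulons = 25, sparsity = 0.1,
                                 n_phenotypes = 62, expr_noise_sd = 0.3,
                                 expr_baseline = c(mean = 7, sd = 6),
                                 replicate_noise = c(meanlog = 0, sdlog = 0.5),
                                 background_rate = 1.5, truth = NULL) {
  design <- generate_design(n_strains, flasks_per_strain, replicates,
                            seed = sub_seed(seed, 1))
  M <- generate_imodulon_model(n_genes, n_imodulons, sparsity,
                               seed = sub_seed(seed, 2))
  truth <- truth %||% default_truth(colnames(M), strains = unique(design$strain),
                                    n_phenotypes = n_phenotypes)
  mutations <- generate_mutations(design, truth, background_rate = background_rate,
                                  seed = sub_seed(seed, 3))
  A <- generate_activities(design, colnames(M), truth,
                           replicate_noise = replicate_noise,
                           seed = sub_seed(seed, 4), mutations = mutations)
  X <- generate_expression(M, A, noise_sd = expr_noise_sd,
                           baseline = expr_baseline, seed = sub_seed(seed, 5))
  phenotypes <- generate_phenotypes(design, truth, seed = sub_seed(seed, 6))
  fluxes <- generate_fluxes(design, truth, seed = sub_seed(seed, 7),
                            mutations = mutations)
  structure(list(
    design = design, M = M, A = A, X = X, phenotypes = phenotypes,
    mutations = mutations, fluxes = fluxes$records,
    flux_matrix = fluxes$matrix, truth = truth,
    params = list(seed = seed, n_strains = n_strains,
                  n_genes = n_genes, n_imodulons = n_imodulons,
                  expr_noise_sd = expr_noise_sd,
                  replicate_noise = replicate_noise)
  ), class = "ale_dataset")
}

#' @export
print.ale_dataset <- function(x, ...) {
  cat("Synthetic ALE multi-omics dataset\n")
  cat(sprintf("  strains: %d | samples: %d | genes: %d | iModulons: %d\n",
              length(unique(x$design$strain)), nrow(x$design),
              nrow(x$X), nrow(x$A)))
  cat(sprintf("  phenotypes: %d | mutation events: %d | flux reactions: %d\n",
              length(unique(x$phenotypes$phenotype_id)), nrow(x$mutations),
              nrow(x$flux_matrix)))
  invisible(x)
}

#' Write a simulated dataset to a directory of CSV files plus truth.json
#'
#' Files follow the reader schemas of this package; numeric cells are
#' serialized at full double precision so [read_dataset()] reproduces the
#' in-memory objects exactly and regeneration under the same seed is
#' byte-identical.
#'
#' @param ds an `ale_dataset`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(ds$X, file.path(dir, "expression.csv"))
  write_metadata(ds$design, file.path(dir, "metadata.csv"))
  write_imodulon_model(ds$M, file.path(dir, "imodulon_model.csv"),
                       file.path(dir, "imodulon_categories.csv"))
  write_mutations(ds$mutations, file.path(dir, "mutations.csv"))
  write_fluxes(ds$fluxes, file.path(dir, "fluxes.csv"))
  write_phenotypes(ds$phenotypes, file.path(dir, "phenotypes.csv"))
  truth <- ds$truth
  class(truth) <- NULL
  # named atomic vectors must serialize as JSON objects, not bare arrays
  truth$growth_correlated_imodulons <-
    as.list(truth$growth_correlated_imodulons)
  truth$wt_offset_imodulons <- lapply(truth$wt_offset_imodulons, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory
#' @return an `ale_dataset`-like list (without the flask-level flux matrix,
#'   which is reconstructed from the flux records)
#' @export
read_dataset <- function(dir) {
  X <- read_expression(file.path(dir, "expression.csv"))
  design <- read_metadata(file.path(dir, "metadata.csv"))
  M <- read_imodulon_model(file.path(dir, "imodulon_model.csv"),
                           file.path(dir, "imodulon_categories.csv"))
  mutations <- read_mutations(file.path(dir, "mutations.csv"))
  fluxes <- read_fluxes(file.path(dir, "fluxes.csv"))
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$growth_correlated_imodulons <- unlist(truth$growth_correlated_imodulons)
  truth$wt_offset_imodulons <- lapply(truth$wt_offset_imodulons, unlist)
  flask_id <- paste0(fluxes$strain, "_f", fluxes$flask_index)
  rx <- unique(fluxes$reaction_id)
  fl <- unique(flask_id)
  Fm <- matrix(NA_real_, length(rx), length(fl), dimnames = list(rx, fl))
  Fm[cbind(match(fluxes$reaction_id, rx), match(flask_id, fl))] <- fluxes$v_net
  list(design = design, M = M, X = X, phenotypes = phenotypes,
       mutations = mutations, fluxes = fluxes, flux_matrix = Fm,
       truth = truth)
}
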