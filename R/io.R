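# Delimited-text readers and writers for the flask-level multi-omics tables.
#
# All tables are comma-separated UTF-8 with a mandatory header row and "."
# decimal separator. Gene and sample identifiers are opaque, case-sensitive
# strings. Empty cells are missing values; no operation imputes silently.

read_table_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a gene expression matrix (log2(TPM + 1))
#'
#' The file must carry a `gene_id` column followed by one numeric column per
#' sample. Values are log2(TPM + 1) and therefore finite and non-negative.
#'
#' @param path path to a CSV file
#' @return a numeric genes x samples matrix with gene ids as row names and
#'   sample ids as column names, in file order
#' @export
read_expression <- function(path) {
  df <- read_table_strict(path, "gene_id")
  genes <- as.character(df$gene_id)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  value_cols <- setdiff(names(df), "gene_id")
  if (!length(value_cols)) stop("no sample columns in ", path, call. = FALSE)
  for (cn in value_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) & !is.na(df[[cn]]))
      stop("non-numeric expression value at row ", bad[1], ", column '", cn, "'",
           call. = FALSE)
    }
  }
  x <- as.matrix(df[value_cols])
  rownames(x) <- genes
  validate_expression(x)
  x
}

validate_expression <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  if (any(x < 0)) stop("expression values must be >= 0 (log2(TPM + 1))", call. = FALSE)
  invisible(x)
}

#' Write an expression matrix to CSV
#'
#' Numeric cells are serialized at full double precision so a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param x genes x samples numeric matrix with dimnames
#' @param path output path
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_csv_precise(df, path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `strain`, `flask_index`, `replicate_id`, `stage`
#' (WT / intermediate / EP), `growth_rate` (1/h; may be empty). The flask
#' index counts evolutionary time, with flask 0 the preculture.
#'
#' @param path path to a CSV file
#' @return a data.frame, one row per sample
#' @export
read_metadata <- function(path) {
  df <- read_table_strict(path, c("sample_id", "strain", "flask_index",
                                  "replicate_id", "stage", "growth_rate"))
  df$sample_id <- as.character(df$sample_id)
  df$strain <- as.character(df$strain)
  df$replicate_id <- as.character(df$replicate_id)
  df$stage <- as.character(df$stage)
  validate_metadata(df)
  df
}

validate_metadata <- function(meta) {
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
                        call. = FALSE)
  key <- paste(meta$strain, meta$flask_index, meta$replicate_id)
  if (anyDuplicated(key)) {
    stop("duplicate (strain, flask_index, replicate_id) combination", call. = FALSE)
  }
  bad_stage <- setdiff(unique(meta$stage), c("WT", "intermediate", "EP"))
  if (length(bad_stage)) stop("unknown stage label(s): ",
                              paste(bad_stage, collapse = ", "), call. = FALSE)
  if (any(meta$flask_index < 0)) stop("flask_index must be >= 0", call. = FALSE)
  gr <- meta$growth_rate
  if (any(!is.na(gr) & gr <= 0)) stop("growth_rate must be > 0 when present",
                                      call. = FALSE)
  invisible(meta)
}

#' @rdname read_metadata
#' @param meta metadata data.frame
#' @export
write_metadata <- function(meta, path) write_csv_precise(meta, path)

#' Read mutation events
#'
#' Columns: `strain`, `replicate_id`, `locus`, `nucleotide_id`,
#' `mutation_type` (SNP / indel / mobile_element / large_deletion) and
#' `observed_flask`. Intergenic loci are written as the flanking gene pair
#' joined by a single slash, e.g. `hns/tdk`.
#'
#' @param path path to a CSV file
#' @return a data.frame of mutation events
#' @export
read_mutations <- function(path) {
  df <- read_table_strict(path, c("strain", "replicate_id", "locus",
                                  "nucleotide_id", "mutation_type",
                                  "observed_flask"))
  df$locus <- as.character(df$locus)
  validate_mutations(df)
  df
}

validate_mutations <- function(df) {
  if (any(is.na(df$locus) | !nzchar(df$locus))) {
    stop("mutation locus must be non-empty", call. = FALSE)
  }
  nslash <- lengths(regmatches(df$locus, gregexpr("/", df$locus, fixed = TRUE)))
  if (any(nslash > 1)) {
    stop("intergenic loci must contain exactly one '/': ",
         paste(unique(df$locus[nslash > 1]), collapse = ", "), call. = FALSE)
  }
  types <- c("SNP", "indel", "mobile_element", "large_deletion")
  bad <- setdiff(unique(df$mutation_type), types)
  if (length(bad)) stop("unknown mutation_type: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  invisible(df)
}

#' @rdname read_mutations
#' @param df mutation data.frame
#' @export
write_mutations <- function(df, path) write_csv_precise(df, path)

#' Is a locus intergenic, and what genes flank it?
#'
#' @param locus character vector of locus labels
#' @return for `is_intergenic`, a logical vector; for `intergenic_genes`, a
#'   two-column character matrix (NA rows for genic loci)
#' @export
is_intergenic <- function(locus) grepl("/", locus, fixed = TRUE)

#' @rdname is_intergenic
#' @export
intergenic_genes <- function(locus) {
  out <- matrix(NA_character_, length(locus), 2,
                dimnames = list(locus, c("gene_a", "gene_b")))
  ig <- is_intergenic(locus)
  if (any(ig)) {
    parts <- strsplit(locus[ig], "/", fixed = TRUE)
    out[ig, ] <- t(vapply(parts, identity, character(2)))
  }
  out
}

#' Read flux estimates with 95% confidence intervals
#'
#' Net and exchange fluxes follow the usual identities for a reversible
#' reaction split into forward and backward components:
#' v_net = v_f - v_b and v_exch = min(v_f, v_b). The flux precision is the
#' quarter-width of the 95% confidence interval,
#' (ci_upper - ci_lower) / 4. Identities present in the file are checked at
#' tolerance 1e-6 and recomputed (with a warning) when violated; absent
#' columns are filled in.
#'
#' @param path path to a CSV file
#' @return a data.frame of flux records with columns reaction_id, strain,
#'   flask_index, v_forward, v_backward, v_net, v_exchange, ci_lower,
#'   ci_upper, precision_stdev, unit
#' @export
read_fluxes <- function(path) {
  df <- read_table_strict(path, c("reaction_id", "strain", "flask_index",
                                  "v_forward", "v_backward",
                                  "ci_lower", "ci_upper", "unit"))
  flux_records(df)
}

#' Construct validated flux records from raw columns
#'
#' @param df data.frame with at least reaction_id, v_forward, v_backward and
#'   the CI bounds; v_net / v_exchange / precision_stdev are recomputed
#' @param tol tolerance for identity checks against supplied columns
#' @export
flux_records <- function(df, tol = 1e-6) {
  if (any(df$v_forward < 0, na.rm = TRUE) || any(df$v_backward < 0, na.rm = TRUE)) {
    stop("v_forward and v_backward must be >= 0", call. = FALSE)
  }
  net <- df$v_forward - df$v_backward
  exch <- pmin(df$v_forward, df$v_backward)
  prec <- (df$ci_upper - df$ci_lower) / 4
  for (col in c("v_net", "v_exchange", "precision_stdev")) {
    want <- switch(col, v_net = net, v_exchange = exch, precision_stdev = prec)
    if (col %in% names(df)) {
      off <- abs(df[[col]] - want) > tol
      if (any(off, na.rm = TRUE)) {
        warning(sum(off, na.rm = TRUE), " record(s) violated the ", col,
                " identity beyond ", tol, "; recomputed", call. = FALSE)
      }
    }
    df[[col]] <- want
  }
  has_ci <- !is.na(df$ci_lower) & !is.na(df$ci_upper)
  bad_ci <- has_ci & (df$ci_lower > df$v_net | df$v_net > df$ci_upper)
  if (any(bad_ci)) {
    warning(sum(bad_ci), " record(s) with v_net outside its 95% CI", call. = FALSE)
  }
  df
}

#' @rdname read_fluxes
#' @param df flux data.frame
#' @export
write_fluxes <- function(df, path) write_csv_precise(df, path)

#' Read a phenotype panel
#'
#' Columns: `phenotype_id`, `unit` (absolute flux in mmol/gDW/h, relative
#' flux in mol/mol glucose, or a physiological unit), `strain`, `stage`,
#' `value`, and optional `stdev`. Each (phenotype, strain, stage) may appear
#' at most once.
#'
#' @param path path to a CSV file
#' @return a data.frame, one row per (phenotype, strain, stage) mean
#' @export
read_phenotypes <- function(path) {
  df <- read_table_strict(path, c("phenotype_id", "unit", "strain",
                                  "stage", "value"))
  if (!"stdev" %in% names(df)) df$stdev <- NA_real_
  key <- paste(df$phenotype_id, df$strain, df$stage)
  if (anyDuplicated(key)) {
    stop("duplicate (phenotype_id, strain, stage) rows", call. = FALSE)
  }
  if (any(!is.finite(df$value))) stop("phenotype values must be finite", call. = FALSE)
  df
}

#' @rdname read_phenotypes
#' @param df phenotype data.frame
#' @export
write_phenotypes <- function(df, path) write_csv_precise(df, path)

#' Read an iModulon gene-weight matrix
#'
#' The file carries `gene_id` plus one numeric column per iModulon. An
#' optional companion CSV maps iModulons to functional categories
#' (`imodulon`, `category`); the map is attached as the `"categories"`
#' attribute.
#'
#' @param path path to the weight CSV
#' @param categories_path optional path to the category CSV
#' @return genes x iModulons numeric matrix, possibly with a named character
#'   `"categories"` attribute
#' @export
read_imodulon_model <- function(path, categories_path = NULL) {
  df <- read_table_strict(path, "gene_id")
  genes <- as.character(df$gene_id)
  if (anyDuplicated(genes)) stop("duplicate gene ids in iModulon model", call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- genes
  if (any(!is.finite(m))) stop("iModulon weights must be finite", call. = FALSE)
  if (any(colSums(abs(m)) == 0)) {
    stop("iModulon column(s) with no nonzero weight: ",
         paste(colnames(m)[colSums(abs(m)) == 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(categories_path)) {
    cat_df <- read_table_strict(categories_path, c("imodulon", "category"))
    attr(m, "categories") <- stats::setNames(as.character(cat_df$category),
                                             as.character(cat_df$imodulon))
  }
  m
}

#' @rdname read_imodulon_model
#' @param m weight matrix (optionally carrying a `"categories"` attribute)
#' @export
write_imodulon_model <- function(m, path, categories_path = NULL) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_csv_precise(df, path)
  cats <- attr(m, "categories")
  if (!is.null(categories_path) && !is.null(cats)) {
    utils::write.csv(data.frame(imodulon = names(cats), category = unname(cats)),
                     categories_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
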