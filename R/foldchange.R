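#' Signed fold change of two positive group means
#'
#' Encodes the treated/control expression ratio in the signed convention
#' common to GEO2R-style differential tables: a ratio r >= 1 is reported as
#' +r, a ratio r < 1 as -1/r (reciprocal negative), so |value| >= 1 always
#' and a ratio of exactly 1 encodes as +1.
#'
#' @param treated_mean,control_mean Positive numeric vectors (recycled).
#' @return Numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(treated_mean, control_mean) {
  if (any(!is.finite(treated_mean)) || any(!is.finite(control_mean)) ||
      any(treated_mean <= 0) || any(control_mean <= 0))
    stop("group means must be positive and finite")
  ratio_to_signed(treated_mean / control_mean)
}

#' Convert between plain ratios and signed fold changes
#'
#' `ratio_to_signed()` maps a positive ratio r to +r (r >= 1) or -1/r
#' (r < 1); `signed_to_ratio()` is its inverse. The round trip is the
#' identity to floating tolerance.
#'
#' @param ratio Positive numeric vector of treated/control ratios.
#' @param signed Numeric vector in the signed convention (|x| >= 1).
#' @return Numeric vector.
#' @export
ratio_to_signed <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratios must be positive and finite")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @rdname ratio_to_signed
#' @export
signed_to_ratio <- function(signed) {
  check_signed(signed)
  ifelse(signed > 0, signed, -1 / signed)
}

check_signed <- function(x) {
  bad <- which(!is.finite(x) | abs(x) < 1)
  if (length(bad))
    stop("signed fold changes must be finite with |value| >= 1; offending ",
         "value ", x[bad[1]], " at position ", bad[1])
  invisible(x)
}

#' Construct a per-gene differential table
#'
#' A differential table holds one signed fold change (and optional p-value)
#' per normalized gene for a single two-group comparison, plus dataset
#' metadata.
#'
#' @param gene Character vector of gene symbols (normalized on the way in).
#' @param fold_change Numeric vector of signed fold changes (|x| >= 1).
#' @param p_value Optional numeric vector in `[0, 1]`.
#' @param dataset_id Non-empty dataset label (e.g. a GEO accession).
#' @param treatment,disease_class,organism Optional metadata labels.
#' @return An object of class `differential_table` with elements `records`
#'   (data frame: `gene`, `fold_change`, `p_value`) and the metadata fields.
#' @export
differential_table <- function(gene, fold_change, p_value = NULL,
                               dataset_id, treatment = "",
                               disease_class = "", organism = "") {
  if (!nzchar(dataset_id)) stop("dataset_id must be non-empty")
  gene <- normalize_symbol(gene)
  check_signed(fold_change)
  if (length(gene) != length(fold_change))
    stop("gene and fold_change lengths differ")
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    stop("duplicate gene(s) after normalization: ", paste(dup, collapse = ", "))
  if (is.null(p_value)) p_value <- rep(NA_real_, length(gene))
  if (any(!is.na(p_value) & (p_value < 0 | p_value > 1)))
    stop("p-values must lie in [0, 1]")
  structure(list(
    dataset_id = dataset_id, treatment = treatment,
    disease_class = disease_class, organism = organism,
    records = data.frame(gene = gene, fold_change = as.numeric(fold_change),
                         p_value = as.numeric(p_value),
                         stringsAsFactors = FALSE)
  ), class = "differential_table")
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("Differential table %s (%s, %s): %d genes\n", x$dataset_id,
              x$treatment, x$disease_class, nrow(x$records)))
  invisible(x)
}

#' Two-group fold changes from an expression matrix
#'
#' Computes per-gene group means and the signed fold change treated vs
#' control. The ratio is that of the geometric group means (the microarray
#' convention: fold changes are averaged on the log scale); with
#' `log2_input = TRUE` the matrix is taken to hold log2 intensities and the
#' ratio is `2^(mean_T - mean_C)`, which is the same quantity, so the two
#' input paths agree exactly on `M` vs `2^M`.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns. Values must be positive unless `log2_input`.
#' @param group_labels Character vector, one label per column.
#' @param treated,control The two labels to compare.
#' @param log2_input Whether `mat` holds log2-scale values.
#' @param dataset_id,treatment,disease_class,organism Metadata for the
#'   resulting table.
#' @return A [differential_table].
#' @export
compute_differential <- function(mat, group_labels, treated = "treated",
                                 control = "control", log2_input = FALSE,
                                 dataset_id = "insilico", treatment = "",
                                 disease_class = "", organism = "") {
  if (length(group_labels) != ncol(mat))
    stop("group_labels length must equal ncol(mat)")
  if (is.null(rownames(mat))) stop("mat must have gene rownames")
  if (anyNA(mat)) stop("every gene row must be complete")
  it <- group_labels == treated
  ic <- group_labels == control
  if (!any(it) || !any(ic))
    stop("both groups need at least one sample (labels '", treated,
         "' and '", control, "')")
  if (!log2_input) {
    if (any(mat <= 0)) stop("linear-scale expression values must be positive")
    mat <- log2(mat)
  }
  ratio <- 2^(rowMeans(mat[, it, drop = FALSE]) -
                rowMeans(mat[, ic, drop = FALSE]))
  differential_table(rownames(mat), ratio_to_signed(ratio),
                     dataset_id = dataset_id, treatment = treatment,
                     disease_class = disease_class, organism = organism)
}

#' Housekeeping-gene quality control
#'
#' Collects the fold changes of the housekeeping panel (CHMP2A, PSMB4, ACTB,
#' GAPDH by default) across a set of differential tables and checks that
#' they all stay inside a narrow band: the dataset batch passes when every
#' available housekeeping value has |fold change| strictly below the
#' threshold. Missing cells (housekeeping genes absent from a platform) are
#' counted, never imputed.
#'
#' @param tables A list of [differential_table] objects (or a single one).
#' @param panel A `gene_panel`; defaults to the packaged housekeeping panel.
#' @param threshold Positive QC cut on |signed fold change| (default 1.5,
#'   the same magnitude as the differential-call cut).
#' @return An object of class `qc_report`: list with `hk_values` (data
#'   frame: `gene`, `dataset`, `fold_change`), `min_value`, `max_value`,
#'   `threshold`, `pass`, `missing_cells`.
#' @export
housekeeping_qc <- function(tables, panel = load_panel("housekeeping"),
                            threshold = 1.5) {
  if (inherits(tables, "differential_table")) tables <- list(tables)
  if (!length(tables)) stop("tables must be non-empty")
  vals <- do.call(rbind, lapply(tables, function(tb) {
    stopifnot(inherits(tb, "differential_table"))
    rec <- tb$records[tb$records$gene %in% panel$members, , drop = FALSE]
    if (!nrow(rec)) return(NULL)
    data.frame(gene = rec$gene, dataset = tb$dataset_id,
               fold_change = rec$fold_change, stringsAsFactors = FALSE)
  }))
  if (is.null(vals) || !nrow(vals))
    stop("none of the housekeeping genes (", paste(panel$members,
         collapse = ", "), ") are present in any table")
  missing_cells <- length(panel$members) * length(tables) - nrow(vals)
  rep <- list(hk_values = vals,
              min_value = min(vals$fold_change),
              max_value = max(vals$fold_change),
              threshold = threshold,
              pass = all(abs(vals$fold_change) < threshold),
              missing_cells = missing_cells)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("Housekeeping QC: %d values over %s, range [%.3f, %.3f]",
                     " (threshold %.2f): %s; %d missing cell(s)\n"),
              nrow(x$hk_values), paste(length(unique(x$hk_values$dataset)),
              "dataset(s)"), x$min_value, x$max_value, x$threshold,
              if (x$pass) "PASS" else "FAIL", x$missing_cells))
  invisible(x)
}

#' Read and write differential tables as TSV
#'
#' The dialect is a plain TSV with a `gene` and a `fold_change` column
#' (optional `p_value`), preceded by `#key<TAB>value` metadata header lines
#' (`dataset_id`, `treatment`, `disease_class`, `organism`, ...). Fold
#' changes may be stored in the signed convention (default), as plain
#' ratios, or as log2 ratios; they are converted to the signed convention on
#' the way in. Writing uses the signed convention, so read/write round-trips
#' are stable on canonical form.
#'
#' @param path File path.
#' @param convention One of `"signed"`, `"ratio"`, `"log2"`.
#' @return `read_differential_tsv()` returns a [differential_table];
#'   `write_differential_tsv()` returns `path` invisibly.
#' @export
read_differential_tsv <- function(path, convention = c("signed", "ratio",
                                                       "log2")) {
  convention <- match.arg(convention)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", lines[h]), "\t", fixed = TRUE)[[1]]
    if (length(kv) >= 2) meta[[kv[1]]] <- kv[2]
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "fold_change") %in% names(df)))
    stop("differential TSV ", path, " must have columns gene, fold_change")
  fc <- suppressWarnings(as.numeric(df$fold_change))
  if (anyNA(fc))
    stop("unparseable fold change in ", path, " at data line ",
         which(is.na(fc))[1])
  fc <- switch(convention,
               signed = fc,
               ratio = ratio_to_signed(fc),
               log2 = ratio_to_signed(2^fc))
  differential_table(df$gene, fc,
                     p_value = if ("p_value" %in% names(df)) df$p_value,
                     dataset_id = meta$dataset_id %||% basename(path),
                     treatment = meta$treatment %||% "",
                     disease_class = meta$disease_class %||% "",
                     organism = meta$organism %||% "")
}

#' @rdname read_differential_tsv
#' @param table A [differential_table].
#' @export
write_differential_tsv <- function(table, path) {
  stopifnot(inherits(table, "differential_table"))
  meta <- c(dataset_id = table$dataset_id, treatment = table$treatment,
            disease_class = table$disease_class, organism = table$organism)
  meta <- meta[nzchar(meta)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(meta), "\t", meta), con)
  rec <- table$records
  if (all(is.na(rec$p_value))) rec$p_value <- NULL
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
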