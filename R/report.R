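#' Registry summary statistics
#'
#' Per-type membership counts plus the totals of the packaged regulatome:
#' total memberships, unique genes, membership excess (total minus unique)
#' and the strict count of multi-type genes.
#'
#' @param registry A `regulatome_registry`.
#' @return A data frame with one row per cell-death type (`type`, `n_genes`)
#'   and attributes `total`, `unique`, `excess`, `n_multi_type`.
#' @export
registry_stats <- function(registry = load_regulatome()) {
  out <- data.frame(type = names(registry$per_type_count),
                    n_genes = as.integer(registry$per_type_count),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- registry$total_memberships
  attr(out, "unique") <- registry$unique_genes
  attr(out, "excess") <- registry$redundant_memberships
  attr(out, "n_multi_type") <- registry$n_multi_type
  out
}

#' Run the housekeeping QC over differential TSV files
#'
#' @param paths Character vector of differential TSV paths, or a list of
#'   [differential_table] objects.
#' @param threshold QC cut (default 1.5).
#' @param out Optional path for a JSON summary.
#' @return The `qc_report`, invisibly when `out` is given.
#' @export
run_qc <- function(paths, threshold = 1.5, out = NULL) {
  tables <- if (is.character(paths)) lapply(paths, read_differential_tsv)
  else paths
  rep <- housekeeping_qc(tables, threshold = threshold)
  if (!is.null(out)) {
    jsonlite::write_json(list(min_value = rep$min_value,
                              max_value = rep$max_value,
                              threshold = rep$threshold, pass = rep$pass,
                              missing_cells = rep$missing_cells,
                              n_values = nrow(rep$hk_values)),
                         out, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

universe_from_name <- function(name) {
  switch(name,
         regulatome = load_regulatome(),
         all = NULL,
         load_panel(name))
}

#' Classify one differential table and write the annotated report
#'
#' Reads a differential TSV, classifies it over the chosen universe at the
#' chosen threshold, annotates calls by cell-death type, and (optionally)
#' writes a call TSV (`direction`, `gene`, `fold_change`,
#' `cell_death_types` semicolon-joined) plus a JSON summary with the counts.
#' Regenerating with the same inputs is byte-identical.
#'
#' @param path Differential TSV path (or a [differential_table]).
#' @param universe `"regulatome"`, a packaged panel name, or `"all"` (every
#'   gene of the table).
#' @param threshold Fold-change cut (default 1.5).
#' @param out_tsv,out_json Optional output paths.
#' @return List with the `condition_callset` and the annotated call table.
#' @export
run_classify <- function(path, universe = "regulatome", threshold = 1.5,
                         out_tsv = NULL, out_json = NULL) {
  tab <- if (inherits(path, "differential_table")) path
  else read_differential_tsv(path)
  uni <- if (is.character(universe) && length(universe) == 1 &&
             universe %in% c("regulatome", "all", "housekeeping", "redox",
                             "chromatin_factors"))
    universe_from_name(universe) %||% tab$records$gene
  else universe
  cs <- classify(tab, universe = uni, threshold = threshold)
  ann <- annotate_calls(cs)
  if (!is.null(out_tsv)) {
    agg <- ann[ann$cell_death_type != "", , drop = FALSE]
    per_gene <- do.call(rbind, lapply(split(agg, agg[c("direction", "gene")],
                                            drop = TRUE), function(d)
      data.frame(direction = d$direction[1], gene = d$gene[1],
                 fold_change = d$fold_change[1],
                 cell_death_types = paste(sort(d$cell_death_type),
                                          collapse = ";"),
                 stringsAsFactors = FALSE)))
    per_gene <- per_gene[order(per_gene$direction, per_gene$gene), ,
                         drop = FALSE]
    utils::write.table(per_gene, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_json)) {
    tc <- attr(ann, "type_counts")
    jsonlite::write_json(list(
      dataset_id = cs$source$dataset_id, universe = cs$universe_label,
      threshold = cs$threshold, n_up = cs$n_up, n_down = cs$n_down,
      n_unchanged = cs$n_unchanged, n_not_measured = length(cs$not_measured),
      type_counts = tc), out_json, auto_unbox = TRUE, digits = NA)
  }
  list(callset = cs, annotated = ann)
}

#' Compare two differential tables' call sets
#'
#' @param path_a,path_b Differential TSV paths (or [differential_table]s).
#' @param universe,threshold As in [run_classify()].
#' @param out Optional JSON output path.
#' @return The `overlap_result`.
#' @export
run_compare <- function(path_a, path_b, universe = "regulatome",
                        threshold = 1.5, out = NULL) {
  a <- run_classify(path_a, universe, threshold)$callset
  b <- run_classify(path_b, universe, threshold)$callset
  ov <- compare_callsets(a, b)
  if (!is.null(out))
    jsonlite::write_json(unclass(ov), out, auto_unbox = TRUE, digits = NA)
  ov
}

#' Run the promoter-distance comparison from files
#'
#' @param interactions_path Interaction TSV path.
#' @param promoters_path Promoter table path (BED6 or gene/tss TSV; format
#'   sniffed from the header).
#' @param up_genes,down_genes Character vectors of gene symbols.
#' @param dialect Interaction coordinate dialect (see
#'   [read_interaction_table()]).
#' @param dedupe Drop duplicated interaction rows first (off by default:
#'   database dumps carry method/cell-type replicates and no deduplication
#'   is assumed).
#' @param out_distances,out_summary,out_ks Optional output paths (distances
#'   TSV; summary JSON; KS JSON).
#' @return The `clri_result`.
#' @export
run_clri <- function(interactions_path, promoters_path, up_genes,
                     down_genes, dialect = "one_based", dedupe = FALSE,
                     out_distances = NULL, out_summary = NULL,
                     out_ks = NULL) {
  ints <- read_interaction_table(interactions_path, dialect)
  if (dedupe)
    ints <- ints[!duplicated(ints[c("chrom_a", "start_a", "end_a",
                                    "chrom_b", "start_b", "end_b")]), ]
  first <- readLines(promoters_path, n = 1)
  fmt <- if (grepl("\\bgene\\b", first) || grepl("^#", first)) "tss2" else
    "bed6"
  prom <- read_promoter_table(promoters_path, format = fmt)
  res <- clri_pipeline(up_genes, down_genes, ints, prom)
  if (!is.null(out_distances)) {
    d <- rbind(cbind(set = res$up$label, res$up$distances),
               cbind(set = res$down$label, res$down$distances))
    utils::write.table(d, out_distances, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_summary)) {
    sm <- function(s, ds) list(
      label = ds$label, n = s$n, fraction_upstream = s$fraction_upstream,
      fraction_downstream = s$fraction_downstream, n_zero = s$n_zero,
      n_trans_excluded = ds$n_trans_excluded,
      n_genes_without_promoter = ds$n_genes_without_promoter,
      histogram = s$histogram)
    jsonlite::write_json(list(up = sm(res$summary_up, res$up),
                              down = sm(res$summary_down, res$down)),
                         out_summary, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out_ks))
    jsonlite::write_json(list(D = res$ks$statistic, n1 = res$ks$n1,
                              n2 = res$ks$n2,
                              p_asymptotic = res$ks$p_asymptotic,
                              p_exact = res$ks$p_exact),
                         out_ks, auto_unbox = TRUE, digits = NA)
  res
}
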