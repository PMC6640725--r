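resolve_universe <- function(universe) {
  if (inherits(universe, "regulatome_registry"))
    return(list(label = "regulatome", genes = regulatome_genes(universe)))
  if (inherits(universe, "gene_panel"))
    return(list(label = universe$name, genes = universe$members))
  if (is.character(universe) && length(universe))
    return(list(label = "custom", genes = unique(normalize_symbol(universe))))
  stop("universe must be a non-empty gene set, panel or registry")
}

#' Classify genes as up-, down-, or unregulated at a fold-change threshold
#'
#' Applies the strict fold-change rule: a gene is called up when its signed
#' fold change exceeds +threshold, down when it is below -threshold, and
#' unchanged otherwise (a value exactly at the threshold is unchanged, per
#' "more than" wording). Only genes in the stated universe are called; genes
#' of the universe absent from the table are reported separately as not
#' measured, never as unchanged.
#'
#' @param table A [differential_table].
#' @param universe Gene universe restricting the calls: a character vector,
#'   a `gene_panel`, or a `regulatome_registry` (the 299-gene regulatome).
#' @param threshold Fold-change cut, >= 1 (default 1.5).
#' @return An object of class `condition_callset`: list with `calls` (data
#'   frame: `gene`, `fold_change`, `call`), counts `n_up`, `n_down`,
#'   `n_unchanged`, the `not_measured` genes, `threshold`, `universe_label`
#'   and `source` metadata.
#' @export
classify <- function(table, universe = load_regulatome(), threshold = 1.5) {
  stopifnot(inherits(table, "differential_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop("threshold must be a single number >= 1")
  uni <- resolve_universe(universe)
  rec <- table$records[table$records$gene %in% uni$genes, , drop = FALSE]
  rec <- rec[order(rec$gene), , drop = FALSE]
  call <- ifelse(rec$fold_change > threshold, "up",
                 ifelse(rec$fold_change < -threshold, "down", "unchanged"))
  calls <- data.frame(gene = rec$gene, fold_change = rec$fold_change,
                      call = call, stringsAsFactors = FALSE)
  structure(list(
    source = list(dataset_id = table$dataset_id, treatment = table$treatment,
                  disease_class = table$disease_class,
                  organism = table$organism),
    threshold = threshold,
    universe_label = uni$label,
    universe_size = length(uni$genes),
    calls = calls,
    n_up = sum(call == "up"),
    n_down = sum(call == "down"),
    n_unchanged = sum(call == "unchanged"),
    not_measured = sort(setdiff(uni$genes, rec$gene))
  ), class = "condition_callset")
}

#' @export
print.condition_callset <- function(x, ...) {
  cat(sprintf(paste0("Call set %s (%s, %s) over '%s' universe at |FC| > ",
                     "%.2f:\n  %d up, %d down, %d unchanged; %d universe ",
                     "gene(s) not measured\n"),
              x$source$dataset_id, x$source$treatment,
              x$source$disease_class, x$universe_label, x$threshold,
              x$n_up, x$n_down, x$n_unchanged, length(x$not_measured)))
  invisible(x)
}

#' Genes called in a given direction
#'
#' @param callset A `condition_callset`.
#' @param direction `"up"`, `"down"` or `"unchanged"`.
#' @return Character vector of gene symbols, sorted.
#' @export
called_genes <- function(callset, direction = c("up", "down", "unchanged")) {
  direction <- match.arg(direction)
  sort(callset$calls$gene[callset$calls$call == direction])
}

#' Annotate calls with cell-death type membership
#'
#' Lists every called (up or down) gene under each cell-death type it
#' belongs to; a multi-type gene appears once per type, and a called gene
#' with no registry membership is listed under `"unassigned"`.
#'
#' @param callset A `condition_callset`.
#' @param registry A `regulatome_registry`.
#' @return An object of class `annotated_call_table`: data frame with
#'   columns `direction`, `gene`, `fold_change`, `cell_death_type`, plus a
#'   `"type_counts"` attribute (per type and direction).
#' @export
annotate_calls <- function(callset, registry = load_regulatome()) {
  called <- callset$calls[callset$calls$call != "unchanged", , drop = FALSE]
  rows <- lapply(seq_len(nrow(called)), function(i) {
    types <- memberships_of(called$gene[i], registry)
    if (!length(types)) types <- "unassigned"
    data.frame(direction = called$call[i], gene = called$gene[i],
               fold_change = called$fold_change[i], cell_death_type = types,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), gene = character(),
               fold_change = numeric(), cell_death_type = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$direction, out$cell_death_type, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "type_counts") <- as.data.frame(
    table(type = out$cell_death_type, direction = out$direction),
    responseName = "n")
  class(out) <- c("annotated_call_table", "data.frame")
  out
}

#' Overlap of two condition call sets
#'
#' Set operations on the called genes of two conditions: genes called in the
#' same direction in both (`shared_up`, `shared_down`), genes called in
#' opposite directions (`discordant`), and Jaccard indices of the up- and
#' down-sets.
#'
#' @param a,b `condition_callset` objects built under the same symbol
#'   normalization.
#' @return An object of class `overlap_result`.
#' @export
compare_callsets <- function(a, b) {
  stopifnot(inherits(a, "condition_callset"), inherits(b, "condition_callset"))
  up_a <- called_genes(a, "up");   up_b <- called_genes(b, "up")
  dn_a <- called_genes(a, "down"); dn_b <- called_genes(b, "down")
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0L) return(NA_real_)
    length(intersect(x, y)) / u
  }
  structure(list(
    labels = c(a$source$dataset_id, b$source$dataset_id),
    shared_up = intersect(up_a, up_b),
    shared_down = intersect(dn_a, dn_b),
    discordant = sort(union(intersect(up_a, dn_b), intersect(dn_a, up_b))),
    jaccard_up = jac(up_a, up_b),
    jaccard_down = jac(dn_a, dn_b)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat(sprintf("Overlap %s vs %s\n", x$labels[1], x$labels[2]))
  cat("  shared up:   ", fmt(x$shared_up), "\n")
  cat("  shared down: ", fmt(x$shared_down), "\n")
  cat("  discordant:  ", fmt(x$discordant), "\n")
  cat(sprintf("  Jaccard up %.3f, down %.3f\n", x$jaccard_up, x$jaccard_down))
  invisible(x)
}

#' Cross-reference calls against a transcription-factor knockout
#'
#' Reports genes that move opposite to their direction under the primary
#' condition when the candidate upstream factor is knocked out or down:
#' genes down under the condition but up in the knockout (consistent with
#' the factor repressing them) and vice versa.
#'
#' @param condition_calls `condition_callset` for the primary condition.
#' @param ko_calls `condition_callset` for the knockout/knock-down dataset;
#'   its metadata names the perturbed factor.
#' @return An object of class `knockout_crossref`: list with
#'   `down_then_up`, `up_then_down` gene vectors and the two source
#'   metadata sets.
#' @export
knockout_crossref <- function(condition_calls, ko_calls) {
  structure(list(
    condition = condition_calls$source,
    knockout = ko_calls$source,
    down_then_up = intersect(called_genes(condition_calls, "down"),
                             called_genes(ko_calls, "up")),
    up_then_down = intersect(called_genes(condition_calls, "up"),
                             called_genes(ko_calls, "down"))
  ), class = "knockout_crossref")
}

#' @export
print.knockout_crossref <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat(sprintf("Knockout cross-reference: %s vs %s\n",
              x$condition$dataset_id, x$knockout$dataset_id))
  cat("  down in condition, up in KO:", fmt(x$down_then_up), "\n")
  cat("  up in condition, down in KO:", fmt(x$up_then_down), "\n")
  invisible(x)
}

#' Screen an auxiliary gene panel
#'
#' Applies the same strict fold-change rule within a panel, subgroup by
#' subgroup. Panel genes absent from the table are treated as
#' unchanged-below-threshold (the blank-cell convention of sparse printed
#' screens where only |FC| >= threshold values appear), not as missing.
#'
#' @param table A [differential_table].
#' @param panel A `gene_panel`.
#' @param threshold Fold-change cut (default 1.5).
#' @return An object of class `panel_screen`: data frame with columns
#'   `subgroup`, `gene`, `fold_change` (NA when absent from the table) and
#'   `call`, plus a `"counts"` attribute of per-subgroup up/down counts.
#' @export
panel_screen <- function(table, panel, threshold = 1.5) {
  stopifnot(inherits(table, "differential_table"),
            inherits(panel, "gene_panel"))
  sg <- if (is.null(panel$subgroups)) list(all = panel$members) else
    panel$subgroups
  rows <- do.call(rbind, lapply(names(sg), function(s) {
    g <- sg[[s]]
    fc <- table$records$fold_change[match(g, table$records$gene)]
    call <- ifelse(is.na(fc), "unchanged",
                   ifelse(fc > threshold, "up",
                          ifelse(fc < -threshold, "down", "unchanged")))
    data.frame(subgroup = s, gene = g, fold_change = fc, call = call,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  cnt <- do.call(rbind, lapply(split(rows, rows$subgroup), function(d)
    data.frame(subgroup = d$subgroup[1], n_up = sum(d$call == "up"),
               n_down = sum(d$call == "down"), n = nrow(d))))
  rownames(cnt) <- NULL
  attr(rows, "counts") <- cnt
  attr(rows, "dataset_id") <- table$dataset_id
  class(rows) <- c("panel_screen", "data.frame")
  rows
}
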