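#' The 13 canonical cell-death type labels
#'
#' The closed set of cell-death modalities covered by the packaged
#' regulatome: apoptosis, mitochondrial-permeability-transition (MPT)-driven
#' necrosis, necroptosis, ferroptosis, pyroptosis, parthanatos, entotic cell
#' death, NETotic cell death, lysosome-dependent cell death (LDCD),
#' autophagy-dependent cell death (ADCD), immunogenic cell death (ICD),
#' mitotic death, and anoikis.
#'
#' @return Character vector of length 13.
#' @export
cell_death_types <- function() {
  c("apoptosis", "MPT-driven necrosis", "necroptosis", "ferroptosis",
    "pyroptosis", "parthanatos", "entotic cell death", "NETotic cell death",
    "LDCD", "ADCD", "ICD", "mitotic death", "anoikis")
}

reg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "regulatome")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Load the packaged gene-symbol alias table
#'
#' Each entry maps a raw printed token to its canonical symbol and documents
#' the reason. Identity entries record tokens that were deliberately kept
#' verbatim despite looking like typos.
#'
#' @return A data frame with columns `raw`, `canonical`, `reason`.
#' @export
load_alias_table <- function() {
  al <- utils::read.delim(reg_extdata("aliases.tsv"), stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("raw", "canonical", "reason")
  if (!all(need %in% names(al)))
    stop("malformed aliases.tsv: expected columns ", paste(need, collapse = ", "))
  al
}

#' Normalize gene symbols
#'
#' Upper-cases and whitespace-strips each token, then resolves it through the
#' alias table. Normalization is idempotent; tokens without an alias entry
#' are kept verbatim (no silent renaming).
#'
#' @param raw Character vector of gene symbols as printed.
#' @param alias_table Data frame with columns `raw` and `canonical`; defaults
#'   to the packaged alias table.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbol <- function(raw, alias_table = load_alias_table()) {
  if (length(raw) == 0L) return(character())
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  if (any(!nzchar(out) | is.na(out)))
    stop("empty gene symbol at position ",
         paste(which(!nzchar(out) | is.na(out)), collapse = ", "))
  if (!is.null(alias_table) && nrow(alias_table)) {
    hit <- match(out, toupper(alias_table$raw))
    out[!is.na(hit)] <- alias_table$canonical[hit[!is.na(hit)]]
  }
  out
}

#' Load the packaged cell-death regulatome registry
#'
#' Reads the packaged per-type membership lists (transcribed from the source
#' study's curation, deduplicated within a type) together with the alias
#' table, validates them, and returns the registry with its membership
#' accounting: 390 memberships over 13 types, 299 unique genes, and a
#' membership excess of 91 (the published "total minus multi-type"
#' arithmetic). Because several genes belong to three or more types, the
#' strict count of multi-type genes (`n_multi_type`) is smaller than the
#' excess; the registry reports both.
#'
#' @return An object of class `regulatome_registry`: a list with elements
#'   `memberships` (data frame: `cell_death_type`, `gene_symbol_raw`,
#'   `gene_symbol_canonical`), `alias_table`, `per_type_count` (named
#'   integer), `total_memberships`, `unique_genes`, `redundant_memberships`
#'   (total minus unique), `n_multi_type` and `multi_type_genes`.
#' @export
load_regulatome <- function() {
  path <- reg_extdata("regulatome.tsv")
  mem <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("cell_death_type", "gene_symbol_raw", "gene_symbol_canonical")
  if (!all(need %in% names(mem)))
    stop("malformed ", path, ": expected columns ", paste(need, collapse = ", "))
  al <- load_alias_table()
  types <- cell_death_types()
  bad <- which(!mem$cell_death_type %in% types)
  if (length(bad))
    stop("malformed ", path, ": unknown cell death type at data line ",
         bad[1], " ('", mem$cell_death_type[bad[1]], "')")
  renorm <- normalize_symbol(mem$gene_symbol_raw, al)
  off <- which(renorm != mem$gene_symbol_canonical)
  if (length(off))
    stop("malformed ", path, ": canonical symbol disagrees with ",
         "normalization at data line ", off[1])
  dup <- duplicated(mem[c("cell_death_type", "gene_symbol_canonical")])
  if (any(dup))
    stop("malformed ", path, ": duplicated membership at data line ",
         which(dup)[1])

  mem$cell_death_type <- factor(mem$cell_death_type, levels = types)
  per_type <- table(mem$cell_death_type)
  k <- table(mem$gene_symbol_canonical)
  multi <- sort(names(k)[k >= 2L])
  reg <- list(
    memberships = mem,
    alias_table = al,
    per_type_count = stats::setNames(as.integer(per_type), names(per_type)),
    total_memberships = nrow(mem),
    unique_genes = length(k),
    redundant_memberships = nrow(mem) - length(k),
    n_multi_type = length(multi),
    multi_type_genes = multi
  )
  class(reg) <- "regulatome_registry"
  reg
}

#' @export
print.regulatome_registry <- function(x, ...) {
  cat("Cell-death regulatome registry\n")
  cat(sprintf("  %d memberships across %d types; %d unique genes\n",
              x$total_memberships, length(x$per_type_count), x$unique_genes))
  cat(sprintf("  membership excess %d; %d genes in >= 2 types\n",
              x$redundant_memberships, x$n_multi_type))
  df <- data.frame(genes = x$per_type_count)
  print(df)
  invisible(x)
}

#' Genes of the regulatome
#'
#' @param registry A `regulatome_registry`.
#' @return Character vector of the unique normalized gene symbols.
#' @export
regulatome_genes <- function(registry = load_regulatome()) {
  sort(unique(registry$memberships$gene_symbol_canonical))
}

#' Cell-death types a gene belongs to
#'
#' @param gene A single gene symbol (normalized on the way in).
#' @param registry A `regulatome_registry`.
#' @return Character vector of type labels, possibly empty; length greater
#'   than one exactly when the gene is multi-type. Unknown genes return an
#'   empty set rather than an error.
#' @export
memberships_of <- function(gene, registry = load_regulatome()) {
  stopifnot(length(gene) == 1L)
  g <- normalize_symbol(gene, registry$alias_table)
  mem <- registry$memberships
  as.character(mem$cell_death_type[mem$gene_symbol_canonical == g])
}

#' Load a packaged auxiliary gene panel
#'
#' Available panels: `housekeeping` (CHMP2A, PSMB4, ACTB, GAPDH), `redox`
#' (ROS-generating vs antioxidant enzymes) and `chromatin_factors`
#' (insulator-binding, promoter-binding and non-promoter-binding chromatin
#' conformation factors). Subgroups, when present, partition the members.
#'
#' @param name Panel name.
#' @return An object of class `gene_panel`: list with `name`, `members`
#'   (character) and `subgroups` (named list of character vectors, or NULL).
#' @export
load_panel <- function(name) {
  pn <- utils::read.delim(reg_extdata("panels.tsv"), stringsAsFactors = FALSE,
                          colClasses = "character")
  avail <- unique(pn$panel)
  if (length(name) != 1L || !name %in% avail)
    stop("unknown panel '", name, "'; available panels: ",
         paste(avail, collapse = ", "))
  pn <- pn[pn$panel == name, , drop = FALSE]
  members <- normalize_symbol(pn$gene_symbol)
  if (anyDuplicated(members)) stop("malformed panels.tsv: duplicate members")
  subgroups <- NULL
  if (any(nzchar(pn$subgroup))) {
    if (!all(nzchar(pn$subgroup)))
      stop("malformed panels.tsv: subgroup set on only part of panel ", name)
    subgroups <- split(members, pn$subgroup)
  }
  structure(list(name = name, members = members, subgroups = subgroups),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s' (%d genes)\n", x$name, length(x$members)))
  if (is.null(x$subgroups)) {
    cat(" ", paste(x$members, collapse = ", "), "\n")
  } else {
    for (sg in names(x$subgroups))
      cat(sprintf("  %s: %s\n", sg, paste(x$subgroups[[sg]], collapse = ", ")))
  }
  invisible(x)
}
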