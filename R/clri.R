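split_genes <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    normalize_symbol(trimws(strsplit(cell, "[,;]")[[1]]))
  })
}

#' Read a chromatin interaction table
#'
#' Parses a tabulated interaction dump with columns `chrA startA endA chrB
#' startB endB` and optional `genesA genesB method cell_type` (header line
#' required; multi-gene cells split on comma or semicolon). Input
#' coordinates are 1-based inclusive by default, the common convention of
#' interaction-database text exports, and are converted to the internal
#' 0-based half-open convention; pass `dialect = "zero_half_open"` for
#' BED-style input. Trans records (anchors on different chromosomes) are
#' retained and flagged; filtering happens downstream.
#'
#' @param path File path.
#' @param dialect Coordinate convention of the input file.
#' @return An object of class `interaction_table`: data frame with columns
#'   `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b` (0-based
#'   half-open), list columns `genes_a`, `genes_b`, `method`, `cell_type`
#'   and logical `trans`.
#' @export
read_interaction_table <- function(path, dialect = c("one_based",
                                                     "zero_half_open")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("chra", "starta", "enda", "chrb", "startb", "endb")
  if (!all(need %in% names(df)))
    stop("interaction table ", path, " must have columns chrA startA endA ",
         "chrB startB endB")
  num <- c("starta", "enda", "startb", "endb")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop("non-numeric coordinate in column ", cn, " at data line ",
           which(is.na(v))[1], " of ", path)
    df[[cn]] <- v
  }
  off <- if (dialect == "one_based") 1 else 0
  out <- data.frame(chrom_a = as.character(df$chra),
                    start_a = df$starta - off, end_a = df$enda,
                    chrom_b = as.character(df$chrb),
                    start_b = df$startb - off, end_b = df$endb,
                    stringsAsFactors = FALSE)
  bad <- which(out$start_a < 0 | out$start_b < 0 |
                 out$start_a >= out$end_a | out$start_b >= out$end_b)
  if (length(bad))
    stop("invalid interval (start >= end after conversion) at data line ",
         bad[1], " of ", path)
  out$genes_a <- split_genes(if ("genesa" %in% names(df)) df$genesa else
    rep(NA_character_, nrow(df)))
  out$genes_b <- split_genes(if ("genesb" %in% names(df)) df$genesb else
    rep(NA_character_, nrow(df)))
  out$method <- if ("method" %in% names(df)) df$method else NA_character_
  out$cell_type <- if ("cell_type" %in% names(df)) df$cell_type else
    NA_character_
  out$trans <- out$chrom_a != out$chrom_b
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Write an interaction table in the tabulated dialect
#'
#' Inverse of [read_interaction_table()]; coordinates are emitted 1-based
#' inclusive.
#'
#' @param interactions An `interaction_table`.
#' @param path Output path.
#' @export
write_interaction_table <- function(interactions, path) {
  join <- function(g) vapply(g, paste, "", collapse = ",")
  df <- data.frame(chrA = interactions$chrom_a,
                   startA = interactions$start_a + 1,
                   endA = interactions$end_a,
                   chrB = interactions$chrom_b,
                   startB = interactions$start_b + 1,
                   endB = interactions$end_b,
                   genesA = join(interactions$genes_a),
                   genesB = join(interactions$genes_b),
                   method = interactions$method,
                   cell_type = interactions$cell_type,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter/TSS table
#'
#' Two formats: BED6 (`chrom start end name score strand`, 0-based
#' half-open; the anchor is the interval start, or the strand-appropriate
#' end with `strand_aware = TRUE`) or a two-column `gene<TAB>tss` file with
#' the chromosome given by a `#chrom<TAB>value` header line or the `chrom`
#' argument.
#'
#' @param path File path.
#' @param format `"bed6"` or `"tss2"`.
#' @param chrom Chromosome label for `tss2` input lacking a `#chrom` header.
#' @param strand_aware For BED6 input, anchor minus-strand genes at the
#'   interval end instead of the start. Off by default: distances are signed
#'   in pure genomic orientation.
#' @return A `promoter_table`: data frame with columns `gene`, `chrom`,
#'   `anchor`, `strand`, one row per gene.
#' @export
read_promoter_table <- function(path, format = c("bed6", "tss2"),
                                chrom = NULL, strand_aware = FALSE) {
  format <- match.arg(format)
  if (format == "bed6") {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED promoter table needs at least 4 columns")
    strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "unknown"
    strand[!strand %in% c("+", "-")] <- "unknown"
    anchor <- ifelse(strand_aware & strand == "-", df[[3]] - 1, df[[2]])
    out <- data.frame(gene = normalize_symbol(df[[4]]),
                      chrom = as.character(df[[1]]),
                      anchor = as.numeric(anchor), strand = strand,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta_chrom <- chrom
    for (h in hdr) {
      kv <- strsplit(sub("^#", "", lines[h]), "\t", fixed = TRUE)[[1]]
      if (length(kv) >= 2 && kv[1] == "chrom") meta_chrom <- kv[2]
    }
    if (is.null(meta_chrom))
      stop("tss2 promoter table needs a #chrom header line or chrom=")
    df <- utils::read.delim(text = paste(if (length(hdr)) lines[-hdr] else
      lines, collapse = "\n"), stringsAsFactors = FALSE)
    if (!all(c("gene", "tss") %in% names(df)))
      stop("tss2 promoter table must have columns gene, tss")
    out <- data.frame(gene = normalize_symbol(df$gene), chrom = meta_chrom,
                      anchor = as.numeric(df$tss), strand = "unknown",
                      stringsAsFactors = FALSE)
  }
  if (anyNA(out$anchor) || any(out$anchor < 0))
    stop("promoter anchors must be non-negative numbers")
  if (anyDuplicated(out$gene))
    stop("promoter table has duplicate gene(s): ",
         paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  class(out) <- c("promoter_table", "data.frame")
  out
}

#' Promoter-aware anchor coordinate of one interaction side
#'
#' If the side's gene list contains a gene with a promoter entry, that
#' gene's start (TSS) coordinate is used (the first listed such gene when
#' there are several, a deterministic tie rule); otherwise the floor
#' midpoint of the anchor interval.
#'
#' @param chrom,start,end The side's interval (0-based half-open).
#' @param genes Character vector of genes annotated to the side.
#' @param promoters A `promoter_table`.
#' @return A single coordinate.
#' @export
promoter_anchor <- function(chrom, start, end, genes, promoters) {
  hit <- genes[genes %in% promoters$gene]
  if (length(hit)) {
    p <- promoters[match(hit[1], promoters$gene), ]
    if (p$chrom == chrom) return(p$anchor)
  }
  floor((start + end) / 2)
}

target_side <- function(record_genes_a, record_genes_b, gene) {
  ina <- gene %in% record_genes_a
  inb <- gene %in% record_genes_b
  if (ina && inb) return("both")
  if (ina) return("a")
  if (inb) return("b")
  "none"
}

#' Signed promoter-anchored distance of one interaction record
#'
#' For a target gene appearing on exactly one side of a cis record, the
#' distance is the partner side's anchor coordinate minus the target gene's
#' promoter coordinate: positive when the interaction partner lies
#' downstream (higher genomic coordinate) of the promoter, negative when
#' upstream. Strand is ignored by default (pure genomic orientation).
#'
#' @param target_gene Gene symbol.
#' @param record One-row `interaction_table` (or a list with the same
#'   fields).
#' @param promoters A `promoter_table` containing the target gene.
#' @return List with `value` (signed bp), `partner_chrom`,
#'   `partner_anchor`, and `status` (`"ok"`, `"trans"`, `"both_sides"`,
#'   `"absent"`, `"no_promoter"`).
#' @export
signed_distance <- function(target_gene, record, promoters) {
  g <- normalize_symbol(target_gene)
  ga <- if (is.list(record$genes_a)) record$genes_a[[1]] else record$genes_a
  gb <- if (is.list(record$genes_b)) record$genes_b[[1]] else record$genes_b
  side <- target_side(ga, gb, g)
  if (side == "none") return(list(value = NA_real_, status = "absent"))
  if (side == "both") return(list(value = NA_real_, status = "both_sides"))
  if (!g %in% promoters$gene)
    return(list(value = NA_real_, status = "no_promoter"))
  if (record$chrom_a != record$chrom_b)
    return(list(value = NA_real_, status = "trans"))
  prom <- promoters[match(g, promoters$gene), ]
  if (side == "a") {
    anc <- promoter_anchor(record$chrom_b, record$start_b, record$end_b,
                           gb, promoters)
    pc <- record$chrom_b
  } else {
    anc <- promoter_anchor(record$chrom_a, record$start_a, record$end_a,
                           ga, promoters)
    pc <- record$chrom_a
  }
  list(value = anc - prom$anchor, partner_chrom = pc, partner_anchor = anc,
       status = "ok")
}

#' Promoter-anchored signed distances for a gene set
#'
#' Collects one signed distance per (gene, matching interaction record)
#' pair over a whole gene set: cis records where the gene is annotated on
#' exactly one side contribute a distance; trans records and records with
#' the gene on both sides are excluded with counts, and genes lacking a
#' promoter entry or any matching record are reported in the diagnostics.
#' A distance of exactly zero is retained (counted as downstream) and
#' flagged.
#'
#' @param gene_set Non-empty character vector of gene symbols.
#' @param interactions An `interaction_table`.
#' @param promoters A `promoter_table`.
#' @param label Label for the resulting set.
#' @return An object of class `signed_distance_set`: list with `label`,
#'   `distances` (data frame: `gene`, `distance_bp`, `partner_chrom`,
#'   `partner_anchor`), `n_trans_excluded`, `n_both_sides_excluded`,
#'   `n_zero`, `n_genes_without_promoter`, `genes_without_interactions`.
#' @export
build_distance_set <- function(gene_set, interactions, promoters,
                               label = "gene set") {
  if (!length(gene_set)) stop("gene_set must be non-empty")
  genes <- unique(normalize_symbol(gene_set))
  no_prom <- setdiff(genes, promoters$gene)
  n_trans <- 0L
  n_both <- 0L
  # invert the per-record gene lists once: record index per gene per side
  idx_a <- rep(seq_len(nrow(interactions)),
               lengths(interactions$genes_a))
  sym_a <- unlist(interactions$genes_a, use.names = FALSE)
  idx_b <- rep(seq_len(nrow(interactions)),
               lengths(interactions$genes_b))
  sym_b <- unlist(interactions$genes_b, use.names = FALSE)
  out <- vector("list", length(genes))
  seen <- logical(length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ra <- idx_a[sym_a == g]
    rb <- idx_b[sym_b == g]
    both <- intersect(ra, rb)
    n_both <- n_both + length(both)
    ra <- setdiff(ra, both); rb <- setdiff(rb, both)
    if (!length(ra) && !length(rb)) next
    seen[gi] <- TRUE
    if (g %in% no_prom) next
    prom <- promoters[match(g, promoters$gene), ]
    one_side <- function(ri, partner) {
      if (!length(ri)) return(NULL)
      rec <- interactions[ri, , drop = FALSE]
      cis <- !rec$trans
      n_trans <<- n_trans + sum(!cis)
      rec <- rec[cis, , drop = FALSE]
      if (!nrow(rec)) return(NULL)
      pc <- rec[[paste0("chrom_", partner)]]
      ps <- rec[[paste0("start_", partner)]]
      pe <- rec[[paste0("end_", partner)]]
      pg <- rec[[paste0("genes_", partner)]]
      anc <- vapply(seq_len(nrow(rec)), function(i)
        promoter_anchor(pc[i], ps[i], pe[i], pg[[i]], promoters), 0)
      data.frame(gene = g, distance_bp = anc - prom$anchor,
                 partner_chrom = pc, partner_anchor = anc,
                 stringsAsFactors = FALSE)
    }
    out[[gi]] <- rbind(one_side(ra, "b"), one_side(rb, "a"))
  }
  dist <- do.call(rbind, out)
  if (is.null(dist))
    dist <- data.frame(gene = character(), distance_bp = numeric(),
                       partner_chrom = character(),
                       partner_anchor = numeric(), stringsAsFactors = FALSE)
  rownames(dist) <- NULL
  res <- structure(list(
    label = label,
    distances = dist,
    n_trans_excluded = n_trans,
    n_both_sides_excluded = n_both,
    n_zero = sum(dist$distance_bp == 0),
    n_genes_without_promoter = length(intersect(no_prom, genes)),
    genes_without_interactions = sort(genes[!seen])
  ), class = "signed_distance_set")
  if (!nrow(dist))
    warning("no promoter-anchored cis distances found for set '", label, "'")
  res
}

#' @export
print.signed_distance_set <- function(x, ...) {
  cat(sprintf(paste0("Signed distance set '%s': %d distances over %d ",
                     "gene(s); %d trans pair(s) excluded, %d gene(s) ",
                     "without promoter\n"),
              x$label, nrow(x$distances), length(unique(x$distances$gene)),
              x$n_trans_excluded, x$n_genes_without_promoter))
  invisible(x)
}

#' Summarize a signed distance distribution
#'
#' Upstream/downstream fractions (zero distances count as downstream, their
#' retained sign) and a histogram over symmetric log-magnitude bins with
#' edges at 10^k bp, k = 3..8: magnitudes below 10^3 bp pool into a central
#' bin and magnitudes above 10^8 bp into the outermost signed bins, so the
#' counts always sum to the number of distances.
#'
#' @param set A `signed_distance_set` (or a bare numeric vector of signed
#'   distances).
#' @return An object of class `distance_summary`: list with `n`,
#'   `fraction_upstream`, `fraction_downstream`, `n_zero` and `histogram`
#'   (data frame: `bin_low`, `bin_high`, `count`; signed bp bounds,
#'   +/-Inf on the outermost bins).
#' @export
summarize_distances <- function(set) {
  d <- if (inherits(set, "signed_distance_set")) set$distances$distance_bp
  else as.numeric(set)
  edges <- c(-Inf, -10^(8:3), 10^(3:8), Inf)
  counts <- if (length(d)) as.integer(table(cut(d, edges, right = FALSE)))
  else integer(length(edges) - 1)
  structure(list(
    n = length(d),
    fraction_upstream = if (length(d)) mean(d < 0) else 0,
    fraction_downstream = if (length(d)) mean(d >= 0) else 0,
    n_zero = sum(d == 0),
    histogram = data.frame(bin_low = edges[-length(edges)],
                           bin_high = edges[-1], count = counts)
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("Distance summary: n = %d, %.1f%% upstream / %.1f%% downstream\n",
              x$n, 100 * x$fraction_upstream, 100 * x$fraction_downstream))
  h <- x$histogram[x$histogram$count > 0, , drop = FALSE]
  if (nrow(h)) {
    lab <- sprintf("[%g, %g)", h$bin_low, h$bin_high)
    cat(paste0("  ", format(lab, width = max(nchar(lab))), "  ", h$count,
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' End-to-end promoter-distance comparison of two gene sets
#'
#' Builds promoter-anchored signed distance sets for an upregulated and a
#' downregulated gene set over the same interaction and promoter tables,
#' summarizes both distributions, and compares them with the two-sample
#' Kolmogorov-Smirnov test. Deterministic given fixed inputs.
#'
#' @param up_set,down_set Non-empty character vectors of gene symbols.
#' @param interactions An `interaction_table`.
#' @param promoters A `promoter_table`.
#' @param labels Length-2 labels for the two sets.
#' @return An object of class `clri_result`: list with `up`, `down`
#'   (`signed_distance_set`), `summary_up`, `summary_down`
#'   (`distance_summary`) and `ks` (`ks_result`).
#' @export
clri_pipeline <- function(up_set, down_set, interactions, promoters,
                          labels = c("up", "down")) {
  up <- build_distance_set(up_set, interactions, promoters, labels[1])
  dn <- build_distance_set(down_set, interactions, promoters, labels[2])
  for (s in list(up, dn)) if (!nrow(s$distances))
    stop("no distances for set '", s$label, "': ",
         s$n_genes_without_promoter, " gene(s) without promoter, ",
         length(s$genes_without_interactions),
         " gene(s) without interactions, ", s$n_trans_excluded,
         " trans pair(s) excluded")
  structure(list(
    up = up, down = dn,
    summary_up = summarize_distances(up),
    summary_down = summarize_distances(dn),
    ks = ks_two_sample(up$distances$distance_bp, dn$distances$distance_bp)
  ), class = "clri_result")
}

#' @export
print.clri_result <- function(x, ...) {
  cat("Promoter-anchored distance comparison\n")
  cat(sprintf("  %s: n = %d (%.1f%% downstream); %s: n = %d (%.1f%% downstream)\n",
              x$up$label, x$summary_up$n,
              100 * x$summary_up$fraction_downstream,
              x$down$label, x$summary_down$n,
              100 * x$summary_down$fraction_downstream))
  print(x$ks)
  invisible(x)
}
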