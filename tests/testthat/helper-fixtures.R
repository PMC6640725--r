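# in-code builders for small chromatin fixtures and an independent KS oracle

# write an interaction TSV (1-based inclusive) and read it back through the
# package parser, so tests exercise the real input path
make_interactions <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- "chrA\tstartA\tendA\tchrB\tstartB\tendB\tgenesA\tgenesB\tmethod\tcell_type"
  writeLines(c(header, rows), path)
  read_interaction_table(path)
}

int_row <- function(chr_a, s_a, e_a, chr_b, s_b, e_b, genes_a = "",
                    genes_b = "", method = "HiC", cell = "IMR90") {
  paste(chr_a, s_a, e_a, chr_b, s_b, e_b, genes_a, genes_b, method, cell,
        sep = "\t")
}

make_promoters <- function(gene, chrom, anchor, strand = "unknown") {
  out <- data.frame(gene = gene, chrom = chrom, anchor = anchor,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("promoter_table", "data.frame")
  out
}

# brute-force sup of |ECDF_x - ECDF_y| over a dense threshold grid, built
# from stats::ecdf -- independent of the package's statistic path
ks_D_oracle <- function(x, y) {
  grid <- sort(c(x, y))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

random_differential <- function(n = 30, seed = 1, id = "rand") {
  set.seed(seed)
  genes <- paste0("RG", seq_len(n))
  fc <- ratio_to_signed(2^stats::rnorm(n, 0, 1.2))
  differential_table(genes, fc, dataset_id = id)
}
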