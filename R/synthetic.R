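# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Specification of a synthetic two-group expression experiment
#'
#' Describes a replicated two-condition experiment with multiplicative
#' planted effects and multiplicative log-normal noise: control samples are
#' `baseline * 2^N(0, noise_sd)`, treated samples of a planted gene are
#' additionally multiplied by its effect (or divided by it, for planted
#' downregulation). A fraction of the gene roster is drawn from the
#' packaged regulatome so that classification against the regulatome
#' universe is exercised end to end.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_planted_up,n_planted_down Number of genes planted up and down
#'   (default 20 each); ignored when explicit `planted_up`/`planted_down`
#'   maps are given.
#' @param effect Multiplicative effect (>= 1) used for default planted
#'   sets (default 2).
#' @param planted_up,planted_down Optional named numeric vectors mapping
#'   gene names to multiplicative effects >= 1; the two sets must be
#'   disjoint.
#' @param replicates Samples per group (default 3).
#' @param noise_sd Standard deviation of the log2-scale noise (default 0.1).
#' @param baseline Positive baseline intensity (default 100).
#' @param regulatome_fraction Fraction of the roster drawn from regulatome
#'   symbols (default 0.5).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_expression_spec`.
#' @export
synthetic_expression_spec <- function(n_genes = 200, n_planted_up = 20,
                                      n_planted_down = 20, effect = 2,
                                      planted_up = NULL, planted_down = NULL,
                                      replicates = 3, noise_sd = 0.1,
                                      baseline = 100,
                                      regulatome_fraction = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, replicates >= 1, noise_sd >= 0, baseline > 0,
            regulatome_fraction >= 0, regulatome_fraction <= 1, effect >= 1)
  spec <- list(n_genes = n_genes, n_planted_up = n_planted_up,
               n_planted_down = n_planted_down, effect = effect,
               planted_up = planted_up, planted_down = planted_down,
               replicates = replicates, noise_sd = noise_sd,
               baseline = baseline,
               regulatome_fraction = regulatome_fraction,
               seed = as.integer(seed))
  if (!is.null(planted_up) || !is.null(planted_down)) {
    if (length(intersect(names(planted_up), names(planted_down))))
      stop("planted up and down sets must be disjoint")
    if (any(c(planted_up, planted_down) < 1))
      stop("planted effects must be >= 1 (multiplicative)")
  }
  class(spec) <- "synthetic_expression_spec"
  spec
}

#' Generate a synthetic two-group expression matrix
#'
#' @param spec A [synthetic_expression_spec()].
#' @return List with `matrix` (genes x samples, linear scale),
#'   `group_labels` (`"treated"`/`"control"` per column) and `truth` (data
#'   frame: `gene`, `direction` in up/down/none, `effect`). Reproducible
#'   from the spec's seed.
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_expression_spec"))
  with_seed(spec$seed, {
    roster <- paste0("SYNG", formatC(seq_len(spec$n_genes), width = 4,
                                     flag = "0"))
    n_reg <- round(spec$regulatome_fraction * spec$n_genes)
    if (n_reg > 0) {
      reg <- regulatome_genes()
      n_reg <- min(n_reg, length(reg))
      roster[seq_len(n_reg)] <- sample(reg, n_reg)
    }
    up <- spec$planted_up
    dn <- spec$planted_down
    if (is.null(up) && is.null(dn)) {
      if (spec$n_planted_up + spec$n_planted_down > spec$n_genes)
        stop("more planted genes than genes")
      pick <- sample(roster, spec$n_planted_up + spec$n_planted_down)
      up <- stats::setNames(rep(spec$effect, spec$n_planted_up),
                            pick[seq_len(spec$n_planted_up)])
      dn <- stats::setNames(rep(spec$effect, spec$n_planted_down),
                            pick[spec$n_planted_up + seq_len(spec$n_planted_down)])
    } else {
      roster <- unique(c(names(up), names(dn), roster))[seq_len(
        max(spec$n_genes, length(up) + length(dn)))]
    }
    eff <- rep(1, length(roster))
    names(eff) <- roster
    eff[names(up)] <- up
    eff[names(dn)] <- 1 / dn
    n <- spec$replicates
    noise <- function() matrix(2^stats::rnorm(length(roster) * n, 0,
                                              spec$noise_sd),
                               nrow = length(roster))
    ctrl <- spec$baseline * noise()
    trt <- spec$baseline * eff * noise()
    mat <- cbind(trt, ctrl)
    rownames(mat) <- roster
    colnames(mat) <- c(paste0("T", seq_len(n)), paste0("C", seq_len(n)))
    dir <- ifelse(roster %in% names(up), "up",
                  ifelse(roster %in% names(dn), "down", "none"))
    truth <- data.frame(gene = roster, direction = dir,
                        effect = ifelse(dir == "down", dn[roster],
                                        ifelse(dir == "up", up[roster], 1)),
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(matrix = mat,
         group_labels = rep(c("treated", "control"), each = n),
         truth = truth)
  })
}

#' Specification of a synthetic chromatin interaction experiment
#'
#' Each gene receives a transcription start site on a synthetic genome (one
#' chromosome per 50 genes, sites spaced 2e8 bp apart so that interaction
#' magnitudes up to 1e8 bp never collide across genes) and a fixed number
#' of interactions, each placed downstream of the TSS with probability
#' `downstream_prob` at a log-uniform magnitude, or on a different
#' chromosome (a trans record) with probability `trans_prob`.
#'
#' @param genes Character vector of gene names (duplicates rejected).
#' @param interactions_per_gene Interactions per gene (default 5).
#' @param downstream_prob Probability a cis interaction lands downstream of
#'   the promoter (default 0.5).
#' @param magnitude_range Length-2 positive bounds of the log-uniform
#'   distance magnitude in bp (default `c(1e4, 1e8)`).
#' @param trans_prob Probability a record is trans (default 0).
#' @param anchor_halfwidth Half-width in bp of emitted anchor intervals
#'   (default 500).
#' @param seed Integer seed.
#' @return An object of class `synthetic_interaction_spec`.
#' @export
synthetic_interaction_spec <- function(genes, interactions_per_gene = 5,
                                       downstream_prob = 0.5,
                                       magnitude_range = c(1e4, 1e8),
                                       trans_prob = 0,
                                       anchor_halfwidth = 500, seed = 1) {
  genes <- normalize_symbol(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene(s) would collide at the same TSS: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  stopifnot(interactions_per_gene >= 1,
            downstream_prob >= 0, downstream_prob <= 1,
            trans_prob >= 0, trans_prob <= 1,
            length(magnitude_range) == 2, all(magnitude_range > 0),
            magnitude_range[1] < magnitude_range[2])
  structure(list(genes = genes,
                 interactions_per_gene = as.integer(interactions_per_gene),
                 downstream_prob = downstream_prob,
                 magnitude_range = magnitude_range,
                 trans_prob = trans_prob,
                 anchor_halfwidth = as.integer(anchor_halfwidth),
                 seed = as.integer(seed)),
            class = "synthetic_interaction_spec")
}

#' Generate a synthetic interaction table with matching promoters
#'
#' @param spec A [synthetic_interaction_spec()].
#' @return List with `interactions` (an `interaction_table`; the gene is
#'   annotated on the B side, the partner anchor is unannotated so its
#'   midpoint — exactly the planted coordinate — is used downstream),
#'   `promoters` (a `promoter_table`) and `truth` (data frame: `gene`,
#'   `downstream`, `magnitude`, `trans`).
#' @export
gen_interactions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_interaction_spec"))
  with_seed(spec$seed, {
    ng <- length(spec$genes)
    chrom <- paste0("synchr", (seq_len(ng) - 1) %/% 50 + 1)
    tss <- ((seq_len(ng) - 1) %% 50 + 1) * 2e8
    promoters <- data.frame(gene = spec$genes, chrom = chrom, anchor = tss,
                            strand = "unknown", stringsAsFactors = FALSE)
    class(promoters) <- c("promoter_table", "data.frame")
    k <- spec$interactions_per_gene
    gi <- rep(seq_len(ng), each = k)
    n <- length(gi)
    down <- stats::runif(n) < spec$downstream_prob
    lr <- log10(spec$magnitude_range)
    mag <- round(10^stats::runif(n, lr[1], lr[2]))
    trans <- stats::runif(n) < spec$trans_prob
    center <- tss[gi] + ifelse(down, mag, -mag)
    pchrom <- chrom[gi]
    pchrom[trans] <- "synchrT"
    center[trans] <- 3e8 + mag[trans]
    w <- spec$anchor_halfwidth
    tab <- data.frame(chrom_a = pchrom, start_a = center - w,
                      end_a = center + w,
                      chrom_b = chrom[gi], start_b = tss[gi] - w,
                      end_b = tss[gi] + w, stringsAsFactors = FALSE)
    tab$genes_a <- rep(list(character()), n)
    tab$genes_b <- as.list(spec$genes[gi])
    tab$method <- "synthetic"
    tab$cell_type <- "synthetic"
    tab$trans <- tab$chrom_a != tab$chrom_b
    class(tab) <- c("interaction_table", "data.frame")
    truth <- data.frame(gene = spec$genes[gi], downstream = down,
                        magnitude = mag, trans = trans,
                        stringsAsFactors = FALSE)
    list(interactions = tab, promoters = promoters, truth = truth)
  })
}

#' Write a promoter table as BED6
#'
#' Each promoter becomes a 1-bp BED feature at its anchor coordinate.
#'
#' @param promoters A `promoter_table`.
#' @param path Output path.
#' @export
write_promoter_bed <- function(promoters, path) {
  df <- data.frame(promoters$chrom, promoters$anchor, promoters$anchor + 1,
                   promoters$gene, 0,
                   ifelse(promoters$strand %in% c("+", "-"),
                          promoters$strand, "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classifier recovery against planted truth
#'
#' Generates a synthetic expression experiment, runs the two-group fold
#' change computation and the strict classifier over all generated genes,
#' and scores the calls against the planted truth: sensitivity is the
#' fraction of planted genes recovered with their planted direction,
#' specificity the fraction of unplanted genes called unchanged. Planted
#' effects at or below the threshold are, by design, not recoverable.
#'
#' @param spec A [synthetic_expression_spec()].
#' @param threshold Fold-change cut (default 1.5).
#' @return An object of class `recovery_report`: list with `sensitivity`,
#'   `specificity`, `n_planted`, `n_null` and the `confusion` table of
#'   planted direction vs call.
#' @export
recovery_experiment <- function(spec, threshold = 1.5) {
  sim <- gen_expression(spec)
  tab <- compute_differential(sim$matrix, sim$group_labels,
                              dataset_id = "synthetic")
  cs <- classify(tab, universe = rownames(sim$matrix),
                 threshold = threshold)
  call <- cs$calls$call[match(sim$truth$gene, cs$calls$gene)]
  planted <- sim$truth$direction != "none"
  structure(list(
    sensitivity = if (any(planted))
      mean(call[planted] == sim$truth$direction[planted]) else NA_real_,
    specificity = if (any(!planted))
      mean(call[!planted] == "unchanged") else NA_real_,
    n_planted = sum(planted), n_null = sum(!planted),
    confusion = table(planted = sim$truth$direction, call = call)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("Recovery: sensitivity %.3f (%d planted), specificity ",
                     "%.3f (%d null)\n"),
              x$sensitivity, x$n_planted, x$specificity, x$n_null))
  print(x$confusion)
  invisible(x)
}
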