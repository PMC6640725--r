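#' Packaged fold-change screen fixtures
#'
#' The package ships the per-gene signed fold-change calls of the source
#' microarray comparisons as plain TSV fixtures: the LIUS (low-intensity
#' ultrasound) cancer and non-cancer screens, the mild-hyperthermia cancer
#' and non-cancer screens, the oscillatory-shear-stress non-cancer screen,
#' and the TP53/SRF perturbation datasets used for transcription-factor
#' cross-referencing. Only genes whose |fold change| reached the reporting
#' cut of the source tables are present.
#'
#' @param condition One of `"lius_cancer"`, `"lius_noncancer"`,
#'   `"hyperthermia_cancer"`, `"hyperthermia_noncancer"`,
#'   `"oss_noncancer"`, `"tp53_kd"`, `"tp53_ko"`, `"srf_ko"`.
#' @return A [differential_table].
#' @export
load_screen_fixture <- function(condition = c("lius_cancer",
                                              "lius_noncancer",
                                              "hyperthermia_cancer",
                                              "hyperthermia_noncancer",
                                              "oss_noncancer", "tp53_kd",
                                              "tp53_ko", "srf_ko")) {
  condition <- match.arg(condition)
  read_differential_tsv(reg_extdata(paste0("diff_", condition, ".tsv")))
}

#' Packaged housekeeping fold-change fixture
#'
#' The housekeeping-gene (CHMP2A, PSMB4, ACTB, GAPDH) fold changes of the
#' nine source microarray datasets, as one small differential table per
#' dataset; one cell (CHMP2A in GSE90) is missing in the source and is
#' absent here too.
#'
#' @return Named list of [differential_table] objects, one per dataset.
#' @export
load_housekeeping_fixture <- function() {
  df <- utils::read.delim(reg_extdata("hk_foldchanges.tsv"),
                          stringsAsFactors = FALSE)
  ids <- unique(df$dataset)
  stats::setNames(lapply(ids, function(id) {
    d <- df[df$dataset == id, ]
    differential_table(d$gene, d$fold_change, dataset_id = id)
  }), ids)
}

#' Packaged auxiliary panel screen fixtures
#'
#' Per-dataset fold changes of the redox panel (ROS-generating and
#' antioxidant enzymes) and of the chromatin conformation factor panel, as
#' printed in the source screens; blank cells of those screens (values
#' below the 1.5-fold reporting cut) are simply absent.
#'
#' @param panel `"redox"` or `"chromatin_factors"`.
#' @return Named list of [differential_table] objects, one per dataset.
#' @export
load_panel_screen_fixture <- function(panel = c("redox",
                                                "chromatin_factors")) {
  panel <- match.arg(panel)
  df <- utils::read.delim(reg_extdata(paste0("screen_", panel, ".tsv")),
                          stringsAsFactors = FALSE)
  ids <- unique(df$dataset)
  stats::setNames(lapply(ids, function(id) {
    d <- df[df$dataset == id, ]
    differential_table(d$gene, d$fold_change, dataset_id = id)
  }), ids)
}
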