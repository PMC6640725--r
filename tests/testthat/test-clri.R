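test_that("interaction tables parse, convert coordinates, flag trans", {
  tab <- make_interactions(c(
    int_row("chr1", 1001, 2000, "chr1", 500001, 501000, "GENEA", "GENEB"),
    int_row("chr1", 1, 100, "chr2", 1, 100),
    int_row("chr3", 50, 60, "chr3", 70, 80, "", "g1,g2;g3")))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$start_a[1], 1000)   # 1-based -> 0-based half-open
  expect_identical(tab$end_a[1], 2000)
  expect_identical(tab$trans, c(FALSE, TRUE, FALSE))
  expect_identical(tab$genes_a[[2]], character())   # empty cells retained
  expect_identical(tab$genes_b[[3]], c("G1", "G2", "G3"))

  # round trip through the writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(tab, path)
  back <- read_interaction_table(path)
  expect_equal(back$start_a, tab$start_a)
  expect_equal(back$genes_b, tab$genes_b)

  p_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrA\tstartA\tendA\tchrB\tstartB\tendB",
               "chr1\t100\t50\tchr1\t1\t10"), p_bad)
  expect_error(read_interaction_table(p_bad), "start >= end")
  p_bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrA\tstartA\tendA\tchrB\tstartB\tendB",
               "chr1\tx\t50\tchr1\t1\t10"), p_bad2)
  expect_error(read_interaction_table(p_bad2), "non-numeric")
})

test_that("promoter tables read from BED6 and two-column TSS formats", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000000\t1000001\tGENEA\t0\t+",
               "chr1\t2000000\t2000500\tgeneb\t0\t-"), bed)
  pt <- read_promoter_table(bed, "bed6")
  expect_identical(pt$gene, c("GENEA", "GENEB"))
  expect_equal(pt$anchor, c(1e6, 2e6))       # start, strand ignored
  pt_sa <- read_promoter_table(bed, "bed6", strand_aware = TRUE)
  expect_equal(pt_sa$anchor, c(1e6, 2000499)) # minus strand anchors at end

  tss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tchr5", "gene\ttss", "GENEC\t42"), tss)
  p2 <- read_promoter_table(tss, "tss2")
  expect_identical(p2$chrom, "chr5")
  expect_equal(p2$anchor, 42)
  tss2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttss", "GENEC\t42"), tss2)
  expect_error(read_promoter_table(tss2, "tss2"), "chrom")
})

test_that("partner anchors prefer annotated gene starts, else midpoints", {
  prom <- make_promoters(c("GENEA", "GENEB"), "chr1", c(1e6, 5e6))
  expect_equal(promoter_anchor("chr1", 999000, 1001000, c("GENEA"), prom),
               1e6)
  expect_equal(promoter_anchor("chr1", 100, 200, character(), prom), 150)
  expect_equal(promoter_anchor("chr1", 100, 201, character(), prom), 150)
  # first listed annotated gene wins (deterministic tie rule)
  expect_equal(promoter_anchor("chr1", 0, 10, c("GENEB", "GENEA"), prom),
               5e6)
  # promoter on another chromosome does not leak in
  expect_equal(promoter_anchor("chr9", 100, 200, c("GENEA"), prom), 150)
})

test_that("signed distances follow the downstream-positive convention", {
  prom <- make_promoters("GENEA", "chr1", 1e6)
  rec <- make_interactions(int_row("chr1", 1500001 - 500, 1500000 + 500,
                                   "chr1", 1e6 - 499, 1e6 + 500,
                                   genes_b = "GENEA"))
  d <- signed_distance("GENEA", rec[1, ], prom)
  expect_identical(d$status, "ok")
  expect_equal(d$value, 5e5)   # partner downstream of promoter

  rec2 <- make_interactions(int_row("chr1", 500001 - 500, 500000 + 500,
                                    "chr1", 1e6 - 499, 1e6 + 500,
                                    genes_b = "GENEA"))
  expect_equal(signed_distance("GENEA", rec2[1, ], prom)$value, -5e5)

  # swapping which side carries the gene flips nothing (antisymmetry is in
  # the anchors, not the sides)
  rec3 <- make_interactions(int_row("chr1", 1e6 - 499, 1e6 + 500,
                                    "chr1", 1500001 - 500, 1500000 + 500,
                                    genes_a = "GENEA"))
  expect_equal(signed_distance("GENEA", rec3[1, ], prom)$value, 5e5)

  trans <- make_interactions(int_row("chr2", 1, 100, "chr1", 1e6 - 499,
                                     1e6 + 500, genes_b = "GENEA"))
  expect_identical(signed_distance("GENEA", trans[1, ], prom)$status,
                   "trans")
  both <- make_interactions(int_row("chr1", 1, 100, "chr1", 200, 300,
                                    genes_a = "GENEA", genes_b = "GENEA"))
  expect_identical(signed_distance("GENEA", both[1, ], prom)$status,
                   "both_sides")
})

test_that("exchanging target and partner flips sign, preserves magnitude", {
  set.seed(31)
  prom <- make_promoters(c("TGT", "PRT"), "chr1", c(5e6, NA))
  for (i in 1:20) {
    p_t <- round(runif(1, 1e6, 9e6))
    p_p <- round(runif(1, 1e6, 9e6))
    prom <- make_promoters(c("TGT", "PRT"), "chr1", c(p_t, p_p))
    rec <- make_interactions(int_row("chr1", p_p + 1 - 50, p_p + 50, "chr1",
                                     p_t + 1 - 50, p_t + 50,
                                     genes_a = "PRT", genes_b = "TGT"))
    d_fwd <- signed_distance("TGT", rec[1, ], prom)$value
    d_rev <- signed_distance("PRT", rec[1, ], prom)$value
    expect_equal(d_fwd, -d_rev)
    expect_equal(abs(d_fwd), abs(p_p - p_t))
  }
})

test_that("distance sets count every (gene, record) pair exactly once", {
  prom <- make_promoters(c("GENEA", "GENEB"), "chr1", c(1e6, 8e6))
  tab <- make_interactions(c(
    int_row("chr1", 2000001, 2001000, "chr1", 1e6 - 499, 1e6 + 500,
            genes_b = "GENEA"),
    int_row("chr1", 3000001, 3001000, "chr1", 1e6 - 499, 1e6 + 500,
            genes_b = "GENEA"),
    int_row("chr1", 1e6 - 499, 1e6 + 500, "chr1", 400001, 401000,
            genes_a = "GENEA"),
    int_row("chr2", 1, 1000, "chr1", 1e6 - 499, 1e6 + 500,
            genes_b = "GENEA")))
  ds <- build_distance_set(c("GENEA", "GENEB", "GENEC"), tab, prom, "t")
  expect_identical(nrow(ds$distances), 3L)       # 3 cis pairs
  expect_identical(ds$n_trans_excluded, 1L)
  # GENEC lacks both a promoter and any interaction: both diagnostics list it
  expect_setequal(ds$genes_without_interactions, c("GENEB", "GENEC"))
  expect_identical(ds$n_genes_without_promoter, 1L)   # GENEC
  expect_setequal(ds$distances$distance_bp,
                  c(2000500 - 1e6, 3000500 - 1e6, 400500 - 1e6))

  # zero distance: retained, flagged, counted downstream
  z <- make_interactions(int_row("chr1", 1e6 + 1 - 500, 1e6 + 500, "chr1",
                                 1e6 + 1 - 500, 1e6 + 500,
                                 genes_b = "GENEA"))
  dz <- build_distance_set("GENEA", z, prom, "z")
  expect_identical(dz$n_zero, 1L)
  expect_equal(summarize_distances(dz)$fraction_downstream, 1)
  expect_warning(build_distance_set("GENEB", z, prom, "none"),
                 "no promoter-anchored")
})

test_that("distance summaries bin by signed decade and conserve counts", {
  s <- summarize_distances(c(-2e6, -5e5, 3e5))
  expect_equal(s$fraction_upstream, 2 / 3)
  expect_equal(s$fraction_downstream, 1 / 3)
  h <- s$histogram
  expect_identical(sum(h$count), 3L)
  expect_identical(h$count[h$bin_low == -1e7 & h$bin_high == -1e6], 1L)
  expect_identical(h$count[h$bin_low == -1e6 & h$bin_high == -1e5], 1L)
  expect_identical(h$count[h$bin_low == 1e5 & h$bin_high == 1e6], 1L)

  expect_equal(summarize_distances(c(1, 10, 1e9))$fraction_upstream, 0)

  # mirroring negates fractions exactly; counts invariant to permutation
  set.seed(13)
  d <- round(runif(500, -1e8, 1e8))
  d <- d[d != 0]
  s1 <- summarize_distances(d)
  s2 <- summarize_distances(-d)
  expect_equal(s1$fraction_upstream, s2$fraction_downstream)
  expect_identical(sum(s1$histogram$count), length(d))
  expect_identical(s1$histogram$count, rev(s2$histogram$count))
  sp <- summarize_distances(sample(d))
  expect_identical(sp$histogram$count, s1$histogram$count)

  s0 <- summarize_distances(numeric())
  expect_identical(s0$n, 0L)
  expect_equal(s0$fraction_upstream + s0$fraction_downstream, 0)
  expect_identical(sum(s0$histogram$count), 0L)
})

test_that("the end-to-end pipeline is deterministic and error-surfacing", {
  spec_up <- synthetic_interaction_spec(paste0("UP", 1:5), 10,
                                        downstream_prob = 1, seed = 5)
  spec_dn <- synthetic_interaction_spec(paste0("DN", 1:5), 10,
                                        downstream_prob = 0, seed = 6)
  up <- gen_interactions(spec_up)
  dn <- gen_interactions(spec_dn)
  ints <- rbind(up$interactions, dn$interactions)
  class(ints) <- c("interaction_table", "data.frame")
  prom <- rbind(up$promoters, dn$promoters)
  class(prom) <- c("promoter_table", "data.frame")
  r1 <- clri_pipeline(paste0("UP", 1:5), paste0("DN", 1:5), ints, prom)
  r2 <- clri_pipeline(paste0("UP", 1:5), paste0("DN", 1:5), ints, prom)
  expect_identical(r1$ks$statistic, r2$ks$statistic)
  expect_equal(r1$ks$statistic, 1)   # opposite-signed supports
  expect_equal(r1$summary_up$fraction_downstream, 1)
  expect_equal(r1$summary_down$fraction_upstream, 1)

  same <- clri_pipeline(paste0("UP", 1:5), paste0("UP", 1:5), ints, prom)
  expect_equal(same$ks$statistic, 0)
  expect_equal(same$ks$p_asymptotic, 1)

  expect_error(
    suppressWarnings(clri_pipeline("ABSENT", paste0("DN", 1:5), ints,
                                   prom)),
    "no distances")
})
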