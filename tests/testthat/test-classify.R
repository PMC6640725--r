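fixture_counts <- list(
  lius_cancer = c(up = 13L, down = 12L),
  lius_noncancer = c(up = 9L, down = 31L),
  hyperthermia_cancer = c(up = 27L, down = 15L),
  hyperthermia_noncancer = c(up = 18L, down = 7L),
  oss_noncancer = c(up = 4L, down = 22L)
)

test_that("strict 1.5-fold classifier reproduces every packaged screen", {
  reg <- load_regulatome()
  for (cond in names(fixture_counts)) {
    cs <- classify(load_screen_fixture(cond), universe = reg)
    expect_identical(cs$n_up, fixture_counts[[cond]][["up"]], label = cond)
    expect_identical(cs$n_down, fixture_counts[[cond]][["down"]],
                     label = cond)
    # partition: every measured universe gene has exactly one call
    expect_identical(cs$n_up + cs$n_down + cs$n_unchanged,
                     nrow(cs$calls))
    expect_identical(nrow(cs$calls) + length(cs$not_measured),
                     cs$universe_size)
  }
})

test_that("the threshold comparison is strict (more-than)", {
  tab <- differential_table(c("TP53", "BAX", "BID", "BAK1"),
                            c(1.5, -1.5, 1.5 + 1e-9, -1.5 - 1e-9),
                            dataset_id = "edge")
  cs <- classify(tab, universe = c("TP53", "BAX", "BID", "BAK1"))
  expect_identical(cs$calls$call[cs$calls$gene == "TP53"], "unchanged")
  expect_identical(cs$calls$call[cs$calls$gene == "BAX"], "unchanged")
  expect_identical(cs$calls$call[cs$calls$gene == "BID"], "up")
  expect_identical(cs$calls$call[cs$calls$gene == "BAK1"], "down")
  expect_error(classify(tab, universe = character()), "universe")
  expect_error(classify(tab, threshold = 0.5), "threshold")
})

test_that("classification is invariant to row order and threshold-monotone", {
  for (seed in 1:5) {
    tab <- random_differential(60, seed = seed)
    uni <- tab$records$gene[1:45]
    cs <- classify(tab, universe = uni)
    # row-order invariance
    perm <- tab
    set.seed(seed + 100)
    perm$records <- perm$records[sample(nrow(perm$records)), ]
    cs_p <- classify(perm, universe = sample(uni))
    expect_identical(cs$calls, cs_p$calls)
    # raising the threshold never adds calls
    for (t2 in c(2, 3, 5)) {
      cs2 <- classify(tab, universe = uni, threshold = t2)
      expect_lte(cs2$n_up, cs$n_up)
      expect_lte(cs2$n_down, cs$n_down)
    }
    expect_identical(cs$n_up + cs$n_down + cs$n_unchanged, nrow(cs$calls))
  }
})

test_that("annotation lists multi-type genes once per type", {
  reg <- load_regulatome()
  ann <- annotate_calls(classify(load_screen_fixture("lius_cancer"), reg),
                        reg)
  panx1 <- ann[ann$gene == "PANX1", ]
  expect_setequal(panx1$cell_death_type, c("pyroptosis", "ICD"))
  expect_true(all(panx1$direction == "up"))
  expect_equal(unique(panx1$fold_change), 1.913)

  ann2 <- annotate_calls(classify(load_screen_fixture("lius_noncancer"),
                                  reg), reg)
  bcl2 <- ann2[ann2$gene == "BCL2", ]
  expect_setequal(bcl2$cell_death_type,
                  c("apoptosis", "MPT-driven necrosis", "LDCD", "ADCD",
                    "mitotic death"))
  expect_true(all(bcl2$direction == "down"))
  # union of annotated genes equals the called genes
  cs2 <- classify(load_screen_fixture("lius_noncancer"), reg)
  expect_setequal(unique(ann2$gene),
                  c(called_genes(cs2, "up"), called_genes(cs2, "down")))

  # a called gene with no membership lands in "unassigned"
  tab <- differential_table(c("TP53", "ZZZNOVEL"), c(2, 3),
                            dataset_id = "x")
  ann3 <- annotate_calls(classify(tab, universe = c("TP53", "ZZZNOVEL")),
                         reg)
  expect_identical(ann3$cell_death_type[ann3$gene == "ZZZNOVEL"],
                   "unassigned")
})

test_that("cross-condition overlaps match the printed call lists", {
  reg <- load_regulatome()
  lius_nc <- classify(load_screen_fixture("lius_noncancer"), reg)
  hyp_nc <- classify(load_screen_fixture("hyperthermia_noncancer"), reg)
  ov <- compare_callsets(lius_nc, hyp_nc)
  expect_setequal(ov$shared_down, c("GCLC", "NLRP3", "CD47"))

  lius_c <- classify(load_screen_fixture("lius_cancer"), reg)
  hyp_c <- classify(load_screen_fixture("hyperthermia_cancer"), reg)
  ov_c <- compare_callsets(lius_c, hyp_c)
  # the printed tables intersect in TLR7 and SRC only: the LIUS cancer list
  # carries MAP2K5, not MAP2K7, so MAP2K7 cannot be shared
  expect_setequal(ov_c$shared_down, c("TLR7", "SRC"))
  expect_false("MAP2K7" %in% ov_c$shared_down)

  oss <- classify(load_screen_fixture("oss_noncancer"), reg)
  ov_o <- compare_callsets(lius_nc, oss)
  # printed lists intersect in 7 genes (BUB1B and TTK beyond the 5 named in
  # the source prose)
  expect_setequal(ov_o$shared_down,
                  c("BIRC5", "CDK1", "E2F8", "CASP1", "BUB1", "BUB1B",
                    "TTK"))
  # shared and discordant sets are disjoint
  for (o in list(ov, ov_c, ov_o)) {
    expect_length(intersect(o$shared_down, o$discordant), 0)
    expect_length(intersect(o$shared_up, o$discordant), 0)
  }
  # self-comparison: shared sets equal the call sets, Jaccard 1
  self <- compare_callsets(lius_nc, lius_nc)
  expect_identical(self$shared_up, called_genes(lius_nc, "up"))
  expect_identical(self$shared_down, called_genes(lius_nc, "down"))
  expect_equal(self$jaccard_up, 1)
  expect_equal(self$jaccard_down, 1)
})

test_that("knockout cross-reference flags opposite movers", {
  reg <- load_regulatome()
  tp53kd <- classify(load_screen_fixture("tp53_kd"), reg)
  xc <- knockout_crossref(classify(load_screen_fixture("lius_cancer"), reg),
                          tp53kd)
  expect_true(all(c("CD47", "ATM") %in% xc$down_then_up))
  xnc <- knockout_crossref(classify(load_screen_fixture("lius_noncancer"),
                                    reg), tp53kd)
  expect_true("CASP1" %in% xnc$down_then_up)
  # disjoint universes give an empty report
  a <- classify(differential_table("TP53", 2, dataset_id = "a"),
                universe = "TP53")
  b <- classify(differential_table("BAX", -2, dataset_id = "b"),
                universe = "BAX")
  empty <- knockout_crossref(a, b)
  expect_length(empty$down_then_up, 0)
  expect_length(empty$up_then_down, 0)
})

test_that("panel screens classify within subgroups, blanks as unchanged", {
  rx <- load_panel("redox")
  screens <- load_panel_screen_fixture("redox")
  ps <- panel_screen(screens$GSE10212, rx)
  expect_identical(ps$call[ps$gene == "NOS2"], "up")
  expect_equal(ps$fold_change[ps$gene == "NOS2"], 4.370)
  expect_identical(ps$call[ps$gene == "GPX3"], "up")
  # genes absent from the sparse screen are unchanged, not missing
  expect_identical(ps$call[ps$gene == "XDH"], "unchanged")
  expect_true(is.na(ps$fold_change[ps$gene == "XDH"]))
  expect_identical(nrow(ps), length(rx$members))

  cf <- load_panel("chromatin_factors")
  cscreens <- load_panel_screen_fixture("chromatin_factors")
  pc <- panel_screen(cscreens$GSE10212, cf)
  expect_identical(pc$call[pc$gene == "GATA2"], "up")
  cnt <- attr(pc, "counts")
  expect_identical(sum(cnt$n_up), 1L)   # 1/24 factors up
  expect_identical(sum(cnt$n_down), 0L)
  pc2 <- panel_screen(cscreens$GSE70662, cf)
  expect_setequal(pc2$gene[pc2$call == "up"], c("POLR3D", "POLR3F"))

  flat <- differential_table(rx$members, rep(1, length(rx$members)),
                             dataset_id = "flat")
  pf <- panel_screen(flat, rx)
  expect_true(all(pf$call == "unchanged"))
})
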