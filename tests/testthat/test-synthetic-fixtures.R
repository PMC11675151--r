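test_that("element generation handles empty enhancer sets and is seeded", {
  cfg <- tiny_config(n_enhancers = 0L, n_promoters = 10L)
  el <- generate_elements(cfg)
  expect_equal(sum(el$etype == "enhancer"), 0)
  expect_equal(sum(el$etype == "promoter"), 10)

  cfg2 <- tiny_config(seed = 42L)
  expect_identical(generate_elements(cfg2), generate_elements(cfg2))
  cfg3 <- tiny_config(seed = 43L)
  expect_false(identical(generate_elements(cfg2), generate_elements(cfg3)))
})

test_that("placed elements are disjoint with full window clearance", {
  cfg <- synthetic_config(n_chromosomes = 1L, chrom_length = 1e7,
                          n_enhancers = 50L, n_promoters = 0L, seed = 5L)
  el <- generate_elements(cfg)
  expect_equal(nrow(el), 50)
  # brute-force pairwise overlap scan
  for (a in seq_len(nrow(el) - 1)) for (b in (a + 1):nrow(el))
    expect_true(el$end[a] <= el$start[b] || el$end[b] <= el$start[a])
  expect_true(all(el$start >= 42000))
  expect_true(all(el$end <= cfg$chrom_length - 42000))
})

test_that("chromosomes too small for the element load are rejected", {
  expect_error(synthetic_config(n_chromosomes = 1L, chrom_length = 1e6,
                                n_enhancers = 50L, n_promoters = 50L),
               "chrom_length too small")
})

test_that("planted network respects topology mix and distance range", {
  # pure one-to-one: every node has degree <= 1 in the positive graph
  cfg1 <- tiny_config(seed = 3L,
                      component_topology = c(one_to_one = 1,
                                             one_to_many = 0,
                                             many_to_many = 0))
  pr1 <- suppressMessages(generate_epi_network(generate_elements(cfg1),
                                               cfg1))
  expect_true(all(table(pr1$enhancer_id) == 1))
  expect_true(all(table(pr1$gene_id) == 1))

  # with many-to-many weight, some component has >= 2 of each type
  cfg2 <- tiny_config(seed = 4L, n_chromosomes = 2L, chrom_length = 1e7,
                      n_enhancers = 30L, n_promoters = 40L,
                      component_topology = c(one_to_one = 0.2,
                                             one_to_many = 0.2,
                                             many_to_many = 0.6))
  pr2 <- suppressMessages(generate_epi_network(generate_elements(cfg2),
                                               cfg2))
  comp <- oracle_bfs(pr2$enhancer_id, pr2$gene_id)
  mm <- vapply(unique(comp), function(cid) {
    nodes <- names(comp)[comp == cid]
    sum(nodes %in% pr2$enhancer_id) >= 2 && sum(nodes %in% pr2$gene_id) >= 2
  }, logical(1))
  expect_true(any(mm))

  for (pr in list(pr1, pr2))
    expect_true(all(pr$distance >= 42000 & pr$distance <= 500000))
})

test_that("recorded component ids match a brute-force BFS census", {
  cfg <- tiny_config(seed = 9L, n_chromosomes = 2L, chrom_length = 1e7,
                     n_enhancers = 30L, n_promoters = 45L)
  pr <- suppressMessages(generate_epi_network(generate_elements(cfg), cfg))
  comp <- oracle_bfs(pr$enhancer_id, pr$gene_id)
  expect_true(same_partition(pr$component_id, comp[pr$enhancer_id]))
  # endpoints of one pair always share a component id
  expect_true(all(comp[pr$enhancer_id] == comp[pr$gene_id]))
})

test_that("signal tracks plant enrichment only when asked", {
  base <- list(seed = 21L, n_chromosomes = 2L, chrom_length = 2e7,
               n_enhancers = 80L, n_promoters = 130L)
  central <- function(cfg) {
    fix <- suppressMessages(generate_fixture(cfg))
    expect_length(fix$tracks, 7)
    el <- fix$elements[, c("id", "chrom", "start", "end")]
    feats <- featurize_all(el, fix$tracks, chrom_length = cfg$chrom_length)
    pos <- unique(c(fix$pairs$enhancer_id, fix$pairs$gene_id))
    list(pos = vapply(feats[names(feats) %in% pos],
                      function(m) m["H3K4me1", "0"], 0),
         iso = vapply(feats[!(names(feats) %in% pos)],
                      function(m) m["H3K4me1", "0"], 0))
  }
  # null: no planted effect, central-window means indistinguishable
  v0 <- central(do.call(synthetic_config,
                        c(base, list(signal_effect = 0))))
  expect_gte(length(v0$pos) + length(v0$iso), 200)
  expect_gt(stats::t.test(v0$pos, v0$iso)$p.value, 0.01)
  # strong effect: difference beyond 3 standard errors
  v1 <- central(do.call(synthetic_config,
                        c(base, list(signal_effect = 2.5, noise_sd = 0.5))))
  se <- sqrt(stats::var(v1$pos) / length(v1$pos) +
               stats::var(v1$iso) / length(v1$iso))
  expect_gt(mean(v1$pos) - mean(v1$iso), 3 * se)
})

test_that("fixtures round-trip through the readers and are byte-stable", {
  cfg <- tiny_config(seed = 6L)
  fix <- suppressMessages(generate_fixture(cfg))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(fix, d1)
  write_fixture(fix, d2)
  files <- list.files(d1)
  expect_setequal(files, c("enhancers.bed", "tss.tsv", "pairs.tsv",
                           paste0(epi_markers(), ".bed"), "manifest.json"))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  rd <- read_fixture(d1)
  enh <- fix$elements[fix$elements$etype == "enhancer", ]
  expect_equal(rd$enhancers$start, enh$start)  # BED stays 0-based
  expect_equal(rd$enhancers$end, enh$end)
  pro <- fix$elements[fix$elements$etype == "promoter", ]
  expect_equal(rd$tss$tss, pro$tss)            # 1-based TSV converted back
  expect_equal(rd$pairs$enhancer_id, fix$pairs$enhancer_id)
  expect_equal(nrow(rd$pairs), nrow(fix$pairs))
  for (m in epi_markers()) {
    tr <- fix$tracks[[m]][order(fix$tracks[[m]]$chrom,
                                fix$tracks[[m]]$start), ]
    expect_equal(rd$tracks[[m]]$start, tr$start)
    expect_equal(rd$tracks[[m]]$signalValue, tr$signalValue)
    expect_true(all(rd$tracks[[m]]$signalValue > 0))
  }
})
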