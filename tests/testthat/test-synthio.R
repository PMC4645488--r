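# Synthetic genome generator: determinism, coordinate sanity, planted
# content, and fixture round-trips.

test_that("an all-zero configuration yields an empty genome", {
  cfg <- simulation_config(seed = 1, architecture_counts = c(CNL = 0))
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$genes), 0L)
  expect_equal(nrow(sim$hits), 0L)
  expect_equal(nrow(sim$truth$genes), 0L)
})

test_that("identical configurations produce byte-identical fixture files", {
  cfg <- small_sim_config(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  p1 <- write_fixtures(s1$genes, s1$hits, d1, truth = s1$truth)
  p2 <- write_fixtures(s2$genes, s2$hits, d2, truth = s2$truth)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("file", nm))
})

test_that("gene coordinates are sane and non-overlapping", {
  for (seed in 1:3) {
    sim <- simulate_genome(small_sim_config(seed = seed))
    g <- sim$genes
    expect_true(all(g$start >= 1))
    expect_true(all(g$start <= g$end))
    expect_true(all(g$end <= 2e8))
    for (chr in unique(g$chromosome)) {
      d <- g[g$chromosome == chr, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1)
        expect_true(all(d$start[-1] > d$end[-nrow(d)]),
                    label = paste("no overlap on", chr, "seed", seed))
    }
    # every gene appears exactly once in the truth ledger
    expect_setequal(sim$truth$genes$gene_id, g$gene_id)
    expect_false(anyDuplicated(sim$truth$genes$gene_id) > 0)
  }
})

test_that("planted families and clusters are recoverable from the raw output", {
  sim <- simulate_genome(small_sim_config(seed = 5))
  tg <- sim$truth$genes
  # family members share architecture and ~target identity (checked by
  # direct column comparison: the mutation model is substitution-only)
  for (i in seq_len(nrow(sim$truth$families))) {
    fam <- sim$truth$families[i, ]
    mem <- strsplit(fam$members, ",")[[1]]
    archs <- tg$architecture[match(mem, tg$gene_id)]
    expect_length(unique(archs), 1L)
    seqs <- sim$genes$protein[match(mem, sim$genes$gene_id)]
    expect_length(unique(nchar(seqs)), 1L)
    for (j in seq_along(seqs)[-1]) {
      h <- mapply(identical, strsplit(seqs[1], "")[[1]],
                  strsplit(seqs[j], "")[[1]])
      ident <- 100 * mean(h)
      expect_gt(ident, fam$target_identity_pct - 6)
    }
  }
  # cluster members share a chromosome and chain within 200 kb
  for (i in seq_len(nrow(sim$truth$clusters))) {
    mem <- strsplit(sim$truth$clusters$members[i], ",")[[1]]
    d <- sim$genes[match(mem, sim$genes$gene_id), ]
    expect_length(unique(d$chromosome), 1L)
    st <- sort(d$start)
    expect_true(all(diff(st) <= 200000))
  }
})

test_that("mutate_to_identity hits the target by direct Hamming count", {
  base <- random_aa(100, seed = 3)
  expect_identical(mutate_to_identity(base, 100, seed = 1), base)
  m <- mutate_to_identity(base, 70, seed = 2)
  hamming <- sum(strsplit(base, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(hamming, 30L)
  expect_equal(nchar(m), 100L)
  # brute-force check through an actual alignment on a longer target
  base2 <- random_aa(200, seed = 4)
  m2 <- mutate_to_identity(base2, 50, seed = 5)
  st <- pair_stats(global_align(base2, m2), 200, 200)
  expect_gte(st$identity_pct, 48)
  expect_lte(st$identity_pct, 52)
  # determinism and input validation
  expect_identical(mutate_to_identity(base, 70, seed = 2), m)
  expect_error(mutate_to_identity(random_aa(20), 70, 1), "50")
  expect_error(mutate_to_identity(base, 0, 1), "\\(0, 100\\]")
})

test_that("plant_coiled_coil replaces exactly the requested segment", {
  base <- strrep("G", 100)
  out <- plant_coiled_coil(base, 20, 4)
  expect_equal(nchar(out), 100L)
  expect_identical(substr(out, 1, 19), strrep("G", 19))
  expect_identical(substr(out, 48, 100), strrep("G", 53))
  expect_identical(substr(out, 20, 47), strrep("LEELKEK", 4))
  expect_identical(plant_coiled_coil(base, 20, 0), base)
  expect_error(plant_coiled_coil(base, 95, 4), "out of range")
})

test_that("fixtures round-trip losslessly through the parsers", {
  sim <- simulate_genome(small_sim_config(seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim$genes, sim$hits, dir)
  rec <- read_gene_records(paths[["proteins"]], paths[["coords"]])
  rec <- rec[match(sim$genes$gene_id, rec$gene_id), ]
  rownames(rec) <- NULL
  expect_equal(rec$gene_id, sim$genes$gene_id)
  expect_equal(rec$chromosome, sim$genes$chromosome)
  expect_equal(rec$start, sim$genes$start)
  expect_equal(rec$end, sim$genes$end)
  expect_equal(rec$protein, sim$genes$protein)
  expect_equal(rec$signal_end, sim$genes$signal_end)
  expect_equal(rec$tm_start, sim$genes$tm_start)
  expect_equal(rec$kinase_type, sim$genes$kinase_type)
  hits <- parse_domtbl(paths[["domtbl"]])
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_equal(hits$gene_id, sim$hits$gene_id)
  expect_equal(hits$accession, sim$hits$accession)
  expect_equal(hits$ali_start, sim$hits$ali_start)
  expect_equal(hits$ali_end, sim$hits$ali_end)
  # E-values survive at the printed precision (2 significant digits)
  expect_equal(hits$evalue, sim$hits$evalue, tolerance = 0.05)
})

test_that("a planted E-value round-trips exactly through the domtbl dialect", {
  hits <- mk_hits("gX", "NBS", evalue = 1e-10, ali_start = 5, ali_end = 60)
  f <- withr::local_tempfile()
  write_domtbl(hits, f)
  back <- parse_domtbl(f)
  expect_equal(back$evalue, 1e-10)
  expect_equal(back$ali_start, 5L)
  expect_equal(back$ali_end, 60L)
})

test_that("oversized co-clustered families trigger a sizing error", {
  cfg <- simulation_config(
    seed = 1, n_chromosomes = 1, chromosome_length_bp = 3e5,
    architecture_counts = c(CNL = 10),
    family_specs = list(family_spec("CNL", 10, 80, co_clustered = TRUE)),
    min_intergene_gap_bp = 1e5, max_intergene_gap_bp = 2e5)
  expect_error(simulate_genome(cfg), "sizing error")
})
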