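# Coiled-coil scorer and TNL/CNL classification.

test_that("profiles have one probability per residue, all within [0,1]", {
  for (seed in 1:3) {
    s <- random_aa(60, seed = seed)
    pr <- coils_scan(s)
    expect_length(pr$probability, 60L)
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  }
  # sequences shorter than the window give an all-zero profile, not an error
  short <- coils_scan(random_aa(10, seed = 1))
  expect_equal(short$probability, rep(0, 10))
  expect_error(coils_scan("ACDB*"), "illegal")
  # X is allowed and scored neutrally
  expect_silent(coils_scan(paste0(random_aa(30, seed = 2), "XXX")))
})

test_that("poly-proline scores as firmly non-coiled-coil", {
  pr <- coils_scan(strrep("P", 50))
  expect_lt(max(pr$probability), 0.1)
  # matches the direct propensity-arithmetic oracle
  expect_equal(pr$probability, oracle_coil_probability(strrep("P", 50)),
               tolerance = 1e-8)
})

test_that("planted ideal heptads reach probability 0.9 over a full heptad", {
  s <- plant_coiled_coil(random_aa(120, seed = 4), 10, 6)
  pr <- coils_scan(s)
  expect_gte(max(pr$probability), 0.9)
  runs <- rle(pr$probability >= 0.9)
  expect_gte(max(runs$lengths[runs$values]), 7)
  # the whole profile agrees with the independent double-loop oracle
  expect_equal(pr$probability, oracle_coil_probability(s), tolerance = 1e-8)
})

test_that("scores agree with the oracle on both matrices and windows", {
  s <- plant_coiled_coil(random_aa(80, seed = 9), 5, 5)
  for (m in c("MTK", "MTIDK")) for (w in c(14, 28)) {
    pr <- coils_scan(s, coils_config(window = w, matrix = m))
    expect_equal(pr$probability, oracle_coil_probability(s, m, w),
                 tolerance = 1e-8, label = paste(m, w))
  }
})

test_that("heptad periodicity: a 7-residue shift leaves the max score unchanged", {
  base <- random_aa(150, seed = 6)
  s1 <- plant_coiled_coil(base, 20, 6)
  s2 <- plant_coiled_coil(base, 27, 6)
  m1 <- max(coils_scan(s1)$score)
  m2 <- max(coils_scan(s2)$score)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("has_cc applies the run-length rule with inclusive boundaries", {
  mk_profile <- function(p) {
    structure(list(probability = p, score = p,
                   register = rep("a", length(p)), window = 21L,
                   matrix = "MTIDK"), class = "coil_profile")
  }
  cfg <- coils_config(search_region = "WHOLE_PROTEIN")
  expect_false(has_cc(mk_profile(rep(0, 30)), cfg)$has_cc)
  p <- rep(0, 30); p[10:16] <- 0.9          # exactly min_run at threshold
  res <- has_cc(mk_profile(p), cfg)
  expect_true(res$has_cc)
  expect_equal(c(res$start, res$end), c(10L, 16L))
  p2 <- rep(0, 30); p2[10:15] <- 0.99       # min_run - 1
  expect_false(has_cc(mk_profile(p2), cfg)$has_cc)
  # raising the threshold can only lose the call, never create one
  for (th in c(0.5, 0.9, 0.95, 0.999)) {
    r <- has_cc(mk_profile(p), coils_config(probability_threshold = th,
                                            search_region = "WHOLE_PROTEIN"))
    if (th > 0.9) expect_false(r$has_cc) else expect_true(r$has_cc)
  }
  # restricted search region before the NBS domain
  p3 <- rep(0, 60); p3[40:50] <- 0.95
  expect_false(has_cc(mk_profile(p3), coils_config(), nbs_start = 30)$has_cc)
  expect_true(has_cc(mk_profile(p3), coils_config(), nbs_start = 55)$has_cc)
  fb <- has_cc(mk_profile(p3), coils_config(), nbs_start = NULL)
  expect_true(fb$has_cc)
  expect_true(fb$fallback_whole_protein)
})

test_that("classification partitions the catalog with TIR precedence", {
  sim <- simulate_genome(small_sim_config(seed = 21))
  kept <- threshold_hits(annotate_roles(sim$hits))
  cat <- build_catalog(kept)
  profiles <- coil_profiles(sim$genes[sim$genes$gene_id %in%
                                        cat$nbs_lrr_genes, ])
  cls <- classify_nterm(cat, kept, profiles)
  expect_equal(sum(cls$counts), length(cat$nbs_lrr_genes))
  truth <- sim$truth$genes
  expect_equal(unname(cls$counts[["CNL"]]),
               sum(truth$architecture == "CNL"))
  expect_equal(unname(cls$counts[["TNL"]]),
               sum(truth$architecture == "TNL"))
  # TIR precedence: give a TNL gene a planted coiled coil too
  tnl <- cls$classes$gene_id[cls$classes$class == "TNL"][1]
  i <- match(tnl, sim$genes$gene_id)
  boosted <- sim$genes
  boosted$protein[i] <- plant_coiled_coil(boosted$protein[i], 3, 6)
  prof2 <- coil_profiles(boosted[boosted$gene_id %in% cat$nbs_lrr_genes, ])
  cls2 <- classify_nterm(cat, kept, prof2)
  expect_equal(cls2$classes$class[cls2$classes$gene_id == tnl], "TNL")
})

test_that("strict mode drops NL genes from the catalog and logs them", {
  cfg <- simulation_config(
    seed = 3, architecture_counts = c(CNL = 3, TNL = 1,
                                      NBS_LRR_NO_NTERM = 2),
    family_specs = list())
  sim <- simulate_genome(cfg)
  kept <- threshold_hits(annotate_roles(sim$hits))
  cat <- build_catalog(kept)
  profiles <- coil_profiles(sim$genes)
  lax <- classify_nterm(cat, kept, profiles, strict = FALSE)
  expect_equal(unname(lax$counts[["NL"]]), 2)
  expect_length(lax$dropped, 0L)
  strict <- classify_nterm(cat, kept, profiles, strict = TRUE)
  expect_length(strict$dropped, 2L)
  expect_equal(length(strict$catalog$nbs_lrr_genes), 4L)
})

test_that("an empty catalog classifies to zero counts", {
  cat <- build_catalog(mk_hits("g1", "OTHER"))
  cls <- classify_nterm(cat, mk_hits("g1", "OTHER"), list())
  expect_equal(nrow(cls$classes), 0L)
  expect_equal(sum(cls$counts), 0L)
})
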