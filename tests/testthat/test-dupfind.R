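# Global alignment, duplicate criteria, and multigene families.

test_that("identical sequences align gap-free at full identity", {
  s <- random_aa(100, seed = 1)
  aln <- global_align(s, s)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  st <- pair_stats(aln, 100, 100)
  expect_equal(st$coverage_pct, 100)
  expect_equal(st$identity_pct, 100)
  expect_true(st$is_duplicate)
  expect_error(global_align("", s), "non-empty")
})

test_that("alignment scores are symmetric and match brute-force enumeration", {
  set.seed(5)
  for (rep in 1:6) {
    a <- random_aa(sample(4:6, 1))
    b <- random_aa(sample(4:6, 1))
    sa <- global_align(a, b)$score
    sb <- global_align(b, a)$score
    expect_equal(sa, sb)
    expect_equal(sa, brute_force_align_score(a, b),
                 label = paste(a, b))
  }
})

test_that("duplicate boundaries: coverage strict, identity inclusive", {
  base <- random_aa(100, seed = 2)
  m70 <- mutate_to_identity(base, 70, seed = 3)
  st <- pair_stats(global_align(base, m70), 100, 100)
  expect_equal(st$identity_pct, 70)       # substitution-only: exact
  expect_equal(st$coverage_pct, 100)
  expect_true(st$is_duplicate)            # identity boundary inclusive
  # coverage exactly at the threshold does not qualify (>70 is strict)
  frag <- substr(base, 1, 70)
  st2 <- pair_stats(global_align(base, frag), 100, 70)
  expect_lte(st2$coverage_pct, 70)
  expect_false(st2$is_duplicate)
  st3 <- pair_stats(global_align(base, frag), 100, 70,
                    dup_criteria(min_coverage_pct = 69))
  expect_true(st3$is_duplicate)
})

test_that("pair statistics are symmetric under argument order", {
  a <- random_aa(120, seed = 6)
  b <- mutate_to_identity(a, 75, seed = 7)
  s1 <- pair_stats(global_align(a, b), 120, 120)
  s2 <- pair_stats(global_align(b, a), 120, 120)
  expect_equal(s1$coverage_pct, s2$coverage_pct)
  expect_equal(s1$identity_pct, s2$identity_pct)
})

test_that("single linkage joins transitive duplicate pairs", {
  stats <- data.frame(gene_a = c("A", "B", "X"),
                      gene_b = c("B", "C", "Y"),
                      is_duplicate = c(TRUE, TRUE, FALSE))
  fams <- build_families(stats)
  expect_equal(nrow(fams), 1L)
  expect_equal(fams$members, "A,B,C")
  expect_equal(fams$family_id, "A")
  empty <- build_families(stats[stats$gene_a == "zz", ])
  expect_equal(nrow(empty), 0L)
  # invariance to pair enumeration order
  fams2 <- build_families(stats[c(2, 3, 1), ])
  expect_identical(fams, fams2)
})

test_that("families equal brute-force transitive closure on random graphs", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    ids <- sprintf("n%02d", 1:n)
    adj <- matrix(FALSE, n, n)
    for (k in seq_len(n)) {
      i <- sample(n, 1); j <- sample(n, 1)
      if (i != j) adj[i, j] <- adj[j, i] <- TRUE
    }
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    stats <- data.frame(gene_a = ids[pairs[, 1]], gene_b = ids[pairs[, 2]],
                        is_duplicate = adj[pairs])
    fams <- build_families(stats)
    comp <- transitive_closure_components(adj)
    oracle <- lapply(split(ids, comp), sort)
    oracle <- oracle[vapply(oracle, length, 1L) >= 2]
    expect_setequal(fams$members,
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("lowering the identity threshold never loses duplicate pairs", {
  set.seed(19)
  base <- random_aa(150)
  seqs <- c(s1 = base,
            s2 = mutate_to_identity(base, 85, 1),
            s3 = mutate_to_identity(base, 72, 2),
            s4 = mutate_to_identity(base, 55, 3),
            s5 = random_aa(150))
  prev <- -1L
  for (minid in c(95, 85, 70, 50, 10)) {
    st <- all_pair_stats(seqs, criteria = dup_criteria(min_identity_pct =
                                                         minid))
    ndup <- sum(st$is_duplicate)
    expect_gte(ndup, prev)
    prev <- ndup
  }
})

test_that("the k-mer prefilter preserves all duplicate calls", {
  sim <- simulate_genome(small_sim_config(seed = 29))
  keep <- !is.na(sim$truth$genes$family_id)
  ids <- sim$truth$genes$gene_id[keep]
  seqs <- setNames(sim$genes$protein[match(ids, sim$genes$gene_id)], ids)
  seqs <- c(seqs, setNames(sim$genes$protein[1:4], sim$genes$gene_id[1:4]))
  seqs <- seqs[!duplicated(names(seqs))]
  ex <- all_pair_stats(seqs, prefilter = "none")
  km <- all_pair_stats(seqs, prefilter = "kmer")
  expect_identical(ex[ex$is_duplicate, c("gene_a", "gene_b")],
                   km[km$is_duplicate, c("gene_a", "gene_b")])
})

test_that("planted families are recovered with perfect precision and recall", {
  sim <- simulate_genome(small_sim_config(seed = 37))
  truth <- sim$truth
  for (arch_set in list(c("CNL", "TNL", "NBS_LRR_NO_NTERM"), "LRR_RLK")) {
    ids <- truth$genes$gene_id[truth$genes$architecture %in% arch_set]
    seqs <- setNames(sim$genes$protein[match(ids, sim$genes$gene_id)], ids)
    fams <- build_families(all_pair_stats(seqs, prefilter = "kmer"))
    want <- truth$families[truth$families$architecture %in% arch_set, ]
    expect_setequal(fams$members, want$members)
  }
})

test_that("family summaries follow the fixed rounding conventions", {
  fams <- data.frame(family_id = c("a", "d"), n = c(3L, 4L),
                     members = c("a,b,c", "d,e,f,g"))
  s <- summarize_families(fams, 10)
  expect_equal(s$n_multigene_families, 2L)
  expect_equal(s$n_multigenes, 7L)
  expect_equal(s$max_family_size, 4L)
  expect_equal(s$mean_family_size, 3.5)
  expect_equal(s$pct_multigenes, 70)
  expect_equal(s$n_single_genes, 3)
  e <- summarize_families(fams[0, ], 10)
  expect_equal(unlist(e[c("n_multigene_families", "n_multigenes",
                          "max_family_size", "mean_family_size",
                          "pct_multigenes")], use.names = FALSE),
               c(0, 0, 0, 0, 0))
  bad <- data.frame(family_id = c("a", "b"), n = c(2L, 2L),
                    members = c("a,b", "b,c"))
  expect_error(summarize_families(bad, 10), "partition")
})
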