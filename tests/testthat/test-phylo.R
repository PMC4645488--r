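# Identity/similarity, progressive alignment, p-distances, NJ trees and
# bootstrap supports, domain-architecture tables.

test_that("identity and similarity behave on the boundary cases", {
  s <- random_aa(60, seed = 1)
  is0 <- identity_similarity(s, s)
  expect_equal(is0$identity_pct, 100)
  expect_equal(is0$similarity_pct, 100)
  # identity <= similarity on random pairs, symmetric in argument order
  set.seed(2)
  for (rep in 1:5) {
    a <- random_aa(80); b <- random_aa(80)
    ab <- identity_similarity(a, b)
    ba <- identity_similarity(b, a)
    expect_lte(ab$identity_pct, ab$similarity_pct)
    expect_equal(ab$identity_pct, ba$identity_pct)
    expect_equal(ab$similarity_pct, ba$similarity_pct)
  }
})

test_that("identity/similarity match hand-derived values on a tiny pair", {
  # unique optimal alignment: ACDEFGHK vs ACDEGHK deletes the F
  r <- identity_similarity("ACDEFGHK", "ACDEGHK")
  expect_equal(r$identity_pct, 100 * 7 / 8)
  expect_equal(r$similarity_pct, 100 * 7 / 8)
  # substitution D->E is positive-scoring under BLOSUM62: similar, not
  # identical
  r2 <- identity_similarity("ACDKW", "ACEKW")
  expect_equal(r2$identity_pct, 80)
  expect_equal(r2$similarity_pct, 100)
})

test_that("progressive alignment conserves every input sequence", {
  set.seed(3)
  for (rep in 1:4) {
    n <- sample(3:6, 1)
    base <- random_aa(60)
    seqs <- setNames(c(base, vapply(seq_len(n - 1), function(i)
      mutate_to_identity(base, sample(60:95, 1), seed = i), "")),
      paste0("s", 1:n))
    msa <- progressive_align(seqs)
    expect_length(unique(nchar(msa)), 1L)
    expect_identical(gsub("-", "", msa, fixed = TRUE), seqs)
    expect_gte(nchar(msa[1]), max(nchar(seqs)))
  }
})

test_that("two identical sequences align without gaps", {
  s <- random_aa(40, seed = 4)
  msa <- progressive_align(c(a = s, b = s))
  expect_identical(unname(msa), c(s, s))
})

test_that("a prefix sequence is padded with terminal gaps only", {
  s <- random_aa(50, seed = 5)
  seqs <- c(full = s, pre = substr(s, 1, 35),
            sib = mutate_to_identity(s, 90, seed = 6))
  msa <- progressive_align(seqs)
  expect_match(msa[["pre"]], "^[^-]+-+$")
  expect_identical(gsub("-", "", msa[["pre"]]), substr(s, 1, 35))
})

test_that("p-distances equal an independent per-pair column scan", {
  set.seed(7)
  rows <- 5; L <- 60
  m <- matrix(sample(c("A", "C", "D", "-"), rows * L, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), rows, L)
  msa <- setNames(apply(m, 1, paste, collapse = ""), paste0("t", 1:rows))
  d <- pdistance_matrix(msa)
  for (i in 1:(rows - 1)) for (j in (i + 1):rows) {
    comp <- 0; mis <- 0
    for (q in 1:L) {
      if (m[i, q] != "-" && m[j, q] != "-") {
        comp <- comp + 1
        if (m[i, q] != m[j, q]) mis <- mis + 1
      }
    }
    expect_equal(d[i, j], mis / comp)
  }
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, rows))
  expect_equal(pdistance_matrix(c(a = "AC", b = "AC"))[1, 2], 0)
  expect_equal(pdistance_matrix(c(a = "AC", b = "CA"))[1, 2], 1)
  expect_error(pdistance_matrix(c(a = "AC-", b = "AC")), "ragged")
  expect_error(pdistance_matrix(c(a = "A-", b = "-A")), "comparable")
})

test_that("three taxa give the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  for (n in 4:8) {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.3, 2))
    d <- ape::cophenetic.phylo(tr)
    got <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(got, tr), 0)
    expect_equal(sum(got$edge.length), sum(tr$edge.length),
                 tolerance = 1e-8)
    # agrees with the independent NJ implementation in ape
    expect_equal(phangorn::RF.dist(got, ape::nj(d)), 0)
    # taxon order invariance (additive matrices are tie-free here)
    perm <- sample(n)
    got2 <- neighbor_joining(d[perm, perm])
    expect_equal(phangorn::RF.dist(got, got2), 0)
    expect_equal(sum(got2$edge.length), sum(got$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  base <- random_aa(120, seed = 12)
  clade1 <- c(a1 = base, a2 = base, a3 = base)
  other <- mutate_to_identity(base, 55, seed = 13)
  clade2 <- c(b1 = other, b2 = other, b3 = other)
  msa <- progressive_align(c(clade1, clade2))
  t1 <- bootstrap_support(msa, n_replicates = 50, seed = 99)
  t2 <- bootstrap_support(msa, n_replicates = 50, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s <- attr(t1, "bootstrap")
  expect_true(all(s >= 0 & s <= 100))
  # the planted two-clade split survives every resample
  expect_true(any(s == 100))
  # single replicate can only give 0 or 100
  t3 <- bootstrap_support(msa, n_replicates = 1, seed = 5)
  expect_true(all(attr(t3, "bootstrap") %in% c(0, 100)))
})

test_that("architecture tables order, merge and classify segments", {
  seg <- data.frame(
    protein = c("rlk", "rlk", "rlk", "rlk", "rlp", "rlp", "rlp",
                "m1", "m1"),
    role = c("SIGNAL", "LRR", "TM", "KINASE_STK", "SIGNAL", "LRR", "TM",
             "LRR", "LRR"),
    start = c(1, 100, 420, 480, 1, 100, 420, 100, 140),
    end = c(25, 400, 440, 750, 25, 400, 440, 150, 200),
    stringsAsFactors = FALSE)
  lens <- c(rlk = 800, rlp = 500, m1 = 300)
  tab <- architecture_table(seg, lens)
  cls <- attr(tab, "classes")
  expect_equal(cls$class[cls$protein == "rlk"], "RLK")
  expect_equal(cls$class[cls$protein == "rlp"], "RLP")
  rlk_rows <- tab[tab$protein == "rlk", ]
  expect_equal(rlk_rows$role, c("SIGNAL", "LRR", "TM", "KINASE_STK"))
  # overlapping same-role hits merge
  m1 <- tab[tab$protein == "m1", ]
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(100, 200))
  expect_error(architecture_table(
    data.frame(protein = "p", role = "WEIRD", start = 1, end = 5), c(p = 10)),
    "unknown")
  expect_error(architecture_table(
    data.frame(protein = "p", role = "LRR", start = 1, end = 50), c(p = 10)),
    "exceeds")
})
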