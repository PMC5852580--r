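test_that("p-distances use complete deletion", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AAAAAAAAAA")
  d <- p_distance_matrix(msa)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.1)
  # a gap column is removed globally and changes nothing else
  msa_gap <- c(a = "AAAAAAAAAA-", b = "AAAAAAAAAC-", c = "AAAAAAAAAAG")
  expect_equal(p_distance_matrix(msa_gap), d)
  expect_error(p_distance_matrix(c(a = "--", b = "--")), "all columns")
})

test_that("NJ resolves a 3-taxon star with the three-point formulas", {
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
})

test_that("NJ reconstructs additive 4- and 5-taxon trees exactly", {
  # tree ((A:1,B:2):1,C:3,D:4) -> additive matrix
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d4)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d4), colnames(d4)], d4)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))

  # caterpillar with 5 taxa: ((A:1,B:1):1,(C:1,(D:1,E:1):1):1)
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  d5 <- ape::cophenetic.phylo(tr0)
  tr5 <- nj_tree(d5)
  expect_equal(ape::cophenetic.phylo(tr5)[rownames(d5), colnames(d5)], d5)
  expect_true(ape::is.monophyletic(tr5, c("D", "E")))
  expect_error(nj_tree(d4[1:2, 1:2]), "at least 3")
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(31)
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1,E:2);")
  d <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[[1]], 0)
})

test_that("bootstrap supports planted clades and is seed-reproducible", {
  set.seed(17)
  # two clades of 4, within-clade divergence ~1%, between ~50%
  base1 <- random_protein(200)
  base2 <- random_protein(200)
  jitter <- function(s, k) {
    res <- strsplit(s, "")[[1]]
    idx <- sample(length(res), k)
    res[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k, TRUE)
    paste(res, collapse = "")
  }
  msa <- c(setNames(vapply(1:4, function(i) jitter(base1, 2), ""),
                    paste0("x", 1:4)),
           setNames(vapply(1:4, function(i) jitter(base2, 2), ""),
                    paste0("y", 1:4)))
  tr <- bootstrap_supports(msa, n_replicates = 200, seed = 99)
  expect_false(attr(tr, "unresolved"))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  # the planted x|y bipartition must be recovered with near-full support
  # (within-clade edges are noise-driven and carry no expectation)
  expect_true(ape::is.monophyletic(tr, paste0("x", 1:4)))
  expect_gte(clade_support(tr, paste0("x", 1:4)), 95)
  expect_gte(clade_support(tr, paste0("y", 1:4)), 95)

  tr2 <- bootstrap_supports(msa, n_replicates = 200, seed = 99)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_supports(msa, n_replicates = 50, seed = 1)
  expect_s3_class(tr3, "phylo")
})

test_that("degenerate identical alignments are flagged unresolved", {
  msa <- setNames(rep("MKTAYIAKQRMKTAYIAKQR", 4), paste0("t", 1:4))
  tr <- bootstrap_supports(msa, n_replicates = 10, seed = 1)
  expect_true(attr(tr, "unresolved"))
})

test_that("assign_classes labels queries from the smallest unanimous clade", {
  tr <- ape::read.tree(
    text = "((q1:0.1,tau_ref:0.1):0.5,((phi_ref1:0.1,phi_ref2:0.1):0.2,q2:0.4):0.3,q3:0.9);")
  refs <- c(tau_ref = "tau", phi_ref1 = "phi", phi_ref2 = "phi")
  cls <- assign_classes(tr, refs)
  expect_equal(cls[["q1"]], "tau")   # sister to a single tau reference
  expect_equal(cls[["q2"]], "phi")   # inside the phi clade side
  # q3 hangs off the central node: its smallest surrounding unanimous side
  # is {q3, q1, tau_ref}
  expect_equal(cls[["q3"]], "tau")
  expect_error(assign_classes(tr, c(absent = "tau")), "reference")
})

test_that("queries whose every surrounding clade mixes classes stay unclassified", {
  tr <- ape::read.tree(
    text = "((tau1:1,phi1:1):1,q:1,(tau2:1,phi2:1):1);")
  refs <- c(tau1 = "tau", tau2 = "tau", phi1 = "phi", phi2 = "phi")
  cls <- assign_classes(tr, refs)
  expect_equal(cls[["q"]], "unclassified")
})

test_that("synthetic per-class families recover their generating class", {
  set.seed(23)
  mk_class <- function(prefix, n, k) {
    anc <- random_protein(150)
    jitter <- function(s) {
      res <- strsplit(s, "")[[1]]
      idx <- sample(length(res), k)
      res[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         length(idx), TRUE)
      paste(res, collapse = "")
    }
    setNames(vapply(1:n, function(i) jitter(anc), ""), paste0(prefix, 1:n))
  }
  msa <- c(mk_class("tauA", 6, 8), mk_class("phiB", 6, 8))
  refs <- c(tauA1 = "tau", tauA2 = "tau", phiB1 = "phi", phiB2 = "phi")
  tree <- nj_tree(p_distance_matrix(msa))
  cls <- assign_classes(tree, refs)
  truth <- ifelse(grepl("^tau", names(cls)), "tau", "phi")
  expect_gte(mean(cls == truth), 0.95)
})
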