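test_that("K2P distance handles identity, the closed form, and saturation", {
  s <- random_seq(80)
  r <- k2p_distance(s, s)
  expect_equal(r$distance, 0)
  expect_equal(c(r$P, r$Q), c(0, 0))

  # 200 sites: 20 transitions, 10 transversions -> P = 0.1, Q = 0.05
  a <- strrep("A", 200)
  b <- paste0(strrep("G", 20), strrep("C", 10), strrep("A", 170))
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$distance, 0.17018, tolerance = 1e-4)
  # independently recomputed closed form -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)
  expect_equal(r$distance, -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)

  # transversions at every site: correction diverges, flagged not thrown
  r <- k2p_distance(strrep("A", 50), strrep("C", 50))
  expect_true(r$saturated)
  expect_true(is.na(r$distance))

  # ambiguous sites are deleted pairwise; none left is an error
  r <- k2p_distance("ANGT", "ANGT")
  expect_equal(r$n_sites, 3)
  expect_error(k2p_distance("NNN", "ACG"), "no unambiguous sites")
  expect_error(k2p_distance("ACGT", "ACG"), "equal length")
})

test_that("K2P is symmetric and agrees with an independent K80 implementation", {
  # related sequences (5-20% divergence), well below saturation
  set.seed(61)
  anc <- strsplit(random_seq(300), "")[[1]]
  seqs <- stats::setNames(vapply(1:5, function(i) {
    s <- anc
    hit <- sample(300, 15 * i)
    s[hit] <- vapply(s[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(s, collapse = "")
  }, character(1)), paste0("t", 1:5))
  m <- k2p_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) {
    tolower(strsplit(s, "")[[1]])
  })))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(m), unname(ref[rownames(m), colnames(m)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("neighbor-joining recovers additive trees exactly", {
  true <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.15,D:0.25);")
  D <- stats::cophenetic(true)
  rec <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
               ignore_attr = TRUE)
  expect_equal(stats::cophenetic(rec)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # three taxa: the unique star resolution from the three-point formulas
  D3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(D3)
  bl <- stats::setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.1, B = 0.2, C = 0.3))

  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
  Dna <- D; Dna["A", "C"] <- Dna["C", "A"] <- NA
  expect_error(nj_tree(Dna), "distance undefined")
})

test_that("negative NJ branch lengths are clamped with compensation", {
  # a random non-additive matrix that produces a negative NJ branch
  set.seed(1)
  D <- matrix(0, 5, 5)
  D[upper.tri(D)] <- runif(10, 0.01, 1)
  D <- D + t(D)
  dimnames(D) <- list(letters[1:5], letters[1:5])
  raw <- ape::nj(D)
  tr <- nj_tree(D)
  expect_true(any(raw$edge.length < 0))
  expect_true(all(tr$edge.length >= 0))
  # total tree length is preserved by the compensation
  expect_equal(sum(tr$edge.length), sum(raw$edge.length))
})

test_that("bootstrap supports are seed-deterministic and reward diagnostic columns", {
  aln <- make_clade_alignment(seed = 3)
  bt <- bootstrap_tree(aln, replicates = 100, seed = 5)
  expect_identical(bt$node.label,
                   bootstrap_tree(aln, replicates = 100, seed = 5)$node.label)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  # the three bipartitions with 20-30 diagnostic columns are near-certain
  expect_gte(sum(sup >= 95, na.rm = TRUE), 3)
  # replicated over an independent seed
  bt2 <- bootstrap_tree(aln, replicates = 100, seed = 42)
  sup2 <- suppressWarnings(as.numeric(bt2$node.label))
  expect_gte(sum(sup2 >= 95, na.rm = TRUE), 3)

  # a single replicate can only give 0 or 100
  b1 <- bootstrap_tree(aln, replicates = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("newick output round-trips and keeps support labels after parentheses", {
  aln <- make_clade_alignment(seed = 13)
  bt <- bootstrap_tree(aln, replicates = 50, seed = 2)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, p)
  txt <- readLines(p)
  expect_match(txt, "\\)[0-9]")  # internal label directly after ')'
  back <- read_newick(p)
  expect_equal(ape::dist.topo(back, bt), 0, ignore_attr = TRUE)
  ed <- stats::setNames(bt$edge.length, bt$edge[, 2])
  expect_equal(sort(round(back$edge.length, 6)),
               sort(round(bt$edge.length, 6)))
})

test_that("rooting on an outgroup preserves all bipartitions", {
  aln <- make_clade_alignment(seed = 23)
  tr <- nj_tree(k2p_matrix(aln))
  rooted <- root_on_outgroup(tr, "b4")
  expect_true(ape::is.rooted(rooted))
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr), 0,
               ignore_attr = TRUE)
  expect_error(root_on_outgroup(tr, "zz"), "not in tree")
})
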