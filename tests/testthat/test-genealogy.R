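test_that("JC distance matrix matches the closed form and validates input", {
  base <- paste(rep("A", 1000), collapse = "")
  mut <- paste(c(rep("A", 900), rep("C", 100)), collapse = "")
  aln <- gene_alignment("g", c(x = base, y = mut, z = base),
                        coding_mask = rep(FALSE, 1000))
  d <- jc_distance_matrix(aln)
  expect_equal(diag(d), setNames(rep(0, 3), c("x", "y", "z")))
  expect_equal(d["x", "y"], jc_correct(0.1), tolerance = 1e-3)
  expect_equal(d["x", "z"], 0)
  expect_equal(d, t(d))

  two <- gene_alignment("g2", c(x = base, y = mut), rep(FALSE, 1000))
  expect_error(jc_distance_matrix(two), class = "tetmat_validation_error")

  # saturated pair: correction undefined, error names the pair
  sat <- gene_alignment("g3", c(
    x = paste(rep("A", 100), collapse = ""),
    y = paste(rep("C", 100), collapse = ""),
    z = paste(rep("A", 100), collapse = "")
  ), rep(FALSE, 100))
  expect_error(jc_distance_matrix(sat), regexp = "x.*y|y.*x",
               class = "tetmat_correction_error")
})

test_that("NJ reproduces additive trees exactly", {
  # fixed 4-taxon case: ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_gene_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr$phy), ape::unroot(truth))), 0)
  expect_equal(max(abs(stats::cophenetic(tr$phy)[rownames(d), colnames(d)] - d)), 0,
               tolerance = 1e-9)

  # three taxa: unique star resolution with exact closed-form lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_gene_tree(d3)
  expect_equal(stats::cophenetic(tr3$phy)[c("a", "b", "c"), c("a", "b", "c")], d3,
               tolerance = 1e-9)

  expect_error(nj_gene_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "tetmat_validation_error")
})

test_that("NJ recovers random additive topologies for n = 4..8 and matches
           exhaustive least squares on 5 taxa", {
  set.seed(99)
  for (n in 4:8) {
    for (rep in 1:3) {
      truth <- ape::rtree(n, rooted = FALSE,
                          br = function(k) runif(k, 0.1, 1))
      d <- stats::cophenetic(truth)
      tr <- nj_gene_tree(d)
      expect_equal(as.numeric(ape::dist.topo(tr$phy, truth)), 0)
      expect_equal(max(abs(stats::cophenetic(tr$phy)[rownames(d), colnames(d)] - d)),
                   0, tolerance = 1e-9)
    }
  }
  # 5-taxon: NJ equals the best of all 15 topologies under least squares
  for (rep in 1:3) {
    truth <- ape::rtree(5, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    d <- stats::cophenetic(truth)
    best <- oracle_ls_topology(d)
    expect_lt(best$ss, 1e-12)
    expect_equal(as.numeric(ape::dist.topo(nj_gene_tree(d)$phy, best$topology)), 0)
  }
})

test_that("bootstrap supports separate clearly diverged clades and are
           deterministic given the seed", {
  set.seed(5)
  L <- 1000
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  other <- evolve_gene(anc, time = 1, mu = 0.05, coding_mask = rep(FALSE, L))
  mk <- function(x) paste(evolve_gene(x, 1, 0.0005, coding_mask = rep(FALSE, L)),
                          collapse = "")
  aln <- gene_alignment("g", c(a1 = mk(anc), a2 = mk(anc), a3 = mk(anc),
                               b1 = mk(other), b2 = mk(other), b3 = mk(other)),
                        coding_mask = rep(FALSE, L))
  tr <- bootstrap_supports(aln, reps = 200, seed = 11)
  key_split <- tetmat:::tree_bipartitions(tr$phy)
  split_node <- as.integer(names(key_split)[key_split == "b1|b2|b3"])
  expect_gte(tr$supports$bootstrap[tr$supports$node %in% split_node][1], 95)

  tr2 <- bootstrap_supports(aln, reps = 200, seed = 11)
  expect_identical(tr$supports, tr2$supports)

  # identical sequences: no branch can reach the threshold
  same <- gene_alignment("g2", c(x = mk(anc), y = mk(anc), z = mk(anc),
                                 w = mk(anc))[c(1, 1, 1, 1)] |>
                           setNames(c("x", "y", "z", "w")),
                         coding_mask = rep(FALSE, L))
  trs <- bootstrap_supports(same, reps = 50, seed = 2)
  expect_true(all(is.na(trs$supports$bootstrap) | trs$supports$bootstrap == 0))
})

test_that("bipartition keys are invariant to rerooting and rotation", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  t2 <- ape::root(t1, outgroup = "d", resolve.root = FALSE)
  t3 <- ape::rotateConstr(t1, rev(t1$tip.label))
  # a rooted input duplicates the root bipartition; compare the unique sets
  k1 <- sort(unique(unname(tetmat:::tree_bipartitions(t1))))
  expect_equal(sort(unique(unname(tetmat:::tree_bipartitions(ape::unroot(t2))))), k1)
  expect_equal(sort(unique(unname(tetmat:::tree_bipartitions(t3)))), k1)
})

test_that("pair phase distinguishes together, separated and unresolved", {
  th <- support_thresholds()
  tog <- read_supported_tree(
    text = "((L4A:0.0,L4a:0.0)100:0.1,(X:0.1,Y:0.1):0.05);")
  call <- pair_phase(tog, "L4", "L4A", "L4a", th)
  expect_equal(call$phase, "together")
  expect_false(call$separation_supported)

  sep <- read_supported_tree(
    text = "((L4A:0.01,L3A:0.01)95:0.05,(L4a:0.01,L3a:0.01)90:0.05);")
  call <- pair_phase(sep, "L4", "L4A", "L4a", th)
  expect_equal(call$phase, "separated")
  expect_true(call$separation_supported)
  expect_gte(call$max_support_on_path, 90)

  # separated alleles but no supported branch and a long path: unresolved
  unres <- read_supported_tree(
    text = "((L4A:0.05,L3A:0.05)40:0.02,(L4a:0.05,L3a:0.05)30:0.02);")
  expect_equal(pair_phase(unres, "L4", "L4A", "L4a", th)$phase, "unresolved")

  # missing leaf: unresolved
  expect_equal(pair_phase(tog, "L9", "L9A", "L9a", th)$phase, "unresolved")

  # posterior supports work through the OR rule
  pp <- read_supported_tree(
    text = "((L4A:0.01,L3A:0.01)0.99:0.05,(L4a:0.01,L3a:0.01)0.5:0.05);")
  expect_equal(pair_phase(pp, "L4", "L4A", "L4a", th)$phase, "separated")
})

test_that("pair phase is invariant to rerooting", {
  th <- support_thresholds()
  base <- read_supported_tree(
    text = "((L4A:0.01,L3A:0.01)95:0.05,((L4a:0.01,L3a:0.01)90:0.05,(X:0.02,Y:0.02)80:0.03)60:0.01);")
  call1 <- pair_phase(base, "L4", "L4A", "L4a", th)
  for (og in c("X", "L3A", "L4a")) {
    re <- ape::root(base$phy, outgroup = og, resolve.root = FALSE)
    # reattach supports by bipartition identity after rerooting
    re_tree <- supported_tree(re, gene = base$gene, supports = {
      keys_re <- tetmat:::tree_bipartitions(re)
      keys_b <- tetmat:::tree_bipartitions(base$phy)
      sup <- tibble::tibble(node = ape::Ntip(re) + seq_len(re$Nnode),
                            bootstrap = NA_real_, posterior = NA_real_)
      for (i in seq_along(keys_re)) {
        m <- which(keys_b == keys_re[i])
        if (length(m) == 1) {
          src <- base$supports[base$supports$node == as.integer(names(keys_b)[m]), ]
          node <- as.integer(names(keys_re)[i])
          sup$bootstrap[sup$node == node] <- src$bootstrap
          sup$posterior[sup$node == node] <- src$posterior
        }
      }
      sup
    })
    call2 <- pair_phase(re_tree, "L4", "L4A", "L4a", th)
    expect_equal(call2$phase, call1$phase)
    expect_equal(call2$separation_supported, call1$separation_supported)
    expect_equal(call2$patristic, call1$patristic, tolerance = 1e-9)
  }
})

test_that("phase matrix covers every gene and pair and flags missing trees", {
  sim <- study_sim()
  res <- study_pipeline()
  ph <- res$phases
  expect_equal(nrow(ph), 24L * 10L)
  expect_setequal(unique(ph$phase), c("together", "separated", "unresolved"))

  # flank genes: alleles cluster by lineage, never separated by mating type
  flank <- ph[ph$gene %in% c("ro-10", "nit-2", "krev-1", "sod-1",
                             "os-1", "prd-4", "arg-13", "phr"), ]
  expect_true(all(flank$phase == "together"))

  # converted cells called together
  expect_equal(ph$phase[ph$gene == "lys-4" & ph$pair_id == "L4"], "together")

  # a gene without a tree is unresolved across pairs
  trees <- res$trees
  trees[["ro-10"]] <- NULL
  ph2 <- phase_matrix(trees, sim$manifest, sim$layout,
                      res$params$thresholds)
  expect_true(all(ph2$phase[ph2$gene == "ro-10"] == "unresolved"))
})
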