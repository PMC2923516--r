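test_that("sequence evolution respects its degenerate limits", {
  set.seed(31)
  L <- 300
  anc <- paste(tetmat:::random_root_sequence(L, 0), collapse = "")
  expect_identical(evolve_gene(anc, time = 5, mu = 0), anc)
  expect_identical(evolve_gene(anc, time = 0, mu = 0.01), anc)

  # omega = 0: all accepted coding changes are synonymous
  dec <- evolve_gene(anc, time = 50, mu = 0.01, omega = 0)
  got <- ng86_pairwise(anc, dec)
  expect_equal(got$Nd, 0)
  expect_gt(got$Sd, 0)

  # evolved coding sequences never contain stop codons
  cods <- tetmat:::split_codons(dec)
  expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
})

test_that("neutral noncoding divergence matches the JC expectation", {
  set.seed(77)
  L <- 10000L
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mu_t <- 0.02
  dec <- evolve_gene(anc, time = 1, mu = mu_t, coding_mask = rep(FALSE, L))
  p_obs <- mean(anc != dec)
  # JC: expected difference proportion = 3/4 (1 - exp(-4/3 mu t))
  p_exp <- 0.75 * (1 - exp(-4 / 3 * mu_t))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
})

test_that("simulated datasets are deterministic and structurally faithful", {
  sim <- study_sim()
  expect_equal(length(sim$alignments), 24L)
  expect_equal(nrow(sim$truth$conversions), 8L)
  expect_equal(nrow(sim$truth$crossovers), 1L)

  # same seed: byte-identical FASTA; different seed: different data
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_sim_dataset(sim, dir1)
  write_sim_dataset(simulate_dataset(sim_config(seed = 1L)), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
  other <- simulate_dataset(sim_config(seed = 2L))
  expect_false(identical(other$alignments[["un-3"]]$seqs,
                         sim$alignments[["un-3"]]$seqs))

  # whole-gene conversion: the pair's alleles are identical at that gene
  lys4 <- sim$alignments[["lys-4"]]
  expect_identical(lys4$seqs[["L4A"]], lys4$seqs[["L4a"]])

  # ancestral conversion: converted alleles identical across the clade
  cys5 <- sim$alignments[["cys-5"]]
  expect_identical(cys5$seqs[["L5A"]], cys5$seqs[["L6A"]])
  expect_identical(cys5$seqs[["L5a"]], cys5$seqs[["L6a"]])
  expect_identical(cys5$seqs[["L5A"]], cys5$seqs[["L5a"]])

  # partial tract: residual differences confined to the unconverted suffix
  ser3 <- sim$alignments[["ser-3"]]
  L <- nchar(ser3$seqs[["L4A"]])
  tract <- seq_len(round(0.95 * L))
  a <- strsplit(ser3$seqs[["L4A"]], "")[[1]]
  b <- strsplit(ser3$seqs[["L4a"]], "")[[1]]
  expect_identical(a[tract], b[tract])

  # crossover: alleles right of the interval swap chromosome linkage, so
  # L4A matches the other pairs' a-alleles more closely than their A-alleles
  # at cys-9 (averaged over pairs to damp per-pair Poisson noise)
  cys9 <- sim$alignments[["cys-9"]]
  x <- strsplit(cys9$seqs[["L4A"]], "")[[1]]
  others <- setdiff(unique(sim$manifest$pair_id), "L4")
  pt <- tetmat:::pair_table(sim$manifest)
  d_to_a <- mean(vapply(others, function(p) {
    sum(x != strsplit(cys9$seqs[[pt$strain_a[pt$pair_id == p]]], "")[[1]])
  }, numeric(1)))
  d_to_A <- mean(vapply(others, function(p) {
    sum(x != strsplit(cys9$seqs[[pt$strain_A[pt$pair_id == p]]], "")[[1]])
  }, numeric(1)))
  expect_lt(d_to_a, d_to_A)
})

test_that("infeasible plans are rejected", {
  expect_error(sim_config(conversions = tibble::tibble(
    gene = "lys-4", scope = "anc56", time = 1.0, template = "a", tract = 1
  )), class = "tetmat_config_error")
  expect_error(sim_config(conversions = tibble::tibble(
    gene = "nope", scope = "L4", time = 1.0, template = "a", tract = 1
  )), class = "tetmat_config_error")
  expect_error(sim_config(conversions = tibble::tibble(
    gene = "lys-4", scope = "L4", time = 1.0, template = "a", tract = 0
  )), class = "tetmat_config_error")
  expect_error(sim_config(crossovers = tibble::tibble(
    pair_id = "L4", left_gene = "upr-1", right_gene = "arg-1", time = 1.0
  )), class = "tetmat_config_error")
  expect_error(sim_config(duplication_age = 4.0), class = "tetmat_config_error")
})

test_that("planted suppression spans are recovered by demarcation whenever
           every span gene is sufficiently diverged", {
  sim <- study_sim()
  div <- divergence_table(sim$alignments, sim$manifest, sim$layout)
  maps <- suppression_maps(classify_allele_pairs(div), sim$layout)
  truth <- sim$truth$spans
  conv_genes <- split(
    strsplit(sim$truth$conversions$pairs, ","),
    sim$truth$conversions$gene
  )
  for (i in seq_len(nrow(truth))) {
    p <- truth$pair_id[i]
    span_genes <- {
      lo <- match(truth$start_gene[i], sim$layout$gene)
      hi <- match(truth$end_gene[i], sim$layout$gene)
      sim$layout$gene[lo:hi]
    }
    boundary <- c(truth$start_gene[i], truth$end_gene[i])
    ok <- vapply(boundary, function(g) {
      div$raw_diffs[div$gene == g & div$pair_id == p] >= 2
    }, logical(1))
    if (all(ok)) {
      expect_equal(maps[[p]]$region_start_gene, truth$start_gene[i], info = p)
      expect_equal(maps[[p]]$region_end_gene, truth$end_gene[i], info = p)
    }
  }
})

test_that("with empty event plans and clear divergence, conversion detection
           stays quiet inside the span (false-positive control)", {
  empty_cv <- tibble::tibble(gene = character(0), scope = character(0),
                             time = numeric(0), template = character(0),
                             tract = numeric(0))
  empty_xo <- tibble::tibble(pair_id = character(0), left_gene = character(0),
                             right_gene = character(0), time = numeric(0))
  clean_seeds <- 0L
  for (seed in 1:20) {
    res <- suppressMessages(run_pipeline(
      sim_config("clear", seed = seed, conversions = empty_cv,
                 crossovers = empty_xo, outcross_snp_rate = 0),
      thresholds = support_thresholds(bootstrap_reps = 100L, seed = seed)
    ))
    inside <- sum(res$merged$in_region)
    if (inside == 0L) clean_seeds <- clean_seeds + 1L
  }
  expect_gte(clean_seeds, 19L)
})
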