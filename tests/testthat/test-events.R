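test_that("the three-genealogy window rule fires only on supported
           separated-together-separated patterns", {
  lay <- toy_layout(5)
  maps <- list(P1 = demarcate_region(
    tibble::tibble(gene = lay$gene,
                   class = c("homoallelic", "diverged", "homoallelic",
                             "diverged", "homoallelic")), lay, "P1"))
  ph <- dplyr::bind_rows(
    phase_row("P1", "g1", 0, "together"),
    phase_row("P1", "g2", 1, "separated", supported = TRUE),
    phase_row("P1", "g3", 2, "together"),
    phase_row("P1", "g4", 3, "separated", supported = FALSE),
    phase_row("P1", "g5", 4, "together")
  )
  ev <- detect_conversions(ph, maps, lay)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "g3")
  expect_equal(ev$left_gene, "g2")
  expect_true(ev$left_supported)
  expect_true(ev$in_region)
  # terminal together genes (g1, g5) never yield events

  # neither flank supported: no event
  ph2 <- dplyr::mutate(ph, separation_supported = FALSE)
  expect_equal(nrow(detect_conversions(ph2, maps, lay)), 0L)

  # all separated: no event
  ph3 <- dplyr::mutate(ph, phase = "separated", separation_supported = TRUE)
  expect_equal(nrow(detect_conversions(ph3, maps, lay)), 0L)

  # no 'together' cell anywhere: nothing
  expect_equal(nrow(detect_conversions(ph3, maps, lay, strict = TRUE)), 0L)
})

test_that("unresolved neighbours extend the window unless strict", {
  lay <- toy_layout(5)
  maps <- list(P1 = demarcate_region(
    tibble::tibble(gene = lay$gene, class = rep("diverged", 5)), lay, "P1"))
  ph <- dplyr::bind_rows(
    phase_row("P1", "g1", 0, "separated", supported = TRUE),
    phase_row("P1", "g2", 1, "unresolved"),
    phase_row("P1", "g3", 2, "together"),
    phase_row("P1", "g4", 3, "separated", supported = TRUE),
    phase_row("P1", "g5", 4, "separated", supported = TRUE)
  )
  ev <- detect_conversions(ph, maps, lay)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left_gene, "g1")
  expect_equal(nrow(detect_conversions(ph, maps, lay, strict = TRUE)), 0L)
})

test_that("emitted events satisfy the evidence invariant structurally", {
  res <- study_pipeline()
  ev <- res$conversions
  expect_gt(nrow(ev), 0)
  ph <- res$phases
  for (i in seq_len(nrow(ev))) {
    focal <- ph[ph$gene == ev$gene[i] & ph$pair_id == ev$pair_id[i], ]
    left <- ph[ph$gene == ev$left_gene[i] & ph$pair_id == ev$pair_id[i], ]
    right <- ph[ph$gene == ev$right_gene[i] & ph$pair_id == ev$pair_id[i], ]
    expect_equal(focal$phase, "together")
    expect_equal(left$phase, "separated")
    expect_equal(right$phase, "separated")
    expect_true(left$separation_supported || right$separation_supported)
  }
})

test_that("template direction follows the nesting clade's mating type", {
  man <- toy_manifest(4)
  th <- support_thresholds()
  a_nested <- read_supported_tree(
    text = "(((P1A:0,P1a:0)100:0.01,P2a:0.01,P3a:0.01)100:0.05,(P2A:0.01,P3A:0.01)100:0.05,P4A:0.02,P4a:0.02);")
  expect_equal(infer_template_direction(a_nested, "P1", man, th), "mat_a")

  A_nested <- read_supported_tree(
    text = "(((P1A:0,P1a:0)100:0.01,P2A:0.01,P3A:0.01)100:0.05,(P2a:0.01,P3a:0.01)100:0.05,P4A:0.02,P4a:0.02);")
  expect_equal(infer_template_direction(A_nested, "P1", man, th), "mat_A")

  mixed <- read_supported_tree(
    text = "(((P1A:0,P1a:0)100:0.01,P2a:0.01,P3A:0.01)100:0.05,(P2A:0.01,P3a:0.01)100:0.05,P4A:0.02,P4a:0.02);")
  expect_equal(infer_template_direction(mixed, "P1", man, th), "unknown")

  # excluded pairs (co-converted at the gene) are ignored as context
  expect_equal(infer_template_direction(mixed, "P1", man, th,
                                        exclude_pairs = c("P1", "P3")),
               "mat_a")
})

test_that("ancestral merging requires identical converted alleles", {
  man <- toy_manifest(4)
  lay <- toy_layout(3)
  base <- paste(rep("ATGGCTAAA", 10), collapse = "")
  variant <- sub("AAA$", "AAG", base)
  # P1 and P2 carry identical converted alleles; P3's differs
  aln <- gene_alignment("g2", c(
    P1A = base, P1a = base, P2A = base, P2a = base,
    P3A = variant, P3a = variant, P4A = base, P4a = base
  ))
  ev <- tibble::tibble(
    gene = "g2", pair_id = c("P1", "P2", "P3"),
    left_gene = "g1", right_gene = "g3",
    left_supported = TRUE, right_supported = TRUE, in_region = TRUE,
    template = c("mat_a", "mat_a", "mat_a")
  )
  merged <- merge_ancestral_events(ev, list(g2 = aln), man)
  expect_equal(nrow(merged), 2L)
  anc <- merged[merged$n_pairs == 2, ]
  expect_equal(anc$pairs, "P1,P2")
  expect_equal(anc$lineages, "1,2")
  expect_true(anc$ancestral)
  expect_false(merged$ancestral[merged$pairs == "P3"])

  # with a one-SNP tolerance the nearly identical allele joins the event
  merged2 <- merge_ancestral_events(ev, list(g2 = aln), man, max_diffs = 1L)
  expect_equal(nrow(merged2), 1L)
  expect_equal(merged2$pairs, "P1,P2,P3")

  # single-pair events pass through unchanged
  single <- merge_ancestral_events(ev[2, ], list(g2 = aln), man)
  expect_equal(nrow(single), 1L)
  expect_false(single$ancestral)
})

test_that("crossovers are called at persistent affiliation swaps", {
  man <- toy_manifest(3)
  lay <- toy_layout(4)
  th <- support_thresholds()
  normal <- "((P1A:0.01,P2A:0.01,P3A:0.01)100:0.05,(P1a:0.01,P2a:0.01,P3a:0.01)100:0.05);"
  swapped <- "((P1A:0.01,P2A:0.01,P3a:0.01)100:0.05,(P1a:0.01,P2a:0.01,P3A:0.01)100:0.05);"
  mk <- function(txt, g) read_supported_tree(text = txt, gene = g)
  trees <- list(g1 = mk(normal, "g1"), g2 = mk(normal, "g2"),
                g3 = mk(swapped, "g3"), g4 = mk(swapped, "g4"))
  xo <- detect_crossovers(trees, man, lay, th, persistence = 2L)
  expect_equal(nrow(xo), 1L)
  expect_equal(xo$pair_id, "P3")
  expect_equal(xo$left_gene, "g2")
  expect_equal(xo$right_gene, "g3")
  expect_equal(xo$state_after, "swapped")

  # no affiliation changes anywhere: empty
  all_norm <- list(g1 = mk(normal, "g1"), g2 = mk(normal, "g2"),
                   g3 = mk(normal, "g3"), g4 = mk(normal, "g4"))
  expect_equal(nrow(detect_crossovers(all_norm, man, lay, th)), 0L)

  # a single-gene blip does not qualify on either side
  blip <- list(g1 = mk(normal, "g1"), g2 = mk(swapped, "g2"),
               g3 = mk(normal, "g3"), g4 = mk(normal, "g4"))
  expect_equal(nrow(detect_crossovers(blip, man, lay, th, persistence = 2L)), 0L)
})

test_that("homogenization rate implements r = K/(2T) with its domain", {
  r1 <- homogenization_rate(1, 9, 4.6)
  expect_equal(r1$r_rounded, 0.012)
  expect_equal(r1$K, 1 / 9)
  expect_equal(homogenization_rate(0, 9, 4.6)$r, 0)
  expect_equal(homogenization_rate(2, 10, 5.0)$r_rounded, 0.020)
  expect_error(homogenization_rate(1, 0, 4.6), class = "tetmat_domain_error")
  expect_error(homogenization_rate(1, 9, 0), class = "tetmat_domain_error")
  expect_error(homogenization_rate(-1, 9, 4.6), class = "tetmat_domain_error")

  # linear in the event count, inversely proportional to T
  for (k in 1:5) {
    expect_equal(homogenization_rate(k, 9, 4.6)$r,
                 k * homogenization_rate(1, 9, 4.6)$r, tolerance = 1e-12)
    expect_equal(homogenization_rate(k, 9, 9.2)$r,
                 homogenization_rate(k, 9, 4.6)$r / 2, tolerance = 1e-12)
  }
})

test_that("rate table reports both event-counting conventions", {
  merged <- tibble::tibble(
    event_id = 1:3, gene = c("gA", "gA", "gB"),
    pairs = c("P1", "P2,P3", "P1"), lineages = c("1", "2,3", "1"),
    n_pairs = c(1L, 2L, 1L), ancestral = c(FALSE, TRUE, FALSE),
    template = "unknown", in_region = c(TRUE, TRUE, FALSE)
  )
  rt <- rate_table(merged, n_lineages = 9, T = 4.6)
  expect_equal(nrow(rt), 1L)  # gB outside the span is excluded
  expect_equal(rt$events, 2L)
  expect_equal(rt$events_per_pair, 3L)
  expect_equal(rt$r_per_event, (2 / 9) / (2 * 4.6))
  rt_all <- rate_table(merged, 9, 4.6, inside_region_only = FALSE)
  expect_equal(nrow(rt_all), 2L)
})
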