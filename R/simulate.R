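# Forward-time simulator for mat-chromosome datasets: lineage divergence on a
# dated species tree, a recombinationally suppressed central span in which the
# two mating-type haplotypes diverge since a duplication (cessation) event,
# homoallelic recombining flanks, planted gene conversions (pair-level and
# ancestral, whole-gene or partial tract), planted crossovers, and rare
# single-SNP outcrossing polymorphisms on recombining genes.

#' Default dated lineage tree of the species complex
#'
#' A star radiation at 4.6 MY with three resolved clades: lineages 3 and 8
#' split at 2.5 MY (the two lineage-8 pairs at 1.0 MY) and lineages 5 and 6
#' split at 2.5 MY. Internal nodes are named (`anc38`, `anc8`, `anc56`) so
#' ancestral conversion events can be planted on them.
#'
#' @param radiation_age Root age in million years.
#' @return A nested-list tree: each node is `list(name, age, children)`.
#' @export
sim_lineage_tree_default <- function(radiation_age = 4.6) {
  leaf <- function(p) list(name = p, age = 0, children = list())
  list(
    name = "root", age = radiation_age,
    children = list(
      leaf("L1"), leaf("L2"), leaf("L4"), leaf("L7"), leaf("L9"),
      list(name = "anc38", age = 2.5, children = list(
        leaf("L3"),
        list(name = "anc8", age = 1.0, children = list(leaf("L8(1)"), leaf("L8(2)")))
      )),
      list(name = "anc56", age = 2.5, children = list(leaf("L5"), leaf("L6")))
    )
  )
}

tree_node_names <- function(node) {
  c(node$name, unlist(purrr::map(node$children, tree_node_names)))
}

tree_leaf_names <- function(node) {
  if (length(node$children) == 0) return(node$name)
  unlist(purrr::map(node$children, tree_leaf_names))
}

# name -> character vector of names in that node's subtree (incl. itself)
tree_subtrees <- function(node) {
  out <- list()
  walk <- function(nd) {
    for (ch in nd$children) walk(ch)
    out[[nd$name]] <<- tree_node_names(nd)
  }
  walk(node)
  out
}

# parent age of each node
tree_parent_ages <- function(node) {
  out <- c()
  walk <- function(nd) {
    for (ch in nd$children) {
      out[ch$name] <<- nd$age
      walk(ch)
    }
  }
  walk(node)
  out
}

default_ds_targets <- function(genes) {
  targets <- c(
    "ro-10" = 0.03, "nit-2" = 0.03, "krev-1" = 0.03, "sod-1" = 0.03,
    "mus-42" = 0.02, "rid" = 0.03, "leu-4" = 0.025, "cys-5" = 0.03,
    "ser-3" = 0.04, "tef-1" = 0.025, "un-3" = 0.04, "upr-1" = 0.055,
    "erg-8" = 0.06, "arg-1" = 0.045, "eth-1" = 0.03, "lys-4" = 0.05,
    "cys-9" = 0.06, "ad-9" = 0.06, "al-1" = 0.06, "lys-3" = 0.05,
    "os-1" = 0.03, "prd-4" = 0.03, "arg-13" = 0.03, "phr" = 0.03
  )
  out <- targets[genes]
  out[is.na(out)] <- 0.03
  setNames(out, genes)
}

default_spans <- function(pairs) {
  spans <- purrr::map(pairs, function(p) {
    switch(p,
           "L4" = c("rid", "al-1"),
           "L9" = c("mus-42", "lys-3"),
           c("leu-4", "lys-3"))
  })
  setNames(spans, pairs)
}

default_conversion_plan <- function() {
  tibble(
    gene = c("cys-5", "ser-3", "ser-3", "ser-3", "ser-3", "arg-1", "lys-4", "ad-9"),
    scope = c("anc56", "anc38", "L2", "L4", "L7", "L3", "L4", "anc8"),
    time = c(2.8, 2.8, 0.5, 0.5, 0.5, 2.0, 0.5, 1.2),
    template = c("a", "a", "A", "a", "A", "A", "a", "a"),
    tract = c(1, 1, 1, 0.95, 0.95, 1, 1, 1)
  )
}

default_crossover_plan <- function() {
  tibble(pair_id = "L4", left_gene = "upr-1", right_gene = "erg-8", time = 1.0)
}

#' Simulation configuration
#'
#' The `"study"` preset emulates the surveyed species complex: the reference
#' layout (24 genes, Table-like coding/intron lengths), 10 pairs over 9
#' lineages, recombination cessation (haplotype duplication) at 5.5 MY,
#' radiation at 4.6 MY, per-gene mutation rates calibrated so allelic dS falls
#' in the observed 0.02-0.06 range, 8 planted conversions (two ancestral, two
#' partial-tract) and one planted crossover between *upr-1* and *erg-8* in
#' pair L4. The `"clear"` preset keeps the same design but gives every gene
#' 1200 coding + 300 intron bp and allelic dS ~0.05, a high-signal regime for
#' event-recovery experiments.
#'
#' @param preset `"study"` or `"clear"`.
#' @param seed RNG seed; the whole dataset is a deterministic function of the
#'   configuration and this seed.
#' @param layout,manifest Layout/manifest tibbles (defaults: packaged
#'   reference versions).
#' @param lineage_tree Dated lineage tree (see [sim_lineage_tree_default()]).
#' @param duplication_age Age (MY) of recombination cessation for ancestral
#'   strata genes; must exceed the tree root age.
#' @param ds_targets Named per-gene target allelic dS used to set mutation
#'   rates (`mu = ds_target / (2 * duplication_age)`).
#' @param omega Acceptance probability of proposed nonsynonymous changes
#'   (purifying selection scaling, <= 1).
#' @param spans Named list `pair_id -> c(start_gene, end_gene)` of the true
#'   suppressed span per pair (`NULL` entry = no suppression).
#' @param strata Tibble `pair_id, gene, time` of lineage-specific cessation
#'   times overriding the ancestral duplication for individual cells.
#' @param conversions Conversion plan: tibble `gene, scope` (pair id or
#'   ancestral node name), `time`, `template` (`"A"`/`"a"`, the allele-clade
#'   used as donor), `tract` (fraction in (0,1], 1 = whole gene).
#' @param crossovers Crossover plan: tibble `pair_id, left_gene, right_gene,
#'   time` (interval genes must be adjacent in the layout).
#' @param outcross_snp_rate Probability that a recombining (pair, gene) cell
#'   carries one planted SNP.
#' @return A list of class `tet_sim_config`.
#' @export
sim_config <- function(preset = c("study", "clear"), seed = 1L,
                       layout = tetrasperma_layout(),
                       manifest = tetrasperma_strains(),
                       lineage_tree = sim_lineage_tree_default(),
                       duplication_age = 5.5,
                       ds_targets = NULL,
                       omega = 0.05,
                       spans = NULL,
                       strata = NULL,
                       conversions = default_conversion_plan(),
                       crossovers = default_crossover_plan(),
                       outcross_snp_rate = 0.06) {
  preset <- match.arg(preset)
  if (preset == "clear") {
    layout$coding_bp <- 1200L
    layout$intron_bp <- 300L
    if (is.null(ds_targets)) {
      ds_targets <- setNames(ifelse(layout$region_hint == "central", 0.05, 0.03),
                             layout$gene)
    }
  }
  if (is.null(ds_targets)) ds_targets <- default_ds_targets(layout$gene)
  pairs <- pair_table(manifest)
  if (is.null(spans)) spans <- default_spans(pairs$pair_id)
  if (is.null(strata)) {
    strata <- tibble(pair_id = c("L4", "L9", "L9"),
                     gene = c("rid", "mus-42", "rid"),
                     time = c(3.0, 3.0, 3.0))
  }
  cfg <- list(
    preset = preset, seed = as.integer(seed), layout = layout,
    manifest = manifest, lineage_tree = lineage_tree,
    duplication_age = duplication_age,
    mu = ds_targets[layout$gene] / (2 * duplication_age),
    omega = omega, spans = spans, strata = strata,
    conversions = conversions, crossovers = crossovers,
    outcross_snp_rate = outcross_snp_rate
  )
  class(cfg) <- "tet_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pairs <- pair_table(cfg$manifest)
  leaves <- tree_leaf_names(cfg$lineage_tree)
  if (!setequal(leaves, pairs$pair_id)) {
    stop_tetmat("lineage tree leaves must be the manifest's pair ids",
                "tetmat_config_error")
  }
  if (cfg$duplication_age <= cfg$lineage_tree$age) {
    stop_tetmat("duplication_age must exceed the lineage tree root age",
                "tetmat_config_error")
  }
  node_names <- tree_node_names(cfg$lineage_tree)
  parent_age <- tree_parent_ages(cfg$lineage_tree)
  node_age <- c()
  walk <- function(nd) { node_age[nd$name] <<- nd$age; for (ch in nd$children) walk(ch) }
  walk(cfg$lineage_tree)
  cv <- cfg$conversions
  if (nrow(cv) > 0) {
    if (!all(cv$gene %in% cfg$layout$gene)) {
      stop_tetmat("conversion plan names a gene absent from the layout",
                  "tetmat_config_error")
    }
    if (!all(cv$scope %in% node_names)) {
      stop_tetmat("conversion scope must be a pair id or lineage-tree node name",
                  "tetmat_config_error")
    }
    if (any(cv$tract <= 0 | cv$tract > 1)) {
      stop_tetmat("conversion tract fractions must lie in (0, 1]", "tetmat_config_error")
    }
    for (i in seq_len(nrow(cv))) {
      sc <- cv$scope[i]
      if (sc %in% leaves) {
        if (cv$time[i] < 0 || cv$time[i] > parent_age[sc]) {
          stop_tetmat(sprintf(
            "infeasible conversion at %s: time %.2f outside the pair's branch",
            cv$gene[i], cv$time[i]), "tetmat_config_error")
        }
      } else {
        if (cv$time[i] < node_age[sc] || cv$time[i] > cfg$duplication_age) {
          stop_tetmat(sprintf(
            "infeasible ancestral conversion at %s: time %.2f is younger than node %s",
            cv$gene[i], cv$time[i], sc), "tetmat_config_error")
        }
      }
    }
  }
  co <- cfg$crossovers
  if (nrow(co) > 0) {
    if (!all(co$pair_id %in% pairs$pair_id)) {
      stop_tetmat("crossover plan names an unknown pair", "tetmat_config_error")
    }
    for (i in seq_len(nrow(co))) {
      lo <- match(co$left_gene[i], cfg$layout$gene)
      ro <- match(co$right_gene[i], cfg$layout$gene)
      if (is.na(lo) || is.na(ro) || ro != lo + 1L) {
        stop_tetmat("crossover interval genes must be adjacent layout genes",
                    "tetmat_config_error")
      }
    }
  }
  invisible(cfg)
}

nonstop_codons <- function() {
  if (is.null(.tetmat$nonstop)) {
    code <- genetic_code()
    .tetmat$nonstop <- names(code)[code != "*"]
  }
  .tetmat$nonstop
}

#' Evolve a sequence forward in time
#'
#' Neutral Jukes-Cantor mutation with purifying scaling on coding changes:
#' every site draws a Poisson(`mu * time`) number of mutation events, each
#' proposing one of the three alternative bases with equal probability.
#' Noncoding proposals are always accepted; coding proposals are accepted
#' with probability 1 when synonymous and `omega` when nonsynonymous, and
#' proposals creating a stop codon are rejected (the reading frame is kept
#' intact).
#'
#' @param seq A sequence string (or character vector of single bases).
#' @param time Elapsed time (million years).
#' @param mu Mutation rate per site per million years.
#' @param omega Acceptance probability for nonsynonymous changes.
#' @param coding_mask Logical per-column coding flag (default: all coding).
#'   Coding columns are assumed in frame from their first column.
#' @return The descendant sequence, same type as the input. Uses the current
#'   RNG state; seed externally for reproducibility.
#' @export
evolve_gene <- function(seq, time, mu, omega = 1, coding_mask = NULL) {
  as_string <- length(seq) == 1L && nchar(seq[1]) > 1L
  x <- if (as_string) strsplit(seq, "")[[1]] else seq
  L <- length(x)
  if (is.null(coding_mask)) coding_mask <- rep(TRUE, L)
  if (time < 0 || mu < 0) stop_tetmat("time and mu must be non-negative", "tetmat_config_error")
  n_events <- rpois(L, mu * time)
  hit <- which(n_events > 0)
  if (length(hit) > 0) {
    coding_pos <- which(coding_mask)
    idx_in_coding <- match(seq_len(L), coding_pos)
    code <- genetic_code()
    for (site in hit) {
      for (k in seq_len(n_events[site])) {
        cur <- x[site]
        if (!cur %in% DNA_BASES) next
        prop <- sample(setdiff(DNA_BASES, cur), 1L)
        if (!coding_mask[site]) {
          x[site] <- prop
          next
        }
        ci <- (idx_in_coding[site] - 1L) %/% 3L
        cols <- coding_pos[(ci * 3L + 1L):(ci * 3L + 3L)]
        if (anyNA(cols) || !all(x[cols] %in% DNA_BASES)) next
        old_cod <- paste(x[cols], collapse = "")
        newx <- x[cols]
        newx[match(site, cols)] <- prop
        new_cod <- paste(newx, collapse = "")
        if (code[new_cod] == "*") next                  # keep ORF intact
        if (code[new_cod] == code[old_cod] || runif(1) < omega) {
          x[site] <- prop
        }
      }
    }
  }
  if (as_string) paste(x, collapse = "") else x
}

# random in-frame root sequence
random_root_sequence <- function(coding_len, intron_len) {
  cod <- sample(nonstop_codons(), coding_len %/% 3L, replace = TRUE)
  c(unlist(strsplit(cod, "")), sample(DNA_BASES, intron_len, replace = TRUE))
}

# cessation time of (pair, gene): Inf = ancestral (duplication), 0 = recombining
cessation_time <- function(cfg, pair, gene) {
  span <- cfg$spans[[pair]]
  if (is.null(span)) return(0)
  lo <- match(span[1], cfg$layout$gene)
  hi <- match(span[2], cfg$layout$gene)
  g <- match(gene, cfg$layout$gene)
  if (g < lo || g > hi) return(0)
  ov <- cfg$strata[cfg$strata$pair_id == pair & cfg$strata$gene == gene, ]
  if (nrow(ov) > 0) return(ov$time[1])
  Inf
}

# simulate one gene; returns list(alleles = list(pair -> list(A=, a=)),
# snapshots = env). Alleles are base-character vectors.
sim_gene_sequences <- function(cfg, gene) {
  lay <- cfg$layout[cfg$layout$gene == gene, ]
  L_cod <- lay$coding_bp %||% 900L
  L_int <- lay$intron_bp %||% 0L
  mask <- c(rep(TRUE, L_cod), rep(FALSE, L_int))
  mu <- cfg$mu[[gene]]
  omega <- cfg$omega
  pairs <- pair_table(cfg$manifest)
  tcs <- setNames(map_dbl(pairs$pair_id, function(p) cessation_time(cfg, p, gene)),
                  pairs$pair_id)
  duplicated_gene <- any(is.infinite(tcs))
  subtrees <- tree_subtrees(cfg$lineage_tree)
  root_age <- cfg$lineage_tree$age

  # snapshot requests: ancestral conversions at this gene need the template
  # haplotype's lineage sequence at the event time
  cv <- cfg$conversions[cfg$conversions$gene == gene, , drop = FALSE]
  if (nrow(cv) > 0) cv$cv_id <- seq_len(nrow(cv))
  anc_cv <- cv[!(cv$scope %in% pairs$pair_id), , drop = FALSE]
  snapshots <- new.env(parent = emptyenv())

  evolve_step <- function(x, dt) evolve_gene(x, dt, mu, omega, mask)

  alleles <- list()

  descend <- function(node, seq_par, age_par, hap) {
    # record snapshots requested on the branch age_par -> node$age for
    # lineages ancestral to anc_cv scopes
    if (nrow(anc_cv) > 0) {
      for (i in seq_len(nrow(anc_cv))) {
        t_e <- anc_cv$time[i]
        snap_hap <- if (duplicated_gene) anc_cv$template[i] else "A"
        if (snap_hap != hap) next
        if (!(anc_cv$scope[i] %in% subtrees[[node$name]])) next
        if (t_e < node$age || t_e >= age_par) next
        seq_par <- evolve_step(seq_par, age_par - t_e)
        age_par <- t_e
        assign(paste0("cv", anc_cv$cv_id[i]), seq_par, envir = snapshots)
      }
    }
    if (length(node$children) == 0) {
      p <- node$name
      tc <- tcs[[p]]
      if (is.finite(tc) && tc > 0 && tc < age_par && hap == "A") {
        s_tc <- evolve_step(seq_par, age_par - tc)
        alleles[[p]] <<- list(A = evolve_step(s_tc, tc), a = evolve_step(s_tc, tc))
      } else {
        tip <- evolve_step(seq_par, age_par - node$age)
        if (is.infinite(tc)) {
          if (is.null(alleles[[p]])) alleles[[p]] <<- list()
          alleles[[p]][[hap]] <<- tip
        } else if (hap == "A") {
          alleles[[p]] <<- list(A = tip, a = tip)
        }
      }
      return(invisible(NULL))
    }
    seq_here <- evolve_step(seq_par, age_par - node$age)
    for (ch in node$children) descend(ch, seq_here, node$age, hap)
  }

  root_seq <- random_root_sequence(L_cod, L_int)
  # evolve the pre-radiation stem per haplotype, snapshotting any ancestral
  # conversion whose event time falls on the stem itself
  evolve_stem <- function(hap) {
    s <- root_seq
    age <- cfg$duplication_age
    if (nrow(anc_cv) > 0) {
      for (i in order(-anc_cv$time)) {
        t_e <- anc_cv$time[i]
        snap_hap <- if (duplicated_gene) anc_cv$template[i] else "A"
        if (snap_hap != hap || t_e < root_age || t_e >= age) next
        s <- evolve_step(s, age - t_e)
        age <- t_e
        assign(paste0("cv", anc_cv$cv_id[i]), s, envir = snapshots)
      }
    }
    evolve_step(s, age - root_age)
  }
  if (duplicated_gene) {
    for (hap in c("A", "a")) {
      descend(cfg$lineage_tree, evolve_stem(hap), root_age, hap)
    }
  } else {
    descend(cfg$lineage_tree, evolve_stem("A"), root_age, "A")
  }

  # conversions: complete (or partial-prefix) homogenization at present day
  if (nrow(cv) > 0) {
    cv <- cv[order(-cv$time), , drop = FALSE]
    L <- L_cod + L_int
    for (i in seq_len(nrow(cv))) {
      tract <- seq_len(max(1L, round(cv$tract[i] * L)))
      sc <- cv$scope[i]
      if (sc %in% pairs$pair_id) {
        tmpl <- cv$template[i]
        other <- if (tmpl == "A") "a" else "A"
        donor <- alleles[[sc]][[tmpl]]
        rec <- alleles[[sc]][[other]]
        rec[tract] <- donor[tract]
        alleles[[sc]][[other]] <- rec
      } else {
        key <- paste0("cv", cv$cv_id[i])
        donor <- get(key, envir = snapshots)
        for (p in intersect(subtrees[[sc]], pairs$pair_id)) {
          for (h in c("A", "a")) {
            rec <- alleles[[p]][[h]]
            rec[tract] <- donor[tract]
            alleles[[p]][[h]] <- rec
          }
        }
      }
    }
  }

  # outcrossing: occasional single SNPs on recombining cells
  snp_log <- list()
  for (p in pairs$pair_id) {
    if (tcs[[p]] != 0) next
    if (runif(1) >= cfg$outcross_snp_rate) next
    site <- sample.int(L_cod + L_int, 1L)
    h <- sample(c("A", "a"), 1L)
    for (try in 1:10) {
      newb <- sample(setdiff(DNA_BASES, alleles[[p]][[h]][site]), 1L)
      x <- alleles[[p]][[h]]
      x[site] <- newb
      if (mask[site]) {
        ci <- (site - 1L) %/% 3L
        cols <- (ci * 3L + 1L):(ci * 3L + 3L)
        if (paste(x[cols], collapse = "") %in% STOP_CODONS) next
      }
      alleles[[p]][[h]] <- x
      snp_log[[length(snp_log) + 1L]] <- tibble(pair_id = p, gene = gene, site = site - 1L)
      break
    }
  }

  # crossovers: swap chromosome linkage right of the interval
  for (i in seq_len(nrow(cfg$crossovers))) {
    co <- cfg$crossovers[i, ]
    if (match(gene, cfg$layout$gene) >= match(co$right_gene, cfg$layout$gene)) {
      p <- co$pair_id
      alleles[[p]] <- list(A = alleles[[p]][["a"]], a = alleles[[p]][["A"]])
    }
  }

  list(alleles = alleles, mask = mask,
       snps = if (length(snp_log)) bind_rows(snp_log) else tibble())
}

#' Simulate a complete mat-chromosome dataset
#'
#' Runs the forward simulation for every layout gene and assembles per-gene
#' [gene_alignment()] objects (strain-labelled via the manifest) together with
#' a ground-truth table of the planted events. Byte-identical outputs are
#' guaranteed for identical configurations and seeds; per-gene seeds are
#' derived from the master seed by gene name, so changing one gene's plan
#' leaves the others' sequences untouched.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `tet_sim`: `alignments` (named list),
#'   `manifest`, `layout`, `truth` (list with `conversions`, `crossovers`,
#'   `spans`, `outcross_snps`), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "tet_sim_config"))
  pairs <- pair_table(cfg$manifest)
  strain_of <- function(p, chrom) {
    i <- match(p, pairs$pair_id)
    if (chrom == "A") pairs$strain_A[i] else pairs$strain_a[i]
  }
  alignments <- list()
  snps <- list()
  for (g in cfg$layout$gene) {
    res <- with_seed(derive_seed(cfg$seed, paste0("gene:", g)),
                     sim_gene_sequences(cfg, g))
    seqs <- character(0)
    for (p in pairs$pair_id) {
      seqs[strain_of(p, "A")] <- paste(res$alleles[[p]][["A"]], collapse = "")
      seqs[strain_of(p, "a")] <- paste(res$alleles[[p]][["a"]], collapse = "")
    }
    seqs <- seqs[cfg$manifest$strain_id]
    alignments[[g]] <- gene_alignment(g, seqs, coding_mask = res$mask)
    if (nrow(res$snps)) snps[[g]] <- res$snps
  }
  pair_ids <- pairs$pair_id
  subtrees <- tree_subtrees(cfg$lineage_tree)
  truth_conversions <- cfg$conversions
  truth_conversions$pairs <- map_chr(truth_conversions$scope, function(sc) {
    if (sc %in% pair_ids) sc else {
      paste(sort(intersect(subtrees[[sc]], pair_ids)), collapse = ",")
    }
  })
  truth_conversions$ancestral <- !(truth_conversions$scope %in% pair_ids)
  truth_conversions$template <- paste0("mat_", truth_conversions$template)
  truth_spans <- tibble(
    pair_id = pairs$pair_id,
    start_gene = map_chr(pairs$pair_id, function(p) cfg$spans[[p]][1] %||% NA_character_),
    end_gene = map_chr(pairs$pair_id, function(p) cfg$spans[[p]][2] %||% NA_character_)
  )
  out <- list(
    alignments = alignments, manifest = cfg$manifest, layout = cfg$layout,
    truth = list(conversions = truth_conversions, crossovers = cfg$crossovers,
                 spans = truth_spans,
                 outcross_snps = if (length(snps)) bind_rows(snps) else tibble()),
    config = cfg
  )
  class(out) <- "tet_sim"
  out
}

#' @export
print.tet_sim <- function(x, ...) {
  cat(sprintf("<tet_sim> %d genes x %d strains; %d planted conversions, %d crossovers (seed %d)\n",
              length(x$alignments), nrow(x$manifest),
              nrow(x$truth$conversions), nrow(x$truth$crossovers),
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' One FASTA per gene plus `manifest.tsv`, `layout.tsv`, `mask.tsv` and
#' `truth.json`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(sim$alignments)) {
    write_gene_alignment(sim$alignments[[g]], file.path(dir, paste0(g, ".fasta")))
  }
  readr::write_tsv(as_tibble(sim$manifest), file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(sim$layout)[setdiff(names(sim$layout), "order")],
                   file.path(dir, "layout.tsv"), progress = FALSE)
  write_coding_mask(sim$alignments, file.path(dir, "mask.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname tetmat-generics
#' @param x A `tet_sim`.
#' @param ... Unused.
#' @exportS3Method
tidy.tet_sim <- function(x, ...) {
  select(x$truth$conversions, "gene", "pairs", "time", "template",
         "tract", "ancestral")
}

#' @rdname tetmat-generics
#' @exportS3Method
glance.tet_sim <- function(x, ...) {
  tibble(
    n_genes = length(x$alignments),
    n_strains = nrow(x$manifest),
    n_conversions = nrow(x$truth$conversions),
    n_crossovers = nrow(x$truth$crossovers),
    n_outcross_snps = nrow(x$truth$outcross_snps),
    seed = x$config$seed
  )
}
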