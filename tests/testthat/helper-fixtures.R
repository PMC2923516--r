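# Shared fixtures: built in code, cached across test files within a run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small manifest of n pairs (P1..Pn), lineages "1".."n"
toy_manifest <- function(n = 4) {
  as_tet_manifest(tibble::tibble(
    strain_id = as.vector(rbind(paste0("P", 1:n, "A"), paste0("P", 1:n, "a"))),
    mating_type = rep(c("A", "a"), n),
    lineage = rep(as.character(1:n), each = 2),
    pair_id = rep(paste0("P", 1:n), each = 2)
  ))
}

# a linear toy layout of k genes g1..gk, all central
toy_layout <- function(k = 5, hints = NULL) {
  as_tet_layout(tibble::tibble(
    gene = paste0("g", seq_len(k)),
    region_hint = hints %||% rep("central", k),
    mat_locus_follows = FALSE,
    centromere_follows = FALSE
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# study-emulating simulated dataset + pipeline, shared across files
study_sim <- function() fixture("study_sim", function() {
  simulate_dataset(sim_config(seed = 1L))
})

study_pipeline <- function() fixture("study_pipeline", function() {
  suppressMessages(run_pipeline(
    study_sim(),
    thresholds = support_thresholds(bootstrap_min = 70, posterior_min = 0.95,
                                    bootstrap_reps = 200L, seed = 1L)
  ))
})

# a phase-call tibble row
phase_row <- function(pair, gene, order, phase, supported = FALSE) {
  tibble::tibble(pair_id = pair, gene = gene, order = order, phase = phase,
                 separation_supported = supported,
                 max_support_on_path = NA_real_, patristic = NA_real_)
}
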