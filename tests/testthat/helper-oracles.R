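# Independent oracles used to validate the package's own implementations.
# They deliberately share no code with the package internals: translation
# goes through Biostrings' genetic code and pathway enumeration is a plain
# recursive search.

oracle_translate <- local({
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  function(codon) unname(code[codon])
})

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

# synonymous site fraction of one codon (stop targets count nonsynonymous)
oracle_syn_sites <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), nt[pos])) {
      alt <- nt; alt[pos] <- b
      if (oracle_translate(paste(alt, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

# all permutations of a vector (n <= 3 here)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# average (syn, nonsyn) steps between two codons over minimal pathways,
# excluding pathways through intermediate stop codons unless all pass through
oracle_codon_steps <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  target <- strsplit(c2, "")[[1]]
  res <- list()
  for (ord in oracle_perms(pos)) {
    cur <- strsplit(c1, "")[[1]]
    syn <- 0; nonsyn <- 0; stopped <- FALSE
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- target[p]
      after <- paste(cur, collapse = "")
      if (oracle_is_stop(after) && after != c2) stopped <- TRUE
      if (oracle_is_stop(before) || oracle_is_stop(after)) {
        nonsyn <- nonsyn + 1
      } else if (oracle_translate(before) == oracle_translate(after)) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
    }
    res[[length(res) + 1]] <- c(syn, nonsyn, stopped)
  }
  m <- do.call(rbind, res)
  keep <- if (all(m[, 3] == 1)) rep(TRUE, nrow(m)) else m[, 3] == 0
  c(mean(m[keep, 1]), mean(m[keep, 2]))
}

# full NG86 proportions for two codon vectors (uncorrected)
oracle_ng86 <- function(cod_a, cod_b) {
  ok <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b) &
    !oracle_is_stop(cod_a) & !oracle_is_stop(cod_b)
  cod_a <- cod_a[ok]; cod_b <- cod_b[ok]
  S <- sum(vapply(cod_a, oracle_syn_sites, 0) + vapply(cod_b, oracle_syn_sites, 0)) / 2
  N <- 3 * length(cod_a) - S
  sd_nd <- rowSums(vapply(seq_along(cod_a), function(i) {
    oracle_codon_steps(cod_a[i], cod_b[i])
  }, numeric(2)))
  list(pS = sd_nd[1] / S, pN = sd_nd[2] / N, S = S, N = N,
       Sd = sd_nd[1], Nd = sd_nd[2])
}

# random in-frame codon-sequence pair with bounded difference density
random_codon_pair <- function(n_codons, diff_density = 0.1) {
  nonstop <- {
    code <- as.character(Biostrings::GENETIC_CODE)
    names(Biostrings::GENETIC_CODE)[code != "*"]
  }
  a <- sample(nonstop, n_codons, replace = TRUE)
  b <- a
  n_mut <- rpois(1, diff_density * 3 * n_codons)
  for (k in seq_len(n_mut)) {
    i <- sample(n_codons, 1)
    nt <- strsplit(b[i], "")[[1]]
    p <- sample(3, 1)
    nt[p] <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1)
    cand <- paste(nt, collapse = "")
    if (!oracle_is_stop(cand)) b[i] <- cand
  }
  list(a = a, b = b)
}

# breadth-first path between two nodes over a phylo edge list
oracle_tree_path <- function(tr, from, to) {
  n <- max(tr$edge)
  adj <- vector("list", n)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  prev <- rep(NA_integer_, n); seen <- rep(FALSE, n)
  queue <- from; seen[from] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) break
    for (nb in adj[[cur]]) if (!seen[nb]) {
      seen[nb] <- TRUE; prev[nb] <- cur; queue <- c(queue, nb)
    }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# exhaustive least-squares topology search: returns the best unrooted
# topology for a distance matrix over its labels
oracle_ls_topology <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  best <- NULL; best_ss <- Inf
  combs <- utils::combn(length(labs), 2)
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]   # [[ restores tip labels from the multiPhylo attribute
    tr$edge.length <- rep(1, nrow(tr$edge))
    # design matrix: which edges lie on the path between each leaf pair
    A <- matrix(0, ncol(combs), nrow(tr$edge))
    y <- numeric(ncol(combs))
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      nodes <- oracle_tree_path(tr, i, j)
      for (e in seq_len(nrow(tr$edge))) {
        u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
        hit <- FALSE
        for (m in seq_len(length(nodes) - 1)) {
          if ((nodes[m] == u && nodes[m + 1] == v) ||
              (nodes[m] == v && nodes[m + 1] == u)) hit <- TRUE
        }
        if (hit) A[k, e] <- 1
      }
      y[k] <- d[labs[i], labs[j]]
    }
    fit <- stats::lm.fit(A, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- tr }
  }
  list(topology = best, ss = best_ss)
}
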