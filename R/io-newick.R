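#' Construct a supported tree
#'
#' Wraps an unrooted `ape::phylo` gene genealogy together with per-internal-
#' branch support values. Supports live on internal nodes (the Newick
#' convention); each internal branch inherits the support of its child node.
#'
#' @param phy An `ape::phylo` object; leaf labels are strain ids.
#' @param gene Gene name.
#' @param supports Optional tibble with columns `node` (ape node number),
#'   `bootstrap` (percent, 0-100 or NA) and `posterior` (probability, 0-1 or
#'   NA). Default: parsed from `phy$node.label` (a bare number > 1 is a
#'   bootstrap percentage, a number <= 1 a posterior probability, and
#'   `"85/0.99"` carries both).
#' @return An object of class `supported_tree`.
#' @export
supported_tree <- function(phy, gene = NA_character_, supports = NULL) {
  if (!inherits(phy, "phylo")) {
    stop_tetmat("phy must be an ape phylo object", "tetmat_validation_error")
  }
  if (is.null(supports)) {
    labs <- phy$node.label %||% rep("", phy$Nnode)
    parsed <- purrr::map(labs, parse_support_label)
    supports <- tibble(
      node = ape::Ntip(phy) + seq_len(phy$Nnode),
      bootstrap = map_dbl(parsed, "bootstrap"),
      posterior = map_dbl(parsed, "posterior")
    )
  }
  ok_b <- is.na(supports$bootstrap) | (supports$bootstrap >= 0 & supports$bootstrap <= 100)
  ok_p <- is.na(supports$posterior) | (supports$posterior >= 0 & supports$posterior <= 1)
  if (!all(ok_b) || !all(ok_p)) {
    stop_tetmat("supports out of range (bootstrap in [0,100], posterior in [0,1])",
                "tetmat_validation_error")
  }
  structure(list(gene = gene, phy = phy, supports = supports),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  n_sup <- sum(!is.na(x$supports$bootstrap) | !is.na(x$supports$posterior))
  cat(sprintf("<supported_tree> %s: %d tips, %d internal nodes (%d with support)\n",
              x$gene %||% "?", ape::Ntip(x$phy), x$phy$Nnode, n_sup))
  invisible(x)
}

# "85" -> bootstrap 85; "0.99" -> posterior; "85/0.99" -> both; "" -> neither
parse_support_label <- function(lab) {
  out <- list(bootstrap = NA_real_, posterior = NA_real_)
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) return(out)
  for (part in strsplit(lab, "/", fixed = TRUE)[[1]]) {
    v <- suppressWarnings(as.numeric(part))
    if (is.na(v)) next
    if (v > 1) out$bootstrap <- v else out$posterior <- v
  }
  out
}

#' Read a Newick tree with support labels
#'
#' @param path Path to a Newick file (or a literal Newick string via `text`).
#' @param text Newick string, as an alternative to `path`.
#' @param gene Gene name attached to the result.
#' @return A [supported_tree()].
#' @export
#' @examples
#' tr <- read_supported_tree(text = "((a:1,b:1)85:1,(c:1,d:1)0.99:1);")
read_supported_tree <- function(path = NULL, text = NULL, gene = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) {
      stop_tetmat(sprintf("tree file not found: %s", path), "tetmat_format_error")
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
    if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  }
  phy <- newick_parse_safe(text)
  supported_tree(phy, gene = gene %||% NA_character_)
}

#' Write a supported tree as Newick
#'
#' Supports are rendered as internal node labels (`85`, `0.99`, or `85/0.99`).
#' Strain ids containing Newick metacharacters are single-quoted.
#'
#' @param tree A [supported_tree()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_supported_tree <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

newick_string <- function(tree) {
  phy <- tree$phy
  sup <- tree$supports[order(tree$supports$node), ]
  lab <- map_chr(seq_len(nrow(sup)), function(i) {
    b <- sup$bootstrap[i]; p <- sup$posterior[i]
    if (!is.na(b) && !is.na(p)) {
      paste0(format_num(b), "/", format_num(p))
    } else if (!is.na(b)) format_num(b) else if (!is.na(p)) format_num(p) else ""
  })
  phy$node.label <- lab
  newick_deparse_safe(phy)
}

format_num <- function(x) {
  formatC(x, format = "fg", digits = 15)
}

# --- quoting-safe Newick round trip -----------------------------------------
# ape's reader/writer do not handle labels containing ( ) : , ; or spaces
# (e.g. strain "L8(1)A"); tunnel such labels through placeholders.

needs_quote <- function(x) grepl("[][(),:;' \t]", x)

newick_parse_safe <- function(text) {
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  if (length(quoted) > 0) {
    ph <- sprintf("TETMATQ%dZ", seq_along(quoted))
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], ph[i], text, fixed = TRUE)
    }
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    stop_tetmat("malformed Newick string", "tetmat_parse_error")
  }
  if (length(quoted) > 0) {
    restore <- function(labs) {
      for (i in seq_along(quoted)) {
        labs[labs == ph[i]] <- gsub("^'|'$", "", quoted[i])
      }
      labs
    }
    phy$tip.label <- restore(phy$tip.label)
    if (!is.null(phy$node.label)) phy$node.label <- restore(phy$node.label)
  }
  phy
}

newick_deparse_safe <- function(phy) {
  orig <- phy$tip.label
  quote_these <- needs_quote(orig)
  ph <- orig
  ph[quote_these] <- sprintf("TETMATQ%dZ", which(quote_these))
  phy$tip.label <- ph
  s <- ape::write.tree(phy)
  for (i in which(quote_these)) {
    s <- sub(sprintf("TETMATQ%dZ", i), paste0("'", orig[i], "'"), s, fixed = TRUE)
  }
  s
}

#' @rdname tetmat-generics
#' @param x A `supported_tree`.
#' @param ... Unused.
#' @exportS3Method
tidy.supported_tree <- function(x, ...) {
  phy <- x$phy
  ed <- phy$edge
  len <- phy$edge.length %||% rep(NA_real_, nrow(ed))
  tibble(
    gene = x$gene,
    parent = ed[, 1], node = ed[, 2],
    length = len,
    is_internal = ed[, 2] > ape::Ntip(phy),
    label = ifelse(ed[, 2] <= ape::Ntip(phy), phy$tip.label[ed[, 2]], NA_character_)
  ) |>
    left_join(x$supports, by = "node")
}

#' @rdname tetmat-generics
#' @exportS3Method
glance.supported_tree <- function(x, ...) {
  tibble(
    gene = x$gene,
    n_tips = ape::Ntip(x$phy),
    n_internal = x$phy$Nnode,
    n_supported = sum(!is.na(x$supports$bootstrap) | !is.na(x$supports$posterior))
  )
}
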