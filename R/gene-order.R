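#' Signed gene order
#'
#' A taxon's mitochondrial gene arrangement: genes in genomic order with the
#' strand of each relative to the majority strand.
#'
#' @param genes Character vector of canonical gene tokens (each at most once).
#' @param strands `"+"`/`"-"` vector of the same length (default all `"+"`).
#' @param taxon Label.
#' @param topology `"circular"` or `"linear"`.
#' @return Tibble of class `mito_order` with columns `gene`, `strand` and
#'   attributes `taxon`, `topology`.
#' @export
gene_order <- function(genes, strands = rep("+", length(genes)),
                       taxon = "unnamed", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene token(s) in order: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (length(strands) != length(genes) || !all(strands %in% c("+", "-"))) {
    abort("strands must be '+'/'-' and match genes in length")
  }
  out <- tibble(gene = genes, strand = strands)
  attr(out, "taxon") <- taxon
  attr(out, "topology") <- topology
  class(out) <- c("mito_order", class(out))
  out
}

order_taxon <- function(o) attr(o, "taxon") %||% "unnamed"
order_topology <- function(o) attr(o, "topology") %||% "circular"

signed_tokens <- function(o) paste0(ifelse(o$strand == "-", "-", ""), o$gene)

#' @export
print.mito_order <- function(x, ...) {
  cat(sprintf("<mito_order> %s (%s): %s\n", order_taxon(x), order_topology(x),
              paste(signed_tokens(x), collapse = ",")))
  invisible(x)
}

#' @export
format.mito_order <- function(x, ...) paste(signed_tokens(x), collapse = ",")

rotate_order <- function(o, offset) {
  n <- nrow(o)
  if (n == 0 || offset %% n == 0) return(o)
  idx <- ((seq_len(n) - 1L + offset) %% n) + 1L
  out <- o
  out$gene <- o$gene[idx]
  out$strand <- o$strand[idx]
  out
}

order_subset <- function(o, keep) {
  out <- o[keep, ]
  attr(out, "taxon") <- order_taxon(o)
  attr(out, "topology") <- order_topology(o)
  class(out) <- class(o)
  out
}

#' Extract the signed gene order of an annotated genome
#'
#' Features with canonical names are sorted by start coordinate; on a
#' circular genome the order is rotated to begin at `trnI` (the ancestral
#' insect anchor), or just after the control region when `trnI` is absent,
#' so orders from different annotation offsets are directly comparable.
#' Features whose names could not be normalized are excluded with a warning.
#'
#' @param genome A [mito_genome()].
#' @return A [gene_order()].
#' @export
extract_gene_order <- function(genome) {
  feats <- genome$features
  unknown <- feats$name == "unknown"
  if (any(unknown)) {
    warn(paste0(sum(unknown), " feature(s) with un-normalizable names excluded ",
                "from the gene order"))
    feats <- feats[!unknown, ]
  }
  feats <- feats[order(feats$start), ]
  o <- gene_order(feats$name, feats$strand, taxon = genome$id,
                  topology = genome$topology)
  if (genome$topology == "circular" && nrow(o) > 1) {
    if ("trnI" %in% o$gene) {
      o <- rotate_order(o, which(o$gene == "trnI")[1] - 1L)
    } else if ("CR" %in% o$gene) {
      o <- rotate_order(o, which(o$gene == "CR")[1] %% nrow(o))
    }
  }
  o
}

# Restrict two orders to their shared token universe, reporting asymmetries.
harmonize_orders <- function(order, reference) {
  missing_in_order <- setdiff(reference$gene, order$gene)
  missing_in_ref <- setdiff(order$gene, reference$gene)
  if (length(missing_in_order) || length(missing_in_ref)) {
    inform(paste0(
      "gene-order comparison over the shared token set only; absent from '",
      order_taxon(order), "': ",
      paste(missing_in_order, collapse = ", ") %||% "", "; absent from '",
      order_taxon(reference), "': ", paste(missing_in_ref, collapse = ", ")))
    order <- order_subset(order, order$gene %in% reference$gene)
    reference <- order_subset(reference, reference$gene %in% order$gene)
  }
  list(order = order, reference = reference)
}

# Best circular alignment: the rotation of `order` minimizing position-wise
# mismatches against `reference` (smallest offset on ties). Linear orders are
# compared as-is.
align_to_reference <- function(order, reference) {
  n <- nrow(order)
  if (order_topology(order) != "circular" || order_topology(reference) != "circular" ||
      n == 0) {
    return(order)
  }
  mism <- vapply(seq_len(n) - 1L, function(off) {
    rot <- ((seq_len(n) - 1L + off) %% n) + 1L
    sum(order$gene[rot] != reference$gene | order$strand[rot] != reference$strand)
  }, integer(1))
  rotate_order(order, which.min(mism) - 1L)
}

#' Rearrangement events between a gene order and a reference
#'
#' Aligns the two orders (best circular rotation), factors out the maximal
#' identical blocks, and reports each remaining local cluster of differences
#' as one typed rearrangement event. Clusters are spelled with the preceding
#' unchanged gene as an anchor (the convention of the comparative
#' literature: `COX2-trnK-trnD` → `COX2-trnD-trnK`); the control region
#' never appears in clusters. Events are ordered by ancestral position.
#'
#' @param order,reference [gene_order()] objects over the same token
#'   universe (missing tokens are excluded pairwise and reported).
#' @return Tibble with one row per event: `kind` (`shuffle`,
#'   `transposition`, `inversion`, `inverse_transposition`, or `complex`),
#'   `anchor`, `ancestral`, `derived` (anchored signed spellings),
#'   `genes` (list of tokens involved), `note`.
#' @export
diff_against <- function(order, reference) {
  h <- harmonize_orders(order, reference)
  order <- align_to_reference(h$order, h$reference)
  reference <- h$reference
  n <- nrow(reference)
  empty <- tibble(kind = character(), anchor = character(),
                  ancestral = character(), derived = character(),
                  genes = list(), note = character())
  if (n == 0) return(empty)
  changed <- order$gene != reference$gene | order$strand != reference$strand
  if (!any(changed)) return(empty)
  runs <- rle(changed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  for (k in which(runs$values)) {
    i <- starts[k]; j <- ends[k]
    anc <- reference[i:j, ]
    der <- order[i:j, ]
    anchor <- NA_character_
    prev <- if (i > 1) i - 1L else if (order_topology(reference) == "circular") n else NA_integer_
    if (!is.na(prev) && reference$gene[prev] != "CR" && !(prev >= i && prev <= j)) {
      anchor <- reference$gene[prev]
    }
    kind <- classify_cluster(anc, der)
    anchor_tok <- if (is.na(anchor)) character(0) else {
      paste0(reference$gene[prev], ifelse(reference$strand[prev] == "-", "(-)", ""))
    }
    rows[[length(rows) + 1L]] <- tibble(
      kind = kind,
      anchor = anchor,
      ancestral = paste(c(anchor_tok, display_tokens(anc)), collapse = "-"),
      derived = paste(c(anchor_tok, display_tokens(der)), collapse = "-"),
      genes = list(anc$gene),
      note = if (kind == "shuffle") {
        "strand-unchanged positional swap (sometimes described as an inversion in the literature)"
      } else NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

display_tokens <- function(o) paste0(o$gene, ifelse(o$strand == "-", "(-)", ""))

flip_strand <- function(s) ifelse(s == "-", "+", "-")

# Classify one changed cluster, order/sign evidence only.
classify_cluster <- function(anc, der) {
  n <- nrow(anc)
  same_strand <- function(d) {
    all(d$strand == anc$strand[match(d$gene, anc$gene)])
  }
  # shuffle: two adjacent genes exchange positions, signs unchanged
  if (n == 2 && identical(der$gene, rev(anc$gene)) && same_strand(der)) {
    return("shuffle")
  }
  # inversion: contiguous block reversed with all signs flipped
  if (identical(der$gene, rev(anc$gene)) &&
      identical(der$strand, flip_strand(rev(anc$strand)))) {
    return("inversion")
  }
  # block-move explanations
  if (block_move_explains(anc, der, flipped = FALSE)) return("transposition")
  if (block_move_explains(anc, der, flipped = TRUE)) return("inverse_transposition")
  "complex"
}

# Does moving one contiguous block of `anc` (optionally reversed with signs
# flipped) to another slot reproduce `der`?
block_move_explains <- function(anc, der, flipped = FALSE) {
  n <- nrow(anc)
  a_g <- anc$gene; a_s <- anc$strand
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L == n) next
    blk_g <- a_g[i:j]; blk_s <- a_s[i:j]
    if (flipped) {
      blk_g <- rev(blk_g); blk_s <- flip_strand(rev(blk_s))
    }
    rest_g <- a_g[-(i:j)]; rest_s <- a_s[-(i:j)]
    for (k in 0:length(rest_g)) {
      cand_g <- append(rest_g, blk_g, after = k)
      cand_s <- append(rest_s, blk_s, after = k)
      if (!flipped && k == i - 1L) next   # identity placement
      if (identical(cand_g, der$gene) && identical(cand_s, der$strand)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Breakpoint distance between two gene orders
#'
#' Number of signed gene adjacencies present in the reference but absent
#' from the order. An adjacency (a, b) is considered preserved if it occurs
#' as (a, b) or, read on the opposite strand, as (-b, -a). Circular orders
#' include the wrap-around adjacency; rotation of a circular order never
#' changes the count.
#'
#' @param order,reference [gene_order()] objects.
#' @return Non-negative integer.
#' @export
breakpoint_count <- function(order, reference) {
  h <- harmonize_orders(order, reference)
  ref_adj <- adjacency_keys(h$reference)
  ord_adj <- adjacency_keys(h$order)
  sum(!(ref_adj %in% ord_adj))
}

adjacency_keys <- function(o) {
  s <- signed_tokens(o)
  n <- length(s)
  if (n < 2) return(character(0))
  a <- s
  b <- c(s[-1], s[1])
  keep <- if (order_topology(o) == "circular") seq_len(n) else seq_len(n - 1L)
  vapply(keep, function(i) {
    neg <- function(x) ifelse(startsWith(x, "-"), sub("^-", "", x), paste0("-", x))
    k1 <- paste(a[i], b[i], sep = ">")
    k2 <- paste(neg(b[i]), neg(a[i]), sep = ">")
    min(k1, k2)
  }, character(1))
}

canonical_pattern <- function(anchor_tok, cluster) {
  toks <- c(anchor_tok, display_tokens(cluster))
  fwd <- paste(toks, collapse = "-")
  # reverse-complement reading of the same anchored token list
  flip_tok <- function(x) {
    ifelse(endsWith(x, "(-)"), sub("\\(-\\)$", "", x), paste0(x, "(-)"))
  }
  rev_str <- paste(flip_tok(rev(toks)), collapse = "-")
  min(fwd, rev_str)
}

#' Catalog distinct rearrangement patterns across taxa
#'
#' Diffs every order against the reference and pools the canonical
#' derived-cluster patterns (orientation-normalized, so a cluster and its
#' reverse-complement reading collide), recording which taxa exhibit each.
#'
#' @param orders List of [gene_order()] objects.
#' @param reference Reference [gene_order()] (default the ancestral insect
#'   order).
#' @return Tibble of class `mito_patterns`: `pattern`, `derived`,
#'   `ancestral`, `kind`, `n_taxa`, `taxa` (list column); the number of
#'   distinct patterns is `nrow()` and also attribute `n_patterns`.
#' @export
catalog_patterns <- function(orders, reference = ancestral_insect_order()) {
  if (!length(orders)) abort("catalog_patterns() needs at least one order")
  rows <- purrr::map_dfr(orders, function(o) {
    ev <- diff_against(o, reference)
    if (!nrow(ev)) return(NULL)
    ev$taxon <- order_taxon(o)
    ev$pattern <- vapply(ev$derived, canonical_from_spelling, character(1),
                         USE.NAMES = FALSE)
    ev
  })
  if (is.null(rows) || !nrow(rows)) {
    out <- tibble(pattern = character(), derived = character(),
                  ancestral = character(), kind = character(),
                  n_taxa = integer(), taxa = list())
  } else {
    out <- rows |>
      dplyr::group_by(.data$pattern) |>
      dplyr::summarise(derived = .data$derived[1], ancestral = .data$ancestral[1],
                       kind = .data$kind[1],
                       n_taxa = dplyr::n_distinct(.data$taxon),
                       taxa = list(sort(unique(.data$taxon))), .groups = "drop")
  }
  attr(out, "n_patterns") <- nrow(out)
  class(out) <- c("mito_patterns", class(out))
  out
}

canonical_from_spelling <- function(spelled) {
  toks <- strsplit(spelled, "-(?!\\))", perl = TRUE)[[1]]
  fwd <- paste(toks, collapse = "-")
  flip_tok <- function(x) {
    ifelse(endsWith(x, "(-)"), sub("\\(-\\)$", "", x), paste0(x, "(-)"))
  }
  rev_str <- paste(flip_tok(rev(toks)), collapse = "-")
  min(fwd, rev_str)
}

#' Gene orders of four recently characterized halictid bees
#'
#' The signed gene orders of *Nomia thoracica*, *Lipotriches guihongi*,
#' *Lipotriches capitata* and *Dufourea subclavicrus*, reconstructed by
#' applying their reported tRNA rearrangements to the ancestral insect
#' order: the `trnK`/`trnD` swap (all four), the `trnI-trnQ-trnM` →
#' `trnM-trnI-trnQ` change (all but *L. guihongi*), the `trnA`/`trnR` swap
#' (the three Nomiinae), the `trnT`/`trnP` swap (*N. thoracica*,
#' *L. capitata*) and the `ND4-ND4L-trnT-trnP` → `ND4-trnP-ND4L-trnT`
#' rearrangement unique to *L. guihongi*.
#'
#' @return Named list of four [gene_order()] objects.
#' @export
halictid_gene_orders <- function() {
  anc <- ancestral_insect_order()
  reorder_run <- function(o, new_genes) {
    pos <- match(new_genes, o$gene)
    span <- seq(min(pos), max(pos))
    if (!setequal(o$gene[span], new_genes)) {
      abort("reorder_run(): genes are not a contiguous run")
    }
    idx <- match(new_genes, o$gene)
    o$gene[span] <- o$gene[idx]
    o$strand[span] <- o$strand[idx]
    o
  }
  with_taxon <- function(o, taxon) { attr(o, "taxon") <- taxon; o }
  thoracica <- anc |>
    reorder_run(c("trnM", "trnI", "trnQ")) |>
    reorder_run(c("trnD", "trnK")) |>
    reorder_run(c("trnR", "trnA")) |>
    reorder_run(c("trnP", "trnT")) |>
    with_taxon("Nomia thoracica")
  capitata <- anc |>
    reorder_run(c("trnM", "trnI", "trnQ")) |>
    reorder_run(c("trnD", "trnK")) |>
    reorder_run(c("trnR", "trnA")) |>
    reorder_run(c("trnP", "trnT")) |>
    with_taxon("Lipotriches capitata")
  guihongi <- anc |>
    reorder_run(c("trnD", "trnK")) |>
    reorder_run(c("trnR", "trnA")) |>
    reorder_run(c("trnP", "ND4L", "trnT")) |>
    with_taxon("Lipotriches guihongi")
  subclavicrus <- anc |>
    reorder_run(c("trnM", "trnI", "trnQ")) |>
    reorder_run(c("trnD", "trnK")) |>
    with_taxon("Dufourea subclavicrus")
  list(`Nomia thoracica` = thoracica,
       `Lipotriches guihongi` = guihongi,
       `Lipotriches capitata` = capitata,
       `Dufourea subclavicrus` = subclavicrus)
}

#' Read and write the one-taxon-per-line gene-order text format
#'
#' Each line is `taxon<TAB>signed,token,list`, e.g.
#' `ancestral\ttrnI,-trnQ,trnM,ND2,...`.
#'
#' @param path File path.
#' @param topology Topology to assign to the parsed orders.
#' @return `read_gene_orders()`: named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  orders <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2) abort(paste0("malformed gene-order line: '", ln, "'"))
    toks <- strsplit(parts[2], ",")[[1]]
    neg <- startsWith(toks, "-")
    gene_order(sub("^-", "", toks), ifelse(neg, "-", "+"),
               taxon = parts[1], topology = topology)
  })
  stats::setNames(orders, vapply(orders, order_taxon, character(1)))
}

#' @rdname read_gene_orders
#' @param orders List of [gene_order()] objects.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(orders, function(o) {
    paste0(order_taxon(o), "\t", paste(signed_tokens(o), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
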