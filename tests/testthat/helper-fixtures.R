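# Fixtures are built in code; no binary data.

# Write a minimal GenBank record to a temp file and return its path.
gb_fixture <- function(id, seq, feature_lines, topology = "circular") {
  path <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  len <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %s %d bp DNA %s UNA", id, len, topology),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    feature_lines,
    "ORIGIN"
  )
  starts <- seq(1L, len, by = 60L)
  lines <- c(lines, sprintf("%9d %s", starts,
                            substring(tolower(seq), starts, pmin(starts + 59L, len))),
             "//")
  writeLines(lines, path)
  path
}

# A tiny hand-annotated genome: one plus-strand PCG, one minus-strand tRNA,
# one rRNA, one CR.
toy_genome <- function() {
  #        PCG (0..9)   trnA(12..18 minus)  rrnS(18..30)  CR(30..38)
  seq <- paste0("ATGTTTTAA", "G", "AG", "TTTCATG", "GGGCCCAAATTT", "ATATATAT")
  feats <- tibble::tibble(
    name = c("COX1", "trnA", "rrnS", "CR"),
    category = c("PCG", "tRNA", "rRNA", "CR"),
    start = c(0L, 12L, 19L, 31L),
    end = c(9L, 19L, 31L, 39L),
    strand = c("+", "-", "+", "+")
  )
  mito_genome("toy", seq, feats, topology = "linear")
}

# Independent RSCU oracle: loop over synonymous families defined straight
# from the translation table.
oracle_rscu <- function(counts, code) {
  fams <- split(names(code$map)[code$map != "*"],
                code$map[code$map != "*"])
  out <- stats::setNames(rep(NA_real_, nrow(counts)), counts$codon)
  for (f in fams) {
    tot <- sum(counts$count[counts$codon %in% f])
    if (tot == 0) next
    for (cod in f) {
      out[cod] <- counts$count[counts$codon == cod] / (tot / length(f))
    }
  }
  out
}

# Brute-force breakpoint oracle over signed token vectors.
oracle_breakpoints <- function(order_signed, ref_signed, circular = FALSE) {
  adj <- function(s) {
    n <- length(s)
    idx <- if (circular) seq_len(n) else seq_len(n - 1L)
    nxt <- c(s[-1], s[1])
    neg <- function(x) ifelse(startsWith(x, "-"), sub("^-", "", x), paste0("-", x))
    vapply(idx, function(i) min(paste(s[i], nxt[i]), paste(neg(nxt[i]), neg(s[i]))),
           character(1))
  }
  sum(!(adj(ref_signed) %in% adj(order_signed)))
}

signed_vec <- function(o) paste0(ifelse(o$strand == "-", "-", ""), o$gene)

# gene_order from a signed integer permutation (for small random cases).
perm_order <- function(perm, taxon = "p", topology = "linear") {
  gene_order(paste0("g", abs(perm)), ifelse(perm < 0, "-", "+"),
             taxon = taxon, topology = topology)
}
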