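#' Per-gene alignment container
#'
#' Holds one already-aligned, already-trimmed gene alignment (alignment and
#' trimming themselves are external, e.g. MAFFT + TrimAl; this package
#' consumes their output). Rows are taxa; all rows must have equal width.
#'
#' @param gene Canonical gene token.
#' @param kind `"PCG_nt"` (codon-aware nucleotide alignment, width divisible
#'   by 3 expected) or `"rRNA_nt"`.
#' @param seqs Named character vector, taxon → aligned sequence.
#' @return Object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, kind = c("PCG_nt", "rRNA_nt"), seqs) {
  kind <- match.arg(kind)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("alignment rows must be named by taxon")
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1) abort(paste0("unequal row widths in alignment of ", gene))
  structure(list(gene = gene, kind = kind, seqs = toupper(seqs),
                 width = w, stripped = FALSE, translated = FALSE),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s (%s): %d taxa x %d columns\n",
              x$gene, x$kind, length(x$seqs), x$width))
  invisible(x)
}

#' Translate a codon-aware nucleotide alignment to amino acids
#'
#' Codons are translated under the given genetic code; any codon containing
#' a gap becomes a gap column; an internal stop codon becomes `X` with a
#' warning (a terminal stop translates to `*`).
#'
#' @param aln A `PCG_nt` [gene_alignment()] with width divisible by 3.
#' @param code A [genetic_code()].
#' @return A `gene_alignment` of amino acids (`translated = TRUE`).
#' @export
translate_alignment <- function(aln, code = genetic_code()) {
  if (aln$kind != "PCG_nt") abort("only PCG_nt alignments can be translated")
  if (aln$width %% 3 != 0) {
    abort(paste0("alignment width ", aln$width, " of ", aln$gene,
                 " is not divisible by 3"))
  }
  n_cod <- aln$width %/% 3L
  out <- vapply(names(aln$seqs), function(tx) {
    s <- as_dna(aln$seqs[[tx]])
    cods <- substring(s, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    aa <- vapply(seq_along(cods), function(i) {
      cod <- cods[i]
      if (grepl("-", cod, fixed = TRUE)) return("-")
      val <- unname(code$map[cod])
      if (is.na(val)) return("X")
      if (val == "*" && i < length(cods)) {
        warn(paste0("internal stop codon in ", aln$gene, " / ", tx,
                    " (codon ", i, "); translated as X"))
        return("X")
      }
      val
    }, character(1))
    paste(aa, collapse = "")
  }, character(1))
  structure(list(gene = aln$gene, kind = "PCG_aa", seqs = out,
                 width = n_cod, stripped = FALSE, translated = TRUE),
            class = "gene_alignment")
}

#' Remove third codon positions from a codon-aware alignment
#'
#' Keeps alignment columns at codon positions 1 and 2 (output width is 2/3
#' of the input). Column provenance is recorded; stripping an
#' already-stripped alignment is rejected.
#'
#' @param aln A `PCG_nt` [gene_alignment()] with width divisible by 3.
#' @return A `gene_alignment` with `stripped = TRUE`.
#' @export
strip_third_positions <- function(aln) {
  if (aln$kind != "PCG_nt") abort("only PCG_nt alignments can be stripped")
  if (isTRUE(aln$stripped)) {
    abort(paste0("alignment of ", aln$gene, " has already had third positions removed"))
  }
  if (aln$width %% 3 != 0) {
    abort(paste0("alignment width ", aln$width, " of ", aln$gene,
                 " is not divisible by 3"))
  }
  keep <- which((seq_len(aln$width) - 1L) %% 3L != 2L)
  out <- vapply(aln$seqs, function(s) {
    paste(strsplit(s, "")[[1]][keep], collapse = "")
  }, character(1))
  structure(list(gene = aln$gene, kind = "PCG_nt", seqs = out,
                 width = length(keep), stripped = TRUE, translated = FALSE),
            class = "gene_alignment")
}

# Concatenate a list of gene_alignments over a fixed taxon set; returns
# list(seqs = named character, partitions = tibble).
concat_alignments <- function(alns, taxa, fill) {
  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  at <- 0L
  for (aln in alns) {
    rows <- vapply(taxa, function(tx) {
      if (tx %in% names(aln$seqs)) {
        aln$seqs[[tx]]
      } else if (fill == "gaps") {
        warn(paste0("taxon '", tx, "' missing from ", aln$gene,
                    "; row filled with gaps"))
        strrep("-", aln$width)
      } else {
        abort(paste0("taxon '", tx, "' missing from alignment of ", aln$gene,
                     " (set fill = \"gaps\" to pad)"))
      }
    }, character(1))
    seqs <- paste0(seqs, rows)
    names(seqs) <- taxa
    parts[[length(parts) + 1L]] <- tibble(
      gene = aln$gene,
      type = c(PCG_nt = "DNA", rRNA_nt = "DNA", PCG_aa = "AA")[[aln$kind]],
      start = at + 1L, end = at + aln$width
    )
    at <- at + aln$width
  }
  list(seqs = seqs, partitions = dplyr::bind_rows(parts))
}

#' Build the five phylogenomic supermatrices
#'
#' Concatenates per-gene alignments into the five standard matrices used in
#' mitogenome phylogenomics: `cds_faa` (translated PCGs), `cds_fna` (PCG
#' nucleotides), `cds_rrna` (PCG nucleotides + rRNAs), `cds12_fna` (PCG
#' nucleotides with third codon positions removed) and `cds12_rrna`
#' (stripped PCGs + rRNAs). Genes are concatenated in the genomic order of
#' the ancestral insect plan (rRNAs appended after the PCGs); per-gene
#' partitions carry 1-based inclusive coordinates. The width identities
#' `width(cds12_fna) = 2/3 * width(cds_fna)` and `width(cds_rrna) =
#' width(cds_fna) + rRNA widths` hold by construction and are verifiable
#' via [glance.supermatrix_bundle()].
#'
#' @param alignments List of [gene_alignment()] objects (PCGs and rRNAs).
#' @param code A [genetic_code()] for translation.
#' @param fill `"error"` (default: every taxon must be present in every
#'   alignment) or `"gaps"` (missing rows padded with gaps, with a warning).
#' @return Object of class `supermatrix_bundle`: `matrices` (named list of
#'   named character vectors) and `partitions` (tibble with columns
#'   `matrix`, `gene`, `type`, `start`, `end`).
#' @export
build_bundle <- function(alignments, code = genetic_code(),
                         fill = c("error", "gaps")) {
  fill <- match.arg(fill)
  kinds <- vapply(alignments, function(a) a$kind, character(1))
  if (any(vapply(alignments, function(a) isTRUE(a$stripped), logical(1)))) {
    abort("build_bundle() expects unstripped PCG alignments; stripping is internal")
  }
  pcgs <- alignments[kinds == "PCG_nt"]
  rrnas <- alignments[kinds == "rRNA_nt"]
  if (!length(pcgs)) abort("no PCG alignments supplied")
  ord <- ancestral_insect_order()$gene
  by_plan <- function(alns) {
    alns[order(match(vapply(alns, function(a) a$gene, character(1)), ord))]
  }
  pcgs <- by_plan(pcgs)
  rrnas <- by_plan(rrnas)

  taxa <- sort(unique(unlist(lapply(alignments, function(a) names(a$seqs)))))
  if (fill == "error") {
    for (a in alignments) {
      miss <- setdiff(taxa, names(a$seqs))
      if (length(miss)) {
        abort(paste0("taxon set mismatch: ", paste(miss, collapse = ", "),
                     " absent from alignment of ", a$gene))
      }
    }
  }

  faa <- lapply(pcgs, translate_alignment, code = code)
  p12 <- lapply(pcgs, strip_third_positions)

  mats <- list(
    cds_faa = concat_alignments(faa, taxa, fill),
    cds_fna = concat_alignments(pcgs, taxa, fill),
    cds_rrna = concat_alignments(c(pcgs, rrnas), taxa, fill),
    cds12_fna = concat_alignments(p12, taxa, fill),
    cds12_rrna = concat_alignments(c(p12, rrnas), taxa, fill)
  )
  partitions <- purrr::imap_dfr(mats, function(m, nm) {
    dplyr::mutate(m$partitions, matrix = nm, .before = 1)
  })
  structure(list(matrices = lapply(mats, `[[`, "seqs"),
                 partitions = partitions, taxa = taxa),
            class = "supermatrix_bundle")
}

#' @export
print.supermatrix_bundle <- function(x, ...) {
  cat("<supermatrix_bundle>\n")
  print(glance(x))
  invisible(x)
}

#' Partition table / width summary of a supermatrix bundle
#'
#' `tidy()` returns the per-gene partition table; `glance()` one row per
#' matrix with taxon count and width.
#'
#' @param x A [build_bundle()] result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.supermatrix_bundle <- function(x, ...) x$partitions

#' @rdname tidy.supermatrix_bundle
#' @exportS3Method generics::glance
glance.supermatrix_bundle <- function(x, ...) {
  tibble(
    matrix = names(x$matrices),
    n_taxa = vapply(x$matrices, length, integer(1)),
    width = vapply(x$matrices, function(m) unique(nchar(m)), integer(1))
  )
}

#' Write a supermatrix bundle to disk
#'
#' Emits each matrix as FASTA and relaxed PHYLIP, plus a RAxML-style
#' partition file and a NEXUS `sets` block per matrix.
#'
#' @param bundle A [build_bundle()] result.
#' @param dir Output directory (created if needed).
#' @param codon_subpartitions Also emit pos1/pos2 subpartitions for the
#'   stripped nucleotide matrices?
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, codon_subpartitions = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$matrices)) {
    seqs <- bundle$matrices[[nm]]
    writeLines(paste0(">", names(seqs), "\n", seqs),
               file.path(dir, paste0(nm, ".fasta")))
    w <- unique(nchar(seqs))
    phy <- c(sprintf("%d %d", length(seqs), w),
             sprintf("%s  %s", names(seqs), seqs))
    writeLines(phy, file.path(dir, paste0(nm, ".phy")))
    parts <- bundle$partitions[bundle$partitions$matrix == nm, ]
    rax <- part_lines(parts, codon_subpartitions, style = "raxml")
    writeLines(rax, file.path(dir, paste0(nm, ".partitions.txt")))
    nex <- c("#NEXUS", "begin sets;",
             paste0("  ", part_lines(parts, codon_subpartitions, style = "nexus")),
             "end;")
    writeLines(nex, file.path(dir, paste0(nm, ".sets.nex")))
  }
  invisible(dir)
}

part_lines <- function(parts, codon_subpartitions, style) {
  mk <- function(name, type, range) {
    if (style == "raxml") sprintf("%s, %s = %s", type, name, range)
    else sprintf("charset %s = %s;", name, range)
  }
  lines <- character(0)
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    if (codon_subpartitions && p$type == "DNA" &&
        (p$end - p$start + 1L) %% 2L == 0L && grepl("^cds12", p$matrix)) {
      lines <- c(lines,
                 mk(paste0(p$gene, "_pos1"), p$type,
                    sprintf("%d-%d\\2", p$start, p$end)),
                 mk(paste0(p$gene, "_pos2"), p$type,
                    sprintf("%d-%d\\2", p$start + 1L, p$end)))
    } else {
      lines <- c(lines, mk(p$gene, p$type, sprintf("%d-%d", p$start, p$end)))
    }
  }
  lines
}

#' Read per-gene alignments from FASTA files
#'
#' Each file holds one aligned gene; the gene token is taken from the file
#' name (normalized via [normalize_gene_name()]) and the kind inferred from
#' its category (PCG → `PCG_nt`, rRNA → `rRNA_nt`).
#'
#' @param paths FASTA file paths, or a directory of `.fasta`/`.fa` files.
#' @return List of [gene_alignment()] objects.
#' @export
read_gene_alignments <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  }
  if (!length(paths)) abort("no alignment FASTA files found")
  lapply(paths, function(p) {
    token <- normalize_gene_name(sub("\\.[^.]+$", "", basename(p)))
    if (token == "unknown") {
      abort(paste0("cannot infer gene from file name: ", basename(p)))
    }
    kind <- switch(gene_category(token), PCG = "PCG_nt", rRNA = "rRNA_nt",
                   abort(paste0(token, " is neither a PCG nor an rRNA")))
    ss <- Biostrings::readBStringSet(p)
    gene_alignment(token, kind,
                   stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  })
}
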