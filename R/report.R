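#' Run the full comparative analysis and write paper-style reports
#'
#' For each input genome, writes a composition table (TSV, Table-2 column
#' order), an RSCU table (TSV), a start/stop-codon census (TSV) and a
#' rearrangement-event report (JSON, diffed against the reference order);
#' across all inputs, a catalog of distinct rearrangement patterns
#' (`patterns.json`). Data go to files; progress goes to messages.
#'
#' @param inputs Character vector of GenBank file paths, or a list of
#'   [mito_genome()] objects.
#' @param out_dir Output directory (created if needed).
#' @param reference Reference [gene_order()] for rearrangement analysis.
#' @param code A [genetic_code()].
#' @return Invisibly, a list with per-genome result tibbles and the pattern
#'   catalog.
#' @export
analyze_mitogenomes <- function(inputs, out_dir,
                                reference = ancestral_insect_order(),
                                code = genetic_code()) {
  if (!length(inputs)) abort("analyze_mitogenomes() needs at least one input genome")
  genomes <- if (is.character(inputs)) lapply(inputs, read_genbank) else inputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  orders <- list()
  results <- list()
  for (g in genomes) {
    stopifnot(inherits(g, "mito_genome"))
    comp <- composition_table(g)
    rs <- rscu(codon_counts(g, code), code)
    cen <- start_stop_census(g, code)
    ord <- extract_gene_order(g)
    ev <- diff_against(ord, reference)
    write_tsv_file(format_composition(comp),
                   file.path(out_dir, paste0(g$id, "_composition.tsv")))
    write_tsv_file(rs, file.path(out_dir, paste0(g$id, "_rscu.tsv")))
    write_tsv_file(cen, file.path(out_dir, paste0(g$id, "_census.tsv")))
    jsonlite::write_json(ev, file.path(out_dir, paste0(g$id, "_events.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    orders[[g$id]] <- ord
    results[[g$id]] <- list(composition = comp, rscu = rs, census = cen,
                            events = ev)
    inform(paste0("analyzed ", g$id, ": ", nrow(ev), " rearrangement event(s)"))
  }
  pats <- catalog_patterns(orders, reference)
  jsonlite::write_json(pats, file.path(out_dir, "patterns.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(paste0(nrow(pats), " distinct rearrangement pattern(s) across ",
                length(orders), " taxa"))
  invisible(list(genomes = results, patterns = pats))
}

write_tsv_file <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], function(col) {
    vapply(col, paste, character(1), collapse = ",")
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build and write the five supermatrices from per-gene alignments
#'
#' @param alignment_dir Directory of per-gene aligned FASTA files (file
#'   names identify the genes).
#' @param out_dir Output directory.
#' @param code A [genetic_code()].
#' @param fill Missing-taxon policy, see [build_bundle()].
#' @param codon_subpartitions Emit pos1/pos2 subpartitions?
#' @return Invisibly, the [build_bundle()] result.
#' @export
export_supermatrices <- function(alignment_dir, out_dir,
                                 code = genetic_code(),
                                 fill = c("error", "gaps"),
                                 codon_subpartitions = FALSE) {
  alns <- read_gene_alignments(alignment_dir)
  bundle <- build_bundle(alns, code = code, fill = match.arg(fill))
  write_bundle(bundle, out_dir, codon_subpartitions = codon_subpartitions)
  g <- glance(bundle)
  inform(paste0("matrix widths: ",
                paste(sprintf("%s=%d", g$matrix, g$width), collapse = ", ")))
  invisible(bundle)
}

#' Simulate a mitogenome and write it with its manifest
#'
#' @param spec A [synthetic_spec()], or the path to a YAML/JSON file whose
#'   top-level keys are `synthetic_spec()` arguments.
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_genome()] result. Outputs are
#'   byte-identical for identical spec and seed.
#' @export
simulate_mitogenome_files <- function(spec, out_dir) {
  if (is.character(spec)) spec <- load_spec_file(spec)
  stopifnot(inherits(spec, "synthetic_spec"))
  res <- generate_genome(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genbank(res$genome, file.path(out_dir, paste0(res$genome$id, ".gb")))
  man <- res$manifest
  man$gene_plan <- as.data.frame(man$gene_plan)
  jsonlite::write_json(man,
                       file.path(out_dir, paste0(res$genome$id, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

load_spec_file <- function(path) {
  args <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML specs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  if (!is.list(args)) abort(paste0("spec file is not a mapping: ", path))
  if (!is.null(args$site_composition)) {
    args$site_composition <- matrix(unlist(args$site_composition),
                                    nrow = 3, byrow = TRUE,
                                    dimnames = list(NULL, c("A", "T", "G", "C")))
  }
  for (nm in c("pcg_lengths", "rrna_lengths", "start_codon_weights",
               "codon_weights")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  bad <- setdiff(names(args), names(formals(synthetic_spec)))
  if (length(bad)) {
    abort(paste0("unknown spec field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(synthetic_spec, args)
}
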