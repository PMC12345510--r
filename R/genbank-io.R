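#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the LOCUS line (length, topology), the feature table and the ORIGIN
#' sequence of a GenBank record. `CDS`, `tRNA`, `rRNA`, `D-loop` and
#' control-region `misc_feature` entries become typed [mito_genome()]
#' features with names normalized via [normalize_gene_name()]; features whose
#' names cannot be normalized are kept with name `"unknown"` (they are still
#' counted in composition, but excluded from gene-order analysis, with a
#' warning). Any other feature keys are retained verbatim in the `extras`
#' table, never dropped. Coordinates are converted from GenBank's 1-based
#' inclusive convention to the package's 0-based half-open one; an
#' origin-spanning `join(a..L,1..b)` on a circular record becomes one
#' internal feature with `end > L`.
#'
#' @param path Path to a GenBank flat file with at least a LOCUS line, a
#'   feature table and an ORIGIN block.
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) abort(paste0("not a GenBank flat file (no LOCUS line): ", path))
  locus <- lines[locus_i[1]]
  topology <- if (grepl("\\bcircular\\b", locus, ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  ori_i <- grep("^ORIGIN", lines)
  if (!length(ori_i)) abort(paste0("GenBank record has no ORIGIN block: ", path))
  seq_lines <- lines[(ori_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) abort(paste0("empty ORIGIN sequence: ", path))
  len <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  feats <- tibble(name = character(), category = character(),
                  start = integer(), end = integer(), strand = character(),
                  raw_name = character())
  extras <- tibble(key = character(), location = character(), raw_name = character())
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1):(ori_i[1] - 1)]
    entries <- parse_feature_block(block, path)
    for (e in entries) {
      loc <- parse_gb_location(e$location, len, topology, path)
      raw <- e$name %||% NA_character_
      if (e$key %in% c("CDS", "tRNA", "rRNA")) {
        nm <- if (is.na(raw)) "unknown" else normalize_gene_name(raw)
        if (nm == "unknown") {
          warn(paste0("gene name not normalizable ('", raw %||% "", "'); ",
                      "feature kept but excluded from gene-order analysis"))
        }
        category <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[[e$key]]
        feats <- dplyr::bind_rows(feats, tibble(
          name = nm, category = category, start = loc$start, end = loc$end,
          strand = loc$strand, raw_name = raw %||% ""))
      } else if (e$key == "D-loop" ||
                 (e$key == "misc_feature" && !is.na(raw) &&
                  normalize_gene_name(raw) == "CR")) {
        feats <- dplyr::bind_rows(feats, tibble(
          name = "CR", category = "CR", start = loc$start, end = loc$end,
          strand = loc$strand, raw_name = raw %||% "D-loop"))
      } else if (e$key != "source") {
        extras <- dplyr::bind_rows(extras, tibble(
          key = e$key, location = e$location, raw_name = raw %||% ""))
      }
    }
  }
  mito_genome(id, sequence, feats, topology, extras = extras)
}

# Split a FEATURES block into entries of (key, location, qualifiers).
parse_feature_block <- function(block, path) {
  entries <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {                    # new feature
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) < 2) {
        abort(paste0("malformed feature line in ", path, ": '", ln, "'"))
      }
      cur <- list(key = parts[1], location = parts[2], name = NULL)
    } else if (!is.null(cur)) {
      t <- trimws(ln)
      if (startsWith(t, "/")) {
        m <- regmatches(t, regexec('^/(gene|product|note)="?([^"]*)"?$', t))[[1]]
        if (length(m)) {
          q <- m[2]; v <- m[3]
          # precedence: gene > product > note
          if (q == "gene" || is.null(cur$name) ||
              (q == "product" && isTRUE(cur$name_src == "note"))) {
            cur$name <- v
            cur$name_src <- q
          }
        }
      } else if (nzchar(t) && !startsWith(t, "/") && grepl("^[0-9.,()a-z<>]+$", t)) {
        cur$location <- paste0(cur$location, t)   # continued location line
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

# Parse a GenBank location string into 0-based half-open coordinates.
# Supports n..m, complement(...), join(...) and partial markers (< >).
# An origin-spanning join on a circular genome yields end > len.
parse_gb_location <- function(loc, len, topology, path = "<input>") {
  raw <- loc
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (!length(m)) {
      m1 <- regmatches(p, regexec("^([0-9]+)$", p))[[1]]
      if (!length(m1)) abort(paste0("unparseable location '", raw, "' in ", path))
      return(c(as.integer(m1[2]), as.integer(m1[2])))
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  if (length(rng) == 1) {
    s <- rng[[1]][1] - 1L; e <- rng[[1]][2]
  } else if (length(rng) == 2 && rng[[1]][2] == len && rng[[2]][1] == 1 &&
             topology == "circular") {
    s <- rng[[1]][1] - 1L
    e <- len + rng[[2]][2]
  } else {
    # non-wrapping multi-segment join: use the overall span
    s <- min(vapply(rng, `[`, integer(1), 1)) - 1L
    e <- max(vapply(rng, `[`, integer(1), 2))
  }
  list(start = s, end = as.integer(e), strand = strand)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a minimal but standard-conformant record (LOCUS, FEATURES, ORIGIN)
#' that [read_genbank()] round-trips exactly: names, 1-based inclusive
#' coordinates, strands and topology are preserved, and origin-wrapping
#' features are written as `join(a..L,1..b)`.
#'
#' @param genome A [mito_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  len <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     %s   UNA",
                     format(genome$id, width = 12), len, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    loc <- if (f$end > len) {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, len, f$end - len)
    } else {
      sprintf("%d..%d", f$start + 1L, f$end)
    }
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key_of[[f$category]], loc), con)
    nm <- if (nzchar(f$raw_name %||% "")) f$raw_name else f$name
    writeLines(sprintf('                     /gene="%s"', nm), con)
  }
  writeLines("ORIGIN", con)
  seq <- tolower(genome$sequence)
  starts <- seq(1L, len, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a mitogenome from FASTA plus a TSV feature table
#'
#' Annotation-free alternative input: the sequence from a single-record FASTA
#' and the features from a tab-separated table with columns `name`,
#' `category`, `start_1based`, `end_1based`, `strand` (1-based inclusive
#' coordinates, per the file convention; `end_1based < start_1based` denotes
#' an origin-wrapping feature on a circular genome).
#'
#' @param fasta_path Single-sequence FASTA file.
#' @param tsv_path Feature table path.
#' @param topology `"circular"` or `"linear"`.
#' @return A [mito_genome()].
#' @export
read_feature_table <- function(fasta_path, tsv_path,
                               topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1) abort("FASTA must contain exactly one sequence")
  len <- Biostrings::width(ss)[1]
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  needed <- c("name", "category", "start_1based", "end_1based", "strand")
  if (!all(needed %in% names(tab))) {
    abort(paste0("feature TSV needs columns: ", paste(needed, collapse = ", ")))
  }
  wraps <- tab$end_1based < tab$start_1based
  if (any(wraps) && topology != "circular") {
    abort("end < start implies an origin wrap, which requires a circular genome")
  }
  feats <- tibble(
    name = normalize_gene_name(tab$name),
    category = tab$category,
    start = as.integer(tab$start_1based) - 1L,
    end = as.integer(ifelse(wraps, tab$end_1based + len, tab$end_1based)),
    strand = tab$strand,
    raw_name = tab$name
  )
  mito_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]), feats, topology)
}

#' Extract a feature's sequence in reading orientation
#'
#' Slices the genomic span of a feature, concatenating across the origin for
#' wrapped features on circular genomes, and reverse-complements minus-strand
#' features so the result reads 5'→3' in the coding direction.
#'
#' @param genome A [mito_genome()].
#' @param feature A one-row slice of `genome$features`, a row index, or a
#'   canonical gene name present in the genome.
#' @return A DNA string (character scalar).
#' @export
region_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    idx <- which(genome$features$name == feature)
    if (!length(idx)) abort(paste0("no feature named '", feature, "'"))
    feature <- genome$features[idx[1], ]
  } else if (is.numeric(feature)) {
    feature <- genome$features[feature, ]
  }
  len <- nchar(genome$sequence)
  s <- feature$start[1]; e <- feature$end[1]
  seq <- if (e > len) {
    paste0(substr(genome$sequence, s + 1L, len), substr(genome$sequence, 1L, e - len))
  } else {
    substr(genome$sequence, s + 1L, e)
  }
  if (feature$strand[1] == "-") seq <- revcomp(seq)
  seq
}
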