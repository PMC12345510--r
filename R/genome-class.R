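#' Construct an annotated mitogenome
#'
#' The central container of the package: a DNA sequence plus an ordered table
#' of typed, stranded gene features. Coordinates are 0-based half-open
#' internally (1-based inclusive on all file I/O). On a circular genome a
#' feature may wrap the origin; it is then stored with `end > length(sequence)`
#' and its coordinates are interpreted modulo the genome length.
#'
#' @param id Accession or label.
#' @param sequence IUPAC DNA string (a single character scalar).
#' @param features Tibble with columns `name` (canonical token or
#'   `"unknown"`), `category` (`PCG`/`tRNA`/`rRNA`/`CR`), `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`). An optional `raw_name`
#'   column preserves the original spelling.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param extras Optional tibble of unclassified features retained verbatim.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, features, topology = c("circular", "linear"),
                        extras = NULL) {
  topology <- match.arg(topology)
  sequence <- as_dna(sequence)
  len <- nchar(sequence)
  if (len == 0) abort("mitogenome sequence must be non-empty")
  features <- as_tibble(features)
  if (!"raw_name" %in% names(features)) features$raw_name <- features$name
  needed <- c("name", "category", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    abort(paste0("features table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  features <- features[, c(needed, "raw_name")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 0) || any(features$end <= features$start)) {
    abort("feature coordinates must satisfy 0 <= start < end")
  }
  if (topology == "linear" && any(features$end > len)) {
    abort("feature exceeds sequence length on a linear genome")
  }
  if (any(features$end - features$start > len)) {
    abort("feature longer than the genome")
  }
  if (!all(features$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  dup <- features$name[features$name != "unknown"][
    duplicated(features$name[features$name != "unknown"])]
  if (length(dup)) {
    abort(paste0("duplicate canonical gene feature(s): ", paste(unique(dup), collapse = ", ")))
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         features = features, extras = extras %||% tibble()),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s, %d features\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features)))
  print(feature_census(x))
  invisible(x)
}

#' Census of annotated features by category
#'
#' @param genome A [mito_genome()].
#' @return Tibble with one row per category (`PCG`, `tRNA`, `rRNA`, `CR`):
#'   number of features and summed span length in bp.
#' @export
feature_census <- function(genome) {
  feats <- genome$features
  cats <- c("PCG", "tRNA", "rRNA", "CR")
  feats |>
    dplyr::filter(.data$category %in% cats) |>
    dplyr::mutate(category = factor(.data$category, levels = cats)) |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     total_bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::mutate(category = as.character(.data$category),
                  total_bp = as.integer(.data$total_bp))
}

#' @rdname feature_census
#' @param x A [mito_genome()].
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.mito_genome <- function(x, ...) {
  cen <- feature_census(x)
  tibble(
    id = x$id,
    length = nchar(x$sequence),
    topology = x$topology,
    n_pcg = cen$n[cen$category == "PCG"],
    n_trna = cen$n[cen$category == "tRNA"],
    n_rrna = cen$n[cen$category == "rRNA"],
    n_cr = cen$n[cen$category == "CR"]
  )
}
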