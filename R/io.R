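#' Read a tab-delimited count matrix
#'
#' Reads a features-by-samples count table. The first column must be
#' `feature_id`; an optional `length` column (bp) carries feature lengths for
#' RPKM normalization; all remaining columns are per-sample counts. Lines
#' starting with `#` are ignored.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `feature_id`, optionally `length`, and one
#'   integer column per sample.
#' @details Counts must be non-negative integers; a violating cell raises an
#'   error naming its row and column. Ragged rows raise an error naming the
#'   offending line.
#' @export
read_counts <- function(path) {
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#",
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed count table '%s': line %d (expected %s, got %s)",
                  path, probs$row[1], probs$expected[1], probs$actual[1]))
  }
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(sprintf("count table '%s' is empty or has no sample columns", path))
  }
  if (names(df)[1] != "feature_id") names(df)[1] <- "feature_id"
  scols <- setdiff(names(df), c("feature_id", "length"))
  for (cn in c(intersect("length", names(df)), scols)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | v < 0 | (cn %in% scols & v != floor(v)))
    if (length(bad)) {
      abort(sprintf("count table '%s': non-integer or negative value '%s' at row %d, column '%s'",
                    path, df[[cn]][bad[1]], bad[1], cn))
    }
    df[[cn]] <- if (cn == "length") v else as.integer(v)
  }
  as_tibble(df)
}

#' Write a count matrix as TSV
#' @param counts Count tibble as returned by [read_counts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a BED file of peak intervals
#'
#' Intervals are 0-based half-open, the BED convention. Peaks are sorted by
#' (chrom, start) on load; missing names get `peak_0001`-style identifiers.
#'
#' @param path Path to a BED file with 3-6 columns (no header).
#' @return A tibble with columns `peak_id`, `chrom`, `start`, `end`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) abort(sprintf("BED file '%s' is empty", path))
  if (ncol(df) < 3) abort(sprintf("BED file '%s' has fewer than 3 columns", path))
  out <- tibble(
    chrom = df[[1]],
    start = as.numeric(df[[2]]),
    end   = as.numeric(df[[3]]),
    peak_id = if (ncol(df) >= 4) df[[4]] else sprintf("peak_%04d", seq_len(nrow(df))),
    score = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else 0,
    strand = if (ncol(df) >= 6) df[[6]] else "."
  )
  if (anyNA(out$start) || anyNA(out$end)) abort(sprintf("BED file '%s': non-numeric coordinates", path))
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("BED file '%s': start >= end at line %d (%s:%s-%s)", path,
                  bad[1], out$chrom[bad[1]], out$start[bad[1]], out$end[bad[1]]))
  }
  if (anyDuplicated(out$peak_id)) abort(sprintf("BED file '%s': duplicate peak ids", path))
  out |>
    arrange(.data$chrom, .data$start, .data$end) |>
    select("peak_id", "chrom", "start", "end", "score", "strand")
}

#' Write peaks as 6-column BED
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end` and
#'   optionally `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  assert_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  bed <- tibble(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = peaks$peak_id,
    score = peaks$score %||% 0,
    strand = peaks$strand %||% "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample_id`, `lineage`, `subset`,
#'   `stim`, `donor`.
#' @return A tibble. `sample_id` must be unique; a TEMRA subset outside the
#'   CD8 lineage triggers a warning (the sorting scheme collects TEMRA from
#'   CD8 only) but is kept.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("sample_id", "lineage", "subset", "stim", "donor"), "sample sheet")
  validate_sample_sheet(as_tibble(df))
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) abort("sample sheet: duplicate sample_id")
  if (!all(df$lineage %in% c("CD4", "CD8"))) abort("sample sheet: lineage must be CD4 or CD8")
  if (!all(df$subset %in% c("naive", "TCM", "TEM", "TEMRA"))) {
    abort("sample sheet: subset must be one of naive, TCM, TEM, TEMRA")
  }
  if (!all(df$stim %in% c("unstim", "stim"))) abort("sample sheet: stim must be unstim or stim")
  if (any(df$subset == "TEMRA" & df$lineage != "CD8")) {
    warn("sample sheet: TEMRA samples outside the CD8 lineage")
  }
  df
}

#' Write a sample sheet as TSV
#' @inheritParams write_counts
#' @param samples Sample sheet tibble.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotation
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length` (0-based half-open coordinates).
#' @return A tibble with a `tss` column added: the start for `+` genes and
#'   the end for `-` genes.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("gene_id", "chrom", "start", "end", "strand", "length"), "gene annotation")
  if (!all(df$strand %in% c("+", "-"))) abort("gene annotation: strand must be '+' or '-'")
  if (any(df$length <= 0)) abort("gene annotation: non-positive gene length")
  df |> mutate(tss = if_else(.data$strand == "+", .data$start, .data$end)) |> as_tibble()
}

#' Write gene annotation as TSV
#' @param genes Gene annotation tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_annotation <- function(genes, path) {
  readr::write_tsv(select(genes, "gene_id", "chrom", "start", "end", "strand", "length"),
                   path, progress = FALSE)
  invisible(path)
}

#' Read a MEME-minimal motif library
#'
#' Parses `MOTIF <id>` blocks followed by a position count matrix, one row
#' per position with four whitespace-separated counts (A, C, G, T). A
#' `Background letter frequencies` line, if present, sets the background
#' model; the default is uniform. Counts are converted to probabilities with
#' a pseudocount of 0.5 per cell: `p = (count + 0.5) / (rowsum + 2)`.
#'
#' @param path Path to a motif file.
#' @return A `motif_library`: a tibble with columns `motif_id`, `width`,
#'   `pcm` (list of 4 x width count matrices, rows A/C/G/T), `ppm` (list of
#'   probability matrices), carrying the background frequencies as an
#'   attribute.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
    if (abs(sum(bg) - 1) > 1e-6) abort("motif background frequencies do not sum to 1")
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) abort(sprintf("no MOTIF blocks found in '%s'", path))
  parse_block <- function(i) {
    id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[(starts[i] + 1L):to]
    rows <- grep("^\\s*[0-9.]+(\\s+[0-9.]+){3}\\s*$", block, value = TRUE)
    if (!length(rows)) abort(sprintf("motif '%s' has width 0", id))
    pcm <- t(vapply(strsplit(trimws(rows), "\\s+"), as.numeric, numeric(4)))
    colnames(pcm) <- c("A", "C", "G", "T")
    if (any(rowSums(pcm) <= 0)) {
      abort(sprintf("motif '%s': position with all-zero counts", id))
    }
    pcm <- t(pcm)  # 4 x width, rows A/C/G/T
    ppm <- (pcm + 0.5) / rep(colSums(pcm) + 2, each = 4)
    list(motif_id = id, width = ncol(pcm), pcm = pcm, ppm = ppm)
  }
  blocks <- lapply(seq_along(starts), parse_block)
  lib <- tibble(
    motif_id = vapply(blocks, `[[`, character(1), "motif_id"),
    width = vapply(blocks, `[[`, integer(1), "width"),
    pcm = lapply(blocks, `[[`, "pcm"),
    ppm = lapply(blocks, `[[`, "ppm")
  )
  attr(lib, "background") <- bg
  class(lib) <- c("motif_library", class(lib))
  lib
}

#' Write a motif library in MEME-minimal format
#' @param motifs A `motif_library` as returned by [read_motifs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motifs <- function(motifs, path) {
  bg <- attr(motifs, "background") %||% c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME-minimal motif library", "",
               "Background letter frequencies",
               sprintf("A %g C %g G %g T %g", bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (i in seq_len(nrow(motifs))) {
    writeLines(sprintf("MOTIF %s", motifs$motif_id[i]), con)
    pcm <- motifs$pcm[[i]]
    writeLines(apply(pcm, 2, function(col) paste(format(col, trim = TRUE), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
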