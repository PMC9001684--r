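# Standard-format I/O.
#
# Interchange dialect: TSV (tab-separated, UTF-8, header row) for primer
# sets, candidate dumps and score/count matrices; FASTA/FASTQ via
# Biostrings for sequences. All coordinates in files are 0-based,
# half-open, matching BED conventions.

#' Write target regions to FASTA + TSV
#'
#' @param regions list of [target_region()] objects.
#' @param fasta_path,tsv_path output paths. The TSV has columns
#'   `target_id`, `fasta_id`, `pivot_start`, `pivot_end` (0-based
#'   half-open), `min_amplicon`, `max_amplicon`.
#' @return invisibly, the TSV data.frame.
#' @export
write_targets <- function(regions, fasta_path, tsv_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(regions, `[[`, character(1L), "template"))
  names(seqs) <- vapply(regions, `[[`, character(1L), "target_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  tab <- data.frame(
    target_id = names(seqs), fasta_id = names(seqs),
    pivot_start = vapply(regions, `[[`, integer(1L), "pivot_start"),
    pivot_end = vapply(regions, `[[`, integer(1L), "pivot_end"),
    min_amplicon = vapply(regions, `[[`, integer(1L), "min_amplicon_len"),
    max_amplicon = vapply(regions, `[[`, integer(1L), "max_amplicon_len"))
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read target regions from FASTA + TSV
#'
#' @param fasta_path multi-record FASTA of templates.
#' @param tsv_path targets TSV as written by [write_targets()].
#' @return list of [target_region()] objects.
#' @export
read_targets <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- read.table(tsv_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    template <- as.character(seqs[[tab$fasta_id[i]]])
    target_region(tab$target_id[i], template,
                  tab$pivot_start[i], tab$pivot_end[i],
                  min_amplicon_len = tab$min_amplicon[i],
                  max_amplicon_len = tab$max_amplicon[i])
  })
}

#' Write / read a primer-set table
#'
#' @param tab data.frame from [primer_set_table()].
#' @param path TSV path.
#' @return `read_primer_set` returns the data.frame.
#' @export
write_primer_set <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_primer_set
#' @export
read_primer_set <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a square score or count matrix as TSV
#'
#' Layout: header row and first column carry primer labels; cell (i, j) is
#' the value for the ordered primer pair (i, j).
#'
#' @param m square numeric matrix.
#' @param path TSV path.
#' @param labels primer labels; defaults to `p1..p2N`.
#' @return `read_pair_matrix` returns the matrix with dimnames.
#' @export
write_pair_matrix <- function(m, path, labels = NULL) {
  labels <- labels %||% paste0("p", seq_len(nrow(m)))
  out <- data.frame(primer = labels, m)
  names(out) <- c("primer", labels)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

#' Pairwise badness matrix of a primer list
#'
#' @param primers character vector (conventionally fPs then rPs).
#' @return symmetric `length(primers)` square matrix; entry (a, b) is
#'   [badness_pair()] of primers a and b, the diagonal holds self terms.
#' @export
badness_matrix <- function(primers) {
  profs <- lapply(primers, primer_profile)
  n <- length(profs)
  m <- matrix(0, n, n)
  for (a in seq_len(n)) {
    m[a, a] <- profs[[a]]$self
    if (a < n)
      for (b in seq.int(a + 1L, n))
        m[a, b] <- m[b, a] <- badness_pair(profs[[a]], profs[[b]])
  }
  m
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame from [simulate_reads()] (columns `read_id`,
#'   `sequence`), or any data.frame with those columns.
#' @param path output FASTQ path (uncompressed).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence),
           function(n) paste(rep("I", n), collapse = ""), character(1L)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(seqs), sequence = as.character(seqs))
}

#' Write a JSON run manifest
#'
#' Records package version, seed and configuration of a run alongside its
#' outputs so results are reproducible.
#'
#' @param path output JSON path.
#' @param seed RNG seed used.
#' @param config configuration list (serialized as-is, functions dropped).
#' @param extra optional named list of additional fields.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(path, seed, config = list(), extra = list()) {
  strip <- function(x) {
    if (is.list(x)) lapply(x[!vapply(x, is.function, logical(1L))], strip)
    else x
  }
  manifest <- c(list(
    package = "plexanneal",
    version = as.character(utils::packageVersion("plexanneal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = strip(unclass(config))), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
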