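#' Write / read an abundance matrix as TSV with sidecar metadata
#'
#' The matrix goes to `<path>` (first column `protein`, then one column
#' per sample) and the sample metadata to `<path>` with a `.meta.tsv`
#' suffix (sample, condition, batch, replicate, is_control).
#'
#' @param x An `abundance_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(protein = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$sample_meta, meta_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(meta_path(path))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  abundance_matrix(vals, meta)
}

meta_path <- function(path) sub("(\\.tsv)?$", ".meta.tsv", path,
                                perl = TRUE)

#' Write / read a spectral-count table as long-format TSV
#'
#' Counts go to `<path>` (run, bait, prey, count), run metadata to the
#' `.meta.tsv` sidecar (run, bait), and lengths to the `.lengths.tsv`
#' sidecar (protein, length).
#'
#' @param x A `spectral_count_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "spectral_count_table"))
  utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$runs, meta_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(protein = names(x$lengths), length = unname(x$lengths)),
    sub("(\\.tsv)?$", ".lengths.tsv", path, perl = TRUE),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_counts_tsv
#' @export
read_spectral_counts_tsv <- function(path) {
  counts <- utils::read.delim(path)
  runs <- utils::read.delim(meta_path(path))
  lt <- utils::read.delim(sub("(\\.tsv)?$", ".lengths.tsv", path,
                              perl = TRUE))
  spectral_count_table(counts, runs,
                       stats::setNames(lt$length, lt$protein))
}

#' Protein lengths from a FASTA file
#'
#' @param path FASTA of amino-acid sequences.
#' @return Named integer vector, id -> residue count.
#' @export
lengths_from_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(Biostrings::width(seqs),
                  sub("\\s.*$", "", names(seqs)))
}

#' Write / read a multichannel image as 16-bit grayscale TIFF
#'
#' One single-channel 16-bit TIFF per channel, named
#' `<prefix>_<channel>.tif`. Intensities are stored as-is (clamped to
#' [0, 65535]).
#'
#' @param image A `multichannel_image`.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_field_tiff <- function(image, prefix) {
  stopifnot(inherits(image, "multichannel_image"))
  paths <- character()
  for (ch in names(image$channels)) {
    p <- paste0(prefix, "_", ch, ".tif")
    m <- pmin(pmax(image$channels[[ch]], 0), 65535) / 65535
    tiff::writeTIFF(m, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_tiff
#' @param pixel_size Micrometres per pixel to record on the read image.
#' @export
read_field_tiff <- function(prefix, pixel_size = 1) {
  ch <- lapply(c(nuclei = "nuclei", pts1 = "pts1", pmp70 = "pmp70"),
               function(nm) {
                 m <- tiff::readTIFF(paste0(prefix, "_", nm, ".tif"))
                 m * 65535
               })
  structure(list(channels = ch, pixel_size = pixel_size),
            class = "multichannel_image")
}

#' Write a similarity matrix as TSV with a kind tag
#'
#' @param sim A `similarity_matrix`.
#' @param path Output TSV path; the kind is written as a `# kind:` header
#'   line.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", sim$kind), con)
  utils::write.table(data.frame(label = sim$labels, sim$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as plain-text node and edge lists
#'
#' @param network An `annotated_network`.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return The written paths, invisibly.
#' @export
write_network_tsv <- function(network, prefix) {
  stopifnot(inherits(network, "annotated_network"))
  pn <- paste0(prefix, "_nodes.tsv")
  pe <- paste0(prefix, "_edges.tsv")
  utils::write.table(network$nodes, pn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$edges, pe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pn, pe))
}
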