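# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines
# ignored, no quoting; missing values are format errors, not NA.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = character())
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids formatted `genotype_condition_rep`
#' (e.g. `OE_drought_3`), a first column of gene ids, and numeric cells.
#' Malformed input fails fast: duplicate gene ids, non-numeric cells (named
#' with their row/column coordinates) and unparseable sample headers are
#' errors.
#'
#' @param path TSV file path.
#' @return an [expression_matrix].
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1])
  sample_ids <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %s",
                   col[bad[1]], bad[1], ids[bad[1]], sample_ids[j]))
    }
    m[, j] <- num
  }
  expression_matrix(m, .parse_sample_ids(sample_ids))
}

.parse_sample_ids <- function(sample_ids) {
  parts <- regmatches(sample_ids,
                      regexec("^([A-Za-z0-9.]+)_([A-Za-z0-9.]+)_([0-9]+)$",
                              sample_ids))
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) {
    stop("unparseable sample header (want genotype_condition_rep): ",
         sample_ids[bad][1])
  }
  data.frame(sample = sample_ids,
             genotype = vapply(parts, `[`, "", 2L),
             condition = vapply(parts, `[`, "", 3L),
             replicate = as.integer(vapply(parts, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] on its own output (round-trip identity on
#' values and labels).
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  v <- expr_values(expr)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a gene annotation table (TF vs structural)
#'
#' Two-column TSV (`gene`, `class`); the class must be `TF` or `structural`,
#' anything else is a format error. An empty table yields an empty mapping
#' with a warning.
#'
#' @param path TSV file path.
#' @return named character vector, gene id -> class.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  if (!nrow(df)) {
    warning("empty annotation file: ", path)
    return(stats::setNames(character(), character()))
  }
  if (ncol(df) < 2) stop("annotation TSV needs two columns (gene, class)")
  cls <- as.character(df[[2]])
  bad <- setdiff(unique(cls), c("TF", "structural"))
  if (length(bad)) {
    stop("unknown gene class label: ", bad[1], " (allowed: TF, structural)")
  }
  stats::setNames(cls, as.character(df[[1]]))
}

#' Write a gene annotation table
#' @param annotation named character vector (gene -> `TF`/`structural`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  .write_tsv(data.frame(gene = names(annotation), class = unname(annotation),
                        stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Write a layered network (edge list TSV + JSON summary + orphan TSV)
#'
#' Produces `<prefix>_edges.tsv` (columns `regulator`, `target`,
#' `regulator_layer`, `target_layer`, `min_pcc`), `<prefix>_summary.json`
#' (per-layer gene counts, per-interlayer edge counts, total) and, when any
#' exist, `<prefix>_orphans.tsv`.
#'
#' @param net a [layered_network()].
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "layered_network"))
  e <- net$edges
  if (!"min_pcc" %in% names(e)) e$min_pcc <- NA_real_
  edges_path <- paste0(prefix, "_edges.tsv")
  .write_tsv(e[, c("regulator", "target", "regulator_layer", "target_layer",
                   "min_pcc")], edges_path)
  json_path <- paste0(prefix, "_summary.json")
  s <- net$summary
  jsonlite::write_json(
    list(layer_sizes = s$layer_sizes, edge_counts = s$edge_counts,
         total = s$total,
         layers = as.list(stats::setNames(as.integer(net$layers),
                                          names(net$layers)))),
    json_path, auto_unbox = TRUE, digits = NA)
  written <- c(edges_path, json_path)
  if (nrow(net$orphan_edges)) {
    orphan_path <- paste0(prefix, "_orphans.tsv")
    .write_tsv(net$orphan_edges, orphan_path)
    written <- c(written, orphan_path)
  }
  invisible(written)
}

#' Read a layered network written by [write_network()]
#' @param prefix the path prefix used when writing.
#' @return a [layered_network()].
#' @export
read_network <- function(prefix) {
  e <- .read_tsv(paste0(prefix, "_edges.tsv"))
  s <- jsonlite::read_json(paste0(prefix, "_summary.json"),
                           simplifyVector = TRUE)
  orphan_path <- paste0(prefix, "_orphans.tsv")
  orphans <- if (file.exists(orphan_path)) .read_tsv(orphan_path) else NULL
  layers <- stats::setNames(as.integer(unlist(s$layers)), names(s$layers))
  layered_network(layers, e[, setdiff(names(e),
                                      c("regulator_layer", "target_layer"))],
                  orphans)
}

#' Write promoter sequences with their ground-truth log as FASTA
#'
#' The FASTA description of each record carries the planted-element log as
#' `element:strand:core_start` tokens, so the ground truth travels with the
#' sequences.
#'
#' @param promoters the list returned by [generate_promoters()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- promoters$sequences
  log <- promoters$log
  desc <- vapply(names(seqs), function(g) {
    rows <- log[log$gene == g, , drop = FALSE]
    if (!nrow(rows)) return(g)
    paste(g, paste(sprintf("%s:%s:%d", rows$element, rows$strand,
                           rows$core_start), collapse = " "))
  }, "")
  names(seqs) <- desc
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a promoter FASTA (ground-truth log recovered from descriptions)
#' @param path FASTA path written by [write_promoters()] (plain FASTA also
#'   works; the log is then empty).
#' @return list with `sequences` (named `DNAStringSet`) and `log` (data.frame
#'   `gene`, `element`, `strand`, `core_start`).
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  full <- names(seqs)
  gene <- sub("\\s.*$", "", full)
  log <- list()
  for (i in seq_along(full)) {
    rest <- sub("^\\S+\\s*", "", full[i])
    if (!nzchar(rest)) next
    toks <- strsplit(rest, "\\s+")[[1]]
    parts <- strsplit(toks, ":", fixed = TRUE)
    log[[i]] <- data.frame(
      gene = gene[i],
      element = vapply(parts, `[`, "", 1L),
      strand = vapply(parts, `[`, "", 2L),
      core_start = as.integer(vapply(parts, `[`, "", 3L)),
      stringsAsFactors = FALSE)
  }
  names(seqs) <- gene
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(gene = character(), element = character(),
               strand = character(), core_start = integer())
  list(sequences = seqs, log = log)
}

#' Write / read a verification record table
#' @param records data.frame as produced by [simulate_verification_table()].
#' @param path TSV path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_verification <- function(records, path) {
  .write_tsv(records, path)
  invisible(path)
}

#' @rdname write_verification
#' @export
read_verification <- function(path) {
  df <- .read_tsv(path)
  df$chip_fragments <- as.character(df$chip_fragments)
  df
}

#' Convert between upstream promoter coordinates and sequence indices
#'
#' Upstream coordinates run `-region_length .. -1`, with `-1` the base
#' adjacent to the transcription start; sequence indices are 1-based from the
#' 5' end of the stored promoter.
#'
#' @param coord upstream coordinate(s), negative.
#' @param i sequence index(es), 1-based.
#' @param region_length promoter length in bp.
#' @return the converted coordinate(s).
#' @export
upstream_to_index <- function(coord, region_length) {
  stopifnot(all(coord >= -region_length), all(coord <= -1))
  as.integer(coord + region_length + 1)
}

#' @rdname upstream_to_index
#' @export
index_to_upstream <- function(i, region_length) {
  stopifnot(all(i >= 1), all(i <= region_length))
  as.integer(i - region_length - 1)
}

#' Write a planted network as TSV edge list + JSON sidecar
#'
#' @param net a `planted_network`.
#' @param prefix output path prefix; writes `<prefix>_truth_edges.tsv` and
#'   `<prefix>_truth.json` (layer membership and seed).
#' @return files written, invisibly.
#' @export
write_planted_network <- function(net, prefix) {
  stopifnot(inherits(net, "planted_network"))
  edges_path <- paste0(prefix, "_truth_edges.tsv")
  .write_tsv(net$edges, edges_path)
  json_path <- paste0(prefix, "_truth.json")
  jsonlite::write_json(
    list(root_tf = net$root_tf, layer2 = net$layer2, layer3 = net$layer3,
         layer4 = net$layer4, seed = net$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edges_path, json_path))
}

#' Read a planted network written by [write_planted_network()]
#' @param prefix the path prefix used when writing.
#' @return a `planted_network`.
#' @export
read_planted_network <- function(prefix) {
  edges <- .read_tsv(paste0(prefix, "_truth_edges.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                              simplifyVector = TRUE)
  structure(list(root_tf = meta$root_tf, layer2 = meta$layer2,
                 layer3 = meta$layer3, layer4 = meta$layer4,
                 edges = edges, seed = as.integer(meta$seed)),
            class = "planted_network")
}
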