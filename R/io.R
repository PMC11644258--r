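# Flat-file round-tripping: tab-separated, header-bearing files
# throughout, plus SIF for network viewers. Writers prepend '#'-prefixed
# provenance lines; readers skip them. Numeric text uses 9 significant
# digits.

.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

.check_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    x <- df[[cn]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
      stop(sprintf("non-numeric value in column '%s' of %s (data row %d)",
                   cn, path, bad))
    }
  }
}

#' Write / read an expression matrix as TSV
#'
#' The matrix file has genes in rows (first column `gene`) and one column
#' per sample; the companion metadata file has columns `sample_id`,
#' `time_dap`, `replicate`.
#'
#' @param expr an [expression_set].
#' @param path matrix file path.
#' @param meta_path sample metadata file path.
#' @param header_lines optional provenance lines (written '#'-prefixed).
#' @return `write_expression_tsv` returns `expr` invisibly;
#'   `read_expression_tsv` returns an [expression_set].
#' @export
write_expression_tsv <- function(expr, path, meta_path,
                                 header_lines = character()) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path, header_lines)
  .write_tsv(expr$samples, meta_path, header_lines)
  invisible(expr)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, meta_path) {
  df <- .read_tsv(path)
  if (anyDuplicated(df$gene))
    stop("duplicate gene ids in ", path)
  meta <- .read_tsv(meta_path)
  .check_numeric_cols(meta, c("time_dap", "replicate"), meta_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s (data row %d, column %d)",
                 path, bad[1], bad[2] + 1L))
  }
  rownames(m) <- df$gene
  m <- m[, meta$sample_id, drop = FALSE]
  expression_set(m, time_dap = meta$time_dap, replicate = meta$replicate,
                 sample_id = meta$sample_id)
}

#' Write / read a ground-truth network as 4-column TSV
#'
#' Columns: `source`, `target`, `sign` (+1/-1), `strength`.
#'
#' @param net a [gt_network].
#' @param path file path.
#' @param genes,regulators gene/regulator sets for reading; default to
#'   the ids present in the file.
#' @param header_lines optional provenance lines.
#' @export
write_gt_network_tsv <- function(net, path, header_lines = character()) {
  .write_tsv(net$edges, path, header_lines)
  invisible(net)
}

#' @rdname write_gt_network_tsv
#' @export
read_gt_network_tsv <- function(path, genes = NULL, regulators = NULL) {
  df <- .read_tsv(path)
  .check_numeric_cols(df, c("sign", "strength"), path)
  gt_network(genes %||% sort(unique(c(df$source, df$target))),
             regulators %||% sort(unique(df$source)), df)
}

#' Write / read an inferred network as signed edge-list TSV
#'
#' Columns: `source`, `target`, `weight`, `sign`, `support`.
#'
#' @param net a [grn].
#' @param path file path.
#' @param nodes node set for reading (defaults to edge endpoints).
#' @param header_lines optional provenance lines.
#' @export
write_grn_tsv <- function(net, path, header_lines = character()) {
  .write_tsv(net$edges, path, header_lines)
  invisible(net)
}

#' @rdname write_grn_tsv
#' @export
read_grn_tsv <- function(path, nodes = NULL) {
  df <- .read_tsv(path)
  .check_numeric_cols(df, "weight", path)
  grn(df, nodes = nodes)
}

#' Write / read a network in SIF format
#'
#' One edge per line: `source <sign-word> target`, tab-separated; the
#' sign word is one of promoting/repressing/regulating.
#'
#' @param net a [grn].
#' @param path file path.
#' @param nodes node set for reading (defaults to edge endpoints).
#' @export
write_sif <- function(net, path) {
  writeLines(paste(net$edges$source, net$edges$sign, net$edges$target,
                   sep = "\t"), path)
  invisible(net)
}

#' @rdname write_sif
#' @export
read_sif <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(grn(data.frame(), nodes = nodes))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed SIF line %d in %s", bad[1], path))
  grn(data.frame(source = vapply(parts, `[`, "", 1),
                 target = vapply(parts, `[`, "", 3),
                 sign = vapply(parts, `[`, "", 2),
                 stringsAsFactors = FALSE),
      nodes = nodes)
}

#' Write / read a gene set (one id per line)
#'
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(genes)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  x <- sub("\r$", "", readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gene annotation table
#'
#' TSV with columns `gene` and `identifiers` (semicolon-separated
#' GO/InterPro/PFam/PANTHER accessions).
#'
#' @param path file path.
#' @return Named list mapping gene id to identifier vector.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene", "identifiers") %in% names(df)))
    stop("annotation table needs 'gene' and 'identifiers' columns: ", path)
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in ", path)
  stats::setNames(lapply(strsplit(df$identifiers, ";", fixed = TRUE),
                         trimws), df$gene)
}
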