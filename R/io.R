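#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are numeric log2-scale values. Empty cells
#' and the tokens "NA"/"NaN" (case-insensitive) are read as missing, since
#' GEO-derived exports vary in how they encode missingness.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows, with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    stop("ragged row(s) at line(s): ",
         paste(which(widths != n_col) + 1L, collapse = ", "))
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  cells <- vapply(body, function(f) f[-1L], character(n_col - 1L))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  vals <- .parse_numeric_cells(cells)
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

# Missing tokens: "", "NA", "NaN" (case-insensitive). Anything else
# non-numeric is a parse error naming the offending line.
.parse_numeric_cells <- function(cells) {
  flat <- as.vector(cells)
  missing <- flat == "" | tolower(flat) %in% c("na", "nan")
  out <- suppressWarnings(as.numeric(flat))
  bad <- !missing & is.na(out)
  if (any(bad)) {
    rows <- unique(((which(bad) - 1L) %% nrow(cells)) + 1L)
    stop("non-numeric cell(s) at data line(s): ", paste(rows + 1L, collapse = ", "))
  }
  out[missing] <- NA_real_
  matrix(out, nrow = nrow(cells))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: round-tripping reproduces ids and
#' values to text float precision. Missing values are written as "NA".
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r) paste(format(r, digits = 15, trim = TRUE),
                                           collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Columns: `sample_id`, `group` (AS/HC), optional `batch`, optional
#' `severity` (0-10 disease-activity score, missing for controls).
#'
#' @param path CSV path.
#' @return data.frame with at least sample_id and group columns.
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("phenotype table needs sample_id and group columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype table")
  if (anyNA(df$group)) stop("missing group labels in phenotype table")
  df
}

#' @rdname read_phenotypes_csv
#' @param phenotypes Phenotype data.frame.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, all
#' tab-separated. Duplicate members within a set are dropped, preserving
#' first occurrence.
#'
#' @param path GMT path.
#' @return Named list of character vectors; set descriptions are kept in
#'   the "descriptions" attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line(s) with fewer than 3 fields: ", paste(short, collapse = ", "))
  }
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_)) stop("duplicate gene-set names in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1L), 2L), names_)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (optionally with a
#'   "descriptions" attribute).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction edge list
#'
#' TSV with two node columns and an optional third numeric score column
#' (STRING-export style). Self-loops are removed, duplicate edges
#' collapsed, and node pairs canonicalized to lexicographic order so the
#' result is a simple undirected edge list.
#'
#' @param path TSV path; a header line is detected (non-numeric third
#'   column on line 1 with a numeric third column later) and skipped.
#' @param score_threshold Minimum score; edges strictly below it are
#'   dropped. Ignored when the file has no score column.
#' @return data.frame with columns node_a, node_b and (if present) score.
#' @export
read_edge_list <- function(path, score_threshold = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("edge-list line(s) with fewer than 2 columns: ",
         paste(which(lengths(fields) < 2L), collapse = ", "))
  }
  has_score <- all(lengths(fields) >= 3L)
  if (has_score && length(fields) > 1L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
    fields <- fields[-1L]  # header line
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  score <- if (has_score) {
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
    if (anyNA(s)) stop("non-numeric score in edge list")
    s
  } else NULL
  if (!is.null(score)) {
    keep <- score >= score_threshold
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (!is.null(score)) score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(node_a = lo[!dup], node_b = hi[!dup],
                    stringsAsFactors = FALSE)
  if (!is.null(score)) out$score <- score[!dup]
  if (nrow(out) == 0L) warning("edge list is empty after filtering")
  out
}

#' @rdname read_edge_list
#' @param edges data.frame as returned by `read_edge_list`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an igraph from an edge list (plus optional isolated nodes)
#'
#' @param edges data.frame with node_a/node_b columns.
#' @param nodes Optional full node universe (isolated nodes retained).
#' @return Undirected simple igraph with vertices ordered by name.
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  verts <- sort(unique(c(edges$node_a, edges$node_b, nodes)))
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Read a GEO series-matrix file
#'
#' Parses the `!`-prefixed metadata block and the probe x sample table
#' between the `!series_matrix_table_begin` / `!series_matrix_table_end`
#' sentinels. The case/control group is inferred by matching a regular
#' expression against one of the `!Sample_characteristics_ch1` lines (GEO
#' metadata is free text, so the key and pattern are configurable).
#'
#' @param path Series-matrix text file (uncompressed).
#' @param group_key Regex selecting which characteristics line carries the
#'   group annotation.
#' @param case_pattern Regex; samples whose selected characteristic matches
#'   it are labelled `case_label`, all others `control_label`.
#' @param case_label,control_label Group labels to assign.
#' @return list(expression = probe x sample matrix,
#'   phenotypes = data.frame(sample_id, group)).
#' @export
read_series_matrix <- function(path, group_key = "disease|group|status",
                               case_pattern = "AS",
                               case_label = "AS", control_label = "HC") {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg) {
    stop("series-matrix table sentinels missing or malformed")
  }
  tab <- lines[(beg + 1L):(end - 1L)]
  fields <- strsplit(tab, "\t", fixed = TRUE)
  strip <- function(x) gsub('^"|"$', "", x)
  sample_ids <- strip(fields[[1L]][-1L])
  body <- fields[-1L]
  probes <- strip(vapply(body, `[[`, character(1L), 1L))
  cells <- t(vapply(body, function(f) strip(f[-1L]), character(length(sample_ids))))
  vals <- .parse_numeric_cells(cells)
  dimnames(vals) <- list(probes, sample_ids)

  char_lines <- lines[grepl("^!Sample_characteristics_ch1", lines)]
  group <- rep(control_label, length(sample_ids))
  hit <- FALSE
  for (cl in char_lines) {
    f <- strip(strsplit(cl, "\t", fixed = TRUE)[[1L]][-1L])
    if (any(grepl(group_key, f, ignore.case = TRUE))) {
      group <- ifelse(grepl(case_pattern, f), case_label, control_label)
      hit <- TRUE
      break
    }
  }
  if (!hit && length(char_lines)) {
    warning("no characteristics line matched group_key; all samples labelled ",
            control_label)
  }
  list(expression = vals,
       phenotypes = data.frame(sample_id = sample_ids, group = group,
                               stringsAsFactors = FALSE))
}

#' Collapse probes to genes
#'
#' GEO platforms map several probes to one gene; the paper-style pipeline
#' needs one row per gene. Two collapse rules are offered: keep the probe
#' with the largest sample variance (default) or average probes.
#'
#' @param mat Probe x sample matrix.
#' @param probe_gene Named character vector probe -> gene symbol.
#' @param method "max_variance" or "mean".
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(mat, probe_gene, method = c("max_variance", "mean")) {
  method <- match.arg(method)
  probes <- intersect(rownames(mat), names(probe_gene))
  mat <- mat[probes, , drop = FALSE]
  genes <- probe_gene[probes]
  if (method == "mean") {
    out <- rowsum(mat, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    return(out)
  }
  v <- apply(mat, 1L, stats::var, na.rm = TRUE)
  ord <- order(genes, -v, probes)
  first <- !duplicated(genes[ord])
  sel <- ord[first]
  out <- mat[sel, , drop = FALSE]
  rownames(out) <- genes[sel]
  out[sort(rownames(out)), , drop = FALSE]
}
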