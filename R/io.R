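#' Construct a longitudinal methylation dataset
#'
#' A `meth_dataset` bundles a probe-by-sample value matrix with the sample
#' sheet describing each column (which individual, which age). Every matrix
#' column must have exactly one sample-sheet row and vice versa; columns are
#' reordered to match the sheet.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `age_months`.
#' @param scale `"beta"` (values in `[0,1]`) or `"M"` (unbounded).
#' @return object of class `meth_dataset`: a list with elements `values`,
#'   `samples`, `scale`.
#' @export
meth_dataset <- function(values, samples, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0 || ncol(values) == 0) stop("empty value matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))]
    stop("duplicate probe ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  req <- c("sample_id", "individual_id", "age_months")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns ", paste(req, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  extra_sheet <- setdiff(samples$sample_id, colnames(values))
  extra_mat <- setdiff(colnames(values), samples$sample_id)
  if (length(extra_sheet)) {
    stop("sample(s) in sheet but not in matrix: ",
         paste(extra_sheet, collapse = ", "))
  }
  if (length(extra_mat)) {
    stop("sample(s) in matrix but not in sheet: ",
         paste(extra_mat, collapse = ", "))
  }
  if (!is.numeric(samples$age_months)) stop("age_months must be numeric")
  values <- values[, samples$sample_id, drop = FALSE]
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("beta-scale values outside [0,1]; range [",
           signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
    }
  }
  structure(
    list(values = values,
         samples = data.frame(sample_id = samples$sample_id,
                              individual_id = as.character(samples$individual_id),
                              age_months = samples$age_months,
                              stringsAsFactors = FALSE),
         scale = scale),
    class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf("meth_dataset: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  %d individuals, ages (months): %s\n",
              length(unique(x$samples$individual_id)),
              paste(sort(unique(x$samples$age_months)), collapse = ", ")))
  invisible(x)
}

#' Convert a dataset between beta and M scales
#'
#' @param dataset a [meth_dataset()].
#' @param to target scale, `"M"` or `"beta"`.
#' @return a `meth_dataset` on the requested scale.
#' @export
convert_scale <- function(dataset, to = c("M", "beta")) {
  to <- match.arg(to)
  stopifnot(inherits(dataset, "meth_dataset"))
  if (dataset$scale == to) return(dataset)
  v <- if (to == "M") beta_to_m(dataset$values) else m_to_beta(dataset$values)
  attr(v, "n_clipped") <- NULL
  meth_dataset(v, dataset$samples, scale = if (to == "M") "M" else "beta")
}

#' Read a methylation dataset from disk
#'
#' The matrix is a TSV with probe ids in the first column and one column
#' per sample; the sample sheet is a CSV with columns `sample_id`,
#' `individual_id`, `age_months`. Sample ids must match one-to-one; any
#' mismatch is reported by name. Column order is taken from the sheet, so
#' a read is deterministic regardless of matrix column order.
#'
#' @param matrix_path path to the beta/M value TSV.
#' @param samplesheet_path path to the sample sheet CSV.
#' @param scale scale of the stored values, `"beta"` (default) or `"M"`.
#' @return a [meth_dataset()].
#' @export
read_dataset <- function(matrix_path, samplesheet_path, scale = "beta") {
  for (p in c(matrix_path, samplesheet_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("empty or single-column matrix in ", matrix_path)
  }
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric cells in matrix column(s): ",
         paste(names(vals)[non_num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  sheet <- utils::read.csv(samplesheet_path, stringsAsFactors = FALSE)
  meth_dataset(m, sheet, scale = scale)
}

#' Write a probe-by-sample matrix as TSV
#'
#' Probe ids go in a first column named `probe_id`; full precision is kept
#' so a write/read round trip reproduces the dataset.
#'
#' @param values numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(probe_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Illumina-style probe annotation manifest
#'
#' Expected CSV columns: `probe_id`, `chromosome`, `position`,
#' `island_relation`, `gene` and `region` (semicolon-separated parallel
#' lists for multi-transcript annotations, empty for intergenic probes),
#' `regulatory_feature`, `dhs`, `enhancer`, `dmr_class`. Quoted
#' multi-gene fields (`"GENE1;GENE2"`) are handled by the CSV parser.
#'
#' @param path manifest CSV path.
#' @return data.frame, one row per probe.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "chromosome", "position", "island_relation",
           "gene", "region")
  miss <- setdiff(req, names(mf))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  mf$gene[is.na(mf$gene)] <- ""
  mf$region[is.na(mf$region)] <- ""
  mf
}

#' Expand a manifest's gene annotations to long form
#'
#' One row per (probe, gene, region) annotation. Probes with no gene
#' annotation are emitted once with `gene = NA` and `region =
#' "Intergenic"`, so downstream category counts can include the
#' intergenic class.
#'
#' @param manifest data.frame as returned by [read_manifest()].
#' @return data.frame with columns `probe_id`, `gene`, `region`.
#' @export
expand_gene_annotations <- function(manifest) {
  genes <- strsplit(manifest$gene, ";", fixed = TRUE)
  regions <- strsplit(manifest$region, ";", fixed = TRUE)
  n <- vapply(genes, length, integer(1))
  nr <- vapply(regions, length, integer(1))
  if (any(n != nr)) {
    stop("gene and region annotation lists differ in length for probe(s): ",
         paste(utils::head(manifest$probe_id[n != nr], 5), collapse = ", "))
  }
  keep <- n > 0
  long <- data.frame(
    probe_id = rep(manifest$probe_id[keep], n[keep]),
    gene = unlist(genes[keep]),
    region = unlist(regions[keep]),
    stringsAsFactors = FALSE)
  if (any(!keep)) {
    long <- rbind(long, data.frame(
      probe_id = manifest$probe_id[!keep],
      gene = NA_character_,
      region = "Intergenic",
      stringsAsFactors = FALSE))
  }
  long[order(match(long$probe_id, manifest$probe_id)), , drop = FALSE]
}

#' Read a SNP-in-probe table
#'
#' CSV columns: `probe_id`, `distance_to_query_bp`, `maf`. MAF must lie
#' in `[0, 0.5]` and distance must be non-negative.
#'
#' @param path CSV path.
#' @return data.frame of SNP records (several rows per probe allowed).
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  snp <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "distance_to_query_bp", "maf")
  miss <- setdiff(req, names(snp))
  if (length(miss)) stop("SNP table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(snp$maf) || anyNA(snp$maf) ||
      any(snp$maf < 0 | snp$maf > 0.5)) {
    stop("malformed MAF: values must be numeric in [0, 0.5]")
  }
  if (any(snp$distance_to_query_bp < 0)) stop("negative SNP distance")
  snp
}

#' Read a cell-type classifier probe list
#'
#' Plain text, one probe id per line.
#'
#' @param path file path.
#' @return character vector of probe ids.
#' @export
read_classifier_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  unique(ids)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}
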