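#' Read a 10x-style count matrix directory
#'
#' Loads one sample's genes x cells counts from a directory holding a
#' Matrix-Market triplet file (`matrix.mtx` or `matrix.mtx.gz`, genes as
#' rows) plus `features.tsv` and `barcodes.tsv` sidecars. The feature table
#' may have one to three columns; the first column is the gene identifier
#' used internally.
#'
#' @param path Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (optionally gzipped).
#' @param sample_id Sample identifier to attach; defaults to the directory
#'   name.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path, sample_id = basename(normalizePath(path))) {
  if (!dir.exists(path)) stop_format(sprintf("no such directory: %s", path))
  find1 <- function(stem) {
    for (f in file.path(path, c(stem, paste0(stem, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop_format(sprintf("missing %s in %s", stem, path))
  }
  mtx <- Matrix::readMM(find1("matrix.mtx"))
  feats <- utils::read.table(find1("features.tsv"), sep = "\t",
                             header = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
  bcs <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                           header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(feats) != nrow(mtx)) {
    stop_format(sprintf("features.tsv has %d rows but matrix header declares %d genes",
                        nrow(feats), nrow(mtx)))
  }
  if (nrow(bcs) != ncol(mtx)) {
    stop_format(sprintf("barcodes.tsv has %d rows but matrix header declares %d cells",
                        nrow(bcs), ncol(mtx)))
  }
  v <- if (inherits(mtx, "sparseMatrix")) mtx@x else as.numeric(mtx)
  if (length(v) && min(v) < 0) stop_format("matrix contains negative values")
  if (length(v) && any(v != floor(v))) stop_format("matrix contains non-integer values")
  mtx <- methods::as(mtx, "CsparseMatrix")
  dimnames(mtx) <- list(feats[[1]], bcs[[1]])
  count_matrix(sample_id, mtx)
}

#' Write a count matrix as a 10x-style directory
#'
#' Writes `matrix.mtx` (Matrix-Market coordinate integer format, 1-based
#' indices, genes as rows), `features.tsv` and `barcodes.tsv` under `path`.
#' `read_count_matrix(write_count_matrix(x, path))` reproduces `x`.
#'
#' @param x A [count_matrix()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(x$counts, "TsparseMatrix")
  con <- file(file.path(path, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))
  ), con)
  if (length(m@x)) {
    o <- order(m@j, m@i)
    writeLines(sprintf("%d %d %d", m@i[o] + 1L, m@j[o] + 1L, as.integer(m@x[o])), con)
  }
  writeLines(rownames(m), file.path(path, "features.tsv"))
  writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' A gene-set collection is a tibble with columns `set`, `description` and
#' `gene`, one row per member gene, genes in within-set order. The GMT format
#' is one line per set: name, description, then tab-separated gene ids.
#'
#' @param x Gene-set tibble (columns `set`, `description`, `gene`).
#' @param path File path.
#' @return `read_gene_sets()` returns the gene-set tibble;
#'   `write_gene_sets()` returns `path` invisibly.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(all(c("set", "description", "gene") %in% names(x)))
  if (any(grepl("\t", c(x$set, x$description, x$gene)))) {
    stop_format("set names, descriptions and gene ids must not contain tabs")
  }
  sets <- split(seq_len(nrow(x)), factor(x$set, levels = unique(x$set)))
  lines <- vapply(names(sets), function(s) {
    rows <- sets[[s]]
    paste(c(s, x$description[rows[1]], x$gene[rows]), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(set = character(), description = character(), gene = character()))
  }
  purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_format("GMT line has fewer than 3 fields")
    tibble(set = f[1], description = f[2], gene = f[-(1:2)])
  })
}

#' Read and write the sample manifest
#'
#' The manifest is a tibble with columns `sample_id`, `path` and `group`,
#' serialized as YAML. Sample ids must be unique and, at read time, every
#' path must resolve to an existing directory.
#'
#' @param x Manifest tibble.
#' @param path YAML file path.
#' @param check_paths Verify that matrix directories exist (default TRUE on
#'   read).
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(x, path) {
  stopifnot(all(c("sample_id", "path", "group") %in% names(x)))
  if (anyDuplicated(x$sample_id)) stop_format("manifest sample_ids must be unique")
  entries <- purrr::pmap(x[c("sample_id", "path", "group")], function(sample_id, path, group) {
    list(sample_id = sample_id, path = path, group = group)
  })
  yaml::write_yaml(list(samples = entries), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop_format("manifest has no `samples` entry")
  m <- purrr::map_dfr(y$samples, function(e) {
    tibble(sample_id = e$sample_id, path = e$path,
           group = e$group %||% "default")
  })
  if (anyDuplicated(m$sample_id)) stop_format("manifest sample_ids must be unique")
  if (check_paths) {
    rel <- !dir.exists(m$path)
    if (any(rel)) {
      # resolve relative to the manifest's own directory
      alt <- file.path(dirname(path), m$path[rel])
      ok <- dir.exists(alt)
      if (any(!ok)) {
        stop_format(sprintf("manifest path not found: %s",
                            paste(m$path[rel][!ok], collapse = ", ")))
      }
      m$path[rel] <- alt
    }
  }
  m
}

#' Write and read a cells-by-programs score table as CSV
#'
#' The CSV has a header row of program (or meta-program) ids and a first
#' column `cell_id`; `read_score_csv(write_score_csv(m))` returns the same
#' matrix.
#'
#' @param m Numeric matrix with cell ids as rownames and program ids as
#'   colnames.
#' @param path CSV path.
#' @param id_col Name of the identifier column (default `"cell_id"`;
#'   `"program_id"` for program-by-program correlation matrices).
#' @return `read_score_csv()` returns the matrix.
#' @export
write_score_csv <- function(m, path, id_col = "cell_id") {
  df <- tibble::as_tibble(as.data.frame(m), rownames = id_col)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_score_csv
#' @export
read_score_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Write and read generator ground truth as JSON
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param path JSON path.
#' @return `read_ground_truth()` returns the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(program_genes = truth$program_genes,
         program_info = truth$program_info,
         cell_activity = truth$cell_activity),
    path, dataframe = "columns", digits = NA
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      program_genes = as_tibble(j$program_genes),
      program_info = as_tibble(j$program_info),
      cell_activity = as_tibble(j$cell_activity)
    ),
    class = "ground_truth"
  )
}
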