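# Readers/writers and provenance serialization.
#
# Conventions: genes are rows everywhere. Counts travel either as TSV
# (first column = gene id, header = sample ids, tab-separated, no quoting)
# or as MatrixMarket (genes x samples) with sidecar label files
# `<path>.genes.txt` / `<path>.samples.txt`, one label per line. Designs
# and coefficients are headered numeric TSV. Permutations are serialized
# 0-based with the convention: applied design row n = design row perm[n].

#' Read a count matrix
#'
#' @param path File path.
#' @param format `"tsv"` (first column gene ids, header sample ids) or
#'   `"mtx"` (MatrixMarket plus `<path>.genes.txt` / `<path>.samples.txt`
#'   sidecars).
#'
#' @return A validated genes x samples numeric matrix with dimnames.
#'   Negative, missing, or non-integer entries are rejected with the
#'   offending gene and sample named in the error.
#'
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (ncol(dt) < 3L) {
      stop("counts TSV needs a gene-id column plus >= 2 sample columns",
           call. = FALSE)
    }
    mat <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      stop("counts TSV contains non-numeric entries", call. = FALSE)
    }
    rownames(mat) <- as.character(dt[[1L]])
  } else {
    m <- Matrix::readMM(path)
    mat <- as.matrix(m)
    genes_file <- paste0(path, ".genes.txt")
    samples_file <- paste0(path, ".samples.txt")
    if (file.exists(genes_file)) {
      rownames(mat) <- readLines(genes_file)
    }
    if (file.exists(samples_file)) {
      colnames(mat) <- readLines(samples_file)
    }
  }
  validate_counts(mat, arg = basename(path))
}

#' Write a count matrix
#'
#' @inheritParams read_counts
#' @param mat Genes x samples count matrix.
#'
#' @return Invisibly, `path`.
#' @export
write_counts <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  mat <- validate_counts(mat)
  if (format == "tsv") {
    dt <- data.table::data.table(gene = rownames(mat))
    dt <- cbind(dt, data.table::as.data.table(mat))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), paste0(path, ".genes.txt"))
    writeLines(colnames(mat), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read / write a design or coefficient matrix (headered numeric TSV)
#'
#' @param path File path.
#' @return `read_design()`: a numeric matrix. `write_design()`: `path`,
#'   invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  mat <- as.matrix(dt)
  if (!is.numeric(mat)) {
    stop(basename(path), " contains non-numeric entries", call. = FALSE)
  }
  mat
}

#' @rdname read_design
#' @param mat Numeric matrix (or vector, written as one column).
#' @export
write_design <- function(mat, path) {
  if (is.vector(mat)) mat <- matrix(mat, ncol = 1L)
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("col_", seq_len(ncol(mat)))
  }
  data.table::fwrite(data.table::as.data.table(mat), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize a thinning result directory
#'
#' `write_result()` writes the thinned counts, every design and coefficient
#' block that is present, the row-offset vector `e`, and a `result.json`
#' holding the seed, the permutation (0-based), the target correlation, and
#' the file inventory. `read_result()` reconstructs the `"thin_result"`
#' (including the `q` matrix, rebuilt from the stored blocks and offsets).
#'
#' @param result A `"thin_result"` from [thin_diff()] or [thin_2group()].
#' @param dir Output directory (created if missing).
#' @param format Count-matrix format, `"tsv"` or `"mtx"`.
#'
#' @return `write_result()`: the path of `result.json`, invisibly.
#'   `read_result()`: a `"thin_result"`.
#'
#' @export
write_result <- function(result, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "thin_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_file <- paste0("counts.", if (format == "tsv") "tsv" else "mtx")
  write_counts(result$counts, file.path(dir, counts_file), format = format)
  files <- list(counts = counts_file)
  for (blk in c("design_fixed", "coef_fixed", "design_perm",
                "design_perm_applied", "coef_perm")) {
    if (!is.null(result[[blk]])) {
      f <- paste0(blk, ".tsv")
      write_design(result[[blk]], file.path(dir, f))
      files[[blk]] <- f
    }
  }
  write_design(matrix(result$thin_log$e, ncol = 1L,
                      dimnames = list(NULL, "e")),
               file.path(dir, "e.tsv"))
  files$e <- "e.tsv"
  meta <- list(
    format = format,
    files = files,
    seed = result$seed,
    permutation_0based = result$permutation - 1L,
    target_cor = result$target_cor,
    target_cor_used = unclass_no_attr(result$target_cor_used),
    null_mask = result$null_mask,
    group = result$group,
    package_version = as.character(packageVersion("thinsim"))
  )
  path <- file.path(dir, "result.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

unclass_no_attr <- function(x) {
  if (is.null(x)) return(NULL)
  attributes(x) <- attributes(x)["dim"]
  x
}

#' @rdname write_result
#' @export
read_result <- function(dir) {
  meta_path <- file.path(dir, "result.json")
  if (!file.exists(meta_path)) {
    stop("not a result directory (no result.json): ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  counts <- read_counts(file.path(dir, meta$files$counts),
                        format = meta$format)
  blk <- function(name) {
    if (!is.null(meta$files[[name]])) {
      read_design(file.path(dir, meta$files[[name]]))
    }
  }
  e <- as.vector(read_design(file.path(dir, meta$files$e)))
  perm <- as.integer(meta$permutation_0based) + 1L
  design_fixed <- blk("design_fixed")
  coef_fixed <- blk("coef_fixed")
  design_perm <- blk("design_perm")
  design_perm_applied <- blk("design_perm_applied")
  coef_perm <- blk("coef_perm")
  g <- nrow(counts)
  n <- ncol(counts)
  if (is.null(design_fixed) && is.null(design_perm)) {
    thin_log <- structure(list(q = matrix(0, g, n), e = e),
                          class = "thin_log")
  } else {
    thin_log <- build_thin_log(coef_fixed = coef_fixed,
                               design_fixed = design_fixed,
                               coef_perm = coef_perm,
                               design_perm = design_perm, perm = perm)
  }
  res <- new_thin_result(counts = counts, thin_log = thin_log,
                         permutation = perm,
                         design_fixed = design_fixed,
                         coef_fixed = coef_fixed,
                         design_perm = design_perm,
                         design_perm_applied = design_perm_applied,
                         coef_perm = coef_perm,
                         target_cor = to_matrix_or_null(meta$target_cor),
                         target_cor_used = to_matrix_or_null(meta$target_cor_used),
                         seed = meta$seed)
  res$null_mask <- if (!is.null(meta$null_mask)) as.logical(meta$null_mask)
  res$group <- meta$group
  res
}

to_matrix_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.matrix(x)) x <- matrix(unlist(x), nrow = length(x), byrow = TRUE)
  x
}

# ---- run manifests ----------------------------------------------------

#' Write and replay run manifests
#'
#' Every CLI run writes a `manifest.json` to its output directory holding
#' the exact argument vector, the package version, and a timestamp.
#' `replay_manifest()` re-executes the stored command (optionally
#' redirecting `--out`), reproducing the outputs bit-exactly because every
#' source of randomness is governed by the stored `--seed`.
#'
#' @param manifest Path to a `manifest.json`.
#' @param out Optional replacement output directory.
#'
#' @return The output directory of the replayed run, invisibly.
#'
#' @export
replay_manifest <- function(manifest, out = NULL) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  argv <- as.character(m$argv)
  if (!is.null(out)) {
    i <- which(argv == "--out")
    if (length(i) == 1L && i < length(argv)) {
      argv[i + 1L] <- out
    } else {
      argv <- c(argv, "--out", out)
    }
  }
  thinsim_cli(argv)
  i <- which(argv == "--out")
  invisible(if (length(i) == 1L) argv[i + 1L] else NULL)
}

write_manifest <- function(dir, argv) {
  meta <- list(argv = as.character(argv),
               package_version = as.character(packageVersion("thinsim")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE)
  invisible(path)
}
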