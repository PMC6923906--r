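#' Construct an expression matrix
#'
#' Canonical container: genes as rows, samples as columns, unique ids on
#' both axes, with a `transform` attribute recording any normalization
#' already applied.
#'
#' @param values Numeric matrix.
#' @param gene_ids,sample_ids Optional identifier vectors (default taken
#'   from dimnames, or generated).
#' @return Numeric matrix of class `m3s_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  gene_ids <- gene_ids %||% rownames(m) %||% paste0("gene", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% colnames(m) %||%
    paste0("sample", seq_len(ncol(m)))
  if (length(gene_ids) != nrow(m) || length(sample_ids) != ncol(m))
    stop_m3s("dim_mismatch", "id lengths do not match matrix dimensions")
  for (ids in list(g = gene_ids, s = sample_ids)) {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0)
      stop_m3s("duplicate_ids", "duplicate identifiers: ",
               paste(utils::head(dup, 5), collapse = ", "))
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  attr(m, "transform") <- attr(values, "transform") %||% "none"
  class(m) <- c("m3s_matrix", class(matrix()))
  m
}

#' Read an expression matrix from TSV/CSV or a MatrixMarket directory
#'
#' TSV/CSV files need a header row of sample ids and a first column of gene
#' ids; gzip is handled transparently. A MatrixMarket directory follows the
#' CellRanger layout: `matrix.mtx[.gz]` plus `features.tsv`/`genes.tsv` and
#' `barcodes.tsv` (optionally gzipped), genes x cells, 1-based coordinates.
#'
#' @param path File (TSV/CSV) or directory (MTX) path.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx_dir"`.
#' @param transpose Transpose after reading (for samples-as-rows files).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx_dir"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_m3s("io", "no such file or directory: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  m <- if (format == "mtx_dir") read_mtx_dir(path) else {
    dt <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                            header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1]])
    mm <- as.matrix(dt[, -1, drop = FALSE])
    rownames(mm) <- ids
    mm
  }
  if (transpose) m <- t(m)
  expression_matrix(m)
}

read_mtx_dir <- function(dir) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop_m3s("io", "none of ", paste(cands, collapse = "/"), " found in ", dir)
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv",
                  "genes.tsv.gz"))
  bc <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- as.matrix(Matrix::readMM(mtx))
  features <- data.table::fread(feat, header = FALSE, data.table = FALSE)
  barcodes <- data.table::fread(bc, header = FALSE, data.table = FALSE)
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m))
    stop_m3s("dim_mismatch", "mtx is ", nrow(m), " x ", ncol(m),
             " but features/barcodes have ", nrow(features), "/",
             nrow(barcodes), " rows")
  rownames(m) <- as.character(features[[1]])
  colnames(m) <- as.character(barcodes[[1]])
  m
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x != 0 & (abs(x) < 1e-4 | abs(x) >= 1e6),
                formatC(x, format = "e", digits = 5),
                formatC(signif(x, 6), format = "fg", digits = 6,
                        flag = "#")))
}

#' Write selection or DE results to TSV
#'
#' Selection results produce one row per gene with the chosen model and,
#' for every examined model, its KS p-value, KS FDR and fitted parameters
#' (`key=value` pairs joined by semicolons). DE results are written as a
#' flat table. Floats carry 6 significant digits; small p-values use
#' scientific notation.
#'
#' @param results An `m3s_result` or `m3s_detest` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- if (inherits(results, "m3s_result")) selection_table(results)
    else if (inherits(results, "m3s_detest")) {
      d <- as.data.frame(results)
      d$p_value <- fmt_num(d$p_value)
      d$fdr <- fmt_num(d$fdr)
      d
    } else stop_m3s("invalid_data", "unsupported results object")
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_m3s("io", "cannot write to ", path)
  invisible(path)
}

#' Flatten an `m3s_result` into the output table
#' @param results An `m3s_result`.
#' @return data.frame: gene, best_model, n_peaks, adequate, then per-model
#'   `<model>_ks_p`, `<model>_ks_fdr`, `<model>_params` columns.
#' @export
selection_table <- function(results) {
  df <- results$summary
  mods <- unique(unlist(lapply(results$fits, names)))
  mods <- mods[order(model_rank(mods))]
  for (mod in mods) {
    pv <- vapply(results$fits, function(g) {
      f <- g[[mod]]
      if (is.null(f)) NA_real_ else f$ks_pvalue
    }, numeric(1))
    fdr <- vapply(results$fits, function(g) {
      f <- g[[mod]]
      if (is.null(f)) NA_real_ else f$ks_fdr
    }, numeric(1))
    par <- vapply(results$fits, function(g) {
      f <- g[[mod]]
      if (is.null(f)) "NA" else format_params(f$params)
    }, character(1))
    df[[paste0(mod, "_ks_p")]] <- fmt_num(pv)
    df[[paste0(mod, "_ks_fdr")]] <- fmt_num(fdr)
    df[[paste0(mod, "_params")]] <- par
  }
  df
}

#' Timestamped log line on stderr
#' @param module Emitting module name.
#' @param ... Message parts.
#' @keywords internal
m3s_log <- function(module, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", module, "] ", ...)
}
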