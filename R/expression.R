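#' Single-cell expression container
#'
#' A light container for a gene x cell UMI count matrix with one cell-type
#' label and one condition label per cell. Counts are stored sparsely
#' (`Matrix::dgCMatrix`).
#'
#' @param counts gene x cell non-negative integer matrix (sparse or dense).
#' @param gene_ids,cell_ids ordered character ids matching the matrix
#'   dimensions.
#' @param cell_type,condition one label per cell.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_ids, cell_ids, cell_type,
                              condition) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) == 0) stop("no cells in expression matrix")
  if (nrow(counts) == 0) stop("no genes in expression matrix")
  if (length(gene_ids) != nrow(counts)) {
    stop("counts have ", nrow(counts), " rows but ", length(gene_ids),
         " gene ids")
  }
  if (length(cell_ids) != ncol(counts)) {
    stop("counts have ", ncol(counts), " columns but ", length(cell_ids),
         " cell ids")
  }
  if (length(cell_type) != ncol(counts) || length(condition) != ncol(counts)) {
    stop("counts have ", ncol(counts), " cells but labels cover ",
         length(cell_type), " cell types / ", length(condition),
         " conditions")
  }
  if (any(counts < 0)) stop("negative counts")
  if (anyNA(cell_type) || anyNA(condition)) {
    stop("every cell needs exactly one cell_type and one condition label")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 cell_type = as.character(cell_type),
                 condition = as.character(condition)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell types:", paste(sort(unique(x$cell_type)), collapse = " "), "\n")
  cat("conditions:", paste(sort(unique(x$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Read single-cell counts from a sparse-triplet fixture
#'
#' Reads a MatrixMarket triplet (genes x cells), gene and cell id files (one
#' id per line), and a tab-separated label table with columns `cell_id`,
#' `cell_type`, `condition` covering every cell.
#'
#' @param matrix_path MatrixMarket (`.mtx`) counts file.
#' @param genes_path,cells_path one id per line, ordered as in the matrix.
#' @param labels_path TSV with header `cell_id`, `cell_type`, `condition`.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(matrix_path, genes_path, cells_path,
                            labels_path) {
  for (p in c(matrix_path, genes_path, cells_path, labels_path)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  counts <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (ncol(counts) == 0) stop("no cells in ", matrix_path)
  if (nrow(counts) != length(genes)) {
    stop("counts have ", nrow(counts), " rows but ", length(genes),
         " gene ids in ", genes_path)
  }
  if (ncol(counts) != length(cells)) {
    stop("counts have ", ncol(counts), " columns but ", length(cells),
         " cell ids in ", cells_path)
  }
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "condition")
  if (!all(need %in% names(lab))) {
    stop("labels file must have columns ", paste(need, collapse = ", "))
  }
  idx <- match(cells, lab$cell_id)
  if (anyNA(idx)) {
    stop("labels file missing cell id: ",
         paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  }
  expression_matrix(counts, genes, cells,
                    cell_type = lab$cell_type[idx],
                    condition = lab$condition[idx])
}

#' Retain cell types with enough cells per condition
#'
#' Mirrors the study-design rule that small clusters absent from one of the
#' compared conditions are excluded from the multi-cell models: a cell type
#' is retained when it has at least `min_cells` cells in every condition
#' (`require_shared = TRUE`) or per condition separately otherwise.
#'
#' @param matrix an `expression_matrix`.
#' @param min_cells minimum cluster size (default 50).
#' @param require_shared require the threshold in every condition.
#' @return a tibble with columns `condition`, `cell_type`, `n_cells`,
#'   restricted to retained combinations.
#' @export
filter_cell_types <- function(matrix, min_cells = 50, require_shared = TRUE) {
  stopifnot(min_cells >= 1)
  tab <- table(condition = matrix$condition, cell_type = matrix$cell_type)
  keep_type <- if (require_shared) {
    colnames(tab)[apply(tab >= min_cells, 2, all)]
  } else NULL
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("condition", "cell_type", "n_cells")
  if (require_shared) {
    df <- df[df$cell_type %in% keep_type, , drop = FALSE]
  } else {
    df <- df[df$n_cells >= min_cells, , drop = FALSE]
  }
  df <- df[df$n_cells > 0, , drop = FALSE]
  if (!nrow(df)) warning("no cell type passes the retention rule")
  df <- df[order(df$condition, df$cell_type), , drop = FALSE]
  tibble::as_tibble(df)
}

#' Pseudobulk expression of one cell-type/condition stratum
#'
#' Per-cell library-size normalization to counts-per-10k followed by a
#' `log2(x + 1)` transform, averaged over the cells of the stratum. Working
#' per cell first and averaging second keeps the value library-size
#' invariant and robust to a few deep cells dominating the mean.
#'
#' @param matrix an `expression_matrix`.
#' @param condition,cell_type stratum labels.
#' @param normalization normalization scheme; only `"mean_cpm_log"` (the
#'   scheme above) is defined.
#' @return named numeric vector, one value per gene.
#' @export
pseudobulk <- function(matrix, condition, cell_type,
                       normalization = "mean_cpm_log") {
  normalization <- match.arg(normalization)
  sel <- matrix$condition == condition & matrix$cell_type == cell_type
  if (!any(sel)) {
    stop("empty stratum: condition ", condition, ", cell type ", cell_type)
  }
  cnt <- matrix$counts[, sel, drop = FALSE]
  libs <- Matrix::colSums(cnt)
  libs[libs == 0] <- 1
  norm <- cnt %*% Matrix::Diagonal(x = 1e4 / libs)
  lg <- log2(as.matrix(norm) + 1)
  stats::setNames(rowMeans(lg), matrix$gene_ids)
}

#' Discretize a pseudobulk profile into a core gene set
#'
#' Splits genes into core (expressed), inactive, and unknown using two
#' thresholds on the distribution of nonzero log-expression values. With a
#' clearly bimodal distribution the upper threshold is placed below the
#' high-expression density peak by twice its half-width at half-maximum
#' (about 2.4 standard deviations for a Gaussian mode, so the expressed
#' component is recovered nearly completely), and the lower threshold one
#' further width below. Unimodal or degenerate distributions fall back to
#' percentile thresholds. Thresholds can be forced through `params` and are
#' reported in the result for run metadata.
#'
#' @param expr named numeric vector of pseudobulk expression values.
#' @param params list of optional entries: `upper`/`lower` (force the
#'   thresholds), `core_quantile` (default 2/3) and `inactive_quantile`
#'   (default 1/3) for the percentile fallback, `peak_min_frac` (default
#'   0.1) minimum relative density height for a mode to count as a peak.
#' @return list with `core` (character), `inactive`, `unknown`, `upper`,
#'   `lower`, `method` (`"density"`, `"percentile"` or `"fixed"`).
#' @export
discretize <- function(expr, params = list()) {
  if (!length(expr)) stop("empty expression vector")
  core_q <- params$core_quantile %||% (2 / 3)
  inact_q <- params$inactive_quantile %||% (1 / 3)
  peak_min_frac <- params$peak_min_frac %||% 0.1
  x <- expr[expr > 0]
  method <- "density"
  if (!is.null(params$upper)) {
    upper <- params$upper
    lower <- params$lower %||% params$upper
    method <- "fixed"
  } else if (length(x) < 8 || stats::sd(x) < 1e-8) {
    if (length(x) && stats::sd(x) < 1e-8) {
      warning("degenerate expression distribution; using percentile rule")
    }
    upper <- if (length(x)) stats::quantile(x, core_q, names = FALSE) else Inf
    lower <- if (length(x)) stats::quantile(x, inact_q, names = FALSE) else Inf
    method <- "percentile"
  } else {
    d <- stats::density(x)
    y <- d$y
    pk <- which(diff(sign(diff(y))) == -2) + 1L
    pk <- pk[y[pk] >= peak_min_frac * max(y)]
    if (length(pk) >= 2) {
      hi <- pk[length(pk)]                    # high-expression mode
      half <- y[hi] / 2
      left <- which(d$y[seq_len(hi)] <= half)
      width <- if (length(left)) d$x[hi] - d$x[max(left)] else stats::sd(x)
      upper <- d$x[hi] - 2 * width
      lower <- upper - 2 * width
    } else {
      upper <- stats::quantile(x, core_q, names = FALSE)
      lower <- stats::quantile(x, inact_q, names = FALSE)
      method <- "percentile"
    }
  }
  upper <- max(upper, 1e-9)   # all-zero genes can never be core
  lower <- min(lower, upper)
  core <- names(expr)[expr > upper]
  inactive <- names(expr)[expr <= lower]
  unknown <- setdiff(names(expr), c(core, inactive))
  list(core = core, inactive = inactive, unknown = unknown,
       upper = unname(upper), lower = unname(lower), method = method)
}

#' Build per-stratum core sets
#'
#' Runs the pseudobulk + discretization + GPR mapping chain for every
#' retained (condition, cell type) stratum, producing the inputs of the
#' multi-cell model builder. The per-stratum cell count is carried along as
#' the FBA weight of that cell type.
#'
#' @param matrix an `expression_matrix`.
#' @param network a `metabolic_network` whose GPR genes the core genes map
#'   onto.
#' @param strata tibble of retained strata as returned by
#'   [filter_cell_types()]; default retains every type with
#'   `min_cells = 1`, `require_shared = FALSE`.
#' @param params discretization parameters, see [discretize()].
#' @return list of `core_set` objects (fields `condition`, `cell_type`,
#'   `core_genes`, `core_reactions`, `n_cells`, `thresholds`).
#' @export
build_core_sets <- function(matrix, network, strata = NULL, params = list()) {
  if (is.null(strata)) {
    strata <- filter_cell_types(matrix, min_cells = 1, require_shared = FALSE)
  }
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    cond <- strata$condition[i]
    ct <- strata$cell_type[i]
    pb <- pseudobulk(matrix, cond, ct)
    disc <- discretize(pb, params)
    core_rxns <- map_core_reactions(network, disc$core)
    out[[i]] <- structure(
      list(condition = cond, cell_type = ct,
           core_genes = sort(disc$core),
           core_reactions = sort(core_rxns),
           n_cells = as.integer(strata$n_cells[i]),
           thresholds = list(upper = disc$upper, lower = disc$lower,
                             method = disc$method)),
      class = "core_set")
  }
  out
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set %s/%s: %d core genes, %d core reactions, %d cells\n",
              x$condition, x$cell_type, length(x$core_genes),
              length(x$core_reactions), x$n_cells))
  invisible(x)
}
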