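#' Construct a paired omics matrix
#'
#' Container for one platform's feature-by-pair measurements with the tumor
#' and normal halves kept aligned: same features in the same order, same
#' pairs in the same order. All downstream paired statistics operate on
#' within-pair differences `tumor - normal`.
#'
#' @param tumor,normal numeric matrices of identical dimension,
#'   features in rows, pairs in columns. Row names are feature ids,
#'   column names are pair ids; if only `tumor` carries dimnames they are
#'   copied to `normal`.
#' @param platform one of `"expression"`, `"methylation"`, `"cnv"`.
#' @param unit measurement unit; defaults to the platform's canonical unit
#'   (`log2_expression`, `methylation_score`, `log_r_ratio`) and must match
#'   it.
#'
#' @return An object of class `paired_omics_matrix`: a list with elements
#'   `platform`, `unit`, `feature_ids`, `pair_ids`, `tumor`, `normal`.
#'   Missing values are `NA`; infinite values are rejected.
#' @export
paired_omics_matrix <- function(tumor, normal, platform, unit = NULL) {
  platform <- match.arg(platform, PLATFORMS)
  if (is.null(unit)) unit <- PLATFORM_UNITS[[platform]]
  if (!identical(unit, PLATFORM_UNITS[[platform]])) {
    stop("unit '", unit, "' inconsistent with platform '", platform, "'")
  }
  tumor <- as.matrix(tumor)
  normal <- as.matrix(normal)
  if (!identical(dim(tumor), dim(normal))) {
    stop("tumor and normal halves must have identical shape")
  }
  storage.mode(tumor) <- "double"
  storage.mode(normal) <- "double"
  if (is.null(rownames(tumor)) && nrow(tumor)) {
    rownames(tumor) <- sprintf("f%d", seq_len(nrow(tumor)))
  }
  if (is.null(colnames(tumor)) && ncol(tumor)) {
    colnames(tumor) <- sprintf("s%d", seq_len(ncol(tumor)))
  }
  if (is.null(rownames(normal))) rownames(normal) <- rownames(tumor)
  if (is.null(colnames(normal))) colnames(normal) <- colnames(tumor)
  if (!identical(rownames(tumor), rownames(normal)) ||
      !identical(colnames(tumor), colnames(normal))) {
    stop("tumor and normal halves must share feature and pair ordering")
  }
  if (anyDuplicated(rownames(tumor))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(tumor))) stop("duplicate pair ids")
  bad <- c(tumor[!is.na(tumor) & !is.finite(tumor)],
           normal[!is.na(normal) & !is.finite(normal)])
  if (length(bad)) stop("non-finite values present; use NA for missing")
  structure(
    list(platform = platform, unit = unit,
         feature_ids = as.character(rownames(tumor)),
         pair_ids = as.character(colnames(tumor)),
         tumor = tumor, normal = normal),
    class = "paired_omics_matrix"
  )
}

#' @export
print.paired_omics_matrix <- function(x, ...) {
  cat("paired_omics_matrix [", x$platform, "/", x$unit, "]: ",
      length(x$feature_ids), " features x ", length(x$pair_ids),
      " tumor/normal pairs\n", sep = "")
  invisible(x)
}

#' @export
dim.paired_omics_matrix <- function(x) {
  c(length(x$feature_ids), length(x$pair_ids))
}

#' Read a paired matrix from TSV
#'
#' The file has a header row; the first column is `feature_id` and every
#' other column is named `<pair>_T` (tumor) or `<pair>_N` (normal). Every
#' pair must contribute both columns. Pair order follows first encounter in
#' the header; feature order follows the file. `NA` marks missing values.
#'
#' @param path path to a tab-separated file.
#' @param platform platform the matrix belongs to (sets the unit).
#' @return a [paired_omics_matrix()].
#' @export
read_matrix <- function(path, platform) {
  platform <- match.arg(platform, PLATFORMS)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (!ncol(raw) || names(raw)[1] != "feature_id") {
    stop("matrix file must start with a 'feature_id' column: ", path)
  }
  sample_cols <- names(raw)[-1]
  is_t <- grepl("_T$", sample_cols)
  is_n <- grepl("_N$", sample_cols)
  if (any(!is_t & !is_n)) {
    stop("column(s) not named <pair>_T or <pair>_N: ",
         paste(sample_cols[!is_t & !is_n], collapse = ", "))
  }
  pair_of <- sub("_[TN]$", "", sample_cols)
  pair_ids <- unique(pair_of)
  t_cols <- setNames(sample_cols[is_t], pair_of[is_t])
  n_cols <- setNames(sample_cols[is_n], pair_of[is_n])
  missing_t <- setdiff(pair_ids, names(t_cols))
  missing_n <- setdiff(pair_ids, names(n_cols))
  if (length(missing_t) || length(missing_n)) {
    stop("pairing error: pair(s) missing a tumor or normal column: ",
         paste(unique(c(missing_t, missing_n)), collapse = ", "))
  }
  if (anyDuplicated(names(t_cols)) || anyDuplicated(names(n_cols))) {
    stop("pairing error: duplicated sample column for a pair")
  }
  feature_ids <- raw[[1]]
  parse_half <- function(cols) {
    m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(pair_ids),
                dimnames = list(feature_ids, pair_ids))
    for (p in pair_ids) {
      txt <- raw[[cols[[p]]]]
      val <- suppressWarnings(as.numeric(txt))
      bad <- which(is.na(val) & !(txt %in% c("NA", "")))
      if (length(bad)) {
        stop("parse error: non-numeric value '", txt[bad[1]],
             "' at row ", bad[1], " (feature ", feature_ids[bad[1]],
             "), column ", cols[[p]])
      }
      m[, p] <- val
    }
    m
  }
  paired_omics_matrix(parse_half(t_cols), parse_half(n_cols), platform)
}

#' Write a paired matrix to TSV
#'
#' Inverse of [read_matrix()]: one `feature_id` column followed by
#' `<pair>_T` and `<pair>_N` columns for every pair (tumor column first).
#' Values are printed with 17 significant digits so the round trip is
#' bit-exact for doubles; missing values are written as `NA`.
#'
#' @param matrix a [paired_omics_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "paired_omics_matrix"))
  fmt <- function(m) {
    out <- sprintf("%.17g", m)
    out[is.na(m)] <- "NA"
    dim(out) <- dim(m)
    out
  }
  tn <- fmt(matrix$tumor)
  nn <- fmt(matrix$normal)
  np <- length(matrix$pair_ids)
  cols <- character(0)
  body <- NULL
  if (np) {
    idx <- rep(seq_len(np), each = 2)
    half <- rep(c("T", "N"), times = np)
    cols <- paste0(matrix$pair_ids[idx], "_", half)
    body <- matrix(NA_character_, nrow = length(matrix$feature_ids),
                   ncol = length(cols))
    for (j in seq_along(cols)) {
      body[, j] <- if (half[j] == "T") tn[, idx[j]] else nn[, idx[j]]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", cols), collapse = "\t"), con)
  if (length(matrix$feature_ids)) {
    lines <- apply(cbind(matrix$feature_ids, body), 1, paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
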