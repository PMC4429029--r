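#' Construct a probe annotation table
#'
#' Maps platform features (expression transcripts, methylation probes,
#' SNP/CN probes) to gene symbols and genomic positions. Coordinates are
#' 0-based, half-open (BED convention). A probe covering several genes
#' appears once per gene; `(platform, probe_id, gene_symbol)` rows are
#' unique.
#'
#' @param chromosome,probe_id,gene_symbol character vectors.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param platform `"expression"`, `"methylation"` or `"cnv"` per row.
#' @param score numeric, carried through from BED input (unused by the
#'   pipeline).
#' @param region_class optional regulatory context per probe
#'   (`promoter`, `cpg_island`, `exon`, `intron`, `intergenic`).
#' @return a `data.frame` of class `probe_annotation` with one row per
#'   (probe, gene) link, input order preserved.
#' @export
probe_annotation <- function(chromosome, start, end, probe_id, score = 0,
                             strand = ".", platform, gene_symbol,
                             region_class = NA_character_) {
  n <- length(probe_id)
  ann <- data.frame(
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    probe_id = as.character(probe_id),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    platform = as.character(platform),
    gene_symbol = as.character(gene_symbol),
    region_class = rep_len(as.character(region_class), n),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (any(!ann$platform %in% PLATFORMS)) {
    stop("format error: unknown platform token(s): ",
         paste(unique(setdiff(ann$platform, PLATFORMS)), collapse = ", "))
  }
  if (any(ann$start < 0L)) stop("coordinate error: start < 0")
  if (any(ann$end <= ann$start)) {
    i <- which(ann$end <= ann$start)[1]
    stop("coordinate error: end <= start for probe ", ann$probe_id[i])
  }
  if (any(!ann$strand %in% c("+", "-", "."))) {
    stop("format error: strand must be one of +, -, .")
  }
  if (any(!is.na(ann$region_class) & !ann$region_class %in% REGION_CLASSES)) {
    stop("format error: unknown region_class")
  }
  if (anyDuplicated(ann[, c("platform", "probe_id", "gene_symbol")])) {
    stop("duplicate (platform, probe_id, gene_symbol) annotation rows")
  }
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read a probe annotation file
#'
#' Tab-separated, no header, BED6 plus two columns:
#' `chrom start end probe_id score strand platform gene_symbol`.
#' Input row order is preserved. A probe mapping to several genes occupies
#' one row per gene.
#'
#' @param path path to the annotation file.
#' @return a [probe_annotation()] table.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) != 8) {
    stop("format error: expected 8 tab-separated columns, found ", ncol(raw))
  }
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  if (anyNA(start) || anyNA(end)) {
    stop("parse error: non-integer coordinate in annotation file")
  }
  score <- suppressWarnings(as.numeric(raw[[5]]))
  score[is.na(score) & raw[[5]] %in% c("NA", ".", "")] <- 0
  probe_annotation(
    chromosome = raw[[1]], start = start, end = end, probe_id = raw[[4]],
    score = score, strand = raw[[6]], platform = raw[[7]],
    gene_symbol = raw[[8]]
  )
}

#' Write a probe annotation file
#'
#' @param ann a [probe_annotation()] table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "probe_annotation"))
  out <- ann[, c("chromosome", "start", "end", "probe_id", "score",
                 "strand", "platform", "gene_symbol")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
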