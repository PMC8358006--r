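## Readers/writers for the plain-text genomics formats the pipeline touches.
## One convention everywhere: 0-based half-open coordinates (BED standard);
## bedGraph gaps mean value 0; output tables are TSV with '#' provenance
## header lines.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file
#'
#' @param path file path.
#' @param min_fields minimum number of tab-separated fields per line
#'   (3 for BED3, 6 for BED6, ...).
#' @return interval data frame sorted by (chrom, start); columns `name` and
#'   `score` are attached when present (fields 4 and 5), `strand` when
#'   present (field 6).
#' @export
read_bed <- function(path, min_fields = 3) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fl <- split_fields(lines)
  nf <- lengths(fl)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": expected >= ",
         min_fields, " fields, got ", nf[bad[1]])
  chrom <- vapply(fl, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ",
         path, ": non-numeric coordinate")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4)) df$name <- vapply(fl, `[[`, "", 4)
  if (all(nf >= 5)) df$score <- suppressWarnings(as.numeric(vapply(fl, `[[`, "", 5)))
  if (all(nf >= 6)) df$strand <- vapply(fl, `[[`, "", 6)
  validate_intervals(df, what = paste0("BED ", path))
  sort_intervals(df)
}

#' Write intervals as BED
#'
#' @param df interval data frame; optional columns `name`, `score`, `strand`
#'   produce BED6 output.
#' @param path destination.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  df <- sort_intervals(df)
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  if (!is.null(df$name) || !is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(
      if (is.null(df$name)) rep(".", nrow(df)) else df$name,
      if (is.null(df$score)) rep("0", nrow(df)) else as.character(df$score),
      if (is.null(df$strand)) rep(".", nrow(df)) else df$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read chromatin loops from a BEDPE file
#'
#' @param path file path; >= 6 fields per line
#'   (chrom1,start1,end1,chrom2,start2,end2, optional name/score).
#' @return data.frame with columns `chrom1,start1,end1,chrom2,start2,end2`,
#'   `score` (NA when absent) and `inter_chrom` flag. Loops are unordered
#'   anchor pairs; both intra- and inter-chromosomal records are retained.
#' @export
read_bedpe <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("empty BEDPE file: ", path)
    return(data.frame(chrom1 = character(0), start1 = numeric(0),
                      end1 = numeric(0), chrom2 = character(0),
                      start2 = numeric(0), end2 = numeric(0),
                      score = numeric(0), inter_chrom = logical(0)))
  }
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 6))
    stop("malformed BEDPE line ", which(nf < 6)[1], " in ", path,
         ": expected >= 6 fields")
  num <- function(i) suppressWarnings(as.numeric(vapply(fl, `[[`, "", i)))
  df <- data.frame(chrom1 = vapply(fl, `[[`, "", 1),
                   start1 = num(2), end1 = num(3),
                   chrom2 = vapply(fl, `[[`, "", 4),
                   start2 = num(5), end2 = num(6),
                   stringsAsFactors = FALSE)
  df$score <- if (all(nf >= 8)) num(8) else NA_real_
  validate_intervals(data.frame(chrom = df$chrom1, start = df$start1,
                                end = df$end1), what = paste0("BEDPE ", path))
  validate_intervals(data.frame(chrom = df$chrom2, start = df$start2,
                                end = df$end2), what = paste0("BEDPE ", path))
  df$inter_chrom <- df$chrom1 != df$chrom2
  df
}

#' @rdname read_bedpe
#' @param loops loop data frame as returned by `read_bedpe`.
#' @export
write_bedpe <- function(loops, path) {
  sc <- ifelse(is.na(loops$score), ".", as.character(loops$score))
  writeLines(paste(loops$chrom1, format_coord(loops$start1),
                   format_coord(loops$end1), loops$chrom2,
                   format_coord(loops$start2), format_coord(loops$end2),
                   ".", sc, sep = "\t"), path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Runs must be non-overlapping within a chromosome; gaps are value 0.
#'
#' @param path file path (4 columns: chrom, start, end, value).
#' @param total_mapped total mapped reads for RPKM scaling (required for
#'   read-derived tracks, ignored for methylation).
#' @param value_bounds optional `c(lo, hi)`; values outside error out
#'   (use `c(0, 1)` for methylation beta values).
#' @return a [coverage_track()] object.
#' @export
read_bedgraph <- function(path, total_mapped = NA, value_bounds = NULL) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(coverage_track(data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0), value = numeric(0)),
                          total_mapped = total_mapped,
                          value_bounds = value_bounds))
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 4))
    stop("malformed bedGraph line ", which(nf < 4)[1], " in ", path,
         ": expected 4 fields")
  df <- data.frame(chrom = vapply(fl, `[[`, "", 1),
                   start = suppressWarnings(as.numeric(vapply(fl, `[[`, "", 2))),
                   end = suppressWarnings(as.numeric(vapply(fl, `[[`, "", 3))),
                   value = suppressWarnings(as.numeric(vapply(fl, `[[`, "", 4))),
                   stringsAsFactors = FALSE)
  coverage_track(df, total_mapped = total_mapped, value_bounds = value_bounds)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path destination.
#' @export
write_bedgraph <- function(track, path) {
  df <- track_runs(track)
  writeLines(paste(df$chrom, format_coord(df$start), format_coord(df$end),
                   format(df$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read gene models
#'
#' Two dialects: `"tsv"` (header `gene_id chrom strand tss tes`, same 0-based
#' convention as BED) and `"bed12"` (name, chromStart/chromEnd as the body,
#' block structure ignored; strand from field 6).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"bed12"`.
#' @return data.frame with columns `gene_id, chrom, strand, tss, tes,
#'   start, end`; `start/end` are the body (`min/max` of tss/tes).
#' @export
read_gene_table <- function(path, dialect = c("tsv", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") {
    df <- read_bed(path, min_fields = 12)
    genes <- data.frame(gene_id = df$name, chrom = df$chrom,
                        strand = df$strand,
                        tss = ifelse(df$strand == "-", df$end, df$start),
                        tes = ifelse(df$strand == "-", df$start, df$end),
                        stringsAsFactors = FALSE)
  } else {
    genes <- read_tsv(path)
    need <- c("gene_id", "chrom", "strand", "tss", "tes")
    if (!all(need %in% names(genes)))
      stop("gene table ", path, " must have columns: ",
           paste(need, collapse = ", "))
    genes$tss <- as.numeric(genes$tss)
    genes$tes <- as.numeric(genes$tes)
  }
  make_gene_models(genes)
}

#' @rdname read_gene_table
#' @param genes data.frame with `gene_id, chrom, strand, tss, tes`.
#' @export
make_gene_models <- function(genes) {
  if (any(duplicated(genes$gene_id)))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         genes$strand[!genes$strand %in% c("+", "-")][1])
  minus <- genes$strand == "-"
  if (any(genes$tss[!minus] >= genes$tes[!minus]) ||
      any(genes$tss[minus] <= genes$tes[minus]))
    stop("tss/tes orientation inconsistent with strand")
  genes$start <- pmin(genes$tss, genes$tes)
  genes$end <- pmax(genes$tss, genes$tes)
  validate_intervals(genes, what = "gene body")
  rownames(genes) <- NULL
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}

#' Read/write tab-separated tables with a provenance header
#'
#' Lines starting with `#` are a provenance header (version, seed,
#' parameters) and are skipped on read; the first non-comment line is the
#' column header.
#'
#' @param path file path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}

#' @rdname read_tsv
#' @param df data.frame to write.
#' @param provenance character vector of header lines (without the leading
#'   `#`); a package-version line is always included.
#' @export
write_tsv <- function(df, path, provenance = character(0)) {
  hdr <- c(paste0("# gsdtools ", as.character(utils::packageVersion("gsdtools")),
                  " | coordinates 0-based half-open"),
           if (length(provenance)) paste0("# ", provenance))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: per line, term id, description, then member genes.
#' @return named list of character vectors (term -> gene ids).
#' @export
read_gmt <- function(path) {
  fl <- split_fields(read_lines_checked(path))
  fl <- fl[lengths(fl) >= 3]
  stats::setNames(lapply(fl, function(f) unique(f[-(1:2)])),
                  vapply(fl, `[[`, "", 1))
}
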