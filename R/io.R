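#' Read a genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' upper-case character sequences named by contig.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Shared validation for interval tables read from disk. Lines are 1-based
# file lines (header/track lines included in the numbering).
#' @noRd
validate_interval_table <- function(dt, line_no, what) {
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 |
                 dt$start >= dt$end)
  if (length(bad))
    stop(what, ": malformed interval at line ", line_no[bad[1]],
         " (need 0 <= start < end)")
  o <- order(dt$chrom, dt$start)
  if (!identical(o, seq_len(nrow(dt)))) {
    first_bad <- which(o != seq_len(nrow(dt)))[1]
    stop(what, ": records not sorted by (chrom, start) at line ",
         line_no[first_bad])
  }
  same <- dt$chrom[-1] == dt$chrom[-nrow(dt)]
  ovl <- which(same & dt$start[-1] < dt$end[-nrow(dt)])
  if (length(ovl))
    stop(what, ": overlapping records at line ", line_no[ovl[1] + 1L])
  invisible(dt)
}

#' @noRd
read_tab_file <- function(path, what, min_cols, header = FALSE) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (header) {
    hdr_line <- which(keep)[1]
    dt <- data.table::fread(text = lines[keep], header = TRUE)
    line_no <- which(keep)[-1]
  } else {
    dt <- data.table::fread(text = lines[keep], header = FALSE)
    line_no <- which(keep)
  }
  if (ncol(dt) < min_cols)
    stop(what, ": expected at least ", min_cols, " columns, found ", ncol(dt))
  attr(dt, "line_no") <- line_no
  dt
}

#' Read a bedGraph track
#'
#' Validates zero-based half-open, sorted, non-overlapping records; errors
#' cite the offending file line. A value of `NA` (serialized by
#' [write_bedgraph()] for masked fragments) is accepted.
#'
#' @param path bedGraph file (track/comment lines are skipped).
#' @return `data.frame` with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  dt <- read_tab_file(path, "bedGraph", 4L)
  dt <- dt[, 1:4]
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), value = as.numeric(value))]
  validate_interval_table(dt, attr(dt, "line_no"), "bedGraph")
  data.table::setDF(dt)
  dt
}

#' Write a bedGraph track
#'
#' Records are sorted by (chrom, start); values use 6 significant digits.
#'
#' @param x `data.frame` with columns chrom, start, end, value.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  dt <- data.table::as.data.table(x)[, c("chrom", "start", "end", "value")]
  data.table::setorder(dt, chrom, start)
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            value = signif(value, 6))]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file, zero-based half-open.
#' @param validate Check sortedness/overlap (on by default; disable for
#'   files such as peak sets where overlap is legitimate).
#' @return `data.frame` with chrom, start, end and any further columns
#'   named name, score, strand.
#' @export
read_bed <- function(path, validate = TRUE) {
  dt <- read_tab_file(path, "BED", 3L)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end))]
  if (validate) validate_interval_table(dt, attr(dt, "line_no"), "BED")
  data.table::setDF(dt)
  dt
}

#' Write a BED file
#' @param x `data.frame`; columns beyond chrom/start/end are written as
#'   name/score/strand in order.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  dt <- data.table::as.data.table(x)
  data.table::setorder(dt, chrom, start)
  num <- vapply(dt, is.numeric, TRUE)
  for (j in which(num & !names(dt) %in% c("start", "end")))
    data.table::set(dt, j = j, value = signif(dt[[j]], 6))
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fragment map as BED4
#'
#' The name column encodes the fragment index with a `_blind` suffix for
#' fragments lacking a secondary-cutter site.
#'
#' @param map A [fragment_map].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  name <- paste0(map$index, ifelse(isTRUE_vec(map$blind), "_blind", ""))
  out <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                    name = name)
  write_bed(out, path)
}

#' @noRd
isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Read a fragment map written by [write_fragment_bed()]
#' @param path BED4 file.
#' @param seqlen Contig length; defaults to the last fragment end.
#' @return A [fragment_map].
#' @export
read_fragment_bed <- function(path, seqlen = NULL) {
  bed <- read_bed(path)
  if (is.null(bed$name)) stop("fragment BED must carry a name column")
  blind <- grepl("_blind$", bed$name)
  new_fragment_map(chrom = bed$chrom, start = bed$start, end = bed$end,
                   blind = blind,
                   seqlen = if (is.null(seqlen)) max(bed$end) else seqlen)
}

#' Read per-fragment count records
#'
#' Four-column TSV (chrom, start, end, count) or bedGraph, one record per
#' fragment or per arbitrary position.
#'
#' @param path TSV/bedGraph file.
#' @return `data.frame` chrom, start, end, count.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  dt <- data.table::fread(text = lines[keep], header = "auto")
  if (ncol(dt) < 4L)
    stop("counts: expected at least 4 columns, found ", ncol(dt))
  dt <- dt[, 1:4]
  data.table::setnames(dt, c("chrom", "start", "end", "count"))
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), count = as.numeric(count))]
  data.table::setDF(dt)
  dt
}

#' Write a TSV table with header
#' @param x `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV table with header
#' @param path Input file.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE))
}
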