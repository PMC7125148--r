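#' Read a BED file of intervals
#'
#' Accepts >= 3 tab-separated columns: chrom, start, end, optionally id
#' (column 4; auto-generated as `"chrom:start-end"` when absent) and
#' strand (column 6).  Coordinates are BED-native 0-based half-open and
#' are kept that way.  Input order is preserved and a subsequent
#' [write_intervals()] round-trips canonical records bit-exactly.
#'
#' @param path path to a BED file.
#' @return Interval data frame (see [genomic_intervals()]).
#' @export
read_intervals <- function(path) {
  lines <- .read_body_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("malformed BED line ", which(n < 3L)[1L], " in ", path,
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": non-integer coordinates or start >= end")
  }
  id <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               NA_character_)
  id[is.na(id) | id == ""] <- sprintf("%s:%d-%d", chrom, start, end)[is.na(id) | id == ""]
  strand <- NULL
  if (any(n >= 6L)) {
    strand <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", "")
  }
  genomic_intervals(chrom, start, end, id, strand)
}

#' Write intervals as BED
#'
#' Emits 4 columns (chrom, start, end, id), or 6 (with score `.` and
#' strand) when a strand column is present.  LF line endings, tab
#' separated.
#'
#' @param intervals interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  if ("strand" %in% names(intervals)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s", intervals$chrom, intervals$start,
                     intervals$end, intervals$id, intervals$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start,
                     intervals$end, intervals$id)
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a BEDPE file of loops
#'
#' Requires >= 6 columns (chrom1, start1, end1, chrom2, start2, end2) with
#' an optional 7th id column.  Inter-chromosomal records are dropped (the
#' count is attached as attribute `n_interchrom_dropped` and reported via
#' a message); anchors are stored left-to-right; records whose anchors
#' overlap after ordering are rejected with a warning.
#'
#' @param path path to a BEDPE file.
#' @return Loop data frame (see [genomic_loops()]).
#' @export
read_loops <- function(path) {
  lines <- .read_body_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6L)) {
    stop("malformed BEDPE line ", which(n < 6L)[1L], " in ", path,
         ": fewer than 6 columns")
  }
  col <- function(k) vapply(fields, `[[`, "", k)
  chrom1 <- col(1L); chrom2 <- col(4L)
  start1 <- suppressWarnings(as.integer(col(2L)))
  end1 <- suppressWarnings(as.integer(col(3L)))
  start2 <- suppressWarnings(as.integer(col(5L)))
  end2 <- suppressWarnings(as.integer(col(6L)))
  if (anyNA(c(start1, end1, start2, end2))) {
    stop("malformed BEDPE line ",
         which(is.na(start1) | is.na(end1) | is.na(start2) | is.na(end2))[1L],
         " in ", path, ": non-integer coordinates")
  }
  id <- ifelse(n >= 7L, vapply(fields, function(f) f[min(7L, length(f))], ""),
               sprintf("loop_%d", seq_along(fields)))
  intra <- chrom1 == chrom2
  n_dropped <- sum(!intra)
  if (n_dropped > 0L) {
    message("read_loops: dropped ", n_dropped, " inter-chromosomal record(s)")
  }
  chrom <- chrom1[intra]
  s1 <- start1[intra]; e1 <- end1[intra]
  s2 <- start2[intra]; e2 <- end2[intra]
  id <- id[intra]
  swap <- s1 > s2
  tmp_s <- s1[swap]; tmp_e <- e1[swap]
  s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
  s2[swap] <- tmp_s; e2[swap] <- tmp_e
  ok <- s1 >= 0L & s1 < e1 & s2 < e2 & e1 <= s2
  if (any(!ok)) {
    warning("read_loops: rejected ", sum(!ok),
            " record(s) with overlapping or invalid anchors")
  }
  out <- genomic_loops(chrom[ok], s1[ok], e1[ok], s2[ok], e2[ok], id[ok])
  attr(out, "n_interchrom_dropped") <- n_dropped
  out
}

#' Write loops as BEDPE
#'
#' @param loops loop data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", loops$chrom, loops$start1,
                   loops$end1, loops$chrom, loops$start2, loops$end2, loops$id)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a features-by-samples count or signal matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids.  Duplicate
#' feature or sample ids and (for raw counts) missing or negative values
#' are rejected.
#'
#' @param path path to a TSV file.
#' @param kind `"raw_counts"` or `"log_normalized"`; stored as the
#'   attribute `kind`.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_matrix <- function(path, kind = c("raw_counts", "log_normalized")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ", ids[anyDuplicated(ids)])
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in ", path, ": ", samples[anyDuplicated(samples)])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    stop("non-numeric cell in ", path, " at feature '", ids[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "'")
  }
  if (kind == "raw_counts") {
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)
      stop("missing value in raw counts at feature '", ids[bad[1L, 1L]],
           "', sample '", samples[bad[1L, 2L]], "'")
    }
    if (any(m < 0) || any(m != round(m))) {
      stop("raw counts must be non-negative integers in ", path)
    }
  }
  dimnames(m) <- list(ids, samples)
  attr(m, "kind") <- kind
  m
}

#' Write a named matrix as TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_col header label of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "feature_id") {
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], trim = TRUE, digits = 15,
                                     scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `condition` and any covariate columns
#' (typically `sex`, `mutation`, `batch`).  For differential analysis the
#' condition must have exactly two levels with at least two samples each.
#'
#' @param path path to a TSV file.
#' @return Data frame of sample metadata.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("sample table must have 'sample_id' and 'condition' columns")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in ", path)
  }
  df
}

#' Write a sample metadata table
#' @param samples sample data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, members.  Lines with fewer than
#' 3 fields are a parse error; duplicate members are de-duplicated; sets
#' left with no members are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of member ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- .read_body_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("malformed GMT line ", which(n < 3L)[1L], " in ", path,
         ": fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][f[-(1:2)] != ""]))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("read_gene_sets: dropped ", sum(empty), " empty set(s): ",
            paste(nm[empty], collapse = ", "))
  }
  out <- stats::setNames(members[!empty], nm[!empty])
  attr(out, "description") <- stats::setNames(desc[!empty], nm[!empty])
  out
}

#' Write gene sets as GMT
#' @param sets named list of member vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# readLines minus empty and track/browser header lines
.read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  drop <- lines == "" | startsWith(lines, "track") | startsWith(lines, "browser") |
    startsWith(lines, "#")
  lines[!drop]
}
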