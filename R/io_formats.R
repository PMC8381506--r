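# Readers and writers for the formats the pipeline touches: FASTA,
# RepeatMasker .out, class-mapping tables and 5-column BED.  All internal
# coordinates are 0-based half-open; conversions happen at the boundary.

#' Read a FASTA file
#'
#' Sequences are uppercased and every non-ACGT symbol (ambiguity codes,
#' gaps) is collapsed to `N`, since downstream encoding knows only the
#' five symbols A, C, G, T, N.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA format error in ", path, ": file is empty")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error in ", path, ": line ", first,
         " does not start a record header ('>')")
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("FASTA format error in ", path, ": no records")
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGT]", "N", seqs)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read a repeat-ID to class mapping table
#'
#' Two-column tab-separated text: repeat identifier (e.g. a RepeatMasker
#' repeat name such as `AluYa5`) and one of the class names `HSAT23`,
#' `ALPHOID`, `ALU`, `LINE1`.  Mapping to the no-repeat class is invalid.
#'
#' @param path Path to the mapping file.
#' @return Named integer vector: repeat id -> class id in 1..4.
#' @export
read_class_mapping <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("repeat_id", "class_name"),
                           colClasses = "character", comment.char = "#")
  ids <- repeat_class_id(tab$class_name)
  if (any(ids == 0L))
    stop("class mapping must not map any repeat id to NOREP")
  stats::setNames(ids, tab$repeat_id)
}

#' Parse a RepeatMasker .out annotation file
#'
#' Expects the standard dialect: three header lines followed by
#' whitespace-delimited columns with 1-based inclusive query coordinates
#' (columns 6/7) and the repeat name in column 10.  Coordinates are
#' converted to 0-based half-open.  Records whose repeat name is absent
#' from `mapping` are dropped; strand is ignored.
#'
#' @param path Path to the .out file.
#' @param mapping Named integer vector from [read_class_mapping()].
#' @return Data frame of annotation records with columns `sequence_name`,
#'   `start`, `end` (0-based half-open), `class_id`, `class_name`,
#'   `source_id`, in file order.
#' @export
parse_repeatmasker_out <- function(path, mapping) {
  if (!file.exists(path)) stop(".out file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 3L) body <- lines[-(1:3)] else body <- character(0)
  keep <- nzchar(trimws(body))
  body_lines <- which(keep)
  recs <- vector("list", length(body_lines))
  k <- 0L
  for (i in body_lines) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(fields) < 10L)
      stop("RepeatMasker format error at line ", i + 3L, " of ", path,
           ": expected >= 10 columns, found ", length(fields))
    begin1 <- suppressWarnings(as.integer(fields[6L]))
    end1 <- suppressWarnings(as.integer(fields[7L]))
    if (is.na(begin1) || is.na(end1))
      stop("RepeatMasker format error at line ", i + 3L, " of ", path,
           ": non-numeric coordinate fields '", fields[6L], "', '",
           fields[7L], "'")
    repname <- fields[10L]
    cls <- mapping[repname]
    if (is.na(cls)) next  # unmapped id: ignored
    k <- k + 1L
    recs[[k]] <- data.frame(sequence_name = fields[5L],
                            start = begin1 - 1L, end = end1,
                            class_id = unname(cls),
                            class_name = repeat_class_name(cls),
                            source_id = repname,
                            stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(sequence_name = character(0), start = integer(0),
                      end = integer(0), class_id = integer(0),
                      class_name = character(0), source_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs[seq_len(k)])
}

#' Convert annotation records to a per-position label track
#'
#' Positions covered by at least one record get that record's class id;
#' where records of different classes overlap, the record appearing later
#' in input order wins (a deterministic tie-break; overlaps are rare in
#' real gold standards).  Uncovered positions are 0.
#'
#' @param records Data frame with `start`, `end` (0-based half-open) and
#'   `class_id` columns.
#' @param sequence_length Length of the track to build.
#' @return Integer vector of length `sequence_length` with values in 0..4.
#' @export
records_to_label_track <- function(records, sequence_length) {
  sequence_length <- as.integer(sequence_length)
  track <- integer(sequence_length)
  if (is.null(records) || nrow(records) == 0L) return(track)
  if (any(records$start < 0L) || any(records$end > sequence_length) ||
      any(records$start >= records$end))
    stop("annotation interval out of range [0, ", sequence_length, ")")
  for (i in seq_len(nrow(records)))
    track[(records$start[i] + 1L):records$end[i]] <- records$class_id[i]
  track
}

#' Write classified segments as BED5
#'
#' Tab-delimited: chrom, start (0-based), end (half-open), class name,
#' integer-rounded score.  Segments must be sorted and non-overlapping
#' per sequence.
#'
#' @param segments Data frame with columns `start`, `end`, `class_id` (or
#'   `class_name`) and `score`; optionally `sequence_name` to override
#'   the `sequence_name` argument per row.
#' @param sequence_name Chromosome/record name used when `segments` has
#'   no `sequence_name` column.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_bed <- function(segments, sequence_name, path) {
  if (is.null(segments) || nrow(segments) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- if ("sequence_name" %in% names(segments))
    segments$sequence_name else rep(sequence_name, nrow(segments))
  cls <- if ("class_name" %in% names(segments))
    segments$class_name else repeat_class_name(segments$class_id)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- segments$start[idx]; e <- segments$end[idx]
    if (is.unsorted(s, strictly = FALSE))
      stop("segments for ", ch, " are not sorted by start")
    if (length(idx) > 1L && any(e[-length(idx)] > s[-1L]))
      stop("segments for ", ch, " overlap")
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d", chrom,
                   as.integer(segments$start), as.integer(segments$end),
                   cls, as.integer(round(segments$score)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of classified segments
#'
#' Accepts 4 or 5 columns (score optional, default 0).  The name column
#' must hold repeat class names.
#'
#' @param path Path to the BED file.
#' @return Data frame with `sequence_name`, `start`, `end`, `class_id`,
#'   `class_name`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sequence_name = character(0), start = integer(0),
                      end = integer(0), class_id = integer(0),
                      class_name = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 4L))
    stop("BED format error in ", path, ": line ", which(ncol < 4L)[1L],
         " has fewer than 4 columns")
  data.frame(
    sequence_name = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    class_id = repeat_class_id(vapply(parts, `[[`, "", 4L)),
    class_name = vapply(parts, `[[`, "", 4L),
    score = vapply(parts, function(p)
      if (length(p) >= 5L) as.numeric(p[[5L]]) else 0, 0),
    stringsAsFactors = FALSE)
}
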