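#' Read long reads from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a tibble with
#' one row per read, normalising the sequence alphabet on the way in: bases
#' are uppercased, `U` is mapped to `T` (so RNA-alphabet input is usable), and
#' every other non-`ACGT` character — IUPAC ambiguity codes included — is
#' collapsed to `N`. Read identifiers are the header token before the first
#' whitespace, matching common aligner behaviour so score tables join cleanly
#' to PAF/SAM records.
#'
#' @param path Path to a FASTA or FASTQ file, plain or gzipped.
#' @param format `"auto"` (default, detected from the file extension, falling
#'   back to the first character of the file), `"fasta"` or `"fastq"`.
#' @param source Provenance tag recorded per read: `"raw"`, `"corrected"` or
#'   `"simulated"`.
#'
#' @return A tibble with columns `read_id` (character), `bases` (character,
#'   alphabet `ACGTN`), `qualities` (character, Sanger Phred+33 string, `NA`
#'   for FASTA input) and `source`.
#'
#' @details A malformed FASTQ record whose quality string length differs from
#'   its sequence length raises an error naming the record number. An empty
#'   file yields a zero-row tibble with a warning.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 a comment", "acgtu", ">r2", "ACRT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           source = c("raw", "corrected", "simulated")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  if (format == "auto") format <- detect_format(path)

  if (file.size(path) == 0L || gz_empty(path)) {
    warn(paste0("empty input file: ", path))
    return(tibble::tibble(
      read_id = character(), bases = character(),
      qualities = character(), source = character()
    ))
  }

  if (format == "fastq") validate_fastq(path)

  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )

  headers <- names(set)
  if (is.null(headers) || anyNA(headers) || any(headers == "")) {
    abort(paste0("record with missing header in ", path))
  }
  ids <- sub("\\s.*$", "", headers)
  bases_raw <- unname(as.character(set))

  quals <- rep(NA_character_, length(set))
  if (format == "fastq") {
    quals <- unname(as.character(S4Vectors::mcols(set)$qualities))
  }
  if (any(nchar(bases_raw) == 0L)) {
    abort(paste0("record ", which(nchar(bases_raw) == 0L)[1],
                 " has an empty sequence in ", path))
  }

  bases <- normalize_bases(bases_raw, context = path)

  tibble::tibble(read_id = ids, bases = bases, qualities = quals,
                 source = source)
}

#' Write reads to FASTA or FASTQ
#'
#' Writes a read tibble (as produced by [read_sequences()] or
#' [simulate_reads()]) back to disk. The round trip
#' `read_sequences(write_sequences(x))` reproduces identifiers, bases and
#' qualities.
#'
#' @param reads Tibble with columns `read_id`, `bases` and (for FASTQ)
#'   `qualities`.
#' @param path Output file path; a `.gz` suffix triggers gzip compression.
#' @param format `"auto"` (from extension), `"fasta"` or `"fastq"`. FASTQ
#'   output requires every read to carry a quality string.
#' @return Invisibly, the number of records written.
#' @export
write_sequences <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path, must_exist = FALSE)
  stopifnot(is.data.frame(reads), all(c("read_id", "bases") %in% names(reads)))

  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  set <- Biostrings::BStringSet(reads$bases)
  names(set) <- reads$read_id
  if (format == "fastq") {
    if (!("qualities" %in% names(reads)) || anyNA(reads$qualities)) {
      abort("fastq output requested but some reads have no qualities")
    }
    q <- Biostrings::BStringSet(reads$qualities)
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta",
                                compress = grepl("\\.gz$", path))
  }
  invisible(nrow(reads))
}

# Structural check of a (4-line-record) FASTQ file. Done before handing the
# file to the Biostrings reader, which accepts records whose quality string
# length disagrees with the sequence length instead of erroring.
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  rec <- 0L
  repeat {
    block <- readLines(con, n = 4L, warn = FALSE)
    if (length(block) == 0L) break
    rec <- rec + 1L
    if (length(block) < 4L) {
      abort(paste0("FASTQ parse error at record ", rec,
                   ": truncated record"))
    }
    if (!startsWith(block[1], "@")) {
      abort(paste0("FASTQ parse error at record ", rec,
                   ": missing @ header"))
    }
    if (!startsWith(block[3], "+")) {
      abort(paste0("FASTQ parse error at record ", rec,
                   ": missing + separator"))
    }
    if (nchar(block[2]) != nchar(block[4])) {
      abort(paste0("FASTQ parse error at record ", rec,
                   ": quality string length ", nchar(block[4]),
                   " != sequence length ", nchar(block[2])))
    }
  }
  invisible(rec)
}

# Uppercase, U->T, anything outside ACGT -> N. One message per file when
# U or ambiguity characters were seen.
normalize_bases <- function(x, context = NULL) {
  up <- toupper(x)
  had_u <- any(grepl("U", up, fixed = TRUE))
  up <- gsub("U", "T", up, fixed = TRUE)
  out <- gsub("[^ACGT]", "N", up)
  if (!is.null(context)) {
    if (had_u) inform(paste0("mapped U -> T in ", context))
    if (any(out != up)) {
      inform(paste0("collapsed non-ACGT characters to N in ", context))
    }
  }
  out
}

detect_format <- function(path, must_exist = TRUE) {
  stem <- sub("\\.(gz|bgz)$", "", path)
  if (grepl("\\.(fq|fastq)$", stem, ignore.case = TRUE)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)$", stem, ignore.case = TRUE)) return("fasta")
  if (must_exist && file.exists(path) && file.size(path) > 0L) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    first <- substr(readLines(con, n = 1L, warn = FALSE), 1L, 1L)
    if (identical(first, "@")) return("fastq")
    if (identical(first, ">")) return("fasta")
    abort(paste0("cannot detect sequence format of ", path,
                 " (first character '", first, "')"))
  }
  abort(paste0("cannot detect sequence format from extension of ", path,
               "; pass format explicitly"))
}

gz_empty <- function(path) {
  if (!grepl("\\.gz$", path)) return(FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  length(readLines(con, n = 1L, warn = FALSE)) == 0L
}
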