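#' Read a DNA FASTA file
#'
#' Reads single- or multi-record FASTA (gzip-compressed files are accepted
#' transparently). Record ids are the first whitespace-delimited token of
#' each header; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA at line 1: expected a '>' header in ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  empty <- which(Biostrings::width(x) == 0L)
  if (length(empty))
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  x
}

# write a data.frame as TSV via a temp file + atomic rename, so failed runs
# leave no partial output behind
.writeTsvAtomic <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  invisible(path)
}

#' Write fragment score table
#'
#' Thirteen tab-separated columns: fragment id, predicted MOB type, then the
#' eleven class scores in the fixed order ([mobClasses()]), printed with
#' four decimal places. Unclassifiable fragments keep the `"unclassified"`
#' sentinel with blank scores.
#'
#' @param predictions Data.frame from [predictMob()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFragmentScores <- function(predictions, path) {
  classes <- mobClasses()
  stopifnot(all(c("fragment_id", "predicted_class", classes) %in%
                  names(predictions)))
  out <- predictions[, c("fragment_id", "predicted_class", classes)]
  for (cl in classes) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.na(v), "", sprintf("%.4f", v))
  }
  .writeTsvAtomic(out, path)
}

#' Write bin score table
#'
#' Bin id, predicted class, then the eleven class scores (four decimals).
#'
#' @param predictions Data.frame from [predictMobBins()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBinScores <- function(predictions, path) {
  classes <- mobClasses()
  out <- predictions[, c("bin_id", "predicted_class", classes)]
  for (cl in classes) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.na(v), "", sprintf("%.4f", v))
  }
  .writeTsvAtomic(out, path)
}

#' Read a fragment-to-bin metatable
#'
#' Two-column TSV mapping fragment ids to bin ids. A header row is
#' auto-detected (first row equal to common header names, or containing
#' the literal tokens `fragment`/`bin`). Fragment ids must be unique.
#'
#' @param path Path to the metatable.
#' @param fragmentIds Optional character vector of known fragment ids; any
#'   metatable fragment missing from it is reported as an error.
#' @return Data.frame with columns `fragment_id`, `bin_id`.
#' @export
readBinMetatable <- function(path, fragmentIds = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty metatable: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed metatable row at line ", bad[1L],
         ": expected 2 tab-separated columns")
  m <- do.call(rbind, fields)
  headerish <- "^(fragment|contig|seq(uence)?|frag)?_?(id|name)?$"
  if ((grepl(headerish, m[1L, 1L], ignore.case = TRUE) &&
       nzchar(m[1L, 1L])) || grepl("^bin_?(id|name)?$", m[1L, 2L],
                                   ignore.case = TRUE))
    m <- m[-1L, , drop = FALSE]
  if (nrow(m) == 0L) stop("metatable has a header but no data rows")
  df <- data.frame(fragment_id = m[, 1L], bin_id = m[, 2L],
                   stringsAsFactors = FALSE)
  dup <- df$fragment_id[duplicated(df$fragment_id)]
  if (length(dup))
    stop("duplicate fragment id(s) in metatable: ",
         paste(unique(dup), collapse = ", "))
  if (!is.null(fragmentIds)) {
    missing <- setdiff(df$fragment_id, fragmentIds)
    if (length(missing))
      stop("metatable fragment(s) absent from FASTA: ",
           paste(missing, collapse = ", "))
  }
  df
}
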