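## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## Normalise interval input (c(start,end), list of pairs, or 2-column
## matrix/data.frame) to an integer matrix with columns start, end.
as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(i) as.integer(i[1:2])))
  if (is.null(dim(x))) x <- matrix(as.integer(x[1:2]), ncol = 2)
  storage.mode(x) <- "integer"
  colnames(x) <- c("start", "end")
  if (any(x[, "end"] < x[, "start"])) {
    stop("interval end precedes start", call. = FALSE)
  }
  x
}

interval_total_length <- function(iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0L) return(0L)
  pos <- unlist(lapply(seq_len(nrow(iv)), function(i) iv[i, 1]:iv[i, 2]))
  length(unique(pos))
}

positions_in_intervals <- function(pos, iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) {
    hit <- hit | (pos >= iv[i, 1] & pos <= iv[i, 2])
  }
  hit
}

## Read/write the package's TSV dialect: tab-separated, header row, UTF-8,
## '.' for empty fields, '#'-prefixed comment lines ignored.
read_tsv_dot <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = ".", comment.char = "#",
                    colClasses = colClasses, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

write_tsv_dot <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

## Stable digest of an R object: md5 of its canonical JSON rendering.
object_digest <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
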