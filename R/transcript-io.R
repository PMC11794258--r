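## Canonical transcript format: UTF-8 tab-separated, one speech act per
## row, fixed leading column order
##   dialogue_id speaker epsilon content act_type x y delta_task
##   delta_interlocutor decisive [delta_<object> ...]
## Tabs/newlines/backslashes inside content are escaped (\t, \n, \\) so a
## row is always one physical line. epsilon is written on its original
## (raw) scale, which may include zero/negative pre-task indices.

TRANSCRIPT_COLS <- c("dialogue_id", "speaker", "epsilon", "content",
                     "act_type", "x", "y", "delta_task",
                     "delta_interlocutor", "decisive")

escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  # unescape in one pass so literal "\\t" survives round-trip
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", "\\" = "\\",
                             paste0("\\", nxt)))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read an annotated transcript from a tab-separated file
#'
#' Parses the canonical transcript format (header row mandatory; columns
#' `dialogue_id`, `speaker`, `epsilon`, `content`, `act_type`, `x`, `y`,
#' `delta_task`, `delta_interlocutor`, `decisive`, plus any further
#' `delta_<object>` columns) and returns a validated [dialogue()].
#'
#' @param path Path to a UTF-8 TSV transcript.
#' @param validate Passed to [dialogue()].
#' @return A `dialogue` object.
#' @export
#' @examples
#' mc <- read_transcript(system.file("extdata", "monte_cristo.tsv",
#'                                   package = "dialtk"))
#' mc
read_transcript <- function(path, validate = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty transcript file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(TRANSCRIPT_COLS, header)
  if (length(missing_cols))
    stop("transcript header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(lines) < 2L)
    stop("transcript contains a header but no speech acts: ", path,
         call. = FALSE)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_col <- length(header)
  bad <- which(vapply(rows, length, 1L) != n_col)
  if (length(bad))
    stop(sprintf("row %d has %d fields, expected %d", bad[1] + 1L,
                 length(rows[[bad[1]]]), n_col), call. = FALSE)
  m <- do.call(rbind, rows)
  acts <- as.data.frame(m, stringsAsFactors = FALSE)
  names(acts) <- header
  acts$content <- unescape_field(acts$content)
  acts$speaker <- unescape_field(acts$speaker)
  int_cols <- c("epsilon", "x", "y", "decisive",
                grep("^delta_", header, value = TRUE))
  for (col in int_cols) {
    val <- suppressWarnings(as.integer(acts[[col]]))
    if (anyNA(val)) {
      row <- which(is.na(val))[1]
      stop(sprintf("row %d: column '%s' is not an integer ('%s')",
                   row + 1L, col, acts[[col]][row]), call. = FALSE)
    }
    acts[[col]] <- val
  }
  bad_type <- which(!acts$act_type %in% ACT_TYPES)
  if (length(bad_type))
    stop(sprintf("row %d: unknown act type '%s'", bad_type[1] + 1L,
                 acts$act_type[bad_type[1]]), call. = FALSE)
  id <- acts$dialogue_id[1]
  acts$dialogue_id <- NULL
  dialogue(acts, id = id, validate = validate)
}

#' Write a dialogue to the canonical transcript format
#'
#' The written file re-reads (via [read_transcript()]) to an equal
#' dialogue: all annotation fields round-trip bit-exactly and content text
#' is preserved verbatim, including brackets and embedded tabs (escaped).
#'
#' @param d A validated `dialogue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(d, path) {
  stopifnot(inherits(d, "dialogue"))
  acts <- d$acts
  extra <- setdiff(grep("^delta_", names(acts), value = TRUE),
                   c("delta_task", "delta_interlocutor"))
  cols <- c(TRANSCRIPT_COLS, extra)
  out <- data.frame(dialogue_id = d$id,
                    speaker = escape_field(acts$speaker),
                    epsilon = acts$epsilon_raw,
                    content = escape_field(acts$content),
                    act_type = acts$act_type,
                    x = acts$x, y = acts$y,
                    delta_task = acts$delta_task,
                    delta_interlocutor = acts$delta_interlocutor,
                    decisive = acts$decisive,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- acts[[col]]
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Serialize metric series or matrices to TSV or JSON
#'
#' `metric_series` objects and numeric matrices (topological/occupancy)
#' are written either as TSV or as a JSON document. The JSON schema is
#' `{granularity, object, points: [{index, vergence, celerity, n_acts}]}`
#' for series and `{n_y, n_x, cells: [[...by row...]]}` for matrices, with
#' any further attributes (`group`, `n_subjects`) carried alongside.
#'
#' @param x A `metric_series`, a numeric matrix, or a named list of such
#'   objects (written as one JSON document; TSV requires a single object).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (inherits(x, "metric_series")) {
      write.table(as.data.frame(unclass(x)), path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    } else if (is.matrix(x)) {
      write_matrix_tsv(x, path)
    } else stop("TSV output requires a single series or matrix", call. = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(metrics_payload(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

metrics_payload <- function(x) {
  if (inherits(x, "metric_series")) {
    list(granularity = attr(x, "granularity"), object = attr(x, "object"),
         points = as.data.frame(unclass(x)))
  } else if (is.matrix(x)) {
    out <- list(n_y = nrow(x), n_x = ncol(x),
                cells = unname(apply(x, 1, as.vector, simplify = FALSE)))
    for (a in c("group", "n_subjects"))
      if (!is.null(attr(x, a))) out[[a]] <- attr(x, a)
    out
  } else if (is.list(x)) {
    lapply(x, metrics_payload)
  } else x
}

#' Read a JSON metrics document written by [write_metrics()]
#' @param path Path to the JSON file.
#' @return A list (or `metric_series` when the document is a single
#'   series).
#' @export
read_metrics <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(node) {
    if (is.list(node) && !is.null(node$points)) {
      metric_series(node$points$index, node$points$vergence,
                    node$points$celerity, node$points$n_acts,
                    granularity = node$granularity, object = node$object)
    } else if (is.list(node) && !is.null(node$cells)) {
      m <- if (is.matrix(node$cells)) node$cells
           else do.call(rbind, node$cells)
      dimnames(m) <- list(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
      if (!is.null(node$group)) attr(m, "group") <- node$group
      if (!is.null(node$n_subjects)) attr(m, "n_subjects") <- node$n_subjects
      m
    } else if (is.list(node)) lapply(node, rebuild)
    else node
  }
  rebuild(doc)
}

# TSV matrix layout mirrors the topological-matrix convention:
# x as columns, y as rows.
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- paste0("x", seq_len(ncol(m)))
  df <- cbind(y = seq_len(nrow(m)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
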