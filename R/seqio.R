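#' Read a FASTA file into a labeled sequence tibble
#'
#' Reads (possibly multi-line) FASTA into the package's standard sequence
#' table: one row per record with columns `id`, `sequence`, `label` and
#' `length`. Sequences are uppercased and RNA `U` is mapped to `T`, so that
#' downstream encoders only ever see the DNA alphabet (plus whatever
#' non-canonical letters the file contained, which [filter_canonical()]
#' removes). Labels, when a label table is supplied, are joined by `id`;
#' records without an entry keep `NA`.
#'
#' @param path Path to a FASTA file.
#' @param label_table Optional path to a tab-delimited two-column file
#'   (id, class) with no header, as written by [write_labels()].
#' @return A tibble with columns `id` (character), `sequence` (character,
#'   uppercase), `label` (character, `NA` where unlabeled) and `length`
#'   (integer), in file order.
#' @seealso [write_fasta()], [filter_canonical()]
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgu", ">s2", "TTAA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, label_table = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  seqs <- character()
  current <- NULL
  chunks <- character()
  flush <- function() {
    if (!is.null(current)) {
      seqs[length(seqs) + 1] <<- paste(chunks, collapse = "")
      chunks <<- character()
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, ">")) {
      flush()
      id <- strsplit(sub("^>", "", line), "\\s+")[[1]][1]
      if (is.na(id) || id == "") {
        abort(paste0("Malformed FASTA header at line ", i, ": empty identifier"))
      }
      ids[length(ids) + 1] <- id
      current <- id
    } else {
      if (is.null(current)) {
        abort(paste0("Malformed FASTA at line ", i,
                     ": sequence data before any '>' header"))
      }
      if (grepl("[^A-Za-z*.-]", line)) {
        abort(paste0("Malformed FASTA body at line ", i,
                     ": unexpected character in '", line, "'"))
      }
      chunks[length(chunks) + 1] <- line
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("Duplicate FASTA identifier: ", dup))
  }
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  out <- tibble::tibble(
    id = ids,
    sequence = seqs,
    label = NA_character_,
    length = nchar(seqs)
  )
  if (!is.null(label_table)) {
    labs <- read_labels(label_table)
    out$label <- labs$label[match(out$id, labs$id)]
  }
  out
}

#' Read / write a two-column label table
#'
#' Tab-delimited, no header, columns (id, class).
#'
#' @param path File path.
#' @return `read_labels()`: a tibble with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("Label table not found: ", path))
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("id", "label"))
  tibble::as_tibble(df)
}

#' @param data A sequence tibble with at least `id` and `label` columns.
#' @rdname read_labels
#' @export
write_labels <- function(data, path) {
  stopifnot(all(c("id", "label") %in% names(data)))
  utils::write.table(data[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sequence tibble to FASTA
#'
#' @param data A sequence tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 70) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(data))) {
    writeLines(paste0(">", data$id[[i]]), con)
    s <- data$sequence[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Class labels of a sequence dataset
#'
#' @param data A sequence tibble.
#' @return Sorted unique non-missing labels (the class vocabulary, size C).
#' @export
dataset_classes <- function(data) {
  sort(unique(data$label[!is.na(data$label)]))
}

#' Filter sequences to the canonical alphabet and drop small classes
#'
#' Applies the dataset-cleaning policy used for family classification:
#' records containing any letter outside {A, C, G, T} are removed (such
#' sequences are a negligible fraction of real family databases), records
#' longer than `max_len` are removed, and then whole classes whose surviving
#' membership falls below `min_class_size` are dropped so every retained
#' family is sufficiently represented for training. Record order is
#' preserved among survivors and the operation is idempotent.
#'
#' @param data A sequence tibble (see [read_fasta()]).
#' @param max_len Maximum sequence length kept, in nucleotides.
#' @param min_class_size Minimum number of surviving records a class needs
#'   to be retained. Unlabeled records are never dropped by this rule.
#' @return The filtered tibble.
#' @examples
#' d <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACNGT"),
#'                     label = c("x", "x"), length = c(4L, 5L))
#' filter_canonical(d, max_len = 200, min_class_size = 0)
#' @export
filter_canonical <- function(data, max_len = 200, min_class_size = 400) {
  stopifnot(max_len > 0, min_class_size >= 0)
  keep <- !grepl("[^ACGT]", data$sequence) & nchar(data$sequence) <= max_len
  out <- data[keep, , drop = FALSE]
  if (nrow(out) > 0 && min_class_size > 0) {
    counts <- table(out$label)
    small <- names(counts)[counts < min_class_size]
    out <- out[is.na(out$label) | !(out$label %in% small), , drop = FALSE]
  }
  out$length <- nchar(out$sequence)
  out
}
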