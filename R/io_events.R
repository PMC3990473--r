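# Tab-separated mutation event log: one event per line,
#   generation  cell_id  kind  payload
# where payload is a semicolon-separated key=value list. Values are scalars,
# comma-separated integer vectors, or typed scalars ("m:0101" for motifs,
# "c:A" for characters) so the log round-trips and replays exactly.

payload_value <- function(v) {
  if (inherits(v, "vc_motif")) return(paste0("m:", motif_key(v), ":", attr(v, "S")))
  if (is.character(v)) return(paste0("c:", v))
  if (is.integer(v) || (is.numeric(v) && all(v == round(v)) && length(v) > 1L))
    return(paste(as.integer(v), collapse = ","))
  if (is.numeric(v)) return(paste(fmt_num(v), collapse = ","))
  stop("event log: cannot serialize value of class ", class(v)[[1]], call. = FALSE)
}

parse_payload_value <- function(s) {
  if (startsWith(s, "m:")) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    return(parse_motif(parts[[2]], nchar(parts[[2]]), as.integer(parts[[3]])))
  }
  if (startsWith(s, "c:")) return(substring(s, 3L))
  vals <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  if (all(vals == round(vals)) && length(vals) > 1L) return(as.integer(vals))
  vals
}

event_to_line <- function(ev, cell_id = NA_integer_) {
  keys <- setdiff(names(ev), c("kind", "generation"))
  payload <- paste(vapply(keys, function(k)
    paste0(k, "=", payload_value(ev[[k]])), character(1)), collapse = ";")
  paste(fmt_int(ev$generation), fmt_int(cell_id), ev$kind, payload, sep = "\t")
}

line_to_event <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  payload <- list()
  if (length(f) >= 4L && nzchar(f[[4]])) {
    for (kv in strsplit(f[[4]], ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      key <- substring(kv, 1L, eq - 1L)
      payload[[key]] <- parse_payload_value(substring(kv, eq + 1L))
    }
  }
  int_keys <- c("gene_id", "start", "len", "insert_at", "size_before",
                "new_ids", "orig_ids", "gene_ids")
  for (k in intersect(names(payload), int_keys))
    payload[[k]] <- as.integer(payload[[k]])
  ev <- do.call(new_event,
                c(list(kind = f[[3]], generation = int_or_na(f[[1]])), payload))
  attr(ev, "cell_id") <- int_or_na(f[[2]])
  ev
}

#' Write / read a tab-separated mutation event log
#'
#' @param events List of `vc_event`s.
#' @param path File path.
#' @param cell_ids Optional integer vector of cell ids, one per event.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   the list of events (cell ids attached as attribute `cell_id`).
#' @export
write_event_log <- function(events, path, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- rep(NA_integer_, length(events))
  lines <- c("#vce\tv1",
             vapply(seq_along(events), function(i)
               event_to_line(events[[i]], cell_ids[[i]]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, line_to_event)
}
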