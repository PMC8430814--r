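# internal helpers shared across modules

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirtarnet_input_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirtarnet_format_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirtarnet_usage_error", "error")))
}

# Parse sample ids of the form <cellline>_<clone>_<replicate>; the cell line
# may itself contain underscores, so split from the right.
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    stop_format("malformed sample id(s): ", paste(ids[bad], collapse = ", "),
                " (expected <cellline>_<clone>_<replicate>)")
  }
  n <- vapply(parts, length, 1L)
  clone <- mapply(function(p, k) p[[k - 1L]], parts, n)
  rep_tok <- mapply(function(p, k) p[[k]], parts, n)
  cell <- mapply(function(p, k) paste(p[seq_len(k - 2L)], collapse = "_"),
                 parts, n)
  rep_num <- suppressWarnings(as.integer(rep_tok))
  if (anyNA(rep_num)) {
    stop_format("non-integer replicate index in sample id(s): ",
                paste(ids[is.na(rep_num)], collapse = ", "))
  }
  data.frame(sample_id = ids, cell_line = unname(cell),
             clone = unname(clone), replicate = unname(rep_num),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
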